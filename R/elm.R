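# Extreme learning machine: random input weights, analytic minimum-norm
# least-squares output solve beta = pinv(H) %*% T.

#' Activation functions for the hidden layer
#'
#' `sigmoid(z) = 1/(1+exp(-z))`, `sin(z) = sin(z)`, `hardlim(z) = 1` for
#' `z >= 0` and `0` otherwise. `identity` is a linear pass-through, useful for
#' testing because the hidden output matrix then collapses to a product.
#'
#' @param name One of `"sigmoid"`, `"sin"`, `"hardlim"`, `"identity"`.
#' @param z Numeric input (vectorised).
#' @return Transformed values.
#' @export
activation_fn <- function(name, z) {
  switch(name,
         sigmoid  = 1 / (1 + exp(-z)),
         sin      = sin(z),
         hardlim  = ifelse(z >= 0, 1, 0),
         identity = z,
         stop_invalid("unknown activation: ", name))
}

# Per-dimension affine scaling to [-1, 1] from training min/max; constant
# dimensions map to 0. Stored in the model and re-applied at prediction.
scale_fit <- function(X) {
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  centre <- (hi + lo) / 2
  half <- (hi - lo) / 2
  half[half == 0] <- 1
  list(centre = centre, half = half)
}

scale_apply <- function(X, scaling) {
  sweep(sweep(X, 2, scaling$centre, "-"), 2, scaling$half, "/")
}

# Moore-Penrose pseudo-inverse via SVD with the standard relative tolerance.
pseudo_inverse <- function(A, tol = NULL) {
  s <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * max(s$d, 0) * .Machine$double.eps
  pos <- s$d > tol
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, pos, drop = FALSE] %*%
    ((1 / s$d[pos]) * t(s$u[, pos, drop = FALSE]))
}

# Class-label ordering: numeric-like labels sort numerically (so age "7"
# precedes "10"), everything else alphabetically.
sort_classes <- function(labels) {
  u <- unique(as.character(labels))
  num <- suppressWarnings(as.numeric(u))
  if (!anyNA(num)) u[order(num)] else sort(u)
}

one_hot <- function(labels, class_labels) {
  tt <- matrix(0, length(labels), length(class_labels))
  tt[cbind(seq_along(labels), match(labels, class_labels))] <- 1
  tt
}

#' Hidden-layer output matrix of a single-hidden-layer network
#'
#' `H[j, i] = g(w_i . x_j + b_i)` for activation `g`: one row per sample, one
#' column per hidden neuron. Operates on the features as given; callers are
#' responsible for any scaling.
#'
#' @param X `N x p` feature matrix.
#' @param input_weights `n_hidden x p` matrix of hidden-unit weight vectors.
#' @param biases Length-`n_hidden` vector of hidden-unit thresholds.
#' @param activation Activation name (see [activation_fn()]).
#' @return `N x n_hidden` matrix.
#' @export
hidden_output_matrix <- function(X, input_weights, biases,
                                 activation = "sigmoid") {
  X <- as.matrix(X)
  if (ncol(X) != ncol(input_weights)) {
    stop_invalid("feature dimension (", ncol(X), ") does not match input ",
                 "weights (", ncol(input_weights), ")")
  }
  z <- X %*% t(input_weights)
  z <- sweep(z, 2, biases, "+")
  activation_fn(activation, z)
}

#' Train a single-hidden-layer network by the extreme learning machine
#'
#' Input weights and biases are drawn uniformly from `[-1, 1]` under `seed`;
#' the output weights are the analytic minimum-norm least-squares solution
#' `beta = pinv(H) %*% T` against the one-hot target encoding. Features are
#' affinely scaled to `[-1, 1]` per dimension using training min/max, and the
#' scaling is stored in the model.
#'
#' @param X `N x p` feature matrix (`N >= 2`, all finite).
#' @param labels Length-`N` class labels (at least two distinct).
#' @param n_hidden Number of hidden neurons.
#' @param activation Activation name (see [activation_fn()]).
#' @param seed Integer seed for the random input layer.
#' @return An object of class `slfn` with fields `input_weights`, `biases`,
#'   `output_weights`, `activation`, `class_labels`, `scaling`.
#' @export
elm_fit <- function(X, labels, n_hidden, activation = "sigmoid", seed = 1L) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop_invalid("non-finite features")
  if (nrow(X) < 2) stop_invalid("need at least 2 samples")
  class_labels <- sort_classes(labels)
  if (length(class_labels) < 2) {
    stop_invalid("need at least 2 distinct classes")
  }
  p <- ncol(X)
  wb <- with_seed(seed, list(
    W = matrix(runif(n_hidden * p, -1, 1), n_hidden, p),
    b = runif(n_hidden, -1, 1)
  ))
  scaling <- scale_fit(X)
  model <- structure(list(input_weights = wb$W, biases = wb$b,
                          output_weights = NULL, activation = activation,
                          class_labels = class_labels, scaling = scaling),
                     class = "slfn")
  H <- hidden_output_matrix(scale_apply(X, scaling), wb$W, wb$b, activation)
  model$output_weights <- pseudo_inverse(H) %*%
    one_hot(as.character(labels), class_labels)
  model
}

#' Scores or labels from a trained single-hidden-layer network
#'
#' Applies the stored feature scaling, computes `H %*% beta`, and either
#' returns the raw `N x m` score matrix (one column per class) or decodes the
#' argmax label per row, breaking ties toward the lowest class index.
#'
#' @param model An `slfn` from [elm_fit()] or [saelm_fit()].
#' @param X Feature matrix (or single feature vector).
#' @param type `"score"` for the raw score matrix, `"label"` for decoded
#'   class labels.
#' @return Score matrix with class-label column names, or character labels.
#' @export
elm_predict <- function(model, X, type = c("score", "label")) {
  type <- match.arg(type)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  H <- hidden_output_matrix(scale_apply(X, model$scaling),
                            model$input_weights, model$biases,
                            model$activation)
  scores <- H %*% model$output_weights
  colnames(scores) <- model$class_labels
  if (type == "score") return(scores)
  model$class_labels[max.col(scores, ties.method = "first")]
}

# --- serialization: JSON with base64-encoded little-endian doubles, so a
# --- round trip reproduces predictions bit-exactly.

encode_numeric <- function(x) {
  list(dim = as.integer(dim(x) %||% length(x)),
       b64 = jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                           size = 8, endian = "little")))
}

decode_numeric <- function(obj) {
  x <- readBin(jsonlite::base64_dec(obj$b64), "numeric",
               n = prod(obj$dim), size = 8, endian = "little")
  if (length(obj$dim) == 2) dim(x) <- obj$dim
  x
}

#' Serialize a single-hidden-layer network to JSON
#'
#' Weight matrices are stored as base64-encoded IEEE-754 doubles so that
#' [slfn_load()] reproduces the model, and hence its predictions, bit-exactly.
#'
#' @param model An `slfn` object.
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
slfn_save <- function(model, path) {
  stopifnot(inherits(model, "slfn"))
  obj <- list(type = "slfn",
              activation = model$activation,
              class_labels = model$class_labels,
              input_weights = encode_numeric(model$input_weights),
              biases = encode_numeric(model$biases),
              output_weights = encode_numeric(model$output_weights),
              scaling_centre = encode_numeric(model$scaling$centre),
              scaling_half = encode_numeric(model$scaling$half))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname slfn_save
#' @export
slfn_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "slfn")) stop_invalid("not an slfn file: ", path)
  structure(list(input_weights = decode_numeric(obj$input_weights),
                 biases = decode_numeric(obj$biases),
                 output_weights = decode_numeric(obj$output_weights),
                 activation = obj$activation,
                 class_labels = obj$class_labels,
                 scaling = list(centre = decode_numeric(obj$scaling_centre),
                                half = decode_numeric(obj$scaling_half))),
            class = "slfn")
}
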