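# Fuzzy decision fusion: per-classifier membership sets, local (score-gap)
# and global (leave-one-out recall) confidence, and the fuzzy-or compromise
# aggregation.

#' Fusion configuration
#'
#' `gamma` is the compensation degree mixing the max-like (`gamma = 1`) and
#' average-like (`gamma = 0`) behaviour of the fuzzy-or operator; `sigma` is
#' the width of the Gaussian membership function used by the local confidence.
#' Defaults are the deployed settings `gamma = 0.6`, `sigma = 0.05`.
#'
#' @param gamma Compensation degree in `[0, 1]`.
#' @param sigma Positive Gaussian width of the local confidence.
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(gamma = 0.6, sigma = 0.05) {
  if (gamma < 0 || gamma > 1) stop_invalid("gamma must lie in [0, 1]")
  if (sigma <= 0) stop_invalid("sigma must be positive")
  structure(list(gamma = gamma, sigma = sigma), class = "fusion_config")
}

#' Min-max normalize one classifier's raw score vector to a membership set
#'
#' `mu_j = (s_j - min) / (max - min)`, so the winning class gets membership 1
#' and the weakest 0. A degenerate all-equal vector carries no preference and
#' maps to the maximally ambiguous uniform set `1/n`.
#'
#' @param raw_scores Numeric vector of `n >= 2` finite per-class scores.
#' @return Numeric vector in `[0, 1]` of the same length.
#' @export
normalize_scores <- function(raw_scores) {
  if (length(raw_scores) < 2) stop_invalid("need at least 2 classes")
  if (!all(is.finite(raw_scores))) stop_invalid("non-finite scores")
  lo <- min(raw_scores); hi <- max(raw_scores)
  if (hi == lo) return(rep(1 / length(raw_scores), length(raw_scores)))
  (raw_scores - lo) / (hi - lo)
}

#' Local confidence of one classifier decision
#'
#' A decision is reliable when the top score clearly separates from the
#' runner-up relative to the full score range:
#' `w = exp(-0.5 * (|1 - (S1 - S2) / (S1 - Smin)| / sigma)^2)` with `S1`,
#' `S2`, `Smin` the highest, second-highest and lowest raw scores. Computed on
#' the raw (pre-normalization) scores, since min-max normalization would pin
#' `Smin` to 0 and lose the spread information. An all-equal score vector is
#' treated as totally unreliable: `w = exp(-0.5 / sigma^2)`, the formula's
#' value at ratio 0.
#'
#' @param raw_scores Numeric vector of `n >= 2` finite per-class scores.
#' @param sigma Positive Gaussian width (default 0.05).
#' @return Scalar confidence in `(0, 1]`.
#' @export
local_confidence <- function(raw_scores, sigma = 0.05) {
  if (length(raw_scores) < 2) stop_invalid("need at least 2 classes")
  if (!all(is.finite(raw_scores))) stop_invalid("non-finite scores")
  s <- sort(raw_scores, decreasing = TRUE)
  s1 <- s[1]; s2 <- s[2]; smin <- s[length(s)]
  ratio <- if (s1 == smin) 0 else (s1 - s2) / (s1 - smin)
  exp(-0.5 * (abs(1 - ratio) / sigma)^2)
}

#' Global confidence by leave-one-out recall
#'
#' For each classifier (one per vowel group), per-class recall is estimated by
#' leave-one-out cross-validation over its own training samples: the factory
#' refits the classifier without sample `s` and the held-out sample is scored.
#' For every age class the classifier with the highest recall receives global
#' confidence `delta = 1` and all others 0 (ties broken toward the lowest
#' classifier index), so exactly one classifier vouches for each class.
#'
#' @param features_by_group List of `m` feature matrices, one per classifier.
#' @param labels_by_group List of `m` label vectors; every group must contain
#'   every class in `class_labels`.
#' @param class_labels Ordered vector of the age-class labels.
#' @param classifier_factory Function `(X, labels, seed)` returning a model
#'   accepted by [elm_predict()]. Default: a plain ELM with 60 hidden neurons.
#' @param seed Integer seed forwarded (derived per refit) to the factory.
#' @return A list of class `global_confidence` with `delta` (`m x n` binary
#'   matrix) and `recall` (`m x n` leave-one-out recall estimates).
#' @export
global_confidence_loo <- function(features_by_group, labels_by_group,
                                  class_labels,
                                  classifier_factory = NULL, seed = 1L) {
  m <- length(features_by_group)
  stopifnot(m == length(labels_by_group), m >= 1)
  n <- length(class_labels)
  class_labels <- as.character(class_labels)
  if (is.null(classifier_factory)) {
    classifier_factory <- function(X, labels, seed) {
      elm_fit(X, labels, n_hidden = 60, seed = seed)
    }
  }
  recall <- matrix(NA_real_, m, n, dimnames = list(NULL, class_labels))
  for (i in seq_len(m)) {
    X <- as.matrix(features_by_group[[i]])
    y <- as.character(labels_by_group[[i]])
    if (!all(class_labels %in% y)) {
      stop_invalid("group ", i, " is missing some classes")
    }
    pred <- character(nrow(X))
    for (s in seq_len(nrow(X))) {
      model <- classifier_factory(X[-s, , drop = FALSE], y[-s],
                                  seed = derive_seed(seed, i, s))
      pred[s] <- elm_predict(model, X[s, , drop = FALSE], type = "label")
    }
    for (j in seq_len(n)) {
      members <- y == class_labels[j]
      recall[i, j] <- mean(pred[members] == class_labels[j])
    }
  }
  delta <- matrix(0L, m, n, dimnames = list(NULL, class_labels))
  for (j in seq_len(n)) delta[which.max(recall[, j]), j] <- 1L
  structure(list(delta = delta, recall = recall),
            class = "global_confidence")
}

#' Fuse classifier decisions with the fuzzy-or compromise operator
#'
#' For each class `j`,
#' `mu_f_j = gamma * max_i(min(w_i * mu_ij, delta_ij)) +
#'   (1 - gamma) * (1/m) * sum_i(w_i * mu_ij * delta_ij)`.
#' At `gamma = 1` the operator is the confidence-gated max; at `gamma = 0` it
#' is the confidence-weighted arithmetic average. The winner is the argmax of
#' the fused vector, ties broken toward the lowest class index.
#'
#' @param memberships `m x n` matrix of membership sets (rows = classifiers),
#'   entries in `[0, 1]` (see [normalize_scores()]).
#' @param local Length-`m` vector of local confidences (see
#'   [local_confidence()]).
#' @param delta `m x n` binary global-confidence matrix (see
#'   [global_confidence_loo()]); a plain matrix or a `global_confidence`.
#' @param config A [fusion_config()].
#' @param class_labels Optional class labels; defaults to the membership
#'   column names or class indices.
#' @return A list of class `fused_decision` with `fused_values` (length `n`),
#'   `winner` and `winner_index`.
#' @export
fuzzy_or_fuse <- function(memberships, local, delta,
                          config = fusion_config(), class_labels = NULL) {
  memberships <- as.matrix(memberships)
  if (inherits(delta, "global_confidence")) delta <- delta$delta
  delta <- as.matrix(delta)
  m <- nrow(memberships); n <- ncol(memberships)
  if (length(local) != m || !all(dim(delta) == c(m, n))) {
    stop_invalid("mismatched dimensions between memberships, local and delta")
  }
  class_labels <- class_labels %||% colnames(memberships) %||%
    as.character(seq_len(n))
  weighted <- memberships * local           # w_i * mu_ij, rows scaled
  gated_max <- apply(pmin(weighted, delta), 2, max)
  averaged <- colMeans(weighted * delta)
  fused <- config$gamma * gated_max + (1 - config$gamma) * averaged
  winner_index <- which.max(fused)          # which.max: lowest index on ties
  names(fused) <- class_labels
  structure(list(fused_values = fused,
                 winner = class_labels[winner_index],
                 winner_index = winner_index),
            class = "fused_decision")
}

#' Conjunctive or disjunctive combination of membership sets
#'
#' Element-wise `min` (a t-norm: the result never exceeds any input) or
#' element-wise `max` (a t-conorm: the result is at least every input) across
#' a list of membership sets of equal length.
#'
#' @param sets Non-empty list of equal-length membership vectors.
#' @param mode `"conjunctive"` (min) or `"disjunctive"` (max).
#' @return A membership vector of the common length.
#' @export
combine_sets <- function(sets, mode = c("conjunctive", "disjunctive")) {
  mode <- match.arg(mode)
  if (length(sets) == 0) stop_invalid("empty set list")
  lens <- vapply(sets, length, integer(1))
  if (length(unique(lens)) != 1) stop_invalid("membership sets differ in length")
  Reduce(if (mode == "conjunctive") pmin else pmax, sets)
}
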