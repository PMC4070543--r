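# Self-adaptive ELM: DE/rand-to-best/2 differential evolution over the
# concatenated input weights and biases; output weights always solved
# analytically; fitness = RMSE on a held-out validation split.

#' Parameters of the self-adaptive ELM search
#'
#' Defaults follow the study conditions: 40 individuals per generation, 15
#' generations, amplification factor `F = 1`, crossover rate `CR = 0.5`, the
#' `DE/rand-to-best/2` mutation strategy, and 60 hidden neurons. Fitness of an
#' individual is the root-mean-square error of the analytically solved network
#' on a stratified 20% validation split carved from the training set.
#'
#' @param population_size Individuals per generation (>= 6: the mutation
#'   strategy needs five indices distinct from each other and from the target).
#' @param generations Number of DE generations (0 = best of the initial
#'   population, i.e. plain multi-start ELM).
#' @param F Positive amplification factor of the difference vectors.
#' @param CR Crossover rate in `[0, 1]`.
#' @param n_hidden Hidden-layer size.
#' @param activation Activation name (see [activation_fn()]).
#' @param validation_fraction Fraction of training data held out for fitness,
#'   in `(0, 1)`.
#' @param seed Integer seed driving the split, initialisation and evolution.
#' @return An object of class `saelm_params`.
#' @export
saelm_params <- function(population_size = 40, generations = 15, F = 1,
                         CR = 0.5, n_hidden = 60, activation = "sigmoid",
                         validation_fraction = 0.2, seed = 1L) {
  if (population_size < 6) {
    stop_invalid("population too small for 5 distinct mutation indices ",
                 "(need population_size >= 6)")
  }
  if (CR < 0 || CR > 1) stop_invalid("CR must lie in [0, 1]")
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    stop_invalid("validation_fraction must lie in (0, 1)")
  }
  if (generations < 0 || F <= 0) stop_invalid("invalid generations or F")
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 F = F, CR = CR,
                 mutation_strategy = "DE/rand-to-best/2",
                 n_hidden = as.integer(n_hidden),
                 activation = activation,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "saelm_params")
}

# Stratified validation indices; classes with a single sample stay in the
# training part. May be empty on very small inputs (fitness then falls back
# to training RMSE).
stratified_val_idx <- function(labels, fraction) {
  idx <- integer(0)
  for (cl in unique(labels)) {
    members <- which(labels == cl)
    n_val <- min(floor(fraction * length(members)), length(members) - 1L)
    if (n_val > 0) idx <- c(idx, sample(members)[seq_len(n_val)])
  }
  sort(idx)
}

#' Train a single-hidden-layer network by self-adaptive ELM
#'
#' Each DE individual encodes the full input layer (weights then biases).
#' Evaluating an individual solves the output weights analytically on the
#' training part and scores RMSE on the validation part. Mutation follows
#' `DE/rand-to-best/2`:
#' `v = x_r1 + F (x_best - x_r1) + F (x_r2 - x_r3) + F (x_r4 - x_r5)`,
#' followed by binomial crossover at rate `CR` (with one guaranteed mutant
#' coordinate) and greedy selection, so the best fitness is non-increasing
#' across generations. Equal-fitness ties are broken toward the smaller output
#' weight norm. The returned model's output weights are re-solved on the full
#' training set with the winning input layer.
#'
#' @param X `N x p` feature matrix.
#' @param labels Length-`N` class labels.
#' @param params An [saelm_params()] object.
#' @return An `slfn` (see [elm_fit()]) with extra fields
#'   `fitness_trajectory` (best validation RMSE after each generation,
#'   starting with the initial population), `initial_fitness` (per-individual
#'   fitness of the initial population) and `params`.
#' @export
saelm_fit <- function(X, labels, params = saelm_params()) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop_invalid("non-finite features")
  labels <- as.character(labels)
  class_labels <- sort_classes(labels)
  if (length(class_labels) < 2) stop_invalid("need at least 2 distinct classes")
  n <- nrow(X)
  p <- ncol(X)
  nh <- params$n_hidden
  d <- nh * (p + 1L)
  scaling <- scale_fit(X)
  Xs <- scale_apply(X, scaling)
  tt_all <- one_hot(labels, class_labels)

  with_seed(params$seed, {
    val <- stratified_val_idx(labels, params$validation_fraction)
    if (length(val) > 0) {
      X_tr <- Xs[-val, , drop = FALSE]; tt_tr <- tt_all[-val, , drop = FALSE]
      X_va <- Xs[val, , drop = FALSE];  tt_va <- tt_all[val, , drop = FALSE]
    } else {
      X_tr <- Xs; tt_tr <- tt_all
      X_va <- Xs; tt_va <- tt_all
    }

    unpack <- function(theta) {
      list(W = matrix(theta[seq_len(nh * p)], nh, p),
           b = theta[nh * p + seq_len(nh)])
    }
    evaluate <- function(theta) {
      wb <- unpack(theta)
      H <- hidden_output_matrix(X_tr, wb$W, wb$b, params$activation)
      beta <- pseudo_inverse(H) %*% tt_tr
      Hv <- hidden_output_matrix(X_va, wb$W, wb$b, params$activation)
      list(fitness = sqrt(mean((Hv %*% beta - tt_va)^2)),
           beta_norm = sqrt(sum(beta^2)))
    }
    better <- function(a, b) {
      a$fitness < b$fitness ||
        (a$fitness == b$fitness && a$beta_norm < b$beta_norm)
    }

    np <- params$population_size
    pop <- matrix(runif(np * d, -1, 1), nrow = d, ncol = np)
    scores <- lapply(seq_len(np), function(i) evaluate(pop[, i]))
    best <- 1L
    for (i in seq_len(np)[-1]) if (better(scores[[i]], scores[[best]])) best <- i
    initial_fitness <- vapply(scores, `[[`, numeric(1), "fitness")
    trajectory <- scores[[best]]$fitness

    if (params$generations > 0) {
      for (gen in seq_len(params$generations)) {
        for (i in seq_len(np)) {
          r <- sample(seq_len(np)[-i], 5)
          v <- pop[, r[1]] +
            params$F * (pop[, best] - pop[, r[1]]) +
            params$F * (pop[, r[2]] - pop[, r[3]]) +
            params$F * (pop[, r[4]] - pop[, r[5]])
          cross <- runif(d) < params$CR
          cross[sample.int(d, 1)] <- TRUE
          trial <- ifelse(cross, v, pop[, i])
          trial_score <- evaluate(trial)
          if (better(trial_score, scores[[i]])) {
            pop[, i] <- trial
            scores[[i]] <- trial_score
            if (better(trial_score, scores[[best]])) best <- i
          }
        }
        trajectory <- c(trajectory, scores[[best]]$fitness)
      }
    }

    wb <- unpack(pop[, best])
    H <- hidden_output_matrix(Xs, wb$W, wb$b, params$activation)
    beta <- pseudo_inverse(H) %*% tt_all
    structure(list(input_weights = wb$W, biases = wb$b, output_weights = beta,
                   activation = params$activation,
                   class_labels = class_labels, scaling = scaling,
                   fitness_trajectory = trajectory,
                   initial_fitness = initial_fitness, params = params),
              class = "slfn")
  })
}
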