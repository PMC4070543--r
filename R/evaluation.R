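# Cross-validated experiment harness: vowel-independent classification,
# vowel-gated per-vowel classification, and per-speaker decision fusion,
# with confusion-matrix reporting and age-group collapsing.

feature_columns <- function(features) {
  grep("^f[0-9]+$", names(features), value = TRUE)
}

feature_matrix <- function(features) {
  as.matrix(features[, feature_columns(features), drop = FALSE])
}

validate_feature_table <- function(features) {
  needed <- c("speaker_id", "age", "vowel")
  missing <- setdiff(needed, names(features))
  if (length(missing) > 0) {
    stop_invalid("feature table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (length(feature_columns(features)) == 0) {
    stop_invalid("feature table has no f### feature columns")
  }
  invisible(features)
}

#' Speaker-disjoint stratified cross-validation folds
#'
#' Partitions speakers into `k` folds, stratified by age (and gender where a
#' `gender` column is present): within each age-by-gender cell the speakers
#' are shuffled and dealt round-robin, so folds are balanced to within one
#' speaker per cell. All utterances of one speaker land in the same fold,
#' keeping train and test sets speaker-disjoint.
#'
#' @param speakers Data frame with columns `speaker_id`, `age` and optionally
#'   `gender` (one row per speaker; a full utterance table is reduced
#'   automatically).
#' @param k Number of folds (>= 2); every age class needs >= `k` speakers.
#' @param seed Integer seed; folds are deterministic given the seed.
#' @return A list of class `cv_split`: `k` character vectors of speaker ids.
#' @export
make_folds <- function(speakers, k = 3, seed = 1L) {
  stopifnot(k >= 2)
  cols <- intersect(c("speaker_id", "age", "gender"), names(speakers))
  speakers <- unique(speakers[, cols, drop = FALSE])
  counts <- table(speakers$age)
  if (any(counts < k)) {
    stop_invalid("every age class needs at least k speakers (k = ", k, ")")
  }
  folds <- rep(list(character(0)), k)
  with_seed(seed, {
    offset <- 0L
    for (age in sort(unique(speakers$age))) {
      members <- speakers[speakers$age == age, , drop = FALSE]
      # shuffle within gender, then interleave genders so round-robin
      # dealing balances both age and gender across folds
      ids <- if ("gender" %in% names(members)) {
        by_gender <- lapply(split(members$speaker_id, members$gender), sample)
        len <- max(lengths(by_gender))
        as.character(stats::na.omit(as.vector(t(vapply(by_gender, function(g) {
          c(g, rep(NA_character_, len - length(g)))
        }, character(len))))))
      } else {
        sample(members$speaker_id)
      }
      assign_to <- ((seq_along(ids) - 1L + offset) %% k) + 1L
      for (f in seq_len(k)) {
        folds[[f]] <- c(folds[[f]], ids[assign_to == f])
      }
      offset <- (offset + 1L) %% k
    }
  })
  structure(lapply(folds, sort), class = "cv_split")
}

fit_age_classifier <- function(X, labels, classifier, n_hidden, saelm, seed) {
  if (classifier == "saelm") {
    p <- saelm %||% saelm_params()
    p$seed <- seed
    p$n_hidden <- n_hidden
    saelm_fit(X, labels, p)
  } else {
    elm_fit(X, labels, n_hidden = n_hidden, seed = seed)
  }
}

#' Build a confusion matrix from true and predicted labels
#'
#' @param true,predicted Label vectors of equal length.
#' @param class_labels Ordered class labels (default: sorted union).
#' @return Integer `n x n` matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(true, predicted,
                             class_labels = sort_classes(c(true, predicted))) {
  true <- factor(as.character(true), levels = as.character(class_labels))
  predicted <- factor(as.character(predicted),
                      levels = as.character(class_labels))
  cm <- table(true, predicted)
  matrix(as.integer(cm), nrow = nrow(cm),
         dimnames = list(rownames(cm), colnames(cm)))
}

#' Overall and per-class accuracy of a confusion matrix
#'
#' Overall accuracy is `100 * trace / total`; per-class accuracy (recall) is
#' `100 * diagonal / row sum`, reported as `NA` for classes with no evaluated
#' samples. Values are returned unrounded; round only for display.
#'
#' @param cm Square count matrix, rows = true class, columns = predicted.
#' @return List with `overall` (percent) and `per_class` (named percents).
#' @export
accuracy_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm))
  total <- sum(cm)
  if (total <= 0) stop_invalid("empty confusion matrix")
  rs <- rowSums(cm)
  per_class <- ifelse(rs > 0, 100 * diag(cm) / rs, NA_real_)
  names(per_class) <- rownames(cm)
  list(overall = 100 * sum(diag(cm)) / total, per_class = per_class)
}

#' Collapse a confusion matrix into wider label groups
#'
#' Sums counts within row groups and column groups, e.g. collapsing six age
#' classes into the 7-8, 9-10 and 11-12 bands. The grouping must partition
#' the matrix labels; totals are preserved.
#'
#' @param cm Square labelled count matrix.
#' @param grouping List of label vectors forming a partition of the labels;
#'   names, if present, label the groups (otherwise labels are joined with
#'   `-`).
#' @return Collapsed count matrix.
#' @export
collapse_confusion <- function(cm, grouping) {
  cm <- as.matrix(cm)
  labels <- rownames(cm)
  flat <- as.character(unlist(grouping))
  if (length(flat) != length(labels) || !setequal(flat, labels) ||
      anyDuplicated(flat) > 0) {
    stop_invalid("grouping must partition the matrix labels")
  }
  group_names <- names(grouping) %||%
    vapply(grouping, function(g) paste(g, collapse = "-"), character(1))
  out <- matrix(0L, length(grouping), length(grouping),
                dimnames = list(group_names, group_names))
  for (i in seq_along(grouping)) {
    for (j in seq_along(grouping)) {
      out[i, j] <- sum(cm[as.character(grouping[[i]]),
                          as.character(grouping[[j]]), drop = FALSE])
    }
  }
  out
}

#' Vowel-independent age classification under cross-validation
#'
#' Per fold, one age classifier is trained on all training utterances pooled
#' across vowels (each utterance is one sample) and evaluated on the held-out
#' fold's utterances. Accuracies of the folds are averaged; confusion counts
#' are reported per fold and pooled.
#'
#' @param features Feature table (columns `speaker_id`, `age`, `vowel`,
#'   `f001...`).
#' @param folds A [make_folds()] split.
#' @param classifier `"saelm"` or `"elm"`.
#' @param n_hidden Hidden-layer size.
#' @param saelm Optional [saelm_params()] template (seed and `n_hidden` are
#'   overridden per fold).
#' @param seed Integer seed.
#' @return List with `accuracy` (fold-averaged percent), `fold_accuracies`,
#'   `confusion` (pooled), `fold_confusions`.
#' @export
run_vowel_independent <- function(features, folds, classifier = c("saelm", "elm"),
                                  n_hidden = 60, saelm = NULL, seed = 1L) {
  classifier <- match.arg(classifier)
  validate_feature_table(features)
  X <- feature_matrix(features)
  ages <- as.character(features$age)
  class_labels <- sort_classes(ages)
  fold_acc <- numeric(length(folds))
  fold_cms <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    test_rows <- features$speaker_id %in% folds[[f]]
    if (!any(!test_rows)) stop_invalid("empty training fold")
    model <- fit_age_classifier(X[!test_rows, , drop = FALSE],
                                ages[!test_rows], classifier, n_hidden,
                                saelm, derive_seed(seed, f))
    pred <- elm_predict(model, X[test_rows, , drop = FALSE], type = "label")
    fold_cms[[f]] <- confusion_matrix(ages[test_rows], pred, class_labels)
    fold_acc[f] <- accuracy_from_confusion(fold_cms[[f]])$overall
  }
  list(accuracy = mean(fold_acc), fold_accuracies = fold_acc,
       confusion = Reduce(`+`, fold_cms), fold_confusions = fold_cms)
}

#' Vowel-gated per-vowel age classification under cross-validation
#'
#' Per fold: a linear vowel gate and six per-vowel age classifiers are trained
#' on the training folds; each test utterance is routed by the gate to one
#' per-vowel classifier and scored by it. Per-fold global confidence is
#' estimated by leave-one-out recall on the training data. The raw score
#' records are returned for decision fusion.
#'
#' @inheritParams run_vowel_independent
#' @param gate_cost Soft-margin cost of the vowel gate.
#' @param loo_factory Optional classifier factory for
#'   [global_confidence_loo()]; default is a plain ELM with `n_hidden` hidden
#'   neurons (a fast surrogate for the deployed classifier).
#' @param compute_global If `FALSE`, skip the leave-one-out global-confidence
#'   estimation (records can then not be fused with LOO confidence).
#' @param route `"gate"` (default) routes test utterances with the trained
#'   vowel gate; `"oracle"` uses the true vowel labels, isolating the age
#'   classifiers from routing errors.
#' @return List with `records` (data frame: `fold`, `speaker_id`, `age`,
#'   `vowel`, `routed_vowel`, plus score columns `s_<class>`),
#'   `per_vowel_accuracy` (percent, by routed vowel, pooled over folds),
#'   `gate_accuracy` (percent of utterances routed to their true vowel),
#'   `global` (per-fold [global_confidence_loo()] results), `vowel_labels`,
#'   `class_labels`.
#' @export
run_vowel_based <- function(features, folds, classifier = c("saelm", "elm"),
                            n_hidden = 60, saelm = NULL, gate_cost = 1,
                            loo_factory = NULL, compute_global = TRUE,
                            route = c("gate", "oracle"), seed = 1L) {
  classifier <- match.arg(classifier)
  route <- match.arg(route)
  validate_feature_table(features)
  X <- feature_matrix(features)
  ages <- as.character(features$age)
  vowels <- as.character(features$vowel)
  class_labels <- sort_classes(ages)
  vowel_labels <- sort(unique(vowels))
  if (is.null(loo_factory)) {
    loo_factory <- function(X, labels, seed) {
      elm_fit(X, labels, n_hidden = n_hidden, seed = seed)
    }
  }
  records <- list()
  global <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    test_rows <- features$speaker_id %in% folds[[f]]
    tr <- which(!test_rows)
    te <- which(test_rows)
    if (length(tr) == 0) stop_invalid("empty training fold")
    missing_v <- setdiff(vowel_labels, unique(vowels[tr]))
    if (length(missing_v) > 0) {
      stop_invalid("vowel(s) absent from training fold ", f, ": ",
                   paste(missing_v, collapse = ", "))
    }
    gate <- fit_vowel_gate(X[tr, , drop = FALSE], vowels[tr], cost = gate_cost)
    models <- lapply(seq_along(vowel_labels), function(vi) {
      rows <- tr[vowels[tr] == vowel_labels[vi]]
      fit_age_classifier(X[rows, , drop = FALSE], ages[rows], classifier,
                         n_hidden, saelm, derive_seed(seed, f, vi))
    })
    names(models) <- vowel_labels
    if (compute_global) {
      global[[f]] <- global_confidence_loo(
        features_by_group = lapply(vowel_labels, function(v) {
          X[tr[vowels[tr] == v], , drop = FALSE]
        }),
        labels_by_group = lapply(vowel_labels, function(v) {
          ages[tr[vowels[tr] == v]]
        }),
        class_labels = class_labels,
        classifier_factory = loo_factory,
        seed = derive_seed(seed, f, 999L)
      )
    }
    routed <- if (route == "gate") {
      predict_vowel(gate, X[te, , drop = FALSE])
    } else {
      vowels[te]
    }
    scores <- matrix(NA_real_, length(te), length(class_labels))
    for (v in vowel_labels) {
      rows <- which(routed == v)
      if (length(rows) > 0) {
        scores[rows, ] <- elm_predict(models[[v]],
                                      X[te[rows], , drop = FALSE])
      }
    }
    rec <- data.frame(fold = f, speaker_id = features$speaker_id[te],
                      age = ages[te], vowel = vowels[te],
                      routed_vowel = routed, stringsAsFactors = FALSE)
    score_df <- as.data.frame(scores)
    names(score_df) <- paste0("s_", class_labels)
    records[[f]] <- cbind(rec, score_df)
  }
  records <- do.call(rbind, records)
  score_cols <- paste0("s_", class_labels)
  pred_age <- class_labels[max.col(as.matrix(records[, score_cols]),
                                   ties.method = "first")]
  per_vowel <- vapply(vowel_labels, function(v) {
    rows <- records$routed_vowel == v
    if (!any(rows)) return(NA_real_)
    100 * mean(pred_age[rows] == records$age[rows])
  }, numeric(1))
  list(records = records,
       per_vowel_accuracy = per_vowel,
       gate_accuracy = 100 * mean(records$routed_vowel == records$vowel),
       global = global,
       vowel_labels = vowel_labels,
       class_labels = class_labels)
}

#' Fuse per-vowel decisions into one age decision per speaker
#'
#' The fusion unit is the speaker: all of a test speaker's score records (one
#' per utterance, each routed to one per-vowel classifier) enter the fuzzy-or
#' operator with `m` = number of utterances. Each record contributes its
#' min-max-normalized membership set, its local confidence from the raw
#' scores, and the global-confidence row of the classifier it was routed to.
#'
#' @param vowel_based The result of [run_vowel_based()] (with
#'   `compute_global = TRUE`).
#' @param config A [fusion_config()].
#' @return List with `confusion` (speaker-level counts), `accuracy`
#'   (percent), and `decisions` (data frame: `fold`, `speaker_id`, `age`,
#'   `predicted`).
#' @export
run_fusion <- function(vowel_based, config = fusion_config()) {
  records <- vowel_based$records
  class_labels <- vowel_based$class_labels
  score_cols <- paste0("s_", class_labels)
  decisions <- list()
  for (f in sort(unique(records$fold))) {
    gc <- vowel_based$global[[f]]
    if (is.null(gc)) stop_invalid("fold ", f, " lacks global confidence")
    fr <- records[records$fold == f, , drop = FALSE]
    for (sp in unique(fr$speaker_id)) {
      rows <- fr[fr$speaker_id == sp, , drop = FALSE]
      if (nrow(rows) == 0) stop_invalid("speaker without records: ", sp)
      raw <- as.matrix(rows[, score_cols, drop = FALSE])
      memberships <- t(apply(raw, 1, normalize_scores))
      w <- apply(raw, 1, local_confidence, sigma = config$sigma)
      delta <- gc$delta[match(rows$routed_vowel, vowel_based$vowel_labels), ,
                        drop = FALSE]
      fused <- fuzzy_or_fuse(memberships, w, delta, config,
                             class_labels = class_labels)
      decisions[[length(decisions) + 1L]] <-
        data.frame(fold = f, speaker_id = sp, age = rows$age[1],
                   predicted = fused$winner, stringsAsFactors = FALSE)
    }
  }
  decisions <- do.call(rbind, decisions)
  cm <- confusion_matrix(decisions$age, decisions$predicted, class_labels)
  list(confusion = cm,
       accuracy = accuracy_from_confusion(cm)$overall,
       decisions = decisions)
}

#' Train-and-fuse pipeline over parallel feature streams
#'
#' A feature-level analogue of the per-vowel pipeline used to study
#' complementarity: each "stream" observes its own feature matrix for the same
#' samples (e.g. different vowels of the same speakers). One classifier per
#' stream is trained on the training rows; global confidence is estimated by
#' leave-one-out recall on the training rows; test rows are fused across
#' streams with the fuzzy-or operator.
#'
#' @param streams List of `m` feature matrices with identical row counts.
#' @param labels Length-`N` class labels shared by all streams.
#' @param train_idx Integer indices of the training rows.
#' @param n_hidden Hidden-layer size of the per-stream ELM classifiers.
#' @param config A [fusion_config()].
#' @param seed Integer seed.
#' @return List with `solo_accuracy` (percent per stream on the test rows),
#'   `fused_accuracy` (percent), and `delta` (the global-confidence matrix).
#' @export
run_stream_fusion <- function(streams, labels, train_idx, n_hidden = 30,
                              config = fusion_config(), seed = 1L) {
  labels <- as.character(labels)
  class_labels <- sort_classes(labels)
  n <- length(labels)
  test_idx <- setdiff(seq_len(n), train_idx)
  stopifnot(length(test_idx) > 0, length(train_idx) > 1)
  m <- length(streams)
  models <- lapply(seq_len(m), function(i) {
    elm_fit(streams[[i]][train_idx, , drop = FALSE], labels[train_idx],
            n_hidden = n_hidden, seed = derive_seed(seed, i))
  })
  gc <- global_confidence_loo(
    features_by_group = lapply(streams, function(S) {
      S[train_idx, , drop = FALSE]
    }),
    labels_by_group = rep(list(labels[train_idx]), m),
    class_labels = class_labels,
    classifier_factory = function(X, labels, seed) {
      elm_fit(X, labels, n_hidden = n_hidden, seed = seed)
    },
    seed = derive_seed(seed, 999L)
  )
  raw <- lapply(seq_len(m), function(i) {
    elm_predict(models[[i]], streams[[i]][test_idx, , drop = FALSE])
  })
  solo <- vapply(seq_len(m), function(i) {
    pred <- class_labels[max.col(raw[[i]], ties.method = "first")]
    100 * mean(pred == labels[test_idx])
  }, numeric(1))
  fused_pred <- vapply(seq_along(test_idx), function(t) {
    memberships <- t(vapply(seq_len(m),
                            function(i) normalize_scores(raw[[i]][t, ]),
                            numeric(length(class_labels))))
    w <- vapply(seq_len(m),
                function(i) local_confidence(raw[[i]][t, ], config$sigma),
                numeric(1))
    fuzzy_or_fuse(memberships, w, gc$delta, config,
                  class_labels = class_labels)$winner
  }, character(1))
  list(solo_accuracy = solo,
       fused_accuracy = 100 * mean(fused_pred == labels[test_idx]),
       delta = gc$delta)
}
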