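test_that("confusion-matrix arithmetic reproduces the reference six-class table", {
  cm <- reference_confusion()
  acc <- accuracy_from_confusion(cm)
  expect_equal(acc$overall, 53.33, tolerance = 0.005 / 53.33)
  expect_equal(unname(acc$per_class), c(85.0, 75.0, 55.0, 30.0, 45.0, 30.0),
               tolerance = 1e-4)
  # identity matrix: 100% everywhere; zero-row classes are NA
  expect_equal(accuracy_from_confusion(diag(5) * 3)$overall, 100)
  z <- rbind(c(4, 0), c(0, 0))
  expect_true(is.na(accuracy_from_confusion(z)$per_class[2]))
  # overall accuracy invariant under uniform scaling of counts
  expect_equal(accuracy_from_confusion(cm * 7)$overall, acc$overall)
})

test_that("collapsing the six ages into three bands matches the scaled table", {
  cm <- reference_confusion()
  grouped <- collapse_confusion(cm, list(`7-8` = c(7, 8), `9-10` = c(9, 10),
                                         `11-12` = c(11, 12)))
  expect_equal(unname(grouped),
               rbind(c(36, 4, 0), c(17, 20, 3), c(18, 5, 17)))
  expect_equal(unname(grouped * 3),
               rbind(c(108, 12, 0), c(51, 60, 9), c(54, 15, 51)))
  acc <- accuracy_from_confusion(grouped)
  expect_equal(acc$overall, 60.83, tolerance = 0.005 / 60.83)
  expect_equal(unname(acc$per_class), c(90.0, 50.0, 42.5), tolerance = 1e-4)
  # collapsing preserves totals; singleton groups leave the matrix unchanged
  expect_equal(sum(grouped), sum(cm))
  singleton <- collapse_confusion(cm, as.list(rownames(cm)))
  expect_equal(unname(singleton), unname(cm))
  whole <- collapse_confusion(cm, list(all = rownames(cm)))
  expect_equal(dim(whole), c(1, 1))
  expect_equal(accuracy_from_confusion(whole)$overall, 100)
  expect_error(collapse_confusion(cm, list(c(7, 8))), "partition")
})

test_that("folds are speaker-disjoint, stratified and deterministic", {
  speakers <- data.frame(
    speaker_id = sprintf("s%03d", 1:360),
    age = rep(7:12, each = 60),
    gender = rep(c("M", "F"), 180))
  folds <- make_folds(speakers, k = 3, seed = 5)
  expect_length(folds, 3)
  expect_equal(lengths(folds), rep(120L, 3), ignore_attr = TRUE)
  expect_setequal(unlist(folds), speakers$speaker_id)
  expect_equal(anyDuplicated(unlist(folds)), 0L)
  for (f in folds) {
    per_age <- table(speakers$age[speakers$speaker_id %in% f])
    expect_equal(unname(as.integer(per_age)), rep(20L, 6))
  }
  expect_identical(folds, make_folds(speakers, k = 3, seed = 5))
  expect_false(identical(folds, make_folds(speakers, k = 3, seed = 6)))
  expect_error(make_folds(speakers[c(1:3, 61:150), ], k = 5), "at least k speakers")
})

test_that("vowel-independent accuracy tracks the class separation", {
  # no signal: close to 1/6 chance
  null_tab <- make_feature_table(n_per_class = 30, separation = 0, seed = 61)
  folds <- make_folds(null_tab, k = 3, seed = 61)
  null_run <- run_vowel_independent(null_tab, folds, classifier = "elm",
                                    n_hidden = 20, seed = 61)
  expect_lt(abs(null_run$accuracy - 100 / 6), 5 * 100 / 6)
  expect_equal(sum(null_run$confusion), nrow(null_tab))
  # strong signal: three seeds all >= 95%
  for (s in 1:3) {
    tab <- make_feature_table(n_per_class = 30, separation = 8, seed = 70 + s)
    folds <- make_folds(tab, k = 3, seed = s)
    run <- run_vowel_independent(tab, folds, classifier = "elm",
                                 n_hidden = 20, seed = s)
    expect_gte(run$accuracy, 95)
    expect_identical(run$accuracy,
                     run_vowel_independent(tab, folds, classifier = "elm",
                                           n_hidden = 20, seed = s)$accuracy)
  }
})

test_that("gated per-vowel classification conserves records and routes well", {
  # features where both vowel identity and age are separable: place vowels in
  # dims 1-6 and ages in dims 7-12
  withr::with_seed(81, {
    n <- 360
    ages <- rep(7:12, each = 60)
    vowels <- rep(c("a", "e", "schwa", "i", "o", "u"), 60)
    X <- matrix(rnorm(n * 12), n, 12)
    X[cbind(1:n, match(vowels, c("a", "e", "schwa", "i", "o", "u")))] <-
      X[cbind(1:n, match(vowels, c("a", "e", "schwa", "i", "o", "u")))] + 8
    X[cbind(1:n, 6 + ages - 6)] <- X[cbind(1:n, 6 + ages - 6)] + 8
    tab <- cbind(data.frame(speaker_id = sprintf("p%03d", 1:n), age = ages,
                            vowel = vowels, stringsAsFactors = FALSE),
                 stats::setNames(as.data.frame(X),
                                 sprintf("f%03d", 1:12)))
  })
  folds <- make_folds(tab, k = 3, seed = 9)
  vb <- run_vowel_based(tab, folds, classifier = "elm", n_hidden = 20,
                        compute_global = FALSE, seed = 9)
  expect_equal(nrow(vb$records), nrow(tab))      # one record per utterance
  expect_gte(vb$gate_accuracy, 95)
  expect_true(all(vb$per_vowel_accuracy >= 95, na.rm = TRUE))
  # oracle routing can only help on average
  vb_oracle <- run_vowel_based(tab, folds, classifier = "elm", n_hidden = 20,
                               compute_global = FALSE, route = "oracle",
                               seed = 9)
  acc <- function(v) {
    s <- as.matrix(v$records[, paste0("s_", v$class_labels)])
    mean(v$class_labels[max.col(s, ties.method = "first")] == v$records$age)
  }
  expect_gte(acc(vb_oracle) + 1e-12, acc(vb))
})

test_that("a single-record speaker is fused to that classifier's decision", {
  class_labels <- as.character(7:9)
  raw <- rbind(c(0.2, 0.9, 0.1), c(0.8, 0.3, 0.4))
  records <- data.frame(fold = 1, speaker_id = c("sA", "sB"),
                        age = c("8", "7"), vowel = c("a", "e"),
                        routed_vowel = c("a", "e"), stringsAsFactors = FALSE)
  records[paste0("s_", class_labels)] <- as.data.frame(raw)
  gc <- structure(list(delta = matrix(1L, 2, 3,
                                      dimnames = list(NULL, class_labels))),
                  class = "global_confidence")
  vb <- list(records = records, global = list(gc),
             vowel_labels = c("a", "e"), class_labels = class_labels)
  fused <- run_fusion(vb, fusion_config())
  got <- fused$decisions$predicted[order(fused$decisions$speaker_id)]
  expect_identical(got, c("8", "7"))    # argmax of each speaker's only record
  expect_equal(fused$accuracy, 100)
})

test_that("fusing complementary streams beats each stream alone", {
  streams <- synth_feature_clusters(6, 30, dim = 6, separation = 6, seed = 17,
                                    complementary_map = list(1:2, 3:4, 5:6))
  train <- withr::with_seed(18, sort(sample(180, 120)))
  run <- run_stream_fusion(streams$streams, streams$labels, train,
                           n_hidden = 20, seed = 17)
  expect_gt(run$fused_accuracy, max(run$solo_accuracy))
  # each class is vouched for by the stream that separates it
  expect_equal(unname(run$delta[1, 1:2]), c(1L, 1L))
  expect_equal(unname(run$delta[2, 3:4]), c(1L, 1L))
  expect_equal(unname(run$delta[3, 5:6]), c(1L, 1L))
})
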