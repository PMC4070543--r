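# Shared in-code fixtures for the test suite.

# The published six-class reference confusion matrix shipped under extdata
# (rows = true age, columns = predicted age).
reference_confusion <- function() {
  as.matrix(read.csv(system.file("extdata", "published_confusion_6class.csv",
                                 package = "vowelage"),
                     row.names = 1, check.names = FALSE))
}

# Well-separated Gaussian clusters: one mean direction per class.
make_clusters <- function(n_per_class, n_classes, dim, separation, seed) {
  withr::with_seed(seed, {
    labels <- rep(seq_len(n_classes), each = n_per_class)
    means <- matrix(0, n_classes, dim)
    for (j in seq_len(n_classes)) means[j, ((j - 1) %% dim) + 1] <- separation
    X <- means[labels, , drop = FALSE] +
      matrix(rnorm(n_per_class * n_classes * dim), ncol = dim)
    list(X = X, labels = labels)
  })
}

# A labelled feature table in the evaluation-module layout, built from
# Gaussian clusters: class j -> age 6 + j, vowels assigned round-robin,
# one synthetic speaker per row.
make_feature_table <- function(n_per_class, separation, seed, dim = 8) {
  cl <- make_clusters(n_per_class, 6, dim, separation, seed)
  vowels <- c("a", "e", "schwa", "i", "o", "u")
  feat <- as.data.frame(cl$X)
  names(feat) <- sprintf("f%03d", seq_len(ncol(cl$X)))
  cbind(data.frame(speaker_id = sprintf("spk%04d", seq_along(cl$labels)),
                   age = 6 + cl$labels,
                   vowel = vowels[(seq_along(cl$labels) - 1) %% 6 + 1],
                   stringsAsFactors = FALSE),
        feat)
}

# Independent minimum-norm least-squares oracle (MASS::ginv route).
minnorm_lsq_oracle <- function(H, targets) {
  MASS::ginv(H) %*% targets
}
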