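# Linear maximum-margin vowel gate: routes an unlabeled utterance to the
# per-vowel age classifier. Backed by libsvm (e1071), linear kernel,
# one-vs-one with majority vote.

#' Train the linear maximum-margin vowel gate
#'
#' Fits one linear maximum-margin decision function per vowel pair (one-vs-one
#' with majority voting, soft margin `C = 1`) on the same features the age
#' classifiers see. Features are affinely scaled to `[-1, 1]` per dimension
#' from training min/max; the scaling is stored and re-applied at prediction.
#'
#' @param X `N x p` feature matrix.
#' @param vowel_labels Length-`N` vowel class labels (>= 2 distinct).
#' @param cost Soft-margin cost parameter `C`.
#' @return An object of class `vowel_gate`.
#' @export
fit_vowel_gate <- function(X, vowel_labels, cost = 1) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop_invalid("non-finite features")
  y <- factor(as.character(vowel_labels))
  if (nlevels(y) < 2) stop_invalid("need at least 2 vowel classes")
  scaling <- scale_fit(X)
  fit <- e1071::svm(x = scale_apply(X, scaling), y = y, kernel = "linear",
                    cost = cost, scale = FALSE)
  structure(list(svm = fit, scaling = scaling, class_labels = levels(y)),
            class = "vowel_gate")
}

#' Route utterances to vowel classes
#'
#' Deterministic label prediction from a trained [fit_vowel_gate()] model;
#' used to send each test utterance to the matching per-vowel age classifier.
#'
#' @param gate A `vowel_gate`.
#' @param x Feature matrix (or a single feature vector).
#' @return Character vector of vowel labels.
#' @export
predict_vowel <- function(gate, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != length(gate$scaling$centre)) {
    stop_invalid("feature dimension does not match the gate")
  }
  as.character(predict(gate$svm, scale_apply(x, gate$scaling)))
}
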