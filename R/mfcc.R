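# Cepstral front end: 55 ms frames, 40-filter ("narrow") Mel filterbank,
# orthonormal DCT-II, regression deltas, single central-frame selection.

#' Front-end configuration
#'
#' Settings for the cepstral front end. The defaults describe the package's
#' standard analysis of sustained vowels: 55 ms frames with 50% overlap, a
#' 40-filter Mel bank spanning 0 Hz to Nyquist, 40 static coefficients
#' (including the 0th), and delta/delta-delta regression over a +/-2 frame
#' window, giving 120 coefficients per utterance.
#'
#' Narrow filters are the point of the 40-filter bank: with more triangles on
#' the same band each filter is narrower than in the conventional 13-filter
#' design, so less spectral smoothing is applied and fine spectral detail that
#' carries age information (harmonic spacing, formant positions) survives into
#' the cepstrum.
#'
#' @param frame_length_ms Analysis frame length in milliseconds.
#' @param hop_length_ms Frame hop in milliseconds (default 50% overlap).
#' @param n_filters Number of triangular Mel filters.
#' @param n_static Number of static cepstral coefficients kept (<= `n_filters`).
#' @param delta_window Half-width (in frames) of the delta regression window.
#' @param fmin,fmax Filterbank band edges in Hz; `fmax = NULL` means Nyquist.
#' @param log_floor Positive floor applied to filterbank energies before the
#'   log, guarding `log(0)` on silence.
#' @param preemphasis First-order pre-emphasis coefficient in `[0, 1)`.
#' @return An object of class `mfcc_config`.
#' @export
mfcc_config <- function(frame_length_ms = 55, hop_length_ms = 27.5,
                        n_filters = 40, n_static = 40, delta_window = 2,
                        fmin = 0, fmax = NULL, log_floor = 1e-10,
                        preemphasis = 0.97) {
  if (frame_length_ms <= 0 || hop_length_ms <= 0) {
    stop_invalid("frame and hop lengths must be positive")
  }
  if (n_static > n_filters) stop_invalid("n_static must not exceed n_filters")
  if (!is.null(fmax) && fmin >= fmax) stop_invalid("fmin must be < fmax")
  if (log_floor <= 0) stop_invalid("log_floor must be positive")
  if (preemphasis < 0 || preemphasis >= 1) {
    stop_invalid("preemphasis must lie in [0, 1)")
  }
  structure(list(frame_length_ms = frame_length_ms,
                 hop_length_ms = hop_length_ms,
                 n_filters = as.integer(n_filters),
                 n_static = as.integer(n_static),
                 delta_window = as.integer(delta_window),
                 fmin = fmin, fmax = fmax,
                 log_floor = log_floor, preemphasis = preemphasis),
            class = "mfcc_config")
}

#' Convert frequency in Hz to the Mel scale
#'
#' Uses the HTK-style formula `2595 * log10(1 + f/700)`: zero at 0 Hz,
#' monotone increasing, and close to the identity near 1 kHz.
#'
#' @param frequency Frequency in Hz (non-negative, vectorised).
#' @return Mel value(s).
#' @export
hz_to_mel <- function(frequency) {
  if (any(frequency < 0)) stop_invalid("frequency must be non-negative")
  2595 * log10(1 + frequency / 700)
}

#' Convert Mel value to frequency in Hz
#' @param mel Mel value(s), non-negative.
#' @return Frequency in Hz.
#' @export
mel_to_hz <- function(mel) {
  if (any(mel < 0)) stop_invalid("mel must be non-negative")
  700 * (10^(mel / 2595) - 1)
}

#' Build a triangular Mel filterbank
#'
#' `n_filters` triangular filters with centres equally spaced on the Mel scale
#' between `fmin` and `fmax`; each triangle rises from the previous centre and
#' falls to the next, so adjacent filters overlap at their neighbours' centres.
#' Weights are evaluated on the actual FFT bin frequencies.
#'
#' @param config An [mfcc_config()].
#' @param sample_rate Sampling rate in Hz.
#' @param n_fft FFT length; `floor(n_fft/2) + 1` bins are produced.
#' @return A list of class `mel_filterbank` with `weights`
#'   (`n_filters x n_bins` matrix) and `center_frequencies` (Hz).
#' @export
build_mel_filterbank <- function(config, sample_rate, n_fft) {
  fmax <- config$fmax %||% (sample_rate / 2)
  if (config$fmin >= fmax || fmax > sample_rate / 2) {
    stop_invalid("need fmin < fmax <= sample_rate/2")
  }
  n_bins <- floor(n_fft / 2) + 1L
  mel_pts <- seq(hz_to_mel(config$fmin), hz_to_mel(fmax),
                 length.out = config$n_filters + 2L)
  hz_pts <- mel_to_hz(mel_pts)
  bin_freq <- (seq_len(n_bins) - 1) * sample_rate / n_fft
  weights <- matrix(0, config$n_filters, n_bins)
  for (i in seq_len(config$n_filters)) {
    lo <- hz_pts[i]; ce <- hz_pts[i + 1]; hi <- hz_pts[i + 2]
    rise <- (bin_freq - lo) / (ce - lo)
    fall <- (hi - bin_freq) / (hi - ce)
    weights[i, ] <- pmax(0, pmin(rise, fall))
  }
  if (any(rowSums(weights) <= 0)) {
    stop_invalid("n_filters too large for this n_fft: ",
                 "some filters cover no FFT bin")
  }
  structure(list(weights = weights, center_frequencies = hz_pts[2:(config$n_filters + 1L)]),
            class = "mel_filterbank")
}

#' Slice a signal into pre-emphasised, Hamming-windowed frames
#'
#' Frames of `round(frame_length_ms * sr / 1000)` samples are taken every
#' `round(hop_length_ms * sr / 1000)` samples; a trailing partial frame is
#' dropped. Each frame is first-order pre-emphasised
#' (`y[t] = x[t] - a * x[t-1]`, first sample against itself) and then
#' Hamming-windowed.
#'
#' @param signal A list with `samples` and `sample_rate` (see [read_wav()]).
#' @param config An [mfcc_config()].
#' @return A `frame_length x n_frames` numeric matrix (frames in columns).
#' @export
frame_signal <- function(signal, config) {
  x <- signal$samples
  sr <- signal$sample_rate
  stopifnot(sr > 0)
  if (!all(is.finite(x))) stop_invalid("signal contains non-finite samples")
  frame_len <- round(config$frame_length_ms * sr / 1000)
  hop <- round(config$hop_length_ms * sr / 1000)
  if (length(x) < frame_len) {
    stop_invalid("signal shorter than one frame (", length(x), " < ",
                 frame_len, " samples)")
  }
  n_frames <- floor((length(x) - frame_len) / hop) + 1L
  starts <- (seq_len(n_frames) - 1L) * hop + 1L
  win <- 0.54 - 0.46 * cos(2 * pi * (seq_len(frame_len) - 1) / (frame_len - 1))
  frames <- vapply(starts, function(s) {
    fr <- x[s:(s + frame_len - 1L)]
    fr <- fr - config$preemphasis * c(fr[1], fr[-frame_len])
    fr * win
  }, numeric(frame_len))
  matrix(frames, nrow = frame_len, ncol = n_frames)
}

# Orthonormal DCT-II matrix (n x n): row 0 scaled by sqrt(1/n), others
# sqrt(2/n), so D %*% t(D) = I.
dct_matrix <- function(n) {
  k <- 0:(n - 1)
  m <- outer(k, k, function(k, j) cos(pi * k * (2 * j + 1) / (2 * n)))
  m * sqrt(2 / n) * ifelse(k == 0, sqrt(1 / 2), 1)
}

#' Static cepstral coefficients of one windowed frame
#'
#' Power spectrum -> Mel filterbank energies -> floored log -> orthonormal
#' DCT-II -> first `n_static` coefficients (the 0th included).
#'
#' @param frame A windowed frame (numeric vector).
#' @param filterbank A [build_mel_filterbank()] result whose bin count matches
#'   the FFT implied by `length(frame)` (zero-padded up).
#' @param n_static Number of coefficients to keep.
#' @param log_floor Positive energy floor.
#' @return Numeric vector of `n_static` coefficients.
#' @export
static_mfcc <- function(frame, filterbank, n_static = nrow(filterbank$weights),
                        log_floor = 1e-10) {
  if (!all(is.finite(frame))) stop_invalid("non-finite frame")
  n_bins <- ncol(filterbank$weights)
  n_fft <- (n_bins - 1L) * 2L
  if (length(frame) > n_fft) stop_invalid("frame longer than filterbank FFT")
  padded <- c(frame, numeric(n_fft - length(frame)))
  pow <- Mod(fft(padded))[seq_len(n_bins)]^2
  energies <- as.numeric(filterbank$weights %*% pow)
  log_e <- log(pmax(energies, log_floor))
  d <- dct_matrix(length(log_e))
  as.numeric(d[seq_len(n_static), , drop = FALSE] %*% log_e)
}

#' Delta (regression) coefficients of a cepstral trajectory
#'
#' Standard regression delta over a window of `W` frames each side:
#' `delta_t = sum_k k * (c_{t+k} - c_{t-k}) / (2 * sum_k k^2)`, with the
#' sequence edge-padded by repeating its boundary frames. Apply twice for
#' delta-delta.
#'
#' @param static_sequence `n_coef x n_frames` matrix (frames in columns).
#' @param window Regression half-width `W` in frames.
#' @return Matrix of the same shape as `static_sequence`.
#' @export
delta_coefficients <- function(static_sequence, window = 2) {
  stopifnot(is.matrix(static_sequence), ncol(static_sequence) >= 1, window >= 1)
  n <- ncol(static_sequence)
  padded <- static_sequence[, c(rep(1L, window), seq_len(n), rep(n, window)),
                            drop = FALSE]
  denom <- 2 * sum((1:window)^2)
  out <- matrix(0, nrow(static_sequence), n)
  for (k in seq_len(window)) {
    idx <- window + seq_len(n)
    out <- out + k * (padded[, idx + k, drop = FALSE] -
                      padded[, idx - k, drop = FALSE])
  }
  out / denom
}

#' Extract the 120-dimensional cepstral vector of an utterance
#'
#' Frames the whole utterance, computes static coefficients per frame, deltas
#' and delta-deltas over the frame sequence, and keeps the central frame's
#' `[static, delta, delta-delta]` stack as the utterance's single feature
#' vector. Sustained vowels are close to stationary, so which frame is kept
#' matters little; the centre avoids onset/offset transients.
#'
#' @param signal A list with `samples` and `sample_rate`.
#' @param config An [mfcc_config()].
#' @return Numeric vector of `3 * n_static` coefficients, named
#'   `f001 ... f120` at the defaults.
#' @export
extract_features <- function(signal, config = mfcc_config()) {
  frames <- frame_signal(signal, config)
  n_fft <- 2^ceiling(log2(nrow(frames)))
  fb <- build_mel_filterbank(config, signal$sample_rate, n_fft)
  n_bins <- ncol(fb$weights)
  padded <- rbind(frames, matrix(0, n_fft - nrow(frames), ncol(frames)))
  pow <- Mod(mvfft(padded))[seq_len(n_bins), , drop = FALSE]^2
  log_e <- log(pmax(fb$weights %*% pow, config$log_floor))
  d <- dct_matrix(config$n_filters)[seq_len(config$n_static), , drop = FALSE]
  static <- d %*% log_e
  del <- delta_coefficients(static, config$delta_window)
  deldel <- delta_coefficients(del, config$delta_window)
  centre <- (ncol(frames) + 1L) %/% 2L
  out <- c(static[, centre], del[, centre], deldel[, centre])
  names(out) <- sprintf("f%03d", seq_along(out))
  out
}
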