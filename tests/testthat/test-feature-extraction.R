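test_that("Mel conversion matches the HTK-style formula and rejects negatives", {
  expect_identical(hz_to_mel(0), 0)
  expect_equal(hz_to_mel(700), 2595 * log10(2), tolerance = 1e-12)
  expect_equal(hz_to_mel(1000), 999.9855, tolerance = 1e-4)
  expect_error(hz_to_mel(-1), "non-negative")
  # round trip and monotonicity
  f <- seq(0, 10000, by = 250)
  expect_equal(mel_to_hz(hz_to_mel(f)), f, tolerance = 1e-8)
  expect_true(all(diff(hz_to_mel(f)) > 0))
})

test_that("Mel filterbank matches a brute-force triangle oracle", {
  cfg <- mfcc_config(n_filters = 13, n_static = 13, fmax = 8000)
  fb <- build_mel_filterbank(cfg, sample_rate = 16000, n_fft = 512)
  # independent construction: evaluate each triangle pointwise on bin
  # frequencies from the Mel-spaced edge grid
  edges <- 700 * (10^(seq(0, 2595 * log10(1 + 8000 / 700),
                          length.out = 15) / 2595) - 1)
  bins <- (0:256) * 16000 / 512
  oracle <- matrix(0, 13, 257)
  for (i in 1:13) {
    for (b in seq_along(bins)) {
      f <- bins[b]
      if (f > edges[i] && f < edges[i + 1]) {
        oracle[i, b] <- (f - edges[i]) / (edges[i + 1] - edges[i])
      } else if (f >= edges[i + 1] && f < edges[i + 2]) {
        oracle[i, b] <- (edges[i + 2] - f) / (edges[i + 2] - edges[i + 1])
      }
    }
  }
  expect_equal(fb$weights, oracle, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("filterbank construction guarantees and narrowness", {
  fb40 <- build_mel_filterbank(mfcc_config(), 20000, 2048)
  expect_equal(nrow(fb40$weights), 40)
  expect_true(all(rowSums(fb40$weights) > 0))
  expect_true(all(fb40$weights >= 0))
  expect_true(all(diff(fb40$center_frequencies) > 0))
  # more filters on the same band are narrower on average
  width_hz <- function(fb, sr, n_fft) {
    bins <- (seq_len(ncol(fb$weights)) - 1) * sr / n_fft
    apply(fb$weights, 1, function(w) diff(range(bins[w > 0])))
  }
  fb13 <- build_mel_filterbank(mfcc_config(n_filters = 13, n_static = 13),
                               20000, 2048)
  expect_lt(mean(width_hz(fb40, 20000, 2048)), mean(width_hz(fb13, 20000, 2048)))
  # too many filters for a coarse FFT grid is a configuration error
  expect_error(build_mel_filterbank(mfcc_config(n_filters = 100), 20000, 128),
               "n_filters too large")
})

test_that("framing arithmetic, windowing and degenerate inputs", {
  cfg <- mfcc_config()
  sig1 <- list(samples = sin(2 * pi * 100 * (0:1099) / 20000),
               sample_rate = 20000)
  expect_equal(ncol(frame_signal(sig1, cfg)), 1)
  sig5 <- list(samples = rnorm(100000), sample_rate = 20000)
  expect_equal(ncol(frame_signal(sig5, cfg)), 180)  # floor((1e5-1100)/550)+1
  zero <- list(samples = numeric(3000), sample_rate = 20000)
  expect_true(all(frame_signal(zero, cfg) == 0))
  expect_error(frame_signal(list(samples = numeric(100), sample_rate = 20000),
                            cfg), "shorter than one frame")
})

test_that("static coefficients: DC-only silence and DCT orthonormality", {
  cfg <- mfcc_config()
  fb <- build_mel_filterbank(cfg, 20000, 2048)
  c_zero <- static_mfcc(numeric(1100), fb, 40, log_floor = 1e-10)
  expect_equal(c_zero[1], sqrt(40) * log(1e-10), tolerance = 1e-8)
  expect_equal(c_zero[-1], rep(0, 39), tolerance = 1e-8)
  # inverse orthonormal DCT of all coefficients recovers the log energies
  frame <- withr::with_seed(42, rnorm(1100))
  coefs <- static_mfcc(frame, fb, 40, 1e-10)
  pow <- Mod(fft(c(frame, numeric(2048 - 1100))))[1:1025]^2
  log_e <- log(pmax(as.numeric(fb$weights %*% pow), 1e-10))
  d <- vowelage:::dct_matrix(40)
  expect_equal(as.numeric(t(d) %*% coefs), log_e, tolerance = 1e-8)
})

test_that("log filterbank energies peak at the filter nearest a pure tone", {
  cfg <- mfcc_config()
  fb <- build_mel_filterbank(cfg, 20000, 2048)
  t <- (0:1099) / 20000
  win <- 0.54 - 0.46 * cos(2 * pi * (0:1099) / 1099)
  frame <- sin(2 * pi * 1000 * t) * win
  pow <- Mod(fft(c(frame, numeric(2048 - 1100))))[1:1025]^2
  energies <- as.numeric(fb$weights %*% pow)
  expect_equal(which.max(energies),
               which.min(abs(fb$center_frequencies - 1000)))
})

test_that("delta operator: symmetry, ramps, padding and linearity", {
  const <- matrix(3, 5, 10)
  expect_true(all(delta_coefficients(const, 2) == 0))
  ramp <- matrix(rep(1:20, each = 4), 4, 20)
  d <- delta_coefficients(ramp, 2)
  expect_equal(d[, 3:18], matrix(1, 4, 16))   # interior slopes of a line
  single <- matrix(rnorm(6), 6, 1)
  expect_true(all(delta_coefficients(single, 2) == 0))
  # linearity
  A <- matrix(rnorm(50), 5, 10); B <- matrix(rnorm(50), 5, 10)
  expect_equal(delta_coefficients(2 * A - 3 * B, 2),
               2 * delta_coefficients(A, 2) - 3 * delta_coefficients(B, 2),
               tolerance = 1e-12)
})

test_that("utterance feature vector: length, determinism, silence, gain shift", {
  cfg <- mfcc_config()
  sig <- withr::with_seed(7, list(samples = rnorm(100000) / 5,
                                  sample_rate = 20000))
  fv <- extract_features(sig, cfg)
  expect_length(fv, 120)
  expect_true(all(is.finite(fv)))
  expect_identical(fv, extract_features(sig, cfg))  # bit-identical rerun
  # silence: static coefficients at the floor, deltas exactly zero
  silent <- extract_features(list(samples = numeric(5000),
                                  sample_rate = 20000), cfg)
  expect_equal(silent[1], c(f001 = sqrt(40) * log(1e-10)), tolerance = 1e-6)
  expect_equal(unname(silent[41:120]), rep(0, 80))
  # doubling the amplitude shifts only the 0th static coefficient
  fv2 <- extract_features(list(samples = 2 * sig$samples, sample_rate = 20000),
                          cfg)
  expect_equal(unname(fv2[2:40]), unname(fv[2:40]), tolerance = 1e-6)
  expect_equal(unname(fv2[1] - fv[1]), sqrt(40) * log(4), tolerance = 1e-6)
  # deltas are invariant to gain up to the same DC-only shift
  expect_equal(unname(fv2[42:80]), unname(fv[42:80]), tolerance = 1e-6)
})

test_that("a stationary synthetic vowel has near-zero central deltas", {
  v <- synth_vowel(default_vowel_specs()$a, f0 = 240, scale = 1,
                   duration = 2, sample_rate = 20000, seed = 5)
  fv <- extract_features(v, mfcc_config())
  static_spread <- stats::sd(fv[1:40])
  expect_lt(max(abs(fv[41:80])), 0.2 * static_spread)
})
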