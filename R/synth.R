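# Synthetic sustained-vowel corpus generator: source-filter synthesis with
# age-dependent pitch and formant scaling, plus feature-level Gaussian
# cluster generators for controlled classifier/fusion experiments.

#' Default formant specifications for the six vowel classes
#'
#' Typical child-like formant targets (Hz) and bandwidths for /a/, /e/,
#' /@/ (schwa), /i/, /o/, /u/: /a/ high-F1/mid-F2, /i/ low-F1/high-F2, back
#' vowels /o/ and /u/ low-F2, schwa central. These are generator constants for
#' producing learnable, plausibly overlapping classes, not measurements of any
#' real corpus.
#'
#' @return Named list of vowel specs, each with `vowel`, `formants` (F1 < F2
#'   < F3, Hz) and `bandwidths` (Hz).
#' @export
default_vowel_specs <- function() {
  spec <- function(v, f) list(vowel = v, formants = f,
                              bandwidths = c(80, 120, 200))
  list(a = spec("a", c(1000, 1600, 3200)),
       e = spec("e", c(600, 2400, 3400)),
       schwa = spec("schwa", c(650, 1700, 3300)),
       i = spec("i", c(400, 3000, 3800)),
       o = spec("o", c(550, 1100, 3200)),
       u = spec("u", c(450, 1000, 3000)))
}

#' Default developmental age model
#'
#' Mean fundamental frequency declines linearly from 280 Hz at age 7 to
#' 230 Hz at age 12, and the vocal-tract formant scale shrinks by 1% per year
#' (scale 1 at age 7) — plausible developmental magnitudes that make the age
#' classes learnable but heavily overlapping. Inter-speaker spread is
#' relative: 5% on f0 and 3% on the formant scale, with girls 3% higher f0.
#'
#' @return A list with `f0_by_age`, `formant_scale_by_age` (named by ages
#'   7-12, both monotone non-increasing), `f0_speaker_sd`, `scale_speaker_sd`,
#'   `gender_f0_shift`.
#' @export
default_age_model <- function() {
  ages <- 7:12
  list(f0_by_age = stats::setNames(280 - 10 * (ages - 7), ages),
       formant_scale_by_age = stats::setNames(1 - 0.01 * (ages - 7), ages),
       f0_speaker_sd = 0.05,
       scale_speaker_sd = 0.03,
       gender_f0_shift = 0.03)
}

#' Corpus layout configuration
#'
#' Defaults reproduce the reference layout: 60 speakers per age, ages 7-12,
#' six vowels, 5 s utterances at 20 kHz — 360 speakers and 2160 utterances,
#' 60 per age-by-vowel cell.
#'
#' @param n_speakers_per_age Speakers per age class.
#' @param ages Integer age classes.
#' @param duration_s Utterance duration in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param seed Integer seed.
#' @return An object of class `corpus_config`.
#' @export
corpus_config <- function(n_speakers_per_age = 60, ages = 7:12,
                          duration_s = 5, sample_rate = 20000, seed = 1L) {
  stopifnot(n_speakers_per_age >= 1, length(ages) >= 1,
            duration_s > 0, sample_rate > 0)
  structure(list(n_speakers_per_age = as.integer(n_speakers_per_age),
                 ages = as.integer(ages),
                 duration_s = duration_s,
                 sample_rate = as.integer(sample_rate),
                 seed = as.integer(seed)),
            class = "corpus_config")
}

#' Synthesize one sustained vowel
#'
#' Source-filter synthesis: a glottal impulse train at `f0` with small
#' period-to-period jitter is passed through cascaded second-order resonators
#' at `scale * F1..F3`, low-level white noise is added, and the amplitude is
#' normalized to `[-1, 1]`.
#'
#' @param spec A vowel spec (see [default_vowel_specs()]).
#' @param f0 Fundamental frequency in Hz.
#' @param scale Formant scale factor; `scale * F3` must stay below Nyquist.
#' @param duration Duration in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param seed Integer seed (jitter and noise).
#' @param jitter Relative standard deviation of the glottal period.
#' @param noise_level Additive white-noise amplitude relative to the filtered
#'   voiced component.
#' @return A list with `samples` and `sample_rate`, as from [read_wav()].
#' @export
synth_vowel <- function(spec, f0, scale = 1, duration = 5,
                        sample_rate = 20000, seed = 1L,
                        jitter = 0.01, noise_level = 0.02) {
  formants <- scale * spec$formants
  if (any(formants >= sample_rate / 2)) {
    stop_invalid("scaled formant at or above Nyquist")
  }
  stopifnot(f0 > 0, duration > 0)
  n <- round(duration * sample_rate)
  with_seed(seed, {
    # impulse train with jittered periods
    excitation <- numeric(n)
    pos <- 1
    while (pos <= n) {
      excitation[ceiling(pos)] <- 1
      period <- (sample_rate / f0) * (1 + jitter * rnorm(1))
      pos <- pos + max(period, 2)
    }
    voiced <- excitation
    for (k in seq_along(formants)) {
      r <- exp(-pi * spec$bandwidths[k] / sample_rate)
      theta <- 2 * pi * formants[k] / sample_rate
      voiced <- as.numeric(stats::filter(voiced, c(2 * r * cos(theta), -r^2),
                                         method = "recursive"))
    }
    x <- voiced + noise_level * max(abs(voiced)) * rnorm(n)
    list(samples = x / max(abs(x)), sample_rate = sample_rate)
  })
}

corpus_speaker_table <- function(config) {
  rows <- list()
  sp <- 0L
  for (age in config$ages) {
    for (i in seq_len(config$n_speakers_per_age)) {
      sp <- sp + 1L
      rows[[sp]] <- data.frame(
        speaker_id = sprintf("spk%04d", sp),
        age = age,
        gender = if (i %% 2 == 0) "F" else "M",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Per-speaker acoustic parameters, deterministic in (seed, speaker index).
speaker_acoustics <- function(speaker_index, age, gender, age_model, seed) {
  with_seed(derive_seed(seed, speaker_index), {
    f0 <- age_model$f0_by_age[[as.character(age)]] *
      (1 + age_model$f0_speaker_sd * rnorm(1)) *
      (1 + if (gender == "F") age_model$gender_f0_shift else 0)
    scale <- age_model$formant_scale_by_age[[as.character(age)]] *
      (1 + age_model$scale_speaker_sd * rnorm(1))
    list(f0 = max(f0, 80), scale = max(scale, 0.5))
  })
}

#' Synthesize a sustained-vowel corpus to disk
#'
#' Each speaker draws a per-speaker f0 and formant-scale offset and utters one
#' sustained token of each vowel. WAV files are written under `dir/wav/` and a
#' manifest CSV (`speaker_id`, `age`, `gender`, `vowel`, `path`, with paths
#' relative to `dir`) under `dir/manifest.csv`. Fully deterministic given the
#' config seed: every utterance's synthesis seed is derived from the seed and
#' the speaker/vowel indices.
#'
#' @param config A [corpus_config()].
#' @param dir Output directory (created if missing).
#' @param age_model See [default_age_model()].
#' @param vowel_specs See [default_vowel_specs()].
#' @return The manifest data frame, invisibly.
#' @export
synth_corpus <- function(config = corpus_config(), dir,
                         age_model = default_age_model(),
                         vowel_specs = default_vowel_specs()) {
  dir.create(file.path(dir, "wav"), recursive = TRUE, showWarnings = FALSE)
  speakers <- corpus_speaker_table(config)
  vowel_names <- names(vowel_specs)
  rows <- vector("list", nrow(speakers) * length(vowel_names))
  k <- 0L
  for (s in seq_len(nrow(speakers))) {
    acoustic <- speaker_acoustics(s, speakers$age[s], speakers$gender[s],
                                  age_model, config$seed)
    for (vi in seq_along(vowel_names)) {
      k <- k + 1L
      rel <- file.path("wav", sprintf("%s_%s.wav", speakers$speaker_id[s],
                                      vowel_names[vi]))
      sig <- synth_vowel(vowel_specs[[vi]], acoustic$f0, acoustic$scale,
                         config$duration_s, config$sample_rate,
                         seed = derive_seed(config$seed, s, vi))
      write_wav(sig$samples, config$sample_rate, file.path(dir, rel))
      rows[[k]] <- data.frame(speaker_id = speakers$speaker_id[s],
                              age = speakers$age[s],
                              gender = speakers$gender[s],
                              vowel = vowel_names[vi], path = rel,
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Synthesize a corpus and extract features without touching disk
#'
#' Streams through the same utterances [synth_corpus()] would write (identical
#' per-utterance seeds, so the audio is bit-identical) and extracts the
#' cepstral feature vector of each, one utterance at a time.
#'
#' @inheritParams synth_corpus
#' @param mfcc An [mfcc_config()].
#' @return Feature table: `speaker_id`, `age`, `gender`, `vowel`,
#'   `f001 ... f120`.
#' @export
synth_feature_corpus <- function(config = corpus_config(),
                                 mfcc = mfcc_config(),
                                 age_model = default_age_model(),
                                 vowel_specs = default_vowel_specs()) {
  speakers <- corpus_speaker_table(config)
  vowel_names <- names(vowel_specs)
  meta <- list()
  feats <- list()
  k <- 0L
  for (s in seq_len(nrow(speakers))) {
    acoustic <- speaker_acoustics(s, speakers$age[s], speakers$gender[s],
                                  age_model, config$seed)
    for (vi in seq_along(vowel_names)) {
      k <- k + 1L
      x <- synth_vowel(vowel_specs[[vi]], acoustic$f0, acoustic$scale,
                       config$duration_s, config$sample_rate,
                       seed = derive_seed(config$seed, s, vi))
      # round-trip through 16-bit quantisation so in-memory features match
      # features extracted from the written WAV files exactly
      pcm <- pmax(-32768, pmin(32767, round(x$samples * 32768))) / 32768
      feats[[k]] <- extract_features(list(samples = pcm,
                                          sample_rate = config$sample_rate),
                                     mfcc)
      meta[[k]] <- data.frame(speaker_id = speakers$speaker_id[s],
                              age = speakers$age[s],
                              gender = speakers$gender[s],
                              vowel = vowel_names[vi],
                              stringsAsFactors = FALSE)
    }
  }
  out <- cbind(do.call(rbind, meta),
               as.data.frame(do.call(rbind, feats)))
  rownames(out) <- NULL
  out
}

#' Gaussian feature clusters with controllable separation and complementarity
#'
#' Draws `n_per_class` samples per class from spherical Gaussian clusters
#' (within-class sd 1) whose class means are `separation` apart from the
#' origin along per-class directions. Without a `complementary_map`, a single
#' labeled feature table is returned. With a map — a list assigning to each
#' stream the subset of classes it separates — one feature matrix per stream
#' is generated for the *same* samples: in stream `s`, only the classes in
#' `complementary_map[[s]]` keep their separated means, all other classes
#' collapse onto the origin. This reproduces the complementary-information
#' regime in which different streams (vowels) are informative about different
#' age classes.
#'
#' @param n_classes Number of classes.
#' @param n_per_class Samples per class.
#' @param dim Feature dimension (>= `n_classes` for orthogonal class
#'   directions; smaller dims reuse rotated directions).
#' @param separation Distance between a separated class mean and the origin,
#'   in units of the within-class standard deviation.
#' @param seed Integer seed.
#' @param complementary_map Optional list of integer class-index vectors, one
#'   per stream; must jointly cover all classes.
#' @return Without a map: a data frame with `class` and `f001...` columns,
#'   plus `speaker_id`. With a map: a list with `labels`, `speaker_id` and
#'   `streams` (list of feature matrices).
#' @export
synth_feature_clusters <- function(n_classes, n_per_class, dim = n_classes,
                                   separation = 4, seed = 1L,
                                   complementary_map = NULL) {
  stopifnot(dim >= 1, separation >= 0, n_classes >= 2, n_per_class >= 1)
  n <- n_classes * n_per_class
  labels <- rep(seq_len(n_classes), each = n_per_class)
  directions <- matrix(0, n_classes, dim)
  for (j in seq_len(n_classes)) {
    directions[j, ((j - 1L) %% dim) + 1L] <- 1
  }
  if (!is.null(complementary_map)) {
    covered <- sort(unique(unlist(complementary_map)))
    if (!identical(covered, seq_len(n_classes)) &&
        !setequal(covered, seq_len(n_classes))) {
      stop_invalid("complementary_map must cover every class")
    }
  }
  with_seed(seed, {
    noise <- matrix(rnorm(n * dim), n, dim)
    if (is.null(complementary_map)) {
      X <- separation * directions[labels, , drop = FALSE] + noise
      out <- data.frame(speaker_id = sprintf("s%05d", seq_len(n)),
                        class = labels, stringsAsFactors = FALSE)
      feat <- as.data.frame(X)
      names(feat) <- sprintf("f%03d", seq_len(dim))
      cbind(out, feat)
    } else {
      streams <- lapply(complementary_map, function(informative) {
        means <- matrix(0, n_classes, dim)
        means[informative, ] <- separation *
          directions[informative, , drop = FALSE]
        stream_noise <- matrix(rnorm(n * dim), n, dim)
        means[labels, , drop = FALSE] + stream_noise
      })
      list(labels = labels,
           speaker_id = sprintf("s%05d", seq_len(n)),
           streams = streams)
    }
  })
}
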