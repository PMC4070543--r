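---
title: "Vowel-partitioned age estimation with fuzzy decision fusion: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vowel-partitioned age estimation with fuzzy decision fusion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the model

Estimating a child's age from voice is hard because the acoustic correlates
of age between 7 and 12 years — fundamental frequency (f0) drifting downward
by roughly 10 Hz per year and vocal-tract resonances (formants) shrinking by
about a percent a year — are small compared to inter-speaker variability.
`vowelage` implements a divide-and-conquer estimator for this setting:

1. **Front end.** Each sustained-vowel utterance is described by a
   120-dimensional cepstral vector: 40 static Mel-frequency cepstral
   coefficients from a 40-filter Mel bank, plus 40 delta and 40 delta-delta
   regression coefficients. Using 40 filters instead of the conventional 13
   makes each filter *narrower*, so less spectral smoothing is applied and
   the fine spectral structure that carries age information (harmonic
   spacing, formant positions) survives into the cepstrum.
2. **Per-vowel classifiers.** The data are partitioned by vowel class
   (/a/, /e/, schwa, /i/, /o/, /u/) and one single-hidden-layer network is
   trained per vowel with the extreme learning machine (ELM): random input
   weights, analytic minimum-norm least-squares output solve
   `beta = pinv(H) T`. The self-adaptive variant (SaELM) wraps the analytic
   solve in a differential-evolution search (`DE/rand-to-best/2`) over the
   input weights and biases.
3. **Vowel gate.** At test time a linear maximum-margin classifier
   (one-vs-one, majority vote) routes each unlabeled utterance to the
   matching per-vowel classifier, so no phonetic annotation of test data is
   needed.
4. **Fuzzy fusion.** A speaker's per-utterance decisions are aggregated by
   the fuzzy-or compromise operator

   `mu_f_j = gamma * max_i(min(w_i mu_ij, delta_ij)) + (1 - gamma) * mean_i(w_i mu_ij delta_ij)`

   where `mu_ij` are min-max-normalized scores interpreted as fuzzy
   memberships, `w_i` is the *local* confidence (a Gaussian function of the
   gap between a classifier's top two raw scores relative to its score
   range, width `sigma`), and `delta_ij` is the *global* confidence (1 only
   for the classifier with the best leave-one-out recall on class `j`). The
   rationale: different vowels carry complementary age information, so the
   operator trusts, per class, the vowel that demonstrably recognises that
   class best, while the compensation degree `gamma` blends optimistic
   (max-like) and consensus (average-like) behaviour.

# Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| frame length / hop | 55 ms / 27.5 ms | analysis frame of the front end; 50% overlap |
| `n_filters`, `n_static` | 40, 40 | Mel filters and retained DCT coefficients (0th included) |
| `delta_window` | 2 frames | regression half-width for delta features |
| `n_hidden` | 60 | hidden neurons of each network |
| population / generations | 40 / 15 | DE search budget of SaELM |
| `F`, `CR` | 1, 0.5 | DE amplification factor and crossover rate |
| `gamma` | 0.6 | compensation degree of the fuzzy-or operator |
| `sigma` | 0.05 | width of the local-confidence Gaussian |
| CV folds | 3 | speaker-disjoint, age- and gender-stratified |

# Design choices in the open points

Several front-end details are not fixed by the method description and were
decided once, as follows.

* **Filter count.** 40 static coefficients require at least 40 filters for a
  full-rank DCT; 40 filters is the minimal consistent choice and realises
  the "narrow filters" idea on the 0–10 kHz band.
* **"Single frame" with deltas.** One feature vector describes a whole
  utterance, yet delta features need temporal context. We frame the entire
  utterance (50% overlap), compute deltas over the frame sequence, and keep
  the central frame's `[static, delta, delta-delta]` stack. Sustained vowels
  are near-stationary, so the choice of frame is low-impact; the centre
  avoids onset/offset transients. Tests verify that central-frame deltas of
  a synthesized steady vowel are small relative to the static spread.
* **Pre-emphasis 0.97, Hamming window, orthonormal DCT-II with the 0th
  coefficient, `log_floor = 1e-10`, band 0 Hz–Nyquist**: standard
  speech-analysis defaults.
* **Local confidence on raw scores.** The confidence formula references the
  minimum score; after min-max normalization that minimum is pinned to 0 and
  the spread information is lost, so `w_i` is computed from the raw
  (pre-normalization) score vector.
* **Degenerate score vectors.** An all-equal score vector normalizes to the
  uniform membership `1/n` and receives the formula's ratio-zero confidence
  `exp(-0.5/sigma^2)` (total unreliability). Ties are always broken toward
  the lowest index (classifier or class), making every decision path
  deterministic.
* **Fusion unit.** The fusion unit is the speaker: every utterance of a test
  speaker contributes one (membership, local confidence, global-confidence
  row) triple, with `m` = number of utterances — including duplicates when
  the gate routes two utterances to the same vowel model.
* **SaELM fitness.** Fitness of a DE individual is the RMSE of the
  analytically solved network on a stratified 20% validation split carved
  from the training set; equal fitness is broken toward the smaller output
  weight norm. On very small training sets where a stratified split would be
  empty, fitness falls back to training RMSE. The five mutation indices are
  drawn distinct from each other *and* from the target index, so the
  population must hold at least six individuals. The returned model re-solves
  its output weights on the full training set with the winning input layer.
* **Folds.** Cross-validation folds are speaker-disjoint (all vowels of one
  child stay together) and stratified by age and gender via round-robin
  dealing, so each fold is balanced to within one speaker per age.
* **Gate backend.** The vowel gate is a soft-margin linear SVM
  (libsvm via e1071) with `C = 1`, one-vs-one with majority vote — the
  standard multi-class scheme of that solver.

# The synthetic corpus: what it emulates and what it does not

The generator reproduces the *layout and statistical structure* the method
assumes: 60 speakers per age (ages 7–12, half girls), six sustained vowels
per speaker, 5 s at 20 kHz with 16-bit quantisation. Acoustically each
utterance is source-filter synthesized: a glottal impulse train at the
speaker's f0 (1% jitter) drives three cascaded second-order resonators at
age-scaled, child-like formant targets, plus low-level noise. The default
age model — f0 declining linearly 280 to 230 Hz and formant scale shrinking
1% per year, with 5%/3% per-speaker spread — makes the age classes learnable
but heavily overlapping, which is the regime the method is designed for.

The generator does *not* model Malay phonetics, articulation dynamics,
recording-channel effects, or children's phonation irregularities beyond
jitter; passing tests therefore demonstrate that the pipeline recovers
age-correlated acoustic structure of this controlled kind, not field
performance on real recordings.

Feature-level generators complement the waveform generator:
`synth_feature_clusters()` draws Gaussian classes at a controllable
separation, and its `complementary_map` mode creates the
complementary-information regime — each stream separates only a subset of
classes — in which fusion demonstrably beats every single stream. The
fusion-adds-value checks use 3 streams over 6 classes at separation 6 with
30 samples per class, 10 seeds.

# Numerical choices

* Pseudo-inverse by SVD with tolerance `max(dim) * max(singular value) *
  machine epsilon`; the analytic solve is verified in the tests against an
  independent minimum-norm least-squares oracle to 1e-8.
* Features are affinely scaled to `[-1, 1]` per dimension using training-set
  min/max; the scaling is stored in every model and re-applied at
  prediction. Constant dimensions map to 0.
* All randomness flows through explicit integer seeds; sub-seeds are derived
  deterministically, and the RNG state of the calling session is always
  restored. Models serialize to JSON with base64-encoded IEEE-754 doubles,
  so a round trip reproduces predictions bit-exactly.
* Problem sizes in the test suite are deliberately modest (tens of samples
  per class, hidden layers of 5–25 units, DE budgets of 6–10 individuals
  over up to 15 generations); the acceptance script runs the full 360-speaker
  layout with the deployed settings (60 hidden neurons, 40 individuals, 15
  generations).

# Known limitations

* The real children's corpus the method was designed around is not
  distributable, so corpus-level accuracies cannot be reproduced here; the
  published six-class confusion matrix ships as a plain-text fixture and its
  arithmetic (overall 53.33%, three-band collapse 60.83%) is recomputed
  exactly.
* ELM output scores are unbounded real values, not probabilities; they are
  treated as raw scores and min-max normalized before fusion.
* The "self-adaptive" DE variant is implemented with the single stated
  mutation strategy and fixed `F`/`CR` — no strategy-pool adaptation, since
  the deployed settings fix all of these.
* The compromise operator is guaranteed bounded in `[0, 1]` for valid
  inputs, but it is not strictly between the per-classifier min and max for
  arbitrary confidence weights; the tests assert boundedness and the two
  limit behaviours instead.
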