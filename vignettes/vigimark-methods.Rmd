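---
title: "Predicting vigilance-task outcomes from ECoG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting vigilance-task outcomes from ECoG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vigimark)
```

## The problem

Sustained-attention performance degrades with time on task. In a visuomotor
reaction-time ("vigilance") task, a subject fixates a flickering target
through a variable delay period and responds to a GO cue; as mental fatigue
builds, incorrect trials (fixation breaks, premature or missed responses)
become more frequent. `vigimark` implements a complete single-trial
classification pipeline for this setting: given a 10-channel epidural ECoG
recording (occipital LO/RO, temporal LT/RT, frontal LFL/LFM/RFL/RFM,
midline FZ/CZ, sampled at 508.6 Hz) and a per-trial event table, it
predicts whether each trial will be performed correctly from 1 s (or
0.5 s) of brain activity recorded several seconds before the behavioural
response. A classifier of this kind is the sensing half of a closed-loop
neuromodulation system: detecting the fatigued state early enough to
intervene.

Because the original recordings are not publicly deposited, the package
ships a synthetic-session generator that carries the statistical structure
the analysis assumes, with per-trial ground truth, so every stage is
testable end to end.

## Pipeline

1. **Eye-artifact removal** (`remove_eye_components()`). Saccadic and
   ocular potentials dominate the frontal channels. The full continuous
   session is decomposed into 10 independent components (FastICA, tanh
   contrast); each component's time course is correlated with the raw LFL
   and RFL channels over the whole session, components exceeding the
   correlation threshold (default 0.1) are dropped, and the rest are
   back-projected.
2. **Epoch extraction** (`extract_epochs()`). Three evaluation periods:
   *pre-target* (a fixed window ending at target onset), *target* (1 s
   from target onset) and *delay* (1 s or 0.5 s from the delay cue — the
   main analysis window).
3. **Biomarkers** (`extract_features()`). Seventeen feature families per
   epoch, 708 columns for 10 channels (see below).
4. **Classification** (`nested_cv_evaluate()`). Gradient-boosted trees (30
   trees, maximum depth 4) with wrapper forward feature selection under
   nested, stratified 5 x 5 cross-validation. The positive class is the
   incorrect trial; the headline metric is F1, reported against the
   all-positive-detector baseline `2P / (2P + N)`.

## Biomarker families

| family | definition | notes |
|---|---|---|
| 8 band powers | Welch PSD integrated over [f_lo, f_hi) | delta 1–4, theta 4–8, alpha 8–13, low beta 13–20, high beta 20–30, low gamma 30–45, gamma 60–90, high gamma 100–200 Hz |
| wavelet entropy | −Σ p_i ln p_i over relative subband energies | db4, 4 levels; all five subbands (4 details + approximation) enter, so energies sum to 1 and E ≤ ln 5 |
| Hjorth activity / mobility / complexity | var(y); sqrt(var(Δy)/var(y)); mobility(Δy)/mobility(y) | first differences; per-sample units |
| phase–amplitude coupling | (log N − H(P)) / log N | phase 3–7 Hz, amplitude 70–130 Hz, N = 18 bins (20°) |
| instantaneous amplitude / frequency | modulus of delta-band analytic signal; phase derivative of the 4–14 Hz analytic signal; their ratio | means over the middle 80 % of samples |
| partial directed coherence | PDC_ij(f) = \|B_ij(f)\| / sqrt(b_j*b_j), B(f) = I − Σ A_k e^{−i2πfk/fs} | MVAR order 5; band feature = mean of squared PDC at 1 Hz resolution over delta, theta, alpha and beta (mapped to low beta); column-normalized per source |
| phase-locking index | \|T⁻¹ Σ e^{iΔθ_t}\| | Hilbert phases of band-filtered pairs, same four bands |
| global coherence | λ_max / Σλ of the cross-spectral matrix | 3 sine tapers, all 8 bands |

Band filtering is zero-phase: the squared magnitude response of a 4-pole
Butterworth band-pass (i.e. the response of one forward and one backward
pass) is applied in the frequency domain after odd-reflection padding to a
fast FFT length. This is what the Hilbert-based measures (PAC, PLI, IA/IF)
require, and batching all channels through one matrix FFT keeps a
708-column epoch under ~50 ms.

### Numerical choices worth knowing

- **Welch PSD**: Hann-windowed, mean-removed, 50 % overlap; for a 1-s
  epoch the segment equals the epoch (a single modified periodogram at
  ~1 Hz resolution). Band integrals are half-open `[f_lo, f_hi)`.
- **Wavelet entropy**: the decomposition is periodized after reflection
  padding to a multiple of 2^4; with an orthonormal filter the subband
  energies then sum exactly to the signal energy. Using all five relative
  energies (rather than the four details alone) keeps that conservation;
  `wavelet_subbands = "details"` is available.
- **MVAR ridge**: back-projecting a session after removing k independent
  components leaves the 10 channels at rank 10 − k, which makes the MVAR
  least-squares design exactly singular. `mvar_fit()` therefore applies a
  small relative ridge (1e−6 of the mean Gram diagonal) by default;
  `ridge = 0` restores the strict error. `mvar_order_scan()` provides an
  AIC scan; order 5 is the default because a 1-s, 10-channel epoch (509
  samples) supports roughly 500 parameters.
- **Global coherence**: a K-taper cross-spectral estimate has rank K, so
  with 3 tapers and 10 channels a *per-frequency* eigenvalue ratio is
  pinned near 1/3–0.5 for any input. The band value is therefore computed
  from the cross-spectral matrix averaged over tapers *and* band
  frequencies, which restores an informative statistic on short epochs
  while keeping the [1/C, 1] bounds.
- **Degenerate values**: Hjorth mobility/complexity of a constant trace
  and the IA/IF ratio at non-positive mean frequency are returned as
  missing and imputed inside the evaluation loop with training-fold
  medians, so no test-fold statistic ever reaches the classifier.
- **Edge handling**: Hilbert-based measures exclude 10 % of samples at
  each epoch edge.

## ICA design

Two points were genuinely open and are decided as follows:

- **Correlation target**: components are correlated against the *raw* LFL
  and RFL traces over the entire session (the cleaning is a session-level
  preprocessing stage, applied before epoching).
- **Removal rule**: a component is removed when |r| exceeds the threshold
  against *both* LFL and RFL (`criterion = "both"`, the default). Ocular
  potentials project bilaterally onto the two lateral-frontal electrodes,
  so the bilateral rule is selective for them. The alternative
  (`"either"`) is much more aggressive: with 10 whitened components the
  squared correlations against any one channel sum to one, so several
  components necessarily exceed |r| = 0.1 against LFL alone in almost any
  recording, and cleaning would strip genuine frontal signal.
- The unmixing matrix is estimated on a decimated subset (at most 250 000
  samples) for speed — it is a sample-average estimate — while source
  extraction and back-projection always use the full session. The seeded
  start makes cleaning deterministic; removing zero components is an exact
  inverse, which the identity test at threshold 1 exercises.
- Cleaning is *not* idempotent (ICA on cleaned, rank-deficient data
  decomposes differently); it is meant to run once per session.

## Classifier design

- **Ensemble**: 30 trees, maximum depth 4, learning rate 0.3, no
  subsampling, `base_score` pinned at 0.5 — a fixed configuration; the
  inner loop tunes only the feature subset and the decision threshold.
- **Wrapper forward selection**: greedy; each step adds the candidate
  maximizing stratified inner 5-fold out-of-fold F1 (probability threshold
  0.5), ties to the lower column index. The search stops at `k_max` or
  after 2 consecutive steps that fail to improve the best score by 1e−3;
  the selected set is the prefix of the path with the best score.
- **Candidate screening**: the greedy pool is pre-restricted to the
  `screen_top` columns with the highest training-fold point-biserial R²
  (default 40). Evaluating all 708 columns per greedy step costs hundreds
  of thousands of ensemble fits per session and adds nothing: wrapper
  selection beyond a univariately screened pool almost never recruits a
  column with near-zero marginal association first. `screen_top = Inf`
  disables screening.
- **Decision-threshold tuning**: after selection, the threshold is tuned
  on out-of-fold probabilities from a *fresh* inner split (grid includes
  0, i.e. the all-positive rule). Two reasons: (i) F1 is the target
  metric, and the F1-optimal rule under class imbalance is not the 0.5
  posterior cut; (ii) reusing the selection folds would inherit the
  winner's-curse bias of the greedy search. A useful consequence: when
  the features carry no signal, the tuned rule collapses toward the
  all-positive detector, so a label-shuffled null scores at the baseline
  rather than below it.
- **Nested evaluation**: outer stratified 5-fold; imputation statistics,
  screening, selection and threshold all come from the outer-training
  folds only (the report retains the fold indices for audit). Pooled
  metrics are computed from summed outer-fold confusion counts; per-fold
  metrics are also reported. Balanced accuracy = (sensitivity +
  specificity)/2 is reported alongside F1 because the unbalanced regime
  inflates F1 mechanically.
- **Feature-set conditions**: `spectral` = the 80 band-power columns,
  `HOST` = the 628 higher-order spectrotemporal and connectivity columns,
  `combined` = all.

## The synthetic generator

`generate_session()` emulates exactly the structure the analysis assumes:

- **Task timing**: 1.5 s pre-target baseline, target onset, 1 s fixation,
  delay cue, delay drawn from N(2500 ms, 250 ms) truncated at 500 ms, GO
  cue, response, 1 s inter-trial interval.
- **Fatigue and outcomes**: a latent bounded random walk with positive
  drift (logistic-squashed) rises over the session;
  P(incorrect) = logistic(a + b·fatigue), with the intercept calibrated so
  the session-mean incorrect rate hits a target (0.515 for the balanced
  regime, 270/524; 0.719 for the unbalanced regime, 518/720 — the two
  subjects' mean trial splits). This reproduces the characteristic
  within-session performance decline.
- **Background**: per-channel 1/f^1.5 noise (SD 20 µV) plus narrowband
  rhythms at 10 Hz (the task's flicker environment) and 20 Hz. The rhythms
  are band-limited noise rather than pure tones: same-frequency tones
  across channels span a shared rank-2 subspace (any mixture of sinusoids
  is a sinusoid), which is both unphysiological and degenerate for ICA. A
  slow multiplicative burst envelope (exp of <0.5 Hz noise) makes each
  channel heavy-tailed, as field potentials are; this is also what makes
  the per-channel sources identifiable to ICA.
- **Injected effects** (on incorrect trials, inside the delay window by
  default): a 1–10 Hz additive power gain; a wavelet-entropy drop
  implemented as fractional attenuation of >14 Hz content (a spectral
  tilt that concentrates relative energy in the lowest subband without
  adding low-frequency power); a stable bivariate AR(2) process with
  one-way coupling added to FZ→CZ (pole at ~4 Hz, radius 0.95), giving an
  analytic PDC target; a power-neutral phase–amplitude modulation
  (the 70–130 Hz content is multiplied by 1 + m·cos(θ_{3–7 Hz})); and
  saccade-like ocular artifacts — a biphasic ~50 ms transient plus a
  low-frequency drift burst, mixed through a fixed spatial vector
  concentrated on the frontal channels. Baseline saccades occur throughout
  every trial; *additional* intrusive saccades occur in the delay window
  of incorrect trials only, which is what makes the frontal channels
  label-informative before cleaning.
- **Ground truth** records the latent fatigue path, outcome
  probabilities, artifact counts, the artifact mixing vector, and, for
  each injected effect, the biomarker families it genuinely moves — e.g.
  the low-frequency gain also lowers Hjorth mobility and shifts relative
  wavelet energies, because any change to the spectrum propagates to
  every spectrum-derived descriptor.

What the generator does **not** emulate: volume conduction / shared
cortical sources across channels, realistic spectral nonstationarity
beyond the burst envelope, reaction-time structure, electrode drift, or
line noise. Effects are injected deterministically given the label, so
synthetic separability is optimistic: a pipeline that recovers injected
effects here is necessary-but-not-sufficient evidence for real recordings.

## Evaluation sizes

The packaged experiments use: recovery cohorts of 10 sessions x ~300
trials (acceptance tests) and 5 sessions in `scripts/acceptance.R`; greedy
search capped at 4 features over a 12-column screened pool for the cohort
experiments (training curves saturate within a handful of features on
these effect sizes); per-channel evaluations with `k_max = 3` over an
8-column pool (each channel only contributes 16 columns). Recovery
cohorts inject neural effects without artifacts so that classification
results are not confounded by the ocular pathway, which is exercised by a
dedicated artifact experiment (artifact-only sessions, before/after
cleaning).

## Known limitations

- With only 10 channels, removing independent components is aggressive:
  each removed component costs one rank of the data and some genuine
  frontal signal leaves with the artifact (visible as a large frontal
  power reduction after cleaning).
- PDC on cleaned (rank-deficient) data relies on the ridge; the
  coefficients are then the minimum-ridge solution, not unique least
  squares.
- The phase-locking statistic is the modulus of the mean phase-difference
  phasor (elsewhere called the phase-locking value); the field also uses
  "PLI" for a different, lag-asymmetric index. The formula implemented is
  the one stated above.
- Wrapper selection with screening is deterministic but greedy; it
  reports *a* near-optimal subset, not the best subset.
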