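---
title: "Methods: automated ICA filter optimization for motor-imagery BCIs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated ICA filter optimization for motor-imagery BCIs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A motor-imagery brain-computer interface (MIBCI) decodes which limb a
subject imagines moving from few-channel scalp EEG. The physiological
signal is event-related desynchronization (ERD): imagery of the left hand,
right hand or foot suppresses mu-band (≈ 8–13 Hz) power over the
contralateral primary motor cortex, i.e. under electrodes C4, C3 and Cz
respectively. Spatial filtering is essential because scalp EEG mixes all
cortical sources with eye, muscle and line interference.

`mibci` implements a fully automated ICA-based pipeline: Infomax ICA
estimates, for short EEG stretches (down to a single 10-s trial), a mixing
matrix A whose columns are spatial patterns and a separating matrix W whose
rows are spatial filters; motor-related independent components (MRICs) are
recognized purely from the mixing-matrix topographies; badly corrupted
trials are rejected in two rounds; and the surviving "high-quality" trials
are concatenated to fit the final detection filters (ICA-T). A
one-versus-rest common-spatial-patterns (CSP) baseline and a segment-level
"accuracy matrix" artifact-localization tool complete the frame.

## Models and procedures

### Infomax ICA with sub/super-Gaussian switching

The data model is a square, noiseless, instantaneous mixture `x = A s`.
`fit_ica()` iterates the natural-gradient information-maximization update

    W <- W + lr * ( I - E[ K tanh(u) u' + u u' ] ) * W,   u = W x

with K diagonal, `k_ii = ±1` the sign of the current kurtosis of source i
(+1 super-Gaussian, −1 sub-Gaussian), re-estimated on the full sources
every sweep. W starts as `0.1 I` (any common positive diagonal works);
channels are centered but **not whitened** — the natural gradient is
affine-equivariant, so pre-whitening is unnecessary and the update stays
closest to the model as written. The expectation is estimated over
shuffled blocks of 256 samples. After fitting, sources are normalized to
unit variance, the removed scale is pushed into the columns of A
(`W = A^{-1}` is recomputed), and each pattern/filter pair is sign-flipped
so the largest-magnitude entry of each A column is positive — removing
ICA's scale and sign indeterminacies before any topography is inspected.

Optimizer constants (all `ica_config()` arguments, none physiological):

* `learning_rate = 0.04 / log(N)`. Chosen by measuring separation on
  unit-variance Laplacian mixtures (N = 6, T = 5000): smaller rates
  (≈ 0.005) leave the transient unfinished after 512 sweeps.
* `anneal_deg = 110`, `anneal_factor = 0.9`. The rate is annealed only
  when successive per-sweep updates point in clearly opposing directions.
  A conventional 60° threshold fires constantly on ordinary
  stochastic-sweep noise and strangles the rate mid-transient (measured:
  median Amari index 0.2–0.27 versus 0.013–0.015 with the obtuse
  threshold on the same problems).
* `max_iter = 512`, `tol = 1e-7` on the largest per-sweep change in W.
  Separation quality on 9-channel, 2 500-sample trials plateaus by about
  64 sweeps; the multi-seed test suites therefore run at `max_iter = 128`
  (64 for the 975-fit accuracy matrix) purely to keep wall time
  proportionate, with no measurable quality loss.
* Degenerate fits (non-finite or exploding W) restart at half the rate,
  up to three times, with a warning.

The Amari index (`amari_index()`), a permutation- and scale-invariant
distance of `W A_true` from a scaled permutation normalized to [0, 1],
quantifies recovery in the tests.

### MRIC detection and the zero-training classifier

Motor sources project most strongly onto the electrode above them, so a
trial "matches" when its fitted A contains three distinct columns whose
largest-magnitude entries sit at C3, Cz and C4 (`match_mrics()`); among
several candidates for one channel, the largest magnitude wins. Matching
uses magnitudes because ICA signs are meaningless (and are canonicalized
anyway). A trial with no complete match is a **first-round bad trial**.

The matched separating rows give detection filters `w_l` (C3-dominant,
left hemisphere), `w_f` (Cz) and `w_r` (C4). One subscript convention
needs stating: the l/f/r naming is *hemisphere-based*, and the
classification rule encodes contralaterality — left-hand imagery
suppresses the right-hemisphere source, so the class is the one whose
*contralateral* source has minimum band variance:

    V = min( var(u_l), var(u_r), var(u_f) )
    class 1 (left hand)  if V = var(u_r)
    class 2 (right hand) if V = var(u_l)
    class 3 (foot)       if V = var(u_f)

Variances are taken on the subject band (10–14 or 12–16 Hz, a
configuration choice — the reactive band is found by inspection in
practice, and automatic band discovery is out of scope) over the 0.5–5 s
analysis window. Exact ties resolve in the order listed. The rule has no
fitted parameters ("zero training"). ICA itself is fitted on the 8–30 Hz
mu+beta band; only the classification variances use the narrow subject
band — the broad band retains enough structure for source separation
while the narrow band concentrates the ERD contrast.

### Two-round trial selection, ICA-T and ICA-S

Every training trial gets its own single-trial ICA; each matching trial's
filters define a single-trial BCI (st-BCI) whose accuracy `R_j` over the
whole training set scores that trial's quality. Round-1 bad trials are
recorded with `R_j = 0` and excluded from all averages. The second round
discards trials with `R_j` below the mean of the P nonzero accuracies
(`second_round_select()`; absolute and quantile thresholds are available).
The kept trials are sorted by descending `R_j` (ties by ascending trial
index, for reproducibility), the top m = 10 are concatenated in time, and
one final ICA on the concatenation yields the optimized **ICA-T** filters.
The **ICA-S** baseline instead fits one ICA per sliding window of 10
consecutive trials at step 1; for a 75-trial run the count formula
`n − win + 1` gives 66 windows (one reference description of the same
protocol counts 65; the arithmetic here is 66 and the implementation
returns 66). `affected_windows()` books which windows touch given artifact
trials: for artifact trials {43, 46}, windows 34–46.

### CSP baseline

For each class versus the pooled rest, the two class covariances (average
of per-trial, trace-normalized covariances — trace normalization is the
standard reading of "centered and scaled" and stops high-power trials from
dominating) are jointly diagonalized: `W' Σ⁺ W = Λ`,
`W' (Σ⁺ + Σ⁻) W = I`, solved as a generalized eigenproblem via whitening
of the composite covariance. The eigenvectors of the largest and smallest
λ are kept — 3 splits × 2 filters = 6 spatial filters. A linear
discriminant on the normalized log-variances of the two filtered signals
(`log(v_i / Σv)`, which makes the whole classifier invariant to a common
rescaling of the data) produces each split's vote; the label is the class
with a lone positive vote, else the largest discriminant score. The
post-CSP binary classifier is a genuinely free choice in this design; LDA
on log-variance features is the field's standard one. `csp_self_test()`
repeats a stratified random 80% train / test-on-all-75 protocol 30 times.

Testing on all trials includes the training set, which matters for one
diagnostic: under label shuffling that protocol still returns ≈ 0.57
(measured), because CSP + LDA partially memorize arbitrary labels. The
chance control in the acceptance suite therefore scores the
`test = "holdout"` variant (only the 20% unseen trials), which sits at
1/3 under shuffling as a permutation baseline must.

### The accuracy matrix

`segment_count()` implements `M = round((T_t − T_o)/(T_s − T_o))`
(half-away-from-zero; R's own `round()` is banker's and would give 4 for
4.5). With 11-s trials, 5-s segments and 4.5-s overlap, M = 13. Each of
the M × L segments (975 for a 75-trial run) gets its own ICA fit + MRIC
match + evaluation over a test set, giving an M × L matrix of accuracies
in which low columns localize artifact *trials* and low cells localize
artifact *segments within a trial*. Cells where matching fails hold the
sentinel −1 — "no BCI could be built" is different information from "a
BCI that always errs" — and are excluded from all summaries
(`summarize_rows()` gives per-segment five-number summaries). A last
segment that overruns the trial is truncated and zero-padded, with a
warning.

### Preprocessing

All temporal filters are linear-phase Hamming windowed-sinc FIRs applied
with explicit group-delay compensation and reflect padding — the realized
response is exactly the designed magnitude response at zero phase. The
band-pass uses a 2 Hz transition (order ≈ 3.3·fs/2), the 49–51 Hz notch a
1 Hz transition. Epoch windows are half-open `[start, end)` in samples;
trial indices are 1-based everywhere a person reads them. Channel
selection is a pure row permutation (the eight-channel frontal/central/
occipital and nine-channel sensorimotor montages are built in).

## The synthetic-data generator

No public recordings accompany the protocol this package targets, so
`generate_dataset()` provides the test substrate: a forward model
`sensors = A_true · sources + noise` on the real 8/9-channel montage
geometry with

* three MRIC sources with compact Gaussian spatial profiles (σ = 0.3 in
  unit-head-circle coordinates, about one inter-electrode spacing)
  centered on C3, Cz, C4 — unimodal topographies like real mu sources,
  with no volume-conduction head model;
* background sources with smooth random topographies at well-separated
  scalp sites, redrawn until the mixing matrix's condition number is
  below 25 (an accidentally near-singular forward model is a numerical
  pathology, not an interesting physiological condition);
* mu carriers: 10–14 Hz Gaussian noise with slow (≤ 1 Hz) amplitude
  modulation (`mod_depth = 0.3`), making them super-Gaussian the way real
  waxing-and-waning mu is — pure sinusoids would be sub-Gaussian and
  atypically easy for ICA;
* ERD: during the 0.5–5 s imagery window the class-appropriate
  contralateral source (class 1 → C4 source, class 2 → C3, class 3 → Cz)
  is attenuated to `erd_depth` of its power (default 0.5);
* white sensor noise at `snr_db = 10` dB below mean signal power;
* artifacts: frontal biphasic blink pulses, occipitally loaded waxing
  10 Hz alpha, and — the disruptive one — broadband white-noise bursts
  (Tukey-tapered, 0.5–1 s, default 10× channel std) on a majority of
  channels of designated trials, emulating body-movement and
  electrode-cable interference.

One calibration deserves emphasis: the carriers' power is standardized
per trial, separately inside and outside the imagery window, so that
`erd_depth` is the *realized* power attenuation rather than its
expectation. A 4 Hz-wide Gaussian carrier has an intrinsic power CV of
≈ 25% over a 4.5-s window (≈ 18 independent spectral degrees of freedom);
left uncalibrated, that fluctuation alone would drown a 3 dB ERD and no
classifier — not even one using the true inverse mixing — could be
reliable. Real mu rhythms are not power-calibrated, so simulated accuracy
ceilings are higher than anything achievable on real EEG; what the
simulator is for is *relative* and *structural* claims (artifact trials
score lower than clean ones; ICA-T beats the single-trial mean; shuffled
labels give chance), not absolute accuracy prediction.

Everything is a deterministic function of the config seed. The ground
truth records `A_true`, the source roles, labels, artifact trials and the
true MRIC source time courses. `oracle_filters()` returns the rows of
`solve(A_true)` rescaled to unit source variance on the 8–30 Hz band —
the same normalization fitted models get, on the same band, without which
the three sources' baseline variances would not be comparable and the
minimum-variance rule would be meaningless.

What the simulator does **not** model: volume-conduction head geometry
(topographies are parametric Gaussians), ECG, inter-session
nonstationarity (a "second session" shares `A_true` exactly), mislabeled
trials, and 1/f structure inside the narrow subject band. Passing tests
on this substrate demonstrate the pipeline's bookkeeping, selection
logic and separation machinery, not clinical-grade performance.

## Problem sizes in the test suite

Module tests run on 12-trial runs; the end-to-end suites use the full
protocol geometry (75 trials, 9 channels, 250 Hz): one 13 × 75 accuracy
matrix (975 ICA fits at 64 sweeps), 50 Laplacian-mixture recovery fits
(T = 5000, 256 sweeps), 20 seeded burst-rejection pipelines and 30 seeded
label-shuffle pipelines (128 sweeps). These sizes were chosen so the
whole suite completes in roughly a quarter hour on one CPU while leaving
every multi-seed proportion estimate with ≤ 1/20 resolution.

## Known limitations

* MRIC identification is purely spatial (argmax of |A| columns); spectral
  or template features are deliberately out of scope, so a non-motor
  source that happens to peak at C3/Cz/C4 can be picked on a bad trial —
  which is exactly what the second selection round is for.
* The square, noiseless ICA model allocates components to strong
  artifacts at the expense of brain sources; that is the failure mode the
  two-round selection exploits, but it also means heavily contaminated
  *test* data degrade gracefully rather than being repaired.
* The EDF reader/writer covers the common continuous-recording subset
  (EDF+C, one annotation channel, uniform rate) only.
* `fit_ica` is restricted to square mixing (as many sources as channels);
  no PCA reduction is offered.
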