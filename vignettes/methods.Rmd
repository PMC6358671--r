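---
title: "Within- and between-subject variability of evoked EEG responses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within- and between-subject variability of evoked EEG responses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

A transient nociceptive stimulus evokes a stereotyped EEG response whose
components — the N1, N2 and P2 vertex waves, the low-frequency
laser-evoked potential (LEP), the alpha-band desynchronisation (α-ERD)
and a brief gamma-band synchronisation (γ-ERS) around 60–90 Hz — are all
graded with the reported intensity of the percept. Two very different
questions hide behind that gradation:

* **Within-subject (state) variability.** Across the trials of one
  individual, does a larger response accompany a higher rating? This is
  quantified per subject as the Pearson correlation between single-trial
  feature magnitude and single-trial rating, carried to the group through
  the Fisher transform $z = \operatorname{atanh}(r)$ and a one-sample
  *t* test of the $z$ values against zero.
* **Between-subject (trait) variability.** Across individuals, does a
  person with a larger average response also report more pain on average?
  This is the Pearson correlation, over subjects, of mean feature
  magnitude with mean rating.

The package implements the full analysis chain for both questions —
preprocessing, single-trial time-frequency decomposition, feature
extraction, correlation statistics with false-discovery-rate control,
point-by-point statistic maps with cluster permutation tests, ROC
analyses, mixed-design ANOVAs on median-split data, and a PCA +
random-forest prediction of individual sensitivity — together with a
synthetic cohort generator whose ground truth makes every stage
testable. The scientifically interesting configuration is a
*dissociation*: all six features carry state coupling, while only the
γ-ERS carries trait coupling.

## The synthetic cohort generator

`generate_cohort()` emulates a single-session design: 96 subjects, 10
trials at each of four stimulus energies (2.5–4 J) in pseudorandom
order, 1.5-s epochs (−0.5 to +1 s around stimulus onset) sampled at
1000 Hz on a small montage (Fz, Cz, C4 and two EOG channels by default;
any montage containing those labels is accepted).

**Ratings.** Subject $i$ rates trial $t$ as
$r_{it} = \mathrm{clip}(b_i + s_i E_{it} + \varepsilon_{it},\,0,\,10)$
with energy level $E\in\{1..4\}$, $b_i \sim N(3.25, 1)$,
$s_i \sim N(1, 0.05)$ and trial noise $\varepsilon \sim N(0,1)$. These
values put the population mean rating at 5.75 with a between-subject
spread of about one rating unit and an average gain of one unit per
energy step, typical of laser-pain cohorts. Ratings are continuous by
default (`round_step` discretises them when rating-scale granularity is
to be emulated); continuous ratings avoid artificial ties in the ROC and
correlation analyses. The slope spread is deliberately small: pilot
simulations showed that marked slope heterogeneity makes a subject's
within-trial rating *spread* a trait, which leaks into extremum-based
peak measures and induces spurious between-subject correlations in
features designed to have none.

**Response features.** Each feature has a latent per-trial amplitude

$$a_{it} = \beta + u_i + \kappa_w\,(r_{it} - \bar r_i) + \kappa_b\,\bar r_i + \eta_{it},$$

with baseline $\beta$, a per-subject trait offset $u_i \sim N(0,
\sigma_u)$, state coupling $\kappa_w$ to the trial-demeaned rating,
trait coupling $\kappa_b$ to the subject-mean rating, and trial noise
$\eta$. Amplitudes are clipped at zero (suppression depths additionally
at one). The waveforms are Gaussian-enveloped: plain enveloped peaks for
N1/N2/P2, envelope × cosine for the oscillatory LEP (4 Hz) and γ burst
(72 Hz, envelope width 28 ms, so its time-frequency support matches the
canonical 180–260 ms, 60–85 Hz region), and a multiplicative suppression
gate on the ongoing alpha process for the α-ERD. Phase-locked features
use phase 0; the γ burst and the alpha process draw a uniform phase per
trial, which is what makes the γ-ERS cancel in the across-trial average.
Channels receive topography-weighted sums of these components plus
1/f-shaped ("pink") background noise (sd 3 µV, independent per channel)
and a 10 Hz alpha oscillation (4 µV); EOG channels receive no γ
component, reflecting the neural (non-ocular) origin of the gamma
response. Spatial noise covariance is not modelled — the downstream
statistics operate per channel or on fixed derivations, so only the
marginal structure matters here.

**Scenarios.** `default_feature_specs()` ships three: `dissociation`
(all six features state-coupled, only γ-ERS trait-coupled; the default),
`null` (all couplings
zero; used for calibration checks) and `trait_dominant` (γ amplitude
near-deterministically encodes the subject-mean rating; used for
prediction-recovery checks).

**Calibration.** The coupling constants are not free dials: they were
fixed once by a pilot simulation so that the *recovered* correlations on
default cohorts land at magnitudes typical of real laser-EEG data —
within-subject mean r of about −0.10 (N1), −0.50 (N2), 0.45 (P2), 0.58
(LEP), −0.06 (α-ERD) and 0.16 (γ-ERS), and a between-subject r of about
0.3 for γ-ERS with all other between-subject correlations near zero.
Because measurement (extremum picking, top-20% ROI averaging) sits
between the latent amplitudes and the recovered statistics, this
calibration is empirical rather than closed-form; the frozen values live
in `default_feature_specs()`.

## Preprocessing

Band-pass filtering uses a 4th-order Butterworth response applied
zero-phase: the exact forward–backward (squared-magnitude) response is
applied in the frequency domain after odd-reflection padding of three
filter time constants (`3·fs/low_hz` samples). A zero-phase response is
essential here because peak latencies feed the analysis windows; an
asymmetric filter would bias them. Epochs are baseline-corrected by
subtracting the per-trial prestimulus mean. Ocular-artifact correction
is deliberately absent — the generator produces no ocular artifacts —
but `select_channels()` provides the channel-exclusion mechanism a real
dataset would need.

Peak amplitudes (N1 on the C4–Fz derivation, N2/P2 on Cz) are measured
on 30-Hz low-passed copies of the waveforms. Peak measurement had to
decide an ambiguity: single-trial extremum search on broadband traces is
biased by whatever high-frequency activity overlaps the search window,
and the γ burst overlaps the N2/P2 windows. Smoothing before peak
picking is the standard ERP practice, and without it a designed-null
feature inherits a spurious trait correlation from the γ component —
the low-pass restores the intended measurement.

## Time-frequency decomposition

`wft_tfd()` computes, per trial, $P(t,f) = \bigl|\sum_n x(n)\,h(n)\,
e^{-i2\pi f n/f_s}\bigr|^2$ over a 250-ms Hanning window centred at $t$
(251 samples at 1000 Hz), on a 1–100 Hz grid in 1-Hz steps and a 10-ms
time step by default; grid points whose window would cross an epoch edge
are dropped. Power is the squared two-sided windowed-DFT magnitude with
no further normalisation — every downstream quantity is a *percent
change*, which cancels any fixed gain. The implementation is a single
real matrix product per subject against a stacked cosine/sine basis; its
contract is pinned by tests comparing ≥100 random (trial, time,
frequency) probes against a directly summed DFT at relative error
below 1e−9.

Baseline normalisation follows the ER%/ERD–ERS convention:
$100\,(P(t,f) - B(f))/B(f)$, where $B(f)$ is the mean of the
trial-averaged prestimulus power over −0.4 to −0.1 s. The margins keep
half a window away from both the epoch start and stimulus onset so no
post-stimulus energy leaks into the baseline; at the default grids the
earliest usable centre is −0.375 s, and the baseline average simply uses
the available grid points in the window. Using the trial-averaged
spectrum as the reference (rather than each trial's own prestimulus
power) keeps single-trial percent-change values finite and comparable
within a subject, which is what makes trial-level correlation possible.
A zero baseline at any frequency is a hard error, not a silent NaN.

`split_phase_locked()` returns the evoked (WFT of the average waveform),
total (average of single-trial WFTs) and induced (total − evoked)
representations. The trial-level feature magnitudes — including the LEP
— are measured on single-trial *total* power: a per-trial "evoked"
quantity does not exist, and the 1–10 Hz band of single trials is
dominated by the phase-locked LEP anyway. The evoked/induced split
remains available for map-level analyses and for demonstrating that the
γ burst is non-phase-locked.

## Feature magnitudes

Time-frequency magnitudes average the most extreme `fraction` (default
0.2, i.e. the top 20%) of baseline-corrected points inside each
rectangular ROI — most positive for LEP and γ-ERS, most *negative* for
the α-ERD, whose defining signature is a power decrease; selecting
maxima there would measure noise. The count is
`ceiling(fraction × ROI size)`; boundary ties break deterministically by
earlier time, then lower frequency. Peak amplitudes are signed extrema
with their latencies; ties break to the earliest sample.

## Correlation statistics and multiplicity

Per-subject correlations require at least 3 trials and nonzero variance;
degenerate subjects are excluded with a logged warning rather than
poisoning the group test. $|r|=1$ is clipped to $1-10^{-12}$ before the
Fisher transform. The six within-subject and six between-subject p
values are treated as one multiple-comparison family and adjusted
jointly by Benjamini–Hochberg; with only one true trait effect among
twelve tests, per-family adjustment would be needlessly conservative for
the within tests and anticonservative decisions would not survive the
pooled family either.

Point-by-point maps apply the same two statistics at every
time-frequency point. Cluster inference thresholds the observed map at
pointwise two-sided p < α (default 0.05), forms 8-connected clusters of
same-signed suprathreshold points, scores each by its mass (sum of
absolute statistic values) and compares against the permutation null of
the *maximum* cluster mass — ratings shuffled across trials within each
subject (within mode) or subject-mean ratings shuffled across subjects
(between mode), 5000 permutations by default. The permutation p is
$(1+\#\{\text{null} \ge \text{obs}\})/(1+B)$: unbiased, never zero, and
consistent with reporting "P < 0.001" at 5000 permutations. Two caveats
are inherent to this construction and documented rather than hidden:
clusters are defined and then tested on the same data (the usual
circularity of cluster-then-test pipelines), and subjects dropped at
degenerate points are dropped pointwise, not globally.

## ROC analyses

AUCs are computed by the Mann–Whitney identity (midranks, so ties count
half). Energy discrimination is summarised as the mean of per-subject
AUCs per energy pair — pooling trials across subjects would conflate
exactly the two levels of variability this package exists to separate.
Sensitivity classification splits subjects at mean-rating cutoffs 4 (the
conventional pain threshold), 5, 6 and 7, with boundary subjects
assigned to the *lower* group ("lower vs higher than"), and computes the
AUC of mean γ-ERS magnitude between groups; cutoffs that empty a group
are skipped with a warning.

## Median splits and mixed ANOVAs

`median_split()` sorts ascending and assigns the lower half to "low"
(`floor(n/2)`, so 96 subjects give 48/48 and 40 trials give 20/20; odd
counts put the extra value in "high"); all-tied inputs still split
deterministically by original index, with a warning. The ANOVAs operate
on per-subject cell means so the mixed design is exactly balanced: a
2×2 (trial category × subject category) per feature, and a three-way
(trial × feature × subject category) on z-scored LEP/α-ERD/γ-ERS cell
means, z-scoring each feature across the full sample so that µV and
percent-change units can share one model. Effects are reported with
partial $\eta^2 = SS_\text{effect}/(SS_\text{effect}+SS_\text{error})$
against each effect's own stratum error. Two-level within factors are
exact; effects involving the three-level feature factor carry a
Greenhouse–Geisser epsilon and corrected p. Post hoc low- vs high-pain
subject contrasts per feature are uncorrected two-sample t tests (with
partial η²), matching the plain post hoc p values such analyses report;
a Bonferroni multiplication is a one-liner the user can apply.

## Prediction

The prediction stage vectorises each subject's mean baseline-corrected
γ-ROI power (the a priori 180–260 ms, 60–85 Hz window, or a data-driven
cluster window when one is supplied), reduces to 20 principal components
and predicts each held-out subject's mean rating with a random forest
(1000 trees, p/3 split variables, unlimited depth) trained on the
remaining 95, repeated so every subject is tested exactly once. The PCA
is refit inside each training fold by default — fitting it once on all
subjects leaks the held-out subject's covariance into training; because
that global variant is a common (if leaky) practice, it is available as
`pca_global = TRUE`. Performance is reported as MAE in rating units and
the Pearson r between predicted and real ratings.

## Orchestration, containers, reproducibility

`run_pipeline()` chains simulate → preprocess → TFD → features →
correlation stats → cluster maps → ROC → ANOVAs → prediction, each stage
consuming only earlier artifacts, and aborts with the stage name on
failure. A single global seed derives per-stage seeds by stable hashing
of the stage names, so a stage rerun in isolation reproduces its
in-pipeline stream. Results serialise as JSON at full double precision
(human-readable tables at 6 significant digits); epoch containers are a
versioned single-file format (R's native serialisation) carrying shape
and channel metadata that is verified on read, plus provenance (config
hash, seed, package version, step log). Configurations round-trip
through YAML with field names mirroring the R objects.

## What the tests do and do not show

The verification suite runs entirely on synthetic cohorts, at sizes
chosen to keep a full run on one CPU within minutes:

* oracle equivalences (windowed DFT, BH step-up, pair counting, ANOVA
  sums of squares, eigendecomposition) at tiny sizes;
* null calibration on 100 zero-coupling cohorts of 12 subjects × 20
  trials at 250 Hz — feature-level group tests and the cluster
  permutation family-wise error both land inside the binomial 95%
  interval of the nominal 5%;
* dissociation recovery on 20 full-size cohorts (96 × 40, three analysis
  channels plus EOG, no band-pass stage — the generator's background is
  already free of the artifacts the filter exists to remove, and the
  filter has its own behavioural tests);
* prediction recovery on 48-subject cohorts at 250 Hz.

Passing these shows the *pipeline* is correct and calibrated under the
generator's assumptions: Gaussian-enveloped components, linear coupling,
1/f noise, no artifacts, no spatial covariance, no latency jitter
coupling. It does not certify performance on real recordings, where
filter choices, artifact correction and electrode-level covariance all
matter. The headline real-data quantities of this literature (e.g. a
between-subject γ correlation near 0.3, prediction MAE near 0.4) depend
on unreleased human recordings; here they appear only as calibration
targets for the generator, not as claims about real data.

A note on the dissociation-recovery margin: with the calibrated effect
sizes, the binding steps are the weakest within-subject effect (α-ERD,
r ≈ −0.06, detection probability ≈ 0.9 per cohort at the pooled-FDR
threshold) and the γ-ERS between-subject test (r ≈ 0.3 against a
q < 0.05 threshold near r ≈ 0.22). The joint "all six within AND only
γ-ERS between" event therefore holds in most, but not reliably ≥ 90%,
of replicate cohorts — a power limit of the study conditions themselves
(real cohorts with α-ERD r = −0.06 sit at the same boundary), not an
implementation defect.
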