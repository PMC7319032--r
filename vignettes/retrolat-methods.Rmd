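---
title: "Models and methods behind retrolat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind retrolat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(retrolat)
```

retrolat implements the analysis chain of a retro-cue experiment on visual
working memory with two lateralized oriented items and concurrent EEG: a
circular mixture model for continuous-report behavior, wavelet time-frequency
analysis of posterior alpha power, nonparametric sample-level inference on
the ipsilateral/contralateral contrast, a single-trial template-correlation
classifier of the cued hemifield, and mixed-model analyses that ask whether
lateralization strength predicts memory performance. Because such studies
rarely deposit raw recordings, the package also contains a synthetic-data
generator that emulates the design, so that every stage can be exercised,
calibrated and stress-tested end to end. This vignette explains the models,
the tunable parameters, the numerical choices, and what the synthetic tests
do and do not establish about real data.

## The behavioral model

Continuous-report errors are coded as signed angles in (-180, 180]:
`signed_error()` measures the circular distance between report and target
and gives it a positive sign when the report lies on the shorter arc from
the target toward the distractor, so positive errors indicate attraction
toward the irrelevant item.

Errors are modeled by the bias-extended standard mixture model. With
probability g the item is absent from memory and the response is uniform on
the circle; otherwise the error follows a von Mises distribution with
concentration kappa and mean mu (degrees, positive toward the distractor):

f(x; g, mu, kappa) = g/360 + (1 - g) * exp(kappa * cos(x - mu)) / (360 * I0(kappa))

The density is *per degree* — the von Mises normalization is 360 I0(kappa)
with the cosine argument converted to radians — so it integrates to 1 over
(-180, 180]. Large concentrations are handled with the exponentially scaled
Bessel function and a log-space path, so the density and log-likelihood are
finite for any kappa.

`fit_mixture()` maximizes the log-likelihood with bounded quasi-Newton
(L-BFGS-B) from eight deterministic starts (a grid over kappa in {2, 10, 40},
g in {0.05, 0.3}, mu in {-10, 0, 10}, subsampled), with bounds kappa in
(1e-3, 200], g in [0, 1], mu in [-180, 180]. kappa = 200 corresponds to a
circular SD of about 4 degrees, beyond the precision the task can produce;
boundary estimates are flagged. The optimum is polished by refitting from
itself. Two numerical choices deserve mention:

* **The uniform ridge.** For data close to circular-uniform, only the
  product (1 - g) * kappa is identified; g can wander anywhere along a
  likelihood ridge. When BIC prefers the zero-parameter pure-guessing model
  over the three-parameter mixture, the fit is reported at the canonical
  guessing end of the ridge (g = 1, kappa at its lower bound, flagged
  `kappa_unidentifiable`) instead of an arbitrary ridge point.
* **Minimum trials.** Fits require 20 errors by default (configurable);
  grouped fits flag cells under 30 trials as unstable without dropping them.

`condition_contrast()` compares the three parameters between cued and
non-cued conditions across participants with paired two-tailed t-tests,
Holm-corrected across the three parameters.

## The synthetic experiment

`design_spec()`/`generate_design()` reproduce the trial structure: 576
retro-cued and 288 non-cued trials per participant in homogeneous blocks of
48 split over two sessions, cue side balanced 50/50 and pseudo-randomized,
and orientation pairs drawn by rejection sampling from the discrete uniform
on 1-360 degrees subject to a pairwise circular difference between 10 and
120 degrees and an exclusion zone of +-5 degrees around the cardinal axes
(the exclusion width is a package choice — the design prose names the
constraint but not its width — set to match the 10-degree granularity of the
minimum-difference rule). Rejection sampling is provably uniform on the
admissible set; a cap of 10^4 rejections per trial turns impossible
constraint combinations into an explicit error.

`generate_montage()` builds an equidistant cap: concentric rings around the
vertex extending to 100 degrees of polar angle (below the equator over
occipital cortex), exactly mirror-symmetric about the sagittal plane, with
two midline channels per ring and all other channels in left/right mirror
pairs. Adjacency connects channels within 1.3 times the median
nearest-neighbour distance; the threshold grows in 10% steps until every
channel has at least two neighbours and the neighbourhood graph is
connected, as on a physical cap.

`simulate_eeg()` writes each epoch as 1/f background noise (spectrally
shaped Gaussian noise, default slope 1) plus a posterior alpha oscillation
(default 10 Hz) whose spatial profile is a Gaussian bump around a posterior
focus in each hemisphere. After cue onset the amplitude of the hemisphere
contralateral to the cued side is scaled by 10^(-L/20), where L is the
trial's realized suppression in power dB: the configured mean
`lateralization_db` plus Gaussian per-trial jitter. Non-cued trials are not
lateralized by default (the probed side can be used instead for stress
tests, `lateralize_uncued`). When `behavior_coupling` c > 0, the trial's
jitter z-score maps to a concentration multiplier max(0.1, 1 + c z) recorded
in the trial metadata and honored by `simulate_responses()`; trials whose
lateralization is not expressed (non-cued by default) keep multiplier 1.
This gives a monotone, tunable link between realized lateralization and
response precision for positive-control tests. One global seed fans out to
per-stage child seeds by fixed offsets (`child_seed()`), and every child
seed is recorded, so any stage can be replayed exactly.

What the generator does *not* emulate: volume conduction from a head model,
ocular and muscle artifacts, event-related potentials (e.g., the
contralateral delay activity), session breaks, or any nonstationarity of the
alpha rhythm beyond the cue-locked gain change. Passing tests on this
generator therefore certify the *analysis machinery* — estimator
consistency, error control, invariances — not the physiological validity of
any conclusion drawn from real recordings.

## Spectral analysis

`morlet_tfr()` convolves each epoch with complex Morlet wavelets on 30
logarithmically spaced frequencies from 2 to 40 Hz, with cycles increasing
from 1 to 10; the cycle schedule is log-spaced to match the log frequency
grid (the prose behind this convention states only that cycles increase with
frequency). Convolution is computed in the frequency domain after
reflection-padding by one half-support (3.5 standard deviations) of the
longest wavelet; samples within one half-support of an epoch edge are
flagged per frequency in an edge mask rather than silently returned.
Wavelets are normalized to unit peak frequency response, so a sinusoid at a
bin's center frequency keeps its amplitude regardless of the cycle schedule.

`db_baseline()` implements single-trial decibel baselining: for each trial,
channel and frequency, raw power is divided by its mean over the baseline
window (default: the 500 ms before cue onset) and scaled by 10 log10. The
per-trial baseline is noisier than a cross-trial mean but is what the
single-trial analyses require; a cross-trial-mean baseline is available as
an explicit non-default (`per_trial = FALSE`). A non-positive baseline is an
error that names the offending trial and frequency. The correction is
exactly invertible, which the tests verify to 1e-10.

`band_average()` and `band_time_average()` reduce dB power to alpha-band
(7-14 Hz, bin centers, inclusive) time courses and per-trial topographies by
unweighted means. `tfr_decimate()` optionally subsamples the power time
axis; band-limited power envelopes carry no information near the raw
sampling rate, and reduced-scale runs decimate to ~32 Hz.

## Sample-level inference

`make_ipsi_contra()` converts channel space into lateralization space: for
every mirror electrode pair, the member contralateral to the cued side is
"contra" and the other "ipsi", per trial, averaged within participant.
Midline channels have no contralateral partner and are excluded from this
contrast by construction.

`cluster_permutation_test()` is a paired, two-tailed cluster-based
permutation test over site x time samples: per-sample paired t-tests,
thresholded at a sample-level alpha of 0.05, suprathreshold samples of equal
sign grouped into spatio-temporally connected clusters (temporal links
between consecutive samples, spatial links from the montage adjacency), each
cluster scored by its summed t (t_sum), and the observed t_sums compared to
the permutation null of the maximum |t_sum| under within-participant
ipsi/contra swaps — equivalently, random sign flips of each participant's
difference, the exchangeable unit in a paired design. A spatial-extent rule
(FieldTrip-style minimum-neighbour criterion, default 2) prunes time slices
whose member sites do not include a spatially connected group of the
required size. Cluster p-values use the +1-corrected Monte-Carlo formula
(n_exceed + 1)/(n_perm + 1); `n_perm = "all"` enumerates all 2^n sign
patterns and returns the exact fraction instead, which the tests compare
against an independent brute-force oracle. Zero-variance samples get t = 0
(excluded from clusters) with a warning. If no cluster is significant,
downstream stages fall back — explicitly and loggedly — to the canonical
300-1070 ms post-cue window (`default_sig_window()`).

`conventional_lateralization_index()` provides the classic scalar summary
(mean ipsi minus contra dB over the significant sites and window, per
participant) for comparison with the classification-based measure.

## Single-trial classification

Per participant, `compute_template()` averages the alpha topographies of all
left-cued trials and subtracts the average of all right-cued trials; each
trial's topography is scored by its Pearson correlation with that template
(`correlate_trials()`). The directional convention is fixed: template =
left - right, so left-typical trials correlate positively and trials with
r above the ROC cutoff are classified "left" (descriptions of this
procedure differ in sign between sources; the direction cancels in accuracy,
so one convention is fixed and documented). The ROC is swept over all
distinct correlation values, AUC computed by trapezoid — the tests verify
the exact identity AUC = U/(n1 n2) with the Mann-Whitney statistic — and
the cutoff maximizes Youden's J (ties toward the smaller threshold), the
equal-cost, equal-prior special case of an "optimal operating point".
Non-cued trials are scored against the same template and cutoff, with the
to-be-probed side as their true label.

By default the template includes the trial being classified (no
leave-one-out), matching the original procedure; `leave_one_out = TRUE`
removes the self-inclusion bias. Because of that bias, inference must not
shuffle labels over *fixed* correlations: a trial's correlation is tilted
toward its own true label, so the observed accuracy would dominate such a
null even without any signal (simulations show mean null p ~ 0.04 instead
of 0.5). `permutation_pvalue()` therefore recomputes the template, the
correlations and the ROC cutoff inside every permutation when topographies
are available, restoring exchangeability; re-optimizing the cutoff per
permutation additionally charges the null for cutoff-selection bias. The
p-value is (n_k + 1)/(n_tot + 1) with n_k the number of null accuracies
above the observed one. Accuracy is discrete (granularity 1/n_trials), and
at reduced scale roughly 10% of permutations tie the observed accuracy;
counting ties as "not higher" would bias p low. Ties are therefore resolved
by the much finer-grained AUC: a tying permutation counts as higher only if
its AUC exceeds the observed AUC. Under a zero-lateralization generator the
resulting p-values are uniform (Kolmogorov-Smirnov check in the test
suite).

`group_trials()` forms the four analysis groups: trials are "consistent" or
"inconsistent" by whether the classifier's prediction matches the true
side, and each consistency set is median-split on |r| into "strong" and
"moderate" (ties at the median count as strong — a documented rule; the
four group labels require a magnitude split).

## Linking lateralization to behavior

`fit_by_group()` fits the mixture model per participant x cue x group cell
(per-participant fits, consistent with study degrees of freedom; cells
under 30 trials flagged, under 20 not fitted but kept as NA rows).
`mixed_model_interface()` builds, per parameter, the long-format table and
fits a linear mixed model with fixed factors cue and lateralization (the
four groups, or classification accuracy as a continuous between-participant
predictor) and a random intercept per participant, via lme4/lmerTest.
F-tests use Kenward-Roger denominator degrees of freedom when pbkrtest is
available (Satterthwaite otherwise, with a message); p-values are
Holm-corrected across the three effects within each parameter
(`holm_correct()`, a validated wrapper over `stats::p.adjust`). For a
complete two-level single-factor design the model reduces exactly to the
paired t-test, which the tests assert to 1e-6. Bayes factors are outside
the package's scope; the summary table carries everything needed to compute
them externally. `accuracy_benefit_correlation()` adds the conventional
between-participant check: the Pearson correlation between a participant's
lateralization measure and their cued-minus-non-cued parameter benefit.

## The replica pipeline and problem sizes

`run_pipeline()` chains all stages — design, EEG simulation, responses,
behavioral fits and contrast, TFR with single-trial dB baseline, cluster
test on the cue-to-probe interval, per-participant classification,
grouping, grouped fits, and both linkage models — from a single validated
configuration (`pipeline_config()`, also readable from YAML). All
randomness derives from per-stage child seeds recorded in the manifest,
along with MD5 checksums of everything written to disk, so a rerun with the
same configuration and seed reproduces every output.

The default configuration is a desk-scale study: 10 participants, 200 cued
+ 100 non-cued trials, 32 channels at 256 Hz; `paper_scale = TRUE` switches
to the full design (39 participants, 576 + 288 trials, 64 channels,
512 Hz). The test suite and the acceptance script use further-reduced
problem sizes chosen once as study conditions: mixture recovery at the real
per-condition trial count (n = 576, 20 replicates); familywise error of the
cluster test over 200 null simulations of 8 participants; classifier null
calibration over 200 zero-lateralization runs of 64 trials at 128 Hz on an
8-channel cap; and linkage calibration over 20 replicate studies of 12
participants x (288 cued + 96 non-cued) trials on 16 channels at 64 Hz,
with 4 dB mean suppression and 4 dB per-trial spread so that single-trial
lateralization genuinely varies between reversed and strong and every
consistency x strength cell stays above the fitting minimum. The
positive-control coupling is 0.5 — chosen a priori so that the per-group
concentration multipliers (about 0.6 to 1.2 across the four groups) are
well inside what the grouped fits can resolve. The detection bar for this
control is statistical power, so the study dimensions, not the effect, are
what the reduced scale trades away; the type-I calibration is read per
parameter (precision), matching the linkage contract's own calibration
band.

## Known limitations

* Epochs and TF power live in memory as R arrays; at the full study scale
  (39 x 864 trials x 64 channels x 512 Hz) a single participant's 30-band
  TFR is several gigabytes, so paper-scale runs should restrict the
  frequency grid (`tfr_freqs`) or process participants one at a time, as
  `run_pipeline()` does.
* On-disk interchange is plain text (trial tables as CSV, montages as TSV,
  results as CSV/JSON); there is no binary epoch container, and import of
  vendor EEG formats is out of scope — `epoch_array()` accepts any
  trials x channels x time array prepared by other tools.
* The classifier's default template includes the classified trial; its
  accuracy is therefore optimistic as a point estimate (the permutation
  null accounts for this, and `leave_one_out = TRUE` avoids it at extra
  cost).
* The mixture model has exactly three parameters; swap-to-distractor
  components and hierarchical pooling across participants are deliberately
  not implemented.
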