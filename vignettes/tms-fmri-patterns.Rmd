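---
title: "Decoding TMS effects without activation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding TMS effects without activation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Concurrent TMS-fMRI asks what transcranial magnetic stimulation does to the
BOLD signal directly under the coil. The surprising answer this package
models is a dissociation: stimulation protocols that differ in intensity or
frequency produce **no reliable change in mean BOLD activity** at the
targeted site, yet the **multivoxel pattern** of activity reliably encodes
which protocol was delivered. `tmspattern` re-implements the full analysis
chain needed to demonstrate that dissociation — slice-locked stimulation
schedules, TMS slice-artifact cleanup, fiducial-based coil localization,
GLM/FIR estimation, and Gaussian naive Bayes (GNB) decoding — and couples it
to a synthetic 4-D BOLD generator whose ground truth embodies the phenomenon
exactly, so every stage can be validated end to end.

# Stimulation schedules

Two experimental designs are built in.

* **Experiment 1** (TR 1000 ms, 25 descending slices of 40 ms): three runs
  of ten 60-s blocks. Each block interleaves, in seed-randomized order, a
  low-intensity 1-Hz train (10 pulses at 50% motor threshold), a
  high-intensity 1-Hz train (10 pulses at 100%), and high-intensity bursts
  (five bursts of four pulses 80 ms apart, i.e. 12.5 Hz within burst, bursts
  2 s apart). Every trial lasts 10 s and is followed by a 10-s break; with a
  10-s lead-in and a 5-s trailing scan each run lasts 615 s and delivers 400
  pulses (1,200 per session). The 1-Hz pulses are timed into the 25th
  (deepest) slice; burst pulses land in slices 19, 21, 23, 25 of one volume,
  so the artifacts stay in slices that are discarded anyway.
* **Experiment 2** (TR 1240 ms, 31 slices of 40 ms, which tile the TR
  exactly): three runs of five blocks of four 30-pulse trials, one per
  frequency. Pulses are delivered every 1, 2, 3 or 5 slices, giving 25,
  12.5, 8.33 and 5 Hz; each train starts at slice 1 of its onset volume, so
  e.g. the 12.5-Hz train corrupts slices 1, 3, ..., 31 of one volume and 2,
  4, ..., 28 of the next, and **no slice is corrupted in two consecutive
  volumes** — the property the cleanup relies on. Trial onsets are 31 s (25
  volumes) apart; runs last 682 s (550 volumes); 1,800 pulses per session.
  The published run length fixes lead-in plus trailing rest at 50 volumes;
  we place 10 volumes of rest before the first trial and the remainder at
  the end.

# The synthetic-data generator

`synth_config()` fixes the study conditions; `make_anatomy()`,
`make_patterns()`, `simulate_run()` and `inject_artifacts()` realize them.

**Phantom.** An ellipsoidal brain in the acquisition grid (default 24 x 24 x
31 voxels of 3.0 x 3.0 x 3.5 mm), six bright capsules in a regular hexagon
on a coil plane 6 mm above the scalp, and a seventh capsule 10 mm above the
hexagon centre: the true entry line is the inward plane normal through that
apex capsule. Capsules are drawn with soft (partial-volume) edges so their
intensity-weighted centroids are recoverable to a fraction of a voxel.

**Patterns.** For condition $c$ with ordinal value $g(c)$ (default: centred
log frequency), the voxel pattern is

$$p_c = a\, e^{-d/\lambda}\,\bigl(w\,g(c)\,U + (1-w)\,V_c\bigr),$$

with $d$ the distance from the brain entry point, $U$ a shared unit-RMS map
and $V_c$ mutually orthogonal condition-unique maps. Two constructions make
the patterns decodable yet univariate-silent:

* the component maps are drawn spatially **correlated at the 6-mm analysis
  smoothing scale**, so the decodable structure survives preprocessing
  instead of being averaged away;
* each pattern is projected orthogonal to the **smoothed ROI-mean
  functionals** of the analysis spheres (radii 8, 12, 16, 20 mm on the entry
  line), so after the 6-mm smoothing every condition's mean over every
  analysis ROI is exactly zero, and each pattern has exact zero mean over
  the whole support. This is the generative statement of "decodable pattern,
  no activation": with 3-mm voxels and 6-mm smoothing no random pattern can
  be simultaneously decodable and mean-free at *arbitrary* scales, so the
  generator is mean-matched at the scales the univariate analysis actually
  examines.

**Defaults and why.** Baseline 1000 a.u.; noise SD 10 a.u. (temporal SNR
100, typical of 3-T EPI) with AR(1) coefficient 0.3, the standard minimal
BOLD noise model; pattern amplitude 10 a.u. (1% signal change) at the entry
point, fixed by a forward power calculation — after 6-mm smoothing the
patterns retain a per-voxel RMS near $0.08 a$ against a smoothed noise SD
near 2.8 a.u., an aggregate multivoxel separation $d' \approx 3$–4 in the
20-mm ROI, decodable from the 60 trials of one session; depth constant
$\lambda = 15$ mm, mimicking the rapid fall-off of the induced field, which
drives the upper-hemisphere enrichment of informative voxels; shared-axis
weight $w = 0.8$, the monotone-pattern account of the frequency effect —
patterns ordered along one axis by log frequency — which is what lets a
5-vs-25 Hz decoder generalize to 8.33-vs-12.5 Hz; artifact gain 2 on every
corrupted slice (the true amplitude is unconstrained; cleanup must not
depend on it); motion 0 by default (no realignment stage), with motion
files still emitted so framewise-displacement code paths run.

**Signal model.** `simulate_run()` renders signal as the condition pattern
times the canonical-HRF-convolved boxcar of each trial's full stimulation
window, on top of baseline and AR(1) noise, then `inject_artifacts()`
multiplies every targeted (volume, slice) plane by the artifact gain.

What the generator does **not** emulate: physiological noise, susceptibility
distortion, realistic anatomy, scanner drift, or session-to-session
variability. Passing tests show the pipeline recovers what this model hides
and finds what it plants; they do not certify performance on real data.

# Cleanup

`cleanup_run()` applies, in order: (1) targeted-slice interpolation — each
corrupted plane becomes the mean of the same slice in the neighbouring
volumes (exact first-order interpolation; run edges fall back to the single
neighbour; a slice targeted in consecutive volumes is refused); (2) 4-SD
outlier detection on each slice's time course of within-plane means,
computed excluding already-interpolated planes, with repair from the nearest
clean volumes (contiguous stretches bridge to the nearest clean pair);
(3) for Experiment 1, removal of slice 25 from all analyses; (4) 6-mm-FWHM
separable Gaussian smoothing with kernel renormalization over the valid
support, so dropped planes neither leak in nor drag means down. Framewise
displacement uses the Power convention (sum of absolute translation
differences plus 50 mm times the rotation differences).

# Coil geometry

All geometry is in world millimetres via the image affine (voxels are
anisotropic). Capsules are detected by thresholding at the head's 99.9th
intensity percentile, labelling 3-D connected components outside the brain
mask, and taking intensity-weighted centroids; exactly seven must survive.
The hexagon plane is found by total-least-squares plane fits to all seven
leave-one-out subsets: the subset with minimal RMS residual is the base, the
left-out point the apex, with an ambiguity error when two subsets fit
comparably (all-coplanar capsules). The entry line runs through the apex
along the base-plane normal, toward the brain; the stimulation spot is the
first brain-mask voxel centre met marching from the apex at 0.1-voxel steps;
ROIs are the shallowest spheres on the line that fit entirely inside the
brain (0.5-mm search steps), split into upper (coil-side) and lower halves
by the plane through the centre orthogonal to the line, ties assigned
upward. Coil displacement between two scans is the Euclidean distance
between their stimulation spots.

# GLM and FIR

The canonical HRF is the standard double-gamma (peak delay 6 s, undershoot
delay 16 s, unit dispersions, undershoot ratio 6, peak normalized to 1).
Designs model each trial's **whole stimulation window** (never individual
pulses) convolved with the HRF, plus six motion regressors and a constant —
10 columns per Experiment-1 run, 11 per Experiment-2 run; trial mode gives
one regressor per trial; FIR mode one indicator per post-onset TR bin per
condition (default window 24 s). Runs are fitted jointly as a
block-diagonal (session-wise) design. Estimation is per-voxel OLS via QR.

ROI inference fits the ROI-mean time series directly and uses **AR(1)
prewhitening** (iterated Cochrane–Orcutt within run blocks, coefficient
estimated from residual lag-1 autocorrelation): with AR(1) noise, naive OLS
t statistics are inflated by roughly $\sqrt{(1+\rho)/(1-\rho)} \approx 1.36$
at $\rho = 0.3$, and the whitened tests are calibrated — the package's null
simulations show a 5.9% rejection rate at nominal 5% over 400 sessions.
Uncorrected OLS is available with `whiten = FALSE`.

A note on multiplicity: one session yields 24 correlated ROI contrasts (6
condition pairs x 4 radii). Any calibrated 5%-level test will reject a few
of them by chance — in the original study about 4–5% of per-subject
comparisons were significant, a rate the authors note matches chance. The
package therefore states the univariate null as a *global* null: no
comparison survives Holm correction across the family, with the raw
significance rate reported alongside. A single unlucky session can show a
raw rate well above 5% (one 2.5-sigma condition-beta fluke propagates
through all nested ROIs) while the global null still holds.

FIR time courses are reported as percent signal change against the run
constant, with the OLS standard error of each bin (a condition-wise FIR has
one beta per bin, so there is no across-trial dispersion to report).

# Decoding

Features are trial-wise betas over ROI voxels. By default they are
**noise-normalised** — divided by each trial regressor's design standard
error factor $\sqrt{(X'X)^{-1}_{jj}}$, the t-map convention: conditions
differ up to fivefold in stimulation duration, hence in trial-beta
estimation variance, and without normalisation a prototype classifier
decodes that nuisance (prototypes of long-duration conditions are estimated
more tightly), lifting even a signal-free pipeline above chance once
smoothing has reduced the data to a few hundred effective dimensions. With
normalisation the signal-free pipeline sits at an exactly calibrated 25%.

The classifier is Gaussian naive Bayes with maximum-likelihood means and
variances (denominator $n$), a variance floor of $10^{-9}$ times the largest
feature variance, uniform priors, and — by default — variances **pooled
across classes** within voxel, which keeps the classifier a mean-pattern
decoder rather than a variance detector; fully class-specific Gaussians are
available with `pooled_variance = FALSE`. Exact posterior ties break to the
first class label and are flagged. Cross-validation is leave-one-run-out
(three folds); chance is tested per trial with one-sample t and exact
binomial tests, and empirically by within-run label permutation with full
re-CV.

Cross-pair generalization trains on two frequencies and tests on the other
two, mapped by frequency order (lower to lower). This analysis uses **raw**
betas: it probes whether conditions share a common pattern axis with
ordered coefficients, and per-trial noise normalisation rescales exactly
that common scale. Voxel selection uses Gini information gain with a median
split (equal-frequency k-bin optional), selecting voxels above the mean
gain (or a top-N); upper-hemisphere enrichment is tested with exact
binomial tests against 0.5 and against the upper half's share of ROI voxels
(the fairer null when the halves are unequal).

Statistical inference on accuracies deliberately replaces the original
mixed-effects models with per-trial/per-session one-sample and binomial
tests: the mixed models are inference machinery, not the phenomenon, and a
single synthetic session has no subject-level random effects to model.

# Problem sizes and numerical choices

The test-suite sessions use the default 24 x 24 x 31 grid (one full
Experiment-2 session simulates, cleans and decodes in well under a minute);
null-calibration sweeps use 400 sessions on a 6 x 6 x 6 grid, which
preserves the temporal structure the calibration tests; mechanism tests for
generalization run at trial-beta level with spatially white maps, averaging
12 seeded sessions because a single orthogonal-pattern session is
intrinsically bimodal (the unique test patterns project onto an arbitrary
side of the trained boundary). Tie-breaks, variance floors, degenerate
inputs (constant series, coplanar capsules, empty selections, zero-length
windows) all have defined, tested behaviour. Seeds propagate explicitly:
every stochastic function takes or derives from a single integer seed, and
regenerating any dataset with the same seed reproduces it exactly.

# Limitations

The generator's mean-matching is exact at the analysis ROIs, approximate
elsewhere; real brains need no such constraint but also offer no ground
truth. The gray-matter proxy in synthetic data is the brain mask (no tissue
segmentation). Slice-time correction, realignment, coregistration and
spatial normalization are out of scope — the synthetic data are generated
aligned. Voxel-wise (map-level) GLM statistics are reported without
autocorrelation correction or multiple-comparison control; calibrated
inference is ROI-level by design.
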