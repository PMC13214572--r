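---
title: "Validating reading localizers with simulated BOLD data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating reading localizers with simulated BOLD data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Functional "localizer" tasks identify a functional network — here, the
fronto-temporal language-selective network — in each individual brain by
contrasting two conditions (reading sentences versus reading pronounceable
nonword sequences). A faster variant of the task, in which each word is
flashed for 200 ms instead of 450 ms, halves scan time; the scientific
question is whether the speeded variant localizes the *same* voxels with
the *same or better* contrast. Answering that requires a pipeline that (i)
reproduces the exact block/trial timing of both task versions, (ii) fits
subject- and run-level GLMs, (iii) defines subject-specific functional
regions of interest (fROIs) inside group-level parcels, (iv) extracts
cross-validated condition responses, and (v) compares versions via
spatial-topography similarity and mixed-effects models.

`froikit` implements that pipeline end to end and pairs it with a
synthetic BOLD generator with known ground truth, so every stage can be
validated quantitatively: effect recovery, type-I calibration, selection
(circularity) bias, and the directional behaviour of the full analysis.

## Paradigm timing

All timing is built from primitive event durations, never hard-coded at
the run level:

* a reading trial is 100 ms blank + 12 words at the version's rate +
  400 ms button cue + 100 ms blank — 6 s (standard, 450 ms/word) or 3 s
  (speeded, 200 ms/word);
* blocks contain 3 trials (18 s / 9 s); a run has 16 experimental blocks
  (8 per condition, counterbalanced) and 5 fixation blocks of 14 s —
  358 s and 214 s in total;
* the spatial working-memory (WM) task used to define Multiple Demand
  (MD) fROIs has 8 s trials, 32 s blocks of 4 trials, and 12 experimental
  + 4 fixation blocks of 16 s — 448 s.

Two layout details are underdetermined by the published design and are
fixed here as package conventions: fixation blocks sit at run start and
end with the remainder spaced as evenly as possible between equal groups
of experimental blocks (symmetric, conventional for blocked localizers),
and "counterbalanced across runs" is operationalized as *run 2 = reverse
of run 1* with run 1 a seeded balanced pseudo-random order, which cancels
linear time-in-run confounds. WM trials are modelled as single 8 s events
because the GLM models conditions at block granularity; sub-trial
dynamics would be invisible to it. Stimulus texts are opaque pseudo-token
strings (5 sets × 48 sentences + 48 nonword strings, 12 tokens each):
only timing, condition labels and item bookkeeping (a single set per
subject, no item repeated across a subject's runs of a version) enter the
analysis, so no linguistic content is modelled.

## The synthetic subject

`makeSubjectTruth()` plants, inside each spherical parcel of a synthetic
atlas, a smooth Gaussian-blob weight field whose top fraction (default
20%) of voxels is "selective". The blob layout is fixed per parcel;
each subject displaces it by a random offset (SD 4 mm per axis),
emulating the inter-individual variability in the precise location of
functional areas that motivates subject-specific fROIs in the first
place. A smaller per-version displacement (SD 1.5 mm) makes the
selective topography differ slightly between localizer versions, so
within-version reliability exceeds between-version similarity — the
qualitative structure the real comparison exhibits, where both
correlations are high but within > between.

Selective voxels carry condition amplitudes in percent signal change.
The defaults encode the qualitative result pattern of the
standard/speeded comparison: sentences > nonwords in both versions
(standard 2.0 vs 0.5), with a larger sentences response (2.3) and a
smaller nonwords response (0.1) under speeded presentation, i.e. a
contrast difference of ~0.7 between versions; MD parcels respond hard >
easy (2.0 vs 1.0) in the WM task and weakly, with the opposite
preference, to the reading conditions. These are fixed study conditions,
chosen once for realism, not tuning knobs.

`simulateBold()` generates
`baseline × (1 + Σ_c amp_c/100 · x_c(t) + drift(t) + σ/100 · e(t))`,
where `x_c` is the condition boxcar convolved with the canonical HRF —
the *same* regressor construction the GLM uses, which is what makes
injected amplitudes and extracted responses commensurable — `drift` is a
0.5% cosine with a 200 s period and a per-run random phase (long enough
that the 128 s high-pass basis attenuates it only partially, so the
drift regressors are actually exercised; the random phase reflects that
scanner drift is not aligned across acquisitions, and keeps its
unremoved residue from biasing every run's effect maps identically),
and `e` is AR(1) noise with unit marginal variance
(stationary initialization), σ = 1% and lag-1 coefficient 0.2, matching
the analysis whitening model. Noise is spatially independent by default,
which keeps null distributions analytically checkable; spatial structure
enters through the 4 mm smoothing step of the analysis itself. The
simulator produces only post-steady-state scans: the conventional
discard of the first seconds of acquisition is modelled as never
generating those volumes, and the schedule clock starts at zero.

What the generator does *not* emulate: head motion, physiological noise,
EPI distortion, T1 saturation, spatially varying baselines and
autocorrelation, and real anatomical parcel shapes. Passing tests
therefore certify the analysis machinery — not that real data would meet
any particular reliability number.

## First-level GLM

* **HRF**: double-gamma, peak delay 6 s, undershoot delay 16 s, unit
  dispersions, peak:undershoot ratio 6, 32 s kernel, peak-normalized —
  the de facto canonical parameterization.
* **Regressors**: condition boxcars at 0.1 s resolution convolved with
  the HRF and area-normalized so a sustained block plateaus near height
  1; sampled at scan onsets (TR = 2 s). Fixation is modelled implicitly.
  Optional temporal derivatives (centered differences, orthogonalized
  against their parent so condition betas keep their interpretation).
* **Drift**: a discrete-cosine basis containing every function with
  period above the 128 s cutoff — `floor(2·N·TR/cutoff)` columns — plus
  a constant. User-supplied nuisance regressors (motion, outlier scans)
  are appended untouched.
* **Whitening**: fixed-coefficient AR(1) prewhitening at ρ = 0.2 (first
  row scaled by √(1−ρ²)), then ordinary least squares. The fuller
  ReML-based scheme this approximates fixes the same coefficient, so the
  extra machinery would not change the estimand materially; the
  whitened fit is verified against a dense GLS oracle in the tests.
* **Scaling**: each voxel's series is divided by its temporal mean and
  multiplied by 100 before fitting, so betas read as percent signal
  change. One consequence worth knowing: because the temporal mean
  includes task signal, recovered amplitudes shrink by roughly the mean
  task-induced signal fraction (~1% at the default amplitudes) — well
  inside the 5% recovery tolerance the package tests.
* **Smoothing**: separable Gaussian, FWHM 4 mm, kernel truncated at 3σ
  and renormalized (constants pass through unchanged at edges). The
  compiled implementation is cross-checked against a dense-matrix
  reference.

Degenerate designs (collinear columns) are rejected with the offending
column names; a t-statistic is reported wherever the residual variance
is positive.

## fROIs and cross-validated responses

Within each parcel, the top `max(1, floor(fraction · n))` voxels by
t-value of the defining contrast form the fROI (fraction 0.10 by
default). Floor rounding with a floor of one voxel is the package's
convention — the printed "top 10%" does not specify rounding — and ties
break by ascending linear voxel index for cross-platform determinism.
Right-hemisphere homologues come from reflecting parcels across the
mid-sagittal plane in world coordinates.

Responses are extracted cross-validated: one run defines the fROI, the
held-out run of the same version provides the per-condition effect
values (unweighted mean over fROI voxels), and the two folds are
averaged. The circular variant (define and read out on the same run) is
deliberately retained behind a flag because the test suite demonstrates
its selection bias on null data — the pedagogical core of why
cross-validation is required.

One ordering choice: fROIs are defined on t-maps computed from smoothed
data, i.e. smoothing precedes the GLM as in the standard preprocessing
order; defining on unsmoothed maps is available by setting the FWHM to
zero.

## Topography similarity and group statistics

Spatial similarity restricted to the language parcels uses Pearson
correlations of contrast **effect** maps (t-maps conflate effect size
with variance; a `what = "t"` switch exists), Fisher-transformed with
clipping at |r| = 1−10⁻⁷ to keep degenerate simulations finite.
Within-version values correlate a version's two runs; between-version
values average the four pairwise run combinations. Dice overlap of
fROIs is computed per fraction (0.1/0.2/0.3 by default) with the same
within/between structure. Aggregates are exact means over parcels.

Group models are Gaussian LMMs with crossed random intercepts for
participant and fROI, fit via `lme4`/`lmerTest`: REML with Satterthwaite
degrees of freedom for reported coefficients, ML for likelihood-ratio
tests of fixed effects (the condition × version interaction), which are
invalid under REML. Singular fits are flagged, not failed. R² follows
the Nakagawa–Schielzeth decomposition. Paired and one-sample t-tests are
classical; an all-zero difference vector returns t = 0, p = 1, while a
constant nonzero difference is a degenerate input and errors.

## Problem sizes and numerical checks

The reference experiment is 24 subjects × 2 versions × 2 runs on a
24×24×24 voxel grid at 2 mm with nine spherical parcels (five
"language", four "MD"). The experiment runner restricts computation to
the bounding box of the parcels plus the smoothing-kernel half-width;
every analysed voxel keeps its complete smoothing neighbourhood, so this
is a pure problem-size reduction with no effect on any analysed value.
The test suite validates, at these conditions: GLS-oracle equivalence
(20 toy problems, <10⁻⁸), type-I calibration on 500 null voxels
(rejection in [0.03, 0.07] at α = 0.05), fROI selection against brute
force for parcel sizes 1–1000, unbiasedness of cross-validated null
responses versus the positive bias of circular extraction (200 simulated
subjects), 5%-accurate recovery of injected contrasts (100 run pairs),
LMM recovery and LRT null calibration (100 and 500 replicates), and the
full-pipeline directional pattern over 50 seeded replicates.

All randomness flows from a single experiment seed through named
substreams (`subSeed(seed, "noise", subject, version, run)` etc.), so
identical seeds give byte-identical report tables and changing one
stage's stream leaves the others untouched.

## Limitations

Volumetric only (no surface analyses); no motion/physiology simulation;
fixed-coefficient whitening rather than ReML; no random slopes in the
group models; parcels are synthetic spheres, not the group-derived
anatomical parcels used with real data (those are distributed at
https://evlab.mit.edu/funcloc/ and can be supplied as NIfTI label
volumes through the same `ParcelAtlas` interface).
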