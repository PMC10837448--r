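---
title: "Depth-resolved decoding of V1 laminar fMRI: models and methods"
author: "laminardecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved decoding of V1 laminar fMRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laminardecode)
```

# What this package computes

Sub-millimetre (laminar) fMRI can resolve BOLD signals at different
cortical depths. In primary visual cortex this matters because feedforward
input from the eyes terminates in the middle layers, while feedback from
higher areas arrives predominantly in superficial and deep layers. A
depth-resolved multivariate analysis can therefore ask not just *whether*
stimulus content is represented in V1, but *through which laminar route*
it arrives: externally driven content should be decodable at different
depths than internally generated content such as mental imagery or
illusory percepts.

`laminardecode` implements the complete analysis chain for this question:

1. **Retinotopy** — Fourier phase mapping of rotating-wedge and
   expanding-ring runs, and population receptive field (pRF) estimation by
   exhaustive grid search over isotropic Gaussian models.
2. **ROI definition** — voxels whose fitted pRF (taken with a spread of
   one standard deviation) falls entirely within a target region of the
   visual field, thresholded on fit quality r².
3. **Laminar sampling** — assignment of voxels to six equidistant,
   partially overlapping cortical-depth bins.
4. **First-level GLM** — two-gamma HRF regressors, trial-wise beta
   estimation by OLS, removal of low-intensity voxels.
5. **Decoding** — per-depth linear C-SVM (C = 1) with leave-one-run-out
   cross-validation, condition-pair decoding and cross-classification.
6. **Inference** — one-sided bootstrap of the across-subject mean against
   chance with BH-FDR correction, and a second-level linear mixed model
   parameterised across continuous cortical depth.
7. **Back-projection** — translation of classifier voxel weights into a
   visual-field image by pRF-weighted averaging.

Because real laminar 7T data are large and access-controlled, the package
ships a seeded synthetic-subject generator that emulates the target study
design with known ground truth; every stage above is tested against it.

# The synthetic subject generator

`simulateSubject()` produces one subject under `subjectConfig()`:

* **Task design** — 6 runs of 272 volumes at TR = 2 s; five conditions
  (perception, imagery, illusory, amodal, mock) in 8-s blocks with ISIs
  drawn uniformly from 7–8 s (rounded to 0.5 s, the design-matrix
  resolution); each condition appears 6 times per run, 3 red and 3 green,
  in seeded random order. The jitter distribution and the unconstrained
  block randomisation are free choices — only the range and the balance
  are fixed by the emulated design.
* **Retinotopy** — a 22.5° wedge rotating anti-clockwise in 12 cycles of
  64 s (396 volumes) and a ring expanding over 8 cycles of 64 s
  (268 volumes), both with 12-s baselines, rasterised on a fixation-centred
  pixel grid.
* **Voxels** — organised in cortical columns of six depths. The six
  voxels of a column share one pRF centre and size (the hypercolumn
  assumption: deeper neurons represent the same visual portion as the ones
  stacked above them) but receive independent noise. Depths sit at the six
  canonical bin centres plus uniform jitter (±0.08), so neighbouring depth
  bins genuinely share voxels. pRF centres are uniform over a 5° disc,
  sizes log-uniform in 0.5–2°.
* **Signal model** — each voxel's task time course is
  `baseline × gain × (1 + Σ_blocks (visualDrive + w) · boxcar)` convolved
  with the two-gamma HRF, plus Gaussian noise. `w` is the colour pattern:
  per condition, a seeded standard-normal voxel pattern scaled by the
  condition's effect size, entering with `+w` for red and `−w` for green
  — colour is therefore a *pattern* code with no mean-amplitude
  difference, mirroring what a linear classifier exploits. Pattern
  weights are nonzero only for voxels inside the condition's target depth
  band. `visualDrive` is a condition-unspecific response shared by every
  block: all visually responsive voxels respond to stimulation, which is
  what makes amplitude-versus-depth profiles meaningful at all (with only
  antisymmetric patterns the mean response would be identically zero).
* **Depth convention** — depth 0 is the white-matter boundary and 1 the
  pial surface; "deep" means low values. Default injection bands encode
  the laminar dissociation the generator emulates: imagery content lives
  in the deep band [0, 0.3], illusory (and amodal) content in the
  superficial band [0.7, 1]; perception and mock carry full-depth
  patterns.
* **Superficial bias** — the amplitude gain `1 + gainSlope × depth`
  increases toward the pial surface, emulating the draining-vein
  amplification of gradient-echo BOLD. The gain multiplies the noise as
  well as the signal: vascular amplification scales fluctuations together
  with the response, so contrast-to-noise is flat across depth and
  amplitude by itself carries no decodable information. This is the
  mechanism behind the amplitude/decodability dissociation the tests
  verify — a steeper gain changes the amplitude profile while leaving
  per-depth accuracies untouched.

Default intensity scales: baseline 500 raw units with noise sd 40
(temporal SNR 12.5, typical for 0.8-mm gradient-echo 7T), colour effect
sizes around 0.002–0.003 of baseline. These were chosen so that in-band
leave-one-run-out accuracies land in the 0.6–0.8 range reported for real
laminar decoding, with off-band bins at chance.

What the generator deliberately omits: temporal autocorrelation and
low-frequency drift (real pipelines high-pass filter; beyond this
package's scope), motion, distortion, physiological noise structure, and
any spatial point-spread. Passing tests therefore demonstrate the
*analysis logic* — calibration, specificity, invariances — not robustness
to every artefact of real acquisitions.

# Numerical and statistical choices

**Two-gamma HRF.** Unit-rate gamma densities with shapes chosen so the
density modes sit exactly at the stated peak times (5 s response,
15 s undershoot); each lobe is peak-normalised before the undershoot is
scaled by the positive-to-negative ratio (6) and subtracted, and the
kernel is renormalised to peak 1. With this parameterisation the sampled
argmax is exactly 5 s and the undershoot magnitude is within a few
percent of 1/6 (the lobes overlap slightly).

**Trial betas.** All 30 blocks of a run are modelled in one GLM
(least-squares-all), one HRF-convolved boxcar column per block plus an
intercept; OLS per voxel. Rank-deficient designs are rejected with the
collinear columns named. Voxels with raw mean intensity below 100 are
removed first; the boundary (exactly 100) is retained.

**pRF fitting.** 24 log-spaced sizes from 0.2° to 4.8° (configurable);
for each size, candidate centres one standard deviation apart, restricted
to the stimulated disc. The score is the squared Pearson correlation
between the HRF-convolved prediction and the measured time course,
concatenated across the wedge and ring runs in a single combined fit —
amplitude and offset are implicitly free, and the fit is invariant to
affine rescaling of the data. Ties resolve to the smallest size, then the
lexicographically smallest centre (candidates are stored in that order,
so the first maximum wins). All-constant voxels return an `r2 = 0`
sentinel rather than an error. Note a resolution constraint: sizes below
the stimulus pixel spacing cannot be reliably distinguished at realistic
noise; the default subject generator draws sizes from 0.5° upward, and
the pixel grid should be chosen with spacing below the smallest size of
interest.

**Fourier phase maps.** Baseline volumes are excluded from the analysis
window (which must then hold an integer number of stimulation cycles) and
the reported phase is referenced back to run start. The F-ratio is the
squared amplitude at the stimulation frequency over the mean squared
amplitude at all other nonzero frequencies below Nyquist; under white
noise it is centred on 1.

**ROI containment.** The closed 1σ disc around the fitted centre must lie
inside the region, boundary-inclusive; regions are discs, semicircles
(disc ∩ half-plane) or unions (containment within a single component —
conservative when components overlap). The study's manual surface-patch
step is replaced by a deterministic stacked-column completion: every
depth-mate of a passing voxel joins the ROI, flagged, so superficial fit
bias does not thin out the deep bins. `checkDepthVoxelBalance()` is the
QC gate that verifies the result carries no depth trend in voxel counts.

**Rescaling and cross-validation.** Betas are rescaled to [−1, 1] per
voxel across trials; the scaling parameters are fitted on the training
folds only and applied unchanged to the held-out fold, so test values may
fall slightly outside [−1, 1] (no clipping). Train-only fitting is the
leakage-safe reading of an operation whose original scope is ambiguous.
Cross-classification between conditions trains on all runs of one
condition and tests on all runs of the other — the sets are disjoint by
construction, so no fold structure is imposed.

**SVM.** C-classification, linear kernel, C = 1, termination tolerance
0.001, equal class costs, via the libsvm family (`e1071`). Primal weights
are recovered from the support vectors with the sign convention that
positive weights favour the first-named class; the test suite anchors the
solution to an independent quadratic-programming oracle on small
instances.

**Bootstrap.** One-sided p with the add-one correction,
`(1 + #{means ≤ chance}) / (nBoot + 1)`, which avoids p = 0 at 10,000
resamples; 90% CIs (5th/95th percentiles) match the one-sided α = 0.05
test. FDR correction is Benjamini–Hochberg over the full comparison
family supplied (e.g. 30 cells for five conditions × six bins in one
ROI; correction is applied within an experiment's family).

**Second-level LMM.** Accuracy is modelled on *continuous* depth (the
number of bins is an arbitrary sampling choice), condition and experiment
as centred ±0.5 contrasts, all interactions as fixed effects, and
per-subject random intercept, depth slope and condition×depth slope;
REML with the nlminb optimiser (`nlme`). Degrees of freedom follow nlme's
within-group convention and are reported alongside the estimates. If the
full random structure fails to converge the model is refit with random
intercept + depth and flagged `degenerate` — reported, never hidden.
With one experiment level, experiment terms are dropped automatically.

**Back-projection.** `y_i = Σ_j w_ij x_j / Σ_j w_ij` with unnormalised
Gaussian pRFs truncated strictly beyond 2σ (boundary-inclusive at exactly
2σ, Euclidean distance in degrees); pixels with zero summed weight are
defined as 0 rather than letting tiny denominators inflate the ratio.
Gaussian peak normalisation cancels in the ratio except through the
truncation, which is why unnormalised kernels are used. Fold-averaged
weights are projected.

**Behavioural pre-test.** Imagery strength is
`nPrimed / (n − nMock − nMixed)`; catch (mock) and mixed trials never
count as primed and never enter the denominator, so adding either leaves
the score unchanged. Selection is at-or-above 60%. Catch-trial failure is
reported as a decision-bias indicator, with no exclusion cut-off applied.

# Problem sizes used in the shipped checks

The test-suite and acceptance-script simulations use 16 subjects of 144
voxels (24 columns × 6 depths) with 6 runs for calibration and
specificity checks, 500 voxels for pRF recovery, 500 simulated datasets
at 26 subjects × 2 conditions × 6 depths for LMM coverage, and 100 paired
seeds for the amplitude/decoding dissociation — sizes at which the Monte
Carlo error of each check is comfortably below its assertion band.

# Known limitations

* The generator's noise is white; analyses of real runs should high-pass
  filter and may need prewhitening (out of scope here, as are motion,
  distortion and surface reconstruction).
* Containment for union regions is per-component, slightly conservative
  for discs straddling two overlapping components.
* The exhaustive pRF grid has no nonlinear refinement stage, so estimated
  centres and sizes are quantised to the grid.
* `fitDepthLmm()` supports the two-condition, up-to-two-experiment design
  it was built for; it is not a general mixed-model interface.

# A minimal end-to-end run

```{r, eval = FALSE}
cfg <- subjectConfig()
folds <- do.call(rbind, lapply(1:8, function(i)
  cbind(subject = i,
        decodeSubject(simulateSubject(cfg, seed = i),
                      conditions = c("imagery", "illusory")))))
acc <- summariseFolds(folds)
inf <- groupDepthInference(acc, nBoot = 10000, seed = 1)
inf[inf$significant, c("condition", "depth", "meanAccuracy", "pAdj")]
```

Under the defaults this reproduces the emulated dissociation: imagery
decodable only in the deep bins, illusory content only in the superficial
bins, with the amplitude profile nonetheless rising monotonically toward
the pial surface.
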