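---
title: "Methods: group-ICA dual-regression connectivity for two-condition resting-state designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group-ICA dual-regression connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis problem

`dmnconn` implements a complete analysis chain for pharmacological
resting-state fMRI studies with a within-subject, two-condition (drug vs.
placebo), two-segment (early and late resting state) design. The scientific
question is whether a drug changes the intrinsic functional connectivity of
the default-mode network (DMN), both at the map level (voxelwise network
membership) and at the regional level (pairwise correlations between
network nodes), and whether regional connectivity covaries with a
behavioural self-report such as visual-analogue alertness (0–100).

Because pharmacological resting-state datasets of this design are rarely
deposited, the package pairs the analysis chain with a synthetic-data
generator that plants known spatial modes, known condition- and
segment-specific node correlations, structured nuisance signals, and a
behaviour–connectivity link. Every downstream stage can therefore be tested
against ground truth.

# Pipeline stages and their models

## Preprocessing

Each run is processed in a fixed order: leading saturation volumes are
discarded; per-voxel linear trends are removed by least squares;
a high-pass filter projects out the mean and the first $n$ discrete Fourier
pairs of every voxel course ($n = 5$ cycles by default, a cutoff of
$n/(T \cdot \mathrm{TR})$ Hz, about 0.0019 Hz for a discarded 1,314-volume
run at TR = 2 s); volumes are smoothed with an isotropic Gaussian kernel
(FWHM 6 mm). The cycle-projection form of the high-pass is exact and
parameter-free, which is why it is preferred here over an IIR design.

Smoothing treats out-of-mask data as zero and then renormalizes by the
identically smoothed mask indicator. Without that correction a spatially
constant signal (e.g. a global physiological oscillation) acquires an
"interiorness" spatial profile from edge attenuation, which leaks global
variance into the spatial-regression step downstream; with the correction,
constants stay constant inside the mask and interior voxels are essentially
unchanged. Kernel mass is conserved for interior sources.

Segment windows are expressed in original volume indices and compose with
the initial discard by pure index arithmetic; each extracted segment
carries its original indices, so provenance round-trips. In the default
full-run layout (1,316 volumes) the first resting window is volumes 1–210
with the last four trimmed (204 analyzed timepoints) and the second is
volumes 1107–1316 with the first four trimmed. Strict arithmetic leaves 206
volumes in the second segment; the default layout additionally trims the
final two volumes — mirroring the initial saturation discard — so both
segments carry exactly 204 timepoints. A layout with any other convention
can be constructed explicitly with `run_layout()`.

The group mask is a quantile threshold (default 0.5) on the mean anatomy:
a deliberately simple stand-in for tissue tagging whose coverage is
reported and controllable.

## Group spatial ICA

Within each condition, the per-voxel z-normalized first-segment time series
of all subjects are concatenated in time (10 subjects x 204 volumes =
2,040 rows in the reference design). The temporal Gram matrix gives the
top-$k$ principal subspace cheaply; the whitened scores are decomposed by
symmetric (parallel) FastICA into $k$ spatial sources, using the classical
cubic (kurtosis) contrast by default (`tanh` available), tolerance $10^{-4}$
on the rotation update, at most 1,000 fixed-point iterations, and up to
five seeded restarts before failing. Component signs are fixed to positive
skewness; each map is z-scored across voxels. The DMN component is the mode
with the highest absolute spatial correlation against a posterior-cingulate
template (a Gaussian centred at (-1, -47, 24) mm), re-oriented so the
template correlation is positive.

Two identifiability caveats matter for synthetic data and are worth
stating plainly. First, near-Gaussian sources (pure noise dimensions) have
no well-defined ICA solution; with a large model order relative to the true
spatial rank, the fixed-point iteration can fail to converge, which the
package reports as an error after its restarts. Second, model order
controls network splitting: spatially disjoint synthetic nodes are
themselves independent spatial sources, so a high model order resolves each
node as its own component, while a low model order (below the node count)
keeps a temporally coherent network in a single union-like component. Both
behaviours are well documented for ICA of real fMRI, where higher orders
split the DMN into subsystems. The demonstration and validation runs in
this package therefore use model order 10 on the seven-node synthetic
cohort — the regime in which the template-matched component spans the
coherent network — while the configuration default remains 40, the
conventional order for real whole-brain data.

## Dual regression

Stage one regresses, at every timepoint, the volume jointly on all $k$
z-scored group maps plus an intercept, giving subject-specific component
time courses. Stage two regresses every voxel course jointly on all $k$
time courses plus an intercept, giving subject-level beta maps. Joint
estimation is the standard dual-regression contract: it prevents shared
variance from leaking into whichever single component is analyzed. Maps are
raw betas; inference is supplied by the group-level tests. Both stages fall
back to a pseudoinverse with a warning if the design is rank-deficient.
The group maps estimated from the first segment are applied to both the
first (in-sample) and second (held-out) segment.

## ROI definition

Subject DMN maps are averaged across the two conditions and two segments,
and a mass-univariate one-sample t-test (df $= n-1$) is computed per voxel.
The map is thresholded at FDR $q = 0.05$ (Benjamini–Hochberg step-up), and
surviving positively-loaded voxels are grouped into face-connected
(6-neighbour) clusters. The minimum cluster extent is calibrated by Monte
Carlo: white noise on the grid is smoothed to the map's estimated
smoothness, standardized in-mask, thresholded two-tailed at the FDR-derived
voxel p, and the largest cluster recorded per iteration (1,000 by default);
the threshold is the smallest extent reached by at most 5% of iterations.
Spatial smoothness is estimated from the variance of first differences
between face-adjacent in-mask voxels relative to map variance,
$\mathrm{FWHM} = 2v\sqrt{\ln 2 / (\mathrm{var}_\Delta/\mathrm{var})}$ per
axis ($v$ = voxel size), combined across axes by geometric mean. This
first-difference estimator converges to about $1.18 v$ on pure white noise
and carries a small positive bias (\~9% at FWHM twice the voxel size);
since the same convention generates the calibration noise, the bias largely
cancels in the cluster threshold. Clusters are labelled by the nearest
canonical node centre within 20 mm, else by coordinates.

## Regional connectivity and nuisance correction

ROI courses are unweighted voxel means of the preprocessed segments. Before
correlation, each course is residualized on an intercept, the time courses
of non-network components from the first dual-regression stage, the
motion-like confound series, and pairs of discrete sines and cosines at
every frequency $j/(T \cdot \mathrm{TR}) > 0.1$ Hz up to Nyquist (zero
columns dropped), built per segment. On synthetic cohorts where single
components can coincide with individual network nodes, components whose map
correlates with the selected network map at $|r| \ge 0.2$ or peaks inside a
defined ROI are excluded from the nuisance set — the analogue of labelling
components before declaring them artifacts; regressing a node's own course
out of the network would otherwise destroy the quantity being measured.

Residual courses are z-normalized and Pearson-correlated pairwise per
segment; correlations are Fisher-Z transformed with clipping at
$|r| = 1 - 10^{-7}$. Seven regions give 21 unique connections.

## Inference

Each connection's Fisher-Z values enter a 2x2 within-subject
repeated-measures ANOVA (factors: drug condition and segment). In a 2x2
design every within-subject F with df $(1, n-1)$ equals the squared paired
t of the corresponding contrast, and the implementation uses that identity
directly (the test suite verifies it against `aov()` error strata to
$10^{-8}$). Per factor, BH-FDR is applied across the 21 connections.
Drug-significant connections receive post-hoc two-tailed paired t-tests per
segment. The same 2x2 model runs voxelwise on the subject maps with the
FDR-plus-cluster-extent rule. All tests are two-tailed.

For brain–behaviour coupling, both the alertness ratings and a
connection's Fisher-Z values are averaged across conditions within subject
before Pearson correlation (df $= n-2$), so the correlation reflects
between-subject covariation rather than the drug contrast itself.

# The synthetic cohort

`simulate_cohort()` draws, per subject and condition, unit-variance node
time courses through the eigen-Cholesky factor of the planted correlation
matrix — imposed on the analyzed sub-window of each segment, uncorrelated
elsewhere — then low-pass filters them below 0.1 Hz within the segment
(resting-state network fluctuations are band-limited, which is precisely
why a > 0.1 Hz regressor bank can serve as a nuisance model; the shared
filter leaves the planted cross-correlations unchanged in expectation
while reducing the effective temporal degrees of freedom to roughly
$2 \cdot f_c T \cdot \mathrm{TR}$). The filtered courses are projected
through Gaussian spatial modes: seven canonical DMN nodes by default, FWHM
15 mm, with each subject's node centres displaced by an independent 2-mm-SD
Gaussian jitter shared across that subject's conditions — the residual
anatomical misregistration real group analyses carry after spatial
normalization. Structured noise comprises a
random-coefficient linear-plus-cosine drift (targeted by detrending and the
high-pass), a global sinusoid between 0.11 and 0.2 Hz with random phase
(targeted by the > 0.1 Hz regressor bank), six smooth motion-like series
coupled through a random spatial pattern (targeted by motion regressors),
and white noise. Defaults: white SD 1.5, drift 1, high-frequency 0.5,
motion 0.3 — relative to unit node-course SD at blob peaks. Sub-unity
voxelwise SNR is the realistic regime for 3-mm resting-state data; region
averaging restores most of the signal (a 20-voxel ROI mean has noise SD
about 0.34), and, importantly, a realistic noise floor keeps the group
t-map's detection boundary near the blob cores. With weaker noise, ten
subjects detect arbitrarily faint blob tails and the FDR-thresholded map
fuses all nodes into a single cluster, leaving the regional stage
undefined — an instructive failure of the idealized high-SNR setting, not
of the method.

The default planted connectivity assigns six drug-sensitive connections
(PCC-RIPC, PCC-RPHC, RIPC-RPHC, LIPC-RPHC, RPHC-ACC, RPHC-RMFG)
condition- and segment-specific correlations between 0.12 and 0.87, with a
common baseline of r = 0.5 elsewhere (identical across conditions; within
the range reported for intra-network coupling at rest); all four matrices
are verified positive semi-definite (minimum eigenvalue about 0.12). The condition effect lives purely in the correlation structure, not
in amplitudes, matching a connectivity-level drug effect. Alertness scores
are generated per subject and condition as
$\mathrm{mean}_c + s_a(\rho \hat z_i + \sqrt{1-\rho^2}\,\varepsilon_i)$,
with $\hat z_i$ the standardized subject-level realized Fisher-Z of a
designated link connection (PCC-RIPC by default), condition means 67.0
(drug) and 81.4 (placebo), link $\rho = 0.78$, and a between-subject SD of
7.5 VAS points — the within-subject rating variance is not constrained by
published data, so a single realistic value is used and condition
separation is carried entirely by the means.

What the generator does *not* emulate: haemodynamic convolution and
autocorrelated BOLD spectra, subject-specific anatomy and spatial
misregistration, rigid-body motion rendering (motion enters as confound
series, not image transformations), non-network brain sources, and scanner
drifts beyond the linear-plus-cosine form. Passing tests therefore
demonstrate the correctness and calibration of the estimators under the
stated generative model, not robustness to every property of scanner data.

# Numerical choices and edge cases

* Zero-variance voxel courses are zeroed with a warning before
  normalization; zero-variance ROI courses flag their pairs `NA`.
* Correlations are clipped at $|r| = 1 - 10^{-7}$ before `atanh`.
* Rank-deficient regressions use an SVD pseudoinverse and warn.
* The Monte-Carlo cluster simulation standardizes each noise field in-mask
  and clusters positive and negative survivors separately.
* All randomness is seeded: the cohort generator takes one integer seed;
  the pipeline derives per-stage seeds from its configuration seed;
  identical seeds give bit-identical outputs.
* Matrices are kept masked (time x voxel) throughout; full 3D grids are
  only materialized for smoothing, cluster analysis and NIfTI export.

# Validation design and problem sizes

The test suite checks each stage against independent oracles: closed-form
projections for detrending and filtering, overlap integrals for spatial
modes, `stats::p.adjust` and hand-worked step-up cases for FDR, `aov()`
error strata for the repeated-measures identity, Fisher sampling theory for
connectivity spread, and an adjacency/binomial approximation for the
cluster threshold under spatial independence. End-to-end recovery uses
`recovery_study()`: 50 replicate ten-subject cohorts on a compact
seven-node world (204 timepoints per segment) with a drug-only correlation
reduction of 0.4 planted on three of 21 connections; detection requires
sensitivity at least 0.8 at BH-controlled false positives, matched effect
signs, and null-distributed segment and interaction factors. The
demonstration pipeline run uses ten subjects on the full seven-node
default-mode geometry with compact two-segment runs; these sizes were
chosen so each validation completes in minutes on a single core while
keeping every statistical contrast at its reference dimensionality
(n = 10, T = 204, 21 connections, df (1, 9)).

# Reading pipeline results on synthetic cohorts

Two systematic features of the demonstration runs deserve emphasis. First,
cluster topology is power-dependent: the strongly coupled
posterior-parietal trio (PCC, RIPC, LIPC) is painted most strongly into
the network component's subject maps, so its clusters tend to fuse into
one large posterior cluster (as low-model-order decompositions of real
data also show), while weakly coupled nodes surface as separate, smaller
clusters or occasionally fall below threshold; the ROI count therefore
varies around the planted node count rather than equalling it. Second, the planted
correlations are *marginal* node-course correlations, and marginal ROI
correlations respond collectively to a change in any strong pair: lowering
six strong connections under drug measurably shifts correlations among
other pairs too (in either direction), so the drug factor can flag more
connections — including non-planted ones — than the planted set. The
`recovery_study()` validation therefore scores detection in a design where
the planted contrast is the only difference between conditions, which is
the setting in which sensitivity and false-positive rate are well defined.

# Known limitations

* With weakly coupled nodes and a high model order, spatial ICA resolves
  nodes as separate components; the template-matched "network" component
  then contains a subset of nodes, and regional analysis degenerates. The
  low-model-order regime (or a coherent network) is required for the
  union-component behaviour.
* The Monte-Carlo calibration assumes stationary Gaussian smoothness; on
  strongly non-stationary maps the cluster threshold is only approximate.
* The behaviour link is planted on realized (sampling-varying)
  connectivity; with only 10 subjects the sampling error of a correlation
  against behaviour is large, so single-cohort behaviour correlations are
  reported descriptively rather than asserted by tests.
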