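---
title: "Methods: beta-series network analysis of cued memory reactivation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: beta-series network analysis of cued memory reactivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its science: the generative
model behind the synthetic data, the analysis model applied to it, the
numerical and design choices made where the field leaves them open, and
what the passing tests do and do not establish about real data.

## The experimental design being emulated

Subjects learn 50 object-location associations, each paired with a unique
sound, and are tested before and after a sleep period in the scanner.
During stable slow-wave sleep, 25 of the learned sounds are replayed
twice (50 cue trials) and 5 unfamiliar sounds five times (25 control
trials), in blocks of five 500 ms presentations separated by a 4–8 s
uniform-jittered inter-stimulus interval. The asymmetric 2:1 cue:control
ratio reflects the practical scarcity of usable slow-wave sleep time.

The published protocol does not state whether blocks mix conditions.
Because 5-presentation blocks with 50 + 25 trials divide exactly into
10 cue and 5 control blocks, `generate_protocol()` uses
condition-homogeneous blocks; block order and the assignment of sound
identities to block slots are randomized per seed. With the default
jitter the expected block duration is `5 x (0.5 + 6) = 32.5` s, matching
the design's nominal 32 s blocks.

## The synthetic BOLD model

`generate_bold()` plants a ground truth at the level of *trial
amplitudes*, which is exactly the quantity the beta-series analysis
estimates:

* Parcel amplitudes per trial are multivariate normal with unit variance
  and a modular correlation structure: `within_module_r = 0.5` inside a
  module, `between_module_r = 0.1` across modules (115 parcels, 5
  modules by default). These values give clearly assortative but not
  degenerate graphs after edge-wise FDR thresholding at the protocol's
  trial counts (50/25).
* In the cue condition only, the correlations between one designated
  "occipital" seed parcel and all parcels of other modules are raised by
  `seed_cross_boost` (default 0.25, per-subject values drawn from
  N(0.25, 0.1) truncated at 0 in the pipeline). If the boost breaks
  positive definiteness the matrix is projected back by eigenvalue
  clipping at `1e-6` and rescaled to unit diagonal; the *projected*
  matrix is the sampling oracle that tests compare against.
* Voxel amplitude = parcel amplitude + N(0, `voxel_amp_sd` = 0.2).
* The time series is the trial-regressor matrix times these amplitudes,
  plus three low-frequency cosine drifts (removed by the high-pass),
  linear contributions of six motion and three compartment nuisance
  series simulated as lightly smoothed random walks (exercising the
  nuisance-regression path), and AR(1) measurement noise with marginal
  SD `noise_sd = 1` and `ar1_rho = 0.3`.

Desk-scale acquisition defaults: a 12x12x12 voxel grid, TR = 2.511 s,
and the run sized to the generated events plus a 30 s tail (about 209
scans under the default protocol). The 115-parcel atlas is grown by
seeded multi-source breadth-first region growing on the 6-connected
lattice, so parcels are contiguous and non-empty by construction;
`default_parcellation()` fixes its seed so every analysis sees the same
atlas.

What the generator does *not* emulate: anatomy and spatial smoothness of
real BOLD (amplitudes are spatially white within parcels), hemodynamic
variability across regions, scanner drift nonstationarity, motion
artifacts coupled to the signal, sleep physiology (spindles, slow
oscillations, arousals), and any preprocessing residue — inputs are
analysis-ready by design. Passing tests therefore validate the
*estimators and inference machinery*, not robustness to real-world
artifacts.

## The beta-series GLM

One regressor per presentation: a boxcar of the event's duration
convolved with the canonical double-gamma HRF (response peak 6 s,
undershoot peak 16 s, unit dispersions, 1/6 undershoot ratio, 32 s
support, unit peak height), sampled at scan times from a 16x oversampled
grid. The 5 s model duration (for a 500 ms sound) absorbs uncertainty
about when and for how long a cue-induced reactivation unfolds. No
temporal derivatives are included in this trial-wise model.

The high-pass filter is the discrete-cosine basis with
`floor(2T/cutoff)` non-constant terms (cutoff 128 s). The basis enters
the design as columns (together with an explicit constant) rather than by
pre-residualising data and design: the two are the same least-squares
projection, and one code path keeps the design object self-describing.

All trials are estimated in a single GLM per voxel
("least-squares-all", the literal reading of one-regressor-per-trial);
the least-squares-separate variant is deliberately not implemented.
Prewhitening is a single Cochrane–Orcutt iteration: OLS fit, lag-1
residual autocorrelation estimate (clipped into (-1, 1)), AR(1)
transform of data and design, refit. Voxels are grouped by their
autocorrelation estimate rounded to 0.005 and refit per group; at that
granularity the induced coefficient perturbation is far below estimation
noise, and the grouped multi-right-hand-side QR is an order of magnitude
faster than per-voxel refits. Tests verify exact recovery without noise
and agreement of the empirical estimator variance with the closed-form
GLS covariance under AR(1) noise (1,000 replicates; the tolerance band
[0.8, 1.3] covers Monte-Carlo error plus the mild variance inflation
from estimating the autocorrelation).

## Graphs, modules, participation

Per condition, the node-by-node Pearson correlation matrix of beta
series (diagonal zeroed) is thresholded by Benjamini–Hochberg FDR at
q = 0.05 over all unique edges, using the t-transform of r with
`n_trials - 2` degrees of freedom; negative edges are removed
unconditionally. Cue (n = 50) and control (n = 25) matrices are
thresholded separately — the literal reading of per-condition
construction, accepting their unequal degrees of freedom.

Community structure is estimated *only* on the coarse 115-parcel graph:
weighted Louvain at resolution gamma = 1 with 100 random restarts, the
partition with the highest directly re-evaluated modularity Q kept, ties
broken towards the lexicographically smallest canonical labelling so
results are reproducible. Voxels inherit their parcel's module, and the
participation coefficient is computed on the voxel-level thresholded
graph as `PC_i = 1 - sum_s (kappa_is / k_i)^2`, with zero-strength nodes
set to 0 by convention. Although PC is informally described as ranging
"to 1", its attainable supremum is `1 - 1/M` for M modules; the package
asserts that bound on every output rather than treating 1 as reachable.
Values within `1e-12` of 0 are clamped to exactly 0 so provincial nodes
report a clean zero.

Dense voxel graphs are guarded by a configurable node budget (default
2,000), which the 12^3 grid (1,728 voxels) fits.

## Group inference

The "undirected" paired comparison of PC maps is implemented as a
two-sided paired t-test, displayed as a signed probit z-map; cluster
maps are formed one-sided on the cue > control direction (the direction
of the planted and the reported effect), with the reverse obtainable by
negating the map. Cluster-forming threshold Z > 2.33 is applied in
t-space through the equivalent-tail-mass t threshold, which avoids a
probit transform per permutation.

The primary multiple-comparison correction is permutation: random sign
flips of the subject difference maps (or random permutations of the
covariate, for the second-level covariate GLM), max cluster extent as
the null statistic, and `p = (1 + #{null >= obs}) / (1 + n_perm)`.
Clusters use 6-connectivity by default (configurable to 18, the SPM
convention, or 26); at the package's grid sizes the choice moves extents
by only a few voxels. A Gaussian-random-field RESEL-based closed form
(expected cluster count from the EC density, exponential extent
approximation, residual smoothness via the variance of spatial
derivatives of normalised residuals) is provided as `method = "grf"`,
documented as an approximation and excluded from calibration guarantees.

Small-volume correction restricts cluster inference to each ROI mask,
takes the minimum corrected cluster p per ROI (1 when nothing survives),
and applies the BH step-up across ROI p-values; the BH critical p is the
largest sorted `p_(i) <= i q / m`, or 0 when none passes. In the
pipeline the ROI masks are unions of atlas parcels outside the seed
module — synthetic stand-ins for anatomical atlas masks.

Calibration simulations for the permutation FWER use spatially smoothed
null subject maps (FWHM 2 voxels). With spatially white maps at this
grid size the max-extent null concentrates on extents of 1–3 voxels and
the attained level is dominated by discreteness; smooth maps match the
smoothed data the method targets and yield a rich extent distribution
against which the nominal 5% level is actually attained (500 replicates,
99% binomial band).

## Behavior

Pre-sleep errors are N(2.74, 1.5) cm truncated at 0 by resampling
(distances are non-negative); the post-sleep error adds a subject-level
forgetting term N(0.37, 0.15) cm and item noise N(0, 0.8) cm, truncated
at 0 the same way. The mean levels reproduce realistic object-placement
performance around the 4 cm learning criterion.

The planted brain-behavior link makes forgetting decrease linearly in
the subject's network effect with slope `coupling = 4` cm per unit
boost, applied with full weight to cued items and weight 0.7 to uncued
items (the association extends, attenuated, to material from the same
learning context). The slope acts on `pc_effect - pc_reference` with
`pc_reference = 0.25` (the default effect-population mean): a raw linear
term would drive mean forgetting negative and violate net overnight
forgetting, whereas centring preserves the population mean change while
leaving the association intact. At the defaults the population Kendall
tau between planted effect and forgetting is about -0.7, strong enough
that the tau-recovery power criterion (0.8 at n = 22) is met with
margin.

Kendall's correlation is tau-b (tie-corrected; with no ties it equals
tau-a), with a two-sided p from the normal approximation for S with
tie-corrected variance and continuity correction. The cued-vs-uncued
contrast is a paired t-test — for a two-level within-subject factor the
equivalent repeated-measures F is exactly t^2. The Williams–Hotelling t
compares the two dependent correlations sharing the network covariate,
df = n - 3, refusing non-positive-semi-definite correlation triples.

## Pipeline and reproducibility

`run_stage()` chains simulate, betas, graph, group and behavior stages
over a `run_config()`; every stochastic stage has an explicit derived
seed, outputs are plain NIfTI/TSV/JSON, and each stage writes a manifest
with parameters and content hashes so deterministic stages rerun
bit-identically. The bundled demo configuration (6 subjects, 12^3 grid)
completes in about a minute on one CPU.

## Problem sizes used by the test suite

Unit tests run on toy graphs (3–50 nodes) and short runs (70–300
scans). The deeper suite uses: 1,000 random graphs for the brute-force
participation-coefficient check; 100 stochastic-block-model realisations
(60 nodes, 4 blocks) for Louvain recovery; 1,000 AR(1) replicates for
GLS calibration; 10^5 null nodes for the z-tail, 2,000 replicates each
for covariate and Williams–Hotelling size, and 500 replicates for the
permutation FWER; and a 22-subject end-to-end run at the full default
protocol for planted-effect recovery. These sizes were chosen so
Monte-Carlo error is small relative to each tolerance.

## Known limitations

* The GRF cluster p-values are a coarse closed-form approximation;
  permutation is the supported inference path.
* A single Cochrane–Orcutt iteration does not reproduce full FSL-style
  autocorrelation modelling; the GLS-variance test bounds, not
  eliminates, the residual miscalibration.
* The simulator's spatially white amplitudes make voxel-level graphs
  cleaner than real smoothed data; planted-effect recovery rates should
  be read as upper bounds on real-data sensitivity.
* Community structure is estimated per condition and subject; no
  group-consensus partition is implemented.
* Sleep physiology, preprocessing, and acquisition artifacts are out of
  scope throughout.
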