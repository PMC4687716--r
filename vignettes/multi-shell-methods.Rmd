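---
title: "Multi-shell diffusion reconstruction and shell-trend analysis with hydikit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-shell diffusion reconstruction and shell-trend analysis with hydikit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Hybrid diffusion imaging (HYDI) samples the diffusion-weighted MR signal on
several concentric q-space shells — here five, at b = 1000, 3000, 4000,
8000 and 12000 s/mm², with 60 gradient directions per shell and 5
unweighted (b0) volumes, 305 volumes in all. Low shells carry high SNR;
high shells carry sharp angular contrast. The analytical question hydikit
addresses is *what each added shell buys*: how tensor-derived anisotropy
(FA, MD, RD, AX), ODF-derived anisotropy (GFA, NQA), dominant fiber
orientations, and anisotropy-aided tractography change as shells are
combined cumulatively — the 1-shell scheme being b = 1000 alone, the
2-shell scheme adding b = 3000, and so on to the full 5-shell scheme.

Because no public multi-shell dataset with this exact geometry exists, the
package is built around a synthetic-data module that emulates an ex vivo
high-field rodent acquisition, plus reconstruction, deviation, tracking and
statistics modules that operate on any dataset in NIfTI + FSL bvals/bvecs
form.

## The signal model and the phantom

Each voxel's signal is a finite mixture of Gaussian diffusion compartments,

S(g, b) = S0 · Σₖ fₖ · exp(−b gᵀ Dₖ g),

which is deliberately *non-monoexponential* in b whenever two compartments
with different diffusivities coexist — the regime that makes the cumulative
shell schemes diverge. Four regions are laid out on a 20 × 20 × 10 grid of
0.15 mm voxels (fractions of the grid, so any shape works):

* **bundle** — a single-fiber slab spanning the full left–right (x) extent,
  a stand-in for the body of the corpus callosum: fast compartment
  eigenvalues (0.72, 0.12, 0.12) × 10⁻³ mm²/s at fraction 0.6, slow
  compartment (0.12, 0.06, 0.06) × 10⁻³ at 0.4;
* **crossing** — the same fiber model duplicated along x and y at 90°;
* **gray** — a scaled-down fast/slow anisotropic pair (0.36, 0.18, 0.18)
  and (0.112, 0.088, 0.088) × 10⁻³, mimicking weakly ordered gray matter;
* **background** — an isotropic fast/slow pair (0.8 and 0.12 × 10⁻³).

Diffusivities sit on the *ex vivo* scale: fixed tissue near 20 °C diffuses
roughly 2–3× slower than in vivo, which is what keeps usable signal in the
b = 8000–12000 shells. With the default Rician noise scale σ = S0/55 the
bundle's measured shell SNRs are ≈ 48/34/29/18/12 and the 5-shell scheme
SNR ≈ 28 — the profile of a high-field fixed-brain acquisition. The
gray-matter compartments were chosen as a weaker copy of the white-matter
fast/slow structure on purpose: a mixture whose *fast* compartment is
isotropic inverts the FA shell trend (apparent anisotropy rises as high-b
shells suppress the isotropic part — the free-water-elimination effect),
which is not the regime this phantom emulates. For the same reason the
optional `edgePartialVolume` blending of background fluid into
region-boundary voxels defaults to 0.

Three pseudo-subjects emulate aging at 10, 15 and 24 months: per age step
the λ1:λ2 eigenvalue ratio of the anisotropic compartments shrinks by 10%
(radial eigenvalues are inflated), so true bundle FA declines monotonically
with age.

Gradient directions are spread by iterative pairwise electrostatic
repulsion on the antipodally symmetrized point set (seeded start, 200
annealed iterations); 60 directions reach ≈ 17.7° minimum separation, and
the identical set is reused on every shell. Noise is Rician,
√((S+ε₁)² + ε₂²), the magnitude-MRI model, so the low-SNR shells acquire
the expected upward bias.

**What the generator does not emulate:** scanner artifacts (eddy currents,
EPI distortion), T1/T2 relaxation, spatially varying noise, orientation
dispersion within a region, gyral geometry, and inter-subject anatomical
variability (subjects are generated pre-aligned on a common grid). Passing
tests therefore demonstrate the *estimators and their shell-dependence* on
a controlled signal model, not robustness to real-world confounds.

## Tensor reconstruction

`fitTensor()` solves log S = log S0 − b gᵀDg per voxel: an OLS pass
followed by one reweighting pass with weights equal to the squared
predicted signal — the standard WLS correction for the heteroscedasticity
introduced by the log transform. All volumes of a scheme are fit jointly;
there is no per-shell tensor averaging. Nonpositive samples are floored at
a small positive value and counted; negative eigenvalues are clamped at
zero and counted. FA with a zero denominator is defined as 0.

A documented numerical property of this estimator on two-compartment
signal: when the nearly adjacent b = 4000 shell joins {1000, 3000}, the
reweighting redistributes a small amount of misfit from the axial to the
radial eigenvalues, so the apparent RD can tick up by ~0.2% at k = 2 → 3
even without noise, while MD remains strictly monotone. The RD *trend*
across schemes is still strongly negative.

## Analytic q-ball reconstruction

Per shell, the normalized signal E = S/S0 is expanded in the real,
symmetric (even-order) orthonormal spherical harmonic basis up to order 8
(45 coefficients), with a Laplace–Beltrami penalty λ·l²(l+1)² at
λ = 0.006 — the order and regularization used throughout. The analytic
Funk–Radon transform then scales each degree-l coefficient by 2π·P_l(0),
which equals the great-circle integral of that harmonic; the package
verifies this against brute-force 720-point great-circle quadrature.

ODFs are sampled on a three-times subdivided icosahedron (642 antipodally
symmetric vertices, 321 canonical hemisphere directions, ≈ 9.4° grid
resolution) with the triangulation as the neighbor graph. Peaks are local
maxima over that graph, selected greedily by amplitude with a 25° minimum
separation and lexicographic tie-breaking, then refined below the grid
resolution by a quadratic fit over the vertex's neighbor patch in
gnomonic coordinates — without refinement, peak directions are quantized
to grid vertices and angular-deviation statistics between schemes collapse
to zero on coherent bundles.

**Multi-shell combination.** Monoexponential q-ball theory holds per
shell, and the Funk–Radon scaling is shell-specific, so shells are
reconstructed separately and their ODFs combined by a weighted average.
The default weights are proportional to each shell's mean normalized
signal (its mean l = 0 coefficient), i.e. close to an inverse-variance
combination; equal weighting is available as an option. The rationale is
numerical: at the study's SNR profile, the b = 12000 ODF carries several
times the noise of the b = 1000 ODF, and an equal-weight average lets the
final shell's noise cancel the anisotropy gain it should contribute —
observable as a reversal of the GFA/NQA trend at the last scheme. Signal
weighting restores the physically expected monotone gain while every
shell still contributes in proportion to the information it carries.

GFA is the normalized ODF standard deviation (scale-invariant, in [0, 1];
an all-zero ODF gives 0). QA of a peak is Z0·(ψ(u) − Iψ) with Iψ the
voxel's minimum ODF sample and Z0 = 1 / max over the volume of Iψ — one of
several conventions consistent with the definition's wording; it is
stated here once and used consistently. NQA divides the largest-peak QA by
its volume-wide maximum, so max(NQA) = 1 exactly per reconstruction;
negative ODF and QA values are floored at zero and counted.

## Angular deviation and trends

The dominant direction per voxel is the tensor's principal eigenvector
(DTI) or the highest-amplitude refined ODF peak (QBI); near-isotropic
tensors and flat ODFs are *excluded and counted* rather than assigned a
direction, because assigning θ = 0 to degenerate voxels would deflate the
statistic. The deviation between a k-shell and the 5-shell reconstruction
is θ = arccos|u₁·u₂| in degrees (antipodally and swap invariant, clipped
to [−1, 1] before arccos), averaged over the homogeneous bundle mask.
Trends of any ROI summary across scheme codes 1..5 use OLS with an
optional age covariate; p-values are two-sided from the t distribution,
with perfect fits resolved by convention (zero slope → p = 1).

## Tractography

Deterministic FACT-style streamline tracking: Euler steps of half the
smallest voxel dimension (the classic compromise between step error and
cost; the protocol leaves step size open), direction taken from the
nearest voxel's peaks, choosing the candidate best aligned with the
incoming heading and sign-flipping to preserve it. A streamline stops when
the trilinearly interpolated stopping map (FA, GFA or NQA) falls below
threshold, the turn exceeds 60°, or it leaves the volume; the sub-step
overshoot is clipped, so no retained point lies below threshold. Seeds are
drawn uniformly at random (seeded RNG) within the seed mask until 300
streamlines of ≥ 2 points are collected. The stopping thresholds follow
the protocol table exactly: FA 0.25 (1-shell) / 0.20 (multi-shell), GFA
0.02 / 0.03, NQA 0.25 / 0.30 — single-shell FA runs high while
single-shell GFA and NQA run low, hence the opposite adjustments.

## Statistics

SNR is estimated as the mask-mean signal of a shell divided by the noise,
where noise is the mask-mean of each voxel's standard deviation across the
b0 volumes; a cumulative scheme's SNR is the mean of its member shells'.
Smoothing is separable Gaussian with σ = FWHM/2.3548 per axis,
mask-renormalized at edges; the protocol's "kernel of 3" is read as
FWHM = 3 voxels (it is stated unitless) and is configurable. The
voxel-wise analysis regresses anisotropy on scheme code with age as a
covariate, pooling subjects — with n = 3 subjects, random effects are
unidentifiable, so a fixed age term is the honest adjustment — and
corrects over in-mask voxels with the Benjamini–Hochberg step-up rule at
q = 0.05.

## Problem sizes and reproducibility

The default experiment — three aged subjects on the 20 × 20 × 10 grid,
five cumulative schemes, both models, tractography and all statistics —
was sized to run end to end in about a minute on a single core, so the
whole study can be recomputed from scratch for every seed. Fixing the
master seed fixes every output bit-exactly; the report JSON is
byte-identical across reruns (stage wall-times are written to a separate
informational file for that reason). All randomness flows from the master
seed by fixed offsets.

## Known limitations

* The two-tensor mixture reproduces the *directions* of shell-dependence,
  not the magnitudes reported on real tissue; angular deviations on the
  phantom are an order of magnitude smaller than on heterogeneous anatomy.
* NQA on a perfectly homogeneous region sits at a mean/max ceiling and its
  shell trend is then driven by noise; the statistic is only meaningful on
  maps with genuine contrast.
* The RD estimator artifact described above makes strict per-pair RD
  monotonicity across adjacent shell additions fragile at the ~0.2% level,
  although the overall RD trend is robustly negative.
* Single-peak deviation statistics ignore secondary peaks; crossing-fiber
  assignment problems are out of scope.
* Tracking uses nearest-voxel directions (FACT); no probabilistic or
  higher-order integration.
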