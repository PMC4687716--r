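# hydikit

Multi-shell ("hybrid") diffusion MRI reconstruction and shell-trend
analysis in R.

Hybrid diffusion imaging (HYDI) samples the diffusion-weighted signal on
several concentric q-space shells — here five, at b = 1000, 3000, 4000,
8000 and 12000 s/mm² with 60 directions per shell and 5 b0 volumes. Low
shells have high SNR, high shells have sharp angular contrast, and the
practical question for anyone designing such a protocol is what each added
shell buys. hydikit implements the full analysis chain needed to answer
it, for researchers working with multi-shell rodent or human data and for
method developers who need a controlled test bed:

* **phantom** — a synthetic-data generator emulating an ex vivo
  high-field acquisition: multi-compartment Gaussian signal
  S(g,b) = S0·Σₖ fₖ·exp(−b gᵀDₖg) with two-compartment (fast/slow)
  non-monoexponential decay, a left–right fiber bundle, a 90° crossing
  region, gray-matter-like and background regions, Rician noise, and
  three pseudo-subjects with age-declining anisotropy (10/15/24 months);
* **gradients** — NIfTI-1 + FSL bvals/bvecs I/O, shell detection, and
  cumulative shell subsets (1-shell = b1000, 2-shell adds b3000, ...);
* **dti** — weighted-least-squares tensor fits and the eigenvalue maps
  FA = √(3/2)·√Σ(λᵢ−MD)² / √Σλᵢ², MD = (λ₁+λ₂+λ₃)/3, RD = (λ₂+λ₃)/2,
  AX = λ₁;
* **qbi** — analytic q-ball ODFs via order-8 spherical harmonics with
  Laplace–Beltrami regularization (λ = 0.006) and the Funk–Radon scaling
  2π·P_l(0); GFA (normalized ODF standard deviation), ODF peak extraction
  with sub-grid refinement, and QA(u) = Z0·(ψ(u) − Iψ) with the
  volume-normalized NQA map;
* **deviation** — the inner angle θ = arccos|u₁·u₂| between dominant fiber
  directions of a k-shell and the 5-shell reconstruction, with OLS shell
  trends;
* **tracking** — deterministic FACT-style streamlines with the protocol's
  stopping-threshold table (FA 0.25/0.20, GFA 0.02/0.03, NQA 0.25/0.30 for
  single-/multi-shell), 60° turning limit, 300 fibers, TrackVis export;
* **stats** — b0-based SNR estimation, NaN-aware Gaussian smoothing,
  voxel-wise shell-trend regression with age adjustment and
  Benjamini–Hochberg FDR at q < 0.05, ROI-mean trends;
* **experiment** — one-call orchestration of the whole study design.

## Worked example

```r
library(hydikit)

cfg <- experimentConfig(masterSeed = 1)   # 3 subjects, 5 shells, both models
report <- runExperiment(cfg)

round(report$snr[[1]]$shellSNR, 1)
#>  1000  3000  4000  8000 12000
#>  47.8  33.9  29.3  18.0  12.0

vapply(c("FA", "GFA", "NQA"), function(m)
  c(slope = report$roiTrends$bundle[[m]]$slope,
    p = report$roiTrends$bundle[[m]]$p), numeric(2))
#>               FA          GFA          NQA
#> slope -2.256735e-02 7.748126e-03 1.161181e-02
#> p      6.163181e-11 1.329235e-06 9.826071e-05

c(DTI = report$deviation$DTI$slope, QBI = report$deviation$QBI$slope)
#>        DTI        QBI
#> -0.2920519 -0.3661568

report$replication$faDecreases      # TRUE
report$tracking$NQA$count           # 300
```

Reading the numbers: SNR falls from ~48 to ~12 as b grows, so the high
shells trade SNR for angular contrast. Across the cumulative schemes
k = 1..5, bundle FA *decreases* (slope −0.023 per shell, p ≈ 6e−11) while
the ODF-derived GFA and NQA *increase* — the signature of
non-monoexponential decay: high-b shells suppress the fast compartment,
lowering apparent tensor diffusivities while sharpening the ODF. Dominant
fiber directions converge onto the 5-shell reference (mean angular
deviation shrinks by ~0.3°/shell, p < 1e−4 for both models), and
NQA-aided tractography returns the requested 300 streamlines spanning the
bundle.

A thin command-line wrapper is included for shell use:

```sh
Rscript inst/scripts/hydikit.R phantom --out phantom-dir --seed 1
Rscript inst/scripts/hydikit.R run --out study-dir --seed 1
```

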