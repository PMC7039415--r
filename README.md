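# anisosim

Regional brain development is usually summarized by volume, which says how
much a structure grew but not *along which directions*. `anisosim`
implements linear registration with the **anisotropic similarity**
transformation — an affine map `A = R diag(S) Uᵀ + t` whose scaling
directions, the columns of the rotation `U`, are fixed a priori — and the
downstream analysis that turns the three per-direction scaling factors
`S = (s₁, s₂, s₃)` into directional growth curves and group comparisons.
It is intended for researchers analysing developmental MRI cohorts who want
an interpretable, low-dimensional measure of directional expansion per
region of interest.

The package provides:

* **Transform algebra** — SVD decomposition `A = R diag(S) Uᵀ`
  (`decomposeAffine`), scalings in a fixed frame (`scalingsInFrame`),
  nearest-similarity projection `B = d̄ V Wᵀ` (`nearestSimilarity`),
  composition and inversion, JSON serialization.
* **Point-set estimators** — weighted least-squares fits of rigid,
  similarity, affine and, the core contribution, the anisotropic similarity
  with fixed frame `U` (`fitAnisotropicSimilarity`): an alternating scheme
  in which the rotation step solves a 4×4 symmetric eigenproblem built from
  matricial quaternions and the scaling step is closed-form, so the cost
  never increases.
* **Block-matching registration** — a deterministic multi-resolution engine
  (`registerImages`, Rcpp inner loops) and the two-step ROI protocol
  (`twoStepRoiRegistration`): whole-brain affine → nearest similarity →
  ROI-masked anisotropic similarity, whose composed scalings are the
  relative directional factors.
* **Scaling frame construction** — mid-sagittal plane by symmetry
  registration plus in-plane PCA (`estimateMidsagittalPlane`,
  `computeScalingFrame`).
* **Growth analysis** — baseline (neonate) normalization, gender-balance
  weights, weighted Levenberg–Marquardt fits of rational / Weibull /
  Gompertz / exponential growth models, AICc model selection with Akaike
  weights, pointwise bootstrap confidence bands, Wilcoxon–Mann–Whitney
  group tests under Benjamini–Hochberg FDR control with effect size
  `d = (median(Sₘ) − median(S_f)) / (σ(Sₘ) + σ(S_f))`, and
  reference-image influence metrics.
* **Synthetic fixtures** — analytic textured brain phantoms, warped
  subjects rendered without resampling, paired point sets and cohorts, so
  the whole pipeline runs and is tested without any external data.

## Worked example

Estimate an anisotropic similarity from paired points with a known frame,
then read off the directional scalings:

```r
library(anisosim)

U   <- quatToRotation(unitQuaternion(c(5, 1, 0.5, -0.3)))   # fixed frame
R   <- quatToRotation(unitQuaternion(c(8, 0.8, -0.5, 0.6)))
S   <- c(1.25, 0.90, 1.10)
tru <- linearTransform3D(R %*% diag(S) %*% t(U), c(4, -6, 3))

pts <- makePairedPoints(20, tru, noiseSd = 0, seed = 1)
fit <- fitAnisotropicSimilarity(pts, U)
fit
#> FitReport [ anisotropic_similarity ]: cost = 1.46952e-20 mm^2 after 12 iteration(s); converged
scalings(decomposition(fit))
#> [1] 1.25 0.90 1.10
```

The vanishing cost says the 20 noiseless pairs are interpolated exactly; the
scalings are the per-direction stretch factors along the columns of `U`.
The same factors come out of image registration:

```r
spec <- defaultPhantomSpec()              # 64^3 textured brain phantom
ref  <- makePhantom(spec)$image
mov  <- transformPhantom(spec, tru)$image # analytic ground-truth subject
reg  <- twoStepRoiRegistration(mov, ref, imageMask(ref), U, registrationConfig())
round(reg$scalings, 3)
#> [1] 1.246 0.894 1.095
```

Here the engine recovers the generating scalings within ~0.7%: a subject
whose brain is 25% larger than the reference along direction 1 gets
`s₁ ≈ 1.25`. After `normalizeToBaseline()` against a neonate group, such
factors read as expansion since birth, and `selectGrowthModel()` /
`compareGroups()` model and test them per ROI and direction.

An end-to-end driver (`runPipeline()`, YAML-configured) and a thin CLI
(`inst/scripts/anisosim` with subcommands `frame`, `register`, `fit-points`,
`simulate`, `extract`, `fit-growth`, `compare-groups`, `ref-influence`,
`pipeline`) wrap the same functions.

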