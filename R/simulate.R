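#' @include AllClasses.R accessors.R quaternion.R transform.R image.R
NULL

#' Random rotation matrix
#'
#' Uniform over SO(3) (normalized Gaussian quaternion), drawn from the
#' current RNG stream.
#' @export
randomRotationMatrix <- function() {
  quatToRotation(unitQuaternion(stats::rnorm(4)))
}

#' Default multi-ellipsoid phantom specification
#'
#' A left-right symmetric "brain" on a 64^3 grid with 2.5 mm isotropic
#' voxels: an outer brain ellipsoid whose in-plane extents differ (so the
#' scaling-frame construction has a well-defined PCA), a mirrored pair of
#' low-intensity ventricles, a mirrored pair of bright deep-grey blobs and a
#' midline cerebellum. Intensities are arbitrary units; edges are smoothed
#' over a relative width `edge` so block matching sees gradients rather than
#' binary steps.
#'
#' A smooth multiplicative texture is applied inside the object so that every
#' block carries three-dimensional intensity structure; flat-interior
#' phantoms leave boundary blocks free to slide tangentially (the aperture
#' problem) and are poor registration targets. The texture is an analytic sum
#' of seeded random-wavevector cosines (so transformed phantoms can be
#' rendered without resampling), mirror-symmetric about the x = 0 plane
#' (even in x), and deliberately aperiodic so that no shifted block is
#' strongly correlated or anti-correlated with the original.
#'
#' @param dim grid size (cubic).
#' @param spacing voxel size (mm).
#' @param noiseSd additive Gaussian noise standard deviation.
#' @param seed RNG seed for the noise.
#' @param textureAmplitude maximum relative amplitude of the texture
#'   modulation (0 disables it).
#' @param textureSeed seed for the texture wavevectors and phases.
#' @return a phantom spec list (fields grid, spacing, ellipsoids, texture,
#'   noiseSd, seed).
#' @export
defaultPhantomSpec <- function(dim = 64L, spacing = 2.5, noiseSd = 0, seed = 0L,
                               textureAmplitude = 0.35, textureSeed = 7L) {
  ell <- function(label, center, semi, intensity, rotation = diag(3))
    list(label = label, center = center, semi = semi, intensity = intensity,
         rotation = rotation)
  tex <- NULL
  if (textureAmplitude > 0) {
    ## texture parameters use a local RNG stream, restored afterwards
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(textureSeed)
    ## wavelengths span block scale (~10 mm) up to structure scale so blocks
    ## are discriminative at full resolution and coarse levels stay smooth
    nComp <- 16L
    k <- 2 * pi / matrix(stats::runif(3 * nComp, 9, 30), nComp, 3)
    phase <- matrix(stats::runif(2 * nComp, 0, 2 * pi), nComp, 2)
    amp <- stats::runif(nComp, 0.5, 1)
    amp <- amp / sum(amp) * textureAmplitude
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
      rm(".Random.seed", envir = .GlobalEnv)
    tex <- list(k = k, phase = phase, amp = amp)
  }
  list(grid = rep(as.integer(dim), 3), spacing = rep(spacing, 3), edge = 0.1,
       noiseSd = noiseSd, seed = as.integer(seed), texture = tex,
       ellipsoids = list(
         ell("brain", c(0, 4, 0), c(34, 42, 32), 100),
         ell("ventricle_L", c(-10, 6, 6), c(6, 14, 8), 30),
         ell("ventricle_R", c(10, 6, 6), c(6, 14, 8), 30),
         ell("deep_L", c(-13, -2, -4), c(7, 9, 7), 150),
         ell("deep_R", c(13, -2, -4), c(7, 9, 7), 150),
         ell("cerebellum", c(0, -30, -16), c(17, 12, 11), 70)))
}

## Squared ellipsoid quadratic coordinate of world points (1 on the surface).
.ellipsoidQ2 <- function(world, e) {
  u <- sweep(world, 2, e$center) %*% e$rotation  # rows: R' (x - c)
  rowSums(sweep(u, 2, e$semi, `/`)^2)
}

## Smooth membership in [0, 1] with a cosine ramp of relative width `edge`
## around the surface.
.softMembership <- function(q2, edge) {
  r <- sqrt(q2)
  a <- numeric(length(r))
  a[r <= 1 - edge] <- 1
  ramp <- r > 1 - edge & r < 1 + edge
  a[ramp] <- 0.5 * (1 + cos(pi * (r[ramp] - (1 - edge)) / (2 * edge)))
  a
}

.renderPhantom <- function(spec, preMap = NULL) {
  d <- spec$grid
  img <- image3D(array(0, d), spacing = spec$spacing)
  world <- voxelToWorld(img, .voxelGrid(d))
  if (!is.null(preMap)) world <- applyTransform(preMap, world)
  vals <- numeric(nrow(world))
  masks <- list()
  labels <- vapply(spec$ellipsoids, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    .asError("ellipsoid labels must be unique", "bad_config")
  for (e in spec$ellipsoids) {
    q2 <- .ellipsoidQ2(world, e)
    a <- .softMembership(q2, spec$edge)
    vals <- vals * (1 - a) + a * e$intensity
    masks[[e$label]] <- array(q2 <= 1, d)
  }
  tex <- spec$texture
  if (!is.null(tex)) {
    field <- 0
    for (j in seq_along(tex$amp))
      field <- field + tex$amp[j] *
        cos(tex$k[j, 1] * world[, 1]) *
        cos(tex$k[j, 2] * world[, 2] + tex$phase[j, 1]) *
        cos(tex$k[j, 3] * world[, 3] + tex$phase[j, 2])
    vals <- vals * (1 + field)
  }
  if (spec$noiseSd > 0) {
    set.seed(spec$seed)
    vals <- vals + stats::rnorm(length(vals), 0, spec$noiseSd)
  }
  union <- Reduce(`|`, masks)
  list(image = image3D(array(vals, d), img@affine, mask = union), masks = masks)
}

#' Render a phantom image
#'
#' Analytic rendering of the spec's ellipsoids (no resampling), plus optional
#' seeded Gaussian noise; a pure function of the spec. The returned image
#' carries the union of the ellipsoid masks; per-label hard masks (quadratic
#' form at most 1) are returned alongside.
#'
#' @param spec a phantom spec, see [defaultPhantomSpec()].
#' @return list with `image` ([Image3D-class]) and `masks` (named list of
#'   logical arrays).
#' @export
makePhantom <- function(spec = defaultPhantomSpec()) .renderPhantom(spec)

#' Render a transformed phantom
#'
#' Renders the subject image corresponding to a ground-truth transform `T`
#' mapping reference coordinates to subject coordinates: the subject image at
#' world position y takes the analytic phantom value at `T^{-1} y`. Because
#' the ellipsoids are evaluated analytically at the mapped coordinates, the
#' result is alias-free ground truth for registration recovery (registering
#' the output onto the reference phantom should recover `T`).
#'
#' @param spec a phantom spec.
#' @param transform ground-truth [LinearTransform3D-class] (reference ->
#'   subject world coordinates).
#' @param grid optional c(dim, spacing) override for the subject grid, given
#'   as a spec-like list with fields `grid` and `spacing`; defaults to the
#'   phantom's own grid.
#' @return list with `image` and `masks` as in [makePhantom()].
#' @export
transformPhantom <- function(spec, transform, grid = NULL) {
  .checkInvertible(transform@matrix)
  if (!is.null(grid)) {
    spec$grid <- rep(as.integer(grid$grid), length.out = 3)
    spec$spacing <- rep(grid$spacing, length.out = 3)
  }
  .renderPhantom(spec, preMap = invertTransform(transform))
}

#' Simulate paired point sets from a known transform
#'
#' Reference points uniform in a cube, moving points their images under the
#' transform plus isotropic Gaussian noise.
#'
#' @param M number of pairs (at least 4).
#' @param transform a [LinearTransform3D-class].
#' @param noiseSd Gaussian noise sd on the moving points (mm).
#' @param seed RNG seed.
#' @param halfWidth half-width of the sampling cube (mm).
#' @param coplanar force all reference points into the z = 0 plane (to
#'   exercise degenerate-geometry errors downstream).
#' @return a [PairedPointSet-class].
#' @export
makePairedPoints <- function(M, transform = identityTransform(), noiseSd = 0,
                             seed = 1, halfWidth = 50, coplanar = FALSE) {
  if (M < 4) .asError("at least 4 pairs are required", "bad_config")
  set.seed(seed)
  x <- matrix(stats::runif(3 * M, -halfWidth, halfWidth), M, 3)
  if (coplanar) x[, 3] <- 0
  y <- applyTransform(transform, x)
  if (noiseSd > 0) y <- y + matrix(stats::rnorm(3 * M, 0, noiseSd), M, 3)
  pairedPointSet(x, y)
}

#' Default synthetic cohort specification
#'
#' Emulates the structure of a developmental cohort: ages 0-19 years with a
#' neonate baseline cluster (ages in [0, 0.1]), balanced sexes, and true
#' per-direction growth following the rational family with direction-specific
#' coefficients (values near 1 at birth rising to an asymptote).
#' Multiplicative lognormal noise is used since scaling factors are positive
#' ratios.
#'
#' @param n number of subjects.
#' @param rois ROI labels.
#' @param neonateFraction fraction of subjects in the neonate cluster.
#' @param sigma lognormal noise sd (on the log scale).
#' @param sexEffect named numeric: multiplicative effect applied to male
#'   subjects per direction (e.g. `c("1" = 1.05)`), empty for none.
#' @param seed RNG seed.
#' @export
defaultCohortSpec <- function(n = 200L, rois = "whole_brain",
                              neonateFraction = 0.12, sigma = 0.03,
                              sexEffect = numeric(0), seed = 1L) {
  list(n = as.integer(n), rois = rois, neonateFraction = neonateFraction,
       sigma = sigma, sexEffect = sexEffect, seed = as.integer(seed),
       ageRange = c(0, 19),
       truth = list(
         `1` = list(family = "rational", coefficients = c(a = 1.35, b = 1.10, c = 1.1)),
         `2` = list(family = "rational", coefficients = c(a = 1.50, b = 1.58, c = 1.5)),
         `3` = list(family = "rational", coefficients = c(a = 1.25, b = 0.86, c = 0.9))))
}

#' Simulate a cohort of scaling records
#'
#' Per subject, ROI and direction the scaling factor is the true growth
#' curve at the subject's age, times lognormal noise, times the sex effect
#' for affected directions of male subjects. The neonate cluster provides the
#' baseline group for [normalizeToBaseline()]. Pure function of spec + seed.
#'
#' @param spec a cohort spec, see [defaultCohortSpec()].
#' @return list with `records` (scaling-record data.frame, reference "ref1"),
#'   `baselineSubjects` (ids of the neonate cluster) and `spec`.
#' @export
makeCohort <- function(spec = defaultCohortSpec()) {
  set.seed(spec$seed)
  n <- spec$n
  if (n < 4) .asError("cohort needs at least 4 subjects", "bad_config")
  nNeo <- max(1L, round(n * spec$neonateFraction))
  ages <- c(stats::runif(nNeo, 0, 0.1),
            stats::runif(n - nNeo, 0.25, spec$ageRange[2]))
  sexes <- sample(rep(c("male", "female"), length.out = n))
  ids <- sprintf("subj%03d", seq_len(n))
  rows <- list()
  for (roi in spec$rois) {
    for (d in 1:3) {
      tr <- spec$truth[[as.character(d)]]
      mu <- growthCurve(tr$family, ages, tr$coefficients)
      s <- mu * exp(stats::rnorm(n, 0, spec$sigma))
      eff <- spec$sexEffect[as.character(d)]
      if (length(eff) == 1 && !is.na(eff)) s[sexes == "male"] <- s[sexes == "male"] * eff
      rows[[length(rows) + 1L]] <- data.frame(
        subject = ids, age = ages, sex = sexes, roi = roi, direction = d,
        reference = "ref1", scaling = s)
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  list(records = records, baselineSubjects = ids[seq_len(nNeo)], spec = spec)
}
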