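#' @include AllClasses.R accessors.R fit.R image.R
NULL

#' Block-matching registration configuration
#'
#' Defaults: 5^3-voxel blocks on a lattice of spacing 2, exhaustive integer
#' search of radius 3 voxels, the least-variant quarter of blocks discarded,
#' a 3-level pyramid (x4, x2, x1) and at most 10 aggregation iterations per
#' level (stopping early once the matches stop changing). All values are in
#' voxels of the current pyramid level. The block similarity metric is the
#' squared correlation coefficient, also used as the per-pair weight in the
#' least-squares aggregation.
#'
#' @param blockSize odd cubic block edge (voxels).
#' @param blockSpacing lattice spacing between block centres (voxels).
#' @param searchRadius exhaustive search radius (voxels).
#' @param keepFraction fraction of highest-variance blocks retained, in (0,1].
#' @param pyramidLevels number of pyramid levels (level l downsamples by
#'   2^(l-1)).
#' @param maxOuterIterations match/aggregate iterations per level.
#' @param kind transform kind to estimate.
#' @param frame [ScalingFrame-class] (required for the anisotropic kind).
#' @param scoreThreshold pairs scoring below this are dropped.
#' @param seed recorded for provenance (the engine itself is deterministic).
#' @return a validated list of class `RegistrationConfig`.
#' @export
registrationConfig <- function(blockSize = 5L, blockSpacing = 2L, searchRadius = 3L,
                               keepFraction = 0.75, pyramidLevels = 3L,
                               maxOuterIterations = 10L, kind = "affine",
                               frame = NULL, scoreThreshold = 0.01, seed = NULL) {
  blockSize <- as.integer(blockSize)
  if (blockSize %% 2L != 1L || blockSize < 3L)
    .asError("blockSize must be odd and >= 3", "bad_config")
  if (keepFraction <= 0 || keepFraction > 1)
    .asError("keepFraction must lie in (0, 1]", "bad_config")
  if (!kind %in% c("rigid", "similarity", "affine", "anisotropic_similarity"))
    .asError(paste("unknown transform kind:", kind), "bad_config")
  if (kind == "anisotropic_similarity" && is.null(frame))
    .asError("anisotropic similarity registration requires a frame", "bad_config")
  structure(list(blockSize = blockSize, blockSpacing = as.integer(blockSpacing),
                 searchRadius = as.integer(searchRadius), keepFraction = keepFraction,
                 pyramidLevels = as.integer(pyramidLevels),
                 maxOuterIterations = as.integer(maxOuterIterations), kind = kind,
                 frame = frame, scoreThreshold = scoreThreshold, seed = seed),
            class = "RegistrationConfig")
}

#' Select reference blocks
#'
#' Lays a regular lattice of block centres inside the reference volume (and
#' inside the mask when one is present), ranks blocks by intensity variance,
#' and keeps the top `keepFraction`. Flat images therefore yield no blocks.
#'
#' @param ref reference [Image3D-class] (its mask, if any, restricts centres).
#' @param cfg a [registrationConfig()].
#' @return list with `vox` (N x 3, 0-based centre indices), `world` (N x 3,
#'   mm) and `variance`.
#' @export
extractBlocks <- function(ref, cfg) {
  d <- dim(ref@data)
  h <- (cfg$blockSize - 1L) %/% 2L
  ax <- lapply(d, function(n) seq.int(h, n - 1L - h, by = cfg$blockSpacing))
  if (any(lengths(ax) == 0)) .asError("image smaller than one block", "empty_blocks")
  vox <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]], KEEP.OUT.ATTRS = FALSE))
  colnames(vox) <- NULL
  if (!is.null(ref@mask)) {
    keep <- ref@mask[vox + 1L] != 0
    vox <- vox[keep, , drop = FALSE]
    if (nrow(vox) == 0) .asError("no block centres inside the mask", "empty_blocks")
  }
  v <- .cppBlockVariances(as.numeric(ref@data), dim(ref@data), vox, h)
  ok <- v > 0
  vox <- vox[ok, , drop = FALSE]
  v <- v[ok]
  if (length(v) == 0)
    .asError("no blocks with positive intensity variance", "empty_blocks")
  nKeep <- max(1L, ceiling(cfg$keepFraction * length(v)))
  ord <- order(v, decreasing = TRUE)[seq_len(nKeep)]
  ord <- sort(ord)  # keep lattice order for determinism of downstream fits
  list(vox = vox[ord, , drop = FALSE], world = voxelToWorld(ref, vox[ord, , drop = FALSE]),
       variance = v[ord])
}

#' Match reference blocks in the moving image
#'
#' Each reference block centre is mapped through the current transform
#' estimate into moving-image voxel space (rounded to the nearest voxel) and
#' an exhaustive integer-offset search within `searchRadius` selects the
#' moving block maximizing the squared correlation coefficient. Pairs with no
#' admissible or informative (non-flat) moving block, or scoring below the
#' threshold, are dropped.
#'
#' @param ref,mov [Image3D-class] images.
#' @param blocks output of [extractBlocks()].
#' @param transform current estimate (reference -> moving, world mm).
#' @param cfg a [registrationConfig()].
#' @return a [BlockMatchSet-class]; x are reference block centres (world mm),
#'   y the matched moving positions, weights the scores.
#' @export
matchBlocks <- function(ref, mov, blocks, transform, cfg) {
  .checkInvertible(transform@matrix)
  h <- (cfg$blockSize - 1L) %/% 2L
  predWorld <- applyTransform(transform, blocks$world)
  predVox <- round(worldToVoxel(mov, predWorld))
  storage.mode(predVox) <- "integer"
  res <- .cppMatchBlocks(as.numeric(ref@data), dim(ref@data),
                         as.numeric(mov@data), dim(mov@data),
                         blocks$vox, predVox, h, cfg$searchRadius)
  keep <- res$valid & res$scores >= cfg$scoreThreshold
  if (sum(keep) < 4)
    .asError("fewer than 4 usable block pairs", "registration_failed")
  matchedVox <- predVox[keep, , drop = FALSE] + res$offsets[keep, , drop = FALSE]
  y <- voxelToWorld(mov, matchedVox)
  new("BlockMatchSet", x = blocks$world[keep, , drop = FALSE], y = y,
      w = res$scores[keep], scores = res$scores[keep])
}

## Transform kind used at a given pyramid level: degrees of freedom are
## released progressively (similarity on the coarse levels, where the few
## matched blocks would let a 9/12-dof fit interpolate matching noise; the
## requested kind on the two finest levels).
.levelKind <- function(kind, level) {
  if (level >= 3L && kind %in% c("affine", "anisotropic_similarity")) "similarity"
  else kind
}

## Fit the configured transform kind to a block-match set, warm-starting the
## anisotropic kind from the current estimate.
.aggregate <- function(pts, cfg, current) {
  if (cfg$kind == "anisotropic_similarity") {
    init <- tryCatch(scalingsInFrame(current@matrix, cfg$frame, current@translation,
                                     tol = 0.5),
                     error = function(e) NULL)
    if (!is.null(init))
      fitAnisotropicSimilarity(pts, cfg$frame, sInit = init@S,
                               qInit = rotationToQuat(init@R)@q)
    else fitAnisotropicSimilarity(pts, cfg$frame)
  } else {
    fitTransform(pts, cfg$kind)
  }
}

#' Block-matching image registration
#'
#' Iterates block matching and weighted least-squares aggregation over a
#' multi-resolution pyramid. At each level, reference blocks are extracted
#' once. Each outer iteration (i) resamples the moving image through the
#' current estimate onto the reference grid, (ii) matches reference blocks in
#' the resampled image (so that, as the estimate converges, matching
#' degenerates to exact self-matching and the estimate stabilizes), (iii)
#' maps the matched positions back to moving space through the current
#' estimate and refits the configured transform kind to the full composed
#' correspondence set, with scores as weights. Iterations stop early when the
#' matches stop changing. The whole procedure is deterministic.
#'
#' @param ref reference [Image3D-class] (mask restricts block extraction).
#' @param mov moving [Image3D-class].
#' @param cfg a [registrationConfig()].
#' @param init optional initial [LinearTransform3D-class] (reference ->
#'   moving); defaults to identity.
#' @param verbose print per-iteration diagnostics.
#' @return a [FitReport-class] for the final transform; `costTrace` holds the
#'   per-iteration aggregation costs across levels.
#' @export
registerImages <- function(ref, mov, cfg, init = NULL, verbose = FALSE) {
  current <- if (is.null(init)) identityTransform() else init
  trace <- numeric(0)
  iterTotal <- 0L
  lastFit <- NULL
  idT <- identityTransform()
  for (level in seq(cfg$pyramidLevels, 1L)) {
    f <- 2L^(level - 1L)
    ## skip levels too coarse to hold a meaningful block lattice
    if (min(dim(ref@data) %/% f) < 3L * cfg$blockSize) next
    refL <- if (f > 1L) downsampleImage(ref, f) else ref
    movL <- if (f > 1L) downsampleImage(mov, f) else mov
    blocks <- extractBlocks(refL, cfg)
    cfgL <- cfg
    cfgL$kind <- .levelKind(cfg$kind, level)
    prevKey <- NULL
    for (it in seq_len(cfg$maxOuterIterations)) {
      resampled <- resampleImage(movL, current, refL)
      ptsRes <- matchBlocks(refL, resampled, blocks, idT, cfg)
      pts <- new("BlockMatchSet", x = ptsRes@x,
                 y = applyTransform(current, ptsRes@y),
                 w = ptsRes@w, scores = ptsRes@scores)
      fit <- .aggregate(pts, cfgL, current)
      current <- fit@transform
      lastFit <- fit
      iterTotal <- iterTotal + 1L
      trace <- c(trace, fit@finalCost)
      if (verbose)
        message(sprintf("level %d it %d: %d pairs, cost %.4g", level, it,
                        nrow(pts@x), fit@finalCost))
      key <- c(ptsRes@y)
      if (!is.null(prevKey) && length(prevKey) == length(key) &&
          all(prevKey == key)) break
      prevKey <- key
    }
  }
  if (is.null(lastFit))
    .asError("no pyramid level large enough for the configured blocks",
             "registration_failed")
  new("FitReport", transform = current, decomposition = lastFit@decomposition,
      finalCost = lastFit@finalCost, nIterations = iterTotal,
      converged = TRUE, costTrace = trace, kind = cfg$kind)
}

#' Two-step ROI registration protocol
#'
#' Step 1 estimates a whole-image affine from the moving image onto the
#' reference and projects it onto its nearest similarity `T_B`. Step 2
#' estimates the anisotropic similarity with frame `U` between the reference
#' restricted to the ROI mask and the moving image, initialized at `T_B`
#' (the mask restricts reference block extraction only). Because composing a
#' similarity with an anisotropic similarity of frame `U` stays in the class,
#' the total transform is an anisotropic similarity of frame `U`; its
#' scalings are returned in `U`'s column order, along with
#' `T_C = T_B^{-1} o T_total`, the anisotropic residual of step 2.
#'
#' @param mov moving (subject) [Image3D-class].
#' @param ref reference [Image3D-class]; its mask (if any) is used for the
#'   whole-image step.
#' @param roiMask mask array on the reference grid (or an [Image3D-class]).
#' @param U a [ScalingFrame-class].
#' @param cfg a [registrationConfig()]; `kind` and `frame` are overridden per
#'   step.
#' @param verbose print per-iteration diagnostics.
#' @return list with elements `similarity` (T_B), `aniso` (T_C), `total`
#'   ([FitReport-class]) and `scalings` (length-3, frame column order).
#' @export
twoStepRoiRegistration <- function(mov, ref, roiMask, U, cfg = registrationConfig(),
                                   verbose = FALSE) {
  if (is(roiMask, "Image3D")) roiMask <- roiMask@data
  cfgA <- cfg
  cfgA$kind <- "affine"
  affineFit <- registerImages(ref, mov, cfgA, verbose = verbose)
  bl <- extractBlocks(ref, cfgA)
  bary <- colMeans(bl$world)
  TB <- nearestSimilarity(affineFit@transform,
                          xbar = bary,
                          ybar = applyTransform(affineFit@transform, bary))
  refRoi <- image3D(ref@data, ref@affine, mask = array(roiMask != 0, dim(ref@data)))
  cfgC <- cfg
  cfgC$kind <- "anisotropic_similarity"
  cfgC$frame <- if (is(U, "ScalingFrame")) U else scalingFrame(U)
  totalFit <- registerImages(refRoi, mov, cfgC, init = TB, verbose = verbose)
  TC <- composeTransforms(invertTransform(TB), totalFit@transform)
  list(similarity = TB, aniso = TC, total = totalFit,
       scalings = totalFit@decomposition@S)
}
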