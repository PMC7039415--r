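## 32^3 phantom at 5 mm voxels: quick enough for unit tests while exercising
## the full pyramid machinery.
bmPhantom <- function(...) makePhantom(defaultPhantomSpec(dim = 32L, spacing = 5, ...))

test_that("block extraction ranks by variance and respects the mask", {
  ph <- bmPhantom()
  ref <- ph$image
  cfg <- registrationConfig(keepFraction = 0.5)
  ## constant image: every variance 0, nothing survives
  flat <- image3D(array(1, dim(imageData(ref))), imageAffine(ref))
  expect_error(extractBlocks(flat, cfg), class = "anisosim_empty_blocks")

  bl <- extractBlocks(ref, cfg)
  ## mask containment: all centres inside the mask
  expect_true(all(imageMask(ref)[bl$vox + 1L]))

  ## independent variance ranking oracle on the same lattice
  a <- imageData(ref)
  h <- 2L
  ax <- seq.int(h, 31L - h, by = cfg$blockSpacing)
  lattice <- as.matrix(expand.grid(ax, ax, ax))
  colnames(lattice) <- NULL
  inMask <- imageMask(ref)[lattice + 1L]
  lattice <- lattice[inMask, , drop = FALSE]
  v <- apply(lattice, 1, function(c0) {
    blk <- a[(c0[1] - h):(c0[1] + h) + 1, (c0[2] - h):(c0[2] + h) + 1,
             (c0[3] - h):(c0[3] + h) + 1]
    mean(blk^2) - mean(blk)^2
  })
  keepN <- ceiling(0.5 * sum(v > 0))
  expect_equal(nrow(bl$vox), keepN)
  expect_gte(min(bl$variance),
             sort(v[v > 0], decreasing = TRUE)[keepN] - 1e-9 * max(v))
})

test_that("self-matching returns zero offsets with perfect scores", {
  ph <- bmPhantom()
  ref <- ph$image
  cfg <- registrationConfig()
  bl <- extractBlocks(ref, cfg)
  pts <- matchBlocks(ref, ref, bl, identityTransform(), cfg)
  expect_equal(movPoints(pts), refPoints(pts))
  expect_true(all(pointWeights(pts) > 1 - 1e-12))
})

test_that("a pure integer-voxel shift is matched exactly", {
  ph <- bmPhantom()
  ref <- ph$image
  a <- imageData(ref)
  ## moving image = ref shifted by +3 voxels along x (content moves so that
  ## mov[i] = ref[i + 3]), i.e. the ref->mov map is x + 3 * spacing
  mov <- array(0, dim(a))
  mov[1:29, , ] <- a[4:32, , ]
  movImg <- image3D(mov, imageAffine(ref))
  cfg <- registrationConfig()
  bl <- extractBlocks(image3D(a, imageAffine(ref),
                              mask = imageMask(ref)), cfg)
  ## keep centres whose shifted block stays inside
  keep <- bl$vox[, 1] <= 23
  bl$vox <- bl$vox[keep, , drop = FALSE]
  bl$world <- bl$world[keep, , drop = FALSE]
  pts <- matchBlocks(ref, movImg, bl, identityTransform(), cfg)
  off <- movPoints(pts) - refPoints(pts)
  sp <- voxelSpacing(ref)[1]
  expect_true(all(abs(off[, 1] + 3 * sp) < 1e-9))
  expect_true(all(abs(off[, 2:3]) < 1e-9))
})

test_that("matching pure noise yields low scores", {
  ph <- bmPhantom()
  ref <- ph$image
  set.seed(61)
  noise <- image3D(array(stats::rnorm(32^3), c(32, 32, 32)), imageAffine(ref))
  cfg <- registrationConfig(scoreThreshold = 0)
  bl <- extractBlocks(ref, cfg)
  pts <- matchBlocks(ref, noise, bl, identityTransform(), cfg)
  ## best-of-343 squared correlations of 125 independent gaussians stay small
  expect_lt(mean(pointWeights(pts)), 0.2)
})

test_that("self-registration returns the identity for every kind", {
  ph <- bmPhantom()
  ref <- ph$image
  for (kind in c("rigid", "similarity", "affine", "anisotropic_similarity")) {
    cfg <- registrationConfig(kind = kind, pyramidLevels = 2L,
                              frame = scalingFrame(diag(3)))
    fit <- registerImages(ref, ref, cfg)
    sp <- max(voxelSpacing(ref))
    expect_lt(max(abs(translationPart(fittedTransform(fit)))), 0.1 * sp)
    expect_lt(rotationAngleDeg(diag(3), linearPart(fittedTransform(fit)) /
                                 det(linearPart(fittedTransform(fit)))^(1 / 3)), 0.5)
    expect_lt(max(abs(linearPart(fittedTransform(fit)) - diag(3))), 0.01)
  }
})

test_that("registration recovers a known similarity warp", {
  spec <- defaultPhantomSpec()  # full resolution: accuracy scales with voxels
  ref <- makePhantom(spec)$image
  th <- 10 * pi / 180
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  Tgt <- linearTransform3D(1.2 * Rz, c(3, -4, 2))
  mov <- transformPhantom(spec, Tgt)$image
  fit <- registerImages(ref, mov, registrationConfig(kind = "similarity"))
  d <- decomposition(fit)
  expect_lt(abs(scalings(d)[1] - 1.2) / 1.2, 0.01)
  expect_lt(rotationAngleDeg(rotationPart(d), Rz), 1)
})

test_that("registration recovers a known anisotropic warp about a known frame", {
  spec <- defaultPhantomSpec(dim = 32L, spacing = 5)
  ref <- makePhantom(spec)$image
  set.seed(62)
  U <- rRotation()
  S <- c(1.3, 0.9, 1.1)
  Tgt <- linearTransform3D(rSmallRotation(8) %*% U %*% diag(S) %*% t(U), c(2, 5, -3))
  mov <- transformPhantom(spec, Tgt)$image
  cfg <- registrationConfig(kind = "anisotropic_similarity", frame = scalingFrame(U))
  fit <- registerImages(ref, mov, cfg)
  expect_lt(max(abs(scalings(decomposition(fit)) - S) / S), 0.02)
})

test_that("register is deterministic and consistent with its own aggregation", {
  ph <- bmPhantom()
  ref <- ph$image
  spec <- defaultPhantomSpec(dim = 32L, spacing = 5)
  Tgt <- linearTransform3D(diag(c(1.1, 1.05, 0.95)), c(2, 0, -1))
  mov <- transformPhantom(spec, Tgt)$image
  cfg <- registrationConfig(kind = "affine")
  f1 <- registerImages(ref, mov, cfg)
  f2 <- registerImages(ref, mov, cfg)
  expect_identical(linearPart(fittedTransform(f1)), linearPart(fittedTransform(f2)))
  expect_identical(f1@costTrace, f2@costTrace)

  ## one iteration of register == matchBlocks on the resampled moving image,
  ## composed through the current estimate, fed to the point-set fitter
  cfg1 <- registrationConfig(kind = "affine", pyramidLevels = 1L,
                             maxOuterIterations = 1L)
  fit1 <- registerImages(ref, mov, cfg1)
  bl <- extractBlocks(ref, cfg1)
  res <- resampleImage(mov, identityTransform(), ref)
  pts <- matchBlocks(ref, res, bl, identityTransform(), cfg1)
  manual <- fitAffine(pts)
  expect_equal(linearPart(fittedTransform(fit1)), linearPart(fittedTransform(manual)),
               tolerance = 1e-12)
})

test_that("two-step ROI protocol returns near-unit scalings for self", {
  ph <- bmPhantom()
  ref <- ph$image
  set.seed(63)
  U <- rRotation()
  res <- twoStepRoiRegistration(ref, ref, imageMask(ref), U,
                                registrationConfig(pyramidLevels = 2L))
  expect_lt(max(abs(res$scalings - 1)), 0.01)
  ## T_B o T_C equals the total transform
  recomposed <- composeTransforms(res$similarity, res$aniso)
  expect_equal(linearPart(recomposed), linearPart(fittedTransform(res$total)),
               tolerance = 1e-9)
})

test_that("two-step protocol absorbs isotropic scale in step 1", {
  spec <- defaultPhantomSpec()  # full resolution: 2% accuracy needs 2.5 mm voxels
  ref <- makePhantom(spec)$image
  Tgt <- linearTransform3D(1.2 * diag(3), c(0, 0, 0))
  mov <- transformPhantom(spec, Tgt)$image
  set.seed(64)
  U <- rRotation()
  res <- twoStepRoiRegistration(mov, ref, imageMask(ref), U, registrationConfig())
  expect_lt(max(abs(res$scalings - 1.2) / 1.2), 0.02)
  sB <- det(linearPart(res$similarity))^(1 / 3)
  expect_lt(abs(sB - 1.2) / 1.2, 0.02)
})

test_that("registration fails cleanly on degenerate inputs", {
  ## grid too small for any pyramid level to hold blocks
  tiny <- image3D(array(seq_len(12^3) %% 2, c(12, 12, 12)))
  expect_error(registerImages(tiny, tiny, registrationConfig(pyramidLevels = 1L)),
               class = "anisosim_registration_failed")
  ## large enough grid but constant reference: no informative blocks
  flat <- image3D(array(0, c(18, 18, 18)))
  expect_error(registerImages(flat, flat, registrationConfig(pyramidLevels = 1L)),
               class = "anisosim_empty_blocks")
})
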