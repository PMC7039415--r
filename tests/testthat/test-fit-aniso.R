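rotZ <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}
rotX <- function(deg) {
  th <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3, 3, byrow = TRUE)
}

test_that("identity data yields the identity anisotropic similarity", {
  set.seed(41)
  x <- matrix(stats::runif(30, -10, 10), 10, 3)
  fit <- fitAnisotropicSimilarity(pairedPointSet(x, x), rRotation())
  expect_equal(linearPart(fittedTransform(fit)), diag(3), tolerance = 1e-9)
  expect_equal(scalings(decomposition(fit)), c(1, 1, 1), tolerance = 1e-9)
  expect_equal(translationPart(fittedTransform(fit)), c(0, 0, 0), tolerance = 1e-9)
  expect_lt(finalCost(fit), 1e-18)
})

test_that("unit-cube ground truth is recovered exactly", {
  x <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  colnames(x) <- NULL
  U0 <- rotZ(30)
  S0 <- c(1.5, 0.7, 1.1)
  R0 <- rotX(20)
  t0 <- c(5, -3, 2)
  y <- x %*% t(R0 %*% diag(S0) %*% t(U0)) + matrix(t0, 8, 3, byrow = TRUE)
  fit <- fitAnisotropicSimilarity(pairedPointSet(x, y), U0, tol = 1e-14,
                                  maxIter = 300L)
  d <- decomposition(fit)
  expect_lt(max(abs(rotationPart(d) - R0)), 1e-6)
  expect_lt(max(abs(scalings(d) - S0)), 1e-6)
  expect_lt(max(abs(translationPart(fittedTransform(fit)) - t0)), 1e-6)
  expect_lt(finalCost(fit), 1e-12)
})

test_that("axis-aligned stretches reduce to per-axis regression slopes", {
  set.seed(42)
  x <- matrix(stats::runif(36, -5, 5), 12, 3)
  cvec <- c(2, 0.5, 1)
  y <- sweep(x, 2, cvec, `*`)
  fit <- fitAnisotropicSimilarity(pairedPointSet(x, y), diag(3), tol = 1e-14,
                                  maxIter = 300L)
  d <- decomposition(fit)
  ## oracle: 1-D least-squares slope per axis on barycentric coordinates
  xp <- sweep(x, 2, colMeans(x)); yp <- sweep(y, 2, colMeans(y))
  slopes <- colSums(xp * yp) / colSums(xp^2)
  expect_equal(scalings(d), slopes, tolerance = 1e-9)
  expect_equal(rotationPart(d), diag(3), tolerance = 1e-7)
})

test_that("weights act like point multiplicity in all fitters", {
  set.seed(43)
  x <- matrix(stats::runif(24, -10, 10), 8, 3)
  y <- x %*% t(rRotation() %*% diag(c(1.3, 0.9, 1.05))) +
    matrix(stats::rnorm(24, 0, 0.2), 8, 3)
  xd <- rbind(x, x[1, ]); yd <- rbind(y, y[1, ])
  wd <- c(0.5, rep(1, 7), 0.5)
  U <- rRotation()
  fits1 <- list(fitAffine(pairedPointSet(x, y)),
                fitRigid(pairedPointSet(x, y)),
                fitSimilarity(pairedPointSet(x, y)),
                fitAnisotropicSimilarity(pairedPointSet(x, y), U))
  fits2 <- list(fitAffine(pairedPointSet(xd, yd, wd)),
                fitRigid(pairedPointSet(xd, yd, wd)),
                fitSimilarity(pairedPointSet(xd, yd, wd)),
                fitAnisotropicSimilarity(pairedPointSet(xd, yd, wd), U))
  for (k in seq_along(fits1)) {
    expect_equal(linearPart(fittedTransform(fits2[[k]])),
                 linearPart(fittedTransform(fits1[[k]])), tolerance = 1e-10)
    expect_equal(translationPart(fittedTransform(fits2[[k]])),
                 translationPart(fittedTransform(fits1[[k]])), tolerance = 1e-10)
  }
})

test_that("translating both point sets leaves the linear part unchanged", {
  set.seed(44)
  g <- rAnisoTransform(sRange = c(0.7, 1.5))
  x <- matrix(stats::runif(45, -10, 10), 15, 3)
  y <- applyTransform(g$transform, x) + matrix(stats::rnorm(45, 0, 0.1), 15, 3)
  shift <- c(100, -50, 20)
  f1 <- fitAnisotropicSimilarity(pairedPointSet(x, y), g$U)
  f2 <- fitAnisotropicSimilarity(pairedPointSet(sweep(x, 2, shift, `+`),
                                                sweep(y, 2, shift, `+`)), g$U)
  expect_equal(linearPart(fittedTransform(f2)), linearPart(fittedTransform(f1)),
               tolerance = 1e-8)
  A <- linearPart(fittedTransform(f1))
  expect_equal(translationPart(fittedTransform(f2)),
               translationPart(fittedTransform(f1)) + shift - as.numeric(A %*% shift),
               tolerance = 1e-7)
})

test_that("cost is non-increasing across sweeps and nests across dof", {
  set.seed(45)
  for (i in 1:25) {
    g <- rAnisoTransform(sRange = c(0.7, 1.5))
    x <- matrix(stats::runif(60, -20, 20), 20, 3)
    y <- applyTransform(g$transform, x) + matrix(stats::rnorm(60, 0, 0.3), 20, 3)
    pts <- pairedPointSet(x, y)
    fa <- fitAnisotropicSimilarity(pts, g$U)
    expect_true(all(diff(fa@costTrace) <= 1e-12))
    cAff <- finalCost(fitAffine(pts))
    cSim <- finalCost(fitSimilarity(pts))
    cRig <- finalCost(fitRigid(pts))
    expect_lte(cAff, finalCost(fa) + 1e-9)
    expect_lte(finalCost(fa), cSim + 1e-9)
    expect_lte(cSim, cRig + 1e-9)
  }
})

test_that("noiseless random anisotropic similarities are recovered exactly", {
  set.seed(46)
  for (i in 1:30) {
    g <- rAnisoTransform(sRange = c(0.5, 2))
    x <- matrix(stats::runif(60, -50, 50), 20, 3)
    y <- applyTransform(g$transform, x)
    fit <- fitAnisotropicSimilarity(pairedPointSet(x, y), g$U, tol = 1e-14,
                                    maxIter = 300L)
    d <- decomposition(fit)
    expect_lt(max(abs(rotationPart(d) - g$R), abs(scalings(d) - g$S),
                  abs(translationPart(fittedTransform(fit)) - g$t)), 1e-6)
    expect_lt(finalCost(fit), 1e-10)
  }
})

test_that("noisy fits match a multi-start generic optimizer", {
  set.seed(47)
  rotvec2R <- function(r) {
    th <- sqrt(sum(r^2))
    if (th < 1e-12) return(diag(3))
    k <- r / th
    K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3, byrow = TRUE)
    diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  }
  for (i in 1:5) {
    g <- rAnisoTransform(sRange = c(0.7, 1.5), tMax = 10)
    x <- matrix(stats::runif(60, -50, 50), 20, 3)
    y <- applyTransform(g$transform, x) + matrix(stats::rnorm(60, 0, 0.05), 20, 3)
    fit <- fitAnisotropicSimilarity(pairedPointSet(x, y), g$U, tol = 1e-14,
                                    maxIter = 500L)
    obj <- function(p) {
      A <- rotvec2R(p[1:3]) %*% diag(exp(p[4:6])) %*% t(g$U)
      sum((y - sweep(x %*% t(A), 2, p[7:9], `+`))^2)
    }
    best <- Inf
    for (s in 1:20) {
      o <- stats::nlminb(c(stats::rnorm(3), stats::rnorm(3, 0, 0.3),
                           stats::rnorm(3, 0, 5)), obj,
                         control = list(rel.tol = 1e-14, iter.max = 1000,
                                        eval.max = 3000))
      best <- min(best, o$objective)
    }
    expect_lt(abs(finalCost(fit) - best) / best, 1e-6)
  }
})

test_that("degenerate spread and wrong inputs raise informative errors", {
  set.seed(48)
  x <- cbind(0, matrix(stats::runif(20, -5, 5), 10, 2))  # no spread along axis 1
  y <- x
  expect_error(fitAnisotropicSimilarity(pairedPointSet(x, y), diag(3)),
               class = "anisosim_degenerate_direction")
  expect_error(fitAnisotropicSimilarity(pairedPointSet(x, y), diag(3)), "1")
  expect_error(fitTransform(pairedPointSet(y, y), "anisotropic_similarity"),
               class = "anisosim_frame_mismatch")
  expect_error(fitTransform(pairedPointSet(y, y), "projective"),
               class = "anisosim_bad_config")
})
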