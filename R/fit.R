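#' @include AllClasses.R accessors.R quaternion.R transform.R pointset.R
NULL

## ---- shared internals ---------------------------------------------------

## Rank check on the weighted covariance of barycentric reference points.
.checkSpread <- function(xp, w, minRank, what) {
  C <- crossprod(sqrt(w) * xp)
  sv <- svd(C)$d
  rank <- sum(sv > max(sv) * 1e-10)
  if (rank < minRank)
    .asError(sprintf("degenerate point geometry for %s fit (rank %d < %d)",
                     what, rank, minRank), "degenerate_pointset")
}

## Closed-form rotation quaternion minimizing sum w ||y' - R x'||^2.
##
## The criterion in quaternion form is q' B q with
## B = sum_i w_i * ( -(Q_{y'_i} + P_{x'_i})^2 ), and both matricial
## quaternions antisymmetric for pure arguments, so B is symmetric and the
## optimum is the eigenvector of its smallest eigenvalue. B is accumulated
## in closed form via u_i = y'_i - x'_i, v_i = y'_i + x'_i:
##   B = [ sum w |u|^2        sum w (u x v)'            ]
##       [ sum w (u x v)  sum w (uu' - vv' + |v|^2 I_3) ]
.quatB <- function(xp, yp, w) {
  u <- yp - xp
  v <- yp + xp
  sw <- sqrt(w)
  uxv <- colSums(w * .rowCross(u, v))
  B <- matrix(0, 4, 4)
  B[1, 1] <- sum(w * rowSums(u^2))
  B[1, 2:4] <- uxv
  B[2:4, 1] <- uxv
  B[2:4, 2:4] <- crossprod(sw * u) - crossprod(sw * v) + sum(w * rowSums(v^2)) * diag(3)
  B
}

## Smallest-eigenvalue eigenvector of B with continuity tie-breaking.
.minEigvec <- function(B, qPrev = NULL) {
  ee <- eigen(B, symmetric = TRUE)  # eigenvalues descending
  q <- ee$vectors[, 4]
  if (!is.null(qPrev)) {
    gap <- ee$values[3] - ee$values[4]
    if (gap < 1e-10 * max(abs(ee$values)) &&
        abs(sum(ee$vectors[, 3] * qPrev)) > abs(sum(q * qPrev)))
      q <- ee$vectors[, 3]
    if (sum(q * qPrev) < 0) q <- -q
  }
  q
}

.rigidQuat <- function(xp, yp, w, qPrev = NULL) .minEigvec(.quatB(xp, yp, w), qPrev)

.makeReport <- function(A, pts, kind, cost = NULL, decomposition = NULL,
                        nIterations = 1L, converged = TRUE, costTrace = numeric(0)) {
  t <- optimalTranslation(A, pts)
  tr <- linearTransform3D(A, t)
  if (is.null(cost)) cost <- transformCost(pts, tr)
  if (!is.null(decomposition)) decomposition@t <- t
  new("FitReport", transform = tr, decomposition = decomposition,
      finalCost = max(cost, 0), nIterations = as.integer(nIterations),
      converged = converged, costTrace = costTrace, kind = kind)
}

## ---- closed-form fitters ------------------------------------------------

#' Closed-form weighted least-squares transform fits
#'
#' Estimate the affine (12 dof), rigid (6 dof) or similarity (7 dof)
#' transform minimizing \eqn{\sum_i w_i \|y_i - (A x_i + t)\|^2} over paired
#' points. The affine solution is the normal-equations solution on
#' barycentric coordinates; rigid and similarity use the unit-quaternion
#' closed form (smallest eigenvalue of the 4x4 criterion matrix), the
#' similarity adding the closed-form single scale. The translation is always
#' \eqn{\bar y - A \bar x}.
#'
#' @param pts a [PairedPointSet-class].
#' @return a [FitReport-class].
#' @export
fitAffine <- function(pts) {
  b <- .barycentric(pts)
  .checkSpread(b$xp, b$w, 3, "affine")
  Cxx <- crossprod(sqrt(b$w) * b$xp)
  Cyx <- crossprod(b$yp * b$w, b$xp)   # sum w y' x''
  A <- Cyx %*% solve(Cxx)
  .makeReport(A, pts, "affine")
}

#' @rdname fitAffine
#' @export
fitRigid <- function(pts) {
  b <- .barycentric(pts)
  .checkSpread(b$xp, b$w, 2, "rigid")
  q <- .canonicalQuat(.rigidQuat(b$xp, b$yp, b$w))
  R <- quatToRotation(q)
  dec <- new("AnisoSimDecomposition", R = R, S = c(1, 1, 1), U = scalingFrame(diag(3)))
  .makeReport(R, pts, "rigid", decomposition = dec)
}

#' @rdname fitAffine
#' @export
fitSimilarity <- function(pts) {
  b <- .barycentric(pts)
  .checkSpread(b$xp, b$w, 2, "similarity")
  q <- .canonicalQuat(.rigidQuat(b$xp, b$yp, b$w))
  R <- quatToRotation(q)
  s <- sum(b$w * rowSums(b$yp * (b$xp %*% t(R)))) / sum(b$w * rowSums(b$xp^2))
  if (s <= 0) .asError("non-positive similarity scale", "ill_posed_fit")
  dec <- new("AnisoSimDecomposition", R = R, S = rep(s, 3), U = scalingFrame(diag(3)))
  .makeReport(s * R, pts, "similarity", decomposition = dec)
}

## ---- anisotropic similarity: alternating quaternion optimization --------

#' Optimal anisotropic similarity between paired point sets
#'
#' Finds the transform `A = R diag(S) U'`, with the scaling frame `U` fixed,
#' minimizing the weighted least-squares criterion over paired points. There
#' is no joint closed form, but each block has one, giving an alternating
#' scheme on barycentric coordinates (`xt = U' x'`, `xi = diag(S) xt`):
#'
#' 1. Rotation step (S fixed): the criterion is the quadratic form
#'    `q' B q` with `B = sum_i w_i (-(Q_{y'_i} + P_{xi_i})^2)`; the optimal
#'    unit quaternion is the eigenvector of B's smallest eigenvalue.
#' 2. Scaling step (q fixed): each scaling has the closed form
#'    `s_j = q' (sum_i w_i Q_{y'_i} dP_{xi_i}/ds_j) q / sum_i w_i xt_ji^2`,
#'    where the derivative matrices are the sparse patterns of
#'    [scalingDerivativeMatrices()]. By linearity of Q in its argument the
#'    numerator collapses to `q' Q_{z_j} E_j q` with
#'    `z_j = sum_i w_i xt_ji y'_i`.
#' 3. Translation: closed form from the barycentres, [optimalTranslation()].
#'
#' Both steps solve their subproblem exactly, so the criterion is
#' non-increasing across sweeps (coordinate descent). Iteration stops when
#' the relative cost decrease falls below `tol`, the cost reaches the
#' numerical floor, or `maxIter` sweeps are exhausted. The rotation update is
#' performed first in each sweep; near-degenerate smallest eigenvalues are
#' tie-broken toward the previous quaternion for continuity.
#'
#' @param pts a [PairedPointSet-class] (at least 4 pairs with spread along
#'   every scaling direction).
#' @param U a [ScalingFrame-class] or 3x3 rotation matrix: the fixed scaling
#'   directions. Scalings are reported in the column order of `U`.
#' @param tol relative cost-change stopping tolerance.
#' @param maxIter maximum number of alternating sweeps.
#' @param sInit initial scalings (default identity; the registration engine
#'   warm-starts from the preceding similarity).
#' @param qInit optional initial rotation quaternion for `R` (a
#'   [UnitQuaternion-class] or length-4 numeric). Default: the closed-form
#'   rigid rotation composed with `U`, so the first sweep starts at the best
#'   rigid alignment.
#' @return a [FitReport-class] whose decomposition carries R, S, U, t; its
#'   `costTrace` holds the criterion value after every sweep.
#' @examples
#' set.seed(1)
#' x <- matrix(runif(60, -50, 50), 20, 3)
#' U <- quatToRotation(unitQuaternion(c(1, 2, 0.5, -1)))
#' A <- quatToRotation(unitQuaternion(c(4, 1, 0, 1))) %*% diag(c(1.3, 0.8, 1.1)) %*% t(U)
#' y <- x %*% t(A) + 5
#' fit <- fitAnisotropicSimilarity(pairedPointSet(x, y), U)
#' scalings(decomposition(fit))
#' @export
fitAnisotropicSimilarity <- function(pts, U, tol = 1e-8, maxIter = 100L,
                                     sInit = c(1, 1, 1), qInit = NULL) {
  frame <- if (is(U, "ScalingFrame")) U else scalingFrame(U)
  Um <- frame@U
  b <- .barycentric(pts)
  w <- b$w
  xt <- b$xp %*% Um                     # rows: xt_i = U' x'_i
  denom <- colSums(w * xt^2)
  scale2 <- sum(w * rowSums(b$yp^2))
  bad <- which(denom <= 1e-12 * max(sum(denom), 1e-300))
  if (length(bad))
    .asError(paste0("no spread along scaling direction(s) ",
                    paste(bad, collapse = ", ")), "degenerate_direction")

  S <- as.numeric(sInit)
  if (is.null(qInit)) {
    q <- .rigidQuat(b$xp, b$yp, w)
    q <- rotationToQuat(quatToRotation(q) %*% Um)@q
  } else {
    q <- if (is(qInit, "UnitQuaternion")) qInit@q else qInit / sqrt(sum(qInit^2))
  }

  ## z_j = sum_i w_i xt_ji y'_i; fixed across sweeps
  z <- lapply(1:3, function(j) colSums(w * xt[, j] * b$yp))
  Qz <- lapply(z, function(zj) quatMatrices(c(0, zj))$Q)

  costOf <- function(q, S) {
    R <- quatToRotation(q)
    res <- b$yp - xt %*% (diag(S) %*% t(R))
    sum(w * rowSums(res^2))
  }

  trace <- numeric(0)
  cPrev <- Inf
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    xi <- sweep(xt, 2, S, `*`)
    q <- .minEigvec(.quatB(xi, b$yp, w), q)
    for (j in 1:3) {
      S[j] <- as.numeric(t(q) %*% Qz[[j]] %*% .PE[[j]] %*% q) / denom[j]
      if (!is.finite(S[j]) || S[j] <= 0)
        .asError(sprintf("ill-posed fit: non-positive scaling s_%d", j), "ill_posed_fit")
    }
    cc <- costOf(q, S)
    trace <- c(trace, cc)
    if (cc <= 1e-24 * scale2 || (is.finite(cPrev) && (cPrev - cc) <= tol * cPrev)) {
      converged <- TRUE
      break
    }
    cPrev <- cc
  }

  q <- .canonicalQuat(q)
  R <- quatToRotation(q)
  A <- R %*% diag(S) %*% t(Um)
  dec <- new("AnisoSimDecomposition", R = R, S = S, U = frame)
  .makeReport(A, pts, "anisotropic_similarity", cost = trace[length(trace)],
              decomposition = dec, nIterations = it, converged = converged,
              costTrace = trace)
}

#' Fit a transform of a requested kind
#'
#' Dispatcher used by the registration engine.
#'
#' @param pts a [PairedPointSet-class].
#' @param kind "rigid", "similarity", "affine" or "anisotropic_similarity".
#' @param frame scaling frame (required for the anisotropic kind).
#' @param ... passed to [fitAnisotropicSimilarity()].
#' @export
fitTransform <- function(pts, kind, frame = NULL, ...) {
  switch(kind,
    rigid = fitRigid(pts),
    similarity = fitSimilarity(pts),
    affine = fitAffine(pts),
    anisotropic_similarity = {
      if (is.null(frame))
        .asError("anisotropic similarity requires a scaling frame", "frame_mismatch")
      fitAnisotropicSimilarity(pts, frame, ...)
    },
    .asError(paste("unknown transform kind:", kind), "bad_config"))
}
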