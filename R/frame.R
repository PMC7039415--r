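#' @include AllClasses.R accessors.R blockmatch.R
NULL

## World-space reflection implied by flipping the voxel array along axis 1.
.gridFlipWorld <- function(img) {
  d <- dim(img@data)
  Fv <- diag(c(-1, 1, 1))
  tv <- c(d[1] - 1, 0, 0)
  A <- img@affine[1:3, 1:3]
  b <- img@affine[1:3, 4]
  lin <- A %*% Fv %*% solve(A)
  linearTransform3D(lin, as.numeric(A %*% tv + b - lin %*% b))
}

## Grid mid-plane fallback: normal along the first voxel axis, through the
## world-space grid centre.
.gridMidPlane <- function(img) {
  n <- img@affine[1:3, 1]
  n <- n / sqrt(sum(n^2))
  lead <- which(abs(n) > 1e-9)[1]
  if (!is.na(lead) && n[lead] < 0) n <- -n
  d <- dim(img@data)
  p <- as.numeric(voxelToWorld(img, matrix((d - 1) / 2, 1)))
  new("PlaneSpec", normal = n, point = p)
}

#' Estimate the mid-sagittal plane by symmetry registration
#'
#' Rigidly registers the image onto its left-right mirror; the composition of
#' the mirror reflection with the fitted rigid transform is then an
#' approximate world-space reflection whose fixed plane is the symmetry
#' plane. The normal is read off the eigenvector of the symmetric part of the
#' composed linear map whose eigenvalue is closest to -1, and a point on the
#' plane solves the fixed-point equation in the least-squares sense. When the
#' composed map is not reflection-like (asymmetric input, failed
#' registration), the grid mid-plane is returned with a warning.
#'
#' This symmetry-registration estimate is a self-contained substitute for
#' dedicated mid-sagittal extraction algorithms; for strongly asymmetric
#' anatomy a dedicated method should be preferred.
#'
#' @param img an [Image3D-class], roughly bilaterally symmetric, with the
#'   left-right axis along the first voxel axis.
#' @param cfg registration configuration for the symmetry fit.
#' @return a [PlaneSpec-class].
#' @export
estimateMidsagittalPlane <- function(img,
                                     cfg = registrationConfig(kind = "rigid",
                                                              pyramidLevels = 2L)) {
  mirrored <- image3D(img@data[dim(img@data)[1]:1, , , drop = FALSE], img@affine,
                      mask = img@mask)
  flipW <- .gridFlipWorld(img)
  fit <- tryCatch(registerImages(img, mirrored, cfg), error = function(e) NULL)
  if (is.null(fit)) {
    warning("symmetry registration failed; falling back to the grid mid-plane")
    return(.gridMidPlane(img))
  }
  M <- composeTransforms(flipW, fit@transform)
  sym <- (M@matrix + t(M@matrix)) / 2
  ee <- eigen(sym, symmetric = TRUE)
  i <- which.min(abs(ee$values + 1))
  if (ee$values[i] > -0.5 || abs(det(M@matrix) + 1) > 0.5) {
    warning("composed map is not reflection-like; falling back to the grid mid-plane")
    return(.gridMidPlane(img))
  }
  n <- ee$vectors[, i]
  lead <- which(abs(n) > 1e-9)[1]
  if (!is.na(lead) && n[lead] < 0) n <- -n
  ## fixed points: (I - M) p = t, solved by pseudo-inverse (rank ~ 1)
  K <- diag(3) - M@matrix
  sv <- svd(K)
  pos <- sv$d > max(sv$d) * 1e-6
  p <- sv$v[, pos, drop = FALSE] %*% ((t(sv$u[, pos, drop = FALSE]) %*%
                                         M@translation) / sv$d[pos])
  new("PlaneSpec", normal = n / sqrt(sum(n^2)), point = as.numeric(p))
}

#' Scaling frame from a plane normal and in-plane principal components
#'
#' Column 1 is the plane normal (mid-sagittal normal in the intended use).
#' Columns 2 and 3 are the leading and secondary eigenvectors of the
#' covariance of the nonzero-voxel world coordinates projected onto the
#' plane: the principal in-plane extents of the object. Signs are fixed so
#' results are reproducible across runs: column 1 has nonnegative dot product
#' with world +x, column 2 with world +y, and column 3 completes a
#' right-handed frame (det +1).
#'
#' @param img an [Image3D-class]; its mask (if present) or nonzero voxels
#'   define the object.
#' @param plane a [PlaneSpec-class].
#' @param gapTol minimum relative gap between the two in-plane eigenvalues;
#'   below it the in-plane directions are ambiguous (e.g. a sphere) and an
#'   error is raised.
#' @return a [ScalingFrame-class].
#' @export
computeScalingFrame <- function(img, plane, gapTol = 0.01) {
  obj <- if (!is.null(img@mask)) img@mask != 0 else img@data != 0
  idx <- which(obj)
  if (length(idx) < 2) .asError("fewer than 2 nonzero voxels", "ambiguous_frame")
  d <- dim(img@data)
  vox <- cbind((idx - 1) %% d[1],
               ((idx - 1) %/% d[1]) %% d[2],
               (idx - 1) %/% (d[1] * d[2]))
  world <- voxelToWorld(img, vox)
  n <- plane@normal
  centred <- sweep(world, 2, colMeans(world))
  proj <- centred - outer(as.numeric(centred %*% n), n)
  C <- crossprod(proj) / nrow(proj)
  ee <- eigen(C, symmetric = TRUE)
  l <- ee$values  # descending; third ~ 0 (out-of-plane)
  if (l[1] <= 0 || (l[1] - l[2]) < gapTol * l[1])
    .asError("in-plane covariance is (near-)isotropic: frame is ambiguous",
             "ambiguous_frame")
  e1 <- ee$vectors[, 1]
  ## orthogonalize against the normal to guard against numerical leakage
  e1 <- e1 - sum(e1 * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  fixSign <- function(v, axis) {
    if (v[axis] < -1e-9) return(-v)
    if (abs(v[axis]) <= 1e-9) {
      lead <- which(abs(v) > 1e-9)[1]
      if (!is.na(lead) && v[lead] < 0) return(-v)
    }
    v
  }
  u1 <- fixSign(n / sqrt(sum(n^2)), 1L)
  e1 <- fixSign(e1, 2L)
  e2 <- .cross3(u1, e1)
  scalingFrame(cbind(u1, e1, e2))
}
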