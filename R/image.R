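#' @include AllClasses.R accessors.R transform.R
NULL

#' Read / write NIfTI images
#'
#' Thin wrappers over RNifti keeping the package's [Image3D-class] container:
#' the voxel array plus the NIfTI sform/qform voxel-to-world affine (0-based
#' voxel indices, world mm).
#'
#' @param path image file (.nii or .nii.gz).
#' @param maskPath optional mask image on the same grid.
#' @param img an [Image3D-class].
#' @export
readImage <- function(path, maskPath = NULL) {
  nim <- RNifti::readNifti(path)
  aff <- matrix(as.numeric(RNifti::xform(nim)), 4, 4)  # strip RNifti attributes
  data <- array(as.numeric(nim), dim = dim(nim)[1:3])
  mask <- NULL
  if (!is.null(maskPath)) {
    mnim <- RNifti::readNifti(maskPath)
    mask <- array(as.numeric(mnim) != 0, dim = dim(mnim)[1:3])
  }
  image3D(data, aff, mask = mask)
}

#' @rdname readImage
#' @export
writeImage <- function(img, path) {
  nim <- RNifti::asNifti(img@data)
  RNifti::pixdim(nim) <- sqrt(colSums(img@affine[1:3, 1:3]^2))
  RNifti::qform(nim) <- structure(img@affine, code = 2L)
  RNifti::sform(nim) <- structure(img@affine, code = 2L)
  RNifti::writeNifti(nim, path)
  invisible(path)
}

## 0-based voxel index grid of an image, as an N x 3 matrix (column-major
## voxel order, matching as.vector of the data array).
.voxelGrid <- function(d) {
  cbind(rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
        rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
        rep(seq_len(d[3]) - 1L, each = d[1] * d[2]))
}

#' Voxel/world coordinate conversion
#'
#' @param img an [Image3D-class].
#' @param vox N x 3 matrix of 0-based voxel indices.
#' @param world N x 3 matrix of world coordinates (mm).
#' @export
voxelToWorld <- function(img, vox) {
  sweep(vox %*% t(img@affine[1:3, 1:3]), 2, img@affine[1:3, 4], `+`)
}

#' @rdname voxelToWorld
#' @export
worldToVoxel <- function(img, world) {
  Ainv <- solve(img@affine[1:3, 1:3])
  sweep(world, 2, img@affine[1:3, 4]) %*% t(Ainv)
}

#' Trilinear interpolation at continuous voxel coordinates
#'
#' Coordinates outside the volume return `outside` (default 0).
#' @noRd
.interpTrilinear <- function(data, coords, outside = 0) {
  d <- dim(data)
  f <- floor(coords)
  r <- coords - f
  ## allow exact upper-boundary points
  hi <- f[, 1] == d[1] - 1L & r[, 1] == 0
  f[hi, 1] <- d[1] - 2L; r[hi, 1] <- 1
  hi <- f[, 2] == d[2] - 1L & r[, 2] == 0
  f[hi, 2] <- d[2] - 2L; r[hi, 2] <- 1
  hi <- f[, 3] == d[3] - 1L & r[, 3] == 0
  f[hi, 3] <- d[3] - 2L; r[hi, 3] <- 1
  inside <- f[, 1] >= 0 & f[, 2] >= 0 & f[, 3] >= 0 &
    f[, 1] <= d[1] - 2L & f[, 2] <= d[2] - 2L & f[, 3] <= d[3] - 2L
  out <- rep(outside, nrow(coords))
  if (!any(inside)) return(out)
  fi <- f[inside, , drop = FALSE]
  ri <- r[inside, , drop = FALSE]
  base <- fi[, 1] + d[1] * (fi[, 2] + d[2] * fi[, 3]) + 1
  v000 <- data[base];                 v100 <- data[base + 1]
  v010 <- data[base + d[1]];          v110 <- data[base + d[1] + 1]
  off <- d[1] * d[2]
  v001 <- data[base + off];           v101 <- data[base + off + 1]
  v011 <- data[base + off + d[1]];    v111 <- data[base + off + d[1] + 1]
  rx <- ri[, 1]; ry <- ri[, 2]; rz <- ri[, 3]
  c00 <- v000 * (1 - rx) + v100 * rx
  c10 <- v010 * (1 - rx) + v110 * rx
  c01 <- v001 * (1 - rx) + v101 * rx
  c11 <- v011 * (1 - rx) + v111 * rx
  c0 <- c00 * (1 - ry) + c10 * ry
  c1 <- c01 * (1 - ry) + c11 * ry
  out[inside] <- c0 * (1 - rz) + c1 * rz
  out
}

#' Resample an image through a transform (backward mapping)
#'
#' For each voxel of the reference grid, the world coordinate is mapped
#' through `transform` into moving space and the moving image is sampled by
#' trilinear interpolation; coordinates falling outside the moving volume get
#' 0. This is the backward mapping convention: `transform` maps
#' reference-space coordinates to moving-space coordinates.
#'
#' @param mov the moving [Image3D-class].
#' @param transform a [LinearTransform3D-class] (reference -> moving).
#' @param refGrid an [Image3D-class] supplying the output grid (data unused).
#' @return an [Image3D-class] on the reference grid.
#' @export
resampleImage <- function(mov, transform, refGrid) {
  .checkInvertible(transform@matrix)
  d <- dim(refGrid@data)
  vox <- .voxelGrid(d)
  world <- voxelToWorld(refGrid, vox)
  movWorld <- applyTransform(transform, world)
  movVox <- worldToVoxel(mov, movWorld)
  vals <- .interpTrilinear(mov@data, movVox)
  image3D(array(vals, dim = d), refGrid@affine)
}

## Separable Gaussian smoothing by shifted-array accumulation (zero padding
## with kernel renormalization at the borders).
.smooth3D <- function(a, sigma) {
  r <- max(1L, ceiling(2.5 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(a)
  for (ax in 1:3) {
    out <- array(0, d)
    norm <- array(0, d)
    n <- d[ax]
    for (i in seq(-r, r)) {
      src <- seq_len(n) - i
      ok <- src >= 1 & src <= n
      di <- which(ok)
      si <- src[ok]
      w <- k[i + r + 1]
      if (ax == 1) {
        out[di, , ] <- out[di, , ] + w * a[si, , ]
        norm[di, , ] <- norm[di, , ] + w
      } else if (ax == 2) {
        out[, di, ] <- out[, di, ] + w * a[, si, ]
        norm[, di, ] <- norm[, di, ] + w
      } else {
        out[, , di] <- out[, , di] + w * a[, , si]
        norm[, , di] <- norm[, , di] + w
      }
    }
    a <- out / norm
  }
  a
}

#' Downsample an image by an integer factor
#'
#' The image is anti-alias smoothed with a separable Gaussian of standard
#' deviation `factor/2` voxels, then blocks of `factor^3` voxels are
#' averaged; trailing voxels that do not fill a block are dropped. The affine
#' is adjusted so that world coordinates of the box centres are preserved.
#' Masks are pooled (without smoothing) and thresholded at 0.5.
#'
#' @param img an [Image3D-class].
#' @param factor positive integer.
#' @export
downsampleImage <- function(img, factor) {
  factor <- as.integer(factor)
  if (factor == 1L) return(img)
  d <- dim(img@data)
  nd <- d %/% factor
  if (any(nd < 2)) .asError("image too small to downsample", "bad_config")
  pool <- function(a) {
    a <- a[seq_len(nd[1] * factor), seq_len(nd[2] * factor), seq_len(nd[3] * factor)]
    out <- array(0, nd)
    for (i in seq_len(factor) - 1L)
      for (j in seq_len(factor) - 1L)
        for (k in seq_len(factor) - 1L)
          out <- out + a[seq(1 + i, by = factor, length.out = nd[1]),
                         seq(1 + j, by = factor, length.out = nd[2]),
                         seq(1 + k, by = factor, length.out = nd[3])]
    out / factor^3
  }
  scale <- diag(c(factor, factor, factor, 1))
  scale[1:3, 4] <- (factor - 1) / 2
  aff <- img@affine %*% scale
  mask <- img@mask
  if (!is.null(mask)) mask <- pool(mask * 1) > 0.5
  image3D(pool(.smooth3D(img@data, factor / 2)), aff, mask = mask)
}
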