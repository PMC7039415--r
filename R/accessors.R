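#' @include AllGenerics.R
NULL

#' Construct a LinearTransform3D
#'
#' @param matrix 3x3 linear part.
#' @param translation length-3 translation in mm.
#' @return a [LinearTransform3D-class].
#' @examples
#' linearTransform3D(diag(3) * 2, c(1, 0, 0))
#' @export
linearTransform3D <- function(matrix = diag(3), translation = c(0, 0, 0)) {
  new("LinearTransform3D", matrix = unname(matrix), translation = as.numeric(translation))
}

#' The identity transform
#' @export
identityTransform <- function() linearTransform3D()

#' Construct a ScalingFrame
#'
#' @param U 3x3 rotation matrix whose columns are the scaling directions.
#' @export
scalingFrame <- function(U) new("ScalingFrame", U = unname(U))

#' Construct a PairedPointSet
#'
#' @param x,y M x 3 matrices of homologous world coordinates (mm).
#' @param w optional nonnegative weights (default all 1).
#' @export
pairedPointSet <- function(x, y, w = rep(1, nrow(x))) {
  new("PairedPointSet", x = unname(as.matrix(x)), y = unname(as.matrix(y)),
      w = as.numeric(w))
}

#' Construct an Image3D
#'
#' @param data 3D numeric array of voxel intensities.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices, mm). The
#'   default places the grid centre at the world origin with the given
#'   `spacing`.
#' @param mask optional mask array on the same grid.
#' @param spacing voxel spacing used when `affine` is missing.
#' @export
image3D <- function(data, affine = NULL, mask = NULL, spacing = c(1, 1, 1)) {
  if (is.null(affine)) {
    d <- dim(data)
    affine <- diag(c(spacing, 1))
    affine[1:3, 4] <- -spacing * (d - 1) / 2
  }
  new("Image3D", data = data, affine = unname(affine), mask = mask)
}

setMethod("linearPart", "LinearTransform3D", function(x) x@matrix)
setMethod("translationPart", "LinearTransform3D", function(x) x@translation)
setMethod("linearPart", "AnisoSimDecomposition",
          function(x) x@R %*% diag(x@S) %*% t(x@U@U))
setMethod("translationPart", "AnisoSimDecomposition", function(x) x@t)
setMethod("rotationPart", "AnisoSimDecomposition", function(x) x@R)
setMethod("scalings", "AnisoSimDecomposition", function(x) x@S)
setMethod("frameMatrix", "AnisoSimDecomposition", function(x) x@U@U)
setMethod("frameMatrix", "ScalingFrame", function(x) x@U)

setMethod("refPoints", "PairedPointSet", function(x) x@x)
setMethod("movPoints", "PairedPointSet", function(x) x@y)
setMethod("pointWeights", "PairedPointSet", function(x) x@w)

setMethod("imageData", "Image3D", function(x) x@data)
setMethod("imageAffine", "Image3D", function(x) x@affine)
setMethod("imageMask", "Image3D", function(x) x@mask)
setMethod("voxelSpacing", "Image3D", function(x) sqrt(colSums(x@affine[1:3, 1:3]^2)))

setMethod("fittedTransform", "FitReport", function(x) x@transform)
setMethod("finalCost", "FitReport", function(x) x@finalCost)
setMethod("decomposition", "FitReport", function(x) x@decomposition)
setMethod("modelFamily", "GrowthFitResult", function(x) x@family)

setMethod("applyTransform", "LinearTransform3D", function(transform, points) {
  if (is.null(dim(points))) {
    as.numeric(transform@matrix %*% points + transform@translation)
  } else {
    sweep(points %*% t(transform@matrix), 2, transform@translation, `+`)
  }
})

setMethod("show", "LinearTransform3D", function(object) {
  cat("LinearTransform3D (world mm)\n")
  m <- cbind(object@matrix, object@translation)
  colnames(m) <- c("A.1", "A.2", "A.3", "t")
  print(round(m, 6))
})

setMethod("show", "AnisoSimDecomposition", function(object) {
  cat("AnisoSimDecomposition: A = R diag(S) U' + t\n")
  cat("  scalings S:", paste(signif(object@S, 6), collapse = ", "), "\n")
  cat("  translation:", paste(signif(object@t, 6), collapse = ", "), "mm\n")
})

setMethod("show", "PairedPointSet", function(object) {
  cat(class(object), "with", nrow(object@x), "pairs;",
      "total weight", signif(sum(object@w), 6), "\n")
})

setMethod("show", "Image3D", function(object) {
  cat("Image3D", paste(dim(object@data), collapse = " x "),
      "voxels; spacing", paste(signif(voxelSpacing(object), 4), collapse = " x "), "mm",
      if (!is.null(object@mask)) sprintf("; mask (%d voxels)", sum(object@mask != 0)) else "",
      "\n")
})

setMethod("show", "FitReport", function(object) {
  cat("FitReport [", object@kind, "]: cost =", signif(object@finalCost, 6),
      "mm^2 after", object@nIterations, "iteration(s);",
      if (object@converged) "converged" else "NOT converged", "\n")
})

setMethod("show", "GrowthFitResult", function(object) {
  cat("GrowthFitResult [", object@family, "] n =", object@n, "\n")
  print(signif(object@coefficients, 6))
  cat("  MSE =", signif(object@mse, 6), " AICc =", signif(object@aicc, 6),
      if (!is.na(object@akaikeWeight)) paste(" w_AIC =", signif(object@akaikeWeight, 4)) else "",
      "\n")
})

setMethod("show", "PlaneSpec", function(object) {
  cat("PlaneSpec: normal =", paste(signif(object@normal, 4), collapse = ", "),
      "; point =", paste(signif(object@point, 4), collapse = ", "), "mm\n")
})
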