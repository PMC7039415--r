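#' @include AllClasses.R
NULL

#' @describeIn LinearTransform3D-class the 3x3 linear part.
#' @param x an object.
#' @export
setGeneric("linearPart", function(x) standardGeneric("linearPart"))

#' @describeIn LinearTransform3D-class the translation part (mm).
#' @export
setGeneric("translationPart", function(x) standardGeneric("translationPart"))

#' @describeIn AnisoSimDecomposition-class the rotation factor R.
#' @export
setGeneric("rotationPart", function(x) standardGeneric("rotationPart"))

#' @describeIn AnisoSimDecomposition-class the three scaling factors.
#' @export
setGeneric("scalings", function(x) standardGeneric("scalings"))

#' @describeIn ScalingFrame-class the frame as a plain 3x3 matrix.
#' @export
setGeneric("frameMatrix", function(x) standardGeneric("frameMatrix"))

#' Apply a transform to points
#'
#' @param transform a [LinearTransform3D-class].
#' @param points an N x 3 matrix (or length-3 vector) of world coordinates.
#' @return transformed coordinates, same shape as the input.
#' @export
setGeneric("applyTransform", function(transform, points) standardGeneric("applyTransform"))

#' @describeIn PairedPointSet-class reference-space points.
#' @param x an object.
#' @export
setGeneric("refPoints", function(x) standardGeneric("refPoints"))

#' @describeIn PairedPointSet-class moving-space points.
#' @export
setGeneric("movPoints", function(x) standardGeneric("movPoints"))

#' @describeIn PairedPointSet-class per-pair weights.
#' @export
setGeneric("pointWeights", function(x) standardGeneric("pointWeights"))

#' @describeIn Image3D-class voxel array.
#' @param x an object.
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))

#' @describeIn Image3D-class 4x4 voxel-to-world affine.
#' @export
setGeneric("imageAffine", function(x) standardGeneric("imageAffine"))

#' @describeIn Image3D-class the optional mask array (or NULL).
#' @export
setGeneric("imageMask", function(x) standardGeneric("imageMask"))

#' @describeIn Image3D-class voxel spacing along the three axes (mm).
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @describeIn FitReport-class the fitted transform.
#' @param x an object.
#' @export
setGeneric("fittedTransform", function(x) standardGeneric("fittedTransform"))

#' @describeIn FitReport-class final weighted least-squares cost (mm^2).
#' @export
setGeneric("finalCost", function(x) standardGeneric("finalCost"))

#' @describeIn FitReport-class the constrained decomposition (or NULL).
#' @export
setGeneric("decomposition", function(x) standardGeneric("decomposition"))

#' @describeIn GrowthFitResult-class model family name.
#' @param x an object.
#' @export
setGeneric("modelFamily", function(x) standardGeneric("modelFamily"))

#' Predict from a fitted growth model
#'
#' @param fit a [GrowthFitResult-class].
#' @param ages numeric ages (years) at which to evaluate the fitted curve.
#' @export
setGeneric("predictGrowth", function(fit, ages) standardGeneric("predictGrowth"))
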