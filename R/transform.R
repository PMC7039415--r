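#' @include AllClasses.R accessors.R
NULL

.checkInvertible <- function(A, what = "transform") {
  if (!.isSquare3(A) || !all(is.finite(A)))
    .asError("linear part must be a finite 3x3 matrix", "degenerate_transform")
  d <- det(A)
  if (abs(d) <= 1e-12)
    .asError(sprintf("%s is singular (|det| = %.3g)", what, abs(d)), "degenerate_transform")
  d
}

#' Decompose an invertible linear map into rotation, scalings and frame
#'
#' Computes the SVD `A = V D W'` and returns the modified decomposition
#' `A = R diag(S) U'` with `R = V det(V)`, `U = W det(W)` and
#' `S = det(V) det(W) D`, so that both `R` and `U` are proper rotations.
#' Singular values are kept in the SVD's descending order; when scalings are
#' needed in a caller-fixed frame use [scalingsInFrame()] instead, which never
#' re-orders the caller's columns.
#'
#' Reflections (det(A) < 0) are rejected: positive scalings are an invariant
#' of the decomposition, and image registration of anatomy never produces
#' them.
#'
#' @param A invertible 3x3 matrix with det(A) > 0.
#' @param t optional translation carried into the result (default 0).
#' @return an [AnisoSimDecomposition-class].
#' @examples
#' d <- decomposeAffine(diag(c(2, 3, 4)))
#' scalings(d)  # 4 3 2, descending
#' @export
decomposeAffine <- function(A, t = c(0, 0, 0)) {
  d <- .checkInvertible(A)
  if (d < 0)
    .asError("reflections (det(A) < 0) are not supported", "degenerate_transform")
  sv <- svd(A)
  dV <- det(sv$u); dW <- det(sv$v)
  R <- sv$u * dV
  U <- sv$v * dW
  S <- dV * dW * sv$d
  new("AnisoSimDecomposition", R = R, S = S, U = scalingFrame(U), t = as.numeric(t))
}

#' Scaling factors of an anisotropic similarity in a fixed frame
#'
#' For a matrix of the form `A = R diag(S) U'` with `U` known, the scalings
#' are the column norms of `A U` and the rotation is `A U diag(1/S)`. Errors
#' if `A` is not an anisotropic similarity with respect to `U` (the recovered
#' `R` fails orthonormality beyond `tol`).
#'
#' Unlike [decomposeAffine()], the scalings are reported in the caller's
#' column order, which is what the registration pipeline consumes.
#'
#' @param A invertible 3x3 matrix.
#' @param U a [ScalingFrame-class] or 3x3 rotation matrix.
#' @param t optional translation carried into the result.
#' @param tol tolerance on the orthonormality defect of the recovered R.
#' @return an [AnisoSimDecomposition-class] with the caller's U.
#' @export
scalingsInFrame <- function(A, U, t = c(0, 0, 0), tol = 1e-6) {
  .checkInvertible(A)
  if (is(U, "ScalingFrame")) U <- U@U
  frame <- scalingFrame(U)  # validates
  AU <- A %*% U
  S <- sqrt(colSums(AU^2))
  R <- AU %*% diag(1 / S)
  if (max(abs(crossprod(R) - diag(3))) > tol || det(R) < 0)
    .asError("matrix is not an anisotropic similarity in the given frame", "frame_mismatch")
  ## re-orthonormalize R so downstream validity (1e-10) holds despite tol
  svR <- svd(R)
  R <- svR$u %*% t(svR$v)
  new("AnisoSimDecomposition", R = R, S = S, U = frame, t = as.numeric(t))
}

#' Nearest similarity of an affine transform
#'
#' Projects the linear part onto similarity transforms: with the SVD
#' `A = V D W'`, the projection is `B = dbar V W'` where `dbar` is the mean
#' singular value; the translation is re-derived from the weighted
#' barycentres as `t = ybar - B xbar`. Used to turn the whole-brain affine of
#' the first registration step into the similarity that initializes the
#' anisotropic step.
#'
#' @param transform a [LinearTransform3D-class] (or 3x3 matrix).
#' @param xbar,ybar barycentres of the reference and moving point sets (mm).
#' @return a [LinearTransform3D-class] with `B'B = dbar^2 I`.
#' @export
nearestSimilarity <- function(transform, xbar = c(0, 0, 0), ybar = c(0, 0, 0)) {
  A <- if (is(transform, "LinearTransform3D")) transform@matrix else transform
  .checkInvertible(A)
  sv <- svd(A)
  dbar <- mean(sv$d)
  B <- dbar * sv$u %*% t(sv$v)
  linearTransform3D(B, as.numeric(ybar - B %*% xbar))
}

#' Compose two transforms
#'
#' Returns the transform mapping `x` to `outer(inner(x))`. Composing a
#' similarity (outer) with an anisotropic similarity of frame U (inner)
#' yields an anisotropic similarity with the same frame and per-direction
#' scalings multiplied by the similarity's scale.
#'
#' @param outer,inner [LinearTransform3D-class] objects.
#' @export
composeTransforms <- function(outer, inner) {
  linearTransform3D(outer@matrix %*% inner@matrix,
                    as.numeric(outer@matrix %*% inner@translation + outer@translation))
}

#' Invert a transform
#' @param transform a [LinearTransform3D-class].
#' @export
invertTransform <- function(transform) {
  .checkInvertible(transform@matrix)
  Ainv <- solve(transform@matrix)
  linearTransform3D(Ainv, as.numeric(-Ainv %*% transform@translation))
}

## ---- transform JSON dialect -------------------------------------------

#' Read/write transforms as JSON
#'
#' The on-disk dialect stores the row-major 3x3 matrix, the translation, the
#' transform kind, and optionally the scaling frame and scalings of the
#' constrained decomposition. Coordinates are world-space mm (RAS+).
#'
#' @param transform a [LinearTransform3D-class] or [FitReport-class].
#' @param path file path.
#' @param kind transform kind recorded in the file.
#' @param frame optional [ScalingFrame-class].
#' @param scalings optional length-3 scalings.
#' @return `readTransform` returns a list with elements `transform`, `kind`,
#'   `frame` (ScalingFrame or NULL) and `scalings` (numeric or NULL).
#' @export
writeTransform <- function(transform, path, kind = "affine", frame = NULL,
                           scalings = NULL) {
  if (is(transform, "FitReport")) {
    kind <- transform@kind
    dec <- transform@decomposition
    if (!is.null(dec)) {
      frame <- dec@U
      scalings <- dec@S
    }
    transform <- transform@transform
  }
  obj <- list(
    matrix = as.numeric(t(transform@matrix)),
    translation = transform@translation,
    frame_U = if (is.null(frame)) NULL else as.numeric(t(frameMatrix(frame))),
    scalings = if (is.null(scalings)) NULL else as.numeric(scalings),
    kind = kind)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- linearTransform3D(matrix(obj$matrix, 3, 3, byrow = TRUE), obj$translation)
  list(transform = tr,
       kind = obj$kind,
       frame = if (is.null(obj$frame_U)) NULL else
         scalingFrame(matrix(obj$frame_U, 3, 3, byrow = TRUE)),
       scalings = if (is.null(obj$scalings)) NULL else as.numeric(obj$scalings))
}
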