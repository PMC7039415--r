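#' Linear transformation of 3D world coordinates
#'
#' A 3x3 linear part plus a translation, acting on world-space millimetre
#' coordinates as \eqn{y = A x + t}. By convention a transform maps
#' reference-space coordinates to moving-space coordinates (backward mapping:
#' resampling pulls each output voxel's value from the moving image).
#'
#' @slot matrix 3x3 numeric matrix (dimensionless).
#' @slot translation numeric length-3 vector (mm).
#' @export
setClass("LinearTransform3D",
  representation(matrix = "matrix", translation = "numeric"),
  prototype(matrix = diag(3), translation = c(0, 0, 0)),
  validity = function(object) {
    if (!.isSquare3(object@matrix)) return("matrix must be numeric 3x3")
    if (!all(is.finite(object@matrix))) return("matrix must be finite")
    if (length(object@translation) != 3 || !all(is.finite(object@translation)))
      return("translation must be a finite length-3 numeric")
    TRUE
  })

#' Scaling frame: the fixed directions of anisotropic scaling
#'
#' A rotation matrix whose columns are the three orthogonal directions along
#' which scaling is measured. Column 1 is, in the intended neuroimaging use,
#' the mid-sagittal plane normal; columns 2-3 the in-plane principal
#' directions.
#'
#' @slot U 3x3 rotation matrix (orthonormal, det +1).
#' @export
setClass("ScalingFrame",
  representation(U = "matrix"),
  prototype(U = diag(3)),
  validity = function(object) {
    if (!.isSquare3(object@U)) return("U must be numeric 3x3")
    if (max(abs(crossprod(object@U) - diag(3))) > 1e-10)
      return("U must be orthonormal (U'U = I to 1e-10)")
    if (abs(det(object@U) - 1) > 1e-10) return("U must have det +1")
    TRUE
  })

#' Anisotropic similarity decomposition R diag(S) U' + t
#'
#' The constrained factorization of an invertible linear map: a rotation `R`,
#' positive scalings `S` applied along the columns of the scaling frame `U`,
#' and a translation.
#'
#' @slot R 3x3 rotation matrix.
#' @slot S numeric length-3, positive scaling factors.
#' @slot U a [ScalingFrame-class].
#' @slot t numeric length-3 translation (mm).
#' @export
setClass("AnisoSimDecomposition",
  representation(R = "matrix", S = "numeric", U = "ScalingFrame", t = "numeric"),
  prototype(R = diag(3), S = c(1, 1, 1), t = c(0, 0, 0)),
  validity = function(object) {
    if (!.isRotation(object@R, tol = 1e-10)) return("R must be a rotation (tol 1e-10)")
    if (length(object@S) != 3 || any(!is.finite(object@S)) || any(object@S <= 0))
      return("S must be three positive finite scalings")
    if (length(object@t) != 3 || !all(is.finite(object@t))) return("t must be finite length-3")
    TRUE
  })

#' Unit quaternion (real part first)
#'
#' Rotation representation used by the estimation core. Canonical sign: the
#' first component exceeding 1e-9 in magnitude is positive, so that q and -q
#' (which encode the same rotation) have a unique representative.
#'
#' @slot q numeric length-4, unit norm.
#' @export
setClass("UnitQuaternion",
  representation(q = "numeric"),
  prototype(q = c(1, 0, 0, 0)),
  validity = function(object) {
    if (length(object@q) != 4 || !all(is.finite(object@q))) return("q must be finite length-4")
    if (abs(sqrt(sum(object@q^2)) - 1) > 1e-12) return("q must have unit norm (tol 1e-12)")
    lead <- which(abs(object@q) > 1e-9)[1]
    if (!is.na(lead) && object@q[lead] < 0) return("q must be sign-canonical")
    TRUE
  })

#' Paired 3D point sets with optional weights
#'
#' Homologous points x (reference space) and y (moving space), in world mm,
#' with nonnegative per-pair weights. Barycentres and barycentric coordinates
#' are always weighted.
#'
#' @slot x M x 3 numeric matrix (mm).
#' @slot y M x 3 numeric matrix (mm).
#' @slot w numeric length-M nonnegative weights.
#' @export
setClass("PairedPointSet",
  representation(x = "matrix", y = "matrix", w = "numeric"),
  validity = function(object) {
    if (!is.numeric(object@x) || ncol(object@x) != 3) return("x must be M x 3 numeric")
    if (!is.numeric(object@y) || ncol(object@y) != 3) return("y must be M x 3 numeric")
    if (nrow(object@x) != nrow(object@y)) return("x and y must have the same number of rows")
    if (nrow(object@x) < 4) return("at least 4 point pairs are required")
    if (length(object@w) != nrow(object@x)) return("w must have one weight per pair")
    if (any(!is.finite(object@w)) || any(object@w < 0)) return("weights must be finite and >= 0")
    if (sum(object@w) <= 0) return("at least one weight must be positive")
    TRUE
  })

#' Block-matching correspondences
#'
#' A [PairedPointSet-class] whose x are reference block centres, y the matched
#' moving-image positions, and whose weights are the squared-correlation
#' similarity scores in [0, 1].
#'
#' @slot scores numeric, the similarity score of each retained pair.
#' @export
setClass("BlockMatchSet", contains = "PairedPointSet",
  representation(scores = "numeric"),
  validity = function(object) {
    if (length(object@scores) != nrow(object@x)) return("one score per pair required")
    if (any(object@scores < 0 | object@scores > 1)) return("scores must lie in [0, 1]")
    TRUE
  })

#' 3D scalar image with world-space affine
#'
#' A voxel array plus the 4x4 voxel-to-world affine (0-based voxel indices,
#' mm world coordinates, NIfTI convention) and an optional binary mask on the
#' same grid.
#'
#' @slot data 3D numeric array.
#' @slot affine 4x4 voxel-to-world matrix.
#' @slot mask optional logical/numeric array on the same grid (or NULL).
#' @export
setClass("Image3D",
  representation(data = "array", affine = "matrix", mask = "ANY"),
  prototype(mask = NULL),
  validity = function(object) {
    if (length(dim(object@data)) != 3) return("data must be a 3D array")
    if (!all(dim(object@affine) == c(4, 4))) return("affine must be 4x4")
    sp <- sqrt(colSums(object@affine[1:3, 1:3]^2))
    if (any(sp <= 0) || !all(is.finite(sp))) return("voxel spacing must be positive")
    if (!is.null(object@mask) && !identical(dim(object@mask), dim(object@data)))
      return("mask must share the image grid")
    TRUE
  })

#' Result of a point-set or image registration fit
#'
#' @slot transform the fitted [LinearTransform3D-class].
#' @slot decomposition an [AnisoSimDecomposition-class] for constrained kinds,
#'   or NULL.
#' @slot finalCost weighted sum of squared residuals (mm^2).
#' @slot nIterations iterations (sweeps) performed.
#' @slot converged whether the stopping tolerance was met.
#' @slot costTrace per-sweep cost values (empty for closed-form fits).
#' @slot kind one of "rigid", "similarity", "anisotropic_similarity", "affine".
#' @export
setClass("FitReport",
  representation(transform = "LinearTransform3D", decomposition = "ANY",
                 finalCost = "numeric", nIterations = "integer",
                 converged = "logical", costTrace = "numeric", kind = "character"),
  prototype(decomposition = NULL, costTrace = numeric(0)),
  validity = function(object) {
    if (length(object@finalCost) != 1 || object@finalCost < -1e-12)
      return("finalCost must be a nonnegative scalar")
    if (!object@kind %in% c("rigid", "similarity", "anisotropic_similarity", "affine"))
      return("unknown transform kind")
    TRUE
  })

#' Fitted growth model for one ROI/direction
#'
#' @slot family one of "rational", "weibull", "gompertz", "exponential".
#' @slot coefficients named numeric coefficients.
#' @slot n number of observations.
#' @slot p number of parameters counted in AIC (coefficients + residual
#'   variance).
#' @slot mse mean of squared (unweighted) errors.
#' @slot logLik Gaussian log-likelihood of the weighted fit.
#' @slot aic,aicc information criteria (standard orientation; lower is better).
#' @slot akaikeWeight relative support within a candidate set (NA until the
#'   fit is placed in one by [selectGrowthModel()]).
#' @slot fitted fitted values at the observed ages.
#' @slot ages,values,weights the data used for the fit.
#' @slot converged whether the optimizer converged from at least one start.
#' @export
setClass("GrowthFitResult",
  representation(family = "character", coefficients = "numeric", n = "integer",
                 p = "integer", mse = "numeric", logLik = "numeric", aic = "numeric",
                 aicc = "numeric", akaikeWeight = "numeric", fitted = "numeric",
                 ages = "numeric", values = "numeric", weights = "numeric",
                 converged = "logical"),
  prototype(akaikeWeight = NA_real_),
  validity = function(object) {
    if (!object@family %in% c("rational", "weibull", "gompertz", "exponential"))
      return("unknown model family")
    if (length(object@mse) == 1 && is.finite(object@mse) && object@mse < 0)
      return("MSE must be nonnegative")
    TRUE
  })

#' Mid-sagittal (or other) plane specification
#'
#' @slot normal unit length-3 normal vector (world space).
#' @slot point a point on the plane (mm).
#' @export
setClass("PlaneSpec",
  representation(normal = "numeric", point = "numeric"),
  validity = function(object) {
    if (length(object@normal) != 3 || abs(sqrt(sum(object@normal^2)) - 1) > 1e-8)
      return("normal must be a unit length-3 vector")
    if (length(object@point) != 3 || !all(is.finite(object@point)))
      return("point must be finite length-3")
    TRUE
  })
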