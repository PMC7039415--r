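#' @include AllClasses.R
NULL

## Quaternion algebra underlying the anisotropic-similarity estimator.
##
## Quaternions are length-4 numeric vectors (q1, q2, q3, q4) with the real
## part first. 3-vectors embed as pure quaternions (0, v1, v2, v3). A unit
## quaternion q acts on a pure quaternion x as the rotation q * x * conj(q).

#' Construct a sign-canonical unit quaternion
#'
#' Normalizes `q` to unit length and flips the sign so that the first
#' component with magnitude above 1e-9 is positive (q and -q encode the same
#' rotation; the canonical representative makes round trips stable).
#'
#' @param q numeric length-4, real part first. Need not be normalized.
#' @return a [UnitQuaternion-class].
#' @export
unitQuaternion <- function(q) {
  n <- sqrt(sum(q^2))
  if (n < 1e-300) .asError("cannot normalize a zero quaternion", "degenerate_quaternion")
  q <- q / n
  new("UnitQuaternion", q = .canonicalQuat(q))
}

.canonicalQuat <- function(q) {
  lead <- which(abs(q) > 1e-9)[1]
  if (!is.na(lead) && q[lead] < 0) q <- -q
  q
}

#' Hamilton product of two quaternions
#'
#' @param p,q numeric length-4 quaternions (not necessarily unit).
#' @return the quaternion product p * q.
#' @export
quatMultiply <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] + p[3] * q[1] + p[4] * q[2] - p[2] * q[4],
    p[1] * q[4] + p[4] * q[1] + p[2] * q[3] - p[3] * q[2])
}

#' Quaternion conjugate
#' @param q numeric length-4 quaternion.
#' @export
quatConjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' Matricial representation of quaternion multiplication
#'
#' Returns the pair of 4x4 matrices (Q_p, P_p) satisfying, for every
#' quaternion q, \eqn{Q_p q = p * q} and \eqn{P_p q = q * \bar p} (hence
#' \eqn{P_p' q = q * p}). These turn the rotation part of the
#' anisotropic-similarity least-squares criterion into a quadratic form in
#' the rotation quaternion.
#'
#' @param p numeric length-4 quaternion (pure quaternions allowed).
#' @return list with elements `Q` and `P`.
#' @export
quatMatrices <- function(p) {
  Q <- matrix(c(p[1], -p[2], -p[3], -p[4],
                p[2],  p[1], -p[4],  p[3],
                p[3],  p[4],  p[1], -p[2],
                p[4], -p[3],  p[2],  p[1]), 4, 4, byrow = TRUE)
  P <- matrix(c(p[1],  p[2],  p[3],  p[4],
               -p[2],  p[1], -p[4],  p[3],
               -p[3],  p[4],  p[1], -p[2],
               -p[4], -p[3],  p[2],  p[1]), 4, 4, byrow = TRUE)
  list(Q = Q, P = P)
}

## Elementary derivative patterns of P_p with respect to the three imaginary
## components p2, p3, p4 (constant antisymmetric matrices).
.PE <- list(
  matrix(c(0, 1, 0, 0,  -1, 0, 0, 0,  0, 0, 0, -1,  0, 0, 1, 0), 4, 4, byrow = TRUE),
  matrix(c(0, 0, 1, 0,  0, 0, 0, 1,  -1, 0, 0, 0,  0, -1, 0, 0), 4, 4, byrow = TRUE),
  matrix(c(0, 0, 0, 1,  0, 0, -1, 0,  0, 1, 0, 0,  -1, 0, 0, 0), 4, 4, byrow = TRUE))

#' Derivatives of the matricial quaternion P with respect to the scalings
#'
#' With xi = diag(S) xt a pure quaternion built from a point xt expressed in
#' the scaling frame, P_xi is linear in each s_j, so dP_xi/ds_j is the
#' constant sparse matrix obtained by placing xt_j in the j-th imaginary slot
#' of the P pattern. Used by the scaling update of the alternating optimizer
#' and locked by a finite-difference test.
#'
#' @param xt numeric length-3: the point coordinates in the scaling frame.
#' @return list of three 4x4 matrices, dP/ds_1, dP/ds_2, dP/ds_3.
#' @export
scalingDerivativeMatrices <- function(xt) {
  lapply(1:3, function(j) xt[j] * .PE[[j]])
}

#' Convert a unit quaternion to a rotation matrix
#'
#' @param q a [UnitQuaternion-class] or a unit-norm length-4 numeric.
#' @return 3x3 rotation matrix.
#' @export
quatToRotation <- function(q) {
  if (is(q, "UnitQuaternion")) q <- q@q
  if (abs(sqrt(sum(q^2)) - 1) > 1e-9)
    .asError("quatToRotation expects a unit quaternion", "degenerate_quaternion")
  q1 <- q[1]; q2 <- q[2]; q3 <- q[3]; q4 <- q[4]
  matrix(c(q1^2 + q2^2 - q3^2 - q4^2, 2 * (q2 * q3 - q1 * q4), 2 * (q2 * q4 + q1 * q3),
           2 * (q2 * q3 + q1 * q4), q1^2 - q2^2 + q3^2 - q4^2, 2 * (q3 * q4 - q1 * q2),
           2 * (q2 * q4 - q1 * q3), 2 * (q3 * q4 + q1 * q2), q1^2 - q2^2 - q3^2 + q4^2),
         3, 3, byrow = TRUE)
}

#' Convert a rotation matrix to its canonical unit quaternion
#'
#' Shepperd's numerically stable branch selection, followed by sign
#' canonicalization.
#'
#' @param R 3x3 rotation matrix (orthonormal, det +1).
#' @return a [UnitQuaternion-class].
#' @export
rotationToQuat <- function(R) {
  if (!.isRotation(R))
    .asError("rotationToQuat expects an orthonormal matrix with det +1", "not_a_rotation")
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  q <- numeric(4)
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q[1] <- 0.25 * s
    q[2] <- (R[3, 2] - R[2, 3]) / s
    q[3] <- (R[1, 3] - R[3, 1]) / s
    q[4] <- (R[2, 1] - R[1, 2]) / s
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q[1] <- (R[3, 2] - R[2, 3]) / s; q[2] <- 0.25 * s
      q[3] <- (R[1, 2] + R[2, 1]) / s; q[4] <- (R[1, 3] + R[3, 1]) / s
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q[1] <- (R[1, 3] - R[3, 1]) / s; q[2] <- (R[1, 2] + R[2, 1]) / s
      q[3] <- 0.25 * s; q[4] <- (R[2, 3] + R[3, 2]) / s
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q[1] <- (R[2, 1] - R[1, 2]) / s; q[2] <- (R[1, 3] + R[3, 1]) / s
      q[3] <- (R[2, 3] + R[3, 2]) / s; q[4] <- 0.25 * s
    }
  }
  unitQuaternion(q)
}
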