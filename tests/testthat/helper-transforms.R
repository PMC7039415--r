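## Shared generators for randomized tests. All draw from the current RNG
## stream; callers set the seed.

rRotation <- function() quatToRotation(unitQuaternion(stats::rnorm(4)))

## Small rotation of at most maxDeg degrees about a random axis.
rSmallRotation <- function(maxDeg = 15) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, 0, maxDeg) * pi / 180
  quatToRotation(unitQuaternion(c(cos(ang / 2), sin(ang / 2) * ax)))
}

rUnitQuat <- function() {
  q <- stats::rnorm(4)
  q / sqrt(sum(q^2))
}

## Random anisotropic similarity in canonical form A = R diag(S) U'.
## With nearIdentity = TRUE the net rotation is small (R = R0 U, the
## roughly-aligned-subject setting); otherwise R is arbitrary.
rAnisoTransform <- function(sRange = c(0.5, 2), tMax = 20, nearIdentity = FALSE,
                            maxDeg = 15) {
  U <- rRotation()
  S <- stats::runif(3, sRange[1], sRange[2])
  R <- if (nearIdentity) rSmallRotation(maxDeg) %*% U else rRotation()
  t <- stats::runif(3, -tMax, tMax)
  list(U = U, S = S, R = R, t = t,
       transform = linearTransform3D(R %*% diag(S) %*% t(U), t))
}

rotationAngleDeg <- function(Ra, Rb) {
  c2 <- (sum(diag(crossprod(Ra, Rb))) - 1) / 2
  acos(min(1, max(-1, c2))) * 180 / pi
}

## Independent Hamilton product oracle via the scalar/vector formula
## (p1 q1 - p.q, p1 q + q1 p + p x q) -- a different expression from the
## component formula used by quatMultiply().
hamiltonOracle <- function(p, q) {
  pv <- p[2:4]; qv <- q[2:4]
  c(p[1] * q[1] - sum(pv * qv),
    p[1] * qv + q[1] * pv + c(pv[2] * qv[3] - pv[3] * qv[2],
                              pv[3] * qv[1] - pv[1] * qv[3],
                              pv[1] * qv[2] - pv[2] * qv[1]))
}
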