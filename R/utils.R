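## Internal helpers shared across the package.

.asError <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("anisosim_", class), "anisosim_error")))
}

.isSquare3 <- function(A) is.matrix(A) && all(dim(A) == c(3L, 3L)) && is.numeric(A)

.isRotation <- function(R, tol = 1e-8) {
  .isSquare3(R) && all(is.finite(R)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

## Cross products of matched rows of two M x 3 matrices.
.rowCross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}
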