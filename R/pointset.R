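#' @include AllClasses.R accessors.R
NULL

## Weighted barycentres and barycentric coordinates of a paired point set.
.barycentric <- function(pts) {
  w <- pts@w
  sw <- sum(w)
  xbar <- colSums(pts@x * w) / sw
  ybar <- colSums(pts@y * w) / sw
  list(xbar = xbar, ybar = ybar,
       xp = sweep(pts@x, 2, xbar), yp = sweep(pts@y, 2, ybar), w = w)
}

#' Weighted least-squares cost of a transform on paired points
#'
#' The registration criterion: \eqn{\sum_i w_i \| y_i - (A x_i + t) \|^2}
#' (mm^2).
#'
#' @param pts a [PairedPointSet-class].
#' @param transform a [LinearTransform3D-class].
#' @export
transformCost <- function(pts, transform) {
  res <- pts@y - applyTransform(transform, pts@x)
  sum(pts@w * rowSums(res^2))
}

#' Optimal translation for a fixed linear part
#'
#' Given the linear part, the translation minimizing the weighted
#' least-squares criterion is closed-form:
#' \eqn{\hat t = \bar y - A \bar x} with weighted barycentres.
#'
#' @param A 3x3 linear part.
#' @param pts a [PairedPointSet-class].
#' @return length-3 translation (mm).
#' @export
optimalTranslation <- function(A, pts) {
  b <- .barycentric(pts)
  as.numeric(b$ybar - A %*% b$xbar)
}

#' Read/write paired point sets as plain text
#'
#' One pair per row: `x1 x2 x3 y1 y2 y3 [w]`, whitespace- or
#' comma-separated. The weight column is optional and defaults to 1.
#'
#' @param path file path.
#' @param pts a [PairedPointSet-class].
#' @export
readPointSet <- function(path) {
  txt <- gsub(",", " ", readLines(path))
  txt <- txt[nzchar(trimws(txt)) & !startsWith(trimws(txt), "#")]
  m <- do.call(rbind, lapply(strsplit(trimws(txt), "\\s+"), as.numeric))
  if (ncol(m) == 6) m <- cbind(m, 1)
  if (ncol(m) != 7) .asError("point-set rows must have 6 or 7 columns", "bad_pointset_file")
  pairedPointSet(m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE], m[, 7])
}

#' @rdname readPointSet
#' @export
writePointSet <- function(pts, path) {
  m <- cbind(pts@x, pts@y, pts@w)
  utils::write.table(format(m, digits = 17, trim = TRUE), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
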