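#' @include AllClasses.R accessors.R growth.R
NULL

## A scaling-record table is a plain data.frame with columns
## subject, age, sex, roi, direction, reference, scaling.

.checkRecords <- function(records, needReference = FALSE) {
  need <- c("subject", "age", "sex", "roi", "direction", "scaling")
  if (needReference) need <- c(need, "reference")
  miss <- setdiff(need, names(records))
  if (length(miss))
    .asError(paste("scaling records missing column(s):", paste(miss, collapse = ", ")),
             "bad_records")
  if (any(records$scaling <= 0)) .asError("scaling factors must be positive", "bad_records")
  if (any(records$age < 0)) .asError("ages must be nonnegative", "bad_records")
  invisible(records)
}

#' Read/write scaling-record tables
#'
#' CSV with columns subject, age, sex, roi, direction, reference, scaling.
#'
#' @param path CSV path.
#' @param records a scaling-record data.frame.
#' @export
readScalingRecords <- function(path) {
  .checkRecords(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname readScalingRecords
#' @export
writeScalingRecords <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract the directional scaling factors of a fitted transform
#'
#' Returns the three scalings of an anisotropic-similarity fit, in the column
#' order of the scaling frame (relative to the reference image: absolute
#' factors require [normalizeToBaseline()]).
#'
#' @param report a [FitReport-class] of kind "anisotropic_similarity".
#' @return numeric length-3.
#' @export
extractScalingFactors <- function(report) {
  if (report@kind != "anisotropic_similarity" || is.null(report@decomposition))
    .asError("scaling factors require an anisotropic similarity fit", "wrong_kind")
  report@decomposition@S
}

#' Normalize relative scaling factors to a baseline (neonate) group
#'
#' Divides every scaling factor by the mean factor of the baseline subjects
#' for the same (roi, direction) cell — and the same reference image when a
#' reference column distinguishes several. After normalization the baseline
#' mean is exactly 1 in every cell and factors read as expansion since the
#' baseline age (birth, when the baseline group are neonates). Idempotent
#' once applied (the baseline means become 1).
#'
#' @param records scaling-record data.frame.
#' @param baselineSubjects subject ids forming the baseline group.
#' @return the records with `scaling` replaced by absolute factors.
#' @export
normalizeToBaseline <- function(records, baselineSubjects) {
  .checkRecords(records)
  isBase <- records$subject %in% baselineSubjects
  if (!any(isBase)) .asError("baseline group is empty", "empty_baseline")
  hasRef <- "reference" %in% names(records)
  key <- if (hasRef) interaction(records$roi, records$direction, records$reference,
                                 drop = TRUE)
         else interaction(records$roi, records$direction, drop = TRUE)
  baseMean <- tapply(records$scaling[isBase], key[isBase], mean)
  missing <- setdiff(levels(key), names(baseMean)[!is.na(baseMean)])
  if (length(missing))
    .asError(paste("no baseline subjects for cell(s):", paste(missing, collapse = "; ")),
             "empty_baseline")
  records$scaling <- records$scaling / as.numeric(baseMean[as.character(key)])
  records
}

#' Group comparison of scaling factors with FDR control
#'
#' For every combination of age interval, ROI and direction, compares the
#' male and female scaling-factor distributions with a two-tailed
#' Wilcoxon-Mann-Whitney test (exact when the combined sample is at most 25
#' with no ties, normal approximation otherwise), then applies the
#' Benjamini-Hochberg step-up procedure at the given FDR level across the
#' whole family of tests. The effect size is
#' \eqn{d = (median(S_m) - median(S_f)) / (\sigma(S_m) + \sigma(S_f))} with
#' sample standard deviations. Cells with an empty group are skipped with a
#' warning; cells with fewer than 3 per group are flagged.
#'
#' @param records scaling-record data.frame with absolute factors.
#' @param baselineSubjects subject ids of the baseline (first) age interval.
#' @param breaks age-class breakpoints for the non-baseline subjects
#'   (default intervals (0,6], (6,12], >12).
#' @param fdrLevel FDR level for the BH decision.
#' @return data.frame with one row per tested cell: interval, roi, direction,
#'   nMale, nFemale, pValue, pAdjusted, rejected, effectSize, flagged.
#' @export
compareGroups <- function(records, baselineSubjects = character(0),
                          breaks = c(0, 6, 12, Inf), fdrLevel = 0.05) {
  .checkRecords(records)
  isBase <- records$subject %in% baselineSubjects
  interval <- character(nrow(records))
  interval[isBase] <- "baseline"
  nb <- !isBase
  interval[nb] <- as.character(cut(records$age[nb], breaks = breaks,
                                   include.lowest = TRUE))
  records$interval <- interval
  cells <- unique(records[, c("interval", "roi", "direction")])
  out <- NULL
  for (i in seq_len(nrow(cells))) {
    sel <- records$interval == cells$interval[i] & records$roi == cells$roi[i] &
      records$direction == cells$direction[i]
    sm <- records$scaling[sel & records$sex == "male"]
    sf <- records$scaling[sel & records$sex == "female"]
    if (length(sm) == 0 || length(sf) == 0) {
      warning(sprintf("cell (%s, %s, d%s) has an empty group; skipped",
                      cells$interval[i], cells$roi[i], cells$direction[i]))
      next
    }
    exact <- (length(sm) + length(sf)) <= 25 &&
      !any(duplicated(c(sm, sf)))
    p <- suppressWarnings(stats::wilcox.test(sm, sf, alternative = "two.sided",
                                             exact = exact)$p.value)
    d <- (stats::median(sm) - stats::median(sf)) /
      (stats::sd(sm) + stats::sd(sf))
    out <- rbind(out, data.frame(
      interval = cells$interval[i], roi = cells$roi[i],
      direction = cells$direction[i], nMale = length(sm), nFemale = length(sf),
      pValue = p, effectSize = d,
      flagged = length(sm) < 3 || length(sf) < 3))
  }
  if (is.null(out)) .asError("no testable cells", "empty_baseline")
  out$pAdjusted <- stats::p.adjust(out$pValue, method = "BH")
  out$rejected <- out$pAdjusted <= fdrLevel
  out[, c("interval", "roi", "direction", "nMale", "nFemale", "pValue",
          "pAdjusted", "rejected", "effectSize", "flagged")]
}

#' Influence of the reference image on scaling factors
#'
#' Quantifies how much the choice of reference image changes the extracted
#' factors. For references k, l the pairwise relative distance is
#' \eqn{D_{k,l} = 2 |s_k - s_l| / (s_k + s_l)} per (subject, roi, direction);
#' across all references the relative standard deviation is
#' \eqn{D = \sigma(s_.) / mean(s_.)} (sample standard deviation).
#' Cells without a complete set of references are excluded and counted.
#'
#' @param records scaling-record data.frame with a `reference` column
#'   covering at least two references.
#' @return list with `pairwise` (data.frame subject, roi, direction, refA,
#'   refB, distance), `dispersion` (data.frame subject, roi, direction,
#'   relativeSD) and `nExcluded`.
#' @export
referenceInfluence <- function(records) {
  .checkRecords(records, needReference = TRUE)
  refs <- sort(unique(records$reference))
  if (length(refs) < 2)
    .asError("at least two references are required", "bad_records")
  wide <- stats::reshape(
    records[, c("subject", "roi", "direction", "reference", "scaling")],
    idvar = c("subject", "roi", "direction"), timevar = "reference",
    direction = "wide")
  sCols <- paste0("scaling.", refs)
  complete <- stats::complete.cases(wide[, sCols])
  nExcluded <- sum(!complete)
  wide <- wide[complete, , drop = FALSE]
  S <- as.matrix(wide[, sCols])
  pair <- NULL
  for (a in seq_along(refs)) for (b in seq_along(refs)) {
    if (b <= a) next
    pair <- rbind(pair, data.frame(
      subject = wide$subject, roi = wide$roi, direction = wide$direction,
      refA = refs[a], refB = refs[b],
      distance = 2 * abs(S[, a] - S[, b]) / (S[, a] + S[, b])))
  }
  disp <- data.frame(subject = wide$subject, roi = wide$roi,
                     direction = wide$direction,
                     relativeSD = apply(S, 1, stats::sd) / rowMeans(S))
  list(pairwise = pair, dispersion = disp, nExcluded = nExcluded)
}
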