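#' @include AllClasses.R accessors.R
NULL

## ---- candidate growth-model families ------------------------------------

.growthFamilies <- list(
  rational = list(
    formula = value ~ (a * age + b) / (age + c),
    npar = 3L,
    fun = function(age, cf) (cf["a"] * age + cf["b"]) / (age + cf["c"]),
    lower = c(a = -Inf, b = -Inf, c = 1e-8)),
  weibull = list(
    formula = value ~ a - b * exp(-c * age^d),
    npar = 4L,
    fun = function(age, cf) cf["a"] - cf["b"] * exp(-cf["c"] * age^cf["d"]),
    lower = c(a = -Inf, b = -Inf, c = 1e-8, d = 0.05)),
  gompertz = list(
    formula = value ~ a * exp(-b * exp(-c * age)),
    npar = 3L,
    fun = function(age, cf) cf["a"] * exp(-cf["b"] * exp(-cf["c"] * age)),
    lower = c(a = 1e-8, b = -Inf, c = 1e-8)),
  exponential = list(
    formula = value ~ a + b * exp(-c * age),
    npar = 3L,
    fun = function(age, cf) cf["a"] + cf["b"] * exp(-cf["c"] * age),
    lower = c(a = -Inf, b = -Inf, c = 1e-8)))

#' Evaluate a growth-model family
#'
#' Model formulas: rational `y = (a x + b)/(x + c)`; Weibull
#' `y = a - b exp(-c x^d)`; Gompertz `y = a exp(-b exp(-c x))`; exponential
#' `y = a + b exp(-c x)`. All four share a horizontal asymptote, matching the
#' assumption that growth eventually stops.
#'
#' @param family one of "rational", "weibull", "gompertz", "exponential".
#' @param ages numeric ages (years).
#' @param coefficients named numeric vector of the family's coefficients.
#' @export
growthCurve <- function(family, ages, coefficients) {
  fam <- .growthFamilies[[match.arg(family, names(.growthFamilies))]]
  unname(fam$fun(ages, coefficients))
}

## Deterministic coarse grid of starting values (10 per family) built from
## the data scale: asymptote near max(y), early value near y at the youngest
## ages, rates in {0.1, 0.5, 1, 2}.
.startGrid <- function(family, ages, values) {
  yMax <- max(values)
  y0 <- mean(values[ages <= stats::quantile(ages, 0.2)])
  if (!is.finite(y0)) y0 <- values[which.min(ages)]
  rates <- c(0.1, 0.5, 1, 2)
  switch(family,
    rational = {
      cs <- c(0.25, 0.5, 1, 2, 4)
      g <- expand.grid(a = yMax * c(1, 1.1), c = cs)
      lapply(seq_len(nrow(g)), function(i)
        list(a = g$a[i], b = y0 * g$c[i], c = g$c[i]))
    },
    weibull = {
      g <- expand.grid(c = rates, d = c(1, 1.6), KEEP.OUT.ATTRS = FALSE)
      starts <- lapply(seq_len(nrow(g)), function(i)
        list(a = yMax, b = yMax - y0, c = g$c[i], d = g$d[i]))
      c(starts, list(list(a = yMax * 1.1, b = yMax * 1.1 - y0, c = 0.5, d = 1.2),
                     list(a = yMax * 1.1, b = yMax * 1.1 - y0, c = 1, d = 0.8)))
    },
    gompertz = {
      b0 <- log(max(yMax, 1e-6) / max(y0, 1e-6 * yMax))
      starts <- lapply(rates, function(r) list(a = yMax, b = max(b0, 0.1), c = r))
      c(starts,
        lapply(rates, function(r) list(a = yMax * 1.1, b = max(2 * b0, 0.2), c = r)),
        list(list(a = yMax, b = 1, c = 0.3), list(a = yMax * 1.2, b = 0.5, c = 0.3)))
    },
    exponential = {
      starts <- lapply(rates, function(r) list(a = yMax, b = y0 - yMax, c = r))
      c(starts,
        lapply(rates, function(r) list(a = yMax * 1.1, b = y0 - yMax * 1.1, c = r)),
        list(list(a = yMax, b = -0.1, c = 0.3), list(a = mean(values), b = 0.1, c = 0.5)))
    })
}

#' Gender-balance regression weights
#'
#' For each subject, the subjects within a window of width `l` years centred
#' on its age are counted; a female subject receives weight n_m/n and a male
#' subject n_f/n (n_m males, n_f females, n total in the window), so that
#' locally over-represented sexes are down-weighted. A window containing a
#' single sex yields zero weights for that sex (warned about, since those
#' observations then drop out of the fit).
#'
#' @param ages numeric ages (years).
#' @param sexes character/factor, "male"/"female".
#' @param window window width l in years (default 2: age +/- 1).
#' @return numeric weights, one per subject.
#' @export
genderBalanceWeights <- function(ages, sexes, window = 2) {
  sexes <- as.character(sexes)
  if (!all(sexes %in% c("male", "female")))
    .asError("sexes must be 'male' or 'female'", "bad_config")
  half <- window / 2
  w <- vapply(seq_along(ages), function(i) {
    inWin <- abs(ages - ages[i]) <= half
    n <- sum(inWin)
    nm <- sum(sexes[inWin] == "male")
    if (sexes[i] == "female") nm / n else (n - nm) / n
  }, numeric(1))
  if (any(w == 0))
    warning("some windows contain a single sex; affected subjects get weight 0")
  w
}

#' Goodness-of-fit statistics for a weighted nonlinear fit
#'
#' The Gaussian log-likelihood uses the maximum-likelihood variance estimate
#' from the weighted residual sum of squares (denominator n), following the
#' convention of [stats::logLik()] for weighted fits:
#' \eqn{\ln L = \frac{1}{2}\sum \ln w_i - \frac{n}{2}(\ln(2\pi) + 1 +
#' \ln(RSS_w/n))}. AIC is the standard orientation \eqn{2p - 2\ln L} (lower
#' is better) and \eqn{AICc = AIC + 2p(p+1)/(n-p-1)}. `p` counts the model
#' coefficients plus the residual variance. MSE is the plain (unweighted)
#' mean of squared errors.
#'
#' @param values,fitted observed and fitted values.
#' @param weights nonnegative weights (zero-weight points are excluded from
#'   the likelihood but kept in MSE).
#' @param nCoef number of model coefficients.
#' @return list with `mse`, `logLik`, `aic`, `aicc`, `p`, `n`.
#' @export
goodnessStats <- function(values, fitted, weights = rep(1, length(values)), nCoef) {
  n <- length(values)
  res <- values - fitted
  mse <- mean(res^2)
  pos <- weights > 0
  npos <- sum(pos)
  rssw <- sum(weights[pos] * res[pos]^2)
  ll <- 0.5 * sum(log(weights[pos])) -
    npos / 2 * (log(2 * pi) + 1 + log(rssw / npos))
  p <- as.integer(nCoef) + 1L
  aic <- 2 * p - 2 * ll
  if (n <= p + 1)
    .asError("AICc undefined: n <= p + 1", "aicc_undefined")
  aicc <- aic + 2 * p * (p + 1) / (n - p - 1)
  list(mse = mse, logLik = ll, aic = aic, aicc = aicc, p = p, n = n)
}

#' Akaike weights
#'
#' Softmax of minus half the AICc differences to the best model: the relative
#' support probability of each candidate. Invariant to adding a constant to
#' all values; sums to 1.
#'
#' @param aicc numeric vector of AIC or AICc values.
#' @export
akaikeWeights <- function(aicc) {
  d <- aicc - min(aicc)
  e <- exp(-d / 2)
  e / sum(e)
}

#' Fit one growth-model family by weighted Levenberg-Marquardt
#'
#' Weighted nonlinear least squares via [minpack.lm::nlsLM()], restarted from
#' a deterministic coarse grid of 10 starting points (asymptote near max(y),
#' rates in 0.1-2); the converged fit with the lowest weighted RSS wins.
#' For the rational family the pole `-c` is constrained out of the
#' nonnegative age range (`c > 0`). Note the rational family is not
#' identifiable on flat data (any `c` with `b = y c` fits exactly); a
#' near-singular fit is still returned, with the ridge reflected in the
#' coefficients.
#'
#' @param family one of "rational", "weibull", "gompertz", "exponential".
#' @param ages,values observations (ages in years).
#' @param weights nonnegative per-point weights (default 1).
#' @return a [GrowthFitResult-class].
#' @export
fitGrowthModel <- function(family, ages, values, weights = rep(1, length(ages))) {
  family <- match.arg(family, names(.growthFamilies))
  fam <- .growthFamilies[[family]]
  if (length(ages) <= fam$npar + 2L)
    .asError("too few points for this family", "fit_failed")
  if (any(ages < 0)) .asError("ages must be nonnegative", "bad_config")
  df <- data.frame(age = ages, value = values)
  fml <- fam$formula
  environment(fml) <- environment()  # so nlsLM finds `weights` here
  best <- NULL
  bestRss <- Inf
  for (st in .startGrid(family, ages, values)) {
    ## a start that already fits exactly (e.g. the rational ridge on constant
    ## data) makes the LM gradient singular; accept it directly
    rss0 <- sum(weights * (values - fam$fun(ages, unlist(st)))^2)
    if (is.finite(rss0) && rss0 <= 1e-18 * max(sum(weights * values^2), 1e-300)) {
      if (rss0 < bestRss) {
        bestRss <- rss0
        best <- unlist(st)
      }
      next
    }
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        fml, data = df, start = st, weights = weights,
        lower = fam$lower[names(st)],
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                             ptol = 1e-12))),
      error = function(e) NULL)
    if (is.null(fit)) next
    cf <- stats::coef(fit)
    if (family == "rational" && cf["c"] <= 0) next
    rss <- sum(weights * (values - fam$fun(ages, cf))^2)
    if (is.finite(rss) && rss < bestRss) {
      bestRss <- rss
      best <- cf
    }
  }
  if (is.null(best))
    .asError(sprintf("all %s starts failed to converge", family), "fit_failed")
  fitted <- fam$fun(ages, best)
  gs <- goodnessStats(values, fitted, weights, fam$npar)
  new("GrowthFitResult", family = family, coefficients = best,
      n = gs$n, p = gs$p, mse = gs$mse, logLik = gs$logLik, aic = gs$aic,
      aicc = gs$aicc, fitted = unname(fitted), ages = as.numeric(ages),
      values = as.numeric(values), weights = as.numeric(weights),
      converged = TRUE)
}

setMethod("predictGrowth", "GrowthFitResult", function(fit, ages) {
  growthCurve(fit@family, ages, fit@coefficients)
})

#' Fit all candidate families and select by AICc
#'
#' Fits the rational, Weibull, Gompertz and exponential families and selects
#' the one with the lowest AICc; Akaike weights are computed across the
#' candidates that converged. Failed fits are recorded and excluded.
#'
#' @param ages,values,weights observations, see [fitGrowthModel()].
#' @param families candidate family names.
#' @return list with `best` (family name), `fits` (named list of
#'   [GrowthFitResult-class]), `table` (data.frame of goodness-of-fit
#'   statistics) and `failed` (names of families that did not fit).
#' @export
selectGrowthModel <- function(ages, values, weights = rep(1, length(ages)),
                              families = names(.growthFamilies)) {
  fits <- list()
  failed <- character(0)
  for (fam in families) {
    f <- tryCatch(fitGrowthModel(fam, ages, values, weights),
                  error = function(e) NULL)
    if (is.null(f)) failed <- c(failed, fam) else fits[[fam]] <- f
  }
  if (length(fits) == 0) .asError("all candidate families failed", "fit_failed")
  aicc <- vapply(fits, function(f) f@aicc, numeric(1))
  wts <- akaikeWeights(aicc)
  for (i in seq_along(fits)) fits[[i]]@akaikeWeight <- unname(wts[i])
  tab <- data.frame(family = names(fits),
                    p = vapply(fits, function(f) f@p, integer(1)),
                    mse = vapply(fits, function(f) f@mse, numeric(1)),
                    aic = vapply(fits, function(f) f@aic, numeric(1)),
                    aicc = aicc, akaikeWeight = wts, row.names = NULL)
  list(best = names(fits)[which.min(aicc)], fits = fits,
       table = tab[order(tab$aicc), ], failed = failed)
}

#' Pointwise bootstrap confidence band for a growth fit
#'
#' Case-resampling bootstrap: observation triplets (age, value, weight) are
#' resampled with replacement, the same family is refit (warm-started at the
#' original coefficients, falling back to the multi-start grid), and the
#' percentile band of the fitted curves is taken at each grid age. The band
#' is pointwise, not simultaneous, and is labelled as such.
#'
#' @param fit a [GrowthFitResult-class].
#' @param level band level (default 0.99).
#' @param nBoot number of bootstrap replicates.
#' @param seed RNG seed (bands are bit-identical for a fixed seed).
#' @param gridAges ages at which to evaluate the band.
#' @return data.frame with columns age, fit, lower, upper; attribute
#'   `failureRate` gives the fraction of failed refits (a warning is raised
#'   above 20%), attribute `bandType` is "pointwise bootstrap".
#' @export
confidenceBands <- function(fit, level = 0.99, nBoot = 400, seed = 1,
                            gridAges = seq(min(fit@ages), max(fit@ages),
                                           length.out = 60)) {
  fam <- .growthFamilies[[fit@family]]
  n <- length(fit@ages)
  curves <- matrix(NA_real_, nBoot, length(gridAges))
  set.seed(seed)
  df0 <- data.frame(age = fit@ages, value = fit@values)
  fml <- fam$formula
  environment(fml) <- environment()  # so nlsLM finds the weights vector here
  for (b in seq_len(nBoot)) {
    idx <- sample.int(n, n, replace = TRUE)
    wIdx <- fit@weights[idx]
    cf <- tryCatch(
      stats::coef(suppressWarnings(minpack.lm::nlsLM(
        fml, data = df0[idx, ], start = as.list(fit@coefficients),
        weights = wIdx, lower = fam$lower,
        control = minpack.lm::nls.lm.control(maxiter = 100)))),
      error = function(e) NULL)
    if (is.null(cf)) {
      cf <- tryCatch(fitGrowthModel(fit@family, fit@ages[idx], fit@values[idx],
                                    fit@weights[idx])@coefficients,
                     error = function(e) NULL)
    }
    if (!is.null(cf)) curves[b, ] <- fam$fun(gridAges, cf)
  }
  ok <- stats::complete.cases(curves)
  failureRate <- 1 - mean(ok)
  if (failureRate > 0.2)
    warning(sprintf("band unreliable: %.0f%% of bootstrap refits failed",
                    100 * failureRate))
  alpha <- (1 - level) / 2
  qs <- apply(curves[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(alpha, 1 - alpha), names = FALSE)
  out <- data.frame(age = gridAges,
                    fit = fam$fun(gridAges, fit@coefficients),
                    lower = qs[1, ], upper = qs[2, ])
  attr(out, "failureRate") <- failureRate
  attr(out, "bandType") <- "pointwise bootstrap"
  out
}
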