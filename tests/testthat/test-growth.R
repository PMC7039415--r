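test_that("gender-balance weights follow the local sex counts", {
  ## window of 3 males + 1 female around age 5
  ages <- c(5, 5.2, 4.8, 5.1)
  sexes <- c("female", "male", "male", "male")
  w <- genderBalanceWeights(ages, sexes)
  expect_equal(w[1], 3 / 4)
  expect_equal(w[2:4], rep(1 / 4, 3))
  ## perfectly balanced window: both sexes get 1/2
  wb <- genderBalanceWeights(c(3, 3.5), c("male", "female"))
  expect_equal(wb, c(0.5, 0.5))
  ## single-sex window: zero weight, warned about
  expect_warning(w0 <- genderBalanceWeights(c(1, 1.2), c("male", "male")),
                 "single sex")
  expect_equal(w0, c(0, 0))
  ## the window is local: distant subjects do not count
  expect_warning(
    wl <- genderBalanceWeights(c(0, 10, 10.5), c("female", "male", "female")),
    "single sex")
  expect_equal(wl[1], 0)
})

test_that("noiseless data recover generating coefficients to 1e-6", {
  ages <- seq(0, 19, length.out = 40)
  ## rational (a, b, c) = (1.3, 1.0, 1.2)
  y <- (1.3 * ages + 1.0) / (ages + 1.2)
  fit <- fitGrowthModel("rational", ages, y)
  expect_lt(max(abs(fit@coefficients - c(a = 1.3, b = 1.0, c = 1.2))), 1e-6)
  expect_lt(fit@mse, 1e-12)
  ## exponential (a, b, c) = (1.5, -0.5, 0.8)
  y2 <- 1.5 - 0.5 * exp(-0.8 * ages)
  fit2 <- fitGrowthModel("exponential", ages, y2)
  expect_lt(max(abs(fit2@coefficients - c(a = 1.5, b = -0.5, c = 0.8))), 1e-6)
  ## weibull and gompertz round-trip their own curves
  y3 <- growthCurve("weibull", ages, c(a = 1.4, b = 0.6, c = 0.3, d = 1.3))
  fit3 <- fitGrowthModel("weibull", ages, y3)
  expect_lt(max(abs(predictGrowth(fit3, ages) - y3)), 1e-6)
  y4 <- growthCurve("gompertz", ages, c(a = 1.4, b = 0.5, c = 0.4))
  fit4 <- fitGrowthModel("gompertz", ages, y4)
  expect_lt(max(abs(fit4@coefficients - c(a = 1.4, b = 0.5, c = 0.4))), 1e-5)
})

test_that("constant data are represented exactly by the rational ridge", {
  ages <- seq(0, 10, length.out = 20)
  fit <- fitGrowthModel("rational", ages, rep(2, 20))
  expect_lt(fit@mse, 1e-12)
  expect_equal(unname(predictGrowth(fit, c(1, 5, 9))), rep(2, 3), tolerance = 1e-6)
})

test_that("goodness statistics match direct arithmetic on a small example", {
  y <- c(1.0, 1.2, 1.5, 1.6, 1.7, 1.75, 1.8)
  yhat <- c(1.1, 1.1, 1.4, 1.7, 1.6, 1.8, 1.75)
  w <- c(1, 0.5, 1, 0.5, 1, 1, 0.25)
  n <- 7
  gs <- goodnessStats(y, yhat, w, nCoef = 3)
  ## independent arithmetic
  res <- y - yhat
  expect_equal(gs$mse, sum(res^2) / n)
  rssw <- sum(w * res^2)
  ll <- 0.5 * sum(log(w)) - n / 2 * (log(2 * pi) + 1 + log(rssw / n))
  expect_equal(gs$logLik, ll)
  expect_equal(gs$p, 4L)
  expect_equal(gs$aic, 2 * 4 - 2 * ll)
  expect_equal(gs$aicc, gs$aic + 2 * 4 * 5 / (n - 4 - 1))
  ## penalty monotonicity at equal likelihood
  gs2 <- goodnessStats(y, yhat, w, nCoef = 4)
  expect_gt(gs2$aic, gs$aic)
  ## AICc needs n > p + 1
  expect_error(goodnessStats(y[1:5], yhat[1:5], w[1:5], nCoef = 4),
               class = "anisosim_aicc_undefined")
  expect_equal(goodnessStats(y, y, w, nCoef = 3)$mse, 0)
})

test_that("Akaike weights are a proper softmax of -AICc/2", {
  expect_equal(akaikeWeights(5), 1)
  expect_equal(akaikeWeights(c(3, 3)), c(0.5, 0.5))
  w <- akaikeWeights(c(10, 12))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  set.seed(81)
  a <- stats::rnorm(6, 100, 10)
  expect_equal(sum(akaikeWeights(a)), 1, tolerance = 1e-9)
  expect_equal(akaikeWeights(a), akaikeWeights(a + 57.3), tolerance = 1e-12)
})

test_that("model selection prefers the generating rational family", {
  set.seed(82)
  ages <- stats::runif(300, 0, 19)
  y <- (1.3 * ages + 1.0) / (ages + 1.2) + stats::rnorm(300, 0, 0.02)
  sel <- selectGrowthModel(ages, y)
  expect_equal(sel$best, "rational")
  expect_equal(sum(sel$table$akaikeWeight), 1, tolerance = 1e-9)
  expect_gte(sel$fits$rational@akaikeWeight, 0.5)
  ## the comparison table is sorted by AICc and complete
  expect_equal(sel$table$family[1], "rational")
  expect_setequal(sel$table$family, c("rational", "weibull", "gompertz", "exponential"))
})

test_that("exponential data select an exponential-like family at large n", {
  set.seed(83)
  ages <- stats::runif(400, 0, 19)
  y <- 1.5 - 0.5 * exp(-0.8 * ages) + stats::rnorm(400, 0, 0.02)
  sel <- selectGrowthModel(ages, y)
  ## weibull with d = 1 and gompertz can mimic the exponential; demand only
  ## that the exponential itself is not rejected by a large margin
  expect_lt(sel$fits$exponential@aicc - min(sel$table$aicc), 6)
})

test_that("small samples fall back to parsimonious families via AICc", {
  ages <- c(0, 2, 5, 9, 14, 19)
  y <- (1.3 * ages + 1.0) / (ages + 1.2)
  sel <- selectGrowthModel(ages, y)
  ## weibull (4 coefficients) cannot even be fit at n = 6; 3-parameter
  ## families compete
  expect_true("weibull" %in% sel$failed)
  expect_true(sel$best %in% c("rational", "gompertz", "exponential"))
})

test_that("bootstrap confidence bands are deterministic and shrink with noise", {
  set.seed(84)
  ages <- stats::runif(80, 0, 19)
  mkfit <- function(sd) {
    y <- (1.3 * ages + 1.0) / (ages + 1.2) + stats::rnorm(80, 0, sd)
    fitGrowthModel("rational", ages, y)
  }
  fitLo <- mkfit(0.005)
  set.seed(84)  # same ages, fresh noise draw for the wider case
  ages2 <- ages
  fitHi <- mkfit(0.05)
  bLo <- confidenceBands(fitLo, nBoot = 120, seed = 3)
  bHi <- confidenceBands(fitHi, nBoot = 120, seed = 3)
  expect_lt(mean(bLo$upper - bLo$lower), mean(bHi$upper - bHi$lower))
  expect_identical(bLo, confidenceBands(fitLo, nBoot = 120, seed = 3))
  expect_equal(attr(bLo, "bandType"), "pointwise bootstrap")
  ## the band brackets its own fit
  expect_true(all(bLo$lower <= bLo$fit + 1e-9 & bLo$fit <= bLo$upper + 1e-9))
})

test_that("band coverage on synthetic rational data is near nominal", {
  set.seed(85)
  ages <- stats::runif(60, 0, 19)
  grid <- seq(0.5, 18.5, length.out = 25)
  truth <- (1.3 * grid + 1.0) / (grid + 1.2)
  hit <- 0
  nRep <- 12
  for (r in seq_len(nRep)) {
    y <- (1.3 * ages + 1.0) / (ages + 1.2) + stats::rnorm(60, 0, 0.02)
    fit <- fitGrowthModel("rational", ages, y)
    b <- confidenceBands(fit, level = 0.99, nBoot = 150, seed = r, gridAges = grid)
    hit <- hit + mean(b$lower <= truth & truth <= b$upper)
  }
  expect_gte(hit / nRep, 0.9)
})
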