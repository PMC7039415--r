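test_that("scaling factors are extracted only from anisotropic fits", {
  set.seed(91)
  g <- rAnisoTransform(sRange = c(0.8, 1.4))
  x <- matrix(stats::runif(30, -20, 20), 10, 3)
  pts <- pairedPointSet(x, applyTransform(g$transform, x))
  fit <- fitAnisotropicSimilarity(pts, g$U)
  expect_equal(extractScalingFactors(fit), g$S, tolerance = 1e-6)
  expect_error(extractScalingFactors(fitRigid(pts)), class = "anisosim_wrong_kind")
  ## identity fit: factors are all 1
  idFit <- fitAnisotropicSimilarity(pairedPointSet(x, x), g$U)
  expect_equal(extractScalingFactors(idFit), c(1, 1, 1), tolerance = 1e-9)
})

test_that("composition with a global similarity multiplies the factors", {
  set.seed(92)
  g <- rAnisoTransform(sRange = c(0.9, 1.2))
  comp <- composeTransforms(linearTransform3D(2 * rRotation()), g$transform)
  d <- scalingsInFrame(linearPart(comp), g$U)
  expect_equal(scalings(d), 2 * g$S, tolerance = 1e-9)
})

test_that("baseline normalization rescales each (roi, direction) cell", {
  rec <- data.frame(
    subject = c("n1", "n2", "s1"), age = c(0.02, 0.05, 10),
    sex = c("male", "female", "male"), roi = "wb", direction = 1,
    reference = "ref1", scaling = c(0.5, 0.5, 1.0))
  out <- normalizeToBaseline(rec, c("n1", "n2"))
  expect_equal(out$scaling, c(1, 1, 2))

  ## all subjects baseline: every cell mean becomes exactly 1
  cohort <- makeCohort(defaultCohortSpec(n = 40, seed = 5))
  allNorm <- normalizeToBaseline(cohort$records, unique(cohort$records$subject))
  means <- tapply(allNorm$scaling,
                  interaction(allNorm$roi, allNorm$direction), mean)
  expect_equal(unname(as.numeric(means)), rep(1, length(means)), tolerance = 1e-12)

  ## idempotence after the first application
  norm1 <- normalizeToBaseline(cohort$records, cohort$baselineSubjects)
  norm2 <- normalizeToBaseline(norm1, cohort$baselineSubjects)
  expect_equal(norm2$scaling, norm1$scaling, tolerance = 1e-12)

  ## empty baseline cell is an error naming the cell
  expect_error(normalizeToBaseline(rec, "absent"), class = "anisosim_empty_baseline")
})

test_that("normalized synthetic cohorts recover expansion from birth", {
  spec <- defaultCohortSpec(n = 150, sigma = 0.02, seed = 6)
  cohort <- makeCohort(spec)
  norm <- normalizeToBaseline(cohort$records, cohort$baselineSubjects)
  ## normalized factors track curve(age) / mean baseline curve value
  isBase <- norm$subject %in% cohort$baselineSubjects
  for (d in 1:3) {
    cf <- spec$truth[[as.character(d)]]$coefficients
    sel <- norm$direction == d
    baseAges <- norm$age[sel & isBase]
    predicted <- growthCurve("rational", norm$age[sel], cf) /
      mean(growthCurve("rational", baseAges, cf))
    ratio <- norm$scaling[sel] / predicted
    expect_equal(mean(ratio), 1, tolerance = 0.01)
    ## the generator grows: expansion from birth exceeds 1 at late ages
    expect_gt(mean(norm$scaling[sel & norm$age > 15]), 1.2)
  }
})

test_that("group comparison handles null, shifted and degenerate cells", {
  ## identical multisets: p = 1, d = 0
  rec <- data.frame(
    subject = sprintf("s%02d", 1:12), age = rep(3, 12),
    sex = rep(c("male", "female"), each = 6), roi = "wb", direction = 1,
    reference = "ref1",
    scaling = c(1.0, 1.1, 1.2, 1.3, 1.4, 1.5, 1.0, 1.1, 1.2, 1.3, 1.4, 1.5))
  out <- compareGroups(rec, breaks = c(0, 6))
  expect_equal(out$pValue, 1)
  expect_equal(out$effectSize, 0)
  expect_false(out$rejected)

  ## direct effect-size example: medians 2 vs 1, sds 1 each -> d = 0.5
  rec2 <- rec
  rec2$scaling <- c(1, 2, 3, 1, 2, 3, 0.5, 1, 2, 0.5, 1, 2)
  rec2$scaling[rec2$sex == "female"] <- c(0, 1, 2, 0, 1, 2) + 1e-9  # keep > 0
  sm <- rec2$scaling[rec2$sex == "male"]
  sf <- rec2$scaling[rec2$sex == "female"]
  out2 <- compareGroups(rec2, breaks = c(0, 6))
  expect_equal(out2$effectSize,
               (stats::median(sm) - stats::median(sf)) / (stats::sd(sm) + stats::sd(sf)))

  ## empty group: cell skipped with a warning
  rec3 <- rec[rec$sex == "male", ]
  expect_error(expect_warning(compareGroups(rec3, breaks = c(0, 6)), "empty group"),
               class = "anisosim_empty_baseline")

  ## small cells are flagged
  rec4 <- rec[c(1:2, 7:8), ]
  out4 <- suppressWarnings(compareGroups(rec4, breaks = c(0, 6)))
  expect_true(out4$flagged)
})

test_that("BH decisions match the brute-force step-up oracle", {
  ## the documented example: reject exactly the two smallest
  p <- c(0.01, 0.02, 0.04, 0.2)
  expect_equal(bhOracle(p, 0.05), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(stats::p.adjust(p, "BH") <= 0.05, bhOracle(p, 0.05))
  set.seed(93)
  for (i in 1:500) {
    m <- sample(3:40, 1)
    p <- stats::runif(m)^sample(1:3, 1)
    expect_identical(stats::p.adjust(p, "BH") <= 0.05, bhOracle(p, 0.05))
  }
})

test_that("group comparison detects an injected sex effect", {
  ## power over replicates at n = 200, 5% male shift on direction 1
  set.seed(94)
  hits <- 0
  nRep <- 15
  for (r in seq_len(nRep)) {
    cohort <- makeCohort(defaultCohortSpec(n = 200, sigma = 0.03,
                                           sexEffect = c("1" = 1.05),
                                           seed = 1000 + r))
    norm <- normalizeToBaseline(cohort$records, cohort$baselineSubjects)
    out <- suppressWarnings(compareGroups(norm, cohort$baselineSubjects))
    hit <- any(out$rejected & out$direction == 1)
    falsePos <- any(out$rejected & out$direction != 1)
    hits <- hits + (hit && !falsePos)
  }
  expect_gte(hits / nRep, 0.8)
})

test_that("reference influence metrics match their definitions", {
  rec <- expand.grid(subject = c("s1", "s2"), roi = "wb", direction = 1:3,
                     reference = c("r1", "r2", "r3"), stringsAsFactors = FALSE)
  rec$age <- 5
  rec$sex <- "male"
  rec$scaling <- 1
  ## identical factors: all distances zero
  out <- referenceInfluence(rec)
  expect_true(all(out$pairwise$distance == 0))
  expect_true(all(out$dispersion$relativeSD == 0))

  ## direct two-reference example: 1.1 vs 0.9 -> D = 0.2
  rec2 <- rec[rec$reference != "r3" & rec$direction == 1, ]
  rec2$scaling <- ifelse(rec2$reference == "r1", 1.1, 0.9)
  out2 <- referenceInfluence(rec2)
  expect_equal(out2$pairwise$distance, rep(0.2, 2))

  ## incomplete cells are excluded and counted
  rec3 <- rec[-1, ]
  out3 <- referenceInfluence(rec3)
  expect_equal(out3$nExcluded, 1)

  ## multiplicative jitter of known scale is recovered by the median D
  set.seed(95)
  n <- 400
  sigma <- 0.05
  recJ <- expand.grid(subject = sprintf("s%03d", 1:n), roi = "wb", direction = 1,
                      reference = c("r1", "r2", "r3"), stringsAsFactors = FALSE)
  recJ$age <- 5; recJ$sex <- "male"
  recJ$scaling <- exp(stats::rnorm(nrow(recJ), 0, sigma))
  outJ <- referenceInfluence(recJ)
  ## relative SD of 3 lognormal draws concentrates near sigma
  expect_equal(stats::median(outJ$dispersion$relativeSD), sigma, tolerance = 0.2)
})

test_that("scaling record CSV round-trips", {
  cohort <- makeCohort(defaultCohortSpec(n = 20, seed = 7))
  path <- tempfile(fileext = ".csv")
  writeScalingRecords(cohort$records, path)
  back <- readScalingRecords(path)
  expect_equal(back$scaling, cohort$records$scaling, tolerance = 1e-12)
  expect_equal(back$subject, cohort$records$subject)
})
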