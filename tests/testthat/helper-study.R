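## Build a small synthetic study on disk: a reference phantom, a whole-brain
## ROI mask, subject images warped by known anisotropic similarities about
## the frame the pipeline itself will compute, and the cohort/config files
## runPipeline() consumes. Returns ground truth alongside the paths.
makeTinyStudy <- function(dir, nSubjects = 4, dim = 32L, spacing = 5,
                          selfOnly = TRUE, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- defaultPhantomSpec(dim = dim, spacing = spacing)
  ph <- makePhantom(spec)
  refPath <- file.path(dir, "ref.nii.gz")
  maskPath <- file.path(dir, "wb_mask.nii.gz")
  writeImage(ph$image, refPath)
  writeImage(image3D(Reduce(`|`, ph$masks) * 1, imageAffine(ph$image)), maskPath)

  refMasked <- image3D(imageData(ph$image), imageAffine(ph$image),
                       mask = Reduce(`|`, ph$masks))
  plane <- estimateMidsagittalPlane(refMasked)
  U <- frameMatrix(computeScalingFrame(refMasked, plane))

  set.seed(seed)
  nNeo <- 2L
  ages <- c(stats::runif(nNeo, 0, 0.1),
            sort(stats::runif(nSubjects - nNeo, 1, 19)))
  sexes <- rep(c("male", "female"), length.out = nSubjects)
  ids <- sprintf("subj%02d", seq_len(nSubjects))
  truth <- matrix(1, nSubjects, 3)
  paths <- character(nSubjects)
  cohortSpec <- defaultCohortSpec()
  for (i in seq_len(nSubjects)) {
    if (selfOnly) {
      S <- c(1, 1, 1)
    } else {
      S <- vapply(1:3, function(d) {
        tr <- cohortSpec$truth[[as.character(d)]]
        growthCurve(tr$family, ages[i], tr$coefficients)
      }, numeric(1))
    }
    truth[i, ] <- S
    Tgt <- linearTransform3D(U %*% diag(S) %*% t(U), stats::runif(3, -3, 3))
    paths[i] <- file.path(dir, paste0(ids[i], ".nii.gz"))
    writeImage(transformPhantom(spec, Tgt)$image, paths[i])
  }
  cohort <- data.frame(subject = ids, age = ages, sex = sexes, image = paths,
                       baseline = seq_len(nSubjects) <= nNeo)
  cohortPath <- file.path(dir, "cohort.csv")
  utils::write.csv(cohort, cohortPath, row.names = FALSE)
  config <- list(
    reference = refPath,
    rois = list(whole_brain = maskPath),
    frame = "computed",
    cohort = cohortPath,
    registration = list(pyramid_levels = 2L),
    analyses = list("fit_growth", "compare_groups"),
    output = file.path(dir, "out"),
    seed = seed)
  configPath <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, configPath)
  list(config = configPath, configList = config, truth = truth, U = U,
       ids = ids, ages = ages, baseline = ids[seq_len(nNeo)])
}
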