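#' @include AllClasses.R accessors.R blockmatch.R frame.R growth.R scaling.R
NULL

.pipelineKeys <- c("reference", "rois", "frame", "cohort", "baseline_subjects",
                   "registration", "analyses", "output", "seed")
.registrationKeys <- c("block_size", "block_spacing", "search_radius",
                       "keep_fraction", "pyramid_levels", "max_outer_iterations",
                       "score_threshold")

#' Validate a pipeline configuration
#'
#' Checks key names (unknown keys are errors), required fields, and existence
#' of the referenced files. Returns the parsed configuration invisibly;
#' errors collect every problem found.
#'
#' @param config a YAML file path or a configuration list.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) .asError(paste("config not found:", config), "bad_config")
    config <- yaml::read_yaml(config)
  }
  errs <- character(0)
  unknown <- setdiff(names(config), .pipelineKeys)
  if (length(unknown)) errs <- c(errs, paste("unknown key(s):", paste(unknown, collapse = ", ")))
  for (k in c("reference", "rois", "cohort", "output"))
    if (is.null(config[[k]])) errs <- c(errs, paste("missing required key:", k))
  if (!is.null(config$reference) && !file.exists(config$reference))
    errs <- c(errs, paste("reference image not found:", config$reference))
  if (!is.null(config$rois)) {
    if (is.null(names(config$rois)) || anyDuplicated(names(config$rois)))
      errs <- c(errs, "rois must be a uniquely named map of ROI id -> mask path")
    for (p in unlist(config$rois))
      if (!file.exists(p)) errs <- c(errs, paste("ROI mask not found:", p))
  }
  if (!is.null(config$cohort) && !file.exists(config$cohort))
    errs <- c(errs, paste("cohort table not found:", config$cohort))
  if (!is.null(config$frame) && !identical(config$frame, "computed") &&
      !file.exists(config$frame))
    errs <- c(errs, paste("frame file not found:", config$frame))
  if (!is.null(config$registration)) {
    unknownR <- setdiff(names(config$registration), .registrationKeys)
    if (length(unknownR))
      errs <- c(errs, paste("unknown registration key(s):", paste(unknownR, collapse = ", ")))
  }
  if (length(errs))
    .asError(paste0("invalid configuration:\n  - ", paste(errs, collapse = "\n  - ")),
             "bad_config")
  invisible(config)
}

.configRegistration <- function(reg) {
  if (is.null(reg)) return(registrationConfig())
  registrationConfig(
    blockSize = reg$block_size %||% 5L,
    blockSpacing = reg$block_spacing %||% 2L,
    searchRadius = reg$search_radius %||% 3L,
    keepFraction = reg$keep_fraction %||% 0.75,
    pyramidLevels = reg$pyramid_levels %||% 3L,
    maxOuterIterations = reg$max_outer_iterations %||% 10L,
    scoreThreshold = reg$score_threshold %||% 0.01)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the scaling-factor extraction and analysis pipeline
#'
#' End-to-end driver: computes (or loads) the constrained scaling frame on
#' the reference image, runs the two-step ROI registration for every subject
#' and ROI, writes the relative scaling records, normalizes them to the
#' baseline (neonate) group, and runs the requested analyses (growth-model
#' selection per ROI and direction with gender-balance weights, and/or
#' male-female group comparisons with BH-FDR control). A manifest records the
#' package version, seed, configuration hash and any per-subject failures
#' (which are logged and skipped, not fatal).
#'
#' The cohort CSV must have columns subject, age, sex, image (path to the
#' subject NIfTI), and optionally baseline (logical; otherwise
#' `baseline_subjects` lists the baseline group).
#'
#' @param config YAML path or configuration list (see [validateConfig()]).
#' @param verbose print progress.
#' @return (invisibly) the output directory path.
#' @export
runPipeline <- function(config, verbose = FALSE) {
  configPath <- if (is.character(config)) config else NULL
  config <- validateConfig(config)
  set.seed(config$seed %||% 0L)
  out <- config$output
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "transforms"), showWarnings = FALSE)

  ref <- readImage(config$reference)
  rois <- lapply(config$rois, function(p) readImage(p)@data != 0)
  refMasked <- image3D(ref@data, ref@affine, mask = Reduce(`|`, rois))

  if (is.null(config$frame) || identical(config$frame, "computed")) {
    plane <- estimateMidsagittalPlane(refMasked)
    frame <- computeScalingFrame(refMasked, plane)
  } else {
    frame <- readTransform(config$frame)$frame
    if (is.null(frame)) .asError("frame file carries no frame_U", "bad_config")
  }
  writeTransform(identityTransform(), file.path(out, "frame.json"),
                 kind = "anisotropic_similarity", frame = frame)

  cohort <- utils::read.csv(config$cohort, stringsAsFactors = FALSE)
  need <- c("subject", "age", "sex", "image")
  if (length(setdiff(need, names(cohort))))
    .asError("cohort table must have columns subject, age, sex, image", "bad_config")
  baseline <- if (!is.null(config$baseline_subjects)) unlist(config$baseline_subjects)
              else if ("baseline" %in% names(cohort)) cohort$subject[cohort$baseline]
              else .asError("no baseline group given", "bad_config")

  cfg <- .configRegistration(config$registration)
  records <- NULL
  failures <- character(0)
  logLines <- character(0)
  for (i in seq_len(nrow(cohort))) {
    subj <- cohort$subject[i]
    res <- tryCatch({
      mov <- readImage(cohort$image[i])
      lapply(names(rois), function(roiId) {
        reg <- twoStepRoiRegistration(mov, refMasked, rois[[roiId]], frame, cfg)
        writeTransform(reg$total, file.path(out, "transforms",
                                            paste0(subj, "_", roiId, ".json")))
        logLines <<- c(logLines, sprintf(
          "%s\t%s\tcost=%.8g\titerations=%d\tscalings=%.8g,%.8g,%.8g",
          subj, roiId, finalCost(reg$total), reg$total@nIterations,
          reg$scalings[1], reg$scalings[2], reg$scalings[3]))
        data.frame(subject = subj, age = cohort$age[i], sex = cohort$sex[i],
                   roi = roiId, direction = 1:3, reference = "reference",
                   scaling = reg$scalings)
      })
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      warning(sprintf("subject %s failed: %s", subj, res))
      failures <- c(failures, subj)
      logLines <- c(logLines, sprintf("%s\tFAILED\t%s", subj, res))
    } else {
      records <- rbind(records, do.call(rbind, res))
    }
    if (verbose) message(sprintf("subject %s done (%d/%d)", subj, i, nrow(cohort)))
  }
  writeLines(logLines, file.path(out, "pipeline.log"))
  if (is.null(records)) .asError("every subject failed", "registration_failed")
  writeScalingRecords(records, file.path(out, "relative_scalings.csv"))
  absRecords <- normalizeToBaseline(records, baseline)
  writeScalingRecords(absRecords, file.path(out, "absolute_scalings.csv"))

  analyses <- unlist(config$analyses %||% character(0))
  if ("fit_growth" %in% analyses) {
    fits <- list()
    for (roi in unique(absRecords$roi)) for (d in 1:3) {
      sub <- absRecords[absRecords$roi == roi & absRecords$direction == d, ]
      w <- genderBalanceWeights(sub$age, sub$sex)
      sel <- tryCatch(selectGrowthModel(sub$age, sub$scaling, w),
                      error = function(e) NULL)
      if (!is.null(sel))
        fits[[paste0(roi, ".d", d)]] <- list(best = sel$best, table = sel$table,
          coefficients = as.list(sel$fits[[sel$best]]@coefficients))
    }
    jsonlite::write_json(fits, file.path(out, "growth_fits.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if ("compare_groups" %in% analyses) {
    tests <- tryCatch(compareGroups(absRecords, baseline), error = function(e) NULL)
    if (!is.null(tests))
      utils::write.csv(tests, file.path(out, "group_tests.csv"), row.names = FALSE)
  }

  manifest <- list(
    package = "anisosim",
    version = as.character(utils::packageVersion("anisosim")),
    seed = config$seed %||% 0L,
    configHash = if (!is.null(configPath)) unname(tools::md5sum(configPath)) else NA,
    nSubjects = nrow(cohort), failures = failures)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Convert a transform file between formats
#'
#' Supported formats: "json" (the package dialect) and "txt" (a plain 4x4
#' homogeneous matrix). Conversion to txt drops frame/scaling metadata.
#'
#' @param input,output file paths; formats inferred from the extensions.
#' @export
convertTransform <- function(input, output) {
  inFmt <- tools::file_ext(input)
  outFmt <- tools::file_ext(output)
  tr <- if (inFmt == "json") readTransform(input)
        else if (inFmt == "txt") {
          m <- as.matrix(utils::read.table(input))
          list(transform = linearTransform3D(m[1:3, 1:3], m[1:3, 4]),
               kind = "affine", frame = NULL, scalings = NULL)
        } else .asError(paste("unsupported input format:", inFmt), "bad_config")
  if (outFmt == "json") {
    writeTransform(tr$transform, output, kind = tr$kind, frame = tr$frame,
                   scalings = tr$scalings)
  } else if (outFmt == "txt") {
    m <- rbind(cbind(tr$transform@matrix, tr$transform@translation), c(0, 0, 0, 1))
    utils::write.table(format(m, digits = 17), output, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  } else .asError(paste("unsupported output format:", outFmt), "bad_config")
  invisible(output)
}
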