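PIPELINE_DEFAULTS <- list(
  samples = NULL, covariates = NULL, gmv_dir = NULL, atlas = NULL,
  expression = NULL, out = NULL,
  auc_variant = "i", t_test = "pooled", z_threshold = 3,
  volume_floor_ul = 200, timing_tolerance_min = 15,
  fwhm_mm = 8, p_max = 0.01, alpha = 0.05, spacing = "linear",
  direction = "pos", min_cluster_voxels = 1, seed = 1
)

#' Default pipeline configuration
#'
#' Defaults mirror the study protocol where it states them: 8-mm FWHM
#' smoothing, 200 ul saliva-volume floor, 15-minute timing tolerance,
#' threshold endpoints P<0.01 uncorrected and P<0.05
#' Bonferroni-corrected within the mask, |z| > 3 outlier screen, pooled
#' two-tailed t-tests.
#'
#' @param ... overrides of default keys.
#' @return named list.
#' @export
defaultConfig <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(PIPELINE_DEFAULTS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- PIPELINE_DEFAULTS
  cfg[names(over)] <- over
  .validateConfig(cfg)
}

.validateConfig <- function(cfg) {
  chk <- function(key, allowed) {
    if (!cfg[[key]] %in% allowed)
      stop("config key '", key, "' must be one of: ",
           paste(allowed, collapse = ", "))
  }
  chk("auc_variant", c("g", "i"))
  chk("t_test", c("pooled", "welch"))
  chk("spacing", c("linear", "log"))
  chk("direction", c("pos", "neg"))
  num <- c("z_threshold", "volume_floor_ul", "timing_tolerance_min",
           "fwhm_mm", "p_max", "alpha", "min_cluster_voxels", "seed")
  for (key in num)
    if (!is.numeric(cfg[[key]]) || length(cfg[[key]]) != 1L ||
        !is.finite(cfg[[key]]))
      stop("config key '", key, "' must be a single finite number")
  if (cfg$fwhm_mm < 0) stop("config key 'fwhm_mm' must be >= 0")
  cfg
}

#' Load and validate a pipeline configuration file
#'
#' YAML config; unknown keys are rejected by name, missing keys are
#' filled with the defaults of [defaultConfig()].
#'
#' @param path YAML file path.
#' @return validated config list.
#' @export
loadValidateConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(PIPELINE_DEFAULTS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- PIPELINE_DEFAULTS
  cfg[names(raw)] <- raw
  .validateConfig(cfg)
}

#' Save a pipeline configuration as YAML
#'
#' @param cfg config list.
#' @param path output path.
#' @return the path, invisibly.
#' @export
saveConfig <- function(cfg, path) {
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}

.configHash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  saveConfig(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full diathesis-stress VBM pipeline
#'
#' Orchestrates, in protocol order: saliva QC and CAR quantification;
#' group comparisons of the CAR (full sample, after standard-score
#' outlier exclusion, and transition subgroup vs controls); smoothing,
#' proportional scaling and the voxelwise GLM for the CAR correlation
#' and the group-by-CAR interaction; construction of the GR/MR
#' expression-ranked threshold map; and flexible thresholding with
#' per-region reports (CAR correlation in the configured direction; the
#' interaction in both directions). Deterministic given inputs and
#' config; emits a provenance record with the config hash, seed and the
#' exclusion list.
#'
#' @param samples long-format cortisol sample table.
#' @param covariates covariate table (subject_id, group, age, gender,
#'   antidepressant, transition).
#' @param stack a [GmvStack] of the QC-retained subjects (extra subjects
#'   are dropped to the QC-passing intersection).
#' @param expression sample-level GR/MR expression table.
#' @param atlas a [LabelAtlas] on the stack grid.
#' @param config list from [defaultConfig()] or [loadValidateConfig()].
#' @return list with car (per-subject CAR/QC table), groupStats,
#'   outliers, thresholdMap, statCar, statInteraction, carResults,
#'   interactionPos, interactionNeg, mask, provenance.
#' @export
runPipeline <- function(samples, covariates, stack, expression, atlas,
                        config = defaultConfig()) {
  config <- .validateConfig(config)
  car <- carTable(samples, config$volume_floor_ul,
                  config$timing_tolerance_min)
  retained <- car$subject_id[car$qc_pass]
  if (!length(retained)) stop("empty cohort: every subject failed QC")
  excluded <- car[!car$qc_pass, c("subject_id", "qc_reasons")]
  aucCol <- if (config$auc_variant == "g") "auc_g" else "auc_i"
  carVal <- setNames(car[[aucCol]], car$subject_id)

  cov <- covariates[covariates$subject_id %in% retained, , drop = FALSE]
  cov$car <- as.numeric(carVal[as.character(cov$subject_id)])
  isUhr <- cov$group %in% c("UHR", "uhr", "1", 1)

  testFun <- function(a, b) groupTTest(a, b, method = config$t_test)
  groupStats <- list(full = testFun(cov$car[isUhr], cov$car[!isUhr]))
  outliers <- detectOutliers(cov$car[isUhr], config$z_threshold)
  outliers$subject_id <- cov$subject_id[isUhr]
  flagged <- outliers$subject_id[outliers$outlier]
  if (length(flagged)) {
    keep <- isUhr & !cov$subject_id %in% flagged
    groupStats$outlier_excluded <- testFun(cov$car[keep], cov$car[!isUhr])
  }
  isTrans <- isUhr & cov$transition == 1
  if (sum(isTrans) >= 2)
    groupStats$transition_vs_controls <-
      testFun(cov$car[isTrans], cov$car[!isUhr])

  # image pathway: subjects present in both the stack and the retained set
  ids <- intersect(subjectIds(stack), cov$subject_id)
  if (length(ids) < nSubjects(stack) || length(ids) < nrow(cov)) {
    v <- voxelData(stack)[, , , match(ids, subjectIds(stack)), drop = FALSE]
    stack <- gmvStack(v, voxelSize(stack), ids)
  }
  cov <- cov[match(subjectIds(stack), cov$subject_id), , drop = FALSE]

  stack <- smoothStack(stack, config$fwhm_mm)
  mask <- analysisMask(atlas, stack)
  stack <- proportionalScale(stack, mask)$stack

  design <- buildDesignMatrix(cov, "car", model = "car")
  statCar <- fitVoxelwiseGlm(stack, design, contrast = "car", mask = mask)
  statInteraction <- fitInteractionGlm(stack, cov, "car", mask = mask)

  thresholdMap <- buildThresholdMap(expression, atlas,
                                    nVoxelsMask = sum(mask),
                                    pMax = config$p_max,
                                    alpha = config$alpha,
                                    spacing = config$spacing)
  carResults <- applyThresholds(statCar, atlas, thresholdMap,
                                direction = config$direction,
                                minClusterVoxels = config$min_cluster_voxels)
  interactionPos <- applyThresholds(statInteraction, atlas, thresholdMap,
                                    direction = "pos",
                                    minClusterVoxels = config$min_cluster_voxels)
  interactionNeg <- applyThresholds(statInteraction, atlas, thresholdMap,
                                    direction = "neg",
                                    minClusterVoxels = config$min_cluster_voxels)

  provenance <- list(config = config[!vapply(config, is.null, logical(1))],
                     config_hash = .configHash(config),
                     seed = config$seed,
                     n_subjects_in = nrow(covariates),
                     n_subjects_retained = length(retained),
                     n_subjects_imaged = length(subjectIds(stack)),
                     excluded = excluded,
                     n_voxels_mask = sum(mask),
                     n_regions_covered = nrow(thresholdTable(thresholdMap)))
  list(car = car, groupStats = groupStats, outliers = outliers,
       thresholdMap = thresholdMap, statCar = statCar,
       statInteraction = statInteraction, carResults = carResults,
       interactionPos = interactionPos, interactionNeg = interactionNeg,
       mask = mask, provenance = provenance)
}

#' Write pipeline results to a directory
#'
#' Emits the CAR/QC table, region reports, threshold map, t-maps and the
#' provenance JSON.
#'
#' @param res list from [runPipeline()].
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writePipelineResults <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeTsv(res$car, file.path(dir, "car.tsv"))
  writeTsv(res$carResults$report, file.path(dir, "report_car.tsv"))
  writeTsv(res$interactionPos$report,
           file.path(dir, "report_interaction_pos.tsv"))
  writeTsv(res$interactionNeg$report,
           file.path(dir, "report_interaction_neg.tsv"))
  writeThresholdMap(res$thresholdMap, file.path(dir, "threshold_map.tsv"))
  writeStatMap(res$statCar, dir, "car")
  writeStatMap(res$statInteraction, dir, "interaction")
  prov <- res$provenance
  prov$excluded <- as.list(prov$excluded)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
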