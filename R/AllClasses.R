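#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' BrainVolume: a 3D scalar grid with voxel geometry
#'
#' Container for a single registered volume (grey-matter map, t-map,
#' per-voxel threshold map, ...) together with its voxel size in mm.
#' Images are assumed to be in a common space; registration is out of
#' scope for this package.
#'
#' @slot values 3D numeric array.
#' @slot voxelSize numeric(3), voxel edge lengths in mm.
#' @exportClass BrainVolume
setClass("BrainVolume",
  representation(values = "array", voxelSize = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3L)
      msg <- c(msg, "'values' must be a 3D array")
    if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
        any(object@voxelSize <= 0))
      msg <- c(msg, "'voxelSize' must be 3 positive finite numbers (mm)")
    if (length(msg)) msg else TRUE
  }
)

#' LabelAtlas: an integer region parcellation
#'
#' A [BrainVolume] whose voxel values are non-negative integer region
#' labels; 0 is background. Every non-background voxel carries exactly
#' one label.
#'
#' @exportClass LabelAtlas
setClass("LabelAtlas", contains = "BrainVolume",
  validity = function(object) {
    v <- object@values
    if (any(v != round(v)) || any(v < 0))
      return("atlas labels must be non-negative integers")
    TRUE
  }
)

#' GmvStack: per-subject grey-matter volumes on a common grid
#'
#' @slot values 4D array, subjects along the 4th dimension.
#' @slot voxelSize numeric(3), mm.
#' @slot subjectIds character, one id per subject.
#' @exportClass GmvStack
setClass("GmvStack",
  representation(values = "array", voxelSize = "numeric",
                 subjectIds = "character"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@values)) != 4L)
      msg <- c(msg, "'values' must be a 4D array (x, y, z, subject)")
    else if (dim(object@values)[4] != length(object@subjectIds))
      msg <- c(msg, "4th dimension must match length(subjectIds)")
    if (anyDuplicated(object@subjectIds))
      msg <- c(msg, "subject ids must be unique")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      msg <- c(msg, "'voxelSize' must be 3 positive numbers (mm)")
    if (length(msg)) msg else TRUE
  }
)

#' StatMap: voxelwise GLM results for one contrast
#'
#' @slot tValues 3D array of t statistics (may contain +/-Inf sentinels at
#'   zero-residual voxels and NA outside the analysis mask).
#' @slot betas named list of 3D arrays, one per model column.
#' @slot df residual degrees of freedom, constant over voxels.
#' @slot contrast human-readable contrast description.
#' @slot columns model column names in design order.
#' @slot voxelSize numeric(3), mm.
#' @exportClass StatMap
setClass("StatMap",
  representation(tValues = "array", betas = "list", df = "numeric",
                 contrast = "character", columns = "character",
                 voxelSize = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@tValues)) != 3L)
      msg <- c(msg, "'tValues' must be a 3D array")
    if (length(object@df) != 1L || object@df < 1)
      msg <- c(msg, "'df' must be a single value >= 1")
    if (length(msg)) msg else TRUE
  }
)

#' ThresholdMap: expression-ranked per-region p thresholds
#'
#' Output of the a priori receptor-expression mask: per atlas region the
#' combined GR/MR expression, its rank (1 = highest expression) and the
#' assigned voxelwise p threshold, linearly (default) spaced between
#' P<0.01 uncorrected (rank 1) and P<0.05 Bonferroni-corrected for the
#' in-mask voxel count (last rank).
#'
#' @slot scores data.frame with columns region_label, mean_gr, mean_mr,
#'   combined, rank, p_threshold.
#' @slot nVoxelsMask in-mask voxel count used as Bonferroni denominator.
#' @slot pMax lenient endpoint (0.01 uncorrected).
#' @slot pMin strict endpoint (0.05 / nVoxelsMask).
#' @slot spacing "linear" or "log".
#' @slot uncovered region labels excluded for lacking expression coverage.
#' @exportClass ThresholdMap
setClass("ThresholdMap",
  representation(scores = "data.frame", nVoxelsMask = "numeric",
                 pMax = "numeric", pMin = "numeric", spacing = "character",
                 uncovered = "numeric"),
  validity = function(object) {
    msg <- character()
    need <- c("region_label", "combined", "rank", "p_threshold")
    if (!all(need %in% names(object@scores)))
      msg <- c(msg, paste("scores must contain columns:",
                          paste(need, collapse = ", ")))
    if (object@nVoxelsMask < 1)
      msg <- c(msg, "'nVoxelsMask' must be >= 1")
    if (nrow(object@scores)) {
      p <- object@scores$p_threshold
      tol <- 1e-12
      if (any(p < object@pMin - tol) || any(p > object@pMax + tol))
        msg <- c(msg, "p thresholds must lie within [pMin, pMax]")
    }
    if (length(msg)) msg else TRUE
  }
)

#' SignificanceMap: thresholded voxelwise decision map
#'
#' @slot significant logical 3D array.
#' @slot pApplied 3D array of the per-voxel p threshold applied (NA
#'   outside the mask).
#' @slot direction "pos" or "neg" (one-sided test direction).
#' @exportClass SignificanceMap
setClass("SignificanceMap",
  representation(significant = "array", pApplied = "array",
                 direction = "character"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@significant), dim(object@pApplied)))
      msg <- c(msg, "'significant' and 'pApplied' must share a grid")
    if (!object@direction %in% c("pos", "neg"))
      msg <- c(msg, "'direction' must be 'pos' or 'neg'")
    ok <- object@significant & is.na(object@pApplied)
    if (any(ok, na.rm = TRUE))
      msg <- c(msg, "significant voxels must carry an applied threshold")
    if (length(msg)) msg else TRUE
  }
)

#' AtlasSpec: parameters for the synthetic label atlas
#'
#' @slot gridShape integer(3), voxels per axis.
#' @slot voxelSize numeric(3), mm.
#' @slot nRegions number of regions.
#' @slot seed RNG seed.
#' @exportClass AtlasSpec
setClass("AtlasSpec",
  representation(gridShape = "integer", voxelSize = "numeric",
                 nRegions = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@gridShape) != 3L || any(object@gridShape < 1))
      msg <- c(msg, "'gridShape' must be 3 positive integers")
    if (object@nRegions < 2L)
      msg <- c(msg, "'nRegions' must be >= 2")
    if (prod(object@gridShape) < object@nRegions)
      msg <- c(msg, "more regions than voxels")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      msg <- c(msg, "'voxelSize' must be 3 positive numbers (mm)")
    if (length(msg)) msg else TRUE
  }
)

#' CohortSpec: parameters for the synthetic cohort
#'
#' Group CAR distributions are given as mean/SD of the area-under-curve
#' measure in nmol.min/l; draws are truncated at 0 (the CAR is the
#' magnitude of a waking response, and planted negative values would be
#' confounded with the negative-delta30 exclusion).
#'
#' @slot nUhr,nControl group sizes.
#' @slot carMeanUhr,carSdUhr,carMeanControl,carSdControl AUC mean/SD per
#'   group, nmol.min/l.
#' @slot nTransition number of UHR subjects flagged as later transitioning
#'   to psychosis.
#' @slot outlierValue optional AUC planted on one UHR subject.
#' @slot nQcFailVolume,nQcFailTiming,nQcFailDelta30,nQcFailMissing planted
#'   QC-failure counts (low saliva volume, timing deviation, negative
#'   delta30, missing sample).
#' @slot ageRange numeric(2), years.
#' @slot antidepFraction proportion of UHR subjects on antidepressants.
#' @slot transitionAssignment "lowest" (default: the nTransition retained
#'   UHR subjects with lowest CAR) or "random" (for null tests).
#' @slot seed RNG seed.
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(nUhr = "integer", nControl = "integer",
                 carMeanUhr = "numeric", carSdUhr = "numeric",
                 carMeanControl = "numeric", carSdControl = "numeric",
                 nTransition = "integer", outlierValue = "numericOrNULL",
                 nQcFailVolume = "integer", nQcFailTiming = "integer",
                 nQcFailDelta30 = "integer", nQcFailMissing = "integer",
                 ageRange = "numeric", antidepFraction = "numeric",
                 transitionAssignment = "character", seed = "integer"),
  validity = function(object) {
    msg <- character()
    cnt <- c(object@nUhr, object@nControl, object@nTransition,
             object@nQcFailVolume, object@nQcFailTiming,
             object@nQcFailDelta30, object@nQcFailMissing)
    if (any(cnt < 0L)) msg <- c(msg, "counts must be >= 0")
    if (object@nTransition > object@nUhr)
      msg <- c(msg, "nTransition cannot exceed nUhr")
    if (object@carSdUhr < 0 || object@carSdControl < 0)
      msg <- c(msg, "group SDs must be >= 0")
    nFail <- object@nQcFailVolume + object@nQcFailTiming +
      object@nQcFailDelta30 + object@nQcFailMissing
    if (nFail > object@nUhr + object@nControl)
      msg <- c(msg, "more planted QC failures than subjects")
    if (length(object@ageRange) != 2L || diff(object@ageRange) < 0)
      msg <- c(msg, "'ageRange' must be increasing numeric(2)")
    if (object@antidepFraction < 0 || object@antidepFraction > 1)
      msg <- c(msg, "'antidepFraction' must be in [0, 1]")
    if (!object@transitionAssignment %in% c("lowest", "random"))
      msg <- c(msg, "'transitionAssignment' must be 'lowest' or 'random'")
    if (length(msg)) msg else TRUE
  }
)

#' EffectSpec: forward model for synthetic grey-matter volumes
#'
#' Voxel value = region baseline + region slope x CAR + covariate terms +
#' interaction slope x CAR (UHR subjects only, in interaction regions) +
#' i.i.d. Gaussian noise. Stands in for the unobservable true effect
#' structure the voxelwise GLM estimates, enabling parameter-recovery and
#' null-calibration tests.
#'
#' @slot effectRegions region labels carrying a CAR slope.
#' @slot slopePerRegion GMV units per nmol.min/l, recycled over
#'   effectRegions.
#' @slot interactionRegions region labels where the UHR slope differs.
#' @slot interactionSlopeDelta additional UHR slope, GMV units per
#'   nmol.min/l.
#' @slot covariateBetas named numeric: any of age, gender, antidepressant.
#' @slot noiseSd i.i.d. Gaussian noise SD, GMV units.
#' @slot baseline per-region baseline GMV (recycled over atlas regions).
#' @exportClass EffectSpec
setClass("EffectSpec",
  representation(effectRegions = "numeric", slopePerRegion = "numeric",
                 interactionRegions = "numeric",
                 interactionSlopeDelta = "numeric",
                 covariateBetas = "numeric", noiseSd = "numeric",
                 baseline = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be >= 0")
    if (length(object@effectRegions) &&
        length(object@slopePerRegion) == 0L)
      msg <- c(msg, "'slopePerRegion' required when effectRegions given")
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "BrainVolume", function(object) {
  cat(class(object), ": ", paste(dim(object@values), collapse = " x "),
      " grid, voxel ", paste(object@voxelSize, collapse = " x "),
      " mm\n", sep = "")
  if (is(object, "LabelAtlas"))
    cat("  regions: ", length(regionLabels(object)), "\n", sep = "")
})

setMethod("show", "GmvStack", function(object) {
  d <- dim(object@values)
  cat("GmvStack: ", d[4], " subjects on a ",
      paste(d[1:3], collapse = " x "), " grid\n", sep = "")
})

setMethod("show", "StatMap", function(object) {
  cat("StatMap: contrast '", object@contrast, "', df = ", object@df,
      "\n  model columns: ", paste(object@columns, collapse = ", "),
      "\n", sep = "")
})

setMethod("show", "ThresholdMap", function(object) {
  cat("ThresholdMap: ", nrow(object@scores), " regions, ",
      object@spacing, " spacing in [",
      format(object@pMin, digits = 3), ", ", format(object@pMax),
      "], Bonferroni denominator ", object@nVoxelsMask, " voxels\n",
      sep = "")
  if (length(object@uncovered))
    cat("  uncovered regions (no expression): ",
        paste(object@uncovered, collapse = ", "), "\n", sep = "")
})

setMethod("show", "SignificanceMap", function(object) {
  cat("SignificanceMap (", object@direction, "): ",
      sum(object@significant, na.rm = TRUE), " significant voxels\n",
      sep = "")
})
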