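#' @importFrom stats rnorm runif
NULL

#' Construct an AtlasSpec
#'
#' @param gridShape voxels per axis (length 3).
#' @param nRegions number of regions (>= 2).
#' @param voxelSize voxel edge lengths in mm.
#' @param seed RNG seed (atlas geometry is deterministic; the seed is
#'   recorded for provenance).
#' @return an [AtlasSpec].
#' @export
atlasSpec <- function(gridShape = c(16, 16, 16), nRegions = 8,
                      voxelSize = c(2, 2, 2), seed = 1) {
  new("AtlasSpec", gridShape = as.integer(rep_len(gridShape, 3L)),
      voxelSize = rep_len(as.numeric(voxelSize), 3L),
      nRegions = as.integer(nRegions), seed = as.integer(seed))
}

# recursive axis-aligned box splitting; each region is a connected block
.splitBox <- function(lab, lo, hi, labels) {
  n <- length(labels)
  if (n == 1L) {
    lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- labels
    return(lab)
  }
  ext <- hi - lo + 1L
  axis <- which.max(ext)
  n1 <- n %/% 2L
  n2 <- n - n1
  volPerSlice <- prod(ext[-axis])
  sLo <- ceiling(n1 / volPerSlice)
  sHi <- ext[axis] - ceiling(n2 / volPerSlice)
  s <- min(max(round(ext[axis] * n1 / n), sLo), sHi)
  hi1 <- hi; hi1[axis] <- lo[axis] + s - 1L
  lo2 <- lo; lo2[axis] <- lo[axis] + s
  lab <- .splitBox(lab, lo, hi1, labels[seq_len(n1)])
  .splitBox(lab, lo2, hi, labels[(n1 + 1L):n])
}

#' Generate a synthetic label atlas
#'
#' Partitions the grid into \code{nRegions} axis-aligned connected blocks
#' of near-equal size by recursive halving, the simplest connected
#' parcellation adequate for region-level thresholding semantics. Every
#' voxel carries exactly one label 1..nRegions (no background).
#'
#' @param spec an [AtlasSpec].
#' @return a [LabelAtlas].
#' @export
generateAtlas <- function(spec) {
  validObject(spec)
  lab <- array(0L, spec@gridShape)
  lab <- .splitBox(lab, c(1L, 1L, 1L), spec@gridShape,
                   seq_len(spec@nRegions))
  labelAtlas(lab, spec@voxelSize)
}

#' Generate a sample-level GR/MR expression table
#'
#' Emulates postmortem-donor microarray sampling: each donor contributes
#' at least one sampling site per region (the first region gets two, so
#' the within-region averaging path is exercised), each gene is targeted
#' by several probes, and expression = region mean + donor effect +
#' probe-level noise.
#'
#' @param atlas a [LabelAtlas] (or integer vector of region labels).
#' @param nDonors number of donors (>= 1; default 6 healthy adult
#'   brains).
#' @param nProbesPerGene probes targeting each gene (default 2).
#' @param regionMeans matrix (regions x 2, columns GR, MR, rows in
#'   region-label order) of true regional expression; NULL draws means
#'   uniformly in [5, 10].
#' @param probeSd SD of i.i.d. per-measurement noise.
#' @param donorSd SD of per-donor, per-gene random offsets.
#' @param seed RNG seed.
#' @return data.frame donor_id, probe_id, gene, region_label, expression.
#' @export
generateExpressionTable <- function(atlas, nDonors = 6,
                                    nProbesPerGene = 2,
                                    regionMeans = NULL,
                                    probeSd = 0.2, donorSd = 0.2,
                                    seed = 1) {
  if (nDonors < 1) stop("invalid spec: nDonors must be >= 1")
  if (nProbesPerGene < 1) stop("invalid spec: nProbesPerGene must be >= 1")
  regions <- if (is(atlas, "LabelAtlas")) regionLabels(atlas) else atlas
  set.seed(seed)
  if (is.null(regionMeans)) {
    regionMeans <- matrix(runif(2 * length(regions), 5, 10),
                          ncol = 2, dimnames = list(NULL, c("GR", "MR")))
  }
  donorEff <- matrix(rnorm(nDonors * 2, sd = donorSd), ncol = 2,
                     dimnames = list(NULL, c("GR", "MR")))
  rows <- list()
  for (d in seq_len(nDonors)) {
    for (ri in seq_along(regions)) {
      nSites <- if (ri == 1L) 2L else 1L
      for (site in seq_len(nSites)) {
        for (g in c("GR", "MR")) {
          for (p in seq_len(nProbesPerGene)) {
            rows[[length(rows) + 1L]] <- data.frame(
              donor_id = sprintf("D%02d", d),
              probe_id = sprintf("%s_probe%d", g, p),
              gene = g,
              region_label = regions[ri],
              expression = regionMeans[ri, g] + donorEff[d, g] +
                rnorm(1, sd = probeSd))
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Construct a CohortSpec
#'
#' Defaults mirror the study conditions: 26 ultra-high-risk and 17
#' control subjects aged 18-30, UHR CAR mean (SD) 223.84 (233.52) and
#' control 320.97 (253.85) nmol.min/l, 4 later transitions, 4 planted
#' QC failures (one of each kind; four subjects were excluded for poor
#' sampling quality, the per-rule breakdown being unreported) and an
#' antidepressant fraction of 5/26 (UHR only).
#'
#' @param nUhr,nControl group sizes.
#' @param carMeanUhr,carSdUhr,carMeanControl,carSdControl AUC mean/SD,
#'   nmol.min/l.
#' @param nTransition UHR subjects flagged as transitioning.
#' @param outlierValue optional extreme AUC planted on one retained UHR
#'   subject.
#' @param nQcFailVolume,nQcFailTiming,nQcFailDelta30,nQcFailMissing
#'   planted QC-failure counts.
#' @param ageRange numeric(2), years.
#' @param antidepFraction proportion of UHR subjects on antidepressants.
#' @param transitionAssignment "lowest" or "random".
#' @param seed RNG seed.
#' @return a [CohortSpec].
#' @export
cohortSpec <- function(nUhr = 26, nControl = 17,
                       carMeanUhr = 223.84, carSdUhr = 233.52,
                       carMeanControl = 320.97, carSdControl = 253.85,
                       nTransition = 4, outlierValue = NULL,
                       nQcFailVolume = 1, nQcFailTiming = 1,
                       nQcFailDelta30 = 1, nQcFailMissing = 1,
                       ageRange = c(18, 30), antidepFraction = 5 / 26,
                       transitionAssignment = c("lowest", "random"),
                       seed = 1) {
  new("CohortSpec", nUhr = as.integer(nUhr), nControl = as.integer(nControl),
      carMeanUhr = carMeanUhr, carSdUhr = carSdUhr,
      carMeanControl = carMeanControl, carSdControl = carSdControl,
      nTransition = as.integer(nTransition),
      outlierValue = if (is.null(outlierValue)) NULL
                     else as.numeric(outlierValue),
      nQcFailVolume = as.integer(nQcFailVolume),
      nQcFailTiming = as.integer(nQcFailTiming),
      nQcFailDelta30 = as.integer(nQcFailDelta30),
      nQcFailMissing = as.integer(nQcFailMissing),
      ageRange = as.numeric(ageRange),
      antidepFraction = antidepFraction,
      transitionAssignment = match.arg(transitionAssignment),
      seed = as.integer(seed))
}

.truncNorm <- function(n, mean, sd) {
  if (sd == 0) return(rep(max(mean, 0), n))
  x <- rnorm(n, mean, sd)
  while (any(x < 0)) x[x < 0] <- rnorm(sum(x < 0), mean, sd)
  x
}

#' Generate a synthetic cohort: covariates and cortisol sample tables
#'
#' Per-subject CAR values (AUCi, the pipeline's default measure) are
#' drawn from the group distributions truncated at 0, then a consistent
#' three-point concentration triple is synthesised around a waking
#' baseline: c30 = c0 + r and c60 = c0 + r/2 with r = AUCi / 37.5, so
#' the AUC code path reconstructs the planted value exactly. Requested
#' QC failures (low volume, timing deviation, negative delta30, missing
#' sample) are planted on distinct subjects, UHR first, mirroring the
#' study's exclusions; if an outlier value is given it replaces one
#' retained UHR subject's CAR. Transition flags go to the
#' \code{nTransition} retained UHR subjects with lowest CAR (or at
#' random, for null tests).
#'
#' @param spec a [CohortSpec].
#' @return list with \code{covariates} (subject_id, group, age, gender,
#'   antidepressant, transition, car_true) and \code{samples} (long
#'   table: subject_id, nominal_time_min, actual_time_min, volume_ul,
#'   cortisol_nmol_l).
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  set.seed(spec@seed)
  n <- spec@nUhr + spec@nControl
  ids <- c(sprintf("UHR-%02d", seq_len(spec@nUhr)),
           sprintf("CTRL-%02d", seq_len(spec@nControl)))
  group <- rep(c("UHR", "control"), c(spec@nUhr, spec@nControl))
  auc <- c(.truncNorm(spec@nUhr, spec@carMeanUhr, spec@carSdUhr),
           .truncNorm(spec@nControl, spec@carMeanControl,
                      spec@carSdControl))
  age <- runif(n, spec@ageRange[1], spec@ageRange[2])
  gender <- sample(0:1, n, replace = TRUE)
  antidep <- integer(n)
  nAd <- round(spec@antidepFraction * spec@nUhr)
  if (nAd > 0) antidep[sample(seq_len(spec@nUhr), nAd)] <- 1L

  nFail <- spec@nQcFailVolume + spec@nQcFailTiming +
    spec@nQcFailDelta30 + spec@nQcFailMissing
  failIdx <- seq_len(nFail)  # UHR first, then controls
  failType <- rep(c("volume", "timing", "delta30", "missing"),
                  c(spec@nQcFailVolume, spec@nQcFailTiming,
                    spec@nQcFailDelta30, spec@nQcFailMissing))
  retained <- setdiff(seq_len(n), failIdx)
  if (!is.null(spec@outlierValue)) {
    retainedUhr <- retained[retained <= spec@nUhr]
    if (!length(retainedUhr))
      stop("invalid spec: no retained UHR subject to carry the outlier")
    auc[max(retainedUhr)] <- spec@outlierValue
  }

  transition <- integer(n)
  if (spec@nTransition > 0) {
    candidates <- retained[retained <= spec@nUhr]
    if (length(candidates) < spec@nTransition)
      candidates <- seq_len(spec@nUhr)
    pick <- if (spec@transitionAssignment == "lowest")
      candidates[order(auc[candidates])][seq_len(spec@nTransition)]
    else sample(candidates, spec@nTransition)
    transition[pick] <- 1L
  }

  c0 <- .truncNorm(n, 10, 2)
  r <- auc / 37.5
  conc <- cbind(c0, c0 + r, c0 + r / 2)
  samples <- list()
  for (i in seq_len(n)) {
    tbl <- data.frame(subject_id = ids[i],
                      nominal_time_min = c(0, 30, 60),
                      actual_time_min = c(0, 30, 60),
                      volume_ul = 400,
                      cortisol_nmol_l = conc[i, ])
    if (i %in% failIdx) {
      tbl <- switch(failType[match(i, failIdx)],
        volume = { tbl$volume_ul[2] <- 150; tbl },
        timing = { tbl$actual_time_min[2] <- 50; tbl },
        delta30 = {
          tbl$cortisol_nmol_l[2] <- max(tbl$cortisol_nmol_l[1] - 2, 0)
          tbl
        },
        missing = tbl[-3, ])
    }
    samples[[i]] <- tbl
  }
  covariates <- data.frame(subject_id = ids, group = group, age = age,
                           gender = gender, antidepressant = antidep,
                           transition = transition, car_true = auc,
                           stringsAsFactors = FALSE)
  list(covariates = covariates, samples = do.call(rbind, samples))
}

#' Construct an EffectSpec
#'
#' @param effectRegions region labels carrying a CAR slope.
#' @param slopePerRegion slope(s) in GMV units per nmol.min/l, recycled
#'   over \code{effectRegions}.
#' @param interactionRegions region labels with a group-dependent slope.
#' @param interactionSlopeDelta additional UHR slope.
#' @param covariateBetas named numeric over age, gender, antidepressant.
#' @param noiseSd i.i.d. Gaussian noise SD, GMV units (default 0.05, a
#'   tenth of the baseline).
#' @param baseline per-region baseline GMV (default 0.5, typical of
#'   modulated grey-matter maps; recycled).
#' @return an [EffectSpec].
#' @export
effectSpec <- function(effectRegions = numeric(),
                       slopePerRegion = numeric(),
                       interactionRegions = numeric(),
                       interactionSlopeDelta = 0,
                       covariateBetas = c(age = 0, gender = 0,
                                          antidepressant = 0),
                       noiseSd = 0.05, baseline = 0.5) {
  new("EffectSpec", effectRegions = as.numeric(effectRegions),
      slopePerRegion = as.numeric(slopePerRegion),
      interactionRegions = as.numeric(interactionRegions),
      interactionSlopeDelta = interactionSlopeDelta,
      covariateBetas = covariateBetas, noiseSd = noiseSd,
      baseline = as.numeric(baseline))
}

#' Generate synthetic grey-matter volumes under a known forward model
#'
#' One volume per retained (QC-passing) subject: voxel value = region
#' baseline + region CAR slope x subject CAR + covariate terms + (UHR
#' only) interaction slope x CAR in interaction regions + i.i.d.
#' Gaussian noise. The planted CAR is the ground-truth value in
#' \code{cohort$covariates$car_true}, enabling exact noise-free
#' parameter recovery by the voxelwise GLM.
#'
#' @param cohort list from [generateCohort()].
#' @param atlas a [LabelAtlas].
#' @param effects an [EffectSpec]; effect and interaction regions must
#'   exist in the atlas.
#' @param seed RNG seed for the noise.
#' @return a [GmvStack] of the retained subjects, in covariate order.
#' @export
generateGmvImages <- function(cohort, atlas, effects, seed = 1) {
  validObject(effects)
  regions <- regionLabels(atlas)
  bad <- setdiff(c(effects@effectRegions, effects@interactionRegions),
                 regions)
  if (length(bad))
    stop("effect region(s) absent from atlas: ", paste(bad, collapse = ", "))
  qc <- qcFilter(cohort$samples)
  keep <- cohort$covariates$subject_id %in%
    qc$subject_id[qc$qc_pass]
  cov <- cohort$covariates[keep, , drop = FALSE]
  if (!nrow(cov)) stop("empty cohort: no subject passes QC")
  lab <- voxelData(atlas)
  d <- dim(lab)
  baseline <- rep_len(effects@baseline, length(regions))
  slope <- setNames(rep(0, length(regions)), regions)
  if (length(effects@effectRegions))
    slope[as.character(effects@effectRegions)] <-
      rep_len(effects@slopePerRegion, length(effects@effectRegions))
  inter <- setNames(rep(0, length(regions)), regions)
  if (length(effects@interactionRegions))
    inter[as.character(effects@interactionRegions)] <-
      effects@interactionSlopeDelta
  baseVol <- array(0, d); slopeVol <- array(0, d); interVol <- array(0, d)
  for (ri in seq_along(regions)) {
    inR <- lab == regions[ri]
    baseVol[inR] <- baseline[ri]
    slopeVol[inR] <- slope[ri]
    interVol[inR] <- inter[ri]
  }
  cb <- effects@covariateBetas
  covTerm <- function(i) {
    sum(c(age = cov$age[i], gender = cov$gender[i],
          antidepressant = cov$antidepressant[i])[names(cb)] * cb)
  }
  set.seed(seed)
  v <- array(0, c(d, nrow(cov)))
  for (i in seq_len(nrow(cov))) {
    carI <- cov$car_true[i]
    isUhr <- cov$group[i] == "UHR"
    img <- baseVol + slopeVol * carI + covTerm(i) +
      if (isUhr) interVol * carI else 0
    if (effects@noiseSd > 0)
      img <- img + array(rnorm(prod(d), sd = effects@noiseSd), d)
    v[, , , i] <- img
  }
  gmvStack(v, voxelSize(atlas), cov$subject_id)
}

#' Affinely calibrate a sample to exact summary statistics
#'
#' Rescales \code{base} so that \code{c(result, fixed)} has exactly the
#' target mean and sample SD. Useful for synthesising a cohort sample
#' consistent with printed summary statistics (e.g. to reconstruct an
#' outlier's standard score from group means and SDs when raw values are
#' unavailable); the result is synthetic, not recovered data.
#'
#' @param base numeric vector to transform (needs nonzero spread).
#' @param targetMean,targetSd mean and sample SD the combined sample must
#'   attain.
#' @param fixed values included untouched in the combined sample.
#' @return numeric vector: the transformed base values (combine with
#'   \code{fixed} yourself).
#' @export
calibrateSampleStats <- function(base, targetMean, targetSd,
                                 fixed = numeric()) {
  nb <- length(base); n <- nb + length(fixed)
  if (nb < 2 || sd(base) == 0) stop("base needs >= 2 distinct values")
  mbt <- (n * targetMean - sum(fixed)) / nb
  ssb <- sum((base - mean(base))^2)
  c2 <- ((n - 1) * targetSd^2 - sum((fixed - targetMean)^2) -
           nb * (mbt - targetMean)^2) / ssb
  if (c2 < 0)
    stop("targets unattainable: implied within-sample variance is negative")
  a <- sqrt(c2)
  mbt + a * (base - mean(base))
}
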