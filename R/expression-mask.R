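RECEPTOR_GENES <- c("GR", "MR")

.checkExpressionTable <- function(samples) {
  need <- c("donor_id", "probe_id", "gene", "region_label", "expression")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("expression table lacks columns: ", paste(miss, collapse = ", "))
  bad <- !samples$gene %in% RECEPTOR_GENES
  if (any(bad))
    stop("gene must be GR or MR (row ", which(bad)[1], ")")
  invisible(samples)
}

#' Average expression samples within template regions
#'
#' Where a template region includes more than one sampling site for the
#' same donor and probe, the measurements are averaged, giving one value
#' per (region, donor, probe).
#'
#' @param samples expression sample table: donor_id, probe_id, gene,
#'   region_label, expression.
#' @param regions atlas region labels ([LabelAtlas] or integer vector);
#'   samples must map to known regions, and regions with no samples are
#'   reported as uncovered.
#' @return list with \code{values} (data.frame region_label, donor_id,
#'   probe_id, gene, expression) and \code{uncovered} (labels without
#'   samples).
#' @export
aggregateSamplesToRegions <- function(samples, regions) {
  .checkExpressionTable(samples)
  if (is(regions, "LabelAtlas")) regions <- regionLabels(regions)
  unknown <- setdiff(unique(samples$region_label), regions)
  if (length(unknown))
    stop("samples map to unknown region label(s): ",
         paste(unknown, collapse = ", "))
  agg <- aggregate(expression ~ region_label + donor_id + probe_id + gene,
                   data = samples, FUN = mean)
  agg <- agg[order(agg$region_label, agg$donor_id, agg$probe_id), ]
  rownames(agg) <- NULL
  list(values = agg,
       uncovered = setdiff(regions, unique(agg$region_label)))
}

#' Probe-then-donor averaging of regional receptor expression
#'
#' A gene's expression is inferred per (region, donor) as the average of
#' the probes targeting it, then the mean is taken across donors. The
#' ordering matters in unbalanced designs: probe means are formed first,
#' each donor then contributes one value regardless of probe count.
#'
#' @param regionValues data.frame from [aggregateSamplesToRegions()]
#'   (region_label, donor_id, probe_id, gene, expression).
#' @return data.frame region_label, gene, expression (one row per covered
#'   region-gene pair).
#' @export
averageProbesThenDonors <- function(regionValues) {
  perDonor <- aggregate(expression ~ region_label + donor_id + gene,
                        data = regionValues, FUN = mean)
  perGene <- aggregate(expression ~ region_label + gene,
                       data = perDonor, FUN = mean)
  perGene[order(perGene$region_label, perGene$gene), ]
}

#' Combine GR and MR into one regional expression score
#'
#' The two receptor-gene values are pooled by an unweighted mean (a large
#' share of corticosteroid-regulated genes respond to both receptor
#' types, and no weighting is established); regions are ranked by
#' descending combined expression, ties sharing the mean of their tied
#' ranks. Regions missing either gene are excluded with a warning.
#'
#' @param geneValues data.frame region_label, gene, expression.
#' @return data.frame region_label, mean_gr, mean_mr, combined, rank
#'   (1 = highest combined expression; ties fractional).
#' @export
combineGrMr <- function(geneValues) {
  wide <- reshape(geneValues, idvar = "region_label", timevar = "gene",
                  direction = "wide")
  gr <- wide[["expression.GR"]]
  mr <- wide[["expression.MR"]]
  if (is.null(gr)) gr <- rep(NA_real_, nrow(wide))
  if (is.null(mr)) mr <- rep(NA_real_, nrow(wide))
  keep <- !is.na(gr) & !is.na(mr)
  if (any(!keep))
    warning("excluding region(s) missing a receptor gene: ",
            paste(wide$region_label[!keep], collapse = ", "))
  out <- data.frame(region_label = wide$region_label[keep],
                    mean_gr = gr[keep], mean_mr = mr[keep])
  out$combined <- (out$mean_gr + out$mean_mr) / 2
  out$rank <- rank(-out$combined, ties.method = "average")
  out[order(out$rank), ]
}

#' Assign expression-ranked flexible p thresholds
#'
#' Regions ranked by combined GR/MR expression receive voxelwise p
#' thresholds between P<0.01 uncorrected (highest expression) and P<0.05
#' Bonferroni-corrected for all voxels within the mask (lowest
#' expression), the range divided into equally sized steps: with R
#' regions, rank r gets \code{p(r) = pMax - (r-1) * (pMax - pMin) / (R-1)}
#' (linear spacing; a log-p option is provided). A single region receives
#' pMax.
#'
#' @param scores data.frame from [combineGrMr()] (region_label, combined,
#'   rank; expression means carried through if present).
#' @param nVoxelsMask in-mask voxel count, the Bonferroni denominator.
#' @param pMax lenient endpoint, default 0.01 uncorrected.
#' @param alpha family-wise level for the strict endpoint, default 0.05;
#'   pMin = alpha / nVoxelsMask.
#' @param spacing "linear" (equal steps on the p scale, default) or "log"
#'   (equal steps on log p).
#' @param uncovered region labels excluded for lacking coverage (carried
#'   into the result for reporting).
#' @return a [ThresholdMap].
#' @export
assignThresholds <- function(scores, nVoxelsMask, pMax = 0.01,
                             alpha = 0.05,
                             spacing = c("linear", "log"),
                             uncovered = numeric()) {
  spacing <- match.arg(spacing)
  if (nVoxelsMask < 1) stop("empty mask: nVoxelsMask must be >= 1")
  if (nrow(scores) < 1) stop("need at least one scored region")
  pMin <- alpha / nVoxelsMask
  R <- nrow(scores)
  r <- scores$rank
  if (R == 1L) {
    p <- pMax
  } else if (spacing == "linear") {
    # convex combination: exact at both endpoints in floating point
    w <- (r - 1) / (R - 1)
    p <- pMax * (1 - w) + pMin * w
  } else {
    w <- (r - 1) / (R - 1)
    p <- exp(log(pMax) * (1 - w) + log(pMin) * w)
  }
  scores$p_threshold <- p
  if (!"mean_gr" %in% names(scores)) scores$mean_gr <- NA_real_
  if (!"mean_mr" %in% names(scores)) scores$mean_mr <- NA_real_
  new("ThresholdMap",
      scores = scores[c("region_label", "mean_gr", "mean_mr", "combined",
                        "rank", "p_threshold")],
      nVoxelsMask = as.numeric(nVoxelsMask), pMax = pMax, pMin = pMin,
      spacing = spacing, uncovered = as.numeric(uncovered))
}

#' Build the a priori receptor-expression threshold map
#'
#' Full aggregation path from a sample-level GR/MR expression table to a
#' [ThresholdMap]: samples are averaged within (region, donor, probe),
#' probes are averaged within (region, donor, gene), donors within
#' (region, gene), GR and MR are pooled, regions ranked, and thresholds
#' assigned.
#'
#' @inheritParams aggregateSamplesToRegions
#' @inheritParams assignThresholds
#' @param nVoxelsMask in-mask voxel count; when \code{regions} is a
#'   [LabelAtlas] and this is NULL, the atlas's non-background voxel
#'   count is used.
#' @return a [ThresholdMap].
#' @export
buildThresholdMap <- function(samples, regions, nVoxelsMask = NULL,
                              pMax = 0.01, alpha = 0.05,
                              spacing = c("linear", "log")) {
  if (is.null(nVoxelsMask)) {
    if (!is(regions, "LabelAtlas"))
      stop("nVoxelsMask required unless 'regions' is a LabelAtlas")
    nVoxelsMask <- sum(voxelData(regions) != 0)
  }
  agg <- aggregateSamplesToRegions(samples, regions)
  genes <- averageProbesThenDonors(agg$values)
  scores <- combineGrMr(genes)
  assignThresholds(scores, nVoxelsMask, pMax = pMax, alpha = alpha,
                   spacing = spacing, uncovered = agg$uncovered)
}

#' Render a ThresholdMap as a per-voxel threshold volume
#'
#' @param thresholdMap a [ThresholdMap].
#' @param atlas a [LabelAtlas] on the analysis grid.
#' @return a [BrainVolume] of per-voxel p thresholds (NA for background
#'   and uncovered regions).
#' @export
thresholdVolume <- function(thresholdMap, atlas) {
  lab <- voxelData(atlas)
  tab <- thresholdTable(thresholdMap)
  p <- array(NA_real_, dim(lab))
  for (i in seq_len(nrow(tab)))
    p[lab == tab$region_label[i]] <- tab$p_threshold[i]
  brainVolume(p, voxelSize(atlas))
}

#' @importFrom stats aggregate reshape
NULL
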