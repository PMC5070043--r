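#' Critical t value for a p threshold
#'
#' Converts a voxelwise p threshold into a Student-t cutoff: the
#' one-sided upper quantile qt(1 - p, df) by default, or the two-sided
#' cutoff qt(1 - p/2, df).
#'
#' @param p probability threshold in (0, 1).
#' @param df residual degrees of freedom (>= 1).
#' @param direction "one-sided" (default) or "two-sided".
#' @return the critical t (vectorised over \code{p}).
#' @export
criticalT <- function(p, df, direction = c("one-sided", "two-sided")) {
  direction <- match.arg(direction)
  if (any(df < 1)) stop("invalid df: must be >= 1")
  if (any(p <= 0 | p >= 1)) stop("p must be in (0, 1)")
  if (direction == "two-sided") p <- p / 2
  qt(1 - p, df)
}

# 26-neighbour connected-component labelling of a logical 3D array
.labelComponents <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  coords <- arrayInd(idx, d)
  nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, , drop = FALSE]
  current <- 0L
  for (start in idx) {
    if (lab[start] != 0L) next
    current <- current + 1L
    queue <- start
    lab[start] <- current
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      vc <- arrayInd(v, d)
      cand <- sweep(nb, 2, as.integer(vc), `+`)
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
            cand[, 2] >= 1 & cand[, 2] <= d[2] &
            cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      ci <- cand[, 1] + d[1] * (cand[, 2] - 1) + d[1] * d[2] * (cand[, 3] - 1)
      ci <- ci[mask[ci] & lab[ci] == 0L]
      lab[ci] <- current
      queue <- c(queue, ci)
    }
  }
  lab
}

#' Apply expression-ranked thresholds to a t-map
#'
#' A voxel is significant iff its t statistic exceeds the critical t of
#' its own region's assigned p threshold (one-sided; \code{direction}
#' "neg" tests -t). Produces the binary significance map, a per-region
#' report and a 26-neighbour connected-component cluster table.
#'
#' @param statMap a [StatMap].
#' @param atlas a [LabelAtlas] on the same grid.
#' @param thresholdMap a [ThresholdMap] covering the atlas regions.
#' @param direction "pos" (default; positive correlation) or "neg".
#' @param lenient if TRUE, atlas regions absent from the threshold map
#'   are skipped with a warning instead of raising an error.
#' @param minClusterVoxels optional minimum cluster extent (default 1,
#'   i.e. no extent threshold).
#' @return list with \code{map} (a [SignificanceMap]), \code{report}
#'   (data.frame region_label, p_threshold, critical_t,
#'   n_significant_voxels, peak_t, peak coordinates in 0-based voxel
#'   indices and mm) and \code{clusters} (data.frame cluster id, region
#'   of the peak, extent, peak_t, peak coordinates).
#' @export
applyThresholds <- function(statMap, atlas, thresholdMap,
                            direction = c("pos", "neg"),
                            lenient = FALSE, minClusterVoxels = 1L) {
  direction <- match.arg(direction)
  tmap <- voxelData(statMap)
  lab <- voxelData(atlas)
  if (!identical(dim(tmap), dim(lab)))
    stop("geometry error: stat map and atlas grids differ")
  tab <- thresholdTable(thresholdMap)
  regions <- regionLabels(atlas)
  missing <- setdiff(regions, c(tab$region_label, thresholdMap@uncovered))
  if (length(missing)) {
    msg <- paste("atlas region(s) without an assigned threshold:",
                 paste(missing, collapse = ", "))
    if (!lenient) stop(msg)
    warning(msg, "; skipped")
  }
  tEff <- if (direction == "pos") tmap else -tmap
  sig <- array(FALSE, dim(tmap))
  pApplied <- array(NA_real_, dim(tmap))
  crit <- criticalT(tab$p_threshold, statMap@df)
  rows <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    r <- tab$region_label[i]
    inR <- which(lab == r & !is.na(tEff))
    pApplied[inR] <- tab$p_threshold[i]
    hit <- inR[tEff[inR] > crit[i]]
    sig[hit] <- TRUE
    peak <- if (length(inR)) inR[which.max(tEff[inR])] else NA_integer_
    pk <- if (length(hit)) .peakRow(peak, tEff, dim(tmap), voxelSize(statMap))
          else list(peak_t = NA_real_, x = NA, y = NA, z = NA,
                    x_mm = NA, y_mm = NA, z_mm = NA)
    rows[[i]] <- data.frame(region_label = r,
                            p_threshold = tab$p_threshold[i],
                            critical_t = crit[i],
                            n_significant_voxels = length(hit),
                            peak_t = pk$peak_t, peak_x = pk$x,
                            peak_y = pk$y, peak_z = pk$z,
                            peak_x_mm = pk$x_mm, peak_y_mm = pk$y_mm,
                            peak_z_mm = pk$z_mm)
  }
  report <- do.call(rbind, rows)
  comp <- .labelComponents(sig)
  clusters <- .clusterTable(comp, tEff, voxelSize(statMap))
  if (minClusterVoxels > 1L && nrow(clusters)) {
    drop <- clusters$cluster[clusters$extent < minClusterVoxels]
    sig[comp %in% drop] <- FALSE
    clusters <- clusters[!clusters$cluster %in% drop, , drop = FALSE]
    # recount per region after extent filtering
    for (i in seq_len(nrow(report))) {
      r <- report$region_label[i]
      report$n_significant_voxels[i] <- sum(sig[lab == r])
    }
  }
  map <- new("SignificanceMap", significant = sig, pApplied = pApplied,
             direction = direction)
  list(map = map, report = report, clusters = clusters)
}

.peakRow <- function(peakIdx, tEff, d, vox) {
  vc <- arrayInd(peakIdx, d)
  list(peak_t = tEff[peakIdx],
       x = vc[1] - 1L, y = vc[2] - 1L, z = vc[3] - 1L,
       x_mm = (vc[1] - 1L) * vox[1], y_mm = (vc[2] - 1L) * vox[2],
       z_mm = (vc[3] - 1L) * vox[3])
}

.clusterTable <- function(comp, tEff, vox) {
  ids <- setdiff(unique(as.vector(comp)), 0L)
  if (!length(ids))
    return(data.frame(cluster = integer(), extent = integer(),
                      peak_t = numeric(), peak_x = integer(),
                      peak_y = integer(), peak_z = integer(),
                      peak_x_mm = numeric(), peak_y_mm = numeric(),
                      peak_z_mm = numeric()))
  rows <- lapply(sort(ids), function(id) {
    inC <- which(comp == id)
    pk <- .peakRow(inC[which.max(tEff[inC])], tEff, dim(comp), vox)
    data.frame(cluster = id, extent = length(inC), peak_t = pk$peak_t,
               peak_x = pk$x, peak_y = pk$y, peak_z = pk$z,
               peak_x_mm = pk$x_mm, peak_y_mm = pk$y_mm,
               peak_z_mm = pk$z_mm)
  })
  do.call(rbind, rows)
}
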