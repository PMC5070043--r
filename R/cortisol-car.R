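#' @importFrom stats pt qt sd setNames
NULL

NOMINAL_TIMES <- c(0, 30, 60)
QC_REASONS <- c("missing_sample", "low_volume", "timing_deviation",
                "negative_delta30")

.checkSampleTable <- function(samples) {
  need <- c("subject_id", "nominal_time_min", "actual_time_min",
            "volume_ul", "cortisol_nmol_l")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("sample table lacks columns: ", paste(miss, collapse = ", "))
  bad <- !samples$nominal_time_min %in% NOMINAL_TIMES
  if (any(bad))
    stop("nominal_time_min must be one of 0, 30, 60 (row ",
         which(bad)[1], ")")
  dup <- duplicated(samples[c("subject_id", "nominal_time_min")])
  if (any(dup))
    stop("duplicate nominal time point for subject ",
         samples$subject_id[which(dup)[1]])
  invisible(samples)
}

#' Quality-control three-point waking cortisol series
#'
#' Applies the saliva-sampling exclusion rules: a missing sample, a sample
#' with very low saliva volume (below \code{volumeFloorUl}), a sample
#' reportedly collected more than \code{timingToleranceMin} minutes before
#' or after its nominal time point, or a negative delta30 (30-minute minus
#' waking concentration, indicative of delayed first-sample collection)
#' each exclude the subject. All triggered rules are reported.
#'
#' @param samples long-format data.frame with columns subject_id,
#'   nominal_time_min (0/30/60), actual_time_min, volume_ul,
#'   cortisol_nmol_l. A missing actual_time_min is treated as on-time
#'   (self-reported timing) unless \code{strictTiming}.
#' @param volumeFloorUl minimum acceptable saliva volume, microlitres.
#' @param timingToleranceMin maximal |actual - nominal| deviation,
#'   minutes; the boundary passes.
#' @param strictTiming if TRUE a missing actual time excludes the subject
#'   (reason timing_deviation).
#' @return data.frame with one row per subject: subject_id, qc_pass,
#'   qc_reasons (";"-separated codes among missing_sample, low_volume,
#'   timing_deviation, negative_delta30; empty when passing).
#' @export
qcFilter <- function(samples, volumeFloorUl = 200, timingToleranceMin = 15,
                     strictTiming = FALSE) {
  .checkSampleTable(samples)
  ids <- unique(samples$subject_id)
  res <- lapply(ids, function(id) {
    s <- samples[samples$subject_id == id, , drop = FALSE]
    reasons <- character()
    present <- NOMINAL_TIMES %in% s$nominal_time_min
    if (!all(present)) reasons <- c(reasons, "missing_sample")
    if (any(s$volume_ul < volumeFloorUl, na.rm = TRUE))
      reasons <- c(reasons, "low_volume")
    dev <- abs(s$actual_time_min - s$nominal_time_min)
    if (any(dev > timingToleranceMin, na.rm = TRUE) ||
        (strictTiming && anyNA(s$actual_time_min)))
      reasons <- c(reasons, "timing_deviation")
    conc <- setNames(rep(NA_real_, 3L), NOMINAL_TIMES)
    conc[as.character(s$nominal_time_min)] <- s$cortisol_nmol_l
    if (!anyNA(conc[c("0", "30")]) && conc["30"] - conc["0"] < 0)
      reasons <- c(reasons, "negative_delta30")
    data.frame(subject_id = id, qc_pass = length(reasons) == 0L,
               qc_reasons = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Pruessner area-under-the-curve CAR summaries
#'
#' For concentrations c0, c30, c60 (nmol/l) at 0, 30 and 60 minutes after
#' awakening, the trapezoidal area with respect to ground is
#' \code{aucG = 15 * (c0 + 2*c30 + c60)} and the area with respect to
#' increase is \code{aucI = aucG - 60*c0}, both in nmol.min/l.
#'
#' @param c0,c30,c60 cortisol concentrations, nmol/l (vectorised).
#' @return data.frame with auc_g, auc_i, delta30.
#' @export
computeCar <- function(c0, c30, c60) {
  data.frame(auc_g = 15 * (c0 + 2 * c30 + c60),
             auc_i = 15 * (c0 + 2 * c30 + c60) - 60 * c0,
             delta30 = c30 - c0)
}

#' QC and CAR quantification for a cohort sample table
#'
#' Runs [qcFilter()] and, for passing subjects only, [computeCar()].
#' Excluded subjects carry NA area-under-curve values.
#'
#' @inheritParams qcFilter
#' @return data.frame per subject: subject_id, c0, c30, c60, auc_g, auc_i,
#'   delta30, qc_pass, qc_reasons.
#' @export
carTable <- function(samples, volumeFloorUl = 200, timingToleranceMin = 15,
                     strictTiming = FALSE) {
  qc <- qcFilter(samples, volumeFloorUl, timingToleranceMin, strictTiming)
  conc <- function(id, t) {
    v <- samples$cortisol_nmol_l[samples$subject_id == id &
                                   samples$nominal_time_min == t]
    if (length(v)) v else NA_real_
  }
  qc$c0 <- vapply(qc$subject_id, conc, numeric(1), t = 0)
  qc$c30 <- vapply(qc$subject_id, conc, numeric(1), t = 30)
  qc$c60 <- vapply(qc$subject_id, conc, numeric(1), t = 60)
  car <- computeCar(qc$c0, qc$c30, qc$c60)
  car[!qc$qc_pass, ] <- NA_real_
  cbind(qc[c("subject_id", "c0", "c30", "c60")], car,
        qc[c("qc_pass", "qc_reasons")])
}

.tResult <- function(t, df, ma, mb, sa, sb, na, nb, method) {
  structure(list(t_statistic = t, df = df,
                 p_two_sided = 2 * pt(-abs(t), df),
                 mean_a = ma, mean_b = mb, sd_a = sa, sd_b = sb,
                 n_a = na, n_b = nb, method = method),
            class = "groupTestResult")
}

#' @export
print.groupTestResult <- function(x, ...) {
  cat(sprintf("Two-sample t-test (%s): t = %.3f, df = %.4g, P = %.3g\n",
              x$method, x$t_statistic, x$df, x$p_two_sided))
  cat(sprintf("  group A: mean %.4g (SD %.4g), n = %d\n",
              x$mean_a, x$sd_a, x$n_a))
  cat(sprintf("  group B: mean %.4g (SD %.4g), n = %d\n",
              x$mean_b, x$sd_b, x$n_b))
  invisible(x)
}

#' Pooled two-sample t-test from summary statistics
#'
#' Independent-sample two-tailed Student t-test with pooled variance and
#' df = nA + nB - 2, computable directly from printed group means and
#' SDs. If both SDs are zero and the means are equal t is defined as 0;
#' if the means differ the variance is degenerate and an error is
#' signalled.
#'
#' @param meanA,sdA,nA group A mean, SD and size.
#' @param meanB,sdB,nB group B mean, SD and size.
#' @return a groupTestResult list: t_statistic, df, p_two_sided, group
#'   summaries.
#' @seealso [groupTTest()] for raw value vectors.
#' @export
pooledTTest <- function(meanA, sdA, nA, meanB, sdB, nB) {
  if (nA < 2 || nB < 2) stop("need at least 2 observations per group")
  if (sdA < 0 || sdB < 0) stop("SDs must be >= 0")
  df <- nA + nB - 2
  sp2 <- ((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / df
  if (sp2 == 0) {
    if (meanA == meanB)
      return(.tResult(0, df, meanA, meanB, sdA, sdB, nA, nB, "pooled"))
    stop("degenerate variance: both SDs zero with unequal means")
  }
  t <- (meanA - meanB) / sqrt(sp2 * (1 / nA + 1 / nB))
  .tResult(t, df, meanA, meanB, sdA, sdB, nA, nB, "pooled")
}

#' Two-sample t-test on raw value vectors
#'
#' Computes group means/SDs and delegates to the pooled-variance test
#' (default) or a Welch test with Satterthwaite df.
#'
#' @param a,b numeric vectors of per-subject values (NAs dropped).
#' @param method "pooled" (Student, df = nA+nB-2) or "welch".
#' @return a groupTestResult list.
#' @export
groupTTest <- function(a, b, method = c("pooled", "welch")) {
  method <- match.arg(method)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 observations per group")
  if (method == "pooled")
    return(pooledTTest(mean(a), sd(a), length(a),
                       mean(b), sd(b), length(b)))
  va <- var(a) / length(a); vb <- var(b) / length(b)
  if (va + vb == 0) {
    if (mean(a) == mean(b))
      return(.tResult(0, length(a) + length(b) - 2, mean(a), mean(b),
                      sd(a), sd(b), length(a), length(b), "welch"))
    stop("degenerate variance: both SDs zero with unequal means")
  }
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  .tResult(t, df, mean(a), mean(b), sd(a), sd(b), length(a), length(b),
           "welch")
}

#' Standard-score outlier screen
#'
#' Standard scores z_i = (x_i - mean) / SD are computed on the full sample
#' including each candidate (sample SD, denominator n - 1); values with
#' |z| above the threshold are flagged.
#'
#' @param values numeric vector (>= 3 values, nonzero spread).
#' @param zThreshold flagging threshold on |z|.
#' @return data.frame with value, z, outlier.
#' @export
detectOutliers <- function(values, zThreshold = 3.0) {
  if (length(values) < 3) stop("need at least 3 values")
  s <- sd(values)
  if (s == 0) stop("no spread: all values equal")
  z <- (values - mean(values)) / s
  data.frame(value = values, z = z, outlier = abs(z) > zThreshold)
}

#' @importFrom stats var
NULL
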