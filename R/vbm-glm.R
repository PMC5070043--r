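#' @importFrom stats dnorm
NULL

.fwhmToSigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

.smoothingMatrix <- function(n, sigmaVox) {
  radius <- max(1L, ceiling(4 * sigmaVox))
  off <- seq(-radius, radius)
  w <- dnorm(off, sd = sigmaVox)
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (k in seq_along(off)) {
    j <- pmin(pmax(seq_len(n) + off[k], 1L), n)  # replicate boundary
    K[cbind(seq_len(n), j)] <- K[cbind(seq_len(n), j)] + w[k]
  }
  K
}

.applyAlongAxis <- function(a, K, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- K %*% matrix(ap, nrow = d[axis])
  aperm(array(m, dim = d[perm]), order(perm))
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian convolution with a kernel of the given full width
#' at half maximum: sigma_mm = fwhm / (2 * sqrt(2 * log 2)) per axis,
#' expressed in voxels through the voxel size. The kernel is normalised
#' to unit sum and the grid is extended by replicating edge values, so a
#' constant image is a fixed point (this differs from SPM's implicit-zero
#' padding). fwhm = 0 returns the input unchanged.
#'
#' @param image a [BrainVolume] or 3D array.
#' @param fwhmMm kernel FWHM in mm (default 8).
#' @param voxelSize voxel edge lengths in mm; taken from the volume when
#'   \code{image} is a [BrainVolume].
#' @return smoothed object of the same type as the input.
#' @export
smoothGaussian <- function(image, fwhmMm = 8, voxelSize = c(2, 2, 2)) {
  isVol <- is(image, "BrainVolume")
  if (isVol) voxelSize <- voxelSize(image)
  voxelSize <- rep_len(voxelSize, 3L)
  if (any(voxelSize <= 0)) stop("invalid geometry: voxel size must be > 0")
  if (fwhmMm < 0) stop("fwhm must be >= 0")
  if (fwhmMm == 0) return(image)
  a <- if (isVol) voxelData(image) else image
  for (axis in 1:3) {
    sigmaVox <- .fwhmToSigma(fwhmMm) / voxelSize[axis]
    a <- .applyAlongAxis(a, .smoothingMatrix(dim(a)[axis], sigmaVox), axis)
  }
  if (isVol) brainVolume(a, voxelSize) else a
}

#' Smooth every subject in a stack
#'
#' @param stack a [GmvStack].
#' @inheritParams smoothGaussian
#' @return a [GmvStack].
#' @export
smoothStack <- function(stack, fwhmMm = 8) {
  if (fwhmMm == 0) return(stack)
  v <- voxelData(stack)
  for (s in seq_len(dim(v)[4]))
    v[, , , s] <- smoothGaussian(v[, , , s], fwhmMm, voxelSize(stack))
  gmvStack(v, voxelSize(stack), subjectIds(stack))
}

#' Proportional scaling of global volume differences
#'
#' Each subject's image is multiplied by (grand mean of in-mask subject
#' means) / (that subject's in-mask mean), so that after scaling all
#' subjects share the same in-mask mean and specific effects are not
#' confounded by global volumetric differences. Normalising to the grand
#' mean rather than an arbitrary constant is inconsequential for t
#' statistics (only relative scaling matters).
#'
#' @param stack a [GmvStack].
#' @param mask logical 3D array (or [BrainVolume] of 0/1) selecting the
#'   global-mean voxels; NULL uses all voxels.
#' @return list with \code{stack} (scaled [GmvStack]), \code{globalMeans}
#'   (per-subject pre-scaling in-mask means) and \code{grandMean}.
#' @export
proportionalScale <- function(stack, mask = NULL) {
  v <- voxelData(stack)
  if (is(mask, "BrainVolume")) mask <- voxelData(mask) != 0
  if (is.null(mask)) mask <- array(TRUE, dim(v)[1:3])
  flat <- matrix(v, ncol = dim(v)[4])
  means <- colMeans(flat[as.vector(mask), , drop = FALSE])
  if (any(means <= 0))
    stop("degenerate global: non-positive in-mask mean for subject(s) ",
         paste(subjectIds(stack)[means <= 0], collapse = ", "))
  grand <- mean(means)
  for (s in seq_len(dim(v)[4])) v[, , , s] <- v[, , , s] * grand / means[s]
  list(stack = gmvStack(v, voxelSize(stack), subjectIds(stack)),
       globalMeans = means, grandMean = grand)
}

#' Build the subjects-by-regressors design matrix
#'
#' Covariate model for the voxelwise analyses: intercept, CAR, and the
#' nuisance covariates age, gender and antidepressant medication. For the
#' interaction model, group (0 = control, 1 = UHR) and group x CAR are
#' added; CAR is mean-centred before forming the interaction column to
#' reduce collinearity (this leaves the interaction coefficient
#' unchanged).
#'
#' @param covariates data.frame with subject_id, group ("UHR"/"control"
#'   or 0/1), age, gender (0/1), antidepressant (0/1).
#' @param car named numeric of per-subject CAR values (nmol.min/l), or
#'   the name of a column of \code{covariates}.
#' @param model "car" (CAR correlation across all subjects) or
#'   "interaction" (group-dependent CAR slope).
#' @param centerCar mean-centre the CAR column (default TRUE).
#' @return numeric matrix, rownames subject ids, with attribute
#'   \code{groupIndicator}.
#' @export
buildDesignMatrix <- function(covariates, car = "car",
                              model = c("car", "interaction"),
                              centerCar = TRUE) {
  model <- match.arg(model)
  if (is.character(car) && length(car) == 1L)
    car <- setNames(covariates[[car]], covariates$subject_id)
  car <- car[as.character(covariates$subject_id)]
  if (anyNA(car)) stop("CAR missing for subject(s) ",
                       paste(covariates$subject_id[is.na(car)],
                             collapse = ", "))
  grp <- covariates$group
  if (!is.numeric(grp)) grp <- as.numeric(grp %in% c("UHR", "uhr", "1"))
  carC <- if (centerCar) car - mean(car) else car
  X <- cbind(intercept = 1, car = as.numeric(carC),
             age = covariates$age, gender = covariates$gender,
             antidepressant = covariates$antidepressant)
  # a constant nuisance covariate is collinear with the intercept
  for (nm in c("age", "gender", "antidepressant")) {
    if (var(X[, nm]) == 0) {
      message("dropping constant covariate column '", nm, "'")
      X <- X[, colnames(X) != nm, drop = FALSE]
    }
  }
  if (model == "interaction")
    X <- cbind(X, group = grp, group_x_car = grp * as.numeric(carC))
  rownames(X) <- covariates$subject_id
  if (nrow(X) < ncol(X) + 1)
    stop("need more subjects than model columns")
  attr(X, "groupIndicator") <- grp
  X
}

.checkFullRank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("rank-deficient design: collinear column(s) ",
         paste(bad, collapse = ", "))
  }
  q
}

#' Fit the voxelwise general linear model
#'
#' Ordinary least squares per voxel with a design shared across voxels:
#' beta = (X'X)^-1 X'y, t = c'beta / sqrt(s2 * c'(X'X)^-1 c) with
#' s2 = RSS / (n - rank X), solved for all voxels at once via the QR
#' decomposition of X. Voxels with (numerically) zero residual variance
#' report a signed infinite t sentinel rather than failing the map; df is
#' recorded once for the whole map.
#'
#' @param stack a [GmvStack] (or an n x V matrix of voxel data).
#' @param design design matrix from [buildDesignMatrix()].
#' @param contrast contrast weight vector (length ncol(design)), or the
#'   name of a single design column.
#' @param mask logical 3D array restricting the analysis; NULL analyses
#'   all voxels.
#' @return a [StatMap] (t values, per-regressor beta maps, df).
#' @export
fitVoxelwiseGlm <- function(stack, design, contrast = "car", mask = NULL) {
  isStack <- is(stack, "GmvStack")
  if (isStack) {
    v <- voxelData(stack)
    gridDim <- dim(v)[1:3]
    Y <- t(matrix(v, ncol = dim(v)[4]))
  } else {
    Y <- stack
    gridDim <- c(ncol(Y), 1L, 1L)
  }
  if (nrow(Y) != nrow(design))
    stop("stack size must equal design rows")
  if (is.character(contrast)) {
    cvec <- as.numeric(colnames(design) == contrast)
    if (sum(cvec) != 1) stop("unknown contrast column: ", contrast)
    cname <- contrast
  } else {
    cvec <- contrast
    cname <- paste(contrast, collapse = ",")
  }
  if (length(cvec) != ncol(design))
    stop("contrast length must equal design columns")
  maskIdx <- if (!is.null(mask)) which(as.vector(mask)) else seq_len(ncol(Y))
  Ym <- Y[, maskIdx, drop = FALSE]
  q <- .checkFullRank(design)
  beta <- qr.coef(q, Ym)
  res <- Ym - design %*% beta
  dfres <- nrow(design) - q$rank
  rss <- colSums(res^2)
  s2 <- rss / dfres
  R <- qr.R(q)[, order(q$pivot), drop = FALSE]
  u <- backsolve(R, cvec, transpose = TRUE)
  varc <- sum(u^2)
  cbeta <- as.vector(crossprod(cvec, beta))
  t <- cbeta / sqrt(s2 * varc)
  # zero-residual (noise-free) voxels: signed infinity sentinel
  zero <- rss <= 1e-20 * pmax(colSums(Ym^2), .Machine$double.xmin)
  t[zero] <- sign(cbeta[zero]) * Inf
  t[zero & cbeta == 0] <- 0
  asGrid <- function(x) {
    full <- rep(NA_real_, ncol(Y))
    full[maskIdx] <- x
    array(full, gridDim)
  }
  betas <- lapply(seq_len(nrow(beta)), function(i) asGrid(beta[i, ]))
  names(betas) <- colnames(design)
  new("StatMap",
      tValues = asGrid(t), betas = betas, df = dfres, contrast = cname,
      columns = colnames(design),
      voxelSize = if (isStack) voxelSize(stack) else c(1, 1, 1))
}

#' Fit the group-by-CAR interaction model
#'
#' Voxelwise GLM with intercept, CAR, nuisance covariates, group and
#' group x CAR; the returned map carries the t statistic of the
#' interaction coefficient. Its positive direction is a stronger CAR
#' slope in the UHR group, the negative direction a stronger slope in
#' controls; threshold the same map in both directions to report both.
#'
#' @inheritParams fitVoxelwiseGlm
#' @param covariates covariate table (see [buildDesignMatrix()]).
#' @param car per-subject CAR values (named numeric or covariate column
#'   name).
#' @return a [StatMap] for the group_x_car contrast.
#' @export
fitInteractionGlm <- function(stack, covariates, car = "car", mask = NULL) {
  X <- buildDesignMatrix(covariates, car, model = "interaction")
  grp <- attr(X, "groupIndicator")
  if (sum(grp == 1) < 3 || sum(grp == 0) < 3)
    stop("insufficient group: need >= 3 subjects per group")
  fitVoxelwiseGlm(stack, X, contrast = "group_x_car", mask = mask)
}

#' Default analysis mask
#'
#' Voxels with a non-background atlas label and positive mean grey-matter
#' volume across subjects.
#'
#' @param atlas a [LabelAtlas].
#' @param stack a [GmvStack] on the same grid.
#' @return logical 3D array.
#' @export
analysisMask <- function(atlas, stack) {
  lab <- voxelData(atlas)
  v <- voxelData(stack)
  if (!identical(dim(lab), dim(v)[1:3]))
    stop("geometry error: atlas and stack grids differ")
  meanGmv <- apply(v, 1:3, mean)
  lab != 0 & meanGmv > 0
}
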