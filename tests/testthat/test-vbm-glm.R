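test_that("smoothing preserves constants and fwhm 0 is the identity", {
  a <- array(3.7, c(8, 8, 8))
  sm <- smoothGaussian(a, 8, c(2, 2, 2))
  expect_equal(sm, a, tolerance = 1e-12)
  b <- array(rnorm(8^3), c(8, 8, 8))
  expect_identical(smoothGaussian(b, 0, c(2, 2, 2)), b)
  expect_error(smoothGaussian(b, 8, c(0, 2, 2)), "invalid geometry")
})

test_that("impulse response matches a dense replicate-padded convolution", {
  d <- c(9, 9, 9); vox <- c(2, 2, 2); fwhm <- 8
  img <- array(0, d); img[5, 5, 5] <- 1
  got <- smoothGaussian(img, fwhm, vox)
  # oracle: direct dense 3D convolution with clamped (replicate) indexing
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  w1 <- function(n) {
    r <- max(1, ceiling(4 * sigma / 2))
    w <- dnorm(seq(-r, r), sd = sigma / 2)
    w / sum(w)
  }
  w <- w1(); r <- (length(w) - 1) / 2
  oracle <- array(0, d)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    acc <- 0
    for (i in -r:r) for (j in -r:r) for (k in -r:r) {
      xi <- min(max(x + i, 1), d[1])
      yj <- min(max(y + j, 1), d[2])
      zk <- min(max(z + k, 1), d[3])
      acc <- acc + w[i + r + 1] * w[j + r + 1] * w[k + r + 1] *
        img[xi, yj, zk]
    }
    oracle[x, y, z] <- acc
  }
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_equal(got[5, 5, 5], w[r + 1]^3, tolerance = 1e-12)
})

test_that("smoothing is linear", {
  set.seed(5)
  x <- array(rnorm(6^3), c(6, 6, 6)); y <- array(rnorm(6^3), c(6, 6, 6))
  lhs <- smoothGaussian(2 * x - 3 * y, 8, c(2, 2, 2))
  rhs <- 2 * smoothGaussian(x, 8, c(2, 2, 2)) -
    3 * smoothGaussian(y, 8, c(2, 2, 2))
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("proportional scaling equalises in-mask means at the grand mean", {
  d <- c(4, 4, 4)
  v <- array(0, c(d, 3))
  for (s in 1:3) v[, , , s] <- c(1, 2, 4)[s]
  stk <- gmvStack(v)
  sc <- proportionalScale(stk)
  means <- apply(voxelData(sc$stack), 4, mean)
  expect_equal(means, rep(7 / 3, 3), tolerance = 1e-12)
  expect_equal(sc$grandMean, 7 / 3)
  # already-equal means: unchanged
  v2 <- array(rnorm(prod(d) * 2), c(d, 2))
  v2[, , , 2] <- v2[, , , 2] - mean(v2[, , , 2]) + mean(v2[, , , 1])
  stk2 <- gmvStack(v2)
  expect_equal(voxelData(proportionalScale(stk2)$stack), v2,
               tolerance = 1e-12)
  vneg <- v; vneg[, , , 1] <- 0
  expect_error(proportionalScale(gmvStack(vneg)), "degenerate global")
})

test_that("voxelwise OLS matches a normal-equations oracle per voxel", {
  set.seed(12)
  n <- 10; V <- 64
  X <- cbind(intercept = 1, car = rnorm(n), age = rnorm(n),
             gender = rbinom(n, 1, 0.5))
  Y <- matrix(rnorm(n * V), n, V)
  cvec <- c(0, 1, 0, 0)
  sm <- fitVoxelwiseGlm(Y, X, contrast = cvec)
  tGot <- as.vector(voxelData(sm))
  for (vx in seq_len(V)) {
    o <- olsOracle(X, Y[, vx], cvec)
    expect_equal(sm@betas$car[vx, 1, 1], o$beta[2], tolerance = 1e-10)
    expect_equal(tGot[vx], o$t, tolerance = 1e-10)
  }
  expect_equal(sm@df, n - ncol(X))
})

test_that("noise-free data recover betas exactly with an infinite t sentinel", {
  set.seed(3)
  n <- 12
  car <- rnorm(n, 200, 50)
  X <- cbind(intercept = 1, car = car)
  Y <- matrix(rep(2 + 3 * car, 4), n, 4)
  sm <- fitVoxelwiseGlm(Y, X, contrast = "car")
  expect_equal(as.vector(sm@betas$car), rep(3, 4), tolerance = 1e-10)
  expect_true(all(voxelData(sm) == Inf))
})

test_that("a covariate orthogonal to CAR and y leaves the CAR beta unchanged", {
  set.seed(21)
  n <- 14
  X <- cbind(intercept = 1, car = rnorm(n))
  y <- 1 + 0.5 * X[, "car"] + rnorm(n)
  raw <- rnorm(n)
  ortho <- residuals(lm(raw ~ X[, "car"] + y))
  b0 <- fitVoxelwiseGlm(matrix(y), X, contrast = "car")@betas$car[1, 1, 1]
  b1 <- fitVoxelwiseGlm(matrix(y), cbind(X, extra = ortho),
                        contrast = c(0, 1, 0))@betas$car[1, 1, 1]
  expect_equal(b0, b1, tolerance = 1e-10)
})

test_that("rank-deficient designs fail naming the collinear columns", {
  n <- 10
  X <- cbind(intercept = 1, car = rnorm(n))
  X <- cbind(X, dup = X[, "car"])
  expect_error(fitVoxelwiseGlm(matrix(rnorm(n)), X, contrast = "car"),
               "collinear.*dup|dup.*collinear")
})

test_that("the design matrix encodes groups and a centred interaction", {
  cov <- data.frame(subject_id = sprintf("S%d", 1:8),
                    group = rep(c("UHR", "control"), each = 4),
                    age = rnorm(8, 22), gender = rep(0:1, 4),
                    antidepressant = c(1, 0, 0, 0, 0, 0, 0, 0),
                    car = c(100, 200, 300, 400, 150, 250, 350, 450))
  X <- buildDesignMatrix(cov, "car", model = "interaction")
  expect_identical(colnames(X),
                   c("intercept", "car", "age", "gender", "antidepressant",
                     "group", "group_x_car"))
  expect_equal(unname(X[, "group"]), rep(c(1, 0), each = 4))
  expect_equal(mean(X[, "car"]), 0)
  expect_equal(unname(X[, "group_x_car"]), X[, "car"] * X[, "group"],
               ignore_attr = TRUE)
  expect_error(buildDesignMatrix(cov[1:6, ], "car", model = "interaction"),
               "more subjects than model columns")
})

test_that("noise-free group slopes 3 vs 1 give an interaction beta of 2", {
  set.seed(8)
  nPer <- 8
  cov <- data.frame(subject_id = sprintf("S%02d", 1:(2 * nPer)),
                    group = rep(c("UHR", "control"), each = nPer),
                    age = runif(2 * nPer, 18, 30),
                    gender = rep(0:1, nPer),
                    antidepressant = 0,
                    car = runif(2 * nPer, 0, 500))
  grp <- as.numeric(cov$group == "UHR")
  slope <- ifelse(grp == 1, 3, 1)
  d <- c(3, 3, 3)
  v <- array(0, c(d, 2 * nPer))
  for (s in seq_len(2 * nPer)) v[, , , s] <- 10 + slope[s] * cov$car[s]
  sm <- fitInteractionGlm(gmvStack(v), cov, "car")
  expect_equal(as.vector(sm@betas$group_x_car),
               rep(2, prod(d)), tolerance = 1e-9)
  # swapping group labels negates the interaction map
  cov2 <- cov
  cov2$group <- ifelse(cov$group == "UHR", "control", "UHR")
  v2 <- v + array(rnorm(length(v), sd = 0.1), dim(v))
  t1 <- voxelData(fitInteractionGlm(gmvStack(v2), cov, "car"))
  t2 <- voxelData(fitInteractionGlm(gmvStack(v2), cov2, "car"))
  expect_equal(t1, -t2, tolerance = 1e-9)
  expect_error(fitInteractionGlm(gmvStack(v[, , , 1:10, drop = FALSE]),
                                 cov[c(1:8, 9:10), ], "car"),
               "insufficient group")
})

test_that("null t-maps reject at about the nominal rate", {
  set.seed(99)
  n <- 30; V <- 4000
  X <- cbind(intercept = 1, car = rnorm(n), age = rnorm(n))
  Y <- matrix(rnorm(n * V), n, V)
  sm <- fitVoxelwiseGlm(Y, X, contrast = "car")
  alpha <- 0.05
  crit <- qt(1 - alpha, sm@df)
  hits <- sum(voxelData(sm) > crit)
  bounds <- qbinom(c(0.005, 0.995), V, alpha)
  expect_gte(hits, bounds[1])
  expect_lte(hits, bounds[2])
})

test_that("contrast t is invariant to per-subject global scale factors", {
  st <- tinyStudy(seed = 6, nUhr = 8, nControl = 7, grid = 6, nRegions = 2,
                  effectRegions = 1, slope = 2e-4, noiseSd = 0.05)
  cov <- st$cohort$covariates
  cov <- cov[match(subjectIds(st$stack), cov$subject_id), ]
  cov$car <- cov$car_true
  runGlm <- function(stk) {
    scaled <- proportionalScale(stk)$stack
    X <- buildDesignMatrix(cov, "car", model = "car")
    voxelData(fitVoxelwiseGlm(scaled, X, contrast = "car"))
  }
  t1 <- runGlm(st$stack)
  set.seed(44)
  v <- voxelData(st$stack)
  for (s in seq_len(dim(v)[4])) v[, , , s] <- v[, , , s] * runif(1, 0.5, 2)
  t2 <- runGlm(gmvStack(v, voxelSize(st$stack), subjectIds(st$stack)))
  expect_equal(t1, t2, tolerance = 1e-8)
})

test_that("the analysis mask needs matching grids and positive mean GMV", {
  atlas <- generateAtlas(atlasSpec(c(4, 4, 4), 2))
  v <- array(1, c(4, 4, 4, 3)); v[1, 1, 1, ] <- 0
  stk <- gmvStack(v)
  m <- analysisMask(atlas, stk)
  expect_false(m[1, 1, 1])
  expect_true(all(m[-1]))
  bad <- gmvStack(array(1, c(5, 5, 5, 3)))
  expect_error(analysisMask(atlas, bad), "geometry error")
})
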