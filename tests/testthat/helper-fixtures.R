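# shared in-code fixtures: everything is generated, nothing is stored

makeSeries <- function(id = "S1", conc = c(10, 18, 14), vol = 400,
                       actual = c(0, 30, 60), nominal = c(0, 30, 60)) {
  data.frame(subject_id = id, nominal_time_min = nominal,
             actual_time_min = actual, volume_ul = vol,
             cortisol_nmol_l = conc)
}

# region means strictly descending in the label order, so region 1 ranks 1
descendingRegionMeans <- function(n) {
  m <- seq(10, 5, length.out = n)
  matrix(c(m, m), ncol = 2, dimnames = list(NULL, c("GR", "MR")))
}

# small full-pipeline inputs: clean cohort, block atlas, known expression
tinyStudy <- function(seed = 1, nUhr = 12, nControl = 10, grid = 10,
                      nRegions = 4, effectRegions = numeric(),
                      slope = 0, noiseSd = 0.05,
                      interactionRegions = numeric(), interDelta = 0) {
  atlas <- generateAtlas(atlasSpec(rep(grid, 3), nRegions))
  spec <- cohortSpec(nUhr = nUhr, nControl = nControl,
                     nTransition = 0, nQcFailVolume = 0,
                     nQcFailTiming = 0, nQcFailDelta30 = 0,
                     nQcFailMissing = 0, seed = seed)
  cohort <- generateCohort(spec)
  eff <- effectSpec(effectRegions = effectRegions, slopePerRegion = slope,
                    interactionRegions = interactionRegions,
                    interactionSlopeDelta = interDelta, noiseSd = noiseSd)
  stack <- generateGmvImages(cohort, atlas, eff, seed = seed + 1000)
  expr <- generateExpressionTable(atlas,
                                  regionMeans = descendingRegionMeans(nRegions),
                                  probeSd = 0.1, donorSd = 0.1,
                                  seed = seed + 2000)
  list(atlas = atlas, cohort = cohort, stack = stack, expr = expr)
}

# independent per-voxel OLS oracle via explicit normal equations
olsOracle <- function(X, y, cvec) {
  XtXi <- solve(t(X) %*% X)
  beta <- XtXi %*% t(X) %*% y
  res <- y - X %*% beta
  s2 <- sum(res^2) / (nrow(X) - ncol(X))
  list(beta = as.vector(beta),
       t = as.numeric(t(cvec) %*% beta) /
         sqrt(s2 * as.numeric(t(cvec) %*% XtXi %*% cvec)))
}
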