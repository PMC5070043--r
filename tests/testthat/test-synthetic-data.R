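test_that("atlas generation is deterministic, complete and connected", {
  spec <- atlasSpec(c(12, 12, 12), 6, seed = 7)
  a1 <- generateAtlas(spec)
  a2 <- generateAtlas(spec)
  expect_identical(voxelData(a1), voxelData(a2))
  expect_identical(regionLabels(a1), 1:6)
  expect_true(all(voxelData(a1) != 0))
  # each region is one 26-connected component
  for (r in regionLabels(a1)) {
    comp <- stressvbm:::.labelComponents(voxelData(a1) == r)
    expect_equal(max(comp), 1L, info = paste("region", r))
  }
})

test_that("odd grids and region counts still give every region >= 1 voxel", {
  for (n in c(2, 3, 5, 11)) {
    a <- generateAtlas(atlasSpec(c(7, 5, 3), n))
    expect_identical(regionLabels(a), seq_len(n))
    expect_true(all(table(voxelData(a)) >= 1))
  }
})

test_that("more regions than voxels is an invalid-spec error", {
  expect_error(atlasSpec(c(2, 2, 2), 9), "more regions than voxels")
})

test_that("zero-noise expression equals region means; fixed seed repeats", {
  atlas <- generateAtlas(atlasSpec(c(6, 6, 6), 4))
  rm <- descendingRegionMeans(4)
  e1 <- generateExpressionTable(atlas, nDonors = 6, nProbesPerGene = 2,
                                regionMeans = rm, probeSd = 0, donorSd = 0,
                                seed = 3)
  e2 <- generateExpressionTable(atlas, nDonors = 6, nProbesPerGene = 2,
                                regionMeans = rm, probeSd = 0, donorSd = 0,
                                seed = 3)
  expect_identical(e1, e2)
  for (i in seq_len(nrow(e1)))
    expect_equal(e1$expression[i],
                 unname(rm[e1$region_label[i], e1$gene[i]]))
  expect_setequal(unique(e1$gene), c("GR", "MR"))
  # averaging paths are exercised: a multi-sample region, multi-probe genes
  perDonorRegion <- table(e1$region_label[e1$gene == "GR" &
                                            e1$probe_id == "GR_probe1" &
                                            e1$donor_id == "D01"])
  expect_true(any(perDonorRegion > 1))
  expect_gt(length(unique(e1$probe_id)), 2)
  expect_error(generateExpressionTable(atlas, nDonors = 0), "invalid spec")
})

test_that("regional sample means approach region means as donors grow", {
  atlas <- generateAtlas(atlasSpec(c(4, 4, 4), 3))
  rm <- descendingRegionMeans(3)
  nDonors <- 200; probeSd <- 0.3; donorSd <- 0.2
  e <- generateExpressionTable(atlas, nDonors = nDonors,
                               nProbesPerGene = 2, regionMeans = rm,
                               probeSd = probeSd, donorSd = donorSd,
                               seed = 11)
  for (r in 1:3) for (g in c("GR", "MR")) {
    x <- e$expression[e$region_label == r & e$gene == g]
    se <- sqrt(donorSd^2 / nDonors + probeSd^2 / length(x))
    expect_lt(abs(mean(x) - rm[r, g]), 3 * se)
  }
})

test_that("cohort plants the requested QC failures and group structure", {
  spec <- cohortSpec(nUhr = 10, nControl = 8, nTransition = 2,
                     nQcFailVolume = 2, nQcFailTiming = 1,
                     nQcFailDelta30 = 1, nQcFailMissing = 1, seed = 5)
  coh <- generateCohort(spec)
  lowVol <- unique(coh$samples$subject_id[coh$samples$volume_ul < 200])
  expect_length(lowVol, 2)
  qc <- qcFilter(coh$samples)
  expect_equal(sum(!qc$qc_pass), 5)
  expect_equal(sum(grepl("timing_deviation", qc$qc_reasons)), 1)
  expect_equal(sum(grepl("negative_delta30", qc$qc_reasons)), 1)
  expect_equal(sum(grepl("missing_sample", qc$qc_reasons)), 1)
  expect_equal(sum(coh$covariates$transition), 2)
  expect_true(all(coh$covariates$group[coh$covariates$transition == 1] ==
                    "UHR"))
})

test_that("zero-SD groups share the group mean and AUC round-trips exactly", {
  spec <- cohortSpec(nUhr = 5, nControl = 4, carMeanUhr = 200,
                     carSdUhr = 0, carMeanControl = 300, carSdControl = 0,
                     nTransition = 0, nQcFailVolume = 0, nQcFailTiming = 0,
                     nQcFailDelta30 = 0, nQcFailMissing = 0, seed = 2)
  coh <- generateCohort(spec)
  expect_true(all(coh$covariates$car_true[coh$covariates$group == "UHR"]
                  == 200))
  expect_true(all(coh$covariates$car_true[coh$covariates$group == "control"]
                  == 300))
  car <- carTable(coh$samples)
  m <- match(car$subject_id, coh$covariates$subject_id)
  expect_equal(car$auc_i, coh$covariates$car_true[m], tolerance = 1e-10)
})

test_that("transition flags go to the lowest-CAR retained UHR subjects", {
  spec <- cohortSpec(nUhr = 8, nControl = 5, nTransition = 3,
                     nQcFailVolume = 0, nQcFailTiming = 0,
                     nQcFailDelta30 = 0, nQcFailMissing = 0, seed = 9)
  coh <- generateCohort(spec)
  uhr <- coh$covariates[coh$covariates$group == "UHR", ]
  picked <- uhr$subject_id[uhr$transition == 1]
  lowest <- uhr$subject_id[order(uhr$car_true)][1:3]
  expect_setequal(picked, lowest)
})

test_that("an infeasible spec (more failures than subjects) errors", {
  expect_error(cohortSpec(nUhr = 2, nControl = 1, nQcFailVolume = 2,
                          nQcFailTiming = 2, nQcFailDelta30 = 0,
                          nQcFailMissing = 0),
               "more planted QC failures")
})

test_that("paper-mirroring cohorts centre the pooled t near the printed value", {
  ts <- vapply(1:200, function(s) {
    coh <- generateCohort(cohortSpec(nUhr = 22, nControl = 17,
                                     nTransition = 0, nQcFailVolume = 0,
                                     nQcFailTiming = 0, nQcFailDelta30 = 0,
                                     nQcFailMissing = 0, seed = s))
    grp <- coh$covariates$group
    groupTTest(coh$covariates$car_true[grp == "UHR"],
               coh$covariates$car_true[grp == "control"])$t_statistic
  }, numeric(1))
  expect_lt(abs(mean(ts) - (-1.24)), 0.3)
})

test_that("noise-free forward model is inverted exactly by regression", {
  st <- tinyStudy(seed = 3, grid = 8, nRegions = 4,
                  effectRegions = 2, slope = 3, noiseSd = 0)
  # region 2 carries slope 3; regress any of its voxels on planted CAR
  lab <- voxelData(st$atlas)
  ci <- arrayInd(which(lab == 2)[1], dim(lab))
  v <- voxelData(st$stack)
  y <- v[ci[1], ci[2], ci[3], ]
  keep <- match(subjectIds(st$stack), st$cohort$covariates$subject_id)
  car <- st$cohort$covariates$car_true[keep]
  fit <- lm(y ~ car)
  expect_equal(unname(coef(fit)["car"]), 3, tolerance = 1e-10)
  expect_lt(max(abs(residuals(fit))), 1e-9)
})

test_that("image generation is seed-deterministic and QC-aware", {
  st <- tinyStudy(seed = 4, grid = 6, nRegions = 2, noiseSd = 0.05)
  again <- generateGmvImages(st$cohort, st$atlas,
                             effectSpec(noiseSd = 0.05), seed = 1004)
  expect_identical(voxelData(st$stack), voxelData(again))
  spec <- cohortSpec(nUhr = 4, nControl = 3, nTransition = 0,
                     nQcFailVolume = 1, nQcFailTiming = 0,
                     nQcFailDelta30 = 0, nQcFailMissing = 0, seed = 6)
  coh <- generateCohort(spec)
  atlas <- generateAtlas(atlasSpec(c(6, 6, 6), 2))
  stk <- generateGmvImages(coh, atlas, effectSpec(), seed = 1)
  expect_equal(nSubjects(stk), 6)  # one volume per retained subject
  expect_error(generateGmvImages(coh, atlas,
                                 effectSpec(effectRegions = 9,
                                            slopePerRegion = 1), seed = 1),
               "absent from atlas")
})
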