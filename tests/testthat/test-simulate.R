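test_that("cohort simulation is deterministic given the seed", {
  h <- defaultHierarchy()
  spec <- defaultCohortSpec(h, n = 10)
  c1 <- simulateControls(spec, h, seed = 81)
  c2 <- simulateControls(spec, h, seed = 81)
  expect_identical(lapply(c1, volumes), lapply(c2, volumes))
  c3 <- simulateControls(spec, h, seed = 82)
  expect_false(identical(volumes(c1[[1]]), volumes(c3[[1]])))
})

test_that("flat generative slopes are recovered as statistically null", {
  h <- defaultHierarchy()
  spec <- defaultCohortSpec(h, n = 200)
  spec@model$intercept <- spec@model$intercept + spec@model$slope * 58
  spec@model$slope <- 0
  ctrl <- simulateControls(spec, h, seed = 83)
  m <- fitNormative(ctrl, h)
  cf <- modelCoefs(m)
  ages <- vapply(ctrl, caseAge, 0)
  se <- cf$residual_sd / sqrt(sum((ages - mean(ages))^2))
  # 61 simultaneous t-like checks: a 3 SE bound would be exceeded by chance
  # in ~15% of cohorts, a 4 SE bound in ~0.4%
  expect_true(all(abs(cf$slope) < 4 * se))
  expect_gt(mean(abs(cf$slope) < 2 * se), 0.9)
})

test_that("generative noise SD is recovered for base structures at n = 500", {
  h <- defaultHierarchy()
  spec <- defaultCohortSpec(h, n = 500)
  m <- fitNormative(simulateControls(spec, h, seed = 84), h)
  cf <- modelCoefs(m)
  base <- baseStructures(h)
  fitted_sd <- cf$residual_sd[match(base, cf$structure_id)]
  gen_sd <- spec@model$noise_sd[match(base, spec@model$structure_id)]
  expect_true(all(abs(fitted_sd - gen_sd) / gen_sd < 0.15))
})

test_that("infeasible ratio models are rejected", {
  h <- tinyHierarchy()
  expect_error(CohortSpec(
    n = 10, age_range = c(20, 96),
    model = data.frame(structure_id = c("A", "B"),
                       intercept = c(0.001, 0.999),
                       slope = c(-1e-4, 0),   # mean ratio of A < 0 by age 30
                       noise_sd = 1e-4)), "positive")
})

test_that("patient injection shifts the target by the stated SD multiple", {
  h <- defaultHierarchy()
  spec <- defaultCohortSpec(h, n = 100)
  tm <- trueAggregateModel(spec, h)
  p <- simulatePatient(spec, AtrophySpec(c(hippocampus_L = -3)), age = 70,
                       seed = 85, h = h)
  expect_identical(patternKeys(p$truth), "direct:hippocampus_L")
  # noiseless truth z of the target is -3 up to denominator coupling
  expect_equal(zscores(p$true_z)[["hippocampus_L"]], -3, tolerance = 0.05)
  expect_error(simulatePatient(spec, AtrophySpec(c(nonexistent = -3)),
                               70, 1, h = h), "nonexistent")
})

test_that("hemispheric injection is reported at hemisphere, not lobe, level", {
  h <- defaultHierarchy()
  spec <- defaultCohortSpec(h, n = 100)
  atro <- AtrophySpec(stats::setNames(rep(-3, 5),
                                      paste0(LOBES <- c("frontal",
                                                        "parietal",
                                                        "temporal",
                                                        "occipital",
                                                        "limbic"), "_L")),
                      "all left lobes")
  m <- fitNormative(simulateControls(spec, h, seed = 86), h)
  hemi_hits <- 0L
  specific_hits <- 0L
  for (i in 1:40) {
    p <- simulatePatient(spec, atro, 70, seed = 8600 + i, h = h)
    keys <- patternKeys(detectPattern(zscoreCase(p$case, m, h)))
    if ("hemispheric:left" %in% keys) hemi_hits <- hemi_hits + 1L
    if (any(startsWith(keys, "specific:left"))) specific_hits <-
        specific_hits + 1L
  }
  expect_gt(hemi_hits, 20L)        # majority of replicates
  expect_lt(specific_hits, hemi_hits)
  expect_identical(patternKeys(p$truth)[1], "hemispheric:left")
})

test_that("null patients trigger a single structure near the normal tail", {
  h <- defaultHierarchy()
  spec <- defaultCohortSpec(h, n = 500)
  m <- fitNormative(simulateControls(spec, h, seed = 101), h)
  # an empty injection makes the patient an ordinary control draw
  nulls <- simulateControls(`slot<-`(spec, "n", value = 2000L), h,
                            seed = 303)
  vols <- vapply(nulls, function(v) volumes(v)[baseStructures(h)],
                 numeric(length(baseStructures(h))))
  rownames(vols) <- baseStructures(h)
  Z <- scoreCohort(vols, vapply(nulls, caseAge, 0), m, h)
  rate <- mean(Z["hippocampus_L", ] < -2)
  expect_gte(rate, 0.017)
  expect_lte(rate, 0.029)
})

test_that("injected -3 SD atrophy is detected at the closed-form power", {
  # with patient-level noise equal to the control noise, z ~ N(-3, 1)
  # approximately, so P(z < -2) is near pnorm(1) = 0.841 (slightly lower
  # because the fitted residual SD absorbs ~2% normalization noise)
  h <- defaultHierarchy()
  spec <- defaultCohortSpec(h, n = 500)
  m <- fitNormative(simulateControls(spec, h, seed = 101), h)
  hits <- 0L
  for (i in 1:200) {
    p <- simulatePatient(spec, AtrophySpec(c(hippocampus_L = -3)), 70,
                         seed = 20000 + i, h = h)
    if (zscores(zscoreCase(p$case, m, h))[["hippocampus_L"]] < -2)
      hits <- hits + 1L
  }
  expect_equal(hits / 200, pnorm(1), tolerance = 0.10)
})

test_that("cohort and atrophy specs serialize through JSON", {
  h <- defaultHierarchy()
  spec <- defaultCohortSpec(h, n = 25)
  p1 <- withr::local_tempfile(fileext = ".json")
  writeCohortSpec(spec, p1)
  spec2 <- readCohortSpec(p1)
  expect_identical(spec2@n, spec@n)
  expect_equal(spec2@model, spec@model, tolerance = 1e-12)
  p2 <- withr::local_tempfile(fileext = ".json")
  writeAtrophySpec(AtrophySpec(c(hippocampus_L = -3, frontal_L = -2.5),
                               "mixed"), p2)
  a2 <- readAtrophySpec(p2)
  expect_identical(a2@targets, c(hippocampus_L = -3, frontal_L = -2.5))
  expect_identical(a2@pattern_name, "mixed")
})

test_that("simulated cohorts interoperate with the file readers", {
  h <- defaultHierarchy()
  spec <- defaultCohortSpec(h, n = 4)
  ctrl <- simulateControls(spec, h, seed = 87)
  path <- withr::local_tempfile(fileext = ".csv")
  writeVolumeTable(ctrl, path)
  back <- readVolumeTable(path)
  expect_length(back, 4L)
  for (i in 1:4)
    expect_equal(volumes(back[[i]]), volumes(ctrl[[i]]), tolerance = 1e-9)
})
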