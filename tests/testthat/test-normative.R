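test_that("ratios follow the total-brain denominator definition", {
  h <- defaultHierarchy()
  base <- baseStructures(h)
  vols <- stats::setNames(rep(0, length(base)), base)
  # build a case with denominator exactly 1,600,000 and hippocampus_L 4,000
  vols["hippocampus_L"] <- 4000
  others <- setdiff(base, "hippocampus_L")
  vols[others] <- (1.6e6 - 4000) / length(others)
  r <- computeRatios(aggregateSuperstructures(VolumeTable("c", 70, vols), h), h)
  expect_equal(volumes(r)[["hippocampus_L"]], 0.0025, tolerance = 1e-12)
  # uniform scaling leaves every ratio unchanged
  r2 <- computeRatios(aggregateSuperstructures(
    VolumeTable("c", 70, vols * 2), h), h)
  expect_equal(volumes(r2), volumes(r), tolerance = 1e-12)
  # base-label ratios partition unity across the three tissue classes
  cls <- stats::setNames(labelData(h)$tissue_class, labelData(h)$id)[base]
  by_class <- tapply(volumes(r)[base], cls, sum)
  expect_equal(sum(by_class), 1, tolerance = 1e-12)
})

test_that("a non-positive denominator is a hard error", {
  h <- tinyHierarchy()
  expect_error(computeRatios(VolumeTable("c", 60, c(A = 0, B = 0, P = 0)), h),
               "denominator")
})

test_that("the age-linear fit recovers known generative parameters", {
  h <- tinyHierarchy()
  controls <- tinyControls(n = 200, intercept = 0.0030, slope = -1e-5,
                           noise_sd = 2e-4, seed = 41)
  m <- fitNormative(controls, h)
  cf <- modelCoefs(m)
  a <- cf[cf$structure_id == "A", ]
  ages <- vapply(controls, caseAge, 0)
  se_slope <- a$residual_sd / sqrt(sum((ages - mean(ages))^2))
  expect_lt(abs(a$slope - (-1e-5)), 3 * se_slope)
  expect_lt(abs(a$residual_sd - 2e-4) / 2e-4, 0.10)
  expect_identical(a$n_controls, 200L)
  expect_equal(ageRange(m), range(ages))
})

test_that("noiseless controls give an exact degenerate fit", {
  h <- tinyHierarchy()
  controls <- tinyControls(n = 50, intercept = 0.0030, slope = -1e-5,
                           noise_sd = 1e-30, seed = 42)
  m <- fitNormative(controls, h)
  a <- modelCoefs(m)[modelCoefs(m)$structure_id == "A", ]
  expect_lt(a$residual_sd, 1e-9)  # guarded to epsilon, effectively 0
  expect_gt(a$residual_sd, 0)
  expect_equal(unname(predictNormative(m, 60, "A")),
               0.0030 - 1e-5 * 60, tolerance = 1e-9)
})

test_that("identical structures get identical fitted parameters", {
  h <- OntologyHierarchy(
    labels = data.frame(id = c("A", "B", "C", "P"), name = letters[1:4],
                        laterality = "midline", tissue_class = "tissue",
                        level = c(0L, 0L, 0L, 1L)),
    children = list(P = c("A", "B", "C")))
  set.seed(43)
  ages <- runif(20, 20, 90)
  controls <- lapply(seq_len(20), function(i) {
    x <- 1000 + 5 * ages[i] + rnorm(1, sd = 30)
    VolumeTable(paste0("c", i), ages[i], c(A = x, B = x, C = 2000))
  })
  cf <- modelCoefs(fitNormative(controls, h))
  expect_equal(cf[cf$structure_id == "A", -1],
               cf[cf$structure_id == "B", -1], ignore_attr = TRUE)
})

test_that("constant ages and missing structures are hard errors", {
  h <- tinyHierarchy()
  same_age <- lapply(1:5, function(i)
    VolumeTable(paste0("c", i), 60, c(A = 3000, B = 997000)))
  expect_error(fitNormative(same_age, h), "constant")
  controls <- tinyControls(5, 0.003, 0, 1e-4, seed = 44)
  controls[[2]]@volumes <- controls[[2]]@volumes["A"]
  expect_error(fitNormative(controls, h), "B")
})

test_that("z-scores follow their definition", {
  h <- tinyHierarchy()
  m <- fitNormative(tinyControls(200, 0.0030, -1e-5, 2e-4, seed = 45), h)
  a <- modelCoefs(m)[modelCoefs(m)$structure_id == "A", ]
  pred <- a$intercept + a$slope * 60
  atPred <- VolumeTable("c", 60, c(A = pred * 1e6, B = (1 - pred) * 1e6))
  expect_equal(zscores(zscoreCase(atPred, m, h))[["A"]], 0, tolerance = 1e-6)
  shifted <- pred - 2 * a$residual_sd
  at2 <- VolumeTable("c", 60, c(A = shifted * 1e6, B = (1 - shifted) * 1e6))
  expect_equal(zscores(zscoreCase(at2, m, h))[["A"]], -2,
               tolerance = 1e-4)
})

test_that("null cases from the fitted model trigger at the normal tail rate", {
  h <- defaultHierarchy()
  spec <- defaultCohortSpec(h, n = 500)
  m <- fitNormative(simulateControls(spec, h, seed = 101), h)
  nc <- simulateNullCases(m, h, n = 10000, seed = 202)
  Z <- scoreCohort(nc$vols, nc$ages, m, h)
  rate <- mean(Z["hippocampus_L", ] < -2)
  expect_equal(rate, pnorm(-2), tolerance = 0.006 / pnorm(-2))
})

test_that("z is invariant to uniform volume rescaling of controls and case", {
  h <- tinyHierarchy()
  controls <- tinyControls(50, 0.003, -1e-5, 2e-4, seed = 46)
  case <- VolumeTable("p", 70, c(A = 2500, B = 980000))
  z1 <- zscores(zscoreCase(case, fitNormative(controls, h), h))
  scaled <- lapply(controls, function(v)
    VolumeTable(caseId(v), caseAge(v), volumes(v) * 7.3))
  case2 <- VolumeTable("p", 70, volumes(case) * 7.3)
  z2 <- zscores(zscoreCase(case2, fitNormative(scaled, h), h))
  expect_equal(z1, z2, tolerance = 1e-9)
})

test_that("fitting and scoring are reproducible for fixed data", {
  h <- tinyHierarchy()
  controls <- tinyControls(50, 0.003, -1e-5, 2e-4, seed = 47)
  case <- VolumeTable("p", 70, c(A = 2500, B = 980000))
  m1 <- fitNormative(controls, h)
  m2 <- fitNormative(controls, h)
  expect_identical(modelCoefs(m1), modelCoefs(m2))
  expect_identical(zscores(zscoreCase(case, m1, h)),
                   zscores(zscoreCase(case, m2, h)))
})

test_that("shrinking a tissue structure never raises its z", {
  h <- tinyHierarchy()
  m <- fitNormative(tinyControls(100, 0.003, -1e-5, 2e-4, seed = 48), h)
  vols <- seq(1500, 4000, by = 250)
  zs <- vapply(vols, function(a)
    zscores(zscoreCase(VolumeTable("p", 70, c(A = a, B = 997000)), m,
                       h))[["A"]], 0)
  expect_true(all(diff(zs) > 0))  # volume up => z up, monotonic
})

test_that("scoring outside the normative age range warns and flags", {
  h <- tinyHierarchy()
  m <- fitNormative(tinyControls(50, 0.003, -1e-5, 2e-4, seed = 49,
                                 age_range = c(40, 80)), h)
  case <- VolumeTable("p", 97, c(A = 3000, B = 997000))
  expect_warning(z <- zscoreCase(case, m, h), "outside")
  expect_true(z@extrapolated)
  expect_true(all(is.finite(zscores(z))))
})

test_that("unmodeled structures get NA markers, not errors", {
  h <- tinyHierarchy()
  m <- fitNormative(tinyControls(50, 0.003, -1e-5, 2e-4, seed = 50), h)
  cf <- modelCoefs(m)
  m2 <- new("NormativeModel", coef = cf[cf$structure_id != "A", ],
            age_range = ageRange(m), units = "ratio")
  z <- zscoreCase(VolumeTable("p", 70, c(A = 3000, B = 997000)), m2, h)
  expect_true(is.na(zscores(z)[["A"]]))
  expect_false(is.na(zscores(z)[["B"]]))
})

test_that("the normative model serializes losslessly", {
  h <- defaultHierarchy()
  spec <- defaultCohortSpec(h, n = 20)
  m <- fitNormative(simulateControls(spec, h, seed = 51), h)
  path <- withr::local_tempfile(fileext = ".json")
  writeNormativeModel(m, path)
  m2 <- readNormativeModel(path)
  expect_equal(modelCoefs(m2), modelCoefs(m), tolerance = 1e-12)
  expect_equal(ageRange(m2), ageRange(m), tolerance = 1e-12)
})

test_that("the vectorized cohort scorer matches the per-case pipeline", {
  h <- defaultHierarchy()
  spec <- defaultCohortSpec(h, n = 30)
  ctrl <- simulateControls(spec, h, seed = 52)
  m <- fitNormative(ctrl, h)
  cases <- simulateControls(spec, h, seed = 53)[1:5]
  vols <- vapply(cases, function(v) volumes(v)[baseStructures(h)],
                 numeric(length(baseStructures(h))))
  rownames(vols) <- baseStructures(h)
  Z <- scoreCohort(vols, vapply(cases, caseAge, 0), m, h)
  for (i in 1:5) {
    z <- zscores(zscoreCase(cases[[i]], m, h))
    expect_equal(Z[names(z), i], z, tolerance = 1e-9)
  }
})
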