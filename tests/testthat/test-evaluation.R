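# brute-force contingency oracle: explicit double loop over all (case, term)
oracleContingency <- function(ref, tst, universe, cases) {
  tp <- fp <- fn <- tn <- 0L
  isPos <- function(df, cid, term)
    any(df$case_id == cid & df$structure_term == term &
          df$polarity == "positive")
  for (cid in cases) for (term in universe) {
    r <- isPos(ref, cid, term)
    t <- isPos(tst, cid, term)
    if (r && t) tp <- tp + 1L else if (t) fp <- fp + 1L
    else if (r) fn <- fn + 1L else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

test_that("empty finding sets give an all-TN table over the universe", {
  cases <- sprintf("case%02d", 1:92)
  universe <- sprintf("term%02d", 1:23)
  empty <- data.frame(case_id = character(0), structure_term = character(0),
                      polarity = character(0))
  cc <- buildContingency(empty, empty, universe, cases)
  expect_identical(counts(cc), c(tp = 0L, fp = 0L, fn = 0L, tn = 2116L))
})

test_that("a single shared positive is a TP", {
  one <- data.frame(case_id = "c1", structure_term = "t1",
                    polarity = "positive")
  cc <- buildContingency(one, one, "t1", "c1")
  expect_identical(counts(cc), c(tp = 1L, fp = 0L, fn = 0L, tn = 0L))
})

test_that("contingency counts match the brute-force oracle on random data", {
  cases <- paste0("c", 1:6)
  universe <- paste0("t", 1:5)
  ref <- randomFindings(71, "RR1", universe, cases, p = 0.4)
  tst <- randomFindings(72, "AS", universe, cases, p = 0.3)
  cc <- buildContingency(ref, tst, universe, cases)
  expect_identical(counts(cc), oracleContingency(ref, tst, universe, cases))
  expect_identical(sum(counts(cc)), length(cases) * length(universe))
})

test_that("terms outside the universe are excluded and logged", {
  ref <- data.frame(case_id = "c1", structure_term = "medial_temporal_lobe",
                    polarity = "positive")
  tst <- data.frame(case_id = "c1", structure_term = "t1",
                    polarity = "positive")
  expect_message(cc <- buildContingency(ref, tst, "t1", "c1"),
                 "medial_temporal_lobe")
  expect_identical(counts(cc), c(tp = 0L, fp = 1L, fn = 0L, tn = 0L))
})

test_that("agreement metrics handle degenerate denominators explicitly", {
  m <- agreementMetrics(ContingencyCounts(0, 0, 0, 10))
  expect_identical(m[["accuracy"]], 1)
  expect_true(is.na(m[["sensitivity"]]))
  expect_error(agreementMetrics(ContingencyCounts(0, 0, 0, 0)), "empty")
})

test_that("kappa equals an independent expansion-based computation", {
  kappaOracle <- function(tp, fp, fn, tn) {
    # expand to paired binary vectors and compute p_o, p_e empirically
    test <- rep(c(1, 1, 0, 0), c(tp, fp, fn, tn))
    ref <- rep(c(1, 0, 1, 0), c(tp, fp, fn, tn))
    po <- mean(test == ref)
    pe <- mean(test) * mean(ref) + mean(!test) * mean(!ref)
    (po - pe) / (1 - pe)
  }
  for (cnt in list(c(23, 94, 98, 1901), c(39, 82, 82, 1913),
                   c(5, 30, 0, 57), c(12, 3, 7, 40))) {
    expect_equal(cohenKappa(ContingencyCounts(cnt[1], cnt[2], cnt[3],
                                              cnt[4])),
                 kappaOracle(cnt[1], cnt[2], cnt[3], cnt[4]),
                 tolerance = 1e-12)
  }
})

test_that("perfect agreement gives kappa 1 and unanimity NA", {
  expect_identical(cohenKappa(ContingencyCounts(7, 0, 0, 13)), 1)
  expect_true(is.na(cohenKappa(ContingencyCounts(5, 0, 0, 0))))
})

test_that("kappa sign follows observed vs chance agreement on the study tables", {
  for (cc in referenceAgreementCounts("structurewise")) {
    cnt <- counts(cc)
    N <- sum(cnt)
    po <- (cnt[["tp"]] + cnt[["tn"]]) / N
    pe <- ((cnt[["tp"]] + cnt[["fp"]]) / N) * ((cnt[["tp"]] + cnt[["fn"]]) / N) +
      ((cnt[["fn"]] + cnt[["tn"]]) / N) * ((cnt[["fp"]] + cnt[["tn"]]) / N)
    expect_identical(cohenKappa(cc) >= 0, po >= pe)
  }
})

test_that("metrics are invariant to case order", {
  cases <- paste0("c", 1:6)
  universe <- paste0("t", 1:4)
  ref <- randomFindings(73, "RR1", universe, cases, p = 0.4)
  tst <- randomFindings(74, "AS", universe, cases, p = 0.3)
  cc1 <- buildContingency(ref, tst, universe, cases)
  perm <- sample(nrow(ref))
  cc2 <- buildContingency(ref[perm, ], tst[rev(seq_len(nrow(tst))), ],
                          universe, rev(cases))
  expect_identical(counts(cc1), counts(cc2))
})

test_that("majority voting implements the 2-of-3 rule", {
  mk <- function(src, terms) data.frame(case_id = "c1", source = src,
                                        structure_term = terms,
                                        polarity = "positive")
  fnd <- rbind(mk("RR1", c("a", "b")), mk("RR2", c("a")), mk("RR3", c("c")))
  rrm <- majorityVote(fnd, c("a", "b", "c"), "c1")
  expect_identical(rrm$structure_term, "a")   # 2 votes; b and c have 1
  expect_identical(unique(rrm$source), "RRm")
  expect_error(majorityVote(fnd[fnd$source != "RR3", ], c("a"), "c1"),
               "exactly 3")
})

test_that("majority voting matches a brute-force vote count on random sets", {
  cases <- paste0("c", 1:5)
  universe <- paste0("t", 1:6)
  fnd <- randomFindings(75, c("RR1", "RR2", "RR3"), universe, cases, p = 0.35)
  rrm <- majorityVote(fnd, universe, cases)
  for (cid in cases) for (term in universe) {
    votes <- sum(vapply(c("RR1", "RR2", "RR3"), function(src)
      any(fnd$case_id == cid & fnd$source == src &
            fnd$structure_term == term & fnd$polarity == "positive"),
      logical(1)))
    got <- any(rrm$case_id == cid & rrm$structure_term == term)
    expect_identical(got, votes >= 2)
  }
})

test_that("the discrepancy tree reproduces its worked examples", {
  h <- defaultHierarchy()
  ckf <- defaultCKF(h)
  # an undefined anatomic term falls in category 1
  r1 <- categorizeDiscrepancy(list(direction = "FN",
                                   term = "medial temporal lobe"), h, ckf)
  expect_identical(r1$category, "1")
  # z supports the human finding but the relational rules suppressed it
  z <- makeZ(c(frontal_L = -2.24, hemisphere_L = -2.1, temporal_L = -2.3), h)
  r3 <- categorizeDiscrepancy(list(direction = "FN", term = "frontal_L",
                                   zscores = z), h, ckf)
  expect_identical(r3$category, "3")
  # ancestor/descendant term pair is an extent mismatch (category 4)
  r4 <- categorizeDiscrepancy(list(direction = "FP", term = "hemisphere_L",
                                   counterpart_term = "frontal_L",
                                   rater_terms = c("frontal_L",
                                                   "hemisphere_L")), h, ckf)
  expect_identical(r4$category, "4")
})

test_that("the remaining discrepancy categories follow the tree order", {
  h <- defaultHierarchy()
  ckf <- defaultCKF(h)
  # structure reported by the tool but never used by any rater
  r21 <- categorizeDiscrepancy(list(direction = "FP", term = "caudate_L",
                                    rater_terms = c("hippocampus_L",
                                                    "hemisphere_L")), h, ckf)
  expect_identical(r21$category, "2-1")
  # structure the raters used but the filter does not report
  r22 <- categorizeDiscrepancy(list(direction = "FN", term = "amygdala_L"),
                               h, ckf)
  expect_identical(r22$category, "2-2")
  # annotated segmentation error
  r5 <- categorizeDiscrepancy(list(direction = "FN", term = "hippocampus_L",
                                   zscores = makeZ(c(hippocampus_L = -1.5), h),
                                   flags = "segmentation_error"), h, ckf)
  expect_identical(r5$category, "5")
  # otherwise the threshold category, split by direction
  r6 <- categorizeDiscrepancy(list(direction = "FN", term = "hippocampus_L",
                                   zscores = makeZ(c(hippocampus_L = -1.5),
                                                   h)), h, ckf)
  expect_identical(r6$category, "6-FN")
  expect_identical(categorizeDiscrepancy(list(direction = "FP",
                                              term = "hippocampus_L"),
                                         h, ckf)$category, "6-FP")
  # alias mapping rescues free vocabulary before category 1
  ra <- categorizeDiscrepancy(list(direction = "FN", term = "hippocampal head",
                                   aliases = c("hippocampal head" =
                                                 "hippocampus_L")), h, ckf)
  expect_identical(ra$category, "6-FN")
  expect_error(categorizeDiscrepancy(list(direction = "TP", term = "x"),
                                     h, ckf), "FP or FN")
})

test_that("metricsTable assembles counts, metrics and kappa per comparison", {
  tab <- metricsTable(referenceAgreementCounts("brain_tissue"))
  expect_identical(tab$comparison, c("AS-RR1", "AS-RR2", "AS-RR3"))
  expect_equal(round(tab$accuracy_pct, 1), c(70.7, 68.5, 70.7))
  expect_true(all(c("kappa", "tp", "specificity_pct") %in% names(tab)))
})
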