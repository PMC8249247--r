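test_that("high-risk selection from the published counts yields the six
           genes and excludes RPL22", {
  m <- matrixFromCounts(list(ACC = ACC_COUNTS, ACA = ACA_COUNTS),
                        c(ACC = 37, ACA = 32))
  tests <- testAllGenes(m, "ACC", "ACA")
  hr <- selectHighRisk(tests, alpha = 0.05)
  expect_setequal(highRiskGenes(hr), CANONICAL_SIX)
  # ordered by ascending p, ties alphabetical
  p <- tests$p_value[match(highRiskGenes(hr), tests$gene)]
  expect_true(all(diff(p) >= 0))
  # RPL22 sits just above the cut
  rpl22 <- tests[tests$gene == "RPL22", ]
  expect_equal(round(rpl22$p_value, 3), 0.052)
  expect_false("RPL22" %in% highRiskGenes(hr))
  # MEN1 and CTNNB1 are not selected either
  expect_false(any(c("MEN1", "CTNNB1") %in% highRiskGenes(hr)))
})

test_that("selection against the normal group adds CTNNB1 but never MEN1", {
  m <- matrixFromCounts(list(ACC = ACC_COUNTS, NORMAL = NORMAL_COUNTS),
                        c(ACC = 37, NORMAL = 25))
  tests <- testAllGenes(m, "ACC", "NORMAL")
  hr <- selectHighRisk(tests, alpha = 0.05)
  expect_true(all(c(CANONICAL_SIX, "CTNNB1") %in% highRiskGenes(hr)))
  expect_false("MEN1" %in% highRiskGenes(hr))
  # RPL22 at 9/37 vs 0/25 is itself below alpha under the exact test
  # (p ~ 0.008, cross-checked against stats::fisher.test)
  pRpl22 <- tests$p_value[tests$gene == "RPL22"]
  expect_equal(pRpl22,
               fisher.test(matrix(c(9, 28, 0, 25), 2, byrow = TRUE))$p.value,
               tolerance = 1e-9)
  expect_true("RPL22" %in% highRiskGenes(hr))
})

test_that("selection edge cases: all-null tests, inclusive alpha,
           duplicates", {
  m0 <- buildMatrix(makeVariants(character(0), character(0)),
                    rbind(makeMetadata(paste0("C", 1:5), "ACC"),
                          makeMetadata(paste0("A", 1:5), "ACA")))
  tests0 <- testAllGenes(m0, "ACC", "ACA")
  expect_length(highRiskGenes(selectHighRisk(tests0)), 0)
  # p exactly at alpha is selected (inclusive rule)
  t1 <- data.frame(gene = c("TP53", "APC"), p_value = c(0.05, 0.051),
                   direction = "group1_higher", rate1 = 0.5, rate2 = 0.1)
  expect_identical(highRiskGenes(selectHighRisk(t1, 0.05)), "TP53")
  # direction matters: a group2-higher gene is never high-risk
  t2 <- data.frame(gene = "TP53", p_value = 0.001,
                   direction = "group2_higher", rate1 = 0.1, rate2 = 0.5)
  expect_length(highRiskGenes(selectHighRisk(t2)), 0)
  expect_error(selectHighRisk(rbind(t1, t1)), "duplicate")
})

test_that("SHGM is the count of mutated high-risk genes", {
  fx <- table5Fixture()
  m <- buildMatrix(fx$variants, fx$metadata)
  hr <- highRiskSet(CANONICAL_SIX)
  sc <- scoreCohort(m, hr)
  expect_identical(sc$shgm, c(2L, 3L, 6L, 0L, 0L, 5L, 1L, 1L))
  one <- computeShgm(m, hr, "C11")
  expect_identical(one$score, 6L)
  expect_setequal(one$genes, CANONICAL_SIX)
  expect_identical(computeShgm(m, hr, "C4")$score, 3L)
  expect_identical(computeShgm(m, hr, "C19")$score, 0L)
  expect_error(computeShgm(m, hr, "C99"), "unknown sample")
  # scores are bounded by the high-risk set size
  expect_true(all(sc$shgm >= 0 & sc$shgm <= length(CANONICAL_SIX)))
})

test_that("threshold diagnostics reproduce the published predictive
           values", {
  pub <- publishedCohortScores()
  d <- evaluateThreshold(pub$scores, pub$labels, thresholds = c(0, 1))
  expect_identical(d$TP, c(27L, 23L))
  expect_identical(d$FP, c(6L, 1L))
  expect_equal(round(d$ppv, 1), c(81.8, 95.8))
  expect_equal(round(d$npv, 1), c(72.2, 68.9))
  expect_equal(round(d$sensitivity, 1), c(73.0, 62.2))
  expect_equal(d$specificity, 100 * c(26 / 32, 31 / 32))
  # confusion counts always partition the cohort
  expect_true(all(d$TP + d$FP + d$FN + d$TN == 69L))
})

test_that("degenerate threshold evaluations produce NAs, not errors", {
  # perfectly separated cohort: all four metrics 100
  d <- evaluateThreshold(c(3, 3, 0, 0), c("ACC", "ACC", "ACA", "ACA"), 0)
  expect_equal(unlist(d[, c("sensitivity", "specificity", "ppv", "npv")]),
               c(sensitivity = 100, specificity = 100, ppv = 100,
                 npv = 100))
  # no positive calls: PPV undefined
  d0 <- evaluateThreshold(c(0, 0, 0), c("ACC", "ACA", "ACA"), 0)
  expect_true(is.na(d0$ppv))
  expect_equal(d0$specificity, 100)
  # single-group input warns and NAs the impossible metrics
  expect_warning(d1 <- evaluateThreshold(c(1, 0), c("ACC", "ACC"), 0),
                 "both ACC and ACA")
  expect_true(is.na(d1$specificity))
})

test_that("sensitivity decreases and specificity increases with the
           threshold", {
  set.seed(606)
  for (seed in 1:5) {
    sim <- simulateCohort(cohortModel(), seed = seed)
    m <- buildMatrix(filterSignificant(sim$variants), sim$metadata)
    sc <- scoreCohort(m, highRiskSet(CANONICAL_SIX))
    d <- evaluateThreshold(sc, thresholds = 0:6)
    expect_true(all(diff(d$positives) <= 0))
    sens <- d$sensitivity[!is.na(d$sensitivity)]
    spec <- d$specificity[!is.na(d$specificity)]
    expect_true(all(diff(sens) <= 1e-9))
    expect_true(all(diff(spec) >= -1e-9))
    expect_true(all(d$TP + d$FP + d$FN + d$TN ==
                      sum(sim$metadata$group %in% c("ACC", "ACA"))))
  }
})

test_that("small-tumor subgroup metrics reproduce the worked example", {
  fx <- table5Fixture()
  m <- buildMatrix(fx$variants, fx$metadata)
  sc <- scoreCohort(m, highRiskSet(CANONICAL_SIX))
  sub <- subgroupMetrics(sc, fx$metadata, diameter_cm <= 5,
                         thresholds = c(0, 1))
  expect_identical(sub$n_subgroup, c(8L, 8L))
  expect_identical(sub$n_positive, c(6L, 4L))
  expect_equal(sub$pct_positive, c(75, 50))
  # the 5.0 cm sample C1 is inside the subgroup (inclusive cutoff)
  subStrict <- subgroupMetrics(sc, fx$metadata, diameter_cm < 5,
                               thresholds = 0)
  expect_identical(subStrict$n_subgroup, 7L)
  # empty subgroup: NA-flagged, not an error
  none <- subgroupMetrics(sc, fx$metadata, diameter_cm > 100,
                          thresholds = 0)
  expect_identical(none$n_subgroup, 0L)
  expect_true(is.na(none$pct_positive))
})

test_that("a pinned high-risk set validates against the panel", {
  expect_error(highRiskSet(c("ZNRF3", "EGFR")), "outside the panel")
  expect_error(highRiskSet(c("ZNRF3", "ZNRF3")), "duplicate")
  hr <- highRiskSet(CANONICAL_SIX)
  expect_identical(highRiskGenes(hr), CANONICAL_SIX)
})
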