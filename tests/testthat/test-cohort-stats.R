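test_that("exact test matches the brute-force enumeration oracle", {
  # printed-table cases and random tables, against the choose()-based oracle
  cases <- list(c(12, 25, 1, 31),   # APC, significant
                c(20, 17, 2, 30),   # ZNRF3
                c(9, 28, 2, 30),    # RPL22, borderline
                c(0, 5, 0, 7), c(3, 0, 0, 3))
  set.seed(101)
  for (i in 1:40)
    cases[[length(cases) + 1]] <- c(sample(0:8, 2), sample(0:8, 2))
  for (cs in cases) {
    if (cs[1] + cs[2] == 0 || cs[3] + cs[4] == 0) next
    expect_equal(fisherExactTwoSided(cs[1], cs[2], cs[3], cs[4]),
                 fisherOracle(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-12, info = paste(cs, collapse = ","))
  }
})

test_that("exact test agrees with stats::fisher.test as a cross-check", {
  set.seed(202)
  for (i in 1:50) {
    a <- rbinom(1, 20, 0.4); b <- rbinom(1, 20, 0.5) + 1
    c <- rbinom(1, 20, 0.2); d <- rbinom(1, 20, 0.5) + 1
    expect_equal(
      fisherExactTwoSided(a, b, c, d),
      fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value,
      tolerance = 1e-9, info = paste(a, b, c, d))
  }
})

test_that("exact test p-values are symmetric and bounded", {
  set.seed(303)
  for (i in 1:30) {
    a <- sample(0:10, 1); b <- sample(0:10, 1) + 1
    c <- sample(0:10, 1); d <- sample(0:10, 1) + 1
    p <- fisherExactTwoSided(a, b, c, d)
    expect_gt(p, 0); expect_lte(p, 1)
    # swapping the groups leaves the two-sided p unchanged
    expect_equal(p, fisherExactTwoSided(c, d, a, b), tolerance = 1e-12)
    # swapping mutated/unmutated columns leaves it unchanged
    expect_equal(p, fisherExactTwoSided(b, a, d, c), tolerance = 1e-12)
  }
  # identical groups give p = 1
  expect_equal(fisherExactTwoSided(5, 12, 5, 12), 1)
  expect_error(fisherExactTwoSided(-1, 2, 3, 4), "non-negative")
  expect_error(fisherExactTwoSided(0, 0, 3, 4), "positive")
})

test_that("per-gene rate tests reproduce the published comparisons", {
  m <- matrixFromCounts(list(ACC = ACC_COUNTS, ACA = ACA_COUNTS),
                        c(ACC = 37, ACA = 32))
  znrf3 <- geneRateTest(m, "ZNRF3", "ACC", "ACA")
  expect_lt(znrf3$p_value, 0.001)
  expect_identical(znrf3$direction, "group1_higher")
  expect_equal(znrf3$rate1, 20 / 37)
  expect_equal(znrf3$rate2, 2 / 32)
  men1 <- geneRateTest(m, "MEN1", "ACC", "ACA")
  expect_gt(men1$p_value, 0.05)
  expect_error(geneRateTest(m, "EGFR"), "unknown panel gene")
  expect_error(geneRateTest(m, "TP53", "ACC", "NORMAL"), "nonempty")
})

test_that("all-gene scan orders by descending rate with alphabetical ties", {
  m <- matrixFromCounts(list(ACC = ACC_COUNTS, ACA = ACA_COUNTS),
                        c(ACC = 37, ACA = 32))
  res <- testAllGenes(m, "ACC", "ACA")
  expect_identical(nrow(res), 9L)
  # MEN1 and ZNRF3 tie at 54.1%; MEN1 first alphabetically
  expect_identical(res$gene[1:2], c("MEN1", "ZNRF3"))
  expect_true(all(diff(res$rate1) <= 1e-12))
  # per-gene recomputation oracle: same p gene by gene
  for (i in seq_len(nrow(res)))
    expect_equal(res$p_value[i],
                 geneRateTest(m, res$gene[i], "ACC", "ACA")$p_value)
  # all-zero matrix: nine results, all p = 1
  m0 <- buildMatrix(makeVariants(character(0), character(0)),
                    rbind(makeMetadata(paste0("C", 1:5), "ACC"),
                          makeMetadata(paste0("A", 1:5), "ACA")))
  res0 <- testAllGenes(m0, "ACC", "ACA")
  expect_true(all(res0$p_value == 1))
  expect_true(all(res0$direction == "equal"))
})

test_that("the exact test holds its nominal type-I error under the null", {
  set.seed(404)
  reps <- 2000
  a <- rbinom(reps, 37, 0.3)
  c <- rbinom(reps, 32, 0.3)
  p <- vapply(seq_len(reps), function(i)
    fisherExactTwoSided(a[i], 37 - a[i], c[i], 32 - c[i]), numeric(1))
  expect_lte(mean(p <= 0.05), 0.05)  # Fisher is conservative
})

test_that("burden comparison picks the right rank test", {
  # three identical groups: statistic 0, p ~ 1
  b3 <- compareBurden(list(g1 = c(1, 2, 3), g2 = c(1, 2, 3),
                           g3 = c(1, 2, 3)))
  expect_identical(b3$method, "kruskal_wallis")
  expect_equal(b3$statistic, 0)
  expect_gt(b3$p_value, 0.99)
  # two fully separated groups of 3: p equals the most extreme ranking,
  # verified by enumerating all C(6,3) = 20 splits of the rank sum
  b2 <- compareBurden(list(lo = c(1, 2, 3), hi = c(101, 102, 103)))
  expect_identical(b2$method, "wilcoxon_rank_sum")
  splits <- combn(6, 3)
  obs <- sum(1:3)  # ranks of the smaller group
  rankSums <- colSums(matrix((1:6)[splits], nrow = 3))
  pEnum <- mean(rankSums <= obs | rankSums >= sum(4:6))
  expect_equal(b2$p_value, pEnum)
  expect_error(compareBurden(list(a = 1:3, b = numeric(0))), "nonempty")
})

test_that("burden separation at published scale is highly significant", {
  # ACC-like (median 4 mutated genes) vs ACA-like (median 1)
  set.seed(505)
  sim <- simulateCohort(cohortModel(), seed = 505)
  m <- buildMatrix(filterSignificant(sim$variants), sim$metadata)
  counts <- split(colSums(mutationIndicator(m)),
                  as.character(sampleGroups(m)))
  b <- compareBurden(counts[c("ACC", "ACA")])
  expect_lt(b$p_value, 0.001)
})

test_that("clinical association handles the continuous and degenerate
           cases", {
  s <- c(0, 2, 3, 6, 1, 5)
  # covariate identical to the score: rho = 1
  ca <- clinicalAssociation(s, s, "continuous", name = "self")
  expect_equal(ca$effect, 1)
  # constant score: undefined, flagged, no error
  flat <- clinicalAssociation(rep(2, 6), s, "continuous")
  expect_false(flat$defined)
  # fewer than 3 complete pairs: undefined
  few <- clinicalAssociation(c(1, 2, NA), c(NA, 5, 6), "continuous")
  expect_false(few$defined)
  # n = 6, no ties: matches the rank-difference formula directly
  x <- c(3, 1, 4, 15, 9, 2)
  d <- rank(s) - rank(x)
  rhoOracle <- 1 - 6 * sum(d^2) / (6 * (36 - 1))
  expect_equal(clinicalAssociation(s, x, "continuous")$effect, rhoOracle)
})

test_that("clinical association compares score medians across two levels", {
  s <- c(0, 2, 3, 6, 1, 5, 4, 2)
  sex <- rep(c("M", "F"), 4)
  ca <- clinicalAssociation(s, sex, "categorical", name = "sex")
  expect_true(ca$defined)
  expect_named(ca$effect, c("F", "M"))
  expect_equal(ca$effect$M$median, median(s[sex == "M"]))
  # three levels are rejected as undefined, not an error
  bad <- clinicalAssociation(s, rep(c("a", "b", "c"), length.out = 8),
                             "categorical")
  expect_false(bad$defined)
})
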