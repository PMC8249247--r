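test_that("simulation is reproducible from the seed", {
  s1 <- simulateCohort(cohortModel(), seed = 42)
  s2 <- simulateCohort(cohortModel(), seed = 42)
  expect_identical(s1, s2)
  s3 <- simulateCohort(cohortModel(), seed = 43)
  expect_false(identical(s1$variants, s3$variants))
  # a model-embedded seed works the same way
  s4 <- simulateCohort(cohortModel(seed = 42))
  expect_identical(s1, s4)
})

test_that("empty groups give empty tables with intact headers", {
  m0 <- cohortModel(nPerGroup = c(ACC = 0L, ACA = 0L, NORMAL = 0L))
  sim <- simulateCohort(m0, seed = 1)
  expect_identical(nrow(sim$variants), 0L)
  expect_identical(nrow(sim$metadata), 0L)
  expect_true(all(c("sample_id", "gene", "chrom", "pos", "ref", "alt",
                    "effect", "pop_af") %in% names(sim$variants)))
  expect_true(all(c("sample_id", "group", "diameter_cm") %in%
                    names(sim$metadata)))
})

test_that("simulated cohorts have the advertised shape", {
  sim <- simulateCohort(cohortModel(), seed = 8)
  expect_identical(as.integer(table(sim$metadata$group)[c("ACC", "ACA",
                                                          "NORMAL")]),
                   c(37L, 32L, 25L))
  expect_true(all(sim$variants$gene %in% panelGenes()))
  expect_true(all(sim$variants$pos >= 1))
  # significant calls carry AF 0; decoys are synonymous or common
  sig <- isSignificant(sim$variants, filterConfig())
  expect_true(all(sim$variants$pop_af[sig] == 0))
  decoys <- sim$variants[!sig, ]
  expect_true(all(normalizeEffectLabel(decoys$effect) == "SYNONYMOUS_SNV" |
                    decoys$pop_af >= 0.01))
  expect_gt(nrow(decoys), 0)
  # covariates within plausible ranges
  expect_true(all(sim$metadata$diameter_cm > 0))
  expect_true(all(sim$metadata$ki67 >= 10 & sim$metadata$ki67 <= 25))
})

test_that("per-gene marginal rates are recovered at large n", {
  n <- 2000L
  model <- cohortModel(nPerGroup = c(ACC = n, ACA = 0L, NORMAL = 0L))
  sim <- simulateCohort(model, seed = 99)
  m <- buildMatrix(filterSignificant(sim$variants), sim$metadata)
  emp <- rowMeans(mutationIndicator(m))
  for (g in panelGenes()) {
    p <- model@rates[g, "ACC"]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(emp[[g]] - p), 3 * se + 1e-9)
  }
  # quiet-sample fraction near its configured weight
  zero <- mean(colSums(mutationIndicator(m)) == 0)
  # quiet samples plus active samples that happen to draw no gene
  pActiveZero <- prod(1 - pmin(model@rates[, "ACC"] / (1 - 6 / 37), 1))
  pZero <- 6 / 37 + (1 - 6 / 37) * pActiveZero
  expect_lt(abs(zero - pZero), 3 * sqrt(pZero * (1 - pZero) / n))
})

test_that("closed-form positivity matches simulation and its trivial
           cases", {
  model <- cohortModel()
  # no genes: probability 0
  expect_equal(independencePositivity(model, "ACC", character(0)), 0)
  # single gene, no mixture: probability equals the marginal rate
  m1 <- cohortModel(quietWeight = c(ACC = 0, ACA = 0, NORMAL = 0),
                    rates = {
                      r <- cohortModel()@rates * 0
                      r["ZNRF3", "ACC"] <- 0.5
                      r
                    })
  expect_equal(independencePositivity(m1, "ACC", "ZNRF3"), 0.5)
  # with the mixture: matches a large simulation within Monte-Carlo error
  n <- 20000L
  big <- cohortModel(nPerGroup = c(ACC = n, ACA = 0L, NORMAL = 0L),
                     decoyFraction = 0)
  sim <- simulateCohort(big, seed = 17)
  m <- buildMatrix(sim$variants, sim$metadata)
  sc <- scoreCohort(m, highRiskSet(CANONICAL_SIX))
  pHat <- mean(sc$shgm > 0)
  pTheory <- independencePositivity(big, "ACC", CANONICAL_SIX)
  expect_lt(abs(pHat - pTheory),
            3 * sqrt(pTheory * (1 - pTheory) / n))
  # the mixture prediction sits below the independence (pi = 0) prediction
  noMix <- cohortModel(quietWeight = c(ACC = 0, ACA = 0, NORMAL = 0))
  expect_lt(pTheory, independencePositivity(noMix, "ACC", CANONICAL_SIX))
})

test_that("mutation-type shares converge to the configured simplex", {
  n <- 1500L
  model <- cohortModel(nPerGroup = c(ACC = n, ACA = 0L, NORMAL = 0L),
                       decoyFraction = 0)
  sim <- simulateCohort(model, seed = 23)
  # exclude RPL22, which carries its own type override
  v <- sim$variants[sim$variants$gene != "RPL22", ]
  emp <- table(normalizeEffectLabel(v$effect)) / nrow(v)
  w <- model@typeWeights$ACC
  l1 <- sum(abs(emp[names(w)] - w))
  expect_lt(l1, 0.02)
  # RPL22 override: frameshift deletions dominate
  rpl <- sim$variants[sim$variants$gene == "RPL22", ]
  shareFs <- mean(normalizeEffectLabel(rpl$effect) ==
                    "FRAMESHIFT_DELETION")
  expect_lt(abs(shareFs - 6 / 9), 3 * sqrt((6 / 9) * (3 / 9) / nrow(rpl)))
})

test_that("power at published scale: ZNRF3 detected in most replicates", {
  model <- cohortModel(nPerGroup = c(ACC = 37L, ACA = 32L, NORMAL = 0L),
                       decoyFraction = 0)
  hits <- vapply(1:50, function(seed) {
    sim <- simulateCohort(model, seed = 7000 + seed)
    m <- buildMatrix(sim$variants, sim$metadata)
    geneRateTest(m, "ZNRF3", "ACC", "ACA")$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("an out-of-range model is rejected by the validity method", {
  expect_error(cohortModel(decoyFraction = 1.5), "decoyFraction")
  expect_error(cohortModel(quietWeight = c(ACC = 1, ACA = 0, NORMAL = 0)),
               "quietWeight")
  badRates <- cohortModel()@rates
  badRates[1, 1] <- 2
  expect_error(cohortModel(rates = badRates), "probabilities")
})

test_that("the packaged worked-example fixture is deterministic and
           self-consistent", {
  fx <- table5Fixture()
  expect_identical(fx, table5Fixture())
  expect_identical(nrow(fx$metadata), 8L)
  expect_true(all(fx$metadata$diameter_cm <= 5))
  expect_identical(sum(fx$metadata$diameter_cm <= 5), 8L)
  # all fixture variants survive the default filter
  expect_identical(filterSignificant(fx$variants), fx$variants)
})
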