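# Shared fixtures and oracles, all built in code.

CANONICAL_SIX <- c("ZNRF3", "TP53", "ARMC5", "APC", "RB1", "PRKAR1A")

# Published per-gene mutated-sample counts (group sizes 37 / 32 / 25).
ACC_COUNTS <- c(MEN1 = 20, ZNRF3 = 20, ARMC5 = 19, TP53 = 19, CTNNB1 = 13,
                APC = 12, RB1 = 11, PRKAR1A = 9, RPL22 = 9)
ACA_COUNTS <- c(MEN1 = 14, ZNRF3 = 2, ARMC5 = 2, TP53 = 2, CTNNB1 = 7,
                APC = 1, RB1 = 0, PRKAR1A = 0, RPL22 = 2)
NORMAL_COUNTS <- c(MEN1 = 10, ZNRF3 = 1, ARMC5 = 1, TP53 = 2, CTNNB1 = 0,
                   APC = 2, RB1 = 0, PRKAR1A = 0, RPL22 = 0)

# Quick variant-row builder with sensible defaults.
makeVariants <- function(sample_id, gene, pos = seq_along(sample_id),
                         chrom = "chr1", ref = "A", alt = "G",
                         effect = "nonsynonymous SNV", pop_af = NA_real_) {
  n <- length(sample_id)
  data.frame(sample_id = sample_id, gene = gene,
             chrom = rep_len(chrom, n), pos = as.integer(pos),
             ref = rep_len(ref, n), alt = rep_len(alt, n),
             effect = rep_len(effect, n), pop_af = rep_len(pop_af, n),
             stringsAsFactors = FALSE)
}

makeMetadata <- function(ids, group) {
  data.frame(sample_id = ids, group = group, stringsAsFactors = FALSE)
}

# Build a MutationMatrix whose per-gene per-group mutated-sample counts are
# exactly the supplied tallies: gene g is mutated in the first counts[g]
# samples of each group (one nonsynonymous variant per mutated cell).
matrixFromCounts <- function(countsByGroup, nByGroup) {
  stopifnot(identical(names(countsByGroup), names(nByGroup)))
  prefix <- c(ACC = "C", ACA = "A", NORMAL = "N")
  vlist <- list()
  mlist <- list()
  for (grp in names(countsByGroup)) {
    ids <- paste0(prefix[[grp]], seq_len(nByGroup[[grp]]))
    mlist[[grp]] <- makeMetadata(ids, grp)
    counts <- countsByGroup[[grp]]
    for (g in names(counts)) {
      k <- counts[[g]]
      if (k > 0)
        vlist[[paste(grp, g)]] <- makeVariants(
          ids[seq_len(k)], g, pos = 1000 * match(g, panelGenes()) +
            seq_len(k), pop_af = 0)
    }
  }
  variants <- do.call(rbind, vlist)
  rownames(variants) <- NULL
  buildMatrix(variants, do.call(rbind, mlist))
}

# Independent brute-force oracle for the two-sided exact test: enumerate all
# 2x2 tables with the observed margins via binomial coefficients and sum the
# probabilities no greater than the observed table's (same 1e-7 relative tie
# tolerance as the implementation under test).
fisherOracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  pObs <- probs[xs == a]
  min(sum(probs[probs <= pObs * (1 + 1e-7)]), 1)
}

# Scores reproducing the published SHGM>0 / SHGM>1 cohort tallies:
# ACC 27/37 above 0 of which 23 above 1; ACA 6/32 above 0, 1 above 1.
publishedCohortScores <- function() {
  list(scores = c(rep(2, 23), rep(1, 4), rep(0, 10),
                  rep(2, 1), rep(1, 5), rep(0, 26)),
       labels = rep(c("ACC", "ACA"), c(37, 32)))
}
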