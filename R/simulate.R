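## Cohort simulation under the quiet/active mixture model.

.randomBase <- function(n, exclude = NULL) {
  bases <- c("A", "C", "G", "T")
  if (is.null(exclude)) return(sample(bases, n, replace = TRUE))
  ## uniform over the three bases other than exclude[i]
  bases[((match(exclude, bases) - 1L + sample.int(3L, n, replace = TRUE))
         %% 4L) + 1L]
}

## ref/alt allele strings per mutation type; decoupled from biology beyond
## the indel/SNV distinction (deletions carry a multi-base ref).
.allelesForType <- function(types) {
  n <- length(types)
  ref <- .randomBase(n)
  alt <- .randomBase(n, exclude = ref)
  del <- types %in% c("FRAMESHIFT_DELETION", "NONFRAMESHIFT_DELETION")
  ins <- types %in% c("FRAMESHIFT_INSERTION", "NONFRAMESHIFT_INSERTION")
  if (any(del)) {
    ext <- vapply(which(del), function(i)
      paste(.randomBase(sample(1:3, 1L)), collapse = ""), character(1))
    alt[del] <- ref[del]
    ref[del] <- paste0(ref[del], ext)
  }
  if (any(ins)) {
    ext <- vapply(which(ins), function(i)
      paste(.randomBase(sample(1:3, 1L)), collapse = ""), character(1))
    alt[ins] <- paste0(ref[ins], ext)
  }
  list(ref = ref, alt = alt)
}

## Types for a vector of calls: draw from the group simplex, then redraw the
## rows of genes with an override from their own simplex.
.sampleTypes <- function(genes, group, model) {
  w <- model@typeWeights[[group]]
  types <- sample(names(w), length(genes), replace = TRUE, prob = w)
  for (g in names(model@geneTypeOverrides[[group]])) {
    idx <- which(genes == g)
    if (length(idx)) {
      wg <- model@geneTypeOverrides[[group]][[g]]
      types[idx] <- sample(names(wg), length(idx), replace = TRUE, prob = wg)
    }
  }
  types
}

.emptyVariantTable <- function() {
  data.frame(sample_id = character(0), gene = character(0),
             chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), effect = character(0),
             pop_af = numeric(0), stringsAsFactors = FALSE)
}

.simulateCovariates <- function(ids, group, model) {
  cv <- model@covariates
  n <- length(ids)
  age <- round(rnorm(n, cv$ageMean, cv$ageSD), 1)
  diameter <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      d <- rnorm(1, cv$diameterMean, cv$diameterSD)
      if (d > 0) break
    }
    diameter[i] <- round(d, 1)
  }
  sex <- ifelse(rbinom(n, 1, cv$pMale) == 1, "M", "F")
  stage <- ifelse(rbinom(n, 1, cv$pStageEarly) == 1, "I-II", "III-IV")
  functional <- ifelse(rbinom(n, 1, cv$pFunctional) == 1, "yes", "no")
  ki67 <- round(cv$ki67Range[1] +
                  diff(cv$ki67Range) * rbeta(n, 2, 1))
  data.frame(sample_id = ids, group = rep(group, n), age = age, sex = sex,
             diameter_cm = diameter, stage = stage, functional = functional,
             ki67 = ki67, stringsAsFactors = FALSE)
}

.simulateGroup <- function(group, model) {
  n <- model@nPerGroup[[group]]
  prefix <- c(ACC = "C", ACA = "A", NORMAL = "N")[[group]]
  ids <- paste0(prefix, seq_len(n))
  if (n == 0)
    return(list(variants = .emptyVariantTable(),
                metadata = .simulateCovariates(character(0), group, model)))

  pi <- model@quietWeight[[group]]
  active <- rbinom(n, 1, 1 - pi) == 1
  pStar <- model@rates[, group] / (1 - pi)
  if (any(pStar > 1)) {
    warning("active-sample rate capped at 1 for gene(s): ",
            paste(.PANEL_GENES[pStar > 1], collapse = ", "),
            " in group ", group, call. = FALSE)
    pStar <- pmin(pStar, 1)
  }
  ind <- matrix(0L, nrow = length(.PANEL_GENES), ncol = n,
                dimnames = list(.PANEL_GENES, ids))
  nAct <- sum(active)
  if (nAct > 0)
    ind[, active] <- matrix(
      rbinom(length(.PANEL_GENES) * nAct, 1, rep(pStar, nAct)),
      nrow = length(.PANEL_GENES))

  lambda <- model@siteLambda[[group]]
  hits <- which(ind == 1L, arr.ind = TRUE)
  nHits <- nrow(hits)
  if (nHits > 0) {
    hitGene <- .PANEL_GENES[hits[, "row"]]
    hitSid <- ids[hits[, "col"]]
    locIdx <- match(hitGene, .GENE_LOCI$gene)
    nSites <- 1L + rpois(nHits, lambda)
    ## positions sampled without replacement within each gene's dummy
    ## range, so sites of one (sample, gene) are distinct by construction
    posList <- lapply(seq_len(nHits), function(h)
      .GENE_LOCI$start[locIdx[h]] +
        sample.int(.GENE_LOCI$width[locIdx[h]], nSites[h]))
    idx <- rep.int(seq_len(nHits), nSites)
    types <- .sampleTypes(hitGene[idx], group, model)
    al <- .allelesForType(types)
    variants <- data.frame(
      sample_id = hitSid[idx], gene = hitGene[idx],
      chrom = .GENE_LOCI$chrom[locIdx][idx],
      pos = as.integer(unlist(posList)),
      ref = al$ref, alt = al$alt,
      effect = types, pop_af = 0, stringsAsFactors = FALSE)
  } else {
    variants <- .emptyVariantTable()
  }

  ## decoy calls that the significance filter must remove: synonymous
  ## variants and common (high population AF) variants of significant types
  f <- model@decoyFraction
  if (f > 0 && n > 0) {
    nDecoy <- round(f / (1 - f) * nrow(variants))
    if (nrow(variants) == 0) nDecoy <- round(f * n)  # still exercise filter
    if (nDecoy > 0) {
      dGene <- sample(.PANEL_GENES, nDecoy, replace = TRUE)
      dSid <- sample(ids, nDecoy, replace = TRUE)
      loc <- .GENE_LOCI[match(dGene, .GENE_LOCI$gene), ]
      dPos <- loc$start + vapply(loc$width, function(w) sample.int(w, 1L),
                                 integer(1))
      synonymous <- rbinom(nDecoy, 1, 0.5) == 1
      dType <- ifelse(synonymous, "SYNONYMOUS_SNV",
                      sample(names(model@typeWeights[[group]]), nDecoy,
                             replace = TRUE,
                             prob = model@typeWeights[[group]]))
      dAf <- ifelse(synonymous, 0, round(runif(nDecoy, 0.05, 0.5), 4))
      al <- .allelesForType(dType)
      decoys <- data.frame(
        sample_id = dSid, gene = dGene, chrom = loc$chrom,
        pos = as.integer(dPos), ref = al$ref, alt = al$alt,
        effect = dType, pop_af = dAf, stringsAsFactors = FALSE)
      ## re-draw loci colliding with an existing call of the same
      ## sample+gene (site identity must stay distinct)
      existing <- .variantKey(variants)
      for (i in seq_len(nDecoy)) {
        while (.variantKey(decoys[i, ]) %in% existing) {
          w <- .GENE_LOCI$width[match(decoys$gene[i], .GENE_LOCI$gene)]
          s <- .GENE_LOCI$start[match(decoys$gene[i], .GENE_LOCI$gene)]
          decoys$pos[i] <- s + sample.int(w, 1L)
        }
        existing <- c(existing, .variantKey(decoys[i, ]))
      }
      variants <- rbind(variants, decoys)
    }
  }
  variants <- variants[order(variants$sample_id, variants$gene,
                             variants$pos), , drop = FALSE]
  rownames(variants) <- NULL
  list(variants = variants,
       metadata = .simulateCovariates(ids, group, model))
}

#' Simulate an annotated-variant cohort
#'
#' Draws a synthetic cohort from a \code{\link{cohortModel}}: per sample,
#' with probability \code{quietWeight} the sample is quiet (zero
#' significant mutations); otherwise each gene mutates independently with
#' probability \code{rate / (1 - quietWeight)} (capped at 1 with a
#' warning), so the per-gene marginal rates match the configured values
#' while quiet samples induce positive within-sample correlation.  Each
#' mutated gene receives \code{1 + Poisson(siteLambda)} distinct sites with
#' types drawn from the configured simplex; significant calls carry
#' population AF 0 and a configurable fraction of decoy calls (synonymous,
#' or common high-AF) is injected to exercise the filter.  Clinical
#' covariates are drawn independently.  Fully reproducible from the seed.
#'
#' @param model a \code{\link{cohortModel}}.
#' @param seed integer seed; overrides the seed stored in the model.
#'   \code{NA} leaves the RNG state alone.
#' @return List with elements \code{variants} (annotated variant
#'   data.frame) and \code{metadata} (sample metadata data.frame).
#' @examples
#' sim <- simulateCohort(cohortModel(), seed = 1)
#' table(sim$metadata$group)
#' @export
simulateCohort <- function(model = cohortModel(), seed = model@seed) {
  stopifnot(is(model, "CohortModel"))
  run <- function() {
    parts <- lapply(.GROUP_LEVELS, .simulateGroup, model = model)
    variants <- do.call(rbind, lapply(parts, `[[`, "variants"))
    metadata <- do.call(rbind, lapply(parts, `[[`, "metadata"))
    rownames(variants) <- NULL
    rownames(metadata) <- NULL
    list(variants = variants, metadata = metadata)
  }
  if (!is.na(seed)) withr::with_seed(as.integer(seed), run()) else run()
}

#' Closed-form positivity probability under the mixture model
#'
#' Probability that a sample's SHGM exceeds 0 under the quiet/active
#' mixture: \deqn{P(SHGM > 0) = (1 - \pi)(1 - \prod_g (1 - p^*_g))} where
#' \eqn{\pi} is the quiet weight and \eqn{p^*_g = p_g / (1 - \pi)} (capped
#' at 1) are the active-sample gene probabilities, the product running over
#' the high-risk genes.  With \eqn{\pi = 0} this reduces to the
#' independence prediction \eqn{1 - \prod_g (1 - p_g)}.
#'
#' @param model a \code{\link{cohortModel}}.
#' @param group group label.
#' @param genes high-risk genes (character vector or
#'   \code{\link{HighRiskSet}}).
#' @return Probability in \[0, 1\].
#' @examples
#' independencePositivity(cohortModel(), "ACC",
#'                        c("ZNRF3", "TP53", "ARMC5", "APC", "RB1",
#'                          "PRKAR1A"))
#' @export
independencePositivity <- function(model, group, genes) {
  stopifnot(is(model, "CohortModel"), group %in% .GROUP_LEVELS)
  if (is(genes, "HighRiskSet")) genes <- highRiskGenes(genes)
  bad <- setdiff(genes, .PANEL_GENES)
  if (length(bad))
    stop("genes outside the panel: ", paste(bad, collapse = ", "),
         call. = FALSE)
  pi <- model@quietWeight[[group]]
  pStar <- pmin(model@rates[genes, group] / (1 - pi), 1)
  (1 - pi) * (1 - prod(1 - pStar))
}
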