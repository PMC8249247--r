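## Generative model of a synthetic panel-sequencing cohort.

## Per-group per-gene marginal mutation probabilities, taken from the
## study's printed group sizes and per-gene mutated-sample counts
## (ACC n=37, ACA n=32, NORMAL n=25).
.DEFAULT_RATES <- local({
  acc <- c(TP53 = 19, CTNNB1 = 13, ARMC5 = 19, PRKAR1A = 9, ZNRF3 = 20,
           RB1 = 11, APC = 12, MEN1 = 20, RPL22 = 9) / 37
  aca <- c(TP53 = 2, CTNNB1 = 7, ARMC5 = 2, PRKAR1A = 0, ZNRF3 = 2,
           RB1 = 0, APC = 1, MEN1 = 14, RPL22 = 2) / 32
  nor <- c(TP53 = 2, CTNNB1 = 0, ARMC5 = 1, PRKAR1A = 0, ZNRF3 = 1,
           RB1 = 0, APC = 2, MEN1 = 10, RPL22 = 0) / 25
  cbind(ACC = acc[.PANEL_GENES], ACA = aca[.PANEL_GENES],
        NORMAL = nor[.PANEL_GENES])
})

## Per-group mutation-type simplex over significant classes, from the
## printed per-type site totals (ACC 169/19/1/19/19 of 227, ACA 21/10/4 of
## 35, NORMAL 13/3/2 of 18).
.DEFAULT_TYPE_WEIGHTS <- list(
  ACC = c(NONSYNONYMOUS_SNV = 169, STOPGAIN = 19, STOPLOSS = 1,
          FRAMESHIFT_DELETION = 19, SPLICING = 19) / 227,
  ACA = c(NONSYNONYMOUS_SNV = 21, FRAMESHIFT_DELETION = 10,
          SPLICING = 4) / 35,
  NORMAL = c(NONSYNONYMOUS_SNV = 13, FRAMESHIFT_DELETION = 3,
             SPLICING = 2) / 18
)

## In the ACC group the dominant RPL22 lesion is a frameshift deletion
## (6 of its 9 mutated samples); all other genes are nonsynonymous-dominated.
.DEFAULT_GENE_TYPE_OVERRIDES <- list(
  ACC = list(RPL22 = c(NONSYNONYMOUS_SNV = 3, FRAMESHIFT_DELETION = 6) / 9)
)

## Dummy per-gene coordinate ranges for synthesizing distinct loci; the
## chromosome assignments follow the genes' real locations, the offsets are
## arbitrary.
.GENE_LOCI <- data.frame(
  gene = .PANEL_GENES,
  chrom = c("chr17", "chr3", "chr16", "chr17", "chr22",
            "chr13", "chr5", "chr11", "chr1"),
  start = c(7571000L, 41265000L, 31470000L, 66508000L, 29320000L,
            48877000L, 112043000L, 64570000L, 6257000L),
  width = 5000L,
  stringsAsFactors = FALSE
)

#' Generative specification of a synthetic cohort
#'
#' Captures everything needed to simulate an annotated variant table and
#' sample metadata with the statistical structure the analysis assumes:
#' per-group sample sizes, per-group per-gene marginal mutation
#' probabilities, a quiet/active mixture (a quiet sample carries zero
#' significant mutations, inducing within-sample correlation between
#' genes), a per-mutated-gene site-count distribution (1 + Poisson), a
#' mutation-type simplex with optional per-gene overrides, clinical
#' covariate distributions, and a decoy fraction of non-significant calls
#' (common polymorphisms and synonymous variants) to exercise the filter.
#'
#' Defaults reproduce the study's printed cohort: group sizes 37/32/25;
#' marginal rates from the per-gene mutated-sample counts (e.g. ZNRF3
#' 20/37 in ACC, 2/32 in ACA); quiet weight 6/37 in ACC (the six ACC
#' samples with no significant mutation) and 0 elsewhere; site-count means
#' matched to the printed sites-per-mutated-gene ratios (227/132 in ACC);
#' type weights from the printed per-type site totals, with the RPL22
#' frameshift-deletion override; age ~ N(44.3, 12.9), diameter ~
#' N(8.5, 3.5) truncated positive, 12/37 male, 19/37 stage I-II, 20/37
#' functional, Ki-67 on \[10, 25\] with median near 20.
#'
#' @slot nPerGroup named integer vector (ACC, ACA, NORMAL).
#' @slot rates 9 x 3 matrix of marginal mutation probabilities.
#' @slot quietWeight named numeric; per-group probability of a quiet sample.
#' @slot siteLambda named numeric; Poisson mean of (sites - 1) per mutated
#'   gene.
#' @slot typeWeights per-group named probability vectors over significant
#'   types.
#' @slot geneTypeOverrides per-group list of per-gene type-weight overrides.
#' @slot covariates named list of clinical-covariate parameters.
#' @slot decoyFraction fraction of emitted rows that are non-significant
#'   decoys.
#' @slot seed integer seed (NA = leave the RNG alone).
#' @seealso \code{\link{cohortModel}}, \code{\link{simulateCohort}}
#' @export
setClass("CohortModel",
  representation(nPerGroup = "integer", rates = "matrix",
                 quietWeight = "numeric", siteLambda = "numeric",
                 typeWeights = "list", geneTypeOverrides = "list",
                 covariates = "list", decoyFraction = "numeric",
                 seed = "integer"))

setValidity("CohortModel", function(object) {
  msg <- NULL
  if (!identical(sort(names(object@nPerGroup)), sort(.GROUP_LEVELS)))
    msg <- c(msg, "nPerGroup must be named ACC, ACA, NORMAL")
  if (any(object@nPerGroup < 0))
    msg <- c(msg, "group sizes must be >= 0")
  if (!identical(rownames(object@rates), .PANEL_GENES) ||
      !identical(colnames(object@rates), .GROUP_LEVELS))
    msg <- c(msg, "rates must be a 9-gene x 3-group matrix")
  if (any(object@rates < 0 | object@rates > 1))
    msg <- c(msg, "rates must be probabilities in [0, 1]")
  if (any(object@quietWeight < 0 | object@quietWeight >= 1))
    msg <- c(msg, "quietWeight must be in [0, 1)")
  if (any(object@siteLambda < 0))
    msg <- c(msg, "siteLambda must be >= 0")
  for (g in names(object@typeWeights)) {
    w <- object@typeWeights[[g]]
    if (abs(sum(w) - 1) > 1e-9 || any(w < 0))
      msg <- c(msg, paste0("typeWeights[", g, "] must be a simplex"))
    if (length(setdiff(names(w), .MUTATION_TYPES)))
      msg <- c(msg, paste0("typeWeights[", g, "] has unknown types"))
  }
  if (object@decoyFraction < 0 || object@decoyFraction >= 1)
    msg <- c(msg, "decoyFraction must be in [0, 1)")
  if (is.null(msg)) TRUE else msg
})

#' Create a cohort model
#'
#' All arguments default to the study-calibrated values described in
#' \linkS4class{CohortModel}; override any subset to explore other designs
#' (e.g. \code{nPerGroup = c(ACC = 370, ACA = 320, NORMAL = 0)} for a
#' power analysis at tenfold size).
#'
#' @param nPerGroup named vector of group sizes.
#' @param rates 9 x 3 matrix of marginal mutation probabilities
#'   (genes x ACC/ACA/NORMAL).
#' @param quietWeight named per-group probability that a sample carries no
#'   significant mutation at all.
#' @param siteLambda named per-group Poisson mean of (site count - 1) per
#'   mutated gene.
#' @param typeWeights per-group named probability vector over mutation
#'   types.
#' @param geneTypeOverrides per-group list of per-gene type-weight
#'   overrides.
#' @param covariates clinical covariate parameters (see Details in
#'   \linkS4class{CohortModel}).
#' @param decoyFraction fraction of output rows that are filtered-out
#'   decoys (default 0.3).
#' @param seed integer seed stored with the model (NA to leave unset).
#' @return A \code{CohortModel}.
#' @examples
#' cohortModel()
#' cohortModel(nPerGroup = c(ACC = 100, ACA = 100, NORMAL = 0))
#' @export
cohortModel <- function(nPerGroup = c(ACC = 37L, ACA = 32L, NORMAL = 25L),
                        rates = .DEFAULT_RATES,
                        quietWeight = c(ACC = 6 / 37, ACA = 0, NORMAL = 0),
                        siteLambda = c(ACC = 227 / 132 - 1,
                                       ACA = 35 / 30 - 1,
                                       NORMAL = 18 / 16 - 1),
                        typeWeights = .DEFAULT_TYPE_WEIGHTS,
                        geneTypeOverrides = .DEFAULT_GENE_TYPE_OVERRIDES,
                        covariates = list(ageMean = 44.3, ageSD = 12.9,
                                          diameterMean = 8.5,
                                          diameterSD = 3.5,
                                          pMale = 12 / 37,
                                          pStageEarly = 19 / 37,
                                          pFunctional = 20 / 37,
                                          ki67Range = c(10, 25)),
                        decoyFraction = 0.3,
                        seed = NA_integer_) {
  storage.mode(nPerGroup) <- "integer"
  new("CohortModel",
      nPerGroup = nPerGroup[.GROUP_LEVELS],
      rates = rates,
      quietWeight = quietWeight[.GROUP_LEVELS],
      siteLambda = siteLambda[.GROUP_LEVELS],
      typeWeights = typeWeights,
      geneTypeOverrides = geneTypeOverrides,
      covariates = covariates,
      decoyFraction = decoyFraction,
      seed = as.integer(seed))
}

setMethod("show", "CohortModel", function(object) {
  cat("CohortModel\n")
  cat("  group sizes:",
      paste(names(object@nPerGroup), object@nPerGroup, sep = "=",
            collapse = " "), "\n")
  cat("  quiet weights:",
      paste(names(object@quietWeight), signif(object@quietWeight, 3),
            sep = "=", collapse = " "), "\n")
  cat("  decoy fraction:", object@decoyFraction,
      " seed:", object@seed, "\n")
  cat("  marginal rates (per gene x group):\n")
  print(round(object@rates, 3))
})
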