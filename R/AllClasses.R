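#' Variant significance filter configuration
#'
#' Holds the two knobs of the biological-significance filter: the set of
#' effect classes considered significant, and the population allele-frequency
#' cutoff above which a variant is regarded as a common polymorphism and
#' discarded.  The AF cutoff stands in for comparison against healthy
#' population databases; variants with no recorded population AF are treated
#' as novel and retained.
#'
#' @slot afThreshold numeric in \[0, 1\]; variants with
#'   \code{pop_af >= afThreshold} are filtered out.
#' @slot significantTypes character; nonempty subset of
#'   \code{\link{mutationTypes}}.
#' @export
setClass("FilterConfig",
  representation(afThreshold = "numeric", significantTypes = "character"))

setValidity("FilterConfig", function(object) {
  msg <- NULL
  if (length(object@afThreshold) != 1L || is.na(object@afThreshold) ||
      object@afThreshold < 0 || object@afThreshold > 1)
    msg <- c(msg, "afThreshold must be a single value in [0, 1]")
  if (length(object@significantTypes) == 0L)
    msg <- c(msg, "significantTypes must be nonempty")
  bad <- setdiff(object@significantTypes, .MUTATION_TYPES)
  if (length(bad))
    msg <- c(msg, paste0("unknown mutation types: ",
                         paste(bad, collapse = ", ")))
  if (is.null(msg)) TRUE else msg
})

#' Create a filter configuration
#'
#' @param afThreshold population allele-frequency cutoff (default 0.01);
#'   a variant is kept only if its population AF is missing or strictly
#'   below this value.
#' @param significantTypes effect classes counted as significant; defaults
#'   to nonsynonymous SNVs, stopgain, stoploss, frameshift
#'   insertions/deletions and splicing variants.
#' @return A \code{FilterConfig} object.
#' @examples
#' filterConfig()
#' filterConfig(afThreshold = 0.001)
#' @export
filterConfig <- function(afThreshold = 0.01,
                         significantTypes = .SIGNIFICANT_TYPES) {
  new("FilterConfig", afThreshold = afThreshold,
      significantTypes = significantTypes)
}

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig\n")
  cat("  afThreshold:", object@afThreshold, "\n")
  cat("  significantTypes:", paste(object@significantTypes, collapse = ", "),
      "\n")
})

#' Gene-by-sample mutation matrix
#'
#' A \linkS4class{SummarizedExperiment} with the nine panel genes as rows and
#' samples as columns, carrying two assays: \code{indicator} (0/1, gene
#' mutated in sample) and \code{siteCount} (number of distinct mutated sites
#' of that gene in that sample, where a site is a distinct
#' (chrom, pos, ref, alt)).  \code{colData} holds the sample metadata,
#' including the mandatory \code{group} column with levels ACC, ACA, NORMAL.
#'
#' @seealso \code{\link{buildMatrix}}, \code{\link{mutationIndicator}},
#'   \code{\link{siteCounts}}, \code{\link{sampleGroups}}
#' @export
setClass("MutationMatrix", contains = "SummarizedExperiment")

setValidity("MutationMatrix", function(object) {
  msg <- NULL
  if (!all(c("indicator", "siteCount") %in% assayNames(object)))
    msg <- c(msg, "assays 'indicator' and 'siteCount' are required")
  else {
    ind <- assay(object, "indicator")
    sc <- assay(object, "siteCount")
    if (!identical(dim(ind), dim(sc)))
      msg <- c(msg, "indicator and siteCount must have identical dimensions")
    else {
      if (any(sc < 0) || any(sc != round(sc)))
        msg <- c(msg, "siteCount must contain non-negative integers")
      if (!all(ind == (sc > 0)))
        msg <- c(msg, "indicator must equal (siteCount > 0)")
    }
  }
  if (!identical(rownames(object), .PANEL_GENES))
    msg <- c(msg, "rows must be the nine panel genes in canonical order")
  if (!("group" %in% colnames(colData(object))))
    msg <- c(msg, "colData must contain a 'group' column")
  else {
    grp <- as.character(colData(object)$group)
    bad <- setdiff(unique(grp), .GROUP_LEVELS)
    if (length(bad))
      msg <- c(msg, paste0("unknown group labels: ",
                           paste(bad, collapse = ", ")))
  }
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "MutationMatrix", function(object) {
  callNextMethod()
  grp <- sampleGroups(object)
  tab <- table(factor(grp, levels = .GROUP_LEVELS))
  cat("group sizes:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  cat("total mutated gene-sample pairs:",
      sum(assay(object, "indicator")), "\n")
})

#' High-risk gene set
#'
#' The ordered set of panel genes whose mutation rate is significantly higher
#' in the ACC group than in the comparison group, together with the
#' significance level used and (optionally) the per-gene test results backing
#' each inclusion.  SHGM is the per-sample count of mutated genes from this
#' set.
#'
#' @slot genes character; ordered subset of the panel genes.
#' @slot alpha numeric; significance level used for selection (NA when the
#'   set was pinned manually).
#' @slot provenance DataFrame of per-gene test results backing the selection
#'   (zero rows when pinned).
#' @seealso \code{\link{selectHighRisk}}, \code{\link{highRiskSet}}
#' @export
setClass("HighRiskSet",
  representation(genes = "character", alpha = "numeric",
                 provenance = "DataFrame"))

setValidity("HighRiskSet", function(object) {
  msg <- NULL
  bad <- setdiff(object@genes, .PANEL_GENES)
  if (length(bad))
    msg <- c(msg, paste0("genes outside the panel: ",
                         paste(bad, collapse = ", ")))
  if (anyDuplicated(object@genes))
    msg <- c(msg, "duplicate genes in the set")
  if (nrow(object@provenance) > 0 && !is.na(object@alpha)) {
    prov <- object@provenance[object@provenance$gene %in% object@genes, ,
                              drop = FALSE]
    if (!all(prov$p_value <= object@alpha))
      msg <- c(msg, "a selected gene has p > alpha in its provenance")
    if (!all(prov$direction == "group1_higher"))
      msg <- c(msg, "a selected gene is not group1_higher in its provenance")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a high-risk gene set directly
#'
#' Pin a gene set by hand (e.g. the canonical six-gene set
#' ZNRF3, TP53, ARMC5, APC, RB1, PRKAR1A) for scoring new cohorts without
#' re-running selection.
#'
#' @param genes character vector of panel gene symbols.
#' @param alpha significance level recorded with the set (NA when pinned).
#' @param provenance optional DataFrame of backing test results.
#' @return A \code{HighRiskSet}.
#' @examples
#' highRiskSet(c("ZNRF3", "TP53", "ARMC5", "APC", "RB1", "PRKAR1A"))
#' @export
highRiskSet <- function(genes, alpha = NA_real_,
                        provenance = S4Vectors::DataFrame()) {
  new("HighRiskSet", genes = as.character(genes), alpha = alpha,
      provenance = provenance)
}

setMethod("show", "HighRiskSet", function(object) {
  cat("HighRiskSet of", length(object@genes), "genes (alpha =",
      object@alpha, ")\n")
  cat(" ", paste(object@genes, collapse = ", "), "\n")
  if (nrow(object@provenance))
    cat("  backed by", nrow(object@provenance), "gene rate tests\n")
})

#' @rdname highRiskSet
#' @param x a \code{HighRiskSet}.
#' @export
highRiskGenes <- function(x) {
  stopifnot(is(x, "HighRiskSet"))
  x@genes
}
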