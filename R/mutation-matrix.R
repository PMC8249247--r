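## Gene-by-sample mutation matrix and group-level burden summaries.

#' Build the gene-by-sample mutation matrix
#'
#' Collapses significance-filtered variant calls into a
#' \linkS4class{MutationMatrix}: for every panel gene and sample,
#' \code{siteCount} is the number of distinct mutated sites (distinct
#' (chrom, pos, ref, alt)) and \code{indicator} is 1 when the gene carries at
#' least one.  All nine panel genes are present as rows even when unmutated
#' cohort-wide, and samples with no variants appear as all-zero columns, so
#' per-sample scores are defined for every sample in the metadata.
#'
#' @param variants a variant table, already passed through
#'   \code{\link{filterSignificant}} (unfiltered calls are counted as-is).
#' @param metadata a sample metadata data.frame with columns
#'   \code{sample_id} and \code{group} (ACC/ACA/NORMAL), plus any clinical
#'   covariates; every variant's sample must appear here.
#' @return A \code{\link{MutationMatrix}}.
#' @examples
#' fx <- table5Fixture()
#' m <- buildMatrix(filterSignificant(fx$variants), fx$metadata)
#' mutationIndicator(m)["ZNRF3", ]
#' @export
buildMatrix <- function(variants, metadata) {
  .checkVariantTable(variants)
  if (!all(c("sample_id", "group") %in% names(metadata)))
    stop("metadata must contain columns sample_id and group", call. = FALSE)
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata", call. = FALSE)
  samples <- as.character(metadata$sample_id)
  unknown <- setdiff(unique(variants$sample_id), samples)
  if (length(unknown))
    stop("variant sample(s) missing from metadata: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  offPanel <- setdiff(unique(variants$gene), .PANEL_GENES)
  if (length(offPanel))
    stop("variant gene(s) outside the panel: ",
         paste(offPanel, collapse = ", "), call. = FALSE)

  v <- variants[!duplicated(.variantKey(variants)), , drop = FALSE]
  sc <- matrix(0L, nrow = length(.PANEL_GENES), ncol = length(samples),
               dimnames = list(.PANEL_GENES, samples))
  if (nrow(v)) {
    counts <- table(factor(v$gene, levels = .PANEL_GENES),
                    factor(v$sample_id, levels = samples))
    sc[] <- as.integer(counts)
  }
  ind <- matrix(as.integer(sc > 0L), nrow = nrow(sc), dimnames = dimnames(sc))
  cd <- S4Vectors::DataFrame(metadata, row.names = samples)
  cd$group <- factor(as.character(metadata$group), levels = .GROUP_LEVELS)
  se <- SummarizedExperiment(
    assays = list(indicator = ind, siteCount = sc), colData = cd)
  new("MutationMatrix", se)
}

#' Accessors for a MutationMatrix
#'
#' @param x a \code{\link{MutationMatrix}}.
#' @return \code{mutationIndicator}: integer 0/1 matrix (genes x samples);
#'   \code{siteCounts}: integer matrix of distinct-site counts;
#'   \code{sampleGroups}: factor of group labels named by sample.
#' @export
mutationIndicator <- function(x) {
  stopifnot(is(x, "MutationMatrix"))
  assay(x, "indicator")
}

#' @rdname mutationIndicator
#' @export
siteCounts <- function(x) {
  stopifnot(is(x, "MutationMatrix"))
  assay(x, "siteCount")
}

#' @rdname mutationIndicator
#' @export
sampleGroups <- function(x) {
  stopifnot(is(x, "MutationMatrix"))
  setNames(colData(x)$group, colnames(x))
}

#' Summarize mutation burden within one group
#'
#' Computes the group-level burden summary: per-gene counts of mutated
#' samples, the total number of mutated gene-sample pairs ("gene
#' mutations"), the total number of distinct mutated sites, the per-type
#' site breakdown, and the per-sample distributions of mutated-gene and
#' site counts (median, range and IQR).
#'
#' @param m a \code{\link{MutationMatrix}}.
#' @param variants the (filtered) variant table the matrix was built from;
#'   used for the mutation-type site breakdown.  May be \code{NULL}, in
#'   which case \code{perTypeSites} is omitted.
#' @param group one of \code{"ACC"}, \code{"ACA"}, \code{"NORMAL"}.
#' @return A list of class \code{"GroupSummary"} with elements
#'   \code{group}, \code{n}, \code{perGeneMutated}, \code{totalGeneMutations},
#'   \code{totalSites}, \code{perTypeSites}, \code{perSampleGeneCounts},
#'   \code{perSampleSiteCounts}, \code{medianGenes}, \code{medianSites},
#'   \code{rangeGenes}, \code{rangeSites}, \code{iqrGenes}, \code{iqrSites}.
#' @examples
#' fx <- table5Fixture()
#' m <- buildMatrix(fx$variants, fx$metadata)
#' summarizeGroup(m, fx$variants, "ACC")
#' @export
summarizeGroup <- function(m, variants = NULL, group) {
  stopifnot(is(m, "MutationMatrix"))
  if (!(group %in% .GROUP_LEVELS))
    stop("unknown group label: ", group, call. = FALSE)
  grp <- as.character(sampleGroups(m))
  keep <- which(grp == group)
  if (!length(keep))
    stop("no samples with group ", group, " in the matrix", call. = FALSE)
  ind <- mutationIndicator(m)[, keep, drop = FALSE]
  sc <- siteCounts(m)[, keep, drop = FALSE]
  perGene <- rowSums(ind)
  geneCounts <- colSums(ind)
  siteCountsPerSample <- colSums(sc)

  perType <- NULL
  if (!is.null(variants)) {
    .checkVariantTable(variants)
    v <- variants[variants$sample_id %in% colnames(ind), , drop = FALSE]
    v <- v[!duplicated(.variantKey(v)), , drop = FALSE]
    perType <- table(factor(normalizeEffectLabel(v$effect),
                            levels = .MUTATION_TYPES))
    perType <- setNames(as.integer(perType), names(perType))
    if (sum(perType) != sum(sc))
      warning("per-type site total (", sum(perType),
              ") differs from matrix site total (", sum(sc),
              "); were the variants filtered identically?", call. = FALSE)
  }

  out <- list(
    group = group,
    n = length(keep),
    perGeneMutated = perGene,
    totalGeneMutations = sum(perGene),
    totalSites = sum(sc),
    perTypeSites = perType,
    perSampleGeneCounts = unname(geneCounts),
    perSampleSiteCounts = unname(siteCountsPerSample),
    medianGenes = median(geneCounts),
    medianSites = median(siteCountsPerSample),
    rangeGenes = range(geneCounts),
    rangeSites = range(siteCountsPerSample),
    iqrGenes = unname(quantile(geneCounts, c(0.25, 0.75))),
    iqrSites = unname(quantile(siteCountsPerSample, c(0.25, 0.75)))
  )
  class(out) <- "GroupSummary"
  out
}

#' @export
print.GroupSummary <- function(x, ...) {
  cat("GroupSummary:", x$group, "(n =", x$n, ")\n")
  cat("  gene mutations:", x$totalGeneMutations,
      " mutation sites:", x$totalSites, "\n")
  cat("  mutated genes/sample: median", x$medianGenes,
      sprintf("(range %g-%g, IQR %g-%g)\n",
              x$rangeGenes[1], x$rangeGenes[2],
              x$iqrGenes[1], x$iqrGenes[2]))
  cat("  mutated sites/sample: median", x$medianSites,
      sprintf("(range %g-%g, IQR %g-%g)\n",
              x$rangeSites[1], x$rangeSites[2],
              x$iqrSites[1], x$iqrSites[2]))
  invisible(x)
}

#' Mutation-type breakdown of a group summary
#'
#' @param summary a \code{GroupSummary} from \code{\link{summarizeGroup}}
#'   (built with \code{variants} supplied), or a named integer vector of
#'   per-type site counts.
#' @param dropEmpty drop types with zero sites (default TRUE).
#' @return data.frame with columns \code{type}, \code{count}, \code{share};
#'   shares sum to 1 (NA when the total is zero).
#' @examples
#' mutationTypeBreakdown(c(NONSYNONYMOUS_SNV = 169, STOPGAIN = 19,
#'                         STOPLOSS = 1, FRAMESHIFT_DELETION = 19,
#'                         SPLICING = 19))
#' @export
mutationTypeBreakdown <- function(summary, dropEmpty = TRUE) {
  counts <- if (inherits(summary, "GroupSummary")) {
    if (is.null(summary$perTypeSites))
      stop("summary has no per-type site counts; ",
           "call summarizeGroup() with the variant table", call. = FALSE)
    summary$perTypeSites
  } else summary
  stopifnot(!is.null(names(counts)))
  if (dropEmpty) counts <- counts[counts > 0]
  total <- sum(counts)
  share <- if (total > 0) unname(counts) / total else rep(NA_real_,
                                                          length(counts))
  out <- data.frame(type = names(counts), count = as.integer(counts),
                    share = share, stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a MutationMatrix to TSV
#'
#' \code{format = "wide"} writes genes as rows and samples as columns with
#' cells \code{indicator:site_count}; \code{format = "long"} writes one row
#' per (sample, gene) with columns \code{sample_id}, \code{gene},
#' \code{indicator}, \code{site_count}.
#'
#' @param m a \code{\link{MutationMatrix}}.
#' @param path output file.
#' @param format \code{"wide"} or \code{"long"}.
#' @return The path, invisibly.
#' @export
writeMutationMatrix <- function(m, path, format = c("wide", "long")) {
  stopifnot(is(m, "MutationMatrix"))
  format <- match.arg(format)
  ind <- mutationIndicator(m)
  sc <- siteCounts(m)
  if (format == "wide") {
    cells <- matrix(paste(ind, sc, sep = ":"), nrow = nrow(ind),
                    dimnames = dimnames(ind))
    df <- data.frame(gene = rownames(cells), cells, check.names = FALSE,
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(
      sample_id = rep(colnames(ind), each = nrow(ind)),
      gene = rep(rownames(ind), times = ncol(ind)),
      indicator = as.integer(ind),
      site_count = as.integer(sc),
      stringsAsFactors = FALSE)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
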