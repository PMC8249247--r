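## High-risk gene selection, per-sample SHGM scoring, threshold diagnostics.

#' Select high-risk genes from per-gene rate tests
#'
#' A panel gene is high-risk when its mutation rate in group 1 (ACC) is
#' significantly higher than in the comparison group: \code{p <= alpha}
#' (inclusive, so a gene at exactly 0.05 is selected) with direction
#' \code{group1_higher}.  Genes are ordered by ascending p-value, ties
#' broken alphabetically.
#'
#' @param tests per-gene results from \code{\link{testAllGenes}} (one row
#'   per panel gene; duplicate genes are an error).
#' @param alpha significance level (default 0.05).
#' @return A \code{\link{HighRiskSet}} whose provenance records the backing
#'   tests.
#' @examples
#' ## with the study's printed 2x2 counts this selects
#' ## ZNRF3, ARMC5, TP53, APC, RB1, PRKAR1A and leaves out RPL22 (p = 0.052)
#' @export
selectHighRisk <- function(tests, alpha = 0.05) {
  stopifnot(is.data.frame(tests) || is(tests, "DataFrame"))
  if (anyDuplicated(tests$gene))
    stop("duplicate gene in tests: ",
         paste(unique(tests$gene[duplicated(tests$gene)]), collapse = ", "),
         call. = FALSE)
  sel <- tests[tests$p_value <= alpha & tests$direction == "group1_higher", ,
               drop = FALSE]
  sel <- sel[order(sel$p_value, sel$gene), , drop = FALSE]
  new("HighRiskSet", genes = as.character(sel$gene), alpha = alpha,
      provenance = S4Vectors::DataFrame(tests))
}

#' Per-sample SHGM scores
#'
#' The SHGM (sum of high-risk gene mutation) of a sample is the number of
#' high-risk genes in which the sample carries at least one significant
#' mutation — an integer between 0 and the size of the high-risk set.
#'
#' \code{scoreCohort} scores every sample in the matrix;
#' \code{computeShgm} scores one sample and also reports the contributing
#' genes.
#'
#' @param m a \code{\link{MutationMatrix}}.
#' @param highRisk a \code{\link{HighRiskSet}} (or character vector of panel
#'   genes).
#' @return \code{scoreCohort}: a \code{DataFrame} with columns
#'   \code{sample_id}, \code{group}, \code{shgm};
#'   \code{computeShgm}: a list with \code{sample_id}, \code{score},
#'   \code{genes} (the mutated high-risk genes).
#' @examples
#' fx <- table5Fixture()
#' m <- buildMatrix(fx$variants, fx$metadata)
#' hr <- highRiskSet(c("ZNRF3", "TP53", "ARMC5", "APC", "RB1", "PRKAR1A"))
#' scoreCohort(m, hr)$shgm          # 2 3 6 0 0 5 1 1
#' computeShgm(m, hr, "C11")$score  # 6
#' @export
scoreCohort <- function(m, highRisk) {
  stopifnot(is(m, "MutationMatrix"))
  genes <- if (is(highRisk, "HighRiskSet")) highRiskGenes(highRisk)
           else as.character(highRisk)
  bad <- setdiff(genes, .PANEL_GENES)
  if (length(bad))
    stop("high-risk genes outside the panel: ",
         paste(bad, collapse = ", "), call. = FALSE)
  ind <- mutationIndicator(m)[genes, , drop = FALSE]
  S4Vectors::DataFrame(sample_id = colnames(m),
                       group = sampleGroups(m),
                       shgm = as.integer(colSums(ind)),
                       row.names = colnames(m))
}

#' @rdname scoreCohort
#' @param sampleId a sample identifier present in the matrix.
#' @export
computeShgm <- function(m, highRisk, sampleId) {
  stopifnot(is(m, "MutationMatrix"))
  if (!(sampleId %in% colnames(m)))
    stop("unknown sample: ", sampleId, call. = FALSE)
  genes <- if (is(highRisk, "HighRiskSet")) highRiskGenes(highRisk)
           else as.character(highRisk)
  ind <- mutationIndicator(m)[genes, sampleId]
  list(sample_id = sampleId, score = as.integer(sum(ind)),
       genes = genes[ind > 0])
}

.confusion <- function(scores, labels, t) {
  pos <- scores > t
  acc <- labels == "ACC"
  c(TP = sum(pos & acc), FP = sum(pos & !acc),
    FN = sum(!pos & acc), TN = sum(!pos & !acc))
}

.metricsFromConfusion <- function(cm) {
  ratio <- function(num, den)
    if (den == 0) NA_real_ else unname(100 * num / den)
  c(sensitivity = ratio(cm["TP"], cm["TP"] + cm["FN"]),
    specificity = ratio(cm["TN"], cm["TN"] + cm["FP"]),
    ppv = ratio(cm["TP"], cm["TP"] + cm["FP"]),
    npv = ratio(cm["TN"], cm["TN"] + cm["FN"]))
}

#' Diagnostic metrics of the rule SHGM > t
#'
#' Evaluates the classification rule "call ACC when SHGM > t" against the
#' true group labels (positive class ACC, comparison class ACA): the 2x2
#' confusion counts and sensitivity, specificity, PPV and NPV, each as a
#' percentage.  Metrics whose denominator is zero are reported as NA.
#'
#' @param scores numeric vector of per-sample SHGM scores (or the
#'   \code{DataFrame} from \code{\link{scoreCohort}}).
#' @param labels group labels aligned with \code{scores}; only ACC and ACA
#'   samples enter the evaluation (taken from \code{scores} when it is a
#'   \code{scoreCohort} result).
#' @param thresholds integer threshold(s) t; one result row per value.
#' @return data.frame with one row per threshold and columns
#'   \code{threshold}, \code{TP}, \code{FP}, \code{FN}, \code{TN},
#'   \code{sensitivity}, \code{specificity}, \code{ppv}, \code{npv},
#'   \code{positives}, \code{positivity_acc}, \code{positivity_aca}.
#' @examples
#' sc <- c(rep(2, 23), rep(1, 4), rep(0, 10),   # ACC-like scores
#'         rep(2, 1), rep(1, 5), rep(0, 26))    # ACA-like scores
#' lb <- rep(c("ACC", "ACA"), c(37, 32))
#' evaluateThreshold(sc, lb, thresholds = c(0, 1))
#' @export
evaluateThreshold <- function(scores, labels = NULL, thresholds = 0) {
  if (is(scores, "DataFrame") || is.data.frame(scores)) {
    labels <- labels %||% as.character(scores$group)
    scores <- scores$shgm
  }
  stopifnot(length(scores) == length(labels))
  labels <- as.character(labels)
  keep <- labels %in% c("ACC", "ACA")
  scores <- scores[keep]; labels <- labels[keep]
  if (!any(labels == "ACC") || !any(labels == "ACA"))
    warning("evaluation needs both ACC and ACA samples; ",
            "metrics with empty denominators are NA", call. = FALSE)
  stopifnot(all(thresholds >= 0), all(thresholds == round(thresholds)))
  rows <- lapply(thresholds, function(t) {
    cm <- .confusion(scores, labels, t)
    mt <- .metricsFromConfusion(cm)
    data.frame(threshold = t,
               TP = cm[["TP"]], FP = cm[["FP"]],
               FN = cm[["FN"]], TN = cm[["TN"]],
               sensitivity = mt[["sensitivity"]],
               specificity = mt[["specificity"]],
               ppv = mt[["ppv"]], npv = mt[["npv"]],
               positives = sum(scores > t),
               positivity_acc = if (any(labels == "ACC"))
                 100 * mean(scores[labels == "ACC"] > t) else NA_real_,
               positivity_aca = if (any(labels == "ACA"))
                 100 * mean(scores[labels == "ACA"] > t) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Diagnostic metrics within a metadata-defined subgroup
#'
#' Restricts the threshold evaluation to samples selected by a predicate on
#' the metadata (e.g. small tumors, \code{diameter_cm <= 5}) and
#' additionally reports the subgroup positivity count and fraction.
#'
#' @param scores a \code{\link{scoreCohort}} result (or numeric vector).
#' @param metadata sample metadata data.frame aligned on \code{sample_id}.
#' @param subset a logical vector over metadata rows, or an unquoted
#'   expression evaluated within \code{metadata}
#'   (e.g. \code{diameter_cm <= 5}).
#' @param thresholds integer threshold(s).
#' @param labels group labels (taken from \code{scores} when omitted).
#' @return As \code{\link{evaluateThreshold}}, with extra columns
#'   \code{n_subgroup}, \code{n_positive}, \code{pct_positive}; when the
#'   subgroup is empty, a single all-NA row flagged by \code{n_subgroup = 0}.
#' @examples
#' fx <- table5Fixture()
#' m <- buildMatrix(fx$variants, fx$metadata)
#' sc <- scoreCohort(m, highRiskSet(c("ZNRF3", "TP53", "ARMC5", "APC",
#'                                    "RB1", "PRKAR1A")))
#' subgroupMetrics(sc, fx$metadata, diameter_cm <= 5, thresholds = c(0, 1))
#' @export
subgroupMetrics <- function(scores, metadata, subset, thresholds = 0,
                            labels = NULL) {
  sel <- eval(substitute(subset), metadata, parent.frame())
  if (!is.logical(sel) || length(sel) != nrow(metadata))
    stop("subset must evaluate to a logical vector over metadata rows",
         call. = FALSE)
  sel <- sel & !is.na(sel)
  if (is(scores, "DataFrame") || is.data.frame(scores)) {
    ord <- match(metadata$sample_id, scores$sample_id)
    if (anyNA(ord))
      stop("metadata sample(s) missing from scores: ",
           paste(metadata$sample_id[is.na(ord)], collapse = ", "),
           call. = FALSE)
    labels <- labels %||% as.character(scores$group)[ord]
    scoreVec <- scores$shgm[ord]
  } else {
    scoreVec <- scores
    stopifnot(!is.null(labels), length(labels) == length(scoreVec))
  }
  if (!any(sel)) {
    out <- suppressWarnings(
      evaluateThreshold(integer(0), character(0), thresholds))
    out[] <- NA
    out$threshold <- thresholds
    out$n_subgroup <- 0L
    out$n_positive <- NA_integer_
    out$pct_positive <- NA_real_
    return(out)
  }
  sub <- suppressWarnings(
    evaluateThreshold(scoreVec[sel], labels[sel], thresholds))
  sub$n_subgroup <- sum(sel)
  sub$n_positive <- vapply(thresholds, function(t)
    sum(scoreVec[sel] > t), integer(1))
  sub$pct_positive <- 100 * sub$n_positive / sum(sel)
  sub
}
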