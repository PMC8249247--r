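## End-to-end orchestration: filter -> matrix -> per-gene tests -> high-risk
## selection -> SHGM scoring -> threshold diagnostics -> clinical
## association, with per-stage TSVs, a JSON report and a run log.

.dfToBase <- function(x) as.data.frame(x, stringsAsFactors = FALSE)

#' Run the full SHGM analysis pipeline
#'
#' Executes every stage on an annotated variant table and sample metadata:
#' significance filtering, matrix construction, per-gene exact rate tests
#' (ACC vs ACA, and ACC vs NORMAL when normal samples are present),
#' high-risk gene selection (or a pinned gene set), per-sample SHGM
#' scoring, threshold diagnostics over all thresholds from 0 to the size of
#' the high-risk set, optional subgroup diagnostics, burden comparison
#' across groups, and SHGM-vs-covariate association for whatever clinical
#' columns the metadata carries.  Re-running with identical inputs and
#' configuration produces byte-identical outputs; the configuration hash is
#' recorded in the report so stale intermediates are detectable.
#'
#' @param variants annotated variant data.frame (unfiltered; the pipeline
#'   filters), or a path to a variant TSV.
#' @param metadata sample metadata data.frame, or a path to a metadata TSV.
#' @param outDir output directory for TSVs, \code{report.json} and
#'   \code{run_log.txt}; \code{NULL} (default) writes nothing.
#' @param config a \code{\link{filterConfig}}.
#' @param alpha significance level for high-risk selection.
#' @param method per-gene test method, \code{"fisher"} or \code{"chisq"}.
#' @param holm also report Holm-adjusted p-values.
#' @param pinnedGenes optional character vector pinning the high-risk set
#'   (e.g. the canonical six genes) instead of data-driven selection.
#' @param subgroupDiameter evaluate a small-tumor subgroup at
#'   \code{diameter_cm <= subgroupDiameter} (default 5; NA to skip).
#' @param thresholds integer thresholds to evaluate; default 0 up to the
#'   high-risk set size.
#' @return List of class \code{"ShgmReport"}: \code{config},
#'   \code{configHash}, \code{nFiltered}, \code{matrix}, \code{geneTests}
#'   (per comparison), \code{highRisk}, \code{scores}, \code{diagnostics},
#'   \code{subgroup}, \code{burden}, \code{clinical}, \code{warnings}.
#' @examples
#' fx <- table5Fixture()
#' rep <- runShgmPipeline(fx$variants, fx$metadata,
#'                        pinnedGenes = c("ZNRF3", "TP53", "ARMC5", "APC",
#'                                        "RB1", "PRKAR1A"))
#' rep$subgroup$pct_positive   # 75, 50, ...
#' @export
runShgmPipeline <- function(variants, metadata, outDir = NULL,
                            config = filterConfig(), alpha = 0.05,
                            method = c("fisher", "chisq"), holm = FALSE,
                            pinnedGenes = NULL, subgroupDiameter = 5,
                            thresholds = NULL) {
  method <- match.arg(method)
  if (is.character(variants) && length(variants) == 1L)
    variants <- readVariantTable(variants)
  if (is.character(metadata) && length(metadata) == 1L)
    metadata <- readSampleMetadata(metadata)
  warningsSeen <- character(0)
  note <- function(msg) warningsSeen <<- c(warningsSeen, msg)

  cfgHash <- rlang::hash(list(
    afThreshold = config@afThreshold,
    significantTypes = config@significantTypes,
    alpha = alpha, method = method, holm = holm,
    pinnedGenes = pinnedGenes, subgroupDiameter = subgroupDiameter,
    thresholds = thresholds))

  ## stage 1: significance filter
  filtered <- filterSignificant(variants, config)
  if (nrow(filtered) == 0)
    note("no variant passed the significance filter")

  ## stage 2: matrix
  m <- buildMatrix(filtered, metadata)
  grp <- as.character(sampleGroups(m))
  groupsPresent <- intersect(.GROUP_LEVELS, unique(grp))

  ## stage 3: per-gene comparisons
  geneTests <- list()
  if (all(c("ACC", "ACA") %in% groupsPresent))
    geneTests$ACC_vs_ACA <- testAllGenes(m, "ACC", "ACA", method = method,
                                         holm = holm)
  if (all(c("ACC", "NORMAL") %in% groupsPresent))
    geneTests$ACC_vs_NORMAL <- testAllGenes(m, "ACC", "NORMAL",
                                            method = method, holm = holm)

  ## stage 4: high-risk set (data-driven from ACC vs ACA, unless pinned)
  highRisk <- if (!is.null(pinnedGenes)) {
    highRiskSet(pinnedGenes)
  } else if (!is.null(geneTests$ACC_vs_ACA)) {
    selectHighRisk(geneTests$ACC_vs_ACA, alpha)
  } else {
    note(paste0("no ACC vs ACA comparison possible and no pinned gene ",
                "set; high-risk set is empty"))
    highRiskSet(character(0))
  }
  if (length(highRiskGenes(highRisk)) == 0)
    note("high-risk set is empty; all SHGM scores are 0")

  ## stage 5: scoring
  scores <- scoreCohort(m, highRisk)

  ## stage 6: threshold diagnostics (ACC vs ACA)
  if (is.null(thresholds))
    thresholds <- 0:max(1L, length(highRiskGenes(highRisk)))
  diagnostics <- NULL
  if (all(c("ACC", "ACA") %in% groupsPresent)) {
    diagnostics <- evaluateThreshold(scores, thresholds = thresholds)
  } else {
    note("threshold diagnostics skipped: need both ACC and ACA samples")
  }

  ## stage 6b: small-tumor subgroup
  subgroup <- NULL
  if (!is.na(subgroupDiameter) && "diameter_cm" %in% names(metadata)) {
    md <- metadata
    md$.sel <- !is.na(md$diameter_cm) & md$diameter_cm <= subgroupDiameter &
      md$group == "ACC"
    subgroup <- suppressWarnings(
      subgroupMetrics(scores, md, .sel, thresholds = thresholds))
  }

  ## stage 7: burden comparison across groups
  burden <- NULL
  if (length(groupsPresent) >= 2) {
    perSampleGenes <- split(colSums(mutationIndicator(m)), grp)
    perSampleSites <- split(colSums(siteCounts(m)), grp)
    burden <- list(
      gene_count = compareBurden(perSampleGenes[groupsPresent],
                                 "gene_count"),
      site_count = compareBurden(perSampleSites[groupsPresent],
                                 "site_count"))
  }

  ## stage 8: SHGM vs clinical covariates (ACC samples)
  clinical <- list()
  accIdx <- which(as.character(scores$group) == "ACC")
  if (length(accIdx) >= 3) {
    md <- metadata[match(scores$sample_id[accIdx], metadata$sample_id), ]
    s <- scores$shgm[accIdx]
    for (col in intersect(c("age", "diameter_cm", "ki67"), names(md)))
      if (!all(is.na(md[[col]])))
        clinical[[col]] <- clinicalAssociation(s, md[[col]], "continuous",
                                               name = col)
    for (col in intersect(c("sex", "functional", "stage"), names(md)))
      if (!all(is.na(md[[col]])))
        clinical[[col]] <- clinicalAssociation(s, md[[col]], "categorical",
                                               name = col)
  }

  report <- structure(list(
    config = list(afThreshold = config@afThreshold,
                  significantTypes = config@significantTypes,
                  alpha = alpha, method = method, holm = holm,
                  pinnedGenes = pinnedGenes,
                  subgroupDiameter = subgroupDiameter,
                  thresholds = thresholds),
    configHash = cfgHash,
    nInput = nrow(variants),
    nFiltered = nrow(filtered),
    matrix = m,
    geneTests = geneTests,
    highRisk = highRisk,
    scores = scores,
    diagnostics = diagnostics,
    subgroup = subgroup,
    burden = burden,
    clinical = clinical,
    warnings = warningsSeen), class = "ShgmReport")

  if (!is.null(outDir)) .writeReportBundle(report, filtered, outDir)
  report
}

#' @export
print.ShgmReport <- function(x, ...) {
  cat("ShgmReport (config hash ", x$configHash, ")\n", sep = "")
  cat("  variants:", x$nInput, "in,", x$nFiltered, "significant\n")
  cat("  samples:", ncol(x$matrix), "\n")
  cat("  high-risk genes:",
      paste(highRiskGenes(x$highRisk), collapse = ", "), "\n")
  if (!is.null(x$diagnostics)) {
    cat("  diagnostics (ACC vs ACA), % to 1 d.p.:\n")
    d <- x$diagnostics
    for (i in seq_len(nrow(d)))
      cat(sprintf(
        "    SHGM > %d: sens %.1f spec %.1f ppv %.1f npv %.1f\n",
        d$threshold[i], d$sensitivity[i], d$specificity[i], d$ppv[i],
        d$npv[i]))
  }
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

.writeReportBundle <- function(report, filtered, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeVariantTable(filtered, file.path(outDir, "filtered_variants.tsv"))
  writeMutationMatrix(report$matrix, file.path(outDir, "matrix_long.tsv"),
                      format = "long")
  writeMutationMatrix(report$matrix, file.path(outDir, "matrix_wide.tsv"),
                      format = "wide")
  for (cmp in names(report$geneTests)) {
    df <- .dfToBase(report$geneTests[[cmp]])
    df$p_printed <- .formatP(df$p_value)
    write.table(df, file.path(outDir, paste0("gene_tests_", cmp, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(.dfToBase(report$scores), file.path(outDir, "scores.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  json <- list(
    config = report$config,
    config_hash = report$configHash,
    n_input = report$nInput,
    n_filtered = report$nFiltered,
    high_risk_genes = highRiskGenes(report$highRisk),
    diagnostics = if (!is.null(report$diagnostics))
      lapply(seq_len(nrow(report$diagnostics)), function(i) {
        d <- report$diagnostics[i, ]
        list(threshold = d$threshold,
             confusion = list(TP = d$TP, FP = d$FP, FN = d$FN, TN = d$TN),
             sensitivity = .pct1(d$sensitivity),
             specificity = .pct1(d$specificity),
             ppv = .pct1(d$ppv), npv = .pct1(d$npv),
             positivity_acc = .pct1(d$positivity_acc),
             positivity_aca = .pct1(d$positivity_aca))
      }),
    subgroup = if (!is.null(report$subgroup))
      lapply(seq_len(nrow(report$subgroup)), function(i) {
        d <- report$subgroup[i, ]
        list(threshold = d$threshold, n = d$n_subgroup,
             n_positive = d$n_positive,
             pct_positive = .pct1(d$pct_positive))
      }),
    warnings = report$warnings)
  jsonlite::write_json(json, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  log <- c(
    paste0("package: shgm ",
           as.character(utils::packageVersion("shgm"))),
    paste0("R: ", R.version.string),
    paste0("config_hash: ", report$configHash),
    paste0("n_input: ", report$nInput),
    paste0("n_filtered: ", report$nFiltered),
    paste0("warnings: ", length(report$warnings)))
  writeLines(log, file.path(outDir, "run_log.txt"))
  invisible(outDir)
}
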