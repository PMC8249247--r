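## Annotated variant tables: normalization, significance filtering, TSV IO.
##
## A variant table is a data.frame with one row per annotated call and the
## columns sample_id, gene, chrom, pos, ref, alt, effect, pop_af.  `effect`
## is free annotation text (normalized on demand); `pop_af` is a population
## allele frequency in [0,1] or NA when the variant is absent from the
## reference population.

.VARIANT_COLUMNS <- c("sample_id", "gene", "chrom", "pos", "ref", "alt",
                      "effect", "pop_af")

## Synonym table for annotation dialects, keyed on the canonicalized label.
.EFFECT_SYNONYMS <- c(
  NONSYNONYMOUS_SNV      = "NONSYNONYMOUS_SNV",
  NONSYNONYMOUS          = "NONSYNONYMOUS_SNV",
  MISSENSE               = "NONSYNONYMOUS_SNV",
  MISSENSE_VARIANT       = "NONSYNONYMOUS_SNV",
  MISSENSE_MUTATION      = "NONSYNONYMOUS_SNV",
  SYNONYMOUS_SNV         = "SYNONYMOUS_SNV",
  SYNONYMOUS             = "SYNONYMOUS_SNV",
  SYNONYMOUS_VARIANT     = "SYNONYMOUS_SNV",
  SILENT                 = "SYNONYMOUS_SNV",
  STOPGAIN               = "STOPGAIN",
  STOP_GAIN              = "STOPGAIN",
  STOP_GAINED            = "STOPGAIN",
  NONSENSE               = "STOPGAIN",
  NONSENSE_MUTATION      = "STOPGAIN",
  STOPLOSS               = "STOPLOSS",
  STOP_LOSS              = "STOPLOSS",
  STOP_LOST              = "STOPLOSS",
  FRAMESHIFT_DELETION    = "FRAMESHIFT_DELETION",
  FRAMESHIFT_DEL         = "FRAMESHIFT_DELETION",
  FS_DEL                 = "FRAMESHIFT_DELETION",
  FRAME_SHIFT_DEL        = "FRAMESHIFT_DELETION",
  FRAMESHIFT_INSERTION   = "FRAMESHIFT_INSERTION",
  FRAMESHIFT_INS         = "FRAMESHIFT_INSERTION",
  FS_INS                 = "FRAMESHIFT_INSERTION",
  FRAME_SHIFT_INS        = "FRAMESHIFT_INSERTION",
  NONFRAMESHIFT_DELETION = "NONFRAMESHIFT_DELETION",
  INFRAME_DELETION       = "NONFRAMESHIFT_DELETION",
  IN_FRAME_DEL           = "NONFRAMESHIFT_DELETION",
  NONFRAMESHIFT_INSERTION = "NONFRAMESHIFT_INSERTION",
  INFRAME_INSERTION      = "NONFRAMESHIFT_INSERTION",
  IN_FRAME_INS           = "NONFRAMESHIFT_INSERTION",
  SPLICING               = "SPLICING",
  SPLICE                 = "SPLICING",
  SPLICE_SITE            = "SPLICING",
  SPLICE_SITE_VARIANT    = "SPLICING",
  SPLICE_REGION          = "SPLICING",
  INTRONIC               = "INTRONIC",
  INTRON                 = "INTRONIC",
  INTRON_VARIANT         = "INTRONIC",
  UTR5                   = "UTR5",
  UTR_5                  = "UTR5",
  X5_UTR                 = "UTR5",
  FIVE_PRIME_UTR         = "UTR5",
  UTR3                   = "UTR3",
  UTR_3                  = "UTR3",
  X3_UTR                 = "UTR3",
  THREE_PRIME_UTR        = "UTR3"
)

#' Normalize a free-text effect label onto the closed taxonomy
#'
#' Deterministic, case/whitespace/punctuation-insensitive mapping from the
#' effect strings that variant annotators emit (e.g. \code{"nonsynonymous
#' SNV"}, \code{"stop_gained"}, \code{"splice site"}) to the closed
#' vocabulary of \code{\link{mutationTypes}}.  Labels that cannot be mapped
#' become \code{"UNKNOWN"}; no input ever errors.
#'
#' @param raw character vector of effect labels.
#' @return Character vector of the same length with values from
#'   \code{mutationTypes()}.
#' @examples
#' normalizeEffectLabel(c("nonsynonymous SNV", "stopgain", "weird_label_42"))
#' @export
normalizeEffectLabel <- function(raw) {
  stopifnot(is.character(raw) | is.factor(raw))
  canon <- toupper(as.character(raw))
  canon <- gsub("[^A-Z0-9]+", "_", canon)
  canon <- gsub("^_+|_+$", "", canon)
  canon <- sub("^([0-9])", "X\\1", canon)  # "5'UTR" -> "X5_UTR"
  out <- unname(.EFFECT_SYNONYMS[canon])
  out[is.na(out)] <- "UNKNOWN"
  out
}

.checkVariantTable <- function(variants) {
  missing <- setdiff(.VARIANT_COLUMNS, names(variants))
  if (length(missing))
    stop("variant table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(variants)
}

.variantKey <- function(variants) {
  paste(variants$sample_id, variants$gene, variants$chrom, variants$pos,
        variants$ref, variants$alt, sep = "\r")
}

.siteKey <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = "\r")
}

#' Is each variant biologically significant?
#'
#' A call is significant when its normalized effect class belongs to the
#' configured significant set and its population allele frequency is either
#' missing (novel variant) or strictly below the configured cutoff.  This is
#' the programmatic form of removing synonymous variants and common
#' polymorphisms seen at high frequency in healthy populations.
#'
#' @param variants a variant table (see \code{\link{readVariantTable}}).
#' @param config a \code{\link{filterConfig}}.
#' @return Logical vector, one element per row of \code{variants}.
#' @examples
#' v <- table5Fixture()$variants
#' table(isSignificant(v, filterConfig()))
#' @export
isSignificant <- function(variants, config = filterConfig()) {
  stopifnot(is(config, "FilterConfig"))
  .checkVariantTable(variants)
  mtype <- normalizeEffectLabel(variants$effect)
  af <- variants$pop_af
  mtype %in% config@significantTypes &
    (is.na(af) | af < config@afThreshold)
}

#' Filter a variant table down to significant calls
#'
#' Row order is preserved and the operation is idempotent.
#'
#' @inheritParams isSignificant
#' @return The subset of rows of \code{variants} for which
#'   \code{\link{isSignificant}} is \code{TRUE}.
#' @export
filterSignificant <- function(variants, config = filterConfig()) {
  keep <- isSignificant(variants, config)
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write an annotated variant table
#'
#' Tab-separated, UTF-8, with the exact header \code{sample_id gene chrom pos
#' ref alt effect pop_af}.  \code{pop_af} may be empty (missing).  Genes
#' outside the nine-gene panel are rejected (\code{panelAction = "error"},
#' the default) or dropped with a warning (\code{"drop"}).  Duplicate
#' identical calls for one (sample, gene, chrom, pos, ref, alt) are
#' deduplicated with a warning.  \code{writeVariantTable} followed by
#' \code{readVariantTable} round-trips the records.
#'
#' @param path file path.
#' @param panelAction what to do with rows whose gene is off-panel.
#' @return \code{readVariantTable}: a variant data.frame;
#'   \code{writeVariantTable}: the path, invisibly.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeVariantTable(table5Fixture()$variants, tf)
#' head(readVariantTable(tf))
#' @export
readVariantTable <- function(path, panelAction = c("error", "drop")) {
  panelAction <- match.arg(panelAction)
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  missing <- setdiff(.VARIANT_COLUMNS, hdr)
  if (length(missing))
    stop("variant table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(pos = "character", pop_af = "character"))
  .checkVariantTable(df)
  df$gene <- toupper(df$gene)
  pos <- suppressWarnings(as.integer(df$pos))
  badPos <- which(is.na(pos) | pos < 1)
  if (length(badPos))
    stop("unparseable or non-positive pos at row(s): ",
         paste(badPos, collapse = ", "), call. = FALSE)
  df$pos <- pos
  afRaw <- df$pop_af
  af <- suppressWarnings(as.numeric(afRaw))
  badAf <- which(!is.na(afRaw) & nzchar(trimws(afRaw)) &
                   (is.na(af) | af < 0 | af > 1))
  if (length(badAf))
    stop("unparseable pop_af (must be in [0,1] or empty) at row(s): ",
         paste(badAf, collapse = ", "), call. = FALSE)
  df$pop_af <- af
  offPanel <- which(!(df$gene %in% .PANEL_GENES))
  if (length(offPanel)) {
    if (panelAction == "error")
      stop("gene(s) outside the nine-gene panel at row(s) ",
           paste(offPanel, collapse = ", "), ": ",
           paste(unique(df$gene[offPanel]), collapse = ", "), call. = FALSE)
    warning("dropping ", length(offPanel), " row(s) with off-panel gene(s): ",
            paste(unique(df$gene[offPanel]), collapse = ", "), call. = FALSE)
    df <- df[-offPanel, , drop = FALSE]
  }
  dup <- duplicated(.variantKey(df))
  if (any(dup)) {
    warning("deduplicated ", sum(dup), " identical call(s)", call. = FALSE)
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df[.VARIANT_COLUMNS]
}

#' @rdname readVariantTable
#' @param variants a variant data.frame.
#' @export
writeVariantTable <- function(variants, path) {
  .checkVariantTable(variants)
  write.table(variants[.VARIANT_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a sample metadata table
#'
#' Tab-separated with header \code{sample_id group age sex diameter_cm stage
#' functional ki67}; the clinical columns are optional and may be empty.
#' Group labels must be ACC, ACA or NORMAL.
#'
#' @param path file path.
#' @return \code{readSampleMetadata}: a data.frame with one row per sample;
#'   \code{writeSampleMetadata}: the path, invisibly.
#' @export
readSampleMetadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("metadata must contain columns sample_id and group", call. = FALSE)
  df$group <- toupper(df$group)
  bad <- setdiff(unique(df$group), .GROUP_LEVELS)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata", call. = FALSE)
  df
}

#' @rdname readSampleMetadata
#' @param metadata a metadata data.frame.
#' @export
writeSampleMetadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}
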