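## Small formatting helpers shared by print methods and reports.

#' @importFrom rlang hash %||%
NULL

## p-values printed with 3 significant figures, "<0.001" below 0.0005,
## matching the usual clinical-table convention.
.formatP <- function(p) {
  ifelse(is.na(p), "NA",
         ifelse(p < 5e-4, "<0.001", formatC(signif(p, 3), format = "fg")))
}

## Percentages to one decimal place, e.g. 81.8.
.pct1 <- function(x) round(x, 1)
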