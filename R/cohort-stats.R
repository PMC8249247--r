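## Two-group statistics: per-gene exact rate tests, burden comparisons,
## clinical-covariate association.

#' Two-sided Fisher exact test (minimum-likelihood rule)
#'
#' Exact two-sided p-value for a 2x2 table under the hypergeometric null,
#' using the minimum-likelihood convention: the p-value is the sum of the
#' probabilities of every table with the observed margins whose probability
#' does not exceed that of the observed table.  This is the convention of
#' mainstream statistics software for two-sided 2x2 exact tests.  Tied
#' probabilities are compared with a relative tolerance of 1e-7 so that
#' exactly symmetric tables are counted as ties despite floating-point
#' rounding.
#'
#' The table layout is rows = groups, columns = mutated/unmutated:
#' \code{a}/\code{b} mutated/unmutated in group 1, \code{c}/\code{d} in
#' group 2.
#'
#' @param a,b,c,d non-negative integer cell counts; \code{a + b} and
#'   \code{c + d} (the group sizes) must be positive.
#' @return The two-sided p-value in (0, 1].
#' @examples
#' fisherExactTwoSided(12, 25, 1, 31)   # ~0.002
#' fisherExactTwoSided(5, 5, 5, 5)      # identical groups -> 1
#' @export
fisherExactTwoSided <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  if (a + b == 0 || c + d == 0)
    stop("both group sizes must be positive", call. = FALSE)
  m <- a + b       # size of group 1
  n <- c + d       # size of group 2
  k <- a + c       # total mutated
  support <- max(0L, k - n):min(k, m)
  dens <- dhyper(support, m, n, k)
  pObs <- dens[match(a, support)]
  p <- sum(dens[dens <= pObs * (1 + 1e-7)])
  min(p, 1)
}

#' Per-gene two-group mutation-rate test
#'
#' Builds the 2x2 table of mutated/unmutated samples for one panel gene from
#' the matrix indicators and tests for a rate difference between two groups.
#' The default method is the two-sided Fisher exact test
#' (\code{\link{fisherExactTwoSided}}); Pearson's chi-squared test (with
#' continuity correction) is available behind \code{method = "chisq"}.
#'
#' @param m a \code{\link{MutationMatrix}}.
#' @param gene one panel gene symbol.
#' @param group1,group2 group labels to compare (group 1 is conventionally
#'   ACC; \code{direction} is reported relative to it).
#' @param method \code{"fisher"} (default) or \code{"chisq"}.
#' @return One-row \code{DataFrame} with columns \code{gene}, \code{a},
#'   \code{b}, \code{c}, \code{d}, \code{rate1}, \code{rate2},
#'   \code{p_value}, \code{method}, \code{direction}
#'   (\code{"group1_higher"}, \code{"group2_higher"} or \code{"equal"}).
#' @examples
#' fx <- table5Fixture()
#' m <- buildMatrix(fx$variants, fx$metadata)
#' ## single-group fixture: compare requires two groups, see testAllGenes()
#' @export
geneRateTest <- function(m, gene, group1 = "ACC", group2 = "ACA",
                         method = c("fisher", "chisq")) {
  stopifnot(is(m, "MutationMatrix"))
  method <- match.arg(method)
  if (!(gene %in% .PANEL_GENES))
    stop("unknown panel gene: ", gene, call. = FALSE)
  grp <- as.character(sampleGroups(m))
  s1 <- which(grp == group1)
  s2 <- which(grp == group2)
  if (!length(s1) || !length(s2))
    stop("both groups must be nonempty (", group1, ": ", length(s1), ", ",
         group2, ": ", length(s2), ")", call. = FALSE)
  ind <- mutationIndicator(m)[gene, ]
  a <- sum(ind[s1]); b <- length(s1) - a
  cc <- sum(ind[s2]); d <- length(s2) - cc
  rate1 <- a / (a + b)
  rate2 <- cc / (cc + d)
  p <- if (method == "fisher") {
    fisherExactTwoSided(a, b, cc, d)
  } else {
    suppressWarnings(
      chisq.test(matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE))$p.value)
  }
  direction <- if (rate1 > rate2) "group1_higher"
               else if (rate1 < rate2) "group2_higher" else "equal"
  S4Vectors::DataFrame(gene = gene, a = a, b = b, c = cc, d = d,
                       rate1 = rate1, rate2 = rate2, p_value = p,
                       method = if (method == "fisher") "fisher_exact"
                                else "chi_squared",
                       direction = direction)
}

#' Rate tests for all nine panel genes
#'
#' Runs \code{\link{geneRateTest}} for every panel gene and orders the
#' results by descending group-1 mutation rate, ties broken alphabetically
#' by gene symbol (the "rates from high to low" presentation).
#'
#' @inheritParams geneRateTest
#' @param holm also report Holm-adjusted p-values in a \code{p_holm} column
#'   (no adjustment is applied to \code{p_value} itself).
#' @return \code{DataFrame} with one row per panel gene (columns as in
#'   \code{\link{geneRateTest}}, plus \code{significant} at
#'   \code{p <= 0.05} and optionally \code{p_holm}).
#' @export
testAllGenes <- function(m, group1 = "ACC", group2 = "ACA",
                         method = c("fisher", "chisq"), holm = FALSE) {
  method <- match.arg(method)
  res <- do.call(rbind, lapply(.PANEL_GENES, function(g)
    geneRateTest(m, g, group1, group2, method)))
  res$significant <- res$p_value <= 0.05
  if (holm) res$p_holm <- p.adjust(res$p_value, method = "holm")
  ord <- order(-res$rate1, res$gene)
  res <- res[ord, ]
  rownames(res) <- NULL
  res
}

#' Compare per-sample burden between groups
#'
#' Nonparametric comparison of per-sample counts (mutated genes, mutation
#' sites or SHGM scores) across groups: Wilcoxon rank-sum for two groups,
#' Kruskal-Wallis for three or more.  Ties are handled by midranks with the
#' standard tie correction (as implemented in \code{stats}).
#'
#' @param groups named list of two or more numeric vectors of per-sample
#'   counts; every vector must be nonempty.
#' @param quantity label for what is being compared
#'   (\code{"gene_count"}, \code{"site_count"} or \code{"shgm"}).
#' @return List of class \code{"BurdenComparison"} with elements
#'   \code{statistic}, \code{p_value}, \code{method}, \code{groups},
#'   \code{quantity}.
#' @examples
#' compareBurden(list(ACC = c(4, 5, 3), ACA = c(0, 1, 1)))
#' @export
compareBurden <- function(groups, quantity = c("gene_count", "site_count",
                                               "shgm")) {
  quantity <- match.arg(quantity)
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) == 0))
    stop("every group must be nonempty", call. = FALSE)
  if (length(groups) == 2) {
    ## exact distribution when sample sizes permit and there are no ties;
    ## midrank normal approximation with tie correction otherwise
    ht <- suppressWarnings(wilcox.test(groups[[1]], groups[[2]],
                                       correct = TRUE))
    method <- "wilcoxon_rank_sum"
  } else {
    x <- unlist(groups, use.names = FALSE)
    g <- factor(rep(seq_along(groups), lengths(groups)))
    ht <- kruskal.test(x, g)
    method <- "kruskal_wallis"
  }
  structure(list(statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 method = method,
                 groups = names(groups) %||% as.character(seq_along(groups)),
                 quantity = quantity),
            class = "BurdenComparison")
}

#' @export
print.BurdenComparison <- function(x, ...) {
  cat("BurdenComparison (", x$method, ") of ", x$quantity, " across ",
      paste(x$groups, collapse = ", "), "\n", sep = "")
  cat("  statistic =", signif(x$statistic, 4),
      " p =", .formatP(x$p_value), "\n")
  invisible(x)
}

#' Association between SHGM and one clinical covariate
#'
#' Continuous covariates (age, diameter, Ki-67 index) are tested by
#' Spearman rank correlation; two-level categorical covariates (sex,
#' endocrine function, stage group) by the Wilcoxon rank-sum test on SHGM
#' between the levels, with per-level median and IQR reported.  Pairs with a
#' missing covariate value are dropped.  With fewer than 3 complete pairs
#' (or zero-variance input) the result is returned flagged as undefined
#' rather than raising an error.
#'
#' @param scores numeric vector of per-sample SHGM scores.
#' @param covariate vector of covariate values aligned with \code{scores}.
#' @param kind \code{"continuous"} or \code{"categorical"}.
#' @param name covariate name carried into the result.
#' @return List of class \code{"ClinicalAssociation"} with elements
#'   \code{covariate}, \code{kind}, \code{effect} (Spearman rho, or a named
#'   list of per-level \code{median}/\code{iqr}), \code{p_value}, \code{n},
#'   \code{defined}.
#' @examples
#' clinicalAssociation(c(0, 2, 3, 6, 1, 5), c(41, 52, 39, 60, 45, 58),
#'                     kind = "continuous", name = "age")
#' @export
clinicalAssociation <- function(scores, covariate,
                                kind = c("continuous", "categorical"),
                                name = "covariate") {
  kind <- match.arg(kind)
  stopifnot(length(scores) == length(covariate))
  ok <- !is.na(scores) & !is.na(covariate)
  s <- scores[ok]; cv <- covariate[ok]
  undefined <- function(reason) {
    structure(list(covariate = name, kind = kind, effect = NA_real_,
                   p_value = NA_real_, n = length(s), defined = FALSE,
                   reason = reason),
              class = "ClinicalAssociation")
  }
  if (length(s) < 3) return(undefined("fewer than 3 complete pairs"))
  if (kind == "continuous") {
    if (length(unique(s)) < 2 || length(unique(cv)) < 2)
      return(undefined("zero variance"))
    ct <- suppressWarnings(cor.test(s, as.numeric(cv), method = "spearman",
                                    exact = FALSE))
    effect <- unname(ct$estimate)
    p <- ct$p.value
  } else {
    f <- factor(cv)
    if (nlevels(f) != 2)
      return(undefined(paste0("expected 2 levels, got ", nlevels(f))))
    if (any(table(f) == 0) || length(unique(s)) < 2)
      return(undefined("degenerate grouping"))
    ht <- suppressWarnings(wilcox.test(s ~ f, exact = FALSE))
    p <- ht$p.value
    effect <- lapply(split(s, f), function(v)
      list(median = median(v), iqr = unname(quantile(v, c(0.25, 0.75)))))
  }
  structure(list(covariate = name, kind = kind, effect = effect,
                 p_value = p, n = length(s), defined = TRUE),
            class = "ClinicalAssociation")
}

#' @export
print.ClinicalAssociation <- function(x, ...) {
  cat("ClinicalAssociation: SHGM vs", x$covariate, paste0("(", x$kind, ")"),
      "n =", x$n, "\n")
  if (!x$defined) {
    cat("  undefined:", x$reason, "\n")
  } else if (x$kind == "continuous") {
    cat("  Spearman rho =", signif(x$effect, 3),
        " p =", .formatP(x$p_value), "\n")
  } else {
    for (lev in names(x$effect))
      cat(sprintf("  %s: median %g (IQR %g-%g)\n", lev,
                  x$effect[[lev]]$median, x$effect[[lev]]$iqr[1],
                  x$effect[[lev]]$iqr[2]))
    cat("  rank-sum p =", .formatP(x$p_value), "\n")
  }
  invisible(x)
}
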