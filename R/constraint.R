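#' Assign constraint deciles to a gene table
#'
#' Genes are sorted by increasing s_het (selection coefficient against
#' heterozygous loss of function), ties broken alphabetically by symbol, and
#' partitioned into 10 contiguous equal-frequency bins. Decile 10 holds the
#' most constrained genes; when the gene count is not divisible by 10 the
#' remainder is absorbed by the lowest deciles, so bin sizes differ by at
#' most one. A pre-binned `decile` column in the input, when supplied to
#' downstream functions, can override this assignment so that either
#' published orientation can be reproduced.
#'
#' @param table Data frame with columns `gene` and `s_het`.
#' @return Data frame with columns `gene`, `s_het`, `decile`, sorted by
#'   ascending s_het.
#' @export
assign_deciles <- function(table) {
  stopifnot(all(c("gene", "s_het") %in% names(table)))
  gene <- as.character(table$gene)
  s_het <- as.numeric(table$s_het)
  if (length(gene) < 10L) stop("need at least 10 genes to assign deciles")
  if (any(!is.finite(s_het))) stop("non-finite s_het value(s)")
  ord <- order(s_het, gene)
  n <- length(gene)
  base <- n %/% 10L; extra <- n %% 10L
  sizes <- rep(base, 10L) + c(rep(1L, extra), rep(0L, 10L - extra))
  decile <- rep.int(1:10, sizes)
  data.frame(gene = gene[ord], s_het = s_het[ord], decile = decile,
             stringsAsFactors = FALSE)
}

#' Select genes in the top constraint deciles
#'
#' @param entries Data frame from [assign_deciles()] (or with a `decile`
#'   column in the 1..10, 10-most-constrained orientation).
#' @param k Number of top deciles to keep (1..10); the study's high-s_het
#'   list is the top 2.
#' @param label Label for the returned set.
#' @return A `gene_set` of all genes with `decile > 10 - k`.
#' @export
select_top_deciles <- function(entries, k = 2L, label = NULL) {
  stopifnot(all(c("gene", "decile") %in% names(entries)))
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 10L) stop("k must be in 1..10")
  if (is.null(label)) label <- sprintf("top_%d_deciles", k)
  gene_set(entries$gene[entries$decile > 10L - k], label = label)
}

#' Decile burden test for a flagged gene list
#'
#' Tests whether genes in a flagged list (e.g., genes carrying damaging de
#' novo variants in disease probands) concentrate in high-constraint
#' deciles. Two statistics are reported side by side: a one-way ANOVA of the
#' binary flagged indicator grouped by decile (the test the study design
#' calls for, even though ANOVA on 0/1 responses is unconventional), and a
#' chi-square test for linear trend in proportions across deciles
#' (Cochran–Armitage style, via [stats::prop.trend.test()]) as a robustness
#' statistic. Neither replaces the other.
#'
#' When the flagged list is disjoint from the table, per-decile counts are
#' still returned and all test statistics are `NA`.
#'
#' @param entries Data frame with columns `gene` and `decile`.
#' @param flagged `gene_set` or character vector of flagged genes.
#' @return List of class `burden_result` with `per_decile` (decile,
#'   n_genes, n_flagged, fraction_flagged), `anova_F`, `anova_p`,
#'   `trend_chi2`, `trend_p`.
#' @export
decile_burden_test <- function(entries, flagged) {
  stopifnot(all(c("gene", "decile") %in% names(entries)))
  flagged <- as_gene_set(flagged, "flagged")
  is_flag <- as.integer(entries$gene %in% flagged$members)
  decile <- factor(entries$decile, levels = 1:10)
  n_genes <- as.integer(table(decile))
  n_flagged <- as.integer(tapply(is_flag, decile, sum, default = 0L))
  per_decile <- data.frame(
    decile = 1:10, n_genes = n_genes, n_flagged = n_flagged,
    fraction_flagged = ifelse(n_genes > 0L, n_flagged / n_genes, NA_real_)
  )
  res <- list(per_decile = per_decile, anova_F = NA_real_, anova_p = NA_real_,
              trend_chi2 = NA_real_, trend_p = NA_real_)
  if (sum(is_flag) > 0L && sum(is_flag) < length(is_flag)) {
    fit <- stats::anova(stats::aov(is_flag ~ decile))
    res$anova_F <- fit[["F value"]][1L]
    res$anova_p <- fit[["Pr(>F)"]][1L]
    keep <- n_genes > 0L
    tr <- suppressWarnings(
      stats::prop.trend.test(n_flagged[keep], n_genes[keep],
                             score = (1:10)[keep]))
    res$trend_chi2 <- unname(tr$statistic)
    res$trend_p <- tr$p.value
  } else if (sum(is_flag) == length(is_flag) && length(is_flag) > 0L) {
    # every gene flagged: no between-decile variation to test
    res$anova_F <- 0; res$anova_p <- 1
  }
  class(res) <- "burden_result"
  res
}

#' @export
print.burden_result <- function(x, ...) {
  cat("<burden_result>\n")
  print(x$per_decile, row.names = FALSE)
  cat(sprintf("ANOVA F = %.4g (p = %.3g); trend chi2 = %.4g (p = %.3g)\n",
              x$anova_F, x$anova_p, x$trend_chi2, x$trend_p))
  invisible(x)
}

#' Read a constraint table from TSV
#'
#' Columns: `gene`, and `s_het` and/or `decile`. If only `s_het` is present,
#' deciles are assigned with [assign_deciles()]; a supplied `decile` column
#' is taken as-is (override for pre-binned published tables).
#'
#' @param path TSV path with a header row.
#' @return Data frame with `gene`, `s_het` (if present), `decile`.
#' @export
read_constraint_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"gene" %in% names(df)) stop("constraint table needs a 'gene' column")
  if ("decile" %in% names(df)) {
    df$decile <- as.integer(df$decile)
    if (any(is.na(df$decile) | df$decile < 1L | df$decile > 10L))
      stop("decile column must contain integers 1..10")
    df
  } else if ("s_het" %in% names(df)) {
    assign_deciles(df)
  } else {
    stop("constraint table needs an 's_het' or 'decile' column")
  }
}
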