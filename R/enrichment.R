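#' Term over-representation for a gene set
#'
#' Flat (no ontology-graph propagation) over-representation analysis: for
#' each annotation term, the upper-tail hypergeometric probability of
#' observing at least the realized number of query hits, given the term's
#' annotated genes within the universe. Bonferroni adjustment multiplies by
#' the number of terms actually tested (those reaching `min_hits` query
#' hits), mirroring the practice of testing only represented terms. An
#' optional EASE-style mode jackknifes one hit (tests `k - 1` instead of
#' `k`), a deliberately conservative variant used by some annotation
#' servers.
#'
#' @param query `gene_set` or character vector; genes outside the universe
#'   are dropped with a warning.
#' @param annotations Named list of `gene_set`s (e.g., from [read_gmt()]);
#'   annotated genes are intersected with the universe.
#' @param universe `gene_set` or character vector. Default: all genes
#'   appearing in the annotation list.
#' @param min_hits Minimum query hits for a term to be tested (default 2).
#' @param ease Use the one-hit jackknife tail (default `FALSE`).
#' @return Data frame sorted by raw p then term id, with columns `term_id`,
#'   `term_name`, `k` (query hits), `K` (annotated in universe), `n` (query
#'   size in universe), `N` (universe size), `fold_enrichment`, `p_raw`,
#'   `p_bonferroni`, and `m_tested` as an attribute.
#' @export
enrich_terms <- function(query, annotations, universe = NULL, min_hits = 2L,
                         ease = FALSE) {
  if (inherits(annotations, "gene_set")) annotations <- list(annotations)
  if (!length(annotations)) stop("empty annotation list")
  if (min_hits < 1L) stop("min_hits must be >= 1")
  if (is.null(universe))
    universe <- union_sets(annotations, label = "annotation_universe")
  universe <- as_gene_set(universe, "universe")
  N <- length(universe$members)
  if (N == 0L) stop("empty universe")
  query <- as_gene_set(query, "query")
  outside <- setdiff(query$members, universe$members)
  if (length(outside))
    warning(length(outside), " query gene(s) outside the universe dropped",
            call. = FALSE)
  q <- intersect(query$members, universe$members)
  n <- length(q)

  rows <- lapply(annotations, function(term) {
    ann <- intersect(term$members, universe$members)
    K <- length(ann)
    k <- length(intersect(q, ann))
    data.frame(term_id = term$label, term_name = term$label, k = k, K = K,
               n = n, N = N, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res <- res[res$k >= min_hits & res$K > 0L, , drop = FALSE]
  m_tested <- nrow(res)
  if (m_tested == 0L) {
    res$fold_enrichment <- numeric(0)
    res$p_raw <- numeric(0)
    res$p_bonferroni <- numeric(0)
    attr(res, "m_tested") <- 0L
    return(res)
  }
  res$fold_enrichment <- (res$k / res$n) / (res$K / res$N)
  k_eff <- if (ease) pmax(res$k - 1L, 0L) else res$k
  res$p_raw <- stats::phyper(k_eff - 1L, res$K, res$N - res$K, res$n,
                             lower.tail = FALSE)
  res$p_bonferroni <- pmin(1, res$p_raw * m_tested)
  res <- res[order(res$p_raw, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "m_tested") <- m_tested
  res
}

#' Write enrichment results as TSV
#' @param results Data frame from [enrich_terms()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
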