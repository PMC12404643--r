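# Shared fixtures and independent oracles, built in code at test time.

# brute-force upper-tail hypergeometric: enumerate every draw of n from a
# universe of N genes of which the first K are successes, count overlaps >= k
hyper_tail_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

toy_catalog <- function() {
  symbol_catalog(data.frame(
    symbol = c("TP53", "GATA4", "NKX2-5", "TBX5", "OLDA", "NEWA",
               "PREV1", "CUR1", "DEAD1"),
    approved_symbol = c("TP53", "GATA4", "NKX2-5", "TBX5", "NEWA", "NEWA",
                        "CUR1", "CUR1", "DEAD1"),
    status = c("approved", "approved", "approved", "approved", "alias",
               "approved", "previous", "approved", "withdrawn"),
    stringsAsFactors = FALSE))
}

# small scored edge file on disk in the 0-1000 integer dialect
write_edge_file <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

triangle_network <- function(categories = NULL) {
  store <- edge_store(data.frame(
    protein1 = c("A", "B", "C"), protein2 = c("B", "C", "A"),
    combined_score = c(0.9, 0.8, 0.95)))
  induce_network(c("A", "B", "C"), store, categories)
}

# ER background plus a planted clique, in one edge store; scores sit above
# the 0.7 threshold so the store keeps everything
planted_clique_store <- function(n_background = 100, clique = 10,
                                 p_background = 0.02, seed = 11) {
  set.seed(seed)
  prot <- sprintf("P%03d", seq_len(n_background))
  cl <- t(utils::combn(prot[seq_len(clique)], 2))
  g <- igraph::sample_gnp(n_background, p_background)
  bg <- matrix(prot[igraph::as_edgelist(g)], ncol = 2)
  edges <- unique(rbind(cl, bg))
  edge_store(data.frame(protein1 = edges[, 1], protein2 = edges[, 2],
                        combined_score = 0.9, stringsAsFactors = FALSE))
}

run_bundle_pipeline <- function(bundle, n_perm = NULL) {
  entries <- assign_deciles(bundle$constraint)
  cand <- intersect_sets(select_top_deciles(entries, 2),
                         union_sets(bundle$expression_sets))
  cats <- categorize(cand, bundle$known)
  store <- edge_store(bundle$edge_table, bundle$config$score_threshold)
  network <- induce_network(union_sets(list(cand, bundle$known)), store, cats)
  out <- list(candidates = cand, categories = cats, network = network,
              cluster_scores = score_clusters(bundle$clusters, network))
  if (!is.null(n_perm))
    out$ppi <- ppi_enrichment_p(network, store, n_perm = n_perm,
                                seed = bundle$seed)
  out
}
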