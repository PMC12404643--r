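test_that("edge loader handles both score dialects and the inclusive cut", {
  p <- write_edge_file(data.frame(protein1 = c("A", "A"),
                                  protein2 = c("B", "C"),
                                  combined_score = c(700L, 699L)))
  store <- load_edge_table(p, 0.7)
  expect_equal(nrow(store$edges), 1L)
  expect_equal(store$edges$protein_a, "A")
  expect_equal(store$edges$protein_b, "B")
  expect_equal(store$edges$combined_score, 0.7)
  # proteins below threshold stay in the protein universe
  expect_setequal(store$proteins, c("A", "B", "C"))

  # real-valued dialect
  p2 <- write_edge_file(data.frame(protein1 = "A", protein2 = "B",
                                   combined_score = 0.9))
  expect_equal(load_edge_table(p2, 0.7)$edges$combined_score, 0.9)

  # symmetric duplicates collapse onto one undirected edge
  s <- edge_store(data.frame(protein1 = c("A", "B"), protein2 = c("B", "A"),
                             combined_score = c(0.9, 0.9)))
  expect_equal(nrow(s$edges), 1L)

  expect_warning(
    s2 <- edge_store(data.frame(protein1 = "A", protein2 = "A",
                                combined_score = 0.95)),
    "self-loop")
  expect_equal(nrow(s2$edges), 0L)

  expect_error(edge_store(data.frame(protein1 = "A", protein2 = "B",
                                     combined_score = "high")), "malformed")
  expect_error(edge_store(data.frame(protein1 = "A", protein2 = "B",
                                     combined_score = 1500)), "dialect")
})

test_that("network induction restricts edges to the query and hides isolates", {
  store <- edge_store(data.frame(protein1 = "A", protein2 = "B",
                                 combined_score = 0.9))
  nw <- induce_network(c("A", "B", "C"), store, hide_disconnected = TRUE)
  expect_setequal(network_nodes(nw), c("A", "B"))
  nw2 <- induce_network(c("A", "B", "C"), store, hide_disconnected = FALSE)
  expect_setequal(network_nodes(nw2), c("A", "B", "C"))

  expect_warning(empty <- induce_network(c("X", "Y"), store), "empty")
  expect_equal(length(network_nodes(empty)), 0L)

  cats <- categorize("A", "B")
  nw3 <- induce_network(c("A", "B", "C"), store, cats,
                        hide_disconnected = FALSE)
  expect_equal(unname(network_categories(nw3)[c("A", "B", "C")]),
               c("candidate_only", "known_only", "neighbor"))
})

test_that("degree histogram counts nodes and satisfies the handshake lemma", {
  tri <- triangle_network()
  expect_equal(degree_histogram(tri), setNames(3L, "2"))

  store <- edge_store(data.frame(protein1 = "A", protein2 = "B",
                                 combined_score = 0.9))
  nw <- induce_network(c("A", "B", "C"), store)
  expect_equal(degree_histogram(nw), setNames(2L, "1"))

  expect_equal(length(degree_histogram(
    suppressWarnings(induce_network("Z", store)))), 0L)

  set.seed(17)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    g <- igraph::sample_gnp(n, 0.2)
    el <- igraph::as_edgelist(g)
    if (nrow(el) == 0) next
    prot <- sprintf("P%02d", 1:n)
    st <- edge_store(data.frame(protein1 = prot[el[, 1]],
                                protein2 = prot[el[, 2]],
                                combined_score = 0.9))
    nw <- induce_network(prot, st)
    d <- degree_histogram(nw)
    expect_equal(sum(as.integer(d)), length(network_nodes(nw)))
    expect_equal(sum(as.integer(names(d)) * as.integer(d)),
                 2L * igraph::ecount(nw$graph))
  }
})

test_that("raising the confidence threshold never grows the network", {
  set.seed(23)
  n <- 60
  g <- igraph::sample_gnp(n, 0.15)
  el <- igraph::as_edgelist(g)
  prot <- sprintf("P%02d", 1:n)
  df <- data.frame(protein1 = prot[el[, 1]], protein2 = prot[el[, 2]],
                   combined_score = round(runif(nrow(el)), 3))
  prev_nodes <- Inf; prev_edges <- Inf
  for (thr in seq(0, 0.9, by = 0.1)) {
    st <- edge_store(df, score_threshold = thr)
    nw <- suppressWarnings(induce_network(prot, st))
    expect_lte(igraph::ecount(nw$graph), prev_edges)
    expect_lte(length(network_nodes(nw)), prev_nodes)
    prev_edges <- igraph::ecount(nw$graph)
    prev_nodes <- length(network_nodes(nw))
  }
})

test_that("permutation enrichment is deterministic, bounded and degenerate-safe", {
  store <- planted_clique_store()
  nw <- induce_network(sprintf("P%03d", 1:10), store)
  r1 <- ppi_enrichment_p(nw, store, n_perm = 199, seed = 5)
  r2 <- ppi_enrichment_p(nw, store, n_perm = 199, seed = 5)
  expect_identical(r1, r2)
  expect_gte(r1$p_perm, 1 / 200)

  # network spanning the whole background reproduces itself in every draw
  all_nw <- suppressWarnings(induce_network(store$proteins, store,
                                            hide_disconnected = FALSE))
  r_all <- ppi_enrichment_p(all_nw, store, n_perm = 100, seed = 1)
  expect_equal(r_all$p_perm, 1)

  # an edgeless observed network can never beat the null
  sparse <- suppressWarnings(
    induce_network(c("P001", "P050"), store, hide_disconnected = FALSE))
  if (igraph::ecount(sparse$graph) == 0) {
    r0 <- ppi_enrichment_p(sparse, store, n_perm = 100, seed = 2)
    expect_equal(r0$p_perm, 1)
  }

  expect_error(ppi_enrichment_p(nw, store, n_perm = 10, seed = 1),
               "at least 100")
})

test_that("a planted clique in a sparse background attains the floor p-value", {
  store <- planted_clique_store(n_background = 100, clique = 10,
                                p_background = 0.02, seed = 11)
  clique <- sprintf("P%03d", 1:10)
  nw <- induce_network(clique, store)
  expect_gte(igraph::ecount(nw$graph), 45)  # the clique's own edges
  r <- ppi_enrichment_p(nw, store, n_perm = 999, seed = 7)
  # no uniform draw of 10 proteins from 100 can reproduce 45 induced edges
  # in a background this sparse, so the add-one estimator sits at its floor
  expect_equal(r$p_perm, 1 / 1000)
  expect_lt(r$null_mean, 5)

  # the degree-binned null resamples from the high-degree bin, which in
  # this background is the clique itself, so it deliberately absorbs the
  # degree-driven part of the signal: p is valid but never below the
  # uniform null's p
  rb <- ppi_enrichment_p(nw, store, n_perm = 199, seed = 7,
                         degree_binned = TRUE)
  expect_gte(rb$p_perm, 1 / 200)
  expect_lte(rb$p_perm, 1)
  expect_gte(rb$null_mean, r$null_mean)
})

test_that("null permutation p-values are approximately uniform", {
  # a reasonably dense background keeps the induced edge count away from
  # small-count discreteness, where the add-one estimator is visibly
  # super-uniform by construction
  set.seed(99)
  n <- 200
  g <- igraph::sample_gnp(n, 0.15)
  el <- igraph::as_edgelist(g)
  prot <- sprintf("P%03d", 1:n)
  store <- edge_store(data.frame(protein1 = prot[el[, 1]],
                                 protein2 = prot[el[, 2]],
                                 combined_score = 0.9))
  pvals <- vapply(1:200, function(i) {
    q <- sample(prot, 30)
    nw <- suppressWarnings(induce_network(q, store,
                                          hide_disconnected = FALSE))
    ppi_enrichment_p(nw, store, n_perm = 199, seed = i)$p_perm
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})
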