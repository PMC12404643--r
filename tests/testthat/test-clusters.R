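make_category_network <- function(edges_df, cats) {
  induce_network(names(cats), edge_store(edges_df), cats,
                 hide_disconnected = FALSE)
}

test_that("cluster scoring ranks by novel fraction, then count, then id", {
  cats <- categorize(c("a1", "a2", "a3", "a4"), c("k1", "k2"))
  edges <- data.frame(
    protein1 = c("a1", "a3", "k1"), protein2 = c("a2", "a4", "k2"),
    combined_score = 0.9)
  nw <- make_category_network(edges, cats)
  clusters <- data.frame(
    cluster_id = c("CQ", "CP"),
    name = c("mostly_known", "all_novel"),
    members = I(list(c("k1", "k2", "a4"), c("a1", "a2", "a3"))))
  cs <- score_clusters(clusters, nw)
  expect_equal(cs$cluster_id, c("CP", "CQ"))
  expect_equal(cs$frac_novel, c(1, 1 / 3))
  expect_equal(cs$n_known, c(0L, 2L))

  # identical fractions: more novel members wins
  cats2 <- categorize(sprintf("a%d", 1:6), sprintf("k%d", 1:6))
  edges2 <- data.frame(protein1 = "a1", protein2 = "a2",
                       combined_score = 0.9)
  nw2 <- make_category_network(edges2, cats2)
  cl2 <- data.frame(
    cluster_id = c("C2", "C1"),
    name = c("small", "large"),
    members = I(list(c("a1", "a2", "k1", "k2"),
                     c("a3", "a4", "a5", "a6", "k3", "k4", "k5", "k6"))))
  cs2 <- score_clusters(cl2, nw2)
  expect_equal(cs2$frac_novel, c(0.5, 0.5))
  expect_equal(cs2$cluster_id, c("C1", "C2"))  # 4 novel beats 2 novel
  expect_equal(cs2$rank_by_count, c(1L, 2L))

  expect_error(score_clusters(clusters[0, ], nw), "empty")
})

test_that("cluster scoring drops out-of-network clusters and ignores input order", {
  cats <- categorize(c("a1", "a2"), "k1")
  nw <- make_category_network(
    data.frame(protein1 = c("a1", "a2"), protein2 = c("a2", "k1"),
               combined_score = 0.9), cats)
  clusters <- data.frame(
    cluster_id = c("C1", "C2", "C3"),
    name = c("x", "ghost", "y"),
    members = I(list(c("a1", "a2"), c("zz1", "zz2"), c("k1", "a1"))))
  expect_warning(cs <- score_clusters(clusters, nw), "dropped")
  expect_setequal(cs$cluster_id, c("C1", "C3"))
  for (i in 1:5) {
    perm <- clusters[sample(nrow(clusters)), ]
    cs_p <- suppressWarnings(score_clusters(perm, nw))
    expect_equal(cs_p$cluster_id, cs$cluster_id)
    expect_equal(cs_p$frac_novel, cs$frac_novel)
  }
})

test_that("an isolated extra node never reorders cluster scores", {
  cats <- categorize(c("a1", "a2", "a3"), c("k1", "k2"))
  edges <- data.frame(protein1 = c("a1", "a2", "k1"),
                      protein2 = c("a2", "a3", "k2"),
                      combined_score = 0.9)
  clusters <- data.frame(
    cluster_id = c("C1", "C2"), name = c("n1", "n2"),
    members = I(list(c("a1", "a2", "k1"), c("a3", "k2"))))
  nw <- make_category_network(edges, cats)
  cs <- score_clusters(clusters, nw)
  cats_plus <- categorize(c("a1", "a2", "a3", "lone"), c("k1", "k2"))
  nw_plus <- make_category_network(edges, cats_plus)
  cs_plus <- score_clusters(clusters, nw_plus)
  expect_equal(cs_plus$cluster_id, cs$cluster_id)
  expect_equal(cs_plus$frac_novel, cs$frac_novel)
})

test_that("scoring against a bare category assignment uses the query universe", {
  cats <- categorize(c("a1", "a2", "a3"), c("k1", "k2"))
  clusters <- data.frame(
    cluster_id = c("C1", "C2"), name = c("n1", "n2"),
    members = I(list(c("a1", "a2", "outsider"), c("k1", "k2", "a3"))))
  cs <- score_clusters(clusters, cats)
  expect_equal(cs$cluster_id, c("C1", "C2"))
  expect_equal(cs$n_in_network, c(2L, 3L))
  expect_equal(cs$frac_novel, c(1, 1 / 3))
})

test_that("subnetwork extraction takes the induced first-neighbor subgraph", {
  # path A-B-C-D seeded at A keeps only A-B
  path_store <- edge_store(data.frame(
    protein1 = c("A", "B", "C"), protein2 = c("B", "C", "D"),
    combined_score = 0.9))
  nw <- induce_network(c("A", "B", "C", "D"), path_store)
  sub <- extract_subnetwork(nw, "A")
  expect_setequal(network_nodes(sub), c("A", "B"))
  expect_equal(igraph::ecount(sub$graph), 1L)

  # triangle seeded at A keeps the neighbor-neighbor edge B-C
  tri <- triangle_network()
  sub_tri <- extract_subnetwork(tri, "A")
  expect_setequal(network_nodes(sub_tri), c("A", "B", "C"))
  expect_equal(igraph::ecount(sub_tri$graph), 3L)

  expect_warning(extract_subnetwork(nw, c("A", "ZZZ")), "dropped")
  sub2 <- suppressWarnings(extract_subnetwork(nw, c("A", "ZZZ")))
  expect_setequal(network_nodes(sub2), c("A", "B"))
  suppressWarnings(expect_error(extract_subnetwork(nw, "ZZZ"), "no seed"))
})

test_that("subnetworks are contained in the parent and anchored on seeds", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(15:40, 1)
    g <- igraph::sample_gnp(n, 0.15)
    el <- igraph::as_edgelist(g)
    if (nrow(el) == 0) next
    prot <- sprintf("P%02d", 1:n)
    st <- edge_store(data.frame(protein1 = prot[el[, 1]],
                                protein2 = prot[el[, 2]],
                                combined_score = 0.9))
    nw <- induce_network(prot, st)
    seeds <- sample(network_nodes(nw), min(3, length(network_nodes(nw))))
    sub <- extract_subnetwork(nw, seeds)
    sub_edges <- igraph::as_data_frame(sub$graph, what = "edges")
    par_edges <- igraph::as_data_frame(nw$graph, what = "edges")
    key <- function(df) paste(pmin(df$from, df$to), pmax(df$from, df$to))
    expect_true(all(key(sub_edges) %in% key(par_edges)))
    for (v in network_nodes(sub)) {
      ok <- v %in% seeds ||
        any(seeds %in% names(igraph::neighbors(nw$graph, v)))
      expect_true(ok)
    }
  }
})

test_that("cluster tables round-trip through the TSV reader", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("cluster_id\tname\tmembers",
               "CL1\tproteasome assembly\tPOMP,PSMA6, PSMD3",
               "CL2\tother\tNF1"), p)
  cl <- read_cluster_table(p)
  expect_equal(cl$members[[1]], c("POMP", "PSMA6", "PSMD3"))
  expect_equal(cl$cluster_id, c("CL1", "CL2"))
  writeLines(c("cluster_id\tname\tmembers", "CL1\tx\tA", "CL1\ty\tB"), p)
  expect_error(read_cluster_table(p), "duplicate")
})
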