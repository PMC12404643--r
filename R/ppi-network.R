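#' Load a scored protein-protein interaction edge table
#'
#' Reads a STRING `protein.links`-style flat file: whitespace- or
#' tab-separated with a header, columns `protein1`, `protein2`,
#' `combined_score` (extra columns such as per-evidence-channel scores are
#' carried along untouched). Two score dialects are accepted: integers on
#' 0–1000 (divided by 1000) and reals on 0–1; the dialect is inferred from
#' the score range. Edges at or above the confidence threshold are retained
#' (inclusive, matching the "minimum required interaction score" semantics),
#' symmetric duplicates are collapsed onto a single undirected edge keeping
#' the larger score, and self-loops are dropped with a warning.
#'
#' @param path Path to the edge file.
#' @param score_threshold Minimum combined score to keep, on the 0–1 scale
#'   (default 0.7, the conventional "high confidence" cut).
#' @return An object of class `edge_store`: list with `edges` (data frame
#'   `protein_a`, `protein_b`, `combined_score`, endpoints ordered
#'   `protein_a < protein_b`), `proteins` (every protein seen in the file,
#'   including those whose edges fell below threshold) and `threshold`.
#' @export
load_edge_table <- function(path, score_threshold = 0.7) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  edge_store(df, score_threshold = score_threshold, source = path)
}

#' Build an edge store from a data frame of scored interactions
#'
#' The in-memory counterpart of [load_edge_table()]; same dialect rules.
#'
#' @param df Data frame with columns `protein1`, `protein2`,
#'   `combined_score` (or `protein_a`/`protein_b`).
#' @param score_threshold Minimum combined score (0–1 scale), inclusive.
#' @param source Provenance string stored on the result.
#' @return An `edge_store`.
#' @export
edge_store <- function(df, score_threshold = 0.7, source = "data.frame") {
  nm <- names(df)
  a_col <- intersect(c("protein1", "protein_a"), nm)[1L]
  b_col <- intersect(c("protein2", "protein_b"), nm)[1L]
  if (is.na(a_col) || is.na(b_col) || !"combined_score" %in% nm)
    stop("edge table needs columns protein1, protein2, combined_score")
  a <- as.character(df[[a_col]]); b <- as.character(df[[b_col]])
  score <- suppressWarnings(as.numeric(df$combined_score))
  bad <- which(is.na(score) | !nzchar(a) | !nzchar(b))
  if (length(bad))
    stop("malformed edge row(s) at line(s): ",
         paste(utils::head(bad + 1L, 5L), collapse = ", "))
  if (any(score < 0) || any(score > 1000))
    stop("unknown score dialect: combined_score outside [0, 1000]")
  if (any(score > 1)) {
    if (any(score != round(score)))
      stop("unknown score dialect: scores > 1 must be 0-1000 integers")
    score <- score / 1000
  }
  loops <- a == b
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped", call. = FALSE)
    a <- a[!loops]; b <- b[!loops]; score <- score[!loops]
  }
  proteins <- sort(unique(c(a, b)))
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  keep <- score >= score_threshold
  a <- a[keep]; b <- b[keep]; score <- score[keep]
  # collapse symmetric duplicates, keeping the larger score
  key <- paste(a, b, sep = "\r")
  ord <- order(key, -score)
  first <- !duplicated(key[ord])
  edges <- data.frame(protein_a = a[ord][first], protein_b = b[ord][first],
                      combined_score = score[ord][first],
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, proteins = proteins,
                 threshold = score_threshold, source = source),
            class = "edge_store")
}

#' @export
print.edge_store <- function(x, ...) {
  cat(sprintf("<edge_store> %d edges >= %.3g over %d proteins (%s)\n",
              nrow(x$edges), x$threshold, length(x$proteins), x$source))
  invisible(x)
}

#' Induce the interaction network over a query gene list
#'
#' Keeps every edge of the store whose two endpoints are both in the query,
#' attaches the candidate/known category of each node, and (by default)
#' hides nodes left without any connection — the network construction used
#' to relate candidate disease genes to known ones.
#'
#' @param query `gene_set` or character vector of gene symbols.
#' @param edges An `edge_store` (already thresholded at load time).
#' @param categories Optional `category_assignment` from [categorize()];
#'   query genes absent from it are labeled `"neighbor"`.
#' @param hide_disconnected Drop zero-degree nodes (default `TRUE`).
#' @return An object of class `ppi_network` wrapping an undirected
#'   [igraph][igraph::igraph-package] graph with vertex attribute
#'   `category` and edge attribute `combined_score`.
#' @export
induce_network <- function(query, edges, categories = NULL,
                           hide_disconnected = TRUE) {
  stopifnot(inherits(edges, "edge_store"))
  query <- as_gene_set(query, "query")
  nodes <- query$members
  e <- edges$edges
  keep <- e$protein_a %in% nodes & e$protein_b %in% nodes
  e <- e[keep, , drop = FALSE]
  if (hide_disconnected) nodes <- sort(unique(c(e$protein_a, e$protein_b)))
  if (!length(nodes))
    warning("induced network is empty", call. = FALSE)
  g <- igraph::graph_from_data_frame(
    e[, c("protein_a", "protein_b", "combined_score")],
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  cat_of <- rep("neighbor", length(nodes))
  if (!is.null(categories)) {
    hit <- nodes %in% names(categories)
    cat_of[hit] <- unname(categories[nodes[hit]])
  }
  igraph::V(g)$category <- cat_of
  structure(list(graph = g, threshold = edges$threshold,
                 hide_disconnected = hide_disconnected),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  g <- x$graph
  cat(sprintf("<ppi_network> %d nodes, %d edges (threshold %.3g)\n",
              igraph::vcount(g), igraph::ecount(g), x$threshold))
  tab <- table(igraph::V(g)$category)
  if (length(tab))
    cat(" ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Node names of a network
#' @param network A `ppi_network`.
#' @return Character vector of node symbols.
#' @export
network_nodes <- function(network) {
  igraph::V(network$graph)$name
}

#' Node categories of a network
#' @param network A `ppi_network`.
#' @return Named character vector gene -> category.
#' @export
network_categories <- function(network) {
  stats::setNames(igraph::V(network$graph)$category,
                  igraph::V(network$graph)$name)
}

#' Degree histogram of a network
#'
#' @param network A `ppi_network`.
#' @return Named integer vector: degree value -> number of nodes. The counts
#'   sum to the node count.
#' @export
degree_histogram <- function(network) {
  d <- igraph::degree(network$graph)
  if (!length(d)) return(stats::setNames(integer(0), character(0)))
  tab <- table(d)
  stats::setNames(as.integer(tab), names(tab))
}

#' Permutation test for interaction enrichment
#'
#' Monte-Carlo analogue of a PPI enrichment P value: how often does a
#' uniformly drawn protein set of the same size induce at least as many
#' edges in the background interactome as the observed network? The
#' add-one estimator `p = (1 + #{null >= observed}) / (n_perm + 1)` is
#' used, so the attainable minimum is `1/(n_perm + 1)`. The default null
#' draws proteins uniformly (degree-naive); `degree_binned = TRUE` instead
#' samples within background degree-quantile bins matched to the query, as
#' a sensitivity analysis for degree-driven inflation.
#'
#' @param network A `ppi_network`.
#' @param background An `edge_store` giving the background interactome and
#'   protein universe (edges below the network's threshold are ignored).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed; results are bit-identical for equal seeds.
#' @param degree_binned Use degree-matched sampling (default `FALSE`).
#' @param n_bins Number of degree bins when `degree_binned`.
#' @return List with `observed_edges`, `null_mean`, `p_perm`, `n_perm`.
#' @export
ppi_enrichment_p <- function(network, background, n_perm = 999, seed = 1L,
                             degree_binned = FALSE, n_bins = 5L) {
  stopifnot(inherits(network, "ppi_network"), inherits(background, "edge_store"))
  if (n_perm < 100L) stop("n_perm must be at least 100")
  nodes <- network_nodes(network)
  prot <- background$proteins
  if (length(nodes) > length(prot))
    stop("background protein universe smaller than the network node set")
  e <- background$edges
  e <- e[e$combined_score >= network$threshold, , drop = FALSE]
  ai <- match(e$protein_a, prot); bi <- match(e$protein_b, prot)
  observed <- igraph::ecount(network$graph)
  n <- length(nodes); N <- length(prot)

  draw_uniform <- function() sample.int(N, n)
  if (degree_binned) {
    deg <- integer(N)
    dt <- table(c(ai, bi))
    deg[as.integer(names(dt))] <- as.integer(dt)
    brk <- unique(stats::quantile(deg, probs = seq(0, 1, length.out = n_bins + 1L)))
    bin <- cut(deg, breaks = brk, include.lowest = TRUE, labels = FALSE)
    q_deg <- deg[match(nodes, prot)]
    q_deg[is.na(q_deg)] <- 0L
    q_bin <- cut(q_deg, breaks = brk, include.lowest = TRUE, labels = FALSE)
    q_bin[is.na(q_bin)] <- 1L
    need <- table(factor(q_bin, levels = seq_along(brk[-1L])))
    pool <- split(seq_len(N), factor(bin, levels = seq_along(brk[-1L])))
    draw <- function() {
      unlist(lapply(seq_along(need), function(i) {
        ni <- need[[i]]
        if (ni == 0L) return(integer(0))
        p <- pool[[i]]
        if (length(p) >= ni) p[sample.int(length(p), ni)]
        else c(p, sample(setdiff(seq_len(N), p), ni - length(p)))
      }), use.names = FALSE)
    }
  } else {
    draw <- draw_uniform
  }

  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  null_counts <- withr_seed({
    vapply(seq_len(n_perm), function(i) {
      sel <- logical(N)
      sel[draw()] <- TRUE
      sum(sel[ai] & sel[bi])
    }, integer(1))
  })
  list(observed_edges = observed,
       null_mean = mean(null_counts),
       p_perm = (1 + sum(null_counts >= observed)) / (n_perm + 1),
       n_perm = n_perm)
}

#' Export a network as edge-list and node-attribute TSVs
#'
#' @param network A `ppi_network`.
#' @param edge_path,node_path Output TSV paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_network <- function(network, edge_path, node_path) {
  g <- network$graph
  el <- igraph::as_data_frame(g, what = "edges")
  names(el) <- c("protein_a", "protein_b", "combined_score")
  utils::write.table(el, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nd <- data.frame(gene = igraph::V(g)$name,
                   category = igraph::V(g)$category,
                   degree = unname(igraph::degree(g)),
                   stringsAsFactors = FALSE)
  utils::write.table(nd, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(edges = edge_path, nodes = node_path))
}
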