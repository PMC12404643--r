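#' Read a functional-cluster membership table
#'
#' TSV with columns `cluster_id`, `name`, `members` (comma-separated gene
#' symbols) — the shape of a local-network-cluster annotation export.
#'
#' @param path TSV path with a header row.
#' @return Data frame with columns `cluster_id`, `name` and a list-column
#'   `members`.
#' @export
read_cluster_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("cluster_id", "name", "members")
  if (!all(need %in% names(df)))
    stop("cluster table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$cluster_id))
    stop("duplicate cluster_id in cluster table")
  df$members <- lapply(strsplit(df$members, ","), function(v) {
    v <- trimws(v); sort(unique(v[nzchar(v)]))
  })
  if (any(lengths(df$members) == 0L)) stop("cluster with no members")
  df[, need]
}

#' Score functional clusters for novel-candidate richness
#'
#' Restricts each cluster to the members actually present as network nodes,
#' counts how many are novel (category `candidate_only`) versus known
#' (`known_only` or `both`), and ranks clusters by novel fraction first and
#' novel count second (both descending; ties broken by `cluster_id`
#' ascending) — the criterion that surfaces the cluster richest in
#' candidate, but unproven, disease genes. The alternative count-first
#' ordering is exported in `rank_by_count` so it can be audited.
#'
#' @param clusters Data frame from [read_cluster_table()] (or with the same
#'   columns; `members` may be a list-column or comma-separated strings).
#' @param network A `ppi_network` with categorized nodes, or — when no
#'   interactome is available — a `category_assignment` from
#'   [categorize()], in which case "in the network" means "in the
#'   categorized query universe".
#' @return Data frame of class `cluster_scores`, ranked, with columns
#'   `cluster_id`, `name`, `n_in_network`, `n_novel`, `frac_novel`,
#'   `n_known`, `rank`, `rank_by_count`, and list-column
#'   `members_in_network`. Clusters with no member in the network are
#'   dropped with a warning.
#' @export
score_clusters <- function(clusters, network) {
  if (!nrow(clusters)) stop("empty cluster list")
  if (!is.list(clusters$members))
    clusters$members <- lapply(strsplit(as.character(clusters$members), ","),
                               trimws)
  cats <- if (inherits(network, "category_assignment"))
    stats::setNames(unclass(network), names(network))
  else network_categories(network)
  nodes <- names(cats)
  in_net <- lapply(clusters$members, function(m) sort(intersect(m, nodes)))
  n_in <- lengths(in_net)
  if (any(n_in == 0L)) {
    warning(sum(n_in == 0L),
            " cluster(s) with no member in the network dropped",
            call. = FALSE)
    keep <- n_in > 0L
    clusters <- clusters[keep, , drop = FALSE]
    in_net <- in_net[keep]; n_in <- n_in[keep]
  }
  if (!nrow(clusters)) stop("no cluster overlaps the network")
  n_novel <- vapply(in_net, function(m) sum(cats[m] == "candidate_only"),
                    integer(1))
  n_known <- vapply(in_net, function(m)
    sum(cats[m] %in% c("known_only", "both")), integer(1))
  out <- data.frame(cluster_id = clusters$cluster_id, name = clusters$name,
                    n_in_network = n_in, n_novel = n_novel,
                    frac_novel = n_novel / n_in, n_known = n_known,
                    stringsAsFactors = FALSE)
  ord <- order(-out$frac_novel, -out$n_novel, out$cluster_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  ord2 <- order(-out$n_novel, -out$frac_novel, out$cluster_id)
  out$rank_by_count <- integer(nrow(out))
  out$rank_by_count[ord2] <- seq_len(nrow(out))
  out$members_in_network <- in_net[ord]
  rownames(out) <- NULL
  class(out) <- c("cluster_scores", "data.frame")
  out
}

#' Extract the first-neighbor subnetwork around seed genes
#'
#' Takes the induced subgraph of the parent network on the seeds plus every
#' node sharing a direct connection with any seed. Because the subgraph is
#' induced, neighbor–neighbor edges are retained as well — equivalent to
#' re-entering the seed+neighbor gene list into the network builder with no
#' shell expansion. Node categories carry over.
#'
#' @param network A `ppi_network`.
#' @param seeds `gene_set` or character vector; seeds absent from the
#'   network are dropped with a warning, and an error is raised if none
#'   remains.
#' @return A `ppi_network`.
#' @export
extract_subnetwork <- function(network, seeds) {
  seeds <- as_gene_set(seeds, "seeds")
  nodes <- network_nodes(network)
  present <- intersect(seeds$members, nodes)
  missing <- setdiff(seeds$members, nodes)
  if (length(missing))
    warning(length(missing), " seed(s) not in the network dropped: ",
            paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  if (!length(present)) stop("no seed gene present in the network")
  g <- network$graph
  nbr <- unique(unlist(igraph::adjacent_vertices(g, present), use.names = FALSE))
  keep <- union(match(present, nodes), nbr)
  sub <- igraph::induced_subgraph(g, sort(keep))
  structure(list(graph = sub, threshold = network$threshold,
                 hide_disconnected = network$hide_disconnected),
            class = "ppi_network")
}
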