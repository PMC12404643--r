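#' Load a pipeline run configuration
#'
#' A run configuration names the input files and the handful of parameters
#' that matter: `top_k_deciles` (default 2), `score_threshold` (default
#' 0.7, the high-confidence interaction cut), `n_perm`, `min_hits`,
#' `universe` (`"constraint"` or `"annotation"`), `seed`, `out_dir`.
#' Accepts a YAML file path or an R list; unknown keys are rejected so
#' typos fail loudly.
#'
#' @param config YAML path or named list. Recognized input keys:
#'   `constraint`, `known_genes`, `expression`, `orthologs`, `catalog`,
#'   `dnv_cases`, `dnv_controls`, `edges`, `clusters`, `annotations`.
#' @return Named list of class `run_config` with defaults filled in.
#' @export
load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(
    constraint = NULL, known_genes = NULL, expression = NULL,
    orthologs = NULL, catalog = NULL, dnv_cases = NULL, dnv_controls = NULL,
    edges = NULL, clusters = NULL, annotations = NULL,
    top_k_deciles = 2L, score_threshold = 0.7, n_perm = 999L,
    min_hits = 2L, universe = "constraint", seed = 1L, out_dir = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (!cfg$universe %in% c("constraint", "annotation"))
    stop("universe must be 'constraint' or 'annotation'")
  if (cfg$top_k_deciles < 1L || cfg$top_k_deciles > 10L)
    stop("top_k_deciles must be in 1..10")
  for (key in c("constraint", "known_genes", "expression"))
    if (is.null(cfg[[key]]))
      stop("required input missing from config: ", key)
  for (key in c("constraint", "known_genes", "expression", "orthologs",
                "catalog", "dnv_cases", "dnv_controls", "edges", "clusters",
                "annotations")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop("input file for '", key, "' not found: ", cfg[[key]])
  }
  structure(cfg, class = "run_config")
}

read_set_file <- function(path, label) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    sets <- read_gmt(path)
    if (length(sets) == 1L) sets[[1L]] else union_sets(sets, label = label)
  } else {
    read_gene_list(path, label = label)
  }
}

maybe_normalize <- function(set, catalog, label) {
  if (is.null(catalog)) return(list(set = set, report = NULL))
  normalize_symbols(set$members, catalog, label = label)
}

#' Run the candidate-gene prioritization pipeline end to end
#'
#' Executes the stages in dependency order: symbol normalization (when a
#' catalog is supplied), decile assignment and top-decile selection,
#' ortholog mapping of the expression sets (when an ortholog table is
#' supplied), union of expression sets, intersection with the
#' high-constraint set to derive candidates, categorization against the
#' known-gene list, de novo variant decile burden tests, network
#' construction and permutation enrichment, cluster scoring, first-neighbor
#' subnetwork extraction around the top-ranked cluster, and term
#' over-representation. Stages whose optional inputs are absent are
#' recorded as `SKIPPED` rather than failing the run, so the set-algebra
#' core is runnable from gene tables alone; any stage error aborts with
#' the stage name.
#'
#' @param config A [load_run_config()] input (YAML path or list).
#' @return List of class `pipeline_result` with the per-stage objects
#'   (`candidates`, `categories`, `burden_cases`, `burden_controls`,
#'   `network`, `ppi_enrichment`, `cluster_scores`, `subnetwork`,
#'   `enrichment`, ...) and a `manifest` (stage statuses, parameters, input
#'   checksums, seed). When `out_dir` is set, all tables and
#'   `manifest.json` are written there.
#' @export
run_pipeline <- function(config) {
  cfg <- load_run_config(config)
  stages <- list()
  note_stage <- function(name, status, detail = NULL)
    stages[[name]] <<- list(status = status, detail = detail)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      note_stage(name, "FAILED", conditionMessage(e))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  res <- list(config = cfg)

  catalog <- if (!is.null(cfg$catalog))
    run_stage("catalog", read_symbol_catalog(cfg$catalog)) else NULL

  res$constraint <- run_stage("constraint", {
    tab <- read_constraint_table(cfg$constraint)
    if (!is.null(catalog)) {
      norm <- normalize_symbols(tab$gene, catalog)
      keep <- casefold_symbol(tab$gene) %in%
        casefold_symbol(catalog$table$symbol)
      tab <- tab[keep, , drop = FALSE]
      tab$gene <- unname(catalog$lookup[casefold_symbol(tab$gene)])
      tab <- tab[!duplicated(tab$gene), , drop = FALSE]
      if ("s_het" %in% names(tab) && nrow(tab) >= 10L)
        tab <- assign_deciles(tab)
    }
    note_stage("constraint", "OK", sprintf("%d genes", nrow(tab)))
    tab
  })

  res$high_constraint <- run_stage("top_deciles", {
    s <- select_top_deciles(res$constraint, cfg$top_k_deciles)
    note_stage("top_deciles", "OK", sprintf("%d genes", length(s)))
    s
  })

  res$expressed <- run_stage("expression", {
    sets <- if (grepl("\\.gmt$", cfg$expression, ignore.case = TRUE))
      unname(read_gmt(cfg$expression))
    else list(read_gene_list(cfg$expression))
    if (!is.null(cfg$orthologs)) {
      om <- read_ortholog_map(cfg$orthologs)
      sets <- lapply(sets, function(s) map_orthologs(s, om, label = s$label)$set)
    }
    u <- union_sets(sets, label = "cardiac_expressed")
    if (!is.null(catalog)) u <- normalize_symbols(u$members, catalog,
                                                 label = u$label)$set
    note_stage("expression", "OK", sprintf("%d genes", length(u)))
    u
  })

  res$known <- run_stage("known_genes", {
    k <- read_set_file(cfg$known_genes, "known_disease_genes")
    if (!is.null(catalog)) k <- normalize_symbols(k$members, catalog,
                                                  label = k$label)$set
    note_stage("known_genes", "OK", sprintf("%d genes", length(k)))
    k
  })

  res$candidates <- run_stage("candidates", {
    cand <- intersect_sets(res$high_constraint, res$expressed)
    cand$label <- "candidate_genes"
    note_stage("candidates", "OK", sprintf("%d genes", length(cand)))
    cand
  })
  res$categories <- categorize(res$candidates, res$known)
  res$overlap <- overlap_significance(res$candidates, res$known,
                                      universe_n = nrow(res$constraint))

  for (grp in c("cases", "controls")) {
    key <- paste0("dnv_", grp); stage <- paste0("burden_", grp)
    if (is.null(cfg[[key]])) { note_stage(stage, "SKIPPED", "no input") }
    else res[[stage]] <- run_stage(stage, {
      b <- decile_burden_test(res$constraint, read_gene_list(cfg[[key]]))
      note_stage(stage, "OK")
      b
    })
  }

  if (is.null(cfg$edges)) {
    note_stage("network", "SKIPPED", "no edge table")
    note_stage("ppi_enrichment", "SKIPPED", "no edge table")
  } else {
    res$edge_store <- run_stage("network",
      load_edge_table(cfg$edges, score_threshold = cfg$score_threshold))
    res$network <- run_stage("network", {
      query <- union_sets(list(res$candidates, res$known), label = "query")
      nw <- induce_network(query, res$edge_store, res$categories,
                           hide_disconnected = TRUE)
      note_stage("network", "OK",
                 sprintf("%d nodes, %d edges", igraph::vcount(nw$graph),
                         igraph::ecount(nw$graph)))
      nw
    })
    res$ppi_enrichment <- run_stage("ppi_enrichment", {
      p <- ppi_enrichment_p(res$network, res$edge_store,
                            n_perm = cfg$n_perm, seed = cfg$seed)
      note_stage("ppi_enrichment", "OK", sprintf("p = %.3g", p$p_perm))
      p
    })
  }

  if (is.null(cfg$clusters) || is.null(res$network)) {
    note_stage("clusters", "SKIPPED",
               if (is.null(cfg$clusters)) "no cluster table" else "no network")
    note_stage("subnetwork", "SKIPPED", "no cluster ranking")
  } else {
    res$cluster_scores <- run_stage("clusters", {
      cs <- score_clusters(read_cluster_table(cfg$clusters), res$network)
      note_stage("clusters", "OK", sprintf("%d clusters ranked", nrow(cs)))
      cs
    })
    res$subnetwork <- run_stage("subnetwork", {
      seeds <- res$cluster_scores$members_in_network[[1L]]
      sn <- extract_subnetwork(res$network, seeds)
      note_stage("subnetwork",
                 "OK", sprintf("%d nodes, %d edges around %s",
                               igraph::vcount(sn$graph),
                               igraph::ecount(sn$graph),
                               res$cluster_scores$cluster_id[1L]))
      sn
    })
  }

  if (is.null(cfg$annotations)) {
    note_stage("enrichment", "SKIPPED", "no annotation file")
  } else {
    res$enrichment <- run_stage("enrichment", {
      ann <- read_gmt(cfg$annotations)
      uni <- if (cfg$universe == "constraint")
        gene_set(res$constraint$gene, "constraint_universe") else NULL
      e <- enrich_terms(res$candidates, ann, universe = uni,
                        min_hits = cfg$min_hits)
      note_stage("enrichment", "OK", sprintf("%d terms tested", nrow(e)))
      e
    })
  }

  inputs <- Filter(Negate(is.null),
                   cfg[c("constraint", "known_genes", "expression",
                         "orthologs", "catalog", "dnv_cases", "dnv_controls",
                         "edges", "clusters", "annotations")])
  res$manifest <- list(
    parameters = cfg[c("top_k_deciles", "score_threshold", "n_perm",
                       "min_hits", "universe", "seed")],
    inputs = lapply(inputs, function(p) list(path = p,
                                             md5 = unname(tools::md5sum(p)))),
    stages = stages,
    n_candidates = length(res$candidates),
    n_overlap_known = res$overlap$k,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("chdnet")))
  class(res) <- "pipeline_result"
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(res, cfg$out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (nm in names(x$manifest$stages)) {
    st <- x$manifest$stages[[nm]]
    cat(sprintf("  %-15s %-8s %s\n", nm, st$status,
                if (is.null(st$detail)) "" else st$detail))
  }
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gene_list(result$candidates, file.path(dir, "candidates.txt"))
  utils::write.table(
    data.frame(gene = names(result$categories),
               category = unname(unclass(result$categories))),
    file.path(dir, "categories.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  for (grp in c("cases", "controls")) {
    b <- result[[paste0("burden_", grp)]]
    if (!is.null(b)) {
      utils::write.table(b$per_decile,
                         file.path(dir, sprintf("burden_%s_per_decile.tsv", grp)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(anova_F = b$anova_F, anova_p = b$anova_p,
                   trend_chi2 = b$trend_chi2, trend_p = b$trend_p),
        file.path(dir, sprintf("burden_%s_stats.tsv", grp)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (!is.null(result$network))
    write_network(result$network, file.path(dir, "network_edges.tsv"),
                  file.path(dir, "network_nodes.tsv"))
  if (!is.null(result$cluster_scores)) {
    cs <- result$cluster_scores
    cs$members_in_network <- vapply(cs$members_in_network, paste,
                                    character(1), collapse = ",")
    utils::write.table(cs, file.path(dir, "cluster_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$subnetwork))
    write_network(result$subnetwork, file.path(dir, "subnetwork_edges.tsv"),
                  file.path(dir, "subnetwork_nodes.tsv"))
  if (!is.null(result$enrichment))
    write_enrichment(result$enrichment, file.path(dir, "enrichment.tsv"))
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
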