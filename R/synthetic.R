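#' Configuration for the synthetic study generator
#'
#' Describes a fully in-silico analogue of the pipeline's source tables: a
#' genome of genes with heavy-tailed constraint scores, a planted disease
#' module enriched for high-constraint and cardiac-expressed genes, de novo
#' variant gene lists enriched in the module, a two-block stochastic block
#' model interactome with confidence scores, cluster annotations with one
#' planted novel-rich cluster, and term annotations with planted
#' enrichment. Defaults are the generator's study conditions; see the
#' methods vignette for the reasoning behind each value.
#'
#' @param n_genes Genome size.
#' @param n_module Planted disease-module size.
#' @param fraction_constrained Probability a background gene draws its
#'   s_het from the constrained (high) mixture component.
#' @param p_module_high_constraint Probability a module gene draws from the
#'   constrained component (approximately its chance of landing in the top
#'   two deciles).
#' @param beta_constrained Shape parameters of the Beta draw for the
#'   constrained component (rescaled above `background_max`).
#' @param background_max Upper bound of the uniform background s_het
#'   component.
#' @param n_known Size of the known-disease-gene list.
#' @param known_module_fraction Fraction of known genes drawn from the
#'   module.
#' @param expression_set_size Number of genes in the cardiac-expression
#'   union.
#' @param p_module_expressed Probability a module gene is expressed.
#' @param dnv_rate Baseline probability a gene appears in a de novo variant
#'   list.
#' @param dnv_enrichment Multiplier on `dnv_rate` for module genes in the
#'   case list (controls are flagged at baseline everywhere).
#' @param p_edge_background,p_edge_module Edge probabilities of the
#'   stochastic block model (within-module must be >= background).
#' @param p_score_above_module,p_score_above_background Probability an
#'   edge's confidence score lands at or above `score_threshold`.
#' @param score_threshold Confidence threshold the scores are drawn around.
#' @param n_clusters Total clusters including the planted one.
#' @param cluster_size_range Size range for background clusters.
#' @param planted_cluster_size,planted_cluster_novel_fraction Size and
#'   novel-candidate fraction of the planted cluster.
#' @param max_background_novel_fraction Cap on the novel fraction of
#'   background clusters.
#' @param n_terms Total annotation terms including two planted ones.
#' @param term_size_range Size range of annotation terms.
#' @param seed Integer root seed; sub-streams per output are derived from
#'   it deterministically.
#' @return Validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 1200L,
                             n_module = 40L,
                             fraction_constrained = 0.18,
                             p_module_high_constraint = 0.9,
                             beta_constrained = c(6, 2),
                             background_max = 0.15,
                             n_known = 40L,
                             known_module_fraction = 0.25,
                             expression_set_size = 400L,
                             p_module_expressed = 0.9,
                             dnv_rate = 0.05,
                             dnv_enrichment = 8,
                             p_edge_background = 0.01,
                             p_edge_module = 0.30,
                             p_score_above_module = 0.9,
                             p_score_above_background = 0.5,
                             score_threshold = 0.7,
                             n_clusters = 12L,
                             cluster_size_range = c(5L, 15L),
                             planted_cluster_size = 10L,
                             planted_cluster_novel_fraction = 0.8,
                             max_background_novel_fraction = 0.3,
                             n_terms = 20L,
                             term_size_range = c(20L, 80L),
                             seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(fraction_constrained, p_module_high_constraint,
             p_module_expressed, dnv_rate, p_edge_background, p_edge_module,
             p_score_above_module, p_score_above_background,
             planted_cluster_novel_fraction, max_background_novel_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (p_edge_module < p_edge_background)
    stop("within-module edge probability must be >= background")
  if (n_module > n_genes) stop("module larger than the genome")
  if (expression_set_size > n_genes) stop("expression set larger than genome")
  if (n_known > n_genes) stop("known list larger than genome")
  structure(cfg, class = "synthetic_config")
}

# one deterministic sub-seed per output stream, all below 2^31
derive_subseeds <- function(seed, n = 8L) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic study bundle
#'
#' Draws every input table the pipeline consumes, plus a ground-truth
#' record of the planted structure, deterministically from the config seed.
#' With `dir` set, all tables are also written in the exact file dialects
#' the package's readers accept, together with a JSON manifest carrying the
#' config, seed and per-file checksums.
#'
#' @param config A [synthetic_config()].
#' @param dir Optional output directory (created if needed).
#' @return List of class `synthetic_bundle` with elements `constraint`
#'   (data frame gene/s_het), `known`, `dnv_cases`, `dnv_controls`
#'   (`gene_set`s), `expression_sets` (list of two `gene_set`s whose union
#'   is the expression list), `edge_table` (0-1000 integer dialect data
#'   frame), `clusters` (cluster table), `terms` (list of `gene_set`s),
#'   `truth` (module genes, planted ids, per-gene latent states), `config`,
#'   and `paths` when written.
#' @export
generate_synthetic_bundle <- function(config = synthetic_config(), dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  ss <- derive_subseeds(config$seed, 8L)
  n <- config$n_genes
  genes <- sprintf("G%05d", seq_len(n))

  module <- with_seed(ss[1L], sort(sample(genes, config$n_module)))
  is_module <- genes %in% module

  # constraint scores: uniform background component + Beta constrained
  # component shifted above it, so the constrained genes fill the top deciles
  constraint <- with_seed(ss[2L], {
    p_high <- ifelse(is_module, config$p_module_high_constraint,
                     config$fraction_constrained)
    high <- stats::runif(n) < p_high
    s <- numeric(n)
    s[!high] <- stats::runif(sum(!high), 0, config$background_max)
    s[high] <- config$background_max +
      (1 - config$background_max) *
      stats::rbeta(sum(high), config$beta_constrained[1L],
                   config$beta_constrained[2L])
    list(df = data.frame(gene = genes, s_het = s, stringsAsFactors = FALSE),
         high = high)
  })

  expressed <- with_seed(ss[3L], {
    in_expr <- is_module & stats::runif(n) < config$p_module_expressed
    n_fill <- max(0L, config$expression_set_size - sum(in_expr))
    pool <- which(!in_expr & !is_module)
    in_expr[sample(pool, min(n_fill, length(pool)))] <- TRUE
    in_expr
  })
  # emit the expression list as two overlapping source sets (the pipeline
  # unions them, as with two independent transcriptome studies)
  expression_sets <- with_seed(ss[3L] + 1L, {
    ex <- genes[expressed]
    a <- sort(sample(ex, ceiling(0.7 * length(ex))))
    b <- sort(union(setdiff(ex, a), sample(a, ceiling(0.2 * length(a)))))
    list(gene_set(a, "cardiac_lineage_study_a"),
         gene_set(b, "cardiac_lineage_study_b"))
  })

  known <- with_seed(ss[4L], {
    n_from_module <- round(config$known_module_fraction * config$n_known)
    n_from_module <- min(n_from_module, config$n_module)
    k <- c(sample(module, n_from_module),
           sample(genes[!is_module], config$n_known - n_from_module))
    gene_set(k, "known_disease_genes")
  })

  dnv <- with_seed(ss[5L], {
    rate_case <- pmin(1, config$dnv_rate *
                        ifelse(is_module, config$dnv_enrichment, 1))
    list(cases = gene_set(genes[stats::runif(n) < rate_case], "dnv_cases"),
         controls = gene_set(genes[stats::runif(n) < config$dnv_rate],
                             "dnv_controls"))
  })

  edge_table <- with_seed(ss[6L], {
    g_bg <- igraph::sample_gnp(n, config$p_edge_background)
    p_extra <- (config$p_edge_module - config$p_edge_background) /
      (1 - config$p_edge_background)
    g_mod <- igraph::sample_gnp(config$n_module, p_extra)
    el_bg <- igraph::as_edgelist(g_bg)
    el_mod <- matrix(match(module, genes)[igraph::as_edgelist(g_mod)],
                     ncol = 2L)
    raw <- rbind(el_bg, el_mod)
    el <- unique(cbind(pmin(raw[, 1L], raw[, 2L]),
                       pmax(raw[, 1L], raw[, 2L])))
    both_mod <- is_module[el[, 1L]] & is_module[el[, 2L]]
    p_above <- ifelse(both_mod, config$p_score_above_module,
                      config$p_score_above_background)
    above <- stats::runif(nrow(el)) < p_above
    thr <- config$score_threshold
    score <- numeric(nrow(el))
    score[above] <- stats::runif(sum(above), thr, 0.999)
    score[!above] <- stats::runif(sum(!above), 0.15, thr - 0.01)
    data.frame(protein1 = genes[el[, 1L]], protein2 = genes[el[, 2L]],
               combined_score = as.integer(round(score * 1000)),
               stringsAsFactors = FALSE)
  })

  # latent candidate state drives cluster/term planting: a gene the
  # pipeline should recover = top-2-deciles by emitted s_het AND expressed
  entries <- assign_deciles(constraint$df)
  top2 <- select_top_deciles(entries, 2L)
  latent_candidate <- genes %in% top2$members & expressed
  novel <- genes[latent_candidate & !(genes %in% known$members)]

  clusters <- with_seed(ss[7L], {
    sz <- config$planted_cluster_size
    n_nov <- round(config$planted_cluster_novel_fraction * sz)
    nov_mod <- intersect(novel, module)
    kn_mod <- intersect(known$members, module)
    planted_nov <- sample(nov_mod, min(n_nov, length(nov_mod)))
    # fill the remaining slots with known module genes first, then other
    # non-novel module genes, so the planted novel fraction is respected
    shuffle <- function(x) x[sample.int(length(x))]
    rest_pool <- c(shuffle(setdiff(kn_mod, planted_nov)),
                   shuffle(setdiff(module, c(planted_nov, kn_mod, novel))),
                   shuffle(setdiff(module, planted_nov)))
    rest_pool <- rest_pool[!duplicated(rest_pool)]
    planted <- c(planted_nov,
                 rest_pool[seq_len(sz - length(planted_nov))])
    nonnov_pool <- setdiff(genes[!latent_candidate], module)
    nov_bg_pool <- setdiff(novel, module)
    bg <- lapply(seq_len(config$n_clusters - 1L), function(i) {
      size <- sample(seq(config$cluster_size_range[1L],
                         config$cluster_size_range[2L]), 1L)
      n_nov_i <- sample(0:floor(config$max_background_novel_fraction * size), 1L)
      n_nov_i <- min(n_nov_i, length(nov_bg_pool))
      # bias background clusters toward known genes, as in curated pathway
      # annotations dominated by well-studied disease genes
      n_known_i <- min(length(known$members), size - n_nov_i)
      c(sample(nov_bg_pool, n_nov_i),
        sample(known$members, n_known_i),
        sample(nonnov_pool, size - n_nov_i - n_known_i))
    })
    members <- c(list(sort(planted)), lapply(bg, sort))
    data.frame(
      cluster_id = sprintf("CL%04d", seq_along(members)),
      name = c("planted_module_cluster",
               sprintf("background_cluster_%d", seq_along(bg))),
      members = I(members), stringsAsFactors = FALSE)
  })

  terms <- with_seed(ss[8L], {
    planted1 <- gene_set(union(module, sample(genes, 20L)),
                         "TERM_planted_module")
    planted2 <- gene_set(union(sample(novel, min(25L, length(novel))),
                               sample(genes, 15L)),
                         "TERM_planted_novel")
    bg <- lapply(seq_len(config$n_terms - 2L), function(i) {
      size <- sample(seq(config$term_size_range[1L],
                         config$term_size_range[2L]), 1L)
      gene_set(sample(genes, size), sprintf("TERM_background_%02d", i))
    })
    all <- c(list(planted1, planted2), bg)
    stats::setNames(all, vapply(all, function(s) s$label, character(1)))
  })

  truth <- list(
    module_genes = module,
    planted_cluster_id = "CL0001",
    planted_term_ids = c("TERM_planted_module", "TERM_planted_novel"),
    states = data.frame(
      gene = genes, module = is_module, constrained = constraint$high,
      expressed = expressed, latent_candidate = latent_candidate,
      known = genes %in% known$members,
      flagged_case = genes %in% dnv$cases$members,
      flagged_control = genes %in% dnv$controls$members,
      stringsAsFactors = FALSE),
    seed = config$seed
  )

  bundle <- structure(list(
    config = config, seed = config$seed,
    constraint = constraint$df, known = known,
    expression_sets = expression_sets,
    dnv_cases = dnv$cases, dnv_controls = dnv$controls,
    edge_table = edge_table, clusters = clusters, terms = terms,
    truth = truth), class = "synthetic_bundle")

  if (!is.null(dir)) bundle$paths <- write_bundle(bundle, dir)
  bundle
}

#' Write a synthetic bundle to disk
#'
#' Emits every table in the dialect its reader expects, plus
#' `manifest.json` (config, seed, md5 checksums) and `truth.json`.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory.
#' @return Named list of file paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- list(
    constraint = file.path(dir, "constraint.tsv"),
    known = file.path(dir, "known_genes.gmt"),
    expression = file.path(dir, "expression.gmt"),
    dnv_cases = file.path(dir, "dnv_cases.txt"),
    dnv_controls = file.path(dir, "dnv_controls.txt"),
    edges = file.path(dir, "ppi_edges.tsv"),
    clusters = file.path(dir, "clusters.tsv"),
    terms = file.path(dir, "terms.gmt"),
    truth = file.path(dir, "truth.json"),
    manifest = file.path(dir, "manifest.json"))
  utils::write.table(bundle$constraint, p$constraint, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(list(bundle$known), p$known)
  write_gmt(bundle$expression_sets, p$expression)
  write_gene_list(bundle$dnv_cases, p$dnv_cases)
  write_gene_list(bundle$dnv_controls, p$dnv_controls)
  utils::write.table(bundle$edge_table, p$edges, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cl <- bundle$clusters
  cl$members <- vapply(cl$members, paste, character(1), collapse = ",")
  utils::write.table(cl, p$clusters, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gmt(bundle$terms, p$terms)
  jsonlite::write_json(bundle$truth, p$truth, auto_unbox = TRUE,
                       digits = NA)
  files <- unlist(p[setdiff(names(p), "manifest")])
  manifest <- list(config = unclass(bundle$config), seed = bundle$seed,
                   checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, digits = NA)
  invisible(p)
}

#' Recovery metrics against the planted truth
#'
#' Compares pipeline outputs with the generator's ground truth by exact set
#' comparison: recall and precision of the candidate set against the
#' planted module, the rank of the planted cluster, and the ranks of the
#' planted terms.
#'
#' @param bundle A `synthetic_bundle`.
#' @param candidates `gene_set` produced by the pipeline from this bundle.
#' @param cluster_scores Optional [score_clusters()] result.
#' @param enrichment Optional [enrich_terms()] result.
#' @param seed Optional seed the outputs were produced under; if given and
#'   different from the bundle's, an error is raised (mismatched runs must
#'   not be compared).
#' @return List with `module_recall`, `module_precision` (`NA` for an
#'   empty candidate set), `planted_cluster_rank`, `planted_term_ranks`.
#' @export
truth_report <- function(bundle, candidates, cluster_scores = NULL,
                         enrichment = NULL, seed = NULL) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  if (!is.null(seed) && seed != bundle$seed)
    stop("output seed (", seed, ") does not match bundle seed (",
         bundle$seed, ")")
  candidates <- as_gene_set(candidates, "candidates")
  module <- bundle$truth$module_genes
  hit <- intersect(candidates$members, module)
  res <- list(
    module_recall = length(hit) / length(module),
    module_precision = if (length(candidates$members))
      length(hit) / length(candidates$members) else NA_real_,
    planted_cluster_rank = NA_integer_,
    planted_term_ranks = stats::setNames(
      rep(NA_integer_, length(bundle$truth$planted_term_ids)),
      bundle$truth$planted_term_ids))
  if (!is.null(cluster_scores)) {
    i <- match(bundle$truth$planted_cluster_id, cluster_scores$cluster_id)
    if (!is.na(i)) res$planted_cluster_rank <- cluster_scores$rank[i]
  }
  if (!is.null(enrichment) && nrow(enrichment)) {
    res$planted_term_ranks[] <- match(bundle$truth$planted_term_ids,
                                      enrichment$term_id)
  }
  res
}
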