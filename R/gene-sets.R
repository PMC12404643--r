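#' Labeled gene set
#'
#' A `gene_set` is the package's basic currency: a label plus a unique,
#' sorted vector of approved gene symbols. All set algebra in the pipeline
#' (candidate derivation, overlap with known disease genes) operates on
#' these objects at the symbol level; no probabilistic matching is done.
#'
#' @param members Character vector of gene symbols. Duplicates are removed;
#'   empty strings and `NA` are dropped.
#' @param label Single string naming the set.
#' @return An object of class `gene_set`.
#' @examples
#' gene_set(c("GATA4", "TBX5", "GATA4"), label = "toy")
#' @export
gene_set <- function(members, label = "gene_set") {
  stopifnot(is.character(label), length(label) == 1L)
  members <- as.character(members)
  members <- members[!is.na(members) & nzchar(members)]
  members <- sort(unique(members))
  structure(list(label = label, members = members), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$label, length(x$members)))
  if (length(x$members)) {
    shown <- utils::head(x$members, 6L)
    cat(" ", paste(shown, collapse = ", "),
        if (length(x$members) > 6L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$members)

as_gene_set <- function(x, label = "gene_set") {
  if (inherits(x, "gene_set")) x else gene_set(x, label = label)
}

#' Intersect two gene sets
#'
#' Exact symbol-level intersection; the label records both parents.
#'
#' @param a,b `gene_set` objects (or character vectors).
#' @return A `gene_set`.
#' @examples
#' intersect_sets(gene_set(c("X", "Y", "Z")), gene_set(c("Y", "Z", "W")))
#' @export
intersect_sets <- function(a, b) {
  a <- as_gene_set(a, "a"); b <- as_gene_set(b, "b")
  gene_set(intersect(a$members, b$members),
           label = paste(a$label, b$label, sep = " & "))
}

#' Union of gene sets with duplicates removed
#'
#' @param sets List of `gene_set` objects (or character vectors).
#' @param label Label for the result.
#' @return A `gene_set`.
#' @export
union_sets <- function(sets, label = "union") {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  stopifnot(is.list(sets), length(sets) >= 1L)
  members <- unlist(lapply(sets, function(s) as_gene_set(s)$members),
                    use.names = FALSE)
  gene_set(members, label = label)
}

#' Categorize genes relative to a known-disease list
#'
#' Partitions the union of a candidate set and a known-gene set into
#' `candidate_only`, `known_only` and `both` — the three node categories
#' used to color the interaction network and to score clusters for their
#' richness in novel (candidate-only) genes.
#'
#' @param candidates,known `gene_set` objects (or character vectors).
#' @return Named character vector mapping gene to category, with class
#'   `category_assignment`.
#' @examples
#' categorize(c("A", "B", "C"), c("C", "D"))
#' @export
categorize <- function(candidates, known) {
  candidates <- as_gene_set(candidates, "candidates")
  known <- as_gene_set(known, "known")
  genes <- sort(union(candidates$members, known$members))
  cat_of <- ifelse(genes %in% candidates$members & genes %in% known$members,
                   "both",
                   ifelse(genes %in% candidates$members,
                          "candidate_only", "known_only"))
  structure(stats::setNames(cat_of, genes), class = "category_assignment")
}

#' Hypergeometric significance of a gene-set overlap
#'
#' Upper-tail probability P(K >= k) of observing at least the realized
#' overlap when `|a|` genes are drawn without replacement from a universe of
#' `universe_n` genes of which `|b|` are "successes". Reported alongside
#' overlap counts; the expected overlap under independence is
#' `|a|*|b|/universe_n`.
#'
#' @param a,b `gene_set` objects (or character vectors).
#' @param universe_n Integer universe size; must be at least `max(|a|, |b|)`.
#' @return List with `k`, `expected` and `p_hyper`.
#' @export
overlap_significance <- function(a, b, universe_n) {
  a <- as_gene_set(a, "a"); b <- as_gene_set(b, "b")
  universe_n <- as.integer(universe_n)
  na <- length(a$members); nb <- length(b$members)
  if (universe_n < na || universe_n < nb)
    stop("universe_n (", universe_n, ") smaller than one of the sets")
  k <- length(intersect(a$members, b$members))
  list(
    k = k,
    expected = na * nb / universe_n,
    p_hyper = stats::phyper(k - 1L, nb, universe_n - nb, na,
                            lower.tail = FALSE)
  )
}

# ---- GMT and plain-list I/O -------------------------------------------------

#' Read gene sets from a GMT file
#'
#' GMT: one set per line, tab-separated — name, description, then member
#' symbols. Empty member fields are ignored.
#'
#' @param path Path to a GMT file.
#' @return Named list of `gene_set` objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop("malformed GMT line (need name, description, >=1 member): ",
           substr(ln, 1L, 60L))
    gene_set(parts[-(1:2)], label = parts[[1L]])
  })
  stats::setNames(sets, vapply(sets, function(s) s$label, character(1)))
}

#' Write gene sets to a GMT file
#'
#' @param sets A `gene_set` or list of them.
#' @param path Output path.
#' @param descriptions Optional character vector of descriptions (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = "na") {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  descriptions <- rep_len(descriptions, length(sets))
  lines <- mapply(function(s, d) {
    paste(c(s$label, d, s$members), collapse = "\t")
  }, sets, descriptions)
  writeLines(lines, path)
  invisible(path)
}

#' Read a one-symbol-per-line gene list
#'
#' Blank lines and lines starting with `#` are skipped.
#'
#' @param path File path.
#' @param label Label for the resulting set (default: file base name).
#' @return A `gene_set`.
#' @export
read_gene_list <- function(path, label = NULL) {
  if (is.null(label))
    label <- sub("\\.[^.]*$", "", basename(path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  gene_set(lines, label = label)
}

#' Write a gene set as a one-symbol-per-line file
#' @param set A `gene_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(set, path) {
  writeLines(as_gene_set(set)$members, path)
  invisible(path)
}
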