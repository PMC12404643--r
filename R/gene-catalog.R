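#' Symbol catalog for gene-name normalization
#'
#' An offline snapshot of an HGNC-style nomenclature table. Every row maps a
#' symbol (approved, alias, previous or withdrawn) to its current approved
#' symbol; lookups are case-insensitive and the approved casing is the
#' canonical output form. Alias chains (alias pointing at another alias) are
#' rejected at load time so that resolution is always a single step.
#'
#' @param df Data frame with columns `symbol`, `approved_symbol`, `status`
#'   (one of approved/alias/previous/withdrawn).
#' @return An object of class `symbol_catalog`.
#' @export
symbol_catalog <- function(df) {
  need <- c("symbol", "approved_symbol", "status")
  if (!all(need %in% names(df)))
    stop("catalog needs columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  df[] <- lapply(df, as.character)
  if (any(!nzchar(df$symbol)) || any(is.na(df$symbol)))
    stop("catalog contains empty symbols")
  bad_status <- setdiff(unique(df$status),
                        c("approved", "alias", "previous", "withdrawn"))
  if (length(bad_status))
    stop("unknown status value(s): ", paste(bad_status, collapse = ", "))

  key <- casefold_symbol(df$symbol)
  if (anyDuplicated(key))
    stop("duplicate symbol entries in catalog: ",
         paste(unique(df$symbol[duplicated(key)]), collapse = ", "))

  approved <- df$approved_symbol[df$status == "approved"]
  approved_keys <- casefold_symbol(approved)
  # an approved row must resolve to itself
  self <- df$status == "approved"
  if (any(casefold_symbol(df$symbol[self]) != casefold_symbol(df$approved_symbol[self])))
    stop("approved symbols must resolve to themselves")
  # alias/previous targets must be approved symbols (no alias->alias chains)
  redir <- df$status %in% c("alias", "previous")
  miss <- !(casefold_symbol(df$approved_symbol[redir]) %in% approved_keys)
  if (any(miss))
    stop("alias/previous entries resolve to non-approved symbols (chain or ",
         "dangling): ", paste(df$symbol[redir][miss], collapse = ", "))

  structure(list(table = df,
                 lookup = stats::setNames(df$approved_symbol, key),
                 status = stats::setNames(df$status, key)),
            class = "symbol_catalog")
}

casefold_symbol <- function(x) toupper(trimws(x))

#' Read a symbol catalog from TSV
#'
#' Expected columns: `symbol`, `approved_symbol`, `status`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A `symbol_catalog`.
#' @export
read_symbol_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  symbol_catalog(df)
}

#' @export
print.symbol_catalog <- function(x, ...) {
  cat(sprintf("<symbol_catalog> %d entries (%d approved)\n",
              nrow(x$table), sum(x$table$status == "approved")))
  invisible(x)
}

#' Normalize gene symbols against a catalog
#'
#' Case-folds the input, resolves aliases and previous symbols to their
#' approved form, merges the resulting duplicates, and drops symbols absent
#' from the catalog (or withdrawn) with a warning. The accounting identity
#' `n_input = n_output + n_merged_duplicates + n_unrecognized` always holds.
#'
#' @param raw Character vector of symbols as found in a source table.
#' @param catalog A `symbol_catalog`.
#' @param label Label for the output `gene_set`.
#' @return List with `set` (a `gene_set` of approved symbols) and `report`
#'   (`n_input`, `n_output`, `n_merged_duplicates`, `n_unrecognized`,
#'   `unrecognized`).
#' @export
normalize_symbols <- function(raw, catalog, label = "normalized") {
  stopifnot(inherits(catalog, "symbol_catalog"))
  raw <- as.character(raw)
  if (!length(raw)) stop("empty input symbol list")
  key <- casefold_symbol(raw)
  hit <- key %in% names(catalog$lookup) &
    catalog$status[key] != "withdrawn"
  resolved <- unname(catalog$lookup[key[hit]])
  out <- unique(resolved)
  report <- list(
    n_input = length(raw),
    n_output = length(out),
    n_merged_duplicates = length(resolved) - length(out),
    n_unrecognized = sum(!hit),
    unrecognized = unique(raw[!hit])
  )
  if (report$n_unrecognized > 0L)
    warning(report$n_unrecognized, " symbol(s) not recognized and dropped: ",
            paste(utils::head(report$unrecognized, 5L), collapse = ", "),
            if (length(report$unrecognized) > 5L) ", ..." else "",
            call. = FALSE)
  list(set = gene_set(out, label = label), report = report)
}

#' Ortholog map between two species' symbol spaces
#'
#' One source symbol may map to several target symbols (the usual situation
#' for duplicated genes); empty target sets are not stored.
#'
#' @param df Data frame with columns `source_symbol`, `target_symbol`,
#'   one pair per row.
#' @return Object of class `ortholog_map` (a named list of character
#'   vectors keyed by case-folded source symbol).
#' @export
ortholog_map <- function(df) {
  need <- c("source_symbol", "target_symbol")
  if (!all(need %in% names(df)))
    stop("ortholog table needs columns: ", paste(need, collapse = ", "))
  df[] <- lapply(df[need], as.character)
  df <- df[nzchar(df$source_symbol) & nzchar(df$target_symbol), , drop = FALSE]
  pairs <- split(df$target_symbol, casefold_symbol(df$source_symbol))
  pairs <- lapply(pairs, function(v) sort(unique(v)))
  structure(pairs, class = "ortholog_map")
}

#' Read an ortholog table from TSV
#' @param path Path to a tab-separated file with columns `source_symbol`,
#'   `target_symbol`.
#' @return An `ortholog_map`.
#' @export
read_ortholog_map <- function(path) {
  ortholog_map(utils::read.delim(path, stringsAsFactors = FALSE,
                                 colClasses = "character"))
}

#' Map a gene set across species through an ortholog table
#'
#' Returns the union of all target symbols over the input genes. One-to-many
#' hits are all retained; genes without an entry are counted but silently
#' dropped from the mapped set.
#'
#' @param genes `gene_set` (or character vector) in the source-species
#'   symbol space.
#' @param orthologs An `ortholog_map`.
#' @param label Label for the mapped set.
#' @return List with `set` (mapped `gene_set`) and `report`
#'   (`n_unmapped`, `n_one_to_many`).
#' @export
map_orthologs <- function(genes, orthologs, label = "orthologs") {
  stopifnot(inherits(orthologs, "ortholog_map"))
  genes <- as_gene_set(genes)
  key <- casefold_symbol(genes$members)
  hits <- unclass(orthologs)[key]
  n_targets <- vapply(hits, function(v) if (is.null(v)) 0L else length(v),
                      integer(1))
  mapped <- unlist(hits[n_targets > 0L], use.names = FALSE)
  list(
    set = gene_set(mapped, label = label),
    report = list(n_unmapped = sum(n_targets == 0L),
                  n_one_to_many = sum(n_targets > 1L))
  )
}
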