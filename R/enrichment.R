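# Gene-set over-representation of differentially methylated genes.

#' Build a gene-set collection
#'
#' @param sets Named list of character vectors (set ID -> member symbols),
#'   or a tibble with columns `set_id`, `name`, `genes` (list-column).
#' @param names Optional character vector of set descriptions, parallel to
#'   `sets` when `sets` is a list.
#' @param background Gene universe; defaults to the union of all set
#'   members. Every set must be a subset of the background.
#' @return A list of class `gene_set_collection` with a tibble `sets`
#'   (`set_id`, `name`, `genes`, `size`) and a character `background`.
#' @export
gene_set_collection <- function(sets, names = NULL, background = NULL) {
  if (is.data.frame(sets)) {
    assert_columns(sets, c("set_id", "genes"), "`sets`")
    tbl <- as_tibble(sets)
    if (!"name" %in% base::names(tbl)) tbl$name <- tbl$set_id
  } else {
    if (length(sets) > 0 && is.null(base::names(sets))) {
      abort("`sets` must be named.", class = "methcall_argument_error")
    }
    tbl <- tibble(
      set_id = base::names(sets) %||% character(0),
      name = names %||% base::names(sets) %||% character(0),
      genes = unname(lapply(sets, as.character))
    )
  }
  tbl$genes <- lapply(tbl$genes, unique)
  tbl$size <- lengths(tbl$genes)
  if (any(tbl$size < 1)) {
    abort("Every gene set must have at least one member.",
      class = "methcall_argument_error"
    )
  }
  members <- unique(unlist(tbl$genes, use.names = FALSE)) %||% character(0)
  if (is.null(background)) {
    background <- members
  } else {
    background <- unique(as.character(background))
    stray <- setdiff(members, background)
    if (length(stray) > 0) {
      abort(
        sprintf(
          "%d set member(s) missing from the background (e.g. %s).",
          length(stray), stray[1]
        ),
        class = "methcall_argument_error"
      )
    }
  }
  structure(
    list(sets = tbl, background = background),
    class = "gene_set_collection"
  )
}

#' Read gene sets in GMT format
#'
#' One set per tab-separated line: ID, description, then member symbols.
#' Duplicate members within a set are collapsed; symbols are
#' case-sensitive.
#'
#' @param path Path to a GMT file (gzip accepted).
#' @param background Optional gene universe (see
#'   [gene_set_collection()]).
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path, background = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("GMT file not found: %s", path), class = "methcall_io_error")
  }
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warn(sprintf("GMT file %s is empty.", path))
    return(gene_set_collection(list(), background = background))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    abort(
      sprintf(
        "GMT line %d has %d field(s); at least 3 (ID, description, members) required.",
        short[1], lengths(fields)[short[1]]
      ),
      class = "methcall_format_error"
    )
  }
  gene_set_collection(
    sets = setNames(lapply(fields, function(f) f[-(1:2)]), vapply(fields, `[[`, "", 1)),
    names = vapply(fields, `[[`, "", 2),
    background = background
  )
}

#' Write a gene-set collection in GMT format
#'
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- purrr::pmap_chr(
    collection$sets[, c("set_id", "name", "genes")],
    function(set_id, name, genes) paste(c(set_id, name, genes), collapse = "\t")
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Gene-set over-representation analysis
#'
#' For each set, counts the query genes it contains and computes the
#' upper-tail hypergeometric probability of at least that many hits when
#' `n` genes are drawn from a background of `N` containing the set's `K`
#' members, the fold enrichment `(k/n) / (K/N)`, the list fraction
#' `k/n` as a percent, and the BH FDR across all sets tested. Testing is
#' one-sided (enrichment only). Query genes absent from the background are
#' dropped with a message.
#'
#' @param query Character vector of gene symbols (deduplicated).
#' @param collection A `gene_set_collection`.
#' @param ease If `TRUE`, apply the EASE-style penalty (one hit removed)
#'   when computing the hypergeometric tail. Off by default.
#' @return A tibble of class `enrichment_tbl`, sorted by p ascending:
#'   `set_id`, `name`, `k`, `list_fraction`, `p`, `fdr`, `fold`.
#' @export
overrepresentation <- function(query, collection, ease = FALSE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(as.character(query))
  dropped <- setdiff(query, collection$background)
  if (length(dropped) > 0) {
    rlang::inform(sprintf(
      "%d query gene(s) absent from the background were dropped.",
      length(dropped)
    ))
  }
  query <- intersect(query, collection$background)
  n <- length(query)
  if (n == 0) {
    abort("Query is empty after intersection with the background.",
      class = "methcall_argument_error"
    )
  }
  N <- length(collection$background)
  out <- collection$sets |>
    mutate(
      k = purrr::map_int(.data$genes, ~ length(intersect(query, .x))),
      k_test = if (ease) pmax(.data$k - 1L, 0L) else .data$k,
      p = phyper(.data$k_test - 1, .data$size, N - .data$size, n, lower.tail = FALSE),
      fold = (.data$k / n) / (.data$size / N),
      list_fraction = 100 * .data$k / n
    ) |>
    mutate(fdr = bh_adjust(.data$p)) |>
    arrange(.data$p) |>
    select("set_id", "name", "k", "list_fraction", "p", "fdr", "fold")
  attr(out, "query_size") <- n
  attr(out, "background_size") <- N
  class(out) <- c("enrichment_tbl", class(out))
  out
}
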