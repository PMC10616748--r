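#' Read / write GMT gene-set collections
#'
#' GMT format: one set per line, tab-separated `set_id`, `description`,
#' then members.
#'
#' @param path GMT file path
#' @return named list of character vectors with a `descriptions` attribute
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) stop("malformed GMT line(s): ", paste(bad, collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  attr(sets, "descriptions") <- stats::setNames(
    vapply(parts, `[`, character(1), 2), names(sets))
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors; an optional `descriptions`
#'   attribute supplies the second column
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(id)
    paste(c(id, desc[[id]], sets[[id]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis of a gene set collection
#'
#' Per annotation set, the upper-tail hypergeometric probability of observing
#' at least the overlap between the query and the set within the universe;
#' Benjamini-Hochberg adjustment across the tested sets. Query genes outside
#' the universe are dropped with a warning; set members outside the universe
#' are ignored. Sets outside `[min_size, max_size]` (after restriction to the
#' universe) are not tested.
#'
#' @param query_genes character vector of query symbols
#' @param annotation named list of character vectors (e.g. from [read_gmt()])
#' @param universe character vector of background genes
#' @param fdr_cutoff rows with adjusted p below this are flagged (default 0.05)
#' @param min_size,max_size set-size filters (defaults 3 and 2000)
#' @return data.frame ordered by p: `set_id`, `set_size`, `overlap`,
#'   `universe_size`, `query_size`, `p_value`, `fdr`, `significant`
#' @export
hypergeometric_enrichment <- function(query_genes, annotation, universe,
                                      fdr_cutoff = 0.05, min_size = 3,
                                      max_size = 2000) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(toupper(universe))
  q <- unique(toupper(query_genes))
  out <- setdiff(q, universe)
  if (length(out)) {
    warning(length(out), " query gene(s) outside the universe dropped")
    q <- intersect(q, universe)
  }
  if (!length(q)) stop("empty query after universe restriction")
  N <- length(universe); n <- length(q)
  rows <- lapply(names(annotation), function(id) {
    s <- intersect(unique(toupper(annotation[[id]])), universe)
    K <- length(s)
    if (K < min_size || K > max_size) return(NULL)
    k <- length(intersect(q, s))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id, set_size = K, overlap = k, universe_size = N,
               query_size = n, p_value = p, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) stop("no annotation set passed the size filters")
  rows$fdr <- stats::p.adjust(rows$p_value, method = "BH")
  rows$significant <- rows$fdr < fdr_cutoff
  rows <- rows[order(rows$p_value, rows$set_id), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Enrichment of a binary gene attribute in a query set
#'
#' Fraction of the query carrying the attribute, with a one-sided (upper
#' tail) hypergeometric p-value against the attribute's prevalence in the
#' universe. Query genes with no attribute record are treated as lacking it,
#' with a warning.
#'
#' @param query_genes character vector of query symbols
#' @param attribute either a named logical/0-1 vector over the universe or a
#'   two-column data.frame (`gene`, flag)
#' @param universe character vector of background genes
#' @return list: `n_query`, `n_with_attribute`, `fraction`,
#'   `universe_prevalence`, `p_value`
#' @export
attribute_enrichment <- function(query_genes, attribute, universe) {
  universe <- unique(toupper(universe))
  if (is.data.frame(attribute)) {
    flags <- stats::setNames(as.logical(attribute[[2]]), toupper(attribute[[1]]))
  } else {
    flags <- stats::setNames(as.logical(attribute), toupper(names(attribute)))
  }
  q <- unique(toupper(query_genes))
  q <- intersect(q, universe)
  if (!length(q)) stop("empty query after universe restriction")
  miss <- setdiff(universe, names(flags))
  if (length(intersect(q, miss)))
    warning("attribute missing for ", length(intersect(q, miss)),
            " query gene(s); treated as absent")
  has <- function(g) !is.na(flags[g]) & flags[g]
  k <- sum(has(q))
  K <- sum(has(universe))
  N <- length(universe); n <- length(q)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(n_query = n, n_with_attribute = k, fraction = k / n,
       universe_prevalence = K / N, p_value = p)
}

#' Write an enrichment table as TSV
#' @param rows data.frame from [hypergeometric_enrichment()]
#' @param path TSV path
#' @export
write_enrichment_tsv <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
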