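#' Ct matrix container
#'
#' A `ct_matrix` bundles a features x samples matrix of qPCR quantification
#' cycles (Cq) with the per-cell nondetect mask, an optional per-well
#' instrument QC-failure mask (supplied by the platform, never recomputed
#' here), and per-sample metadata.
#'
#' @param values numeric matrix, features in rows, samples in columns; rownames
#'   are miRNA identifiers, colnames are sample identifiers. Cells that are
#'   nondetects may be `NA`.
#' @param nondetect logical matrix of the same shape; `TRUE` marks a nondetect.
#'   Defaults to `is.na(values)`.
#' @param qc_flag logical matrix of the same shape; `TRUE` marks a well that
#'   failed instrument QC. Defaults to all-`FALSE`.
#' @param metadata data.frame with one row per sample; must contain a
#'   `sample_id` column matching `colnames(values)`. May be `NULL`.
#' @return an object of class `ct_matrix`.
#' @export
ct_matrix <- function(values, nondetect = NULL, qc_flag = NULL, metadata = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop("feature ids must be unique")
  if (anyDuplicated(colnames(values))) stop("sample ids must be unique")
  if (is.null(nondetect)) nondetect <- is.na(values)
  if (is.null(qc_flag)) qc_flag <- matrix(FALSE, nrow(values), ncol(values))
  stopifnot(is.logical(nondetect), is.logical(qc_flag))
  if (!all(dim(nondetect) == dim(values)) || !all(dim(qc_flag) == dim(values)))
    stop("mask shapes must match `values`")
  dimnames(nondetect) <- dimnames(values)
  dimnames(qc_flag) <- dimnames(values)
  if (any(!is.finite(values[!nondetect])))
    stop("Cq values must be finite where not masked as nondetect")
  if (!is.null(metadata)) {
    if (!"sample_id" %in% names(metadata))
      stop("metadata must have a `sample_id` column")
    if (!setequal(metadata$sample_id, colnames(values)))
      stop("metadata sample ids must match matrix columns")
    metadata <- metadata[match(colnames(values), metadata$sample_id), , drop = FALSE]
    rownames(metadata) <- NULL
  }
  structure(
    list(values = values, nondetect = nondetect, qc_flag = qc_flag,
         metadata = metadata),
    class = "ct_matrix"
  )
}

#' @export
dim.ct_matrix <- function(x) dim(x$values)

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("ct_matrix: %d features x %d samples, %.1f%% nondetect\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$nondetect)))
  invisible(x)
}

#' Feature and sample identifiers of a `ct_matrix`
#' @param x a `ct_matrix`
#' @return character vector of ids
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset a `ct_matrix` by features and/or samples
#' @param x a `ct_matrix`
#' @param i feature index (row) selector
#' @param j sample index (column) selector
#' @param ... ignored
#' @export
`[.ct_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  md <- x$metadata
  if (!is.null(md)) {
    keep <- colnames(x$values[, j, drop = FALSE])
    md <- md[match(keep, md$sample_id), , drop = FALSE]
    rownames(md) <- NULL
  }
  ct_matrix(x$values[i, j, drop = FALSE],
            x$nondetect[i, j, drop = FALSE],
            x$qc_flag[i, j, drop = FALSE],
            md)
}

#' Write / read a Ct matrix as CSV
#'
#' Rows are miRNA ids, columns sample ids; a nondetect is written as an empty
#' cell. Round-trips through [read_ct_csv()].
#'
#' @param ct a `ct_matrix`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_ct_csv <- function(ct, path) {
  vals <- ct$values
  out <- matrix("", nrow(vals), ncol(vals), dimnames = dimnames(vals))
  det <- !ct$nondetect
  out[det] <- format(vals[det], digits = 10, trim = TRUE, scientific = FALSE)
  df <- data.frame(mirna = rownames(vals), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ct_csv
#' @param metadata optional sample metadata data.frame to attach; rows for
#'   samples absent from the matrix (e.g. excluded upstream) are dropped
#' @export
read_ct_csv <- function(path, metadata = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- df[[1]]
  if (!is.null(metadata)) {
    if (!all(colnames(vals) %in% metadata$sample_id))
      stop("metadata is missing rows for some matrix columns")
    metadata <- metadata[metadata$sample_id %in% colnames(vals), , drop = FALSE]
  }
  ct_matrix(vals, metadata = metadata)
}

#' Write / read sample metadata TSV
#'
#' Columns: `sample_id`, `group` (case/control), `vitd`
#' (sufficient/insufficient), `arm`.
#' @param metadata data.frame of per-sample covariates
#' @param path TSV path
#' @export
write_metadata_tsv <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metadata_tsv
#' @export
read_metadata_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Normalize a miRNA name for matching
#'
#' Case-folds, optionally strips the `hsa-` species prefix, and preserves the
#' arm suffix (`-5p`/`-3p`). Published tables mix naming styles (e.g.
#' `miR-885` vs `hsa-miR-885-5p`); exact matching is done after this
#' normalization.
#'
#' @param x character vector of miRNA names
#' @param strip_species drop a leading `hsa-` prefix (default `TRUE`)
#' @return normalized character vector
#' @export
normalize_mirna_name <- function(x, strip_species = TRUE) {
  out <- tolower(trimws(x))
  if (strip_species) out <- sub("^hsa-", "", out)
  out
}
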