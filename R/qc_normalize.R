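#' Detection filter: mask high-Ct and QC-flagged wells
#'
#' Cells with Cq at or above `threshold` (low abundance) or with an instrument
#' QC flag become nondetects; retained values are untouched. Idempotent.
#'
#' @param ct a [ct_matrix()]
#' @param threshold Cq cutoff; cells with `Cq >= threshold` are excluded
#'   (default 30)
#' @return a `ct_matrix` with updated nondetect mask
#' @export
apply_detection_filter <- function(ct, threshold = 30) {
  stopifnot(inherits(ct, "ct_matrix"), threshold > 0)
  high <- !ct$nondetect & ct$values >= threshold
  nd <- ct$nondetect | high | ct$qc_flag
  ct_matrix(ct$values, nondetect = nd, qc_flag = ct$qc_flag,
            metadata = ct$metadata)
}

#' Haemolysis assessment by delta-Cq
#'
#' Per sample, delta-Cq = mean Cq(miR-23a wells) - mean Cq(miR-451a wells).
#' Erythrocyte lysis releases miR-451a, lowering its Cq and inflating the
#' difference. Status: `pass` below `possible_threshold`, `possible` above it,
#' `high_risk` above `high_threshold`; `indeterminate` when either reference
#' is missing or nondetected in that sample. Replicate wells of a reference
#' miRNA are averaged; a single well is its own mean.
#'
#' @param ct a [ct_matrix()]
#' @param mir23a_id,mir451a_id reference feature ids (all rows whose id
#'   matches after [normalize_mirna_name()] count as replicate wells)
#' @param possible_threshold,high_threshold delta-Cq cutoffs (defaults 5 and 7)
#' @return data.frame (`sample_id`, `delta_cq`, `status`, `exclude`) with
#'   attribute `reference_ids`; `exclude` is `TRUE` for any status other than
#'   `pass`
#' @export
hemolysis_assess <- function(ct, mir23a_id = "hsa-miR-23a",
                             mir451a_id = "hsa-miR-451a",
                             possible_threshold = 5, high_threshold = 7) {
  stopifnot(inherits(ct, "ct_matrix"))
  norm <- normalize_mirna_name(feature_ids(ct))
  i23 <- which(norm == normalize_mirna_name(mir23a_id))
  i451 <- which(norm == normalize_mirna_name(mir451a_id))
  if (!length(i23) || !length(i451))
    stop("both reference features must be present in the matrix")
  mean_ref <- function(rows, j) {
    v <- ct$values[rows, j]
    ok <- !ct$nondetect[rows, j]
    if (!any(ok)) NA_real_ else mean(v[ok])
  }
  n <- ncol(ct$values)
  dcq <- vapply(seq_len(n), function(j) {
    m23 <- mean_ref(i23, j); m451 <- mean_ref(i451, j)
    m23 - m451
  }, numeric(1))
  status <- ifelse(is.na(dcq), "indeterminate",
            ifelse(dcq > high_threshold, "high_risk",
            ifelse(dcq > possible_threshold, "possible", "pass")))
  out <- data.frame(sample_id = sample_ids(ct), delta_cq = dcq,
                    status = status, exclude = status != "pass",
                    stringsAsFactors = FALSE)
  attr(out, "reference_ids") <- c(feature_ids(ct)[i23], feature_ids(ct)[i451])
  out
}

#' Drop features with excessive missingness
#'
#' A feature is excluded when its nondetect fraction strictly exceeds
#' `max_missing_fraction` ("more than" rule: exactly at the cutoff is kept).
#'
#' @param ct a [ct_matrix()]
#' @param max_missing_fraction cutoff in `[0, 1]` (default 0.20)
#' @return the filtered `ct_matrix`, with attribute `dropped_ids`
#' @export
filter_by_missingness <- function(ct, max_missing_fraction = 0.20) {
  stopifnot(inherits(ct, "ct_matrix"),
            max_missing_fraction >= 0, max_missing_fraction <= 1)
  frac <- rowMeans(ct$nondetect)
  keep <- frac <= max_missing_fraction
  if (!any(keep))
    stop("all features exceed the missingness cutoff; nothing retained")
  out <- ct[keep, ]
  attr(out, "dropped_ids") <- feature_ids(ct)[!keep]
  out
}

#' Quantile normalization of detected Cq values
#'
#' Equalizes every sample's detected-value distribution to the mean
#' order-statistic reference. Nondetects are excluded from rank computation;
#' masks are preserved. With unequal numbers of detected values per sample the
#' reference curve is interpolated at each sample's quantile positions; ties
#' within a sample receive the average of their reference values.
#'
#' @param ct a [ct_matrix()]
#' @return a `ct_matrix` on the normalized scale
#' @export
quantile_normalize <- function(ct) {
  stopifnot(inherits(ct, "ct_matrix"))
  if (ncol(ct$values) < 2) stop("quantile normalization needs >= 2 samples")
  ndet <- colSums(!ct$nondetect)
  if (any(ndet < 2))
    stop("sample(s) with fewer than 2 detected values: ",
         paste(sample_ids(ct)[ndet < 2], collapse = ", "))
  # mean order-statistic reference on a common grid of n_ref quantiles
  n_ref <- max(ndet)
  grid <- if (n_ref == 1) 0.5 else seq(0, 1, length.out = n_ref)
  curves <- vapply(seq_len(ncol(ct$values)), function(j) {
    v <- sort(ct$values[!ct$nondetect[, j], j])
    if (length(v) == n_ref) v
    else stats::approx(seq(0, 1, length.out = length(v)), v, xout = grid)$y
  }, numeric(n_ref))
  ref <- rowMeans(curves)
  vals <- ct$values
  for (j in seq_len(ncol(vals))) {
    det <- !ct$nondetect[, j]
    v <- vals[det, j]
    k <- sum(det)
    # map each detected value's quantile position onto the reference curve
    pos <- (rank(v, ties.method = "average") - 1) / max(k - 1, 1)
    vals[det, j] <- stats::approx(grid, ref, xout = pos)$y
  }
  ct_matrix(vals, nondetect = ct$nondetect, qc_flag = ct$qc_flag,
            metadata = ct$metadata)
}

#' One-call QC chain
#'
#' Canonical order: detection filter, haemolysis-based sample exclusion,
#' missingness filter, quantile normalization. Running the chain twice equals
#' running it once.
#'
#' @param ct a [ct_matrix()]
#' @param ct_threshold,max_missing_fraction,possible_threshold,high_threshold
#'   cutoffs passed through to the individual steps
#' @param exclude_hemolysed drop samples whose haemolysis status is not `pass`
#'   (default `TRUE`)
#' @param normalize apply quantile normalization at the end (default `TRUE`)
#' @return list: `ct` (processed matrix), `hemolysis` (report), `dropped_features`,
#'   `excluded_samples`, `counts` (funnel of feature/sample counts)
#' @export
qc_pipeline <- function(ct, ct_threshold = 30, max_missing_fraction = 0.20,
                        possible_threshold = 5, high_threshold = 7,
                        exclude_hemolysed = TRUE, normalize = TRUE) {
  n0 <- nrow(ct$values); s0 <- ncol(ct$values)
  ct1 <- apply_detection_filter(ct, ct_threshold)
  hem <- hemolysis_assess(ct1, possible_threshold = possible_threshold,
                          high_threshold = high_threshold)
  excluded <- character(0)
  if (exclude_hemolysed && any(hem$exclude)) {
    excluded <- hem$sample_id[hem$exclude]
    ct1 <- ct1[, !sample_ids(ct1) %in% excluded]
  }
  ct2 <- filter_by_missingness(ct1, max_missing_fraction)
  dropped <- attr(ct2, "dropped_ids")
  ct3 <- if (normalize) quantile_normalize(ct2) else ct2
  list(ct = ct3, hemolysis = hem, dropped_features = dropped,
       excluded_samples = excluded,
       counts = c(features_in = n0, features_out = nrow(ct3$values),
                  samples_in = s0, samples_out = ncol(ct3$values)))
}
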