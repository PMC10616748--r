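#' Read a published-style miRNA signature table
#'
#' TSV with columns `mirna`, `regulation` (Upregulated/Downregulated),
#' `fold_change`, `fdr`. The package ships the 16-row shared
#' preeclampsia/vitamin-D signature under
#' `system.file("extdata", "table2_signature.tsv", package = "premodmir")`.
#'
#' @param path TSV path; defaults to the shipped signature
#' @return data.frame with an added `direction` column (up/down)
#' @export
read_signature_table <- function(path = system.file("extdata", "table2_signature.tsv",
                                                    package = "premodmir")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna", "regulation", "fold_change", "fdr")
  if (!all(need %in% names(df)))
    stop("signature table must have columns: ", paste(need, collapse = ", "))
  reg <- tolower(df$regulation)
  if (!all(reg %in% c("upregulated", "downregulated")))
    stop("regulation must be Upregulated or Downregulated")
  df$direction <- ifelse(reg == "upregulated", "up", "down")
  df
}

#' Summary statistics of a signature table
#'
#' @param sig data.frame from [read_signature_table()]
#' @return list: `n`, `n_up`, `n_down`, `pct_upregulated` (0-100 scale),
#'   `max_fold_change`, `min_fold_change`, `fold_change` (named per-miRNA
#'   vector)
#' @export
signature_table_stats <- function(sig) {
  fc <- stats::setNames(sig$fold_change, sig$mirna)
  list(n = nrow(sig), n_up = sum(sig$direction == "up"),
       n_down = sum(sig$direction == "down"),
       pct_upregulated = 100 * mean(sig$direction == "up"),
       max_fold_change = max(fc), min_fold_change = min(fc),
       fold_change = fc)
}
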