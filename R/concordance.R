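#' Microarray / qRT-PCR fold-change concordance
#'
#' Pearson correlation of log10 fold changes between the two assays, the
#' standard cross-platform validation of array calls. Tissues are pooled into
#' one correlation by default; per-tissue rows are reported alongside when a
#' tissue column is present.
#'
#' @param pairs Data frame with columns `gene_id`, `fc_array`, `fc_qpcr` and
#'   optionally `tissue`. Rows with a missing fold change in either assay are
#'   dropped (a message reports how many).
#' @param by_tissue Also report per-tissue correlations (default TRUE).
#' @return Data frame with rows `pooled` (and per tissue), columns `tissue`,
#'   `n_pairs`, `r`, `r2`. `r` is `NA` with a warning when either coordinate
#'   has zero variance or fewer than 3 pairs remain.
#' @export
concordance <- function(pairs, by_tissue = TRUE) {
  keep <- stats::complete.cases(pairs[, c("fc_array", "fc_qpcr")])
  if (any(!keep))
    message("dropping ", sum(!keep), " pair(s) with a missing fold change")
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) && any(pairs$fc_array <= 0 | pairs$fc_qpcr <= 0))
    stop("fold changes must be positive", call. = FALSE)
  one <- function(df, label) {
    n <- nrow(df)
    if (n < 3) {
      warning("fewer than 3 pairs for ", label, "; correlation undefined")
      return(data.frame(tissue = label, n_pairs = n, r = NA_real_,
                        r2 = NA_real_, stringsAsFactors = FALSE))
    }
    x <- log10(df$fc_array); y <- log10(df$fc_qpcr)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("zero variance in log10 fold changes for ", label)
      r <- NA_real_
    } else r <- stats::cor(x, y)
    data.frame(tissue = label, n_pairs = n, r = r, r2 = r^2,
               stringsAsFactors = FALSE)
  }
  out <- one(pairs, "pooled")
  if (by_tissue && "tissue" %in% names(pairs) &&
      !all(is.na(pairs$tissue))) {
    per <- lapply(sort(unique(pairs$tissue)), function(ti)
      one(pairs[pairs$tissue == ti, , drop = FALSE], ti))
    out <- rbind(out, do.call(rbind, per))
  }
  out
}
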