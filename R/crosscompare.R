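#' Venn partition of regulated genes between two species
#'
#' Splits the regulated genes of one tissue into genes regulated in the
#' tolerant species only (metal-specific), in the sensitive species only, and
#' in both (metal-common). Each common gene carries a sign category: first
#' sign the tolerant species' direction, second the sensitive species'
#' (`++`, `--`, `+-`, `-+`).
#'
#' @param de_tol,de_sen DE tables for the same tissue, computed on a shared
#'   gene universe (the genes surviving background filtering in both species).
#' @param tissue Tissue label recorded in the result.
#' @return A list of class `pb_venn`: `tissue`, `specific_tolerant`,
#'   `specific_sensitive` (character vectors), `common` (data frame `gene_id`,
#'   `sign`).
#' @export
venn_partition <- function(de_tol, de_sen, tissue) {
  unmatched <- c(setdiff(de_tol$gene_id, de_sen$gene_id),
                 setdiff(de_sen$gene_id, de_tol$gene_id))
  if (length(unmatched))
    stop("mismatched gene universes; unmatched id(s): ",
         paste(utils::head(sort(unmatched), 10), collapse = ", "),
         if (length(unmatched) > 10) ", ...", call. = FALSE)
  reg_tol <- de_tol$gene_id[de_tol$regulated]
  reg_sen <- de_sen$gene_id[de_sen$regulated]
  common_ids <- sort(intersect(reg_tol, reg_sen))
  sign_of <- function(de, ids) {
    d <- de$direction[match(ids, de$gene_id)]
    ifelse(d == "up", "+", ifelse(d == "down", "-", "?"))
  }
  common <- data.frame(gene_id = common_ids,
                       sign = paste0(sign_of(de_tol, common_ids),
                                     sign_of(de_sen, common_ids)),
                       stringsAsFactors = FALSE)
  if (nrow(common) == 0) common$sign <- character(0)
  structure(list(tissue = tissue,
                 specific_tolerant = sort(setdiff(reg_tol, reg_sen)),
                 specific_sensitive = sort(setdiff(reg_sen, reg_tol)),
                 common = common),
            class = "pb_venn")
}

#' @export
print.pb_venn <- function(x, ...) {
  cat("Venn partition (", x$tissue, "): specific tolerant ",
      length(x$specific_tolerant), ", specific sensitive ",
      length(x$specific_sensitive), ", common ", nrow(x$common), "\n",
      sep = "")
  if (nrow(x$common)) print(table(x$common$sign))
  invisible(x)
}

#' Twofold-change filter
#'
#' Retains genes whose fold change in the given DE table is above `hi`
#' (up-regulated) or below `lo` (down-regulated); strict inequalities, so
#' boundary values are discarded.
#'
#' @param genes Character vector of gene ids.
#' @param de DE table supplying the fold changes.
#' @param hi,lo Thresholds with `hi > 1 > lo > 0` (defaults 2.0 and 0.5).
#' @return List with character vectors `up` and `down`.
#' @export
fc_filter <- function(genes, de, hi = 2.0, lo = 0.5) {
  if (!(hi > 1 && lo < 1 && lo > 0))
    stop("thresholds must satisfy hi > 1 > lo > 0", call. = FALSE)
  fc <- de$fc[match(genes, de$gene_id)]
  if (anyNA(fc))
    stop("gene id(s) missing from DE table: ",
         paste(utils::head(genes[is.na(fc)], 5), collapse = ", "),
         call. = FALSE)
  list(up = sort(genes[fc > hi]), down = sort(genes[fc < lo]))
}

#' Cross-species fold-change-ratio filter
#'
#' Retains genes whose tolerant-to-sensitive fold-change ratio (linear scale)
#' exceeds `hi` or falls below `lo` — the step that demands the tolerant
#' species' response differ in magnitude from the standard (sensitive-plant)
#' response. The ratio is taken regardless of direction agreement.
#'
#' @param genes Character vector of gene ids present in both tables.
#' @param de_tol,de_sen DE tables for the two species.
#' @param hi,lo Ratio thresholds (defaults 2.0 and 0.5).
#' @return Sorted character vector of retained gene ids.
#' @export
ratio_filter <- function(genes, de_tol, de_sen, hi = 2.0, lo = 0.5) {
  if (!(hi > 1 && lo < 1 && lo > 0))
    stop("thresholds must satisfy hi > 1 > lo > 0", call. = FALSE)
  fc_t <- de_tol$fc[match(genes, de_tol$gene_id)]
  fc_s <- de_sen$fc[match(genes, de_sen$gene_id)]
  if (anyNA(fc_t) || anyNA(fc_s))
    stop("gene id(s) missing from a DE table: ",
         paste(utils::head(genes[is.na(fc_t) | is.na(fc_s)], 5),
               collapse = ", "), call. = FALSE)
  if (any(fc_s <= 0)) stop("fold changes must be positive", call. = FALSE)
  ratio <- fc_t / fc_s
  sort(genes[ratio > hi | ratio < lo])
}

#' Candidate-selection accounting for one tissue
#'
#' Applies the full selection cascade to a Venn partition: the fold-change
#' filter to the metal-specific genes; the cross-species fold-change-ratio
#' filter and then the fold-change filter to the metal-common genes. Reports
#' every stage's counts (an accounting ledger, one row per cascade stage) and
#' the final candidate set split by direction.
#'
#' @param vp A `pb_venn` partition.
#' @param de_tol,de_sen DE tables for the same tissue.
#' @param fc_hi,fc_lo Fold-change thresholds (defaults 2.0, 0.5).
#' @param ratio_hi,ratio_lo Fold-change-ratio thresholds (defaults 2.0, 0.5).
#' @return A list of class `pb_candidates`: tissue, per-stage gene sets
#'   (`specific_retained_up/down`, `common_ratio_pass`,
#'   `common_retained_up/down`), the union `candidates`, counts
#'   `candidate_up`/`candidate_down`, and an `accounting` data frame.
#' @export
candidate_accounting <- function(vp, de_tol, de_sen, fc_hi = 2.0,
                                 fc_lo = 0.5, ratio_hi = 2.0,
                                 ratio_lo = 0.5) {
  spec <- fc_filter(vp$specific_tolerant, de_tol, fc_hi, fc_lo)
  ratio_pass <- ratio_filter(vp$common$gene_id, de_tol, de_sen,
                             ratio_hi, ratio_lo)
  comm <- fc_filter(ratio_pass, de_tol, fc_hi, fc_lo)
  candidates <- sort(c(spec$up, spec$down, comm$up, comm$down))
  stopifnot(!anyDuplicated(candidates))  # specific/common disjoint by Venn
  accounting <- data.frame(
    tissue = vp$tissue,
    category = c("specific", "specific", "common", "common", "common",
                 "candidates"),
    stage = c("total", "fc_filter", "total", "ratio_filter", "fc_filter",
              "total"),
    n = c(length(vp$specific_tolerant),
          length(spec$up) + length(spec$down),
          nrow(vp$common), length(ratio_pass),
          length(comm$up) + length(comm$down), length(candidates)),
    up = c(NA, length(spec$up), NA, NA, length(comm$up),
           length(spec$up) + length(comm$up)),
    down = c(NA, length(spec$down), NA, NA, length(comm$down),
             length(spec$down) + length(comm$down)),
    stringsAsFactors = FALSE)
  structure(list(tissue = vp$tissue,
                 specific_retained_up = spec$up,
                 specific_retained_down = spec$down,
                 common_ratio_pass = ratio_pass,
                 common_retained_up = comm$up,
                 common_retained_down = comm$down,
                 candidates = candidates,
                 candidate_up = length(spec$up) + length(comm$up),
                 candidate_down = length(spec$down) + length(comm$down),
                 accounting = accounting),
            class = "pb_candidates")
}

#' @export
print.pb_candidates <- function(x, ...) {
  print(x$accounting)
  invisible(x)
}

#' Candidate genes shared between roots and shoots
#'
#' @param roots,shoots `pb_candidates` objects for the two tissues of one
#'   species.
#' @return Sorted character vector of genes selected in both tissues.
#' @export
tissue_overlap <- function(roots, shoots) {
  sort(intersect(roots$candidates, shoots$candidates))
}
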