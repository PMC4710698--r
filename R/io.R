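#' Read an expression matrix and sample sheet
#'
#' The matrix TSV has `probe_id` as its first column and one numeric column
#' per array; the sample sheet TSV has columns `sample_id`, `species`,
#' `tissue`, `treatment`, `replicate`. Both LF and CRLF line endings are
#' accepted. Duplicate probe ids, non-numeric cells, and matrix columns
#' absent from the sample sheet are rejected with informative errors.
#'
#' @param matrix_path,samples_path Paths to the two TSV files.
#' @return A `pb_exprset`.
#' @export
read_expression <- function(matrix_path, samples_path) {
  raw <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(raw)[1] != "probe_id")
    stop("first column of ", matrix_path, " must be `probe_id`, found `",
         names(raw)[1], "`", call. = FALSE)
  dup <- raw$probe_id[duplicated(raw$probe_id)]
  if (length(dup))
    stop("duplicate probe_id in ", matrix_path, ": ",
         paste(utils::head(unique(dup), 5), collapse = ", "), call. = FALSE)
  vals <- raw[, -1, drop = FALSE]
  nonnum <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(nonnum)) {
    bad_col <- nonnum[1]
    bad_row <- which(is.na(suppressWarnings(as.numeric(raw[[bad_col]]))))[1]
    stop("non-numeric cell in ", matrix_path, ", column `", bad_col,
         "`, line ", bad_row + 1L, call. = FALSE)
  }
  m <- as.matrix(vals)
  rownames(m) <- raw$probe_id
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  missing <- setdiff(colnames(m), samples$sample_id)
  if (length(missing))
    stop("matrix column(s) missing from sample sheet: ",
         paste(missing, collapse = ", "), call. = FALSE)
  samples <- samples[match(colnames(m), samples$sample_id), , drop = FALSE]
  expression_set(m, samples)
}

#' Write an expression set to TSV
#'
#' @param m A `pb_exprset`.
#' @param matrix_path,samples_path Output paths.
#' @param digits Significant digits for intensities (default 8).
#' @return Invisibly, the input.
#' @export
write_expression <- function(m, matrix_path, samples_path, digits = 8) {
  df <- data.frame(probe_id = rownames(m$values),
                   signif(m$values, digits), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(m$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(m)
}

#' Read a probe/gene/class annotation table
#'
#' @param path TSV with columns `probe_id`, `gene_id`, `classes`
#'   (semicolon-separated; empty allowed).
#' @return Data frame with those columns.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = NULL, colClasses = "character")
  need <- c("probe_id", "gene_id")
  missing <- setdiff(need, names(ann))
  if (length(missing))
    stop("annotation missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!"classes" %in% names(ann)) ann$classes <- ""
  ann
}

#' Write a DE table to TSV
#'
#' Fold changes and means are serialized with 6 significant digits, p- and
#' q-values in scientific notation.
#'
#' @param de DE table from [de_test()].
#' @param path Output path.
#' @return Invisibly, the input.
#' @export
write_de_table <- function(de, path) {
  out <- de
  for (col in c("mean_control", "mean_treated", "fc"))
    if (col %in% names(out)) out[[col]] <- signif(out[[col]], 6)
  for (col in c("p", "q"))
    if (col %in% names(out))
      out[[col]] <- format(out[[col]], digits = 6, scientific = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(de)
}

#' Read a qRT-PCR fold-change table
#'
#' @param path TSV with columns `gene_id`, `tissue`, `fc_array`, `fc_qpcr`.
#' @return Data frame.
#' @export
read_qpcr <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("gene_id", "fc_array", "fc_qpcr"), names(df))
  if (length(missing))
    stop("qPCR table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df
}

pipeline_defaults <- function() {
  list(matrix = NULL, samples = NULL, annotation = NULL, qpcr = NULL,
       background = 50, log_base = 2, p_threshold = 0.05,
       fdr_threshold = 0.1, fc_hi = 2.0, fc_lo = 0.5, ratio_hi = 2.0,
       ratio_lo = 0.5, bootstrap_B = 100, alpha = 0.05, small_class_min = 5,
       normalization_mode = "quartile", seed = 1, out_dir = ".")
}

#' Read and validate a pipeline configuration
#'
#' Accepts a YAML file path or a named list; unknown keys are rejected and
#' threshold ranges validated. Defaults: background 50, log base 2, raw-p
#' threshold 0.05, FDR threshold 0.1, fold-change and ratio cutoffs 2.0/0.5,
#' 100 bootstrap resamples, alpha 0.05, small-class minimum 5, upper-quartile
#' normalization.
#'
#' @param config Path to a YAML file, or a named list of overrides.
#' @return Full configuration list of class `pb_config`.
#' @export
read_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, config)
  chk <- function(ok, key, why)
    if (!ok) stop("invalid config `", key, "`: ", why, call. = FALSE)
  chk(cfg$background > 0, "background", "must be > 0")
  chk(cfg$log_base %in% c(2, 10), "log_base", "must be 2 or 10")
  chk(cfg$fdr_threshold > 0 && cfg$fdr_threshold <= 1, "fdr_threshold",
      "must be in (0, 1]")
  chk(cfg$p_threshold > 0 && cfg$p_threshold <= 1, "p_threshold",
      "must be in (0, 1]")
  chk(cfg$fc_hi > 1 && cfg$fc_lo > 0 && cfg$fc_lo < 1, "fc_hi",
      "need fc_hi > 1 > fc_lo > 0")
  chk(cfg$ratio_hi > 1 && cfg$ratio_lo > 0 && cfg$ratio_lo < 1, "ratio_hi",
      "need ratio_hi > 1 > ratio_lo > 0")
  chk(cfg$bootstrap_B >= 2, "bootstrap_B", "must be >= 2")
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha", "must be in (0, 1)")
  chk(cfg$small_class_min >= 1, "small_class_min", "must be >= 1")
  chk(cfg$normalization_mode %in% c("quartile", "quantile"),
      "normalization_mode", "must be 'quartile' or 'quantile'")
  structure(cfg, class = c("pb_config", "list"))
}
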