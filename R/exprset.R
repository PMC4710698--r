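#' Expression set container
#'
#' A lightweight container pairing a probes x samples intensity matrix with a
#' sample sheet describing each array. All preprocessing functions in the
#' package take and return this class.
#'
#' @param values Numeric matrix, probes in rows (rownames are probe ids),
#'   samples in columns (colnames are sample ids).
#' @param samples Data frame with one row per array and columns `sample_id`,
#'   `species`, `tissue`, `treatment`, `replicate`. Row order must match the
#'   column order of `values`.
#' @return An object of class `pb_exprset`: a list with elements `values` and
#'   `samples`.
#' @examples
#' v <- matrix(rexp(8) + 1, 2, 4,
#'             dimnames = list(c("p1", "p2"), paste0("s", 1:4)))
#' s <- data.frame(sample_id = paste0("s", 1:4),
#'                 species = "tolerant", tissue = "roots",
#'                 treatment = rep(c("control", "Pb"), each = 2),
#'                 replicate = rep(1:2, 2))
#' es <- expression_set(v, s)
#' @export
expression_set <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)))
    stop("`values` must have probe ids as rownames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe_id in expression matrix: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  required <- c("sample_id", "species", "tissue", "treatment", "replicate")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols))
    stop("sample sheet missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (is.null(colnames(values)))
    colnames(values) <- samples$sample_id
  if (!identical(colnames(values), as.character(samples$sample_id)))
    stop("sample sheet rows must match matrix columns; mismatched: ",
         paste(setdiff(colnames(values), samples$sample_id), collapse = ", "),
         call. = FALSE)
  key <- interaction(samples$species, samples$tissue, samples$treatment,
                     samples$replicate, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicate (species, tissue, treatment, replicate) in sample sheet",
         call. = FALSE)
  structure(list(values = values, samples = as.data.frame(samples)),
            class = "pb_exprset")
}

#' @export
print.pb_exprset <- function(x, ...) {
  cat("pb_exprset:", nrow(x$values), "probes x", ncol(x$values), "samples\n")
  cat("species:  ", paste(unique(x$samples$species), collapse = ", "), "\n")
  cat("tissues:  ", paste(unique(x$samples$tissue), collapse = ", "), "\n")
  cat("treatments:", paste(unique(x$samples$treatment), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.pb_exprset <- function(x) dim(x$values)

# Columns belonging to one species x tissue (optionally one treatment).
sample_index <- function(m, species, tissue, treatment = NULL) {
  s <- m$samples
  idx <- s$species == species & s$tissue == tissue
  if (!is.null(treatment)) idx <- idx & s$treatment == treatment
  which(idx)
}

#' Subset an expression set to one species/tissue contrast
#'
#' @param m A `pb_exprset`.
#' @param species,tissue Values to match in the sample sheet.
#' @param probes Optional character vector of probe ids to keep.
#' @return A `pb_exprset` restricted to the selected arrays (and probes).
#' @export
subset_exprset <- function(m, species, tissue, probes = NULL) {
  idx <- sample_index(m, species, tissue)
  if (!length(idx))
    stop("no samples for species=", species, ", tissue=", tissue, call. = FALSE)
  v <- m$values[, idx, drop = FALSE]
  if (!is.null(probes)) {
    bad <- setdiff(probes, rownames(v))
    if (length(bad))
      stop("unknown probe id(s): ", paste(utils::head(bad, 5), collapse = ", "),
           call. = FALSE)
    v <- v[probes, , drop = FALSE]
  }
  expression_set(v, m$samples[idx, , drop = FALSE])
}

stopifnot_positive <- function(values, what = "intensity") {
  if (any(!is.finite(values)) || any(values <= 0))
    stop("all ", what, " values must be positive and finite", call. = FALSE)
  invisible(TRUE)
}
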