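#' Upper-quartile normalization between arrays
#'
#' Rescales each array so that its 75th percentile equals the geometric mean
#' of the input arrays' 75th percentiles. A pure per-array rescaling:
#' within-array value ratios are preserved, and applying it twice equals
#' applying it once. Percentiles use linear interpolation between order
#' statistics (`stats::quantile` type 7).
#'
#' @param m A `pb_exprset` of positive linear intensities.
#' @return The rescaled `pb_exprset`.
#' @export
quartile_normalize <- function(m) {
  stopifnot_positive(m$values)
  q75 <- apply(m$values, 2, stats::quantile, probs = 0.75, names = FALSE)
  target <- exp(mean(log(q75)))
  m$values <- sweep(m$values, 2, target / q75, `*`)
  m
}

#' Between-array normalization with selectable method
#'
#' `"quartile"` (default) is upper-quartile scaling ([quartile_normalize()]);
#' `"quantile"` is full quantile normalization (all arrays forced to share one
#' intensity distribution), provided as a sensitivity check and delegated to
#' \pkg{limma}.
#'
#' @param m A `pb_exprset`.
#' @param method One of `"quartile"`, `"quantile"`.
#' @return The normalized `pb_exprset`.
#' @export
normalize_arrays <- function(m, method = c("quartile", "quantile")) {
  method <- match.arg(method)
  if (method == "quartile") return(quartile_normalize(m))
  if (!requireNamespace("limma", quietly = TRUE))
    stop("quantile mode requires the limma package", call. = FALSE)
  stopifnot_positive(m$values)
  m$values <- limma::normalizeQuantiles(m$values)
  m
}

#' Per-probe median centering
#'
#' Divides each probe's values by that probe's median across all samples, so
#' every probe's output median is 1. Because the same factor divides every
#' sample of a probe, condition-mean ratios (fold changes) and log-scale
#' t-statistics are unchanged.
#'
#' @param m A `pb_exprset` with at least one sample.
#' @return The centered `pb_exprset`.
#' @export
median_center_probes <- function(m) {
  if (ncol(m$values) < 1) stop("need at least one sample", call. = FALSE)
  med <- apply(m$values, 1, stats::median)
  if (any(med == 0))
    stop("probe(s) with zero median cannot be centered: ",
         paste(utils::head(rownames(m$values)[med == 0], 5), collapse = ", "),
         call. = FALSE)
  m$values <- m$values / med
  m
}

#' Elementwise log transform
#'
#' @param m A `pb_exprset` of positive values.
#' @param base Logarithm base, 2 (default, intensity convention) or 10.
#' @return The transformed `pb_exprset`.
#' @export
log_transform <- function(m, base = 2) {
  if (!base %in% c(2, 10)) stop("base must be 2 or 10", call. = FALSE)
  stopifnot_positive(m$values)
  m$values <- log(m$values, base)
  m
}

#' Background-based probe retention
#'
#' For one species x tissue contrast, a probe is retained iff there exists a
#' condition (control or treated) in which all replicates exceed the
#' background floor. Probes silenced by cross-species hybridization failure
#' sit at or below background in every replicate of both conditions and are
#' removed here.
#'
#' @param m A `pb_exprset` of linear intensities (raw or between-array
#'   normalized).
#' @param background Single background intensity value.
#' @param species,tissue The contrast to evaluate.
#' @return Character vector of retained probe ids.
#' @export
background_filter <- function(m, background, species, tissue) {
  sub <- subset_exprset(m, species, tissue)
  trt <- sub$samples$treatment
  groups <- split(seq_along(trt), trt)
  if (length(groups) < 2 || any(lengths(groups) == 0))
    stop("need both control and treated arrays for species=", species,
         ", tissue=", tissue, call. = FALSE)
  above <- vapply(groups, function(idx)
    matrixStats_rowAll(sub$values[, idx, drop = FALSE] > background),
    logical(nrow(sub$values)))
  rownames(sub$values)[rowSums(above) > 0]
}

# rowAll without a matrixStats dependency
matrixStats_rowAll <- function(x) rowSums(x) == ncol(x)
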