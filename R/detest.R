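#' Collapse probes to genes
#'
#' When several probes map to one gene, the probe with the largest mean
#' intensity across all samples represents the gene (the brightest probe is
#' the least likely to be degraded by cross-species sequence divergence).
#'
#' @param m A `pb_exprset`.
#' @param annotation Data frame with `probe_id`, `gene_id`.
#' @return A `pb_exprset` with one row per gene, rownames set to gene ids.
#' @export
collapse_probes <- function(m, annotation) {
  idx <- match(rownames(m$values), annotation$probe_id)
  if (anyNA(idx))
    stop("probe id(s) missing from annotation: ",
         paste(utils::head(rownames(m$values)[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  gene <- annotation$gene_id[idx]
  means <- rowMeans(m$values)
  ord <- order(gene, -means)
  keep <- ord[!duplicated(gene[ord])]
  v <- m$values[keep, , drop = FALSE]
  rownames(v) <- gene[keep]
  v <- v[order(rownames(v)), , drop = FALSE]
  expression_set(v, m$samples)
}

# Vectorized two-sample pooled-variance Student t-test, two-sided,
# rows = features. Returns p-values; zero pooled variance gives p = 1 when
# means agree and p = 0 (degenerate) when they differ.
row_t_test <- function(x_control, x_treated) {
  n1 <- ncol(x_control); n2 <- ncol(x_treated)
  if (n1 < 2 || n2 < 2)
    stop("need >= 2 replicates per condition for the t-test", call. = FALSE)
  m1 <- rowMeans(x_control); m2 <- rowMeans(x_treated)
  v1 <- rowSums((x_control - m1)^2) / (n1 - 1)
  v2 <- rowSums((x_treated - m2)^2) / (n2 - 1)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (m2 - m1) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se == 0
  p[degenerate & m1 == m2] <- 1
  p[degenerate & m1 != m2] <- 0
  list(p = p, t = tstat, degenerate = degenerate)
}

#' Differential-expression test for one species x tissue contrast
#'
#' Runs the classical pooled-variance Student t-test (two-sided, asymptotic
#' t-distribution p-value) on log-transformed normalized intensities,
#' Benjamini-Hochberg adjustment across all tested genes in the contrast, and
#' linear fold changes as the ratio of treated to control condition means on
#' the linear scale. A gene is called regulated when its BH-adjusted q-value
#' falls below `fdr_threshold`.
#'
#' @param m A `pb_exprset` of normalized linear intensities.
#' @param species,tissue The contrast to test.
#' @param probes Optional retained probe set (from [background_filter()]).
#' @param annotation Optional `probe_id`/`gene_id` map; when given, probes are
#'   collapsed to genes via [collapse_probes()] before testing.
#' @param fdr_threshold BH q-value cutoff for the regulated call (default 0.1).
#' @param p_threshold Raw p-value recorded alongside (default 0.05); exposed
#'   for sensitivity analyses, not applied as an extra filter by default.
#' @param log_base Log base used for the test scale (default 2).
#' @return A data frame (DE table) with columns `gene_id`, `species`,
#'   `tissue`, `mean_control`, `mean_treated`, `fc`, `p`, `q`, `regulated`,
#'   `direction` (`up`/`down`/`none`), `degenerate`.
#' @export
de_test <- function(m, species, tissue, probes = NULL, annotation = NULL,
                    fdr_threshold = 0.1, p_threshold = 0.05, log_base = 2) {
  sub <- subset_exprset(m, species, tissue, probes)
  if (!is.null(annotation)) sub <- collapse_probes(sub, annotation)
  stopifnot_positive(sub$values, "normalized intensity")
  ctl <- sub$values[, sub$samples$treatment == "control", drop = FALSE]
  trt <- sub$values[, sub$samples$treatment != "control", drop = FALSE]
  if (ncol(ctl) == 0 || ncol(trt) == 0)
    stop("both control and treated arrays are required", call. = FALSE)
  tt <- row_t_test(log(ctl, log_base), log(trt, log_base))
  mean_control <- rowMeans(ctl)
  mean_treated <- rowMeans(trt)
  fc <- mean_treated / mean_control
  q <- stats::p.adjust(tt$p, method = "BH")
  regulated <- q < fdr_threshold
  direction <- ifelse(!regulated | fc == 1, "none",
                      ifelse(fc > 1, "up", "down"))
  data.frame(gene_id = rownames(sub$values), species = species,
             tissue = tissue, mean_control = mean_control,
             mean_treated = mean_treated, fc = fc, p = tt$p, q = q,
             regulated = regulated, direction = direction,
             degenerate = tt$degenerate, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Tally regulated genes across tissues for one species
#'
#' Counts up- and down-regulated genes per tissue and expresses each tissue's
#' share of the species total as a percentage rounded to one decimal.
#'
#' @param roots,shoots Either a DE table (from [de_test()]) or a numeric
#'   vector `c(up, down)` of pre-tallied counts.
#' @return A list with `counts` (data frame tissue/up/down/total), `total`,
#'   and `pct` (named numeric, `roots` and `shoots`; `NA` when the species
#'   total is zero).
#' @export
summarize_regulated <- function(roots, shoots) {
  tally <- function(x) {
    if (is.data.frame(x))
      c(up = sum(x$regulated & x$direction == "up"),
        down = sum(x$regulated & x$direction == "down"))
    else if (is.numeric(x) && length(x) == 2) c(up = x[[1]], down = x[[2]])
    else stop("expected a DE table or c(up, down) counts", call. = FALSE)
  }
  r <- tally(roots); s <- tally(shoots)
  counts <- data.frame(tissue = c("roots", "shoots"),
                       up = c(r["up"], s["up"]), down = c(r["down"], s["down"]),
                       row.names = NULL)
  counts$total <- counts$up + counts$down
  total <- sum(counts$total)
  pct <- if (total == 0) c(roots = NA_real_, shoots = NA_real_)
         else round(100 * c(roots = counts$total[1], shoots = counts$total[2]) /
                      total, 1)
  list(counts = counts, total = total, pct = pct)
}
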