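#' Build a gene-to-class map from an annotation table
#'
#' @param annotation Data frame with `gene_id` and `classes`
#'   (semicolon-separated labels; empty string means unclassified).
#' @return Named list mapping each gene id to a character vector of class
#'   labels (possibly empty). Duplicate gene rows are collapsed.
#' @export
class_map <- function(annotation) {
  ann <- annotation[!duplicated(annotation$gene_id), , drop = FALSE]
  cm <- strsplit(as.character(ann$classes), ";", fixed = TRUE)
  cm <- lapply(cm, function(x) x[nzchar(trimws(x))])
  names(cm) <- ann$gene_id
  cm
}

#' Count class membership of a gene list
#'
#' Counts, per functional class, the input genes carrying that class, along
#' with the number of input genes having at least one class. Genes may belong
#' to several classes (each membership counts); genes with no class — or
#' absent from the map — are excluded from the classified denominator.
#' Duplicated input genes count multiply, which is what bootstrap resampling
#' requires.
#'
#' @param genes Character vector of gene ids (duplicates allowed).
#' @param cmap A class map from [class_map()].
#' @return List with `counts` (named integer vector over classes seen in the
#'   input) and `n_classified`.
#' @export
classify_genes <- function(genes, cmap) {
  cls <- cmap[match(genes, names(cmap))]
  cls[is.na(names(cls))] <- list(character(0))
  n_classified <- sum(lengths(cls) > 0)
  counts <- table(unlist(cls, use.names = FALSE))
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(counts = counts, n_classified = n_classified)
}

#' Normed frequency of a functional class
#'
#' The enrichment statistic: the class's share of the classified input list
#' divided by its share of the classified reference list,
#' `(n_class_input / n_classified_input) / (n_class_reference /
#' n_classified_reference)`. Equals 1 when the input composition matches the
#' reference, > 1 for over-representation.
#'
#' @param n_class_input,n_classified_input Class count and classified size of
#'   the input list.
#' @param n_class_reference,n_classified_reference Same for the reference.
#' @return The ratio; `NA` with a warning when the reference class count is 0.
#' @export
normed_frequency <- function(n_class_input, n_classified_input,
                             n_class_reference, n_classified_reference) {
  if (n_classified_input <= 0 || n_classified_reference <= 0)
    stop("classified set sizes must be positive", call. = FALSE)
  if (any(n_class_reference == 0)) {
    warning("class absent from reference; normed frequency undefined")
    return(ifelse(n_class_reference == 0, NA_real_,
                  (n_class_input / n_classified_input) /
                    (n_class_reference / n_classified_reference)))
  }
  (n_class_input / n_classified_input) /
    (n_class_reference / n_classified_reference)
}

#' Bootstrap class-score means and standard errors
#'
#' Resamples the input gene list with replacement at its original size `B`
#' times, recomputes the normed frequency of every class per resample
#' (duplicated genes counting multiply in both class count and classified
#' size), and reports the mean and the standard deviation of the `B`
#' resampled scores as the bootstrap SE of the class score.
#'
#' @param genes Character vector, the input gene list.
#' @param cmap Class map from [class_map()].
#' @param reference Character vector, the reference gene set.
#' @param B Number of bootstrap resamples (default 100).
#' @param seed Optional integer seed.
#' @return Data frame `class`, `boot_mean`, `boot_se`, one row per class
#'   present in the reference.
#' @export
bootstrap_scores <- function(genes, cmap, reference, B = 100, seed = NULL) {
  if (B < 2) stop("B must be >= 2", call. = FALSE)
  if (!length(genes)) stop("input gene list is empty", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ref <- classify_genes(reference, cmap)
  classes <- names(ref$counts)
  if (!length(classes))
    stop("reference contains no classified genes", call. = FALSE)
  # genes x classes incidence for the input list
  cls <- cmap[match(genes, names(cmap))]
  cls[is.na(names(cls))] <- list(character(0))
  inc <- vapply(classes, function(cl)
    vapply(cls, function(g) cl %in% g, logical(1)), logical(length(genes)))
  inc <- matrix(inc, nrow = length(genes), ncol = length(classes),
                dimnames = list(NULL, classes))
  classified <- lengths(cls) > 0
  n <- length(genes)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
  grp <- rep(seq_len(B), times = n)            # column-major unrolling
  counts_b <- rowsum(inc[as.vector(idx), , drop = FALSE] * 1, grp)
  nclass_b <- rowsum(classified[as.vector(idx)] * 1, grp)[, 1]
  ref_frac <- ref$counts / ref$n_classified
  scores <- sweep(counts_b / nclass_b, 2, ref_frac, `/`)
  scores[nclass_b == 0, ] <- NA                # resample with nothing classified
  data.frame(class = classes,
             boot_mean = colMeans(scores, na.rm = TRUE),
             boot_se = apply(scores, 2, stats::sd, na.rm = TRUE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-sided hypergeometric over-representation test
#'
#' Tests whether a class's count in the input list is compatible with drawing
#' `n_classified_input` genes from the classified reference
#' (Fisher's exact test on the corresponding 2x2 table).
#'
#' @inheritParams normed_frequency
#' @return Two-sided p-value.
#' @export
over_representation_test <- function(n_class_input, n_classified_input,
                                     n_class_reference,
                                     n_classified_reference) {
  a <- n_class_input; n <- n_classified_input
  K <- n_class_reference; N <- n_classified_reference
  if (a > K || (n - a) > (N - K) || a > n || n > N || a < 0)
    stop("input counts exceed reference counts", call. = FALSE)
  stats::fisher.test(matrix(c(a, n - a, K - a, (N - K) - (n - a)),
                            nrow = 2))$p.value
}

#' Functional-class enrichment of a gene list
#'
#' Full over-representation analysis in the Classification-SuperViewer style:
#' per-class counts with multi-membership, the normed-frequency point
#' estimate, bootstrap mean and SE over `B` resamples, a two-sided
#' hypergeometric p-value, and a small-class flag for classes represented by
#' fewer than `small_class_min` input genes. A display column reproduces the
#' `*` (significant) / `o` (small class) convention.
#'
#' @param genes Input gene list (e.g. selected candidates).
#' @param cmap Class map from [class_map()].
#' @param reference Reference gene set; defaults to all classified genes in
#'   the map (the array annotation universe).
#' @param B Bootstrap resamples (default 100).
#' @param seed Optional integer seed for the bootstrap.
#' @param alpha Significance level (default 0.05).
#' @param small_class_min Classes with fewer input genes than this are
#'   flagged (default 5).
#' @param bh Apply BH correction across classes before flagging significance
#'   (off by default; raw class-level p-values are the convention).
#' @return Data frame sorted by decreasing normed frequency with columns
#'   `class`, `n_class_input`, `n_classified_input`, `n_class_reference`,
#'   `n_classified_reference`, `normed_frequency`, `boot_mean`, `boot_se`,
#'   `p_value`, `significant`, `small_class`, `flags`.
#' @export
enrich <- function(genes, cmap, reference = NULL, B = 100, seed = NULL,
                   alpha = 0.05, small_class_min = 5, bh = FALSE) {
  if (is.null(reference))
    reference <- names(cmap)[lengths(cmap) > 0]
  ref <- classify_genes(reference, cmap)
  classes <- names(ref$counts)
  empty <- data.frame(class = character(0), n_class_input = integer(0),
                      n_classified_input = integer(0),
                      n_class_reference = integer(0),
                      n_classified_reference = integer(0),
                      normed_frequency = numeric(0), boot_mean = numeric(0),
                      boot_se = numeric(0), p_value = numeric(0),
                      significant = logical(0), small_class = logical(0),
                      flags = character(0), stringsAsFactors = FALSE)
  if (!length(genes) || !length(classes)) return(empty)
  inp <- classify_genes(genes, cmap)
  if (inp$n_classified == 0) return(empty)
  n_in <- stats::setNames(rep(0L, length(classes)), classes)
  n_in[names(inp$counts)] <- inp$counts
  nf <- normed_frequency(n_in, inp$n_classified, ref$counts,
                         ref$n_classified)
  boot <- bootstrap_scores(genes, cmap, reference, B = B, seed = seed)
  p <- vapply(classes, function(cl)
    over_representation_test(n_in[[cl]], inp$n_classified,
                             ref$counts[[cl]], ref$n_classified),
    numeric(1))
  p_eff <- if (bh) stats::p.adjust(p, "BH") else p
  out <- data.frame(class = classes, n_class_input = as.integer(n_in),
                    n_classified_input = inp$n_classified,
                    n_class_reference = as.integer(ref$counts),
                    n_classified_reference = ref$n_classified,
                    normed_frequency = as.numeric(nf),
                    boot_mean = boot$boot_mean, boot_se = boot$boot_se,
                    p_value = p, significant = p_eff < alpha,
                    small_class = n_in < small_class_min,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$flags <- paste0(ifelse(out$significant, "*", ""),
                      ifelse(out$small_class, "o", ""))
  out[order(-out$normed_frequency, out$class), , drop = FALSE]
}
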