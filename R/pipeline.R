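#' Run the full analysis pipeline
#'
#' Orchestrates every stage on one dataset: between-array normalization,
#' per-probe median centering, background-based probe retention per species x
#' tissue, differential-expression testing with BH correction, per-species
#' regulated-gene summaries, the two-species Venn partition and
#' candidate-selection cascade per tissue, the root/shoot candidate overlap,
#' functional-class enrichment of the up- and down-regulated candidates, and
#' (when a qPCR table is supplied) array/qPCR concordance.
#'
#' Inputs come either from file paths in the configuration (`matrix`,
#' `samples`, `annotation`, `qpcr`) or from objects passed directly. When
#' `out_dir` is set (argument or config key), all result tables are written
#' as TSV/JSON together with a run manifest (configuration echo, package
#' version, seed, and per-stage row counts); outputs are deterministic given
#' the same inputs, configuration and seed.
#'
#' @param config Path to a YAML configuration or a named list (see
#'   [read_config()]).
#' @param exprs Optional `pb_exprset` of raw intensities (overrides the
#'   `matrix`/`samples` paths).
#' @param annotation Optional annotation data frame (`probe_id`, `gene_id`,
#'   `classes`).
#' @param qpcr Optional qPCR pairs data frame.
#' @param out_dir Optional output directory; overrides the config key.
#' @return A result bundle (list): `config`, `de` (per species, per tissue),
#'   `summary` (per species), `venn`, `candidates` (per tissue), `overlap`,
#'   `enrichment` (per tissue, up/down), `concordance` (or NULL), `manifest`.
#' @export
run_all <- function(config = list(), exprs = NULL, annotation = NULL,
                    qpcr = NULL, out_dir = NULL) {
  cfg <- read_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir

  if (is.null(exprs)) {
    if (is.null(cfg$matrix) || is.null(cfg$samples))
      stop("stage input: no expression data (pass `exprs` or set `matrix` ",
           "and `samples` in the config)", call. = FALSE)
    exprs <- read_expression(cfg$matrix, cfg$samples)
  }
  if (is.null(annotation) && !is.null(cfg$annotation))
    annotation <- read_annotation(cfg$annotation)
  if (is.null(annotation))
    annotation <- data.frame(probe_id = rownames(exprs$values),
                             gene_id = rownames(exprs$values),
                             classes = "", stringsAsFactors = FALSE)
  if (is.null(qpcr) && !is.null(cfg$qpcr)) qpcr <- read_qpcr(cfg$qpcr)

  species <- unique(exprs$samples$species)
  tissues <- unique(exprs$samples$tissue)
  if (length(species) != 2)
    stop("stage crosscompare: exactly two species required, found: ",
         paste(species, collapse = ", "), call. = FALSE)
  sp_tol <- if ("tolerant" %in% species) "tolerant" else species[1]
  sp_sen <- setdiff(species, sp_tol)[1]

  norm <- normalize_arrays(exprs, cfg$normalization_mode)
  centered <- median_center_probes(norm)

  de <- list()
  for (sp in c(sp_tol, sp_sen)) {
    de[[sp]] <- list()
    for (ti in tissues) {
      retained <- background_filter(norm, cfg$background, sp, ti)
      if (!length(retained))
        stop("stage preprocess: no probes above background for ", sp, "/",
             ti, call. = FALSE)
      de[[sp]][[ti]] <- de_test(centered, sp, ti, probes = retained,
                                annotation = annotation,
                                fdr_threshold = cfg$fdr_threshold,
                                p_threshold = cfg$p_threshold,
                                log_base = cfg$log_base)
    }
  }

  summary <- lapply(de, function(tabs)
    summarize_regulated(tabs[["roots"]], tabs[["shoots"]]))

  venn <- candidates <- list()
  for (ti in tissues) {
    universe <- intersect(de[[sp_tol]][[ti]]$gene_id,
                          de[[sp_sen]][[ti]]$gene_id)
    dt <- de[[sp_tol]][[ti]]
    ds <- de[[sp_sen]][[ti]]
    dt <- dt[dt$gene_id %in% universe, , drop = FALSE]
    ds <- ds[ds$gene_id %in% universe, , drop = FALSE]
    venn[[ti]] <- venn_partition(dt, ds, ti)
    candidates[[ti]] <- candidate_accounting(venn[[ti]], dt, ds,
                                             fc_hi = cfg$fc_hi,
                                             fc_lo = cfg$fc_lo,
                                             ratio_hi = cfg$ratio_hi,
                                             ratio_lo = cfg$ratio_lo)
  }
  overlap <- if (all(c("roots", "shoots") %in% tissues))
    tissue_overlap(candidates[["roots"]], candidates[["shoots"]])
  else character(0)

  cmap <- class_map(annotation)
  reference <- names(cmap)[lengths(cmap) > 0]
  enrichment <- list()
  for (ti in tissues) {
    cs <- candidates[[ti]]
    enrichment[[ti]] <- list(
      up = enrich(c(cs$specific_retained_up, cs$common_retained_up), cmap,
                  reference, B = cfg$bootstrap_B, seed = cfg$seed,
                  alpha = cfg$alpha, small_class_min = cfg$small_class_min),
      down = enrich(c(cs$specific_retained_down, cs$common_retained_down),
                    cmap, reference, B = cfg$bootstrap_B, seed = cfg$seed,
                    alpha = cfg$alpha, small_class_min = cfg$small_class_min))
  }

  concord <- if (!is.null(qpcr)) concordance(qpcr) else NULL

  manifest <- list(
    package = "pbarray",
    version = as.character(utils::packageVersion("pbarray")),
    seed = cfg$seed,
    # out_dir is a deployment detail, not part of the analysis configuration
    config = unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1)) &
                            names(cfg) != "out_dir"],
    rows = list(
      probes = nrow(exprs$values), samples = ncol(exprs$values),
      de = lapply(de, function(tabs) lapply(tabs, nrow)),
      regulated = lapply(summary, function(s) s$total),
      candidates = lapply(candidates, function(cs) length(cs$candidates)),
      overlap = length(overlap)))

  bundle <- list(config = cfg, de = de, summary = summary, venn = venn,
                 candidates = candidates, overlap = overlap,
                 enrichment = enrichment, concordance = concord,
                 manifest = manifest)
  if (!is.null(cfg$out_dir) && !identical(cfg$out_dir, "."))
    write_bundle(bundle, cfg$out_dir)
  invisible(bundle)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  for (sp in names(bundle$de))
    for (ti in names(bundle$de[[sp]]))
      write_de_table(bundle$de[[sp]][[ti]], p(paste0("de_", sp, "_", ti,
                                                    ".tsv")))
  venn_json <- lapply(bundle$venn, function(v) list(
    tissue = v$tissue,
    specific_tolerant = length(v$specific_tolerant),
    specific_sensitive = length(v$specific_sensitive),
    common = nrow(v$common),
    sign_categories = as.list(table(v$common$sign))))
  jsonlite::write_json(venn_json, p("venn_summary.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  accounting <- do.call(rbind, lapply(bundle$candidates,
                                      function(cs) cs$accounting))
  utils::write.table(accounting, p("accounting.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cand_rows <- do.call(rbind, lapply(bundle$candidates, function(cs) {
    ids <- cs$candidates
    if (!length(ids)) return(NULL)
    origin <- ifelse(ids %in% c(cs$common_retained_up,
                                cs$common_retained_down), "common",
                     "specific")
    direction <- ifelse(ids %in% c(cs$specific_retained_up,
                                   cs$common_retained_up), "up", "down")
    data.frame(gene_id = ids, tissue = cs$tissue, origin = origin,
               direction = direction, stringsAsFactors = FALSE)
  }))
  if (is.null(cand_rows))
    cand_rows <- data.frame(gene_id = character(0), tissue = character(0),
                            origin = character(0), direction = character(0))
  utils::write.table(cand_rows, p("candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (ti in names(bundle$enrichment))
    for (dir in c("up", "down")) {
      tab <- bundle$enrichment[[ti]][[dir]]
      tab_fmt <- tab
      for (col in c("normed_frequency", "boot_mean", "boot_se"))
        if (col %in% names(tab_fmt)) tab_fmt[[col]] <- signif(tab_fmt[[col]], 6)
      if ("p_value" %in% names(tab_fmt))
        tab_fmt$p_value <- format(tab_fmt$p_value, digits = 6,
                                  scientific = TRUE)
      utils::write.table(tab_fmt, p(paste0("enrichment_", ti, "_", dir,
                                           ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  if (!is.null(bundle$concordance))
    utils::write.table(bundle$concordance, p("concordance.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$manifest, p("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
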