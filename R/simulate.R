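#' @keywords internal
default_class_labels <- c(
  "photosynthesis", "cell wall", "metal handling", "hormone metabolism",
  "stress", "transport", "protein", "RNA", "signalling", "secondary metabolism"
)

#' Configuration for the synthetic microarray experiment
#'
#' Builds and validates the parameter set for [simulate_experiment()]. The
#' generated design mirrors a two-species hydroponic metal-exposure study: a
#' tolerant species and a sensitive model species, roots and shoots, control
#' versus Pb-treated, with independent biological replicates hybridized to the
#' model species' array. The tolerant species is the cross-species hybridizer,
#' so a configurable fraction of its probes is silenced to emulate sequence
#' divergence.
#'
#' @param n_probes Number of probes on the array.
#' @param n_genes Number of genes (<= `n_probes`); probes beyond the first
#'   `n_genes` are extra probes assigned to random genes.
#' @param n_up,n_down Planted up-/down-regulated genes per (species, tissue).
#' @param fc_planted Linear fold-change magnitude of planted genes (> 1).
#' @param noise_sd Replicate noise sd on the log2 scale.
#' @param array_scale_sd Per-array multiplicative scale jitter, sd on log2 scale.
#' @param background Intensity floor; silenced probes fall at or below it.
#' @param dropout_rate Fraction of probes silenced for the tolerant
#'   (cross-hybridizing) species, both conditions.
#' @param n_replicates Biological replicates per condition (default 3).
#' @param shared_fraction Fraction of each planted set shared between the two
#'   species (same direction), so the metal-common Venn sector is populated.
#' @param base_mean,base_sd Mean and sd of per-gene baseline log2 expression.
#' @param classes Functional-class labels for the simulated annotation.
#' @param multi_class_prob Probability a classified gene gets a second class.
#' @param unclassified_prob Probability a gene carries no class at all.
#' @param seed Integer RNG seed; fixed seed gives byte-identical output.
#' @return A validated list of class `pb_sim_config`.
#' @export
sim_config <- function(n_probes = 2000, n_genes = n_probes,
                       n_up = 100, n_down = 100, fc_planted = 4,
                       noise_sd = 0.25, array_scale_sd = 0.1,
                       background = 50, dropout_rate = 0.2,
                       n_replicates = 3, shared_fraction = 0.5,
                       base_mean = 10, base_sd = 1.5,
                       classes = default_class_labels,
                       multi_class_prob = 0.15, unclassified_prob = 0.1,
                       seed = 1) {
  cfg <- list(n_probes = n_probes, n_genes = n_genes, n_up = n_up,
              n_down = n_down, fc_planted = fc_planted, noise_sd = noise_sd,
              array_scale_sd = array_scale_sd, background = background,
              dropout_rate = dropout_rate, n_replicates = n_replicates,
              shared_fraction = shared_fraction, base_mean = base_mean,
              base_sd = base_sd, classes = classes,
              multi_class_prob = multi_class_prob,
              unclassified_prob = unclassified_prob, seed = seed)
  bad <- function(field, why)
    stop("invalid sim_config field `", field, "`: ", why, call. = FALSE)
  count_fields <- c("n_probes", "n_genes", "n_up", "n_down", "n_replicates")
  for (f in count_fields)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 0 ||
        cfg[[f]] != round(cfg[[f]]))
      bad(f, "must be a single non-negative integer")
  if (cfg$n_genes > cfg$n_probes) bad("n_genes", "must be <= n_probes")
  if (cfg$n_up + cfg$n_down > cfg$n_genes)
    bad("n_up", "n_up + n_down must be <= n_genes")
  if (cfg$n_replicates < 2) bad("n_replicates", "need >= 2 replicates")
  if (!is.numeric(cfg$fc_planted) || cfg$fc_planted <= 1)
    bad("fc_planted", "must be > 1")
  for (f in c("noise_sd", "array_scale_sd", "base_sd"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) bad(f, "must be >= 0")
  for (f in c("dropout_rate", "shared_fraction", "multi_class_prob",
              "unclassified_prob"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      bad(f, "must be in [0, 1]")
  if (!is.numeric(cfg$background) || cfg$background <= 0)
    bad("background", "must be > 0")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 ||
      cfg$seed != round(cfg$seed))
    bad("seed", "must be a single integer")
  structure(cfg, class = "pb_sim_config")
}

#' Simulate a two-species metal-exposure microarray experiment
#'
#' Draws a per-gene baseline log2 expression, plants up- and down-regulated
#' genes (treated mean times `fc_planted` or its reciprocal, applied on the
#' linear scale before noise), adds log-normal replicate noise and per-array
#' scale jitter, and silences a random probe subset for the tolerant species
#' by drawing both conditions uniformly in (0, background]. Planted gene sets
#' partially overlap between species (`shared_fraction`, same direction), so
#' downstream species comparison yields both metal-specific and metal-common
#' genes. Dropped probes are never planted as regulated.
#'
#' @param config A `pb_sim_config` from [sim_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{exprs}{`pb_exprset` of raw intensities, `n_probes` rows and
#'       2 species x 2 tissues x 2 treatments x `n_replicates` columns.}
#'     \item{annotation}{Data frame `probe_id`, `gene_id`, `classes`
#'       (semicolon-separated, possibly empty).}
#'     \item{truth}{List with `planted_up` / `planted_down` (gene-id sets per
#'       "species.tissue") and `dropped_probes` per species.}
#'   }
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "pb_sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  np <- config$n_probes; ng <- config$n_genes
  probe_ids <- sprintf("P%05d", seq_len(np))
  gene_ids <- sprintf("G%05d", seq_len(ng))
  # first ng probes map 1:1; extras land on random genes
  probe_gene <- c(gene_ids,
                  if (np > ng) sample(gene_ids, np - ng, replace = TRUE))

  classes <- replicate(ng, {
    if (stats::runif(1) < config$unclassified_prob) return("")
    k <- 1 + (stats::runif(1) < config$multi_class_prob)
    paste(sample(config$classes, min(k, length(config$classes))),
          collapse = ";")
  })
  annotation <- data.frame(probe_id = probe_ids, gene_id = probe_gene,
                           classes = classes[match(probe_gene, gene_ids)],
                           stringsAsFactors = FALSE)

  mu <- stats::rnorm(ng, config$base_mean, config$base_sd)   # log2 baseline
  base_linear <- 2^mu
  names(base_linear) <- gene_ids

  n_drop <- round(config$dropout_rate * np)
  dropped <- sort(sample(probe_ids, n_drop))
  dropped_genes <- unique(probe_gene[match(dropped, probe_ids)])
  eligible <- setdiff(gene_ids, dropped_genes)
  n_plant <- config$n_up + config$n_down
  if (length(eligible) < 2 * n_plant && n_plant > 0)
    stop("invalid sim_config field `dropout_rate`: too few non-dropped genes ",
         "to plant n_up + n_down regulated genes", call. = FALSE)

  species <- c("tolerant", "sensitive")
  tissues <- c("roots", "shoots")
  planted_up <- planted_down <- list()
  pick <- function(pool, n) if (n > 0) sample(pool, n) else character(0)
  for (ti in tissues) {
    tol_up <- pick(eligible, config$n_up)
    tol_down <- pick(setdiff(eligible, tol_up), config$n_down)
    n_sh_up <- round(config$shared_fraction * config$n_up)
    n_sh_down <- round(config$shared_fraction * config$n_down)
    fresh <- setdiff(eligible, c(tol_up, tol_down))
    sen_up <- c(pick(tol_up, n_sh_up), pick(fresh, config$n_up - n_sh_up))
    fresh <- setdiff(fresh, sen_up)
    sen_down <- c(pick(tol_down, n_sh_down),
                  pick(fresh, config$n_down - n_sh_down))
    planted_up[[paste("tolerant", ti, sep = ".")]] <- sort(tol_up)
    planted_down[[paste("tolerant", ti, sep = ".")]] <- sort(tol_down)
    planted_up[[paste("sensitive", ti, sep = ".")]] <- sort(sen_up)
    planted_down[[paste("sensitive", ti, sep = ".")]] <- sort(sen_down)
  }

  n_arrays <- 2 * 2 * 2 * config$n_replicates
  samples <- expand.grid(replicate = seq_len(config$n_replicates),
                         treatment = c("control", "Pb"),
                         tissue = tissues, species = species,
                         stringsAsFactors = FALSE)
  samples <- samples[, c("species", "tissue", "treatment", "replicate")]
  samples$sample_id <- with(samples, paste(substr(species, 1, 3),
                                           substr(tissue, 1, 2),
                                           substr(treatment, 1, 2),
                                           replicate, sep = "_"))
  samples <- samples[, c("sample_id", "species", "tissue", "treatment",
                         "replicate")]

  values <- matrix(NA_real_, np, n_arrays,
                   dimnames = list(probe_ids, samples$sample_id))
  array_scale <- 2^stats::rnorm(n_arrays, 0, config$array_scale_sd)
  drop_idx <- match(dropped, probe_ids)
  for (j in seq_len(n_arrays)) {
    sp <- samples$species[j]; ti <- samples$tissue[j]
    trt <- samples$treatment[j]
    key <- paste(sp, ti, sep = ".")
    mean_linear <- base_linear[probe_gene]
    if (trt == "Pb") {
      up <- probe_gene %in% planted_up[[key]]
      dn <- probe_gene %in% planted_down[[key]]
      mean_linear[up] <- mean_linear[up] * config$fc_planted
      mean_linear[dn] <- mean_linear[dn] / config$fc_planted
    }
    col <- mean_linear * 2^stats::rnorm(np, 0, config$noise_sd) *
      array_scale[j]
    if (sp == "tolerant" && length(drop_idx))
      col[drop_idx] <- stats::runif(length(drop_idx)) * config$background
    values[, j] <- col
  }

  truth <- list(planted_up = planted_up, planted_down = planted_down,
                dropped_probes = list(tolerant = dropped,
                                      sensitive = character(0)))
  list(exprs = expression_set(values, samples), annotation = annotation,
       truth = truth)
}

#' Simulate a qRT-PCR validation table
#'
#' Samples genes from the regulated rows of a differential-expression table
#' (falling back to all rows when too few are regulated) and produces qPCR
#' fold changes equal to the array fold change perturbed by Gaussian noise on
#' the log10 scale, emulating independent technical validation of a subset of
#' differentially expressed genes.
#'
#' @param de A DE table (as from [de_test()]) with columns `gene_id`, `fc`,
#'   `regulated`, and optionally `tissue`.
#' @param n_genes Number of genes to sample (default 33).
#' @param noise_sd Gaussian noise sd on log10 fold change.
#' @param seed Integer RNG seed.
#' @return Data frame `gene_id`, `tissue`, `fc_array`, `fc_qpcr`.
#' @export
simulate_qpcr <- function(de, n_genes = 33, noise_sd = 0.05, seed = 1) {
  if (n_genes > nrow(de))
    stop("n_genes (", n_genes, ") exceeds available genes (", nrow(de), ")",
         call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  set.seed(seed)
  pool <- de[de$regulated, , drop = FALSE]
  if (nrow(pool) < n_genes) pool <- de
  rows <- pool[sample(nrow(pool), n_genes), , drop = FALSE]
  tissue <- if ("tissue" %in% names(rows)) rows$tissue else NA_character_
  data.frame(gene_id = rows$gene_id, tissue = tissue, fc_array = rows$fc,
             fc_qpcr = 10^(log10(rows$fc) + stats::rnorm(n_genes, 0, noise_sd)),
             stringsAsFactors = FALSE)
}
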