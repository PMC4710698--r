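# Small fixtures built in code.

# Minimal expression set for one species/tissue: two treatment groups with
# n replicates each, values supplied per probe as c(control..., treated...).
make_contrast_exprset <- function(rows, n_rep = 3, species = "tolerant",
                                  tissue = "roots") {
  v <- do.call(rbind, rows)
  rownames(v) <- names(rows)
  samples <- data.frame(
    sample_id = paste0("s", seq_len(2 * n_rep)),
    species = species, tissue = tissue,
    treatment = rep(c("control", "Pb"), each = n_rep),
    replicate = rep(seq_len(n_rep), 2), stringsAsFactors = FALSE)
  colnames(v) <- samples$sample_id
  expression_set(v, samples)
}

# Hand-built DE table.
make_de <- function(gene_id, fc, regulated = fc > 2 | fc < 0.5,
                    species = "tolerant", tissue = "roots") {
  data.frame(gene_id = gene_id, species = species, tissue = tissue,
             mean_control = 1, mean_treated = fc, fc = fc,
             p = ifelse(regulated, 1e-4, 0.9),
             q = ifelse(regulated, 1e-3, 0.95),
             regulated = regulated,
             direction = ifelse(!regulated, "none",
                                ifelse(fc > 1, "up", "down")),
             degenerate = FALSE, stringsAsFactors = FALSE)
}

# Two-species DE tables engineered to reproduce a published-style selection
# ledger for one tissue. `spec` counts: total / up-retained / down-retained;
# `common` counts: total / ratio-pass / up-retained / down-retained.
make_cascade_fixture <- function(tissue, spec_total, spec_up, spec_down,
                                 common_total, ratio_pass, common_up,
                                 common_down) {
  stopifnot(spec_up + spec_down <= spec_total,
            common_up + common_down <= ratio_pass,
            ratio_pass <= common_total)
  n <- spec_total + common_total + 50          # 50 unregulated filler genes
  ids <- sprintf("%s_g%04d", substr(tissue, 1, 1), seq_len(n))
  spec_ids <- ids[seq_len(spec_total)]
  common_ids <- ids[spec_total + seq_len(common_total)]
  fc_tol <- rep(1, n)
  names(fc_tol) <- ids
  # specific: first spec_up above 2, next spec_down below 0.5, rest mid-range
  fc_tol[spec_ids] <- c(rep(4, spec_up), rep(0.25, spec_down),
                        rep(1.5, spec_total - spec_up - spec_down))
  # common ratio-passers: fc_sen = fc_tol / 3 (ratio 3 > 2); ratio-fails:
  # fc_sen = fc_tol (ratio 1)
  pass_ids <- common_ids[seq_len(ratio_pass)]
  fc_tol[pass_ids] <- c(rep(4, common_up), rep(0.25, common_down),
                        rep(1.5, ratio_pass - common_up - common_down))
  fail_ids <- setdiff(common_ids, pass_ids)
  fc_tol[fail_ids] <- 3
  fc_sen <- fc_tol
  fc_sen[pass_ids] <- fc_tol[pass_ids] / 3
  reg_tol <- ids %in% c(spec_ids, common_ids)
  reg_sen <- ids %in% common_ids
  list(de_tol = make_de(ids, unname(fc_tol), reg_tol, "tolerant", tissue),
       de_sen = make_de(ids, unname(fc_sen), reg_sen, "sensitive", tissue),
       tissue = tissue)
}

# Gene -> class map fixture with multi-membership.
make_cmap_fixture <- function() {
  ann <- data.frame(
    gene_id = paste0("g", 1:8),
    classes = c("X;Y", "X", "Y", "Z", "X;Z", "", "Y", "Z"),
    stringsAsFactors = FALSE)
  ann$probe_id <- ann$gene_id
  class_map(ann)
}
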