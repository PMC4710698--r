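test_that("Venn partition splits regulated genes and signs them", {
  de_tol <- make_de(c("g1", "g2", "g3", "g4"), c(3, 4, 0.2, 1.1),
                    regulated = c(TRUE, TRUE, TRUE, FALSE))
  de_sen <- make_de(c("g1", "g2", "g3", "g4"), c(1.2, 0.3, 1.0, 3.0),
                    regulated = c(FALSE, TRUE, FALSE, FALSE),
                    species = "sensitive")
  vp <- venn_partition(de_tol, de_sen, "roots")
  expect_setequal(vp$specific_tolerant, c("g1", "g3"))
  expect_equal(vp$common$gene_id, "g2")
  expect_equal(vp$common$sign, "+-")
  expect_length(vp$specific_sensitive, 0)
  # degenerate: nothing regulated in the sensitive species
  de_sen0 <- make_de(c("g1", "g2", "g3", "g4"), c(1, 1, 1, 1),
                     regulated = FALSE, species = "sensitive")
  vp0 <- venn_partition(de_tol, de_sen0, "roots")
  expect_equal(nrow(vp0$common), 0)
  expect_setequal(vp0$specific_tolerant, c("g1", "g2", "g3"))
  expect_error(venn_partition(de_tol, de_sen[-1, ], "roots"),
               "mismatched gene universes.*g1")
})

test_that("Venn conservation and sign categories hold on simulated data", {
  sim <- simulate_experiment(sim_config(n_probes = 400, n_up = 30,
                                        n_down = 30, seed = 21))
  norm <- median_center_probes(quartile_normalize(sim$exprs))
  raw <- quartile_normalize(sim$exprs)
  des <- list()
  for (sp in c("tolerant", "sensitive")) {
    ret <- background_filter(raw, 50, sp, "roots")
    des[[sp]] <- de_test(norm, sp, "roots", probes = ret,
                         annotation = sim$annotation)
  }
  universe <- intersect(des$tolerant$gene_id, des$sensitive$gene_id)
  dt <- des$tolerant[des$tolerant$gene_id %in% universe, ]
  ds <- des$sensitive[des$sensitive$gene_id %in% universe, ]
  vp <- venn_partition(dt, ds, "roots")
  expect_equal(length(vp$specific_tolerant) + nrow(vp$common),
               sum(dt$regulated))
  expect_equal(length(vp$specific_sensitive) + nrow(vp$common),
               sum(ds$regulated))
  expect_length(intersect(vp$specific_tolerant, vp$common$gene_id), 0)
  # sign categories agree with the DE directions
  if (nrow(vp$common)) {
    plus_minus <- vp$common$gene_id[vp$common$sign == "+-"]
    expect_true(all(dt$fc[match(plus_minus, dt$gene_id)] > 1))
    expect_true(all(ds$fc[match(plus_minus, ds$gene_id)] < 1))
    both_up <- vp$common$gene_id[vp$common$sign == "++"]
    expect_true(all(dt$fc[match(both_up, dt$gene_id)] > 1))
  }
})

test_that("fold-change filter uses strict twofold thresholds", {
  de <- make_de(c("a", "b", "c", "d", "e"),
                c(16.664, 0.499, 1.0, 2.0, 0.5),
                regulated = TRUE)
  out <- fc_filter(de$gene_id, de)
  expect_equal(out$up, "a")        # 16.664 > 2
  expect_equal(out$down, "b")      # 0.499 < 0.5
  # boundary values 2.0 / 0.5 and interior 1.0 are discarded
  expect_false(any(c("c", "d", "e") %in% c(out$up, out$down)))
  expect_error(fc_filter("a", de, hi = 0.9), "thresholds")
})

test_that("cross-species ratio filter retains divergent responses", {
  ids <- c("a", "b", "c")
  de_tol <- make_de(ids, c(4.0, 2.0, 0.2), regulated = TRUE)
  de_sen <- make_de(ids, c(1.5, 2.0, 0.6), regulated = TRUE,
                    species = "sensitive")
  kept <- ratio_filter(ids, de_tol, de_sen)
  expect_setequal(kept, c("a", "c"))  # ratios 2.667 and 0.333; 1.0 removed
  # a discordant gene passes on ratio magnitude alone
  de_tol2 <- make_de("x", 3, TRUE)
  de_sen2 <- make_de("x", 0.4, TRUE, species = "sensitive")
  expect_equal(ratio_filter("x", de_tol2, de_sen2), "x")  # ratio 7.5
})

test_that("candidate accounting reproduces the published selection ledger", {
  roots <- make_cascade_fixture("roots", spec_total = 341, spec_up = 62,
                                spec_down = 59, common_total = 1102,
                                ratio_pass = 315, common_up = 125,
                                common_down = 102)
  vp <- venn_partition(roots$de_tol, roots$de_sen, "roots")
  cs <- candidate_accounting(vp, roots$de_tol, roots$de_sen)
  expect_length(cs$specific_retained_up, 62)
  expect_length(cs$specific_retained_down, 59)
  expect_length(cs$common_ratio_pass, 315)
  expect_length(cs$common_retained_up, 125)
  expect_length(cs$common_retained_down, 102)
  expect_equal(cs$candidate_up, 187)
  expect_equal(cs$candidate_down, 161)
  expect_length(cs$candidates, 348)
  # stage-level count conservation: input = retained + discarded
  acc <- cs$accounting
  expect_equal(acc$n[acc$category == "candidates"],
               acc$n[acc$stage == "fc_filter" & acc$category == "specific"] +
                 acc$n[acc$stage == "fc_filter" & acc$category == "common"])
  expect_lte(acc$n[acc$stage == "ratio_filter"],
             acc$n[acc$category == "common" & acc$stage == "total"])
  expect_equal(cs$candidate_up + cs$candidate_down, length(cs$candidates))
})

test_that("threshold monotonicity: tighter windows retain more genes", {
  fix <- make_cascade_fixture("roots", 50, 20, 15, 80, 40, 18, 12)
  vp <- venn_partition(fix$de_tol, fix$de_sen, "roots")
  wide <- candidate_accounting(vp, fix$de_tol, fix$de_sen,
                               fc_hi = 1e9, fc_lo = 1e-9,
                               ratio_hi = 1e9, ratio_lo = 1e-9)
  expect_length(wide$candidates, 0)
  eps <- 1e-6
  tight <- candidate_accounting(vp, fix$de_tol, fix$de_sen,
                                fc_hi = 1 + eps, fc_lo = 1 - eps,
                                ratio_hi = 1 + eps, ratio_lo = 1 - eps)
  # every regulated gene with fc != 1 and ratio != 1 is retained
  expect_setequal(tight$candidates,
                  c(vp$specific_tolerant, fix$de_tol$gene_id[
                    fix$de_tol$regulated & fix$de_sen$regulated &
                      abs(fix$de_tol$fc / fix$de_sen$fc - 1) > eps]))
  mid <- candidate_accounting(vp, fix$de_tol, fix$de_sen)
  expect_true(all(mid$candidates %in% tight$candidates))
  expect_true(all(wide$candidates %in% mid$candidates))
})

test_that("tissue overlap is the candidate-set intersection", {
  r <- make_cascade_fixture("roots", 30, 10, 10, 20, 10, 5, 3)
  s <- make_cascade_fixture("shoots", 30, 10, 10, 20, 10, 5, 3)
  cs_r <- candidate_accounting(venn_partition(r$de_tol, r$de_sen, "roots"),
                               r$de_tol, r$de_sen)
  cs_s <- candidate_accounting(venn_partition(s$de_tol, s$de_sen, "shoots"),
                               s$de_tol, s$de_sen)
  expect_length(tissue_overlap(cs_r, cs_s), 0)  # ids are tissue-prefixed
  expect_setequal(tissue_overlap(cs_r, cs_r), cs_r$candidates)
  expect_lte(length(tissue_overlap(cs_r, cs_s)),
             min(length(cs_r$candidates), length(cs_s$candidates)))
})
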