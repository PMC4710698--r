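test_that("upper-quartile normalization equalizes 75th percentiles", {
  # hand oracle on two 4-probe arrays, one twice the other
  m <- make_contrast_exprset(list(p1 = c(1, 2, 1, 2, 1, 2),
                                  p2 = c(2, 4, 2, 4, 2, 4),
                                  p3 = c(3, 6, 3, 6, 3, 6),
                                  p4 = c(4, 8, 4, 8, 4, 8)))
  out <- quartile_normalize(m)
  qa <- q75_oracle(c(1, 2, 3, 4))   # 3.25
  qb <- q75_oracle(c(2, 4, 6, 8))   # 6.5
  target <- sqrt(qa * qb)           # geometric mean over the 3 A + 3 B arrays
  q75_out <- apply(out$values, 2, q75_oracle)
  expect_equal(unname(q75_out), rep(target, 6), tolerance = 1e-12)
  # within-array ratios preserved: pure rescaling
  expect_equal(out$values[, 2] / out$values[, 1],
               m$values[, 2] / m$values[, 1] *
                 (q75_oracle(m$values[, 1]) / q75_oracle(m$values[, 2])),
               tolerance = 1e-12)
  expect_equal(out$values["p4", 1] / out$values["p1", 1], 4)
})

test_that("quartile normalization: identity, single array, idempotence", {
  same <- make_contrast_exprset(list(p1 = rep(1, 6), p2 = rep(2, 6),
                                     p3 = rep(3, 6), p4 = rep(4, 6)))
  expect_equal(quartile_normalize(same)$values, same$values)
  single <- expression_set(
    matrix(c(5, 1, 9), 3, 1, dimnames = list(paste0("p", 1:3), "s1")),
    data.frame(sample_id = "s1", species = "tolerant", tissue = "roots",
               treatment = "control", replicate = 1))
  expect_equal(quartile_normalize(single)$values, single$values)
  set.seed(1)
  rnd <- make_contrast_exprset(lapply(stats::setNames(1:20, paste0("p", 1:20)),
                                      function(i) rexp(6) + 0.1))
  once <- quartile_normalize(rnd)
  expect_equal(quartile_normalize(once)$values, once$values,
               tolerance = 1e-9)
  rnd$values[1, 1] <- -1
  expect_error(quartile_normalize(rnd), "positive")
})

test_that("median centering divides by the probe median", {
  m <- make_contrast_exprset(list(p1 = c(2, 4, 8, 2, 4, 8),
                                  p2 = rep(5, 6)), n_rep = 3)
  out <- median_center_probes(m)
  expect_equal(unname(out$values["p1", 1:3]), c(2, 4, 8) / 4)
  expect_equal(unname(out$values["p2", ]), rep(1, 6))
  set.seed(2)
  rnd <- make_contrast_exprset(lapply(stats::setNames(1:30, paste0("p", 1:30)),
                                      function(i) rexp(6) + 0.01))
  meds <- apply(median_center_probes(rnd)$values, 1, median)
  expect_equal(unname(meds), rep(1, 30), tolerance = 1e-12)
})

test_that("log transform is the elementwise log and round-trips", {
  m <- make_contrast_exprset(list(p1 = c(8, 1, 2, 8, 1, 2)))
  expect_equal(unname(log_transform(m, 2)$values[1, 1:3]), c(3, 0, 1))
  expect_equal(unname(log_transform(m, 10)$values[1, 2]), 0)
  set.seed(3)
  rnd <- make_contrast_exprset(list(p1 = rexp(6) + 0.1, p2 = rexp(6) + 0.1))
  back <- 2^log_transform(rnd, 2)$values
  expect_equal(back, rnd$values, tolerance = 1e-12)
  rnd$values[1, 1] <- 0
  expect_error(log_transform(rnd), "positive")
  expect_error(log_transform(make_contrast_exprset(list(p1 = rep(1, 6))),
                             base = 3), "base")
})

test_that("background retention keeps probes with one fully-above condition", {
  m <- make_contrast_exprset(list(
    ctrl_above = c(60, 70, 80, 10, 20, 30),
    neither    = c(60, 40, 80, 10, 20, 30),
    trt_above  = c(10, 20, 30, 60, 70, 80),
    both_above = c(60, 70, 80, 90, 95, 99)))
  kept <- background_filter(m, 50, "tolerant", "roots")
  expect_setequal(kept, c("ctrl_above", "trt_above", "both_above"))
  expect_setequal(background_filter(m, 0, "tolerant", "roots"),
                  rownames(m$values))
})

test_that("DE test matches t.test, handles degenerate rows, calls directions", {
  set.seed(4)
  rows <- lapply(stats::setNames(1:25, paste0("p", 1:25)),
                 function(i) rlnorm(6, 5, 0.5))
  rows$flat <- rep(2, 6)                       # identical groups
  rows$shift <- c(2, 2, 2, 8, 8, 8)            # zero variance, unequal means
  m <- make_contrast_exprset(rows)
  de <- de_test(m, "tolerant", "roots", fdr_threshold = 0.1)
  # cross-check each p against stats::t.test on the log2 values
  for (g in paste0("p", 1:25)) {
    v <- log2(m$values[g, ])
    ref <- stats::t.test(v[4:6], v[1:3], var.equal = TRUE)$p.value
    expect_equal(de$p[de$gene_id == g], ref, tolerance = 1e-12)
  }
  expect_equal(de$p[de$gene_id == "flat"], 1)
  expect_false(de$regulated[de$gene_id == "flat"])
  expect_equal(de$p[de$gene_id == "shift"], 0)
  expect_true(de$degenerate[de$gene_id == "shift"])
  expect_equal(de$direction[de$gene_id == "shift"], "up")
  expect_equal(de$fc[de$gene_id == "shift"], 4)
  # q from BH oracle; invariants q >= p and direction/regulated consistency
  expect_equal(de$q, bh_oracle(de$p), tolerance = 1e-12)
  expect_true(all(de$q >= de$p - 1e-15))
  expect_true(all((de$direction == "up") == (de$regulated & de$fc > 1)))
  expect_true(all((de$direction == "down") == (de$regulated & de$fc < 1)))
  expect_error(de_test(make_contrast_exprset(list(p1 = c(1, 2)), n_rep = 1),
                       "tolerant", "roots"), "replicates")
})

test_that("BH adjustment agrees with the brute-force step-up oracle", {
  # hand case: (0.01, 0.02, 0.03, 0.04) all adjust to 0.04
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  grid <- seq(0.01, 1, by = 0.01)
  set.seed(5)
  for (len in 1:6) {
    for (rep in 1:60) {
      p <- sample(grid, len, replace = TRUE)
      expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p),
                   tolerance = 1e-12)
    }
  }
  # rejection-set monotonicity in alpha
  p <- runif(50)
  q <- stats::p.adjust(p, "BH")
  sets <- lapply(c(0.2, 0.1, 0.05, 0.01), function(a) which(q < a))
  for (i in 2:4) expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("planted genes are recovered and FC survives median centering", {
  hits <- 0
  for (s in 1:5) {
    sim <- simulate_experiment(sim_config(n_probes = 150, n_up = 8,
                                          n_down = 8, fc_planted = 4,
                                          noise_sd = 0.1, seed = s))
    norm <- quartile_normalize(sim$exprs)
    ret <- background_filter(norm, 50, "tolerant", "roots")
    de_raw <- de_test(norm, "tolerant", "roots", probes = ret,
                      annotation = sim$annotation)
    de_cen <- de_test(median_center_probes(norm), "tolerant", "roots",
                      probes = ret, annotation = sim$annotation)
    expect_equal(de_cen$fc, de_raw$fc, tolerance = 1e-12)
    up <- sim$truth$planted_up[["tolerant.roots"]]
    hits <- hits + mean(de_cen$regulated[de_cen$gene_id %in% up] &
                          de_cen$direction[de_cen$gene_id %in% up] == "up")
  }
  expect_gte(hits / 5, 0.95)
})

test_that("regulated-gene summaries report totals and tissue percentages", {
  s <- summarize_regulated(c(1, 0), c(0, 1))
  expect_equal(s$total, 2)
  expect_equal(unname(s$pct), c(50.0, 50.0))
  set.seed(6)
  for (i in 1:20) {
    counts <- sample(0:500, 4)
    s <- summarize_regulated(counts[1:2], counts[3:4])
    expect_equal(s$total, sum(counts))
    if (s$total > 0) expect_lte(abs(sum(s$pct) - 100), 0.1)
    else expect_true(all(is.na(s$pct)))
  }
  de <- make_de(c("a", "b", "c"), c(3, 0.2, 1.2))
  s <- summarize_regulated(de, c(0, 0))
  expect_equal(s$counts$up[1], 1)
  expect_equal(s$counts$down[1], 1)
})
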