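# Evaluation metrics: slopes, null log-ratios, SNR/POT, consistency MADs.

test_that("signal slopes hit the analytic optimum and the OLS oracle", {
  conc <- matrix(c(2, 4, 8, 16), 1, 4,
                 dimnames = list("s1", paste0("a", 1:4)))
  # perfect response: expression = log2(conc) + constant -> slope 1
  e1 <- matrix(log2(conc[1, ]) + 3, 1, 4, dimnames = dimnames(conc))
  got <- signal_detect_slope(e1, conc, n_strata = 1)
  expect_equal(got$per_stratum$slope, 1, tolerance = 1e-12)
  # flat response -> slope 0
  e0 <- matrix(5, 1, 4, dimnames = dimnames(conc))
  expect_equal(signal_detect_slope(e0, conc, 1)$per_stratum$slope, 0)
  # toy regression against the closed-form least-squares solution
  y <- c(1.0, 1.9, 3.1, 3.9)
  e2 <- matrix(y, 1, 4, dimnames = dimnames(conc))
  x <- log2(c(2, 4, 8, 16))
  want <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(signal_detect_slope(e2, conc, 1)$per_stratum$slope, want,
               tolerance = 1e-10)
})

test_that("strata partition the concentrations exhaustively", {
  concs <- c(0, 0.25 * 2^(0:12))
  breaks <- frmakit:::conc_strata_breaks(concs, 3)
  pos <- concs[concs > 0]
  strat <- frmakit:::stratum_of_conc(pos, breaks)
  expect_setequal(strat, 1:3)
  expect_equal(length(strat), 13)
  # contiguous: sorted concentrations have nondecreasing stratum
  expect_true(all(diff(strat[order(pos)]) >= 0))
  # every concentration in exactly one stratum
  expect_equal(table(strat)[["1"]] + table(strat)[["2"]] +
                 table(strat)[["3"]], 13)
})

test_that("null log-ratio statistics match large-sample theory", {
  expect_equal(null_log_ratio_stats(matrix(5, 50, 10),
                                    cbind(1:9, 2:10))[c(1, 2)],
               list(null_sd = 0, null_q995 = 0))
  set.seed(61)
  # expression built so that column differences are exactly N(0, 1)
  n <- 200000
  a <- matrix(rnorm(n), n, 1)
  expr <- cbind(a, a - rnorm(n))           # col1 - col2 ~ N(0,1)
  st <- null_log_ratio_stats(expr, cbind(1, 2))
  expect_lt(abs(st$null_sd - 1), 0.01)
  expect_lt(abs(st$null_q995 - qnorm(0.9975)), 0.02)
  # by construction exactly 0.5% of |ratios| strictly exceed the q995
  expect_equal(mean(abs(st$log_ratios) > st$null_q995), 0.005,
               tolerance = 1e-6)
  expect_error(null_log_ratio_stats(matrix(1, 5, 2), cbind(1, 2)),
               ">= 200")
})

test_that("snr is the slope to null-sd ratio, matching printed triples", {
  triples <- list(c(0.14, 0.47, 0.30), c(0.20, 0.40, 0.50),
                  c(0.69, 0.39, 1.77), c(0.75, 0.34, 2.21),
                  c(0.61, 0.33, 1.85), c(0.60, 0.28, 2.14))
  for (tr in triples)
    expect_equal(round(tr[1] / tr[2], 2), tr[3],
                 tolerance = 0.0051, label = paste(tr, collapse = "/"))
})

test_that("pot agrees with a brute-force rank-and-count oracle", {
  sim <- simulate_spikein(make_latin_square(6), n_batches = 3,
                          n_null_probesets = 60, probes_per_set = 3,
                          spiked_per_group = 2, seed = 67)
  expr <- rma(sim$pm, model_config())$expression
  got <- snr_and_pot(slope = 1, null_sd = 0.3, expr, sim$truth,
                     list_size = 10, target_lfc = 2)
  expect_equal(got$snr, 1 / 0.3)
  # oracle: enumerate all within-batch pairs, all lags, count by sorting
  truth <- sim$truth
  spiked <- names(truth$spiked)[truth$spiked]
  batches <- split(seq_len(ncol(expr)), truth$batch_of[colnames(expr)])
  hits <- 0L; total <- 0L
  for (idx in batches) {
    for (i in idx) for (j in idx) {
      if (i >= j) next
      lr <- log2(truth$concentration[spiked, i] /
                   truth$concentration[spiked, j])
      qual <- spiked[which(is.finite(lr) & abs(abs(lr) - 2) < 1e-9)]
      if (length(qual) == 0) next
      fc <- abs(expr[, i] - expr[, j])
      top <- names(sort(fc, decreasing = TRUE))[1:10]
      hits <- hits + sum(qual %in% top)
      total <- total + length(qual)
    }
  }
  expect_equal(got$pot, hits / total)
  expect_equal(got$n_instances, total)
})

test_that("pot is 1 when true changes dominate a clean simulation", {
  sim <- simulate_spikein(
    make_latin_square(6), n_batches = 2, n_null_probesets = 30,
    probes_per_set = 3, spiked_per_group = 1,
    noise_config = sim_config(sigma = 0.01, tau_fraction = 0,
                              baseline_range = c(3, 12)), seed = 71)
  expr <- rma(sim$pm, model_config())$expression
  got <- snr_and_pot(1, 0.3, expr, sim$truth, list_size = 36,
                     target_lfc = 2)
  expect_equal(got$pot, 1)
})

test_that("consistency MADs behave like a scale estimator", {
  reps <- matrix(rep(c(1, 5, 9), 4), 3, 4)
  rownames(reps) <- paste0("ps", 1:3)
  rep0 <- consistency_mad(reps)
  expect_equal(unname(rep0$mad), c(0, 0, 0))
  expect_equal(rep0$median_mad, 0)
  expect_equal(rep0$iqr_mad, 0)
  set.seed(73)
  s <- 0.3
  noisy <- matrix(rnorm(400 * 100, 0, s), 400, 100) + rnorm(400, 8)
  repn <- consistency_mad(noisy)
  expect_lt(abs(repn$median_mad - s) / s, 0.10)
  # invariant to adding a constant to every replicate
  rep_shift <- consistency_mad(noisy + 3.7)
  expect_equal(rep_shift$mad, repn$mad)
  expect_error(consistency_mad(noisy[, 1, drop = FALSE]), ">= 2")
  expect_error(consistency_mad(list(c(a = 1, b = 2), c(a = 1, c = 2))),
               "mismatched")
})

test_that("more training batches improve replicate consistency", {
  pool <- simulate_training_set(n_probesets = 40, probes_per_set = 4,
                                n_batches = 12, batch_size = 12,
                                seed = 79)$pm
  reps <- run_consistency_experiment(
    pool, list(c(3, 3), c(10, 3)), n_replicates = 8,
    seed = 83, config = no_bg_config())
  expect_lt(reps[[2]]$median_mad, reps[[1]]$median_mad)
  # reproducible under the same seed
  reps2 <- run_consistency_experiment(
    pool, list(c(3, 3), c(10, 3)), n_replicates = 8,
    seed = 83, config = no_bg_config())
  expect_identical(reps[[1]]$mad, reps2[[1]]$mad)
})
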