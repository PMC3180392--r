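# Background model, quantile normalization, median polish, RMA baseline.

test_that("background parameters are recovered from model-generated data", {
  set.seed(101)
  x <- rnorm(50000, 100, 10) + rexp(50000, 1 / 200)
  p <- estimate_background(x)
  expect_lt(abs(p$mu - 100) / 100, 0.15)
  expect_lt(abs(p$sigma - 10) / 10, 0.15)
  expect_lt(abs(p$alpha - 1 / 200) / (1 / 200), 0.15)
})

test_that("a nearly signal-free sample pins the noise mean", {
  set.seed(102)
  x <- rnorm(50000, 100, 1)
  p <- estimate_background(x)
  expect_lt(abs(p$mu - 100), 1)
  p2 <- estimate_background(x, method = "mode")
  expect_lt(abs(p2$mu - 100), 1)
})

test_that("degenerate background inputs are rejected", {
  expect_error(estimate_background(rep(5, 200)), "constant")
  expect_error(estimate_background(runif(50) + 1), ">= 100")
  expect_error(estimate_background(c(rep(1, 99), -2)), "> 0")
})

test_that("background adjustment matches the quadrature posterior mean", {
  cases <- expand.grid(x = c(60, 90, 100, 120, 250),
                       mu = c(80, 100), sigma = c(5, 15),
                       alpha = c(1 / 50, 1 / 300))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    got <- adjust_background(cs$x, list(mu = cs$mu, sigma = cs$sigma,
                                        alpha = cs$alpha))
    want <- oracle_normexp_posterior_mean(cs$x, cs$mu, cs$sigma, cs$alpha)
    expect_equal(got, want, tolerance = 1e-6,
                 label = sprintf("case %d", i))
  }
})

test_that("background adjustment is positive and monotone", {
  p <- list(mu = 100, sigma = 12, alpha = 1 / 150)
  grid <- seq(1, 2000, by = 0.5)
  adj <- adjust_background(grid, p)
  expect_true(all(adj > 0))
  expect_true(all(diff(adj) >= 0))
  # far below the noise mean the posterior mean is tiny but positive
  expect_gt(adjust_background(1, p), 0)
  expect_lt(adjust_background(1, p), adjust_background(100, p))
})

test_that("the reference distribution averages order statistics", {
  # hand sort-and-average: (1,3,2) -> (1,2,3); (2,1,3) -> (1,2,3)
  expect_equal(build_reference(cbind(c(1, 3, 2), c(2, 1, 3))),
               c(1, 2, 3))
  expect_equal(build_reference(cbind(c(1, 3, 2), c(2, 1, 4))),
               c(1, 2, 3.5))
  x <- cbind(c(4, 2, 9), c(4, 2, 9))
  expect_equal(build_reference(x), c(2, 4, 9))
  set.seed(7)
  r <- build_reference(matrix(rnorm(200), 50, 4))
  expect_false(is.unsorted(r))
  expect_error(build_reference(list(1:3, 1:4)), "unequal length")
  expect_error(build_reference(matrix(1:4, 4, 1)), ">= 2 arrays")
})

test_that("quantile mapping preserves ranks and reference multiset", {
  ref <- sort(rnorm(100))
  col <- rnorm(100)
  out <- normalize_to_reference(col, ref)
  expect_equal(sort(out), ref)                     # multiset identity
  expect_equal(rank(out), rank(col))               # rank preservation
  expect_equal(normalize_to_reference(ref, ref), ref)  # identity
  # idempotence against the same reference
  expect_equal(normalize_to_reference(out, ref), out)
  expect_error(normalize_to_reference(col[-1], ref), "length")
})

test_that("ties receive the mean of the reference values they span", {
  ref <- c(10, 20, 30, 40)
  col <- c(5, 1, 1, 7)
  # the tied pair spans ranks 1 and 2 in either assignment; averaging over
  # both assignments gives (10 + 20) / 2 for each
  expect_equal(normalize_to_reference(col, ref), c(30, 15, 15, 40))
  # a three-way tie spans three reference slots
  expect_equal(normalize_to_reference(c(2, 2, 2, 9), ref),
               c(20, 20, 20, 40))
})

test_that("median polish reproduces the literal sweep oracle", {
  m_add <- outer(c(1, 2, 4), c(0, 3, 5, 7), "+")
  mp <- median_polish(m_add)
  expect_equal(max(abs(mp$residuals)), 0)
  expect_equal(mp$row_effects, c(1, 2, 4) - mean(c(1, 2, 4)),
               ignore_attr = TRUE)
  m_out <- matrix(c(1, 2, 3, 2, 3, 4, 3, 4, 50), 3, 3)
  got <- median_polish(m_out)
  want <- oracle_median_polish(m_out)
  expect_equal(got$overall, want$overall)
  expect_equal(unname(got$row_effects), want$row_effects)
  expect_equal(unname(got$col_effects), want$col_effects)
  expect_equal(got$residuals, want$residuals, ignore_attr = TRUE)
  set.seed(33)
  for (k in 1:5) {
    m <- matrix(rnorm(35), 7, 5)
    got <- median_polish(m)
    want <- oracle_median_polish(m)
    expect_equal(got$overall, want$overall)
    expect_equal(got$residuals, want$residuals, ignore_attr = TRUE)
    # exact reconstruction identity
    rec <- got$overall + outer(got$row_effects, got$col_effects, "+") +
      got$residuals
    expect_lt(max(abs(rec - m)), 1e-12)
  }
})

test_that("converged polish residuals have near-zero row/col medians", {
  set.seed(44)
  m <- matrix(rnorm(60), 10, 6)
  mp <- median_polish(m, eps = 1e-9, maxiter = 200)
  # the relative-L1 stopping rule leaves residual medians below the
  # default sweep tolerance, not at machine zero
  expect_lt(max(abs(apply(mp$residuals, 1, median))), 0.01)
  expect_lt(max(abs(apply(mp$residuals, 2, median))), 0.01)
})

test_that("rma recovers known signal profiles on noise-free data", {
  # latin-square signals keep every array's value multiset identical, so
  # quantile normalization is information-preserving and the true
  # per-probeset signal must come back exactly (up to an additive
  # constant per probeset)
  sim <- simulate_spikein(
    make_latin_square(6), n_batches = 2, n_null_probesets = 0,
    probes_per_set = 3, spiked_per_group = 1,
    noise_config = sim_config(sigma = 0, tau_fraction = 0, theta_sd = 0,
                              batch_theta_sd = 0,
                              phi = c(-0.5, 0, 0.5), bg_mu = 0, bg_sd = 0),
    seed = 9)
  res <- rma(sim$pm, no_bg_config())
  truth_sig <- log2(sim$truth$concentration[rownames(res$expression), ] +
                      0.25)
  for (s in rownames(res$expression)) {
    d <- res$expression[s, ] - truth_sig[s, ]
    expect_lt(diff(range(d)), 1e-8)        # constant offset only
    expect_equal(cor(res$expression[s, ], truth_sig[s, ]), 1,
                 tolerance = 1e-10)
  }
  expect_equal(dim(res$expression), c(6, 12))
})

test_that("duplicated arrays receive identical rma expression", {
  pm <- tiny_probe_matrix()
  m <- pm$intensities[, c(1, 2, 2, 3)]
  colnames(m) <- c("a1", "a2", "a2copy", "a3")
  pm2 <- probe_matrix(m, pm$probeset_of)
  res <- rma(pm2, no_bg_config())
  expect_equal(res$expression[, "a2"], res$expression[, "a2copy"],
               ignore_attr = TRUE)
})

test_that("joint quantile normalization equalizes array distributions", {
  set.seed(55)
  L <- matrix(rnorm(300, 8), 100, 3)
  ref <- build_reference(L)
  N <- apply(L, 2, normalize_to_reference, reference = ref)
  expect_equal(sort(N[, 1]), sort(N[, 2]))
  expect_equal(sort(N[, 2]), sort(N[, 3]))
})
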