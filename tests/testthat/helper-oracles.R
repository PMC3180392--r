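# Independent oracles and small fixture builders used across the suite.

# literal sweep-by-sweep median polish (rows first, L1 convergence rule),
# followed by the package's mean-centering convention for the effects
oracle_median_polish <- function(x, eps = 0.01, maxiter = 10L) {
  z <- as.matrix(x)
  nr <- nrow(z); nc <- ncol(z)
  t <- 0
  r <- numeric(nr); c <- numeric(nc)
  oldsum <- 0
  for (iter in 1:maxiter) {
    rdelta <- apply(z, 1, median)
    z <- z - matrix(rdelta, nr, nc)
    r <- r + rdelta
    delta <- median(c)
    c <- c - delta
    t <- t + delta
    cdelta <- apply(z, 2, median)
    z <- z - matrix(cdelta, nr, nc, byrow = TRUE)
    c <- c + cdelta
    delta <- median(r)
    r <- r - delta
    t <- t + delta
    newsum <- sum(abs(z))
    if (newsum == 0 || abs(newsum - oldsum) < eps * newsum) break
    oldsum <- newsum
  }
  list(overall = t + mean(r) + mean(c),
       row_effects = r - mean(r),
       col_effects = c - mean(c),
       residuals = z)
}

# posterior mean of the exponential signal under the normal+exponential
# convolution, by adaptive quadrature over an interval wide enough to
# cover the posterior mass (the posterior is a truncated normal centred
# at b = x - mu - sigma^2 * alpha with SD sigma)
oracle_normexp_posterior_mean <- function(x, mu, sigma, alpha) {
  b <- x - mu - sigma^2 * alpha
  lo <- 0
  hi <- max(b + 40 * sigma, 40 * sigma)
  dens <- function(s) exp(-alpha * s) * dnorm(x - s, mu, sigma)
  num <- integrate(function(s) s * dens(s), lo, hi, rel.tol = 1e-12,
                   abs.tol = 0)$value
  den <- integrate(dens, lo, hi, rel.tol = 1e-12, abs.tol = 0)$value
  num / den
}

# ordinary least-squares fit of Y[j,i] = theta_i + phi_j via the normal
# equations, with phi constrained to sum to zero (for a complete two-way
# layout this reduces to row/column means)
oracle_ols_two_way <- function(Y) {
  theta <- colMeans(Y)
  phi <- rowMeans(Y - rep(theta, each = nrow(Y)))
  shift <- mean(phi)
  list(probe_effects = phi - shift, array_effects = theta + shift)
}

# area under the ROC curve via the rank-sum statistic (ties get half credit)
oracle_auc <- function(positives, negatives) {
  n1 <- length(positives); n0 <- length(negatives)
  (sum(rank(c(positives, negatives))[seq_len(n1)]) -
      n1 * (n1 + 1) / 2) / (n1 * n0)
}

# tiny hand-assembled probe matrix: 2 probesets x 2 probes, 4 arrays in
# 2 batches, intensities on the raw scale
tiny_probe_matrix <- function(seed = 1) {
  set.seed(seed)
  m <- matrix(2^(rnorm(16, 8, 1)), 4, 4,
              dimnames = list(c("p1", "p2", "p3", "p4"),
                              c("a1", "a2", "a3", "a4")))
  probe_matrix(m, setNames(c("psA", "psA", "psB", "psB"),
                           c("p1", "p2", "p3", "p4")),
               setNames(c("b1", "b1", "b2", "b2"),
                        c("a1", "a2", "a3", "a4")))
}

# hand-built frozen bundle over `pm`'s probes with constant variances
flat_frozen_vectors <- function(pm, reference, phi = NULL, sigma2 = 0.04,
                                tau2 = 0.01, median_se = NULL) {
  np <- n_probes(pm)
  if (is.null(phi)) phi <- rep(0, np)
  sets <- split(seq_len(np),
                factor(pm$probeset_of, levels = unique(pm$probeset_of)))
  avg_sd <- vapply(sets, function(i) mean(sqrt(sigma2 + tau2)), numeric(1))
  frozen_vectors(reference_distribution = sort(reference),
                 probe_effects = phi,
                 within_batch_var = rep(sigma2, np),
                 between_batch_var = rep(tau2, np),
                 probeset_avg_sd = avg_sd,
                 median_se = median_se,
                 probe_ids = rownames(pm$intensities),
                 probeset_of = pm$probeset_of)
}

withr_local_tempdir <- function(env = parent.frame()) {
  d <- tempfile("frmakit-test-")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}

no_bg_config <- function(...) {
  model_config(bg_correct = FALSE, compute_median_se = FALSE, ...)
}
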