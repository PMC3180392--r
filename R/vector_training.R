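# Frozen-vector training: robust probe-level model fitting, variance
# decomposition across batches, and assembly of the full bundle.

#' Robust two-way probe-level fit
#'
#' Fits the additive probe-level model `Y[j, i] = theta_i + phi_j + e` to
#' one probeset's log2 normalized submatrix by iteratively reweighted
#' least squares with Huber weights.  The residual scale is re-estimated
#' each iteration by the MAD (about zero); probe effects are constrained
#' to sum to zero so that `theta` absorbs the probeset mean and `phi` is
#' comparable across trainings.
#'
#' @param Y Numeric matrix, probes x arrays (>= 1 probe, >= 3 arrays).
#' @param huber_c Huber tuning constant.
#' @param max_iter Maximum IRLS iterations.
#' @param tol Convergence tolerance on the maximum parameter change.
#' @return An object of class `probe_level_fit`: `probe_effects` (phi),
#'   `array_effects` (theta), `residuals`, `converged`, `n_iterations`.
#' @export
fit_probe_effects <- function(Y, huber_c = 1.345, max_iter = 50L,
                              tol = 1e-6) {
  Y <- as.matrix(Y)
  J <- nrow(Y); N <- ncol(Y)
  if (J < 1 || N < 3) stop_("need >= 1 probe and >= 3 arrays (got %dx%d)", J, N)
  if (J == 1) {
    return(structure(list(
      probe_effects = setNames(0, rownames(Y)),
      array_effects = setNames(Y[1, ], colnames(Y)),
      residuals = matrix(0, 1, N, dimnames = dimnames(Y)),
      converged = TRUE, n_iterations = 0L),
      class = "probe_level_fit"))
  }
  theta <- apply(Y, 2, median)
  phi <- apply(Y - rep(theta, each = J), 1, median)
  phi <- phi - mean(phi)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    R <- Y - outer(phi, theta, "+")
    s <- mad(R, center = 0)
    if (s < 1e-10) { converged <- TRUE; break }
    u <- abs(R) / s
    w <- ifelse(u <= huber_c, 1, huber_c / u)
    theta_new <- colSums(w * (Y - phi)) / colSums(w)
    phi_new <- rowSums(w * (Y - rep(theta_new, each = J))) / rowSums(w)
    shift <- mean(phi_new)
    phi_new <- phi_new - shift
    theta_new <- theta_new + shift
    delta <- max(abs(c(theta_new - theta, phi_new - phi)))
    theta <- theta_new
    phi <- phi_new
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(list(probe_effects = setNames(phi, rownames(Y)),
                 array_effects = setNames(theta, colnames(Y)),
                 residuals = Y - outer(phi, theta, "+"),
                 converged = converged, n_iterations = iter),
            class = "probe_level_fit")
}

#' Within- and between-batch residual variances
#'
#' Moment decomposition of probe-level residual variance across batches.
#' For each probe, the within-batch variance is the mean over batches of
#' the within-batch sample variance; the between-batch variance is the
#' variance of the batch-mean residuals minus its within-batch sampling
#' contribution (`sigma2 / k_tilde`, with `k_tilde` the harmonic-mean
#' batch size), truncated below at `variance_floor`.  Batches with fewer
#' than two arrays are excluded.
#'
#' @param residuals Numeric matrix, probes x arrays, of probe-level fit
#'   residuals (log2 scale).
#' @param batch Character or factor of batch labels, one per array.
#' @param variance_floor Lower bound for both variance estimates.
#' @return List with numeric vectors `within` (sigma2) and `between`
#'   (tau2), per probe, plus `batch_sizes` of the batches used.
#' @export
estimate_batch_variances <- function(residuals, batch,
                                     variance_floor = 1e-8) {
  residuals <- as.matrix(residuals)
  if (length(batch) != ncol(residuals))
    stop_("batch labels (%d) do not match arrays (%d)",
          length(batch), ncol(residuals))
  batch <- as.character(batch)
  sizes <- table(batch)
  usable <- names(sizes)[sizes >= 2]
  if (length(usable) < 2)
    stop_("need >= 2 batches with >= 2 arrays; only %d usable",
          length(usable))
  idx <- lapply(usable, function(b) which(batch == b))
  nk <- lengths(idx)
  means <- vapply(idx, function(i) rowMeans(residuals[, i, drop = FALSE]),
                  numeric(nrow(residuals)))
  vars <- vapply(seq_along(idx), function(k) {
    d <- residuals[, idx[[k]], drop = FALSE] - means[, k]
    rowSums(d^2) / (nk[k] - 1)
  }, numeric(nrow(residuals)))
  sigma2 <- rowMeans(vars)
  k_tilde <- length(nk) / sum(1 / nk)
  grand <- rowMeans(means)
  between_raw <- rowSums((means - grand)^2) / (length(nk) - 1)
  tau2 <- pmax(variance_floor, between_raw - sigma2 / k_tilde)
  sigma2 <- pmax(variance_floor, sigma2)
  names(sigma2) <- names(tau2) <- rownames(residuals)
  list(within = sigma2, between = tau2,
       batch_sizes = setNames(as.integer(nk), usable))
}

#' Train frozen parameter vectors
#'
#' The training core: background-corrects the batch-labelled training
#' arrays, builds (or accepts) the reference quantile distribution,
#' quantile-normalizes every array to it, and per probeset fits the
#' robust probe-level model ([fit_probe_effects()]) and decomposes the
#' residual variance across batches ([estimate_batch_variances()]).  The
#' probeset average SD is the mean over a probeset's probes of
#' `sqrt(sigma2 + tau2)`.  When `config$compute_median_se` is `TRUE`, the
#' optional sixth vector is obtained by applying [frma_single()] with
#' these vectors back to each training array and taking the per-probeset
#' median standard error.
#'
#' @param pm A [probe_matrix()] with batch labels (>= 2 batches of >= 2
#'   arrays, >= 3 arrays total).
#' @param config A [model_config()].
#' @param reference Optional fixed reference distribution (log2 scale) to
#'   normalize against instead of one built from the training arrays;
#'   sharing a reference across trainings removes normalization bias
#'   between them.
#' @return A [frozen_vectors()] bundle.  Probesets whose fit fails are
#'   dropped and recorded in `metadata$dropped_probesets`.
#' @export
make_vectors <- function(pm, config = model_config(), reference = NULL) {
  stopifnot(inherits(pm, "probe_matrix"))
  config <- as_model_config(config)
  if (is.null(pm$batch_of)) stop_("training data must carry batch labels")
  if (n_arrays(pm) < 3) stop_("need >= 3 training arrays")
  L <- preprocess_log2(pm$intensities, config$bg_correct)
  if (is.null(reference)) reference <- build_reference(L)
  N <- apply(L, 2, normalize_to_reference, reference = reference)
  rownames(N) <- rownames(L)
  sets <- split_probesets(pm$probeset_of)
  batch <- unname(pm$batch_of[colnames(N)])
  keep <- logical(length(sets))
  phi <- sigma2 <- tau2 <- numeric(0)
  avg_sd <- numeric(length(sets))
  names(avg_sd) <- names(sets)
  res_list <- vector("list", length(sets))
  for (k in seq_along(sets)) {
    rows <- sets[[k]]
    fit <- tryCatch({
      f <- fit_probe_effects(N[rows, , drop = FALSE],
                             huber_c = config$huber_c,
                             max_iter = config$max_iter)
      bv <- estimate_batch_variances(f$residuals, batch,
                                     variance_floor = config$variance_floor)
      list(f = f, bv = bv)
    }, error = function(e) NULL)
    if (is.null(fit)) next
    keep[k] <- TRUE
    phi <- c(phi, fit$f$probe_effects)
    sigma2 <- c(sigma2, fit$bv$within)
    tau2 <- c(tau2, fit$bv$between)
    avg_sd[k] <- mean(sqrt(fit$bv$within + fit$bv$between))
  }
  if (!any(keep)) stop_("no probeset could be fitted")
  dropped <- names(sets)[!keep]
  if (length(dropped) > 0) {
    # the frozen reference must span exactly the retained probes, so
    # retrain on the reduced probe set (rebuilding the reference)
    message(sprintf("dropping %d unfittable probeset(s): %s",
                    length(dropped), paste(dropped, collapse = ", ")))
    keep_rows <- unlist(sets[keep], use.names = FALSE)
    pm2 <- probe_matrix(pm$intensities[keep_rows, , drop = FALSE],
                        pm$probeset_of[keep_rows], pm$batch_of)
    fv <- make_vectors(pm2, config, reference = NULL)
    fv$metadata$dropped_probesets <- as.list(dropped)
    return(fv)
  }
  probe_rows <- unlist(sets[keep], use.names = FALSE)
  probe_ids <- rownames(N)[probe_rows]
  probeset_of <- pm$probeset_of[probe_ids]
  fv <- frozen_vectors(
    reference_distribution = reference,
    probe_effects = phi,
    within_batch_var = sigma2,
    between_batch_var = tau2,
    probeset_avg_sd = avg_sd[keep],
    median_se = NULL,
    probe_ids = probe_ids,
    probeset_of = probeset_of,
    metadata = list(n_training_arrays = n_arrays(pm),
                    n_batches = length(unique(batch)),
                    seed = config$seed,
                    dropped_probesets = list()))
  if (config$compute_median_se) {
    ses <- vapply(seq_len(n_arrays(pm)), function(i) {
      frma_single(pm$intensities[probe_ids, i], fv, config)$stderr
    }, numeric(length(unique(probeset_of))))
    fv$median_se <- setNames(apply(ses, 1, median),
                             unique(unname(probeset_of)))
    validate_frozen_vectors(fv)
  }
  fv
}
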