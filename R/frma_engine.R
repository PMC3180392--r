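# Apply frozen parameter vectors to new arrays: single-array (or
# small-batch) preprocessing with variance-based probe down-weighting.

#' Preprocess one array against frozen vectors
#'
#' Background-corrects the raw column, quantile-normalizes it against the
#' frozen reference distribution, subtracts the frozen probe effects, and
#' summarizes each probeset by a robust precision-weighted mean: the base
#' weight of probe j is `1 / (sigma2_j + tau2_j)` (down-weighting probes
#' with large frozen within- or between-batch variance), multiplied by
#' Huber weights on the standardized residuals from an IRLS loop
#' (down-weighting outlying observations on this particular array).  The
#' standard error is `sqrt(1 / sum(final weights))`; when the bundle
#' carries the optional median-SE vector, the quality score is the ratio
#' of each probeset's SE to its frozen median SE (a score of 1 marks
#' typical training-array quality).
#'
#' Because every quantity other than the raw column is frozen, the result
#' for an array never depends on which other arrays are processed with it.
#'
#' @param column Numeric vector of raw intensities for one array, in the
#'   probe order of `fv` (checked against names when present).
#' @param fv A [frozen_vectors()] bundle.
#' @param config A [model_config()].
#' @return List with `expression`, `stderr`, `quality` (per probeset;
#'   `quality` is `NULL` without the median-SE vector) and `probe_weights`
#'   (per probe).
#' @export
frma_single <- function(column, fv, config = model_config()) {
  stopifnot(inherits(fv, "frozen_vectors"))
  config <- as_model_config(config)
  np <- length(fv$probe_ids)
  if (length(column) != np)
    stop_("column length %d does not match frozen probe count %d",
          length(column), np)
  if (!is.null(names(column)) && !identical(names(column), fv$probe_ids))
    stop_("probe order of the input column does not match the frozen bundle")
  if (config$bg_correct)
    column <- adjust_background(column, estimate_background(column))
  y <- normalize_to_reference(log2(column), fv$reference_distribution)
  e <- y - fv$probe_effects
  v <- pmax(fv$within_batch_var + fv$between_batch_var,
            config$variance_floor)
  sets <- split_probesets(fv$probeset_of)
  ns <- length(sets)
  expr <- se <- numeric(ns)
  weights <- numeric(np)
  for (k in seq_len(ns)) {
    rows <- sets[[k]]
    ek <- e[rows]; vk <- v[rows]
    if (length(rows) == 1) {
      expr[k] <- ek
      se[k] <- sqrt(vk)
      weights[rows] <- 1 / vk
      next
    }
    w0 <- 1 / vk
    sk <- sqrt(vk)
    theta <- sum(w0 * ek) / sum(w0)
    w <- w0
    for (it in seq_len(config$max_iter)) {
      u <- abs(ek - theta) / sk
      h <- ifelse(u <= config$huber_c, 1, config$huber_c / u)
      w <- w0 * h
      theta_new <- sum(w * ek) / sum(w)
      if (abs(theta_new - theta) < config$convergence_tol) {
        theta <- theta_new
        break
      }
      theta <- theta_new
    }
    expr[k] <- theta
    se[k] <- sqrt(1 / sum(w))
    weights[rows] <- w
  }
  names(expr) <- names(se) <- names(sets)
  names(weights) <- fv$probe_ids
  quality <- NULL
  if (!is.null(fv$median_se))
    quality <- se / fv$median_se[names(se)]
  list(expression = expr, stderr = se, quality = quality,
       probe_weights = weights)
}

#' Preprocess a batch of arrays against frozen vectors
#'
#' Applies [frma_single()] independently to each column; column i of the
#' result equals a standalone `frma_single()` call on array i exactly, so
#' estimates are invariant to the composition of the batch.
#'
#' @param pm A [probe_matrix()] whose probes match the frozen bundle.
#' @param fv A [frozen_vectors()] bundle.
#' @param config A [model_config()].
#' @return An [expression_result()] with expression, standard errors,
#'   probe weights and (when available) quality scores.
#' @export
frma_batch <- function(pm, fv, config = model_config()) {
  stopifnot(inherits(pm, "probe_matrix"), inherits(fv, "frozen_vectors"))
  config <- as_model_config(config)
  if (!identical(rownames(pm$intensities), fv$probe_ids))
    stop_("probe set/order of the input does not match the frozen bundle")
  cols <- lapply(seq_len(n_arrays(pm)), function(i)
    frma_single(pm$intensities[, i], fv, config))
  arr <- colnames(pm$intensities)
  expr <- do.call(cbind, lapply(cols, `[[`, "expression"))
  se <- do.call(cbind, lapply(cols, `[[`, "stderr"))
  w <- do.call(cbind, lapply(cols, `[[`, "probe_weights"))
  colnames(expr) <- colnames(se) <- colnames(w) <- arr
  quality <- NULL
  if (!is.null(fv$median_se)) {
    quality <- do.call(cbind, lapply(cols, `[[`, "quality"))
    colnames(quality) <- arr
  }
  expression_result(expression = expr, stderr = se, probe_weights = w,
                    quality = quality)
}
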