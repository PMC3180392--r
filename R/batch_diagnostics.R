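# Per-probe batch-effect diagnostics: one-way ANOVA F statistics on
# probe-level residuals, and a dataset-level summary.

#' Per-probe batch-effect F statistics
#'
#' For each probe, performs a one-way ANOVA of its residuals across
#' batches: F is the ratio of the between-batch to the within-batch mean
#' square, with (B - 1, N - B) degrees of freedom.  A large F flags a
#' probe whose behaviour shifts between batches.  The summary fraction of
#' probes significant at `alpha` (unadjusted, plus a Benjamini-Hochberg
#' adjusted companion) measures the extent of batch effects in the
#' dataset as a whole.
#'
#' @param residuals Numeric matrix, probes x arrays, of probe-level
#'   residuals (or normalized log2 intensities, for a per-probe location
#'   comparison).
#' @param batch Batch label per array; batches with fewer than two arrays
#'   are excluded, and at least two usable batches are required.
#' @param alpha Significance level for the summary fraction.
#' @return An object of class `batch_effect_report`: `f_stat`, `p_value`,
#'   `p_adjusted` (BH), `fraction_significant`,
#'   `fraction_significant_adjusted`, `batch_sizes`, `df`, `alpha`.
#' @export
probe_f_statistics <- function(residuals, batch, alpha = 0.05) {
  residuals <- as.matrix(residuals)
  stopifnot(alpha > 0, alpha < 1)
  if (length(batch) != ncol(residuals))
    stop_("batch labels (%d) do not match arrays (%d)",
          length(batch), ncol(residuals))
  batch <- as.character(batch)
  sizes <- table(batch)
  usable <- names(sizes)[sizes >= 2]
  if (length(usable) < 2)
    stop_("need >= 2 batches with >= 2 arrays; only %d usable",
          length(usable))
  keep <- batch %in% usable
  R <- residuals[, keep, drop = FALSE]
  b <- factor(batch[keep])
  nk <- as.vector(table(b))
  B <- nlevels(b)
  N <- ncol(R)
  ind <- outer(b, levels(b), "==") * 1            # arrays x batches
  means <- (R %*% ind) %*% diag(1 / nk, B)         # probes x batches
  grand <- rowMeans(R)
  ssb <- rowSums(sweep(means - grand, 2, nk, "*") * (means - grand))
  ssw <- rowSums((R - means[, as.integer(b), drop = FALSE])^2)
  msb <- ssb / (B - 1)
  msw <- ssw / (N - B)
  f <- msb / msw
  p <- pf(f, B - 1, N - B, lower.tail = FALSE)
  padj <- p.adjust(p, method = "BH")
  names(f) <- names(p) <- names(padj) <- rownames(residuals)
  structure(list(f_stat = f, p_value = p, p_adjusted = padj,
                 fraction_significant = mean(p < alpha),
                 fraction_significant_adjusted = mean(padj < alpha),
                 batch_sizes = setNames(nk, levels(b)),
                 df = c(B - 1, N - B), alpha = alpha),
            class = "batch_effect_report")
}

#' @export
print.batch_effect_report <- function(x, ...) {
  cat(sprintf(paste0("batch_effect_report: %d probes, %d batches; ",
                     "%.1f%% significant at alpha = %g ",
                     "(%.1f%% after BH adjustment)\n"),
              length(x$f_stat), length(x$batch_sizes),
              100 * x$fraction_significant, x$alpha,
              100 * x$fraction_significant_adjusted))
  invisible(x)
}

#' Dataset-level batch-effect diagnosis
#'
#' Convenience wrapper: preprocesses a batch-labelled probe matrix
#' (background correction, joint quantile normalization, log2), fits the
#' robust probe-level model per probeset, and runs
#' [probe_f_statistics()] on the pooled residuals.
#'
#' @param pm A [probe_matrix()] with batch labels.
#' @param config A [model_config()]; `alpha` sets the significance level.
#' @return A `batch_effect_report`.
#' @export
diagnose_batch_effects <- function(pm, config = model_config()) {
  stopifnot(inherits(pm, "probe_matrix"))
  config <- as_model_config(config)
  if (is.null(pm$batch_of)) stop_("probe matrix has no batch labels")
  L <- preprocess_log2(pm$intensities, config$bg_correct)
  reference <- build_reference(L)
  N <- apply(L, 2, normalize_to_reference, reference = reference)
  rownames(N) <- rownames(L)
  sets <- split_probesets(pm$probeset_of)
  res <- matrix(NA_real_, nrow(N), ncol(N), dimnames = dimnames(N))
  for (rows in sets) {
    fit <- fit_probe_effects(N[rows, , drop = FALSE],
                             huber_c = config$huber_c,
                             max_iter = config$max_iter)
    res[rows, ] <- fit$residuals
  }
  probe_f_statistics(res, unname(pm$batch_of[colnames(N)]),
                     alpha = config$alpha)
}
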