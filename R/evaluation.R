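# Assessment metrics: spike-in accuracy/precision (signal-detect slope,
# null log-ratio SD and 99.5th percentile, SNR, POT) and the training
# consistency (MAD) protocol.

# split the distinct positive concentrations into n_strata contiguous
# groups; returns the upper boundary of each group for interval lookup
conc_strata_breaks <- function(concs, n_strata = 3) {
  d <- sort(unique(concs[is.finite(concs) & concs > 0]))
  if (length(d) < n_strata)
    stop_("only %d distinct positive concentrations for %d strata",
          length(d), n_strata)
  grp <- ceiling(seq_along(d) * n_strata / length(d))
  vapply(seq_len(n_strata), function(s) max(d[grp == s]), numeric(1))
}

stratum_of_conc <- function(conc, breaks) {
  findInterval(conc, c(-Inf, breaks[-length(breaks)]), left.open = FALSE)
}

stratum_labels <- function(n) {
  if (n == 3) c("low", "medium", "high") else paste0("stratum", seq_len(n))
}

#' Signal-detection slope per expression stratum
#'
#' For each spiked probeset, regresses observed expression on log2 nominal
#' concentration (least squares over the arrays whose concentration for
#' that probeset is positive and falls in the stratum).  A slope of 1 is
#' optimal: it is the expected observed difference when the true change is
#' a doubling.  Strata partition the distinct positive concentrations into
#' `n_strata` contiguous groups (tertiles by default).
#'
#' @param expression Probeset x array matrix of expression estimates
#'   (rows must include the spiked probesets).
#' @param concentration Matching matrix of nominal concentrations (pM; NA
#'   or 0 entries are ignored in the regression).
#' @param n_strata Number of concentration strata.
#' @return List with `per_stratum` (data.frame: stratum, mean slope, SD
#'   over probesets, n), `slopes` (probeset x stratum matrix), `breaks`.
#' @export
signal_detect_slope <- function(expression, concentration, n_strata = 3) {
  ids <- rownames(concentration)
  if (!all(ids %in% rownames(expression)))
    stop_("expression is missing spiked probesets")
  expression <- expression[ids, colnames(concentration), drop = FALSE]
  breaks <- conc_strata_breaks(concentration, n_strata)
  slopes <- matrix(NA_real_, length(ids), n_strata,
                   dimnames = list(ids, stratum_labels(n_strata)))
  for (p in seq_along(ids)) {
    conc <- concentration[p, ]
    ok <- is.finite(conc) & conc > 0
    if (!any(ok)) next
    strat <- stratum_of_conc(conc[ok], breaks)
    x_all <- log2(conc[ok]); y_all <- expression[p, ok]
    for (s in seq_len(n_strata)) {
      x <- x_all[strat == s]; y <- y_all[strat == s]
      if (length(unique(x)) < 2) next
      slopes[p, s] <- sum((x - mean(x)) * (y - mean(y))) /
        sum((x - mean(x))^2)
    }
  }
  per_stratum <- data.frame(
    stratum = stratum_labels(n_strata),
    slope = colMeans(slopes, na.rm = TRUE),
    slope_sd = apply(slopes, 2, sd, na.rm = TRUE),
    n = colSums(!is.na(slopes)),
    row.names = NULL)
  list(per_stratum = per_stratum, slopes = slopes, breaks = breaks)
}

#' Null log-ratio precision statistics
#'
#' Log-ratios from probesets with no true change estimate the precision
#' of a preprocessing method: their SD measures typical variability and
#' the 99.5th percentile of their absolute values flags outliers -- 0.5%
#' of unchanged probesets are expected to exceed it.
#'
#' @param expression Matrix of expression estimates for null probesets.
#' @param pairs Two-column integer matrix of array-column pairs to
#'   difference.
#' @return List with `null_sd`, `null_q995` (empirical, inverted-ECDF
#'   quantile), `n`, and the `log_ratios` themselves.
#' @export
null_log_ratio_stats <- function(expression, pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  lr <- as.vector(expression[, pairs[, 1], drop = FALSE] -
                    expression[, pairs[, 2], drop = FALSE])
  if (length(lr) < 200)
    stop_("only %d null log-ratios; need >= 200", length(lr))
  list(null_sd = sd(lr),
       null_q995 = quantile(abs(lr), 0.995, type = 1, names = FALSE),
       n = length(lr), log_ratios = lr)
}

# all ordered within-batch array pairs at the given lag(s)
within_batch_pairs <- function(batch_of, lag = 1) {
  out <- lapply(split(seq_along(batch_of), batch_of), function(idx) {
    do.call(rbind, lapply(lag, function(l) {
      if (length(idx) <= l) return(NULL)
      cbind(idx[seq_len(length(idx) - l)], idx[-seq_len(l)])
    }))
  })
  do.call(rbind, out)
}

#' Signal-to-noise ratio and top-list detection probability
#'
#' `snr = slope / null_sd` summarizes accuracy relative to precision.
#' POT is the probability that a probeset with a true log2 fold change of
#' `target_lfc` ranks among the `list_size` probesets with the largest
#' observed absolute fold change: for every within-batch array pair in
#' which some spiked probeset has a true log2 concentration ratio of
#' `target_lfc`, all probesets are ranked by observed |fold change| and
#' the qualifying probesets are counted against the top of the list.
#'
#' @param slope Signal-detection slope (scalar or per-stratum vector).
#' @param null_sd Null log-ratio SD (matching `slope`), > 0.
#' @param expression Probeset x array matrix (all probesets).
#' @param truth A `spikein_truth` with `concentration` and `batch_of`.
#' @param list_size Size of the top list.
#' @param target_lfc True absolute log2 fold change defining a detection.
#' @return List with `snr`, `pot`, and `n_instances` used for POT.
#' @export
snr_and_pot <- function(slope, null_sd, expression, truth,
                        list_size = 100, target_lfc = 2) {
  if (any(null_sd == 0)) stop_("null_sd must be positive")
  snr <- slope / null_sd
  pot <- pot_by_stratum(expression, truth, list_size, target_lfc,
                        breaks = NULL)
  list(snr = snr, pot = pot$pot, n_instances = pot$n)
}

# POT, optionally stratified by the geometric-mean concentration of the
# qualifying pair; breaks = NULL pools all instances
pot_by_stratum <- function(expression, truth, list_size = 100,
                           target_lfc = 2, breaks = NULL) {
  conc <- truth$concentration
  spiked <- rownames(conc)[truth$spiked[rownames(conc)]]
  # all within-batch pairs, every lag, so every achievable true fold
  # change between co-hybridized arrays is represented
  pairs <- within_batch_pairs(truth$batch_of[colnames(expression)],
                              lag = seq_len(max(table(truth$batch_of)) - 1))
  lconc <- log2(conc[spiked, colnames(expression), drop = FALSE])
  n_strata <- if (is.null(breaks)) 1L else length(breaks)
  hits <- total <- integer(n_strata)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    dl <- lconc[, i] - lconc[, j]
    qual <- which(is.finite(dl) & abs(abs(dl) - target_lfc) < 1e-9)
    if (length(qual) == 0) next
    fc <- abs(expression[, i] - expression[, j])
    top <- rank(-fc, ties.method = "min")[spiked[qual]] <= list_size
    s <- if (is.null(breaks)) rep(1L, length(qual)) else
      stratum_of_conc(sqrt(conc[spiked[qual], i] * conc[spiked[qual], j]),
                      breaks)
    for (k in seq_along(qual)) {
      hits[s[k]] <- hits[s[k]] + top[k]
      total[s[k]] <- total[s[k]] + 1L
    }
  }
  list(pot = ifelse(total > 0, hits / total, NA_real_), n = total)
}

#' Full spike-in evaluation report
#'
#' Computes the complete accuracy/precision panel for one expression
#' matrix derived from a simulated latin-square spike-in dataset: per
#' stratum, the signal-detection slope (and its SD over probesets), the
#' null log-ratio SD and 99.5th percentile, SNR, and POT.  Spiked
#' probesets are stratified by nominal concentration; null probesets by
#' tertiles of their average observed expression; null log-ratios are
#' taken over adjacent within-batch array pairs.
#'
#' @param expression Probeset x array expression matrix (all probesets of
#'   the simulated dataset).
#' @param truth The `spikein_truth` from [simulate_spikein()].
#' @param n_strata Number of strata.
#' @param list_size,target_lfc POT parameters (see [snr_and_pot()]).
#' @return An object of class `evaluation_report`: a data.frame with one
#'   row per stratum and columns `stratum`, `slope`, `slope_sd`,
#'   `null_sd`, `null_q995`, `snr`, `pot`.
#' @export
spikein_report <- function(expression, truth, n_strata = 3,
                           list_size = 100, target_lfc = 2) {
  stopifnot(inherits(truth, "spikein_truth"))
  if (is.null(truth$concentration))
    stop_("truth carries no spike-in design")
  spiked <- names(truth$spiked)[truth$spiked]
  nulls <- names(truth$spiked)[!truth$spiked]
  sds <- signal_detect_slope(expression,
                             truth$concentration[spiked, , drop = FALSE],
                             n_strata)
  pairs <- within_batch_pairs(truth$batch_of[colnames(expression)], lag = 1)
  nexp <- expression[nulls, , drop = FALSE]
  avg <- rowMeans(nexp)
  qs <- quantile(avg, probs = seq_len(n_strata - 1) / n_strata,
                 names = FALSE)
  nstrat <- findInterval(avg, c(-Inf, qs))
  null_sd <- null_q995 <- numeric(n_strata)
  for (s in seq_len(n_strata)) {
    st <- null_log_ratio_stats(nexp[nstrat == s, , drop = FALSE], pairs)
    null_sd[s] <- st$null_sd
    null_q995[s] <- st$null_q995
  }
  pot <- pot_by_stratum(expression, truth, list_size, target_lfc,
                        breaks = sds$breaks)
  rep <- data.frame(stratum = stratum_labels(n_strata),
                    slope = sds$per_stratum$slope,
                    slope_sd = sds$per_stratum$slope_sd,
                    null_sd = null_sd, null_q995 = null_q995,
                    snr = sds$per_stratum$slope / null_sd,
                    pot = pot$pot, row.names = NULL)
  structure(rep, class = c("evaluation_report", "data.frame"))
}

#' Consistency of expression estimates across replicate trainings
#'
#' Given expression vectors for one fixed test array preprocessed against
#' several independently trained frozen bundles, computes the per-probeset
#' median absolute deviation (MAD, scaled by 1.4826) across replicates
#' and summarizes it by its median and inter-quartile range.  Smaller
#' values mean more reproducible frozen vectors.
#'
#' @param replicates Probeset x replicate matrix, or a list of named
#'   per-probeset expression vectors (identical probeset sets required).
#' @param design Optional list/vector describing the training design
#'   (recorded in the report).
#' @return An object of class `consistency_report`: `mad` (per probeset),
#'   `median_mad`, `iqr_mad`, `n_replicates`, `design`.
#' @export
consistency_mad <- function(replicates, design = NULL) {
  if (is.list(replicates) && !is.matrix(replicates)) {
    nms <- lapply(replicates, names)
    if (any(!vapply(nms[-1], identical, logical(1), nms[[1]])))
      stop_("replicates have mismatched probeset sets")
    replicates <- do.call(cbind, replicates)
  }
  if (ncol(replicates) < 2)
    stop_("need >= 2 replicates, got %d", ncol(replicates))
  mads <- apply(replicates, 1, mad)
  structure(list(mad = mads,
                 median_mad = median(mads),
                 iqr_mad = stats::IQR(mads),
                 n_replicates = ncol(replicates),
                 design = design),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  d <- if (is.null(x$design)) "" else
    sprintf(" [%s batches x %s]", x$design[[1]], x$design[[2]])
  cat(sprintf("consistency_report%s: %d replicates, median MAD %.4f (IQR %.4f)\n",
              d, x$n_replicates, x$median_mad, x$iqr_mad))
  invisible(x)
}

#' Replicate-training consistency experiment
#'
#' For each training design `(n_batches, batch_size)`, repeatedly draws a
#' balanced training sample from the pool (excluding the held-out test
#' array), trains frozen vectors, preprocesses the test array against
#' them, and summarizes the spread of the resulting expression estimates
#' with [consistency_mad()].  Larger, more diverse trainings are expected
#' to yield smaller MADs.
#'
#' @param pool A batch-labelled [probe_matrix()] large enough for every
#'   design.
#' @param designs List of `c(n_batches, batch_size)` pairs.
#' @param n_replicates Replicate trainings per design (>= 2).
#' @param test_array Array id (or column index) held out and preprocessed.
#' @param seed Integer seed; replicate r of design d uses a sub-seed
#'   derived from it.
#' @param config A [model_config()] (the median-SE vector is skipped
#'   during these trainings; it does not affect expression).
#' @return List of `consistency_report`, one per design.
#' @export
run_consistency_experiment <- function(pool, designs, n_replicates = 20,
                                       test_array = NULL, seed = 1L,
                                       config = model_config()) {
  stopifnot(inherits(pool, "probe_matrix"), n_replicates >= 2)
  config <- as_model_config(config)
  config$compute_median_se <- FALSE
  arr <- colnames(pool$intensities)
  if (is.null(test_array)) test_array <- arr[length(arr)]
  if (is.numeric(test_array)) test_array <- arr[test_array]
  test_col <- pool$intensities[, test_array]
  train_pool <- subset_arrays(pool, setdiff(arr, test_array))
  lapply(seq_along(designs), function(d) {
    nb <- designs[[d]][1]; bs <- designs[[d]][2]
    reps <- vapply(seq_len(n_replicates), function(r) {
      sub <- balanced_sample(train_pool, nb, bs,
                             seed = seed + 10000L * d + r)
      fv <- make_vectors(sub, config)
      frma_single(test_col, fv, config)$expression
    }, numeric(n_probesets(pool)))
    consistency_mad(reps, design = list(n_batches = nb, batch_size = bs))
  })
}
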