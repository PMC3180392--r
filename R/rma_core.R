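# RMA building blocks: normal+exponential background correction, quantile
# normalization (joint or against a frozen reference), median polish, and
# the multi-array RMA baseline.

#' Estimate normal-exponential background parameters
#'
#' Models observed raw intensities as the sum of normal optical noise
#' (mean `mu`, SD `sigma`) and exponentially distributed signal (rate
#' `alpha`).  Starting values come from the classic kernel-density
#' heuristic (noise mean at the density mode, noise SD from the spread
#' below the mode, signal rate from the mean excess above it); by default
#' they are then refined by maximizing the closed-form convolution
#' likelihood, which removes the upward bias of the raw mode when the
#' signal dominates.
#'
#' @param x Numeric vector of raw intensities (length >= 100, all > 0).
#' @param method `"mle"` (default) for likelihood refinement, `"mode"` for
#'   the plain kernel-mode heuristic.
#' @return An object of class `background_params`: list with `mu`,
#'   `sigma`, `alpha` (`alpha` is the exponential rate, 1/intensity).
#' @examples
#' x <- rnorm(5000, 80, 10) + rexp(5000, 1 / 150)
#' estimate_background(x)
#' @export
estimate_background <- function(x, method = c("mle", "mode")) {
  method <- match.arg(method)
  stopifnot(is.numeric(x))
  if (length(x) < 100) stop_("need >= 100 intensities, got %d", length(x))
  if (any(!is.finite(x) | x <= 0)) stop_("intensities must be finite and > 0")
  if (diff(range(x)) < .Machine$double.eps * max(x))
    stop_("constant intensities: background density is degenerate")
  d <- stats::density(x, kernel = "gaussian", n = 2^14)
  mu <- d$x[which.max(d$y)]
  below <- x[x < mu]
  if (length(below) < 2) stop_("no intensity mass below the density mode")
  sigma <- sqrt(mean((below - mu)^2))
  above <- x[x > mu]
  if (length(above) < 2) stop_("no intensity mass above the density mode")
  alpha <- 1 / mean(above - mu)
  if (method == "mle") {
    nll <- function(p) {
      m <- p[1]; s <- exp(p[2]); a <- exp(p[3])
      z <- (x - m) / s - a * s
      v <- -sum(log(a) + a^2 * s^2 / 2 - a * (x - m) +
                  pnorm(z, log.p = TRUE))
      if (!is.finite(v)) .Machine$double.xmax else v
    }
    # box around the heuristic start: keeps the likelihood refinement from
    # running off along the degenerate large-sigma/large-alpha ridge when
    # the data depart from the normal+exponential model
    start <- c(mu, log(sigma), log(alpha))
    lower <- c(mu - 6 * sigma, log(sigma) - 3, log(alpha) - 2)
    upper <- c(mu + 2 * sigma, log(sigma) + 1, log(alpha) + 2)
    fit <- tryCatch(
      stats::optim(start, nll, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) &&
        fit$value < .Machine$double.xmax) {
      mu <- fit$par[1]
      sigma <- exp(fit$par[2])
      alpha <- exp(fit$par[3])
    }
  }
  structure(list(mu = mu, sigma = sigma, alpha = alpha),
            class = "background_params")
}

#' Background-correct raw intensities
#'
#' Returns the posterior mean of the exponential signal given the observed
#' intensity under the normal+exponential convolution model: a truncated
#' normal expectation, strictly positive and nondecreasing in `x`.
#'
#' @param x Numeric vector of raw intensities.
#' @param params `background_params` from [estimate_background()] (or a
#'   list with `mu`, `sigma`, `alpha`).
#' @return Corrected intensities, same length as `x`, all > 0.
#' @export
adjust_background <- function(x, params) {
  mu <- params$mu; sigma <- params$sigma; alpha <- params$alpha
  stopifnot(is.numeric(x), sigma > 0, alpha > 0)
  b <- x - mu - sigma^2 * alpha
  z <- b / sigma
  # E[S | X = x] = b + sigma * phi(z) / Phi(z), computed on the log scale
  # so the Mills ratio stays finite deep in the lower tail
  out <- b + sigma * exp(dnorm(z, log = TRUE) - pnorm(z, log.p = TRUE))
  # deep in the lower tail the posterior mean approaches 1/alpha from above;
  # use that limit where cancellation degrades the direct formula
  bad <- !is.finite(out) | out <= 0
  if (any(bad))
    out[bad] <- pmax(sigma^2 / pmax(abs(b[bad]), sigma),
                     .Machine$double.xmin)
  out
}

#' Build a reference quantile distribution
#'
#' Element r of the reference is the mean over arrays of each array's r-th
#' order statistic -- the target distribution of joint quantile
#' normalization, and the first frozen parameter vector.
#'
#' @param x Numeric matrix (probes x arrays, >= 2 arrays) or list of
#'   equal-length numeric vectors, on the scale to be normalized
#'   (background-corrected log2 in the standard pipeline).
#' @return Nondecreasing numeric vector of length `nrow(x)`.
#' @export
build_reference <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    lens <- lengths(x)
    if (length(unique(lens)) != 1)
      stop_("arrays of unequal length: %s", paste(unique(lens), collapse = ", "))
    x <- do.call(cbind, x)
  }
  x <- as.matrix(x)
  if (ncol(x) < 2) stop_("need >= 2 arrays to build a reference")
  if (any(!is.finite(x))) stop_("non-finite values in reference input")
  rowMeans(apply(x, 2, sort))
}

#' Quantile-normalize one array against a fixed reference
#'
#' The value at the probe holding rank r becomes `reference[r]`, so ranks
#' are preserved and (absent ties) the output multiset equals the
#' reference multiset exactly.  Tied input values receive the mean of the
#' reference values at the ranks they span, a deterministic,
#' order-independent policy.
#'
#' @param column Numeric vector for one array.
#' @param reference Nondecreasing reference of the same length.
#' @return Normalized vector, same order as `column`.
#' @export
normalize_to_reference <- function(column, reference) {
  n <- length(column)
  if (length(reference) != n)
    stop_("column length %d does not match reference length %d",
          n, length(reference))
  if (is.unsorted(reference)) stop_("reference must be nondecreasing")
  o <- order(column)
  sorted <- column[o]
  grp <- cumsum(c(TRUE, diff(sorted) != 0))
  out_sorted <- stats::ave(reference, grp, FUN = mean)
  out <- numeric(n)
  out[o] <- out_sorted
  names(out) <- names(column)
  out
}

#' Median polish decomposition
#'
#' Robust additive decomposition `x[j, i] = overall + row_effects[j] +
#' col_effects[i] + residuals[j, i]` by alternating row/column median
#' sweeps (rows first, tolerance 0.01 on the sweep scale, at most 10
#' iterations).  The reconstruction identity holds exactly by
#' construction.
#'
#' Median sweeps leave the effect vectors centered at (approximately)
#' zero *median*; since a polish decomposition is only unique up to
#' constant shifts between its components, the returned effects are
#' re-centered to zero *mean* (the compensating constants move into
#' `overall`).  This makes the probeset location convention identical to
#' the sum-to-zero convention used by the frozen probe effects, so
#' median-polish and frozen-vector expression values are directly
#' comparable.
#'
#' @param x Numeric matrix without missing values.
#' @param eps Convergence tolerance on the change in the residual L1 norm.
#' @param maxiter Maximum number of sweep iterations.
#' @return An object of class `polish_decomposition` with elements
#'   `overall`, `row_effects`, `col_effects`, `residuals`.
#' @export
median_polish <- function(x, eps = 0.01, maxiter = 10L) {
  x <- as.matrix(x)
  if (any(is.na(x))) stop_("median_polish input must be complete")
  mp <- stats::medpolish(x, eps = eps, maxiter = maxiter,
                         trace.iter = FALSE)
  mr <- mean(mp$row); mc <- mean(mp$col)
  structure(list(overall = mp$overall + mr + mc,
                 row_effects = setNames(mp$row - mr, rownames(x)),
                 col_effects = setNames(mp$col - mc, colnames(x)),
                 residuals = mp$residuals),
            class = "polish_decomposition")
}

# shared first stages of the pipeline: background-correct (per array),
# log2-transform; returns probes x arrays matrix
preprocess_log2 <- function(intensities, bg_correct = TRUE) {
  if (bg_correct) {
    corrected <- vapply(seq_len(ncol(intensities)), function(i) {
      col <- intensities[, i]
      adjust_background(col, estimate_background(col))
    }, numeric(nrow(intensities)))
    dimnames(corrected) <- dimnames(intensities)
    log2(corrected)
  } else {
    log2(intensities)
  }
}

#' Multi-array RMA preprocessing
#'
#' The comparison baseline: normal-exponential background correction,
#' joint quantile normalization of all arrays (the reference is the mean
#' order-statistic distribution of these same arrays, on the log2 scale),
#' and per-probeset median-polish summarization.  Expression for array i
#' is `overall + col_effects[i]`.
#'
#' @param pm A [probe_matrix()] with >= 2 arrays.
#' @param config A [model_config()]; only `bg_correct` is used.
#' @param reference Optional fixed reference distribution (log2 scale);
#'   by default the reference is built from `pm` itself.
#' @return An [expression_result()] with the `expression` matrix
#'   (probesets x arrays) filled in.
#' @export
rma <- function(pm, config = model_config(), reference = NULL) {
  stopifnot(inherits(pm, "probe_matrix"))
  config <- as_model_config(config)
  if (n_arrays(pm) < 2) stop_("rma needs >= 2 arrays")
  L <- preprocess_log2(pm$intensities, config$bg_correct)
  if (is.null(reference)) reference <- build_reference(L)
  N <- apply(L, 2, normalize_to_reference, reference = reference)
  sets <- split_probesets(pm$probeset_of)
  expr <- matrix(NA_real_, length(sets), ncol(N),
                 dimnames = list(names(sets), colnames(N)))
  for (s in names(sets)) {
    mp <- median_polish(N[sets[[s]], , drop = FALSE])
    expr[s, ] <- mp$overall + mp$col_effects
  }
  expression_result(expression = expr)
}

#' Expression result container
#'
#' @param expression Probeset x array matrix of log2 expression.
#' @param stderr Optional matching matrix of standard errors (> 0).
#' @param probe_weights Optional probe x array matrix of final
#'   summarization weights (>= 0).
#' @param quality Optional probeset x array matrix of quality scores
#'   (standard error divided by the frozen median standard error).
#' @return An object of class `expression_result`.
#' @export
expression_result <- function(expression, stderr = NULL,
                              probe_weights = NULL, quality = NULL) {
  stopifnot(is.matrix(expression))
  if (!is.null(stderr)) {
    stopifnot(identical(dim(stderr), dim(expression)))
    if (any(stderr <= 0)) stop_("standard errors must be > 0")
  }
  if (!is.null(quality) && any(quality <= 0))
    stop_("quality scores must be > 0")
  structure(list(expression = expression, stderr = stderr,
                 probe_weights = probe_weights, quality = quality),
            class = "expression_result")
}

#' @export
print.expression_result <- function(x, ...) {
  cat(sprintf("expression_result: %d probesets x %d arrays (SE %s, quality %s)\n",
              nrow(x$expression), ncol(x$expression),
              if (is.null(x$stderr)) "absent" else "present",
              if (is.null(x$quality)) "absent" else "present"))
  invisible(x)
}
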