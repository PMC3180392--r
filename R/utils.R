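# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# run `expr` under a fixed seed without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# locale-independent lexicographic order (C collation via radix sort)
c_order <- function(...) order(..., method = "radix")

# row indices per probeset, in canonical (appearance) order; assumes the
# canonical row ordering of probe_matrix so no locale-sensitive sort happens
split_probesets <- function(probeset_of) {
  split(seq_along(probeset_of),
        factor(probeset_of, levels = unique(probeset_of)))
}

# scaled-chi draw: positive with expectation `mean`; df controls spread
rscaled_chi <- function(n, mean, df = 4) {
  norm_const <- sqrt(2 / df) * exp(lgamma((df + 1) / 2) - lgamma(df / 2))
  mean * sqrt(stats::rchisq(n, df) / df) / norm_const
}

# full-precision numeric formatting for lossless TSV round trips
format_full <- function(x) sprintf("%.17g", x)

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Model configuration
#'
#' Container for the tuning constants used across training and
#' single-array preprocessing.  All robust fits share the Huber tuning
#' constant `huber_c`; `variance_floor` keeps frozen variances (and hence
#' probe weights) finite; `alpha` is the significance level used by the
#' batch-effect diagnostics.
#'
#' @param huber_c Huber tuning constant for the robust probe-level fits
#'   (dimensionless; 1.345 gives 95% efficiency at the normal model).
#' @param max_iter Maximum IRLS iterations.
#' @param convergence_tol Convergence tolerance on the summarized
#'   expression value in [frma_single()] (log2 units).
#' @param variance_floor Lower bound applied to all variance estimates
#'   (log2^2 units).
#' @param alpha Significance level for batch-effect diagnostics.
#' @param seed Integer seed recorded in trained bundles.
#' @param bg_correct Logical; apply normal-exponential background
#'   correction before normalization.  Disable only for data already on a
#'   background-corrected scale.
#' @param compute_median_se Logical; compute the optional median
#'   standard-error vector during training (needed for quality scores).
#' @return An object of class `model_config` (a named list).
#' @examples
#' cfg <- model_config(huber_c = 2)
#' cfg$huber_c
#' @export
model_config <- function(huber_c = 1.345, max_iter = 50L,
                         convergence_tol = 1e-8, variance_floor = 1e-8,
                         alpha = 0.05, seed = 1L, bg_correct = TRUE,
                         compute_median_se = TRUE) {
  stopifnot(is.numeric(huber_c), huber_c > 0,
            is.numeric(variance_floor), variance_floor > 0,
            is.numeric(alpha), alpha > 0, alpha < 1,
            max_iter >= 1, convergence_tol > 0)
  structure(list(huber_c = huber_c, max_iter = as.integer(max_iter),
                 convergence_tol = convergence_tol,
                 variance_floor = variance_floor, alpha = alpha,
                 seed = as.integer(seed), bg_correct = isTRUE(bg_correct),
                 compute_median_se = isTRUE(compute_median_se)),
            class = "model_config")
}

as_model_config <- function(config) {
  if (inherits(config, "model_config")) return(config)
  if (is.null(config)) return(model_config())
  do.call(model_config, config)
}
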