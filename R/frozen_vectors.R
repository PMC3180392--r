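# The frozen parameter bundle: constructor, validation, and lossless
# on-disk serialization as a directory of TSV files plus JSON metadata.

BUNDLE_VERSION <- 1L
MANDATORY_VECTORS <- c("reference_distribution", "probe_effects",
                       "within_batch_var", "between_batch_var",
                       "probeset_avg_sd")

#' Construct a frozen parameter bundle
#'
#' Single-array preprocessing requires five frozen parameter vectors: the
#' reference quantile distribution, the probe effects, the within-batch and
#' between-batch residual variances (all probe-level), and the probeset
#' average SD.  A sixth vector of median standard errors is optional and
#' enables the quality score of [frma_single()].
#'
#' @param reference_distribution Nondecreasing numeric vector of length
#'   `n_probes` on the background-corrected log2 scale.
#' @param probe_effects Per-probe effects (log2), summing to zero within
#'   each probeset.
#' @param within_batch_var,between_batch_var Per-probe residual variance
#'   components (log2^2), nonnegative.
#' @param probeset_avg_sd Per-probeset average total probe SD (log2).
#' @param median_se Optional per-probeset median standard error (log2).
#' @param probe_ids,probeset_of Probe ids in canonical order and their
#'   probeset mapping (named by probe id).
#' @param metadata List of training metadata (`n_training_arrays`,
#'   `n_batches`, `seed`, ...).
#' @return An object of class `frozen_vectors`.
#' @export
frozen_vectors <- function(reference_distribution, probe_effects,
                           within_batch_var, between_batch_var,
                           probeset_avg_sd, median_se = NULL,
                           probe_ids, probeset_of, metadata = list()) {
  probeset_ids <- unique(as.character(probeset_of[probe_ids]))
  fv <- structure(list(
    reference_distribution = as.numeric(reference_distribution),
    probe_effects = setNames(as.numeric(probe_effects), probe_ids),
    within_batch_var = setNames(as.numeric(within_batch_var), probe_ids),
    between_batch_var = setNames(as.numeric(between_batch_var), probe_ids),
    probeset_avg_sd = setNames(as.numeric(probeset_avg_sd), probeset_ids),
    median_se = if (is.null(median_se)) NULL else
      setNames(as.numeric(median_se), probeset_ids),
    probe_ids = as.character(probe_ids),
    probeset_of = setNames(as.character(probeset_of[probe_ids]), probe_ids),
    metadata = modifyList(list(format_version = BUNDLE_VERSION), metadata)),
    class = "frozen_vectors")
  validate_frozen_vectors(fv)
  fv
}

#' Validate a frozen parameter bundle
#'
#' Checks the structural invariants: vector lengths, a nondecreasing
#' reference distribution, nonnegative variances, and probe effects that
#' sum to zero within each probeset (tolerance 1e-8).
#'
#' @param fv A `frozen_vectors` object.
#' @return `fv`, invisibly; errors describe the first violated invariant.
#' @export
validate_frozen_vectors <- function(fv) {
  stopifnot(inherits(fv, "frozen_vectors"))
  np <- length(fv$probe_ids)
  ns <- length(unique(fv$probeset_of))
  for (v in c("probe_effects", "within_batch_var", "between_batch_var"))
    if (length(fv[[v]]) != np)
      stop_("%s has length %d; expected n_probes = %d", v, length(fv[[v]]), np)
  if (length(fv$reference_distribution) != np)
    stop_("reference_distribution has length %d; expected n_probes = %d",
          length(fv$reference_distribution), np)
  for (v in c("probeset_avg_sd", "median_se"))
    if (!is.null(fv[[v]]) && length(fv[[v]]) != ns)
      stop_("%s has length %d; expected n_probesets = %d",
            v, length(fv[[v]]), ns)
  if (is.unsorted(fv$reference_distribution))
    stop_("reference_distribution must be nondecreasing")
  if (any(fv$within_batch_var < 0) || any(fv$between_batch_var < 0))
    stop_("variance vectors must be nonnegative")
  sums <- tapply(fv$probe_effects, fv$probeset_of, sum)
  if (any(abs(sums) > 1e-8))
    stop_("probe effects do not sum to zero within probeset '%s' (sum %.3g)",
          names(sums)[which.max(abs(sums))], max(abs(sums)))
  invisible(fv)
}

#' @export
print.frozen_vectors <- function(x, ...) {
  cat(sprintf(paste0("frozen_vectors: %d probes / %d probesets",
                     " (median SE %s)\n"),
              length(x$probe_ids), length(unique(x$probeset_of)),
              if (is.null(x$median_se)) "absent" else "present"))
  md <- x$metadata
  cat(sprintf("  trained on %s arrays in %s batches (seed %s)\n",
              md$n_training_arrays %||% "?", md$n_batches %||% "?",
              md$seed %||% "?"))
  invisible(x)
}

bundle_files <- function() {
  c(reference_distribution = "reference_distribution.tsv",
    probe_effects = "probe_effects.tsv",
    within_batch_var = "within_batch_var.tsv",
    between_batch_var = "between_batch_var.tsv",
    probeset_avg_sd = "probeset_avg_sd.tsv",
    median_se = "median_se.tsv")
}

#' Write a frozen bundle to disk
#'
#' Serializes a [frozen_vectors()] object as a directory holding one TSV
#' file per vector plus `metadata.json`.  Values are written at full
#' double precision so that [read_frozen_vectors()] reproduces the bundle
#' exactly; the plain-text layout keeps bundles diffable and shareable.
#'
#' @param fv A `frozen_vectors` object.
#' @param path Directory to create (must not be an existing file).
#' @return Invisibly, `path`.
#' @export
write_frozen_vectors <- function(fv, path) {
  validate_frozen_vectors(fv)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- bundle_files()
  write2 <- function(ids, extra, values, file) {
    df <- data.frame(ids, value = format_full(values),
                     stringsAsFactors = FALSE)
    if (!is.null(extra)) df <- cbind(df[1], probeset_id = extra, df[2])
    write.table(df, file.path(path, file), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  write2(data.frame(rank = seq_along(fv$reference_distribution)), NULL,
         fv$reference_distribution, files["reference_distribution"])
  for (v in c("probe_effects", "within_batch_var", "between_batch_var"))
    write2(data.frame(probe_id = fv$probe_ids), unname(fv$probeset_of),
           fv[[v]], files[v])
  write2(data.frame(probeset_id = names(fv$probeset_avg_sd)), NULL,
         fv$probeset_avg_sd, files["probeset_avg_sd"])
  if (!is.null(fv$median_se))
    write2(data.frame(probeset_id = names(fv$median_se)), NULL,
           fv$median_se, files["median_se"])
  md <- modifyList(fv$metadata,
                   list(n_probes = length(fv$probe_ids),
                        n_probesets = length(unique(fv$probeset_of)),
                        has_median_se = !is.null(fv$median_se)))
  jsonlite::write_json(md, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a frozen bundle from disk
#'
#' @param path Bundle directory written by [write_frozen_vectors()].
#' @return A `frozen_vectors` object.  A bundle without the optional
#'   median-SE vector loads with quality scoring disabled; a bundle missing
#'   a mandatory vector is an error naming the vector.
#' @export
read_frozen_vectors <- function(path) {
  if (!dir.exists(path)) stop_("no frozen-vector bundle at '%s'", path)
  mdp <- file.path(path, "metadata.json")
  if (!file.exists(mdp)) stop_("bundle is missing metadata.json")
  md <- jsonlite::read_json(mdp, simplifyVector = TRUE)
  files <- bundle_files()
  for (v in MANDATORY_VECTORS)
    if (!file.exists(file.path(path, files[v])))
      stop_("missing mandatory vector: %s", v)
  rd <- read.delim(file.path(path, files["reference_distribution"]))
  pe <- read.delim(file.path(path, files["probe_effects"]),
                   colClasses = c("character", "character", "numeric"))
  wv <- read.delim(file.path(path, files["within_batch_var"]))
  bv <- read.delim(file.path(path, files["between_batch_var"]))
  as_ <- read.delim(file.path(path, files["probeset_avg_sd"]),
                    colClasses = c("character", "numeric"))
  np <- md$n_probes %||% nrow(pe)
  ns <- md$n_probesets %||% nrow(as_)
  if (nrow(pe) != np || nrow(rd) != np)
    stop_("probe-level vector length %d does not match recorded n_probes %d",
          nrow(pe), np)
  if (nrow(as_) != ns)
    stop_("probeset-level vector length %d does not match n_probesets %d",
          nrow(as_), ns)
  msp <- file.path(path, files["median_se"])
  mse <- NULL
  if (isTRUE(md$has_median_se) || file.exists(msp)) {
    if (!file.exists(msp)) stop_("metadata records median_se but file absent")
    ms <- read.delim(msp, colClasses = c("character", "numeric"))
    mse <- setNames(ms$value, ms$probeset_id)[as_$probeset_id]
  }
  md$n_probes <- md$n_probesets <- md$has_median_se <- NULL
  frozen_vectors(reference_distribution = rd$value,
                 probe_effects = pe$value,
                 within_batch_var = wv$value,
                 between_batch_var = bv$value,
                 probeset_avg_sd = setNames(as_$value, as_$probeset_id),
                 median_se = mse,
                 probe_ids = pe$probe_id,
                 probeset_of = setNames(pe$probeset_id, pe$probe_id),
                 metadata = md)
}
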