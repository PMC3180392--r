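# Probe-level data model and I/O: probe matrices, annotations, batch labels,
# frozen-vector bundles, and balanced training-set sampling.

#' Construct a probe-level intensity matrix
#'
#' Bundles raw probe intensities with the probe-to-probeset annotation and
#' optional array-to-batch labels, and places rows in the canonical order
#' (probeset id, then probe id, C collation) so that vector positions are
#' reproducible across runs and platforms.
#'
#' @param intensities Numeric matrix of positive raw intensities with probe
#'   ids as row names and array ids as column names.
#' @param probeset_of Named character vector mapping every probe id to its
#'   probeset id.
#' @param batch_of Optional named character vector mapping every array id to
#'   a batch label.
#' @return An object of class `probe_matrix`: a list with elements
#'   `intensities`, `probeset_of` (in canonical row order) and `batch_of`.
#' @examples
#' x <- matrix(2^rnorm(12, 8), 4, 3,
#'             dimnames = list(paste0("p", 1:4), paste0("a", 1:3)))
#' pm <- probe_matrix(x, setNames(c("ps1", "ps1", "ps2", "ps2"),
#'                                paste0("p", 1:4)))
#' n_probesets(pm)
#' @export
probe_matrix <- function(intensities, probeset_of, batch_of = NULL) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop_("intensities must be a numeric matrix")
  probe_ids <- rownames(intensities)
  array_ids <- colnames(intensities)
  if (is.null(probe_ids) || is.null(array_ids))
    stop_("intensities must have probe row names and array column names")
  if (anyDuplicated(probe_ids))
    stop_("duplicate probe id: %s", probe_ids[duplicated(probe_ids)][1])
  if (anyDuplicated(array_ids))
    stop_("duplicate array id: %s", array_ids[duplicated(array_ids)][1])
  bad <- which(!is.finite(intensities) | intensities <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_("non-positive or non-numeric intensity at probe '%s', array '%s'",
          probe_ids[bad[1, 1]], array_ids[bad[1, 2]])
  miss <- setdiff(probe_ids, names(probeset_of))
  if (length(miss) > 0)
    stop_("annotation does not map probe(s): %s",
          paste(miss, collapse = ", "))
  probeset_of <- probeset_of[probe_ids]
  if (!is.null(batch_of)) {
    missb <- setdiff(array_ids, names(batch_of))
    if (length(missb) > 0)
      stop_("batch labels missing for array(s): %s",
            paste(missb, collapse = ", "))
    batch_of <- as.character(batch_of[array_ids])
    names(batch_of) <- array_ids
  }
  ord <- c_order(as.character(probeset_of), probe_ids)
  structure(list(intensities = intensities[ord, , drop = FALSE],
                 probeset_of = setNames(as.character(probeset_of)[ord],
                                        probe_ids[ord]),
                 batch_of = batch_of),
            class = "probe_matrix")
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat(sprintf("probe_matrix: %d probes / %d probesets x %d arrays%s\n",
              n_probes(x), n_probesets(x), n_arrays(x),
              if (is.null(x$batch_of)) "" else
                sprintf(" (%d batches)", length(unique(x$batch_of)))))
  invisible(x)
}

#' Dimensions of a probe matrix
#' @param pm A `probe_matrix`.
#' @return Integer count.
#' @rdname probe_matrix-dims
#' @export
n_probes <- function(pm) nrow(pm$intensities)

#' @rdname probe_matrix-dims
#' @export
n_probesets <- function(pm) length(unique(pm$probeset_of))

#' @rdname probe_matrix-dims
#' @export
n_arrays <- function(pm) ncol(pm$intensities)

#' Read a probe-level dataset from delimited text
#'
#' Reads a tab-separated intensity matrix (probe ids in the first column,
#' array ids in the header), a two-column probe-to-probeset annotation, and
#' optionally a two-column array-to-batch table, and returns a validated
#' [probe_matrix()] in canonical row order.
#'
#' @param matrix_path Path to the TSV intensity matrix.
#' @param annotation_path Path to a TSV with columns `probe_id`,
#'   `probeset_id`.
#' @param batch_path Optional path to a TSV with columns `array_id`,
#'   `batch`.
#' @return A `probe_matrix`.
#' @seealso [write_probe_matrix()] for the inverse.
#' @export
read_probe_matrix <- function(matrix_path, annotation_path,
                              batch_path = NULL) {
  raw <- read.delim(matrix_path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) stop_("matrix file must have probe ids plus >= 1 array")
  probe_ids <- raw[[1]]
  vals <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw))))
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = nrow(raw))
  nas <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(nas) > 0)
    stop_("non-numeric intensity at row %d (probe '%s'), column '%s'",
          nas[1, 1], probe_ids[nas[1, 1]], colnames(raw)[-1][nas[1, 2]])
  dimnames(vals) <- list(probe_ids, colnames(raw)[-1])
  ann <- read.delim(annotation_path, colClasses = "character")
  if (ncol(ann) < 2) stop_("annotation must have two columns")
  probeset_of <- setNames(ann[[2]], ann[[1]])
  batch_of <- NULL
  if (!is.null(batch_path)) {
    bt <- read.delim(batch_path, colClasses = "character")
    if (ncol(bt) < 2) stop_("batch table must have two columns")
    batch_of <- setNames(bt[[2]], bt[[1]])
  }
  probe_matrix(vals, probeset_of, batch_of)
}

#' Write a probe-level dataset as delimited text
#'
#' Emits the three TSV files consumed by [read_probe_matrix()]:
#' `<prefix>_matrix.tsv`, `<prefix>_annotation.tsv` and (when batch labels
#' are present) `<prefix>_batches.tsv`.
#'
#' @param pm A `probe_matrix`.
#' @param prefix Path prefix for the output files.
#' @return Invisibly, the paths written.
#' @export
write_probe_matrix <- function(pm, prefix) {
  stopifnot(inherits(pm, "probe_matrix"))
  mp <- paste0(prefix, "_matrix.tsv")
  ap <- paste0(prefix, "_annotation.tsv")
  m <- pm$intensities
  df <- data.frame(probe_id = rownames(m), apply(m, 2, format_full),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(probe_id = rownames(m),
                         probeset_id = unname(pm$probeset_of)),
              ap, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(mp, ap)
  if (!is.null(pm$batch_of)) {
    bp <- paste0(prefix, "_batches.tsv")
    write.table(data.frame(array_id = names(pm$batch_of),
                           batch = unname(pm$batch_of)),
                bp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, bp)
  }
  invisible(paths)
}

#' Subset the arrays of a probe matrix
#'
#' @param pm A `probe_matrix`.
#' @param arrays Array ids or column indices to keep.
#' @return A `probe_matrix` with the selected arrays.
#' @export
subset_arrays <- function(pm, arrays) {
  stopifnot(inherits(pm, "probe_matrix"))
  m <- pm$intensities[, arrays, drop = FALSE]
  probe_matrix(m, pm$probeset_of,
               if (is.null(pm$batch_of)) NULL else pm$batch_of[colnames(m)])
}

#' Draw a balanced training sample across batches
#'
#' Samples `batch_size` arrays without replacement from each of `n_batches`
#' batches (themselves sampled from the batches holding at least
#' `batch_size` arrays).  Frozen-parameter training sets are built this way
#' so that between-batch variability is represented evenly.  Batches and
#' arrays are sorted lexicographically before seeded sampling, making the
#' selection reproducible across platforms.
#'
#' @param pm A `probe_matrix` with batch labels.
#' @param n_batches Number of batches to sample.
#' @param batch_size Number of arrays per sampled batch.
#' @param seed Integer seed controlling the sampling.
#' @return A `probe_matrix` containing exactly `n_batches * batch_size`
#'   arrays.
#' @export
balanced_sample <- function(pm, n_batches, batch_size, seed = 1L) {
  stopifnot(inherits(pm, "probe_matrix"))
  if (is.null(pm$batch_of)) stop_("probe matrix has no batch labels")
  counts <- table(pm$batch_of)
  eligible <- names(counts)[counts >= batch_size]
  if (length(eligible) < n_batches)
    stop_(paste0("only %d of %d batches hold >= %d arrays; ",
                 "%d eligible batches required"),
          length(eligible), length(counts), batch_size, n_batches)
  eligible <- eligible[c_order(eligible)]
  with_preserved_seed(seed, {
    chosen <- eligible[sample.int(length(eligible), n_batches)]
    chosen <- chosen[c_order(chosen)]
    arrays <- unlist(lapply(chosen, function(b) {
      ids <- names(pm$batch_of)[pm$batch_of == b]
      ids <- ids[c_order(ids)]
      ids[sample.int(length(ids), batch_size)]
    }), use.names = FALSE)
    subset_arrays(pm, arrays)
  })
}
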