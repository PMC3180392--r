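# Synthetic probe-level data: generic training sets with known truth, and
# latin-square spike-in benchmark datasets.

#' Simulation configuration
#'
#' Parameters of the additive probe-level generative model
#' `log2 intensity = baseline + array effect + probe effect +
#' batch shift + noise`, exponentiated back to the raw scale with added
#' normal optical background so that the full pipeline (background
#' correction onward) is exercised.
#'
#' Probe noise SDs `sigma_j` follow a scaled-chi distribution with mean
#' `sigma_mean`; a fraction `tau_fraction` of probes carry batch-shift SDs
#' `tau_j` (scaled chi, mean `tau_mean`), the rest have `tau_j = 0`.
#' Passing scalars (or vectors) as `sigma` / `tau` fixes them exactly.
#'
#' @param baseline_range Range (log2) of per-probeset baseline abundances.
#' @param theta_sd SD (log2) of per-array effects.
#' @param batch_theta_sd SD (log2) of batch-level brightness shifts shared
#'   by all arrays of a batch (scanner/lab differences); these are what
#'   make reference distributions differ between trainings drawn from
#'   different batches.
#' @param phi_sd SD (log2) of probe effects (centered within probeset).
#' @param phi Optional fixed probe-effect vector (recycled per probeset).
#' @param sigma,sigma_mean Probe noise SD: fixed value(s), or the mean of
#'   the scaled-chi draw when `sigma = NULL` (log2 units).
#' @param tau,tau_mean Batch-shift SD for affected probes: fixed value(s)
#'   or scaled-chi mean (log2 units).
#' @param tau_fraction Fraction of probes with a nonzero batch-shift SD.
#' @param bg_mu,bg_sd Mean and SD of the additive optical background
#'   (raw intensity units).
#' @param spike_base Log2 signal at 1 pM for spiked probesets.
#' @param conc_floor Soft floor (pM) added to nominal concentrations, so
#'   the 0 pM response is finite.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(baseline_range = c(7, 12), theta_sd = 0.1,
                       batch_theta_sd = 0.3,
                       phi_sd = 1, phi = NULL,
                       sigma = NULL, sigma_mean = 0.25,
                       tau = NULL, tau_mean = 0.5, tau_fraction = 0.25,
                       bg_mu = 30, bg_sd = 6,
                       spike_base = 6, conc_floor = 0.25) {
  structure(as.list(environment()), class = "sim_config")
}

as_sim_config <- function(x) {
  if (inherits(x, "sim_config")) return(x)
  if (is.null(x)) return(sim_config())
  do.call(sim_config, x)
}

draw_probe_sds <- function(cfg, n_probes) {
  sigma <- if (is.null(cfg$sigma))
    rscaled_chi(n_probes, cfg$sigma_mean) else rep_len(cfg$sigma, n_probes)
  has_tau <- runif(n_probes) < cfg$tau_fraction
  tau <- numeric(n_probes)
  tau[has_tau] <- if (is.null(cfg$tau))
    rscaled_chi(sum(has_tau), cfg$tau_mean) else
      rep_len(cfg$tau, n_probes)[has_tau]
  list(sigma = sigma, tau = tau)
}

draw_phi <- function(cfg, n_probesets, probes_per_set) {
  if (!is.null(cfg$phi)) {
    phi <- matrix(rep_len(cfg$phi, n_probesets * probes_per_set),
                  probes_per_set, n_probesets)
  } else {
    phi <- matrix(rnorm(n_probesets * probes_per_set, 0, cfg$phi_sd),
                  probes_per_set, n_probesets)
  }
  # center within probeset so truth satisfies the frozen-vector constraint
  as.vector(sweep(phi, 2, colMeans(phi)))
}

pad_id <- function(prefix, i, n) sprintf("%s%0*d", prefix, nchar(n), i)

#' Cyclic latin-square spike-in design
#'
#' Concentrations form a doubling series in pM including 0; array i of a
#' replicate block receives the concentration row rotated by i, so every
#' concentration appears exactly once per probeset group and once per
#' array.
#'
#' @param n_groups Number of probeset groups (= concentrations = arrays
#'   per replicate block).
#' @param base_conc Smallest nonzero concentration (pM).
#' @param concentrations Optional explicit concentration vector of length
#'   `n_groups` (overrides the doubling series).
#' @return An object of class `spikein_design`: `n_groups`,
#'   `concentrations`, and the group x array `assignment` matrix.
#' @examples
#' make_latin_square(3, concentrations = c(0, 1, 2))$assignment
#' @export
make_latin_square <- function(n_groups, base_conc = 0.25,
                              concentrations = NULL) {
  if (is.null(concentrations))
    concentrations <- c(0, base_conc * 2^(0:(n_groups - 2)))
  if (length(concentrations) != n_groups)
    stop_("%d concentrations for %d groups", length(concentrations),
          n_groups)
  assignment <- matrix(NA_real_, n_groups, n_groups)
  for (g in seq_len(n_groups))
    assignment[g, ] <- concentrations[((g - 1 + seq_len(n_groups) - 1) %%
                                         n_groups) + 1]
  structure(list(n_groups = n_groups, concentrations = concentrations,
                 assignment = assignment),
            class = "spikein_design")
}

# shared final stage: exponentiate log2 signal and add optical background
to_raw_scale <- function(L, cfg) {
  raw <- 2^L + matrix(rnorm(length(L), cfg$bg_mu, cfg$bg_sd),
                      nrow(L), ncol(L))
  pmax(raw, 0.5)
}

#' Simulate a latin-square spike-in dataset
#'
#' Emulates an extended spike-in benchmark: `n_batches` replicate blocks
#' of one latin-square design each (so `n_batches * n_groups` arrays),
#' with `spiked_per_group` spiked probesets per concentration group and
#' `n_null_probesets` null probesets that are constant across arrays.
#' Spiked probesets respond with slope 1 in log2(concentration) above a
#' soft floor; every probe carries its own effect, noise SD and (for a
#' fraction of probes) batch-specific shifts redrawn per block.
#'
#' @param design A [make_latin_square()] design.
#' @param n_batches Number of replicate blocks (= batches).
#' @param n_null_probesets Number of non-spiked probesets.
#' @param probes_per_set Probes per probeset.
#' @param spiked_per_group Spiked probesets per concentration group.
#' @param noise_config A [sim_config()].  The default null baselines span
#'   log2 3--12, so (as on real arrays) a fraction of probes sit at
#'   background level, making the optical background identifiable.
#' @param seed Integer seed; output is bit-identical given the seed.
#' @return List with `pm` (a [probe_matrix()] with block batch labels)
#'   and `truth` (class `spikein_truth`: probe effects, noise SDs,
#'   batch-shift SDs and realizations, baselines, nominal concentration
#'   per probeset and array, spiked flags, array batch labels, design,
#'   seed).
#' @export
simulate_spikein <- function(design, n_batches = 9, n_null_probesets = 400,
                             probes_per_set = 8, spiked_per_group = 3,
                             noise_config = sim_config(
                               baseline_range = c(3, 12)),
                             seed = 1L) {
  stopifnot(inherits(design, "spikein_design"))
  cfg <- as_sim_config(noise_config)
  G <- design$n_groups
  n_spiked <- G * spiked_per_group
  n_sets <- n_spiked + n_null_probesets
  n_arrays <- n_batches * G
  np <- n_sets * probes_per_set
  with_preserved_seed(seed, {
    spiked_ids <- sprintf("spk_g%02d_%02d",
                          rep(seq_len(G), each = spiked_per_group),
                          rep(seq_len(spiked_per_group), G))
    null_ids <- pad_id("null_", seq_len(n_null_probesets), n_null_probesets)
    set_ids <- c(spiked_ids, null_ids)
    group_of <- c(rep(seq_len(G), each = spiked_per_group),
                  rep(NA_integer_, n_null_probesets))
    array_ids <- pad_id("arr", seq_len(n_arrays), n_arrays)
    batch_of <- setNames(pad_id("batch", rep(seq_len(n_batches), each = G),
                                n_batches), array_ids)
    pos_in_block <- rep(seq_len(G), n_batches)

    baseline <- setNames(ifelse(is.na(group_of), NA_real_, cfg$spike_base),
                         set_ids)
    baseline[is.na(baseline)] <-
      runif(n_null_probesets, cfg$baseline_range[1], cfg$baseline_range[2])
    # nominal concentration per probeset x array (NA for null probesets)
    conc <- matrix(NA_real_, n_sets, n_arrays,
                   dimnames = list(set_ids, array_ids))
    for (k in seq_len(n_spiked))
      conc[k, ] <- design$assignment[group_of[k], pos_in_block]
    sds <- draw_probe_sds(cfg, np)
    phi <- draw_phi(cfg, n_sets, probes_per_set)
    theta <- rnorm(n_arrays, 0, cfg$theta_sd) +
      rep(rnorm(n_batches, 0, cfg$batch_theta_sd), each = G)
    gamma <- matrix(rnorm(np * n_batches, 0, sds$tau), np, n_batches)

    set_of_probe <- rep(seq_len(n_sets), each = probes_per_set)
    sig <- matrix(baseline[set_of_probe], np, n_arrays)
    spk_probe <- !is.na(group_of[set_of_probe])
    sig[spk_probe, ] <- cfg$spike_base +
      log2(conc[set_of_probe[spk_probe], , drop = FALSE] + cfg$conc_floor)
    L <- sig +
      phi +
      gamma[, rep(seq_len(n_batches), each = G), drop = FALSE] +
      matrix(rnorm(np * n_arrays, 0, sds$sigma), np, n_arrays) +
      rep(theta, each = np)
    raw <- to_raw_scale(L, cfg)
    probe_ids <- paste0(rep(set_ids, each = probes_per_set), "_p",
                        rep(seq_len(probes_per_set), n_sets))
    dimnames(raw) <- list(probe_ids, array_ids)
    probeset_of <- setNames(rep(set_ids, each = probes_per_set), probe_ids)
    pm <- probe_matrix(raw, probeset_of, batch_of)
    ord <- match(rownames(pm$intensities), probe_ids)
    truth <- structure(list(
      probe_effects = setNames(phi[ord], rownames(pm$intensities)),
      sigma = setNames(sds$sigma[ord], rownames(pm$intensities)),
      tau = setNames(sds$tau[ord], rownames(pm$intensities)),
      gamma = gamma[ord, , drop = FALSE],
      baseline = baseline,
      array_effects = setNames(theta, array_ids),
      concentration = conc,
      spiked = setNames(!is.na(group_of), set_ids),
      batch_of = batch_of,
      design = design, seed = seed),
      class = "spikein_truth")
    list(pm = pm, truth = truth)
  })
}

#' Simulate a batch-labelled training set with known parameters
#'
#' Generates probe intensities from the purely additive model `baseline +
#' array effect + probe effect + batch shift + noise` on the log2 scale,
#' exponentiated back to raw intensities, together with the full ground
#' truth, for parameter-recovery and consistency experiments.  Unlike
#' [simulate_spikein()], no optical background is added: this generator
#' realizes the additive probe-level model exactly, so recovery metrics
#' isolate the training estimators (run the pipeline with
#' `bg_correct = FALSE` on such data; background parameters are not
#' identifiable without background-dominated probes).
#'
#' @param n_probesets,probes_per_set,n_batches,batch_size Design sizes
#'   (`n_batches >= 2`, `batch_size >= 2`).
#' @param effect_config A [sim_config()].
#' @param seed Integer seed.
#' @return List with `pm` and `truth`, as in [simulate_spikein()] (no
#'   concentration/design components).
#' @export
simulate_training_set <- function(n_probesets = 100, probes_per_set = 4,
                                  n_batches = 20, batch_size = 5,
                                  effect_config = sim_config(),
                                  seed = 1L) {
  stopifnot(n_batches >= 2, batch_size >= 2, probes_per_set >= 1)
  cfg <- as_sim_config(effect_config)
  n_arrays <- n_batches * batch_size
  np <- n_probesets * probes_per_set
  with_preserved_seed(seed, {
    set_ids <- pad_id("ps", seq_len(n_probesets), n_probesets)
    array_ids <- pad_id("arr", seq_len(n_arrays), n_arrays)
    batch_of <- setNames(pad_id("batch",
                                rep(seq_len(n_batches), each = batch_size),
                                n_batches), array_ids)
    baseline <- setNames(runif(n_probesets, cfg$baseline_range[1],
                               cfg$baseline_range[2]), set_ids)
    sds <- draw_probe_sds(cfg, np)
    phi <- draw_phi(cfg, n_probesets, probes_per_set)
    theta <- rnorm(n_arrays, 0, cfg$theta_sd) +
      rep(rnorm(n_batches, 0, cfg$batch_theta_sd), each = batch_size)
    gamma <- matrix(rnorm(np * n_batches, 0, sds$tau), np, n_batches)
    set_of_probe <- rep(seq_len(n_probesets), each = probes_per_set)
    L <- matrix(baseline[set_of_probe], np, n_arrays) +
      phi +
      gamma[, rep(seq_len(n_batches), each = batch_size), drop = FALSE] +
      matrix(rnorm(np * n_arrays, 0, sds$sigma), np, n_arrays) +
      rep(theta, each = np)
    raw <- 2^L   # purely additive on log2; no optical background term
    probe_ids <- paste0(rep(set_ids, each = probes_per_set), "_p",
                        rep(seq_len(probes_per_set), n_probesets))
    dimnames(raw) <- list(probe_ids, array_ids)
    pm <- probe_matrix(raw, setNames(rep(set_ids, each = probes_per_set),
                                     probe_ids), batch_of)
    ord <- match(rownames(pm$intensities), probe_ids)
    truth <- structure(list(
      probe_effects = setNames(phi[ord], rownames(pm$intensities)),
      sigma = setNames(sds$sigma[ord], rownames(pm$intensities)),
      tau = setNames(sds$tau[ord], rownames(pm$intensities)),
      gamma = gamma[ord, , drop = FALSE],
      baseline = baseline,
      array_effects = setNames(theta, array_ids),
      concentration = NULL, spiked = NULL,
      batch_of = batch_of, design = NULL, seed = seed),
      class = "spikein_truth")
    list(pm = pm, truth = truth)
  })
}

#' Write / read simulation ground truth
#'
#' Serializes a `spikein_truth` object as JSON so simulated datasets can
#' round-trip through the command-line interface.
#'
#' @param truth A `spikein_truth`.
#' @param path JSON file path.
#' @return `write_spikein_truth()`: invisibly, `path`;
#'   `read_spikein_truth()`: the reconstructed `spikein_truth`.
#' @export
write_spikein_truth <- function(truth, path) {
  stopifnot(inherits(truth, "spikein_truth"))
  obj <- truth
  class(obj) <- NULL
  obj$design <- if (!is.null(truth$design)) unclass(truth$design)
  # store named vectors as JSON objects so the names survive the trip
  for (nm in c("probe_effects", "sigma", "tau", "baseline",
               "array_effects", "batch_of", "spiked"))
    if (!is.null(obj[[nm]])) obj[[nm]] <- as.list(obj[[nm]])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE, matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname write_spikein_truth
#' @export
read_spikein_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x, nr) {
    if (is.matrix(x)) return(x)
    matrix(vapply(unlist(x, recursive = FALSE), function(v)
      if (is.null(v)) NA_real_ else as.numeric(v), numeric(1)),
      nrow = nr, byrow = TRUE)
  }
  for (nm in c("probe_effects", "sigma", "tau"))
    obj[[nm]] <- unlist(obj[[nm]])
  obj$gamma <- as_mat(obj$gamma, length(obj$probe_effects))
  rownames(obj$gamma) <- names(obj$probe_effects)
  obj$baseline <- unlist(obj$baseline)
  obj$array_effects <- unlist(obj$array_effects)
  obj$batch_of <- unlist(obj$batch_of)
  if (!is.null(obj$concentration)) {
    obj$concentration <- as_mat(obj$concentration, length(obj$baseline))
    dimnames(obj$concentration) <- list(names(obj$baseline),
                                        names(obj$array_effects))
  }
  if (!is.null(obj$spiked)) obj$spiked <- unlist(obj$spiked)
  if (!is.null(obj$design))
    obj$design <- make_latin_square(obj$design$n_groups,
                                    concentrations =
                                      unlist(obj$design$concentrations))
  structure(obj, class = "spikein_truth")
}
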