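# Probe-level data model, file I/O, balanced sampling, frozen bundles.

write_fixture_files <- function(dir, vals = NULL, drop_annotation = NULL) {
  if (is.null(vals))
    vals <- matrix(c(5.5, 7, 1024, 9.25,
                     6, 8, 2048, 10,
                     7, 9, 4096, 11), 4, 3,
                   dimnames = list(c("p1", "p2", "q1", "q2"),
                                   c("a1", "a2", "a3")))
  mp <- file.path(dir, "m.tsv"); ap <- file.path(dir, "ann.tsv")
  bp <- file.path(dir, "b.tsv")
  write.table(data.frame(probe_id = rownames(vals), vals),
              mp, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- data.frame(probe_id = c("p1", "p2", "q1", "q2"),
                    probeset_id = c("psA", "psA", "psB", "psB"))
  if (!is.null(drop_annotation))
    ann <- ann[ann$probe_id != drop_annotation, ]
  write.table(ann, ap, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(array_id = c("a1", "a2", "a3"),
                         batch = c("b1", "b1", "b2")),
              bp, sep = "\t", quote = FALSE, row.names = FALSE)
  list(matrix = mp, annotation = ap, batch = bp)
}

test_that("a complete delimited dataset parses into canonical form", {
  d <- withr_local_tempdir()
  f <- write_fixture_files(d)
  pm <- read_probe_matrix(f$matrix, f$annotation, f$batch)
  expect_s3_class(pm, "probe_matrix")
  expect_equal(n_probes(pm), 4)
  expect_equal(n_probesets(pm), 2)
  expect_equal(n_arrays(pm), 3)
  expect_equal(unname(pm$batch_of), c("b1", "b1", "b2"))
  # canonical ordering: probeset then probe id
  expect_equal(rownames(pm$intensities), c("p1", "p2", "q1", "q2"))
  # reading the same files twice is bit-identical
  expect_identical(pm, read_probe_matrix(f$matrix, f$annotation, f$batch))
})

test_that("invalid inputs fail with informative errors", {
  d <- withr_local_tempdir()
  bad <- matrix(c(5.5, 7, 1024, 9.25, 0, 8, 2048, 10, 7, 9, 4096, 11),
                4, 3, dimnames = list(c("p1", "p2", "q1", "q2"),
                                      paste0("a", 1:3)))
  f <- write_fixture_files(d, vals = bad)
  expect_error(read_probe_matrix(f$matrix, f$annotation),
               "non-positive")
  f2 <- write_fixture_files(d, drop_annotation = "q1")
  expect_error(read_probe_matrix(f2$matrix, f2$annotation), "q1")
  m <- matrix(1:4, 2, 2, dimnames = list(c("p1", "p2"), c("a1", "a1")))
  expect_error(probe_matrix(m + 0.5, setNames(c("s", "s"), c("p1", "p2"))),
               "duplicate array id")
})

test_that("probe matrices round-trip through write_probe_matrix", {
  d <- withr_local_tempdir()
  sim <- simulate_training_set(n_probesets = 4, probes_per_set = 3,
                               n_batches = 2, batch_size = 2, seed = 5)
  paths <- write_probe_matrix(sim$pm, file.path(d, "sim"))
  pm2 <- read_probe_matrix(paths[1], paths[2], paths[3])
  expect_equal(pm2$intensities, sim$pm$intensities)
  expect_identical(pm2$probeset_of, sim$pm$probeset_of)
  expect_identical(pm2$batch_of, sim$pm$batch_of)
})

test_that("balanced_sample draws exactly batch_size arrays per batch", {
  sim <- simulate_training_set(n_probesets = 5, probes_per_set = 2,
                               n_batches = 20, batch_size = 8, seed = 2)
  sub <- balanced_sample(sim$pm, n_batches = 20, batch_size = 5, seed = 4)
  expect_equal(n_arrays(sub), 100)
  expect_true(all(table(sub$batch_of) == 5))
  # deterministic given the seed
  sub2 <- balanced_sample(sim$pm, n_batches = 20, batch_size = 5, seed = 4)
  expect_identical(colnames(sub$intensities), colnames(sub2$intensities))
  # a different seed picks a different set
  sub3 <- balanced_sample(sim$pm, n_batches = 20, batch_size = 5, seed = 5)
  expect_false(identical(colnames(sub$intensities),
                         colnames(sub3$intensities)))
})

test_that("under-filled batches are ineligible and counted in the error", {
  sim <- simulate_training_set(n_probesets = 5, probes_per_set = 2,
                               n_batches = 4, batch_size = 3, seed = 2)
  # batches hold 3 arrays; asking for 5-array batches leaves none eligible
  expect_error(balanced_sample(sim$pm, n_batches = 2, batch_size = 5),
               "only 0 of 4 batches")
  expect_error(balanced_sample(sim$pm, n_batches = 5, batch_size = 3),
               "only 4 of 4")
})

test_that("frozen bundles round-trip losslessly with metadata", {
  d <- withr_local_tempdir()
  pm <- tiny_probe_matrix()
  fv <- flat_frozen_vectors(pm, reference = log2(sort(pm$intensities[, 1])),
                            phi = c(-0.25, 0.25, 1 / 3, -1 / 3),
                            median_se = c(psA = 0.11, psB = 0.21))
  fv$metadata$n_training_arrays <- 4L
  fv$metadata$n_batches <- 2L
  fv$metadata$seed <- 99L
  write_frozen_vectors(fv, file.path(d, "bundle"))
  fv2 <- read_frozen_vectors(file.path(d, "bundle"))
  for (v in c("reference_distribution", "probe_effects",
              "within_batch_var", "between_batch_var",
              "probeset_avg_sd", "median_se"))
    expect_identical(fv2[[v]], fv[[v]], label = v)
  expect_identical(fv2$probe_ids, fv$probe_ids)
  expect_equal(fv2$metadata$n_training_arrays, 4)
  expect_equal(fv2$metadata$seed, 99)
})

test_that("bundle loading enforces mandatory vectors, tolerates median_se", {
  d <- withr_local_tempdir()
  pm <- tiny_probe_matrix()
  fv <- flat_frozen_vectors(pm, reference = log2(sort(pm$intensities[, 1])))
  p <- file.path(d, "bundle")
  write_frozen_vectors(fv, p)
  # no median_se: loads with quality scoring disabled
  fv2 <- read_frozen_vectors(p)
  expect_null(fv2$median_se)
  file.remove(file.path(p, "between_batch_var.tsv"))
  expect_error(read_frozen_vectors(p),
               "missing mandatory vector: between_batch_var")
})

test_that("frozen-vector invariants are enforced", {
  pm <- tiny_probe_matrix()
  ref <- log2(sort(pm$intensities[, 1]))
  expect_error(flat_frozen_vectors(pm, ref, phi = c(1, 1, 0, 0)),
               "sum to zero")
  expect_error(suppressWarnings(flat_frozen_vectors(pm, ref, sigma2 = -1)),
               "nonnegative")
  fv <- flat_frozen_vectors(pm, ref)
  fv$reference_distribution <- rev(fv$reference_distribution)
  expect_error(validate_frozen_vectors(fv), "nondecreasing")
})
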