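test_that("pair_deviation matches its closed form and conventions", {
  expect_equal(pair_deviation(100, 100), 0)
  expect_equal(pair_deviation(150, 50), 0.5)
  expect_equal(pair_deviation(0, 0), 0)
  expect_error(pair_deviation(-1, 5), ">= 0")
  # symmetric, bounded, zero iff equal
  set.seed(21)
  a <- runif(200, 0, 50); b <- runif(200, 0, 50)
  expect_equal(pair_deviation(a, b), pair_deviation(b, a))
  expect_true(all(pair_deviation(a, b) >= 0 & pair_deviation(a, b) <= 1))
  expect_true(all((pair_deviation(a, b) == 0) == (a == b)))
})

test_that("direction_weight encodes antipodal symmetry of diffusion encoding", {
  ex <- c(1, 0, 0); ey <- c(0, 1, 0)
  expect_equal(direction_weight(ex, ex), 1)
  expect_equal(direction_weight(ex, ey), 0)
  expect_equal(direction_weight(ex, -ex, antipodal = TRUE), 1)
  expect_equal(direction_weight(ex, -ex, antipodal = FALSE), 0)
  expect_error(direction_weight(c(2, 0, 0), ex), "unit")
  # simulated signal really is identical under g -> -g
  truth <- small_phantom(c(6, 6, 4))
  g <- rbind(c(1, 0, 0), c(-1, 0, 0))
  ds <- simulate_signal(truth, gradient_table(g, c(1000, 1000)), snr = NULL)
  expect_equal(ds$intensities[, , , 1], ds$intensities[, , , 2])
})

test_that("slice_means computes per-slice arithmetic means, honoring masks", {
  ds <- toy_dataset(dims = c(4, 4, 4), fill = 7)
  sm <- slice_means(ds)
  expect_equal(dim(sm$means), c(10L, 4L))
  expect_true(all(sm$means == 7))
  # halving one slice of one volume halves exactly that entry
  arr <- ds$intensities
  arr[, , 2, 3] <- arr[, , 2, 3] * 0.5
  sm2 <- slice_means(dwi_dataset(arr, 2.3, ds$gradients))
  expect_equal(sm2$means[3, 2], 3.5)
  changed <- sm2$means != sm$means
  expect_equal(which(changed), which(row(sm$means) == 3 & col(sm$means) == 2))
  # a mask excluding slice 4 marks it NA, and downstream it is not evaluated
  mask <- array(TRUE, c(4, 4, 4)); mask[, , 4] <- FALSE
  sm3 <- slice_means(ds, mask)
  expect_true(all(is.na(sm3$means[, 4])))
  dev <- deviation_matrix(sm3, ds$gradients, qc_config(background_floor = 0))
  expect_true(all(is.na(dev$delta[, 4])))
  expect_true(all(!is.na(dev$delta[, 1:3])))
  expect_error(slice_means(ds, array(TRUE, c(3, 3, 3))), "mask grid")
})

test_that("deviation_matrix equals the brute-force double-loop oracle", {
  cfgs <- expand.grid(antipodal = c(TRUE, FALSE), normalize = c(TRUE, FALSE))
  set.seed(31)
  for (rep in 1:10) {
    V <- sample(3:8, 1); Z <- sample(2:6, 1)
    means <- matrix(runif(V * Z, 5, 100), V, Z)
    dirs <- random_unit_vectors(V)
    gt <- gradient_table(dirs, rep(1000, V))
    for (k in seq_len(nrow(cfgs))) {
      cfg <- qc_config(antipodal_weights = cfgs$antipodal[k],
                       normalize_weights = cfgs$normalize[k],
                       background_floor = 0)
      got <- deviation_matrix(as_slice_means(means), gt, cfg)$delta
      want <- bf_deviation_matrix(means, dirs, cfgs$antipodal[k], cfgs$normalize[k])
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("deviation_matrix is zero for identical volumes and scale invariant", {
  V <- 6; Z <- 5
  means <- matrix(rep(runif(Z, 10, 50), each = V), V, Z)
  gt <- gradient_table(random_unit_vectors(V), rep(1000, V))
  dev <- deviation_matrix(as_slice_means(means), gt, qc_config(background_floor = 0))
  expect_true(all(dev$delta == 0))
  # Eq. 1 is a ratio: rescaling the dataset leaves the statistic unchanged
  set.seed(41)
  means2 <- matrix(runif(V * Z, 5, 80), V, Z)
  d1 <- deviation_matrix(as_slice_means(means2), gt, qc_config(background_floor = 0))$delta
  d2 <- deviation_matrix(as_slice_means(means2 * 37.5), gt,
                         qc_config(background_floor = 0))$delta
  expect_equal(d1, d2, tolerance = 1e-12)
  expect_error(deviation_matrix(as_slice_means(means2[1, , drop = FALSE]),
                                subset_gradients(gt, 1), qc_config()),
               "at least 2 volumes")
})

test_that("an attenuated slice dominates the deviation matrix", {
  gt <- default_gradient_scheme(6, 0, 1000, 0)
  truth <- small_phantom(c(8, 8, 6))
  ds <- simulate_signal(truth, gt, snr = NULL)
  inj <- inject_artifacts(ds, artifact_spec(volume = 4, slice_lo = 3,
                                            attenuation = 0.5))
  dev <- deviation_matrix(slice_means(inj$dataset), gt, qc_config())
  hit <- which(dev$delta == max(dev$delta, na.rm = TRUE), arr.ind = TRUE)
  expect_equal(unname(hit[1, ]), c(4L, 3L))
  expect_gt(max(dev$delta, na.rm = TRUE),
            max(dev$delta[-4, ], na.rm = TRUE))
})

test_that("flag_volumes applies the whole-volume elimination rule", {
  gt <- gradient_table(random_unit_vectors(4), rep(1000, 4))
  mk <- function(delta) structure(list(delta = delta, n_comparisons = 3L,
                                       background = rep(FALSE, ncol(delta)),
                                       shell_label = "high",
                                       volume_indices = seq_len(nrow(delta))),
                                  class = "deviation_matrix")
  expect_equal(flag_volumes(mk(matrix(0, 4, 5)), qc_config(threshold = 0.2)),
               integer(0))
  d <- matrix(0.01, 4, 5); d[2, 3] <- 0.25
  expect_equal(flag_volumes(mk(d), qc_config(threshold = 0.2)), 2L)
  d[2, 4] <- 0.3   # two slices above threshold: volume listed once
  expect_equal(flag_volumes(mk(d), qc_config(threshold = 0.2)), 2L)
  # monotonicity: raising the threshold never adds a flagged volume
  set.seed(51)
  d2 <- matrix(runif(20, 0, 0.5), 4, 5)
  flags <- lapply(c(0.1, 0.2, 0.3, 0.4), function(th)
    flag_volumes(mk(d2), qc_config(threshold = th)))
  for (k in 2:4) expect_true(all(flags[[k]] %in% flags[[k - 1]]))
})

test_that("voxel_outlier_counts matches the per-voxel brute-force oracle", {
  set.seed(61)
  gt <- gradient_table(random_unit_vectors(3), rep(1000, 3))
  arr <- array(runif(2 * 2 * 2 * 3, 10, 100), c(2, 2, 2, 3))
  ds <- dwi_dataset(arr, 2.3, gt)
  expect_equal(voxel_outlier_counts(ds), bf_outlier_counts(arr, gt$directions))
  # identical volumes: zero spread, zero counts
  same <- dwi_dataset(array(rep(arr[, , , 1], 3), dim(arr)), 2.3, gt)
  expect_true(all(voxel_outlier_counts(same) == 0L))
  expect_error(voxel_outlier_counts(dwi_dataset(arr[, , , 1:2, drop = FALSE], 2.3,
                                                subset_gradients(gt, 1:2))),
               "at least 3")
  # a larger random instance against the oracle
  gt2 <- default_gradient_scheme(7, 0, 1000, 0)
  arr2 <- array(runif(3 * 3 * 3 * 7, 5, 50), c(3, 3, 3, 7))
  expect_equal(voxel_outlier_counts(dwi_dataset(arr2, 2.3, gt2)),
               bf_outlier_counts(arr2, gt2$directions))
})

test_that("a dropout slice shows elevated voxel outlier counts", {
  truth <- small_phantom()
  gt <- default_gradient_scheme(30, 0, 1000, 0)
  ds <- simulate_signal(truth, gt, snr = 30, seed = 77)
  inj <- inject_artifacts(ds, artifact_spec(volume = 12, slice_lo = 6,
                                            attenuation = 0.3))
  counts <- voxel_outlier_counts(inj$dataset)
  clean <- counts[-12, 3:10]
  expect_gt(counts[12, 6], median(clean))
})

test_that("apply_qc removes volumes consistently and guards the tensor fit", {
  gt <- default_gradient_scheme(64, 8)
  set.seed(71)
  arr <- array(runif(3 * 3 * 3 * 72, 10, 100), c(3, 3, 3, 72))
  ds <- dwi_dataset(arr, 2.3, gt)
  expect_equal(apply_qc(ds, integer(0)), ds)
  flagged <- c(3L, 10L, 25L, 40L, 60L)
  out <- apply_qc(ds, flagged)
  expect_equal(dim(out$intensities)[4], 67L)
  expect_equal(out$volume_indices, setdiff(1:72, flagged))
  keep <- setdiff(1:72, flagged)
  expect_equal(out$gradients$bvalues, gt$bvalues[keep])
  expect_equal(out$gradients$directions, gt$directions[keep, ], ignore_attr = TRUE)
  expect_equal(out$intensities, arr[, , , keep])
  expect_error(apply_qc(ds, setdiff(1:72, c(1, 2, 65, 66))),
               "insufficient data for tensor fit")
  expect_error(apply_qc(ds, c(1L, 999L)), "not present")
})

test_that("run_qc is deterministic and flags dropouts in either shell", {
  truth <- small_phantom()
  gt <- default_gradient_scheme(30, 4)
  ds <- simulate_signal(truth, gt, snr = 25, seed = 99)
  r1 <- run_qc(ds)
  r2 <- run_qc(ds)
  expect_identical(r1, r2)
  expect_length(r1$flagged_volumes, 0L)
  expect_named(r1$worst_slice,
               c("volume_index", "shell", "worst_slice", "delta_I", "flagged"))
  expect_equal(nrow(r1$worst_slice), 34L)
  # dropouts in a high-b and a low-b volume are both caught
  inj <- inject_artifacts(ds, artifact_spec(volume = c(5, 32), slice_lo = c(5, 7),
                                            slice_hi = c(6, 7),
                                            attenuation = c(0.5, 0.4)))
  r3 <- run_qc(inj$dataset)
  expect_equal(r3$flagged_volumes, c(5L, 32L))
  expect_true(all(r3$worst_slice$flagged[r3$worst_slice$volume_index %in% c(5, 32)]))
  expect_equal(dim(r3$outlier_counts), c(30L, 12L))
})
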