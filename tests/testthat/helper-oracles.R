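# Independent brute-force oracles and small fixture builders.  The oracles
# deliberately use plain double loops and share no code with the package
# internals they are checked against.

# weighted slicewise deviation, double loop over all (volume, slice) pairs
bf_deviation_matrix <- function(means, directions, antipodal = TRUE,
                                normalize = TRUE, background_floor = 0) {
  V <- nrow(means); Z <- ncol(means)
  delta <- matrix(NA_real_, V, Z)
  for (z in seq_len(Z)) {
    if (median(means[, z]) < background_floor) next
    for (j in seq_len(V)) {
      acc <- 0; wsum <- 0
      for (i in seq_len(V)) {
        if (i == j) next
        gi <- directions[i, ]; gj <- directions[j, ]
        if (sqrt(sum(gi^2)) < 0.5 || sqrt(sum(gj^2)) < 0.5) {
          w <- 1
        } else {
          d <- sum(gi * gj)
          w <- if (antipodal) abs(d) else max(d, 0)
          w <- min(w, 1)
        }
        s <- means[i, z] + means[j, z]
        dI <- if (s > 0) abs(means[i, z] - means[j, z]) / s else 0
        acc <- acc + w * dI
        wsum <- wsum + w
      }
      delta[j, z] <- acc / (if (normalize) wsum else V - 1)
    }
  }
  delta
}

# per-voxel weighted mean/SD outlier counting, all plain loops
bf_outlier_counts <- function(arr, directions, antipodal = TRUE) {
  d <- dim(arr); V <- d[4]
  counts <- matrix(0L, V, d[3])
  for (j in seq_len(V)) {
    w <- numeric(V)
    for (i in seq_len(V)) {
      if (i == j) next
      gi <- directions[i, ]; gj <- directions[j, ]
      if (sqrt(sum(gi^2)) < 0.5 || sqrt(sum(gj^2)) < 0.5) {
        w[i] <- 1
      } else {
        dd <- sum(gi * gj)
        w[i] <- min(if (antipodal) abs(dd) else max(dd, 0), 1)
      }
    }
    for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
      v <- arr[x, y, z, ]
      wm <- sum(w * v) / sum(w)
      wsd <- sqrt(max(sum(w * v^2) / sum(w) - wm^2, 0))
      if (abs(v[j] - wm) > 2 * wsd + 1e-8 * (abs(wm) + 1e-12))
        counts[j, z] <- counts[j, z] + 1L
    }
  }
  counts
}

random_unit_vectors <- function(n) {
  m <- matrix(rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

random_spd_tensor <- function(scale = 1e-3) {
  A <- matrix(rnorm(9), 3, 3)
  S <- crossprod(A) * scale / 3 + diag(3) * scale * 0.05
  c(S[1, 1], S[2, 2], S[3, 3], S[1, 2], S[1, 3], S[2, 3])
}

random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3, 3)))
}

# wrap a bare V x Z matrix as a slice-mean object
as_slice_means <- function(means) {
  structure(list(means = means, volume_indices = seq_len(nrow(means))),
            class = "slice_intensity_matrix")
}

# concatenate two intensity arrays along the volume axis
abind_volumes <- function(a, b) {
  d <- dim(a)
  array(c(a, b), c(d[1:3], d[4] + dim(b)[4]))
}

# small dataset with explicit intensities and a well-spread scheme
toy_dataset <- function(dims = c(4, 4, 4), gradients = default_gradient_scheme(8, 2),
                        fill = 100) {
  arr <- array(fill, c(dims, length(gradients)))
  dwi_dataset(arr, 2.3, gradients)
}

# compact phantom + acquisition used by simulation-heavy tests
small_phantom <- function(grid = c(16, 16, 12)) {
  build_phantom(phantom_spec(grid_shape = grid))
}
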