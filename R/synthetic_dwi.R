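#' Deterministic single-shell gradient scheme
#'
#' Generates `n_high` approximately uniformly spread unit directions on the
#' upper hemisphere via the spherical Fibonacci lattice (deterministic, no
#' randomness), followed by `n_low` low-b anchor volumes sharing the
#' direction (0, 0, 1) (or the zero vector if `b_low = 0`).  The default
#' mirrors a single-shell clinical protocol: 64 directions at
#' b = 1000 s/mm^2 plus 8 volumes at b = 100 s/mm^2.
#'
#' @param n_high number of diffusion-weighted directions (>= 6).
#' @param n_low number of low-b anchor volumes.
#' @param b_high,b_low b-values in s/mm^2.
#' @return A [gradient_table()] of length `n_high + n_low` with the high
#'   shell first.
#' @export
default_gradient_scheme <- function(n_high = 64L, n_low = 8L,
                                    b_high = 1000, b_low = 100) {
  if (n_high < 6L)
    stop("at least 6 diffusion-weighted directions are required")
  i <- seq_len(n_high) - 1
  z <- (i + 0.5) / n_high
  r <- sqrt(1 - z^2)
  phi <- i * pi * (3 - sqrt(5))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  low_dir <- if (b_low > 0) c(0, 0, 1) else c(0, 0, 0)
  if (n_low > 0L)
    dirs <- rbind(dirs, matrix(low_dir, nrow = n_low, ncol = 3L, byrow = TRUE))
  gradient_table(dirs, c(rep(b_high, n_high), rep(b_low, n_low)))
}

# full-sphere Fibonacci lattice, used for orientation-mixed phantom regions
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 2 * (i + 0.5) / n - 1
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Describe a rectangular phantom region
#'
#' @param x,y,z integer index ranges (inclusive) of the box.
#' @param eigenvalues length-3 diffusivities (l1 >= l2 >= l3) in mm^2/s.
#' @param direction principal-direction rule: `"fixed"` aligns every voxel
#'   with `axis`; `"mixed"` assigns each voxel a direction from a
#'   deterministic Fibonacci-sphere lattice, emulating the orientation
#'   diversity of white matter within a slice.
#' @param axis principal direction for `direction = "fixed"`.
#' @param label region name carried into the ground-truth region map.
#' @return A `phantom_region` list.
#' @export
phantom_region <- function(x, y, z, eigenvalues,
                           direction = c("fixed", "mixed"),
                           axis = c(1, 0, 0), label = "region") {
  direction <- match.arg(direction)
  eigenvalues <- as.numeric(eigenvalues)
  if (length(eigenvalues) != 3L || any(!is.finite(eigenvalues)) || any(eigenvalues < 0))
    stop("eigenvalues must be 3 finite non-negative diffusivities")
  axis <- as.numeric(axis)
  axis <- axis / sqrt(sum(axis^2))
  structure(list(x = range(x), y = range(y), z = range(z),
                 eigenvalues = eigenvalues, direction = direction,
                 axis = axis, label = label),
            class = "phantom_region")
}

default_phantom_regions <- function(grid_shape) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  xi <- seq(max(2, round(0.15 * nx)), min(nx - 1, round(0.87 * nx)))
  zi <- seq(max(2, round(0.07 * nz)), min(nz - 1, round(0.95 * nz)))
  ysplit <- round(ny / 2)
  list(
    phantom_region(xi, seq(max(2, round(0.15 * ny)), ysplit), zi,
                   eigenvalues = c(0.7, 0.7, 0.7) * 1e-3,
                   label = "isotropic"),
    phantom_region(xi, seq(ysplit + 1, min(ny - 1, round(0.87 * ny))), zi,
                   eigenvalues = c(1.7, 0.3, 0.3) * 1e-3,
                   direction = "mixed", label = "anisotropic")
  )
}

#' Phantom specification
#'
#' Geometry and tissue model of the synthetic phantom.  The default is a
#' 32 x 32 x 40 grid of 2.3 mm isotropic voxels — 40 axial slices as in a
#' typical clinical acquisition — containing an isotropic region
#' (diffusivity 0.7e-3 mm^2/s, FA 0) and an anisotropic region with
#' eigenvalues (1.7, 0.3, 0.3)e-3 mm^2/s (FA ~ 0.80) whose per-voxel
#' principal directions sample the sphere quasi-uniformly, surrounded by
#' signal-free background.
#'
#' @param grid_shape 3 integers, the voxel grid.
#' @param voxel_size voxel edge lengths in mm (scalar or length 3).
#' @param regions list of [phantom_region()] objects; must not overlap and
#'   must contain at least one region.
#' @param s0 baseline non-diffusion-weighted signal inside regions.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 40L), voxel_size = 2.3,
                         regions = default_phantom_regions(grid_shape),
                         s0 = 100) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("grid_shape must be 3 positive integers")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(regions) < 1L)
    stop("at least one foreground region is required")
  if (!all(vapply(regions, inherits, logical(1), "phantom_region")))
    stop("regions must be phantom_region objects")
  if (!is.finite(s0) || s0 <= 0) stop("s0 must be positive")
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 regions = regions, s0 = s0),
            class = "phantom_spec")
}

tensor6_from_eig <- function(eigenvalues, u) {
  # complete u to an orthonormal basis (l2 and l3 may differ)
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * u) * u
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  D <- eigenvalues[1] * tcrossprod(u) + eigenvalues[2] * tcrossprod(v) +
    eigenvalues[3] * tcrossprod(w)
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}

#' Build the ground-truth tensor field of a phantom
#'
#' Assembles per-voxel diffusion tensors from the region eigenvalues and
#' principal-direction rules of a [phantom_spec()].  Background voxels have
#' zero tensor and zero S0.
#'
#' @param spec a [phantom_spec()].
#' @return A `tensor_field` (as from [fit_tensor()]) with an additional
#'   `region` element, a 3-D character array of region labels (`NA` in the
#'   background), usable as ground truth.
#' @export
build_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  occupancy <- array(0L, d)
  tensor <- array(0, c(d, 6L), dimnames = list(NULL, NULL, NULL, tensor_names))
  region <- array(NA_character_, d)
  for (rg in spec$regions) {
    if (rg$x[2] > d[1] || rg$y[2] > d[2] || rg$z[2] > d[3] || min(rg$x, rg$y, rg$z) < 1)
      stop(sprintf("region '%s' exceeds the phantom grid", rg$label))
    xs <- rg$x[1]:rg$x[2]; ys <- rg$y[1]:rg$y[2]; zs <- rg$z[1]:rg$z[2]
    occupancy[xs, ys, zs] <- occupancy[xs, ys, zs] + 1L
    if (any(occupancy > 1L))
      stop(sprintf("region '%s' overlaps a previous region", rg$label))
    region[xs, ys, zs] <- rg$label
    if (rg$direction == "fixed") {
      t6 <- tensor6_from_eig(rg$eigenvalues, rg$axis)
      for (k in 1:6) tensor[xs, ys, zs, k] <- t6[k]
    } else {
      # one direction per in-plane position, replicated across slices, so
      # every slice carries the same quasi-uniform orientation distribution
      nxy <- length(xs) * length(ys)
      U <- fibonacci_sphere(nxy)
      T6 <- t(vapply(seq_len(nxy), function(i)
        tensor6_from_eig(rg$eigenvalues, U[i, ]), numeric(6)))
      for (k in 1:6)
        tensor[xs, ys, zs, k] <- array(T6[, k], c(nxy, length(zs)))
    }
  }
  mask <- occupancy > 0L
  s0 <- array(0, d)
  s0[mask] <- spec$s0
  structure(list(tensor = tensor, s0 = s0, mask = mask,
                 voxel_size = spec$voxel_size, region = region),
            class = "tensor_field")
}

#' Simulate diffusion-weighted signal from a tensor field
#'
#' Monoexponential tensor signal model: for every voxel and volume,
#' `S = S0 exp(-b g' D g)`.  If `snr` is given, Rician noise is applied —
#' the magnitude of the signal plus two independent Gaussian channels with
#' `sigma = mean(foreground S0) / snr` — emulating magnitude MRI; `snr =
#' NULL` yields the noise-free signal.  All randomness derives from `seed`
#' without touching the global random state.
#'
#' @param truth a `tensor_field` (e.g. from [build_phantom()]).
#' @param gradients a [gradient_table()].
#' @param snr signal-to-noise ratio of the baseline signal, or `NULL`.
#' @param seed integer seed for the noise (ignored when `snr` is `NULL`).
#' @return A [dwi_dataset()].
#' @export
simulate_signal <- function(truth, gradients, snr = NULL, seed = 1L) {
  stopifnot(inherits(truth, "tensor_field"), inherits(gradients, "gradient_table"))
  if (!is.null(snr) && (!is.finite(snr) || snr <= 0))
    stop("snr must be positive (or NULL for noise-free)")
  d <- dim(truth$s0)
  V <- length(gradients)
  Xb <- design_matrix(gradients)[, 1:6, drop = FALSE]     # -b quadratic forms
  T6 <- matrix(truth$tensor, ncol = 6L)
  S <- as.vector(truth$s0) * exp(T6 %*% t(Xb))            # voxels x volumes
  if (!is.null(snr)) {
    sigma <- mean(truth$s0[truth$mask]) / snr
    S <- withr::with_seed(as.integer(seed), {
      n1 <- matrix(rnorm(length(S), sd = sigma), nrow(S))
      n2 <- matrix(rnorm(length(S), sd = sigma), nrow(S))
      sqrt((S + n1)^2 + n2^2)
    })
  }
  dwi_dataset(array(S, c(d, V)), truth$voxel_size, gradients)
}

#' Slice-dropout artifact specification
#'
#' A list of dropout events, each attenuating a contiguous range of axial
#' slices of one volume by a multiplicative factor in \[0, 1) — the
#' phenomenology of motion-related signal loss, without modelling the
#' underlying spin-history physics.
#'
#' @param volume integer volume indices (one per event).
#' @param slice_lo,slice_hi inclusive slice ranges (one per event).
#' @param attenuation multiplicative factors in \[0, 1), one per event.
#' @return An `artifact_spec` data.frame with one row per event.
#' @export
artifact_spec <- function(volume, slice_lo, slice_hi = slice_lo, attenuation) {
  ev <- data.frame(volume = as.integer(volume), slice_lo = as.integer(slice_lo),
                   slice_hi = as.integer(slice_hi),
                   attenuation = as.numeric(attenuation))
  if (any(!is.finite(ev$attenuation)) || any(ev$attenuation < 0) ||
      any(ev$attenuation >= 1))
    stop("attenuation must lie in [0, 1): an event must change the signal")
  if (any(ev$slice_hi < ev$slice_lo))
    stop("slice_hi must be >= slice_lo")
  class(ev) <- c("artifact_spec", "data.frame")
  ev
}

#' Inject slice-dropout artifacts with ground-truth labels
#'
#' Multiplies the named slices of the named volumes by their attenuation
#' factors and returns the corrupted dataset together with the ground
#' truth needed to score a detector.
#'
#' @param dataset a [dwi_dataset()].
#' @param spec an [artifact_spec()] (may have zero rows).
#' @return A list with elements `dataset` (corrupted copy) and `truth`, a
#'   list holding `corrupted_volumes` (sorted original volume indices) and
#'   `slice_mask` (V x Z logical corruption map).
#' @export
inject_artifacts <- function(dataset, spec) {
  stopifnot(inherits(dataset, "dwi_dataset"), inherits(spec, "artifact_spec"))
  d <- dim(dataset$intensities)
  if (nrow(spec) > 0L &&
      (any(spec$volume < 1L) || any(spec$volume > d[4L]) ||
       any(spec$slice_lo < 1L) || any(spec$slice_hi > d[3L])))
    stop("artifact volume/slice indices out of range")
  arr <- dataset$intensities
  slice_mask <- matrix(FALSE, d[4L], d[3L])
  for (k in seq_len(nrow(spec))) {
    zs <- spec$slice_lo[k]:spec$slice_hi[k]
    arr[, , zs, spec$volume[k]] <- arr[, , zs, spec$volume[k]] * spec$attenuation[k]
    slice_mask[spec$volume[k], zs] <- TRUE
  }
  list(dataset = dwi_dataset(arr, dataset$voxel_size, dataset$gradients,
                             dataset$volume_indices),
       truth = list(corrupted_volumes = sort(unique(dataset$volume_indices[spec$volume])),
                    slice_mask = slice_mask))
}
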