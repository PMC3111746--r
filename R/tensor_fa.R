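#' Log-linear tensor design matrix
#'
#' Builds the V x 7 design matrix of the log-linear diffusion signal model
#' `log S = -b g' D g + log S0`.  Row v is
#' `(-b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz, -2b gy gz, 1)`,
#' so the coefficient vector is `(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz, log S0)`.
#'
#' @param gradients a [gradient_table()].
#' @return Numeric V x 7 matrix.
#' @export
design_matrix <- function(gradients) {
  stopifnot(inherits(gradients, "gradient_table"))
  g <- gradients$directions
  b <- gradients$bvalues
  cbind(-b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3], 1,
        deparse.level = 0)
}

tensor_names <- c("Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz")

#' Fit the diffusion tensor by linear least squares on log-signals
#'
#' Ordinary least squares of the log intensities on the quadratic-form
#' design of [design_matrix()], solved per voxel.  The exponentiated
#' intercept is the effective non-diffusion-weighted signal S0, standing in
#' for an unweighted acquisition even when only low-b (e.g. b = 100 s/mm^2)
#' anchor volumes were acquired.  Zero or near-zero intensities (Rician
#' noise floor) are clamped to `1e-4 * S0_estimate` before the logarithm.
#'
#' @param dataset a [dwi_dataset()] with at least 7 volumes spanning a
#'   rank-7 design.
#' @param mask optional 3-D logical array restricting the fit; if `NULL`,
#'   all voxels are fitted and the stored foreground mask is derived as
#'   S0 > 10\% of its robust (99th percentile) maximum.
#' @return An object of class `tensor_field` with elements `tensor`
#'   (X x Y x Z x 6 array, components Dxx, Dyy, Dzz, Dxy, Dxz, Dyz in
#'   mm^2/s), `s0` (3-D array), `mask` (3-D logical) and `voxel_size`.
#' @export
fit_tensor <- function(dataset, mask = NULL) {
  stopifnot(inherits(dataset, "dwi_dataset"))
  d <- dim(dataset$intensities)
  V <- d[4L]
  X <- design_matrix(dataset$gradients)
  if (V < 7L || qr(X)$rank < 7L)
    stop("insufficient gradient scheme: the log-linear design must have rank 7")
  if (!is.null(mask) && !identical(dim(mask), d[1:3]))
    stop("mask grid does not match dataset grid")

  Y <- matrix(dataset$intensities, ncol = V)              # voxels x volumes
  lowb <- dataset$gradients$bvalues <= min(dataset$gradients$bvalues) + 1e-9
  s0_est <- rowMeans(Y[, lowb, drop = FALSE])
  Y <- pmax(Y, pmax(1e-4 * s0_est, 1e-12))                # log-safe floor
  coef <- qr.coef(qr(X), t(log(Y)))                       # 7 x voxels

  tensor <- array(t(coef[1:6, , drop = FALSE]), dim = c(d[1:3], 6L),
                  dimnames = list(NULL, NULL, NULL, tensor_names))
  s0 <- array(exp(coef[7L, ]), dim = d[1:3])
  if (is.null(mask)) {
    mask <- s0 > 0.1 * quantile(s0, 0.99, names = FALSE)
  } else {
    mask <- array(as.logical(mask), d[1:3])
  }
  structure(list(tensor = tensor, s0 = s0, mask = mask,
                 voxel_size = dataset$voxel_size),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  d <- dim(x$s0)
  cat(sprintf("<tensor_field> %d x %d x %d voxels, %d foreground\n",
              d[1], d[2], d[3], sum(x$mask)))
  invisible(x)
}

#' Fractional anisotropy from tensor eigenvalues
#'
#' `FA = sqrt(1/2) * sqrt((l1-l2)^2 + (l2-l3)^2 + (l1-l3)^2) /
#' sqrt(l1^2 + l2^2 + l3^2)`: 0 for isotropic diffusion (water), 1 in the
#' limit where a single diffusion direction dominates.  Negative
#' eigenvalues, which can arise from noise in the linear fit, are clipped
#' to 0 first; if all eigenvalues are 0 after clipping the result is 0.
#' Inputs are vectorized and need not be sorted.
#'
#' @param l1,l2,l3 tensor eigenvalues in mm^2/s (any order).
#' @return FA value(s) in \[0, 1\].
#' @examples
#' fa_from_eigenvalues(1.7e-3, 0.3e-3, 0.3e-3)  # ~0.80
#' @export
fa_from_eigenvalues <- function(l1, l2, l3) {
  if (any(!is.finite(c(l1, l2, l3))))
    stop("eigenvalues must be finite")
  l1 <- pmax(l1, 0); l2 <- pmax(l2, 0); l3 <- pmax(l3, 0)
  num <- sqrt((l1 - l2)^2 + (l2 - l3)^2 + (l1 - l3)^2)
  den <- sqrt(l1^2 + l2^2 + l3^2)
  fa <- ifelse(den > 0, sqrt(0.5) * num / den, 0)
  pmin(pmax(fa, 0), 1)
}

# eigenvalues of each voxel's symmetric 3x3 tensor inside the mask
tensor_eigenvalues <- function(field) {
  idx <- which(field$mask)
  Tm <- matrix(field$tensor, ncol = 6L)[idx, , drop = FALSE]
  ev <- matrix(NA_real_, length(idx), 3L)
  for (k in seq_along(idx)) {
    D <- matrix(c(Tm[k, 1], Tm[k, 4], Tm[k, 5],
                  Tm[k, 4], Tm[k, 2], Tm[k, 6],
                  Tm[k, 5], Tm[k, 6], Tm[k, 3]), 3L, 3L)
    ev[k, ] <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  }
  list(idx = idx, values = ev)
}

#' FA map from a fitted (or ground-truth) tensor field
#'
#' Eigen-decomposes every foreground voxel's tensor and applies
#' [fa_from_eigenvalues()].  Voxels outside the mask are `NA`.
#'
#' @param field a `tensor_field` (from [fit_tensor()] or [build_phantom()]).
#' @return An object of class `fa_map` with elements `fa` (3-D array, `NA`
#'   outside the mask), `mask` and `voxel_size`.
#' @export
fa_map <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  ev <- tensor_eigenvalues(field)
  fa <- array(NA_real_, dim(field$s0))
  fa[ev$idx] <- fa_from_eigenvalues(ev$values[, 1], ev$values[, 2], ev$values[, 3])
  structure(list(fa = fa, mask = field$mask, voxel_size = field$voxel_size),
            class = "fa_map")
}

#' Compute an FA map from a diffusion-weighted dataset
#'
#' Convenience composition of [fit_tensor()] and [fa_map()].
#'
#' @inheritParams fit_tensor
#' @return An `fa_map`.
#' @export
compute_fa_map <- function(dataset, mask = NULL) {
  fa_map(fit_tensor(dataset, mask))
}

#' @export
print.fa_map <- function(x, ...) {
  v <- x$fa[x$mask]
  cat(sprintf("<fa_map> %s voxels, %d foreground; FA median %.3f, max %.3f\n",
              paste(dim(x$fa), collapse = " x "), sum(x$mask),
              median(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}

gaussian_kernel_1d <- function(fwhm_mm, voxel_mm) {
  if (fwhm_mm <= 0) return(1)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm   # in voxels
  r <- max(1L, ceiling(4 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# separable 1-D convolution along the given axis with zero padding
convolve_axis <- function(arr, kernel, axis) {
  if (length(kernel) == 1L) return(arr * kernel)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  d <- dim(a)
  m <- matrix(a, nrow = d[1L])
  out <- matrix(0, nrow = d[1L], ncol = ncol(m))
  r <- (length(kernel) - 1L) / 2L
  for (s in seq_along(kernel)) {
    off <- s - r - 1L
    src <- seq_len(d[1L]) + off
    ok <- src >= 1L & src <= d[1L]
    out[ok, ] <- out[ok, ] + kernel[s] * m[src[ok], ]
  }
  aperm(array(out, d), order(perm))
}

#' Gaussian smoothing of an FA map
#'
#' Separable Gaussian smoothing with the kernel width given as full width
#' at half maximum (FWHM) in mm per axis, converted to voxels via the map's
#' voxel size (`sigma = fwhm / (2 sqrt(2 ln 2))`).  Smoothing is masked:
#' the map (zero-filled outside the mask) and the mask indicator are
#' convolved separately and their ratio taken, so foreground values are
#' never diluted by background zeros and a constant map stays constant.
#'
#' @param map an `fa_map`.
#' @param fwhm_mm scalar or length-3 FWHM in mm (e.g. `c(8, 8, 8)`); 0
#'   disables smoothing on that axis.
#' @param voxel_size voxel edge lengths in mm (defaults to the map's own).
#' @return A smoothed `fa_map` on the same grid and mask.
#' @export
smooth_map <- function(map, fwhm_mm, voxel_size = map$voxel_size) {
  stopifnot(inherits(map, "fa_map"))
  fwhm_mm <- as.numeric(fwhm_mm)
  if (length(fwhm_mm) == 1L) fwhm_mm <- rep(fwhm_mm, 3L)
  if (length(fwhm_mm) != 3L || any(fwhm_mm < 0))
    stop("fwhm_mm must be >= 0 per axis")
  vals <- map$fa
  vals[!map$mask | is.na(vals)] <- 0
  wts <- array(as.numeric(map$mask), dim(map$fa))
  for (ax in 1:3) {
    k <- gaussian_kernel_1d(fwhm_mm[ax], voxel_size[ax])
    vals <- convolve_axis(vals, k, ax)
    wts <- convolve_axis(wts, k, ax)
  }
  sm <- array(NA_real_, dim(map$fa))
  inside <- map$mask & wts > 0
  sm[inside] <- vals[inside] / wts[inside]
  structure(list(fa = sm, mask = map$mask, voxel_size = map$voxel_size),
            class = "fa_map")
}

#' Summarize voxelwise FA differences between two maps
#'
#' Quantifies the effect of quality control by comparing the FA map fitted
#' from all volumes against the FA map fitted after artifact removal, on
#' their shared foreground mask.
#'
#' @param fa_without_qc,fa_with_qc two `fa_map` objects on identical grids
#'   with identical masks.
#' @return A one-row `data.frame` with columns `median`, `mean`, `p95`,
#'   `p99`, `max` (of the per-voxel absolute FA difference),
#'   `frac_ge_0.1` (fraction of voxels with |dFA| >= 0.1) and `n_voxels`.
#' @export
fa_difference_report <- function(fa_without_qc, fa_with_qc) {
  stopifnot(inherits(fa_without_qc, "fa_map"), inherits(fa_with_qc, "fa_map"))
  if (!identical(dim(fa_without_qc$fa), dim(fa_with_qc$fa)))
    stop("FA maps are on different grids")
  if (!identical(fa_without_qc$mask, fa_with_qc$mask))
    stop("FA maps have different foreground masks")
  m <- fa_without_qc$mask
  d <- abs(fa_without_qc$fa[m] - fa_with_qc$fa[m])
  d <- d[is.finite(d)]
  data.frame(median = median(d), mean = mean(d),
             p95 = quantile(d, 0.95, names = FALSE),
             p99 = quantile(d, 0.99, names = FALSE),
             max = max(d), frac_ge_0.1 = mean(d >= 0.1),
             n_voxels = length(d))
}
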