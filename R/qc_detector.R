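#' Quality-control configuration
#'
#' Collects the tunable parameters of the slicewise dropout detector.
#'
#' @param threshold dimensionless flagging threshold on the weighted slice
#'   deviation; a volume is eliminated as soon as one slice exceeds it.
#'   Default 0.2; detection is insensitive to the exact value between 0.2
#'   and 0.3.
#' @param b_split shell boundary in s/mm^2 passed to [split_by_shell()];
#'   the detector runs separately per shell.  Default 500.
#' @param background_floor minimum slice mean (signal units) below which a
#'   slice position is treated as background and excluded from flagging.
#'   `NULL` (default) derives it at run time as 5\% of the shell's robust
#'   maximum intensity (99th percentile).
#' @param antipodal_weights if `TRUE` (default), direction similarity is
#'   `|g_i . g_j|`: diffusion weighting is invariant under g -> -g, so
#'   antipodal directions carry identical contrast and are maximally
#'   similar.  If `FALSE`, the signed dot product clipped below at zero is
#'   used.
#' @param normalize_weights if `TRUE` (default), the weighted slice
#'   deviation is the weight-normalized mean
#'   `sum(w * dI) / sum(w)`, which makes a uniform dropout of attenuation
#'   `a` score `(1 - a) / (1 + a)` regardless of the gradient scheme and
#'   keeps the 0.2 threshold meaningful across acquisitions.  If `FALSE`,
#'   the plain `1/N` sum over comparison volumes is used; its scale then
#'   depends on the direction scheme.
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(threshold = 0.2, b_split = 500, background_floor = NULL,
                      antipodal_weights = TRUE, normalize_weights = TRUE) {
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly between 0 and 1")
  if (!is.null(background_floor) &&
      (!is.finite(background_floor) || background_floor < 0))
    stop("background_floor must be >= 0")
  structure(list(threshold = threshold, b_split = b_split,
                 background_floor = background_floor,
                 antipodal_weights = isTRUE(antipodal_weights),
                 normalize_weights = isTRUE(normalize_weights)),
            class = "qc_config")
}

#' Per-slice mean intensities
#'
#' Computes the arithmetic mean intensity of every axial slice of every
#' volume, optionally restricted to a foreground mask.  Slice positions
#' whose mask contains no voxels are returned as `NA` and excluded from all
#' downstream statistics.
#'
#' @param dataset a [dwi_dataset()].
#' @param mask optional 3-D logical array on the dataset's spatial grid.
#' @return An object of class `slice_intensity_matrix` holding `means`, a
#'   V x Z matrix (volume by slice).
#' @export
slice_means <- function(dataset, mask = NULL) {
  stopifnot(inherits(dataset, "dwi_dataset"))
  d <- dim(dataset$intensities)
  nxy <- d[1L] * d[2L]
  if (is.null(mask)) {
    m <- colMeans(matrix(dataset$intensities, nrow = nxy))   # (z*v) columns
  } else {
    if (!identical(dim(mask), d[1:3]))
      stop(sprintf("mask grid %s does not match dataset grid %s",
                   paste(dim(mask), collapse = "x"), paste(d[1:3], collapse = "x")))
    mask <- array(as.logical(mask), d[1:3])
    nvox <- colSums(matrix(mask, nrow = nxy))                # voxels per slice
    msum <- colSums(matrix(dataset$intensities * as.numeric(mask), nrow = nxy))
    m <- msum / rep(nvox, d[4L])                             # NaN where slice empty
    m[!is.finite(m)] <- NA_real_
  }
  means <- t(matrix(m, nrow = d[3L], ncol = d[4L]))          # V x Z
  structure(list(means = means, volume_indices = dataset$volume_indices),
            class = "slice_intensity_matrix")
}

#' Relative pairwise slice deviation
#'
#' The scale-free deviation between two slice means,
#' `|a_i - a_j| / (a_i + a_j)`, lying in \[0, 1\] and equal to 0 iff the two
#' means agree.  By convention 0 when both means are 0.
#'
#' @param abar_i,abar_j non-negative slice mean intensities (vectorized).
#' @return Dimensionless deviation(s) in \[0, 1\].
#' @examples
#' pair_deviation(150, 50)  # 0.5
#' @export
pair_deviation <- function(abar_i, abar_j) {
  if (any(abar_i < 0, na.rm = TRUE) || any(abar_j < 0, na.rm = TRUE))
    stop("slice means must be >= 0")
  s <- abar_i + abar_j
  d <- abs(abar_i - abar_j)
  out <- ifelse(s > 0, d / s, 0)
  out
}

#' Gradient-direction similarity weight
#'
#' The weighting factor used to compare slices across volumes: the dot
#' product of the two encoding directions, a value near 1 reflecting great
#' similarity.  With `antipodal = TRUE` (default) the absolute value is
#' taken, since the diffusion-weighted signal is identical for g and -g;
#' with `antipodal = FALSE` the signed product is clipped below at zero.
#'
#' @param g_i,g_j unit 3-vectors (norm 1 within 1e-3).
#' @param antipodal treat antipodal directions as identical (default `TRUE`).
#' @return A similarity weight in \[0, 1\].
#' @export
direction_weight <- function(g_i, g_j, antipodal = TRUE) {
  g_i <- as.numeric(g_i); g_j <- as.numeric(g_j)
  for (g in list(g_i, g_j))
    if (length(g) != 3L || abs(sqrt(sum(g^2)) - 1) > 1e-3)
      stop("gradient directions must be unit 3-vectors")
  d <- sum(g_i * g_j)
  w <- if (antipodal) abs(d) else max(d, 0)
  min(w, 1)
}

# pairwise weight matrix for one shell; b ~ 0 volumes (zero direction) and
# shells whose directions coincide get uniform weight 1, since direction
# contrast is negligible there
weight_matrix <- function(gradients, antipodal = TRUE) {
  G <- gradients$directions
  nrm <- sqrt(rowSums(G^2))
  W <- G %*% t(G)
  W <- if (antipodal) abs(W) else pmax(W, 0)
  W[nrm < 0.5, ] <- 1                       # unweighted anchors (b = 0)
  W[, nrm < 0.5] <- 1
  W <- pmin(W, 1)
  diag(W) <- 0
  W
}

#' Weighted slicewise deviation matrix
#'
#' For every volume j and slice z, averages the pairwise relative deviation
#' [pair_deviation()] of slice z against the same slice in every other
#' volume i of the shell, weighted by the direction similarity
#' [direction_weight()].  Slice positions whose median slice mean across
#' volumes falls below the background floor are not evaluated (returned as
#' `NA`): at the apex and base of the head the means are dominated by
#' noise and the ratio in the pairwise deviation becomes unstable.
#'
#' @param slice_means a [slice_means()] result.
#' @param gradients the matching [gradient_table()] (all volumes one shell).
#' @param config a [qc_config()].
#' @param shell_label optional label stored with the result.
#' @return An object of class `deviation_matrix` with elements `delta`
#'   (V x Z matrix, `NA` where not evaluated), `n_comparisons` (V - 1),
#'   `background` (logical per slice), `shell_label` and `volume_indices`.
#' @export
deviation_matrix <- function(slice_means, gradients, config = qc_config(),
                             shell_label = NA_character_) {
  stopifnot(inherits(slice_means, "slice_intensity_matrix"),
            inherits(gradients, "gradient_table"),
            inherits(config, "qc_config"))
  A <- slice_means$means
  V <- nrow(A); Z <- ncol(A)
  if (V != length(gradients))
    stop("slice_means volumes do not match gradient table length")
  if (V < 2L)
    stop("at least 2 volumes are required to compute slice deviations")

  floor_ <- config$background_floor
  if (is.null(floor_))
    floor_ <- 0.05 * quantile(A, 0.99, na.rm = TRUE, names = FALSE)
  med <- apply(A, 2L, median, na.rm = TRUE)
  background <- !is.finite(med) | med < floor_ | apply(A, 2L, anyNA)

  W <- weight_matrix(gradients, config$antipodal_weights)
  denom <- if (config$normalize_weights) rowSums(W) else rep(V - 1, V)
  denom[denom <= 0] <- NA_real_

  delta <- matrix(NA_real_, V, Z)
  for (z in which(!background)) {
    a <- A[, z]
    dI <- pair_deviation(matrix(a, V, V), matrix(a, V, V, byrow = TRUE))
    delta[, z] <- rowSums(W * dI) / denom
  }
  structure(list(delta = delta, n_comparisons = V - 1L, background = background,
                 shell_label = shell_label,
                 volume_indices = slice_means$volume_indices,
                 normalize_weights = config$normalize_weights,
                 antipodal_weights = config$antipodal_weights,
                 background_floor = floor_),
            class = "deviation_matrix")
}

#' @export
print.deviation_matrix <- function(x, ...) {
  cat(sprintf("<deviation_matrix> shell %s: %d volumes x %d slices (%d background), max dI = %.4g\n",
              x$shell_label, nrow(x$delta), ncol(x$delta), sum(x$background),
              suppressWarnings(max(x$delta, na.rm = TRUE))))
  invisible(x)
}

#' Flag corrupted volumes
#'
#' A volume is eliminated as soon as the weighted deviation of any single
#' evaluated slice exceeds the threshold; dropout artifacts affect
#' individual slices, but the whole gradient direction is unusable for the
#' tensor fit.
#'
#' @param deviation a [deviation_matrix()].
#' @param config a [qc_config()] supplying the threshold.
#' @return Sorted integer vector of flagged (original) volume indices.
#' @export
flag_volumes <- function(deviation, config = qc_config()) {
  stopifnot(inherits(deviation, "deviation_matrix"), inherits(config, "qc_config"))
  mx <- apply(deviation$delta, 1L, function(r)
    if (all(is.na(r))) -Inf else max(r, na.rm = TRUE))
  sort(deviation$volume_indices[mx > config$threshold])
}

#' Voxelwise outlier counts per volume and slice
#'
#' The review statistic of the QC panel: for every voxel, the
#' direction-similarity-weighted mean and standard deviation of its
#' intensity across all other volumes are computed; the entry (volume,
#' slice) counts the voxels of that slice deviating from their weighted
#' mean by more than 2 weighted standard deviations.
#'
#' @param dataset a single-shell [dwi_dataset()] with at least 3 volumes.
#' @param gradients gradient table (defaults to the dataset's own).
#' @param antipodal passed to the direction weighting.
#' @return Integer V x Z matrix of outlier voxel counts.
#' @export
voxel_outlier_counts <- function(dataset, gradients = dataset$gradients,
                                 antipodal = TRUE) {
  stopifnot(inherits(dataset, "dwi_dataset"))
  d <- dim(dataset$intensities)
  V <- d[4L]
  if (V < 3L) stop("at least 3 volumes are required for outlier counts")
  if (length(gradients) != V)
    stop("gradient table length does not match volume count")
  Y <- matrix(dataset$intensities, ncol = V)          # voxels x volumes
  W <- weight_matrix(gradients, antipodal)
  zidx <- rep(seq_len(d[3L]), each = d[1L] * d[2L])
  counts <- matrix(0L, V, d[3L])
  for (j in seq_len(V)) {
    w <- W[j, ]
    sw <- sum(w)
    wm <- as.vector(Y %*% w) / sw
    wv <- pmax(as.vector(Y^2 %*% w) / sw - wm^2, 0)
    # strict band with a relative guard so exactly-replicated volumes never count
    out <- abs(Y[, j] - wm) > 2 * sqrt(wv) + 1e-8 * (abs(wm) + 1e-12)
    counts[j, ] <- as.integer(rowsum(as.integer(out), zidx))
  }
  counts
}

#' Remove flagged volumes from a dataset
#'
#' Drops the flagged volumes from intensities and gradient table alike,
#' preserving order and original volume indices.  Refuses to produce a
#' dataset that can no longer support a tensor fit: at least 6 distinct
#' (non-antipodal) diffusion-weighted directions plus one low-b/b0 anchor
#' volume must remain.
#'
#' @param dataset a [dwi_dataset()].
#' @param flagged integer vector of original volume indices to remove
#'   (as returned by [flag_volumes()] or found in a [run_qc()] report).
#' @return The cleaned [dwi_dataset()].
#' @export
apply_qc <- function(dataset, flagged) {
  stopifnot(inherits(dataset, "dwi_dataset"))
  flagged <- as.integer(flagged)
  if (length(setdiff(flagged, dataset$volume_indices)) > 0L)
    stop("flagged indices not present in the dataset")
  keep <- !(dataset$volume_indices %in% flagged)
  out <- dwi_dataset(dataset$intensities[, , , keep, drop = FALSE],
                     dataset$voxel_size,
                     subset_gradients(dataset$gradients, keep),
                     dataset$volume_indices[keep])
  b <- out$gradients$bvalues
  if (length(b) > 0L) {
    dirs <- out$gradients$directions[b > 0, , drop = FALSE]
    # canonical antipodal representative, rounded, to count distinct directions
    if (nrow(dirs) > 0L) {
      flip <- sign(dirs[, 1] + 1e-9 * dirs[, 2] + 1e-12 * dirs[, 3])
      flip[flip == 0] <- 1
      ndir <- nrow(unique(round(dirs * flip, 4L)))
    } else ndir <- 0L
    has_anchor <- any(b <= max(b) / 3)
    if (ndir < 6L || !has_anchor)
      stop("insufficient data for tensor fit: fewer than 6 distinct diffusion directions or no low-b anchor volume remains")
  } else {
    stop("insufficient data for tensor fit: no volumes remain")
  }
  out
}

#' Run the full slicewise quality control
#'
#' Splits the acquisition into b-shells, computes the weighted slicewise
#' deviation matrix and flags per shell, unions the flags, and assembles
#' the review statistics (worst slice per volume, voxelwise outlier counts
#' on the high shell).  Deterministic for fixed input.
#'
#' @param dataset a [dwi_dataset()].
#' @param config a [qc_config()].
#' @param mask optional 3-D logical foreground mask for the slice means.
#' @return An object of class `qc_report` with elements `flagged_volumes`,
#'   `deviation` (named list per shell), `worst_slice` (data.frame with one
#'   row per volume: volume_index, shell, worst_slice, delta_I, flagged),
#'   `outlier_counts`, `config`, `n_volumes`, `n_slices`.
#' @export
run_qc <- function(dataset, config = qc_config(), mask = NULL) {
  stopifnot(inherits(dataset, "dwi_dataset"), inherits(config, "qc_config"))
  shells <- split_by_shell(dataset, config$b_split)
  labels <- c(low = "low", high = "high")
  deviation <- list()
  flagged <- integer()
  rows <- list()
  for (s in names(shells)) {
    shl <- shells[[s]]
    if (n_volumes(shl) == 0L) next
    if (n_volumes(shl) < 2L) {
      rows[[s]] <- data.frame(volume_index = shl$volume_indices,
                              shell = labels[[s]], worst_slice = NA_integer_,
                              delta_I = NA_real_, flagged = FALSE)
      next
    }
    cfg <- config
    if (is.null(cfg$background_floor))
      cfg$background_floor <-
        0.05 * quantile(shl$intensities, 0.99, na.rm = TRUE, names = FALSE)
    sm <- slice_means(shl, mask)
    dev <- deviation_matrix(sm, shl$gradients, cfg, shell_label = labels[[s]])
    deviation[[s]] <- dev
    fl <- flag_volumes(dev, cfg)
    flagged <- union(flagged, fl)
    worst <- apply(dev$delta, 1L, function(r)
      if (all(is.na(r))) NA_integer_ else which.max(r))
    wval <- vapply(seq_len(nrow(dev$delta)), function(j)
      if (is.na(worst[j])) NA_real_ else dev$delta[j, worst[j]], numeric(1))
    rows[[s]] <- data.frame(volume_index = dev$volume_indices,
                            shell = labels[[s]],
                            worst_slice = as.integer(worst),
                            delta_I = wval,
                            flagged = dev$volume_indices %in% fl)
  }
  worst_slice <- do.call(rbind, rows)
  worst_slice <- worst_slice[order(worst_slice$volume_index), , drop = FALSE]
  rownames(worst_slice) <- NULL

  outlier_counts <- NULL
  if (n_volumes(shells$high) >= 3L)
    outlier_counts <- voxel_outlier_counts(shells$high,
                                           antipodal = config$antipodal_weights)

  structure(list(flagged_volumes = sort(flagged), deviation = deviation,
                 worst_slice = worst_slice, outlier_counts = outlier_counts,
                 config = config, n_volumes = n_volumes(dataset),
                 n_slices = n_slices(dataset)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d volumes, %d slices; %d volume(s) flagged at threshold %.3g\n",
              x$n_volumes, x$n_slices, length(x$flagged_volumes), x$config$threshold))
  if (length(x$flagged_volumes))
    cat("  flagged volumes:", paste(x$flagged_volumes, collapse = ", "), "\n")
  invisible(x)
}
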