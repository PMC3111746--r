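#' Diffusion gradient table
#'
#' Bundles one diffusion-encoding direction and b-value per acquired volume.
#' Directions of diffusion-weighted volumes (b > 0) must be unit vectors
#' (tolerance 1e-3); volumes without diffusion weighting (b = 0) carry the
#' zero vector.  Directions are kept in the frame they are supplied in: the
#' slicewise QC statistic depends only on relative angles, which any rigid
#' reorientation preserves.
#'
#' @param directions numeric matrix with one row per volume and 3 columns,
#'   or a length-3 vector for a single volume.
#' @param bvalues numeric vector of b-values in s/mm^2, one per volume.
#' @param renormalize if `TRUE`, directions of b > 0 volumes that are not
#'   unit norm are rescaled to unit length with a warning instead of
#'   raising an error.
#' @return An object of class `gradient_table` with elements `directions`
#'   (V x 3 matrix) and `bvalues` (length-V vector).
#' @examples
#' gt <- gradient_table(rbind(c(1, 0, 0), c(0, 0, 0)), c(1000, 0))
#' length(gt)
#' @export
gradient_table <- function(directions, bvalues, renormalize = FALSE,
                           allow_empty = FALSE) {
  if (is.null(dim(directions))) directions <- matrix(directions, ncol = 3L)
  directions <- as.matrix(directions)
  storage.mode(directions) <- "double"
  bvalues <- as.numeric(bvalues)
  if (ncol(directions) != 3L && nrow(directions) > 0L)
    stop("directions must have 3 columns (one unit vector per volume)")
  if (nrow(directions) != length(bvalues))
    stop(sprintf("gradient table mismatch: %d directions but %d b-values",
                 nrow(directions), length(bvalues)))
  if (length(bvalues) < 1L && !allow_empty)
    stop("gradient table must describe at least one volume")
  if (any(!is.finite(bvalues)) || any(bvalues < 0))
    stop("all b-values must be finite and >= 0")
  if (any(!is.finite(directions))) stop("all directions must be finite")

  nrm <- sqrt(rowSums(directions^2))
  dw <- bvalues > 0
  bad <- dw & abs(nrm - 1) > 1e-3
  if (any(bad)) {
    if (!renormalize)
      stop(sprintf("%d diffusion-weighted direction(s) are not unit norm", sum(bad)))
    warning(sprintf("renormalizing %d non-unit gradient direction(s) to unit length",
                    sum(bad)))
    directions[bad, ] <- directions[bad, , drop = FALSE] / nrm[bad]
  }
  # snap near-unit directions exactly; b = 0 volumes carry the zero vector
  ok <- dw & !bad & nrm > 0
  directions[ok, ] <- directions[ok, , drop = FALSE] / nrm[ok]
  directions[!dw, ] <- 0

  structure(list(directions = directions, bvalues = bvalues),
            class = "gradient_table")
}

#' @export
length.gradient_table <- function(x) length(x$bvalues)

#' @export
print.gradient_table <- function(x, ...) {
  shells <- table(round(x$bvalues))
  cat("<gradient_table> ", length(x), " volumes; b-values: ",
      paste(sprintf("%s x b=%s", shells, names(shells)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

subset_gradients <- function(gt, keep) {
  gradient_table(gt$directions[keep, , drop = FALSE], gt$bvalues[keep],
                 allow_empty = TRUE)
}

#' Diffusion-weighted MRI dataset
#'
#' A 4-D intensity array indexed (x, y, slice, volume) together with its
#' voxel geometry and gradient table.  Axial slices are the third array
#' axis; datasets acquired with a different slice axis must be permuted by
#' the caller before use.
#'
#' @param intensities 4-D numeric array, non-negative, indexed
#'   (x, y, z, volume).
#' @param voxel_size length-3 numeric vector of voxel edge lengths in mm.
#' @param gradients a [gradient_table()] whose length equals the fourth
#'   array extent.
#' @param volume_indices integer vector of original volume indices, used to
#'   track provenance across shell splitting and QC removal.  Defaults to
#'   `1:V`.
#' @return An object of class `dwi_dataset`.
#' @export
dwi_dataset <- function(intensities, voxel_size, gradients,
                        volume_indices = NULL) {
  if (length(dim(intensities)) != 4L)
    stop("intensities must be a 4-D array (x, y, slice, volume)")
  if (!inherits(gradients, "gradient_table"))
    stop("gradients must be a gradient_table")
  nv <- dim(intensities)[4L]
  if (nv != length(gradients))
    stop(sprintf("volume-count mismatch: image has %d volumes but gradient table has %d",
                 nv, length(gradients)))
  if (nv > 0L && (any(!is.finite(intensities)) || any(intensities < 0)))
    stop("all intensities must be finite and >= 0")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive lengths in mm")
  if (is.null(volume_indices)) volume_indices <- seq_len(nv)
  volume_indices <- as.integer(volume_indices)
  if (length(volume_indices) != nv)
    stop("volume_indices must have one entry per volume")
  structure(list(intensities = intensities, voxel_size = voxel_size,
                 gradients = gradients, volume_indices = volume_indices),
            class = "dwi_dataset")
}

#' @export
print.dwi_dataset <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<dwi_dataset> %d x %d x %d voxels (%.3g x %.3g x %.3g mm), %d volumes\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3], d[4]))
  print(x$gradients)
  invisible(x)
}

#' @export
dim.dwi_dataset <- function(x) dim(x$intensities)

n_volumes <- function(dataset) dim(dataset$intensities)[4L]
n_slices <- function(dataset) dim(dataset$intensities)[3L]

read_bval <- function(path) {
  b <- scan(path, what = numeric(), quiet = TRUE)
  if (any(!is.finite(b)) || any(b < 0))
    stop(sprintf("invalid b-values in '%s': must be finite and >= 0", path))
  b
}

read_bvec <- function(path, n_volumes) {
  m <- as.matrix(read.table(path, header = FALSE))
  storage.mode(m) <- "double"
  if (nrow(m) == 3L && ncol(m) == n_volumes) {
    t(m)                                   # canonical FSL layout: 3 rows x V columns
  } else if (ncol(m) == 3L && nrow(m) == n_volumes && n_volumes != 3L) {
    warning(sprintf("'%s' appears to be transposed (%d rows x 3 columns); accepting V x 3 layout",
                    path, nrow(m)))
    m
  } else {
    stop(sprintf("bvec file '%s' has shape %d x %d; expected 3 x %d (FSL layout)",
                 path, nrow(m), ncol(m), n_volumes))
  }
}

#' Read a diffusion-weighted dataset from NIfTI + bval/bvec files
#'
#' Reads a 4-D NIfTI-1 image together with FSL-style `bval` (one row of V
#' b-values) and `bvec` (3 rows of V direction components) text files.  A
#' transposed V x 3 `bvec` layout is auto-detected by shape and accepted
#' with a warning.  Non-unit directions of diffusion-weighted volumes are
#' renormalized with a warning.
#'
#' @param image_path path to a 4-D NIfTI-1 file.
#' @param bval_path path to the b-value text file.
#' @param bvec_path path to the gradient-direction text file.
#' @return A [dwi_dataset()].
#' @export
read_dwi <- function(image_path, bval_path, bvec_path) {
  img <- RNifti::readNifti(image_path)
  d <- dim(img)
  if (length(d) != 4L)
    stop(sprintf("'%s' is %d-D; a 4-D diffusion series is required", image_path, length(d)))
  bval <- read_bval(bval_path)
  if (length(bval) != d[4L])
    stop(sprintf("volume-count mismatch: image '%s' has %d volumes but bval file has %d entries",
                 image_path, d[4L], length(bval)))
  bvec <- read_bvec(bvec_path, d[4L])
  gt <- gradient_table(bvec, bval, renormalize = TRUE)
  vs <- RNifti::pixdim(img)[1:3]
  arr <- array(as.numeric(img), dim = d)
  arr[arr < 0] <- 0                       # guard against signed storage round-off
  dwi_dataset(arr, vs, gt)
}

#' Write a diffusion-weighted dataset to NIfTI + bval/bvec files
#'
#' Writes the dataset in the same dialect [read_dwi()] accepts, so that
#' reading the files back reproduces the dataset to within storage
#' precision.  All three parent directories must exist; nothing is written
#' otherwise.
#'
#' @param dataset a [dwi_dataset()].
#' @param image_path output NIfTI path (`.nii` or `.nii.gz`).
#' @param bval_path output b-value text path.
#' @param bvec_path output direction text path (3 x V).
#' @return Invisibly, `NULL`.
#' @export
write_dwi <- function(dataset, image_path, bval_path, bvec_path) {
  stopifnot(inherits(dataset, "dwi_dataset"))
  for (p in c(image_path, bval_path, bvec_path)) {
    dir <- dirname(p)
    if (!dir.exists(dir))
      stop(sprintf("output directory '%s' does not exist", dir))
  }
  img <- RNifti::asNifti(dataset$intensities)
  RNifti::pixdim(img) <- c(dataset$voxel_size, 1)
  write_atomic(image_path, function(tmp) RNifti::writeNifti(img, tmp, datatype = "double"))
  write_atomic(bval_path, function(tmp)
    writeLines(paste(format(dataset$gradients$bvalues, trim = TRUE), collapse = " "), tmp))
  write_atomic(bvec_path, function(tmp)
    write.table(t(dataset$gradients$directions), tmp, row.names = FALSE,
                col.names = FALSE))
  invisible(NULL)
}

#' Split a dataset into low- and high-b shells
#'
#' Partitions the volumes at `b_split`: volumes with b <= `b_split` form the
#' low shell, the rest the high shell.  Volume order is preserved within
#' each partition and original volume indices are retained, so QC flags
#' raised per shell can be mapped back to the full acquisition.
#'
#' @param dataset a [dwi_dataset()].
#' @param b_split shell boundary in s/mm^2 (default 500, separating
#'   b = 100 anchor volumes from b = 1000 diffusion-weighted volumes).
#' @return A list with elements `low` and `high`, each a [dwi_dataset()]
#'   (possibly with zero volumes).
#' @export
split_by_shell <- function(dataset, b_split = 500) {
  stopifnot(inherits(dataset, "dwi_dataset"), is.finite(b_split))
  low <- dataset$gradients$bvalues <= b_split
  take <- function(keep) {
    dwi_dataset(dataset$intensities[, , , keep, drop = FALSE],
                dataset$voxel_size,
                subset_gradients(dataset$gradients, keep),
                dataset$volume_indices[keep])
  }
  list(low = take(low), high = take(!low))
}

# temp-then-rename so a failure never leaves a partial output file; the
# temp name keeps the full basename suffix so extension-sensitive writers
# (NIfTI) pick the right format
write_atomic <- function(path, writer) {
  tmp <- file.path(dirname(path),
                   paste0(".tmp", Sys.getpid(), "-", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop(sprintf("could not write '%s'", path))
  invisible(path)
}
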