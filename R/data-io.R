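#' Masked voxel-by-time dataset
#'
#' Container for one subject-run: an `n_voxels x n_timepoints` matrix of
#' in-mask voxel timecourses, the mask voxel coordinates, and the TR.
#'
#' @param data Numeric matrix, voxels in rows, timepoints in columns.
#' @param mask_coords Optional integer matrix of (x, y, z) grid coordinates,
#'   one row per voxel, in the same row order as `data`.
#' @param mask_dim Optional 3D grid dimensions.
#' @param tr Repetition time in seconds.
#' @param subject_id,run_id Identifiers.
#' @return An object of class `masked_dataset`.
#' @export
masked_dataset <- function(data, mask_coords = NULL, mask_dim = NULL,
                           tr = 0.72, subject_id = "sub1", run_id = "run1") {
  data <- as.matrix(data)
  if (is.null(mask_coords)) {
    mask_coords <- cbind(seq_len(nrow(data)), 1L, 1L)
    mask_dim <- c(nrow(data), 1L, 1L)
  }
  stopifnot(nrow(mask_coords) == nrow(data), tr > 0)
  structure(list(data = data, mask_coords = mask_coords,
                 mask_dim = mask_dim, tr = tr,
                 subject_id = subject_id, run_id = run_id),
            class = "masked_dataset")
}

#' @export
print.masked_dataset <- function(x, ...) {
  cat(sprintf("masked_dataset %s/%s: %d voxels x %d timepoints, TR %.3fs\n",
              x$subject_id, x$run_id, nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

#' Load a masked dataset from NIfTI files
#'
#' Reads a 4D NIfTI image and a 3D binary mask on the same grid. Rows of the
#' returned matrix are ordered by the column-major linear index of the mask
#' voxels (x fastest, then y, then z — the order returned by
#' `which(mask > 0)`); this ordering is fixed and documented so that bases
#' and maps are reproducible across runs. The TR is read from the fourth
#' pixdim entry of the image header.
#'
#' @param nifti_path Path to the 4D image.
#' @param mask_path Path to the 3D mask.
#' @param subject_id,run_id Identifiers.
#' @return A [masked_dataset()].
#' @export
load_masked <- function(nifti_path, mask_path, subject_id = "sub1",
                        run_id = "run1") {
  img <- RNifti::readNifti(nifti_path)
  msk <- RNifti::readNifti(mask_path)
  di <- dim(img); dm <- dim(msk)
  if (length(di) != 4) stop("expected a 4D image, got ", length(di), "D")
  if (!all(di[1:3] == dm[1:3]))
    stop("grid mismatch between image ", paste(di[1:3], collapse = "x"),
         " and mask ", paste(dm[1:3], collapse = "x"))
  keep <- which(msk > 0)
  if (length(keep) == 0) stop("empty mask")
  nvox <- prod(di[1:3])
  mat <- matrix(as.numeric(img), nvox, di[4])[keep, , drop = FALSE]
  coords <- arrayInd(keep, dm[1:3])
  tr <- RNifti::pixdim(img)[4]
  if (!is.finite(tr) || tr <= 0) tr <- 1
  masked_dataset(mat, mask_coords = coords, mask_dim = dm[1:3], tr = tr,
                 subject_id = subject_id, run_id = run_id)
}

#' Write a masked dataset back to NIfTI
#'
#' Inverse of [load_masked()]: scatters the matrix rows into the 3D grid and
#' writes a 4D image plus the binary mask.
#'
#' @param ds A [masked_dataset()] with grid geometry.
#' @param nifti_path,mask_path Output paths.
#' @return `nifti_path`, invisibly.
#' @export
write_masked <- function(ds, nifti_path, mask_path = NULL) {
  if (is.null(ds$mask_dim)) stop("dataset carries no grid geometry")
  dm <- ds$mask_dim
  arr <- array(0, c(dm, ncol(ds$data)))
  lin <- ds$mask_coords[, 1] + dm[1] * (ds$mask_coords[, 2] - 1) +
    dm[1] * dm[2] * (ds$mask_coords[, 3] - 1)
  for (t in seq_len(ncol(ds$data)))
    arr[lin + (t - 1) * prod(dm)] <- ds$data[, t]
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, c(1, 1, 1, ds$tr))
  RNifti::writeNifti(img, nifti_path)
  if (!is.null(mask_path)) {
    m <- array(0L, dm)
    m[lin] <- 1L
    RNifti::writeNifti(RNifti::asNifti(m), mask_path)
  }
  invisible(nifti_path)
}

#' Demean and variance-normalise voxel timecourses
#'
#' Removes each voxel's timecourse mean and scales it to unit variance, the
#' model's standard preprocessing. Rows whose variance falls below
#' `var_floor` are set to zero and reported in the `flagged_voxels`
#' attribute. Optionally applies Gaussian smoothing on the 3D grid first
#' (useful to raise subject-level SNR).
#'
#' @param ds A [masked_dataset()].
#' @param smooth_fwhm Full-width-half-maximum of the Gaussian smoothing in
#'   voxel units, or `NULL` for none.
#' @param var_floor Variance below which a voxel is considered empty.
#' @return The preprocessed [masked_dataset()]; idempotent.
#' @export
preprocess <- function(ds, smooth_fwhm = NULL, var_floor = 1e-8) {
  x <- ds$data
  if (!is.null(smooth_fwhm) && smooth_fwhm > 0)
    x <- smooth_grid(x, ds$mask_coords, ds$mask_dim, smooth_fwhm)
  x <- x - rowMeans(x)
  v <- rowSums(x^2) / (ncol(x) - 1)
  flagged <- which(v < var_floor)
  scl <- ifelse(v < var_floor, 0, 1 / sqrt(pmax(v, var_floor)))
  if (length(flagged) == nrow(x))
    stop("degenerate input: all voxel timecourses are constant")
  out <- ds
  out$data <- x * scl
  attr(out$data, "flagged_voxels") <- flagged
  out
}

# Separable Gaussian smoothing of in-mask data scattered onto the 3D grid.
smooth_grid <- function(x, coords, dm, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  lin <- coords[, 1] + dm[1] * (coords[, 2] - 1) +
    dm[1] * dm[2] * (coords[, 3] - 1)
  out <- x
  vol <- array(0, dm)
  for (t in seq_len(ncol(x))) {
    vol[] <- 0
    vol[lin] <- x[, t]
    for (axis in 1:3) {
      if (dm[axis] > 1) vol <- conv_axis(vol, k, axis)
    }
    out[, t] <- vol[lin]
  }
  out
}

conv_axis <- function(vol, k, axis) {
  half <- (length(k) - 1) / 2
  res <- array(0, dim(vol))
  for (j in seq_along(k)) {
    off <- j - half - 1
    src <- shift_axis(vol, -off, axis)
    res <- res + k[j] * src
  }
  res
}

shift_axis <- function(vol, off, axis) {
  if (off == 0) return(vol)
  d <- dim(vol)
  out <- array(0, d)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  n <- d[axis]
  if (off > 0) {
    idx_dst[[axis]] <- (off + 1):n
    idx_src[[axis]] <- 1:(n - off)
  } else {
    idx_dst[[axis]] <- 1:(n + off)
    idx_src[[axis]] <- (1 - off):n
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    vol[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}
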