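#' Incremental group principal component analysis (MIGP)
#'
#' Streaming spatial PCA over a cohort: subjects are visited one at a time,
#' each subject's (preprocessed) data matrix is concatenated in the time
#' dimension with the running reduced matrix, and the top `n_components`
#' left singular directions are retained. Memory never exceeds one subject
#' plus the running `n_voxels x n_components` matrix, regardless of cohort
#' size, which is what makes bases for very large populations feasible.
#'
#' @param datasets A list whose elements are [masked_dataset()] objects,
#'   file paths to RDS-serialised ones, or zero-argument functions returning
#'   one (lazy loading keeps the memory contract).
#' @param n_components Number of basis columns to retain (conventionally
#'   twice the target mode count).
#' @param seed Integer seed controlling the subject visiting order
#'   (`NULL` keeps the given order).
#' @return An object of class `spatial_basis`: list with `basis`
#'   (`n_voxels x n_components`, orthonormal columns), `singular_values`,
#'   and `n_visited`.
#' @export
migp <- function(datasets, n_components, seed = NULL) {
  stopifnot(length(datasets) >= 1)
  order_idx <- seq_along(datasets)
  if (!is.null(seed)) order_idx <- with_seed(seed, sample(order_idx))
  running <- NULL
  nv <- NULL
  for (i in order_idx) {
    ds <- fetch_dataset(datasets[[i]])
    if (is.null(nv)) {
      nv <- nrow(ds$data)
      if (n_components > nv) stop("n_components exceeds the voxel count")
    } else if (nrow(ds$data) != nv) {
      stop("all datasets must share the same mask")
    }
    stacked <- cbind(running, ds$data)
    # eigen-decompose the small Gram matrix instead of the voxel covariance
    g <- crossprod(stacked)
    eg <- eigen(g, symmetric = TRUE)
    d <- sqrt(pmax(eg$values, 0))
    keep <- min(n_components, sum(d > d[1] * 1e-7))
    d <- d[seq_len(keep)]
    u <- stacked %*% eg$vectors[, seq_len(keep), drop = FALSE] %*%
      diag(1 / d, keep)
    running <- u %*% diag(d, keep)
    rm(ds, stacked, g, eg)
  }
  d <- sqrt(colSums(running^2))
  basis <- sweep(running, 2, pmax(d, 1e-12), "/")
  structure(list(basis = basis, singular_values = d,
                 n_visited = length(datasets)),
            class = "spatial_basis")
}

fetch_dataset <- function(x) {
  if (inherits(x, "masked_dataset")) return(x)
  if (is.function(x)) return(x())
  if (is.character(x)) return(readRDS(x))
  stop("cannot interpret dataset entry of class ", class(x)[1])
}

#' @export
print.spatial_basis <- function(x, ...) {
  cat(sprintf("spatial_basis: %d voxels x %d components (from %d datasets)\n",
              nrow(x$basis), ncol(x$basis), x$n_visited))
  invisible(x)
}
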