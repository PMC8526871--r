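#' Spatial ICA on a group spatial basis
#'
#' Deterministic fixed-point ICA (symmetric decorrelation, tanh contrast)
#' applied to the MIGP basis, extracting `n_modes` maximally non-Gaussian
#' spatial sources. Used both to initialise the hierarchical model and as
#' the group stage of the ICA-dual-regression baseline — both share this
#' code path and the same PCA input, so method comparisons are not
#' confounded by initialisation.
#'
#' Conventions: each map has unit variance and nonnegative skewness, and
#' columns are ordered by descending explained variance in the basis.
#'
#' @param basis A `spatial_basis` from [migp()].
#' @param n_modes Number of modes to extract (at most the number of basis
#'   components).
#' @param seed Integer seed for the random orthogonal starting rotation;
#'   two runs with the same seed are bit-identical.
#' @param max_iter,tol Fixed-point iteration controls.
#' @return An object of class `initial_maps`: list with `maps`
#'   (`n_voxels x n_modes`), `mixing` (`n_components x n_modes`), `seed`,
#'   and the convergence trace.
#' @export
spatial_ica_init <- function(basis, n_modes, seed = 1L, max_iter = 500,
                             tol = 1e-7) {
  stopifnot(inherits(basis, "spatial_basis"))
  nc <- ncol(basis$basis)
  if (n_modes > nc) stop("n_modes exceeds the number of basis components")
  nv <- nrow(basis$basis)

  # observations: singular-value-weighted basis, rows = components
  x <- t(basis$basis * rep(basis$singular_values, each = nv))
  x <- x - rowMeans(x)
  # whiten onto the top n_modes principal directions
  cv <- tcrossprod(x) / nv
  eg <- eigen(cv, symmetric = TRUE)
  keep <- seq_len(n_modes)
  wh <- diag(1 / sqrt(pmax(eg$values[keep], 1e-12)), n_modes) %*%
    t(eg$vectors[, keep, drop = FALSE])
  z <- wh %*% x

  w <- with_seed(seed, {
    q <- qr.Q(qr(matrix(stats::rnorm(n_modes^2), n_modes)))
    q
  })
  sym_decorrelate <- function(w) {
    s <- w %*% t(w)
    e <- eigen(s, symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), nrow(w)) %*%
      t(e$vectors) %*% w
  }
  w <- sym_decorrelate(w)
  trace <- numeric(0)
  converged <- FALSE
  # plain fixed-point phase; if it oscillates, a damped rescue phase
  # follows (identical results whenever the plain iteration converges)
  for (phase in 1:2) {
    damp <- if (phase == 1) 1 else 0.25
    for (it in seq_len(max_iter)) {
      wx <- w %*% z
      gwx <- tanh(wx)
      g1 <- rowMeans(1 - gwx^2)
      w_new <- sym_decorrelate(gwx %*% t(z) / nv - g1 * w)
      delta <- max(abs(abs(diag(w_new %*% t(w))) - 1))
      trace <- c(trace, delta)
      w <- if (damp < 1) sym_decorrelate(damp * w_new + (1 - damp) * w) else
        w_new
      if (delta < tol) { converged <- TRUE; break }
    }
    if (converged) break
  }
  it <- length(trace)
  if (!converged) {
    last <- trace[length(trace)]
    if (last < 0.15) {
      # component directions are stable to within a few percent: good
      # enough for an initialiser whose job is a realistic ballpark;
      # accept with a warning rather than abort a long pipeline
      warning(sprintf("spatial ICA stopped at delta %.3g after %d iterations",
                      last, max_iter))
    } else {
      e <- simpleError(sprintf(
        "spatial ICA did not converge after %d iterations (last delta %.3g)",
        max_iter, last))
      # nb: not named "trace" -- that condition field is reserved for
      # backtraces by condition formatters
      e$iteration_trace <- trace
      stop(e)
    }
  }

  s <- w %*% z                      # n_modes x n_voxels sources
  maps <- t(s)
  # unit variance per map, nonnegative skewness sign convention
  maps <- sweep(maps, 2, pmax(apply(maps, 2, stats::sd), 1e-12), "/")
  sk <- apply(maps, 2, function(v) mean((v - mean(v))^3))
  maps <- sweep(maps, 2, ifelse(sk < 0, -1, 1), "*")
  # mixing back in basis space and explained-variance ordering
  mixing <- t(x %*% maps) / nv      # n_modes x n_components weights
  ev <- rowSums(mixing^2)
  ord <- order(ev, decreasing = TRUE)
  structure(list(maps = maps[, ord, drop = FALSE],
                 mixing = t(mixing[ord, , drop = FALSE]),
                 explained_variance = ev[ord],
                 seed = seed, iterations = it,
                 iteration_trace = trace),
            class = "initial_maps")
}

#' Group spatial ICA maps for the baseline pipeline
#'
#' Same estimator and conventions as [spatial_ica_init()] (shared code
#' path); returned as a plain map matrix for use with [dual_regression()].
#'
#' @inheritParams spatial_ica_init
#' @return `n_voxels x n_modes` matrix of group IC maps.
#' @export
group_spatial_ica <- function(basis, n_modes, seed = 1L, ...) {
  spatial_ica_init(basis, n_modes, seed = seed, ...)$maps
}

#' @export
print.initial_maps <- function(x, ...) {
  cat(sprintf("initial_maps: %d voxels x %d modes (ICA, %d iterations)\n",
              nrow(x$maps), ncol(x$maps), x$iterations))
  invisible(x)
}
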