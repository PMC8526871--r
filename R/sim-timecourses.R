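#' Canonical haemodynamic response basis
#'
#' Double-gamma canonical HRF with its temporal and dispersion derivatives,
#' sampled at the acquisition TR. Used both by the simulator (random
#' nonnegative-dominant mixtures mimic haemodynamic variability across
#' subject-runs) and by the model's HRF-informed temporal prior.
#'
#' @param tr Repetition time in seconds.
#' @param duration Kernel length in seconds.
#' @return A matrix with columns `canonical`, `temporal_deriv`,
#'   `dispersion_deriv`.
#' @export
hrf_basis <- function(tr, duration = 24) {
  t <- seq(0, duration, by = tr)
  dg <- function(t, a1 = 6, a2 = 16, b = 1, c = 1 / 6) {
    stats::dgamma(t, shape = a1, rate = b) -
      c * stats::dgamma(t, shape = a2, rate = b)
  }
  h <- dg(t)
  dt <- 0.1
  h_t <- (dg(t + dt) - h) / dt
  disp <- 1.01
  h_d <- (dg(t * disp) * disp - h) / (disp - 1)
  b <- cbind(canonical = h, temporal_deriv = h_t, dispersion_deriv = h_d)
  sweep(b, 2, pmax(sqrt(colSums(b^2)), 1e-12), "/")
}

# Random HRF kernel: canonical plus small derivative admixture.
random_hrf_kernel <- function(tr) {
  b <- hrf_basis(tr)
  w <- c(1, stats::rnorm(2, 0, 0.2))
  k <- as.numeric(b %*% w)
  k / sum(abs(k))
}

# Frequency-domain low-pass weighting amplifying frequencies below f_cut.
# Soft rolloff keeps some broadband power, as in spontaneous BOLD.
lowpass_weights <- function(n, tr, f_cut = 0.1) {
  k <- 0:(n - 1)
  f <- pmin(k, n - k) / (n * tr)
  0.15 + 0.85 / (1 + (f / f_cut)^6)
}

# Apply the spectral weighting to each row of x (modes x time).
lowpass_filter_rows <- function(x, tr, f_cut = 0.1) {
  n <- ncol(x)
  w <- lowpass_weights(n, tr, f_cut)
  out <- t(apply(x, 1, function(r) {
    Re(stats::fft(stats::fft(r) * w, inverse = TRUE)) / n
  }))
  # preserve overall scale so the cross-mode covariance is unchanged up to
  # a common factor
  out / sqrt(mean(w^2))
}

#' Simulate mode timecourses for every subject and run
#'
#' Subject precision matrices are drawn from a Wishart distribution centred
#' on the group precision (`E[alpha_s] = group_precision`). Neural
#' timecourses are zero-mean Gaussian series with cross-mode covariance
#' `solve(alpha_s)` whose spectrum is low-pass weighted below 0.1 Hz; BOLD
#' timecourses are convolutions with a random haemodynamic kernel, one per
#' subject-run, normalised to unit variance per mode. Timecourses differ
#' between a subject's runs.
#'
#' @param config An [sim_config()] object.
#' @param group_precision Symmetric positive-definite `n_modes x n_modes`
#'   matrix.
#' @return A list with `subject_precisions` and, per subject, per run,
#'   `neural` and `bold` `n_modes x n_timepoints` matrices.
#' @export
make_timecourses <- function(config, group_precision) {
  validate_sim_config(config)
  nm <- config$n_modes
  nt <- config$n_timepoints
  if (config$wishart_dof <= nm - 1)
    stop("invalid prior: wishart_dof must exceed n_modes - 1")
  group_precision <- ensure_spd(group_precision)
  with_seed(child_seed(config$seed, "timecourses"), {
    lapply(seq_len(config$n_subjects), function(s) {
      prec_s <- stats::rWishart(1, config$wishart_dof,
                                group_precision / config$wishart_dof)[, , 1]
      cov_s <- chol2inv(chol(prec_s))
      L <- t(chol(cov_s))
      runs <- lapply(seq_len(config$n_runs), function(r) {
        z <- L %*% matrix(stats::rnorm(nm * nt), nm, nt)
        neural <- lowpass_filter_rows(z, config$tr)
        k <- random_hrf_kernel(config$tr)
        bold <- t(apply(neural, 1, function(x)
          stats::filter(x, k, method = "convolution", sides = 1) |>
            (\(v) { v[is.na(v)] <- 0; v })()))
        bold <- bold / pmax(apply(bold, 1, stats::sd), 1e-12)
        list(neural = neural, bold = bold)
      })
      list(precision = prec_s, runs = runs)
    })
  })
}
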