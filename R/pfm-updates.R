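#' Double-Gaussian mixture update of a subject's spatial maps
#'
#' Conjugate mean-field update of the per-voxel-mode spatial posterior.
#' Regression evidence from all of the subject's runs is combined (the
#' spatial maps are shared across runs): for each mode, holding the other
#' modes at their expectations, the Gaussian posteriors of the signal and
#' noise components are computed in closed form and the membership
#' probability is the normalised marginal likelihood of the two components.
#'
#' @param subject An `spfm_subject`.
#' @param group The current `spfm_group`.
#' @param data List of `n_voxels x n_timepoints` matrices, one per run.
#' @param n_passes Inner mean-field passes over the modes (the regression
#'   evidence is computed once and reused).
#' @param ex Precomputed [group] expectations (internal optimisation).
#' @return The subject with updated `ms`, `vs`, `mn`, `vn`, `q`.
#' @export
dgmm_spatial_update <- function(subject, group, data, n_passes = 1,
                                ex = group_expect(group)) {
  nm <- group$n_modes
  nv <- group$n_voxels
  B <- matrix(0, nv, nm)
  F_ev <- matrix(0, nm, nm)
  for (r in seq_along(data)) {
    run <- subject$runs[[r]]
    am <- amp_moments(run)
    Epsi <- run$psi_a / run$psi_b
    B <- B + Epsi * (data[[r]] %*% t(run$A_mean)) *
      rep(am$Eh, each = nv)
    F_ev <- F_ev + Epsi * (am$Ehh * run$E_AAt)
  }
  prior_quad <- 0.5 * ex$E_taus * (ex$Mg^2 + ex$Vg)
  E_P <- subject$q * subject$ms + (1 - subject$q) * subject$mn
  for (pass in seq_len(n_passes)) {
    for (m in seq_len(nm)) {
      r_v <- B[, m] - E_P[, -m, drop = FALSE] %*% F_ev[-m, m]
      prec_s <- F_ev[m, m] + ex$E_taus[, m]
      ms <- (r_v + ex$E_taus[, m] * ex$Mg[, m]) / prec_s
      prec_n <- F_ev[m, m] + ex$E_taun[, m]
      mn <- r_v / prec_n
      L_s <- ex$Elog_pi[, m] + 0.5 * ex$Elog_taus[, m] -
        prior_quad[, m] - 0.5 * log(prec_s) + 0.5 * ms^2 * prec_s
      L_n <- ex$Elog_1mpi[, m] + 0.5 * ex$Elog_taun[, m] -
        0.5 * log(prec_n) + 0.5 * mn^2 * prec_n
      q <- stats::plogis(L_s - L_n)
      q <- pmin(pmax(q, 1e-8), 1 - 1e-8)
      subject$ms[, m] <- ms
      subject$vs[, m] <- 1 / prec_s
      subject$mn[, m] <- as.numeric(mn)
      subject$vn[, m] <- 1 / prec_n
      subject$q[, m] <- q
      E_P[, m] <- q * ms + (1 - q) * mn
    }
  }
  subject
}

#' HRF-informed temporal prior
#'
#' Eigendecomposition of the effective timepoint covariance
#' `K = w * K_bold + (1 - w) * I`, where `K_bold` is the stationary
#' autocorrelation of HRF-filtered low-frequency spontaneous activity (the
#' canonical HRF kernel applied to < 0.1 Hz-weighted noise): the
#' matrix-normal column prior realising the HRF constraint on the temporal
#' signal component. Matching the prior spectrum to the BOLD signal class
#' keeps the Wishart precision posterior on the correct scale — a purely
#' white prior would misattribute temporal smoothness to tiny mode
#' variances.
#'
#' @param n_timepoints Run length.
#' @param tr Repetition time in seconds.
#' @param hrf_weight Weight of the BOLD autocorrelation vs the white
#'   component, in \[0, 1\].
#' @return List with eigenvectors `Q`, eigenvalues `k` and the covariance
#'   `K`.
#' @export
temporal_prior <- function(n_timepoints, tr, hrf_weight = 0.8) {
  n <- n_timepoints
  kern <- numeric(n)
  b <- hrf_basis(tr)[, 1]
  kern[seq_len(min(length(b), n))] <- b[seq_len(min(length(b), n))]
  S <- (lowpass_weights(n, tr) * Mod(stats::fft(kern)))^2
  ac <- Re(stats::fft(S, inverse = TRUE))
  ac <- ac / ac[1]
  K <- stats::toeplitz(ac)
  K <- hrf_weight * K + (1 - hrf_weight) * diag(n)
  K <- ensure_spd(K, 1e-6)
  eg <- eigen(K, symmetric = TRUE)
  list(Q = eg$vectors, k = pmax(eg$values, 1e-8), K = K,
       hrf_weight = hrf_weight)
}

#' Update a subject-run's timecourse posterior
#'
#' Gaussian posterior over the mode timecourses given the expected maps and
#' amplitudes, with the expected between-mode precision coupling modes and
#' the HRF-informed temporal prior coupling timepoints (a matrix-normal
#' prior `A ~ MN(0, alpha^{-1}, K)`). Solved exactly in the eigenbasis of
#' the temporal prior, one small generalised-ridge system per eigenmode.
#'
#' @param subject An `spfm_subject`.
#' @param run_idx Run index.
#' @param group The current `spfm_group`.
#' @param data_run The run's `n_voxels x n_timepoints` data matrix.
#' @param tp A [temporal_prior()] object for this run length.
#' @param ex Precomputed group expectations (internal optimisation).
#' @return The subject with the run's `A_mean`, `E_AAt`, `E_AKiAt`, `ent_A`
#'   replaced.
#' @export
temporal_update <- function(subject, run_idx, group, data_run, tp,
                            ex = NULL) {
  run <- subject$runs[[run_idx]]
  mm <- subject_map_moments(subject)
  am <- amp_moments(run)
  nm <- group$n_modes
  nt <- ncol(data_run)
  Epsi <- run$psi_a / run$psi_b
  WtW <- am$Ehh * mm$E_PtP
  Ealpha <- run$alpha_nu * run$alpha_V
  Ct <- (am$Eh * t(mm$E_P)) %*% data_run        # E[W]' D
  Ct_t <- Ct %*% tp$Q

  # simultaneous diagonalisation of (Epsi WtW, Ealpha)
  L <- t(chol(ensure_spd(Ealpha)))
  Bm <- forwardsolve(L, t(forwardsolve(L, Epsi * WtW)))
  eg <- eigen((Bm + t(Bm)) / 2, symmetric = TRUE)
  U <- eg$vectors
  sdiag <- pmax(eg$values, 0)
  Linv_t <- backsolve(t(L), diag(nm))
  Tmat <- Linv_t %*% U                           # columns: joint eigvecs
  Z <- t(Tmat) %*% (Epsi * Ct_t)                 # nm x nt
  denom <- outer(sdiag, 1 / tp$k, function(s, ik) s + ik)
  A_t <- Tmat %*% (Z / denom)                    # posterior means, eigenbasis
  cov_scale <- rowSums(1 / denom)
  covK_scale <- rowSums(t(t(1 / denom) / tp$k))
  Sigma_sum <- Tmat %*% (cov_scale * t(Tmat))
  SigmaK_sum <- Tmat %*% (covK_scale * t(Tmat))
  E_AAt <- tcrossprod(A_t) + Sigma_sum
  E_AKiAt <- tcrossprod(A_t %*% diag(1 / sqrt(tp$k), nt)) + SigmaK_sum
  logdet_Ealpha <- 2 * sum(log(diag(L)))
  logdet_Sig <- -(nt * logdet_Ealpha +
                    sum(log(outer(sdiag, 1 / tp$k, `+`))))
  run$A_mean <- A_t %*% t(tp$Q)
  run$E_AAt <- (E_AAt + t(E_AAt)) / 2
  run$E_AKiAt <- (E_AKiAt + t(E_AKiAt)) / 2
  run$ent_A <- 0.5 * nm * nt * log(2 * pi * exp(1)) + 0.5 * logdet_Sig
  subject$runs[[run_idx]] <- run
  subject
}

#' Wishart update of a subject-run's between-mode precision
#'
#' Conjugate update combining the hierarchical group Wishart prior with the
#' expected scatter of the run's timecourses (including their posterior
#' covariance): the posterior degrees of freedom are the prior dof plus the
#' number of timepoints.
#'
#' @param subject An `spfm_subject`.
#' @param run_idx Run index.
#' @param group The current `spfm_group`.
#' @param n_timepoints Timepoints contributing to the run.
#' @param ex Precomputed group expectations (internal optimisation).
#' @return The subject with the run's Wishart posterior replaced.
#' @export
precision_update <- function(subject, run_idx, group, n_timepoints,
                             ex = group_expect(group)) {
  run <- subject$runs[[run_idx]]
  run$alpha_nu <- group$hyper$nu0 + n_timepoints
  run$alpha_V <- chol2inv(chol(ensure_spd(ex$E_Rg + run$E_AKiAt)))
  subject$runs[[run_idx]] <- run
  subject
}

#' Update a subject-run's positive mode amplitudes
#'
#' The amplitudes are log-normal: `h = exp(g)` with a Gaussian posterior on
#' `g`, regularised by the hierarchical group amplitude model. The
#' fixed-form Gaussian `q(g)` is optimised against its closed-form local
#' free-energy contribution (the expected quadratic data term has closed
#' form under log-normal moments); a final safeguard keeps the previous
#' posterior if the optimiser failed to improve, so the total free energy
#' cannot decrease.
#'
#' @param subject An `spfm_subject`.
#' @param run_idx Run index.
#' @param group The current `spfm_group`.
#' @param data_run The run's data matrix.
#' @param ex Precomputed group expectations (internal optimisation).
#' @param mm Precomputed subject map moments (internal optimisation).
#' @return The subject with the run's `g_mean`, `g_var` replaced.
#' @export
amplitude_update <- function(subject, run_idx, group, data_run,
                             ex = group_expect(group),
                             mm = subject_map_moments(subject)) {
  run <- subject$runs[[run_idx]]
  nm <- group$n_modes
  Epsi <- run$psi_a / run$psi_b
  M <- Epsi * (mm$E_PtP * run$E_AAt)
  cvec <- Epsi * rowSums((t(mm$E_P) %*% data_run) * run$A_mean)
  Md <- diag(M); Moff <- M; diag(Moff) <- 0

  elbo <- function(par) {
    mu <- par[1:nm]; v <- exp(par[nm + 1:nm])
    Eh <- exp(mu + v / 2); Eh2 <- exp(2 * mu + 2 * v)
    sum(cvec * Eh) - 0.5 * (Eh %*% Moff %*% Eh) - 0.5 * sum(Md * Eh2) -
      0.5 * sum(ex$E_taua * ((mu - ex$Ma)^2 + v + ex$Va)) +
      0.5 * sum(log(v))
  }
  grad <- function(par) {
    mu <- par[1:nm]; v <- exp(par[nm + 1:nm])
    Eh <- exp(mu + v / 2); Eh2 <- exp(2 * mu + 2 * v)
    off <- as.numeric(Moff %*% Eh)
    dmu <- cvec * Eh - off * Eh - Md * Eh2 - ex$E_taua * (mu - ex$Ma)
    dv <- 0.5 * cvec * Eh - 0.5 * off * Eh - Md * Eh2 -
      0.5 * ex$E_taua + 0.5 / v
    c(dmu, dv * v)
  }
  par0 <- c(run$g_mean, log(run$g_var))
  opt <- tryCatch(
    stats::optim(par0, fn = function(p) -elbo(p),
                 gr = function(p) -grad(p),
                 method = "BFGS", control = list(maxit = 60)),
    error = function(e) NULL)
  if (!is.null(opt) && is.finite(opt$value) && -opt$value >= elbo(par0)) {
    run$g_mean <- opt$par[1:nm]
    run$g_var <- pmin(exp(opt$par[nm + 1:nm]), 25)
  }
  subject$runs[[run_idx]] <- run
  subject
}

#' Gamma update of a subject-run's residual precision
#'
#' Conjugate Gamma posterior from the expected squared residuals of the
#' reconstruction (all posterior second moments included). In the
#' flat-prior limit the posterior mean precision is the reciprocal
#' mean-squared residual.
#'
#' @param subject An `spfm_subject`.
#' @param run_idx Run index.
#' @param group The current `spfm_group`.
#' @param data_run The run's data matrix.
#' @return The subject with the run's Gamma posterior replaced.
#' @export
noise_update <- function(subject, run_idx, group, data_run) {
  run <- subject$runs[[run_idx]]
  rss <- expected_rss(subject, run, data_run)
  run$psi_a <- group$hyper$psi_a0 + length(data_run) / 2
  run$psi_b <- group$hyper$psi_b0 + 0.5 * max(rss, 1e-12)
  subject$runs[[run_idx]] <- run
  subject
}

# E || D - P diag(h) A ||^2 under the full posterior.
expected_rss <- function(subject, run, data_run) {
  mm <- subject_map_moments(subject)
  am <- amp_moments(run)
  cvec <- rowSums((t(mm$E_P) %*% data_run) * run$A_mean)
  sum(data_run^2) - 2 * sum(am$Eh * cvec) +
    sum((am$Ehh * mm$E_PtP) * run$E_AAt)
}

#' One full sweep of a subject's local factors
#'
#' Updates, in order: timecourses, amplitudes, residual noise (per run),
#' then the shared spatial maps (several inner passes of the per-mode
#' mean-field, which needs a few alternations to residualise overlapping
#' modes), and finally the between-mode precisions, whose conjugate update
#' then sees timecourse scales already adapted to the current maps. Each
#' step is an exact conditional update, so a sweep cannot decrease the
#' free energy.
#'
#' @param subject An `spfm_subject`.
#' @param group The current `spfm_group`.
#' @param data List of run data matrices.
#' @param tp A [temporal_prior()].
#' @param n_spatial_passes Inner iterations of the spatial mean-field.
#' @return The updated subject.
#' @export
subject_sweep <- function(subject, group, data, tp, n_spatial_passes = 3) {
  ex <- group_expect(group)
  for (r in seq_along(data)) {
    subject <- temporal_update(subject, r, group, data[[r]], tp, ex = ex)
    subject <- amplitude_update(subject, r, group, data[[r]], ex = ex)
    subject <- noise_update(subject, r, group, data[[r]])
  }
  subject <- dgmm_spatial_update(subject, group, data,
                                 n_passes = n_spatial_passes, ex = ex)
  for (r in seq_along(data))
    subject <- precision_update(subject, r, group, ncol(data[[r]]), ex = ex)
  subject
}

#' Accumulate subject evidence into an intermediate group model
#'
#' Conjugate natural-parameter updates for every group factor, with each
#' subject's sufficient statistics multiplied by `scale_factor` (the number
#' of batches N) so that a batch acts as if the full population were
#' present. With `scale_factor = 1` and the batch equal to the full
#' population this is the classic full-batch VB group update.
#'
#' @param subjects List of `spfm_subject` states (the batch).
#' @param group The current `spfm_group` (supplies hyperpriors and the
#'   expectations entering the variance updates).
#' @param scale_factor Multiplier N for the subject statistics.
#' @return The intermediate group model (theta-hat), an `spfm_group`.
#' @export
accumulate_and_update_group <- function(subjects, group, scale_factor = 1) {
  if (length(subjects) == 0) stop("empty batch")
  h <- group$hyper
  nv <- group$n_voxels; nm <- group$n_modes
  N <- scale_factor

  sum_q <- matrix(0, nv, nm); sum_1q <- matrix(0, nv, nm)
  sum_mu_prec <- matrix(0, nv, nm); sum_mu_pm <- matrix(0, nv, nm)
  sum_ms <- vector("list", length(subjects))
  sum_alpha <- matrix(0, nm, nm); n_runs_tot <- 0
  sum_g <- rep(0, nm); sum_g2 <- rep(0, nm); n_amp <- 0

  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    sum_q <- sum_q + s$q
    sum_1q <- sum_1q + (1 - s$q)
    sum_mu_prec <- sum_mu_prec + s$q
    sum_mu_pm <- sum_mu_pm + s$q * s$ms
    for (run in s$runs) {
      sum_alpha <- sum_alpha + run$alpha_nu * run$alpha_V
      n_runs_tot <- n_runs_tot + 1
      sum_g <- sum_g + run$g_mean
      n_amp <- n_amp + 1
    }
  }

  g <- group
  # group signal means (precision-weighted by the signal precision)
  E_taus <- group$taus_a / group$taus_b
  prec <- h$mu_prec0 + N * E_taus * sum_mu_prec
  g$mu_mean <- (h$mu_prec0 * h$mu_mean0 + N * E_taus * sum_mu_pm) / prec
  g$mu_var <- 1 / prec

  # signal / noise precisions given the new group means
  ss_s <- matrix(0, nv, nm); ss_n <- matrix(0, nv, nm)
  for (s in subjects) {
    ss_s <- ss_s + s$q * ((s$ms^2 + s$vs) - 2 * s$ms * g$mu_mean +
                            (g$mu_mean^2 + g$mu_var))
    ss_n <- ss_n + (1 - s$q) * (s$mn^2 + s$vn)
  }
  g$taus_a <- h$taus_a0 + N * sum_q / 2
  g$taus_b <- h$taus_b0 + N * ss_s / 2
  g$taun_a <- h$taun_a0 + N * sum_1q / 2
  g$taun_b <- h$taun_b0 + N * ss_n / 2

  g$pi_a <- h$pi_a0 + N * sum_q
  g$pi_b <- h$pi_b0 + N * sum_1q

  g$Rg_eta <- h$Rg_eta0 + N * n_runs_tot * h$nu0
  Phi0_inv <- diag(1 / h$Rg_Phi0_scale, nm)
  g$Rg_Phi <- chol2inv(chol(ensure_spd(Phi0_inv + N * sum_alpha)))

  E_taua <- group$ampt_a / group$ampt_b
  prec_a <- h$amp_prec0 + N * n_amp * E_taua
  g$amp_mean <- (h$amp_prec0 * h$amp_mean0 + N * E_taua * sum_g) / prec_a
  g$amp_var <- 1 / prec_a
  ss_a <- rep(0, nm)
  for (s in subjects) for (run in s$runs)
    ss_a <- ss_a + (run$g_mean - g$amp_mean)^2 + run$g_var + g$amp_var
  g$ampt_a <- h$ampt_a0 + N * n_amp / 2
  g$ampt_b <- h$ampt_b0 + N * ss_a / 2
  g
}
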