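#' Hyperpriors for the hierarchical mode model
#'
#' Weakly-informative conjugate hyperpriors for every group-level factor.
#' The spatial signal/noise mixture is sparsity-inducing: the membership
#' prior mean is 0.05 (most voxels belong to the background for any given
#' mode) and the noise component is tight around zero. All values are
#' exposed so they can be tuned per study.
#'
#' @param n_modes Number of modes.
#' @param nu0 Subject-level Wishart prior degrees of freedom for the
#'   between-mode precision matrices (> n_modes - 1).
#' @param membership_prior_mean Prior probability that a voxel carries
#'   signal for a mode.
#' @param membership_prior_strength Beta pseudo-count total.
#' @return A list of class `spfm_hyper`.
#' @export
spfm_hyperpriors <- function(n_modes,
                             nu0 = n_modes + 2,
                             membership_prior_mean = 0.05,
                             membership_prior_strength = 10) {
  if (nu0 <= n_modes - 1) stop("nu0 must exceed n_modes - 1")
  structure(list(
    mu_mean0 = 0, mu_prec0 = 0.01,
    taus_a0 = 2, taus_b0 = 2,          # signal variance ~ 1 (unit-var data)
    taun_a0 = 2, taun_b0 = 0.02,       # background tight around zero
    pi_a0 = membership_prior_mean * membership_prior_strength,
    pi_b0 = (1 - membership_prior_mean) * membership_prior_strength,
    nu0 = nu0,
    Rg_eta0 = n_modes + 2,
    Rg_Phi0_scale = nu0 / (n_modes + 2), # E[R_g] = nu0 * I a priori
    amp_mean0 = 0, amp_prec0 = 1,
    ampt_a0 = 2, ampt_b0 = 0.5,
    psi_a0 = 1e-3, psi_b0 = 1e-3,
    n_modes = n_modes
  ), class = "spfm_hyper")
}

#' Initialise the group model from initial maps
#'
#' Places the group spatial posterior in the ballpark of the ICA initial
#' maps: group signal means follow the maps, membership probabilities are
#' high where the map magnitude is large and at the sparse prior mean
#' elsewhere, and all remaining factors start at their hyperpriors.
#'
#' @param init An `initial_maps` object (or a plain map matrix).
#' @param hyper An [spfm_hyperpriors()] list.
#' @return A group model of class `spfm_group`.
#' @export
init_group_model <- function(init, hyper) {
  maps <- if (inherits(init, "initial_maps")) init$maps else as.matrix(init)
  nv <- nrow(maps); nm <- ncol(maps)
  stopifnot(nm == hyper$n_modes)
  q0 <- pmin(pmax(0.05 + 0.9 * stats::plogis(3 * (abs(maps) - 1.5)),
                  0.02), 0.98)
  maps <- scale_init_maps(maps)
  g <- list(
    mu_mean = maps, mu_var = matrix(0.5, nv, nm),
    taus_a = matrix(hyper$taus_a0, nv, nm),
    taus_b = matrix(hyper$taus_b0, nv, nm),
    taun_a = matrix(hyper$taun_a0, nv, nm),
    taun_b = matrix(hyper$taun_b0, nv, nm),
    pi_a = 10 * q0, pi_b = 10 * (1 - q0),
    Rg_eta = hyper$Rg_eta0,
    Rg_Phi = diag(hyper$Rg_Phi0_scale, nm),
    amp_mean = rep(hyper$amp_mean0, nm), amp_var = rep(1, nm),
    ampt_a = rep(hyper$ampt_a0, nm), ampt_b = rep(hyper$ampt_b0, nm),
    hyper = hyper, n_voxels = nv, n_modes = nm
  )
  class(g) <- "spfm_group"
  g
}

# Initial maps arrive z-scored; rescale them so the per-voxel signal
# variance share matches variance-normalised data (about half the unit
# variance), which keeps timecourses, amplitudes and precisions near their
# prior scales from the first sweep.
scale_init_maps <- function(maps) {
  maps * sqrt(0.5 * nrow(maps) / max(sum(maps^2), 1e-12))
}

# Moment expectations used throughout the updates.
group_expect <- function(g) {
  list(
    Mg = g$mu_mean, Vg = g$mu_var,
    E_taus = g$taus_a / g$taus_b,
    Elog_taus = digamma(g$taus_a) - log(g$taus_b),
    E_taun = g$taun_a / g$taun_b,
    Elog_taun = digamma(g$taun_a) - log(g$taun_b),
    Elog_pi = digamma(g$pi_a) - digamma(g$pi_a + g$pi_b),
    Elog_1mpi = digamma(g$pi_b) - digamma(g$pi_a + g$pi_b),
    E_Rg = g$Rg_eta * g$Rg_Phi,
    Elogdet_Rg = mvdigamma(g$Rg_eta / 2, g$n_modes) +
      g$n_modes * log(2) + logdet(g$Rg_Phi),
    Ma = g$amp_mean, Va = g$amp_var,
    E_taua = g$ampt_a / g$ampt_b,
    Elog_taua = digamma(g$ampt_a) - log(g$ampt_b)
  )
}

# Natural-parameter view of the group state: every entry is linear in the
# accumulated sufficient statistics, so a convex combination here is the
# correct stochastic-VB blend for each conjugate family.
group_to_nat <- function(g) {
  list(
    mu_prec = 1 / g$mu_var, mu_pm = g$mu_mean / g$mu_var,
    taus_a = g$taus_a, taus_b = g$taus_b,
    taun_a = g$taun_a, taun_b = g$taun_b,
    pi_a = g$pi_a, pi_b = g$pi_b,
    Rg_eta = g$Rg_eta, Rg_Phi_inv = chol2inv(chol(g$Rg_Phi)),
    amp_prec = 1 / g$amp_var, amp_pm = g$amp_mean / g$amp_var,
    ampt_a = g$ampt_a, ampt_b = g$ampt_b
  )
}

nat_to_group <- function(nat, template) {
  g <- template
  g$mu_var <- 1 / nat$mu_prec
  g$mu_mean <- nat$mu_pm / nat$mu_prec
  g$taus_a <- nat$taus_a; g$taus_b <- nat$taus_b
  g$taun_a <- nat$taun_a; g$taun_b <- nat$taun_b
  g$pi_a <- nat$pi_a; g$pi_b <- nat$pi_b
  g$Rg_eta <- nat$Rg_eta
  g$Rg_Phi <- chol2inv(chol(ensure_spd(nat$Rg_Phi_inv)))
  g$amp_var <- 1 / nat$amp_prec
  g$amp_mean <- nat$amp_pm / nat$amp_prec
  g$ampt_a <- nat$ampt_a; g$ampt_b <- nat$ampt_b
  g
}

#' Initialise one subject's posteriors from the initial maps
#'
#' First-visit initialisation: the spatial signal means follow the initial
#' maps, memberships follow the map magnitude, and temporal, amplitude and
#' noise factors start at diffuse defaults; the first subject sweep
#' replaces them with proper conditional posteriors.
#'
#' @param init An `initial_maps` object (or plain matrix).
#' @param group The current group model (for variance expectations).
#' @param n_runs Number of runs for this subject.
#' @param n_timepoints Timepoints per run.
#' @return A subject state of class `spfm_subject`.
#' @export
init_subject <- function(init, group, n_runs, n_timepoints) {
  maps <- if (inherits(init, "initial_maps")) init$maps else as.matrix(init)
  nv <- nrow(maps); nm <- ncol(maps)
  ex <- group_expect(group)
  q0 <- pmin(pmax(0.05 + 0.9 * stats::plogis(3 * (abs(maps) - 1.5)),
                  0.02), 0.98)
  s <- list(
    # initial maps enter as confident point estimates: diffuse variances
    # here would leak into E[P'P] and mis-scale the first timecourse fit
    ms = scale_init_maps(maps), vs = matrix(0.01, nv, nm),
    mn = matrix(0, nv, nm), vn = matrix(0.01, nv, nm),
    q = q0,
    runs = lapply(seq_len(n_runs), function(r) list(
      A_mean = matrix(0, nm, n_timepoints),
      E_AAt = diag(1e-3, nm),
      E_AKiAt = diag(1e-3, nm),
      ent_A = 0.5 * nm * n_timepoints * log(2 * pi * exp(1) * 1e-3),
      alpha_nu = group$hyper$nu0,
      # prior E[alpha] = nu0 * E[R_g]^{-1}
      alpha_V = chol2inv(chol(group$Rg_eta * group$Rg_Phi)),
      g_mean = rep(0, nm), g_var = rep(0.04, nm),
      psi_a = 1, psi_b = 1
    )),
    n_visits = 0L
  )
  class(s) <- "spfm_subject"
  s
}

# Spatial map moments of one subject.
subject_map_moments <- function(s) {
  E_P <- s$q * s$ms + (1 - s$q) * s$mn
  E_P2 <- s$q * (s$ms^2 + s$vs) + (1 - s$q) * (s$mn^2 + s$vn)
  E_PtP <- crossprod(E_P)
  diag(E_PtP) <- colSums(E_P2)
  list(E_P = E_P, E_P2 = E_P2, E_PtP = E_PtP)
}

# Amplitude moments of one run.
amp_moments <- function(run) {
  Eh <- exp(run$g_mean + run$g_var / 2)
  Ehh <- outer(Eh, Eh)
  diag(Ehh) <- exp(2 * run$g_mean + 2 * run$g_var)
  list(Eh = Eh, Ehh = Ehh)
}

#' Expected subject spatial maps
#'
#' The membership-weighted signal mean, the model's point summary of a
#' subject's mode topography.
#'
#' @param s An `spfm_subject`.
#' @return `n_voxels x n_modes` matrix.
#' @export
expected_maps <- function(s) s$q * s$ms

#' Expected group spatial maps
#'
#' @param g An `spfm_group`.
#' @return `n_voxels x n_modes` matrix (membership-probability-weighted
#'   group signal means).
#' @export
expected_group_maps <- function(g) {
  (g$pi_a / (g$pi_a + g$pi_b)) * g$mu_mean
}
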