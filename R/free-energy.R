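# Entropies and cross-entropies of the conjugate families used by the
# variational objective. All return scalars.

gaussian_entropy <- function(v) 0.5 * sum(log(2 * pi * exp(1) * v))

gamma_entropy <- function(a, b) {
  sum(a - log(b) + lgamma(a) + (1 - a) * digamma(a))
}

beta_entropy <- function(a, b) {
  sum(lbeta(a, b) - (a - 1) * digamma(a) - (b - 1) * digamma(b) +
        (a + b - 2) * digamma(a + b))
}

wishart_entropy <- function(nu, V) {
  d <- nrow(V)
  0.5 * (d + 1) * logdet(V) + 0.5 * d * (d + 1) * log(2) +
    lmvgamma(nu / 2, d) - 0.5 * (nu - d - 1) * mvdigamma(nu / 2, d) +
    0.5 * nu * d
}

# KL(q || p) between two Gaussians, elementwise over vectors/matrices.
kl_gaussian <- function(m_q, v_q, m_p, v_p) {
  sum(0.5 * (log(v_p / v_q) + (v_q + (m_q - m_p)^2) / v_p - 1))
}

# KL(q || p) between two Gamma distributions.
kl_gamma <- function(a_q, b_q, a_p, b_p) {
  sum((a_q - a_p) * digamma(a_q) - lgamma(a_q) + lgamma(a_p) +
        a_p * (log(b_q) - log(b_p)) + a_q * (b_p - b_q) / b_q)
}

# KL(q || p) between two Beta distributions.
kl_beta <- function(a_q, b_q, a_p, b_p) {
  sum(lbeta(a_p, b_p) - lbeta(a_q, b_q) +
        (a_q - a_p) * digamma(a_q) + (b_q - b_p) * digamma(b_q) +
        (a_p - a_q + b_p - b_q) * digamma(a_q + b_q))
}

# KL(q || p) between two Wisharts sharing dimension d, via the
# cross-entropy E_q[log p] and the Wishart entropy.
kl_wishart <- function(nu_q, V_q, nu_p, V_p) {
  d <- nrow(V_q)
  Vp_inv <- chol2inv(chol(V_p))
  Elogdet <- mvdigamma(nu_q / 2, d) + d * log(2) + logdet(V_q)
  Elogp <- 0.5 * (nu_p - d - 1) * Elogdet -
    0.5 * nu_q * sum(Vp_inv * V_q) -
    0.5 * nu_p * logdet(V_p) - 0.5 * nu_p * d * log(2) -
    lmvgamma(nu_p / 2, d)
  -wishart_entropy(nu_q, V_q) - Elogp
}

# Free-energy contribution of one subject (data fit plus all local
# KL-style terms, each as E_q[log p] - E_q[log q]).
subject_free_energy_terms <- function(subject, group, data, tp) {
  ex <- group_expect(group)
  h <- group$hyper
  nm <- group$n_modes
  s <- subject
  q <- s$q

  # spatial: mixture assignments and the two Gaussian components
  Elogp_sp <- sum(q * (ex$Elog_pi + 0.5 * ex$Elog_taus -
                         0.5 * log(2 * pi) -
                         0.5 * ex$E_taus * ((s$ms^2 + s$vs) -
                                              2 * s$ms * ex$Mg +
                                              (ex$Mg^2 + ex$Vg)))) +
    sum((1 - q) * (ex$Elog_1mpi + 0.5 * ex$Elog_taun -
                     0.5 * log(2 * pi) -
                     0.5 * ex$E_taun * (s$mn^2 + s$vn)))
  Elogq_sp <- sum(q * log(q) + (1 - q) * log(1 - q)) -
    sum(q * 0.5 * log(2 * pi * exp(1) * s$vs)) -
    sum((1 - q) * 0.5 * log(2 * pi * exp(1) * s$vn))

  data_fit <- 0
  temporal <- 0
  precision <- 0
  amplitude <- 0
  noise <- 0
  for (r in seq_along(data)) {
    run <- s$runs[[r]]
    nt <- ncol(data[[r]])
    Epsi <- run$psi_a / run$psi_b
    Elogpsi <- digamma(run$psi_a) - log(run$psi_b)
    rss <- expected_rss(s, run, data[[r]])
    data_fit <- data_fit +
      0.5 * length(data[[r]]) * (Elogpsi - log(2 * pi)) - 0.5 * Epsi * rss

    Ealpha <- run$alpha_nu * run$alpha_V
    Elogdet_a <- mvdigamma(run$alpha_nu / 2, nm) + nm * log(2) +
      logdet(run$alpha_V)
    temporal <- temporal +
      0.5 * nt * Elogdet_a - 0.5 * nm * sum(log(2 * pi * tp$k)) -
      0.5 * sum(Ealpha * run$E_AKiAt) + run$ent_A

    precision <- precision +
      0.5 * (h$nu0 - nm - 1) * Elogdet_a - 0.5 * sum(ex$E_Rg * Ealpha) +
      0.5 * h$nu0 * ex$Elogdet_Rg - 0.5 * h$nu0 * nm * log(2) -
      lmvgamma(h$nu0 / 2, nm) + wishart_entropy(run$alpha_nu, run$alpha_V)

    amplitude <- amplitude +
      sum(0.5 * (ex$Elog_taua - log(2 * pi)) -
            0.5 * ex$E_taua * ((run$g_mean - ex$Ma)^2 + run$g_var +
                                 ex$Va)) +
      gaussian_entropy(run$g_var)

    noise <- noise +
      h$psi_a0 * log(h$psi_b0) - lgamma(h$psi_a0) +
      (h$psi_a0 - 1) * Elogpsi - h$psi_b0 * Epsi +
      gamma_entropy(run$psi_a, run$psi_b)
  }

  c(data_fit = data_fit, spatial = Elogp_sp - Elogq_sp,
    temporal = temporal, precision = precision,
    amplitude = amplitude, noise = noise)
}

# Free-energy contribution of the group factors against their hyperpriors.
group_free_energy_term <- function(group) {
  h <- group$hyper
  nm <- group$n_modes
  g <- group
  term <- -kl_gaussian(g$mu_mean, g$mu_var, h$mu_mean0, 1 / h$mu_prec0)
  term <- term - kl_gamma(g$taus_a, g$taus_b, h$taus_a0, h$taus_b0)
  term <- term - kl_gamma(g$taun_a, g$taun_b, h$taun_a0, h$taun_b0)
  term <- term - kl_beta(g$pi_a, g$pi_b, h$pi_a0, h$pi_b0)
  term <- term - kl_wishart(g$Rg_eta, g$Rg_Phi, h$Rg_eta0,
                            diag(h$Rg_Phi0_scale, nm))
  term <- term - kl_gaussian(g$amp_mean, g$amp_var, h$amp_mean0,
                             1 / h$amp_prec0)
  term <- term - kl_gamma(g$ampt_a, g$ampt_b, h$ampt_a0, h$ampt_b0)
  term
}

#' Variational free energy with per-term breakdown
#'
#' The evidence lower bound of the hierarchical model, split into the data
#' fit and one term per factor family. When `subjects` is a batch rather
#' than the full population, `n_batches` scales the subject-side terms so
#' the value is an unbiased estimate of the full-population free energy.
#'
#' @param group An `spfm_group`.
#' @param subjects List of `spfm_subject` states.
#' @param data List (per subject) of lists (per run) of data matrices.
#' @param tp A [temporal_prior()].
#' @param n_batches Scale factor N for the subject terms.
#' @return An object of class `free_energy_ledger`: list with `total` and
#'   the per-term breakdown (`total` equals the sum of terms).
#' @export
free_energy <- function(group, subjects, data, tp, n_batches = 1) {
  terms <- c(data_fit = 0, spatial = 0, temporal = 0, precision = 0,
             amplitude = 0, noise = 0)
  for (i in seq_along(subjects)) {
    terms <- terms +
      subject_free_energy_terms(subjects[[i]], group, data[[i]], tp)
  }
  terms <- n_batches * terms
  terms["group"] <- group_free_energy_term(group)
  structure(list(total = sum(terms), terms = terms,
                 n_subjects = length(subjects), n_batches = n_batches),
            class = "free_energy_ledger")
}

#' @export
print.free_energy_ledger <- function(x, ...) {
  cat(sprintf("free energy: %.4f\n", x$total))
  for (nm in names(x$terms))
    cat(sprintf("  %-10s %14.4f\n", nm, x$terms[[nm]]))
  invisible(x)
}
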