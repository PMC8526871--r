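# Conjugate-update oracles: each variational update is checked against an
# independent dense/numeric computation on small instances.

test_that("symmetric signal and noise components leave membership at its prior", {
  st <- tiny_state()
  g <- st$group
  # make the two mixture components identical: zero-mean group signal with
  # the same precision as the noise component
  g$mu_mean[] <- 0; g$mu_var[] <- 0
  g$taus_a <- g$taun_a; g$taus_b <- g$taun_b
  s <- dgmm_spatial_update(st$subject, g, st$data)
  prior_q <- plogis(digamma(g$pi_a) - digamma(g$pi_b))
  expect_equal(s$q, prior_q, tolerance = 1e-10)
})

test_that("single voxel-mode DGMM posterior matches grid integration", {
  # one voxel, one mode, fixed timecourse evidence
  nv <- 1; nt <- 50
  set.seed(10)
  maps <- matrix(1.2, nv, 1)
  init <- structure(list(maps = maps, seed = 1L), class = "initial_maps")
  hyper <- spfm_hyperpriors(1)
  group <- init_group_model(init, hyper)
  group$mu_mean[] <- 0.7; group$mu_var[] <- 0.2
  subject <- init_subject(init, group, 1, nt)
  A <- matrix(rnorm(nt), 1)
  subject$runs[[1]]$A_mean <- A
  subject$runs[[1]]$E_AAt <- tcrossprod(A)
  subject$runs[[1]]$g_mean <- 0.1; subject$runs[[1]]$g_var <- 0.02
  subject$runs[[1]]$psi_a <- 30; subject$runs[[1]]$psi_b <- 10
  D <- 0.9 * A + 0.3 * matrix(rnorm(nt), 1)
  out <- dgmm_spatial_update(subject, group, list(D))

  # oracle: numeric integration of the two-component model under the same
  # expected natural parameters
  ex <- spfm:::group_expect(group)
  am <- spfm:::amp_moments(subject$runs[[1]])
  Epsi <- 3
  f <- Epsi * am$Ehh[1, 1] * tcrossprod(A)[1, 1]
  r <- Epsi * am$Eh[1] * sum(D * A)
  pgrid <- seq(-6, 6, length.out = 40001)
  lik <- r * pgrid - 0.5 * f * pgrid^2
  ls <- ex$Elog_pi[1, 1] + 0.5 * ex$Elog_taus[1, 1] -
    0.5 * ex$E_taus[1, 1] * ((pgrid - ex$Mg[1, 1])^2 + ex$Vg[1, 1])
  ln <- ex$Elog_1mpi[1, 1] + 0.5 * ex$Elog_taun[1, 1] -
    0.5 * ex$E_taun[1, 1] * pgrid^2
  m <- max(c(lik + ls, lik + ln))
  ws <- exp(lik + ls - m); wn <- exp(lik + ln - m)
  q_oracle <- sum(ws) / (sum(ws) + sum(wn))
  ms_oracle <- sum(pgrid * ws) / sum(ws)
  mn_oracle <- sum(pgrid * wn) / sum(wn)
  expect_equal(out$q[1, 1], q_oracle, tolerance = 1e-6)
  expect_equal(out$ms[1, 1], ms_oracle, tolerance = 1e-6)
  expect_equal(out$mn[1, 1], mn_oracle, tolerance = 1e-6)
})

test_that("zero-evidence limit shrinks the signal mean to the group prior", {
  st <- tiny_state()
  s <- st$subject
  for (r in seq_along(s$runs)) {
    s$runs[[r]]$A_mean[] <- 0
    s$runs[[r]]$E_AAt <- matrix(0, 2, 2)
  }
  out <- dgmm_spatial_update(s, st$group, lapply(st$data, function(d) d * 0))
  expect_equal(out$ms, st$group$mu_mean, tolerance = 1e-10)
})

test_that("temporal posterior equals the dense generalised-ridge solution", {
  nv <- 10; nm <- 3; nt <- 12
  set.seed(20)
  maps <- matrix(rnorm(nv * nm), nv)
  init <- structure(list(maps = scale(maps), seed = 1L),
                    class = "initial_maps")
  hyper <- spfm_hyperpriors(nm)
  group <- init_group_model(init, hyper)
  subject <- init_subject(init, group, 1, nt)
  # pin the spatial posterior to exact values
  subject$ms <- maps; subject$vs[] <- 0; subject$mn[] <- 0
  subject$vn[] <- 0; subject$q[] <- 1
  subject$runs[[1]]$g_mean <- c(0.2, -0.1, 0); subject$runs[[1]]$g_var <- rep(0, nm)
  subject$runs[[1]]$psi_a <- 20; subject$runs[[1]]$psi_b <- 10
  P <- matrix(rnorm(nm^2), nm); alpha <- crossprod(P) + diag(nm)
  subject$runs[[1]]$alpha_nu <- 100
  subject$runs[[1]]$alpha_V <- alpha / 100
  D <- matrix(rnorm(nv * nt), nv)
  tp <- temporal_prior(nt, 0.72)
  out <- temporal_update(subject, 1, group, D, tp)

  h <- exp(subject$runs[[1]]$g_mean)
  W <- maps %*% diag(h)
  Epsi <- 2
  Kinv <- solve(tp$K)
  prec <- Epsi * kronecker(diag(nt), crossprod(W)) +
    kronecker(Kinv, alpha)
  mu <- solve(prec, Epsi * as.numeric(crossprod(W, D)))
  A_dense <- matrix(mu, nm, nt)
  expect_equal(out$runs[[1]]$A_mean, A_dense, tolerance = 1e-6)

  Cov <- solve(prec)
  EAAt <- tcrossprod(A_dense)
  for (t in seq_len(nt)) {
    idx <- (t - 1) * nm + 1:nm
    EAAt <- EAAt + Cov[idx, idx]
  }
  expect_equal(out$runs[[1]]$E_AAt, EAAt, tolerance = 1e-6)
})

test_that("all-zero data give all-zero posterior mean timecourses", {
  st <- tiny_state()
  out <- temporal_update(st$subject, 1, st$group,
                         st$data[[1]] * 0, st$tp)
  expect_equal(max(abs(out$runs[[1]]$A_mean)), 0)
})

test_that("precision update: dof bookkeeping and scalar Gamma equivalence", {
  st <- tiny_state()
  nt <- ncol(st$data[[1]])
  out <- precision_update(st$subject, 1, st$group, nt)
  expect_equal(out$runs[[1]]$alpha_nu, st$group$hyper$nu0 + nt)

  # one mode: Wishart posterior reduces to the Gamma closed form
  nv <- 20; nm <- 1; ntt <- 35
  maps <- matrix(rnorm(nv), nv, 1)
  init <- structure(list(maps = scale(maps), seed = 1L),
                    class = "initial_maps")
  group1 <- init_group_model(init, spfm_hyperpriors(1))
  s1 <- init_subject(init, group1, 1, ntt)
  scatter <- 4.2
  s1$runs[[1]]$E_AKiAt <- matrix(scatter, 1, 1)
  out1 <- precision_update(s1, 1, group1, ntt)
  ERg <- group1$Rg_eta * group1$Rg_Phi[1, 1]
  gamma_mean <- ((group1$hyper$nu0 + ntt) / 2) / ((ERg + scatter) / 2)
  expect_equal(out1$runs[[1]]$alpha_nu * out1$runs[[1]]$alpha_V[1, 1],
               gamma_mean, tolerance = 1e-10)
})

test_that("precision posterior recovers a known precision from many samples", {
  nm <- 3; n <- 10000
  set.seed(30)
  P <- crossprod(matrix(rnorm(nm^2), nm)) + diag(nm)
  A <- t(chol(solve(P))) %*% matrix(rnorm(nm * n), nm)
  maps <- matrix(rnorm(50 * nm), 50)
  init <- structure(list(maps = scale(maps), seed = 1L),
                    class = "initial_maps")
  group <- init_group_model(init, spfm_hyperpriors(nm))
  # weak hierarchical prior
  group$Rg_eta <- nm + 2
  group$Rg_Phi <- diag(1e-4, nm)
  s <- init_subject(init, group, 1, n)
  s$runs[[1]]$E_AKiAt <- tcrossprod(A)
  out <- precision_update(s, 1, group, n)
  Ealpha <- out$runs[[1]]$alpha_nu * out$runs[[1]]$alpha_V
  expect_lt(max(abs(Ealpha - solve(tcrossprod(A) / n)) /
                  max(abs(P))), 0.05)
})

test_that("amplitude posterior is positive and scale-equivariant", {
  st <- tiny_state()
  g <- st$group
  g$ampt_a[] <- 1e-4; g$ampt_b[] <- 1   # near-flat amplitude prior
  g$amp_var[] <- 1e6
  s <- st$subject
  s <- temporal_update(s, 1, g, st$data[[1]], st$tp)
  base <- amplitude_update(s, 1, g, st$data[[1]])
  h0 <- exp(base$runs[[1]]$g_mean + base$runs[[1]]$g_var / 2)
  expect_true(all(h0 > 0))

  cfac <- 3
  s2 <- s
  s2$runs[[1]]$psi_a <- s$runs[[1]]$psi_a
  s2$runs[[1]]$psi_b <- s$runs[[1]]$psi_b * cfac^2   # same E[psi]*scale
  scaled <- amplitude_update(s2, 1, g, st$data[[1]] * cfac)
  h1 <- exp(scaled$runs[[1]]$g_mean + scaled$runs[[1]]$g_var / 2)
  expect_equal(h1 / h0, rep(cfac, 2), tolerance = 0.05)
})

test_that("noise update matches the direct mean-squared-residual computation", {
  nv <- 30; nm <- 2; nt <- 25
  set.seed(40)
  maps <- matrix(rnorm(nv * nm), nv)
  init <- structure(list(maps = scale(maps), seed = 1L),
                    class = "initial_maps")
  group <- init_group_model(init, spfm_hyperpriors(nm))
  s <- init_subject(init, group, 1, nt)
  s$ms <- maps; s$vs[] <- 0; s$mn[] <- 0; s$vn[] <- 0; s$q[] <- 1
  A <- matrix(rnorm(nm * nt), nm)
  s$runs[[1]]$A_mean <- A; s$runs[[1]]$E_AAt <- tcrossprod(A)
  s$runs[[1]]$g_mean <- rep(0, nm); s$runs[[1]]$g_var <- rep(0, nm)
  D <- maps %*% A + 0.5 * matrix(rnorm(nv * nt), nv)
  out <- noise_update(s, 1, group, D)
  run <- out$runs[[1]]
  rss <- sum((D - maps %*% A)^2)
  # flat-prior limit: posterior mean precision = 1 / mean squared residual
  expect_equal(run$psi_a / run$psi_b, (nv * nt) / rss, tolerance = 1e-3)

  # doubling the residuals quarters the posterior mean precision
  D2 <- maps %*% A + 2 * (D - maps %*% A)
  out2 <- noise_update(s, 1, group, D2)
  expect_equal((out2$runs[[1]]$psi_a / out2$runs[[1]]$psi_b) /
                 (run$psi_a / run$psi_b), 0.25, tolerance = 1e-3)
})

test_that("degenerate population: group signal mean equals the shared map", {
  st <- tiny_state()
  s <- subject_sweep(st$subject, st$group, st$data, st$tp)
  g <- st$group
  g$hyper$mu_prec0 <- 0          # flat hyperprior isolates the accumulation
  out <- accumulate_and_update_group(list(s, s, s), g, scale_factor = 10)
  expect_equal(out$mu_mean, s$ms, tolerance = 1e-6)
  expect_error(accumulate_and_update_group(list(), g), "empty batch")
})

test_that("spatial posterior is invariant to run accumulation order", {
  st2 <- tiny_state(seed = 9)
  set.seed(50)
  d2 <- list(st2$data[[1]],
             scale(t(scale(t(st2$maps %*%
                               matrix(rnorm(2 * 30), 2) +
                               0.4 * matrix(rnorm(40 * 30), 40))))))
  s <- init_subject(structure(list(maps = st2$maps, seed = 1L),
                              class = "initial_maps"),
                    st2$group, 2, 30)
  s <- subject_sweep(s, st2$group, d2, st2$tp)
  fwd <- dgmm_spatial_update(s, st2$group, d2)
  s_rev <- s
  s_rev$runs <- rev(s_rev$runs)
  rev_ <- dgmm_spatial_update(s_rev, st2$group, rev(d2))
  expect_equal(fwd$ms, rev_$ms, tolerance = 1e-12)
  expect_equal(fwd$q, rev_$q, tolerance = 1e-12)
})
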