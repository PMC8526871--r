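test_that("step size follows the power-law schedule", {
  # high-precision values of (t + tau)^(-beta)
  expect_equal(step_size(1, 5, 0.6), 6^(-0.6), tolerance = 1e-12)
  expect_equal(round(step_size(1, 5, 0.6), 4), 0.3413)
  expect_equal(round(step_size(245, 5, 0.6), 4), 0.0364)
  rho <- step_size(1:500, 5, 0.6)
  expect_true(all(diff(rho) < 0))
  expect_lt(step_size(1e8, 5, 0.6), 1e-4)
  expect_error(step_size(1, 5, 0.4), "beta")
  expect_error(step_size(1, 5, 1.2), "beta")
  expect_error(step_size(1, -1, 0.6), "tau")
})

test_that("batch sampling is uniform for equal counts and favours
           rarely-visited subjects", {
  set.seed(70)
  led <- visit_ledger(10)
  counts <- integer(10)
  for (i in 1:10000) {
    sb <- sample_batch(led, 3)       # ledger deliberately not carried over
    counts[sb$batch] <- counts[sb$batch] + 1L
  }
  expect_gt(chisq.test(counts)$p.value, 0.01)

  led2 <- visit_ledger(10)
  led2$counts <- rep(c(0L, 5L), each = 5)
  picks <- integer(10)
  for (i in 1:5000) {
    sb <- sample_batch(led2, 3)
    picks[sb$batch] <- picks[sb$batch] + 1L
  }
  expect_gt(sum(picks[1:5]), 1.5 * sum(picks[6:10]))

  # exhaustive batch selects everyone once and the ledger tracks it
  led3 <- visit_ledger(6)
  sb <- sample_batch(led3, 6)
  expect_equal(sort(sb$batch), 1:6)
  expect_equal(sb$ledger$counts, rep(1L, 6))
})

test_that("blending endpoints and Gaussian natural-parameter arithmetic", {
  st <- tiny_state()
  g1 <- st$group
  s <- subject_sweep(st$subject, g1, st$data, st$tp)
  g2 <- accumulate_and_update_group(list(s), g1, 5)
  expect_identical(blend_global(g1, g2, 0), g1)
  expect_identical(blend_global(g1, g2, 1), g2)

  mix <- blend_global(g1, g2, 0.3)
  # 1-D manual natural-parameter arithmetic: precision-weighted means
  v <- 1 / (0.7 / g1$mu_var + 0.3 / g2$mu_var)
  m <- v * (0.7 * g1$mu_mean / g1$mu_var + 0.3 * g2$mu_mean / g2$mu_var)
  expect_equal(mix$mu_mean, m, tolerance = 1e-12)
  expect_equal(mix$mu_var, v, tolerance = 1e-12)
  expect_equal(mix$pi_a, 0.7 * g1$pi_a + 0.3 * g2$pi_a, tolerance = 1e-12)
})

test_that("zero full updates leave the group unchanged", {
  st <- tiny_state()
  cfgs <- stochastic_config(batch_size = 1, n_batches = 1,
                            n_initial_updates = 2, n_full_updates = 0,
                            seed = 1)
  out <- run_batch(list(NULL), st$group, list(st$data),
                   structure(list(maps = st$maps, seed = 1L),
                             class = "initial_maps"),
                   cfgs, st$tp, scale_factor = 1)
  expect_identical(out$theta_hat, st$group)
})

test_that("one batch with N=1, K=S and rho=1 reproduces the full-batch
           reference update bit-for-bit", {
  tr <- small_study()
  data <- small_study_data()[1:4]
  nm <- tr$config$n_modes
  nt <- ncol(data[[1]][[1]])
  init <- structure(list(maps = scale(unclass(tr$group_maps)), seed = 1L),
                    class = "initial_maps")
  hyper <- spfm_hyperpriors(nm)
  tp <- temporal_prior(nt, tr$config$tr)
  cfgs <- stochastic_config(batch_size = 4, n_batches = 1,
                            n_initial_updates = 2, n_full_updates = 3,
                            seed = 1)

  group <- init_group_model(init, hyper)
  out <- run_batch(replicate(4, NULL), group, data, init, cfgs, tp,
                   scale_factor = 1)
  theta <- blend_global(group, out$theta_hat, 1)

  # independent reference loop over the same update operations
  g_ref <- init_group_model(init, hyper)
  subs <- lapply(1:4, function(i) {
    s <- init_subject(init, g_ref, 2, nt)
    s$n_visits <- 1L
    s
  })
  for (k in 1:2) for (i in 1:4)
    subs[[i]] <- subject_sweep(subs[[i]], g_ref, data[[i]], tp)
  for (k in 1:3) {
    for (i in 1:4)
      subs[[i]] <- subject_sweep(subs[[i]], g_ref, data[[i]], tp)
    g_ref <- accumulate_and_update_group(subs, g_ref, 1)
  }
  expect_identical(theta$mu_mean, g_ref$mu_mean)
  expect_identical(theta$pi_a, g_ref$pi_a)
  expect_identical(theta$Rg_Phi, g_ref$Rg_Phi)
  expect_identical(lapply(out$subjects, `[[`, "ms"),
                   lapply(subs, `[[`, "ms"))
})

test_that("scaled batch free energy is an unbiased estimator by exhaustive
           enumeration (S=6, K=2)", {
  tr <- small_study()
  data <- small_study_data()
  nm <- tr$config$n_modes
  nt <- ncol(data[[1]][[1]])
  init <- structure(list(maps = scale(unclass(tr$group_maps)), seed = 1L),
                    class = "initial_maps")
  group <- init_group_model(init, spfm_hyperpriors(nm))
  tp <- temporal_prior(nt, tr$config$tr)
  subjects <- lapply(1:6, function(i) {
    s <- init_subject(init, group, 2, nt)
    subject_sweep(s, group, data[[i]], tp)
  })
  full <- free_energy(group, subjects, data, tp, n_batches = 1)$total
  combos <- combn(6, 2)
  batch_fes <- apply(combos, 2, function(idx)
    free_energy(group, subjects[idx], data[idx], tp, n_batches = 3)$total)
  expect_equal(mean(batch_fes), full, tolerance = 1e-6 * abs(full))
})

test_that("final pass covers every subject and is idempotent at convergence", {
  tr <- small_study()
  data <- small_study_data()[1:3]
  nm <- tr$config$n_modes
  nt <- ncol(data[[1]][[1]])
  init <- structure(list(maps = scale(unclass(tr$group_maps)), seed = 1L),
                    class = "initial_maps")
  group <- init_group_model(init, spfm_hyperpriors(nm))
  tp <- temporal_prior(nt, tr$config$tr)
  cfgs <- stochastic_config(batch_size = 3, n_batches = 1,
                            n_final_updates = 10, seed = 1)
  fp <- final_pass(replicate(3, NULL), group, data, init, cfgs, tp)
  expect_equal(fp$pass_log, 1:3)
  # repeated passes against the frozen group contract towards a fixed
  # point: the free energy keeps increasing and the map drift shrinks
  deltas <- c(); fes <- c()
  prev <- lapply(fp$subjects, expected_maps)
  for (p in 1:4) {
    fp <- final_pass(fp$subjects, group, data, init, cfgs, tp)
    cur <- lapply(fp$subjects, expected_maps)
    deltas <- c(deltas, sqrt(sum(mapply(function(a, b) sum((a - b)^2),
                                        cur, prev))))
    fes <- c(fes, free_energy(group, fp$subjects, data, tp)$total)
    prev <- cur
  }
  expect_lt(deltas[4], deltas[1])
  expect_true(all(diff(fes) > -1e-6 * abs(fes[-1])))
})

test_that("the full fit is deterministic given the seed", {
  data <- small_study_data()[1:3]
  tr <- small_study()
  basis <- migp(lapply(unlist(data, recursive = FALSE), masked_dataset),
                n_components = 2 * tr$config$n_modes)
  init <- spatial_ica_init(basis, tr$config$n_modes, seed = 1)
  cfgs <- stochastic_config(batch_size = 2, n_batches = 3,
                            n_initial_updates = 1, n_full_updates = 2,
                            n_final_updates = 1, seed = 99)
  f1 <- spfm_fit(data, init, cfgs, tr = tr$config$tr)
  f2 <- spfm_fit(data, init, cfgs, tr = tr$config$tr)
  expect_identical(fitted_group_maps(f1), fitted_group_maps(f2))
  expect_identical(f1$history, f2$history)
  expect_identical(fitted_subject_maps(f1), fitted_subject_maps(f2))

  # disk-backed subject store gives the same answer
  f3 <- spfm_fit(data, init, cfgs, tr = tr$config$tr, store = "disk")
  expect_equal(fitted_group_maps(f3), fitted_group_maps(f1))

  # tidiers
  expect_s3_class(tidy(f1), "tbl_df")
  expect_equal(nrow(tidy(f1)), 3)
  expect_equal(glance(f1)$n_modes, 5)
})
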