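test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_modes = 0), "n_modes")
  expect_error(sim_config(tr = 0), "tr")
  expect_error(sim_config(target_misalignment = 1), "misalignment")
  expect_error(sim_config(mean_mode_size = 1e-6), "mean_mode_size")
  expect_error(sim_config(n_modes = 5, wishart_dof = 3), "wishart_dof")
  expect_error(sim_config(n_modes = 20, mean_mode_size = 0.086,
                          overlap_enabled = FALSE),
               "infeasible")
})

test_that("scenario presets carry the study parameters", {
  p <- scenario_presets("overlap_40")
  expect_equal(p$n_modes, 40L)
  expect_equal(p$mean_mode_size, 0.086)
  expect_equal(p$modes_per_voxel, 3.5)
  d <- scenario_presets("set1_default")
  expect_equal(d$n_modes, 15L)
  expect_equal(d$n_subjects, 500L)
  expect_equal(d$n_runs, 2L)
  expect_equal(d$n_voxels, 10000L)
  expect_equal(d$n_timepoints, 300L)
  expect_equal(d$tr, 0.72)
  expect_error(scenario_presets("nope"), "unknown preset")

  # serialisation round trip for every preset
  for (nm in c("set1_default", "misalignment_23.1", "misalignment_57.7",
               "overlap_20", "overlap_30", "overlap_40",
               "modesize_20", "modesize_30", "modesize_40")) {
    cfg <- scenario_presets(nm, n_subjects = 4, n_voxels = 1000)
    f <- tempfile(fileext = ".json")
    write_sim_config(cfg, f)
    expect_equal(read_sim_config(f), cfg)
  }
})

test_that("group maps are Gamma-weighted contiguous blocks at the target size", {
  cfg <- sim_config(n_voxels = 4000, n_modes = 10, modes_per_voxel = 1.3,
                    n_subjects = 1, seed = 5)
  gm <- make_group_maps(cfg)
  expect_equal(dim(gm), c(4000, 10))
  sizes <- colSums(unclass(gm) > 0)
  expect_lt(abs(mean(sizes) / (cfg$mean_mode_size * cfg$n_voxels) - 1), 0.15)
  # supports are unions of few contiguous runs
  n_runs <- vapply(seq_len(10), function(m) {
    r <- rle(gm[, m] > 0)
    sum(r$values)
  }, numeric(1))
  expect_true(all(n_runs >= 1 & n_runs <= 6))
  # in-mode weights are positive and right-skewed, off-mode exactly zero
  w <- gm[gm > 0]
  expect_true(all(w > 0))
  expect_gt(mean((w - mean(w))^3) / sd(w)^3, 0)
  expect_true(all(gm[gm <= 0] == 0))
})

test_that("overlap statistic matches a brute-force membership count", {
  for (seed in 1:3) {
    cfg <- sim_config(n_voxels = 3000, n_modes = 12, modes_per_voxel = 1.7,
                      n_subjects = 1, seed = seed)
    gm <- make_group_maps(cfg)
    memb <- unclass(gm) > 0
    brute <- sum(memb) / sum(rowSums(memb) > 0)
    expect_equal(attr(gm, "modes_per_voxel"), brute)
    expect_lt(abs(brute - 1.7) / 1.7, 0.15)
  }
})

test_that("single-mode configuration produces one nonzero block", {
  cfg <- sim_config(n_voxels = 500, n_modes = 1, n_subjects = 1,
                    mean_mode_size = 0.1, modes_per_voxel = NULL, seed = 2)
  gm <- make_group_maps(cfg)
  memb <- rowSums(unclass(gm) > 0)
  expect_equal(attr(gm, "modes_per_voxel"), 1)
  r <- rle(gm[, 1] > 0)
  expect_lte(sum(r$values), 3)
})

test_that("subject warps: identity limit, monotone overlap, calibration", {
  cfg <- sim_config(n_voxels = 3000, n_modes = 8, n_subjects = 1, seed = 9)
  gm <- make_group_maps(cfg)

  sm0 <- make_subject_maps(gm, warp_frac = 0, noise_sd = 0, seed = 1)
  expect_equal(unclass(sm0)[, ], unclass(gm)[, ], ignore_attr = TRUE)
  expect_equal(mean(attr(sm0, "overlap")), 1)

  ovl <- vapply(c(0, 0.1, 0.2, 0.4, 0.577), function(w) {
    mean(attr(make_subject_maps(gm, warp_frac = w, noise_sd = 0, seed = 4),
              "overlap"), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(ovl) <= 1e-8))

  # calibrated targets: ~80% retained at the 23.1% level, ~half at 57.7%
  ov231 <- mean(attr(make_subject_maps(gm, warp_frac = 0.231, noise_sd = 0,
                                       seed = 5), "overlap"), na.rm = TRUE)
  ov577 <- mean(attr(make_subject_maps(gm, warp_frac = 0.577, noise_sd = 0,
                                       seed = 5), "overlap"), na.rm = TRUE)
  expect_lt(abs(ov231 - 0.80), 0.06)
  expect_lt(abs(ov577 - 0.50), 0.06)
})

test_that("set-1 defaults reproduce the calibrated study statistics", {
  tr <- small_study()
  expect_lt(abs(attr(tr$group_maps, "modes_per_voxel") - 1.3) / 1.3, 0.15)
  expect_lt(abs(mean(unlist(tr$overlap), na.rm = TRUE) - 0.85), 0.06)
})

test_that("timecourses have the stated spectral and hierarchical structure", {
  cfg <- sim_config(n_voxels = 100, n_timepoints = 256, n_subjects = 3,
                    n_modes = 4, seed = 21)
  expect_error(make_timecourses(sim_config(n_modes = 4, wishart_dof = 2),
                                diag(4)),
               "wishart_dof")

  tcs <- make_timecourses(cfg, diag(4))
  # runs differ within a subject
  expect_gt(max(abs(tcs[[1]]$runs[[1]]$neural - tcs[[1]]$runs[[2]]$neural)),
            0.1)
  # >= 60% of neural spectral power below 0.1 Hz (FFT oracle)
  fr <- sapply(tcs, function(s) {
    x <- s$runs[[1]]$neural
    apply(x, 1, function(v) {
      sp <- Mod(fft(v))^2
      n <- length(v)
      f <- pmin(0:(n - 1), n - (0:(n - 1))) / (n * cfg$tr)
      sum(sp[f < 0.1]) / sum(sp)
    })
  })
  expect_gt(mean(fr), 0.6)
})

test_that("independence limit: identity precision with large dof gives
           near-zero partial correlations", {
  cfg <- sim_config(n_voxels = 100, n_timepoints = 400, n_subjects = 8,
                    n_modes = 3, wishart_dof = 5000, seed = 31)
  tcs <- make_timecourses(cfg, diag(3))
  pc <- sapply(tcs, function(s) {
    p <- partial_netmat(s$runs[[1]]$neural, rho = 1e-4)
    mean(abs(p[upper.tri(p)]))
  })
  expect_lt(mean(pc), 0.12)
})

test_that("subject precision draws average to the group partial correlations", {
  nm <- 3
  set.seed(11)
  L <- matrix(rnorm(nm^2), nm)
  gp <- crossprod(L) + diag(nm)
  cfg <- sim_config(n_voxels = 100, n_timepoints = 500, n_subjects = 200,
                    n_modes = nm, wishart_dof = 60, seed = 13)
  tcs <- make_timecourses(cfg, gp)
  target <- spfm:::precision_to_partial(gp)
  est <- Reduce(`+`, lapply(tcs, function(s)
    partial_netmat(s$runs[[1]]$neural, rho = 1e-3))) / length(tcs)
  expect_lt(mean(abs(est[upper.tri(est)] - target[upper.tri(target)])), 0.1)
})

test_that("assembled data follow the outer-product model", {
  tr <- small_study()
  cfg <- tr$config
  # noiseless limit
  d0 <- assemble_dataset(tr$subject_maps[1], tr$amplitudes[1],
                         tr$bold_timecourses[1], noise_snr = Inf, seed = 1)
  recon <- tr$subject_maps[[1]] %*%
    (tr$amplitudes[[1]][[1]] * tr$bold_timecourses[[1]][[1]])
  expect_equal(unclass(d0[[1]][[1]])[, ], recon, ignore_attr = TRUE)

  # realised SNR within 10% of the configured ratio
  sig <- var(as.numeric(recon))
  d1 <- tr$data[[1]][[1]]
  noise <- d1 - recon
  expect_lt(abs(sig / var(as.numeric(noise)) / cfg$noise_snr - 1), 0.1)

  # residuals are Gaussian (moment check on a subsample)
  res <- as.numeric(noise)[seq(1, length(noise), by = 7)]
  expect_gt(stats::shapiro.test(sample(res, 2000))$p.value, 0.01)

  # runs share spatial maps but not timecourses
  expect_identical(tr$subject_maps[[1]], tr$subject_maps[[1]])
  expect_gt(max(abs(tr$bold_timecourses[[1]][[1]] -
                      tr$bold_timecourses[[1]][[2]])), 0.1)
})

test_that("fixed seed gives bit-identical bundles", {
  cfg <- sim_config(n_voxels = 300, n_timepoints = 40, n_subjects = 2,
                    n_modes = 3, seed = 77)
  expect_identical(simulate_study(cfg), simulate_study(cfg))
})
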