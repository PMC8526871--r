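# Shared fixtures, built lazily and cached for the whole test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# A small but realistic simulated study used by several test files.
small_study <- function() {
  fixture("small_study", function() {
    cfg <- sim_config(n_voxels = 600, n_timepoints = 100, n_subjects = 6,
                      n_modes = 5, modes_per_voxel = 1.3,
                      target_misalignment = 0.17, seed = 42)
    simulate_study(cfg)
  })
}

# Preprocessed per-subject run matrices of the small study.
small_study_data <- function() {
  fixture("small_study_data", function() {
    tr <- small_study()
    lapply(seq_len(tr$config$n_subjects), function(s)
      lapply(seq_len(tr$config$n_runs), function(r)
        preprocess(truth_dataset(tr, s, r))$data))
  })
}

# A tiny deterministic model state (group + one subject + data) for the
# conjugate-update oracles: 2 modes, few voxels.
tiny_state <- function(n_voxels = 40, n_modes = 2, n_timepoints = 30,
                       seed = 7) {
  set.seed(seed)
  maps <- matrix(0, n_voxels, n_modes)
  maps[1:12, 1] <- rgamma(12, 3, 1)
  maps[20:34, 2] <- rgamma(15, 3, 1)
  maps <- scale(maps)
  init <- structure(list(maps = maps, seed = 1L), class = "initial_maps")
  hyper <- spfm_hyperpriors(n_modes)
  group <- init_group_model(init, hyper)
  subject <- init_subject(init, group, n_runs = 1,
                          n_timepoints = n_timepoints)
  A <- matrix(rnorm(n_modes * n_timepoints), n_modes)
  data <- list(scale(t(scale(t(maps %*% A +
                                 0.4 * matrix(rnorm(n_voxels * n_timepoints),
                                              n_voxels))))))
  tp <- temporal_prior(n_timepoints, tr = 0.72)
  list(group = group, subject = subject, data = data, tp = tp,
       true_A = A, maps = maps)
}

# Sparse independent sources with a known mixing, as a spatial basis.
known_mixing_basis <- function(n_voxels = 1500, n_modes = 5,
                               n_components = 10, seed = 3) {
  set.seed(seed)
  S <- matrix(0, n_voxels, n_modes)
  for (m in seq_len(n_modes)) {
    idx <- sample(n_voxels, 120)
    S[idx, m] <- rgamma(120, 3, 1)
  }
  A <- matrix(rnorm(n_components * n_modes), n_components, n_modes)
  X <- S %*% t(A)
  sv <- svd(X)
  k <- min(n_components, ncol(sv$u))
  basis <- structure(list(basis = sv$u[, 1:k, drop = FALSE],
                          singular_values = sv$d[1:k], n_visited = 1),
                     class = "spatial_basis")
  list(basis = basis, sources = S, mixing = A)
}
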