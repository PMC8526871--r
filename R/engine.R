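#' Stochastic inference configuration
#'
#' Controls of the stochastic variational optimiser. The defaults mirror
#' the reference large-cohort analysis: batches of 50 subjects, delay
#' tau = 5, forget rate beta = 0.6, 10 initial (subject-only) and 20 full
#' (joint) updates per batch.
#'
#' @param batch_size Subjects per batch (K).
#' @param n_batches Number of batches (N); also the factor scaling batch
#'   sufficient statistics to population size.
#' @param tau Delay parameter of the step-size schedule (> 0).
#' @param beta Forget rate, in (0.5, 1].
#' @param n_initial_updates Subject-only sweeps per batch with the group
#'   frozen.
#' @param n_full_updates Joint subject+group sweeps per batch.
#' @param n_final_updates Subject-only sweeps in the final alignment pass.
#' @param seed Integer seed for batch randomisation.
#' @return A list of class `stochastic_config`.
#' @export
stochastic_config <- function(batch_size = 50, n_batches = 250, tau = 5,
                              beta = 0.6, n_initial_updates = 10,
                              n_full_updates = 20, n_final_updates = NULL,
                              seed = 1L) {
  if (beta <= 0.5 || beta > 1)
    stop("beta must lie in (0.5, 1]")
  if (tau <= 0) stop("tau must be positive")
  structure(list(batch_size = as.integer(batch_size),
                 n_batches = as.integer(n_batches),
                 tau = tau, beta = beta,
                 n_initial_updates = as.integer(n_initial_updates),
                 n_full_updates = as.integer(n_full_updates),
                 n_final_updates = as.integer(n_final_updates %||%
                                                max(2L, n_initial_updates %/% 2L)),
                 seed = as.integer(seed)),
            class = "stochastic_config")
}

#' Stochastic step size
#'
#' The decreasing step size `rho_t = (t + tau)^(-beta)` of the stochastic
#' gradient schedule; `tau` delays the decay and larger `beta` forgets the
#' current batch faster.
#'
#' @param t Batch index (>= 1).
#' @param tau Delay parameter (> 0).
#' @param beta Forget rate in (0.5, 1].
#' @return `rho_t` in (0, 1).
#' @export
step_size <- function(t, tau = 5, beta = 0.6) {
  if (beta <= 0.5 || beta > 1)
    stop("beta must lie in (0.5, 1]")
  if (tau <= 0) stop("tau must be positive")
  stopifnot(all(t >= 1))
  (t + tau)^(-beta)
}

#' Create a subject visit ledger
#'
#' @param n_subjects Number of subjects.
#' @return A list of class `visit_ledger` with per-subject visit counts and
#'   the batch membership history.
#' @export
visit_ledger <- function(n_subjects) {
  structure(list(counts = integer(n_subjects), history = list()),
            class = "visit_ledger")
}

#' Sample a subject batch with visit-weighted probabilities
#'
#' Draws `k` distinct subjects without replacement with probability weights
#' `1 / (1 + n_i)`, strictly decreasing in the visit count, so that every
#' subject is likely to be selected several times over the inference.
#'
#' @param ledger A [visit_ledger()].
#' @param k Batch size (at most the number of subjects).
#' @return List with the sampled `batch` (integer vector) and the updated
#'   `ledger`.
#' @export
sample_batch <- function(ledger, k) {
  n <- length(ledger$counts)
  stopifnot(k <= n)
  w <- 1 / (1 + ledger$counts)
  batch <- sort(sample.int(n, k, prob = w))
  ledger$counts[batch] <- ledger$counts[batch] + 1L
  ledger$history[[length(ledger$history) + 1]] <- batch
  list(batch = batch, ledger = ledger)
}

#' Blend global parameters in natural-parameter space
#'
#' The stochastic global update `theta_t = (1 - rho) * theta_prev +
#' rho * theta_hat`, applied as a convex combination of the natural
#' parameters of every group factor (precision-weighted for Gaussians,
#' pseudo-count-wise for Beta/Gamma, inverse-scale-wise for the Wishart).
#'
#' @param theta_prev,theta_hat `spfm_group` states with identical shapes.
#' @param rho Step size in \[0, 1\].
#' @return The blended `spfm_group`.
#' @export
blend_global <- function(theta_prev, theta_hat, rho) {
  stopifnot(theta_prev$n_modes == theta_hat$n_modes,
            theta_prev$n_voxels == theta_hat$n_voxels)
  if (rho == 0) return(theta_prev)
  if (rho == 1) return(theta_hat)
  a <- group_to_nat(theta_prev)
  b <- group_to_nat(theta_hat)
  mixed <- Map(function(x, y) (1 - rho) * x + rho * y, a, b)
  nat_to_group(mixed, theta_prev)
}

#' Run one batch of stochastic variational updates
#'
#' First-visit subjects are initialised from the initial maps; revisited
#' subjects resume their stored posteriors. The batch then receives
#' `n_initial_updates` subject-only sweeps with the group frozen, followed
#' by `n_full_updates` joint sweeps in which the intermediate group model
#' (theta-hat) is re-accumulated from the batch with the population scale
#' factor N after every sweep.
#'
#' @param subjects List (length = batch size) of `spfm_subject` or `NULL`
#'   for first visits.
#' @param group Current `spfm_group`.
#' @param data List (per batch subject) of lists (per run) of data
#'   matrices.
#' @param init Initial maps for first-visit subjects.
#' @param config A [stochastic_config()].
#' @param tp A [temporal_prior()].
#' @param scale_factor Population scale N applied to batch statistics.
#' @return List with updated `subjects` and the intermediate group model
#'   `theta_hat`.
#' @export
run_batch <- function(subjects, group, data, init, config, tp,
                      scale_factor) {
  if (length(subjects) == 0) stop("empty batch")
  for (i in seq_along(subjects)) {
    if (is.null(subjects[[i]]))
      subjects[[i]] <- init_subject(init, group, length(data[[i]]),
                                    ncol(data[[i]][[1]]))
    subjects[[i]]$n_visits <- subjects[[i]]$n_visits + 1L
  }
  for (sweep in seq_len(config$n_initial_updates)) {
    for (i in seq_along(subjects))
      subjects[[i]] <- subject_sweep(subjects[[i]], group, data[[i]], tp)
  }
  theta_hat <- group
  for (sweep in seq_len(config$n_full_updates)) {
    for (i in seq_along(subjects))
      subjects[[i]] <- subject_sweep(subjects[[i]], theta_hat, data[[i]], tp)
    theta_hat <- accumulate_and_update_group(subjects, theta_hat,
                                             scale_factor)
  }
  list(subjects = subjects, theta_hat = theta_hat)
}

#' Final subject alignment pass
#'
#' Revisits every subject once against the frozen final group model
#' (subject factors only), so that all posteriors refer to the same group
#' model regardless of when each subject was last visited. At convergence
#' the pass is idempotent.
#'
#' @param subjects List of `spfm_subject` (or `NULL` for never-visited
#'   subjects).
#' @param group The final `spfm_group`.
#' @param data List (per subject) of lists (per run) of data matrices.
#' @param init Initial maps for never-visited subjects.
#' @param config A [stochastic_config()].
#' @param tp A [temporal_prior()].
#' @return List with `subjects` and `pass_log` (one row per subject).
#' @export
final_pass <- function(subjects, group, data, init, config, tp) {
  log_ids <- integer(0)
  for (i in seq_along(subjects)) {
    if (is.null(subjects[[i]]))
      subjects[[i]] <- init_subject(init, group, length(data[[i]]),
                                    ncol(data[[i]][[1]]))
    for (sweep in seq_len(config$n_final_updates))
      subjects[[i]] <- subject_sweep(subjects[[i]], group, data[[i]], tp)
    log_ids <- c(log_ids, i)
  }
  list(subjects = subjects, pass_log = log_ids)
}

#' Fit the hierarchical mode model with stochastic variational Bayes
#'
#' Full orchestration: weighted batch sampling, per-batch subject and group
#' updates, natural-parameter blending with the decreasing step size, and
#' the final subject alignment pass. Logs the batch free energy (scaled to
#' population size), the step size, and the change in group maps and group
#' precision per batch as convergence monitors.
#'
#' @param datasets List (per subject) of lists (per run) of
#'   [masked_dataset()] objects or plain data matrices. Matrices are used
#'   as-is; datasets are preprocessed with [preprocess()].
#' @param init An `initial_maps` object from [spatial_ica_init()].
#' @param config A [stochastic_config()].
#' @param tr Repetition time in seconds (for the HRF temporal prior).
#' @param hyper Optional [spfm_hyperpriors()] override.
#' @param hrf_prior_weight Weight of the HRF autocorrelation in the
#'   temporal prior covariance, in \[0, 1\].
#' @param store Keep subject posteriors `"memory"` (default) or on
#'   `"disk"` (one RDS file per subject under `store_dir`, loaded only
#'   while the subject is in a batch — the memory contract for very large
#'   cohorts).
#' @param store_dir Directory for `store = "disk"`.
#' @param verbose Print per-batch progress.
#' @return An object of class `spfm_fit` with the final `group`,
#'   per-subject posteriors, the visit ledger and a per-batch `history`
#'   tibble.
#' @export
spfm_fit <- function(datasets, init, config = stochastic_config(),
                     tr = 0.72, hyper = NULL, hrf_prior_weight = 0.5,
                     store = c("memory", "disk"), store_dir = NULL,
                     verbose = FALSE) {
  store <- match.arg(store)
  n_subj <- length(datasets)
  data <- lapply(datasets, function(runs) lapply(runs, function(ds) {
    if (inherits(ds, "masked_dataset")) preprocess(ds)$data else
      as.matrix(ds)
  }))
  nt <- ncol(data[[1]][[1]])
  nm <- ncol(init$maps)
  hyper <- hyper %||% spfm_hyperpriors(nm)
  tp <- temporal_prior(nt, tr, hrf_prior_weight)
  group <- init_group_model(init, hyper)

  if (store == "disk") {
    store_dir <- store_dir %||% tempfile("spfm_subjects_")
    dir.create(store_dir, showWarnings = FALSE, recursive = TRUE)
  }
  subj_env <- new.env(parent = emptyenv())
  get_subj <- function(i) {
    key <- as.character(i)
    if (store == "memory") {
      if (is.null(subj_env[[key]])) NULL else subj_env[[key]]
    } else {
      f <- file.path(store_dir, paste0("subject_", i, ".rds"))
      if (file.exists(f)) readRDS(f) else NULL
    }
  }
  put_subj <- function(i, s) {
    key <- as.character(i)
    if (store == "memory") assign(key, s, envir = subj_env) else
      saveRDS(s, file.path(store_dir, paste0("subject_", i, ".rds")))
  }

  ledger <- visit_ledger(n_subj)
  history <- list()
  prev_maps <- expected_group_maps(group)
  prev_prec <- group$Rg_eta * group$Rg_Phi

  with_seed(config$seed, {
    for (t in seq_len(config$n_batches)) {
      sb <- sample_batch(ledger, config$batch_size)
      ledger <- sb$ledger
      batch <- sb$batch
      res <- run_batch(lapply(batch, get_subj), group,
                       data[batch], init, config, tp,
                       scale_factor = config$n_batches)
      rho <- step_size(t, config$tau, config$beta)
      group <- blend_global(group, res$theta_hat, rho)
      for (j in seq_along(batch)) put_subj(batch[j], res$subjects[[j]])

      fe <- free_energy(group, res$subjects, data[batch], tp,
                        n_batches = config$n_batches)
      new_maps <- expected_group_maps(group)
      new_prec <- group$Rg_eta * group$Rg_Phi
      history[[t]] <- tibble::tibble(
        batch = t, rho = rho, free_energy = fe$total,
        group_map_delta = sqrt(mean((new_maps - prev_maps)^2)),
        precision_delta = sqrt(mean((new_prec - prev_prec)^2)))
      prev_maps <- new_maps; prev_prec <- new_prec
      if (verbose)
        message(sprintf("batch %d/%d rho=%.4f F=%.1f", t,
                        config$n_batches, rho, fe$total))
    }

    fp <- final_pass(lapply(seq_len(n_subj), get_subj), group, data,
                     init, config, tp)
    for (i in seq_len(n_subj)) put_subj(i, fp$subjects[[i]])
  })

  subjects <- lapply(seq_len(n_subj), get_subj)
  structure(list(group = group, subjects = subjects,
                 history = do.call(rbind, history),
                 ledger = ledger, config = config, init = init,
                 tr = tr, tp = tp,
                 data_dims = c(n_voxels = nrow(data[[1]][[1]]),
                               n_timepoints = nt, n_modes = nm,
                               n_subjects = n_subj)),
            class = "spfm_fit")
}

#' @export
print.spfm_fit <- function(x, ...) {
  d <- x$data_dims
  cat(sprintf("spfm_fit: %d modes, %d subjects (%d voxels x %d timepoints)\n",
              d["n_modes"], d["n_subjects"], d["n_voxels"],
              d["n_timepoints"]))
  cat(sprintf("  %d batches of %d, beta=%.2f tau=%.1f\n",
              x$config$n_batches, x$config$batch_size, x$config$beta,
              x$config$tau))
  cat(sprintf("  final free energy (last batch estimate): %.1f\n",
              x$history$free_energy[nrow(x$history)]))
  invisible(x)
}

#' Point summaries of a fitted model
#'
#' `fitted_group_maps` returns the membership-weighted group signal means;
#' `fitted_subject_maps` the per-subject expected maps;
#' `fitted_timecourses` the posterior mean timecourses;
#' `fitted_amplitudes` the posterior mean amplitudes per subject-run.
#'
#' @param fit An `spfm_fit`.
#' @return A matrix or list of matrices/vectors.
#' @export
fitted_group_maps <- function(fit) expected_group_maps(fit$group)

#' @rdname fitted_group_maps
#' @export
fitted_subject_maps <- function(fit) lapply(fit$subjects, expected_maps)

#' @rdname fitted_group_maps
#' @export
fitted_timecourses <- function(fit)
  lapply(fit$subjects, function(s) lapply(s$runs, `[[`, "A_mean"))

#' @rdname fitted_group_maps
#' @export
fitted_amplitudes <- function(fit)
  lapply(fit$subjects, function(s)
    lapply(s$runs, function(r) exp(r$g_mean + r$g_var / 2)))
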