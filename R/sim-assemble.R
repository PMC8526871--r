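#' Assemble data matrices from ground-truth components
#'
#' Builds each subject-run data matrix as the outer-product model
#' `D = P %*% diag(h) %*% A + E`, where `P` is the subject map matrix, `h`
#' the run amplitudes, `A` the BOLD timecourses and `E` i.i.d. Gaussian
#' noise scaled so that `var(signal) / var(noise)` equals `noise_snr`
#' (`Inf` for noiseless data).
#'
#' @param subject_maps List (per subject) of `n_voxels x n_modes` matrices.
#' @param amplitudes List (per subject) of lists (per run) of positive
#'   length-`n_modes` vectors.
#' @param bold_timecourses List (per subject) of lists (per run) of
#'   `n_modes x n_timepoints` matrices.
#' @param noise_snr Signal-to-noise variance ratio.
#' @param seed Integer seed for the noise draws.
#' @return List (per subject) of lists (per run) of data matrices, with the
#'   realised noise standard deviations as attribute `noise_sd`.
#' @export
assemble_dataset <- function(subject_maps, amplitudes, bold_timecourses,
                             noise_snr = Inf, seed = 1L) {
  ns <- length(subject_maps)
  stopifnot(length(amplitudes) == ns, length(bold_timecourses) == ns)
  with_seed(seed, {
    noise_sds <- list()
    data <- lapply(seq_len(ns), function(s) {
      lapply(seq_along(bold_timecourses[[s]]), function(r) {
        h <- amplitudes[[s]][[r]]
        A <- bold_timecourses[[s]][[r]]
        stopifnot(length(h) == nrow(A),
                  ncol(subject_maps[[s]]) == length(h))
        signal <- subject_maps[[s]] %*% (h * A)
        if (is.finite(noise_snr)) {
          sd_n <- sqrt(stats::var(as.numeric(signal)) / noise_snr)
          signal + matrix(stats::rnorm(length(signal), sd = sd_n),
                          nrow(signal), ncol(signal)) |>
            structure(noise_sd = sd_n)
        } else structure(signal, noise_sd = 0)
      })
    })
    data
  })
}

#' Simulate a full multi-subject study with ground truth
#'
#' End-to-end simulator: group maps, warped subject maps (identical across a
#' subject's runs), hierarchically Wishart-correlated HRF-convolved
#' timecourses, log-normal amplitudes, and additive Gaussian noise at the
#' configured SNR.
#'
#' @param config An [sim_config()] object.
#' @return An object of class `spfm_truth` with elements `group_maps`,
#'   `subject_maps`, `amplitudes`, `neural_timecourses`, `bold_timecourses`,
#'   `group_precision`, `subject_precisions`, `data`, `overlap` (per-subject
#'   per-mode retained support fraction) and `config`.
#' @export
simulate_study <- function(config) {
  validate_sim_config(config)
  nm <- config$n_modes
  group_maps <- make_group_maps(config)

  group_precision <- with_seed(child_seed(config$seed, "group_precision"), {
    # moderate, structured between-mode partial correlations
    ensure_spd(stats::rWishart(1, nm + 10, diag(nm) / (nm + 10))[, , 1])
  })

  subject_maps <- lapply(seq_len(config$n_subjects), function(s) {
    make_subject_maps(
      group_maps,
      warp_scale = config$warp_scale,
      warp_frac = if (is.null(config$warp_scale)) config$target_misalignment,
      noise_sd = config$map_noise_sd * config$gamma_shape * config$gamma_scale,
      seed = child_seed(config$seed, paste0("subject_maps", s))
    )
  })

  tcs <- make_timecourses(config, group_precision)
  amplitudes <- with_seed(child_seed(config$seed, "amplitudes"), {
    lapply(seq_len(config$n_subjects), function(s)
      lapply(seq_len(config$n_runs), function(r)
        exp(stats::rnorm(nm, 0, config$amplitude_log_sd))))
  })

  bold <- lapply(tcs, function(s) lapply(s$runs, `[[`, "bold"))
  neural <- lapply(tcs, function(s) lapply(s$runs, `[[`, "neural"))
  data <- assemble_dataset(subject_maps, amplitudes, bold,
                           noise_snr = config$noise_snr,
                           seed = child_seed(config$seed, "noise"))

  structure(list(
    group_maps = group_maps,
    subject_maps = subject_maps,
    amplitudes = amplitudes,
    neural_timecourses = neural,
    bold_timecourses = bold,
    group_precision = group_precision,
    subject_precisions = lapply(tcs, `[[`, "precision"),
    data = data,
    overlap = lapply(subject_maps, attr, "overlap"),
    config = config
  ), class = "spfm_truth")
}

#' @export
print.spfm_truth <- function(x, ...) {
  cfg <- x$config
  cat("Simulated functional-mode study\n")
  cat(sprintf("  %d subjects x %d runs, %d voxels x %d timepoints (TR %.2fs)\n",
              cfg$n_subjects, cfg$n_runs, cfg$n_voxels, cfg$n_timepoints,
              cfg$tr))
  cat(sprintf("  %d modes, %.2f modes per active voxel, mean subject-group overlap %.1f%%\n",
              cfg$n_modes, attr(x$group_maps, "modes_per_voxel"),
              100 * mean(unlist(x$overlap), na.rm = TRUE)))
  invisible(x)
}

#' Convert one simulated subject-run to a masked dataset
#'
#' @param truth An `spfm_truth` bundle.
#' @param subject,run Indices.
#' @return A [masked_dataset()].
#' @export
truth_dataset <- function(truth, subject, run) {
  masked_dataset(truth$data[[subject]][[run]],
                 tr = truth$config$tr,
                 subject_id = paste0("sub", subject),
                 run_id = paste0("run", run))
}
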