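#' Dual regression of group maps onto one subject-run
#'
#' Stage 1 regresses the group maps against the data to give subject
#' timecourses; stage 2 regresses the variance-normalised timecourses
#' against the data to give subject spatial maps. Mode amplitudes are the
#' standard deviations of the unnormalised stage-1 timecourses. No
#' intercepts are used: data are demeaned upstream by [preprocess()].
#'
#' @param group_maps `n_voxels x n_modes` matrix (spatial ICA output).
#' @param ds A [masked_dataset()] on the same mask.
#' @return An object of class `dual_regression`: list with
#'   `timecourses` (`n_modes x n_timepoints`), `maps`
#'   (`n_voxels x n_modes`), `amplitudes` (positive length-`n_modes`).
#' @export
dual_regression <- function(group_maps, ds) {
  d <- if (inherits(ds, "masked_dataset")) ds$data else as.matrix(ds)
  stopifnot(nrow(group_maps) == nrow(d))
  qrg <- qr(group_maps)
  if (qrg$rank < ncol(group_maps)) {
    dropped <- setdiff(seq_len(ncol(group_maps)),
                       sort(qrg$pivot[seq_len(qrg$rank)]))
    stop("group maps are rank deficient; collinear modes: ",
         paste(dropped, collapse = ", "))
  }
  tc <- qr.coef(qrg, d)                       # stage 1
  amplitudes <- apply(tc, 1, stats::sd)
  tc_n <- tc / pmax(amplitudes, 1e-12)
  maps <- t(qr.coef(qr(t(tc_n)), t(d)))       # stage 2
  structure(list(timecourses = tc, maps = maps,
                 amplitudes = pmax(amplitudes, .Machine$double.eps)),
            class = "dual_regression")
}

#' Tikhonov-regularised partial correlation NetMat
#'
#' Inverts `cov + rho * mean(diag(cov)) * I` and converts the regularised
#' precision to partial correlations with unit diagonal. The identity is
#' scaled by the mean variance so the regularisation is invariant to the
#' overall data scale.
#'
#' @param timecourses `n_modes x n_timepoints` matrix.
#' @param rho Ridge parameter (default 0.01).
#' @return Symmetric partial-correlation matrix with unit diagonal, entries
#'   in \[-1, 1\]. Constant rows are reported in attribute
#'   `flagged_modes`.
#' @export
partial_netmat <- function(timecourses, rho = 0.01) {
  stopifnot(ncol(timecourses) > 1)
  flagged <- which(apply(timecourses, 1, stats::sd) == 0)
  cv <- stats::cov(t(timecourses))
  prec <- chol2inv(chol(cv + rho * mean(diag(cv)) * diag(nrow(cv))))
  structure(precision_to_partial(prec), flagged_modes = flagged)
}

#' Run the full ICA + dual-regression baseline
#'
#' Group spatial ICA on the MIGP basis, dual regression onto every
#' subject-run, amplitudes, and Tikhonov partial-correlation NetMats.
#' Subject maps are averaged over a subject's runs (stage-2 maps are
#' estimated per run; the spatial layout is assumed run-stable).
#'
#' @param basis A `spatial_basis` from [migp()].
#' @param datasets List (per subject) of lists (per run) of
#'   [masked_dataset()] objects (or plain matrices).
#' @param n_modes Number of modes.
#' @param rho Tikhonov parameter for the partial NetMats.
#' @param seed Passed to the ICA.
#' @return An object of class `icadr_fit`: list with `group_maps`,
#'   per-subject `maps`, per-subject-run `timecourses`, `amplitudes`,
#'   `netmats`.
#' @export
icadr_pipeline <- function(basis, datasets, n_modes, rho = 0.01, seed = 1L) {
  gmaps <- group_spatial_ica(basis, n_modes, seed = seed)
  subj <- lapply(datasets, function(runs) {
    drs <- lapply(runs, function(ds) dual_regression(gmaps, ds))
    maps <- Reduce(`+`, lapply(drs, `[[`, "maps")) / length(drs)
    list(maps = maps,
         timecourses = lapply(drs, `[[`, "timecourses"),
         amplitudes = lapply(drs, `[[`, "amplitudes"),
         netmats = lapply(drs, function(d) partial_netmat(d$timecourses,
                                                          rho = rho)))
  })
  structure(list(group_maps = gmaps,
                 maps = lapply(subj, `[[`, "maps"),
                 timecourses = lapply(subj, `[[`, "timecourses"),
                 amplitudes = lapply(subj, `[[`, "amplitudes"),
                 netmats = lapply(subj, `[[`, "netmats")),
            class = "icadr_fit")
}
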