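#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the convergence history of a fit
#'
#' @param x An `spfm_fit`.
#' @param ... Unused.
#' @return The per-batch history tibble (`batch`, `rho`, `free_energy`,
#'   `group_map_delta`, `precision_delta`).
#' @export
tidy.spfm_fit <- function(x, ...) x$history

#' One-row summary of a fit
#'
#' @param x An `spfm_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the model dimensions, stochastic
#'   parameters and final batch free energy.
#' @export
glance.spfm_fit <- function(x, ...) {
  d <- x$data_dims
  tibble::tibble(n_modes = unname(d["n_modes"]),
                 n_subjects = unname(d["n_subjects"]),
                 n_voxels = unname(d["n_voxels"]),
                 n_timepoints = unname(d["n_timepoints"]),
                 batch_size = x$config$batch_size,
                 n_batches = x$config$n_batches,
                 beta = x$config$beta, tau = x$config$tau,
                 free_energy = x$history$free_energy[nrow(x$history)])
}

#' Tidy an accuracy report
#'
#' @param x An `accuracy_report`.
#' @param ... Unused.
#' @return The long per-mode correlation tibble.
#' @export
tidy.accuracy_report <- function(x, ...) x$correlations

#' @export
glance.accuracy_report <- function(x, ...) {
  tibble::tibble(group_map_corr = x$group_map_corr,
                 subject_map_corr = x$subject_map_corr,
                 subject_timecourse_corr = x$subject_timecourse_corr,
                 n_missing = x$n_missing)
}

#' Plot the convergence monitors of a fit
#'
#' Free energy, group-map change and group-precision change per batch.
#'
#' @param object An `spfm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spfm_fit <- function(object, ...) {
  h <- object$history
  long <- rbind(
    tibble::tibble(batch = h$batch, metric = "free energy",
                   value = h$free_energy),
    tibble::tibble(batch = h$batch, metric = "group map delta",
                   value = h$group_map_delta),
    tibble::tibble(batch = h$batch, metric = "precision delta",
                   value = h$precision_delta))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$batch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "batch", y = NULL,
                  title = "Stochastic inference convergence") +
    ggplot2::theme_minimal()
}

#' Plot per-element accuracies
#'
#' @param object An `accuracy_report`.
#' @param ... Unused.
#' @return A ggplot object (per-mode correlation distributions by element).
#' @export
autoplot.accuracy_report <- function(object, ...) {
  d <- object$correlations
  ggplot2::ggplot(d, ggplot2::aes(x = .data$element,
                                  y = .data$correlation)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::ylim(min(0, min(d$correlation, na.rm = TRUE)), 1) +
    ggplot2::labs(x = NULL, y = "correlation with ground truth") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
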