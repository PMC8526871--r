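#' Pair estimated modes with reference modes
#'
#' Solves the assignment problem maximising the total absolute spatial
#' correlation between estimated and reference maps (maximum-weight
#' bipartite matching), fixes signs so paired correlations are positive, and
#' flags one-to-one matches: a pair is one-to-one when its absolute
#' correlation exceeds 0.7 and is at least two standard deviations above the
#' next-best correlation for that estimated mode.
#'
#' @param est_maps,ref_maps `n_voxels x k` matrices on the same voxel
#'   space; mode counts may differ (rectangular assignment).
#' @param r_threshold One-to-one correlation threshold.
#' @return An object of class `mode_pairing`: tibble with one row per
#'   paired estimated mode (`est`, `ref`, `sign`, `correlation`,
#'   `one_to_one`), plus the full correlation matrix as attribute
#'   `cor_matrix`.
#' @export
pair_modes <- function(est_maps, ref_maps, r_threshold = 0.7) {
  stopifnot(nrow(est_maps) == nrow(ref_maps))
  ne <- ncol(est_maps); nr <- ncol(ref_maps)
  cm <- suppressWarnings(stats::cor(est_maps, ref_maps))
  zero_var <- which(!is.finite(rowSums(cm)))
  cm[!is.finite(cm)] <- 0
  acm <- abs(cm)

  # maximum-weight bipartite matching on |correlation| (+1 keeps weights > 0)
  edges <- as.vector(t(cbind(rep(seq_len(ne), each = nr),
                             ne + rep(seq_len(nr), times = ne))))
  g <- igraph::make_bipartite_graph(c(rep(FALSE, ne), rep(TRUE, nr)), edges)
  m <- igraph::max_bipartite_match(g, weights = as.vector(t(acm)) + 1)
  match_vec <- m$matching[seq_len(ne)] - ne

  rows <- lapply(seq_len(ne), function(i) {
    j <- match_vec[i]
    if (is.na(j) || j < 1) return(NULL)
    r <- cm[i, j]
    others <- acm[i, -j]
    one2one <- abs(r) > r_threshold &&
      (length(others) == 0 ||
         abs(r) >= max(others) + 2 * stats::sd(acm[i, ]))
    tibble::tibble(est = i, ref = j,
                   sign = ifelse(r < 0, -1, 1),
                   correlation = abs(r),
                   one_to_one = one2one)
  })
  out <- do.call(rbind, rows)
  structure(out, cor_matrix = cm, zero_variance = zero_var,
            class = c("mode_pairing", class(out)))
}

# Reorder/sign-flip estimated maps to the reference layout; unmatched
# reference modes become zero columns.
apply_pairing <- function(est_maps, pairing, n_ref) {
  out <- matrix(0, nrow(est_maps), n_ref)
  for (k in seq_len(nrow(pairing)))
    out[, pairing$ref[k]] <- pairing$sign[k] * est_maps[, pairing$est[k]]
  out
}

#' Accuracy of estimates against simulator ground truth
#'
#' Pairs modes on the group maps, then computes Pearson correlations between
#' ground truth and estimates for: group maps (per mode), subject maps (per
#' subject-mode) and subject timecourses (per subject-run-mode). Estimated
#' modes with zero variance count as missing and are excluded from means.
#' Per-mode correlations are averaged within subjects first, then across
#' subjects.
#'
#' @param truth An `spfm_truth` bundle.
#' @param group_maps Estimated group maps (`n_voxels x n_modes`).
#' @param subject_maps Optional list of estimated subject map matrices.
#' @param timecourses Optional list (per subject) of lists (per run) of
#'   `n_modes x n_timepoints` estimated timecourses.
#' @return An object of class `accuracy_report`: list with the pairing, the
#'   per-mode correlation tibble and named means `group_map_corr`,
#'   `subject_map_corr`, `subject_timecourse_corr`.
#' @export
accuracy_report <- function(truth, group_maps, subject_maps = NULL,
                            timecourses = NULL) {
  pairing <- pair_modes(group_maps, unclass(truth$group_maps))
  nm <- ncol(truth$group_maps)
  g_paired <- apply_pairing(group_maps, pairing, nm)
  g_corr <- colwise_cor(g_paired, unclass(truth$group_maps))
  missing <- which(colSums(abs(g_paired)) == 0 | !is.finite(g_corr))

  rows <- tibble::tibble(element = "group_map",
                         subject = NA_integer_, run = NA_integer_,
                         mode = seq_len(nm), correlation = g_corr)

  if (!is.null(subject_maps)) {
    for (s in seq_along(subject_maps)) {
      sp <- apply_pairing(subject_maps[[s]], pairing, nm)
      sc <- colwise_cor(sp, truth$subject_maps[[s]])
      sc[colSums(abs(sp)) == 0] <- NA_real_
      rows <- rbind(rows, tibble::tibble(element = "subject_map",
                                         subject = s, run = NA_integer_,
                                         mode = seq_len(nm),
                                         correlation = sc))
    }
  }
  if (!is.null(timecourses)) {
    for (s in seq_along(timecourses)) {
      for (r in seq_along(timecourses[[s]])) {
        tc <- timecourses[[s]][[r]]
        tcp <- apply_pairing(t(tc), pairing, nm)
        cc <- colwise_cor(tcp, t(truth$bold_timecourses[[s]][[r]]))
        cc[colSums(abs(tcp)) == 0] <- NA_real_
        rows <- rbind(rows, tibble::tibble(element = "subject_timecourse",
                                           subject = s, run = r,
                                           mode = seq_len(nm),
                                           correlation = cc))
      }
    }
  }

  mean_by <- function(el) {
    d <- rows[rows$element == el, ]
    if (nrow(d) == 0) return(NA_real_)
    if (all(is.na(d$subject))) return(mean(d$correlation, na.rm = TRUE))
    # average over modes within subject first, then across subjects
    per_subj <- tapply(d$correlation, d$subject,
                       function(v) mean(v, na.rm = TRUE))
    mean(per_subj, na.rm = TRUE)
  }
  structure(list(pairing = pairing, correlations = rows,
                 missing_modes = missing, n_missing = length(missing),
                 group_map_corr = mean_by("group_map"),
                 subject_map_corr = mean_by("subject_map"),
                 subject_timecourse_corr = mean_by("subject_timecourse")),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("accuracy_report (correlation with ground truth)\n")
  cat(sprintf("  group maps:          %.3f\n", x$group_map_corr))
  if (!is.na(x$subject_map_corr))
    cat(sprintf("  subject maps:        %.3f\n", x$subject_map_corr))
  if (!is.na(x$subject_timecourse_corr))
    cat(sprintf("  subject timecourses: %.3f\n", x$subject_timecourse_corr))
  if (x$n_missing > 0)
    cat(sprintf("  missing modes: %d\n", x$n_missing))
  invisible(x)
}

#' Spatial NetMat: cross-mode correlations of spatial maps
#'
#' @param maps `n_voxels x n_modes` matrix (at least two modes).
#' @param fisher_z Apply the Fisher r-to-Z transform (`atanh`) to
#'   off-diagonal entries, for feature export.
#' @return Symmetric `n_modes x n_modes` matrix; unit diagonal when
#'   `fisher_z = FALSE`. Zero-variance maps are reported in attribute
#'   `flagged_modes`.
#' @export
spatial_netmat <- function(maps, fisher_z = FALSE) {
  stopifnot(ncol(maps) >= 2)
  flagged <- which(apply(maps, 2, stats::sd) == 0)
  cm <- suppressWarnings(stats::cor(maps))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 1
  if (fisher_z) {
    z <- atanh(pmin(pmax(cm, -0.999999), 0.999999))
    diag(z) <- 0
    cm <- z
  }
  structure(cm, flagged_modes = flagged)
}

#' Subject-to-subject and subject-to-group consistency
#'
#' S2S is the mean pairwise cross-subject correlation of a model element;
#' S2G is the mean correlation of each subject's element with the group
#' element. Computed for whichever elements are supplied (maps, spatial
#' NetMats, temporal NetMats, amplitudes), each flattened to a vector
#' (upper triangle for symmetric matrices).
#'
#' @param subject_elements Named list; each entry is a list over subjects of
#'   matrices or vectors for one element type.
#' @param group_elements Named list with the matching group-level element
#'   (optional entries).
#' @return A tibble with columns `element`, `s2s`, `s2g`.
#' @export
consistency <- function(subject_elements, group_elements = list()) {
  stopifnot(length(subject_elements) >= 1)
  flatten <- function(x) {
    if (is.matrix(x) && nrow(x) == ncol(x) && isSymmetric(unname(x)))
      x[upper.tri(x)] else as.numeric(x)
  }
  rows <- lapply(names(subject_elements), function(nm) {
    xs <- lapply(subject_elements[[nm]], flatten)
    stopifnot(length(xs) >= 2)
    mat <- do.call(cbind, xs)
    cc <- suppressWarnings(stats::cor(mat))
    s2s <- mean(cc[upper.tri(cc)], na.rm = TRUE)
    s2g <- NA_real_
    if (!is.null(group_elements[[nm]])) {
      gv <- flatten(group_elements[[nm]])
      s2g <- mean(suppressWarnings(apply(mat, 2, stats::cor, y = gv)),
                  na.rm = TRUE)
    }
    tibble::tibble(element = nm, s2s = s2s, s2g = s2g)
  })
  do.call(rbind, rows)
}

#' Long-format accuracy table across scenarios and methods
#'
#' Aggregates [accuracy_report()] objects into a tidy table of means and
#' standard deviations per scenario, method and model element.
#'
#' @param reports Named list (scenario) of named lists (method) of
#'   `accuracy_report` objects.
#' @param file Optional CSV output path.
#' @return A tibble with columns `scenario`, `method`, `element`, `mean`,
#'   `sd`.
#' @export
accuracy_tables <- function(reports, file = NULL) {
  rows <- list()
  for (sc in names(reports)) {
    for (me in names(reports[[sc]])) {
      d <- reports[[sc]][[me]]$correlations
      for (el in unique(d$element)) {
        v <- d$correlation[d$element == el]
        rows[[length(rows) + 1]] <-
          tibble::tibble(scenario = sc, method = me, element = el,
                         mean = mean(v, na.rm = TRUE),
                         sd = stats::sd(v, na.rm = TRUE))
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
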