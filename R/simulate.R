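# Synthetic cohort generators. All three generators are deterministic
# functions of (design, design$seed): per-subject sub-seeds are drawn from
# independent named streams so that, e.g., adding task studies never
# perturbs the structural cohort.

subject_ids <- function(n) sprintf("sub%02d", seq_len(n))

subject_seeds <- function(design, stream, n = design$n_subjects) {
  with_seed(stream_seed(design$seed, stream), sample.int(2147483646L, n))
}

#' Generate a structural (streamline-count) cohort
#'
#' Each subject gets a directional ROI x ROI integer matrix emulating
#' probabilistic-tractography output: for each unordered ROI pair a
#' connection is present with probability `within_edge_prob` (same module)
#' or `between_edge_prob` (different modules). Present connections yield
#' high counts near `streamline_scale` in both directions (each of the
#' `streamline_scale` streamlines hits unless lost at rate
#' `lambda_noise / streamline_scale`); absent connections yield a low
#' Poisson(`lambda_noise`) noise floor. Diagonals are zero.
#'
#' @param design a [planted_design()].
#' @return list of `n_subjects` integer matrices (dimnames = ROI labels),
#'   each with a `subject_id` attribute.
#' @export
generate_structural_cohort <- function(design) {
  stopifnot(inherits(design, "planted_design"))
  labels <- unclass(design$roi_set)
  n <- length(labels)
  part <- design$true_partition
  same <- outer(part, part, "==")
  ut <- upper.tri(same)
  p_edge <- ifelse(same[ut], design$within_edge_prob, design$between_edge_prob)
  n_pairs <- length(p_edge)
  scale <- design$streamline_scale
  loss_rate <- min(1, design$lambda_noise / scale)
  seeds <- subject_seeds(design, "structural")
  ids <- subject_ids(design$n_subjects)
  cohort <- lapply(seq_len(design$n_subjects), function(s) {
    with_seed(seeds[s], {
      present <- stats::runif(n_pairs) < p_edge
      draw_dir <- function() {
        x <- integer(n_pairs)
        np <- sum(present)
        if (np > 0) x[present] <- scale - stats::rbinom(np, scale, loss_rate)
        na <- n_pairs - np
        if (na > 0) x[!present] <- pmin(stats::rpois(na, design$lambda_noise), scale)
        x
      }
      m <- matrix(0L, n, n, dimnames = list(labels, labels))
      m[upper.tri(m)] <- draw_dir()
      m <- t(m)                      # lower triangle = first direction
      m[upper.tri(m)] <- draw_dir()  # upper triangle = reverse direction
      storage.mode(m) <- "integer"
      attr(m, "subject_id") <- ids[s]
      m
    })
  })
  stats::setNames(cohort, ids)
}

#' Generate a functional (BOLD-like) cohort
#'
#' Each subject gets an ROI x time matrix following the shared-latent-signal
#' model for block-structured correlations:
#' `x_i(t) = sqrt(rho) * s_m(i)(t) + sqrt(1 - rho) * e_i(t)` with
#' independent unit-variance Gaussian module signals `s` and noise `e`, so
#' the expected correlation is `rho` within a module and 0 between modules.
#' Per-subject motion summaries (half-normal translation and rotation) are
#' attached for the censoring stage.
#'
#' @param design a [planted_design()]; requires `ts_length >= 20`.
#' @return list of `subject_ts` objects with fields `series` (ROI x time),
#'   `motion_translation_mm`, `motion_rotation_deg`, `subject_id`.
#' @export
generate_functional_cohort <- function(design) {
  stopifnot(inherits(design, "planted_design"))
  if (design$ts_length < 20L) stop("ts_length must be >= 20", call. = FALSE)
  labels <- unclass(design$roi_set)
  n <- length(labels)
  tl <- design$ts_length
  rho <- design$within_corr
  part <- design$true_partition
  seeds <- subject_seeds(design, "functional")
  mseeds <- subject_seeds(design, "motion")
  ids <- subject_ids(design$n_subjects)
  cohort <- lapply(seq_len(design$n_subjects), function(s) {
    series <- with_seed(seeds[s], {
      latent <- matrix(stats::rnorm(design$n_modules * tl), design$n_modules, tl)
      noise <- matrix(stats::rnorm(n * tl), n, tl)
      x <- sqrt(rho) * latent[part, , drop = FALSE] + sqrt(1 - rho) * noise
      dimnames(x) <- list(labels, NULL)
      x
    })
    motion <- with_seed(mseeds[s], c(
      abs(stats::rnorm(1, 0, design$motion_translation_sd)),
      abs(stats::rnorm(1, 0, design$motion_rotation_sd))
    ))
    structure(list(series = series,
                   motion_translation_mm = motion[1],
                   motion_rotation_deg = motion[2],
                   subject_id = ids[s]),
              class = "subject_ts")
  })
  stats::setNames(cohort, ids)
}

#' Generate task-contrast betas for one or more studies
#'
#' Per study and subject, ROI activity under each contrast is the ROI's
#' module profile plus Gaussian noise:
#' `b[i, c] = contrast_profiles[module(i), c] + N(0, beta_noise_sd)`.
#' The same planted partition drives all studies.
#'
#' @param design a [planted_design()].
#' @param n_studies number of task-fMRI studies to emulate (default 3).
#' @param n_subjects subjects per study (default `design$n_subjects`).
#' @return list of `contrast_betas` objects, one per study, each with
#'   `values` (subject x ROI x contrast array), `contrast_names`,
#'   `study_id` and `roi_set`.
#' @export
generate_task_betas <- function(design, n_studies = 3L, n_subjects = design$n_subjects) {
  stopifnot(inherits(design, "planted_design"))
  labels <- unclass(design$roi_set)
  n <- length(labels)
  nc <- length(design$contrast_names)
  part <- design$true_partition
  profile_by_roi <- design$contrast_profiles[part, , drop = FALSE]  # ROI x contrast
  study_seeds <- with_seed(stream_seed(design$seed, "betas"),
                           sample.int(2147483646L, n_studies))
  lapply(seq_len(n_studies), function(st) {
    values <- with_seed(study_seeds[st], {
      arr <- array(stats::rnorm(n_subjects * n * nc, sd = design$beta_noise_sd),
                   dim = c(n_subjects, n, nc),
                   dimnames = list(subject_ids(n_subjects), labels, design$contrast_names))
      sweep(arr, c(2, 3), profile_by_roi, "+")
    })
    structure(list(values = values,
                   contrast_names = design$contrast_names,
                   study_id = sprintf("study%d", st),
                   roi_set = design$roi_set),
              class = "contrast_betas")
  })
}

#' @export
print.subject_ts <- function(x, ...) {
  cat("Subject time series", x$subject_id, ":", nrow(x$series), "ROIs x",
      ncol(x$series), "volumes; motion",
      sprintf("%.2f mm / %.2f deg\n", x$motion_translation_mm, x$motion_rotation_deg))
  invisible(x)
}

#' @export
print.contrast_betas <- function(x, ...) {
  d <- dim(x$values)
  cat("Contrast betas", x$study_id, ":", d[1], "subjects x", d[2], "ROIs x",
      d[3], "contrasts (", paste(x$contrast_names, collapse = ", "), ")\n")
  invisible(x)
}
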