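#' Balanced planted partition
#'
#' Splits an ROI set into `n_modules` contiguous blocks of as-equal-as
#' possible size, labelled `1..n_modules`.
#'
#' @param rois `roi_set` (or anything `roi_set()` accepts).
#' @param n_modules number of modules.
#' @return named integer vector, ROI label -> module id.
#' @export
balanced_partition <- function(rois, n_modules = 5L) {
  rois <- roi_set(rois)
  n <- length(rois)
  n_modules <- as.integer(n_modules)
  if (n_modules < 1L || n_modules > n) stop("n_modules must be in [1, n_rois]", call. = FALSE)
  sizes <- rep(n %/% n_modules, n_modules)
  extra <- n %% n_modules
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  stats::setNames(rep(seq_len(n_modules), sizes), unclass(rois))
}

#' Evenly spread module contrast profiles
#'
#' Mean task-contrast activity per module, constructed so that every pair of
#' module profiles has correlation strictly below 1. Centered 3-contrast
#' profiles live on a 2-dimensional plane; modules are placed at equally
#' spaced angles on the unit circle of that plane, giving pairwise profile
#' correlations of `cos(2*pi*k/n_modules)`.
#'
#' @param n_modules number of modules.
#' @param n_contrasts number of task contrasts (default 3).
#' @param amplitude profile magnitude in activity units (default 1).
#' @return `n_modules x n_contrasts` matrix.
#' @export
default_contrast_profiles <- function(n_modules, n_contrasts = 3L, amplitude = 1) {
  if (n_contrasts != 3L) {
    stop("default profiles are defined for 3 contrasts; supply contrast_profiles explicitly",
         call. = FALSE)
  }
  e1 <- c(1, -1, 0) / sqrt(2)
  e2 <- c(1, 1, -2) / sqrt(6)
  theta <- 2 * pi * (seq_len(n_modules) - 1) / n_modules
  p <- amplitude * (cos(theta) %o% e1 + sin(theta) %o% e2)
  rownames(p) <- paste0("module", seq_len(n_modules))
  p
}

#' Specify a planted-partition study design
#'
#' A planted design fixes everything the synthetic generators need: the ROI
#' set, the ground-truth module assignment, cohort size, connectivity edge
#' probabilities, the streamline count scale and Poisson noise floor, BOLD
#' time-series length and within-module latent-signal loading, and the
#' module-specific task-contrast profiles. A single seed makes every
#' generated cohort reproducible.
#'
#' Defaults emulate the study conditions the pipeline targets: 43 ROIs over
#' associative cortex, 5 modules, 24 subjects, streamline counts up to
#' 20,000 with a Poisson noise floor of 2, 128 retained BOLD volumes, and
#' motion scalars calibrated so roughly 8% of subjects exceed the
#' 3 mm / 1 degree censoring rule.
#'
#' @param roi_set `roi_set` or integer ROI count.
#' @param true_partition named integer vector ROI -> module id (contiguous
#'   from 1). Default: balanced 5-module split.
#' @param n_subjects cohort size.
#' @param seed integer master seed; all generator output is a deterministic
#'   function of it.
#' @param within_edge_prob,between_edge_prob probability a within- /
#'   between-module ROI pair is structurally connected in one subject.
#' @param streamline_scale maximum streamline count per ROI pair.
#' @param lambda_noise Poisson noise-floor rate for absent connections, in
#'   streamline hits; also sets the per-streamline loss rate of present
#'   connections (so `lambda_noise = 0` gives noiseless counts).
#' @param ts_length BOLD time points per subject.
#' @param within_corr latent-signal loading rho in `[0, 1)`; expected
#'   within-module BOLD correlation.
#' @param contrast_profiles module x contrast matrix of mean activity;
#'   default [default_contrast_profiles()].
#' @param beta_noise_sd s.d. of additive Gaussian noise on task betas.
#' @param contrast_names character names of the task contrasts.
#' @param motion_translation_sd,motion_rotation_sd half-normal scale of the
#'   per-subject motion summaries (mm, degrees); set to 0 to disable motion.
#' @return object of class `planted_design`.
#' @export
#' @examples
#' d <- planted_design(roi_set = 12, true_partition = balanced_partition(roi_set(12), 3))
#' d$n_modules
planted_design <- function(roi_set = 43L,
                           true_partition = NULL,
                           n_subjects = 24L,
                           seed = 1L,
                           within_edge_prob = 0.9,
                           between_edge_prob = 0.05,
                           streamline_scale = 20000L,
                           lambda_noise = 2,
                           ts_length = 128L,
                           within_corr = 0.8,
                           contrast_profiles = NULL,
                           beta_noise_sd = 0.5,
                           contrast_names = c("semantic>control", "rest>semantic", "control>rest"),
                           motion_translation_sd = 1.5,
                           motion_rotation_sd = 0.45) {
  rois <- connsig::roi_set(roi_set)
  if (is.null(true_partition)) true_partition <- balanced_partition(rois, 5L)
  if (is.null(names(true_partition)) ||
      !setequal(names(true_partition), unclass(rois)) ||
      length(true_partition) != length(rois)) {
    stop("true_partition must assign every ROI exactly once", call. = FALSE)
  }
  true_partition <- true_partition[unclass(rois)]
  ids <- sort(unique(true_partition))
  if (!identical(as.integer(ids), seq_along(ids))) {
    stop("module ids must be contiguous integers starting at 1", call. = FALSE)
  }
  n_modules <- length(ids)
  if (streamline_scale < 1) stop("streamline_scale must be >= 1", call. = FALSE)
  if (within_corr < 0 || within_corr >= 1) {
    stop("within_corr must lie in [0, 1)", call. = FALSE)
  }
  if (within_edge_prob < 0 || within_edge_prob > 1 ||
      between_edge_prob < 0 || between_edge_prob > 1) {
    stop("edge probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (n_modules > 1 && within_edge_prob <= between_edge_prob) {
    warning("within_edge_prob <= between_edge_prob: planted structure is not recoverable")
  }
  if (beta_noise_sd < 0) stop("beta_noise_sd must be >= 0", call. = FALSE)
  if (lambda_noise < 0) stop("lambda_noise must be >= 0", call. = FALSE)
  if (is.null(contrast_profiles)) {
    contrast_profiles <- default_contrast_profiles(n_modules, length(contrast_names))
  }
  contrast_profiles <- as.matrix(contrast_profiles)
  if (nrow(contrast_profiles) != n_modules) {
    stop("contrast_profiles must have one row per module", call. = FALSE)
  }
  if (ncol(contrast_profiles) != length(contrast_names)) {
    stop("contrast_profiles must have one column per contrast", call. = FALSE)
  }
  colnames(contrast_profiles) <- contrast_names
  structure(list(
    roi_set = rois,
    true_partition = true_partition,
    n_modules = n_modules,
    n_subjects = as.integer(n_subjects),
    seed = as.integer(seed),
    within_edge_prob = within_edge_prob,
    between_edge_prob = between_edge_prob,
    streamline_scale = as.integer(streamline_scale),
    lambda_noise = lambda_noise,
    ts_length = as.integer(ts_length),
    within_corr = within_corr,
    contrast_profiles = contrast_profiles,
    beta_noise_sd = beta_noise_sd,
    contrast_names = contrast_names,
    motion_translation_sd = motion_translation_sd,
    motion_rotation_sd = motion_rotation_sd
  ), class = "planted_design")
}

#' @export
print.planted_design <- function(x, ...) {
  cat("Planted design:", length(x$roi_set), "ROIs,", x$n_modules, "modules,",
      x$n_subjects, "subjects (seed", paste0(x$seed, ")\n"))
  cat("  edges: within", x$within_edge_prob, "/ between", x$between_edge_prob,
      "| streamline scale", x$streamline_scale, "| noise floor", x$lambda_noise, "\n")
  cat("  BOLD:", x$ts_length, "volumes, within-module rho", x$within_corr, "\n")
  invisible(x)
}
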