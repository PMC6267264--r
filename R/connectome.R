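# Group connectome construction: structural double threshold (per-subject
# Poisson threshold, then group consistency) and functional Fisher-z group
# averaging with negative weights zeroed.

#' Combine the two directional streamline estimates per ROI pair
#'
#' Probabilistic tracking is run in both directions (A to B and B to A), so
#' a subject matrix holds two probability estimates per pair. These are
#' combined into one symmetric estimate; the default rule is the arithmetic
#' mean, with `max` available since the combination rule is a genuine
#' methodological choice.
#'
#' @param m directional ROI x ROI matrix (nonnegative counts).
#' @param rule `"mean"` (default) or `"max"`.
#' @return symmetric matrix with zero diagonal.
#' @export
#' @examples
#' m <- matrix(c(0, 200, 100, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
#' combine_directional(m)["A", "B"]  # 150
combine_directional <- function(m, rule = c("mean", "max")) {
  rule <- match.arg(rule)
  assert_square_labelled(m, "subject structural matrix")
  if (any(m < 0)) stop("streamline counts must be nonnegative", call. = FALSE)
  out <- if (rule == "mean") (m + t(m)) / 2 else pmax(m, t(m))
  diag(out) <- 0
  out
}

#' Poisson threshold value for a given rate
#'
#' Smallest integer `v` with survival probability `P(X >= v) < alpha` under
#' `Poisson(lambda)`; computed from the exact (numerically stable) upper
#' tail, which remains accurate for the large rates streamline matrices
#' produce.
#'
#' @param lambda Poisson rate (streamline hits).
#' @param alpha significance level, in (0, 1).
#' @return integer threshold.
#' @export
#' @examples
#' poisson_threshold_value(3)   # 7
#' poisson_threshold_value(10)  # 16
poisson_threshold_value <- function(lambda, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (lambda < 0) stop("lambda must be nonnegative", call. = FALSE)
  if (lambda == 0) return(1L)
  v <- stats::qpois(1 - alpha, lambda) + 1  # P(X >= v) <= alpha by construction
  # walk up while the tail is not strictly below alpha (quantile boundary ties)
  while (stats::ppois(v - 1, lambda, lower.tail = FALSE) >= alpha) v <- v + 1
  # walk down while the next-lower threshold still satisfies the criterion
  while (v > 1 && stats::ppois(v - 2, lambda, lower.tail = FALSE) < alpha) v <- v - 1
  as.integer(v)
}

#' Per-subject Poisson threshold of a combined streamline matrix
#'
#' Fits a Poisson rate to the subject's off-diagonal connection values and
#' binarizes at the smallest count whose upper-tail probability falls below
#' `alpha`. The rate is by default the mean of the nonzero off-diagonal
#' entries (zero entries dominate sparse matrices and would collapse the
#' rate); the all-entries mean is available via `lambda_estimator`.
#'
#' @param combined symmetric nonnegative matrix from [combine_directional()].
#' @param alpha individual-threshold significance level (default 0.05).
#' @param lambda_estimator `"nonzero_mean"` (default) or `"all_mean"`.
#' @return binary matrix of the same shape, with attributes `lambda` and
#'   `threshold`.
#' @export
poisson_threshold <- function(combined, alpha = 0.05,
                              lambda_estimator = c("nonzero_mean", "all_mean")) {
  lambda_estimator <- match.arg(lambda_estimator)
  assert_symmetric(combined, "combined matrix")
  if (any(combined < 0)) stop("entries must be nonnegative", call. = FALSE)
  off <- upper_vec(combined)
  vals <- if (lambda_estimator == "nonzero_mean") off[off > 0] else off
  if (length(vals) == 0 || all(vals == 0)) {
    warning("all-zero matrix: Poisson rate undefined, returning all-zero adjacency")
    out <- combined * 0
    attr(out, "lambda") <- NA_real_
    attr(out, "threshold") <- NA_integer_
    return(out)
  }
  lambda <- mean(vals)
  v <- poisson_threshold_value(lambda, alpha)
  out <- (combined >= v) + 0
  diag(out) <- 0
  attr(out, "lambda") <- lambda
  attr(out, "threshold") <- v
  out
}

#' Group-consistency threshold over subject binary matrices
#'
#' An edge enters the group binary connectome iff it is present in at least
#' `ceiling(min_fraction * n_subjects)` subjects — the inclusive "at least
#' half" convention, so with 24 subjects and `min_fraction = 0.5` an edge
#' present in exactly 12 subjects is kept.
#'
#' @param binary_matrices list of subject binary matrices (common labels).
#' @param min_fraction required fraction of subjects, in (0, 1].
#' @return `group_connectome` object: binary symmetric `adjacency` with zero
#'   diagonal, plus `provenance` (rule parameters).
#' @export
group_consistency <- function(binary_matrices, min_fraction = 0.5) {
  if (length(binary_matrices) == 0) stop("need at least one subject matrix", call. = FALSE)
  if (min_fraction <= 0 || min_fraction > 1) {
    stop("min_fraction must be in (0, 1]", call. = FALSE)
  }
  labels <- rownames(binary_matrices[[1]])
  for (m in binary_matrices) {
    assert_symmetric(m, "subject binary matrix")
    if (!identical(rownames(m), labels)) stop("subject matrices disagree on ROI labels", call. = FALSE)
  }
  n_sub <- length(binary_matrices)
  need <- ceiling(min_fraction * n_sub)
  counts <- Reduce("+", lapply(binary_matrices, function(m) (m > 0) + 0))
  adj <- (counts >= need) + 0
  diag(adj) <- 0
  structure(list(adjacency = adj,
                 roi_set = roi_set(labels),
                 provenance = list(min_fraction = min_fraction,
                                   min_subjects = need,
                                   n_subjects = n_sub)),
            class = "group_connectome")
}

#' Censor subjects on head-motion summaries
#'
#' Excludes a subject when translation exceeds `max_translation_mm` or
#' rotation exceeds `max_rotation_deg` (strict inequalities, matching the
#' "greater than 3 mm / 1 degree" rule). Subjects without motion fields
#' pass with a warning.
#'
#' @param cohort list of `subject_ts` objects.
#' @param max_translation_mm,max_rotation_deg censoring thresholds.
#' @return list with `included` (surviving cohort) and `report`
#'   (data.frame: subject_id, translation, rotation, excluded, reason).
#' @export
censor_subjects <- function(cohort, max_translation_mm = 3, max_rotation_deg = 1) {
  rows <- lapply(cohort, function(s) {
    tr <- s$motion_translation_mm
    ro <- s$motion_rotation_deg
    if (is.null(tr) || is.null(ro)) {
      warning("subject ", s$subject_id, " has no motion summary; treated as passing")
      tr <- if (is.null(tr)) NA_real_ else tr
      ro <- if (is.null(ro)) NA_real_ else ro
    }
    excl_tr <- isTRUE(tr > max_translation_mm)
    excl_ro <- isTRUE(ro > max_rotation_deg)
    reason <- paste(c(
      if (excl_tr) sprintf("translation %.2f mm > %g mm", tr, max_translation_mm),
      if (excl_ro) sprintf("rotation %.2f deg > %g deg", ro, max_rotation_deg)
    ), collapse = "; ")
    data.frame(subject_id = s$subject_id,
               translation_mm = tr, rotation_deg = ro,
               excluded = excl_tr || excl_ro,
               reason = if (nzchar(reason)) reason else "",
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  list(included = cohort[!report$excluded], report = report)
}

#' ROI-to-ROI correlation matrix for one subject
#'
#' Pearson correlation between every pair of ROI time series; the diagonal
#' is set to 0 by convention so downstream graph code can treat the matrix
#' as an edge-weight matrix.
#'
#' @param ts a `subject_ts` or a plain ROI x time matrix.
#' @return symmetric correlation matrix with zero diagonal.
#' @export
subject_functional_matrix <- function(ts) {
  series <- if (inherits(ts, "subject_ts")) ts$series else ts
  if (!is.matrix(series) || ncol(series) < 2) {
    stop("need an ROI x time matrix with >= 2 time points", call. = FALSE)
  }
  sds <- apply(series, 1, stats::sd)
  if (any(sds == 0)) {
    stop("constant time series for ROI(s): ",
         paste(rownames(series)[sds == 0], collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(t(series))
  diag(r) <- 0
  r
}

#' Fisher-z group functional connectome
#'
#' Per edge, subject correlations are transformed to Fisher z-scores
#' (`atanh`, with r clipped to +/-(1 - 1e-6) to keep perfect correlations
#' finite), averaged across subjects, and transformed back; negative group
#' correlations are set to 0, so the result is a nonnegative weighted
#' network. A single-subject group returns the input with negatives zeroed
#' exactly (no transform round trip).
#'
#' @param subject_matrices list of subject correlation matrices.
#' @return `group_connectome` object with a `weights` matrix in `[0, 1]`.
#' @export
group_functional_matrix <- function(subject_matrices) {
  if (length(subject_matrices) == 0) stop("need at least one subject matrix", call. = FALSE)
  labels <- rownames(subject_matrices[[1]])
  for (m in subject_matrices) {
    assert_symmetric(m, "subject correlation matrix")
    if (!identical(rownames(m), labels)) stop("subject matrices disagree on ROI labels", call. = FALSE)
  }
  if (length(subject_matrices) == 1L) {
    w <- pmax(subject_matrices[[1]], 0)
  } else {
    clip <- 1 - 1e-6
    zs <- lapply(subject_matrices, function(m) atanh(pmin(pmax(m, -clip), clip)))
    w <- pmax(tanh(Reduce("+", zs) / length(zs)), 0)
  }
  diag(w) <- 0
  structure(list(weights = w,
                 roi_set = roi_set(labels),
                 provenance = list(n_subjects_included = length(subject_matrices),
                                   transform = "fisher-z mean, negatives zeroed")),
            class = "group_connectome")
}

#' @export
print.group_connectome <- function(x, ...) {
  m <- if (!is.null(x$adjacency)) x$adjacency else x$weights
  kind <- if (!is.null(x$adjacency)) "binary" else "weighted"
  n <- nrow(m)
  dens <- sum(upper_vec(m) > 0) / (n * (n - 1) / 2)
  cat(sprintf("Group %s connectome: %d ROIs, density %.3f\n", kind, n, dens))
  invisible(x)
}
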