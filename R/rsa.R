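# Network-level representational similarity analysis: activation RDMs from
# ROI x contrast activity, binary model RDMs from partitions, second-order
# Spearman correlation over the strict upper triangle, and group/model
# inference.

new_rdm <- function(d, labels, kind) {
  dimnames(d) <- list(labels, labels)
  diag(d) <- 0
  structure(list(dissimilarity = d, roi_set = roi_set(labels), kind = kind),
            class = "rdm")
}

#' Activation RDM for one subject
#'
#' Pairwise dissimilarity `1 - Pearson(r)` between the ROIs' activity
#' profiles across task contrasts, giving a symmetric zero-diagonal matrix
#' with entries in `[0, 2]`.
#'
#' @param betas_one_subject ROI x contrast matrix (>= 3 contrasts).
#' @return `rdm` object of kind `"activation"`.
#' @export
#' @examples
#' b <- rbind(ROI1 = c(1, 0, -1), ROI2 = c(0, 1, -1))
#' activation_rdm(b)$dissimilarity["ROI1", "ROI2"]  # 0.5
activation_rdm <- function(betas_one_subject) {
  m <- as.matrix(betas_one_subject)
  if (ncol(m) < 3) stop("need >= 3 contrasts for a correlation over conditions", call. = FALSE)
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    stop("constant activity profile for ROI(s): ",
         paste(rownames(m)[sds == 0], collapse = ", "), call. = FALSE)
  }
  d <- 1 - stats::cor(t(m))
  d <- pmin(pmax(d, 0), 2)  # guard float drift at |r| = 1
  new_rdm(d, rownames(m), "activation")
}

#' Per-subject activation RDMs for a study
#'
#' @param betas a `contrast_betas` object.
#' @return list of `rdm` objects, one per subject.
#' @export
subject_rdms <- function(betas) {
  stopifnot(inherits(betas, "contrast_betas"))
  lapply(seq_len(dim(betas$values)[1]), function(s) {
    activation_rdm(betas$values[s, , ])
  })
}

#' Model RDM from a network partition
#'
#' Encodes the hypothesis that ROIs within a module share an activity
#' pattern: dissimilarity 0 for same-module pairs, 1 for between-module
#' pairs.
#'
#' @param partition a `partition` object (or named assignment vector).
#' @return `rdm` object of kind `"model"`.
#' @export
model_rdm <- function(partition) {
  memb <- if (inherits(partition, "partition")) partition$assignment else partition
  if (is.null(names(memb))) stop("partition assignment must be named by ROI", call. = FALSE)
  d <- outer(memb, memb, "!=") + 0
  new_rdm(d, names(memb), "model")
}

#' Second-order Spearman correlation between two RDMs
#'
#' Spearman rank correlation (average-rank tie handling) over the strict
#' upper triangles — `n(n-1)/2` pairs, 903 for 43 ROIs; the structurally
#' zero diagonal is never included.
#'
#' @param x,y `rdm` objects over the same ROI set.
#' @return Spearman rho.
#' @export
rdm_correlation <- function(x, y) {
  stopifnot(inherits(x, "rdm"), inherits(y, "rdm"))
  if (!identical(unclass(x$roi_set), unclass(y$roi_set))) {
    stop("RDMs are defined over different ROI sets", call. = FALSE)
  }
  xv <- upper_vec(x$dissimilarity)
  yv <- upper_vec(y$dissimilarity)
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop("RDM with zero variance over pairs: Spearman rho undefined ",
         "(single-module model RDM?)", call. = FALSE)
  }
  stats::cor(xv, yv, method = "spearman")
}

#' Group RSA of individual RDMs against a model RDM
#'
#' Computes one Spearman rho per subject, then tests the group with a
#' two-tailed one-sample t-test on the Fisher-z transformed rhos; the
#' reported `mean_rho` is the mean of the raw rhos. Bonferroni correction
#' multiplies the p-value by `n_comparisons` (default 6: two model RDMs by
#' three studies). Subjects with undefined rho are dropped with a warning.
#'
#' As a chance-correspondence control, `shuffle_labels = TRUE` permutes the
#' model RDM's ROI labels independently for every subject before computing
#' that subject's rho. This destroys the ROI correspondence between model
#' and data while preserving the module-size structure, making the control
#' rhos exactly mean-zero by symmetry; a single fixed shuffled model would
#' instead retain a small but systematic chance overlap with the data.
#'
#' @param individual_rdms list of activation `rdm` objects.
#' @param model a model `rdm`.
#' @param n_comparisons Bonferroni family size.
#' @param shuffle_labels permute the model's ROI labels per subject
#'   (no-correspondence control).
#' @param seed seed for the control shuffles.
#' @return `rsa_result`: `subject_rhos`, `mean_rho`, `t`, `df`,
#'   `p_uncorrected`, `p_corrected`, `n_comparisons`, `n_dropped`.
#' @export
group_rsa <- function(individual_rdms, model, n_comparisons = 6L,
                      shuffle_labels = FALSE, seed = 1L) {
  if (length(individual_rdms) < 2) stop("need >= 2 subjects", call. = FALSE)
  models <- if (shuffle_labels) {
    n <- nrow(model$dissimilarity)
    with_seed(seed, lapply(seq_along(individual_rdms), function(i) {
      p <- sample.int(n)
      m <- model
      m$dissimilarity <- model$dissimilarity[p, p]
      dimnames(m$dissimilarity) <- dimnames(model$dissimilarity)
      m
    }))
  } else {
    rep(list(model), length(individual_rdms))
  }
  rhos <- vapply(seq_along(individual_rdms), function(i) {
    tryCatch(rdm_correlation(individual_rdms[[i]], models[[i]]),
             error = function(e) NA_real_)
  }, 0)
  n_dropped <- sum(is.na(rhos))
  if (n_dropped > 0) {
    warning(n_dropped, " subject(s) with undefined rho dropped from group RSA")
    rhos <- rhos[!is.na(rhos)]
  }
  if (length(rhos) < 2) stop("fewer than 2 usable subjects", call. = FALSE)
  clip <- 1 - 1e-12
  z <- atanh(pmin(pmax(rhos, -clip), clip))
  if (stats::sd(z) == 0) {
    # degenerate: identical rhos across subjects; report t = +/-Inf, no
    # fabricated p-value
    tstat <- if (mean(z) == 0) 0 else sign(mean(z)) * Inf
    tt <- list(statistic = tstat, parameter = length(z) - 1,
               p.value = if (mean(z) == 0) 1 else NA_real_)
  } else {
    tt <- stats::t.test(z, mu = 0)
  }
  p <- tt$p.value
  structure(list(subject_rhos = rhos,
                 mean_rho = mean(rhos),
                 t = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_uncorrected = p,
                 p_corrected = if (is.na(p)) NA_real_ else min(1, p * n_comparisons),
                 n_comparisons = n_comparisons,
                 n_dropped = n_dropped),
            class = "rsa_result")
}

#' Compare two model RDMs
#'
#' Spearman correlation between two partition-derived model RDMs, with a
#' parametric p (t approximation on the `n(n-1)/2` pairs) and a
#' Mantel-style permutation p obtained by permuting the ROI labels of one
#' RDM (rows and columns together), which respects the dependence structure
#' of distance-matrix entries.
#'
#' @param m1,m2 model `rdm` objects over the same ROI set.
#' @param n_perm label permutations (default 1e5).
#' @param seed integer seed.
#' @return list with `rho`, `p_parametric`, `p_permutation`, `n_pairs`,
#'   `n_perm`.
#' @export
compare_model_rdms <- function(m1, m2, n_perm = 1e5, seed = 1L) {
  rho <- rdm_correlation(m1, m2)
  n_pairs <- length(upper_vec(m1$dissimilarity))
  tstat <- rho * sqrt((n_pairs - 2) / (1 - rho^2))
  p_param <- 2 * stats::pt(-abs(tstat), df = n_pairs - 2)
  xr <- rank(upper_vec(m1$dissimilarity))
  d2 <- m2$dissimilarity
  n <- nrow(d2)
  perm_rhos <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    p <- sample.int(n)
    stats::cor(xr, rank(upper_vec(d2[p, p])))
  }, 0))
  p_perm <- (1 + sum(abs(perm_rhos) >= abs(rho))) / (n_perm + 1)
  list(rho = rho, p_parametric = p_param, p_permutation = p_perm,
       n_pairs = n_pairs, n_perm = n_perm)
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("%s RDM over %d ROIs (%d pairs)\n",
              x$kind, nrow(x$dissimilarity),
              sum(upper.tri(x$dissimilarity))))
  invisible(x)
}

#' @export
print.rsa_result <- function(x, ...) {
  cat(sprintf("Group RSA: mean rho = %.4f over %d subjects, t(%g) = %.2f\n",
              x$mean_rho, length(x$subject_rhos), x$df, x$t))
  cat(sprintf("  p = %.3g (uncorrected), %.3g (Bonferroni x %d)\n",
              x$p_uncorrected, x$p_corrected, x$n_comparisons))
  invisible(x)
}
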