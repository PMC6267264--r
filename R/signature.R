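# Cognitive signature of a network: module-averaged task-contrast activity,
# z-scored, with one-sample t-tests over subjects.

#' Module-averaged activity per subject
#'
#' Groups the ROIs by the partition's modules and averages regional
#' activity within each module, per subject and contrast.
#'
#' @param betas a `contrast_betas` object.
#' @param partition a `partition` covering every ROI in `betas`.
#' @return subject x module x contrast array.
#' @export
subject_module_activity <- function(betas, partition) {
  stopifnot(inherits(betas, "contrast_betas"), inherits(partition, "partition"))
  labels <- dimnames(betas$values)[[2]]
  memb <- partition$assignment[labels]
  if (anyNA(memb)) {
    stop("partition does not cover ROI(s): ",
         paste(labels[is.na(memb)], collapse = ", "), call. = FALSE)
  }
  modules <- sort(unique(memb))
  out <- array(NA_real_,
               dim = c(dim(betas$values)[1], length(modules), dim(betas$values)[3]),
               dimnames = list(dimnames(betas$values)[[1]],
                               paste0("module", modules),
                               betas$contrast_names))
  for (m in seq_along(modules)) {
    rois <- labels[memb == modules[m]]
    if (length(rois) == 0) stop("empty module ", modules[m], call. = FALSE)
    block <- betas$values[, rois, , drop = FALSE]
    out[, m, ] <- apply(block, c(1, 3), mean)
  }
  out
}

#' One-sample t-tests on module activity
#'
#' Two-tailed one-sample t-test of subject-level module activity against 0,
#' per module and contrast. Zero-variance cells get `t = sign(mean) * Inf`
#' and `p = NA` with a `degenerate` flag rather than a fabricated p-value.
#'
#' @param activity subject x module x contrast array from
#'   [subject_module_activity()].
#' @return list of module x contrast matrices `t`, `p`, `degenerate`.
#' @export
network_ttest <- function(activity) {
  stopifnot(length(dim(activity)) == 3)
  if (dim(activity)[1] < 2) stop("need at least 2 subjects", call. = FALSE)
  dn <- dimnames(activity)[2:3]
  tmat <- matrix(NA_real_, dim(activity)[2], dim(activity)[3], dimnames = dn)
  pmat <- tmat
  degen <- matrix(FALSE, dim(activity)[2], dim(activity)[3], dimnames = dn)
  for (m in seq_len(dim(activity)[2])) {
    for (cc in seq_len(dim(activity)[3])) {
      x <- activity[, m, cc]
      if (stats::sd(x) == 0) {
        degen[m, cc] <- TRUE
        tmat[m, cc] <- sign(mean(x)) * Inf
        if (mean(x) == 0) tmat[m, cc] <- 0
      } else {
        tt <- stats::t.test(x, mu = 0)
        tmat[m, cc] <- unname(tt$statistic)
        pmat[m, cc] <- tt$p.value
      }
    }
  }
  list(t = tmat, p = pmat, degenerate = degen)
}

#' Cognitive signature of a network partition
#'
#' Computes the group-mean module x contrast activity pattern, presents it
#' as z-scores, and attaches two-tailed one-sample t-tests over subjects.
#' The z-scoring scope defaults to all module x contrast cells of the study
#' (`"study"`), with per-contrast standardization (`"contrast"`) available.
#'
#' @param betas a `contrast_betas` object.
#' @param partition a `partition` covering every ROI in `betas`.
#' @param zscore_scope `"study"` or `"contrast"`.
#' @return `network_signature` object with `mean_activity`, `z_activity`,
#'   `t`, `p`, `subject_activity`, `study_id`.
#' @export
network_activity <- function(betas, partition, zscore_scope = c("study", "contrast")) {
  zscore_scope <- match.arg(zscore_scope)
  subj <- subject_module_activity(betas, partition)
  mean_act <- apply(subj, c(2, 3), mean)
  zscore <- function(x) {
    s <- stats::sd(x)
    if (s == 0) {
      warning("degenerate variance in z-scoring scope: z set to 0")
      return(x * 0)
    }
    (x - mean(x)) / s
  }
  z <- if (zscore_scope == "study") {
    matrix(zscore(as.vector(mean_act)), nrow(mean_act), ncol(mean_act),
           dimnames = dimnames(mean_act))
  } else {
    apply(mean_act, 2, zscore)
  }
  tests <- network_ttest(subj)
  structure(list(mean_activity = mean_act, z_activity = z,
                 t = tests$t, p = tests$p, degenerate = tests$degenerate,
                 subject_activity = subj,
                 zscore_scope = zscore_scope,
                 study_id = betas$study_id),
            class = "network_signature")
}

#' @export
print.network_signature <- function(x, ...) {
  cat("Network signature (", x$study_id, "), z-scored activity (scope: ",
      x$zscore_scope, "):\n", sep = "")
  print(round(x$z_activity, 3))
  invisible(x)
}
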