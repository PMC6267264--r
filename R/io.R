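# Plain-text readers and writers. Matrices travel as TSV with ROI labels
# as header row and first column; partitions, designs and result summaries
# as JSON with a provenance block.

#' Write a labelled square matrix as TSV
#'
#' Values are serialized with 17 significant digits so that
#' `read_matrix(write_matrix(x))` reproduces `x` to full double precision.
#'
#' @param m square numeric matrix with row/column labels.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  assert_square_labelled(m)
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("matrix must carry ROI labels on both dimensions", call. = FALSE)
  }
  ch <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
  lines <- c(paste(c("roi", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(rownames(m)[i], ch[i, ]), collapse = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a labelled square matrix from TSV
#'
#' Validates squareness and label consistency; with a reference `roi_set`
#' the matrix is reordered to canonical order (with a message) and any
#' label mismatch is an error naming the offending rows/columns.
#'
#' @param path TSV file written by [write_matrix()] (label header row and
#'   first column).
#' @param rois optional `roi_set` defining the canonical order.
#' @return labelled numeric matrix.
#' @export
read_matrix <- function(path, rois = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- labels
  if (nrow(m) != ncol(m)) {
    stop("matrix in ", path, " is not square: ", nrow(m), " rows x ",
         ncol(m), " columns", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("duplicate row labels in ", path, ": ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "), call. = FALSE)
  }
  if (!identical(rownames(m), colnames(m))) {
    bad <- union(setdiff(rownames(m), colnames(m)), setdiff(colnames(m), rownames(m)))
    stop("row/column labels disagree in ", path,
         if (length(bad)) paste0(": ", paste(bad, collapse = ", ")) else
           ": same labels, different order", call. = FALSE)
  }
  if (!is.null(rois)) {
    rois <- roi_set(rois)
    if (!setequal(rownames(m), unclass(rois))) {
      bad <- union(setdiff(rownames(m), unclass(rois)),
                   setdiff(unclass(rois), rownames(m)))
      stop("labels in ", path, " do not match the ROI set: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (!identical(rownames(m), unclass(rois))) {
      message("reordering ", path, " to canonical ROI order")
      m <- m[unclass(rois), unclass(rois)]
    }
  }
  m
}

#' Write a partition as JSON
#'
#' @param partition a `partition` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "partition"))
  jsonlite::write_json(list(assignment = as.list(partition$assignment),
                            q = partition$q,
                            n_modules = partition$n_modules),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a partition from JSON
#'
#' @param path file written by [write_partition()].
#' @return `partition` object.
#' @export
read_partition <- function(path) {
  x <- jsonlite::read_json(path)
  memb <- unlist(x$assignment)
  structure(list(assignment = stats::setNames(as.integer(memb), names(memb)),
                 q = if (is.null(x$q)) NA_real_ else as.numeric(x$q),
                 n_modules = as.integer(x$n_modules)),
            class = "partition")
}

#' Write a cohort of subject matrices as per-subject TSV files
#'
#' @param cohort named list of subject matrices.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(cohort), function(id) {
    p <- file.path(dir, paste0(id, ".tsv"))
    write_matrix(cohort[[id]], p)
    p
  }, "")
  invisible(paths)
}

#' Write task-contrast betas as long-format TSV
#'
#' Columns: subject, roi, contrast, value.
#'
#' @param betas a `contrast_betas` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_betas_long <- function(betas, path) {
  stopifnot(inherits(betas, "contrast_betas"))
  df <- as.data.frame.table(betas$values, stringsAsFactors = FALSE)
  names(df) <- c("subject", "roi", "contrast", "value")
  df$value <- sprintf("%.17g", df$value)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read task-contrast betas from long-format TSV
#'
#' @param path TSV with columns subject, roi, contrast, value.
#' @param study_id study identifier attached to the result.
#' @return `contrast_betas` object.
#' @export
read_betas_long <- function(path, study_id = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject", "roi", "contrast", "value")
  if (!all(need %in% names(df))) {
    stop("betas file must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  subjects <- unique(df$subject)
  rois <- unique(df$roi)
  contrasts <- unique(df$contrast)
  arr <- array(NA_real_, dim = c(length(subjects), length(rois), length(contrasts)),
               dimnames = list(subjects, rois, contrasts))
  arr[cbind(match(df$subject, subjects), match(df$roi, rois),
            match(df$contrast, contrasts))] <- df$value
  if (anyNA(arr)) stop("incomplete subject x roi x contrast grid in ", path, call. = FALSE)
  structure(list(values = arr, contrast_names = contrasts,
                 study_id = study_id, roi_set = roi_set(rois)),
            class = "contrast_betas")
}

#' Write a design descriptor as JSON
#'
#' Records the planted partition, seed and all generator parameters so a
#' simulated dataset is fully reproducible from its descriptor.
#'
#' @param design a `planted_design`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "planted_design"))
  x <- design
  x$roi_set <- unclass(x$roi_set)
  x$true_partition <- as.list(x$true_partition)
  x$contrast_profiles <- apply(x$contrast_profiles, 1, as.list)
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
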