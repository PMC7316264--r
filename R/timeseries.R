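#' ROI time-series container
#'
#' Holds one subject/timepoint worth of BOLD data: an ROI x time matrix with
#' ROI labels, the sampling interval (repetition time, seconds), and optional
#' nuisance channels (channel x time, e.g. white-matter and CSF averages).
#'
#' @param data numeric ROI x time matrix (rows = regions, columns = volumes).
#' @param roi_labels character vector, one label per row of `data`.
#' @param tr_seconds sampling interval in seconds (> 0).
#' @param nuisance optional channel x time numeric matrix with rownames.
#' @return object of class `subject_ts`.
#' @export
subject_ts <- function(data, roi_labels, tr_seconds, nuisance = NULL) {
  data <- as.matrix(data)
  if (length(roi_labels) != nrow(data))
    stop2("roi_labels length (%d) != number of ROI rows (%d)",
          length(roi_labels), nrow(data))
  if (!is.numeric(tr_seconds) || tr_seconds <= 0)
    stop2("tr_seconds must be > 0")
  if (anyNA(data)) stop2("time-series data contains missing values")
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (ncol(nuisance) != ncol(data))
      stop2("nuisance channels have %d volumes, data has %d",
            ncol(nuisance), ncol(data))
    if (is.null(rownames(nuisance)))
      rownames(nuisance) <- sprintf("nuisance%d", seq_len(nrow(nuisance)))
  }
  rownames(data) <- roi_labels
  structure(list(data = data, roi_labels = as.character(roi_labels),
                 tr_seconds = tr_seconds, nuisance = nuisance),
            class = "subject_ts")
}

#' @export
print.subject_ts <- function(x, ...) {
  cat(sprintf("<subject_ts> %d ROIs x %d volumes, TR = %gs, %d nuisance channel(s)\n",
              nrow(x$data), ncol(x$data), x$tr_seconds,
              if (is.null(x$nuisance)) 0L else nrow(x$nuisance)))
  invisible(x)
}

n_volumes <- function(ts) ncol(ts$data)

#' Write / read a subject time series as TSV
#'
#' Table layout: rows = volumes, columns = ROI labels followed by the
#' nuisance channels (their column names carry a `nuisance.` prefix).
#'
#' @param ts `subject_ts` object.
#' @param path output file.
#' @export
write_timeseries_tsv <- function(ts, path) {
  tab <- t(ts$data)
  if (!is.null(ts$nuisance)) {
    nui <- t(ts$nuisance)
    colnames(nui) <- paste0("nuisance.", rownames(ts$nuisance))
    tab <- cbind(tab, nui)
  }
  write.table(format(tab, digits = 10, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries_tsv
#' @param tr_seconds repetition time to attach on read (seconds).
#' @export
read_timeseries_tsv <- function(path, tr_seconds = 2.0) {
  tab <- as.matrix(read.table(path, sep = "\t", header = TRUE,
                              check.names = FALSE))
  is_nui <- startsWith(colnames(tab), "nuisance.")
  nuisance <- NULL
  if (any(is_nui)) {
    nuisance <- t(tab[, is_nui, drop = FALSE])
    rownames(nuisance) <- sub("^nuisance\\.", "", rownames(nuisance))
  }
  dat <- t(tab[, !is_nui, drop = FALSE])
  subject_ts(dat, rownames(dat), tr_seconds, nuisance)
}

#' Write / read a labelled square matrix as TSV
#'
#' Full symmetric storage with a header row and a leading label column.
#'
#' @param m numeric square matrix with dimnames.
#' @param path file path.
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  df <- data.frame(label = rownames(m),
                   format(m, digits = 10, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (!identical(rownames(m), colnames(m)))
    stop2("matrix file %s: row labels differ from column labels", path)
  m
}
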