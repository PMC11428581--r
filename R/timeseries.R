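#' Construct an ROI time-series object
#'
#' Wraps a T_scan x N matrix of per-ROI BOLD signals (rows = time points,
#' columns = ROIs in atlas order) with its repetition time.
#'
#' @param data Numeric matrix, rows = time points, columns = ROIs.
#' @param tr_seconds Positive repetition time in seconds.
#' @param subject_id Subject identifier string.
#' @param atlas Optional `flex_atlas`; if given, the column count must match.
#' @return A `roi_ts` object.
#' @export
roi_timeseries <- function(data, tr_seconds, subject_id = "subject",
                           atlas = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop("tr_seconds must be a single positive number")
  bad <- which(!is.finite(data), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("time-series data error: non-finite value at row %d, column %d",
                 bad[1, 1], bad[1, 2]))
  if (!is.null(atlas) && ncol(data) != n_nodes(atlas))
    stop(sprintf("time-series shape error: %d columns but atlas has %d ROIs",
                 ncol(data), n_nodes(atlas)))
  structure(list(subject_id = as.character(subject_id), data = data,
                 tr_seconds = as.numeric(tr_seconds)),
            class = "roi_ts")
}

# sniff the delimiter of an ABIDE-style ROI extract (tab / comma / whitespace)
.sniff_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl(",", line, fixed = TRUE)) return(",")
  if (grepl("\t", line, fixed = TRUE)) return("\t")
  ""
}

#' Read one subject's ROI time series from delimited text
#'
#' Rows are time points and columns ROIs in atlas order; no header. The
#' delimiter (tab, comma, or whitespace) is sniffed from the first line.
#'
#' @param path Path to the delimited text file.
#' @param atlas `flex_atlas` defining the expected column count and order.
#' @param tr_seconds Repetition time in seconds for this subject.
#' @param subject_id Subject identifier; defaults to the file stem.
#' @return A `roi_ts` object.
#' @export
load_timeseries <- function(path, atlas, tr_seconds,
                            subject_id = sub("\\.[^.]*$", "", basename(path))) {
  sep <- .sniff_sep(path)
  df <- utils::read.table(path, header = FALSE, sep = sep,
                          colClasses = "numeric", na.strings = c("NA", "nan",
                                                                 "NaN", "inf",
                                                                 "-inf", "Inf",
                                                                 "-Inf"))
  m <- as.matrix(df)
  if (ncol(m) != n_nodes(atlas))
    stop(sprintf("time-series shape error: file '%s' has %d columns but atlas has %d ROIs",
                 basename(path), ncol(m), n_nodes(atlas)))
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("time-series data error in '%s': non-finite value at row %d, column %d",
                 basename(path), bad[1, 1], bad[1, 2]))
  roi_timeseries(m, tr_seconds, subject_id, atlas)
}

#' Write an ROI time series as whitespace-delimited text
#'
#' @param ts A `roi_ts`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "roi_ts"))
  utils::write.table(ts$data, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> subject '%s': %d time points x %d ROIs, TR = %g s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}
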