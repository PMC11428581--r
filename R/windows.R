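#' Sliding-window parameters
#'
#' Defaults follow the common dynamic-connectivity choice of a 100 s window
#' (50 TRs at TR = 2 s) sliding by one TR.
#'
#' @param width_trs Window width in TRs (>= 2).
#' @param step_trs Step between consecutive window starts in TRs (>= 1).
#' @param tr_seconds Repetition time in seconds.
#' @return A `windowing_params` list.
#' @export
windowing_params <- function(width_trs = 50L, step_trs = 1L, tr_seconds = 2) {
  width_trs <- as.integer(width_trs)
  step_trs <- as.integer(step_trs)
  stopifnot(width_trs >= 2L, step_trs >= 1L, tr_seconds > 0)
  structure(list(width_trs = width_trs, step_trs = step_trs,
                 tr_seconds = tr_seconds),
            class = "windowing_params")
}

#' Enumerate sliding windows over a scan
#'
#' Windows are half-open, 0-based index pairs `[start, start + width)`; the
#' first starts at 0, consecutive starts are `step_trs` apart, and only
#' windows fully inside the scan are kept (trailing partial windows are
#' dropped, never padded). The count is
#' `floor((t_scan - width) / step) + 1`.
#'
#' @param t_scan Number of time points in the scan.
#' @param params A [windowing_params()] object.
#' @return Data frame with integer columns `start` and `end` (half-open).
#' @export
slide_windows <- function(t_scan, params = windowing_params()) {
  t_scan <- as.integer(t_scan)
  if (t_scan < params$width_trs)
    stop(sprintf("input too short: t_scan = %d < window width = %d TRs",
                 t_scan, params$width_trs))
  starts <- seq.int(0L, t_scan - params$width_trs, by = params$step_trs)
  data.frame(start = starts, end = starts + params$width_trs)
}

#' Windowed functional-connectivity matrix
#'
#' Pearson correlation of every ROI pair over one window's rows. The diagonal
#' is set to 0 (self-connections are not edges).
#'
#' @param ts A `roi_ts`.
#' @param window Length-2 half-open 0-based index pair `c(start, end)` (or a
#'   one-row slice of [slide_windows()] output).
#' @return Symmetric N x N matrix with zero diagonal, entries in `[-1, 1]`.
#' @export
window_fc <- function(ts, window) {
  stopifnot(inherits(ts, "roi_ts"))
  window <- unlist(window, use.names = FALSE)
  start <- as.integer(window[1]); end <- as.integer(window[2])
  if (start < 0L || end > nrow(ts$data) || end - start < 2L)
    stop("window out of range")
  x <- ts$data[(start + 1L):end, , drop = FALSE]
  sds <- apply(x, 2L, stats::sd)
  degen <- which(sds == 0)
  if (length(degen))
    stop(sprintf("degenerate signal: node %d has zero variance in window [%d, %d)",
                 degen[1], start, end))
  r <- stats::cor(x)
  diag(r) <- 0
  r
}

#' Build the multilayer dynamic network for one subject
#'
#' Slides windows over the scan and stacks the window-wise Pearson
#' correlation matrices into an N x N x T tensor (layer t = window t).
#'
#' @param ts A `roi_ts`.
#' @param params A [windowing_params()] object.
#' @return A `dyn_network` with fields `tensor` (N x N x T), `windowing`,
#'   `windows` (the [slide_windows()] table), `n_nodes`, `n_layers`, and
#'   `subject_id`.
#' @export
build_dynamic_network <- function(ts, params = windowing_params()) {
  stopifnot(inherits(ts, "roi_ts"))
  wins <- slide_windows(nrow(ts$data), params)
  N <- ncol(ts$data)
  # incremental sliding-window correlation (C++); identical to stacking
  # window_fc() layer by layer
  tensor <- fc_tensor_cpp(ts$data, as.integer(wins$start),
                          params$width_trs)
  structure(list(tensor = tensor, windowing = params, windows = wins,
                 n_nodes = N, n_layers = nrow(wins),
                 subject_id = ts$subject_id),
            class = "dyn_network")
}

#' Wrap an existing connectivity tensor as a dynamic network
#'
#' Useful for toy constructions and tests; validates symmetry and the zero
#' diagonal.
#'
#' @param tensor N x N x T numeric array of layer-wise edge weights.
#' @param params A [windowing_params()] object (metadata only).
#' @param subject_id Subject identifier.
#' @return A `dyn_network`.
#' @export
dynamic_network <- function(tensor, params = windowing_params(),
                            subject_id = "subject") {
  stopifnot(is.array(tensor), length(dim(tensor)) == 3L,
            dim(tensor)[1] == dim(tensor)[2])
  for (t in seq_len(dim(tensor)[3])) {
    if (max(abs(tensor[, , t] - t(tensor[, , t]))) > 1e-12)
      stop(sprintf("layer %d is not symmetric", t))
    if (any(diag(tensor[, , t]) != 0))
      stop(sprintf("layer %d has a nonzero diagonal", t))
  }
  structure(list(tensor = tensor, windowing = params, windows = NULL,
                 n_nodes = dim(tensor)[1], n_layers = dim(tensor)[3],
                 subject_id = subject_id),
            class = "dyn_network")
}

#' @export
print.dyn_network <- function(x, ...) {
  cat(sprintf("<dyn_network> subject '%s': %d nodes x %d layers (width %d, step %d TRs)\n",
              x$subject_id, x$n_nodes, x$n_layers,
              x$windowing$width_trs, x$windowing$step_trs))
  invisible(x)
}
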