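#' Flexibility (switching rate) of one node
#'
#' The fraction of adjacent layer pairs in which the node changes community:
#' `f = N_switch / (T - 1)`, where `N_switch` counts layers t with a label
#' different from layer t - 1. Invariant to community relabeling and to
#' reversal of layer order.
#'
#' @param labels_i Integer vector of one node's community labels across the
#'   T layers (T >= 2).
#' @return Flexibility in `[0, 1]`.
#' @export
node_flexibility <- function(labels_i) {
  T <- length(labels_i)
  if (T < 2L)
    stop("flexibility is undefined for fewer than 2 layers")
  sum(labels_i[-1L] != labels_i[-T]) / (T - 1)
}

#' Nodal flexibility of one partition
#'
#' @param partition An `ml_partition` (or bare N x T label matrix).
#' @return Length-N vector of per-node flexibilities.
#' @export
partition_flexibility <- function(partition) {
  labels <- if (inherits(partition, "ml_partition")) partition$labels
            else as.matrix(partition)
  if (ncol(labels) < 2L)
    stop("flexibility is undefined for fewer than 2 layers")
  apply(labels, 1L, node_flexibility)
}

#' Subnetwork-mean flexibility
#'
#' Unweighted mean of the nodal values within each subnetwork of the atlas.
#'
#' @param nodal Length-N numeric vector in atlas node order.
#' @param atlas A `flex_atlas` with N ROIs.
#' @return Named numeric vector, one mean per subnetwork.
#' @export
aggregate_subnetwork <- function(nodal, atlas) {
  stopifnot(inherits(atlas, "flex_atlas"))
  if (length(nodal) != n_nodes(atlas))
    stop(sprintf("shape error: %d nodal values but atlas has %d ROIs",
                 length(nodal), n_nodes(atlas)))
  vapply(split(nodal, atlas$subnetwork), mean, numeric(1))
}

#' Run-averaged flexibility at nodal, subnetwork and global levels
#'
#' Per-run nodal flexibility is computed first, then averaged across runs;
#' subnetwork values are the unweighted means of their member nodes and the
#' global value the mean over all nodes.
#'
#' @param partitions List of `ml_partition` objects (an ensemble from
#'   [run_ensemble()]); all must share N and T.
#' @param atlas A `flex_atlas` with matching N.
#' @return A `flex_result`: `nodal` (named length-N vector), `subnetwork`
#'   (named vector of subnetwork means), `global_mean`, `n_runs`, `T`.
#' @export
run_averaged_flexibility <- function(partitions, atlas) {
  if (!length(partitions)) stop("empty partition ensemble")
  mats <- lapply(partitions, function(p)
    if (inherits(p, "ml_partition")) p$labels else as.matrix(p))
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("shape error: partitions differ in N or T")
  if (dims[1, 1] != n_nodes(atlas))
    stop(sprintf("shape error: partitions have %d nodes but atlas has %d ROIs",
                 dims[1, 1], n_nodes(atlas)))
  per_run <- vapply(mats, function(m) apply(m, 1L, node_flexibility),
                    numeric(dims[1, 1]))
  nodal <- rowMeans(per_run)
  names(nodal) <- atlas$labels
  structure(list(nodal = nodal,
                 subnetwork = aggregate_subnetwork(nodal, atlas),
                 global_mean = mean(nodal),
                 n_runs = length(partitions), T = dims[2, 1]),
            class = "flex_result")
}

#' @export
print.flex_result <- function(x, ...) {
  cat(sprintf("<flex_result> %d nodes, %d layers, %d runs; global flexibility = %.4f\n",
              length(x$nodal), x$T, x$n_runs, x$global_mean))
  print(round(x$subnetwork, 4))
  invisible(x)
}
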