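#' Parameters for multilayer modularity optimization
#'
#' `gamma` is the intra-layer resolution of the degree-based null model and
#' `omega` the ordinal inter-layer coupling rewarding label persistence
#' between adjacent layers; both default to 1, the customary choice of the
#' generalized Louvain literature. Negative correlation weights are clipped
#' to zero by default (`negative_policy = "zero"`) because the Newman-Girvan
#' null term is not defined for sign-mixed strengths; `"keep"` retains them
#' for sensitivity analyses.
#'
#' @param gamma Intra-layer resolution (> 0).
#' @param omega Inter-layer coupling (>= 0).
#' @param negative_policy `"zero"` (clip negative weights) or `"keep"`.
#' @param max_sweeps Maximum greedy sweeps per level.
#' @param tolerance Minimum modularity gain for a move.
#' @param seed Integer seed for the node-visit order.
#' @return A `modularity_params` list.
#' @export
modularity_params <- function(gamma = 1, omega = 1,
                              negative_policy = c("zero", "keep"),
                              max_sweeps = 1000L, tolerance = 1e-10,
                              seed = 1L) {
  negative_policy <- match.arg(negative_policy)
  stopifnot(gamma > 0, omega >= 0, max_sweeps >= 1, tolerance >= 0)
  structure(list(gamma = gamma, omega = omega,
                 negative_policy = negative_policy,
                 max_sweeps = as.integer(max_sweeps),
                 tolerance = tolerance, seed = as.integer(seed)),
            class = "modularity_params")
}

.policy_tensor <- function(net, params) {
  if (params$negative_policy == "zero") pmax(net$tensor, 0) else net$tensor
}

#' Multilayer modularity of a given partition
#'
#' Evaluates the multilayer quality function with ordinal coupling,
#' \deqn{Q = \frac{1}{2\mu} \sum_{ijsr} \left[ \left(A_{ijs} -
#'   \gamma \frac{k_{is} k_{js}}{2 m_s}\right) \delta_{sr} +
#'   \delta_{ij}\, \omega\, 1\{|s-r|=1\} \right] \delta(g_{is}, g_{jr}),}
#' where \eqn{2\mu} is the total intra-layer strength plus all coupling
#' weights. The value is invariant to any permutation of community ids.
#'
#' @param net A `dyn_network`.
#' @param labels Integer N x T matrix of community labels.
#' @param params A [modularity_params()] object.
#' @return The scalar modularity Q.
#' @export
modularity_value <- function(net, labels, params = modularity_params()) {
  stopifnot(inherits(net, "dyn_network"))
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (nrow(labels) != net$n_nodes || ncol(labels) != net$n_layers)
    stop(sprintf("labels must be %d x %d", net$n_nodes, net$n_layers))
  if (any(labels < 0L)) stop("labels must be non-negative")
  ml_modularity_cpp(.policy_tensor(net, params), labels,
                    params$gamma, params$omega)
}

#' Optimize multilayer modularity by generalized Louvain
#'
#' Greedy phase: node-layer tuples are visited in seeded random order and
#' each is moved to the community (among its intra-layer neighbours'
#' communities and the same node's communities in adjacent layers) with the
#' largest positive modularity gain; ties keep the current community, and
#' among new communities the lowest id wins. When a full sweep makes no
#' move, communities are collapsed into super-nodes (preserving intra-layer
#' and coupling weight structure) and the procedure recurses on the
#' aggregated modularity matrix until no further improvement.
#'
#' @param net A `dyn_network`.
#' @param params A [modularity_params()] object; `params$seed` drives the
#'   visit order, making each run fully reproducible.
#' @return An `ml_partition`: `labels` (N x T integer matrix, ids 1..C),
#'   `q_value` (the modularity of the returned labels, recomputed through
#'   [modularity_value()] for self-consistency), `converged` (FALSE when the
#'   sweep budget ran out; the best partition so far is still returned),
#'   `n_levels`, `q_trace` (per-move modularity gains), `params`, `run_seed`.
#' @export
louvain_optimize <- function(net, params = modularity_params()) {
  stopifnot(inherits(net, "dyn_network"))
  A <- .policy_tensor(net, params)
  res <- ml_louvain_cpp(A, params$gamma, params$omega, params$seed,
                        params$max_sweeps, params$tolerance)
  q <- ml_modularity_cpp(A, res$labels, params$gamma, params$omega)
  structure(list(labels = res$labels, q_value = q,
                 converged = res$converged, n_levels = res$n_levels,
                 q_trace = res$q_trace, params = params,
                 run_seed = params$seed),
            class = "ml_partition")
}

#' Repeated community detection with independent seeds
#'
#' Runs [louvain_optimize()] `n_runs` times; run `r` uses
#' `seed = base_seed + r`, so the ensemble is reproducible and
#' order-preserving.
#'
#' @param net A `dyn_network`.
#' @param params A [modularity_params()]; its `seed` is the base seed.
#' @param n_runs Number of independent runs (>= 1; 100 is the conventional
#'   choice for flexibility estimation).
#' @return List of `ml_partition` objects, in run order.
#' @export
run_ensemble <- function(net, params = modularity_params(), n_runs = 100L) {
  n_runs <- as.integer(n_runs)
  if (is.na(n_runs) || n_runs < 1L) stop("n_runs must be a positive integer")
  lapply(seq_len(n_runs), function(r) {
    p <- params
    p$seed <- params$seed + r
    louvain_optimize(net, p)
  })
}

#' Exhaustive multilayer-modularity optimum for tiny instances
#'
#' Enumerates every set partition of the node-layer tuples and returns the
#' partition with maximal [modularity_value()]. Only feasible for very small
#' instances (N x T <= 10); used as a reference for validating the greedy
#' optimizer.
#'
#' @param net A `dyn_network` with few node-layer tuples.
#' @param params A [modularity_params()].
#' @return List with `labels` (N x T matrix) and `q_value`.
#' @export
exhaustive_optimum <- function(net, params = modularity_params()) {
  n <- net$n_nodes * net$n_layers
  if (n > 10L) stop("exhaustive enumeration is limited to <= 10 node-layer tuples")
  best_q <- -Inf; best <- NULL
  for (rgs in enumerate_set_partitions(n)) {
    lab <- matrix(rgs, nrow = net$n_nodes, ncol = net$n_layers)
    q <- modularity_value(net, lab, params)
    if (q > best_q) { best_q <- q; best <- lab }
  }
  list(labels = best, q_value = best_q)
}

#' Enumerate all set partitions of n items
#'
#' Returns every restricted-growth string of length `n` (Bell(n) of them),
#' each a vector of 1-based block labels.
#'
#' @param n Number of items (small).
#' @return List of integer vectors.
#' @keywords internal
#' @export
enumerate_set_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1L))
      recurse(c(prefix, lab), max(maxlab, lab))
  }
  recurse(integer(0), 0L)
  out
}

#' @export
print.ml_partition <- function(x, ...) {
  cat(sprintf("<ml_partition> %d x %d labels, %d communities, Q = %.6f%s\n",
              nrow(x$labels), ncol(x$labels), length(unique(as.vector(x$labels))),
              x$q_value, if (x$converged) "" else " (not converged)"))
  invisible(x)
}
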