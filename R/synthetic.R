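#' Planted time-varying community model for one subject
#'
#' Defines the ground-truth generative process behind a synthetic ROI time
#' series: nodes start evenly split across `n_communities`; at every TR each
#' node independently reassigns, with its own probability `switch_prob`, to a
#' uniformly chosen other community (memoryless switching, so the planted
#' per-TR switching probability is directly comparable to the measured
#' flexibility). Signals mix a shared per-community white signal with node
#' noise so that two same-community nodes have expected window correlation
#' `within_corr`.
#'
#' @param n_nodes Number of nodes.
#' @param n_communities Number of planted communities K (>= 2 whenever any
#'   switching probability is positive).
#' @param t_scan Scan length in TRs.
#' @param tr_seconds Repetition time in seconds.
#' @param switch_prob Per-node per-TR switching probability; scalar or
#'   length-`n_nodes` vector in `[0, 1]`.
#' @param within_corr Target within-community correlation share in `(0, 1)`
#'   (boundary values allowed for degenerate checks).
#' @param noise_sd Overall signal scale.
#' @param seed Integer seed; the whole subject is reproducible from it.
#' @return A `planted_model` list.
#' @export
planted_model <- function(n_nodes = 160L, n_communities = 4L, t_scan = 200L,
                          tr_seconds = 2, switch_prob = 0.05,
                          within_corr = 0.6, noise_sd = 1, seed = 1L) {
  n_nodes <- as.integer(n_nodes); n_communities <- as.integer(n_communities)
  t_scan <- as.integer(t_scan)
  switch_prob <- rep_len(as.numeric(switch_prob), n_nodes)
  stopifnot(n_nodes >= 1, n_communities >= 1, n_communities <= n_nodes,
            t_scan >= 2, tr_seconds > 0,
            all(switch_prob >= 0 & switch_prob <= 1),
            within_corr >= 0, within_corr <= 1, noise_sd > 0)
  if (n_communities == 1L && any(switch_prob > 0))
    stop("parameter error: K = 1 leaves nowhere to switch")
  structure(list(n_nodes = n_nodes, n_communities = n_communities,
                 t_scan = t_scan, tr_seconds = tr_seconds,
                 switch_prob = switch_prob, within_corr = within_corr,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "planted_model")
}

#' Simulate the planted community-label sequence
#'
#' @param model A [planted_model()].
#' @return A `flex_truth`: `labels` (n_nodes x t_scan integers), per-node
#'   realized `switch_count`, and the planted `switch_prob`.
#' @export
generate_partition_sequence <- function(model) {
  stopifnot(inherits(model, "planted_model"))
  N <- model$n_nodes; K <- model$n_communities; T <- model$t_scan
  labels <- matrix(0L, N, T)
  withr::with_seed(model$seed, {
    labels[, 1L] <- rep_len(seq_len(K), N)
    for (t in 2:T) {
      prev <- labels[, t - 1L]
      sw <- stats::runif(N) < model$switch_prob
      cur <- prev
      if (any(sw)) {
        # uniform over the K - 1 other communities
        offs <- sample.int(K - 1L, sum(sw), replace = TRUE)
        cur[sw] <- ((prev[sw] - 1L + offs) %% K) + 1L
      }
      labels[, t] <- cur
    }
  })
  structure(list(labels = labels,
                 switch_count = rowSums(labels[, -1L, drop = FALSE] !=
                                          labels[, -T, drop = FALSE]),
                 switch_prob = model$switch_prob),
            class = "flex_truth")
}

#' Simulate the ROI time series for a planted label sequence
#'
#' Node i at TR t is
#' `x_i(t) = noise_sd * (sqrt(w) * s_g(t) + sqrt(1 - w) * e_i(t))`, with one
#' standard-normal community signal `s_k(t)` per community per TR and
#' independent standard-normal node noise, so same-community node pairs have
#' expected Pearson correlation `w` over any window in which they share a
#' community.
#'
#' @param model A [planted_model()].
#' @param truth A `flex_truth` from [generate_partition_sequence()].
#' @param subject_id Subject identifier.
#' @param amplitude Multiplicative amplitude (site offsets).
#' @param noise_sd Overrides `model$noise_sd` (motion-coupled noise).
#' @param seed Overrides `model$seed + 1` for the signal draw.
#' @return A `roi_ts` (rows = TRs, columns = nodes).
#' @export
generate_timeseries <- function(model, truth, subject_id = "synthetic",
                                amplitude = 1, noise_sd = model$noise_sd,
                                seed = model$seed + 1L) {
  stopifnot(inherits(model, "planted_model"), inherits(truth, "flex_truth"))
  N <- model$n_nodes; K <- model$n_communities; T <- model$t_scan
  if (T < 2L) stop("parameter error: t_scan must be at least 2")
  stopifnot(all(dim(truth$labels) == c(N, T)))
  w <- model$within_corr
  x <- withr::with_seed(seed, {
    s <- matrix(stats::rnorm(K * T), K, T)     # community signals, white
    e <- matrix(stats::rnorm(N * T), N, T)     # node noise
    idx <- cbind(as.vector(truth$labels), rep(seq_len(T), each = N))
    shared <- matrix(s[idx], N, T)
    amplitude * noise_sd * (sqrt(w) * shared + sqrt(1 - w) * e)
  })
  roi_timeseries(t(x), model$tr_seconds, subject_id)
}

#' Specification of a synthetic multi-site two-group cohort
#'
#' Emulates the structure of a multi-site case-control resting-state cohort:
#' patients ("ASD") carry a raised per-TR switching probability (`delta_p`)
#' on a designated node subset; sites differ in signal amplitude and noise;
#' sex ratio, age, and head motion are drawn per group, with motion linearly
#' inflating the noise scale so that covariate adjustment has something real
#' to remove. Demographic defaults mirror a typical ASD/TD comparison
#' (male-skewed patient group, higher patient head motion, patient symptom
#' scores around 8.5 vs near 0 in controls).
#'
#' @param n_per_group Subjects per group per site.
#' @param sites Site names.
#' @param site_amplitude Per-site amplitude multipliers (NULL = all 1).
#' @param site_noise Per-site noise multipliers (NULL = all 1).
#' @param delta_p Added switching probability in the patient group on the
#'   effect nodes (may be negative).
#' @param effect_subnetwork Subnetwork name whose nodes receive `delta_p`
#'   (used when an atlas is supplied to [generate_cohort()]).
#' @param effect_nodes Explicit node indices (overrides
#'   `effect_subnetwork`).
#' @param male_prob Per-group probability of male sex, named ASD/TD.
#' @param age_mean,age_sd Per-group age distributions (years), named.
#' @param fd_mean,fd_sd Per-group mean-FD distributions (mm), named.
#' @param motion_noise_coupling Linear coefficient c in
#'   `noise_sd * (1 + c * mean_fd)`.
#' @param ados_mean,ados_sd Per-group symptom-score distributions, named.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = 20L,
                        sites = c("SITE_A", "SITE_B"),
                        site_amplitude = NULL,
                        site_noise = NULL,
                        delta_p = 0.04,
                        effect_subnetwork = "default mode",
                        effect_nodes = NULL,
                        male_prob = c(ASD = 0.86, TD = 0.75),
                        age_mean = c(ASD = 16.35, TD = 15.86),
                        age_sd = c(ASD = 6.72, TD = 5.16),
                        fd_mean = c(ASD = 0.09, TD = 0.06),
                        fd_sd = c(ASD = 0.05, TD = 0.03),
                        motion_noise_coupling = 2,
                        ados_mean = c(ASD = 8.48, TD = 0.08),
                        ados_sd = c(ASD = 5.90, TD = 0.44)) {
  if (!length(n_per_group) %in% c(1L, length(sites)))
    stop("parameter error: n_per_group must have length 1 or length(sites)")
  n_per_group <- rep_len(as.integer(n_per_group), length(sites))
  if (is.null(site_amplitude)) site_amplitude <- rep(1, length(sites))
  if (is.null(site_noise)) site_noise <- rep(1, length(sites))
  stopifnot(all(n_per_group >= 1),
            length(site_amplitude) == length(sites),
            length(site_noise) == length(sites))
  structure(list(n_per_group = n_per_group, sites = sites,
                 site_amplitude = site_amplitude, site_noise = site_noise,
                 delta_p = delta_p, effect_subnetwork = effect_subnetwork,
                 effect_nodes = effect_nodes, male_prob = male_prob,
                 age_mean = age_mean, age_sd = age_sd,
                 fd_mean = fd_mean, fd_sd = fd_sd,
                 motion_noise_coupling = motion_noise_coupling,
                 ados_mean = ados_mean, ados_sd = ados_sd),
            class = "cohort_spec")
}

# truncated-normal draw, resampled until above `lower`
.rtrunc <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= lower))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic multi-site cohort with ground truth
#'
#' Draws demographics, planted label sequences and ROI time series for every
#' subject of a two-group multi-site cohort. Patient-group subjects receive
#' `spec$delta_p` extra switching probability on the effect nodes (clipped to
#' `[0, 1]`); motion inflates each subject's noise scale linearly. Every
#' subject is reproducible from `(model$seed, subject index)` alone.
#'
#' @param spec A [cohort_spec()].
#' @param model A [planted_model()] giving the base dynamics shared by all
#'   subjects.
#' @param atlas Optional `flex_atlas`; when given, `n_nodes` must match and
#'   `spec$effect_subnetwork` resolves the effect nodes.
#' @return List with `cohort` (a `flex_cohort`), `timeseries` (named list of
#'   `roi_ts`), `truth` (named list of `flex_truth`), and `effect_nodes`.
#' @export
generate_cohort <- function(spec, model, atlas = NULL) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(model, "planted_model"))
  if (!is.null(atlas) && n_nodes(atlas) != model$n_nodes)
    stop("parameter error: atlas has a different node count than the model")
  effect_nodes <- spec$effect_nodes
  if (is.null(effect_nodes)) {
    if (!is.null(atlas) && !is.null(spec$effect_subnetwork))
      effect_nodes <- which(atlas$subnetwork == spec$effect_subnetwork)
    else effect_nodes <- integer(0)
  }
  p_patient <- model$switch_prob
  p_patient[effect_nodes] <- pmin(pmax(
    p_patient[effect_nodes] + spec$delta_p, 0), 1)

  rows <- list(); ts_list <- list(); truth_list <- list()
  idx <- 0L
  for (si in seq_along(spec$sites)) {
    for (grp in .flex_groups) {
      for (r in seq_len(spec$n_per_group[si])) {
        idx <- idx + 1L
        id <- sprintf("sub%03d", idx)
        sseed <- (model$seed + 7919L * idx) %% 2147483647L
        demo <- withr::with_seed(sseed, {
          list(sex = if (stats::runif(1) < spec$male_prob[[grp]]) "male"
                     else "female",
               age = .rtrunc(1, spec$age_mean[[grp]], spec$age_sd[[grp]], 3),
               fd = .rtrunc(1, spec$fd_mean[[grp]], spec$fd_sd[[grp]], 0.005),
               ados = max(0, round(stats::rnorm(1, spec$ados_mean[[grp]],
                                                spec$ados_sd[[grp]]))))
        })
        sm <- model
        sm$seed <- sseed + 1L
        if (grp == "ASD") sm$switch_prob <- p_patient
        truth <- generate_partition_sequence(sm)
        noise <- model$noise_sd * spec$site_noise[si] *
          (1 + spec$motion_noise_coupling * demo$fd)
        ts <- generate_timeseries(sm, truth, subject_id = id,
                                  amplitude = spec$site_amplitude[si],
                                  noise_sd = noise, seed = sseed + 2L)
        rows[[idx]] <- data.frame(subject_id = id, group = grp,
                                  sex = demo$sex, age = demo$age,
                                  mean_fd = demo$fd, site = spec$sites[si],
                                  ados_total = demo$ados,
                                  tr_seconds = model$tr_seconds,
                                  stringsAsFactors = FALSE)
        ts_list[[id]] <- ts
        truth_list[[id]] <- truth
      }
    }
  }
  list(cohort = as_cohort(do.call(rbind, rows)),
       timeseries = ts_list, truth = truth_list,
       effect_nodes = effect_nodes)
}
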