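#' Configuration of an end-to-end flexibility analysis
#'
#' @param windowing A [windowing_params()].
#' @param modularity A [modularity_params()].
#' @param n_runs Community-detection runs per subject to average over
#'   (default 100, the conventional choice).
#' @param base_seed Base seed; each subject's run seeds are derived from it
#'   and a stable hash of the subject id, so adding or removing subjects
#'   never shifts another subject's results.
#' @param run_subset_analysis Whether [run_cohort()] repeats significant
#'   group comparisons in the motion/sex-matched subset.
#' @return A `flex_config` list.
#' @export
flex_config <- function(windowing = windowing_params(),
                        modularity = modularity_params(),
                        n_runs = 100L, base_seed = 1L,
                        run_subset_analysis = TRUE) {
  n_runs <- as.integer(n_runs)
  stopifnot(n_runs >= 1L)
  structure(list(windowing = windowing, modularity = modularity,
                 n_runs = n_runs, base_seed = as.integer(base_seed),
                 run_subset_analysis = isTRUE(run_subset_analysis)),
            class = "flex_config")
}

#' Stable per-subject seed
#'
#' Small deterministic hash of the subject id added to the base seed (kept
#' below 2^31).
#'
#' @param base_seed Integer base seed.
#' @param subject_id Subject identifier string.
#' @return Integer seed.
#' @export
subject_seed <- function(base_seed, subject_id) {
  h <- 0
  for (ch in utf8ToInt(subject_id)) h <- (h * 31 + ch) %% 1000003
  as.integer((base_seed + h) %% 2147483647)
}

#' Run the flexibility pipeline for one subject
#'
#' Builds the sliding-window dynamic network, runs the community-detection
#' ensemble with subject-specific seeds, and returns run-averaged
#' flexibility. Deterministic given the configuration and the subject's
#' data.
#'
#' @param ts A `roi_ts`.
#' @param atlas A `flex_atlas` matching the time-series columns.
#' @param config A [flex_config()].
#' @return A `flex_result`.
#' @export
run_subject <- function(ts, atlas, config = flex_config()) {
  stopifnot(inherits(ts, "roi_ts"))
  net <- build_dynamic_network(ts, config$windowing)
  mp <- config$modularity
  mp$seed <- subject_seed(config$base_seed, ts$subject_id)
  parts <- run_ensemble(net, mp, config$n_runs)
  run_averaged_flexibility(parts, atlas)
}

# flexibility results of a list of subjects -> one data.frame
.flex_table <- function(results, atlas) {
  rows <- lapply(names(results), function(id) {
    r <- results[[id]]
    cbind(data.frame(subject_id = id, stringsAsFactors = FALSE),
          as.data.frame(as.list(r$nodal), check.names = FALSE),
          as.data.frame(as.list(r$subnetwork), check.names = FALSE),
          data.frame(global = r$global_mean, n_runs = r$n_runs, T = r$T))
  })
  do.call(rbind, rows)
}

# group comparisons with FDR over a set of measures (columns of `values`)
.group_tests <- function(values, cohort, fdr = TRUE) {
  stats_list <- lapply(colnames(values), function(nm)
    ancova_group_f(values[, nm], cohort, term = nm))
  p <- vapply(stats_list, function(s) s$p_raw, numeric(1))
  p_adj <- if (fdr) bh_fdr(p) else rep(NA_real_, length(p))
  data.frame(term = colnames(values),
             F = vapply(stats_list, function(s) s$value, numeric(1)),
             df1 = 1,
             df2 = vapply(stats_list, function(s) s$df[2], numeric(1)),
             estimate = vapply(stats_list, function(s) s$estimate, numeric(1)),
             p_raw = p, p_fdr = p_adj, stringsAsFactors = FALSE)
}

# partial correlations of measures with ADOS, with FDR
.ados_correlations <- function(values, cohort) {
  keep <- !is.na(cohort$ados_total)
  cz <- cohort[keep, , drop = FALSE]
  Z <- .covariate_matrix(cz)
  res <- lapply(colnames(values), function(nm)
    partial_pearson(values[keep, nm], cz$ados_total, Z, term = nm))
  p <- vapply(res, function(s) s$p_raw, numeric(1))
  data.frame(term = colnames(values),
             r = vapply(res, function(s) s$value, numeric(1)),
             df = vapply(res, function(s) s$df[1], numeric(1)),
             p_raw = p, p_fdr = bh_fdr(p), stringsAsFactors = FALSE)
}

#' Run the full cohort analysis
#'
#' For every subject: dynamic network, community ensemble, flexibility.
#' Then: demographic group comparisons (Welch t for age/motion/symptoms,
#' chi-square for sex), covariate-adjusted group ANCOVAs at the global level
#' (single test, reported uncorrected), the subnetwork level (FDR across the
#' six subnetworks) and the nodal level (FDR across nodes), partial
#' correlations of flexibility with the symptom score in the entire sample
#' and in patients only (FDR within each family), and optionally a repeat of
#' the group comparisons in the motion/sex-matched subset. Subjects whose
#' pipeline fails (e.g. scan shorter than the window) are logged and do not
#' affect the others.
#'
#' @param cohort A `flex_cohort`.
#' @param timeseries Named list of `roi_ts`, keyed by subject id.
#' @param atlas A `flex_atlas`.
#' @param config A [flex_config()].
#' @return A `flex_cohort_results` list: `flexibility` (per-subject table),
#'   `demographics`, `global`, `subnetwork`, `nodal`, `correlations`
#'   (`entire` and `patients`), `subset` (matched-subset re-analysis or
#'   NULL), `failures`.
#' @export
run_cohort <- function(cohort, timeseries, atlas, config = flex_config()) {
  stopifnot(inherits(cohort, "flex_cohort"))
  missing_ts <- setdiff(cohort$subject_id, names(timeseries))
  if (length(missing_ts))
    stop("missing time series for: ", paste(missing_ts, collapse = ", "))

  results <- list(); failures <- list()
  for (id in cohort$subject_id) {
    res <- tryCatch(run_subject(timeseries[[id]], atlas, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[id]] <- conditionMessage(res)
      message(sprintf("subject %s failed: %s", id, conditionMessage(res)))
    } else results[[id]] <- res
  }
  cohort <- cohort[cohort$subject_id %in% names(results), , drop = FALSE]
  flex_tab <- .flex_table(results, atlas)

  asd <- cohort$group == "ASD"
  demographics <- list(
    age = welch_t(mean(cohort$age[asd]), stats::sd(cohort$age[asd]), sum(asd),
                  mean(cohort$age[!asd]), stats::sd(cohort$age[!asd]),
                  sum(!asd), term = "age"),
    sex = chisq_2x2(table(factor(cohort$group, .flex_groups),
                          factor(cohort$sex, .flex_sexes))),
    mean_fd = welch_t(mean(cohort$mean_fd[asd]), stats::sd(cohort$mean_fd[asd]),
                      sum(asd), mean(cohort$mean_fd[!asd]),
                      stats::sd(cohort$mean_fd[!asd]), sum(!asd),
                      term = "mean_fd"))
  has_ados <- !all(is.na(cohort$ados_total))
  if (has_ados) {
    ka <- asd & !is.na(cohort$ados_total)
    kt <- !asd & !is.na(cohort$ados_total)
    demographics$ados <- welch_t(
      mean(cohort$ados_total[ka]), stats::sd(cohort$ados_total[ka]), sum(ka),
      mean(cohort$ados_total[kt]), stats::sd(cohort$ados_total[kt]), sum(kt),
      term = "ados_total")
  }

  sub_cols <- levels(atlas$subnetwork)
  nodal_cols <- atlas$labels
  global <- .group_tests(flex_tab[, "global", drop = FALSE], cohort,
                         fdr = FALSE)
  subnetwork <- .group_tests(as.matrix(flex_tab[, sub_cols]), cohort)
  nodal <- .group_tests(as.matrix(flex_tab[, nodal_cols]), cohort)

  correlations <- NULL
  if (has_ados) {
    vals <- as.matrix(flex_tab[, c("global", sub_cols)])
    correlations <- list(entire = .ados_correlations(vals, cohort),
                         patients = tryCatch(
                           .ados_correlations(vals[asd, , drop = FALSE],
                                              cohort[asd, , drop = FALSE]),
                           error = function(e) NULL))
  } else warning("no ADOS scores available; correlation stage skipped")

  subset_res <- NULL
  if (config$run_subset_analysis) {
    sm <- subset_match(cohort)
    if (nrow(sm$cohort) && length(unique(sm$cohort$group)) == 2L) {
      keep <- flex_tab$subject_id %in% sm$cohort$subject_id
      subset_res <- list(
        filter = sm,
        global = .group_tests(flex_tab[keep, "global", drop = FALSE],
                              sm$cohort, fdr = FALSE),
        subnetwork = .group_tests(as.matrix(flex_tab[keep, sub_cols]),
                                  sm$cohort))
    }
  }

  structure(list(flexibility = flex_tab, demographics = demographics,
                 global = global, subnetwork = subnetwork, nodal = nodal,
                 correlations = correlations, subset = subset_res,
                 failures = failures, atlas = atlas, config = config),
            class = "flex_cohort_results")
}

#' @export
print.flex_cohort_results <- function(x, ...) {
  cat(sprintf("<flex_cohort_results> %d subjects analysed, %d failed\n",
              nrow(x$flexibility), length(x$failures)))
  cat("\nGlobal flexibility ANCOVA (uncorrected):\n")
  print(x$global, row.names = FALSE)
  cat("\nSubnetwork flexibility ANCOVA (BH-FDR over subnetworks):\n")
  print(x$subnetwork, row.names = FALSE)
  invisible(x)
}

#' Write the cohort results bundle to disk
#'
#' Writes the per-subject flexibility table and the statistical summaries as
#' CSV plus one JSON summary.
#'
#' @param results A `flex_cohort_results`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  stopifnot(inherits(results, "flex_cohort_results"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(results$flexibility, file.path(dir, "flexibility.csv"),
                   row.names = FALSE)
  utils::write.csv(results$subnetwork, file.path(dir, "subnetwork_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(results$nodal, file.path(dir, "nodal_tests.csv"),
                   row.names = FALSE)
  summary <- list(
    n_subjects = nrow(results$flexibility),
    failures = results$failures,
    global = results$global,
    subnetwork = results$subnetwork,
    demographics = lapply(results$demographics, function(s)
      list(statistic = s$statistic_name, value = s$value, p = s$p_raw)))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
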