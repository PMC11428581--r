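#' Build and validate a cohort table
#'
#' A cohort table is a data frame with one row per subject: `subject_id`,
#' `group` (ASD/TD), `sex` (male/female), `age` (years), `mean_fd` (mm),
#' `site`, and optionally `ados_total` (symptom-severity total, may be NA),
#' `tr_seconds`, and `qc_pass` (manual-quality flag; absent column means all
#' pass).
#'
#' @param df Data frame with the columns above.
#' @return A validated `flex_cohort` (a data.frame subclass).
#' @export
as_cohort <- function(df) {
  need <- c("subject_id", "group", "sex", "age", "mean_fd", "site")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort format error: missing column(s): ", paste(miss, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id))
    stop("cohort format error: duplicate subject_id")
  badg <- setdiff(unique(df$group), .flex_groups)
  if (length(badg))
    stop("cohort format error: unknown group level(s): ",
         paste(badg, collapse = ", "))
  bads <- setdiff(unique(df$sex), .flex_sexes)
  if (length(bads))
    stop("cohort format error: unknown sex level(s): ",
         paste(bads, collapse = ", "))
  if (any(!is.finite(df$age)) || any(df$age <= 0))
    stop("cohort format error: age must be positive")
  if (any(!is.finite(df$mean_fd)) || any(df$mean_fd < 0))
    stop("cohort format error: mean_fd must be non-negative")
  df$site <- as.character(df$site)
  if (!"ados_total" %in% names(df)) df$ados_total <- NA_real_
  if (any(df$ados_total < 0, na.rm = TRUE))
    stop("cohort format error: ados_total must be non-negative")
  class(df) <- c("flex_cohort", "data.frame")
  df
}

#' Read a cohort table from CSV
#'
#' @param path CSV path with header `subject_id,group,sex,age,mean_fd,site,
#'   ados_total` (`ados_total` cells may be empty; optional `tr_seconds` and
#'   `qc_pass` columns are honoured).
#' @return A `flex_cohort`.
#' @export
load_cohort <- function(path) {
  as_cohort(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a cohort table to CSV
#' @param cohort A `flex_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "flex_cohort"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply the cohort-level quality-control exclusions
#'
#' Excludes subjects with high head motion (mean framewise displacement above
#' `max_mean_fd`), a repetition time different from `required_tr`, or a failed
#' manual quality rating (`qc_pass == FALSE`, when that column is present);
#' afterwards drops whole sites left with fewer than `min_site_n` subjects.
#' The site-size rule is applied last, after all per-subject rules. Each
#' excluded subject is logged with the first rule it violated, in that order.
#'
#' @param cohort A `flex_cohort`. Per-subject TR must be available either as
#'   a `tr_seconds` column or via the `tr_seconds` argument.
#' @param max_mean_fd Motion threshold in mm (subjects strictly above are
#'   excluded).
#' @param required_tr Required repetition time in seconds; `NA` disables the
#'   rule.
#' @param min_site_n Minimum per-site subject count after the per-subject
#'   rules.
#' @param tr_seconds Optional scalar or per-subject TR vector used when the
#'   cohort has no `tr_seconds` column.
#' @return A list of class `flex_filter`: `cohort` (retained rows) and
#'   `exclusions` (data frame `subject_id`, `reason`). Filtering to an empty
#'   cohort raises a warning, not an error.
#' @export
subject_filter <- function(cohort, max_mean_fd = 0.2, required_tr = 2,
                           min_site_n = 10, tr_seconds = NULL) {
  stopifnot(inherits(cohort, "flex_cohort"))
  n <- nrow(cohort)
  tr <- cohort$tr_seconds
  if (is.null(tr)) {
    if (is.null(tr_seconds) && !is.na(required_tr))
      stop("subject_filter requires per-subject TR (tr_seconds column or argument)")
    tr <- rep_len(if (is.null(tr_seconds)) NA_real_ else tr_seconds, n)
  }
  qc <- if ("qc_pass" %in% names(cohort)) cohort$qc_pass else rep(TRUE, n)

  reason <- rep(NA_character_, n)
  hit <- cohort$mean_fd > max_mean_fd
  reason[hit] <- sprintf("mean FD > %g mm", max_mean_fd)
  if (!is.na(required_tr)) {
    hit2 <- is.na(reason) & tr != required_tr
    reason[hit2] <- sprintf("TR != %g s", required_tr)
  }
  hit3 <- is.na(reason) & !qc
  reason[hit3] <- "QC rating fail"

  keep <- is.na(reason)
  site_n <- table(cohort$site[keep])
  small <- names(site_n)[site_n < min_site_n]
  hit4 <- keep & cohort$site %in% small
  reason[hit4] <- sprintf("site n < %d", min_site_n)
  keep <- is.na(reason)

  out <- cohort[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("subject_filter: no subjects remain after filtering")
  structure(list(cohort = out,
                 exclusions = data.frame(
                   subject_id = cohort$subject_id[!keep],
                   reason = reason[!keep],
                   stringsAsFactors = FALSE)),
            class = "flex_filter")
}

#' Draw the motion- and sex-matched comparison subset
#'
#' Implements the sensitivity subset: all patient (ASD) rows are retained;
#' control (TD) males with mean FD strictly above 0.05 mm and TD females with
#' mean FD strictly above 0.06 mm are excluded, yielding a subset in which sex
#' ratio and head motion are matched between groups.
#'
#' @param cohort A `flex_cohort`.
#' @param male_fd_max TD-male retention threshold in mm (default 0.05).
#' @param female_fd_max TD-female retention threshold in mm (default 0.06).
#' @return A `flex_filter` list (`cohort`, `exclusions`) as in
#'   [subject_filter()].
#' @export
subset_match <- function(cohort, male_fd_max = 0.05, female_fd_max = 0.06) {
  stopifnot(inherits(cohort, "flex_cohort"))
  drop_m <- cohort$group == "TD" & cohort$sex == "male" &
    cohort$mean_fd > male_fd_max
  drop_f <- cohort$group == "TD" & cohort$sex == "female" &
    cohort$mean_fd > female_fd_max
  reason <- rep(NA_character_, nrow(cohort))
  reason[drop_m] <- sprintf("TD male with mean FD > %g mm", male_fd_max)
  reason[drop_f] <- sprintf("TD female with mean FD > %g mm", female_fd_max)
  keep <- is.na(reason)
  if (!any(keep))
    warning("subset_match: no subjects remain")
  structure(list(cohort = cohort[keep, , drop = FALSE],
                 exclusions = data.frame(
                   subject_id = cohort$subject_id[!keep],
                   reason = reason[!keep],
                   stringsAsFactors = FALSE)),
            class = "flex_filter")
}

#' @export
print.flex_filter <- function(x, ...) {
  cat(sprintf("<flex_filter> %d retained, %d excluded\n",
              nrow(x$cohort), nrow(x$exclusions)))
  if (nrow(x$exclusions))
    print(table(x$exclusions$reason))
  invisible(x)
}
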