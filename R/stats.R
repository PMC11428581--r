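flex_stat <- function(statistic_name, value, df, p_raw, term,
                      p_fdr = NA_real_, estimate = NA_real_) {
  stopifnot(statistic_name %in% c("welch_t", "chi_square", "ancova_F",
                                  "partial_r"))
  if (!is.na(p_raw) && (p_raw < 0 || p_raw > 1)) stop("p_raw outside [0, 1]")
  structure(list(statistic_name = statistic_name, value = value, df = df,
                 p_raw = p_raw, p_fdr = p_fdr, term = term,
                 estimate = estimate),
            class = "flex_stat")
}

#' @export
print.flex_stat <- function(x, ...) {
  cat(sprintf("<flex_stat> %s[%s] = %.4f (df = %s), p = %.4g%s\n",
              x$statistic_name, x$term, x$value,
              paste(signif(x$df, 5), collapse = ", "), x$p_raw,
              if (!is.na(x$p_fdr)) sprintf(", FDR p = %.4g", x$p_fdr) else ""))
  invisible(x)
}

#' Welch two-sample t test from summary statistics
#'
#' Unequal-variance t test computed from group means, standard deviations and
#' sizes (the form in which demographic tables are published):
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite degrees
#' of freedom and a two-sided p value.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @param term Label for the compared variable.
#' @return A `flex_stat` with `statistic_name = "welch_t"`.
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2, term = "group") {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0)
    stop("degenerate: both standard deviations are zero")
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  flex_stat("welch_t", t, df, 2 * stats::pt(-abs(t), df), term,
            estimate = mean1 - mean2)
}

#' Pearson chi-square test on a 2 x 2 table
#'
#' No continuity correction (the convention under which published sex-ratio
#' chi-squares in this literature reproduce exactly); df = 1.
#'
#' @param table 2 x 2 matrix of non-negative counts with no zero margin.
#' @param term Label for the compared variable.
#' @return A `flex_stat` with `statistic_name = "chi_square"`.
#' @export
chisq_2x2 <- function(table, term = "sex") {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate: zero margin in 2 x 2 table")
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  flex_stat("chi_square", unname(res$statistic), unname(res$parameter),
            res$p.value, term)
}

# Design matrix for covariate adjustment: age, sex (female = 1), mean FD,
# site dummies (reference = alphabetically first site). Errors on constant
# columns instead of silently dropping them.
.covariate_matrix <- function(cohort,
                              covariates = c("age", "sex", "mean_fd", "site")) {
  cols <- list()
  if ("age" %in% covariates) cols$age <- cohort$age
  if ("sex" %in% covariates) cols$sex <- as.numeric(cohort$sex == "female")
  if ("mean_fd" %in% covariates) cols$mean_fd <- cohort$mean_fd
  X <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), nrow = nrow(cohort), ncol = 0)
  if ("site" %in% covariates && length(unique(cohort$site)) > 1L) {
    lev <- sort(unique(cohort$site))
    dummies <- vapply(lev[-1], function(s) as.numeric(cohort$site == s),
                      numeric(nrow(cohort)))
    colnames(dummies) <- paste0("site", lev[-1])
    X <- cbind(X, dummies)
  }
  const <- which(apply(X, 2L, function(v) stats::sd(v) == 0))
  if (length(const))
    stop("design error: constant covariate column(s): ",
         paste(colnames(X)[const], collapse = ", "))
  X
}

#' Covariate-adjusted group comparison (ANCOVA)
#'
#' Ordinary least squares of the response on an intercept, the group
#' indicator, and the covariates (age, sex coded female = 1, mean FD, and
#' dummy-coded site with the alphabetically first site as reference). The
#' reported F for the single-df group term is the squared t of the group
#' coefficient.
#'
#' @param response Per-subject numeric response (e.g. a flexibility value),
#'   in cohort row order.
#' @param cohort A `flex_cohort`.
#' @param covariates Subset of `c("age", "sex", "mean_fd", "site")`.
#' @param term Label for the response being compared.
#' @return A `flex_stat` with `statistic_name = "ancova_F"`; `estimate` is
#'   the ASD-minus-TD adjusted difference (positive = higher in ASD).
#' @export
ancova_group_f <- function(response, cohort,
                           covariates = c("age", "sex", "mean_fd", "site"),
                           term = "flexibility") {
  stopifnot(inherits(cohort, "flex_cohort"),
            length(response) == nrow(cohort))
  if (length(unique(cohort$group)) < 2L)
    stop("both groups must be present")
  if (min(table(cohort$group)) < 2L)
    stop("need at least 2 subjects per group")
  grp <- as.numeric(cohort$group == "ASD")
  X <- cbind(`(Intercept)` = 1, group = grp,
             .covariate_matrix(cohort, covariates))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design error: rank-deficient design; collinear column(s): ",
         paste(aliased, collapse = ", "))
  }
  n <- nrow(X); p <- ncol(X)
  fit <- stats::lm.fit(X, response)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - p)
  XtXinv_gg <- chol2inv(chol(crossprod(X)))[2L, 2L]
  b <- fit$coefficients["group"]
  t <- b / sqrt(sigma2 * XtXinv_gg)
  Fv <- t^2
  df <- c(1, n - p)
  flex_stat("ancova_F", unname(Fv), df,
            stats::pf(unname(Fv), 1, n - p, lower.tail = FALSE),
            term, estimate = unname(b))
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up FDR adjustment, monotone-enforced and capped at 1, returned in
#' input order.
#'
#' @param p_values Numeric vector of raw p values in `[0, 1]`.
#' @return Adjusted p values, same order and length.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Partial Pearson correlation after covariate residualization
#'
#' Both variables are residualized on an intercept plus the covariate
#' columns by least squares; the partial correlation is the Pearson r of the
#' residuals, with `t = r sqrt((n - 2 - k) / (1 - r^2))` on `n - 2 - k`
#' degrees of freedom (k = number of covariate columns).
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates Optional numeric matrix / data frame of covariate
#'   columns (no intercept; e.g. from the design used for ANCOVA).
#' @param term Label for the tested association.
#' @return A `flex_stat` with `statistic_name = "partial_r"`.
#' @export
partial_pearson <- function(x, y, covariates = NULL, term = "ados") {
  n <- length(x)
  stopifnot(length(y) == n)
  Z <- if (is.null(covariates))
    matrix(1, n, 1) else cbind(1, as.matrix(covariates))
  k <- ncol(Z) - 1L
  if (n <= k + 2L)
    stop(sprintf("insufficient df: n = %d with %d covariates", n, k))
  rx <- stats::lm.fit(Z, x)$residuals
  ry <- stats::lm.fit(Z, y)$residuals
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  t <- r * sqrt(df / (1 - r^2))
  flex_stat("partial_r", r, df, 2 * stats::pt(-abs(t), df), term)
}
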