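#' Pearson chi-squared test on a contingency table
#'
#' Condition-by-category counts compared by the Pearson statistic without
#' continuity correction, df = (r-1)(c-1), upper-tail p.
#'
#' @param table Integer matrix of counts, >= 2 rows and >= 2 columns, no
#'   all-zero row or column margin.
#' @return A list: `statistic`, `df`, `p`.
#' @export
chi_squared_table <- function(table) {
  tab <- as.matrix(table)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("table needs >= 2 rows and >= 2 columns", call. = FALSE)
  if (any(tab < 0) || any(!is.finite(tab)))
    stop("counts must be finite and >= 0", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin: expected counts are undefined", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Welch's unequal-variance t test
#'
#' @param sample_a,sample_b Numeric samples, each with n >= 2 and nonzero
#'   variance.
#' @return A list: `t`, `df` (Welch-Satterthwaite), `p` (two-sided).
#' @export
welch_t <- function(sample_a, sample_b) {
  for (s in list(a = sample_a, b = sample_b)) {
    if (length(s) < 2 || any(!is.finite(s)))
      stop("each sample needs >= 2 finite values", call. = FALSE)
  }
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0)
    stop("degenerate samples: both variances are zero", call. = FALSE)
  res <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided D = sup |ECDF difference|; exact small-sample p when both
#' samples have n <= 25 (or when forced), asymptotic otherwise.
#'
#' @param sample_a,sample_b Numeric samples, each non-empty with n >= 2.
#' @param exact Logical; default chooses the exact distribution when both
#'   n <= 25.
#' @return A list: `D`, `p`.
#' @export
ks_two_sample <- function(sample_a, sample_b, exact = NULL) {
  for (s in list(sample_a, sample_b)) {
    if (length(s) < 2 || any(!is.finite(s)))
      stop("each sample needs >= 2 finite values", call. = FALSE)
  }
  if (is.null(exact)) exact <- length(sample_a) <= 25 && length(sample_b) <= 25
  res <- suppressWarnings(stats::ks.test(sample_a, sample_b, exact = exact))
  list(D = unname(res$statistic), p = res$p.value)
}

#' Two-way ANOVA without interaction
#'
#' Additive two-factor ANOVA as reported in figure legends (row and column
#' factors only). Type-II sums of squares, so unbalanced layouts are
#' handled: each factor is tested by the residual-sum-of-squares drop
#' relative to the model containing the other factor.
#'
#' @param values Numeric response.
#' @param factor_a,factor_b Factors (coerced), each with >= 2 observed
#'   levels.
#' @return A data frame with one row per factor: `factor`, `F`, `df1`,
#'   `df2`, `p`. Constant responses give F = 0, p = 1.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  fa <- factor(factor_a); fb <- factor(factor_b)
  if (nlevels(fa) < 2 || nlevels(fb) < 2)
    stop("each factor needs >= 2 levels", call. = FALSE)
  if (length(values) != length(fa) || length(values) != length(fb))
    stop("values and factors must have equal length", call. = FALSE)
  full <- stats::lm(values ~ fa + fb)
  rss_full <- sum(stats::residuals(full)^2)
  df_resid <- full$df.residual
  if (df_resid < 1) stop("no residual degrees of freedom", call. = FALSE)
  one <- function(drop_which) {
    reduced <- if (drop_which == "a") stats::lm(values ~ fb)
               else stats::lm(values ~ fa)
    ss <- sum(stats::residuals(reduced)^2) - rss_full
    df1 <- if (drop_which == "a") nlevels(fa) - 1 else nlevels(fb) - 1
    mse <- rss_full / df_resid
    if (ss <= 1e-12 * max(sum(values^2), 1) || mse == 0) {
      # no explainable variation (e.g. constant response)
      return(c(F = 0, df1 = df1, df2 = df_resid, p = 1))
    }
    Fv <- (ss / df1) / mse
    c(F = Fv, df1 = df1, df2 = df_resid,
      p = stats::pf(Fv, df1, df_resid, lower.tail = FALSE))
  }
  ra <- one("a"); rb <- one("b")
  data.frame(factor = c("a", "b"),
             F = c(ra["F"], rb["F"]),
             df1 = c(ra["df1"], rb["df1"]),
             df2 = c(ra["df2"], rb["df2"]),
             p = c(ra["p"], rb["p"]),
             row.names = NULL)
}

#' Tidy statistics table for a set of pairwise comparisons
#'
#' Convenience wrapper producing one tidy row per test, as written into
#' result bundles. P-values are reported unadjusted; set `adjust` to
#' `"holm"` to add an adjusted column.
#'
#' @param tests A list of lists, each with `test` ("chisq", "welch",
#'   "ks"), `groups` (label), and the samples or table under `a`, `b`, or
#'   `table`.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return A data frame: `test`, `groups`, `statistic`, `df`, `p`
#'   (optionally `p_adj`), `n`.
#' @export
compare_conditions <- function(tests, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  rows <- lapply(tests, function(tt) {
    switch(tt$test,
      chisq = {
        r <- chi_squared_table(tt$table)
        data.frame(test = "chisq", groups = tt$groups,
                   statistic = r$statistic, df = r$df, p = r$p,
                   n = sum(tt$table))
      },
      welch = {
        r <- welch_t(tt$a, tt$b)
        data.frame(test = "welch", groups = tt$groups, statistic = r$t,
                   df = r$df, p = r$p, n = length(tt$a) + length(tt$b))
      },
      ks = {
        r <- ks_two_sample(tt$a, tt$b)
        data.frame(test = "ks", groups = tt$groups, statistic = r$D,
                   df = NA_real_, p = r$p,
                   n = length(tt$a) + length(tt$b))
      },
      stop("unknown test: ", tt$test, call. = FALSE))
  })
  out <- do.call(rbind, rows)
  if (adjust == "holm") out$p_adj <- stats::p.adjust(out$p, "holm")
  out
}
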