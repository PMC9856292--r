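# Group-statistics layer: thin, convention-pinned wrappers around base R's
# test routines, each returning a uniform `stat_result` so the pipeline can
# tabulate them. Conventions that matter downstream:
#   * pooled (not Welch) two-sample t; statistic sign follows mean(x) - mean(y)
#     in the caller's argument order;
#   * paired t computed on (before - after);
#   * Mann-Whitney U with tie-corrected normal-approximation z;
#   * Pearson chi-square without continuity correction;
#   * two-level repeated-measures ANOVA (F identical to paired-t squared).

stat_result <- function(method, statistic, df, p, direction = NULL, extra = list()) {
  structure(c(list(method = method, statistic = unname(statistic),
                   df = unname(df), p = unname(p), p_adjusted = NULL,
                   direction_convention = direction), extra),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: statistic = %.4f, df = %s, p = %.4g\n",
              x$method, x$statistic, paste(round(x$df, 2), collapse = ", "), x$p))
  invisible(x)
}

#' Pooled-variance two-sample t-test
#'
#' Student's t with pooled variance, `df = n_x + n_y - 2`. The sign of the
#' statistic follows `mean(x) - mean(y)` in the order the caller passes the
#' groups.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return `stat_result`.
#' @export
two_sample_t_pooled <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need at least 2 values per group")
  if (stats::var(x) + stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(stat_result("pooled t", 0, length(x) + length(y) - 2, 1,
                         "mean(x) - mean(y)"))
    }
    stop("zero pooled variance with unequal means: t is infinite")
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  stat_result("pooled t", tt$statistic, tt$parameter, tt$p.value,
              "mean(x) - mean(y)")
}

#' Paired t-test
#'
#' One-sample t on the differences `before - after`, `df = n - 1`. A
#' negative statistic therefore means the values increased.
#'
#' @param before,after paired numeric vectors of equal length >= 2.
#' @return `stat_result`.
#' @export
paired_t <- function(before, after) {
  if (length(before) != length(after)) stop("paired vectors differ in length")
  if (length(before) < 2) stop("need at least 2 pairs")
  d <- before - after
  if (stats::var(d) == 0) {
    return(stat_result("paired t", if (mean(d) == 0) 0 else NA_real_,
                       length(d) - 1, if (mean(d) == 0) 1 else NA_real_,
                       "before - after",
                       extra = list(zero_variance = TRUE)))
  }
  tt <- stats::t.test(d)
  stat_result("paired t", tt$statistic, tt$parameter, tt$p.value,
              "before - after")
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples, reported as the U
#' statistic for `x` with a tie-corrected normal-approximation z and
#' two-sided p (no continuity correction).
#'
#' @param x,y numeric vectors, non-empty.
#' @return `stat_result` (df is `NA`; z is carried in `$z`).
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 == 0) {
    return(stat_result("Mann-Whitney U", U, NA_real_, 1, "U for x",
                       extra = list(z = 0)))
  }
  z <- (U - mu) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  stat_result("Mann-Whitney U", U, NA_real_, p, "U for x", extra = list(z = z))
}

#' Pearson chi-square test on a contingency table
#'
#' No continuity correction by default (configurable), so the statistic is
#' the plain Pearson sum over cells.
#'
#' @param table matrix of non-negative integer counts with positive margins.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return `stat_result`.
#' @export
chi_square <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (any(table < 0) || any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("contingency table needs non-negative counts and positive margins")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  stat_result("chi-square", ct$statistic, ct$parameter, ct$p.value)
}

#' Two-level repeated-measures ANOVA
#'
#' One-way within-subject ANOVA with two time levels (pre, post), fitted
#' with `aov` and a subject error stratum; `F` has df (1, n - 1) and equals
#' the squared paired-t statistic.
#'
#' @param pre,post paired numeric vectors of equal length >= 2.
#' @return `stat_result` (df is `c(1, n - 1)`).
#' @export
rm_anova_two_level <- function(pre, post) {
  if (length(pre) != length(post)) stop("paired vectors differ in length")
  n <- length(pre)
  if (n < 2) stop("need at least 2 subjects")
  if (stats::var(pre - post) == 0) {
    return(stat_result("RM-ANOVA (2 levels)", if (mean(pre - post) == 0) 0 else NA_real_,
                       c(1, n - 1), if (mean(pre - post) == 0) 1 else NA_real_,
                       extra = list(zero_variance = TRUE)))
  }
  d <- data.frame(y = c(pre, post),
                  time = factor(rep(c("pre", "post"), each = n), c("pre", "post")),
                  subject = factor(rep(seq_len(n), 2)))
  fit <- stats::aov(y ~ time + Error(subject / time), data = d)
  tab <- summary(fit)[["Error: subject:time"]][[1]]
  stat_result("RM-ANOVA (2 levels)", tab["time", "F value"],
              c(tab["time", "Df"], tab["Residuals", "Df"]),
              tab["time", "Pr(>F)"])
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone in the sorted order and capped at 1.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, elementwise >= the input.
#' @export
fdr_bh <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}
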