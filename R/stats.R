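#' One-way (single-factor) ANOVA across groups
#'
#' Wraps the textbook equal-variance decomposition (via
#' [stats::oneway.test()]) and reports the quantities printed in the
#' figure legends: F, its degrees of freedom, the p-value and the critical
#' F at the chosen alpha.
#'
#' @param groups named list of numeric vectors, one per group; unequal n is
#'   allowed but every group needs n >= 2.
#' @param alpha significance level for the reported `F_crit`.
#' @param warn_small warn when any group has exactly 2 observations.
#' @return list of class `anova_result`: `F`, `df` (between, within), `p`,
#'   `F_crit`, `alpha`, `n`.
#' @export
one_way_anova <- function(groups, alpha = 0.05, warn_small = TRUE) {
  stopifnot(is.list(groups), length(groups) >= 2)
  n <- vapply(groups, length, integer(1))
  if (any(n < 2)) {
    bad <- names(groups)[n < 2]
    if (is.null(bad) || !length(bad)) bad <- which(n < 2)
    stop("one_way_anova(): group(s) with fewer than 2 observations: ",
         paste(bad, collapse = ", "))
  }
  if (warn_small && any(n == 2))
    warning("one_way_anova(): group(s) with n = 2 included; the F-test has ",
            "very little power there")
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_along(groups), times = n))
  df <- c(between = length(groups) - 1L, within = length(values) -
            length(groups))
  if (stats::var(values) == 0) {
    res <- list(statistic = 0, p.value = 1)
  } else {
    ow <- stats::oneway.test(values ~ fac, var.equal = TRUE)
    res <- list(statistic = unname(ow$statistic), p.value = ow$p.value)
    if (is.nan(res$statistic)) { res$statistic <- 0; res$p.value <- 1 }
  }
  structure(list(F = res$statistic, df = df, p = res$p.value,
                 F_crit = f_critical(alpha, df[["between"]], df[["within"]]),
                 alpha = alpha, n = n),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d,%d) = %.4g, p = %.4g (F_crit %.3f at a = %g)\n",
              x$df[["between"]], x$df[["within"]], x$F, x$p, x$F_crit,
              x$alpha))
  invisible(x)
}

#' One-way ANOVA from summary statistics
#'
#' Recomputes the equal-variance F-ratio from per-group means, standard
#' deviations (or SEMs) and sample sizes — the algebraic identity that lets
#' published mean +/- SEM tables be checked without the raw data.
#'
#' @param means,ns numeric vectors per group.
#' @param sds per-group sample standard deviations; alternatively give
#'   `sems`.
#' @param sems per-group standard errors (converted via `sd = sem * sqrt(n)`).
#' @param alpha significance level for `F_crit`.
#' @return an `anova_result`.
#' @export
anova_from_summary <- function(means, sds = NULL, ns, sems = NULL,
                               alpha = 0.05) {
  if (is.null(sds)) {
    if (is.null(sems)) stop("anova_from_summary(): give sds or sems")
    sds <- sems * sqrt(ns)
  }
  stopifnot(length(means) == length(sds), length(means) == length(ns),
            all(ns >= 2))
  k <- length(means)
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  df <- c(between = k - 1L, within = as.integer(N - k))
  F <- if (ssw == 0) {
    if (ssb == 0) 0 else Inf
  } else (ssb / df[["between"]]) / (ssw / df[["within"]])
  p <- if (is.infinite(F)) 0 else
    stats::pf(F, df[["between"]], df[["within"]], lower.tail = FALSE)
  if (F == 0) p <- 1
  structure(list(F = F, df = df, p = p,
                 F_crit = f_critical(alpha, df[["between"]], df[["within"]]),
                 alpha = alpha, n = ns),
            class = "anova_result")
}

#' Critical value of the F distribution
#' @param alpha upper-tail probability.
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @return the upper-alpha quantile.
#' @examples
#' f_critical(0.05, 3, 20) # 3.098
#' @export
f_critical <- function(alpha, df1, df2) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("f_critical(): alpha must lie in (0, 1)")
  if (df1 < 1 || df2 < 1) stop("f_critical(): degrees of freedom must be >= 1")
  stats::qf(1 - alpha, df1, df2)
}

#' Welch's unequal-variance two-tailed t-test
#'
#' @param a,b numeric vectors, n >= 2 each.
#' @return list of class `ttest_result`: `t`, `df`
#'   (Welch-Satterthwaite), `p` (two-sided), group means.
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    ## degenerate: no variance anywhere
    t <- if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b))
    p <- if (mean(a) == mean(b)) 1 else 0
    df <- length(a) + length(b) - 2
  } else {
    tt <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
    t <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
  }
  structure(list(t = t, df = df, p = p, mean_a = mean(a), mean_b = mean(b)),
            class = "ttest_result")
}

#' Simple linear regression
#'
#' Ordinary least squares of `y` on `x`, reporting slope, intercept,
#' Pearson r and the two-sided p-value for the slope.
#'
#' @param x,y numeric vectors, n >= 3, `x` not constant.
#' @return list of class `linreg_result`.
#' @export
linreg <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0) stop("linreg(): x is constant")
  fit <- stats::lm(y ~ x)
  ## summary.lm warns on an exactly collinear fit; r = +/-1 is a legitimate
  ## input here
  sm <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2])
  r <- suppressWarnings(stats::cor(x, y))
  p <- if (nrow(sm$coefficients) < 2 || stats::var(y) == 0) 1
       else sm$coefficients[2, 4]
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 r = r, p = p),
            class = "linreg_result")
}

#' Significance stars at the conventional thresholds
#' @param p p-value(s).
#' @return `""`, `"*"`, `"**"` or `"***"` (p < 0.05, 0.01, 0.001).
#' @export
significance_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) "" else if (pp < 0.001) "***" else if (pp < 0.01) "**"
    else if (pp < 0.05) "*" else ""
  }, character(1))
}

#' Category summary table across groups
#'
#' Builds the published-table layout: one row per structural category with
#' per-group mean +/- SEM, the one-way ANOVA F and p across groups and a
#' significance flag at `F > F_crit`. With a single group only the means
#' are reported. No multiple-testing correction is applied by default,
#' mirroring per-category ANOVA practice; `adjust = "BH"` switches on
#' Benjamini-Hochberg adjusted p-values in an extra column.
#'
#' @param category_values named list: group -> matrix/data.frame with rows =
#'   samples and columns = categories (each row one sample's category
#'   percentages).
#' @param alpha significance level.
#' @param adjust `"none"` or `"BH"`.
#' @return data.frame with class `category_summary`.
#' @export
summary_table <- function(category_values, alpha = 0.05,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(is.list(category_values), length(category_values) >= 1)
  category_values <- lapply(category_values, as.matrix)
  cats <- colnames(category_values[[1]])
  groups <- names(category_values)
  out <- data.frame(category = cats, stringsAsFactors = FALSE)
  for (g in groups) {
    m <- category_values[[g]]
    out[[paste0(g, "_mean")]] <- colMeans(m)[cats]
    out[[paste0(g, "_sem")]] <-
      if (nrow(m) >= 2) apply(m, 2, stats::sd)[cats] / sqrt(nrow(m))
      else NA_real_
  }
  if (length(groups) >= 2) {
    stat <- lapply(cats, function(cc)
      one_way_anova(lapply(category_values, function(m) m[, cc]),
                    alpha = alpha, warn_small = FALSE))
    out$F <- vapply(stat, `[[`, numeric(1), "F")
    out$p <- vapply(stat, `[[`, numeric(1), "p")
    out$F_crit <- vapply(stat, `[[`, numeric(1), "F_crit")
    out$significant <- out$F > out$F_crit
    out$stars <- significance_stars(out$p)
    if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p, "BH")
  }
  rownames(out) <- NULL
  class(out) <- c("category_summary", "data.frame")
  out
}
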