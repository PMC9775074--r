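# The group-comparison battery: normality-gated descriptives, one-way
# ANOVA (raw and from sufficient statistics), covariate-adjusted linear
# models with Bonferroni post hoc contrasts, Kruskal-Wallis, chi-square and
# Fisher exact tests, Pearson and partial correlation. Standard tests call
# the base stats implementations; the summary-statistic ANOVA and the
# partial correlation are computed here.

new_stat_result <- function(test, statistic, df, p.value, ...) {
  structure(c(list(test = test, statistic = unname(statistic),
                   df = unname(df), p.value = unname(p.value)), list(...)),
            class = "alps_stat")
}

#' @export
print.alps_stat <- function(x, ...) {
  dfs <- if (length(x$df) == 2L) sprintf("(%g, %g)", x$df[1], x$df[2])
         else if (length(x$df)) sprintf("(df = %g)", x$df) else ""
  cat(sprintf("%s: statistic = %.4g %s, p = %.4g\n", x$test, x$statistic,
              dfs, x$p.value))
  if (!is.null(x$posthoc)) {
    cat("Post hoc (Bonferroni-adjusted):\n")
    print(x$posthoc, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

as_group_list <- function(x, g = NULL) {
  if (is.list(x) && is.null(g)) return(lapply(x, as.numeric))
  if (is.null(g)) stop_("supply either a list of group vectors or (values, group)")
  split(as.numeric(x), g)
}

#' Per-group descriptive summary with a normality gate
#'
#' Each variable is Shapiro-Wilk tested per group at `alpha`; variables
#' normal in every group are summarized as mean (SD), others as median
#' (IQR), following the usual reporting convention for cohort tables.
#'
#' @param x numeric values.
#' @param g group labels.
#' @param alpha normality test level (default 0.05).
#' @return Data frame with one row per group, plus attributes `normal`
#'   (the gate verdict) and `shapiro_p` (per-group p-values).
#' @export
group_summary <- function(x, g, alpha = 0.05) {
  groups <- as_group_list(x, g)
  sh <- vapply(groups, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 3L || length(unique(v)) == 1L) return(0)
    shapiro.test(v)$p.value
  }, numeric(1))
  normal <- all(sh > alpha)
  out <- data.frame(
    group = names(groups),
    n = vapply(groups, function(v) sum(!is.na(v)), integer(1)),
    mean = vapply(groups, mean, numeric(1), na.rm = TRUE),
    sd = vapply(groups, sd, numeric(1)),
    median = vapply(groups, median, numeric(1), na.rm = TRUE),
    iqr = vapply(groups, IQR, numeric(1), na.rm = TRUE),
    row.names = NULL)
  out$display <- if (normal)
    sprintf("%.2f ± %.2f", out$mean, out$sd)
  else sprintf("%.2f (%.2f)", out$median, out$iqr)
  attr(out, "normal") <- normal
  attr(out, "shapiro_p") <- sh
  out
}

#' One-way ANOVA
#'
#' Classic fixed-effects between/within decomposition with F on
#' (k - 1, N - k) degrees of freedom.
#'
#' @param x numeric values, or a list of per-group numeric vectors.
#' @param g group labels (ignored when `x` is a list).
#' @return An `alps_stat`.
#' @export
anova_oneway <- function(x, g = NULL) {
  groups <- as_group_list(x, g)
  groups <- lapply(groups, function(v) v[!is.na(v)])
  if (length(groups) < 2L) stop_("at least two groups are required")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop_("every group needs n >= 2")
  if (all(vapply(groups, var, numeric(1)) == 0))
    stop_("degenerate ANOVA: zero within-group variance in every group")
  y <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups), lengths(groups)))
  an <- anova(lm(y ~ grp))
  new_stat_result("one-way ANOVA", statistic = an[1, "F value"],
                  df = c(an[1, "Df"], an[2, "Df"]),
                  p.value = an[1, "Pr(>F)"])
}

#' One-way ANOVA from summary statistics
#'
#' Recovers the exact fixed-effects ANOVA from per-group sufficient
#' statistics: `SSB = sum n_i (mean_i - grand)^2`,
#' `SSW = sum (n_i - 1) sd_i^2`,
#' `F = (SSB / (k - 1)) / (SSW / (N - k))`. Lets published per-group
#' n/mean/sd tables be re-tested without the raw data.
#'
#' @param n,means,sds per-group sample sizes (>= 2), means and standard
#'   deviations (>= 0).
#' @return An `alps_stat`.
#' @export
anova_from_summary <- function(n, means, sds) {
  k <- length(n)
  stopifnot(length(means) == k, length(sds) == k)
  if (k < 2L) stop_("at least two groups are required")
  if (any(n < 2L)) stop_("every group needs n >= 2")
  if (any(sds < 0)) stop_("standard deviations must be >= 0")
  N <- sum(n)
  if (N <= k) stop_("total N must exceed the number of groups")
  grand <- sum(n * means) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum((n - 1) * sds^2)
  if (ssw == 0) stop_("degenerate ANOVA: zero within-group variance")
  Fv <- (ssb / (k - 1)) / (ssw / (N - k))
  new_stat_result("one-way ANOVA (from summary statistics)",
                  statistic = Fv, df = c(k - 1, N - k),
                  p.value = stats::pf(Fv, k - 1, N - k, lower.tail = FALSE))
}

#' Covariate-adjusted group comparison (general linear model)
#'
#' Least-squares fit of `outcome ~ group + covariates`; the overall group
#' effect is the nested-model F test against the covariate-only model, and
#' the post hoc table holds pairwise contrasts of covariate-adjusted group
#' means with Bonferroni correction over all k(k-1)/2 pairs (via emmeans).
#' With no covariates this reduces exactly to [anova_oneway()].
#'
#' @param data data frame.
#' @param outcome outcome column name.
#' @param group grouping column name (coerced to factor).
#' @param covariates character vector of covariate column names.
#' @return An `alps_stat` with elements `posthoc` (adjusted pairwise
#'   contrasts), `adjusted_means` and `model`.
#' @export
glm_adjusted <- function(data, outcome, group = "group",
                         covariates = character()) {
  need <- c(outcome, group, covariates)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop_("data lacks column(s): %s", paste(missing_cols, collapse = ", "))
  d <- data[need]
  d[[group]] <- factor(d[[group]])
  d <- droplevels(d[complete.cases(d), , drop = FALSE])
  k <- nlevels(d[[group]])
  if (k < 2L) stop_("grouping column has fewer than two observed levels")
  full <- lm(reformulate(c(group, covariates), response = outcome), data = d)
  if (anyNA(coef(full))) {
    bad <- names(coef(full))[is.na(coef(full))]
    stop_("collinear design; aliased term(s): %s", paste(bad, collapse = ", "))
  }
  reduced <- lm(reformulate(if (length(covariates)) covariates else "1",
                            response = outcome), data = d)
  cmp <- anova(reduced, full)
  Fv <- cmp[2, "F"]
  df <- c(cmp[2, "Df"], cmp[2, "Res.Df"])
  em <- emmeans::emmeans(full, group)
  ph <- summary(emmeans::contrast(em, method = "pairwise",
                                  adjust = "bonferroni"))
  ph_raw <- summary(emmeans::contrast(em, method = "pairwise",
                                      adjust = "none"))
  posthoc <- data.frame(contrast = as.character(ph$contrast),
                        estimate = ph$estimate, se = ph$SE,
                        t = ph$t.ratio, p_raw = ph_raw$p.value,
                        p_adj = ph$p.value)
  new_stat_result("group GLM (covariate-adjusted)", statistic = Fv, df = df,
                  p.value = cmp[2, "Pr(>F)"], posthoc = posthoc,
                  adjusted_means = as.data.frame(em),
                  bonferroni_m = k * (k - 1) / 2,
                  covariates = covariates, model = full)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H with the chi-square approximation on k - 1 degrees of
#' freedom (wraps `stats::kruskal.test`).
#'
#' @inheritParams anova_oneway
#' @return An `alps_stat`.
#' @export
kruskal_wallis <- function(x, g = NULL) {
  groups <- as_group_list(x, g)
  groups <- lapply(groups, function(v) v[!is.na(v)])
  if (length(groups) < 2L) stop_("at least two groups are required")
  y <- unlist(groups, use.names = FALSE)
  if (length(unique(y)) == 1L)
    stop_("degenerate Kruskal-Wallis: all values are tied")
  grp <- factor(rep(names(groups), lengths(groups)))
  kt <- kruskal.test(y, grp)
  new_stat_result("Kruskal-Wallis", statistic = kt$statistic,
                  df = kt$parameter, p.value = kt$p.value)
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson chi-square without continuity correction,
#' df = (r - 1)(c - 1). Cells with expected counts below 5 are flagged in
#' `low_expected` (an indication to prefer an exact test), not silently
#' accepted.
#'
#' @param table matrix of non-negative integer counts with positive row and
#'   column margins.
#' @return An `alps_stat` with `expected` and `low_expected`.
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop_("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop_("zero row or column margin")
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  new_stat_result("Pearson chi-square", statistic = ct$statistic,
                  df = ct$parameter, p.value = ct$p.value,
                  expected = ct$expected,
                  low_expected = sum(ct$expected < 5))
}

#' Fisher exact test on a 2x2 table
#'
#' Two-sided p-value by summing the probabilities of all tables (under the
#' hypergeometric null with fixed margins) no more probable than the
#' observed one (wraps `stats::fisher.test`). Larger tables are rejected;
#' collapse or use [chi_square_test()] with the low-expected-count flag.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return An `alps_stat` with the conditional odds-ratio estimate.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!identical(dim(table), c(2L, 2L)))
    stop_("fisher_exact is restricted to 2x2 tables; got %s",
          paste(dim(table), collapse = " x "))
  if (any(table < 0) || any(table != round(table)))
    stop_("counts must be non-negative integers")
  ft <- fisher.test(table)
  new_stat_result("Fisher exact (2x2)", statistic = unname(ft$estimate),
                  df = NULL, p.value = ft$p.value)
}

#' Pearson correlation
#'
#' r with the t-based test on n - 2 degrees of freedom (wraps
#' `stats::cor.test`).
#'
#' @param x,y numeric vectors (n >= 3 complete pairs, nonzero variance).
#' @return An `alps_stat` with `estimate = r` and `n`.
#' @export
pearson_corr <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop_("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop_("zero variance in x or y")
  ct <- cor.test(x, y, method = "pearson")
  new_stat_result("Pearson correlation", statistic = ct$statistic,
                  df = ct$parameter, p.value = ct$p.value,
                  estimate = unname(ct$estimate), n = length(x))
}

#' Partial correlation
#'
#' Pearson correlation of the least-squares residuals of `x` and `y` on the
#' covariates (with intercept), with the t test on n - 2 - q degrees of
#' freedom where q is the number of covariate design columns. With no
#' covariates this is exactly [pearson_corr()].
#'
#' @param x,y numeric vectors.
#' @param covariates data frame (or matrix) of covariates; factors are
#'   expanded to dummies.
#' @return An `alps_stat` with `estimate = r`, `n` and `q`.
#' @export
partial_corr <- function(x, y, covariates = NULL) {
  if (is.null(covariates) || (!is.null(ncol(covariates)) && ncol(covariates) == 0L))
    return(pearson_corr(x, y))
  cdf <- as.data.frame(covariates)
  ok <- complete.cases(x, y, cdf)
  x <- x[ok]; y <- y[ok]
  cdf <- cdf[ok, , drop = FALSE]
  Z <- model.matrix(~ ., data = cdf)
  q <- ncol(Z) - 1L
  n <- length(x)
  if (n <= q + 2L) stop_("need n > number of covariate columns + 2")
  qz <- qr(Z)
  if (qz$rank < ncol(Z))
    stop_("collinear covariates: rank %d < %d columns", qz$rank, ncol(Z))
  rx <- qr.resid(qz, x)
  ry <- qr.resid(qz, y)
  # a variable lying (numerically) in the covariate span leaves nothing to
  # correlate
  if (sd(rx) <= 1e-10 * max(sd(x), 1e-300) ||
      sd(ry) <= 1e-10 * max(sd(y), 1e-300))
    stop_("zero residual variance after removing covariates")
  r <- cor(rx, ry)
  df <- n - 2L - q
  tval <- r * sqrt(df / (1 - r^2))
  new_stat_result("partial correlation", statistic = tval, df = df,
                  p.value = 2 * pt(-abs(tval), df), estimate = r,
                  n = n, q = q)
}
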