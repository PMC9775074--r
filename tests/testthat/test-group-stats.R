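# The group-statistics battery, each operation checked against an
# independent route (closed form, enumeration, or a distinct formulation).

test_that("one-way ANOVA matches its definition and the t-test relation", {
  # identical group means: F = 0
  g1 <- c(1, 2, 3); g2 <- c(0, 2, 4); g3 <- c(2, 2, 2, 2)
  st <- anova_oneway(list(a = g1, b = g2, c = g3))
  expect_equal(st$statistic, 0, tolerance = 1e-12)

  # two groups: F equals the squared pooled-variance t statistic
  set.seed(41)
  x <- rnorm(12); y <- rnorm(15, 0.5)
  st2 <- anova_oneway(list(x = x, y = y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(st2$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(st2$p.value, tt$p.value, tolerance = 1e-10)
  expect_equal(st2$df, c(1, 25))

  expect_error(anova_oneway(list(a = c(1, 1), b = c(2, 2))), "degenerate")
  expect_error(anova_oneway(list(a = 1:3)), "two groups")
})

test_that("summary-statistic ANOVA reproduces the raw decomposition", {
  set.seed(42)
  groups <- list(a = rnorm(20, 0), b = rnorm(25, 0.3), c = rnorm(15, -0.2),
                 d = rnorm(30, 0.5))
  raw <- anova_oneway(groups)
  st <- anova_from_summary(lengths(groups), sapply(groups, mean),
                           sapply(groups, sd))
  expect_equal(st$statistic, raw$statistic, tolerance = 1e-10)
  expect_equal(st$p.value, raw$p.value, tolerance = 1e-10)
  expect_equal(st$df, raw$df)

  expect_equal(anova_from_summary(c(5, 5), c(2, 2), c(1, 1))$statistic, 0)
  expect_error(anova_from_summary(c(1, 5), c(1, 2), c(1, 1)), "n >= 2")
  expect_error(anova_from_summary(c(5, 5), c(1, 2), c(-1, 1)), ">= 0")
})

test_that("covariate-free GLM comparison reduces to one-way ANOVA", {
  set.seed(7)
  d <- data.frame(y = rnorm(60), grp = rep(letters[1:3], each = 20))
  st_glm <- glm_adjusted(d, "y", "grp")
  st_aov <- anova_oneway(d$y, d$grp)
  expect_equal(st_glm$statistic, st_aov$statistic, tolerance = 1e-10)
  expect_equal(st_glm$p.value, st_aov$p.value, tolerance = 1e-10)
})

test_that("GLM adjustment removes covariate-driven differences", {
  set.seed(8)
  n <- 40
  d <- data.frame(age = rnorm(4 * n, rep(c(55, 60, 65, 70), each = n), 4),
                  grp = rep(letters[1:4], each = n))
  d$y <- 0.5 * d$age + rnorm(4 * n, 0, 0.2)  # outcome is pure covariate
  st <- glm_adjusted(d, "y", "grp", covariates = "age")
  expect_lt(st$statistic, 3)
  expect_gt(st$p.value, 0.01)
  expect_true(all(st$posthoc$p_adj[st$posthoc$p_raw > 0.2] == 1 |
                    st$posthoc$p_adj[st$posthoc$p_raw > 0.2] >= 0.9))

  # a built-in adjusted gap is recovered by the contrasts
  d$y2 <- 0.5 * d$age + ifelse(d$grp == "d", 1, 0) + rnorm(4 * n, 0, 0.3)
  st2 <- glm_adjusted(d, "y2", "grp", covariates = "age")
  ad <- st2$posthoc[st2$posthoc$contrast == "a - d", ]
  expect_lt(abs(ad$estimate - (-1)), 3 * ad$se)
  expect_equal(st2$bonferroni_m, 6)
})

test_that("Bonferroni adjustment is min(1, m * p) and never below raw p", {
  set.seed(9)
  d <- data.frame(y = rnorm(80), grp = rep(letters[1:4], each = 20))
  st <- glm_adjusted(d, "y", "grp")
  expect_true(all(st$posthoc$p_adj >= st$posthoc$p_raw - 1e-12))
  expect_equal(st$posthoc$p_adj,
               pmin(1, 6 * st$posthoc$p_raw), tolerance = 1e-10)
})

test_that("collinear GLM designs are rejected with the aliased term named", {
  d <- data.frame(y = rnorm(20), grp = rep(c("a", "b"), 10),
                  x1 = rnorm(20))
  d$x2 <- 2 * d$x1
  expect_error(glm_adjusted(d, "y", "grp", covariates = c("x1", "x2")),
               "collinear.*x2")
})

test_that("Kruskal-Wallis H matches the direct rank formula", {
  # no ties: brute-force H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2
  groups <- list(a = c(1.1, 3.4, 7.2, 0.5), b = c(2.2, 5.1, 9.9),
                 c = c(4.4, 6.6, 8.8, 10.1, 11.3))
  y <- unlist(groups)
  r <- rank(y)
  N <- length(y)
  rs <- split(r, rep(names(groups), lengths(groups)))
  H_oracle <- 12 / (N * (N + 1)) *
    sum(lengths(rs) * (sapply(rs, mean) - (N + 1) / 2)^2)
  st <- kruskal_wallis(groups)
  expect_equal(st$statistic, H_oracle, tolerance = 1e-12)
  expect_equal(st$df, 2)

  # two groups: H is the squared standardized Wilcoxon rank-sum statistic
  two <- list(a = c(1.3, 2.7, 8.1, 4.2), b = c(3.3, 5.5, 9.7, 0.4, 6.6))
  st2 <- kruskal_wallis(two)
  W <- sum(rank(unlist(two))[1:4])  # rank sum of group a
  n1 <- 4; n2 <- 5; Nt <- 9
  z <- (W - n1 * (Nt + 1) / 2) / sqrt(n1 * n2 * (Nt + 1) / 12)
  expect_equal(st2$statistic, z^2, tolerance = 1e-12)

  expect_error(kruskal_wallis(list(a = c(1, 1), b = c(1, 1))), "tied")
})

test_that("chi-square follows the Pearson formula and its invariances", {
  tab <- rbind(c(20, 30, 25), c(15, 35, 30))
  st <- chi_square_test(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(st$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_equal(st$df, 2)
  expect_equal(st$expected, E, ignore_attr = TRUE)

  # permutation invariance
  expect_equal(chi_square_test(tab[, c(3, 1, 2)])$statistic, st$statistic)
  expect_equal(chi_square_test(tab[2:1, ])$statistic, st$statistic)
  # a table equal to its own expected counts scores zero
  expect_equal(chi_square_test(rbind(c(10, 20), c(20, 40)))$statistic, 0)
  expect_error(chi_square_test(rbind(c(0, 0), c(5, 3))), "margin")
  expect_error(chi_square_test(rbind(c(1.5, 2), c(3, 4))), "integer")
})

test_that("Fisher exact matches full hypergeometric enumeration", {
  # independent oracle: enumerate all tables with the observed margins and
  # sum the probabilities of those no more probable than the observed
  fisher_oracle <- function(tab) {
    m <- rowSums(tab); k <- colSums(tab)
    p_obs <- dhyper(tab[1, 1], m[1], m[2], k[1])
    xs <- max(0, k[1] - m[2]):min(k[1], m[1])
    ps <- dhyper(xs, m[1], m[2], k[1])
    sum(ps[ps <= p_obs * (1 + 1e-7)])
  }
  tabs <- list(rbind(c(1, 9), c(11, 3)), rbind(c(3, 5), c(6, 2)),
               rbind(c(0, 7), c(4, 4)))
  for (tab in tabs)
    expect_equal(fisher_exact(tab)$p.value, fisher_oracle(tab),
                 tolerance = 1e-10)
  # identical rows: independence, p = 1
  expect_equal(fisher_exact(rbind(c(5, 7), c(5, 7)))$p.value, 1)
  # row swap leaves p unchanged
  tab <- rbind(c(2, 8), c(9, 1))
  expect_equal(fisher_exact(tab)$p.value,
               fisher_exact(tab[2:1, ])$p.value)
  expect_error(fisher_exact(matrix(1, 2, 3)), "2x2")
})

test_that("Pearson correlation matches hand computation", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_corr(x, 2 * x + 1)$estimate, 1, tolerance = 1e-12)

  y <- c(2.1, 1.9, 3.8, 3.4, 5.5)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  st <- pearson_corr(x, y)
  expect_equal(st$estimate, r_hand, tolerance = 1e-12)
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(st$p.value, 2 * pt(-abs(t_hand), 3), tolerance = 1e-12)
  expect_error(pearson_corr(c(1, 1, 1), y[1:3]), "variance")
})

test_that("partial correlation equals the precision-matrix oracle", {
  set.seed(50)
  n <- 50
  cov3 <- matrix(rnorm(n * 3), n, 3)
  x <- rnorm(n) + 0.5 * cov3[, 1]
  y <- rnorm(n) + 0.4 * cov3[, 1] - 0.3 * cov3[, 2]
  st <- partial_corr(x, y, as.data.frame(cov3))

  # independent route 1: explicit lm residualization
  rx <- resid(lm(x ~ cov3)); ry <- resid(lm(y ~ cov3))
  expect_equal(st$estimate, cor(rx, ry), tolerance = 1e-12)
  # independent route 2: negated scaled inverse of the joint covariance
  Om <- solve(cov(cbind(x, y, cov3)))
  expect_equal(st$estimate, -Om[1, 2] / sqrt(Om[1, 1] * Om[2, 2]),
               tolerance = 1e-10)
  expect_equal(st$df, n - 2 - 3)

  # nesting: empty covariates give plain Pearson
  st0 <- partial_corr(x, y)
  stp <- pearson_corr(x, y)
  expect_equal(st0$estimate, stp$estimate)
  expect_equal(st0$p.value, stp$p.value)

  # y carried entirely by a covariate: nothing left to correlate
  expect_error(partial_corr(x, cov3[, 1], as.data.frame(cov3)),
               "zero residual variance")
  y_near <- cov3[, 1] + rnorm(n, 0, 1e-6)
  st_near <- partial_corr(x, y_near, as.data.frame(cov3))
  expect_lt(abs(st_near$estimate), 0.5)
})

test_that("degenerate partial-correlation inputs error", {
  set.seed(51)
  x <- rnorm(30); y <- rnorm(30)
  cv <- data.frame(a = rnorm(30))
  cv$b <- 2 * cv$a
  expect_error(partial_corr(x, y, cv), "collinear")
  expect_error(partial_corr(x[1:4], y[1:4], data.frame(a = rnorm(4),
                                                       b = rnorm(4))),
               "n >")
})

test_that("group summaries gate on normality", {
  set.seed(52)
  g <- rep(c("a", "b"), each = 40)
  x_norm <- rnorm(80)
  s1 <- group_summary(x_norm, g)
  expect_true(attr(s1, "normal"))
  expect_match(s1$display[1], "±")
  x_skew <- rexp(80)^2
  s2 <- group_summary(x_skew, g)
  expect_false(attr(s2, "normal"))
  expect_match(s2$display[1], "\\(")
})
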