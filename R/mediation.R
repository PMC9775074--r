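# Covariate-adjusted single-mediator analysis with case-resampling
# bootstrap confidence intervals for the indirect effect — the classic
# three-regression formulation:
#
#   mediator ~ exposure + covariates            -> a
#   outcome  ~ exposure + mediator + covariates -> b (mediator), c' (exposure)
#   outcome  ~ exposure + covariates            -> c
#
# indirect effect = a * b; for OLS with the same covariates in all three
# models the decomposition c = c' + a*b holds exactly. All coefficients are
# non-standardized. The bootstrap resamples subjects (rows) with
# replacement, refits the a and b paths on each resample, and builds a
# percentile or bias-corrected (BC) interval from the k resampled a*b
# values.

#' Fit a bootstrap mediation model
#'
#' @param data data frame of complete cases (rows with missing values in
#'   any used column are dropped).
#' @param exposure,mediator,outcome column names of the exposure (e.g.
#'   log-transformed WMH volume), mediator (e.g. ALPS index) and outcome
#'   (e.g. episodic-memory composite).
#' @param covariates character vector of covariate column names entering
#'   all three regressions.
#' @param k bootstrap replicates (default 5000). Values below 100 give
#'   unusable intervals and are refused unless `force = TRUE`.
#' @param method `"bias_corrected"` (the PROCESS-style default) or
#'   `"percentile"`.
#' @param seed integer seed; fixed seed reproduces the interval exactly.
#' @param conf confidence level (default 0.95).
#' @param force allow k < 100.
#' @return Object of class `mediation_fit` with paths `a`, `b`, `c`,
#'   `c_prime`, the `indirect` effect, bootstrap draws and CI, the three
#'   fitted `lm` models, and `significant` (TRUE iff the CI excludes 0).
#' @seealso [mediation_report()], and the `print`, `summary`, `coef`,
#'   `confint` and `plot` methods.
#' @export
fit_mediation <- function(data, exposure, mediator, outcome,
                          covariates = character(), k = 5000L,
                          method = c("bias_corrected", "percentile"),
                          seed = NULL, conf = 0.95, force = FALSE) {
  method <- match.arg(method)
  k <- as.integer(k)
  if (k < 100L && !force)
    stop_("k = %d bootstrap replicates is too few for a stable interval; use k >= 100 or force = TRUE",
          k)
  need <- c(exposure, mediator, outcome, covariates)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop_("data lacks column(s): %s", paste(missing_cols, collapse = ", "))
  d <- data[need]
  d <- d[complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n <= length(covariates) + 3L)
    stop_("need n > number of covariates + 3 (have n = %d)", n)

  f_a <- reformulate(c(exposure, covariates), response = mediator)
  f_b <- reformulate(c(exposure, mediator, covariates), response = outcome)
  f_c <- reformulate(c(exposure, covariates), response = outcome)
  m_a <- lm(f_a, data = d)
  m_b <- lm(f_b, data = d)
  m_c <- lm(f_c, data = d)
  cf <- c(coef(m_a), coef(m_b), coef(m_c))
  if (anyNA(cf) || any(!is.finite(cf)))
    stop_("non-finite regression coefficients; check the design for collinearity")
  a <- unname(coef(m_a)[exposure])
  b <- unname(coef(m_b)[mediator])
  c_prime <- unname(coef(m_b)[exposure])
  c_total <- unname(coef(m_c)[exposure])
  indirect <- a * b

  # bootstrap on precomputed design matrices; the exposure/mediator
  # coefficient positions are fixed by column order
  Xa <- model.matrix(m_a)
  Xb <- model.matrix(m_b)
  mv <- d[[mediator]]
  yv <- d[[outcome]]
  pos_a <- match(exposure, colnames(Xa))
  pos_b <- match(mediator, colnames(Xb))
  boot <- with_seed(seed, boot_indirect_draws(Xa, Xb, mv, yv, pos_a, pos_b, k))
  ci <- boot_ci(boot$ab, indirect, conf = conf, method = method)

  structure(list(
    a = a, b = b, c = c_total, c_prime = c_prime, indirect = indirect,
    ci_low = ci[1], ci_high = ci[2], conf = conf, method = method, k = k,
    seed = seed, n = n, covariates = covariates,
    exposure = exposure, mediator = mediator, outcome = outcome,
    significant = ci[1] > 0 || ci[2] < 0,
    boot = boot$ab, boot_redraws = boot$redraws,
    models = list(a = m_a, b = m_b, c = m_c)),
    class = "mediation_fit")
}

# k bootstrap draws of a*b; degenerate (rank-deficient) resamples are
# redrawn and counted
boot_indirect_draws <- function(Xa, Xb, mv, yv, pos_a, pos_b, k) {
  n <- nrow(Xa)
  pa <- ncol(Xa); pb <- ncol(Xb)
  ab <- numeric(k)
  redraws <- 0L
  for (i in seq_len(k)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      XaI <- Xa[idx, , drop = FALSE]
      XbI <- Xb[idx, , drop = FALSE]
      ca <- tryCatch(solve(crossprod(XaI), crossprod(XaI, mv[idx])),
                     error = function(e) NULL)
      cb <- if (is.null(ca)) NULL
            else tryCatch(solve(crossprod(XbI), crossprod(XbI, yv[idx])),
                          error = function(e) NULL)
      if (!is.null(ca) && !is.null(cb)) break
      redraws <- redraws + 1L
      if (redraws > 100L * k)
        stop_("bootstrap cannot find full-rank resamples; the design is (nearly) degenerate")
    }
    ab[i] <- ca[pos_a] * cb[pos_b]
  }
  list(ab = ab, redraws = redraws)
}

# percentile / bias-corrected bootstrap interval. When the bootstrap
# distribution median equals the point estimate the BC adjustment is zero
# and both methods coincide.
boot_ci <- function(draws, point, conf, method) {
  alpha <- 1 - conf
  probs <- c(alpha / 2, 1 - alpha / 2)
  if (method == "bias_corrected") {
    prop <- mean(draws < point)
    # guard the degenerate all-above/all-below cases
    prop <- min(max(prop, 1 / (length(draws) + 1)),
                length(draws) / (length(draws) + 1))
    z0 <- qnorm(prop)
    probs <- pnorm(2 * z0 + qnorm(probs))
  }
  unname(quantile(draws, probs, type = 7))
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat("Bootstrap mediation model\n")
  cat(sprintf("  %s -> %s -> %s (n = %d%s)\n", x$exposure, x$mediator,
              x$outcome, x$n,
              if (length(x$covariates))
                paste0("; covariates: ", paste(x$covariates, collapse = ", "))
              else ""))
  cat(sprintf("  a = %.4f, b = %.4f, c = %.4f, c' = %.4f\n",
              x$a, x$b, x$c, x$c_prime))
  cat(sprintf("  indirect (a*b) = %.4f, %d%% %s CI [%.4f, %.4f] (k = %d)\n",
              x$indirect, round(100 * x$conf),
              if (x$method == "bias_corrected") "bias-corrected" else "percentile",
              x$ci_low, x$ci_high, x$k))
  cat(sprintf("  mediating effect %s (CI %s 0)\n",
              if (x$significant) "present" else "not demonstrated",
              if (x$significant) "excludes" else "contains"))
  invisible(x)
}

#' @export
summary.mediation_fit <- function(object, ...) {
  out <- list(fit = object,
              a_path = coef(summary(object$models$a)),
              b_path = coef(summary(object$models$b)),
              total = coef(summary(object$models$c)))
  class(out) <- "summary.mediation_fit"
  out
}

#' @export
print.summary.mediation_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("\nMediator model (%s):\n", x$fit$mediator))
  stats::printCoefmat(x$a_path, digits = 4)
  cat(sprintf("\nOutcome model (%s):\n", x$fit$outcome))
  stats::printCoefmat(x$b_path, digits = 4)
  invisible(x)
}

#' @export
coef.mediation_fit <- function(object, ...) {
  c(a = object$a, b = object$b, c = object$c, c_prime = object$c_prime,
    indirect = object$indirect)
}

#' Bootstrap confidence interval(s) of the indirect effect
#'
#' @param object a [fit_mediation()] fit.
#' @param parm ignored (only the indirect effect has a bootstrap interval).
#' @param level confidence level; defaults to the level used at fit time
#'   (re-deriving the interval from the stored draws for other levels).
#' @param method interval type; defaults to the fit's method.
#' @param ... unused.
#' @return Length-2 numeric `c(lower, upper)`.
#' @export
confint.mediation_fit <- function(object, parm = "indirect", level = NULL,
                                  method = NULL, ...) {
  level <- level %||% object$conf
  method <- method %||% object$method
  boot_ci(object$boot, object$indirect, conf = level, method = method)
}

#' Path diagram of a mediation fit
#'
#' Base-graphics triangle diagram: exposure and outcome on the base,
#' mediator at the apex; solid arrows carry the a, b and direct (c') path
#' coefficients, the dashed base annotation the indirect effect with its
#' bootstrap CI. Stars mark paths with p < 0.05 (CI excluding 0 for the
#' indirect effect).
#'
#' @param x a `mediation_fit`.
#' @param ... unused.
#' @return Invisibly, `x`.
#' @export
plot.mediation_fit <- function(x, ...) {
  star <- function(p) if (p < 0.05) "*" else ""
  pa <- coef(summary(x$models$a))[x$exposure, 4]
  pb <- coef(summary(x$models$b))[x$mediator, 4]
  pc <- coef(summary(x$models$b))[x$exposure, 4]
  plot.new()
  plot.window(xlim = c(0, 10), ylim = c(0, 10))
  boxes <- list(exposure = c(1.8, 2), mediator = c(5, 8), outcome = c(8.2, 2))
  for (nm in names(boxes)) {
    p <- boxes[[nm]]
    rect(p[1] - 1.6, p[2] - 0.8, p[1] + 1.6, p[2] + 0.8)
    text(p[1], p[2], x[[nm]])
  }
  arr <- function(from, to) arrows(from[1], from[2], to[1], to[2],
                                   length = 0.1)
  arr(c(2.6, 3), c(4.0, 7.2))
  arr(c(6.0, 7.2), c(7.4, 3))
  arr(c(3.5, 2), c(6.5, 2))
  text(2.4, 5.4, sprintf("a = %.3f%s", x$a, star(pa)), adj = 1)
  text(7.6, 5.4, sprintf("b = %.3f%s", x$b, star(pb)), adj = 0)
  text(5, 2.45, sprintf("c' = %.3f%s", x$c_prime, star(pc)))
  text(5, 1.2, sprintf("indirect a*b = %.3f [%.3f, %.3f]%s",
                       x$indirect, x$ci_low, x$ci_high,
                       if (x$significant) "*" else ""))
  title(main = "Mediation paths (non-standardized coefficients)")
  invisible(x)
}

#' Serializable mediation report
#'
#' Flattens a fit into a list of scalars (paths, interval, significance
#' flag, bootstrap settings) that survives a JSON round trip unchanged, and
#' renders as text via `format()`.
#'
#' @param fit a [fit_mediation()] fit.
#' @return List of class `mediation_report`.
#' @export
mediation_report <- function(fit) {
  stopifnot(inherits(fit, "mediation_fit"))
  structure(list(
    exposure = fit$exposure, mediator = fit$mediator, outcome = fit$outcome,
    covariates = paste(fit$covariates, collapse = ","),
    n = fit$n, k = fit$k, method = fit$method, conf = fit$conf,
    seed = if (is.null(fit$seed)) NA else fit$seed,
    a = fit$a, b = fit$b, c = fit$c, c_prime = fit$c_prime,
    indirect = fit$indirect, ci_low = fit$ci_low, ci_high = fit$ci_high,
    mediation_present = fit$significant,
    scale = "non-standardized"), class = "mediation_report")
}

#' @export
format.mediation_report <- function(x, ...) {
  paste0(
    sprintf("%s -> %s -> %s (n = %d, k = %d, %s CI)\n", x$exposure,
            x$mediator, x$outcome, x$n, x$k, x$method),
    sprintf("a = %.4f  b = %.4f  c = %.4f  c' = %.4f\n", x$a, x$b, x$c,
            x$c_prime),
    sprintf("indirect = %.4f [%.4f, %.4f]%s\n", x$indirect, x$ci_low,
            x$ci_high, if (x$mediation_present) " *" else ""))
}

#' @export
print.mediation_report <- function(x, ...) {
  cat(format(x))
  invisible(x)
}
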