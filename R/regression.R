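#' Rayleigh regression of a bulk enrichment factor
#'
#' Fits the linearized Rayleigh distillation model
#' \deqn{\ln(R_t/R_0) = (\varepsilon/1000)\,\ln(C_t/C_0)}
#' by ordinary least squares with a free intercept, where
#' \eqn{R = 1 + \delta} (delta as a fraction). The slope, rescaled to
#' permil, is the bulk enrichment factor \eqn{\varepsilon}; its 95%
#' confidence interval comes from the two-tailed t distribution with
#' n - 2 degrees of freedom.
#'
#' The free intercept absorbs mis-specification of the initial
#' composition; on exact Rayleigh data the intercept is zero and the slope
#' is recovered to machine precision. Replicate measurements enter as
#' individual points by default, preserving the degrees of freedom used by
#' the t-based interval; set `average_replicates = TRUE` to collapse each
#' vial to its replicate mean first.
#'
#' @param series an [experiment_series] with initial composition available
#'   for the requested element.
#' @param element `"C"` or `"Cl"`.
#' @param alpha two-sided significance level for the confidence interval
#'   (default 0.05, i.e. a 95% CI).
#' @param average_replicates collapse replicates to vial means before
#'   fitting (default `FALSE`).
#' @return An object of class `rayleigh_fit`: `element`, `epsilon` (permil),
#'   `stderr` (permil), `ci95` (permil, length 2), `r_squared`, `n_points`,
#'   `intercept` (ln-ratio units), `alpha`.
#' @examples
#' s <- simulate_rayleigh_series(
#'   simulation_config(epsilon_c = -27.5, noise_sd = 0, seed = 1))
#' fit_rayleigh(s, "C")
#' @export
fit_rayleigh <- function(series, element = c("C", "Cl"), alpha = 0.05,
                         average_replicates = FALSE) {
  stopifnot(inherits(series, "experiment_series"))
  element <- match.arg(element)
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1)
  m <- series$measurements
  d <- if (element == "C") m$delta_c else m$delta_cl
  d0 <- if (element == "C") series$delta0_c else series$delta0_cl
  keep <- !is.na(d) & is.finite(m$f)
  if (any(m$f[keep] <= 0)) {
    stop("fraction remaining must be > 0 for Rayleigh regression",
         call. = FALSE)
  }
  if (is.na(d0)) {
    stop(sprintf("no initial composition (delta0) for element %s", element),
         call. = FALSE)
  }
  f <- m$f[keep]
  d <- d[keep]
  if (average_replicates) {
    agg <- stats::aggregate(cbind(f = f, d = d),
                            by = list(vial = m$vial_id[keep]), FUN = mean)
    f <- agg$f
    d <- agg$d
  }
  if (length(d) < 3L) {
    stop(sprintf("insufficient data: %d points with element %s (need >= 3)",
                 length(d), element), call. = FALSE)
  }
  x <- log(f)
  y <- log(delta_to_ratio_factor(d) / delta_to_ratio_factor(d0))
  if (stats::var(x) == 0) {
    stop("degenerate design: no variance in ln(f)", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  slope <- stats::coef(fit)[["x"]]
  se <- sm$coefficients["x", "Std. Error"]
  ci <- stats::confint(fit, "x", level = 1 - alpha)
  structure(list(
    element = element,
    epsilon = 1000 * slope,
    stderr = 1000 * se,
    ci95 = 1000 * as.numeric(ci),
    r_squared = sm$r.squared,
    n_points = length(d),
    intercept = stats::coef(fit)[["(Intercept)"]],
    alpha = alpha
  ), class = "rayleigh_fit")
}

#' @export
print.rayleigh_fit <- function(x, ...) {
  cat(sprintf(
    "Rayleigh fit (%s): epsilon = %.1f permil [%.1f, %.1f] (95%% CI), R2 = %.2f, n = %d\n",
    x$element, x$epsilon, x$ci95[1], x$ci95[2], x$r_squared, x$n_points))
  invisible(x)
}

#' Dual-element (Lambda) slope
#'
#' Ordinary least-squares slope of delta 13C (response, ordinate) against
#' delta 37Cl (predictor, abscissa) with a free intercept — the
#' dual-element plot orientation in which the slope Lambda approximately
#' equals the ratio of enrichment factors, epsilon_C / epsilon_Cl. The
#' confidence interval is the two-tailed t interval on the slope.
#'
#' Lambda is fit in delta space (not on ln-ratio transforms); the mild
#' curvature of exact Rayleigh data in delta space makes the OLS slope
#' deviate slightly from epsilon_C / epsilon_Cl.
#'
#' @param series an [experiment_series] with paired carbon and chlorine
#'   measurements.
#' @param alpha two-sided significance level (default 0.05).
#' @return An object of class `dual_element_fit`: `lambda`, `stderr`,
#'   `ci95`, `r_squared`, `n_points`, `intercept`, `alpha`.
#' @export
fit_lambda <- function(series, alpha = 0.05) {
  stopifnot(inherits(series, "experiment_series"))
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1)
  m <- series$measurements
  keep <- stats::complete.cases(m$delta_c, m$delta_cl)
  if (sum(keep) < 3L) {
    stop(sprintf(
      "insufficient data: %d paired (delta13C, delta37Cl) measurements (need >= 3)",
      sum(keep)), call. = FALSE)
  }
  x <- m$delta_cl[keep]
  y <- m$delta_c[keep]
  if (stats::var(x) == 0) {
    stop("degenerate design: no variance in delta 37Cl", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  ci <- stats::confint(fit, "x", level = 1 - alpha)
  structure(list(
    lambda = stats::coef(fit)[["x"]],
    stderr = sm$coefficients["x", "Std. Error"],
    ci95 = as.numeric(ci),
    r_squared = sm$r.squared,
    n_points = sum(keep),
    intercept = stats::coef(fit)[["(Intercept)"]],
    alpha = alpha
  ), class = "dual_element_fit")
}

#' @export
print.dual_element_fit <- function(x, ...) {
  cat(sprintf(
    "Dual-element fit: Lambda = %.1f [%.1f, %.1f] (95%% CI), R2 = %.2f, n = %d\n",
    x$lambda, x$ci95[1], x$ci95[2], x$r_squared, x$n_points))
  invisible(x)
}

#' Build a dual-element fit from published summary statistics
#'
#' Reconstructs a `dual_element_fit` from a reported Lambda and the
#' half-width of its 95% confidence interval, interpreting the published
#' "±" as the two-tailed t interval half-width with `n_points - 2` degrees
#' of freedom. Used to compare new fits against literature values.
#'
#' @param lambda reported slope.
#' @param ci_half_width reported 95% CI half-width (the "±" value).
#' @param n_points number of regression points behind the reported value
#'   (default 27: nine vials in triplicate).
#' @param r_squared optional reported coefficient of determination.
#' @param alpha significance level the interval corresponds to.
#' @return A `dual_element_fit`.
#' @export
lambda_from_summary <- function(lambda, ci_half_width, n_points = 27L,
                                r_squared = NA_real_, alpha = 0.05) {
  stopifnot(ci_half_width > 0, n_points >= 3L)
  tcrit <- stats::qt(1 - alpha / 2, df = n_points - 2)
  structure(list(
    lambda = lambda,
    stderr = ci_half_width / tcrit,
    ci95 = c(lambda - ci_half_width, lambda + ci_half_width),
    r_squared = r_squared,
    n_points = as.integer(n_points),
    intercept = NA_real_,
    alpha = alpha
  ), class = "dual_element_fit")
}

#' Compare two dual-element slopes
#'
#' Welch-type t statistic on the difference of two regression slopes using
#' their standard errors, with Welch-Satterthwaite degrees of freedom built
#' from each fit's residual degrees of freedom (n - 2). Also reports
#' whether the two 95% confidence intervals overlap.
#'
#' @param fit_a,fit_b objects of class `dual_element_fit`.
#' @param alpha significance level for the verdict (default 0.05).
#' @return A list with `difference`, `t`, `df`, `p_value`, `verdict`
#'   (`"distinct"` or `"indistinguishable"`), and `ci_overlap`.
#' @export
compare_lambdas <- function(fit_a, fit_b, alpha = 0.05) {
  stopifnot(inherits(fit_a, "dual_element_fit"),
            inherits(fit_b, "dual_element_fit"))
  se2 <- c(fit_a$stderr^2, fit_b$stderr^2)
  dfs <- c(fit_a$n_points - 2, fit_b$n_points - 2)
  diff <- fit_a$lambda - fit_b$lambda
  if (sum(se2) == 0) {
    # two exact slopes: identical or trivially distinct
    p <- if (diff == 0) 1 else 0
    tstat <- if (diff == 0) 0 else Inf
    dfw <- sum(dfs)
  } else {
    tstat <- diff / sqrt(sum(se2))
    dfw <- sum(se2)^2 / sum(se2^2 / dfs)
    p <- 2 * stats::pt(-abs(tstat), df = dfw)
  }
  overlap <- fit_a$ci95[1] <= fit_b$ci95[2] && fit_b$ci95[1] <= fit_a$ci95[2]
  list(
    difference = diff,
    t = tstat,
    df = dfw,
    p_value = p,
    verdict = if (p < alpha) "distinct" else "indistinguishable",
    ci_overlap = overlap
  )
}
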