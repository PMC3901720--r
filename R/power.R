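#' Non-centrality parameter of the association F test
#'
#' \eqn{\lambda = n\rho^2/(1-\rho^2)} for the slope test in simple linear
#' regression with `n` observations, where \eqn{\rho^2} is the squared
#' correlation between phenotype (or squared standardized phenotype) and
#' allelic dosage.
#'
#' @param n Total sample size (>= 3).
#' @param rho_sq Squared correlation, in \[0, 1).
#' @return The non-centrality parameter, a nonnegative number.
#' @examples
#' ncp(15000, 0.001152)
#' @export
ncp <- function(n, rho_sq) {
  if (!is.numeric(n) || any(n < 3)) stop("n must be >= 3", call. = FALSE)
  if (!is.numeric(rho_sq) || any(rho_sq < 0) || any(rho_sq >= 1)) {
    stop("rho_sq must lie in [0, 1); got ", format(rho_sq), call. = FALSE)
  }
  n * rho_sq / (1 - rho_sq)
}

#' Power of the F(1, n-2) test at a given non-centrality
#'
#' One minus the non-central F(1, n-2; \eqn{\lambda}) distribution function
#' evaluated at the upper-\eqn{\alpha} quantile of the central F(1, n-2)
#' distribution. At \eqn{\lambda = 0} this equals \eqn{\alpha} exactly.
#'
#' @param lambda Non-centrality parameter, >= 0.
#' @param n Total sample size (>= 3); denominator degrees of freedom n - 2.
#' @param alpha Significance level.
#' @return The power, in \[0, 1\].
#' @examples
#' power_from_ncp(7.535, 30000, 0.05)
#' @export
power_from_ncp <- function(lambda, n, alpha = 0.05) {
  if (any(lambda < 0)) stop("lambda must be >= 0", call. = FALSE)
  .check_scenario_common(n, 0, alpha, allow_null_n = FALSE)
  crit <- qf(1 - alpha, df1 = 1, df2 = n - 2)
  pf(crit, df1 = 1, df2 = n - 2, ncp = lambda, lower.tail = FALSE)
}

#' Analytic power of a mean- or variance-comparison scenario
#'
#' Wires the scenario's squared correlation through the non-centrality
#' parameter into the non-central-F tail probability.
#'
#' @param s A scenario from [mean_scenario()] or [variance_scenario()],
#'   with `n` set.
#' @return An object of class `power_computation`: a list with `test_kind`,
#'   `rho_sq`, `ncp`, `df_num` (1), `df_den` (n - 2), `alpha`,
#'   `critical_value` and `power`.
#' @examples
#' analytic_power(variance_scenario(0.06, 0.2, 30000, sigma_e = 0.7))
#' @export
analytic_power <- function(s) {
  if (!inherits(s, "pheno_scenario")) {
    stop("analytic_power() expects a scenario object", call. = FALSE)
  }
  .check_scenario_common(s$n, s$sigma_e, s$alpha, allow_null_n = FALSE)
  r2 <- rho_sq(s)
  lam <- ncp(s$n, r2)
  structure(
    list(test_kind = .test_kind(s),
         rho_sq = r2,
         ncp = lam,
         df_num = 1L,
         df_den = s$n - 2L,
         alpha = s$alpha,
         critical_value = qf(1 - s$alpha, 1, s$n - 2),
         power = power_from_ncp(lam, s$n, s$alpha)),
    class = "power_computation")
}

#' @export
print.power_computation <- function(x, digits = 4, ...) {
  cat(sprintf("Analytic power (%s test)\n", x$test_kind))
  cat(sprintf("  rho^2 = %.3e, NCP = %.4f, F(%d, %d) at alpha = %g\n",
              x$rho_sq, x$ncp, x$df_num, x$df_den, x$alpha))
  cat(sprintf("  power = %.*f\n", digits, x$power))
  invisible(x)
}

#' Smallest sample size reaching a target power
#'
#' Inverts the analytic power calculation: the smallest integer `n >= 3`
#' whose power meets `target_power`, found by bracketed doubling followed by
#' integer bisection (power is monotone increasing in `n`).
#'
#' @param s A scenario; its `n` field (if any) is ignored.
#' @param target_power Desired power, strictly between 0 and 1.
#' @param n_max Safety cap on the search (default 1e9).
#' @return The required sample size, an integer-valued number.
#' @examples
#' required_n(mean_scenario(0.06, 0.2), 0.8)
#' @export
required_n <- function(s, target_power, n_max = 1e9) {
  if (!inherits(s, "pheno_scenario")) {
    stop("required_n() expects a scenario object", call. = FALSE)
  }
  if (!is.numeric(target_power) || length(target_power) != 1L ||
      target_power <= 0 || target_power >= 1) {
    stop("target_power must lie strictly in (0, 1)", call. = FALSE)
  }
  if (.effect(s) == 0) {
    stop("target power is unreachable with a zero effect size",
         call. = FALSE)
  }
  r2 <- rho_sq(s)
  pw <- function(n) power_from_ncp(ncp(n, r2), n, s$alpha)
  lo <- 3
  if (pw(lo) >= target_power) return(lo)
  hi <- 6
  while (pw(hi) < target_power) {
    lo <- hi
    hi <- hi * 2
    if (hi > n_max) {
      stop("required sample size exceeds n_max = ", format(n_max),
           call. = FALSE)
    }
  }
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (pw(mid) >= target_power) hi <- mid else lo <- mid
  }
  hi
}

#' Cost of phenotype measurement error
#'
#' The percentage increase in sample size required to keep the analytic
#' power constant when measurement error of SD `sigma_e` is introduced,
#' obtained by matching non-centrality parameters between the error-free
#' and with-error designs.
#'
#' For the comparison of means, with \eqn{\rho_0^2 = \beta^2 2p(1-p)} and
#' \eqn{\rho_e^2 = \rho_0^2/(1+\sigma_e^2)},
#' \deqn{C = 100\left[(1+\sigma_e^2)\frac{1-\rho_e^2}{1-\rho_0^2}-1\right].}
#' For small GWAS-scale effects \eqn{C \approx 100\,\sigma_e^2}.
#'
#' For the comparison of variances the effect term cancels in the NCP ratio
#' and
#' \deqn{C = 100\left[\frac{E_g[(1+\beta_v g+\sigma_e^2)^2]}
#'   {E_g[(1+\beta_v g)^2]}-1\right].}
#'
#' `cost_by_ncp_matching()` is an independent numeric route to the same
#' quantity: it solves \eqn{\lambda_0(n) = \lambda_e(n')} for the sample
#' size ratio \eqn{n'/n} by root finding and reports \eqn{100(n'/n - 1)}.
#'
#' @param sigma_e Measurement-error SD(s); vectorized.
#' @param beta,beta_v Per-allele effect on the mean / on the variance.
#' @param maf Minor allele frequency.
#' @return Cost in percent (vector matching `sigma_e`).
#' @examples
#' cost_means(1.0, beta = 0.06, maf = 0.2)      # 100.1 after rounding
#' cost_variances(1.0, beta_v = 0.06, maf = 0.2) # 290.4 after rounding
#' @export
cost_means <- function(sigma_e, beta, maf) {
  if (any(sigma_e < 0)) stop("sigma_e must be >= 0", call. = FALSE)
  rho0 <- rho_sq_means(beta, maf, sigma_e = 0)
  if (rho0 >= 1) stop("beta^2 * 2p(1-p) must be < 1", call. = FALSE)
  rho_e <- rho0 / (1 + sigma_e^2)
  100 * ((1 + sigma_e^2) * (1 - rho_e) / (1 - rho0) - 1)
}

#' @rdname cost_means
#' @export
cost_variances <- function(sigma_e, beta_v, maf) {
  if (any(sigma_e < 0)) stop("sigma_e must be >= 0", call. = FALSE)
  if (beta_v <= -0.5) stop("beta_v must be > -0.5", call. = FALSE)
  e0 <- .second_moment_sq(beta_v, maf, 0)
  ee <- vapply(sigma_e^2, function(c2) .second_moment_sq(beta_v, maf, c2),
               numeric(1))
  100 * (ee / e0 - 1)
}

#' @rdname cost_means
#' @param test_kind `"means"` or `"variances"`.
#' @param effect `beta` for the means test, `beta_v` for the variances test.
#' @export
cost_by_ncp_matching <- function(test_kind = c("means", "variances"),
                                 sigma_e, effect, maf) {
  test_kind <- match.arg(test_kind)
  if (effect == 0) stop("effect must be nonzero", call. = FALSE)
  rho_at <- function(se) {
    if (test_kind == "means") rho_sq_means(effect, maf, se)
    else rho_sq_variances(effect, maf, se)
  }
  rho0 <- rho_at(0)
  n0 <- 1000  # reference size; the matched ratio is independent of it
  lam0 <- ncp(n0, rho0)
  one <- function(se) {
    if (se == 0) return(0)
    rho_e <- rho_at(se)
    f <- function(ratio) ncp(n0 * ratio, rho_e) - lam0
    upper <- 2
    while (f(upper) < 0) {
      upper <- upper * 2
      if (upper > 1e9) stop("NCP matching failed to bracket a root for ",
                            "sigma_e = ", format(se), call. = FALSE)
    }
    sol <- stats::uniroot(f, c(1, upper), tol = 1e-12)
    100 * (sol$root - 1)
  }
  vapply(sigma_e, one, numeric(1))
}

#' Measurement-error cost table for both tests
#'
#' Closed-form cost coefficients across a grid of measurement-error SDs,
#' for the comparison of means and the comparison of variances side by side.
#'
#' @param sigma_e Vector of measurement-error SDs.
#' @param beta Per-allele mean effect (means column).
#' @param beta_v Per-allele variance effect (variances column).
#' @param maf Minor allele frequency shared by both columns.
#' @return A data frame with columns `sigma_e`, `cost_means`,
#'   `cost_variances` (percent, full precision).
#' @examples
#' cost_table(seq(0.1, 1, by = 0.1), beta = 0.06, beta_v = 0.06, maf = 0.2)
#' @export
cost_table <- function(sigma_e, beta = 0.06, beta_v = 0.06, maf = 0.2) {
  data.frame(sigma_e = sigma_e,
             cost_means = cost_means(sigma_e, beta, maf),
             cost_variances = cost_variances(sigma_e, beta_v, maf))
}
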