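#' Hardy-Weinberg genotype distribution for a biallelic SNP
#'
#' Genotype law implied by random mating at minor allele frequency `p`:
#' frequencies \eqn{(1-p)^2, 2p(1-p), p^2} for genotypes AA, AB, BB, so that
#' the allelic dosage (count of minor alleles, 0/1/2) follows Binomial(2, p)
#' with mean \eqn{2p} and variance \eqn{2p(1-p)}.
#'
#' @param p Minor allele frequency, strictly between 0 and 1.
#' @return An object of class `hwe_dist`: a list with elements `p`,
#'   `freq_AA`, `freq_AB`, `freq_BB`, `mean_g`, `var_g`.
#' @examples
#' hwe_distribution(0.2)
#' @export
hwe_distribution <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1) {
    stop("minor allele frequency must lie strictly in (0, 1); got p = ",
         deparse(substitute(p)), " = ", format(p), call. = FALSE)
  }
  structure(
    list(p = p,
         freq_AA = (1 - p)^2,
         freq_AB = 2 * p * (1 - p),
         freq_BB = p^2,
         mean_g = 2 * p,
         var_g = 2 * p * (1 - p)),
    class = "hwe_dist")
}

#' @export
print.hwe_dist <- function(x, ...) {
  cat("HWE genotype distribution (MAF =", format(x$p), ")\n")
  cat(sprintf("  freq AA/AB/BB: %.6f / %.6f / %.6f\n",
              x$freq_AA, x$freq_AB, x$freq_BB))
  cat(sprintf("  dosage mean %.4f, variance %.4f\n", x$mean_g, x$var_g))
  invisible(x)
}

# shared checks for both scenario constructors; n may be NULL so a scenario
# can be handed to required_n() before a sample size exists
.check_scenario_common <- function(n, sigma_e, alpha, allow_null_n = TRUE) {
  if (is.null(n)) {
    if (!allow_null_n) stop("sample size n is required here", call. = FALSE)
  } else {
    if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 3 ||
        n != round(n)) {
      stop("n must be an integer >= 3 (the F test needs n - 2 >= 1 ",
           "denominator degrees of freedom); got n = ", format(n),
           call. = FALSE)
    }
  }
  if (!is.numeric(sigma_e) || length(sigma_e) != 1L || !is.finite(sigma_e) ||
      sigma_e < 0) {
    stop("sigma_e must be a nonnegative measurement-error SD; got ",
         format(sigma_e), call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly in (0, 1); got ", format(alpha),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Scenario for testing genotype effects on the phenotype mean
#'
#' Parameterizes one power calculation for the comparison-of-means trend
#' test. The true phenotype is standardized (unit variance), the SNP shifts
#' the mean by `beta` standard deviations per copy of the minor allele, and
#' independent measurement error with SD `sigma_e` (in units of the true
#' phenotype SD) is added on top.
#'
#' The residual variance is \eqn{1 - \beta^2 \, 2p(1-p)} so that the true
#' phenotype has total variance exactly 1; the constraint
#' \eqn{\beta^2 2p(1-p) \le 1 + \sigma_e^2} keeps the squared correlation in
#' \[0, 1\] and is enforced here.
#'
#' @param beta Per-allele shift of the standardized true phenotype (SD units).
#' @param maf Minor allele frequency (0, 1).
#' @param n Total sample size (>= 3), or `NULL` when the scenario is only
#'   used for sample-size inversion via [required_n()].
#' @param sigma_e Measurement-error SD in units of the true-phenotype SD.
#' @param alpha Significance level of the test.
#' @return An object of class `c("mean_scenario", "pheno_scenario")`.
#' @seealso [variance_scenario()], [analytic_power()], [required_n()]
#' @examples
#' mean_scenario(beta = 0.06, maf = 0.2, n = 15000)
#' @export
mean_scenario <- function(beta, maf, n = NULL, sigma_e = 0, alpha = 0.05) {
  dist <- hwe_distribution(maf)
  .check_scenario_common(n, sigma_e, alpha)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta)) {
    stop("beta must be a finite number", call. = FALSE)
  }
  if (beta^2 * dist$var_g > 1 + sigma_e^2) {
    stop("beta^2 * 2p(1-p) must be <= 1 + sigma_e^2 so that the squared ",
         "correlation stays in [0, 1]; got ",
         format(beta^2 * dist$var_g), " > ", format(1 + sigma_e^2),
         call. = FALSE)
  }
  structure(
    list(beta = beta, dist = dist, n = n, sigma_e = sigma_e, alpha = alpha),
    class = c("mean_scenario", "pheno_scenario"))
}

#' Scenario for testing genotype effects on the phenotype variance
#'
#' Parameterizes one power calculation for the variance-heterogeneity (vQTL)
#' test. The phenotype is conditionally normal with mean 0 and variance
#' \eqn{1 + \beta_v g} (baseline variance 1 for the AA genotype), plus
#' independent measurement error variance \eqn{\sigma_e^2}. The test
#' regresses the squared standardized phenotype on allelic dosage.
#'
#' @param beta_v Per-allele additive increment of the phenotypic variance on
#'   a scale where the AA-genotype variance is 1. Must exceed -0.5 so all
#'   three conditional variances stay positive.
#' @inheritParams mean_scenario
#' @return An object of class `c("variance_scenario", "pheno_scenario")`.
#' @seealso [mean_scenario()], [moment_table()], [analytic_power()]
#' @examples
#' variance_scenario(beta_v = 0.06, maf = 0.2, n = 30000)
#' @export
variance_scenario <- function(beta_v, maf, n = NULL, sigma_e = 0,
                              alpha = 0.05) {
  dist <- hwe_distribution(maf)
  .check_scenario_common(n, sigma_e, alpha)
  if (!is.numeric(beta_v) || length(beta_v) != 1L || !is.finite(beta_v)) {
    stop("beta_v must be a finite number", call. = FALSE)
  }
  if (beta_v <= -0.5) {
    stop("1 + beta_v * g must be > 0 for g in {0, 1, 2}, i.e. beta_v > -0.5; ",
         "got beta_v = ", format(beta_v), call. = FALSE)
  }
  structure(
    list(beta_v = beta_v, dist = dist, n = n, sigma_e = sigma_e,
         alpha = alpha),
    class = c("variance_scenario", "pheno_scenario"))
}

# effect size and human-readable kind, used by the simulator and CLI
.effect <- function(s) if (inherits(s, "mean_scenario")) s$beta else s$beta_v

.test_kind <- function(s) {
  if (inherits(s, "mean_scenario")) "means" else "variances"
}

#' @export
print.pheno_scenario <- function(x, ...) {
  cat(sprintf("%s-comparison scenario\n",
              if (inherits(x, "mean_scenario")) "Mean" else "Variance"))
  cat(sprintf("  effect %s = %g, MAF = %g, n = %s\n",
              if (inherits(x, "mean_scenario")) "beta" else "beta_v",
              .effect(x), x$dist$p,
              if (is.null(x$n)) "(unset)" else format(x$n)))
  cat(sprintf("  sigma_e = %g, alpha = %g\n", x$sigma_e, x$alpha))
  invisible(x)
}
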