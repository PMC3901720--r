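#' Squared correlation between phenotype and dosage
#'
#' The squared correlation coefficient \eqn{\rho^2} that drives the
#' non-central-F power calculation: between the observed phenotype and
#' allelic dosage for a mean-effect scenario, or between the squared
#' standardized phenotype and dosage for a variance-effect scenario.
#'
#' For the mean-effect model,
#' \deqn{\rho^2 = \frac{\beta^2 \, 2p(1-p)}{1 + \sigma_e^2},}
#' which reduces to \eqn{\beta^2 2p(1-p)} without measurement error.
#'
#' For the variance-effect model, with \eqn{v = 2p(1-p)} and the expectation
#' taken over the HWE genotype law,
#' \deqn{\rho^2 = \frac{\beta_v^2 v}
#'   {2\,E_g\!\left[(1+\beta_v g+\sigma_e^2)^2\right] + \beta_v^2 v},}
#' the squared correlation between \eqn{y^2} and \eqn{g} when \eqn{y} is
#' conditionally normal with variance \eqn{1+\beta_v g+\sigma_e^2}.
#'
#' @param s A scenario from [mean_scenario()] or [variance_scenario()].
#' @return The squared correlation, a number in \[0, 1\].
#' @examples
#' rho_sq(mean_scenario(0.06, 0.2, 15000))              # 0.001152
#' rho_sq(mean_scenario(0.06, 0.2, 15000, sigma_e = 1)) # halved
#' @export
rho_sq <- function(s) UseMethod("rho_sq")

#' @rdname rho_sq
#' @export
rho_sq.mean_scenario <- function(s) {
  rho_sq_means(beta = s$beta, maf = s$dist$p, sigma_e = s$sigma_e)
}

#' @rdname rho_sq
#' @export
rho_sq.variance_scenario <- function(s) {
  rho_sq_variances(beta_v = s$beta_v, maf = s$dist$p, sigma_e = s$sigma_e)
}

#' @rdname rho_sq
#' @param beta,beta_v,maf,sigma_e Raw parameters, for callers that do not
#'   want to build a scenario object first.
#' @export
rho_sq_means <- function(beta, maf, sigma_e = 0) {
  v <- hwe_distribution(maf)$var_g
  num <- beta^2 * v
  if (num > 1 + sigma_e^2) {
    stop("beta^2 * 2p(1-p) must be <= 1 + sigma_e^2; got ",
         format(num), call. = FALSE)
  }
  num / (1 + sigma_e^2)
}

# E_g[(1 + beta_v g + c)^2] under HWE: E[g] = 2p, E[g^2] = 2p(1-p) + 4p^2
.second_moment_sq <- function(beta_v, maf, const) {
  d <- hwe_distribution(maf)
  Eg <- d$mean_g
  Eg2 <- d$var_g + d$mean_g^2
  (1 + const)^2 + 2 * (1 + const) * beta_v * Eg + beta_v^2 * Eg2
}

#' @rdname rho_sq
#' @export
rho_sq_variances <- function(beta_v, maf, sigma_e = 0) {
  if (beta_v <= -0.5) {
    stop("beta_v must be > -0.5 so all conditional variances are positive",
         call. = FALSE)
  }
  v <- hwe_distribution(maf)$var_g
  num <- beta_v^2 * v
  num / (2 * .second_moment_sq(beta_v, maf, sigma_e^2) + num)
}

#' Per-genotype moments of the variance-effect phenotype model
#'
#' Tabulates, for each genotype, the HWE frequency, the dosage, and the
#' second and fourth moments of the conditionally normal phenotype, both
#' without measurement error (conditional variance \eqn{1+\beta_v g}) and
#' with it (variance incremented by \eqn{\sigma_e^2}). For a zero-mean
#' normal with variance \eqn{s^2}, \eqn{E(y^2)=s^2} and \eqn{E(y^4)=3s^4}.
#'
#' @param s A [variance_scenario()].
#' @return A data frame with one row per genotype (AA, AB, BB) and columns
#'   `genotype`, `freq`, `g`, `Ey2`, `Ey4` (error-free) and `Ey2_err`,
#'   `Ey4_err` (with measurement error).
#' @examples
#' moment_table(variance_scenario(0.1, 0.2, 1000))
#' @export
moment_table <- function(s) {
  if (!inherits(s, "variance_scenario")) {
    stop("moment_table() expects a variance_scenario", call. = FALSE)
  }
  g <- 0:2
  freq <- c(s$dist$freq_AA, s$dist$freq_AB, s$dist$freq_BB)
  v0 <- 1 + s$beta_v * g
  ve <- v0 + s$sigma_e^2
  data.frame(genotype = c("AA", "AB", "BB"),
             freq = freq,
             g = g,
             Ey2 = v0,
             Ey4 = 3 * v0^2,
             Ey2_err = ve,
             Ey4_err = 3 * ve^2)
}
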