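# Independent oracles used across the suite. These deliberately avoid the
# package's closed forms: rho^2 by enumeration over the three genotypes,
# power by numeric integration of the non-central F density.

enum_rho_sq_means <- function(beta, p, sigma_e) {
  g <- 0:2
  f <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  mu <- beta * g                       # conditional mean
  v <- (1 - beta^2 * 2 * p * (1 - p)) + sigma_e^2  # conditional variance
  Eg <- sum(f * g)
  Vg <- sum(f * g^2) - Eg^2
  Ey <- sum(f * mu)
  Vy <- sum(f * (v + mu^2)) - Ey^2
  cov <- sum(f * g * mu) - Eg * Ey
  cov^2 / (Vg * Vy)
}

enum_rho_sq_variances <- function(beta_v, p, sigma_e) {
  g <- 0:2
  f <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  s2 <- 1 + beta_v * g + sigma_e^2     # conditional variance of y
  Ey2 <- sum(f * s2)                   # E[y^2]
  Ey4 <- sum(f * 3 * s2^2)             # normal fourth moment 3 s^4
  Eg <- sum(f * g)
  Vg <- sum(f * g^2) - Eg^2
  cov <- sum(f * g * s2) - Eg * Ey2
  cov^2 / (Vg * (Ey4 - Ey2^2))
}

# power by quadrature of the non-central F density over the rejection region
quad_power <- function(lambda, n, alpha) {
  crit <- qf(1 - alpha, 1, n - 2)
  stats::integrate(function(x) stats::df(x, 1, n - 2, ncp = lambda),
                   crit, Inf, rel.tol = 1e-10)$value
}

# simulated repeated-measurement pairs with known error SD (true-trait units)
make_repeats <- function(n, sigma_e) {
  z <- rnorm(n)
  data.frame(m1 = z + rnorm(n, 0, sigma_e),
             m2 = z + rnorm(n, 0, sigma_e))
}

# Table 2 of printed cost coefficients (percent, 1 decimal)
printed_cost_table <- data.frame(
  sigma_e = seq(0.1, 1.0, by = 0.1),
  cost_means = c(1.0, 4.0, 9.0, 16.0, 25.0, 36.0, 49.1, 64.1, 81.1, 100.1),
  cost_variances = c(2.0, 8.0, 18.3, 33.7, 54.7, 82.6, 118.5, 163.9,
                     220.5, 290.4))
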