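#' Simulate allelic dosages under Hardy-Weinberg equilibrium
#'
#' Draws `n` dosages from Binomial(2, p), the genotype law of a biallelic
#' SNP at minor allele frequency `p` under HWE. Uses R's global RNG;
#' call `set.seed()` for reproducibility.
#'
#' @param n Number of individuals.
#' @param p Minor allele frequency.
#' @return Integer vector of dosages in \{0, 1, 2\}.
#' @examples
#' set.seed(1); table(simulate_genotypes(1000, 0.2))
#' @export
simulate_genotypes <- function(n, p) {
  hwe_distribution(p)  # validates p
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  rbinom(n, 2L, p)
}

#' Simulate phenotypes under the mean-effect model
#'
#' \eqn{y_i = \beta g_i + \varepsilon_i + e_i} with residual
#' \eqn{\varepsilon \sim N(0, 1-\beta^2 2p(1-p))} (so the true phenotype has
#' unit variance) and measurement error \eqn{e \sim N(0, \sigma_e^2)},
#' independent of each other and of genotype. The two independent normal
#' noise terms are drawn as a single normal with their summed variance,
#' which leaves the law of `y` unchanged.
#'
#' @param g Dosage vector (from [simulate_genotypes()]).
#' @param beta Per-allele mean shift in true-phenotype SD units.
#' @param maf Minor allele frequency used to size the residual variance.
#' @param sigma_e Measurement-error SD.
#' @return Numeric phenotype vector, same length as `g`.
#' @export
simulate_phenotype_means <- function(g, beta, maf, sigma_e = 0) {
  resid <- 1 - beta^2 * hwe_distribution(maf)$var_g
  if (resid <= 0) {
    stop("residual variance 1 - beta^2 * 2p(1-p) must be positive",
         call. = FALSE)
  }
  beta * g + rnorm(length(g), 0, sqrt(resid + sigma_e^2))
}

#' Simulate phenotypes under the variance-effect model
#'
#' \eqn{y_i \sim N(0, 1+\beta_v g_i)} plus independent measurement error of
#' variance \eqn{\sigma_e^2}; drawn as one conditional normal with variance
#' \eqn{1+\beta_v g_i+\sigma_e^2}.
#'
#' @param g Dosage vector.
#' @param beta_v Per-allele variance increment (> -0.5).
#' @param sigma_e Measurement-error SD.
#' @return Numeric phenotype vector, same length as `g`.
#' @export
simulate_phenotype_variances <- function(g, beta_v, sigma_e = 0) {
  v <- 1 + beta_v * g + sigma_e^2
  if (any(v <= 0)) {
    stop("conditional variance 1 + beta_v * g must be positive for all ",
         "genotypes", call. = FALSE)
  }
  rnorm(length(g), 0, sqrt(v))
}

#' Regression trend test of phenotype on allelic dosage
#'
#' Two-sided p-value of the slope in simple linear regression of `y` on
#' `g`, computed as the F(1, n-2) test. `vqtl_trend_test()` first
#' standardizes `y` by its sample mean and SD and squares it, the
#' variance-heterogeneity regressand.
#'
#' @param y Phenotype vector.
#' @param g Dosage vector of the same length.
#' @return The p-value.
#' @examples
#' set.seed(1)
#' g <- simulate_genotypes(500, 0.2)
#' trend_test(simulate_phenotype_means(g, 0.3, 0.2), g)
#' @export
trend_test <- function(y, g) {
  n <- length(y)
  if (length(g) != n) stop("y and g must have equal length", call. = FALSE)
  if (n < 3) stop("need n >= 3 observations", call. = FALSE)
  sxx <- sum(g^2) - sum(g)^2 / n
  if (sxx <= 0) {
    stop("genotype vector is constant; the trend test is undefined",
         call. = FALSE)
  }
  syy <- sum(y^2) - sum(y)^2 / n
  if (syy <= 0) return(1)  # constant phenotype: no association
  sxy <- sum(g * y) - sum(g) * sum(y) / n
  r2 <- sxy^2 / (sxx * syy)
  if (r2 >= 1) return(0)  # exact linear relation
  f <- (n - 2) * r2 / (1 - r2)
  pf(f, 1, n - 2, lower.tail = FALSE)
}

#' @rdname trend_test
#' @export
vqtl_trend_test <- function(y, g) {
  s <- sd(y)
  if (!is.finite(s) || s <= 0) {
    stop("phenotype has zero variance; cannot standardize", call. = FALSE)
  }
  z <- (y - mean(y)) / s
  trend_test(z^2, g)
}

# Deterministic per-cell seed: polynomial hash of the canonical parameter
# string combined with the root seed, reduced mod 2^31 - 1. Results for a
# grid cell are therefore invariant to the cell's position in the grid.
.cell_seed <- function(s, reps, root_seed) {
  key <- sprintf("%s|p=%.10g|n=%d|effect=%.10g|se=%.10g|alpha=%.10g|reps=%d",
                 .test_kind(s), s$dist$p, as.integer(s$n), .effect(s),
                 s$sigma_e, s$alpha, as.integer(reps))
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + (as.numeric(root_seed) %% 2147483647) * 69069) %%
               2147483647)
}

#' Empirical power of a scenario by Monte-Carlo simulation
#'
#' Simulates `reps` independent studies under the scenario (genotypes from
#' Binomial(2, p), phenotypes from the mean- or variance-effect model with
#' measurement error), applies the trend test at level `alpha`, and reports
#' the rejection fraction next to the analytic power.
#'
#' The default engine is compiled (one-pass accumulation of the regression
#' sums, no stored vectors); `engine = "r"` runs the same pipeline through
#' [simulate_genotypes()], the phenotype simulators and [trend_test()] one
#' replicate at a time, as an independent cross-check. The two engines
#' consume random numbers in different orders, so they agree statistically,
#' not replicate-by-replicate.
#'
#' @param s A scenario with `n` set.
#' @param reps Number of replicate studies.
#' @param seed Root seed; the cell's RNG stream is derived from it and the
#'   scenario parameters (see [run_grid()]), so results are reproducible.
#' @param engine `"compiled"` (default) or `"r"`.
#' @return An object of class `simulation_outcome`: a one-row data frame
#'   with columns `test_kind`, `p`, `n`, `effect`, `sigma_e`, `alpha`,
#'   `reps`, `seed`, `empirical_power`, `mc_se`, `analytic_power`,
#'   `abs_diff`.
#' @examples
#' empirical_power(mean_scenario(0.3, 0.2, 200), reps = 200, seed = 1)
#' @export
empirical_power <- function(s, reps = 10000, seed = 1L,
                            engine = c("compiled", "r")) {
  engine <- match.arg(engine)
  if (!inherits(s, "pheno_scenario")) {
    stop("empirical_power() expects a scenario object", call. = FALSE)
  }
  .check_scenario_common(s$n, s$sigma_e, s$alpha, allow_null_n = FALSE)
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  ap <- analytic_power(s)
  cell <- .cell_seed(s, reps, seed)
  is_means <- inherits(s, "mean_scenario")

  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cell)

  if (engine == "compiled") {
    hits <- .sim_count_rejections(if (is_means) 0L else 1L,
                                  as.integer(s$n), s$dist$p, .effect(s),
                                  s$sigma_e, ap$critical_value,
                                  as.integer(reps))
  } else {
    hits <- 0L
    for (r in seq_len(reps)) {
      g <- simulate_genotypes(s$n, s$dist$p)
      pv <- if (is_means) {
        y <- simulate_phenotype_means(g, s$beta, s$dist$p, s$sigma_e)
        if (var(g) == 0) 1 else trend_test(y, g)
      } else {
        y <- simulate_phenotype_variances(g, s$beta_v, s$sigma_e)
        if (var(g) == 0) 1 else vqtl_trend_test(y, g)
      }
      if (pv < s$alpha) hits <- hits + 1L
    }
  }
  phat <- hits / reps
  out <- data.frame(test_kind = .test_kind(s),
                    p = s$dist$p,
                    n = s$n,
                    effect = .effect(s),
                    sigma_e = s$sigma_e,
                    alpha = s$alpha,
                    reps = as.integer(reps),
                    seed = as.integer(seed),
                    empirical_power = phat,
                    mc_se = sqrt(phat * (1 - phat) / reps),
                    analytic_power = ap$power,
                    abs_diff = abs(phat - ap$power),
                    stringsAsFactors = FALSE)
  class(out) <- c("simulation_outcome", "data.frame")
  out
}

#' Run a grid of power simulations
#'
#' Runs [empirical_power()] for every scenario in a list and stacks the
#' outcomes. Each cell draws from its own RNG stream derived from the root
#' seed and the cell's parameters, so the table is bit-identical under
#' re-runs and invariant to reordering of the scenario list.
#'
#' @param scenarios A list of scenario objects.
#' @param reps Replicates per cell.
#' @param seed Root seed.
#' @param engine Passed to [empirical_power()].
#' @return A data frame (class `power_grid`) with one row per cell plus a
#'   `summary` attribute: per-test-kind and overall mean and max `abs_diff`.
#' @examples
#' g <- default_grid(sigma_e = c(0, 0.5))
#' run_grid(g, reps = 50, seed = 1)
#' @export
run_grid <- function(scenarios, reps = 10000, seed = 1L,
                     engine = c("compiled", "r")) {
  engine <- match.arg(engine)
  if (!length(scenarios)) stop("empty scenario list", call. = FALSE)
  rows <- vector("list", length(scenarios))
  for (i in seq_along(scenarios)) {
    rows[[i]] <- tryCatch(
      empirical_power(scenarios[[i]], reps = reps, seed = seed,
                      engine = engine),
      error = function(e) {
        warning("grid cell ", i, " failed: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("every grid cell failed", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  kinds <- unique(out$test_kind)
  summ <- do.call(rbind, lapply(c(kinds, "all"), function(k) {
    d <- if (k == "all") out else out[out$test_kind == k, ]
    data.frame(test_kind = k,
               cells = nrow(d),
               mean_abs_diff = mean(d$abs_diff),
               max_abs_diff = max(d$abs_diff),
               stringsAsFactors = FALSE)
  }))
  attr(out, "summary") <- summ
  class(out) <- c("power_grid", "data.frame")
  out
}

#' @export
print.power_grid <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  s <- attr(x, "summary")
  if (!is.null(s)) {
    cat("\nAgreement between empirical and analytic power:\n")
    print.data.frame(s, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Default verification grid
#'
#' The default simulation configurations: comparison of means at p = 0.2,
#' n = 15,000, beta = 0.06 and comparison of variances at p = 0.2,
#' n = 30,000, beta_v = 0.06, each across a grid of measurement-error SDs,
#' at alpha = 0.05.
#'
#' @param sigma_e Measurement-error SDs (default 0 to 1 in steps of 0.1).
#' @param tests Which test kinds to include.
#' @return A list of scenario objects.
#' @export
default_grid <- function(sigma_e = seq(0, 1, by = 0.1),
                         tests = c("means", "variances")) {
  tests <- match.arg(tests, several.ok = TRUE)
  out <- list()
  if ("means" %in% tests) {
    out <- c(out, lapply(sigma_e, function(se)
      mean_scenario(0.06, 0.2, 15000, sigma_e = se, alpha = 0.05)))
  }
  if ("variances" %in% tests) {
    out <- c(out, lapply(sigma_e, function(se)
      variance_scenario(0.06, 0.2, 30000, sigma_e = se, alpha = 0.05)))
  }
  out
}
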