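test_that("simulated genotypes match the binomial law at large n", {
  set.seed(101)
  n <- 1e6; p <- 0.3
  g <- simulate_genotypes(n, p)
  expect_true(all(g %in% 0:2))
  v <- 2 * p * (1 - p)
  expect_lt(abs(mean(g) - 2 * p), 3 * sqrt(v / n))
  # SE of the sample variance of a bounded variate, normal approximation
  m4 <- mean((g - mean(g))^4)
  expect_lt(abs(var(g) - v), 3 * sqrt((m4 - v^2) / n))
  set.seed(77)
  g1 <- simulate_genotypes(1000, 0.2)
  set.seed(77)
  expect_identical(g1, simulate_genotypes(1000, 0.2))
})

test_that("mean-model phenotypes have the specified moments", {
  set.seed(102)
  n <- 1e6
  g <- simulate_genotypes(n, 0.2)
  y0 <- simulate_phenotype_means(g, 0, 0.2, sigma_e = 0)
  expect_lt(abs(var(y0) - 1), 3 * sqrt(2 / n))
  y <- simulate_phenotype_means(g, 0.3, 0.2, sigma_e = 0.5)
  # total variance beta^2 v + resid + sigma_e^2 = 1 + sigma_e^2
  expect_lt(abs(var(y) - 1.25), 3 * sqrt(2 / n) * 1.25 * 2)
  # group means step by beta per allele
  mg <- tapply(y, g, mean)
  for (k in 1:2) {
    n_pair <- min(table(g)[k], table(g)[k + 1])
    expect_lt(abs((mg[k + 1] - mg[k]) - 0.3),
              3 * sqrt(2 * 1.25 / n_pair))
  }
  expect_error(simulate_phenotype_means(g, 1.9, 0.5), "residual variance")
})

test_that("variance-model phenotypes have per-genotype normal moments", {
  set.seed(103)
  n <- 6e5
  g <- simulate_genotypes(n, 0.3)
  y <- simulate_phenotype_variances(g, 0.4, sigma_e = 0.5)
  for (k in 0:2) {
    yk <- y[g == k]
    vk <- 1 + 0.4 * k + 0.25
    expect_lt(abs(var(yk) - vk), 3 * vk * sqrt(2 / length(yk)))
    # normal kurtosis: fourth moment is 3 * variance^2 (SE from m8 = 105 s^8)
    expect_lt(abs(mean(yk^4) - 3 * vk^2),
              3 * sqrt((105 - 9) * vk^4 / length(yk)))
  }
  y0 <- simulate_phenotype_variances(g, 0, sigma_e = 0.5)
  expect_lt(abs(var(y0) - 1.25), 3 * 1.25 * sqrt(2 / n))
  expect_error(simulate_phenotype_variances(g, -0.6), "positive")
})

test_that("trend test matches lm's F test and handles edge cases", {
  set.seed(104)
  for (i in 1:5) {
    g <- simulate_genotypes(50, 0.3)
    y <- simulate_phenotype_means(g, 0.4, 0.3)
    fit <- summary(lm(y ~ g))
    expect_equal(trend_test(y, g), fit$coefficients["g", "Pr(>|t|)"],
                 tolerance = 1e-9)
    # t^2 equals the F statistic
    expect_equal(fit$coefficients["g", "t value"]^2, fit$fstatistic[["value"]],
                 tolerance = 1e-9)
  }
  g <- c(0, 1, 2, 1, 0, 2)
  expect_equal(trend_test(2 + 3 * g, g), 0)  # exact linearity
  expect_error(trend_test(rnorm(10), rep(1, 10)), "constant")
  # vqtl variant is invariant to affine transformation of the phenotype
  y <- rnorm(200); g <- simulate_genotypes(200, 0.4)
  expect_equal(vqtl_trend_test(y, g), vqtl_trend_test(5 - 2 * y, g),
               tolerance = 1e-9)
})

test_that("permuting the phenotype destroys the association", {
  set.seed(105)
  g <- simulate_genotypes(300, 0.3)
  y <- simulate_phenotype_means(g, 0.5, 0.3)
  expect_lt(trend_test(y, g), 1e-6)
  rej <- mean(replicate(400, trend_test(sample(y), g) < 0.05))
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("empirical power is reproducible and matches between engines", {
  s <- mean_scenario(0.25, 0.3, 400)
  o1 <- empirical_power(s, reps = 300, seed = 42)
  o2 <- empirical_power(s, reps = 300, seed = 42)
  expect_identical(o1, o2)
  expect_equal(o1$mc_se,
               sqrt(o1$empirical_power * (1 - o1$empirical_power) / 300))
  # compiled and R-level paths agree within Monte-Carlo error
  or <- empirical_power(s, reps = 300, seed = 43, engine = "r")
  ap <- analytic_power(s)$power
  se_pair <- sqrt(2 * ap * (1 - ap) / 300)
  expect_lt(abs(o1$empirical_power - or$empirical_power), 3 * se_pair)
  expect_lt(or$abs_diff, 3 * sqrt(ap * (1 - ap) / 300) + 0.005)
  # degenerate replicate counts
  o_single <- empirical_power(s, reps = 1, seed = 1)
  expect_true(o_single$empirical_power %in% c(0, 1))
})

test_that("the R engine agrees for the variance test too", {
  s <- variance_scenario(0.8, 0.3, 500)
  oc <- empirical_power(s, reps = 250, seed = 7)
  or <- empirical_power(s, reps = 250, seed = 7, engine = "r")
  ap <- analytic_power(s)$power
  expect_lt(abs(oc$empirical_power - or$empirical_power),
            3 * sqrt(2 * ap * (1 - ap) / 250) + 0.01)
})

test_that("grids are reproducible and invariant to cell order", {
  scen <- list(mean_scenario(0.3, 0.2, 300),
               mean_scenario(0.3, 0.2, 300, sigma_e = 0.5),
               variance_scenario(0.8, 0.2, 300))
  strip <- function(d, idx = seq_len(nrow(d))) {
    d <- as.data.frame(d)[idx, ]
    class(d) <- "data.frame"
    attr(d, "summary") <- NULL
    rownames(d) <- NULL
    d
  }
  g1 <- run_grid(scen, reps = 100, seed = 9)
  g2 <- run_grid(rev(scen), reps = 100, seed = 9)
  expect_identical(strip(g1), strip(g2, 3:1))
  summ <- attr(g1, "summary")
  expect_equal(summ$max_abs_diff[summ$test_kind == "all"], max(g1$abs_diff))
  expect_equal(summ$mean_abs_diff[summ$test_kind == "all"],
               mean(g1$abs_diff))
  # single-cell grid: summary equals the lone outcome
  g3 <- run_grid(list(mean_scenario(0, 0.2, 300)), reps = 100, seed = 9)
  s3 <- attr(g3, "summary")
  expect_equal(s3$mean_abs_diff, rep(g3$abs_diff, 2))
})
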