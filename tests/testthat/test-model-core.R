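test_that("HWE distribution has the right frequencies and moments", {
  d <- hwe_distribution(0.2)
  expect_equal(c(d$freq_AA, d$freq_AB, d$freq_BB), c(0.64, 0.32, 0.04))
  expect_equal(d$freq_AA + d$freq_AB + d$freq_BB, 1, tolerance = 1e-12)
  expect_equal(d$mean_g, 0.4)
  expect_equal(d$var_g, 0.32)
  expect_equal(hwe_distribution(0.5)$var_g, 0.5)  # maximum at p = 0.5
  for (p in c(0.01, 0.13, 0.37, 0.8)) {
    d <- hwe_distribution(p)
    expect_lte(d$var_g, 0.5)
    expect_equal(d$freq_AA + d$freq_AB + d$freq_BB, 1, tolerance = 1e-12)
  }
})

test_that("out-of-range allele frequencies are rejected by name", {
  expect_error(hwe_distribution(0), "0, 1")
  expect_error(hwe_distribution(1), "0, 1")
  expect_error(hwe_distribution(-0.2), "-0.2")
  expect_error(hwe_distribution(1.5), "1.5")
})

test_that("scenario constructors enforce their invariants", {
  expect_error(mean_scenario(0.06, 0.2, n = 2), "n - 2")
  expect_error(mean_scenario(0.06, 0.2, 100, alpha = 0), "alpha")
  expect_error(mean_scenario(0.06, 0.2, 100, sigma_e = -1), "sigma_e")
  # beta^2 * 2p(1-p) must not exceed 1 + sigma_e^2
  expect_error(mean_scenario(2, 0.5, 100), "1 \\+ sigma_e\\^2")
  expect_silent(mean_scenario(2, 0.5, 100, sigma_e = 1.1))
  expect_error(variance_scenario(-0.5, 0.2, 100), "beta_v > -0.5")
  expect_silent(variance_scenario(-0.49, 0.2, 100))
})

test_that("rho^2 for the means test matches hand-derived values", {
  expect_equal(rho_sq_means(0.06, 0.2, 0), 0.001152, tolerance = 1e-12)
  expect_equal(rho_sq_means(0.06, 0.2, 1), 0.000576, tolerance = 1e-12)
  expect_equal(rho_sq_means(0, 0.37, 0.5), 0)
  s <- mean_scenario(0.06, 0.2, 15000, sigma_e = 1)
  expect_equal(rho_sq(s), 0.000576, tolerance = 1e-12)
})

test_that("rho^2 for the variance test matches the enumeration value", {
  # denominator 2 * E_g[(1 + 0.06 g)^2] + beta_v^2 v with
  # E_g[(1 + 0.06 g)^2] = 1 + 2*0.06*0.4 + 0.0036*0.48 = 1.049728
  expect_equal(rho_sq_variances(0.06, 0.2, 0),
               0.001152 / (2 * 1.049728 + 0.001152), tolerance = 1e-12)
  expect_equal(rho_sq_variances(0, 0.2, 0.5), 0)
  # odds ratio under sigma_e = 1 vs 0 equals the second-moment ratio
  r0 <- rho_sq_variances(0.06, 0.2, 0)
  r1 <- rho_sq_variances(0.06, 0.2, 1)
  expect_equal((r1 / (1 - r1)) / (r0 / (1 - r0)), 1.049728 / 4.097728,
               tolerance = 1e-12)
})

test_that("closed-form rho^2 equals brute-force genotype enumeration", {
  for (p in c(0.05, 0.2, 0.5, 0.8)) {
    for (se in c(0, 0.3, 1)) {
      expect_equal(rho_sq_means(0.06, p, se),
                   enum_rho_sq_means(0.06, p, se), tolerance = 1e-10)
      expect_equal(rho_sq_variances(0.1, p, se),
                   enum_rho_sq_variances(0.1, p, se), tolerance = 1e-10)
    }
  }
})

test_that("rho^2 is strictly decreasing in measurement error", {
  se <- seq(0, 2, by = 0.25)
  rm_ <- vapply(se, function(s) rho_sq_means(0.06, 0.2, s), numeric(1))
  rv <- vapply(se, function(s) rho_sq_variances(0.06, 0.2, s), numeric(1))
  expect_true(all(diff(rm_) < 0))
  expect_true(all(diff(rv) < 0))
})

test_that("rho^2 is invariant under effect-sign flip and allele relabeling", {
  expect_equal(rho_sq_means(0.06, 0.2, 0.4), rho_sq_means(-0.06, 0.2, 0.4))
  # relabeling alleles: p -> 1 - p with g -> 2 - g leaves rho^2 unchanged
  expect_equal(rho_sq_means(0.06, 0.2, 0.4), rho_sq_means(0.06, 0.8, 0.4))
  # variance model: the relabeled model has baseline variance 1 + 2 beta_v,
  # so the matching transformation is beta_v' = -beta_v / (1 + 2 beta_v)
  # and sigma_e' = sigma_e / sqrt(1 + 2 beta_v)
  bv <- 0.06; se <- 0.4
  expect_equal(rho_sq_variances(bv, 0.2, se),
               rho_sq_variances(-bv / (1 + 2 * bv), 0.8,
                                se / sqrt(1 + 2 * bv)),
               tolerance = 1e-10)
})

test_that("genotype moment table obeys the normal-moment identities", {
  tab <- moment_table(variance_scenario(0.1, 0.2, 1000))
  expect_equal(tab$Ey2, c(1, 1.1, 1.2))
  expect_equal(tab$Ey4, 3 * tab$Ey2^2, tolerance = 1e-12)
  expect_equal(tab$Ey4[1], 3)   # AA baseline: unit variance, kurtosis 3
  expect_equal(tab$Ey2[3], 1.2) # BB at beta_v = 0.1
  expect_equal(tab$Ey4[3], 4.32)
  expect_equal(sum(tab$freq), 1, tolerance = 1e-12)

  with_err <- moment_table(variance_scenario(0.1, 0.2, 1000, sigma_e = 0.5))
  expect_equal(with_err$Ey2_err, with_err$Ey2 + 0.25, tolerance = 1e-12)
  expect_equal(with_err$Ey4_err, 3 * with_err$Ey2_err^2, tolerance = 1e-12)

  flat <- moment_table(variance_scenario(0, 0.3, 1000))
  expect_equal(flat$Ey2, rep(1, 3))
  expect_equal(flat$Ey4, rep(3, 3))
})
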