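test_that("variance building blocks match their definitions", {
  expect_equal(empirical_outcome_variance(c(1, 2, 3, 4)), 5 / 3)
  expect_equal(empirical_outcome_variance(rep(2, 5)), 0)
  expect_error(empirical_outcome_variance(1), "two")

  expect_equal(binary_outcome_variance(rep(c(0, 1), 10)), 0.25)
  d <- c(rep(1, 4312), rep(0, 4356))      # case-control sample fractions
  p <- 4312 / 8668
  expect_equal(binary_outcome_variance(d), p * (1 - p))
  expect_error(binary_outcome_variance(rep(1, 5)), "degenerate")
})

test_that("observed-scale heritability is the unclipped variance ratio", {
  expect_equal(heritability_observed(1, 1.111), 1 - 1 / 1.111)
  expect_equal(heritability_observed(2, 2), 0)
  expect_warning(h <- heritability_observed(1.05, 1), "outside")
  expect_equal(h, -0.05)
  expect_error(heritability_observed(1, 0), "sigma_total")
})

test_that("liability transform reproduces the case-control worked example", {
  # ascertainment-corrected transform at K = 0.004, P = sample fraction
  expect_equal(round(liability_transform(0.244, 0.004, 4312 / 8668), 3),
               0.110)
  expect_equal(liability_transform(0, 0.2, 0.5), 0)
  # closed form at K = 0.5 without ascertainment: 0.25 / dnorm(0)^2
  expect_equal(liability_transform(0.1, 0.5), 0.1 * 0.25 / dnorm(0)^2)
  expect_equal(liability_transform(0.1, 0.5), 0.1 * pi / 2)
  # both branches coincide at P = K
  for (K in c(0.01, 0.1, 0.5)) {
    expect_equal(liability_transform(0.3, K, P = K),
                 liability_transform(0.3, K))
  }
  # monotone increasing in the observed-scale value
  hs <- vapply(seq(0, 0.5, by = 0.05), liability_transform, 0,
               K = 0.01, P = 0.4)
  expect_true(all(diff(hs) > 0))
  expect_error(liability_transform(0.1, 1.2), "K")
  expect_error(liability_transform(0.1, 0.1, P = 0), "P")
})

test_that("covariate adjustment subtracts the explained covariate variance", {
  expect_equal(covariate_adjusted_heritability(0.8, 1, 0.2, 1.25), 0.2)
  expect_equal(covariate_adjusted_heritability(0.5, 0, 0.3, 1),
               heritability_observed(0.5, 1))
  # PSD quadratic form can only lower the estimate
  sw <- matrix(c(0.3, 0.1, 0.1, 0.2), 2)
  expect_lte(covariate_adjusted_heritability(0.5, c(1, -2), sw, 2),
             heritability_observed(0.5, 2))
  expect_error(covariate_adjusted_heritability(0.5, c(1, 2),
                                               diag(3), 1), "dimension")
})

test_that("continuous heritability is invariant to outcome rescaling", {
  r <- run_sim_replicate(301, n = 400, m = 120, p = 8, h2 = 0.4, ld = 0)
  ph <- r$sim$phenotypes
  ph_scaled <- new_phenotype_set("continuous", ph$y * 7.3,
                                 sample_id = ph$sample_id)
  res2 <- estimate_heritability(r$sim$genotypes, ph_scaled,
                                rcv_cfg = rcv_config(split_seed = 301))
  expect_equal(res2$h2_observed, r$res$h2_observed, tolerance = 1e-6)
})

test_that("zero-censoring survival reproduces the continuous path exactly", {
  r <- run_sim_replicate(311, n = 400, m = 120, p = 8, h2 = 0.4, ld = 0)
  ph <- r$sim$phenotypes
  ph_surv <- new_phenotype_set("survival", ph$y, event = rep(1, 400),
                               sample_id = ph$sample_id)
  cfg <- rcv_config(split_seed = 311, penalty_rule = "min")
  res_c <- estimate_heritability(r$sim$genotypes, ph, rcv_cfg = cfg)
  res_s <- estimate_heritability(r$sim$genotypes, ph_surv, rcv_cfg = cfg)
  expect_identical(res_s$h2_observed, res_c$h2_observed)
  expect_identical(res_s$sigma_e, res_c$sigma_e)
  expect_equal(res_s$sigma_total, res_c$sigma_total)
})

test_that("covariates are exempt from selection and adjust the estimate", {
  set.seed(321)
  n <- 600
  g <- make_geno_dataset(n, 80, seed = 33)
  xs <- standardize(g)
  w <- matrix(rnorm(n), ncol = 1)
  y <- as.vector(xs$matrix[, 1:4] %*% rep(0.3, 4) + 0.8 * w + rnorm(n))
  ph <- new_phenotype_set("continuous", y, covariates = w,
                          sample_id = g$sample_id)
  res <- estimate_heritability(g, ph, rcv_cfg = rcv_config(split_seed = 9))
  ph0 <- new_phenotype_set("continuous", y, sample_id = g$sample_id)
  res0 <- estimate_heritability(g, ph0, rcv_cfg = rcv_config(split_seed = 9))
  # removing the covariate-explained variance lowers the genetic share
  expect_lt(res$h2_observed, res0$h2_observed)
  expect_true(is.finite(res$h2_observed))
})

test_that("binary estimation attaches the liability-scale conversion", {
  r <- run_sim_replicate(341, n = 1200, m = 200, p = 10, h2 = 0.3,
                         outcome = "binary", K = 0.5)
  expect_false(is.null(r$res$h2_liability))
  expect_equal(r$res$P, mean(r$sim$phenotypes$y))
  expect_equal(r$res$z, dnorm(qnorm(1 - 0.5)))
  # with P = K = sample fraction the transform matches the direct formula
  expect_equal(r$res$h2_liability,
               liability_transform(r$res$h2_observed, 0.5, r$res$P))
})
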