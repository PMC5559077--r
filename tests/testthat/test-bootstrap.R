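test_that("bootstrap weights are positive, mean-1 and seed-deterministic", {
  w <- draw_bootstrap_weights(1e5, 1)
  expect_true(all(w > 0))
  expect_lt(abs(mean(w) - 1), 0.02)
  expect_identical(w, draw_bootstrap_weights(1e5, 1))
  expect_false(identical(w[1], draw_bootstrap_weights(1, 2)))
  # scale option shrinks the perturbation towards unit weights
  expect_equal(draw_bootstrap_weights(10, 3, scale = 0), rep(1, 10))
})

test_that("degenerate unit weights give identical replicates and SE 0", {
  xs <- standardize(make_geno_matrix(200, 40, seed = 91))
  y <- xs$matrix[, 3] * 0.5 + with_seed(92, rnorm(200))
  rcfg <- rcv_config(split_seed = 4, penalty_rule = "min")
  bcfg <- bootstrap_config(n_calibration = 2, n_replicates = 4,
                           seed = 7, weight_scale = 0)
  lam <- calibrate_penalty(xs$matrix, y, rcfg, bcfg)
  bt <- weighted_bootstrap_se(xs$matrix, y, "continuous", rcfg, bcfg, lam)
  expect_equal(bt$se, 0)
  expect_equal(length(unique(bt$replicates)), 1L)

  # with unit weights the calibrated penalty is the unweighted one-SE one
  sup <- lasso_select(xs$matrix[split_sample(200, 4)$A, ],
                      y[split_sample(200, 4)$A],
                      rcv_config(split_seed = 4, penalty_rule = "one_se"),
                      foldid_seed = herra:::child_seed(4, 11L))
  expect_equal(lam, mean(c(attr(sup, "lambda"), attr(lasso_select(
    xs$matrix[split_sample(200, 4)$B, ], y[split_sample(200, 4)$B],
    rcv_config(split_seed = 4, penalty_rule = "one_se"),
    foldid_seed = herra:::child_seed(4, 11L)), "lambda"))))
})

test_that("calibrated penalty exceeds the unweighted one-SE penalty", {
  xs <- standardize(make_geno_matrix(300, 60, seed = 93))
  y <- xs$matrix[, 1:3] %*% rep(0.4, 3) + with_seed(94, rnorm(300))
  rcfg <- rcv_config(split_seed = 11, penalty_rule = "one_se")
  lam_unw <- calibrate_penalty(xs$matrix, y, rcfg,
                               bootstrap_config(n_calibration = 1,
                                                n_replicates = 2,
                                                weight_scale = 0))
  lam_cal <- calibrate_penalty(xs$matrix, y, rcfg,
                               bootstrap_config(n_calibration = 20,
                                                n_replicates = 2,
                                                seed = 5))
  expect_gte(lam_cal, 0.9 * lam_unw)   # directional, with sampling slack
})

test_that("bootstrap SE tracks the Monte-Carlo variability of the estimate", {
  # Monte-Carlo truth: independent datasets
  mc <- vapply(1:25, function(i) {
    run_sim_replicate(2500 + i, n = 800, m = 150, p = 5, h2 = 0.3,
                      ld = 0, exact = TRUE)$res$h2_observed
  }, 0)
  # bootstrap on one fixture
  r <- run_sim_replicate(2400, n = 800, m = 150, p = 5, h2 = 0.3,
                         ld = 0, exact = TRUE)
  xs <- standardize(r$sim$genotypes)
  sel <- sis_screen(xs, r$sim$phenotypes$y, 0.3)
  xsel <- xs$matrix[, sel$snp_indices]
  rcfg <- rcv_config(split_seed = 2400, penalty_rule = "min")
  bcfg <- bootstrap_config(n_calibration = 10, n_replicates = 40, seed = 6)
  lam <- calibrate_penalty(xsel, r$sim$phenotypes$y, rcfg, bcfg)
  bt <- weighted_bootstrap_se(xsel, r$sim$phenotypes$y, "continuous",
                              rcfg, bcfg, lam)
  expect_gt(bt$se, sd(mc) / 2)
  expect_lt(bt$se, sd(mc) * 2)
})

test_that("bootstrap SE shrinks roughly like 1/sqrt(N)", {
  se_at <- function(n, seed) {
    r <- run_sim_replicate(seed, n = n, m = 150, p = 5, h2 = 0.3,
                           ld = 0, exact = TRUE)
    xs <- standardize(r$sim$genotypes)
    sel <- sis_screen(xs, r$sim$phenotypes$y, 0.3)
    xsel <- xs$matrix[, sel$snp_indices]
    rcfg <- rcv_config(split_seed = seed, penalty_rule = "min")
    bcfg <- bootstrap_config(n_calibration = 5, n_replicates = 30,
                             seed = 8)
    lam <- calibrate_penalty(xsel, r$sim$phenotypes$y, rcfg, bcfg)
    weighted_bootstrap_se(xsel, r$sim$phenotypes$y, "continuous", rcfg,
                          bcfg, lam)$se
  }
  ratio <- se_at(500, 2600) / se_at(2000, 2601)
  expect_gt(ratio, 1.2)      # expected ratio 2 with replicate noise
  expect_lt(ratio, 3.4)
})

test_that("estimate_heritability integrates the bootstrap SE", {
  r <- run_sim_replicate(2700, n = 400, m = 80, p = 5, h2 = 0.3, ld = 0)
  res <- estimate_heritability(r$sim$genotypes, r$sim$phenotypes,
                               rcv_cfg = rcv_config(split_seed = 2700),
                               bootstrap = bootstrap_config(
                                 n_calibration = 3, n_replicates = 10,
                                 seed = 9))
  expect_true(is.finite(res$se))
  expect_gt(res$se, 0)
  expect_length(res$bootstrap$replicates, 10)
})
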