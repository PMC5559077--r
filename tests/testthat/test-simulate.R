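test_that("haplotype-pool LD control produces the requested correlation", {
  # independence limit
  cfg0 <- sim_config(n_samples = 5000, n_snps = 40, n_causal = 2,
                     ld_decay = 0, seed = 101)
  g0 <- with_seed(101, simulate_genotypes(cfg0))
  r0 <- vapply(1:39, function(j) {
    cor(g0$genotypes[, j], g0$genotypes[, j + 1])
  }, 0)
  expect_lt(mean(abs(r0)), 0.06)

  # strong-LD regime
  cfg9 <- sim_config(n_samples = 5000, n_snps = 40, n_causal = 2,
                     ld_decay = 0.9, seed = 102)
  g9 <- with_seed(102, simulate_genotypes(cfg9))
  r9 <- vapply(1:39, function(j) {
    cor(g9$genotypes[, j], g9$genotypes[, j + 1])^2
  }, 0)
  expect_gt(mean(r9), 0.5)

  # empirical MAF stays inside the target range (sampling slack)
  expect_true(all(g9$maf >= cfg9$maf_range[1] - 0.03))
  expect_true(all(g9$maf <= cfg9$maf_range[2] + 0.03))
})

test_that("causal effect variance matches the heritability target", {
  g <- make_geno_dataset(100, 50, seed = 111)
  cfg1 <- sim_config(n_samples = 100, n_snps = 50, n_causal = 10,
                     h2 = 0.1, seed = 1)
  expect_equal(cfg1$h2 * cfg1$sigma_e2 / (1 - cfg1$h2), 1 / 9,
               tolerance = 1e-12)
  cfg6 <- sim_config(n_samples = 100, n_snps = 50, n_causal = 10,
                     h2 = 0.6, seed = 1)
  expect_equal(cfg6$h2 * cfg6$sigma_e2 / (1 - cfg6$h2), 1.5,
               tolerance = 1e-12)

  # exact-normalization mode pins sum(u^2) to sigma_g^2
  cfgx <- sim_config(n_samples = 100, n_snps = 50, n_causal = 10,
                     h2 = 0.6, exact_normalization = TRUE, seed = 2)
  tr <- with_seed(2, draw_causal_effects(cfgx, g))
  expect_equal(sum(tr$effects^2), 1.5, tolerance = 1e-12)
  expect_equal(tr$sigma_g2, 1.5)

  # random mode matches in expectation over draws
  cfgr <- sim_config(n_samples = 100, n_snps = 50, n_causal = 25,
                     h2 = 0.1, seed = 3)
  sg <- vapply(1:200, function(i) {
    with_seed(i, draw_causal_effects(cfgr, g))$sigma_g2
  }, 0)
  expect_lt(abs(mean(sg) - 1 / 9), 0.01)

  # MAF restriction errors out when too few rare SNPs exist
  cfgm <- sim_config(n_samples = 100, n_snps = 50, n_causal = 40,
                     h2 = 0.1, scenario = "maf_restricted",
                     causal_maf_max = 1e-6, seed = 4)
  expect_error(with_seed(4, draw_causal_effects(cfgm, g)), "MAF")
})

test_that("phenotype generation hits the documented population moments", {
  # var(Y) near sigma_g2 + sigma_e2 = 1.111 at h2 = 0.1
  cfg <- sim_config(n_samples = 20000, n_snps = 300, n_causal = 100,
                    h2 = 0.1, ld_decay = 0, exact_normalization = TRUE,
                    seed = 121)
  sim <- simulate_dataset(cfg)
  expect_lt(abs(var(sim$phenotypes$y) - 1.111), 0.05)

  # liability threshold 0 gives K = 0.5
  cfgb <- sim_config(n_samples = 10000, n_snps = 200, n_causal = 50,
                     h2 = 0.3, outcome = "binary", binary_K = 0.5,
                     seed = 122)
  simb <- simulate_dataset(cfgb)
  expect_lt(abs(mean(simb$phenotypes$y) - 0.5), 0.02)

  # sd-2 normal censoring gives ~50% censoring at h2 = 0.1
  cfgs <- sim_config(n_samples = 10000, n_snps = 200, n_causal = 50,
                     h2 = 0.1, outcome = "survival", seed = 123)
  sims <- simulate_dataset(cfgs)
  expect_lt(abs(mean(1 - sims$phenotypes$event) - 0.5), 0.04)
})

test_that("untyped-causal exclusions drop causal SNPs and their flanks", {
  g <- make_geno_dataset(50, 40, seed = 131)
  cfg <- sim_config(n_samples = 50, n_snps = 40, n_causal = 1, h2 = 0.1,
                    scenario = "untyped_causal", flank_exclusion = 5,
                    seed = 5)
  truth <- with_seed(5, draw_causal_effects(cfg, g))
  truth$causal_indices <- 10L
  ex <- apply_scenario_exclusions(g, truth, cfg)
  expect_identical(ex$genotypes$n_snps, 40L - 11L)
  expect_false(any(5:15 %in% ex$truth$observed_snp_indices))

  # clipping at the chromosome edge: causal 3rd from the end keeps only
  # the 5 + 3 = 8-SNP window that exists
  truth$causal_indices <- 3L
  ex2 <- apply_scenario_exclusions(g, truth, cfg)
  expect_identical(ex2$genotypes$n_snps, 40L - 8L)

  # typed scenario is the identity
  cfg_t <- sim_config(n_samples = 50, n_snps = 40, n_causal = 1, h2 = 0.1,
                      seed = 5)
  ex3 <- apply_scenario_exclusions(g, truth, cfg_t)
  expect_identical(ex3$genotypes$genotypes, g$genotypes)
  expect_identical(ex3$truth$observed_snp_indices, 1:40)
})

test_that("simulated datasets survive a PLINK round trip", {
  cfg <- sim_config(n_samples = 60, n_snps = 30, n_causal = 5, h2 = 0.3,
                    maf_range = c(0.2, 0.5), seed = 141)
  sim <- simulate_dataset(cfg)
  prefix <- file.path(withr::local_tempdir(), "simrt")
  write_plink(sim$genotypes, prefix)
  g2 <- read_plink(prefix)
  expect_equal(g2$genotypes, sim$genotypes$genotypes, ignore_attr = TRUE)
  expect_identical(g2$snp_chrom, sim$genotypes$snp_chrom)
})

test_that("simulate_dataset is deterministic given its seed", {
  cfg <- sim_config(n_samples = 80, n_snps = 40, n_causal = 5, h2 = 0.3,
                    seed = 151)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$genotypes$genotypes, s2$genotypes$genotypes)
  expect_identical(s1$phenotypes$y, s2$phenotypes$y)
  expect_identical(s1$truth$effects, s2$truth$effects)
})
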