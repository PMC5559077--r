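# Synthetic GWAS data generator.
#
# Genotypes come from a haplotype pool with local LD: along each
# chromosome, haplotype alleles follow a first-order "copying" Markov
# chain — the allele at locus j+1 copies the allele at locus j with
# probability ld_decay and is otherwise drawn fresh at that locus's target
# frequency, giving adjacent-allele correlation ~= ld_decay and k-step
# correlation ~= ld_decay^k. Haplotypes are drawn from the pool with
# replacement and paired to form diploid genotypes; chromosomes are
# independent. p causal SNPs get effects u_j ~ N(0, sigma_g^2 / p) with
# sigma_g^2 = h^2 sigma_e^2 / (1 - h^2), acting on standardized genotypes.
#
# Outcomes: continuous Y = X u + e; binary via a liability threshold at the
# upper-K quantile of Y's theoretical distribution (0 for K = 0.5);
# log-normal AFT survival with normally distributed log-scale censoring
# (sd 2 gives ~50% censoring when var(Y) = 1.111).
#
# The "untyped causal" scenario removes the causal SNPs and a fixed number
# of flanking SNPs per side from the returned genotypes, leaving only LD
# proxies for the estimator to exploit.

#' Simulation configuration
#'
#' @param n_samples,n_snps,n_chromosomes,n_causal Design dimensions.
#' @param h2 True narrow-sense heritability.
#' @param sigma_e2 Environmental variance (default 1).
#' @param maf_range Range the per-locus target allele frequencies are drawn
#'   from (default `c(0.05, 0.5)`).
#' @param causal_maf_max Optional MAF ceiling theta for causal SNPs
#'   (scenario `"maf_restricted"`).
#' @param scenario `"typed"`, `"maf_restricted"` or `"untyped_causal"`.
#' @param flank_exclusion Flanking SNPs removed per side under
#'   `"untyped_causal"` (default 5).
#' @param outcome `"continuous"`, `"binary"` or `"survival"`.
#' @param binary_K Liability-threshold prevalence for binary outcomes
#'   (default 0.5, i.e. threshold 0).
#' @param censor_sd SD of the zero-mean normal log-scale censoring times
#'   (default 2, ~50\% censoring at `h2 = 0.1`).
#' @param haplotype_pool_size Haplotypes in the pool (even, default 200).
#' @param ld_decay Adjacent-allele copying probability in \[0, 1)
#'   (default 0.5).
#' @param exact_normalization Rescale effects so `sum(u^2)` equals
#'   `sigma_g^2` exactly (default `FALSE`: exact in expectation only).
#' @param seed RNG seed for the whole dataset draw.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples, n_snps, n_chromosomes = 1L,
                       n_causal = 100L, h2 = 0.1, sigma_e2 = 1,
                       maf_range = c(0.05, 0.5), causal_maf_max = NULL,
                       scenario = c("typed", "maf_restricted",
                                    "untyped_causal"),
                       flank_exclusion = 5L,
                       outcome = c("continuous", "binary", "survival"),
                       binary_K = 0.5, censor_sd = 2,
                       haplotype_pool_size = 200L, ld_decay = 0.5,
                       exact_normalization = FALSE, seed = 1L) {
  scenario <- match.arg(scenario)
  outcome <- match.arg(outcome)
  stopifnot(n_causal <= n_snps, h2 >= 0, h2 < 1, sigma_e2 > 0,
            ld_decay >= 0, ld_decay < 1,
            haplotype_pool_size %% 2 == 0,
            maf_range[1] > 0, maf_range[2] <= 0.5)
  if (scenario == "maf_restricted" && is.null(causal_maf_max)) {
    stop("scenario 'maf_restricted' requires causal_maf_max", call. = FALSE)
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_snps = as.integer(n_snps),
                 n_chromosomes = as.integer(n_chromosomes),
                 n_causal = as.integer(n_causal), h2 = h2,
                 sigma_e2 = sigma_e2, maf_range = maf_range,
                 causal_maf_max = causal_maf_max, scenario = scenario,
                 flank_exclusion = as.integer(flank_exclusion),
                 outcome = outcome, binary_K = binary_K,
                 censor_sd = censor_sd,
                 haplotype_pool_size = as.integer(haplotype_pool_size),
                 ld_decay = ld_decay,
                 exact_normalization = exact_normalization,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Split M loci over chromosomes as evenly as possible.
.chrom_sizes <- function(m, n_chrom) {
  base <- m %/% n_chrom
  sizes <- rep(base, n_chrom)
  extra <- m - base * n_chrom
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

#' Simulate genotypes from a Markov-LD haplotype pool
#'
#' @param cfg A [sim_config()]. Uses the RNG state of the caller; wrap in a
#'   seed yourself or use [simulate_dataset()] for a fully seeded draw.
#' @return A `genotype_dataset`; the haplotype pool (list of per-chromosome
#'   0/1 matrices) is attached as attribute `"haplotype_pool"`.
#' @export
simulate_genotypes <- function(cfg) {
  sizes <- .chrom_sizes(cfg$n_snps, cfg$n_chromosomes)
  n <- cfg$n_samples
  hp <- cfg$haplotype_pool_size
  s <- cfg$ld_decay
  g <- matrix(0, nrow = n, ncol = cfg$n_snps)
  chrom <- character(cfg$n_snps)
  pool_list <- vector("list", cfg$n_chromosomes)
  off <- 0L
  for (ci in seq_len(cfg$n_chromosomes)) {
    m <- sizes[ci]
    freqs <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
    pool <- matrix(0L, nrow = hp, ncol = m)
    pool[, 1L] <- stats::rbinom(hp, 1L, freqs[1L])
    if (m > 1L) {
      for (j in 2:m) {
        copy <- stats::rbinom(hp, 1L, s)
        fresh <- stats::rbinom(hp, 1L, freqs[j])
        pool[, j] <- copy * pool[, j - 1L] + (1L - copy) * fresh
      }
    }
    # keep every pooled locus polymorphic
    mono <- which(colSums(pool) %in% c(0L, hp))
    for (j in mono) {
      flip <- sample.int(hp, 1L)
      pool[flip, j] <- 1L - pool[flip, j]
    }
    i1 <- sample.int(hp, n, replace = TRUE)
    i2 <- sample.int(hp, n, replace = TRUE)
    cols <- off + seq_len(m)
    g[, cols] <- pool[i1, , drop = FALSE] + pool[i2, , drop = FALSE]
    chrom[cols] <- as.character(ci)
    pool_list[[ci]] <- pool
    off <- off + m
  }
  gd <- new_genotype_dataset(g, snp_chrom = chrom,
                             snp_id = sprintf("snp%06d",
                                              seq_len(cfg$n_snps)),
                             sample_id = sprintf("ind%06d", seq_len(n)))
  attr(gd, "haplotype_pool") <- pool_list
  gd
}

#' Draw causal SNP indices and effect sizes
#'
#' Picks `n_causal` indices uniformly among eligible SNPs (polymorphic in
#' the sample; MAF <= `causal_maf_max` under the MAF-restricted scenario)
#' and draws effects `u_j ~ N(0, sigma_g^2 / p)` with
#' `sigma_g^2 = h^2 sigma_e^2 / (1 - h^2)`.
#'
#' @param cfg A [sim_config()].
#' @param g The simulated `genotype_dataset`.
#' @return A `simulation_truth`: `causal_indices`, `effects`, `sigma_g2`,
#'   `h2_true`, `sigma_e2`; `observed_snp_indices` is filled by
#'   [apply_scenario_exclusions()].
#' @export
draw_causal_effects <- function(cfg, g) {
  eligible <- which(g$maf > 0)
  if (!is.null(cfg$causal_maf_max) && cfg$scenario == "maf_restricted") {
    eligible <- eligible[g$maf[eligible] <= cfg$causal_maf_max]
    if (length(eligible) < cfg$n_causal) {
      stop("fewer than p SNPs with MAF <= ", cfg$causal_maf_max,
           call. = FALSE)
    }
  }
  causal <- sort(sample(eligible, cfg$n_causal))
  sigma_g2 <- cfg$h2 * cfg$sigma_e2 / (1 - cfg$h2)
  u <- stats::rnorm(cfg$n_causal, 0, sqrt(sigma_g2 / cfg$n_causal))
  if (cfg$exact_normalization) {
    u <- u * sqrt(sigma_g2 / sum(u^2))
  }
  structure(list(causal_indices = causal, effects = u,
                 sigma_g2 = if (cfg$exact_normalization) sigma_g2
                            else sum(u^2),
                 sigma_g2_target = sigma_g2,
                 h2_true = cfg$h2, sigma_e2 = cfg$sigma_e2,
                 observed_snp_indices = seq_len(g$n_snps),
                 genetic_values = NULL),
            class = "simulation_truth")
}

#' Simulate a phenotype given genotypes and causal effects
#'
#' Continuous: `Y = X_causal u + e` with standardized causal columns and
#' `e ~ N(0, sigma_e2)` (intercept 0). Binary: liability threshold at the
#' upper-`binary_K` quantile of the theoretical `N(0, sigma_g2 + sigma_e2)`
#' distribution of `Y` (threshold 0 for K = 0.5). Survival: `Y` is the
#' log failure time; log censoring times are `N(0, censor_sd^2)`.
#'
#' @param g The `genotype_dataset` (pre-exclusion).
#' @param truth A `simulation_truth` from [draw_causal_effects()].
#' @param cfg A [sim_config()].
#' @return A `phenotype_set`; the per-sample genetic values are attached as
#'   attribute `"genetic_values"`.
#' @export
simulate_phenotype <- function(g, truth, cfg) {
  xc <- g$genotypes[, truth$causal_indices, drop = FALSE]
  xc <- scale(xc)             # standardized causal columns
  gv <- as.vector(xc %*% truth$effects)
  e <- stats::rnorm(cfg$n_samples, 0, sqrt(cfg$sigma_e2))
  yo <- gv + e
  ph <- switch(cfg$outcome,
    continuous = new_phenotype_set("continuous", yo,
                                   sample_id = g$sample_id),
    binary = {
      thr <- if (cfg$binary_K == 0.5) 0 else
        stats::qnorm(1 - cfg$binary_K, 0,
                     sqrt(truth$sigma_g2_target + cfg$sigma_e2))
      new_phenotype_set("binary", as.numeric(yo > thr),
                        sample_id = g$sample_id)
    },
    survival = {
      cens <- stats::rnorm(cfg$n_samples, 0, cfg$censor_sd)
      new_phenotype_set("survival", pmin(yo, cens),
                        event = as.numeric(yo <= cens),
                        sample_id = g$sample_id)
    })
  attr(ph, "genetic_values") <- gv
  ph
}

#' Remove causal SNPs and their flanks (untyped-causal scenario)
#'
#' Under scenario `"untyped_causal"`, drops every causal SNP together with
#' `flank_exclusion` neighbours on each side (within the same chromosome,
#' clipped at chromosome ends); otherwise returns the dataset unchanged.
#'
#' @param g The `genotype_dataset`.
#' @param truth A `simulation_truth`; `observed_snp_indices` is updated to
#'   the kept original column indices.
#' @param cfg A [sim_config()].
#' @return List with the reduced `genotypes` and updated `truth`.
#' @export
apply_scenario_exclusions <- function(g, truth, cfg) {
  if (cfg$scenario != "untyped_causal") {
    truth$observed_snp_indices <- seq_len(g$n_snps)
    return(list(genotypes = g, truth = truth))
  }
  fl <- cfg$flank_exclusion
  drop <- integer(0)
  for (cidx in truth$causal_indices) {
    same <- which(g$snp_chrom == g$snp_chrom[cidx])
    window <- seq.int(max(min(same), cidx - fl),
                      min(max(same), cidx + fl))
    drop <- c(drop, window)
  }
  keep <- setdiff(seq_len(g$n_snps), drop)
  g2 <- new_genotype_dataset(g$genotypes[, keep, drop = FALSE],
                             snp_chrom = g$snp_chrom[keep],
                             snp_id = g$snp_id[keep],
                             sample_id = g$sample_id,
                             maf = g$maf[keep])
  truth$observed_snp_indices <- keep
  list(genotypes = g2, truth = truth)
}

#' Simulate a complete dataset
#'
#' Seeded end-to-end draw: genotypes, causal effects, phenotype, scenario
#' exclusions.
#'
#' @param cfg A [sim_config()].
#' @return List with `genotypes` (post-exclusion), `phenotypes`, and
#'   `truth` (including `genetic_values` and the observed-SNP mapping).
#' @export
simulate_dataset <- function(cfg) {
  with_seed(cfg$seed, {
    g <- simulate_genotypes(cfg)
    truth <- draw_causal_effects(cfg, g)
    ph <- simulate_phenotype(g, truth, cfg)
    truth$genetic_values <- attr(ph, "genetic_values")
    ex <- apply_scenario_exclusions(g, truth, cfg)
    list(genotypes = ex$genotypes, phenotypes = ph, truth = ex$truth)
  })
}
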