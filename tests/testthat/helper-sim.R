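# Shared fixtures and desk-scale replicate runners.

`%||%` <- function(a, b) if (is.null(a)) b else a

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Small deterministic genotype matrix with guaranteed polymorphism.
make_geno_matrix <- function(n, m, seed = 1) {
  with_seed(seed, {
    g <- matrix(rbinom(n * m, 2, runif(m, 0.2, 0.5)[rep(seq_len(m),
                                                        each = n)]),
                n, m)
    for (j in seq_len(m)) {
      if (length(unique(g[, j])) == 1L) {
        g[1:2, j] <- c(0, 2)
      }
    }
    g
  })
}

make_geno_dataset <- function(n, m, seed = 1, chrom = NULL) {
  g <- make_geno_matrix(n, m, seed)
  new_genotype_dataset(g,
                       snp_chrom = chrom %||% rep("1", m),
                       snp_id = sprintf("rs%04d", seq_len(m)),
                       sample_id = sprintf("s%04d", seq_len(n)))
}

# One desk-scale estimation replicate on simulated data; returns the
# pieces the recovery checks look at.
run_sim_replicate <- function(seed, n, m, p, h2, outcome = "continuous",
                              n_chrom = 1L, ld = 0.5,
                              scenario = "typed", exact = FALSE,
                              K = NULL, screen_cfg = NULL) {
  cfg <- sim_config(n_samples = n, n_snps = m, n_chromosomes = n_chrom,
                    n_causal = p, h2 = h2, outcome = outcome,
                    ld_decay = ld, scenario = scenario,
                    exact_normalization = exact, seed = seed)
  sim <- simulate_dataset(cfg)
  res <- estimate_heritability(sim$genotypes, sim$phenotypes,
                               screen_cfg = screen_cfg,
                               rcv_cfg = rcv_config(split_seed = seed),
                               K = K)
  list(res = res, sim = sim)
}
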