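# Weighted-bootstrap standard error for the heritability estimate.
#
# Each replicate perturbs every observation's contribution with i.i.d.
# positive mean-1, variance-1 weights (standard exponential) and re-runs
# Steps 2-4 only: the screening step is held fixed across replicates, which
# is justified by the oracle property of the selection stage and is the
# main cost saver. The lasso penalty is first calibrated as the average
# one-SE penalty over a batch of weighted datasets, then frozen.

#' Bootstrap configuration
#'
#' @param n_calibration Weighted datasets used to calibrate the fixed lasso
#'   penalty (default 100).
#' @param n_replicates Weighted datasets used for the standard error
#'   (default 100).
#' @param seed Seed for the weight draws.
#' @param weight_scale Scale of the weight perturbation: replicate weights
#'   are `1 + weight_scale * (Exp(1) - 1)`. The default 1 gives standard
#'   exponential weights; 0 degenerates to unit weights (useful in tests).
#' @return A `bootstrap_config` list.
#' @export
bootstrap_config <- function(n_calibration = 100L, n_replicates = 100L,
                             seed = 1L, weight_scale = 1) {
  stopifnot(n_replicates >= 2L, n_calibration >= 1L,
            weight_scale >= 0, weight_scale <= 1)
  structure(list(n_calibration = as.integer(n_calibration),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), weight_scale = weight_scale),
            class = "bootstrap_config")
}

#' Draw bootstrap weights
#'
#' I.i.d. standard-exponential weights (positive, mean 1, variance 1),
#' deterministic given the seed.
#'
#' @param n Number of weights.
#' @param seed Integer seed.
#' @param scale Perturbation scale (see [bootstrap_config()]).
#' @return Positive numeric vector of length `n`.
#' @export
draw_bootstrap_weights <- function(n, seed, scale = 1) {
  1 + scale * (with_seed(seed, stats::rexp(n)) - 1)
}

#' Calibrate the bootstrap lasso penalty
#'
#' For each of `n_calibration` weighted datasets, runs the weighted
#' cross-validated lasso on both half-samples with the one-SE rule and
#' returns the average chosen penalty. The average is expected to exceed
#' the unweighted one-SE penalty because of the noise added by the weights.
#'
#' @param x Numeric matrix restricted to the screened SNPs.
#' @param y Outcome vector.
#' @param rcv_cfg An [rcv_config()] (fixes the split).
#' @param boot_cfg A [bootstrap_config()].
#' @param base_weights Optional baseline weights (IPCW) multiplied into the
#'   bootstrap weights.
#' @param covariates Optional covariate matrix, exempt from selection.
#' @return The average one-SE penalty `lambda_bar`.
#' @export
calibrate_penalty <- function(x, y, rcv_cfg, boot_cfg,
                              base_weights = NULL, covariates = NULL) {
  x <- .as_geno_matrix(x)
  n <- nrow(x)
  sp <- split_sample(n, rcv_cfg$split_seed)
  cfg <- rcv_cfg
  cfg$penalty_rule <- "one_se"
  cfg$fixed_penalty <- NULL
  pf <- if (is.null(covariates)) NULL else
    c(rep(1, ncol(x)), rep(0, ncol(covariates)))
  xfull <- if (is.null(covariates)) x else cbind(x, covariates)
  lams <- numeric(0)
  for (b in seq_len(boot_cfg$n_calibration)) {
    xi <- draw_bootstrap_weights(n, child_seed(boot_cfg$seed, b),
                                 boot_cfg$weight_scale)
    w <- if (is.null(base_weights)) xi else xi * base_weights
    for (half in list(sp$A, sp$B)) {
      sup <- lasso_select(xfull[half, , drop = FALSE], y[half], cfg,
                          weights = w[half], penalty_factor = pf,
                          foldid_seed = child_seed(rcv_cfg$split_seed, 11L))
      lams <- c(lams, attr(sup, "lambda"))
    }
  }
  mean(lams)
}

#' Weighted-bootstrap standard error of the heritability estimate
#'
#' Re-runs Steps 2-4 (lasso selection at the fixed calibrated penalty, OLS
#' refit, averaging) and the total-variance estimate on `n_replicates`
#' weighted datasets, and reports the standard deviation of the replicate
#' heritability estimates. Screening and (for censored outcomes) the IPCW
#' weights are held fixed.
#'
#' @param x Numeric matrix restricted to the screened SNPs.
#' @param y Outcome vector (0/1 for binary, observed log-times for
#'   survival).
#' @param outcome_type `"continuous"`, `"binary"` or `"survival"`.
#' @param rcv_cfg An [rcv_config()].
#' @param boot_cfg A [bootstrap_config()].
#' @param lambda_bar Fixed lasso penalty from [calibrate_penalty()].
#' @param base_weights Baseline (IPCW) weights for survival outcomes.
#' @param covariates Optional covariate matrix.
#' @param K,P Optional prevalence inputs; when supplied for a binary
#'   outcome the SE of the liability-scale estimate is also returned.
#' @return List with `se` (observed scale), `se_liability` (if requested),
#'   and the vector of `replicates`.
#' @export
weighted_bootstrap_se <- function(x, y, outcome_type, rcv_cfg, boot_cfg,
                                  lambda_bar, base_weights = NULL,
                                  covariates = NULL, K = NULL, P = NULL) {
  x <- .as_geno_matrix(x)
  n <- nrow(x)
  cfg <- rcv_cfg
  cfg$fixed_penalty <- lambda_bar
  h2s <- numeric(boot_cfg$n_replicates)
  for (r in seq_len(boot_cfg$n_replicates)) {
    xi <- draw_bootstrap_weights(n, child_seed(boot_cfg$seed, 100000L + r),
                                 boot_cfg$weight_scale)
    w <- if (is.null(base_weights)) xi else xi * base_weights
    sig <- rcv_sigma_e(x, y, cfg, weights = w, covariates = covariates)
    v1 <- sum(w)
    v2 <- sum(w^2)
    sigma_total <- if (outcome_type == "binary") {
      dbar <- sum(w * y) / v1
      dbar * (1 - dbar)
    } else {
      mw <- sum(w * y) / v1
      v1 * sum(w * (y - mw)^2) / (v1^2 - v2)
    }
    h2s[r] <- 1 - sig$sigma_e / sigma_total
  }
  out <- list(se = stats::sd(h2s), replicates = h2s,
              lambda_bar = lambda_bar)
  if (outcome_type == "binary" && !is.null(K)) {
    hl <- vapply(h2s, liability_transform, numeric(1), K = K, P = P)
    out$se_liability <- stats::sd(hl)
    out$replicates_liability <- hl
  }
  out
}
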