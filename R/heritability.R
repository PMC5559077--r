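# Assembling the heritability estimate: h^2 = 1 - sigma_e^2 / sigma_Y^2,
# with the total variance measured on the scale appropriate to the outcome
# (empirical variance, Dbar(1 - Dbar), or the IPCW-weighted variance), the
# Robertson liability transform for binary traits, and optional covariate
# adjustment.

#' Unbiased empirical variance of a continuous outcome
#'
#' @param y Numeric vector, length >= 2.
#' @return `sum((y - mean(y))^2) / (N - 1)`.
#' @export
empirical_outcome_variance <- function(y) {
  if (length(y) < 2) stop("need at least two observations", call. = FALSE)
  stats::var(y)
}

#' Total variance of a binary outcome
#'
#' @param d 0/1 vector.
#' @return `Dbar * (1 - Dbar)` with `Dbar` the case fraction.
#' @export
binary_outcome_variance <- function(d) {
  if (!all(d %in% c(0, 1))) stop("binary outcome must be 0/1", call. = FALSE)
  dbar <- mean(d)
  if (dbar == 0 || dbar == 1) {
    stop("degenerate binary outcome (all ", dbar, "s)", call. = FALSE)
  }
  dbar * (1 - dbar)
}

#' Observed-scale heritability
#'
#' @param sigma_e Environmental (residual) variance estimate.
#' @param sigma_total Total outcome variance estimate (> 0).
#' @return `1 - sigma_e / sigma_total`, unclipped; a warning is raised when
#'   the value falls outside `[0, 1]`.
#' @export
heritability_observed <- function(sigma_e, sigma_total) {
  if (!(sigma_total > 0)) stop("sigma_total must be > 0", call. = FALSE)
  h2 <- 1 - sigma_e / sigma_total
  if (h2 < 0 || h2 > 1) {
    warning("heritability estimate ", signif(h2, 4), " outside [0, 1]")
  }
  h2
}

#' Liability-scale heritability (Robertson transform)
#'
#' Converts an observed-scale 0/1 heritability to the liability scale. For
#' cohort data (no ascertainment) the transform is
#' `h_o^2 K(1-K)/z^2`; for case-control data oversampled to a case fraction
#' `P` the ascertainment-corrected transform
#' `h_o^2 K^2 (1-K)^2 / {P(1-P) z^2}` is used, where
#' `z = dnorm(qnorm(1-K))` is the standard-normal density at the threshold
#' truncating the upper proportion `K`.
#'
#' @param h2_observed Observed-scale heritability.
#' @param K Population prevalence, in (0, 1).
#' @param P Optional sample case fraction, in (0, 1); triggers the
#'   ascertainment correction. At `P = K` both branches coincide.
#' @return Liability-scale heritability.
#' @export
liability_transform <- function(h2_observed, K, P = NULL) {
  if (!(K > 0 && K < 1)) stop("K must be in (0, 1)", call. = FALSE)
  z <- stats::dnorm(stats::qnorm(1 - K))
  if (is.null(P)) {
    h2_observed * K * (1 - K) / z^2
  } else {
    if (!(P > 0 && P < 1)) stop("P must be in (0, 1)", call. = FALSE)
    h2_observed * K^2 * (1 - K)^2 / (P * (1 - P) * z^2)
  }
}

#' Covariate-adjusted heritability
#'
#' Removes the variance explained by fixed covariates from the genetic
#' share: `1 - (sigma_e + beta' var(W) beta) / sigma_total`.
#'
#' @param sigma_e Environmental variance estimate.
#' @param beta Refit covariate coefficients.
#' @param cov_w Empirical covariance matrix of the covariates.
#' @param sigma_total Total outcome variance.
#' @return Adjusted heritability (unclipped).
#' @export
covariate_adjusted_heritability <- function(sigma_e, beta, cov_w,
                                            sigma_total) {
  beta <- as.numeric(beta)
  cov_w <- as.matrix(cov_w)
  if (length(beta) != nrow(cov_w) || nrow(cov_w) != ncol(cov_w)) {
    stop("dimension mismatch between beta and cov_w", call. = FALSE)
  }
  heritability_observed(sigma_e + as.numeric(t(beta) %*% cov_w %*% beta),
                        sigma_total)
}

#' Estimate narrow-sense heritability (full pipeline)
#'
#' Runs the complete estimator: genotype standardization, SNP screening
#' (Step 1), refitted cross-validation environmental-variance estimation
#' (Steps 2-4), outcome-appropriate total-variance estimation, and scale
#' conversion. Dispatch on the phenotype's `outcome_type`:
#' \describe{
#'   \item{continuous}{`sigma_total` = empirical variance of `y`.}
#'   \item{binary}{`sigma_total = Dbar(1-Dbar)`; when `K` is supplied the
#'     liability-scale estimate with ascertainment correction (at the
#'     sample case fraction `P`, overridable) is added.}
#'   \item{survival}{IPCW weights from the Kaplan-Meier censoring survival
#'     feed weighted screening, weighted RCV, and the weighted outcome
#'     variance; the lasso penalty rule defaults to one-SE.}
#' }
#'
#' @param g A `genotype_dataset` (or `std_genotypes`).
#' @param ph A `phenotype_set` aligned to `g`.
#' @param screen_cfg A [screening_config()]; default: SIS keeping 30\% for
#'   `M <= 10000`, else per-chromosome ITRRS (6 iterations keeping 50\%).
#' @param rcv_cfg An [rcv_config()].
#' @param K Optional population prevalence for the liability scale
#'   (binary outcomes).
#' @param P Optional sample case fraction; defaults to `mean(D)`.
#' @param bootstrap Optional [bootstrap_config()]; adds a weighted-bootstrap
#'   standard error (screening held fixed across replicates).
#' @param clip Clip the reported estimate into `[0, 1]` (off by default).
#' @return A `herra_result` with `h2_observed`, `h2_liability` (binary),
#'   `sigma_e`, `sigma_total`, `K`, `P`, `z`, `se`, the screening and RCV
#'   intermediates, and a `warning_flag` when the estimate leaves `[0, 1]`.
#' @export
estimate_heritability <- function(g, ph, screen_cfg = NULL,
                                  rcv_cfg = rcv_config(), K = NULL,
                                  P = NULL, bootstrap = NULL, clip = FALSE) {
  stopifnot(inherits(ph, "phenotype_set"))
  if (inherits(g, "genotype_dataset") && !is.null(ph$sample_id) &&
      !identical(g$sample_id, ph$sample_id)) {
    stop("genotype and phenotype sample orders differ", call. = FALSE)
  }
  xs <- standardize(g)
  m <- ncol(xs$matrix)
  if (is.null(screen_cfg)) {
    screen_cfg <- if (m <= 10000) screening_config("sis")
                  else screening_config("itrrs")
  }
  y <- ph$y
  weights <- NULL
  ipw <- NULL
  if (ph$outcome_type == "survival") {
    ipw <- ipcw_weights(y, ph$event)
    weights <- ipw$weights
  }
  # CV-min default for every outcome: the cross-fitted refit keeps sigma_e
  # unbiased under liberal selection, whereas under-selection (one-SE)
  # leaves genetic variance in the residual.
  if (is.null(rcv_cfg$penalty_rule)) rcv_cfg$penalty_rule <- "min"

  sel <- if (screen_cfg$method == "sis") {
    sis_screen(xs, y, screen_cfg$keep_fraction, weights)
  } else {
    itrrs_screen(xs, y, xs$snp_chrom, screen_cfg, weights)
  }
  x_sel <- xs$matrix[, sel$snp_indices, drop = FALSE]
  sig <- rcv_sigma_e(x_sel, y, rcv_cfg, weights = weights,
                     covariates = ph$covariates)

  sigma_total <- switch(ph$outcome_type,
    continuous = empirical_outcome_variance(y),
    binary = binary_outcome_variance(y),
    survival = weighted_outcome_variance(ipw, y))

  if (is.null(ph$covariates)) {
    h2 <- 1 - sig$sigma_e / sigma_total
  } else {
    cov_w <- stats::cov(ph$covariates)
    q1 <- as.numeric(t(sig$beta_cov1) %*% cov_w %*% sig$beta_cov1)
    q2 <- as.numeric(t(sig$beta_cov2) %*% cov_w %*% sig$beta_cov2)
    h2 <- 1 - (sig$sigma_e + (q1 + q2) / 2) / sigma_total
  }
  warning_flag <- h2 < 0 || h2 > 1
  h2_report <- if (clip) min(max(h2, 0), 1) else h2

  h2_liability <- NULL
  z <- NULL
  if (ph$outcome_type == "binary" && !is.null(K)) {
    if (is.null(P)) P <- mean(y)
    z <- stats::dnorm(stats::qnorm(1 - K))
    h2_liability <- liability_transform(h2_report, K, P)
  }

  res <- structure(
    list(h2_observed = h2_report, h2_liability = h2_liability,
         sigma_e = sig$sigma_e, sigma_total = sigma_total,
         K = K, P = P, z = z, se = NULL,
         outcome_type = ph$outcome_type,
         warning_flag = warning_flag,
         screening = sel, sigma_estimate = sig, ipcw = ipw,
         screen_cfg = screen_cfg, rcv_cfg = rcv_cfg),
    class = "herra_result")

  if (!is.null(bootstrap)) {
    lam_bar <- calibrate_penalty(x_sel, y, rcv_cfg, bootstrap,
                                 base_weights = weights,
                                 covariates = ph$covariates)
    bt <- weighted_bootstrap_se(x_sel, y, ph$outcome_type, rcv_cfg,
                                bootstrap, lam_bar, base_weights = weights,
                                covariates = ph$covariates, K = K, P = P)
    res$se <- bt$se
    res$bootstrap <- bt
    res$lambda_bar <- lam_bar
  }
  res
}

#' @exportS3Method base::print
print.herra_result <- function(x, ...) {
  cat("HERRA heritability estimate (", x$outcome_type, " outcome)\n",
      sep = "")
  cat(sprintf("  h2 (observed scale): %.4f%s\n", x$h2_observed,
              if (isTRUE(x$warning_flag)) "  [outside [0,1]]" else ""))
  if (!is.null(x$h2_liability)) {
    cat(sprintf("  h2 (liability scale): %.4f  (K = %g, P = %g)\n",
                x$h2_liability, x$K, x$P))
  }
  cat(sprintf("  sigma_e = %.4f, sigma_total = %.4f\n",
              x$sigma_e, x$sigma_total))
  if (!is.null(x$se)) cat(sprintf("  bootstrap SE = %.4g\n", x$se))
  cat(sprintf("  screening: %s, %d SNPs retained; supports: %d / %d\n",
              x$screening$method, length(x$screening$snp_indices),
              length(x$sigma_estimate$support1),
              length(x$sigma_estimate$support2)))
  invisible(x)
}
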