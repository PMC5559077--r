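# Steps 2-4: refitted cross-validation estimate of the environmental
# variance. The sample is split in half; a cross-validated lasso selects a
# parsimonious SNP set on one half, an ordinary (or weighted) least-squares
# refit on the other half gives a nearly unbiased residual-variance
# estimate; roles are switched and the two estimates averaged.

#' Refitted cross-validation configuration
#'
#' @param cv_folds Folds for the lasso cross-validation (default 10).
#' @param penalty_rule `"min"` (minimum mean cross-validated error) or
#'   `"one_se"` (most regularized model within one standard error of the
#'   minimum). `NULL` lets the caller pick an outcome-appropriate default
#'   (min for continuous/binary, one-SE for censored outcomes and bootstrap
#'   replicates).
#' @param split_seed Seed controlling the half-sample split and the CV fold
#'   assignment; the whole estimate is deterministic given it.
#' @param fixed_penalty Optional fixed lasso penalty overriding CV.
#' @param max_support Cap on the number of SNPs kept per half-sample
#'   selection; defaults to `n_half - 3` at fit time.
#' @param nlambda,lambda_min_ratio Lasso path resolution passed to
#'   [glmnet::cv.glmnet()].
#' @return An `rcv_config` list.
#' @export
rcv_config <- function(cv_folds = 10L, penalty_rule = NULL,
                       split_seed = 1L, fixed_penalty = NULL,
                       max_support = NULL, nlambda = 40L,
                       lambda_min_ratio = 0.02) {
  if (!is.null(penalty_rule)) {
    penalty_rule <- match.arg(penalty_rule, c("min", "one_se"))
  }
  stopifnot(cv_folds >= 2L)
  structure(list(cv_folds = as.integer(cv_folds),
                 penalty_rule = penalty_rule,
                 split_seed = as.integer(split_seed),
                 fixed_penalty = fixed_penalty,
                 max_support = max_support,
                 nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio),
            class = "rcv_config")
}

#' Split a sample into two halves
#'
#' Random equal split (the first half takes the extra observation for odd
#' `n`), deterministic given `seed`; the caller's RNG state is untouched.
#'
#' @param n Sample size (`>= 8` for a meaningful refit).
#' @param seed Integer seed.
#' @return List with sorted index vectors `A` and `B`.
#' @export
split_sample <- function(n, seed) {
  stopifnot(n >= 8)
  perm <- with_seed(seed, sample.int(n))
  na <- ceiling(n / 2)
  list(A = sort(perm[seq_len(na)]), B = sort(perm[-seq_len(na)]))
}

# Deterministic CV fold assignment.
.cv_foldid <- function(n, nfolds, seed) {
  with_seed(seed, sample(rep_len(seq_len(nfolds), n)))
}

#' Lasso variable selection on a half-sample
#'
#' Runs a cross-validated (or fixed-penalty) lasso and returns the indices
#' of the columns with nonzero coefficients. When more than
#' `config$max_support` columns survive, the largest-|coefficient| ones are
#' kept. Zero-weight observations are dropped before fitting.
#'
#' @param x Numeric matrix restricted to the screened SNPs and the
#'   half-sample rows.
#' @param y Outcome vector for the same rows.
#' @param config An [rcv_config()].
#' @param weights Optional nonnegative observation weights.
#' @param penalty_factor Optional per-column penalty factors (0 exempts a
#'   column, e.g. fixed covariates).
#' @param foldid_seed Seed for the deterministic fold assignment.
#' @return Sorted integer support with attributes `lambda` (penalty used)
#'   and `coef` (coefficients on the support).
#' @export
lasso_select <- function(x, y, config = rcv_config(), weights = NULL,
                         penalty_factor = NULL, foldid_seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  w <- weights %||% rep(1, n)
  keep <- w > 0
  xk <- x[keep, , drop = FALSE]
  yk <- y[keep]
  wk <- w[keep]
  if (stats::var(yk) == 0) stop("outcome has zero variance", call. = FALSE)
  pf <- penalty_factor %||% rep(1, ncol(x))
  rule <- config$penalty_rule %||% "min"
  if (!is.null(config$fixed_penalty)) {
    lam <- config$fixed_penalty
    lam_seq <- if (lam > 0) lam * c(16, 8, 4, 2, 1) else c(0.1, 0.01, 0.001, 0)
    fit <- glmnet::glmnet(xk, yk, weights = wk, lambda = lam_seq,
                          penalty.factor = pf, standardize = TRUE)
    cf <- as.vector(stats::coef(fit, s = lam, exact = FALSE))[-1L]
  } else {
    foldid <- .cv_foldid(length(yk), config$cv_folds,
                         foldid_seed %||% child_seed(config$split_seed, 11L))
    cvfit <- glmnet::cv.glmnet(xk, yk, weights = wk, foldid = foldid,
                               nlambda = config$nlambda,
                               lambda.min.ratio = config$lambda_min_ratio,
                               penalty.factor = pf, standardize = TRUE)
    lam <- if (rule == "one_se") cvfit$lambda.1se else cvfit$lambda.min
    cf <- as.vector(stats::coef(cvfit, s = lam))[-1L]
  }
  support <- which(cf != 0)
  cap <- config$max_support %||% (n - 3L)
  if (length(support) > cap) {
    ord <- order(-abs(cf[support]), support)
    support <- support[ord[seq_len(cap)]]
  }
  support <- sort(support)
  attr(support, "lambda") <- lam
  attr(support, "coef") <- cf[support]
  support
}

# Weighted residual variance with an effective-df correction:
# denominator V1 - (k + 1) * V2 / V1, which is n - k - 1 for unit weights
# and matches the weighted outcome-variance denominator when k = 0.
.weighted_resid_var <- function(resid, w, k) {
  v1 <- sum(w)
  v2 <- sum(w^2)
  denom <- v1 - (k + 1) * v2 / v1
  if (denom <= 0) {
    stop("refit is rank-deficient; lower max_support", call. = FALSE)
  }
  sum(w * resid^2) / denom
}

#' Least-squares refit on the complementary half-sample
#'
#' Ordinary (or weighted) least squares of the outcome on an intercept plus
#' the selected columns, returning the residual-variance estimate with
#' degrees-of-freedom correction `n - |support| - 1` (its weighted
#' analogue under observation weights). An empty support degenerates to the
#' (weighted) sample variance of the outcome.
#'
#' @param x Numeric matrix on the refit half-sample (all screened columns;
#'   only `support` columns enter the fit).
#' @param y Outcome vector.
#' @param support Integer column indices selected on the other half.
#' @param weights Optional nonnegative observation weights.
#' @param covariates Optional fixed covariate matrix, always included.
#' @return List with `sigma2`, `coefficients` (intercept first), and
#'   `beta_cov` (covariate coefficients, if any).
#' @export
refit_residual_variance <- function(x, y, support, weights = NULL,
                                    covariates = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  w <- weights %||% rep(1, n)
  k_snp <- length(support)
  k_cov <- if (is.null(covariates)) 0L else ncol(covariates)
  k <- k_snp + k_cov
  v1 <- sum(w)
  if (k >= sum(w > 0) - 1L) {
    stop("support size ", k, " too large for refit half (", sum(w > 0),
         " effective observations); lower max_support", call. = FALSE)
  }
  if (k == 0L) {
    mw <- sum(w * y) / v1
    v2 <- sum(w^2)
    sigma2 <- v1 * sum(w * (y - mw)^2) / (v1^2 - v2)
    return(list(sigma2 = sigma2, coefficients = c(intercept = mw),
                beta_cov = NULL))
  }
  design <- cbind(`(Intercept)` = 1,
                  if (k_snp) x[, support, drop = FALSE],
                  covariates)
  fit <- stats::lm.wfit(design, y, w)
  resid <- fit$residuals
  sigma2 <- .weighted_resid_var(resid, w, fit$rank - 1L)
  cf <- fit$coefficients
  beta_cov <- if (k_cov) {
    bc <- cf[seq.int(1L + k_snp + 1L, length.out = k_cov)]
    bc[is.na(bc)] <- 0
    bc
  }
  cf[is.na(cf)] <- 0
  list(sigma2 = sigma2, coefficients = cf, beta_cov = beta_cov)
}

#' Refitted cross-validation estimate of the environmental variance
#'
#' Executes split -> (select on A, refit on B) -> (select on B, refit on A)
#' -> average. Deterministic given `config$split_seed` (and
#' `fixed_penalty`, when set).
#'
#' @param x Numeric matrix already restricted to the screened SNPs
#'   (a `std_genotypes` is also accepted).
#' @param y Outcome vector.
#' @param config An [rcv_config()].
#' @param weights Optional nonnegative observation weights.
#' @param covariates Optional covariate matrix, exempt from selection and
#'   always refit.
#' @return A `sigma_estimate`: `sigma_e` (the average), the two split
#'   estimates, supports, chosen penalties, refit coefficients, and the
#'   per-split covariate coefficients.
#' @export
rcv_sigma_e <- function(x, y, config = rcv_config(), weights = NULL,
                        covariates = NULL) {
  xm <- .as_geno_matrix(x)
  n <- nrow(xm)
  stopifnot(length(y) == n)
  sp <- split_sample(n, config$split_seed)
  pf <- if (is.null(covariates)) NULL else
    c(rep(1, ncol(xm)), rep(0, ncol(covariates)))
  xfull <- if (is.null(covariates)) xm else cbind(xm, covariates)

  run_one <- function(sel_idx, fit_idx, seed_off) {
    cfg <- config
    cfg$max_support <- min(config$max_support %||% Inf,
                           length(fit_idx) - 3L)
    sup <- lasso_select(xfull[sel_idx, , drop = FALSE], y[sel_idx],
                        cfg, weights = weights[sel_idx],
                        penalty_factor = pf,
                        foldid_seed = child_seed(config$split_seed, seed_off))
    sup_snp <- sup[sup <= ncol(xm)]
    cov_fit <- if (is.null(covariates)) NULL else
      covariates[fit_idx, , drop = FALSE]
    refit <- refit_residual_variance(xm[fit_idx, , drop = FALSE], y[fit_idx],
                                     sup_snp, weights = weights[fit_idx],
                                     covariates = cov_fit)
    list(support = as.integer(sup_snp), lambda = attr(sup, "lambda"),
         refit = refit)
  }
  r1 <- run_one(sp$A, sp$B, 101L)
  r2 <- run_one(sp$B, sp$A, 202L)
  structure(list(sigma_e_split1 = r1$refit$sigma2,
                 sigma_e_split2 = r2$refit$sigma2,
                 sigma_e = (r1$refit$sigma2 + r2$refit$sigma2) / 2,
                 support1 = r1$support, support2 = r2$support,
                 lambda1 = r1$lambda, lambda2 = r2$lambda,
                 coefficients1 = r1$refit$coefficients,
                 coefficients2 = r2$refit$coefficients,
                 beta_cov1 = r1$refit$beta_cov,
                 beta_cov2 = r2$refit$beta_cov,
                 split = sp),
            class = "sigma_estimate")
}

#' @exportS3Method base::print
print.sigma_estimate <- function(x, ...) {
  cat("Refitted cross-validation variance estimate\n")
  cat(sprintf("  sigma_e = %.6g  (splits: %.6g, %.6g)\n",
              x$sigma_e, x$sigma_e_split1, x$sigma_e_split2))
  cat(sprintf("  support sizes: %d, %d\n",
              length(x$support1), length(x$support2)))
  invisible(x)
}
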