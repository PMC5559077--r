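# Step 1 of the estimator: dimension reduction below the sample size.
#
# Two screeners are provided. SIS ranks SNPs by the magnitude of their
# (optionally weighted) marginal correlation with the outcome and keeps the
# top fraction. ITRRS iterates ridge fits within each chromosome, keeping
# the SNPs with the largest absolute ridge coefficients at every iteration.
# Ties are always broken towards the lower SNP index so screening is
# reproducible without a seed.

#' Screening configuration
#'
#' @param method `"sis"` (marginal correlation ranking) or `"itrrs"`
#'   (iteratively thresholded ridge regression).
#' @param keep_fraction Fraction of SNPs kept per iteration, in (0, 1].
#'   Defaults to 0.3 for SIS (one pass) and 0.5 per ITRRS iteration.
#' @param n_iterations Number of ITRRS iterations (ignored for SIS).
#' @param shrinkage Ridge penalty `lambda >= 0`; applied as `lambda * N` on
#'   the standardized genotype scale (ITRRS only, must be > 0).
#' @param per_chromosome Run ITRRS separately within each chromosome and
#'   combine the survivors (the recommended large-M mode).
#' @return A `screening_config` list.
#' @export
screening_config <- function(method = c("sis", "itrrs"),
                             keep_fraction = NULL,
                             n_iterations = 6L,
                             shrinkage = 0.01,
                             per_chromosome = TRUE) {
  method <- match.arg(method)
  keep_fraction <- keep_fraction %||% if (method == "sis") 0.3 else 0.5
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  if (method == "itrrs") {
    stopifnot(n_iterations >= 1L, shrinkage > 0)
  }
  structure(list(method = method, keep_fraction = keep_fraction,
                 n_iterations = as.integer(n_iterations),
                 shrinkage = shrinkage, per_chromosome = per_chromosome),
            class = "screening_config")
}

new_selected_set <- function(snp_indices, per_iteration_sizes, method) {
  snp_indices <- sort(unique(as.integer(snp_indices)))
  structure(list(snp_indices = snp_indices,
                 per_iteration_sizes = as.integer(per_iteration_sizes),
                 method = method),
            class = "selected_set")
}

#' @exportS3Method base::print
print.selected_set <- function(x, ...) {
  cat("Selected SNP set (", x$method, "): ", length(x$snp_indices),
      " SNPs\n", sep = "")
  if (length(x$per_iteration_sizes) > 1L) {
    cat("  retained per iteration: ",
        paste(x$per_iteration_sizes, collapse = " -> "), "\n", sep = "")
  }
  invisible(x)
}

.as_geno_matrix <- function(x) {
  if (inherits(x, "std_genotypes")) x$matrix
  else if (inherits(x, "genotype_dataset")) x$genotypes
  else as.matrix(x)
}

# |weighted marginal correlation| of every column of x with y.
.marginal_abs_cor <- function(x, y, weights = NULL) {
  n <- nrow(x)
  w <- weights %||% rep(1, n)
  sw <- sum(w)
  my <- sum(w * y) / sw
  yc <- y - my
  vy <- sum(w * yc^2)
  if (vy <= 0) stop("outcome has zero (weighted) variance", call. = FALSE)
  mx <- as.vector(crossprod(x, w)) / sw
  num <- as.vector(crossprod(x, w * yc))          # = sum w (x - mx)(y - my)
  vx <- as.vector(crossprod(x * x, w)) - sw * mx^2
  r <- num / sqrt(pmax(vx, .Machine$double.eps) * vy)
  r[vx <= 0] <- 0
  abs(r)
}

#' Sure independence screening (marginal correlation ranking)
#'
#' Keeps the `ceiling(keep_fraction * M)` SNPs with the largest absolute
#' (weighted) sample correlation with the outcome.
#'
#' @param x Standardized genotypes (`std_genotypes`) or a numeric matrix.
#' @param y Outcome vector of length `nrow(x)`.
#' @param keep_fraction Fraction of SNPs to keep, in (0, 1].
#' @param weights Optional nonnegative observation weights (IPCW weights for
#'   censored outcomes).
#' @return A `selected_set`.
#' @export
sis_screen <- function(x, y, keep_fraction = 0.3, weights = NULL) {
  xm <- .as_geno_matrix(x)
  stopifnot(length(y) == nrow(xm), keep_fraction > 0, keep_fraction <= 1)
  r <- .marginal_abs_cor(xm, y, weights)
  k <- ceiling(keep_fraction * ncol(xm))
  ord <- order(-r, seq_along(r))
  new_selected_set(ord[seq_len(k)], k, "sis")
}

#' Ridge regression fit with an unpenalized intercept
#'
#' Minimizes `sum_i w_i (y_i - a - x_i' b)^2 + lambda * N * ||b||^2` over
#' `(a, b)`. Solved in the primal when columns <= rows and through the dual
#' (kernel) form otherwise, so any column count is handled exactly.
#'
#' @param x Numeric matrix (rows = samples).
#' @param y Outcome vector.
#' @param shrinkage Penalty `lambda > 0`.
#' @param weights Optional nonnegative observation weights.
#' @return Coefficient vector `b` with the fitted intercept in
#'   `attr(, "intercept")`.
#' @export
ridge_fit <- function(x, y, shrinkage, weights = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  stopifnot(length(y) == n, shrinkage > 0)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("ridge_fit: non-finite inputs", call. = FALSE)
  }
  w <- weights %||% rep(1, n)
  if (!all(is.finite(w)) || any(w < 0)) {
    stop("ridge_fit: invalid weights", call. = FALSE)
  }
  sw <- sum(w)
  mx <- as.vector(crossprod(x, w)) / sw
  my <- sum(w * y) / sw
  rw <- sqrt(w)
  xc <- sweep(x, 2L, mx, "-") * rw
  yc <- (y - my) * rw
  lam <- shrinkage * n
  if (p <= n) {
    b <- solve(crossprod(xc) + diag(lam, p), crossprod(xc, yc))
  } else {
    alpha <- solve(tcrossprod(xc) + diag(lam, n), yc)
    b <- crossprod(xc, alpha)
  }
  b <- as.vector(b)
  attr(b, "intercept") <- my - sum(mx * b)
  b
}

#' Iteratively thresholded ridge regression screening
#'
#' Within each chromosome independently: fit a ridge regression on the
#' currently retained SNPs, keep the top `ceiling(keep_fraction * m)` by
#' absolute coefficient, and repeat for `n_iterations` rounds. The union of
#' per-chromosome survivors is returned.
#'
#' @param x Standardized genotypes or numeric matrix.
#' @param y Outcome vector.
#' @param chrom_labels Per-SNP chromosome labels (length `ncol(x)`); ignored
#'   when `config$per_chromosome` is `FALSE`.
#' @param config A `screening_config` with `method = "itrrs"`.
#' @param weights Optional nonnegative observation weights.
#' @return A `selected_set`; `per_iteration_sizes` holds the total retained
#'   count after each iteration (summed over chromosomes).
#' @export
itrrs_screen <- function(x, y, chrom_labels = NULL, config = screening_config("itrrs"),
                         weights = NULL) {
  xm <- .as_geno_matrix(x)
  stopifnot(config$method == "itrrs", length(y) == nrow(xm))
  m <- ncol(xm)
  if (is.null(chrom_labels) || !config$per_chromosome) {
    chrom_labels <- rep("1", m)
  }
  stopifnot(length(chrom_labels) == m)
  chroms <- unique(chrom_labels)
  per_iter <- matrix(0L, nrow = config$n_iterations, ncol = length(chroms))
  survivors <- integer(0)
  for (ci in seq_along(chroms)) {
    cur <- which(chrom_labels == chroms[ci])
    if (!length(cur)) {
      warning("itrrs_screen: chromosome ", chroms[ci], " has no SNPs")
      next
    }
    for (it in seq_len(config$n_iterations)) {
      b <- ridge_fit(xm[, cur, drop = FALSE], y, config$shrinkage, weights)
      k <- ceiling(config$keep_fraction * length(cur))
      ord <- order(-abs(b), seq_along(b))
      cur <- sort(cur[ord[seq_len(k)]])
      per_iter[it, ci] <- length(cur)
    }
    survivors <- c(survivors, cur)
  }
  new_selected_set(survivors, rowSums(per_iter), "itrrs")
}

# Exact survivor count of the iterated-ceiling thresholding rule.
iterated_ceiling <- function(m, keep_fraction, n_iterations) {
  for (i in seq_len(n_iterations)) m <- ceiling(keep_fraction * m)
  m
}
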