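# PLINK binary genotype and phenotype input.
#
# Only PLINK v1 SNP-major .bed files are supported (magic bytes 0x6c 0x1b
# 0x01). Decoding is done in pure R through a 256-entry byte lookup table;
# no external genotype-reader package is required.

.plink_magic <- as.raw(c(0x6c, 0x1b, 0x01))

# 2-bit PLINK codes -> additive count of the A1 allele:
# 00 -> 2 copies, 01 -> missing, 10 -> 1 copy (het), 11 -> 0 copies.
.plink_decode_tab <- local({
  code <- c(2, NA, 1, 0)
  tab <- matrix(NA_real_, nrow = 256, ncol = 4)
  for (b in 0:255) {
    for (k in 0:3) {
      tab[b + 1L, k + 1L] <- code[bitwAnd(bitwShiftR(b, 2L * k), 3L) + 1L]
    }
  }
  tab
})

#' Construct a genotype dataset in memory
#'
#' @param genotypes `N x M` additive 0/1/2 matrix (missing allowed).
#' @param snp_chrom,snp_id Per-SNP chromosome labels and identifiers.
#' @param sample_id Per-sample identifiers.
#' @param maf Optional per-SNP minor allele frequencies (computed from the
#'   matrix when omitted).
#' @param n_imputed Number of mean-imputed entries (bookkeeping).
#' @return A `genotype_dataset`.
#' @export
new_genotype_dataset <- function(genotypes, snp_chrom, snp_id, sample_id,
                                 maf = NULL, n_imputed = 0L) {
  stopifnot(is.matrix(genotypes))
  n <- nrow(genotypes)
  m <- ncol(genotypes)
  stopifnot(length(snp_chrom) == m, length(snp_id) == m,
            length(sample_id) == n)
  if (is.null(maf)) {
    f <- colMeans(genotypes, na.rm = TRUE) / 2
    maf <- pmin(f, 1 - f)
  }
  structure(
    list(n_samples = n, n_snps = m, genotypes = genotypes,
         snp_chrom = as.character(snp_chrom), snp_id = as.character(snp_id),
         sample_id = as.character(sample_id), maf = as.numeric(maf),
         n_imputed = as.integer(n_imputed)),
    class = "genotype_dataset")
}

#' Read a PLINK bed/bim/fam fileset
#'
#' Decodes a PLINK v1 binary fileset (SNP-major) into an additive 0/1/2
#' genotype matrix with the `.bim` A1 allele as the counted allele.
#' Monomorphic SNPs are dropped and missing genotypes are imputed to the
#' per-SNP mean of the non-missing entries; both actions are reported via
#' [message()].
#'
#' @param prefix File-path stem: `<prefix>.bed`, `<prefix>.bim` and
#'   `<prefix>.fam` must all exist.
#' @return A `genotype_dataset`: a list with the `N x M` `genotypes` matrix,
#'   `snp_chrom`, `snp_id`, `sample_id`, per-SNP `maf` and the number of
#'   imputed entries `n_imputed`.
#' @export
read_plink <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  bim_path <- paste0(prefix, ".bim")
  fam_path <- paste0(prefix, ".fam")
  for (p in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(p)) stop("PLINK file not found: ", p, call. = FALSE)
  }
  bim <- utils::read.table(bim_path, header = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "numeric", "character", "character"))
  fam <- utils::read.table(fam_path, header = FALSE,
                           colClasses = "character")
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(bed_path, what = "raw", n = file.size(bed_path))
  if (length(raw) < 3L || !identical(raw[1:3], .plink_magic)) {
    stop("not a PLINK v1 SNP-major .bed file (bad magic bytes): ", bed_path,
         call. = FALSE)
  }
  bpv <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bpv * m) {
    stop(".bed size inconsistent with .bim/.fam dimensions (N=", n,
         ", M=", m, "): ", bed_path, call. = FALSE)
  }
  byte_mat <- matrix(as.integer(body), nrow = bpv, ncol = m)
  g <- matrix(NA_real_, nrow = n, ncol = m)
  for (k in 0:3) {
    srows <- seq.int(k + 1L, n, by = 4L)
    if (!length(srows)) next
    brows <- seq_along(srows)
    g[srows, ] <- .plink_decode_tab[byte_mat[brows, , drop = FALSE] + 1L,
                                    k + 1L]
  }
  n_missing <- sum(is.na(g))
  if (n_missing > 0L) {
    cm <- colMeans(g, na.rm = TRUE)
    idx <- which(is.na(g), arr.ind = TRUE)
    g[idx] <- cm[idx[, 2L]]
    message("read_plink: imputed ", n_missing,
            " missing genotype(s) to per-SNP means")
  }
  f <- colMeans(g) / 2
  maf <- pmin(f, 1 - f)
  sds <- apply(g, 2L, stats::sd)
  keep <- maf > 0 & sds > 0
  if (any(!keep)) {
    message("read_plink: dropped ", sum(!keep), " monomorphic SNP(s)")
  }
  new_genotype_dataset(g[, keep, drop = FALSE],
                       snp_chrom = bim[[1L]][keep], snp_id = bim[[2L]][keep],
                       sample_id = fam[[2L]], maf = maf[keep],
                       n_imputed = n_missing)
}

#' Write a genotype dataset as a PLINK bed/bim/fam fileset
#'
#' Inverse of [read_plink()] for integer 0/1/2 matrices (missing entries are
#' written as the PLINK missing code). Used mainly to export simulated data.
#'
#' @param g A `genotype_dataset` with integer-valued genotypes.
#' @param prefix Output file-path stem.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "genotype_dataset"))
  x <- g$genotypes
  if (any(!is.na(x) & x != round(x))) {
    stop("write_plink requires integer 0/1/2 genotypes (no imputed values)",
         call. = FALSE)
  }
  n <- nrow(x)
  m <- ncol(x)
  # value -> 2-bit code: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  code <- matrix(3L, n, m)
  code[x == 1] <- 2L
  code[x == 2] <- 0L
  code[is.na(x)] <- 1L
  pad <- (-n) %% 4L
  if (pad > 0L) code <- rbind(code, matrix(0L, pad, m))
  k <- nrow(code) / 4L
  shift <- rep(c(1L, 4L, 16L, 64L), times = k)
  bytes <- code * shift
  dim(bytes) <- c(4L, k, m)
  byte_vals <- as.integer(colSums(bytes))
  writeBin(c(.plink_magic, as.raw(byte_vals)), paste0(prefix, ".bed"))
  bim <- data.frame(chrom = g$snp_chrom, id = g$snp_id, cm = 0,
                    bp = seq_len(m), a1 = "A", a2 = "B")
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = g$sample_id, iid = g$sample_id, pat = 0, mat = 0,
                    sex = 0, phe = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Column-standardize a genotype matrix
#'
#' Centers every SNP column by its sample mean and scales by its sample
#' standard deviation (denominator `N - 1`), so each column has mean 0 and
#' variance 1 exactly in-sample.
#'
#' @param g A `genotype_dataset` or a plain numeric matrix without missing
#'   values.
#' @return A `std_genotypes` object: list with `matrix`, `column_means`,
#'   `column_sds`, and (when available) `snp_chrom`/`snp_id` carried over.
#' @export
standardize <- function(g) {
  if (inherits(g, "std_genotypes")) {
    x <- g$matrix
    chrom <- g$snp_chrom
    ids <- g$snp_id
  } else if (inherits(g, "genotype_dataset")) {
    x <- g$genotypes
    chrom <- g$snp_chrom
    ids <- g$snp_id
  } else {
    x <- as.matrix(g)
    chrom <- NULL
    ids <- colnames(x)
  }
  if (anyNA(x)) stop("standardize: missing genotypes present; impute first",
                     call. = FALSE)
  n <- nrow(x)
  mu <- colMeans(x)
  sds <- sqrt(pmax(colSums(x * x) - n * mu^2, 0) / (n - 1))
  if (any(sds == 0)) {
    bad <- which(sds == 0)[1L]
    nm <- if (!is.null(ids)) ids[bad] else paste0("column ", bad)
    stop("standardize: degenerate (constant) SNP: ", nm, call. = FALSE)
  }
  xs <- sweep(sweep(x, 2L, mu, "-"), 2L, sds, "/")
  structure(list(matrix = xs, column_means = mu, column_sds = sds,
                 snp_chrom = chrom, snp_id = ids),
            class = "std_genotypes")
}

#' Construct a phenotype set in memory
#'
#' @param outcome_type `"continuous"`, `"binary"` or `"survival"`.
#' @param y Outcome vector (0/1 for binary; observed log-scale times for
#'   survival).
#' @param event 0/1 event indicator (survival only).
#' @param covariates Optional numeric covariate matrix.
#' @param covariate_names Optional covariate labels.
#' @param sample_id Optional sample identifiers (checked against the
#'   genotype order by [estimate_heritability()]).
#' @return A `phenotype_set`.
#' @export
new_phenotype_set <- function(outcome_type, y, event = NULL,
                              covariates = NULL, covariate_names = NULL,
                              sample_id = NULL) {
  outcome_type <- match.arg(outcome_type,
                            c("continuous", "binary", "survival"))
  y <- as.numeric(y)
  if (any(!is.finite(y))) stop("phenotype y must be finite", call. = FALSE)
  if (outcome_type == "binary" && !all(y %in% c(0, 1))) {
    stop("binary outcome must be coded 0/1", call. = FALSE)
  }
  if (outcome_type == "survival") {
    if (is.null(event)) stop("survival outcome requires an event indicator",
                             call. = FALSE)
    event <- as.numeric(event)
    if (!all(event %in% c(0, 1))) {
      stop("event indicator must be coded 0/1", call. = FALSE)
    }
    if (length(event) != length(y)) stop("length(event) != length(y)",
                                         call. = FALSE)
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != length(y)) {
      stop("covariate rows must match phenotype length", call. = FALSE)
    }
    if (is.null(covariate_names)) covariate_names <- colnames(covariates)
  }
  structure(list(outcome_type = outcome_type, y = y, event = event,
                 covariates = covariates, covariate_names = covariate_names,
                 sample_id = if (is.null(sample_id)) NULL
                             else as.character(sample_id)),
            class = "phenotype_set")
}

#' Read a phenotype (and optional covariate) table
#'
#' Reads a whitespace/tab-delimited file with a header whose first column is
#' the sample ID, joins it to the genotype sample order, and validates the
#' outcome coding. Survival times are expected on the original (positive)
#' time scale; the log is taken internally.
#'
#' @param path Phenotype file. Continuous/binary: second column is the value
#'   (or set `value_col`). Survival: needs `time_col` and `status_col`.
#' @param outcome_type `"continuous"`, `"binary"` or `"survival"`.
#' @param sample_ids Character vector giving the genotype sample order
#'   (typically `g$sample_id`); the returned set is aligned to it.
#' @param covariate_path Optional covariate table, same ID-keyed layout;
#'   all non-ID columns are used as numeric covariates.
#' @param value_col,time_col,status_col Column names (defaults: second
#'   column, `"time"`, `"status"`).
#' @return A `phenotype_set` aligned to `sample_ids`.
#' @export
read_phenotypes <- function(path, outcome_type, sample_ids,
                            covariate_path = NULL, value_col = NULL,
                            time_col = "time", status_col = "status") {
  outcome_type <- match.arg(outcome_type,
                            c("continuous", "binary", "survival"))
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  missing_ids <- setdiff(sample_ids, ids)
  if (length(missing_ids)) {
    stop("phenotype file lacks genotyped sample(s): ",
         paste(utils::head(missing_ids, 10L), collapse = ", "),
         if (length(missing_ids) > 10L) ", ...", call. = FALSE)
  }
  tab <- tab[match(sample_ids, ids), , drop = FALSE]
  if (outcome_type == "survival") {
    for (cn in c(time_col, status_col)) {
      if (!cn %in% names(tab)) {
        stop("survival phenotype file must contain column '", cn, "'",
             call. = FALSE)
      }
    }
    tt <- as.numeric(tab[[time_col]])
    if (any(!is.finite(tt)) || any(tt <= 0)) {
      stop("survival times must be finite and > 0 (log is taken internally)",
           call. = FALSE)
    }
    y <- log(tt)
    event <- as.numeric(tab[[status_col]])
  } else {
    vc <- value_col %||% names(tab)[2L]
    y <- as.numeric(tab[[vc]])
    event <- NULL
    if (outcome_type == "binary" && !all(y %in% c(0, 1))) {
      stop("binary phenotype contains values outside {0, 1}", call. = FALSE)
    }
  }
  covariates <- NULL
  if (!is.null(covariate_path)) {
    ct <- utils::read.table(covariate_path, header = TRUE,
                            stringsAsFactors = FALSE)
    cids <- as.character(ct[[1L]])
    miss <- setdiff(sample_ids, cids)
    if (length(miss)) {
      stop("covariate file lacks genotyped sample(s): ",
           paste(utils::head(miss, 10L), collapse = ", "), call. = FALSE)
    }
    ct <- ct[match(sample_ids, cids), -1L, drop = FALSE]
    covariates <- as.matrix(data.matrix(ct))
  }
  new_phenotype_set(outcome_type, y, event = event, covariates = covariates,
                    sample_id = sample_ids)
}
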