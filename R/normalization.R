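#' Counts per million
#'
#' Scales each column of a count matrix by its library size (column sum)
#' times one million.
#'
#' @param counts Non-negative gene-by-sample matrix with dimnames.
#' @return Numeric matrix of CPM values with a `scale = "linear"` attribute.
#' @export
cpm <- function(counts) {
  check_count_matrix(counts)
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("zero-sum column(s): ", paste(colnames(counts)[lib == 0], collapse = ", "))
  out <- sweep(counts, 2L, lib, `/`) * 1e6
  attr(out, "scale") <- "linear"
  out
}

#' Filter low-expression genes
#'
#' Keeps genes expressed at or above `min_cpm` counts per million in at
#' least `min_samples` samples (the standard pre-test expression filter).
#' Idempotent; gene order and the sample set are preserved.
#'
#' @param counts Count matrix.
#' @param min_cpm CPM threshold (inclusive; default 1).
#' @param min_samples Minimum number of samples meeting the threshold
#'   (default 1).
#' @return The filtered count matrix.
#' @export
filter_low_expression <- function(counts, min_cpm = 1, min_samples = 1) {
  x <- cpm(counts)
  keep <- rowSums(x >= min_cpm) >= min_samples
  counts[keep, , drop = FALSE]
}

# Per-sample quantile of CPM (used to pick the TMM reference column).
sample_quantile <- function(counts, p = 0.75) {
  lib <- colSums(counts)
  vapply(seq_len(ncol(counts)),
         function(j) stats::quantile(counts[, j], p) / lib[j], numeric(1))
}

# One TMM factor: weighted trimmed mean of M-values of obs vs ref.
tmm_one <- function(obs, ref, trim_m, trim_a, min_genes = 20) {
  n_obs <- sum(obs); n_ref <- sum(ref)
  # single-expression forms keep floating-point ties identical across genes
  # with equal count ratios, so the rank-based trim is reproducible
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a)
  if (!any(fin))
    stop("no co-expressed genes between sample and reference")
  m <- m[fin]; a <- a[fin]; w <- w[fin]
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  keep <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (sum(keep) < min_genes) {
    warning("fewer than ", min_genes,
            " genes survive TMM trimming; using the untrimmed mean")
    keep <- rep(TRUE, n)
  }
  2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
}

#' TMM normalization factors
#'
#' Computes trimmed-mean-of-M-values scaling factors. For each sample
#' against a reference, genes with positive counts in both are used; the
#' most extreme `trim_m` fractions of log-ratios (M) and `trim_a` fractions
#' of average log-abundances (A) are discarded, and the factor is two to
#' the power of the weighted mean of the remaining M values, with inverse
#' approximate-binomial-variance weights. Factors are rescaled to geometric
#' mean 1.
#'
#' @param counts Count matrix (apply [filter_low_expression()] first).
#' @param trim_m,trim_a Two-sided trim fractions for M and A (defaults 0.30
#'   and 0.05, the published algorithm's defaults).
#' @param reference Reference sample id, or `NULL` to pick the sample whose
#'   upper-quartile CPM is closest to the mean upper-quartile.
#' @return Data frame with `sample_id`, `lib_size`, `factor`,
#'   `effective_lib_size` (= lib_size * factor).
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05, reference = NULL) {
  check_count_matrix(counts)
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("zero-sum column(s): ", paste(colnames(counts)[lib == 0], collapse = ", "))
  if (is.null(reference)) {
    uq <- sample_quantile(counts, 0.75)
    ref_j <- which.min(abs(uq - mean(uq)))
  } else {
    ref_j <- match(reference, colnames(counts))
    if (is.na(ref_j)) stop("reference sample not found: ", reference)
  }
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref_j) return(1)
    tmm_one(as.numeric(counts[, j]), as.numeric(counts[, ref_j]),
            trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  data.frame(sample_id = colnames(counts), lib_size = lib, factor = f,
             effective_lib_size = lib * f, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' TMM-normalized expression values
#'
#' "TMM values": counts per million computed on the TMM-effective library
#' size (library size times TMM factor). This is the standard meaning of
#' TMM-normalized expression and the substrate of all downstream distance
#' and correlation statistics here.
#'
#' @param counts Count matrix.
#' @param factors Result of [tmm_factors()] on the same samples, or `NULL`
#'   to compute them.
#' @return Linear-scale expression matrix (`scale = "linear"` attribute).
#' @export
tmm_values <- function(counts, factors = NULL) {
  check_count_matrix(counts)
  if (is.null(factors)) factors <- tmm_factors(counts)
  if (!setequal(factors$sample_id, colnames(counts)) ||
      nrow(factors) != ncol(counts))
    stop("factor table does not match the sample set")
  eff <- factors$effective_lib_size[match(colnames(counts), factors$sample_id)]
  out <- sweep(counts, 2L, eff, `/`) * 1e6
  attr(out, "scale") <- "linear"
  out
}

#' Log2-transform an expression matrix
#'
#' @param expr Linear-scale expression matrix.
#' @param pseudocount Added before the log (default 1).
#' @return Matrix of `log2(value + pseudocount)` with `scale = "log2"`.
#' @export
log_transform <- function(expr, pseudocount = 1) {
  if (expr_scale(expr) != "linear")
    stop("input is already log-scale")
  stopifnot(pseudocount > 0)
  out <- log2(expr + pseudocount)
  attr(out, "scale") <- "log2"
  attr(out, "pseudocount") <- pseudocount
  out
}
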