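#' Per-gene differential expression between two groups
#'
#' Calls fight-responsive genes against the non-fighting baseline. The log2
#' fold change is the difference of group means of log2 TMM values
#' (`group_b` minus `group_a`). P-values come from either a Welch
#' two-sample t-test on log2 TMM values (`welch_log`, the default) or a
#' negative-binomial likelihood-ratio test with a common method-of-moments
#' dispersion (`nb_lrt`). FDR is Benjamini-Hochberg over all tested genes.
#' Genes constant across both groups get p = 1 by convention and are
#' flagged.
#'
#' @param log_expr Log2-scale expression matrix (see [log_transform()]).
#' @param counts Count matrix on the same genes/samples (used by `nb_lrt`).
#' @param group_a,group_b Disjoint character vectors of sample ids, each of
#'   size >= 2; `group_a` is the reference (baseline).
#' @param method `"welch_log"` or `"nb_lrt"`.
#' @return Data frame with `gene_id`, `logFC`, `p_value`, `fdr`,
#'   `direction` (`"up"`/`"down"`), `constant`.
#' @export
de_test <- function(log_expr, counts = NULL, group_a, group_b,
                    method = c("welch_log", "nb_lrt")) {
  method <- match.arg(method)
  if (expr_scale(log_expr) != "log2") stop("log_expr must be log2-scale")
  if (length(intersect(group_a, group_b)))
    stop("groups overlap")
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs >= 2 samples")
  miss <- setdiff(c(group_a, group_b), colnames(log_expr))
  if (length(miss)) stop("samples not in matrix: ", paste(miss, collapse = ", "))

  xa <- log_expr[, group_a, drop = FALSE]
  xb <- log_expr[, group_b, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  lfc <- mb - ma
  const <- apply(cbind(xa, xb), 1L, function(v) max(v) == min(v))

  if (method == "welch_log") {
    va <- apply(xa, 1L, stats::var); vb <- apply(xb, 1L, stats::var)
    na <- ncol(xa); nb <- ncol(xb)
    se2 <- va / na + vb / nb
    tstat <- (mb - ma) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
    p[!is.finite(p)] <- 1
  } else {
    if (is.null(counts)) stop("nb_lrt needs the count matrix")
    check_count_matrix(counts)
    p <- nb_lrt_p(counts, group_a, group_b)
  }
  p[const] <- 1

  data.frame(
    gene_id = rownames(log_expr), logFC = lfc, p_value = p,
    fdr = bh_fdr(p), direction = ifelse(lfc >= 0, "up", "down"),
    constant = const, row.names = NULL, stringsAsFactors = FALSE
  )
}

# NB likelihood-ratio p-values with one method-of-moments dispersion shared
# across genes; group means are fit on library-size offsets by 1-D
# likelihood maximization.
nb_lrt_p <- function(counts, group_a, group_b) {
  samp <- c(group_a, group_b)
  cts <- counts[, samp, drop = FALSE]
  lib <- colSums(counts)[samp]
  rel <- sweep(cts, 2L, lib, `/`)
  # pooled MoM dispersion on within-group CPM-scale moments
  mom <- function(ids) {
    x <- sweep(cts[, ids, drop = FALSE], 2L, lib[ids], `/`) * mean(lib)
    m <- rowMeans(x); v <- apply(x, 1L, stats::var)
    (v - m) / m^2
  }
  phis <- c(mom(group_a), mom(group_b))
  phi <- max(1e-4, stats::median(phis[is.finite(phis)], na.rm = TRUE))
  size <- 1 / phi
  ll <- function(y, mu) sum(stats::dnbinom(y, size = size, mu = pmax(mu, 1e-12), log = TRUE))
  fit_ll <- function(y, off) {
    # maximize over the common relative expression q: mu = q * off
    q0 <- sum(y) / sum(off)
    if (q0 == 0) return(ll(y, q0 * off))
    opt <- stats::optimize(function(lq) -ll(y, exp(lq) * off),
                           interval = log(q0) + c(-4, 4))
    -opt$objective
  }
  ia <- match(group_a, samp); ib <- match(group_b, samp)
  vapply(seq_len(nrow(cts)), function(g) {
    y <- cts[g, ]
    l1 <- fit_ll(y[ia], lib[ia]) + fit_ll(y[ib], lib[ib])
    l0 <- fit_ll(y, lib)
    stats::pchisq(max(0, 2 * (l1 - l0)), df = 1, lower.tail = FALSE)
  }, numeric(1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment over the supplied p-values (wraps
#' `stats::p.adjust(method = "BH")` behind a validated interface).
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Adjusted values, capped at 1, monotone in the p-value ranking.
#' @export
bh_fdr <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must be in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Select differentially expressed genes under a threshold profile
#'
#' Two named profiles mirror the study's two uses of the DE results:
#' `"characterization"` (FDR <= 0.05 and |logFC| > 2, the stringent DEG
#' list) and `"sync_input"` (FDR <= 0.05 and logFC > 0, the permissive
#' up-regulated list feeding the synchronization analysis). A custom
#' profile is available through the threshold arguments.
#'
#' @param de Result of [de_test()].
#' @param profile `"characterization"`, `"sync_input"` or `"custom"`.
#' @param fdr_max,min_abs_lfc,direction Custom thresholds (used when
#'   `profile = "custom"`): FDR cutoff (inclusive), minimum |logFC|
#'   (exclusive), and `"up"`, `"down"` or `"any"`.
#' @return Character vector of gene ids with a `provenance` attribute
#'   recording the thresholds.
#' @export
select_degs <- function(de, profile = c("characterization", "sync_input", "custom"),
                        fdr_max = 0.05, min_abs_lfc = 0, direction = "any") {
  profile <- match.arg(profile)
  sel <- switch(profile,
    characterization = de$fdr <= 0.05 & abs(de$logFC) > 2,
    sync_input = de$fdr <= 0.05 & de$logFC > 0,
    custom = de$fdr <= fdr_max & abs(de$logFC) > min_abs_lfc &
      switch(direction, up = de$logFC > 0, down = de$logFC < 0,
             any = rep(TRUE, nrow(de)))
  )
  out <- de$gene_id[sel]
  attr(out, "provenance") <- switch(profile,
    characterization = list(profile = profile, fdr_max = 0.05, min_abs_lfc = 2,
                            direction = "any"),
    sync_input = list(profile = profile, fdr_max = 0.05, min_abs_lfc = 0,
                      direction = "up"),
    custom = list(profile = profile, fdr_max = fdr_max,
                  min_abs_lfc = min_abs_lfc, direction = direction))
  out
}

#' Venn partition of two gene sets
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @return List with `a_only`, `b_only`, `both` (counts) and `union`
#'   (= a_only + b_only + both).
#' @export
venn_partition <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  both <- length(intersect(a, b))
  out <- list(a_only = length(a) - both, b_only = length(b) - both,
              both = both)
  out$union <- out$a_only + out$b_only + out$both
  out
}

#' Hypergeometric tail probability of a set overlap
#'
#' Upper-tail probability P(X >= overlap) that two gene sets of the given
#' sizes drawn from a common universe share at least the observed number of
#' genes. Evaluated in log space so that extreme significance (p far below
#' 1e-300) remains representable; both `p` (possibly underflowing to 0) and
#' `log10_p` are returned.
#'
#' @param size_a,size_b Sizes of the two sets.
#' @param overlap Observed intersection size.
#' @param universe Universe size.
#' @return List with `p` and `log10_p`.
#' @examples
#' overlap_hypergeometric(5, 5, 5, 10)      # 1 / choose(10, 5)
#' overlap_hypergeometric(518, 859, 295, 23306)$log10_p  # about -297.1
#' @export
overlap_hypergeometric <- function(size_a, size_b, overlap, universe) {
  stopifnot(size_a >= 0, size_b >= 0, overlap >= 0,
            size_a <= universe, size_b <= universe)
  if (overlap > min(size_a, size_b))
    stop("overlap exceeds the smaller set")
  if (overlap == 0) return(list(p = 1, log10_p = 0))
  lp <- stats::phyper(overlap - 1, size_a, universe - size_a, size_b,
                      lower.tail = FALSE, log.p = TRUE)
  list(p = exp(lp), log10_p = lp / log(10))
}

#' Cross-classify genes by significance in two DE comparisons
#'
#' Projects one comparison's DEG calls onto the other's: each gene is
#' classified as `ns` (significant in neither), `a_only`, `b_only` or
#' `both`, together with the logFC sign pattern, and sign-discordant genes
#' among the `both` class are counted.
#'
#' @param de_a,de_b Results of [de_test()] over the same gene universe.
#' @param profile Threshold profile passed to [select_degs()].
#' @param ... Custom thresholds forwarded to [select_degs()].
#' @return List with `table` (per-gene data frame: `gene_id`, `category`,
#'   `sign_a`, `sign_b`, `pattern`) and `n_discordant`.
#' @export
projection_categories <- function(de_a, de_b, profile = "characterization", ...) {
  if (!identical(de_a$gene_id, de_b$gene_id))
    stop("the two DE results must cover the same gene universe in order")
  in_a <- de_a$gene_id %in% select_degs(de_a, profile, ...)
  in_b <- de_b$gene_id %in% select_degs(de_b, profile, ...)
  category <- ifelse(in_a & in_b, "both",
              ifelse(in_a, "a_only", ifelse(in_b, "b_only", "ns")))
  sign_a <- ifelse(de_a$logFC >= 0, "up", "down")
  sign_b <- ifelse(de_b$logFC >= 0, "up", "down")
  pattern <- ifelse(category == "ns", "ns", paste(sign_a, sign_b, sep = "-"))
  tab <- data.frame(gene_id = de_a$gene_id, category = category,
                    sign_a = sign_a, sign_b = sign_b, pattern = pattern,
                    stringsAsFactors = FALSE)
  list(table = tab,
       n_discordant = sum(category == "both" & sign_a != sign_b))
}
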