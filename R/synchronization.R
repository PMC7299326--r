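#' Enumerate all sample dyads within a fighting group
#'
#' Lists every unordered pair of samples ("dyad") in a group; a dyad is
#' "paired" when its two samples are the two opponents of one fighting
#' pair, and "unpaired" otherwise. With the study design of 10 fish in 5
#' pairs this yields 45 dyads: 5 paired and 40 unpaired.
#'
#' @param design Sample design (see [simulate_design()]).
#' @param group Group label, e.g. `"D20"` or `"D60"`.
#' @return Data frame with `sample_1`, `sample_2`, `is_paired`, `group` and
#'   `pair_id` (the shared fighting-pair id for paired dyads, `NA`
#'   otherwise).
#' @export
enumerate_sample_pairs <- function(design, group) {
  d <- design[design$group == group, , drop = FALSE]
  if (nrow(d) == 0) stop("group not present in design: ", group)
  if (nrow(d) < 2) stop("group has fewer than 2 samples")
  idx <- utils::combn(nrow(d), 2L)
  s1 <- d$sample_id[idx[1, ]]; s2 <- d$sample_id[idx[2, ]]
  p1 <- d$pair_id[idx[1, ]]; p2 <- d$pair_id[idx[2, ]]
  paired <- !is.na(p1) & !is.na(p2) & p1 == p2
  data.frame(sample_1 = s1, sample_2 = s2, is_paired = paired,
             group = group, pair_id = ifelse(paired, p1, NA_character_),
             stringsAsFactors = FALSE)
}

#' Between-sample Pearson correlations over genes
#'
#' Pearson correlation of log2 TMM values across genes for every dyad.
#'
#' @param log_expr Log2-scale expression matrix.
#' @param pairing Dyad table from [enumerate_sample_pairs()].
#' @return The dyad table with an added `r` column.
#' @export
sample_correlations <- function(log_expr, pairing) {
  if (expr_scale(log_expr) != "log2") stop("log_expr must be log2-scale")
  if (nrow(log_expr) < 3) stop("need at least 3 genes")
  samp <- unique(c(pairing$sample_1, pairing$sample_2))
  miss <- setdiff(samp, colnames(log_expr))
  if (length(miss)) stop("samples not in matrix: ", paste(miss, collapse = ", "))
  sds <- apply(log_expr[, samp, drop = FALSE], 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance sample(s): ", paste(samp[sds == 0], collapse = ", "))
  cm <- stats::cor(log_expr[, samp, drop = FALSE])
  pairing$r <- cm[cbind(match(pairing$sample_1, samp),
                        match(pairing$sample_2, samp))]
  pairing
}

#' Permutation test of paired vs unpaired dyad correlations
#'
#' Tests whether the correlations of paired dyads exceed those of unpaired
#' dyads by permuting the paired/unpaired labels over all dyads (the dyads
#' are treated as exchangeable, as in the original analysis; they share
#' samples, so this exchangeability is an approximation).
#'
#' @param correlations Result of [sample_correlations()].
#' @param alternative Test direction; default `"greater"` (paired r
#'   larger).
#' @param mode,n_mc,seed Passed to [permutation_test()].
#' @return The p-value.
#' @export
group_sync_test <- function(correlations, alternative = "greater",
                            mode = "exact_rank", n_mc = 10000, seed = NULL) {
  if (!any(correlations$is_paired) || all(correlations$is_paired))
    stop("need at least one paired and one unpaired dyad")
  permutation_test(correlations$r, correlations$is_paired,
                   alternative = alternative, mode = mode, n_mc = n_mc,
                   seed = seed)
}

#' Per-gene expression distances over all dyads
#'
#' For gene i and dyad j with linear-scale TMM values x1, x2, the distance
#' is `D_ij = |log10((x1 + eps) / (x2 + eps))|`. The offset `eps` guards
#' the ratio against zero TMM values; by default it is half the smallest
#' positive value in the matrix.
#'
#' @param expr Linear-scale TMM expression matrix (from [tmm_values()]).
#' @param pairing Dyad table from [enumerate_sample_pairs()].
#' @param epsilon Positive offset, or `NULL` for the default.
#' @return List of class `"pibs_distances"` with `distances` (gene-by-dyad
#'   matrix), `pairing` and `epsilon`.
#' @export
gene_pair_distances <- function(expr, pairing, epsilon = NULL) {
  if (expr_scale(expr) != "linear")
    stop("expr must be linear-scale TMM values, not log-transformed")
  if (is.null(epsilon)) {
    pos <- expr[expr > 0]
    epsilon <- if (length(pos)) min(pos) / 2 else 0.5
  }
  stopifnot(epsilon > 0)
  x1 <- expr[, pairing$sample_1, drop = FALSE]
  x2 <- expr[, pairing$sample_2, drop = FALSE]
  d <- abs(log10((x1 + epsilon) / (x2 + epsilon)))
  colnames(d) <- paste(pairing$sample_1, pairing$sample_2, sep = ":")
  structure(list(distances = d, pairing = pairing, epsilon = epsilon),
            class = "pibs_distances")
}

#' Per-gene synchrony test
#'
#' For each gene, tests whether its paired-dyad distances are smaller than
#' its unpaired-dyad distances by a permutation test over the dyad labels
#' (default: exact Wilcoxon rank-sum via the shift algorithm). A gene with
#' p < `alpha` (strict) is called synchronized.
#'
#' @param dist_obj Result of [gene_pair_distances()].
#' @param alpha Significance level (default 0.05, strict `<`).
#' @param alternative Default `"less"` (paired distances smaller).
#' @param mode,n_mc,seed Passed to [permutation_test()].
#' @return Data frame with `gene_id`, `p`, `is_synchronized`.
#' @export
gene_sync_test <- function(dist_obj, alpha = 0.05, alternative = "less",
                           mode = "exact_rank", n_mc = 10000, seed = NULL) {
  stopifnot(inherits(dist_obj, "pibs_distances"))
  g1 <- dist_obj$pairing$is_paired
  p <- apply(dist_obj$distances, 1L, function(v)
    permutation_test(v, g1, alternative = alternative, mode = mode,
                     n_mc = n_mc, seed = seed))
  data.frame(gene_id = rownames(dist_obj$distances), p = p,
             is_synchronized = p < alpha, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-gene unpaired-distance baseline
#'
#' The baseline B_i of gene i is the 25th percentile of its distances over
#' the unpaired dyads (linear-interpolation percentile convention
#' h = (n - 1) p + 1 on the sorted values; for the study design the 40
#' unpaired dyads give h = 10.75).
#'
#' @param dist_obj Result of [gene_pair_distances()].
#' @param prob Percentile (default 0.25).
#' @return Named numeric vector of baselines B_i.
#' @export
sync_baseline <- function(dist_obj, prob = 0.25) {
  stopifnot(inherits(dist_obj, "pibs_distances"))
  up <- dist_obj$distances[, !dist_obj$pairing$is_paired, drop = FALSE]
  if (ncol(up) < 4) stop("need at least 4 unpaired dyads")
  apply(up, 1L, stats::quantile, probs = prob, type = 7, names = FALSE)
}

#' Assign synchronized genes to specific fighting pairs
#'
#' A synchronized gene i is called synchronized in fighting pair j when its
#' paired-dyad distance is strictly below its baseline: `D_ij < B_i`.
#' Non-synchronized genes receive no per-pair flags.
#'
#' @param dist_obj Result of [gene_pair_distances()].
#' @param sync Result of [gene_sync_test()].
#' @param baselines Result of [sync_baseline()].
#' @return List of class `"pibs_sync"` with `genes` (data frame `gene_id`,
#'   `p`, `is_synchronized`, `baseline`, `n_pairs`), `pair_flags`
#'   (gene-by-pair logical matrix) and `pair_ids`.
#' @export
assign_sync_pairs <- function(dist_obj, sync, baselines) {
  stopifnot(inherits(dist_obj, "pibs_distances"))
  paired <- dist_obj$pairing$is_paired
  dp <- dist_obj$distances[, paired, drop = FALSE]
  pair_ids <- dist_obj$pairing$pair_id[paired]
  colnames(dp) <- pair_ids
  stopifnot(identical(sync$gene_id, rownames(dist_obj$distances)),
            length(baselines) == nrow(dist_obj$distances))
  flags <- dp < baselines
  flags[!sync$is_synchronized, ] <- FALSE
  genes <- data.frame(
    gene_id = sync$gene_id, p = sync$p,
    is_synchronized = sync$is_synchronized,
    baseline = as.numeric(baselines), n_pairs = rowSums(flags),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(genes = genes, pair_flags = flags, pair_ids = pair_ids),
            class = "pibs_sync")
}

#' Full synchronization analysis for one fighting group
#'
#' Runs the complete per-group pipeline on a DEG set: TMM normalization,
#' dyad enumeration, per-gene distances, the per-gene synchrony permutation
#' test, the unpaired-distance baseline, and per-pair assignment. Emits the
#' per-gene table together with the tally of synchronized genes by the
#' number of pairs they are synchronized in and the synchronized fraction
#' of the DEG set.
#'
#' @param counts Count matrix (all genes; filtering/normalization happen
#'   inside on the full matrix so TMM factors reflect the whole library).
#' @param design Sample design.
#' @param group Fighting group, e.g. `"D60"`.
#' @param deg_set Character vector of gene ids to analyze (must be a subset
#'   of the expressed genes).
#' @param alpha Per-gene significance level.
#' @param mode,n_mc,seed Passed to [permutation_test()].
#' @param epsilon Distance offset (see [gene_pair_distances()]).
#' @param min_cpm,min_samples Expression filter (see
#'   [filter_low_expression()]).
#' @return List of class `"pibs_sync_pipeline"`: `result` (the
#'   `"pibs_sync"` object), `tally` (named counts over 1..n_pairs),
#'   `n_deg`, `n_synchronized`, `fraction_synchronized` (percent),
#'   `group_p` (paired-vs-unpaired correlation test p), `correlations`.
#' @export
sync_pipeline <- function(counts, design, group, deg_set, alpha = 0.05,
                          mode = "exact_rank", n_mc = 10000, seed = NULL,
                          epsilon = NULL, min_cpm = 1, min_samples = 1) {
  kept <- filter_low_expression(counts, min_cpm, min_samples)
  missing_genes <- setdiff(deg_set, rownames(kept))
  if (length(missing_genes))
    stop("deg_set genes absent after filtering: ",
         paste(utils::head(missing_genes, 5), collapse = ", "))
  expr <- tmm_values(kept)
  lexpr <- log_transform(expr)
  pairing <- enumerate_sample_pairs(design, group)
  corr <- sample_correlations(lexpr, pairing)
  group_p <- group_sync_test(corr, mode = mode, n_mc = n_mc, seed = seed)

  n_pairs <- sum(pairing$is_paired)
  if (length(deg_set) == 0) {
    tally <- stats::setNames(rep(0L, n_pairs), seq_len(n_pairs))
    return(structure(list(result = NULL, tally = tally, n_deg = 0L,
                          n_synchronized = 0L, fraction_synchronized = NaN,
                          group_p = group_p, correlations = corr),
                     class = "pibs_sync_pipeline"))
  }
  sub <- expr[deg_set, , drop = FALSE]
  attr(sub, "scale") <- "linear"
  dist_obj <- gene_pair_distances(sub, pairing, epsilon)
  sync <- gene_sync_test(dist_obj, alpha = alpha, mode = mode,
                         n_mc = n_mc, seed = seed)
  bi <- sync_baseline(dist_obj)
  res <- assign_sync_pairs(dist_obj, sync, bi)
  tally <- stats::setNames(
    vapply(seq_len(n_pairs),
           function(k) sum(res$genes$n_pairs == k & res$genes$is_synchronized),
           integer(1)),
    seq_len(n_pairs))
  n_sync <- sum(res$genes$is_synchronized)
  structure(list(
    result = res, tally = tally, n_deg = length(deg_set),
    n_synchronized = n_sync,
    fraction_synchronized = 100 * n_sync / length(deg_set),
    group_p = group_p, correlations = corr
  ), class = "pibs_sync_pipeline")
}

#' Most variable genes
#'
#' Ranks genes by the standard deviation of their log2 TMM values across
#' all samples and keeps the top fraction (`floor(fraction * n)` genes;
#' ties broken lexicographically by gene id for determinism).
#'
#' @param log_expr Log2-scale expression matrix.
#' @param fraction Fraction in (0, 1].
#' @return Character vector of gene ids in the input row order.
#' @export
top_variable_genes <- function(log_expr, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  sds <- apply(log_expr, 1L, stats::sd)
  n_keep <- floor(fraction * nrow(log_expr))
  ord <- order(-sds, rownames(log_expr))
  keep <- sort(ord[seq_len(n_keep)])
  rownames(log_expr)[keep]
}

#' Sister-leaf pair co-clustering score
#'
#' Hierarchically clusters one group's samples (distance 1 - Pearson r over
#' genes, average linkage) and scores what fraction of fighting pairs have
#' their two members as sister leaves, i.e. merged with each other before
#' either joins any other sample. A score of 1 reproduces "every pair
#' clusters together".
#'
#' @param log_expr Log2-scale expression matrix.
#' @param design Sample design.
#' @param group Fighting group label.
#' @param genes Optional gene subset (e.g. from [top_variable_genes()]).
#' @param linkage Agglomeration method for [stats::hclust()].
#' @return List with `score`, `n_pairs`, `sister` (named logical per
#'   pair), `tree` (the `hclust` object) and `phylo` (an [ape::as.phylo]
#'   tree, writable as Newick via [ape::write.tree]).
#' @export
pair_coclustering <- function(log_expr, design, group, genes = NULL,
                              linkage = "average") {
  d <- design[design$group == group & !is.na(design$pair_id), , drop = FALSE]
  pairs <- split(d$sample_id, d$pair_id)
  if (length(pairs) < 2) stop("need at least 2 pairs in the group")
  x <- log_expr[, d$sample_id, drop = FALSE]
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant sample(s): ", paste(colnames(x)[sds == 0], collapse = ", "))
  hc <- stats::hclust(stats::as.dist(1 - stats::cor(x)), method = linkage)
  # sister leaves: a merge row joining two singletons
  leaf_merges <- hc$merge[hc$merge[, 1] < 0 & hc$merge[, 2] < 0, , drop = FALSE]
  sister_sets <- apply(leaf_merges, 1L, function(m) sort(hc$labels[-m]),
                       simplify = FALSE)
  sister <- vapply(pairs, function(p)
    any(vapply(sister_sets, function(s) identical(s, sort(p)), logical(1))),
    logical(1))
  list(score = mean(sister), n_pairs = length(pairs), sister = sister,
       tree = hc, phylo = ape::as.phylo(hc))
}
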