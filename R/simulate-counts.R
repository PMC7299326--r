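#' Build the fighting-experiment sample design
#'
#' Lays out the three-group design of the study: a set of non-fighting
#' baseline individuals (group `B`) and, for each of the two fight durations
#' (`D20`, 20-min fight; `D60`, 60-min fight), a number of fighting pairs
#' contributing two opponents each.
#'
#' @param n_baseline Number of non-fighting baseline fish (default 5).
#' @param n_pairs_per_group Number of fighting pairs in each of D20 and D60
#'   (default 5).
#' @return A data frame with one row per sample and columns `sample_id`,
#'   `group` (one of `"B"`, `"D20"`, `"D60"`), `pair_id` (`NA` for baseline
#'   fish) and `fish_id` (1 or 2 within a pair).
#' @examples
#' d <- simulate_design(5, 5)   # 25 samples: 5 B + 10 D20 + 10 D60
#' table(d$group)
#' @export
simulate_design <- function(n_baseline = 5, n_pairs_per_group = 5) {
  stopifnot(length(n_baseline) == 1L, length(n_pairs_per_group) == 1L)
  if (!is.finite(n_baseline) || n_baseline < 1 || n_baseline != round(n_baseline))
    stop("n_baseline must be a positive integer")
  if (!is.finite(n_pairs_per_group) || n_pairs_per_group < 1 ||
      n_pairs_per_group != round(n_pairs_per_group))
    stop("n_pairs_per_group must be a positive integer")
  base <- data.frame(
    sample_id = paste0("B", seq_len(n_baseline)),
    group = "B", pair_id = NA_character_, fish_id = NA_integer_,
    stringsAsFactors = FALSE
  )
  one_group <- function(g) {
    pid <- rep(seq_len(n_pairs_per_group), each = 2L)
    fid <- rep(1:2, n_pairs_per_group)
    data.frame(
      sample_id = paste0(g, "_", pid, fid),
      group = g, pair_id = paste0(g, "_", pid), fish_id = fid,
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(base, one_group("D20"), one_group("D60"))
  rownames(out) <- NULL
  out
}

#' Parameters for the count simulator
#'
#' Collects and validates the parameters of the negative-binomial count
#' simulator. Defaults describe a desk-scale version of the study: 2,000
#' genes (scalable to the study's 23,306), 5 baseline fish and 5 pairs per
#' fighting group, with a minority of genes responding to the fight and a
#' subset of those carrying a pair-shared ("synchronized") effect whose
#' weight grows from the D20 to the D60 group.
#'
#' @param n_genes Number of genes.
#' @param n_baseline,n_pairs_per_group Design dimensions (see
#'   [simulate_design()]).
#' @param baseline_logmean_mu,baseline_logmean_sigma Mean and sd of the
#'   per-gene baseline expression level on the log2 scale.
#' @param dispersion_range Range for the per-gene NB dispersion phi
#'   (variance = mu + phi * mu^2), drawn log-uniformly; a length-1 value
#'   fixes phi for all genes.
#' @param library_size_mean,library_size_cv Mean and coefficient of
#'   variation of the per-sample library size (lognormal).
#' @param frac_responsive Fraction of genes with a fight response.
#' @param frac_synchronized_of_responsive Fraction of responsive genes whose
#'   fight effect is pair-shared.
#' @param lfc_mu,lfc_sigma Mean and sd of the log2 fold change of the fight
#'   response.
#' @param sigma_pair Sd of the pair-shared log2 effect.
#' @param sigma_fish Sd of the fish-specific log2 effect.
#' @param sync_weight_d20,sync_weight_d60 Weight in \[0,1\] of the
#'   pair-shared component for synchronized genes in each group; must
#'   satisfy `sync_weight_d20 <= sync_weight_d60` (synchrony strengthens
#'   with fight duration).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A validated list of class `"pibs_sim_params"`.
#' @export
sim_params <- function(n_genes = 2000,
                       n_baseline = 5, n_pairs_per_group = 5,
                       baseline_logmean_mu = 5, baseline_logmean_sigma = 2,
                       dispersion_range = c(0.05, 0.2),
                       library_size_mean = 5e5, library_size_cv = 0.2,
                       frac_responsive = 0.10,
                       frac_synchronized_of_responsive = 0.65,
                       lfc_mu = 2.5, lfc_sigma = 1,
                       sigma_pair = 2.5, sigma_fish = 0.5,
                       sync_weight_d20 = 0.3, sync_weight_d60 = 0.9,
                       seed = NULL) {
  p <- list(
    n_genes = n_genes, n_baseline = n_baseline,
    n_pairs_per_group = n_pairs_per_group,
    baseline_logmean_mu = baseline_logmean_mu,
    baseline_logmean_sigma = baseline_logmean_sigma,
    dispersion_range = rep(dispersion_range, length.out = 2L),
    library_size_mean = library_size_mean, library_size_cv = library_size_cv,
    frac_responsive = frac_responsive,
    frac_synchronized_of_responsive = frac_synchronized_of_responsive,
    lfc_mu = lfc_mu, lfc_sigma = lfc_sigma,
    sigma_pair = sigma_pair, sigma_fish = sigma_fish,
    sync_weight_d20 = sync_weight_d20, sync_weight_d60 = sync_weight_d60,
    seed = seed
  )
  num <- p[setdiff(names(p), "seed")]
  if (!all(vapply(num, function(x) all(is.finite(x)), logical(1))))
    stop("all simulation parameters must be finite")
  stopifnot(
    p$n_genes >= 1,
    all(p$dispersion_range > 0),
    p$library_size_mean > 0, p$library_size_cv >= 0,
    p$frac_responsive >= 0, p$frac_responsive <= 1,
    p$frac_synchronized_of_responsive >= 0,
    p$frac_synchronized_of_responsive <= 1,
    p$sigma_pair >= 0, p$sigma_fish >= 0,
    p$sync_weight_d20 >= 0, p$sync_weight_d20 <= 1,
    p$sync_weight_d60 >= 0, p$sync_weight_d60 <= 1
  )
  if (p$sync_weight_d20 > p$sync_weight_d60)
    stop("sync_weight_d20 must be <= sync_weight_d60")
  class(p) <- "pibs_sim_params"
  p
}

#' Simulate a gene-by-sample count matrix with pair-shared effects
#'
#' Draws counts from a negative-binomial model (variance = mu + phi * mu^2).
#' Per gene g and sample s the relative expression is
#' `log2 q_gs = log2 lambda_g + fight * LFC_g + w * u_(g,pair(s)) +
#' (1 - w) * e_(g,s)` for responsive genes, where `u` is a pair-shared
#' normal effect, `e` a fish-specific normal effect, and `w` the group's
#' synchrony weight for synchronized genes (0 for non-synchronized
#' responsive genes). Expected counts are `L_s * q_gs / sum_g q_gs` on a
#' lognormal library size `L_s`.
#'
#' @param design Sample design from [simulate_design()].
#' @param params Parameters from [sim_params()].
#' @return A list of class `"pibs_sim"` with elements `counts` (integer
#'   gene-by-sample matrix), `truth` (per-gene data frame with
#'   `is_responsive`, `is_synchronized`, `lfc`), `pair_effects` (gene-by-pair
#'   matrix of shared effects, zero rows for non-synchronized genes),
#'   `design` and `params`.
#' @export
simulate_counts <- function(design, params = sim_params()) {
  stopifnot(inherits(params, "pibs_sim_params"))
  stopifnot(all(c("sample_id", "group", "pair_id") %in% names(design)))
  with_seed(params$seed, {
    ng <- params$n_genes
    ns <- nrow(design)
    genes <- sprintf("g%05d", seq_len(ng))

    lambda_log2 <- stats::rnorm(ng, params$baseline_logmean_mu,
                                params$baseline_logmean_sigma)
    dr <- params$dispersion_range
    phi <- exp(stats::runif(ng, log(dr[1]), log(dr[2])))

    n_resp <- round(params$frac_responsive * ng)
    n_sync <- round(params$frac_synchronized_of_responsive * n_resp)
    responsive <- sort(sample.int(ng, n_resp))
    synchronized <- sort(sample(responsive, n_sync))
    is_resp <- seq_len(ng) %in% responsive
    is_sync <- seq_len(ng) %in% synchronized

    lfc <- numeric(ng)
    lfc[is_resp] <- stats::rnorm(n_resp, params$lfc_mu, params$lfc_sigma)

    pairs <- unique(design$pair_id[!is.na(design$pair_id)])
    u <- matrix(0, ng, length(pairs), dimnames = list(genes, pairs))
    if (n_sync > 0 && length(pairs) > 0)
      u[is_sync, ] <- stats::rnorm(n_sync * length(pairs), 0, params$sigma_pair)

    # fish-specific effect, fight samples only
    e <- matrix(0, ng, ns, dimnames = list(genes, design$sample_id))
    fight <- design$group != "B"
    if (n_resp > 0 && any(fight))
      e[is_resp, fight] <- stats::rnorm(n_resp * sum(fight), 0, params$sigma_fish)

    w_group <- c(B = 0, D20 = params$sync_weight_d20, D60 = params$sync_weight_d60)
    log2q <- matrix(lambda_log2, ng, ns, dimnames = list(genes, design$sample_id))
    for (s in seq_len(ns)) {
      if (!fight[s]) next
      w <- ifelse(is_sync, w_group[[design$group[s]]], 0)
      shared <- if (is.na(design$pair_id[s])) 0 else u[, design$pair_id[s]]
      log2q[, s] <- log2q[, s] + lfc * is_resp + w * shared + (1 - w) * e[, s]
    }

    q <- 2^log2q
    lp <- lnorm_params(params$library_size_mean,
                       params$library_size_cv * params$library_size_mean)
    lib <- stats::rlnorm(ns, lp[1], lp[2])
    mu <- sweep(q, 2L, lib / colSums(q), `*`)
    counts <- matrix(
      stats::rnbinom(ng * ns, mu = mu, size = rep(1 / phi, ns)),
      ng, ns, dimnames = dimnames(mu)
    )
    storage.mode(counts) <- "integer"

    truth <- data.frame(
      gene_id = genes, is_responsive = is_resp, is_synchronized = is_sync,
      lfc = lfc, stringsAsFactors = FALSE
    )
    structure(
      list(counts = counts, truth = truth, pair_effects = u,
           design = design, params = params),
      class = "pibs_sim"
    )
  })
}

#' Write simulated data to plain-text files
#'
#' Writes the count matrix (TSV, first column `gene_id`), the sample design
#' (CSV), and the ground-truth table (TSV) into a directory.
#'
#' @param sim Result of [simulate_counts()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "pibs_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    design = file.path(dir, "design.csv"),
    truth = file.path(dir, "truth.tsv")
  )
  cts <- data.frame(gene_id = rownames(sim$counts), sim$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(cts, paths["counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(sim$design, paths["design"], row.names = FALSE, quote = FALSE)
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read a gene-by-sample count matrix from TSV
#'
#' Expects a header line of sample ids and a first column of gene ids, as
#' written by [write_sim()].
#'
#' @param path TSV file path.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  check_count_matrix(m)
  m
}
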