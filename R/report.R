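#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_all()]. A YAML file
#' with any subset of these fields may be supplied instead of arguments.
#'
#' @param seed Master seed; every random stage derives from it.
#' @param sim Count-simulation parameters ([sim_params()] or a list of
#'   overrides).
#' @param behavior Behavior-simulation parameters ([behavior_params()] or
#'   overrides).
#' @param fdr_max,min_abs_lfc DEG thresholds of the characterization
#'   profile echoed into the report.
#' @param alpha Per-gene synchrony significance level.
#' @param mode Permutation mode for the synchrony tests.
#' @param n_mc Monte-Carlo assignments when `mode = "monte_carlo"`.
#' @param top_fraction Variable-gene fraction used for pair co-clustering.
#' @param window_width,window_step Behavior window grid (minutes).
#' @param n_annotation_terms Number of synthetic annotation terms for the
#'   over-representation stage.
#' @return List of class `"pibs_config"`.
#' @export
pipeline_config <- function(seed = 1,
                            sim = list(), behavior = list(),
                            fdr_max = 0.05, min_abs_lfc = 2,
                            alpha = 0.05, mode = "exact_rank", n_mc = 10000,
                            top_fraction = 0.1,
                            window_width = 2, window_step = 1,
                            n_annotation_terms = 20) {
  stopifnot(fdr_max > 0, fdr_max <= 1, min_abs_lfc >= 0,
            alpha > 0, alpha < 1, top_fraction > 0, top_fraction <= 1,
            window_width > 0, window_step > 0)
  if (!inherits(sim, "pibs_sim_params"))
    sim <- do.call(sim_params, sim)
  if (!inherits(behavior, "pibs_behavior_params"))
    behavior <- do.call(behavior_params, behavior)
  structure(list(seed = seed, sim = sim, behavior = behavior,
                 fdr_max = fdr_max, min_abs_lfc = min_abs_lfc, alpha = alpha,
                 mode = mode, n_mc = n_mc, top_fraction = top_fraction,
                 window_width = window_width, window_step = window_step,
                 n_annotation_terms = n_annotation_terms),
            class = "pibs_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments (`sim` and `behavior` as nested maps).
#' @return List of class `"pibs_config"`.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

# stable polynomial hash of the configuration for provenance stamping
config_hash <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "")
  h <- 0
  for (v in utf8ToInt(txt)) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", h)
}

report_schema_version <- "1.0"

#' Run the full synchronization pipeline on simulated data
#'
#' Executes simulate -> normalize -> differential expression (both
#' contrasts, both threshold profiles) -> per-group synchronization ->
#' behavior summaries -> over-representation, and returns one
#' machine-readable report with the study's bookkeeping quantities: DEG
#' counts per contrast, the Venn partition of the two characterization DEG
#' lists with its hypergeometric overlap p, the paired-vs-unpaired
#' correlation test p per fighting group, synchronized-gene counts with the
#' tally by number of pairs, pair co-clustering scores, and per-pair
#' behavioral summaries. Deterministic under a fixed configuration seed.
#'
#' @param config A `"pibs_config"` (see [pipeline_config()]) or the path
#'   to a YAML configuration.
#' @return A nested list (the report), including `schema_version`,
#'   `config_hash` and `seed`.
#' @export
run_all <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pibs_config"))
  run_all_impl(config)
}

run_all_impl <- function(config) {
  sp <- config$sim
  sp$seed <- config$seed
  design <- simulate_design(sp$n_baseline, sp$n_pairs_per_group)
  sim <- simulate_counts(design, sp)

  kept <- filter_low_expression(sim$counts)
  expr <- tmm_values(kept)
  lexpr <- log_transform(expr)

  groups <- c("D20", "D60")
  samples_of <- function(g) design$sample_id[design$group == g]
  de <- lapply(groups, function(g)
    de_test(lexpr, kept, samples_of("B"), samples_of(g)))
  names(de) <- groups

  deg_char <- lapply(de, select_degs, profile = "characterization")
  deg_sync <- lapply(de, select_degs, profile = "sync_input")
  venn <- venn_partition(deg_char$D20, deg_char$D60)
  hyp <- if (venn$both > 0)
    overlap_hypergeometric(length(unique(deg_char$D20)),
                           length(unique(deg_char$D60)),
                           venn$both, nrow(kept))
  else list(p = 1, log10_p = 0)

  sync <- lapply(groups, function(g)
    sync_pipeline(sim$counts, design, g, deg_sync[[g]],
                  alpha = config$alpha, mode = config$mode,
                  n_mc = config$n_mc, seed = config$seed))
  names(sync) <- groups

  coclust <- lapply(groups, function(g) {
    tv <- top_variable_genes(lexpr, config$top_fraction)
    pair_coclustering(lexpr, design, g, genes = tv)$score
  })
  names(coclust) <- groups

  bp <- config$behavior
  pair_ids <- unique(design$pair_id[design$group == "D60"])
  behavior <- lapply(seq_along(pair_ids), function(i) {
    b <- bp; b$seed <- config$seed + i
    bb <- simulate_behavior(pair_ids[i], b)
    s1 <- window_series(bb$events, 1, "bite_strike", config$window_width,
                        config$window_step)
    s2 <- window_series(bb$events, 2, "bite_strike", config$window_width,
                        config$window_step)
    ml <- mouthlock_summary(bb$events)
    list(pair_id = pair_ids[i],
         first_occurrences = as.list(first_occurrences(bb$events)),
         mouthlock = ml,
         bite_synchrony = tryCatch(behavior_synchrony(s1, s2),
                                   error = function(e) NA_real_),
         n_violations = nrow(interval_check(bb$events)))
  })

  # synthetic annotation: random gene groups over the expressed universe
  universe <- rownames(kept)
  ann <- with_seed(config$seed + 999, {
    terms <- lapply(seq_len(config$n_annotation_terms), function(i)
      sample(universe, max(5, round(length(universe) / 50))))
    names(terms) <- sprintf("T%03d", seq_along(terms))
    terms
  })
  enrich <- ora(intersect(deg_sync$D60, universe), ann, universe)

  list(
    schema_version = report_schema_version,
    seed = config$seed,
    config_hash = config_hash(config),
    thresholds = list(fdr_max = config$fdr_max,
                      min_abs_lfc = config$min_abs_lfc,
                      alpha = config$alpha),
    n_genes_expressed = nrow(kept),
    deg_counts = list(
      characterization = lapply(deg_char, length),
      sync_input = lapply(deg_sync, length)
    ),
    venn = venn,
    overlap_log10_p = hyp$log10_p,
    sync = lapply(sync, function(s) list(
      group_p = s$group_p,
      n_deg = s$n_deg,
      n_synchronized = s$n_synchronized,
      fraction_synchronized = round(s$fraction_synchronized, 1),
      tally = as.list(s$tally)
    )),
    coclustering_score = coclust,
    behavior = behavior,
    enrichment = list(n_terms_tested = nrow(enrich),
                      n_significant = sum(enrich$significant))
  )
}

#' Write a pipeline report to JSON
#'
#' @param report Result of [run_all()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a pipeline report from JSON
#'
#' @param path JSON written by [write_report()].
#' @return The report list.
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(rep$schema_version) ||
      !identical(rep$schema_version, report_schema_version))
    stop("unknown report schema version: ",
         rep$schema_version %||% "<missing>")
  rep
}
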