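make_log_expr <- function(mat) {
  attr(mat, "scale") <- "log2"
  mat
}

test_that("logFC is the group-mean difference and constant genes get p = 1", {
  m <- matrix(8, 3, 6, dimnames = list(paste0("g", 1:3),
                                       c(paste0("a", 1:3), paste0("b", 1:3))))
  m[2, 4:6] <- 10                           # means 8 vs 10 -> logFC 2
  m[3, ] <- c(5, 6, 7, 9, 9.5, 10.5)
  lx <- make_log_expr(m)
  de <- de_test(lx, NULL, paste0("a", 1:3), paste0("b", 1:3))
  expect_equal(de$logFC, unname(c(0, 2, mean(m[3, 4:6]) - mean(m[3, 1:3]))))
  expect_equal(de$p_value[1], 1)            # identical in both groups
  expect_true(de$constant[1])
  expect_equal(de$direction[2], "up")
  expect_error(de_test(lx, NULL, c("a1", "a2"), c("a2", "b1")), "overlap")
  expect_error(de_test(lx, NULL, "a1", paste0("b", 1:3)), ">= 2 samples")
})

test_that("p-value ranking recovers true responders (AUROC > 0.9)", {
  design <- simulate_design(5, 5)
  params <- sim_params(n_genes = 1000, frac_responsive = 0.1,
                       frac_synchronized_of_responsive = 0,
                       lfc_mu = 3, lfc_sigma = 0, sigma_pair = 0,
                       sigma_fish = 0.3, dispersion_range = c(0.1, 0.1),
                       seed = 55)
  sim <- simulate_counts(design, params)
  kept <- filter_low_expression(sim$counts)
  lx <- log_transform(tmm_values(kept))
  de <- de_test(lx, kept, design$sample_id[design$group == "B"],
                design$sample_id[design$group == "D60"])
  truth <- sim$truth$is_responsive[match(de$gene_id, sim$truth$gene_id)]
  # AUROC by the rank-sum identity
  r <- rank(-de$p_value)
  auroc <- (sum(r[truth]) - sum(truth) * (sum(truth) + 1) / 2) /
    (sum(truth) * sum(!truth))
  expect_gt(auroc, 0.9)
})

test_that("the NB likelihood-ratio method behaves on a strong toy effect", {
  set.seed(10)
  base <- exp(runif(60, 3, 6))
  cts <- cbind(matrix(rnbinom(60 * 4, mu = base, size = 10), 60, 4),
               matrix(rnbinom(60 * 4, mu = base, size = 10), 60, 4))
  cts[1:5, 5:8] <- rnbinom(20, mu = 8 * base[1:5], size = 10)
  dimnames(cts) <- list(paste0("g", 1:60), paste0("s", 1:8))
  storage.mode(cts) <- "integer"
  lx <- log_transform(as_linear(cpm(cts)))
  de <- de_test(lx, cts, paste0("s", 1:4), paste0("s", 5:8), method = "nb_lrt")
  expect_true(all(de$fdr[1:5] < 0.05))
  expect_gt(min(de$p_value[6:60]), min(de$p_value[1:5]))
})

test_that("BH adjustment equals the brute-force step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(99)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_fdr(p), bh_brute(p))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DEG selection applies the two printed threshold profiles", {
  de <- data.frame(
    gene_id = paste0("g", 1:5),
    logFC = c(2.5, 0.5, -3, 2.1, 1),
    p_value = c(1e-4, 1e-4, 1e-4, 0.2, 1e-4),
    fdr = c(0.04, 0.04, 0.01, 0.4, 0.051),
    stringsAsFactors = FALSE
  )
  expect_setequal(select_degs(de, "characterization"), c("g1", "g3"))
  expect_setequal(select_degs(de, "sync_input"), c("g1", "g2"))
  prov <- attr(select_degs(de, "characterization"), "provenance")
  expect_equal(prov$min_abs_lfc, 2)
  custom <- select_degs(de, "custom", fdr_max = 0.06, min_abs_lfc = 0,
                        direction = "down")
  expect_setequal(custom, "g3")
})

test_that("venn partition reproduces the study bookkeeping and set algebra", {
  universe <- paste0("g", 1:3000)
  both <- universe[1:295]
  a <- c(both, universe[296:(296 + 223 - 1)])          # |A| = 518
  b <- c(both, universe[600:(600 + 564 - 1)])          # |B| = 859
  v <- venn_partition(a, b)
  expect_equal(v, list(a_only = 223, b_only = 564, both = 295, union = 1082))
  expect_equal(venn_partition(a, a), list(a_only = 0, b_only = 0,
                                          both = 518, union = 518))
  expect_equal(venn_partition(a[1:5], b[300:310])$both, 0)
})

test_that("hypergeometric overlap matches enumeration and stays finite in log space", {
  h <- overlap_hypergeometric(5, 5, 5, 10)
  expect_equal(h$p, 1 / 252)
  expect_equal(overlap_hypergeometric(7, 9, 0, 50)$p, 1)
  set.seed(12)
  for (i in 1:25) {
    N <- sample(20:2000, 1)
    ka <- sample(1:(N - 1), 1); kb <- sample(1:(N - 1), 1)
    ov <- sample(0:min(ka, kb), 1)
    h <- overlap_hypergeometric(ka, kb, ov, N)
    expect_equal(h$p, hyper_brute(ka, kb, ov, N), tolerance = 1e-10)
  }
  extreme <- overlap_hypergeometric(518, 859, 295, 23306)
  expect_lt(extreme$log10_p, -250)
  expect_true(is.finite(extreme$log10_p))
  expect_error(overlap_hypergeometric(5, 5, 6, 10), "overlap")
})

test_that("projection categories follow the two significance calls", {
  g <- paste0("g", 1:6)
  de_a <- data.frame(gene_id = g, logFC = c(3, 3, -3, 0.1, 3, -4),
                     p_value = 0.001, fdr = c(0.01, 0.01, 0.01, 0.9, 0.9, 0.01),
                     stringsAsFactors = FALSE)
  de_b <- data.frame(gene_id = g, logFC = c(3, -3, -3, 0.1, 3, 3),
                     p_value = 0.001, fdr = c(0.01, 0.01, 0.9, 0.9, 0.01, 0.01),
                     stringsAsFactors = FALSE)
  pc <- projection_categories(de_a, de_b)
  expect_equal(pc$table$category, c("both", "both", "a_only", "ns",
                                    "b_only", "both"))
  expect_equal(pc$table$pattern[1], "up-up")
  expect_equal(pc$table$category[4], "ns")
  expect_equal(pc$n_discordant, 2)  # g2 up->down, g6 down->up
  expect_error(projection_categories(de_a, de_b[c(2:6, 1), ]), "universe")
})
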