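test_that("dyad enumeration counts paired and unpaired combinations", {
  d <- simulate_design(5, 5)
  pr <- enumerate_sample_pairs(d, "D60")
  expect_equal(nrow(pr), 45)
  expect_equal(sum(pr$is_paired), 5)
  expect_equal(sum(!pr$is_paired), 40)
  # every sample appears in n - 1 dyads
  apps <- table(c(pr$sample_1, pr$sample_2))
  expect_true(all(apps == 9))

  d2 <- simulate_design(1, 2)
  pr2 <- enumerate_sample_pairs(d2, "D20")
  expect_equal(c(nrow(pr2), sum(pr2$is_paired)), c(6, 2))
  d3 <- simulate_design(1, 1)
  pr3 <- enumerate_sample_pairs(d3, "D20")
  expect_equal(c(nrow(pr3), sum(pr3$is_paired)), c(1, 1))
  expect_error(enumerate_sample_pairs(d, "D90"), "not present")
})

test_that("dyad correlations are Pearson r over genes", {
  m <- matrix(c(1, 2, 3, 1, 2, 3, 3, 2, 1), 3, 3,
              dimnames = list(paste0("g", 1:3), c("a", "b", "c")))
  attr(m, "scale") <- "log2"
  pairing <- data.frame(sample_1 = c("a", "a"), sample_2 = c("b", "c"),
                        is_paired = c(TRUE, FALSE), stringsAsFactors = FALSE)
  r <- sample_correlations(m, pairing)$r
  expect_equal(r, c(1, -1))
  m2 <- m; m2[, 2] <- 5
  expect_error(sample_correlations(m2, pairing), "zero-variance.*b")
})

test_that("expression distances are |log10| ratios, symmetric, zero at equality", {
  expr <- as_linear(rbind(g1 = c(5, 5), g2 = c(100, 10), g3 = c(0, 10)))
  colnames(expr) <- c("a", "b")
  pairing <- data.frame(sample_1 = "a", sample_2 = "b", is_paired = TRUE,
                        stringsAsFactors = FALSE)
  d <- gene_pair_distances(expr, pairing, epsilon = 1e-9)
  expect_equal(unname(d$distances["g1", 1]), 0)
  expect_equal(unname(d$distances["g2", 1]), 1, tolerance = 1e-6)
  # symmetry under swapping the two samples
  pairing_sw <- data.frame(sample_1 = "b", sample_2 = "a", is_paired = TRUE,
                           stringsAsFactors = FALSE)
  d_sw <- gene_pair_distances(expr, pairing_sw, epsilon = 1e-9)
  expect_equal(unname(d$distances), unname(d_sw$distances))
  # default epsilon: half the smallest positive value
  d_def <- gene_pair_distances(expr, pairing)
  expect_equal(d_def$epsilon, 2.5)
  expect_error(gene_pair_distances(log_transform(expr), pairing), "linear")
})

test_that("per-gene synchrony test flags extreme configurations correctly", {
  d <- simulate_design(1, 5)
  pairing <- enumerate_sample_pairs(d, "D60")
  dist_mat <- rbind(
    g1 = ifelse(pairing$is_paired, 0, 1),   # paired clearly closer
    g2 = rep(0.3, 45)                       # no signal
  )
  obj <- structure(list(distances = dist_mat, pairing = pairing,
                        epsilon = 1e-6), class = "pibs_distances")
  res <- gene_sync_test(obj)
  expect_equal(res$p[1], 1 / choose(45, 5))
  expect_true(res$is_synchronized[1])
  expect_equal(res$p[2], 1)
  expect_false(res$is_synchronized[2])
})

test_that("the baseline is the 25th percentile of unpaired distances", {
  d <- simulate_design(1, 5)
  pairing <- enumerate_sample_pairs(d, "D60")
  up <- which(!pairing$is_paired)
  dm <- matrix(0, 3, 45, dimnames = list(paste0("g", 1:3), NULL))
  dm[1, up] <- sample(1:40)                 # order must not matter
  dm[2, up] <- 7
  dm[3, up] <- c(rep(0, 3), 4, rep(0.123, 36))  # convention on small n values
  obj <- structure(list(distances = dm, pairing = pairing, epsilon = 1e-6),
                   class = "pibs_distances")
  b <- sync_baseline(obj)
  expect_equal(unname(b[1]), 10.75)         # h = (40 - 1) * 0.25 + 1
  expect_equal(unname(b[2]), 7)
  expect_equal(unname(sync_baseline(structure(list(
    distances = matrix(c(rep(0, 5), 0, 0, 0, 4), 1,
                       dimnames = list("g", NULL)),
    pairing = data.frame(is_paired = rep(c(TRUE, FALSE), c(5, 4)))),
    class = "pibs_distances"))), 0)
})

test_that("pair assignment uses the strict D_ij < B_i rule", {
  d <- simulate_design(1, 5)
  pairing <- enumerate_sample_pairs(d, "D60")
  dm <- matrix(1, 2, 45, dimnames = list(c("g1", "g2"), NULL))
  dm[1, pairing$is_paired] <- c(0, 0.5, 0.5, 0.2, 0)  # baseline will be 0.5
  dm[1, !pairing$is_paired] <- rep(c(0.5, 10), c(12, 28))
  dm[2, ] <- 0.3
  obj <- structure(list(distances = dm, pairing = pairing, epsilon = 1e-6),
                   class = "pibs_distances")
  sync <- data.frame(gene_id = c("g1", "g2"), p = c(0.001, 1),
                     is_synchronized = c(TRUE, FALSE))
  b <- sync_baseline(obj)
  expect_equal(unname(b[1]), 0.5)
  res <- assign_sync_pairs(obj, sync, b)
  # D = 0.5 equals B exactly -> NOT synchronized in those pairs
  expect_equal(unname(res$pair_flags[1, ]), c(TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(res$genes$n_pairs[1], 3)
  # non-synchronized genes get no flags even where D < B
  expect_false(any(res$pair_flags[2, ]))
  expect_equal(res$genes$n_pairs[2], 0)
})

test_that("the null rejection rate is controlled (conservative) and effects are recovered", {
  # Under the generative null (no pair-shared effect) the test is valid but
  # conservative: the five paired dyads are sample-disjoint whereas the
  # permutation null treats all 45 correlated distances as exchangeable.
  # Empirically the rate sits near 0.034 at alpha = 0.05.
  design <- simulate_design(5, 5)
  null_params <- sim_params(n_genes = 1000, sigma_pair = 0, seed = 31)
  sim <- simulate_counts(design, null_params)
  kept <- filter_low_expression(sim$counts)
  expr <- tmm_values(kept)
  pairing <- enumerate_sample_pairs(design, "D60")
  dobj <- gene_pair_distances(expr, pairing)
  res <- gene_sync_test(dobj)
  rate <- mean(res$is_synchronized)
  expect_gt(rate, 0.015)
  expect_lt(rate, 0.055)
  # with exchangeable labels the same machinery is nominally calibrated
  lab <- rep(FALSE, 45); lab[c(3, 11, 19, 27, 44)] <- TRUE
  p_arb <- apply(dobj$distances, 1L, function(v)
    permutation_test(v, lab, "less", "exact_rank"))
  expect_lt(abs(mean(p_arb < 0.05) - 0.05),
            2 * sqrt(0.05 * 0.95 / nrow(kept)) + 0.01)

  # recovery: defaults are the strong-synchrony (D60) regime
  qs <- quick_sim(n_genes = 800, seed = 61)
  kept <- filter_low_expression(qs$sim$counts)
  lx <- log_transform(tmm_values(kept))
  de <- de_test(lx, kept, qs$design$sample_id[qs$design$group == "B"],
                qs$design$sample_id[qs$design$group == "D60"])
  degs <- select_degs(de, "sync_input")
  sp <- sync_pipeline(qs$sim$counts, qs$design, "D60", degs, seed = 61)
  truth <- qs$sim$truth[match(degs, qs$sim$truth$gene_id), ]
  called <- sp$result$genes$is_synchronized
  expect_gt(mean(called[truth$is_synchronized]), 0.7)
  expect_gt(mean(!called[!truth$is_synchronized]), 0.9)
  # bookkeeping: tally counts only synchronized genes, fraction consistent
  expect_equal(sum(sp$tally), sum(called & sp$result$genes$n_pairs > 0))
  expect_equal(sp$fraction_synchronized,
               100 * sp$n_synchronized / sp$n_deg)
})

test_that("the group-level correlation test is calibrated under an exchangeable null", {
  # paired and unpaired r drawn from the same distribution: p is uniform,
  # so the rejection rate at alpha = 0.05 stays inside the binomial CI
  d <- simulate_design(1, 5)
  pairing <- enumerate_sample_pairs(d, "D60")
  n_sim <- 400
  rej <- withr::with_seed(303, replicate(n_sim, {
    pairing$r <- runif(45, 0.5, 1)
    group_sync_test(pairing) < 0.05
  }))
  expect_lt(abs(mean(rej) - 0.05), 2 * sqrt(0.05 * 0.95 / n_sim) + 0.01)

  # and a strongly synchronized group is detected decisively
  pairing$r <- ifelse(pairing$is_paired, 0.99, 0.90)
  expect_equal(group_sync_test(pairing), 1 / choose(45, 5))
})

test_that("sync_pipeline on an empty DEG set returns an all-zero tally", {
  qs <- quick_sim(n_genes = 120, seed = 5)
  sp <- sync_pipeline(qs$sim$counts, qs$design, "D60", character(0))
  expect_equal(unname(sp$tally), rep(0L, 5))
  expect_equal(sp$n_synchronized, 0L)
  expect_true(is.nan(sp$fraction_synchronized))
  expect_true(sp$group_p >= 0 && sp$group_p <= 1)
})

test_that("top_variable_genes ranks by sd with floor() and deterministic ties", {
  m <- matrix(rnorm(20 * 4), 20, 4,
              dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:4)))
  m[1, ] <- m[1, ] * 10
  attr(m, "scale") <- "log2"
  tv <- top_variable_genes(m, 0.1)           # floor(2) = 2 genes
  expect_length(tv, 2)
  expect_true("g01" %in% tv)
  expect_length(top_variable_genes(m, 1), 20)
  # ties broken lexicographically
  mt <- rbind(gB = c(0, 1, 0, 1), gA = c(0, 1, 0, 1), gC = c(0, 0, 0, 0))
  colnames(mt) <- paste0("s", 1:4); attr(mt, "scale") <- "log2"
  expect_equal(top_variable_genes(mt, 1 / 3), "gA")
  # study-scale arithmetic
  expect_equal(floor(0.5 * 23306), 11653)
  expect_equal(floor(0.1 * 23306), 2330)
})

test_that("pair co-clustering scores sister-leaf pairs", {
  # two pairs with identical within-pair profiles: perfect score
  set.seed(14)
  base <- matrix(rnorm(50 * 2, sd = 2), 50, 2)
  m <- cbind(base[, 1] + rnorm(50, sd = .01), base[, 1] + rnorm(50, sd = .01),
             base[, 2] + rnorm(50, sd = .01), base[, 2] + rnorm(50, sd = .01))
  dimnames(m) <- list(paste0("g", 1:50),
                      c("D60_11", "D60_12", "D60_21", "D60_22"))
  attr(m, "scale") <- "log2"
  design <- simulate_design(1, 2)
  cc <- pair_coclustering(m, design, "D60")
  expect_equal(cc$score, 1)
  expect_s3_class(cc$phylo, "phylo")
  expect_match(ape::write.tree(cc$phylo), "D60_11")

  # i.i.d. profiles: each fish's nearest neighbour is uniform on the other 9,
  # so a pair is sister with probability about 1/9
  score_null <- replicate(150, {
    mm <- matrix(rnorm(40 * 10), 40, 10)
    d <- simulate_design(1, 5)
    dimnames(mm) <- list(paste0("g", 1:40),
                         d$sample_id[d$group == "D60"])
    attr(mm, "scale") <- "log2"
    pair_coclustering(mm, d, "D60")$score
  })
  se <- sqrt(var(score_null) / length(score_null))
  expect_lt(abs(mean(score_null) - 1 / 9), 4 * se + 0.02)
})
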