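# Small fixtures built in code; no files.

toy_counts <- function(x, genes = NULL, samples = NULL) {
  m <- as.matrix(x)
  rownames(m) <- genes %||% paste0("g", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("s", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# linear-scale expression matrix with the attribute the package expects
as_linear <- function(m) {
  attr(m, "scale") <- "linear"
  m
}

# a small simulated study used by several tests
quick_sim <- function(n_genes = 600, seed = 42, ...) {
  design <- simulate_design(5, 5)
  params <- sim_params(n_genes = n_genes, seed = seed, ...)
  list(design = design, sim = simulate_counts(design, params))
}

# brute-force BH step-up, the independent oracle for bh_fdr()
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in seq(m, 1)) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- min(1, running)
  }
  adj
}

# brute-force upper-tail hypergeometric by pmf summation
hyper_brute <- function(size_a, size_b, overlap, universe) {
  k <- overlap:min(size_a, size_b)
  sum(exp(lchoose(size_a, k) + lchoose(universe - size_a, size_b - k) -
            lchoose(universe, size_b)))
}

# brute-force exact rank-sum p by full enumeration (small n only)
ranksum_brute <- function(values, is_group1, alternative) {
  r <- rank(values)
  n <- length(values); n1 <- sum(is_group1)
  ws <- colSums(matrix(r[utils::combn(n, n1)], n1))
  wobs <- sum(r[is_group1])
  p_le <- mean(ws <= wobs + 1e-9)
  p_ge <- mean(ws >= wobs - 1e-9)
  switch(alternative, less = p_le, greater = p_ge,
         two_sided = min(1, 2 * min(p_le, p_ge)))
}
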