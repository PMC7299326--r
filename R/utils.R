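#' @keywords internal
"_PACKAGE"

# Run expr with a temporarily fixed RNG state; restores the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# meanlog/sdlog for a lognormal with the given arithmetic mean and sd
lnorm_params <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  if (sd == 0) return(c(meanlog = log(mean), sdlog = 0))
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

check_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix (genes x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(counts < 0)) stop("counts must be non-negative")
  invisible(counts)
}

expr_scale <- function(x) {
  sc <- attr(x, "scale")
  if (is.null(sc)) "linear" else sc
}

`%||%` <- function(a, b) if (is.null(a)) b else a
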