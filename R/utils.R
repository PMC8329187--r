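# Internal helpers shared across modules.

# Run code with a temporarily fixed RNG state, restoring the caller's
# stream afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Dirichlet draw via normalised gammas; alpha entries equal to 0 give
# structural zeros (taxon absent from the sample).
rdirichlet1 <- function(alpha) {
  x <- numeric(length(alpha))
  pos <- alpha > 0
  g <- rgamma(sum(pos), shape = alpha[pos], rate = 1)
  if (all(g == 0)) g[sample.int(length(g), 1)] <- 1  # degenerate guard
  x[pos] <- g / sum(g)
  x
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same samples,
#' used to score recovery of planted enterotype labels. 1 means identical
#' partitions (up to label permutation), 0 is the expected value under
#' random labelling.
#'
#' @param x,y vectors of cluster labels of equal length.
#' @return a single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) > 0)
  tab <- table(x, y)
  n <- length(x)
  comb2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- comb2(as.vector(tab))
  sum_i <- comb2(rowSums(tab))
  sum_j <- comb2(colSums(tab))
  n2 <- n * (n - 1) / 2
  expected <- sum_i * sum_j / n2
  maxidx <- (sum_i + sum_j) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}

# stop()/warning() with sprintf formatting, no call in the condition
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# check a genes/features x samples numeric matrix with dimnames
check_table <- function(x, what = "abundance table") {
  if (!is.matrix(x) || !is.numeric(x))
    fail("%s must be a numeric matrix (features x samples)", what)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    fail("%s must carry feature rownames and sample colnames", what)
  invisible(x)
}
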