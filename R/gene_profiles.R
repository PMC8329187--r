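# Gene-level profiles: downsizing to common depth, normalisation to
# relative abundance, gene richness, and the baseline prevalence filter.

# multivariate hypergeometric draw: k reads without replacement from
# integer counts x (processed in the order given)
.rmvhyper <- function(x, k) {
  out <- integer(length(x))
  remaining <- sum(x)
  still <- k
  for (j in seq_along(x)) {
    if (still == 0L) break
    remaining <- remaining - x[j]
    out[j] <- rhyper(1, x[j], remaining, still)
    still <- still - out[j]
  }
  out
}

#' Downsize a raw gene count table to a common sequencing depth
#'
#' Each retained sample is a without-replacement (multivariate
#' hypergeometric) subsample of exactly `depth` reads, making per-sample
#' gene richness comparable across sequencing depths. With `n_draws > 1`
#' the per-gene counts are averaged over independent draws (non-integer
#' values, flagged on the result); per-draw richness is retained so
#' [gene_richness()] can report the average number of detected genes over
#' draws. Samples whose total count falls below `depth` are dropped with a
#' warning. Genes are processed internally in sorted-id order, so the
#' result is invariant to the row order of the input.
#'
#' @param genes integer gene x sample count matrix (raw).
#' @param depth target reads per sample.
#' @param seed integer seed.
#' @param n_draws number of independent subsamples to average (default 30,
#'   common quantitative-metagenomics practice).
#' @return downsized count matrix with attributes `downsized_depth`,
#'   `n_draws`, `draw_richness` (draws x samples) and `normalised = FALSE`.
#' @export
downsize_genes <- function(genes, depth, seed = 1L, n_draws = 30L) {
  check_table(genes, "gene table")
  if (depth <= 0) fail("downsize_genes: depth must be positive")
  totals <- colSums(genes)
  keep <- totals >= depth
  if (!any(keep)) fail("downsize_genes: all samples fall below depth %d", depth)
  if (any(!keep))
    warn("downsize_genes: dropping %d sample(s) below depth %d: %s",
         sum(!keep), depth, paste(colnames(genes)[!keep], collapse = ", "))
  genes <- genes[, keep, drop = FALSE]
  ord <- order(rownames(genes))
  out <- matrix(0, nrow(genes), ncol(genes), dimnames = dimnames(genes))
  draw_rich <- matrix(0L, n_draws, ncol(genes),
                      dimnames = list(NULL, colnames(genes)))
  with_seed(seed, {
    for (j in seq_len(ncol(genes))) {
      acc <- numeric(nrow(genes))
      xj <- genes[ord, j]
      for (d in seq_len(n_draws)) {
        sub <- .rmvhyper(xj, depth)
        acc <- acc + sub
        draw_rich[d, j] <- sum(sub >= 1L)
      }
      out[ord, j] <- acc / n_draws
    }
  })
  structure(out, downsized_depth = depth, n_draws = n_draws,
            draw_richness = draw_rich, normalised = FALSE)
}

#' Normalise a count table to per-sample relative abundances
#'
#' Divides every column by its total so columns sum to 1.
#'
#' @param genes count matrix (features x samples).
#' @return matrix of relative abundances with attribute `normalised = TRUE`.
#' @export
normalise_genes <- function(genes) {
  check_table(genes, "gene table")
  totals <- colSums(genes)
  zero <- totals <= 0
  if (any(zero))
    fail("normalise_genes: zero-total sample(s): %s",
         paste(colnames(genes)[zero], collapse = ", "))
  out <- sweep(genes, 2, totals, "/")
  attrs <- attributes(genes)
  structure(out, downsized_depth = attrs$downsized_depth,
            n_draws = attrs$n_draws, normalised = TRUE)
}

#' Gene richness per sample
#'
#' Number of genes with at least one mapped read per sample, computed on a
#' downsized raw count table so depths are comparable. When the table was
#' downsized with multiple draws, the average richness over draws is
#' reported (matching the definition of gene count as the average number
#' of detected genes per sample).
#'
#' @param genes downsized count matrix from [downsize_genes()].
#' @return named numeric vector of per-sample richness.
#' @export
gene_richness <- function(genes) {
  check_table(genes, "gene table")
  if (isTRUE(attr(genes, "normalised")))
    fail("gene_richness: richness is defined on downsized raw counts, not normalised abundances")
  if (is.null(attr(genes, "downsized_depth")))
    warn("gene_richness: table is not flagged as downsized; richness values are not comparable across sequencing depths")
  dr <- attr(genes, "draw_richness")
  if (!is.null(dr) && nrow(dr) > 1L) return(colMeans(dr))
  colSums(genes >= 1)
}

#' Baseline prevalence filter
#'
#' Keeps features whose nonzero prevalence among samples at the reference
#' timepoint is strictly greater than `threshold` (so exactly 20% presence
#' is excluded at the default 0.20 threshold).
#'
#' @param tab feature x sample matrix.
#' @param metadata per-sample metadata with `sample_id` and `timepoint`.
#' @param threshold prevalence threshold in \[0, 1).
#' @param at reference timepoint (default `"T0"`).
#' @return character vector of retained feature ids.
#' @export
prevalence_filter <- function(tab, metadata, threshold = 0.20, at = "T0") {
  check_table(tab, "feature table")
  if (threshold < 0 || threshold >= 1)
    fail("prevalence_filter: threshold must lie in [0, 1)")
  base <- intersect(colnames(tab), metadata$sample_id[metadata$timepoint == at])
  if (!length(base))
    fail("prevalence_filter: no samples at timepoint '%s' in the table", at)
  prev <- rowMeans(tab[, base, drop = FALSE] > 0)
  rownames(tab)[prev > threshold]
}
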