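# Beta-diversity (Bray-Curtis, PCoA, PERMANOVA) and per-feature dynamics
# (log fold change, Cliff's delta).

#' Bray-Curtis dissimilarity
#'
#' `BC(u, v) = sum |u_i - v_i| / sum (u_i + v_i)`, computed pairwise over
#' the columns of an abundance table (0 for identical samples, 1 for
#' disjoint supports).
#'
#' @param tab nonnegative feature x sample matrix.
#' @return a symmetric sample x sample distance matrix with zero diagonal
#'   and attribute `metric = "bray-curtis"`.
#' @export
bray_curtis <- function(tab) {
  check_table(tab, "abundance table")
  if (any(tab < 0)) fail("bray_curtis: negative abundances")
  n <- ncol(tab)
  d <- matrix(0, n, n, dimnames = list(colnames(tab), colnames(tab)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    u <- tab[, i]; v <- tab[, j]
    denom <- sum(u + v)
    if (denom == 0)
      fail("bray_curtis: samples '%s' and '%s' are both all-zero; dissimilarity undefined",
           colnames(tab)[i], colnames(tab)[j])
    d[i, j] <- d[j, i] <- sum(abs(u - v)) / denom
  }
  attr(d, "metric") <- "bray-curtis"
  d
}

#' Principal coordinate analysis (classical scaling)
#'
#' Double-centres `-D^2 / 2`, eigendecomposes, and returns coordinates
#' `eigenvector * sqrt(eigenvalue)` on the axes with positive eigenvalues,
#' ordered by decreasing eigenvalue. Negative eigenvalues (possible for
#' non-Euclidean dissimilarities such as Bray-Curtis) are reported, not
#' silently dropped.
#'
#' @param d symmetric distance matrix.
#' @param n_axes number of axes to return.
#' @return list with `coordinates` (samples x axes), `eigenvalues` (all,
#'   non-increasing) and `relative_eig` (share of the positive part).
#' @export
pcoa <- function(d, n_axes = 2) {
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    fail("pcoa: distance matrix must be symmetric")
  n <- nrow(d)
  A <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- which(e$values > 1e-12)
  if (n_axes > length(pos)) {
    warn("pcoa: only %d positive axes available; truncating from %d", length(pos), n_axes)
    n_axes <- length(pos)
  }
  idx <- pos[seq_len(n_axes)]
  coords <- sweep(e$vectors[, idx, drop = FALSE], 2, sqrt(e$values[idx]), "*")
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(n_axes))
  list(coordinates = coords, eigenvalues = e$values,
       relative_eig = e$values[idx] / sum(e$values[e$values > 0]))
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' One-way pseudo-F from within- and between-group sums of squared
#' distances, with a permutation p-value
#' `(1 + #permuted F >= observed) / (1 + n_perm)` and
#' `R^2 = SS_between / SS_total`.
#'
#' @param d symmetric distance matrix.
#' @param labels group label per sample (in `d`'s order).
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return list with `F`, `R2`, `p`, `n_perm`.
#' @export
permanova <- function(d, labels, n_perm = 999L, seed = 1L) {
  n <- nrow(d)
  stopifnot(length(labels) == n)
  labels <- as.character(labels)
  groups <- unique(labels)
  if (length(groups) < 2) fail("permanova: need at least two groups")
  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- function(lab) {
    s <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      if (length(idx) > 1)
        s <- s + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    s
  }
  k <- length(groups)
  f_stat <- function(lab) {
    sw <- ss_within(lab)
    ((ss_total - sw) / (k - 1)) / (sw / (n - k))
  }
  f_obs <- f_stat(labels)
  sw_obs <- ss_within(labels)
  r2 <- (ss_total - sw_obs) / ss_total
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) f_stat(sample(labels)) >= f_obs, TRUE))
  })
  list(F = f_obs, R2 = r2, p = (1 + exceed) / (1 + n_perm), n_perm = n_perm)
}

#' Cliff's delta effect size
#'
#' `delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (|x| |y|)`; ties contribute
#' zero. Lies in \[-1, 1\] and is antisymmetric in its arguments.
#'
#' @param x,y non-empty numeric vectors.
#' @return a single number.
#' @export
cliffs_delta <- function(x, y) {
  if (!length(x) || !length(y)) fail("cliffs_delta: both samples must be non-empty")
  gt <- sum(outer(x, y, ">"))
  lt <- sum(outer(x, y, "<"))
  (gt - lt) / (length(x) * length(y))
}

# shared pseudocount rule: half the smallest nonzero value in the table
default_pseudocount <- function(tab) {
  nz <- tab[tab > 0]
  if (!length(nz)) fail("pseudocount undefined: table is all zero")
  min(nz) / 2
}

#' Per-feature log fold change between paired timepoints
#'
#' For each subject and feature, `log((a_T12 + eps) / (a_T0 + eps))`
#' (natural log by default; `base` is recorded on the output). The
#' pseudocount `eps` defaults to half the smallest nonzero abundance in
#' the table. Per-arm and pooled means over subjects are reported, along
#' with Cliff's delta of time (T12 values versus T0 values) per feature
#' and arm.
#'
#' @param tab feature x sample abundance matrix (nonnegative).
#' @param metadata per-sample metadata (`sample_id`, `subject`, `arm`,
#'   `timepoint`).
#' @param pseudocount pseudocount; `NULL` for the default rule.
#' @param base logarithm base (`exp(1)` natural, or e.g. 2).
#' @return list with `lfc` (feature x subject matrix of per-subject log
#'   ratios), `summary` (per feature and arm: mean log fold change and
#'   Cliff's delta), `pseudocount`, `base`.
#' @export
log_fold_change <- function(tab, metadata, pseudocount = NULL, base = exp(1)) {
  check_table(tab, "feature table")
  if (any(tab < 0)) fail("log_fold_change: negative abundances")
  if (is.null(pseudocount)) pseudocount <- default_pseudocount(tab)
  md0 <- metadata[metadata$timepoint == "T0", ]
  md1 <- metadata[metadata$timepoint == "T12", ]
  subjects <- intersect(md0$subject, md1$subject)
  s0 <- vapply(subjects, function(s) md0$sample_id[md0$subject == s][1], "")
  s1 <- vapply(subjects, function(s) md1$sample_id[md1$subject == s][1], "")
  ok <- s0 %in% colnames(tab) & s1 %in% colnames(tab)
  subjects <- subjects[ok]; s0 <- s0[ok]; s1 <- s1[ok]
  if (!length(subjects)) fail("log_fold_change: no subjects with both timepoints in the table")
  lfc <- log((tab[, s1, drop = FALSE] + pseudocount) /
             (tab[, s0, drop = FALSE] + pseudocount)) / log(base)
  colnames(lfc) <- subjects
  arm <- vapply(subjects, function(s) md0$arm[md0$subject == s][1], "")
  arms <- sort(unique(arm))
  rows <- list()
  for (f in rownames(tab)) {
    for (a in c(arms, "pooled")) {
      idx <- if (a == "pooled") seq_along(subjects) else which(arm == a)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, arm = a,
        mean_lfc = mean(lfc[f, idx]),
        cliffs_delta = cliffs_delta(tab[f, s1[idx]], tab[f, s0[idx]]),
        n = length(idx), stringsAsFactors = FALSE)
    }
  }
  list(lfc = lfc, summary = do.call(rbind, rows),
       pseudocount = pseudocount, base = base)
}
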