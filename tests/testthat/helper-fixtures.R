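# Shared fixtures and independent oracles for the test suite.

.fixtures <- new.env(parent = emptyenv())

# small, fast cohort reused across test files (generated once per run)
small_cfg <- function(seed = 42L) {
  sim_config(n_subjects = 8, n_mgs = 12, genes_per_mgs = 501,
             n_marker_genes = 20, sequencing_depth = 12000, seed = seed)
}

get_small_catalog <- function() {
  if (is.null(.fixtures$small_catalog))
    .fixtures$small_catalog <- generate_catalog(small_cfg())
  .fixtures$small_catalog
}

get_small_cohort <- function() {
  if (is.null(.fixtures$small_cohort))
    .fixtures$small_cohort <- generate_cohort(small_cfg(), get_small_catalog())
  .fixtures$small_cohort
}

# default-scale study fixtures (used by recovery and acceptance tests)
get_default_catalog <- function() {
  if (is.null(.fixtures$default_catalog))
    .fixtures$default_catalog <- generate_catalog(sim_config(seed = 5L))
  .fixtures$default_catalog
}

get_default_cohort <- function() {
  if (is.null(.fixtures$default_cohort))
    .fixtures$default_cohort <- generate_cohort(sim_config(seed = 5L),
                                                get_default_catalog())
  .fixtures$default_cohort
}

# run one cohort through the gene -> KO -> module -> enrichment chain
run_enrichment_chain <- function(cfg, catalog, category = "aa_synthesis") {
  coh <- generate_cohort(cfg, catalog)
  norm <- normalise_genes(coh$genes)
  kos <- ko_abundance(norm, catalog$gene_ko)
  ma <- module_abundance(kos, catalog$modules)
  dyn <- module_dynamics(ma$abundance, coh$metadata, catalog$modules)
  enrichment_proportion_test(dyn, category)
}

# Fisher exact two-sided p by full enumeration of 2x2 tables with fixed
# margins (hypergeometric probabilities; sum of tables no more probable
# than the observed one).
fisher_exact_enum <- function(m) {
  a <- m[1, 1]
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x) dhyper(x, r1, r2, c1), 0)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up, written independently of p.adjust
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# paired two-arm null metadata (no true effects anywhere)
null_metadata <- function(n_subjects = 50, seed = 1) {
  set.seed(seed)
  subj <- sprintf("N%03d", seq_len(n_subjects))
  arm <- sample(rep(c("IP", "CP"), n_subjects / 2))
  data.frame(
    sample_id = as.vector(t(outer(subj, c("T0", "T12"), paste, sep = "_"))),
    subject = rep(subj, each = 2),
    arm = rep(arm, each = 2),
    timepoint = rep(c("T0", "T12"), n_subjects),
    age = rep(round(rnorm(n_subjects, 48, 10)), each = 2),
    sex = rep(sample(c("M", "F"), n_subjects, TRUE), each = 2),
    stringsAsFactors = FALSE)
}

# null features with a subject random intercept (ICC 0.5)
null_features <- function(md, n_features, seed = 1) {
  set.seed(seed)
  n_sub <- length(unique(md$subject))
  feats <- t(sapply(seq_len(n_features), function(i) {
    u <- rnorm(n_sub, 0, sqrt(0.5))
    as.vector(rbind(u + rnorm(n_sub, 0, sqrt(0.5)),
                    u + rnorm(n_sub, 0, sqrt(0.5))))
  }))
  rownames(feats) <- sprintf("f%04d", seq_len(n_features))
  colnames(feats) <- md$sample_id
  feats
}
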