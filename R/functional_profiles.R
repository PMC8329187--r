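# Functional profiles: gene -> KO -> module abundance with a step-coverage
# rule, module dynamics and the amino-acid enrichment statistic, and
# producer/degrader functional groups from per-MGS module completeness.

#' Collapse gene abundances to KO abundances
#'
#' KO abundance is the sum of the abundances of genes annotated to that
#' KO. A gene carrying several KO annotations contributes fully to each
#' (a message reports how many such genes were seen); unannotated genes
#' are ignored. KOs with no annotated gene in the table are absent from
#' the output.
#'
#' @param genes normalised gene x sample matrix.
#' @param gene_ko data.frame with columns `gene` and `ko`.
#' @return KO x sample abundance matrix.
#' @export
ko_abundance <- function(genes, gene_ko) {
  check_table(genes, "gene table")
  map <- gene_ko[gene_ko$gene %in% rownames(genes), , drop = FALSE]
  if (!nrow(map)) return(matrix(0, 0, ncol(genes),
                                dimnames = list(NULL, colnames(genes))))
  multi <- sum(duplicated(map$gene))
  if (multi > 0)
    message(sprintf("ko_abundance: %d gene(s) carry multiple KO annotations and contribute fully to each", multi))
  rowsum(genes[map$gene, , drop = FALSE], group = map$ko)
}

#' Module abundance from KO abundances with a step-coverage rule
#'
#' Each module is an ordered list of steps, each step a set of alternative
#' KOs. Per sample: a step's abundance is the sum of its alternative KOs'
#' abundances; coverage is the fraction of steps with nonzero abundance;
#' the module abundance is the median over all step abundances (zeros
#' included) when coverage reaches `coverage_cutoff`, else 0. These
#' defaults mirror common module-scoring practice for gut metabolic
#' modules.
#'
#' @param kos KO x sample abundance matrix.
#' @param modules named list of module definitions (see
#'   [read_modules_txt()]).
#' @param coverage_cutoff minimum step coverage in (0, 1\] (default 0.66).
#' @return list with `abundance` (module x sample) and `coverage`
#'   (module x sample step-coverage fractions).
#' @export
module_abundance <- function(kos, modules, coverage_cutoff = 0.66) {
  check_table(kos, "KO table")
  if (coverage_cutoff <= 0 || coverage_cutoff > 1)
    fail("module_abundance: coverage_cutoff must lie in (0, 1]")
  ids <- names(modules)
  ab <- cov <- matrix(0, length(ids), ncol(kos),
                      dimnames = list(ids, colnames(kos)))
  for (m in seq_along(modules)) {
    steps <- modules[[m]]$steps
    known <- vapply(steps, function(s) any(s %in% rownames(kos)), TRUE)
    if (!any(known)) {
      warn("module_abundance: module '%s' references only unknown KOs", ids[m])
      next
    }
    step_ab <- t(matrix(vapply(steps, function(s) {
      hit <- intersect(s, rownames(kos))
      if (!length(hit)) rep(0, ncol(kos))
      else colSums(kos[hit, , drop = FALSE])
    }, numeric(ncol(kos))), nrow = ncol(kos)))  # steps x samples
    cov[m, ] <- colMeans(step_ab > 0)
    med <- apply(step_ab, 2, stats::median)
    ab[m, ] <- ifelse(cov[m, ] >= coverage_cutoff, med, 0)
  }
  list(abundance = ab, coverage = cov)
}

#' Per-module, per-arm fold-change direction
#'
#' Computes each module's mean log fold change per arm (via
#' [log_fold_change()], shared pseudocount rule) and classes modules as
#' `"increase"` (mean fold change > 0), `"decrease"` (< 0) or
#' `"unchanged"` (exactly 0; excluded from enrichment proportions).
#'
#' @param mod_tab module x sample abundance matrix (from
#'   [module_abundance()]`$abundance`).
#' @param metadata per-sample metadata.
#' @param modules module definitions, used to attach category and amino
#'   acid to each row.
#' @param ... passed to [log_fold_change()].
#' @return data.frame: module, arm, category, amino_acid, mean_lfc, class.
#' @export
module_dynamics <- function(mod_tab, metadata, modules = NULL, ...) {
  dyn <- log_fold_change(mod_tab, metadata, ...)
  out <- dyn$summary[dyn$summary$arm != "pooled", ]
  out$class <- ifelse(out$mean_lfc > 0, "increase",
                      ifelse(out$mean_lfc < 0, "decrease", "unchanged"))
  if (!is.null(modules)) {
    out$category <- vapply(out$feature, function(f)
      if (f %in% names(modules)) modules[[f]]$category else NA_character_, "")
    out$amino_acid <- vapply(out$feature, function(f)
      if (f %in% names(modules)) modules[[f]]$amino_acid else NA_character_, "")
  }
  names(out)[names(out) == "feature"] <- "module"
  rownames(out) <- NULL
  out
}

#' Enrichment of increased modules within a category
#'
#' For each arm, the proportion of classified modules (increase or
#' decrease; unchanged excluded) whose abundance increased, with a
#' two-sided exact binomial test against 0.5; between arms, a chi-square
#' test (no continuity correction) on the 2 x 2 increased/decreased by arm
#' table.
#'
#' @param dynamics output of [module_dynamics()].
#' @param category module category to test (e.g. `"aa_synthesis"`).
#' @return list with per-arm `prop_increased`, `n_classified`,
#'   `binomial_p`, and the between-arm `chisq_p` and `counts`.
#' @export
enrichment_proportion_test <- function(dynamics, category = "aa_synthesis") {
  d <- dynamics[!is.na(dynamics$category) & dynamics$category == category &
                dynamics$class != "unchanged", ]
  if (!nrow(d)) fail("enrichment_proportion_test: no classified modules in category '%s'", category)
  arms <- sort(unique(d$arm))
  per_arm <- lapply(arms, function(a) {
    k <- sum(d$class[d$arm == a] == "increase")
    m <- sum(d$arm == a)
    list(arm = a, n_classified = m, n_increased = k,
         prop_increased = k / m,
         binomial_p = binom.test(k, m, p = 0.5)$p.value)
  })
  names(per_arm) <- arms
  counts <- t(vapply(arms, function(a)
    c(increased = sum(d$class[d$arm == a] == "increase"),
      decreased = sum(d$class[d$arm == a] == "decrease")), numeric(2)))
  chisq_p <- if (length(arms) == 2 && all(colSums(counts) >= 0) &&
                 sum(counts) > 0 && all(rowSums(counts) > 0))
    suppressWarnings(chisq.test(counts, correct = FALSE)$p.value)
  else NA_real_
  list(per_arm = per_arm, counts = counts, chisq_p = chisq_p,
       category = category)
}

#' Per-MGS module completeness
#'
#' Fraction of each module's steps for which the MGS's own annotated gene
#' repertoire carries at least one alternative KO — the basis for
#' producer/degrader guild assignment.
#'
#' @param catalog an `mgs_catalog`.
#' @param gene_ko optional gene-to-KO map (defaults to the catalog's).
#' @param modules optional module definitions (defaults to the catalog's).
#' @return MGS x module matrix of completeness fractions in \[0, 1\].
#' @export
module_completeness <- function(catalog, gene_ko = NULL, modules = NULL) {
  if (is.null(gene_ko)) gene_ko <- catalog$gene_ko
  if (is.null(modules)) modules <- catalog$modules
  ids <- names(catalog$mgs)
  comp <- matrix(0, length(ids), length(modules),
                 dimnames = list(ids, names(modules)))
  ko_by_gene <- split(gene_ko$ko, gene_ko$gene)
  for (i in seq_along(ids)) {
    kos <- unique(unlist(ko_by_gene[catalog$mgs[[i]]$genes], use.names = FALSE))
    for (m in seq_along(modules)) {
      steps <- modules[[m]]$steps
      comp[i, m] <- mean(vapply(steps, function(s) any(s %in% kos), TRUE))
    }
  }
  comp
}

#' Producer / degrader functional groups and their per-sample abundance
#'
#' An MGS joins the producer group for amino acid X when its completeness
#' of X's synthesis module reaches `threshold` (degraders analogously from
#' degradation modules). Group abundance per sample is the sum of member
#' MGS abundances. Lowering the threshold never shrinks a group.
#'
#' @param completeness MGS x module matrix from [module_completeness()].
#' @param mgs_tab MGS x sample abundance matrix.
#' @param modules module definitions (to find each amino acid's modules).
#' @param threshold completeness threshold in (0, 1\] (default 0.66; the
#'   sparse degradation-module coverage of real catalogs makes this
#'   threshold the main sensitivity knob, so it is surfaced in reports).
#' @return list with `members` (per amino acid x role, member MGS ids) and
#'   `abundance` (group x sample matrix, rows named `<aa>_producer` /
#'   `<aa>_degrader`; empty groups are absent).
#' @export
functional_groups <- function(completeness, mgs_tab, modules, threshold = 0.66) {
  if (threshold <= 0 || threshold > 1)
    fail("functional_groups: threshold must lie in (0, 1]")
  check_table(mgs_tab, "MGS table")
  members <- list()
  rows <- list()
  for (m in modules) {
    if (!(m$category %in% c("aa_synthesis", "aa_degradation"))) next
    role <- if (m$category == "aa_synthesis") "producer" else "degrader"
    mem <- rownames(completeness)[completeness[, m$id] >= threshold]
    mem <- intersect(mem, rownames(mgs_tab))
    key <- paste0(m$amino_acid, "_", role)
    members[[key]] <- mem
    if (length(mem))
      rows[[key]] <- colSums(mgs_tab[mem, , drop = FALSE])
  }
  ab <- if (length(rows)) do.call(rbind, rows)
        else matrix(0, 0, ncol(mgs_tab), dimnames = list(NULL, colnames(mgs_tab)))
  list(members = members, abundance = ab, threshold = threshold)
}

#' Completeness summary per module category
#'
#' Distribution of per-MGS completeness for every module: mean, median and
#' the fraction of MGS at or above `threshold`, plus a flag for
#' degradation modules that no MGS carries completely (the sparse-coverage
#' problem of degradation pathways in gene catalogs).
#'
#' @param completeness MGS x module matrix.
#' @param modules module definitions.
#' @param threshold membership threshold used for the fraction column.
#' @return data.frame with one row per module.
#' @export
coverage_report <- function(completeness, modules, threshold = 0.66) {
  rows <- lapply(modules, function(m) {
    v <- completeness[, m$id]
    data.frame(module = m$id, category = m$category,
               amino_acid = m$amino_acid,
               mean_completeness = mean(v),
               median_completeness = stats::median(v),
               frac_mgs_at_threshold = mean(v >= threshold),
               no_complete_mgs = m$category == "aa_degradation" && !any(v >= 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
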