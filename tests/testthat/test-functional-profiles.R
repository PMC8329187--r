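# KO collapse, module scoring, enrichment statistic, completeness and
# functional groups.

test_that("KO abundance sums annotated genes and keeps multi-KO genes whole", {
  genes <- matrix(c(0.01, 0.02, 0.5, 0.05), 4, 1,
                  dimnames = list(c("g1", "g2", "g3", "g4"), "s1"))
  map <- data.frame(gene = c("g1", "g2", "g4", "g4"),
                    ko = c("K00001", "K00001", "K00002", "K00003"),
                    stringsAsFactors = FALSE)
  expect_message(kos <- ko_abundance(genes, map), "multiple KO")
  expect_equal(unname(kos["K00001", 1]), 0.03)
  expect_equal(unname(kos["K00002", 1]), 0.05)  # full contribution to each
  expect_equal(unname(kos["K00003", 1]), 0.05)
  expect_false("g3" %in% rownames(kos))         # unannotated gene ignored
})

test_that("module abundance applies the median-with-zeros coverage rule", {
  mods <- list(M1 = list(id = "M1", name = "m", source = "kegg",
                         category = "other", amino_acid = NA,
                         steps = list("K1", "K2", "K3")))
  kos <- matrix(c(0, 4e-4, 6e-4), 3, 1, dimnames = list(c("K1", "K2", "K3"), "s"))
  res <- module_abundance(kos, mods, coverage_cutoff = 0.66)
  expect_equal(unname(res$coverage["M1", 1]), 2 / 3)
  expect_equal(unname(res$abundance["M1", 1]), 4e-4)  # median([0, 4e-4, 6e-4])
  # coverage below cutoff zeroes the module despite nonzero steps
  kos2 <- matrix(c(0, 0, 6e-4), 3, 1, dimnames = list(c("K1", "K2", "K3"), "s"))
  res2 <- module_abundance(kos2, mods, coverage_cutoff = 0.66)
  expect_equal(unname(res2$abundance["M1", 1]), 0)
  # all-zero steps give zero
  kos3 <- kos2; kos3[] <- 0
  expect_equal(unname(module_abundance(kos3, mods)$abundance["M1", 1]), 0)
  # alternatives within a step are summed
  mods2 <- list(M2 = list(id = "M2", name = "m2", source = "kegg",
                          category = "other", amino_acid = NA,
                          steps = list(c("K1", "K2"), "K3")))
  res3 <- module_abundance(kos, mods2, coverage_cutoff = 0.5)
  expect_equal(unname(res3$abundance["M2", 1]), median(c(4e-4, 6e-4)))
})

test_that("modules referencing only unknown KOs warn and score zero", {
  mods <- list(MX = list(id = "MX", name = "x", source = "kegg",
                         category = "other", amino_acid = NA,
                         steps = list("K9")))
  kos <- matrix(1e-3, 1, 1, dimnames = list("K1", "s"))
  expect_warning(res <- module_abundance(kos, mods), "unknown KOs")
  expect_equal(unname(res$abundance["MX", 1]), 0)
  expect_equal(unname(res$coverage["MX", 1]), 0)
  expect_error(module_abundance(kos, mods, coverage_cutoff = 0), "\\(0, 1\\]")
})

test_that("module abundance is monotone in KO abundance", {
  set.seed(12)
  mods <- list(M1 = list(id = "M1", name = "m", source = "kegg",
                         category = "other", amino_acid = NA,
                         steps = list(c("K1", "K2"), "K3", "K4")))
  for (i in 1:20) {
    kos <- matrix(runif(4, 0, 1e-3) * rbinom(4, 1, 0.7), 4, 1,
                  dimnames = list(c("K1", "K2", "K3", "K4"), "s"))
    bumped <- kos
    j <- sample(4, 1)
    bumped[j, 1] <- bumped[j, 1] + runif(1, 0, 1e-3)
    a0 <- module_abundance(kos, mods)$abundance[1, 1]
    a1 <- module_abundance(bumped, mods)$abundance[1, 1]
    expect_gte(a1, a0)
  }
})

test_that("exact-zero mean fold change is classed unchanged", {
  md <- data.frame(sample_id = c("a_T0", "a_T12"), subject = "a", arm = "IP",
                   timepoint = c("T0", "T12"), stringsAsFactors = FALSE)
  mods <- list(M1 = list(id = "M1", name = "m", source = "kegg",
                         category = "aa_synthesis", amino_acid = "lysine",
                         steps = list("K1")))
  tab <- matrix(c(0.2, 0.2), 1, 2, dimnames = list("M1", c("a_T0", "a_T12")))
  dyn <- module_dynamics(tab, md, mods)
  expect_equal(dyn$class, "unchanged")
  expect_error(enrichment_proportion_test(dyn, "aa_synthesis"), "no classified")
})

test_that("enrichment test matches the exact binomial and chi-square oracles", {
  mk_dyn <- function(k_ip, m_ip, k_cp, m_cp) {
    data.frame(
      module = sprintf("M%02d", seq_len(m_ip + m_cp)),
      arm = c(rep("IP", m_ip), rep("CP", m_cp)),
      category = "aa_synthesis", amino_acid = "lysine",
      mean_lfc = c(rep(1, k_ip), rep(-1, m_ip - k_ip),
                   rep(1, k_cp), rep(-1, m_cp - k_cp)),
      class = c(rep("increase", k_ip), rep("decrease", m_ip - k_ip),
                rep("increase", k_cp), rep("decrease", m_cp - k_cp)),
      stringsAsFactors = FALSE)
  }
  # 10 of 10 increased: two-sided binomial p = 2 * 0.5^10
  en <- enrichment_proportion_test(mk_dyn(10, 10, 5, 10))
  expect_equal(en$per_arm$IP$binomial_p, 2 * 0.5^10, tolerance = 1e-9)
  expect_equal(en$per_arm$CP$binomial_p, 1, tolerance = 1e-9)  # symmetric centre
  # chi-square with no continuity correction against the hand formula
  en2 <- enrichment_proportion_test(mk_dyn(18, 20, 2, 15))
  O <- matrix(c(18, 2, 2, 13), 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  stat <- sum((O - E)^2 / E)
  expect_equal(en2$chisq_p, pchisq(stat, df = 1, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("completeness counts covered steps per MGS", {
  cat <- get_small_catalog()
  comp <- module_completeness(cat)
  expect_true(all(comp >= 0 & comp <= 1))
  # hand-built: MGS with 3 of 4 steps covered scores 0.75; none scores 0
  mods <- list(M1 = list(id = "M1", name = "m", source = "kegg",
                         category = "other", amino_acid = NA,
                         steps = list("K1", "K2", "K3", "K4")))
  toy <- structure(list(
    mgs = list(A = list(genes = c("a1", "a2", "a3"), markers = "a1",
                        genus = "Bacteroides", species = "sp"),
               B = list(genes = "b1", markers = "b1",
                        genus = "Prevotella", species = "sp")),
    gene_ko = data.frame(gene = c("a1", "a2", "a3"),
                         ko = c("K1", "K2", "K3"), stringsAsFactors = FALSE),
    modules = mods), class = "mgs_catalog")
  cm <- module_completeness(toy)
  expect_equal(unname(cm["A", "M1"]), 0.75)
  expect_equal(unname(cm["B", "M1"]), 0)   # no annotated genes at all
})

test_that("functional groups at threshold 1 recover the planted membership", {
  cat <- get_small_catalog()
  coh <- get_small_cohort()
  comp <- module_completeness(cat)
  mgs <- mgs_abundance(normalise_genes(coh$genes), cat)
  fg <- functional_groups(comp, mgs$abundance, cat$modules, threshold = 1.0)
  for (aa in cat$amino_acids) {
    expect_setequal(fg$members[[paste0(aa, "_producer")]], cat$producers[[aa]])
    expect_setequal(fg$members[[paste0(aa, "_degrader")]], cat$degraders[[aa]])
  }
  # group abundance is the member sum
  aa1 <- cat$amino_acids[1]
  expect_equal(fg$abundance[paste0(aa1, "_producer"), ],
               colSums(mgs$abundance[fg$members[[paste0(aa1, "_producer")]], ,
                                     drop = FALSE]))
})

test_that("lowering the membership threshold never shrinks a group", {
  cat <- get_small_catalog()
  comp <- module_completeness(cat)
  mgs_tab <- matrix(1, nrow(comp), 2,
                    dimnames = list(rownames(comp), c("s1", "s2")))
  hi <- functional_groups(comp, mgs_tab, cat$modules, threshold = 0.9)
  lo <- functional_groups(comp, mgs_tab, cat$modules, threshold = 0.3)
  for (key in names(hi$members))
    expect_true(all(hi$members[[key]] %in% lo$members[[key]]))
})

test_that("coverage report summarises every module and ranks categories", {
  cat <- get_small_catalog()
  comp <- module_completeness(cat)
  rep_ <- coverage_report(comp, cat$modules)
  expect_equal(nrow(rep_), length(cat$modules))
  expect_gt(mean(rep_$mean_completeness[rep_$category == "aa_synthesis"]),
            mean(rep_$mean_completeness[rep_$category == "aa_degradation"]))
  # all-complete corner
  full <- matrix(1, 2, 1, dimnames = list(c("A", "B"), "M1"))
  mods <- list(M1 = list(id = "M1", name = "m", source = "gmm",
                         category = "aa_degradation", amino_acid = "lysine",
                         steps = list("K1")))
  r2 <- coverage_report(full, mods)
  expect_equal(r2$mean_completeness, 1)
  expect_false(r2$no_complete_mgs)
})

test_that("planted synthesis shift propagates through the whole chain", {
  cat <- get_default_catalog()
  en <- suppressMessages(run_enrichment_chain(sim_config(seed = 900), cat))
  expect_gte(en$per_arm$IP$prop_increased, 4 / 6)
  expect_lte(en$per_arm$CP$prop_increased, 5 / 6)
})
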