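# FDR, Grubbs, clinical contrasts, richness regressions, correlations,
# dietary plausibility.

test_that("BH adjustment matches hand-computed and brute-force values", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(17)
  for (i in 1:200) {
    p <- runif(sample(1:30, 1))
    expect_lt(max(abs(fdr_adjust(p) - bh_brute(p))), 1e-12)
  }
  # order invariance after matching back
  p <- runif(15)
  o <- sample(15)
  expect_equal(fdr_adjust(p)[o], fdr_adjust(p[o]))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Grubbs critical values reproduce the published table", {
  expect_equal(round(grubbs_critical(4), 3), 1.481)
  expect_equal(round(grubbs_critical(10), 3), 2.290)
  expect_equal(round(grubbs_critical(30), 3), 2.908)
  expect_error(grubbs_critical(2), ">= 3")
})

test_that("Grubbs test flags the spec example and respects invariances", {
  x <- c(1, 1, 1, 10)           # G = 1.5 > 1.481
  expect_equal(grubbs_outliers(x), 4L)
  expect_equal(grubbs_outliers(x + 100), 4L)  # location invariance
  expect_length(grubbs_outliers(c(-2, -1, 0, 1, 2)), 0)
  expect_error(grubbs_outliers(c(1, 2)), "at least 3")
  # iteration removes successive outliers
  y <- c(rnorm(20, 0, 0.1), 50, 30)
  expect_setequal(grubbs_outliers(y), c(21L, 22L))
})

test_that("clinical change analysis recovers a planted arm contrast", {
  mk_md <- function(effect, seed) {
    set.seed(seed)
    n <- 50
    subj <- sprintf("c%03d", 1:(2 * n))
    arm <- rep(c("IP", "CP"), n)
    base <- rnorm(2 * n, 200, 50)
    change <- -15 + ifelse(arm == "IP", effect, 0) + rnorm(2 * n, 0, 10)
    data.frame(
      sample_id = as.vector(t(outer(subj, c("T0", "T12"), paste, sep = "_"))),
      subject = rep(subj, each = 2), arm = rep(arm, each = 2),
      timepoint = rep(c("T0", "T12"), 2 * n),
      age = rep(50, 4 * n), sex = rep(rep(c("M", "F"), n), each = 2),
      bmi = rep(32, 4 * n),
      vfa_cm2 = as.vector(rbind(base, base + change)),
      stringsAsFactors = FALSE)
  }
  ests <- vapply(1:30, function(s) {
    r <- clinical_change_analysis(mk_md(-6, s), "vfa_cm2")
    (if (r$between$term == "armIP") 1 else -1) * r$between$estimate
  }, 0)
  expect_lt(abs(mean(ests) - (-6)), 3 * sd(ests) / sqrt(30))
  # all-zero changes give a zero contrast
  md0 <- mk_md(0, 1)
  md0$vfa_cm2 <- rep(100, nrow(md0))
  r0 <- clinical_change_analysis(md0, "vfa_cm2")
  expect_equal(unname(r0$between$estimate), 0, tolerance = 1e-12)
  expect_error(clinical_change_analysis(md0[, setdiff(names(md0), "bmi")], "vfa_cm2"),
               "bmi")
})

test_that("between-arm p-values are uniform when arms are identical", {
  mk_md <- function(seed) {
    set.seed(seed)
    n <- 30
    subj <- sprintf("c%03d", 1:(2 * n))
    arm <- rep(c("IP", "CP"), n)
    base <- rnorm(2 * n, 200, 50)
    change <- rnorm(2 * n, -15, 10)
    data.frame(
      sample_id = as.vector(t(outer(subj, c("T0", "T12"), paste, sep = "_"))),
      subject = rep(subj, each = 2), arm = rep(arm, each = 2),
      timepoint = rep(c("T0", "T12"), 2 * n),
      age = rep(50, 4 * n), sex = rep(rep(c("M", "F"), n), each = 2),
      bmi = rep(32, 4 * n),
      vfa_cm2 = as.vector(rbind(base, base + change)), stringsAsFactors = FALSE)
  }
  ps <- vapply(1:60, function(s)
    clinical_change_analysis(mk_md(s), "vfa_cm2")$between$p, 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("richness regression is standardized and recovers the planted sign", {
  coh <- get_default_cohort()
  mgs <- mgs_abundance(normalise_genes(coh$genes), get_default_catalog())
  rr <- classify_richness_response(mgs_richness(mgs), coh$metadata)
  reg <- richness_clinical_regression(rr, coh$metadata)
  expect_true(all(c("weight_kg", "fat_mass_kg", "vfa_cm2") %in% reg$variable))
  expect_lt(reg$beta[reg$variable == "weight_kg"], 0)
  expect_lt(reg$p[reg$variable == "weight_kg"], 0.05)
  # unit invariance: rescaling the outcome leaves beta unchanged
  md_g <- coh$metadata
  md_g$weight_kg <- md_g$weight_kg * 1000
  rr_g <- classify_richness_response(mgs_richness(mgs), md_g)
  reg_g <- richness_clinical_regression(rr_g, md_g)
  expect_equal(reg_g$beta[reg_g$variable == "weight_kg"],
               reg$beta[reg$variable == "weight_kg"], tolerance = 1e-9)
})

test_that("fold-change/clinical Spearman correlations behave as rank statistics", {
  set.seed(30)
  n <- 20
  subj <- sprintf("s%02d", 1:n)
  x <- rnorm(n)
  lfc <- rbind(perfect = x, noise = rnorm(n), flat = rep(1, n))
  colnames(lfc) <- subj
  clinical <- data.frame(subject = subj, protein_intake = x,
                         other = rnorm(n), stringsAsFactors = FALSE)
  res <- fc_clinical_correlation(lfc, clinical)
  expect_equal(res$rho[res$module == "perfect" & res$variable == "protein_intake"], 1)
  expect_true(is.na(res$rho[res$module == "flat" & res$variable == "other"]))
  # invariance under monotone transforms
  clinical2 <- clinical
  clinical2$protein_intake <- exp(clinical2$protein_intake)
  res2 <- fc_clinical_correlation(lfc, clinical2)
  expect_equal(res$rho[res$variable == "protein_intake"],
               res2$rho[res2$variable == "protein_intake"])
})

test_that("Harris-Benedict BMR and the plausibility bounds match the formulas", {
  expect_equal(harris_benedict_bmr(90, 180, 40, "M"), 1934.511, tolerance = 1e-9)
  md <- data.frame(
    sample_id = c("a_T0", "b_T0", "c_T0", "d_T0"),
    subject = c("a", "b", "c", "d"),
    timepoint = "T0",
    age = c(40, 40, 40, 40), sex = c("M", "M", "M", "M"),
    height_cm = c(180, 180, 180, NA),
    weight_kg = c(90, 90, 90, 90),
    energy_intake_kcal = c(900, 0.5 * harris_benedict_bmr(90, 180, 40, "M"),
                           2500, 2000),
    stringsAsFactors = FALSE)
  res <- dietary_plausibility_filter(md)
  expect_false("a" %in% res$retained)          # 900 < 0.5 * 1934.5
  expect_true("b" %in% res$retained)           # exactly the boundary: kept
  expect_true("c" %in% res$retained)
  expect_equal(res$excluded_missing, "d")      # missing anthropometry, separate
  expect_equal(res$table$prescribed_intake[1], 1.3 * 1934.511 - 600,
               tolerance = 1e-9)
})

test_that("feature scan flags constants and keeps null rejection near nominal", {
  md <- null_metadata(40, seed = 3)
  feats <- null_features(md, 60, seed = 4)
  feats[1, ] <- 5  # constant feature
  fs <- suppressMessages(feature_scan(feats, md, effect = "time_x_arm"))
  expect_true(fs$singular[1])
  expect_true(is.na(fs$q[1]))
  expect_lt(mean(fs$p[-1] < 0.05), 0.15)  # coarse sanity; the tight band
                                          # is checked on 1000 features
})

test_that("feature scan recovers the planted shift's direction by category", {
  cat <- get_default_catalog()
  coh <- get_default_cohort()
  norm <- normalise_genes(coh$genes)
  kos <- ko_abundance(norm, cat$gene_ko)
  ma <- module_abundance(kos, cat$modules)
  eps <- min(ma$abundance[ma$abundance > 0]) / 2
  fs <- suppressMessages(
    feature_scan(ma$abundance, coh$metadata, effect = "time_x_arm",
                 transform = function(x) log(x + eps)))
  syn <- grepl("^MS", fs$feature)
  deg <- grepl("^MD", fs$feature)
  expect_gt(mean(fs$estimate[syn]), 0)
  expect_lt(mean(fs$estimate[deg]), 0)
  expect_gt(mean(fs$estimate[syn]), mean(fs$estimate[deg]))
})
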