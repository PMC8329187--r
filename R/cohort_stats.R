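# Cohort-level inference: per-feature longitudinal mixed models with FDR
# control, Grubbs outlier handling, clinical change contrasts,
# richness-clinical regressions, fold-change/clinical correlations, and
# dietary plausibility filtering with the Harris-Benedict BMR.

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values; `q` is monotone in BH rank and lies in
#' \[0, 1\]. The study-wide significance threshold for adjusted analyses
#' is 0.1.
#'
#' @param p vector of p-values in \[0, 1\] (NAs propagate).
#' @return q-values in the input order.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) fail("fdr_adjust: p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Per-feature longitudinal mixed-model scan
#'
#' Fits, for every feature, a linear mixed model with a subject random
#' intercept on the paired T0/T12 values: pooled analysis reports the
#' fixed effect of time adjusted for baseline age and sex; the
#' between-group analysis adds the arm main effect and reports the
#' time-by-arm interaction with the same adjustments. The subject's
#' baseline feature value is deliberately not a fixed effect: with both
#' timepoints as responses it duplicates the T0 response on the
#' right-hand side, which collapses the subject random intercept and
#' distorts the interaction test (set `baseline_adjust = TRUE` to get
#' that variant anyway). Wald tests on REML coefficients use a t
#' reference with subject-level degrees of freedom. Singular or failed
#' fits are flagged and excluded from the FDR family.
#'
#' @param tab feature x sample matrix (prevalence-filtered).
#' @param metadata per-sample metadata (`sample_id`, `subject`, `arm`,
#'   `timepoint`, `age`, `sex`).
#' @param effect `"time"` (pooled) or `"time_x_arm"` (between-group).
#' @param transform optional response transform, e.g. `log1p`.
#' @param fdr_threshold significance threshold on q (default 0.1).
#' @param baseline_adjust also include the feature's baseline value as a
#'   fixed effect (default FALSE; see Details).
#' @return data.frame: feature, estimate, se, p, q, n, singular,
#'   significant.
#' @export
feature_scan <- function(tab, metadata, effect = c("time", "time_x_arm"),
                         transform = NULL, fdr_threshold = 0.1,
                         baseline_adjust = FALSE) {
  check_table(tab, "feature table")
  effect <- match.arg(effect)
  md <- metadata[match(colnames(tab), metadata$sample_id), ]
  if (any(is.na(md$subject))) fail("feature_scan: samples missing from metadata")
  md$time <- as.integer(md$timepoint == "T12")
  base_map <- md$sample_id[md$time == 0][match(md$subject, md$subject[md$time == 0])]
  term <- if (effect == "time") "time" else "time:arm"
  rows <- lapply(rownames(tab), function(f) {
    y <- tab[f, ]
    if (!is.null(transform)) y <- transform(y)
    dat <- data.frame(y = y, time = md$time, arm = md$arm, age = md$age,
                      sex = md$sex, subject = md$subject,
                      baseline = y[match(base_map, colnames(tab))])
    res <- data.frame(feature = f, estimate = NA_real_, se = NA_real_,
                      p = NA_real_, n = sum(complete.cases(dat)),
                      singular = TRUE, stringsAsFactors = FALSE)
    if (stats::sd(dat$y) == 0) return(res)  # constant feature: singular by design
    rhs <- c(if (effect == "time") "time" else "time * arm",
             "age", "sex", if (baseline_adjust) "baseline", "(1 | subject)")
    form <- as.formula(paste("y ~", paste(rhs, collapse = " + ")))
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(form, data = dat, REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore")))),
      error = function(e) NULL)
    if (is.null(fit)) return(res)
    cf <- lme4::fixef(fit)
    nm <- grep(if (effect == "time") "^time$" else "^time:arm", names(cf), value = TRUE)
    if (!length(nm)) return(res)
    se <- sqrt(diag(as.matrix(vcov(fit))))[nm]
    df <- length(unique(dat$subject)) - length(cf)
    res$estimate <- unname(cf[nm]); res$se <- unname(se)
    res$p <- 2 * pt(-abs(cf[nm] / se), df)
    res$singular <- lme4::isSingular(fit)
    res
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  family <- !out$singular & !is.na(out$p)
  out$q[family] <- fdr_adjust(out$p[family])
  out$significant <- !is.na(out$q) & out$q < fdr_threshold
  if (any(!family))
    message(sprintf("feature_scan: %d feature(s) flagged singular/failed and excluded from the FDR family", sum(!family)))
  out
}

#' Grubbs critical value (two-sided)
#'
#' `G_crit = (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t = t_{alpha / (2n), n - 2}`, reproducing the published two-sided
#' critical-value tables (e.g. 1.481 at n = 4, alpha = 0.05).
#'
#' @param n sample size (>= 3).
#' @param alpha significance level.
#' @return the critical value of the Grubbs statistic.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  if (n < 3) fail("grubbs_critical: n must be >= 3")
  t <- qt(1 - alpha / (2 * n), n - 2)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

#' Grubbs outlier test
#'
#' Two-sided Grubbs test: `G = max |x - mean| / sd` compared to the
#' t-based critical value at level `alpha`; with `iterate = TRUE` the test
#' repeats after removing each detected outlier until no further
#' rejection (or fewer than 3 values remain). Assumes approximate
#' normality of the non-outlying values.
#'
#' @param x numeric vector, length >= 3.
#' @param alpha significance level (default 0.05, the study's setting).
#' @param iterate repeat after removal (default TRUE).
#' @return integer indices of flagged outliers in `x` (possibly empty).
#' @export
grubbs_outliers <- function(x, alpha = 0.05, iterate = TRUE) {
  if (length(x) < 3) fail("grubbs_outliers: need at least 3 values")
  idx <- seq_along(x)
  flagged <- integer(0)
  repeat {
    v <- x[idx]
    if (length(v) < 3) break
    s <- stats::sd(v)
    if (s == 0) break
    dev <- abs(v - mean(v))
    g <- max(dev) / s
    if (g <= grubbs_critical(length(v), alpha)) break
    worst <- idx[which.max(dev)]
    flagged <- c(flagged, worst)
    idx <- setdiff(idx, worst)
    if (!iterate) break
  }
  sort(flagged)
}

#' Between-arm clinical change analysis
#'
#' Within each arm: the mean and SD of the T12 - T0 change and a paired t
#' test. Between arms: the adjusted difference from a linear change-score
#' model `change ~ arm + baseline + age + sex + bmi` (a fixed-covariate
#' analogue of the trial's repeated-measures model, usable with the two
#' in-scope timepoints). Optionally pre-filters changes with the Grubbs
#' test.
#'
#' @param metadata per-sample metadata.
#' @param outcome outcome column name (e.g. `"vfa_cm2"`).
#' @param covariates additional subject-level adjustment columns.
#' @param grubbs_filter drop Grubbs outliers of the pooled change scores
#'   first (default FALSE).
#' @return list with `within` (per-arm change summary) and `between`
#'   (adjusted arm contrast: estimate, se, p, n).
#' @export
clinical_change_analysis <- function(metadata, outcome,
                                     covariates = c("age", "sex", "bmi"),
                                     grubbs_filter = FALSE) {
  for (cv in c(outcome, covariates))
    if (!cv %in% names(metadata)) fail("clinical_change_analysis: missing covariate '%s'", cv)
  md0 <- metadata[metadata$timepoint == "T0", ]
  md1 <- metadata[metadata$timepoint == "T12", ]
  subjects <- intersect(md0$subject, md1$subject)
  i0 <- match(subjects, md0$subject); i1 <- match(subjects, md1$subject)
  dat <- data.frame(subject = subjects,
                    arm = md0$arm[i0],
                    baseline = md0[[outcome]][i0],
                    change = md1[[outcome]][i1] - md0[[outcome]][i0],
                    stringsAsFactors = FALSE)
  for (cv in covariates) dat[[cv]] <- md0[[cv]][i0]
  if (grubbs_filter) {
    out_idx <- grubbs_outliers(dat$change)
    if (length(out_idx)) dat <- dat[-out_idx, ]
  }
  within <- lapply(split(dat, dat$arm), function(d)
    list(n = nrow(d), mean_change = mean(d$change), sd_change = stats::sd(d$change),
         p = t.test(d$change)$p.value))
  form <- as.formula(paste("change ~ arm + baseline +",
                           paste(covariates, collapse = " + ")))
  fit <- lm(form, data = dat)
  cf <- summary(fit)$coefficients
  arm_row <- grep("^arm", rownames(cf), value = TRUE)[1]
  list(within = within,
       between = list(term = arm_row,
                      estimate = cf[arm_row, 1], se = cf[arm_row, 2],
                      p = cf[arm_row, 4], n = nrow(dat)),
       data = dat)
}

#' Standardized regression of clinical changes on richness change
#'
#' Per clinical variable, regresses its relative change on the subject's
#' richness change, adjusted for the variable's baseline value, baseline
#' BMI and sex (plus baseline statin intake for cholesterol/triglyceride
#' variables when a `statin` column is present). Both the response and the
#' richness change are z-scored, so the reported beta is the standardized
#' coefficient and is invariant to the clinical variable's units.
#'
#' @param response output of [classify_richness_response()] (needs
#'   `delta_richness` and `rel_*` columns).
#' @param metadata per-sample metadata (baselines read from T0 rows).
#' @param lipid_vars outcome columns that additionally adjust for statin.
#' @return data.frame: variable, beta (standardized), se, p, n.
#' @export
richness_clinical_regression <- function(response, metadata,
                                         lipid_vars = c("cholesterol", "triglycerides")) {
  md0 <- metadata[metadata$timepoint == "T0", ]
  i0 <- match(response$subject, md0$subject)
  rel_cols <- grep("^rel_", names(response), value = TRUE)
  zscore <- function(v) (v - mean(v)) / stats::sd(v)
  rows <- lapply(rel_cols, function(rc) {
    oc <- sub("^rel_", "", rc)
    dat <- data.frame(y = response[[rc]],
                      dr = response$delta_richness,
                      baseline = md0[[oc]][i0],
                      bmi = md0$bmi[i0], sex = md0$sex[i0])
    use_statin <- any(vapply(lipid_vars, function(lv) grepl(lv, oc), TRUE)) &&
      "statin" %in% names(md0)
    if (use_statin) dat$statin <- md0$statin[i0]
    dat <- dat[complete.cases(dat), ]
    dat$y <- zscore(dat$y); dat$dr <- zscore(dat$dr)
    form <- if (use_statin) y ~ dr + baseline + bmi + sex + statin
            else y ~ dr + baseline + bmi + sex
    cf <- summary(lm(form, data = dat))$coefficients
    data.frame(variable = oc, beta = cf["dr", 1], se = cf["dr", 2],
               p = cf["dr", 4], n = nrow(dat), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Spearman correlation of module fold changes with clinical changes
#'
#' Subject-level Spearman rho for every (module, clinical variable) pair,
#' BH-adjusted across the whole matrix. Pairs involving a constant vector
#' have undefined rho and are reported as missing.
#'
#' @param lfc module x subject matrix of per-subject log fold changes
#'   (e.g. [log_fold_change()]`$lfc`).
#' @param clinical subject x variable data.frame of relative clinical
#'   changes, with a `subject` column.
#' @return data.frame: module, variable, rho, p, q.
#' @export
fc_clinical_correlation <- function(lfc, clinical) {
  subjects <- intersect(colnames(lfc), clinical$subject)
  if (!length(subjects)) fail("fc_clinical_correlation: no shared subjects")
  ci <- match(subjects, clinical$subject)
  vars <- setdiff(names(clinical), "subject")
  rows <- list()
  for (m in rownames(lfc)) for (v in vars) {
    x <- lfc[m, subjects]; y <- clinical[[v]][ci]
    ok <- complete.cases(x, y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(module = m, variable = v,
                                              rho = NA_real_, p = NA_real_)
      next
    }
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman"))
    rows[[length(rows) + 1L]] <- data.frame(module = m, variable = v,
                                            rho = unname(ct$estimate),
                                            p = ct$p.value)
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- fdr_adjust(out$p[ok])
  out
}

#' Harris-Benedict basal metabolic rate
#'
#' Original (1919) coefficients: men
#' `66.473 + 13.7516 W + 5.0033 H - 6.755 A`, women
#' `655.0955 + 9.5634 W + 1.8496 H - 4.6756 A` (W kg, H cm, A years,
#' result kcal/day). `revised = TRUE` switches to the Roza-Shizgal (1984)
#' coefficients.
#'
#' @param weight_kg,height_cm,age_years anthropometry (vectorised).
#' @param sex `"M"` or `"F"` per subject.
#' @param revised use the revised coefficients (default FALSE).
#' @return BMR in kcal/day.
#' @export
harris_benedict_bmr <- function(weight_kg, height_cm, age_years, sex,
                                revised = FALSE) {
  male <- sex == "M"
  if (!revised)
    ifelse(male,
           66.473 + 13.7516 * weight_kg + 5.0033 * height_cm - 6.755 * age_years,
           655.0955 + 9.5634 * weight_kg + 1.8496 * height_cm - 4.6756 * age_years)
  else
    ifelse(male,
           88.362 + 13.397 * weight_kg + 4.799 * height_cm - 5.677 * age_years,
           447.593 + 9.247 * weight_kg + 3.098 * height_cm - 4.330 * age_years)
}

#' Dietary plausibility filter
#'
#' Excludes subjects with implausible energy-intake declarations: a
#' subject is retained iff `0.5 * BMR <= intake <= 3 * BMR`, with BMR from
#' [harris_benedict_bmr()] (boundary values are kept: the exclusion rule
#' is strict). Also reports each subject's prescribed intake under the
#' intervention design, `1.3 * BMR - 600` kcal (sedentary activity
#' coefficient 1.3, 600 kcal deficit). Subjects with missing
#' anthropometry are reported separately from implausible ones.
#'
#' @param metadata per-sample metadata; the row at `at` provides weight
#'   and intake.
#' @param at timepoint whose weight/intake to use (default `"T0"`).
#' @param revised passed to [harris_benedict_bmr()].
#' @return list with `retained` (subject ids), `excluded_implausible`,
#'   `excluded_missing`, and `table` (subject, bmr, intake, prescribed
#'   intake, retained flag).
#' @export
dietary_plausibility_filter <- function(metadata, at = "T0", revised = FALSE) {
  md <- metadata[metadata$timepoint == at, ]
  need <- c("weight_kg", "height_cm", "age", "sex", "energy_intake_kcal")
  for (cv in need)
    if (!cv %in% names(md)) fail("dietary_plausibility_filter: missing column '%s'", cv)
  missing <- !complete.cases(md[, need])
  bmr <- rep(NA_real_, nrow(md))
  bmr[!missing] <- harris_benedict_bmr(md$weight_kg[!missing], md$height_cm[!missing],
                                       md$age[!missing], md$sex[!missing], revised)
  intake <- md$energy_intake_kcal
  plausible <- !missing & intake >= 0.5 * bmr & intake <= 3 * bmr
  tab <- data.frame(subject = md$subject, bmr = bmr, intake = intake,
                    prescribed_intake = 1.3 * bmr - 600,
                    retained = plausible, stringsAsFactors = FALSE)
  list(retained = md$subject[plausible],
       excluded_implausible = md$subject[!missing & !plausible],
       excluded_missing = md$subject[missing],
       table = tab)
}

#' Macronutrient energy shares by Atwater factors
#'
#' Converts gram composition to shares of total energy using the Atwater
#' factors 4 / 9 / 4 kcal per gram of protein / fat / carbohydrate. Used
#' for supplement-composition arithmetic (e.g. the comparator sachet's
#' 7.3 g protein, 7.6 g fat, 24.5 g carbohydrate give 15% / 35% / 50%
#' after rounding).
#'
#' @param protein_g,fat_g,carb_g grams per serving.
#' @return list with `energy_kcal` (total) and `percent` (named vector,
#'   protein/fat/carbohydrate shares of energy in percent).
#' @export
energy_shares <- function(protein_g, fat_g, carb_g) {
  kcal <- c(protein = 4 * protein_g, fat = 9 * fat_g, carbohydrate = 4 * carb_g)
  total <- sum(kcal)
  if (total <= 0) fail("energy_shares: total energy must be positive")
  list(energy_kcal = total, percent = 100 * kcal / total)
}
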