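# Synthetic trial cohort: catalog + gene counts + metadata with known
# ground truth. Emulates a two-arm (IP/CP), two-timepoint (T0/T12)
# dietary-intervention cohort with mixture-structured genus compositions,
# heterogeneous richness trajectories tied to clinical changes, and an
# arm-specific planted shift on amino-acid-producer MGS.

#' Simulation configuration for the synthetic cohort generator
#'
#' Bundles and validates all generator knobs. Defaults define the study
#' conditions used throughout the package's recovery tests: 25 subjects per
#' arm (1:1 randomisation, microbiome subcohort scale), 30 MGS of 600 genes
#' each (the catalog rule requires > 500 genes per MGS), 50 marker genes per
#' MGS, 200,000 reads per sample, two enterotype components (Bacteroides- and
#' Prevotella-dominated), and a planted 1.0 log2 fold change on
#' amino-acid-producer MGS in the IP arm at T12.
#'
#' @param n_subjects subjects per arm.
#' @param n_mgs number of metagenomic species in the catalog.
#' @param genes_per_mgs genes per MGS; must exceed 500.
#' @param n_marker_genes designated marker genes per MGS.
#' @param sequencing_depth reads per sample; must be at least 10 x `n_mgs`.
#' @param n_enterotypes number of Dirichlet mixture components.
#' @param enterotype_separation concentration multiplier applied to the
#'   dominant genus of each component (dimensionless); larger values give
#'   better-separated community types.
#' @param planted_aa_synthesis_log2fc log2 multiplicative effect applied to
#'   amino-acid-producer MGS in IP-arm T12 samples before renormalisation.
#' @param richness_trajectory_sd standard deviation of the per-subject
#'   relative MGS-richness change, in percent of baseline richness.
#' @param richness_weightloss_slope kg of additional weight change per MGS
#'   gained (negative: gaining species goes with losing weight).
#' @param temporal_stability within-subject Dirichlet concentration: each
#'   timepoint's composition is drawn around the subject's own long-term
#'   composition with this concentration, reproducing the strong
#'   autocorrelation of longitudinal gut microbiomes (larger = more
#'   stable; default 200).
#' @param n_amino_acids number of amino acids given both a synthesis and a
#'   degradation module (at least 2).
#' @param seed integer seed; fixing it makes all outputs byte-identical.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_subjects = 25,
                       n_mgs = 30,
                       genes_per_mgs = 600,
                       n_marker_genes = 50,
                       sequencing_depth = 200000,
                       n_enterotypes = 2,
                       enterotype_separation = 10,
                       planted_aa_synthesis_log2fc = 1.0,
                       richness_trajectory_sd = 10,
                       richness_weightloss_slope = -0.3,
                       temporal_stability = 200,
                       n_amino_acids = 6,
                       seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_mgs = as.integer(n_mgs),
              genes_per_mgs = as.integer(genes_per_mgs),
              n_marker_genes = as.integer(n_marker_genes),
              sequencing_depth = as.integer(sequencing_depth),
              n_enterotypes = as.integer(n_enterotypes),
              enterotype_separation = enterotype_separation,
              planted_aa_synthesis_log2fc = planted_aa_synthesis_log2fc,
              richness_trajectory_sd = richness_trajectory_sd,
              richness_weightloss_slope = richness_weightloss_slope,
              temporal_stability = temporal_stability,
              n_amino_acids = as.integer(n_amino_acids),
              seed = as.integer(seed))
  counts <- c("n_subjects", "n_mgs", "genes_per_mgs", "n_marker_genes",
              "sequencing_depth", "n_enterotypes", "n_amino_acids")
  for (f in counts)
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      fail("sim_config: '%s' must be a count >= 1", f)
  if (cfg$sequencing_depth < 10L * cfg$n_mgs)
    fail("sim_config: sequencing_depth must be >= 10 x n_mgs")
  if (cfg$n_marker_genes > cfg$genes_per_mgs)
    fail("sim_config: n_marker_genes cannot exceed genes_per_mgs")
  if (cfg$n_amino_acids < 2L)
    fail("sim_config: n_amino_acids must be >= 2")
  if (cfg$temporal_stability <= 0)
    fail("sim_config: temporal_stability must be positive")
  if (cfg$n_mgs < 2L * cfg$n_amino_acids)
    fail("sim_config: n_mgs must be >= 2 x n_amino_acids so every amino acid gets disjoint producer and degrader MGS")
  class(cfg) <- "sim_config"
  cfg
}

.genus_pool <- c("Bacteroides", "Prevotella", "Ruminococcus",
                 "Faecalibacterium", "Alistipes", "Roseburia",
                 "Akkermansia", "Bifidobacterium")

.amino_acid_pool <- c("lysine", "histidine", "leucine", "threonine",
                      "cysteine", "isoleucine", "proline", "methionine",
                      "ornithine", "glutamine")

# Build module definitions for n_aa amino acids (5-step synthesis, 3-step
# degradation, 1-2 alternative KOs per step) plus two unrelated modules.
.make_modules <- function(n_aa) {
  aa <- .amino_acid_pool[seq_len(n_aa)]
  ko_counter <- 0L
  next_kos <- function(n) {
    ids <- sprintf("K%05d", ko_counter + seq_len(n))
    ko_counter <<- ko_counter + n
    ids
  }
  modules <- list()
  for (i in seq_along(aa)) {
    steps <- lapply(1:5, function(s) next_kos(if (s <= 2) 2L else 1L))
    modules[[length(modules) + 1L]] <- list(
      id = sprintf("MS%03d", i), name = paste(aa[i], "biosynthesis"),
      source = "kegg", category = "aa_synthesis", amino_acid = aa[i],
      steps = steps)
  }
  for (i in seq_along(aa)) {
    steps <- lapply(1:3, function(s) next_kos(if (s == 1) 2L else 1L))
    modules[[length(modules) + 1L]] <- list(
      id = sprintf("MD%03d", i), name = paste(aa[i], "degradation"),
      source = "gmm", category = "aa_degradation", amino_acid = aa[i],
      steps = steps)
  }
  for (i in 1:2) {
    steps <- lapply(1:4, function(s) next_kos(1L))
    modules[[length(modules) + 1L]] <- list(
      id = sprintf("MO%03d", i),
      name = c("central glycolysis", "butyrate production")[i],
      source = c("kegg", "gmm")[i], category = "other", amino_acid = NA_character_,
      steps = steps)
  }
  names(modules) <- vapply(modules, `[[`, "", "id")
  attr(modules, "n_module_kos") <- ko_counter
  modules
}

#' Generate a synthetic MGS catalog with functional annotation
#'
#' Builds `n_mgs` metagenomic species, each with `genes_per_mgs` member
#' genes (pairwise-disjoint gene sets) and `n_marker_genes` designated
#' markers, a gene-to-KO annotation map, and module definitions for
#' `n_amino_acids` amino acids (both a multi-step synthesis and a
#' degradation module each, plus two unrelated modules). Disjoint MGS
#' subsets are designated producers (complete synthesis module) and
#' degraders (complete degradation module) per amino acid; all other MGS
#' carry only the first two synthesis steps, and a random 20% carry one
#' degradation step, so biosynthesis completeness across the catalog far
#' exceeds degradation completeness, as observed in real gene catalogs.
#'
#' @param config a [sim_config()].
#' @return an `mgs_catalog` list with elements `mgs` (per-MGS gene sets,
#'   markers, genus/species labels), `gene_ko` (data.frame `gene`, `ko`),
#'   `modules` (module definitions), `producers` and `degraders` (per
#'   amino acid, the planted member MGS ids).
#' @export
generate_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$genes_per_mgs <= 500L)
    fail("generate_catalog: genes_per_mgs must exceed 500 (MGS are defined as gene clusters of > 500 genes); got %d",
         config$genes_per_mgs)
  with_seed(config$seed, {
    n_aa <- config$n_amino_acids
    modules <- .make_modules(n_aa)
    aa <- vapply(modules[grepl("^MS", names(modules))], `[[`, "", "amino_acid")
    mgs_ids <- sprintf("MGS%03d", seq_len(config$n_mgs))
    genus <- rep(.genus_pool, length.out = config$n_mgs)

    # disjoint producer / degrader blocks per amino acid
    p_per <- max(1L, as.integer(floor(0.6 * config$n_mgs / n_aa)))
    d_per <- max(1L, as.integer(floor(0.3 * config$n_mgs / n_aa)))
    while (n_aa * (p_per + d_per) > config$n_mgs) {
      if (p_per > 1L) p_per <- p_per - 1L else d_per <- d_per - 1L
    }
    shuffled <- sample(mgs_ids)
    producers <- degraders <- stats::setNames(vector("list", n_aa), aa)
    off <- 0L
    for (i in seq_len(n_aa)) {
      producers[[i]] <- sort(shuffled[off + seq_len(p_per)]); off <- off + p_per
    }
    for (i in seq_len(n_aa)) {
      degraders[[i]] <- sort(shuffled[off + seq_len(d_per)]); off <- off + d_per
    }

    background_kos <- sprintf("K%05d", 90000L + seq_len(100))
    mgs <- vector("list", config$n_mgs)
    names(mgs) <- mgs_ids
    map_gene <- character(0); map_ko <- character(0)
    for (m in seq_len(config$n_mgs)) {
      id <- mgs_ids[m]
      genes <- sprintf("%s_g%04d", id, seq_len(config$genes_per_mgs))
      markers <- genes[seq_len(config$n_marker_genes)]
      # which module steps does this MGS carry?
      carried <- list()  # list of KO ids, one gene each
      for (mod in modules) {
        n_steps <- length(mod$steps)
        keep <- switch(mod$category,
          aa_synthesis = if (id %in% producers[[mod$amino_acid]])
            seq_len(n_steps) else seq_len(min(2L, n_steps - 1L)),
          aa_degradation = if (id %in% degraders[[mod$amino_acid]])
            seq_len(n_steps)
          else if (runif(1) < 0.2) 1L else integer(0),
          other = if (runif(1) < 0.5) seq_len(n_steps) else integer(0))
        for (s in keep)
          carried[[length(carried) + 1L]] <-
            mod$steps[[s]][sample.int(length(mod$steps[[s]]), 1L)]
      }
      carried <- unlist(carried, use.names = FALSE)
      # functional genes sit after the marker block; keep indices stable
      fn_idx <- config$n_marker_genes + seq_along(carried)
      map_gene <- c(map_gene, genes[fn_idx])
      map_ko <- c(map_ko, carried)
      # background annotation on 60% of the remaining genes
      rest <- setdiff(seq_len(config$genes_per_mgs),
                      c(seq_len(config$n_marker_genes), fn_idx))
      bg <- rest[runif(length(rest)) < 0.6]
      map_gene <- c(map_gene, genes[bg])
      map_ko <- c(map_ko, sample(background_kos, length(bg), replace = TRUE))
      mgs[[m]] <- list(genes = genes, markers = markers, genus = genus[m],
                       species = sprintf("%s sp. %03d", genus[m], m))
    }
    structure(list(mgs = mgs,
                   gene_ko = data.frame(gene = map_gene, ko = map_ko,
                                        stringsAsFactors = FALSE),
                   modules = modules,
                   amino_acids = aa,
                   producers = producers,
                   degraders = degraders),
              class = "mgs_catalog")
  })
}

#' Generate a synthetic two-arm, two-timepoint cohort
#'
#' Draws, per subject, an enterotype component and per-sample MGS
#' compositions from that component's Dirichlet distribution (restricted to
#' a per-sample presence mask that realises heterogeneous richness
#' trajectories), multiplies amino-acid-producer MGS in IP-arm T12 samples
#' by `2^planted_aa_synthesis_log2fc` before renormalisation, and draws
#' gene read counts multinomially at `sequencing_depth` with uniform gene
#' weights within each MGS (so marker-gene means are unbiased estimators of
#' MGS abundance). Clinical changes (weight, fat mass, visceral fat area)
#' are linear in the subject's true MGS-richness change plus Gaussian
#' noise; baselines are drawn near the trial's Table-1 magnitudes (BMI ~32,
#' VFA ~200 cm2).
#'
#' @param config a [sim_config()].
#' @param catalog the matching [generate_catalog()] output.
#' @return a list with `genes` (integer gene x sample count matrix, every
#'   column summing to `sequencing_depth`), `metadata` (one row per sample:
#'   subject, arm, timepoint, covariates, outcomes, intake), and `truth`
#'   (true enterotypes, true MGS relative abundances, producer/degrader
#'   lists, per-subject true richness change and clinical changes).
#' @export
generate_cohort <- function(config, catalog) {
  stopifnot(inherits(config, "sim_config"), inherits(catalog, "mgs_catalog"))
  n_genes_total <- config$n_mgs * config$genes_per_mgs
  if (config$sequencing_depth < n_genes_total)
    warn("generate_cohort: sequencing_depth (%d) below the catalog gene count (%d); many genes will go undetected",
         config$sequencing_depth, n_genes_total)
  with_seed(config$seed + 1L, {
    mgs_ids <- names(catalog$mgs)
    genus <- vapply(catalog$mgs, `[[`, "", "genus")
    K <- config$n_enterotypes
    dominant <- .genus_pool[((seq_len(K) - 1L) %% length(.genus_pool)) + 1L]
    alpha <- sapply(seq_len(K), function(k) {
      a <- rep(1, config$n_mgs)
      a[genus == dominant[k]] <- config$enterotype_separation
      a
    })  # n_mgs x K
    rownames(alpha) <- mgs_ids

    n_sub <- 2L * config$n_subjects
    subjects <- sprintf("S%03d", seq_len(n_sub))
    arm <- sample(rep(c("IP", "CP"), config$n_subjects))
    ent <- sample.int(K, n_sub, replace = TRUE)
    sex <- sample(c("M", "F"), n_sub, replace = TRUE)
    age <- pmin(65, pmax(18, round(rnorm(n_sub, 48, 10))))
    height <- ifelse(sex == "M", rnorm(n_sub, 175, 7), rnorm(n_sub, 162, 6))
    bmi <- pmax(25, pmin(40, rnorm(n_sub, 32, 3.8)))
    weight0 <- bmi * (height / 100)^2
    fat0 <- pmax(15, rnorm(n_sub, 35, 8))
    vfa0 <- pmax(60, rnorm(n_sub, 200, 60))
    statin <- runif(n_sub) < 0.2

    prod_union <- sort(unique(unlist(catalog$producers)))
    fc <- 2^config$planted_aa_synthesis_log2fc

    sample_ids <- as.vector(t(outer(subjects, c("T0", "T12"), paste, sep = "_")))
    true_ab <- matrix(0, config$n_mgs, 2L * n_sub,
                      dimnames = list(mgs_ids, sample_ids))
    gene_ids <- unlist(lapply(catalog$mgs, `[[`, "genes"), use.names = FALSE)
    genes <- matrix(0L, n_genes_total, 2L * n_sub,
                    dimnames = list(gene_ids, sample_ids))
    gene_mgs <- rep(seq_len(config$n_mgs), each = config$genes_per_mgs)
    d_rich <- integer(n_sub)

    for (i in seq_len(n_sub)) {
      a_k <- alpha[, ent[i]]
      dom <- genus == dominant[ent[i]]
      present0 <- dom | runif(config$n_mgs) < 0.92
      n0 <- sum(present0)
      delta <- round(rnorm(1, 0, config$richness_trajectory_sd / 100 * n0))
      present1 <- present0
      if (delta > 0) {
        absent <- which(!present0)
        add <- head(sample(absent), delta)
        present1[add] <- TRUE
      } else if (delta < 0) {
        removable <- which(present0 & !dom)
        drop <- head(sample(removable), min(-delta, max(0, length(removable) - 1L)))
        present1[drop] <- FALSE
      }
      d_rich[i] <- sum(present1) - n0

      # subject's long-term composition; timepoints vary around it
      p_subj <- rdirichlet1(a_k)
      for (tp in 1:2) {
        mask <- if (tp == 1) present0 else present1
        p_mgs <- stats::setNames(
          rdirichlet1(config$temporal_stability * p_subj * mask), mgs_ids)
        if (tp == 2 && arm[i] == "IP") {
          p_mgs[prod_union] <- p_mgs[prod_union] * fc
          p_mgs <- p_mgs / sum(p_mgs)
        }
        col <- 2L * (i - 1L) + tp
        true_ab[, col] <- p_mgs
        p_gene <- p_mgs[gene_mgs] / config$genes_per_mgs
        genes[, col] <- rmultinom(1, config$sequencing_depth, p_gene)[, 1]
      }
    }

    s <- config$richness_weightloss_slope
    d_weight <- -3.0 + s * d_rich + rnorm(n_sub, 0, 1.0)
    d_fat <- -2.5 + 0.7 * s * d_rich + rnorm(n_sub, 0, 0.9)
    d_vfa <- -17 + 8 * s * d_rich + rnorm(n_sub, 0, 10)
    intake0 <- pmax(800, rnorm(n_sub, 2350, 850))
    intake1 <- pmax(600, rnorm(n_sub, 1780, 500))

    metadata <- data.frame(
      sample_id = sample_ids,
      subject = rep(subjects, each = 2),
      arm = rep(arm, each = 2),
      timepoint = rep(c("T0", "T12"), n_sub),
      age = rep(age, each = 2),
      sex = rep(sex, each = 2),
      height_cm = round(rep(height, each = 2), 1),
      bmi = round(rep(bmi, each = 2), 2),
      statin = rep(statin, each = 2),
      weight_kg = round(as.vector(rbind(weight0, weight0 + d_weight)), 2),
      fat_mass_kg = round(as.vector(rbind(fat0, fat0 + d_fat)), 2),
      vfa_cm2 = round(as.vector(rbind(vfa0, vfa0 + d_vfa)), 1),
      energy_intake_kcal = round(as.vector(rbind(intake0, intake1))),
      stringsAsFactors = FALSE)

    truth <- list(
      enterotype = stats::setNames(ent, subjects),
      dominant_genus = dominant,
      abundance = true_ab,
      producers = catalog$producers,
      degraders = catalog$degraders,
      richness_change = stats::setNames(d_rich, subjects),
      clinical_change = data.frame(subject = subjects,
                                   d_weight = d_weight, d_fat = d_fat,
                                   d_vfa = d_vfa, stringsAsFactors = FALSE))
    list(genes = genes, metadata = metadata, truth = truth)
  })
}
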