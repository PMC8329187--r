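---
title: "Models and design choices in protshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in protshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

protshift analyses two-arm (high-protein investigational product, IP,
versus isocaloric comparator, CP), two-timepoint (T0/T12) shotgun
metagenomics cohorts. This vignette explains the models behind each
stage, the parameters that matter, what the synthetic cohort generator
does and does not emulate, and the design decisions taken where the
methodology was genuinely open. Every empirical claim here is one the
package's own test suite or `scripts/acceptance.R` recomputes.

## Gene-level processing

Raw gene counts are made comparable across samples by downsizing: each
sample is reduced to exactly `depth` reads by multivariate hypergeometric
(without-replacement) subsampling, averaged over `n_draws` independent
draws (default 30, common practice in quantitative metagenomics). Gene
richness — the number of genes with at least one read — is defined only
on downsized raw counts, never on normalised abundances, and is averaged
over draws. Internally genes are processed in sorted-id order, so results
do not depend on the row order of the input table. The baseline
prevalence filter uses a strict inequality: a feature present in exactly
20% of baseline samples is excluded at the default 0.20 threshold.

## MGS abundance from marker genes

A metagenomic species (MGS) is a catalog-defined cluster of more than 500
co-abundant genes with a designated marker subset. Abundance is the
untrimmed mean relative abundance of all markers: under the generator's
uniform within-MGS gene weights this estimator is unbiased, and whether
the original pipelines trim marker means is not decidable from the
available descriptions, so the simplest testable contract was chosen. A
species is called present when strictly more than 10% of its markers are
detected (configurable; no published definition of "present" exists for
this estimator). Note the marker mean is the per-gene share, i.e. the MGS
relative abundance divided by its gene count — a fixed scale factor that
cancels in every ratio, rank and collapse the pipeline performs.

The low/high gene count (LGC/HGC) stratification defaults to a cohort
median split with ties assigned to HGC (strict `< median` for LGC); a
fixed external threshold is available when one wants to reuse a published
cut-off. Subjects with unchanged MGS richness are classed "stable" and
excluded from gained-versus-lost contrasts, which are defined only for
the two responding classes.

## Dirichlet multinomial mixture enterotyping

Genus-level counts are modelled as a K-component mixture of
Dirichlet-multinomials. EM alternates posterior responsibilities
(E-step) with mixture-weight and Dirichlet-parameter updates, the latter
by Minka's responsibility-weighted fixed-point iteration, which is
monotone in the weighted likelihood; `alpha` is floored at 1e-10.
Initialisation is k-means on sample proportions with moment-matched
concentrations; 5 restarts and a relative log-likelihood tolerance of
1e-6 are the defaults. Relative-abundance input is converted to
pseudo-counts by scaling with the downsizing depth and rounding half to
even, with a message.

Two model-selection criteria are reported per fit. BIC is the default:
in repeated simulations from one- and two-component mixtures it
recovered the true K essentially always. The Laplace approximation of
the negative log evidence is also computed, assembled from per-component
responsibility-weighted Hessians in log-alpha space (block-diagonal;
mixture weights excluded). We deliberately do not use the full joint
Hessian: when EM fits K+1 components to K-component data the surplus
component nearly duplicates another, the likelihood becomes locally
degenerate along cross-component directions, and the resulting near-zero
curvature spuriously inflates the evidence — the full-Hessian criterion
systematically preferred overfitted K. Even the block-diagonal variant
mis-selected K in 10–40% of small-cohort simulations, which is why BIC
was promoted to default rather than kept as the fallback.

Components are labelled by the genus carrying the largest share of the
fitted Dirichlet parameter vector; assignment ties go to the lowest
component index and are logged. The switch analysis contrasts switching
against the baseline Bacteroides enterotype and between arms with
two-sided Fisher exact tests, chosen for the small counts such 2x2
tables contain.

## Beta-diversity and per-feature dynamics

Bray–Curtis dissimilarity, classical-scaling PCoA (negative eigenvalues
reported, not hidden) and one-way PERMANOVA are implemented directly and
cross-checked in the test suite against vegan's `vegdist`, `cmdscale`
and `adonis2` on shared instances. The permutation p-value uses the
add-one convention `(1 + #{F* >= F}) / (1 + n_perm)` with 999
permutations by default, so its smallest attainable value is
`1/(n_perm+1)` — and only when the permutation space is large enough for
random permutations to essentially never reproduce the observed
partition.

Per-subject log fold changes use `log((a_T12 + eps)/(a_T0 + eps))` with
`eps` defaulting to half the smallest nonzero abundance in the table;
natural log by default with the base recorded in the output, since the
convention is not fixed in the field. Cliff's delta uses strict
inequalities (ties contribute zero).

## Functional modules and the enrichment statistic

A module is an ordered list of steps, each satisfiable by alternative
KOs (one level of alternatives; the full nested Boolean grammar of KEGG
modules is out of scope). Scoring follows the conventions of the
gut-metabolic-module tooling: step abundance is the sum of its
alternatives, coverage is the fraction of steps detected, and the module
abundance is the median over all step abundances — zeros included — when
coverage reaches the 0.66 cutoff, else zero. Both the cutoff and the
score are configurable because the upstream tools expose them too.

Module dynamics are classed per arm by the sign of the mean log fold
change; an exact zero is "unchanged" and drops out of the enrichment
proportions, which are defined by strict signs. The enrichment statistic
tests, per arm, the proportion of increased modules in a category
against 0.5 with an exact binomial test, and between arms with a
chi-square on the increased/decreased-by-arm 2x2 without continuity
correction (the uncorrected statistic is what the hand formula
`sum((O-E)^2/E)` gives; the choice is logged in the output contract).

Producer/degrader functional groups come from per-MGS module
completeness: the fraction of a module's steps for which the MGS's own
annotated genes carry at least one alternative KO. Membership requires
completeness at or above a threshold, default 0.66 and deliberately
prominent in `coverage_report()`: real gene catalogs cover degradation
pathways far more sparsely than biosynthesis ones, so group composition
is most sensitive to this single number. Multi-KO genes count fully
toward each KO; fractional splitting is configurable ground we chose not
to take by default because the toy catalogs are one-to-one.

## Cohort-level inference

Per-feature longitudinal models are linear mixed models with a subject
random intercept, REML estimation, and Wald t tests with subject-level
degrees of freedom (Satterthwaite refinements are out of scope; a
standard-normal reference is visibly anticonservative at 25
subjects/arm). The pooled analysis reports the time effect, the
between-group analysis the time-by-arm interaction, both adjusted for
baseline age and sex. The feature's own baseline value is *not* a
covariate by default: with both timepoints as responses, conditioning on
the T0 response collapses the subject random intercept (99% of fits were
singular) and inflated the interaction's type-I error to about 7.8% in
null simulations, versus about 5–6% without it. The variant remains
available via `baseline_adjust = TRUE` for comparison. Singular or
failed fits are flagged and excluded from the Benjamini–Hochberg family;
the FDR threshold is 0.1 and families are never pooled across feature
types.

The trial's stepwise repeated-measures GEE for clinical endpoints is not
reproducible from its published description (no selection recipe), so
between-arm clinical contrasts use a fixed-covariate change-score model
— change on arm plus baseline value, age, sex and BMI — which is the
standard two-timepoint analogue; within-arm changes get paired t tests
and an optional Grubbs pre-filter (two-sided, alpha 0.05, iterated until
no rejection). The Harris–Benedict BMR uses the original 1919
coefficients (the revised 1984 form is a flag); dietary plausibility
keeps a subject iff `0.5*BMR <= intake <= 3*BMR`, boundary included,
because the published exclusion rule is strict. The prescribed intake of
the intervention design is `1.3*BMR − 600` kcal.

## The synthetic cohort generator

The generator defines the study conditions under which the package's
recovery and calibration claims hold. Defaults: 25 subjects per arm
(1:1), 30 MGS of 600 genes each with 50 markers, 200,000 reads per
sample, two enterotype components whose dominant genus
(Bacteroides/Prevotella) gets a 10-fold concentration boost, six amino
acids with a 5-step synthesis and a 3-step degradation module each plus
two unrelated modules, and a planted log2 fold change of 1.0 on
producer MGS in IP-arm T12 samples.

Choices worth knowing about:

* **Depth.** 200,000 reads over the 18,000-gene toy catalog (~11
  reads/gene) keeps compositional variation, not Poisson counting noise,
  as the dominant error source — matching the regime of the multi-million
  read cohorts being emulated. (At 50k reads, module scores ride on ~7
  reads per step and sign-flip constantly, which describes shallow
  sequencing, not these studies.)
* **Temporal stability.** Each subject has a long-term composition drawn
  from their enterotype component; the two timepoints are Dirichlet draws
  around it with concentration 200. Longitudinal gut microbiomes are
  strongly autocorrelated — enterotypes switch rarely — and independent
  draws per timepoint would make every paired log-ratio analysis
  needlessly noisy and the switch analysis meaningless.
* **Disjoint producer/degrader blocks.** Producer MGS sets are disjoint
  across amino acids (3 per amino acid by default), degraders likewise
  (drawn from the remaining MGS). This keeps the per-amino-acid module
  dynamics approximately independent, which the binomial/chi-square
  enrichment tests implicitly assume; it also makes
  ground-truth recovery of group membership an exact set-equality test.
  Real catalogs overlap these phenotypes; the package itself makes no
  independence assumption beyond the tests' own.
* **Richness trajectories.** Per-sample presence masks realise a
  per-subject richness change drawn with SD 10% of baseline richness;
  clinical changes are linear in the true richness change
  (−0.3 kg, −0.21 kg fat and −2.4 cm² visceral fat per gained species,
  plus Gaussian noise) around mean changes of −3.0 kg / −2.5 kg /
  −17 cm². At the toy scale of ~30 species a per-species slope of −0.3 kg
  gives the richness–weight-loss association a realistic effect size
  (correlation ≈ 0.5–0.6) at n = 50; clinical baselines sit near the
  trial's magnitudes (BMI ≈ 32, visceral fat area ≈ 200 cm²) purely so
  printed numbers look familiar.
* **What is not modelled.** Read-level artefacts (FASTQ, gene length, GC
  bias), strain variation, more than two timepoints, centre effects,
  drop-out, and overlap between producer and degrader phenotypes. A pass
  on synthetic data therefore demonstrates correctness of the pipeline's
  arithmetic and statistics under its stated assumptions, not robustness
  to mapping artefacts or annotation error in real cohorts.
* **The planted effect after renormalisation.** Multiplying producers by
  `2^1` and renormalising compresses the realised group fold change to
  `2/(1+s)` where `s` is the producers' abundance share (≈ 0.6 by
  default, so ≈ log2 1.25). Recovery is therefore always judged against
  the realised ground-truth fold change the generator records, not the
  nominal planted exponent.

## Problem sizes and numerical conventions

The shipped tests and the acceptance script use: 100 samples for DMM
recovery, 50 replicate cohorts for planted-shift recovery, 200 cohorts
and 1000 features for null calibration, and a small 12-MGS cohort for
unit-level contracts — sizes chosen so the whole suite re-runs in a few
minutes while keeping Monte-Carlo error well below every asserted
margin. Ties in Cliff's delta count zero; rounding of pseudo-counts is
half-to-even; eigenvalues below 1e-12 are treated as null space in PCoA;
the EM convergence check is relative; and all generator and fitting
randomness flows from explicit integer seeds, restoring the caller's RNG
state afterwards.
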