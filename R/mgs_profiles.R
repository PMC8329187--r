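# MGS-level profiles: marker-based abundance, presence, MGS richness,
# genus collapse, richness-response classification, LGC/HGC strata.

#' MGS abundance and presence from marker genes
#'
#' The abundance of each metagenomic species is the mean relative abundance
#' of its designated marker genes (untrimmed mean over all markers, which
#' is unbiased when genes within an MGS are evenly covered). A species is
#' called present when strictly more than `presence_min_markers` of its
#' markers have nonzero abundance. MGS with fewer than half of their
#' markers in the gene table are dropped with a warning.
#'
#' @param genes normalised gene x sample matrix ([normalise_genes()]).
#' @param catalog an `mgs_catalog`.
#' @param presence_min_markers fraction of markers that must be detected
#'   for presence (default 0.10).
#' @return list with `abundance` (MGS x sample matrix, marker-mean scale)
#'   and `presence` (logical matrix of the same shape).
#' @export
mgs_abundance <- function(genes, catalog, presence_min_markers = 0.10) {
  check_table(genes, "gene table")
  if (!isTRUE(attr(genes, "normalised")))
    warn("mgs_abundance: input is not flagged normalised; marker means will be on the raw count scale")
  ids <- names(catalog$mgs)
  keep <- logical(length(ids))
  ab <- matrix(0, length(ids), ncol(genes), dimnames = list(ids, colnames(genes)))
  pres <- matrix(FALSE, length(ids), ncol(genes), dimnames = dimnames(ab))
  for (i in seq_along(ids)) {
    markers <- catalog$mgs[[i]]$markers
    if (!length(markers)) fail("mgs_abundance: MGS '%s' has an empty marker set", ids[i])
    found <- intersect(markers, rownames(genes))
    if (length(found) < length(markers) / 2) next
    keep[i] <- TRUE
    sub <- genes[found, , drop = FALSE]
    ab[i, ] <- colMeans(sub)
    pres[i, ] <- colMeans(sub > 0) > presence_min_markers
  }
  if (any(!keep))
    warn("mgs_abundance: dropping %d MGS with < 50%% of markers in the gene table: %s",
         sum(!keep), paste(ids[!keep], collapse = ", "))
  list(abundance = ab[keep, , drop = FALSE],
       presence = pres[keep, , drop = FALSE])
}

#' MGS richness per sample
#'
#' Number of metagenomic species called present in each sample.
#'
#' @param mgs output of [mgs_abundance()].
#' @return named integer vector.
#' @export
mgs_richness <- function(mgs) {
  stopifnot(is.matrix(mgs$presence))
  colSums(mgs$presence)
}

#' Collapse an MGS abundance table to genus level
#'
#' Genus abundance is the sum of member MGS abundances; MGS without a
#' genus label are pooled into `"unclassified"`.
#'
#' @param mgs output of [mgs_abundance()] (or a bare MGS x sample matrix).
#' @param catalog an `mgs_catalog`.
#' @return genus x sample abundance matrix.
#' @export
collapse_to_genus <- function(mgs, catalog) {
  ab <- if (is.list(mgs) && !is.null(mgs$abundance)) mgs$abundance else mgs
  check_table(ab, "MGS table")
  genus <- vapply(catalog$mgs[rownames(ab)], function(m) {
    g <- m$genus
    if (is.null(g) || is.na(g) || !nzchar(g)) "unclassified" else g
  }, "")
  rowsum(ab, group = genus)
}

#' Classify subjects by MGS-richness response and compute relative
#' clinical changes
#'
#' Subjects who increased their MGS richness between baseline and end of
#' intervention are classed `"gained"`, those who decreased `"lost"`, and
#' unchanged subjects `"stable"`. Relative clinical change is
#' `(T12 - T0) / T0 * 100` for each supplied outcome column. Subjects with
#' a missing timepoint are excluded with a message.
#'
#' @param richness named per-sample richness vector (names `subject_T0` /
#'   `subject_T12`) or the output of [mgs_richness()].
#' @param metadata per-sample metadata (`sample_id`, `subject`,
#'   `timepoint`, outcome columns).
#' @param outcomes outcome columns to express as relative changes.
#' @return data.frame with one row per subject: `delta_richness`, `class`,
#'   and a `rel_<outcome>` column per outcome.
#' @export
classify_richness_response <- function(richness, metadata,
                                       outcomes = c("weight_kg", "fat_mass_kg", "vfa_cm2")) {
  md0 <- metadata[metadata$timepoint == "T0", ]
  md1 <- metadata[metadata$timepoint == "T12", ]
  subjects <- intersect(md0$subject, md1$subject)
  rows <- lapply(subjects, function(s) {
    s0 <- md0$sample_id[md0$subject == s]
    s1 <- md1$sample_id[md1$subject == s]
    if (!(s0 %in% names(richness)) || !(s1 %in% names(richness))) return(NULL)
    d <- unname(richness[s1] - richness[s0])
    out <- data.frame(subject = s, delta_richness = d,
                      class = if (d > 0) "gained" else if (d < 0) "lost" else "stable",
                      stringsAsFactors = FALSE)
    for (oc in outcomes) {
      v0 <- md0[[oc]][md0$subject == s]
      v1 <- md1[[oc]][md1$subject == s]
      out[[paste0("rel_", oc)]] <- (v1 - v0) / v0 * 100
    }
    out
  })
  dropped <- sum(vapply(rows, is.null, TRUE))
  if (dropped > 0)
    message(sprintf("classify_richness_response: excluded %d subject(s) with a missing timepoint", dropped))
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

#' Stratify subjects into low / high gene count groups
#'
#' Deterministic baseline stratum per subject: `"LGC"` when baseline gene
#' richness is strictly below the rule's boundary, `"HGC"` otherwise (ties
#' at the boundary go to HGC). The default rule is a cohort median split;
#' a fixed external threshold is supported via `threshold`.
#'
#' @param baseline_richness named per-subject baseline gene richness.
#' @param rule `"median"` or `"threshold"`.
#' @param threshold numeric boundary when `rule = "threshold"`.
#' @return named character vector of strata.
#' @export
stratify_lgc_hgc <- function(baseline_richness, rule = c("median", "threshold"),
                             threshold = NULL) {
  rule <- match.arg(rule)
  cut <- switch(rule,
    median = stats::median(baseline_richness),
    threshold = {
      if (is.null(threshold)) fail("stratify_lgc_hgc: 'threshold' rule needs a threshold")
      threshold
    })
  stats::setNames(ifelse(baseline_richness < cut, "LGC", "HGC"),
                  names(baseline_richness))
}
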