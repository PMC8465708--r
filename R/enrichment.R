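# Disease-enrichment analysis: sample/taxon filters, per-method enrichment
# criteria applied to differential-abundance tables, and the one-tailed
# two-proportion Z-test with continuity correction that asks whether
# histamine-secreting species are over-represented among disease-enriched
# species.

#' Filter a count table by library size and taxon rarity
#'
#' Samples with fewer than `min_library_size` total counts are removed
#' first (a sample at exactly the threshold is kept).  A taxon is then
#' retained iff its within-sample relative abundance reaches
#' `rare_rel_abundance` in at least `rare_sample_fraction` of the
#' remaining samples.
#'
#' @param table an `hdc_counts` object, see [count_table()].
#' @param min_library_size minimum total counts per sample (default 1e6).
#' @param rare_rel_abundance relative-abundance threshold (default 1e-4,
#'   i.e. 0.01 percent).
#' @param rare_sample_fraction fraction of samples in which the threshold
#'   must be reached (default 0.10).
#' @return the filtered `hdc_counts` object.
#' @export
filter_count_table <- function(table, min_library_size = 1e6,
                               rare_rel_abundance = 1e-4,
                               rare_sample_fraction = 0.10) {
  if (min_library_size <= 0 || rare_rel_abundance <= 0 ||
      rare_sample_fraction <= 0) {
    stop_hdc("filter parameters must be positive",
             class = "hdcminer_validation_error")
  }
  libsize <- colSums(table$counts)
  keep_s <- libsize >= min_library_size
  if (!any(keep_s)) {
    stop_hdc("all samples removed by the library-size filter",
             class = "hdcminer_validation_error")
  }
  counts <- table$counts[, keep_s, drop = FALSE]
  rel <- sweep(counts, 2L, colSums(counts), "/")
  frac <- rowMeans(rel >= rare_rel_abundance)
  keep_t <- frac >= rare_sample_fraction
  count_table(counts[keep_t, , drop = FALSE],
              table$meta[keep_s, , drop = FALSE])
}

#' Per-method enrichment criteria
#'
#' Thresholds deciding when a differential-abundance result counts as
#' disease-enriched, per method: `deseq2_like` log2FC > 1 and q < 0.05
#' (HMP2 variant: log2FC > 0.5); `maaslin2_like` coefficient > 0.2 and
#' q < 0.05 (HMP2 variant: > 0); `lefse_like` LDA > 2 and q < 0.001.
#' The built-in rank-sum routine uses the `deseq2_like` thresholds since
#' its effect is a log2 fold change.  All inequalities are strict.
#'
#' @param hmp2 use the HMP2 effect-size variants (default FALSE); in the
#'   source cohorts HMP2 is by far the largest study and was screened with
#'   relaxed effect thresholds.
#' @return named list of `(min_effect, max_q)` pairs, class
#'   `hdc_criteria`.
#' @export
enrich_criteria <- function(hmp2 = FALSE) {
  crit <- list(
    deseq2_like = c(min_effect = if (hmp2) 0.5 else 1.0, max_q = 0.05),
    maaslin2_like = c(min_effect = if (hmp2) 0.0 else 0.2, max_q = 0.05),
    lefse_like = c(min_effect = 2.0, max_q = 0.001)
  )
  crit$builtin <- crit$deseq2_like
  structure(crit, class = "hdc_criteria")
}

#' Flag disease-enriched species
#'
#' A species is enriched iff its result row has direction `disease`,
#' effect strictly above the method's `min_effect` and q-value strictly
#' below the method's `max_q`.
#'
#' @param results differential-abundance data frame with columns
#'   `species_id`, `method`, `effect`, `qvalue`, `direction`.
#' @param criteria an [enrich_criteria()] object (or named list with
#'   `min_effect`/`max_q` entries per method).
#' @return sorted character vector of enriched species identifiers.
#' @export
flag_enriched <- function(results, criteria = enrich_criteria()) {
  assert_columns(results, c("species_id", "method", "effect", "qvalue",
                            "direction"), "differential-abundance table")
  unknown <- setdiff(unique(results$method), names(criteria))
  if (length(unknown) > 0L) {
    stop_hdc("no enrichment criteria for method(s): ",
             paste(unknown, collapse = ", "),
             class = "hdcminer_validation_error")
  }
  min_effect <- vapply(criteria, `[[`, 0, "min_effect")[results$method]
  max_q <- vapply(criteria, `[[`, 0, "max_q")[results$method]
  hit <- results$direction == "disease" &
    results$effect > min_effect & results$qvalue < max_q
  sort(unique(results$species_id[hit]))
}

#' One-tailed two-proportion Z-test with continuity correction
#'
#' Tests whether the proportion `x1/n1` exceeds `x2/n2`.  With pooled
#' proportion pi = (x1+x2)/(n1+n2) and continuity correction
#' c = (1/n1 + 1/n2)/2, the difference d = x1/n1 - x2/n2 is shrunk
#' towards zero by c (clamped so the correction never flips its sign) and
#' standardised by sqrt(pi (1-pi) (1/n1 + 1/n2)).  The one-tailed p-value
#' is the upper-tail standard normal probability of z.  Degenerate pooled
#' proportions (0 or 1) give z = 0 and p = 0.5.
#'
#' @param x1,n1 successes and trials in the first group.
#' @param x2,n2 successes and trials in the second group.
#' @param alternative `"greater"` (default; first proportion larger),
#'   `"less"` or `"two.sided"`.
#' @return list with elements `z` and `p`.
#' @export
two_proportion_ztest <- function(x1, n1, x2, n2,
                                 alternative = c("greater", "less",
                                                 "two.sided")) {
  alternative <- match.arg(alternative)
  if (n1 <= 0 || n2 <= 0) {
    stop_hdc("group sizes must be positive",
             class = "hdcminer_validation_error")
  }
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) {
    stop_hdc("successes must lie in [0, n]",
             class = "hdcminer_validation_error")
  }
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled <= 0 || pooled >= 1) {
    z <- 0
  } else {
    d <- x1 / n1 - x2 / n2
    cc <- (1 / n1 + 1 / n2) / 2
    num <- sign(d) * max(abs(d) - cc, 0)
    z <- num / sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  }
  p <- switch(alternative,
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z),
              two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  list(z = z, p = p)
}

#' Convert a p-value to a significance label
#'
#' `n.s.` for p > 0.05; `*` for p <= 0.05; `**` for p <= 0.01; `***` for
#' p <= 0.001; `****` for p <= 0.0001 (boundaries inclusive toward more
#' asterisks).
#'
#' @param p p-value(s) in \[0, 1\].
#' @return character vector of labels.
#' @export
p_to_label <- function(p) {
  if (any(p < 0 | p > 1 | is.na(p))) {
    stop_hdc("p-value outside [0, 1]", class = "hdcminer_validation_error")
  }
  ifelse(p <= 1e-4, "****",
         ifelse(p <= 1e-3, "***",
                ifelse(p <= 0.01, "**",
                       ifelse(p <= 0.05, "*", "n.s."))))
}

#' Test over-representation of HSB among disease-enriched species
#'
#' Compares the proportion of disease-enriched species among
#' histamine-secreting species with the proportion among all tested
#' species (the HSB set is a subset of the reference set, as the original
#' comparison was framed); set `overlap = FALSE` for a sensitivity variant
#' comparing HSB against non-HSB species instead.
#'
#' @param enriched character vector of disease-enriched species, e.g. from
#'   [flag_enriched()].
#' @param hsb character vector of histamine-secreting species.
#' @param all_species character vector of all species tested.
#' @param study,method labels copied into the result row.
#' @param overlap keep HSB inside the reference group (default TRUE).
#' @return one-row data frame: `study`, `method`, `x_hsb`, `n_hsb`,
#'   `x_all`, `n_all`, `z`, `p_one_tailed`, `label`.
#' @export
hsb_enrichment_test <- function(enriched, hsb, all_species,
                                study = "study", method = "builtin",
                                overlap = TRUE) {
  hsb <- intersect(hsb, all_species)
  enriched <- intersect(enriched, all_species)
  ref <- if (overlap) all_species else setdiff(all_species, hsb)
  if (length(hsb) == 0L || length(ref) == 0L) {
    stop_hdc("empty comparison group",
             class = "hdcminer_validation_error")
  }
  x1 <- length(intersect(enriched, hsb))
  x2 <- length(intersect(enriched, ref))
  zt <- two_proportion_ztest(x1, length(hsb), x2, length(ref),
                             alternative = "greater")
  data.frame(study = study, method = method,
             x_hsb = x1, n_hsb = length(hsb),
             x_all = x2, n_all = length(ref),
             z = zt$z, p_one_tailed = zt$p, label = p_to_label(zt$p),
             stringsAsFactors = FALSE)
}

#' Built-in differential-abundance routine
#'
#' Simple plumbing used for fully synthetic end-to-end runs in place of
#' external DESeq2/MaAsLin2/LEfSe fits: per species, relative abundances
#' are compared between disease and control samples with a two-sided
#' Wilcoxon rank-sum test, p-values are Benjamini-Hochberg adjusted, and
#' the effect is `log2((mean_rel_disease + eps) / (mean_rel_control +
#' eps))` with `eps = 1e-6`; direction follows the sign of the effect.
#'
#' @param table a filtered `hdc_counts` object with at least two samples
#'   per condition.
#' @param eps pseudo-relative-abundance added to both means (default 1e-6).
#' @return data frame with columns `species_id`, `method` (`"builtin"`),
#'   `effect`, `pvalue`, `qvalue`, `direction`.
#' @export
builtin_da <- function(table, eps = 1e-6) {
  cond <- table$meta$condition
  if (sum(cond == "control") < 2L || sum(cond == "disease") < 2L) {
    stop_hdc("need at least two samples per condition",
             class = "hdcminer_validation_error")
  }
  rel <- sweep(table$counts, 2L, colSums(table$counts), "/")
  dis <- rel[, cond == "disease", drop = FALSE]
  ctl <- rel[, cond == "control", drop = FALSE]
  pvals <- vapply(seq_len(nrow(rel)), function(i) {
    x <- dis[i, ]
    y <- ctl[i, ]
    if (all(x == x[1L]) && all(y == y[1L]) && x[1L] == y[1L]) return(1)
    suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                        correct = TRUE)$p.value)
  }, 0)
  pvals[is.na(pvals)] <- 1
  effect <- log2((rowMeans(dis) + eps) / (rowMeans(ctl) + eps))
  data.frame(
    species_id = rownames(rel),
    method = "builtin",
    effect = effect,
    pvalue = pvals,
    qvalue = stats::p.adjust(pvals, method = "BH"),
    direction = ifelse(effect > 0, "disease", "control"),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
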