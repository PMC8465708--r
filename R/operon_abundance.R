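# Operon read-depth quantification in counts per million mapped reads
# (CPM) and one-sided rank-sum comparison of patients vs controls.

#' Compute operon abundance in counts per million mapped reads
#'
#' Drops samples with fewer than `min_total` total mapped reads (a sample
#' at exactly the threshold is kept), then computes
#' `cpm = reads_on_operon / total_mapped * 1e6` per remaining sample.
#' CPM is invariant to scaling both read counts by the same factor.
#'
#' @param counts data frame with columns `sample_id`, `condition`,
#'   `reads_on_operon`, `total_mapped` (see [read_operon_counts()]).
#' @param min_total minimum total mapped reads per sample (default 1e6).
#' @return the filtered data frame with an added `cpm` column.
#' @export
compute_cpm <- function(counts, min_total = 1e6) {
  assert_columns(counts, c("sample_id", "condition", "reads_on_operon",
                           "total_mapped"), "operon read counts")
  if (anyDuplicated(counts$sample_id)) {
    stop_hdc("duplicate sample_id in operon read counts",
             class = "hdcminer_validation_error")
  }
  if (any(counts$reads_on_operon > counts$total_mapped)) {
    stop_hdc("reads_on_operon exceeds total_mapped",
             class = "hdcminer_validation_error")
  }
  out <- counts[counts$total_mapped >= min_total, , drop = FALSE]
  out$cpm <- out$reads_on_operon / out$total_mapped * 1e6
  rownames(out) <- NULL
  out
}

#' One-sided rank-sum test (first group greater)
#'
#' Tests whether values in `x` tend to exceed values in `y`.  The
#' statistic is the rank sum W of `x` using midranks for ties.  For small
#' tie-free samples (`n1 + n2 <= exact_limit`) the one-sided p-value is
#' computed by exhaustive enumeration of all `choose(n1+n2, n1)` rank
#' assignments, `p = P(W' >= W)`; otherwise the normal approximation with
#' tie-corrected variance and a 0.5 continuity correction is used.
#'
#' @param x numeric values of the first group (e.g. disease CPM).
#' @param y numeric values of the second group (e.g. control CPM).
#' @param exact_limit largest `n1 + n2` for which exact enumeration is
#'   used when there are no ties (default 12).
#' @return list with `W` (rank sum of `x`), `p` (one-sided, `x` greater),
#'   and `method` (`"exact"` or `"normal"`).
#' @export
ranksum_one_sided <- function(x, y, exact_limit = 12L) {
  if (length(x) == 0L || length(y) == 0L) {
    stop_hdc("both groups must be non-empty",
             class = "hdcminer_validation_error")
  }
  n1 <- length(x)
  n2 <- length(y)
  nn <- n1 + n2
  r <- rank(c(x, y))  # midranks for ties
  W <- sum(r[seq_len(n1)])
  ties <- anyDuplicated(c(x, y)) > 0L
  if (!ties && nn <= exact_limit) {
    sets <- utils::combn(nn, n1)
    rs <- colSums(matrix(seq_len(nn)[sets], nrow = n1))
    return(list(W = W, p = mean(rs >= W), method = "exact"))
  }
  mu <- n1 * (nn + 1) / 2
  tie_tab <- table(r)
  sigma2 <- n1 * n2 / 12 *
    ((nn + 1) - sum(tie_tab^3 - tie_tab) / (nn * (nn - 1)))
  if (sigma2 <= 0) {
    # all observations identical: no evidence either way
    return(list(W = W, p = 0.5, method = "normal"))
  }
  z <- (W - mu - 0.5) / sqrt(sigma2)
  list(W = W, p = stats::pnorm(z, lower.tail = FALSE), method = "normal")
}

#' Compare operon CPM between disease and control samples
#'
#' Convenience wrapper: computes per-sample CPM with [compute_cpm()] and
#' runs [ranksum_one_sided()] with the disease group first.
#'
#' @inheritParams compute_cpm
#' @param study label copied into the result row.
#' @return list with `cpm` (per-sample data frame) and `test` (one-row
#'   data frame: `study`, `n_disease`, `n_control`, `W`, `p_one_sided`,
#'   `method`).
#' @export
operon_abundance_test <- function(counts, min_total = 1e6, study = "study") {
  cpm <- compute_cpm(counts, min_total = min_total)
  x <- cpm$cpm[cpm$condition == "disease"]
  y <- cpm$cpm[cpm$condition == "control"]
  if (length(x) == 0L || length(y) == 0L) {
    stop_hdc("a condition has no samples after the read-depth filter",
             class = "hdcminer_validation_error")
  }
  rs <- ranksum_one_sided(x, y)
  list(cpm = cpm,
       test = data.frame(study = study, n_disease = length(x),
                         n_control = length(y), W = rs$W,
                         p_one_sided = rs$p, method = rs$method,
                         stringsAsFactors = FALSE))
}
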