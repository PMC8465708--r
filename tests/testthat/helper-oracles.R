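# Independent oracles kept deliberately separate from the package code
# paths they check.

# Brute-force cluster enumeration: all subsets of role-bearing genes on a
# contig that (a) have at most max_intervening genes between consecutive
# members, (b) contain an hdcA and an antiporter themselves within the
# neighborhood distance, and (c) are maximal (no further role-bearing
# gene can be added without breaking (a)).  Returns a list of
# semicolon-joined gene_id strings, sorted, one per cluster.
oracle_clusters <- function(genes, roles, max_intervening) {
  hdca <- c("HDCA_PYR", "HDCA_PLP")
  out <- character(0)
  for (ct in split(seq_len(nrow(genes)),
                   paste(genes$genome_id, genes$contig_id))) {
    g <- genes[ct, , drop = FALSE]
    g <- g[order(g$ordinal), , drop = FALSE]
    rl <- roles$role[match(g$protein_id, roles$protein_id)]
    rl[is.na(rl)] <- "OTHER"
    cand <- which(rl != "OTHER")
    n <- length(cand)
    if (n < 2L) next
    adjacency_ok <- function(pos) {
      all(diff(g$ordinal[pos]) - 1L <= max_intervening)
    }
    has_seed <- function(pos) {
      hd <- g$ordinal[pos][rl[pos] %in% hdca]
      ap <- g$ordinal[pos][rl[pos] == "ANTIPORTER"]
      length(hd) > 0L && length(ap) > 0L &&
        min(abs(outer(hd, ap, "-"))) - 1L <= max_intervening
    }
    for (mask in seq_len(2^n - 1L)) {
      pick <- cand[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L]
      if (length(pick) < 2L) next
      if (!adjacency_ok(pick) || !has_seed(pick)) next
      extras <- setdiff(cand, pick)
      maximal <- !any(vapply(extras, function(e) {
        adjacency_ok(sort(c(pick, e)))
      }, logical(1L)))
      if (maximal) {
        out <- c(out, paste(g$gene_id[pick], collapse = ";"))
      }
    }
  }
  sort(unique(out))
}

# Reference two-proportion z via stats::prop.test (Yates-corrected
# chi-square; z is its signed square root, p its one-sided p-value).
oracle_ztest <- function(x1, n1, x2, n2) {
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled <= 0 || pooled >= 1) {
    return(list(z = 0, p = 0.5))
  }
  pt <- suppressWarnings(
    stats::prop.test(c(x1, x2), c(n1, n2), alternative = "greater",
                     correct = TRUE)
  )
  list(z = sign(x1 / n1 - x2 / n2) * sqrt(unname(pt$statistic)),
       p = unname(pt$p.value))
}

# Exact one-sided rank-sum p by exhaustive enumeration of group
# assignments over the pooled observations (tie-free data only).
oracle_ranksum_exact <- function(x, y) {
  n1 <- length(x)
  nn <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  ws <- apply(utils::combn(nn, n1), 2L, function(i) sum(r[i]))
  mean(ws >= w_obs)
}
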