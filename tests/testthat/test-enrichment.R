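test_that("library-size filter keeps the one-million boundary sample", {
  counts <- matrix(c(999999, 0, 1000000, 0, 2000000, 0), nrow = 2,
                   dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  ct <- make_counts(counts, c("control", "control", "disease"))
  f <- filter_count_table(ct, rare_sample_fraction = 1e-9)
  expect_setequal(colnames(f$counts), c("b", "c"))
})

test_that("rare-taxon filter applies relative abundance and sample fraction", {
  # 20 samples of 1e6 reads; taxon "rare_low" at 0.005% everywhere; taxon
  # "rare_occ" at 0.02% in 3/20 samples (15%) and 0 elsewhere.
  n <- 20
  base <- matrix(0, nrow = 3, ncol = n,
                 dimnames = list(c("common", "rare_occ", "rare_low"),
                                 sprintf("s%02d", 1:n)))
  base["rare_low", ] <- 50          # 0.005%
  base["rare_occ", 1:3] <- 200      # 0.02%
  base["common", ] <- 1e6 - colSums(base)
  ct <- make_counts(base, rep(c("control", "disease"), each = n / 2))
  f <- filter_count_table(ct)
  expect_setequal(rownames(f$counts), c("common", "rare_occ"))
})

test_that("a planted rare taxon is the only loss on a toy table", {
  # 10 species x 6 samples; one planted rare taxon -> 9 survive.
  set.seed(5)
  counts <- matrix(rpois(60, 2e5), nrow = 10,
                   dimnames = list(sprintf("sp%02d", 1:10),
                                   sprintf("s%d", 1:6)))
  counts["sp10", ] <- 3   # well below 0.01% of ~1.8M totals
  ct <- make_counts(counts, rep(c("control", "disease"), each = 3))
  f <- filter_count_table(ct)
  # independent brute-force re-application of the two filters
  keep_s <- colSums(counts) >= 1e6
  rel <- sweep(counts[, keep_s], 2, colSums(counts[, keep_s]), "/")
  keep_t <- rowMeans(rel >= 1e-4) >= 0.10
  expect_equal(rownames(f$counts), rownames(counts)[keep_t])
  expect_equal(nrow(f$counts), 9L)
})

test_that("filtering everything out is an explicit error", {
  counts <- matrix(10, 1, 2, dimnames = list("s1", c("a", "b")))
  ct <- make_counts(counts, c("control", "disease"))
  expect_error(filter_count_table(ct), "all samples removed")
})

da_row <- function(species, method, effect, q, direction = "disease") {
  data.frame(species_id = species, method = method, effect = effect,
             qvalue = q, direction = direction, stringsAsFactors = FALSE)
}

test_that("enrichment criteria apply strict per-method thresholds", {
  da <- rbind(
    da_row("a", "deseq2_like", 1.0, 0.01),          # boundary: NOT enriched
    da_row("b", "deseq2_like", 1.1, 0.04),          # enriched
    da_row("c", "deseq2_like", 1.1, 0.05),          # q boundary: NOT
    da_row("d", "maaslin2_like", 0.2, 0.01),        # boundary: NOT
    da_row("e", "maaslin2_like", 0.3, 0.04),        # enriched
    da_row("f", "lefse_like", 3.0, 0.01),           # q >= 0.001: NOT
    da_row("g", "lefse_like", 2.5, 5e-4),           # enriched
    da_row("h", "lefse_like", 2.0, 5e-4),           # LDA boundary: NOT
    da_row("i", "deseq2_like", 2.0, 0.01, "control") # wrong direction
  )
  expect_setequal(flag_enriched(da, enrich_criteria()), c("b", "e", "g"))
})

test_that("HMP2 variants relax the effect thresholds only", {
  da <- rbind(da_row("a", "deseq2_like", 0.6, 0.04),
              da_row("b", "maaslin2_like", 0.1, 0.04))
  expect_equal(flag_enriched(da, enrich_criteria()), character(0))
  expect_setequal(flag_enriched(da, enrich_criteria(hmp2 = TRUE)),
                  c("a", "b"))
})

test_that("unknown methods are rejected", {
  expect_error(flag_enriched(da_row("a", "ancom", 1, 0.01)),
               "no enrichment criteria")
})

test_that("relaxing criteria never shrinks the enriched set", {
  set.seed(31)
  da <- da_row(sprintf("sp%03d", 1:300), "deseq2_like",
               rnorm(300, 0.8, 0.6), runif(300, 0, 0.2),
               sample(c("disease", "control"), 300, replace = TRUE))
  strict <- enrich_criteria()
  for (i in 1:20) {
    relaxed <- strict
    relaxed$deseq2_like["min_effect"] <- runif(1, 0, 1)
    relaxed$deseq2_like["max_q"] <- runif(1, 0.05, 1)
    expect_true(all(flag_enriched(da, strict) %in%
                      flag_enriched(da, relaxed)))
  }
})

test_that("equal proportions give z = 0 and p = 0.5", {
  r <- two_proportion_ztest(5, 10, 50, 100)
  expect_equal(r$z, 0)
  expect_equal(r$p, 0.5)
})

test_that("extreme separation gives a vanishing one-tailed p", {
  r <- two_proportion_ztest(10, 10, 0, 100)
  expect_lt(r$p, 1e-6)
  expect_equal(r$z, oracle_ztest(10, 10, 0, 100)$z, tolerance = 1e-12)
})

test_that("the corrected z matches the reference implementation", {
  r <- two_proportion_ztest(12, 40, 30, 400)
  o <- oracle_ztest(12, 40, 30, 400)
  expect_equal(r$z, o$z, tolerance = 1e-12)
  expect_equal(r$p, o$p, tolerance = 1e-12)
  # frozen from the oracle
  expect_equal(r$z, 4.335277, tolerance = 1e-6)
  expect_equal(r$p, 7.27883e-06, tolerance = 1e-4)
})

test_that("degenerate pooled proportions fall back to z = 0, p = 0.5", {
  expect_equal(two_proportion_ztest(0, 10, 0, 20), list(z = 0, p = 0.5))
  expect_equal(two_proportion_ztest(10, 10, 20, 20), list(z = 0, p = 0.5))
})

test_that("swapping groups flips the sign of the uncorrected difference", {
  set.seed(8)
  for (i in 1:50) {
    n1 <- sample(2:50, 1); n2 <- sample(2:50, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    a <- two_proportion_ztest(x1, n1, x2, n2)
    b <- two_proportion_ztest(x2, n2, x1, n1)
    expect_equal(a$z, -b$z, tolerance = 1e-12)
  }
})

test_that("invalid inputs to the z-test raise validation errors", {
  expect_error(two_proportion_ztest(1, 0, 1, 10), "positive")
  expect_error(two_proportion_ztest(11, 10, 1, 10), "\\[0, n\\]")
})

test_that("p-values map to asterisk labels with inclusive boundaries", {
  expect_equal(p_to_label(c(0.05, 0.051, 1e-5, 0.01, 0.001, 1e-4, 0.3)),
               c("*", "n.s.", "****", "**", "***", "****", "n.s."))
  expect_error(p_to_label(1.2), "outside")
  expect_error(p_to_label(-0.1), "outside")
})

test_that("hsb_enrichment_test counts overlapping groups as framed", {
  res <- hsb_enrichment_test(enriched = c("a", "b", "c"),
                             hsb = c("a", "b", "x"),
                             all_species = c("a", "b", "c", "x", "y", "z"),
                             study = "s1", method = "m")
  expect_equal(res$x_hsb, 2L)
  expect_equal(res$n_hsb, 3L)
  expect_equal(res$x_all, 3L)
  expect_equal(res$n_all, 6L)
  expect_equal(res$label, p_to_label(res$p_one_tailed))
  # non-overlapping sensitivity variant
  res2 <- hsb_enrichment_test(c("a", "b", "c"), c("a", "b", "x"),
                              c("a", "b", "c", "x", "y", "z"),
                              overlap = FALSE)
  expect_equal(res2$n_all, 3L)
  expect_equal(res2$x_all, 1L)
})

test_that("builtin DA is flat for species identical across samples", {
  counts <- matrix(c(rep(1e6, 8), rep(c(2e6, 1e6), 4)), nrow = 2,
                   byrow = TRUE, dimnames = list(c("flat", "var"),
                                                 sprintf("s%d", 1:8)))
  counts["flat", ] <- 5e5
  ct <- make_counts(counts, rep(c("control", "disease"), each = 4))
  da <- builtin_da(ct)
  flat <- da[da$species_id == "flat", ]
  expect_gte(flat$qvalue, 0.05)
})

test_that("a planted 8-fold increase is flagged in nearly all replicates", {
  hits <- 0
  n_rep <- 200
  for (s in seq_len(n_rep)) {
    sim <- simulate_abundance(n_species = 20, n_hsb = 5, n_control = 30,
                              n_disease = 30, dispersion = 0.05,
                              planted_fold_change = 8,
                              fraction_hsb_affected = 0.2,
                              fraction_other_affected = 0,
                              seed = s)
    da <- builtin_da(sim$table)
    if (all(sim$affected %in% flag_enriched(da, enrich_criteria()))) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("permuting condition labels controls the q < 0.05 rate", {
  sim <- simulate_abundance(n_species = 50, n_hsb = 10, seed = 77)
  ct <- sim$table
  set.seed(99)
  n_sig <- 0L
  n_tests <- 0L
  for (i in 1:200) {
    perm <- ct
    perm$meta$condition <- sample(perm$meta$condition)
    da <- builtin_da(perm)
    n_sig <- n_sig + sum(da$qvalue < 0.05)
    n_tests <- n_tests + nrow(da)
  }
  expect_lte(n_sig / n_tests, 0.05)
})
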