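make_hit <- function(protein, profile, evalue, bitscore = 100) {
  data.frame(protein_id = protein, profile_id = profile, evalue = evalue,
             bitscore = bitscore, stringsAsFactors = FALSE)
}

test_that("role cutoffs are inclusive at the threshold", {
  th <- role_thresholds()
  # custom PLP profile: 1e-100 or less passes
  r <- call_roles(make_hit("p1", "HDC_PLP_custom", 1e-100), th)
  expect_equal(r$role, "HDCA_PLP")
  # pyruvoyl profile PF02329 at cutoff 1e-40: pass; just above: fail
  expect_equal(call_roles(make_hit("p2", "PF02329", 1e-41), th)$role,
               "HDCA_PYR")
  expect_equal(call_roles(make_hit("p3", "PF02329", 1e-39), th)$role,
               "OTHER")
  expect_equal(call_roles(make_hit("p4", "PF02329", 1e-40), th)$role,
               "HDCA_PYR")
})

test_that("the smallest passing e-value wins across profiles", {
  hits <- rbind(make_hit("p1", "PF02329", 1e-50),
                make_hit("p1", "PTHR42770", 1e-60))
  r <- call_roles(hits)
  expect_equal(r$role, "ANTIPORTER")
  expect_equal(r$best_evalue, 1e-60)
})

test_that("antiporter subtype comes from the winning profile only", {
  hits <- rbind(make_hit("p1", "AAXC_custom", 1e-55),
                make_hit("p2", "HDCB_custom", 1e-55))
  r <- call_roles(hits)
  expect_equal(r$antiporter_subtype[r$protein_id == "p1"], "aaxC")
  expect_true(is.na(r$antiporter_subtype[r$protein_id == "p2"]))
  expect_equal(r$role[r$protein_id == "p2"], "HDCB")
})

test_that("hits against unmapped profiles are ignored with a message", {
  hits <- rbind(make_hit("p1", "PF02329", 1e-50),
                make_hit("p1", "PF99999", 1e-200))
  expect_message(r <- call_roles(hits), "ignored")
  expect_equal(r$role, "HDCA_PYR")
})

test_that("near-threshold report lists failing hits within 10x of cutoff", {
  hits <- rbind(make_hit("p1", "PF02329", 5e-40),   # within 10x, failing
                make_hit("p2", "PF02329", 5e-38),   # far above
                make_hit("p3", "PF02329", 1e-41))   # passing
  nt <- near_threshold_hits(hits)
  expect_equal(nt$protein_id, "p1")
  expect_equal(nt$cutoff, 1e-40)
})

test_that("neighborhood rule: two intervening genes cluster, three do not", {
  fx <- make_contig(c("OTHER", "OTHER", "OTHER", "OTHER", "OTHER",
                      "HDCA_PYR", "OTHER", "OTHER", "ANTIPORTER", "OTHER"))
  cl <- find_clusters(fx$genes, fx$roles, max_intervening = 2)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$architecture, "hdcA_pyr/antiporter")
  expect_equal(cl$pathway, "PYR")

  fx3 <- make_contig(c("OTHER", "OTHER", "OTHER", "OTHER", "OTHER",
                       "HDCA_PYR", "OTHER", "OTHER", "OTHER", "ANTIPORTER"))
  expect_equal(nrow(find_clusters(fx3$genes, fx3$roles, max_intervening = 2)),
               0L)
})

test_that("hdcA and antiporter on different contigs never cluster", {
  fx <- bind_contigs(
    make_contig(c("OTHER", "HDCA_PYR", "OTHER"), contig = "c1"),
    make_contig(c("ANTIPORTER", "OTHER", "OTHER"), contig = "c2")
  )
  expect_equal(nrow(find_clusters(fx$genes, fx$roles)), 0L)
})

test_that("three-component arginine/histidine systems are flagged", {
  fx <- make_contig(c("OTHER", "ADIA", "ANTIPORTER", "HDCA_PYR", "OTHER"),
                    subtypes = c(NA, NA, "aaxC", NA, NA))
  cl <- find_clusters(fx$genes, fx$roles)
  expect_equal(nrow(cl), 1L)
  expect_true(cl$three_component)
  expect_equal(cl$architecture, "adiA/antiporter/hdcA_pyr")
  expect_equal(cl$member_subtypes, ".;aaxC;.")

  fx2 <- make_contig(c("AAXB", "ANTIPORTER", "HDCA_PYR"))
  cl2 <- find_clusters(fx2$genes, fx2$roles)
  expect_true(cl2$three_component)
  expect_equal(cl2$architecture, "aaxB/antiporter/hdcA_pyr")
})

test_that("antiporters flanking a PLP hdcA set duplicated_antiporter", {
  fx <- make_contig(c("ANTIPORTER", "HDCA_PLP", "ANTIPORTER"))
  cl <- find_clusters(fx$genes, fx$roles)
  expect_equal(nrow(cl), 1L)
  expect_true(cl$duplicated_antiporter)
  expect_equal(cl$pathway, "PLP")

  # two antiporters on the same side: not a duplication in the flag sense
  fx2 <- make_contig(c("ANTIPORTER", "ANTIPORTER", "HDCA_PLP"))
  expect_false(find_clusters(fx2$genes, fx2$roles)$duplicated_antiporter)
})

test_that("accessory genes extend clusters and set hdcB/hisRS flags", {
  fx <- make_contig(c("HDCA_PYR", "HDCB", "ANTIPORTER", "HISRS"))
  cl <- find_clusters(fx$genes, fx$roles)
  expect_equal(cl$architecture, "hdcA_pyr/hdcB/antiporter/hisRS")
  expect_true(cl$has_hdcB)
  expect_true(cl$has_hisRS)

  fx2 <- make_contig(c("HDCA_PYR", "ANTIPORTER", "HDCB"))
  cl2 <- find_clusters(fx2$genes, fx2$roles)
  expect_equal(cl2$architecture, "hdcA_pyr/antiporter/hdcB")
  expect_true(cl2$has_hdcB)
  expect_false(cl2$has_hisRS)
})

test_that("a lone decarboxylase or antiporter pair beyond reach is silent", {
  fx <- make_contig(c("HDCA_PYR", rep("OTHER", 6), "HISRS"))
  expect_equal(nrow(find_clusters(fx$genes, fx$roles)), 0L)
})

test_that("classify_architecture rejects invalid member sets", {
  expect_error(classify_architecture(c("HDCA_PYR", "HDCB")), "antiporter")
  expect_error(classify_architecture(c("ANTIPORTER", "HISRS")), "hdcA")
  expect_error(classify_architecture(c("HDCA_PYR", "OTHER", "ANTIPORTER")),
               "role-less")
})

random_contig_fixture <- function(n, p_other = 0.5) {
  pool <- c("HDCA_PYR", "HDCA_PLP", "ANTIPORTER", "HDCB", "HISRS",
            "ADIA", "AAXB")
  role_vec <- ifelse(stats::runif(n) < p_other, "OTHER",
                     sample(pool, n, replace = TRUE))
  make_contig(role_vec)
}

test_that("find_clusters matches brute-force enumeration on random contigs", {
  set.seed(42)
  for (i in 1:120) {
    fx <- random_contig_fixture(sample(2:12, 1))
    mi <- sample(0:3, 1)
    got <- find_clusters(fx$genes, fx$roles, max_intervening = mi)
    expect_equal(sort(got$member_gene_ids),
                 oracle_clusters(fx$genes, fx$roles, mi),
                 info = sprintf("case %d, max_intervening %d", i, mi))
  }
})

test_that("increasing max_intervening never loses clustered hdcA-antiporter pairs", {
  set.seed(7)
  for (i in 1:40) {
    fx <- random_contig_fixture(12)
    sizes <- vapply(0:4, function(mi) {
      cl <- find_clusters(fx$genes, fx$roles, max_intervening = mi)
      if (nrow(cl) == 0L) 0L else sum(cl$n_members)
    }, integer(1))
    expect_true(all(diff(sizes) >= 0))
  }
})

test_that("reversing gene order yields the same clusters mirrored", {
  set.seed(13)
  for (i in 1:30) {
    fx <- random_contig_fixture(10)
    fwd <- find_clusters(fx$genes, fx$roles)
    rev_genes <- fx$genes
    span <- max(fx$genes$end) + 1000L
    new_start <- span - rev_genes$end
    rev_genes$end <- span - rev_genes$start
    rev_genes$start <- new_start
    rev_genes <- assign_ordinals(rev_genes)
    bwd <- find_clusters(rev_genes, fx$roles)
    expect_equal(nrow(fwd), nrow(bwd))
    if (nrow(fwd) > 0L) {
      fwd_members <- strsplit(fwd$member_gene_ids, ";")
      bwd_members <- lapply(strsplit(bwd$member_gene_ids, ";"), rev)
      expect_setequal(
        vapply(fwd_members, paste, "", collapse = ";"),
        vapply(bwd_members, paste, "", collapse = ";")
      )
    }
  }
})
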