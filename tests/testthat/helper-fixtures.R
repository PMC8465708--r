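# Fixture builders used across test files.

# Build a single-contig gene table plus a matching role-call table from a
# vector of role codes by ordinal position ("OTHER" = role-less filler).
make_contig <- function(role_vec, genome = "g1", contig = "c1",
                        subtypes = NULL) {
  n <- length(role_vec)
  ids <- sprintf("%s_%s_g%02d", genome, contig, seq_len(n))
  genes <- data.frame(
    gene_id = ids, genome_id = genome, contig_id = contig,
    start = seq_len(n) * 1000L, end = seq_len(n) * 1000L + 500L,
    strand = "+", protein_id = ids, stringsAsFactors = FALSE
  )
  genes <- assign_ordinals(genes)
  roles <- data.frame(
    protein_id = ids, role = role_vec,
    antiporter_subtype = if (is.null(subtypes)) NA_character_ else subtypes,
    best_evalue = ifelse(role_vec == "OTHER", NA_real_, 1e-50),
    stringsAsFactors = FALSE
  )
  list(genes = genes, roles = roles)
}

# Stack several make_contig() fixtures into one gene/role table pair.
bind_contigs <- function(...) {
  parts <- list(...)
  list(genes = assign_ordinals(do.call(rbind, lapply(parts, `[[`, "genes"))),
       roles = do.call(rbind, lapply(parts, `[[`, "roles")))
}

# Small count-table fixture with explicit library sizes.
make_counts <- function(counts, condition, study = "toy") {
  meta <- data.frame(sample_id = colnames(counts), study = study,
                     condition = condition, stringsAsFactors = FALSE)
  count_table(counts, meta)
}
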