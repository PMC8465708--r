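# Readers and writers for the standard-format inputs of the pipeline:
# GFF3 genome annotations, HMMER3 per-domain tabular output ("domtblout"),
# genome-to-species maps, count tables, differential-abundance tables and
# per-sample operon read counts.  All coordinates are 1-based inclusive
# (the GFF3 convention); no half-open conversion is ever exposed.

#' Read gene annotations from a GFF3 file
#'
#' Parses features of the requested type (CDS by default) into a gene table,
#' groups genes by genome and contig, sorts them by start coordinate (ties
#' broken by end, then by gene identifier) and assigns per-contig ordinals
#' starting at 0.  The ordinal is the substrate of the gene-neighborhood
#' rule used by [find_clusters()]: the number of genes intervening between
#' two genes on one contig is the difference of their ordinals minus one.
#'
#' The genome identifier is taken from the `genome_id` attribute when
#' present, otherwise from the `##genome-id` pragma, otherwise the file
#' name sans extension.  The gene identifier comes from the `ID` or
#' `locus_tag` attribute; the protein identifier from `protein_id`,
#' falling back to the gene identifier.
#'
#' @param path path to a GFF3 file.
#' @param feature_type feature type(s) to keep (column 3), default `"CDS"`.
#' @return A data frame with columns `gene_id`, `genome_id`, `contig_id`,
#'   `start`, `end`, `strand`, `ordinal`, `protein_id`, sorted by genome,
#'   contig and ordinal.  Empty input yields a zero-row frame with the
#'   same columns.
#' @seealso [write_gff3()] for the inverse operation.
#' @export
read_gff3 <- function(path, feature_type = "CDS") {
  if (!file.exists(path)) {
    stop_hdc("GFF3 file not found: ", path,
             class = "hdcminer_validation_error")
  }
  lines <- readLines(path, warn = FALSE)
  default_genome <- sub("\\.[^.]*$", "", basename(path))
  pragma <- grep("^##genome-id\\s", lines, value = TRUE)
  if (length(pragma) > 0L) {
    default_genome <- sub("^##genome-id\\s+", "", pragma[1L])
  }
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(empty_gene_table())
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- idx[which(nf != 9L)[1L]]
    stop_hdc("malformed GFF3 line ", bad, ": expected 9 tab-separated ",
             "fields, got ", nf[which(nf != 9L)[1L]],
             class = "hdcminer_parse_error")
  }
  m <- do.call(rbind, fields)
  type_ok <- m[, 3L] %in% feature_type
  m <- m[type_ok, , drop = FALSE]
  line_no <- idx[type_ok]
  if (nrow(m) == 0L) {
    return(empty_gene_table())
  }
  start <- suppressWarnings(as.integer(m[, 4L]))
  end <- suppressWarnings(as.integer(m[, 5L]))
  if (anyNA(start) || anyNA(end)) {
    bad <- line_no[which(is.na(start) | is.na(end))[1L]]
    stop_hdc("malformed GFF3 line ", bad, ": non-integer coordinate",
             class = "hdcminer_parse_error")
  }
  if (any(end < start)) {
    bad <- line_no[which(end < start)[1L]]
    stop_hdc("invalid GFF3 line ", bad, ": end < start",
             class = "hdcminer_validation_error")
  }
  attr_field <- m[, 9L]
  genes <- data.frame(
    gene_id = gff3_attribute(attr_field, c("ID", "locus_tag")),
    genome_id = gff3_attribute(attr_field, "genome_id",
                               default = default_genome),
    contig_id = m[, 1L],
    start = start,
    end = end,
    strand = m[, 7L],
    stringsAsFactors = FALSE
  )
  if (anyNA(genes$gene_id)) {
    bad <- line_no[which(is.na(genes$gene_id))[1L]]
    stop_hdc("GFF3 line ", bad, ": feature lacks ID/locus_tag attribute",
             class = "hdcminer_parse_error")
  }
  genes$protein_id <- gff3_attribute(attr_field, "protein_id")
  genes$protein_id[is.na(genes$protein_id)] <- genes$gene_id[is.na(genes$protein_id)]
  assign_ordinals(genes)
}

empty_gene_table <- function() {
  data.frame(gene_id = character(), genome_id = character(),
             contig_id = character(), start = integer(), end = integer(),
             strand = character(), ordinal = integer(),
             protein_id = character(), stringsAsFactors = FALSE)
}

gff3_attribute <- function(attrs, keys, default = NA_character_) {
  out <- rep(NA_character_, length(attrs))
  for (key in keys) {
    pat <- paste0("(?:^|;)\\s*", key, "=([^;]*)")
    m <- regexpr(pat, attrs, perl = TRUE)
    has <- m > 0L
    val <- rep(NA_character_, length(attrs))
    val[has] <- sub(pat, "\\1", regmatches(attrs, m), perl = TRUE)
    fill <- is.na(out) & has
    out[fill] <- val[fill]
  }
  out[is.na(out)] <- default
  out
}

#' Assign per-contig gene ordinals
#'
#' Sorts genes by genome, contig and start coordinate (ties broken by end,
#' then gene identifier) and numbers them 0, 1, 2, ... within each contig.
#' Ordinals are therefore invariant to input row order.
#'
#' @param genes gene data frame (ordinal column, if present, is recomputed).
#' @return The sorted gene data frame with an `ordinal` column.
#' @export
assign_ordinals <- function(genes) {
  assert_columns(genes, c("gene_id", "genome_id", "contig_id", "start", "end"),
                 "gene table")
  key <- paste(genes$genome_id, genes$contig_id, genes$start, genes$end,
               genes$gene_id)
  if (anyDuplicated(key)) {
    stop_hdc("duplicate gene: identical (genome, contig, start, end, gene_id)",
             class = "hdcminer_validation_error")
  }
  o <- order(genes$genome_id, genes$contig_id, genes$start, genes$end,
             genes$gene_id, method = "radix")
  genes <- genes[o, , drop = FALSE]
  grp <- paste(genes$genome_id, genes$contig_id, sep = "\r")
  genes$ordinal <- stats::ave(seq_len(nrow(genes)), grp,
                              FUN = function(i) seq_along(i) - 1L)
  rownames(genes) <- NULL
  genes
}

#' Write gene annotations to GFF3
#'
#' Emits one CDS feature per gene with `ID`, `protein_id` and `genome_id`
#' attributes, such that [read_gff3()] round-trips genes and ordinals
#' exactly.
#'
#' @param genes gene data frame as returned by [read_gff3()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  assert_columns(genes, c("gene_id", "genome_id", "contig_id", "start",
                          "end", "strand", "protein_id"), "gene table")
  lines <- c("##gff-version 3",
             sprintf("%s\thdcminer\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;protein_id=%s;genome_id=%s",
                     genes$contig_id, genes$start, genes$end, genes$strand,
                     genes$gene_id, genes$protein_id, genes$genome_id))
  writeLines(lines, path)
  invisible(path)
}

#' Read HMMER3 per-domain tabular output (domtblout)
#'
#' Parses the whitespace-delimited table hmmscan writes with
#' `--domtblout`: `#` lines are comments; the first 22 fields are fixed,
#' everything after is free-text description.  One hit record per data row
#' is returned; multiple rows per protein are retained.  The e-value kept
#' is the full-sequence e-value (field 7), hmmscan's headline statistic.
#'
#' @param path path to a domtblout file.
#' @return data frame with columns `protein_id`, `profile_id`, `evalue`,
#'   `bitscore`.  A comment-only file yields a zero-row frame.
#' @export
read_domtblout <- function(path) {
  if (!file.exists(path)) {
    stop_hdc("domtblout file not found: ", path,
             class = "hdcminer_validation_error")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(data.frame(protein_id = character(), profile_id = character(),
                      evalue = double(), bitscore = double(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 22L)) {
    bad <- idx[which(nf < 22L)[1L]]
    stop_hdc("malformed domtblout line ", bad, ": fewer than 22 fields",
             class = "hdcminer_parse_error")
  }
  # domtblout layout: 1 target name, 2 target accession, ... 4 query name,
  # ... 7 full-sequence E-value, 8 full-sequence score.  hmmscan puts the
  # profile in the target column and the protein in the query column.
  target <- vapply(fields, `[`, "", 1L)
  query <- vapply(fields, `[`, "", 4L)
  evalue <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 7L)))
  bitscore <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 8L)))
  if (anyNA(evalue)) {
    bad <- idx[which(is.na(evalue))[1L]]
    stop_hdc("malformed domtblout line ", bad, ": non-numeric e-value",
             class = "hdcminer_parse_error")
  }
  if (any(evalue < 0)) {
    bad <- idx[which(evalue < 0)[1L]]
    stop_hdc("invalid domtblout line ", bad, ": negative e-value",
             class = "hdcminer_validation_error")
  }
  data.frame(protein_id = query, profile_id = target, evalue = evalue,
             bitscore = bitscore, stringsAsFactors = FALSE)
}

#' Write domain hits in domtblout dialect
#'
#' Writes the minimal whitespace-delimited table [read_domtblout()] parses
#' back: profile as target (field 1), protein as query (field 4),
#' full-sequence e-value (field 7) and score (field 8); remaining fixed
#' fields are padded with `-` or 0.
#'
#' @param hits data frame with columns `protein_id`, `profile_id`,
#'   `evalue`, `bitscore`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_domtblout <- function(hits, path) {
  assert_columns(hits, c("protein_id", "profile_id", "evalue", "bitscore"),
                 "hit table")
  header <- c("# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
              "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------")
  rows <- sprintf("%s - 100 %s - 100 %.3g %.1f 0.0 1 1 %.3g %.3g %.1f 0.0 1 100 1 100 1 100 0.90 -",
                  hits$profile_id, hits$protein_id, hits$evalue,
                  hits$bitscore, hits$evalue, hits$evalue, hits$bitscore)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a genome-to-species map
#'
#' @param path TSV with columns `genome_id`, `species_id`, `lineage`
#'   (semicolon-joined taxon labels, domain to species).
#' @return data frame with one row per genome.  A genome listed twice with
#'   the same species is deduplicated; with conflicting species it is an
#'   error, since every genome must map to exactly one species.
#' @export
read_species_map <- function(path) {
  map <- read_tsv_strict(path, "species map")
  assert_columns(map, c("genome_id", "species_id"), "species map")
  if (is.null(map$lineage)) map$lineage <- NA_character_
  map <- unique(map[, c("genome_id", "species_id", "lineage")])
  dup <- duplicated(map$genome_id)
  if (any(dup)) {
    stop_hdc("genome(s) mapped to conflicting species: ",
             paste(unique(map$genome_id[dup]), collapse = ", "),
             class = "hdcminer_validation_error")
  }
  rownames(map) <- NULL
  map
}

#' Read a species-by-sample count table with metadata
#'
#' @param counts_path TSV whose first column is `species_id` and remaining
#'   columns are per-sample counts.
#' @param meta_path TSV with columns `sample_id`, `study`, `condition`
#'   (condition is `control` or `disease`).
#' @return a count-table object; see [count_table()].
#' @export
read_count_table <- function(counts_path, meta_path) {
  tab <- read_tsv_strict(counts_path, "count table")
  assert_columns(tab, "species_id", "count table")
  counts <- as.matrix(tab[, setdiff(names(tab), "species_id"), drop = FALSE])
  rownames(counts) <- tab$species_id
  storage.mode(counts) <- "double"
  meta <- read_tsv_strict(meta_path, "sample metadata")
  count_table(counts, meta)
}

#' Construct and validate a count-table object
#'
#' Bundles a species-by-sample count matrix with per-sample metadata.
#' All counts must be non-negative and every sample column must have a
#' metadata row with a `control`/`disease` condition.
#'
#' @param counts numeric matrix, species in rows, samples in columns.
#' @param meta data frame with columns `sample_id`, `study`, `condition`.
#' @return list with elements `counts` and `meta`, class `hdc_counts`.
#' @export
count_table <- function(counts, meta) {
  assert_columns(meta, c("sample_id", "condition"), "sample metadata")
  if (is.null(meta$study)) meta$study <- "unknown"
  if (any(counts < 0)) {
    stop_hdc("negative counts in count table",
             class = "hdcminer_validation_error")
  }
  missing <- setdiff(colnames(counts), meta$sample_id)
  if (length(missing) > 0L) {
    stop_hdc("samples without metadata: ", paste(missing, collapse = ", "),
             class = "hdcminer_validation_error")
  }
  bad <- setdiff(unique(meta$condition), c("control", "disease"))
  if (length(bad) > 0L) {
    stop_hdc("unknown condition label(s): ", paste(bad, collapse = ", "),
             class = "hdcminer_validation_error")
  }
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(counts = counts, meta = meta), class = "hdc_counts")
}

#' @export
print.hdc_counts <- function(x, ...) {
  cat(sprintf("count table: %d species x %d samples (%d control, %d disease)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$meta$condition == "control"),
              sum(x$meta$condition == "disease")))
  invisible(x)
}

#' Read a differential-abundance result table
#'
#' @param path TSV with columns `species_id`, `method`, `effect`, `qvalue`,
#'   `direction` (method is one of `deseq2_like`, `maaslin2_like`,
#'   `lefse_like`, `builtin`; effect is the method's native scale —
#'   log2 fold change, model coefficient or LDA score).
#' @return validated data frame.
#' @export
read_da_table <- function(path) {
  da <- read_tsv_strict(path, "differential-abundance table")
  assert_columns(da, c("species_id", "method", "effect", "qvalue", "direction"),
                 "differential-abundance table")
  if (any(da$qvalue < 0 | da$qvalue > 1, na.rm = TRUE)) {
    stop_hdc("qvalue outside [0, 1]", class = "hdcminer_validation_error")
  }
  da
}

#' Read per-sample operon read counts
#'
#' @param path TSV with columns `sample_id`, `condition`,
#'   `reads_on_operon`, `total_mapped`.
#' @return validated data frame (reads_on_operon must not exceed
#'   total_mapped).
#' @export
read_operon_counts <- function(path) {
  oc <- read_tsv_strict(path, "operon read counts")
  assert_columns(oc, c("sample_id", "condition", "reads_on_operon",
                       "total_mapped"), "operon read counts")
  if (any(oc$reads_on_operon > oc$total_mapped)) {
    stop_hdc("reads_on_operon exceeds total_mapped",
             class = "hdcminer_validation_error")
  }
  if (any(oc$reads_on_operon < 0 | oc$total_mapped < 0)) {
    stop_hdc("negative read counts", class = "hdcminer_validation_error")
  }
  oc
}
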