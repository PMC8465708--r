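# End-to-end orchestration: simulate (or read) inputs, call roles, mine
# clusters, summarise species prevalence, run the differential-abundance
# plumbing and the HSB enrichment Z-test, quantify operon CPM, and write
# TSV reports plus a JSON run manifest.

#' Build a pipeline configuration
#'
#' Collects every tunable of the pipeline in one list.  When
#' `simulate = TRUE` all inputs are generated with the synthetic-data
#' module; otherwise the `*_path` entries must point to files in the
#' formats the readers in this package consume.  The accession list in
#' `seed_profiles` records the curated seed sequences behind the custom
#' PLP-dependent hdcA profile; it is metadata only and is never executed.
#'
#' @param out_dir directory for reports and the manifest.
#' @param seed integer master seed for all synthetic stages.
#' @param simulate generate inputs synthetically (default TRUE).
#' @param genome_spec species spec for [simulate_genomes()]
#'   (default [demo_genome_spec()]).
#' @param abundance_args list of overrides for [simulate_abundance()].
#' @param thresholds [role_thresholds()] object.
#' @param max_intervening neighborhood rule, see [find_clusters()].
#' @param hsb_threshold prevalence cutoff, see [summarize_species()].
#' @param min_library_size,rare_rel_abundance,rare_sample_fraction
#'   count-table filters, see [filter_count_table()].
#' @param criteria [enrich_criteria()] object.
#' @param length_weight operon length fraction for
#'   [simulate_operon_reads()].
#' @param gff_path,hits_path,species_map_path,counts_path,meta_path,operon_counts_path
#'   input files used when `simulate = FALSE`.
#' @return list of class `hdc_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("hdcminer_run_"),
                            seed = 1L,
                            simulate = TRUE,
                            genome_spec = demo_genome_spec(),
                            abundance_args = list(),
                            thresholds = role_thresholds(),
                            max_intervening = 2L,
                            hsb_threshold = 0.5,
                            min_library_size = 1e6,
                            rare_rel_abundance = 1e-4,
                            rare_sample_fraction = 0.10,
                            criteria = enrich_criteria(),
                            length_weight = 0.002,
                            gff_path = NULL, hits_path = NULL,
                            species_map_path = NULL, counts_path = NULL,
                            meta_path = NULL, operon_counts_path = NULL) {
  structure(list(
    out_dir = out_dir, seed = as.integer(seed), simulate = simulate,
    genome_spec = genome_spec, abundance_args = abundance_args,
    thresholds = thresholds, max_intervening = max_intervening,
    hsb_threshold = hsb_threshold, min_library_size = min_library_size,
    rare_rel_abundance = rare_rel_abundance,
    rare_sample_fraction = rare_sample_fraction, criteria = criteria,
    length_weight = length_weight,
    gff_path = gff_path, hits_path = hits_path,
    species_map_path = species_map_path, counts_path = counts_path,
    meta_path = meta_path, operon_counts_path = operon_counts_path,
    seed_profiles = c("WP_191935110.1", "WP_068969528.1",
                      "WP_152135723.1", "WP_136342781.1")
  ), class = "hdc_config")
}

#' Run the full pipeline
#'
#' Executes annotation input, role calling, cluster mining, species
#' prevalence, count-table filtering, differential abundance, the HSB
#' enrichment Z-test and operon CPM analysis in order; writes one TSV
#' report per stage plus `manifest.json` into `config$out_dir`; and
#' returns the results.  Reruns with the same configuration and seed are
#' identical.
#'
#' @param config an [pipeline_config()] object.
#' @param quiet suppress per-stage log lines (default FALSE).
#' @return invisibly, a list with `clusters`, `prevalence`, `da`,
#'   `enrichment`, `operon`, `truth` (synthetic runs only) and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  log_line <- function(...) if (!quiet) message("[hdcminer] ", ...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  truth <- NULL
  if (config$simulate) {
    log_line("simulating genomes (seed ", config$seed, ")")
    sim <- simulate_genomes(config$genome_spec,
                            thresholds = config$thresholds,
                            seed = config$seed)
    genes <- sim$genes
    hits <- sim$hits
    species_map <- sim$species_map
    truth <- sim$truth
    ab_args <- utils::modifyList(list(seed = config$seed),
                                 config$abundance_args)
    ab <- do.call(simulate_abundance, ab_args)
    tab <- ab$table
    hsb_label <- ab$hsb
    operon_counts <- simulate_operon_reads(tab, hsb_label,
                                           length_weight = config$length_weight,
                                           seed = config$seed)
  } else {
    log_line("reading inputs")
    genes <- read_gff3(config$gff_path)
    hits <- read_domtblout(config$hits_path)
    species_map <- read_species_map(config$species_map_path)
    tab <- read_count_table(config$counts_path, config$meta_path)
    operon_counts <- if (!is.null(config$operon_counts_path)) {
      read_operon_counts(config$operon_counts_path)
    }
    hsb_label <- NULL
  }

  roles <- call_roles(hits, config$thresholds)
  clusters <- find_clusters(genes, roles,
                            max_intervening = config$max_intervening)
  log_line(nrow(clusters), " cluster(s) in ",
           length(unique(genes$genome_id)), " genome(s)")
  prevalence <- summarize_species(clusters, species_map, genes,
                                  hsb_threshold = config$hsb_threshold)
  hsb <- hsb_species(prevalence)
  log_line(length(hsb), " HSB species of ", nrow(prevalence))

  filtered <- filter_count_table(tab,
                                 min_library_size = config$min_library_size,
                                 rare_rel_abundance = config$rare_rel_abundance,
                                 rare_sample_fraction = config$rare_sample_fraction)
  da <- builtin_da(filtered)
  enriched <- flag_enriched(da, config$criteria)
  # In synthetic runs the HSB labels of the abundance table are the ones
  # the table was generated with; in real runs they come from prevalence.
  test_hsb <- hsb_label %||% hsb
  enrichment <- hsb_enrichment_test(enriched, test_hsb,
                                    rownames(filtered$counts),
                                    study = filtered$meta$study[1L])
  log_line("enrichment z = ", signif(enrichment$z, 4), ", p = ",
           signif(enrichment$p_one_tailed, 4))

  operon <- NULL
  if (!is.null(operon_counts)) {
    operon <- operon_abundance_test(operon_counts,
                                    min_total = config$min_library_size,
                                    study = filtered$meta$study[1L])
  }

  write_report(clusters, file.path(config$out_dir, "clusters.tsv"))
  write_report(prevalence, file.path(config$out_dir, "species_prevalence.tsv"))
  write_report(da, file.path(config$out_dir, "differential_abundance.tsv"))
  write_report(enrichment, file.path(config$out_dir, "enrichment.tsv"))
  nearmiss <- near_threshold_hits(hits, config$thresholds)
  write_report(nearmiss, file.path(config$out_dir, "near_threshold_hits.tsv"))
  if (!is.null(truth)) {
    write_report(truth, file.path(config$out_dir, "truth_clusters.tsv"))
  }
  if (!is.null(operon)) {
    write_report(operon$cpm, file.path(config$out_dir, "operon_cpm.tsv"))
    write_report(operon$test, file.path(config$out_dir, "operon_test.tsv"))
  }

  manifest <- list(
    seed = config$seed,
    simulate = config$simulate,
    n_genomes = length(unique(genes$genome_id)),
    n_genes = nrow(genes),
    n_hits = nrow(hits),
    n_clusters = nrow(clusters),
    n_truth_clusters = if (!is.null(truth)) nrow(truth) else NA,
    n_species = nrow(prevalence),
    n_hsb = length(hsb),
    n_species_tested = nrow(filtered$counts),
    n_samples_tested = ncol(filtered$counts),
    n_enriched = length(enriched),
    enrichment_z = enrichment$z,
    enrichment_p = enrichment$p_one_tailed,
    operon_p = if (!is.null(operon)) operon$test$p_one_sided else NA,
    max_intervening = config$max_intervening,
    hsb_threshold = config$hsb_threshold,
    seed_profiles = config$seed_profiles
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("reports written to ", config$out_dir)
  invisible(list(clusters = clusters, prevalence = prevalence, da = da,
                 enrichment = enrichment, operon = operon, truth = truth,
                 manifest = manifest))
}
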