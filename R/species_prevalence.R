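# Species-level aggregation of per-genome cluster presence.
#
# A species is called histamine-secreting (HSB) when more than half of
# its genomes carry a decarboxylase-antiporter cluster; the inequality is
# strict, so a species with clusters in exactly half of its genomes is
# strain-specific, not HSB.

#' Summarise cluster presence per species
#'
#' Counts, for every species with at least one annotated genome, how many
#' genomes carry at least one cluster (a genome with several clusters
#' counts once), computes the strain prevalence, collects the decarboxylase
#' pathways present across the species' clusters, and sets two mutually
#' exclusive flags: `is_hsb` (prevalence strictly above `hsb_threshold`)
#' and `is_strain_specific` (some but at most `hsb_threshold` of genomes
#' carry the cluster).
#'
#' @param clusters cluster table from [find_clusters()].
#' @param species_map data frame from [read_species_map()].
#' @param genes gene table covering every screened genome (genomes without
#'   clusters must appear here to enter the denominator).
#' @param hsb_threshold prevalence above which a species is called
#'   histamine-secreting (default 0.5).
#' @return data frame with columns `species_id`, `lineage`, `n_genomes`,
#'   `n_with_cluster`, `prevalence`, `pathways_present` (comma-joined
#'   subset of PYR, PLP), `is_hsb`, `is_strain_specific`.
#' @export
summarize_species <- function(clusters, species_map, genes,
                              hsb_threshold = 0.5) {
  assert_columns(species_map, c("genome_id", "species_id"), "species map")
  genomes <- unique(genes$genome_id)
  unmapped <- setdiff(genomes, species_map$genome_id)
  if (length(unmapped) > 0L) {
    stop_hdc("genome(s) missing from species map: ",
             paste(unmapped, collapse = ", "),
             class = "hdcminer_validation_error")
  }
  if (nrow(clusters) > 0L) {
    stray <- setdiff(clusters$genome_id, genomes)
    if (length(stray) > 0L) {
      stop_hdc("cluster(s) from genome(s) absent from annotations: ",
               paste(stray, collapse = ", "),
               class = "hdcminer_validation_error")
    }
  }
  map <- species_map[match(genomes, species_map$genome_id), , drop = FALSE]
  species <- sort(unique(map$species_id))
  genome_has <- genomes %in% unique(clusters$genome_id)
  cl_species <- map$species_id[match(clusters$genome_id, map$genome_id)]

  res <- lapply(species, function(sp) {
    in_sp <- map$species_id == sp
    n <- sum(in_sp)
    k <- sum(genome_has[in_sp])
    pw <- clusters$pathway[cl_species == sp]
    pw[pw == "BOTH"] <- "PYR,PLP"
    pw_set <- sort(intersect(c("PYR", "PLP"),
                             unique(unlist(strsplit(pw, ",", fixed = TRUE)))),
                   decreasing = TRUE)
    lineage <- map$lineage[in_sp][1L] %||% NA_character_
    data.frame(
      species_id = sp,
      lineage = lineage,
      n_genomes = n,
      n_with_cluster = k,
      prevalence = k / n,
      pathways_present = paste(pw_set, collapse = ","),
      is_hsb = k / n > hsb_threshold,
      is_strain_specific = k > 0L & k / n <= hsb_threshold,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Histamine-secreting species identifiers
#'
#' @param prevalence output of [summarize_species()].
#' @return character vector of species with `is_hsb` set.
#' @export
hsb_species <- function(prevalence) {
  prevalence$species_id[prevalence$is_hsb]
}
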