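# Seeded generators for every input the pipeline consumes: annotated
# genomes with planted decarboxylase-antiporter operons and decoy hits,
# overdispersed species count tables with planted disease effects, and
# per-sample operon read counts.  All randomness flows from a single
# integer seed; each generator derives its own substream so outputs are
# reproducible independently of call order.

# Derive a substream seed (< 2^31) from a base seed and a stage tag.
substream_seed <- function(seed, stage) {
  offs <- c(genomes = 101L, abundance = 211L, operon = 307L,
            pipeline = 401L)
  if (!stage %in% names(offs)) stop_hdc("unknown seed stage: ", stage)
  (as.integer(seed) %% 1000000L) * 1000L + offs[[stage]]
}

#' Demo genome simulation specification
#'
#' Five species of six strains each, covering the architecture space the
#' miner must distinguish: a plain pyruvoyl cluster with hdcB, both
#' three-component arginine/histidine systems (adiA and aaxB variants),
#' a strain-specific species at exactly half prevalence, a
#' duplicated-antiporter PLP cluster, and a four-gene
#' hdcA/hdcB/antiporter/hisRS cluster.
#'
#' @return data frame accepted by [simulate_genomes()].
#' @export
demo_genome_spec <- function() {
  data.frame(
    species_id = sprintf("species%d", 1:5),
    n_strains = 6L,
    operon_prevalence = c(1, 2 / 3, 0.5, 1, 5 / 6),
    architecture = c("hdcA_pyr/antiporter/hdcB",
                     "adiA/antiporter/hdcA_pyr",
                     "aaxB/antiporter/hdcA_pyr",
                     "antiporter/hdcA_plp/antiporter",
                     "hdcA_pyr/hdcB/antiporter/hisRS"),
    antiporter_subtype = c("gadC", "aaxC", "aaxC", "adiC", "gadC"),
    stringsAsFactors = FALSE
  )
}

#' Simulate annotated genomes with planted operons
#'
#' For each species, exactly `round(n_strains * operon_prevalence)` strains
#' (chosen at random) receive one planted cluster with the requested
#' architecture; consecutive members are separated by 0 to
#' `max_member_gap` decoy genes.  Planted member proteins receive hits
#' that pass the role thresholds, with e-values drawn log-uniformly in
#' `[cutoff * 1e-20, cutoff]` so threshold boundaries are exercised.
#' Decoy genes receive either no hit or a failing hit above the cutoff;
#' a fraction `near_threshold_fraction` of failing hits falls within 10x
#' of the cutoff (the review band of [near_threshold_hits()]), the rest
#' far above it.  Identifiers follow the scheme
#' `<species>_strain<M>` / `<genome>_g<K>`.
#'
#' @param species_spec data frame with columns `species_id`, `n_strains`,
#'   `operon_prevalence`, `architecture` (slash-joined role labels, must
#'   include an hdcA and an antiporter) and optionally
#'   `antiporter_subtype` (gadC, aaxC or adiC).
#' @param genes_per_contig genes per (single-contig) genome, default 30.
#' @param decoy_hit_fraction fraction of non-member genes receiving a
#'   failing decoy hit, default 0.3.
#' @param near_threshold_fraction fraction of failing hits within 10x of
#'   the cutoff, default 0 (noiseless regime).
#' @param max_member_gap maximum decoys between consecutive members,
#'   default 2.
#' @param thresholds [role_thresholds()] object supplying cutoffs and the
#'   profile map used to assign planted hits.
#' @param seed integer seed.
#' @return list with `genes`, `hits`, `species_map` and `truth` (one row
#'   per planted cluster: genome, contig, architecture, pathway,
#'   member gene ids).
#' @export
simulate_genomes <- function(species_spec,
                             genes_per_contig = 30L,
                             decoy_hit_fraction = 0.3,
                             near_threshold_fraction = 0,
                             max_member_gap = 2L,
                             thresholds = role_thresholds(),
                             seed = 1L) {
  assert_columns(species_spec, c("species_id", "n_strains",
                                 "operon_prevalence", "architecture"),
                 "species spec")
  if (is.null(species_spec$antiporter_subtype)) {
    species_spec$antiporter_subtype <- NA_character_
  }
  if (any(species_spec$operon_prevalence < 0 |
          species_spec$operon_prevalence > 1)) {
    stop_hdc("operon_prevalence must lie in [0, 1]",
             class = "hdcminer_validation_error")
  }
  arch_roles <- lapply(strsplit(species_spec$architecture, "/", fixed = TRUE),
                       label_role)
  ok <- vapply(arch_roles, function(r) {
    any(r %in% HDCA_ROLES) && any(r == "ANTIPORTER")
  }, logical(1L))
  if (!all(ok)) {
    stop_hdc("architecture must contain an hdcA and an antiporter: ",
             paste(species_spec$architecture[!ok], collapse = ", "),
             class = "hdcminer_validation_error")
  }
  set.seed(substream_seed(seed, "genomes"))
  cutoffs <- profile_cutoffs(thresholds)
  pm <- thresholds$profile_map

  genes <- list()
  hits <- list()
  truth <- list()
  map <- list()
  for (s in seq_len(nrow(species_spec))) {
    sp <- species_spec$species_id[s]
    n <- species_spec$n_strains[s]
    k <- round(n * species_spec$operon_prevalence[s])
    carriers <- sort(sample.int(n, k))
    roles <- arch_roles[[s]]
    map[[s]] <- data.frame(
      genome_id = sprintf("%s_strain%02d", sp, seq_len(n)),
      species_id = sp,
      lineage = sprintf("d__Bacteria;p__SimPhylum;g__SimGenus;s__%s", sp),
      stringsAsFactors = FALSE
    )
    for (m in seq_len(n)) {
      genome <- sprintf("%s_strain%02d", sp, m)
      g <- simulate_one_genome(
        genome, genes_per_contig,
        roles = if (m %in% carriers) roles else NULL,
        subtype = species_spec$antiporter_subtype[s],
        decoy_hit_fraction = decoy_hit_fraction,
        near_threshold_fraction = near_threshold_fraction,
        max_member_gap = max_member_gap,
        cutoffs = cutoffs, profile_map = pm
      )
      genes[[length(genes) + 1L]] <- g$genes
      if (nrow(g$hits) > 0L) hits[[length(hits) + 1L]] <- g$hits
      if (!is.null(g$truth)) {
        g$truth$species_id <- sp
        truth[[length(truth) + 1L]] <- g$truth
      }
    }
  }
  genes <- assign_ordinals(do.call(rbind, genes))
  hits <- if (length(hits) > 0L) do.call(rbind, hits)
          else data.frame(protein_id = character(), profile_id = character(),
                          evalue = double(), bitscore = double(),
                          stringsAsFactors = FALSE)
  truth <- if (length(truth) > 0L) do.call(rbind, truth)
           else data.frame(genome_id = character(), contig_id = character(),
                           architecture = character(), pathway = character(),
                           member_gene_ids = character(),
                           species_id = character(), stringsAsFactors = FALSE)
  rownames(hits) <- rownames(truth) <- NULL
  list(genes = genes, hits = hits, species_map = do.call(rbind, map),
       truth = truth)
}

# One single-contig genome; plants `roles` at a random locus when not NULL.
simulate_one_genome <- function(genome, n_genes, roles, subtype,
                                decoy_hit_fraction, near_threshold_fraction,
                                max_member_gap, cutoffs, profile_map) {
  lengths <- sample(900:1500, n_genes, replace = TRUE)
  gaps <- sample(50:200, n_genes, replace = TRUE)
  start <- cumsum(c(1L, (lengths + gaps)[-n_genes]))
  gene_id <- sprintf("%s_g%03d", genome, seq_len(n_genes))
  genes <- data.frame(
    gene_id = gene_id, genome_id = genome, contig_id = "contig1",
    start = start, end = start + lengths - 1L,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    protein_id = gene_id, stringsAsFactors = FALSE
  )
  member_pos <- integer(0)
  truth <- NULL
  if (!is.null(roles)) {
    nm <- length(roles)
    gapseq <- sample_member_gaps(roles, max_member_gap)
    span <- nm + sum(gapseq)
    if (span > n_genes) {
      stop_hdc("contig too short for requested architecture",
               class = "hdcminer_validation_error")
    }
    first <- sample.int(n_genes - span + 1L, 1L)
    member_pos <- first + cumsum(c(0L, gapseq + 1L))
    flags <- classify_architecture(roles)
    truth <- data.frame(
      genome_id = genome, contig_id = "contig1",
      architecture = flags$architecture, pathway = flags$pathway,
      member_gene_ids = paste(gene_id[member_pos], collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  hits <- list()
  for (i in seq_along(member_pos)) {
    prof <- role_profile(roles[i], subtype, profile_map)
    cut <- cutoffs[[prof]]
    ev <- 10^stats::runif(1L, log10(cut) - 20, log10(cut))
    hits[[length(hits) + 1L]] <- data.frame(
      protein_id = gene_id[member_pos[i]], profile_id = prof,
      evalue = ev, bitscore = round(200 - 1.5 * log10(ev), 1),
      stringsAsFactors = FALSE
    )
  }
  decoys <- setdiff(seq_len(n_genes), member_pos)
  hit_decoys <- decoys[stats::runif(length(decoys)) < decoy_hit_fraction]
  for (d in hit_decoys) {
    prof <- sample(profile_map$profile_id, 1L)
    cut <- cutoffs[[prof]]
    ev <- if (stats::runif(1L) < near_threshold_fraction) {
      10^stats::runif(1L, log10(cut), log10(cut) + 1)  # within 10x of cutoff
    } else {
      10^stats::runif(1L, log10(cut) + 2, min(log10(cut) + 20, 0))
    }
    ev <- max(ev, cut * 1.0000001)  # failing, never exactly at cutoff
    hits[[length(hits) + 1L]] <- data.frame(
      protein_id = gene_id[d], profile_id = prof,
      evalue = ev, bitscore = round(30 - 2 * log10(ev), 1),
      stringsAsFactors = FALSE
    )
  }
  list(genes = genes,
       hits = if (length(hits) > 0L) do.call(rbind, hits)
              else data.frame(protein_id = character(),
                              profile_id = character(), evalue = double(),
                              bitscore = double(), stringsAsFactors = FALSE),
       truth = truth)
}

# Sample decoy gaps between consecutive members such that the planted
# layout still satisfies the neighborhood seed rule: some hdcA and some
# antiporter must end up with at most max_member_gap intervening genes
# (members between them count as intervening).  Rejection-samples gap
# vectors; an architecture where even all-zero gaps cannot satisfy the
# rule is impossible to plant and raises an error.
sample_member_gaps <- function(roles, max_member_gap) {
  nm <- length(roles)
  if (nm == 1L) return(integer(0))
  positions <- function(gaps) cumsum(c(1L, gaps + 1L))
  seed_ok <- function(gaps) {
    pos <- positions(gaps)
    hd <- pos[roles %in% HDCA_ROLES]
    ap <- pos[roles == "ANTIPORTER"]
    min(abs(outer(hd, ap, "-"))) - 1L <= max_member_gap
  }
  if (!seed_ok(rep(0L, nm - 1L))) {
    stop_hdc("architecture cannot satisfy the neighborhood rule even ",
             "with adjacent members", class = "hdcminer_validation_error")
  }
  for (attempt in 1:100) {
    gaps <- sample(0:max_member_gap, nm - 1L, replace = TRUE)
    if (seed_ok(gaps)) return(gaps)
  }
  rep(0L, nm - 1L)
}

# Pick the profile conferring a role (subtype-specific for antiporters).
role_profile <- function(role, subtype, profile_map) {
  cand <- profile_map[profile_map$role == role, , drop = FALSE]
  if (role == "ANTIPORTER" && !is.na(subtype)) {
    sub <- cand[!is.na(cand$antiporter_subtype) &
                  cand$antiporter_subtype == subtype, , drop = FALSE]
    if (nrow(sub) > 0L) cand <- sub
  } else if (role == "ANTIPORTER") {
    cand <- cand[is.na(cand$antiporter_subtype), , drop = FALSE]
  }
  if (nrow(cand) == 0L) {
    stop_hdc("no profile confers role ", role,
             class = "hdcminer_validation_error")
  }
  cand$profile_id[1L]
}

#' Simulate an overdispersed species count table with planted effects
#'
#' Counts follow a negative-binomial model: species baseline abundances
#' are log-normal, library sizes vary log-normally around
#' `library_size_mean`, and in disease samples the abundance of affected
#' species is multiplied by `planted_fold_change` (per-sample species
#' weights are renormalised, as sequencing observes proportions).  The
#' first `n_hsb` species are labelled histamine-secreting; exactly
#' `round(fraction_hsb_affected * n_hsb)` of them and
#' `round(fraction_other_affected * (n_species - n_hsb))` of the others
#' are affected.  A fold change of 1 plants nothing: the truth list is
#' empty by construction.
#'
#' @param n_species number of species (default 200).
#' @param n_hsb number of histamine-secreting species (default 40).
#' @param n_control,n_disease samples per condition (default 30 each).
#' @param library_size_mean mean library size (default 5e6 reads, so that
#'   the 1-million-read filter rarely bites).
#' @param library_size_sdlog log-scale sd of library sizes (default 0.25).
#' @param baseline_sdlog log-scale sd of species baseline abundances
#'   (default 1.5).
#' @param dispersion negative-binomial dispersion (NB size = 1/dispersion;
#'   default 0.3, typical of stool metagenome species counts).
#' @param planted_fold_change multiplicative disease effect (default 1,
#'   i.e. a null table).
#' @param fraction_hsb_affected fraction of HSB species affected
#'   (default 0.5).
#' @param fraction_other_affected fraction of non-HSB species affected
#'   (default 0.05).
#' @param seed integer seed.
#' @return list with `table` (an `hdc_counts` object), `hsb` (species
#'   labelled HSB) and `affected` (species with a planted effect).
#' @export
simulate_abundance <- function(n_species = 200L, n_hsb = 40L,
                               n_control = 30L, n_disease = 30L,
                               library_size_mean = 5e6,
                               library_size_sdlog = 0.25,
                               baseline_sdlog = 1.5,
                               dispersion = 0.3,
                               planted_fold_change = 1,
                               fraction_hsb_affected = 0.5,
                               fraction_other_affected = 0.05,
                               seed = 1L) {
  if (n_hsb > n_species) {
    stop_hdc("n_hsb cannot exceed n_species",
             class = "hdcminer_validation_error")
  }
  if (planted_fold_change < 1) {
    stop_hdc("planted_fold_change must be >= 1",
             class = "hdcminer_validation_error")
  }
  set.seed(substream_seed(seed, "abundance"))
  species <- sprintf("sp%03d", seq_len(n_species))
  hsb <- species[seq_len(n_hsb)]
  other <- setdiff(species, hsb)
  affected <- character(0)
  if (planted_fold_change > 1) {
    affected <- c(sample(hsb, round(fraction_hsb_affected * n_hsb)),
                  sample(other, round(fraction_other_affected *
                                        length(other))))
  }
  base <- stats::rlnorm(n_species, meanlog = 0, sdlog = baseline_sdlog)
  names(base) <- species
  w_control <- base / sum(base)
  w_disease <- base *
    ifelse(species %in% affected, planted_fold_change, 1)
  w_disease <- w_disease / sum(w_disease)

  n_samples <- n_control + n_disease
  cond <- c(rep("control", n_control), rep("disease", n_disease))
  libsize <- round(stats::rlnorm(n_samples, log(library_size_mean),
                                 library_size_sdlog))
  counts <- matrix(0, nrow = n_species, ncol = n_samples,
                   dimnames = list(species,
                                   sprintf("sample%03d", seq_len(n_samples))))
  for (j in seq_len(n_samples)) {
    w <- if (cond[j] == "disease") w_disease else w_control
    counts[, j] <- stats::rnbinom(n_species, mu = w * libsize[j],
                                  size = 1 / dispersion)
  }
  meta <- data.frame(sample_id = colnames(counts), study = "sim",
                     condition = cond, stringsAsFactors = FALSE)
  list(table = count_table(counts, meta), hsb = hsb,
       affected = sort(affected))
}

#' Simulate per-sample operon read counts from a count table
#'
#' For each sample, the total mapped reads equal the sample's library
#' size, and the reads mapped to the operon are binomial with success
#' probability `length_weight` times the summed relative abundance of the
#' operon-bearing (HSB) species — `length_weight` being the fraction of an
#' operon-bearing genome the operon occupies (a few kb of a few Mb, hence
#' the default 0.002).  Expected operon reads scale linearly with the
#' weight.
#'
#' @param table an `hdc_counts` object.
#' @param hsb character vector of operon-bearing species.
#' @param length_weight operon-to-genome length fraction (> 0, <= 1).
#' @param seed integer seed.
#' @return data frame with columns `sample_id`, `condition`,
#'   `reads_on_operon`, `total_mapped`.
#' @export
simulate_operon_reads <- function(table, hsb, length_weight = 0.002,
                                  seed = 1L) {
  if (length_weight <= 0 || length_weight > 1) {
    stop_hdc("length_weight must lie in (0, 1]",
             class = "hdcminer_validation_error")
  }
  set.seed(substream_seed(seed, "operon"))
  total <- colSums(table$counts)
  in_hsb <- rownames(table$counts) %in% hsb
  rel_hsb <- if (any(in_hsb)) {
    colSums(table$counts[in_hsb, , drop = FALSE]) / pmax(total, 1)
  } else rep(0, ncol(table$counts))
  prob <- pmin(rel_hsb * length_weight, 1)
  data.frame(
    sample_id = colnames(table$counts),
    condition = table$meta$condition,
    reads_on_operon = stats::rbinom(length(total), size = round(total),
                                    prob = prob),
    total_mapped = round(total),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
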