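# Role assignment from profile-HMM hits and detection of histidine
# decarboxylase / antiporter gene clusters by the gene-neighborhood rule.
#
# Two unrelated hdcA families are recognised: the pyruvoyl-dependent
# enzyme (Pfam PF02329) and the PLP-dependent enzyme (matched by a custom
# profile built from curated seed sequences).  Antiporters are matched by
# PANTHER PTHR42770 or by subtype-specific profiles (gadC, aaxC, adiC).
# Accessory roles: hdcB (maturation factor of the pyruvoyl enzyme), hisRS
# (histidyl-tRNA synthetase) and the arginine decarboxylases adiA
# (PLP-dependent) and aaxB (pyruvoyl-dependent), whose co-location with
# hdcA and a shared antiporter forms a three-component decarboxylation
# system.

HDC_ROLES <- c("HDCA_PYR", "HDCA_PLP", "ANTIPORTER", "HDCB", "HISRS",
               "ADIA", "AAXB", "OTHER")
HDCA_ROLES <- c("HDCA_PYR", "HDCA_PLP")

ROLE_LABELS <- c(HDCA_PYR = "hdcA_pyr", HDCA_PLP = "hdcA_plp",
                 ANTIPORTER = "antiporter", HDCB = "hdcB", HISRS = "hisRS",
                 ADIA = "adiA", AAXB = "aaxB")

#' Role label <-> role code conversion
#'
#' Architecture strings use the field's lower-case gene labels
#' (`hdcA_pyr`, `antiporter`, `adiA`, ...); internally roles are upper-case
#' codes.  These helpers convert between the two.
#'
#' @param roles character vector of role codes (e.g. `"HDCA_PYR"`).
#' @return `role_label()`: the label vector; `label_role()`: the code vector.
#' @export
role_label <- function(roles) {
  out <- unname(ROLE_LABELS[roles])
  if (anyNA(out)) {
    stop_hdc("unknown role code(s): ",
             paste(setdiff(roles, names(ROLE_LABELS)), collapse = ", "),
             class = "hdcminer_validation_error")
  }
  out
}

#' @rdname role_label
#' @param labels character vector of labels (e.g. `"hdcA_pyr"`).
#' @export
label_role <- function(labels) {
  inv <- stats::setNames(names(ROLE_LABELS), ROLE_LABELS)
  out <- unname(inv[labels])
  if (anyNA(out)) {
    stop_hdc("unknown role label(s): ",
             paste(setdiff(labels, ROLE_LABELS), collapse = ", "),
             class = "hdcminer_validation_error")
  }
  out
}

#' Default profile-to-role map
#'
#' Maps profile identifiers to gene roles, the antiporter subtype carried
#' by each antiporter profile, and the threshold class applied to hits
#' against it.  `HDC_PLP_custom` stands for the curated PLP-dependent
#' hdcA profile (threshold class `plp`, cutoff 1e-100 by default);
#' `PF02329` is the Pfam pyruvoyl hdcA profile and `PTHR42770` the PANTHER
#' antiporter profile (both class `pyr`/`antiporter`, cutoff 1e-40);
#' subtype-specific antiporter profiles and accessory-gene profiles use
#' the `accessory`/`antiporter` class (cutoff 1e-40).
#'
#' @return data frame with columns `profile_id`, `role`,
#'   `antiporter_subtype`, `threshold_class`.
#' @export
default_profile_map <- function() {
  data.frame(
    profile_id = c("HDC_PLP_custom", "PF02329", "PTHR42770",
                   "GADC_custom", "AAXC_custom", "ADIC_custom",
                   "HDCB_custom", "HISRS_custom", "ADIA_custom",
                   "AAXB_custom"),
    role = c("HDCA_PLP", "HDCA_PYR", "ANTIPORTER",
             "ANTIPORTER", "ANTIPORTER", "ANTIPORTER",
             "HDCB", "HISRS", "ADIA", "AAXB"),
    antiporter_subtype = c(NA, NA, NA, "gadC", "aaxC", "adiC",
                           NA, NA, NA, NA),
    threshold_class = c("plp", "pyr", "antiporter", "antiporter",
                        "antiporter", "antiporter", "accessory",
                        "accessory", "accessory", "accessory"),
    stringsAsFactors = FALSE
  )
}

#' Role-calling e-value thresholds
#'
#' A hit confers a role when its full-sequence e-value is at or below the
#' cutoff of its profile's threshold class: 1e-100 for the custom
#' PLP-dependent hdcA profile, 1e-40 for the pyruvoyl hdcA profile
#' (PF02329), the antiporter profiles and the accessory-gene profiles.
#' Cutoffs are inclusive ("1e-100 or less" passes).
#'
#' @param plp_hdca_max_evalue cutoff for the PLP-dependent hdcA profile.
#' @param pyr_hdca_max_evalue cutoff for the pyruvoyl-dependent hdcA
#'   profile.
#' @param antiporter_max_evalue cutoff for antiporter profiles.
#' @param accessory_max_evalue cutoff for hdcB/hisRS/adiA/aaxB profiles.
#' @param profile_map profile-to-role map, see [default_profile_map()].
#' @return object of class `hdc_thresholds`.
#' @export
role_thresholds <- function(plp_hdca_max_evalue = 1e-100,
                            pyr_hdca_max_evalue = 1e-40,
                            antiporter_max_evalue = 1e-40,
                            accessory_max_evalue = 1e-40,
                            profile_map = default_profile_map()) {
  cutoffs <- c(plp = plp_hdca_max_evalue, pyr = pyr_hdca_max_evalue,
               antiporter = antiporter_max_evalue,
               accessory = accessory_max_evalue)
  if (any(cutoffs <= 0)) {
    stop_hdc("all e-value cutoffs must be > 0",
             class = "hdcminer_validation_error")
  }
  assert_columns(profile_map, c("profile_id", "role", "antiporter_subtype",
                                "threshold_class"), "profile map")
  bad <- setdiff(profile_map$threshold_class, names(cutoffs))
  if (length(bad) > 0L) {
    stop_hdc("unknown threshold class(es): ", paste(bad, collapse = ", "),
             class = "hdcminer_validation_error")
  }
  structure(list(cutoffs = cutoffs, profile_map = profile_map),
            class = "hdc_thresholds")
}

profile_cutoffs <- function(thresholds) {
  pm <- thresholds$profile_map
  stats::setNames(unname(thresholds$cutoffs[pm$threshold_class]),
                  pm$profile_id)
}

#' Assign gene roles from domain hits
#'
#' For each protein, hits against profiles in the map are filtered to
#' those passing their profile's e-value cutoff (inclusive); among passing
#' hits the smallest e-value wins (ties broken by higher bit score, then
#' profile identifier), and the protein takes the winning profile's role
#' and, for antiporters, its subtype.  Proteins with hits but no passing
#' hit are assigned role `OTHER`.  Hits against profiles absent from the
#' map are ignored (a message reports how many).
#'
#' @param hits data frame from [read_domtblout()].
#' @param thresholds an [role_thresholds()] object.
#' @return data frame with columns `protein_id`, `role`,
#'   `antiporter_subtype`, `best_evalue` (NA when role is `OTHER`).
#' @export
call_roles <- function(hits, thresholds = role_thresholds()) {
  assert_columns(hits, c("protein_id", "profile_id", "evalue", "bitscore"),
                 "hit table")
  pm <- thresholds$profile_map
  known <- hits$profile_id %in% pm$profile_id
  if (any(!known)) {
    message(sum(!known), " hit(s) against profiles outside the role map ignored")
  }
  hits <- hits[known, , drop = FALSE]
  proteins <- unique(hits$protein_id)
  out <- data.frame(protein_id = proteins, role = "OTHER",
                    antiporter_subtype = NA_character_,
                    best_evalue = NA_real_, stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(out)
  cutoff <- profile_cutoffs(thresholds)[hits$profile_id]
  pass <- hits[hits$evalue <= cutoff, , drop = FALSE]
  if (nrow(pass) == 0L) return(out)
  o <- order(pass$protein_id, pass$evalue, -pass$bitscore, pass$profile_id,
             method = "radix")
  pass <- pass[o, , drop = FALSE]
  win <- pass[!duplicated(pass$protein_id), , drop = FALSE]
  i <- match(win$protein_id, out$protein_id)
  j <- match(win$profile_id, pm$profile_id)
  out$role[i] <- pm$role[j]
  out$antiporter_subtype[i] <- ifelse(pm$role[j] == "ANTIPORTER",
                                      pm$antiporter_subtype[j], NA_character_)
  out$best_evalue[i] <- win$evalue
  out
}

#' Report hits near their e-value cutoff
#'
#' Deterministic replacement for manual hit curation: lists failing hits
#' whose e-value is within `fold` of the relevant cutoff, so a reviewer
#' can inspect borderline calls.
#'
#' @param hits data frame from [read_domtblout()].
#' @param thresholds an [role_thresholds()] object.
#' @param fold width of the review band above the cutoff (default 10).
#' @return subset of `hits` with added `cutoff` column.
#' @export
near_threshold_hits <- function(hits, thresholds = role_thresholds(),
                                fold = 10) {
  pm <- thresholds$profile_map
  hits <- hits[hits$profile_id %in% pm$profile_id, , drop = FALSE]
  cutoff <- profile_cutoffs(thresholds)[hits$profile_id]
  near <- hits$evalue > cutoff & hits$evalue <= cutoff * fold
  out <- hits[near, , drop = FALSE]
  out$cutoff <- unname(cutoff[near])
  rownames(out) <- NULL
  out
}

#' Detect decarboxylase-antiporter gene clusters
#'
#' Implements the gene-neighborhood rule: an hdcA gene (either family) and
#' an antiporter gene on the same contig with at most `max_intervening`
#' genes between them seed a cluster ("less than three genes away" means
#' at most two intervening genes under the default).  Each seed is
#' extended greedily with any role-bearing gene (any role except `OTHER`)
#' within `max_intervening` intervening genes of a current member, and
#' overlapping seeds are merged, so the emitted clusters are maximal runs
#' of role-bearing genes whose consecutive gaps never exceed
#' `max_intervening` and which contain at least one hdcA-antiporter pair
#' within the neighborhood distance.  Strand is ignored; clusters never
#' span contigs.
#'
#' @param genes gene table from [read_gff3()] (ordinals assigned).
#' @param roles role calls from [call_roles()].
#' @param max_intervening maximum number of genes allowed between cluster
#'   members (default 2).
#' @return data frame with one row per cluster: `cluster_id`, `genome_id`,
#'   `contig_id`, `start`, `end`, `n_members`, `member_gene_ids` and
#'   `member_roles` (semicolon-joined, ordinal order),
#'   `member_subtypes`, `architecture` (slash-joined role labels),
#'   `pathway` (`PYR`, `PLP` or `BOTH`), and logical flags `has_hdcB`,
#'   `has_hisRS`, `three_component`, `duplicated_antiporter`.
#' @export
find_clusters <- function(genes, roles, max_intervening = 2L) {
  if (max_intervening < 0) {
    stop_hdc("max_intervening must be >= 0",
             class = "hdcminer_validation_error")
  }
  assert_columns(genes, c("gene_id", "genome_id", "contig_id", "ordinal",
                          "start", "end", "protein_id"), "gene table")
  assert_columns(roles, c("protein_id", "role"), "role table")
  genes <- genes[order(genes$genome_id, genes$contig_id, genes$ordinal,
                       method = "radix"), , drop = FALSE]
  ri <- match(genes$protein_id, roles$protein_id)
  generole <- ifelse(is.na(ri), "OTHER", roles$role[ri])
  subtype <- ifelse(is.na(ri), NA_character_, roles$antiporter_subtype[ri])

  out <- list()
  for (ct in split(seq_len(nrow(genes)),
                   paste(genes$genome_id, genes$contig_id, sep = "\r"))) {
    member <- ct[generole[ct] != "OTHER"]
    if (length(member) < 2L) next
    ords <- genes$ordinal[member]
    runs <- cumsum(c(0L, diff(ords) - 1L > max_intervening))
    for (run in split(member, runs)) {
      rr <- generole[run]
      oo <- genes$ordinal[run]
      hd <- oo[rr %in% HDCA_ROLES]
      ap <- oo[rr == "ANTIPORTER"]
      if (length(hd) == 0L || length(ap) == 0L) next
      if (min(abs(outer(hd, ap, "-"))) - 1L > max_intervening) next
      out[[length(out) + 1L]] <-
        cluster_record(genes[run, , drop = FALSE], rr, subtype[run])
    }
  }
  clusters <- if (length(out) == 0L) empty_cluster_table()
              else do.call(rbind, out)
  if (nrow(clusters) > 0L) {
    clusters <- clusters[order(clusters$genome_id, clusters$contig_id,
                               clusters$start, method = "radix"), ,
                         drop = FALSE]
    clusters$cluster_id <- sprintf("cluster%04d", seq_len(nrow(clusters)))
    clusters <- clusters[, c("cluster_id", setdiff(names(clusters),
                                                   "cluster_id"))]
  }
  rownames(clusters) <- NULL
  clusters
}

cluster_record <- function(member_genes, member_roles, member_subtypes) {
  flags <- classify_architecture(member_roles)
  data.frame(
    genome_id = member_genes$genome_id[1L],
    contig_id = member_genes$contig_id[1L],
    start = min(member_genes$start),
    end = max(member_genes$end),
    n_members = nrow(member_genes),
    member_gene_ids = paste(member_genes$gene_id, collapse = ";"),
    member_roles = paste(member_roles, collapse = ";"),
    member_subtypes = paste(ifelse(is.na(member_subtypes), ".",
                                   member_subtypes), collapse = ";"),
    architecture = flags$architecture,
    pathway = flags$pathway,
    has_hdcB = flags$has_hdcB,
    has_hisRS = flags$has_hisRS,
    three_component = flags$three_component,
    duplicated_antiporter = flags$duplicated_antiporter,
    stringsAsFactors = FALSE
  )
}

empty_cluster_table <- function() {
  data.frame(cluster_id = character(), genome_id = character(),
             contig_id = character(), start = integer(), end = integer(),
             n_members = integer(), member_gene_ids = character(),
             member_roles = character(), member_subtypes = character(),
             architecture = character(), pathway = character(),
             has_hdcB = logical(), has_hisRS = logical(),
             three_component = logical(), duplicated_antiporter = logical(),
             stringsAsFactors = FALSE)
}

#' Classify the architecture of a gene cluster
#'
#' Given member roles in ordinal order, builds the architecture string
#' (slash-joined role labels, e.g. `adiA/antiporter/hdcA_pyr`) and sets
#' the layout flags: `pathway` from the hdcA families present (`PYR`,
#' `PLP` or `BOTH`); `has_hdcB` / `has_hisRS` from membership;
#' `three_component` when an arginine decarboxylase (adiA or aaxB) is a
#' member — the two-decarboxylase, one-transporter arginine/histidine
#' system; `duplicated_antiporter` when an hdcA lies between two
#' antiporter members (antiporters both upstream and downstream).
#'
#' @param member_roles character vector of role codes in ordinal order;
#'   must contain at least one hdcA and one antiporter.
#' @return list with `architecture`, `pathway`, `has_hdcB`, `has_hisRS`,
#'   `three_component`, `duplicated_antiporter`.
#' @export
classify_architecture <- function(member_roles) {
  if (!any(member_roles %in% HDCA_ROLES) ||
      !any(member_roles == "ANTIPORTER")) {
    stop_hdc("invalid cluster: needs at least one hdcA and one antiporter",
             class = "hdcminer_internal_error")
  }
  if (any(member_roles == "OTHER")) {
    stop_hdc("invalid cluster: role-less member",
             class = "hdcminer_internal_error")
  }
  has_pyr <- any(member_roles == "HDCA_PYR")
  has_plp <- any(member_roles == "HDCA_PLP")
  ap <- which(member_roles == "ANTIPORTER")
  hd <- which(member_roles %in% HDCA_ROLES)
  dup <- length(ap) >= 2L &&
    any(vapply(hd, function(k) any(ap < k) && any(ap > k), logical(1L)))
  list(
    architecture = paste(role_label(member_roles), collapse = "/"),
    pathway = if (has_pyr && has_plp) "BOTH" else if (has_pyr) "PYR" else "PLP",
    has_hdcB = any(member_roles == "HDCB"),
    has_hisRS = any(member_roles == "HISRS"),
    three_component = any(member_roles %in% c("ADIA", "AAXB")),
    duplicated_antiporter = dup
  )
}
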