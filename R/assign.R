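# Per-sample coverage CF of a branch: total cell fraction of descendant
# tips of the node in each sample.
branch_coverage_cf <- function(nodes, dtips = desc_tip_ids(nodes)) {
  lapply(setNames(as.character(nodes$id), as.character(nodes$id)), function(k) {
    tips <- dtips[[k]]
    tt <- match(tips, nodes$id)
    out <- tapply(nodes$cf[tt], nodes$sample[tt], sum)
    setNames(as.numeric(out), names(out))
  })
}

# Nodes strictly tipward of a genome-doubling branch (SNVs there sit on
# 1 of 4 copies in doubled samples).
post_gd_nodes <- function(nodes) {
  gd_ids <- nodes$id[nodes$gd]
  if (!length(gd_ids)) return(integer(0))
  nodes$id[vapply(nodes$id, function(i) any(gd_ids %in% ancestor_ids(nodes, i)),
                  logical(1))]
}

#' Assign SNVs to branches and set branch lengths
#'
#' An SNV detected in several samples is assigned to the branch leading
#' to tip lineages seen in exactly those samples.  When several branches
#' match, the branch whose expected VAF (from descendant-tip cell
#' fractions and ploidy context) is closest to the observed VAF wins.
#' SNVs matching no branch are discordant with the phylogeny and are
#' dropped.  Private SNVs are assigned among the pendant branches of
#' their sample's tips by the same VAF rule.  Branch lengths are the
#' counts of assigned SNVs.
#'
#' @param cohort a [be_cohort()].
#' @param patient patient id.
#' @param forest the patient's [be_forest()].
#' @param config a [be_config()].
#' @return list with `assignments` (data.frame: snv_row, node, status in
#'   placed/private/discordant) and `forest` with updated branch lengths.
#' @export
assign_snvs_to_branches <- function(cohort, patient, forest,
                                    config = be_config()) {
  nodes <- forest$nodes
  retained <- unique(nodes$sample[nodes$type == "tip"])
  empty <- data.frame(snv_row = integer(), node = integer(),
                      status = character(), stringsAsFactors = FALSE)
  if (!length(retained)) return(list(assignments = empty, forest = forest))
  det <- detection_matrix(cohort, patient, config$detection_min_alt)
  keep <- apply_loh_exclusion(cohort, patient, det)$keep
  det <- det[keep, retained, drop = FALSE]
  rows <- as.integer(rownames(det))
  dtips <- desc_tip_ids(nodes)
  skeys <- sample_keys(nodes, dtips)
  cov <- branch_coverage_cf(nodes, dtips)
  post_gd <- post_gd_nodes(nodes)
  tetra <- cohort$meta$sample[cohort$meta$ploidy_class == "near_tetraploid"]

  internal_ids <- nodes$id[nodes$type == "internal" &
                             lengths(strsplit(skeys[as.character(nodes$id)],
                                              "|", fixed = TRUE)) >= 2]
  internal_keys <- skeys[as.character(internal_ids)]
  tip_ids <- nodes$id[nodes$type == "tip"]
  tip_sample <- nodes$sample[match(tip_ids, nodes$id)]

  vaf_row <- function(r, smp) {
    a <- vapply(smp, function(s) cohort$snv[[paste0(s, "_alt")]][r], numeric(1))
    t <- vapply(smp, function(s) cohort$snv[[paste0(s, "_tot")]][r], numeric(1))
    a / pmax(1, t)
  }
  expected_vaf <- function(id, smp) {
    cf <- cov[[as.character(id)]][smp]
    cf[is.na(cf)] <- 0
    denom <- ifelse(smp %in% tetra & id %in% post_gd, 4, 2)
    cf / denom
  }
  pick_nearest <- function(cand_ids, r, smp) {
    obs <- vaf_row(r, smp)
    dev <- vapply(cand_ids, function(id) {
      mean(abs(obs - expected_vaf(id, smp)))
    }, numeric(1))
    cand_ids[which.min(dev)]
  }

  n <- length(rows)
  node_out <- rep(NA_integer_, n)
  status <- rep(NA_character_, n)
  keyvec <- apply(det, 1L, function(d) paste(sort(retained[d]), collapse = "|"))
  nd <- rowSums(det)
  for (i in seq_len(n)) {
    if (nd[i] == 0L) { status[i] <- "undetected"; next }
    smp <- strsplit(keyvec[i], "|", fixed = TRUE)[[1]]
    if (nd[i] == 1L) {
      cand <- tip_ids[tip_sample == smp]
      status[i] <- "private"
      node_out[i] <- if (length(cand) == 1L) cand else
        pick_nearest(cand, rows[i], smp)
      next
    }
    cand <- internal_ids[internal_keys == keyvec[i]]
    if (!length(cand)) { status[i] <- "discordant"; next }
    status[i] <- "placed"
    node_out[i] <- if (length(cand) == 1L) cand else
      pick_nearest(cand, rows[i], smp)
  }
  assignments <- data.frame(snv_row = rows, node = node_out, status = status,
                            stringsAsFactors = FALSE)
  counts <- table(factor(node_out[!is.na(node_out)], levels = nodes$id))
  forest$nodes$n_snvs <- as.numeric(counts[as.character(nodes$id)])
  list(assignments = assignments, forest = forest)
}

#' Proportion of usable SNVs placed on the phylogeny
#'
#' Usable SNVs are those informative for tree building: detected in two
#' or more samples (not private) and not excluded by the LOH filter.
#' The placed fraction is placed / (placed + discordant).
#'
#' @param assignments from [assign_snvs_to_branches()].
#' @return Proportion in \[0, 1\], or `NA` with a warning when no SNV is
#'   usable.
#' @export
placed_fraction <- function(assignments) {
  placed <- sum(assignments$status == "placed")
  disc <- sum(assignments$status == "discordant")
  if (placed + disc == 0L) {
    warning("no usable SNVs; placed fraction undefined", call. = FALSE)
    return(NA_real_)
  }
  placed / (placed + disc)
}

#' Infer zygosity of a mutation from its VAF and lineage cell fraction
#'
#' Heterozygous means at least one wild-type copy remains (expected VAF =
#' CF x 1/total copies); homozygous means no wild-type copy (expected VAF
#' = CF).  The numerically closer expectation wins; exact ties resolve to
#' heterozygous.
#'
#' @param observed_vaf observed VAF of the mutation in one sample.
#' @param cf cell fraction of the carrying lineage in that sample.
#' @param total_copies total copies at the locus (2 diploid, 4 doubled,
#'   or from a CN segment).
#' @return `"heterozygous"` or `"homozygous"`.
#' @export
assign_zygosity <- function(observed_vaf, cf, total_copies = 2) {
  het <- cf / total_copies
  hom <- cf
  ifelse(abs(observed_vaf - hom) < abs(observed_vaf - het),
         "homozygous", "heterozygous")
}

#' Place candidate-locus functional mutations on branches with zygosity
#'
#' Functional (MODERATE or HIGH severity) mutations in candidate loci are
#' matched to branches like ordinary SNVs, but branches permitting a
#' heterozygous interpretation are preferred over branches forcing
#' homozygosity.  When a mutation is heterozygous in some lineages and
#' homozygous in others, the ancestral state is assumed heterozygous and
#' the losses of the wild-type allele are scored as secondary events on
#' tipward branches.
#'
#' @param cohort a [be_cohort()].
#' @param patient patient id.
#' @param forest the patient's [be_forest()].
#' @param candidate_loci character vector of locus symbols.
#' @param config a [be_config()].
#' @return data.frame: patient, locus, snv_row, node, zygosity,
#'   secondary_nodes (comma-separated, "" if none), status
#'   (placed/discordant).
#' @export
place_candidate_mutations <- function(cohort, patient, forest, candidate_loci,
                                      config = be_config()) {
  empty <- data.frame(patient = character(), locus = character(),
                      snv_row = integer(), node = integer(),
                      zygosity = character(), secondary_nodes = character(),
                      status = character(), stringsAsFactors = FALSE)
  nodes <- forest$nodes
  retained <- unique(nodes$sample[nodes$type == "tip"])
  if (!length(retained)) return(empty)
  rows <- patient_snvs(cohort, patient)
  rows <- rows[cohort$snv$severity[rows] %in% c("MODERATE", "HIGH") &
                 !is.na(cohort$snv$locus[rows]) &
                 cohort$snv$locus[rows] %in% candidate_loci]
  if (!length(rows)) return(empty)
  det <- detection_matrix(cohort, patient, config$detection_min_alt)
  det <- det[as.character(rows), retained, drop = FALSE]
  dtips <- desc_tip_ids(nodes)
  skeys <- sample_keys(nodes, dtips)
  cov <- branch_coverage_cf(nodes, dtips)
  tetra <- cohort$meta$sample[cohort$meta$ploidy_class == "near_tetraploid"]
  internal_ids <- nodes$id[nodes$type == "internal"]
  tip_ids <- nodes$id[nodes$type == "tip"]

  total_copies_at <- function(s, r) {
    cn <- cn_at(cohort$cn, s, cohort$snv$chrom[r], cohort$snv$pos[r])
    if (!is.na(cn[1, 1])) return(sum(cn[1, ]))
    if (s %in% tetra) 4 else 2
  }

  out <- list()
  for (i in seq_along(rows)) {
    r <- rows[i]
    smp <- retained[det[i, ]]
    if (!length(smp)) next
    key <- paste(sort(smp), collapse = "|")
    cand <- if (length(smp) == 1L) {
      tip_ids[nodes$sample[match(tip_ids, nodes$id)] == smp]
    } else {
      internal_ids[skeys[as.character(internal_ids)] == key]
    }
    if (!length(cand)) {
      out[[length(out) + 1L]] <- data.frame(
        patient = patient, locus = cohort$snv$locus[r], snv_row = r,
        node = NA_integer_, zygosity = NA_character_, secondary_nodes = "",
        status = "discordant", stringsAsFactors = FALSE
      )
      next
    }
    obs <- vapply(smp, function(s) {
      cohort$snv[[paste0(s, "_alt")]][r] /
        max(1, cohort$snv[[paste0(s, "_tot")]][r])
    }, numeric(1))
    eval_branch <- function(id) {
      cf <- cov[[as.character(id)]][smp]
      cf[is.na(cf)] <- 0
      tot <- vapply(smp, total_copies_at, numeric(1), r = r)
      zy <- assign_zygosity(obs, cf, tot)
      exp_v <- ifelse(zy == "homozygous", cf, cf / tot)
      list(zy = zy, dev = mean(abs(obs - exp_v)),
           permits_het = any(zy == "heterozygous") || all(cf == 0))
    }
    ev <- lapply(cand, eval_branch)
    permits <- vapply(ev, `[[`, logical(1), "permits_het")
    pool <- if (any(permits)) which(permits) else seq_along(cand)
    best <- pool[which.min(vapply(ev[pool], `[[`, numeric(1), "dev"))]
    id <- cand[best]
    zy <- ev[[best]]$zy
    secondary <- ""
    if (all(zy == "homozygous")) {
      zygosity <- "homozygous"
    } else if (all(zy == "heterozygous")) {
      zygosity <- "heterozygous"
    } else {
      # ancestral state heterozygous; wild-type loss on tipward branches
      zygosity <- "heterozygous"
      hom_s <- smp[zy == "homozygous"]
      sec <- vapply(hom_s, function(s) {
        below <- dtips[[as.character(id)]]
        tips_s <- below[nodes$sample[match(below, nodes$id)] == s]
        tips_s[which.max(nodes$cf[match(tips_s, nodes$id)])]
      }, integer(1))
      secondary <- paste(sort(unique(sec)), collapse = ",")
    }
    out[[length(out) + 1L]] <- data.frame(
      patient = patient, locus = cohort$snv$locus[r], snv_row = r,
      node = id, zygosity = zygosity, secondary_nodes = secondary,
      status = "placed", stringsAsFactors = FALSE
    )
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Run branch assignment and candidate placement across a cohort
#'
#' @param cohort a [be_cohort()].
#' @param forests named list of [be_forest()] from [deconvolute_cohort()];
#'   unresolvable patients are skipped.
#' @param candidate_loci character vector of candidate locus symbols.
#' @param config a [be_config()].
#' @return list with `forests` (branch lengths updated), `assignments`,
#'   `placements`, and `placed` (per-patient placed fractions).
#' @export
assign_cohort <- function(cohort, forests,
                          candidate_loci = default_candidate_loci()$locus,
                          config = be_config()) {
  assignments <- list(); placements <- list(); placed <- list()
  for (p in names(forests)) {
    f <- forests[[p]]
    if (f$status != "ok" || !nrow(f$nodes)) next
    a <- assign_snvs_to_branches(cohort, p, f, config)
    forests[[p]] <- a$forest
    a$assignments$patient <- p
    assignments[[p]] <- a$assignments
    placements[[p]] <- place_candidate_mutations(cohort, p, a$forest,
                                                 candidate_loci, config)
    placed[[p]] <- data.frame(patient = p,
                              placed_fraction = suppressWarnings(placed_fraction(a$assignments)),
                              stringsAsFactors = FALSE)
  }
  list(
    forests = forests,
    assignments = if (length(assignments)) do.call(rbind, assignments) else NULL,
    placements = if (length(placements)) do.call(rbind, placements) else NULL,
    placed = if (length(placed)) do.call(rbind, placed) else NULL
  )
}
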