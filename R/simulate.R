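#' Default candidate-locus table for the simulator
#'
#' Fourteen loci recurrently hit by functional (missense or worse)
#' mutations in Barrett's segments.  `p_mut` is the expected number of
#' functional mutations per patient per locus, `p_hom` the probability a
#' mutation has lost all wild-type copies, and `bias` the clonal
#' expansion bias exponent applied when a homozygous mutation is placed
#' (0 = placement proportional to branch length, i.e. selectively
#' neutral; positive values up-weight branches with many descendant
#' leaves).  TP53 and CDKN2A default to a positive homozygous bias.
#'
#' @return A data.frame with columns locus, chrom, pos, p_mut, p_hom, bias.
#' @export
default_candidate_loci <- function() {
  data.frame(
    locus = c("ARID1A", "CDKN2A", "CSMD1", "CSMD3", "FAT3", "LAMA1", "LRP1B",
              "MUC16", "MUC19", "PCLO", "SMARCA4", "SYNE1", "TP53", "TTN"),
    chrom = c("1", "9", "8", "8", "11", "18", "2", "19", "12", "7", "19",
              "6", "17", "2"),
    pos = c(26696000L, 21968000L, 2792000L, 113236000L, 92085000L, 6941000L,
            140990000L, 8959000L, 40788000L, 82387000L, 11071000L,
            152121000L, 7571000L, 179391000L),
    p_mut = 0.35, p_hom = 0.4,
    bias = c(0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0),
    stringsAsFactors = FALSE
  )
}

#' Simulation parameters
#'
#' Defaults emulate the cohort structure the pipeline targets: 4 biopsies
#' (2 time points) in cancer-outcome patients and 4 or 6 in noncancer
#' outcome, ~60x depth, origin counts drawn from the observed 43/29/5/1
#' split over 1-4 origins, branch lengths of 150-600 SNVs, lineages
#' detectable down to ~15% cell fraction, and about 44% of biopsies
#' containing two lineages.
#'
#' @param n_patients number of patients.
#' @param prop_co fraction of patients with cancer outcome.
#' @param p_six_biopsies probability an NCO patient has 6 biopsies (3 TPs).
#' @param depth_mean mean sequencing depth (reads).
#' @param n_origins_prob named probabilities for 1..4 independent origins.
#' @param snvs_per_branch_range min/max SNVs drawn per branch.
#' @param min_clone_cf smallest reportable lineage cell fraction.
#' @param p_subclonal probability a biopsy holds two lineages.
#' @param p_genome_doubling per-eligible-branch genome doubling probability.
#' @param p_unbalanced_cn per (near-diploid sample, chromosome) probability
#'   of an unbalanced 2+1 copy-number call.
#' @param p_loh per (near-diploid sample, chromosome) probability of a
#'   one-haplotype loss (copy-neutral LOH 2+0 or deletion 1+0).
#' @param dropout_rate extra per (SNV, sample) probability that alt reads
#'   are missed entirely (allelic dropout beyond binomial sampling).
#' @param detection_min_alt alt reads needed to call an SNV present.
#' @param spatial_autocorrelation 0-1 knob tying tree topology to biopsy
#'   position along the segment (0 = topology independent of position,
#'   the null used for test calibration).
#' @param candidate_loci table as in [default_candidate_loci()].
#' @param seed RNG seed used by [simulate_cohort()].
#' @return A list of class `be_sim_params`.
#' @export
sim_params <- function(n_patients = 10, prop_co = 0.5, p_six_biopsies = 0.25,
                       depth_mean = 60,
                       n_origins_prob = c(`1` = 43, `2` = 29, `3` = 5, `4` = 1) / 78,
                       snvs_per_branch_range = c(150, 600),
                       min_clone_cf = 0.15, p_subclonal = 0.44,
                       p_genome_doubling = 0.03, p_unbalanced_cn = 0.05,
                       p_loh = 0.03, dropout_rate = 0.01,
                       detection_min_alt = 3, spatial_autocorrelation = 0.7,
                       candidate_loci = default_candidate_loci(), seed = 1L) {
  p <- list(
    n_patients = n_patients, prop_co = prop_co, p_six_biopsies = p_six_biopsies,
    depth_mean = depth_mean, n_origins_prob = n_origins_prob,
    snvs_per_branch_range = snvs_per_branch_range, min_clone_cf = min_clone_cf,
    p_subclonal = p_subclonal, p_genome_doubling = p_genome_doubling,
    p_unbalanced_cn = p_unbalanced_cn, p_loh = p_loh,
    dropout_rate = dropout_rate, detection_min_alt = detection_min_alt,
    spatial_autocorrelation = spatial_autocorrelation,
    candidate_loci = candidate_loci, seed = seed
  )
  probs <- c(p$n_origins_prob, p$p_subclonal, p$p_genome_doubling,
             p$p_unbalanced_cn, p$p_loh, p$dropout_rate, p$prop_co)
  if (any(probs < 0 | probs > 1)) {
    stop("sim_params: probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(p$snvs_per_branch_range <= 0) ||
      p$snvs_per_branch_range[1] > p$snvs_per_branch_range[2]) {
    stop("sim_params: snvs_per_branch_range must be a positive min/max pair",
         call. = FALSE)
  }
  if (p$min_clone_cf <= 0 || p$min_clone_cf >= 1) {
    stop("sim_params: min_clone_cf must lie in (0, 1)", call. = FALSE)
  }
  structure(p, class = "be_sim_params")
}

#' Draw read counts for one site
#'
#' Total reads are Poisson around the mean depth (floored at 1); alt reads
#' are Binomial at the true VAF.  A site is called detected when alt reads
#' reach `min_alt`, which is what makes low-cell-fraction lineages drop
#' out of some biopsies.
#'
#' @param true_vaf true variant allele frequency in \[0, 1\].
#' @param depth_mean mean total depth.
#' @param n number of independent draws.
#' @param min_alt detection threshold (alt reads).
#' @return data.frame with columns alt, total, detected.
#' @export
sample_reads <- function(true_vaf, depth_mean = 60, n = 1, min_alt = 3) {
  stopifnot(true_vaf >= 0, true_vaf <= 1)
  total <- pmax(1L, stats::rpois(n, depth_mean))
  alt <- stats::rbinom(n, total, true_vaf)
  data.frame(alt = alt, total = total, detected = alt >= min_alt)
}

# Build one origin's bifurcating tree over its tips by agglomerative
# joining on a trait that mixes biopsy position with noise.  Joins that
# would create a clade spanning a single biopsy are forbidden: such
# substructure is indistinguishable from private variation and is not
# deconvoluted downstream.
grow_origin <- function(nodes, tip_ids, gej_by_tip, s_autoc, draw_len) {
  if (length(tip_ids) == 1L) {
    nodes <- add_node(nodes, type = "internal", n_snvs = 0)
    root <- nodes$id[nrow(nodes)]
    nodes$parent[nodes$id == tip_ids] <- root
    return(nodes)
  }
  g <- gej_by_tip
  zg <- if (stats::sd(g) > 0) (g - mean(g)) / stats::sd(g) else g * 0
  trait <- s_autoc * zg + (1 - s_autoc) * stats::rnorm(length(g))
  cl <- lapply(seq_along(tip_ids), function(i) {
    list(id = tip_ids[i], trait = trait[i],
         bio = nodes$biopsy[nodes$id == tip_ids[i]])
  })
  while (length(cl) > 1L) {
    best <- NULL; bestd <- Inf
    for (i in seq_len(length(cl) - 1L)) {
      for (j in seq(i + 1L, length(cl))) {
        if (length(unique(c(cl[[i]]$bio, cl[[j]]$bio))) < 2L) next
        d <- abs(cl[[i]]$trait - cl[[j]]$trait)
        if (d < bestd) { bestd <- d; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    nodes <- add_node(nodes, type = "internal", n_snvs = draw_len())
    new_id <- nodes$id[nrow(nodes)]
    nodes$parent[nodes$id %in% c(cl[[i]]$id, cl[[j]]$id)] <- new_id
    merged <- list(id = new_id, trait = mean(c(cl[[i]]$trait, cl[[j]]$trait)),
                   bio = unique(c(cl[[i]]$bio, cl[[j]]$bio)))
    cl <- c(cl[-c(i, j)], list(merged))
  }
  nodes
}

#' Simulate one patient with known ground truth
#'
#' Draws the origin count, grows a bifurcating lineage tree per origin
#' (tips are biopsy-lineage pairs with cell fractions), loads every
#' branch with neutral SNVs, optionally places genome doubling and
#' candidate-locus functional mutations, then generates per-sample read
#' counts under the Poisson-depth / Binomial-alt noise model.
#'
#' @param params a [sim_params()] list.
#' @param patient_id patient identifier.
#' @param outcome `"CO"` or `"NCO"`.
#' @param seed optional seed; when NULL the current RNG stream is used
#'   (as when called from [simulate_cohort()]).
#' @return list with elements `truth` (a `be_truth`: forest, placements,
#'   per-SNV true branch), `snv`, `cn`, `meta`.
#' @export
simulate_patient <- function(params, patient_id = "P01", outcome = "NCO",
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draw_len <- function() {
    r <- params$snvs_per_branch_range
    sample(seq(r[1], r[2]), 1L)
  }

  n_b <- if (outcome == "CO") 4L else {
    if (stats::runif(1) < params$p_six_biopsies) 6L else 4L
  }
  biopsies <- LETTERS[seq_len(n_b)]
  tp <- rep(paste0("TP", seq_len(n_b / 2L)), each = 2L)
  gej <- as.numeric(sample(1:12, n_b, replace = TRUE))

  k <- as.integer(sample(names(params$n_origins_prob), 1L,
                         prob = params$n_origins_prob))
  k <- min(k, n_b)
  # origins occupy contiguous blocks along the same noisy spatial trait
  # that shapes the trees: at full autocorrelation origins are contiguous
  # stretches of the segment, at zero they are spatially random
  s_a <- params$spatial_autocorrelation
  zg <- if (stats::sd(gej) > 0) (gej - mean(gej)) / stats::sd(gej) else gej * 0
  block_trait <- s_a * zg + (1 - s_a) * stats::rnorm(n_b)
  ord <- order(block_trait, biopsies)
  cuts <- if (k > 1L) sort(sample(seq_len(n_b - 1L), k - 1L)) else integer(0)
  block <- rep(NA_integer_, n_b)
  block[ord] <- findInterval(seq_len(n_b), c(cuts + 0.5)) + 1L

  n_lin <- 1L + stats::rbinom(n_b, 1L, params$p_subclonal)
  n_lin[tabulate(block, k)[block] == 1L] <- 1L  # singleton origins stay clonal

  nodes <- empty_nodes()
  tip_meta <- list()
  for (b in seq_len(n_b)) {
    if (n_lin[b] == 1L) {
      cfs <- stats::runif(1, 0.60, 0.95)
    } else {
      # lineage CFs separated by at least twice the detectable minimum:
      # closer mixtures are below the VAF peak resolution at ~60x and are
      # not deconvolutable (the method's stated resolution limit)
      cf2 <- stats::runif(1, 0.30, 0.33)
      cfs <- c(cf2 + stats::runif(1, 0.32, 0.34), cf2)
    }
    for (l in seq_len(n_lin[b])) {
      nodes <- add_node(nodes, type = "tip",
                        sample = paste0(patient_id, "_", biopsies[b]),
                        biopsy = biopsies[b], lineage = l, cf = cfs[l],
                        n_snvs = draw_len())
      tip_meta[[length(tip_meta) + 1L]] <-
        data.frame(id = nodes$id[nrow(nodes)], biopsy = biopsies[b],
                   gej = gej[b], origin = block[b])
    }
  }
  tip_meta <- do.call(rbind, tip_meta)

  for (o in seq_len(k)) {
    sel <- tip_meta$origin == o
    nodes <- grow_origin(nodes, tip_meta$id[sel], tip_meta$gej[sel],
                         params$spatial_autocorrelation, draw_len)
  }

  # --- genome doubling ---------------------------------------------------
  dtips <- desc_tip_ids(nodes)
  all_tips_of <- split(nodes$id[nodes$type == "tip"],
                       nodes$biopsy[nodes$type == "tip"])
  gd_eligible <- vapply(seq_len(nrow(nodes)), function(i) {
    if (nodes$type[i] != "internal") return(FALSE)
    tips <- dtips[[as.character(nodes$id[i])]]
    if (length(tips) < 1L) return(FALSE)
    bios <- unique(nodes$biopsy[match(tips, nodes$id)])
    all(vapply(bios, function(b) all(all_tips_of[[b]] %in% tips), logical(1)))
  }, logical(1))
  gd_samples <- character(0)
  trees <- tree_of(nodes)
  for (r in unique(trees)) {
    cand <- nodes$id[gd_eligible & trees[as.character(nodes$id)] == r]
    hit <- cand[stats::runif(length(cand)) < params$p_genome_doubling]
    if (length(hit)) {
      g <- hit[1]
      nodes$gd[nodes$id == g] <- TRUE
      tips <- dtips[[as.character(g)]]
      gd_samples <- union(gd_samples,
                          nodes$sample[match(tips, nodes$id)])
    }
  }

  samples <- paste0(patient_id, "_", biopsies)
  is_tetra <- samples %in% gd_samples

  # --- copy-number segments ---------------------------------------------
  chroms <- as.character(1:22)
  cn_rows <- list()
  maj_m <- matrix(1, length(chroms), n_b, dimnames = list(chroms, samples))
  min_m <- matrix(1, length(chroms), n_b, dimnames = list(chroms, samples))
  for (si in seq_len(n_b)) {
    if (is_tetra[si]) {
      maj_m[, si] <- 2; min_m[, si] <- 2
    } else {
      u <- stats::runif(length(chroms))
      unb <- u < params$p_unbalanced_cn
      loh <- !unb & u < params$p_unbalanced_cn + params$p_loh
      maj_m[unb, si] <- 2; min_m[unb, si] <- 1
      maj_m[loh, si] <- sample(c(2, 1), sum(loh), replace = TRUE)
      min_m[loh, si] <- 0
    }
    cn_rows[[si]] <- data.frame(
      sample = samples[si], chrom = chroms, start = 1L, end = 250000000L,
      major = maj_m[, si], minor = min_m[, si], stringsAsFactors = FALSE
    )
  }
  cn <- do.call(rbind, cn_rows)

  # --- background SNVs ---------------------------------------------------
  edge_ids <- nodes$id
  n_e <- nodes$n_snvs
  snv_edge <- rep(edge_ids, n_e)
  N <- length(snv_edge)
  snv_chrom <- sample(chroms, N, replace = TRUE)
  snv_pos <- sample.int(200000000L, N, replace = TRUE)
  snv_hap <- sample(1:2, N, replace = TRUE)
  gd_edge_ids <- nodes$id[nodes$gd]
  pre_gd <- rep(TRUE, N)
  on_gd <- snv_edge %in% gd_edge_ids
  pre_gd[on_gd] <- stats::runif(sum(on_gd)) < 0.5
  severity <- sample(c("MODIFIER", "LOW"), N, replace = TRUE, prob = c(0.9, 0.1))
  locus <- rep(NA_character_, N)
  zyg <- rep("het", N)

  # --- candidate-locus functional mutations ------------------------------
  leaves_per_edge <- vapply(as.character(edge_ids),
                            function(k) length(dtips[[k]]), numeric(1))
  placements <- list()
  cl_tab <- params$candidate_loci
  for (li in seq_len(nrow(cl_tab))) {
    m <- min(stats::rpois(1, cl_tab$p_mut[li]), 3L)
    if (m == 0L) next
    for (j in seq_len(m)) {
      hom <- stats::runif(1) < cl_tab$p_hom[li]
      w <- n_e * leaves_per_edge^(if (hom) cl_tab$bias[li] else 0)
      if (sum(w) == 0) next
      e <- sample(edge_ids, 1L, prob = w)
      snv_edge <- c(snv_edge, e)
      snv_chrom <- c(snv_chrom, cl_tab$chrom[li])
      snv_pos <- c(snv_pos, cl_tab$pos[li] + sample.int(5000L, 1L))
      snv_hap <- c(snv_hap, sample(1:2, 1L))
      pre_gd <- c(pre_gd, !e %in% gd_edge_ids)
      severity <- c(severity, sample(c("MODERATE", "HIGH"), 1L, prob = c(0.6, 0.4)))
      locus <- c(locus, cl_tab$locus[li])
      zyg <- c(zyg, if (hom) "hom" else "het")
      placements[[length(placements) + 1L]] <- data.frame(
        patient = patient_id, locus = cl_tab$locus[li], node = e,
        zygosity = if (hom) "homozygous" else "heterozygous",
        stringsAsFactors = FALSE
      )
    }
  }
  placements <- if (length(placements)) do.call(rbind, placements) else
    data.frame(patient = character(), locus = character(), node = integer(),
               zygosity = character(), stringsAsFactors = FALSE)
  N <- length(snv_edge)

  # --- expected VAFs and reads ------------------------------------------
  edge_cf <- matrix(0, length(edge_ids), n_b,
                    dimnames = list(as.character(edge_ids), samples))
  for (i in seq_along(edge_ids)) {
    tips <- dtips[[as.character(edge_ids[i])]]
    tt <- match(tips, nodes$id)
    cf_by_sample <- tapply(nodes$cf[tt], nodes$sample[tt], sum)
    edge_cf[i, names(cf_by_sample)] <- cf_by_sample
  }
  # which GD node is ancestral to each edge (at most one per tree here)
  anc_of_gd <- lapply(gd_edge_ids, function(g) c(g, rev(ancestor_ids(nodes, g))))
  edge_is_pregd <- function(e, pre_flag) {
    # TRUE when the SNV predates the doubling seen by descendant samples
    for (gi in seq_along(gd_edge_ids)) {
      g <- gd_edge_ids[gi]
      if (e == g) return(pre_flag)
      if (e %in% ancestor_ids(nodes, g)) return(TRUE)
      if (g %in% ancestor_ids(nodes, e)) return(FALSE)
    }
    TRUE
  }
  pre_for_sample <- vapply(seq_len(N), function(i)
    edge_is_pregd(snv_edge[i], pre_gd[i]), logical(1))

  cf_m <- edge_cf[as.character(snv_edge), , drop = FALSE]
  vaf <- matrix(0, N, n_b, dimnames = list(NULL, samples))
  chrom_idx <- match(snv_chrom, chroms)
  for (si in seq_len(n_b)) {
    if (is_tetra[si]) {
      mult <- ifelse(pre_for_sample, 2, 1) / 4
    } else {
      maj <- maj_m[chrom_idx, si]; mn <- min_m[chrom_idx, si]
      copies <- ifelse(snv_hap == 1L, maj, mn)
      mult <- copies / (maj + mn)
    }
    mult[zyg == "hom"] <- 1
    vaf[, si] <- pmin(1, cf_m[, si] * mult)
  }

  tot <- matrix(pmax(1L, stats::rpois(N * n_b, params$depth_mean)), N, n_b)
  alt <- matrix(stats::rbinom(N * n_b, as.vector(tot), as.vector(vaf)), N, n_b)
  if (params$dropout_rate > 0) {
    drop <- matrix(stats::runif(N * n_b) < params$dropout_rate, N, n_b)
    alt[drop] <- 0L
  }

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, N, replace = TRUE)
  altb <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  snv <- data.frame(patient = patient_id, chrom = snv_chrom, pos = snv_pos,
                    ref = ref, alt = altb, severity = severity, locus = locus,
                    stringsAsFactors = FALSE)
  for (si in seq_len(n_b)) {
    snv[[paste0(samples[si], "_alt")]] <- alt[, si]
    snv[[paste0(samples[si], "_tot")]] <- tot[, si]
  }

  meta <- data.frame(
    patient = patient_id, biopsy = biopsies, sample = samples,
    time_point = tp, gej_cm = gej, outcome = outcome,
    ploidy_class = ifelse(is_tetra, "near_tetraploid", "near_diploid"),
    gd_corroborated = is_tetra, stringsAsFactors = FALSE
  )

  # number tip lineages by descending cell fraction, as reported downstream
  for (b in biopsies) {
    sel <- which(nodes$type == "tip" & nodes$biopsy == b)
    nodes$lineage[sel[order(-nodes$cf[sel])]] <- seq_along(sel)
  }
  truth <- structure(
    list(forest = be_forest(patient_id, nodes),
         placements = placements, snv_edge = snv_edge),
    class = "be_truth"
  )
  list(truth = truth, snv = snv, cn = cn, meta = meta)
}

#' Ground-truth candidate placements in the standard placement shape
#'
#' Formats a `be_truth`'s candidate-mutation placements like the output
#' of [place_candidate_mutations()], so the statistical tests can run
#' directly on simulator truth (e.g. for calibration studies).
#'
#' @param truths named list of `be_truth` objects.
#' @return data.frame: patient, locus, snv_row, node, zygosity,
#'   secondary_nodes, status.
#' @export
truth_placements <- function(truths) {
  out <- lapply(truths, function(tr) {
    pl <- tr$placements
    if (!nrow(pl)) return(NULL)
    data.frame(patient = pl$patient, locus = pl$locus,
               snv_row = NA_integer_, node = pl$node,
               zygosity = pl$zygosity, secondary_nodes = "",
               status = "placed", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(out)) {
    out <- data.frame(patient = character(), locus = character(),
                      snv_row = integer(), node = integer(),
                      zygosity = character(), secondary_nodes = character(),
                      status = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

rbind_fill <- function(dfs) {
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (c in setdiff(cols, names(d))) d[[c]] <- NA
    d[, cols, drop = FALSE]
  }))
}

#' Simulate a cohort of patients with ground truth
#'
#' @param params a [sim_params()] list; `params$seed` controls all
#'   randomness so that the same parameters reproduce the same cohort.
#' @return list with `cohort` (a [be_cohort()]), `truths` (named list of
#'   `be_truth`, one per patient), and `params`.
#' @export
simulate_cohort <- function(params = sim_params()) {
  set.seed(params$seed)
  n <- params$n_patients
  n_co <- round(n * params$prop_co)
  outcomes <- c(rep("CO", n_co), rep("NCO", n - n_co))
  ids <- sprintf("P%02d", seq_len(n))
  sims <- lapply(seq_len(n), function(i) {
    simulate_patient(params, ids[i], outcomes[i])
  })
  cohort <- be_cohort(
    snv = rbind_fill(lapply(sims, `[[`, "snv")),
    cn = do.call(rbind, lapply(sims, `[[`, "cn")),
    meta = do.call(rbind, lapply(sims, `[[`, "meta"))
  )
  truths <- setNames(lapply(sims, `[[`, "truth"), ids)
  list(cohort = cohort, truths = truths, params = params)
}

#' Serialize a patient's ground truth to JSON
#'
#' @param truth a `be_truth` from [simulate_patient()].
#' @param path output path (`truth.json`).
#' @return Invisibly, `path`.  Round-trips through [read_truth()].
#' @export
export_truth <- function(truth, path) {
  jsonlite::write_json(
    list(patient_id = truth$forest$patient_id,
         nodes = truth$forest$nodes,
         placements = truth$placements,
         snv_edge = truth$snv_edge,
         origin_count = count_origins(truth$forest)),
    path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  invisible(path)
}

#' Read a ground-truth file written by [export_truth()]
#' @param path path to `truth.json`.
#' @return A `be_truth`.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- normalize_nodes(as.data.frame(x$nodes, stringsAsFactors = FALSE))
  pl <- as.data.frame(x$placements, stringsAsFactors = FALSE)
  if (!nrow(pl)) {
    pl <- data.frame(patient = character(), locus = character(),
                     node = integer(), zygosity = character(),
                     stringsAsFactors = FALSE)
  }
  structure(
    list(forest = be_forest(x$patient_id, nodes),
         placements = pl, snv_edge = as.integer(x$snv_edge)),
    class = "be_truth"
  )
}
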