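#' Order partitions for incremental forest assembly
#'
#' Assembly starts from the partitions containing exactly two samples and
#' works toward the root: ascending sample-set size, then descending SNV
#' count, residual ties by lexicographic sample-set key (deterministic).
#' Private partitions are excluded (they are not deconvoluted).
#'
#' @param partitions output of [partition_snvs()].
#' @return The non-private rows, ordered for assembly.
#' @export
order_partitions <- function(partitions) {
  p <- partitions[!partitions$private, , drop = FALSE]
  p[order(p$n_samples, -p$n_snvs, p$key), , drop = FALSE]
}

#' Convert a VAF peak to a cell fraction
#'
#' A peak at VAF v, for a mutation carried on `mut_copies` of
#' `total_copies` at its locus, corresponds to a lineage cell fraction of
#' `v * total_copies / mut_copies`, capped at 1.
#'
#' @param vaf peak location in \[0, 1\].
#' @param mut_copies copies carrying the mutation (>= 1).
#' @param total_copies total copies at the locus (>= mut_copies).
#' @return Cell fraction in \[0, 1\].
#' @export
vaf_peak_to_cf <- function(vaf, mut_copies, total_copies) {
  if (any(mut_copies < 1)) {
    stop("vaf_peak_to_cf: mut_copies must be >= 1", call. = FALSE)
  }
  stopifnot(all(total_copies >= mut_copies))
  pmin(1, vaf * total_copies / mut_copies)
}

#' Choose an explanation for a multi-peak copy-number group
#'
#' Multiple VAF peaks within one partition group can arise from (1) an
#' unbalanced copy-number region, accepted only when the CN call is
#' actually unbalanced and the peak ratio matches the haplotype copy
#' ratio; (2) a genome doubling on the branch, accepted only when every
#' partition sample has externally corroborated doubling and the peaks
#' differ by a factor of two; otherwise (3) the partition represents two
#' lineages relating the same samples at different time depths
#' (`split_lineages`).  A pattern resembling doubling without
#' corroboration is never treated as doubling.  More than three peaks in
#' any sample is unresolvable.
#'
#' @param peaks_by_sample named list: per sample, increasing peak
#'   locations.
#' @param gd_corroborated named logical: external genome-doubling
#'   evidence per partition sample.
#' @param cn_signature named list: per sample `c(major, minor)`.
#' @param ratio_tol relative tolerance for the ratio tests.
#' @return One of `"unbalanced_cn"`, `"genome_doubling"`,
#'   `"split_lineages"`, `"unresolved"`.
#' @export
interpret_multi_peaks <- function(peaks_by_sample, gd_corroborated,
                                  cn_signature, ratio_tol = 0.25) {
  kk <- lengths(peaks_by_sample)
  if (any(kk > 3L)) return("unresolved")
  multi <- names(peaks_by_sample)[kk >= 2L]
  if (!length(multi)) return("single")
  two <- names(peaks_by_sample)[kk == 2L]
  if (length(two) == length(multi)) {
    unb_ok <- all(vapply(two, function(s) {
      sig <- cn_signature[[s]]
      if (sig[1] == sig[2] || sig[2] == 0) return(FALSE)
      pk <- peaks_by_sample[[s]]
      ratio <- pk[2] / pk[1]
      abs(ratio / (sig[1] / sig[2]) - 1) <= ratio_tol
    }, logical(1)))
    if (unb_ok) return("unbalanced_cn")
    gd_ok <- all(unlist(gd_corroborated)) &&
      all(vapply(two, function(s) {
        pk <- peaks_by_sample[[s]]
        abs(pk[2] / pk[1] - 2) <= 2 * ratio_tol
      }, logical(1)))
    if (gd_ok) return("genome_doubling")
  }
  "split_lineages"
}

# Resolve a single VAF value to a cell fraction given the sample's local
# copy state.  `ref` is the lineage CF implied by balanced-diploid
# samples of the same claim, used to pick a haplotype (or the pre/post
# doubling copy count); NA when no such reference exists.
resolve_cf <- function(v, maj, mn, ref = NA_real_) {
  tot <- maj + mn
  if (maj == mn) {
    if (maj == 2) {  # near-tetraploid: 2-of-4 (ancestral) or 1-of-4
      cands <- c(vaf_peak_to_cf(v, 2, 4), vaf_peak_to_cf(v, 1, 4))
      if (!is.na(ref)) return(list(cf = cands[which.min(abs(cands - ref))], by_ref = TRUE))
      return(list(cf = cands[1], by_ref = FALSE))
    }
    return(list(cf = vaf_peak_to_cf(v, 1, tot), by_ref = TRUE))
  }
  cands <- vaf_peak_to_cf(v, c(maj, if (mn > 0) mn), tot)
  if (!is.na(ref)) return(list(cf = cands[which.min(abs(cands - ref))], by_ref = TRUE))
  cf <- if (cands[1] <= 1.05) cands[1] else cands[length(cands)]
  list(cf = min(1, cf), by_ref = FALSE)
}

# Diagonal-covariance multivariate Gaussian mixture EM with optional
# per-dimension cap on component spread (read-sampling noise level).
gmm_nd_em <- function(x, centers, var_floor = 1e-4, sd_cap_fn = NULL,
                      max_iter = 100, tol = 1e-7) {
  n <- nrow(x); d <- ncol(x); k <- nrow(centers)
  clamp <- function(sg, mu) {
    sg <- pmax(sqrt(var_floor), sg)
    if (!is.null(sd_cap_fn)) sg <- pmin(sg, pmax(sqrt(var_floor), sd_cap_fn(mu)))
    sg
  }
  mu <- centers
  sg <- matrix(rep(apply(x, 2L, stats::sd) / k, each = k), k, d)
  for (j in seq_len(k)) sg[j, ] <- clamp(sg[j, ], mu[j, ])
  pi_k <- rep(1 / k, k)
  ll_old <- -Inf; ll <- NA_real_
  resp <- matrix(1 / k, n, k)
  for (it in seq_len(max_iter)) {
    lp <- matrix(0, n, k)
    for (j in seq_len(k)) {
      v <- log(pi_k[j])
      for (c in seq_len(d)) {
        lp[, j] <- lp[, j] + stats::dnorm(x[, c], mu[j, c], sg[j, c], log = TRUE)
      }
      lp[, j] <- lp[, j] + v
    }
    mx <- apply(lp, 1L, max)
    lse <- mx + log(rowSums(exp(lp - mx)))
    resp <- exp(lp - lse)
    ll <- sum(lse)
    if (!is.finite(ll)) return(NULL)
    if (abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
    nk <- pmax(colSums(resp), 1e-8)
    pi_k <- nk / n
    for (j in seq_len(k)) {
      mu[j, ] <- colSums(resp[, j] * x) / nk[j]
      sgj <- sqrt(colSums(resp[, j] * sweep(x, 2L, mu[j, ])^2) / nk[j])
      sg[j, ] <- clamp(sgj, mu[j, ])
    }
  }
  list(mean = mu, sd = sg, pi = pi_k, resp = resp, ll = ll)
}

# Fit the lineage structure of a group in the joint VAF space: Ward
# initialization, diagonal-Gaussian EM with binomial-capped spread, and
# BIC selection of the component count.  Per-sample peak counts only
# lower-bound the lineage count (distinct VAF vectors can project onto
# the same marginal peak in every single sample), hence the joint fit.
fit_lineage_mixture <- function(vaf_mat, k_min, k_max, depth = NULL,
                                var_floor = 1e-4, max_points = 1500L) {
  n <- nrow(vaf_mat); d <- ncol(vaf_mat)
  sub <- if (n > max_points) seq(1L, n, length.out = max_points) else seq_len(n)
  x <- vaf_mat[sub, , drop = FALSE]
  m <- nrow(x)
  cap <- if (!is.null(depth)) binomial_sd_cap(depth) else NULL
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  best <- NULL; best_bic <- Inf; best_k <- k_min
  for (k in seq(k_min, k_max)) {
    cl <- stats::cutree(hc, k = k)
    if (min(tabulate(cl, k)) < 5L) next
    centers <- do.call(rbind, lapply(seq_len(k), function(j) {
      colMeans(x[cl == j, , drop = FALSE])
    }))
    fit <- gmm_nd_em(x, centers, var_floor, cap)
    if (is.null(fit)) next
    bic <- -2 * fit$ll + (k * (2 * d + 1) - 1) * log(m)
    if (bic < best_bic) { best_bic <- bic; best <- fit; best_k <- k }
  }
  if (is.null(best)) {
    return(list(K = 1L, cluster = rep(1L, n),
                means = matrix(colMeans(vaf_mat), 1), pi = 1))
  }
  # hard-assign the full group under the selected model
  k <- best_k
  lp <- matrix(0, n, k)
  for (j in seq_len(k)) {
    v <- log(best$pi[j])
    for (c in seq_len(d)) {
      lp[, j] <- lp[, j] + stats::dnorm(vaf_mat[, c], best$mean[j, c],
                                        best$sd[j, c], log = TRUE)
    }
    lp[, j] <- lp[, j] + v
  }
  cl_full <- max.col(lp, ties.method = "first")
  list(K = k, cluster = cl_full, means = best$mean, pi = best$pi)
}

# Build lineage claims for one non-private partition.  Returns a list of
# claims (key, samples, cf, n, gd, by_ref) or the string "unresolved".
claims_for_partition <- function(cohort, part_key, snv_rows, config, meta_p) {
  part_samples <- strsplit(part_key, "|", fixed = TRUE)[[1]]
  groups <- cn_group_split(cohort, snv_rows, part_samples)
  gd_flags <- setNames(meta_p$gd_corroborated[match(part_samples, meta_p$sample)],
                       part_samples)
  claims <- list()
  for (g in groups) {
    if (length(g) < config$min_group_snvs) next
    vaf_mat <- vapply(part_samples, function(s) {
      cohort$snv[[paste0(s, "_alt")]][g] / pmax(1, cohort$snv[[paste0(s, "_tot")]][g])
    }, numeric(length(g)))
    vaf_mat <- matrix(vaf_mat, nrow = length(g),
                      dimnames = list(NULL, part_samples))
    sig <- lapply(part_samples, function(s) {
      cn <- cn_at(cohort$cn, s, cohort$snv$chrom[g[1]], cohort$snv$pos[g[1]])
      c(major = if (is.na(cn[1, 1])) 1 else unname(cn[1, 1]),
        minor = if (is.na(cn[1, 2])) 1 else unname(cn[1, 2]))
    })
    names(sig) <- part_samples

    dep <- vapply(part_samples, function(s) {
      mean(cohort$snv[[paste0(s, "_tot")]][g], na.rm = TRUE)
    }, numeric(1))
    peaks <- lapply(part_samples, function(s) {
      pk <- detect_peaks(vaf_mat[, s], config$bandwidth_scale, config$merge_tol)
      fit_peak_weights(vaf_mat[, s], pk, config$min_peak_snvs, depth = dep[s])
    })
    names(peaks) <- part_samples
    if (any(vapply(peaks, nrow, integer(1)) == 0L)) next  # no peak survives

    loc_list <- lapply(peaks, function(p) p$location)
    hyp <- interpret_multi_peaks(loc_list, gd_flags, sig, config$ratio_tol)
    if (hyp == "unresolved") return("unresolved")
    split_fit <- NULL
    if (hyp == "single" && length(g) >= 2 * config$min_peak_snvs) {
      # marginally unimodal groups can still hide two lineages whose VAF
      # vectors differ in only one sample; probe the joint space
      probe <- fit_lineage_mixture(vaf_mat, 1L, 2L, depth = mean(dep))
      if (probe$K == 2L) {
        sep <- max(abs(probe$means[1, ] - probe$means[2, ]))
        if (sep >= 0.1 &&
            min(round(length(g) * probe$pi)) >= config$min_peak_snvs) {
          hyp <- "split_lineages"
          split_fit <- probe
        }
      }
    }

    balanced_ref <- function(vafs_by_sample) {
      refs <- unlist(lapply(part_samples, function(s) {
        if (sig[[s]]["major"] == 1 && sig[[s]]["minor"] == 1)
          2 * vafs_by_sample[[s]]
      }))
      if (length(refs)) stats::median(refs) else NA_real_
    }

    if (hyp %in% c("single", "genome_doubling", "unbalanced_cn")) {
      gd_here <- hyp == "genome_doubling"
      top_vaf <- lapply(part_samples, function(s) {
        p <- peaks[[s]]
        if (hyp == "unbalanced_cn" && nrow(p) >= 2) {
          # both peaks are the same lineage on different haplotypes
          return(sum(p$weight / sum(p$weight) *
                       vaf_peak_to_cf(p$location,
                                      c(sig[[s]]["minor"], sig[[s]]["major"]),
                                      sum(sig[[s]]))) / 2)
        }
        if (gd_here && nrow(p) >= 2) return(p$location[nrow(p)])
        p$location[which.max(p$weight)]
      })
      names(top_vaf) <- part_samples
      ref <- balanced_ref(top_vaf)
      res <- lapply(part_samples, function(s) {
        if (hyp == "unbalanced_cn" && nrow(peaks[[s]]) >= 2) {
          return(list(cf = min(1, 2 * top_vaf[[s]]), by_ref = TRUE))
        }
        if (gd_here && nrow(peaks[[s]]) >= 2) {
          return(list(cf = vaf_peak_to_cf(top_vaf[[s]], 2, 4), by_ref = TRUE))
        }
        resolve_cf(top_vaf[[s]], sig[[s]]["major"], sig[[s]]["minor"], ref)
      })
      claims[[length(claims) + 1L]] <- list(
        key = part_key, samples = part_samples,
        cf = setNames(vapply(res, `[[`, numeric(1), "cf"), part_samples),
        n = length(g), gd = gd_here,
        by_ref = all(vapply(res, `[[`, logical(1), "by_ref"))
      )
    } else {  # split_lineages
      if (is.null(split_fit)) {
        k_min <- max(vapply(peaks, nrow, integer(1)))
        k_max <- max(2L, min(4L, 1L + sum(vapply(peaks, nrow, integer(1)) - 1L)))
        split_fit <- fit_lineage_mixture(vaf_mat, k_min, k_max,
                                         depth = mean(dep))
      }
      K <- split_fit$K
      for (k in seq_len(K)) {
        # mixture soft counts estimate the SNVs under each lineage
        n_k <- round(length(g) * split_fit$pi[k])
        if (n_k < config$min_peak_snvs) next
        mv <- split_fit$means[k, ]
        names(mv) <- part_samples
        mv_list <- as.list(mv)
        ref <- balanced_ref(mv_list)
        res <- lapply(part_samples, function(s) {
          resolve_cf(mv[s], sig[[s]]["major"], sig[[s]]["minor"], ref)
        })
        claims[[length(claims) + 1L]] <- list(
          key = part_key, samples = part_samples,
          cf = setNames(vapply(res, `[[`, numeric(1), "cf"), part_samples),
          n = n_k, gd = FALSE,
          by_ref = all(vapply(res, `[[`, logical(1), "by_ref"))
        )
      }
    }
  }
  if (!length(claims)) return(list())
  # merge claims from different CN groups that describe the same lineage
  merged <- list()
  for (cl in claims[order(-vapply(claims, `[[`, numeric(1), "n"))]) {
    hit <- NA_integer_
    for (i in seq_along(merged)) {
      if (all(abs(merged[[i]]$cf - cl$cf) <= config$cf_tol)) { hit <- i; break }
    }
    if (is.na(hit)) {
      merged[[length(merged) + 1L]] <- cl
    } else {
      m <- merged[[hit]]
      w <- c(m$n, cl$n)
      m$cf <- (m$cf * w[1] + cl$cf * w[2]) / sum(w)
      m$n <- sum(w)
      m$gd <- m$gd || cl$gd
      m$by_ref <- m$by_ref && cl$by_ref
      merged[[hit]] <- m
    }
  }
  merged
}

# Global claim ordering: partitions by (sample-set size, descending total
# SNVs, lexicographic key); within a partition, derived (lower-CF)
# lineages before ancestral ones so nesting assembles bottom-up.
order_claims <- function(claims) {
  if (!length(claims)) return(claims)
  key <- vapply(claims, `[[`, character(1), "key")
  nsmp <- lengths(lapply(claims, `[[`, "samples"))
  tot_by_key <- tapply(vapply(claims, `[[`, numeric(1), "n"), key, sum)
  cfsum <- vapply(claims, function(cl) sum(cl$cf), numeric(1))
  claims[order(nsmp, -tot_by_key[key], key, cfsum)]
}

# Incremental forest assembly from ordered claims.  Each claim becomes an
# internal node; existing root clades whose sample set is a subset of the
# claim's and whose CFs fit inside the claim's CF budget become children;
# per-sample CF left over (or uncovered samples) become new tips.
assemble_forest_impl <- function(claims, retained_samples, private_cf,
                                 sample_biopsy, config) {
  nodes <- empty_nodes()
  node_claims <- list()
  for (cl in claims) {
    S <- cl$samples
    roots <- forest_roots(nodes)
    roots <- roots[nodes$type[match(roots, nodes$id)] == "internal"]
    cand <- Filter(function(r) {
      rc <- node_claims[[as.character(r)]]
      all(rc$samples %in% S) &&
        all(rc$cf <= cl$cf[rc$samples] + config$cf_tol)
    }, roots)
    cand_n <- vapply(cand, function(r) node_claims[[as.character(r)]]$n, numeric(1))
    cand <- cand[order(-cand_n, cand)]
    coverage <- setNames(rep(0, length(S)), S)
    children <- integer(0)
    for (r in cand) {
      rc <- node_claims[[as.character(r)]]
      if (all(coverage[rc$samples] + rc$cf <= cl$cf[rc$samples] + config$cf_tol)) {
        children <- c(children, r)
        coverage[rc$samples] <- coverage[rc$samples] + rc$cf
      }
    }
    nodes <- add_node(nodes, type = "internal", n_snvs = cl$n, gd = cl$gd,
                      claim_key = cl$key)
    new_id <- nodes$id[nrow(nodes)]
    node_claims[[as.character(new_id)]] <- cl
    nodes$parent[nodes$id %in% children] <- new_id
    for (s in S) {
      res <- cl$cf[s] - coverage[s]
      if (coverage[s] == 0 || res >= config$min_clone_cf) {
        nodes <- add_node(nodes, parent = new_id, type = "tip", sample = s,
                          biopsy = sample_biopsy[s],
                          cf = if (coverage[s] == 0) cl$cf[s] else res)
      }
    }
  }
  # samples with signal but no non-private claim: isolated single-tip trees
  placed <- unique(nodes$sample[nodes$type == "tip"])
  for (s in setdiff(retained_samples, placed)) {
    nodes <- add_node(nodes, type = "internal", n_snvs = 0)
    root <- nodes$id[nrow(nodes)]
    cf <- private_cf[s]
    nodes <- add_node(nodes, parent = root, type = "tip", sample = s,
                      biopsy = sample_biopsy[s],
                      cf = if (is.na(cf)) 0.5 else cf)
  }
  list(nodes = nodes, node_claims = node_claims)
}

#' Assemble a phylogeny forest from lineage claims
#'
#' Direct interface to the incremental assembly step of
#' [deconvolute_patient()]: claims (one per partition lineage, with
#' per-sample cell fractions and SNV support) are ordered by the
#' two-samples-first rule and stacked into rooted trees; sample groups
#' never joined by a claim remain disjoint trees.
#'
#' @param claims list of claims: each a list with `samples` (character),
#'   `cf` (named numeric), `n` (SNV support), and optionally `gd`,
#'   `key`, `by_ref`.
#' @param samples all retained sample ids (samples untouched by any
#'   claim become isolated single-tip trees).
#' @param config a [be_config()].
#' @param private_cf optional named CFs for isolated samples.
#' @return A [be_forest()] (patient id `"assembled"`), with the `claims`
#'   attribute mapping internal nodes to their claims.
#' @export
assemble_forest <- function(claims, samples, config = be_config(),
                            private_cf = NULL) {
  claims <- lapply(claims, function(cl) {
    if (is.null(cl$key)) cl$key <- paste(sort(cl$samples), collapse = "|")
    if (is.null(cl$gd)) cl$gd <- FALSE
    if (is.null(cl$by_ref)) cl$by_ref <- TRUE
    cl
  })
  if (is.null(private_cf)) {
    private_cf <- setNames(rep(NA_real_, length(samples)), samples)
  }
  res <- assemble_forest_impl(order_claims(claims), samples, private_cf,
                              setNames(samples, samples), config)
  nodes <- refine_tip_cfs(res$nodes, res$node_claims)
  for (b in unique(nodes$biopsy[nodes$type == "tip"])) {
    sel <- which(nodes$type == "tip" & nodes$biopsy == b)
    nodes$lineage[sel[order(-nodes$cf[sel])]] <- seq_along(sel)
  }
  f <- be_forest("assembled", nodes)
  attr(f, "claims") <- res$node_claims
  f
}

# Weighted-average tip cell fractions: a tip inherits the CF it possessed
# when diverging, estimated from all branches on its root path in which
# it is the only lineage of its sample, weighted by branch SNV support.
refine_tip_cfs <- function(nodes, node_claims) {
  dtips <- desc_tip_ids(nodes)
  for (i in which(nodes$type == "tip")) {
    id <- nodes$id[i]; s <- nodes$sample[i]
    num <- 0; den <- 0
    for (a in ancestor_ids(nodes, id)) {
      cl <- node_claims[[as.character(a)]]
      if (is.null(cl) || !s %in% cl$samples) next
      tips_a <- dtips[[as.character(a)]]
      same <- nodes$sample[match(tips_a, nodes$id)] == s
      if (sum(same) != 1L) next
      num <- num + cl$cf[s] * cl$n
      den <- den + cl$n
    }
    if (den > 0) nodes$cf[i] <- num / den
  }
  nodes
}

# After assembly, branches strictly tipward of a genome doubling carry
# post-doubling SNVs (1 of 4 copies); claims that had no balanced-diploid
# reference were resolved as 2-of-4 and are doubled here.
apply_gd_correction <- function(nodes, node_claims) {
  gd_ids <- nodes$id[nodes$gd]
  if (!length(gd_ids)) return(node_claims)
  for (key in names(node_claims)) {
    id <- as.integer(key)
    cl <- node_claims[[key]]
    if (cl$by_ref || cl$gd) next
    if (any(gd_ids %in% ancestor_ids(nodes, id))) {
      cl$cf <- pmin(1, cl$cf * 2)
      node_claims[[key]] <- cl
    }
  }
  node_claims
}

#' Deconvolute one patient into a phylogeny forest
#'
#' Runs the full per-patient inference: detection, LOH exclusion,
#' thin-biopsy filtering, partitioning, copy-number grouping, VAF peak
#' detection and mixture weighting, multi-peak interpretation, claim
#' assembly into a forest, cell-fraction refinement and lineage
#' numbering.  Logically incompatible partition sets are reconciled by
#' reclassifying the smallest conflicting partition as allelic dropout of
#' a compatible superset (bounded attempts); failing that the patient is
#' flagged unresolvable and excluded from statistics.
#'
#' @param cohort a [be_cohort()].
#' @param patient patient id.
#' @param config a [be_config()].
#' @return A [be_forest()] with attributes `log` (filter counts) and
#'   `claims`.
#' @export
deconvolute_patient <- function(cohort, patient, config = be_config()) {
  meta_p <- cohort$meta[cohort$meta$patient == patient, , drop = FALSE]
  samples <- meta_p$sample
  sample_biopsy <- setNames(meta_p$biopsy, meta_p$sample)
  det <- detection_matrix(cohort, patient, config$detection_min_alt)
  loh <- apply_loh_exclusion(cohort, patient, det)
  det <- det[loh$keep, , drop = FALSE]
  parts <- partition_snvs(det)
  dropped_s <- drop_thin_biopsies(parts, samples, config$thin_biopsy_min)
  if (length(dropped_s)) {
    det <- det[, setdiff(samples, dropped_s), drop = FALSE]
    parts <- partition_snvs(det)
  }
  retained <- setdiff(samples, dropped_s)
  log <- list(n_snvs = nrow(det), loh_excluded = loh$n_excluded,
              dropped_biopsies = unname(sample_biopsy[dropped_s]))
  if (!length(retained) || !nrow(parts)) {
    f <- be_forest(patient, empty_nodes(), dropped_biopsies = unname(sample_biopsy[dropped_s]))
    attr(f, "log") <- log
    return(f)
  }

  # CF scale for isolated samples, from private-partition VAFs
  private_cf <- setNames(rep(NA_real_, length(retained)), retained)
  for (i in which(parts$private)) {
    s <- parts$key[i]
    rows <- as.integer(parts$snv_rows[[i]])
    v <- cohort$snv[[paste0(s, "_alt")]][rows] /
      pmax(1, cohort$snv[[paste0(s, "_tot")]][rows])
    private_cf[s] <- min(1, 2 * stats::median(v))
  }

  claims <- list()
  for (i in which(!parts$private)) {
    cl <- claims_for_partition(cohort, parts$key[i], parts$snv_rows[[i]],
                               config, meta_p)
    if (identical(cl, "unresolved")) {
      f <- be_forest(patient, empty_nodes(), status = "unresolvable",
                     dropped_biopsies = unname(sample_biopsy[dropped_s]))
      attr(f, "log") <- log
      return(f)
    }
    claims <- c(claims, cl)
  }

  status <- "ok"
  for (attempt in 0:config$max_reclassify) {
    res <- assemble_forest_impl(order_claims(claims), retained, private_cf,
                                sample_biopsy, config)
    nodes <- res$nodes
    # per-sample CF budget
    cfsum <- tapply(nodes$cf[nodes$type == "tip"],
                    nodes$sample[nodes$type == "tip"], sum)
    bad <- names(cfsum)[cfsum > 1 + 0.05]
    if (!length(bad) || !length(claims)) break
    if (attempt == config$max_reclassify) { status <- "unresolvable"; break }
    # reclassify the smallest conflicting claim as allelic dropout of a
    # compatible superset claim
    involved <- which(vapply(claims, function(cl) any(bad %in% cl$samples),
                             logical(1)))
    involved <- involved[order(vapply(claims[involved], `[[`, numeric(1), "n"))]
    merged_any <- FALSE
    for (ci in involved) {
      cl <- claims[[ci]]
      targets <- which(vapply(claims, function(t) {
        all(cl$samples %in% t$samples) && length(t$samples) > length(cl$samples) &&
          all(abs(t$cf[cl$samples] - cl$cf) <= 2 * config$cf_tol)
      }, logical(1)))
      if (length(targets)) {
        t1 <- targets[which.max(vapply(claims[targets], `[[`, numeric(1), "n"))]
        claims[[t1]]$n <- claims[[t1]]$n + cl$n
        claims <- claims[-ci]
        merged_any <- TRUE
        break
      }
    }
    if (!merged_any) { status <- "unresolvable"; break }
  }

  node_claims <- apply_gd_correction(nodes, res$node_claims)
  # re-apply corrected claim CFs to tips created from those claims
  nodes <- refine_tip_cfs(nodes, node_claims)
  for (b in unique(nodes$biopsy[nodes$type == "tip"])) {
    sel <- which(nodes$type == "tip" & nodes$biopsy == b)
    nodes$lineage[sel[order(-nodes$cf[sel])]] <- seq_along(sel)
  }
  f <- be_forest(patient, nodes, status = status,
                 dropped_biopsies = unname(sample_biopsy[dropped_s]))
  attr(f, "log") <- log
  attr(f, "claims") <- node_claims
  f
}

#' Deconvolute every patient of a cohort
#'
#' @param cohort a [be_cohort()].
#' @param config a [be_config()].
#' @param verbose print a one-line log per patient.
#' @return Named list of [be_forest()] objects.
#' @export
deconvolute_cohort <- function(cohort, config = be_config(), verbose = FALSE) {
  patients <- unique(cohort$meta$patient)
  out <- lapply(patients, function(p) {
    f <- deconvolute_patient(cohort, p, config)
    if (verbose) {
      lg <- attr(f, "log")
      message(sprintf("deconvolute %s: %d SNVs, %d LOH-excluded, %d dropped biopsies, %d origin(s), %s",
                      p, lg$n_snvs, lg$loh_excluded, length(lg$dropped_biopsies),
                      count_origins(f), f$status))
    }
    f
  })
  setNames(out, patients)
}

#' Estimate tip cell fractions from supporting partitions
#'
#' Exposed wrapper over the weighted-average rule used inside
#' [deconvolute_patient()]: each tip's CF is the SNV-count-weighted mean
#' of the CF estimates from all branches on its root path in which the
#' tip is its sample's only lineage.
#'
#' @param forest a [be_forest()] with a `claims` attribute.
#' @return The forest with refined tip CFs.
#' @export
estimate_tip_cfs <- function(forest) {
  forest$nodes <- refine_tip_cfs(forest$nodes, attr(forest, "claims"))
  forest
}
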