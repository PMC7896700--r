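#' Classify a patient's biopsies as Upper or Lower
#'
#' The lowest biopsy, and any biopsy closer to it than to the highest,
#' is labelled `"L"`; the rest are `"U"`.  Biopsies equidistant between
#' lowest and highest join the less numerous group, or `"U"` when the
#' groups are equal.  Patients whose biopsies all sit at the same
#' distance from the gastroesophageal junction cannot be classified and
#' return `NULL` (excluded from the spatial analysis).
#'
#' @param gej_cm named numeric vector of distances (cm) above the GEJ,
#'   one per biopsy.
#' @return Named character vector of `"U"`/`"L"`, or `NULL`.
#' @export
classify_upper_lower <- function(gej_cm) {
  lo <- min(gej_cm); hi <- max(gej_cm)
  if (lo == hi) return(NULL)
  d_lo <- gej_cm - lo; d_hi <- hi - gej_cm
  lab <- ifelse(d_lo < d_hi, "L", ifelse(d_lo > d_hi, "U", NA))
  if (anyNA(lab)) {
    nl <- sum(lab == "L", na.rm = TRUE); nu <- sum(lab == "U", na.rm = TRUE)
    lab[is.na(lab)] <- if (nl < nu) "L" else if (nu < nl) "U" else "U"
  }
  setNames(lab, names(gej_cm))
}

# Precomputed traversal context for repeated parsimony scoring.
sankoff_ctx <- function(forest) {
  nodes <- forest$nodes
  idx <- setNames(seq_len(nrow(nodes)), as.character(nodes$id))
  po <- unname(idx[as.character(postorder_ids(nodes))])
  kids <- lapply(nodes$id, function(p) unname(idx[as.character(nodes$id[!is.na(nodes$parent) & nodes$parent == p])]))
  roots <- unname(idx[as.character(forest_roots(nodes))])
  is_tip <- nodes$type == "tip"
  list(po = po, kids = kids, roots = roots, is_tip = is_tip,
       tip_biopsy = nodes$biopsy, n = nrow(nodes))
}

# Minimum-cost (Sankoff) state changes over a forest; `tip_state` is an
# integer state index per node row (tips only used), `cost` an S x S
# transition cost matrix.  No cost is scored between disjoint trees.
sankoff_score <- function(ctx, tip_state, cost) {
  S <- ncol(cost)
  M <- matrix(0, ctx$n, S)
  for (i in ctx$po) {
    if (ctx$is_tip[i]) {
      v <- rep(Inf, S); v[tip_state[i]] <- 0
    } else {
      v <- rep(0, S)
      for (k in ctx$kids[[i]]) {
        mc <- M[k, ]
        v <- v + vapply(seq_len(S), function(s) min(cost[s, ] + mc), numeric(1))
      }
    }
    M[i, ] <- v
  }
  sum(vapply(ctx$roots, function(r) min(M[r, ]), numeric(1)))
}

#' Minimum parsimony state changes required by a forest
#'
#' For an unordered trait the count is the classic minimum number of
#' state transitions (Fitch on bifurcating trees, generalized to
#' multifurcations); for an ordered trait the cost of a change is the
#' absolute difference of the numeric states (Wagner parsimony).  Changes
#' are never scored between disjoint trees.
#'
#' @param forest a [be_forest()].
#' @param tip_states labels named by biopsy; all tips of a biopsy share
#'   its state.  Character for unordered, numeric for ordered.
#' @param mode `"unordered"` or `"ordered"`.
#' @return Minimum total number of changes (unordered) or total change
#'   (ordered), summed over the forest's trees.
#' @export
parsimony_changes <- function(forest, tip_states,
                              mode = c("unordered", "ordered")) {
  mode <- match.arg(mode)
  ctx <- sankoff_ctx(forest)
  bio <- ctx$tip_biopsy
  if (any(ctx$is_tip & !bio %in% names(tip_states))) {
    stop("parsimony_changes: unlabeled tip", call. = FALSE)
  }
  vals <- tip_states[bio]
  if (mode == "unordered") {
    states <- sort(unique(unname(tip_states)))
    cost <- 1 - diag(length(states))
  } else {
    states <- sort(unique(as.numeric(tip_states)))
    cost <- abs(outer(states, states, "-"))
  }
  tip_state <- match(vals, states)
  sankoff_score(ctx, tip_state, cost)
}

#' Permutation p-value with randomized tie breaking
#'
#' The p-value is the fraction of resampled statistics more extreme than
#' the observed one; ties between resampled and observed values are
#' resolved by fair coin flips.  For a two-tailed test the smaller tail
#' fraction is doubled and capped at 1.  A p of exactly zero is reported
#' as below one over the number of resamples.
#'
#' @param observed observed statistic.
#' @param resampled numeric vector of resampled statistics.
#' @param tail `"less"` (smaller is more extreme), `"greater"`, or
#'   `"two"`.
#' @param name test label.
#' @param seed seed recorded in the result (set it before resampling).
#' @return A `be_permtest` list: name, observed, null_mean, n_resamples,
#'   tail, p_value (in (0, 1\]), p_label, less_than.
#' @export
permutation_pvalue <- function(observed, resampled,
                               tail = c("less", "greater", "two"),
                               name = "permutation test", seed = NA) {
  tail <- match.arg(tail)
  n <- length(resampled)
  stopifnot(n >= 1)
  a_less <- sum(resampled < observed)
  a_greater <- sum(resampled > observed)
  t_ties <- n - a_less - a_greater
  r <- stats::rbinom(1, t_ties, 0.5)
  p <- switch(tail,
    less = (a_less + r) / n,
    greater = (a_greater + r) / n,
    two = min(1, 2 * min((a_less + r) / n, (a_greater + (t_ties - r)) / n))
  )
  less_than <- p == 0
  structure(list(
    name = name, observed = observed, null_mean = mean(resampled),
    n_resamples = n, tail = tail,
    p_value = if (less_than) 1 / n else p,
    p_label = if (less_than) sprintf("<%.4g", 1 / n) else sprintf("%.4g", p),
    less_than = less_than, seed = seed
  ), class = "be_permtest")
}

#' @export
print.be_permtest <- function(x, ...) {
  cat(sprintf("%s: observed %.4g (null mean %.4g), %s-tailed p %s (n = %d)\n",
              x$name, x$observed, x$null_mean,
              if (x$tail == "two") "two" else "one", x$p_label, x$n_resamples))
  invisible(x)
}

# All permutations of a vector (n <= 7 expected).
all_perms <- function(v) {
  n <- length(v)
  if (n <= 1L) return(matrix(v, nrow = 1L))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- all_perms(v[-i])
    out[[i]] <- cbind(v[i], rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

# Distinct permutations of a label multiset, with multiplicities.
distinct_labelings <- function(labels) {
  pm <- all_perms(labels)
  key <- apply(pm, 1L, paste, collapse = "\r")
  tab <- table(key)
  first <- match(names(tab), key)
  list(labelings = pm[first, , drop = FALSE], weight = as.numeric(tab))
}

# Patients usable for tree statistics: resolved, non-empty forests.
usable_forests <- function(forests) {
  Filter(function(f) f$status == "ok" && nrow(f$nodes) > 0, forests)
}

#' Permutation test of phylogenetic clustering of a biopsy trait
#'
#' The statistic is the summed minimum number of parsimony state changes
#' over patients' forests; the null permutes the trait labels among each
#' patient's biopsies (all tips of a biopsy move together).  Clustering
#' means fewer changes than expected, so the test is one-tailed.
#'
#' @param forests named list of [be_forest()].
#' @param meta cohort metadata (see [be_cohort()]).
#' @param labeling `"upper_lower"` (unordered U/L), `"time_point"`
#'   (unordered), or `"gej_cm"` (ordered distance in cm).
#' @param subgroup `"all"`, `"CO"` or `"NCO"`.
#' @param n_resamples number of permutation resamples.
#' @param seed RNG seed.
#' @return A `be_permtest`.
#' @export
clustering_test <- function(forests, meta,
                            labeling = c("upper_lower", "time_point", "gej_cm"),
                            subgroup = c("all", "CO", "NCO"),
                            n_resamples = 10000, seed = 1) {
  labeling <- match.arg(labeling)
  subgroup <- match.arg(subgroup)
  set.seed(seed)
  forests <- usable_forests(forests)
  if (subgroup != "all") {
    keep <- vapply(names(forests), function(p) {
      meta$outcome[meta$patient == p][1] == subgroup
    }, logical(1))
    forests <- forests[keep]
  }
  if (!length(forests)) stop("clustering_test: empty subgroup", call. = FALSE)
  mode <- if (labeling == "gej_cm") "ordered" else "unordered"

  observed <- 0
  res <- matrix(0, n_resamples, 1)
  for (p in names(forests)) {
    f <- forests[[p]]
    bios <- unique(f$nodes$biopsy[f$nodes$type == "tip"])
    mp <- meta[meta$patient == p & meta$biopsy %in% bios, , drop = FALSE]
    labels <- switch(labeling,
      upper_lower = classify_upper_lower(setNames(mp$gej_cm, mp$biopsy)),
      time_point = setNames(mp$time_point, mp$biopsy),
      gej_cm = setNames(mp$gej_cm, mp$biopsy)
    )
    if (is.null(labels)) next  # all biopsies at the same distance
    score <- function(lab) {
      parsimony_changes(f, setNames(lab, names(labels)), mode)
    }
    observed <- observed + score(unname(labels))
    dl <- distinct_labelings(unname(labels))
    scores <- apply(dl$labelings, 1L, score)
    draw <- sample.int(length(scores), n_resamples, replace = TRUE,
                       prob = dl$weight)
    res <- res + scores[draw]
  }
  permutation_pvalue(observed, as.numeric(res), tail = "less",
                     name = sprintf("clustering (%s, %s)", labeling, subgroup),
                     seed = seed)
}

# Subclonal samples: represented by two or more lineages in the forest
# (subclonality evident only in private SNVs is disregarded upstream).
subclonal_samples <- function(forests) {
  out <- list()
  for (f in usable_forests(forests)) {
    tips <- f$nodes[f$nodes$type == "tip", , drop = FALSE]
    cnt <- table(tips$sample)
    out[[f$patient_id]] <- data.frame(
      patient = f$patient_id, sample = names(cnt),
      subclonal = as.numeric(cnt) >= 2, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Permutation tests of the distribution of subclonal samples
#'
#' A sample is subclonal when the forest represents it by two or more
#' lineages.  Four two-tailed tests permute subclonality status across
#' samples of the whole data set: (1) clustering of subclonal samples
#' within patients (statistic: number of patients with at least one
#' subclonal sample); imbalance between (2) CO and NCO patients, (3)
#' Upper and Lower positions, and (4) TP1 and TP2 (TP3 samples omitted).
#'
#' @inheritParams clustering_test
#' @return Named list of `be_permtest` objects.
#' @export
subclonality_tests <- function(forests, meta, n_resamples = 10000, seed = 1) {
  set.seed(seed)
  sc <- subclonal_samples(forests)
  sc <- merge(sc, meta, by = c("patient", "sample"), sort = FALSE)
  ul <- rep(NA_character_, nrow(sc))
  for (p in unique(sc$patient)) {
    rows <- which(sc$patient == p)
    lab <- classify_upper_lower(setNames(sc$gej_cm[rows], sc$biopsy[rows]))
    if (!is.null(lab)) ul[rows] <- lab[sc$biopsy[rows]]
  }
  sc$ul <- ul

  run <- function(include, stat_fn, name) {
    d <- sc[include, , drop = FALSE]
    k <- sum(d$subclonal)
    obs <- stat_fn(d, which(d$subclonal))
    res <- vapply(seq_len(n_resamples), function(i) {
      stat_fn(d, sample.int(nrow(d), k))
    }, numeric(1))
    permutation_pvalue(obs, res, tail = "two", name = name, seed = seed)
  }
  list(
    patient_clustering = run(rep(TRUE, nrow(sc)),
      function(d, idx) length(unique(d$patient[idx])),
      "subclonality clustering among patients"),
    co_nco = run(rep(TRUE, nrow(sc)),
      function(d, idx) sum(d$outcome[idx] == "CO"),
      "subclonal samples in CO vs NCO"),
    upper_lower = run(!is.na(sc$ul),
      function(d, idx) sum(d$ul[idx] == "U"),
      "subclonal samples in Upper vs Lower"),
    tp1_tp2 = run(sc$time_point != "TP3",
      function(d, idx) sum(d$time_point[idx] == "TP1"),
      "subclonal samples in TP1 vs TP2")
  )
}

# Branch table for resampling: every node's edge with its SNV length,
# descendant leaf count and descendant CF sum.
branch_table <- function(forest) {
  nodes <- forest$nodes
  dtips <- desc_tip_ids(nodes)
  data.frame(
    patient = forest$patient_id,
    node = nodes$id,
    len = ifelse(is.na(nodes$n_snvs), 0, nodes$n_snvs),
    leaves = vapply(as.character(nodes$id), function(k) length(dtips[[k]]), numeric(1)),
    cf = vapply(as.character(nodes$id), function(k) {
      sum(nodes$cf[match(dtips[[k]], nodes$id)])
    }, numeric(1)),
    gd = nodes$gd,
    stringsAsFactors = FALSE
  )
}

# Strictly tipward node ids for every node.
tipward_ids <- function(nodes) {
  lapply(setNames(nodes$id, as.character(nodes$id)), function(id) {
    nodes$id[vapply(nodes$id, function(j) id %in% ancestor_ids(nodes, j), logical(1))]
  })
}

#' Clonal expansion test for a candidate locus
#'
#' For lineages carrying functional mutations in the locus, the total
#' number of descendant phylogeny leaves and the total cell fraction of
#' those leaves are compared with resampled data in which the same
#' number of mutations per patient is placed on branches at random,
#' weighted by branch SNV length.  Placements restricted by
#' `zygosity_filter`: `"het"` counts only lineage segments where at least
#' one wild-type copy remains, `"hom"` only segments after loss of the
#' wild-type allele (secondary events re-placed tipward of the initial
#' mutation in resamples, mirroring the ancestral-heterozygous
#' assumption).  Two-tailed.
#'
#' @param forests named list of [be_forest()].
#' @param placements from [place_candidate_mutations()]/[assign_cohort()].
#' @param locus locus symbol.
#' @param zygosity_filter `"all"`, `"het"`, or `"hom"`.
#' @param n_resamples,seed resampling controls.
#' @return list of `be_permtest`: `leaves` and `cf`.
#' @export
expansion_test <- function(forests, placements, locus,
                           zygosity_filter = c("all", "het", "hom"),
                           n_resamples = 10000, seed = 1) {
  zygosity_filter <- match.arg(zygosity_filter)
  set.seed(seed)
  pl <- placements[placements$locus == locus & placements$status == "placed", ,
                   drop = FALSE]
  if (!nrow(pl)) stop(sprintf("no placements for locus %s", locus), call. = FALSE)
  forests <- usable_forests(forests)

  metrics_for <- function(bt, node, sec_nodes) {
    prim <- bt[match(node, bt$node), c("leaves", "cf")]
    sec <- if (length(sec_nodes)) {
      colSums(bt[match(sec_nodes, bt$node), c("leaves", "cf"), drop = FALSE])
    } else c(leaves = 0, cf = 0)
    switch(zygosity_filter,
      all = unlist(prim),
      het = pmax(0, unlist(prim) - sec),
      hom = sec
    )
  }
  # a pure placement contributes its primary branch under its own class
  contrib <- function(bt, node, zyg, sec_nodes) {
    if (!length(sec_nodes)) {
      m <- unlist(bt[match(node, bt$node), c("leaves", "cf")])
      ok <- switch(zygosity_filter, all = TRUE,
                   het = zyg == "heterozygous", hom = zyg == "homozygous")
      return(if (ok) m else c(leaves = 0, cf = 0))
    }
    metrics_for(bt, node, sec_nodes)
  }

  bts <- lapply(forests, branch_table)
  tw <- lapply(forests, function(f) tipward_ids(f$nodes))

  obs <- c(leaves = 0, cf = 0)
  res <- matrix(0, n_resamples, 2, dimnames = list(NULL, c("leaves", "cf")))
  for (p in unique(pl$patient)) {
    if (!p %in% names(forests)) next
    bt <- bts[[p]]; tw_p <- tw[[p]]
    rows <- which(pl$patient == p)
    for (i in rows) {
      sec <- if (nzchar(pl$secondary_nodes[i])) {
        as.integer(strsplit(pl$secondary_nodes[i], ",")[[1]])
      } else integer(0)
      obs <- obs + contrib(bt, pl$node[i], pl$zygosity[i], sec)
      k <- length(sec)
      if (k == 0L) {
        if (sum(bt$len) == 0) next
        draw <- sample(bt$node, n_resamples, replace = TRUE, prob = bt$len)
        m <- as.matrix(bt[match(draw, bt$node), c("leaves", "cf")])
        ok <- switch(zygosity_filter, all = TRUE,
                     het = pl$zygosity[i] == "heterozygous",
                     hom = pl$zygosity[i] == "homozygous")
        if (ok) res <- res + m
      } else {
        eligible <- bt$node[vapply(as.character(bt$node), function(nk) {
          sum(bt$len[match(tw_p[[nk]], bt$node)] > 0) >= k
        }, logical(1)) & bt$len > 0]
        if (!length(eligible)) next
        for (rsp in seq_len(n_resamples)) {
          init <- if (length(eligible) == 1L) eligible else
            sample(eligible, 1L, prob = bt$len[match(eligible, bt$node)])
          below <- tw_p[[as.character(init)]]
          below <- below[bt$len[match(below, bt$node)] > 0]
          secs <- if (length(below) == 1L) below else
            sample(below, k, prob = bt$len[match(below, bt$node)])
          res[rsp, ] <- res[rsp, ] + metrics_for(bt, init, secs)
        }
      }
    }
  }
  list(
    leaves = permutation_pvalue(obs["leaves"], res[, "leaves"], tail = "two",
      name = sprintf("expansion of %s (%s): leaves", locus, zygosity_filter),
      seed = seed),
    cf = permutation_pvalue(obs["cf"], res[, "cf"], tail = "two",
      name = sprintf("expansion of %s (%s): cell fraction", locus, zygosity_filter),
      seed = seed)
  )
}

#' Dispersion test: concentration of a locus's mutations among patients
#'
#' The observed number of patients carrying at least one functional
#' mutation in the locus is compared with resamples placing the same
#' total number of mutations at random across all patients' branches,
#' proportional to branch lengths.  Two-tailed: mutations may concentrate
#' in few patients or disperse across many.
#'
#' @inheritParams expansion_test
#' @return A `be_permtest`.
#' @export
dispersion_test <- function(forests, placements, locus,
                            n_resamples = 10000, seed = 1) {
  set.seed(seed)
  pl <- placements[placements$locus == locus & placements$status == "placed", ,
                   drop = FALSE]
  if (!nrow(pl)) stop(sprintf("no placements for locus %s", locus), call. = FALSE)
  forests <- usable_forests(forests)
  pool <- do.call(rbind, lapply(forests, branch_table))
  pool <- pool[pool$len > 0, , drop = FALSE]
  m <- nrow(pl)
  obs <- length(unique(pl$patient))
  draws <- matrix(sample.int(nrow(pool), m * n_resamples, replace = TRUE,
                             prob = pool$len), nrow = m)
  res <- apply(draws, 2L, function(ix) length(unique(pool$patient[ix])))
  permutation_pvalue(obs, res, tail = "two",
                     name = sprintf("dispersion of %s across patients", locus),
                     seed = seed)
}

# Event branches for ordering analysis: placements of a locus, or
# genome-doubling branches when locus == "GD".
ordering_events <- function(forests, placements, locus) {
  if (identical(locus, "GD")) {
    out <- list()
    for (f in usable_forests(forests)) {
      ids <- f$nodes$id[f$nodes$gd]
      if (length(ids)) out[[f$patient_id]] <- ids
    }
    return(out)
  }
  pl <- placements[placements$locus == locus & placements$status == "placed", ,
                   drop = FALSE]
  split(pl$node, pl$patient)
}

#' Phylogenetic ordering of events in two candidate loci (or a locus and GD)
#'
#' For every patient with at least one event in each locus, each event
#' pair is classified as same-branch, A-first (A's branch ancestral to
#' B's), B-first, or skew (including disjoint trees); indicator vectors
#' are averaged within a patient and summed over patients.  The expected
#' configuration counts come from resamples that re-place each patient's
#' events at random, weighted by branch lengths.  Heterogeneity between
#' observed and expected counts is assessed with a chi-square statistic
#' (default 6 degrees of freedom).
#'
#' @param forests named list of [be_forest()].
#' @param placements placement table ([assign_cohort()]).
#' @param locus_a,locus_b locus symbols, or `"GD"` for genome doubling.
#' @param n_resamples,seed resampling controls.
#' @param df chi-square degrees of freedom.
#' @return list: observed and expected 4-vectors, n_patients, statistic,
#'   p_value, most_elevated.
#' @export
ordering_test <- function(forests, placements, locus_a, locus_b,
                          n_resamples = 10000, seed = 1, df = 6) {
  set.seed(seed)
  ev_a <- ordering_events(forests, placements, locus_a)
  ev_b <- ordering_events(forests, placements, locus_b)
  patients <- intersect(names(ev_a), names(ev_b))
  patients <- patients[patients %in% names(usable_forests(forests))]
  if (!length(patients)) {
    return(list(observed = NULL, n_patients = 0L, p_value = NA_real_,
                skipped = TRUE))
  }
  cats <- c("same_branch", "a_first", "b_first", "skew")
  anc <- lapply(forests[patients], function(f) {
    lapply(setNames(f$nodes$id, as.character(f$nodes$id)),
           function(i) ancestor_ids(f$nodes, i))
  })
  config_vec <- function(p, a_nodes, b_nodes) {
    v <- c(0, 0, 0, 0)
    np <- 0L
    for (a in a_nodes) for (b in b_nodes) {
      np <- np + 1L
      if (a == b) v[1] <- v[1] + 1
      else if (a %in% anc[[p]][[as.character(b)]]) v[2] <- v[2] + 1
      else if (b %in% anc[[p]][[as.character(a)]]) v[3] <- v[3] + 1
      else v[4] <- v[4] + 1
    }
    v / np
  }
  bts <- lapply(forests[patients], branch_table)
  obs <- c(0, 0, 0, 0)
  res <- matrix(0, n_resamples, 4)
  for (p in patients) {
    obs <- obs + config_vec(p, ev_a[[p]], ev_b[[p]])
    bt <- bts[[p]]
    w <- bt$len
    if (sum(w) == 0) next
    na <- length(ev_a[[p]]); nb <- length(ev_b[[p]])
    da <- matrix(sample(bt$node, na * n_resamples, replace = TRUE, prob = w), nrow = na)
    db <- matrix(sample(bt$node, nb * n_resamples, replace = TRUE, prob = w), nrow = nb)
    for (rsp in seq_len(n_resamples)) {
      res[rsp, ] <- res[rsp, ] + config_vec(p, da[, rsp], db[, rsp])
    }
  }
  expected <- colMeans(res)
  floor_e <- pmax(expected, 0.5 / n_resamples)
  stat <- sum((obs - floor_e)^2 / floor_e)
  list(
    observed = setNames(obs, cats),
    expected = setNames(expected, cats),
    n_patients = length(patients),
    statistic = stat, df = df,
    p_value = stats::pchisq(stat, df, lower.tail = FALSE),
    most_elevated = cats[which.max(obs / floor_e)],
    seed = seed
  )
}

#' Benjamini-Hochberg corrected q-values
#'
#' Standard step-up false-discovery-rate correction within one family of
#' tests; a thin wrapper over [stats::p.adjust()].
#'
#' @param p numeric p-values in \[0, 1\].
#' @return q-values, same order as `p`.
#' @export
bh_correct <- function(p) {
  if (!length(p)) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Run the full statistics battery over a deconvoluted cohort
#'
#' Families mirror the analysis tables: nine clustering tests (three
#' labelings x all/CO/NCO) corrected together; the four subclonality
#' tests; expansion tests per locus x metric x zygosity class; dispersion
#' per locus; and ordering for locus pairs co-mutated in at least
#' `min_pair_patients` patients (plus each locus against genome doubling
#' when present).
#'
#' @param cohort a [be_cohort()].
#' @param forests deconvoluted forests with assigned branch lengths.
#' @param placements candidate placements ([assign_cohort()]).
#' @param n_resamples resamples per test.
#' @param seed base seed; each test derives a distinct stream.
#' @param ordering_pairs optional list of `c(locus_a, locus_b)` pairs;
#'   NULL selects pairs automatically.
#' @param min_pair_patients minimum co-mutated patients for ordering.
#' @return Nested list of results with BH q-values attached per family.
#' @export
run_stats <- function(cohort, forests, placements, n_resamples = 10000,
                      seed = 1, ordering_pairs = NULL, min_pair_patients = 2) {
  meta <- cohort$meta
  off <- 0
  next_seed <- function() { off <<- off + 1; seed + off }

  clustering <- list()
  for (lab in c("time_point", "upper_lower", "gej_cm")) {
    for (sg in c("all", "CO", "NCO")) {
      clustering[[paste(lab, sg, sep = ".")]] <-
        clustering_test(forests, meta, lab, sg, n_resamples, next_seed())
    }
  }
  qs <- bh_correct(vapply(clustering, `[[`, numeric(1), "p_value"))
  for (i in seq_along(clustering)) clustering[[i]]$q_value <- qs[i]

  subclonality <- subclonality_tests(forests, meta, n_resamples, next_seed())
  qs <- bh_correct(vapply(subclonality, `[[`, numeric(1), "p_value"))
  for (i in seq_along(subclonality)) subclonality[[i]]$q_value <- qs[i]

  expansion <- list(); dispersion <- list()
  loci <- if (!is.null(placements) && nrow(placements)) {
    sort(unique(placements$locus[placements$status == "placed"]))
  } else character(0)
  for (lc in loci) {
    for (zf in c("all", "het", "hom")) {
      key <- paste(lc, zf, sep = ".")
      expansion[[key]] <- tryCatch(
        expansion_test(forests, placements, lc, zf, n_resamples, next_seed()),
        error = function(e) NULL
      )
    }
    dispersion[[lc]] <- dispersion_test(forests, placements, lc,
                                        n_resamples, next_seed())
  }
  expansion <- Filter(Negate(is.null), expansion)
  ep <- unlist(lapply(expansion, function(x) {
    c(x$leaves$p_value, x$cf$p_value)
  }))
  eq <- bh_correct(ep)
  j <- 0
  for (i in seq_along(expansion)) {
    expansion[[i]]$leaves$q_value <- eq[j + 1]
    expansion[[i]]$cf$q_value <- eq[j + 2]
    j <- j + 2
  }
  qs <- bh_correct(vapply(dispersion, `[[`, numeric(1), "p_value"))
  for (i in seq_along(dispersion)) dispersion[[i]]$q_value <- qs[i]

  has_gd <- any(vapply(usable_forests(forests),
                       function(f) any(f$nodes$gd), logical(1)))
  if (is.null(ordering_pairs)) {
    ordering_pairs <- list()
    by_pat <- if (length(loci)) {
      split(placements$locus[placements$status == "placed"],
            placements$patient[placements$status == "placed"])
    } else list()
    if (length(loci) >= 2) {
      combos <- utils::combn(loci, 2, simplify = FALSE)
      for (cmb in combos) {
        npair <- sum(vapply(by_pat, function(l) all(cmb %in% l), logical(1)))
        if (npair >= min_pair_patients) {
          ordering_pairs[[length(ordering_pairs) + 1L]] <- cmb
        }
      }
    }
    if (has_gd) {
      for (lc in loci) {
        ordering_pairs[[length(ordering_pairs) + 1L]] <- c(lc, "GD")
      }
    }
  }
  ordering <- list()
  for (pair in ordering_pairs) {
    key <- paste(pair, collapse = ".")
    ordering[[key]] <- ordering_test(forests, placements, pair[1], pair[2],
                                     n_resamples, next_seed())
  }
  ordering <- Filter(function(x) !isTRUE(x$skipped), ordering)
  if (length(ordering)) {
    qs <- bh_correct(vapply(ordering, `[[`, numeric(1), "p_value"))
    for (i in seq_along(ordering)) ordering[[i]]$q_value <- qs[i]
  }

  list(clustering = clustering, subclonality = subclonality,
       expansion = expansion, dispersion = dispersion, ordering = ordering)
}

#' Serialize statistics results to JSON
#'
#' @param stats result of [run_stats()].
#' @param path output path (`stats.json`).
#' @return Invisibly, `path`.
#' @export
write_stats_json <- function(stats, path) {
  strip <- function(x) {
    if (inherits(x, "be_permtest")) {
      unclass(x)
    } else if (is.list(x)) {
      lapply(x, strip)
    } else x
  }
  jsonlite::write_json(strip(stats), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
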