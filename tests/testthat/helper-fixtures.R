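# In-code fixtures shared across the suite.

# A tiny hand-built cohort: one patient, three samples, a handful of SNVs
# with known detection patterns.  Sample S_C carries copy-neutral LOH on
# chr2 so the LOH-exclusion rule has something to bite on.
toy_cohort <- function() {
  samples <- c("S_A", "S_B", "S_C")
  snv <- data.frame(
    patient = "PT1",
    chrom = c("1", "1", "2", "2", "3"),
    pos = c(100L, 200L, 300L, 400L, 500L),
    ref = "A", alt = "T",
    severity = c("MODIFIER", "LOW", "MODIFIER", "MODERATE", "HIGH"),
    locus = c(NA, NA, NA, "TP53", "CDKN2A"),
    stringsAsFactors = FALSE
  )
  # detection: row1 {A,B}; row2 {A,B,C}; row3 {A,B} (absent C, LOH chr2);
  # row4 {A}; row5 {C}
  alt <- rbind(c(20, 18, 0), c(15, 16, 14), c(21, 19, 1), c(12, 0, 0),
               c(0, 0, 22))
  tot <- matrix(60L, 5, 3)
  for (i in seq_along(samples)) {
    snv[[paste0(samples[i], "_alt")]] <- alt[, i]
    snv[[paste0(samples[i], "_tot")]] <- tot[, i]
  }
  cn <- expand.grid(sample = samples, chrom = c("1", "2", "3"),
                    stringsAsFactors = FALSE)
  cn$start <- 1L; cn$end <- 1000000L; cn$major <- 1; cn$minor <- 1
  cn$major[cn$sample == "S_C" & cn$chrom == "2"] <- 2
  cn$minor[cn$sample == "S_C" & cn$chrom == "2"] <- 0
  meta <- data.frame(
    patient = "PT1", biopsy = c("A", "B", "C"), sample = samples,
    time_point = c("TP1", "TP1", "TP2"), gej_cm = c(1, 3, 5),
    outcome = "NCO", ploidy_class = "near_diploid",
    gd_corroborated = FALSE, stringsAsFactors = FALSE
  )
  be_cohort(snv, cn, meta)
}

# A two-tree forest built by hand: ((A-1,B-1),C-1) plus an isolated D-1.
toy_forest <- function() {
  nodes <- data.frame(
    id = 1:7,
    parent = c(NA, 1L, 2L, 2L, 1L, NA, 6L),
    type = c("internal", "internal", "tip", "tip", "tip", "internal", "tip"),
    sample = c(NA, NA, "S_A", "S_B", "S_C", NA, "S_D"),
    biopsy = c(NA, NA, "A", "B", "C", NA, "D"),
    lineage = c(NA, NA, 1L, 1L, 1L, NA, 1L),
    cf = c(NA, NA, 0.8, 0.7, 0.6, NA, 0.9),
    n_snvs = c(0, 500, 200, 150, 300, 0, 400),
    gd = FALSE,
    claim_key = c(NA, "S_A|S_B", NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  be_forest("PT1", nodes)
}

# Minimal claim constructor for assembly tests.
claim <- function(samples, cf, n, gd = FALSE) {
  list(key = paste(sort(samples), collapse = "|"), samples = samples,
       cf = setNames(cf, samples), n = n, gd = gd, by_ref = TRUE)
}

# Small random forest generator for parsimony property tests: a single
# random bifurcating tree with ntips tips, each its own biopsy.
random_tree_forest <- function(ntips) {
  nodes <- empty_nodes_for_tests()
  for (i in seq_len(ntips)) {
    nodes <- rbind(nodes, data.frame(
      id = i, parent = NA_integer_, type = "tip",
      sample = paste0("S", i), biopsy = paste0("B", i), lineage = 1L,
      cf = 0.8, n_snvs = 10, gd = FALSE, claim_key = NA_character_,
      stringsAsFactors = FALSE
    ))
  }
  roots <- seq_len(ntips)
  next_id <- ntips
  while (length(roots) > 1L) {
    pick <- sample(seq_along(roots), 2L)
    next_id <- next_id + 1L
    nodes <- rbind(nodes, data.frame(
      id = next_id, parent = NA_integer_, type = "internal",
      sample = NA_character_, biopsy = NA_character_, lineage = NA_integer_,
      cf = NA_real_, n_snvs = 10, gd = FALSE, claim_key = NA_character_,
      stringsAsFactors = FALSE
    ))
    nodes$parent[nodes$id %in% roots[pick]] <- next_id
    roots <- c(roots[-pick], next_id)
  }
  be_forest("RT", nodes)
}

empty_nodes_for_tests <- function() {
  data.frame(
    id = integer(), parent = integer(), type = character(),
    sample = character(), biopsy = character(), lineage = integer(),
    cf = numeric(), n_snvs = numeric(), gd = logical(),
    claim_key = character(), stringsAsFactors = FALSE
  )
}

# Ordered-parsimony oracle over a state grid denser than the tip values.
brute_force_parsimony_dense <- function(forest, tip_states) {
  nodes <- forest$nodes
  internals <- nodes$id[nodes$type == "internal"]
  tips <- nodes$id[nodes$type == "tip"]
  states <- seq(min(tip_states), max(tip_states), by = 0.5)
  tip_val <- tip_states[nodes$biopsy[match(tips, nodes$id)]]
  grid <- do.call(expand.grid, rep(list(states), length(internals)))
  edges <- nodes[!is.na(nodes$parent), c("id", "parent")]
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    assign <- setNames(as.numeric(grid[r, ]), internals)
    val_of <- function(id) {
      if (id %in% tips) tip_val[[match(id, tips)]] else assign[[as.character(id)]]
    }
    tot <- 0
    for (e in seq_len(nrow(edges))) {
      tot <- tot + abs(val_of(edges$id[e]) - val_of(edges$parent[e]))
    }
    best <- min(best, tot)
  }
  best
}

# Exhaustive minimum-change oracle: enumerate internal-node state
# assignments over the given candidate states and take the cheapest.
brute_force_parsimony <- function(forest, tip_states, mode) {
  nodes <- forest$nodes
  internals <- nodes$id[nodes$type == "internal"]
  tips <- nodes$id[nodes$type == "tip"]
  states <- if (mode == "ordered") {
    sort(unique(as.numeric(tip_states)))
  } else sort(unique(unname(tip_states)))
  cost <- if (mode == "ordered") {
    function(a, b) abs(a - b)
  } else function(a, b) as.numeric(a != b)
  tip_val <- tip_states[nodes$biopsy[match(tips, nodes$id)]]
  grid <- do.call(expand.grid, c(rep(list(states), length(internals)),
                                 list(stringsAsFactors = FALSE)))
  best <- Inf
  edges <- nodes[!is.na(nodes$parent), c("id", "parent")]
  for (r in seq_len(nrow(grid))) {
    assign <- setNames(as.list(grid[r, ]), internals)
    val_of <- function(id) {
      if (id %in% tips) tip_val[[match(id, tips)]] else assign[[as.character(id)]]
    }
    tot <- 0
    for (e in seq_len(nrow(edges))) {
      tot <- tot + cost(val_of(edges$id[e]), val_of(edges$parent[e]))
    }
    best <- min(best, tot)
  }
  best
}
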