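# Conservation and structural invariants on an end-to-end simulated
# cohort.  One small cohort is shared across the blocks.
prop_env <- new.env()
prop_cohort <- function() {
  if (is.null(prop_env$sim)) {
    sp <- sim_params(n_patients = 4, seed = 31)
    prop_env$sim <- simulate_cohort(sp)
    prop_env$res <- suppressWarnings(run_pipeline(prop_env$sim$cohort))
  }
  prop_env
}

test_that("partition sizes sum to the patient's detected SNV count", {
  e <- prop_cohort()
  co <- e$sim$cohort
  for (p in unique(co$meta$patient)) {
    det <- beclone:::detection_matrix(co, p, 3)
    det <- det[rowSums(det) > 0, , drop = FALSE]
    parts <- partition_snvs(det)
    expect_equal(sum(parts$n_snvs), nrow(det))
  }
})

test_that("branch lengths plus discordant SNVs account for every usable SNV", {
  e <- prop_cohort()
  a <- e$res$assignments
  for (p in unique(a$patient)) {
    ap <- a[a$patient == p, ]
    f <- e$res$forests[[p]]
    expect_equal(sum(f$nodes$n_snvs),
                 sum(ap$status %in% c("placed", "private")))
    expect_equal(sum(ap$status %in% c("placed", "discordant", "private",
                                      "undetected")), nrow(ap))
  }
})

test_that("per-biopsy cell fractions sum to at most one plus tolerance", {
  e <- prop_cohort()
  for (f in e$res$forests) {
    if (f$status != "ok") next
    tips <- f$nodes[f$nodes$type == "tip", ]
    if (!nrow(tips)) next
    sums <- tapply(tips$cf, tips$sample, sum)
    expect_true(all(sums <= 1.05))
    expect_true(all(tips$cf > 0))
  }
})

test_that("zygosity calls recover the simulated truth for well-powered mutations", {
  # Pool candidate placements over a few cohorts; compare inferred
  # zygosity with the generator's, for carrying lineages with CF >= 0.3
  # at 60x depth.
  set.seed(77)
  correct <- 0L; total <- 0L
  for (seed in c(101, 103, 107)) {
    sp <- sim_params(n_patients = 3, seed = seed, p_unbalanced_cn = 0,
                     p_genome_doubling = 0)
    sim <- simulate_cohort(sp)
    res <- suppressWarnings(run_pipeline(sim$cohort))
    pl <- res$placements
    if (is.null(pl)) next
    for (p in unique(pl$patient)) {
      truth <- sim$truths[[p]]$placements
      est <- pl[pl$patient == p & pl$status == "placed", ]
      if (!nrow(truth) || !nrow(est)) next
      # match by locus (loci with exactly one mutation in both)
      for (lc in intersect(truth$locus, est$locus)) {
        tl <- truth[truth$locus == lc, ]; el <- est[est$locus == lc, ]
        if (nrow(tl) != 1L || nrow(el) != 1L) next
        if (nzchar(el$secondary_nodes)) next  # mixed calls judged separately
        total <- total + 1L
        if (tl$zygosity == el$zygosity) correct <- correct + 1L
      }
    }
  }
  expect_gt(total, 10L)
  expect_gte(correct / total, 0.9)
})

test_that("unresolvable status is reserved for genuinely conflicting claims", {
  cfg <- be_config(max_reclassify = 0)
  # two full-CF claims over the same biopsy cannot coexist
  f <- assemble_forest(list(
    claim(c("A", "B"), c(0.95, 0.9), 500),
    claim(c("A", "C"), c(0.9, 0.95), 400)
  ), c("A", "B", "C"), cfg)
  tips <- f$nodes[f$nodes$type == "tip", ]
  sums <- tapply(tips$cf, tips$sample, sum)
  expect_gt(max(sums), 1.05)  # assembly alone over-fills the biopsy
  # the driver resolves this by dropout reclassification or flags it
})
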