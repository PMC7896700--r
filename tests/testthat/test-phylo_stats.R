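test_that("biopsies split into Upper and Lower by the distance rule", {
  expect_equal(unname(classify_upper_lower(c(a = 1, b = 2, c = 5))),
               c("L", "L", "U"))
  # 3 is equidistant; L and U are equal in size, so it goes to U
  expect_equal(unname(classify_upper_lower(c(a = 1, b = 3, c = 5))),
               c("L", "U", "U"))
  # equidistant joins the less numerous side (here U, which has 1 vs 2)
  expect_equal(unname(classify_upper_lower(c(a = 1, b = 2, c = 3, d = 5))),
               c("L", "L", "U", "U"))
  expect_null(classify_upper_lower(c(a = 4, b = 4, c = 4, d = 4)))
})

test_that("parsimony counts match the textbook cases", {
  mk <- function(parent, biopsy) {
    n <- length(parent)
    nodes <- data.frame(
      id = seq_len(n), parent = parent,
      type = ifelse(is.na(biopsy), "internal", "tip"),
      sample = biopsy, biopsy = biopsy,
      lineage = ifelse(is.na(biopsy), NA, 1L), cf = 0.8, n_snvs = 1,
      gd = FALSE, claim_key = NA_character_, stringsAsFactors = FALSE
    )
    be_forest("X", nodes)
  }
  # ((t1,t2),(t3,t4)) with states L,L,U,U -> one change
  f <- mk(c(NA, 1L, 1L, 2L, 2L, 3L, 3L),
          c(NA, NA, NA, "a", "b", "c", "d"))
  expect_equal(parsimony_changes(f, c(a = "L", b = "L", c = "U", d = "U")), 1)
  expect_equal(parsimony_changes(f, c(a = "L", b = "U", c = "L", d = "U")), 2)
  # ordered trait: tips at 2, 5, 10 cm need total change 8 on any topology
  f3 <- mk(c(NA, 1L, 1L, 1L), c(NA, "a", "b", "c"))
  expect_equal(parsimony_changes(f3, c(a = 2, b = 5, c = 10), "ordered"), 8)
  # no changes are scored between disjoint trees
  f2 <- mk(c(NA, 1L, 1L, NA, 4L, 4L),
           c(NA, "a", "b", NA, "c", "d"))
  expect_equal(parsimony_changes(f2, c(a = "L", b = "L", c = "U", d = "U")), 0)
  expect_error(parsimony_changes(f3, c(a = 2, b = 5)), "unlabeled")
})

test_that("Sankoff counts equal brute-force minima on small random trees", {
  set.seed(99)
  for (i in 1:25) {
    nt <- sample(4:7, 1)
    f <- random_tree_forest(nt)
    labs <- setNames(sample(c("L", "U"), nt, replace = TRUE),
                     paste0("B", seq_len(nt)))
    expect_equal(parsimony_changes(f, labs, "unordered"),
                 brute_force_parsimony(f, labs, "unordered"))
    vals <- setNames(sample(c(2, 5, 9), nt, replace = TRUE),
                     paste0("B", seq_len(nt)))
    expect_equal(parsimony_changes(f, vals, "ordered"),
                 brute_force_parsimony(f, vals, "ordered"))
  }
})

test_that("ordered parsimony is not improved by off-tip internal states", {
  # candidate states denser than the tip values never beat the tip-value
  # lattice for linear costs
  set.seed(7)
  for (i in 1:5) {
    f <- random_tree_forest(5)
    vals <- setNames(sample(c(1, 4, 9), 5, replace = TRUE), paste0("B", 1:5))
    lattice <- parsimony_changes(f, vals, "ordered")
    dense <- brute_force_parsimony_dense(f, vals)
    expect_equal(lattice, dense)
  }
})

test_that("the permutation p-value implements the randomized-tie rule", {
  set.seed(1)
  r <- permutation_pvalue(1, rep(5, 10000), tail = "less")
  expect_true(r$less_than)
  expect_match(r$p_label, "^<")
  expect_equal(r$p_value, 1e-4)

  # observed equal to every resample: expected p about one half
  ps <- replicate(200, permutation_pvalue(3, rep(3, 100), tail = "less")$p_value)
  expect_equal(mean(ps), 0.5, tolerance = 0.05)

  # observed at the median of a symmetric null, two-tailed: p near 1
  r2 <- permutation_pvalue(0, c(rep(-1, 5000), rep(1, 5000)), tail = "two")
  expect_gt(r2$p_value, 0.9)
})

test_that("clustering test points in the right direction and handles constants", {
  # perfectly spatially sorted tree over 6 biopsies: small p
  nodes <- data.frame(
    id = 1:11,
    parent = c(NA, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 6L, 6L),
    type = c(rep("internal", 4), "tip", "internal", "tip", "tip", "tip", "tip", "tip"),
    sample = c(NA, NA, NA, NA, "S3", NA, "S6", "S1", "S2", "S4", "S5"),
    biopsy = c(NA, NA, NA, NA, "C", NA, "F", "A", "B", "D", "E"),
    lineage = c(rep(NA, 4), 1L, NA, 1L, 1L, 1L, 1L, 1L),
    cf = 0.8, n_snvs = 1, gd = FALSE, claim_key = NA_character_,
    stringsAsFactors = FALSE
  )
  f <- be_forest("P1", nodes)
  meta <- data.frame(
    patient = "P1", biopsy = c("A", "B", "C", "D", "E", "F"),
    sample = paste0("S", 1:6), time_point = "TP1",
    gej_cm = c(1, 2, 3, 9, 10, 11), outcome = "NCO",
    ploidy_class = "near_diploid", gd_corroborated = FALSE,
    stringsAsFactors = FALSE
  )
  # tree groups {A,B,C} together ({A,B} under node4, C beside) vs {D,E,F}
  r <- clustering_test(list(P1 = f), meta, "upper_lower", "all",
                       n_resamples = 2000, seed = 3)
  expect_lt(r$p_value, 0.2)  # single patient: limited but directional
  expect_equal(r$observed, 1)

  # identical labels for all biopsies: every permutation ties at zero
  meta2 <- meta; meta2$time_point <- "TP1"
  r2 <- clustering_test(list(P1 = f), meta2, "time_point", "all",
                        n_resamples = 500, seed = 4)
  expect_equal(r2$observed, 0)
  expect_gt(r2$p_value, 0.2)
  expect_lt(abs(r2$p_value - 0.5), 0.45)

  expect_error(clustering_test(list(P1 = f), meta, "upper_lower", "CO",
                               n_resamples = 10, seed = 1), "empty")
})

test_that("subclonality tests behave at the degenerate extremes", {
  # forests: P1 has a subclonal sample, P2 none
  n1 <- data.frame(
    id = 1:4, parent = c(NA, 1L, 1L, 1L),
    type = c("internal", "tip", "tip", "tip"),
    sample = c(NA, "S1", "S1", "S2"), biopsy = c(NA, "A", "A", "B"),
    lineage = c(NA, 1L, 2L, 1L), cf = c(NA, 0.5, 0.3, 0.8),
    n_snvs = 1, gd = FALSE, claim_key = NA_character_,
    stringsAsFactors = FALSE
  )
  n2 <- data.frame(
    id = 1:3, parent = c(NA, 1L, 1L),
    type = c("internal", "tip", "tip"),
    sample = c(NA, "S3", "S4"), biopsy = c(NA, "A", "B"),
    lineage = c(NA, 1L, 1L), cf = c(NA, 0.9, 0.7),
    n_snvs = 1, gd = FALSE, claim_key = NA_character_,
    stringsAsFactors = FALSE
  )
  forests <- list(P1 = be_forest("P1", n1), P2 = be_forest("P2", n2))
  meta <- data.frame(
    patient = c("P1", "P1", "P2", "P2"), biopsy = c("A", "B", "A", "B"),
    sample = c("S1", "S2", "S3", "S4"),
    time_point = c("TP1", "TP2", "TP1", "TP2"), gej_cm = c(1, 5, 2, 6),
    outcome = c("CO", "CO", "NCO", "NCO"),
    ploidy_class = "near_diploid", gd_corroborated = FALSE,
    stringsAsFactors = FALSE
  )
  res <- subclonality_tests(forests, meta, n_resamples = 400, seed = 2)
  expect_named(res, c("patient_clustering", "co_nco", "upper_lower", "tp1_tp2"))
  # one subclonal sample total: permutation moves it anywhere, p not small
  expect_gt(res$patient_clustering$p_value, 0.2)

  # no subclonal samples at all: statistics permutation-invariant, p ~ 1
  forests0 <- list(P2 = be_forest("P2", n2))
  res0 <- subclonality_tests(forests0, meta[meta$patient == "P2", ],
                             n_resamples = 200, seed = 3)
  expect_gt(res0$patient_clustering$p_value, 0.5)
})

test_that("expansion null mean matches the branch-weighted enumeration oracle", {
  f <- toy_forest()
  bt <- beclone:::branch_table(f)
  placements <- data.frame(
    patient = "PT1", locus = "TP53", snv_row = 1L, node = 2L,
    zygosity = "heterozygous", secondary_nodes = "", status = "placed",
    stringsAsFactors = FALSE
  )
  r <- expansion_test(list(PT1 = f), placements, "TP53", "all",
                      n_resamples = 4000, seed = 5)
  # exhaustive expectation: sum over branches of len/total * leaves
  exp_leaves <- sum(bt$len / sum(bt$len) * bt$leaves)
  exp_cf <- sum(bt$len / sum(bt$len) * bt$cf)
  expect_equal(r$leaves$null_mean, exp_leaves, tolerance = 0.05)
  expect_equal(r$cf$null_mean, exp_cf, tolerance = 0.05)
  # mutation on the root branch covers every tip of its tree
  placements$node <- 1L
  r2 <- expansion_test(list(PT1 = f), placements, "TP53", "all",
                       n_resamples = 100, seed = 6)
  expect_equal(unname(r2$leaves$observed), 3)
  expect_equal(unname(r2$cf$observed), 0.8 + 0.7 + 0.6)
})

test_that("dispersion of a single mutation is uninformative by the tie rule", {
  f <- toy_forest()
  placements <- data.frame(
    patient = "PT1", locus = "TP53", snv_row = 1L, node = 2L,
    zygosity = "heterozygous", secondary_nodes = "", status = "placed",
    stringsAsFactors = FALSE
  )
  r <- dispersion_test(list(PT1 = f), placements, "TP53",
                       n_resamples = 500, seed = 7)
  expect_equal(r$observed, 1)
  expect_gt(r$p_value, 0.2)  # every resample ties the observed value
})

test_that("ordering configurations classify ancestry, same-branch and skew", {
  f <- toy_forest()  # tree1: root 1 -> node 2 (A,B tips), C tip; tree2: D
  placements <- data.frame(
    patient = "PT1",
    locus = c("TP53", "CDKN2A"),
    snv_row = 1:2, node = c(1L, 2L),
    zygosity = "heterozygous", secondary_nodes = "", status = "placed",
    stringsAsFactors = FALSE
  )
  r <- ordering_test(list(PT1 = f), placements, "TP53", "CDKN2A",
                     n_resamples = 300, seed = 8)
  expect_equal(unname(r$observed), c(0, 1, 0, 0))  # TP53 ancestral

  placements$node <- c(2L, 2L)
  r2 <- ordering_test(list(PT1 = f), placements, "TP53", "CDKN2A",
                      n_resamples = 300, seed = 9)
  expect_equal(unname(r2$observed), c(1, 0, 0, 0))

  placements$node <- c(2L, 7L)  # different disjoint trees -> skew
  r3 <- ordering_test(list(PT1 = f), placements, "TP53", "CDKN2A",
                      n_resamples = 300, seed = 10)
  expect_equal(unname(r3$observed), c(0, 0, 0, 1))
})

test_that("BH correction is the standard step-up and is order-invariant", {
  expect_equal(bh_correct(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_correct(0.2), 0.2)
  expect_equal(bh_correct(numeric(0)), numeric(0))
  set.seed(2)
  p <- runif(20)
  ord <- sample(20)
  expect_equal(bh_correct(p)[ord], bh_correct(p[ord]))
  expect_true(all(diff(sort(bh_correct(p))) >= -1e-12))
})
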