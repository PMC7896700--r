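test_that("partitions are ordered two-samples-first, larger-SNV-count-first", {
  parts <- data.frame(
    key = c("A|B", "A|C", "A|B|C", "A"),
    n_samples = c(2L, 2L, 3L, 1L),
    n_snvs = c(500L, 700L, 900L, 50L),
    private = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  expect_equal(order_partitions(parts)$key, c("A|C", "A|B", "A|B|C"))

  # full tie resolves lexicographically
  parts2 <- parts[1:2, ]
  parts2$n_snvs <- 500L
  expect_equal(order_partitions(parts2)$key, c("A|B", "A|C"))

  expect_equal(order_partitions(parts[3, ])$key, "A|B|C")
})

test_that("VAF peaks convert to cell fractions by copy arithmetic", {
  expect_equal(vaf_peak_to_cf(0.25, 1, 2), 0.5)
  expect_equal(vaf_peak_to_cf(0.40, 2, 2), 0.4)
  expect_equal(vaf_peak_to_cf(0.10, 1, 4), 0.4)
  expect_equal(vaf_peak_to_cf(0.8, 1, 2), 1)  # capped
  expect_error(vaf_peak_to_cf(0.25, 0, 2), "mut_copies")
})

test_that("multi-peak groups are interpreted by the three-hypothesis rule", {
  # (1) unbalanced copy number, ratio 2:1 in a 2+1 region
  expect_equal(interpret_multi_peaks(
    list(A = c(0.17, 0.33)), c(A = FALSE),
    list(A = c(major = 2, minor = 1))), "unbalanced_cn")

  # (2) factor-of-two peaks in corroborated genome-doubled samples
  expect_equal(interpret_multi_peaks(
    list(A = c(0.15, 0.30), B = c(0.2, 0.41)), c(A = TRUE, B = TRUE),
    list(A = c(major = 2, minor = 2), B = c(major = 2, minor = 2))),
    "genome_doubling")

  # (3) same pattern without corroboration is never called doubling
  expect_equal(interpret_multi_peaks(
    list(A = c(0.15, 0.30)), c(A = FALSE),
    list(A = c(major = 1, minor = 1))), "split_lineages")

  # balanced region, non-doubling ratio: two lineages at different depths
  expect_equal(interpret_multi_peaks(
    list(A = c(0.20, 0.50)), c(A = FALSE),
    list(A = c(major = 1, minor = 1))), "split_lineages")

  expect_equal(interpret_multi_peaks(
    list(A = c(0.1, 0.2, 0.3, 0.4)), c(A = FALSE),
    list(A = c(major = 1, minor = 1))), "unresolved")
})

test_that("assembly nests supersets, draws polytomies, and splits origins", {
  cfg <- be_config()
  # {A,B}:500 then {A,B,C}:400 with consistent CFs -> ((A,B),C)
  f <- assemble_forest(list(
    claim(c("A", "B"), c(0.8, 0.7), 500),
    claim(c("A", "B", "C"), c(0.8, 0.7, 0.9), 400)
  ), c("A", "B", "C"), cfg)
  expect_equal(count_origins(f), 1L)
  expect_setequal(tip_label(f$nodes)[f$nodes$type == "tip"],
                  c("A-1", "B-1", "C-1"))
  ab <- f$nodes$id[!is.na(f$nodes$claim_key) & f$nodes$claim_key == "A|B"]
  abc <- f$nodes$id[!is.na(f$nodes$claim_key) & f$nodes$claim_key == "A|B|C"]
  expect_equal(f$nodes$parent[f$nodes$id == ab], abc)

  # a three-sample partition with no pairwise support is a polytomy
  f2 <- assemble_forest(list(
    claim(c("A", "B", "C"), c(0.8, 0.7, 0.9), 1000)
  ), c("A", "B", "C"), cfg)
  root <- f2$nodes$id[is.na(f2$nodes$parent)]
  kids <- f2$nodes$id[!is.na(f2$nodes$parent) & f2$nodes$parent == root]
  expect_length(kids, 3L)
  expect_true(all(f2$nodes$type[match(kids, f2$nodes$id)] == "tip"))

  # samples never joined by a >=100-SNV partition stay disjoint trees
  f3 <- assemble_forest(list(), c("A", "B"), cfg,
                        private_cf = c(A = 0.9, B = 0.8))
  expect_equal(count_origins(f3), 2L)
})

test_that("split-lineage claims stack as nested lineages with a residual tip", {
  cfg <- be_config()
  f <- assemble_forest(list(
    claim(c("A", "B"), c(0.40, 0.50), 300),   # derived (cherry)
    claim(c("A", "B"), c(0.90, 0.50), 500)    # ancestral (adds an A lineage)
  ), c("A", "B"), cfg)
  tips <- f$nodes[f$nodes$type == "tip", ]
  expect_equal(sum(tips$biopsy == "A"), 2L)
  expect_equal(sum(tips$biopsy == "B"), 1L)
  # the residual A lineage carries the leftover cell fraction
  expect_equal(sort(tips$cf[tips$biopsy == "A"]), c(0.40, 0.50))
})

test_that("tip cell fractions average supporting partitions by SNV weight", {
  cfg <- be_config()
  f <- assemble_forest(list(
    claim(c("A", "B"), c(0.40, 0.60), 600),
    claim(c("A", "B", "C"), c(0.50, 0.62, 0.70), 200)
  ), c("A", "B", "C"), cfg)
  tips <- f$nodes[f$nodes$type == "tip", ]
  # A-1 is measured by both partitions: (0.40*600 + 0.50*200) / 800
  expect_equal(tips$cf[tips$biopsy == "A"], 0.425)
  # C-1 only by the ancestral partition
  expect_equal(tips$cf[tips$biopsy == "C"], 0.70)
})

test_that("forest distance agrees with an independent tree-distance oracle", {
  skip_if_not_installed("phangorn")
  set.seed(13)
  f1 <- random_tree_forest(6)
  expect_equal(forest_rf(f1, f1), 0L)
  # a different random resolution of the same tips: both measures nonzero
  f2 <- random_tree_forest(6)
  rf_pkg <- forest_rf(f1, f2)
  t1 <- forest_to_phylo(f1); t2 <- forest_to_phylo(f2)
  rf_oracle <- phangorn::RF.dist(t1, t2, rooted = TRUE)
  expect_equal(rf_pkg > 0, rf_oracle > 0)
  expect_equal(rf_pkg, rf_oracle)
})

test_that("origin counting ignores trees made only of dropped thin biopsies", {
  f <- toy_forest()
  expect_equal(count_origins(f), 2L)
  f$dropped_biopsies <- "D"
  expect_equal(count_origins(f), 1L)
  f$dropped_biopsies <- character()
  f$nodes <- f$nodes[1:5, ]  # single tree
  expect_equal(count_origins(f), 1L)
})
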