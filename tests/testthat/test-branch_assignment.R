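# A hand-built patient around toy_forest(): samples S_A, S_B, S_C in one
# tree (((A,B),C)), S_D isolated.
assign_fixture <- function() {
  samples <- c("S_A", "S_B", "S_C", "S_D")
  mk <- function(alt) alt
  snv <- data.frame(
    patient = "PT1",
    chrom = "1", pos = seq(1000L, 9000L, by = 1000L),
    ref = "A", alt = "T",
    severity = c(rep("MODIFIER", 7), "MODERATE", "HIGH"),
    locus = c(rep(NA, 7), "TP53", "CDKN2A"),
    stringsAsFactors = FALSE
  )
  # rows 1-3: {A,B}; row 4: {A,B,C}; row 5: {A,C} (discordant);
  # row 6: {A} private; row 7: {D}; row 8: TP53 in {A,B}, VAF ~ hom;
  # row 9: CDKN2A private to C
  alt <- rbind(
    c(24, 21, 0, 0), c(23, 22, 0, 0), c(25, 20, 0, 0),
    c(24, 20, 18, 0), c(22, 0, 17, 0), c(12, 0, 0, 0),
    c(0, 0, 0, 25),
    c(45, 40, 0, 0),     # TP53: VAF ~0.7 in A/B -> homozygous-like
    c(0, 0, 19, 0)
  )
  tot <- matrix(60L, nrow(alt), 4)
  for (i in seq_along(samples)) {
    snv[[paste0(samples[i], "_alt")]] <- alt[, i]
    snv[[paste0(samples[i], "_tot")]] <- tot[, i]
  }
  cn <- data.frame(sample = rep(samples, each = 1), chrom = "1",
                   start = 1L, end = 100000L, major = 1, minor = 1,
                   stringsAsFactors = FALSE)
  meta <- data.frame(
    patient = "PT1", biopsy = c("A", "B", "C", "D"), sample = samples,
    time_point = c("TP1", "TP1", "TP2", "TP2"), gej_cm = c(1, 2, 6, 8),
    outcome = "NCO", ploidy_class = "near_diploid", gd_corroborated = FALSE,
    stringsAsFactors = FALSE
  )
  list(cohort = be_cohort(snv, cn, meta), forest = toy_forest())
}

test_that("SNVs land on the branch matching their detected-sample set", {
  fx <- assign_fixture()
  res <- assign_snvs_to_branches(fx$cohort, "PT1", fx$forest)
  a <- res$assignments
  ab_node <- 2L  # the (A,B) clade in toy_forest
  expect_true(all(a$node[1:3] == ab_node))
  expect_true(all(a$status[1:3] == "placed"))
  expect_equal(a$node[4], 1L)           # root of tree 1 = {A,B,C}
  expect_equal(a$status[5], "discordant")  # {A,C} has no branch
  expect_equal(a$status[6], "private")
  expect_equal(a$node[6], 3L)           # A's pendant tip
  # branch lengths are assigned-SNV counts
  expect_equal(res$forest$nodes$n_snvs[res$forest$nodes$id == ab_node], 4)  # 3 + TP53
  expect_equal(sum(res$forest$nodes$n_snvs) + sum(a$status == "discordant"),
               sum(a$status %in% c("placed", "private")) + 1)
})

test_that("among equally matching branches the nearest expected VAF wins", {
  # two branches both lead to tips {A,B}: one high-CF, one low-CF
  nodes <- data.frame(
    id = 1:7,
    parent = c(NA, 1L, 2L, 2L, 1L, 5L, 5L),
    type = c("internal", "internal", "tip", "tip", "internal", "tip", "tip"),
    sample = c(NA, NA, "S_A", "S_B", NA, "S_A", "S_B"),
    biopsy = c(NA, NA, "A", "B", NA, "A", "B"),
    lineage = c(NA, NA, 1L, 1L, NA, 2L, 2L),
    cf = c(NA, NA, 0.9, 0.9, NA, 0.4, 0.4),
    n_snvs = 0, gd = FALSE, claim_key = NA_character_,
    stringsAsFactors = FALSE
  )
  f <- be_forest("PT2", nodes)
  snv <- data.frame(patient = "PT2", chrom = "1", pos = 100L, ref = "A",
                    alt = "T", severity = "MODIFIER", locus = NA,
                    S_A_alt = 25L, S_A_tot = 60L, S_B_alt = 26L, S_B_tot = 60L,
                    stringsAsFactors = FALSE)
  cn <- data.frame(sample = c("S_A", "S_B"), chrom = "1", start = 1L,
                   end = 1000L, major = 1, minor = 1, stringsAsFactors = FALSE)
  meta <- data.frame(patient = "PT2", biopsy = c("A", "B"),
                     sample = c("S_A", "S_B"), time_point = "TP1",
                     gej_cm = c(1, 2), outcome = "NCO",
                     ploidy_class = "near_diploid", gd_corroborated = FALSE,
                     stringsAsFactors = FALSE)
  co <- be_cohort(snv, cn, meta)
  res <- assign_snvs_to_branches(co, "PT2", f)
  # observed VAF ~0.42 -> expected 0.45 branch (CF 0.9) beats 0.20 (CF 0.4)
  expect_equal(res$assignments$node, 2L)
})

test_that("placed fraction counts usable SNVs only", {
  a <- data.frame(status = c(rep("placed", 95), rep("discordant", 5),
                             rep("private", 10)))
  expect_equal(placed_fraction(a), 0.95)
  expect_equal(placed_fraction(data.frame(status = rep("placed", 3))), 1.0)
  expect_warning(pf <- placed_fraction(data.frame(status = "private")),
                 "undefined")
  expect_true(is.na(pf))
})

test_that("zygosity follows the nearer expected VAF, ties to heterozygous", {
  expect_equal(assign_zygosity(0.70, 0.8, 2), "homozygous")
  expect_equal(assign_zygosity(0.50, 0.8, 2), "heterozygous")
  expect_equal(assign_zygosity(0.60, 0.8, 2), "heterozygous")  # equidistant
  expect_equal(assign_zygosity(0.10, 0.8, 4), "heterozygous")  # doubled context
})

test_that("candidate mutations prefer het-permitting branches and score secondary loss", {
  fx <- assign_fixture()
  pl <- place_candidate_mutations(fx$cohort, "PT1", fx$forest,
                                  c("TP53", "CDKN2A"))
  tp53 <- pl[pl$locus == "TP53", ]
  expect_equal(tp53$node, 2L)  # the {A,B} branch
  expect_equal(tp53$status, "placed")
  # VAF ~0.71 vs CF 0.8/0.7: homozygous in both carrying samples
  expect_equal(tp53$zygosity, "homozygous")
  # single-sample candidate goes to the pendant branch of its tip
  cdkn <- pl[pl$locus == "CDKN2A", ]
  expect_equal(cdkn$node, 5L)  # C's tip
})

test_that("mixed het/hom mutations become ancestral-het with tipward secondary events", {
  fx <- assign_fixture()
  co <- fx$cohort
  # make TP53 heterozygous-like in A (VAF ~0.4*CF) but homozygous in B
  co$snv$S_A_alt[8] <- 24L  # VAF 0.40 ~ het at CF 0.8
  co$snv$S_B_alt[8] <- 41L  # VAF 0.68 ~ hom at CF 0.7
  pl <- place_candidate_mutations(co, "PT1", fx$forest, "TP53")
  expect_equal(pl$zygosity, "heterozygous")
  sec <- as.integer(strsplit(pl$secondary_nodes, ",")[[1]])
  expect_equal(sec, 4L)  # B's tip, tipward of the {A,B} branch
  # structural invariant: secondary events strictly tipward of the primary
  anc <- beclone:::ancestor_ids(fx$forest$nodes, sec)
  expect_true(pl$node %in% anc)
})
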