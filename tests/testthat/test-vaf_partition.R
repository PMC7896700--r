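test_that("SNVs partition by detected-sample subset, conserving totals", {
  det <- matrix(c(
    TRUE, TRUE, FALSE,   # {A,B}
    TRUE, TRUE, TRUE,    # {A,B,C}
    TRUE, TRUE, FALSE,   # {A,B}
    TRUE, FALSE, FALSE,  # {A} private
    FALSE, FALSE, TRUE   # {C} private
  ), ncol = 3, byrow = TRUE, dimnames = list(1:5, c("A", "B", "C")))
  parts <- partition_snvs(det)
  expect_setequal(parts$key, c("A|B", "A|B|C", "A", "C"))
  expect_equal(parts$n_snvs[parts$key == "A|B"], 2L)
  expect_equal(sum(parts$n_snvs), 5L)  # conservation
  expect_true(all(parts$private == (parts$n_samples == 1L)))

  # all-private case
  det2 <- diag(3) == 1
  dimnames(det2) <- list(1:3, c("A", "B", "C"))
  parts2 <- partition_snvs(det2)
  expect_true(all(parts2$private))
})

test_that("LOH exclusion drops exactly the SNVs unreadable in an absent sample", {
  co <- toy_cohort()
  det <- detection_matrix(co, "PT1", 3)
  res <- apply_loh_exclusion(co, "PT1", det)
  # row 3 (chr2, absent in S_C which carries 2+0 there) is excluded;
  # row 1 (chr1, absent in S_C with 1+1) is retained; row 2 (present
  # everywhere) can never be excluded; row 4 (chr2 absent in B and C;
  # C has 2+0) is excluded
  expect_equal(unname(res$keep), c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(res$n_excluded, 2L)
})

test_that("thin biopsies are dropped at the under-100-SNV boundary", {
  parts <- data.frame(
    key = c("A|B", "A", "B", "C"),
    n_samples = c(2L, 1L, 1L, 1L),
    n_snvs = c(150L, 40L, 100L, 99L),
    private = c(FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  # A and B both reach 150 via the shared partition; C's best is 99
  expect_equal(drop_thin_biopsies(parts, c("A", "B", "C"), 100), "C")
  parts$n_snvs[4] <- 100L
  expect_equal(drop_thin_biopsies(parts, c("A", "B", "C"), 100), character(0))
})

test_that("kernel smoothing recovers peak structure", {
  set.seed(42)
  v1 <- pmin(1, pmax(0, rnorm(1000, 0.25, 0.03)))
  pk <- detect_peaks(v1)
  pw <- fit_peak_weights(v1, pk, 100)
  expect_equal(nrow(pw), 1L)
  expect_equal(pw$location, 0.25, tolerance = 0.02)

  # constant values: a single peak at that value
  expect_equal(as.numeric(detect_peaks(rep(0.4, 200))), 0.4)

  v2 <- c(rnorm(500, 0.15, 0.03), rnorm(500, 0.45, 0.03))
  pk2 <- detect_peaks(v2)
  pw2 <- fit_peak_weights(v2, pk2, 100)
  expect_equal(nrow(pw2), 2L)
  # independent mixture-model oracle for the two locations
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  mfit <- Mclust(v2, G = 2, verbose = FALSE)
  expect_equal(sort(pw2$location), sort(as.numeric(mfit$parameters$mean)),
               tolerance = 0.02)
})

test_that("mixture weights match hard-assignment counts and honor the 100-SNV rule", {
  set.seed(7)
  v <- c(rnorm(800, 0.25, 0.03), rnorm(300, 0.50, 0.03))
  pw <- fit_peak_weights(v, detect_peaks(v), 100)
  expect_equal(nrow(pw), 2L)
  # hard-assignment oracle: split at the midpoint
  expect_equal(pw$weight[1], sum(v < 0.375), tolerance = 80)
  expect_equal(pw$weight[2], sum(v >= 0.375), tolerance = 30)
  # pre-filter weights conserve the group size
  expect_equal(sum(attr(pw, "all_weights")$weight), length(v), tolerance = 1)

  v2 <- c(rnorm(950, 0.25, 0.03), rnorm(50, 0.50, 0.03))
  pw2 <- fit_peak_weights(v2, detect_peaks(v2), 100)
  expect_equal(nrow(pw2), 1L)  # minor peak below the 100-SNV floor
  expect_equal(pw2$location, 0.25, tolerance = 0.02)

  v3 <- rnorm(400, 0.3, 0.03)
  pw3 <- fit_peak_weights(v3, detect_peaks(v3), 100)
  expect_equal(nrow(pw3), 1L)
  expect_equal(pw3$weight, 400, tolerance = 1)
})
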