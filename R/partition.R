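#' Pipeline configuration
#'
#' Tunable thresholds of the deconvolution pipeline.  The 100-SNV floors
#' (`min_peak_snvs`, `min_group_snvs`, `thin_biopsy_min`,
#' `origin_share_threshold`) reflect the reliability cutoff used
#' throughout the analysis: partitions and peaks supported by fewer SNVs
#' are not treated as phylogenetic evidence.
#'
#' @param min_peak_snvs discard VAF peaks assigned fewer SNVs than this.
#' @param min_group_snvs minimum SNVs for a copy-number group to be
#'   deconvoluted at all.
#' @param bandwidth_scale kernel bandwidth = this times Silverman's rule
#'   (floored at 0.01 VAF).
#' @param merge_tol VAF peaks closer than this merge into the higher one.
#' @param detection_min_alt alt reads needed to call an SNV present in a
#'   sample.
#' @param cf_tol cell-fraction slack used for nesting/compatibility checks.
#' @param ratio_tol relative tolerance for peak-ratio tests (unbalanced
#'   copy number, factor-of-two genome doubling).
#' @param min_clone_cf smallest cell fraction reported as a tip.
#' @param thin_biopsy_min biopsies whose every partition (including
#'   private SNVs) has fewer SNVs than this are dropped.
#' @param origin_share_threshold lineage groups sharing fewer SNVs than
#'   this stay disjoint trees (independent origins).
#' @param max_reclassify dropout reclassification attempts before a
#'   patient is declared unresolvable.
#' @return A list of class `be_config`.
#' @export
be_config <- function(min_peak_snvs = 100, min_group_snvs = 100,
                      bandwidth_scale = 0.5, merge_tol = 0.03,
                      detection_min_alt = 3, cf_tol = 0.10, ratio_tol = 0.25,
                      min_clone_cf = 0.15, thin_biopsy_min = 100,
                      origin_share_threshold = 100, max_reclassify = 5) {
  structure(list(
    min_peak_snvs = min_peak_snvs, min_group_snvs = min_group_snvs,
    bandwidth_scale = bandwidth_scale, merge_tol = merge_tol,
    detection_min_alt = detection_min_alt, cf_tol = cf_tol,
    ratio_tol = ratio_tol, min_clone_cf = min_clone_cf,
    thin_biopsy_min = thin_biopsy_min,
    origin_share_threshold = origin_share_threshold,
    max_reclassify = max_reclassify
  ), class = "be_config")
}

#' Detection calls for one patient's SNVs
#'
#' @param cohort a [be_cohort()].
#' @param patient patient id.
#' @param min_alt alt reads needed to call an SNV present in a sample.
#' @return Logical matrix (SNV rows x samples); row names are the SNV
#'   row indices in the cohort table.
#' @export
detection_matrix <- function(cohort, patient, min_alt = 3) {
  rows <- patient_snvs(cohort, patient)
  samples <- patient_samples(cohort, patient)
  det <- vapply(samples, function(s) {
    a <- cohort$snv[[paste0(s, "_alt")]][rows]
    !is.na(a) & a >= min_alt
  }, logical(length(rows)))
  det <- matrix(det, nrow = length(rows),
                dimnames = list(NULL, samples))
  rownames(det) <- as.character(rows)
  det
}

#' Partition a patient's SNVs by the sample subset in which they occur
#'
#' Each SNV belongs to exactly one partition, keyed by the set of samples
#' in which it is detected.  Private (single-sample) partitions are kept
#' but flagged: they are not deconvoluted.
#'
#' @param detected logical matrix (SNVs x samples), e.g. from read counts
#'   at the detection threshold.
#' @return data.frame with one row per partition: `key` (sorted sample
#'   ids joined by `|`), `n_samples`, `n_snvs`, `private`, and a
#'   list-column `snv_rows` of member row indices (names of `detected`).
#' @export
partition_snvs <- function(detected) {
  stopifnot(ncol(detected) >= 1)
  samples <- colnames(detected)
  keys <- apply(detected, 1L, function(d) paste(sort(samples[d]), collapse = "|"))
  keep <- keys != ""  # SNVs detected nowhere carry no signal
  keys <- keys[keep]
  rows <- rownames(detected)[keep]
  if (is.null(rows)) rows <- as.character(which(keep))
  sp <- split(rows, keys)
  out <- data.frame(
    key = names(sp),
    n_samples = lengths(strsplit(names(sp), "|", fixed = TRUE)),
    n_snvs = lengths(sp),
    stringsAsFactors = FALSE
  )
  out$private <- out$n_samples == 1L
  out$snv_rows <- unname(sp)
  out[order(out$n_samples, -out$n_snvs, out$key), , drop = FALSE]
}

#' Exclude SNVs whose absence is unreadable due to haplotype loss
#'
#' An SNV is discarded when one or more samples *lacking* it carry a
#' copy-number call with minor copy number 0 at its position (deletion or
#' copy-neutral LOH): the ancestral presence or absence of the SNV in
#' that sample cannot be determined.
#'
#' @param cohort a [be_cohort()].
#' @param patient patient id.
#' @param detected detection matrix from [detection_matrix()].
#' @param on_missing_segment `"keep"` (default, with a warning) or
#'   `"drop"` for SNVs not covered by any CN segment in an absent sample.
#' @return list with `keep` (logical over SNV rows of `detected`) and
#'   `n_excluded`.
#' @export
apply_loh_exclusion <- function(cohort, patient, detected,
                                on_missing_segment = c("keep", "drop")) {
  on_missing_segment <- match.arg(on_missing_segment)
  rows <- as.integer(rownames(detected))
  chrom <- cohort$snv$chrom[rows]
  pos <- cohort$snv$pos[rows]
  samples <- colnames(detected)
  exclude <- rep(FALSE, length(rows))
  uncovered <- FALSE
  for (s in samples) {
    absent <- !detected[, s]
    if (!any(absent)) next
    cn <- cn_at(cohort$cn, s, chrom[absent], pos[absent])
    mn <- cn[, "minor"]
    if (any(is.na(mn))) {
      uncovered <- TRUE
      if (on_missing_segment == "drop") mn[is.na(mn)] <- 0
    }
    exclude[absent][!is.na(mn) & mn == 0] <- TRUE
  }
  if (uncovered && on_missing_segment == "keep") {
    warning("some SNV positions lack a covering CN segment in an absent sample; kept",
            call. = FALSE)
  }
  list(keep = !exclude, n_excluded = sum(exclude))
}

#' Drop biopsies with too little phylogenetic signal
#'
#' A biopsy is removed from phylogenetic analysis when every partition
#' containing it (including its private SNVs) has fewer than
#' `min_snvs` members; such biopsies may not even represent segment
#' tissue.
#'
#' @param partitions output of [partition_snvs()].
#' @param samples all samples of the patient.
#' @param min_snvs threshold (default 100).
#' @return character vector of dropped sample ids.
#' @export
drop_thin_biopsies <- function(partitions, samples, min_snvs = 100) {
  dropped <- character(0)
  for (s in samples) {
    containing <- vapply(strsplit(partitions$key, "|", fixed = TRUE),
                         function(k) s %in% k, logical(1))
    if (!any(containing) || max(partitions$n_snvs[containing]) < min_snvs) {
      dropped <- c(dropped, s)
    }
  }
  dropped
}

#' Locate VAF peaks by kernel smoothing
#'
#' Local maxima of a Gaussian-kernel density estimate on \[0, 1\];
#' maxima closer than `merge_tol` are merged into the higher one.  The
#' bandwidth is Silverman's rule scaled by `bandwidth_scale` with a floor
#' of 0.01 VAF, chosen to resolve peaks ~0.1 apart at around 100 SNVs.
#'
#' @param vafs numeric VAF values in \[0, 1\].
#' @param bandwidth_scale,merge_tol see [be_config()].
#' @param min_n below this many values an empty result is returned (the
#'   group is discarded upstream).
#' @return numeric vector of peak locations, increasing.
#' @export
detect_peaks <- function(vafs, bandwidth_scale = 0.5, merge_tol = 0.03,
                         min_n = 1) {
  vafs <- vafs[!is.na(vafs)]
  if (length(vafs) < min_n) return(numeric(0))
  if (length(unique(vafs)) == 1L) return(unique(vafs))
  bw <- max(0.01, bandwidth_scale * stats::bw.nrd0(vafs))
  d <- stats::density(vafs, bw = bw, from = 0, to = 1, n = 512)
  y <- d$y; x <- d$x
  is_max <- c(y[1] > y[2], diff(sign(diff(y))) == -2, y[512] > y[511])
  peaks_x <- x[is_max]; peaks_y <- y[is_max]
  # merge close maxima, keeping the higher
  repeat {
    if (length(peaks_x) < 2L) break
    gaps <- diff(peaks_x)
    j <- which.min(gaps)
    if (gaps[j] >= merge_tol) break
    drop <- if (peaks_y[j] >= peaks_y[j + 1]) j + 1L else j
    peaks_x <- peaks_x[-drop]; peaks_y <- peaks_y[-drop]
  }
  ord <- order(peaks_x)
  out <- peaks_x[ord]
  attr(out, "height") <- peaks_y[ord]
  out
}

# One-dimensional Gaussian mixture EM with means initialized at the
# candidate peaks and a variance floor of (0.01)^2 to avoid singular
# components.  Returns means, sds and mixing proportions.
gmm1d_em <- function(x, means, var_floor = 1e-4, max_iter = 100, tol = 1e-7,
                     sd_cap_fn = NULL) {
  k <- length(means)
  n <- length(x)
  clamp_sd <- function(sg, mu) {
    sg <- pmax(sqrt(var_floor), sg)
    if (!is.null(sd_cap_fn)) sg <- pmin(sg, pmax(sqrt(var_floor), sd_cap_fn(mu)))
    sg
  }
  if (k == 1L) {
    mu <- mean(x)
    return(list(mean = mu, sd = clamp_sd(stats::sd(x), mu),
                pi = 1, resp = matrix(1, n, 1)))
  }
  mu <- means
  sg <- clamp_sd(rep(stats::sd(x) / k, k), mu)
  pi_k <- rep(1 / k, k)
  ll_old <- -Inf
  resp <- matrix(1 / k, n, k)
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) pi_k[j] * stats::dnorm(x, mu[j], sg[j]),
                   numeric(n))
    tot <- rowSums(dens)
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    resp <- dens / tot
    nk <- colSums(resp)
    nk[nk < 1e-10] <- 1e-10
    pi_k <- nk / n
    mu <- colSums(resp * x) / nk
    sg <- clamp_sd(sqrt(colSums(resp * (outer(x, mu, "-"))^2) / nk), mu)
    ll <- sum(log(tot))
    if (!is.finite(ll)) return(NULL)
    if (abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  list(mean = mu, sd = sg, pi = pi_k, resp = resp)
}

# VAF standard deviation expected from read sampling alone at a given
# depth, with slack for depth heterogeneity.  Component spread beyond
# this is structural (several lineages, haplotype levels), not noise.
binomial_sd_cap <- function(depth, slack = 1.3) {
  force(depth); force(slack)
  function(mu) slack * sqrt(pmax(mu * (1 - mu), 0.005) / depth)
}

#' Estimate the number of SNVs under each VAF peak
#'
#' Fits Gaussian mixtures with means initialized at the candidate peak
#' locations (free variances floored at (0.01)^2); the weight of a peak
#' is the sample size times its mixing proportion.  When several
#' candidate peaks are offered, nested models using the 1..K most
#' prominent peaks are compared by BIC, so kernel-smoothing wiggles on a
#' genuinely unimodal histogram do not split it.  Peaks assigned fewer
#' than `min_peak_snvs` SNVs are discarded.  If the mixture fit
#' degenerates, weights fall back to hard assignment by nearest peak,
#' with a warning.
#'
#' @param vafs numeric VAF values.
#' @param peaks candidate peak locations from [detect_peaks()] (the
#'   `"height"` attribute, if present, orders candidates by prominence).
#' @param min_peak_snvs discard threshold (default 100).
#' @param depth optional mean read depth; when given, mixture component
#'   spread is capped at the binomial sampling level for that depth,
#'   which sharpens the distinction between one over-dispersed component
#'   and two genuine peaks.
#' @return data.frame with columns `location`, `weight` for retained
#'   peaks (possibly zero rows); attribute `"all_weights"` carries the
#'   pre-filter weights, which sum to `length(vafs)`.
#' @export
fit_peak_weights <- function(vafs, peaks, min_peak_snvs = 100, depth = NULL) {
  stopifnot(length(peaks) >= 1)
  n <- length(vafs)
  h <- attr(peaks, "height")
  prominence <- if (is.null(h)) rev(seq_along(peaks)) else h
  cap <- if (!is.null(depth)) binomial_sd_cap(depth) else NULL
  # fit on a deterministic subsample: mixture means/proportions stabilize
  # well below the full group size, and weights rescale to n
  x <- if (n > 800) sort(vafs)[round(seq(1, n, length.out = 800))] else vafs
  m <- length(x)
  fit <- NULL
  best_bic <- Inf
  for (k in seq_along(peaks)) {
    init <- sort(as.numeric(peaks)[order(-prominence)][seq_len(k)])
    fk <- gmm1d_em(x, init, sd_cap_fn = cap)
    if (is.null(fk)) next
    ll <- sum(log(pmax(.Machine$double.xmin, rowSums(
      vapply(seq_len(k), function(j) fk$pi[j] * stats::dnorm(x, fk$mean[j], fk$sd[j]),
             numeric(m))
    ))))
    bic <- -2 * ll + (3 * k - 1) * log(m)
    if (bic < best_bic) { best_bic <- bic; fit <- fk }
  }
  if (is.null(fit)) {
    warning("mixture fit failed to converge; falling back to hard assignment",
            call. = FALSE)
    assign <- apply(outer(as.numeric(vafs), as.numeric(peaks),
                          function(a, b) abs(a - b)), 1L, which.min)
    w <- tabulate(assign, length(peaks))
    loc <- as.numeric(peaks)
  } else {
    w <- n * fit$pi
    loc <- fit$mean
  }
  ord <- order(loc)
  loc <- loc[ord]; w <- w[ord]
  out <- data.frame(location = loc[w >= min_peak_snvs],
                    weight = w[w >= min_peak_snvs])
  attr(out, "all_weights") <- data.frame(location = loc, weight = w)
  out
}

# Subdivide a partition's SNVs by local copy-number signature across the
# partition's samples.  Returns a list of integer-vector groups (cohort
# SNV row indices) named by the signature key.
cn_group_split <- function(cohort, snv_rows, part_samples) {
  rows <- as.integer(snv_rows)
  chrom <- cohort$snv$chrom[rows]
  pos <- cohort$snv$pos[rows]
  sig <- rep("", length(rows))
  for (s in part_samples) {
    cn <- cn_at(cohort$cn, s, chrom, pos)
    sig <- paste(sig, paste0(cn[, "major"], "+", cn[, "minor"]), sep = ";")
  }
  split(rows, sig)
}
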