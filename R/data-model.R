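#' Cohort container
#'
#' A `be_cohort` bundles the three tabular inputs of the pipeline:
#' \describe{
#'   \item{snv}{wide table of somatic SNVs: `patient`, `chrom`, `pos`
#'     (1-based), `ref`, `alt`, `severity` (MODIFIER/LOW/MODERATE/HIGH),
#'     `locus` (gene symbol or NA), then one `<sample>_alt` /
#'     `<sample>_tot` read-count column pair per sample.  Count columns
#'     are NA for samples belonging to other patients.}
#'   \item{cn}{allele-specific copy-number segments: `sample`, `chrom`,
#'     `start`, `end` (1-based inclusive), `major`, `minor`.}
#'   \item{meta}{biopsy metadata: `patient`, `biopsy` (letter code),
#'     `sample`, `time_point` (TP1/TP2/TP3), `gej_cm` (distance above the
#'     gastroesophageal junction, cm), `outcome` (CO/NCO), `ploidy_class`
#'     (near_diploid/near_tetraploid), `gd_corroborated` (logical).}
#' }
#'
#' @param snv,cn,meta data.frames as described above.
#' @return An object of class `be_cohort`.
#' @seealso [read_cohort()], [validate_cohort()]
#' @export
be_cohort <- function(snv, cn, meta) {
  obj <- structure(list(snv = snv, cn = cn, meta = meta), class = "be_cohort")
  validate_cohort(obj)
  obj
}

#' @export
print.be_cohort <- function(x, ...) {
  cat(sprintf(
    "be_cohort: %d patients, %d samples, %d SNVs, %d CN segments\n",
    length(unique(x$meta$patient)), nrow(x$meta), nrow(x$snv), nrow(x$cn)
  ))
  invisible(x)
}

SEVERITY_LEVELS <- c("MODIFIER", "LOW", "MODERATE", "HIGH")

snv_required_cols <- c("patient", "chrom", "pos", "ref", "alt", "severity", "locus")
cn_required_cols <- c("sample", "chrom", "start", "end", "major", "minor")
meta_required_cols <- c(
  "patient", "biopsy", "sample", "time_point", "gej_cm", "outcome",
  "ploidy_class", "gd_corroborated"
)

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf(
      "schema error: %s is missing column(s) %s", what,
      paste(sQuote(missing), collapse = ", ")
    ), call. = FALSE)
  }
}

#' Sample ids carried by the count columns of an SNV table
#' @param snv an SNV table (see [be_cohort()]).
#' @return Character vector of sample ids.
#' @export
snv_samples <- function(snv) {
  alt_cols <- grep("_alt$", names(snv), value = TRUE)
  sub("_alt$", "", alt_cols)
}

#' Validate a cohort against the data-model invariants
#'
#' Checks the schema of all three tables and every stated invariant:
#' `alt_reads <= total_reads`, non-negative GEJ distances, TP3 restricted
#' to noncancer-outcome patients, unique biopsy codes within a patient,
#' `major >= minor`, non-overlapping segments per sample, and
#' `gd_corroborated` implying a near-tetraploid ploidy class.  Errors name
#' the offending column or record.
#'
#' @param cohort a [be_cohort()].
#' @return The cohort, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(cohort) {
  snv <- cohort$snv; cn <- cohort$cn; meta <- cohort$meta
  check_columns(snv, snv_required_cols, "SNV table")
  check_columns(cn, cn_required_cols, "CN table")
  check_columns(meta, meta_required_cols, "metadata table")

  samples <- snv_samples(snv)
  tot_missing <- setdiff(paste0(samples, "_tot"), names(snv))
  if (length(tot_missing)) {
    stop(sprintf("schema error: SNV table is missing column(s) %s",
                 paste(sQuote(tot_missing), collapse = ", ")), call. = FALSE)
  }

  unknown <- setdiff(samples, meta$sample)
  if (length(unknown)) {
    stop(sprintf("referential error: SNV table has count columns for sample(s) %s absent from metadata",
                 paste(sQuote(unknown), collapse = ", ")), call. = FALSE)
  }
  unknown_cn <- setdiff(unique(cn$sample), meta$sample)
  if (length(unknown_cn)) {
    stop(sprintf("referential error: CN table has sample(s) %s absent from metadata",
                 paste(sQuote(unknown_cn), collapse = ", ")), call. = FALSE)
  }

  dup <- duplicated(meta[, c("patient", "biopsy")])
  if (any(dup)) {
    stop(sprintf("referential error: duplicate biopsy_id within patient at metadata row(s) %s",
                 paste(which(dup), collapse = ", ")), call. = FALSE)
  }
  if (any(duplicated(meta$sample))) {
    stop("referential error: duplicate sample id in metadata", call. = FALSE)
  }
  if (any(meta$gej_cm < 0)) {
    stop("validation error: gej_cm must be non-negative", call. = FALSE)
  }
  if (!all(meta$time_point %in% c("TP1", "TP2", "TP3"))) {
    stop("validation error: time_point must be one of TP1, TP2, TP3", call. = FALSE)
  }
  if (any(meta$time_point == "TP3" & meta$outcome == "CO")) {
    stop("validation error: TP3 biopsies only occur in NCO patients", call. = FALSE)
  }
  if (!all(meta$ploidy_class %in% c("near_diploid", "near_tetraploid"))) {
    stop("validation error: ploidy_class must be near_diploid or near_tetraploid",
         call. = FALSE)
  }
  bad_gd <- meta$gd_corroborated & meta$ploidy_class != "near_tetraploid"
  if (any(bad_gd)) {
    stop(sprintf("validation error: gd_corroborated sample(s) %s not near_tetraploid",
                 paste(sQuote(meta$sample[bad_gd]), collapse = ", ")), call. = FALSE)
  }

  if (!all(snv$severity %in% SEVERITY_LEVELS)) {
    stop("validation error: severity must be one of MODIFIER, LOW, MODERATE, HIGH",
         call. = FALSE)
  }
  for (s in samples) {
    a <- snv[[paste0(s, "_alt")]]; t <- snv[[paste0(s, "_tot")]]
    both <- !is.na(a) & !is.na(t)
    if (any(a[both] < 0) || any(t[both] < 0)) {
      stop(sprintf("validation error: negative read count for sample %s", sQuote(s)),
           call. = FALSE)
    }
    bad <- which(both & a > t)
    if (length(bad)) {
      stop(sprintf("validation error: alt_reads > total_reads for sample %s at SNV row(s) %s",
                   sQuote(s), paste(bad, collapse = ", ")), call. = FALSE)
    }
  }

  if (nrow(cn)) {
    if (any(cn$start > cn$end)) {
      stop("validation error: CN segment with start > end", call. = FALSE)
    }
    if (any(cn$major < cn$minor)) {
      stop("validation error: CN segment with major < minor", call. = FALSE)
    }
    bychrom <- split(cn, list(cn$sample, cn$chrom), drop = TRUE)
    for (seg in bychrom) {
      seg <- seg[order(seg$start), , drop = FALSE]
      if (nrow(seg) > 1 && any(seg$start[-1] <= seg$end[-nrow(seg)])) {
        stop(sprintf("validation error: overlapping CN segments for sample %s chrom %s",
                     sQuote(seg$sample[1]), seg$chrom[1]), call. = FALSE)
      }
    }
  }
  invisible(cohort)
}

#' Read a cohort from the three tab-separated input files
#'
#' @param snv_path,cn_path,meta_path paths to `snvs.tsv`, `cn.tsv`,
#'   `meta.tsv` (see [be_cohort()] for the column dialect).
#' @return A validated [be_cohort()].
#' @export
read_cohort <- function(snv_path, cn_path, meta_path) {
  for (p in c(snv_path, cn_path, meta_path)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
  }
  snv <- utils::read.delim(snv_path, stringsAsFactors = FALSE, check.names = FALSE)
  cn <- utils::read.delim(cn_path, stringsAsFactors = FALSE)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  meta$gd_corroborated <- as.logical(meta$gd_corroborated)
  if ("locus" %in% names(snv)) snv$locus[snv$locus %in% c("", "NA")] <- NA
  be_cohort(snv, cn, meta)
}

#' Write a cohort back to the tab-separated dialect read by [read_cohort()]
#'
#' @param cohort a [be_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written (snvs.tsv, cn.tsv, meta.tsv).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("snvs.tsv", "cn.tsv", "meta.tsv"))
  utils::write.table(cohort$snv, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$cn, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$meta, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

# Per-patient convenience accessors -------------------------------------

patient_samples <- function(cohort, patient) {
  cohort$meta$sample[cohort$meta$patient == patient]
}

patient_snvs <- function(cohort, patient) {
  which(cohort$snv$patient == patient)
}

# Allele-specific copy number at positions, for one sample.  Returns a
# two-column matrix (major, minor); NA where no segment covers a position.
cn_at <- function(cn, sample, chrom, pos) {
  out <- matrix(NA_real_, length(pos), 2, dimnames = list(NULL, c("major", "minor")))
  seg <- cn[cn$sample == sample, , drop = FALSE]
  if (!nrow(seg)) return(out)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    s <- seg[seg$chrom == ch, , drop = FALSE]
    if (!nrow(s)) next
    s <- s[order(s$start), , drop = FALSE]
    j <- findInterval(pos[idx], s$start)
    hit <- j >= 1 & pos[idx] <= s$end[pmax(j, 1)]
    out[idx[hit], "major"] <- s$major[j[hit]]
    out[idx[hit], "minor"] <- s$minor[j[hit]]
  }
  out
}
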