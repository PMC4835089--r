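# Variant-type classification and the two-level variant filter:
# a variant-level average-depth criterion and a sample-level minimum
# genotype quality over the whole-blood reference samples (minGQ_WB).

VARIANT_CLASSES <- c("SNP", "INSERTION", "DELETION",
                     "MULTIALLELIC_COMPLEX", "MULTIALLELIC_MIXED")
REPORTING_GROUPS <- c("SNP", "insertion", "deletion", "multiallelic")

#' Classify variant records by allele structure
#'
#' Each alternate allele is typed against the reference: SNP (both length
#' 1), insertion (ALT longer), deletion (ALT shorter), or complex
#' (equal length > 1, e.g. an MNP). A single-ALT record takes its allele's
#' type; a multi-ALT record where every ALT is a SNP stays `SNP`; a
#' multi-ALT record whose ALTs are all insertions and/or deletions is
#' `MULTIALLELIC_COMPLEX`; any mixture of SNP and indel alleles, or any
#' complex allele, yields `MULTIALLELIC_MIXED`. A single-ALT complex
#' substitution has no bucket of its own in the reporting taxonomy; it is
#' classed `MULTIALLELIC_MIXED` (hence reported under "multiallelic") and
#' counted in the `n_single_alt_complex` attribute rather than silently
#' absorbed.
#'
#' @param cs a `callset`
#' @return character vector of classes (one of
#'   `SNP`, `INSERTION`, `DELETION`, `MULTIALLELIC_COMPLEX`,
#'   `MULTIALLELIC_MIXED`), with attribute `n_single_alt_complex`
#' @export
classify_variants <- function(cs) {
  alts <- alt_list(cs)
  ref_len <- nchar(cs$variants$ref)
  n_single_complex <- 0L
  out <- vapply(seq_along(alts), function(i) {
    al <- nchar(alts[[i]])
    rl <- ref_len[i]
    type <- ifelse(al == rl & rl == 1L, "SNP",
            ifelse(al > rl, "INSERTION",
            ifelse(al < rl, "DELETION", "COMPLEX")))
    if (length(type) == 1L) {
      if (type == "COMPLEX") {
        n_single_complex <<- n_single_complex + 1L
        return("MULTIALLELIC_MIXED")
      }
      return(type)
    }
    if (all(type == "SNP")) return("SNP")
    if (all(type %in% c("INSERTION", "DELETION")))
      return("MULTIALLELIC_COMPLEX")
    "MULTIALLELIC_MIXED"
  }, "")
  structure(out, n_single_alt_complex = n_single_complex)
}

#' Map variant classes to reporting groups
#'
#' `MULTIALLELIC_COMPLEX` and `MULTIALLELIC_MIXED` are both reported as
#' `multiallelic`; the other classes keep their own name.
#'
#' @param class character vector of variant classes
#' @return character vector over
#'   `c("SNP", "insertion", "deletion", "multiallelic")`
#' @export
reporting_group <- function(class) {
  out <- c(SNP = "SNP", INSERTION = "insertion", DELETION = "deletion",
           MULTIALLELIC_COMPLEX = "multiallelic",
           MULTIALLELIC_MIXED = "multiallelic")[as.character(class)]
  unname(out)
}

#' Filter thresholds
#'
#' Both criteria are strict inequalities: a record is kept when the average
#' sample depth exceeds `min_avg_depth` AND the minimum genotype quality
#' over the reference-standard samples exceeds `min_gq_wb`. The defaults
#' (>20, >30) are the study's settings.
#'
#' @param min_avg_depth average-sample-depth threshold (default 20)
#' @param min_gq_wb reference minimum-GQ threshold (default 30)
#' @return list of thresholds
#' @export
filter_thresholds <- function(min_avg_depth = 20, min_gq_wb = 30) {
  stopifnot(min_avg_depth >= 0, min_gq_wb >= 0)
  list(min_avg_depth = min_avg_depth, min_gq_wb = min_gq_wb)
}

#' Average sample depth per record
#'
#' The multi-sample combined depth divided by the number of samples included
#' in the calling, i.e. the full roster size — not the count of non-missing
#' calls at the site.
#'
#' @param cs a `callset`
#' @param n_samples denominator; defaults to the roster size
#' @return numeric vector
#' @export
average_sample_depth <- function(cs, n_samples = nrow(cs$roster)) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  cs$variants$site_dp / n_samples
}

#' Minimum genotype quality across reference-standard samples
#'
#' Per record, the minimum GQ over roster samples flagged
#' `is_reference_standard`. A reference call that is missing, or lacks a
#' GQ value, contributes 0, so any missing reference data forces the
#' statistic to 0.
#'
#' @param cs a `callset`
#' @return integer vector, one value per record
#' @export
min_gq_wb <- function(cs) {
  ref <- which(cs$roster$is_reference_standard)
  if (!length(ref)) stop("no reference-standard samples on the roster")
  gq <- cs$gq[, ref, drop = FALSE]
  gq[is.na(gq)] <- 0L
  gq[is.na(cs$gt_a1[, ref, drop = FALSE])] <- 0L
  if (nrow(gq) == 0) return(integer())
  as.integer(apply(gq, 1, min))
}

#' Apply the two-level variant filter
#'
#' Keeps exactly the records with average sample depth strictly above
#' `thresholds$min_avg_depth` and reference minimum GQ strictly above
#' `thresholds$min_gq_wb`. Record contents are unmodified; the operation is
#' a pure subset (idempotent, order-preserving, monotone in thresholds).
#'
#' @param cs a `callset`
#' @param thresholds see [filter_thresholds()]
#' @return list with `callset` (the kept records) and `decisions`, a
#'   per-record table of both statistics and the verdict
#' @export
apply_filters <- function(cs, thresholds = filter_thresholds()) {
  avg_dp <- average_sample_depth(cs)
  mgq <- min_gq_wb(cs)
  keep <- avg_dp > thresholds$min_avg_depth & mgq > thresholds$min_gq_wb
  decisions <- data.frame(
    chrom = cs$variants$chrom, pos = cs$variants$pos,
    avg_depth = avg_dp, min_gq_wb = mgq,
    pass_depth = avg_dp > thresholds$min_avg_depth,
    pass_gq = mgq > thresholds$min_gq_wb,
    kept = keep)
  list(callset = subset_callset(cs, keep,
                                paste0(cs$provenance, "|filtered")),
       decisions = decisions)
}

#' Variant counts and percentages per reporting group
#'
#' The layout of the study's variant-type summary: one row per reporting
#' group with its count and share of all records.
#'
#' @param cs a `callset`
#' @return data.frame with columns `group`, `n`, `pct` (percent of all
#'   records; `NA` for an empty call set)
#' @export
variant_type_summary <- function(cs) {
  grp <- reporting_group(classify_variants(cs))
  n <- vapply(REPORTING_GROUPS, function(g) sum(grp == g), 0L)
  total <- sum(n)
  data.frame(group = REPORTING_GROUPS, n = unname(n),
             pct = if (total == 0) NA_real_ else unname(100 * n / total),
             row.names = NULL)
}
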