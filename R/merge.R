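# Priority merge of two callers' call sets. HaplotypeCaller (HC) PASS calls
# win at any shared site; UnifiedGenotyper (UG) PASS calls are kept where HC
# has no PASS record (HC absent or VQSR-filtered).

#' Merge key of a variant record
#'
#' Two records "overlap" when they share the same (chrom, pos) anchor.
#' Anchor-position semantics (rather than REF-interval overlap) reflects
#' multi-sample calling on shared alignments, where allele representations
#' at a site share an anchor.
#'
#' @param variants variant table (or one-row subset) of a `callset`
#' @return character vector of keys
#' @export
merge_key <- function(variants) {
  paste(variants$chrom, variants$pos, sep = ":")
}

#' Merge two callers' outputs by PASS priority
#'
#' Keeps, in order of priority: (i) every PASS record of `hc`; (ii) every
#' PASS record of `ug` at a key where the `hc` record is VQSR-filtered;
#' (iii) every PASS record unique to either caller. Non-PASS records that
#' are not rescued are dropped. Priority is record-level: where both callers
#' PASS the same key, the HC record is kept wholesale, whatever its alleles.
#'
#' @param hc `callset` from the priority caller (HaplotypeCaller)
#' @param ug `callset` from the secondary caller (UnifiedGenotyper)
#' @return list with `callset` (source `"MERGED"`, per-record `origin`
#'   `"HC"`/`"UG"`) and `report`, a one-row data.frame of category counts:
#'   `n_hc_pass`, `n_ug_pass`, `n_overlap_hc_wins`, `n_ug_rescued`,
#'   `n_unique_hc`, `n_unique_ug`, `n_merged`.
#' @export
merge_caller_outputs <- function(hc, ug) {
  if (!identical(hc$roster$sample_id, ug$roster$sample_id))
    stop("roster mismatch between caller outputs")
  hk <- merge_key(hc$variants)
  uk <- merge_key(ug$variants)
  if (anyDuplicated(hk))
    stop("duplicate merge-key within HC input: ", hk[duplicated(hk)][1])
  if (anyDuplicated(uk))
    stop("duplicate merge-key within UG input: ", uk[duplicated(uk)][1])

  hc_pass <- hc$variants$filter == "PASS"
  ug_pass <- ug$variants$filter == "PASS"
  hc_pass_keys <- hk[hc_pass]

  # UG PASS records kept wherever no PASS HC record claims the key
  ug_keep <- ug_pass & !(uk %in% hc_pass_keys)

  hc_sub <- subset_callset(hc, hc_pass)
  ug_sub <- subset_callset(ug, ug_keep)
  hc_sub$variants$filter <- rep("PASS", nrow(hc_sub$variants))
  ug_sub$variants$filter <- rep("PASS", nrow(ug_sub$variants))
  hc_sub$variants$origin <- rep("HC", nrow(hc_sub$variants))
  ug_sub$variants$origin <- rep("UG", nrow(ug_sub$variants))

  merged <- new_callset(
    rbind(hc_sub$variants, ug_sub$variants),
    rbind(hc_sub$gt_a1, ug_sub$gt_a1),
    rbind(hc_sub$gt_a2, ug_sub$gt_a2),
    rbind(hc_sub$gq, ug_sub$gq),
    rbind(hc_sub$dp, ug_sub$dp),
    hc$roster, "MERGED",
    paste0("merge(", hc$provenance, "+", ug$provenance, ")"))

  ug_rescued <- ug_pass & (uk %in% hk[!hc_pass])
  report <- data.frame(
    n_hc_pass = sum(hc_pass),
    n_ug_pass = sum(ug_pass),
    n_overlap_hc_wins = sum(hc_pass & hk %in% uk[ug_pass]),
    n_ug_rescued = sum(ug_rescued),
    n_unique_hc = sum(hc_pass & !(hk %in% uk)),
    n_unique_ug = sum(ug_pass & !(uk %in% hk)),
    n_merged = n_variants(merged))
  stopifnot(report$n_merged ==
              report$n_hc_pass + report$n_ug_rescued + report$n_unique_ug)
  list(callset = merged, report = report)
}
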