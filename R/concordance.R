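# Pairwise genotype concordance in five categories, per-variant-type rates,
# replicate averaging, and the per-pilot concordance report.

CONCORDANCE_CATEGORIES <- c("CONCORDANT", "DISCORDANT_HET_HOMO",
                            "DISCORDANT_HOMO_HOMO", "DISCORDANT_OTHER",
                            "MISSING")

#' Classify pairs of genotypes into the five similarity categories
#'
#' Vectorised over sites. The categories partition every compared pair:
#' \describe{
#'   \item{CONCORDANT}{identical unordered genotypes, including both calls
#'     missing;}
#'   \item{DISCORDANT_HET_HOMO}{one call homozygous (reference or first
#'     alternative allele), the other heterozygous 0/1;}
#'   \item{DISCORDANT_HOMO_HOMO}{one homozygous reference, the other
#'     homozygous for the first alternative allele;}
#'   \item{DISCORDANT_OTHER}{differing genotypes involving any alternative
#'     allele other than the first;}
#'   \item{MISSING}{a no-call in exactly one of the two samples.}
#' }
#' Comparison is order-insensitive (0/1 is 1/0) and symmetric in the two
#' samples. Identical genotypes carrying higher alternative alleles (e.g.
#' 1/2 vs 1/2) are CONCORDANT: the identity rule takes precedence and
#' DISCORDANT_OTHER applies only to differing pairs.
#'
#' @param a1,a2 integer allele indices for sample A (`NA` = missing)
#' @param b1,b2 integer allele indices for sample B
#' @return character vector of categories
#' @export
classify_genotype_pairs <- function(a1, a2, b1, b2) {
  stopifnot(length(a1) == length(a2), length(b1) == length(b2),
            length(a1) == length(b1))
  miss_a <- is.na(a1)
  miss_b <- is.na(b1)
  amin <- pmin(a1, a2); amax <- pmax(a1, a2)
  bmin <- pmin(b1, b2); bmax <- pmax(b1, b2)
  equal <- amin == bmin & amax == bmax

  out <- rep(NA_character_, length(a1))
  out[miss_a & miss_b] <- "CONCORDANT"
  out[xor(miss_a, miss_b)] <- "MISSING"
  both <- !miss_a & !miss_b
  out[both & equal] <- "CONCORDANT"
  differ <- both & !equal
  other <- differ & (amax >= 2L | bmax >= 2L)
  out[other] <- "DISCORDANT_OTHER"
  rest <- differ & !other                       # alleles within {0, 1}
  hom_a <- amin == amax
  hom_b <- bmin == bmax
  out[rest & hom_a & hom_b] <- "DISCORDANT_HOMO_HOMO"
  out[rest & xor(hom_a, hom_b)] <- "DISCORDANT_HET_HOMO"
  out
}

#' Classify one genotype pair
#'
#' Scalar convenience wrapper around [classify_genotype_pairs()].
#'
#' @param a,b length-2 integer vectors of allele indices, or `NULL`/`NA`
#'   for a missing call
#' @return one of the five category labels
#' @export
classify_genotype_pair <- function(a, b) {
  norm <- function(g) {
    if (is.null(g) || length(g) == 0 || anyNA(g)) c(NA_integer_, NA_integer_)
    else as.integer(g)
  }
  a <- norm(a); b <- norm(b)
  classify_genotype_pairs(a[1], a[2], b[1], b[2])
}

#' Pairwise concordance table for one sample pair
#'
#' Every record contributes exactly one category count within its reporting
#' group.
#'
#' @param cs a `callset`
#' @param a,b sample identifiers on the roster
#' @param filter_state `"RAW"` or `"FILTERED"` (carried into the table)
#' @param groups optional precomputed reporting groups
#'   (`reporting_group(classify_variants(cs))`)
#' @return object of class `concordance_table`: sample ids, a groups x
#'   categories count matrix, per-group site totals and the filter state
#' @export
pairwise_concordance <- function(cs, a, b, filter_state = "RAW",
                                 groups = NULL) {
  ia <- match(a, sample_ids(cs))
  ib <- match(b, sample_ids(cs))
  if (is.na(ia)) stop("unknown sample id: ", a)
  if (is.na(ib)) stop("unknown sample id: ", b)
  if (is.null(groups)) groups <- reporting_group(classify_variants(cs))
  cat <- classify_genotype_pairs(cs$gt_a1[, ia], cs$gt_a2[, ia],
                                 cs$gt_a1[, ib], cs$gt_a2[, ib])
  counts <- table(factor(groups, REPORTING_GROUPS),
                  factor(cat, CONCORDANCE_CATEGORIES))
  counts <- matrix(as.integer(counts), nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
  structure(list(sample_a = a, sample_b = b, counts = counts,
                 n_sites = rowSums(counts), filter_state = filter_state),
            class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("<concordance_table> ", x$sample_a, " vs ", x$sample_b,
      " (", x$filter_state, ")\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Concordance rate for a reporting group
#'
#' 100 x concordant / total sites of the group. Both-missing pairs count as
#' concordant and one-sided no-calls sit in the denominator, so the five
#' category counts form a partition and the rate's complement is the sum of
#' the four non-concordant fractions. `NA` (not 0) when the group has no
#' sites.
#'
#' @param t a `concordance_table`
#' @param group one of `"SNP"`, `"insertion"`, `"deletion"`,
#'   `"multiallelic"`
#' @return percentage, or `NA`
#' @export
concordance_rate <- function(t, group) {
  n <- t$n_sites[[group]]
  if (is.na(n) || n == 0) return(NA_real_)
  100 * t$counts[group, "CONCORDANT"] / n
}

# per-group stats matrix: rate plus the five category fractions
table_stats <- function(t) {
  frac <- t$counts / ifelse(t$n_sites == 0, NA, t$n_sites)
  cbind(rate = 100 * frac[, "CONCORDANT"], frac, n_sites = t$n_sites)
}

#' Average concordance rates over replicate comparisons
#'
#' Arithmetic mean of the per-table rates for each reporting group — a mean
#' of rates, not of pooled counts, matching how triplicate comparisons are
#' combined before reporting. Groups empty in some tables are averaged over
#' the tables where they occur.
#'
#' @param tables list of `concordance_table`s sharing one filter state
#' @return data.frame with columns `group` and `rate`
#' @export
average_replicate_rates <- function(tables) {
  if (!length(tables)) stop("no tables to average")
  states <- unique(vapply(tables, function(t) t$filter_state, ""))
  if (length(states) != 1) stop("mixed filter_state in replicate tables")
  rates <- vapply(tables, function(t)
    vapply(REPORTING_GROUPS, function(g) concordance_rate(t, g), 0.0),
    numeric(length(REPORTING_GROUPS)))
  rates <- matrix(rates, nrow = length(REPORTING_GROUPS))
  out <- apply(rates, 1, function(r)
    if (all(is.na(r))) NA_real_ else mean(r, na.rm = TRUE))
  data.frame(group = REPORTING_GROUPS, rate = out, row.names = NULL)
}

#' Per-pilot concordance report
#'
#' For each sample-type pairing and reporting group, the mean concordance
#' rate over subjects, before (RAW) and after (FILTERED) filtering. Where a
#' subject contributes several comparisons for a pairing (replicated sample
#' types), each replicate is compared first and the per-subject value is the
#' average of those comparisons. All five category fractions are reported
#' alongside the rate so alternative denominators can be recomputed.
#'
#' @param raw unfiltered (merged) `callset`
#' @param filtered filtered `callset` (same roster)
#' @param manifest roster data.frame; pairing is within `subject_id`
#' @param pairing_plan data.frame with columns `type_a`, `type_b` of sample
#'   types to compare
#' @return data.frame: `type_a`, `type_b`, `filter_state`, `group`,
#'   `rate`, the five `frac_*` columns, `mean_n_sites`, `n_subjects`
#' @export
pilot_concordance_report <- function(raw, filtered, manifest, pairing_plan) {
  stopifnot(all(c("type_a", "type_b") %in% names(pairing_plan)))
  out <- list()
  for (state in c("RAW", "FILTERED")) {
    cs <- if (state == "RAW") raw else filtered
    grp <- reporting_group(classify_variants(cs))
    for (k in seq_len(nrow(pairing_plan))) {
      ta <- pairing_plan$type_a[k]
      tb <- pairing_plan$type_b[k]
      for (tt in c(ta, tb)) {
        if (!tt %in% manifest$sample_type)
          stop("pairing references sample type absent from manifest: ", tt)
      }
      subjects <- intersect(manifest$subject_id[manifest$sample_type == ta],
                            manifest$subject_id[manifest$sample_type == tb])
      subj_stats <- lapply(subjects, function(s) {
        sa <- manifest$sample_id[manifest$subject_id == s &
                                   manifest$sample_type == ta]
        sb <- manifest$sample_id[manifest$subject_id == s &
                                   manifest$sample_type == tb]
        combos <- expand.grid(a = sa, b = sb, stringsAsFactors = FALSE)
        mats <- lapply(seq_len(nrow(combos)), function(i)
          table_stats(pairwise_concordance(cs, combos$a[i], combos$b[i],
                                           state, grp)))
        Reduce(`+`, mats) / length(mats)      # replicate averaging
      })
      mean_stats <- apply(
        array(unlist(subj_stats),
              dim = c(length(REPORTING_GROUPS), 7, length(subjects))),
        c(1, 2), function(v)
          if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
      dimnames(mean_stats) <- list(REPORTING_GROUPS,
                                   colnames(subj_stats[[1]]))
      out[[length(out) + 1L]] <- data.frame(
        type_a = ta, type_b = tb, filter_state = state,
        group = REPORTING_GROUPS,
        rate = mean_stats[, "rate"],
        frac_concordant = mean_stats[, "CONCORDANT"],
        frac_het_homo = mean_stats[, "DISCORDANT_HET_HOMO"],
        frac_homo_homo = mean_stats[, "DISCORDANT_HOMO_HOMO"],
        frac_other = mean_stats[, "DISCORDANT_OTHER"],
        frac_missing = mean_stats[, "MISSING"],
        mean_n_sites = mean_stats[, "n_sites"],
        n_subjects = length(subjects), row.names = NULL)
    }
  }
  do.call(rbind, out)
}
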