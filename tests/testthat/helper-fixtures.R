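# Fixture builders and an independent brute-force oracle for the five
# concordance categories. The oracle applies the category definitions
# literally on scalar genotypes and never calls the vectorised
# implementation.

test_roster <- function(n_subjects = 1,
                        sample_types = c(WB_ref = 1, DBS_2x3.2 = 1),
                        pilot = 1,
                        reference_types = "WB_ref") {
  rows <- list()
  for (s in seq_len(n_subjects)) {
    for (tt in names(sample_types)) {
      for (r in seq_len(sample_types[[tt]])) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("S%02d_%s_r%d", s, tt, r),
          subject_id = sprintf("SUBJ%02d", s),
          sample_type = tt, replicate = r, pilot = pilot,
          is_reference_standard = tt %in% reference_types,
          stringsAsFactors = FALSE)
      }
    }
  }
  validate_manifest(do.call(rbind, rows))
}

# sites: data.frame(chrom, pos, ref, alt[, filter, site_dp])
# gt: character matrix of GT strings ("0/1", "./."), one column per sample
test_callset <- function(sites, gt, roster, gq = NULL, dp = NULL,
                         source = "HC") {
  n <- nrow(sites)
  s <- nrow(roster)
  if (is.null(sites$filter)) sites$filter <- "PASS"
  if (is.null(sites$site_dp)) sites$site_dp <- 100L
  gt <- matrix(gt, n, s)
  g <- parse_gt(as.vector(gt))
  if (is.null(gq)) gq <- matrix(99L, n, s)
  if (is.null(dp)) dp <- matrix(30L, n, s)
  new_callset(sites, matrix(g$a1, n, s), matrix(g$a2, n, s),
              gq, dp, roster, source)
}

# literal statement of the five similarity categories; a genotype is an
# unordered pair of allele indices, NULL = no call
oracle_category <- function(a, b) {
  no_call_a <- is.null(a) || anyNA(a)
  no_call_b <- is.null(b) || anyNA(b)
  if (no_call_a && no_call_b) return("CONCORDANT")
  if (no_call_a || no_call_b) return("MISSING")
  if (identical(sort(a), sort(b))) return("CONCORDANT")
  if (any(c(a, b) >= 2)) return("DISCORDANT_OTHER")
  is_hom <- function(g) g[1] == g[2]
  if (is_hom(a) && is_hom(b)) return("DISCORDANT_HOMO_HOMO")
  "DISCORDANT_HET_HOMO"
}

# all diploid genotypes with allele indices <= max_allele, plus no-call
all_genotypes <- function(max_allele = 3) {
  gts <- list(NULL)
  for (i in 0:max_allele) for (j in i:max_allele)
    gts[[length(gts) + 1L]] <- c(i, j)
  gts
}
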