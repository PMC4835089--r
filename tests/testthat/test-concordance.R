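test_that("genotype pairs fall into the documented categories", {
  expect_equal(classify_genotype_pair(c(0, 1), c(1, 0)), "CONCORDANT")
  expect_equal(classify_genotype_pair(NULL, NULL), "CONCORDANT")
  expect_equal(classify_genotype_pair(c(1, 2), c(1, 2)), "CONCORDANT")
  expect_equal(classify_genotype_pair(c(0, 0), c(0, 1)),
               "DISCORDANT_HET_HOMO")
  expect_equal(classify_genotype_pair(c(1, 1), c(0, 1)),
               "DISCORDANT_HET_HOMO")
  expect_equal(classify_genotype_pair(c(0, 0), c(1, 1)),
               "DISCORDANT_HOMO_HOMO")
  expect_equal(classify_genotype_pair(c(0, 1), c(1, 2)), "DISCORDANT_OTHER")
  expect_equal(classify_genotype_pair(c(2, 2), c(0, 0)), "DISCORDANT_OTHER")
  expect_equal(classify_genotype_pair(c(0, 1), NULL), "MISSING")
})

test_that("pair classification matches the brute-force oracle everywhere", {
  gts <- all_genotypes(3)
  for (a in gts) for (b in gts) {
    expect_equal(classify_genotype_pair(a, b), oracle_category(a, b),
                 label = paste(deparse(a), "vs", deparse(b)))
  }
})

test_that("pair classification is symmetric for every genotype combination", {
  gts <- all_genotypes(3)
  for (a in gts) for (b in gts) {
    expect_equal(classify_genotype_pair(a, b), classify_genotype_pair(b, a))
  }
})

conc_fixture <- function() {
  roster <- test_roster(sample_types = c(WB_ref = 1, DBS_2x3.2 = 1,
                                         WB_ref_replica = 1))
  sites <- data.frame(
    chrom = "chr1", pos = seq(10L, by = 10L, length.out = 6),
    ref = c("A", "A", "A", "A", "AT", "A"),
    alt = c("G", "G", "G,T", "G", "A", "AT"),
    filter = "PASS", site_dp = 100L, stringsAsFactors = FALSE)
  gt <- rbind(
    c("0/1", "1/0", "0/1"),   # SNP concordant (order-insensitive)
    c("0/0", "1/1", "0/0"),   # SNP homo/homo
    c("0/1", "1/2", "0/1"),   # SNP (multi-alt) other
    c("0/1", "./.", "0/1"),   # SNP missing
    c("1/1", "0/1", "1/1"),   # deletion het/homo
    c("./.", "./.", "./."))   # insertion both-missing -> concordant
  test_callset(sites, gt, roster)
}

test_that("pairwise tables count every record once per reporting group", {
  cs <- conc_fixture()
  ids <- sample_ids(cs)
  t <- pairwise_concordance(cs, ids[1], ids[2])
  expect_equal(sum(t$counts), n_variants(cs))
  expect_equal(unname(rowSums(t$counts)), unname(t$n_sites))
  expect_equal(t$counts["SNP", "CONCORDANT"], 1L)
  expect_equal(t$counts["SNP", "DISCORDANT_HOMO_HOMO"], 1L)
  expect_equal(t$counts["SNP", "DISCORDANT_OTHER"], 1L)
  expect_equal(t$counts["SNP", "MISSING"], 1L)
  expect_equal(t$counts["deletion", "DISCORDANT_HET_HOMO"], 1L)
  expect_equal(t$counts["insertion", "CONCORDANT"], 1L)
  expect_error(pairwise_concordance(cs, "nope", ids[1]), "unknown sample")
})

test_that("self-comparison is fully concordant and pair order is immaterial", {
  cs <- conc_fixture()
  ids <- sample_ids(cs)
  self <- pairwise_concordance(cs, ids[1], ids[1])
  expect_equal(sum(self$counts[, "CONCORDANT"]), n_variants(cs))
  ab <- pairwise_concordance(cs, ids[1], ids[2])
  ba <- pairwise_concordance(cs, ids[2], ids[1])
  expect_equal(ab$counts, ba$counts)
})

test_that("concordance rate is concordant over all sites, NA when empty", {
  cs <- conc_fixture()
  ids <- sample_ids(cs)
  t <- pairwise_concordance(cs, ids[1], ids[2])
  expect_equal(concordance_rate(t, "SNP"), 100 * 1 / 4)
  expect_equal(concordance_rate(t, "insertion"), 100)  # both-missing site
  expect_true(is.na(concordance_rate(t, "multiallelic")))
  t13 <- pairwise_concordance(cs, ids[1], ids[3])
  expect_equal(concordance_rate(t13, "SNP"), 100)
})

test_that("replicate averaging is a mean of rates and validates its input", {
  cs <- conc_fixture()
  ids <- sample_ids(cs)
  t <- pairwise_concordance(cs, ids[1], ids[3])
  avg <- average_replicate_rates(list(t, t, t))
  expect_equal(avg$rate[avg$group == "SNP"], 100)

  t2 <- pairwise_concordance(cs, ids[1], ids[2])
  mixed <- average_replicate_rates(list(t, t2))
  expect_equal(mixed$rate[mixed$group == "SNP"], mean(c(100, 25)))

  single <- average_replicate_rates(list(t2))
  expect_equal(single$rate[single$group == "SNP"], 25)

  tf <- pairwise_concordance(cs, ids[1], ids[2], filter_state = "FILTERED")
  expect_error(average_replicate_rates(list(t, tf)), "mixed filter_state")
  expect_error(average_replicate_rates(list()), "no tables")
})

test_that("the pilot report covers each pairing, group and filter state", {
  cfg <- sim_config(pilot = 2, n_sites = 500, seed = 11, n_subjects = 3)
  sim <- simulate_cohort(cfg)
  merged <- merge_caller_outputs(sim$hc, sim$ug)$callset
  filtered <- apply_filters(merged)$callset
  rep <- pilot_concordance_report(merged, filtered, sim$manifest,
                                  default_pairing_plan(2))
  expect_equal(nrow(rep), 2 * 4 * 2)  # pairings x groups x filter states
  expect_setequal(unique(rep$type_b), c("WB_ref", "WB_ref_replica"))
  expect_true(all(rep$n_subjects == 3))
  got <- rep$frac_concordant + rep$frac_het_homo + rep$frac_homo_homo +
    rep$frac_other + rep$frac_missing
  expect_equal(got[!is.na(got)], rep(1, sum(!is.na(got))))

  bad_plan <- data.frame(type_a = "DBS_2x1.6", type_b = "WB_ref")
  expect_error(
    pilot_concordance_report(merged, filtered, sim$manifest, bad_plan),
    "absent from manifest")
})

test_that("a one-subject cohort's per-subject rate equals the cohort mean", {
  cfg <- sim_config(pilot = 1, n_sites = 300, seed = 3, n_subjects = 1)
  sim <- simulate_cohort(cfg)
  merged <- merge_caller_outputs(sim$hc, sim$ug)$callset
  filtered <- apply_filters(merged)$callset
  rep <- pilot_concordance_report(merged, filtered, sim$manifest,
                                  default_pairing_plan(1))
  grp <- reporting_group(classify_variants(merged))
  t <- pairwise_concordance(merged, sim$manifest$sample_id[1],
                            sim$manifest$sample_id[2], "RAW", grp)
  expect_equal(rep$rate[rep$group == "SNP" & rep$filter_state == "RAW"],
               concordance_rate(t, "SNP"))
})
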