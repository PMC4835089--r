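test_that("pilot designs reproduce the study layouts", {
  m1 <- build_manifest(sim_config(pilot = 1, n_sites = 10))
  expect_equal(nrow(m1), 7 * 2)
  m3 <- build_manifest(sim_config(pilot = 3, n_sites = 10))
  expect_equal(nrow(m3), 7 * (1 + 3 + 1 + 1))      # 42 samples
  expect_equal(sum(m3$sample_type == "DBS_2x1.6"), 21L)
  expect_equal(sort(unique(m3$replicate[m3$sample_type == "DBS_2x1.6"])),
               1:3)
  expect_true(all(m3$is_reference_standard == (m3$sample_type == "WB_ref")))
})

test_that("invalid simulation configs are rejected with the field names", {
  expect_error(sim_config(pilot = 2, n_sites = 0), "n_sites")
  expect_error(sim_config(pilot = 2, dropout_prob = 1.5), "dropout_prob")
  expect_error(sim_config(pilot = 2,
                          class_mix = c(SNP = 0.7, INSERTION = 0.1,
                                        DELETION = 0.1,
                                        MULTIALLELIC_COMPLEX = 0.05,
                                        MULTIALLELIC_MIXED = 0.1)),
               "class_mix")
  expect_error(simulate_depth_tracks(sim_config(pilot = 1, n_sites = 10),
                                     build_manifest(sim_config(pilot = 1,
                                                               n_sites = 10)),
                                     make_targets(n_regions = 0)),
               "at least one region")
})

test_that("same config and seed give byte-identical VCF output", {
  cfg <- sim_config(pilot = 3, n_sites = 300, seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  fa <- withr::local_tempfile(fileext = ".vcf")
  fb <- withr::local_tempfile(fileext = ".vcf")
  write_callset_vcf(a$hc, fa)
  write_callset_vcf(b$hc, fb)
  expect_identical(readLines(fa), readLines(fb))
  expect_identical(a$ug$variants, b$ug$variants)
  expect_identical(a$truth$truth_a1, b$truth$truth_a1)
})

test_that("generated allele templates classify as intended", {
  cfg <- sim_config(pilot = 1, n_sites = 2000, seed = 77)
  sim <- simulate_cohort(cfg)
  cls <- as.vector(classify_variants(sim$hc))
  truth_cls <- sim$truth$sites$class[sim$truth$sites$caller_status !=
                                       "ug_only"]
  expect_equal(cls, truth_cls)
})

test_that("the default mix is SNP-dominated in the study's range", {
  sim <- simulate_cohort(sim_config(pilot = 2, n_sites = 5000, seed = 2))
  merged <- merge_caller_outputs(sim$hc, sim$ug)$callset
  s <- variant_type_summary(merged)
  snp_pct <- s$pct[s$group == "SNP"]
  expect_gte(snp_pct, 84)
  expect_lte(snp_pct, 94)
  # qualitative frequency ordering: SNP > insertion > deletion > multiallelic
  ord <- s$n[match(c("SNP", "insertion", "deletion", "multiallelic"),
                   s$group)]
  expect_true(all(diff(ord) < 0))
})

test_that("the artifact-free limit gives identical callers, all PASS", {
  cfg <- sim_config(pilot = 2, n_sites = 500, seed = 6, n_subjects = 3,
                    dropout_prob = 0, error_prob = 0,
                    missing_prob = list(max = 0, midpoint = 12, scale = 3),
                    caller_disagreement = list(unique_prob = 0,
                                               hc_filtered_prob = 0))
  sim <- simulate_cohort(cfg)
  expect_identical(sim$hc$variants[, 1:6], sim$ug$variants[, 1:6])
  expect_identical(sim$hc$gt_a1, sim$ug$gt_a1)
  expect_true(all(sim$hc$variants$filter == "PASS"))
  # observed genotypes equal subject truth for every sample
  subj <- match(sim$manifest$subject_id, sim$truth$subjects)
  for (j in seq_len(nrow(sim$manifest))) {
    expect_equal(pmin(sim$hc$gt_a1[, j], sim$hc$gt_a2[, j]),
                 pmin(sim$truth$truth_a1[, subj[j]],
                      sim$truth$truth_a2[, subj[j]]))
    expect_equal(pmax(sim$hc$gt_a1[, j], sim$hc$gt_a2[, j]),
                 pmax(sim$truth$truth_a1[, subj[j]],
                      sim$truth$truth_a2[, subj[j]]))
  }
})

test_that("dropout fires only on heterozygous calls in WGA-derived types", {
  cfg <- sim_config(pilot = 3, n_sites = 10, dropout_prob = 1,
                    error_prob = 0,
                    missing_prob = list(max = 0, midpoint = 12, scale = 3))
  set.seed(1)
  n <- 5000L
  ta1 <- rep(0L, n); ta2 <- rep(1L, n)
  o <- observe_genotypes(ta1, ta2, rep(1L, n), "DBS_2x3.2", rep(60L, n),
                         cfg)
  expect_true(all(o$a1 == o$a2))                  # every het dropped out
  expect_true(all(o$dropout))
  hom_first <- mean(o$a1 == 0)                    # uniform choice of allele
  expect_lt(abs(hom_first - 0.5), 3 * sqrt(0.25 / n))

  o_wb <- observe_genotypes(ta1, ta2, rep(1L, n), "WB_ref", rep(60L, n),
                            cfg)
  expect_true(all(o_wb$a1 == 0L & o_wb$a2 == 1L))  # non-WGA type: gated off
  expect_false(any(o_wb$dropout))

  o_hom <- observe_genotypes(rep(1L, n), rep(1L, n), rep(1L, n),
                             "DBS_2x3.2", rep(60L, n), cfg)
  expect_false(any(o_hom$dropout))                # homozygous truth: no ADO
})

test_that("dropout frequency recovers the configured rate", {
  cfg <- sim_config(pilot = 1, n_sites = 10, dropout_prob = 0.05,
                    error_prob = 0,
                    missing_prob = list(max = 0, midpoint = 12, scale = 3))
  set.seed(2)
  n <- 10000L
  o <- observe_genotypes(rep(0L, n), rep(1L, n), rep(1L, n), "DBS_2x1.6",
                         rep(60L, n), cfg)
  rate <- mean(o$a1 == o$a2)
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("missingness increases as depth decreases", {
  cfg <- sim_config(pilot = 1, n_sites = 10)
  set.seed(3)
  n <- 4000L
  miss_at <- function(d) {
    o <- observe_genotypes(rep(0L, n), rep(0L, n), rep(1L, n), "WB_ref",
                           rep(d, n), cfg)
    mean(o$missing)
  }
  expect_gt(miss_at(2L), miss_at(12L))
  expect_gt(miss_at(12L), miss_at(40L))
  expect_lt(miss_at(60L), 0.01)
})

test_that("genotype quality rises with depth and drops on artifact calls", {
  cfg <- sim_config(pilot = 1, n_sites = 10, dropout_prob = 1,
                    error_prob = 0,
                    missing_prob = list(max = 0, midpoint = 12, scale = 3))
  set.seed(4)
  n <- 2000L
  hi <- observe_genotypes(rep(0L, n), rep(0L, n), rep(1L, n), "WB_ref",
                          rep(50L, n), cfg)
  lo <- observe_genotypes(rep(0L, n), rep(0L, n), rep(1L, n), "WB_ref",
                          rep(8L, n), cfg)
  expect_gt(mean(hi$gq), mean(lo$gq, na.rm = TRUE))
  expect_gt(mean(hi$gq), 90)
  ado <- observe_genotypes(rep(0L, n), rep(1L, n), rep(1L, n), "DBS_2x3.2",
                           rep(50L, n), cfg)
  expect_lt(mean(ado$gq), mean(hi$gq))
})
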