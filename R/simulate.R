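# Synthetic cohort generator: emulates the pilot study designs (subjects x
# sample types, triplicated small-disc DBS samples) and the artifact
# mechanisms of whole-genome amplification — allele dropout, amplification
# error, depth attenuation, depth-dependent missingness — so the entire
# pipeline runs with no external data. Parameter defaults are artifact
# defaults chosen for test power, not estimates from any real cohort.

#' Pilot study designs
#'
#' The three pilot layouts: Pilot 1 pairs a 2x3.2 mm DBS sample with a
#' whole-blood reference for 7 subjects; Pilot 2 adds a WB reference
#' sequencing replica (8 subjects); Pilot 3 (7 subjects) adds triplicated
#' 2x1.6 mm DBS samples and a whole-genome-amplified WB sample.
#'
#' @param pilot 1, 2 or 3
#' @return list with `n_subjects` and `sample_types`, a named vector of
#'   replicate counts
#' @export
pilot_design <- function(pilot) {
  switch(as.character(pilot),
    "1" = list(n_subjects = 7L,
               sample_types = c(DBS_2x3.2 = 1L, WB_ref = 1L)),
    "2" = list(n_subjects = 8L,
               sample_types = c(DBS_2x3.2 = 1L, WB_ref = 1L,
                                WB_ref_replica = 1L)),
    "3" = list(n_subjects = 7L,
               sample_types = c(DBS_2x3.2 = 1L, DBS_2x1.6 = 3L,
                                WB_ref = 1L, WB_WGA_ref = 1L)),
    stop("pilot must be 1, 2 or 3"))
}

#' Simulation configuration
#'
#' All generative parameters of the synthetic cohort. Defaults give an
#' SNP-dominated variant mix (SNP share within 84-94%), a negative-binomial
#' depth model (Gamma site factor x Poisson sampling) with WGA-derived
#' sample types attenuated below whole blood, allele dropout confined to
#' WGA-derived types, rare genotype errors, logistic-in-depth missingness,
#' and genotype qualities that grow with depth and collapse on
#' artifact-affected calls.
#'
#' @param pilot pilot design to emulate (1, 2 or 3); sets `n_subjects` and
#'   `sample_types` unless overridden
#' @param seed integer RNG seed; identical configurations give
#'   byte-identical outputs
#' @param n_sites number of variant sites
#' @param n_subjects subjects in the cohort
#' @param sample_types named vector of replicate counts per sample type
#' @param class_mix probabilities over the five variant classes (must sum
#'   to 1)
#' @param alt_af_beta Beta(a, b) parameters of the per-site alternate
#'   allele frequency
#' @param depth_model list: `mean` per-sample depth at unamplified sites,
#'   `dispersion` (Gamma shape of the shared site factor; smaller = more
#'   site-to-site spread), `attenuation` named multiplier per sample type
#'   (< 1 for WGA-derived types)
#' @param dropout_prob probability a truth-heterozygous call in a
#'   WGA-derived sample is observed as one of the two homozygotes
#' @param error_prob probability an observed genotype is perturbed to a
#'   random different genotype
#' @param missing_prob list: `max`, `midpoint`, `scale` of the logistic
#'   no-call probability `max * plogis((midpoint - depth) / scale)`
#' @param gq_model list: `per_read` GQ points per read, `sd` Gaussian
#'   noise, `artifact_factor` multiplier on the GQ mean of
#'   dropout/error-affected calls, `max` GQ cap
#' @param caller_disagreement list: `unique_prob` probability a site is
#'   emitted by only one caller (split evenly), `hc_filtered_prob`
#'   probability the priority caller's record is VQSR-filtered while the
#'   secondary caller's is PASS
#' @param replica_is_reference should WB_ref_replica samples join the
#'   reference-standard set used by the genotype-quality filter? Default
#'   `FALSE`: only WB_ref samples define the standard.
#' @return validated list of class `sim_config`
#' @export
sim_config <- function(pilot = 2,
                       seed = 20160401,
                       n_sites = 10000L,
                       n_subjects = NULL,
                       sample_types = NULL,
                       class_mix = c(SNP = 0.89, INSERTION = 0.05,
                                     DELETION = 0.04,
                                     MULTIALLELIC_COMPLEX = 0.01,
                                     MULTIALLELIC_MIXED = 0.01),
                       alt_af_beta = c(1, 3),
                       depth_model = list(
                         mean = 60,
                         dispersion = 3,
                         attenuation = c(DBS_2x3.2 = 0.75, DBS_2x1.6 = 0.7,
                                         WB_ref = 1, WB_ref_replica = 1,
                                         WB_WGA_ref = 0.85)),
                       dropout_prob = 0.05,
                       error_prob = 0.002,
                       missing_prob = list(max = 0.25, midpoint = 12,
                                           scale = 3),
                       gq_model = list(per_read = 3, sd = 6,
                                       artifact_factor = 0.3, max = 99L),
                       caller_disagreement = list(unique_prob = 0.04,
                                                  hc_filtered_prob = 0.03),
                       replica_is_reference = FALSE) {
  design <- pilot_design(pilot)
  cfg <- list(
    pilot = as.integer(pilot), seed = as.integer(seed),
    n_sites = as.integer(n_sites),
    n_subjects = if (is.null(n_subjects)) design$n_subjects
                 else as.integer(n_subjects),
    sample_types = if (is.null(sample_types)) design$sample_types
                   else sample_types,
    class_mix = class_mix, alt_af_beta = alt_af_beta,
    depth_model = depth_model, dropout_prob = dropout_prob,
    error_prob = error_prob, missing_prob = missing_prob,
    gq_model = gq_model, caller_disagreement = caller_disagreement,
    replica_is_reference = isTRUE(replica_is_reference))
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' @param cfg a `sim_config` list
#' @return the configuration, classed `sim_config`; errors list every
#'   offending field
#' @export
validate_sim_config <- function(cfg) {
  bad <- character()
  chk <- function(cond, field) if (!isTRUE(all(cond))) bad <<- c(bad, field)
  chk(cfg$n_sites >= 1, "n_sites")
  chk(cfg$n_subjects >= 1, "n_subjects")
  chk(length(cfg$sample_types) >= 1 &&
        all(names(cfg$sample_types) %in% SAMPLE_TYPES) &&
        all(cfg$sample_types >= 1), "sample_types")
  chk(abs(sum(cfg$class_mix) - 1) <= 1e-9 &&
        all(cfg$class_mix >= 0) &&
        setequal(names(cfg$class_mix), VARIANT_CLASSES), "class_mix")
  chk(all(cfg$alt_af_beta > 0) && length(cfg$alt_af_beta) == 2,
      "alt_af_beta")
  chk(cfg$depth_model$mean > 0 && cfg$depth_model$dispersion > 0 &&
        all(cfg$depth_model$attenuation > 0), "depth_model")
  chk(cfg$dropout_prob >= 0 && cfg$dropout_prob <= 1, "dropout_prob")
  chk(cfg$error_prob >= 0 && cfg$error_prob <= 1, "error_prob")
  chk(cfg$missing_prob$max >= 0 && cfg$missing_prob$max <= 1 &&
        cfg$missing_prob$scale > 0, "missing_prob")
  chk(cfg$gq_model$per_read >= 0 && cfg$gq_model$sd >= 0 &&
        cfg$gq_model$artifact_factor >= 0 &&
        cfg$gq_model$artifact_factor <= 1, "gq_model")
  chk(cfg$caller_disagreement$unique_prob >= 0 &&
        cfg$caller_disagreement$hc_filtered_prob >= 0 &&
        cfg$caller_disagreement$unique_prob +
          cfg$caller_disagreement$hc_filtered_prob <= 1,
      "caller_disagreement")
  if (length(bad))
    stop("invalid simulation config field(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "sim_config")
}

#' Build the manifest implied by a simulation configuration
#'
#' One sample per subject x sample type x replicate. WB_ref samples (and,
#' if `replica_is_reference`, WB_ref_replica samples) are flagged as the
#' reference standard for the genotype-quality filter.
#'
#' @param cfg a `sim_config`
#' @return roster data.frame
#' @export
build_manifest <- function(cfg) {
  rows <- list()
  for (s in seq_len(cfg$n_subjects)) {
    for (tt in names(cfg$sample_types)) {
      for (r in seq_len(cfg$sample_types[[tt]])) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("P%d_S%02d_%s_r%d", cfg$pilot, s, tt, r),
          subject_id = sprintf("SUBJ%02d", s),
          sample_type = tt, replicate = r, pilot = cfg$pilot,
          is_reference_standard = tt == "WB_ref" ||
            (cfg$replica_is_reference && tt == "WB_ref_replica"),
          stringsAsFactors = FALSE)
      }
    }
  }
  validate_manifest(do.call(rbind, rows))
}

# random allele template for one site of a given class
make_alleles <- function(class) {
  bases <- c("A", "C", "G", "T")
  b <- function(n = 1) paste(sample(bases, n, replace = TRUE), collapse = "")
  snp_alt <- function(ref) sample(setdiff(bases, ref), 1)
  switch(class,
    SNP = { r <- b(); list(ref = r, alts = snp_alt(r)) },
    INSERTION = { r <- b(); list(ref = r,
                                 alts = paste0(r, b(sample(1:3, 1)))) },
    DELETION = { r <- b(1 + sample(1:3, 1)); list(ref = r,
                                                  alts = substr(r, 1, 1)) },
    MULTIALLELIC_COMPLEX = {   # two insertions of different sizes
      r <- b()
      list(ref = r, alts = c(paste0(r, b(1)), paste0(r, b(2))))
    },
    MULTIALLELIC_MIXED = {     # a SNP allele plus an insertion allele
      r <- b()
      list(ref = r, alts = c(snp_alt(r), paste0(r, b(1))))
    },
    stop("unknown class: ", class))
}

#' Observe genotypes through the WGA artifact model
#'
#' Applies, in order: allele dropout (only when the truth genotype is
#' heterozygous and the sample type is WGA-derived — the artifact is
#' attributed to amplification, so `WB_WGA_ref` is included), genotype
#' error (perturbation to a uniformly chosen different genotype),
#' depth-dependent missingness, and GQ assignment. Vectorised over sites;
#' uses the current RNG state.
#'
#' @param truth_a1,truth_a2 integer truth allele indices per site
#' @param n_alt number of alternate alleles per site
#' @param sample_type the sample's type (gates dropout)
#' @param depth per-site read depth for this sample
#' @param cfg a `sim_config`
#' @return list: `a1`, `a2`, `gq`, `dropout`, `error`, `missing`
#' @export
observe_genotypes <- function(truth_a1, truth_a2, n_alt, sample_type,
                              depth, cfg) {
  n <- length(truth_a1)
  a1 <- truth_a1; a2 <- truth_a2
  is_wga <- sample_type %in% WGA_TYPES

  dropout <- logical(n)
  if (is_wga && cfg$dropout_prob > 0) {
    het <- a1 != a2
    dropout <- het & stats::runif(n) < cfg$dropout_prob
    pick_first <- stats::runif(n) < 0.5   # drawn for all sites: fixed stream
    keep <- ifelse(pick_first, truth_a1, truth_a2)
    a1[dropout] <- keep[dropout]
    a2[dropout] <- keep[dropout]
  }

  error <- stats::runif(n) < cfg$error_prob
  if (any(error)) {
    for (i in which(error)) {
      k <- n_alt[i]
      gts <- cbind(rep(0:k, times = (k + 1):1),
                   unlist(lapply(0:k, function(x) x:k)))
      cur <- which(gts[, 1] == min(a1[i], a2[i]) &
                     gts[, 2] == max(a1[i], a2[i]))
      pick <- gts[sample(setdiff(seq_len(nrow(gts)), cur), 1), ]
      a1[i] <- pick[1]; a2[i] <- pick[2]
    }
  }

  p_miss <- cfg$missing_prob$max *
    stats::plogis((cfg$missing_prob$midpoint - depth) /
                    cfg$missing_prob$scale)
  missing <- stats::runif(n) < p_miss
  a1[missing] <- NA_integer_
  a2[missing] <- NA_integer_

  correct <- !dropout & !error
  gq_mean <- cfg$gq_model$per_read * depth *
    ifelse(correct, 1, cfg$gq_model$artifact_factor)
  gq <- as.integer(pmax(0, pmin(cfg$gq_model$max,
                                round(stats::rnorm(n, gq_mean,
                                                   cfg$gq_model$sd)))))
  gq[missing] <- NA_integer_

  list(a1 = a1, a2 = a2, gq = gq,
       dropout = dropout & !missing, error = error & !missing,
       missing = missing)
}

#' Observe a single genotype
#'
#' Scalar wrapper around [observe_genotypes()] for one truth genotype.
#'
#' @param truth_gt length-2 integer vector of truth allele indices
#' @param sample_type the sample's type
#' @param depth read depth at the site
#' @param cfg a `sim_config`
#' @param n_alt number of alternate alleles at the site (default 1)
#' @return list: `alleles` (length-2 integer or `NA`s), `gq`, `dp`
#' @export
observe_genotype <- function(truth_gt, sample_type, depth, cfg, n_alt = 1L) {
  o <- observe_genotypes(truth_gt[1], truth_gt[2], n_alt, sample_type,
                         depth, cfg)
  list(alleles = c(o$a1, o$a2), gq = o$gq, dp = depth)
}

#' Simulate a two-caller synthetic cohort
#'
#' Draws variant sites (class mix, allele templates, Beta-distributed
#' alternate allele frequencies), truth genotypes per subject under
#' Hardy-Weinberg, per-site per-sample depths (shared Gamma site factor x
#' Poisson, attenuated for WGA-derived types), then observes every sample's
#' genotype through the artifact model. Two caller-style call sets over the
#' same roster are produced: the secondary caller agrees with the priority
#' caller except at sites assigned to one caller only or VQSR-filtered in
#' the priority caller. Deterministic under `cfg$seed`.
#'
#' @param cfg a `sim_config`
#' @return list: `hc` and `ug` (`callset`s), `manifest`, `truth` (truth
#'   genotype matrices, site table and per-sample artifact flags), `config`
#' @export
simulate_cohort <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  set.seed(cfg$seed)
  manifest <- build_manifest(cfg)
  n <- cfg$n_sites
  ns <- nrow(manifest)

  classes <- sample(names(cfg$class_mix), n, replace = TRUE,
                    prob = cfg$class_mix)
  pos <- cumsum(sample(20:200, n, replace = TRUE))
  alleles <- lapply(classes, make_alleles)
  n_alt <- lengths(lapply(alleles, `[[`, "alts"))

  # per-site allele frequencies (alt1 [, alt2])
  p_alt_total <- stats::rbeta(n, cfg$alt_af_beta[1], cfg$alt_af_beta[2])
  w <- stats::runif(n, 0.3, 0.7)
  p1 <- ifelse(n_alt == 1, p_alt_total, p_alt_total * w)
  p2 <- ifelse(n_alt == 1, 0, p_alt_total * (1 - w))
  p0 <- 1 - p1 - p2

  # truth genotypes per subject under Hardy-Weinberg
  draw_allele <- function() {
    u <- matrix(stats::runif(n * cfg$n_subjects), n, cfg$n_subjects)
    (u > p0) + (u > p0 + p1)
  }
  truth_a1 <- draw_allele()
  truth_a2 <- draw_allele()
  storage.mode(truth_a1) <- "integer"
  storage.mode(truth_a2) <- "integer"

  # depth: shared Gamma site factor, Poisson per sample, attenuated by type
  site_factor <- stats::rgamma(n, shape = cfg$depth_model$dispersion,
                               rate = cfg$depth_model$dispersion)
  atten <- cfg$depth_model$attenuation[manifest$sample_type]
  dp <- matrix(stats::rpois(n * ns,
                            lambda = outer(cfg$depth_model$mean * site_factor,
                                           atten)), n, ns)
  storage.mode(dp) <- "integer"

  a1 <- a2 <- gq <- matrix(NA_integer_, n, ns)
  fl_dropout <- fl_error <- fl_missing <- matrix(FALSE, n, ns)
  subj_idx <- match(manifest$subject_id,
                    sprintf("SUBJ%02d", seq_len(cfg$n_subjects)))
  for (j in seq_len(ns)) {
    o <- observe_genotypes(truth_a1[, subj_idx[j]], truth_a2[, subj_idx[j]],
                           n_alt, manifest$sample_type[j], dp[, j], cfg)
    a1[, j] <- o$a1; a2[, j] <- o$a2; gq[, j] <- o$gq
    fl_dropout[, j] <- o$dropout
    fl_error[, j] <- o$error
    fl_missing[, j] <- o$missing
  }

  # caller emission status per site
  u <- stats::runif(n)
  up <- cfg$caller_disagreement$unique_prob
  fp <- cfg$caller_disagreement$hc_filtered_prob
  status <- ifelse(u < up / 2, "hc_only",
            ifelse(u < up, "ug_only",
            ifelse(u < up + fp, "hc_filtered", "both_pass")))

  variants <- data.frame(
    chrom = "chr1", pos = as.integer(pos),
    ref = vapply(alleles, `[[`, "", "ref"),
    alt = vapply(alleles, function(a) paste(a$alts, collapse = ","), ""),
    filter = "PASS", site_dp = as.integer(rowSums(dp)),
    stringsAsFactors = FALSE)

  mk <- function(keep, filt, label) {
    v <- variants[keep, , drop = FALSE]
    v$filter <- filt[keep]
    new_callset(v, a1[keep, , drop = FALSE], a2[keep, , drop = FALSE],
                gq[keep, , drop = FALSE], dp[keep, , drop = FALSE],
                manifest, label,
                sprintf("sim(pilot=%d,seed=%d):%s", cfg$pilot, cfg$seed,
                        label))
  }
  hc <- mk(status != "ug_only",
           ifelse(status == "hc_filtered", "FILTERED", "PASS"), "HC")
  ug <- mk(status != "hc_only", rep("PASS", n), "UG")

  truth <- list(
    truth_a1 = truth_a1, truth_a2 = truth_a2,
    subjects = sprintf("SUBJ%02d", seq_len(cfg$n_subjects)),
    sites = data.frame(chrom = "chr1", pos = as.integer(pos),
                       class = classes, n_alt = n_alt, af1 = p1, af2 = p2,
                       caller_status = status, stringsAsFactors = FALSE),
    dropout = fl_dropout, error = fl_error, missing = fl_missing)
  colnames(truth$dropout) <- colnames(truth$error) <-
    colnames(truth$missing) <- manifest$sample_id

  list(hc = hc, ug = ug, manifest = manifest, truth = truth, config = cfg)
}

#' Default exome-like target regions
#'
#' Deterministic BED-style interval set (no RNG): `n_regions` regions of
#' `region_len` bases separated by fixed gaps on one contig.
#'
#' @param n_regions number of regions
#' @param region_len region width in bases
#' @param gap gap between regions
#' @param chrom contig name
#' @return data.frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open)
#' @export
make_targets <- function(n_regions = 150, region_len = 120, gap = 80,
                         chrom = "chr1") {
  start <- (seq_len(n_regions) - 1L) * (region_len + gap)
  data.frame(chrom = rep(chrom, n_regions), start = as.integer(start),
             end = as.integer(start + region_len), stringsAsFactors = FALSE)
}

#' Simulate per-sample depth tracks over target regions
#'
#' Per region, a Gamma capture-efficiency factor shared across samples;
#' per base, Poisson depths around the sample type's attenuated mean.
#' Reproduces the qualitative coverage deficit of WGA-derived samples.
#' Seeded from `cfg$seed` (offset so tracks are independent of the cohort
#' draw).
#'
#' @param cfg a `sim_config`
#' @param manifest roster data.frame
#' @param targets target regions (see [make_targets()])
#' @return named list of `depth_track`s, one per sample
#' @export
simulate_depth_tracks <- function(cfg, manifest, targets) {
  cfg <- validate_sim_config(cfg)
  if (is.null(nrow(targets)) || nrow(targets) == 0)
    stop("targets must contain at least one region")
  set.seed((cfg$seed + 1L) %% .Machine$integer.max)
  lens <- targets$end - targets$start
  region_factor <- stats::rgamma(nrow(targets),
                                 shape = cfg$depth_model$dispersion,
                                 rate = cfg$depth_model$dispersion)
  tracks <- lapply(seq_len(nrow(manifest)), function(j) {
    mu <- cfg$depth_model$mean *
      cfg$depth_model$attenuation[[manifest$sample_type[j]]]
    depths <- lapply(seq_len(nrow(targets)), function(i)
      stats::rpois(lens[i], mu * region_factor[i]))
    depth_track(manifest$sample_id[j], targets, depths)
  })
  names(tracks) <- manifest$sample_id
  tracks
}
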