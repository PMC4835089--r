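# End-to-end orchestration: simulate (or load) -> merge -> classify/filter
# -> concordance -> coverage, with all tables written to one run directory.

#' Default pairing plan for a pilot
#'
#' The sample-type comparisons reported for each pilot design: DBS_2x3.2 vs
#' WB_ref in every pilot; WB_ref vs WB_ref_replica in Pilot 2; DBS_2x1.6 vs
#' WB_ref, DBS_2x3.2 vs DBS_2x1.6 and WB_ref vs WB_WGA_ref in Pilot 3.
#'
#' @param pilot 1, 2 or 3
#' @return data.frame with columns `type_a`, `type_b`
#' @export
default_pairing_plan <- function(pilot) {
  base <- data.frame(type_a = "DBS_2x3.2", type_b = "WB_ref",
                     stringsAsFactors = FALSE)
  extra <- switch(as.character(pilot),
    "1" = NULL,
    "2" = data.frame(type_a = "WB_ref", type_b = "WB_ref_replica",
                     stringsAsFactors = FALSE),
    "3" = data.frame(type_a = c("DBS_2x1.6", "DBS_2x3.2", "WB_ref"),
                     type_b = c("WB_ref", "DBS_2x1.6", "WB_WGA_ref"),
                     stringsAsFactors = FALSE),
    stop("pilot must be 1, 2 or 3"))
  rbind(base, extra)
}

#' Run configuration
#'
#' Bundles either a simulation configuration or paths to real inputs (two
#' caller VCFs plus a manifest), the filter thresholds, the pairing plan
#' and the output directory.
#'
#' @param outdir run directory (created if absent)
#' @param sim a `sim_config`, or `NULL` when real inputs are given
#' @param hc_vcf,ug_vcf,manifest_path input paths (used when `sim` is
#'   `NULL`)
#' @param thresholds see [filter_thresholds()]
#' @param pairing_plan data.frame `type_a`/`type_b`; default derived from
#'   the pilot
#' @param coverage_thresholds depth thresholds for the coverage report
#' @return list of class `run_config`
#' @export
run_config <- function(outdir, sim = NULL, hc_vcf = NULL, ug_vcf = NULL,
                       manifest_path = NULL,
                       thresholds = filter_thresholds(),
                       pairing_plan = NULL,
                       coverage_thresholds = c(10, 30)) {
  if (is.null(sim) && (is.null(hc_vcf) || is.null(ug_vcf) ||
                       is.null(manifest_path)))
    stop("either a simulation config or all input paths must be given")
  structure(list(outdir = outdir, sim = sim, hc_vcf = hc_vcf,
                 ug_vcf = ug_vcf, manifest_path = manifest_path,
                 thresholds = thresholds, pairing_plan = pairing_plan,
                 coverage_thresholds = coverage_thresholds),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full evaluation pipeline
#'
#' Simulates (or loads) the two caller call sets, merges them by PASS
#' priority, classifies and filters the merged set, computes the per-pilot
#' concordance report and, for simulated runs, the coverage report. All
#' tables are written under `cfg$outdir` together with a machine-readable
#' run manifest (seed, thresholds, file hashes).
#'
#' @param cfg a `run_config`
#' @return list with the merged and filtered call sets and every report
#'   table, invisibly
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(cfg$outdir, f)

  if (!is.null(cfg$sim)) {
    sim <- simulate_cohort(cfg$sim)
    hc <- sim$hc; ug <- sim$ug; manifest <- sim$manifest
    write_callset_vcf(hc, p("hc.vcf"))
    write_callset_vcf(ug, p("ug.vcf"))
    write_manifest(manifest, p("manifest.tsv"))
  } else {
    manifest <- read_manifest(cfg$manifest_path)
    hc <- read_multisample_vcf(cfg$hc_vcf, manifest, "HC")
    ug <- read_multisample_vcf(cfg$ug_vcf, manifest, "UG")
    sim <- NULL
  }
  message("merge: ", n_variants(hc), " HC / ", n_variants(ug),
          " UG records in")
  m <- merge_caller_outputs(hc, ug)
  merged <- m$callset
  write_callset_vcf(merged, p("merged.vcf"))
  write_tsv(m$report, p("merge_report.tsv"))

  f <- apply_filters(merged, cfg$thresholds)
  filtered <- f$callset
  message("filter: ", n_variants(merged), " -> ", n_variants(filtered),
          " records")
  write_callset_vcf(filtered, p("filtered.vcf"))
  write_tsv(f$decisions, p("filter_decisions.tsv"))

  before <- variant_type_summary(merged)
  after <- variant_type_summary(filtered)
  vsum <- data.frame(group = before$group,
                     n_before = before$n, pct_before = before$pct,
                     n_after = after$n, pct_after = after$pct)
  write_tsv(vsum, p("variant_type_summary.tsv"))

  plan <- cfg$pairing_plan
  if (is.null(plan)) {
    pilot <- unique(manifest$pilot)
    if (length(pilot) != 1)
      stop("multi-pilot manifest needs an explicit pairing plan")
    plan <- default_pairing_plan(pilot)
  }
  conc <- pilot_concordance_report(merged, filtered, manifest, plan)
  write_tsv(conc, p("concordance.tsv"))

  coverage <- NULL
  if (!is.null(cfg$sim)) {
    targets <- make_targets()
    tracks <- simulate_depth_tracks(cfg$sim, manifest, targets)
    coverage <- coverage_report(tracks, manifest, cfg$coverage_thresholds)
    write_tsv(coverage, p("coverage.tsv"))
  }

  run_manifest <- list(
    seed = if (!is.null(cfg$sim)) cfg$sim$seed else NA,
    thresholds = cfg$thresholds,
    pairing_plan = plan,
    n_merged = n_variants(merged),
    n_filtered = n_variants(filtered),
    file_md5 = as.list(tools::md5sum(
      list.files(cfg$outdir, full.names = TRUE,
                 pattern = "\\.(vcf|tsv)$"))))
  names(run_manifest$file_md5) <- basename(names(run_manifest$file_md5))
  writeLines(yaml::as.yaml(run_manifest), p("run_manifest.yaml"))

  invisible(list(merged = merged, filtered = filtered,
                 merge_report = m$report, decisions = f$decisions,
                 variant_summary = vsum, concordance = conc,
                 coverage = coverage, manifest = manifest, sim = sim))
}
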