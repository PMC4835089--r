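# Core containers: a call set is a position-sorted table of variant sites plus
# per-sample genotype matrices sharing one sample roster.

#' Recognised sample types
#'
#' The five sample types of the pilot designs: whole-genome-amplified DNA of
#' 2x3.2 mm and 2x1.6 mm dried-blood-spot discs, the whole-blood reference,
#' its sequencing replica, and whole-genome-amplified whole-blood DNA.
#'
#' @export
SAMPLE_TYPES <- c("DBS_2x3.2", "DBS_2x1.6", "WB_ref", "WB_ref_replica",
                  "WB_WGA_ref")

#' Whole-genome-amplified sample types
#'
#' Sample types derived through whole-genome amplification; allele dropout
#' in the synthetic cohort is confined to these.
#'
#' @export
WGA_TYPES <- c("DBS_2x3.2", "DBS_2x1.6", "WB_WGA_ref")

#' Construct a call set
#'
#' A `callset` bundles a variant table with per-sample genotype matrices.
#' Rows of every matrix correspond to rows of `variants`; columns correspond
#' to `roster$sample_id`. Genotypes are stored as two allele-index matrices
#' (`gt_a1`, `gt_a2`, `NA` = no call); half-calls must already be normalised
#' to missing. Records are sorted by (chrom, pos) with a stable sort.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (comma-separated alternate alleles), `filter` (`"PASS"` or
#'   `"FILTERED"`), `site_dp` (multi-sample combined depth) and optionally
#'   `origin` (per-record caller tag).
#' @param gt_a1,gt_a2 integer matrices of allele indices (0 = REF).
#' @param gq,gt_dp integer matrices of genotype quality and per-sample depth
#'   (`NA` permitted).
#' @param roster data.frame of sample metadata (see [read_manifest()]).
#' @param source one of `"HC"`, `"UG"`, `"MERGED"`, or a free label.
#' @param provenance free-text processing trail.
#' @return an object of class `callset`.
#' @export
new_callset <- function(variants, gt_a1, gt_a2, gq, gt_dp, roster,
                        source = "HC", provenance = source) {
  stopifnot(is.data.frame(variants), is.data.frame(roster))
  need <- c("chrom", "pos", "ref", "alt", "filter", "site_dp")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variant table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!"origin" %in% names(variants))
    variants$origin <- rep(source, nrow(variants))
  n <- nrow(variants)
  s <- nrow(roster)
  for (m in list(gt_a1, gt_a2, gq, gt_dp)) {
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != s)
      stop("genotype matrices must be ", n, " x ", s)
  }
  colnames(gt_a1) <- colnames(gt_a2) <- colnames(gq) <- colnames(gt_dp) <-
    roster$sample_id
  bad <- which(xor(is.na(gt_a1), is.na(gt_a2)))
  if (length(bad)) stop("half-calls must be normalised to missing before ",
                        "construction (", length(bad), " cells)")
  ord <- order(variants$chrom, variants$pos, method = "radix")
  cs <- structure(list(
    variants = variants[ord, , drop = FALSE],
    gt_a1 = gt_a1[ord, , drop = FALSE],
    gt_a2 = gt_a2[ord, , drop = FALSE],
    gq = gq[ord, , drop = FALSE],
    dp = gt_dp[ord, , drop = FALSE],
    roster = roster,
    source = source,
    provenance = provenance
  ), class = "callset")
  rownames(cs$variants) <- NULL
  cs
}

#' @export
print.callset <- function(x, ...) {
  cat("<callset> ", n_variants(x), " variants x ", n_samples(x),
      " samples [", x$source, "] ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Number of variant records in a call set
#' @param cs a `callset`
#' @export
n_variants <- function(cs) nrow(cs$variants)

#' Number of samples on the roster
#' @param cs a `callset`
#' @export
n_samples <- function(cs) nrow(cs$roster)

#' Sample identifiers of a call set
#' @param cs a `callset`
#' @export
sample_ids <- function(cs) cs$roster$sample_id

#' Alternate alleles as a list
#' @param cs a `callset`
#' @return list of character vectors, one per record
#' @export
alt_list <- function(cs) strsplit(cs$variants$alt, ",", fixed = TRUE)

#' Subset a call set by record index
#'
#' Pure row subset: roster, sample order and record contents are untouched.
#'
#' @param cs a `callset`
#' @param idx logical or integer row index
#' @param provenance optional new provenance label
#' @export
subset_callset <- function(cs, idx, provenance = cs$provenance) {
  new_callset(cs$variants[idx, , drop = FALSE],
              cs$gt_a1[idx, , drop = FALSE],
              cs$gt_a2[idx, , drop = FALSE],
              cs$gq[idx, , drop = FALSE],
              cs$dp[idx, , drop = FALSE],
              cs$roster, cs$source, provenance)
}

# ---- manifest ---------------------------------------------------------------

#' Read and validate a sample manifest
#'
#' Tab-separated manifest with columns `sample_id`, `subject_id`,
#' `sample_type`, `replicate`, `pilot`, `is_reference_standard`. The
#' reference-standard flag marks the whole-blood samples whose genotype
#' qualities define the sample-level filter statistic (minGQ over the WB
#' reference set).
#'
#' @param path path to a TSV file
#' @return validated data.frame of sample metadata
#' @export
read_manifest <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample_id", "subject_id", "sample_type", "replicate", "pilot",
            "is_reference_standard")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("manifest lacks columns: ",
                         paste(miss, collapse = ", "))
  df$replicate <- as.integer(df$replicate)
  df$pilot <- as.integer(df$pilot)
  df$is_reference_standard <-
    tolower(df$is_reference_standard) %in% c("true", "t", "1", "yes")
  validate_manifest(df)
}

#' Validate a manifest data.frame
#'
#' Enforces the roster invariants: known sample types, unique sample ids,
#' unique (subject, type, replicate) within a pilot, and at least one
#' reference-standard sample per pilot.
#'
#' @param df data.frame as produced by [read_manifest()]
#' @return the validated data.frame, invisibly identical to the input
#' @export
validate_manifest <- function(df) {
  bad <- setdiff(unique(df$sample_type), SAMPLE_TYPES)
  if (length(bad))
    stop("unknown sample_type: ", paste(bad, collapse = ", "),
         "; allowed: ", paste(SAMPLE_TYPES, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in manifest")
  key <- paste(df$pilot, df$subject_id, df$sample_type, df$replicate)
  if (anyDuplicated(key))
    stop("duplicate (subject_id, sample_type, replicate) within a pilot: ",
         key[duplicated(key)][1])
  if (any(df$replicate < 1L)) stop("replicate must be >= 1")
  for (p in unique(df$pilot)) {
    if (!any(df$is_reference_standard[df$pilot == p]))
      stop("pilot ", p, " has no reference-standard sample")
  }
  df
}

# ---- genotype string handling ----------------------------------------------

#' Parse VCF GT strings into allele-index pairs
#'
#' Accepts `/` and `|` separators (phase is discarded). A half-call such as
#' `./1` or `1/.` is normalised to missing, as are non-diploid strings: the
#' concordance categories only distinguish a present diploid genotype from a
#' no-call.
#'
#' @param gt character vector of GT fields (e.g. `"0/1"`, `"./."`, `"1|2"`)
#' @return list with integer vectors `a1`, `a2` (`NA` = missing)
#' @export
parse_gt <- function(gt) {
  gt[is.na(gt)] <- "."
  parts <- strsplit(gt, "[/|]")
  len <- lengths(parts)
  flat1 <- vapply(parts, function(p) if (length(p) >= 1) p[1] else ".", "")
  flat2 <- vapply(parts, function(p) if (length(p) >= 2) p[2] else ".", "")
  a1 <- suppressWarnings(as.integer(flat1))
  a2 <- suppressWarnings(as.integer(flat2))
  drop <- len != 2L | is.na(a1) | is.na(a2)
  a1[drop] <- NA_integer_
  a2[drop] <- NA_integer_
  list(a1 = a1, a2 = a2)
}

format_gt <- function(a1, a2) {
  out <- paste0(a1, "/", a2)
  out[is.na(a1) | is.na(a2)] <- "./."
  out
}

# ---- VCF I/O ----------------------------------------------------------------

#' Read a multi-sample VCF into a call set
#'
#' Reads a VCF v4.x file (plain or bgzipped) via \pkg{vcfR}, restricts it to
#' the manifest samples and maps fields onto the internal model: FILTER
#' `"PASS"` or `"."` becomes `PASS`, anything else (e.g. a VQSR tranche
#' label) becomes `FILTERED`; a missing INFO `DP` is replaced by the sum of
#' per-sample depths. Records with symbolic or non-ACGTN alleles or
#' non-diploid genotypes are skipped and counted in a message.
#'
#' @param path VCF path
#' @param manifest roster data.frame (see [read_manifest()]); the VCF sample
#'   columns must be a superset of `manifest$sample_id`
#' @param source_label caller tag stored in `source`/`origin` (e.g. `"HC"`)
#' @return a `callset`
#' @export
read_multisample_vcf <- function(path, manifest, source_label = "HC") {
  if (!file.exists(path)) stop("no such VCF: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e)))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  vcf_samples <- colnames(v@gt)[-1]
  absent <- setdiff(manifest$sample_id, vcf_samples)
  if (length(absent))
    stop("manifest samples absent from VCF header: ",
         paste(absent, collapse = ", "))

  n <- nrow(fix)
  if (n == 0) {
    empty <- matrix(NA_integer_, 0, nrow(manifest))
    return(new_callset(
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), filter = character(),
                 site_dp = integer(), stringsAsFactors = FALSE),
      empty, empty, empty, empty, manifest, source_label))
  }

  gt_chr <- vcfR::extract.gt(v, element = "GT")
  gq_chr <- tryCatch(vcfR::extract.gt(v, element = "GQ"),
                     error = function(e) matrix(NA_character_, n,
                                                length(vcf_samples)))
  dp_chr <- tryCatch(vcfR::extract.gt(v, element = "DP"),
                     error = function(e) matrix(NA_character_, n,
                                                length(vcf_samples)))
  sel <- match(manifest$sample_id, vcf_samples)
  gt_chr <- gt_chr[, sel, drop = FALSE]
  gq <- matrix(suppressWarnings(as.integer(gq_chr[, sel, drop = FALSE])),
               n, nrow(manifest))
  dp <- matrix(suppressWarnings(as.integer(dp_chr[, sel, drop = FALSE])),
               n, nrow(manifest))

  g <- parse_gt(as.vector(gt_chr))
  a1 <- matrix(g$a1, n, nrow(manifest))
  a2 <- matrix(g$a2, n, nrow(manifest))

  filt <- fix$FILTER
  filt[is.na(filt) | filt == "." | filt == "PASS"] <- "PASS"
  filt[filt != "PASS"] <- "FILTERED"

  info_dp <- suppressWarnings(
    as.integer(sub(".*?DP=([0-9]+).*", "\\1",
                   ifelse(grepl("(^|;)DP=", fix$INFO), fix$INFO, NA))))
  row_dp <- rowSums(dp, na.rm = TRUE)
  site_dp <- ifelse(is.na(info_dp), as.integer(row_dp), info_dp)

  alleles_ok <- grepl("^[ACGTNacgtn,]+$", fix$ALT) &
    grepl("^[ACGTNacgtn]+$", fix$REF) & !grepl("(^,)|(,,)|(,$)", fix$ALT)
  keep <- alleles_ok & !is.na(fix$ALT)
  if (any(!keep))
    message(sum(!keep), " record(s) with symbolic/unsupported alleles skipped")

  variants <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
    alt = fix$ALT, filter = filt, site_dp = site_dp,
    origin = source_label, stringsAsFactors = FALSE)

  new_callset(variants[keep, , drop = FALSE],
              a1[keep, , drop = FALSE], a2[keep, , drop = FALSE],
              gq[keep, , drop = FALSE], dp[keep, , drop = FALSE],
              manifest, source_label)
}

#' Write a call set as a VCF v4.2 file
#'
#' Plain-text, deterministic output; GT/GQ/DP per sample, INFO DP for the
#' multi-sample depth. `FILTERED` records carry the FILTER token
#' `"FILTERED"`; reading the file back reproduces every field used
#' downstream.
#'
#' @param cs a `callset`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_callset_vcf <- function(cs, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=dbsconcord:", cs$provenance),
    "##FILTER=<ID=FILTERED,Description=\"Did not pass caller filters\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Combined depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids(cs)), collapse = "\t"))
  n <- n_variants(cs)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  if (n == 0) return(invisible(path))

  fmt_int <- function(m) {
    x <- matrix(as.character(m), nrow(m), ncol(m))
    x[is.na(x)] <- "."
    x
  }
  gt <- matrix(format_gt(as.vector(cs$gt_a1), as.vector(cs$gt_a2)),
               n, n_samples(cs))
  cells <- matrix(paste(gt, fmt_int(cs$gq), fmt_int(cs$dp), sep = ":"),
                  n, n_samples(cs))
  lines <- paste(cs$variants$chrom, cs$variants$pos, ".", cs$variants$ref,
                 cs$variants$alt, ".", cs$variants$filter,
                 paste0("DP=", cs$variants$site_dp), "GT:GQ:DP", sep = "\t")
  lines <- paste(lines, apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Write a manifest TSV
#' @param manifest roster data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_manifest <- function(manifest, path) {
  out <- manifest
  out$is_reference_standard <- ifelse(out$is_reference_standard,
                                      "true", "false")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
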