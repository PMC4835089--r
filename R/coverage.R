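# Exome coverage-by-depth: per-sample percentage of target bases above a
# depth threshold, and Tukey box-plot summaries per sample type.

#' Construct a per-sample depth track
#'
#' Per-base depths over the target intervals. `targets` uses BED
#' conventions (0-based, half-open); each region's depth vector has length
#' `end - start`.
#'
#' @param sample_id sample identifier
#' @param targets data.frame with columns `chrom`, `start`, `end`
#' @param depths list of non-negative integer vectors, one per region
#' @return object of class `depth_track`
#' @export
depth_track <- function(sample_id, targets, depths) {
  stopifnot(nrow(targets) == length(depths))
  len <- targets$end - targets$start
  if (any(len <= 0)) stop("empty or inverted target region")
  if (!all(lengths(depths) == len))
    stop("depth vector length must equal region width")
  if (any(unlist(depths, use.names = FALSE) < 0))
    stop("negative depth")
  structure(list(sample_id = sample_id, targets = targets, depths = depths),
            class = "depth_track")
}

#' Read BED3 target regions
#' @param path BED file (chrom, start, end; 0-based half-open)
#' @return data.frame with columns `chrom`, `start`, `end`
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end"),
                          colClasses = c("character", "integer", "integer"))
  if (any(df$end <= df$start)) stop("BED region with end <= start")
  df
}

#' Read a per-base depth TSV into a depth track
#'
#' Three-column table (chrom, 1-based position, depth) as produced by
#' standard depth tools. Target positions absent from the table get depth
#' 0; positions outside the targets are ignored. BED-to-1-based conversion
#' happens here and only here.
#'
#' @param path depth TSV path
#' @param targets BED-style target data.frame (see [read_bed()])
#' @param sample_id identifier for the resulting track
#' @return a `depth_track`
#' @export
read_depth_tsv <- function(path, targets, sample_id) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "pos", "depth"),
                          colClasses = c("character", "integer", "integer"))
  depths <- lapply(seq_len(nrow(targets)), function(i) {
    w <- targets$end[i] - targets$start[i]
    v <- integer(w)
    sel <- df$chrom == targets$chrom[i] & df$pos > targets$start[i] &
      df$pos <= targets$end[i]
    v[df$pos[sel] - targets$start[i]] <- df$depth[sel]
    v
  })
  depth_track(sample_id, targets, depths)
}

#' Write a depth track as a per-base TSV
#' @param track a `depth_track`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_depth_tsv <- function(track, path) {
  tg <- track$targets
  chrom <- rep(tg$chrom, tg$end - tg$start)
  pos <- unlist(lapply(seq_len(nrow(tg)), function(i)
    (tg$start[i] + 1L):tg$end[i]), use.names = FALSE)
  utils::write.table(
    data.frame(chrom = chrom, pos = pos,
               depth = unlist(track$depths, use.names = FALSE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Percentage of target coverage above a depth threshold
#'
#' Default mode counts target bases with depth strictly above `threshold`
#' as a percentage of all target bases (the per-base reading of "coverage
#' >30X"). Mode `"region_mean"` instead reports the percentage of whole
#' regions whose mean depth exceeds the threshold.
#'
#' @param track a `depth_track`
#' @param threshold depth threshold (strict `>`)
#' @param mode `"per_base"` (default) or `"region_mean"`
#' @return percentage in `[0, 100]`
#' @export
fraction_above_depth <- function(track, threshold,
                                 mode = c("per_base", "region_mean")) {
  mode <- match.arg(mode)
  if (!length(track$depths)) stop("empty depth track")
  if (mode == "per_base") {
    d <- unlist(track$depths, use.names = FALSE)
    100 * sum(d > threshold) / length(d)
  } else {
    m <- vapply(track$depths, mean, 0.0)
    100 * sum(m > threshold) / length(m)
  }
}

#' Tukey box-plot summary
#'
#' Median and quartiles by linear interpolation between order statistics;
#' whiskers at the most extreme data points within 1.5 x IQR of the
#' quartiles; everything beyond is an outlier.
#'
#' @param values numeric vector (non-empty)
#' @return list with `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`, `n`
#' @export
boxplot_summary <- function(values) {
  if (!length(values)) stop("empty group")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(values[inside]),
       whisker_high = max(values[inside]),
       outliers = sort(values[!inside]),
       n = length(values))
}

#' Box-plot summaries per sample type
#'
#' @param values numeric vector (e.g. per-sample percent coverage >30X)
#' @param sample_type character vector parallel to `values`
#' @return named list of [boxplot_summary()] results, one per sample type
#' @export
sample_type_boxplot <- function(values, sample_type) {
  stopifnot(length(values) == length(sample_type))
  lapply(split(values, sample_type), boxplot_summary)
}

#' Signed difference of box-plot medians
#'
#' `median(b) - median(a)`, e.g. the whole-blood minus dried-blood-spot gap
#' in percent coverage above 30X.
#'
#' @param summary_a,summary_b [boxplot_summary()] results
#' @return signed difference
#' @export
coverage_delta <- function(summary_a, summary_b) {
  summary_b$median - summary_a$median
}

#' Coverage report for a set of depth tracks
#'
#' Per sample, the percentage of target bases above each threshold.
#'
#' @param tracks list of `depth_track`s
#' @param manifest roster data.frame (adds `sample_type`)
#' @param thresholds integer depth thresholds (default `c(10, 30)`)
#' @param mode passed to [fraction_above_depth()]
#' @return data.frame: `sample_id`, `sample_type`, one `pct_gt_<t>` column
#'   per threshold
#' @export
coverage_report <- function(tracks, manifest, thresholds = c(10, 30),
                            mode = "per_base") {
  ids <- vapply(tracks, function(t) t$sample_id, "")
  out <- data.frame(
    sample_id = ids,
    sample_type = manifest$sample_type[match(ids, manifest$sample_id)])
  for (t in thresholds) {
    out[[paste0("pct_gt_", t)]] <-
      vapply(tracks, fraction_above_depth, 0.0, threshold = t, mode = mode)
  }
  out
}
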