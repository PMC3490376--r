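# Capture coverage quality control.
#
# Depth tracks are integer vectors of per-base coverage over a target
# region (see read_depth()).  All statistics are computed over the target
# bases only; near-target accounting needs read placements and is optional.

#' Median coverage of one target
#'
#' @param depths integer vector of per-base depths over the target.
#' @return median depth; even-length targets use the mean of the two
#'   central values.
#' @examples
#' target_median_coverage(c(5, 5, 5))   # 5
#' target_median_coverage(c(0, 10))     # 5
#' @export
target_median_coverage <- function(depths) {
  if (length(depths) == 0L) stop("empty depth track")
  if (any(depths < 0)) stop("negative depth")
  stats::median(as.numeric(depths))
}

#' Fraction of target bases covered at least k times
#'
#' @param tracks named list of depth vectors (one per target) or a single
#'   numeric vector.
#' @param k minimum depth, `k >= 0`.
#' @return fraction in \[0, 1\] of all target bases with depth >= k.
#' @export
fraction_bases_at_least <- function(tracks, k) {
  stopifnot(k >= 0)
  depths <- if (is.list(tracks)) unlist(tracks, use.names = FALSE)
            else tracks
  if (length(depths) == 0L) stop("no depth tracks")
  mean(depths >= k)
}

#' Evenness score of coverage
#'
#' Summarises how uniformly coverage is distributed over the target bases
#' as a percentage: with mean depth `m`,
#' `E = 100 * (1/ceiling(m)) * sum_{i=1..ceiling(m)} P(depth >= i)`.
#' Perfectly uniform coverage scores 100; any non-uniform profile scores
#' strictly less.
#'
#' @inheritParams fraction_bases_at_least
#' @return evenness percent in \[0, 100\].
#' @examples
#' evenness_score(rep(20, 100))        # 100
#' evenness_score(c(rep(2, 5), rep(0, 5)))  # 50
#' @export
evenness_score <- function(tracks) {
  depths <- if (is.list(tracks)) unlist(tracks, use.names = FALSE)
            else tracks
  if (length(depths) == 0L) stop("no depth tracks")
  m <- mean(depths)
  if (m <= 0) stop("all-zero depth: evenness undefined")
  cm <- ceiling(m)
  p <- vapply(seq_len(cm), function(i) mean(depths >= i), 0.0)
  100 * sum(p) / cm
}

#' Flag poorly covered targets
#'
#' @param per_target_median named numeric vector (or list) of median depth
#'   per `region_id`.
#' @param cfg [threshold_config()]; a target is poor when its median is
#'   below `cfg$poor_target_median_lt` (default 5).
#' @return sorted character vector of poor `region_id`s.
#' @export
flag_poor_targets <- function(per_target_median, cfg = threshold_config()) {
  med <- unlist(per_target_median)
  sort(names(med)[med < cfg$poor_target_median_lt])
}

#' Count bases mapped near (but not on) the targets
#'
#' Given read placements as intervals, counts the placed bases that fall
#' within `cfg$near_target_bp` of a target but outside every target.
#' Coordinates are 0-based half-open on both sides.
#'
#' @param placements data.frame `chrom`, `start`, `end` of read placements.
#' @param targets target data.frame (see [read_targets()]).
#' @param cfg [threshold_config()].
#' @return integer count of near-target bases.
#' @export
near_target_bases <- function(placements, targets,
                              cfg = threshold_config()) {
  if (!nrow(placements)) return(0L)
  total <- 0L
  for (ch in unique(placements$chrom)) {
    pl <- placements[placements$chrom == ch, , drop = FALSE]
    tg <- targets[targets$chrom == ch, , drop = FALSE]
    if (!nrow(tg)) next
    flank_s <- pmax(0L, tg$start - cfg$near_target_bp)
    flank_e <- tg$end + cfg$near_target_bp
    for (i in seq_len(nrow(pl))) {
      covered <- rep(FALSE, pl$end[i] - pl$start[i])
      base_pos <- seq.int(pl$start[i], pl$end[i] - 1L)
      near <- rep(FALSE, length(base_pos))
      for (j in seq_len(nrow(tg))) {
        near <- near | (base_pos >= flank_s[j] & base_pos < flank_e[j])
        covered <- covered | (base_pos >= tg$start[j] & base_pos < tg$end[j])
      }
      total <- total + sum(near & !covered)
    }
  }
  total
}

#' Per-sample coverage report
#'
#' Aggregates all coverage QC statistics for one sample: per-target median
#' depth, mean depth, fraction of bases at >= 10x, evenness score, poor
#' targets, and (when read placements are supplied) near-target bases.
#'
#' @param tracks named list of depth vectors, one per target.
#' @param cfg [threshold_config()].
#' @param placements optional read-placement data.frame for near-target
#'   accounting; without it the `near_target_bases` field is `NA` (depth
#'   tracks alone cannot see off-target bases).
#' @param targets optional target data.frame (required with `placements`).
#' @return list of class `rp_coverage_report` with fields
#'   `per_target_median`, `mean_coverage`, `frac_ge_10x`, `evenness`,
#'   `poor_targets`, `poor_fraction_pct`, `near_target_bases`.
#' @export
coverage_report <- function(tracks, cfg = threshold_config(),
                            placements = NULL, targets = NULL) {
  if (!length(tracks)) stop("no depth tracks")
  med <- vapply(tracks, target_median_coverage, 0.0)
  poor <- flag_poor_targets(med, cfg)
  rep <- list(
    per_target_median = med,
    mean_coverage = mean(unlist(tracks, use.names = FALSE)),
    frac_ge_10x = fraction_bases_at_least(tracks, 10),
    evenness = evenness_score(tracks),
    poor_targets = poor,
    poor_fraction_pct = round(100 * length(poor) / length(tracks), 1),
    near_target_bases = if (is.null(placements)) NA_integer_ else
      near_target_bases(placements, targets, cfg)
  )
  structure(rep, class = "rp_coverage_report")
}

#' @export
print.rp_coverage_report <- function(x, ...) {
  cat("Coverage report:", length(x$per_target_median), "targets\n")
  cat(sprintf("  mean coverage   : %.1fx\n", x$mean_coverage))
  cat(sprintf("  bases >= 10x    : %.1f%%\n", 100 * x$frac_ge_10x))
  cat(sprintf("  evenness score  : %.1f%%\n", x$evenness))
  cat(sprintf("  poor targets    : %d (%.1f%%)\n",
              length(x$poor_targets), x$poor_fraction_pct))
  invisible(x)
}

#' Write a coverage report as TSV (per-target) + JSON (summary)
#'
#' @param report `rp_coverage_report`.
#' @param tsv_path,json_path output paths.
#' @return invisibly, the two paths.
#' @export
write_coverage_report <- function(report, tsv_path, json_path) {
  df <- data.frame(region_id = names(report$per_target_median),
                   median_depth = unname(report$per_target_median),
                   poor = names(report$per_target_median) %in%
                     report$poor_targets)
  utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary <- report[c("mean_coverage", "frac_ge_10x", "evenness",
                      "poor_fraction_pct", "near_target_bases")]
  summary$n_targets <- length(report$per_target_median)
  summary$n_poor_targets <- length(report$poor_targets)
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(tsv = tsv_path, json = json_path))
}
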