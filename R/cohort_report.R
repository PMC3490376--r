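# Per-sample diagnosis calls and cohort-level diagnostic statistics.
#
# Rounding conventions are pinned per statistic to the reporting style of
# clinical gene-panel studies: integer percent for solved / confirmation
# rates and the projected yield, one decimal for detection and reduction,
# truncation at one decimal for the enrichment percentage (two decimals
# below 1%).

#' Mutation detection rate
#'
#' Percentage of known mutations recovered by the assay, to one decimal.
#'
#' @param n_detected,n_known counts, `0 <= n_detected <= n_known`,
#'   `n_known > 0`.
#' @return percent (one decimal).
#' @examples
#' detection_rate(21, 24)  # 87.5
#' @export
detection_rate <- function(n_detected, n_known) {
  if (n_known <= 0) stop("n_known must be positive")
  stopifnot(n_detected >= 0, n_detected <= n_known)
  round(100 * n_detected / n_known, 1)
}

#' Solved rate (diagnostic yield)
#'
#' Percentage of samples with a molecular diagnosis, as integer percent.
#'
#' @param n_solved,n_samples counts, `n_samples > 0`.
#' @return integer percent.
#' @examples
#' solved_rate(10, 12)   # 83
#' solved_rate(36, 100)  # 36
#' @export
solved_rate <- function(n_solved, n_samples) {
  if (n_samples <= 0) stop("n_samples must be positive")
  stopifnot(n_solved >= 0, n_solved <= n_samples)
  round(100 * n_solved / n_samples)
}

#' Reduction of candidate variants by the prioritization funnel
#'
#' @param n_before,n_after candidate counts before and after filtering,
#'   `n_before >= n_after >= 0`, `n_before > 0`.
#' @return percent reduction, one decimal.
#' @examples
#' reduction_percent(14144, 48)     # 99.7
#' reduction_percent(128557, 359)   # 99.7
#' @export
reduction_percent <- function(n_before, n_after) {
  if (n_before <= 0) stop("n_before must be positive")
  if (n_after > n_before) stop("n_after exceeds n_before")
  round(100 * (1 - n_after / n_before), 1)
}

#' Enrichment of true mutations among retained variants
#'
#' Share of retained variants that are disease-causing.  Reported
#' truncated (not rounded) at one decimal; values below 1% are reported
#' rounded to two decimals instead.
#'
#' @param n_true_retained,n_retained counts, `n_retained > 0`.
#' @return percent.
#' @examples
#' enrichment_percent(20, 48)      # 41.6
#' enrichment_percent(21, 14144)   # 0.15
#' @export
enrichment_percent <- function(n_true_retained, n_retained) {
  if (n_retained <= 0) stop("n_retained must be positive")
  stopifnot(n_true_retained >= 0, n_true_retained <= n_retained)
  pct <- 100 * n_true_retained / n_retained
  if (pct < 1) round(pct, 2) else floor(pct * 10) / 10
}

#' Projected diagnostic yield for a full referral cohort
#'
#' Extrapolates the yield of the assay over an entire cohort by combining
#' (a) previously solved cases rescreened at the validation solved rate,
#' (b) cases diagnosed by the assay itself, and (c) untested cases
#' projected at the assay's observed diagnosis rate.  Intermediate terms
#' are rounded to whole patients before summing, and the result is an
#' integer percent.
#'
#' @param n_prev_solved patients solved by earlier methods.
#' @param prev_rate fraction of those the assay would also solve (0--1).
#' @param n_ngs_solved patients diagnosed by the assay.
#' @param n_untested patients not yet run on the assay.
#' @param ngs_rate observed per-patient diagnosis rate of the assay (0--1).
#' @param n_total full cohort size.
#' @return integer percent.
#' @examples
#' projected_yield(57, 0.83, 36, 77, 0.36, 234)  # 47
#' @export
projected_yield <- function(n_prev_solved, prev_rate, n_ngs_solved,
                            n_untested, ngs_rate, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  stopifnot(prev_rate >= 0, prev_rate <= 1, ngs_rate >= 0, ngs_rate <= 1)
  solved <- round(n_prev_solved * prev_rate) + n_ngs_solved +
    round(n_untested * ngs_rate)
  round(100 * solved / n_total)
}

#' Call the molecular diagnosis for one sample
#'
#' A sample is solved when some gene carries pathogenic-tier
#' (`pathogenic` / `probably_pathogenic`) variants satisfying the allele
#' count of one of the gene's inheritance modes (AR: homozygous or two het
#' loci; AD: one het/hom; XL: hemizygous in males, biallelic in females)
#' and the family evidence does not contradict that mode.  Untested or
#' partial segregation still permits a diagnosis; a contradicted verdict
#' vetoes the gene.
#'
#' @param classified the sample's classified shortlist (columns of
#'   [classify_variants()] output).
#' @param panel validated gene panel.
#' @param sex `"male"`, `"female"` or `NA`.
#' @param segregation optional named list gene -> `rp_segregation` (or a
#'   status string) carrying the family evidence per candidate gene.
#' @return list of class `rp_diagnosis`: `sample_id`, `solved`, `gene`,
#'   `mode`, `variants` (the diagnostic rows), `segregation_status`,
#'   `de_novo`.
#' @export
diagnose_sample <- function(classified, panel, sex = NA,
                            segregation = NULL) {
  sample_id <- if (nrow(classified)) classified$sample_id[1] else
    NA_character_
  modes_by_gene <- panel_modes(panel)
  seg_status <- function(g) {
    s <- segregation[[g]]
    if (is.null(s)) "untested"
    else if (inherits(s, "rp_segregation")) s$status
    else as.character(s)
  }
  seg_de_novo <- function(g) {
    s <- segregation[[g]]
    inherits(s, "rp_segregation") && length(s$de_novo_loci) > 0
  }
  best <- NULL
  path <- classified[is_pathogenic_tier(classified$final_class), ,
                     drop = FALSE]
  for (g in unique(path$gene)) {
    if (seg_status(g) == "contradicted") next
    gv <- path[path$gene == g, , drop = FALSE]
    for (mode in modes_by_gene[[g]]) {
      ok <- switch(mode,
        AR = sum(gv$zygosity == "hom") >= 1L ||
          length(unique(variant_key(gv)[gv$zygosity == "het"])) >= 2L,
        AD = nrow(gv) >= 1L,
        XL = if (identical(sex, "male"))
          any(gv$zygosity %in% c("hemi", "hom"))
        else sum(gv$zygosity == "hom") >= 1L ||
          length(unique(variant_key(gv)[gv$zygosity == "het"])) >= 2L)
      if (ok && is.null(best)) {
        best <- list(gene = g, mode = mode, variants = gv)
      }
    }
  }
  if (is.null(best)) {
    structure(list(sample_id = sample_id, solved = FALSE,
                   gene = NA_character_, mode = NA_character_,
                   variants = classified[0, , drop = FALSE],
                   segregation_status = NA_character_, de_novo = FALSE),
              class = "rp_diagnosis")
  } else {
    structure(list(sample_id = sample_id, solved = TRUE,
                   gene = best$gene, mode = best$mode,
                   variants = best$variants,
                   segregation_status = seg_status(best$gene),
                   de_novo = seg_de_novo(best$gene)),
              class = "rp_diagnosis")
  }
}

#' Cohort-level summary statistics
#'
#' Aggregates per-sample funnels, diagnoses and Sanger-confirmation flags
#' into the cohort report: stage totals, detection / solved / reduction /
#' enrichment / confirmation rates, mean counts per sample and (when the
#' extrapolation inputs are supplied) the projected diagnostic yield.
#'
#' @param funnels list (or rbind-able set) of [funnel_counts()] rows, one
#'   per sample.
#' @param diagnoses list of `rp_diagnosis` objects, one per sample.
#' @param n_confirmed optional count of selected variants confirmed by
#'   Sanger resequencing (for the confirmation rate).
#' @param n_known,n_known_detected optional counts of planted/known
#'   mutations and those recovered (for the detection rate and
#'   enrichment).
#' @param projection optional named list with the [projected_yield()]
#'   arguments.
#' @return list of class `rp_cohort_summary`.
#' @export
summarize_cohort <- function(funnels, diagnoses, n_confirmed = NULL,
                             n_known = NULL, n_known_detected = NULL,
                             projection = NULL) {
  if (!length(funnels)) stop("empty cohort")
  fun <- do.call(rbind, lapply(funnels, as.data.frame))
  n_samples <- nrow(fun)
  totals <- as.list(colSums(fun))
  n_solved <- sum(vapply(diagnoses, function(d) isTRUE(d$solved), TRUE))
  out <- list(
    n_samples = n_samples,
    funnel_totals = totals,
    mean_auto_detected = round(totals$n_auto_detected / n_samples),
    mean_selected_per_sample = round(totals$n_selected / n_samples, 1),
    n_solved = n_solved,
    solved_rate = solved_rate(n_solved, n_samples),
    reduction = if (totals$n_auto_detected > 0)
      reduction_percent(totals$n_auto_detected, totals$n_selected) else
        NA_real_
  )
  if (!is.null(n_confirmed) && totals$n_selected > 0)
    out$confirmation_rate <- round(100 * n_confirmed / totals$n_selected)
  if (!is.null(n_known) && !is.null(n_known_detected)) {
    out$detection_rate <- detection_rate(n_known_detected, n_known)
    out$enrichment_before <- enrichment_percent(n_known,
                                                totals$n_auto_detected)
  }
  if (!is.null(projection))
    out$projected_yield <- do.call(projected_yield, projection)
  structure(out, class = "rp_cohort_summary")
}

#' @export
print.rp_cohort_summary <- function(x, ...) {
  cat("Cohort of", x$n_samples, "samples\n")
  cat(sprintf("  auto-detected (mean/sample): %d\n", x$mean_auto_detected))
  cat(sprintf("  selected for validation    : %d (mean %.1f/sample)\n",
              x$funnel_totals$n_selected, x$mean_selected_per_sample))
  cat(sprintf("  funnel reduction           : %.1f%%\n", x$reduction))
  cat(sprintf("  solved                     : %d (%d%%)\n",
              x$n_solved, x$solved_rate))
  if (!is.null(x$detection_rate))
    cat(sprintf("  mutation detection rate    : %.1f%%\n",
                x$detection_rate))
  if (!is.null(x$confirmation_rate))
    cat(sprintf("  Sanger confirmation rate   : %d%%\n",
                x$confirmation_rate))
  if (!is.null(x$projected_yield))
    cat(sprintf("  projected cohort yield     : %d%%\n",
                x$projected_yield))
  invisible(x)
}

#' Write the cohort summary and per-sample diagnoses
#'
#' Emits the summary as JSON and the diagnosis table as TSV (sample, gene,
#' mode, solved, segregation, de novo, the two diagnostic alleles).
#'
#' @param summary `rp_cohort_summary`.
#' @param diagnoses list of `rp_diagnosis`.
#' @param json_path,tsv_path output paths.
#' @return invisibly, the two paths.
#' @export
write_cohort_report <- function(summary, diagnoses, json_path, tsv_path) {
  jsonlite::write_json(unclass(summary), json_path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  rows <- lapply(diagnoses, function(d) {
    vk <- if (nrow(d$variants)) variant_key(d$variants) else character()
    data.frame(sample_id = d$sample_id, solved = d$solved,
               gene = d$gene, mode = d$mode,
               segregation = d$segregation_status, de_novo = d$de_novo,
               m1 = if (length(vk) >= 1) vk[1] else NA_character_,
               m2 = if (length(vk) >= 2) vk[2] else NA_character_,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), tsv_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(json = json_path, tsv = tsv_path))
}
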