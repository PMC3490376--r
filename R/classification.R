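# Three-axis rule-based pathogenicity classification.
#
# Axis 1: in silico tool evidence -- a majority vote over three missense
#         tools (SIFT / PolyPhen / MutPred class calls) or three splice
#         tools (SpliceSiteFinder, MaxEntScan, NNSplice wt/mut scores).
# Axis 2: evolutionary conservation (PhyloP, 44-way).
# Axis 3: population frequency in a reference exome cohort and in the
#         disease panel cohort.
# Truncating and canonical splice site variants bypass the axes and are
# pathogenic outright; for the rest the axes are combined with a
# frequency-benign override and a majority vote.

#' Majority vote over three three-state calls
#'
#' @param calls character vector of exactly three values among
#'   `pathogenic`, `unknown`, `benign`.
#' @return the class with at least two votes; `"unknown"` when all three
#'   differ.
#' @examples
#' vote(c("pathogenic", "pathogenic", "benign"))  # pathogenic
#' vote(c("pathogenic", "unknown", "benign"))     # unknown
#' @export
vote <- function(calls) {
  if (length(calls) != 3L) stop("vote expects exactly three calls")
  bad <- setdiff(calls, TRI_LEVELS)
  if (length(bad)) stop("unknown class: ", bad[1])
  tab <- table(factor(calls, levels = TRI_LEVELS))
  if (max(tab) >= 2L) names(tab)[which.max(tab)] else "unknown"
}

#' SpliceSiteFinder score classification
#'
#' Site scores run 0--100.  A wild-type score above 50 dropping below 50
#' in the mutant is pathogenic; otherwise a wt - mut difference greater
#' than 5 is unknown; otherwise benign.
#'
#' @param wt,mut wild-type and mutant site scores.
#' @param cfg [threshold_config()].
#' @return `"pathogenic"`, `"unknown"` or `"benign"` (vectorised).
#' @export
classify_ssf <- function(wt, mut, cfg = threshold_config()) {
  stopifnot(all(is.finite(wt)), all(is.finite(mut)))
  ifelse(wt > cfg$ssf_site & mut < cfg$ssf_site, "pathogenic",
         ifelse(wt - mut > cfg$ssf_diff, "unknown", "benign"))
}

#' MaxEntScan score classification
#'
#' A wt - mut difference greater than 0.8 is pathogenic; identical scores
#' are benign; any other (nonzero, <= 0.8) difference is unknown.  The
#' difference is directional (loss of splice-site strength): a score gain
#' never classifies pathogenic.
#'
#' @inheritParams classify_ssf
#' @return three-state class (vectorised).
#' @export
classify_maxent <- function(wt, mut, cfg = threshold_config()) {
  stopifnot(all(is.finite(wt)), all(is.finite(mut)))
  ifelse(wt - mut > cfg$maxent_diff, "pathogenic",
         ifelse(wt == mut, "benign", "unknown"))
}

#' NNSplice score classification
#'
#' Scores are probabilities in \[0, 1\].  wt above 0.5 with mut below 0.5
#' is pathogenic; otherwise a wt - mut difference greater than 0.05 is
#' unknown; otherwise benign.
#'
#' @inheritParams classify_ssf
#' @return three-state class (vectorised).
#' @export
classify_nnsplice <- function(wt, mut, cfg = threshold_config()) {
  if (any(wt < 0 | wt > 1 | mut < 0 | mut > 1))
    stop("NNSplice scores must lie in [0, 1]")
  ifelse(wt > cfg$nnsplice_site & mut < cfg$nnsplice_site, "pathogenic",
         ifelse(wt - mut > cfg$nnsplice_diff, "unknown", "benign"))
}

#' Conservation classification from PhyloP
#'
#' PhyloP (44 vertebrate species) below 1 is benign, above 2.5 pathogenic,
#' intermediate values (boundaries included) unknown.
#'
#' @param phylop conservation score(s).
#' @param cfg [threshold_config()].
#' @return three-state class (vectorised).
#' @export
classify_conservation <- function(phylop, cfg = threshold_config()) {
  stopifnot(all(is.finite(phylop)))
  ifelse(phylop < cfg$phylop_benign_lt, "benign",
         ifelse(phylop > cfg$phylop_patho_gt, "pathogenic", "unknown"))
}

#' Frequency classification from the two cohorts
#'
#' Exome-cohort frequency above 3% is benign; an exome frequency between
#' 1% and 3% (inclusive) or a disease-cohort frequency of 3% or more is
#' unknown; the remaining (rare) variants are pathogenic on this axis.
#'
#' @param exome_freq,disease_cohort_freq allele frequencies in \[0, 1\].
#' @param cfg [threshold_config()].
#' @return three-state class (vectorised).
#' @export
classify_frequency <- function(exome_freq, disease_cohort_freq,
                               cfg = threshold_config()) {
  ef <- ifelse(is.na(exome_freq), 0, exome_freq)
  cf <- ifelse(is.na(disease_cohort_freq), 0, disease_cohort_freq)
  if (any(ef < 0 | ef > 1 | cf < 0 | cf > 1))
    stop("frequencies must lie in [0, 1]")
  ifelse(ef > cfg$freq_benign_gt, "benign",
         ifelse((ef >= cfg$freq_unknown_lo & ef <= cfg$freq_unknown_hi) |
                  cf >= cfg$cohort_unknown_ge,
                "unknown", "pathogenic"))
}

#' Combine the three classification axes into the final verdict
#'
#' If the frequency axis is benign the final classification is
#' `probably_benign` regardless of the other axes.  Otherwise the three
#' axes are combined by majority vote; a three-way split is `unknown`.
#' Majority pathogenic maps to `probably_pathogenic` (the plain
#' `pathogenic` verdict is reserved for truncating and canonical splice
#' variants), majority benign to `probably_benign`.
#'
#' @param insilico,conservation,frequency three-state axis calls
#'   (vectorised).
#' @return final class: `probably_pathogenic`, `unknown` or
#'   `probably_benign`.
#' @export
combine_classes <- function(insilico, conservation, frequency) {
  n <- length(insilico)
  stopifnot(length(conservation) == n, length(frequency) == n)
  out <- character(n)
  for (i in seq_len(n)) {
    if (frequency[i] == "benign") {
      out[i] <- "probably_benign"
    } else {
      v <- vote(c(insilico[i], conservation[i], frequency[i]))
      out[i] <- c(pathogenic = "probably_pathogenic",
                  benign = "probably_benign",
                  unknown = "unknown")[v]
    }
  }
  unname(out)
}

#' The 27-row axis combination table
#'
#' Enumerates every (in silico, conservation, frequency) triple with the
#' final verdict from [combine_classes()]; useful for audit.
#'
#' @return data.frame with columns `insilico`, `conservation`, `frequency`,
#'   `final`.
#' @export
combination_truth_table <- function() {
  grid <- expand.grid(insilico = TRI_LEVELS, conservation = TRI_LEVELS,
                      frequency = TRI_LEVELS, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid$final <- combine_classes(grid$insilico, grid$conservation,
                                grid$frequency)
  grid
}

# in silico axis for one variant row; emits a warning for a missense
# variant carrying no tool calls (axis falls back to "unknown")
insilico_axis <- function(v, cfg) {
  has_splice <- !is.na(v$ssf_wt) && !is.na(v$maxent_wt) &&
    !is.na(v$nnsplice_wt)
  has_missense <- !is.na(v$sift) && !is.na(v$polyphen) && !is.na(v$mutpred)
  if (v$effect == "missense" || has_missense) {
    if (!has_missense) {
      warning("missense variant without tool calls at ",
              variant_key(v), "; in silico axis set to unknown")
      return("unknown")
    }
    return(vote(c(v$sift, v$polyphen, v$mutpred)))
  }
  if (has_splice) {
    return(vote(c(classify_ssf(v$ssf_wt, v$ssf_mut, cfg),
                  classify_maxent(v$maxent_wt, v$maxent_mut, cfg),
                  classify_nnsplice(v$nnsplice_wt, v$nnsplice_mut, cfg))))
  }
  "unknown"
}

#' Classify annotated variants
#'
#' Applies the full classification scheme to each row of an annotated
#' variant table.  Nonsense, frameshift, canonical splice site and large
#' deletion variants are pathogenic outright.  Missense (and in-frame
#' indel) variants take the in silico axis from the missense tool vote;
#' noncanonical splice variants from the splice tool vote; the axis calls
#' are then combined with conservation and frequency via
#' [combine_classes()].
#'
#' @param variants annotated variant data.frame.
#' @param cfg [threshold_config()].
#' @return `variants` with four added columns: `axis_insilico`,
#'   `axis_conservation`, `axis_frequency`, `final_class`.
#' @export
classify_variants <- function(variants, cfg = threshold_config()) {
  n <- nrow(variants)
  ins <- cons <- freq <- final <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    v <- variants[i, , drop = FALSE]
    if (v$effect %in% TRUNCATING_EFFECTS) {
      final[i] <- "pathogenic"
      next
    }
    ins[i] <- insilico_axis(v, cfg)
    cons[i] <- classify_conservation(v$phylop, cfg)
    freq[i] <- classify_frequency(v$exome_freq, v$cohort_freq, cfg)
    final[i] <- combine_classes(ins[i], cons[i], freq[i])
  }
  variants$axis_insilico <- ins
  variants$axis_conservation <- cons
  variants$axis_frequency <- freq
  variants$final_class <- final
  variants
}

#' Is a final class in the pathogenic tier?
#'
#' @param final_class vector of final verdicts.
#' @return logical: TRUE for `pathogenic` and `probably_pathogenic`.
#' @export
is_pathogenic_tier <- function(final_class) {
  final_class %in% c("pathogenic", "probably_pathogenic")
}
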