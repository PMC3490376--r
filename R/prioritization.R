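# High-quality variant designation and the six-criterion prioritization
# cascade with second-allele rescue.
#
# Filters 1-5 are pure, vectorised predicates over the annotated variant
# table; criterion 6 (inheritance consistency) acts per gene per sample,
# and the rescue step may re-introduce variants for recessive genes that
# retained a single strong (truncating) allele.

#' High-quality call designation
#'
#' A called difference is high quality when either (1) it is supported by
#' at least three nonduplicate reads including at least one forward and one
#' reverse read, or (2) it is seen in at least five reads with base quality
#' scores greater than 20.  Variants failing this designation never enter
#' the prioritization cascade.
#'
#' @param support data.frame with columns `nondup_variant_reads`,
#'   `fwd_variant_reads`, `rev_variant_reads`, `hq_variant_reads` (a full
#'   annotated variant table works).
#' @param cfg [threshold_config()].
#' @return logical vector, one element per row.
#' @examples
#' is_high_quality(data.frame(nondup_variant_reads = 3,
#'   fwd_variant_reads = 2, rev_variant_reads = 1, hq_variant_reads = 0))
#' @export
is_high_quality <- function(support, cfg = threshold_config()) {
  rule1 <- support$nondup_variant_reads >= cfg$hq_rule1_reads &
    support$fwd_variant_reads >= 1L & support$rev_variant_reads >= 1L
  rule2 <- support$hq_variant_reads >= cfg$hq_rule2_reads
  rule1 | rule2
}

#' Criterion 1: effect-class filter
#'
#' Keeps protein-changing and splice-relevant variants: missense, nonsense,
#' frameshift, in-frame indels, canonical splice sites and large deletions
#' always pass; `splice_region`/`intronic` variants pass only when they lie
#' within 8 bp of a splice acceptor or 20 bp of a splice donor (offsets are
#' signed distances on the intronic side); synonymous, UTR and deeper
#' intronic variants fail.
#'
#' @param variants annotated variant data.frame (`effect`,
#'   `acceptor_offset`, `donor_offset`).
#' @param cfg [threshold_config()].
#' @return logical vector.
#' @export
passes_effect_filter <- function(variants, cfg = threshold_config()) {
  eff <- variants$effect
  always <- eff %in% c("missense", "nonsense", "frameshift",
                       "inframe_indel", "canonical_splice",
                       "large_deletion")
  splicey <- eff %in% c("splice_region", "intronic")
  acc <- variants$acceptor_offset
  don <- variants$donor_offset
  no_offset <- is.na(acc) & is.na(don)
  if (any(eff == "splice_region" & no_offset))
    stop("splice_region variant without splice offsets at ",
         variant_key(variants)[eff == "splice_region" & no_offset][1])
  in_window <- (!is.na(acc) & abs(acc) <= cfg$splice_acceptor_window) |
               (!is.na(don) & abs(don) <= cfg$splice_donor_window)
  always | (splicey & in_window)
}

#' Criterion 2: novelty filter
#'
#' Excludes variants catalogued in dbSNP130 unless they are reported in
#' HGMD or previously defined as a pathogenic blindness mutation.
#'
#' @param variants data.frame with logical columns `in_dbsnp130`,
#'   `in_hgmd`, `known_blindness` (NA reads as FALSE).
#' @return logical vector.
#' @export
passes_novelty_filter <- function(variants) {
  dbsnp <- variants$in_dbsnp130 %in% TRUE
  hgmd <- variants$in_hgmd %in% TRUE
  known <- variants$known_blindness %in% TRUE
  !dbsnp | hgmd | known
}

#' Criteria 3 and 4: cohort frequency filters
#'
#' Excludes variants with a frequency greater than 5% in the reference
#' exome cohort or more than 15% within the disease panel cohort.  Both
#' bounds are strict, so boundary frequencies pass.  Missing frequencies
#' (e.g., large deletions absent from the frequency databases) read as 0.
#'
#' @param variants data.frame with `exome_freq`, `cohort_freq`.
#' @param cfg [threshold_config()].
#' @return logical vector.
#' @export
passes_frequency_filters <- function(variants, cfg = threshold_config()) {
  ef <- ifelse(is.na(variants$exome_freq), 0, variants$exome_freq)
  cf <- ifelse(is.na(variants$cohort_freq), 0, variants$cohort_freq)
  ef <= cfg$exome_filter_max & cf <= cfg$cohort_filter_max
}

#' Criterion 5: read-support filter
#'
#' Requires coverage by at least 10 reads with at least 20% variant reads,
#' or at least 5 reads with 80--100% variant reads.  Both branches read
#' "reads" as total site depth with a variant-read fraction.  Zero total
#' depth fails without division.
#'
#' @param support data.frame with `total_reads`, `variant_reads`.
#' @param cfg [threshold_config()].
#' @return logical vector.
#' @export
passes_support_filter <- function(support, cfg = threshold_config()) {
  tot <- support$total_reads
  frac <- ifelse(tot > 0, support$variant_reads / tot, 0)
  (tot >= cfg$support_reads_a & frac >= cfg$support_frac_a) |
    (tot >= cfg$support_reads_b & frac >= cfg$support_frac_b_lo)
}

#' Criterion 6: inheritance-consistency filter for one gene
#'
#' Given all of one sample's variants in a single gene that already passed
#' criteria 1--5, keeps those compatible with at least one of the gene's
#' inheritance modes:
#' \describe{
#'   \item{AR}{the gene qualifies with a homozygous variant or with two or
#'     more distinct heterozygous loci (putative compound heterozygote,
#'     phase unknown at this stage); a qualifying gene keeps all its
#'     variants, a single het does not qualify.}
#'   \item{AD}{any het or hom variant qualifies on its own.}
#'   \item{XL}{males keep hemizygous (or hom-called) X variants; females
#'     qualify like AR (hom or >= 2 het).}
#' }
#' Genes carrying several modes keep the union of the per-mode survivors.
#'
#' @param variants one gene's variants for one sample.
#' @param modes character vector, nonempty subset of AR/AD/XL.
#' @param sex `"male"`, `"female"` or `NA`; with unknown sex the XL rule
#'   accepts either qualification.
#' @return the surviving subset of `variants` (possibly empty).
#' @export
passes_inheritance_filter <- function(variants, modes, sex = NA) {
  if (!nrow(variants)) return(variants)
  if (length(unique(variants$gene)) > 1L)
    stop("inheritance filter expects variants of a single gene")
  bad <- setdiff(modes, MODE_TOKENS)
  if (length(bad)) stop("unknown inheritance mode: ", bad[1])
  zyg <- variants$zygosity
  n_hom <- sum(zyg == "hom")
  n_het_loci <- length(unique(variant_key(variants)[zyg == "het"]))
  keep <- rep(FALSE, nrow(variants))
  biallelic <- n_hom >= 1L || n_het_loci >= 2L
  hemi_ok <- zyg %in% c("hemi", "hom")
  for (mode in modes) {
    keep <- keep | switch(
      mode,
      AR = rep(biallelic, nrow(variants)),
      AD = zyg %in% c("het", "hom", "hemi"),
      XL = if (identical(sex, "male")) hemi_ok
           else if (identical(sex, "female")) rep(biallelic, nrow(variants))
           else hemi_ok | rep(biallelic, nrow(variants))
    )
  }
  variants[keep, , drop = FALSE]
}

#' Effects accepted as a strong single candidate allele for rescue
#' @keywords internal
RESCUE_ANCHOR_EFFECTS <- c("nonsense", "canonical_splice")

#' Second-allele rescue for recessive genes
#'
#' When criteria 1--5 leave a single strong candidate allele — a
#' heterozygous nonsense or canonical splice site variant — in a gene that
#' can act recessively, a search for a second variant allele is performed
#' in the unfiltered variant set.  The search relaxes the novelty and
#' frequency criteria (a true second allele may be a catalogued or locally
#' frequent variant) but retains the effect and read-support criteria so
#' that sequencing noise is not rescued.
#'
#' @param survivors the gene's variants that passed criteria 1--5.
#' @param unfiltered all of the sample's high-quality variants in the same
#'   gene (the pre-filter set).
#' @param modes the gene's inheritance modes.
#' @param cfg [threshold_config()].
#' @return data.frame of rescued second-allele candidates (with a logical
#'   `rescued` column set to TRUE), empty when the preconditions do not
#'   hold or no candidate is found.
#' @export
rescue_second_allele <- function(survivors, unfiltered, modes,
                                 cfg = threshold_config()) {
  empty <- unfiltered[0, , drop = FALSE]
  if (!("AR" %in% modes)) return(empty)
  if (nrow(survivors) != 1L) return(empty)
  if (survivors$zygosity != "het") return(empty)
  if (!survivors$effect %in% RESCUE_ANCHOR_EFFECTS) return(empty)
  pool <- unfiltered[!variant_key(unfiltered) %in% variant_key(survivors), ,
                     drop = FALSE]
  if (!nrow(pool)) return(empty)
  keep <- passes_effect_filter(pool, cfg) & passes_support_filter(pool, cfg)
  out <- pool[keep, , drop = FALSE]
  if (nrow(out)) out$rescued <- TRUE
  out
}

#' Funnel counts constructor
#'
#' Per-stage candidate counts for one sample: automatically detected
#' (high-quality) variants, survivors of the effect/novelty/frequency/
#' support criteria, survivors of the inheritance criterion, the count
#' after second-allele rescue, and the final selected count.
#'
#' @param n_auto_detected,n_after_effect_novelty_frequency,
#'   n_after_inheritance,n_after_rescue,n_selected stage counts.
#' @return one-row data.frame of class `rp_funnel`.
#' @export
funnel_counts <- function(n_auto_detected,
                          n_after_effect_novelty_frequency,
                          n_after_inheritance, n_after_rescue, n_selected) {
  stopifnot(n_after_effect_novelty_frequency <= n_auto_detected,
            n_after_inheritance <= n_after_effect_novelty_frequency,
            n_after_rescue >= n_after_inheritance,
            n_selected <= n_after_rescue)
  structure(
    data.frame(n_auto_detected = as.integer(n_auto_detected),
               n_after_effect_novelty_frequency =
                 as.integer(n_after_effect_novelty_frequency),
               n_after_inheritance = as.integer(n_after_inheritance),
               n_after_rescue = as.integer(n_after_rescue),
               n_selected = as.integer(n_selected)),
    class = c("rp_funnel", "data.frame"))
}

#' Prioritize one sample's variants
#'
#' Runs the complete cascade: high-quality designation, criteria 1--5
#' (effect, novelty, exome frequency, cohort frequency, read support),
#' per-gene inheritance consistency, then second-allele rescue for
#' recessive genes left with a single strong truncating allele.  The
#' shortlist is deterministic, sorted by gene and locus.
#'
#' @param variants one sample's annotated variant data.frame.
#' @param panel validated gene panel (see [read_panel()]); variants in
#'   genes absent from the panel are an error.
#' @param sex `"male"`, `"female"` or `NA`.  An unknown sex (e.g., the
#'   sample is absent from the pedigree) triggers a warning and applies the
#'   permissive mode-union inheritance rule.
#' @param cfg [threshold_config()].
#' @return list with `shortlist` (surviving variants, extra logical column
#'   `rescued`) and `funnel` ([funnel_counts()]).
#' @export
prioritize_sample <- function(variants, panel, sex = NA,
                              cfg = threshold_config()) {
  modes_by_gene <- panel_modes(panel)
  if (nrow(variants)) {
    unknown <- setdiff(unique(variants$gene), names(modes_by_gene))
    if (length(unknown))
      stop("variant in gene absent from panel: ", unknown[1])
  }
  if (is.na(sex) && nrow(variants))
    warning("sample sex unknown; applying mode-union inheritance rule")

  hq <- variants[is_high_quality(variants, cfg), , drop = FALSE]
  n_auto <- nrow(hq)

  if (n_auto) {
    p15 <- passes_effect_filter(hq, cfg) &
      passes_novelty_filter(hq) &
      passes_frequency_filters(hq, cfg) &
      passes_support_filter(hq, cfg)
  } else p15 <- logical()
  filtered <- hq[p15, , drop = FALSE]
  n_15 <- nrow(filtered)

  kept <- list(); rescued <- list()
  for (g in unique(filtered$gene)) {
    gv <- filtered[filtered$gene == g, , drop = FALSE]
    modes <- modes_by_gene[[g]]
    surv <- passes_inheritance_filter(gv, modes, sex)
    if (nrow(surv)) kept[[g]] <- surv
    # rescue: single strong het allele in an AR-capable gene
    add <- rescue_second_allele(gv, hq[hq$gene == g, , drop = FALSE],
                                modes, cfg)
    if (nrow(add)) {
      anchor <- gv
      anchor$rescued <- FALSE
      already <- if (nrow(surv)) variant_key(surv) else character()
      anchor <- anchor[!variant_key(anchor) %in% already, , drop = FALSE]
      rescued[[g]] <- rbind(anchor, add)
    }
  }
  bindup <- function(lst, template) {
    if (length(lst)) do.call(rbind, unname(lst)) else
      template[0, , drop = FALSE]
  }
  kept_df <- bindup(kept, filtered)
  if (nrow(kept_df)) kept_df$rescued <- FALSE else
    kept_df$rescued <- logical(0)
  resc_tmpl <- kept_df
  resc_df <- bindup(rescued, resc_tmpl)
  gkey <- function(df) paste(df$gene, variant_key(df))
  resc_df <- resc_df[!gkey(resc_df) %in% gkey(kept_df), , drop = FALSE]
  n_inherit <- nrow(kept_df)
  shortlist <- rbind(kept_df, resc_df)
  n_rescue <- nrow(shortlist)
  shortlist <- shortlist[order(shortlist$gene, shortlist$chrom,
                               shortlist$pos, shortlist$ref,
                               shortlist$alt), , drop = FALSE]
  rownames(shortlist) <- NULL
  list(shortlist = shortlist,
       funnel = funnel_counts(n_auto, n_15, n_inherit, n_rescue, n_rescue))
}
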