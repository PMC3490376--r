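# End-to-end cohort analysis: prioritize -> classify -> segregate ->
# diagnose -> summarize, over an in-memory cohort object (either freshly
# simulated or loaded back from disk).

#' Load a cohort from a directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return `rp_cohort`-shaped list (without truth when `truth.json` is
#'   absent).
#' @export
load_cohort <- function(dir) {
  panel <- read_panel(file.path(dir, "panel.tsv"))
  targets <- read_targets(file.path(dir, "targets.bed"))
  ped <- read_pedigree(file.path(dir, "cohort.ped"))
  rg_path <- file.path(dir, "relative_genotypes.tsv")
  mk_path <- file.path(dir, "markers.tsv")
  vcfs <- list.files(file.path(dir, "samples"), pattern = "\\.vcf$",
                     full.names = TRUE)
  variants <- do.call(rbind, lapply(vcfs, function(p) {
    sid <- sub("\\.vcf$", "", basename(p))
    read_variants(p,
                  file.path(dirname(p), paste0(sid, "_support.tsv")),
                  file.path(dirname(p), paste0(sid, "_annot.tsv")),
                  sample_id = sid)
  }))
  depth_files <- list.files(dir, pattern = "^depth_.*\\.tsv$",
                            full.names = TRUE)
  depth <- stats::setNames(
    lapply(depth_files, read_depth),
    sub("^depth_(.*)\\.tsv$", "\\1", basename(depth_files)))
  sexes <- stats::setNames(ped$sex, ped$individual_id)
  structure(list(
    panel = panel, targets = targets, pedigree = ped,
    variants = variants,
    relative_genotypes = if (file.exists(rg_path))
      read_relative_genotypes(rg_path) else NULL,
    markers = if (file.exists(mk_path)) read_markers(mk_path) else NULL,
    depth = depth,
    sexes = sexes[unique(variants$sample_id)]
  ), class = "rp_cohort")
}

# genotype table for one gene's candidate loci across one family,
# assembled from the proband call set and the relative genotype table
candidate_genotypes <- function(variants_gene, relative_genotypes,
                                family_id, proband_id) {
  loci <- variant_key(variants_gene)
  pro_gt <- c(het = "het", hom = "hom_alt", hemi = "hemi_alt")[
    variants_gene$zygosity]
  out <- data.frame(individual_id = proband_id, locus = loci, gt = pro_gt,
                    stringsAsFactors = FALSE)
  if (!is.null(relative_genotypes)) {
    rg <- relative_genotypes[relative_genotypes$family_id == family_id, ,
                             drop = FALSE]
    if (nrow(rg)) {
      rg_locus <- paste(rg$chrom, rg$pos, rg$ref, rg$alt, sep = ":")
      keep <- rg_locus %in% loci
      if (any(keep))
        out <- rbind(out, data.frame(individual_id = rg$individual_id[keep],
                                     locus = rg_locus[keep],
                                     gt = rg$gt[keep],
                                     stringsAsFactors = FALSE))
    }
  }
  out
}

# pick the inheritance mode under which this gene's pathogenic-tier
# variants satisfy the allele count, if any
satisfied_mode <- function(gv, modes, sex) {
  n_hom <- sum(gv$zygosity == "hom")
  n_het <- length(unique(variant_key(gv)[gv$zygosity == "het"]))
  biallelic <- n_hom >= 1L || n_het >= 2L
  for (mode in modes) {
    ok <- switch(mode,
      AR = biallelic,
      AD = nrow(gv) >= 1L,
      XL = if (identical(sex, "male"))
        any(gv$zygosity %in% c("hemi", "hom")) else biallelic)
    if (ok) return(mode)
  }
  NA_character_
}

#' Analyse one sample end to end
#'
#' Prioritizes the sample's variants, classifies the shortlist, runs
#' segregation (and de novo marker confirmation where marker data exist)
#' for each candidate gene, and calls the diagnosis.
#'
#' @param variants the sample's annotated variants.
#' @param cohort `rp_cohort` (supplies panel, pedigree, relative
#'   genotypes, markers).
#' @param cfg [threshold_config()].
#' @return list with `shortlist` (classified), `funnel`, `segregation`
#'   (per gene), `diagnosis`.
#' @export
analyze_sample <- function(variants, cohort, cfg = threshold_config()) {
  sid <- if (nrow(variants)) variants$sample_id[1] else NA_character_
  ped <- cohort$pedigree
  in_ped <- !is.na(sid) && sid %in% ped$individual_id
  sex <- if (in_ped) ped$sex[match(sid, ped$individual_id)] else NA
  pri <- prioritize_sample(variants, cohort$panel, sex, cfg)
  shortlist <- classify_variants(pri$shortlist, cfg)

  segregation <- list()
  if (in_ped && nrow(shortlist)) {
    fam_id <- ped$family_id[match(sid, ped$individual_id)]
    family <- ped[ped$family_id == fam_id, , drop = FALSE]
    modes_by_gene <- panel_modes(cohort$panel)
    path <- shortlist[is_pathogenic_tier(shortlist$final_class), ,
                      drop = FALSE]
    for (g in unique(path$gene)) {
      gv <- path[path$gene == g, , drop = FALSE]
      mode <- satisfied_mode(gv, modes_by_gene[[g]], sex)
      if (is.na(mode)) next
      gts <- candidate_genotypes(gv, cohort$relative_genotypes, fam_id, sid)
      seg <- check_segregation(gts, family, mode, sid,
                               gene_modes = modes_by_gene[[g]])
      # marker-based paternity confirmation for apparent de novo events
      if (length(seg$de_novo_loci) && !is.null(cohort$markers)) {
        mk <- cohort$markers[cohort$markers$family_id == fam_id, ,
                             drop = FALSE]
        pro <- family[family$individual_id == sid, , drop = FALSE]
        if (nrow(mk) && !is.na(pro$father_id) && !is.na(pro$mother_id)) {
          by_ind <- split(mk, mk$individual_id)
          if (all(c(sid, pro$father_id, pro$mother_id) %in%
                    names(by_ind))) {
            mc <- mendelian_consistency(by_ind[[sid]],
                                        by_ind[[pro$father_id]],
                                        by_ind[[pro$mother_id]])
            seg$notes <- c(seg$notes, sprintf(
              "markers %d/%d consistent: de novo %s",
              mc$consistent_count, mc$total,
              if (mc$confirmed) "confirmed" else "not confirmed"))
            if (!mc$confirmed) seg$de_novo_loci <- character()
          }
        }
      }
      segregation[[g]] <- seg
    }
  }
  diagnosis <- diagnose_sample(shortlist, cohort$panel, sex, segregation)
  if (!is.na(sid)) diagnosis$sample_id <- sid
  list(shortlist = shortlist, funnel = pri$funnel,
       segregation = segregation, diagnosis = diagnosis)
}

#' Analyse a whole cohort
#'
#' Runs [analyze_sample()] for every sample and aggregates the cohort
#' summary.  Sanger-confirmation accounting uses the truth record's
#' failed-confirmation keys when the cohort carries one (synthetic
#' cohorts); otherwise the confirmation rate is omitted.
#'
#' @param cohort `rp_cohort`.
#' @param cfg [threshold_config()].
#' @param sample_ids subset of samples to analyse (default: all).
#' @return list with `per_sample` (named list of [analyze_sample()]
#'   results) and `summary` ([summarize_cohort()]).
#' @export
run_pipeline <- function(cohort, cfg = threshold_config(),
                         sample_ids = NULL) {
  ids <- unique(cohort$variants$sample_id)
  if (!is.null(sample_ids)) ids <- intersect(ids, sample_ids)
  per_sample <- lapply(ids, function(sid) {
    analyze_sample(
      cohort$variants[cohort$variants$sample_id == sid, , drop = FALSE],
      cohort, cfg)
  })
  names(per_sample) <- ids
  funnels <- lapply(per_sample, `[[`, "funnel")
  diagnoses <- lapply(per_sample, `[[`, "diagnosis")

  # Sanger accounting: truth stores sample-qualified keys of background
  # calls that would fail confirmation
  n_confirmed <- NULL
  fails <- cohort$truth$sanger_fail_keys
  if (!is.null(fails)) {
    selected_keys <- unlist(lapply(ids, function(sid) {
      sl <- per_sample[[sid]]$shortlist
      if (nrow(sl)) paste(sid, variant_key(sl)) else character()
    }), use.names = FALSE)
    n_confirmed <- sum(!selected_keys %in% fails)
  }
  list(per_sample = per_sample,
       summary = summarize_cohort(funnels, diagnoses,
                                  n_confirmed = n_confirmed))
}
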