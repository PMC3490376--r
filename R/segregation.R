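# Family-level evidence: co-segregation with affection status, de novo
# detection, marker-based Mendelian consistency (paternity testing),
# trans-phase checks for compound heterozygotes and multilocus flagging.
#
# Genotype codes follow the relative-genotype table: ref_ref, het,
# hom_alt, hemi_alt, missing.

GT_CODES <- c("ref_ref", "het", "hom_alt", "hemi_alt", "missing")

carries_allele <- function(gt) gt %in% c("het", "hom_alt", "hemi_alt")
gt_known <- function(gt) !is.na(gt) & gt != "missing"

# does this individual's genotype set over the candidate loci amount to a
# biallelic (both-alleles) state? one locus: hom/hemi; two or more loci:
# carrying the allele at every locus (unphased compound het)
carries_both <- function(gts) {
  if (length(gts) == 1L) gts %in% c("hom_alt", "hemi_alt")
  else all(carries_allele(gts))
}

#' Co-segregation of candidate genotypes with affection status
#'
#' Tests whether the proband's candidate genotype(s) track with disease
#' through the family under a fixed inheritance mode:
#' \describe{
#'   \item{AR}{every affected member must carry both alleles (homozygous,
#'     or het at both loci of a compound-het pair); no unaffected member
#'     may carry both.}
#'   \item{AD}{every affected member carries the variant; every unaffected
#'     member is reference.}
#'   \item{XL}{affected males are hemizygous; unaffected males reference;
#'     females may carry one allele unaffected (transmitting carriers) but
#'     an unaffected female must not carry both and an affected female
#'     must.}
#' }
#' Any violation by a typed member yields `contradicted`.  With no typed
#' relatives the verdict is `untested`; with every relative typed and
#' consistent (and at least one informative relative) it is `full`,
#' otherwise `partial`.  Loci at which both parents are typed reference
#' while the proband carries the allele are reported as `de_novo_loci`.
#'
#' @param genotypes data.frame with columns `individual_id`, `locus`
#'   (any stable locus key) and `gt` (codes `ref_ref`, `het`, `hom_alt`,
#'   `hemi_alt`, `missing`) covering the candidate locus or compound-het
#'   pair.
#' @param family one family's pedigree rows (see [read_pedigree()]).
#' @param mode `"AR"`, `"AD"` or `"XL"`.
#' @param proband_id individual id of the index patient.
#' @param gene_modes optional: the gene's panel modes; an error is raised
#'   when `mode` is not among them.
#' @return list of class `rp_segregation` with `status` (`full`,
#'   `partial`, `contradicted`, `untested`), `de_novo_loci`, `notes`.
#' @export
check_segregation <- function(genotypes, family, mode, proband_id,
                              gene_modes = NULL) {
  stopifnot(mode %in% MODE_TOKENS)
  if (!is.null(gene_modes) && !(mode %in% gene_modes))
    stop("mode ", mode, " incompatible with the gene's panel modes (",
         paste(gene_modes, collapse = ","), ")")
  loci <- unique(genotypes$locus)
  if (!length(loci)) stop("no candidate loci supplied")
  pro <- genotypes[genotypes$individual_id == proband_id, , drop = FALSE]
  if (!all(loci %in% pro$locus[gt_known(pro$gt)]))
    stop("proband must be genotyped at every candidate locus")

  member_gts <- function(id) {
    g <- genotypes[genotypes$individual_id == id, , drop = FALSE]
    out <- g$gt[match(loci, g$locus)]
    out[is.na(out)] <- "missing"
    out
  }
  relatives <- family[family$individual_id != proband_id, , drop = FALSE]
  n_typed <- 0L; n_full <- 0L
  notes <- character()
  status <- NULL
  for (i in seq_len(nrow(relatives))) {
    id <- relatives$individual_id[i]
    gts <- member_gts(id)
    known <- gt_known(gts)
    if (!any(known)) next
    n_typed <- n_typed + 1L
    if (all(known)) n_full <- n_full + 1L
    # evaluate only on the typed loci: untyped loci cannot contradict
    ok <- consistent_partial(gts, known, relatives$affected[i],
                             relatives$sex[i], mode)
    if (!ok) {
      status <- "contradicted"
      notes <- c(notes, paste0("genotype of ", id,
                               " inconsistent with ", mode))
    }
  }
  if (is.null(status)) {
    status <- if (n_typed == 0L) "untested"
    else if (n_full == nrow(relatives)) "full"
    else "partial"
  }

  # de novo loci: proband carries, both parents typed reference
  fam_pro <- family[family$individual_id == proband_id, , drop = FALSE]
  de_novo <- character()
  if (nrow(fam_pro) == 1L && !is.na(fam_pro$father_id) &&
      !is.na(fam_pro$mother_id)) {
    f_gts <- member_gts(fam_pro$father_id)
    m_gts <- member_gts(fam_pro$mother_id)
    p_gts <- member_gts(proband_id)
    for (k in seq_along(loci)) {
      dn <- detect_de_novo(p_gts[k], f_gts[k], m_gts[k])
      if (isTRUE(dn)) de_novo <- c(de_novo, loci[k])
    }
  }
  structure(list(status = status, de_novo_loci = de_novo, notes = notes),
            class = "rp_segregation")
}

# per-member consistency restricted to typed loci; untyped loci can never
# contradict (they reduce "full" to "partial" instead)
consistent_partial <- function(gts, known, affected, sex, mode) {
  if (!any(known)) return(TRUE)
  typed <- gts[known]
  # biallelic state provable from the typed loci alone
  both_certain <- all(known) && carries_both(gts)
  # an affected member must be *able* to carry both alleles: every typed
  # locus carries, and a fully-typed single locus must be hom/hemi
  both_possible <- all(carries_allele(typed)) &&
    !(length(gts) == 1L && all(known) &&
        !gts %in% c("hom_alt", "hemi_alt"))
  switch(mode,
    AR = if (affected) both_possible else !both_certain,
    AD = if (affected) all(carries_allele(typed)) else
      all(typed == "ref_ref"),
    XL = if (sex == "male") {
      if (affected) all(typed %in% c("hemi_alt", "hom_alt", "het")) else
        all(typed == "ref_ref")
    } else {
      if (affected) both_possible else !both_certain
    })
}

#' De novo test for one locus in a trio
#'
#' @param child_gt,father_gt,mother_gt genotype codes (`ref_ref`, `het`,
#'   `hom_alt`, `hemi_alt`, `missing`).
#' @return `TRUE` when the child carries the allele and neither parent
#'   does; `FALSE` when a parent carries it (or the child does not); `NA`
#'   (untestable) when a parent genotype is missing — the absence of data
#'   from a parent blocks a definite conclusion.
#' @examples
#' detect_de_novo("het", "ref_ref", "ref_ref")  # TRUE
#' detect_de_novo("het", "ref_ref", "het")      # FALSE
#' detect_de_novo("het", "missing", "ref_ref")  # NA
#' @export
detect_de_novo <- function(child_gt, father_gt, mother_gt) {
  stopifnot(child_gt %in% GT_CODES, father_gt %in% GT_CODES,
            mother_gt %in% GT_CODES)
  if (!gt_known(child_gt)) return(NA)
  if (!carries_allele(child_gt)) return(FALSE)
  if (!gt_known(father_gt) || !gt_known(mother_gt)) return(NA)
  !carries_allele(father_gt) && !carries_allele(mother_gt)
}

#' Mendelian consistency of polymorphic marker genotypes in a trio
#'
#' A marker is consistent when the child's allele pair can be partitioned
#' into one allele present in the father and one present in the mother.
#' A fully consistent marker set (e.g., 16/16) confirms the parental
#' relationships and thereby a de novo event at the candidate locus.
#'
#' @param child,father,mother data.frames with columns `marker_id`,
#'   `allele1`, `allele2`; markers are matched by `marker_id`.
#' @return list with `consistent_count`, `total`, `confirmed`
#'   (`consistent_count == total`), and `inconsistent_markers`.
#' @export
mendelian_consistency <- function(child, father, mother) {
  ids <- child$marker_id
  if (!length(ids)) stop("at least one marker is required")
  f_idx <- match(ids, father$marker_id)
  m_idx <- match(ids, mother$marker_id)
  if (anyNA(f_idx) || anyNA(m_idx))
    stop("parents must be typed at every child marker")
  ok <- logical(length(ids))
  for (i in seq_along(ids)) {
    a <- child$allele1[i]; b <- child$allele2[i]
    f <- c(father$allele1[f_idx[i]], father$allele2[f_idx[i]])
    m <- c(mother$allele1[m_idx[i]], mother$allele2[m_idx[i]])
    ok[i] <- (a %in% f && b %in% m) || (b %in% f && a %in% m)
  }
  list(consistent_count = sum(ok), total = length(ok),
       confirmed = all(ok), inconsistent_markers = ids[!ok])
}

#' Phase of a compound-heterozygous variant pair
#'
#' Infers whether two heterozygous variants in one gene lie on opposite
#' chromosomes (trans) from the parental genotypes.  A variant's origin is
#' the parent that carries it (or "de novo" when neither does); the pair
#' is `trans` when the origins differ — including one inherited and one de
#' novo allele — `cis` when both trace to the same parent, and `unknown`
#' when the parents are uninformative or untyped.
#'
#' @param var1_gts,var2_gts named character vectors with elements `child`,
#'   `father`, `mother` holding genotype codes for each variant.
#' @return `"trans"`, `"cis"` or `"unknown"`.
#' @export
check_trans_phase <- function(var1_gts, var2_gts) {
  origin <- function(g) {
    if (!gt_known(g[["father"]]) || !gt_known(g[["mother"]]))
      return("unknown")
    f <- carries_allele(g[["father"]])
    m <- carries_allele(g[["mother"]])
    if (f && !m) "father" else if (m && !f) "mother"
    else if (!f && !m) "de_novo" else "unknown"
  }
  o1 <- origin(var1_gts); o2 <- origin(var2_gts)
  if (o1 == "unknown" || o2 == "unknown") return("unknown")
  if (o1 == "de_novo" && o2 == "de_novo") return("unknown")
  if (o1 == o2) "cis" else "trans"
}

#' Flag samples carrying pathogenic-tier variants in several genes
#'
#' Identifies candidates for a cumulative mutational load: samples whose
#' classified variants include pathogenic or probably pathogenic calls in
#' two or more genes, with each gene's variant set separately consistent
#' with one of that gene's inheritance modes.
#'
#' @param results classified variant data.frame with columns `sample_id`,
#'   `gene`, `zygosity`, `final_class` (plus locus columns).
#' @param panel validated gene panel.
#' @param sexes optional named character vector sample_id -> sex.
#' @return data.frame `sample_id`, `genes` (comma-joined, sorted), one row
#'   per flagged sample.
#' @export
detect_multilocus <- function(results, panel, sexes = NULL) {
  modes_by_gene <- panel_modes(panel)
  out <- list()
  for (s in unique(results$sample_id)) {
    rv <- results[results$sample_id == s &
                    is_pathogenic_tier(results$final_class), , drop = FALSE]
    sex <- if (!is.null(sexes) && s %in% names(sexes)) sexes[[s]] else NA
    genes <- character()
    for (g in unique(rv$gene)) {
      gv <- rv[rv$gene == g, , drop = FALSE]
      surv <- passes_inheritance_filter(gv, modes_by_gene[[g]], sex)
      if (nrow(surv)) genes <- c(genes, g)
    }
    if (length(genes) >= 2L)
      out[[s]] <- data.frame(sample_id = s,
                             genes = paste(sort(genes), collapse = ","),
                             stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, unname(out)) else
    data.frame(sample_id = character(), genes = character())
}
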