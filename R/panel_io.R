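# Domain tables, file formats and threshold configuration.
#
# All pipeline state is held in plain data.frames with documented column
# schemas; files are the tab-separated dialects used throughout targeted
# resequencing diagnostics (VCF, BED, PED, TSV, YAML).

#' Recognised variant effect classes
#'
#' Closed vocabulary of per-variant consequence labels used by the
#' prioritization cascade and the pathogenicity classifier.
#'
#' @format Character vector of effect labels.
#' @export
EFFECT_CLASSES <- c(
  "synonymous", "missense", "nonsense", "frameshift", "inframe_indel",
  "canonical_splice", "splice_region", "intronic", "utr", "large_deletion"
)

#' Truncating / automatically pathogenic effect classes
#' @keywords internal
TRUNCATING_EFFECTS <- c("nonsense", "frameshift", "canonical_splice",
                        "large_deletion")

#' Inheritance mode tokens
#' @keywords internal
MODE_TOKENS <- c("AR", "AD", "XL")

#' Three-state classifier levels
#' @keywords internal
TRI_LEVELS <- c("pathogenic", "unknown", "benign")

#' Final pathogenicity verdict levels
#' @keywords internal
FINAL_LEVELS <- c("pathogenic", "probably_pathogenic", "unknown",
                  "probably_benign")

#' Pipeline threshold configuration
#'
#' Builds the complete set of numeric cutoffs used by coverage QC, the
#' high-quality call designation, the prioritization cascade and the
#' pathogenicity classifier.  Every default is the operational constant of
#' the diagnostic workflow; overriding a value changes the corresponding
#' rule everywhere it is applied.
#'
#' @param ... named overrides for individual thresholds.
#'
#' @return A list of class `rp_config`. Fields:
#' \describe{
#'   \item{splice_acceptor_window, splice_donor_window}{intronic windows in
#'     bp around splice sites admitted by the effect filter (8 / 20).}
#'   \item{exome_filter_max, cohort_filter_max}{maximum allele frequency in
#'     the reference exome cohort (0.05) and in the disease panel cohort
#'     (0.15) tolerated by the frequency filters; bounds are strict
#'     ("greater than"), so boundary values pass.}
#'   \item{support_reads_a, support_frac_a, support_reads_b,
#'     support_frac_b_lo}{read-support rule: at least 10 reads with >= 20%
#'     variant reads, or at least 5 reads with 80--100% variant reads.}
#'   \item{hq_rule1_reads, hq_rule2_reads, hq_rule2_qual}{high-quality call
#'     designation: >= 3 nonduplicate reads with both strands, or >= 5 reads
#'     with base quality > 20.}
#'   \item{phylop_benign_lt, phylop_patho_gt}{conservation banding: PhyloP
#'     (44-way) < 1 is benign, > 2.5 is pathogenic.}
#'   \item{freq_benign_gt, freq_unknown_lo, freq_unknown_hi,
#'     cohort_unknown_ge}{frequency banding for classification: exome
#'     frequency > 3% benign, 1--3% unknown; panel-cohort frequency >= 3%
#'     unknown.}
#'   \item{ssf_site, ssf_diff, maxent_diff, nnsplice_site,
#'     nnsplice_diff}{splice-tool cutoffs (SpliceSiteFinder site score 50,
#'     difference 5; MaxEntScan difference 0.8; NNSplice site score 0.5,
#'     difference 0.05).}
#'   \item{poor_target_median_lt}{median depth below which a capture target
#'     is flagged poor (5).}
#'   \item{near_target_bp}{flank width in bp within which off-target bases
#'     count as "near target" (500).}
#' }
#' @examples
#' cfg <- threshold_config()
#' cfg$phylop_patho_gt
#' threshold_config(exome_filter_max = 0.01)$exome_filter_max
#' @export
threshold_config <- function(...) {
  cfg <- list(
    splice_acceptor_window = 8L,
    splice_donor_window    = 20L,
    exome_filter_max       = 0.05,
    cohort_filter_max      = 0.15,
    support_reads_a        = 10L,
    support_frac_a         = 0.20,
    support_reads_b        = 5L,
    support_frac_b_lo      = 0.80,
    hq_rule1_reads         = 3L,
    hq_rule2_reads         = 5L,
    hq_rule2_qual          = 20L,
    phylop_benign_lt       = 1.0,
    phylop_patho_gt        = 2.5,
    freq_benign_gt         = 0.03,
    freq_unknown_lo        = 0.01,
    freq_unknown_hi        = 0.03,
    cohort_unknown_ge      = 0.03,
    ssf_site               = 50,
    ssf_diff               = 5,
    maxent_diff            = 0.8,
    nnsplice_site          = 0.5,
    nnsplice_diff          = 0.05,
    poor_target_median_lt  = 5,
    near_target_bp         = 500L
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad))
      stop("unknown threshold name(s): ", paste(bad, collapse = ", "))
    for (nm in names(overrides)) {
      val <- overrides[[nm]]
      if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
        stop("threshold '", nm, "' must be a single finite number")
      cfg[[nm]] <- val
    }
  }
  counts <- c("splice_acceptor_window", "splice_donor_window",
              "support_reads_a", "support_reads_b", "hq_rule1_reads",
              "hq_rule2_reads", "near_target_bp")
  for (nm in counts)
    if (cfg[[nm]] <= 0) stop("threshold '", nm, "' must be positive")
  structure(cfg, class = "rp_config")
}

#' Read / write a threshold configuration as YAML
#'
#' @param path YAML file with a flat mapping of threshold names to numbers.
#'   Unknown keys are rejected; missing keys keep their defaults.
#' @return `read_threshold_config` returns an `rp_config`;
#'   `write_threshold_config` returns `path` invisibly.
#' @export
read_threshold_config <- function(path) {
  stopifnot(file.exists(path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(threshold_config, vals)
}

#' @rdname read_threshold_config
#' @param cfg an `rp_config`.
#' @export
write_threshold_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "rp_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Gene panel

#' Read a gene panel table
#'
#' The panel TSV has columns `gene`, `chrom`, `modes`; `modes` is a
#' comma-separated nonempty subset of `AR`, `AD`, `XL` giving the
#' inheritance patterns under which mutations in the gene act.
#'
#' @param path panel TSV.
#' @return data.frame with columns `gene`, `chrom`, `modes` (comma-joined,
#'   normalised order AR,AD,XL).
#' @export
read_panel <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("gene", "chrom", "modes")
  if (!all(need %in% names(df)))
    stop("panel file must have columns: ", paste(need, collapse = ", "))
  validate_panel(df[need])
}

#' @rdname read_panel
#' @param panel panel data.frame as returned by `read_panel`.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Validate (and normalise) a gene panel table
#'
#' Checks mode tokens against the closed vocabulary and enforces that
#' X-linked inheritance is only declared for X-chromosome genes.
#'
#' @param panel data.frame with `gene`, `chrom`, `modes`.
#' @return the panel with modes normalised to AR,AD,XL order.
#' @export
validate_panel <- function(panel) {
  modes <- strsplit(panel$modes, ",[ ]*")
  for (i in seq_along(modes)) {
    m <- toupper(trimws(modes[[i]]))
    bad <- setdiff(m, MODE_TOKENS)
    if (length(bad))
      stop("panel row ", i, " (", panel$gene[i], "): unknown mode token '",
           bad[1], "'")
    if (length(m) == 0L)
      stop("panel row ", i, " (", panel$gene[i], "): empty mode set")
    if ("XL" %in% m && !grepl("X$", panel$chrom[i]))
      stop("panel row ", i, " (", panel$gene[i],
           "): XL inheritance declared off chromosome X")
    modes[[i]] <- intersect(MODE_TOKENS, m)   # canonical order, dedup
  }
  panel$modes <- vapply(modes, paste, "", collapse = ",")
  if (anyDuplicated(panel$gene))
    stop("duplicated gene symbol in panel: ",
         panel$gene[duplicated(panel$gene)][1])
  panel
}

#' Split a panel's mode strings into a named list
#' @param panel validated panel data.frame.
#' @return named list gene -> character vector of modes.
#' @export
panel_modes <- function(panel) {
  out <- strsplit(panel$modes, ",")
  names(out) <- panel$gene
  out
}

# ---------------------------------------------------------------------------
# Capture targets (BED dialect: chrom, start, end, region_id, gene)

#' Read / write capture target regions
#'
#' Targets use 0-based half-open BED coordinates with two extra columns:
#' column 4 is the region identifier, column 5 the gene symbol.
#'
#' @param path BED file (no header).
#' @return data.frame `chrom`, `start`, `end`, `region_id`, `gene`.
#' @export
read_targets <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end",
                                        "region_id", "gene"))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(df$end <= df$start))
    stop("target with end <= start: ",
         df$region_id[df$end <= df$start][1])
  df
}

#' @rdname read_targets
#' @param targets target data.frame.
#' @export
write_targets <- function(targets, path) {
  utils::write.table(
    targets[c("chrom", "start", "end", "region_id", "gene")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Pedigrees (6-column PED)

#' Read a pedigree file
#'
#' Standard 6-column PED: family, individual, father, mother, sex
#' (1 = male, 2 = female), phenotype (1 = unaffected, 2 = affected).
#' `"0"` in a parent column means the parent is not recorded.
#'
#' @param path PED file, whitespace separated, no header.
#' @return data.frame `family_id`, `individual_id`, `father_id`,
#'   `mother_id` (NA when absent), `sex` ("male"/"female"), `affected`
#'   (logical).
#' @export
read_pedigree <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("family_id", "individual_id",
                                        "father_id", "mother_id", "sex",
                                        "phenotype"),
                          colClasses = "character")
  if (!all(df$sex %in% c("1", "2")))
    stop("PED sex code outside {1,2} for individual ",
         df$individual_id[!df$sex %in% c("1", "2")][1])
  ped <- data.frame(
    family_id     = df$family_id,
    individual_id = df$individual_id,
    father_id     = ifelse(df$father_id == "0", NA_character_, df$father_id),
    mother_id     = ifelse(df$mother_id == "0", NA_character_, df$mother_id),
    sex           = ifelse(df$sex == "1", "male", "female"),
    affected      = df$phenotype == "2",
    stringsAsFactors = FALSE
  )
  validate_pedigree(ped)
}

#' @rdname read_pedigree
#' @param ped pedigree data.frame.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(
    ped$family_id, ped$individual_id,
    ifelse(is.na(ped$father_id), "0", ped$father_id),
    ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    ifelse(ped$sex == "male", "1", "2"),
    ifelse(ped$affected, "2", "1")
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Validate pedigree structure
#'
#' Parent references must stay within the family (orphan references are
#' flagged) and the parent graph must be acyclic.
#'
#' @param ped pedigree data.frame (see [read_pedigree()]).
#' @return `ped`, invisibly checked.
#' @export
validate_pedigree <- function(ped) {
  for (fam in unique(ped$family_id)) {
    sub <- ped[ped$family_id == fam, ]
    ids <- sub$individual_id
    for (col in c("father_id", "mother_id")) {
      refs <- sub[[col]]
      orphan <- !is.na(refs) & !(refs %in% ids)
      if (any(orphan))
        warning("family ", fam, ": parent id '", refs[orphan][1],
                "' not a member of the family")
    }
    # cycle check by repeated parent pruning (topological peel)
    parent_of <- function(id) {
      r <- sub[sub$individual_id == id, ]
      stats::na.omit(c(r$father_id, r$mother_id))
    }
    for (id in ids) {
      seen <- character()
      frontier <- id
      while (length(frontier)) {
        frontier <- unique(unlist(lapply(
          intersect(frontier, ids), parent_of)))
        if (id %in% frontier)
          stop("family ", fam, ": cyclic parentage involving ", id)
        frontier <- setdiff(frontier, seen)
        seen <- c(seen, frontier)
      }
    }
  }
  ped
}

# ---------------------------------------------------------------------------
# Variants: VCF + support TSV + annotation TSV

SUPPORT_COLS <- c("total_reads", "variant_reads", "nondup_variant_reads",
                  "fwd_variant_reads", "rev_variant_reads",
                  "hq_variant_reads")

ANNOT_COLS <- c("gene", "effect", "acceptor_offset", "donor_offset",
                "in_dbsnp130", "in_hgmd", "known_blindness",
                "exome_freq", "cohort_freq", "phylop",
                "sift", "polyphen", "mutpred",
                "ssf_wt", "ssf_mut", "maxent_wt", "maxent_mut",
                "nnsplice_wt", "nnsplice_mut")

KEY_CLASSES <- c(chrom = "character", pos = "integer", ref = "character",
                 alt = "character")

SUPPORT_CLASSES <- c(KEY_CLASSES,
                     stats::setNames(rep("integer", length(SUPPORT_COLS)),
                                     SUPPORT_COLS))

ANNOT_CLASSES <- c(KEY_CLASSES,
  gene = "character", effect = "character",
  acceptor_offset = "integer", donor_offset = "integer",
  in_dbsnp130 = "logical", in_hgmd = "logical",
  known_blindness = "logical",
  exome_freq = "numeric", cohort_freq = "numeric", phylop = "numeric",
  sift = "character", polyphen = "character", mutpred = "character",
  ssf_wt = "numeric", ssf_mut = "numeric",
  maxent_wt = "numeric", maxent_mut = "numeric",
  nnsplice_wt = "numeric", nnsplice_mut = "numeric")

variant_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

#' Read one sample's annotated variants
#'
#' Joins the three per-sample inputs on the variant key
#' (chrom, pos, ref, alt): a VCF (defines the loci and the zygosity from the
#' single sample GT column), a read-support TSV and an annotation TSV.
#' Multi-allelic VCF records are split into one row per alternate allele
#' before joining.
#'
#' Genotype conventions: `0/1` (or `0|1`) is `het`, `1/1` is `hom`, a
#' single `1` on the X chromosome of a male sample is `hemi`; records where
#' the sample carries no alternate allele are dropped.
#'
#' @param vcf_path VCF v4.x with exactly one sample column.
#' @param support_path TSV with columns chrom, pos, ref, alt and the six
#'   read-support counts (`total_reads`, `variant_reads`,
#'   `nondup_variant_reads`, `fwd_variant_reads`, `rev_variant_reads`,
#'   `hq_variant_reads`).
#' @param annot_path TSV with columns chrom, pos, ref, alt plus the
#'   annotation bundle (effect class, splice offsets, dbSNP130/HGMD/known
#'   mutation flags, exome and disease-cohort frequencies, PhyloP, three
#'   missense tool classes, three splice tool wt/mut score pairs).
#' @param sample_id label stored in the `sample_id` column; defaults to the
#'   VCF sample name.
#' @return data.frame with one row per called alternate allele, containing
#'   locus, gene, zygosity, support counts and annotations.  A VCF record
#'   with no matching annotation row is an error (the pipeline requires
#'   full annotation); annotation rows without a VCF record are skipped
#'   with a warning.
#' @export
read_variants <- function(vcf_path, support_path, annot_path,
                          sample_id = NULL) {
  stopifnot(file.exists(vcf_path), file.exists(support_path),
            file.exists(annot_path))
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (is.null(sample_id)) sample_id <- colnames(vcf@gt)[2]
  gt_raw <- unname(vcfR::extract.gt(vcf, element = "GT")[, 1])

  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    gt <- gt_raw[i]
    alleles <- strsplit(gt, "[/|]")[[1]]
    for (a in seq_along(alts)) {
      n_alt <- sum(alleles == as.character(a))
      if (n_alt == 0L) next
      zyg <- if (length(alleles) == 1L) "hemi"
             else if (n_alt == length(alleles)) "hom" else "het"
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[a], zygosity = zyg,
        stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), zygosity = character())

  sup <- utils::read.table(support_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = SUPPORT_CLASSES)
  ann <- utils::read.table(annot_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = ANNOT_CLASSES,
                           na.strings = c("NA", "."))
  missing_sup <- setdiff(SUPPORT_COLS, names(sup))
  if (length(missing_sup))
    stop("support table lacks column(s): ",
         paste(missing_sup, collapse = ", "))
  missing_ann <- setdiff(ANNOT_COLS, names(ann))
  if (length(missing_ann))
    stop("annotation table lacks column(s): ",
         paste(missing_ann, collapse = ", "))

  key <- variant_key(calls)
  sup_idx <- match(key, variant_key(sup))
  ann_idx <- match(key, variant_key(ann))
  if (anyNA(ann_idx))
    stop("VCF record without annotation: ", key[is.na(ann_idx)][1])
  if (anyNA(sup_idx))
    stop("VCF record without read support: ", key[is.na(sup_idx)][1])
  extra <- setdiff(variant_key(ann), key)
  if (length(extra))
    warning(length(extra), " annotation row(s) without a VCF record; skipped")

  out <- cbind(
    data.frame(sample_id = rep(sample_id, nrow(calls)),
               stringsAsFactors = FALSE),
    calls,
    sup[sup_idx, SUPPORT_COLS, drop = FALSE],
    ann[ann_idx, ANNOT_COLS, drop = FALSE]
  )
  rownames(out) <- NULL
  validate_variants(out)
}

#' Validate an annotated variant table
#'
#' Checks locus invariants (positive positions, ref != alt), read-support
#' consistency (strand counts summing to variant reads, all counts bounded
#' by total), frequency ranges and the effect vocabulary.
#'
#' @param variants annotated variant data.frame.
#' @return `variants` unchanged.
#' @export
validate_variants <- function(variants) {
  if (!nrow(variants)) return(variants)
  stopifnot(all(variants$pos >= 1L))
  if (any(variants$ref == variants$alt))
    stop("variant with ref == alt at ",
         variant_key(variants)[variants$ref == variants$alt][1])
  bad_eff <- setdiff(unique(variants$effect), EFFECT_CLASSES)
  if (length(bad_eff))
    stop("unknown effect class: ", bad_eff[1])
  with(variants, {
    if (any(variant_reads > total_reads) ||
        any(nondup_variant_reads > variant_reads) ||
        any(hq_variant_reads > variant_reads))
      stop("read-support counts violate ordering invariants")
    if (any(fwd_variant_reads + rev_variant_reads != variant_reads))
      stop("forward + reverse variant reads must equal variant reads")
  })
  fr <- c(variants$exome_freq, variants$cohort_freq)
  if (any(fr < 0 | fr > 1, na.rm = TRUE))
    stop("allele frequencies must lie in [0, 1]")
  variants
}

#' Write one sample's variants as VCF + support TSV + annotation TSV
#'
#' Inverse of [read_variants()]; used by the synthetic cohort generator and
#' by round-trip tests.  The VCF is minimal v4.2 with a single sample and a
#' GT field.
#'
#' @param variants one sample's annotated variant data.frame.
#' @param vcf_path,support_path,annot_path output paths.
#' @param sample_id sample column name for the VCF; defaults to the table's
#'   `sample_id`.
#' @return invisibly, the three paths.
#' @export
write_variant_files <- function(variants, vcf_path, support_path,
                                annot_path, sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- if (nrow(variants)) variants$sample_id[1] else "SAMPLE"
  gt <- c(het = "0/1", hom = "1/1", hemi = "1")[variants$zygosity]
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_id)
  )
  body <- if (nrow(variants)) {
    paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
          ".", "PASS", ".", "GT", gt, sep = "\t")
  } else character()
  writeLines(c(hdr, body), vcf_path)

  keycols <- c("chrom", "pos", "ref", "alt")
  utils::write.table(variants[c(keycols, SUPPORT_COLS)], support_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(variants[c(keycols, ANNOT_COLS)], annot_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(vcf = vcf_path, support = support_path, annot = annot_path))
}

# ---------------------------------------------------------------------------
# Depth tracks, markers, relative genotypes

#' Read / write per-base depth tracks
#'
#' Depth TSV columns: `region_id`, `offset` (0-based within the target),
#' `depth`.  Returned as a named list of integer vectors, one per target,
#' ordered by offset.
#'
#' @param path depth TSV.
#' @return named list of integer depth vectors.
#' @export
read_depth <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("region_id", "offset", "depth") %in% names(df)))
  if (any(df$depth < 0)) stop("negative depth value")
  df <- df[order(df$region_id, df$offset), ]
  split(as.integer(df$depth), df$region_id)
}

#' @rdname read_depth
#' @param tracks named list of integer depth vectors.
#' @export
write_depth <- function(tracks, path) {
  df <- data.frame(
    region_id = rep(names(tracks), lengths(tracks)),
    offset = unlist(lapply(tracks, function(d) seq_along(d) - 1L),
                    use.names = FALSE),
    depth = unlist(tracks, use.names = FALSE)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write polymorphic marker genotypes
#'
#' Marker TSV columns: `family_id`, `individual_id`, `marker_id`,
#' `allele1`, `allele2` — one row per individual per marker, two allele
#' labels each (the paternity-testing panel layout).
#'
#' @param path marker TSV.
#' @return data.frame with the five columns above.
#' @export
read_markers <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("family_id", "individual_id", "marker_id", "allele1", "allele2")
  stopifnot(all(need %in% names(df)))
  df[need]
}

#' @rdname read_markers
#' @param markers marker data.frame.
#' @export
write_markers <- function(markers, path) {
  utils::write.table(markers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write follow-up genotypes of relatives at candidate loci
#'
#' Sanger-style follow-up genotyping is targeted: relatives are typed only
#' at the proband's candidate loci.  Columns: `family_id`,
#' `individual_id`, `chrom`, `pos`, `ref`, `alt`, `gt` with `gt` in
#' `ref_ref`, `het`, `hom_alt`, `hemi_alt`, `missing`.
#'
#' @param path genotype TSV.
#' @return data.frame with the seven columns above.
#' @export
read_relative_genotypes <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("family_id", "individual_id", "chrom", "pos", "ref", "alt", "gt")
  stopifnot(all(need %in% names(df)))
  ok <- df$gt %in% c("ref_ref", "het", "hom_alt", "hemi_alt", "missing")
  if (!all(ok)) stop("unknown genotype code: ", df$gt[!ok][1])
  df[need]
}

#' @rdname read_relative_genotypes
#' @param genotypes relative-genotype data.frame.
#' @export
write_relative_genotypes <- function(genotypes, path) {
  utils::write.table(genotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
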