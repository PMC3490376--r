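# In-code fixtures: a one-row variant builder with filter-passing
# defaults, a small gene panel, and a trio pedigree.

make_variant <- function(sample_id = "S1", chrom = "chr1", pos = 1000L,
                         ref = "A", alt = "T", zygosity = "het",
                         total_reads = 30L, variant_reads = 15L,
                         nondup_variant_reads = 14L,
                         fwd_variant_reads = 8L, rev_variant_reads = 7L,
                         hq_variant_reads = 12L,
                         gene = "GA", effect = "missense",
                         acceptor_offset = NA_integer_,
                         donor_offset = NA_integer_,
                         in_dbsnp130 = FALSE, in_hgmd = FALSE,
                         known_blindness = FALSE,
                         exome_freq = 0.001, cohort_freq = 0.005,
                         phylop = 3.2,
                         sift = "pathogenic", polyphen = "pathogenic",
                         mutpred = "pathogenic",
                         ssf_wt = NA_real_, ssf_mut = NA_real_,
                         maxent_wt = NA_real_, maxent_mut = NA_real_,
                         nnsplice_wt = NA_real_, nnsplice_mut = NA_real_) {
  data.frame(sample_id = sample_id, chrom = chrom, pos = pos, ref = ref,
             alt = alt, zygosity = zygosity, total_reads = total_reads,
             variant_reads = variant_reads,
             nondup_variant_reads = nondup_variant_reads,
             fwd_variant_reads = fwd_variant_reads,
             rev_variant_reads = rev_variant_reads,
             hq_variant_reads = hq_variant_reads, gene = gene,
             effect = effect, acceptor_offset = acceptor_offset,
             donor_offset = donor_offset, in_dbsnp130 = in_dbsnp130,
             in_hgmd = in_hgmd, known_blindness = known_blindness,
             exome_freq = exome_freq, cohort_freq = cohort_freq,
             phylop = phylop, sift = sift, polyphen = polyphen,
             mutpred = mutpred, ssf_wt = ssf_wt, ssf_mut = ssf_mut,
             maxent_wt = maxent_wt, maxent_mut = maxent_mut,
             nnsplice_wt = nnsplice_wt, nnsplice_mut = nnsplice_mut,
             stringsAsFactors = FALSE)
}

make_variants <- function(...) do.call(rbind, list(...))

small_panel <- function() {
  validate_panel(data.frame(
    gene = c("GA", "GB", "GC", "GX"),
    chrom = c("chr1", "chr2", "chr3", "chrX"),
    modes = c("AR", "AD", "AR,AD", "XL"),
    stringsAsFactors = FALSE))
}

trio_ped <- function(family_id = "F1", child = "C", father = "F",
                     mother = "M", child_sex = "male") {
  data.frame(
    family_id = family_id,
    individual_id = c(child, father, mother),
    father_id = c(father, NA, NA),
    mother_id = c(mother, NA, NA),
    sex = c(child_sex, "male", "female"),
    affected = c(TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

seg_gts <- function(...) {
  # seg_gts(C = c(l1 = "het"), F = c(l1 = "ref_ref"), ...)
  args <- list(...)
  do.call(rbind, lapply(names(args), function(id) {
    data.frame(individual_id = id, locus = names(args[[id]]),
               gt = unname(args[[id]]), stringsAsFactors = FALSE)
  }))
}
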