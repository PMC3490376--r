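# The high-quality designation and the six-criterion cascade.

sup <- function(nondup, fwd, rev, hq, total = 30L) {
  data.frame(total_reads = total, variant_reads = fwd + rev,
             nondup_variant_reads = nondup, fwd_variant_reads = fwd,
             rev_variant_reads = rev, hq_variant_reads = hq)
}

test_that("high-quality designation implements both calling rules", {
  # rule 1: >= 3 nonduplicate reads, both strands seen
  expect_true(is_high_quality(sup(nondup = 3, fwd = 2, rev = 1, hq = 0)))
  # rule 2 alone: >= 5 reads with quality > 20
  expect_true(is_high_quality(sup(nondup = 2, fwd = 1, rev = 1, hq = 5)))
  # neither: strand requirement unmet, too few high-quality reads
  expect_false(is_high_quality(sup(nondup = 3, fwd = 3, rev = 0, hq = 4)))
})

test_that("effect filter admits protein-changing and near-splice variants", {
  expect_true(passes_effect_filter(make_variant(effect = "missense")))
  expect_true(passes_effect_filter(make_variant(
    effect = "nonsense", sift = NA, polyphen = NA, mutpred = NA)))
  expect_false(passes_effect_filter(make_variant(effect = "synonymous")))
  expect_false(passes_effect_filter(make_variant(effect = "utr")))
  # intronic 14 bp from the acceptor: outside the 8 bp window
  expect_false(passes_effect_filter(make_variant(
    effect = "intronic", acceptor_offset = -14L)))
  # intronic 3 bp past the donor: inside the 20 bp window
  expect_true(passes_effect_filter(make_variant(
    effect = "intronic", donor_offset = 3L)))
  # boundary offsets
  expect_true(passes_effect_filter(make_variant(
    effect = "splice_region", acceptor_offset = -8L)))
  expect_false(passes_effect_filter(make_variant(
    effect = "splice_region", acceptor_offset = -9L)))
  expect_true(passes_effect_filter(make_variant(
    effect = "splice_region", donor_offset = 20L)))
  expect_error(passes_effect_filter(make_variant(
    effect = "splice_region")), "without splice offsets")
})

test_that("novelty filter excludes dbSNP entries unless HGMD/known", {
  expect_true(passes_novelty_filter(make_variant(in_dbsnp130 = FALSE)))
  expect_true(passes_novelty_filter(make_variant(in_dbsnp130 = TRUE,
                                                 in_hgmd = TRUE)))
  expect_true(passes_novelty_filter(make_variant(in_dbsnp130 = TRUE,
                                                 known_blindness = TRUE)))
  expect_false(passes_novelty_filter(make_variant(in_dbsnp130 = TRUE)))
})

test_that("frequency filters use strict greater-than bounds", {
  expect_true(passes_frequency_filters(make_variant(exome_freq = 0.04,
                                                    cohort_freq = 0.10)))
  expect_false(passes_frequency_filters(make_variant(exome_freq = 0.06,
                                                     cohort_freq = 0.01)))
  expect_false(passes_frequency_filters(make_variant(exome_freq = 0.01,
                                                     cohort_freq = 0.16)))
  # boundary values pass
  expect_true(passes_frequency_filters(make_variant(exome_freq = 0.05,
                                                    cohort_freq = 0.15)))
})

test_that("support filter implements both depth/fraction branches", {
  sp <- function(total, variant)
    data.frame(total_reads = total, variant_reads = variant)
  expect_true(passes_support_filter(sp(10, 2)))    # 20% at 10 reads
  expect_true(passes_support_filter(sp(5, 4)))     # 80% at 5 reads
  expect_false(passes_support_filter(sp(9, 5)))    # neither branch
  expect_false(passes_support_filter(sp(10, 1)))
  expect_false(passes_support_filter(sp(0, 0)))    # no division by zero
})

test_that("inheritance filter enforces per-mode allele counts", {
  # single het in an AR-only gene is inconsistent with recessive disease
  one_het <- make_variant(gene = "GA")
  expect_equal(nrow(passes_inheritance_filter(one_het, "AR")), 0)
  # two het loci: putative compound heterozygote, both kept
  two_het <- make_variants(make_variant(gene = "GA", pos = 100L),
                           make_variant(gene = "GA", pos = 200L))
  expect_equal(nrow(passes_inheritance_filter(two_het, "AR")), 2)
  # hom qualifies alone
  hom <- make_variant(gene = "GA", zygosity = "hom")
  expect_equal(nrow(passes_inheritance_filter(hom, "AR")), 1)
  # AD keeps a single het
  expect_equal(nrow(passes_inheritance_filter(
    make_variant(gene = "GB"), "AD")), 1)
  # XL male: hemi kept, het dropped
  hemi <- make_variant(gene = "GX", chrom = "chrX", zygosity = "hemi")
  expect_equal(nrow(passes_inheritance_filter(hemi, "XL", "male")), 1)
  expect_equal(nrow(passes_inheritance_filter(
    make_variant(gene = "GX", chrom = "chrX"), "XL", "male")), 0)
  # XL female needs both alleles
  expect_equal(nrow(passes_inheritance_filter(
    make_variant(gene = "GX", chrom = "chrX"), "XL", "female")), 0)
  # multi-mode gene keeps the union
  expect_equal(nrow(passes_inheritance_filter(
    make_variant(gene = "GC"), c("AR", "AD"))), 1)
  expect_error(passes_inheritance_filter(one_het, "ZZ"), "unknown")
})

test_that("second-allele rescue requires a single strong recessive anchor", {
  anchor <- make_variant(gene = "GA", pos = 100L, effect = "nonsense",
                         sift = NA, polyphen = NA, mutpred = NA)
  partner <- make_variant(gene = "GA", pos = 200L, in_dbsnp130 = TRUE)
  pool <- make_variants(anchor, partner)
  out <- rescue_second_allele(anchor, pool, "AR")
  expect_equal(out$pos, 200L)
  expect_true(all(out$rescued))
  # a missense anchor does not trigger the search
  mis <- make_variant(gene = "GA", pos = 100L)
  expect_equal(nrow(rescue_second_allele(mis, pool, "AR")), 0)
  # no rescue in a dominant-only gene
  expect_equal(nrow(rescue_second_allele(anchor, pool, "AD")), 0)
  # no other variant in the gene: empty result
  expect_equal(nrow(rescue_second_allele(anchor, anchor, "AR")), 0)
  # rescue keeps the effect and support criteria
  bad_partner <- make_variant(gene = "GA", pos = 300L,
                              effect = "synonymous", in_dbsnp130 = TRUE)
  expect_equal(nrow(rescue_second_allele(
    anchor, make_variants(anchor, bad_partner), "AR")), 0)
})

test_that("prioritize_sample rescues a catalogued second allele and counts
           funnel stages", {
  panel <- small_panel()
  anchor <- make_variant(gene = "GA", pos = 100L, effect = "nonsense",
                         sift = NA, polyphen = NA, mutpred = NA)
  partner <- make_variant(gene = "GA", pos = 200L, in_dbsnp130 = TRUE)
  noise <- make_variant(gene = "GB", pos = 50L, chrom = "chr2",
                        effect = "synonymous")
  res <- prioritize_sample(make_variants(anchor, partner, noise), panel,
                           sex = "female")
  expect_equal(res$funnel$n_auto_detected, 3)
  expect_equal(res$funnel$n_after_effect_novelty_frequency, 1)
  expect_equal(res$funnel$n_after_inheritance, 0)
  expect_equal(res$funnel$n_after_rescue, 2)
  expect_setequal(res$shortlist$pos, c(100L, 200L))
  expect_equal(res$shortlist$rescued[res$shortlist$pos == 200L], TRUE)
  expect_equal(res$shortlist$rescued[res$shortlist$pos == 100L], FALSE)
})

test_that("prioritize_sample handles empty input and unknown genes", {
  panel <- small_panel()
  empty <- make_variant()[0, ]
  res <- prioritize_sample(empty, panel, sex = "male")
  expect_equal(nrow(res$shortlist), 0)
  expect_equal(unlist(res$funnel), c(n_auto_detected = 0,
    n_after_effect_novelty_frequency = 0, n_after_inheritance = 0,
    n_after_rescue = 0, n_selected = 0))
  expect_error(prioritize_sample(make_variant(gene = "NOPE"), panel,
                                 sex = "male"), "absent from panel")
  expect_warning(prioritize_sample(make_variant(gene = "GB"), panel),
                 "sex unknown")
})

test_that("low-quality calls never enter the cascade", {
  panel <- small_panel()
  weak <- make_variant(gene = "GB", nondup_variant_reads = 2L,
                       fwd_variant_reads = 2L, rev_variant_reads = 0L,
                       variant_reads = 2L, hq_variant_reads = 2L,
                       total_reads = 4L)
  res <- prioritize_sample(weak, panel, sex = "male")
  expect_equal(res$funnel$n_auto_detected, 0)
  expect_equal(nrow(res$shortlist), 0)
})

test_that("cascade equals the intersection of pure predicates plus
           inheritance and rescue (brute-force oracle)", {
  panel <- small_panel()
  cfg <- threshold_config()
  # enumerated table touching every flag/threshold boundary combination
  rows <- list(); i <- 0
  add <- function(...) {
    i <<- i + 1
    rows[[i]] <<- make_variant(pos = 1000L + 10L * i, ...)
  }
  for (eff in c("missense", "synonymous", "nonsense"))
    for (db in c(TRUE, FALSE))
      for (ef in c(0.01, 0.05, 0.06))
        add(gene = "GC", effect = eff, in_dbsnp130 = db, exome_freq = ef,
            sift = NA, polyphen = NA, mutpred = NA)
  for (tot_var in list(c(10L, 2L), c(9L, 5L), c(5L, 4L), c(4L, 4L)))
    add(gene = "GB", chrom = "chr2", total_reads = tot_var[1],
        variant_reads = tot_var[2],
        fwd_variant_reads = tot_var[2] - 1L, rev_variant_reads = 1L,
        nondup_variant_reads = tot_var[2],
        hq_variant_reads = tot_var[2])
  for (off in c(-8L, -9L)) add(gene = "GA", effect = "splice_region",
                               acceptor_offset = off)
  add(gene = "GA", effect = "nonsense", zygosity = "het",
      sift = NA, polyphen = NA, mutpred = NA)            # rescue anchor
  add(gene = "GA", effect = "missense", in_dbsnp130 = TRUE)  # partner
  add(gene = "GX", chrom = "chrX", zygosity = "hemi")
  tab <- do.call(rbind, rows)
  expect_lte(nrow(tab), 50)

  # independent brute-force evaluation of the cascade
  oracle <- function(v, sex) {
    hq <- (v$nondup_variant_reads >= 3 & v$fwd_variant_reads >= 1 &
             v$rev_variant_reads >= 1) | v$hq_variant_reads >= 5
    p <- logical(nrow(v))
    for (j in seq_len(nrow(v))) {
      eff_ok <- v$effect[j] %in% c("missense", "nonsense", "frameshift",
                                   "inframe_indel", "canonical_splice",
                                   "large_deletion") ||
        (v$effect[j] %in% c("splice_region", "intronic") &&
           ((!is.na(v$acceptor_offset[j]) &&
               abs(v$acceptor_offset[j]) <= 8) ||
              (!is.na(v$donor_offset[j]) && abs(v$donor_offset[j]) <= 20)))
      nov_ok <- !isTRUE(v$in_dbsnp130[j]) || isTRUE(v$in_hgmd[j]) ||
        isTRUE(v$known_blindness[j])
      fr_ok <- v$exome_freq[j] <= 0.05 && v$cohort_freq[j] <= 0.15
      su_ok <- (v$total_reads[j] >= 10 &&
                  v$variant_reads[j] / v$total_reads[j] >= 0.2) ||
        (v$total_reads[j] >= 5 &&
           v$variant_reads[j] / v$total_reads[j] >= 0.8)
      p[j] <- hq[j] && eff_ok && nov_ok && fr_ok && su_ok
    }
    keep <- rep(FALSE, nrow(v))
    modes_by_gene <- panel_modes(panel)
    for (g in unique(v$gene)) {
      gi <- which(v$gene == g & p)
      if (!length(gi)) next
      zy <- v$zygosity[gi]
      bi <- sum(zy == "hom") >= 1 ||
        length(unique(paste(v$chrom[gi], v$pos[gi])[zy == "het"])) >= 2
      for (mode in modes_by_gene[[g]]) {
        keep[gi] <- keep[gi] | switch(mode,
          AR = bi, AD = TRUE,
          XL = if (sex == "male") zy %in% c("hemi", "hom") else bi)
      }
    }
    # rescue: lone strong het anchor in an AR-capable gene
    for (g in unique(v$gene)) {
      if (!"AR" %in% modes_by_gene[[g]]) next
      gi <- which(v$gene == g & p)
      if (length(gi) == 1 && v$zygosity[gi] == "het" &&
            v$effect[gi] %in% c("nonsense", "canonical_splice")) {
        others <- which(v$gene == g & hq & seq_len(nrow(v)) != gi)
        for (o in others) {
          eff_ok <- v$effect[o] %in% c("missense", "nonsense", "frameshift",
                                       "inframe_indel", "canonical_splice",
                                       "large_deletion") ||
            (v$effect[o] %in% c("splice_region", "intronic") &&
               ((!is.na(v$acceptor_offset[o]) &&
                   abs(v$acceptor_offset[o]) <= 8) ||
                  (!is.na(v$donor_offset[o]) &&
                     abs(v$donor_offset[o]) <= 20)))
          su_ok <- (v$total_reads[o] >= 10 &&
                      v$variant_reads[o] / v$total_reads[o] >= 0.2) ||
            (v$total_reads[o] >= 5 &&
               v$variant_reads[o] / v$total_reads[o] >= 0.8)
          if (eff_ok && su_ok) {
            keep[o] <- TRUE
            keep[gi] <- TRUE
          }
        }
      }
    }
    sort(paste(v$chrom, v$pos)[keep])
  }

  for (sex in c("male", "female")) {
    got <- prioritize_sample(tab, panel, sex, cfg)$shortlist
    expect_identical(sort(paste(got$chrom, got$pos)), oracle(tab, sex),
                     label = paste("cascade vs oracle, sex =", sex))
  }
})

test_that("funnel counts reject impossible stage orderings", {
  expect_error(funnel_counts(10, 12, 2, 2, 2))
  expect_error(funnel_counts(10, 5, 6, 6, 6))
  expect_error(funnel_counts(10, 5, 3, 2, 2))
  f <- funnel_counts(10, 5, 3, 4, 4)
  expect_s3_class(f, "rp_funnel")
})
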