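# Family-level evidence: segregation, de novo, markers, phase, multilocus.

test_that("a classic recessive trio fully segregates", {
  fam <- trio_ped()
  gts <- seg_gts(C = c(l1 = "hom_alt"), F = c(l1 = "het"),
                 M = c(l1 = "het"))
  seg <- check_segregation(gts, fam, "AR", "C")
  expect_equal(seg$status, "full")
  expect_length(seg$de_novo_loci, 0)
})

test_that("an unaffected carrier of both alleles contradicts AR", {
  fam <- rbind(trio_ped(),
               data.frame(family_id = "F1", individual_id = "SIB",
                          father_id = "F", mother_id = "M", sex = "female",
                          affected = FALSE, stringsAsFactors = FALSE))
  gts <- seg_gts(C = c(l1 = "het", l2 = "het"),
                 F = c(l1 = "het", l2 = "ref_ref"),
                 M = c(l1 = "ref_ref", l2 = "het"),
                 SIB = c(l1 = "het", l2 = "het"))
  expect_equal(check_segregation(gts, fam, "AR", "C")$status,
               "contradicted")
})

test_that("a dominant variant in an unaffected relative contradicts AD", {
  fam <- rbind(trio_ped(),
               data.frame(family_id = "F1", individual_id = "SIB",
                          father_id = "F", mother_id = "M", sex = "male",
                          affected = FALSE, stringsAsFactors = FALSE))
  gts <- seg_gts(C = c(l1 = "het"), F = c(l1 = "ref_ref"),
                 M = c(l1 = "ref_ref"), SIB = c(l1 = "het"))
  expect_equal(check_segregation(gts, fam, "AD", "C")$status,
               "contradicted")
})

test_that("untyped relatives yield untested or partial verdicts", {
  fam <- trio_ped()
  gts <- seg_gts(C = c(l1 = "het"))
  expect_equal(check_segregation(gts, fam, "AD", "C")$status, "untested")
  gts <- seg_gts(C = c(l1 = "het"), M = c(l1 = "ref_ref"))
  expect_equal(check_segregation(gts, fam, "AD", "C")$status, "partial")
  expect_error(check_segregation(seg_gts(F = c(l1 = "het")), fam, "AD",
                                 "C"), "proband")
  expect_error(check_segregation(gts, fam, "AD", "C",
                                 gene_modes = c("AR", "XL")),
               "incompatible")
})

test_that("XL segregation tracks hemizygous males and carrier females", {
  fam <- rbind(trio_ped(),
               data.frame(family_id = "F1", individual_id = "U",
                          father_id = "F", mother_id = "M", sex = "male",
                          affected = FALSE, stringsAsFactors = FALSE))
  gts <- seg_gts(C = c(l1 = "hemi_alt"), F = c(l1 = "ref_ref"),
                 M = c(l1 = "het"), U = c(l1 = "ref_ref"))
  expect_equal(check_segregation(gts, fam, "XL", "C")$status, "full")
  gts$gt[gts$individual_id == "U"] <- "hemi_alt"
  expect_equal(check_segregation(gts, fam, "XL", "C")$status,
               "contradicted")
})

test_that("de novo loci are reported when both parents are typed reference", {
  fam <- trio_ped()
  gts <- seg_gts(C = c(l1 = "het"), F = c(l1 = "ref_ref"),
                 M = c(l1 = "ref_ref"))
  seg <- check_segregation(gts, fam, "AD", "C")
  expect_equal(seg$de_novo_loci, "l1")
})

test_that("adding consistent relatives keeps full; one inconsistent
           relative degrades to contradicted", {
  fam <- trio_ped()
  gts <- seg_gts(C = c(l1 = "hom_alt"), F = c(l1 = "het"),
                 M = c(l1 = "het"))
  expect_equal(check_segregation(gts, fam, "AR", "C")$status, "full")
  fam2 <- rbind(fam, data.frame(family_id = "F1", individual_id = "S2",
                                father_id = "F", mother_id = "M",
                                sex = "female", affected = TRUE,
                                stringsAsFactors = FALSE))
  gts2 <- rbind(gts, data.frame(individual_id = "S2", locus = "l1",
                                gt = "hom_alt"))
  expect_equal(check_segregation(gts2, fam2, "AR", "C")$status, "full")
  gts2$gt[gts2$individual_id == "S2"] <- "ref_ref"  # affected, no alleles
  expect_equal(check_segregation(gts2, fam2, "AR", "C")$status,
               "contradicted")
})

test_that("de novo detection distinguishes true, false and untestable", {
  expect_true(detect_de_novo("het", "ref_ref", "ref_ref"))
  expect_false(detect_de_novo("het", "ref_ref", "het"))  # maternal
  expect_true(is.na(detect_de_novo("het", "missing", "ref_ref")))
  expect_false(detect_de_novo("ref_ref", "ref_ref", "ref_ref"))
  expect_error(detect_de_novo("01", "ref_ref", "ref_ref"))
})

test_that("de novo detection matches its truth table exhaustively and is
           symmetric in parents", {
  codes <- c("ref_ref", "het", "hom_alt", "hemi_alt", "missing")
  carrier <- function(g) g %in% c("het", "hom_alt", "hemi_alt")
  for (ch in codes) for (f in codes) for (m in codes) {
    got <- detect_de_novo(ch, f, m)
    want <- if (ch == "missing") NA
    else if (!carrier(ch)) FALSE
    else if (f == "missing" || m == "missing") NA
    else !carrier(f) && !carrier(m)
    expect_identical(got, want, label = paste(ch, f, m))
    expect_identical(got, detect_de_novo(ch, m, f))
    if (carrier(f) && ch != "missing")
      expect_false(isTRUE(got))
  }
})

test_that("marker consistency agrees with an exhaustive transmission
           oracle on randomized trios", {
  # oracle: enumerate the four parental transmissions explicitly
  oracle_marker <- function(child, father, mother) {
    for (fa in father) for (mo in mother) {
      if (identical(sort(c(fa, mo)), sort(child))) return(TRUE)
    }
    FALSE
  }
  set.seed(21)
  n_agree <- 0
  for (i in 1:1000) {
    pool <- as.character(seq_len(sample(2:5, 1)))
    ch <- sample(pool, 2, replace = TRUE)
    fa <- sample(pool, 2, replace = TRUE)
    mo <- sample(pool, 2, replace = TRUE)
    mk <- function(al) data.frame(marker_id = "MK01", allele1 = al[1],
                                  allele2 = al[2])
    got <- mendelian_consistency(mk(ch), mk(fa), mk(mo))
    expect_equal(got$consistent_count == 1, oracle_marker(ch, fa, mo),
                 label = paste(i, paste(ch, collapse = "/"),
                               paste(fa, collapse = "/"),
                               paste(mo, collapse = "/")))
    n_agree <- n_agree + 1
  }
  expect_equal(n_agree, 1000)
})

test_that("a fully consistent marker panel confirms; one inconsistency
           refutes", {
  set.seed(33)
  n <- 16
  f_al <- matrix(as.character(sample(8, 2 * n, replace = TRUE)), ncol = 2)
  m_al <- matrix(as.character(sample(8, 2 * n, replace = TRUE)), ncol = 2)
  c_al <- cbind(f_al[cbind(1:n, sample(1:2, n, TRUE))],
                m_al[cbind(1:n, sample(1:2, n, TRUE))])
  df <- function(al) data.frame(marker_id = sprintf("MK%02d", 1:n),
                                allele1 = al[, 1], allele2 = al[, 2])
  mc <- mendelian_consistency(df(c_al), df(f_al), df(m_al))
  expect_equal(mc$consistent_count, 16)
  expect_true(mc$confirmed)
  # corrupt one child marker with an allele absent from both parents
  c_bad <- c_al; c_bad[7, ] <- c("99", "99")
  mc2 <- mendelian_consistency(df(c_bad), df(f_al), df(m_al))
  expect_equal(mc2$consistent_count, 15)
  expect_false(mc2$confirmed)
  expect_equal(mc2$inconsistent_markers, "MK07")
  expect_error(mendelian_consistency(df(c_al)[0, ], df(f_al), df(m_al)),
               "at least one marker")
})

test_that("trans-phase calls follow parental origin", {
  gts <- function(c1, f1, m1) c(child = c1, father = f1, mother = m1)
  # one maternal, one de novo: trans
  expect_equal(check_trans_phase(gts("het", "ref_ref", "het"),
                                 gts("het", "ref_ref", "ref_ref")),
               "trans")
  # classic biparental trans
  expect_equal(check_trans_phase(gts("het", "het", "ref_ref"),
                                 gts("het", "ref_ref", "het")),
               "trans")
  # both from the father: cis
  expect_equal(check_trans_phase(gts("het", "het", "ref_ref"),
                                 gts("het", "het", "ref_ref")), "cis")
  # parents unavailable
  expect_equal(check_trans_phase(gts("het", "missing", "het"),
                                 gts("het", "ref_ref", "het")), "unknown")
  # a parent carrying both is uninformative
  expect_equal(check_trans_phase(gts("het", "het", "het"),
                                 gts("het", "ref_ref", "het")), "unknown")
})

test_that("multilocus detection requires pathogenic-tier, mode-consistent
           variants in two genes", {
  panel <- small_panel()
  res <- make_variants(
    make_variant(sample_id = "P9472", gene = "GA", pos = 100L,
                 zygosity = "hom", effect = "canonical_splice"),
    make_variant(sample_id = "P9472", gene = "GB", chrom = "chr2",
                 pos = 200L, zygosity = "het"))
  res$final_class <- c("pathogenic", "probably_pathogenic")
  out <- detect_multilocus(res, panel)
  expect_equal(out$sample_id, "P9472")
  expect_equal(out$genes, "GA,GB")
  # one gene only: not flagged
  expect_equal(nrow(detect_multilocus(res[1, ], panel)), 0)
  # second gene classified unknown: not flagged
  res2 <- res; res2$final_class[2] <- "unknown"
  expect_equal(nrow(detect_multilocus(res2, panel)), 0)
  # second gene mode-inconsistent (single het in AR-only gene)
  res3 <- res
  res3$gene[2] <- "GA2"
  panel3 <- validate_panel(rbind(panel, data.frame(
    gene = "GA2", chrom = "chr2", modes = "AR")))
  expect_equal(nrow(detect_multilocus(res3, panel3)), 0)
})
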