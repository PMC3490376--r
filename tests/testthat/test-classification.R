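# Per-tool cutoffs, axis banding, the combination rule and classify_variants.

test_that("majority vote is permutation-invariant and handles splits", {
  expect_equal(vote(c("pathogenic", "pathogenic", "benign")), "pathogenic")
  expect_equal(vote(c("pathogenic", "unknown", "benign")), "unknown")
  expect_equal(vote(c("benign", "benign", "benign")), "benign")
  # permutation invariance over all triples
  for (a in c("pathogenic", "unknown", "benign"))
    for (b in c("pathogenic", "unknown", "benign"))
      for (c_ in c("pathogenic", "unknown", "benign")) {
        v0 <- vote(c(a, b, c_))
        expect_equal(vote(c(c_, a, b)), v0)
        expect_equal(vote(c(b, c_, a)), v0)
      }
  expect_error(vote(c("pathogenic", "benign")), "three")
  expect_error(vote(c("pathogenic", "benign", "oops")), "unknown class")
})

test_that("SpliceSiteFinder branches follow the 50/5 cutoffs", {
  expect_equal(classify_ssf(60, 40), "pathogenic")  # crosses 50
  expect_equal(classify_ssf(60, 54), "unknown")     # diff 6 > 5
  expect_equal(classify_ssf(60, 58), "benign")      # neither
  expect_equal(classify_ssf(49, 30), "unknown")     # wt below site cutoff
  expect_equal(classify_ssf(60, 55), "benign")      # diff exactly 5
})

test_that("MaxEntScan branches follow the 0.8 difference rule", {
  expect_equal(classify_maxent(8.0, 6.5), "pathogenic")  # diff 1.5
  expect_equal(classify_maxent(8.0, 8.0), "benign")      # no difference
  expect_equal(classify_maxent(8.0, 7.6), "unknown")     # diff 0.4
  expect_equal(classify_maxent(8.0, 7.2), "unknown")     # diff exactly 0.8
  # a score gain is never pathogenic
  expect_equal(classify_maxent(6.0, 9.0), "unknown")
})

test_that("NNSplice branches follow the 0.5/0.05 cutoffs", {
  expect_equal(classify_nnsplice(0.8, 0.3), "pathogenic")
  expect_equal(classify_nnsplice(0.8, 0.74), "unknown")   # diff 0.06
  expect_equal(classify_nnsplice(0.8, 0.78), "benign")
  expect_error(classify_nnsplice(1.3, 0.5), "\\[0, 1\\]")
})

test_that("conservation banding uses strict 1 / 2.5 cutoffs", {
  expect_equal(classify_conservation(0.5), "benign")
  expect_equal(classify_conservation(3.0), "pathogenic")
  expect_equal(classify_conservation(1.7), "unknown")
  # boundaries fall in the intermediary band
  expect_equal(classify_conservation(1.0), "unknown")
  expect_equal(classify_conservation(2.5), "unknown")
})

test_that("frequency banding combines both cohorts", {
  expect_equal(classify_frequency(0.04, 0.0), "benign")
  expect_equal(classify_frequency(0.02, 0.0), "unknown")
  expect_equal(classify_frequency(0.005, 0.01), "pathogenic")
  expect_equal(classify_frequency(0.0, 0.03), "unknown")  # cohort >= 3%
  # band boundaries are unknown
  expect_equal(classify_frequency(0.01, 0.0), "unknown")
  expect_equal(classify_frequency(0.03, 0.0), "unknown")
  expect_error(classify_frequency(2, 0), "\\[0, 1\\]")
})

test_that("the 27-cell combination matches a hand-enumerated oracle", {
  # oracle written out cell by cell, independent of combine_classes
  P <- "pathogenic"; U <- "unknown"; B <- "benign"
  oracle <- list(
    # frequency = benign: override on all 9 cells
    list(P, P, B, "probably_benign"), list(P, U, B, "probably_benign"),
    list(P, B, B, "probably_benign"), list(U, P, B, "probably_benign"),
    list(U, U, B, "probably_benign"), list(U, B, B, "probably_benign"),
    list(B, P, B, "probably_benign"), list(B, U, B, "probably_benign"),
    list(B, B, B, "probably_benign"),
    # frequency = pathogenic
    list(P, P, P, "probably_pathogenic"),
    list(P, U, P, "probably_pathogenic"),
    list(P, B, P, "probably_pathogenic"),
    list(U, P, P, "probably_pathogenic"),
    list(U, U, P, "unknown"),
    list(U, B, P, "unknown"),
    list(B, P, P, "probably_pathogenic"),
    list(B, U, P, "unknown"),
    list(B, B, P, "probably_benign"),
    # frequency = unknown
    list(P, P, U, "probably_pathogenic"),
    list(P, U, U, "unknown"),
    list(P, B, U, "unknown"),          # three different votes
    list(U, P, U, "unknown"),
    list(U, U, U, "unknown"),
    list(U, B, U, "unknown"),
    list(B, P, U, "unknown"),          # three different votes
    list(B, U, U, "unknown"),
    list(B, B, U, "probably_benign"))
  expect_length(oracle, 27)
  for (cell in oracle)
    expect_equal(combine_classes(cell[[1]], cell[[2]], cell[[3]]),
                 cell[[4]],
                 label = paste(cell[[1]], cell[[2]], cell[[3]]))
  # the audit table agrees cell for cell
  tab <- combination_truth_table()
  expect_equal(nrow(tab), 27)
  for (cell in oracle) {
    got <- tab$final[tab$insilico == cell[[1]] &
                       tab$conservation == cell[[2]] &
                       tab$frequency == cell[[3]]]
    expect_equal(got, cell[[4]])
  }
})

test_that("classify_variants routes by effect class", {
  cfg <- threshold_config()
  # truncating variants are pathogenic outright
  for (eff in c("nonsense", "frameshift", "canonical_splice",
                "large_deletion")) {
    v <- classify_variants(make_variant(effect = eff, sift = NA,
                                        polyphen = NA, mutpred = NA), cfg)
    expect_equal(v$final_class, "pathogenic", label = eff)
  }
  # missense with two pathogenic calls, high conservation, rare
  v <- classify_variants(make_variant(
    sift = "pathogenic", polyphen = "pathogenic", mutpred = "benign",
    phylop = 3.1, exome_freq = 0.001, cohort_freq = 0.0), cfg)
  expect_equal(v$axis_insilico, "pathogenic")
  expect_equal(v$axis_conservation, "pathogenic")
  expect_equal(v$axis_frequency, "pathogenic")
  expect_equal(v$final_class, "probably_pathogenic")
  # frequency-benign override regardless of other evidence
  v <- classify_variants(make_variant(exome_freq = 0.05, phylop = 5), cfg)
  expect_equal(v$final_class, "probably_benign")
  # noncanonical splice variant votes over the three splice tools
  v <- classify_variants(make_variant(
    effect = "splice_region", acceptor_offset = -4L,
    sift = NA, polyphen = NA, mutpred = NA,
    ssf_wt = 60, ssf_mut = 40, maxent_wt = 8, maxent_mut = 6.5,
    nnsplice_wt = 0.8, nnsplice_mut = 0.78,
    phylop = 3.0, exome_freq = 0.001, cohort_freq = 0.0), cfg)
  expect_equal(v$axis_insilico, "pathogenic")   # (P, P, benign)
  expect_equal(v$final_class, "probably_pathogenic")
  # missense without tool calls: warned, in silico axis unknown
  expect_warning(
    v <- classify_variants(make_variant(sift = NA, polyphen = NA,
                                        mutpred = NA, phylop = 0.2), cfg),
    "without tool calls")
  expect_equal(v$axis_insilico, "unknown")
})

test_that("raising the exome frequency never moves a variant toward
           pathogenic", {
  cfg <- threshold_config()
  rank <- c(probably_benign = 1, unknown = 2, probably_pathogenic = 3,
            pathogenic = 4)
  set.seed(9)
  freqs <- sort(c(0, 0.005, 0.01, 0.02, 0.03, 0.031, 0.05, 0.2))
  for (i in 1:20) {
    base <- make_variant(
      sift = sample(c("pathogenic", "unknown", "benign"), 1),
      polyphen = sample(c("pathogenic", "unknown", "benign"), 1),
      mutpred = sample(c("pathogenic", "unknown", "benign"), 1),
      phylop = runif(1, -1, 5), cohort_freq = runif(1, 0, 0.05))
    classes <- vapply(freqs, function(f) {
      base$exome_freq <- f
      classify_variants(base, cfg)$final_class
    }, "")
    expect_true(all(diff(rank[classes]) <= 0),
                label = paste("monotone at iteration", i))
  }
})
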