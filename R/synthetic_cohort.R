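# Deterministic, seeded synthetic cohort generator.
#
# Emulates every input the pipeline touches -- gene panel, capture
# targets, per-base depth tracks, pedigrees, fully annotated per-sample
# variant tables, relative genotypes at candidate loci, paternity marker
# panels -- and plants causal genotypes under recessive (homozygous and
# compound-heterozygous), dominant (inherited and de novo) and X-linked
# scenarios, with a machine-readable truth record for recovery tests.
#
# Background annotation strata are explicit artifact choices: they are
# sampled so that background variants predominantly fail at least one
# prioritization criterion and so that pathogenic-tier classification
# evidence arises only from planted variants (conservation is capped
# below the pathogenic cutoff and in silico votes carry at most one
# pathogenic call).  The funnel reduction is the emergent consequence of
# the filters, not a hard-coded count.

#' Simulation configuration
#'
#' @param seed master RNG seed; per-sample substreams are derived by a
#'   stable hash of the sample id so generation is order-independent.
#' @param n_samples number of probands.
#' @param n_genes panel size.
#' @param n_targets number of capture targets (default 2011).
#' @param mean_background_variants Poisson mean of per-sample background
#'   variant counts (default 1274).
#' @param fraction_dbsnp probability that a background substitution is a
#'   catalogued dbSNP130 polymorphism.
#' @param fraction_false_indels fraction of background calls marked as
#'   failing Sanger confirmation in the truth record (indel-type calls are
#'   marked first, mirroring the dominance of falsely called homopolymer
#'   indels among nonconfirmed variants).
#' @param poor_target_count number of capture targets degraded to
#'   near-zero coverage (default 15).
#' @param scenario_mix named proportions over `AR_hom`,
#'   `AR_compound_het`, `AD_inherited`, `AD_de_novo`, `XL`, `unsolved`;
#'   must sum to 1.
#' @param de_novo_marker_count polymorphic markers generated per de novo
#'   trio (default 16).
#' @param mean_depth mean sequencing depth over targets.
#' @param sibling_prob probability that a recessive-scenario family has an
#'   affected sibling genotyped.
#' @return list of class `rp_sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_samples = 100L,
                              n_genes = 111L,
                              n_targets = 2011L,
                              mean_background_variants = 1274,
                              fraction_dbsnp = 0.94,
                              fraction_false_indels = 0.21,
                              poor_target_count = 15L,
                              scenario_mix = c(AR_hom = 0.13,
                                               AR_compound_het = 0.14,
                                               AD_inherited = 0.03,
                                               AD_de_novo = 0.03,
                                               XL = 0.03,
                                               unsolved = 0.64),
                              de_novo_marker_count = 16L,
                              mean_depth = 26,
                              sibling_prob = 0.3) {
  cfg <- as.list(environment())
  stopifnot(n_samples >= 1, n_genes >= 4, n_targets >= n_genes,
            poor_target_count <= n_targets,
            mean_background_variants > 0, de_novo_marker_count >= 1)
  need <- c("AR_hom", "AR_compound_het", "AD_inherited", "AD_de_novo",
            "XL", "unsolved")
  if (!setequal(names(scenario_mix), need))
    stop("scenario_mix must name exactly: ", paste(need, collapse = ", "))
  if (abs(sum(scenario_mix) - 1) > 1e-8)
    stop("scenario_mix proportions must sum to 1")
  cfg$scenario_mix <- scenario_mix[need]
  structure(cfg, class = "rp_sim_config")
}

# stable 31-bit hash of a sample id, folded with the master seed
sample_substream_seed <- function(sample_id, master_seed) {
  h <- 0
  for (ch in utf8ToInt(sample_id)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + (master_seed %% 2147483647) * 97) %% 2147483647)
}

rcategory <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

BASES <- c("A", "C", "G", "T")

random_alleles <- function(n) {
  ref <- sample(BASES, n, replace = TRUE)
  shift <- sample(1:3, n, replace = TRUE)
  alt <- BASES[(match(ref, BASES) - 1L + shift) %% 4L + 1L]
  list(ref = ref, alt = alt)
}

# ---------------------------------------------------------------------------
# cohort-level structures

simulate_panel <- function(cfg) {
  n <- cfg$n_genes
  genes <- sprintf("GENE%03d", seq_len(n))
  # mode composition mirrors a retinal dystrophy panel: predominantly
  # recessive genes, a minority dominant or dual-mode, a few X-linked
  modes <- rcategory(n, c("AR" = 0.58, "AR,AD" = 0.16, "AD" = 0.16,
                          "XL" = 0.10))
  # guarantee at least one gene per scenario class
  modes[1] <- "AR"; modes[2] <- "AR,AD"; modes[3] <- "AD"; modes[4] <- "XL"
  chrom <- paste0("chr", sample(1:22, n, replace = TRUE))
  chrom[modes == "XL"] <- "chrX"
  validate_panel(data.frame(gene = genes, chrom = chrom, modes = modes,
                            stringsAsFactors = FALSE))
}

simulate_targets <- function(cfg, panel) {
  n <- cfg$n_targets
  gene_idx <- sort(rep_len(seq_len(nrow(panel)), n))
  len <- sample(250:400, n, replace = TRUE)
  start <- integer(n); chrom <- character(n)
  offset_by_chrom <- new.env()
  for (i in seq_len(n)) {
    ch <- panel$chrom[gene_idx[i]]
    cur <- if (is.null(offset_by_chrom[[ch]])) 10000L else
      offset_by_chrom[[ch]]
    start[i] <- cur
    offset_by_chrom[[ch]] <- cur + len[i] + sample(500:5000, 1)
    chrom[i] <- ch
  }
  data.frame(chrom = chrom, start = start, end = start + len,
             region_id = sprintf("T%04d", seq_len(n)),
             gene = panel$gene[gene_idx], stringsAsFactors = FALSE)
}

#' Simulate per-base depth tracks for one sample
#'
#' Per-target depth is Poisson around a target-specific rate drawn from a
#' gamma law (mean near `cfg$mean_depth`, floored at 8 so only designated
#' targets can fall below the poor-coverage threshold); degraded targets
#' get near-zero coverage.
#'
#' @param targets target data.frame.
#' @param cfg `rp_sim_config`.
#' @param degraded_ids region ids to degrade.
#' @return named list of integer depth vectors.
#' @export
simulate_depth_tracks <- function(targets, cfg = simulation_config(),
                                  degraded_ids = character()) {
  n <- nrow(targets)
  lambda <- pmax(8, stats::rgamma(n, shape = 9,
                                  scale = cfg$mean_depth / 9))
  tracks <- vector("list", n)
  names(tracks) <- targets$region_id
  for (i in seq_len(n)) {
    len <- targets$end[i] - targets$start[i]
    d <- stats::rpois(len, lambda[i])
    if (stats::median(d) < 5) d <- d + 5L   # guard: only degraded targets
    tracks[[i]] <- as.integer(d)            # may be poor by construction
  }
  degrade_targets(tracks, degraded_ids)
}

#' Degrade designated targets to near-zero coverage
#'
#' Emulates capture failure of high-GC or repeat-rich targets: depths of
#' the designated regions are zeroed, forcing their median below the
#' poor-target threshold.  Variants placed inside degraded targets are
#' removed from the emitted call set by the generator (their read support
#' collapses), which is what makes detection-rate experiments possible.
#'
#' @param depth_tracks named list of depth vectors.
#' @param region_ids ids of the targets to degrade.
#' @return the modified track list.
#' @export
degrade_targets <- function(depth_tracks, region_ids) {
  for (id in intersect(region_ids, names(depth_tracks)))
    depth_tracks[[id]] <- rep(0L, length(depth_tracks[[id]]))
  depth_tracks
}

# ---------------------------------------------------------------------------
# background variants

empty_variant_table <- function() {
  data.frame(sample_id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), zygosity = character(),
             total_reads = integer(), variant_reads = integer(),
             nondup_variant_reads = integer(), fwd_variant_reads = integer(),
             rev_variant_reads = integer(), hq_variant_reads = integer(),
             gene = character(), effect = character(),
             acceptor_offset = integer(), donor_offset = integer(),
             in_dbsnp130 = logical(), in_hgmd = logical(),
             known_blindness = logical(), exome_freq = numeric(),
             cohort_freq = numeric(), phylop = numeric(),
             sift = character(), polyphen = character(),
             mutpred = character(), ssf_wt = numeric(), ssf_mut = numeric(),
             maxent_wt = numeric(), maxent_mut = numeric(),
             nnsplice_wt = numeric(), nnsplice_mut = numeric(),
             stringsAsFactors = FALSE)
}

BG_EFFECT_PROBS <- c(synonymous = 0.28, intronic = 0.40, utr = 0.145,
                     missense = 0.12, splice_region = 0.03,
                     inframe_indel = 0.01, frameshift = 0.006,
                     nonsense = 0.005, canonical_splice = 0.004)

simulate_background <- function(sample_id, sex, targets, cfg) {
  n <- stats::rpois(1, cfg$mean_background_variants)
  if (n == 0L) return(empty_variant_table())
  ti <- sample(nrow(targets), n, replace = TRUE)
  pos <- as.integer(targets$start[ti] +
    floor(stats::runif(n) * (targets$end[ti] - targets$start[ti])) + 1L)
  al <- random_alleles(n)
  chrom <- targets$chrom[ti]
  effect <- rcategory(n, BG_EFFECT_PROBS)

  truncating <- effect %in% c("nonsense", "frameshift", "canonical_splice")
  # catalogued truncating polymorphisms only: novel truncating calls in
  # panel genes are reserved for planted mutations
  in_dbsnp <- ifelse(truncating, TRUE,
                     stats::runif(n) < cfg$fraction_dbsnp)

  # zygosity tracks population frequency (Hardy-Weinberg): rare, novel
  # variants are almost always heterozygous
  p_hom <- ifelse(in_dbsnp, 0.38, 0.03)
  zyg <- ifelse(stats::runif(n) < p_hom, "hom", "het")
  zyg[chrom == "chrX" & sex == "male"] <- "hemi"

  total <- stats::rpois(n, cfg$mean_depth) + 1L
  p_var <- ifelse(zyg == "het", 0.5, 0.93)
  variant <- pmax(1L, stats::rbinom(n, total, p_var))
  nondup <- pmax(1L, stats::rbinom(n, variant, 0.92))
  fwd <- stats::rbinom(n, variant, 0.5)
  rev <- variant - fwd
  hq <- stats::rbinom(n, variant, 0.85)
  exome_freq <- ifelse(in_dbsnp,
                       stats::rbeta(n, 2, 5),
                       stats::rbeta(n, 0.5, 60))
  cohort_freq <- pmin(1, exome_freq * stats::runif(n, 0.4, 1.6) +
                        stats::runif(n, 0, 0.01))
  phylop <- round(pmin(stats::rnorm(n, 0.5, 1.0), 2.4), 3)

  acc <- rep(NA_integer_, n); don <- rep(NA_integer_, n)
  splicey <- effect %in% c("splice_region", "intronic")
  side_acc <- splicey & stats::runif(n) < 0.5
  acc[side_acc] <- -sample(1:120, sum(side_acc), replace = TRUE)
  side_don <- splicey & !side_acc
  don[side_don] <- sample(1:200, sum(side_don), replace = TRUE)
  acc[effect == "canonical_splice"] <- NA_integer_
  can <- effect == "canonical_splice"
  don[can] <- sample(1:2, sum(can), replace = TRUE)

  # in silico strata: at most one pathogenic vote per background variant
  tool <- function(k) rcategory(k, c(benign = 0.6, unknown = 0.4))
  sift <- polyphen <- mutpred <- rep(NA_character_, n)
  mis <- effect == "missense"
  k <- sum(mis)
  if (k) {
    sift[mis] <- tool(k); polyphen[mis] <- tool(k); mutpred[mis] <- tool(k)
    flip <- which(mis)[stats::runif(k) < 0.2]
    which_tool <- sample(1:3, length(flip), replace = TRUE)
    sift[flip[which_tool == 1]] <- "pathogenic"
    polyphen[flip[which_tool == 2]] <- "pathogenic"
    mutpred[flip[which_tool == 3]] <- "pathogenic"
  }
  ssf_wt <- ssf_mut <- maxent_wt <- maxent_mut <-
    nnsplice_wt <- nnsplice_mut <- rep(NA_real_, n)
  sp <- splicey & (!is.na(acc) | !is.na(don))
  ks <- sum(sp)
  if (ks) {
    ssf_wt[sp] <- round(stats::runif(ks, 20, 85), 1)
    ssf_mut[sp] <- round(pmax(0, ssf_wt[sp] - stats::runif(ks, 0, 4)), 1)
    maxent_wt[sp] <- round(stats::runif(ks, 4, 10), 2)
    maxent_mut[sp] <- round(maxent_wt[sp] - stats::runif(ks, 0, 0.5), 2)
    nnsplice_wt[sp] <- round(stats::runif(ks, 0.55, 0.95), 2)
    nnsplice_mut[sp] <- round(pmax(0, nnsplice_wt[sp] -
                                     stats::runif(ks, 0, 0.04)), 2)
  }

  data.frame(sample_id = sample_id, chrom = chrom, pos = pos,
             ref = al$ref, alt = al$alt, zygosity = zyg,
             total_reads = total, variant_reads = variant,
             nondup_variant_reads = pmin(nondup, variant),
             fwd_variant_reads = fwd, rev_variant_reads = rev,
             hq_variant_reads = pmin(hq, variant),
             gene = targets$gene[ti], effect = effect,
             acceptor_offset = acc, donor_offset = don,
             in_dbsnp130 = in_dbsnp, in_hgmd = FALSE,
             known_blindness = FALSE,
             exome_freq = round(exome_freq, 4),
             cohort_freq = round(cohort_freq, 4), phylop = phylop,
             sift = sift, polyphen = polyphen, mutpred = mutpred,
             ssf_wt = ssf_wt, ssf_mut = ssf_mut,
             maxent_wt = maxent_wt, maxent_mut = maxent_mut,
             nnsplice_wt = nnsplice_wt, nnsplice_mut = nnsplice_mut,
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# planted causal variants

CAUSAL_EFFECT_PROBS <- c(missense = 0.45, nonsense = 0.22,
                         frameshift = 0.18, canonical_splice = 0.15)

# one causal variant with filter-proof support and pathogenic-grade
# annotations; `zygosity` in het/hom/hemi
plant_variant <- function(sample_id, gene_row, targets, zygosity,
                          effect = NULL, weak_support = FALSE,
                          avoid_pos = integer()) {
  gt <- targets[targets$gene == gene_row$gene, , drop = FALSE]
  repeat {
    ti <- sample(nrow(gt), 1)
    pos <- as.integer(gt$start[ti] +
      floor(stats::runif(1) * (gt$end[ti] - gt$start[ti])) + 1L)
    if (!pos %in% avoid_pos) break
  }
  al <- random_alleles(1)
  if (is.null(effect)) effect <- rcategory(1, CAUSAL_EFFECT_PROBS)

  if (weak_support) {
    # below both high-quality designation rules and the support criterion
    total <- 4L; variant <- 2L; nondup <- 2L; fwd <- 1L; rev <- 1L; hq <- 4L
  } else {
    total <- stats::rpois(1, 30) + 15L
    variant <- if (zygosity == "het") {
      max(ceiling(0.3 * total), stats::rbinom(1, total, 0.5))
    } else max(ceiling(0.85 * total), stats::rbinom(1, total, 0.95))
    variant <- min(variant, total)
    nondup <- max(3L, stats::rbinom(1, variant, 0.95))
    nondup <- min(nondup, variant)
    fwd <- max(1L, min(variant - 1L, stats::rbinom(1, variant, 0.5)))
    rev <- variant - fwd
    hq <- max(5L, stats::rbinom(1, variant, 0.9))
    hq <- min(hq, variant)
  }

  known <- stats::runif(1) < 0.15   # some causal alleles are catalogued
  mis <- effect == "missense"
  triple <- if (mis) {
    pick <- rcategory(1, c(PPP = 0.6, PPB = 0.2, PPU = 0.2))
    switch(pick,
           PPP = c("pathogenic", "pathogenic", "pathogenic"),
           PPB = sample(c("pathogenic", "pathogenic", "benign")),
           PPU = sample(c("pathogenic", "pathogenic", "unknown")))
  } else rep(NA_character_, 3)
  can <- effect == "canonical_splice"
  don <- if (can) sample(1:2, 1) else NA_integer_

  v <- empty_variant_table()[0, ]
  v[1, ] <- NA
  v$sample_id <- sample_id; v$chrom <- gt$chrom[ti]; v$pos <- pos
  v$ref <- al$ref; v$alt <- al$alt; v$zygosity <- zygosity
  v$total_reads <- total; v$variant_reads <- variant
  v$nondup_variant_reads <- nondup; v$fwd_variant_reads <- fwd
  v$rev_variant_reads <- rev; v$hq_variant_reads <- hq
  v$gene <- gene_row$gene; v$effect <- effect
  v$acceptor_offset <- NA_integer_; v$donor_offset <- don
  v$in_dbsnp130 <- known; v$in_hgmd <- FALSE; v$known_blindness <- known
  v$exome_freq <- round(stats::runif(1, 0, 0.008), 4)
  v$cohort_freq <- round(stats::runif(1, 0, 0.02), 4)
  v$phylop <- round(stats::runif(1, 2.6, 6), 3)
  v$sift <- triple[1]; v$polyphen <- triple[2]; v$mutpred <- triple[3]
  if (can) {
    v$ssf_wt <- 78.5; v$ssf_mut <- 21.0
    v$maxent_wt <- 9.2; v$maxent_mut <- 2.1
    v$nnsplice_wt <- 0.93; v$nnsplice_mut <- 0.08
  }
  v
}

random_marker_alleles <- function(n_markers, pool = 8) {
  matrix(as.character(sample(pool, 2 * n_markers, replace = TRUE)),
         ncol = 2)
}

marker_frame <- function(family_id, individual_id, alleles) {
  data.frame(family_id = family_id, individual_id = individual_id,
             marker_id = sprintf("MK%02d", seq_len(nrow(alleles))),
             allele1 = alleles[, 1], allele2 = alleles[, 2],
             stringsAsFactors = FALSE)
}

#' Plant a de novo mutation in a trio
#'
#' Emits a causal variant carried by the child but by neither parent,
#' together with a fully Mendelian-consistent polymorphic marker panel
#' that confirms the parental relationships.  In a dominant gene the
#' child receives a single de novo heterozygous truncating variant; in a
#' recessive gene the child receives a compound-heterozygous pair of
#' which one allele is maternally inherited and the other de novo.
#'
#' @param family one family's pedigree rows; must contain the proband and
#'   both parents (a trio).
#' @param gene_row one row of the gene panel.
#' @param targets target data.frame.
#' @param proband_id the child's individual id.
#' @param mode `"AD"` (single de novo allele) or `"AR"` (maternal +
#'   de novo pair).
#' @param marker_count polymorphic markers to generate.
#' @return list with `variants`, `relative_genotypes`, `markers`,
#'   `de_novo_loci`.
#' @export
plant_de_novo <- function(family, gene_row, targets, proband_id,
                          mode = c("AD", "AR"), marker_count = 16L) {
  mode <- match.arg(mode)
  pro <- family[family$individual_id == proband_id, , drop = FALSE]
  if (nrow(pro) != 1L || is.na(pro$father_id) || is.na(pro$mother_id) ||
      !all(c(pro$father_id, pro$mother_id) %in% family$individual_id))
    stop("de novo planting requires a full trio")
  fam <- pro$family_id

  v1 <- plant_variant(proband_id, gene_row, targets, "het",
                      effect = if (mode == "AD") "nonsense" else NULL)
  variants <- v1
  rel <- data.frame(family_id = fam,
                    individual_id = c(pro$father_id, pro$mother_id),
                    chrom = v1$chrom, pos = v1$pos, ref = v1$ref,
                    alt = v1$alt, gt = c("ref_ref", "ref_ref"),
                    stringsAsFactors = FALSE)
  de_novo_loci <- variant_key(v1)
  if (mode == "AR") {
    v2 <- plant_variant(proband_id, gene_row, targets, "het",
                        avoid_pos = v1$pos)
    variants <- rbind(v1, v2)
    rel <- rbind(rel, data.frame(
      family_id = fam,
      individual_id = c(pro$father_id, pro$mother_id),
      chrom = v2$chrom, pos = v2$pos, ref = v2$ref, alt = v2$alt,
      gt = c("ref_ref", "het"), stringsAsFactors = FALSE))
    # v1 is the de novo allele, v2 the maternally inherited one
  }

  f_al <- random_marker_alleles(marker_count)
  m_al <- random_marker_alleles(marker_count)
  pick_f <- sample(1:2, marker_count, replace = TRUE)
  pick_m <- sample(1:2, marker_count, replace = TRUE)
  c_al <- cbind(f_al[cbind(seq_len(marker_count), pick_f)],
                m_al[cbind(seq_len(marker_count), pick_m)])
  markers <- rbind(marker_frame(fam, proband_id, c_al),
                   marker_frame(fam, pro$father_id, f_al),
                   marker_frame(fam, pro$mother_id, m_al))
  list(variants = variants, relative_genotypes = rel, markers = markers,
       de_novo_loci = de_novo_loci)
}

# ---------------------------------------------------------------------------
# whole-cohort simulation

scenario_counts <- function(mix, n) {
  k <- floor(mix * n)
  rem <- n - sum(k)
  if (rem > 0) {
    extra <- order(mix * n - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1L
  }
  k
}

pick_gene <- function(panel, want_mode, chrom_x = (want_mode == "XL")) {
  has <- vapply(panel_modes(panel), function(m) want_mode %in% m, TRUE)
  cand <- panel[has & (grepl("X$", panel$chrom) == chrom_x), , drop = FALSE]
  if (!nrow(cand)) cand <- panel[has, , drop = FALSE]
  cand[sample(nrow(cand), 1), , drop = FALSE]
}

#' Simulate a complete synthetic cohort
#'
#' Generates all pipeline inputs under the study conditions of a
#' target-capture gene-panel diagnostic screen and plants causal
#' genotypes per scenario, writing files when `out_dir` is given and
#' always returning the in-memory cohort.
#'
#' Outputs (when `out_dir` is set): `panel.tsv`, `targets.bed`,
#' `cohort.ped`, `relative_genotypes.tsv`, `markers.tsv`, per-sample
#' `<id>.vcf` / `<id>_support.tsv` / `<id>_annot.tsv` under `samples/`,
#' per-base depth tracks for the first sample (`depth_<id>.tsv`), and
#' `truth.json`.  Identical seeds yield byte-identical files.
#'
#' @param cfg [simulation_config()].
#' @param out_dir optional output directory.
#' @return list of class `rp_cohort` with elements `panel`, `targets`,
#'   `pedigree`, `variants` (single data.frame, all samples),
#'   `relative_genotypes`, `markers`, `depth` (named list of track lists),
#'   `degraded_targets`, `sexes` (named vector), `truth` (list with
#'   `samples` and `variants` data.frames).
#' @export
simulate_cohort <- function(cfg = simulation_config(), out_dir = NULL) {
  set.seed(cfg$seed)
  panel <- simulate_panel(cfg)
  targets <- simulate_targets(cfg, panel)
  degraded <- sort(sample(targets$region_id, cfg$poor_target_count))

  counts <- scenario_counts(cfg$scenario_mix, cfg$n_samples)
  scenarios <- sample(rep(names(counts), counts))
  sample_ids <- sprintf("S%03d", seq_len(cfg$n_samples))

  ped <- list(); rel <- list(); markers <- list()
  variants <- list(); truth_s <- list(); truth_v <- list()

  for (i in seq_along(sample_ids)) {
    sid <- sample_ids[i]
    scen <- scenarios[i]
    set.seed(sample_substream_seed(sid, cfg$seed))
    sex <- if (scen == "XL") "male" else
      sample(c("male", "female"), 1)
    fid <- sid
    f_id <- paste0(sid, "_F"); m_id <- paste0(sid, "_M")
    fam <- data.frame(
      family_id = fid,
      individual_id = c(sid, f_id, m_id),
      father_id = c(f_id, NA, NA), mother_id = c(m_id, NA, NA),
      sex = c(sex, "male", "female"),
      affected = c(TRUE, scen == "AD_inherited", FALSE),
      stringsAsFactors = FALSE)
    sib_id <- NULL
    if (scen %in% c("AR_hom", "AR_compound_het") &&
        stats::runif(1) < cfg$sibling_prob) {
      sib_id <- paste0(sid, "_S")
      fam <- rbind(fam, data.frame(
        family_id = fid, individual_id = sib_id, father_id = f_id,
        mother_id = m_id, sex = sample(c("male", "female"), 1),
        affected = TRUE, stringsAsFactors = FALSE))
    }

    planted <- empty_variant_table()
    rel_i <- NULL; mk_i <- NULL
    de_novo_loci <- character(); mode <- NA_character_
    gene <- NA_character_

    rel_row <- function(v, ids, gts) data.frame(
      family_id = fid, individual_id = ids, chrom = v$chrom, pos = v$pos,
      ref = v$ref, alt = v$alt, gt = gts, stringsAsFactors = FALSE)

    if (scen == "AR_hom") {
      g <- pick_gene(panel, "AR"); gene <- g$gene; mode <- "AR"
      v <- plant_variant(sid, g, targets, "hom")
      planted <- v
      rel_i <- rel_row(v, c(f_id, m_id), c("het", "het"))
      if (!is.null(sib_id))
        rel_i <- rbind(rel_i, rel_row(v, sib_id, "hom_alt"))
    } else if (scen == "AR_compound_het") {
      g <- pick_gene(panel, "AR"); gene <- g$gene; mode <- "AR"
      v1 <- plant_variant(sid, g, targets, "het")          # paternal
      v2 <- plant_variant(sid, g, targets, "het",
                          avoid_pos = v1$pos)              # maternal
      planted <- rbind(v1, v2)
      rel_i <- rbind(rel_row(v1, c(f_id, m_id), c("het", "ref_ref")),
                     rel_row(v2, c(f_id, m_id), c("ref_ref", "het")))
      if (!is.null(sib_id))
        rel_i <- rbind(rel_i, rel_row(v1, sib_id, "het"),
                       rel_row(v2, sib_id, "het"))
    } else if (scen == "AD_inherited") {
      g <- pick_gene(panel, "AD"); gene <- g$gene; mode <- "AD"
      v <- plant_variant(sid, g, targets, "het")
      planted <- v
      rel_i <- rel_row(v, c(f_id, m_id), c("het", "ref_ref"))
    } else if (scen == "AD_de_novo") {
      g <- pick_gene(panel, "AD"); gene <- g$gene; mode <- "AD"
      dn <- plant_de_novo(fam, g, targets, sid, mode = "AD",
                          marker_count = cfg$de_novo_marker_count)
      planted <- dn$variants; rel_i <- dn$relative_genotypes
      mk_i <- dn$markers; de_novo_loci <- dn$de_novo_loci
    } else if (scen == "XL") {
      g <- pick_gene(panel, "XL"); gene <- g$gene; mode <- "XL"
      v <- plant_variant(sid, g, targets, "hemi")
      planted <- v
      rel_i <- rel_row(v, c(f_id, m_id), c("ref_ref", "het"))
    }

    bg <- simulate_background(sid, sex, targets, cfg)
    # background must not collide with planted loci
    if (nrow(planted))
      bg <- bg[!variant_key(bg) %in% variant_key(planted), , drop = FALSE]

    # Sanger-confirmation truth: indel-type background calls first
    n_fail <- round(cfg$fraction_false_indels * nrow(bg))
    indel_first <- order(!bg$effect %in% c("frameshift", "inframe_indel"),
                         stats::runif(nrow(bg)))
    sanger_fail_keys <- paste(sid,
                              variant_key(bg)[indel_first[seq_len(n_fail)]])
    if (n_fail == 0L) sanger_fail_keys <- character()

    all_v <- rbind(planted, bg)

    # variants inside degraded targets are not detectable
    dg <- targets[targets$region_id %in% degraded, , drop = FALSE]
    in_degraded <- rep(FALSE, nrow(all_v))
    for (j in seq_len(nrow(dg)))
      in_degraded <- in_degraded |
        (all_v$chrom == dg$chrom[j] & all_v$pos > dg$start[j] &
           all_v$pos <= dg$end[j])
    detectable_planted <- if (nrow(planted))
      !in_degraded[seq_len(nrow(planted))] else logical()
    emitted <- all_v[!in_degraded, , drop = FALSE]

    variants[[sid]] <- emitted
    ped[[sid]] <- fam
    if (!is.null(rel_i)) rel[[sid]] <- rel_i
    if (!is.null(mk_i)) markers[[sid]] <- mk_i

    expected_solved <- scen != "unsolved" && nrow(planted) > 0 &&
      all(detectable_planted)
    truth_s[[sid]] <- data.frame(
      sample_id = sid, scenario = scen, gene = gene, mode = mode,
      sex = sex, expected_solved = expected_solved,
      n_sanger_fail_background = n_fail, stringsAsFactors = FALSE)
    if (nrow(planted))
      truth_v[[sid]] <- data.frame(
        sample_id = sid, locus = variant_key(planted),
        gene = planted$gene, zygosity = planted$zygosity,
        effect = planted$effect,
        intended_class = ifelse(
          planted$effect %in% TRUNCATING_EFFECTS, "pathogenic",
          "probably_pathogenic"),
        de_novo = variant_key(planted) %in% de_novo_loci,
        detectable = detectable_planted, stringsAsFactors = FALSE)
    attr(truth_s[[sid]], "sanger_fail_keys") <- sanger_fail_keys
  }

  # depth tracks for the first sample (representative; per-base tracks for
  # every sample would dominate the output volume without adding signal)
  set.seed(sample_substream_seed(paste0(sample_ids[1], ":depth"),
                                 cfg$seed))
  depth <- list()
  depth[[sample_ids[1]]] <- simulate_depth_tracks(targets, cfg, degraded)

  sanger_fails <- unlist(lapply(truth_s, attr, "sanger_fail_keys"),
                         use.names = FALSE)
  cohort <- structure(list(
    cfg = cfg,
    panel = panel, targets = targets,
    pedigree = do.call(rbind, c(unname(ped),
                                list(make.row.names = FALSE))),
    variants = do.call(rbind, c(unname(variants),
                                list(make.row.names = FALSE))),
    relative_genotypes = if (length(rel))
      do.call(rbind, c(unname(rel), list(make.row.names = FALSE))) else
        NULL,
    markers = if (length(markers))
      do.call(rbind, c(unname(markers), list(make.row.names = FALSE)))
      else NULL,
    depth = depth, degraded_targets = degraded,
    sexes = stats::setNames(
      vapply(truth_s, function(t) t$sex, ""),
      vapply(truth_s, function(t) t$sample_id, "")),
    truth = list(
      samples = do.call(rbind, c(unname(truth_s),
                                 list(make.row.names = FALSE))),
      variants = if (length(truth_v))
        do.call(rbind, c(unname(truth_v), list(make.row.names = FALSE)))
        else NULL,
      sanger_fail_keys = sanger_fails)
  ), class = "rp_cohort")

  assert_planted_pass_filters(cohort)
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

# every planted, detectable variant must pass the calling-quality
# designation and criteria 1-5 by construction
assert_planted_pass_filters <- function(cohort,
                                        cfg = threshold_config()) {
  tv <- cohort$truth$variants
  if (is.null(tv)) return(invisible(TRUE))
  det <- tv[tv$detectable, , drop = FALSE]
  v <- cohort$variants
  idx <- match(paste(det$sample_id, det$locus),
               paste(v$sample_id, variant_key(v)))
  if (anyNA(idx))
    stop("internal: planted detectable variant missing from call set")
  pv <- v[idx, , drop = FALSE]
  ok <- is_high_quality(pv, cfg) & passes_effect_filter(pv, cfg) &
    passes_novelty_filter(pv) & passes_frequency_filters(pv, cfg) &
    passes_support_filter(pv, cfg)
  if (!all(ok))
    stop("internal: planted variant fails a prioritization criterion at ",
         det$locus[!ok][1])
  invisible(TRUE)
}

#' Write a cohort to disk in the pipeline's file dialects
#'
#' @param cohort `rp_cohort`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(file.path(out_dir, "samples"), recursive = TRUE,
             showWarnings = FALSE)
  write_panel(cohort$panel, file.path(out_dir, "panel.tsv"))
  write_targets(cohort$targets, file.path(out_dir, "targets.bed"))
  write_pedigree(cohort$pedigree, file.path(out_dir, "cohort.ped"))
  if (!is.null(cohort$relative_genotypes))
    write_relative_genotypes(cohort$relative_genotypes,
                             file.path(out_dir, "relative_genotypes.tsv"))
  if (!is.null(cohort$markers))
    write_markers(cohort$markers, file.path(out_dir, "markers.tsv"))
  for (sid in unique(cohort$variants$sample_id)) {
    sv <- cohort$variants[cohort$variants$sample_id == sid, , drop = FALSE]
    write_variant_files(
      sv,
      file.path(out_dir, "samples", paste0(sid, ".vcf")),
      file.path(out_dir, "samples", paste0(sid, "_support.tsv")),
      file.path(out_dir, "samples", paste0(sid, "_annot.tsv")),
      sample_id = sid)
  }
  for (sid in names(cohort$depth))
    write_depth(cohort$depth[[sid]],
                file.path(out_dir, paste0("depth_", sid, ".tsv")))
  truth <- list(samples = cohort$truth$samples,
                variants = cohort$truth$variants,
                sanger_fail_keys = cohort$truth$sanger_fail_keys,
                degraded_targets = cohort$degraded_targets)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       dataframe = "rows", auto_unbox = FALSE, digits = NA,
                       na = "null")
  invisible(out_dir)
}

#' The 12-sample validation fixture
#'
#' A preset cohort mirroring an assay-validation experiment: 12 samples,
#' each planted with a known compound-heterozygous mutation pair in a
#' recessive gene (24 mutations in total), of which three are rendered
#' undetectable upstream of filtering — two by placing the first sample's
#' entire pair inside a zero-coverage (capture-failed) target and one by
#' giving the second sample's second allele read support below the
#' high-quality designation.  The three dropouts therefore sit in exactly
#' two distinct samples.
#'
#' @param seed master seed.
#' @param mean_background_variants background variant load per sample.
#' @return `rp_cohort` whose truth records 21 of 24 planted mutations as
#'   detectable and 10 of 12 samples as solvable.
#' @export
simulate_validation_fixture <- function(seed = 1L,
                                        mean_background_variants = 1274) {
  cfg <- simulation_config(
    seed = seed, n_samples = 12L,
    mean_background_variants = mean_background_variants,
    scenario_mix = c(AR_hom = 0, AR_compound_het = 1, AD_inherited = 0,
                     AD_de_novo = 0, XL = 0, unsolved = 0),
    poor_target_count = 0L, sibling_prob = 0)
  cohort <- simulate_cohort(cfg)
  v <- cohort$variants
  tv <- cohort$truth$variants
  ts <- cohort$truth$samples

  # sample 1: both alleles of the pair fall in one capture-failed target
  s1 <- ts$sample_id[1]
  s1_loci <- tv$locus[tv$sample_id == s1]
  s1_rows <- match(paste(s1, s1_loci), paste(v$sample_id, variant_key(v)))
  tgt <- locate_target(cohort$targets, v$chrom[s1_rows[1]],
                       v$pos[s1_rows[1]])
  tg <- cohort$targets[cohort$targets$region_id == tgt, , drop = FALSE]
  # move the second allele into the same target so one capture failure
  # removes the pair
  old_pos <- v$pos[s1_rows[2]]
  new_pos <- tg$start + 1L +
    (v$pos[s1_rows[1]] - tg$start + 37L) %% (tg$end - tg$start)
  if (new_pos == v$pos[s1_rows[1]])
    new_pos <- tg$start + 1L + (new_pos - tg$start) %% (tg$end - tg$start)
  old_locus <- s1_loci[2]
  v$pos[s1_rows[2]] <- new_pos
  new_locus <- variant_key(v[s1_rows[2], , drop = FALSE])
  tv$locus[tv$sample_id == s1 & tv$locus == old_locus] <- new_locus
  rg <- cohort$relative_genotypes
  sel <- rg$family_id == s1 &
    paste(rg$chrom, rg$pos, rg$ref, rg$alt, sep = ":") == old_locus
  rg$pos[sel] <- new_pos
  cohort$relative_genotypes <- rg

  cohort$degraded_targets <- tgt
  # drop every sample-1 call inside the degraded target (background calls
  # there vanish with the capture failure too)
  in_tgt <- v$sample_id == s1 & v$chrom == tg$chrom &
    v$pos > tg$start & v$pos <= tg$end
  v <- v[!in_tgt, , drop = FALSE]
  tv$detectable[tv$sample_id == s1] <- FALSE

  # sample 2: second allele present but below the calling-quality rules
  s2 <- ts$sample_id[2]
  s2_loci <- tv$locus[tv$sample_id == s2]
  r2 <- match(paste(s2, s2_loci[2]), paste(v$sample_id, variant_key(v)))
  v$total_reads[r2] <- 4L; v$variant_reads[r2] <- 2L
  v$nondup_variant_reads[r2] <- 2L
  v$fwd_variant_reads[r2] <- 1L; v$rev_variant_reads[r2] <- 1L
  v$hq_variant_reads[r2] <- 2L
  tv$detectable[tv$sample_id == s2 & tv$locus == s2_loci[2]] <- FALSE

  ts$expected_solved[ts$sample_id %in% c(s1, s2)] <- FALSE
  cohort$variants <- v
  cohort$truth$variants <- tv
  cohort$truth$samples <- ts
  # degrade the depth track of the failed target if present
  for (sid in names(cohort$depth))
    cohort$depth[[sid]] <- degrade_targets(cohort$depth[[sid]], tgt)
  cohort
}

locate_target <- function(targets, chrom, pos) {
  hit <- targets$chrom == chrom & pos > targets$start & pos <= targets$end
  if (!any(hit)) stop("position not inside any target")
  targets$region_id[which(hit)[1]]
}
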