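# rptriage

Gene-panel variant triage and diagnostic-yield analysis for retinitis
pigmentosa (RP) and other genetically heterogeneous Mendelian diseases.

Molecular diagnostics for RP has to contend with 50+ causal genes, every
mode of inheritance, and mostly isolated patients whose inheritance mode
is unknown. Target-capture sequencing of a full retinal-gene panel
yields on the order of 1,200 variants per patient; `rptriage`
implements the downstream decision pipeline that turns those calls into
a per-patient molecular diagnosis:

- **Coverage QC** — per-target median depth, fraction of bases ≥ k×, an
  evenness score (E = (100/⌈m⌉)·Σᵢ P(depth ≥ i), 100 for uniform
  coverage), and poor-target flagging (median < 5×).
- **Calling-quality designation** — a call is high quality iff it has
  ≥ 3 nonduplicate reads with both strands represented, or ≥ 5 reads
  with base quality > 20.
- **Six-rule prioritization cascade** — effect class (nonsynonymous or
  within 8 bp of a splice acceptor / 20 bp of a donor), dbSNP novelty
  (with HGMD/known-mutation exceptions), ≤ 5% exome-cohort and ≤ 15%
  disease-cohort frequency, read support (≥ 10 reads with ≥ 20% variant
  reads or ≥ 5 with 80–100%), and per-gene inheritance consistency —
  plus a second-allele rescue that re-searches the unfiltered call set
  when a recessive gene retains a single heterozygous nonsense or
  canonical-splice allele.
- **Three-axis pathogenicity classifier** — truncating variants are
  pathogenic outright; others combine an in silico tool vote
  (SIFT/PolyPhen/MutPred classes, or SpliceSiteFinder/MaxEntScan/
  NNSplice wt–mut cutoffs), PhyloP conservation banding (< 1 benign,
  > 2.5 pathogenic) and dual-cohort frequency banding, with a
  frequency-benign override and a majority vote over the axes.
- **Segregation & de novo analysis** — co-segregation verdicts
  (full/partial/contradicted/untested) under AR/AD/XL models, de novo
  detection in trios, marker-based Mendelian (paternity) consistency,
  compound-het trans-phase inference, and multilocus (cumulative load)
  flagging.
- **Cohort statistics** — funnel reduction, detection/solved/
  confirmation rates, enrichment, and the projected diagnostic yield
  for a full referral cohort.
- **Synthetic cohorts** — a seeded, byte-reproducible generator that
  emits panel/BED/PED/VCF/TSV inputs with causal genotypes planted
  under recessive, dominant, de novo and X-linked scenarios, plus a
  machine-readable truth record.

## Worked example

```r
library(rptriage)

cfg    <- simulation_config(seed = 42, n_samples = 20)
cohort <- simulate_cohort(cfg)        # in memory; add out_dir= to write files
res    <- run_pipeline(cohort)
res$summary
#> Cohort of 20 samples
#>   auto-detected (mean/sample): 1261
#>   selected for validation    : 106 (mean 5.3/sample)
#>   funnel reduction           : 99.6%
#>   solved                     : 7 (35%)
#>   Sanger confirmation rate   : 78%
```

Each sample's ~1,260 automatically detected variants are reduced by
99.6% to ~5 validation candidates; 7 of 20 samples receive a molecular
diagnosis, and comparing against the generator's truth record shows the
7 are exactly the planted solvable scenarios:

```r
solved <- vapply(res$per_sample, function(p) p$diagnosis$solved, TRUE)
table(cohort$truth$samples$scenario, solved[cohort$truth$samples$sample_id])
#>                   FALSE TRUE
#>   AD_inherited        0    1
#>   AR_compound_het     0    3
#>   AR_hom              0    3
#>   unsolved           13    0
```

Coverage QC on the emitted depth tracks flags exactly the 15 degraded
targets of 2,011 (0.7%):

```r
coverage_report(cohort$depth[[1]])
#> Coverage report: 2011 targets
#>   mean coverage   : 25.6x
#>   bases >= 10x    : 96.8%
#>   evenness score  : 83.5%
#>   poor targets    : 15 (0.7%)
```

A thin CLI wraps the same functions (`exec/rptriage`):

```sh
rptriage simulate --seed 1 --samples 20 --out-dir cohort/
rptriage triage   --cohort-dir cohort/ --sample S001 --out-prefix S001
rptriage report   --cohort-dir cohort/ --out-prefix cohort
```

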