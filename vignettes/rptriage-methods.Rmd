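---
title: "Methods: gene-panel variant triage for retinitis pigmentosa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-panel variant triage for retinitis pigmentosa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rptriage)
```

## The diagnostic problem

Retinitis pigmentosa (RP) is an inherited retinal degeneration with
extreme locus heterogeneity: mutations in more than fifty genes cause
nonsyndromic RP alone, under autosomal recessive, autosomal dominant and
X-linked inheritance, and most patients are isolated cases whose mode of
inheritance is unknown. Target-capture sequencing of a full retinal-gene
panel finds on the order of a thousand variants per patient; the
diagnostic task is to reduce those to a handful of validation candidates
and to decide, per patient, whether a molecular diagnosis is supported.

`rptriage` implements that decision pipeline as composable, testable
pieces: capture coverage QC, a calling-quality designation, a six-rule
prioritization cascade with a second-allele rescue step for recessive
genes, a three-axis rule-based pathogenicity classifier, family-level
segregation and de novo analysis, and cohort-level yield statistics. A
seeded generator produces complete synthetic cohorts with planted causal
genotypes so that every stage, and the pipeline end to end, can be tested
without patient data.

## Coverage quality control

Per-base depth tracks over the capture targets yield per-target median
coverage (even-length targets use the mean of the central pair), the
fraction of target bases covered at least $k\times$, and an evenness
score. For mean depth $m$ the evenness is

$$E = \frac{100}{\lceil m\rceil}\sum_{i=1}^{\lceil m\rceil} P(d \ge i),$$

where $P(d \ge i)$ is the fraction of target bases with depth at least
$i$. Perfectly uniform coverage gives $E = 100$; any non-uniform profile
is strictly below 100 (both properties are tested, the second by brute
force over random profiles). The published evenness summary this mirrors
is cited to Mokry and colleagues without a printed formula; the
cumulative-coverage definition above is this package's documented
reading, anchored by the uniform-coverage = 100 property.

Targets whose median depth falls below 5 are flagged poor — in a
2,011-target panel a capture failure of 15 targets is reported as 0.7%.
Bases mapped within 500 bp of a target count as "near target"; this
needs read placements, so the field is `NA` when only depth tracks are
available.

## Calling quality and the prioritization cascade

A called difference is designated high quality when (1) at least three
nonduplicate reads support it, including at least one forward and one
reverse read, or (2) at least five reads with base quality above 20
support it. Low-quality calls never enter the cascade.

The cascade then applies six criteria:

1. **Effect**: nonsynonymous (missense, nonsense, frameshift, in-frame
   indel), canonical splice site and large-deletion variants pass;
   `splice_region`/`intronic` variants pass only within 8 bp of a splice
   acceptor or 20 bp of a splice donor. The windows are measured on the
   intronic side; the canonical ±1/±2 positions are their own effect
   class and always pass.
2. **Novelty**: variants catalogued in dbSNP130 fail unless reported in
   HGMD or known as pathogenic blindness mutations.
3. **Exome-cohort frequency**: fail above 5% in the reference exome
   cohort.
4. **Disease-cohort frequency**: fail above 15% in the panel cohort.
   Both frequency bounds are strict ("greater than"), so boundary values
   pass.
5. **Read support**: at least 10 reads with ≥ 20% variant reads, or at
   least 5 reads with 80–100% variant reads. Both branches read "reads"
   as total site depth with a variant-read fraction; the alternative
   reading (variant reads in the second branch) is ambiguous in the
   underlying rule and is noted here as the road not taken.
6. **Inheritance consistency**, per gene: a recessive-capable gene needs
   a homozygote or two distinct heterozygous loci (phase is not required
   at this stage); a dominant-capable gene keeps any het/hom; an
   X-linked gene keeps hemizygous variants in males and biallelic
   genotypes in females. Multi-mode genes keep the union.

Criteria 1–5 are pure per-variant predicates, so the cascade equals
their conjunction followed by the per-gene inheritance rule — a property
the tests verify against an independently coded brute-force evaluation.

**Second-allele rescue.** When criteria 1–5 leave a single strong
candidate — a heterozygous nonsense or canonical splice variant — in a
recessive-capable gene, the unfiltered (high-quality) variant set of that
gene is searched for a second allele. The search relaxes novelty and
frequency (a true second allele may be catalogued or locally frequent)
but deliberately retains effect and read support, so sequencing noise
cannot be rescued; this narrowing of "unfiltered" is a design choice of
this package and is covered by tests. The strong anchor re-enters the
shortlist together with any partner found. Frameshift anchors do not
trigger the search: the rescue rule is stated for nonsense and canonical
splice alleles only, and we keep that literal scope.

## Pathogenicity classification

Truncating variants (nonsense, frameshift, canonical splice, large
deletion) are *pathogenic* outright. All other variants are scored on
three axes, each three-state (pathogenic / unknown / benign):

- **In silico tools.** Missense variants take a majority vote over three
  missense tool classes (SIFT, PolyPhen, MutPred); noncanonical splice
  variants vote over three splice tools with fixed wt/mut cutoffs —
  SpliceSiteFinder: pathogenic if wt > 50 and mut < 50, else unknown if
  wt − mut > 5, else benign; MaxEntScan: pathogenic if wt − mut > 0.8,
  benign if wt = mut, else unknown; NNSplice: pathogenic if wt > 0.5 and
  mut < 0.5, else unknown if wt − mut > 0.05, else benign. The MaxEntScan
  difference is directional (wt − mut, loss of splice strength): a score
  *gain* lands in unknown, never pathogenic. A three-way split at tool
  level maps to unknown, mirroring the stated rule for the final
  combination. A variant that is both missense and near a splice site
  uses the missense vote.
- **Conservation.** PhyloP (44-way) below 1 is benign, above 2.5
  pathogenic, intermediate (boundaries included) unknown.
- **Frequency.** Exome-cohort frequency above 3% is benign; 1–3%
  (inclusive), or a disease-cohort frequency of 3% or more, is unknown;
  the rest is pathogenic on this axis.

The final verdict applies a frequency override — frequency-benign means
*probably benign* regardless of the other axes — then a majority vote;
a three-way split is *unknown*. Majority pathogenic yields *probably
pathogenic* (plain *pathogenic* is reserved for truncating variants).
The full 27-cell combination table is exported
(`combination_truth_table()`) and tested cell by cell against a
hand-enumerated oracle, including all nine override cells. Raising the
exome frequency can never move a verdict toward pathogenic (tested as a
monotonicity property).

## Segregation and de novo analysis

`check_segregation()` tests candidate genotypes against affection status
under a fixed mode: recessive — every affected member carries both
alleles (hom, or het at both loci of a compound-het pair) and no
unaffected member does; dominant — affected carry, unaffected are
reference; X-linked — affected males hemizygous, unaffected males
reference, females may carry one allele silently. Any violation by a
typed member gives *contradicted*; no typed relatives gives *untested*;
all relatives typed and consistent gives *full*, otherwise *partial*.
The full/partial boundary (all-typed vs some-typed) is a convention of
this package; the underlying workflow does not quantify "partial".

`detect_de_novo()` distinguishes true (child carries, both parents typed
reference), false (a parent carries) and *untestable* (a parent
genotype missing) — the missing-parent case is deliberately not `FALSE`.
`mendelian_consistency()` checks a polymorphic marker panel in the trio:
a marker is consistent when the child's allele pair splits into one
paternal and one maternal allele; a fully consistent panel (e.g., 16/16)
confirms parenthood and thereby the de novo event. When marker data are
present, the pipeline requires this confirmation before reporting a de
novo; without markers the event is only "apparent de novo".
`check_trans_phase()` infers cis/trans for compound-het pairs from
parental origins (one inherited plus one de novo allele counts as
trans), and `detect_multilocus()` flags samples with pathogenic-tier,
mode-consistent variants in two or more genes (cumulative mutational
load).

A sample is **solved** when some gene carries pathogenic-tier variants
satisfying one of its modes' allele counts and segregation does not
contradict that mode. Untested or partial segregation does not block a
diagnosis — cohorts legitimately include diagnoses without full
segregation — but a contradiction vetoes the gene.

## Yield statistics and rounding conventions

Rounding is pinned per statistic to reproduce conventional reporting:
detection rate and funnel reduction to one decimal; solved rate,
confirmation rate and projected yield as integer percent; enrichment
truncated (not rounded) at one decimal, except below 1% where two
rounded decimals are reported. The projected cohort yield rounds each
extrapolated patient count to whole patients before summing:

$$\text{yield} = \frac{\operatorname{round}(n_{\text{prev}}\cdot r_{\text{val}}) + n_{\text{ngs}} + \operatorname{round}(n_{\text{untested}}\cdot r_{\text{ngs}})}{n_{\text{total}}}.$$

## The synthetic cohort generator

The generator emulates the study conditions of a 12-plex capture screen:
a 111-gene panel (predominantly recessive genes, a minority dominant or
dual-mode, a few X-linked), 2,011 targets of ≥ 250 bp, per-sample
background variant counts Poisson with mean 1,274, mean target depth
26×, 15 capture-failed targets, and a scenario mix over planted causal
genotypes — AR homozygous 13%, AR compound-het 14%, AD inherited 3%, AD
de novo 3%, X-linked 3%, unsolved 64% — chosen to mirror a 100-patient
referral cohort with 36 diagnoses (27 recessive, 6 dominant, 3
X-linked). All randomness flows from one master seed; per-sample
substreams are derived by a stable hash of the sample id, so output is
byte-identical across runs and independent of generation order.

Background annotation strata are explicit artifact choices, documented
here because the real joint distribution of annotations is unknown:

- catalogued (dbSNP) status is Bernoulli(0.94) for non-truncating calls;
  background truncating calls are always catalogued, reserving novel
  truncating alleles for planted mutations;
- exome frequencies are Beta(2, 5) for catalogued and Beta(0.5, 60) for
  novel variants; zygosity follows frequency (rare variants are almost
  always heterozygous);
- background PhyloP is normal (0.5, 1) capped below the 2.5 pathogenic
  cutoff, and background in silico votes carry at most one pathogenic
  call, so pathogenic-tier classification evidence arises only from
  planted variants.

The last two choices buy structural specificity: unsolved-scenario
samples can never be called solved, which makes the recovery tests
exact. The corresponding limitation is real and stated: actual cohorts
contain incidental variants with pathogenic-looking annotations, so the
zero-false-positive behaviour of the pipeline on synthetic data says
nothing about its specificity on real data — it validates the plumbing,
the rule logic and the funnel mechanics, not clinical performance. The
generator also does not model sequence content (no FASTQ, no GC model),
homopolymer error mechanics (non-confirming calls are simply marked in
the truth record, indel-type calls first, at a configurable 21%
fraction), or phasing beyond parental genotypes.

A fixed preset, `simulate_validation_fixture()`, mirrors an
assay-validation experiment: 12 samples each carrying a known
compound-heterozygous pair (24 mutations), with three made undetectable
upstream of filtering — one sample's entire pair lost to a zero-coverage
capture-failed target and a second sample's second allele dropped below
the calling-quality rules — so the fixture reproduces a 21/24 = 87.5%
detection rate and a 10/12 = 83% solved rate by construction of the
inputs, computed by the pipeline.

## Problem sizes and numerical choices

The test suite exercises the full cascade oracle on enumerated tables of
≤ 50 variants, segregation primitives on 1,000 randomized trios against
exhaustive transmission oracles, and end-to-end recovery on a 100-sample
cohort at the default background load (~127,000 variants), which runs in
a few seconds. Degenerate inputs are pinned: empty depth tracks,
all-zero coverage and zero-depth support are errors or fail-closed;
boundary thresholds follow the strict/inclusive readings stated above;
shortlists are sorted by gene and locus so output is deterministic.

## Known limitations

- Annotations are consumed, not computed: effect classes, tool scores
  and cohort frequencies arrive precomputed per variant.
- Phase at the filtering stage counts distinct het loci without
  parental information; phase is resolved only in segregation.
- Penetrance is assumed complete for dominant and X-linked-male
  genotypes; reduced penetrance must be handled by editing affection
  status.
- Internal mutation databases are modelled as boolean flags and
  frequency columns supplied by the user.
- No liftover, no HGVS parsing, no reference-genome validation of
  alleles, and no linkage/haplotype reconstruction beyond the
  marker-consistency primitive.
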