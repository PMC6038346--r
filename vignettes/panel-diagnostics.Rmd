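---
title: "Targeted panel diagnostics for hereditary hearing loss: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted panel diagnostics for hereditary hearing loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelvar)
library(dplyr)
```

panelvar implements the computational core of a clinical targeted-sequencing
pipeline for syndromic and non-syndromic sensorineural hearing loss (SNHL):
threshold-based SNV/indel calling, pooled-background copy-number detection,
homology-aware flagging, ACMG/AMP triage with tiered reporting, cohort
yield summarisation, and a simulator that generates every sequencing-level
input with recorded seeds. This vignette explains the models and the design
decisions behind them.

## The panel model

A diagnostic panel is a tiered gene list. Tier 1 holds genes with
strong/moderate disease association (reported from class 3 upward); tier 2
holds genes with weak or preliminary association (reported only for class
4–5 findings compatible with the patient's phenotype). The shipped fixture
`example_panel()` has 199 genes (154 tier 1, 45 tier 2) with reference
transcripts. Inheritance modes and phenotype classes are curated for the
genes that appear in the packaged case series; the remaining genes carry a
synthetic default (AR/nonsyndromic, XR for X-chromosomal genes, MT for
mitochondrial loci), which is sufficient because only the curated genes are
exercised by case-level logic.

Coordinates follow each format's native convention — target intervals are
0-based half-open (BED), per-position records 1-based (pileup/VCF) — and the
conversion lives in exactly one internal helper, so off-by-one drift cannot
creep in per module.

Callability at depth `t` (DPt) is the fraction of a gene's target bases
covered by at least `t` reads; it is computed at 10/20/50/100 by default.
DP20 is the reporting floor: positions below it enter the per-patient
low-coverage report, so a negative result can be read against the regions
where the assay had no power.

```{r callability}
targets <- tibble(chrom = "chr1", start = 0L, end = 50L,
                  gene = "GENE1", label = "e1")
depth <- tibble(chrom = "chr1", pos = 1:50, sample = "patient",
                depth = c(rep(40L, 45), rep(15L, 5)))
compute_callability(depth, targets, thresholds = c(10, 20, 50))
low_coverage_report(depth, targets)
```

## Threshold calling and the reportable range

A call is emitted for every non-reference allele with total quality-filtered
depth ≥ 6, alternate count ≥ 3 and VAF ≥ 0.1 (all comparisons inclusive).
The VAF denominator is the quality-filtered depth — base quality ≥ 20 and
mapping quality ≥ 30 gate reads when the pileup is built, so they gate the
evidence, not just the call. Reportability is stricter: depth ≥ 10 and ≥ 4
alternate reads. Calls passing the permissive but failing the strict pair
are annotated `low_confidence`, the automated stand-in for the manual-review
rescue of borderline events such as long indels with underestimated
frequencies.

Zygosity from VAF needs a homozygosity threshold the source material does
not state. We use VAF ≥ 0.80: at depth 20 and above, the binomial read-count
distributions of heterozygotes (centred at 0.5) and homozygotes (near 1.0)
are separated at 0.80 with negligible overlap, and the packaged tests verify
the separation on simulated pileups. Male X loci are hemizygous regardless
of VAF; mitochondrial loci are flagged rather than forced into diploid
labels, since heteroplasmy is out of scope.

Multi-allelic columns are evaluated per alternate allele with no tie-break:
discarding evidence automatically would pre-empt the downstream review that
such columns require. Indels are stored left-trimmed and parsimonious; the
benchmark comparator normalises both sides the same way so equivalent
spellings match.

## Copy-number detection against a pooled background

Depth normalisation is median-of-ratios: each sample's per-target counts are
divided by its own median (library size), then by the background median of
the same ratio (capture efficiency). The result is 0 in expectation for two
copies, −1 for one, +0.585 (log2 3/2) for three. The background must have at
least 8 samples — large enough for a stable median, small enough to assemble
from one capture batch. Decision thresholds (−0.6 for loss, +0.42 for gain)
sit midway between the expected levels of adjacent copy states; they are not
taken from the source material, which names the evidence types but not the
cut-offs.

Homozygous deletions are detected separately as runs of targets with
essentially no reads (≤ 2) in the test sample but proper background coverage
(median ≥ 50): a target poorly covered in everyone is uncallable, not
deleted. Allelic imbalance — exact binomial tests of heterozygous-SNP BAFs
against 0.5, combined by Fisher's method at α = 0.01 — annotates confidence
but never vetoes a depth call, because the integration weights of the
original method are not published and depth is the primary signal. Absence
of heterozygous SNPs across a long region is additional loss evidence via a
Poisson tail on the background heterozygote density.

Segmentation is rule-based merging of adjacent same-state targets within a
gene. Panel targets are sparse and exon-sized and the clinically relevant
events run from one exon to a whole gene, so an HMM or CBS would add free
parameters without adding power. Sex chromosomes are handled by requiring a
sex-matched background for X targets, under which the log2 ratios are
already relative to the correct baseline. GC correction is not implemented
and the simulator injects no GC bias; on real data this is a known gap.

```{r cnv}
sim <- simulate_patient(seed = 42,
                        events = tibble(gene = "G07", first_exon = 2,
                                        last_exon = 6, cn = 3))
ratios <- normalize_depth(sim$counts, "case")
call_cnv(ratios, sim$targets)
```

## Homology-aware calling

Regions with DP20 callability below 1 in strictly more than half the cohort
are "conflictive" — a systematic coverage defect, typically a pseudogene
shadow. The >50% rule is implemented as a strict inequality, the literal
reading of the source criterion. Homology annotation (which conflictive
regions have a high-identity counterpart) is supplied as an input table;
discovering homologous pairs by genome self-alignment is out of scope.
Variants in homologous conflictive regions are flagged
`needs_orthogonal_confirmation` and cannot support a causative diagnosis
until a confirmation record (e.g. long-range PCR plus Sanger) is supplied.
A variant recurring in ≥ 90% of the cohort inside such a region is marked
`suspected_bleed_through`: true rare variants are private, whereas a
pseudogene's reference sequence leaks into nearly every sample.

## ACMG triage, inheritance and reporting

MAF filtering is class-aware: 5% for variants with prior support (HGMD-DM,
ClinVar P/LP, or predicted null — nonsense, frameshift with premature stop,
canonical splice, start loss, whole-exon deletion/duplication) and 1% for
all other protein/RNA-affecting variants. A variant with no recorded MAF is
treated as rare and never dropped on frequency.

The combining-rules engine is a total, deterministic function of the
applied-strength multiset. The criteria grammar accepts strength modifiers
written `STRENGTH(code)` — `PS(PM3)` applies the in-trans criterion PM3 at
strong — with nesting rejected. Two conventions required a decision:

* an extra very-strong criterion (beyond the first) counts as strong, so the
  function stays total on arbitrary multisets;
* when both a pathogenic and a benign combination fire, the evidence is
  contradictory and the class is 3 (VUS). Benign rules are implemented in
  full even though the packaged case series contains no benign-classified
  rows — a classification engine that cannot classify benign evidence would
  not be total.

Replaying the 29 criteria sets of the packaged case series reproduces the
printed class for 27. The two deviations are surfaced, never absorbed: a
SOX10 frameshift where the rules give pathogenic (PVS1 + PM2 + PP3) but the
report printed likely pathogenic, and a heterozygous whole-gene deletion
carrying an explicit expert override from likely pathogenic to pathogenic.
The override mechanism records the original class and a justification.

Inheritance consistency is checked per gene: AR needs biallelic qualifying
variants (a homozygote, or ≥ 2 variants assumed in trans — compound
heterozygotes are taken at face value when phase is unknown, matching how
such pairs are reported clinically); AD needs one; de-novo-AD needs a
de novo assertion (a per-variant input, as trio analysis is out of scope);
X-linked logic keys on sex and hemizygosity. A case is diagnosed when some
gene carries an inheritance-consistent configuration of confirmed class 4–5
variants; configurations that only work when VUS count as positive are
marked suspicious, not diagnosed. A hidden syndrome is flagged when the
causative gene's phenotype is exclusively syndromic but the patient
presented as non-syndromic; phenotype matching for tier-2 reporting is a
per-variant input flag with the same rationale (clinical judgement is not
replicated, only recorded).

```{r cohort}
summarize_cohort(diagnose_cohort(build_table_fixtures()))
```

## The analytical-validation simulator

`simulate_mixture()` emulates an equimolar pool of ten deeply genotyped
reference genomes over 1,034,817 callable positions at mean depth 1000 with
per-base error 0.001: depth is Poisson around a lognormal
capture-efficiency multiplier (σ = 0.3), alternate reads at a truth locus
with mixture AF `f` are Binomial with success probability
`f(1−e) + (1−f)e/3`, and errors elsewhere are spread uniformly over the
three non-reference bases. Pileups are simulated directly at the position
level — read simulation and alignment are upstream of this pipeline, and
calling consumes pileup evidence.

The truth set holds 1624 variants (121 indels) placed on `k ≥ 2` of the 20
haplotypes, so every mixture AF is a multiple of 1/20 and at least 0.1. The
AF spectrum is the one genuinely open design choice. We model the truth
variants as well-genotyped common polymorphisms: population frequency
`q ~ Uniform(0.3, 0.7)`, `k ~ Binomial(20, q)` conditioned on `k ≥ 2`. The
reasoning is that a validation specimen of this design only behaves as
reported if variants sitting exactly at the VAF cut-off are rare — a variant
at AF = 0.10 has expected observed VAF ≈ 0.1002, so the inclusive ≥ 0.1
comparison passes it only about half the time at any depth, and a spectrum
heavy in doubletons would be inconsistent with near-total detection. Common
polymorphisms concentrate `k` well above 2 (P(k = 2) ≈ 0.4%), matching the
design of a specimen assembled from reference individuals genotyped by
population-scale projects. The range is exposed as `af_q_range` for
sensitivity analysis.

What the simulator does *not* emulate — and what passing tests therefore do
not show about real data: alignment and mapping bias, GC bias, strand
artefacts, pseudogene read bleed at the sequence level (bleed-through is
modelled as a cohort-recurrent variant, not as misaligned reads), indel
representation ambiguity beyond trimming, and batch effects in the CNV
background. Indel error events are folded into the uniform substitution
model; this suffices to exercise the thresholds but is not an indel error
model.

Problem sizes in the packaged tests: module tests use target spaces of
20,000–200,000 positions and 60–150 truth variants; the end-to-end
analytical check runs the full 1,034,817-position, 1624-variant design
once, and the copy-number parameter-recovery study uses 100 seeded
single-event simulations on a 20-gene grid at per-target depth 400. These
sizes keep each property statistically decisive while the whole suite stays
desk-scale.

## Benchmarking and sample tracking

`benchmark_calls()` matches calls to truth exactly on the normalised
(position, ref, alt) triple; genotype concordance is deliberately not
scored, since analytical validation of this kind counts detection. True
negatives are per-position: the denominator for specificity is the count of
target positions bearing no truth variant, and a position with any false
call is not a true negative. Per-type (SNV vs indel) stratification is
always reported.

Sample tracking compares sequencing-derived genotypes at six
high-heterozygosity SNPs against orthogonal genotypes; the check passes
only at 6/6 concordance. Under Hardy–Weinberg equilibrium the probability
that two *unrelated* samples agree on the whole panel is the product over
SNPs of `sum(g²)` of the genotype probabilities — about 1 in 160 at these
allele frequencies — which the test suite verifies by simulation against
the closed form in `hw_genotype_match_prob()`.

## Degenerate inputs and numerical conventions

* Empty panel, empty truth set, empty cohort: the first two return typed
  empty results (sensitivity is reported as not applicable); an empty
  cohort is an error, since a yield over zero cases is meaningless.
* Targets with no depth records are an error naming the first missing base;
  genes in the panel without targets are dropped from callability with a
  warning.
* Background targets with median ratio 0 are masked, not called.
* All threshold comparisons (depth, alternate count, VAF, log2 ratios) are
  inclusive; boundary cases are pinned by tests.
* Every simulator records its seed; identical seeds give byte-identical
  outputs.

## Known limitations

The engine classifies from supplied criteria; it does not gather evidence
(literature, cosegregation, predictor scores). Phenotype matching and de
novo status are input assertions. CNV breakpoints are reported at target
resolution, not base pair. Mitochondrial heteroplasmy, mosaic CNVs and
whole-chromosome events are out of scope. GC bias is neither modelled nor
corrected.
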