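---
title: "Screening pooled RNA-seq of a selfing cross for causal mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening pooled RNA-seq of a selfing cross for causal mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscreen)
```

## The screening design

In a self-fertilizing, highly inbred line, a recessive zygotic mutation can
be mapped without outcrossing or a reference genome. A single hermaphroditic
F1 parent heterozygous for the mutation is selfed; its F2 brood segregates
1:2:1 (hom-ref : het : hom-alt) at the causal locus. Embryos are sorted by
phenotype into a *mutant* pool (all homozygous for the causal allele) and a
phenotypically normal *sibling* pool (hom-ref : het in expected ratio 1:2,
so the causal allele is at an expected frequency of 1/3). Pooled RNA from
each group, plus a pool of the unmutagenized wild-type strain, is sequenced;
per-variant read counts then carry the genotype frequencies of each pool.
Because the background is nearly isogenic, almost no other site shows the
diagnostic pattern: alternate fraction 1.0 in the mutant pool, 0.0 in the
wild type, intermediate (≈1/3) in the siblings.

`poolscreen` implements the desk side of this design end to end: a
generative model of the cross ([simulate_cross()]), the read-count
filtering cascade that nominates candidates ([run_cascade()]), codon-level
consequence annotation ([call_consequences()], [conservation_at()]), and a
coverage-based expression comparison ([coverage_table()],
[top_downregulated()]).

## The six screens

Candidate variants must pass, in order (all "more than" comparisons are
strict; ties fail; a pool with zero reads has an *undefined* allele
fraction and conservatively fails any screen that references it):

1. **Homozygous difference** — wild-type and mutant pools are each
   homozygous (alternate fraction ≥ `screen1_hom_fraction`, default 0.9,
   or ≤ one minus it) and fixed for *different* alleles. The first pass is
   looser than exact fixation so that near-fixed sites survive to the
   stricter second screen; the cut is configurable because published
   screens of this kind do not pin down the first pass numerically.
2. **Full enrichment** — exactly 100% alternate reads in the mutant pool
   and exactly 0% in the wild type (defaults `mut_alt_fraction_required =
   1`, `wt_alt_fraction_max = 0`: a single discordant read fails the
   variant).
3. **Wild-type depth** — more than 10 wild-type reads.
4. **Mutant depth** — more than 5 mutant reads.
5. **Sibling heterozygosity** — more than 4 sibling reads of *each*
   allele.
6. **Sibling ratio** — sibling reference reads strictly exceed sibling
   alternate reads, the Mendelian expectation when carriers are
   heterozygous.

A seventh, non-synonymous condition restricts candidates to
protein-changing variants (missense, nonsense, stop-loss). Both published
orderings are defensible — tallied as a final screen or applied before
screen 1 — so [run_cascade()] exposes `nonsyn_mode = "final"` (default),
`"prefilter"`, or `"off"`. The final candidate set is identical either way
because the cascade is a pure conjunction; only the per-screen survivor
counts differ. For the same reason the final set is invariant under any
reordering of the screens, a property the test suite asserts against a
brute-force row-by-row oracle. The cascade is a deterministic filter, not
a hypothesis test: no p-values are computed and no multiple-testing
correction applies.

```{r demo}
res <- run_pipeline(poolscreen_demo_config(), out_dir = tempfile("demo_"))
res$report
```

## The generative model

[cross_model()] fixes the study conditions; [simulate_cross()] draws from
them. Defaults describe the emulated screen: 20 embryos per pool, 5000
background variant sites, negative-binomial per-site per-pool depth with
mean 50 and size 10, and a symmetric per-read allele miscall rate of
0.005.

* **Segregation.** Offspring of the selfed heterozygous founder receive
  two independent gametes, so genotypes follow Binom(2, ½) — the 1:2:1
  law. Phenotype selection conditions only the causal site: mutant-pool
  embryos are hom-alt there, sibling-pool embryos are drawn hom-ref : het
  with probability 1/3 : 2/3. Background sites segregate independently of
  phenotype (transcript variants are treated as unlinked; a selfing
  isogenic line offers no informative background polymorphism for linkage
  anyway, which is the design's point).
* **Background composition.** Each background site is heterozygous in the
  founder with probability `residual_het_rate + enu_het_rate`, otherwise
  homozygous, split evenly between reference and alternate relative to the
  wild-type strain (fixed differences). `residual_het_rate` (default
  3 × 10⁻⁴, matching 99.97% SNP homozygosity of a long-inbred strain)
  marks residual strain polymorphisms that the wild-type pool also
  segregates; `enu_het_rate` (default 0.1) marks induced mutations not yet
  fixed by the line's continued selfing — published screens give no rate,
  so both are exposed parameters with defaults we consider realistic for a
  line maintained by selfing for several generations after mutagenesis.
* **Sequencing.** RNA pools measure expression-weighted allele dosage. By
  default all embryos contribute equally; `expression_weight_dispersion`
  draws per-embryo gamma weights (mean 1) to mimic unequal expression —
  exposed because observed sibling enrichment in real screens can sit
  below the Mendelian 1/3 without the cause being identifiable from count
  data. Depth is negative-binomial (overdispersed coverage is standard for
  RNA-seq and approaches Poisson as the size parameter grows); alternate
  reads are binomial with success probability `d(1−e) + (1−d)e`, a
  symmetric biallelic flip. Third alleles are not modeled — the screen as
  implemented is biallelic — and no read-level (FASTQ) simulation is
  attempted.
* **The causal allele.** Unless configured otherwise the generator
  overwrites a random internal CDS codon with an arginine codon and plants
  a C→T transition making it cysteine — the classic CpG-type missense
  change; ground truth (founder genotypes, expected pool fractions,
  per-embryo genotypes) is returned alongside the counts.
* **Expression truth.** For the coverage comparison, 30 transcripts
  (configurable) receive a −2 log2 fold change in the mutant pool, on
  lognormal baseline means.

The generator is seeded explicitly (`seed` is mandatory; never from the
clock), and identical `(model, seed)` pairs reproduce byte-identical
output files.

### What the simulation does and does not establish

The generator reproduces the segregation arithmetic, pooling, and
count-level noise that the cascade's thresholds act on; passing tests
show the screening logic is faithful to its stated rules and recovers a
planted allele under the modeled conditions. It does not emulate
assembler or bubble-caller artifacts, mapping bias, strand effects,
linked selection near the causal locus, isoform-collapse ambiguity, or
instrument-specific error profiles — so recovery rates on real libraries
can differ from simulated ones in either direction.

### A note on exact enrichment under noise

The default screen demands *exactly* zero discordant reads in two pools.
Under a per-read miscall rate `e` and negative-binomial depth `D`, a truly
fixed site survives screen 2 with probability `E[(1−e)^D]²` — about 0.61
at the default depth 50, size 10 and `e = 0.005` — so roughly half of the
simulated screens lose the causal variant to a single miscalled read, and
the measured planted-recovery rate sits near 55–65%. This is a property
of the exact-enrichment rule itself, which we keep faithful to its
published wording; screens run at higher error rates should either trim
counts upstream (as read-trimming pipelines do) or relax
`mut_alt_fraction_required` / `wt_alt_fraction_max` deliberately. When
the causal variant does survive screen 2, the remaining screens retain it
essentially always, and the median final candidate list has length 1 —
matching the narrowing-to-one-or-two-genes behaviour such screens report.

## Consequence annotation

Coordinates are 1-based on the transcript cDNA throughout (de novo
transcripts have no genomic strand); coding positions are interpreted
against an explicit CDS annotation from the FASTA sidecar, with the codon
index `ceil((position − cds_start + 1)/3)`. Translation uses the standard
nuclear genetic code. The variant's reference allele is validated against
the cDNA, and positions outside the CDS are classed `noncoding`. No
attempt is made to reverse-engineer 5′-UTR offsets from protein-level
residue numbers reported elsewhere: the CDS sidecar is the single source
of the nt↔aa relation. Conservation of the affected residue is scored on
a protein alignment as the fraction of sequences carrying the reference
residue at the mapped column, excluding gap characters from the
denominator by default, flagged conserved at a configurable threshold
(default unanimity).

## Expression comparison

The expression pass mirrors coverage-based ranking: per-pool depths are
scaled to a common total (counts-per-million by default), and genes are
ranked by `log2((mut + pc)/(sib + pc))` with pseudo-count 1 (both
configurable). Ranking is scale- and permutation-invariant, ties break by
gene id for determinism, and no dispersion model or significance call is
made — length normalization of coverage, if wanted, belongs upstream in
the depth table. Identities of real downregulated gene lists are not
reproducible from simulation; the tests instead check the ranking
contract and that planted downregulated genes dominate the top of the
list.

## Configuration, determinism, degenerate inputs

The pipeline is configured from one hierarchical YAML file (one block per
stage, plus a free-text provenance block — e.g. assembler and k-mer
settings — that is recorded verbatim and never computed on). Validation
constructs the cross model and thresholds before any compute, so
impossible settings (e.g. `wt_alt_fraction_max ≥
mut_alt_fraction_required`) fail immediately. A run directory contains
every report table, a VCF of candidates (written via VariantAnnotation,
transcript ids as contigs, no coordinate shift), a machine-readable
summary, a log of per-screen survivor counts, and a config snapshot that
re-runs to identical results. Exit statuses distinguish "candidates
found" (0) from "cascade emptied" (3).

Degenerate cases are handled conservatively: zero-depth pools yield an
undefined allele fraction (`NA`, never 0) and fail fraction-based
screens; empty variant tables produce an all-zero report and a valid
header-only VCF; an all-zero expression pool is refused rather than
normalized.

## Problem sizes used by the test suite

The bundled demonstration uses 500 background variants on 60 transcripts
at mean depth 60 — small enough to read, large enough that the cascade's
narrowing (hundreds → tens → one) is visible. Property tests run the
cascade against an independently coded brute-force conjunction on 1000
random tables, consequence calls against a whole-ORF
retranslate-and-diff oracle on 200 random transcripts, and the planted
recovery experiment at the full default model (5000 background variants,
100 seeds). These sizes were chosen so the whole suite exercises the
study-scale design while remaining a coffee-break run on a laptop.
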