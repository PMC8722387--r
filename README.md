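# poolscreen

Forward-genetics mutation identification from pooled RNA-seq of
self-fertilizing, near-isogenic lines — simulation, screening, annotation
and expression ranking in one R package.

## The problem

In a selfing hermaphroditic model organism kept as a highly inbred
(isogenic) strain, a recessive zygotic mutation can be identified without
a reference genome, genetic mapping, or outcrossing. Selfing a single
heterozygous F1 parent yields an F2 brood segregating 1:2:1 at the causal
locus. Sorting embryos by phenotype gives a **mutant pool** (homozygous for
the causal allele, expected alternate-allele fraction 1), a **sibling
pool** (hom-ref : het in ratio 1:2, expected fraction 1/3), and the
unmutagenized **wild-type strain** (expected fraction 0). One lane of
pooled RNA-seq then suffices: per-variant read counts carry the pool
allele frequencies, and on an isogenic background almost no other site can
mimic that signature.

`poolscreen` provides:

* a generative model of the cross (`cross_model()`, `simulate_cross()`):
  selfing segregation, phenotype pooling, residual strain polymorphism
  and induced background variants, negative-binomial depth, symmetric
  per-read allele miscalls, expression-weighted dosage — with full ground
  truth for benchmarking;
* the six-screen read-count filtering cascade (`run_cascade()`), with
  strict "more than" thresholds: homozygous WT/mutant difference, exact
  100%/0% enrichment, WT reads > 10, mutant reads > 5, sibling reads > 4
  of each allele, sibling ref > alt — plus a non-synonymous condition;
* codon-level consequence annotation on transcript coordinates
  (`call_consequences()`) and residue conservation across orthologue
  alignments (`conservation_at()`);
* coverage-based expression ranking between mutant and sibling pools
  (`coverage_table()`, `top_downregulated()`);
* an end-to-end, YAML-configured, fully deterministic pipeline
  (`run_pipeline()`) with TSV/FASTA/VCF output, and a thin command-line
  wrapper in `inst/scripts/poolscreen`.

## Worked example

```r
library(poolscreen)

res <- run_pipeline(poolscreen_demo_config(), out_dir = "demo_run")
res$report
#> Variant screening cascade: 501 input variants
#>   hom_difference      219 survivors
#>   full_enrichment     171 survivors
#>   wt_depth            171 survivors
#>   mut_depth           171 survivors
#>   sib_het               1 survivors
#>   sib_ratio             1 survivors
#>   nonsynonymous         1 survivors
#> Final candidates: 1
#>  variant_id transcript_id position ref alt mut_alt_fraction sib_alt_fraction
#>      v00194        tx0021      373   C   T                1        0.3829787
#>  wt_alt_fraction consequence_class
#>                0          missense
```

The 501 simulated variants (500 background sites plus one planted
recessive missense allele) are first reduced to the 219 sites where the
wild-type and mutant pools are each homozygous for different alleles, then
to the 171 showing exact 100% mutant / 0% wild-type enrichment (mostly
fixed strain differences), and the sibling screens — which demand a
heterozygous sibling pool with more reference than alternate reads — leave
exactly one variant: the planted C→T arginine→cysteine missense change,
at mutant fraction 1.00, sibling fraction 0.38 (Mendelian expectation
1/3), wild-type fraction 0.00. The run directory contains the cascade
report, candidate table, consequence calls, a VCF of candidates, the
ranked expression table and a re-runnable config snapshot.

Lower-level entry points mirror the pipeline stages:

```r
sim <- simulate_cross(cross_model(seed = 42))       # 5001 variants, truth set
cons <- call_consequences(sim$variants, sim$transcripts)
rep <- run_cascade(sim$variants, consequences = cons)
sim$truth$variant_id[sim$truth$causal] %in% rep$candidates$variant_id
```

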