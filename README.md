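# chromsandbox

Quantifying the hallmarks of a "sandbox" chromosome — a chromosome under
relaxed selection that accumulates lineage-specific genes, pseudogenes and
variants — from a genome annotation, an expression matrix, cross-species
protein hit tables, an orthogroup table and pooled-variant calls. The
motivating system is the anhydrobiotic midge *Polypedilum vanderplanki*,
whose smallest chromosome concentrates species-specific genes, a largely
silent 117-copy receptor-like family, and tandem islands of desiccation
effector (*Lea*) paralogs.

The package is written for comparative genomicists who have the standard
upstream outputs in hand (FASTA/GFF3, TPM matrix, DE calls, blast-style
tabular hits, orthogroups, VCF) and want the chromosome-level
characterization reproducibly wired together — plus a seeded synthetic
genome generator so every stage can be validated against ground truth at
desk scale.

## What it computes

* **Windowed tracks** — GC ratio, gene density, pooled-read pairwise
  nucleotide diversity with the unbiased per-site estimator
  π̂ = n/(n−1) · (1 − p² − q²), and the Ts/Tv ratio.
* **Conservation ratios** per chromosome from reciprocal protein hits, and
  reciprocal-best-hit 1-to-1 orthologs with deterministic tie-breaking.
* **Clade specificity** (focal-specific / genus-specific / conserved) from
  orthogroups and a species clade map, with cumulative profiles along each
  chromosome.
* **Gene-set enrichment/depletion** per chromosome via the exact
  hypergeometric test (Fisher's two-sided rule), BH-corrected.
* **Pseudogene flagging** (mean TPM ≤ 1), chromosome summary tables,
  tandem-array detection.
* **Subfunctionalization of tandem paralog islands** — regulation-profile
  blocks, protein isoelectric points (Henderson–Hasselbalch + bisection),
  heat-shock-element scanning (alternating nGAAn/nTTCn units), and
  Nei–Gojobori (1986) dN/dS with Jukes–Cantor correction.
* **A ranked sandbox report** combining six indicators (GC, π,
  conservation, specificity share, essential-set depletion, non-expressed
  share).

## Worked example

Recompute the per-chromosome summary from the published raw counts of the
midge assembly, and test the 45-of-117 family concentration on the
smallest chromosome:

```r
library(chromsandbox)

s <- summarize_chromosome_counts(pv_chromosome_counts())
dplyr::select(s, chrom, genes_per_mb, expressed_per_mb,
              pct_genes, pct_nonexpressed)
#>   chrom genes_per_mb expressed_per_mb pct_genes pct_nonexpressed
#> 1 chr_1         143              81          30               43
#> 2 chr_2         140.             77.8        28               44
#> 3 chr_3         134.             70.5        24               47
#> 4 chr_4         231.             82.5        18               64

hypergeom_test(45, 117, 3241, 17624)
#>      p_enrich p_deplete p_two_sided
#> 1 0.000000266     1.000 0.000000414
```

Despite holding only 18% of the genes, `chr_4` has the highest gene
density (231 genes/Mb, from its short length) and by far the highest
non-expressed share (64%) — and the 117-copy family is significantly
concentrated on it (enrichment p ≈ 2.7 × 10⁻⁷ under the all-genes
background).

End to end on synthetic data:

```r
dir <- tempfile()
simulate_bundle(simulation_config(seed = 17), dir)
report <- run_sandbox_pipeline(read_bundle(dir))
report
#> <sandbox_report>
#>   candidate sandbox chromosome: chr_4
#>   top-ranked indicators per chromosome:
#>     chr_4 - 6 of 6

dplyr::select(report$indicators, chrom, gc_mean, pi_mean, conservation_mean)
#>   chrom gc_mean pi_mean conservation_mean
#> 1 chr_1   0.287 0.00195             0.410
#> 2 chr_2   0.288 0.00196             0.433
#> 3 chr_3   0.287 0.00196             0.464
#> 4 chr_4   0.263 0.00437             0.148
```

The generated sandbox chromosome is recovered as the top-ranked candidate
on all six indicators: lowest GC (0.263 vs ≈0.287), highest windowed π
(enriched by its high-diversity sub-region), and lowest outgroup
conservation.

A thin command-line wrapper over the same functions lives at
`inst/scripts/sandbox-pipeline.R`
(`Rscript sandbox-pipeline.R simulate --seed 17 --out bundle/`, then
`run-all --bundle bundle/ --out out/`).

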