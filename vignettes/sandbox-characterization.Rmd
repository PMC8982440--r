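---
title: "Characterizing a sandbox chromosome: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a sandbox chromosome: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromsandbox)
```

## The question this package addresses

In the anhydrobiotic midge *Polypedilum vanderplanki*, the smallest of the
four chromosomes behaves like a genetic "sandbox": a chromosome under
relaxed selective pressure that accumulates lineage-specific genes,
pseudogenes and variants, and hosts tandemly duplicated effector-gene
islands. Detecting such a chromosome is a matter of quantifying a set of
complementary signals on a common per-chromosome backbone:

* depressed GC, genome-wide and in coding sequence;
* elevated pairwise nucleotide diversity (π) in a sub-region, estimated
  from pooled sequencing;
* depressed transition/transversion (Ts/Tv) ratio;
* fewer genes with cross-species homologs (conservation ratio);
* an excess of species- and genus-specific genes;
* depletion of essential/universal single-copy genes and enrichment of
  multicopy, largely silent families;
* tandem paralog islands whose sub-blocks differ in regulation profile,
  protein isoelectric point (pI), and upstream heat-shock elements (HSEs).

`chromsandbox` implements each of these as a tibble-in, tibble-out stage
over a validated `genome_annotation`, plus a seeded synthetic-genome
generator so that the entire pipeline is testable at desk scale without
any external data.

## Windowed statistics

Chromosomes are tiled into consecutive, non-overlapping windows whose last
window keeps its true (shorter) span; internally windows are 0-based
half-open, reported 1-based inclusive to match GFF3/VCF conventions.

**GC.** Per-window GC is (G+C)/(A+C+G+T); ambiguous bases are excluded from
numerator and denominator, and windows with more than half non-ACGT bases
are masked. The default window is 100 kb for GC and 50 kb for π, the sizes
at which these profiles are conventionally drawn for genomes of this size.

**π from pooled reads.** With reference and alternate read counts $r, a$
at a site ($n = r + a$, $p = r/n$, $q = a/n$), the per-site estimator is

$$\hat\pi = \frac{n}{n-1}\left(1 - p^2 - q^2\right),$$

the unbiased average pairwise difference among reads drawn without
replacement (the package tests this against explicit read-pair
enumeration). Window π sums per-site values over qualifying polymorphic
sites and divides by the number of window positions with qualifying depth.
Positions absent from the variant table are treated as covered and
monomorphic — variant files rarely list invariant sites, and window π is a
per-base quantity — while listed sites failing the depth filter are
removed from the denominator. Defaults follow common pool-seq practice and
are all configurable: `min_depth = 10`, `min_minor_count = 2`,
`min_fraction = 0.5`. This is a read-count estimator, not a pool-size
corrected one; absolute values may differ from pool-aware estimators by a
small factor, which does not affect the between-chromosome contrasts the
pipeline ranks on.

**Ts/Tv** is computed from site classification alone (A↔G and C↔T are
transitions), with no frequency weighting, and is undefined (missing) when
a scope contains no transversions.

Between-chromosome comparisons of per-window values (GC, Ts/Tv) and of
per-block pI use one shared engine: one-way ANOVA followed by Tukey's HSD
on the studentized-range distribution (`group_compare()`, with
broom-style `tidy()`/`glance()` methods). All-identical inputs yield a
missing F rather than a spurious one.

## Homology stages

**Conservation ratio.** A gene counts as conserved against a target
species if it has a *reciprocated* protein hit — some target gene hit in
the forward table that hits it back in the reverse table. This is
deliberately weaker than reciprocal best hit: the two notions serve
different purposes (chromosome-level conservation ratios vs 1-to-1
ortholog extraction) and both are exposed. An `any_hit` mode relaxes
further, since plain "bidirectional hits" is ambiguous in common usage.
Hit tables are standard 12-column tabular output; records above the
E-value ceiling (default `1e-5`, configurable — alignment tools differ in
their defaults) are dropped at read time.

**RBH.** Best hits maximize bitscore, with ties broken by minimal E-value
and then lexicographically smallest target id, so the ortholog set is
reproducible run to run.

**Clade specificity.** Each orthogroup is labelled by the narrowest clade
on the focal species' clade path containing every member species: focal
only → focal-specific, within the genus → genus-specific, anything wider →
conserved. Focal genes absent from every orthogroup are singletons and
default to focal-specific — consistent with clade-specific counts that
exceed orthogroup membership — with a flag to label them `unassigned`
instead. Cumulative per-label counts along the gene order of each
chromosome provide the coordinates for cumulative-specificity plots.

## Gene-set and expression stages

**Enrichment/depletion.** Each (set, chromosome) pair is tested with the
exact hypergeometric distribution: `p_enrich` = P[X ≥ k], `p_deplete` =
P[X ≤ k], and a two-sided p following Fisher's rule (the sum of all
outcome probabilities no more likely than the observed one). The
Benjamini–Hochberg correction is applied across the whole set × chromosome
family — the analysis-level family, chosen because reported FDRs of this
kind rarely state a finer family. The default background is all genes on
placed chromosomes, matching whole-annotation denominators; a coding-only
background is selectable, and because the published family-concentration
p-value depends on that unstated choice, the package's worked example
checks direction and magnitude (p < 1e-5) rather than equality.

**Pseudogene flagging.** A gene is operationally non-expressed when its
mean TPM across all samples is at or below 1. The inclusive threshold
(≤ 1, not < 1) follows the per-chromosome summary-table convention, which
partitions genes into "TPM > 1" and "TPM ≤ 1"; genes missing from the
expression table get a distinct `no_data` status and count as
non-expressed in summaries.

**Tandem arrays.** Maximal runs of same-family genes along the gene order,
allowing up to `max_intervening` (default 1) other genes between
consecutive members; strand homogeneity is reported always and enforced
only on request. Arrays partition genes: no gene belongs to two arrays.

## Subfunctionalization of tandem paralog islands

**Regulation signatures.** Differential-expression calls (up/down/ns per
condition) are collapsed to the set of condition *categories* with at
least one call. The default map collapses a 20-condition desiccation
time-course design into "osmotic" (mannitol/NaCl/trehalose exposures),
"anhydrobiosis" (trehalose preconditioning and rehydration series) and
"stress" (heat, oxidative) — the third category exists so that every
condition is mapped, a hard invariant. The full per-condition vector can
be used instead by supplying an identity category map.

**Blocks.** Scanning the island's gene order, genes sharing a signature
join the open block; a signature change opens a new block; up to
`max_silent_gap` (default 1) consecutive silent genes are bridged, and a
longer silent stretch terminates the block. Blocks therefore partition the
island's non-silent genes.

**Isoelectric points.** pI is the root of the Henderson–Hasselbalch net
charge (one N- and one C-terminal group plus C, D, E, H, K, R, Y side
chains), found by bisection on pH 0–14 to |Δ| < 0.001 with the pKa set
(N-term 8.6, C-term 3.6, C 8.5, D 3.9, E 4.1, H 6.5, K 10.8, R 12.5,
Y 10.1). pI is composition-determined, which the tests exploit as a
permutation-invariance property. One (longest) protein per gene is used;
isoform pooling is not modelled.

**HSEs.** A heat-shock element is defined as ≥ 3 contiguous 5-mer units
alternating between `nGAAn` and `nTTCn` with zero mismatches by default
(a one-mismatch-per-run tolerance flag exists); the upstream window is
1,000 bases 5′ of the gene start, strand-aware. Both the unit count and
the window are conventions — motif definitions in the literature vary —
and are exposed as parameters.

**dN/dS.** Pairwise dN/dS uses the Nei–Gojobori (1986) counting method:
per-codon synonymous site fractions averaged over the two sequences
(mutations creating stops count as nonsynonymous), substitution counts
averaged over all orderings of the observed per-codon differences with
stop-containing pathways excluded, and the Jukes–Cantor correction
$d = -\tfrac34\ln(1 - \tfrac43 p)$ applied to both proportions. A
proportion at or above 3/4 leaves the distance missing and flagged
`saturated`; dN/dS is missing when dS = 0. NG86 was chosen over
maximum-likelihood codon models as a transparent, dependency-free
estimator that is fully checkable against exhaustive pathway enumeration;
its absolute values differ somewhat from ML estimates, so it should be
read through relative contrasts (e.g. island orthologs vs genome-wide
1-to-1 orthologs), which is how the pipeline uses it.

## The synthetic generator

`simulate_bundle()` emits a complete, internally consistent bundle —
FASTA, GFF3, protein FASTA, expression and DE-call TSVs, a pooled-variant
VCF, forward/reverse hit tables against five species (two congeners,
three outgroups), an orthogroup table, a clade map, conserved gene sets
and aligned ortholog CDS pairs — plus a JSON truth manifest recording
every sampled latent value, so that each stage can be scored against
ground truth.

Defaults encode the study conditions of the four-chromosome midge genome:
length ratios ≈ 37:35:31:14, gene densities 143.0/139.5/133.5/231.2 per
Mb, coding-GC targets 34.2/34.6/34.2/31.5%, expressed fractions
57/56/53/36%, a 117-copy family with 45 copies on the sandbox and 115
silent, a high-diversity sandbox region spanning the 3–12 Mb analog with
a 3× site-density multiplier, Ts/Tv targets 2/2/2/1, a sandbox
lineage-specific fraction of 0.6 vs 0.3 elsewhere, and a tandem island of
three 5-gene blocks with pI targets 6.87/5.18/4.74 (SD 0.3) and an HSE
insertion probability of 4/5 in the widely-expressed block.

Two deliberate scale choices: the default genome totals ~4 Mb — the
smallest round size at which the per-Mb densities, the 45 sandbox family
copies and the 15-gene island can coexist on the smallest chromosome —
and sequence realism is minimal (i.i.d. bases per GC stratum, no repeats
or introns), because every statistic in scope is composition-, coordinate-
or table-driven; higher sequence realism would add nothing the pipeline
measures. Coding sequences are drawn with exact per-gene GC counts
(stop codons repaired by GC-preserving permutation), so recovered
coding-GC chromosome means sit within ±0.005 of their targets; island
proteins are tuned to their pI targets by accept-reject over single
charged-residue substitutions with a restart cap.

What passing the recovery suite does **not** show about real data:
the generator has no alignment error, no annotation error, no coverage
heterogeneity beyond depth-binomial sampling, no paralog-collapse
artefacts in hit tables, and its orthogroups are internally consistent
with its clade labels by construction. Recovery therefore validates the
*estimators and their wiring*, not robustness to the failure modes of
real upstream tools.

## Degenerate inputs and numerical choices

* Readers reject rather than repair: out-of-range coordinates, duplicate
  ids, negative TPM, unmapped conditions and double-grouped genes are
  hard errors; skipped variant records (indels, multiallelics, depth
  mismatches) are counted and reported.
* Window masking is monotone in `min_depth` (raising it never unmasks).
* All randomness flows from a single mandatory seed; two runs of the
  generator with the same configuration are byte-identical, and the
  generator restores the caller's RNG state.
* Problem sizes in the test suite: the recovery tests run on an ~0.8 Mb
  four-chromosome genome (a scaled copy of the default configuration) and
  the full-default ~4 Mb genome is exercised once in the end-to-end
  acceptance test; oracle equivalence tests enumerate exhaustively where
  the domain is finite (hypergeometric N ≤ 30, read pairs n ≤ 12, codon
  pairs differing at ≤ 2 positions) and use 60–300 seeded random cases
  for the scanners.

## Known limitations

* Coding GC uses the gene span (no intron/CDS-union model); with the
  intronless synthetic genes the two coincide, but on real annotations
  the exonic CDS union would be preferable.
* π and Ts/Tv assume biallelic SNVs from a single pooled sample.
* The clade classifier assumes clades nest along the focal path; it does
  not handle reticulate or conflicting clade maps.
* Blocks are defined on the collapsed category signature; two genes
  regulated in different conditions of the same category share a
  signature by design.
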