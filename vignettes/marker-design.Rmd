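---
title: "Mining transcriptome SNPs and designing KASP assay targets in a paleopolyploid"
author: "transmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining transcriptome SNPs and designing KASP assay targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transmark)
```

## The problem

Oleiferous *Brassica rapa* breeding needs dense genic markers, but the
species is an ancient paleohexaploid: after extensive gene loss, a
reference gene model may exist as a single copy or with one or two
paralogs that are 90--98% identical to each other. A raw transcriptome
SNP call against such a reference confounds two things:

* **allelic SNPs** -- true differences between the same locus in two
  lines, usable as mapping markers;
* **paralog-specific variations (PSVs)** -- fixed differences between
  duplicated copies within every line, which masquerade as SNPs whenever
  reads or contigs from one paralog are compared against another.

`transmark` implements the full marker-design analysis: de novo contigs
from each line are grouped to reference coding sequences, SSRs and SNPs
are detected, allelic SNPs are separated from PSVs in duplicated
families, and surviving SNPs are turned into KASP-style assay targets
through a three-criteria filter cascade. Two-point linkage utilities
validate designed markers on simulated recombinant inbred lines (RILs).
Because the original raw sequencing data are not reproducible at desk
scale, a synthetic-data generator with planted, machine-readable ground
truth stands in for them; every stage is tested against that truth.

## Pipeline stages and their rules

### Homolog grouping

Contigs are aligned to gene models by exact k-mer seeding (default
k = 15) followed by full Smith--Waterman dynamic programming with a
linear gap penalty (match +2, mismatch -3, gap -5 per column). A contig
is a *homolog* of a gene model when some hit reaches **at least 80%
identity over at least 100 aligned columns**; each contig is assigned to
its single best gene (highest identity, then longest alignment, then
smallest gene id -- a deterministic, order-free tie-break).

Two conventions are worth stating because alignment tools disagree on
them: identity is computed as matches over *all* aligned columns, gap
columns included (the conservative reading), and `N` never counts as a
match. Both strands are searched; minus-strand hits report plus-strand
contig coordinates.

### SSR detection and comparison

Perfect tandem repeats of 1--6 bp units are reported at MISA-style
minimum repeat counts of **10, 6, 5, 5, 5 and 5** for mono- through
hexanucleotide motifs. Only maximal runs are reported; a run whose unit
is itself periodic (e.g. `ATAT`) is reported at the shortest unit; runs
of `N` break repeats; motifs are canonicalised to the lexicographically
smallest rotation but *not* folded with the reverse complement, since
transcripts have a defined strand. Two qualifying SSRs within 100 bp
(the MISA default) are additionally labelled one *complex* locus.

Cross-line comparison is deliberately stringent: a locus pair is
polymorphic only when the motifs agree, the repeat counts differ, and
the **50 bp flanks on both sides are exactly identical** between lines.
Loci with less than 50 bp of available flank are excluded and counted.

### SNP calling and filtering

Homolog pairs with **at least 90% identity** are scanned column by
column; every mismatching column yields a variant site. Columns within
5 bp of an alignment gap are excluded (a configurable guard band
standing in for the removal of indel-containing stretches). Depth is
attached from the contig's per-base depth track; the reference line
(gene models, which carry no reads) is treated as unbounded, so the
filter applies to the contig line only. Sites are retained when
**depth >= 7 and quality >= 40**, both boundaries inclusive.

The alignment route has no native consensus quality, so when no quality
column is supplied a deterministic stand-in `min(60, 10 + 5 * depth)` is
imputed and flagged `quality_imputed`. It preserves the shape of the
published filter (low-depth sites fail both criteria) without
pretending to be a calibrated error probability.

### PSV discrimination in paralog families

For a family whose paralogs are column-aligned across two or more
lines, each segregating column is classified exhaustively and mutually
exclusively:

* `psv` -- paralogs differ, but each paralog is identical across lines;
* `allelic_snp` -- exactly one paralog differs between lines and every
  other paralog is line-invariant;
* `conflict` -- any other segregating pattern (two or more paralogs
  varying across lines).

Columns containing an unresolved base (`N`) in any sequence are skipped
and counted. A 256-case enumeration of all base assignments for two
paralogs in two lines is checked against a hand-coded truth table in the
test suite.

A paralog-allelic SNP becomes a marker only when **at least one PSV lies
within its 50 bp flanks** (either flank by default; a strict both-flanks
mode is available), so that locus-specific primers can anchor on the
target copy. In the emitted target the PSV positions carry the target
paralog's own bases -- they are the discriminators and are never
degenerate -- while residual non-target variable positions receive IUPAC
degeneracy codes.

### The three-criteria cascade

Each candidate SNP is evaluated against three independent criteria, in
the stated order for funnel reporting:

1. **Conserved flanks** -- all 50 alignment columns on each side of the
   SNP are identical between the lines: no substitution, no gap, no `N`.
   Strict identity is the testable reading of "strictly similar".
2. **No exon--intron junction** in the 101 bp window (variable base at
   1-based offset 51). The window is aligned to the gene's genomic
   (intron-bearing) copy and passes only when it aligns as one
   contiguous, gap-free block covering the full window. An intron
   insertion point strictly inside the window splits that alignment.
3. **Read depth >= 7** (with quality >= 40) at the SNP base.

All three flags are computed for every candidate, so the accepted set is
provably independent of evaluation order; only the funnel's intermediate
counts depend on it. The funnel reports both candidate-site counts and
distinct-gene counts; the gene count is the analogue of the published
cascade figures.

Accepted markers are emitted as a table mirroring the published assay
layout: ids, alignment direction, the SNP position in both gene-model
and contig coordinates, the per-base (A/T/G/C) depth decomposition at
the SNP, and the 101 bp target rendered with a single bracket
(`...[A/G]...`, reference-line base first -- an arbitrary but
deterministic order, as the source material states none).

## The synthetic data regime

`simulation_config()` states the world once; its defaults are not tuned
to any test outcome.

| Parameter | Default | Why |
|---|---|---|
| `cds_len_range` | 400--1600 bp | brackets the observed N50 contig range (roughly 500--1100 bp) while always admitting the 201 bp minimum for a centered window |
| `psv_rate` | 0.03/bp | paralogs from an ancient triplication at 94--97% identity; capped at 0.08 to respect the 90% family-identity floor |
| `snp_rate` | 0.01/bp | order-of-magnitude match to the published inter-line SNP yields (hundreds of thousands of SNPs over tens of Mb of coding sequence); the source gives no direct divergence figure, so this is a loosely calibrated free parameter |
| `intron_count_range` | 1--5 | typical plant gene structure |
| `intron_len_range` | 80--300 bp | typical plant introns; minimum 60 bp enforced so a junction inside a window reliably breaks its genomic alignment |
| `contig_coverage` | 0.8 | assembled contigs were "predominantly partial sequences" |
| `depth_law` | negative binomial, mu = 120, size = 5 | the published mean contig depths range 76--181; the negative binomial gives realistic overdispersion |
| RIL population | n = 93, F7 | the published validation population |

The generator plants: single/two/three-paralog families with fixed PSVs
(paralog 1 keeps the ancestral base; others draw alternatives, so mixed
three-copy patterns occur); line-specific allelic substitutions; SSR
repeat-length edits with guard bases so planted repeats never merge with
their surroundings; genomic copies with `GT...AG` introns inserted only
strictly between coding bases (a junction at a window edge would
otherwise be undetectable); contigs as strand-random substrings with
per-base depth; and F7 RIL genotypes by single-seed descent with
Haldane (no-interference) meioses.

**Clean-flank mode** spaces planted SNPs at least 102 bp apart, keeps
them 51 bp from junctions and sequence ends, off PSV columns, and off
columns already carrying a sibling paralog's SNP (a same-column pair
would be a doubly-segregating `conflict`, not a usable marker). This
isolates each criterion so the planted expectation
`expected_marker_ids` is *exact*, which is what the recovery tests
assert. Deliberate failure plantings (an extra SNP inside a flank, a
junction inside the window, depth 6 at the SNP) occupy disjoint gene
subsets for the funnel oracle.

What a green test does **not** establish: the generator plants
substitutions only (no indels, no sequencing error, no chimeric or
misassembled contigs), depth is independent of position, and paralog
family members share one coordinate frame (equal lengths). Real data
break all four assumptions; the cascade's gap guard, identity floors and
`N`-handling are the designed mitigations, but their real-data
error rates are not measured here. Exact planted-truth recovery is
likewise only asserted at full contig coverage, because classifying a
paralog column requires every paralog's line base to be resolved.

## Two-point linkage utilities

Markers are screened for segregation distortion with a 1-df chi-square
against the 1:1 RIL expectation (default alpha 0.01, configurable;
fewer than 20 informative calls flags low power). For a marker pair,
the observed recombinant fraction `R` (heterozygous and missing calls
excluded, capped at 0.5) is converted to a per-meiosis `r`, LOD score
`k log10(R/0.5) + (n-k) log10((1-R)/0.5)` with `k = round(Rn)`, and the
Kosambi distance `d = 25 ln((1+2r)/(1-2r))` cM. Linkage groups are the
connected components of the graph with edges at **LOD > 6.0**, labelled
by their smallest member so the partition is order-free.

One design choice deserves its own paragraph. For selfed RILs the
classical fixation correction is `R = 2r/(1+2r)`. At F7, however, the
population is not at fixation: the exact expectation (obtained by
iterating the 16-state two-locus diplotype chain through six selfing
rounds) is visibly below the fixation value -- at r = 0.01 it is 0.0179
versus 0.0196, a 9% gap that the fixation-based inversion turns into a
~17% downward bias in `r`. Since the package's own recovery requirement
is 10% median relative error across r in [0.01, 0.2], `estimate_rf()`
inverts the exact finite-generation expectation `ril_expected_R(r,
generation)` numerically (memoised; `generation = Inf` recovers the
closed form). The residual heterozygosity itself is simulated
faithfully: about (1/2)^6 = 1.56% of F7 calls are heterozygous.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive in every emitted table; internal
  arithmetic converts explicitly.
* Alignment tie-breaks are deterministic (first maximal cell in
  row-major order; traceback prefers diagonal over up over left). Equal
  score co-optimal alignments can differ from another optimal aligner by
  a gap-pair-versus-substitutions trade; tests therefore assert exact
  score equality and identity agreement within 0.01.
* `filter_reads` evaluates the low-quality fraction on the full read
  ("more than 30%" is strict, so exactly 30% survives), then trims the
  31-base tail; reads too short to survive trimming are counted
  separately. Orphaned mates are dropped by the pairing pass.
* Empty inputs return empty, correctly-typed results (an empty contig
  set is not an error); malformed files raise typed errors naming the
  offending record, position or constraint -- including invalid FASTA
  characters, which the underlying parser would otherwise silently drop.
* An empty copy class reports `NA` presence, never a misleading zero.
* Genes shorter than the minimum alignment length are skipped with a
  warning; depth tracks shorter than their contig are an error.

## Known limitations

* Paralog classification requires column-aligned (equal-length) family
  members; real families with indels would need a multiple alignment
  step that is out of scope here. Families violating this are flagged
  `family_unalignable` and their candidates rejected.
* The junction check's "single contiguous block" criterion can, in
  principle, pass a junction within a few bases of the window edge if
  the short exon fragment fails to seed its own alignment; clean-flank
  fixtures keep junctions either inside by >= 10 bp or outside by
  >= 51 bp, where the criterion is exact.
* Multipoint ordering, integrated multi-population maps and primer
  thermodynamics are explicitly out of scope; the two-point seriation
  view is approximate and labelled as such.

## A minimal run

```{r demo, eval = FALSE}
cfg <- pipeline_config(
  sim = simulation_config(n_single = 40, n_two = 15, n_three = 8,
                          seed = 1),
  out_dir = "demo_run")
res <- run_pipeline(cfg)
res$manifest$counts$funnel     # genes surviving each criterion
head(res$cascade$markers$target_sequence, 3)
```

The funnel, the accepted-marker count and every output file are
reproduced byte-identically by a rerun with the same configuration and
seed; the manifest records both.
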