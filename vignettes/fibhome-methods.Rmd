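---
title: "Methods: anatomy, comparison and pedigree of fibroin heavy-chain loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anatomy, comparison and pedigree of fibroin heavy-chain loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibhome)
```

## The locus model

The fibroin heavy-chain (*FibH*) gene is modelled as

```
[5 kb upstream] exonI(67 bp) intron(~958-1007 bp) exonII [5 kb downstream]
                                  exonII = TNR5 + RC + TNR3
```

Exon I carries a 25-bp 5' UTR followed by the ATG; the open reading frame is
exon I from the ATG plus the whole of exon II, ending in the stop codon that
this package includes in the 3' TNR (a convention, stated here once: whether
the terminal block includes the stop codon is not standardised, and all
interval arithmetic in this package treats the last codon of the gene as part
of TNR3). With the default reference components — exon I 67 bp, intron 971 bp,
TNR5 198 bp, RC 15,489 bp, TNR3 63 bp — the canonical gene is 16,788 bp long
with a 15,750-bp exon II, and its CDS (42 bp of exon I plus exon II) is a
multiple of three with no internal stop. Note the widely quoted component
lengths (exon I 67 bp + exon II 15,750 bp) are not jointly divisible by three;
the resolution is precisely that translation starts at the internal ATG of
exon I, which is why `annotate_gene()` carries a `cds_offset` (default 25).

The repetitive core is a tandem concatenation of GC-rich units, each starting
`GGTGCT` (encoding Gly-Ala), ending `TCA` (Ser), in frame and stop-free, so
the translation is a run of GAGAGS-family hexapeptides. Amorphous (non-
crystalline) spacer regions are represented by a fixed 33-bp in-frame linker
containing exactly one NdeI site (`CATATG`), so NdeI site counts delimit the
amorphous regions — `scan_ndei()` is the deterministic stand-in for a
restriction-site scan.

## The synthetic cohort generator

`synth_cohort_spec()` fixes the study conditions; the defaults are the
cohort-level statistics reported for the silkworm pan-genome and are not
tuning knobs:

* class mean total gene lengths: wild 19,698 bp, local 16,427 bp, improved
  15,795 bp. The per-class standard deviations are not published; the
  defaults (1500 / 800 / 600 bp) were chosen once from the printed ranges
  (wild 17,664–24,162 bp; local 14–19 kb; improved mostly 13–19 kb) so that
  ±2 SD roughly spans those ranges.
* intron length: 971 bp with probability 0.55, 986 bp with 0.40, and one of
  the other observed lengths (958–988, 1007 bp) otherwise. The published
  shares are 51.14% and 37.50%; the exact mixture weights are a free choice
  and are documented here, not fitted.
* unit alphabet: four blocks seeded on the `GGTGCT` hexanucleotide
  (`u1 = GGTGCTGGAGCTGGTTCA`, `u2` differing from `u1` by one base — the
  Group-2/3 pair —, `u3 = GGTGCTGGTGCTGGTTCA`, and a 39-bp `u4`). `u3` is the
  consensus instantiation of the 49-bp degenerate motif, and cores are
  sampled as geometric runs of `u3` (run probability 0.62, mean run length
  10) interleaved with the other units. These two constants were set at
  design time so that (a) core GC lands in the published 58.9–60.0% band
  (the generator produces ~60.8% for the core and ~59.5% for the whole gene)
  and (b) exact matches of the degenerate motif tile ≥ 80% of core positions,
  which is how the real cores behave under the same scan. The real silkworm
  unit inventory is far richer; reproducing it is out of scope.
* variation: whole-unit block insertions/deletions (Groups 1–4, Poisson
  counts per strain) applied at unit boundaries; rare substitutions
  (default 5e-4/bp) in the intron, TNRs and flanks only — the core is
  indel-only, reflecting the observation that TNR variation is
  substitution-dominated. Splice dinucleotides, the planted intron element,
  the terminal barcode and the 3' UTR are protected from SNPs, otherwise
  extraction and conservation statements would measure the mutation model
  rather than the biology.
* every strain is embedded at a random offset, on a random strand, in a
  random chromosome background (default 60 kb, GC 0.38).

Group-4 insertions are built from whole 18-bp units, i.e. their lengths are
multiples of 18 inside the published 54–4302 bp envelope. The classifier
accepts the full envelope (any in-frame length in range); the generator
simply does not exercise non-multiple-of-18 lengths.

Shared alleles are explicit: `share_alleles = list(c("P1", "P3"))` makes the
named strains byte-identical (the first member is the founder). The default
cohort has none, so that the class mean-length recovery check is a clean iid
sampling statement; pedigree families in default cohorts arise only from
explicitly configured sharing, mirroring the fact that identical alleles in
real cohorts are a breeding signal, not a sampling accident.

Determinism: one master seed; per-strain seeds are derived by stable hashing
of the strain id with extra avalanche rounds (near-identical ids must not
produce correlated draws — R's Mersenne-Twister warm-up is weak for
consecutive seeds, so `with_seed()` also discards the first eight draws).
Reruns under the same spec are byte-identical.

What the generator deliberately does **not** emulate: sequencing or assembly
errors (a poly-N injection option exists purely as a QC fixture), the real
unit inventory and codon usage, heterozygous assemblies, and realistic
flank/intron sequence content (flanks are fixed random backbones with planted
elements). Passing tests therefore demonstrate correctness of the machinery
on loci with the documented statistical structure, not performance on real
assemblies.

## Locus extraction

`extract_locus()` finds the 20-bp terminal barcodes (default: the terminal
sequences of the synthetic reference gene; real analyses supply their own)
on both strands with `max_mismatch` substitutions (default 0 — the inputs
are assemblies, not reads). Exactly one consistent start/end pair on one
strand is required; zero pairs raise `fibh_not_found`, and anything else —
including pairs on opposite strands or multiple candidate loci — raises
`fibh_ambiguous` with all candidates listed, never a silent guess
(heterozygous assemblies surface this way). Coordinates are 0-based
half-open on the forward strand of the source record; all sequences
(gene, flanks) are returned gene-oriented. Gene lengths outside 13–25 kb are
flagged (`LENGTH_OUT_OF_RANGE`), not rejected. Homopolymer QC uses N-run ≥ 10
and G-run ≥ 20 (both configurable); 20 exceeds the longest legitimate G-run
in the coding repeat units, so a POLY_G flag cannot be triggered by clean
coding sequence.

## Gene anatomy

Boundary detection is anchor-based: exon I is the reference length at the
gene start; the 5' TNR start is located by scanning a 30-bp reference probe
(IUPAC scan at 90% identity) in a window after exon I, taking the leftmost
best hit; the intron is the gap, with GT...AG splice consistency reported but
not enforced. TNR ends are delimited by free-end-gap alignment of the full
reference TNR blocks against the ends of exon II; identity below 0.9 raises
the `TNR_MISMATCH` diagnostic with best-effort intervals. The core is the
remainder, so `tnr5 + rc + tnr3` tiles exon II by construction, and the test
suite asserts byte-for-byte tiling and exact truth-table equality on
generated cohorts.

The degenerate-motif scan (`scan_iupac`) is deterministic: a window matches
when every position's subject symbol is contained in the pattern's IUPAC
class (an optional `min_identity` relaxes this fractionally). Subject `N` is
satisfied only by pattern `N` — an ambiguous base is never silently accepted
by a specific pattern symbol. This replaces probabilistic motif discovery
entirely: de novo discovery is a non-goal, the published motif is scanned
as-is.

## Identity and differential sequences

Pairwise identity is affine-gap global alignment (match 5, mismatch −4, gap
open −10, extend −1; ties broken diagonal > gap-in-b > gap-in-a), with
identity = identical columns / alignment length. The C++ kernel carries the
match count along the optimal path in linear memory, so no traceback matrix
is needed for statistics. Pairs whose DP matrix would exceed `cap_cells`
(default 2.5e7) are handled by the anchored scheme: common prefix/suffix
trimming, then a single chaining pass over rare shared k-mers (k = 24,
occurrence-bounded, longest-increasing-subsequence chaining, merged into
exact anchor segments) with DP only between anchors. The scheme is exact
whenever the pair fits under the cap — which covers the ≤ 200 bp oracle
regime, where the suite asserts agreement with a brute-force R dynamic
program to 0.1 identity points — and is a deterministic approximation above
it. On tandem-repeat cores the optimal alignment is itself ambiguous at unit
granularity, so a chained approximation is an appropriate cohort summary;
this is why full-length core-by-core DP is deliberately avoided.

Group identity aligns a cohort progressively under an average-linkage
(UPGMA) guide tree built from pairwise identities; profiles are merged by
aligning their column consensus strings (most frequent non-gap symbol,
alphabetical on ties) and propagating the new gap columns. Column identity
is the fraction of columns in which every row carries the same non-gap
symbol. Consensus-progressive merging is simple and deterministic; it is
accurate for the near-identical region cohorts it is applied to (TNRs,
introns, flanks) and a coarse summary for diverged cores — a documented
limitation, not a defect.

`differential_sequence()` trims the longest common prefix and suffix; if one
remainder is empty the pair differs by one block. Placement inside a tandem
run is ambiguous (all valid placements give rotations of the same block), so
the canonical choice is: the leftmost placement whose block starts `GGTGCT`
and ends `TCA` (unit-anchored, matching how the groups are defined), then
the leftmost starting `GGTGCT`, then the leftmost placement outright. This
refines plain VCF-style left-alignment, which would report a rotated block
and defeat group classification; with it, injected Group 1–3 blocks are
recovered byte-identically and Group 4 blocks up to unit rotation. Pairs
that do not reduce to one block are split recursively at shared k-mer
anchors and every row is flagged `pair_complex` — the "two or more
differential sequences" case; each block still receives its own structural
label, and `classify_differential()` itself is total and deterministic over
{1, 2/3, 4, OTHER}. Groups 2 and 3 are reported jointly as "2/3": the two
published 18-bp sequences differ by one base but are not printed anywhere
machine-readable, so subtype resolution is deferred; the exact block
sequence is always retained.

## Pedigree

Families are equivalence classes of byte-identical gene bodies
(exon I + intron + exon II, gene-oriented); intron SNPs therefore break
family identity. This is the stricter of the two defensible definitions and
the default; callers who want coding-only identity can partition on the
concatenated CDS instead, since `family_partition()` takes arbitrary
id → sequence maps. Families are named by Roman numerals in decreasing size
(ties by allele length), members sorted lexicographically, singletons
reported separately.

`upgma()` is the classical size-weighted average-linkage agglomeration:
merge height is half the merge distance, giving a rooted ultrametric tree;
ties are broken by merging the lexicographically smallest label pair (a
cluster is labelled by its smallest member), so taxon input order never
changes the result. The suite checks closed-form two-taxon output, exact
reconstruction of randomly generated ultrametrics, and cophenetic agreement
with `stats::hclust(method = "average")` on random matrices. Tree distances
in the pipeline are 1 − identity/100 on full gene sequences; the pipeline
caps the tree at `tree_max_n` strains (family representatives first) because
an all-pairs alignment matrix grows quadratically — the default pipeline
sizes (tens of strains) run in minutes on one CPU.

## Regulatory scan

Element definitions are user-supplied patterns over IUPAC codes with a
target region (upstream / intron / downstream). The shipped defaults —
E-box `CANNTG`, TATA-box `TATAWAW`, and a synthetic FMBP-site placeholder —
are deliberately generic: the real binding-site strings are attributed to
primary literature that does not print them, and inventing specific sites
would be worse than shipping marked placeholders that the generator plants
and the scanner finds. Scans cover both strands; positions are region-local
and 0-based (upstream position 0 is `flank_len` bp before the gene start).
The 3' UTR is defined as the first 85 bp of the downstream flank.
`conservation_report()` aligns a region across strains, counts variant
columns, and tests class exclusivity: a variant column is class-exclusive
only if its minority carriers are exactly the members of one class — the
generator's SNPs are strain-private, so cohort-level class exclusivity in
synthetic data indicates a bookkeeping error, and the fixture tests
construct both the negative (shared across classes) and positive controls
explicitly.

## Pipeline and problem sizes

`run_pipeline()` chains the six stages and writes TSV/FASTA/JSON/Newick
outputs plus a manifest; reruns under the same spec and seed are
byte-identical (the manifest omits wall-clock time for this reason). The
default test cohorts are 8 strains; the cohort-level self-consistency check
runs 8 wild + 10 local + 10 improved strains through the full pipeline with
the tree capped at 12 representatives, which completes in about four minutes
on one CPU, and asserts that each class's mean extracted gene length falls
within 3 standard errors of its configured mean. Identity oracles run at
≤ 200 bp and UPGMA oracles at ≤ 8 taxa.

## Known limitations

* The consensus-progressive MSA can misplace gaps between highly diverged
  repeat cores; its column identities for such cohorts are summaries, not
  optimal-alignment statistics.
* Anchored identity above the DP cap depends on shared rare k-mers; two
  cores with no shared structure degrade to a coarse midpoint-split
  alignment (still deterministic).
* Group 2 vs Group 3 cannot be distinguished without their published
  sequences; the joint label retains the block for later resolution.
* The generator's flanks and intron are fixed backbones with planted
  elements; conservation statistics on synthetic cohorts are therefore
  near-saturated by construction and exercise the reporting machinery, not
  sequence evolution.
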