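---
title: "Finishing and dissecting plant mitogenomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finishing and dissecting plant mitogenomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mitomosaic)
```

## The problem

Plant mitochondrial genomes recombine through their dispersed repeats,
absorb plastid DNA (MTPTs), nuclear DNA and horizontally transferred
segments, and consequently vary severalfold in size between close
relatives while keeping a nearly constant gene set. Two practical
obstacles dominate their analysis from short-read data. First,
assemblies fragment exactly at repeats and MTPTs: a two-copy repeat
collapses into one contig at twice the depth, and an MTPT collapses
into the plastome, which is sequenced at far higher depth than the
mitogenome. Second, once genomes are finished, the interesting
comparative quantities — repeat content, MTPT content,
lineage-specific sequence and its provenance — are all defined through
local homology searches with specific length and identity cut-offs, so
small definitional choices change the numbers.

`mitomosaic` implements both halves — finishing and dissection — with
every cut-off collected in one place (`default_thresholds()`) and a
simulator that generates data with known ground truth, so the whole
chain is testable without any external download.

## The homology engine

All stages consume hit tables from one deterministic seed-and-extend
matcher (C++): exact 16-bp word seeds, grouped per diagonal, extended
ungapped in both directions under an X-drop of 20 with +1/−2
match/mismatch scoring. Identity is matching columns over alignment
columns; hits are filtered by aligned length and identity; a hit
contained in a higher-scoring hit on both axes is merged away; output
order is score-descending, then query start, with no randomization
anywhere.

The matcher is deliberately **ungapped**. The package's divergence
model for planted features is substitutions-only, which makes planted
identity arithmetic exact, and homologous regions that do contain
indels simply appear as several collinear hits — adequate for every
masking and quantification rule here, all of which act on position-set
unions of hits. The e-value thresholds carried in `Thresholds` apply
only when hits come from an external aligner through
`external_search_adapter()` (12-column tabular dialect, coordinates
converted to 0-based half-open, strand from subject coordinate order);
the built-in matcher's filters are length and identity, which at these
sequence sizes dominate the corresponding e-value cut-offs. In the
test-suite, the matcher is cross-checked against an independent
external aligner on planted fixtures.

Length/identity floors follow the protocol the package implements:
reference-classification hits ≥ 500 bp; repeats ≥ 50 bp at ≥ 95 %
identity; MTPT hits < 100 bp masked; cross-genus homology evidence
< 70 bp disregarded; specific runs ≥ 300 bp; attribution best hits
≥ 100 bp; mitovirus cross-taxon hits ≥ 700 bp.

## Assembly finishing

`assemble()` wires the stages:

1. **Classification.** Contigs with a ≥ 500 bp hit to the reference
   mitogenome are mitochondrial; contigs whose plastome homology
   covers ≥ 80 % of their length *and* whose depth is well above the
   mitochondrial band (default 3×) are plastid. The single-copy depth
   `base_cov` is the length-weighted median of mitochondrial contig
   depths, refined over the single-copy band; a weighted median
   resists inflation by collapsed repeats.
2. **Baiting.** Unassigned contigs with depth within
   `base_cov × (1 ± 0.4)` are promoted to mitochondrial; each
   promotion is logged with its ratio. Nuclear background sits far
   below the band, plastid far above.
3. **Copy number.** `round(cov / base_cov)` with floor 1. Ratios whose
   fractional part falls in [0.35, 0.65] are flagged ambiguous — they
   sit between plausible integer assignments and would have required
   manual read-level inspection — but the hard assignment still comes
   from rounding.
4. **MTPT end pairing.** Ends whose terminal window maps to the
   plastome (reaching the contig tip; the mapped interval is projected
   to the exact tip so an edge mismatch cannot shift the boundary) are
   paired greedily by smallest forward plastome gap among
   same-orientation ends, ties broken by contig id. The spanned
   plastome segment becomes the junction filler. Gaps over 10 kb are
   never filled without read-pair evidence (an unbounded fill would
   silently fabricate sequence), and opposite-orientation ends —
   the signature of rearrangement within an MTPT — pair only when
   read-pair evidence names them.
5. **Filler correction.** MTPTs diverge from their plastome source;
   per-base evidence (in simulation, the recorded divergences; in
   practice, re-mapped reads that disagree with the plastome) replaces
   filler bases where the alternative has majority support. Ties keep
   the plastome base and are counted as ambiguous.
6. **Traversal.** Read-pair links resolve which flank enters and which
   leaves each repeat copy, so each pass through a repeat contig is an
   explicit junction. The walk starts at the lexicographically
   smallest unvisited contig (making the chosen traversal
   reproducible), consumes each single-copy contig once and each
   repeat contig once per pass, emits circular chromosomes for closed
   walks and linear ones otherwise, and never force-joins unresolved
   ends — an unresolvable structure comes out as several linear
   chromosomes.
7. **Verification.** `verify_assembly()` flags zero-coverage positions
   and junction windows not spanned by any single reference alignment.
   Inverted repeat pairs longer than the evidence span are reported as
   isomer counts: a flip across such a pair is a valid alternative
   conformation, not an error.

Circular chromosomes are compared by canonical rotation: the
lexicographically smallest rotation over both strands, which makes
round-trip equality well defined.

## The simulator and what it does (not) show

`generate_mitogenome()` plants features into random backbone:
dispersed repeat pairs (identity controlled by point substitutions),
MTPTs copied from a synthetic plastome with recorded divergences,
donor-pool HGT segments, toy gene cassettes, and optionally a
nuclear-origin plasmid-like circle carrying named ORFs.
`fragment_to_contigs()` reproduces the short-read breakage model: cuts
at every repeat and MTPT boundary, one contig per distinct repeat unit
at copy-number-proportional depth with multiplicative lognormal noise,
MTPT interiors absent from the mitochondrial contigs (150-bp stubs
remain on the flanks), plus plastid, nuclear and plasmid background.

Study-condition defaults: genomes 60–150 kb at GC 45 %, 2–4 repeat
pairs of 0.5–3 kb, 1–3 MTPTs of 0.3–5 kb at 0.5 % divergence, 5–10 %
coverage noise, plastome 30 kb at GC 37 %. Two construction choices
matter for interpretation. Features are separated by at least a
configurable backbone gap (800 bp in assembly fixtures, so every
single-copy fragment clears the 500-bp classification rule on its
own; coverage baiting would rescue shorter ones). And assembly
fixtures plant repeat copies at identity 100: short-read assembly
collapses only near-identical repeats into one contig, and
reconstructing base-identical sequence through a collapsed repeat
requires the copies to be identical — diverged repeats are exercised
in the quantification fixtures instead, where the ±2 % recovery
tolerance absorbs boundary trimming at mutated edges. A related
detail: the generator forces the backbone base flanking each planted
repeat copy and MTPT to mismatch its homolog's flank, so that local
alignments stop exactly at planted boundaries and truth totals are
exact rather than inflated by chance flank matches.

What passing these tests does **not** show about real data: no indel
divergence, no chimeric or low-quality contigs, no coverage biases
correlated with GC, no nuclear insertions of mitochondrial DNA
(NUMT-like ambiguity), and read-pair evidence is idealized as correct
links. The simulator fixes the statistical shape of the problem, not
its full messiness.

## Genus-specific sequences

For a target genome, every position covered by a cross-genus hit of
≥ 70 aligned bp is masked; same-genus hits and sub-70-bp hits carry no
evidence. The 70-bp rule is read genome-wide — short scattered
cross-genus hits cannot break a specific run — because the alternative
reading (hiding < 70 bp of sequence from the output) would contradict
the goal of isolating specific sequence. Maximal unmasked runs ≥ 300 bp
are the GSS records; on circular genomes a run may join across the
origin.

Attribution computes hits of each GSS against a labelled reference
collection (`>id [taxon=..] [order=..] [compartment=..]`), then keeps
the maximal-score hit of each non-overlapping sub-region (reciprocal
overlap below 50 %), so a chimeric GSS with two donors yields two best
hits. Score is the ranking criterion; equal-score ties over the same
sub-region are all reported with linkage weight split equally. Best
hits under 100 bp are dropped, and a plastid-compartment best hit
overlapping the genome's own MTPT annotation by ≥ 50 % is flagged an
artifact and excluded from linkage totals. The linkage table aggregates
weighted best-hit lengths per (genus, order) with per-genus compartment
proportions — the quantities a mosaic-origin figure plots.

`shared_homology_fraction()` is the complement of GSS-eligible space.
The simulator's `carpinus_like` genome — enlarged by an extra, slightly
diverged copy of shared core sequence rather than by private
sequence — reproduces the diagnostic contrast: the largest genome shows
the *highest* shared fraction and not the highest GSS total, the
signature of expansion by homolog gain rather than by specific
sequence.

In the multi-genus generator, genus cores diverge ~3 % from a common
ancestor and ~0.5 % within a genus: far inside the matcher's 70 %
identity floor for masking (so shared cores always mask) and far
outside any chance that private random segments mask.

## Other DNA

Plasmid-like screening keeps circular contigs of 1–20 kb whose depth
lies within 0.5–2× of the mitochondrial band and whose mitochondrial
homology covers < 20 % of their length; the coverage band and homology
ceiling are free parameters (they were resolved by inspection in
manual practice) recorded in `default_thresholds()`. Candidates are
reported with GC, ORFs ≥ 100 codons, plastid homology and — when
nuclear references are supplied — whether a single reference's hits
fully encompass the circle. ORF names count sense codons with the stop
excluded (ORF244 spans 732 bp), and circular candidates are scanned
across the origin by doubling.

The mitovirus screen reports genome regions best matching a viral
reference, then searches each region against the other genomes of the
set; hits ≥ 700 bp enter an alignment-ready sequence set (tree
building itself is outside the package's scope).

## Survey statistics and rounding

`table1_stats()` reproduces a survey table's headline numbers from a
metadata table: species/genus/family counts, max/min size ratio,
per-species repeat and MTPT percentages, circular vs linear topology
counts over newly assembled species (an asterisked species name marks
a previously published assembly), and the sampled-family percentage.
Percentages and the ratio round half-up at one decimal — half-even
rounding would change reported values — and a species counts as
circular when its chromosome spec ends in `C` (per-species topology is
uniform in the bundled table; a mixed spec would warn and count as
linear). The total number of families in the order is an input, not a
constant.

## Numerical and degenerate-input choices

- Coordinates are 0-based half-open throughout; circularity is
  sequence metadata and features never wrap (wrapped features are two
  intervals; wrapped GSS runs keep `end = start + length` virtually
  past `L`).
- Interval unions go through `IRanges::reduce`; FASTA IO and
  translation through `Biostrings`; the test-suite's union oracle is an
  independent boolean-array count.
- `union_length` on an empty set is 0; an all-`N` sequence has no
  defined GC; an empty FASTA, an empty plastome collection, a
  singleton genus set, and a reference with no contig hits all raise
  named errors rather than returning empty results silently.
- Copy-number rounding is half-away-from-zero (`floor(r + 0.5)`), so
  the assignment at `r = k + 0.5` does not depend on the parity
  behaviour of `round()`.
- Determinism: the matcher has no randomness; greedy pairings and walk
  starts have total, documented tie-breaks; simulator outputs are
  byte-identical under a fixed seed.

## Problem sizes used in the checks

The bundled checks run entirely on simulated data chosen at desk
scale: twenty 60–150 kb assembly round-trips with ablations,
one hundred 25 kb quantification fixtures, eight three-genus sets of
35 kb genomes for GSS recovery/attribution (with an independent
external aligner as the soundness oracle on three of them), and three
seeds of the shared-versus-specific contrast. These sizes keep the
whole suite a few minutes on one CPU while leaving every rule — length
floors, identity floors, union arithmetic, tie-breaks — exercised at
the same values used on real data.

## Known limitations

Real BAM/SAM read evidence is not ingested; read pairs enter as an
abstract link table. Isomer handling reports flip counts across
inverted repeats but does not enumerate alternative conformations.
E-value statistics are not computed internally. HGT directionality is
deliberately not called — genus-specific presence with foreign best
hits is evidence of transfer, not of its direction. Tandem repeats are
quantified as overlapping self-hits rather than by a dedicated tandem
model, and repeat families are not clustered.
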