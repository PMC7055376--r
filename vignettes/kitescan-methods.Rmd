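---
title: "Surveying smc/scpA/scpB co-occurrence and the ScpA middle region"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying smc/scpA/scpB co-occurrence and the ScpA middle region}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kitescan)
```

## The problem

Prokaryotic condensin-like complexes are built around an SMC dimer, a
kleisin (ScpA) that bridges the two SMC ATPase heads, and — in bacteria —
a pair of kite proteins (ScpB) clamped onto the kleisin's middle region.
Archaea encode Smc and ScpA almost universally, but the third subunit is
a different story: many archaeal lineages have no recognizable *scpB*,
and where the gene exists its product often fails to bind ScpA. The
structural correlate is the length of the kleisin middle region — the
segment between helix α3 and the next conserved helix — which in
bacterial ScpA carries the ScpB-binding interface and is 61–72 residues
long, while in most archaeal ScpAs it is far shorter.

`kitescan` implements the two desk analyses this picture rests on: a
genome-annotation survey of the three genes (occurrence, pseudogene
marks, juxtaposition) and the alignment-based measurement of the
middle-region length. This vignette records the models, the tunable
parameters and the design decisions.

## Occurrence calling

A genome is represented as one record per gene (RefSeq GFF3 splits
genes across gene/CDS rows; the parser unifies them, inheriting the
`product` string from the first CDS child). Only features that can
carry a product name — CDS-bearing genes and pseudogenes — are
*searchable*; RNA genes are invisible to every downstream step,
including intervening-gene counts.

Presence of *smc*, *scpA* and *scpB* is decided in two steps, mirroring
how an annotation-based survey must work:

1. **String search.** Case-insensitive plain-substring match of the
   product text against per-class pattern lists (defaults:
   `"chromosome segregation protein SMC"`;
   `"segregation/condensation protein A"`, `"ScpA"`;
   `"segregation and condensation protein B"`, `"ScpB"`). Substring
   matching without word boundaries is deliberate: RefSeq
   capitalization varies, and the short tokens have no plausible
   case-folded false positives among product names. Matching is
   monotone — adding a pattern can only convert an absent call into a
   string match.

2. **Homology fallback.** Only for classes with no string match, the
   class's query protein is aligned against the genome's proteome with
   the built-in local aligner, and hits are accepted when identity
   exceeds 20% with query coverage above 70% (any class) or identity
   exceeds 50% with coverage above 25% (ScpA only — its conserved
   N-terminal domain is frequently the only aligned segment). All
   inequalities are strict ("higher than"), and the boundary behavior
   is tested on a grid around each cutoff. Imported HMM hit tables are
   classified by E-value instead: below 10⁻⁴ for ScpA and ScpB, below
   10⁻¹⁰⁰ for Smc (the Smc coiled-coil recruits spurious low-E-value
   matches, hence the drastic cutoff).

String evidence dominates: a class with a string match never reports a
homology status. Paralogs collapse to a single per-class call carrying
all matching loci, because the report counts species, not genes. A
class whose every supporting feature is pseudogene-marked is reported
present-with-pseudo-mark; the per-order table counts these separately,
and the HMM comparison columns subtract them (configurable), since a
pseudogene has no protein for an HMM search to find.

## Synteny

Two genes are *neighbors* when zero searchable genes lie strictly
between them on the same replicon — a positional criterion, independent
of strand and of intergenic distance in bp, so strand flips change
nothing. Genes on different replicons are *remote* (not comparable).
Replicons are linear by default; a `circular` flag counts the shorter
arc instead, which can affect at most one gene pair per replicon. When
a class has several loci, the pair minimizing the intervening count is
reported, preferring same-replicon pairs. Intervening counts are
symmetric and additive along a replicon
(`i(a,c) = i(a,b) + i(b,c) + 1` for ordered loci), and both properties
are tested.

## The aligner

The homology fallback and the regions stage share one Gotoh affine-gap
kernel (Rcpp), run in local mode for homology evidence and global mode
for anchor projection. Scoring follows protein-BLAST defaults: BLOSUM62,
gap open 11, gap extend 1, a gap of length *k* costing 11 + *k*; the
ambiguity residue X is rescored to 0 against everything. Identity is
identical pairs over alignment columns including gaps (the BLAST
`pident` convention, which the survey's thresholds presuppose); query
coverage is the query span of the single best local alignment over the
query length — no HSP tiling, the simplest defensible reading of
"coverage of the query". No E-value is computed for the built-in
aligner (Karlin–Altschul statistics are out of scope); E-values enter
only through imported BLAST/HMMER tables.

The test suite checks the kernel against an independently written
pure-R three-matrix DP on hundreds of random short sequences, and
against a second independent implementation (`Biostrings`) on real
protein lengths. Score equality is asserted exactly; identity is
checked on constructed cases rather than between tracebacks, because
distinct optimal alignments of equal score may legitimately differ in
identity.

## Middle-region length by anchor projection

The reference kleisin carries two anchors: the last ordered residue
before the middle region and the first residue of the next conserved
helix — residues 75 and 107 by default, bracketing a 31-residue middle
region. The right anchor is where the fourth helix begins; the left
anchor is fixed so that the reference's own middle region measures 31,
consistent with the disordered stretch beginning at residue 76. Both
anchors are configurable (`anchor_set()`).

For a target sequence, the target is **globally** aligned to the
reference — global, not local, because both kleisin termini are
conserved and both anchors must land in the alignment — and the
target's residues strictly between the columns holding the two anchor
residues are counted. Gaps never shift an anchor: the column actually
containing the reference residue defines the boundary, which makes the
measurement deterministic and direction-independent. The same column
arithmetic applied to a multiple-alignment row gives the MSA variant,
and the two agree on two-sequence inputs (tested).

Properties that hold by construction and are enforced in the suite:
self-measurement returns `right - left - 1` for any valid anchors;
inserting *k* residues strictly inside the middle region and realigning
yields `31 + k` (tested for k up to 35); substitution-only divergence
at ≥ 50% residual identity leaves the length unchanged. Bins are
data-derived and configurable: short-archaeal 30–47, intermediate
48–60, bacterial-like 61–72, anything else out of range. The 61–66
overlap between long archaeal and bacterial lengths is resolved by
length alone in favor of bacterial-like; binning is descriptive — a
bacterial-length archaeal middle region does not imply ScpB binding,
and the package makes no such claim.

## The synthetic-cohort generator

Desk-scale reproduction of a database-wide survey is impossible — the
headline counts of any such survey are snapshots of an annotation
database at a point in time. What *is* testable is the machinery, and
for that the generator is a first-class module, not a fixture: it emits
RefSeq-convention GFF3 (gene/CDS rows, `pseudo=true` flags, a decoy
tRNA gene, percent-encoded products), protein FASTA, a taxonomy
sidecar, and a ground-truth table derived from the cohort
specification alone.

Controlled per genome: presence per class; annotation style (canonical
product name vs `"hypothetical protein"`, which forces the homology
fallback); pseudogene flags; divergence from the bundled seed proteins
(substitutions only, to a target identity realized within ±0.02);
adjacency of the two gene pairs (an exact intervening-gene count, or
remote placement on a second replicon); a middle-region insertion for
scpA; and the number of decoy filler genes, whose product names are
validated never to substring-match any search pattern. The seed
proteins are fixed synthetic sequences (Smc 1180 aa, ScpA 220 aa, ScpB
190 aa — length-matched to the real subunits, with amino-acid
composition drawn from typical prokaryotic frequencies); no real
sequence is redistributed, and the ScpA entry doubles as the regions
reference.

Two generator constraints keep the truth table *derivable*, i.e.
independent of alignment noise:

* Hypothetical-style genes require identity ≥ 0.40 to the seed. Below
  ~40% identity, local-alignment end trimming moves the measured query
  coverage across the 70% cutoff for a few percent of random draws, so
  the expected verdict would not be a function of the specification.
  The classifier's own behavior at the cutoffs is tested separately on
  an explicit boundary grid, so nothing about the thresholds is hidden
  by this floor.
* An expected middle-region length (31 + insertion) is recorded only at
  ≥ 50% residual identity, the regime where substitution-only
  divergence provably preserves the projection.

What the generator does **not** emulate: realistic proteome
composition, codon usage, operon structure, phylogenetic correlation
between genomes, multi-HSP homology, or annotation errors beyond the
hypothetical/pseudogene styles. Passing the closure suite therefore
demonstrates that the pipeline implements its stated rules exactly on
RefSeq-convention inputs — not that those rules recover every true
homolog in real proteomes, where remote homology below the identity
floor is genuinely ambiguous.

## Cohort report

The per-order table counts species (one assembly per species, first by
assembly-id sort), with columns for occurrence per class, the
HMM-comparison columns (populated only when imported HMM tables are
supplied), juxtaposition counts for *smc*–*scpA* and *scpA*–*scpB*, and
pseudogene counts. Invariants enforced in the suite: every count is
bounded by the species count, neighbor counts are bounded by the
occurrence counts of both members, the per-order species counts sum to
the cohort size, and the outlier list is exactly the complement of the
species with all three genes. Serialization (TSV with fixed column
order, JSON with stable keys) is byte-deterministic.

## Problem sizes and numerical notes

The closure suite runs 30 seeded cohorts of 4–50 genomes (the deck of
hand-written genomes covers every presence/style/pseudo/adjacency
combination; the remainder are drawn randomly under a fixed seed), and
the aligner oracle suite uses 500 random pairs of length ≤ 12 over a
4-letter alphabet — small enough for an exhaustive reference DP, large
enough to exercise every recurrence branch. All DP scores are small
integers held in doubles, so equality comparisons are exact. Ties
between optimal alignments are broken deterministically
(match > gap-in-subject > gap-in-query), which fixes the traceback but
never the score. Degenerate inputs error early and name the offending
position: empty sequences, non-alphabet residues, malformed GFF lines
(with line number), unknown loci, ragged alignments, anchors outside
the reference.

## Limitations

* The survey is annotation-driven: genes missing from the GFF are
  invisible to the string step, and the fallback only sees proteins
  supplied in the proteome FASTA.
* Coverage is single-alignment query coverage; fragmented homologs
  (split genes, contig breaks) may under-cover and be missed, as in
  any single-HSP reading of the thresholds.
* The middle-region measurement assumes the target is alignable to the
  reference at both anchors; for kleisins diverged beyond global
  alignability the MSA route with a curated alignment is the right
  tool.
* Bin membership is a length statement only.
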