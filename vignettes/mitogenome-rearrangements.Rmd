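---
title: "Models and methods for mitochondrial gene-rearrangement analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for mitochondrial gene-rearrangement analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitorearr)
```

## The problem

Vertebrate mitochondrial genomes are compact circular DNAs of 16–18 kbp
carrying a nearly fixed set of 37 genes (13 respiratory proteins, 22
tRNAs, 2 rRNAs), a light-strand replication origin (OL) and one major
noncoding region (MNC). The *arrangement* of those genes is strongly
conserved, which makes the occasional rearrangement informative: a
duplicated block, a translocated tRNA, a lost gene, or a tRNA whose
anticodon mutated into a different identity each leaves a recognisable
footprint. `mitorearr` provides the analysis chain for such footprints:
structural annotation of tRNA genes, comparison of circular gene orders,
inference of tandem duplication–random loss (TDRL) events, pseudogene
assessment of duplicated protein genes, and codon-usage deviation tests
that ask whether a lost or reassigned tRNA left a trace in codon
frequencies.

All gene orders are *circular*: every comparison, equality test and
inference in the package is invariant under rotation, and the
conventional origin (`trnF`) is only a display convention.

## The clover-leaf model for mitochondrial tRNA genes

Mitochondrial tRNAs are smaller and looser than cytosolic ones, but a
functional gene still folds into the clover leaf: a 7-bp acceptor stem,
a D arm, a 5-bp anticodon stem with a 7-nt loop, a short extra arm and a
T arm. The package's template fixes what the literature treats as hard
constraints of the compact vertebrate mitochondrial tRNA — two
nucleotides between acceptor and D stems, one between D and anticodon
stems, none between T and acceptor stems, the anticodon at loop
positions 34–36 flanked by T33 and a purine at 37 — and treats the rest
as scored preferences:

* **Stem lengths.** Acceptor 7 bp and anticodon 5 bp (fixed); D stem
  3–4 bp and T stem 4–5 bp; D and T loops 4–9 nt. These ranges are the
  standard envelope of vertebrate mitochondrial tRNAs.
* **Pairing.** Watson–Crick pairs score +2, the G·T wobble +1,
  mismatches −2 with an escalating −2 per mismatch beyond one per stem
  (one wobble-ish defect is ordinary; several in one stem are not).
* **Extra arm.** 3–5 nt is canonical; each nucleotide outside that
  range costs −2.
* **Anticodon-loop bonuses.** +1 each for T33 and purine-37.

Because candidate genes are at most 80 nt, the search is an exhaustive
enumeration of all arm-boundary placements; ties break deterministically
(fewer mismatches, extra arm closest to 4 nt, then enumeration order),
so folding is reproducible to the byte. A fold *succeeds* when at least
70% of the structure's stem positions pair. That floor is a
reconstruction — the original annotation software thresholds are not
published — chosen so that a tRNA with one scrambled stem (7 of 21
pairings lost) falls below it while any single point mutation does not.

Identity is then read from the anticodon (22 isoacceptors; `TTG` = Gln,
`TCG` = Arg, `TTC` = Glu, ...). Functionality has three grades:
`pseudogene` (fold fails or a stem pairs fewer than half its positions),
`degraded` (folds, but the conserved tertiary-interaction motifs
G18–G19 / T55-T56-C57-R58-A59 are absent or the extra arm is
non-canonical), and `functional`. The motif positions are located from
the arm parse — D-loop offsets 5–6 and T-loop offsets 2–6 — so a loop
shorter than six nucleotides is reported as truncated and fails the
motif, which is exactly the situation of a duplicated tRNA gene that
kept its stems but shed loop nucleotides. The motif check matters most
for glutamine tRNAs, whose charging pathway (glutamylation followed by
transamidation) is thought to require the intact L-shaped fold.

## Reassignment detection

A duplicated tRNA gene can acquire a new identity through a single
anticodon substitution. `detect_reassignment()` folds both copies,
aligns them globally, and classifies each substitution as anticodon
(positions 34–36, located independently in each parse) or elsewhere.
The reassignment flag requires that the two assigned identities differ
*and* that at least one substitution sits in the anticodon — the
parsimonious footprint of duplication followed by anticodon point
mutation.

## TDRL: the rearrangement model

A TDRL event duplicates a contiguous block of genes in tandem; each
gene of the block then keeps its first copy, its second copy, or both
(a retained-but-degraded copy is a pseudogene, which the model counts
as retained). For a block of k genes that is 3^k retention patterns;
`enumerate_tdrl_products()` generates all of them and deduplicates the
results as circular orders. Inversions are excluded from the model:
they are rare in vertebrate mitogenomes and absent from the
rearrangement classes handled here.

`infer_tdrl()` searches blocks (capped at 8 genes — every case treated
here needs far less) and retention patterns breadth-first, returning
*all* minimal explanations ordered by block size and leftmost start.
The default budget of two events keeps the search desk-scale; one event
suffices for every worked example. Depth-2 search keys intermediates by
their exact linearisation so that a second event's block indices remain
valid for each stored first event.

Pseudogene-marked genes should be supplied to the inference as retained
copies (strip the `*` marks, and map a reassigned copy back to its
source gene once paralogy is established); projecting pseudogenes out
instead yields the arrangement the genome will show after redundant
copies are deleted.

## Order comparison

`compare_orders()` works on base labels (copy indices and pseudogene
marks stripped, pseudogenes counting as present) and reports missing
genes, duplicated genes, translocated genes — those none of whose copies
preserve a single canonical directed adjacency — and maximal shared
blocks. The shuffling/translocation distinction is the package's own
rule, since the field uses the words informally: a moved gene whose
observed neighbours lie within two canonical steps of its own canonical
position was shuffled locally; anything further travelled is a
translocation. This reproduces the conventional description of the two
motivating cases (a replication-origin cluster shuffle versus a tRNA
moved to the far side of the genome next to the control region).

## Pseudogene assessment

`assess_cds_copy()` aligns a candidate copy to an intact reference CDS
(global alignment, affine gaps: match +1, mismatch −1, gap open 4, gap
extend 1 — ordinary defaults, overridable), classifies indels by length
modulo 3, translates the candidate in the reference frame under the
vertebrate mitochondrial code (AGA/AGG are stops) and counts premature
stops. The three-way status follows the treatment of duplicated
mitochondrial protein genes in the literature: any frameshift indel or
in-frame stop (or identity below 0.5) makes a `pseudogene`; a
frame-intact copy truncated by more than 10% is a `possible_pseudogene`
(the 10% rule is a declared reconstruction — no quantitative threshold
is published); otherwise `functional`. `paralog_vs_ortholog_test()`
flags a recent duplication when the two copies are more similar to each
other than either is to any orthologue, and
`shared_derived_insertion()` finds insertions common to both copies but
absent from an outgroup — evidence that the insertion predates the
duplication.

## Codon-usage deviation tests

The three tests are one-sample goodness-of-fit chi-squares (df = 1, no
continuity correction): a species' observed pair of counts — CAA/CAG,
GAA/GAG, or (CAA+CAG)/(GAA+GAG) — is split against the proportion
implied by a reference panel's average counts, under the null that the
relative frequency is equal across species. The one-sample form (rather
than a 2×2 table against pooled counts) is what reproduces the
published significance pattern: a strong GAA-vs-GAG deviation in the
species that lost its glutamate tRNA gene, and none elsewhere. The
17-species panel averages ship with the package as printed inputs;
absolute codon totals depend on an unpublished multi-species alignment
mask and are deliberately not reproduced (a `mask` argument exists for
users who have their own).

Exact binomial computation puts the true size of the nominal 5% test at
4.75% at the study's typical counts (n = 73, p = 0.778); the test suite
verifies 5% ± 1% over 10,000 simulated nulls.

## Annotation scans

`scan_trnas()` seeds candidate anticodon stems (perfect 5-bp pairing
plus T33 by default), extends each seed over all upstream/downstream arm
placements, and confirms candidates with the full fold. The default
acceptance score of 34 sits between planted synthetic genes (low 40s)
and the best random structures (below the mid 30s); lower it to chase
degraded genes. `scan_cds()` reads open reading frames between tRNA
anchors under the mitochondrial code (start codons ATG/GTG/ATA/ATT,
incomplete terminal T/TA stops allowed); same-strand overlaps in
different frames are kept, because overlapping reading frames
(ND4L/ND4, ATP8/ATP6) are genuine mitogenome architecture, while
same-frame overlaps are nested readings of one gene and opposite-strand
overlaps are mirror artefacts. Gene naming and rRNA boundaries come
from a supplied annotation or simulation truth; homology search is out
of scope. `find_ol_hairpin()` enumerates inverted repeats (stem ≥ 5 bp,
loop 3–20 nt) exhaustively; `find_tandem_repeats()` compares the region
with itself at each candidate unit length, extends exact seed runs over
mismatches while copy identity stays ≥ 85% (the threshold that stops an
array at a flanking weakly-repetitive stretch), never jumps a mismatch
gap longer than half a unit, trims partial-unit boundary creep by
sliding the array phase, and suppresses harmonic calls by preferring the
unit with the most copies.

## The synthetic-data generator

`generate_mitogenome()` is first-class, tested code: it builds a
complete circular genome in a configurable gene order with known ground
truth. Defaults are the study conditions — the canonical 39-element
arrangement; structured tRNA genes with planted motifs; coding genes of
realistic lengths whose Gln/Glu codon proportions default to the
17-species panel averages; rRNA placeholders of 950 and 1,550 bp
(random sequence — rRNA structure is out of scope); an 11-bp-stem
hairpin for OL; 0–5 bp intergenic spacers; and a control region
carrying a 74-bp × 4 array at its 5' end and a 100-bp × 10 array at its
3' end, the repeat architecture reported for the rearranged gecko
control region. Configurable events mirror the phenomena analysed:
TDRL duplications applied to the gene-parts list before assembly,
anticodon point mutations, pseudogenization by 1-bp indels, planted
in-frame stops or stem scrambling, gene deletions, and whole-genome
rotation. A fixed seed gives byte-identical output.

What the generator does *not* emulate: realistic substitution processes
along a phylogeny, strand-asymmetric base composition, heteroplasmy,
rRNA or control-region internal structure beyond the repeats, and the
ND4L/ND4 overlapping reading frames (synthetic genes abut instead).
Passing recovery tests on synthetic genomes therefore demonstrates that
the algorithms detect what they model — planted structures and events —
not that they will annotate any real genome perfectly.

## Worked-example reconstructions

The published worked examples report their sequences only as figures,
which are not distributed with this package. The objects returned by
`example_trna_sequences()`, `example_intergenic_sequences()` and
`example_junction_features()` are **synthetic reconstructions** built to
satisfy every printed property (anticodons, the 4-substitution paralogy
with one change at position 35, extra-arm lengths, motif presence and
absence, the 54/62-bp intergenic lengths); they are labelled synthetic
in code and documentation and must not be mistaken for database
sequences.

## Problem sizes and determinism

The shipped tests exercise: exhaustive TDRL-product equivalence against
an independent deletion-enumeration oracle for every circular source
order of 3–5 genes (all blocks) and 6 genes (blocks to half the
circle); alignment against a brute-force dynamic-programming oracle on
random pairs up to 12 nt; 10,000-replicate type-I calibration of the 5%
test; 22 × 50 seeded tRNA identity recoveries; defect recovery on 100
seeded rearranged genomes; and de-novo scan recall on 20 clean genomes.
All randomness is seeded; every simulation is reproducible.

## Known limitations

* The fold model is combinatorial, not thermodynamic; it will not rank
  near-isoenergetic alternative structures the way an energy model
  would.
* The 70% pairing floor, the stem-length envelope, and the 10%
  truncation rule are reconstructions of published qualitative calls,
  not published parameters.
* TDRL inference reports minimal explanations; biological history may
  of course have been longer.
* `scan_cds()` without a reference annotation names readings `ORF1...`
  and cannot flag split genes; pseudogene flagging needs the reference.
* The shuffling/translocation threshold (two canonical steps) is a
  convention; report consumers should rely on the underlying
  `translocated` set rather than the word.
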