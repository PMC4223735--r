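# mitorearr

Comparative analysis of vertebrate mitochondrial gene rearrangements in
R. The package covers the analysis chain used to characterise rearranged
mitogenomes such as those of gekkonid lizards: structural annotation of
mitochondrial tRNA genes by clover-leaf folding, anticodon-based
identity assignment and detection of identity *reassignment* among
duplicated tRNA genes, comparison of circular gene orders against the
canonical vertebrate arrangement, inference of tandem
duplication–random loss (TDRL) rearrangement events, pseudogene
assessment of duplicated protein-coding genes, stem-loop and
tandem-repeat annotation of noncoding regions, and chi-square tests for
codon-usage deviation. A fully seeded synthetic mitogenome generator
provides ground truth for every stage.

## The models in brief

**Clover-leaf folding.** A candidate tRNA gene (55–80 nt) is parsed by
exhaustive enumeration of arm boundaries under the compact mitochondrial
template (acceptor 7 bp, D stem 3–4 bp, anticodon stem 5 bp with a 7-nt
loop, extra arm 3–5 nt, T stem 4–5 bp; spacers 2/1/0 nt). Watson–Crick
pairs score +2, G·T wobbles +1, mismatches −2 (escalating past one per
stem); a fold succeeds when ≥ 70% of stem positions pair. Identity is
read from the anticodon at positions 34–36; functionality additionally
requires the conserved tertiary-interaction motifs G18G19 (D loop) and
T55T56C57R58A59 (T loop).

**TDRL.** An event duplicates a contiguous gene block in tandem; each
gene keeps its first copy, second copy, or both (pseudogenized copies
count as retained) — 3^k retention patterns for a k-gene block.
`infer_tdrl()` finds all minimal event explanations between two
circular orders; all comparisons are rotation-invariant.

**Codon-usage deviation.** One-sample goodness-of-fit chi-square
(df = 1): a species' CAA/CAG, GAA/GAG or Gln/Glu codon counts are split
against the proportion implied by a 17-species reference-panel average,
under the null that relative frequencies are equal across species.

## Worked example

The two glutamine-family tRNA genes of the worked examples (synthetic
reconstructions of the published figures — see
`?example_trna_sequences`) and the arginine tRNA they derive from:

```r
library(mitorearr)

ex <- example_trna_sequences()
fold_cloverleaf(ex$seq[ex$name == "trnQ1"])
#> <mito_cloverleaf> 71 nt, anticodon TTG, extra arm 4 nt, score 44 (21/21 stem pairs)

rep <- detect_reassignment(ex$seq[ex$name == "trnR"],
                           ex$seq[ex$name == "trnQ2"])
rep
#> <mito_reassignment> trnR vs trnQ: 4 substitutions (anticodon-mediated reassignment)
tidy(rep)
#> # A tibble: 4 x 5
#>   pos_a pos_b base_a base_b anticodon_position
#>   <int> <int> <chr>  <chr>               <int>
#> 1     9     9 A      G                      NA
#> 2    32    32 C      T                      35
#> 3    42    42 A      G                      NA
#> 4    52    52 A      C                      NA
```

Four substitutions separate the paralogs; the one at tRNA position 35
(C→T) converts the arginine anticodon TCG into the glutamine anticodon
TTG — a duplicated tRNA gene reassigned to a new identity.

One TDRL event explains the duplicated ND3–trnH region (pseudogene
copies are retained copies, the reassigned tRNA maps back to its source
gene):

```r
src <- gene_order(c("ND3", "trnR", "ND4L", "ND4", "trnH"))
tgt <- gene_order(c("ND3", "trnR", "ND4L", "ND4",
                    "trnR", "ND4L", "ND4", "trnH"))
infer_tdrl(src, tgt)[[1]][[1]]
#> <tdrl_event> block (trnR, ND4L, ND4), retention: both/both/both
```

And the codon-usage table reproduces the published significance
pattern — only the GAA/GAG cells of the species that lost its glutamate
tRNA gene are starred:

```r
tab <- usage_table(gecko_codon_panel()$species)
tab[, c("species", "cell_gaa", "cell_gag", "p_gaa_gag")]
#> # A tibble: 4 x 4
#>   species                    cell_gaa cell_gag p_gaa_gag
#>   <chr>                      <chr>    <chr>        <dbl>
#> 1 Tropiocolotes tripolitanus 55       18       0.612
#> 2 Tropiocolotes steudneri    61       11       0.158
#> 3 Uroplatus fimbriatus       55       18       0.612
#> 4 Uroplatus ebenaui          42*      31*      0.0000307
```

Simulated genomes give every stage ground truth:

```r
sim <- generate_mitogenome(simulation_config(seed = 1))
sim$record$length
#> [1] 17250
calls <- scan_trnas(sim$record)
truth <- sim$features[sim$features$kind == "tRNA", ]
sum(vapply(seq_len(nrow(truth)), function(i) {
  any(abs(calls$start - truth$start[i]) <= 3 &
        calls$strand == truth$strand[i])
}, logical(1)))   # all 22 planted tRNA genes are called
#> [1] 22
```

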