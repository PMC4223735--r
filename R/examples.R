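# Synthetic reconstructions of the published worked examples.
#
# The primary literature on gecko mitogenome rearrangement reports its
# tRNA and intergenic evidence as figures; the sequences themselves are
# not part of this package's inputs. The objects below are SYNTHETIC
# reconstructions built to satisfy every property stated in print: the
# two glutamine tRNA genes fold with TTG anticodons and 4-nt extra arms,
# the first conserves the D/T-loop tertiary motifs while the second (a
# recent arginine-tRNA paralog) does not and carries truncated D and T
# loops; the arginine tRNA differs from the reassigned copy by exactly
# four substitutions, one of them C->T at the second anticodon position
# (tRNA position 35), the others in the acceptor/D spacer, the extra arm
# and the T loop; the two intergenic stretches at the ND6/cytb junction
# measure 54 and 62 bp and contain no tRNA-like structure.

# construction layout (5'->3'): acceptor 7 | spacer 2 | D stem 4 | D loop |
# D stem' | spacer 1 | AC stem 5 | AC loop 7 | AC stem' 5 | extra arm |
# T stem 5 | T loop | T stem' 5 | acceptor' 7
.syn_trnQ1 <- paste0(
  "TAGGATG", "TA", "AGGC", "TTAAGGTA", "GCCT", "A",
  "CTGGA", "CTTTGGA", "TCCAG", "ACCT",
  "CGGGT", "ATTCGAA", "ACCCG", "CATCCTA"
)
.syn_trnR <- paste0(
  "AGCCTTA", "CA", "CTCA", "TATCA", "TGAG", "G",
  "GCTCA", "TTTCGAT", "TGAGC", "GATA",
  "CCTGA", "CAATG", "TCAGG", "TAAGGCT"
)
.syn_trnQ2 <- paste0(
  "AGCCTTA", "CG", "CTCA", "TATCA", "TGAG", "G",
  "GCTCA", "TTTTGAT", "TGAGC", "GGTA",
  "CCTGA", "CACTG", "TCAGG", "TAAGGCT"
)

#' Synthetic reconstructions of the worked-example tRNA genes
#'
#' Three sense-strand tRNA gene sequences built for the worked examples
#' (see the file-level comment in the source for the construction):
#' `trnQ1`, a canonical glutamine tRNA with both tertiary-interaction
#' motifs; `trnR`, an arginine tRNA with truncated D and T loops; and
#' `trnQ2`, the `trnR` paralog converted to glutamine identity by a C->T
#' substitution at anticodon position 35 plus three accompanying
#' substitutions. All three are synthetic stand-ins, not database
#' sequences.
#'
#' @return A tibble with columns `name`, `seq`, `synthetic`, `note`.
#' @export
example_trna_sequences <- function() {
  tibble(
    name = c("trnQ1", "trnQ2", "trnR"),
    seq = c(.syn_trnQ1, .syn_trnQ2, .syn_trnR),
    synthetic = TRUE,
    note = c(
      "canonical Gln tRNA; G18G19 and T-loop motif present; extra arm 4 nt",
      "trnR paralog reassigned to Gln by C->T at position 35; motifs absent",
      "Arg tRNA (anticodon TCG) with truncated D and T loops"
    )
  )
}

#' Synthetic ND6/cytb intergenic stretches of the two flat-tail geckos
#'
#' Random fixed-seed sequences of the reported lengths (54 and 62 bp)
#' standing in for the intergenic stretches left behind by the loss of
#' the glutamate tRNA gene; they carry no clover-leaf structure.
#'
#' @return A tibble `species`, `length`, `seq`, `synthetic`.
#' @export
example_intergenic_sequences <- function() {
  withr::with_seed(4041L, tibble(
    species = c("U_fimbriatus_like", "U_ebenaui_like"),
    length = c(54L, 62L),
    seq = c(rand_dna(54L), rand_dna(62L)),
    synthetic = TRUE
  ))
}

#' Worked-example gene orders of the rearranged gecko mitogenomes
#'
#' The canonical vertebrate arrangement and the four rearranged
#' organisations analysed in the worked examples: a tandem duplication of
#' the (trnR, ND4L, ND4) block with one copy of each protein gene
#' pseudogenized and one trnR copy reassigned to glutamine; a fourfold
#' tandem duplication of trnL1 plus a shuffled (trnA, OL) x4 unit ahead
#' of the remaining WNCY genes; a glutamate tRNA gene relocated to the 5'
#' end of the major noncoding region; and its outright loss.
#'
#' @return A named list of `mito_order` objects: `canonical`,
#'   `nd3_region_duplication`, `leu_ala_shuffling`, `trne_relocated`,
#'   `trne_lost`.
#' @export
example_gene_orders <- function() {
  canon <- canonical_gene_order()
  replace_span <- function(ord, at, labels, strands) {
    gene_order(append(ord$label[-at], labels, after = at[1] - 1L),
               append(ord$strand[-at], strands, after = at[1] - 1L))
  }
  # ND3 .. trnH region after duplication, reassignment, pseudogenization
  at <- match(c("trnR", "ND4L", "ND4"), canon$label)
  tb <- replace_span(canon, at,
                     c("trnQ2", "ND4L", "ND4*", "trnR", "ND4L*", "ND4"),
                     c("+", "+", "+", "+", "+", "+"))
  # trnL1 x4 (first copy pseudogenized) and (trnA, OL) x4 before WNCY
  sp <- canon
  atL <- match("trnL1", sp$label)
  sp <- replace_span(sp, atL,
                     c("trnL1_1*", "trnL1_2", "trnL1_3", "trnL1_4"),
                     rep("+", 4L))
  atA <- match(c("trnW", "trnA", "trnN", "OL"), sp$label)
  sp <- replace_span(sp, atA,
                     c("trnA1", "OL1", "trnA2", "OL2", "trnA3", "OL3",
                       "trnA4", "OL4", "trnW", "trnN"),
                     c("-", "+", "-", "+", "-", "+", "-", "+", "+", "-"))
  # trnE relocated to the 5' end of the major noncoding region
  uf <- canon
  atE <- match("trnE", uf$label)
  uf <- gene_order(uf$label[-atE], uf$strand[-atE])
  atM <- match("MNC", uf$label)
  uf <- replace_span(uf, atM, c("trnE", "MNC"), c("-", "+"))
  # trnE lost outright
  ue <- canon
  ue <- gene_order(ue$label[-atE], ue$strand[-atE])
  list(canonical = canon, nd3_region_duplication = tb,
       leu_ala_shuffling = sp, trne_relocated = uf, trne_lost = ue)
}

#' Minimal feature tables around the ND6/cytb junction
#'
#' Two synthetic feature tables (coordinates in bp, 0-based half-open)
#' reproducing the junction architecture of the two flat-tail gecko
#' mitogenomes: the glutamate tRNA gene is gone and an unannotated
#' intergenic stretch of 54 bp (relocated-copy species) or 62 bp
#' (loss species) separates ND6 from cytb.
#'
#' @return A named list of two feature tibbles.
#' @export
example_junction_features <- function() {
  mk <- function(gap) {
    nd6_end <- 522L
    tibble(
      label = c("ND6", "CYTB", "trnT", "trnP"),
      kind = c("CDS", "CDS", "tRNA", "tRNA"),
      start = c(0L, nd6_end + gap, nd6_end + gap + 1140L,
                nd6_end + gap + 1140L + 70L),
      end = c(nd6_end, nd6_end + gap + 1140L,
              nd6_end + gap + 1140L + 70L,
              nd6_end + gap + 1140L + 140L),
      strand = c("-", "+", "+", "-"),
      pseudo = "functional",
      aa = c(NA, NA, "T", "P")
    )
  }
  list(U_fimbriatus_like = mk(54L), U_ebenaui_like = mk(62L))
}
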