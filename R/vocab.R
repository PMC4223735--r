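# Gene-name vocabulary, canonical gene order, anticodon table and the
# vertebrate mitochondrial genetic code. Everything downstream (order
# comparison, TDRL inference, simulation) speaks this vocabulary.

trna_bases <- c(
  "trnF", "trnV", "trnL1", "trnL2", "trnI", "trnQ", "trnM", "trnW", "trnA",
  "trnN", "trnC", "trnY", "trnS1", "trnS2", "trnD", "trnK", "trnG", "trnR",
  "trnH", "trnE", "trnT", "trnP"
)

cds_bases <- c(
  "ND1", "ND2", "ND3", "ND4L", "ND4", "ND5", "ND6",
  "COX1", "COX2", "COX3", "ATP6", "ATP8", "CYTB"
)

rrna_bases <- c("rrnS", "rrnL")

#' Canonical gene-name vocabulary
#'
#' The 37 mitochondrial genes of vertebrates (22 tRNAs named `trnX` with the
#' single-letter amino acid, the two leucine and serine isoacceptors
#' disambiguated as `trnL1`/`trnL2` and `trnS1`/`trnS2`, 13 protein-coding
#' genes, 2 rRNAs) plus the light-strand replication origin `OL` and the
#' major noncoding (control) region `MNC`. Labels may carry a copy index
#' (`trnQ2`, `ND4_2`) and a trailing `*` marking a probable pseudogene.
#'
#' @return A character vector of the 39 base labels.
#' @export
gene_vocabulary <- function() {
  c(trna_bases, cds_bases, rrna_bases, "OL", "MNC")
}

kind_of_base <- function(base) {
  dplyr::case_when(
    base %in% trna_bases ~ "tRNA",
    base %in% cds_bases ~ "CDS",
    base %in% rrna_bases ~ "rRNA",
    base == "OL" ~ "OL",
    TRUE ~ "noncoding"
  )
}

#' Parse a gene label into base name, copy index and pseudogene mark
#'
#' @param label Character vector of labels such as `"ND4"`, `"trnQ2"`,
#'   `"trnL1_3"` or `"ND4L*"`.
#' @return A tibble with columns `label`, `base`, `copy` (integer, `NA` when
#'   unindexed), `pseudo` (logical) and `kind`.
#' @export
parse_gene_label <- function(label) {
  vocab <- gene_vocabulary()
  one <- function(lab) {
    pseudo <- grepl("\\*$", lab)
    core <- sub("\\*$", "", lab)
    if (core %in% vocab) {
      return(list(base = core, copy = NA_integer_, pseudo = pseudo))
    }
    m <- regmatches(core, regexec("^([A-Za-z0-9]+)_([0-9]+)$", core))[[1]]
    if (length(m) == 3 && m[2] %in% vocab) {
      return(list(base = m[2], copy = as.integer(m[3]), pseudo = pseudo))
    }
    # bare trailing digit allowed when the base itself carries no digit
    m <- regmatches(core, regexec("^([A-Za-z]+)([0-9]+)$", core))[[1]]
    if (length(m) == 3 && m[2] %in% vocab) {
      return(list(base = m[2], copy = as.integer(m[3]), pseudo = pseudo))
    }
    abort(paste0("unknown gene label: '", lab, "'"))
  }
  parts <- purrr::map(label, one)
  tibble(
    label = label,
    base = map_chr(parts, "base"),
    copy = map_int(parts, "copy"),
    pseudo = map_lgl(parts, "pseudo"),
    kind = kind_of_base(map_chr(parts, "base"))
  )
}

#' The typical vertebrate mitochondrial gene arrangement
#'
#' The canonical circular order of the 37 genes, the light-strand
#' replication origin and the major noncoding region, rooted at `trnF`.
#' Eight tRNAs (`Q A N C Y S1 E P`) and `ND6` lie on the light strand.
#'
#' @return A `mito_order` tibble with columns `label` and `strand`.
#' @export
canonical_gene_order <- function() {
  labels <- c(
    "trnF", "rrnS", "trnV", "rrnL", "trnL1", "ND1", "trnI", "trnQ", "trnM",
    "ND2", "trnW", "trnA", "trnN", "OL", "trnC", "trnY", "COX1", "trnS1",
    "trnD", "COX2", "trnK", "ATP8", "ATP6", "COX3", "trnG", "ND3", "trnR",
    "ND4L", "ND4", "trnH", "trnS2", "trnL2", "ND5", "ND6", "trnE", "CYTB",
    "trnT", "trnP", "MNC"
  )
  light <- c("trnQ", "trnA", "trnN", "trnC", "trnY", "trnS1", "ND6", "trnE",
             "trnP")
  gene_order(labels, ifelse(labels %in% light, "-", "+"))
}

#' Anticodon table for the 22 vertebrate mitochondrial tRNAs
#'
#' Sense-strand DNA anticodon triplets (positions 34-36) keyed to tRNA
#' identity. `TTG` reads the glutamine codons CAR, `TCG` the arginine codons
#' CGN, `TTC` the glutamate codons GAR.
#'
#' @return A tibble with columns `anticodon` and `identity` (the `trnX`
#'   base label).
#' @export
anticodon_table <- function() {
  tibble(
    identity = c("trnF", "trnV", "trnL1", "trnL2", "trnI", "trnQ", "trnM",
                 "trnW", "trnA", "trnN", "trnC", "trnY", "trnS1", "trnS2",
                 "trnD", "trnK", "trnG", "trnR", "trnH", "trnE", "trnT",
                 "trnP"),
    anticodon = c("GAA", "TAC", "TAA", "TAG", "GAT", "TTG", "CAT",
                  "TCA", "TGC", "GTT", "GCA", "GTA", "TGA", "GCT",
                  "GTC", "TTT", "TCC", "TCG", "GTG", "TTC", "TGT",
                  "TGG")
  )
}

# vertebrate mitochondrial genetic code (AGA/AGG stops, ATA Met, TGA Trp);
# fetched from Biostrings once and cached
.code_cache <- new.env(parent = emptyenv())
mito_code <- function() {
  if (is.null(.code_cache$code)) {
    .code_cache$code <- Biostrings::getGeneticCode("2")
  }
  .code_cache$code
}

#' Translate a coding sequence under the vertebrate mitochondrial code
#'
#' @param dna A single DNA string; trailing partial codons are dropped.
#' @return A single amino-acid string with `*` for stop codons.
#' @export
mito_translate <- function(dna) {
  dna <- str_to_upper(dna)
  n <- nchar(dna) %/% 3L
  if (n == 0L) return("")
  codons <- substring(dna, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  code <- mito_code()
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Reverse complement of DNA strings
#'
#' @param dna Character vector over `A C G T N`.
#' @return Character vector of reverse complements.
#' @export
dna_revcomp <- function(dna) {
  vapply(dna, function(s) {
    comp <- chartr("ACGTNacgtn", "TGCANtgcan", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

mito_start_codons <- function() c("ATG", "GTG", "ATA", "ATT")

mito_stop_codons <- function() {
  code <- mito_code()
  names(code)[code == "*"]
}
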