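# Seeded synthetic mitogenome generator. Genomes are assembled gene by
# gene in a configurable circular order, with plantable TDRL duplications,
# pseudogenizations (frameshift indels, in-frame stops, scrambled stems),
# anticodon point mutations, and tandem-repeat arrays in the major
# noncoding region. Every planted fact is returned as ground truth so the
# analysis stages can be scored without external data.

rand_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

aa_letter <- function(base) {
  sub("^trn([A-Z])[0-9]?$", "\\1", base)
}

# realistic vertebrate mitochondrial CDS lengths (bp, multiples of 3)
cds_length_table <- c(
  ND1 = 957, ND2 = 1044, COX1 = 1545, COX2 = 684, ATP8 = 168, ATP6 = 681,
  COX3 = 786, ND3 = 348, ND4L = 297, ND4 = 1377, ND5 = 1812, ND6 = 522,
  CYTB = 1140
)

#' Generate a synthetic mitochondrial tRNA gene with known structure
#'
#' Builds a sense-strand tRNA gene on the compact mitochondrial template:
#' perfectly paired 7-bp acceptor, 4-bp D and 5-bp T stems (T stem 5 bp),
#' 5-bp anticodon stem, canonical spacers (2/1/0 nt), a 7-nt anticodon
#' loop with T33 and purine 37, the anticodon of the requested identity,
#' G18-G19 planted in the D loop and T55-T56-C57-R58-A59 in the T loop.
#'
#' @param identity A `trnX` identity label from [anticodon_table()].
#' @param seed Optional integer seed (same seed, same sequence).
#' @param d_loop_len D-loop length (6-9, default 8).
#' @param extra_len Extra-arm length (default 4).
#' @return A list: `seq`, `identity`, `anticodon`, and `truth` (arm
#'   sequences and coordinates as planted).
#' @export
generate_trna_gene <- function(identity, seed = NULL, d_loop_len = 8L,
                               extra_len = 4L) {
  tab <- anticodon_table()
  if (!identity %in% tab$identity) {
    abort(paste0("unknown tRNA identity: ", identity))
  }
  if (d_loop_len < 6L || d_loop_len > 9L) abort("d_loop_len must be 6-9")
  build <- function() {
    anticodon <- tab$anticodon[tab$identity == identity]
    acc5 <- rand_dna(7L)
    sp2 <- rand_dna(2L)
    d5 <- rand_dna(4L)
    dloop <- paste0(rand_dna(4L), "GG", rand_dna(d_loop_len - 6L))
    sp1 <- rand_dna(1L)
    ac5 <- rand_dna(5L)
    acloop <- paste0(rand_dna(1L), "T", anticodon,
                     sample(c("A", "G"), 1L), rand_dna(1L))
    extra <- rand_dna(extra_len)
    t5 <- rand_dna(5L)
    tloop <- paste0(rand_dna(1L), "TTC", sample(c("A", "G"), 1L), "A",
                    rand_dna(1L))
    seq <- paste0(acc5, sp2, d5, dloop, dna_revcomp(d5), sp1,
                  ac5, acloop, dna_revcomp(ac5), extra,
                  t5, tloop, dna_revcomp(t5), dna_revcomp(acc5))
    anticodon_start <- 7L + 2L + 4L + d_loop_len + 4L + 1L + 5L + 2L + 1L
    list(seq = seq, identity = identity, anticodon = anticodon,
         truth = list(acceptor = acc5, d_stem = d5, d_loop = dloop,
                      anticodon_stem = ac5, anticodon_loop = acloop,
                      extra_arm = extra, t_stem = t5, t_loop = tloop,
                      d_loop_len = d_loop_len, extra_len = extra_len,
                      anticodon_positions = anticodon_start + 0:2))
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Generate an in-frame coding sequence with controlled codon usage
#'
#' Codons are drawn independently: with probability `gln_rate` a glutamine
#' codon (CAA with probability `caa_frac`, else CAG), with probability
#' `glu_rate` a glutamate codon (GAA/GAG via `gaa_frac`), otherwise
#' uniformly from the remaining non-stop codons. The gene starts with ATG
#' and ends with a complete TAA stop; no internal stops can arise.
#'
#' @param length_bp Total length including start and stop (multiple of 3).
#' @param caa_frac,gaa_frac Within-amino-acid codon proportions.
#' @param gln_rate,glu_rate Per-codon probabilities of Gln/Glu.
#' @return A DNA string.
#' @export
generate_cds <- function(length_bp, caa_frac = 69.5 / 81.5,
                         gaa_frac = 58.9 / 75.7,
                         gln_rate = 0.03, glu_rate = 0.03) {
  if (length_bp %% 3L != 0L || length_bp < 9L) {
    abort("CDS length must be a multiple of 3 and >= 9")
  }
  n_mid <- length_bp %/% 3L - 2L
  bases <- c("A", "C", "G", "T")
  space <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  other <- setdiff(space, c(mito_stop_codons(), "CAA", "CAG", "GAA", "GAG"))
  cat_draw <- runif(n_mid)
  codons <- character(n_mid)
  is_gln <- cat_draw < gln_rate
  is_glu <- !is_gln & cat_draw < gln_rate + glu_rate
  codons[is_gln] <- ifelse(runif(sum(is_gln)) < caa_frac, "CAA", "CAG")
  codons[is_glu] <- ifelse(runif(sum(is_glu)) < gaa_frac, "GAA", "GAG")
  rest <- !(is_gln | is_glu)
  codons[rest] <- sample(other, sum(rest), replace = TRUE)
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

#' Simulate a pair of codon counts under a fixed proportion
#'
#' A single binomial draw: `n` codons split between the two synonymous
#' codons with probability `proportion` for the first.
#'
#' @param proportion Probability of the first codon, in (0, 1).
#' @param n Total codon count (>= 1).
#' @param seed Optional seed for reproducibility.
#' @return An integer pair `c(first, second)`.
#' @export
simulate_codon_counts <- function(proportion, n, seed = NULL) {
  if (proportion <= 0 || proportion >= 1) abort("proportion must be in (0,1)")
  if (n < 1L) abort("n must be >= 1")
  draw <- function() {
    k <- rbinom(1L, n, proportion)
    c(k, n - k)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulation configuration for a synthetic mitogenome
#'
#' Defaults generate a typical vertebrate arrangement of 16-18 kbp: 22
#' structured tRNA genes, 13 coding genes with realistic lengths and
#' panel-average Gln/Glu codon proportions, rRNA placeholders (950 and
#' 1,550 bp of random sequence; rRNA structure is out of scope), a
#' stem-loop replication origin inside the WANCY cluster, 0-5 bp
#' intergenic spacers, and a major noncoding region carrying a 74-bp x4
#' array at its 5' end and a 100-bp x10 array at its 3' end — the repeat
#' architecture reported for rearranged gecko control regions.
#'
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @param gene_order A `mito_order` (default [canonical_gene_order()]).
#' @param tdrl_events List of `list(block = c(labels), retention = c(...))`
#'   applied in sequence to the gene parts before assembly.
#' @param pseudogenize List of `list(label =, indels =, stops =,
#'   scramble_stem =)` defects applied to named (post-event) gene copies.
#' @param anticodon_mutations List of `list(label =, position = 34|35|36,
#'   base =)` point mutations in tRNA anticodons.
#' @param delete_genes Labels removed outright (models gene loss).
#' @param repeat_arrays List of `list(unit_length =, copies =,
#'   where = "5prime"|"3prime")` tandem arrays planted in the noncoding
#'   region.
#' @param caa_frac,gaa_frac Codon proportions for CDS synthesis.
#' @param mnc_core_length Length of the central (non-repetitive) control
#'   region.
#' @param spacer_max Maximum intergenic spacer (bp).
#' @param rotate Rotation offset in bp applied to the finished circle.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              gene_order = canonical_gene_order(),
                              tdrl_events = list(),
                              pseudogenize = list(),
                              anticodon_mutations = list(),
                              delete_genes = character(0),
                              repeat_arrays = list(
                                list(unit_length = 74L, copies = 4L,
                                     where = "5prime"),
                                list(unit_length = 100L, copies = 10L,
                                     where = "3prime")
                              ),
                              caa_frac = 69.5 / 81.5,
                              gaa_frac = 58.9 / 75.7,
                              mnc_core_length = 400L,
                              spacer_max = 5L,
                              rotate = 0L) {
  structure(list(seed = seed, gene_order = gene_order,
                 tdrl_events = tdrl_events, pseudogenize = pseudogenize,
                 anticodon_mutations = anticodon_mutations,
                 delete_genes = delete_genes,
                 repeat_arrays = repeat_arrays,
                 caa_frac = caa_frac, gaa_frac = gaa_frac,
                 mnc_core_length = mnc_core_length,
                 spacer_max = spacer_max, rotate = rotate),
            class = "simulation_config")
}

mutate_anticodon <- function(part, position, base) {
  if (is.null(part$trna_truth)) abort("anticodon mutation on a non-tRNA")
  if (!position %in% 34:36) abort("anticodon positions are 34-36")
  at <- part$trna_truth$anticodon_positions[position - 33L]
  old <- substr(part$seq, at, at)
  substr(part$seq, at, at) <- base
  part$mutation <- paste0(old, position, base)
  part
}

pseudogenize_part <- function(part, indels = 0L, stops = 0L,
                              scramble_stem = NULL) {
  s <- part$seq
  if (stops > 0L) {
    n_codon <- nchar(s) %/% 3L
    at <- sample(3:(n_codon - 2L), stops)
    for (k in at) substr(s, 3L * k - 2L, 3L * k) <- "TAA"
  }
  if (indels > 0L) {
    for (i in seq_len(indels)) {
      at <- sample(seq(10L, nchar(s) - 10L), 1L)
      s <- paste0(substr(s, 1L, at - 1L), substr(s, at + 1L, nchar(s)))
    }
  }
  if (!is.null(scramble_stem)) {
    if (is.null(part$trna_truth)) abort("stem scrambling needs a tRNA")
    if (scramble_stem != "acceptor") abort("only acceptor scrambling supported")
    # rewrite the 3' acceptor strand so every paired position faces an
    # identical base: A.A, C.C, G.G, T.T are neither Watson-Crick nor
    # wobble, so the stem cannot pair at all
    acc <- part$trna_truth$acceptor
    repl <- paste(rev(strsplit(acc, "", fixed = TRUE)[[1]]), collapse = "")
    substr(s, nchar(s) - 6L, nchar(s)) <- repl
  }
  part$seq <- s
  part$pseudo <- "pseudogene"
  part
}

#' Generate a synthetic mitogenome with ground truth
#'
#' Assembles the genome in the configured order, applies TDRL events at
#' the gene-parts level (duplicated copies are labelled `base_1`,
#' `base_2` in genomic order), then anticodon mutations, pseudogenizing
#' defects and deletions, and finally concatenates parts (light-strand
#' genes as reverse complements) with short random spacers. The truth set
#' records every planted feature, event and defect.
#'
#' @param config A [simulation_config()].
#' @return A list: `record` (tibble `id`, `seq`, `length`, `circular`),
#'   `features` (truth annotation, 0-based half-open), `truth` (planted
#'   events, defects, repeat arrays, codon proportions, per-gene
#'   sequences).
#' @export
generate_mitogenome <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config")) {
    abort("config must be a simulation_config")
  }
  withr::with_seed(config$seed, {
    parts <- purrr::pmap(
      list(config$gene_order$label, config$gene_order$strand),
      function(label, strand) {
        info <- parse_gene_label(label)
        part <- list(label = label, base = info$base, kind = info$kind,
                     strand = strand, pseudo = "functional",
                     aa = NA_character_, trna_truth = NULL)
        if (info$kind == "tRNA") {
          g <- generate_trna_gene(info$base)
          part$seq <- g$seq
          part$trna_truth <- g$truth
          part$aa <- aa_letter(info$base)
        } else if (info$kind == "CDS") {
          part$seq <- generate_cds(cds_length_table[[info$base]],
                                   config$caa_frac, config$gaa_frac)
        } else if (info$base == "rrnS") {
          part$seq <- rand_dna(950L)
        } else if (info$base == "rrnL") {
          part$seq <- rand_dna(1550L)
        } else if (info$base == "OL") {
          stem <- rand_dna(11L)
          part$seq <- paste0(stem, rand_dna(5L), dna_revcomp(stem))
        } else if (info$base == "MNC") {
          part$seq <- NA_character_  # built below, after the RNG draws
        } else {
          part$seq <- rand_dna(50L)
        }
        part
      })

    # major noncoding region with planted tandem repeats
    repeat_truth <- list()
    mnc_at <- which(vapply(parts, function(p) p$base, character(1)) == "MNC")
    if (length(mnc_at) == 1L) {
      five <- ""
      three <- ""
      for (ra in config$repeat_arrays) {
        cons <- rand_dna(ra$unit_length)
        arr <- strrep(cons, ra$copies)
        if (identical(ra$where, "3prime")) {
          three <- paste0(three, arr)
          repeat_truth[[length(repeat_truth) + 1L]] <-
            list(unit_length = ra$unit_length, copies = ra$copies,
                 consensus = cons, where = "3prime")
        } else {
          five <- paste0(five, arr)
          repeat_truth[[length(repeat_truth) + 1L]] <-
            list(unit_length = ra$unit_length, copies = ra$copies,
                 consensus = cons, where = "5prime")
        }
      }
      parts[[mnc_at]]$seq <- paste0(five, rand_dna(config$mnc_core_length),
                                    three)
    }

    labels_of <- function(ps) vapply(ps, function(p) p$label, character(1))

    # TDRL events on the parts list
    for (ev in config$tdrl_events) {
      labs <- labels_of(parts)
      at <- match(ev$block, labs)
      if (anyNA(at)) {
        abort(paste0("TDRL event references absent gene: ",
                     paste(ev$block[is.na(at)], collapse = ", ")))
      }
      if (!all(diff(at) == 1L)) abort("TDRL block must be contiguous")
      k <- length(at)
      retention <- ev$retention %||% rep("both", k)
      block <- parts[at]
      copy1 <- block[retention != "second"]
      copy2 <- block[retention != "first"]
      both <- ev$block[retention == "both"]
      relabel <- function(ps, which_copy) {
        purrr::map(ps, function(p) {
          if (p$label %in% both) {
            p$label <- paste0(p$label,
                              if (grepl("[0-9]", p$label)) "_" else "",
                              which_copy)
          }
          p
        })
      }
      parts <- c(parts[seq_len(at[1] - 1L)],
                 relabel(copy1, 1L), relabel(copy2, 2L),
                 if (at[k] < length(parts)) {
                   parts[(at[k] + 1L):length(parts)]
                 })
    }

    # anticodon point mutations
    for (mu in config$anticodon_mutations) {
      labs <- labels_of(parts)
      at <- match(mu$label, labs)
      if (is.na(at)) abort(paste0("anticodon mutation references absent ",
                                  "gene: ", mu$label))
      parts[[at]] <- mutate_anticodon(parts[[at]], mu$position, mu$base)
    }

    # pseudogenizing defects
    for (pz in config$pseudogenize) {
      labs <- labels_of(parts)
      at <- match(pz$label, labs)
      if (is.na(at)) abort(paste0("pseudogenization references absent ",
                                  "gene: ", pz$label))
      parts[[at]] <- pseudogenize_part(parts[[at]],
                                       indels = pz$indels %||% 0L,
                                       stops = pz$stops %||% 0L,
                                       scramble_stem = pz$scramble_stem)
    }

    # deletions (gene loss)
    if (length(config$delete_genes) > 0L) {
      labs <- labels_of(parts)
      miss <- setdiff(config$delete_genes, labs)
      if (length(miss) > 0L) {
        abort(paste0("deletion references absent gene: ",
                     paste(miss, collapse = ", ")))
      }
      parts <- parts[!labs %in% config$delete_genes]
    }

    # assembly
    seqs <- character(0)
    rows <- list()
    pos <- 0L
    for (p in parts) {
      fwd <- if (p$strand == "-") dna_revcomp(p$seq) else p$seq
      len <- nchar(fwd)
      rows[[length(rows) + 1L]] <- tibble(
        label = p$label, kind = p$kind, start = pos, end = pos + len,
        strand = p$strand, pseudo = p$pseudo, aa = p$aa
      )
      seqs <- c(seqs, fwd)
      pos <- pos + len
      sp <- sample(0:config$spacer_max, 1L)
      if (sp > 0L) {
        seqs <- c(seqs, rand_dna(sp))
        pos <- pos + sp
      }
    }
    genome <- paste(seqs, collapse = "")
    features <- list_rbind(rows)

    if (config$rotate != 0L) {
      L <- nchar(genome)
      off <- config$rotate %% L
      genome <- paste0(substr(genome, off + 1L, L), substr(genome, 1L, off))
      new_start <- (features$start - off) %% L
      features$end <- new_start + (features$end - features$start)
      features$start <- new_start
      features <- arrange(features, .data$start)
    }

    gene_seqs <- setNames(purrr::map_chr(parts, function(p) p$seq),
                          labels_of(parts))
    list(
      record = tibble(id = paste0("synthetic_mitogenome_seed",
                                  config$seed),
                      seq = genome, length = nchar(genome),
                      circular = TRUE),
      features = features,
      truth = list(seed = config$seed,
                   gene_order = extract_gene_order(features,
                                                   nchar(genome)),
                   events = config$tdrl_events,
                   anticodon_mutations = config$anticodon_mutations,
                   pseudogenize = config$pseudogenize,
                   delete_genes = config$delete_genes,
                   repeat_arrays = repeat_truth,
                   caa_frac = config$caa_frac, gaa_frac = config$gaa_frac,
                   gene_seqs = gene_seqs)
    )
  })
}
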