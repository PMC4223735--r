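# Pairwise alignment of duplicated gene copies and pseudogene assessment.
# Alignment is standard global (Needleman-Wunsch) with affine gaps,
# delegated to Biostrings; the classification logic on top (frameshift
# indels, in-frame stops, truncation) is what this module adds.

detect_alphabet <- function(x) {
  if (grepl("[^ACGTN]", str_to_upper(gsub("-", "", x)))) "protein" else "dna"
}

dna_sub_matrix <- function(match = 1, mismatch = -1) {
  m <- matrix(mismatch, 5, 5, dimnames = list(pair_letters, pair_letters))
  diag(m) <- match
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch global alignment. Nucleotide mode scores match +1,
#' mismatch -1; protein mode uses BLOSUM62. A gap of length L costs
#' `gap_open + L * gap_extend`. Traceback is deterministic.
#'
#' @param a,b Sequences (single strings). Both must be the same alphabet;
#'   mixing DNA and protein is an error.
#' @param mode `"auto"` (default), `"dna"` or `"protein"`.
#' @param match,mismatch Nucleotide scores.
#' @param gap_open,gap_extend Affine gap costs (positive numbers).
#' @return A `mito_alignment` list: `aligned_a`, `aligned_b`, `matches`,
#'   `mismatches`, `gap_openings`, `gap_positions`, `identity`
#'   (matches / aligned columns, excluding double gaps), `score`, `mode`.
#' @export
global_align <- function(a, b, mode = c("auto", "dna", "protein"),
                         match = 1, mismatch = -1,
                         gap_open = 4, gap_extend = 1) {
  mode <- match.arg(mode)
  if (!nzchar(a) || !nzchar(b)) abort("cannot align an empty sequence")
  a <- str_to_upper(a); b <- str_to_upper(b)
  alph <- c(detect_alphabet(a), detect_alphabet(b))
  if (mode == "auto") {
    if (alph[1] != alph[2]) abort("sequences have mixed alphabets")
    mode <- alph[1]
  } else if (mode == "dna" && any(alph == "protein")) {
    abort("non-nucleotide letters in dna-mode alignment")
  }
  if (mode == "dna") {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b),
      type = "global", substitutionMatrix = dna_sub_matrix(match, mismatch),
      gapOpening = gap_open, gapExtension = gap_extend
    )
  } else {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = gap_open, gapExtension = gap_extend
    )
  }
  al_a <- as.character(Biostrings::alignedPattern(pa))
  al_b <- as.character(Biostrings::alignedSubject(pa))
  va <- strsplit(al_a, "", fixed = TRUE)[[1]]
  vb <- strsplit(al_b, "", fixed = TRUE)[[1]]
  cols <- va != "-" | vb != "-"
  matches <- sum(va == vb & va != "-")
  gaps <- c(rle(va == "-"), rle(vb == "-"))
  gap_open_n <- sum(rle(va == "-")$values) + sum(rle(vb == "-")$values)
  structure(list(
    aligned_a = al_a, aligned_b = al_b,
    matches = matches,
    mismatches = sum(va != vb & va != "-" & vb != "-"),
    gap_openings = gap_open_n,
    gap_positions = sum(va == "-") + sum(vb == "-"),
    identity = matches / sum(cols),
    score = Biostrings::score(pa),
    mode = mode
  ), class = "mito_alignment")
}

#' @export
print.mito_alignment <- function(x, ...) {
  cat("<mito_alignment> identity ", round(x$identity, 3), ", ",
      x$mismatches, " mismatches, ", x$gap_positions,
      " gap positions, score ", x$score, "\n", sep = "")
  invisible(x)
}

#' @method glance mito_alignment
#' @export
glance.mito_alignment <- function(x, ...) {
  tibble(matches = x$matches, mismatches = x$mismatches,
         gap_openings = x$gap_openings, gap_positions = x$gap_positions,
         identity = x$identity, score = x$score, mode = x$mode)
}

gap_runs <- function(gapped) {
  v <- strsplit(gapped, "", fixed = TRUE)[[1]]
  r <- rle(v == "-")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble(start = starts[r$values], length = r$lengths[r$values])
}

#' Assess a candidate copy of a protein-coding gene against a reference
#'
#' Aligns the candidate to a validated in-frame reference CDS at the
#' nucleotide level, classifies every indel by length modulo 3, translates
#' the candidate in the reference frame under the vertebrate mitochondrial
#' code (AGA/AGG are stops) and counts premature stop codons. Status
#' follows the three-way scheme used for duplicated mitochondrial genes:
#' `pseudogene` with any frameshift indel, in-frame stop, or identity
#' below `identity_floor`; `possible_pseudogene` when frame-intact but
#' truncated by more than 10% relative to the reference; `functional`
#' otherwise.
#'
#' @param candidate Candidate copy (DNA, sense strand).
#' @param reference_cds Validated reference CDS (DNA, in frame, no
#'   internal stops; an invalid reference is an error).
#' @param identity_floor Identity below which the copy is called a
#'   pseudogene outright (default 0.5).
#' @return A one-row tibble: `frameshift_indels`, `inframe_stops`,
#'   `identity_to_reference`, `status`, `evidence`.
#' @export
assess_cds_copy <- function(candidate, reference_cds, identity_floor = 0.5) {
  ref_aa <- mito_translate(reference_cds)
  internal <- substr(ref_aa, 1, nchar(ref_aa) - 1L)
  if (grepl("\\*", internal)) {
    abort("reference CDS contains internal stop codons")
  }
  aln <- global_align(candidate, reference_cds, mode = "dna")
  indels <- bind_rows(gap_runs(aln$aligned_a), gap_runs(aln$aligned_b))
  frameshift <- sum(indels$length %% 3L != 0L)

  # translate the candidate in the frame carried over from the reference
  va <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  vb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  ref_pos <- cumsum(vb != "-")
  cand_pos <- cumsum(va != "-")
  anchor <- which(va != "-" & vb != "-" & (ref_pos - 1L) %% 3L == 0L)
  stops <- 0L
  if (length(anchor) > 0L) {
    p <- cand_pos[anchor[1]]
    cand <- gsub("-", "", aln$aligned_a)
    aa <- mito_translate(substr(cand, p, nchar(cand)))
    if (nchar(aa) > 1L) {
      stops <- lengths(regmatches(substr(aa, 1, nchar(aa) - 1L),
                                  gregexpr("\\*", substr(aa, 1,
                                                         nchar(aa) - 1L))))
    }
  }
  truncated <- nchar(candidate) < 0.9 * nchar(reference_cds)
  evidence <- character(0)
  if (frameshift > 0L) evidence <- c(evidence,
                                     paste0(frameshift, " frameshift indel(s)"))
  if (stops > 0L) evidence <- c(evidence,
                                paste0(stops, " premature stop codon(s)"))
  if (aln$identity < identity_floor) {
    evidence <- c(evidence, "identity below floor")
  }
  status <- if (length(evidence) > 0L) {
    "pseudogene"
  } else if (truncated) {
    evidence <- "frame-intact but truncated >10%"
    "possible_pseudogene"
  } else {
    "functional"
  }
  tibble(frameshift_indels = frameshift, inframe_stops = as.integer(stops),
         identity_to_reference = aln$identity, status = status,
         evidence = paste(evidence, collapse = "; "))
}

#' Test whether two gene copies are a recent duplication
#'
#' Compares the identity between two paralogous copies with the identity
#' of each copy to a panel of orthologues. A recent duplication leaves the
#' paralogs more similar to each other than either is to any orthologue.
#'
#' @param copy1,copy2 The two paralogous sequences.
#' @param orthologs A character vector of orthologue sequences (>= 1).
#' @param mode Alignment mode passed to [global_align()].
#' @return A one-row tibble: `paralog_identity`, `mean_ortholog_identity`,
#'   `max_ortholog_identity`, `recent_duplication`.
#' @export
paralog_vs_ortholog_test <- function(copy1, copy2, orthologs,
                                     mode = "auto") {
  if (length(orthologs) < 1L) abort("need at least one orthologue")
  par_id <- global_align(copy1, copy2, mode = mode)$identity
  orth <- unlist(purrr::map(orthologs, function(o) {
    c(global_align(copy1, o, mode = mode)$identity,
      global_align(copy2, o, mode = mode)$identity)
  }))
  tibble(paralog_identity = par_id,
         mean_ortholog_identity = mean(orth),
         max_ortholog_identity = max(orth),
         recent_duplication = par_id > max(orth) ||
           (par_id == 1 && max(orth) == 1))
}

insertion_runs <- function(copy, outgroup, mode) {
  aln <- global_align(copy, outgroup, mode = mode)
  vo <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  out_pos <- cumsum(vo != "-")
  r <- gap_runs(aln$aligned_b)  # gaps in outgroup = insertions in copy
  if (nrow(r) == 0L) return(r |> mutate(after = integer(0)))
  r$after <- ifelse(r$start == 1L, 0L, out_pos[r$start - 1L])
  r
}

#' Shared derived insertions of two gene copies relative to an outgroup
#'
#' Finds sequence blocks present in both paralogous copies but absent from
#' the outgroup — the signature of an insertion predating the duplication.
#' Alignment is progressive pairwise (each copy against the outgroup);
#' intervals are reported in outgroup coordinates as the position after
#' which the block inserts.
#'
#' @param copy1,copy2 The two copies.
#' @param outgroup The outgroup sequence.
#' @param mode Alignment mode.
#' @return A tibble with columns `after` (outgroup position) and `length`;
#'   empty when no insertion is shared.
#' @export
shared_derived_insertion <- function(copy1, copy2, outgroup, mode = "auto") {
  r1 <- insertion_runs(copy1, outgroup, mode)
  r2 <- insertion_runs(copy2, outgroup, mode)
  if (nrow(r1) == 0L || nrow(r2) == 0L) {
    return(tibble(after = integer(0), length = integer(0)))
  }
  shared <- dplyr::inner_join(
    select(r1, "after", len1 = "length"),
    select(r2, "after", len2 = "length"),
    by = "after"
  )
  tibble(after = shared$after,
         length = pmin(shared$len1, shared$len2))
}
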