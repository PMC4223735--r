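# Clover-leaf folding of candidate mitochondrial tRNA genes.
#
# The structural template is the compact vertebrate mitochondrial tRNA:
# 7-bp acceptor stem, 2-nt spacer, D arm (3-4 bp stem, 4-9 nt loop), 1-nt
# spacer, anticodon arm (5-bp stem, 7-nt loop with the anticodon at loop
# positions 3-5 = tRNA positions 34-36), extra arm (canonically 3-5 nt),
# T arm (4-5 bp stem, 4-9 nt loop), no spacer before the 3' acceptor
# strand. Watson-Crick pairs and the G.T wobble count as pairings. Search
# is exhaustive over arm-boundary placements (sequences are <= 80 nt), so
# folding is deterministic.

pair_letters <- c("A", "C", "G", "T", "N")

.pair_score <- local({
  m <- matrix(-2L, 5, 5, dimnames = list(pair_letters, pair_letters))
  m["A", "T"] <- m["T", "A"] <- m["G", "C"] <- m["C", "G"] <- 2L
  m["G", "T"] <- m["T", "G"] <- 1L
  m
})

stem_stats <- function(v, i5, i3) {
  sc <- .pair_score[cbind(v[i5], v[rev(i3)])]
  paired <- sum(sc > 0L)
  mism <- length(i5) - paired
  list(score = sum(sc) - if (mism > 1L) 2L * (mism - 1L) else 0L,
       paired = paired, mismatch = mism, wobble = sum(sc == 1L))
}

cloverleaf_combos <- function(L) {
  g <- expand.grid(d = 3:4, dl = 4:9, v = 0:8, t = 4:5, tl = 4:9,
                   KEEP.OUT.ATTRS = FALSE)
  g[34L + 2L * g$d + g$dl + g$v + 2L * g$t + g$tl == L, , drop = FALSE]
}

#' Fold a candidate sequence into a mitochondrial tRNA clover-leaf
#'
#' Exhaustively enumerates arm-boundary placements under the hard
#' constraints of the compact mitochondrial tRNA template (7-nt anticodon
#' loop; 2 nt between acceptor and D stems; 1 nt between D and anticodon
#' stems; 0 nt between T and acceptor stems) and returns the best-scoring
#' structure. The score rewards Watson-Crick (+2) over wobble G.T (+1)
#' pairs, penalises stem mismatches (-2, escalating past one mismatch per
#' stem), penalises extra-arm lengths outside 3-5 nt, and gives small
#' bonuses for the conserved T33 and purine-37 of the anticodon loop. Ties
#' break towards fewer mismatches, an extra arm closest to 4 nt, then the
#' first structure in enumeration order.
#'
#' Folding fails (returns `NULL`) when the best structure pairs fewer than
#' 70% of its stem positions; with `enforce_floor = FALSE` the best
#' structure is returned regardless, with `passes_floor` recording the
#' verdict — useful for describing why a degenerate candidate fails.
#'
#' @param seq A sense-strand DNA string, 55-80 nt.
#' @param enforce_floor Return `NULL` below the pairing floor (default).
#' @return A `mito_cloverleaf` object, or `NULL` when no structure reaches
#'   the pairing floor.
#' @export
fold_cloverleaf <- function(seq, enforce_floor = TRUE) {
  seq <- str_to_upper(seq)
  L <- nchar(seq)
  if (L < 55L || L > 80L) {
    abort(paste0("candidate tRNA length ", L, " outside 55-80 nt"))
  }
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  v[!v %in% pair_letters] <- "N"
  combos <- cloverleaf_combos(L)
  if (nrow(combos) == 0L) return(NULL)

  best <- NULL
  for (r in seq_len(nrow(combos))) {
    d <- combos$d[r]; dl <- combos$dl[r]; vv <- combos$v[r]
    t <- combos$t[r]; tl <- combos$tl[r]
    acc5 <- 1:7
    d5 <- 10:(9L + d)
    dloop <- (10L + d):(9L + d + dl)
    d3 <- (10L + d + dl):(9L + 2L * d + dl)
    ac5 <- (11L + 2L * d + dl):(15L + 2L * d + dl)
    acloop <- (16L + 2L * d + dl):(22L + 2L * d + dl)
    ac3 <- (23L + 2L * d + dl):(27L + 2L * d + dl)
    extra <- if (vv > 0L) (28L + 2L * d + dl):(27L + 2L * d + dl + vv)
             else integer(0)
    t5 <- (28L + 2L * d + dl + vv):(27L + 2L * d + dl + vv + t)
    tloop <- (28L + 2L * d + dl + vv + t):(27L + 2L * d + dl + vv + t + tl)
    t3 <- (28L + 2L * d + dl + vv + t + tl):(27L + 2L * d + dl + vv + 2L * t + tl)
    acc3 <- (L - 6L):L

    s_acc <- stem_stats(v, acc5, acc3)
    s_d <- stem_stats(v, d5, d3)
    s_ac <- stem_stats(v, ac5, ac3)
    s_t <- stem_stats(v, t5, t3)

    score <- s_acc$score + s_d$score + s_ac$score + s_t$score
    if (vv < 3L) score <- score - 2L * (3L - vv)
    if (vv > 5L) score <- score - 2L * (vv - 5L)
    if (v[acloop[2]] == "T") score <- score + 1L
    if (v[acloop[6]] %in% c("A", "G")) score <- score + 1L

    mism <- s_acc$mismatch + s_d$mismatch + s_ac$mismatch + s_t$mismatch
    cand_rank <- c(score, -mism, -abs(vv - 4L))
    if (is.null(best) ||
        (cand_rank[1] > best$rank[1]) ||
        (cand_rank[1] == best$rank[1] && cand_rank[2] > best$rank[2]) ||
        (cand_rank[1] == best$rank[1] && cand_rank[2] == best$rank[2] &&
         cand_rank[3] > best$rank[3])) {
      best <- list(
        rank = cand_rank, score = score,
        d = d, dl = dl, v = vv, t = t, tl = tl,
        idx = list(acceptor_5 = acc5, spacer_acc_d = 8:9, d_stem_5 = d5,
                   d_loop = dloop, d_stem_3 = d3,
                   spacer_d_ac = 10L + 2L * d + dl,
                   anticodon_stem_5 = ac5, anticodon_loop = acloop,
                   anticodon_stem_3 = ac3, extra_arm = extra,
                   t_stem_5 = t5, t_loop = tloop, t_stem_3 = t3,
                   acceptor_3 = acc3),
        stems = tibble(
          stem = c("acceptor", "D", "anticodon", "T"),
          length = c(7L, d, 5L, t),
          paired = c(s_acc$paired, s_d$paired, s_ac$paired, s_t$paired),
          wobble = c(s_acc$wobble, s_d$wobble, s_ac$wobble, s_t$wobble),
          mismatches = c(s_acc$mismatch, s_d$mismatch, s_ac$mismatch,
                         s_t$mismatch)
        )
      )
    }
  }

  target_pairs <- 7L + best$d + 5L + best$t
  pairs_present <- sum(best$stems$paired)
  passes_floor <- pairs_present >= ceiling(0.7 * target_pairs)
  if (!passes_floor && enforce_floor) return(NULL)

  idx <- best$idx
  structure(
    list(
      seq = seq, length = L,
      anticodon = paste(v[idx$anticodon_loop[3:5]], collapse = ""),
      anticodon_positions = idx$anticodon_loop[3:5],
      extra_arm_length = best$v,
      d_loop_length = best$dl, t_loop_length = best$tl,
      d_stem_length = best$d, t_stem_length = best$t,
      spacer_acc_d = 2L, spacer_d_ac = 1L, spacer_t_acc = 0L,
      stems = best$stems,
      pairs_present = pairs_present, target_pairs = target_pairs,
      passes_floor = passes_floor,
      score = best$score,
      arms = idx,
      d_loop_seq = paste(v[idx$d_loop], collapse = ""),
      t_loop_seq = paste(v[idx$t_loop], collapse = "")
    ),
    class = "mito_cloverleaf"
  )
}

#' @export
print.mito_cloverleaf <- function(x, ...) {
  cat("<mito_cloverleaf> ", x$length, " nt, anticodon ", x$anticodon,
      ", extra arm ", x$extra_arm_length, " nt, score ", x$score,
      " (", x$pairs_present, "/", x$target_pairs, " stem pairs)\n", sep = "")
  invisible(x)
}

#' @describeIn fold_cloverleaf Arm-by-arm tidy view of a folded structure.
#' @param x A `mito_cloverleaf`.
#' @param ... Unused.
#' @method tidy mito_cloverleaf
#' @export
tidy.mito_cloverleaf <- function(x, ...) {
  v <- strsplit(x$seq, "", fixed = TRUE)[[1]]
  purrr::imap(x$arms, function(idx, nm) {
    tibble(element = nm,
           start = if (length(idx)) min(idx) else NA_integer_,
           end = if (length(idx)) max(idx) else NA_integer_,
           seq = paste(v[idx], collapse = ""))
  }) |> list_rbind()
}

#' @describeIn fold_cloverleaf One-row structural summary.
#' @method glance mito_cloverleaf
#' @export
glance.mito_cloverleaf <- function(x, ...) {
  tibble(length = x$length, anticodon = x$anticodon,
         extra_arm_length = x$extra_arm_length,
         pairs_present = x$pairs_present, target_pairs = x$target_pairs,
         mismatches = sum(x$stems$mismatches), score = x$score)
}

#' Assign tRNA identity from the anticodon
#'
#' @param cl A `mito_cloverleaf`.
#' @param table An anticodon table ([anticodon_table()] by default).
#' @return The `trnX` identity label, or `"unassigned"` when the anticodon
#'   triplet is absent from the table.
#' @export
assign_identity <- function(cl, table = anticodon_table()) {
  hit <- table$identity[table$anticodon == cl$anticodon]
  if (length(hit) == 1L) hit else "unassigned"
}

#' Check the conserved D-loop and T-loop tertiary-interaction motifs
#'
#' Functional mitochondrial tRNA-Gln genes conserve G18-G19 in the D loop
#' and T55-T56-C57-R58-A59 (R = purine) in the T loop, nucleotides that
#' form the tertiary hydrogen bonds of the L-shaped fold. Positions are
#' located from the arm parse: 18-19 are D-loop positions 5-6 and 55-59
#' are T-loop positions 2-6, so a loop shorter than six nucleotides is
#' reported as truncated and fails the motif.
#'
#' @param cl A `mito_cloverleaf`.
#' @return A one-row tibble with `motif_d_loop`, `motif_t_loop`, `note`.
#' @export
check_conserved_motifs <- function(cl) {
  notes <- character(0)
  dseq <- strsplit(cl$d_loop_seq, "", fixed = TRUE)[[1]]
  if (length(dseq) >= 6L) {
    d_ok <- dseq[5] == "G" && dseq[6] == "G"
    if (!d_ok) notes <- c(notes, "G18G19 absent")
  } else {
    d_ok <- FALSE
    notes <- c(notes, "D loop truncated")
  }
  tseq <- strsplit(cl$t_loop_seq, "", fixed = TRUE)[[1]]
  if (length(tseq) >= 6L) {
    t_ok <- tseq[2] == "T" && tseq[3] == "T" && tseq[4] == "C" &&
      tseq[5] %in% c("A", "G") && tseq[6] == "A"
    if (!t_ok) notes <- c(notes, "T55T56C57R58A59 absent")
  } else {
    t_ok <- FALSE
    notes <- c(notes, "T loop truncated")
  }
  tibble(motif_d_loop = d_ok, motif_t_loop = t_ok,
         note = paste(notes, collapse = "; "))
}

#' Classify the functionality of a candidate tRNA gene
#'
#' A candidate is a `pseudogene` when folding fails or any stem pairs
#' fewer than half of its positions; `degraded` when it folds but violates
#' the conserved-motif or extra-arm constraints; `functional` otherwise.
#' Every non-functional call carries at least one recorded reason.
#'
#' @param cl A `mito_cloverleaf`, or `NULL` for a failed fold.
#' @param motifs Optional precomputed [check_conserved_motifs()] row.
#' @param table Anticodon table for identity assignment.
#' @return A one-row tibble: `identity`, `functionality`, `motif_d_loop`,
#'   `motif_t_loop`, `notes`.
#' @export
classify_functionality <- function(cl, motifs = NULL,
                                   table = anticodon_table()) {
  if (is.null(cl)) {
    return(tibble(identity = "unassigned", functionality = "pseudogene",
                  motif_d_loop = NA, motif_t_loop = NA,
                  notes = "no clover-leaf structure above the pairing floor"))
  }
  reasons <- character(0)
  weak <- cl$stems$paired < cl$stems$length / 2
  if (any(weak)) {
    reasons <- c(reasons,
                 paste0(cl$stems$stem[weak], " stem degenerate"))
  }
  below_floor <- !(cl$passes_floor %||% TRUE)
  if (below_floor && length(reasons) == 0L) {
    reasons <- "stem pairings below the structural floor"
  }
  if (is.null(motifs)) motifs <- check_conserved_motifs(cl)
  status <- if (any(weak) || below_floor) "pseudogene" else "functional"
  if (status == "functional") {
    if (!motifs$motif_d_loop || !motifs$motif_t_loop) {
      status <- "degraded"
      reasons <- c(reasons, motifs$note)
    }
    if (cl$extra_arm_length < 3L || cl$extra_arm_length > 5L) {
      status <- "degraded"
      reasons <- c(reasons, "extra arm outside 3-5 nt")
    }
  }
  tibble(identity = assign_identity(cl, table), functionality = status,
         motif_d_loop = motifs$motif_d_loop,
         motif_t_loop = motifs$motif_t_loop,
         notes = paste(reasons, collapse = "; "))
}

#' Detect identity reassignment between two paralogous tRNA genes
#'
#' Folds both sequences, aligns them globally and classifies every
#' substitution as lying inside the anticodon (tRNA positions 34-36) or
#' elsewhere. Reassignment is flagged when the two assigned identities
#' differ and at least one anticodon-position substitution accounts for
#' the difference — the signature of a duplicated tRNA gene converted to a
#' new identity by anticodon point mutation.
#'
#' @param gene_a,gene_b Sense-strand DNA sequences of the two genes.
#' @param table Anticodon table.
#' @return A list of class `mito_reassignment`: `identity_a`,
#'   `identity_b`, `substitutions` (tibble with `pos_a`, `pos_b`, `base_a`,
#'   `base_b`, `anticodon_position`), `n_substitutions`, `identity`
#'   (alignment identity), `reassigned`, `degraded`.
#' @export
detect_reassignment <- function(gene_a, gene_b, table = anticodon_table()) {
  cl_a <- tryCatch(fold_cloverleaf(gene_a), error = function(e) NULL)
  cl_b <- tryCatch(fold_cloverleaf(gene_b), error = function(e) NULL)
  aln <- global_align(gene_a, gene_b)
  av <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  bv <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  pos_a <- cumsum(av != "-")
  pos_b <- cumsum(bv != "-")
  subs_i <- which(av != "-" & bv != "-" & av != bv)
  anticodon_pos <- function(cl, p) {
    if (is.null(cl)) return(NA_integer_)
    k <- match(p, cl$anticodon_positions)
    if (is.na(k)) NA_integer_ else 33L + k
  }
  acp <- vapply(subs_i, function(i) {
    p <- anticodon_pos(cl_a, pos_a[i])
    if (is.na(p)) p <- anticodon_pos(cl_b, pos_b[i])
    p
  }, integer(1))
  subs <- tibble(
    pos_a = pos_a[subs_i], pos_b = pos_b[subs_i],
    base_a = av[subs_i], base_b = bv[subs_i],
    anticodon_position = acp
  )
  id_a <- if (is.null(cl_a)) "unassigned" else assign_identity(cl_a, table)
  id_b <- if (is.null(cl_b)) "unassigned" else assign_identity(cl_b, table)
  structure(list(
    identity_a = id_a, identity_b = id_b,
    substitutions = subs, n_substitutions = nrow(subs),
    identity = aln$identity,
    reassigned = !is.null(cl_a) && !is.null(cl_b) && id_a != id_b &&
      id_a != "unassigned" && id_b != "unassigned" &&
      any(!is.na(subs$anticodon_position)),
    degraded = is.null(cl_a) || is.null(cl_b)
  ), class = "mito_reassignment")
}

#' @export
print.mito_reassignment <- function(x, ...) {
  cat("<mito_reassignment> ", x$identity_a, " vs ", x$identity_b, ": ",
      x$n_substitutions, " substitutions",
      if (x$reassigned) " (anticodon-mediated reassignment)" else "",
      "\n", sep = "")
  invisible(x)
}

#' @method tidy mito_reassignment
#' @export
tidy.mito_reassignment <- function(x, ...) x$substitutions
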