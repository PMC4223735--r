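# De-novo annotation scans: tRNA genes by clover-leaf folding of sliding
# candidates on both strands of the circular genome, protein-coding genes
# as open reading frames between tRNA punctuation anchors, the
# light-strand replication origin as an inverted-repeat hairpin, and
# tandem-repeat arrays in noncoding regions by seed-and-extend self
# matching.

#' Fold, motif-check and classify one candidate tRNA sequence
#'
#' Convenience wrapper running [fold_cloverleaf()] (best effort),
#' [check_conserved_motifs()] and [classify_functionality()].
#'
#' @param seq Sense-strand DNA, 55-80 nt.
#' @param table Anticodon table.
#' @return A one-row tibble: `identity`, `functionality`, `anticodon`,
#'   `extra_arm_length`, `motif_d_loop`, `motif_t_loop`, `score`, `notes`.
#' @export
assess_trna <- function(seq, table = anticodon_table()) {
  cl <- fold_cloverleaf(seq, enforce_floor = FALSE)
  cls <- classify_functionality(cl, table = table)
  tibble(
    identity = cls$identity, functionality = cls$functionality,
    anticodon = if (is.null(cl)) NA_character_ else cl$anticodon,
    extra_arm_length = if (is.null(cl)) NA_integer_ else cl$extra_arm_length,
    motif_d_loop = cls$motif_d_loop, motif_t_loop = cls$motif_t_loop,
    score = if (is.null(cl)) NA_integer_ else cl$score,
    notes = cls$notes
  )
}

# candidate anticodon-stem seeds: 5-bp stem, 7-nt loop, >= 4/5 pairings
# and the conserved T33 at loop position 2
anticodon_seeds <- function(v, min_pairs = 5L) {
  n <- length(v)
  if (n < 17L) return(integer(0))
  i <- seq_len(n - 16L)
  cnt <- integer(length(i))
  for (k in 0:4) {
    cnt <- cnt + as.integer(.pair_score[cbind(v[i + k], v[i + 16L - k])] > 0L)
  }
  i[cnt >= min_pairs & v[i + 6L] == "T"]
}

scan_strand <- function(v, score_min, seed_pairs = 5L) {
  seeds <- anticodon_seeds(v, seed_pairs)
  n <- length(v)
  up <- expand.grid(d = 3:4, dl = 4:9, KEEP.OUT.ATTRS = FALSE)
  up$off <- 10L + 2L * up$d + up$dl      # seed - start
  down <- expand.grid(vv = 0:8, t = 4:5, tl = 4:9, KEEP.OUT.ATTRS = FALSE)
  down$off <- 16L + down$vv + 2L * down$t + down$tl + 7L  # end - seed
  hits <- list()
  for (i in seeds) {
    starts <- i - up$off
    ends <- i + down$off
    ok_u <- starts >= 1L
    ok_d <- ends <= n
    if (!any(ok_u) || !any(ok_d)) next
    # D-stem score per upstream option
    d_sc <- rep(-Inf, nrow(up))
    for (u in which(ok_u)) {
      s0 <- starts[u]; d <- up$d[u]; dl <- up$dl[u]
      i5 <- (s0 + 9L):(s0 + 8L + d)
      i3 <- (s0 + 9L + d + dl):(s0 + 8L + 2L * d + dl)
      d_sc[u] <- stem_stats(v, i5, i3)$score
    }
    # T-stem score per downstream option
    t_sc <- rep(-Inf, nrow(down))
    for (w in which(ok_d)) {
      t <- down$t[w]; vv <- down$vv[w]; tl <- down$tl[w]
      i5 <- (i + 17L + vv):(i + 16L + vv + t)
      i3 <- (i + 17L + vv + t + tl):(i + 16L + vv + 2L * t + tl)
      t_sc[w] <- stem_stats(v, i5, i3)$score
    }
    # acceptor couples upstream starts with downstream ends
    best <- NULL
    for (u in which(ok_u)) {
      e <- ends[ok_d]
      acc <- numeric(length(e))
      for (k in 0:6) {
        acc <- acc + .pair_score[cbind(rep(v[starts[u] + k], length(e)),
                                       v[e - k])]
      }
      len <- e - starts[u] + 1L
      tot <- acc + d_sc[u] + t_sc[ok_d]
      tot[len < 55L | len > 80L] <- -Inf
      w <- which.max(tot)
      if (is.finite(tot[w]) &&
          (is.null(best) || tot[w] > best$tot)) {
        best <- list(tot = tot[w], start = starts[u], end = e[w])
      }
    }
    if (is.null(best)) next
    sub <- paste(v[best$start:best$end], collapse = "")
    cl <- fold_cloverleaf(sub)
    if (is.null(cl) || cl$score < score_min) next
    hits[[length(hits) + 1L]] <- tibble(
      start = best$start, end = best$end, score = cl$score,
      anticodon = cl$anticodon, extra_arm_length = cl$extra_arm_length
    )
  }
  if (length(hits) == 0L) return(tibble(start = integer(0),
                                        end = integer(0),
                                        score = integer(0),
                                        anticodon = character(0),
                                        extra_arm_length = integer(0)))
  list_rbind(hits)
}

#' Scan a circular genome for tRNA genes
#'
#' Seeds candidate anticodon stems on both strands (including across the
#' origin), extends each seed to the best-scoring full clover-leaf, keeps
#' folds above the structural floor and a score threshold, and resolves
#' overlapping same-strand calls in favour of the higher score. Calls on
#' opposite strands may overlap, as real heavy/light-strand gene packing
#' does.
#'
#' @param record A one-row tibble from [read_fasta()] or
#'   [generate_mitogenome()]`$record`, or a plain DNA string.
#' @param score_min Minimum fold score for a call (default 34; planted
#'   synthetic genes score in the low 40s, random structure rarely
#'   reaches the mid 30s).
#' @param seed_pairs Anticodon-stem pairings (out of 5) required to seed
#'   a candidate (default 5; lower to chase degraded genes).
#' @param table Anticodon table for identity assignment.
#' @return A feature tibble: `label` (identity), `kind`, `start`, `end`
#'   (0-based half-open, `end` may exceed the genome length for wrapped
#'   calls), `strand`, `pseudo`, `aa`, `anticodon`, `score`.
#' @export
scan_trnas <- function(record, score_min = 34L, seed_pairs = 5L,
                       table = anticodon_table()) {
  seq <- if (is.data.frame(record)) record$seq[1] else record
  L <- nchar(seq)
  wrap <- min(100L, L)
  ext <- paste0(seq, substr(seq, 1L, wrap))

  calls <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "-") paste0(dna_revcomp(seq),
                                   substr(dna_revcomp(seq), 1L, wrap)) else ext
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    h <- scan_strand(v, score_min, seed_pairs)
    if (nrow(h) == 0L) next
    if (strand == "+") {
      h$g_start <- (h$start - 1L) %% L
    } else {
      h$g_start <- (L - h$end) %% L
    }
    h$g_end <- h$g_start + (h$end - h$start + 1L)
    h$strand <- strand
    calls[[length(calls) + 1L]] <- h
  }
  if (length(calls) == 0L) {
    return(tibble(label = character(0), kind = character(0),
                  start = integer(0), end = integer(0),
                  strand = character(0), pseudo = character(0),
                  aa = character(0), anticodon = character(0),
                  score = integer(0)))
  }
  all <- list_rbind(calls) |>
    distinct(.data$g_start, .data$strand, .keep_all = TRUE) |>
    arrange(desc(.data$score))

  # greedy same-strand overlap resolution by score
  keep <- rep(TRUE, nrow(all))
  for (i in seq_len(nrow(all))) {
    if (!keep[i]) next
    if (i == nrow(all)) break
    for (j in (i + 1L):nrow(all)) {
      if (!keep[j] || all$strand[j] != all$strand[i]) next
      ov <- min(all$g_end[i], all$g_end[j]) -
        max(all$g_start[i], all$g_start[j])
      if (ov > 0.3 * min(all$g_end[i] - all$g_start[i],
                         all$g_end[j] - all$g_start[j])) {
        keep[j] <- FALSE
      }
    }
  }
  all <- all[keep, ]

  identity <- table$identity[match(all$anticodon, table$anticodon)]
  identity[is.na(identity)] <- "unassigned"
  out <- tibble(
    label = identity, kind = "tRNA",
    start = as.integer(all$g_start), end = as.integer(all$g_end),
    strand = all$strand, pseudo = "functional",
    aa = ifelse(identity == "unassigned", NA_character_,
                aa_letter(identity)),
    anticodon = all$anticodon, score = all$score
  ) |> arrange(.data$start)
  # disambiguate repeated identities with copy suffixes
  out |>
    group_by(.data$label) |>
    mutate(label = if (n() > 1L && .data$label[1] != "unassigned") {
      paste0(.data$label, if (grepl("[0-9]", .data$label[1])) "_" else "",
             row_number())
    } else .data$label) |>
    ungroup()
}

orf_scan_region <- function(region_seq, min_len) {
  n <- nchar(region_seq)
  starts_ok <- mito_start_codons()
  stops <- mito_stop_codons()
  orfs <- list()
  for (frame in 0:2) {
    n_cod <- (n - frame) %/% 3L
    if (n_cod < min_len %/% 3L) next
    cod <- substring(region_seq, frame + 3L * seq_len(n_cod) - 2L,
                     frame + 3L * seq_len(n_cod))
    is_stop <- cod %in% stops
    is_start <- cod %in% starts_ok
    i <- 1L
    while (i <= n_cod) {
      if (is_start[i]) {
        j <- i
        while (j <= n_cod && !is_stop[j]) j <- j + 1L
        complete <- j <= n_cod
        end_cod <- if (complete) j else n_cod
        len <- (end_cod - i + 1L) * 3L
        # incomplete terminal stop: ORF abuts the region end with 0-2
        # trailing nt that begin a stop codon (T / TA)
        trailing <- substr(region_seq, frame + 3L * end_cod + 1L, n)
        incomplete_ok <- !complete &&
          (nchar(trailing) == 0L || trailing %in% c("T", "TA"))
        if (len >= min_len && (complete || incomplete_ok)) {
          orfs[[length(orfs) + 1L]] <- tibble(
            start = frame + 3L * (i - 1L),             # 0-based in region
            end = frame + 3L * end_cod + (if (complete) 0L else 0L),
            length = len, complete = complete
          )
          i <- j + 1L
          next
        }
        i <- i + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  if (length(orfs) == 0L) {
    return(tibble(start = integer(0), end = integer(0),
                  length = integer(0), complete = logical(0)))
  }
  list_rbind(orfs)
}

#' Scan for protein-coding genes between annotation anchors
#'
#' Extracts the intergenic stretches between the supplied anchor features
#' (tRNA calls and any rRNA/noncoding annotation — the punctuation marks
#' of the mitogenome), and reports open reading frames of at least
#' `min_len` nt under the vertebrate mitochondrial code on both strands.
#' Start codons are ATG/GTG/ATA/ATT; a reading frame running into the
#' region end with a trailing T or TA counts as an incomplete stop. A
#' region whose best reading is interrupted by premature stops (ORFs
#' covering less than half of a long region) is emitted with a pseudogene
#' flag rather than as a functional gene.
#'
#' @param record Genome record or DNA string.
#' @param anchors Feature tibble of anchor features.
#' @param labels Optional truth/homology feature tibble used to name the
#'   recovered ORFs by maximal overlap (homology search itself is out of
#'   scope).
#' @param min_len Minimum ORF length in nt (default 150).
#' @return A CDS feature tibble (0-based half-open, genome coordinates).
#' @export
scan_cds <- function(record, anchors, labels = NULL, min_len = 150L) {
  seq <- if (is.data.frame(record)) record$seq[1] else record
  L <- nchar(seq)
  anc <- anchors |> arrange(.data$start)
  n_anc <- nrow(anc)
  if (n_anc == 0L) abort("scan_cds needs anchor features")
  out <- list()
  slack <- 6L  # anchor boundaries are approximate; do not clip a start codon
  for (k in seq_len(n_anc)) {
    from <- anc$end[k] - slack
    to <- (if (k < n_anc) anc$start[k + 1L] else anc$start[1L] + L) + slack
    reg_len <- to - from
    if (reg_len < min_len) next
    from <- from %% L
    reg <- extract_feature_seq(seq, from, from + reg_len, "+")
    for (strand in c("+", "-")) {
      rs <- if (strand == "-") dna_revcomp(reg) else reg
      orfs <- orf_scan_region(rs, min_len)
      if (nrow(orfs) == 0L) next
      g_start <- if (strand == "+") from + orfs$start else {
        from + reg_len - orfs$end
      }
      out[[length(out) + 1L]] <- tibble(
        label = NA_character_, kind = "CDS",
        start = as.integer(g_start %% L),
        end = as.integer(g_start %% L + orfs$length),
        strand = strand, pseudo = "functional", aa = NA_character_,
        region_start = as.integer(from),
        region_len = as.integer(reg_len), complete = orfs$complete
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble(label = character(0), kind = character(0),
                  start = integer(0), end = integer(0),
                  strand = character(0), pseudo = character(0),
                  aa = character(0), complete = logical(0)))
  }
  # greedy resolution, complete readings before incomplete, longest first:
  feats <- list_rbind(out) |>
    arrange(desc(.data$complete), desc(.data$end - .data$start))
  # same-strand same-frame
  # overlaps are nested readings of one gene (keep the longest);
  # opposite-strand overlaps are mirror artefacts of real genes; but
  # same-strand different-frame overlaps are kept — overlapping reading
  # frames (ND4L/ND4, ATP8/ATP6) are genuine mitogenome architecture
  frame <- ifelse(feats$strand == "+", feats$start %% 3L,
                  feats$end %% 3L)
  keep <- rep(TRUE, nrow(feats))
  for (i in seq_len(nrow(feats))) {
    if (!keep[i] || i == nrow(feats)) next
    for (j in (i + 1L):nrow(feats)) {
      if (!keep[j]) next
      ov <- min(feats$end[i], feats$end[j]) -
        max(feats$start[i], feats$start[j])
      if (ov <= 0) next
      if (feats$strand[i] != feats$strand[j]) {
        if (ov > 0.3 * (feats$end[j] - feats$start[j])) keep[j] <- FALSE
      } else if (frame[i] == frame[j]) {
        keep[j] <- FALSE
      }
    }
  }
  feats <- feats[keep, ]
  if (!is.null(labels)) {
    cds_truth <- labels[labels$kind == "CDS", ]
    feats$label <- vapply(seq_len(nrow(feats)), function(i) {
      ov <- pmin(feats$end[i], cds_truth$end) -
        pmax(feats$start[i], cds_truth$start)
      if (length(ov) == 0L || max(ov) <= 0) return(NA_character_)
      cds_truth$label[which.max(ov)]
    }, character(1))
    # a named gene counts as functionally recovered only when one
    # same-strand reading, frame-concordant with the reference at both
    # ends, covers >= 80% of the reference span. A frameshifted copy has
    # a span that is no longer a multiple of three, so no single reading
    # can be concordant at both ends — its fragments are flagged
    for (lb in unique(stats::na.omit(feats$label))) {
      tr_i <- which(cds_truth$label == lb)[1]
      span <- cds_truth$end[tr_i] - cds_truth$start[tr_i]
      rows <- which(feats$label == lb)
      cov <- vapply(rows, function(i) {
        if (feats$strand[i] != cds_truth$strand[tr_i]) return(0)
        if ((feats$start[i] - cds_truth$start[tr_i]) %% 3L != 0L ||
            (feats$end[i] - cds_truth$end[tr_i]) %% 3L != 0L) return(0)
        (min(feats$end[i], cds_truth$end[tr_i]) -
           max(feats$start[i], cds_truth$start[tr_i])) / span
      }, numeric(1))
      if (max(cov) < 0.8) feats$pseudo[rows] <- "pseudogene"
    }
  }
  if (anyNA(feats$label)) {
    feats$label[is.na(feats$label)] <-
      paste0("ORF", seq_len(sum(is.na(feats$label))))
  }
  feats |> select(-"region_start", -"region_len") |>
    arrange(.data$start)
}

#' Find the light-strand replication-origin hairpin in a region
#'
#' Exhaustively enumerates inverted repeats (Watson-Crick plus G.T
#' pairing, no bulges) with stem length >= `min_stem` and loop length
#' within `loop_range`, and returns the longest-stem hairpin; ties go to
#' the leftmost start, then the shortest loop.
#'
#' @param region DNA string (an intergenic stretch, e.g. inside the WANCY
#'   cluster).
#' @param min_stem Minimum stem length (default 5 bp).
#' @param loop_range Allowed loop lengths (default 3-20 nt).
#' @param max_stem Largest stem searched (default 20 bp).
#' @return A one-row tibble `start` (0-based), `stem_length`,
#'   `loop_length`, `strand`; zero rows when no hairpin qualifies.
#' @export
find_ol_hairpin <- function(region, min_stem = 5L, loop_range = c(3L, 20L),
                            max_stem = 20L) {
  v <- strsplit(str_to_upper(region), "", fixed = TRUE)[[1]]
  n <- length(v)
  empty <- tibble(start = integer(0), stem_length = integer(0),
                  loop_length = integer(0), strand = character(0))
  if (n < 2L * min_stem + loop_range[1]) return(empty)
  for (s in seq(min(max_stem, (n - loop_range[1]) %/% 2L), min_stem)) {
    for (i in seq_len(n - 2L * s - loop_range[1] + 1L)) {
      for (l in seq(loop_range[1], min(loop_range[2], n - i + 1L - 2L * s))) {
        j <- i + s + l
        ok <- all(.pair_score[cbind(v[i:(i + s - 1L)],
                                    v[(j + s - 1L):j])] > 0L)
        if (ok) {
          return(tibble(start = i - 1L, stem_length = s, loop_length = l,
                        strand = "+"))
        }
      }
    }
  }
  empty
}

#' Find tandem-repeat arrays by seed-and-extend self matching
#'
#' For every candidate unit length, the region is compared with itself
#' shifted by the unit; exact seed runs are extended over mismatches while
#' the array identity stays at or above `min_identity`. Harmonic calls of
#' the same array at multiples of the true unit are removed by preferring
#' the smallest unit covering a span; reported arrays never overlap and
#' are listed 5' to 3'.
#'
#' @param region DNA string.
#' @param min_unit Minimum repeat-unit length (default 10 bp).
#' @param min_copies Minimum copy number (default 2).
#' @param min_identity Identity floor for copies against the array
#'   consensus (default 0.85).
#' @return A tibble `start` (0-based), `unit_length`, `copy_number`
#'   (floor of possibly fractional copies), `span`, `identity`,
#'   `consensus`.
#' @export
find_tandem_repeats <- function(region, min_unit = 10L, min_copies = 2L,
                                min_identity = 0.85) {
  region <- str_to_upper(region)
  v <- strsplit(region, "", fixed = TRUE)[[1]]
  L <- length(v)
  empty <- tibble(start = integer(0), unit_length = integer(0),
                  copy_number = integer(0), span = integer(0),
                  identity = numeric(0), consensus = character(0))
  if (L < min_unit * min_copies) return(empty)
  cand <- list()
  for (u in seq(min_unit, L %/% min_copies)) {
    m <- v[seq_len(L - u)] == v[(u + 1L):L]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    seed_len <- min(u, 12L)
    seed_i <- which(r$values & r$lengths >= seed_len)
    used_upto <- 0L
    for (si in seed_i) {
      if (starts[si] <= used_upto) next
      a <- starts[si]; b <- ends[si]
      # extend outward while identity holds; never jump a mismatch gap
      # longer than half a unit (that is the end of the array, not
      # divergence between copies)
      max_gap <- max(u %/% 2L, 3L)
      local_ok <- function(lo, hi) {
        mean(m[max(lo, 1L):min(hi, length(m))]) >= min_identity
      }
      repeat {
        grown <- FALSE
        if (b < length(m)) {
          nb <- b + 1L
          while (nb <= length(m) && !m[nb]) nb <- nb + 1L
          # the last unit ending at the new boundary must itself match:
          # chance matches beyond the array may not drag the array out
          if (nb <= length(m) && nb - b <= max_gap &&
              local_ok(nb - u + 1L, nb) &&
              mean(m[a:nb]) >= min_identity) { b <- nb; grown <- TRUE }
        }
        if (a > 1L) {
          na_ <- a - 1L
          while (na_ >= 1L && !m[na_]) na_ <- na_ - 1L
          if (na_ >= 1L && a - na_ <= max_gap &&
              local_ok(na_, na_ + u - 1L) &&
              mean(m[na_:b]) >= min_identity) {
            a <- na_; grown <- TRUE
          }
        }
        if (!grown) break
      }
      span <- b - a + 1L + u
      if (span >= min_copies * u) {
        cand[[length(cand) + 1L]] <- tibble(
          start = a - 1L, unit_length = u,
          copy_number = (b - a + 1L + u) %/% u,
          span = span, match_identity = mean(m[a:b])
        )
      }
      used_upto <- b
    }
  }
  if (length(cand) == 0L) return(empty)
  # among overlapping calls of one array, the true unit carries the most
  # copies; harmonics at multiples of the unit halve the copy number
  cand <- list_rbind(cand) |>
    arrange(desc(.data$copy_number), desc(.data$span), .data$unit_length,
            .data$start)
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i] || i == nrow(cand)) next
    for (j in (i + 1L):nrow(cand)) {
      if (min(cand$start[i] + cand$span[i], cand$start[j] + cand$span[j]) -
          max(cand$start[i], cand$start[j]) > 0) keep[j] <- FALSE
    }
  }
  cand <- cand[keep, ] |> arrange(.data$start)
  # phase trimming: a boundary that crept into flanking sequence leaves
  # slack between span and a whole number of units; slide the start
  # within the slack to the offset where the copies agree best
  for (i in seq_len(nrow(cand))) {
    u <- cand$unit_length[i]
    k <- cand$span[i] %/% u
    slack <- cand$span[i] - k * u
    if (slack > 0L && k >= 2L) {
      ident_at <- vapply(0:slack, function(o) {
        first <- substr(region, cand$start[i] + o + 1L,
                        cand$start[i] + o + u)
        second <- substr(region, cand$start[i] + o + u + 1L,
                         cand$start[i] + o + 2L * u)
        mean(strsplit(first, "")[[1]] == strsplit(second, "")[[1]])
      }, numeric(1))
      best_o <- which.max(ident_at) - 1L
      cand$start[i] <- cand$start[i] + best_o
      cand$span[i] <- k * u
    }
    cand$copy_number[i] <- k
  }
  # consensus and copy-vs-consensus identity over full copies
  cons <- character(nrow(cand))
  idy <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    u <- cand$unit_length[i]
    k <- cand$copy_number[i]
    copies <- vapply(seq_len(k), function(c0) {
      substr(region, cand$start[i] + (c0 - 1L) * u + 1L,
             cand$start[i] + c0 * u)
    }, character(1))
    mat <- do.call(rbind, strsplit(copies, "", fixed = TRUE))
    cons_v <- apply(mat, 2, function(col) {
      names(sort(table(col), decreasing = TRUE))[1]
    })
    cons[i] <- paste(cons_v, collapse = "")
    idy[i] <- mean(vapply(seq_len(k), function(c0) {
      mean(mat[c0, ] == cons_v)
    }, numeric(1)))
  }
  tibble(start = cand$start, unit_length = cand$unit_length,
         copy_number = cand$copy_number, span = cand$span,
         identity = idy, consensus = cons)
}

#' Annotate a mitogenome end to end
#'
#' Runs the tRNA scan, anchors the ORF scan on the tRNA calls plus any
#' supplied rRNA/noncoding annotation (rRNA boundary determination is out
#' of scope and is taken from the input), locates the replication-origin
#' hairpin between the asparagine and cysteine tRNA genes, and reports
#' tandem-repeat arrays in the longest unannotated stretch (the major
#' noncoding region).
#'
#' @param record Genome record tibble or DNA string.
#' @param known Optional feature tibble contributing rRNA/noncoding
#'   anchors and CDS names (e.g. simulation truth or a prior annotation).
#' @param score_min Passed to [scan_trnas()].
#' @return A list: `features` (combined feature tibble), `trnas`, `cds`,
#'   `ol` (hairpin call in genome coordinates), `repeats`.
#' @export
annotate_mitogenome <- function(record, known = NULL, score_min = 34L) {
  seq <- if (is.data.frame(record)) record$seq[1] else record
  L <- nchar(seq)
  trnas <- scan_trnas(record, score_min = score_min)
  # unassigned folds are not trustworthy punctuation for the ORF scan
  anchors <- trnas[trnas$label != "unassigned", ]
  if (!is.null(known)) {
    extra <- known[known$kind %in% c("rRNA", "noncoding"), ]
    if (nrow(extra) > 0L) {
      anchors <- bind_rows(anchors[, c("label", "kind", "start", "end",
                                       "strand", "pseudo", "aa")],
                           extra[, c("label", "kind", "start", "end",
                                     "strand", "pseudo", "aa")])
    }
  }
  anchors <- arrange(anchors, .data$start)
  cds <- scan_cds(record, anchors, labels = known)

  # hairpin between trnN and trnC (the WANCY cluster interior)
  ol <- tibble(start = integer(0), stem_length = integer(0),
               loop_length = integer(0), strand = character(0))
  base <- rep(NA_character_, nrow(trnas))
  named <- trnas$label != "unassigned"
  if (any(named)) base[named] <- parse_gene_label(trnas$label[named])$base
  iN <- which(base == "trnN")
  iC <- which(base == "trnC")
  if (length(iN) > 0L && length(iC) > 0L) {
    from <- trnas$end[iN[1]] %% L
    to <- trnas$start[iC[1]] %% L
    gap <- (to - from) %% L
    if (gap >= 13L && gap <= 120L) {
      h <- find_ol_hairpin(extract_feature_seq(seq, from, from + gap, "+"))
      if (nrow(h) == 1L) {
        h$start <- (from + h$start) %% L
        ol <- h
      }
    }
  }

  # repeats in the longest gap between annotated features (the MNC)
  allf <- bind_rows(
    trnas[, c("label", "kind", "start", "end", "strand", "pseudo", "aa")],
    cds[, c("label", "kind", "start", "end", "strand", "pseudo", "aa")]
  ) |> arrange(.data$start)
  reps <- tibble(start = integer(0), unit_length = integer(0),
                 copy_number = integer(0), span = integer(0),
                 identity = numeric(0), consensus = character(0))
  if (nrow(allf) > 1L) {
    gaps <- tibble(
      from = allf$end %% L,
      to = c(allf$start[-1], allf$start[1] + L) %% L
    ) |> mutate(len = (.data$to - .data$from) %% L)
    g <- gaps[which.max(gaps$len), ]
    if (g$len >= 20L) {
      reps <- find_tandem_repeats(
        extract_feature_seq(seq, g$from, g$from + g$len, "+"))
      if (nrow(reps) > 0L) reps$start <- (g$from + reps$start) %% L
    }
  }

  list(features = allf, trnas = trnas, cds = cds, ol = ol, repeats = reps)
}
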