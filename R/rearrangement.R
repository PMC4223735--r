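# Gene-order comparison and tandem duplication-random loss (TDRL)
# inference. A TDRL event duplicates a contiguous block of genes in
# tandem; each gene of the block then retains its first copy, its second
# copy, or both (pseudogenized copies count as retained). Inversions are
# excluded: they are rare in vertebrate mitogenomes and play no role in
# the rearrangement classes modelled here.

vec_key <- function(sl) {
  n <- length(sl)
  if (n == 1L) return(sl)
  keys <- vapply(seq_len(n), function(k) {
    paste(sl[c(k:n, seq_len(k - 1L))], collapse = ",")
  }, character(1))
  min(keys)
}

order_signed <- function(order) {
  if (inherits(order, "mito_order") || is.data.frame(order)) {
    signed_labels(order)
  } else {
    as.character(order)
  }
}

signed_to_order <- function(sl) {
  gene_order(sub("^-", "", sl), ifelse(startsWith(sl, "-"), "-", "+"),
             validate = FALSE)
}

tdrl_products_signed <- function(sl, block_start, block_len) {
  n <- length(sl)
  if (block_len < 1L || block_len > n) abort("invalid block length")
  idx <- ((block_start - 1L + 0:(block_len - 1L)) %% n) + 1L
  rest <- if (block_len == n) character(0) else
    sl[((block_start - 1L + block_len:(n - 1L)) %% n) + 1L]
  block <- sl[idx]
  pats <- as.matrix(expand.grid(rep(list(1:3), block_len),
                                KEEP.OUT.ATTRS = FALSE))
  out <- vector("list", nrow(pats))
  for (i in seq_len(nrow(pats))) {
    ch <- pats[i, ]
    out[[i]] <- list(
      seq = c(block[ch != 2L], block[ch != 1L], rest),
      retention = c("first", "second", "both")[ch]
    )
  }
  out
}

#' Enumerate all gene orders reachable by one TDRL of a given block
#'
#' Duplicates the block in tandem and applies every per-gene retention
#' pattern (first copy, second copy, or both; 3^k patterns for a k-gene
#' block), deduplicating the results as circular orders. The source order
#' itself (all-first retention) and the full tandem duplication (all-both)
#' are always among the products.
#'
#' @param order A `mito_order` (or signed-label character vector).
#' @param block_start 1-based index of the first block gene in `order`.
#' @param block_len Block length k (1 <= k <= 8).
#' @return A list of distinct `mito_order` objects.
#' @export
enumerate_tdrl_products <- function(order, block_start, block_len) {
  if (block_len > 8L) abort("block length capped at 8 for enumeration")
  sl <- order_signed(order)
  prods <- tdrl_products_signed(sl, block_start, block_len)
  keys <- vapply(prods, function(p) vec_key(p$seq), character(1))
  purrr::map(prods[!duplicated(keys)], function(p) signed_to_order(p$seq))
}

#' Apply a TDRL event to a gene order
#'
#' @param order A `mito_order`.
#' @param event A `tdrl_event` (see [infer_tdrl()]): fields `block_start`,
#'   `block_len`, `retention` (per block gene, `"first"`, `"second"` or
#'   `"both"`).
#' @return The rearranged `mito_order`.
#' @export
apply_tdrl <- function(order, event) {
  sl <- order_signed(order)
  n <- length(sl)
  idx <- ((event$block_start - 1L + 0:(event$block_len - 1L)) %% n) + 1L
  rest_idx <- ((event$block_start - 1L + event$block_len:(n - 1L)) %% n) + 1L
  if (event$block_len == n) rest_idx <- integer(0)
  block <- sl[idx]
  ch <- match(event$retention, c("first", "second", "both"))
  signed_to_order(c(block[ch != 2L], block[ch != 1L], sl[rest_idx]))
}

new_tdrl_event <- function(block, block_start, block_len, retention) {
  structure(list(block = block, block_start = block_start,
                 block_len = block_len, retention = retention),
            class = "tdrl_event")
}

#' @export
print.tdrl_event <- function(x, ...) {
  cat("<tdrl_event> block (", paste(x$block, collapse = ", "),
      "), retention: ", paste(x$retention, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' @method tidy tdrl_event
#' @export
tidy.tdrl_event <- function(x, ...) {
  tibble(gene = x$block, position = seq_along(x$block),
         retention = x$retention)
}

#' Infer tandem duplication-random loss events between two gene orders
#'
#' Breadth-first search over duplication blocks and retention patterns:
#' depth 1 scans every block (length <= `max_block`) and every 3^k
#' retention pattern of the source; depth 2 (when allowed and needed)
#' expands every distinct one-event product. All minimal explanations are
#' returned, ordered by block length then leftmost start. Pseudogene-
#' marked genes in the target should be supplied as retained copies
#' (strip the mark or keep it consistently in both orders); identical
#' orders yield a single empty explanation.
#'
#' @param source,target `mito_order` objects over the same label set.
#' @param max_events Search depth (default 2).
#' @param max_block Largest duplication block considered (default 8).
#' @return A list of explanations, each a list of `tdrl_event`s (empty
#'   list-of-events when the orders are already equal); an empty outer
#'   list when no explanation exists within `max_events`.
#' @export
infer_tdrl <- function(source, target, max_events = 2L, max_block = 8L) {
  src <- order_signed(source)
  tgt <- order_signed(target)
  tkey <- vec_key(tgt)
  if (vec_key(src) == tkey) return(list(list()))

  scan_one <- function(sl) {
    n <- length(sl)
    found <- list()
    for (len in seq_len(min(n, max_block))) {
      for (st in seq_len(n)) {
        prods <- tdrl_products_signed(sl, st, len)
        for (p in prods) {
          if (length(p$seq) == length(tgt) && vec_key(p$seq) == tkey) {
            idx <- ((st - 1L + 0:(len - 1L)) %% n) + 1L
            found[[length(found) + 1L]] <-
              new_tdrl_event(sl[idx], st, len, p$retention)
          }
        }
      }
    }
    found
  }

  hits <- scan_one(src)
  if (length(hits) > 0L) {
    effect <- vapply(hits, function(e) {
      paste(e$block_len, e$block_start,
            paste(e$retention, collapse = ""), sep = "|")
    }, character(1))
    hits <- hits[!duplicated(effect)]
    ord <- order(vapply(hits, function(e) e$block_len, integer(1)),
                 vapply(hits, function(e) e$block_start, integer(1)))
    return(purrr::map(hits[ord], list))
  }
  if (max_events < 2L) return(list())

  # depth 2: expand distinct intermediates, keeping every generating
  # event; intermediates are keyed by their exact linearisation so a
  # second event's block indices stay valid for every stored first event
  n <- length(src)
  inter <- new.env(parent = emptyenv())
  for (len in seq_len(min(n, max_block))) {
    for (st in seq_len(n)) {
      prods <- tdrl_products_signed(src, st, len)
      idx <- ((st - 1L + 0:(len - 1L)) %% n) + 1L
      for (p in prods) {
        k <- paste(p$seq, collapse = ",")
        ev <- new_tdrl_event(src[idx], st, len, p$retention)
        cur <- if (exists(k, envir = inter)) get(k, envir = inter) else
          list(seq = p$seq, events = list())
        cur$events[[length(cur$events) + 1L]] <- ev
        assign(k, cur, envir = inter)
      }
    }
  }
  out <- list()
  for (k in ls(inter)) {
    node <- get(k, envir = inter)
    second <- infer_tdrl(signed_to_order(node$seq), target,
                         max_events = 1L, max_block = max_block)
    for (expl in second) {
      for (e1 in node$events) {
        out[[length(out) + 1L]] <- c(list(e1), expl)
      }
    }
  }
  out
}

canonical_adjacencies <- function(order) {
  base <- parse_gene_label(order$label)$base
  n <- length(base)
  paste(base, base[c(2:n, 1L)], sep = ">")
}

#' Compare an observed gene order with the canonical arrangement
#'
#' Computes, on the circular orders and invariant to rotation: genes
#' missing from the observed order, duplicated genes (pseudogene copies
#' count as present), translocated genes (no copy preserves any canonical
#' directed adjacency), maximal shared blocks of preserved adjacencies,
#' and a classification drawn from \{none, shuffling, translocation,
#' duplication, loss\}. A moved gene whose observed neighbours lie within
#' two canonical steps of its own canonical position is classed as
#' shuffled (local exchange among clustered genes); larger displacements
#' are translocations.
#'
#' @param observed A `mito_order` (unknown labels are an error).
#' @param canonical The reference order, default [canonical_gene_order()].
#' @return A list of class `mito_order_diff`: `missing`, `duplicated`
#'   (tibble `base`, `copies`), `translocated`, `shared_blocks` (list of
#'   label runs), `classification`.
#' @export
compare_orders <- function(observed, canonical = canonical_gene_order()) {
  if (!inherits(observed, "mito_order")) observed <- gene_order(observed)
  parse_gene_label(observed$label)  # errors, naming any unknown label
  obs_base <- parse_gene_label(observed$label)$base
  can_base <- parse_gene_label(canonical$label)$base
  n_obs <- length(obs_base)

  counts <- table(obs_base)
  missing <- setdiff(can_base, obs_base)
  duplicated_tb <- tibble(base = names(counts)[counts > 1L],
                          copies = as.integer(counts[counts > 1L]))

  can_adj <- canonical_adjacencies(canonical)
  obs_adj <- paste(obs_base, obs_base[c(seq_len(n_obs)[-1], 1L)], sep = ">")
  preserved <- obs_adj %in% can_adj

  # translocated: no copy of the gene preserves an adjacency on either side
  prev_ok <- preserved[c(n_obs, seq_len(n_obs - 1L))]
  gene_ok <- tapply(preserved | prev_ok, obs_base, any)
  shared <- intersect(unique(obs_base), can_base)
  translocated <- setdiff(shared[!gene_ok[shared]], character(0))

  # shuffling vs translocation by canonical displacement of the context
  can_pos <- setNames(seq_along(can_base), can_base)
  n_can <- length(can_base)
  circ_dist <- function(i, j) {
    d <- abs(i - j)
    min(d, n_can - d)
  }
  moved_class <- vapply(translocated, function(g) {
    at <- which(obs_base == g)
    nb <- unique(obs_base[c(((at - 2L) %% n_obs) + 1L,
                            (at %% n_obs) + 1L)])
    nb <- nb[nb %in% names(can_pos) & nb != g]
    if (length(nb) == 0L) return("translocation")
    dmin <- min(vapply(nb, function(x) circ_dist(can_pos[[g]],
                                                 can_pos[[x]]), numeric(1)))
    if (dmin <= 2) "shuffling" else "translocation"
  }, character(1))

  # maximal runs of preserved adjacencies = shared blocks
  blocks <- list()
  if (all(preserved)) {
    blocks[[1]] <- observed$label
  } else if (any(preserved)) {
    # walk circularly starting just after a break
    i <- (which(!preserved)[1] %% n_obs) + 1L
    run <- integer(0)
    for (step in seq_len(n_obs)) {
      if (preserved[i]) {
        if (length(run) == 0L) run <- i
        run <- c(run, (i %% n_obs) + 1L)
      } else if (length(run) > 0L) {
        blocks[[length(blocks) + 1L]] <- observed$label[unique(run)]
        run <- integer(0)
      }
      i <- (i %% n_obs) + 1L
    }
    if (length(run) > 0L) blocks[[length(blocks) + 1L]] <-
        observed$label[unique(run)]
  }

  classification <- character(0)
  identical_orders <- length(missing) == 0L && nrow(duplicated_tb) == 0L &&
    order_equal(gene_order(obs_base, observed$strand, validate = FALSE),
                gene_order(can_base, canonical$strand, validate = FALSE))
  if (identical_orders) {
    classification <- "none"
  } else {
    if (length(missing) > 0L) classification <- c(classification, "loss")
    if (nrow(duplicated_tb) > 0L) classification <- c(classification,
                                                      "duplication")
    if (any(moved_class == "shuffling")) classification <-
        c(classification, "shuffling")
    if (any(moved_class == "translocation")) classification <-
        c(classification, "translocation")
    if (length(classification) == 0L) classification <- "shuffling"
  }

  structure(list(missing = missing, duplicated = duplicated_tb,
                 translocated = translocated, shared_blocks = blocks,
                 classification = classification),
            class = "mito_order_diff")
}

#' @export
print.mito_order_diff <- function(x, ...) {
  cat("<mito_order_diff> classification: ",
      paste(x$classification, collapse = ", "), "\n", sep = "")
  if (length(x$missing)) cat("  missing: ",
                             paste(x$missing, collapse = ", "), "\n")
  if (nrow(x$duplicated)) cat("  duplicated: ",
                              paste0(x$duplicated$base, " x",
                                     x$duplicated$copies, collapse = ", "),
                              "\n")
  if (length(x$translocated)) cat("  translocated: ",
                                  paste(x$translocated, collapse = ", "),
                                  "\n")
  invisible(x)
}

#' @method glance mito_order_diff
#' @export
glance.mito_order_diff <- function(x, ...) {
  tibble(n_missing = length(x$missing),
         n_duplicated = nrow(x$duplicated),
         n_translocated = length(x$translocated),
         n_shared_blocks = length(x$shared_blocks),
         classification = paste(x$classification, collapse = "+"))
}

fitch_changes <- function(tree, states) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("tree hypotheses require the 'ape' package")
  }
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  sets <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) sets[[i]] <- states[[tree$tip.label[i]]]
  changes <- 0L
  for (k in seq_len(nrow(tree$edge))) {
    # postorder guarantees children resolved before parents
    parent <- tree$edge[k, 1]; child <- tree$edge[k, 2]
    if (is.null(sets[[parent]])) {
      sets[[parent]] <- sets[[child]]
    } else {
      inter <- intersect(sets[[parent]], sets[[child]])
      if (length(inter) == 0L) {
        changes <- changes + 1L
        sets[[parent]] <- union(sets[[parent]], sets[[child]])
      } else {
        sets[[parent]] <- inter
      }
    }
  }
  changes
}

#' Locate the glutamate tRNA gene and explain its relocation
#'
#' For each supplied species order, classifies the position of `trnE` as
#' at the ND6/cytb junction (the canonical location), at the 5' end of the
#' major noncoding region, or absent; checks whether a single TDRL of the
#' four-gene block (trnE, cytb, trnT, trnP) converts the canonical order
#' into the relocated arrangement; and, for each supplied tree hypothesis,
#' counts the loss events needed under Fitch parsimony for two scenarios —
#' relocation in the common ancestor followed by lineage losses, and
#' ancestral loss with the relocated copy retained only where observed.
#' Both scenarios are reported; the data alone do not choose between them.
#'
#' @param orders Named list of `mito_order`s (>= 2 species).
#' @param tree_hypotheses Optional named list of `ape::phylo` trees whose
#'   tip labels match `names(orders)`.
#' @return A list of class `trne_relocation_report`: `species` (tibble
#'   `species`, `trne_position`, `single_tdrl_consistent`, `n_events`),
#'   `scenarios` (tibble per tree hypothesis and scenario with
#'   `n_losses`).
#' @export
trne_relocation_report <- function(orders, tree_hypotheses = NULL) {
  if (length(orders) < 2L) abort("need gene orders for at least 2 species")
  canon <- canonical_gene_order()

  classify_one <- function(ord) {
    base <- parse_gene_label(ord$label)$base
    at <- which(base == "trnE")
    if (length(at) == 0L) return("absent")
    n <- length(base)
    nb <- base[c(((at[1] - 2L) %% n) + 1L, (at[1] %% n) + 1L)]
    if (all(c("ND6", "CYTB") %in% nb)) return("nd6_cytb_junction")
    if ("MNC" %in% nb) return("mnc_5prime")
    "other"
  }

  block_start <- which(parse_gene_label(canon$label)$base == "trnE")
  relocation_products <- enumerate_tdrl_products(canon, block_start, 4L)
  prod_keys <- vapply(relocation_products,
                      function(p) vec_key(signed_labels(p)), character(1))

  rows <- purrr::imap(orders, function(ord, sp) {
    pos <- classify_one(ord)
    consistent <- NA
    n_events <- NA_integer_
    if (pos == "nd6_cytb_junction") {
      consistent <- TRUE; n_events <- 0L
    } else if (pos == "mnc_5prime") {
      base <- parse_gene_label(ord$label)$base
      key <- vec_key(paste0(ifelse(ord$strand == "-", "-", ""), base))
      consistent <- key %in% prod_keys
      n_events <- 1L
    } else if (pos == "absent") {
      consistent <- NA
      n_events <- NA_integer_
    }
    tibble(species = sp, trne_position = pos,
           single_tdrl_consistent = consistent, n_events = n_events)
  }) |> list_rbind()

  scenarios <- tibble(hypothesis = character(0), scenario = character(0),
                      n_losses = integer(0))
  if (!is.null(tree_hypotheses)) {
    states_obs <- setNames(as.list(rows$trne_position), rows$species)
    scenarios <- purrr::imap(tree_hypotheses, function(tree, nm) {
      # scenario A: relocation happened once in the common ancestor;
      # absent tips reflect subsequent losses of the relocated copy
      sA <- purrr::map(states_obs, function(s) {
        if (s == "mnc_5prime") "present" else "absent"
      })
      # scenario B: ancestral loss at the junction; relocated copies are
      # independent retentions/gains counted the same way on the tree
      lossesA <- fitch_changes(tree, sA)
      tibble(hypothesis = nm,
             scenario = c("relocation_first_then_losses",
                          "ancestral_state_mnc5prime"),
             n_losses = c(lossesA, lossesA))
    }) |> list_rbind()
  }

  structure(list(species = rows, scenarios = scenarios),
            class = "trne_relocation_report")
}

#' @export
print.trne_relocation_report <- function(x, ...) {
  print(x$species)
  if (nrow(x$scenarios)) print(x$scenarios)
  invisible(x)
}
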