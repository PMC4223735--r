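test_that("one-gene TDRL yields exactly the original and the doubling", {
  ord <- gene_order(c("ND3", "trnR", "ND4L", "ND4", "trnH"))
  prods <- enumerate_tdrl_products(ord, 2L, 1L)
  keys <- sort(vapply(prods, order_to_string, character(1)))
  expect_equal(length(prods), 2L)
  expect_true(any(vapply(prods, order_equal, logical(1), b = ord)))
  expect_true(any(vapply(prods, function(p) {
    order_equal(p, gene_order(c("ND3", "trnR", "trnR", "ND4L", "ND4",
                                "trnH")))
  }, logical(1))))
})

test_that("two-gene TDRL products match exhaustive deletion enumeration", {
  x <- c("ND1", "ND2", "ND3", "ND4", "ND5")
  prods <- enumerate_tdrl_products(gene_order(x), 2L, 2L)
  got <- sort(vapply(prods, function(p) oracle_circ_key(p$label),
                     character(1)))
  want <- sort(oracle_tdrl_products(x, 2L, 2L))
  expect_equal(got, want)
  # all-both retention is the plain tandem duplication
  expect_true(oracle_circ_key(c("ND1", "ND2", "ND3", "ND2", "ND3", "ND4",
                                "ND5")) %in% want)
})

test_that("TDRL product sets equal the oracle for all small orders", {
  labs <- c("ND1", "ND2", "ND3", "ND4", "ND5", "ND6")
  for (n in 3:5) {
    for (perm in all_circular_orders(labs[seq_len(n)])) {
      for (len in 1:n) {
        for (st in seq_len(n)) {
          prods <- enumerate_tdrl_products(gene_order(perm), st, len)
          got <- sort(vapply(prods, function(p) oracle_circ_key(p$label),
                             character(1)))
          expect_equal(got, sort(oracle_tdrl_products(perm, st, len)))
        }
      }
    }
  }
})

test_that("one-event inference agrees with product membership (n = 4)", {
  labs <- c("ND1", "ND2", "ND3", "ND4")
  sources <- all_circular_orders(labs)
  targets <- c(all_circular_orders(labs),
               list(c("ND1", "ND2", "ND2", "ND3", "ND4")))
  for (src in sources) {
    reach <- unique(unlist(lapply(1:4, function(len) {
      unlist(lapply(1:4, function(st) oracle_tdrl_products(src, st, len)))
    })))
    for (tgt in targets) {
      expl <- infer_tdrl(gene_order(src), gene_order(tgt),
                         max_events = 1L)
      in_reach <- oracle_circ_key(tgt) %in% reach ||
        oracle_circ_key(tgt) == oracle_circ_key(src)
      expect_equal(length(expl) > 0L, in_reach)
    }
  }
})

test_that("inferred events replay onto the source to give the target", {
  src <- canonical_gene_order()
  at <- match("trnR", src$label)
  tgt_lab <- append(src$label, c("trnR", "ND4L", "ND4"), after = at + 2L)
  tgt_str <- append(src$strand, c("+", "+", "+"), after = at + 2L)
  tgt <- gene_order(tgt_lab, tgt_str)
  expl <- infer_tdrl(src, tgt)
  expect_gt(length(expl), 0L)
  for (e in expl) {
    expect_length(e, 1L)
    expect_true(order_equal(apply_tdrl(src, e[[1]]), tgt))
  }
  expect_equal(expl[[1]][[1]]$block_len, 3L)
  expect_equal(expl[[1]][[1]]$block, c("trnR", "ND4L", "ND4"))
})

test_that("inference is invariant under rotation of both orders", {
  src <- gene_order(c("ND3", "trnR", "ND4L", "ND4", "trnH"))
  tgt <- gene_order(c("ND3", "trnR", "ND4L", "ND4", "trnR", "ND4L",
                      "ND4", "trnH"))
  base <- infer_tdrl(src, tgt)
  for (k in 2:4) {
    src_r <- gene_order(src$label[c(k:5, 1:(k - 1))])
    tgt_r <- gene_order(tgt$label[c(k:8, 1:(k - 1))])
    rot <- infer_tdrl(src_r, tgt_r)
    expect_equal(length(rot), length(base))
    expect_equal(rot[[1]][[1]]$block_len, base[[1]][[1]]$block_len)
  }
  # identical orders need no event
  expect_equal(infer_tdrl(src, src), list(list()))
})

test_that("two-event searches explain what one event cannot", {
  src <- gene_order(c("ND1", "ND2", "ND3", "ND4", "ND5"))
  mid <- apply_tdrl(src, structure(list(block_start = 1L, block_len = 2L,
                                        retention = c("second", "first")),
                                   class = "tdrl_event"))
  tgt <- apply_tdrl(mid, structure(list(block_start = 3L, block_len = 2L,
                                        retention = c("second", "first")),
                                   class = "tdrl_event"))
  if (length(infer_tdrl(src, tgt, max_events = 1L)) == 0L) {
    expl <- infer_tdrl(src, tgt, max_events = 2L)
    expect_gt(length(expl), 0L)
    for (e in expl) {
      stepped <- src
      for (ev in e) stepped <- apply_tdrl(stepped, ev)
      expect_true(order_equal(stepped, tgt))
    }
  }
  # unreachable within the budget: empty, not an error
  far <- gene_order(c("ND5", "ND3", "ND1", "ND4", "ND2"))
  expect_length(infer_tdrl(src, far, max_events = 1L,
                           max_block = 1L), 0L)
})

test_that("order comparison reproduces the rearrangement classes", {
  eg <- example_gene_orders()

  d0 <- compare_orders(eg$canonical)
  expect_equal(d0$classification, "none")
  expect_length(d0$missing, 0L)
  expect_equal(nrow(d0$duplicated), 0L)

  d1 <- compare_orders(eg$trne_lost)
  expect_equal(d1$missing, "trnE")
  expect_true("loss" %in% d1$classification)

  d2 <- compare_orders(eg$leu_ala_shuffling)
  expect_true(all(c("trnL1", "trnA", "OL") %in% d2$duplicated$base))
  expect_equal(d2$duplicated$copies[d2$duplicated$base == "trnL1"], 4L)
  expect_true(all(c("trnA", "OL") %in% d2$translocated))
  expect_true("shuffling" %in% d2$classification)
  expect_true("duplication" %in% d2$classification)

  d3 <- compare_orders(eg$nd3_region_duplication)
  expect_true(all(c("trnQ", "ND4L", "ND4") %in% d3$duplicated$base))
  expect_true("duplication" %in% d3$classification)

  d4 <- compare_orders(eg$trne_relocated)
  expect_true("translocation" %in% d4$classification)
  expect_true("trnE" %in% d4$translocated)

  expect_error(compare_orders(c("trnF", "trnZZ")), "trnZZ")
})

test_that("the glutamate tRNA relocation report covers all states", {
  eg <- example_gene_orders()
  orders <- list(fim = eg$trne_relocated, ebe = eg$trne_lost,
                 canon = eg$canonical)
  rep <- trne_relocation_report(orders)
  sp <- rep$species
  expect_equal(sp$trne_position[sp$species == "fim"], "mnc_5prime")
  expect_true(sp$single_tdrl_consistent[sp$species == "fim"])
  expect_equal(sp$n_events[sp$species == "fim"], 1L)
  expect_equal(sp$trne_position[sp$species == "ebe"], "absent")
  expect_equal(sp$trne_position[sp$species == "canon"],
               "nd6_cytb_junction")
  expect_equal(sp$n_events[sp$species == "canon"], 0L)

  tr <- ape::read.tree(text = "((fim,canon),ebe);")
  rep2 <- trne_relocation_report(orders, tree_hypotheses = list(h1 = tr))
  expect_equal(nrow(rep2$scenarios), 2L)
  expect_true(all(rep2$scenarios$n_losses >= 1L))
})
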