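ex <- example_trna_sequences()
seq_of <- function(nm) ex$seq[ex$name == nm]

test_that("the two glutamine tRNA reconstructions fold as reported", {
  q1 <- fold_cloverleaf(seq_of("trnQ1"))
  q2 <- fold_cloverleaf(seq_of("trnQ2"))
  expect_equal(q1$anticodon, "TTG")
  expect_equal(q2$anticodon, "TTG")
  expect_equal(q1$extra_arm_length, 4L)
  expect_equal(q2$extra_arm_length, 4L)
  expect_equal(assign_identity(q1), "trnQ")
  expect_equal(assign_identity(q2), "trnQ")
  m1 <- check_conserved_motifs(q1)
  m2 <- check_conserved_motifs(q2)
  expect_true(m1$motif_d_loop && m1$motif_t_loop)
  expect_false(m2$motif_d_loop && m2$motif_t_loop)
  expect_match(m2$note, "truncated")
  # spacers follow the compact mitochondrial template
  expect_equal(c(q1$spacer_acc_d, q1$spacer_d_ac, q1$spacer_t_acc),
               c(2L, 1L, 0L))
})

test_that("folding fails on unpairable sequence and bad lengths", {
  expect_null(fold_cloverleaf(strrep("A", 70)))
  expect_error(fold_cloverleaf(strrep("ACGT", 30)), "55-80")
  expect_error(fold_cloverleaf(random_dna(40)), "55-80")
})

test_that("identity assignment follows the anticodon table", {
  tab <- anticodon_table()
  expect_equal(nrow(tab), 22L)
  expect_equal(anyDuplicated(tab$anticodon), 0L)
  expect_equal(tab$identity[tab$anticodon == "TTG"], "trnQ")
  expect_equal(tab$identity[tab$anticodon == "TCG"], "trnR")
  expect_equal(tab$identity[tab$anticodon == "TTC"], "trnE")
  fake <- fold_cloverleaf(seq_of("trnQ1"))
  fake$anticodon <- "NNN"
  expect_equal(assign_identity(fake), "unassigned")
})

test_that("generated tRNA genes are recovered with planted structure", {
  tab <- anticodon_table()
  for (id in tab$identity) {
    g <- generate_trna_gene(id, seed = 100 + match(id, tab$identity))
    cl <- fold_cloverleaf(g$seq)
    expect_false(is.null(cl))
    expect_equal(assign_identity(cl), id)
    expect_equal(cl$extra_arm_length, g$truth$extra_len)
    expect_equal(cl$d_loop_length, g$truth$d_loop_len)
    expect_equal(cl$anticodon_positions, g$truth$anticodon_positions)
  }
  # same seed, same sequence
  expect_identical(generate_trna_gene("trnK", seed = 9)$seq,
                   generate_trna_gene("trnK", seed = 9)$seq)
  expect_error(generate_trna_gene("trnZ"), "unknown")
})

test_that("fold score decreases on average with planted stem mutations", {
  g <- generate_trna_gene("trnW", seed = 21)
  base_score <- fold_cloverleaf(g$seq)$score
  stem_pos <- c(1:7, 10:13, 65:71)  # acceptor and D-stem territory
  withr::with_seed(77, {
    deltas <- replicate(100, {
      s <- g$seq
      at <- sample(stem_pos, 1)
      old <- substr(s, at, at)
      substr(s, at, at) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      cl <- fold_cloverleaf(s, enforce_floor = FALSE)
      cl$score - base_score
    })
  })
  expect_lt(mean(deltas), 0)
  expect_true(all(deltas <= 0))
})

test_that("motif checks fail without guanines and note truncation", {
  g <- generate_trna_gene("trnM", seed = 31)
  cl <- fold_cloverleaf(g$seq)
  noG <- chartr("G", "A", g$seq)
  cl2 <- fold_cloverleaf(noG, enforce_floor = FALSE)
  expect_false(check_conserved_motifs(cl2)$motif_d_loop)
  expect_true(check_conserved_motifs(cl)$motif_d_loop)
})

test_that("functionality classification separates the three grades", {
  good <- generate_trna_gene("trnH", seed = 41)
  cls <- classify_functionality(fold_cloverleaf(good$seq))
  expect_equal(cls$functionality, "functional")
  expect_equal(cls$identity, "trnH")

  # scrambled acceptor stem: below the pairing floor, named reason
  sim <- generate_mitogenome(simulation_config(
    seed = 42,
    pseudogenize = list(list(label = "trnN", scramble_stem = "acceptor"))))
  seqN <- sim$truth$gene_seqs[["trnN"]]
  expect_null(fold_cloverleaf(seqN))
  cls2 <- classify_functionality(fold_cloverleaf(seqN,
                                                 enforce_floor = FALSE))
  expect_equal(cls2$functionality, "pseudogene")
  expect_match(cls2$notes, "acceptor")

  # folds cleanly but lost the tertiary-interaction motifs: degraded
  cls3 <- classify_functionality(fold_cloverleaf(seq_of("trnQ2")))
  expect_equal(cls3$functionality, "degraded")
  expect_match(cls3$notes, "truncated|absent")
  # a failed fold is a pseudogene with a recorded reason
  cls4 <- classify_functionality(NULL)
  expect_equal(cls4$functionality, "pseudogene")
  expect_true(nzchar(cls4$notes))
})

test_that("reassignment detection recovers the anticodon conversion", {
  rep1 <- detect_reassignment(seq_of("trnR"), seq_of("trnQ2"))
  expect_equal(rep1$n_substitutions, 4L)
  expect_equal(rep1$identity_a, "trnR")
  expect_equal(rep1$identity_b, "trnQ")
  expect_true(rep1$reassigned)
  ac <- rep1$substitutions[!is.na(rep1$substitutions$anticodon_position), ]
  expect_equal(nrow(ac), 1L)
  expect_equal(ac$anticodon_position, 35L)
  expect_equal(c(ac$base_a, ac$base_b), c("C", "T"))

  # symmetric up to direction labelling
  rep2 <- detect_reassignment(seq_of("trnQ2"), seq_of("trnR"))
  expect_equal(rep2$n_substitutions, 4L)
  expect_true(rep2$reassigned)
  expect_equal(rep2$identity_a, rep1$identity_b)

  # identical inputs: nothing to report
  rep3 <- detect_reassignment(seq_of("trnR"), seq_of("trnR"))
  expect_equal(rep3$n_substitutions, 0L)
  expect_false(rep3$reassigned)
})

test_that("planted anticodon mutations are recovered from simulations", {
  hits <- vapply(1:10, function(sd) {
    sim <- generate_mitogenome(simulation_config(
      seed = sd,
      tdrl_events = list(list(block = c("trnR", "ND4L", "ND4"),
                              retention = rep("both", 3))),
      anticodon_mutations = list(list(label = "trnR1", position = 35,
                                      base = "T"))))
    a <- sim$truth$gene_seqs[["trnR1"]]
    b <- sim$truth$gene_seqs[["trnR2"]]
    rep <- detect_reassignment(b, a)
    rep$reassigned && rep$identity_b == "trnQ" &&
      any(rep$substitutions$anticodon_position == 35, na.rm = TRUE)
  }, logical(1))
  expect_true(all(hits))
})
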