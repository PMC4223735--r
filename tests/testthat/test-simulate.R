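test_that("simulation is byte-identical under a fixed seed", {
  a <- generate_mitogenome(simulation_config(seed = 7))
  b <- generate_mitogenome(simulation_config(seed = 7))
  expect_identical(a$record$seq, b$record$seq)
  expect_identical(a$features, b$features)
  c <- generate_mitogenome(simulation_config(seed = 8))
  expect_false(identical(a$record$seq, c$record$seq))
})

test_that("default genomes look like compact vertebrate mitogenomes", {
  sim <- generate_mitogenome(simulation_config(seed = 9))
  expect_gte(sim$record$length, 16000L)
  expect_lte(sim$record$length, 18500L)
  k <- table(sim$features$kind)
  expect_equal(unname(k["tRNA"]), 22L)
  expect_equal(unname(k["CDS"]), 13L)
  expect_equal(unname(k["rRNA"]), 2L)
  expect_true(order_equal(sim$truth$gene_order, canonical_gene_order()))
  # light-strand genes sit as reverse complements on the forward strand
  nd6 <- sim$features[sim$features$label == "ND6", ]
  fwd <- extract_feature_seq(sim$record$seq, nd6$start, nd6$end, "-")
  expect_identical(fwd, sim$truth$gene_seqs[["ND6"]])
})

test_that("TDRL replay produces the duplicated gene arrangement", {
  cfg <- simulation_config(
    seed = 10,
    tdrl_events = list(list(block = c("trnR", "ND4L", "ND4"),
                            retention = rep("both", 3))),
    anticodon_mutations = list(list(label = "trnR1", position = 35,
                                    base = "T")),
    pseudogenize = list(list(label = "ND4_1", stops = 1L, indels = 1L),
                        list(label = "ND4L_2", indels = 2L)))
  sim <- generate_mitogenome(cfg)
  labs <- sim$features$label
  at <- match("ND3", labs)
  expect_equal(labs[at:(at + 7)],
               c("ND3", "trnR1", "ND4L_1", "ND4_1", "trnR2", "ND4L_2",
                 "ND4_2", "trnH"))
  expect_equal(sim$features$pseudo[labs == "ND4_1"], "pseudogene")
  # the mutated first copy now reads as a glutamine tRNA
  cl <- fold_cloverleaf(sim$truth$gene_seqs[["trnR1"]])
  expect_equal(assign_identity(cl), "trnQ")
  cl2 <- fold_cloverleaf(sim$truth$gene_seqs[["trnR2"]])
  expect_equal(assign_identity(cl2), "trnR")
})

test_that("inconsistent configurations are rejected", {
  expect_error(generate_mitogenome(simulation_config(
    seed = 1, tdrl_events = list(list(block = c("trnR", "ND9"),
                                      retention = c("both", "both"))))),
    "absent gene")
  expect_error(generate_mitogenome(simulation_config(
    seed = 1, tdrl_events = list(list(block = c("trnR", "trnH"),
                                      retention = c("both", "both"))))),
    "contiguous")
  expect_error(generate_mitogenome(simulation_config(
    seed = 1, delete_genes = "trnZ9")), "absent|unknown")
  expect_error(generate_mitogenome(simulation_config(
    seed = 1,
    anticodon_mutations = list(list(label = "ND1", position = 35,
                                    base = "T")))), "non-tRNA")
})

test_that("gene deletion shows up as loss in the order comparison", {
  sim <- generate_mitogenome(simulation_config(seed = 12,
                                               delete_genes = "trnE"))
  ord <- extract_gene_order(sim$features, sim$record$length)
  d <- compare_orders(ord)
  expect_equal(d$missing, "trnE")
  expect_true("loss" %in% d$classification)
})

test_that("every planted defect class is detected by its analysis", {
  hits <- vapply(1:15, function(sd) {
    cfg <- simulation_config(
      seed = 2000 + sd,
      tdrl_events = list(list(block = c("trnR", "ND4L", "ND4"),
                              retention = rep("both", 3))),
      anticodon_mutations = list(list(label = "trnR1", position = 35,
                                      base = "T")),
      pseudogenize = list(list(label = "ND4_1", indels = 1L),
                          list(label = "ND4L_2", stops = 1L)))
    sim <- generate_mitogenome(cfg)
    gs <- sim$truth$gene_seqs
    frameshift_found <- assess_cds_copy(gs[["ND4_1"]],
                                        gs[["ND4_2"]])$status == "pseudogene"
    stop_found <- assess_cds_copy(gs[["ND4L_2"]],
                                  gs[["ND4L_1"]])$inframe_stops >= 1L
    reass <- detect_reassignment(gs[["trnR2"]], gs[["trnR1"]])
    frameshift_found && stop_found && reass$reassigned
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
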