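test_that("the tRNA scan recovers all planted genes on a clean genome", {
  sim <- generate_mitogenome(simulation_config(seed = 101))
  calls <- scan_trnas(sim$record)
  truth <- sim$features[sim$features$kind == "tRNA", ]
  found <- vapply(seq_len(nrow(truth)), function(i) {
    any(abs(calls$start - truth$start[i]) <= 3L &
          calls$strand == truth$strand[i])
  }, logical(1))
  expect_equal(sum(found), 22L)
  # identities match the planted genes at matched loci
  for (i in seq_len(nrow(truth))) {
    j <- which(abs(calls$start - truth$start[i]) <= 3L &
                 calls$strand == truth$strand[i])[1]
    expect_equal(parse_gene_label(calls$label[j])$base, truth$label[i])
  }
})

test_that("a single planted tRNA in random sequence is the only call", {
  withr::with_seed(71, {
    bg <- random_dna(2000)
    g <- generate_trna_gene("trnD")
  })
  genome <- paste0(substr(bg, 1, 1000), g$seq, substr(bg, 1001, 2000))
  calls <- scan_trnas(genome)
  expect_equal(nrow(calls), 1L)
  expect_lte(abs(calls$start - 1000L), 3L)
  expect_equal(parse_gene_label(calls$label)$base, "trnD")
  # an empty/short input yields an empty call set
  expect_equal(nrow(scan_trnas(random_dna(30))), 0L)
})

test_that("tRNA calls follow the genome under rotation", {
  sim <- generate_mitogenome(simulation_config(seed = 102))
  L <- sim$record$length
  base <- scan_trnas(sim$record)
  off <- 4321L
  rot <- paste0(substr(sim$record$seq, off + 1L, L),
                substr(sim$record$seq, 1L, off))
  moved <- scan_trnas(rot)
  expect_equal(sort((moved$start + off) %% L), sort(base$start %% L))
})

test_that("ORF scanning recovers the 13 coding genes and flags defects", {
  cfg <- simulation_config(
    seed = 103,
    tdrl_events = list(list(block = c("trnR", "ND4L", "ND4"),
                            retention = rep("both", 3))),
    pseudogenize = list(list(label = "ND4_1", stops = 1L),
                        list(label = "ND4L_2", indels = 1L)))
  sim <- generate_mitogenome(cfg)
  trnas <- scan_trnas(sim$record)
  anchors <- rbind(
    trnas[trnas$label != "unassigned",
          c("label", "kind", "start", "end", "strand", "pseudo", "aa")],
    sim$features[sim$features$kind %in% c("rRNA", "noncoding"),
                 c("label", "kind", "start", "end", "strand", "pseudo",
                   "aa")])
  cds <- scan_cds(sim$record, anchors, labels = sim$features)

  truth <- sim$features[sim$features$kind == "CDS" &
                          sim$features$pseudo == "functional", ]
  # recovered = a functional same-strand reading covering >= 95% of the
  # planted gene (readings may extend into a spacer via an upstream
  # in-frame start codon)
  recovered <- vapply(seq_len(nrow(truth)), function(i) {
    ov <- pmin(cds$end, truth$end[i]) - pmax(cds$start, truth$start[i])
    any(cds$strand == truth$strand[i] & cds$pseudo == "functional" &
          ov >= 0.95 * (truth$end[i] - truth$start[i]))
  }, logical(1))
  expect_equal(sum(recovered), nrow(truth))
  # the stop-interrupted and frameshifted copies are not functional calls
  expect_false(any(cds$label == "ND4_1" & cds$pseudo == "functional"))
  expect_false(any(cds$label == "ND4L_2" & cds$pseudo == "functional"))
})

test_that("ORF scanning returns nothing without a long reading frame", {
  anchors <- tibble::tibble(label = c("trnF", "trnV"), kind = "tRNA",
                            start = c(0L, 500L), end = c(70L, 570L),
                            strand = "+", pseudo = "functional",
                            aa = c("F", "V"))
  # C/G-only filler: every start codon needs an A or T, so neither
  # strand can open a reading frame
  filler <- strrep("CCGG", 110)
  withr::with_seed(81, {
    genome <- paste0(random_dna(70), substr(filler, 1, 430),
                     random_dna(70))
  })
  expect_equal(nrow(scan_cds(genome, anchors)), 0L)
})

test_that("hairpin search finds planted stems and prefers longer ones", {
  withr::with_seed(91, {
    stem <- random_dna(8)
    flank1 <- random_dna(30)
    flank2 <- random_dna(30)
  })
  region <- paste0(flank1, stem, "TTTTT", dna_revcomp(stem), flank2)
  h <- find_ol_hairpin(region)
  expect_equal(nrow(h), 1L)
  expect_gte(h$stem_length, 8L)
  expect_equal(nrow(find_ol_hairpin(strrep("A", 60))), 0L)

  # two candidates: the longer stem wins regardless of position
  withr::with_seed(92, {
    s5 <- random_dna(5)
    s9 <- random_dna(9)
  })
  two <- paste0("AC", s5, "TTT", dna_revcomp(s5), "ACGTACGT",
                s9, "TTTT", dna_revcomp(s9), "GG")
  h2 <- find_ol_hairpin(two)
  expect_gte(h2$stem_length, 9L)
  expect_gt(h2$start, 10L)
})

test_that("the simulated replication origin hairpin is recovered", {
  sim <- generate_mitogenome(simulation_config(seed = 104))
  ol <- sim$features[sim$features$label == "OL", ]
  region <- extract_feature_seq(sim$record$seq, ol$start, ol$end, "+")
  h <- find_ol_hairpin(region)
  expect_equal(nrow(h), 1L)
  expect_gte(h$stem_length, 11L)
})

test_that("tandem repeat arrays are found with correct copy numbers", {
  withr::with_seed(95, {
    u74 <- random_dna(74)
    u100 <- random_dna(100)
    spacer <- random_dna(150)
  })
  region <- paste0(strrep(u74, 4), spacer, strrep(u100, 10))
  arrays <- find_tandem_repeats(region)
  expect_equal(nrow(arrays), 2L)
  expect_equal(arrays$unit_length, c(74L, 100L))
  expect_equal(arrays$copy_number, c(4L, 10L))
  expect_equal(arrays$start, c(0L, 74L * 4L + 150L))
  expect_true(all(arrays$identity >= 0.99))
  # reported arrays never overlap
  expect_true(all(arrays$start[-1] >=
                    (arrays$start + arrays$span)[-nrow(arrays)]))

  # minimal exact case with a short unit
  a2 <- find_tandem_repeats(strrep("ACGT", 50), min_unit = 4L)
  expect_equal(nrow(a2), 1L)
  expect_equal(a2$unit_length, 4L)
  expect_equal(a2$copy_number, 50L)
  expect_equal(a2$consensus, "ACGT")
})

test_that("random sequence yields no repeat arrays", {
  withr::with_seed(96, {
    for (rep in 1:5) {
      expect_equal(nrow(find_tandem_repeats(random_dna(500))), 0L)
    }
  })
})

test_that("diverged copies still count while above the identity floor", {
  withr::with_seed(97, u <- random_dna(40))
  copies <- vapply(1:5, function(i) {
    v <- strsplit(u, "")[[1]]
    at <- ((i * 7) %% 40) + 1
    v[at] <- setdiff(c("A", "C", "G", "T"), v[at])[1]
    paste(v, collapse = "")
  }, character(1))
  arrays <- find_tandem_repeats(paste(copies, collapse = ""))
  expect_equal(nrow(arrays), 1L)
  expect_equal(arrays$unit_length, 40L)
  expect_equal(arrays$copy_number, 5L)
  expect_lt(arrays$identity, 1)
})

test_that("end-to-end annotation reports the control-region arrays", {
  sim <- generate_mitogenome(simulation_config(seed = 105))
  ann <- annotate_mitogenome(sim$record, known = sim$features)
  expect_gte(nrow(ann$trnas), 22L)
  expect_equal(nrow(ann$ol), 1L)
  units <- sort(ann$repeats$unit_length)
  expect_true(all(c(74L, 100L) %in% units))
  cp <- ann$repeats$copy_number[ann$repeats$unit_length == 74L]
  expect_gte(cp[1], 4L)
})
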