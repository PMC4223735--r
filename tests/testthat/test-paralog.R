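test_that("global alignment handles identity and the tRNA paralogs", {
  a <- "ACGTACGTAC"
  al <- global_align(a, a)
  expect_equal(al$identity, 1)
  expect_equal(al$gap_positions, 0L)
  expect_equal(al$mismatches, 0L)

  ex <- example_trna_sequences()
  al2 <- global_align(ex$seq[ex$name == "trnR"],
                      ex$seq[ex$name == "trnQ2"])
  expect_equal(al2$mismatches, 4L)
  expect_equal(al2$gap_positions, 0L)

  expect_error(global_align("", "ACGT"), "empty")
  expect_error(global_align("ACGT", "MKLV"), "mixed")
})

test_that("alignment scores equal the dynamic-programming oracle", {
  withr::with_seed(11, {
    for (rep in 1:50) {
      a <- random_dna(sample(3:12, 1))
      b <- random_dna(sample(3:12, 1))
      al <- global_align(a, b)
      expect_equal(al$score, oracle_align_score(a, b),
                   tolerance = 1e-9)
    }
  })
})

test_that("alignment identity is symmetric", {
  withr::with_seed(12, {
    for (rep in 1:10) {
      a <- random_dna(40)
      b <- random_dna(sample(30:50, 1))
      expect_equal(global_align(a, b)$identity,
                   global_align(b, a)$identity)
    }
  })
})

test_that("a reference CDS assesses as functional against itself", {
  withr::with_seed(21, ref <- generate_cds(300))
  rep <- assess_cds_copy(ref, ref)
  expect_equal(rep$status, "functional")
  expect_equal(rep$frameshift_indels, 0L)
  expect_equal(rep$inframe_stops, 0L)
  expect_equal(rep$identity_to_reference, 1)
})

test_that("frameshift indels and internal stops make a pseudogene", {
  withr::with_seed(22, ref <- generate_cds(300))
  # one planted 1-bp deletion
  mut <- paste0(substr(ref, 1, 149), substr(ref, 151, 300))
  rep <- assess_cds_copy(mut, ref)
  expect_equal(rep$status, "pseudogene")
  expect_gte(rep$frameshift_indels, 1L)

  # planted in-frame TAA
  mut2 <- ref
  substr(mut2, 151, 153) <- "TAA"
  rep2 <- assess_cds_copy(mut2, ref)
  expect_equal(rep2$status, "pseudogene")
  expect_gte(rep2$inframe_stops, 1L)

  # 5'-truncated but frame-intact, stop-free: a possible pseudogene
  short <- substr(ref, 61, 300)
  rep3 <- assess_cds_copy(short, ref)
  expect_equal(rep3$status, "possible_pseudogene")
  expect_equal(rep3$frameshift_indels, 0L)
  expect_equal(rep3$inframe_stops, 0L)

  # a reference with internal stops is rejected
  bad_ref <- ref
  substr(bad_ref, 31, 33) <- "AGA"
  expect_error(assess_cds_copy(ref, bad_ref), "internal stop")
})

mutate_pct <- function(seq, pct, seed) {
  withr::with_seed(seed, {
    v <- strsplit(seq, "")[[1]]
    at <- sample(length(v), round(pct * length(v)))
    v[at] <- vapply(v[at], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
    paste(v, collapse = "")
  })
}

test_that("recent duplications are more similar than any orthologue", {
  withr::with_seed(31, anc <- generate_cds(420))
  copy1 <- mutate_pct(anc, 0.02, 1)
  copy2 <- mutate_pct(anc, 0.02, 2)
  orths <- c(mutate_pct(anc, 0.15, 3), mutate_pct(anc, 0.15, 4))
  r <- paralog_vs_ortholog_test(copy1, copy2, orths)
  expect_true(r$recent_duplication)
  expect_gt(r$paralog_identity, r$max_ortholog_identity)

  # old duplication: copies diverged far beyond the orthologue distance
  old1 <- mutate_pct(anc, 0.20, 5)
  old2 <- mutate_pct(anc, 0.20, 6)
  close_orth <- mutate_pct(old1, 0.05, 7)
  r2 <- paralog_vs_ortholog_test(old1, old2, close_orth)
  expect_false(r2$recent_duplication)

  expect_true(paralog_vs_ortholog_test(copy1, copy1,
                                       orths)$recent_duplication)
  expect_error(paralog_vs_ortholog_test(copy1, copy2, character(0)))
})

test_that("shared derived insertions are found in outgroup coordinates", {
  withr::with_seed(41, {
    out <- generate_cds(300)
    ins <- random_dna(9)
  })
  with_ins <- paste0(substr(out, 1, 150), ins, substr(out, 151, 300))
  copy1 <- with_ins
  copy2 <- with_ins
  substr(copy2, 10, 10) <- "A"
  substr(copy2, 50, 50) <- "C"
  sh <- shared_derived_insertion(copy1, copy2, out)
  expect_equal(nrow(sh), 1L)
  expect_equal(sh$length, 9L)
  expect_lte(abs(sh$after - 150L), 5L)

  expect_equal(nrow(shared_derived_insertion(out, out, out)), 0L)
  # an insertion in only one copy is not shared
  expect_equal(nrow(shared_derived_insertion(with_ins, out, out)), 0L)
})
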