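# The processing grammar: signal stripping, basic-site finding, the five
# processing strategies, allelic expansion, and recovery of the reference
# mature peptides.

test_that("strip_signal removes exactly the annotated signal peptide", {
  expect_equal(strip_signal("MAGK", 1), "AGK")
  expect_equal(strip_signal("MA", 1), "A")
  expect_error(strip_signal("MA", 2), "out of range")
  expect_error(strip_signal("MA", 0), "out of range")
  # reference precursor: chain starts at the annotated boundary
  pre <- euscorpius_precursors()
  ei4 <- pre[pre$id == "EUTX-Ei4", ]
  expect_true(startsWith(strip_signal(ei4$sequence, ei4$signal_end),
                         "EKEGYPLDATRN"))
})

test_that("find_basic_sites reports maximal K/R runs with their kind", {
  s <- find_basic_sites("AADKELSYRRK")
  expect_equal(nrow(s), 2)
  terminal <- s[s$start == 8, ]
  expect_equal(terminal$kind, "tribasic")
  expect_equal(terminal$end, 11)
  s2 <- find_basic_sites("ILSDIWNGIKGLFGKRGL")
  expect_true(any(s2$kind == "dibasic" & s2$start == 14))
  expect_equal(nrow(find_basic_sites("ASDFGH")), 0)
  expect_warning(s3 <- find_basic_sites("AAKRKRKAA"), "longer than 3")
  expect_equal(s3$kind, "tribasic")
})

test_that("FULL_CHAIN and Gly-amidation strategies", {
  cand <- apply_processing("PEPTIDE", "FULL_CHAIN")
  expect_equal(cand$sequence, "PEPTIDE")
  expect_false(cand$amidated)
  cand <- apply_processing("PEPTIDEG", "FULL_CHAIN_GLY_AMIDE")
  expect_equal(cand$sequence, "PEPTIDE")
  expect_true(cand$amidated)
  none <- apply_processing("PEPTIDE", "FULL_CHAIN_GLY_AMIDE")
  expect_equal(nrow(none), 0)
  expect_match(attr(none, "reason"), "does not end in G")
})

test_that("N-terminal region strategy yields the amidated SIFamide-like AMP", {
  chain <- "ILSDIWNGIKGLFGKRGLFPQRPLINRDQFDDVFDDDLSAADLKFLQELLK"
  cand <- apply_processing(chain, "N_TERM_REGION")
  expect_true(any(cand$sequence == "ILSDIWNGIKGLF" & cand$amidated))
})

test_that("dibasic/monobasic cleavage with trimming yields the trimmed AMP", {
  chain <- "FWGFLAKLATKVVPSLFGSSSEKSKREIENFFEPYQKDLDLELDRFDRFLSKLDLN"
  cand <- apply_processing(chain, "N_TERM_REGION", run_config())
  expect_true(any(cand$sequence == "FWGFLAKLATKVVPSLFGSSSEKS" & !cand$amidated))
})

test_that("C-terminal basic cleavage excludes the run and consumes a Gly", {
  cand <- apply_processing("PEPTIDEKKKTAIL", "C_TERM_BASIC_CLEAVE")
  expect_true(any(cand$sequence == "PEPTIDE" & !cand$amidated))
  cand <- apply_processing("PEPTIDEGKRTAIL", "C_TERM_BASIC_CLEAVE")
  expect_true(any(cand$sequence == "PEPTIDE" & cand$amidated))
})

test_that("quadruplet strategy cleaves after a spacer R, keeping basic starts", {
  # mature product may itself begin with K (cleavage R + mature K)
  cand <- apply_processing("IENGRKSPNFAAAG", "N_TERM_QUADRUPLET")
  expect_true(any(cand$sequence == "KSPNFAAA" & cand$amidated))
  # no qualifying R -> empty with reason
  none <- apply_processing("AAAAAA", "N_TERM_QUADRUPLET")
  expect_equal(nrow(none), 0)
  expect_true(nzchar(attr(none, "reason")))
})

test_that("every product is contiguous in the chain modulo terminal edits", {
  cfg <- run_config()
  seqs <- random_peptides(25, min_len = 25, max_len = 70, seed = 31)
  for (chain in seqs) {
    cand <- suppressWarnings(apply_processing(chain, "AUTO", cfg))
    for (j in seq_len(nrow(cand))) {
      core <- cand$sequence[j]
      restored <- if (cand$amidated[j]) paste0(core, "G") else core
      # trimmed trailing basics may sit between the core and the site
      expect_true(grepl(core, chain, fixed = TRUE),
                  info = paste(chain, cand$derivation[j]))
      expect_true(cand$n_disulfides[j] == count_disulfides(core))
      expect_true(grepl(sub("G$", "", restored), chain, fixed = TRUE))
    }
  }
})

test_that("amidation is set only when a terminal Gly was consumed", {
  cfg <- run_config()
  seqs <- random_peptides(25, min_len = 25, max_len = 70, seed = 32)
  for (chain in seqs) {
    cand <- suppressWarnings(apply_processing(chain, "AUTO", cfg))
    for (j in which(cand$amidated)) {
      # the consumed G must sit right after the product in the chain
      expect_true(grepl(paste0(cand$sequence[j], "G"), chain, fixed = TRUE))
    }
  }
})

test_that("allelic expansion handles one marker, rejects two", {
  expect_equal(expand_alleles("AAKE"), "AAKE")
  expect_equal(expand_alleles("AA[K/E]KE"), c("AAKKE", "AAEKE"))
  expect_error(expand_alleles("A[K/E]C[D/E]G"), "more than one")
})

test_that("AUTO candidates of each reference precursor hit the printed mass", {
  pre <- euscorpius_precursors()
  ref <- euscorpius_mature_peptides()
  for (i in seq_len(nrow(pre))) {
    cand <- suppressWarnings(mature_candidates(pre[i, ], strategy = "AUTO"))
    want <- ref[ref$precursor_id == pre$id[i], ]
    for (k in seq_len(nrow(want))) {
      expect_true(min(abs(cand$predicted_mh - want$printed_mh[k])) < 0.1,
                  info = pre$id[i])
    }
  }
})
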