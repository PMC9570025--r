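# The generator: determinism, grammar soundness, planted-truth recovery.

test_that("same seed reproduces identical outputs", {
  a <- generate_precursors(15, seed = 9, allelic_fraction = 0.3)
  b <- generate_precursors(15, seed = 9, allelic_fraction = 0.3)
  expect_identical(a, b)
  p1 <- simulate_peaklists(a$truth, seed = 4)
  p2 <- simulate_peaklists(b$truth, seed = 4)
  expect_identical(p1, p2)
  expect_false(identical(p1, simulate_peaklists(a$truth, seed = 5)))
  e1 <- simulate_expression(a$truth, seed = 4)
  expect_identical(e1, simulate_expression(a$truth, seed = 4))
})

test_that("invalid mixes are rejected", {
  expect_error(generate_precursors(5, class_mix = c(AMP = 0.5)), "sum to 1")
  expect_error(generate_precursors(5, label_mix = c(up_in_males = 1, down_in_males = 1,
                                                    unspecific = 0)), "sum to 1")
})

test_that("grammar soundness: AUTO always contains the planted product", {
  for (seed in c(7, 19, 33)) {
    gen <- generate_precursors(12, seed = seed, allelic_fraction = 0.25)
    for (i in seq_len(nrow(gen$precursors))) {
      cand <- suppressWarnings(
        mature_candidates(gen$precursors[i, ], strategy = "AUTO"))
      want <- gen$truth[gen$truth$id == gen$precursors$id[i], ]
      for (k in seq_len(nrow(want)))
        expect_true(any(cand$sequence == want$mature_sequence[k] &
                          cand$amidated == want$amidated[k]),
                    info = sprintf("seed %d, %s", seed, want$id[k]))
    }
  }
})

test_that("toxin-like classes carry even cysteine counts; AMPs none", {
  gen <- generate_precursors(40, seed = 13)
  cys <- vapply(gen$truth$mature_sequence, function(s)
    sum(strsplit(s, "")[[1]] == "C"), numeric(1))
  toxinlike <- gen$truth$class %in% c("neurotoxin", "protease inhibitor", "novel")
  expect_true(all(cys[toxinlike] %% 2 == 0 & cys[toxinlike] > 0))
  expect_true(all(cys[gen$truth$class == "AMP"] == 0))
})

test_that("planted masses are pairwise separated", {
  gen <- generate_precursors(40, seed = 17, min_mass_gap_da = 5)
  d <- diff(sort(gen$truth$true_mh))
  expect_true(all(d > 5 | d == 0))  # allelic twins of one precursor may be close
})

test_that("noise-free peak lists reproduce the truth presence exactly", {
  gen <- generate_precursors(20, seed = 23)
  pl <- simulate_peaklists(gen$truth, p_detect_present = 1, p_detect_absent = 0,
                           jitter_sd_da = 0, spurious_rate = 0, seed = 23)
  cand <- gen$truth
  cand$precursor_id <- cand$id
  cand$predicted_mh <- cand$true_mh
  cons <- consensus_by_group(pl, 0.15, 0.5)
  pres <- presence_table(cand, cons, 0.2)
  for (i in seq_len(nrow(pres))) {
    lab <- gen$truth$true_label[gen$truth$id == pres$precursor_id[i]][1]
    expect_equal(pres$present_male[i], lab %in% c("up_in_males", "unspecific"))
    expect_equal(pres$present_female[i], lab %in% c("down_in_males", "unspecific"))
    expect_equal(pres$present_juvenile[i], lab %in% c("down_in_males", "unspecific"))
  }
})

test_that("expression generator recovers planted directions when quiet", {
  gen <- generate_precursors(60, seed = 29)
  ex <- simulate_expression(gen$truth, dispersion = 1e-6, seed = 29)
  dir <- expression_contrast(ex$tpm_male_telson, ex$tpm_female_telson,
                             ex$tpm_negative_control)$direction
  truth <- gen$truth[!duplicated(gen$truth$id), ]
  expected <- c(up_in_males = "male_up", down_in_males = "female_up",
                unspecific = "flat")[truth$true_label]
  expect_equal(dir, unname(expected))
})

test_that("PSM generator plants pass/fail records consistent with the filter", {
  gen <- generate_precursors(50, seed = 31)
  psms <- simulate_psms(gen$precursors, frac_low_quality = 0.3, seed = 31)
  kept <- filter_psms(psms)
  expect_setequal(kept$id, psms$id[psms$passes_filters])
})

test_that("evaluate_recovery: perfect and degenerate calls", {
  truth <- tibble::tibble(id = c("a", "b", "c"),
                          true_label = c("up_in_males", "down_in_males",
                                         "unspecific"))
  perfect <- evaluate_recovery(
    tibble::tibble(id = truth$id, call = truth$true_label), truth)
  expect_true(all(perfect$precision == 1 & perfect$recall == 1))
  allun <- evaluate_recovery(
    tibble::tibble(id = truth$id, call = rep("unspecific", 3)), truth)
  expect_equal(allun$recall[allun$label != "unspecific"], c(0, 0))
  expect_error(evaluate_recovery(tibble::tibble(id = "z", call = "unspecific"),
                                 truth), "same precursor ids")
})
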