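# Evidence filters, annotation classification, expression contrast and the
# final up-/down-in-males calls.

test_that("PSM filter applies strict inequalities and the signal-peptide gate", {
  psms <- tibble::tibble(
    id = c("a", "b", "c", "d"),
    neg_log_p = c(30.0, 45, 45, 45),
    coverage_pct = c(50, 7.0, 20, 20),
    has_signal_peptide = c(TRUE, TRUE, FALSE, TRUE)
  )
  kept <- filter_psms(psms)
  expect_equal(kept$id, "d")   # boundary -10lgP=30 and coverage=7 both rejected
})

test_that("PSM filter is idempotent and monotone over random tables", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    psms <- tibble::tibble(
      id = paste0("p", seq_len(n)),
      neg_log_p = round(runif(n, 0, 60), 1),
      coverage_pct = round(runif(n, 0, 30), 1),
      has_signal_peptide = runif(n) < 0.8
    )
    kept <- filter_psms(psms)
    expect_true(all(kept$id %in% psms$id))
    expect_equal(filter_psms(kept), kept)
    expect_true(all(kept$neg_log_p > 30 & kept$coverage_pct > 7 &
                      kept$has_signal_peptide))
    rejected <- psms[!psms$id %in% kept$id, ]
    expect_true(all(rejected$neg_log_p <= 30 | rejected$coverage_pct <= 7 |
                      !rejected$has_signal_peptide))
  }
})

test_that("annotation classification by keyword, E-value gates, novel fallback", {
  hit <- function(db, desc, e)
    tibble::tibble(id = "x", database = db, description = desc, e_value = e)
  expect_equal(classify_annotation(hit("metazoa", "Putative sodium channel toxin", 1e-20)),
               "neurotoxin")
  expect_equal(classify_annotation(hit("metazoa", "La1-like protein 15", 1e-8)),
               "neurotoxin")
  expect_equal(classify_annotation(hit("metazoa", "Antimicrobial peptide UyCT3", 1e-10)),
               "AMP")
  expect_equal(classify_annotation(hit("metazoa", "Putative non-disulfide bridge peptide", 1e-10)),
               "AMP")
  expect_equal(classify_annotation(hit("metazoa", "Chymotrypsin-elastase inhibitor ixodidin-like", 1e-9)),
               "protease inhibitor")
  expect_equal(classify_annotation(hit("metazoa", "Venom hyaluronidase", 1e-9)),
               "enzyme")
  expect_equal(classify_annotation(hit("metazoa", "Uncharacterized protein", 1e-9)),
               "other")
  expect_equal(classify_annotation(NULL), "novel")
  expect_equal(classify_annotation(hit("metazoa", "x", 1)[0, ]), "novel")
  # a toxin-database hit above the classification E-value does not classify
  expect_equal(classify_annotation(hit("toxprot", "Some toxin", 0.05)), "novel")
  expect_equal(classify_annotation(hit("toxprot", "Some toxin", 1e-9)), "neurotoxin")
})

test_that("expression contrast: direction by fold, gland enrichment vs control", {
  # male-specific toxin row: strongly male-biased and gland-enriched
  r <- expression_contrast(8482.11, 60.96, 17.54, min_fold = 2)
  expect_equal(r$direction, "male_up"); expect_true(r$gland_enriched)
  # down-regulated toxin row: female-biased, no control expression
  r <- expression_contrast(349.45, 4136.68, 0, min_fold = 2)
  expect_equal(r$direction, "female_up"); expect_true(r$gland_enriched)
  r <- expression_contrast(100, 100, 100, min_fold = 2)
  expect_equal(r$direction, "flat"); expect_false(r$gland_enriched)
  expect_error(expression_contrast(1, 1, 1, min_fold = 0.5))
  expect_error(expression_contrast(-1, 1, 1))
})

test_that("specificity calls need concordant MALDI pattern and expression", {
  expect_equal(call_specificity(TRUE, FALSE, FALSE, "male_up"), "up_in_males")
  expect_equal(call_specificity(FALSE, TRUE, TRUE, "female_up"), "down_in_males")
  expect_equal(call_specificity(TRUE, TRUE, TRUE, "male_up"), "unspecific")
  expect_equal(call_specificity(TRUE, FALSE, FALSE, "female_up"), "unspecific")
  expect_equal(call_specificity(FALSE, TRUE, FALSE, "female_up"), "unspecific")
})

test_that("calls are symmetric under relabelling the sexes", {
  set.seed(78)
  for (i in 1:50) {
    pm <- runif(1) < 0.5; pf <- runif(1) < 0.5; pj <- runif(1) < 0.5
    tm <- runif(1, 0, 100); tf <- runif(1, 0, 100)
    dir1 <- expression_contrast(tm, tf, 0)$direction
    dir2 <- expression_contrast(tf, tm, 0)$direction
    c1 <- call_specificity(pm, pf, pj, dir1)
    # swap sexes: male<->female presence (juvenile follows the female pattern
    # in the mirrored design) and expression columns
    c2 <- call_specificity(pf, pm, pm, dir2)
    mirror <- c(up_in_males = "down_in_males", down_in_males = "up_in_males",
                unspecific = "unspecific")
    if (pj == pf)   # mirrored worlds coincide only when juveniles track females
      expect_equal(unname(mirror[c1]), c2)
  }
})

test_that("the reference set yields exactly 3 up- and 9 down-in-males calls", {
  pres <- euscorpius_presence()
  expr <- euscorpius_expression()
  expr <- expr[match(pres$precursor_id, expr$id), ]
  dir <- expression_contrast(expr$tpm_male_telson, expr$tpm_female_telson,
                             expr$tpm_negative_control, min_fold = 2)$direction
  calls <- call_specificity(pres$present_male, pres$present_female,
                            pres$present_juvenile, dir)
  expect_equal(sum(calls == "up_in_males"), 3)
  expect_equal(sum(calls == "down_in_males"), 9)
  up_ids <- pres$precursor_id[calls == "up_in_males"]
  expect_setequal(up_ids, c("EUTX-Ei4", "PI-Ei1a", "EUTX-Ei5"))
})

test_that("build_report handles empty input and collapses redundant chains", {
  cfg <- run_config()
  empty <- build_report(euscorpius_precursors()[0, ],
                        tibble::tibble(specimen_id = character(),
                                       replicate_id = character(),
                                       group = character(), mz = double()),
                        euscorpius_expression(), euscorpius_psms(),
                        config = cfg)
  expect_equal(nrow(empty), 0)

  # duplicate precursor with identical mature chain collapses to one row
  s <- simulate_study(n = 6, seed = 3, p_detect_present = 1,
                      p_detect_absent = 0, jitter_sd_da = 0, spurious_rate = 0)
  dup <- s$precursors[1, ]
  dup$id <- "SYN-DUP"
  pre2 <- dplyr::bind_rows(s$precursors, dup)
  psm2 <- dplyr::bind_rows(s$psms,
                           tibble::tibble(id = "SYN-DUP", neg_log_p = 99,
                                          coverage_pct = 50,
                                          has_signal_peptide = TRUE,
                                          experiments = "D-m",
                                          passes_filters = TRUE))
  rep <- suppressWarnings(
    build_report(pre2, s$peaklists, s$expression, psm2, config = cfg))
  expect_equal(sum(rep$id %in% c(s$precursors$id[1], "SYN-DUP")), 1)
  # the higher-scoring duplicate wins
  expect_true("SYN-DUP" %in% rep$id)
})
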