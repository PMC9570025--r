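# Synthetic inputs with planted ground truth.
#
# The generator emulates the study design this pipeline targets: a small
# scorpion colony (2 adult males, 4 adult females, 4 juveniles), two venom
# extractions per specimen fingerprinted by MALDI-TOF, one telson
# transcriptome per sex plus a tail-tissue negative control, and a
# search-engine PSM export. Precursors are built from the maturation grammar
# itself so that every planted mature peptide is derivable from its precursor,
# and planted [M+H]+ values are kept pairwise separated so presence calls are
# identifiable in the noise-free limit.

.AA_NO_KRG <- setdiff(.AA_CODES, c("K", "R", "G"))
.AA_NO_KRGC <- setdiff(.AA_NO_KRG, "C")
.HYDROPHOBIC <- c("A", "L", "I", "V", "F", "M", "W")

.rand_seq <- function(n, alphabet) paste(sample(alphabet, n, TRUE), collapse = "")

# One mature core; toxin-like classes get an even number of cysteines.
.rand_mature <- function(class) {
  len <- sample(12:45, 1)
  cys_rich <- class %in% c("neurotoxin", "protease inhibitor", "novel")
  core <- .rand_seq(len, .AA_NO_KRGC)
  if (cys_rich) {
    n_cys <- sample(c(4L, 6L, 8L), 1)
    pos <- sort(sample(seq_len(len), n_cys))
    chars <- strsplit(core, "")[[1]]
    chars[pos] <- "C"
    core <- paste(chars, collapse = "")
  }
  core
}

.strategy_for_class <- function(class) {
  switch(class,
    AMP = sample(c("N_TERM_REGION", "C_TERM_BASIC_CLEAVE"), 1),
    neurotoxin = sample(c("FULL_CHAIN", "FULL_CHAIN_GLY_AMIDE",
                          "C_TERM_BASIC_CLEAVE"), 1),
    novel = "N_TERM_QUADRUPLET",
    sample(c("FULL_CHAIN", "FULL_CHAIN_GLY_AMIDE", "N_TERM_REGION",
             "C_TERM_BASIC_CLEAVE"), 1)
  )
}

# Assemble precursor sequence around a mature core for one strategy.
# Returns list(sequence, signal_end, mature, amidated).
.assemble_precursor <- function(mature, strategy) {
  signal <- paste0("M", .rand_seq(sample(15:24, 1), .HYDROPHOBIC), "A")
  tail_seq <- function() .rand_seq(sample(6:20, 1), .AA_NO_KRG)
  basic_run <- function(len) .rand_seq(len, c("K", "R"))
  amidated <- FALSE
  chain <- switch(strategy,
    FULL_CHAIN = mature,
    FULL_CHAIN_GLY_AMIDE = { amidated <- TRUE; paste0(mature, "G") },
    C_TERM_BASIC_CLEAVE = {
      amidated <- stats::runif(1) < 0.5
      paste0(mature, if (amidated) "G" else "", basic_run(sample(1:3, 1)),
             tail_seq())
    },
    N_TERM_REGION = {
      amidated <- stats::runif(1) < 0.5
      paste0(mature, if (amidated) "G" else "", basic_run(sample(1:2, 1)),
             tail_seq())
    },
    N_TERM_QUADRUPLET = {
      amidated <- TRUE
      paste0(.rand_seq(sample(3:6, 1), .AA_NO_KRG), "R", mature, "G")
    }
  )
  list(sequence = paste0(signal, chain), signal_end = nchar(signal),
       mature = mature, amidated = amidated)
}

#' Generate a synthetic precursor library with planted ground truth
#'
#' Each precursor is assembled from the maturation grammar around a planted
#' mature peptide, so applying the annotated processing strategy (and `AUTO`)
#' recovers the planted product. Cysteine-rich classes receive an even number
#' of cysteines; AMPs are cysteine-free. Planted [M+H]+ values are resampled
#' until pairwise separated by more than `min_mass_gap_da`, which makes
#' presence/absence calls identifiable.
#'
#' @param n Number of precursors (>= 1).
#' @param class_mix Named probabilities over
#'   neurotoxin/AMP/enzyme/protease inhibitor/other/novel; must sum to 1.
#' @param label_mix Named probabilities over
#'   up_in_males/down_in_males/unspecific; must sum to 1.
#' @param allelic_fraction Fraction of precursors carrying one `[X/Y]` allelic
#'   position inside the mature region.
#' @param min_mass_gap_da Minimum pairwise separation of planted masses (Da).
#' @param seed Integer seed; the same seed reproduces identical output.
#' @return A list with `precursors` (tibble: `id`, `sequence`, `signal_end`,
#'   `processing_strategy`, `class_label`) and `truth` (tibble: one row per
#'   planted product with `id`, `allele`, `mature_sequence`, `amidated`,
#'   `n_disulfides`, `true_mh`, `class`, `true_label`, `strategy`).
#' @export
generate_precursors <- function(n,
                                class_mix = c(neurotoxin = 0.35, AMP = 0.2,
                                              enzyme = 0.15,
                                              `protease inhibitor` = 0.1,
                                              other = 0.1, novel = 0.1),
                                label_mix = c(up_in_males = 0.2,
                                              down_in_males = 0.3,
                                              unspecific = 0.5),
                                allelic_fraction = 0,
                                min_mass_gap_da = 5,
                                seed = 1L) {
  stopifnot(n >= 1)
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1", call. = FALSE)
  if (abs(sum(label_mix) - 1) > 1e-8) stop("label_mix must sum to 1", call. = FALSE)
  set.seed(seed)
  classes <- sample(names(class_mix), n, TRUE, prob = class_mix)
  labels <- sample(names(label_mix), n, TRUE, prob = label_mix)

  precursors <- vector("list", n)
  truth <- vector("list", n)
  planted_mh <- numeric(0)
  for (i in seq_len(n)) {
    repeat {
      strategy <- .strategy_for_class(classes[i])
      mature <- .rand_mature(classes[i])
      built <- .assemble_precursor(mature, strategy)
      mh <- mh_plus(built$mature, built$amidated, count_disulfides(built$mature))
      if (!length(planted_mh) || min(abs(planted_mh - mh)) > min_mass_gap_da)
        break
    }
    id <- sprintf("SYN-%03d", i)
    seq_out <- built$sequence
    allele <- NA_character_
    truth_rows <- tibble::tibble(
      id = id, allele = allele, mature_sequence = built$mature,
      amidated = built$amidated,
      n_disulfides = count_disulfides(built$mature), true_mh = mh,
      class = classes[i], true_label = labels[i], strategy = strategy
    )
    if (stats::runif(1) < allelic_fraction) {
      # plant one allelic position inside the mature region
      rel <- sample(seq_len(nchar(mature)), 1)
      ref <- substr(mature, rel, rel)
      alt <- sample(setdiff(.AA_NO_KRG, c(ref, "C")), 1)
      pos <- regexpr(mature, built$sequence, fixed = TRUE) + rel - 1L
      seq_out <- paste0(substr(built$sequence, 1, pos - 1L),
                        sprintf("[%s/%s]", ref, alt),
                        substr(built$sequence, pos + 1L, nchar(built$sequence)))
      alt_mature <- paste0(substr(mature, 1, rel - 1L), alt,
                           substr(mature, rel + 1L, nchar(mature)))
      truth_rows$allele <- ref
      truth_rows <- dplyr::bind_rows(truth_rows, tibble::tibble(
        id = id, allele = alt, mature_sequence = alt_mature,
        amidated = built$amidated,
        n_disulfides = count_disulfides(alt_mature),
        true_mh = mh_plus(alt_mature, built$amidated,
                          count_disulfides(alt_mature)),
        class = classes[i], true_label = labels[i], strategy = strategy
      ))
    }
    planted_mh <- c(planted_mh, truth_rows$true_mh)
    precursors[[i]] <- tibble::tibble(
      id = id, sequence = seq_out, signal_end = built$signal_end,
      processing_strategy = strategy, class_label = classes[i]
    )
    truth[[i]] <- truth_rows
  }
  list(precursors = dplyr::bind_rows(precursors),
       truth = dplyr::bind_rows(truth))
}

.present_groups <- function(label) {
  switch(label,
    up_in_males = "male",
    down_in_males = c("female", "juvenile"),
    unspecific = .GROUPS
  )
}

#' Simulate replicate MALDI-TOF peak lists for a planted truth
#'
#' Every planted [M+H]+ appears in a given spectrum with probability
#' `p_detect_present` in the groups where its specificity label says it is
#' present (`p_detect_absent` elsewhere), perturbed by Gaussian m/z jitter;
#' spurious peaks are added per spectrum at a Poisson rate, uniform over
#' `mz_range`.
#'
#' @param truth Truth tibble from [generate_precursors()].
#' @param specimens Named counts of specimens per group; default the study
#'   design 2 males / 4 females / 4 juveniles.
#' @param replicates Spectra per specimen; default 2.
#' @param p_detect_present,p_detect_absent Detection probabilities in [0, 1].
#' @param jitter_sd_da Gaussian m/z jitter SD in Da (>= 0).
#' @param spurious_rate Mean number of spurious peaks per spectrum.
#' @param mz_range Range spurious peaks are drawn from (Da).
#' @param seed Integer seed.
#' @return A peak-list tibble (`specimen_id`, `replicate_id`, `group`, `mz`),
#'   sorted within each spectrum, including rows for empty spectra omitted
#'   (use the specimen design to know the denominator).
#' @export
simulate_peaklists <- function(truth,
                               specimens = c(male = 2, female = 4, juvenile = 4),
                               replicates = 2,
                               p_detect_present = 0.9,
                               p_detect_absent = 0.02,
                               jitter_sd_da = 0.05,
                               spurious_rate = 5,
                               mz_range = c(800, 10000),
                               seed = 1L) {
  stopifnot(p_detect_present >= 0, p_detect_present <= 1,
            p_detect_absent >= 0, p_detect_absent <= 1, jitter_sd_da >= 0)
  set.seed(seed)
  rows <- list()
  k <- 0L
  for (g in names(specimens)) {
    if (specimens[[g]] == 0) next
    for (s in seq_len(specimens[[g]])) {
      specimen <- sprintf("%s-%d", g, s)
      for (r in seq_len(replicates)) {
        p <- ifelse(vapply(truth$true_label, function(l)
          g %in% .present_groups(l), logical(1)),
          p_detect_present, p_detect_absent)
        det <- stats::runif(nrow(truth)) < p
        mz <- truth$true_mh[det] + stats::rnorm(sum(det), 0, jitter_sd_da)
        n_spur <- stats::rpois(1, spurious_rate)
        mz <- c(mz, stats::runif(n_spur, mz_range[1], mz_range[2]))
        if (!length(mz)) next
        k <- k + 1L
        rows[[k]] <- tibble::tibble(specimen_id = specimen,
                                    replicate_id = as.character(r),
                                    group = g, mz = sort(mz))
      }
    }
  }
  if (!k) return(tibble::tibble(specimen_id = character(),
                                replicate_id = character(),
                                group = character(), mz = double()))
  dplyr::bind_rows(rows)
}

#' Simulate the three-transcriptome expression table
#'
#' Log-normal TPM around `base_tpm`; sex-specific precursors are scaled by
#' `fold_specific` in the favored sex; the negative control (tail tissue
#' without venom gland) sits near zero for gland genes.
#'
#' @param truth Truth tibble from [generate_precursors()].
#' @param base_tpm Median TPM of a gland gene; default 500.
#' @param fold_specific Expression fold in the favored sex (> 1); default 50.
#' @param dispersion Log-normal SD (natural-log scale); default 0.5.
#' @param nc_fraction Negative-control TPM as a fraction of base; default 0.02.
#' @param seed Integer seed.
#' @return An expression tibble (`id`, `tpm_male_telson`, `tpm_female_telson`,
#'   `tpm_negative_control`), one row per precursor.
#' @export
simulate_expression <- function(truth, base_tpm = 500, fold_specific = 50,
                                dispersion = 0.5, nc_fraction = 0.02,
                                seed = 1L) {
  stopifnot(fold_specific > 1, dispersion >= 0)
  set.seed(seed)
  per <- truth[!duplicated(truth$id), c("id", "true_label")]
  n <- nrow(per)
  noise <- function() stats::rlnorm(n, 0, dispersion)
  base <- base_tpm * stats::rlnorm(n, 0, dispersion)
  fold_m <- ifelse(per$true_label == "up_in_males", fold_specific, 1)
  fold_f <- ifelse(per$true_label == "down_in_males", fold_specific, 1)
  tibble::tibble(
    id = per$id,
    tpm_male_telson = base * fold_m * noise(),
    tpm_female_telson = base * fold_f * noise(),
    tpm_negative_control = base * nc_fraction * noise()
  )
}

#' Simulate a search-engine PSM export
#'
#' Plants high-quality evidence for every precursor, with an optional fraction
#' of low-quality records (below the -10lgP/coverage thresholds or lacking a
#' signal peptide) to exercise the filters.
#'
#' @param precursors Precursor tibble from [generate_precursors()].
#' @param frac_low_quality Fraction of records planted below the filter
#'   thresholds; default 0.
#' @param seed Integer seed.
#' @return A PSM tibble (`id`, `neg_log_p`, `coverage_pct`,
#'   `has_signal_peptide`, `experiments`, `passes_filters`); the last column is
#'   generator truth, not search-engine output.
#' @export
simulate_psms <- function(precursors, frac_low_quality = 0, seed = 1L) {
  set.seed(seed)
  n <- nrow(precursors)
  low <- stats::runif(n) < frac_low_quality
  neg_log_p <- ifelse(low, stats::runif(n, 5, 30), stats::runif(n, 35, 90))
  coverage <- ifelse(low, stats::runif(n, 0, 7), stats::runif(n, 10, 85))
  tags <- vapply(seq_len(n), function(i)
    paste(sample(c("D-m", "D-f", "ND-m", "ND-f"), sample(2:4, 1)),
          collapse = ","), character(1))
  tibble::tibble(
    id = precursors$id,
    neg_log_p = neg_log_p,
    coverage_pct = coverage,
    has_signal_peptide = TRUE,
    experiments = tags,
    passes_filters = !low
  )
}

#' Generate a full synthetic study in one call
#'
#' Convenience wrapper: precursor library, peak lists, expression and PSM
#' tables, plus the truth, under a single master seed (sub-seeds are derived
#' deterministically).
#'
#' @inheritParams generate_precursors
#' @param ... Passed on to [simulate_peaklists()] (e.g. noise settings).
#' @return A list with `precursors`, `truth`, `peaklists`, `expression`,
#'   `psms`, and `n_spectra` (named per-group spectra counts).
#' @export
simulate_study <- function(n = 40, seed = 1L, allelic_fraction = 0, ...) {
  gen <- generate_precursors(n, allelic_fraction = allelic_fraction, seed = seed)
  dots <- list(...)
  specimens <- dots$specimens %||% c(male = 2, female = 4, juvenile = 4)
  replicates <- dots$replicates %||% 2
  pk <- do.call(simulate_peaklists,
                c(list(truth = gen$truth, seed = seed + 1000L), dots))
  expr <- simulate_expression(gen$truth, seed = seed + 2000L)
  psms <- simulate_psms(gen$precursors, seed = seed + 3000L)
  list(precursors = gen$precursors, truth = gen$truth, peaklists = pk,
       expression = expr, psms = psms,
       n_spectra = specimens * replicates)
}

#' Precision and recall of specificity calls against planted truth
#'
#' @param calls Tibble with columns `id` and `call`.
#' @param truth Truth tibble with columns `id` and `true_label` (one label per
#'   id; allelic duplicates are collapsed).
#' @return A tibble with one row per label (`up_in_males`, `down_in_males`,
#'   `unspecific`): `n_true`, `n_called`, `n_correct`, `precision`, `recall`.
#'   Precision/recall are NA when undefined (no calls / no truth of a label).
#' @export
evaluate_recovery <- function(calls, truth) {
  truth <- truth[!duplicated(truth$id), c("id", "true_label")]
  if (!setequal(calls$id, truth$id))
    stop("calls and truth must cover the same precursor ids", call. = FALSE)
  lab <- truth$true_label[match(calls$id, truth$id)]
  labels <- c("up_in_males", "down_in_males", "unspecific")
  rows <- lapply(labels, function(L) {
    n_true <- sum(lab == L)
    n_called <- sum(calls$call == L)
    n_correct <- sum(calls$call == L & lab == L)
    tibble::tibble(label = L, n_true = n_true, n_called = n_called,
                   n_correct = n_correct,
                   precision = if (n_called) n_correct / n_called else NA_real_,
                   recall = if (n_true) n_correct / n_true else NA_real_)
  })
  dplyr::bind_rows(rows)
}
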