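# Evidence filters and integration into up-/down-in-males calls.

#' Filter PSM records on evidence quality
#'
#' Retains records with -10lgP strictly above `min_neg_log_p`, coverage
#' strictly above `min_coverage_pct`, and a predicted signal peptide. Boundary
#' values (e.g. -10lgP exactly 30, coverage exactly 7) are rejected.
#'
#' @param psms Tibble of PSM records (`id`, `neg_log_p`, `coverage_pct`,
#'   `has_signal_peptide`).
#' @param min_neg_log_p Confidence threshold; default 30.
#' @param min_coverage_pct Coverage threshold in percent; default 7.
#' @return The retained subset, same columns.
#' @export
filter_psms <- function(psms, min_neg_log_p = 30, min_coverage_pct = 7) {
  keep <- psms$neg_log_p > min_neg_log_p &
    psms$coverage_pct > min_coverage_pct &
    psms$has_signal_peptide %in% TRUE
  psms[keep, ]
}

.CLASS_KEYWORDS <- list(
  neurotoxin = c("toxin", "channel", "la1", "aktx"),
  AMP = c("antimicrobial", "non-disulfide"),
  `protease inhibitor` = c("inhibitor"),
  enzyme = c("hyaluronidase", "phospholipase", "protease", "peptidase",
             "metalloprotein", "lipase", "esterase", "chitinase")
)

#' Classify a precursor from its homology hits
#'
#' Hits against the general metazoan database are accepted at
#' `e_value < max_e_metazoa`; hits against the toxin-focused database are
#' reported at a looser threshold but contribute to classification only when
#' their E-value is below `max_e_metazoa` as well. The best (lowest-E)
#' accepted hit's description is mapped to a class by keyword; precursors with
#' no accepted hit are `"novel"`. The keyword order gives protease inhibitors
#' precedence over the enzyme keyword "protease".
#'
#' @param hits Tibble of hits for one precursor (`database`, `description`,
#'   `e_value`); zero rows allowed.
#' @param max_e_metazoa Acceptance E-value; default 1e-5.
#' @return One of `"neurotoxin"`, `"AMP"`, `"protease inhibitor"`, `"enzyme"`,
#'   `"other"`, `"novel"`.
#' @export
classify_annotation <- function(hits, max_e_metazoa = 1e-5) {
  if (is.null(hits) || nrow(hits) == 0L) return("novel")
  ok <- hits$e_value < max_e_metazoa
  hits <- hits[ok, ]
  if (nrow(hits) == 0L) return("novel")
  desc <- tolower(hits$description[which.min(hits$e_value)])
  for (cls in c("protease inhibitor", "neurotoxin", "AMP", "enzyme"))
    if (any(vapply(.CLASS_KEYWORDS[[cls]], grepl, TRUE, x = desc, fixed = TRUE)))
      return(cls)
  "other"
}

#' Three-way expression contrast
#'
#' Compares TPM in the male and female venom-gland (telson) transcriptomes at
#' a fold-change threshold, and flags gland enrichment against the negative
#' control (tail tissue without venom gland).
#'
#' @param tpm_male,tpm_female,tpm_negative_control Non-negative TPM values
#'   (vectorised).
#' @param min_fold Fold-change threshold (>= 1); default 2.
#' @return A tibble with columns `direction` (`"male_up"`, `"female_up"`,
#'   `"flat"`) and `gland_enriched` (TRUE iff min(male, female) exceeds the
#'   negative control).
#' @export
expression_contrast <- function(tpm_male, tpm_female, tpm_negative_control,
                                min_fold = 2) {
  stopifnot(min_fold >= 1)
  if (any(c(tpm_male, tpm_female, tpm_negative_control) < 0))
    stop("TPM values must be non-negative", call. = FALSE)
  direction <- rep("flat", length(tpm_male))
  direction[tpm_male > min_fold * tpm_female] <- "male_up"
  direction[tpm_female > min_fold * tpm_male] <- "female_up"
  tibble::tibble(
    direction = direction,
    gland_enriched = pmin(tpm_male, tpm_female) > tpm_negative_control
  )
}

#' Combine MALDI presence and expression direction into a specificity call
#'
#' A precursor is called `up_in_males` when its peptide is present in the male
#' consensus fingerprint but absent from both the female and juvenile ones AND
#' its expression contrast is male-biased; `down_in_males` is the mirror image
#' (absent in males, present in females and juveniles, female-biased
#' expression). Everything else is `unspecific`.
#'
#' @param present_male,present_female,present_juvenile Logical presence flags
#'   (vectorised).
#' @param direction Expression direction from [expression_contrast()].
#' @return Character vector of calls.
#' @export
call_specificity <- function(present_male, present_female, present_juvenile,
                             direction) {
  up <- present_male & !present_female & !present_juvenile & direction == "male_up"
  down <- !present_male & present_female & present_juvenile & direction == "female_up"
  ifelse(up, "up_in_males", ifelse(down, "down_in_males", "unspecific"))
}

#' Assemble the final per-precursor report
#'
#' Joins candidate mature peptides (best-supported per precursor), MALDI
#' presence, expression and PSM evidence into one row per precursor that
#' passed the evidence filters, and appends the specificity call.
#'
#' Redundant precursors (identical mature-chain sequence after signal-peptide
#' removal) are collapsed to the record with the highest -10lgP.
#'
#' @param precursors Tibble of precursor records (`id`, `sequence`,
#'   `signal_end`, optional `processing_strategy`, `class_label`).
#' @param peaklists Tibble of peak-list rows (all groups).
#' @param expression Tibble from [read_expression_table()].
#' @param psms Tibble of PSM records.
#' @param hits Optional tibble of homology hits.
#' @param config A [run_config()] list.
#' @return A tibble with one row per retained precursor: `id`, `class`,
#'   `mature_sequence`, `amidated`, `n_disulfides`, `predicted_mh`,
#'   `present_male`, `present_female`, `present_juvenile`, the TPM triplet,
#'   `direction`, `gland_enriched`, `call`.
#' @export
build_report <- function(precursors, peaklists, expression, psms,
                         hits = NULL, config = run_config()) {
  empty <- tibble::tibble(
    id = character(), class = character(), mature_sequence = character(),
    amidated = logical(), n_disulfides = integer(), predicted_mh = double(),
    present_male = logical(), present_female = logical(),
    present_juvenile = logical(), tpm_male_telson = double(),
    tpm_female_telson = double(), tpm_negative_control = double(),
    direction = character(), gland_enriched = logical(), call = character()
  )
  if (nrow(precursors) == 0L) return(empty)

  kept_psms <- filter_psms(psms, config$min_neg_log_p, config$min_coverage_pct)
  precursors <- precursors[precursors$id %in% kept_psms$id, ]
  if (nrow(precursors) == 0L) return(empty)

  # redundancy removal: identical mature chain -> keep highest-scoring PSM
  chain <- vapply(seq_len(nrow(precursors)), function(i)
    strip_signal(precursors$sequence[i], precursors$signal_end[i]), character(1))
  score <- kept_psms$neg_log_p[match(precursors$id, kept_psms$id)]
  keep <- order(-score)
  keep <- keep[!duplicated(chain[keep])]
  precursors <- precursors[sort(keep), ]

  cand <- dplyr::bind_rows(lapply(seq_len(nrow(precursors)), function(i)
    mature_candidates(precursors[i, ], config)))

  cons <- consensus_by_group(peaklists, config$cluster_tolerance_da,
                             config$min_occurrence_fraction)
  pres <- presence_table(cand, cons, config$mass_tolerance_da)

  # best-supported candidate per precursor: matched candidates first (smallest
  # |delta|), else the first enumerated candidate
  matches <- match_predictions(cand, cons, config$mass_tolerance_da)
  best <- vapply(precursors$id, function(pid) {
    idx <- which(cand$precursor_id == pid)
    m <- matches[matches$precursor_id == pid, ]
    if (nrow(m)) {
      hit <- idx[which.min(vapply(cand$predicted_mh[idx], function(x)
        min(abs(x - m$centroid_mz)), numeric(1)))]
    } else hit <- idx[1]
    hit
  }, integer(1))

  expr <- expression[match(precursors$id, expression$id), ]
  expr$tpm_male_telson[is.na(expr$tpm_male_telson)] <- 0
  expr$tpm_female_telson[is.na(expr$tpm_female_telson)] <- 0
  expr$tpm_negative_control[is.na(expr$tpm_negative_control)] <- 0

  contrast <- expression_contrast(expr$tpm_male_telson, expr$tpm_female_telson,
                                  expr$tpm_negative_control,
                                  config$min_fold_change)

  class <- if ("class_label" %in% names(precursors) &&
               !all(is.na(precursors$class_label))) {
    precursors$class_label
  } else if (!is.null(hits)) {
    vapply(precursors$id, function(pid)
      classify_annotation(hits[hits$id == pid, ]), character(1))
  } else rep(NA_character_, nrow(precursors))

  p <- pres[match(precursors$id, pres$precursor_id), ]
  tibble::tibble(
    id = precursors$id,
    class = class,
    mature_sequence = cand$sequence[best],
    amidated = cand$amidated[best],
    n_disulfides = cand$n_disulfides[best],
    predicted_mh = cand$predicted_mh[best],
    present_male = p$present_male,
    present_female = p$present_female,
    present_juvenile = p$present_juvenile,
    tpm_male_telson = expr$tpm_male_telson,
    tpm_female_telson = expr$tpm_female_telson,
    tpm_negative_control = expr$tpm_negative_control,
    direction = contrast$direction,
    gland_enriched = contrast$gland_enriched,
    call = call_specificity(p$present_male, p$present_female,
                            p$present_juvenile, contrast$direction)
  )
}
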