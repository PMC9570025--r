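# Consensus building over replicate MALDI-TOF fingerprints and matching of
# predicted [M+H]+ values against them. Presence calls use only signal
# presence/absence; intensities, when present, are carried through for
# reporting and never enter any decision.

#' Reproducible consensus signals of one specimen group
#'
#' Pools the signals of all spectra of one group and clusters them by greedy
#' single-linkage in ascending m/z order: a signal joins the current cluster
#' while its gap to the cluster's previous (largest) member is at most
#' `tolerance_da`, otherwise it opens a new cluster. A cluster is kept when the
#' fraction of the group's spectra supporting it (each spectrum counted once)
#' reaches `min_occurrence_fraction`. The centroid is the mean m/z of the
#' cluster's member signals.
#'
#' @param peaklists Tibble of peak-list rows (`specimen_id`, `replicate_id`,
#'   `group`, `mz`) belonging to one group; rows of other groups are an error.
#' @param tolerance_da Single-linkage threshold in Da (> 0).
#' @param min_occurrence_fraction Minimum supported fraction of spectra in
#'   [0, 1]; at 0 every distinct cluster is kept.
#' @param n_spectra Total number of spectra in the group. Defaults to the
#'   number of distinct (specimen, replicate) pairs present in `peaklists`;
#'   pass it explicitly when some spectra are empty (an empty spectrum still
#'   counts in the denominator).
#' @return A tibble with columns `group`, `centroid_mz`, `occurrence_fraction`,
#'   `n_support` and a list-column `supporting_spectra` of
#'   (specimen_id, replicate_id) tibbles, sorted by centroid m/z.
#' @export
consensus_signals <- function(peaklists, tolerance_da = 0.15,
                              min_occurrence_fraction = 0.5,
                              n_spectra = NULL) {
  stopifnot(tolerance_da > 0)
  empty <- tibble::tibble(group = character(), centroid_mz = double(),
                          occurrence_fraction = double(), n_support = integer(),
                          supporting_spectra = list())
  if (nrow(peaklists) == 0L) return(empty)
  grp <- unique(peaklists$group)
  if (length(grp) != 1L)
    stop("consensus_signals() expects peak lists of a single group", call. = FALSE)
  spec_key <- paste(peaklists$specimen_id, peaklists$replicate_id, sep = "\r")
  if (is.null(n_spectra)) n_spectra <- length(unique(spec_key))
  ord <- order(peaklists$mz)
  mz <- peaklists$mz[ord]
  key <- spec_key[ord]
  cluster <- cumsum(c(1L, diff(mz) > tolerance_da))
  rows <- lapply(split(seq_along(mz), cluster), function(idx) {
    support <- unique(key[idx])
    frac <- length(support) / n_spectra
    parts <- strsplit(support, "\r", fixed = TRUE)
    tibble::tibble(
      group = grp,
      centroid_mz = mean(mz[idx]),
      occurrence_fraction = frac,
      n_support = length(support),
      supporting_spectra = list(tibble::tibble(
        specimen_id = vapply(parts, `[`, "", 1L),
        replicate_id = vapply(parts, `[`, "", 2L)
      ))
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- out[out$occurrence_fraction >= min_occurrence_fraction |
               min_occurrence_fraction == 0, ]
  out[order(out$centroid_mz), ]
}

#' Consensus signals for every group at once
#'
#' @inheritParams consensus_signals
#' @param n_spectra Optional named vector of spectra counts per group.
#' @return Row-bound [consensus_signals()] results for each group present.
#' @export
consensus_by_group <- function(peaklists, tolerance_da = 0.15,
                               min_occurrence_fraction = 0.5,
                               n_spectra = NULL) {
  parts <- lapply(split(peaklists, peaklists$group), function(pl) {
    ns <- if (!is.null(n_spectra)) n_spectra[[pl$group[1]]] else NULL
    consensus_signals(pl, tolerance_da, min_occurrence_fraction, ns)
  })
  dplyr::bind_rows(parts)
}

#' Match predicted masses against consensus signals
#'
#' A (peptide, consensus signal) pair is reported iff
#' |predicted [M+H]+ - centroid| <= `tolerance_da` (boundary inclusive). A
#' peptide may match signals in several groups; within one group only the
#' nearest centroid is kept.
#'
#' @param predicted Tibble of candidate peptides with columns `precursor_id`
#'   and `predicted_mh` (one row per candidate).
#' @param consensus Tibble from [consensus_signals()]/[consensus_by_group()].
#' @param tolerance_da Matching tolerance in Da (>= 0).
#' @return A tibble with columns `precursor_id`, `predicted_mh`, `group`,
#'   `centroid_mz`, `delta_da`.
#' @export
match_predictions <- function(predicted, consensus, tolerance_da = 0.2) {
  stopifnot(tolerance_da >= 0)
  empty <- tibble::tibble(precursor_id = character(), predicted_mh = double(),
                          group = character(), centroid_mz = double(),
                          delta_da = double())
  if (nrow(predicted) == 0L || nrow(consensus) == 0L) return(empty)
  rows <- lapply(seq_len(nrow(predicted)), function(i) {
    d <- abs(predicted$predicted_mh[i] - consensus$centroid_mz)
    hit <- which(d <= tolerance_da)
    if (!length(hit)) return(NULL)
    h <- consensus[hit, ]
    h$delta_da <- predicted$predicted_mh[i] - h$centroid_mz
    # nearest centroid per group
    h <- h[order(abs(h$delta_da)), ]
    h <- h[!duplicated(h$group), ]
    tibble::tibble(precursor_id = predicted$precursor_id[i],
                   predicted_mh = predicted$predicted_mh[i],
                   group = h$group, centroid_mz = h$centroid_mz,
                   delta_da = h$delta_da)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) empty else out
}

#' Per-group presence of each predicted peptide
#'
#' Reduces [match_predictions()] output to a boolean presence matrix: a
#' precursor is present in a group when any of its candidate masses matches a
#' reproducible consensus signal of that group.
#'
#' @inheritParams match_predictions
#' @param groups Groups to report columns for.
#' @return A tibble with one row per precursor and logical columns
#'   `present_male`, `present_female`, `present_juvenile` (for the requested
#'   groups).
#' @export
presence_table <- function(predicted, consensus, tolerance_da = 0.2,
                           groups = c("male", "female", "juvenile")) {
  stopifnot(all(groups %in% .GROUPS))
  matches <- match_predictions(predicted, consensus, tolerance_da)
  ids <- unique(predicted$precursor_id)
  out <- tibble::tibble(precursor_id = ids)
  for (g in groups)
    out[[paste0("present_", g)]] <-
      ids %in% matches$precursor_id[matches$group == g]
  out
}
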