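# Curated reference set: the twelve sexually dimorphic venom precursors of
# Euscorpius italicus, with signal-peptide boundaries, processing strategies,
# PTM flags, annotated mature regions, published predicted [M+H]+ values,
# TPM triplets and MALDI-derived regulation (up/down in males).
#
# The homology and PSM companion files carry *synthetic* placeholder numbers
# where the study published none: E-values are set to a nominal 1e-20 (only
# filtered hits were reported) and -10lgP/coverage to nominal passing values.
# Their filenames say so.

.extdata <- function(file)
  system.file("extdata", file, package = "venomdimorph", mustWork = TRUE)

#' Reference venom precursors of Euscorpius italicus
#'
#' Twelve precursors whose mature peptides are up- or down-regulated in male
#' venom, with sequences (one `[X/Y]` allelic marker where applicable),
#' signal-peptide boundaries, processing strategies, PTM flags (`A` =
#' C-terminal amidation, `C-C` = disulfide bridges), the annotated mature
#' region, the published predicted [M+H]+ (slash-separated for the two
#' alleles), the MALDI regulation call, and Orbitrap experiment tags.
#'
#' The `class_label` column is the curated class; for EUTX-Ei2b it reflects a
#' manual override (its best homology hit is an AMP, but the peptide is
#' paralogous to the sodium-channel-toxin-like EUTX-Ei2a).
#'
#' @return A 12-row tibble.
#' @export
euscorpius_precursors <- function() {
  read_precursor_fasta(.extdata("euscorpius_precursors.fasta"),
                       .extdata("euscorpius_annotations.tsv"))
}

#' Reference expression triplets (TPM)
#'
#' TPM of each reference precursor in the male telson, female telson and
#' negative-control (tail without venom gland) transcriptomes; `-` in the
#' source file (no detected expression) reads as 0.
#'
#' @return A 12-row tibble.
#' @export
euscorpius_expression <- function() {
  read_expression_table(.extdata("euscorpius_expression.tsv"))
}

#' Reference homology hits (synthetic E-values)
#'
#' Best database hits of the reference precursors. Descriptions, identities
#' and accessions are the published ones; E-values are synthetic placeholders
#' (1e-20, below every acceptance threshold) because only filtered hits were
#' published. The novel compound NVC-Ei1 has no hit and therefore no row.
#'
#' @return An 11-row tibble.
#' @export
euscorpius_homology <- function() {
  read_homology_table(.extdata("euscorpius_homology_synthetic_evalues.tsv"))
}

#' Reference PSM evidence (synthetic scores)
#'
#' Experiment tags are the published ones (D/ND = digested / not digested,
#' m/f = male/female venom); -10lgP and coverage are synthetic placeholders
#' above the filter thresholds, because per-precursor scores were not
#' published.
#'
#' @return A 12-row tibble.
#' @export
euscorpius_psms <- function() {
  read_psm_table(.extdata("euscorpius_psm_synthetic_scores.tsv"))
}

#' MALDI presence patterns implied by the regulation calls
#'
#' Expands the `regulation` column of [euscorpius_precursors()] into the
#' per-group presence pattern it encodes: `up` (male-specific) means present
#' in male fingerprints and absent from female and juvenile ones; `down` the
#' reverse.
#'
#' @return A tibble with `precursor_id`, `present_male`, `present_female`,
#'   `present_juvenile`.
#' @export
euscorpius_presence <- function() {
  ann <- euscorpius_precursors()
  tibble::tibble(
    precursor_id = ann$id,
    present_male = ann$regulation == "up",
    present_female = ann$regulation == "down",
    present_juvenile = ann$regulation == "down"
  )
}

#' Annotated mature peptides of the reference precursors
#'
#' Expands each annotated mature region (both alleles where marked), derives
#' PTM flags from the `ptm` column and the cysteine count, and predicts
#' [M+H]+. This is the reference answer the maturation grammar is validated
#' against.
#'
#' @return A tibble with one row per (precursor, allele): `precursor_id`,
#'   `allele`, `sequence`, `amidated`, `n_disulfides`, `predicted_mh`,
#'   `printed_mh`, `regulation`.
#' @export
euscorpius_mature_peptides <- function() {
  ann <- euscorpius_precursors()
  rows <- lapply(seq_len(nrow(ann)), function(i) {
    seqs <- expand_alleles(ann$mature_sequence[i])
    printed <- as.numeric(strsplit(ann$printed_mh[i], "/", fixed = TRUE)[[1]])
    amid <- grepl("A", ann$ptm[i], fixed = TRUE)
    tibble::tibble(
      precursor_id = ann$id[i],
      allele = if (length(seqs) == 1L) NA_character_ else c("ref", "alt"),
      sequence = seqs,
      amidated = amid,
      n_disulfides = vapply(seqs, count_disulfides, integer(1)),
      predicted_mh = vapply(seq_along(seqs), function(j)
        mh_plus(seqs[j], amid, count_disulfides(seqs[j])), numeric(1)),
      printed_mh = printed,
      regulation = ann$regulation[i]
    )
  })
  dplyr::bind_rows(rows)
}
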