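# Readers/writers for the pipeline's external formats. Everything tabular is
# plain TSV; precursors are FASTA plus a companion annotation table (the
# signal-peptide boundary and processing strategy are consumed as annotations,
# they are never predicted here).

#' Pipeline run configuration
#'
#' Bundles the tunable parameters of the pipeline with their defaults:
#' \describe{
#'   \item{mass_tolerance_da}{m/z tolerance (Da) for matching predicted
#'     [M+H]+ against consensus signals; default 0.2.}
#'   \item{cluster_tolerance_da}{single-linkage threshold (Da) for clustering
#'     signals across replicate spectra; default 0.15.}
#'   \item{min_occurrence_fraction}{fraction of a group's spectra a signal must
#'     occur in to count as reproducible; default 0.5.}
#'   \item{min_neg_log_p}{PSM confidence threshold (-10lgP, strict >);
#'     default 30.}
#'   \item{min_coverage_pct}{precursor coverage threshold (%, strict >);
#'     default 7.}
#'   \item{min_fold_change}{fold-change threshold for the expression contrast;
#'     default 2.}
#'   \item{trim_basic_residues}{trim basic residues left adjacent to a cleavage
#'     site on the mature side; default TRUE.}
#'   \item{max_basic_trim}{maximum number of trailing basics trimmed;
#'     default 1.}
#'   \item{random_seed}{seed for the synthetic-data generators.}
#' }
#'
#' @param ... Named overrides of the defaults above.
#' @return A named list of class `"venomdimorph_config"`.
#' @export
run_config <- function(...) {
  cfg <- list(
    mass_tolerance_da = 0.2,
    cluster_tolerance_da = 0.15,
    min_occurrence_fraction = 0.5,
    min_neg_log_p = 30,
    min_coverage_pct = 7,
    min_fold_change = 2,
    trim_basic_residues = TRUE,
    max_basic_trim = 1L,
    random_seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  stopifnot(
    cfg$mass_tolerance_da > 0, cfg$cluster_tolerance_da > 0,
    cfg$min_occurrence_fraction >= 0, cfg$min_occurrence_fraction <= 1,
    cfg$min_fold_change >= 1, cfg$max_basic_trim >= 0
  )
  class(cfg) <- "venomdimorph_config"
  cfg
}

#' Read or write a run configuration as YAML
#'
#' @param path File path.
#' @return For the reader, a [run_config()] list with file values applied over
#'   the defaults.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config A [run_config()] list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.GROUPS <- c("male", "female", "juvenile")

#' Read venom precursor sequences
#'
#' Reads a FASTA file of precursor amino-acid sequences together with a
#' companion annotation table (TSV with at least `id` and `signal_end`;
#' optional `processing_strategy`, `class_label` and further columns, which are
#' carried through). Sequences use one-letter codes and may contain one
#' allelic marker `[X/Y]` (see [expand_alleles()]); any other non-standard
#' character is rejected. `signal_end` is 0-based: the index of the first
#' mature-chain residue.
#'
#' @param fasta_path Path to the FASTA file.
#' @param annotation_path Path to the annotation TSV.
#' @return A tibble of precursor records, one row per precursor, with columns
#'   `id`, `sequence`, `signal_end` plus any extra annotation columns.
#' @export
read_precursor_fasta <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate precursor identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  sequences <- as.character(seqs)
  for (i in seq_along(sequences)) {
    plain <- expand_alleles(sequences[i])
    bad <- grepl(sprintf("[^%s]", paste(.AA_CODES, collapse = "")), plain)
    if (nchar(plain[1]) == 0L)
      stop("empty sequence for record ", ids[i], call. = FALSE)
    if (any(bad))
      stop("record ", ids[i],
           " contains non-standard residues (only the 20 one-letter codes and one [X/Y] allelic marker are allowed)",
           call. = FALSE)
  }
  ann <- tibble::as_tibble(utils::read.delim(annotation_path, sep = "\t",
                                             stringsAsFactors = FALSE,
                                             check.names = FALSE))
  if (!all(c("id", "signal_end") %in% names(ann)))
    stop("annotation table must have columns 'id' and 'signal_end'", call. = FALSE)
  missing <- setdiff(ids, ann$id)
  if (length(missing))
    stop("no annotation for precursor(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- tibble::tibble(id = ids, sequence = unname(sequences))
  dplyr::left_join(out, ann, by = "id")
}

#' Write precursors as FASTA + annotation table
#'
#' @param precursors Tibble as returned by [read_precursor_fasta()].
#' @inheritParams read_precursor_fasta
#' @export
write_precursor_fasta <- function(precursors, fasta_path, annotation_path) {
  lines <- as.vector(rbind(paste0(">", precursors$id), precursors$sequence))
  writeLines(lines, fasta_path)
  ann <- precursors[setdiff(names(precursors), "sequence")]
  utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(fasta_path)
}

#' Read replicate MALDI-TOF peak lists
#'
#' Peak lists are stored as one TSV with columns `specimen_id`, `replicate_id`,
#' `group` (male/female/juvenile) and `mz` (monoisotopic [M+H]+, Da); an
#' optional `intensity` column is carried through. Within one spectrum, m/z
#' values are sorted ascending and exact duplicates merged.
#'
#' @param path Path to the TSV.
#' @return A tibble with one row per retained signal.
#' @export
read_peaklists <- function(path) {
  x <- tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                           stringsAsFactors = FALSE))
  req <- c("specimen_id", "replicate_id", "group", "mz")
  if (!all(req %in% names(x)))
    stop("peak-list table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(x$group), .GROUPS)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(x$mz < 0)) stop("negative m/z value", call. = FALSE)
  x <- x[order(x$specimen_id, x$replicate_id, x$mz), ]
  x[!duplicated(x[c("specimen_id", "replicate_id", "group", "mz")]), ]
}

#' @rdname read_peaklists
#' @param peaklists Tibble of peak-list rows.
#' @export
write_peaklists <- function(peaklists, path) {
  utils::write.table(peaklists, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the expression table
#'
#' TSV with columns `id`, `tpm_male_telson`, `tpm_female_telson`,
#' `tpm_negative_control`. Missing values and `"-"` (the conventional mark for
#' no detected expression) map to 0; negative TPM is an error.
#'
#' @param path Path to the TSV.
#' @return A tibble with the four columns above, all TPM numeric and >= 0.
#' @export
read_expression_table <- function(path) {
  x <- tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                           stringsAsFactors = FALSE,
                                           colClasses = "character"))
  req <- c("id", "tpm_male_telson", "tpm_female_telson", "tpm_negative_control")
  if (!all(req %in% names(x)))
    stop("expression table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  for (col in req[-1]) {
    v <- x[[col]]
    v[is.na(v) | v %in% c("", "-")] <- "0"
    v <- gsub(",", "", v)            # tolerate thousands separators
    num <- suppressWarnings(as.numeric(v))
    if (any(is.na(num)))
      stop("non-numeric value in column ", col, call. = FALSE)
    if (any(num < 0)) stop("negative TPM in column ", col, call. = FALSE)
    x[[col]] <- num
  }
  x[req]
}

#' Read a PSM-evidence table
#'
#' TSV mimicking a search-engine export: `id`, `neg_log_p` (-10lgP),
#' `coverage_pct`, `has_signal_peptide` (logical), optional `experiments`
#' (comma-separated tags such as `D-m,ND-f`).
#'
#' @param path Path to the TSV.
#' @return A tibble of PSM records.
#' @export
read_psm_table <- function(path) {
  x <- tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                           stringsAsFactors = FALSE))
  req <- c("id", "neg_log_p", "coverage_pct", "has_signal_peptide")
  if (!all(req %in% names(x)))
    stop("PSM table must have columns ", paste(req, collapse = ", "), call. = FALSE)
  stopifnot(is.numeric(x$neg_log_p), is.numeric(x$coverage_pct))
  if (any(x$coverage_pct < 0 | x$coverage_pct > 100))
    stop("coverage_pct outside [0, 100]", call. = FALSE)
  if (any(x$neg_log_p < 0)) stop("negative -10lgP", call. = FALSE)
  x$has_signal_peptide <- as.logical(x$has_signal_peptide)
  x
}

#' Read a homology-hit table
#'
#' TSV with columns `id`, `database` (`metazoa` or `toxprot`), `description`,
#' `e_value`; used by [classify_annotation()].
#'
#' @param path Path to the TSV.
#' @return A tibble of hits.
#' @export
read_homology_table <- function(path) {
  x <- tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                           stringsAsFactors = FALSE))
  req <- c("id", "database", "description", "e_value")
  if (!all(req %in% names(x)))
    stop("homology table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(x$database), c("metazoa", "toxprot"))
  if (length(bad))
    stop("unknown database label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  x
}
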