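# Precursor maturation grammar.
#
# A venom precursor is signal peptide + (propeptides +) mature peptide. The
# grammar implemented here covers the processing routes seen in scorpion venom
# precursors: use of the complete chain after the signal peptide, C-terminal
# Gly consumed as amidation signal, cleavage at mono-/di-/tribasic K/R runs
# (the mature product never retains any residue of the basic run), an
# N-terminal quadruplet motif around a monobasic R, and optional trimming of
# basic residues left adjacent to a cleavage site on the mature side.
#
# Coordinates are 0-based half-open throughout; `signal_end` is the index of
# the first mature-chain residue.

.STRATEGIES <- c("FULL_CHAIN", "FULL_CHAIN_GLY_AMIDE", "C_TERM_BASIC_CLEAVE",
                 "N_TERM_REGION", "N_TERM_QUADRUPLET", "AUTO")

#' Remove the signal peptide from a precursor sequence
#'
#' @param sequence Full precursor amino-acid string.
#' @param signal_end 0-based index of the first mature-chain residue (= length
#'   of the signal peptide).
#' @return The chain downstream of the signal peptide.
#' @export
strip_signal <- function(sequence, signal_end) {
  n <- nchar(sequence)
  if (signal_end <= 0 || signal_end >= n)
    stop(sprintf("signal_end = %d out of range for sequence of length %d (mature chain must be non-empty)",
                 signal_end, n), call. = FALSE)
  substr(sequence, signal_end + 1L, n)
}

#' Locate basic-residue cleavage sites
#'
#' Finds maximal runs of K/R in a chain and classifies them as monobasic,
#' dibasic or tribasic. Runs longer than three are not part of the grammar;
#' they are reported as a tribasic site over the run's C-terminal three
#' residues, with a warning.
#'
#' @param chain Amino-acid string (mature chain, signal peptide removed).
#' @return A tibble with columns `start`, `end` (0-based half-open span of the
#'   reported basic run), `kind` (`"monobasic"`, `"dibasic"`, `"tribasic"`) and
#'   `run_length` (length of the reported run, 1-3).
#' @export
find_basic_sites <- function(chain) {
  m <- gregexpr("[KR]+", chain)[[1]]
  out <- tibble::tibble(start = integer(), end = integer(),
                        kind = character(), run_length = integer())
  if (m[1] == -1L) return(out)
  start0 <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  if (any(len > 3L)) {
    warning("basic run longer than 3 residues; reported as tribasic at its C-terminal three residues",
            call. = FALSE)
    start0[len > 3L] <- start0[len > 3L] + (len[len > 3L] - 3L)
    len[len > 3L] <- 3L
  }
  tibble::tibble(
    start = start0,
    end = start0 + len,
    kind = c("monobasic", "dibasic", "tribasic")[len],
    run_length = len
  )
}

# One row of the candidate table.
.candidate <- function(sequence, amidated, derivation) {
  tibble::tibble(
    sequence = sequence,
    amidated = amidated,
    n_disulfides = count_disulfides(sequence),
    derivation = derivation
  )
}

.empty_candidates <- function() {
  tibble::tibble(sequence = character(), amidated = logical(),
                 n_disulfides = integer(), derivation = character())
}

# Trim trailing K/R left adjacent to a cleavage site on the mature side.
.trim_trailing_basics <- function(segment, max_trim = 1L) {
  trimmed <- 0L
  while (trimmed < max_trim && nchar(segment) > 1L &&
         substr(segment, nchar(segment), nchar(segment)) %in% c("K", "R")) {
    segment <- substr(segment, 1L, nchar(segment) - 1L)
    trimmed <- trimmed + 1L
  }
  segment
}

# Strip a terminal Gly amidation signal if present: returns list(seq, amidated).
.consume_gly <- function(segment) {
  n <- nchar(segment)
  if (n > 1L && substr(segment, n, n) == "G")
    list(sequence = substr(segment, 1L, n - 1L), amidated = TRUE)
  else
    list(sequence = segment, amidated = FALSE)
}

#' Derive candidate mature peptides from a processed chain
#'
#' Applies one processing strategy (or all of them under `"AUTO"`) to a mature
#' chain and returns the candidate products. Strategies:
#' \describe{
#'   \item{FULL_CHAIN}{the chain itself, unmodified termini.}
#'   \item{FULL_CHAIN_GLY_AMIDE}{chain minus its terminal Gly, C-terminally
#'     amidated; applicable only when the chain ends in G.}
#'   \item{C_TERM_BASIC_CLEAVE}{for each basic run, the prefix ending
#'     immediately before the run; a Gly immediately preceding the run is
#'     consumed as amidation signal.}
#'   \item{N_TERM_REGION}{for each mono- or dibasic site, the segment from the
#'     chain start to the site; Gly before the site is consumed as amidation
#'     signal; with `trim_basic_residues`, trailing K/R left adjacent to the
#'     site are trimmed from the mature side.}
#'   \item{N_TERM_QUADRUPLET}{for each monobasic R preceded by a spacer of at
#'     least three residues after the signal peptide, the segment from just
#'     after the R through the chain end; a terminal Gly is consumed as
#'     amidation signal.}
#' }
#' An inapplicable strategy yields zero candidates (with the reason attached as
#' attribute `"reason"`), never an error. Every product carries
#' `n_disulfides = count_disulfides(product)`. Under `"AUTO"`, duplicates
#' (identical sequence and amidation) are collapsed, keeping the first
#' derivation in enumeration order (FULL_CHAIN, FULL_CHAIN_GLY_AMIDE, then
#' site-based strategies N- to C-terminal).
#'
#' @param chain Mature chain (signal peptide already removed).
#' @param strategy One of `"FULL_CHAIN"`, `"FULL_CHAIN_GLY_AMIDE"`,
#'   `"C_TERM_BASIC_CLEAVE"`, `"N_TERM_REGION"`, `"N_TERM_QUADRUPLET"`,
#'   `"AUTO"`.
#' @param config A [run_config()] list; `trim_basic_residues` and
#'   `max_basic_trim` are consulted.
#' @return A tibble of candidates with columns `sequence`, `amidated`,
#'   `n_disulfides`, `derivation`.
#' @export
apply_processing <- function(chain, strategy = "AUTO", config = run_config()) {
  strategy <- match.arg(strategy, .STRATEGIES)
  n <- nchar(chain)
  if (strategy == "AUTO") {
    parts <- list(
      apply_processing(chain, "FULL_CHAIN", config),
      apply_processing(chain, "FULL_CHAIN_GLY_AMIDE", config),
      apply_processing(chain, "N_TERM_REGION", config),
      apply_processing(chain, "N_TERM_QUADRUPLET", config),
      apply_processing(chain, "C_TERM_BASIC_CLEAVE", config)
    )
    all <- dplyr::bind_rows(parts)
    return(all[!duplicated(all[c("sequence", "amidated")]), ])
  }

  sites <- find_basic_sites(chain)

  if (strategy == "FULL_CHAIN")
    return(.candidate(chain, FALSE, "FULL_CHAIN"))

  if (strategy == "FULL_CHAIN_GLY_AMIDE") {
    if (substr(chain, n, n) != "G") {
      out <- .empty_candidates()
      attr(out, "reason") <- "chain does not end in G; no amidation signal"
      return(out)
    }
    return(.candidate(substr(chain, 1L, n - 1L), TRUE, "FULL_CHAIN_GLY_AMIDE"))
  }

  if (strategy == "C_TERM_BASIC_CLEAVE") {
    keep <- sites[sites$start > 0L, , drop = FALSE]
    if (nrow(keep) == 0L) {
      out <- .empty_candidates()
      attr(out, "reason") <- "no basic run with a non-empty prefix"
      return(out)
    }
    rows <- lapply(keep$start, function(s) {
      g <- .consume_gly(substr(chain, 1L, s))
      .candidate(g$sequence, g$amidated,
                 sprintf("C_TERM_BASIC_CLEAVE@%d", s))
    })
    return(dplyr::bind_rows(rows))
  }

  if (strategy == "N_TERM_REGION") {
    keep <- sites[sites$run_length <= 2L & sites$start > 0L, , drop = FALSE]
    if (nrow(keep) == 0L) {
      out <- .empty_candidates()
      attr(out, "reason") <- "no mono- or dibasic site downstream of a non-empty N-terminal region"
      return(out)
    }
    rows <- lapply(keep$start, function(s) {
      seg <- substr(chain, 1L, s)
      # trim first (carboxypeptidase step), then consume the amidation Gly
      if (isTRUE(config$trim_basic_residues))
        seg <- .trim_trailing_basics(seg, config$max_basic_trim)
      g <- .consume_gly(seg)
      .candidate(g$sequence, g$amidated, sprintf("N_TERM_REGION@%d", s))
    })
    return(dplyr::bind_rows(rows))
  }

  # N_TERM_QUADRUPLET: an R whose left neighbour is not basic (the motif spans
  # the four residues ending at the R), preceded by a >= 3-residue spacer after
  # the signal peptide. Cleavage is immediately after the R; downstream
  # residues belong to the mature peptide even when basic (the mature product
  # of this route may itself start with K/R).
  aa <- strsplit(chain, "", fixed = TRUE)[[1]]
  pos0 <- which(aa == "R") - 1L                      # 0-based
  pos0 <- pos0[pos0 >= 3L & pos0 < n - 1L & !aa[pos0] %in% c("K", "R")]
  if (!length(pos0)) {
    out <- .empty_candidates()
    attr(out, "reason") <- "no cleavage R with a >=3-residue spacer and downstream segment"
    return(out)
  }
  rows <- lapply(pos0, function(p) {
    g <- .consume_gly(substr(chain, p + 2L, n))
    .candidate(g$sequence, g$amidated, sprintf("N_TERM_QUADRUPLET@%d", p))
  })
  dplyr::bind_rows(rows)
}

#' Expand an allelic marker into plain sequences
#'
#' Sequences may carry at most one allelic position written `[X/Y]` (for
#' example `...VLKEKE[K/E]KE...`). Expansion yields the two plain sequences;
#' a sequence without a marker is returned as a singleton.
#'
#' @param sequence Amino-acid string, possibly with one `[X/Y]` marker.
#' @return Character vector of one or two plain sequences.
#' @export
expand_alleles <- function(sequence) {
  m <- gregexpr("\\[([A-Z])/([A-Z])\\]", sequence)[[1]]
  if (m[1] == -1L) return(sequence)
  if (length(m) > 1L)
    stop("more than one allelic marker in sequence", call. = FALSE)
  alleles <- substr(sequence, m + 1L, m + 1L)
  alleles <- c(alleles, substr(sequence, m + 3L, m + 3L))
  vapply(alleles, function(a)
    sub("\\[([A-Z])/([A-Z])\\]", a, sequence), character(1), USE.NAMES = FALSE)
}

#' Enumerate candidate mature peptides of a precursor
#'
#' Expands any allelic marker, strips the signal peptide, applies the
#' precursor's processing strategy (or `"AUTO"`) and predicts [M+H]+ for every
#' candidate.
#'
#' @param precursor A one-row data frame or list with fields `id`, `sequence`,
#'   `signal_end` and optionally `processing_strategy`.
#' @param config A [run_config()] list.
#' @param strategy Overrides the precursor's own strategy when non-NULL.
#' @return A tibble with columns `precursor_id`, `allele`, `sequence`,
#'   `amidated`, `n_disulfides`, `derivation`, `predicted_mh`.
#' @export
mature_candidates <- function(precursor, config = run_config(), strategy = NULL) {
  strat <- strategy %||% precursor$processing_strategy %||% "AUTO"
  if (is.null(strat) || is.na(strat) || !nzchar(strat)) strat <- "AUTO"
  alleles <- expand_alleles(precursor$sequence)
  rows <- lapply(seq_along(alleles), function(i) {
    chain <- strip_signal(alleles[i], precursor$signal_end)
    cand <- apply_processing(chain, strat, config)
    if (nrow(cand) == 0L) return(NULL)
    cand$precursor_id <- precursor$id
    cand$allele <- if (length(alleles) == 1L) NA_character_ else
      substr(alleles[i], .allele_pos(precursor$sequence), .allele_pos(precursor$sequence))
    cand
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L)
    return(tibble::tibble(precursor_id = character(), allele = character(),
                          sequence = character(), amidated = logical(),
                          n_disulfides = integer(), derivation = character(),
                          predicted_mh = double()))
  out$predicted_mh <- mapply(mh_plus, out$sequence, out$amidated, out$n_disulfides)
  out[c("precursor_id", "allele", "sequence", "amidated", "n_disulfides",
        "derivation", "predicted_mh")]
}

# 1-based position of the allelic residue in the expanded sequence.
.allele_pos <- function(marked_sequence) {
  m <- regexpr("\\[([A-Z])/([A-Z])\\]", marked_sequence)
  as.integer(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
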