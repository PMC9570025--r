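# Monoisotopic mass arithmetic for venom peptides.
#
# Two independent routes to the same quantity are kept deliberately separate:
#   (1) residue-sum: sum of per-residue monoisotopic masses + water;
#   (2) elemental: count atoms, then multiply by exact element masses.
# Route (2) is the in-package oracle for route (1); both derive from the same
# exact element masses so they agree to < 1e-6 Da on arbitrary sequences.

# Exact monoisotopic element masses (Da).
.ELEMENT_MASS <- c(
  H = 1.0078250319,
  C = 12.0,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

# Residue (i.e. dehydrated amino-acid) elemental formulas, 20 standard codes.
# Rows: H, C, N, O, S counts per residue.
.RESIDUE_FORMULA <- local({
  f <- rbind(
    G = c(3, 2, 1, 1, 0),
    A = c(5, 3, 1, 1, 0),
    S = c(5, 3, 1, 2, 0),
    P = c(7, 5, 1, 1, 0),
    V = c(9, 5, 1, 1, 0),
    T = c(7, 4, 1, 2, 0),
    C = c(5, 3, 1, 1, 1),
    L = c(11, 6, 1, 1, 0),
    I = c(11, 6, 1, 1, 0),
    N = c(6, 4, 2, 2, 0),
    D = c(5, 4, 1, 3, 0),
    Q = c(8, 5, 2, 2, 0),
    K = c(12, 6, 2, 1, 0),
    E = c(7, 5, 1, 3, 0),
    M = c(9, 5, 1, 1, 1),
    H = c(7, 6, 3, 1, 0),
    F = c(9, 9, 1, 1, 0),
    R = c(12, 6, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0),
    W = c(10, 11, 2, 1, 0)
  )
  colnames(f) <- c("H", "C", "N", "O", "S")
  f
})

.AA_CODES <- rownames(.RESIDUE_FORMULA)

#' Monoisotopic residue mass table and PTM constants
#'
#' Returns the mass model used throughout the package: monoisotopic masses of
#' the 20 standard amino-acid residues (dehydrated), derived from exact
#' monoisotopic element masses, plus the constants for terminal water, the
#' proton, C-terminal amidation and disulfide-bridge formation.
#'
#' The amidation delta (-0.984016 Da) corresponds to replacing the C-terminal
#' hydroxyl oxygen by NH (free acid -> amide); each disulfide bridge removes
#' two hydrogens (-2.015650 Da).
#'
#' @return A list with components `residues` (named numeric vector, Da),
#'   `water`, `proton`, `amidation_delta`, `disulfide_delta` (all Da).
#' @examples
#' residue_mass_table()$residues["G"]  # 57.02146
#' @export
residue_mass_table <- function() {
  res <- as.numeric(.RESIDUE_FORMULA %*% .ELEMENT_MASS[colnames(.RESIDUE_FORMULA)])
  names(res) <- .AA_CODES
  list(
    residues = res,
    water = 2 * .ELEMENT_MASS[["H"]] + .ELEMENT_MASS[["O"]],
    proton = 1.007276466879,
    amidation_delta = .ELEMENT_MASS[["N"]] + .ELEMENT_MASS[["H"]] - .ELEMENT_MASS[["O"]],
    disulfide_delta = -2 * .ELEMENT_MASS[["H"]]
  )
}

.MASS <- residue_mass_table()

.check_sequence <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop("peptide sequence must be a single non-empty string", call. = FALSE)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!aa %in% .AA_CODES)
  if (length(bad))
    stop(sprintf("unknown residue '%s' at position %d", aa[bad[1]], bad[1]),
         call. = FALSE)
  aa
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of monoisotopic residue masses plus one water (unmodified termini).
#'
#' @param sequence One-letter amino-acid string (20 standard residues;
#'   ambiguity codes B/Z/X are rejected).
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_neutral_mass("G")   # 75.03203
#' @export
peptide_neutral_mass <- function(sequence) {
  aa <- .check_sequence(sequence)
  sum(.MASS$residues[aa]) + .MASS$water
}

#' Count of cysteines in a sequence
#'
#' All cysteines are assumed to pair into disulfide bridges, so the bridge
#' count is floor(#C / 2). Odd cysteines leave one free thiol.
#'
#' @param sequence One-letter amino-acid string.
#' @return Non-negative integer number of disulfide bridges.
#' @export
count_disulfides <- function(sequence) {
  aa <- .check_sequence(sequence)
  sum(aa == "C") %/% 2L
}

#' Predicted singly protonated ion mass [M+H]+
#'
#' Monoisotopic [M+H]+ of a mature peptide with optional C-terminal amidation
#' (-0.984016 Da) and disulfide bridges (-2.015650 Da each), as observed in
#' reflector MALDI-TOF spectra.
#'
#' @param sequence One-letter amino-acid string.
#' @param amidated Logical; C-terminal amide instead of free acid.
#' @param n_disulfides Number of disulfide bridges; must not exceed
#'   floor(#C / 2).
#' @return Predicted [M+H]+ in Da.
#' @examples
#' mh_plus("ILSDIWNGIKGLF", amidated = TRUE)  # 1474.84
#' @export
mh_plus <- function(sequence, amidated = FALSE, n_disulfides = 0L) {
  if (n_disulfides < 0 || n_disulfides != round(n_disulfides))
    stop("n_disulfides must be a non-negative integer", call. = FALSE)
  max_ss <- count_disulfides(sequence)
  if (n_disulfides > max_ss)
    stop(sprintf("n_disulfides = %d exceeds floor(#C/2) = %d", n_disulfides, max_ss),
         call. = FALSE)
  peptide_neutral_mass(sequence) + .MASS$proton +
    (if (isTRUE(amidated)) .MASS$amidation_delta else 0) +
    n_disulfides * .MASS$disulfide_delta
}

#' Elemental composition of a (possibly modified) peptide
#'
#' Atom counts of the neutral species. Amidation replaces one O by N + H; each
#' disulfide removes two H. Serves as the independent oracle for the
#' residue-sum mass route.
#'
#' @inheritParams mh_plus
#' @return Named integer vector with elements H, C, N, O, S.
#' @export
elemental_composition <- function(sequence, amidated = FALSE, n_disulfides = 0L) {
  aa <- .check_sequence(sequence)
  if (n_disulfides < 0 || n_disulfides > sum(aa == "C") %/% 2L)
    stop("invalid n_disulfides for this sequence", call. = FALSE)
  counts <- colSums(.RESIDUE_FORMULA[aa, , drop = FALSE])
  counts["H"] <- counts["H"] + 2L          # terminal water
  counts["O"] <- counts["O"] + 1L
  if (isTRUE(amidated)) {
    counts["O"] <- counts["O"] - 1L
    counts["N"] <- counts["N"] + 1L
    counts["H"] <- counts["H"] + 1L
  }
  counts["H"] <- counts["H"] - 2L * n_disulfides
  storage.mode(counts) <- "integer"
  counts
}

#' Neutral mass from an elemental composition
#'
#' @param composition Named integer vector of atom counts (subset of
#'   H, C, N, O, S), as returned by [elemental_composition()].
#' @return Neutral monoisotopic mass in Da.
#' @export
mass_from_composition <- function(composition) {
  el <- names(composition)
  unknown <- setdiff(el, names(.ELEMENT_MASS))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  sum(.ELEMENT_MASS[el] * as.numeric(composition))
}
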