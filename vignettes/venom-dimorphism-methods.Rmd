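---
title: "Methods: calling sex-specific venom peptides from proteo-transcriptomic evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling sex-specific venom peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomdimorph)
```

## The problem

Some scorpions, among them *Euscorpius italicus*, remodel their venom after
the male adult molt: MALDI-TOF fingerprints of male venom lack several
prominent ion signals seen in females and juveniles and show additional
male-specific ones. Identifying the peptides behind those signals requires
connecting three evidence layers that are individually inconclusive:

1. **precursor sequences** from a venom-gland transcriptome, with
   signal-peptide annotations, which determine the *possible* mature peptides;
2. **replicate MALDI-TOF peak lists** from venom of males, females and
   juveniles, which show which masses are *actually, reproducibly* present in
   which group;
3. **expression levels** (TPM) in male telson, female telson and a
   venom-gland-free negative control, which say whether the gene itself is
   sex-biased and gland-associated.

`venomdimorph` implements this chain as a tested pipeline with a
synthetic-data generator for end-to-end validation.

## Maturation grammar

A venom precursor is a signal peptide followed by the mature peptide and
optional propeptides. The processing routes covered, each a `strategy` in
`apply_processing()`:

* **FULL_CHAIN** — the entire chain after the signal peptide is the mature
  peptide (e.g. reference precursors EUTX-Ei1, EUTX-Ei3a, EUTX-Ei5).
* **FULL_CHAIN_GLY_AMIDE** — the chain's C-terminal Gly is consumed by
  peptidylglycine α-amidation, leaving an amidated peptide one residue shorter
  (EUTX-Ei3b, EUTX-Ei4).
* **C_TERM_BASIC_CLEAVE** — proprotein convertases cleave at a run of 1–3
  basic residues (K/R); the mature peptide is the prefix before the run and
  never retains any residue of it (EUTX-Ei2a at a tribasic RRK, EUTX-Ei2b at
  KKK, PI-Ei1a at a monobasic R). A Gly immediately preceding the run is an
  amidation signal.
* **N_TERM_REGION** — the mature peptide sits between the signal peptide and
  the first processing site; candidates are enumerated at every mono- and
  dibasic site (AMP-Ei1, AMP-Ei2a/b). Trailing basic residues left on the
  mature side are trimmed (carboxypeptidase step, `trim_basic_residues`,
  at most `max_basic_trim = 1` residue) *before* Gly consumption, mirroring
  the enzymatic order (convertase → carboxypeptidase → amidating enzyme).
* **N_TERM_QUADRUPLET** — a four-residue motif ending in R marks an N-terminal
  cleavage; the mature peptide runs from just after the R to the chain end
  (NVC-Ei1).

Three design decisions deserve justification:

* *Site enumeration instead of "first site".* For AMP-Ei2a the supported
  product ends at a dibasic KR although an earlier monobasic K exists inside
  the mature sequence (…IWNGIK…). Single-site rules are therefore ambiguous on
  real precursors; `N_TERM_REGION` and `C_TERM_BASIC_CLEAVE` emit one
  candidate per site and `AUTO` collapses duplicates. Downstream mass matching
  selects the candidate the spectra support. The invariant the test suite
  enforces is that the true product is always *among* the candidates.
* *The quadruplet rule.* The motif is defined here operationally: an R whose
  left neighbour is not basic, preceded by a spacer of at least three residues
  after the signal peptide. Cleavage is immediately after the R, and
  downstream residues belong to the mature peptide *even when basic* — the
  NVC-Ei1 mature peptide itself starts with K, so folding the R into a maximal
  K/R run would make the rule unsatisfiable on the very case it exists for.
* *Disulfide counts.* All cysteines are assumed paired:
  `n_disulfides = floor(#C / 2)`. This matches both reference peptides with
  stated bridge counts (three cystines in EUTX-Ei4, two in NVC-Ei1) and is the
  parsimonious default when connectivity is unknown. Pairing topology is out
  of scope; only the count affects mass.

Allelic variants are written `[X/Y]` at a single position and expanded by
`expand_alleles()` before processing; runs of more than three basic residues
are outside the grammar and reported as a tribasic site at the run's
C-terminal three residues, with a warning.

## Mass model

`mh_plus(sequence, amidated, n_disulfides)` returns

$$[M+H]^+ = \sum_i m_i + m_{H_2O} + m_{H^+} + a\,\Delta_{amide} + s\,\Delta_{SS}$$

with monoisotopic residue masses $m_i$, $\Delta_{amide} = -0.984016$ Da
(−OH replaced by −NH$_2$) and $\Delta_{SS} = -2.015650$ Da per bridge (two
hydrogens lost). Residue masses are derived internally from exact monoisotopic
element masses rather than a rounded table, so the residue-sum route and the
independent elemental-composition route (`elemental_composition()` +
`mass_from_composition()`) agree to below $10^{-6}$ Da — a property the test
suite checks on 1,000 random peptides. Only singly protonated monoisotopic
ions are modelled; average masses, other charge states and fragment ions are
out of scope.

All 14 reference products (12 precursors, two of them biallelic) reproduce
their published predicted masses within 0.05 Da. The residual +0.02–0.04 Da
offset is systematic and consistent with the original predictions having used
a slightly different amidation convention (≈ −1.008 rather than −0.984 Da);
the acceptance tolerance of 0.1 Da absorbs it.

## Spectral evidence

Replicate fingerprints are reduced to group-level **consensus signals** by
greedy single-linkage clustering in ascending m/z (`consensus_signals()`):
a signal joins the current cluster while its gap to the previous signal is at
most `cluster_tolerance_da` (default 0.15 Da). This is deterministic,
order-independent after sorting, and adequate for sparse fingerprints; density
methods would add tuning without benefit at ~10–60 peaks per spectrum. A
cluster is *reproducible* when supported by at least
`min_occurrence_fraction` (default 0.5) of the group's spectra — each spectrum
counts once, and empty spectra stay in the denominator (pass `n_spectra`).
The occurrence threshold is interpreted per group; requiring 50% of *all*
spectra would conflate group sizes with reproducibility.

Predicted masses are then matched against consensus centroids at
`mass_tolerance_da` (default 0.2 Da, boundary inclusive, nearest centroid per
group). Both defaults reflect externally calibrated reflector MALDI-TOF
accuracy at m/z 3,000–10,000 and are configuration knobs, not claims about
any instrument. Intensities never affect presence calls.

## Evidence filters and the specificity call

PSM records are retained only with $-10\lg P > 30$, coverage $> 7\%$ and a
predicted signal peptide — all strict inequalities, so boundary records are
rejected. Precursors with identical mature chains collapse to the
highest-scoring record. Homology hits classify a precursor by keyword of the
best accepted hit (E-value $< 10^{-5}$; hits from the toxin-focused database
are reported at E $< 0.1$ but classify only below $10^{-5}$); no accepted hit
means `novel`.

The expression contrast calls `male_up` when
$\mathrm{TPM}_m > f \cdot \mathrm{TPM}_f$ (default fold $f = 2$), `female_up`
symmetrically, else `flat`; `gland_enriched` requires both telson values to
exceed the negative control. The fold threshold is deliberately conservative:
every reference precursor exceeds 2-fold, so the default reproduces the
reference calls while remaining visible and adjustable. The final call is the
strict conjunction

* `up_in_males` = present in male fingerprints, absent in female *and*
  juvenile ones, *and* `male_up`;
* `down_in_males` = the mirror image;
* anything else `unspecific`.

Juveniles contribute MALDI evidence only — no juvenile transcriptome exists
in the emulated design, so expression never refers to them. When MALDI and
expression disagree the verdict is `unspecific`; a disagreement is evidence
of a quantitative rather than qualitative difference, and the pipeline only
claims qualitative specificity.

## Synthetic data: what it emulates, and what not

`simulate_study()` mirrors the emulated study design: 2 male, 4 female and 4
juvenile specimens, two fingerprints each (20 spectra); one transcriptome per
sex plus negative control; a PSM export per precursor. Defaults, chosen once
as field-plausible values: detection probability 0.9 for a peptide present in
a group, 0.02 elsewhere (up/down-regulation is quantitative, trace detection
happens); m/z jitter SD 0.05 Da; 5 spurious peaks per spectrum uniform over
m/z 800–10,000; expression log-normal around 500 TPM with dispersion 0.5 on
the natural-log scale and a 50-fold boost in the favoured sex (reference
TPM values span ~5 to ~30,000 with fold ratios from ~4 to ~140); negative
control at 2% of base. Planted [M+H]+ values are kept pairwise separated by
more than 5 Da so presence is identifiable — without this, mass collisions
make the noise-free limit unrecoverable by *any* presence-based method, which
would test the generator, not the pipeline.

The generator builds precursors *from* the grammar, so it cannot detect
processing routes the grammar lacks; background residues are uniform, not
venom-like; intensities, isotope envelopes and chromatography are not
modelled. Passing tests therefore demonstrate internal consistency and
statistical behaviour (binomial retention of planted signals, recovery
precision/recall), not performance on raw instrument data.

## Problem sizes and numerical choices

The test suite runs the mass-oracle property at 1,000 random peptides, the
binomial-retention law at 2,000 simulated replicate sets (8 spectra each),
and end-to-end recovery at 60 precursors for two seeds — sizes at which the
Monte-Carlo error of every checked quantity is well below its acceptance
margin. Ties in matching resolve to the nearest centroid; duplicate
candidates collapse keeping the first derivation in enumeration order
(FULL_CHAIN first, then site-based N- to C-terminal); degenerate inputs
(empty peak lists, empty tables, inapplicable strategies) return empty
results, never errors, except where the input violates a format contract.
All generators take explicit integer seeds and are byte-reproducible.

## Known limitations

* Signal peptides are annotations, never predictions; the pipeline is blind
  to precursors whose boundary annotation is wrong.
* The quadruplet rule is an operational reconstruction; other N-terminal
  motifs would need new strategies.
* Expression contrast has no replicates and hence no inferential statistics;
  the fold threshold is descriptive, which is why MALDI evidence is primary.
* EUTX-Ei3a's internal basic residues are treated as unprocessed
  (FULL_CHAIN), following the explicit description of its maturation; if the
  internal sites were real, its predicted mass would change.
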