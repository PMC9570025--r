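# venomdimorph

Identification of sex-specific venom peptides in scorpions from combined
proteo-transcriptomic evidence.

Male *Euscorpius italicus* remodel their venom after the adult molt — a
plausible adaptation to the "sexual sting" these scorpions perform during
mating. The remodelling shows up as presence/absence differences between
MALDI-TOF mass fingerprints of male venom and those of females and juveniles.
`venomdimorph` implements the analysis chain that turns such fingerprints,
together with venom-gland transcriptome annotations and expression levels,
into per-precursor *up-in-males* / *down-in-males* calls:

1. **Maturation** — a processing grammar derives candidate mature peptides
   from precursor sequences: signal-peptide removal, cleavage at mono-, di-
   and tribasic K/R sites, an N-terminal quadruplet motif, C-terminal Gly
   consumption by amidation, basic-residue trimming, allelic expansion.
2. **Mass prediction** — monoisotopic [M+H]⁺ for every candidate:

   [M+H]⁺ = Σᵢ mᵢ + m(H₂O) + m(H⁺) + a·Δ(amide) + s·Δ(S–S),

   with Δ(amide) = −0.984016 Da and Δ(S–S) = −2.015650 Da per bridge
   (all cysteines assumed paired, s = ⌊#C/2⌋).
3. **Spectral evidence** — replicate peak lists are clustered per group
   (greedy single-linkage, 0.15 Da) into consensus signals kept only when
   reproducible (present in ≥ 50% of the group's spectra); predicted masses
   are matched at 0.2 Da.
4. **Filters and call** — PSM records pass only with −10lgP > 30, coverage
   > 7% and a signal peptide (strict); expression must be > 2-fold sex-biased;
   the final call is the strict conjunction of the MALDI presence pattern and
   the expression direction.

A curated reference set of the twelve dimorphic *E. italicus* precursors
(sequences, signal boundaries, PTM flags, TPM triplets, regulation calls) is
packaged, and a synthetic-data generator plants full ground truth for
end-to-end validation.

## Worked example

Derive the mature peptide of the most prominent male-specific toxin precursor
and predict its mass:

```r
library(venomdimorph)

pre <- euscorpius_precursors()
ei4 <- pre[pre$id == "EUTX-Ei4", ]
mature_candidates(ei4)[, c("sequence", "amidated", "n_disulfides", "predicted_mh")]
#> # A tibble: 1 × 4
#>   sequence                                    amidated n_disulfides predicted_mh
#>   <chr>                                       <lgl>           <int>        <dbl>
#> 1 EKEGYPLDATRNIYQCYDLGENDYCEKKCKEFGGHGYCYGFA… TRUE                3        6684.
```

The 56-residue amidated peptide with three disulfide bridges has a predicted
[M+H]⁺ of 6683.97 Da — the mass of the dominant male-specific MALDI ion
signal. Running the whole reference analysis:

```sh
Rscript analysis/01_predict_masses.R    # masses vs published values
Rscript analysis/02_reference_calls.R   # specificity calls
Rscript analysis/03_simulate_study.R    # synthetic cohort with planted truth
Rscript analysis/04_end_to_end_recovery.R
```

prints, among other things:

```
14 mature products derived; max |delta| vs published mass: 0.046 Da
calls: 3 up_in_males, 9 down_in_males, 0 unspecific
up_in_males: EUTX-Ei4, PI-Ei1a, EUTX-Ei5
```

i.e. every reference mature peptide reproduces its published predicted mass
within 0.05 Da, and the evidence integration calls exactly the three
male-up-regulated precursors (a sodium-channel-toxin-like peptide, a
protease-inhibitor-like peptide and a second toxin-like peptide) and nine
down-regulated ones. The synthetic end-to-end run recovers all planted
specificity labels at precision and recall 1.0 for the default seed. Tables
land under `results/`.

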