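#!/usr/bin/env Rscript
# Step 2: specificity calls for the reference set.
#
# Combines the MALDI-derived presence patterns of the twelve reference
# precursors with their TPM triplets (male telson / female telson / negative
# control) at a 2-fold expression threshold. Finding: exactly 3 precursors are
# called up_in_males (EUTX-Ei4, PI-Ei1a, EUTX-Ei5) and 9 down_in_males.

suppressPackageStartupMessages(library(venomdimorph))
dir.create("results", showWarnings = FALSE)

pres <- euscorpius_presence()
expr <- euscorpius_expression()
expr <- expr[match(pres$precursor_id, expr$id), ]

contrast <- expression_contrast(expr$tpm_male_telson, expr$tpm_female_telson,
                                expr$tpm_negative_control, min_fold = 2)
calls <- call_specificity(pres$present_male, pres$present_female,
                          pres$present_juvenile, contrast$direction)

ann <- euscorpius_precursors()
tab <- data.frame(
  id = pres$precursor_id,
  class = ann$class_label[match(pres$precursor_id, ann$id)],
  present_male = pres$present_male,
  present_female = pres$present_female,
  tpm_male = expr$tpm_male_telson,
  tpm_female = expr$tpm_female_telson,
  tpm_negative_control = expr$tpm_negative_control,
  direction = contrast$direction,
  gland_enriched = contrast$gland_enriched,
  call = calls
)
write.table(tab, "results/reference_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("calls: %d up_in_males, %d down_in_males, %d unspecific\n",
            sum(calls == "up_in_males"), sum(calls == "down_in_males"),
            sum(calls == "unspecific")))
cat("up_in_males:", paste(tab$id[tab$call == "up_in_males"], collapse = ", "), "\n")
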