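#!/usr/bin/env Rscript
# Step 3: generate a synthetic study with planted ground truth.
#
# Emulates the study design (2 adult males, 4 adult females, 4 juveniles, two
# venom fingerprints each) for 60 synthetic precursors and writes the full
# input bundle — FASTA + annotations, peak lists, expression, PSM evidence —
# plus the planted truth, under results/simulated_study/.

suppressPackageStartupMessages(library(venomdimorph))
seed <- 7L
out <- "results/simulated_study"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

s <- simulate_study(n = 60, seed = seed, allelic_fraction = 0.1)

write_precursor_fasta(s$precursors,
                      file.path(out, "precursors.fasta"),
                      file.path(out, "annotations.tsv"))
write_peaklists(s$peaklists, file.path(out, "peaklists.tsv"))
write.table(s$expression, file.path(out, "expression.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(s$psms, file.path(out, "psms.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(s$truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_run_config(run_config(random_seed = seed), file.path(out, "config.yaml"))

cat(sprintf("simulated %d precursors (%d planted products), %d spectra, seed %d\n",
            nrow(s$precursors), nrow(s$truth),
            length(unique(paste(s$peaklists$specimen_id,
                                s$peaklists$replicate_id))), seed))
print(table(s$truth$true_label[!duplicated(s$truth$id)]))
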