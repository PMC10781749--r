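#!/usr/bin/env Rscript
# emPAI stoichiometry of the TssNQOPR membrane complex from the
# simulated replicated peptide counts, plus the small assay metrics on
# worked examples.

library(t6sscan)

sim_dir <- "results/simulated"
out <- "results/stoichiometry"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

counts <- read.delim(file.path(sim_dir, "peptide_counts.tsv"))
truth <- read.delim(file.path(sim_dir, "peptide_counts_truth.tsv"))

res <- pooled_stoichiometry(counts, pool = "mean")
res <- res[order(-res$relative_integer, res$protein), ]
write_tsv(res, file.path(out, "stoichiometry.tsv"))

message("relative stoichiometry from mean emPAI over 100 replicates:")
print(res, row.names = FALSE)
cmp <- merge(res, truth, by = "protein")
message(sprintf("recovered integers equal the true copies for %d/%d
proteins", sum(cmp$relative_integer == cmp$true_copies), nrow(cmp)))

# worked assay examples: a 10:1 donor:recipient mix and an ELISA plate
ci <- competitive_index(donor_initial = 1e7, recipient_initial = 1e6,
                        donor_final = 5e8, recipient_final = 5e5)
message(sprintf("competitive index for the worked example: %.1f", ci))
hcp <- normalized_hcp_signal(od450 = c(0.52, 0.48, 0.55),
                             od600 = c(0.81, 0.79, 0.83),
                             blank_od450 = 0.08)
message("normalized Hcp signals: ",
        paste(sprintf("%.3f", hcp), collapse = ", "))
write_tsv(data.frame(metric = c("competitive_index",
                                paste0("hcp_signal_", 1:3)),
                     value = c(ci, hcp)),
          file.path(out, "assay_metrics.tsv"))
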