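#!/usr/bin/env Rscript
# Crosslink-to-structure validation: filter the simulated crosslink
# identifications (ld >= 25, deltaS < 0.95), map them on the Calpha
# chain, classify at the 35 A threshold and summarize violations.

library(t6sscan)

sim_dir <- "results/simulated"
out <- "results/xl"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

links <- read_crosslinks(file.path(sim_dir, "crosslinks.tsv"))
chain <- read_structure_ca(file.path(sim_dir, "sim_chain.pdb"),
                           protein = "SIM")
truth <- read.delim(file.path(sim_dir, "crosslinks_truth.tsv"))

kept <- filter_crosslinks(links)
counts <- attr(kept, "counts")
message(sprintf("filter: %d kept, %d dropped, %d deduplicated",
                counts["kept"], counts["dropped"],
                counts["deduplicated"]))

classified <- classify_links(kept, list(SIM = chain))
write_tsv(classified, file.path(out, "classified_links.tsv"))

s <- violation_summary(classified, long_range_sep = 20)
message(sprintf(
  "%d unique high-confidence crosslinks; %d violated (%.1f%%); %d
satisfied links span >= 20 residues", s$n_mapped, s$n_violated,
  s$violated_pct, s$n_long_range_satisfied))
print(s$per_protein)

# verdicts must agree with the planted labels
key <- function(d) paste(pmin(d$residue_a, d$residue_b),
                         pmax(d$residue_a, d$residue_b))
planted <- truth[!truth$decoy, ]
agree <- classified$verdict[match(key(planted), key(classified))] ==
  planted$planted_verdict
message(sprintf("verdicts agree with planted labels for %d/%d links",
                sum(agree), length(agree)))

jsonlite::write_json(
  list(n_mapped = s$n_mapped, n_violated = s$n_violated,
       violated_pct = s$violated_pct,
       n_long_range_satisfied = s$n_long_range_satisfied),
  file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA)
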