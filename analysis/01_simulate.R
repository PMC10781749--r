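#!/usr/bin/env Rscript
# Generate the synthetic study inputs with ground truth: annotated
# genomes carrying T6SS-iii loci in three architectures, a Calpha chain
# with a crosslink set of known composition, and replicated peptide
# counts from known complex stoichiometry. Downstream drivers
# (02-05) consume the files written here.

library(t6sscan)

seed <- 20260919
out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

model <- t6ss_iii_model()
write_system_model(model, file.path(out, "t6ss_iii_model.yaml"))

# -- genomes: 20 contiguous, 20 split into 4 loci, 20 with tssO/Q/R
#    degraded, all with a light spurious-hit background ----------------
arch <- list(
  contiguous = simulate_genomes(model, n_genomes = 20,
    genes_per_replicon = 300, architecture = "contiguous",
    spurious_hit_rate = 0.002, seed = seed),
  split4 = simulate_genomes(model, n_genomes = 20,
    genes_per_replicon = 300, architecture = "split", k = 4,
    spurious_hit_rate = 0.002, seed = seed + 1),
  degraded = simulate_genomes(model, n_genomes = 20,
    genes_per_replicon = 300, architecture = "degraded",
    deleted_components = c("TssO", "TssQ", "TssR"),
    spurious_hit_rate = 0.002, seed = seed + 2))

genes <- do.call(rbind, lapply(names(arch), function(a) {
  g <- arch[[a]]$genes
  g$genome_id <- paste0(a, "_", g$genome_id)
  g$replicon_id <- paste0(a, "_", g$replicon_id)
  g$locus_tag <- paste0(a, "_", g$locus_tag)
  g
}))
truth <- do.call(rbind, lapply(names(arch), function(a) {
  t <- arch[[a]]$truth
  t$genome_id <- paste0(a, "_", t$genome_id)
  t
}))
write_gene_table(genes, file.path(out, "genomes.tsv"))
write_tsv(truth, file.path(out, "genomes_truth.tsv"))
message("wrote ", length(unique(genes$genome_id)), " genomes (",
        nrow(genes), " genes) in three architectures")

# -- structure + crosslinks: 64 planted links, 8 violated, plus 20
#    decoys that must fall to the confidence filter -------------------
xl <- simulate_structure_and_links(n_residues = 300, n_links = 64,
                                   target_violation_fraction = 0.125,
                                   n_decoys = 20, seed = seed)
write_structure_pdb(xl$structure, file.path(out, "sim_chain.pdb"))
write_tsv(xl$links, file.path(out, "crosslinks.tsv"))
write_tsv(xl$truth, file.path(out, "crosslinks_truth.tsv"))
message("wrote a ", xl$structure$length, "-residue chain with ",
        nrow(xl$links), " candidate crosslinks (8 planted violations)")

# -- peptide counts from the TssNQOPR copy numbers --------------------
copies <- c(TssN = 5, TssQ = 5, TssP = 4, TssR = 2, TssO = 1)
pc <- simulate_peptide_counts(copies, n_observable = 40,
                              noise = "binomial", n_replicates = 100,
                              seed = seed)
write_tsv(pc$counts, file.path(out, "peptide_counts.tsv"))
write_tsv(pc$truth, file.path(out, "peptide_counts_truth.tsv"))
message("wrote 100 replicates of peptide counts for the TssNQOPR complex")

write_run_manifest(file.path(out, "manifest.json"),
                   inputs = list(),
                   parameters = list(n_genomes = 60, n_links = 64,
                                     violation_fraction = 0.125,
                                     n_observable = 40,
                                     n_replicates = 100),
                   seed = seed)
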