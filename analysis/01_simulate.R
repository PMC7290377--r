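#!/usr/bin/env Rscript
# Step 1: generate the synthetic study data — clone sets for each satellite
# family, the four satellite-TE archetype mini-chromosomes, and the
# 12-chromosome genome with planted central / multisite / dispersed
# placements — and write them (with planted truth) under results/sim/.

suppressPackageStartupMessages(library(satkit))
seed <- 20260930L
dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)

## clone sets: simulated multimeric PCR clones for the 146-bp family
clones <- scenario_clone_ladder(seed = seed, copies = 8, max_multimer = 3)
write_fasta(clones$clones, "results/sim/clones_sat1.fasta")
cat("clone set (146-bp family): lengths",
    paste(nchar(clones$clones), collapse = ", "), "bp\n")

## monomer sets per family for HOR and diversity analysis
presets <- sat_family_presets()
for (fam in names(presets)) {
  sc <- scenario_hor_monomers(fam, seed = seed, n_monomers = 12)
  write_fasta(sc$monomers, sprintf("results/sim/monomers_%s.fasta", fam))
}
cat("monomer sets written for:", paste(names(presets), collapse = ", "), "\n")

## TE archetypes
arcs <- scenario_te_archetypes(seed = seed)
arc_seqs <- vapply(arcs, `[[`, character(1), "chrom")
names(arc_seqs) <- sprintf("archetype_%s", names(arcs))
write_fasta(arc_seqs, "results/sim/te_archetypes.fasta")
truth <- do.call(rbind, lapply(names(arcs), function(id) {
  t <- arcs[[id]]$truth
  t$archetype <- id
  t
}))
write.table(truth, "results/sim/te_archetypes_truth.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("TE archetypes:", length(arcs), "mini-chromosomes\n")

## distribution genome (6 chromosomes instead of the full 12 so the whole
## workflow reruns in a couple of minutes; chromosome length keeps the
## scenario default so run-gap geometry is unchanged)
g <- scenario_distribution_genome(seed = seed, n_chrom = 6L)
write_fasta(g$chroms, "results/sim/genome.fasta")
write_fasta(unlist(g$families), "results/sim/family_consensus.fasta")
write.table(g$truth, "results/sim/genome_truth.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("genome:", length(g$chroms), "chromosomes x",
    format(nchar(g$chroms[1]), big.mark = ","), "bp\n")
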