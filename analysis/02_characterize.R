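#!/usr/bin/env Rscript
# Step 2: characterize each family from its simulated monomers — periodicity,
# consensus, HOR decomposition, identity matrices, NJ dendrograms and the
# species-specificity score. Reads results/sim/, writes results/characterize/.

suppressPackageStartupMessages(library(satkit))
dir.create("results/characterize", recursive = TRUE, showWarnings = FALSE)

presets <- sat_family_presets()
summary_rows <- list()
for (fam in names(presets)) {
  mons <- read_fasta(sprintf("results/sim/monomers_%s.fasta", fam))

  # periodicity check on the concatenated (array-like) monomers
  concat <- paste(mons, collapse = "")
  pe <- estimate_period(concat, min_period = 10,
                        max_period = min(300, nchar(concat) %/% 2))

  cons <- build_consensus(mons)
  write_fasta(setNames(cons$residues, paste0(fam, "_consensus")),
              sprintf("results/characterize/consensus_%s.fasta", fam))
  write.table(data.frame(column = seq_along(cons$column_support),
                         support = cons$column_support),
              sprintf("results/characterize/consensus_%s_support.tsv", fam),
              sep = "\t", row.names = FALSE, quote = FALSE)

  hm <- decompose_monomer(mons)
  report_to_json(
    family_report(list(name = fam, consensus = cons$residues), hor = hm,
                  monomer_stats = list(n = length(mons),
                                       length_range = range(nchar(mons)))),
    sprintf("results/characterize/report_%s.json", fam))

  I <- identity_matrix(mons)
  write.table(round(I, 4),
              sprintf("results/characterize/identity_%s.tsv", fam),
              sep = "\t", quote = FALSE)

  nj <- nj_tree(1 - I)
  writeLines(nj$newick, sprintf("results/characterize/nj_%s.nwk", fam))

  summary_rows[[fam]] <- data.frame(
    family = fam, n_monomers = length(mons),
    consensus_bp = nchar(cons$residues),
    period = if (is.null(pe)) NA_integer_ else pe$period,
    n_subunits = nrow(hm$subunits),
    hor_lag = hm$lag,
    hor_support = round(hm$support, 3),
    mean_identity = round(mean(I[upper.tri(I)]), 3))
  cat(sprintf("%s: period %s, %d subunit(s), mean pairwise identity %.2f\n",
              fam, ifelse(is.null(pe), "-", pe$period), nrow(hm$subunits),
              mean(I[upper.tri(I)])))
}
tab <- do.call(rbind, summary_rows)
write.table(tab, "results/characterize/family_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

## species specificity: two-species monomer sets from distinct vs shared
## templates (the planted analogue of species-specific satellite variants)
seed <- 20260930L
tplA <- make_family_template(presets$sat6, seed = seed)$monomer
tplB <- apply_mutations(tplA, mutation_model(0.3, seed = seed + 1L))
mons2 <- c(
  setNames(vapply(1:6, function(i) apply_mutations(
    tplA, mutation_model(0.05, seed = seed + 10L + i)), character(1)),
    paste0("spA_", 1:6)),
  setNames(vapply(1:6, function(i) apply_mutations(
    tplB, mutation_model(0.05, seed = seed + 20L + i)), character(1)),
    paste0("spB_", 1:6)))
D <- distance_matrix(mons2)
sp <- setNames(rep(c("speciesA", "speciesB"), each = 6), names(mons2))
ss <- species_specificity(D, sp)
cat(sprintf("species specificity: %.1f points -> %s\n", ss$score,
            ifelse(ss$verdict, "species-specific", "not species-specific")))
writeLines(jsonlite::toJSON(list(
  score_points = ss$score, within = ss$within, between = ss$between,
  monophyletic = ss$monophyletic_species, verdict = ss$verdict),
  auto_unbox = TRUE, pretty = TRUE),
  "results/characterize/species_specificity.json")
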