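#!/usr/bin/env Rscript
# Generate the study-scale synthetic datasets used by the downstream
# analysis scripts: a three-lineage codominant genotype dataset (75
# individuals, 40 loci, 4/6/8 planted diagnostic loci, 5% missing data, two
# sites per lineage) plus a two-lineage dataset with planted F1 hybrids,
# and a cytochrome-b-like alignment evolved under Jukes-Cantor along a
# three-clade tree with variable sequence lengths.

suppressMessages(library(cladelim))
dir.create("results/synthetic", showWarnings = FALSE, recursive = TRUE)
seed <- 20240915L

## three-lineage genotype scenario (the default study conditions)
sim <- simulate_genotypes(default_scenario(), seed = seed)
write_genotypes(sim$dataset, "results/synthetic/genotypes.csv")
write.csv(sim$truth, "results/synthetic/truth.csv", row.names = FALSE)
write_genepop(sim$dataset, "results/synthetic/genotypes.gen",
              title = "three-lineage synthetic scenario")
cat(sprintf("genotypes: %d individuals x %d loci, %.1f%% missing\n",
            n_individuals(sim$dataset), length(sim$dataset$loci),
            100 * mean(is.na(sim$dataset$a1))))

## two lineages with two planted F1 hybrids (for the admixture detector)
cfg_adm <- scenario_config(c("A", "B"), n_per = 20,
                           diag_counts = c("A|B" = 6L), shared_loci = 12,
                           missing_rate = 0.05, admixed = c("A|B" = 2L))
sim_adm <- simulate_genotypes(cfg_adm, seed = seed + 1L)
write_genotypes(sim_adm$dataset, "results/synthetic/genotypes_admixed.csv")
write.csv(sim_adm$truth, "results/synthetic/truth_admixed.csv", row.names = FALSE)

## mtDNA-like alignment: three clades (two shallow, one deep split), with
## terminal masking emulating partial amplicons (roughly 400-1100 bp of an
## 1145-column alignment)
tree <- ape::read.tree(text = paste0(
  "((s1:0.005,s2:0.006,s3:0.004):0.06,",
  "((n1:0.004,n2:0.005,n3:0.006):0.012,",
  "(w1:0.005,w2:0.004,w3:0.006):0.012):0.05);"))
clades <- c(s1 = "South", s2 = "South", s3 = "South",
            n1 = "North", n2 = "North", n3 = "North",
            w1 = "West", w2 = "West", w3 = "West")
seqs <- simulate_sequences(tree, length = 1145, seed = seed + 2L,
                           clades = clades,
                           seq_lengths = c(1145, 1145, 400, 1145, 900, 1145,
                                           1145, 400, 1145))
write_alignment(seqs$alignment, "results/synthetic/cytb.fasta")
write.csv(data.frame(id = names(clades), clade = unname(clades)),
          "results/synthetic/clades.csv", row.names = FALSE)
cat(sprintf("alignment: %d sequences x %d columns\n",
            nrow(seqs$alignment), ncol(seqs$alignment)))
cat("wrote results/synthetic/\n")
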