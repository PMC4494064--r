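#!/usr/bin/env Rscript
# Stage 1: build the synthetic study cohort with recorded ground truth.
#
# A 12-genome dated species tree (root 800 Ma) stands in for the sequenced
# genomes; pectin-specific gene families evolve along it under a
# duplication-loss birth-death process; a relaxed-clock phylogram carries
# the sequence-divergence signal used for dating; ortholog cluster tables
# and homology hit tables are planted with known defects for the filter
# stages. Everything is written under results/sim/.

suppressPackageStartupMessages(library(paleozyme))
dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)
SEED <- 20260923L

sp <- sim_species_tree(12, 800, seed = SEED)
writeLines(write_newick(sp), "results/sim/species_tree.nwk")
write_tsv(data.frame(node = seq_along(sp$age), age_ma = sp$age),
          "results/sim/species_ages.tsv")

fams <- c("GH28", "GH53", "PL1", "PL3", "CE8")
truths <- list()
for (i in seq_along(fams)) {
  fam <- sim_gene_family(sp, dup_rate = 0.002, loss_rate = 0.002,
                         seed = SEED + i, family = fams[i])
  truths[[fams[i]]] <- fam
  if (!inherits(fam$tree, "single_tip"))
    writeLines(write_newick(fam$tree),
               sprintf("results/sim/genetree_%s.nwk", fams[i]))
  write_tsv(fam$branches, sprintf("results/sim/truth_%s.tsv", fams[i]))
}
jsonlite::write_json(
  lapply(truths, function(f)
    list(leaf_counts = as.list(f$leaf_counts),
         n_resampled = f$n_resampled)),
  "results/sim/family_truth.json", auto_unbox = TRUE, digits = NA)

ph <- sim_relaxed_phylogram(sp, mean_rate = 5e-4, sigma = 0.2,
                            seed = SEED + 20L)
writeLines(write_newick(ph$tree), "results/sim/phylogram.nwk")

clu <- sim_cluster_table(12, 300, paralog_fraction = 0.25,
                         dropout_fraction = 0.2,
                         rbh_violation_fraction = 0.25, seed = SEED + 30L)
write_tsv(clu$clusters, "results/sim/clusters.tsv")
write_tsv(clu$scores, "results/sim/scores.tsv")
write_tsv(clu$truth, "results/sim/cluster_truth.tsv")

counts <- do.call(cbind, lapply(truths, function(f)
  f$leaf_counts[sp$tip.label]))
hits <- sim_hit_table(fams, sp$tip.label, counts, decoy_rate = 4,
                      seed = SEED + 40L)
write_tsv(hits, "results/sim/hits.tsv")
write_tsv(as.data.frame(attr(hits, "truth")), "results/sim/hit_truth.tsv")

cat("simulated", length(fams), "gene families on a 12-genome tree;",
    nrow(clu$truth), "clusters (", sum(clu$truth$keep), "clean );",
    nrow(hits), "homology hits\n")
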