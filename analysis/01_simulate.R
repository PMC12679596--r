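#!/usr/bin/env Rscript
# Stage 1 — simulate the study: a duplicated genome with planted ACR
# divergence, pseudobulk expression with planted pair patterns, and
# planted cell-type-specificity trajectories for the 4-gene sets.
# Writes everything as standard formats under results/01_simulate/.

library(dupdiverge)

out <- "results/01_simulate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
set.seed(20240901)

cfg <- synth_config(n_pairs = 150L, n_quads = 40L, sub_rate = 0.05)

sim <- gen_duplicated_genome(cfg)
expr <- gen_expression(cfg, sim$pairs)
traj <- gen_trajectories(cfg, sim$quads, acrs = sim$acrs)

Biostrings::writeXStringSet(sim$genome, file.path(out, "genome.fa"))
write_gff3(sim$genes, file.path(out, "genes.gff3"))
write_bed(sim$acrs, file.path(out, "acrs.bed"))
data.table::fwrite(sim$pairs, file.path(out, "pairs.tsv"), sep = "\t")
data.table::fwrite(sim$quads, file.path(out, "quads.tsv"), sep = "\t")
ape::write.tree(sim$trees, file.path(out, "trees.nwk"))
for (tis in names(expr$counts)) {
  write_counts(expr$counts[[tis]]$counts,
               file.path(out, sprintf("counts_%s.tsv", tis)))
}
write_counts(traj$counts$counts, file.path(out, "counts_trajectory.tsv"))
if (!is.null(traj$ctacrs)) write_bed(traj$ctacrs, file.path(out, "ctacrs.bed"))
data.table::fwrite(expr$truth, file.path(out, "truth_patterns.tsv"), sep = "\t")
data.table::fwrite(sim$truth$pair_acrs, file.path(out, "truth_pair_acrs.tsv"), sep = "\t")
data.table::fwrite(sim$truth$quad_acrs, file.path(out, "truth_quad_acrs.tsv"), sep = "\t")
data.table::fwrite(traj$truth, file.path(out, "truth_trajectories.tsv"), sep = "\t")

cat(sprintf(
  "simulated %d duplicate pairs and %d 4-gene sets on %d chromosomes\n",
  nrow(sim$pairs), nrow(sim$quads), length(sim$genome)))
cat(sprintf("%d ACRs placed (substitution rate %.2f, loss %.2f, de novo %.2f)\n",
            nrow(sim$acrs), cfg$sub_rate, cfg$p_acr_loss, cfg$p_de_novo))
cat(sprintf("pseudobulk counts for %d tissues x %d cell types x %d replicates\n",
            length(expr$counts), cfg$cell_types, cfg$replicates))
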