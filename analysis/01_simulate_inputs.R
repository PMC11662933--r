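#!/usr/bin/env Rscript
# Generate every pipeline input with planted structure: toy annotation +
# sequence, the SNORD116/SNORD115 registry, NB counts for the
# 2-background x 3-genotype design, DE result tables, and window scores
# with 2.5-fold group-III targeting planted on the shared DEGs.
# All later steps read only the files written here.

suppressMessages(library(snordnet))

seed <- 1L
dir.create("results/inputs", recursive = TRUE, showWarnings = FALSE)

toy <- build_toy_annotation(800, n_chroms = 3, seed = seed)
write_gtf(toy$annotation, "results/inputs/annotation.gtf")
write_fasta(toy$sequences, "results/inputs/genome.fa")

reg <- build_snorna_registry(seed = seed + 1L)
write.table(reg, "results/inputs/snorna_registry.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

sim <- simulate_counts(toy$annotation, n_reps = 6, seed = seed + 2L)
write.table(data.frame(gene_id = rownames(sim$counts), sim$counts,
                       check.names = FALSE),
            "results/inputs/counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(sim$samples, "results/inputs/samples.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$truth, "results/inputs/truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

de <- simulate_de_tables(sim$truth, power = 0.9, seed = seed + 3L)
for (m in names(de)) for (d in names(de[[m]])) {
  write_de_table(de[[m]][[d]],
                 sprintf("results/inputs/de_%s_%s.tsv", m, d))
}

cat(sprintf("inputs: %d genes, %d samples, %d planted shared DEGs\n",
            nrow(sim$truth), ncol(sim$counts),
            sum(sim$truth$status %in% c("shared_up", "shared_down"))))
cat("window scores are generated in 04 after the shared list is known\n")
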