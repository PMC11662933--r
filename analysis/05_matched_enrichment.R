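#!/usr/bin/env Rscript
# Covariate-matched control enrichment: 100 lists matched to the shared
# genes on exonic length, GC and neuron expression (all three Wilcoxon
# p > 0.05), then the mean/median/sum of group-III targeting events on the
# shared list versus the distribution over control lists.

suppressMessages(library(snordnet))
dir.create("results/matched", recursive = TRUE, showWarnings = FALSE)

ann <- read_gtf("results/inputs/annotation.gtf")
annf <- filter_transcripts(ann)
seqs <- read_fasta("results/inputs/genome.fa")
counts <- as.matrix(read.delim("results/inputs/counts.tsv",
                               row.names = 1, check.names = FALSE))
samples <- read.delim("results/inputs/samples.tsv")
shared <- read.delim("results/deg/shared_genes.tsv")$gene_id
events <- read.delim("results/interactions/events.tsv")
reg <- read.delim("results/inputs/snorna_registry.tsv")

neuron <- samples$sample_id[samples$genotype != "WT"]
cov <- compute_covariates(ann$genes$gene_id, annf, seqs, counts,
                          expr_samples = neuron)
write.table(cov, "results/matched/covariates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

ml <- sample_matched_lists(shared, cov, k = 100, alpha = 0.05, seed = 31L)
cat(sprintf("matched lists: %d accepted after %d draws\n",
            length(ml$lists), ml$n_tried))

g3 <- reg$copy_id[reg$cluster == "SNORD116" & !is.na(reg$group) &
                    reg$group == "III"]
ev3 <- events[events$sno_id %in% g3, ]
per_gene <- table(ev3$target_gene_id)
per_gene <- setNames(as.integer(per_gene), names(per_gene))

enr <- enrichment_vs_controls(shared, ml, per_gene)
print(enr)
write.table(enr, "results/matched/enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(list = rep(seq_along(ml$lists),
                                  each = length(shared)),
                       gene_id = unlist(ml$lists)),
            "results/matched/control_lists.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
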