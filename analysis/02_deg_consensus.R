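#!/usr/bin/env Rscript
# Low-count filter, padj < 0.05 significance filter, three-design consensus
# per deletion model, and the cross-model shared gene list.

suppressMessages(library(snordnet))
dir.create("results/deg", recursive = TRUE, showWarnings = FALSE)

counts <- as.matrix(read.delim("results/inputs/counts.tsv",
                               row.names = 1, check.names = FALSE))
kept <- filter_low_counts(counts, min_mean = 1)
cat(sprintf("low-count filter: %d of %d genes kept\n", length(kept),
            nrow(counts)))

models <- c("smDEL", "lgDEL")
designs <- c("bg_shared", "interaction", "condition_only")
consensus <- lapply(models, function(m) {
  sets <- lapply(designs, function(d) {
    tab <- read_de_table(sprintf("results/inputs/de_%s_%s.tsv", m, d))
    significant_degs(tab[tab$gene_id %in% kept, ],
                     contrast_id = paste(m, d, sep = ":"))
  })
  cons <- consensus_across_designs(sets, contrast_id = m)
  cat(sprintf("%s: %s -> consensus %d up / %d down\n", m,
              paste(vapply(sets, function(s)
                length(s$up) + length(s$down), numeric(1)), collapse = "/"),
              length(cons$up), length(cons$down)))
  cons
})
names(consensus) <- models

shared <- shared_across_models(consensus$smDEL, consensus$lgDEL,
                               mode = "concordant")
cat(sprintf("shared across models (concordant): %d genes\n",
            length(shared)))

truth <- read.delim("results/inputs/truth.tsv")
planted <- truth$gene_id[truth$status %in% c("shared_up", "shared_down")]
cat(sprintf("recall of planted shared DEGs: %.3f (expected ~0.9^6 = %.3f)\n",
            length(intersect(shared, planted)) / length(planted), 0.9^6))

for (m in models) {
  write.table(data.frame(gene_id = c(consensus[[m]]$up,
                                     consensus[[m]]$down),
                         direction = rep(c("up", "down"),
                                         c(length(consensus[[m]]$up),
                                           length(consensus[[m]]$down)))),
              sprintf("results/deg/consensus_%s.tsv", m), sep = "\t",
              quote = FALSE, row.names = FALSE)
}
write.table(data.frame(gene_id = shared), "results/deg/shared_genes.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
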