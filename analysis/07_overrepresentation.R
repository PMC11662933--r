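#!/usr/bin/env Rscript
# Hypergeometric over-representation of the shared gene list against
# user-style gene-set collections (GMT), with BH adjustment and
# foldEnrichment = GeneRatio / BgRatio. Collections here are synthetic: the
# planted shared set plus random sets, written as a GMT and read back.

suppressMessages(library(snordnet))
dir.create("results/enrichment", recursive = TRUE, showWarnings = FALSE)

truth <- read.delim("results/inputs/truth.tsv")
shared <- read.delim("results/deg/shared_genes.tsv")$gene_id
universe <- truth$gene_id

set.seed(41L)
collections <- c(
  list(planted_shared = truth$gene_id[truth$status %in%
                                        c("shared_up", "shared_down")]),
  setNames(lapply(1:10, function(i) sample(universe, sample(30:150, 1))),
           paste0("random_set_", 1:10)))
gmt <- "results/enrichment/collections.gmt"
writeLines(vapply(names(collections), function(nm)
  paste(c(nm, "synthetic", collections[[nm]]), collapse = "\t"),
  character(1)), gmt)

res <- gene_set_enrichment(shared, read_gmt(gmt), universe)
print(head(res, 5))
write.table(res, "results/enrichment/overrepresentation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("top set: %s (fold %.1f, padj %.2g)\n", res$set_id[1],
            res$fold_enrichment[1], res$padj[1]))
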