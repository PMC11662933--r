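#!/usr/bin/env Rscript
# Directional overlap permutation test between the two deletion models'
# consensus DEG sets: shuffle each side's tested universe, designate the
# observed numbers of up/down genes, count coincidences, repeat 10 000
# times; enrichment = observed / median(null).

suppressMessages(library(snordnet))
dir.create("results/permutation", recursive = TRUE, showWarnings = FALSE)

counts <- as.matrix(read.delim("results/inputs/counts.tsv",
                               row.names = 1, check.names = FALSE))
kept <- filter_low_counts(counts, min_mean = 1)

load_set <- function(m) {
  tab <- read.delim(sprintf("results/deg/consensus_%s.tsv", m))
  degset(m, kept, up = tab$gene_id[tab$direction == "up"],
         down = tab$gene_id[tab$direction == "down"])
}
a <- load_set("smDEL"); b <- load_set("lgDEL")

perm <- overlap_permutation_test(a, b, n_perm = 10000, seed = 11L)
print(perm)

write.table(data.frame(
  observed = perm$observed, null_median = perm$null_median,
  fold = perm$fold, p_value = perm$p_value,
  p_is_floor = perm$p_is_floor, n_perm = perm$n_perm),
  "results/permutation/overlap_test.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
h <- table(perm$null_values)
write.table(data.frame(overlap = as.integer(names(h)),
                       count = as.integer(h)),
            "results/permutation/null_histogram.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
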