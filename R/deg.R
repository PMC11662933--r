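#' Directional significant-gene set
#'
#' Holds the up- and down-regulated significant genes of one contrast
#' together with the full tested-gene universe.
#'
#' @param contrast_id label for the contrast.
#' @param universe character vector of all tested gene ids.
#' @param up,down character vectors of significant gene ids (disjoint,
#'   subsets of the universe).
#' @return object of class `degset`.
#' @export
degset <- function(contrast_id, universe, up = character(0),
                   down = character(0)) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  universe <- unique(as.character(universe))
  assert_that(length(intersect(up, down)) == 0,
              "up and down sets must be disjoint")
  assert_that(all(c(up, down) %in% universe),
              "up/down genes must lie in the universe")
  structure(list(contrast_id = contrast_id, universe = universe,
                 up = up, down = down), class = "degset")
}

#' @export
print.degset <- function(x, ...) {
  cat(sprintf("degset '%s': %d up, %d down, universe %d\n", x$contrast_id,
              length(x$up), length(x$down), length(x$universe)))
  invisible(x)
}

#' Low-count gene filter
#'
#' Keeps genes whose mean count across all samples is at least `min_mean`.
#' The two thresholds used in practice are 1 (one count per sample, for
#' neuron-vs-neuron comparisons) and 39 (for comparisons against ESCs with 39
#' samples).
#'
#' @param counts gene x sample count matrix with rownames.
#' @param min_mean minimum row mean (>= 0).
#' @return character vector of kept gene ids.
#' @export
filter_low_counts <- function(counts, min_mean = 1) {
  assert_that(min_mean >= 0, "min_mean must be >= 0")
  assert_that(nrow(counts) > 0 && ncol(counts) > 0, "empty count matrix")
  rownames(counts)[rowMeans(counts) >= min_mean]
}

#' Extract significant DEGs from a DE result table
#'
#' Genes with padj below the cutoff enter the up set when log2FoldChange > 0
#' and the down set when log2FoldChange < 0 (strict inequalities; a zero fold
#' change is excluded from both). Rows with NA padj are never significant.
#' The universe is every row of the table.
#'
#' @param table data.frame with gene_id, log2FoldChange, padj.
#' @param padj_lt adjusted-p cutoff (default 0.05).
#' @param contrast_id label for the resulting set.
#' @return a [degset].
#' @export
significant_degs <- function(table, padj_lt = 0.05,
                             contrast_id = "contrast") {
  assert_that(!anyDuplicated(table$gene_id), "duplicate gene_id in DE table")
  sig <- !is.na(table$padj) & table$padj < padj_lt
  degset(contrast_id, table$gene_id,
         up = table$gene_id[sig & table$log2FoldChange > 0],
         down = table$gene_id[sig & table$log2FoldChange < 0])
}

#' Three-design consensus for one deletion model
#'
#' A gene enters the consensus only if significant in all three designs;
#' with `require_sign_consistency` its direction must also agree across the
#' three (the consensus direction). With the flag off, genes significant in
#' all three designs by identifier alone are kept, and the direction of the
#' first design is carried. The consensus universe is the intersection of the
#' three universes.
#'
#' @param degsets list of exactly 3 [degset] objects.
#' @param require_sign_consistency default TRUE.
#' @param contrast_id label for the consensus set.
#' @return a [degset].
#' @export
consensus_across_designs <- function(degsets, require_sign_consistency = TRUE,
                                     contrast_id = "consensus") {
  assert_that(length(degsets) == 3, "exactly 3 design DEG sets are required")
  universe <- Reduce(intersect, lapply(degsets, `[[`, "universe"))
  if (require_sign_consistency) {
    up <- Reduce(intersect, lapply(degsets, `[[`, "up"))
    down <- Reduce(intersect, lapply(degsets, `[[`, "down"))
  } else {
    sig <- lapply(degsets, function(d) union(d$up, d$down))
    all_sig <- Reduce(intersect, sig)
    up <- intersect(all_sig, degsets[[1]]$up)
    down <- intersect(all_sig, degsets[[1]]$down)
  }
  degset(contrast_id, universe, up = intersect(up, universe),
         down = intersect(down, universe))
}

#' Genes shared between two deletion models
#'
#' @param a,b [degset] objects (e.g. per-model consensus sets).
#' @param mode "any_direction" intersects the pooled significant sets;
#'   "concordant" requires the same direction in both models.
#' @return character vector of shared gene ids.
#' @export
shared_across_models <- function(a, b,
                                 mode = c("any_direction", "concordant")) {
  mode <- match.arg(mode)
  if (mode == "any_direction") {
    intersect(union(a$up, a$down), union(b$up, b$down))
  } else {
    union(intersect(a$up, b$up), intersect(a$down, b$down))
  }
}

#' Pseudocount log2 fold change between two sample groups
#'
#' log2((mean_a + pc) / (mean_b + pc)) per gene; the pseudocount keeps the
#' ratio finite for genes with zero counts.
#'
#' @param counts gene x sample count matrix.
#' @param group_a,group_b column names or indices of the two groups.
#' @param pseudocount added to both group means (> 0, default 1).
#' @return named numeric vector of per-gene log2 fold changes.
#' @export
log2fc_pseudocount <- function(counts, group_a, group_b, pseudocount = 1) {
  assert_that(pseudocount > 0, "pseudocount must be > 0")
  assert_that(length(group_a) > 0 && length(group_b) > 0,
              "both groups must be non-empty")
  ma <- rowMeans(counts[, group_a, drop = FALSE])
  mb <- rowMeans(counts[, group_b, drop = FALSE])
  log2((ma + pseudocount) / (mb + pseudocount))
}
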