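#' Default window-score column map
#'
#' Maps on-disk TSV column names to the canonical internal names used by the
#' interaction filter. The on-disk dialect is configurable because window
#' prediction tools do not share a single header convention. Start columns are
#' 1-based in this dialect.
#'
#' @return Named character vector: internal name -> on-disk column name.
#' @export
default_window_column_map <- function() {
  c(sno_id = "sno_id",
    sno_start = "sno_window_start",
    target_gene_id = "target_id",
    target_chrom = "target_chrom",
    target_start = "target_window_start",
    strand = "strand",
    score = "score",
    window_length = "window_length")
}

#' Read a per-window interaction score table
#'
#' Reads a TSV of per-window snoRNA-target scores, validates scores lie in
#' [0, 1] and that strands are "+" or "-" (targeting is stranded, so "." is
#' rejected).
#'
#' @param path TSV path with a header row.
#' @param column_map named character vector mapping internal names to on-disk
#'   columns; see [default_window_column_map()].
#' @return data.frame with columns sno_id, sno_start, target_gene_id,
#'   target_chrom, target_start, strand, score, window_length.
#' @export
read_window_scores <- function(path, column_map = default_window_column_map()) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = column_map[["strand"]]))
  missing <- setdiff(unname(column_map), names(dt))
  assert_that(length(missing) == 0,
              paste0("window-score table is missing columns: ",
                     paste(missing, collapse = ", ")))
  out <- as.data.frame(dt)[, unname(column_map), drop = FALSE]
  names(out) <- names(column_map)
  if (nrow(out) == 0) return(out)
  assert_that(is.numeric(out$score) && !anyNA(out$score),
              "non-numeric or missing score values")
  bad <- which(out$score < 0 | out$score > 1)
  assert_that(length(bad) == 0,
              sprintf("score outside [0,1] at row %d (%.3f)", bad[1],
                      out$score[bad[1]]))
  badstrand <- which(!out$strand %in% c("+", "-"))
  assert_that(length(badstrand) == 0,
              sprintf("invalid strand at row %d: '%s' (targeting is stranded)",
                      badstrand[1], out$strand[badstrand[1]]))
  assert_that(all(out$window_length > 0), "window_length must be positive")
  out
}

#' Write a per-window interaction score table
#'
#' @param windows data.frame as returned by [read_window_scores()].
#' @param path output TSV path.
#' @param column_map see [default_window_column_map()].
#' @export
write_window_scores <- function(windows, path,
                                column_map = default_window_column_map()) {
  out <- windows[, names(column_map), drop = FALSE]
  names(out) <- unname(column_map)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write intervals as a BED6 file
#'
#' Writes 0-based half-open BED (conversion handled by \pkg{rtracklayer}),
#' with scores clamped to integer [0, 1000] and rows sorted by
#' (chrom, start, end, name) so output is byte-deterministic.
#'
#' @param gr a [GenomicRanges::GRanges]; metadata columns `name` and `score`
#'   are used when present.
#' @param path output path.
#' @export
write_bed <- function(gr, path) {
  if (length(gr) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  md <- S4Vectors::mcols(gr)
  nm <- if (!is.null(md$name)) as.character(md$name) else
    paste0("iv", seq_along(gr))
  sc <- if (!is.null(md$score)) md$score else rep(0, length(gr))
  sc <- pmin(pmax(round(as.numeric(sc)), 0L), 1000L)
  out <- GenomicRanges::granges(gr)
  S4Vectors::mcols(out)$name <- nm
  S4Vectors::mcols(out)$score <- as.integer(sc)
  ord <- order(as.character(GenomicRanges::seqnames(out)),
               GenomicRanges::start(out), GenomicRanges::end(out),
               S4Vectors::mcols(out)$name, method = "radix")
  rtracklayer::export(out[ord], path, format = "bed")
  invisible(path)
}

#' Read a BED6 file as GRanges
#'
#' @param path BED path.
#' @return [GenomicRanges::GRanges] with `name` and `score` columns.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) return(GenomicRanges::GRanges())
  rtracklayer::import(path, format = "bed")
}

#' Read a differential-expression result table
#'
#' Tolerant of DESeq2-style headers: requires a gene identifier column (first
#' column or one named gene_id/gene/ensembl_id) plus baseMean,
#' log2FoldChange, pvalue and padj.
#'
#' @param path TSV path.
#' @return data.frame with columns gene_id, baseMean, log2FoldChange,
#'   pvalue, padj.
#' @export
read_de_table <- function(path) {
  dt <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  idcol <- intersect(c("gene_id", "gene", "ensembl_id"), names(dt))
  if (length(idcol) == 0) {
    names(dt)[1] <- "gene_id"
  } else {
    names(dt)[names(dt) == idcol[1]] <- "gene_id"
  }
  need <- c("baseMean", "log2FoldChange", "pvalue", "padj")
  missing <- setdiff(need, names(dt))
  assert_that(length(missing) == 0,
              paste0("DE table missing columns: ",
                     paste(missing, collapse = ", ")))
  dt[, c("gene_id", need)]
}

#' Write a DE result table
#' @param tab data.frame as from [read_de_table()].
#' @param path output TSV path.
#' @export
write_de_table <- function(tab, path) {
  data.table::fwrite(tab, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read gene-set collections in GMT format
#'
#' @param path GMT path (one set per line: name, description, genes...).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
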