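#' Gene annotation container
#'
#' A `snord_annotation` bundles gene, transcript and exon/CDS structure parsed
#' from a GENCODE-dialect GTF. Coordinates follow the Bioconductor convention
#' (1-based, closed) throughout; conversion to and from on-disk conventions
#' (GTF 1-based closed, BED 0-based half-open) happens at read/write time via
#' \pkg{rtracklayer}.
#'
#' @param genes data.frame with columns gene_id, symbol, biotype, chrom,
#'   start, end, strand.
#' @param transcripts data.frame with columns transcript_id, gene_id, chrom,
#'   strand, start, end, support_level (integer or NA), basic (logical).
#' @param exons,cds [GenomicRanges::GRanges] with metadata columns
#'   transcript_id and gene_id.
#' @return An object of class `snord_annotation`.
#' @export
snord_annotation <- function(genes, transcripts, exons, cds) {
  assert_that(!anyDuplicated(genes$gene_id),
              "duplicate gene_id in annotation")
  assert_that(!anyDuplicated(transcripts$transcript_id),
              "duplicate transcript_id in annotation")
  orphan <- setdiff(transcripts$gene_id, genes$gene_id)
  assert_that(length(orphan) == 0,
              paste0("transcript without gene parent: ",
                     paste(head(orphan, 3), collapse = ", ")))
  rownames(genes) <- NULL
  rownames(transcripts) <- NULL
  structure(list(genes = genes, transcripts = transcripts,
                 exons = exons, cds = cds),
            class = "snord_annotation")
}

#' @export
print.snord_annotation <- function(x, ...) {
  cat(sprintf("snord_annotation: %d genes, %d transcripts, %d exons, %d CDS\n",
              nrow(x$genes), nrow(x$transcripts),
              length(x$exons), length(x$cds)))
  invisible(x)
}

parse_tsl <- function(x) {
  # GENCODE writes transcript_support_level as "1".."5" or "NA"; anything
  # non-numeric (including absent) maps to NA and therefore fails a 1-3 filter.
  suppressWarnings(as.integer(x))
}

#' Read a GENCODE-dialect GTF into an annotation object
#'
#' Parses gene/transcript/exon/CDS records, the `transcript_support_level`
#' attribute (absent or "NA" becomes NA) and the `tag "basic"` attribute.
#'
#' @param path path to a GTF file (9 tab-separated columns, 1-based closed
#'   coordinates).
#' @return A [snord_annotation].
#' @export
read_gtf <- function(path) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    bad <- which(body)[which(nf != 9L)[1]]
    stop(sprintf("malformed GTF line %d in %s: expected 9 fields, got %d",
                 bad, path, nf[nf != 9L][1]), call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  typ <- as.character(md$type)

  gene_rows <- gr[typ == "gene"]
  tx_rows <- gr[typ == "transcript"]
  genes <- data.frame(
    gene_id = S4Vectors::mcols(gene_rows)$gene_id,
    symbol = S4Vectors::mcols(gene_rows)$gene_name %||%
      S4Vectors::mcols(gene_rows)$gene_id,
    biotype = S4Vectors::mcols(gene_rows)$gene_type %||% NA_character_,
    chrom = as.character(GenomicRanges::seqnames(gene_rows)),
    start = GenomicRanges::start(gene_rows),
    end = GenomicRanges::end(gene_rows),
    strand = as.character(GenomicRanges::strand(gene_rows)),
    stringsAsFactors = FALSE
  )
  tmd <- S4Vectors::mcols(tx_rows)
  tags <- tmd$tag
  basic <- if (is.null(tags)) rep(FALSE, length(tx_rows)) else {
    if (is.list(tags) || inherits(tags, "List")) {
      vapply(tags, function(v) "basic" %in% v, logical(1))
    } else tags == "basic" & !is.na(tags)
  }
  tsl <- if (is.null(tmd$transcript_support_level)) {
    rep(NA_integer_, length(tx_rows))
  } else parse_tsl(tmd$transcript_support_level)
  transcripts <- data.frame(
    transcript_id = tmd$transcript_id,
    gene_id = tmd$gene_id,
    chrom = as.character(GenomicRanges::seqnames(tx_rows)),
    strand = as.character(GenomicRanges::strand(tx_rows)),
    start = GenomicRanges::start(tx_rows),
    end = GenomicRanges::end(tx_rows),
    support_level = tsl,
    basic = basic,
    stringsAsFactors = FALSE
  )

  keep_feature <- function(what) {
    sub <- gr[typ == what]
    out <- GenomicRanges::granges(sub)
    S4Vectors::mcols(out)$transcript_id <- S4Vectors::mcols(sub)$transcript_id
    S4Vectors::mcols(out)$gene_id <- S4Vectors::mcols(sub)$gene_id
    out
  }
  snord_annotation(genes, transcripts, keep_feature("exon"),
                   keep_feature("CDS"))
}

#' Write an annotation object as GTF
#'
#' Emits gene, transcript, exon and CDS records with `gene_id`,
#' `transcript_id`, `transcript_support_level` and `tag "basic"` attributes in
#' a fixed order, so output is byte-deterministic for identical inputs.
#'
#' @param ann a [snord_annotation].
#' @param path output path.
#' @export
write_gtf <- function(ann, path) {
  attr_str <- function(gene_id, transcript_id = NULL, tsl = NULL,
                       basic = NULL, gene_name = NULL, gene_type = NULL) {
    s <- sprintf('gene_id "%s";', gene_id)
    if (!is.null(gene_name)) {
      s <- paste0(s, sprintf(' gene_name "%s";', gene_name))
    }
    if (!is.null(gene_type) && !is.na(gene_type)) {
      s <- paste0(s, sprintf(' gene_type "%s";', gene_type))
    }
    if (!is.null(transcript_id)) {
      s <- paste0(s, sprintf(' transcript_id "%s";', transcript_id))
    }
    if (!is.null(tsl)) {
      s <- paste0(s, sprintf(' transcript_support_level "%s";',
                             ifelse(is.na(tsl), "NA", tsl)))
    }
    if (!is.null(basic)) {
      s <- paste0(s, ifelse(basic, ' tag "basic";', ""))
    }
    s
  }
  g <- ann$genes
  tx <- ann$transcripts
  line <- function(chrom, feat, start, end, strand, attrs) {
    paste(chrom, "snordnet", feat, start, end, ".", strand, ".", attrs,
          sep = "\t")
  }
  out <- character(0)
  for (i in seq_len(nrow(g))) {
    out <- c(out, line(g$chrom[i], "gene", g$start[i], g$end[i], g$strand[i],
                       attr_str(g$gene_id[i], gene_name = g$symbol[i],
                                gene_type = g$biotype[i])))
    txi <- tx[tx$gene_id == g$gene_id[i], , drop = FALSE]
    for (j in seq_len(nrow(txi))) {
      tid <- txi$transcript_id[j]
      out <- c(out, line(txi$chrom[j], "transcript", txi$start[j], txi$end[j],
                         txi$strand[j],
                         attr_str(g$gene_id[i], tid, txi$support_level[j],
                                  txi$basic[j])))
      for (feat in c("exon", "CDS")) {
        fr <- ann[[if (feat == "exon") "exons" else "cds"]]
        fr <- fr[S4Vectors::mcols(fr)$transcript_id == tid]
        fr <- GenomicRanges::sort(fr)
        if (length(fr)) {
          out <- c(out, line(as.character(GenomicRanges::seqnames(fr)), feat,
                             GenomicRanges::start(fr), GenomicRanges::end(fr),
                             as.character(GenomicRanges::strand(fr)),
                             attr_str(g$gene_id[i], tid, txi$support_level[j],
                                      txi$basic[j])))
        }
      }
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Filter transcripts by support level and basic tag
#'
#' Keeps transcripts with support level in 1..`tsl_max` carrying the "basic"
#' tag (when required). NA or non-numeric support levels always fail the
#' filter. Genes left with zero retained transcripts are recorded in the
#' `flagged_genes` attribute of the result.
#'
#' @param ann a [snord_annotation].
#' @param tsl_max highest transcript support level retained (default 3).
#' @param require_basic require the "basic" tag (default TRUE).
#' @return A filtered [snord_annotation] with attribute `flagged_genes`.
#' @export
filter_transcripts <- function(ann, tsl_max = 3, require_basic = TRUE) {
  tx <- ann$transcripts
  keep <- !is.na(tx$support_level) & tx$support_level >= 1 &
    tx$support_level <= tsl_max
  if (require_basic) keep <- keep & tx$basic
  kept <- tx[keep, , drop = FALSE]
  flagged <- setdiff(ann$genes$gene_id, kept$gene_id)
  sel <- function(gr) gr[S4Vectors::mcols(gr)$transcript_id %in%
                           kept$transcript_id]
  out <- snord_annotation(ann$genes, kept, sel(ann$exons), sel(ann$cds))
  attr(out, "flagged_genes") <- flagged
  out
}

#' Per-transcript exon/CDS/UTR structure
#'
#' Derives the 5' and 3' UTR intervals of each transcript as exon space minus
#' CDS space, oriented by strand (on "-" the 5' UTR occupies the highest
#' coordinates). Non-coding transcripts have empty CDS and UTRs. Intervals
#' are returned as plain start/end data.frames (1-based closed, sorted,
#' disjoint) because these structures feed tight per-transcript loops.
#'
#' @param ann a [snord_annotation] (typically after [filter_transcripts()]).
#' @return Named list (by transcript_id) of lists with data.frame elements
#'   `exons`, `cds`, `utr5`, `utr3` (columns start, end), plus `chrom`,
#'   `strand`, `gene_id` and `coding`.
#' @export
transcript_regions <- function(ann) {
  ex_df <- data.frame(start = GenomicRanges::start(ann$exons),
                      end = GenomicRanges::end(ann$exons))
  ex_idx <- split(seq_len(length(ann$exons)),
                  S4Vectors::mcols(ann$exons)$transcript_id)
  cds_df <- data.frame(start = GenomicRanges::start(ann$cds),
                       end = GenomicRanges::end(ann$cds))
  cds_idx <- split(seq_len(length(ann$cds)),
                   S4Vectors::mcols(ann$cds)$transcript_id)
  out <- vector("list", nrow(ann$transcripts))
  names(out) <- ann$transcripts$transcript_id
  for (i in seq_len(nrow(ann$transcripts))) {
    tid <- ann$transcripts$transcript_id[i]
    strand <- ann$transcripts$strand[i]
    exons <- iv_merge(ex_df[ex_idx[[tid]], , drop = FALSE])
    cds <- if (!is.null(cds_idx[[tid]])) {
      iv_merge(cds_df[cds_idx[[tid]], , drop = FALSE])
    } else iv_df()
    if (nrow(cds)) {
      utr <- iv_setdiff(exons, cds)
      cs <- min(cds$start); ce <- max(cds$end)
      left <- utr[utr$end < cs, , drop = FALSE]
      right <- utr[utr$start > ce, , drop = FALSE]
      if (strand == "-") {
        utr5 <- right; utr3 <- left
      } else {
        utr5 <- left; utr3 <- right
      }
    } else {
      utr5 <- iv_df(); utr3 <- iv_df()
    }
    rownames(exons) <- rownames(cds) <- rownames(utr5) <- rownames(utr3) <-
      NULL
    out[[i]] <- list(transcript_id = tid,
                     gene_id = ann$transcripts$gene_id[i],
                     chrom = ann$transcripts$chrom[i],
                     strand = strand, coding = nrow(cds) > 0,
                     exons = exons, cds = cds, utr5 = utr5, utr3 = utr3)
  }
  out
}
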