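#' Generate a toy genome annotation with sequence
#'
#' Builds a small multi-chromosome annotation whose genes have 1-3
#' transcripts and 1-8 exons each, with per-transcript CDS/UTR partitions,
#' mixed transcript support levels (1-5 and NA) and basic tags, plus
#' per-chromosome sequence with a controlled per-gene GC fraction. The first
#' transcript of every gene is always TSL 1-3 with the basic tag so that
#' every gene survives the standard transcript filter.
#'
#' @param n_genes number of genes (>= 1).
#' @param n_chroms number of chromosomes to spread genes over.
#' @param gc_targets target GC fraction(s), recycled over genes; each must be
#'   in (0, 1). Realized per-gene GC is within about +/-0.05 for gene bodies
#'   of a few hundred bp or more.
#' @param coding_fraction fraction of genes given a CDS.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return list with elements `annotation` ([snord_annotation]) and
#'   `sequences` ([Biostrings::DNAStringSet] of chromosomes).
#' @export
build_toy_annotation <- function(n_genes, n_chroms = 2, gc_targets = 0.45,
                                 coding_fraction = 0.9, seed = NULL) {
  assert_that(n_genes >= 1, "n_genes must be >= 1")
  assert_that(all(gc_targets > 0 & gc_targets < 1),
              "infeasible GC target: must be in (0, 1)")
  with_seed(seed, {
    gc_targets <- rep_len(gc_targets, n_genes)
    chroms <- paste0("chr", rep_len(seq_len(n_chroms), n_genes))
    genes <- vector("list", n_genes); txs <- list()
    # exon/CDS rows accumulated as flat vectors; one GRanges built at the end
    fr <- list(chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), tid = character(0), gid = character(0),
               feat = character(0))
    add_feat <- function(fr, chrom, start, end, strand, tid, gid, feat) {
      n <- length(start)
      fr$chrom <- c(fr$chrom, rep(chrom, n))
      fr$start <- c(fr$start, start); fr$end <- c(fr$end, end)
      fr$strand <- c(fr$strand, rep(strand, n))
      fr$tid <- c(fr$tid, rep(tid, n)); fr$gid <- c(fr$gid, rep(gid, n))
      fr$feat <- c(fr$feat, rep(feat, n))
      fr
    }
    seq_pieces <- setNames(vector("list", n_chroms),
                           paste0("chr", seq_len(n_chroms)))
    cursor <- setNames(rep(1L, n_chroms), names(seq_pieces))
    rand_seq <- function(width, gc) {
      paste(sample(c("A", "C", "G", "T"), width, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
            collapse = "")
    }
    for (g in seq_len(n_genes)) {
      chrom <- chroms[g]
      gid <- sprintf("GENE%04d", g)
      strand <- sample(c("+", "-"), 1)
      coding <- runif(1) < coding_fraction
      n_ex <- sample(1:8, 1)
      ex_w <- sample(80:300, n_ex, replace = TRUE)
      in_w <- if (n_ex > 1) sample(60:400, n_ex - 1, replace = TRUE) else
        integer(0)
      gap <- sample(300:600, 1)
      gstart <- cursor[[chrom]] + gap
      starts <- as.integer(gstart + cumsum(c(0L, head(ex_w, -1) + in_w)))
      ends <- as.integer(starts + ex_w - 1L)
      gend <- ends[n_ex]
      # master CDS strictly inside the exon chain so UTRs are non-empty;
      # offsets capped at a third of the terminal exon keeps cs < ce even
      # for single-exon genes (min exon width 80)
      cds_master <- NULL
      if (coding) {
        cs <- starts[1] + sample(15:floor(ex_w[1] / 3), 1)
        ce <- ends[n_ex] - sample(15:floor(ex_w[n_ex] / 3), 1)
        cds_master <- c(cs, ce)
      }
      n_tx <- sample(1:3, 1)
      for (t in seq_len(n_tx)) {
        tid <- sprintf("%s.T%d", gid, t)
        if (t == 1) {
          lo <- 1L; hi <- n_ex
          tsl <- sample(1:3, 1); basic <- TRUE
        } else {
          lo <- 1L
          hi <- if (n_ex > 2) sample(2:n_ex, 1) else n_ex
          tsl <- sample(c(1:5, NA), 1)
          basic <- runif(1) < 0.7
        }
        fr <- add_feat(fr, chrom, starts[lo:hi], ends[lo:hi], strand, tid,
                       gid, "exon")
        if (coding && ends[hi] > cds_master[1] + 60) {
          ce_t <- min(cds_master[2], ends[hi] - 20L)
          cs_i <- pmax(starts[lo:hi], cds_master[1])
          ce_i <- pmin(ends[lo:hi], ce_t)
          keep <- cs_i <= ce_i
          if (any(keep)) {
            fr <- add_feat(fr, chrom, cs_i[keep], ce_i[keep], strand, tid,
                           gid, "CDS")
          }
        }
        txs[[tid]] <- data.frame(transcript_id = tid, gene_id = gid,
                                 chrom = chrom, strand = strand,
                                 start = starts[lo], end = ends[hi],
                                 support_level = tsl, basic = basic,
                                 stringsAsFactors = FALSE)
      }
      genes[[g]] <- data.frame(gene_id = gid, symbol = gid,
                               biotype = if (coding) "protein_coding" else
                                 "lncRNA",
                               chrom = chrom, start = gstart, end = gend,
                               strand = strand, stringsAsFactors = FALSE)
      # sequence: intergenic gap at GC 0.45, gene body at its target GC
      seq_pieces[[chrom]] <- c(seq_pieces[[chrom]], rand_seq(gap, 0.45),
                               rand_seq(gend - gstart + 1L, gc_targets[g]))
      cursor[[chrom]] <- gend
    }
    seqs <- Biostrings::DNAStringSet(vapply(seq_pieces, function(p)
      paste(p, collapse = ""), character(1)))
    mk_gr <- function(feat) {
      sel <- fr$feat == feat
      gr <- GenomicRanges::GRanges(
        fr$chrom[sel], IRanges::IRanges(fr$start[sel], fr$end[sel]),
        strand = fr$strand[sel],
        seqinfo = GenomeInfoDb::Seqinfo(names(seq_pieces)))
      S4Vectors::mcols(gr)$transcript_id <- fr$tid[sel]
      S4Vectors::mcols(gr)$gene_id <- fr$gid[sel]
      gr
    }
    ann <- snord_annotation(do.call(rbind, genes), do.call(rbind, txs),
                            mk_gr("exon"), mk_gr("CDS"))
    list(annotation = ann, sequences = seqs)
  })
}

#' Build the SNORD116/SNORD115 snoRNA copy registry
#'
#' Thirty SNORD116 copies partitioned into the established sequence-similarity
#' groups (I: copies 1-9, II: copies 10-24, III: copies 25-30) plus 48
#' SNORD115 copies (no group). Copy lengths and C/D'/C'/D box coordinates are
#' synthetic placeholders at canonical relative positions (box order 5'->3' is
#' C < D' < C' < D); coordinates are 1-based closed on the snoRNA. The second
#' antisense element (ASE2) is the segment between the 3' end of the C' box
#' and the 5' end of the D box.
#'
#' @param seed integer seed for the per-copy length jitter.
#' @param length_range inclusive range of copy lengths (nt).
#' @return data.frame with one row per copy: copy_id, cluster, copy_index,
#'   group, length and box_{c,dprime,cprime,d}_{start,end} columns.
#' @export
build_snorna_registry <- function(seed = NULL, length_range = c(90, 100)) {
  with_seed(seed, {
    n116 <- 30; n115 <- 48
    idx <- c(seq_len(n116), seq_len(n115))
    cluster <- rep(c("SNORD116", "SNORD115"), c(n116, n115))
    copy_id <- paste0(cluster, "-", idx)
    group <- c(ifelse(seq_len(n116) <= 9, "I",
                      ifelse(seq_len(n116) <= 24, "II", "III")),
               rep(NA_character_, n115))
    len <- sample(length_range[1]:length_range[2], n116 + n115,
                  replace = TRUE)
    reg <- data.frame(
      copy_id = copy_id, cluster = cluster, copy_index = idx, group = group,
      length = len,
      box_c_start = 5L, box_c_end = 11L,
      box_dprime_start = 26L, box_dprime_end = 29L,
      box_cprime_start = 49L, box_cprime_end = 55L,
      box_d_start = len - 7L, box_d_end = len - 4L,
      stringsAsFactors = FALSE
    )
    stopifnot(all(reg$box_c_end < reg$box_dprime_start),
              all(reg$box_dprime_end < reg$box_cprime_start),
              all(reg$box_cprime_end < reg$box_d_start),
              all(reg$box_d_end <= reg$length))
    reg
  })
}

#' ASE2 interval of each snoRNA copy
#'
#' The second antisense element: positions strictly between the C' box and
#' the D box (1-based closed on the snoRNA).
#'
#' @param registry from [build_snorna_registry()].
#' @return data.frame copy_id, ase2_start, ase2_end.
#' @export
ase2_intervals <- function(registry) {
  data.frame(copy_id = registry$copy_id,
             ase2_start = registry$box_cprime_end + 1L,
             ase2_end = registry$box_d_start - 1L,
             stringsAsFactors = FALSE)
}

#' Write chromosome sequences as FASTA
#' @param sequences a [Biostrings::DNAStringSet].
#' @param path output path.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(sequences, path)
  invisible(path)
}

#' Read FASTA sequences
#' @param path FASTA path.
#' @return [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}
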