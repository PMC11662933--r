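# Independent brute-force oracles used across tests. These deliberately use
# naive per-element algorithms, not the package's code paths.

# maximal-run enumerator over a window table: chains qualifying windows by
# following (sno_start + step, target_start + dir * step) successors
brute_force_runs <- function(windows, t = 0.98, w = 3, step = 1) {
  q <- windows[windows$score >= t, , drop = FALSE]
  if (nrow(q) == 0) return(list())
  key <- function(g, s, tt) paste(g$sno_id, g$target_gene_id,
                                  g$target_chrom, g$strand, s, tt)
  have <- new.env()
  for (i in seq_len(nrow(q))) {
    assign(key(q[i, ], q$sno_start[i], q$target_start[i]), i, envir = have)
  }
  runs <- list()
  for (i in seq_len(nrow(q))) {
    row <- q[i, ]
    dir <- if (row$strand == "+") step else -step
    # run start: no predecessor present
    if (exists(key(row, row$sno_start - step, row$target_start - dir),
               envir = have)) next
    chain <- i
    s <- row$sno_start; tt <- row$target_start
    repeat {
      nk <- key(row, s + step, tt + dir)
      if (!exists(nk, envir = have)) break
      nxt <- get(nk, envir = have)
      chain <- c(chain, nxt)
      s <- s + step; tt <- tt + dir
    }
    if (length(chain) >= w) runs[[length(runs) + 1]] <- q[chain, ]
  }
  runs
}

# per-base feature labeler: returns a character label for every bp of every
# gene, by looping over positions and transcripts
brute_force_labels <- function(ann) {
  regs <- transcript_regions(ann)
  out <- list()
  for (gi in seq_len(nrow(ann$genes))) {
    g <- ann$genes[gi, ]
    gtx <- regs[vapply(regs, function(r) r$gene_id == g$gene_id,
                       logical(1))]
    if (length(gtx) == 0) next
    lab <- character(g$end - g$start + 1)
    for (p in g$start:g$end) {
      votes <- c("5'UTR" = 0, CDS = 0, "3'UTR" = 0, other = 0)
      in_exon <- FALSE; in_intron <- FALSE
      for (r in gtx) {
        inside <- function(df) nrow(df) > 0 &&
          any(p >= df$start & p <= df$end)
        if (inside(r$exons)) {
          in_exon <- TRUE
          if (!r$coding) votes["other"] <- votes["other"] + 1
          else if (inside(r$utr5)) votes["5'UTR"] <- votes["5'UTR"] + 1
          else if (inside(r$cds)) votes["CDS"] <- votes["CDS"] + 1
          else if (inside(r$utr3)) votes["3'UTR"] <- votes["3'UTR"] + 1
        } else if (p >= min(r$exons$start) && p <= max(r$exons$end)) {
          in_intron <- TRUE
        }
      }
      lab[p - g$start + 1] <- if (in_exon) {
        mx <- max(votes)
        # tie-break: CDS, then 5'UTR, then 3'UTR, then other
        names(votes)[votes == mx][order(match(
          names(votes)[votes == mx], c("CDS", "5'UTR", "3'UTR", "other")))][1]
      } else if (in_intron) "intron" else "none"
    }
    out[[g$gene_id]] <- lab
  }
  out
}

# enumerate every bp position covered by a start/end interval data.frame
df_bp <- function(df) {
  if (nrow(df) == 0) return(integer(0))
  unlist(Map(seq.int, df$start, df$end))
}

# exact hypergeometric upper tail by direct summation of choose() terms
brute_force_hyper_tail <- function(k, K, M, n) {
  kk <- max(k, 0):min(K, n)
  sum(choose(K, kk) * choose(M - K, n - kk)) / choose(M, n)
}

# reflect a GRanges / annotation through position L on every chromosome,
# flipping strand; used for strand-symmetry checks
mirror_granges <- function(gr, L) {
  GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(gr)),
    IRanges::IRanges(L - GenomicRanges::end(gr) + 1L,
                     L - GenomicRanges::start(gr) + 1L),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "+",
                    "-", "+"))
}

mirror_annotation <- function(ann, L) {
  flip_df <- function(df) {
    s <- L - df$end + 1L
    df$end <- L - df$start + 1L
    df$start <- s
    df$strand <- ifelse(df$strand == "+", "-", "+")
    df
  }
  mk <- function(gr) {
    out <- mirror_granges(gr, L)
    S4Vectors::mcols(out) <- S4Vectors::mcols(gr)
    out
  }
  snord_annotation(flip_df(ann$genes), flip_df(ann$transcripts),
                   mk(ann$exons), mk(ann$cds))
}

# tiny deterministic annotation with one fully-specified coding transcript,
# used for hand-computed positional examples
manual_annotation <- function(strand = "+", chrom_len = 3000) {
  # exon1 101-400 (5'UTR 101-200, CDS 201-400), intron 401-600,
  # exon2 601-900 (CDS 601-700, 3'UTR 701-900)   [+ strand labels]
  genes <- data.frame(gene_id = "G1", symbol = "G1",
                      biotype = "protein_coding", chrom = "chr1",
                      start = 101L, end = 900L, strand = strand,
                      stringsAsFactors = FALSE)
  tx <- data.frame(transcript_id = "G1.T1", gene_id = "G1", chrom = "chr1",
                   strand = strand, start = 101L, end = 900L,
                   support_level = 1L, basic = TRUE, stringsAsFactors = FALSE)
  mk <- function(s, e) {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e),
                                 strand = strand,
                                 seqinfo = GenomeInfoDb::Seqinfo("chr1",
                                                                 chrom_len))
    S4Vectors::mcols(gr)$transcript_id <- "G1.T1"
    S4Vectors::mcols(gr)$gene_id <- "G1"
    gr
  }
  snord_annotation(genes, tx, mk(c(101L, 601L), c(400L, 900L)),
                   mk(c(201L, 601L), c(400L, 700L)))
}
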