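#' snoRNA-side relative positions of binding events against the boxes
#'
#' The center of each binding event (midpoint of its snoRNA interval,
#' floored at .5) is divided by the copy length to give a relative position
#' in [0, 1]; per snoRNA group a histogram of these positions is returned
#' together with the group-mean relative intervals of the C, D', C' and D
#' boxes.
#'
#' @param interactions events from [merge_consecutive_windows()].
#' @param registry from [build_snorna_registry()].
#' @param bin_width histogram bin width in relative units (default 0.01).
#' @return named list (one element per group, e.g. "SNORD116-III",
#'   "SNORD115") of `sno_position_profile` objects: group, n, positions,
#'   histogram (bin_lo, bin_mid, bin_hi, count), boxes (box, rel_start,
#'   rel_end).
#' @export
sno_relative_positions <- function(interactions, registry, bin_width = 0.01) {
  ri <- match(interactions$sno_id, registry$copy_id)
  assert_that(!anyNA(ri), "interactions contain sno_ids not in the registry")
  grp_of <- function(reg) ifelse(is.na(reg$group), reg$cluster,
                                 paste0(reg$cluster, "-", reg$group))
  all_groups <- unique(grp_of(registry))
  center <- floor((interactions$sno_start + interactions$sno_end) / 2)
  rel <- center / registry$length[ri]
  grp <- grp_of(registry[ri, , drop = FALSE])
  breaks <- seq(0, 1, by = bin_width)
  out <- lapply(all_groups, function(g) {
    reg <- registry[grp_of(registry) == g, , drop = FALSE]
    pos <- rel[grp == g]
    cnt <- if (length(pos)) {
      tabulate(pmin(findInterval(pos, breaks, rightmost.closed = TRUE),
                    length(breaks) - 1), length(breaks) - 1)
    } else integer(length(breaks) - 1)
    boxes <- do.call(rbind, lapply(
      c(c = "c", dprime = "dprime", cprime = "cprime", d = "d"),
      function(b) data.frame(
        box = b,
        rel_start = mean((reg[[paste0("box_", b, "_start")]] - 1) /
                           reg$length),
        rel_end = mean(reg[[paste0("box_", b, "_end")]] / reg$length),
        stringsAsFactors = FALSE)))
    rownames(boxes) <- NULL
    structure(list(group = g, n = length(pos), positions = pos,
                   histogram = data.frame(bin_lo = head(breaks, -1),
                                          bin_mid = head(breaks, -1) +
                                            bin_width / 2,
                                          bin_hi = breaks[-1],
                                          count = cnt),
                   boxes = boxes),
              class = "sno_position_profile")
  })
  names(out) <- all_groups
  out
}

#' Build the labeled genomic feature space of a gene set
#'
#' Per gene, the exon space is the union of retained-transcript exons and
#' the intron space the union of per-transcript introns minus the exon space
#' (exonic precedence). Exonic bp are labeled 5'UTR, CDS, 3'UTR or other by
#' a per-bp vote across retained transcripts (non-coding transcripts vote
#' "other"); ties are resolved in favour of CDS, then 5'UTR, then 3'UTR.
#'
#' @param ann a filtered [snord_annotation]; genes with no retained
#'   transcripts are excluded with a warning.
#' @param gene_ids optional subset of genes (default: all).
#' @return object of class `feature_space`: GRanges elements exon, intron,
#'   utr5, cds, utr3, other, gene_spans; `bp` (data.frame of totals);
#'   `background` (a `feature_coverage_profile` with basis
#'   "background gene space").
#' @export
build_feature_space <- function(ann, gene_ids = NULL) {
  regions <- transcript_regions(ann)
  region_gene <- vapply(regions, `[[`, character(1), "gene_id")
  genes <- ann$genes
  if (!is.null(gene_ids)) {
    genes <- genes[genes$gene_id %in% gene_ids, , drop = FALSE]
  }
  covered <- unique(region_gene)
  skipped <- setdiff(genes$gene_id, covered)
  if (length(skipped)) {
    warning("excluded ", length(skipped),
            " gene(s) with no retained transcripts")
    genes <- genes[genes$gene_id %in% covered, , drop = FALSE]
  }
  acc <- list(exon = list(), intron = list(), utr5 = list(), cds = list(),
              utr3 = list(), other = list())
  si <- GenomeInfoDb::Seqinfo(sort(unique(genes$chrom)))
  spans <- GenomicRanges::GRanges(genes$chrom,
                                  IRanges::IRanges(genes$start, genes$end),
                                  strand = genes$strand, seqinfo = si)
  S4Vectors::mcols(spans)$gene_id <- genes$gene_id
  local_ir <- function(df, gstart) {
    IRanges::IRanges(df$start - gstart + 1L, df$end - gstart + 1L)
  }
  for (gi in seq_len(nrow(genes))) {
    gid <- genes$gene_id[gi]
    gstart <- genes$start[gi]
    w <- genes$end[gi] - gstart + 1L
    gtx <- regions[region_gene == gid]
    cov_of <- function(field, noncoding_exons = FALSE) {
      irs <- lapply(gtx, function(r) {
        src <- if (noncoding_exons) {
          if (r$coding) iv_df() else r$exons
        } else r[[field]]
        local_ir(src, gstart)
      })
      IRanges::coverage(do.call(c, unname(irs)), width = w)
    }
    c5 <- cov_of("utr5"); cc <- cov_of("cds"); c3 <- cov_of("utr3")
    cn <- cov_of(NULL, noncoding_exons = TRUE)
    exonic <- (c5 + cc + c3 + cn) > 0
    is_cds <- cc > 0 & cc >= c5 & cc >= c3 & cc >= cn
    is_u5 <- !is_cds & c5 > 0 & c5 >= c3 & c5 >= cn
    is_u3 <- !is_cds & !is_u5 & c3 > 0 & c3 >= cn
    is_other <- exonic & !is_cds & !is_u5 & !is_u3
    to_gr <- function(lr) {
      ir <- IRanges::IRanges(lr)
      if (length(ir) == 0) return(GenomicRanges::GRanges(seqinfo = si))
      GenomicRanges::GRanges(genes$chrom[gi],
                             IRanges::shift(ir, gstart - 1L),
                             strand = genes$strand[gi], seqinfo = si)
    }
    acc$exon[[gid]] <- to_gr(exonic)
    acc$utr5[[gid]] <- to_gr(is_u5)
    acc$cds[[gid]] <- to_gr(is_cds)
    acc$utr3[[gid]] <- to_gr(is_u3)
    acc$other[[gid]] <- to_gr(is_other)
    # introns: union of per-transcript (span minus exons), minus exon space
    intr <- lapply(gtx, function(r) {
      ir <- local_ir(r$exons, gstart)
      sp <- IRanges::IRanges(min(IRanges::start(ir)),
                             max(IRanges::end(ir)))
      IRanges::setdiff(sp, ir)
    })
    intr <- IRanges::reduce(do.call(c, unname(intr)))
    intr <- IRanges::setdiff(intr, IRanges::IRanges(exonic))
    acc$intron[[gid]] <- if (length(intr) == 0)
      GenomicRanges::GRanges(seqinfo = si) else
      GenomicRanges::GRanges(genes$chrom[gi],
                             IRanges::shift(intr, gstart - 1L),
                             strand = genes$strand[gi], seqinfo = si)
  }
  cat_gr <- function(l) {
    l <- l[vapply(l, length, integer(1)) > 0]
    if (length(l) == 0) GenomicRanges::GRanges(seqinfo = si) else
      GenomicRanges::sort(do.call(c, unname(l)), ignore.strand = TRUE)
  }
  fs <- lapply(acc, cat_gr)
  bp <- vapply(fs, function(g) sum(GenomicRanges::width(g)), numeric(1))
  tier1_tot <- bp[["exon"]] + bp[["intron"]]
  tier1 <- c(exon = unname(bp[["exon"]]) / tier1_tot,
             intron = unname(bp[["intron"]]) / tier1_tot,
             junction = 0)
  tier2 <- c("5'UTR" = unname(bp[["utr5"]]), CDS = unname(bp[["cds"]]),
             "3'UTR" = unname(bp[["utr3"]]), "5'UTR+CDS" = 0,
             "3'UTR+CDS" = 0, other = unname(bp[["other"]]))
  tier2 <- tier2 / sum(tier2)
  structure(c(fs, list(gene_spans = spans,
                       bp = data.frame(category = names(bp), bp = unname(bp)),
                       background = structure(
                         list(basis = "background gene space",
                              tier1 = tier1, tier2 = tier2,
                              n_unassigned = 0),
                         class = "feature_coverage_profile"))),
            class = "feature_space")
}

#' @export
print.feature_space <- function(x, ...) {
  cat("feature_space bp totals:\n")
  print(x$bp)
  invisible(x)
}

#' Classify intervals against a feature space
#'
#' Tier 1: an interval overlapping only exonic bp is "exon", only intronic
#' bp "intron", both "junction"; intervals touching no gene space go to an
#' explicit "unassigned" bucket. Tier 2 (exon intervals only): labeled by
#' the set of exonic subspaces overlapped -- a single subspace gives its own
#' label; 5'UTR with CDS gives "5'UTR+CDS"; 3'UTR with CDS gives
#' "3'UTR+CDS"; any other combination is "other".
#'
#' @param gr intervals as [GenomicRanges::GRanges] (or an interactions
#'   data.frame, converted via [interactions_as_granges()]).
#' @param fs a `feature_space` from [build_feature_space()].
#' @return object of class `feature_coverage_profile` with basis
#'   "predicted binding events": `tier1` and `tier2` fraction vectors,
#'   `n_unassigned`, and `detail` (per-interval tier1/tier2 labels).
#' @export
classify_intervals <- function(gr, fs) {
  if (is.data.frame(gr)) gr <- interactions_as_granges(gr)
  n <- length(gr)
  ov_bp <- function(space) {
    if (length(space) == 0 || n == 0) return(numeric(n))
    hits <- GenomicRanges::findOverlaps(gr, space, ignore.strand = TRUE)
    pi <- GenomicRanges::pintersect(
      gr[S4Vectors::queryHits(hits)], space[S4Vectors::subjectHits(hits)],
      ignore.strand = TRUE)
    out <- numeric(n)
    if (length(hits)) {
      agg <- tapply(GenomicRanges::width(pi), S4Vectors::queryHits(hits), sum)
      out[as.integer(names(agg))] <- agg
    }
    out
  }
  we <- ov_bp(fs$exon); wi <- ov_bp(fs$intron)
  tier1 <- rep("unassigned", n)
  tier1[we > 0 & wi == 0] <- "exon"
  tier1[wi > 0 & we == 0] <- "intron"
  tier1[we > 0 & wi > 0] <- "junction"
  touch <- function(space) ov_bp(space) > 0
  u5 <- touch(fs$utr5); cd <- touch(fs$cds); u3 <- touch(fs$utr3)
  ot <- touch(fs$other)
  tier2 <- rep(NA_character_, n)
  ex <- tier1 == "exon"
  lab <- function(i) {
    s <- c("5'UTR"[u5[i]], "CDS"[cd[i]], "3'UTR"[u3[i]], "other"[ot[i]])
    if (length(s) == 1) return(s)
    if (setequal(s, c("5'UTR", "CDS"))) return("5'UTR+CDS")
    if (setequal(s, c("3'UTR", "CDS"))) return("3'UTR+CDS")
    "other"
  }
  tier2[ex] <- vapply(which(ex), lab, character(1))
  assigned <- tier1 != "unassigned"
  t1_levels <- c("exon", "intron", "junction")
  t1 <- table(factor(tier1[assigned], levels = t1_levels))
  tier1_frac <- if (sum(t1) > 0) as.numeric(t1) / sum(t1) else
    rep(0, length(t1_levels))
  names(tier1_frac) <- t1_levels
  t2_levels <- c("5'UTR", "3'UTR", "CDS", "5'UTR+CDS", "3'UTR+CDS", "other")
  t2 <- table(factor(tier2[ex], levels = t2_levels))
  tier2_frac <- if (sum(t2) > 0) as.numeric(t2) / sum(t2) else
    rep(0, length(t2_levels))
  names(tier2_frac) <- t2_levels
  structure(list(basis = "predicted binding events",
                 tier1 = tier1_frac, tier2 = tier2_frac,
                 n_unassigned = sum(!assigned),
                 detail = data.frame(tier1 = tier1, tier2 = tier2,
                                     stringsAsFactors = FALSE)),
            class = "feature_coverage_profile")
}

#' @export
print.feature_coverage_profile <- function(x, ...) {
  cat("feature coverage (", x$basis, ")\n tier1: ", sep = "")
  cat(paste(names(x$tier1), sprintf("%.3f", x$tier1), collapse = ", "), "\n")
  cat(" tier2:", paste(names(x$tier2), sprintf("%.3f", x$tier2),
                       collapse = ", "), "\n")
  invisible(x)
}

# transcript-coordinate of a genomic position within a transcript's exonic
# space, counted 5'->3' (1-based); NA when outside
exonic_position <- function(r, pos) {
  st <- r$exons$start; en <- r$exons$end
  hit <- which(pos >= st & pos <= en)
  if (length(hit) == 0) return(NA_integer_)
  before <- sum(pmax(0L, pmin(en, pos - 1L) - st + 1L)[seq_len(hit - 1)])
  p5 <- before + (pos - st[hit] + 1L)
  if (r$strand == "-") sum(en - st + 1L) - p5 + 1L else p5
}

#' Metagene density of binding events over 5'UTR / gene body / 3'UTR
#'
#' Each event midpoint is mapped per matched retained transcript into a
#' metagene coordinate: fractional position within the 5'UTR gives [0, 1),
#' within the CDS (the gene body of coding transcripts) 1 + fraction, and
#' within the 3'UTR 2 + fraction; non-coding transcripts map their whole
#' exonic span to [1, 2). Contributions are averaged over the transcripts
#' whose exonic space contains the midpoint; events matching none are
#' skipped. Densities are normalized to integrate to 1.
#'
#' @param gr events ([GenomicRanges::GRanges] or interactions data.frame).
#' @param ann a filtered [snord_annotation].
#' @param n_bins number of bins over [0, 3) (default 60).
#' @param groups optional character vector (length of `gr`) of curve labels
#'   (e.g. snoRNA group); an "all" curve pooling every event is always
#'   included.
#' @return object of class `metagene_density`: `bins` (bin_lo, bin_mid,
#'   bin_hi), `curves` (named list of per-bin densities), `n_events`,
#'   `n_skipped`.
#' @export
metagene_density <- function(gr, ann, n_bins = 60, groups = NULL) {
  if (is.data.frame(gr)) gr <- interactions_as_granges(gr)
  regions <- transcript_regions(ann)
  mids <- floor((GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2)
  chroms <- as.character(GenomicRanges::seqnames(gr))
  coords <- vector("list", length(gr))
  skipped <- 0L
  tx_chrom <- ann$transcripts$chrom[match(
    vapply(regions, `[[`, character(1), "transcript_id"),
    ann$transcripts$transcript_id)]
  for (i in seq_along(gr)) {
    cand <- regions[tx_chrom == chroms[i]]
    cs <- numeric(0)
    for (r in cand) {
      pos <- exonic_position(r, mids[i])
      if (is.na(pos)) next
      if (r$coding) {
        l5 <- iv_width(r$utr5)
        lc <- iv_width(r$cds)
        l3 <- iv_width(r$utr3)
        cs <- c(cs, if (pos <= l5) (pos - 1) / l5
                else if (pos <= l5 + lc) 1 + (pos - l5 - 1) / lc
                else 2 + (pos - l5 - lc - 1) / l3)
      } else {
        tot <- iv_width(r$exons)
        cs <- c(cs, 1 + (pos - 1) / tot)
      }
    }
    if (length(cs) == 0) skipped <- skipped + 1L else coords[[i]] <- cs
  }
  breaks <- seq(0, 3, length.out = n_bins + 1)
  bw <- 3 / n_bins
  hist_of <- function(idx) {
    w <- numeric(n_bins)
    tot <- 0
    for (i in idx) {
      cs <- coords[[i]]
      if (is.null(cs)) next
      b <- pmin(pmax(findInterval(cs, breaks, rightmost.closed = TRUE), 1),
                n_bins)
      for (j in seq_along(b)) w[b[j]] <- w[b[j]] + 1 / length(cs)
      tot <- tot + 1
    }
    if (tot > 0) w / (tot * bw) else w
  }
  curves <- list(all = hist_of(seq_along(gr)))
  if (!is.null(groups)) {
    for (g in sort(unique(groups))) {
      curves[[g]] <- hist_of(which(groups == g))
    }
  }
  structure(list(bins = data.frame(bin_lo = head(breaks, -1),
                                   bin_mid = head(breaks, -1) + bw / 2,
                                   bin_hi = breaks[-1]),
                 curves = curves, n_events = length(gr) - skipped,
                 n_skipped = skipped),
            class = "metagene_density")
}

#' @export
print.metagene_density <- function(x, ...) {
  cat(sprintf("metagene_density: %d events (%d skipped), %d bins, curves: %s\n",
              x$n_events, x$n_skipped, nrow(x$bins),
              paste(names(x$curves), collapse = ", ")))
  invisible(x)
}
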