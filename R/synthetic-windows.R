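#' Simulate a per-window snoRNA-target score table with planted binding runs
#'
#' Background windows carry scores strictly below the merge threshold and can
#' never form a binding event; planted events are runs of >= `min_run`
#' consecutive windows (step 1 nt on both the snoRNA and the target) with
#' scores >= 0.98. Events are planted on every gene at a Poisson base rate
#' and on `target_genes` at `enrichment_fold` times that rate. Each event's
#' snoRNA copy is biased toward SNORD116 group III, its snoRNA position
#' toward the ASE2 segment (between the C' and D boxes) and its target
#' position toward 5'UTR space of a retained transcript; the same copy and
#' position biases apply on target and non-target genes, so only the event
#' rate distinguishes them.
#'
#' For "-" strand genes, consecutive windows advance by -1 on the genome as
#' the snoRNA position advances by +1 (the duplex slides along the mRNA).
#'
#' @param registry from [build_snorna_registry()].
#' @param annotation a filtered [snord_annotation] (retained transcripts).
#' @param target_genes character vector of planted target gene ids (subset of
#'   annotation genes).
#' @param enrichment_fold event-rate fold on target genes (>= 1).
#' @param params list overriding defaults: base_rate (mean events per
#'   non-target gene, 4), window_length (13), run_extra_lambda (Poisson mean
#'   of extra windows beyond min_run, 0.7), min_run (3), group3_bias (0.8),
#'   ase2_bias (0.8), utr5_bias (0.8), noise_windows (mean sub-threshold
#'   windows per gene, 20), score_threshold (0.98).
#' @param seed integer seed.
#' @return list with `windows` (data.frame in the canonical window-score
#'   layout) and `events` (data.frame of planted events: gene_id, is_target,
#'   copy_id, group, n_windows, sno_start, target_start, strand, in_ase2,
#'   in_utr5).
#' @export
simulate_window_scores <- function(registry, annotation, target_genes,
                                   enrichment_fold = 2.5, params = list(),
                                   seed = NULL) {
  p <- utils::modifyList(list(base_rate = 4, window_length = 13,
                              run_extra_lambda = 0.7, min_run = 3,
                              group3_bias = 0.8, ase2_bias = 0.8,
                              utr5_bias = 0.8, noise_windows = 20,
                              score_threshold = 0.98), params)
  assert_that(enrichment_fold >= 1, "enrichment_fold must be >= 1")
  genes <- annotation$genes
  assert_that(all(target_genes %in% genes$gene_id),
              "target_genes must be annotation genes")
  regions <- transcript_regions(annotation)
  region_gene <- vapply(regions, `[[`, character(1), "gene_id")
  ase2 <- ase2_intervals(registry)
  g3 <- registry$copy_id[registry$cluster == "SNORD116" &
                           registry$group == "III" &
                           !is.na(registry$group)]
  wl <- as.integer(p$window_length)
  # merged 5'UTR space per gene, for the 5'UTR placement bias
  utr5_by_gene <- lapply(genes$gene_id, function(gid) {
    iv_merge(do.call(rbind, c(lapply(regions[region_gene == gid],
                                     `[[`, "utr5"), list(iv_df()))))
  })
  names(utr5_by_gene) <- genes$gene_id
  with_seed(seed, {
    is_target <- genes$gene_id %in% target_genes
    n_ev <- rpois(nrow(genes),
                  p$base_rate * ifelse(is_target, enrichment_fold, 1))
    m <- sum(n_ev)
    gi <- rep(seq_len(nrow(genes)), n_ev)
    n_w <- p$min_run + rpois(m, p$run_extra_lambda)
    extent <- wl + n_w - 1L
    copy <- ifelse(runif(m) < p$group3_bias,
                   sample(g3, m, replace = TRUE),
                   sample(registry$copy_id, m, replace = TRUE))
    ri <- match(copy, registry$copy_id)
    L <- registry$length[ri]
    in_ase2 <- runif(m) < p$ase2_bias
    center <- ifelse(in_ase2,
                     ase2$ase2_start[ri] +
                       floor(runif(m) * (ase2$ase2_end[ri] -
                                           ase2$ase2_start[ri] + 1L)),
                     1L + floor(runif(m) * L))
    s_start <- pmin(pmax(1L, as.integer(center) - extent %/% 2L),
                    L - extent + 1L)
    in_utr5 <- runif(m) < p$utr5_bias
    mid <- integer(m)
    u_draw <- runif(m)
    for (e in seq_len(m)) {
      u5 <- utr5_by_gene[[gi[e]]]
      if (in_utr5[e] && nrow(u5) > 0) {
        w <- u5$end - u5$start + 1L
        off <- floor(u_draw[e] * sum(w))
        seg <- findInterval(off, cumsum(c(0L, w)), rightmost.closed = FALSE)
        mid[e] <- u5$start[seg] + off - c(0L, cumsum(w))[seg]
      } else {
        in_utr5[e] <- FALSE
        mid[e] <- genes$start[gi[e]] +
          floor(u_draw[e] * (genes$end[gi[e]] - genes$start[gi[e]] + 1L))
      }
    }
    t_start <- mid - extent %/% 2L
    strand <- genes$strand[gi]
    events <- data.frame(gene_id = genes$gene_id[gi],
                         is_target = is_target[gi], copy_id = copy,
                         group = registry$group[ri], n_windows = n_w,
                         sno_start = s_start, target_start = t_start,
                         strand = strand, in_ase2 = in_ase2,
                         in_utr5 = in_utr5, stringsAsFactors = FALSE)
    # expand events to window rows
    er <- rep(seq_len(m), n_w)
    iw <- sequence(n_w)
    sno_pos <- s_start[er] + iw - 1L
    t_pos <- ifelse(strand[er] == "+", t_start[er] + iw - 1L,
                    t_start[er] + extent[er] - wl - (iw - 1L))
    planted <- data.frame(sno_id = copy[er], sno_start = sno_pos,
                          target_gene_id = genes$gene_id[gi[er]],
                          target_chrom = genes$chrom[gi[er]],
                          target_start = as.integer(t_pos),
                          strand = strand[er],
                          score = runif(length(er), p$score_threshold, 1),
                          window_length = rep(wl, length(er)),
                          stringsAsFactors = FALSE)
    # sub-threshold background noise windows
    n_noise <- rpois(nrow(genes), p$noise_windows)
    ng <- rep(seq_len(nrow(genes)), n_noise)
    nn <- length(ng)
    ncopy <- sample(registry$copy_id, nn, replace = TRUE)
    nri <- match(ncopy, registry$copy_id)
    noise <- data.frame(
      sno_id = ncopy,
      sno_start = 1L + floor(runif(nn) *
                               (registry$length[nri] - wl + 1L)),
      target_gene_id = genes$gene_id[ng],
      target_chrom = genes$chrom[ng],
      target_start = genes$start[ng] +
        as.integer(floor(runif(nn) *
                           (genes$end[ng] - genes$start[ng] + 1L))),
      strand = genes$strand[ng],
      score = runif(nn, 0, p$score_threshold - 1e-4),
      window_length = rep(wl, nn), stringsAsFactors = FALSE)
    windows <- rbind(planted, noise)
    # drop accidental key collisions between independently planted sites
    key <- with(windows, paste(sno_id, target_gene_id, target_chrom, strand,
                               sno_start, target_start))
    windows <- windows[!duplicated(key), , drop = FALSE]
    rownames(windows) <- NULL
    list(windows = windows, events = events)
  })
}
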