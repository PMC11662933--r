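#' Merge consecutive high-score windows into predicted binding events
#'
#' Keeps windows with score >= `score_threshold` and groups them into maximal
#' runs in which successive windows advance by exactly `step` nt on the
#' snoRNA and, simultaneously, by `step` nt along the target mRNA (genomic
#' +`step` on "+" genes, -`step` on "-" genes: the duplex slides along the
#' transcript). Equivalently, qualifying windows on a common
#' (snoRNA, gene, chromosome, strand) grouping and a common duplex diagonal
#' are chained when their snoRNA starts are consecutive. Each maximal run of
#' at least `min_run` windows yields exactly one event spanning the run's
#' full extent on both sides; shorter runs are discarded.
#'
#' @param windows data.frame in the layout of [read_window_scores()].
#' @param score_threshold minimum per-window score (default 0.98).
#' @param min_run minimum run length in windows (default 3).
#' @param step window step in nt (default 1).
#' @param max_gap number of missing windows tolerated inside a run
#'   (default 0).
#' @param keep_windows retain constituent window rows per event in a
#'   `window_rows` attribute (list of integer row indices into `windows`).
#' @return data.frame of events: sno_id, sno_start, sno_end, target_gene_id,
#'   target_chrom, target_start, target_end, strand, n_windows, min_score,
#'   mean_score, window_length; 1-based closed intervals, sorted by
#'   (sno_id, target_chrom, target_start, sno_start).
#' @export
merge_consecutive_windows <- function(windows, score_threshold = 0.98,
                                      min_run = 3, step = 1, max_gap = 0,
                                      keep_windows = FALSE) {
  assert_that(score_threshold >= 0 && score_threshold <= 1,
              "score_threshold must be in [0, 1]")
  assert_that(min_run >= 1 && step >= 1, "min_run and step must be >= 1")
  empty <- data.frame(sno_id = character(0), sno_start = integer(0),
                      sno_end = integer(0), target_gene_id = character(0),
                      target_chrom = character(0), target_start = integer(0),
                      target_end = integer(0), strand = character(0),
                      n_windows = integer(0), min_score = numeric(0),
                      mean_score = numeric(0), window_length = integer(0))
  if (nrow(windows) == 0) return(empty)
  key <- with(windows, paste(sno_id, target_gene_id, target_chrom, strand,
                             sno_start, target_start, sep = "\r"))
  dup <- duplicated(key)
  if (any(dup)) {
    # identical duplicate rows (e.g. the same genomic site reached through
    # several transcripts) are collapsed; conflicting scores are an error
    first <- match(key[dup], key)
    if (any(windows$score[dup] != windows$score[first])) {
      stop("duplicate (sno_id, sno_start, target_start) rows with ",
           "conflicting scores", call. = FALSE)
    }
    windows <- windows[!dup, , drop = FALSE]
  }
  wl <- unique(windows$window_length)
  assert_that(length(wl) == 1, "window_length must be constant per table")
  dt <- data.table::as.data.table(windows)
  dt[, row_id := .I]
  dt <- dt[score >= score_threshold]
  if (nrow(dt) == 0) return(empty)
  dir <- ifelse(dt$strand == "+", 1L, -1L)
  # windows on one diagonal belong to the same sliding duplex
  dt[, diag := target_start - dir * sno_start]
  data.table::setorder(dt, sno_id, target_gene_id, target_chrom, strand,
                       diag, sno_start)
  dt[, run := {
    d <- diff(sno_start)
    ok <- d %in% (step * seq_len(max_gap + 1))
    cumsum(c(TRUE, !ok))
  }, by = .(sno_id, target_gene_id, target_chrom, strand, diag)]
  ev <- dt[, .(sno_start = min(sno_start),
               sno_end = max(sno_start) + wl - 1L,
               target_start = min(target_start),
               target_end = max(target_start) + wl - 1L,
               n_windows = .N, min_score = min(score),
               mean_score = mean(score),
               rows = list(row_id)),
           by = .(sno_id, target_gene_id, target_chrom, strand, diag, run)]
  ev <- ev[n_windows >= min_run]
  data.table::setorder(ev, sno_id, target_chrom, target_start, sno_start)
  out <- as.data.frame(ev[, .(sno_id, sno_start, sno_end, target_gene_id,
                              target_chrom, target_start, target_end, strand,
                              n_windows, min_score, mean_score)])
  out$window_length <- rep(wl, nrow(out))
  if (keep_windows) attr(out, "window_rows") <- ev$rows
  out
}

#' Count predicted targeting events per snoRNA copy and group
#'
#' One merged binding event counts as one targeting event. Per-group means
#' divide the group total by the number of copies in the group, including
#' copies with zero events.
#'
#' @param interactions events from [merge_consecutive_windows()].
#' @param registry from [build_snorna_registry()].
#' @return list with `per_copy` (copy_id, cluster, group, n_events) and
#'   `per_group` (cluster, group, n_copies, total_events, mean_per_copy).
#' @export
count_events <- function(interactions, registry) {
  unknown <- setdiff(interactions$sno_id, registry$copy_id)
  assert_that(length(unknown) == 0,
              paste0("unknown sno_id: ", paste(head(unknown, 3),
                                               collapse = ", ")))
  tab <- table(factor(interactions$sno_id, levels = registry$copy_id))
  per_copy <- data.frame(copy_id = registry$copy_id,
                         cluster = registry$cluster,
                         group = registry$group,
                         n_events = as.integer(tab),
                         stringsAsFactors = FALSE)
  grp_key <- ifelse(is.na(per_copy$group), per_copy$cluster,
                    paste0(per_copy$cluster, "-", per_copy$group))
  agg <- stats::aggregate(per_copy$n_events, by = list(key = grp_key), sum)
  ncp <- table(grp_key)
  per_group <- data.frame(group = agg$key,
                          n_copies = as.integer(ncp[agg$key]),
                          total_events = agg$x,
                          mean_per_copy = agg$x / as.integer(ncp[agg$key]),
                          stringsAsFactors = FALSE)
  list(per_copy = per_copy, per_group = per_group)
}

#' Events as target-side genomic intervals
#'
#' @param interactions events from [merge_consecutive_windows()].
#' @return [GenomicRanges::GRanges] with name (sno_id:gene) and score
#'   metadata, suitable for [write_bed()] and positional analysis.
#' @export
interactions_as_granges <- function(interactions) {
  if (nrow(interactions) == 0) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(
    interactions$target_chrom,
    IRanges::IRanges(interactions$target_start, interactions$target_end),
    strand = interactions$strand)
  S4Vectors::mcols(gr)$name <- paste0(interactions$sno_id, ":",
                                      interactions$target_gene_id)
  S4Vectors::mcols(gr)$score <- round(interactions$mean_score * 1000)
  S4Vectors::mcols(gr)$sno_id <- interactions$sno_id
  S4Vectors::mcols(gr)$target_gene_id <- interactions$target_gene_id
  gr
}
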