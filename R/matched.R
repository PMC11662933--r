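#' Per-gene matching covariates: exonic length, GC content, expression
#'
#' Length is the bp of the union of exons over the annotation's (retained)
#' transcripts; GC is computed over that same merged exonic sequence;
#' expression is the mean of library-size-normalized counts over the given
#' samples.
#'
#' @param gene_ids genes to cover.
#' @param annotation a filtered [snord_annotation].
#' @param sequences chromosome [Biostrings::DNAStringSet].
#' @param counts gene x sample count matrix (rownames = gene ids).
#' @param expr_samples column names/indices of the samples defining the
#'   expression covariate (e.g. neuron samples).
#' @return data.frame gene_id, length, gc, expression. Genes without
#'   sequence or retained exons are dropped with a warning.
#' @export
compute_covariates <- function(gene_ids, annotation, sequences, counts,
                               expr_samples = colnames(counts)) {
  sf <- colSums(counts)
  fac <- sf / mean(sf)
  fac[!is.finite(fac) | fac == 0] <- 1   # zero-library guard
  norm <- sweep(counts, 2, fac, "/")
  expr <- rowMeans(norm[, expr_samples, drop = FALSE])
  ex <- annotation$exons
  out <- vector("list", length(gene_ids))
  dropped <- character(0)
  for (i in seq_along(gene_ids)) {
    g <- gene_ids[i]
    exg <- GenomicRanges::reduce(ex[S4Vectors::mcols(ex)$gene_id == g])
    chrom <- unique(as.character(GenomicRanges::seqnames(exg)))
    if (length(exg) == 0 || !all(chrom %in% names(sequences))) {
      dropped <- c(dropped, g)
      next
    }
    len <- sum(GenomicRanges::width(exg))
    seqs <- Biostrings::extractAt(
      sequences[[chrom[1]]],
      IRanges::IRanges(GenomicRanges::start(exg), GenomicRanges::end(exg)))
    gc <- sum(Biostrings::letterFrequency(seqs, c("G", "C"))) / len
    out[[i]] <- data.frame(gene_id = g, length = len, gc = gc,
                           expression = if (g %in% rownames(counts))
                             unname(expr[g]) else 0,
                           stringsAsFactors = FALSE)
  }
  if (length(dropped)) {
    warning("excluded ", length(dropped),
            " gene(s) without retained exons or sequence: ",
            paste(head(dropped, 3), collapse = ", "))
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

wilcox_p <- function(x, y) {
  suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
}

#' Sample covariate-matched control gene lists
#'
#' Rejection sampling: candidate lists of `m` genes are drawn without
#' replacement from the universe (query genes excluded) and accepted when a
#' two-sided Wilcoxon rank-sum test against the query exceeds `alpha` for
#' length, GC content AND expression, i.e. the list does not differ
#' significantly from the query in any of the three covariates. Lists are
#' sampled independently and may overlap one another.
#'
#' @param query character vector of query gene ids.
#' @param covariates data.frame from [compute_covariates()] covering query
#'   and universe (no NA covariates).
#' @param k number of control lists (default 100).
#' @param m list size (default the query size).
#' @param alpha acceptance level for each Wilcoxon test (default 0.05).
#' @param max_iter candidate draws allowed before giving up.
#' @param log_expression test expression on the log2(x+1) scale (rank tests
#'   are invariant to this, kept for reporting symmetry; default TRUE).
#' @param seed integer seed.
#' @return object of class `matched_lists`: `lists` (list of k character
#'   vectors), `pvalues` (k x 3 data.frame), `alpha`, `n_tried`.
#' @export
sample_matched_lists <- function(query, covariates, k = 100,
                                 m = length(query), alpha = 0.05,
                                 max_iter = 200 * k, log_expression = TRUE,
                                 seed = NULL) {
  cov <- covariates
  assert_that(!any(is.na(cov$length) | is.na(cov$gc) | is.na(cov$expression)),
              "covariates must have no NA for genes entering matching")
  rownames(cov) <- cov$gene_id
  pool <- setdiff(cov$gene_id, query)
  assert_that(m <= length(pool),
              "universe (minus query) is smaller than the list size m")
  q <- cov[intersect(query, cov$gene_id), , drop = FALSE]
  assert_that(nrow(q) == length(query),
              "every query gene needs covariates")
  tx <- if (log_expression) function(x) log2(x + 1) else identity
  lists <- vector("list", k)
  pv <- matrix(NA_real_, k, 3,
               dimnames = list(NULL, c("length", "gc", "expression")))
  fails <- c(length = 0, gc = 0, expression = 0)
  accepted <- 0L; tried <- 0L
  with_seed(seed, {
    while (accepted < k && tried < max_iter) {
      tried <- tried + 1L
      cand <- sample(pool, m)
      cc <- cov[cand, ]
      p_len <- wilcox_p(q$length, cc$length)
      if (p_len <= alpha) { fails["length"] <- fails["length"] + 1; next }
      p_gc <- wilcox_p(q$gc, cc$gc)
      if (p_gc <= alpha) { fails["gc"] <- fails["gc"] + 1; next }
      p_ex <- wilcox_p(tx(q$expression), tx(cc$expression))
      if (p_ex <= alpha) { fails["expression"] <- fails["expression"] + 1; next }
      accepted <- accepted + 1L
      lists[[accepted]] <- cand
      pv[accepted, ] <- c(p_len, p_gc, p_ex)
    }
  })
  if (accepted < k) {
    stop(sprintf(paste0(
      "only %d/%d matched lists accepted after %d draws ",
      "(acceptance rate %.3f); rejections by covariate: ",
      "length %d, gc %d, expression %d"),
      accepted, k, tried, accepted / tried,
      fails["length"], fails["gc"], fails["expression"]), call. = FALSE)
  }
  structure(list(lists = lists,
                 pvalues = as.data.frame(pv),
                 alpha = alpha, m = m, n_tried = tried,
                 log_expression = log_expression),
            class = "matched_lists")
}

#' @export
print.matched_lists <- function(x, ...) {
  cat(sprintf("matched_lists: %d lists of %d genes (alpha %.3g, %d draws)\n",
              length(x$lists), x$m, x$alpha, x$n_tried))
  invisible(x)
}

#' Enrichment of per-gene event counts versus matched control lists
#'
#' For each summary statistic, the observed value over the query genes'
#' event counts is compared with the distribution of the same statistic over
#' the control lists: fold = observed / median(null), and
#' p = (number of control values >= observed) / k, floored at 1/k when no
#' control value reaches the observed value.
#'
#' @param query character vector of query gene ids.
#' @param control_lists a `matched_lists` object (or list of gene-id
#'   vectors).
#' @param per_gene_events named integer vector of event counts; genes absent
#'   from it count 0.
#' @param stats statistics to test (subset of mean/median/sum).
#' @return data.frame: stat, observed, null_median, fold, zero_null_median,
#'   p_value, p_is_floor, k.
#' @export
enrichment_vs_controls <- function(query, control_lists, per_gene_events,
                                   stats = c("mean", "median", "sum")) {
  lists <- if (inherits(control_lists, "matched_lists"))
    control_lists$lists else control_lists
  k <- length(lists)
  assert_that(k > 0, "no control lists supplied")
  counts_of <- function(g) {
    v <- per_gene_events[g]
    v[is.na(v)] <- 0
    unname(v)
  }
  qc <- counts_of(query)
  rows <- lapply(stats, function(s) {
    f <- match.fun(s)
    obs <- f(qc)
    null <- vapply(lists, function(g) f(counts_of(g)), numeric(1))
    med <- median(null)
    n_ge <- sum(null >= obs)
    p_is_floor <- n_ge == 0
    data.frame(stat = s, observed = obs, null_median = med,
               fold = if (med == 0) Inf else obs / med,
               zero_null_median = med == 0,
               p_value = if (p_is_floor) 1 / k else n_ge / k,
               p_is_floor = p_is_floor, k = k,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
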