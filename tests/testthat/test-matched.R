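test_that("covariates match hand-computed length, GC and expression", {
  # one gene, one transcript: exon 101-1100 (1000 bp) of repeated ATGC
  genes <- data.frame(gene_id = "G1", symbol = "G1", biotype = "lncRNA",
                      chrom = "chr1", start = 101L, end = 1100L,
                      strand = "+", stringsAsFactors = FALSE)
  tx <- data.frame(transcript_id = "G1.T1", gene_id = "G1", chrom = "chr1",
                   strand = "+", start = 101L, end = 1100L,
                   support_level = 1L, basic = TRUE, stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 1100))
  S4Vectors::mcols(gr)$transcript_id <- "G1.T1"
  S4Vectors::mcols(gr)$gene_id <- "G1"
  ann <- snord_annotation(genes, tx, gr, GenomicRanges::GRanges())
  seqs <- Biostrings::DNAStringSet(c(
    chr1 = paste(rep("ATGC", 300), collapse = "")))
  counts <- matrix(0L, 1, 4, dimnames = list("G1", paste0("s", 1:4)))
  cov <- compute_covariates("G1", ann, seqs, counts)
  expect_equal(cov$length, 1000)
  expect_equal(cov$gc, 0.5)
  expect_equal(cov$expression, 0)   # all-zero counts

  # a gene with no sequence is excluded with a warning
  genes2 <- rbind(genes, transform(genes, gene_id = "G2", chrom = "chrX"))
  tx2 <- rbind(tx, transform(tx, transcript_id = "G2.T1", gene_id = "G2",
                             chrom = "chrX"))
  gr2 <- suppressWarnings(
    c(gr, GenomicRanges::GRanges("chrX", IRanges::IRanges(101, 1100))))
  S4Vectors::mcols(gr2)$transcript_id <- c("G1.T1", "G2.T1")
  S4Vectors::mcols(gr2)$gene_id <- c("G1", "G2")
  ann2 <- snord_annotation(genes2, tx2, gr2, GenomicRanges::GRanges())
  expect_warning(cov2 <- compute_covariates(c("G1", "G2"), ann2, seqs,
                                            counts),
                 "without retained exons or sequence")
  expect_identical(cov2$gene_id, "G1")
})

test_that("covariates equal brute-force recomputation from GTF and FASTA", {
  toy <- build_toy_annotation(30, n_chroms = 2, seed = 71)
  annf <- filter_transcripts(toy$annotation)
  sim <- simulate_counts(toy$annotation, n_reps = 2, seed = 72)
  cov <- compute_covariates(annf$genes$gene_id, annf, toy$sequences,
                            sim$counts)
  regs <- transcript_regions(annf)
  sf <- colSums(sim$counts); norm <- sweep(sim$counts, 2, sf / mean(sf), "/")
  for (i in seq_len(nrow(cov))) {
    g <- cov$gene_id[i]
    gtx <- regs[vapply(regs, function(r) r$gene_id == g, logical(1))]
    bp <- sort(unique(unlist(lapply(gtx, function(r) df_bp(r$exons)))))
    expect_equal(cov$length[i], length(bp))
    chrom <- toy$annotation$genes$chrom[
      toy$annotation$genes$gene_id == g]
    chars <- strsplit(as.character(toy$sequences[[chrom]]), "")[[1]]
    expect_equal(cov$gc[i], mean(chars[bp] %in% c("G", "C")))
    expect_equal(cov$expression[i], mean(norm[g, ]))
  }
})

sim_covariates <- function(n, shift_length = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(gene_id = paste0("g", seq_len(n)),
             length = exp(rnorm(n, log(2000 * shift_length), 0.6)),
             gc = stats::rbeta(n, 20, 25),
             expression = exp(rnorm(n, log(50), 1)),
             stringsAsFactors = FALSE)
}

test_that("matched lists reach k and re-pass all three Wilcoxon tests", {
  cov <- sim_covariates(400, seed = 81)
  query <- cov$gene_id[1:42]
  ml <- sample_matched_lists(query, cov, k = 25, alpha = 0.05, seed = 82)
  expect_length(ml$lists, 25)
  expect_true(all(lengths(ml$lists) == 42))
  expect_true(all(vapply(ml$lists, function(l)
    !any(l %in% query), logical(1))))
  rownames(cov) <- cov$gene_id
  for (l in ml$lists) {
    for (v in c("length", "gc", "expression")) {
      p <- suppressWarnings(stats::wilcox.test(cov[query, v], cov[l, v],
                                               exact = FALSE)$p.value)
      expect_gt(p, 0.05)
    }
  }
})

test_that("an unmatchable universe fails with an informative error", {
  cov_q <- sim_covariates(42, seed = 83)
  cov_u <- sim_covariates(300, shift_length = 10, seed = 84)
  cov_u$gene_id <- paste0("u", seq_len(300))
  cov <- rbind(cov_q, cov_u)
  expect_error(
    sample_matched_lists(cov_q$gene_id, cov, k = 10, max_iter = 50,
                         seed = 85),
    "acceptance rate")
  expect_error(
    sample_matched_lists(cov_q$gene_id, cov_q, k = 10, m = 42, seed = 86),
    "smaller than the list size")
})

test_that("enrichment versus controls applies the fold and p formulas", {
  lists <- replicate(100, paste0("c", sample(1:500, 42)), simplify = FALSE)
  # all-zero events: p = 1, fold flagged undefined
  ev0 <- setNames(integer(0), character(0))
  e0 <- enrichment_vs_controls(paste0("q", 1:42), lists, ev0)
  expect_true(all(e0$p_value == 1))
  expect_true(all(e0$zero_null_median))

  # observed sum 100 vs all control sums <= 40 with median 40
  query <- paste0("q", 1:10)
  ev <- c(setNames(rep(10L, 10), query),
          setNames(rep(1L, 500), paste0("c", 1:500)))
  lists40 <- replicate(100, paste0("c", sample(1:500, 40)),
                       simplify = FALSE)
  e <- enrichment_vs_controls(query, lists40, ev, stats = "sum")
  expect_equal(e$observed, 100)
  expect_equal(e$null_median, 40)
  expect_equal(e$fold, 2.5)
  expect_equal(e$p_value, 1 / 100)
  expect_true(e$p_is_floor)
})

test_that("fold is invariant to control-list order; p is seed-stable", {
  set.seed(91)
  ev <- setNames(rpois(600, 3), paste0("g", 1:600))
  query <- paste0("g", 1:42)
  lists <- replicate(50, sample(paste0("g", 43:600), 42), simplify = FALSE)
  e1 <- enrichment_vs_controls(query, lists, ev)
  e2 <- enrichment_vs_controls(query, rev(lists), ev)
  expect_equal(e1$fold, e2$fold)
  expect_equal(e1$p_value, e2$p_value)
})
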