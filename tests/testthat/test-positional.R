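toy_interaction <- function(sno_id, sno_start, sno_end, gene = "G1",
                            chrom = "chr1", target_start = 150L,
                            target_end = 170L, strand = "+") {
  data.frame(sno_id = sno_id, sno_start = sno_start, sno_end = sno_end,
             target_gene_id = gene, target_chrom = chrom,
             target_start = target_start, target_end = target_end,
             strand = strand, n_windows = 3L, min_score = 0.99,
             mean_score = 0.99, window_length = 13L,
             stringsAsFactors = FALSE)
}

test_that("snoRNA-side relative positions and box overlays", {
  reg <- build_snorna_registry(seed = 1)
  reg$length[reg$copy_id == "SNORD116-25"] <- 100L
  reg$box_d_start <- reg$length - 7L
  reg$box_d_end <- reg$length - 4L
  # interval covering positions 41..50 on a 100-nt copy:
  # center floor((41+50)/2) = 45 -> relative 0.45
  iv <- toy_interaction("SNORD116-25", 41L, 50L)
  prof <- sno_relative_positions(iv, reg)
  p3 <- prof[["SNORD116-III"]]
  expect_equal(p3$positions, 0.45)
  expect_equal(sum(p3$histogram$count), 1)
  hit <- p3$histogram[p3$histogram$count == 1, ]
  expect_true(hit$bin_lo <= 0.45 && 0.45 <= hit$bin_hi)
  # box overlay ordered C < D' < C' < D on the relative axis
  expect_true(all(diff(p3$boxes$rel_start) > 0))
  # histogram mass equals the number of interactions
  expect_equal(sum(prof[["SNORD115"]]$histogram$count), 0)
  # empty interactions still emit the overlay for every group
  prof0 <- sno_relative_positions(iv[0, ], reg)
  expect_named(prof0, names(prof))
  expect_equal(nrow(prof0[["SNORD116-I"]]$boxes), 4)
})

test_that("feature space of the manual gene matches its construction", {
  for (strand in c("+", "-")) {
    ann <- manual_annotation(strand = strand)
    fs <- build_feature_space(ann)
    bp <- setNames(fs$bp$bp, fs$bp$category)
    expect_equal(unname(bp["exon"]), 600)
    expect_equal(unname(bp["intron"]), 200)
    expect_equal(unname(bp["cds"]), 300)
    # 5'UTR is 101-200 on "+", 701-900 on "-"
    if (strand == "+") {
      expect_equal(unname(bp["utr5"]), 100)
      expect_equal(unname(bp["utr3"]), 200)
    } else {
      expect_equal(unname(bp["utr5"]), 200)
      expect_equal(unname(bp["utr3"]), 100)
    }
    expect_equal(sum(fs$background$tier1), 1)
    expect_equal(sum(fs$background$tier2), 1)
  }
})

test_that("feature space equals the per-base brute-force labeler", {
  toy <- build_toy_annotation(25, n_chroms = 2, seed = 95)
  annf <- filter_transcripts(toy$annotation)
  fs <- build_feature_space(annf)
  brute <- brute_force_labels(annf)
  lab_map <- c(exon = NA, utr5 = "5'UTR", cds = "CDS", utr3 = "3'UTR",
               other = "other", intron = "intron")
  for (cat in c("utr5", "cds", "utr3", "other", "intron")) {
    got <- fs[[cat]]
    got_bp <- unlist(lapply(seq_along(got), function(i)
      paste0(as.character(GenomicRanges::seqnames(got))[i], ":",
             GenomicRanges::start(got)[i]:GenomicRanges::end(got)[i])))
    want_bp <- unlist(lapply(names(brute), function(gid) {
      g <- annf$genes[annf$genes$gene_id == gid, ]
      pos <- which(brute[[gid]] == lab_map[cat])
      if (length(pos)) paste0(g$chrom, ":", g$start + pos - 1) else
        character(0)
    }))
    expect_setequal(got_bp, want_bp)
  }
  # exon space is the union of the exonic sub-labels
  expect_equal(sum(GenomicRanges::width(fs$exon)),
               sum(fs$bp$bp[fs$bp$category %in%
                              c("utr5", "cds", "utr3", "other")]))
})

test_that("interval classification covers the canonical cases", {
  ann <- manual_annotation()   # 5'UTR 101-200, CDS 201-400 + 601-700,
  fs <- build_feature_space(ann)  # intron 401-600, 3'UTR 701-900
  mk <- function(s, e) GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e),
                                              strand = "+")
  p <- classify_intervals(c(mk(120, 140),   # inside 5'UTR exon
                            mk(390, 420),   # exon-intron straddle
                            mk(450, 500),   # intron only
                            mk(180, 230),   # 5'UTR into CDS, same exon
                            mk(2000, 2100)),  # outside all gene space
                          fs)
  expect_identical(p$detail$tier1,
                   c("exon", "junction", "intron", "exon", "unassigned"))
  expect_identical(p$detail$tier2[1], "5'UTR")
  expect_identical(p$detail$tier2[4], "5'UTR+CDS")
  expect_equal(p$n_unassigned, 1)
  expect_equal(sum(p$tier1), 1)
  expect_equal(sum(p$tier2), 1)
})

test_that("metagene coordinates map the three regions as documented", {
  ann <- manual_annotation()
  mk <- function(pos) GenomicRanges::GRanges("chr1",
                                             IRanges::IRanges(pos, pos))
  md <- function(pos) {
    m <- metagene_density(mk(pos), ann, n_bins = 60)
    # recover the coordinate from the single filled bin
    b <- which(m$curves$all > 0)
    c(m$bins$bin_lo[b], m$bins$bin_hi[b])
  }
  # 5'UTR is 101-200; its 51st base (151) sits at exactly half -> 0.5
  expect_true(md(151)[1] <= 0.5 && 0.5 <= md(151)[2])
  # CDS start (201) -> coordinate 1.0
  b <- md(201)
  expect_true(b[1] <= 1.0 && 1.0 < b[2])
  # 3'UTR is 701-900; its 101st base (801) -> 2.5
  b <- md(801)
  expect_true(b[1] <= 2.5 && 2.5 <= b[2])
  # density integrates to 1
  m <- metagene_density(c(mk(151), mk(201), mk(801), mk(450)), ann)
  expect_equal(sum(m$curves$all) * 3 / 60, 1, tolerance = 1e-9)
  # intronic midpoint matches no transcript region -> skipped
  expect_equal(m$n_skipped, 1)
})

test_that("relative and metagene coordinates are strand-mirror invariant", {
  toy <- build_toy_annotation(12, n_chroms = 1, seed = 97)
  annf <- filter_transcripts(toy$annotation)
  L <- max(annf$genes$end) + 100L

  annm <- mirror_annotation(annf, L)
  regs <- transcript_regions(annf)
  # events at deterministic exonic positions of each coding transcript
  pts <- unlist(lapply(regs, function(r)
    if (r$coding && nrow(r$utr5)) r$utr5$start[1] + 2L else NULL))
  gr <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(pts, pts + 4L),
    strand = annf$transcripts$strand[match(
      names(pts), annf$transcripts$transcript_id)])
  m1 <- metagene_density(gr, annf, n_bins = 30)
  m2 <- metagene_density(mirror_granges(gr, L), annm, n_bins = 30)
  expect_equal(m1$curves$all, m2$curves$all, tolerance = 1e-12)
  expect_equal(m1$n_skipped, m2$n_skipped)
})
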