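test_that("generators are seed-deterministic", {
  a <- build_toy_annotation(15, seed = 5)
  b <- build_toy_annotation(15, seed = 5)
  expect_identical(a$annotation$genes, b$annotation$genes)
  expect_identical(as.character(a$sequences), as.character(b$sequences))

  r1 <- build_snorna_registry(seed = 9)
  r2 <- build_snorna_registry(seed = 9)
  expect_identical(r1, r2)

  s1 <- simulate_counts(a$annotation, seed = 3)
  s2 <- simulate_counts(a$annotation, seed = 3)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)

  annf <- filter_transcripts(a$annotation)
  w1 <- simulate_window_scores(r1, annf, a$annotation$genes$gene_id[1:3],
                               seed = 4)
  w2 <- simulate_window_scores(r1, annf, a$annotation$genes$gene_id[1:3],
                               seed = 4)
  expect_identical(w1$windows, w2$windows)
})

test_that("snoRNA registry has the canonical copy and group structure", {
  reg <- build_snorna_registry(seed = 1)
  expect_equal(sum(reg$cluster == "SNORD116"), 30)
  expect_equal(sum(reg$cluster == "SNORD115"), 48)
  grp <- table(reg$group[reg$cluster == "SNORD116"])
  expect_equal(as.integer(grp[c("I", "II", "III")]), c(9, 15, 6))
  expect_true(all(is.na(reg$group[reg$cluster == "SNORD115"])))
  # box order along 5'->3' is C < D' < C' < D, all within the copy
  expect_true(all(reg$box_c_start >= 1))
  expect_true(all(reg$box_c_end < reg$box_dprime_start))
  expect_true(all(reg$box_dprime_end < reg$box_cprime_start))
  expect_true(all(reg$box_cprime_end < reg$box_d_start))
  expect_true(all(reg$box_d_end <= reg$length))
  # ASE2 sits strictly between C' and D
  a2 <- ase2_intervals(reg)
  expect_true(all(a2$ase2_start > reg$box_cprime_end))
  expect_true(all(a2$ase2_end < reg$box_d_start))
})

test_that("realized gene GC tracks the target", {
  toy <- build_toy_annotation(12, n_chroms = 1, gc_targets = 0.60,
                              seed = 21)
  g <- toy$annotation$genes
  seqs <- toy$sequences
  # the +/-0.05 band is a claim about genes of kb scale, where the binomial
  # sampling error is several-fold smaller than the band
  long <- which(g$end - g$start + 1 >= 1000)
  expect_gte(length(long), 3)
  gc <- vapply(long, function(i) {
    s <- Biostrings::subseq(seqs[[g$chrom[i]]], g$start[i], g$end[i])
    sum(Biostrings::letterFrequency(s, c("G", "C"))) / length(s)
  }, numeric(1))
  expect_true(all(gc >= 0.55 & gc <= 0.65))
  expect_error(build_toy_annotation(3, gc_targets = 1.2), "GC target")
})

test_that("planted log2 fold changes are realized in NB counts", {
  toy <- build_toy_annotation(600, n_chroms = 1, seed = 31)
  sim <- simulate_counts(toy$annotation, n_reps = 6,
                         truth_params = list(prop_shared_up = 0.4,
                                             prop_shared_down = 0,
                                             prop_background_specific = 0,
                                             lfc = 1, dispersion = 0.05,
                                             mu_range = c(100, 2000)),
                         seed = 32)
  planted <- sim$truth$gene_id[sim$truth$status == "shared_up"]
  expect_gte(length(planted), 200)
  wt <- sim$samples$sample_id[sim$samples$genotype == "WT"]
  del <- sim$samples$sample_id[sim$samples$genotype != "WT"]
  mu <- sim$truth$mu[match(planted, sim$truth$gene_id)]
  # lfc = 1 -> planted-group mean doubles the baseline mean
  ratio <- rowMeans(sim$counts[planted, del]) / mu
  expect_gte(mean(ratio >= 1.7 & ratio <= 2.3), 0.95)
  # wild-type samples stay at baseline
  rwt <- rowMeans(sim$counts[planted, wt]) / mu
  expect_lt(abs(mean(rwt) - 1), 0.05)
  # null genes: deletion/WT count ratio centred on 1
  nulls <- sim$truth$gene_id[sim$truth$status == "null"]
  rnull <- rowMeans(sim$counts[nulls, del]) / rowMeans(sim$counts[nulls, wt])
  expect_lt(abs(mean(rnull) - 1), 0.05)
  expect_error(simulate_counts(toy$annotation,
                               truth_params = list(dispersion = 0)),
               "dispersion")
})

test_that("DE tables realize the requested power and FDR structure", {
  toy <- build_toy_annotation(300, n_chroms = 1, seed = 41)
  sim <- simulate_counts(toy$annotation, seed = 42)
  # power 1: every planted shared gene significant in every design
  de1 <- simulate_de_tables(sim$truth, power = 1, seed = 43)
  planted <- sim$truth$gene_id[sim$truth$status %in%
                                 c("shared_up", "shared_down")]
  for (m in names(de1)) for (d in names(de1[[m]])) {
    tab <- de1[[m]][[d]]
    expect_true(all(tab$padj[tab$gene_id %in% planted] < 0.05))
    # planted signs match the truth
    sg <- sign(tab$log2FoldChange[match(planted, tab$gene_id)])
    expect_identical(sg, sign(sim$truth$lfc_smDEL[match(
      planted, sim$truth$gene_id)]))
  }
  # power 0: planted genes indistinguishable from null (uniform p)
  de0 <- simulate_de_tables(sim$truth, power = 0, seed = 44)
  pv <- de0$smDEL$bg_shared$pvalue[de0$smDEL$bg_shared$gene_id %in% planted]
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})

test_that("BH over simulated null tables controls the false-positive rate", {
  truth <- data.frame(gene_id = paste0("g", 1:10000), status = "null",
                      lfc_smDEL = 0, lfc_lgDEL = 0,
                      specific_background = NA_character_,
                      is_planted_target = FALSE, stringsAsFactors = FALSE)
  de <- simulate_de_tables(truth, power = 1, seed = 45,
                           models = "smDEL", designs = "condition_only")
  fp <- mean(de$smDEL$condition_only$padj < 0.05, na.rm = TRUE)
  se <- sqrt(0.05 * 0.95 / 10000)
  expect_lte(fp, 0.05 + 3 * se)
})

test_that("window simulator plants merge-recoverable runs and nothing else", {
  toy <- build_toy_annotation(20, n_chroms = 1, seed = 51)
  annf <- filter_transcripts(toy$annotation)
  reg <- build_snorna_registry(seed = 1)
  tg <- annf$genes$gene_id[1:4]

  # zero planted events, background only -> no merged interactions
  ws0 <- simulate_window_scores(reg, annf, tg, enrichment_fold = 1,
                                params = list(base_rate = 0), seed = 52)
  expect_true(all(ws0$windows$score < 0.98))
  expect_equal(nrow(merge_consecutive_windows(ws0$windows)), 0)

  # runs of exactly 3 windows merge to one interaction each
  ws3 <- simulate_window_scores(reg, annf, tg, enrichment_fold = 1,
                                params = list(base_rate = 2,
                                              run_extra_lambda = 0,
                                              noise_windows = 0), seed = 53)
  expect_true(all(ws3$events$n_windows == 3))
  iv <- merge_consecutive_windows(ws3$windows)
  expect_true(all(iv$n_windows == 3))
  # every merged event is a planted event (by copy, gene and position)
  key_iv <- paste(iv$sno_id, iv$target_gene_id, iv$sno_start,
                  iv$target_start)
  key_ev <- paste(ws3$events$copy_id, ws3$events$gene_id,
                  ws3$events$sno_start, ws3$events$target_start)
  expect_true(all(key_iv %in% key_ev))
  expect_error(simulate_window_scores(reg, annf, tg, enrichment_fold = 0.5),
               "enrichment_fold")
})
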