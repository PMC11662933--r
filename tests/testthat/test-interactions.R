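win_row <- function(sno_start, target_start, score, sno_id = "SNORD116-25",
                    gene = "G1", chrom = "chr1", strand = "+", wl = 13L) {
  data.frame(sno_id = sno_id, sno_start = sno_start, target_gene_id = gene,
             target_chrom = chrom, target_start = target_start,
             strand = strand, score = score, window_length = wl,
             stringsAsFactors = FALSE)
}

run_vector <- function(scores, strand = "+", start = 10L, t0 = 100L) {
  # windows advancing jointly by 1 nt on snoRNA and (stranded) target
  n <- length(scores)
  dir <- if (strand == "+") 1L else -1L
  win_row(start + seq_len(n) - 1L, t0 + dir * (seq_len(n) - 1L), scores,
          strand = strand)
}

test_that("consecutive-window rule merges runs of >= 3 at score >= 0.98", {
  iv <- merge_consecutive_windows(run_vector(c(0.99, 0.985, 0.99)))
  expect_equal(nrow(iv), 1)
  expect_equal(iv$n_windows, 3)
  # run extent covers all windows plus the window length
  expect_equal(iv$sno_end - iv$sno_start + 1, 13 + 2)
  expect_equal(iv$target_end - iv$target_start + 1, 13 + 2)

  # two windows never qualify
  expect_equal(nrow(merge_consecutive_windows(run_vector(c(0.99, 0.99)))), 0)

  # a sub-threshold window splits the run; only the trailing 3 survive
  iv <- merge_consecutive_windows(
    run_vector(c(0.99, 0.97, 0.99, 0.99, 0.99)))
  expect_equal(nrow(iv), 1)
  expect_equal(iv$n_windows, 3)
  expect_equal(iv$sno_start, 12)   # third window of the vector

  # threshold is inclusive: score exactly 0.98 counts
  iv <- merge_consecutive_windows(run_vector(c(0.98, 0.98, 0.98)))
  expect_equal(nrow(iv), 1)
  expect_equal(iv$min_score, 0.98)

  # a maximal run of 5 is ONE interaction, not three overlapping ones
  iv <- merge_consecutive_windows(run_vector(rep(0.99, 5)))
  expect_equal(nrow(iv), 1)
  expect_equal(iv$n_windows, 5)
})

test_that("strand determines the direction of target advancement", {
  # on "-", target coordinates decrease as the snoRNA position advances
  iv <- merge_consecutive_windows(run_vector(rep(0.99, 4), strand = "-"))
  expect_equal(nrow(iv), 1)
  expect_equal(iv$n_windows, 4)
  # windows advancing the wrong way on "-" do not chain
  w <- run_vector(rep(0.99, 4), strand = "+")
  w$strand <- "-"
  expect_equal(nrow(merge_consecutive_windows(w)), 0)
})

test_that("interleaved duplexes on one snoRNA-gene pair stay separate", {
  w <- rbind(run_vector(rep(0.99, 3), start = 10L, t0 = 100L),
             run_vector(rep(0.99, 3), start = 11L, t0 = 500L))
  iv <- merge_consecutive_windows(w)
  expect_equal(nrow(iv), 2)
  expect_setequal(iv$target_start, c(100, 500))
})

test_that("duplicate rows collapse; conflicting scores are an error", {
  w <- run_vector(rep(0.99, 3))
  expect_equal(nrow(merge_consecutive_windows(rbind(w, w))), 1)
  w2 <- rbind(w, transform(w[1, ], score = 0.985))
  expect_error(merge_consecutive_windows(w2), "conflicting")
})

test_that("merge agrees with a brute-force maximal-run enumerator", {
  set.seed(17)
  for (i in 1:200) {
    n <- sample(1:50, 1)
    strand <- sample(c("+", "-"), 1)
    dir <- if (strand == "+") 1L else -1L
    sno <- sort(sample(1:60, n))
    w <- win_row(sno, 300L + dir * sno + sample(c(0L, 0L, 5L), n, TRUE),
                 score = round(runif(n, 0.9, 1), 4), strand = strand)
    w <- w[!duplicated(w[c("sno_start", "target_start")]), ]
    iv <- merge_consecutive_windows(w)
    runs <- brute_force_runs(w)
    expect_equal(nrow(iv), length(runs))
    if (length(runs)) {
      got <- iv[order(iv$sno_start, iv$target_start), ]
      want <- t(vapply(runs, function(r)
        c(min(r$sno_start), length(r$sno_start)), numeric(2)))
      want <- want[order(want[, 1]), , drop = FALSE]
      expect_equal(got$sno_start, unname(want[, 1]))
      expect_equal(got$n_windows, unname(want[, 2]))
    }
  }
})

test_that("raising the threshold or run length never adds interactions", {
  set.seed(19)
  w <- do.call(rbind, lapply(1:30, function(i)
    run_vector(round(runif(sample(3:8, 1), 0.95, 1), 4),
               start = sample(1:60, 1) + 0L,
               t0 = sample(1:5000, 1) + 0L)))
  w <- w[!duplicated(w[c("sno_start", "target_start")]), ]
  n_t <- vapply(c(0.95, 0.97, 0.98, 0.99),
                function(t) nrow(merge_consecutive_windows(
                  w, score_threshold = t)), numeric(1))
  expect_true(all(diff(n_t) <= 0))
  n_w <- vapply(2:6, function(k) nrow(merge_consecutive_windows(
    w, min_run = k)), numeric(1))
  expect_true(all(diff(n_w) <= 0))
})

test_that("debug flag exposes constituent windows, all above threshold", {
  w <- rbind(run_vector(c(0.99, 0.985, 0.99, 0.2)),
             run_vector(rep(0.995, 3), start = 40L, t0 = 700L))
  iv <- merge_consecutive_windows(w, keep_windows = TRUE)
  rows <- attr(iv, "window_rows")
  expect_equal(length(rows), nrow(iv))
  for (i in seq_along(rows)) {
    expect_true(all(w$score[rows[[i]]] >= 0.98))
    expect_equal(length(rows[[i]]), iv$n_windows[i])
  }
})

test_that("event counting tallies per copy and per group with zeros", {
  reg <- build_snorna_registry(seed = 1)
  g3 <- reg$copy_id[reg$cluster == "SNORD116" & !is.na(reg$group) &
                      reg$group == "III"]
  iv <- do.call(rbind, lapply(rep(g3, 5), function(cp)
    merge_consecutive_windows(run_vector(rep(0.99, 3), start = 20L,
                                         t0 = sample(1:1000, 1) + 0L))))
  iv$sno_id <- rep(g3, 5)
  ce <- count_events(iv, reg)
  expect_equal(sum(ce$per_copy$n_events), 30)
  pg <- ce$per_group
  expect_equal(pg$mean_per_copy[pg$group == "SNORD116-III"], 5)
  expect_equal(pg$total_events[pg$group == "SNORD116-I"], 0)
  expect_equal(pg$n_copies[pg$group == "SNORD115"], 48)

  # no events -> all zeros
  ce0 <- count_events(iv[0, ], reg)
  expect_true(all(ce0$per_copy$n_events == 0))

  # random assignment equals a brute-force tally
  set.seed(23)
  iv$sno_id <- sample(reg$copy_id, nrow(iv), replace = TRUE)
  ce2 <- count_events(iv, reg)
  brute <- vapply(reg$copy_id, function(cp) sum(iv$sno_id == cp),
                  numeric(1))
  expect_equal(ce2$per_copy$n_events, unname(as.integer(brute)))
  iv$sno_id[1] <- "SNORD999-1"
  expect_error(count_events(iv, reg), "unknown sno_id")
})
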