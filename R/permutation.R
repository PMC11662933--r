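#' Observed directional overlap between two DEG sets
#'
#' @param a,b [degset] objects.
#' @return list with n_up_shared, n_down_shared and n_total.
#' @export
observed_overlap <- function(a, b) {
  up <- length(intersect(a$up, b$up))
  down <- length(intersect(a$down, b$down))
  list(n_up_shared = up, n_down_shared = down, n_total = up + down)
}

#' Null distribution of directional overlaps by list shuffling
#'
#' Emulates the shuffled-list null: per replicate each side's gene list is
#' shuffled, the first `n_up` genes are designated upregulated and the last
#' `n_down` downregulated (matching that side's observed DEG counts, with
#' up/down disjoint by construction), and the replicate value is the number
#' of genes designated up on both sides plus the number designated down on
#' both sides. By default the shuffled list is the side's full tested-gene
#' universe; pass the significant lists as universes to shuffle those
#' instead.
#'
#' @param universe_a,universe_b character vectors to shuffle.
#' @param n_up_a,n_down_a,n_up_b,n_down_b designated counts per side.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed; identical seeds give identical null vectors.
#' @return integer vector of length `n_perm`.
#' @export
permuted_overlaps <- function(universe_a, n_up_a, n_down_a,
                              universe_b, n_up_b, n_down_b,
                              n_perm = 10000, seed = NULL) {
  na <- length(universe_a); nb <- length(universe_b)
  assert_that(n_up_a + n_down_a <= na && n_up_b + n_down_b <= nb,
              "designated up+down counts exceed a universe size")
  map <- match(universe_a, universe_b)
  ka <- n_up_a + n_down_a
  kb <- n_up_b + n_down_b
  with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      # drawing k items without replacement and splitting first/last blocks
      # is distributionally identical to a full shuffle's head and tail
      ia <- sample.int(na, ka)
      ib <- sample.int(nb, kb)
      up_b <- logical(nb); dn_b <- logical(nb)
      if (n_up_b > 0) up_b[ib[seq_len(n_up_b)]] <- TRUE
      if (n_down_b > 0) dn_b[ib[kb - seq_len(n_down_b) + 1L]] <- TRUE
      ma_up <- if (n_up_a > 0) map[ia[seq_len(n_up_a)]] else integer(0)
      ma_dn <- if (n_down_a > 0) map[ia[ka - seq_len(n_down_a) + 1L]] else
        integer(0)
      sum(up_b[ma_up[!is.na(ma_up)]]) + sum(dn_b[ma_dn[!is.na(ma_dn)]])
    }, numeric(1))
  })
}

#' Summarize a permutation test
#'
#' Applies the two permutation p-value formulas: when at least one permuted
#' value reaches the observed value, p = (number of permuted values >= the
#' observed value) / (number of permutations); when none does, p is reported
#' as the upper bound 1 / (number of permutations) with `p_is_floor = TRUE`.
#' The enrichment value is the observed overlap divided by the median of the
#' permuted overlaps (infinite, with a flag, when that median is zero).
#'
#' @param observed observed statistic.
#' @param null_values numeric vector of permuted statistics.
#' @param n_perm number of permutations (defaults to the null length).
#' @return object of class `permutation_summary`: observed, null_values,
#'   n_perm, fold, null_median, zero_null_median, p_value, p_is_floor.
#' @export
summarize_permutation <- function(observed, null_values,
                                  n_perm = length(null_values)) {
  assert_that(n_perm > 0, "n_perm must be positive")
  assert_that(length(null_values) == n_perm,
              "null vector length must equal n_perm")
  n_ge <- sum(null_values >= observed)
  p_is_floor <- n_ge == 0
  p_value <- if (p_is_floor) 1 / n_perm else n_ge / n_perm
  med <- median(null_values)
  zero_med <- med == 0
  fold <- if (zero_med) Inf else observed / med
  structure(list(observed = observed, null_values = null_values,
                 n_perm = n_perm, fold = fold, null_median = med,
                 zero_null_median = zero_med, p_value = p_value,
                 p_is_floor = p_is_floor),
            class = "permutation_summary")
}

#' @export
print.permutation_summary <- function(x, ...) {
  cat(sprintf("permutation test: observed %g, null median %g, fold %.3g, %s%g (n_perm = %d)\n",
              x$observed, x$null_median, x$fold,
              if (x$p_is_floor) "p < " else "p = ", x$p_value, x$n_perm))
  invisible(x)
}

#' Directional overlap permutation test between two DEG sets
#'
#' Convenience wrapper: observed directional overlap via
#' [observed_overlap()], null via [permuted_overlaps()] with each side's
#' observed up/down counts, summarized by [summarize_permutation()].
#'
#' @param a,b [degset] objects.
#' @param n_perm permutations (default 10000).
#' @param shuffle "universe" (default) shuffles each side's tested-gene
#'   universe; "significant" shuffles only the pooled significant list.
#' @param seed integer seed.
#' @return a `permutation_summary` with an `observed_detail` element.
#' @export
overlap_permutation_test <- function(a, b, n_perm = 10000,
                                     shuffle = c("universe", "significant"),
                                     seed = NULL) {
  shuffle <- match.arg(shuffle)
  obs <- observed_overlap(a, b)
  ua <- if (shuffle == "universe") a$universe else union(a$up, a$down)
  ub <- if (shuffle == "universe") b$universe else union(b$up, b$down)
  null <- permuted_overlaps(ua, length(a$up), length(a$down),
                            ub, length(b$up), length(b$down),
                            n_perm = n_perm, seed = seed)
  out <- summarize_permutation(obs$n_total, null, n_perm)
  out$observed_detail <- obs
  out
}
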