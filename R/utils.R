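#' @importFrom stats median p.adjust phyper rnbinom rnorm rpois runif
#'   setNames wilcox.test ks.test
#' @importFrom utils head tail
NULL

# lets data.table's `[` NSE work from this namespace
.datatable.aware <- TRUE

# Seed discipline: every stochastic entry point takes `seed`; NULL leaves the
# RNG stream untouched so callers can manage their own stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, seed == floor(seed))
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic sub-seed derivation, kept inside 32-bit integer range.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 7919L + as.integer(k) * 104729L) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Plain-integer interval algebra on data.frames with start/end columns
# (1-based closed). Kept dependency-free because it runs in tight per-
# transcript loops where S4 dispatch dominates runtime.
iv_df <- function(start = integer(0), end = integer(0)) {
  data.frame(start = as.integer(start), end = as.integer(end))
}

iv_merge <- function(x) {
  if (nrow(x) <= 1) return(x[order(x$start), , drop = FALSE])
  x <- x[order(x$start, x$end), , drop = FALSE]
  s <- x$start; e <- x$end
  out_s <- s[1]; out_e <- e[1]
  for (i in 2:nrow(x)) {
    if (s[i] <= out_e[length(out_e)] + 1L) {
      out_e[length(out_e)] <- max(out_e[length(out_e)], e[i])
    } else {
      out_s <- c(out_s, s[i]); out_e <- c(out_e, e[i])
    }
  }
  iv_df(out_s, out_e)
}

iv_setdiff <- function(a, b) {
  # a, b merged/sorted; returns a minus b
  if (nrow(a) == 0 || nrow(b) == 0) return(a)
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_len(nrow(a))) {
    s <- a$start[i]; e <- a$end[i]
    for (j in seq_len(nrow(b))) {
      bs <- b$start[j]; be <- b$end[j]
      if (be < s || bs > e) next
      if (bs > s) { out_s <- c(out_s, s); out_e <- c(out_e, bs - 1L) }
      s <- be + 1L
      if (s > e) break
    }
    if (s <= e) { out_s <- c(out_s, s); out_e <- c(out_e, e) }
  }
  iv_df(out_s, out_e)
}

iv_width <- function(x) if (nrow(x) == 0) 0L else
  sum(x$end - x$start + 1L)

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
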