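#' Simulate an RNA-seq count matrix for the isogenic deletion design
#'
#' Negative-binomial counts (variance = mu + alpha * mu^2) over a
#' 2-background x 3-genotype design with planted effects: "shared" genes are
#' perturbed with the stated log2 fold change in both backgrounds and both
#' deletion genotypes; "background-specific" genes are perturbed in the
#' deletion genotypes of exactly one background; null genes are unperturbed.
#'
#' @param annotation a [snord_annotation] supplying gene ids (or a character
#'   vector of gene ids).
#' @param n_reps biological replicates per background x genotype cell
#'   (default 6, the upper end of the 5-6 used in inducible-neuron designs).
#' @param truth_params list with elements prop_shared_up, prop_shared_down,
#'   prop_background_specific, lfc (planted |log2FC|), mu_range (baseline
#'   mean range, log-uniform), dispersion (NB alpha).
#' @param seed integer seed.
#' @return list with `counts` (gene x sample integer matrix), `samples`
#'   (data.frame background/genotype/replicate) and `truth` (data.frame
#'   gene_id, status, lfc_smDEL, lfc_lgDEL, specific_background,
#'   is_planted_target, mu -- the baseline NB mean).
#' @export
simulate_counts <- function(annotation, n_reps = 6,
                            truth_params = list(), seed = NULL) {
  p <- utils::modifyList(list(prop_shared_up = 0.03, prop_shared_down = 0.03,
                              prop_background_specific = 0.04, lfc = 1,
                              mu_range = c(20, 2000), dispersion = 0.05),
                         truth_params)
  assert_that(p$dispersion > 0, "invalid dispersion <= 0")
  assert_that(n_reps >= 2, "n_reps must be >= 2")
  gene_ids <- if (inherits(annotation, "snord_annotation"))
    annotation$genes$gene_id else as.character(annotation)
  n <- length(gene_ids)
  with_seed(seed, {
    status <- rep("null", n)
    n_up <- round(p$prop_shared_up * n)
    n_dn <- round(p$prop_shared_down * n)
    n_bg <- round(p$prop_background_specific * n)
    pick <- sample.int(n, n_up + n_dn + n_bg)
    status[pick[seq_len(n_up)]] <- "shared_up"
    status[pick[n_up + seq_len(n_dn)]] <- "shared_down"
    status[pick[n_up + n_dn + seq_len(n_bg)]] <- "background_specific"
    spec_bg <- rep(NA_character_, n)
    spec_bg[status == "background_specific"] <-
      sample(c("H9", "CT2"), n_bg, replace = TRUE)
    lfc <- ifelse(status == "shared_up", p$lfc,
                  ifelse(status == "shared_down", -p$lfc,
                         ifelse(status == "background_specific",
                                sample(c(-p$lfc, p$lfc), n, replace = TRUE),
                                0)))
    mu0 <- exp(runif(n, log(p$mu_range[1]), log(p$mu_range[2])))
    truth <- data.frame(gene_id = gene_ids, status = status,
                        lfc_smDEL = lfc, lfc_lgDEL = lfc,
                        specific_background = spec_bg,
                        is_planted_target = FALSE, mu = mu0,
                        stringsAsFactors = FALSE)
    samples <- expand.grid(replicate = seq_len(n_reps),
                           genotype = c("WT", "smDEL", "lgDEL"),
                           background = c("H9", "CT2"),
                           stringsAsFactors = FALSE)
    samples <- samples[, c("background", "genotype", "replicate")]
    samples$sample_id <- with(samples,
                              paste(background, genotype, replicate,
                                    sep = "_"))
    counts <- matrix(0L, n, nrow(samples),
                     dimnames = list(gene_ids, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      eff <- rep(0, n)
      if (samples$genotype[j] != "WT") {
        on <- status %in% c("shared_up", "shared_down") |
          (status == "background_specific" &
             spec_bg == samples$background[j] & !is.na(spec_bg))
        eff[on] <- lfc[on]
      }
      counts[, j] <- rnbinom(n, mu = mu0 * 2^eff, size = 1 / p$dispersion)
    }
    list(counts = counts, samples = samples, truth = truth)
  })
}

#' Simulate differential-expression result tables from planted truth
#'
#' Parametric stand-in for an external DE engine: for each of the three
#' per-model designs ("bg_shared": DEGs reproducible across the two
#' per-background pairwise analyses; "interaction": background + condition +
#' interaction design; "condition_only": pooled condition design), planted
#' genes receive a near-zero p-value (hence padj < 0.05 after BH) with
#' probability `power`, independently per design; all other p-values are
#' uniform, and padj is BH over the whole table. Planted log2 fold changes
#' carry the true sign. Background-specific genes reach significance only in
#' the pooled "condition_only" design, reflecting dilution of one-background
#' effects across backgrounds, so they cannot survive a three-design
#' consensus. This is not an emulation of any specific DE tool.
#'
#' @param truth truth data.frame from [simulate_counts()] (or compatible).
#' @param power per-design probability that a planted gene is significant.
#' @param seed integer seed.
#' @param models,designs character vectors naming the tables to emit.
#' @return Nested named list: `tables[[model]][[design]]` is a data.frame
#'   with gene_id, baseMean, log2FoldChange, pvalue, padj.
#' @export
simulate_de_tables <- function(truth, power = 1, seed = NULL,
                               models = c("smDEL", "lgDEL"),
                               designs = c("bg_shared", "interaction",
                                           "condition_only")) {
  assert_that(power >= 0 && power <= 1, "power must be in [0, 1]")
  n <- nrow(truth)
  with_seed(seed, {
    out <- list()
    base_mean <- exp(rnorm(n, log(200), 1))
    for (m in models) {
      lfc_true <- truth[[paste0("lfc_", m)]]
      out[[m]] <- list()
      for (d in designs) {
        planted <- truth$status %in% c("shared_up", "shared_down")
        if (d == "condition_only") {
          planted <- planted | truth$status == "background_specific"
        }
        hit <- planted & runif(n) < power
        pvalue <- runif(n)
        pvalue[hit] <- runif(sum(hit), 0, 1e-9)
        padj <- p.adjust(pvalue, method = "BH")
        lfc <- rnorm(n, 0, 0.3)
        lfc[planted] <- sign(lfc_true[planted]) *
          pmax(0.1, abs(lfc_true[planted] + rnorm(sum(planted), 0, 0.1)))
        out[[m]][[d]] <- data.frame(gene_id = truth$gene_id,
                                    baseMean = base_mean,
                                    log2FoldChange = lfc,
                                    pvalue = pvalue, padj = padj,
                                    stringsAsFactors = FALSE)
      }
    }
    out
  })
}
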