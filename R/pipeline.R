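#' Default pipeline parameters
#'
#' Study-condition defaults for the synthetic end-to-end run: a
#' 2-background x 3-genotype x 6-replicate design, padj < 0.05 significance,
#' the 0.98 / 3-consecutive-window merge rule, 10 000 overlap permutations
#' scaled to `n_perm`, 100 covariate-matched control lists and a planted
#' 2.5-fold group-III targeting enrichment.
#'
#' @return named list of parameters.
#' @export
default_pipeline_params <- function() {
  list(n_genes = 800, n_chroms = 3, n_reps = 6, power = 0.9,
       padj_lt = 0.05, min_mean = 1,
       n_perm = 2000, shuffle = "universe",
       score_threshold = 0.98, min_run = 3,
       k_lists = 100, match_alpha = 0.05,
       enrichment_fold = 2.5,
       truth_params = list(), window_params = list(),
       n_bins = 60)
}

#' Run the full synthetic analysis pipeline
#'
#' Generates all inputs (annotation + sequence, snoRNA registry, counts, DE
#' tables, window scores), then runs every downstream stage: low-count
#' filter, significance filter, three-design consensus per deletion model,
#' cross-model shared genes, the directional overlap permutation test,
#' consecutive-window merging and per-copy/group event counts,
#' covariate-matched control enrichment of group-III targeting, snoRNA-side
#' box-relative profiles, target-side feature coverage and metagene density,
#' and a gene-set over-representation check against synthetic collections.
#' Writes per-stage TSVs and a machine-readable JSON summary; fully
#' deterministic given `seed`.
#'
#' @param out_dir output directory (created if missing); NULL skips writing.
#' @param seed integer master seed; all stage seeds derive from it.
#' @param params overrides of [default_pipeline_params()].
#' @return (invisibly) list with all stage objects and `summary` (the JSON
#'   payload).
#' @export
run_pipeline <- function(out_dir = NULL, seed = 1, params = list()) {
  p <- utils::modifyList(default_pipeline_params(), params)
  t0 <- Sys.time()
  log_stage <- function(...) message(sprintf(...))

  # --- synthetic inputs ------------------------------------------------
  toy <- build_toy_annotation(p$n_genes, n_chroms = p$n_chroms,
                              seed = derive_seed(seed, 1))
  ann <- toy$annotation
  registry <- build_snorna_registry(seed = derive_seed(seed, 2))
  sim <- simulate_counts(ann, n_reps = p$n_reps,
                         truth_params = p$truth_params,
                         seed = derive_seed(seed, 3))
  log_stage("synthetic: %d genes, %d samples", nrow(sim$truth),
            ncol(sim$counts))

  # --- DEG consensus ---------------------------------------------------
  kept <- filter_low_counts(sim$counts, min_mean = p$min_mean)
  truth <- sim$truth[sim$truth$gene_id %in% kept, , drop = FALSE]
  de <- simulate_de_tables(truth, power = p$power,
                           seed = derive_seed(seed, 4))
  consensus <- lapply(names(de), function(m) {
    sets <- lapply(names(de[[m]]), function(d)
      significant_degs(de[[m]][[d]], padj_lt = p$padj_lt,
                       contrast_id = paste(m, d, sep = ":")))
    consensus_across_designs(sets, contrast_id = paste0(m, ":consensus"))
  })
  names(consensus) <- names(de)
  shared <- shared_across_models(consensus$smDEL, consensus$lgDEL,
                                 mode = "concordant")
  planted_shared <- truth$gene_id[truth$status %in%
                                    c("shared_up", "shared_down")]
  recall <- if (length(planted_shared))
    length(intersect(shared, planted_shared)) / length(planted_shared) else
      NA_real_
  log_stage("consensus: %d smDEL, %d lgDEL, %d shared (recall %.3f)",
            length(union(consensus$smDEL$up, consensus$smDEL$down)),
            length(union(consensus$lgDEL$up, consensus$lgDEL$down)),
            length(shared), recall)

  # --- overlap permutation test ---------------------------------------
  perm <- overlap_permutation_test(consensus$smDEL, consensus$lgDEL,
                                   n_perm = p$n_perm, shuffle = p$shuffle,
                                   seed = derive_seed(seed, 5))

  # --- window scores, merge, event counts ------------------------------
  ann_f <- filter_transcripts(ann)
  target_genes <- shared
  ws <- simulate_window_scores(registry, ann_f, target_genes,
                               enrichment_fold = p$enrichment_fold,
                               params = p$window_params,
                               seed = derive_seed(seed, 6))
  inter <- merge_consecutive_windows(ws$windows,
                                     score_threshold = p$score_threshold,
                                     min_run = p$min_run)
  counts_ev <- count_events(inter, registry)
  log_stage("interactions: %d windows -> %d events", nrow(ws$windows),
            nrow(inter))

  # --- matched-control enrichment (group III) --------------------------
  neuron_samples <- sim$samples$sample_id[sim$samples$genotype != "WT"]
  cov <- compute_covariates(ann$genes$gene_id, ann_f, toy$sequences,
                            sim$counts, neuron_samples)
  matched <- sample_matched_lists(target_genes, cov, k = p$k_lists,
                                  alpha = p$match_alpha,
                                  seed = derive_seed(seed, 7))
  g3 <- inter$sno_id %in% registry$copy_id[registry$cluster == "SNORD116" &
                                             !is.na(registry$group) &
                                             registry$group == "III"]
  ev_g3 <- table(inter$target_gene_id[g3])
  per_gene_events <- setNames(as.integer(ev_g3), names(ev_g3))
  enr <- enrichment_vs_controls(target_genes, matched, per_gene_events)
  log_stage("matched enrichment: fold(sum) %.2f, p %.3g",
            enr$fold[enr$stat == "sum"], enr$p_value[enr$stat == "sum"])

  # --- positional analyses ---------------------------------------------
  pos <- sno_relative_positions(inter, registry)
  fs <- build_feature_space(ann_f, gene_ids = target_genes)
  target_inter <- inter[inter$target_gene_id %in% target_genes, ,
                        drop = FALSE]
  covg <- classify_intervals(target_inter, fs)
  grp_lab <- ifelse(is.na(registry$group), registry$cluster,
                    paste0(registry$cluster, "-", registry$group))
  mg <- metagene_density(
    target_inter, ann_f, n_bins = p$n_bins,
    groups = grp_lab[match(target_inter$sno_id, registry$copy_id)])

  # --- over-representation against synthetic collections ---------------
  universe <- truth$gene_id
  set.seed(derive_seed(seed, 8))
  collections <- list(
    planted_shared = planted_shared,
    random_a = sample(universe, min(80, length(universe))),
    random_b = sample(universe, min(120, length(universe))))
  gse <- gene_set_enrichment(shared, collections, universe)

  summary <- list(
    seed = seed,
    params = p[c("n_genes", "n_reps", "power", "padj_lt", "n_perm",
                 "score_threshold", "min_run", "k_lists", "match_alpha",
                 "enrichment_fold")],
    n_genes_kept = length(kept),
    n_consensus_smdel = length(union(consensus$smDEL$up,
                                     consensus$smDEL$down)),
    n_consensus_lgdel = length(union(consensus$lgDEL$up,
                                     consensus$lgDEL$down)),
    n_shared_genes = length(shared),
    shared_recall = recall,
    overlap_observed = perm$observed,
    overlap_null_median = perm$null_median,
    overlap_fold = perm$fold,
    overlap_p = perm$p_value,
    overlap_p_is_floor = perm$p_is_floor,
    n_windows = nrow(ws$windows),
    n_events = nrow(inter),
    group3_mean_events_per_copy = counts_ev$per_group$mean_per_copy[
      counts_ev$per_group$group == "SNORD116-III"],
    matched_fold_sum = enr$fold[enr$stat == "sum"],
    matched_p_sum = enr$p_value[enr$stat == "sum"],
    matched_fold_mean = enr$fold[enr$stat == "mean"],
    matched_fold_median = enr$fold[enr$stat == "median"],
    utr5_event_fraction = unname(covg$tier2[["5'UTR"]] +
                                   covg$tier2[["5'UTR+CDS"]]),
    utr5_background_fraction = unname(fs$background$tier2[["5'UTR"]]),
    metagene_utr5_mass = sum(mg$curves$all[mg$bins$bin_hi <= 1]) *
      (3 / p$n_bins),
    planted_set_padj = gse$padj[gse$set_id == "planted_shared"],
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  result <- list(annotation = ann, registry = registry, sim = sim, de = de,
                 consensus = consensus, shared = shared, permutation = perm,
                 windows = ws, interactions = inter,
                 event_counts = counts_ev, covariates = cov,
                 matched = matched, enrichment = enr, positions = pos,
                 feature_space = fs, coverage = covg, metagene = mg,
                 gse = gse, summary = summary)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fw <- function(x, f) data.table::fwrite(x, file.path(out_dir, f),
                                            sep = "\t", quote = FALSE)
    fw(data.frame(gene_id = shared), "shared_genes.tsv")
    fw(counts_ev$per_copy, "events_per_copy.tsv")
    fw(counts_ev$per_group, "events_per_group.tsv")
    fw(enr, "matched_enrichment.tsv")
    fw(inter, "interactions.tsv")
    fw(data.frame(tier = "tier1",
                  category = names(covg$tier1), fraction = covg$tier1),
       "event_feature_coverage.tsv")
    fw(gse, "gene_set_enrichment.tsv")
    write_bed(interactions_as_granges(inter),
              file.path(out_dir, "events.bed"))
    el <- summary[!vapply(summary, is.null, logical(1))]
    el$elapsed_sec <- NULL  # keep the summary file byte-reproducible
    jsonlite::write_json(el, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(result)
}
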