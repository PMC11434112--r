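# Ground-truth recovery evaluation on synthetic studies: runs the full
# inference chain on a generated dataset and scores it against the planted
# truth. Used by the validation suite and the acceptance script.

#' Evaluate pipeline recovery against planted ground truth
#'
#' Generates a synthetic study, runs promoter assignment, motif scanning,
#' footprint support, importance estimation, footprint-conditioned
#' significance and network assembly, then the candidate-regulator triage,
#' and scores everything against the generator's truth: network precision and
#' recall (with footprint evidence, and without it), TF-significance power,
#' and recovery/false positives of the planted all-evidence regulators.
#'
#' @param seed root seed for the synthetic study.
#' @param sim_cfg a [sim_config()]; defaults to the standard study design
#'   with the given seed.
#' @param n_trees trees per target ensemble (default 300; recovery is stable
#'   from a few hundred trees at this problem size).
#' @param n_perm permutations for the structure-TF test (default 499).
#' @param alpha significance level used throughout (default 0.05).
#' @return list with `precision`, `recall`, `precision_nofp`, `recall_nofp`,
#'   `power`, `n_regulators`, `triage_recovered`, `triage_false_positives`,
#'   `n_planted`, `high_confidence`, `median_r_ac`, `median_r_me`, and the
#'   underlying `study` and `trn`.
#' @export
evaluate_recovery <- function(seed, sim_cfg = sim_config(seed = seed),
                              n_trees = 300, n_perm = 499, alpha = 0.05) {
  study <- simulate_study(sim_cfg)
  truth <- study$truth
  pm <- assign_promoter_peaks(study$annotation, study$peaks)
  hits <- scan_promoter_peaks(study$genome, study$peaks, study$pwms, pm)
  hits <- mark_footprint_support(hits, study$footprints)
  tfm <- map_tf_to_motif(explicit = truth$tf_motif)
  mt_fp <- derive_motif_targets(hits, require_footprint = TRUE)
  mt_all <- derive_motif_targets(hits, require_footprint = FALSE)
  W <- genie3_importance(study$expr, truth$tf_ids, n_trees = n_trees,
                         seed = derive_seed(seed, 103L))
  sig <- footprint_conditioned_significance(W, mt_fp, tfm, alpha = alpha,
                                            expr = study$expr)
  trn <- assemble_trn(W, mt_fp, tfm, study$expr, sig, alpha = alpha)
  sig_all <- footprint_conditioned_significance(W, mt_all, tfm, alpha = alpha,
                                                expr = study$expr)
  trn_all <- assemble_trn(W, mt_all, tfm, study$expr, sig_all, alpha = alpha,
                          footprint_supported = FALSE)

  truth_e <- paste(truth$network$tf_id, truth$network$target_id)
  score <- function(tr) {
    pred <- paste(tr$edges$tf_id, tr$edges$target_id)
    c(precision = if (length(pred)) mean(pred %in% truth_e) else NA_real_,
      recall = mean(truth_e %in% pred))
  }
  s_fp <- score(trn); s_all <- score(trn_all)
  regulators <- unique(truth$network$tf_id)
  power <- mean(sig$significant[sig$tf_id %in% regulators])

  structure_tfs <- suppressWarnings(
    identify_structure_tfs(trn, tf_ids = truth$tf_ids, n_perm = n_perm,
                           alpha = alpha, seed = derive_seed(seed, 104L)))
  direct <- identify_direct_regulators(trn, truth$starch_genes, truth$ssp_genes)
  sets <- core_tf_sets(structure_tfs, direct)
  gwas <- gwas_overlap(study$annotation, truth$tf_ids, study$gwas_signals)
  groups <- expression_phenotype_groups(study$panels, study$traits,
                                        study$trait_classes, truth$tf_ids,
                                        alpha = alpha)
  triage <- build_triage_table(truth$tf_ids, sets$core, sets$novel, gwas,
                               groups, study$mutant_flags)
  hc <- select_high_confidence(triage)
  planted <- truth$all_evidence_tfs

  es <- stage_means(study$expr)
  med_r <- function(mark) {
    ms <- stage_means(mark)
    stats::median(vapply(rownames(es), function(g) {
      pk <- paste0("peak_", g)
      if (!pk %in% rownames(ms)) return(NA_real_)
      suppressWarnings(stats::cor(es[g, colnames(ms)], ms[pk, ]))
    }, 0), na.rm = TRUE)
  }

  list(precision = unname(s_fp["precision"]), recall = unname(s_fp["recall"]),
       precision_nofp = unname(s_all["precision"]),
       recall_nofp = unname(s_all["recall"]),
       power = power, n_regulators = length(regulators),
       triage_recovered = if (length(planted)) mean(planted %in% hc) else NA_real_,
       triage_false_positives = length(setdiff(hc, planted)),
       n_planted = length(planted), high_confidence = hc,
       median_r_ac = med_r(study$marks$ac), median_r_me = med_r(study$marks$me),
       study = study, trn = trn)
}

#' Null calibration of the footprint-conditioned significance test
#'
#' Builds one synthetic study without planted regulation (effect size 0),
#' computes the importance matrix once, and repeatedly re-tests it against
#' random motif-target memberships of the configured size. Under this null
#' the BH-selected TF fraction should stay near (below ~2x) alpha.
#'
#' @param seed RNG seed.
#' @param n_replicates random-membership replicates (default 200).
#' @param targets_per_tf membership size per motif (default 8).
#' @param sim_cfg synthetic design (default: the standard design with
#'   effect_beta = 0).
#' @param n_trees trees per target for the one-off importance fit.
#' @param alpha selection level (default 0.05).
#' @return list with `selected_rate` (mean selected fraction), `rates`
#'   (per replicate), `n_replicates`.
#' @export
significance_null_calibration <- function(seed, n_replicates = 200,
                                          targets_per_tf = 8,
                                          sim_cfg = sim_config(seed = seed,
                                                               effect_beta = 0),
                                          n_trees = 150, alpha = 0.05) {
  gl <- simulate_genome(sim_cfg)
  expr <- simulate_timeseries_expression(gl$truth, gl$annotation, sim_cfg)
  W <- genie3_importance(expr, gl$truth$tf_ids, n_trees = n_trees,
                         seed = derive_seed(seed, 103L))
  tfm <- map_tf_to_motif(explicit = gl$truth$tf_motif)
  genes <- colnames(W)
  rates <- with_seed(derive_seed(seed, 7L), {
    vapply(seq_len(n_replicates), function(b) {
      mt <- lapply(stats::setNames(tfm$motif_id, tfm$motif_id), function(m)
        sample(genes, targets_per_tf))
      sig <- footprint_conditioned_significance(W, mt, tfm, alpha = alpha,
                                                expr = expr)
      mean(sig$significant[sig$tested])
    }, 0)
  })
  list(selected_rate = mean(rates), rates = rates, n_replicates = n_replicates)
}
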