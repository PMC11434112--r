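# Stage orchestration over a single flat config, with deterministic seeding
# and a machine-readable run manifest.

#' Default pipeline configuration
#'
#' Flat named list of every tunable threshold, with the package defaults:
#' promoter window (-3000/+1000 bp), expressed-gene TPM threshold 0.5, PWM
#' hit threshold 0.8 of the maximum score, TF-significance alpha 0.05,
#' per-TF edge weight quantile 0.75, sign dead zone r_min 0.1, GWAS window 3
#' Mb, group_min 2, variant filters (<0.5 missing, >0.05 MAF, <0.5 het),
#' n_trees 1000, n_background 50, n_perm 1000, k 6 clusters, seed 1.
#'
#' @return Named list.
#' @export
default_pipeline_config <- function() {
  list(window_up = 3000, window_down = 1000, tpm_threshold = 0.5,
       threshold_frac = 0.8, min_overlap_frac = 1.0, alpha = 0.05,
       weight_quantile = 0.75, r_min = 0.1, window_total = 3e6,
       group_min = 2, max_missing = 0.5, min_maf = 0.05, max_het = 0.5,
       n_trees = 1000, n_background = 50, n_bins = 10, n_perm = 1000,
       k = 6, min_group = 5, require_footprint = TRUE, seed = 1)
}

validate_pipeline_config <- function(config) {
  def <- default_pipeline_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  out <- utils::modifyList(def, config)
  num <- setdiff(names(out), "require_footprint")
  for (f in num) if (!is.numeric(out[[f]])) stopf("config key %s must be numeric", f)
  out
}

#' Run the analysis pipeline on a synthetic or loaded study
#'
#' Stages: `simulate` (generate the synthetic study), `dynamics`
#' (expressed-gene filter, temporal clustering, triad balance,
#' expression-mark correlation), `chromatin` (promoter map, PWM scan,
#' footprint support, TF-activity deviations), `trn` (importance matrix,
#' footprint-conditioned significance, network assembly), `triage`
#' (structure/direct regulators, GWAS overlap, expression-phenotype groups,
#' high-confidence selection), or `all`. Artifacts are written under
#' `outdir` together with a JSON run manifest.
#'
#' @param stage one of "simulate", "dynamics", "chromatin", "trn", "triage",
#'   "all".
#' @param config named list of overrides of [default_pipeline_config()], or a
#'   YAML file path; unknown keys are rejected.
#' @param outdir output directory (default: a temporary directory).
#' @param sim_cfg a [sim_config()] for the synthetic study (its seed is set
#'   from the pipeline seed unless supplied explicitly).
#' @param study an existing study list (from [simulate_study()]); when NULL
#'   the simulate stage runs first.
#' @return Invisible list with the study, stage results and the manifest.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "dynamics", "chromatin",
                                   "trn", "triage"),
                         config = list(), outdir = tempfile("grainTRN_run_"),
                         sim_cfg = NULL, study = NULL) {
  stage <- match.arg(stage)
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  cfg <- validate_pipeline_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t_start <- Sys.time()
  timings <- list()
  tick <- function(name, expr) {
    t0 <- Sys.time()
    val <- force(expr)
    timings[[name]] <<- as.numeric(Sys.time() - t0, units = "secs")
    val
  }
  res <- list()
  if (is.null(study)) {
    if (is.null(sim_cfg)) sim_cfg <- sim_config(seed = cfg$seed)
    study <- tick("simulate", simulate_study(sim_cfg, dir = file.path(outdir, "data")))
  }
  res$study <- study
  want <- function(s) stage %in% c("all", s)

  if (want("dynamics")) {
    res$dynamics <- tick("dynamics", {
      expressed <- filter_expressed(study$expr, cfg$tpm_threshold)
      clusters <- cluster_temporal_profiles(study$expr, expressed, k = cfg$k,
                                            seed = derive_seed(cfg$seed, 101L))
      triads <- triad_balance_table(study$expr, study$annotation)
      corr_ac <- expression_mark_correlation(study$expr, study$marks$ac,
                                             study$annotation, study$peaks,
                                             up = cfg$window_up, down = cfg$window_down)
      corr_me <- expression_mark_correlation(study$expr, study$marks$me,
                                             study$annotation, study$peaks,
                                             up = cfg$window_up, down = cfg$window_down)
      utils::write.table(data.frame(gene_id = names(clusters$assignments),
                                    cluster = clusters$assignments),
                         file.path(outdir, "clusters.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(triads, file.path(outdir, "triad_balance.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(corr_ac, file.path(outdir, "expr_ac_correlation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(corr_me, file.path(outdir, "expr_me_correlation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(expressed = expressed, clusters = clusters, triads = triads,
           corr_ac = corr_ac, corr_me = corr_me)
    })
  }

  if (want("chromatin") || want("trn") || want("triage")) {
    res$chromatin <- tick("chromatin", {
      pm <- assign_promoter_peaks(study$annotation, study$peaks,
                                  up = cfg$window_up, down = cfg$window_down)
      hits <- scan_promoter_peaks(study$genome, study$peaks, study$pwms, pm,
                                  threshold_frac = cfg$threshold_frac)
      hits <- mark_footprint_support(hits, study$footprints,
                                     min_overlap_frac = cfg$min_overlap_frac)
      membership <- lapply(derive_motif_targets(hits, require_footprint = FALSE),
                           function(genes) unique(paste0("peak_", genes)))
      membership <- lapply(membership, intersect, study$peaks$name)
      membership <- membership[lengths(membership) > 0]
      activity <- if (length(membership))
        tf_activity_deviation(study$marks$ac, membership,
                              n_background = cfg$n_background, n_bins = cfg$n_bins,
                              seed = derive_seed(cfg$seed, 102L)) else NULL
      utils::write.table(hits, file.path(outdir, "motif_hits.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      if (!is.null(activity))
        write_matrix_tsv(activity$z, file.path(outdir, "tf_activity_z.tsv"),
                         id_col = "motif_id")
      list(promoter_map = pm, hits = hits, activity = activity)
    })
  }

  if (want("trn") || want("triage")) {
    res$trn <- tick("trn", {
      tf_motif <- map_tf_to_motif(explicit = study$truth$tf_motif)
      motif_targets <- derive_motif_targets(res$chromatin$hits,
                                            require_footprint = cfg$require_footprint)
      weights <- genie3_importance(study$expr, study$truth$tf_ids,
                                   n_trees = cfg$n_trees,
                                   seed = derive_seed(cfg$seed, 103L))
      sig <- footprint_conditioned_significance(weights, motif_targets, tf_motif,
                                                alpha = cfg$alpha,
                                                min_group = cfg$min_group,
                                                expr = study$expr)
      trn <- assemble_trn(weights, motif_targets, tf_motif, study$expr, sig,
                          alpha = cfg$alpha, weight_quantile = cfg$weight_quantile,
                          r_min = cfg$r_min,
                          footprint_supported = cfg$require_footprint)
      write_trn(trn, file.path(outdir, "trn_edges.tsv"),
                file.path(outdir, "tf_significance.json"))
      list(tf_motif = tf_motif, motif_targets = motif_targets,
           weights = weights, significance = sig, trn = trn)
    })
  }

  if (want("triage")) {
    res$triage <- tick("triage", {
      trn <- res$trn$trn
      structure_tfs <- identify_structure_tfs(trn, tf_ids = study$truth$tf_ids,
                                              n_perm = cfg$n_perm, alpha = cfg$alpha,
                                              seed = derive_seed(cfg$seed, 104L))
      direct <- identify_direct_regulators(trn, study$truth$starch_genes,
                                           study$truth$ssp_genes)
      sets <- core_tf_sets(structure_tfs, direct)
      gwas <- gwas_overlap(study$annotation, study$truth$tf_ids,
                           study$gwas_signals, window_total = cfg$window_total)
      groups <- expression_phenotype_groups(study$panels, study$traits,
                                            study$trait_classes,
                                            study$truth$tf_ids, alpha = cfg$alpha)
      triage <- build_triage_table(study$truth$tf_ids, sets$core, sets$novel,
                                   gwas, groups, study$mutant_flags,
                                   group_min = cfg$group_min)
      high_conf <- select_high_confidence(triage, group_min = cfg$group_min)
      reg_class <- classify_regulators(trn, study$truth$starch_genes,
                                       study$truth$ssp_genes)
      utils::write.table(triage, file.path(outdir, "triage.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(reg_class, file.path(outdir, "regulator_classes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      writeLines(high_conf, file.path(outdir, "high_confidence_tfs.txt"))
      list(structure_tfs = structure_tfs, direct = direct, sets = sets,
           gwas = gwas, groups = groups, triage = triage,
           high_confidence = high_conf, regulator_classes = reg_class)
    })
  }

  manifest <- list(
    config = cfg, stage = stage, seed = cfg$seed,
    started = format(t_start, "%Y-%m-%dT%H:%M:%S"),
    elapsed_sec = as.numeric(Sys.time() - t_start, units = "secs"),
    stage_timings = timings,
    outputs = list.files(outdir, recursive = TRUE),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("grainTRN")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(res, list(manifest = manifest, outdir = outdir)))
}
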