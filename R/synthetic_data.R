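# Seeded generator for a complete miniature endosperm study: genome, peaks,
# footprints, motifs, a planted TF->target network, time-series and
# population expression, epigenetic marks, variants, traits, GWAS signals and
# mutant flags -- with known ground truth for every downstream stage.

#' Simulation configuration
#'
#' Defaults describe the study design being emulated: 8 developmental stages
#' (DAP0-DAP22) x 3 replicates of endosperm time-series expression, a
#' ~100-accession population panel, hexaploid triads across three subgenome
#' chromosomes, and a planted TF->target network with footprint-supported
#' motif occurrences in target promoters.
#'
#' @param n_triads gene triads (one gene per A/B/D chromosome).
#' @param n_tfs transcription factors (a fraction are "silent": motif but no
#'   targets).
#' @param targets_per_tf regulon size of each active TF.
#' @param n_stages,n_reps time-series design (defaults 8 stages x 3 reps).
#' @param n_accessions population panel size (default 100).
#' @param noise_sd residual SD of target log2 expression (default 0.3).
#' @param effect_beta regulatory effect size on the log2 scale (default 0.8).
#' @param decoy_motif_rate per-(TF, non-target gene) probability of a motif
#'   occurrence without footprint cover (default 0.05).
#' @param mark_expr_corr target log-scale correlation between expression and
#'   the activating mark; the repressive mark uses its negative (default 0.9).
#' @param seed root seed; every sub-generator derives its own stream.
#' @param n_causal_tfs TFs driving traits, carrying cis variants and GWAS
#'   signals (default 6).
#' @param n_storage genes per storage class (starch / SSP; default 40 each).
#' @param variant_effect log2-expression shift per alt allele at a causal
#'   cis variant (default 1.5).
#' @param panel_noise_sd,trait_noise_sd residual SDs in the population layer.
#' @param n_background_variants non-causal variants scattered in and out of
#'   peaks (default 120).
#' @param gene_length,gene_spacing,chrom_margin,peak_width,motif_length
#'   genome layout in bp.
#' @param chrom_length optional fixed chromosome length; error if too short
#'   for the requested gene count.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_triads = 200, n_tfs = 20, targets_per_tf = 8,
                       n_stages = 8, n_reps = 3, n_accessions = 100,
                       noise_sd = 0.3, effect_beta = 0.8,
                       decoy_motif_rate = 0.05, mark_expr_corr = 0.9,
                       seed = 1, n_causal_tfs = 6, n_storage = 40,
                       variant_effect = 1.5, panel_noise_sd = 0.3,
                       trait_noise_sd = 0.5, n_background_variants = 120,
                       gene_length = 2000, gene_spacing = 10000,
                       chrom_margin = 20000, peak_width = 500,
                       motif_length = 8, chrom_length = NULL) {
  cfg <- as.list(environment())
  counts <- c("n_triads", "n_tfs", "targets_per_tf", "n_stages", "n_reps",
              "n_accessions")
  for (f in counts) if (cfg[[f]] < 1) stopf("%s must be >= 1", f)
  if (cfg$noise_sd <= 0) stopf("noise_sd must be > 0")
  if (abs(cfg$mark_expr_corr) > 1) stopf("|mark_expr_corr| must be <= 1")
  if (cfg$decoy_motif_rate < 0 || cfg$decoy_motif_rate > 1)
    stopf("decoy_motif_rate must be a probability")
  if (3 * cfg$n_tfs > 3 * cfg$n_triads) stopf("more TFs than genes")
  structure(cfg, class = "sim_config")
}

# Canonical stage labels: days-after-pollination grid.
stage_labels <- function(n_stages) {
  grid <- c(0, 2, 4, 6, 8, 12, 16, 22)
  if (n_stages > length(grid)) grid <- c(grid, seq(26, by = 4, length.out = n_stages - 8))
  paste0("DAP", grid[seq_len(n_stages)])
}

#' Simulate the genome layer: annotation, peaks, footprints, motifs, truth
#'
#' Lays out `n_triads` triads across three subgenome chromosomes, gives
#' every gene one promoter-proximal accessible peak, plants a cycle-free
#' TF->target network (1-3 regulators per target; a subset of causal TFs
#' regulate the starch/SSP storage sets), and embeds each regulating TF's
#' motif consensus in its target's peak under an exactly-covering footprint.
#' Decoy consensus occurrences are embedded in non-target peaks without
#' footprint cover at `decoy_motif_rate`.
#'
#' @param config a [sim_config()].
#' @return list with `annotation`, `peaks`, `footprints` (interval
#'   data.frames), `pwms`, `genome` (`DNAStringSet`), `truth`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  chroms <- c(A = "chr1A", B = "chr1B", D = "chr1D")
  need <- 2 * cf$chrom_margin + cf$n_triads * cf$gene_spacing
  clen <- cf$chrom_length %||% need
  if (clen < need)
    stopf("chromosome length %d too short for %d genes (need %d)", clen,
          cf$n_triads, need)
  chrom_sizes <- stats::setNames(rep(clen, 3), chroms)

  genes <- with_seed(derive_seed(cf$seed, 1L), {
    do.call(rbind, lapply(seq_len(cf$n_triads), function(t) {
      s <- cf$chrom_margin + (t - 1) * cf$gene_spacing
      strand <- if (t %% 2 == 0) "-" else "+"
      data.frame(gene_id = sprintf("g%03d%s", t, names(chroms)),
                 chrom = unname(chroms), start = s, end = s + cf$gene_length,
                 strand = strand, subgenome = names(chroms),
                 triad_id = sprintf("tri%03d", t), is_tf = FALSE,
                 stringsAsFactors = FALSE)
    }))
  })

  truth <- with_seed(derive_seed(cf$seed, 2L), {
    tf_ids <- sort(sample(genes$gene_id, cf$n_tfs))
    n_silent <- max(0L, round(0.2 * cf$n_tfs))
    topo <- sample(tf_ids)
    silent <- if (n_silent) topo[seq(length(topo) - n_silent + 1, length(topo))] else character(0)
    active <- setdiff(topo, silent)
    non_tf <- setdiff(genes$gene_id, tf_ids)
    storage_pool <- sample(non_tf, 2 * cf$n_storage)
    starch <- sort(storage_pool[seq_len(cf$n_storage)])
    ssp <- sort(storage_pool[cf$n_storage + seq_len(cf$n_storage)])
    causal <- sample(active, min(cf$n_causal_tfs, length(active)))
    reg_count <- stats::setNames(integer(nrow(genes)), genes$gene_id)
    net <- list()
    for (j in seq_along(topo)) {
      tf <- topo[j]
      if (tf %in% silent) next
      later_tfs <- if (j < length(topo)) topo[(j + 1):length(topo)] else character(0)
      pool <- if (tf %in% causal) c(starch, ssp) else
        setdiff(non_tf, c(starch, ssp))
      pool <- pool[reg_count[pool] < 3]
      n_take <- min(cf$targets_per_tf, length(pool))
      tg <- sample(pool, n_take)
      later_ok <- later_tfs[reg_count[later_tfs] < 3]
      if (length(later_ok) && stats::runif(1) < 0.7)
        tg <- c(tg, sample(later_ok, 1))
      reg_count[tg] <- reg_count[tg] + 1L
      net[[tf]] <- data.frame(tf_id = tf, target_id = tg,
                              sign = ifelse(stats::runif(length(tg)) < 0.6, 1, -1),
                              beta = cf$effect_beta, stringsAsFactors = FALSE)
    }
    network <- do.call(rbind, net)
    rownames(network) <- NULL
    list(network = network, tf_ids = tf_ids, silent_tfs = sort(silent),
         causal_tfs = sort(causal), starch_genes = starch, ssp_genes = ssp,
         tf_motif = stats::setNames(sprintf("MOTIF%02d", seq_along(tf_ids)), tf_ids))
  })
  genes$is_tf <- genes$gene_id %in% truth$tf_ids

  pwms <- with_seed(derive_seed(cf$seed, 3L), {
    bases <- c("A", "C", "G", "T")
    consensi <- character(0)
    repeat {
      consensi <- vapply(seq_len(cf$n_tfs), function(i)
        paste(sample(bases, cf$motif_length, replace = TRUE), collapse = ""), "")
      if (!anyDuplicated(consensi)) break
    }
    fams <- rep(c("Dof", "bZIP", "NAC", "MYB", "AP2", "C2H2", "B3", "MADS"),
                length.out = cf$n_tfs)
    out <- lapply(seq_len(cf$n_tfs), function(i) {
      m <- matrix(3, 4, cf$motif_length, dimnames = list(bases, NULL))
      cons <- strsplit(consensi[i], "")[[1]]
      for (j in seq_len(cf$motif_length)) m[cons[j], j] <- 91
      pwm(sprintf("MOTIF%02d", i), fams[i], m)
    })
    stats::setNames(out, vapply(out, `[[`, "", "motif_id"))
  })

  # one promoter-proximal peak per gene, strand-aware upstream-heavy
  ann0 <- genome_annotation(genes, chrom_sizes)
  g <- ann0$genes
  pk_start <- ifelse(g$strand == "+", g$tss - cf$peak_width + 50, g$tss - 50)
  peaks <- data.frame(chrom = g$chrom, start = pk_start,
                      end = pk_start + cf$peak_width,
                      name = paste0("peak_", g$gene_id), score = NA_real_,
                      strand = ".", stringsAsFactors = FALSE)
  peak_of_gene <- stats::setNames(seq_len(nrow(peaks)), g$gene_id)

  emb <- with_seed(derive_seed(cf$seed, 4L), {
    base_utf <- utf8ToInt("ACGT")
    seqs <- lapply(chrom_sizes, function(n)
      base_utf[sample.int(4L, n, replace = TRUE)])
    L <- cf$motif_length
    slot_step <- L + 16L
    n_slots <- (cf$peak_width - 20L) %/% slot_step
    next_slot <- stats::setNames(integer(nrow(peaks)), peaks$name)
    fp <- list()
    edits <- list()   # deferred sequence edits: (chrom, pos, consensus codes)
    embed <- function(gene, motif, footprint) {
      pi <- peak_of_gene[[gene]]
      k <- next_slot[[peaks$name[pi]]]
      if (k >= n_slots) return(FALSE)
      next_slot[[peaks$name[pi]]] <<- k + 1L
      pos <- peaks$start[pi] + 10L + k * slot_step  # 0-based chrom offset
      edits[[length(edits) + 1L]] <<- list(chrom = peaks$chrom[pi], pos = pos,
                                           codes = utf8ToInt(pwm_consensus(pwms[[motif]])))
      if (footprint)
        fp[[length(fp) + 1L]] <<- data.frame(chrom = peaks$chrom[pi], start = pos,
                                             end = pos + L, stringsAsFactors = FALSE)
      TRUE
    }
    for (i in seq_len(nrow(truth$network)))
      embed(truth$network$target_id[i], truth$tf_motif[[truth$network$tf_id[i]]], TRUE)
    if (cf$decoy_motif_rate > 0) {
      tgt_of <- split(truth$network$target_id, truth$network$tf_id)
      for (tf in truth$tf_ids) {
        non_targets <- setdiff(g$gene_id, c(tgt_of[[tf]], tf))
        hit <- non_targets[stats::runif(length(non_targets)) < cf$decoy_motif_rate]
        for (gene in hit) embed(gene, truth$tf_motif[[tf]], FALSE)
      }
    }
    for (ch in unique(vapply(edits, `[[`, "", "chrom"))) {
      sel <- edits[vapply(edits, `[[`, "", "chrom") == ch]
      at <- unlist(lapply(sel, function(e) (e$pos + 1):(e$pos + L)))
      seqs[[ch]][at] <- unlist(lapply(sel, `[[`, "codes"))
    }
    footprints <- if (length(fp)) do.call(rbind, fp) else
      data.frame(chrom = character(), start = numeric(), end = numeric())
    footprints$name <- if (nrow(footprints)) sprintf("fp%04d", seq_len(nrow(footprints))) else character(0)
    footprints$score <- NA_real_
    footprints$strand <- "."
    list(genome = Biostrings::DNAStringSet(vapply(seqs, intToUtf8, "")),
         footprints = footprints)
  })

  list(annotation = ann0, peaks = peaks, footprints = emb$footprints,
       pwms = pwms, genome = emb$genome, truth = truth)
}

#' Simulate time-series endosperm expression from the planted network
#'
#' TF log2 profiles are smooth stage-shifted Gaussian bumps with replicate
#' noise sd/2; each target's log2 expression adds, per regulator, sign x
#' beta x z(TF profile), plus Normal(0, sd^2) noise. Unregulated genes get
#' small intrinsic bumps. Values are exponentiated and column-rescaled so
#' each sample sums to 1e6 (TPM-like).
#'
#' @param truth,annotation from [simulate_genome()].
#' @param config the [sim_config()].
#' @return genes x (stages x reps) TPM matrix; columns `<stage>_<rep>`.
#' @export
simulate_timeseries_expression <- function(truth, annotation, config) {
  cf <- config
  g <- annotation$genes$gene_id
  if (!all(unique(c(truth$network$tf_id, truth$network$target_id)) %in% g))
    stopf("truth network references genes absent from annotation")
  stages <- stage_labels(cf$n_stages)
  cols <- as.vector(outer(stages, seq_len(cf$n_reps), paste, sep = "_"))
  cols <- cols[order(rep(seq_len(cf$n_stages), cf$n_reps))]
  sidx <- rep(seq_len(cf$n_stages), each = cf$n_reps)
  with_seed(derive_seed(cf$seed, 10L), {
    n <- length(g)
    baseline <- stats::runif(n, 2, 6)
    center <- stats::runif(n, 1, cf$n_stages)
    width <- stats::runif(n, 1, 2.5)
    is_target <- g %in% truth$network$target_id
    # regulated genes carry no intrinsic program: their dynamics come from
    # their regulators, so the planted effect is the only TF-target coupling
    amp <- ifelse(g %in% truth$tf_ids, stats::runif(n, 2, 4),
                  ifelse(is_target, 0, stats::runif(n, 0, 2)))
    bump <- function(i) amp[i] * exp(-(sidx - center[i])^2 / (2 * width[i]^2))
    M <- matrix(NA_real_, n, length(cols), dimnames = list(g, cols))
    regs <- split(seq_len(nrow(truth$network)), truth$network$target_id)
    # regulators first (TF rows in topological order), then everything else
    topo <- intersect(unique(truth$network$tf_id), g)
    ord <- c(match(topo, g), setdiff(seq_len(n), match(topo, g)))
    for (i in ord) {
      sd_i <- if (g[i] %in% truth$tf_ids) cf$noise_sd / 2 else cf$noise_sd
      mu <- baseline[i] + bump(i)
      reg_term <- 0
      ri <- regs[[g[i]]]
      if (!is.null(ri)) {
        for (k in ri) {
          tfrow <- M[truth$network$tf_id[k], ]
          z <- zscale(tfrow)
          if (anyNA(z)) z <- rep(0, length(tfrow))
          reg_term <- reg_term + truth$network$sign[k] * truth$network$beta[k] * z
        }
      }
      M[i, ] <- mu + reg_term + stats::rnorm(length(cols), 0, sd_i)
    }
    tpm <- 2^M
    tpm <- sweep(tpm, 2, colSums(tpm), "/") * 1e6
    attr(tpm, "unit") <- "TPM"
    tpm
  })
}

#' Simulate promoter-peak epigenetic mark signal
#'
#' Per gene peak, generates stage-level log signal correlated at
#' `mark_expr_corr` (activating mark, e.g. H3K27ac / accessibility) and at
#' `-mark_expr_corr` (repressive mark, e.g. H3K27me3) with the gene's
#' stage-mean log2 expression, then exponentiates and column-normalizes to
#' CPM.
#'
#' @param expr time-series TPM matrix.
#' @param peaks peak interval data.frame (names `peak_<gene_id>`).
#' @param annotation `genome_annotation`.
#' @param config the [sim_config()].
#' @return list with `ac` and `me`: peaks x stages CPM matrices.
#' @export
simulate_marks <- function(expr, peaks, annotation, config) {
  cf <- config
  rho <- cf$mark_expr_corr
  gene_of_peak <- sub("^peak_", "", peaks$name)
  known <- gene_of_peak %in% rownames(expr)
  if (any(!known)) warnf("%d peak(s) without an expressed gene skipped", sum(!known))
  pk <- peaks$name[known]
  gn <- gene_of_peak[known]
  es <- stage_means(log2(expr + 1))
  stages <- colnames(es)
  with_seed(derive_seed(cf$seed, 20L), {
    mk <- function(sgn) {
      lg <- t(vapply(gn, function(g) {
        e <- zscale(es[g, ])
        if (anyNA(e)) e <- rep(0, length(stages))
        5 + sgn * rho * e + sqrt(max(0, 1 - rho^2)) * stats::rnorm(length(stages))
      }, numeric(length(stages))))
      rownames(lg) <- pk
      colnames(lg) <- stages
      cpm <- 2^lg
      cpm <- sweep(cpm, 2, colSums(cpm), "/") * 1e6
      attr(cpm, "unit") <- "CPM"
      cpm
    }
    list(ac = mk(1), me = mk(-1))
  })
}

#' Simulate the population layer: panel expression, traits, variants, GWAS
#' signals and mutant flags
#'
#' Causal cis variants inside the causal TFs' promoter peaks shift those
#' genes' log2 expression additively per alt allele; the planted network
#' propagates regulation into the panel; traits are weighted sums of the
#' causal TFs' z-scaled expression plus noise; one GWAS signal is placed
#' within 1 Mb of each causal TF per driven trait class; mutant flags mark
#' regulating TFs "altered" with probability 0.9 (others 0.1; a small
#' fraction of TFs have no line). Two stage panels are emitted (DAP10,
#' DAP20).
#'
#' @param truth,annotation,peaks from [simulate_genome()].
#' @param config the [sim_config()].
#' @return list with `panels` (named list of genes x accessions TPM
#'   matrices), `traits` (accessions x traits data.frame), `genotypes`
#'   (`genotype_table`), `gwas_signals`, `mutant_flags`, `trait_classes`,
#'   and the augmented `truth` (causal variants, trait weights, and the
#'   planted all-evidence TF set).
#' @export
simulate_population <- function(truth, annotation, peaks, config) {
  cf <- config
  if (cf$n_accessions < 10) stopf("need at least 10 accessions")
  g <- annotation$genes
  acc <- sprintf("acc%03d", seq_len(cf$n_accessions))
  gs_traits <- c("grain_length", "grain_width", "thousand_kernel_weight")
  gq_traits <- c("gluten_content", "sedimentation_volume")
  trait_classes <- stats::setNames(c(rep("GS", 3), rep("GQ", 2)),
                                   c(gs_traits, gq_traits))
  with_seed(derive_seed(cf$seed, 30L), {
    # ---- variants -----------------------------------------------------------
    draw_dosage <- function(p) {
      d <- ifelse(stats::runif(cf$n_accessions) < 0.05, 1L,
                  2L * (stats::runif(cf$n_accessions) < p))
      d[stats::runif(cf$n_accessions) < 0.02] <- NA_integer_
      d
    }
    bases <- c("A", "C", "G", "T")
    causal <- truth$causal_tfs
    vrows <- list(); calls <- list(); causal_var <- list()
    for (tf in causal) {
      pi <- match(paste0("peak_", tf), peaks$name)
      pos <- peaks$start[pi] + 3
      ra <- sample(bases, 2)
      vrows[[length(vrows) + 1L]] <- data.frame(chrom = peaks$chrom[pi], pos = pos,
                                                ref = ra[1], alt = ra[2],
                                                stringsAsFactors = FALSE)
      calls[[length(calls) + 1L]] <- draw_dosage(stats::runif(1, 0.3, 0.7))
      causal_var[[length(causal_var) + 1L]] <- data.frame(
        gene_id = tf, effect = cf$variant_effect, stringsAsFactors = FALSE)
    }
    n_bg <- cf$n_background_variants
    for (b in seq_len(n_bg)) {
      if (b %% 2 == 0) {            # inside a random peak
        pi <- sample.int(nrow(peaks), 1)
        pos <- peaks$start[pi] + sample.int(peaks$end[pi] - peaks$start[pi], 1) - 1
        chrom <- peaks$chrom[pi]
      } else {                      # intergenic
        chrom <- sample(names(annotation$chrom_sizes), 1)
        pos <- sample.int(annotation$chrom_sizes[[chrom]], 1) - 1
      }
      ra <- sample(bases, 2)
      vrows[[length(vrows) + 1L]] <- data.frame(chrom = chrom, pos = pos,
                                                ref = ra[1], alt = ra[2],
                                                stringsAsFactors = FALSE)
      calls[[length(calls) + 1L]] <- draw_dosage(stats::runif(1, 0.02, 0.98))
    }
    variants <- do.call(rbind, vrows)
    variants$id <- sprintf("var%04d", seq_len(nrow(variants)))
    callm <- do.call(rbind, calls)
    colnames(callm) <- acc
    ord <- order(variants$chrom, variants$pos)
    genotypes <- genotype_table(variants[ord, , drop = FALSE],
                                callm[ord, , drop = FALSE])
    causal_variants <- do.call(rbind, causal_var)
    causal_variants$variant_id <- variants$id[seq_along(causal)]

    # ---- panel expression ---------------------------------------------------
    dose0 <- callm[seq_along(causal), , drop = FALSE]
    dose0[is.na(dose0)] <- 1  # population-mean fill for expression simulation
    base_pop <- stats::setNames(stats::runif(nrow(g), 2, 6), g$gene_id)
    shift20 <- stats::setNames(stats::runif(nrow(g), -0.5, 0.5), g$gene_id)
    regs <- split(seq_len(nrow(truth$network)), truth$network$target_id)
    topo <- intersect(unique(truth$network$tf_id), g$gene_id)
    ord_g <- c(match(topo, g$gene_id),
               setdiff(seq_len(nrow(g)), match(topo, g$gene_id)))
    make_panel <- function(stage_shift) {
      M <- matrix(NA_real_, nrow(g), cf$n_accessions,
                  dimnames = list(g$gene_id, acc))
      for (i in ord_g) {
        id <- g$gene_id[i]
        mu <- base_pop[[id]] + stage_shift[[id]]
        cis <- if (id %in% causal) cf$variant_effect * dose0[match(id, causal), ] else 0
        reg_term <- 0
        ri <- regs[[id]]
        if (!is.null(ri)) for (k in ri) {
          z <- zscale(M[truth$network$tf_id[k], ])
          if (anyNA(z)) z <- rep(0, cf$n_accessions)
          reg_term <- reg_term + truth$network$sign[k] * truth$network$beta[k] * z
        }
        M[i, ] <- mu + cis + reg_term + stats::rnorm(cf$n_accessions, 0, cf$panel_noise_sd)
      }
      tpm <- 2^M
      tpm <- sweep(tpm, 2, colSums(tpm), "/") * 1e6
      attr(tpm, "unit") <- "TPM"
      tpm
    }
    zero_shift <- stats::setNames(rep(0, nrow(g)), g$gene_id)
    panels <- list(DAP10 = make_panel(zero_shift), DAP20 = make_panel(shift20))

    # ---- traits -------------------------------------------------------------
    lg20 <- log2(panels$DAP20 + 1)
    causal_trait_genes <- stats::setNames(
      lapply(names(trait_classes), function(tr) NULL), names(trait_classes))
    wsign <- ifelse(stats::runif(length(causal)) < 0.5, 1, -1)
    for (i in seq_along(causal)) {
      gs <- gs_traits[(i - 1) %% length(gs_traits) + 1]
      gq <- gq_traits[(i - 1) %% length(gq_traits) + 1]
      for (tr in c(gs, gq))
        causal_trait_genes[[tr]] <- rbind(causal_trait_genes[[tr]],
                                          data.frame(gene_id = causal[i],
                                                     weight = 0.8 * wsign[i],
                                                     stringsAsFactors = FALSE))
    }
    traits <- as.data.frame(stats::setNames(lapply(names(trait_classes), function(tr) {
      ctg <- causal_trait_genes[[tr]]
      y <- stats::rnorm(cf$n_accessions, 0, cf$trait_noise_sd)
      if (!is.null(ctg)) for (k in seq_len(nrow(ctg))) {
        z <- zscale(lg20[ctg$gene_id[k], ])
        if (anyNA(z)) z <- rep(0, cf$n_accessions)
        y <- y + ctg$weight[k] * z
      }
      y
    }), names(trait_classes)), row.names = acc)
    # a measured but unclassified trait with no causal genes: a built-in null
    traits$plant_height <- stats::rnorm(cf$n_accessions)

    # ---- GWAS signals and mutant flags -------------------------------------
    srows <- list()
    for (i in seq_along(causal)) {
      tf <- causal[i]
      gi <- match(tf, g$gene_id)
      for (cl in unique(trait_classes[c(gs_traits[(i - 1) %% 3 + 1],
                                        gq_traits[(i - 1) %% 2 + 1])])) {
        pos <- g$tss[gi] + round(stats::runif(1, -1e6, 1e6))
        pos <- max(0, min(pos, annotation$chrom_sizes[[g$chrom[gi]]] - 1))
        srows[[length(srows) + 1L]] <- data.frame(chrom = g$chrom[gi], pos = pos,
                                                  trait_class = cl,
                                                  stringsAsFactors = FALSE)
      }
    }
    gwas_signals <- do.call(rbind, srows)
    regulators <- unique(truth$network$tf_id)
    status <- vapply(truth$tf_ids, function(tf) {
      if (stats::runif(1) < 0.05) return("no_line")
      p <- if (tf %in% regulators) 0.9 else 0.1
      if (stats::runif(1) < p) "altered" else "not_altered"
    }, "")
    mutant_flags <- data.frame(tf_id = truth$tf_ids, status = unname(status),
                               stringsAsFactors = FALSE)

    truth$causal_variants <- causal_variants
    truth$causal_trait_genes <- causal_trait_genes
    truth$all_evidence_tfs <- sort(causal[status[causal] == "altered"])
    list(panels = panels, traits = traits, genotypes = genotypes,
         gwas_signals = gwas_signals, mutant_flags = mutant_flags,
         trait_classes = trait_classes, truth = truth)
  })
}

#' Generate and write a complete synthetic study
#'
#' Runs all generator layers under one root seed and writes every artifact
#' as plain text: genome.fa, genes.gff3, peaks.bed, footprints.bed,
#' motifs.jaspar, expr_timeseries.tsv, ac.tsv, me.tsv, panel_*.tsv,
#' traits.tsv, variants.vcf, gwas_signals.tsv, mutants.tsv, truth.json,
#' config.yaml.
#'
#' @param config a [sim_config()].
#' @param dir output directory (NULL: nothing written).
#' @return list with all in-memory objects (annotation, peaks, footprints,
#'   pwms, genome, expr, marks, population layers, truth), invisibly when
#'   `dir` is given.
#' @export
simulate_study <- function(config = sim_config(), dir = NULL) {
  gl <- simulate_genome(config)
  expr <- simulate_timeseries_expression(gl$truth, gl$annotation, config)
  marks <- simulate_marks(expr, gl$peaks, gl$annotation, config)
  pop <- simulate_population(gl$truth, gl$annotation, gl$peaks, config)
  out <- list(config = config, annotation = gl$annotation, peaks = gl$peaks,
              footprints = gl$footprints, pwms = gl$pwms, genome = gl$genome,
              expr = expr, marks = marks, panels = pop$panels,
              traits = pop$traits, genotypes = pop$genotypes,
              gwas_signals = pop$gwas_signals, mutant_flags = pop$mutant_flags,
              trait_classes = pop$trait_classes, truth = pop$truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(f) file.path(dir, f)
    write_genome_fasta(out$genome, fp("genome.fa"))
    write_gene_models(out$annotation, fp("genes.gff3"))
    write_bed(out$peaks, fp("peaks.bed"))
    write_bed(out$footprints, fp("footprints.bed"))
    write_jaspar_pwm(out$pwms, fp("motifs.jaspar"))
    write_matrix_tsv(out$expr, fp("expr_timeseries.tsv"))
    write_matrix_tsv(out$marks$ac, fp("ac.tsv"), id_col = "peak")
    write_matrix_tsv(out$marks$me, fp("me.tsv"), id_col = "peak")
    for (st in names(out$panels))
      write_matrix_tsv(out$panels[[st]], fp(sprintf("panel_%s.tsv", st)))
    utils::write.table(data.frame(accession = rownames(out$traits), out$traits),
                       fp("traits.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    write_vcf_lite(out$genotypes, fp("variants.vcf"))
    utils::write.table(out$gwas_signals, fp("gwas_signals.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(out$mutant_flags, fp("mutants.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(out$truth, fp("truth.json"), auto_unbox = TRUE,
                         digits = NA, na = "null")
    yaml::write_yaml(unclass(config), fp("config.yaml"))
    return(invisible(out))
  }
  out
}
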