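# Core/structure TF identification, regulator classification, three-evidence
# candidate triage, and population haplotype/variability statistics.

#' Identify structure TFs (hubs of the TF-TF subnetwork)
#'
#' Restricts the TRN to edges whose target is itself a TF and asks whether
#' each TF's out-degree exceeds what degree-preserving randomizations of that
#' subnetwork produce. Each randomization reshuffles all edge endpoint stubs
#' (preserving every node's total degree) and re-orients edges at random;
#' empirical p = (1 + #\{perm >= observed\}) / (n_perm + 1), BH-adjusted.
#'
#' @param trn a `trn`.
#' @param tf_ids the TF universe (default: TFs with out-edges in the TRN).
#' @param n_perm number of randomizations (default 1000).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param seed RNG seed.
#' @return Character vector of structure TFs, with the per-TF statistics
#'   data.frame as attribute `stats`.
#' @export
identify_structure_tfs <- function(trn, tf_ids = unique(trn$edges$tf_id),
                                   n_perm = 1000, alpha = 0.05, seed = 1) {
  e <- trn$edges[trn$edges$target_id %in% tf_ids, , drop = FALSE]
  if (!nrow(e)) {
    warnf("TF-TF subnetwork is empty")
    out <- character(0)
    attr(out, "stats") <- data.frame(tf_id = character(), out_degree = integer(),
                                     p = numeric(), q = numeric())
    return(out)
  }
  nodes <- sort(unique(c(e$tf_id, e$target_id)))
  obs <- table(factor(e$tf_id, levels = nodes))
  stubs <- c(match(e$tf_id, nodes), match(e$target_id, nodes))
  m <- nrow(e)
  exceed <- stats::setNames(integer(length(nodes)), nodes)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      s <- sample(stubs)
      heads <- s[seq_len(m)]                 # random pairing + orientation
      perm_out <- tabulate(heads, nbins = length(nodes))
      exceed <- exceed + (perm_out >= as.integer(obs))
    }
  })
  p <- (1 + exceed) / (n_perm + 1)
  q <- stats::p.adjust(p, method = "BH")
  stats_df <- data.frame(tf_id = nodes, out_degree = as.integer(obs),
                         p = as.numeric(p), q = as.numeric(q),
                         stringsAsFactors = FALSE)
  out <- stats_df$tf_id[stats_df$q <= alpha & stats_df$out_degree > 0]
  attr(out, "stats") <- stats_df
  out
}

#' Identify direct regulators of storage-production genes
#'
#' TFs with at least one TRN edge into the starch-synthesis or seed-storage-
#' protein gene sets.
#'
#' @param trn a `trn`.
#' @param starch_genes,ssp_genes character vectors of gene ids.
#' @return Character vector of TF ids.
#' @export
identify_direct_regulators <- function(trn, starch_genes, ssp_genes) {
  storage <- union(starch_genes, ssp_genes)
  sort(unique(trn$edges$tf_id[trn$edges$target_id %in% storage]))
}

#' Core and novel candidate-regulator sets
#'
#' Core = structure TFs union direct regulators; novel = core minus the
#' caller-supplied known-regulator list.
#'
#' @param structure_tfs,direct_tfs character vectors.
#' @param known_tfs previously described regulators (default none).
#' @return list with `core` and `novel`.
#' @export
core_tf_sets <- function(structure_tfs, direct_tfs, known_tfs = character(0)) {
  core <- sort(union(structure_tfs, direct_tfs))
  list(core = core, novel = setdiff(core, known_tfs))
}

#' Classify regulators by starch/SSP target composition and sign mode
#'
#' A TF is starch- (SSP-) enriched when its count of distinct starch (SSP)
#' targets strictly exceeds the median count over TFs with any storage
#' target; "dual" when both do. Mode is "positive"/"negative" when all
#' signed edges into the storage sets agree, "opposite" when starch and SSP
#' edges carry uniform opposite signs, else "mixed".
#'
#' @param trn a `trn`.
#' @param starch_genes,ssp_genes character vectors of gene ids.
#' @return data.frame with `tf_id`, `n_starch_targets`, `n_ssp_targets`,
#'   `class`, `mode`.
#' @export
classify_regulators <- function(trn, starch_genes, ssp_genes) {
  e <- trn$edges
  tfs <- sort(unique(e$tf_id))
  n_st <- vapply(tfs, function(tf)
    length(unique(e$target_id[e$tf_id == tf & e$target_id %in% starch_genes])), 0L)
  n_sp <- vapply(tfs, function(tf)
    length(unique(e$target_id[e$tf_id == tf & e$target_id %in% ssp_genes])), 0L)
  has_storage <- n_st + n_sp > 0
  med_st <- stats::median(n_st[has_storage])
  med_sp <- stats::median(n_sp[has_storage])
  cls <- rep("neither", length(tfs))
  cls[has_storage & n_st > med_st & n_sp <= med_sp] <- "starch-enriched"
  cls[has_storage & n_sp > med_sp & n_st <= med_st] <- "SSP-enriched"
  cls[has_storage & n_st > med_st & n_sp > med_sp] <- "dual"
  mode <- vapply(seq_along(tfs), function(i) {
    if (!has_storage[i]) return(NA_character_)
    tf <- tfs[i]
    s_st <- unique(e$sign[e$tf_id == tf & e$target_id %in% starch_genes])
    s_sp <- unique(e$sign[e$tf_id == tf & e$target_id %in% ssp_genes])
    all_s <- c(s_st, s_sp)
    if (all(all_s == 1)) return("positive")
    if (all(all_s == -1)) return("negative")
    if (length(s_st) == 1 && length(s_sp) == 1 && s_st != 0 && s_sp == -s_st)
      return("opposite")
    "mixed"
  }, "")
  data.frame(tf_id = tfs, n_starch_targets = n_st, n_ssp_targets = n_sp,
             class = cls, mode = mode, stringsAsFactors = FALSE)
}

#' GWAS-interval overlap flags
#'
#' Flags a TF when its gene interval intersects a window of `window_total`
#' bp centered on any GWAS signal position (half-open window, inclusive
#' reading: the whole gene interval is tested, not just the TSS).
#'
#' @param annotation `genome_annotation`.
#' @param tf_ids TFs to flag.
#' @param signals data.frame with `chrom`, `pos` (0-based) and optionally
#'   `trait_class`.
#' @param window_total total window size in bp (default 3e6, i.e. +/- 1.5 Mb).
#' @return data.frame with `tf_id`, `gwas_hit`, `gwas_classes`
#'   (comma-separated trait classes of the overlapping signals, "" if none).
#' @export
gwas_overlap <- function(annotation, tf_ids, signals, window_total = 3e6) {
  g <- annotation$genes
  known <- signals$chrom %in% names(annotation$chrom_sizes)
  if (any(!known)) {
    warnf("skipping %d signal(s) on unknown chromosomes", sum(!known))
    signals <- signals[known, , drop = FALSE]
  }
  half <- window_total / 2
  cls <- if ("trait_class" %in% names(signals)) signals$trait_class else
    rep("", nrow(signals))
  rows <- lapply(tf_ids, function(tf) {
    i <- match(tf, g$gene_id)
    if (is.na(i)) stopf("unknown tf %s", tf)
    hit <- signals$chrom == g$chrom[i] &
      g$start[i] < signals$pos + half & g$end[i] > signals$pos - half
    data.frame(tf_id = tf, gwas_hit = any(hit),
               gwas_classes = paste(sort(unique(cls[hit & nzchar(cls)])), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Expression-phenotype correlation groups
#'
#' For each TF, stage panel and trait, computes the two-sided Pearson
#' correlation p-value between the TF's expression across accessions and the
#' trait (missing trait values excluded pairwise). The TF joins group
#' "<class>-<stage>" when any trait of that class is significant at `alpha`
#' in that stage's panel.
#'
#' @param panels named list: stage label -> genes x accessions TPM matrix.
#' @param traits accessions x traits data.frame (rownames = accession ids).
#' @param trait_classes named character vector: trait -> class ("GS"/"GQ").
#' @param tf_ids TFs to test.
#' @param alpha per-test significance level (default 0.05, uncorrected as in
#'   per-trait significant-correlation reporting).
#' @param adjust "none" (default) or "BH" across all (tf, stage, trait) tests.
#' @return Named list tf_id -> character vector of groups; per-test table as
#'   attribute `tests`.
#' @export
expression_phenotype_groups <- function(panels, traits, trait_classes, tf_ids,
                                        alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  tests <- list()
  for (stage in names(panels)) {
    ex <- panels[[stage]]
    acc <- intersect(colnames(ex), rownames(traits))
    if (length(acc) < 10) stopf("stage %s: fewer than 10 shared accessions", stage)
    for (tf in tf_ids) {
      if (!tf %in% rownames(ex)) next
      x <- ex[tf, acc]
      sx <- stats::sd(x)
      if (!is.finite(sx) || sx == 0) next
      for (tr in names(trait_classes)) {
        y <- traits[acc, tr]
        ok <- !is.na(y)
        if (sum(ok) < 10) next
        ct <- stats::cor.test(x[ok], y[ok])
        tests[[length(tests) + 1L]] <- data.frame(
          tf_id = tf, stage = stage, trait = tr,
          class = unname(trait_classes[tr]), r = unname(ct$estimate),
          p = ct$p.value, stringsAsFactors = FALSE)
      }
    }
  }
  tests <- do.call(rbind, tests)
  if (is.null(tests)) tests <- data.frame(tf_id = character(), stage = character(),
                                          trait = character(), class = character(),
                                          r = numeric(), p = numeric())
  tests$p_use <- if (adjust == "BH") stats::p.adjust(tests$p, "BH") else tests$p
  sig <- tests[tests$p_use <= alpha, , drop = FALSE]
  groups <- stats::setNames(vector("list", length(tf_ids)), tf_ids)
  for (tf in tf_ids) {
    s <- sig[sig$tf_id == tf, , drop = FALSE]
    groups[[tf]] <- sort(unique(paste0(s$class, "-", s$stage)))
  }
  attr(groups, "tests") <- tests
  groups
}

#' Build the candidate-regulator triage table
#'
#' @param tf_ids TF universe.
#' @param core,novel core and novel TF sets ([core_tf_sets()]).
#' @param gwas data.frame from [gwas_overlap()].
#' @param groups named list from [expression_phenotype_groups()].
#' @param mutant_flags data.frame with `tf_id` and `status` in
#'   \{"altered", "not_altered", "no_line"\}.
#' @param group_min minimum number of expression-phenotype groups (default 2).
#' @return data.frame with per-TF evidence flags and `high_confidence`.
#' @export
build_triage_table <- function(tf_ids, core, novel, gwas, groups, mutant_flags,
                               group_min = 2) {
  st <- mutant_flags$status[match(tf_ids, mutant_flags$tf_id)]
  st[is.na(st)] <- "no_line"
  n_groups <- vapply(tf_ids, function(tf) length(groups[[tf]] %||% character(0)), 0L)
  out <- data.frame(
    tf_id = tf_ids,
    is_core = tf_ids %in% core,
    is_novel = tf_ids %in% novel,
    gwas_hit = gwas$gwas_hit[match(tf_ids, gwas$tf_id)] %in% TRUE,
    n_groups = n_groups,
    groups = vapply(tf_ids, function(tf) paste(groups[[tf]] %||% character(0), collapse = ","), ""),
    mutant_altered = st,
    stringsAsFactors = FALSE)
  out$high_confidence <- out$is_novel & out$gwas_hit &
    out$n_groups >= group_min & out$mutant_altered == "altered"
  attr(out, "group_min") <- group_min
  out
}

#' Select high-confidence candidate regulators
#'
#' The conjunction of all evidence: novel core regulator, inside a GWAS
#' window, significantly trait-correlated in at least `group_min`
#' expression-phenotype groups, and altered in a mutant line.
#'
#' @param triage data.frame from [build_triage_table()].
#' @param group_min minimum group count (default 2).
#' @return Character vector of TF ids.
#' @export
select_high_confidence <- function(triage, group_min = 2) {
  sel <- triage$is_novel & triage$gwas_hit & triage$n_groups >= group_min &
    triage$mutant_altered == "altered"
  sort(triage$tf_id[sel])
}

# ---- Population statistics --------------------------------------------------

#' Filter variants by missingness, MAF and heterozygosity
#'
#' Retains variants with missing rate < `max_missing`, minor-allele
#' frequency > `min_maf` (from non-missing dosages) and heterozygote
#' fraction < `max_het` (strict inequalities).
#'
#' @param gt a `genotype_table`.
#' @param max_missing,min_maf,max_het thresholds (defaults 0.5, 0.05, 0.5).
#' @return Filtered `genotype_table`.
#' @export
filter_variants <- function(gt, max_missing = 0.5, min_maf = 0.05, max_het = 0.5) {
  calls <- gt$calls
  miss <- rowMeans(is.na(calls))
  p_alt <- rowMeans(calls, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  het <- rowMeans(calls == 1, na.rm = TRUE)
  het[is.nan(het)] <- 0
  keep <- miss < max_missing & !is.nan(maf) & maf > min_maf & het < max_het
  genotype_table(gt$variants[keep, , drop = FALSE], calls[keep, , drop = FALSE])
}

#' Group accessions into haplotypes over a gene region
#'
#' The haplotype is the tuple of alt-allele dosages over the region's
#' variants. Accessions with any missing or heterozygous call in the region
#' are excluded (inbred-line assumption). Haplotypes are labelled Hap1,
#' Hap2, ... by descending frequency, ties by lexicographic tuple.
#'
#' @param gt filtered `genotype_table`.
#' @param region list/vector with `chrom`, `start`, `end` (0-based half-open).
#' @return Object of class `haplotype_groups`: list with `assignments`
#'   (named character), `sites`, `n_haplotypes`, `definitions`, `n_excluded`.
#' @export
assign_haplotypes <- function(gt, region) {
  v <- gt$variants
  inr <- v$chrom == region$chrom & v$pos >= region$start & v$pos < region$end
  if (!any(inr)) stopf("no variants in region %s:%s-%s", region$chrom,
                       region$start, region$end)
  calls <- gt$calls[inr, , drop = FALSE]
  bad <- apply(calls, 2, function(x) anyNA(x) || any(x == 1))
  kept <- calls[, !bad, drop = FALSE]
  if (!ncol(kept)) stopf("no accession has a complete homozygous genotype in region")
  tup <- apply(kept, 2, paste, collapse = "/")
  tab <- table(tup)
  ord <- order(-as.integer(tab), names(tab))
  lab <- stats::setNames(paste0("Hap", seq_along(ord)), names(tab)[ord])
  structure(list(assignments = stats::setNames(unname(lab[tup]), colnames(kept)),
                 sites = v$id[inr], n_haplotypes = length(tab),
                 definitions = stats::setNames(names(tab)[ord], lab[names(tab)[ord]]),
                 n_excluded = sum(bad)),
            class = "haplotype_groups")
}

#' @export
print.haplotype_groups <- function(x, ...) {
  cat(sprintf("haplotype_groups: %d haplotypes over %d sites, %d accessions (%d excluded)\n",
              x$n_haplotypes, length(x$sites), length(x$assignments), x$n_excluded))
  invisible(x)
}

#' Pairwise haplotype-trait tests
#'
#' Welch two-sample t-test of the trait between every pair of haplotype
#' groups with n >= 3; delta_mean = mean(first) - mean(second).
#'
#' @param groups a `haplotype_groups`.
#' @param trait named numeric vector (accession -> value); NAs dropped.
#' @return data.frame with `hap_a`, `hap_b`, `n_a`, `n_b`, `delta_mean`,
#'   `t`, `p`.
#' @export
haplotype_trait_test <- function(groups, trait) {
  a <- groups$assignments
  acc <- intersect(names(a), names(trait)[!is.na(trait)])
  a <- a[acc]
  haps <- sort(unique(a))
  rows <- list()
  if (length(haps) >= 2) {
    cmb <- utils::combn(haps, 2)
    for (k in seq_len(ncol(cmb))) {
      ha <- cmb[1, k]; hb <- cmb[2, k]
      xa <- trait[acc[a == ha]]; xb <- trait[acc[a == hb]]
      if (length(xa) < 3 || length(xb) < 3) next
      tt <- tryCatch(stats::t.test(xa, xb), error = function(e) NULL)
      if (is.null(tt)) next
      rows[[length(rows) + 1L]] <- data.frame(
        hap_a = ha, hap_b = hb, n_a = length(xa), n_b = length(xb),
        delta_mean = mean(xa) - mean(xb), t = unname(tt$statistic),
        p = tt$p.value, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame(hap_a = character(), hap_b = character(),
                                       n_a = integer(), n_b = integer(),
                                       delta_mean = numeric(), t = numeric(),
                                       p = numeric()))
  do.call(rbind, rows)
}

#' Haplotype frequencies per era (or any categorical label)
#'
#' @param groups a `haplotype_groups`.
#' @param era_labels named character vector (accession -> era); accessions
#'   without a label are dropped, eras with zero accessions omitted.
#' @return era x haplotype matrix of frequencies; rows sum to 1.
#' @export
haplotype_frequency_trend <- function(groups, era_labels) {
  a <- groups$assignments
  acc <- intersect(names(a), names(era_labels)[!is.na(era_labels)])
  tab <- table(era_labels[acc], a[acc])
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
  m <- m[rowSums(m) > 0, , drop = FALSE]
  sweep(m, 1, rowSums(m), "/")
}

#' SNP density in promoter-proximal accessible chromatin
#'
#' Number of variants falling in a gene's pACRs divided by the total pACR
#' length in kb (overlapping peaks merged before measuring length).
#'
#' @param gt a `genotype_table`.
#' @param peaks interval data.frame with unique `name`s.
#' @param promoter_map output of [assign_promoter_peaks()].
#' @return Named numeric vector, SNPs per kb; genes without pACR omitted.
#' @export
snp_density_in_peaks <- function(gt, peaks, promoter_map) {
  v <- gt$variants
  genes <- names(promoter_map)[lengths(promoter_map) > 0]
  out <- numeric(0)
  for (g in genes) {
    pk <- peaks[peaks$name %in% promoter_map[[g]], , drop = FALSE]
    gr <- GenomicRanges::reduce(as_granges0(pk), ignore.strand = TRUE)
    len <- sum(BiocGenerics::width(gr))
    if (len == 0) { warnf("gene %s has zero total pACR length", g); next }
    st0 <- BiocGenerics::start(gr) - 1
    en0 <- BiocGenerics::end(gr)
    chr <- as.character(GenomicRanges::seqnames(gr))
    n <- sum(vapply(seq_len(nrow(v)), function(i)
      any(chr == v$chrom[i] & st0 <= v$pos[i] & v$pos[i] < en0), TRUE))
    out[g] <- n / (len / 1000)
  }
  out
}
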