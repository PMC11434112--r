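# Normalization, expressed-gene filtering, temporal clustering, triad balance,
# coefficient of variation, and expression-vs-mark correlation.

#' TPM normalization of a raw count matrix
#'
#' TPM_gs = (count_gs / length_g) / sum_g'(count_g's / length_g') * 1e6, so
#' every sample column sums to one million.
#'
#' @param counts genes x samples matrix of non-negative raw counts.
#' @param lengths named vector of gene lengths in bp (> 0), covering all rows.
#' @return Matrix of TPM values with `unit` attribute "TPM".
#' @export
normalize_tpm <- function(counts, lengths) {
  if (is.null(rownames(counts))) stopf("counts must have gene rownames")
  if (!all(rownames(counts) %in% names(lengths)))
    stopf("lengths missing for some genes")
  len <- lengths[rownames(counts)]
  if (any(len <= 0)) stopf("gene lengths must be > 0")
  if (any(counts < 0)) stopf("counts must be non-negative")
  rate <- counts / len
  cs <- colSums(rate)
  if (any(cs == 0)) stopf("all-zero sample column: %s", colnames(counts)[which(cs == 0)[1]])
  tpm <- sweep(rate, 2, cs, "/") * 1e6
  attr(tpm, "unit") <- "TPM"
  tpm
}

#' Filter to expressed genes
#'
#' A gene is expressed when its TPM reaches `threshold` in at least one
#' sample (boundary inclusive).
#'
#' @param expr TPM matrix.
#' @param threshold minimum TPM (default 0.5).
#' @return Character vector of retained gene ids.
#' @export
filter_expressed <- function(expr, threshold = 0.5) {
  u <- attr(expr, "unit")
  if (!is.null(u) && u != "TPM") stopf("filter_expressed expects TPM values, got %s", u)
  rownames(expr)[apply(expr, 1, max) >= threshold]
}

#' Stage labels of sample columns
#'
#' Sample columns are named `<stage>_<replicate>` (e.g. "DAP8_2"); columns
#' without a replicate suffix are their own stage.
#'
#' @param cols character vector of column names.
#' @return Character vector of stage labels.
#' @export
stage_of_columns <- function(cols) sub("_[0-9]+$", "", cols)

#' Average replicate columns per stage
#'
#' @param expr genes x samples matrix with `<stage>_<rep>` column names.
#' @param stages optional explicit stage label per column.
#' @return genes x stages matrix of stage means, stages in order of first
#'   appearance.
#' @export
stage_means <- function(expr, stages = stage_of_columns(colnames(expr))) {
  lv <- unique(stages)
  out <- vapply(lv, function(s) rowMeans(expr[, stages == s, drop = FALSE]),
                numeric(nrow(expr)))
  if (nrow(expr) == 1L) out <- matrix(out, nrow = 1, dimnames = list(rownames(expr), lv))
  out
}

#' K-means clustering of temporal expression profiles
#'
#' Replicate columns are averaged per stage and each gene's stage profile is
#' z-scaled before standard k-means (multiple restarts). Genes with zero
#' variance across stages are excluded with a warning.
#'
#' @param expr expression matrix with `<stage>_<rep>` columns.
#' @param genes gene subset to cluster (default all rows).
#' @param k number of clusters (>= 2 unless k equals the gene count).
#' @param seed RNG seed for reproducible restarts.
#' @param nstart number of k-means restarts.
#' @return Object of class `cluster_model`: list with `k`, `assignments`
#'   (named integer vector), `centroids` (k x stages), `wcss`, `seed`.
#' @export
cluster_temporal_profiles <- function(expr, genes = rownames(expr), k, seed = 1,
                                      nstart = 10) {
  genes <- intersect(genes, rownames(expr))
  prof <- stage_means(expr[genes, , drop = FALSE])
  sds <- apply(prof, 1, stats::sd)
  drop <- sds == 0 | !is.finite(sds)
  if (any(drop)) {
    warnf("excluding %d gene(s) with zero variance across stages", sum(drop))
    prof <- prof[!drop, , drop = FALSE]
  }
  if (k < 1 || k > nrow(prof)) stopf("k must be in [1, number of clusterable genes]")
  z <- t(apply(prof, 1, zscale))
  colnames(z) <- colnames(prof)
  # Hartigan-Wong needs k strictly below the point count; fall back to Lloyd
  # for the degenerate one-gene-per-cluster case
  alg <- if (k < nrow(z)) "Hartigan-Wong" else "Lloyd"
  km <- with_seed(seed, stats::kmeans(z, centers = k, nstart = nstart,
                                      iter.max = 100, algorithm = alg))
  structure(list(k = k, assignments = stats::setNames(km$cluster, rownames(z)),
                 centroids = km$centers, wcss = km$tot.withinss, seed = seed),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: k=%d over %d genes (WCSS %.3f)\n",
              x$k, length(x$assignments), x$wcss))
  invisible(x)
}

#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the mean.
#'
#' @param values non-negative numeric vector, length >= 2, mean > 0.
#' @return CV, unitless.
#' @export
compute_cv <- function(values) {
  if (length(values) < 2) stopf("CV needs at least 2 values")
  m <- mean(values)
  if (m == 0) stopf("CV undefined for zero mean")
  stats::sd(values) / m
}

#' Relative expression of a homoeolog triad
#'
#' Each member's mean TPM over the requested samples divided by the triad
#' total, giving (a, b, d) summing to 1. Triads whose total mean TPM is below
#' `min_total` are flagged unexpressed (components NA).
#'
#' @param expr TPM matrix.
#' @param annotation `genome_annotation` with triad membership.
#' @param triad_id triad to evaluate.
#' @param samples columns to average over (default all).
#' @param min_total minimum triad-total TPM (default 0.5).
#' @return Named numeric (a, b, d) with attribute `unexpressed`.
#' @export
triad_relative_expression <- function(expr, annotation, triad_id,
                                      samples = colnames(expr), min_total = 0.5) {
  g <- annotation$genes
  mem <- g[!is.na(g$triad_id) & g$triad_id == triad_id, ]
  if (nrow(mem) != 3) stopf("triad %s does not have 3 members", triad_id)
  mem <- mem[match(c("A", "B", "D"), mem$subgenome), ]
  if (anyNA(mem$gene_id)) stopf("triad %s lacks one gene per subgenome", triad_id)
  if (!all(mem$gene_id %in% rownames(expr)))
    stopf("triad %s member missing from expression matrix", triad_id)
  v <- rowMeans(expr[mem$gene_id, samples, drop = FALSE])
  tot <- sum(v)
  if (tot < min_total) {
    out <- stats::setNames(rep(NA_real_, 3), c("a", "b", "d"))
    attr(out, "unexpressed") <- TRUE
    return(out)
  }
  out <- stats::setNames(as.numeric(v / tot), c("a", "b", "d"))
  attr(out, "unexpressed") <- FALSE
  out
}

# Fixed centroids of the seven triad-balance categories, in tie-break order.
triad_centroids <- function() {
  rbind(balanced = c(1, 1, 1) / 3,
        `A-dominant` = c(1, 0, 0),
        `B-dominant` = c(0, 1, 0),
        `D-dominant` = c(0, 0, 1),
        `A-suppressed` = c(0, 0.5, 0.5),
        `B-suppressed` = c(0.5, 0, 0.5),
        `D-suppressed` = c(0.5, 0.5, 0))
}

#' Classify a triad's expression balance
#'
#' Assigns the nearest (Euclidean) of seven fixed centroids on the (a, b, d)
#' simplex: balanced (1/3,1/3,1/3), the three single-homoeolog dominant
#' corners, and the three single-homoeolog suppressed mid-edges (0, 0.5,
#' 0.5) and permutations. Ties resolve in that fixed order.
#'
#' @param rel numeric (a, b, d) summing to 1; NA components (unexpressed
#'   triads) return "unexpressed".
#' @return Category label.
#' @export
classify_triad <- function(rel) {
  if (anyNA(rel)) return("unexpressed")
  if (length(rel) != 3 || any(rel < 0) || abs(sum(rel) - 1) > 1e-6)
    stopf("rel must be 3 non-negative components summing to 1")
  cen <- triad_centroids()
  d2 <- rowSums(sweep(cen, 2, as.numeric(rel))^2)
  rownames(cen)[which.min(d2)]
}

#' Triad balance over all triads
#'
#' @inheritParams triad_relative_expression
#' @return data.frame with `triad_id`, `a`, `b`, `d`, `category`.
#' @export
triad_balance_table <- function(expr, annotation, samples = colnames(expr),
                                min_total = 0.5) {
  ids <- unique(stats::na.omit(annotation$genes$triad_id))
  rows <- lapply(ids, function(tid) {
    rel <- triad_relative_expression(expr, annotation, tid, samples, min_total)
    data.frame(triad_id = tid, a = rel[["a"]], b = rel[["b"]], d = rel[["d"]],
               category = classify_triad(rel), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Correlation between expression and a promoter epigenetic mark
#'
#' For each gene, sums the mark CPM over peaks intersecting the strand-aware
#' promoter window (default -3000/+1000 bp around the TSS), averages
#' replicates per stage on both sides, z-scales the two stage series and
#' reports the Pearson correlation with a two-sided p-value. Genes without a
#' promoter peak are omitted; zero-variance series yield a flagged record
#' with r = NA.
#'
#' @param expr TPM matrix (`<stage>_<rep>` columns).
#' @param mark peaks x samples CPM matrix (rownames = peak names; stage or
#'   `<stage>_<rep>` columns).
#' @param annotation `genome_annotation`.
#' @param peaks interval data.frame of accessible peaks ([read_bed()] layout).
#' @param up,down promoter window extent upstream/downstream of the TSS (bp).
#' @return data.frame with `gene_id`, `r`, `n`, `p`, `flagged`.
#' @export
expression_mark_correlation <- function(expr, mark, annotation, peaks,
                                        up = 3000, down = 1000) {
  pm <- assign_promoter_peaks(annotation, peaks, up = up, down = down)
  es <- stage_means(expr)
  ms <- stage_means(mark)
  common <- intersect(colnames(es), colnames(ms))
  if (length(common) < 3) stopf("expression and mark share fewer than 3 stages")
  es <- es[, common, drop = FALSE]
  ms <- ms[, common, drop = FALSE]
  genes <- intersect(names(pm)[lengths(pm) > 0], rownames(es))
  rows <- lapply(genes, function(g) {
    pk <- intersect(pm[[g]], rownames(ms))
    if (!length(pk)) return(NULL)
    x <- es[g, ]
    y <- colSums(ms[pk, , drop = FALSE])
    zx <- zscale(x); zy <- zscale(y)
    if (anyNA(zx) || anyNA(zy))
      return(data.frame(gene_id = g, r = NA_real_, n = length(common),
                        p = NA_real_, flagged = TRUE, stringsAsFactors = FALSE))
    ct <- stats::cor.test(zx, zy)
    data.frame(gene_id = g, r = unname(ct$estimate), n = length(common),
               p = ct$p.value, flagged = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
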