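# TF->target network construction: TF-motif mapping, footprint-derived motif
# targets, tree-ensemble importance, with/without-footprint significance,
# signed edge assembly, and cluster-level regulation enrichment.

#' Map transcription factors to binding motifs
#'
#' Either validates an explicit tf -> motif map, or picks the best-scoring
#' motif per TF from a similarity table (ties broken by lexicographically
#' smaller motif_id). TFs without any candidate are dropped with a warning.
#'
#' @param similarities data.frame with columns `tf_id`, `motif_id`, `score`
#'   (protein-alignment similarity), or NULL when `explicit` is given.
#' @param explicit named character vector motif_id per tf_id, validated and
#'   passed through.
#' @return data.frame with `tf_id`, `motif_id`, `provenance`
#'   ("best_hit"/"supplied"), `score`.
#' @export
map_tf_to_motif <- function(similarities = NULL, explicit = NULL) {
  if (!is.null(explicit)) {
    if (is.null(names(explicit))) stopf("explicit map must be named by tf_id")
    return(data.frame(tf_id = names(explicit), motif_id = unname(explicit),
                      provenance = "supplied", score = NA_real_,
                      stringsAsFactors = FALSE))
  }
  stopifnot(all(c("tf_id", "motif_id", "score") %in% names(similarities)))
  rows <- lapply(split(similarities, similarities$tf_id), function(d) {
    d <- d[order(-d$score, d$motif_id), , drop = FALSE]
    d[1, c("tf_id", "motif_id", "score")]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$provenance <- "best_hit"
  out[, c("tf_id", "motif_id", "provenance", "score")]
}

#' Derive motif -> target-gene sets from promoter motif hits
#'
#' A gene is a target of a motif when at least one hit of that motif lies in
#' one of the gene's promoter-proximal accessible regions; with
#' `require_footprint = TRUE` (the default, the footprint-anchored mode) only
#' footprint-supported hits count.
#'
#' @param hits motif-hit data.frame with `footprint_supported` filled in.
#' @param require_footprint logical.
#' @return Named list motif_id -> character vector of target gene ids.
#' @export
derive_motif_targets <- function(hits, require_footprint = TRUE) {
  if (require_footprint) hits <- hits[hits$footprint_supported %in% TRUE, , drop = FALSE]
  lapply(split(hits$gene_id, hits$motif_id), function(g) sort(unique(g)))
}

#' Tree-ensemble regulator-importance matrix (GENIE3-style)
#'
#' For every target gene, fits a random-forest regression of the target's
#' z-scaled log2(TPM+1) profile on all other TFs' z-scaled profiles and
#' records each TF's total impurity (variance-reduction) importance,
#' normalized per target to sum to 1. Self-importance is 0. Targets are
#' processed in canonical (sorted) gene order with per-target seeds derived
#' from `seed`, so results do not depend on input row order.
#'
#' @param expr genes x samples expression matrix (TPM), >= 6 samples.
#' @param tf_ids candidate regulators (subset of rownames).
#' @param n_trees trees per target ensemble (default 1000).
#' @param mtry_rule "sqrt" (default), "third" or "all" predictors per split.
#' @param seed pipeline seed.
#' @param targets optional subset of genes to score (default all).
#' @return tf x gene matrix of importance weights; zero-variance targets get
#'   an all-zero column, recorded in attribute `flagged`.
#' @export
genie3_importance <- function(expr, tf_ids, n_trees = 1000,
                              mtry_rule = c("sqrt", "third", "all"), seed = 1,
                              targets = rownames(expr)) {
  mtry_rule <- match.arg(mtry_rule)
  if (ncol(expr) < 6) stopf("need >= 6 samples for importance estimation")
  tf_ids <- sort(intersect(tf_ids, rownames(expr)))
  if (!length(tf_ids)) stopf("no tf_ids present in expression matrix")
  targets <- sort(intersect(targets, rownames(expr)))
  lg <- log2(expr + 1)
  zmat <- t(apply(lg, 1, zscale))        # genes x samples, NA rows = constant
  rownames(zmat) <- rownames(lg)
  X <- t(zmat[tf_ids, , drop = FALSE])   # samples x tfs
  W <- matrix(0, length(tf_ids), length(targets),
              dimnames = list(tf_ids, targets))
  flagged <- character(0)
  for (ti in seq_along(targets)) {
    g <- targets[ti]
    y <- zmat[g, ]
    if (anyNA(y)) { flagged <- c(flagged, g); next }
    pred <- setdiff(tf_ids, g)
    if (!length(pred)) next
    Xp <- X[, pred, drop = FALSE]
    if (anyNA(Xp)) Xp[is.na(Xp)] <- 0   # constant TFs carry no signal
    p <- ncol(Xp)
    mtry <- switch(mtry_rule, sqrt = max(1L, floor(sqrt(p))),
                   third = max(1L, floor(p / 3)), all = p)
    d <- data.frame(.y = y, Xp, check.names = FALSE)
    fit <- ranger::ranger(dependent.variable.name = ".y", data = d,
                          num.trees = n_trees, mtry = mtry,
                          importance = "impurity", num.threads = 1,
                          seed = derive_seed(seed, ti))
    imp <- pmax(fit$variable.importance, 0)
    tot <- sum(imp)
    if (tot > 0) W[pred, ti] <- imp / tot
  }
  attr(W, "flagged") <- flagged
  W
}

#' One-sided Mann-Whitney U test (x stochastically greater than y)
#'
#' Exact p by full enumeration of all choose(n1+n2, n1) group labelings when
#' that count is at most `max_enum` (ties handled correctly); otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y numeric samples.
#' @param max_enum enumeration budget (default 2e5 labelings, covering groups
#'   of up to 10 vs 10).
#' @return list with `U`, `p`, `method` ("exact"/"normal").
#' @export
mann_whitney_test <- function(x, y, max_enum = 2e5) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n_comb <- choose(N, min(n1, n2))
  if (is.finite(n_comb) && n_comb <= max_enum) {
    idx <- utils::combn(N, n1)
    rs <- colSums(matrix(r[idx], nrow = n1))
    Us <- rs - n1 * (n1 + 1) / 2
    p <- mean(Us >= U - 1e-12)
    return(list(U = U, p = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  tie <- table(r)
  sig2 <- n1 * n2 / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
  z <- (U - mu - 0.5) / sqrt(sig2)
  list(U = U, p = stats::pnorm(z, lower.tail = FALSE), method = "normal")
}

#' Footprint-conditioned TF significance
#'
#' For each TF, compares its transcriptional correlation with genes carrying
#' a footprint-supported motif occurrence in their promoter against genes
#' without one, using a one-sided Mann-Whitney U test (footprint-positive >
#' footprint-negative). P-values are BH-adjusted across tested TFs. The
#' default statistic is |Pearson r| of TF and gene log2(TPM+1) profiles;
#' `stat = "weight"` compares the tree-ensemble importance weights instead
#' (with many co-expressed TFs, importance diffuses across correlated
#' regulators, which costs this mode power).
#'
#' @param weights tf x gene matrix from [genie3_importance()] (defines the
#'   TF and gene universes; compared directly when `stat = "weight"`).
#' @param motif_targets named list from [derive_motif_targets()].
#' @param tf_motif data.frame from [map_tf_to_motif()].
#' @param alpha significance level carried into the result (default 0.05).
#' @param min_group minimum genes per group (default 5); smaller TFs are
#'   reported untested.
#' @param stat "pearson" (default) compares |r| computed from `expr`;
#'   "weight" compares importance weights.
#' @param expr expression matrix, required for `stat = "pearson"`.
#' @return data.frame with `tf_id`, `n_pos`, `n_neg`, `U`, `p`, `q`,
#'   `tested`, `significant`.
#' @export
footprint_conditioned_significance <- function(weights, motif_targets, tf_motif,
                                               alpha = 0.05, min_group = 5,
                                               stat = c("pearson", "weight"),
                                               expr = NULL) {
  stat <- match.arg(stat)
  if (stat == "pearson" && is.null(expr)) stopf("stat='pearson' needs expr")
  genes <- colnames(weights)
  if (stat == "pearson") {
    lg <- log2(expr[intersect(rownames(expr), union(genes, rownames(weights))), ,
                    drop = FALSE] + 1)
  }
  rows <- lapply(rownames(weights), function(tf) {
    motif <- tf_motif$motif_id[match(tf, tf_motif$tf_id)]
    pos <- setdiff(intersect(motif_targets[[motif]] %||% character(0), genes), tf)
    neg <- setdiff(genes, c(pos, tf))
    if (length(pos) < min_group || length(neg) < min_group)
      return(data.frame(tf_id = tf, n_pos = length(pos), n_neg = length(neg),
                        U = NA_real_, p = NA_real_, tested = FALSE,
                        stringsAsFactors = FALSE))
    if (stat == "weight") {
      xv <- weights[tf, pos]; yv <- weights[tf, neg]
    } else {
      rv <- suppressWarnings(abs(as.vector(stats::cor(t(lg[c(pos, neg), , drop = FALSE]),
                                                      lg[tf, ]))))
      rv[is.na(rv)] <- 0
      xv <- rv[seq_along(pos)]; yv <- rv[length(pos) + seq_along(neg)]
    }
    mw <- mann_whitney_test(xv, yv)
    data.frame(tf_id = tf, n_pos = length(pos), n_neg = length(neg),
               U = mw$U, p = mw$p, tested = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  out$q[out$tested] <- stats::p.adjust(out$p[out$tested], method = "BH")
  out$significant <- !is.na(out$q) & out$q <= alpha
  attr(out, "alpha") <- alpha
  out
}

#' Assemble the footprint-anchored transcriptional regulatory network
#'
#' An edge tf -> target is retained when (i) the target carries a motif
#' occurrence of the TF's motif in its promoter-proximal accessible
#' chromatin (per `motif_targets`), (ii) the TF's footprint-conditioned
#' significance passes q <= alpha, and (iii) the importance weight reaches
#' the TF's `weight_quantile` quantile over all genes. The edge sign is the
#' sign of the Pearson correlation between TF and target log2(TPM+1)
#' profiles, with a dead zone: |r| < r_min gives sign 0.
#'
#' @param weights tf x gene importance matrix.
#' @param motif_targets named list motif -> targets.
#' @param tf_motif TF-motif map data.frame.
#' @param expr expression matrix used for edge signs.
#' @param tf_significance result of [footprint_conditioned_significance()].
#' @param alpha TF-level significance threshold (default 0.05).
#' @param weight_quantile per-TF weight quantile an edge must reach (default
#'   0.75).
#' @param r_min dead zone for the sign correlation (default 0.1).
#' @param footprint_supported logical recorded on every edge (TRUE when
#'   `motif_targets` was derived with footprints required).
#' @return Object of class `trn`: list with `edges` (data.frame `tf_id`,
#'   `target_id`, `weight`, `sign`, `r`, `footprint_supported`),
#'   `tf_significance`, `thresholds`.
#' @export
assemble_trn <- function(weights, motif_targets, tf_motif, expr, tf_significance,
                         alpha = 0.05, weight_quantile = 0.75, r_min = 0.1,
                         footprint_supported = TRUE) {
  sig_tfs <- tf_significance$tf_id[tf_significance$tested &
                                     !is.na(tf_significance$q) &
                                     tf_significance$q <= alpha]
  lg <- log2(expr + 1)
  edges <- list()
  for (tf in sort(sig_tfs)) {
    if (!tf %in% rownames(weights)) stopf("tf %s absent from weights", tf)
    motif <- tf_motif$motif_id[match(tf, tf_motif$tf_id)]
    cand <- setdiff(intersect(motif_targets[[motif]] %||% character(0),
                              colnames(weights)), tf)
    if (!length(cand)) next
    thr <- stats::quantile(weights[tf, ], probs = weight_quantile, names = FALSE)
    keep <- cand[weights[tf, cand] >= thr]
    if (!length(keep)) next
    r <- vapply(keep, function(g) pearson_r(lg[tf, ], lg[g, ]), 0)
    r[is.na(r)] <- 0
    edges[[tf]] <- data.frame(
      tf_id = tf, target_id = keep, weight = unname(weights[tf, keep]),
      sign = ifelse(abs(r) >= r_min, sign(r), 0), r = unname(r),
      footprint_supported = footprint_supported, stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(tf_id = character(), target_id = character(), weight = numeric(),
               sign = numeric(), r = numeric(), footprint_supported = logical(),
               stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(edges = edges, tf_significance = tf_significance,
                 thresholds = list(alpha = alpha, weight_quantile = weight_quantile,
                                   r_min = r_min)),
            class = "trn")
}

#' @export
print.trn <- function(x, ...) {
  cat(sprintf("trn: %d edges, %d TFs, %d targets\n", nrow(x$edges),
              length(unique(x$edges$tf_id)), length(unique(x$edges$target_id))))
  invisible(x)
}

#' Write a TRN edge list and its TF significance to disk
#' @param trn a `trn`.
#' @param edges_path TSV path for the edge list.
#' @param json_path optional JSON path for TF significance + thresholds.
#' @return `edges_path`, invisibly.
#' @export
write_trn <- function(trn, edges_path, json_path = NULL) {
  utils::write.table(trn$edges, edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(tf_significance = trn$tf_significance,
                              thresholds = trn$thresholds),
                         json_path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(edges_path)
}

#' Cluster-by-cluster regulation counts and enrichment
#'
#' Cell (i, j) counts TRN edges from TFs in cluster i to targets in cluster
#' j. Over-representation of cluster-j targets among cluster-i TFs' edges is
#' scored by a hypergeometric upper-tail p, BH-adjusted across cells.
#'
#' @param trn a `trn`.
#' @param clusters a `cluster_model` (or named vector of cluster labels).
#' @return list with `counts` (k x k), `p`, `q` matrices, and `n_dropped`
#'   (edges with an unclustered endpoint).
#' @export
cluster_regulation_enrichment <- function(trn, clusters) {
  lab <- if (inherits(clusters, "cluster_model")) clusters$assignments else clusters
  ks <- sort(unique(lab))
  if (length(ks) < 2) stopf("need at least 2 clusters")
  e <- trn$edges
  ok <- e$tf_id %in% names(lab) & e$target_id %in% names(lab)
  n_dropped <- sum(!ok)
  e <- e[ok, , drop = FALSE]
  ci <- factor(lab[e$tf_id], levels = ks)
  cj <- factor(lab[e$target_id], levels = ks)
  counts <- table(ci, cj)
  counts <- matrix(as.integer(counts), length(ks), length(ks),
                   dimnames = list(paste0("C", ks), paste0("C", ks)))
  tot <- sum(counts)
  to_j <- colSums(counts)
  from_i <- rowSums(counts)
  p <- matrix(NA_real_, length(ks), length(ks), dimnames = dimnames(counts))
  for (i in seq_along(ks)) for (j in seq_along(ks))
    p[i, j] <- stats::phyper(counts[i, j] - 1, to_j[j], tot - to_j[j],
                             from_i[i], lower.tail = FALSE)
  q <- matrix(stats::p.adjust(p, method = "BH"), nrow(p), dimnames = dimnames(p))
  list(counts = counts, p = p, q = q, n_dropped = n_dropped)
}
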