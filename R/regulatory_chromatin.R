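# Promoter-proximal peak assignment, PWM scanning, footprint support,
# motif-count dynamics, and background-matched TF-activity deviations.

#' Assign accessible peaks to promoter windows
#'
#' The promoter window is strand-aware: for "+" genes \[tss-up, tss+down),
#' for "-" genes the mirror \[tss-down+1, tss+up+1), so "upstream" always
#' means 5' of the gene. Windows are clipped at chromosome bounds. A peak may
#' be assigned to several genes; assignment requires a non-empty overlap.
#'
#' @param annotation `genome_annotation`.
#' @param peaks interval data.frame ([read_bed()] layout) with unique names.
#' @param up,down window extent upstream/downstream of the TSS in bp
#'   (defaults 3000/1000).
#' @return Named list: gene_id -> character vector of intersecting peak
#'   names, with the window parameters as attributes.
#' @export
assign_promoter_peaks <- function(annotation, peaks, up = 3000, down = 1000) {
  g <- annotation$genes
  ws <- ifelse(g$strand == "+", g$tss - up, g$tss - down + 1)
  we <- ifelse(g$strand == "+", g$tss + down, g$tss + up + 1)
  ws <- pmax(ws, 0)
  we <- pmin(we, annotation$chrom_sizes[g$chrom])
  win <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(ws + 1, we))
  pk <- as_granges0(peaks)
  ov <- GenomicRanges::findOverlaps(win, pk, ignore.strand = TRUE)
  out <- stats::setNames(vector("list", nrow(g)), g$gene_id)
  for (i in seq_len(nrow(g))) out[[i]] <- character(0)
  hits <- split(peaks$name[S4Vectors::subjectHits(ov)],
                g$gene_id[S4Vectors::queryHits(ov)])
  out[names(hits)] <- hits
  attr(out, "up") <- up
  attr(out, "down") <- down
  out
}

# Log-odds score matrix of a PWM against a uniform 0.25 background (bits).
pwm_lod <- function(p) log2(p$matrix / 0.25)

#' Maximum attainable log-odds score of a PWM (bits)
#' @param p a `pwm`.
#' @return Sum over columns of the best per-base log-odds.
#' @export
pwm_max_score <- function(p) sum(apply(pwm_lod(p), 2, max))

#' Scan a sequence with a PWM
#'
#' Scores every window of PWM length on both strands with the log2-odds of
#' the PWM against a uniform 0.25 background; a window is a hit when its
#' score reaches `threshold_frac` times the maximum attainable score.
#' Windows containing N are skipped. Reverse-strand hits are reported at
#' their leftmost forward-strand coordinate.
#'
#' @param sequence character string or `DNAString` over A/C/G/T/N.
#' @param pwm a `pwm`.
#' @param threshold_frac fraction of the maximum score (0 < f <= 1, default
#'   0.8).
#' @return data.frame with `offset` (0-based within the sequence), `strand`,
#'   `score` (bits).
#' @export
scan_pwm <- function(sequence, pwm, threshold_frac = 0.8) {
  s <- toupper(as.character(sequence))
  base_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  idx <- unname(base_idx[strsplit(s, "", fixed = TRUE)[[1]]])  # NA for N
  scan_pwm_indexed(idx, pwm, threshold_frac)
}

# Lean scanning core over a pre-indexed sequence (1..4, NA for N): returns
# NULL or a list of parallel vectors, ordered by offset then strand.
scan_core <- function(idx, lod, thr, L) {
  n <- length(idx)
  if (n < L) return(NULL)
  score_strand <- function(ix) {
    nw <- n - L + 1L
    sc <- rep(0, nw)
    for (j in seq_len(L)) sc <- sc + lod[, j][ix[j:(j + nw - 1L)]]
    sc
  }
  fwd <- score_strand(idx)
  rev_idx <- rev(5L - idx)  # reverse complement in index space (NA stays NA)
  rv <- rev(score_strand(rev_idx))  # align window i to forward offset i
  keep_f <- which(!is.na(fwd) & fwd >= thr)
  keep_r <- which(!is.na(rv) & rv >= thr)
  if (!length(keep_f) && !length(keep_r)) return(NULL)
  offset <- c(keep_f, keep_r) - 1L
  strand <- rep(c("+", "-"), c(length(keep_f), length(keep_r)))
  score <- c(fwd[keep_f], rv[keep_r])
  o <- order(offset, strand)
  list(offset = offset[o], strand = strand[o], score = score[o])
}

# data.frame wrapper over scan_core; shared by scan_pwm and the peak scanner.
scan_pwm_indexed <- function(idx, pwm, threshold_frac = 0.8) {
  if (threshold_frac <= 0 || threshold_frac > 1) stopf("threshold_frac must be in (0, 1]")
  h <- scan_core(idx, pwm_lod(pwm), threshold_frac * pwm_max_score(pwm),
                 ncol(pwm$matrix))
  if (is.null(h))
    return(data.frame(offset = integer(), strand = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  data.frame(offset = h$offset, strand = h$strand, score = h$score,
             stringsAsFactors = FALSE)
}

#' Scan promoter-proximal peaks for motif occurrences
#'
#' Extracts each peak's sequence from the genome, scans it with every PWM,
#' and attributes hits to the genes owning the peak via the promoter map.
#'
#' @param genome `DNAStringSet` (or named character) of chromosome sequences.
#' @param peaks interval data.frame with unique `name`s.
#' @param pwms list of `pwm` objects.
#' @param promoter_map output of [assign_promoter_peaks()].
#' @param threshold_frac passed to [scan_pwm()].
#' @return data.frame of motif hits: `motif_id`, `peak`, `gene_id`, `chrom`,
#'   `offset` (0-based chromosomal), `strand`, `score`,
#'   `footprint_supported` (NA until [mark_footprint_support()]).
#' @export
scan_promoter_peaks <- function(genome, peaks, pwms, promoter_map,
                                threshold_frac = 0.8) {
  if (!methods::is(genome, "DNAStringSet")) genome <- Biostrings::DNAStringSet(genome)
  gene_of_peak <- split(rep(names(promoter_map), lengths(promoter_map)),
                        unlist(promoter_map, use.names = FALSE))
  use <- peaks[peaks$name %in% names(gene_of_peak), , drop = FALSE]
  base_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  lods <- lapply(pwms, pwm_lod)
  thrs <- vapply(pwms, function(p) threshold_frac * pwm_max_score(p), 0)
  Ls <- vapply(pwms, function(p) ncol(p$matrix), 0L)
  if (threshold_frac <= 0 || threshold_frac > 1) stopf("threshold_frac must be in (0, 1]")
  acc <- list(motif_id = list(), peak = list(), gene_id = list(), chrom = list(),
              offset = list(), strand = list(), score = list(), width = list())
  push <- function(...) {
    vals <- list(...)
    for (f in names(vals)) acc[[f]][[length(acc[[f]]) + 1L]] <<- vals[[f]]
  }
  for (i in seq_len(nrow(use))) {
    seq_i <- as.character(Biostrings::subseq(genome[[use$chrom[i]]],
                                             use$start[i] + 1, use$end[i]))
    idx <- unname(base_idx[strsplit(toupper(seq_i), "", fixed = TRUE)[[1]]])
    genes_i <- gene_of_peak[[use$name[i]]]
    ng <- length(genes_i)
    for (k in seq_along(pwms)) {
      h <- scan_core(idx, lods[[k]], thrs[k], Ls[k])
      if (is.null(h)) next
      nh <- length(h$offset)
      push(motif_id = rep(pwms[[k]]$motif_id, nh * ng),
           peak = rep(use$name[i], nh * ng),
           gene_id = rep(genes_i, each = nh),
           chrom = rep(use$chrom[i], nh * ng),
           offset = use$start[i] + rep(h$offset, ng),
           strand = rep(h$strand, ng),
           score = rep(h$score, ng),
           width = rep(Ls[k], nh * ng))
    }
  }
  out <- data.frame(
    motif_id = unlist(acc$motif_id) %||% character(0),
    peak = unlist(acc$peak) %||% character(0),
    gene_id = unlist(acc$gene_id) %||% character(0),
    chrom = unlist(acc$chrom) %||% character(0),
    offset = unlist(acc$offset) %||% numeric(0),
    strand = unlist(acc$strand) %||% character(0),
    score = unlist(acc$score) %||% numeric(0),
    width = unlist(acc$width) %||% integer(0),
    stringsAsFactors = FALSE)
  out$footprint_supported <- rep(NA, nrow(out))
  out
}

#' Mark motif hits supported by ATAC footprints
#'
#' A hit is footprint-supported when at least `min_overlap_frac` of its span
#' lies within a single footprint interval (default 1.0: fully contained).
#'
#' @param hits data.frame from [scan_promoter_peaks()].
#' @param footprints interval data.frame ([read_bed()] layout).
#' @param min_overlap_frac minimum covered fraction of the hit span.
#' @return `hits` with `footprint_supported` filled in.
#' @export
mark_footprint_support <- function(hits, footprints, min_overlap_frac = 1.0) {
  if (!nrow(hits)) { hits$footprint_supported <- logical(0); return(hits) }
  hg <- GenomicRanges::GRanges(hits$chrom,
                               IRanges::IRanges(hits$offset + 1, hits$offset + hits$width))
  fg <- as_granges0(footprints)
  ov <- GenomicRanges::findOverlaps(hg, fg, ignore.strand = TRUE)
  supported <- rep(FALSE, nrow(hits))
  if (length(ov)) {
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    inter <- pmin(hits$offset[qi] + hits$width[qi], footprints$end[si]) -
      pmax(hits$offset[qi], footprints$start[si])
    frac <- inter / hits$width[qi]
    ok <- tapply(frac, qi, max) >= min_overlap_frac
    supported[as.integer(names(ok))] <- as.logical(ok)
  }
  hits$footprint_supported <- supported
  hits
}

#' Footprint depletion score of a candidate binding site
#'
#' Ratio of mean Tn5 cut density in the flanks to mean density in the core
#' (+1 in the denominator); higher means more protected. A simple descriptive
#' score over a per-base cut-count profile.
#'
#' @param cut_counts numeric vector of per-base cut counts.
#' @param core integer pair (start, end), 1-based inclusive indices of the
#'   core within `cut_counts`.
#' @param flank_width flank width in bp on each side (> 0).
#' @return Depletion score.
#' @export
footprint_depletion_score <- function(cut_counts, core, flank_width) {
  if (flank_width <= 0) stopf("flank_width must be > 0")
  a <- core[1]; b <- core[2]
  if (a - flank_width < 1 || b + flank_width > length(cut_counts))
    stopf("core +/- flank exceeds profile bounds")
  flank <- c(cut_counts[(a - flank_width):(a - 1)],
             cut_counts[(b + 1):(b + flank_width)])
  mean(flank) / (mean(cut_counts[a:b]) + 1)
}

#' Motif-occurrence counts by developmental stage
#'
#' Counts, for each stage, the hits whose span lies fully within a peak that
#' is accessible at that stage.
#'
#' @param hits motif-hit data.frame.
#' @param stage_peaks named list: stage label -> interval data.frame of peaks
#'   accessible at that stage.
#' @param gene_subset optional gene ids to restrict the hits to.
#' @param stages stage labels to tabulate (default all in `stage_peaks`).
#' @return Named integer vector of counts per stage.
#' @export
motif_count_by_stage <- function(hits, stage_peaks, gene_subset = NULL,
                                 stages = names(stage_peaks)) {
  unknown <- setdiff(stages, names(stage_peaks))
  if (length(unknown)) stopf("unknown stage label: %s", unknown[1])
  if (!is.null(gene_subset)) hits <- hits[hits$gene_id %in% gene_subset, , drop = FALSE]
  vapply(stages, function(s) {
    pk <- stage_peaks[[s]]
    if (!nrow(hits) || !nrow(pk)) return(0L)
    n <- 0L
    for (i in seq_len(nrow(hits))) {
      inside <- pk$chrom == hits$chrom[i] & pk$start <= hits$offset[i] &
        pk$end >= hits$offset[i] + hits$width[i]
      if (any(inside)) n <- n + 1L
    }
    n
  }, integer(1))
}

#' Background-matched TF-activity deviation scores
#'
#' For each motif's peak set, the expected count in sample s is the set's
#' share of mean accessibility times the sample's total counts; the raw
#' deviation is (observed - expected) / expected. Each motif set is compared
#' with `n_background` random peak sets of equal size drawn from the same
#' mean-accessibility bins, giving a deviation z-score per sample
#' (chromVAR-style, without GC matching).
#'
#' @param peak_counts peaks x samples non-negative matrix (rownames = peak
#'   names).
#' @param motif_membership named list: motif_id -> character vector of member
#'   peak names (each motif needs >= 1 member).
#' @param n_background number of background sets (default 50).
#' @param n_bins number of accessibility bins (default 10).
#' @param seed RNG seed.
#' @return Object of class `activity_matrix`: list with `z` and `raw`
#'   (motif x sample matrices), `flagged` (motifs with undefined z),
#'   `n_background`, `seed`.
#' @export
tf_activity_deviation <- function(peak_counts, motif_membership,
                                  n_background = 50, n_bins = 10, seed = 1) {
  if (any(peak_counts < 0)) stopf("peak counts must be non-negative")
  peaks <- rownames(peak_counts)
  if (is.null(peaks)) stopf("peak_counts needs rownames")
  tot <- sum(peak_counts)
  frac <- rowSums(peak_counts) / tot            # mean-accessibility fraction
  col_tot <- colSums(peak_counts)
  mm <- rowMeans(peak_counts)
  br <- unique(stats::quantile(mm, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(mm, breaks = br, include.lowest = TRUE, labels = FALSE)
  by_bin <- split(seq_along(peaks), bin)
  raw_dev <- function(members) {
    idx <- match(members, peaks)
    exp_s <- sum(frac[idx]) * col_tot
    obs_s <- colSums(peak_counts[idx, , drop = FALSE])
    if (all(exp_s == 0)) stopf("motif peak set has zero expected counts")
    (obs_s - exp_s) / exp_s
  }
  with_seed(seed, {
    z <- raw <- matrix(NA_real_, length(motif_membership), ncol(peak_counts),
                       dimnames = list(names(motif_membership), colnames(peak_counts)))
    flagged <- character(0)
    for (m in names(motif_membership)) {
      members <- motif_membership[[m]]
      if (!length(members) || !all(members %in% peaks))
        stopf("motif %s has missing or unknown member peaks", m)
      obs_raw <- raw_dev(members)
      idx <- match(members, peaks)
      bg_raw <- matrix(NA_real_, n_background, ncol(peak_counts))
      for (b in seq_len(n_background)) {
        bg_idx <- vapply(idx, function(i) {
          pool <- by_bin[[as.character(bin[i])]]
          pool[sample.int(length(pool), 1L)]
        }, integer(1))
        bg_raw[b, ] <- raw_dev(peaks[bg_idx])
      }
      mu <- colMeans(bg_raw)
      sdv <- apply(bg_raw, 2, stats::sd)
      zi <- (obs_raw - mu) / sdv
      # a degenerate background with zero spread is only informative when the
      # observed deviation equals the background's: that is exactly null
      zi[sdv == 0 & obs_raw == mu] <- 0
      if (any(!is.finite(zi))) flagged <- c(flagged, m)
      z[m, ] <- zi
      raw[m, ] <- obs_raw
    }
    structure(list(z = z, raw = raw, flagged = flagged,
                   n_background = n_background, seed = seed),
              class = "activity_matrix")
  })
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat(sprintf("activity_matrix: %d motifs x %d samples (%d background sets)\n",
              nrow(x$z), ncol(x$z), x$n_background))
  invisible(x)
}
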