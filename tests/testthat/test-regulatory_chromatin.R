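test_that("promoter windows are strand-aware, half-open and clipped", {
  ann <- toy_annotation(tss = 5000, strand = "+")
  pk <- interval_df("chr1A", c(2000, 1900, 5990), c(2100, 2000, 6100),
                    c("in", "out", "edge"))
  pm <- assign_promoter_peaks(ann, pk)   # window [2000, 6000)
  expect_true("in" %in% pm$g1)
  expect_false("out" %in% pm$g1)        # ends exactly at window start
  expect_true("edge" %in% pm$g1)        # overlaps [5990, 6000)
  pk2 <- interval_df("chr1A", 6000, 6100, "past")
  expect_length(assign_promoter_peaks(ann, pk2)$g1, 0)
  # "-" gene: upstream is to the right; window [tss-999, tss+3001)
  annm <- toy_annotation(tss = 5000, strand = "-")
  pkm <- interval_df("chr1A", c(7900, 8100, 4000), c(8000, 8200, 4002),
                     c("up_in", "up_out", "down_in"))
  pmm <- assign_promoter_peaks(annm, pkm)
  expect_setequal(pmm$g1, c("up_in", "down_in"))
  # clipping at chromosome start is not an error
  ann0 <- genome_annotation(
    data.frame(gene_id = "g0", chrom = "chr1A", start = 100, end = 600,
               strand = "+", stringsAsFactors = FALSE), c(chr1A = 1e4))
  expect_silent(assign_promoter_peaks(ann0, interval_df("chr1A", 0, 50, "p")))
})

test_that("promoter assignment equals brute-force all-pairs overlap", {
  set.seed(21)
  n <- 200
  genes <- data.frame(gene_id = sprintf("g%03d", 1:n),
                      chrom = sample(c("chr1A", "chr1B"), n, TRUE),
                      start = sample.int(5e5, n), strand = sample(c("+", "-"), n, TRUE),
                      stringsAsFactors = FALSE)
  genes$end <- genes$start + sample(500:3000, n, TRUE)
  ann <- genome_annotation(genes, c(chr1A = 1e6, chr1B = 1e6))
  ps <- sample.int(9e5, n)
  pk <- interval_df(sample(c("chr1A", "chr1B"), n, TRUE), ps, ps + sample(200:2000, n, TRUE))
  pm <- assign_promoter_peaks(ann, pk, up = 3000, down = 1000)
  g <- ann$genes
  for (i in seq_len(nrow(g))) {
    ws <- if (g$strand[i] == "+") g$tss[i] - 3000 else g$tss[i] - 1000 + 1
    we <- if (g$strand[i] == "+") g$tss[i] + 1000 else g$tss[i] + 3000 + 1
    ws <- max(ws, 0)
    brute <- pk$name[pk$chrom == g$chrom[i] & pk$start < we & pk$end > ws]
    expect_setequal(pm[[g$gene_id[i]]], brute)
  }
})

test_that("PWM scanning scores log2 odds on both strands", {
  pa <- pwm("PA", "t", matrix(c(10, 0, 0, 0), 4, 1), pseudocount = 0)
  h <- scan_pwm("AAA", pa, threshold_frac = 1)
  expect_equal(nrow(h), 3L)
  expect_equal(h$offset, 0:2)
  expect_true(all(h$strand == "+"))
  expect_equal(h$score, rep(2, 3), tolerance = 1e-12)
  # palindromic consensus (ACGT is its own reverse complement):
  # forward and reverse hits at the same offset
  pal <- pwm("PAL", "t", {
    m <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
    m["A", 1] <- 10; m["C", 2] <- 10; m["G", 3] <- 10; m["T", 4] <- 10
    m
  }, pseudocount = 0)
  hp <- scan_pwm("ACGT", pal, threshold_frac = 1)
  expect_equal(nrow(hp), 2L)
  expect_equal(hp$offset, c(0L, 0L))
  expect_setequal(hp$strand, c("+", "-"))
  # sequence shorter than the motif -> empty
  expect_equal(nrow(scan_pwm("AC", pal)), 0L)
})

test_that("PWM scanning equals exhaustive window scoring on random input", {
  set.seed(31)
  revcomp <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  for (rep in 1:5) {
    p <- random_pwm(8)
    seqc <- paste(sample(c("A", "C", "G", "T", "N"), 200, TRUE,
                         prob = c(.24, .24, .24, .24, .04)), collapse = "")
    thr_frac <- 0.6
    hits <- scan_pwm(seqc, p, thr_frac)
    lod <- log2(p$matrix / 0.25)
    maxs <- sum(apply(lod, 2, max))
    score1 <- function(w) {
      b <- strsplit(w, "")[[1]]
      if (any(!b %in% c("A", "C", "G", "T"))) return(NA_real_)
      sum(lod[cbind(match(b, c("A", "C", "G", "T")), seq_along(b))])
    }
    brute <- list()
    for (o in 0:(200 - 8)) {
      w <- substr(seqc, o + 1, o + 8)
      for (sdir in c("+", "-")) {
        sc <- if (sdir == "+") score1(w) else score1(revcomp(w))
        if (!is.na(sc) && sc >= thr_frac * maxs)
          brute[[length(brute) + 1L]] <- data.frame(offset = o, strand = sdir,
                                                    score = sc, stringsAsFactors = FALSE)
      }
    }
    brute <- do.call(rbind, brute)
    brute <- brute[order(brute$offset, brute$strand), , drop = FALSE]
    rownames(brute) <- NULL
    rownames(hits) <- NULL
    expect_equal(hits, brute, tolerance = 1e-12)
  }
})

test_that("footprint support requires the configured overlap fraction", {
  mkhit <- function(start, width = 10) data.frame(
    motif_id = "M", peak = "p", gene_id = "g", chrom = "chr1A", offset = start,
    strand = "+", score = 1, width = width, footprint_supported = NA,
    stringsAsFactors = FALSE)
  fp <- interval_df("chr1A", 90, 120, "f1")
  expect_true(mark_footprint_support(mkhit(100), fp)$footprint_supported)
  fp2 <- interval_df("chr1A", 105, 120, "f2")
  expect_false(mark_footprint_support(mkhit(100), fp2)$footprint_supported)
  expect_true(mark_footprint_support(mkhit(100), fp2, min_overlap_frac = 0.5)$footprint_supported)
})

test_that("footprint support equals brute-force overlap fractions on random pairs", {
  set.seed(41)
  n <- 500
  hs <- sample.int(1e4, n)
  hits <- data.frame(motif_id = "M", peak = "p", gene_id = "g",
                     chrom = sample(c("c1", "c2"), n, TRUE), offset = hs,
                     strand = "+", score = 1, width = sample(5:15, n, TRUE),
                     footprint_supported = NA, stringsAsFactors = FALSE)
  fs <- sample.int(1e4, 300)
  fps <- interval_df(sample(c("c1", "c2"), 300, TRUE), fs, fs + sample(5:40, 300, TRUE))
  for (frac in c(1, 0.5)) {
    got <- mark_footprint_support(hits, fps, min_overlap_frac = frac)$footprint_supported
    brute <- vapply(seq_len(n), function(i) {
      same <- fps$chrom == hits$chrom[i]
      ov <- pmin(hits$offset[i] + hits$width[i], fps$end[same]) -
        pmax(hits$offset[i], fps$start[same])
      any(ov / hits$width[i] >= frac)
    }, TRUE)
    expect_identical(got, brute)
  }
})

test_that("footprint depletion score follows its definition", {
  expect_equal(footprint_depletion_score(rep(10, 30), c(11, 20), 5), 10 / 11,
               tolerance = 1e-12)
  prof <- c(rep(20, 5), rep(0, 10), rep(20, 5))
  expect_equal(footprint_depletion_score(prof, c(6, 15), 5), 20)
  expect_equal(footprint_depletion_score(rep(0, 30), c(11, 20), 5), 0)
  expect_error(footprint_depletion_score(rep(1, 30), c(11, 20), 0), "flank_width")
  expect_error(footprint_depletion_score(rep(1, 30), c(2, 20), 5), "bounds")
})

test_that("motif counts by stage tally full containment in stage peaks", {
  hits <- data.frame(motif_id = "M", peak = "p", gene_id = c("g1", "g2"),
                     chrom = "c1", offset = c(100, 500), strand = "+", score = 1,
                     width = 8, footprint_supported = TRUE, stringsAsFactors = FALSE)
  sp <- list(DAP4 = interval_df("c1", 90, 120, "a"),
             DAP8 = interval_df("c1", c(90, 490), c(120, 520), c("a", "b")))
  ct <- motif_count_by_stage(hits, sp)
  expect_equal(unname(ct), c(1L, 2L))
  expect_equal(unname(motif_count_by_stage(hits, sp, gene_subset = character(0))),
               c(0L, 0L))
  expect_error(motif_count_by_stage(hits, sp, stages = "DAP99"), "unknown stage")
  # brute-force tally on random stage-varying peak sets
  set.seed(51)
  hs <- sample.int(5000, 120)
  rh <- data.frame(motif_id = "M", peak = "p", gene_id = "g", chrom = "c1",
                   offset = hs, strand = "+", score = 1, width = 8,
                   footprint_supported = TRUE, stringsAsFactors = FALSE)
  sps <- lapply(1:4, function(i) {
    s <- sample.int(5000, 40)
    interval_df("c1", s, s + sample(5:60, 40, TRUE))
  })
  names(sps) <- paste0("DAP", 1:4)
  got <- motif_count_by_stage(rh, sps)
  brute <- vapply(sps, function(pk) sum(vapply(seq_len(nrow(rh)), function(i)
    any(pk$start <= rh$offset[i] & pk$end >= rh$offset[i] + 8), TRUE)), 0)
  expect_equal(unname(got), unname(as.integer(brute)))
})

test_that("activity deviations are null on homogeneous counts and conserve totals", {
  counts <- matrix(5, 60, 6, dimnames = list(sprintf("p%02d", 1:60), paste0("s", 1:6)))
  mem <- list(M1 = sprintf("p%02d", 1:10), M2 = sprintf("p%02d", 21:35))
  act <- tf_activity_deviation(counts, mem, n_background = 20, seed = 3)
  expect_equal(unname(act$raw), matrix(0, 2, 6), tolerance = 1e-12)
  expect_equal(unname(act$z), matrix(0, 2, 6))
  # conservation: sum_s observed = sum_s expected for any counts
  set.seed(8)
  counts2 <- matrix(rpois(360, 30), 60, 6, dimnames = dimnames(counts))
  act2 <- tf_activity_deviation(counts2, mem, n_background = 20, seed = 3)
  for (m in names(mem)) {
    obs <- colSums(counts2[mem[[m]], ])
    expc <- obs / (1 + act2$raw[m, ])
    expect_equal(sum(obs), sum(expc), tolerance = 1e-6 * sum(obs))
  }
  # determinism
  act3 <- tf_activity_deviation(counts2, mem, n_background = 20, seed = 3)
  expect_identical(act2$z, act3$z)
})

test_that("planted accessibility enrichment is detected; permuted membership is null", {
  set.seed(12)
  peaks <- sprintf("p%03d", 1:200)
  zmax <- replicate(5, {
    counts <- matrix(rpois(200 * 8, 50), 200, 8,
                     dimnames = list(peaks, paste0("s", 1:8)))
    members <- sample(peaks, 20)
    counts[members, 3] <- counts[members, 3] * 2
    act <- tf_activity_deviation(counts, list(M = members), n_background = 50,
                                 seed = sample.int(1e6, 1))
    c(which.max(act$z["M", ]), act$z["M", 3])
  })
  expect_true(all(zmax[1, ] == 3))
  expect_gt(mean(zmax[2, ]), 2)
  # permutation null
  counts <- matrix(rpois(200 * 8, 50), 200, 8, dimnames = list(peaks, paste0("s", 1:8)))
  # a random membership behaves like its own background: z is centred at 0
  # (per-entry |z| is ~N(0,1), so the unbiasedness is what is checkable)
  zs <- replicate(20, {
    act <- tf_activity_deviation(counts, list(M = sample(peaks, 20)),
                                 n_background = 50, seed = sample.int(1e6, 1))
    mean(act$z["M", ])
  })
  expect_lt(abs(mean(zs)), 0.5)
  expect_lt(sd(unlist(zs)), 2)
})
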