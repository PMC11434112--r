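mk_trn <- function(tf, target, sign = 1) {
  structure(list(edges = data.frame(tf_id = tf, target_id = target, weight = 1,
                                    sign = sign, r = sign * 0.5,
                                    footprint_supported = TRUE,
                                    stringsAsFactors = FALSE)), class = "trn")
}

test_that("a star hub is selected as a structure TF", {
  tfs <- paste0("tf", 1:11)
  trn <- mk_trn(rep("tf1", 10), paste0("tf", 2:11))
  # BH across 11 nodes needs min attainable q = 11/(n_perm+1) below alpha
  sel <- identify_structure_tfs(trn, tf_ids = tfs, n_perm = 999, seed = 5)
  expect_true("tf1" %in% sel)
  st <- attr(sel, "stats")
  expect_equal(st$p[st$tf_id == "tf1"], 1 / 1000, tolerance = 1e-12)
  # empty TF-TF subnetwork
  trn2 <- mk_trn("tf1", "geneX")
  expect_warning(sel2 <- identify_structure_tfs(trn2, tf_ids = tfs, n_perm = 99),
                 "empty")
  expect_length(sel2, 0)
})

test_that("structure-TF selection is calibrated on random TF-TF networks", {
  set.seed(43)
  fracs <- replicate(20, {
    tfs <- paste0("tf", 1:15)
    ne <- 30
    ed <- data.frame(tf = sample(tfs, ne, TRUE), tg = sample(tfs, ne, TRUE))
    ed <- ed[ed$tf != ed$tg, ]
    trn <- mk_trn(ed$tf, ed$tg)
    sel <- identify_structure_tfs(trn, tf_ids = tfs, n_perm = 199,
                                  seed = sample.int(1e6, 1))
    length(sel) / length(tfs)
  })
  expect_lte(mean(fracs), 0.10)
})

test_that("direct regulators require an edge into the storage sets", {
  trn <- mk_trn(c("tf1", "tf2", "tf3"), c("starchA", "other1", "sspB"))
  dr <- identify_direct_regulators(trn, "starchA", "sspB")
  expect_setequal(dr, c("tf1", "tf3"))
  sets <- core_tf_sets(structure_tfs = "tf9", direct_tfs = dr, known_tfs = "tf1")
  expect_setequal(sets$core, c("tf1", "tf3", "tf9"))
  expect_setequal(sets$novel, c("tf3", "tf9"))
})

test_that("regulator classes use strict over-the-median counts and sign modes", {
  starch <- paste0("st", 1:6); ssp <- paste0("sp", 1:6)
  tf <- c(rep("A", 4), rep("B", 2), rep("C", 3), rep("D", 1))
  tg <- c("st1", "st2", "st3", "sp1",          # A: 3 starch, 1 ssp
          "st1", "sp1",                        # B: 1 starch, 1 ssp
          "sp1", "sp2", "st1",                 # C: 1 starch, 2 ssp
          "st1")                               # D: 1 starch
  sg <- c(1, 1, 1, -1, 1, 1, -1, -1, -1, 1)
  rc <- classify_regulators(mk_trn(tf, tg, sg), starch, ssp)
  # medians over TFs with storage targets: starch counts (3,1,1,1) -> 1;
  # ssp counts (1,1,2,0) -> 1
  expect_equal(rc$class[rc$tf_id == "A"], "starch-enriched")
  expect_equal(rc$class[rc$tf_id == "B"], "neither")   # exactly at both medians
  expect_equal(rc$class[rc$tf_id == "C"], "SSP-enriched")
  expect_equal(rc$mode[rc$tf_id == "A"], "opposite")   # starch +1, ssp -1
  expect_equal(rc$mode[rc$tf_id == "B"], "positive")
  expect_equal(rc$mode[rc$tf_id == "C"], "negative")
  expect_equal(rc$mode[rc$tf_id == "D"], "positive")
})

test_that("regulator classification equals brute-force reclassification on random tables", {
  set.seed(47)
  starch <- paste0("st", 1:8); ssp <- paste0("sp", 1:8)
  for (i in 1:20) {
    ne <- 60
    ed <- data.frame(tf = sample(paste0("tf", 1:8), ne, TRUE),
                     tg = sample(c(starch, ssp, paste0("o", 1:8)), ne, TRUE))
    ed <- unique(ed)
    sg <- sample(c(-1, 0, 1), nrow(ed), TRUE)
    rc <- classify_regulators(mk_trn(ed$tf, ed$tg, sg), starch, ssp)
    n_st <- vapply(rc$tf_id, function(t) length(unique(ed$tg[ed$tf == t & ed$tg %in% starch])), 0L)
    n_sp <- vapply(rc$tf_id, function(t) length(unique(ed$tg[ed$tf == t & ed$tg %in% ssp])), 0L)
    has <- n_st + n_sp > 0
    ms <- median(n_st[has]); mp <- median(n_sp[has])
    for (j in seq_along(rc$tf_id)) {
      want <- if (!has[j]) "neither"
      else if (n_st[j] > ms && n_sp[j] > mp) "dual"
      else if (n_st[j] > ms) "starch-enriched"
      else if (n_sp[j] > mp) "SSP-enriched"
      else "neither"
      expect_equal(rc$class[j], want)
    }
  }
})

test_that("GWAS overlap uses a 3 Mb centered window on the gene interval", {
  genes <- data.frame(gene_id = c("near", "far"), chrom = "chr1A",
                      start = c(1.4e6, 1.6e6), end = c(1.4e6, 1.6e6) + 2000,
                      strand = "+", is_tf = TRUE, stringsAsFactors = FALSE)
  ann <- genome_annotation(genes, c(chr1A = 1e7))
  sig <- data.frame(chrom = "chr1A", pos = 0, trait_class = "GS",
                    stringsAsFactors = FALSE)
  ov <- gwas_overlap(ann, c("near", "far"), sig)
  expect_true(ov$gwas_hit[ov$tf_id == "near"])    # 1.4 Mb < 1.5 Mb half-window
  expect_false(ov$gwas_hit[ov$tf_id == "far"])    # 1.6 Mb away
  expect_equal(ov$gwas_classes[ov$tf_id == "near"], "GS")
  expect_warning(gwas_overlap(ann, "near", data.frame(chrom = "chrUn", pos = 1)),
                 "unknown chromosome")
})

test_that("GWAS flags equal brute-force distance computation on random placements", {
  set.seed(53)
  n <- 100
  genes <- data.frame(gene_id = sprintf("tf%03d", 1:n), chrom = "chr1A",
                      start = sample.int(5e7, n), strand = "+",
                      stringsAsFactors = FALSE)
  genes$end <- genes$start + 3000
  ann <- genome_annotation(genes, c(chr1A = 6e7))
  sig <- data.frame(chrom = "chr1A", pos = sample.int(5.5e7, 8))
  ov <- gwas_overlap(ann, genes$gene_id, sig, window_total = 3e6)
  for (i in seq_len(n)) {
    brute <- any(genes$start[i] < sig$pos + 1.5e6 & genes$end[i] > sig$pos - 1.5e6)
    expect_equal(ov$gwas_hit[i], brute)
  }
})

test_that("expression-phenotype groups flag planted trait correlations", {
  set.seed(59)
  n <- 100
  acc <- sprintf("a%03d", 1:n)
  ok <- 0L
  for (i in 1:30) {
    ex <- matrix(2^rnorm(2 * n, 5, 1), 2, n,
                 dimnames = list(c("tf1", "tf2"), acc))
    z <- as.numeric(scale(ex["tf1", ]))
    traits <- data.frame(gl = 0.9 * z + 0.1 * rnorm(n), row.names = acc)
    gr <- expression_phenotype_groups(list(DAP10 = ex), traits, c(gl = "GS"),
                                      c("tf1", "tf2"))
    if (identical(gr$tf1, "GS-DAP10")) ok <- ok + 1L
  }
  expect_gte(ok, 29L)
  # bookkeeping: significant for one class at one stage only
  ex <- matrix(2^rnorm(2 * n, 5, 1), 2, n, dimnames = list(c("tf1", "tf2"), acc))
  z <- as.numeric(scale(ex["tf1", ]))
  traits <- data.frame(gl = z, gq1 = rnorm(n), row.names = acc)
  flat <- ex; flat[] <- 1   # constant panel: zero variance, stage skipped
  gr <- expression_phenotype_groups(list(DAP10 = ex, DAP20 = flat),
                                    traits, c(gl = "GS", gq1 = "GQ"), "tf1")
  expect_equal(gr$tf1, "GS-DAP10")
})

test_that("high-confidence selection is the conjunction of all evidence", {
  groups <- list(tfA = c("GS-DAP10", "GQ-DAP20"), tfB = c("GS-DAP10", "GS-DAP20"),
                 tfC = c("GS-DAP10", "GQ-DAP10"), tfD = "GS-DAP10")
  gwas <- data.frame(tf_id = paste0("tf", LETTERS[1:4]),
                     gwas_hit = c(TRUE, TRUE, FALSE, TRUE))
  mut <- data.frame(tf_id = paste0("tf", LETTERS[1:4]),
                    status = c("altered", "no_line", "altered", "altered"))
  tri <- build_triage_table(paste0("tf", LETTERS[1:4]),
                            core = paste0("tf", LETTERS[1:4]),
                            novel = paste0("tf", LETTERS[1:3]),
                            gwas = gwas, groups = groups, mutant_flags = mut)
  expect_equal(select_high_confidence(tri), "tfA")
  # tfB fails on mutant (no_line), tfC on GWAS, tfD on group count and novelty
  expect_false(tri$high_confidence[tri$tf_id == "tfB"])
  # monotonicity: relaxing group_min never shrinks the set
  expect_true(all(select_high_confidence(tri, group_min = 2) %in%
                    select_high_confidence(tri, group_min = 1)))
})

test_that("variant filtering applies strict thresholds and is idempotent", {
  # 8 hand-enumerable variants x 10 accessions
  calls <- rbind(
    c(0, 0, 2, 2, 2, 2, 2, 2, 2, 2),    # MAF 0.2 -> keep
    c(0, 2, 2, 2, 2, 2, 2, 2, 2, 2),    # MAF 0.1 -> keep
    c(2, 2, 2, 2, 2, 2, 2, 2, 2, 2),    # MAF 0   -> drop
    c(0, 0, 0, 2, 2, 2, 2, 2, 2, NA),   # MAF 1/3, miss 0.1 -> keep
    c(NA, NA, NA, NA, NA, 0, 2, 2, 2, 2), # miss 0.5 -> drop (strict <)
    c(NA, NA, NA, NA, 0, 0, 2, 2, 2, 2),  # miss 0.4 -> keep
    c(1, 1, 1, 1, 1, 0, 0, 2, 2, 2),    # het 0.5 -> drop (strict <)
    c(1, 1, 1, 1, 0, 0, 0, 2, 2, 2))    # het 0.4, MAF 0.35 -> keep
  mode(calls) <- "integer"
  v <- data.frame(chrom = "c1", pos = seq_len(8) * 100, ref = "A", alt = "T",
                  stringsAsFactors = FALSE)
  colnames(calls) <- sprintf("a%02d", 1:10)
  gt <- genotype_table(v, calls)
  f1 <- filter_variants(gt)
  expect_equal(f1$variants$pos, c(1, 2, 4, 6, 8) * 100)
  # MAF exactly at the boundary is removed (strict >)
  calls_b <- matrix(rep(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1), 2), 2, 10, byrow = TRUE)
  mode(calls_b) <- "integer"
  colnames(calls_b) <- sprintf("a%02d", 1:10)
  gtb <- genotype_table(data.frame(chrom = "c1", pos = c(1, 2), ref = "A",
                                   alt = "T", stringsAsFactors = FALSE), calls_b)
  expect_equal(nrow(filter_variants(gtb)$variants), 0L)  # MAF = 0.05 exactly
  # idempotence
  f2 <- filter_variants(f1)
  expect_identical(f1$variants, f2$variants)
  expect_identical(f1$calls, f2$calls)
})

test_that("haplotype grouping orders by frequency and excludes incomplete accessions", {
  calls <- rbind(c(0, 0, 0, 2, 2, 2, 2, NA, 1, 2),
                 c(2, 2, 2, 0, 0, 0, 0, 0, 0, 0))
  mode(calls) <- "integer"
  colnames(calls) <- sprintf("a%02d", 1:10)
  v <- data.frame(chrom = "c1", pos = c(100, 200), ref = "A", alt = "T",
                  stringsAsFactors = FALSE)
  gt <- genotype_table(v, calls)
  hg <- assign_haplotypes(gt, list(chrom = "c1", start = 0, end = 1000))
  expect_equal(hg$n_haplotypes, 2L)
  expect_equal(hg$n_excluded, 2L)  # one missing, one heterozygous
  # (2,0) carried by a04-a07 and a10 (5 accessions) -> Hap1; (0,2) by a01-a03
  expect_equal(unname(hg$assignments[c("a04", "a10")]), c("Hap1", "Hap1"))
  expect_equal(sum(hg$assignments == "Hap1"), 5L)
  expect_equal(sum(hg$assignments == "Hap2"), 3L)
  # single haplotype when all tuples identical
  calls1 <- matrix(2L, 1, 10, dimnames = list(NULL, sprintf("a%02d", 1:10)))
  gt1 <- genotype_table(v[1, ], calls1)
  hg1 <- assign_haplotypes(gt1, list(chrom = "c1", start = 0, end = 1000))
  expect_equal(hg1$n_haplotypes, 1L)
  expect_length(hg1$assignments, 10L)
  expect_error(assign_haplotypes(gt, list(chrom = "c1", start = 5000, end = 6000)),
               "no variants")
})

test_that("haplotype grouping equals brute-force tuple hashing on random tables", {
  set.seed(61)
  for (i in 1:10) {
    nv <- sample(2:5, 1); na <- 30
    calls <- matrix(sample(c(0L, 2L), nv * na, TRUE, prob = c(0.5, 0.5)), nv, na)
    calls[sample(length(calls), 3)] <- NA
    colnames(calls) <- sprintf("a%03d", 1:na)
    v <- data.frame(chrom = "c1", pos = seq_len(nv) * 50, ref = "A", alt = "T",
                    stringsAsFactors = FALSE)
    hg <- assign_haplotypes(genotype_table(v, calls),
                            list(chrom = "c1", start = 0, end = 1e4))
    keep <- colnames(calls)[colSums(is.na(calls) | calls == 1) == 0]
    tup <- apply(calls[, keep, drop = FALSE], 2, paste, collapse = "/")
    expect_setequal(names(hg$assignments), keep)
    # same tuple <=> same label
    for (t in unique(tup)) {
      labs <- unique(hg$assignments[names(tup)[tup == t]])
      expect_length(labs, 1L)
    }
    # Hap1 is (one of) the most frequent tuple(s)
    expect_equal(sum(hg$assignments == "Hap1"), max(table(tup)))
  }
})

test_that("haplotype trait tests match the closed-form Welch statistic", {
  acc <- sprintf("a%02d", 1:12)
  hg <- structure(list(assignments = setNames(rep(c("Hap1", "Hap2"), each = 6), acc),
                       sites = "v1", n_haplotypes = 2L,
                       definitions = c(Hap1 = "0", Hap2 = "2"), n_excluded = 0L),
                  class = "haplotype_groups")
  trait <- setNames(c(5.1, 4.9, 5.3, 5.2, 4.8, 5.0, 6.4, 6.1, 6.6, 6.0, 6.3, 6.2), acc)
  res <- haplotype_trait_test(hg, trait)
  xa <- trait[1:6]; xb <- trait[7:12]
  tref <- (mean(xa) - mean(xb)) / sqrt(var(xa) / 6 + var(xb) / 6)
  expect_equal(res$t, tref, tolerance = 1e-12)
  expect_equal(res$delta_mean, mean(xa) - mean(xb), tolerance = 1e-15)
  expect_equal(res$p, t.test(xa, xb)$p.value, tolerance = 1e-15)
  # identical groups -> t = 0, p = 1
  t2 <- setNames(rep(c(1, 2, 3), 4), acc)
  res2 <- haplotype_trait_test(hg, t2)
  expect_equal(res2$t, 0)
  expect_equal(res2$p, 1)
  # power: well-separated groups essentially always significant
  set.seed(67)
  acc30 <- sprintf("b%03d", 1:60)
  hg30 <- structure(list(assignments = setNames(rep(c("Hap1", "Hap2"), each = 30), acc30),
                         sites = "v1", n_haplotypes = 2L,
                         definitions = c(Hap1 = "0", Hap2 = "2"), n_excluded = 0L),
                    class = "haplotype_groups")
  ps <- replicate(20, haplotype_trait_test(
    hg30, setNames(c(rnorm(30, 0), rnorm(30, 2)), acc30))$p)
  expect_true(all(ps < 1e-6))
})

test_that("haplotype frequencies per era sum to one and match hand tallies", {
  acc <- sprintf("a%02d", 1:20)
  hg <- structure(list(assignments = setNames(rep(c("Hap1", "Hap2"), c(7, 13)), acc),
                       sites = "v1", n_haplotypes = 2L,
                       definitions = c(Hap1 = "0", Hap2 = "2"), n_excluded = 0L),
                  class = "haplotype_groups")
  era <- setNames(rep(c("1949-1957", "1958-1977", "1978-1999"), c(10, 6, 4)), acc)
  fr <- haplotype_frequency_trend(hg, era)
  expect_equal(unname(rowSums(fr)), rep(1, 3), tolerance = 1e-12)
  expect_equal(fr["1949-1957", "Hap1"], 0.7)     # 7 of the first 10
  expect_equal(fr["1958-1977", "Hap1"], 0)
  expect_equal(fr["1978-1999", "Hap2"], 1)
  # single era, 3 of 10 Hap1
  hg2 <- hg
  hg2$assignments <- setNames(rep(c("Hap1", "Hap2"), c(3, 7)), acc[1:10])
  fr2 <- haplotype_frequency_trend(hg2, setNames(rep("modern", 10), acc[1:10]))
  expect_equal(fr2["modern", "Hap1"], 0.30)
})

test_that("SNP density in pACRs counts variants per merged kb", {
  ann <- toy_annotation(tss = 5000, strand = "+")
  pk <- interval_df("chr1A", c(3000, 3500), c(3600, 4000), c("p1", "p2"))
  pm <- assign_promoter_peaks(ann, pk)
  # merged pACR = [3000, 4000) = 1000 bp; variants at 3100 and 3900 inside
  v <- data.frame(chrom = "chr1A", pos = c(3100, 3900, 4500), ref = "A",
                  alt = "T", stringsAsFactors = FALSE)
  calls <- matrix(0L, 3, 4, dimnames = list(NULL, paste0("a", 1:4)))
  gt <- genotype_table(v, calls)
  d <- snp_density_in_peaks(gt, pk, pm)
  expect_equal(unname(d["g1"]), 2.0)
  # no variants in the region -> 0
  gt0 <- genotype_table(v[3, , drop = FALSE], calls[3, , drop = FALSE])
  expect_equal(unname(snp_density_in_peaks(gt0, pk, pm)["g1"]), 0)
})

test_that("SNP density equals brute-force point-in-interval counting", {
  set.seed(71)
  n <- 40
  genes <- data.frame(gene_id = sprintf("g%03d", 1:n), chrom = "chr1A",
                      start = seq(10000, by = 12000, length.out = n),
                      strand = sample(c("+", "-"), n, TRUE), stringsAsFactors = FALSE)
  genes$end <- genes$start + 2000
  ann <- genome_annotation(genes, c(chr1A = 1e6))
  ps <- genes$start - sample(500:2500, n, TRUE)
  pk <- interval_df("chr1A", ps, ps + sample(300:900, n, TRUE))
  pm <- assign_promoter_peaks(ann, pk)
  v <- data.frame(chrom = "chr1A", pos = sample.int(6e5, 200), ref = "A",
                  alt = "T", stringsAsFactors = FALSE)
  calls <- matrix(0L, 200, 3, dimnames = list(NULL, paste0("a", 1:3)))
  d <- snp_density_in_peaks(genotype_table(v, calls), pk, pm)
  for (g in names(d)) {
    pks <- pk[pk$name %in% pm[[g]], ]
    # peaks here are disjoint, so merged length = summed length
    len <- sum(pks$end - pks$start)
    cnt <- sum(vapply(v$pos, function(p) any(pks$start <= p & p < pks$end), TRUE))
    expect_equal(unname(d[g]), cnt / (len / 1000), tolerance = 1e-12)
  }
})
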