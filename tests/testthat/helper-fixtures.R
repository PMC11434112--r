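# Shared fixtures, computed once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_env, inherits = FALSE))
    assign(key, force(expr), .fixture_env)
  get(key, .fixture_env, inherits = FALSE)
}

# A compact synthetic study for module-level tests.
small_config <- function(seed = 11, ...) {
  args <- utils::modifyList(
    list(n_triads = 40, n_tfs = 8, targets_per_tf = 6, n_causal_tfs = 3,
         n_storage = 10, n_accessions = 60, seed = seed),
    list(...))
  do.call(sim_config, args)
}

small_study <- function() cached("small_study", simulate_study(small_config()))

small_weights <- function() cached("small_weights", {
  st <- small_study()
  genie3_importance(st$expr, st$truth$tf_ids, n_trees = 200, seed = 5)
})

small_hits <- function() cached("small_hits", {
  st <- small_study()
  pm <- assign_promoter_peaks(st$annotation, st$peaks)
  hits <- scan_promoter_peaks(st$genome, st$peaks, st$pwms, pm)
  mark_footprint_support(hits, st$footprints)
})

small_trn <- function() cached("small_trn", {
  st <- small_study()
  tfm <- map_tf_to_motif(explicit = st$truth$tf_motif)
  mt <- derive_motif_targets(small_hits(), require_footprint = TRUE)
  sig <- footprint_conditioned_significance(small_weights(), mt, tfm,
                                            expr = st$expr)
  assemble_trn(small_weights(), mt, tfm, st$expr, sig)
})

# Tiny hand-built annotation on one chromosome, for interval-level tests.
toy_annotation <- function(tss = 5000, strand = "+", size = 20000) {
  genes <- data.frame(gene_id = "g1", chrom = "chr1A",
                      start = if (strand == "+") tss else tss - 1999,
                      end = if (strand == "+") tss + 2000 else tss + 1,
                      strand = strand, stringsAsFactors = FALSE)
  genome_annotation(genes, c(chr1A = size))
}

interval_df <- function(chrom, start, end, name = sprintf("iv%03d", seq_along(start))) {
  data.frame(chrom = chrom, start = start, end = end, name = name,
             score = NA_real_, strand = ".", stringsAsFactors = FALSE)
}

random_pwm <- function(L = 8, motif_id = "M1") {
  m <- matrix(stats::runif(4 * L, 0, 20), 4, L)
  pwm(motif_id, "test", m)
}
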