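# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a root seed and a stream index; arithmetic in
# doubles (exact below 2^53), reduced to a valid 32-bit integer so nested
# derivations stay reproducible without overflow.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1103 + as.numeric(stream) * 12347) %% 2147483629)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Convert a 0-based half-open interval data.frame to GRanges (1-based closed).
as_granges0 <- function(df, seqlengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) ifelse(df$strand %in% c("+", "-"), df$strand, "*") else "*"
  )
  gr
}

# Pearson r with the standard closed form; NA if either series is constant.
pearson_r <- function(x, y) {
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) return(NA_real_)
  stats::cov(x, y) / (sx * sy)
}

zscale <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(NA_real_, length(x)))
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
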