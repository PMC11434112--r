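#' @import methods
NULL

# ---- GenomeAnnotation ------------------------------------------------------

#' Construct a genome annotation
#'
#' Container for gene models plus chromosome sizes. All coordinates are
#' 0-based half-open (BED convention); GFF3 input is converted at the
#' boundary. The TSS is derived from strand: `start` for "+" genes and
#' `end - 1` (the last covered base) for "-" genes.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` ("+"/"-"), and optionally `subgenome` ("A","B","D","unknown"),
#'   `triad_id` (NA for genes outside a triad) and `is_tf` (logical).
#' @param chrom_sizes named numeric vector of chromosome lengths in bp.
#' @return An object of class `genome_annotation`: a list with elements
#'   `genes` (the validated data.frame, with a `tss` column added) and
#'   `chrom_sizes`.
#' @export
genome_annotation <- function(genes, chrom_sizes) {
  stopifnot(is.data.frame(genes))
  req <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(req, names(genes))
  if (length(miss)) stopf("genes is missing columns: %s", paste(miss, collapse = ", "))
  if (!"subgenome" %in% names(genes)) genes$subgenome <- "unknown"
  if (!"triad_id" %in% names(genes)) genes$triad_id <- NA_character_
  if (!"is_tf" %in% names(genes)) genes$is_tf <- FALSE
  genes$start <- as.numeric(genes$start)
  genes$end <- as.numeric(genes$end)
  genes$is_tf <- as.logical(genes$is_tf)
  if (anyDuplicated(genes$gene_id))
    stopf("duplicate gene_id: %s", genes$gene_id[duplicated(genes$gene_id)][1])
  if (!all(genes$strand %in% c("+", "-")))
    stopf("every gene needs strand '+' or '-'")
  if (any(genes$start < 0) || any(genes$start >= genes$end))
    stopf("gene coordinates must satisfy 0 <= start < end")
  if (is.null(names(chrom_sizes)) || !all(genes$chrom %in% names(chrom_sizes)))
    stopf("chrom_sizes must name every chromosome used by genes")
  over <- genes$end > chrom_sizes[genes$chrom]
  if (any(over)) stopf("gene %s extends past its chromosome", genes$gene_id[which(over)[1]])
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  tri <- genes$triad_id[!is.na(genes$triad_id)]
  if (length(tri)) {
    bad <- names(which(table(tri) != 3))
    if (length(bad)) stopf("triad %s does not have exactly 3 members", bad[1])
  }
  structure(list(genes = genes, chrom_sizes = chrom_sizes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d genes (%d TFs, %d triads) on %d chromosomes\n",
              nrow(x$genes), sum(x$genes$is_tf),
              length(unique(stats::na.omit(x$genes$triad_id))),
              length(x$chrom_sizes)))
  invisible(x)
}

#' Read gene models from GFF3
#'
#' Parses `gene` features from a GFF3 file into a [genome_annotation()].
#' GFF3 1-based closed coordinates are converted to the package-internal
#' 0-based half-open convention. Chromosome sizes are taken from
#' `##sequence-region` pragmas when present, otherwise from the maximum gene
#' end per chromosome. Optional attributes `subgenome`, `triad_id` and
#' `is_tf` are carried through.
#'
#' @param path GFF3 file.
#' @return A `genome_annotation`.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9))
    stopf("malformed GFF3 line %d: expected 9 tab-separated fields, got %d",
          body[which(nf != 9)[1]], nf[which(nf != 9)[1]])
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stopf("GFF3 parse error in %s: %s", path, conditionMessage(e)))
  gr <- gr[gr$type == "gene"]
  if (!length(gr)) stopf("no gene features in %s", path)
  st <- as.character(BiocGenerics::strand(gr))
  if (any(!st %in% c("+", "-")))
    stopf("gene without strand: %s", gr$ID[which(!st %in% c("+", "-"))[1]])
  if (anyDuplicated(gr$ID)) stopf("duplicate gene_id: %s", gr$ID[duplicated(gr$ID)][1])
  mc <- S4Vectors::mcols(gr)
  genes <- data.frame(
    gene_id = as.character(gr$ID),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1,
    end = as.numeric(BiocGenerics::end(gr)),
    strand = st,
    subgenome = if ("subgenome" %in% names(mc)) as.character(mc$subgenome) else "unknown",
    triad_id = if ("triad_id" %in% names(mc)) as.character(mc$triad_id) else NA_character_,
    is_tf = if ("is_tf" %in% names(mc)) as.logical(as.integer(mc$is_tf)) else FALSE,
    stringsAsFactors = FALSE
  )
  genes$subgenome[is.na(genes$subgenome)] <- "unknown"
  genes$is_tf[is.na(genes$is_tf)] <- FALSE
  # chromosome sizes from ##sequence-region pragmas where available
  prag <- grep("^##sequence-region", lines, value = TRUE)
  sizes <- NULL
  if (length(prag)) {
    f <- strsplit(trimws(prag), "\\s+")
    sizes <- stats::setNames(vapply(f, function(x) as.numeric(x[4]), 0),
                             vapply(f, function(x) x[2], ""))
  }
  need <- unique(genes$chrom)
  if (is.null(sizes) || !all(need %in% names(sizes))) {
    mx <- tapply(genes$end, genes$chrom, max)
    add <- stats::setNames(as.numeric(mx), names(mx))
    sizes <- c(sizes, add[setdiff(names(add), names(sizes))])
  }
  genome_annotation(genes, sizes[need])
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gene_models()]; emits one `gene` feature per row with
#' `subgenome`, `triad_id` and `is_tf` attributes and `##sequence-region`
#' pragmas for the chromosome sizes.
#'
#' @param annotation a `genome_annotation`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(annotation, path) {
  g <- annotation$genes
  attrs <- sprintf("ID=%s;subgenome=%s;is_tf=%d%s",
                   g$gene_id, g$subgenome, as.integer(g$is_tf),
                   ifelse(is.na(g$triad_id), "", paste0(";triad_id=", g$triad_id)))
  rows <- sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\t%s",
                  g$chrom, "grainTRN", as.integer(g$start) + 1L, as.integer(g$end),
                  g$strand, attrs)
  header <- c("##gff-version 3",
              sprintf("##sequence-region %s 1 %d",
                      names(annotation$chrom_sizes),
                      as.integer(annotation$chrom_sizes)))
  writeLines(c(header, rows), path)
  invisible(path)
}

# ---- BED -------------------------------------------------------------------

#' Read a BED3/BED6 file
#'
#' Returns intervals in BED's native 0-based half-open convention as a
#' data.frame with columns `chrom`, `start`, `end`, `name`, `score`,
#' `strand`. Missing optional columns are filled with ".", `NA` and ".".
#'
#' @param path BED file.
#' @return data.frame of intervals.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), score = numeric(), strand = character(),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  f <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(f)
  if (any(n < 3)) stopf("BED line %d has fewer than 3 columns", which(n < 3)[1])
  get <- function(i, default) vapply(f, function(x) if (length(x) >= i) x[i] else default, "")
  start <- suppressWarnings(as.numeric(get(2, NA)))
  end <- suppressWarnings(as.numeric(get(3, NA)))
  bad <- is.na(start) | is.na(end) | start != floor(start) | end != floor(end)
  if (any(bad)) stopf("BED line %d: non-integer coordinates", which(bad)[1])
  if (any(start >= end)) stopf("BED line %d: start >= end", which(start >= end)[1])
  score <- suppressWarnings(as.numeric(get(5, NA_character_)))
  strand <- get(6, ".")
  strand[!strand %in% c("+", "-", ".")] <- "."
  data.frame(chrom = get(1, "."), start = start, end = end,
             name = get(4, "."), score = score, strand = strand,
             stringsAsFactors = FALSE)
}

#' Write intervals to BED
#'
#' @param intervals data.frame as returned by [read_bed()] (extra columns are
#'   ignored; missing `name`/`score`/`strand` are written as ".").
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  x <- intervals
  name <- if ("name" %in% names(x)) x$name else rep(".", nrow(x))
  score <- if ("score" %in% names(x)) ifelse(is.na(x$score), ".", format(x$score, trim = TRUE, scientific = FALSE)) else rep(".", nrow(x))
  strand <- if ("strand" %in% names(x)) x$strand else rep(".", nrow(x))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s", x$chrom, as.integer(x$start),
                     as.integer(x$end), name, score, strand), path)
  invisible(path)
}

# ---- JASPAR PWM ------------------------------------------------------------

#' Construct a position weight matrix
#'
#' @param motif_id motif identifier (e.g. "MA0001.1").
#' @param tf_family TF family / motif name.
#' @param counts 4 x L non-negative matrix, rows A, C, G, T.
#' @param pseudocount pseudocount added to every cell before per-column
#'   normalization to probabilities.
#' @return Object of class `pwm` with elements `motif_id`, `tf_family`,
#'   `counts`, `matrix` (probabilities, columns sum to 1) and `pseudocount`.
#' @export
pwm <- function(motif_id, tf_family, counts, pseudocount = 1e-3) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stopf("PWM %s: counts must have 4 rows (A,C,G,T)", motif_id)
  if (ncol(counts) < 1) stopf("PWM %s: length must be >= 1", motif_id)
  if (any(counts < 0)) stopf("PWM %s: negative counts", motif_id)
  rownames(counts) <- c("A", "C", "G", "T")
  prob <- sweep(counts + pseudocount, 2, colSums(counts) + 4 * pseudocount, "/")
  if (any(abs(colSums(prob) - 1) > 1e-9)) stopf("PWM %s: column normalization failed", motif_id)
  structure(list(motif_id = motif_id, tf_family = tf_family, counts = counts,
                 matrix = prob, pseudocount = pseudocount), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s (%s), length %d\n", x$motif_id, x$tf_family, ncol(x$matrix)))
  invisible(x)
}

#' Consensus sequence of a PWM
#' @param x a `pwm`.
#' @return Character string of per-column most probable bases.
#' @export
pwm_consensus <- function(x) {
  paste(rownames(x$matrix)[apply(x$matrix, 2, which.max)], collapse = "")
}

#' Read JASPAR text-format PWMs
#'
#' Parses the JASPAR 2016 flat text format: blocks of `>motif_id name`
#' followed by four bracketed count rows (A, C, G, T). Counts are converted
#' to probabilities per column after adding `pseudocount` to every cell.
#'
#' @param path JASPAR text file.
#' @param pseudocount per-cell pseudocount (default 1e-3).
#' @return Named list of `pwm` objects, in file order.
#' @export
read_jaspar_pwm <- function(path, pseudocount = 1e-3) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- which(startsWith(lines, ">"))
  if (!length(hdr)) stopf("no motif blocks in %s", path)
  out <- list()
  for (h in hdr) {
    tok <- strsplit(sub("^>", "", lines[h]), "\\s+")[[1]]
    id <- tok[1]; fam <- if (length(tok) > 1) tok[2] else tok[1]
    if (h + 4 > length(lines)) stopf("truncated motif block for %s", id)
    rows <- lapply(lines[(h + 1):(h + 4)], function(l) {
      l <- gsub("^[ACGT]\\s*\\[|\\]\\s*$", "", trimws(l))
      v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
      if (anyNA(v)) stopf("unparseable count row in motif %s", id)
      v
    })
    if (length(unique(lengths(rows))) != 1)
      stopf("motif %s: count rows of unequal length", id)
    m <- do.call(rbind, rows)
    out[[id]] <- pwm(id, fam, m, pseudocount = pseudocount)
  }
  out
}

#' Write PWMs in JASPAR text format
#' @param pwms list of `pwm` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_jaspar_pwm <- function(pwms, path) {
  fmt_row <- function(b, v) sprintf("%s  [ %s ]", b, paste(format(v, trim = TRUE, scientific = FALSE), collapse = " "))
  blocks <- unlist(lapply(pwms, function(p) {
    c(sprintf(">%s %s", p$motif_id, p$tf_family),
      vapply(c("A", "C", "G", "T"), function(b) fmt_row(b, p$counts[b, ]), ""))
  }))
  writeLines(blocks, path)
  invisible(path)
}

# ---- Expression matrices ---------------------------------------------------

#' Read a genes x samples expression matrix from TSV
#'
#' First column holds gene identifiers, header row holds sample identifiers.
#'
#' @param path TSV file.
#' @param unit one of "TPM", "CPM", "count", or "signal" (unconstrained).
#' @return Numeric matrix with gene rownames, sample colnames and a `unit`
#'   attribute.
#' @export
read_matrix_tsv <- function(path, unit = c("TPM", "CPM", "count", "signal")) {
  unit <- match.arg(unit)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, fill = FALSE,
                          colClasses = c("character"), quote = "")
  if (anyDuplicated(df[[1]])) stopf("duplicated gene id: %s", df[[1]][duplicated(df[[1]])][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  if (anyNA(m)) stopf("missing or non-numeric cells in %s", path)
  if (unit %in% c("TPM", "CPM", "count") && any(m < 0))
    stopf("negative values are not valid %s", unit)
  rownames(m) <- df[[1]]
  attr(m, "unit") <- unit
  m
}

#' Write an expression matrix to TSV
#' @param m numeric matrix with row and column names.
#' @param path output file.
#' @param id_col header for the gene-id column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- VCF -------------------------------------------------------------------

#' Construct a genotype table
#'
#' @param variants data.frame with columns `chrom`, `pos` (0-based), `ref`,
#'   `alt` and optionally `id`.
#' @param calls variants x accessions integer matrix of alt-allele dosages
#'   (0/1/2, NA = missing).
#' @return Object of class `genotype_table`.
#' @export
genotype_table <- function(variants, calls) {
  stopifnot(is.data.frame(variants), is.matrix(calls),
            nrow(variants) == nrow(calls))
  if (!"id" %in% names(variants))
    variants$id <- sprintf("var%04d", seq_len(nrow(variants)))
  ok <- calls %in% c(0L, 1L, 2L) | is.na(calls)
  if (!all(ok)) stopf("genotype calls must be 0/1/2 or NA")
  structure(list(variants = variants, calls = calls), class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d biallelic variants x %d accessions\n",
              nrow(x$variants), ncol(x$calls)))
  invisible(x)
}

#' Read a minimal VCF into a genotype table
#'
#' Consumes CHROM/POS/REF/ALT and the GT field of a VCF v4.x file. Genotypes
#' are coded as alt-allele dosage: 0/0 -> 0, 0/1 or 1/0 -> 1, 1/1 -> 2,
#' ./. -> NA (phased separators accepted). Multi-allelic records are skipped
#' with a warning; POS is converted to the internal 0-based convention.
#'
#' @param path VCF file.
#' @return A `genotype_table`.
#' @export
read_vcf_lite <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stopf("VCF parse error in %s: %s", path, conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) warnf("skipping %d multi-allelic record(s)", sum(multi))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix), dimnames = list(NULL, names(gt)))
  gt <- gsub("|", "/", gt, fixed = TRUE)
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dose[gt %in% "0/0"] <- 0L
  dose[gt %in% c("0/1", "1/0")] <- 1L
  dose[gt %in% "1/1"] <- 2L
  keep <- !multi
  variants <- data.frame(chrom = fix[keep, "CHROM"],
                         pos = as.numeric(fix[keep, "POS"]) - 1,
                         ref = fix[keep, "REF"], alt = fix[keep, "ALT"],
                         id = fix[keep, "ID"], stringsAsFactors = FALSE)
  na_id <- is.na(variants$id)
  variants$id[na_id] <- sprintf("var%04d", which(na_id))
  genotype_table(variants, dose[keep, , drop = FALSE])
}

#' Write a genotype table as a minimal VCF
#' @param gt a `genotype_table`.
#' @param path output file.
#' @param accessions optional accession names (defaults to calls colnames).
#' @return `path`, invisibly.
#' @export
write_vcf_lite <- function(gt, path, accessions = colnames(gt$calls)) {
  if (is.null(accessions)) accessions <- sprintf("acc%03d", seq_len(ncol(gt$calls)))
  gmap <- c("0" = "0/0", "1" = "0/1", "2" = "1/1")
  gtxt <- matrix(gmap[as.character(gt$calls)], nrow = nrow(gt$calls))
  gtxt[is.na(gtxt)] <- "./."
  rows <- vapply(seq_len(nrow(gt$calls)), function(i) {
    paste(c(gt$variants$chrom[i], as.integer(gt$variants$pos[i]) + 1L,
            gt$variants$id[i], gt$variants$ref[i], gt$variants$alt[i],
            ".", "PASS", ".", "GT", gtxt[i, ]), collapse = "\t")
  }, "")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", accessions), collapse = "\t"),
               rows), path)
  invisible(path)
}

# ---- FASTA -----------------------------------------------------------------

#' Read genome sequence from FASTA
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write genome sequence to FASTA
#' @param genome a `DNAStringSet` or named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}
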