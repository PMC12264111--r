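#' @importFrom stats median optimize p.adjust pnorm rnbinom rnorm runif
#'   setNames var dhyper lm anova as.dist cutree pchisq qnorm rbinom
#' @importFrom utils read.delim write.table combn head tail
NULL

STRANDS <- c("+", "-", "*")

#' Construct a genomic interval table
#'
#' Intervals use 0-based half-open coordinates throughout the package
#' (the BED convention). `strand` is `"+"`, `"-"` or `"*"` (unstranded).
#'
#' @param chrom chromosome labels
#' @param start 0-based inclusive start (bp)
#' @param end 0-based exclusive end (bp)
#' @param name interval identifiers
#' @param strand strand, one of `"+"`, `"-"`, `"*"`
#' @param score numeric score column (BED column 5)
#' @return a `data.frame` with columns chrom, start, end, name, score, strand
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL, strand = "*",
                              score = 0L) {
  n <- length(chrom)
  if (is.null(name)) name <- sprintf("iv%d", seq_len(n))
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   name = as.character(name), score = score,
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "name", "strand") %in% names(df)))
  if (any(df$start < 0)) stop("interval start must be >= 0")
  bad <- which(df$end <= df$start)
  if (length(bad))
    stop("interval end must exceed start (record ", bad[1], ")")
  if (!all(df$strand %in% STRANDS))
    stop("strand must be one of +, -, *")
  invisible(df)
}

#' Read genomic intervals from a BED6 or TEV-TSV file
#'
#' `BED6` is tab-separated chrom/start/end/name/score/strand with no header.
#' `TEV-TSV` is BED6 plus a header line and extra columns
#' (`raw_annotation`, `present_in`); extra columns are preserved.
#'
#' @param path file path
#' @param format `"BED6"` or `"TEV-TSV"`
#' @return interval `data.frame`; extra columns kept for TEV-TSV
#' @export
read_intervals <- function(path, format = c("BED6", "TEV-TSV")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "BED6") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 6))
      stop("malformed BED6 line ", which(nf < 6)[1], " in ", path)
    df <- data.frame(
      chrom = vapply(parts, `[`, "", 1L),
      start = suppressWarnings(as.integer(vapply(parts, `[`, "", 2L))),
      end = suppressWarnings(as.integer(vapply(parts, `[`, "", 3L))),
      name = vapply(parts, `[`, "", 4L),
      score = suppressWarnings(as.numeric(vapply(parts, `[`, "", 5L))),
      strand = vapply(parts, `[`, "", 6L),
      stringsAsFactors = FALSE)
    if (anyNA(df$start) || anyNA(df$end))
      stop("malformed coordinate on line ",
           which(is.na(df$start) | is.na(df$end))[1], " in ", path)
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "name", "score", "strand")
    if (!all(need %in% names(df)))
      stop("TEV-TSV must carry columns ", paste(need, collapse = ", "))
  }
  bad <- which(df$end <= df$start)
  if (length(bad)) stop("end <= start on line ", bad[1], " in ", path)
  validate_intervals(df)
  df
}

#' Write genomic intervals
#'
#' @param df interval table as from [read_intervals()]
#' @param path output path
#' @param format `"BED6"` (first six columns, no header) or `"TEV-TSV"`
#'   (all columns, with header)
#' @export
write_intervals <- function(df, path, format = c("BED6", "TEV-TSV")) {
  format <- match.arg(format)
  validate_intervals(df)
  if (format == "BED6") {
    out <- df[, c("chrom", "start", "end", "name", "score", "strand")]
    write.table(out, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand)
}

#' Read small RNA reads from a FASTQ file (Phred+33)
#'
#' @param path FASTQ path (uncompressed or gzip)
#' @return `data.frame` with columns read_id, sequence, and a list column
#'   `qualities` of integer Phred scores
#' @export
read_fastq <- function(path) {
  sr <- Biostrings::readQualityScaledDNAStringSet(path)
  qual <- as(Biostrings::quality(sr), "IntegerList")
  data.frame(read_id = names(sr),
             sequence = as.character(sr),
             qualities = I(as.list(qual)),
             stringsAsFactors = FALSE)
}

#' Filter small RNA reads on length and base quality
#'
#' Retains reads of length `min_len`..`max_len` whose fraction of bases with
#' Phred quality at least `min_q` is at least `min_frac`. Input order is
#' preserved and the filter is idempotent.
#'
#' @param reads `data.frame` with `sequence` and list column `qualities`
#'   (integer Phred scores per base), as from [read_fastq()]
#' @param min_len,max_len retained read length bounds (nt)
#' @param min_q per-base quality threshold
#' @param min_frac minimum fraction of bases at or above `min_q`
#' @return the retained subset of `reads`
#' @export
filter_reads <- function(reads, min_len = 19L, max_len = 36L,
                         min_q = 30L, min_frac = 0.9) {
  if (nrow(reads) == 0) return(reads)
  len <- nchar(reads$sequence)
  ql <- reads$qualities
  stopifnot(all(lengths(ql) == len))
  if (any(unlist(ql, use.names = FALSE) < 0))
    stop("quality scores must be non-negative")
  frac <- vapply(ql, function(q) mean(q >= min_q), numeric(1))
  keep <- len >= min_len & len <= max_len & frac >= min_frac
  reads[keep, , drop = FALSE]
}

#' Read / write the alignment table dialect
#'
#' Tab-separated with header: read_id, sample_id, chrom, start, end, strand,
#' n_hits. Coordinates are 0-based half-open; `n_hits` is the number of
#' genomic loci the read maps to (1 = uniquely mapping).
#'
#' @param path file path
#' @return alignment `data.frame`
#' @export
read_alignments <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("read_id", "sample_id", "chrom", "start", "end", "strand",
            "n_hits")
  if (!all(need %in% names(df)))
    stop("alignment table must carry columns ", paste(need, collapse = ", "))
  if (any(df$n_hits < 1)) stop("n_hits must be >= 1")
  if (any(df$end <= df$start)) stop("alignment end must exceed start")
  df
}

#' @rdname read_alignments
#' @param aln alignment `data.frame`
#' @export
write_alignments <- function(aln, path) {
  write.table(aln, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a cluster-by-sample count matrix
#'
#' TSV with cluster ids in the first column and one column per sample.
#'
#' @param path file path
#' @return integer matrix, rows = clusters, columns = samples
#' @export
read_count_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  validate_count_matrix(m)
  m
}

validate_count_matrix <- function(m) {
  if (any(m < 0)) stop("counts must be non-negative")
  if (anyDuplicated(rownames(m))) stop("cluster ids not unique")
  if (anyDuplicated(colnames(m))) stop("sample ids not unique")
  invisible(m)
}

#' @rdname read_count_matrix
#' @param m count matrix
#' @export
write_count_matrix <- function(m, path) {
  df <- data.frame(cluster_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' TSV with header; required columns sample_id, strain, tissue, batch;
#' optional individual_id linking samples to a pedigree.
#'
#' @param path file path
#' @return `data.frame`
#' @export
read_sample_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "strain", "tissue", "batch")
  if (!all(need %in% names(df)))
    stop("sample table must carry columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("sample_id not unique")
  df
}

#' Count reads over clusters
#'
#' A read contributes one count to a (cluster, sample) cell iff its overlap
#' with the cluster is at least `min_overlap` bp; counting is
#' strand-agnostic. With `unique_only` only uniquely-mapping reads
#' (`n_hits == 1`) are counted. With `exclude_repeats` given, reads
#' overlapping any repeat interval (by >= 1 bp) are discarded first. A read
#' overlapping several clusters at or above `min_overlap` contributes to
#' each of them.
#'
#' @param alignments alignment `data.frame` (see [read_alignments()])
#' @param clusters interval `data.frame`; names must be unique
#' @param min_overlap minimum read/cluster overlap in bp
#' @param unique_only count only reads with `n_hits == 1`
#' @param exclude_repeats optional interval `data.frame` of repeats
#' @param sample_ids optional character vector fixing the column order
#'   (samples without alignments get zero columns)
#' @return integer count matrix, clusters x samples
#' @export
count_reads_in_clusters <- function(alignments, clusters, min_overlap = 18L,
                                    unique_only = TRUE,
                                    exclude_repeats = NULL,
                                    sample_ids = NULL) {
  if (anyDuplicated(clusters$name)) stop("cluster ids not unique")
  aln <- alignments
  if (unique_only) aln <- aln[aln$n_hits == 1L, , drop = FALSE]
  if (is.null(sample_ids)) sample_ids <- sort(unique(alignments$sample_id))
  m <- matrix(0L, nrow = nrow(clusters), ncol = length(sample_ids),
              dimnames = list(clusters$name, sample_ids))
  if (nrow(aln) == 0) return(m)
  agr <- GenomicRanges::GRanges(aln$chrom,
                                IRanges::IRanges(aln$start + 1L, aln$end))
  if (!is.null(exclude_repeats) && nrow(exclude_repeats) > 0) {
    rgr <- intervals_to_granges(exclude_repeats)
    GenomicRanges::strand(rgr) <- "*"
    hits <- GenomicRanges::countOverlaps(agr, rgr, ignore.strand = TRUE)
    keep <- hits == 0L
    aln <- aln[keep, , drop = FALSE]
    agr <- agr[keep]
    if (nrow(aln) == 0) return(m)
  }
  cgr <- intervals_to_granges(clusters)
  GenomicRanges::strand(cgr) <- "*"
  ov <- GenomicRanges::findOverlaps(agr, cgr, minoverlap = min_overlap,
                                    ignore.strand = TRUE)
  if (length(ov) == 0) return(m)
  tab <- table(factor(clusters$name[S4Vectors::subjectHits(ov)],
                      levels = clusters$name),
               factor(aln$sample_id[S4Vectors::queryHits(ov)],
                      levels = sample_ids))
  m[] <- as.integer(tab)
  m
}

#' All interval pairs within a maximum gap
#'
#' Returns every (a, b) index pair whose edge-to-edge gap is at most
#' `max_gap` bp; overlapping pairs have gap 0 and a positive overlap length.
#' Strand is ignored.
#'
#' @param a,b interval `data.frame`s
#' @param max_gap maximum separation (bp); 0 reports overlaps only
#' @return `data.frame` with columns a_idx, b_idx, overlap, gap
#' @export
interval_overlap <- function(a, b, max_gap = 0L) {
  empty <- data.frame(a_idx = integer(), b_idx = integer(),
                      overlap = integer(), gap = integer())
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  agr <- intervals_to_granges(a); GenomicRanges::strand(agr) <- "*"
  bgr <- intervals_to_granges(b); GenomicRanges::strand(bgr) <- "*"
  # maxgap in findOverlaps counts the bp strictly between the intervals
  ov <- GenomicRanges::findOverlaps(agr, bgr, maxgap = max_gap,
                                    ignore.strand = TRUE)
  if (length(ov) == 0) return(empty)
  i <- S4Vectors::queryHits(ov); j <- S4Vectors::subjectHits(ov)
  inter_start <- pmax(a$start[i], b$start[j])
  inter_end <- pmin(a$end[i], b$end[j])
  overlap <- pmax(0L, inter_end - inter_start)
  gap <- pmax(0L, inter_start - inter_end)
  gap[a$chrom[i] != b$chrom[j]] <- NA_integer_
  keep <- !is.na(gap) & gap <= max_gap
  data.frame(a_idx = i[keep], b_idx = j[keep],
             overlap = overlap[keep], gap = gap[keep])
}
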