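# Cross-strain harmonization: block-map coordinate conversion, same-strand
# union merging of per-strain cluster sets, and the ordered filter cascade
# (repeat overlap, bi-over-mono, low count).

#' Read a strain coordinate map
#'
#' Chain-like TSV with header columns source_chrom, source_start,
#' source_end, target_chrom, target_start (and optionally strain). Blocks
#' must be non-overlapping in source coordinates; target block length
#' equals source block length by construction.
#'
#' @param path file path
#' @return `data.frame` of alignment blocks
#' @export
read_strain_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("source_chrom", "source_start", "source_end", "target_chrom",
            "target_start")
  if (!all(need %in% names(df)))
    stop("strain map must carry columns ", paste(need, collapse = ", "))
  validate_strain_map(df)
  df
}

validate_strain_map <- function(map) {
  if (any(map$source_end <= map$source_start))
    stop("map block with source_end <= source_start")
  for (blocks in split(map, map$source_chrom)) {
    o <- order(blocks$source_start)
    if (any(blocks$source_start[o][-1] <
            blocks$source_end[o][-nrow(blocks)]))
      stop("map blocks overlap in source coordinates on ",
           blocks$source_chrom[1])
  }
  invisible(map)
}

#' Convert intervals through a strain coordinate map
#'
#' An interval fully contained in a single alignment block is shifted by
#' that block's offset (length-preserving). Intervals on chromosomes absent
#' from the map are dropped with reason `no_alignment`; intervals spanning
#' block boundaries, extending into unaligned gaps, or falling entirely in
#' a gap of an aligned chromosome are dropped with reason `not_one_to_one`
#' — mirroring the exclusion of clusters that do not convert one-to-one
#' between strain assemblies.
#'
#' @param intervals interval `data.frame`
#' @param map strain map as from [read_strain_map()]
#' @return list with `converted` (shifted intervals) and `dropped`
#'   (original intervals plus a `reason` column)
#' @export
convert_intervals <- function(intervals, map) {
  validate_strain_map(map)
  n <- nrow(intervals)
  reason <- rep(NA_character_, n)
  conv <- intervals
  for (i in seq_len(n)) {
    blocks <- map[map$source_chrom == intervals$chrom[i], , drop = FALSE]
    if (nrow(blocks) == 0) { reason[i] <- "no_alignment"; next }
    hit <- blocks$source_start < intervals$end[i] &
      blocks$source_end > intervals$start[i]
    nb <- sum(hit)
    if (nb == 0 || nb > 1) { reason[i] <- "not_one_to_one"; next }
    b <- blocks[hit, ]
    if (intervals$start[i] < b$source_start ||
        intervals$end[i] > b$source_end) {
      reason[i] <- "not_one_to_one"; next
    }
    off <- b$target_start - b$source_start
    conv$chrom[i] <- b$target_chrom
    conv$start[i] <- intervals$start[i] + off
    conv$end[i] <- intervals$end[i] + off
  }
  keep <- is.na(reason)
  dropped <- intervals[!keep, , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- reason[!keep]
  else dropped$reason <- character(0)
  list(converted = conv[keep, , drop = FALSE], dropped = dropped)
}

#' Merge per-strain cluster sets by same-strand union
#'
#' Clusters from all strains (in common coordinates) are merged by taking
#' the union of overlapping intervals, only merging clusters of the same
#' strand class: `+`, `-`, and `*` (bi-directional) are three separate
#' classes, so a plus cluster overlapping a minus or bi-directional one is
#' never merged with it. Merging is transitive (connected components of the
#' overlap graph within a class). Provenance records the contributing
#' (strain, sample, cluster) rows per merged cluster.
#'
#' @param cluster_lists named list (by strain) of cluster `data.frame`s;
#'   each needs chrom, start, end, name, strand and optionally sample_id
#' @return object of class `merged_cluster_set`: list with `clusters`,
#'   `provenance` and an empty `filter_log`
#' @export
merge_same_strand_union <- function(cluster_lists) {
  all_cl <- do.call(rbind, lapply(names(cluster_lists), function(s) {
    df <- cluster_lists[[s]]
    if (nrow(df) == 0) return(NULL)
    data.frame(chrom = df$chrom, start = df$start, end = df$end,
               strand = df$strand, strain = s,
               sample_id = if (!is.null(df$sample_id)) df$sample_id else s,
               source_name = df$name, stringsAsFactors = FALSE)
  }))
  merged <- NULL
  prov <- NULL
  if (!is.null(all_cl) && nrow(all_cl)) {
    for (cls in unique(all_cl$strand)) {
      sub <- all_cl[all_cl$strand == cls, , drop = FALSE]
      gr <- GenomicRanges::GRanges(sub$chrom,
                                   IRanges::IRanges(sub$start + 1L, sub$end))
      # min.gapwidth = 0: merge truly overlapping intervals only, not
      # half-open abutting ones
      red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
      ov <- GenomicRanges::findOverlaps(gr, red)
      comp <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
      mdf <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(red)),
        start = GenomicRanges::start(red) - 1L,
        end = GenomicRanges::end(red),
        name = NA_character_, score = 0, strand = cls,
        stringsAsFactors = FALSE)
      pid <- paste(cls, comp, sep = "_")
      mdf$merge_key <- paste(cls, seq_len(nrow(mdf)), sep = "_")
      pdf <- data.frame(merge_key = pid, strain = sub$strain,
                        sample_id = sub$sample_id,
                        source_name = sub$source_name,
                        stringsAsFactors = FALSE)
      merged <- rbind(merged, mdf)
      prov <- rbind(prov, pdf)
    }
  }
  if (is.null(merged))
    merged <- data.frame(chrom = character(), start = integer(),
                         end = integer(), name = character(),
                         score = numeric(), strand = character(),
                         merge_key = character())
  o <- order(merged$chrom, merged$start)
  merged <- merged[o, , drop = FALSE]
  merged$name <- sprintf("merged%d", seq_len(nrow(merged)))
  if (!is.null(prov)) {
    prov$cluster_id <- merged$name[match(prov$merge_key, merged$merge_key)]
    prov$merge_key <- NULL
  } else {
    prov <- data.frame(strain = character(), sample_id = character(),
                       source_name = character(), cluster_id = character())
  }
  merged$merge_key <- NULL
  rownames(merged) <- NULL
  structure(list(clusters = merged, provenance = prov,
                 filter_log = data.frame(name = character(),
                                         reason = character(),
                                         stringsAsFactors = FALSE)),
            class = "merged_cluster_set")
}

#' @export
print.merged_cluster_set <- function(x, ...) {
  cat("merged_cluster_set:", nrow(x$clusters), "clusters,",
      nrow(x$filter_log), "filtered\n")
  invisible(x)
}

#' Apply the cluster filter cascade to a merged set
#'
#' Removes, in this fixed order:
#' 1. `repeat_overlap`: clusters whose overlap with the bp-union of repeat
#'    and polymorphic-TE intervals exceeds `repeat_frac` of their length
#'    (strictly more than; exactly `repeat_frac` is retained);
#' 2. `bi_over_mono`: bi-directional clusters (strand `*`) overlapping any
#'    surviving mono-directional cluster, to avoid double counting;
#' 3. `low_count`: clusters whose count is below `min_count` in every
#'    sample (i.e. no single sample reaches `min_count`).
#'
#' @param merged a `merged_cluster_set`
#' @param repeats repeat interval `data.frame` (RepeatMasker-style)
#' @param tevs polymorphic TE interval `data.frame` (may be `NULL`)
#' @param counts count matrix covering all merged clusters (rows by
#'   cluster name); required unless `min_count = 0`
#' @param repeat_frac fraction of cluster length above which the repeat
#'   filter removes the cluster
#' @param min_count minimum per-sample count to survive the count filter
#' @return the filtered `merged_cluster_set`; removals appended to
#'   `filter_log`
#' @export
apply_cluster_filters <- function(merged, repeats = NULL, tevs = NULL,
                                  counts = NULL, repeat_frac = 0.80,
                                  min_count = 10L) {
  stopifnot(inherits(merged, "merged_cluster_set"))
  cl <- merged$clusters
  log <- merged$filter_log
  drop_rows <- function(idx, reason) {
    if (!length(idx)) return(invisible())
    log <<- rbind(log, data.frame(name = cl$name[idx], reason = reason,
                                  stringsAsFactors = FALSE))
    cl <<- cl[-idx, , drop = FALSE]
  }

  rep_all <- rbind(
    if (!is.null(repeats) && nrow(repeats))
      repeats[, c("chrom", "start", "end")],
    if (!is.null(tevs) && nrow(tevs)) tevs[, c("chrom", "start", "end")])
  if (!is.null(rep_all) && nrow(rep_all) && nrow(cl)) {
    rgr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      rep_all$chrom, IRanges::IRanges(rep_all$start + 1L, rep_all$end)))
    cgr <- GenomicRanges::GRanges(cl$chrom,
                                  IRanges::IRanges(cl$start + 1L, cl$end))
    ov <- GenomicRanges::findOverlaps(cgr, rgr)
    cov_bp <- numeric(nrow(cl))
    if (length(ov)) {
      qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
      w <- pmin(GenomicRanges::end(cgr)[qi], GenomicRanges::end(rgr)[si]) -
        pmax(GenomicRanges::start(cgr)[qi],
             GenomicRanges::start(rgr)[si]) + 1L
      cov_bp <- tapply(w, factor(qi, levels = seq_len(nrow(cl))), sum)
      cov_bp[is.na(cov_bp)] <- 0
    }
    drop_rows(which(cov_bp > repeat_frac * (cl$end - cl$start)),
              "repeat_overlap")
  }

  if (nrow(cl)) {
    bi <- which(cl$strand == "*")
    if (length(bi)) {
      mono <- cl[cl$strand %in% c("+", "-"), , drop = FALSE]
      if (nrow(mono)) {
        ov <- interval_overlap(cl[bi, , drop = FALSE], mono)
        ov <- ov[ov$overlap > 0, , drop = FALSE]
        drop_rows(bi[unique(ov$a_idx)], "bi_over_mono")
      }
    }
  }

  if (min_count > 0 && nrow(cl)) {
    if (is.null(counts)) stop("counts required for the low-count filter")
    missing <- setdiff(cl$name, rownames(counts))
    if (length(missing))
      stop("counts do not cover cluster ", missing[1])
    mx <- apply(counts[cl$name, , drop = FALSE], 1, max)
    drop_rows(which(mx < min_count), "low_count")
  }

  structure(list(clusters = cl, provenance = merged$provenance,
                 filter_log = log),
            class = "merged_cluster_set")
}
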