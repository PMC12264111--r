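# De novo piRNA cluster calling: multimapper reallocation by local
# unique-read density, density-threshold cluster calling on 1-kb tiles,
# and mono/bi directionality annotation.

#' Reallocate multimapping reads by flanking unique-read density
#'
#' Each multimapping read (records sharing a `read_id` within a sample, with
#' `n_hits > 1`) is split across its candidate loci. Locus i receives weight
#' `s_i / sum(s_j)` where `s_i` is a bell-weighted unique-read density score
#' of the +/- `flank` region around the locus: unique-read midpoints are
#' binned into sliding windows of width `window` and each window count is
#' weighted by a Gaussian kernel `exp(-d^2 / (2 sigma^2))` with
#' `sigma = flank / 3`, `d` the window-center offset from the locus center.
#' Loci scoring 0 while a sibling locus scores positively are dropped; if
#' all loci score 0 the weights fall back to uniform `1 / n_hits`. Unique
#' reads pass through with weight 1, so total weight is conserved.
#'
#' @param alignments alignment `data.frame`; all candidate loci of each
#'   multimapper must be present
#' @param flank half-width of the flanking region scored (bp)
#' @param window sliding window width (bp)
#' @return the alignments with a `weight` column, zero-weight loci removed
#' @export
reallocate_multimappers <- function(alignments, flank = 10000L,
                                    window = 1000L) {
  aln <- alignments
  key <- paste(aln$sample_id, aln$read_id, sep = "\r")
  nrec <- table(key)
  mism <- aln$n_hits[match(names(nrec), key)] != as.integer(nrec)
  if (any(mism))
    stop("n_hits inconsistent with number of records for read ",
         sub(".*\r", "", names(nrec)[mism][1]))
  aln$weight <- 1
  multi <- aln$n_hits > 1L
  if (!any(multi)) return(aln)

  uni <- aln[!multi, , drop = FALSE]
  sigma <- flank / 3
  # unique-read midpoints per (sample, chrom), sorted for findInterval
  umid <- split((uni$start + uni$end) / 2,
                paste(uni$sample_id, uni$chrom, sep = "\r"))
  umid <- lapply(umid, sort)

  score_locus <- function(sample_id, chrom, center) {
    mids <- umid[[paste(sample_id, chrom, sep = "\r")]]
    if (is.null(mids) || length(mids) == 0) return(0)
    edges <- seq(center - flank, center + flank, by = window)
    counts <- diff(findInterval(edges, mids))
    centers <- (edges[-1] + edges[-length(edges)]) / 2
    sum(counts * exp(-(centers - center)^2 / (2 * sigma^2)))
  }

  mi <- which(multi)
  mkey <- key[mi]
  scores <- vapply(mi, function(r)
    score_locus(aln$sample_id[r], aln$chrom[r],
                (aln$start[r] + aln$end[r]) / 2), numeric(1))
  drop <- logical(length(mi))
  for (grp in split(seq_along(mi), mkey)) {
    s <- scores[grp]
    tot <- sum(s)
    if (tot > 0) {
      aln$weight[mi[grp]] <- s / tot
      drop[grp] <- s == 0
    } else {
      aln$weight[mi[grp]] <- 1 / length(grp)
    }
  }
  aln[setdiff(seq_len(nrow(aln)), mi[drop]), , drop = FALSE]
}

#' Call piRNA clusters from reallocated alignments of one sample
#'
#' The genome is tiled into fixed windows of `tile` bp; a tile qualifies
#' when its weighted read count (reads assigned by midpoint) exceeds
#' `density_fold` times the genome-wide mean per-tile weight. Qualifying
#' tiles separated by at most `merge_gap` bp are merged, the merged region
#' is trimmed to the outermost boundaries of its reads, and regions are
#' retained when the trimmed span is at least `min_span` bp and the summed
#' read weight at least `min_weighted_reads`. Directionality is annotated
#' with [annotate_directionality()]. Deterministic for fixed input.
#'
#' @param reallocated alignments of one sample with a `weight` column
#' @param genome named vector of chromosome lengths (bp); defaults to the
#'   maximum alignment end per chromosome
#' @param min_span minimum cluster span (bp)
#' @param min_weighted_reads minimum summed read weight
#' @param density_fold fold over genome-wide mean tile weight
#' @param merge_gap maximum gap between merged tiles (bp)
#' @param tile tile width (bp)
#' @param refine_bin sub-tile bin width (bp) for edge refinement: before
#'   the final read-boundary trim, bins at either edge of a merged region
#'   whose weighted density falls below the tile threshold (scaled to bin
#'   width) are dropped, so stray reads in a partially covered edge tile
#'   do not inflate the cluster span; set 0 to disable
#' @return `data.frame` of clusters with weighted_read_count, sense_count,
#'   antisense_count, directionality, assigned strand
#' @export
call_clusters <- function(reallocated, genome = NULL, min_span = 1000L,
                          min_weighted_reads = 20, density_fold = 5,
                          merge_gap = 500L, tile = 1000L,
                          refine_bin = 100L) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), score = numeric(),
                      strand = character(), sample_id = character(),
                      weighted_read_count = numeric(),
                      sense_count = numeric(), antisense_count = numeric(),
                      directionality = character())
  if (nrow(reallocated) == 0) return(empty)
  aln <- reallocated
  if (is.null(aln$weight)) aln$weight <- 1
  sample_id <- unique(aln$sample_id)
  if (length(sample_id) != 1)
    stop("call_clusters expects alignments of a single sample")
  if (is.null(genome)) {
    genome <- tapply(aln$end, aln$chrom, max)
    genome <- setNames(as.numeric(genome), names(genome))
  }
  n_tiles_total <- sum(ceiling(genome / tile))
  mean_tile_weight <- sum(aln$weight) / n_tiles_total
  threshold <- density_fold * mean_tile_weight

  mid <- floor((aln$start + aln$end) / 2)
  out <- list()
  for (chrom in names(genome)) {
    on_chr <- which(aln$chrom == chrom)
    if (!length(on_chr)) next
    tidx <- mid[on_chr] %/% tile
    w <- tapply(aln$weight[on_chr], tidx, sum)
    tpos <- as.integer(names(w))
    qual <- tpos[w > threshold]
    if (!length(qual)) next
    qual <- sort(qual)
    # merge qualifying tiles whose edge gap <= merge_gap
    gap_tiles <- ceiling(merge_gap / tile)
    brk <- c(0L, which(diff(qual) > gap_tiles + 0L), length(qual))
    # diff(qual) - 1 tiles lie between; their bp gap is (diff-1)*tile
    brk <- c(0L, which((diff(qual) - 1L) * tile > merge_gap), length(qual))
    for (k in seq_len(length(brk) - 1L)) {
      tiles_k <- qual[(brk[k] + 1L):brk[k + 1L]]
      reg_start <- min(tiles_k) * tile
      reg_end <- (max(tiles_k) + 1L) * tile
      if (refine_bin > 0) {
        reg <- .refine_edges(reg_start, reg_end, mid[on_chr],
                             aln$weight[on_chr], threshold, tile,
                             refine_bin)
        reg_start <- reg[1]; reg_end <- reg[2]
        if (reg_end <= reg_start) next
      }
      inside <- on_chr[mid[on_chr] >= reg_start & mid[on_chr] < reg_end]
      if (!length(inside)) next
      cl_start <- min(aln$start[inside])
      cl_end <- max(aln$end[inside])
      wsum <- sum(aln$weight[inside])
      if (cl_end - cl_start < min_span || wsum < min_weighted_reads) next
      plus <- sum(aln$weight[inside][aln$strand[inside] == "+"])
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = cl_start, end = cl_end,
        name = NA_character_, score = 0,
        strand = "*", sample_id = sample_id,
        weighted_read_count = wsum,
        sense_count = NA_real_, antisense_count = NA_real_,
        directionality = NA_character_, plus_w = plus,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  cl <- do.call(rbind, out)
  cl <- cl[order(cl$chrom, cl$start), , drop = FALSE]
  cl$name <- sprintf("%s_cl%d", sample_id, seq_len(nrow(cl)))
  rownames(cl) <- NULL
  for (i in seq_len(nrow(cl)))
    cl[i, ] <- annotate_directionality(
      cl[i, ], plus_weight = cl$plus_w[i],
      minus_weight = cl$weighted_read_count[i] - cl$plus_w[i])
  cl$plus_w <- NULL
  cl
}

# refine merged-region edges at sub-tile resolution: trim leading/trailing
# bins below the (bin-scaled) tile threshold, then extend outward through
# adjacent supra-threshold bins (at most one tile each side) so cluster
# tails in a non-qualifying partial edge tile are recovered; returns the
# refined [start, end)
.refine_edges <- function(reg_start, reg_end, mids, weights, threshold,
                          tile, refine_bin) {
  # hysteresis: tiles are CALLED at the full threshold, but edges are
  # DELIMITED at half of it — boundary bins carry partial signal and
  # Poisson noise is relatively larger at bin scale, while background
  # density stays far below half-threshold
  thr_bin <- 0.5 * threshold * refine_bin / tile
  edges <- seq(reg_start - tile, reg_end + tile, by = refine_bin)
  nb <- length(edges) - 1L
  w <- vapply(seq_len(nb), function(b) {
    sel <- mids >= edges[b] & mids < edges[b + 1L]
    if (any(sel)) sum(weights[sel]) else 0
  }, numeric(1))
  keep <- w > thr_bin
  core <- which(edges[-1] > reg_start & edges[-(nb + 1)] < reg_end)
  if (!any(keep[core])) return(c(reg_start, reg_start))
  runs <- rle(keep)
  run_id <- rep(seq_along(runs$lengths), runs$lengths)
  core_runs <- unique(run_id[core][keep[core]])
  # the cluster is the heaviest run; isolated noise bins that sneak into
  # a partially covered edge tile form light runs and are discarded
  run_w <- vapply(core_runs, function(rn) sum(w[run_id == rn]), numeric(1))
  sel_bins <- which(run_id == core_runs[which.max(run_w)])
  c(edges[min(sel_bins)], edges[max(sel_bins) + 1L])
}

#' Annotate cluster directionality from strand-weighted read counts
#'
#' The antisense strand is the minority strand by weighted count. A cluster
#' is bi-directional iff the antisense fraction is at least
#' `antisense_threshold` (default 0.10, "at least 10%"); otherwise it is
#' mono-directional with the majority strand assigned.
#'
#' @param cluster one-row cluster `data.frame` with sense_count and
#'   antisense_count (sense = majority), or plus/minus weights via
#'   `plus_weight` / `minus_weight`
#' @param plus_weight,minus_weight optional explicit per-strand weighted
#'   counts; override sense/antisense columns
#' @param antisense_threshold minimum antisense fraction for "bi"
#' @return the cluster row with directionality and strand filled in
#' @export
annotate_directionality <- function(cluster, plus_weight = NULL,
                                    minus_weight = NULL,
                                    antisense_threshold = 0.10) {
  if (!is.null(plus_weight)) {
    cluster$sense_count <- max(plus_weight, minus_weight)
    cluster$antisense_count <- min(plus_weight, minus_weight)
    maj <- if (plus_weight >= minus_weight) "+" else "-"
  } else {
    maj <- if (cluster$strand %in% c("+", "-")) cluster$strand else "+"
  }
  tot <- cluster$sense_count + cluster$antisense_count
  if (tot <= 0) stop("directionality undefined for zero weighted reads")
  cluster$weighted_read_count <- tot
  frac_anti <- cluster$antisense_count / tot
  if (frac_anti >= antisense_threshold) {
    cluster$directionality <- "bi"
    cluster$strand <- "*"
  } else {
    cluster$directionality <- "mono"
    cluster$strand <- maj
  }
  cluster
}
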