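# End-to-end driver: per-sample cluster calling, cross-strain merging and
# filtering, counting, differential expression, and TEV association.

#' Run the inbred-strain analysis pipeline on simulated (or real) inputs
#'
#' Per sample: reallocate multimappers and call clusters. Per strain:
#' pool the samples' calls. Across strains: same-strand union merge, the
#' filter cascade (repeat/TEV overlap, bi-over-mono, low count), unique
#' read counting over the merged set, all pairwise differential
#' expression, and TEV association (Fisher per class and strand mode,
#' fold-change groups for `pair`).
#'
#' @param alignments alignment table for all samples
#' @param samples sample table
#' @param genome named chromosome lengths
#' @param tevs TEV table (may be `NULL` to skip association)
#' @param repeats repeat intervals for the filter cascade (may be `NULL`)
#' @param pair two strain labels for the fold-change group comparison
#' @param flank,window reallocation parameters
#' @param call_args list of extra arguments to [call_clusters()]
#' @param min_overlap minimum read/cluster overlap for counting (bp)
#' @return list with per_sample_clusters, merged, counts, de, de_summary,
#'   te (or NULL)
#' @export
run_inbred_pipeline <- function(alignments, samples, genome, tevs = NULL,
                                repeats = NULL, pair = NULL,
                                flank = 10000L, window = 1000L,
                                call_args = list(), min_overlap = 18L) {
  per_sample <- list()
  for (sid in samples$sample_id) {
    aln <- alignments[alignments$sample_id == sid, , drop = FALSE]
    re <- reallocate_multimappers(aln, flank = flank, window = window)
    per_sample[[sid]] <- do.call(call_clusters,
                                 c(list(re, genome = genome), call_args))
  }
  by_strain <- lapply(split(samples$sample_id, samples$strain),
                      function(sids)
                        do.call(rbind, per_sample[sids]))
  merged <- merge_same_strand_union(by_strain)
  counts <- count_reads_in_clusters(alignments, merged$clusters,
                                    min_overlap = min_overlap,
                                    unique_only = TRUE,
                                    sample_ids = samples$sample_id)
  merged <- apply_cluster_filters(merged, repeats = repeats, tevs = tevs,
                                  counts = counts)
  counts <- counts[merged$clusters$name, , drop = FALSE]
  de <- all_pairwise_de(counts, samples)
  de_sum <- summarize_de(de)
  te <- NULL
  if (!is.null(tevs))
    te <- run_te_association(merged$clusters, de_sum, tevs,
                             counts = counts, samples = samples,
                             pair = pair)
  list(per_sample_clusters = per_sample, merged = merged, counts = counts,
       de = de, de_summary = de_sum, te = te)
}
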