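# Synthetic-data generator: emits inputs with the statistical structure the
# analysis assumes (NB counts with strain and TEV effects, read-level
# alignments inside planted clusters, pedigrees with additive genetic
# effects, strain coordinate maps, junction reads) plus ground truth.

#' Simulation configuration with the study-design defaults
#'
#' Defaults emulate the study design: four inbred strains with 3 testis
#' samples each, negative-binomial cluster counts (dispersion 0.05, base
#' mean 500), a 4-fold strain effect on 20% of clusters, sense-strand ERV
#' variants multiplying expression 4-fold in carrier strains, 18%
#' bi-directional clusters, and an outbred design of 7 pedigrees in two
#' pedigree sets with 40 recorded males and true h2 = 0.8.
#'
#' @param seed master seed
#' @param ... overrides of any default field
#' @return a `sim_config` list
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    strains = c("BL6", "NOD", "C3H", "129"),
    n_samples_per_strain = 3L,
    tissue = "testis",
    genome = c(chr1 = 1500000L, chr2 = 1500000L),
    n_clusters = 30L,
    cluster_span = c(1500L, 2500L),
    cluster_spacing = 50000L,
    fraction_bi_clusters = 0.18,
    antisense_read_fraction = 0.03,
    bi_antisense_fraction = 0.30,
    nb_dispersion = 0.05,
    base_mean_counts = 500,
    strain_effect_log2fc = 2,
    fraction_de_clusters = 0.2,
    tev_effect_log2fc = 2,
    fraction_clusters_with_tev = 0.4,
    sense_fraction_of_tevs = 0.5,
    tev_annotations = c("IAP-I", "RLTR10", "MERVL"),
    tev_gap = c(500L, 4000L),
    multimapper_fraction = 0.10,
    background_reads_per_kb = 0.5,
    read_length = c(26L, 32L),
    pedigree = list(n_pedigrees = 7L, generations = 3L,
                    litters_per_generation = 1L, litter_size = 4L,
                    n_recorded_males = 40L, max_recorded_per_litter = Inf),
    true_h2 = 0.8,
    n_pedigree_clusters = 50L,
    junction = list(n_junctions = 20L, true_efficiency = 0.8,
                    reads_per_junction = 100L))
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field: ", bad[1])
  cfg[names(over)] <- over
  structure(cfg, class = "sim_config")
}

#' Simulate the inbred multi-strain small-RNA experiment
#'
#' Plants non-overlapping clusters on the genome, assigns strand and
#' antisense fraction (a configurable fraction bi-directional), plants
#' strain effects on a fraction of clusters and TE variants near another
#' fraction (sense-strand variants multiply carrier-strain expression,
#' antisense variants add nothing), draws negative-binomial counts per
#' cluster and sample, and materializes read-level alignments consistent
#' with the counts: counting the unique reads over the (disjoint) planted
#' clusters with [count_reads_in_clusters()] reproduces the count matrix
#' exactly. Multimapping reads (two loci each) and background unique reads
#' placed clear of the clusters add realistic noise without touching the
#' counts.
#'
#' @param config a [sim_config()]
#' @return list with clusters, tevs, alignments, counts, samples, truth
#' @export
simulate_inbred_experiment <- function(config = sim_config()) {
  set.seed(config$seed)
  gen <- config$genome
  n_cl <- config$n_clusters

  # --- planted clusters, spaced so no 5-kb TEV window or read spills over
  per_chrom <- ceiling(n_cl / length(gen))
  pos <- list()
  k <- 0L
  for (chrom in names(gen)) {
    n_here <- min(per_chrom, n_cl - k)
    if (n_here <= 0) break
    starts <- config$cluster_spacing * seq_len(n_here)
    stopifnot(max(starts) + max(config$cluster_span) < gen[chrom])
    span <- sample(config$cluster_span[1]:config$cluster_span[2], n_here,
                   replace = TRUE)
    pos[[chrom]] <- data.frame(chrom = chrom, start = starts,
                               end = starts + span,
                               stringsAsFactors = FALSE)
    k <- k + n_here
  }
  clusters <- do.call(rbind, pos)
  clusters$name <- sprintf("pl%02d", seq_len(nrow(clusters)))
  clusters$score <- 0
  clusters$strand <- sample(c("+", "-"), n_cl, replace = TRUE)
  is_bi <- seq_len(n_cl) %in%
    sample(n_cl, round(config$fraction_bi_clusters * n_cl))
  clusters$bi <- is_bi
  clusters$antisense_frac <- ifelse(is_bi, config$bi_antisense_fraction,
                                    config$antisense_read_fraction)
  clusters <- clusters[, c("chrom", "start", "end", "name", "score",
                           "strand", "bi", "antisense_frac")]

  # --- strain DE effects
  n_de <- round(config$fraction_de_clusters * n_cl)
  if (n_de > n_cl) stop("more DE clusters than clusters")
  de_idx <- sort(sample(n_cl, n_de))
  de_strain <- sample(config$strains, n_de, replace = TRUE)
  truth_de <- data.frame(cluster_id = clusters$name[de_idx],
                         high_strain = de_strain,
                         log2fc = rep(config$strain_effect_log2fc, n_de),
                         stringsAsFactors = FALSE)

  # --- TE variants within 5 kb of a fraction of clusters
  n_tev <- round(config$fraction_clusters_with_tev * n_cl)
  tev_idx <- sort(sample(n_cl, n_tev))
  tevs <- NULL
  if (n_tev > 0) {
    gaps <- sample(config$tev_gap[1]:config$tev_gap[2], n_tev,
                   replace = TRUE)
    tev_len <- sample(300:800, n_tev, replace = TRUE)
    tev_start <- clusters$end[tev_idx] + gaps
    sense <- runif(n_tev) < config$sense_fraction_of_tevs
    tev_strand <- ifelse(sense, clusters$strand[tev_idx],
                         c("+" = "-", "-" = "+")[clusters$strand[tev_idx]])
    carriers <- lapply(seq_len(n_tev), function(i)
      sort(sample(config$strains,
                  sample(length(config$strains) - 1L, 1L))))
    tevs <- data.frame(
      chrom = clusters$chrom[tev_idx], start = tev_start,
      end = tev_start + tev_len,
      name = sprintf("tev%02d", seq_len(n_tev)), score = 0,
      strand = unname(tev_strand),
      raw_annotation = sample(config$tev_annotations, n_tev,
                              replace = TRUE),
      present_in = vapply(carriers, paste, "", collapse = ","),
      stringsAsFactors = FALSE)
    truth_tev <- data.frame(tev_id = tevs$name,
                            near_cluster = clusters$name[tev_idx],
                            sense = sense,
                            log2fc = ifelse(sense,
                                            config$tev_effect_log2fc, 0),
                            stringsAsFactors = FALSE)
  } else {
    truth_tev <- data.frame(tev_id = character(),
                            near_cluster = character(),
                            sense = logical(), log2fc = numeric())
  }

  # --- samples and NB counts
  samples <- data.frame(
    sample_id = paste0(rep(config$strains,
                           each = config$n_samples_per_strain), "_s",
                       seq_len(config$n_samples_per_strain)),
    strain = rep(config$strains, each = config$n_samples_per_strain),
    tissue = config$tissue,
    batch = "b1", stringsAsFactors = FALSE)
  log2mu <- matrix(log2(config$base_mean_counts), n_cl, nrow(samples),
                   dimnames = list(clusters$name, samples$sample_id))
  for (r in seq_len(nrow(truth_de))) {
    sel <- samples$strain == truth_de$high_strain[r]
    log2mu[truth_de$cluster_id[r], sel] <-
      log2mu[truth_de$cluster_id[r], sel] + truth_de$log2fc[r]
  }
  for (r in seq_len(nrow(truth_tev))) {
    if (truth_tev$log2fc[r] == 0) next
    carr <- strsplit(tevs$present_in[match(truth_tev$tev_id[r],
                                           tevs$name)], ",")[[1]]
    sel <- samples$strain %in% carr
    log2mu[truth_tev$near_cluster[r], sel] <-
      log2mu[truth_tev$near_cluster[r], sel] + truth_tev$log2fc[r]
  }
  alpha <- config$nb_dispersion
  counts <- matrix(as.integer(rnbinom(length(log2mu), mu = 2^log2mu,
                                      size = 1 / alpha)),
                   nrow = n_cl, dimnames = dimnames(log2mu))

  # --- read-level alignments consistent with the counts
  aln <- .materialize_alignments(clusters, counts, samples, config)

  list(clusters = clusters[, 1:6], tevs = tevs, alignments = aln,
       counts = counts, samples = samples,
       truth = list(clusters = clusters, de = truth_de, tev = truth_tev,
                    log2mu = log2mu))
}

.materialize_alignments <- function(clusters, counts, samples, config) {
  rl <- config$read_length
  flip <- c("+" = "-", "-" = "+")
  out <- list()
  rid <- 0L
  for (j in seq_len(ncol(counts))) {
    sid <- colnames(counts)[j]
    for (i in seq_len(nrow(counts))) {
      n <- counts[i, j]
      if (n == 0) next
      len <- sample(rl[1]:rl[2], n, replace = TRUE)
      # fully inside the cluster: always >= 18 bp overlap, never near a
      # neighbouring cluster (spacing >> span)
      start <- clusters$start[i] +
        floor(runif(n) * (clusters$end[i] - clusters$start[i] - len))
      anti <- runif(n) < clusters$antisense_frac[i]
      strand <- ifelse(anti, flip[clusters$strand[i]], clusters$strand[i])
      out[[length(out) + 1L]] <- data.frame(
        read_id = sprintf("r%07d", rid + seq_len(n)), sample_id = sid,
        chrom = clusters$chrom[i], start = start, end = start + len,
        strand = unname(strand), n_hits = 1L, stringsAsFactors = FALSE)
      rid <- rid + n
    }
    # multimappers: fraction of the sample's reads, two loci each (one in
    # a random cluster, one at a random background position); n_hits = 2
    # keeps them out of unique-only counting
    n_sample <- sum(counts[, j])
    n_mm <- round(config$multimapper_fraction * n_sample)
    if (n_mm > 0) {
      ci <- sample(nrow(clusters), n_mm, replace = TRUE)
      len <- sample(rl[1]:rl[2], n_mm, replace = TRUE)
      s1 <- clusters$start[ci] +
        floor(runif(n_mm) * (clusters$end[ci] - clusters$start[ci] - len))
      bg <- .background_positions(n_mm, len, clusters, config$genome)
      ids <- sprintf("m%07d", rid + seq_len(n_mm))
      # cluster-side locus follows the cluster's strand composition (a
      # multimapper piRNA still originates from the cluster's precursor)
      flip <- c("+" = "-", "-" = "+")
      anti <- runif(n_mm) < clusters$antisense_frac[ci]
      s_strand <- ifelse(anti, flip[clusters$strand[ci]],
                         clusters$strand[ci])
      out[[length(out) + 1L]] <- data.frame(
        read_id = rep(ids, 2), sample_id = sid,
        chrom = c(clusters$chrom[ci], bg$chrom),
        start = c(s1, bg$start), end = c(s1, bg$start) + rep(len, 2),
        strand = c(unname(s_strand),
                   sample(c("+", "-"), n_mm, replace = TRUE)),
        n_hits = 2L, stringsAsFactors = FALSE)
      rid <- rid + n_mm
    }
    # background unique reads, rejected away from all clusters
    n_bg <- round(config$background_reads_per_kb *
                    sum(config$genome) / 1000)
    if (n_bg > 0) {
      len <- sample(rl[1]:rl[2], n_bg, replace = TRUE)
      bg <- .background_positions(n_bg, len, clusters, config$genome)
      out[[length(out) + 1L]] <- data.frame(
        read_id = sprintf("b%07d", rid + seq_len(n_bg)), sample_id = sid,
        chrom = bg$chrom, start = bg$start, end = bg$start + len,
        strand = sample(c("+", "-"), n_bg, replace = TRUE),
        n_hits = 1L, stringsAsFactors = FALSE)
      rid <- rid + n_bg
    }
  }
  aln <- do.call(rbind, out)
  rownames(aln) <- NULL
  aln
}

# uniform positions at least 100 bp clear of every cluster
.background_positions <- function(n, len, clusters, genome) {
  chrom <- sample(names(genome), n, replace = TRUE,
                  prob = genome / sum(genome))
  start <- floor(runif(n) * (genome[chrom] - max(len)))
  for (it in 1:50) {
    bad <- rep(FALSE, n)
    for (i in seq_len(nrow(clusters))) {
      bad <- bad | (chrom == clusters$chrom[i] &
                      start + len > clusters$start[i] - 100 &
                      start < clusters$end[i] + 100)
    }
    if (!any(bad)) break
    chrom[bad] <- sample(names(genome), sum(bad), replace = TRUE,
                         prob = genome / sum(genome))
    start[bad] <- floor(runif(sum(bad)) * (genome[chrom[bad]] - max(len)))
  }
  list(chrom = chrom, start = as.integer(start))
}

#' Simulate the outbred pedigree expression experiment
#'
#' Builds `n_pedigrees` branching multi-generation pedigrees, as in a
#' breeding colony: a founding pair produces the first litter; each later
#' generation mates up to `litters_per_generation` males of the previous
#' generation, each with a new unrelated founder dam, producing separate
#' litters. Pedigrees are split into two pedigree sets. Per cluster,
#' breeding values `u ~ N(0, sigma_a^2 A)` are drawn via
#' the Cholesky factor of the tabular-method relationship matrix (1e-8
#' jitter on numerical failure) and expression is
#' `y = set_effect + u + e` with `sigma_a^2 / (sigma_a^2 + sigma_e^2) =
#' true_h2` (total variance 1). Expression is recorded only for
#' `n_recorded_males` males, mirroring a males-only phenotype; records
#' are spread over litters (`max_recorded_per_litter` per litter first,
#' topped up at random), as ~40 phenotyped males across seven
#' multi-generation pedigrees implies roughly one male per litter — this
#' also keeps animals within a (generation, pedigree-set) permutation
#' stratum approximately exchangeable, which the stratified null assumes.
#'
#' @param config a [sim_config()]
#' @return list with ped (pedigree table), expression (clusters x recorded
#'   individuals), truth (true_h2, breeding values, set effects)
#' @export
simulate_outbred_pedigree_experiment <- function(config = sim_config()) {
  set.seed(config$seed + 1L)
  pc <- config$pedigree
  recs <- list()
  for (p in seq_len(pc$n_pedigrees)) {
    set <- if (p <= ceiling(pc$n_pedigrees / 2)) "set1" else "set2"
    pid_n <- 0L
    pid <- function(tag, g) {
      pid_n <<- pid_n + 1L
      sprintf("P%d_g%d_%s%d", p, g, tag, pid_n)
    }
    founder_m <- pid("m", 0); founder_f <- pid("f", 0)
    recs[[length(recs) + 1L]] <- data.frame(
      individual_id = c(founder_m, founder_f),
      sire_id = NA_character_, dam_id = NA_character_,
      generation = 0L, pedigree_set = set, sex = c("M", "F"),
      stringsAsFactors = FALSE)
    prev_males <- founder_m
    for (g in seq_len(pc$generations)) {
      n_litters <- if (g == 1) 1L
                   else min(pc$litters_per_generation, length(prev_males))
      sires <- if (g == 1) founder_m
               else sample(prev_males, n_litters)
      new_males <- character(0)
      for (li in seq_len(n_litters)) {
        dam <- if (g == 1) founder_f else pid("f", g - 1L)
        if (g > 1)  # migrant founder dam for this litter
          recs[[length(recs) + 1L]] <- data.frame(
            individual_id = dam, sire_id = NA_character_,
            dam_id = NA_character_, generation = g - 1L,
            pedigree_set = set, sex = "F", stringsAsFactors = FALSE)
        sex <- sample(c("M", "F"), pc$litter_size, replace = TRUE)
        # guarantee a male to continue the line
        if (!any(sex == "M")) sex[1] <- "M"
        kids <- data.frame(
          individual_id = vapply(sex, function(sx)
            pid(if (sx == "M") "m" else "f", g), ""),
          sire_id = sires[li], dam_id = dam, generation = g,
          pedigree_set = set, sex = sex, stringsAsFactors = FALSE)
        recs[[length(recs) + 1L]] <- kids
        new_males <- c(new_males, kids$individual_id[kids$sex == "M"])
      }
      prev_males <- new_males
    }
  }
  ped <- do.call(rbind, recs)
  rownames(ped) <- NULL

  A <- build_relationship_matrix(ped)
  L <- tryCatch(chol(A), error = function(e) {
    warning("Cholesky of A failed; adding 1e-8 jitter")
    chol(A + diag(1e-8, nrow(A)))
  })
  males <- ped[ped$sex == "M" & ped$generation > 0, , drop = FALSE]
  litter <- paste(males$sire_id, males$dam_id, males$generation)
  max_pl <- if (is.null(pc$max_recorded_per_litter)) Inf
            else pc$max_recorded_per_litter
  first_pick <- unlist(lapply(split(males$individual_id, litter),
                              function(x)
                                x[sample.int(length(x),
                                             min(length(x), max_pl))]),
                       use.names = FALSE)
  n_rec <- min(pc$n_recorded_males, nrow(males))
  recorded <- if (length(first_pick) >= n_rec)
    sample(first_pick, n_rec)
  else c(first_pick, sample(setdiff(males$individual_id, first_pick),
                            n_rec - length(first_pick)))
  recorded <- sort(recorded)

  n_cl <- config$n_pedigree_clusters
  s_a <- sqrt(config$true_h2)
  s_e <- sqrt(1 - config$true_h2)
  n_ind <- nrow(A)
  u_all <- matrix(rnorm(n_cl * n_ind), n_cl, n_ind) %*% L * s_a
  colnames(u_all) <- rownames(A)
  set_eff <- matrix(rnorm(n_cl * 2), n_cl, 2,
                    dimnames = list(NULL, c("set1", "set2")))
  pset <- ped$pedigree_set[match(recorded, ped$individual_id)]
  e <- matrix(rnorm(n_cl * length(recorded), sd = s_e), n_cl,
              length(recorded))
  expr <- u_all[, recorded, drop = FALSE] + e +
    set_eff[, pset, drop = FALSE]
  dimnames(expr) <- list(sprintf("pcl%03d", seq_len(n_cl)), recorded)

  list(ped = ped[, c("individual_id", "sire_id", "dam_id", "generation",
                     "pedigree_set", "sex")],
       expression = expr,
       truth = list(true_h2 = config$true_h2,
                    breeding_values = u_all[, recorded, drop = FALSE],
                    set_effects = set_eff, A = A))
}

#' Simulate strain coordinate maps with one-to-one and split regions
#'
#' Tiles each chromosome into ~100-kb alignment blocks with cumulative
#' indel offsets. A configurable fraction of blocks is split in two with a
#' target-side gap (non-one-to-one), so intervals inside the split point
#' exercise the `not_one_to_one` drop path. When planted `clusters` are
#' supplied, each is tagged convertible or not in the returned truth table.
#'
#' @param config a [sim_config()]
#' @param clusters optional planted cluster table to tag
#' @param split_fraction fraction of blocks split non-one-to-one
#' @return list with `maps` (one block table per strain) and `truth`
#' @export
simulate_strain_maps <- function(config = sim_config(), clusters = NULL,
                                 split_fraction = 0.1) {
  set.seed(config$seed + 2L)
  block <- 100000L
  maps <- list()
  for (s in config$strains) {
    rows <- list()
    for (chrom in names(config$genome)) {
      starts <- seq(0L, config$genome[chrom] - 1L, by = block)
      ends <- pmin(starts + block, config$genome[chrom])
      off <- cumsum(sample(-500:500, length(starts), replace = TRUE))
      split_me <- runif(length(starts)) < split_fraction
      for (b in seq_along(starts)) {
        if (split_me[b]) {
          mid <- starts[b] + (ends[b] - starts[b]) %/% 2L
          # two blocks with a 1-kb target gap: intervals crossing `mid`
          # no longer convert one-to-one
          rows[[length(rows) + 1L]] <- data.frame(
            source_chrom = chrom,
            source_start = c(starts[b], mid),
            source_end = c(mid, ends[b]),
            target_chrom = chrom,
            target_start = c(starts[b] + off[b], mid + off[b] + 1000L),
            stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            source_chrom = chrom, source_start = starts[b],
            source_end = ends[b], target_chrom = chrom,
            target_start = starts[b] + off[b], stringsAsFactors = FALSE)
        }
      }
    }
    maps[[s]] <- do.call(rbind, rows)
  }
  truth <- NULL
  if (!is.null(clusters)) {
    truth <- do.call(rbind, lapply(names(maps), function(s) {
      conv <- convert_intervals(clusters, maps[[s]])
      data.frame(strain = s, cluster_id = clusters$name,
                 convertible = clusters$name %in% conv$converted$name,
                 stringsAsFactors = FALSE)
    }))
  }
  list(maps = maps, truth = truth)
}

#' Simulate split / unsplit junction reads
#'
#' Plants `n_junctions` introns, derives their 14-bp splice-site windows,
#' and emits `reads_per_junction` reads per junction, each split with
#' probability `true_efficiency` and placed to cover its window fully
#' (assignment-safe under the >= 7-of-14-bp rule). With
#' `with_negative_controls`, extra reads overlapping a window by exactly
#' 6 bp are added; the 0.5-fraction rule must exclude them.
#'
#' @param config a [sim_config()]
#' @param with_negative_controls add 6-bp-overlap decoy reads
#' @return list with introns, windows, reads, truth
#' @export
simulate_junction_reads <- function(config = sim_config(),
                                    with_negative_controls = FALSE) {
  set.seed(config$seed + 3L)
  jc <- config$junction
  n <- jc$n_junctions
  eff <- rep_len(jc$true_efficiency, n)
  intron_start <- 10000L + 5000L * seq_len(n)
  intron_len <- sample(200:500, n, replace = TRUE)
  introns <- data.frame(chrom = "chr1", start = intron_start,
                        end = intron_start + intron_len,
                        name = sprintf("jx%03d", seq_len(n)), score = 0,
                        strand = "+", stringsAsFactors = FALSE)
  windows <- splice_site_windows(introns)
  reads <- list()
  rid <- 0L
  for (i in seq_len(n)) {
    w <- windows[windows$junction_id == introns$name[i], ]
    nr <- jc$reads_per_junction
    side <- sample(seq_len(nrow(w)), nr, replace = TRUE)
    # start <= window start and end >= window end: full 14-bp coverage
    start <- w$start[side] - sample(0:16, nr, replace = TRUE)
    split <- as.integer(runif(nr) < eff[i])
    reads[[length(reads) + 1L]] <- data.frame(
      read_id = sprintf("j%06d", rid + seq_len(nr)), sample_id = "jx_s1",
      chrom = "chr1", start = start, end = start + 30L, split = split,
      stringsAsFactors = FALSE)
    rid <- rid + nr
    if (with_negative_controls) {
      # overlap exactly 6 bp of the donor window, all unsplit: would drag
      # efficiency down if wrongly assigned
      nd <- 20L
      dstart <- w$start[1] + 8L
      reads[[length(reads) + 1L]] <- data.frame(
        read_id = sprintf("n%06d", rid + seq_len(nd)), sample_id = "jx_s1",
        chrom = "chr1", start = dstart, end = dstart + 30L,
        split = 0L, stringsAsFactors = FALSE)
      rid <- rid + nd
    }
  }
  reads <- do.call(rbind, reads)
  list(introns = introns, windows = windows, reads = reads,
       truth = data.frame(junction_id = introns$name,
                          true_efficiency = eff,
                          stringsAsFactors = FALSE))
}

#' Write a simulated inbred experiment to a directory
#'
#' Emits the exact file dialects consumed by the other modules: clusters
#' BED6, TEV TSV, one alignment TSV per sample, count matrix TSV, sample
#' table TSV, and ground-truth TSVs under `truth/`.
#'
#' @param sim result of [simulate_inbred_experiment()]
#' @param dir output directory (created)
#' @return `dir`, invisibly
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  write_intervals(sim$clusters, file.path(dir, "clusters.bed"), "BED6")
  if (!is.null(sim$tevs))
    write_intervals(sim$tevs, file.path(dir, "tevs.tsv"), "TEV-TSV")
  for (sid in unique(sim$alignments$sample_id))
    write_alignments(sim$alignments[sim$alignments$sample_id == sid, ],
                     file.path(dir, paste0(sid, ".alignments.tsv")))
  write_count_matrix(sim$counts, file.path(dir, "counts.tsv"))
  write.table(sim$samples, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth$de, file.path(dir, "truth", "de.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth$tev, file.path(dir, "truth", "tev.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
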