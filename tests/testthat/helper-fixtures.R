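# Shared fixture builders and independent brute-force oracles.

make_aln <- function(chrom, start, end, strand = "+", n_hits = 1L,
                     sample_id = "s1", read_id = NULL) {
  n <- length(start)
  if (is.null(read_id)) read_id <- sprintf("r%03d", seq_len(n))
  data.frame(read_id = read_id, sample_id = sample_id,
             chrom = rep_len(chrom, n), start = start, end = end,
             strand = rep_len(strand, n), n_hits = rep_len(n_hits, n),
             stringsAsFactors = FALSE)
}

make_iv <- function(start, end, strand = "+", chrom = "chr1",
                    name = NULL) {
  genomic_intervals(rep_len(chrom, length(start)), start, end,
                    name = name, strand = strand)
}

# O(n*m) pairwise interval scan (oracle for interval_overlap)
bf_interval_pairs <- function(a, b, max_gap = 0L) {
  out <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    inter <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    gap <- max(0L, -inter)
    if (gap <= max_gap)
      out <- rbind(out, data.frame(a_idx = i, b_idx = j,
                                   overlap = max(0L, inter), gap = gap))
  }
  out
}

# brute-force double-loop read counter (oracle for count_reads_in_clusters)
bf_count <- function(aln, clusters, min_overlap = 18L,
                     unique_only = TRUE) {
  sids <- sort(unique(aln$sample_id))
  m <- matrix(0L, nrow(clusters), length(sids),
              dimnames = list(clusters$name, sids))
  for (r in seq_len(nrow(aln))) {
    if (unique_only && aln$n_hits[r] != 1L) next
    for (k in seq_len(nrow(clusters))) {
      if (aln$chrom[r] != clusters$chrom[k]) next
      ov <- min(aln$end[r], clusters$end[k]) -
        max(aln$start[r], clusters$start[k])
      if (ov >= min_overlap)
        m[k, aln$sample_id[r]] <- m[k, aln$sample_id[r]] + 1L
    }
  }
  m
}

# exact recursive kinship (path-counting oracle); A = 2 * phi
bf_kinship_A <- function(ped) {
  ids <- ped$individual_id
  sire <- match(ped$sire_id, ids)
  dam <- match(ped$dam_id, ids)
  gen <- ped$generation
  phi <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    if (i == j)
      return(0.5 * (1 + phi(sire[i], dam[i])))
    # recurse through the later-generation individual
    if (gen[i] < gen[j]) { tmp <- i; i <- j; j <- tmp }
    0.5 * (phi(sire[i], j) + phi(dam[i], j))
  }
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(i))
    A[i, j] <- A[j, i] <- 2 * phi(i, j)
  A
}

# gene-dropping Monte-Carlo kinship oracle (vectorized over drops)
bf_genedrop_A <- function(ped, n_drop = 1e5, seed = 99L) {
  set.seed(seed)
  o <- order(ped$generation)
  ids <- ped$individual_id[o]
  sire <- match(ped$sire_id[o], ids)
  dam <- match(ped$dam_id[o], ids)
  n <- length(ids)
  M <- matrix(0L, n, n_drop)  # maternal allele label per drop
  P <- matrix(0L, n, n_drop)  # paternal allele label per drop
  lab <- 0L
  for (i in seq_len(n)) {
    if (is.na(sire[i])) {
      P[i, ] <- lab + 1L; lab <- lab + 1L
    } else {
      pick <- stats::runif(n_drop) < 0.5
      P[i, ] <- ifelse(pick, M[sire[i], ], P[sire[i], ])
    }
    if (is.na(dam[i])) {
      M[i, ] <- lab + 1L; lab <- lab + 1L
    } else {
      pick <- stats::runif(n_drop) < 0.5
      M[i, ] <- ifelse(pick, M[dam[i], ], P[dam[i], ])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(i)) {
    if (i == j) {
      A[i, i] <- 1 + mean(M[i, ] == P[i, ])
    } else {
      phi <- (mean(M[i, ] == M[j, ]) + mean(M[i, ] == P[j, ]) +
                mean(P[i, ] == M[j, ]) + mean(P[i, ] == P[j, ])) / 4
      A[i, j] <- A[j, i] <- 2 * phi
    }
  }
  A[ped$individual_id, ped$individual_id]
}

# random valid pedigree generator for oracle comparisons
random_pedigree <- function(n, seed, n_founders = max(4L, n %/% 4L)) {
  set.seed(seed)
  ids <- sprintf("i%02d", seq_len(n))
  ped <- data.frame(individual_id = ids, sire_id = NA_character_,
                    dam_id = NA_character_, generation = 0L,
                    pedigree_set = "s1", stringsAsFactors = FALSE)
  for (i in (n_founders + 1):n) {
    prev <- seq_len(i - 1L)
    s <- sample(prev, 1); d <- sample(setdiff(prev, s), 1)
    ped$sire_id[i] <- ids[s]; ped$dam_id[i] <- ids[d]
    ped$generation[i] <- max(ped$generation[c(s, d)]) + 1L
  }
  ped
}

# direct-density cluster-calling world: planted clusters at exactly
# `fold`x the uniform background read density (criterion-5 fixture)
make_density_world <- function(seed, fold = 10, dens_cl = 0.25) {
  set.seed(seed)
  genome <- c(chr1 = 1500000L, chr2 = 1500000L)
  cl <- do.call(rbind, lapply(names(genome), function(ch) {
    st <- 50000L * seq_len(15)
    data.frame(chrom = ch, start = st,
               end = st + sample(1500:2500, 15, TRUE),
               stringsAsFactors = FALSE)
  }))
  cl$name <- sprintf("pl%02d", seq_len(nrow(cl)))
  cl$score <- 0; cl$strand <- "+"
  dens_bg <- dens_cl / fold
  reads <- lapply(seq_len(nrow(cl)), function(i) {
    n <- round(dens_cl * (cl$end[i] - cl$start[i]))
    len <- sample(26:32, n, TRUE)
    s <- cl$start[i] + floor(runif(n) * (cl$end[i] - cl$start[i] - len))
    make_aln(cl$chrom[i], s, s + len,
             read_id = sprintf("c%d_%d", i, seq_len(n)))
  })
  nbg <- round(dens_bg * sum(as.numeric(genome)))
  lenb <- sample(26:32, nbg, TRUE)
  chb <- sample(names(genome), nbg, TRUE)
  sb <- floor(runif(nbg) * (genome[chb] - 40))
  keep <- rep(TRUE, nbg)
  for (i in seq_len(nrow(cl)))
    keep <- keep & !(chb == cl$chrom[i] & sb + lenb > cl$start[i] &
                       sb < cl$end[i])
  reads[[length(reads) + 1L]] <-
    make_aln(chb[keep], sb[keep], (sb + lenb)[keep],
             read_id = sprintf("b%d", which(keep)))
  aln <- do.call(rbind, reads)
  aln$weight <- 1
  list(clusters = cl, alignments = aln, genome = genome)
}

jaccard_vs_planted <- function(called, planted) {
  vapply(seq_len(nrow(planted)), function(i) {
    p <- planted[i, ]
    ov <- called[called$chrom == p$chrom & called$start < p$end &
                   called$end > p$start, , drop = FALSE]
    if (nrow(ov) == 0) return(0)
    inter <- sum(pmin(ov$end, p$end) - pmax(ov$start, p$start))
    uni <- max(c(ov$end, p$end)) - min(c(ov$start, p$start))
    inter / uni
  }, numeric(1))
}

# the 12-interval merge/filter fixture with expectations frozen from an
# independent brute-force script run before the build
filter_fixture <- function() {
  cl <- data.frame(
    chrom = "chr1",
    start = c(0, 2000, 4000, 6000, 8000, 8500, 10000, 12000, 14000,
              16000, 16500, 18000),
    end = c(1000, 3000, 5000, 7000, 9000, 9500, 11000, 13000, 15000,
            17000, 17500, 19000),
    name = sprintf("c%02d", 1:12), score = 0,
    strand = c("+", "+", "-", "-", "*", "+", "*", "+", "-", "*", "+",
               "+"),
    stringsAsFactors = FALSE)
  repeats <- data.frame(
    chrom = "chr1",
    start = c(0, 2000, 14000, 14300, 16500),
    end = c(800, 2850, 14500, 14700, 17400),
    name = sprintf("r%d", 1:5), score = 0, strand = "+",
    stringsAsFactors = FALSE)
  tevs <- data.frame(chrom = "chr1", start = 12000, end = 13000,
                     name = "t1", score = 0, strand = "+",
                     stringsAsFactors = FALSE)
  counts <- matrix(rep(c(50L, 60L, 70L), each = 12), nrow = 12,
                   dimnames = list(cl$name, c("sA", "sB", "sC")))
  counts["c03", ] <- c(4L, 9L, 3L)
  counts["c04", ] <- c(4L, 10L, 3L)
  merged <- structure(list(
    clusters = cl,
    provenance = data.frame(strain = character(), sample_id = character(),
                            source_name = character(),
                            cluster_id = character()),
    filter_log = data.frame(name = character(), reason = character(),
                            stringsAsFactors = FALSE)),
    class = "merged_cluster_set")
  list(merged = merged, repeats = repeats, tevs = tevs, counts = counts,
       expected_survivors = c("c01", "c04", "c06", "c07", "c09", "c10",
                              "c12"),
       expected_log = c(c02 = "repeat_overlap", c08 = "repeat_overlap",
                        c11 = "repeat_overlap", c05 = "bi_over_mono",
                        c03 = "low_count"))
}

# independent two-sided Fisher oracle by explicit binomial-coefficient
# enumeration over all tables with the observed margins
bf_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  if (r1 == 0 || r1 == N || c1 == 0 || c1 == N) return(1)
  lo <- max(0, r1 + c1 - N); hi <- min(r1, c1)
  lp <- vapply(lo:hi, function(x)
    lchoose(r1, x) + lchoose(N - r1, c1 - x) - lchoose(N, c1),
    numeric(1))
  p <- exp(lp)
  p_obs <- p[a - lo + 1]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}
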