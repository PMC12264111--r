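# Splicing diagnostics (splicing efficiency at splice-site windows,
# relative intron expression) and genetic-vs-expression distance trees
# (UPGMA, Robinson-Foulds, Adjusted Rand Index).

#' Splice-site windows from intron coordinates
#'
#' Each intron yields a donor and an acceptor window spanning 7 bp into
#' the exon and 7 bp into the intron (14 bp total) around each intron
#' boundary.
#'
#' @param introns interval `data.frame` (0-based half-open), `name` used
#'   as junction id
#' @param pad bp on each side of the boundary (window width = 2 * pad)
#' @return `data.frame` of windows with junction_id and side
#' @export
splice_site_windows <- function(introns, pad = 7L) {
  donor <- data.frame(chrom = introns$chrom,
                      start = introns$start - pad,
                      end = introns$start + pad,
                      name = paste0(introns$name, "_donor"),
                      score = 0, strand = introns$strand,
                      junction_id = introns$name, side = "donor",
                      stringsAsFactors = FALSE)
  acceptor <- data.frame(chrom = introns$chrom,
                         start = introns$end - pad,
                         end = introns$end + pad,
                         name = paste0(introns$name, "_acceptor"),
                         score = 0, strand = introns$strand,
                         junction_id = introns$name, side = "acceptor",
                         stringsAsFactors = FALSE)
  rbind(donor, acceptor)
}

#' Splicing efficiency from split and unsplit junction reads
#'
#' A read is assigned to a splice-site window iff the overlap covers at
#' least `min_frac` of the window (>= 7 of 14 bp by default, the
#' `bedtools intersect -f 0.5` rule applied to the window side). Donor and
#' acceptor windows of a junction are pooled; efficiency is
#' `split / (split + unsplit)`, undefined (NA, flagged) when no read is
#' assigned.
#'
#' @param junction_reads `data.frame` with chrom, start, end and a `split`
#'   column (1 = gapped/split alignment, 0 = unsplit)
#' @param windows splice-site windows from [splice_site_windows()]
#' @param min_frac minimum assigned fraction of the window
#' @return `data.frame` with junction_id, n_split, n_unsplit, efficiency,
#'   undefined
#' @export
splicing_efficiency <- function(junction_reads, windows, min_frac = 0.5) {
  width <- windows$end - windows$start
  need <- ceiling(min_frac * width)
  jr <- junction_reads
  res <- lapply(split(seq_len(nrow(windows)), windows$junction_id),
                function(widx) {
    ns <- 0L; nu <- 0L
    for (w in widx) {
      ov <- pmin(jr$end, windows$end[w]) - pmax(jr$start, windows$start[w])
      hit <- jr$chrom == windows$chrom[w] & ov >= need[w]
      ns <- ns + sum(jr$split[hit] == 1)
      nu <- nu + sum(jr$split[hit] == 0)
    }
    c(ns, nu)
  })
  jid <- names(res)
  ns <- vapply(res, `[`, 0, 1); nu <- vapply(res, `[`, 0, 2)
  tot <- ns + nu
  data.frame(junction_id = jid, n_split = ns, n_unsplit = nu,
             efficiency = ifelse(tot > 0, ns / tot, NA_real_),
             undefined = tot == 0, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Relative intron expression
#'
#' Mean coverage in the intron divided by the mean of the two surrounding
#' exons' mean coverages; the standard intron-retention diagnostic.
#'
#' @param intron_cov mean per-base coverage in the intron
#' @param exon_cov_left,exon_cov_right mean coverages of the flanking exons
#' @return the ratio; NA (flagged via attribute) when exon coverage is 0
#' @export
relative_intron_expression <- function(intron_cov, exon_cov_left,
                                       exon_cov_right) {
  exon_mean <- mean(c(exon_cov_left, exon_cov_right))
  if (exon_mean <= 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  intron_cov / exon_mean
}

#' UPGMA distance tree from a per-strain feature table
#'
#' Computes pairwise Euclidean distances between the rows of `features`
#' (strains x features: 0/1 SNP genotypes or transformed expression
#' values) and builds a UPGMA tree by average-linkage agglomeration with
#' deterministic lowest-label tie-breaking.
#'
#' @param features numeric matrix with strain row names
#' @param method distance tree method; only `"euclidean+UPGMA"`
#' @return object of class `distance_tree`: list with `phylo` (ape tree),
#'   `hclust`, `dist` (matrix) and `degenerate` flag (all-zero distances)
#' @export
build_distance_tree <- function(features, method = "euclidean+UPGMA") {
  stopifnot(method == "euclidean+UPGMA")
  if (nrow(features) < 3)
    stop("need >= 3 strains for an informative topology")
  d <- as.matrix(stats::dist(features, method = "euclidean"))
  hc <- upgma_hclust(d)
  structure(list(phylo = ape::as.phylo(hc), hclust = hc, dist = d,
                 labels = rownames(features),
                 degenerate = all(d == 0)),
            class = "distance_tree")
}

# UPGMA with explicit lowest-label-first tie-break, returning an hclust
upgma_hclust <- function(dmat) {
  n <- nrow(dmat)
  labs <- rownames(dmat)
  if (is.null(labs)) labs <- as.character(seq_len(n))
  active <- as.list(seq_len(n))       # leaf sets per active node
  node_id <- -seq_len(n)              # hclust convention: leaves negative
  heights <- numeric(n - 1)
  merge <- matrix(0L, n - 1, 2)
  D <- dmat
  sizes <- rep(1L, n)
  for (step in seq_len(n - 1)) {
    k <- length(active)
    best <- c(NA, NA); bd <- Inf
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (D[i, j] < bd - 1e-12) { bd <- D[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort(c(node_id[[i]], node_id[[j]]))
    heights[step] <- bd  # hclust convention: raw merge distance
    # average linkage update
    newd <- (D[i, ] * sizes[i] + D[j, ] * sizes[j]) / (sizes[i] + sizes[j])
    keep <- setdiff(seq_len(k), c(i, j))
    D2 <- matrix(0, length(keep) + 1, length(keep) + 1)
    if (length(keep)) {
      D2[seq_along(keep), seq_along(keep)] <- D[keep, keep, drop = FALSE]
      D2[length(keep) + 1, seq_along(keep)] <- newd[keep]
      D2[seq_along(keep), length(keep) + 1] <- newd[keep]
    }
    D <- D2
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
    node_id <- c(node_id[keep], step)
    active <- c(active[keep], list(c(active[[i]], active[[j]])))
  }
  # hclust merge rows must reference prior rows with positive sign
  structure(list(merge = merge, height = heights,
                 order = order_leaves(merge, n), labels = labs,
                 method = "average", call = match.call(),
                 dist.method = "euclidean"),
            class = "hclust")
}

order_leaves <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(nrow(merge))
}

# non-trivial bipartitions of an unrooted tree as canonical strings
.bipartitions <- function(phy) {
  phy <- ape::unroot(phy)
  tips <- phy$tip.label
  n <- length(tips)
  edge <- phy$edge
  out <- character(0)
  for (e in seq_len(nrow(edge))) {
    child <- edge[e, 2]
    if (child <= n) next  # pendant edge: trivial split
    desc <- ape::extract.clade(phy, child)$tip.label
    side <- sort(desc)
    other <- sort(setdiff(tips, desc))
    if (length(side) < 2 || length(other) < 2) next
    canon <- if (tips[1] %in% side) other else side
    out <- c(out, paste(canon, collapse = "|"))
  }
  unique(out)
}

#' Compare two distance trees
#'
#' Robinson-Foulds distance: size of the symmetric difference of the sets
#' of non-trivial bipartitions of the two unrooted topologies. Adjusted
#' Rand Index: computed on the flat clusterings obtained by cutting each
#' tree into `k` groups (default 2).
#'
#' @param t1,t2 `distance_tree` objects (or ape `phylo` trees for the RF
#'   part alone)
#' @param k number of groups for the ARI cut
#' @return list with rf_distance and ari (NA if inputs lack hclust)
#' @export
compare_trees <- function(t1, t2, k = 2L) {
  p1 <- if (inherits(t1, "distance_tree")) t1$phylo else t1
  p2 <- if (inherits(t2, "distance_tree")) t2$phylo else t2
  if (!setequal(p1$tip.label, p2$tip.label))
    stop("trees have different leaf sets")
  b1 <- .bipartitions(p1); b2 <- .bipartitions(p2)
  rf <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  ari <- NA_real_
  if (inherits(t1, "distance_tree") && inherits(t2, "distance_tree")) {
    c1 <- cutree(t1$hclust, k = k)
    c2 <- cutree(t2$hclust, k = k)
    ari <- adjusted_rand_index(c1[t1$labels], c2[t1$labels])
  }
  list(rf_distance = rf, ari = ari)
}

#' Adjusted Rand Index between two flat partitions
#'
#' @param c1,c2 cluster label vectors over the same items
#' @return ARI in \[-1, 1\]; 1 for identical partitions
#' @export
adjusted_rand_index <- function(c1, c2) {
  stopifnot(length(c1) == length(c2))
  tab <- table(c1, c2)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
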