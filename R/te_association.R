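# Association of polymorphic transposable-element variants (TEVs) with
# differential piRNA-cluster expression: TE classification, 5-kb proximity
# annotation (strand-aware), exact tests implemented from first principles,
# and the end-to-end association driver.

TE_CLASSES <- c("SINE", "LINE", "ERV", "IAP")

#' Classify raw TE variant annotations into SINE / LINE / ERV / IAP
#'
#' SINE iff annotated SINE; LINE iff annotated LINE or a LINE fragment;
#' everything else is an ERV; additionally IAP iff annotated IAP-I. IAP
#' records remain ERVs for ERV-level queries, so an IAP-I element counts
#' under both the ERV and IAP classes.
#'
#' @param tevs `data.frame` with interval columns plus `raw_annotation`,
#'   `strand`, and `present_in` (comma-separated strain labels)
#' @return the input with list column `classes` and character column
#'   `te_class` (the most specific class)
#' @export
classify_tevs <- function(tevs) {
  ann <- tevs$raw_annotation
  if (any(is.na(ann) | !nzchar(ann))) stop("empty TE annotation")
  classes <- lapply(ann, function(a) {
    if (grepl("SINE", a, ignore.case = TRUE)) return("SINE")
    if (grepl("LINE", a, ignore.case = TRUE)) return("LINE")
    if (grepl("IAP-I", a, fixed = TRUE)) return(c("ERV", "IAP"))
    "ERV"
  })
  tevs$classes <- I(classes)
  tevs$te_class <- vapply(classes, function(x) x[length(x)], "")
  if (is.character(tevs$present_in))
    tevs$present_in <- I(strsplit(tevs$present_in, ","))
  if (any(lengths(tevs$present_in) == 0))
    stop("present_in must be non-empty")
  tevs
}

#' Cluster / TEV proximity by class, strand mode and strain
#'
#' A cluster is TEV-positive for a class and strain iff some TEV of that
#' class carried by the strain lies within `window` bp (edge-to-edge gap;
#' overlap counts as gap 0). Under `sense` / `antisense` modes the TEV
#' strand must equal / oppose the cluster's assigned strand, and
#' bi-directional clusters (strand `*`) are excluded from the table.
#'
#' @param clusters cluster `data.frame` with assigned strand
#' @param tevs classified TEVs (see [classify_tevs()])
#' @param window proximity window (bp)
#' @param strains strain labels to tabulate; default: all strains seen in
#'   `present_in`
#' @return `data.frame` with cluster_id, te_class, strand_mode, strain,
#'   tev_positive
#' @export
annotate_cluster_tev_proximity <- function(clusters, tevs, window = 5000L,
                                           strains = NULL) {
  if (is.null(tevs$classes)) tevs <- classify_tevs(tevs)
  if (is.null(strains))
    strains <- sort(unique(unlist(tevs$present_in)))
  out <- list()
  prox <- interval_overlap(clusters, tevs, max_gap = window)
  for (mode in c("any", "sense", "antisense")) {
    cl_keep <- if (mode == "any") seq_len(nrow(clusters))
               else which(clusters$strand %in% c("+", "-"))
    for (cls in TE_CLASSES) {
      tev_has <- vapply(tevs$classes, function(x) cls %in% x, logical(1))
      for (st in strains) {
        carried <- vapply(tevs$present_in, function(x) st %in% x,
                          logical(1))
        ok_t <- tev_has & carried
        pr <- prox[ok_t[prox$b_idx], , drop = FALSE]
        if (mode != "any") {
          same <- clusters$strand[pr$a_idx] == tevs$strand[pr$b_idx]
          pr <- pr[if (mode == "sense") same else !same, , drop = FALSE]
        }
        pos <- seq_len(nrow(clusters)) %in% pr$a_idx
        out[[length(out) + 1L]] <- data.frame(
          cluster_id = clusters$name[cl_keep],
          te_class = cls, strand_mode = mode, strain = st,
          tev_positive = pos[cl_keep], stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' With margins fixed, the two-sided p value is the sum of hypergeometric
#' probabilities of all tables whose probability does not exceed that of
#' the observed table (minimum-likelihood definition). The odds ratio is
#' the sample `(a d) / (b c)`; a zero row or column margin yields p = 1
#' and an undefined odds ratio.
#'
#' @param a,b,c,d the 2x2 cell counts (a = DE & TEV-positive etc.)
#' @return list with odds_ratio (possibly NA or Inf), p, undefined flag
#' @export
fisher_exact_test <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, a + b + c + d > 0)
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  if (r1 == 0 || r1 == N || c1 == 0 || c1 == N)
    return(list(odds_ratio = NA_real_, p = 1, undefined = TRUE))
  lo <- max(0, r1 + c1 - N); hi <- min(r1, c1)
  x <- lo:hi
  probs <- dhyper(x, c1, N - c1, r1)
  p_obs <- dhyper(a, c1, N - c1, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- if (b * c == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else (a * d) / (b * c)
  list(odds_ratio = or, p = min(1, p), undefined = FALSE)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Uses the exact permutation distribution of the rank sum (with midranks
#' for ties) when `length(x) + length(y) <= exact_limit`, enumerating all
#' group assignments; otherwise the normal approximation with tie
#' correction and continuity correction. Two-sided p is twice the smaller
#' tail, capped at 1.
#'
#' @param x,y numeric samples
#' @param exact_limit maximum combined size for exact enumeration
#' @return two-sided p value
#' @export
wilcoxon_rank_sum <- function(x, y, exact_limit = 20L) {
  m <- length(x); n <- length(y)
  stopifnot(m >= 1, n >= 1)
  all_v <- c(x, y)
  if (length(unique(all_v)) == 1) return(1)
  r <- rank(all_v)
  w_obs <- sum(r[seq_len(m)])
  if (m + n <= exact_limit) {
    combs <- combn(m + n, m)
    ws <- colSums(matrix(r[combs], nrow = m))
    eps <- 1e-9
    p_lo <- mean(ws <= w_obs + eps)
    p_hi <- mean(ws >= w_obs - eps)
    return(min(1, 2 * min(p_lo, p_hi)))
  }
  N <- m + n
  mu <- m * (N + 1) / 2
  ties <- table(all_v)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- m * n / 12 * ((N + 1) - tie_term)
  z <- (w_obs - mu - sign(w_obs - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' End-to-end TEV / differential-expression association
#'
#' Builds, per TE class and strand mode, the 2x2 table of clusters
#' cross-classified by differential-expression status (significant in at
#' least `de_min_comparisons` pairwise comparisons) and TEV proximity
#' (positive in at least one strain for that class/mode), applying the
#' Fisher exact test. For the strain pair `pair = c(A, B)`, also computes
#' per-cluster log2 fold changes of mean normalized counts and compares
#' the `tev_only_in_A` and `tev_only_in_B` groups per class with the
#' Wilcoxon rank-sum test.
#'
#' @param clusters merged cluster `data.frame`
#' @param de_summary result of [summarize_de()]
#' @param tevs classified TEV table
#' @param counts count matrix (for fold-change groups)
#' @param samples sample table
#' @param pair character vector of two strains for the fold-change part;
#'   `NULL` skips it
#' @param window proximity window (bp)
#' @param de_min_comparisons minimum significant comparisons to call a
#'   cluster differentially expressed
#' @return list with `association` (class x mode Fisher table) and
#'   `fold_change_groups` (per-cluster groups and per-class Wilcoxon p)
#' @export
run_te_association <- function(clusters, de_summary, tevs, counts = NULL,
                               samples = NULL, pair = NULL,
                               window = 5000L, de_min_comparisons = 1L) {
  if (is.null(tevs$classes)) tevs <- classify_tevs(tevs)
  prox <- annotate_cluster_tev_proximity(clusters, tevs, window = window)
  de_tab <- de_summary$per_cluster
  de_pos <- de_tab$cluster_id[de_tab$n_significant >= de_min_comparisons]

  assoc <- list()
  for (mode in c("any", "sense", "antisense")) {
    for (cls in TE_CLASSES) {
      sub <- prox[prox$strand_mode == mode & prox$te_class == cls, ,
                  drop = FALSE]
      if (!nrow(sub)) next
      pos_any <- tapply(sub$tev_positive, sub$cluster_id, any)
      elig <- names(pos_any)
      is_de <- elig %in% de_pos
      is_pos <- as.logical(pos_any)
      a <- sum(is_de & is_pos); b <- sum(is_de & !is_pos)
      cc <- sum(!is_de & is_pos); d <- sum(!is_de & !is_pos)
      ft <- fisher_exact_test(a, b, cc, d)
      assoc[[length(assoc) + 1L]] <- data.frame(
        te_class = cls, strand_mode = mode, a = a, b = b, c = cc, d = d,
        odds_ratio = ft$odds_ratio, p = ft$p, stringsAsFactors = FALSE)
    }
  }
  assoc <- do.call(rbind, assoc)

  fc <- NULL
  if (!is.null(pair)) {
    stopifnot(length(pair) == 2, !is.null(counts), !is.null(samples))
    f <- size_factors(counts)
    norm <- sweep(counts, 2, f[colnames(counts)], "/")
    sa <- samples$sample_id[samples$strain == pair[1]]
    sb <- samples$sample_id[samples$strain == pair[2]]
    ma <- rowMeans(norm[, sa, drop = FALSE])
    mb <- rowMeans(norm[, sb, drop = FALSE])
    l2fc <- log2((ma + 0.5) / (mb + 0.5))  # positive = higher in A
    groups <- list()
    for (cls in TE_CLASSES) {
      sub <- prox[prox$strand_mode == "any" & prox$te_class == cls, ,
                  drop = FALSE]
      pos_a <- sub$cluster_id[sub$strain == pair[1] & sub$tev_positive]
      pos_b <- sub$cluster_id[sub$strain == pair[2] & sub$tev_positive]
      grp <- rep("no_tev", nrow(clusters))
      names(grp) <- clusters$name
      grp[names(grp) %in% setdiff(pos_a, pos_b)] <- "tev_only_in_A"
      grp[names(grp) %in% setdiff(pos_b, pos_a)] <- "tev_only_in_B"
      grp[names(grp) %in% intersect(pos_a, pos_b)] <- "tev_in_both"
      ga <- l2fc[names(grp)[grp == "tev_only_in_A"]]
      gb <- l2fc[names(grp)[grp == "tev_only_in_B"]]
      wp <- if (length(ga) >= 1 && length(gb) >= 1)
        wilcoxon_rank_sum(ga, gb) else {
          warning("empty TEV group for class ", cls, "; Wilcoxon skipped")
          NA_real_
        }
      groups[[cls]] <- list(
        table = data.frame(cluster_id = names(grp), log2fc = l2fc[names(grp)],
                           group = unname(grp), stringsAsFactors = FALSE),
        wilcoxon_p = wp,
        mean_log2fc_only_A = if (length(ga)) mean(ga) else NA_real_,
        mean_log2fc_only_B = if (length(gb)) mean(gb) else NA_real_)
    }
    fc <- groups
  }
  list(association = assoc, fold_change_groups = fc)
}
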