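# Normalization, transformation and the strain-effect statistics:
# median-of-ratios size factors, log2 stabilizing transform, pairwise
# negative-binomial differential expression (moment dispersion, Wald test),
# per-cluster strain variance decomposition, and the global mixed model.

#' Median-of-ratios size factors
#'
#' For each sample j, the factor is the median over clusters (restricted to
#' rows positive in all samples) of `counts[i, j] / geomean_i`, where
#' `geomean_i` is the row geometric mean. Factors are rescaled to geometric
#' mean 1 so normalized totals stay on the scale of the input counts.
#'
#' @param counts cluster x sample count matrix
#' @return named positive numeric vector of size factors, one per sample
#' @export
size_factors <- function(counts) {
  validate_count_matrix(counts)
  if (ncol(counts) == 1) return(setNames(1, colnames(counts)))
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no cluster has nonzero counts in every sample; ",
         "consider total-count normalization")
  m <- counts[pos, , drop = FALSE]
  loggeo <- rowMeans(log(m))
  f <- apply(m, 2, function(cnt) exp(median(log(cnt) - loggeo)))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

#' Variance-stabilizing transform surrogate
#'
#' `log2(count / size_factor + 1)`, monotone in counts within each sample.
#'
#' @param counts count matrix
#' @param factors size factors as from [size_factors()]
#' @return numeric matrix of transformed expression values
#' @export
transform_counts <- function(counts, factors = size_factors(counts)) {
  stopifnot(all(factors > 0))
  sweep_f <- matrix(factors[colnames(counts)], nrow = nrow(counts),
                    ncol = ncol(counts), byrow = TRUE)
  log2(counts / sweep_f + 1)
}

# pooled method-of-moments NB dispersion for one cluster:
# Var = mu + alpha mu^2, within-group moments, floored
.moment_dispersion <- function(norm_counts, group, floor = 0.01) {
  num <- 0; den <- 0
  for (g in unique(group)) {
    x <- norm_counts[group == g]
    if (length(x) < 2) next
    mu <- mean(x)
    if (mu <= 0) next
    num <- num + (var(x) - mu) * (length(x) - 1)
    den <- den + mu^2 * (length(x) - 1)
  }
  if (den <= 0) return(floor)
  max(floor, num / den)
}

#' Pairwise differential expression between two strains
#'
#' Per cluster, counts are normalized by size factors (computed on the two
#' groups' samples), a negative-binomial dispersion is estimated by pooled
#' method of moments with a floor of 0.01, and a Wald test is applied to
#' the log2 fold change of group means (delta-method standard error under
#' Var = mu + alpha mu^2). P values are BH-adjusted within the comparison.
#' A cluster is significant iff `|log2fc| > lfc_threshold` and
#' `padj < fdr`.
#'
#' @param counts count matrix (clusters pre-filtered for low counts)
#' @param samples sample table with sample_id and strain
#' @param strain_a,strain_b the two strains compared; log2fc is
#'   `log2(mean_b / mean_a)`
#' @param tissue optional tissue restriction
#' @param lfc_threshold absolute log2 fold-change threshold
#' @param fdr adjusted-p threshold
#' @return `data.frame` with cluster_id, strain_a, strain_b, base_mean,
#'   log2fc, p, padj, significant
#' @export
pairwise_de <- function(counts, samples, strain_a, strain_b,
                        tissue = NULL, lfc_threshold = 1, fdr = 0.05) {
  s <- samples
  if (!is.null(tissue)) s <- s[s$tissue == tissue, , drop = FALSE]
  sa <- s$sample_id[s$strain == strain_a]
  sb <- s$sample_id[s$strain == strain_b]
  if (length(sa) < 2 || length(sb) < 2)
    stop("need >= 2 samples per strain (", strain_a, ": ", length(sa),
         ", ", strain_b, ": ", length(sb), ")")
  sub <- counts[, c(sa, sb), drop = FALSE]
  f <- size_factors(sub)
  norm <- sweep(sub, 2, f, "/")
  group <- c(rep("a", length(sa)), rep("b", length(sb)))
  na <- length(sa); nb <- length(sb)

  res <- lapply(seq_len(nrow(norm)), function(i) {
    x <- norm[i, ]
    ma <- mean(x[group == "a"]); mb <- mean(x[group == "b"])
    alpha <- .moment_dispersion(x, group)
    # pseudocount guards the log at zero means
    l2fc <- log2((mb + 0.5) / (ma + 0.5))
    va <- ma + alpha * ma^2
    vb <- mb + alpha * mb^2
    se2 <- va / (na * (ma + 0.5)^2) + vb / (nb * (mb + 0.5)^2)
    se <- sqrt(se2) / log(2)
    p <- if (se == 0) 1 else 2 * pnorm(-abs(l2fc) / se)
    c(base_mean = mean(x), log2fc = l2fc, p = p)
  })
  res <- as.data.frame(do.call(rbind, res))
  out <- data.frame(cluster_id = rownames(counts),
                    strain_a = strain_a, strain_b = strain_b,
                    base_mean = res$base_mean, log2fc = res$log2fc,
                    p = res$p, stringsAsFactors = FALSE)
  out$padj <- adjust_bh(out$p)
  out$significant <- abs(out$log2fc) > lfc_threshold & out$padj < fdr
  out
}

#' Run all pairwise strain comparisons
#'
#' Enumerates all strain pairs within each tissue present in `samples`
#' (testis comparisons among its strains, spermatogonia among its strains),
#' mirroring "six pairwise comparisons between testis samples from four
#' strains and one pairwise comparison between spermatogonia samples from
#' two strains".
#'
#' @inheritParams pairwise_de
#' @return a `data.frame` of stacked [pairwise_de()] results with a
#'   `tissue` column
#' @export
all_pairwise_de <- function(counts, samples, lfc_threshold = 1,
                            fdr = 0.05) {
  out <- NULL
  for (tis in unique(samples$tissue)) {
    st <- sort(unique(samples$strain[samples$tissue == tis]))
    if (length(st) < 2) next
    for (pair in combn(st, 2, simplify = FALSE)) {
      de <- pairwise_de(counts, samples, pair[1], pair[2], tissue = tis,
                        lfc_threshold = lfc_threshold, fdr = fdr)
      de$tissue <- tis
      out <- rbind(out, de)
    }
  }
  out
}

#' Summarize significance across pairwise comparisons
#'
#' @param de_results stacked [pairwise_de()] results over comparisons
#' @return list with `per_cluster` (cluster_id, n_significant,
#'   n_comparisons), `de_any` (significant in >= 1 comparison) and
#'   `de_three_plus` (significant in >= 3)
#' @export
summarize_de <- function(de_results) {
  key <- paste(de_results$strain_a, de_results$strain_b,
               if (!is.null(de_results$tissue)) de_results$tissue else "")
  n_comp <- length(unique(key))
  agg <- tapply(de_results$significant, de_results$cluster_id, sum)
  per_cluster <- data.frame(cluster_id = names(agg),
                            n_significant = as.integer(agg),
                            n_comparisons = n_comp,
                            stringsAsFactors = FALSE)
  list(per_cluster = per_cluster,
       de_any = per_cluster$cluster_id[per_cluster$n_significant >= 1],
       de_three_plus =
         per_cluster$cluster_id[per_cluster$n_significant >= 3])
}

#' Per-cluster variance in expression explained by strain
#'
#' For each cluster, fits the one-way fixed-effect model
#' `expression ~ strain` and reports the adjusted R-squared, the F-test
#' p value and the BH-adjusted p value across clusters. Clusters with zero
#' total variance are flagged undefined with r2_adj = 0 and p = 1.
#'
#' @param expression transformed expression matrix (clusters x samples)
#' @param samples sample table; strains taken from `samples$strain`
#' @return `data.frame` with cluster_id, r2_adj, p, padj, undefined
#' @export
strain_variance_explained <- function(expression, samples) {
  strain <- factor(samples$strain[match(colnames(expression),
                                        samples$sample_id)])
  if (nlevels(strain) < 2) stop("need >= 2 strains")
  res <- lapply(seq_len(nrow(expression)), function(i) {
    y <- as.numeric(expression[i, ])
    if (var(y) == 0)
      return(c(r2_adj = 0, p = 1, undefined = 1))
    fit <- lm(y ~ strain)
    sm <- summary(fit)
    fstat <- sm$fstatistic
    if (is.null(fstat) || fstat[3] == 0)
      return(c(r2_adj = sm$adj.r.squared, p = NA_real_, undefined = 1))
    p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
    c(r2_adj = sm$adj.r.squared, p = unname(p), undefined = 0)
  })
  res <- as.data.frame(do.call(rbind, res))
  out <- data.frame(cluster_id = rownames(expression),
                    r2_adj = res$r2_adj, p = res$p,
                    undefined = res$undefined == 1,
                    stringsAsFactors = FALSE)
  out$padj <- adjust_bh(ifelse(is.na(out$p), 1, out$p))
  out[, c("cluster_id", "r2_adj", "p", "padj", "undefined")]
}

#' Global strain effect across all clusters (mixed model)
#'
#' Fits `expression ~ strain + (1 | cluster)` by REML for the variance
#' components, and tests the strain effect by a likelihood-ratio test
#' between ML refits with and without the strain term.
#'
#' @param expression transformed expression matrix (clusters x samples)
#' @param samples sample table
#' @return list with strain_p, cluster_variance, residual_variance,
#'   strain_coefficients, singular
#' @export
global_strain_effect <- function(expression, samples) {
  strain <- samples$strain[match(colnames(expression), samples$sample_id)]
  if (length(unique(strain)) < 2) stop("need >= 2 strains")
  long <- data.frame(
    expr = as.numeric(expression),
    cluster = factor(rep(rownames(expression), times = ncol(expression))),
    strain = factor(rep(strain, each = nrow(expression))))
  if (nlevels(long$cluster) < 2) {
    # single cluster: the random intercept is void; use fixed-effect ANOVA
    fit <- lm(expr ~ strain, data = long)
    an <- anova(fit)
    return(list(strain_p = an[["Pr(>F)"]][1], cluster_variance = 0,
                residual_variance = an[["Mean Sq"]][2],
                strain_coefficients = stats::coef(fit), singular = TRUE))
  }
  reml <- lme4::lmer(expr ~ strain + (1 | cluster), data = long, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(reml))
  cluster_var <- vc$vcov[vc$grp == "cluster"]
  resid_var <- vc$vcov[vc$grp == "Residual"]
  full <- lme4::lmer(expr ~ strain + (1 | cluster), data = long,
                     REML = FALSE)
  null <- lme4::lmer(expr ~ 1 + (1 | cluster), data = long, REML = FALSE)
  lrt <- anova(null, full)
  list(strain_p = lrt[["Pr(>Chisq)"]][2],
       cluster_variance = cluster_var,
       residual_variance = resid_var,
       strain_coefficients = lme4::fixef(reml),
       singular = lme4::isSingular(reml))
}

#' Benjamini-Hochberg adjusted p values
#'
#' Standard step-up procedure: sort ascending, `q_(i) = min_{j >= i}
#' p_(j) * m / j`, capped at 1, returned in input order.
#'
#' @param p numeric vector of p values in \[0, 1\]
#' @return adjusted p values in input order
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}
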