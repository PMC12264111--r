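test_that("size factors follow median-of-ratios with geomean rescale", {
  m1 <- matrix(c(5L, 9L, 20L), 3, 1, dimnames = list(NULL, "s1"))
  expect_equal(unname(size_factors(m1)), 1)
  m2 <- cbind(s1 = c(10L, 20L, 40L), s2 = c(20L, 40L, 80L))
  rownames(m2) <- sprintf("c%d", 1:3)
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)))
  m3 <- cbind(s1 = c(10L, 30L), s2 = c(10L, 30L), s3 = c(10L, 30L))
  rownames(m3) <- c("c1", "c2")
  expect_equal(unname(size_factors(m3)), c(1, 1, 1))
  # invariant under row permutation
  set.seed(1)
  m4 <- matrix(rnbinom(60, mu = 50, size = 10) + 1L, 20, 3,
               dimnames = list(sprintf("c%d", 1:20), c("a", "b", "c")))
  expect_equal(size_factors(m4), size_factors(m4[sample(20), ]))
  m5 <- cbind(s1 = c(0L, 5L), s2 = c(5L, 0L))
  rownames(m5) <- c("c1", "c2")
  expect_error(size_factors(m5), "total-count")
})

test_that("transform_counts is log2(normalized + 1) and monotone", {
  m <- cbind(s1 = c(0L, 7L, 14L))
  rownames(m) <- sprintf("c%d", 1:3)
  tr <- transform_counts(m, c(s1 = 1))
  expect_equal(unname(tr[, 1]), c(0, 3, log2(15)))
  expect_true(all(diff(tr[, 1]) > 0))
})

test_that("pairwise_de handles the null cluster and is antisymmetric", {
  set.seed(5)
  counts <- matrix(rnbinom(200 * 6, mu = 300, size = 20), 200, 6,
                   dimnames = list(sprintf("c%d", 1:200),
                                   sprintf("s%d", 1:6)))
  counts["c1", ] <- 250L  # identical in both strains
  samples <- data.frame(sample_id = sprintf("s%d", 1:6),
                        strain = rep(c("A", "B"), each = 3),
                        tissue = "testis", batch = "b1")
  de_ab <- pairwise_de(counts, samples, "A", "B")
  de_ba <- pairwise_de(counts, samples, "B", "A")
  expect_equal(de_ab$log2fc, -de_ba$log2fc)
  # identical counts in both strains: log2fc ~ 0 (exactly 0 when size
  # factors are equal; here factors differ slightly through the other
  # clusters) and never significant
  r1 <- de_ab[de_ab$cluster_id == "c1", ]
  expect_equal(r1$log2fc, 0, tolerance = 0.05)
  expect_false(r1$significant)
  # fully symmetric matrix: exact zero
  eq <- matrix(rep(c(100L, 220L, 87L, 430L), 6), 4, 6,
               dimnames = list(sprintf("e%d", 1:4), sprintf("s%d", 1:6)))
  de_eq <- pairwise_de(eq, samples, "A", "B")
  expect_equal(de_eq$log2fc, rep(0, 4))
  expect_false(any(de_eq$significant))
  expect_true(all(de_ab$padj >= de_ab$p - 1e-12))
  expect_error(pairwise_de(counts, samples[-(1:2), ], "A", "B"), ">= 2")
})

test_that("pairwise_de detects a planted 4-fold change", {
  set.seed(6)
  mu <- matrix(500, 50, 6)
  mu[1:10, 4:6] <- 2000  # |log2fc| = 2 in strain B
  counts <- matrix(rnbinom(300, mu = mu, size = 20), 50, 6,
                   dimnames = list(sprintf("c%d", 1:50),
                                   sprintf("s%d", 1:6)))
  samples <- data.frame(sample_id = sprintf("s%d", 1:6),
                        strain = rep(c("A", "B"), each = 3),
                        tissue = "testis", batch = "b1")
  de <- pairwise_de(counts, samples, "A", "B")
  expect_gte(mean(de$significant[1:10]), 0.9)
  expect_lte(mean(de$significant[11:50]), 0.1)
})

test_that("summarize_de counts comparisons and builds membership sets", {
  de <- do.call(rbind, lapply(1:6, function(k)
    data.frame(cluster_id = c("x", "y"),
               strain_a = "A", strain_b = sprintf("B%d", k),
               tissue = "testis", log2fc = 0, p = 1, padj = 1,
               significant = c(k %in% c(1, 2, 4), FALSE))))
  s <- summarize_de(de)
  expect_equal(s$per_cluster$n_comparisons, c(6L, 6L))
  expect_equal(s$per_cluster$n_significant[s$per_cluster$cluster_id ==
                                             "x"], 3L)
  expect_true("x" %in% s$de_any && "x" %in% s$de_three_plus)
  expect_false("y" %in% s$de_any)
})

test_that("four testis strains give exactly six pairwise comparisons", {
  set.seed(8)
  counts <- matrix(rnbinom(30 * 8, mu = 200, size = 20), 30, 8,
                   dimnames = list(sprintf("c%d", 1:30),
                                   sprintf("s%d", 1:8)))
  samples <- data.frame(sample_id = sprintf("s%d", 1:8),
                        strain = rep(c("BL6", "NOD", "C3H", "129"),
                                     each = 2),
                        tissue = "testis", batch = "b1")
  de <- all_pairwise_de(counts, samples)
  expect_equal(length(unique(paste(de$strain_a, de$strain_b))), 6)
  expect_equal(nrow(de), 6 * 30)
})

test_that("strain_variance_explained matches the one-way ANOVA facts", {
  expr <- rbind(perfect = c(0, 0, 10, 10),
                flat = c(5, 5, 5, 5),
                noisy = c(1, 2, 9.5, 10.5))
  colnames(expr) <- sprintf("s%d", 1:4)
  samples <- data.frame(sample_id = sprintf("s%d", 1:4),
                        strain = rep(c("A", "B"), each = 2),
                        tissue = "testis", batch = "b1")
  v <- strain_variance_explained(expr, samples)
  expect_equal(v$r2_adj[1], 1)
  expect_lt(v$p[1], 0.05)
  expect_equal(v$r2_adj[2], 0)
  expect_true(v$undefined[2])
  expect_false(v$undefined[3])
})

test_that("strain_variance_explained p is null-uniform", {
  set.seed(13)
  n <- 12
  samples <- data.frame(sample_id = sprintf("s%d", 1:n),
                        strain = rep(c("A", "B", "C"), each = 4),
                        tissue = "testis", batch = "b1")
  expr <- matrix(rnorm(400 * n), 400, n,
                 dimnames = list(sprintf("c%d", 1:400),
                                 samples$sample_id))
  v <- strain_variance_explained(expr, samples)
  ks <- stats::ks.test(v$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("global strain model detects shifts and degrades to ANOVA", {
  set.seed(14)
  samples <- data.frame(sample_id = sprintf("s%d", 1:6),
                        strain = rep(c("A", "B"), each = 3),
                        tissue = "testis", batch = "b1")
  base <- matrix(rnorm(20 * 6, sd = 0.5), 20, 6,
                 dimnames = list(sprintf("c%d", 1:20),
                                 samples$sample_id))
  shifted <- base + rep(c(0, 0, 0, 2, 2, 2), each = 20)
  g <- global_strain_effect(shifted + rnorm(20) * 0, samples)
  expect_lt(g$strain_p, 0.01)
  expect_gte(g$cluster_variance, 0)
  expect_gt(g$residual_variance, 0)
  # single cluster degenerates to the fixed-effect ANOVA p
  one <- base[1, , drop = FALSE]
  g1 <- global_strain_effect(one, samples)
  v1 <- strain_variance_explained(one, samples)
  expect_equal(g1$strain_p, v1$p[1], tolerance = 1e-8)
})

test_that("adjust_bh reproduces the step-up procedure", {
  expect_equal(adjust_bh(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(15)
  for (k in 1:25) {
    p <- runif(sample(1:50, 1))
    expect_equal(adjust_bh(p), p.adjust(p, "BH"))
  }
})
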