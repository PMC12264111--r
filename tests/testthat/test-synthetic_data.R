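test_that("sim_config validates overrides", {
  cfg <- sim_config(seed = 2, n_clusters = 10L)
  expect_equal(cfg$n_clusters, 10L)
  expect_error(sim_config(seed = 2, not_a_field = 1), "unknown config")
})

test_that("simulation is deterministic given config and seed", {
  a <- simulate_inbred_experiment(sim_config(seed = 5, n_clusters = 8L))
  b <- simulate_inbred_experiment(sim_config(seed = 5, n_clusters = 8L))
  expect_identical(a, b)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(a, d1); write_simulation(b, d2)
  for (f in list.files(d1, recursive = TRUE))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  c2 <- simulate_inbred_experiment(sim_config(seed = 6, n_clusters = 8L))
  expect_false(identical(a$counts, c2$counts))
})

test_that("counting the emitted alignments reproduces the count matrix", {
  sim <- simulate_inbred_experiment(sim_config(seed = 7))
  m <- count_reads_in_clusters(sim$alignments, sim$clusters,
                               sample_ids = colnames(sim$counts))
  expect_identical(m[rownames(sim$counts), colnames(sim$counts)],
                   sim$counts)
})

test_that("infeasible configs error and ground truth is complete", {
  expect_error(simulate_inbred_experiment(
    sim_config(seed = 1, n_clusters = 10L, fraction_de_clusters = 1.5)),
    "more DE clusters")
  sim <- simulate_inbred_experiment(sim_config(seed = 8))
  expect_true(all(sim$truth$de$cluster_id %in% sim$clusters$name))
  expect_true(all(sim$truth$tev$tev_id %in% sim$tevs$name))
  expect_true(all(sim$truth$tev$near_cluster %in% sim$clusters$name))
})

test_that("sense TEV carriers show the planted fold change in counts", {
  sim <- simulate_inbred_experiment(
    sim_config(seed = 9, fraction_de_clusters = 0))
  tev <- sim$truth$tev[sim$truth$tev$sense, ]
  expect_gt(nrow(tev), 0)
  ratios <- vapply(seq_len(nrow(tev)), function(r) {
    carr <- strsplit(sim$tevs$present_in[sim$tevs$name == tev$tev_id[r]],
                     ",")[[1]]
    in_c <- sim$samples$sample_id[sim$samples$strain %in% carr]
    out_c <- setdiff(sim$samples$sample_id, in_c)
    mean(sim$counts[tev$near_cluster[r], in_c]) /
      mean(sim$counts[tev$near_cluster[r], out_c])
  }, numeric(1))
  expect_gt(mean(ratios), 3)
  expect_lt(mean(ratios), 5)
})

test_that("pedigree output satisfies the pedigree invariants", {
  sim <- simulate_outbred_pedigree_experiment(sim_config(seed = 10))
  ped <- validate_pedigree(sim$ped)  # errors on violation
  gen_of <- function(id) ped$generation[match(id, ped$individual_id)]
  for (col in c("sire_id", "dam_id")) {
    ok <- is.na(ped[[col]]) | gen_of(ped[[col]]) < ped$generation
    expect_true(all(ok))
  }
  expect_equal(length(unique(ped$pedigree_set)), 2)
  expect_true(all(colnames(sim$expression) %in% ped$individual_id))
})

test_that("simulated breeding values have covariance sigma_a^2 * A", {
  cfg <- sim_config(seed = 12, true_h2 = 0.8)
  sim <- simulate_outbred_pedigree_experiment(cfg)
  A <- sim$truth$A
  ids <- colnames(sim$expression)[1:20]
  As <- A[ids, ids]
  set.seed(13)
  L <- chol(A)
  n_rep <- 5000
  u <- matrix(rnorm(n_rep * nrow(A)), n_rep) %*% L * sqrt(0.8)
  colnames(u) <- rownames(A)
  emp <- crossprod(u[, ids]) / n_rep
  expect_lt(max(abs(emp - 0.8 * As)), 0.05)
})

test_that("strain maps convert identically or drop split regions", {
  cfg <- sim_config(seed = 14)
  sim <- simulate_inbred_experiment(cfg)
  sm <- simulate_strain_maps(cfg, clusters = sim$clusters)
  map1 <- sm$maps[[1]]
  # block lengths conserved implies interval lengths conserved
  res <- convert_intervals(sim$clusters, map1)
  if (nrow(res$converted))
    expect_equal(res$converted$end - res$converted$start,
                 sim$clusters$end[match(res$converted$name,
                                        sim$clusters$name)] -
                   sim$clusters$start[match(res$converted$name,
                                            sim$clusters$name)])
  # truth table tags exactly the convertible clusters
  t1 <- sm$truth[sm$truth$strain == names(sm$maps)[1], ]
  expect_setequal(t1$cluster_id[t1$convertible], res$converted$name)
  # identity map converts everything unchanged
  idmap <- data.frame(source_chrom = names(cfg$genome),
                      source_start = 0L,
                      source_end = as.integer(cfg$genome),
                      target_chrom = names(cfg$genome),
                      target_start = 0L, stringsAsFactors = FALSE)
  rid <- convert_intervals(sim$clusters, idmap)
  expect_equal(nrow(rid$dropped), 0)
  expect_equal(rid$converted$start, sim$clusters$start)
})

test_that("junction simulator hits its efficiency and decoys drop out", {
  cfg <- sim_config(seed = 15)
  cfg$junction <- list(n_junctions = 5L, true_efficiency = 1.0,
                       reads_per_junction = 50L)
  sim <- simulate_junction_reads(cfg)
  se <- splicing_efficiency(sim$reads, sim$windows)
  expect_true(all(se$efficiency == 1))
  cfg$junction$true_efficiency <- 0.7
  sim2 <- simulate_junction_reads(cfg, with_negative_controls = TRUE)
  se_with <- splicing_efficiency(sim2$reads, sim2$windows)
  se_wo <- splicing_efficiency(
    sim2$reads[!grepl("^n", sim2$reads$read_id), ], sim2$windows)
  expect_equal(se_with$efficiency, se_wo$efficiency)
})
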