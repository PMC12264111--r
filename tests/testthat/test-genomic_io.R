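test_that("BED6 reader maps fields and round-trips canonically", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tc1\t0\t+",
               "chr1\t300\t450\tc2\t0\t-",
               "chr2\t0\t50\tc3\t1.5\t*"), path)
  iv <- read_intervals(path, "BED6")
  expect_equal(iv$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(iv$start, c(100L, 300L, 0L))
  expect_equal(iv$end, c(200L, 450L, 50L))
  expect_equal(iv$strand, c("+", "-", "*"))
  out <- withr::local_tempfile(fileext = ".bed")
  write_intervals(iv, out, "BED6")
  expect_identical(readLines(out), readLines(path))
})

test_that("interval readers reject malformed input", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tc1\t0\t+", "chr1\t50"), path)
  expect_error(read_intervals(path, "BED6"), "line 2")
  writeLines("chr1\t100\t100\tc1\t0\t+", path)
  expect_error(read_intervals(path, "BED6"), "end <= start")
  expect_error(genomic_intervals("chr1", 10, 5), "end must exceed")
  expect_error(genomic_intervals("chr1", -1, 5), "start")
})

test_that("TEV-TSV round-trips with extra columns preserved", {
  tev <- data.frame(chrom = "chr1", start = 10L, end = 500L, name = "t1",
                    score = 0, strand = "+", raw_annotation = "IAP-I",
                    present_in = "BL6,NOD", stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_intervals(tev, path, "TEV-TSV")
  back <- read_intervals(path, "TEV-TSV")
  expect_equal(back$raw_annotation, "IAP-I")
  expect_equal(back$present_in, "BL6,NOD")
  expect_equal(back$start, 10L)
})

test_that("filter_reads enforces length and quality rules", {
  reads <- data.frame(
    read_id = c("a", "b", "c", "d"),
    sequence = c(strrep("A", 18), strrep("A", 25), strrep("A", 36),
                 strrep("A", 30)),
    stringsAsFactors = FALSE)
  reads$qualities <- I(list(
    rep(40L, 18),                     # too short despite high quality
    c(rep(40L, 23), rep(10L, 2)),     # 23/25 = 0.92 >= 0.9 -> keep
    c(rep(40L, 31), rep(10L, 5)),     # 31/36 = 0.861 < 0.9 -> drop
    rep(35L, 30)))                    # clean -> keep
  kept <- filter_reads(reads)
  expect_equal(kept$read_id, c("b", "d"))
  # idempotence and empty input
  expect_identical(filter_reads(kept), kept)
  expect_equal(nrow(filter_reads(reads[0, ])), 0)
})

test_that("FASTQ reader decodes Phred+33 qualities", {
  path <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGTACGTACGTACGTACGTACGTA",
               paste0("+"), strrep("I", 25),      # I = Q40
               "@r2", "ACGTACGTACGTACGTAC", "+", strrep("5", 18)), path)
  reads <- read_fastq(path)
  expect_equal(reads$read_id, c("r1", "r2"))
  expect_equal(reads$qualities[[1]], rep(40L, 25))
  expect_equal(reads$qualities[[2]], rep(20L, 18))
  kept <- filter_reads(reads)
  expect_equal(kept$read_id, "r1")  # r2 too short and low quality
})

test_that("count_reads_in_clusters applies overlap, uniqueness, repeats", {
  cl <- make_iv(c(1000L, 5000L), c(2000L, 6000L), name = c("k1", "k2"))
  aln <- rbind(
    make_aln("chr1", 1975L, 2000L, read_id = "ov25_in20"),  # 25 nt, 20 in
    make_aln("chr1", 1983L, 2008L, read_id = "ov17"),       # only 17 in
    make_aln("chr1", 1500L, 1525L, n_hits = 2L, read_id = "multi"),
    make_aln("chr1", 5100L, 5125L, read_id = "k2read"))
  m <- count_reads_in_clusters(aln, cl)
  expect_equal(m["k1", "s1"], 1L)  # 20 >= 18 counted; 17 not; multi not
  expect_equal(m["k2", "s1"], 1L)
  m2 <- count_reads_in_clusters(aln, cl, unique_only = FALSE)
  expect_equal(m2["k1", "s1"], 2L)
  reps <- make_iv(5000L, 5200L)
  m3 <- count_reads_in_clusters(aln, cl, exclude_repeats = reps)
  expect_equal(m3["k2", "s1"], 0L)
  expect_error(
    count_reads_in_clusters(aln, rbind(cl, cl)), "not unique")
})

test_that("a unique read spanning two clusters counts in both", {
  cl <- make_iv(c(100L, 140L), c(140L, 200L), name = c("a", "b"))
  aln <- make_aln("chr1", 120L, 160L)  # 20 bp in each
  m <- count_reads_in_clusters(aln, cl)
  expect_equal(unname(m[, "s1"]), c(1L, 1L))
})

test_that("counting agrees with the brute-force double loop", {
  set.seed(7)
  cl <- make_iv(seq(0L, 9000L, by = 1000L),
                seq(0L, 9000L, by = 1000L) + sample(200:900, 10),
                name = sprintf("k%d", 1:10))
  start <- sample(0:9800, 300, TRUE)
  aln <- make_aln("chr1", start, start + sample(19:36, 300, TRUE),
                  n_hits = sample(c(1L, 1L, 1L, 2L), 300, TRUE),
                  sample_id = sample(c("s1", "s2"), 300, TRUE))
  expect_identical(
    count_reads_in_clusters(aln, cl),
    bf_count(aln, cl))
  # disjoint clusters: each unique read counted at most once
  expect_lte(sum(count_reads_in_clusters(aln, cl)),
             sum(aln$n_hits == 1L))
})

test_that("interval_overlap matches spec examples and brute force", {
  a <- make_iv(0L, 10L)
  expect_equal(interval_overlap(a, make_iv(5L, 15L))$overlap, 5L)
  expect_equal(interval_overlap(a, make_iv(5L, 15L))$gap, 0L)
  g4 <- interval_overlap(a, make_iv(14L, 20L), max_gap = 5L)
  expect_equal(g4$gap, 4L)
  expect_equal(nrow(interval_overlap(a, make_iv(16L, 20L), max_gap = 5L)),
               0)
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(50:200, 1)
    s <- sample(0:5000, n, TRUE)
    a <- make_iv(s, s + sample(1:400, n, TRUE),
                 chrom = sample(c("c1", "c2"), n, TRUE))
    m <- sample(50:200, 1)
    s <- sample(0:5000, m, TRUE)
    b <- make_iv(s, s + sample(1:400, m, TRUE),
                 chrom = sample(c("c1", "c2"), m, TRUE))
    gap <- sample(0:50, 1)
    got <- interval_overlap(a, b, max_gap = gap)
    want <- bf_interval_pairs(a, b, max_gap = gap)
    key <- function(d) if (is.null(d) || nrow(d) == 0) character(0) else
      sort(sprintf("%d:%d:%d:%d", d$a_idx, d$b_idx, d$overlap, d$gap))
    expect_identical(key(got), key(want))
  }
})

test_that("count matrix and sample table readers validate input", {
  m <- matrix(1:6, 2, 3, dimnames = list(c("a", "b"),
                                         c("s1", "s2", "s3")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(m, path)
  expect_identical(read_count_matrix(path), m)
  st <- data.frame(sample_id = c("s1", "s2"), strain = "BL6",
                   tissue = "testis", batch = "b1")
  sp <- withr::local_tempfile(fileext = ".tsv")
  write.table(st, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_sample_table(sp)$strain, c("BL6", "BL6"))
})
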