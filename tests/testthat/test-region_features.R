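test_that("fixed segmentation tiles exactly and keeps trailing partials", {
  chs <- data.table::data.table(chrom = "c1", size = 1000L)
  w <- segment_genome(chs, window_scheme("fixed", 250L))
  expect_equal(nrow(w), 4L)
  expect_equal(w$start, c(0L, 250L, 500L, 750L))
  expect_equal(w$end, c(250L, 500L, 750L, 1000L))
  # partition: union covers [0, size), pairwise disjoint
  w2 <- segment_genome(data.table::data.table(chrom = "c1", size = 1037L),
                       window_scheme("fixed", 250L))
  expect_equal(w2$end[nrow(w2)], 1037L)
  expect_equal(w2$start[-1L], w2$end[-nrow(w2)])
  expect_equal(sum(w2$end - w2$start), 1037L)
})

test_that("sliding segmentation truncates at the chromosome end", {
  chs <- data.table::data.table(chrom = "c1", size = 200L)
  w <- segment_genome(chs, window_scheme("sliding", 100L, 20L))
  expect_equal(nrow(w), 10L)
  expect_equal(w$start, seq(0L, 180L, 20L))
  expect_equal(w$end, pmin(w$start + 100L, 200L))
  expect_equal(w$set_label, rep("100_20", 10L))
})

test_that("sex chromosomes and mitochondrion are excluded", {
  chs <- data.table::data.table(chrom = c("chr1", "chrX", "chrY", "chrM", "2"),
                                size = rep(500L, 5))
  w <- segment_genome(chs, window_scheme("fixed", 250L))
  expect_setequal(unique(w$chrom), c("chr1", "2"))
  expect_error(segment_genome(chs, list(type = "fixed")), "unknown scheme")
})

test_that("the default scheme list has 14 members with the expected labels", {
  sch <- default_window_schemes()
  expect_length(sch, 14L)
  expect_true("100_20" %in% names(sch))
  expect_true(all(c("9000bp", "100bp", "250bp", "150bp") %in% names(sch)))
})

test_that("window averaging filters low-coverage CpGs and call-weights", {
  win <- data.table::data.table(chrom = "c1", start = 0L, end = 100L,
                                set_label = "100bp")
  cov1 <- data.table::data.table(chrom = "c1", pos = 10L, meth_percent = 100,
                                 count_meth = 5L, count_unmeth = 0L)
  m <- window_average_methylation(list(s1 = cov1), win)
  expect_equal(unname(m[1, 1]), 1.0)

  cov2 <- data.table::data.table(chrom = "c1", pos = c(10L, 20L),
                                 meth_percent = c(50, 200 / 3),
                                 count_meth = c(4L, 2L), count_unmeth = c(4L, 1L))
  m2 <- window_average_methylation(list(s1 = cov2), win, min_cov = 5L)
  expect_equal(unname(m2[1, 1]), 0.5)   # the 3x CpG is dropped; 4/8

  # undetermined in one of two samples -> window removed
  cov3 <- data.table::data.table(chrom = "c1", pos = 10L, meth_percent = 50,
                                 count_meth = 2L, count_unmeth = 2L)
  m3 <- window_average_methylation(list(s1 = cov2, s2 = cov3), win, min_cov = 5L)
  expect_equal(nrow(m3), 0L)

  expect_error(window_average_methylation(list(s1 = cov1), win[0]), "empty window")
})

test_that("window boundaries follow the 1-based/0-based convention", {
  # CpG at 1-based pos p lies in [s,e) iff p-1 in [s,e): pos 100 -> window [0,100)
  win <- data.table::data.table(chrom = "c1", start = c(0L, 100L),
                                end = c(100L, 200L), set_label = "100bp")
  cov <- data.table::data.table(chrom = "c1", pos = c(100L, 101L),
                                meth_percent = c(100, 0),
                                count_meth = c(5L, 0L), count_unmeth = c(0L, 5L))
  m <- window_average_methylation(list(s = cov), win)
  expect_equal(unname(m["c1:0-100", "s"]), 1)
  expect_equal(unname(m["c1:100-200", "s"]), 0)
})

test_that("fully methylated coverage gives all-1 cells; values order-invariant", {
  win <- segment_genome(data.table::data.table(chrom = "c1", size = 300L),
                        window_scheme("fixed", 100L))
  cov <- data.table::data.table(chrom = "c1", pos = c(10L, 50L, 150L, 250L),
                                meth_percent = 100, count_meth = 6L,
                                count_unmeth = 0L)
  m <- window_average_methylation(list(s = cov), win)
  expect_true(all(m == 1))
  m_shuf <- window_average_methylation(list(s = cov[c(3, 1, 4, 2)]), win)
  expect_equal(m_shuf, m)
})

test_that("deduplication keeps the first of identical rows and maps removals", {
  m <- matrix(c(0.1, 0.2, 0.1, 0.2, 0.3, 0.4), nrow = 3, byrow = TRUE,
              dimnames = list(c("c1:0-100", "c1:20-120", "c1:40-140"),
                              c("s1", "s2")))
  d <- deduplicate_windows(m)
  expect_equal(rownames(d), c("c1:0-100", "c1:40-140"))
  map <- attr(d, "dedup_map")
  expect_equal(map$removed, "c1:20-120")
  expect_equal(map$kept, "c1:0-100")

  distinct <- matrix(1:6 / 10, nrow = 3,
                     dimnames = list(paste0("w", 1:3), c("a", "b")))
  d2 <- deduplicate_windows(distinct)
  expect_equal(unclass(d2)[, ], distinct, ignore_attr = TRUE)
  expect_equal(nrow(attr(d2, "dedup_map")), 0L)

  trip <- matrix(rep(c(0.2, 0.4), each = 3), nrow = 3,
                 dimnames = list(paste0("w", 1:3), c("a", "b")))
  d3 <- deduplicate_windows(trip)
  expect_equal(nrow(d3), 1L)
  expect_equal(nrow(attr(d3, "dedup_map")), 2L)
})
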