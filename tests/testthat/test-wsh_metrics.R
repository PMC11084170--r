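# Kernel unit tests against worked examples and the brute-force oracles,
# plus the fast per-sample paths checked against the kernels.

p10 <- metric_params(min_depth = 10L)
p2 <- metric_params(min_depth = 2L)
p_nosub <- metric_params(min_depth = 2L, fdrp_max_reads = Inf)

test_that("PDR kernel matches worked examples", {
  all_m <- uniform_reads(10, c(10L, 20L, 30L, 40L), c(1L, 1L, 1L, 1L))
  expect_equal(compute_pdr(all_m, p10), 0)
  mixed <- c(uniform_reads(5, c(10L, 20L, 30L, 40L), c(1L, 1L, 1L, 1L)),
             uniform_reads(5, c(10L, 20L, 30L, 40L), c(1L, 1L, 0L, 1L)))
  expect_equal(compute_pdr(mixed, p10), 0.5)
  short <- uniform_reads(10, c(10L, 20L), c(1L, 0L))
  expect_true(is.na(compute_pdr(short, p10)))  # nothing reaches 4 CpGs
})

test_that("PM kernel matches worked examples", {
  q <- c(10L, 20L, 30L, 40L)
  one <- uniform_reads(16, q, c(1L, 0L, 1L, 0L))
  expect_equal(compute_pm(one, q, p10), 0)
  all16 <- lapply(0:15, function(k) {
    list(pos = q, state = as.integer(intToBits(k)[4:1] == 1))
  })
  expect_equal(compute_pm(all16, q, p10), 0.9375)
  half <- c(uniform_reads(5, q, c(1L, 1L, 1L, 1L)),
            uniform_reads(5, q, c(0L, 0L, 0L, 0L)))
  expect_equal(compute_pm(half, q, p10), 0.5)
})

test_that("MHL kernel matches worked examples and limits", {
  pos4 <- c(10L, 20L, 30L, 40L)
  expect_equal(compute_mhl(uniform_reads(10, pos4, rep(1L, 4)), p10), 1)
  expect_equal(compute_mhl(uniform_reads(10, pos4, rep(0L, 4)), p10), 0)
  # two copies of "MU": l=1 -> 2/4, l=2 -> 0/2; (1*(1/2) + 2*0)/(1+2) = 1/6
  mu <- uniform_reads(2, c(10L, 20L), c(1L, 0L))
  expect_equal(compute_mhl(mu, p2), 1 / 6)
  expect_equal(oracle_mhl(mu, min_depth = 2L), 1 / 6)
})

test_that("FDRP and qFDRP kernels match worked examples", {
  pos4 <- c(10L, 20L, 30L, 40L)
  ident <- uniform_reads(10, pos4, c(1L, 0L, 1L, 0L))
  expect_equal(compute_fdrp(ident, 10L, p10), 0)
  expect_equal(compute_qfdrp(ident, 10L, p10), 0)
  pair <- list(list(pos = pos4, state = c(1L, 1L, 1L, 1L)),
               list(pos = pos4, state = c(1L, 0L, 1L, 1L)))
  expect_equal(compute_fdrp(pair, 10L, p2), 1)
  expect_equal(compute_qfdrp(pair, 10L, p2), 0.25)
  trio <- c(uniform_reads(2, pos4, c(1L, 1L, 1L, 1L)),
            list(list(pos = pos4, state = c(1L, 0L, 1L, 1L))))
  expect_equal(compute_fdrp(trio, 10L, p2), 2 / 3)
  expect_equal(compute_qfdrp(trio, 10L, p2), mean(c(0, 1 / 4, 1 / 4)))
})

test_that("kernels agree with brute-force oracles on random read sets", {
  for (seed in 1:200) {
    rs <- random_read_set(seed)
    r <- rs$reads
    expect_equal(compute_pdr(r, p2),
                 oracle_pdr(r, min_cpgs = 4L, min_depth = 2L), tolerance = 1e-12)
    expect_equal(compute_mhl(r, p2), oracle_mhl(r, min_depth = 2L),
                 tolerance = 1e-12)
    expect_equal(compute_fdrp(r, rs$anchor, p_nosub),
                 oracle_fdrp(r, rs$anchor, 50L, 2L), tolerance = 1e-12)
    expect_equal(compute_qfdrp(r, rs$anchor, p_nosub),
                 oracle_qfdrp(r, rs$anchor, 50L, 2L), tolerance = 1e-12)
    if (length(rs$pool) >= 4L) {
      q <- rs$pool[1:4]
      expect_equal(compute_pm(r, q, p2), oracle_pm(r, q, min_depth = 2L),
                   tolerance = 1e-12)
    }
  }
})

test_that("scores are bounded, order-invariant and satisfy qFDRP <= FDRP", {
  for (seed in 201:260) {
    rs <- random_read_set(seed)
    r <- rs$reads
    vals <- c(compute_pdr(r, p2), compute_mhl(r, p2),
              compute_fdrp(r, rs$anchor, p_nosub),
              compute_qfdrp(r, rs$anchor, p_nosub))
    if (length(rs$pool) >= 4L) {
      vals <- c(vals, compute_pm(r, rs$pool[1:4], p2))
    }
    expect_true(all(is.na(vals) | (vals >= 0 & vals <= 1)))
    f <- compute_fdrp(r, rs$anchor, p_nosub)
    q <- compute_qfdrp(r, rs$anchor, p_nosub)
    if (!is.na(f)) expect_lte(q, f + 1e-12)
    # read order / id relabeling invariance
    perm <- sample(length(r))
    expect_equal(compute_mhl(r[perm], p2), compute_mhl(r, p2))
    expect_equal(compute_fdrp(r[perm], rs$anchor, p_nosub), f)
  }
})

test_that("homogeneity limits hold at sample level", {
  pos <- seq(100L, 200L, by = 10L)
  calls <- data.table::rbindlist(lapply(1:12, function(i) {
    data.table::data.table(read_id = sprintf("r%02d", i), chrom = "chr1",
                           pos = pos, state = 1L)
  }))
  for (m in c("PDR", "PM", "FDRP", "qFDRP")) {
    sc <- score_sample(calls, m)
    expect_true(nrow(sc) > 0)
    expect_true(all(sc$score == 0), label = m)
  }
  mhl <- score_sample(calls, "MHL")
  expect_true(all(mhl$score == 1))
  calls$state <- 0L
  mhl0 <- score_sample(calls, "MHL")
  expect_true(all(mhl0$score == 0))
})

test_that("score_sample handles empty and unsorted input", {
  empty <- data.table::data.table(read_id = character(), chrom = character(),
                                  pos = integer(), state = integer())
  sc <- score_sample(empty, "PDR")
  expect_equal(nrow(sc), 0L)
  bad <- data.table::data.table(read_id = "r1", chrom = "chr1",
                                pos = c(30L, 10L), state = c(1L, 0L))
  expect_error(score_sample(bad, "PDR"), "unsorted")
})

test_that("fast per-sample paths agree with the kernels at every locus", {
  set.seed(314)
  # build a sample of many overlapping reads on a shared position grid
  pool <- seq(1000L, 1150L, by = 15L)
  reads <- lapply(1:60, function(i) {
    span <- sample(3:6, 1L)
    start <- sample(seq_len(length(pool) - span + 1L), 1L)
    pos <- pool[start:(start + span - 1L)]
    list(pos = pos, state = sample(c(0L, 1L), span, replace = TRUE))
  })
  calls <- reads_to_calls(reads)
  params <- metric_params(min_depth = 5L, fdrp_max_reads = Inf)
  covering <- function(p) Filter(function(r) p %in% r$pos, reads)
  for (metric in c("PDR", "MHL", "FDRP", "qFDRP")) {
    sc <- score_sample(calls, metric, params)
    expect_gt(nrow(sc), 0)
    for (i in seq_len(nrow(sc))) {
      p <- as.integer(sub("^chr1:", "", sc$locus[i]))
      rr <- covering(p)
      exp_val <- switch(metric,
                        PDR = compute_pdr(rr, params),
                        MHL = compute_mhl(rr, params),
                        FDRP = compute_fdrp(rr, p, params),
                        qFDRP = compute_qfdrp(rr, p, params))
      expect_equal(sc$score[i], exp_val, tolerance = 1e-12,
                   label = paste(metric, sc$locus[i]))
    }
  }
  pm <- score_sample(calls, "PM", params)
  expect_gt(nrow(pm), 0)
  for (i in seq_len(nrow(pm))) {
    q <- as.integer(strsplit(sub("^chr1:", "", pm$locus[i]), ".", fixed = TRUE)[[1]])
    rr <- Filter(function(r) all(q %in% r$pos), reads)
    expect_equal(pm$score[i], compute_pm(rr, q, params), tolerance = 1e-12)
  }
})

test_that("assemble_score_matrix takes the locus union with NA fill", {
  s1 <- data.table::data.table(locus = c("chr1:10", "chr1:20", "chr1:30"),
                               chrom = "chr1", score = c(0.1, 0.2, 0.3))
  data.table::setattr(s1, "metric", "PDR")
  s2 <- data.table::data.table(locus = c("chr1:10", "chr1:20", "chr1:30", "chr1:40"),
                               chrom = "chr1", score = c(0.4, 0.5, 0.6, 0.7))
  data.table::setattr(s2, "metric", "PDR")
  m <- assemble_score_matrix(list(a = s1, b = s2))
  expect_equal(dim(m), c(4L, 2L))
  expect_true(is.na(m["chr1:40", "a"]))
  expect_equal(m["chr1:40", "b"], 0.7)

  single <- assemble_score_matrix(list(a = s1))
  expect_equal(ncol(single), 1L)

  s3 <- data.table::copy(s1)
  data.table::setattr(s3, "metric", "MHL")
  expect_error(assemble_score_matrix(list(a = s1, b = s3)), "different metrics")
})

test_that("pair subsampling is deterministic and capped", {
  rs <- random_read_set(500)
  many <- rep(rs$reads, 10)  # deep locus
  p_cap <- metric_params(min_depth = 2L, fdrp_max_reads = 10L, rng_seed = 7L)
  v1 <- compute_fdrp(many, rs$anchor, p_cap)
  v2 <- compute_fdrp(many, rs$anchor, p_cap)
  expect_identical(v1, v2)
})
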