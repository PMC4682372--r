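test_that("threshold_for_fraction picks the largest threshold meeting the target", {
  h <- score_histogram(rep(c(2, 10, 30), c(50, 30, 20)), "mqv")
  # enumeration oracle over all candidate thresholds
  cp <- cumulative_percent(h, "at_least") / 100
  for (target in c(0.1, 0.2, 0.5, 0.55, 0.9, 1.0)) {
    got <- threshold_for_fraction(h, target)
    want <- max(as.integer(names(cp)[cp >= target]))
    expect_equal(got$threshold, want)
    expect_gte(got$kept_fraction, target)
  }
  expect_equal(threshold_for_fraction(h, 1.0)$threshold, 2)  # keep everything
  single <- score_histogram(rep(30, 100), "mqv")
  expect_equal(threshold_for_fraction(single, 0.2)$threshold, 30)
  expect_error(threshold_for_fraction(h, 0), "\\(0, 1\\]")
  expect_error(threshold_for_fraction(h, 1.2), "\\(0, 1\\]")
})

test_that("fraction_for_depth converts a depth target into a kept fraction", {
  expect_equal(fraction_for_depth(60, 1.1e9, 125e9), 0.528)
  expect_equal(fraction_for_depth(100, 1000, 1000), 1)   # clamp at 1
  expect_equal(fraction_for_depth(0.5, 1000, 1000), 0.5)
  expect_error(fraction_for_depth(-1, 1, 1), "positive")
})

test_that("filter_minq keeps exactly the reads at or above the threshold", {
  reads <- rs_from_quals(c(2, 5), c(9, 40), c(10, 12), c(40, 40))
  res <- filter_minq(reads, 10)
  expect_equal(res$reads$read_id, c("r3", "r4"))
  expect_equal(res$report$n_kept, 2)
  expect_equal(res$report$kept_fraction, 0.5)
  all_kept <- filter_minq(reads, 0)
  expect_equal(nrow(all_kept$reads), 4)
  expect_equal(all_kept$reads$read_id, reads$read_id)  # order preserved
  expect_error(filter_minq(reads, 94), "\\[0, 93\\]")
})

test_that("filter_productq keeps reads at or above the product threshold", {
  reads <- rs_from_quals(c(7, 7, 7), rep(10, 10), c(30, 40))
  pq <- product_q(reads)
  res <- filter_productq(reads, 0.5)
  expect_equal(res$reads$read_id, reads$read_id[pq >= 0.5])
  # boundary is inclusive
  res2 <- filter_productq(reads, pq[2])
  expect_true(reads$read_id[2] %in% res2$reads$read_id)
  expect_equal(nrow(filter_productq(reads, 0)$reads), 3)
  expect_equal(nrow(filter_productq(reads, 1)$reads), 0)  # finite Q never reaches 1
  # k-mer variant filters on the windowed minimum
  resk <- filter_productq(reads, 0.9, k = 2)
  kq <- kmer_min_product_q(reads, 2)
  expect_equal(resk$reads$read_id, reads$read_id[kq >= 0.9])
})

test_that("filter_pe keeps a pair iff filter_minq would keep both mates", {
  sim <- generate_from_genome(500, 8, L = 50, paired = TRUE,
                              insert_mean = 150, insert_sd = 10,
                              model = quality_model("iid_categorical",
                                                    scores = c(5L, 20L, 35L),
                                                    probs = c(0.1, 0.3, 0.6)),
                              seed = 13)
  pairs <- sim$pairs
  for (t in c(0, 5, 20, 21, 35)) {
    res <- filter_pe(pairs, t)
    keep1 <- min_quality(pairs$mate1) >= t
    keep2 <- min_quality(pairs$mate2) >= t
    expect_equal(res$pairs$pair_id, pairs$pair_id[keep1 & keep2])
    expect_equal(res$report$n_kept, sum(keep1 & keep2))
  }
  # strict mode uses >
  pe <- pe_mqv(pairs)$pe_mqv
  expect_equal(filter_pe(pairs, 20, strict = TRUE)$report$n_kept, sum(pe > 20))
  # a good mate cannot rescue a bad one
  m1 <- read_set("p/1", "AAAA", strrep(qchar(40), 4))
  m2 <- read_set("p/2", "AAAA", strrep(qchar(5), 4))
  expect_equal(filter_pe(pair_set(m1, m2), 21)$report$n_kept, 0)
})

test_that("filter/statistics consistency: kept counts equal cumulative counts", {
  reads <- generate_reads(2000, L = 30, seed = 17)
  h <- chunked_stats(reads, "mqv", chunk_size = 128)$histogram
  bins <- as.integer(names(h$counts))
  al <- cumulative_percent(h, "at_least")
  for (t in 0:45) {
    n_kept <- filter_minq(reads, t)$report$n_kept
    expect_identical(as.integer(n_kept), sum(h$counts[bins >= t]))
    # and the percentage view agrees exactly where it is defined
    if (as.character(t) %in% names(al))
      expect_equal(al[[as.character(t)]], 100 * n_kept / h$total)
  }
})

test_that("kept sets are nested as thresholds rise", {
  reads <- generate_reads(300, L = 40, seed = 23)
  prev <- filter_minq(reads, 0)$reads$read_id
  for (t in c(3, 8, 9, 30, 41)) {
    cur <- filter_minq(reads, t)$reads$read_id
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  pqs <- seq(0, 1, by = 0.25)
  prev <- filter_productq(reads, 0, k = 10)$reads$read_id
  for (p in pqs[-1]) {
    cur <- filter_productq(reads, p, k = 10)$reads$read_id
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("threshold round-trip keeps at least the target with minimal overshoot", {
  reads <- generate_reads(5000, L = 60, seed = 29)
  h <- chunked_stats(reads, "mqv", chunk_size = 1e6)$histogram
  for (target in c(0.1, 0.25, 0.5, 0.9)) {
    thr <- threshold_for_fraction(h, target)
    res <- filter_minq(reads, thr$threshold)
    expect_gte(res$report$kept_fraction, target)
    # no larger integer threshold still meets the target
    above <- filter_minq(reads, thr$threshold + 1)
    expect_lt(above$report$kept_fraction, target)
  }
})

test_that("filter_random is seed-deterministic and unbiased", {
  reads <- generate_reads(4000, L = 20, seed = 31)
  a <- filter_random(reads, 0.3, seed = 99)
  b <- filter_random(reads, 0.3, seed = 99)
  expect_identical(a$reads, b$reads)
  expect_equal(a$report$seed, 99)
  band <- stats::qnorm(0.995) * sqrt(0.3 * 0.7 / 4000)
  expect_lt(abs(a$report$kept_fraction - 0.3), band)
  expect_equal(filter_random(reads, 1.0, seed = 1)$report$n_kept, 4000)
  c2 <- filter_random(reads, 0.3, seed = 100)
  expect_false(identical(a$reads$read_id, c2$reads$read_id))
  # pair input keeps mates together
  sim <- generate_from_genome(400, 4, L = 40, paired = TRUE,
                              insert_mean = 120, insert_sd = 5, seed = 3)
  pr <- filter_random(sim$pairs, 0.5, seed = 7)
  expect_equal(pair_id_stem(pr$pairs$mate1$read_id), pr$pairs$pair_id)
  expect_error(filter_random(reads, 0), "\\(0, 1\\]")
})
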