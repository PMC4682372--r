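test_that("score_histogram bins integer scores and floor-bins products", {
  h <- score_histogram(c(2, 2, 9), "mqv")
  expect_equal(h$counts, c(`2` = 2L, `9` = 1L))
  expect_equal(h$total, 3)

  p <- score_histogram(c(0.999, 0.105, 0.1), "correctness_score")
  expect_equal(p$counts, c(`10` = 2L, `99` = 1L))
  # a product of exactly 1 bins to 100; exactly 0 bins to 0
  expect_equal(names(score_histogram(c(1, 0), "correctness_score")$counts),
               c("0", "100"))

  e <- score_histogram(numeric(), "mqv")
  expect_equal(e$total, 0)
  expect_length(e$counts, 0)

  expect_error(score_histogram(c(-1), "mqv"), "\\[0, 93\\]")
  expect_error(score_histogram(1.5, "correctness_score"), "\\[0, 1\\]")
})

test_that("merge_histograms is a commutative monoid with empty identity", {
  a <- score_histogram(c(2), "mqv")
  b <- score_histogram(c(2, 2, 2, 5), "mqv")
  ab <- merge_histograms(a, b)
  expect_equal(ab$counts, c(`2` = 4L, `5` = 1L))
  expect_equal(ab$total, 5)
  empty <- score_histogram(numeric(), "mqv")
  expect_equal(merge_histograms(a, empty), a)
  expect_equal(merge_histograms(empty, a), a)
  expect_error(merge_histograms(a, score_histogram(0.5, "correctness_score")),
               "kind")

  # associativity/commutativity vs direct concatenation on random scores
  set.seed(8)
  for (i in 1:20) {
    xs <- lapply(1:3, function(j) sample(0:40, sample(0:30, 1), replace = TRUE))
    hs <- lapply(xs, score_histogram, kind = "mqv")
    direct <- score_histogram(unlist(xs), "mqv")
    expect_equal(merge_histograms(merge_histograms(hs[[1]], hs[[2]]), hs[[3]]),
                 direct)
    expect_equal(merge_histograms(hs[[1]], merge_histograms(hs[[2]], hs[[3]])),
                 direct)
    expect_equal(merge_histograms(hs[[3]], hs[[1]])$counts,
                 merge_histograms(hs[[1]], hs[[3]])$counts)
  }
})

test_that("cumulative views match hand summation and complementarity", {
  h <- score_histogram(rep(c(2, 10, 30), c(50, 30, 20)), "mqv")
  al <- cumulative_percent(h, "at_least")
  expect_equal(unname(al["3"]), 50)
  expect_equal(unname(al["2"]), 100)     # smallest occupied bin keeps all
  expect_equal(unname(al["31"]), 0)      # one past the largest keeps none
  expect_true(all(diff(al) <= 0))
  am <- cumulative_percent(h, "at_most")
  # exact complementarity: P(>= t) + P(<= t-1) == 100
  t <- 3:31
  expect_equal(unname(al[as.character(t)] + am[as.character(t - 1)]),
               rep(100, length(t)))
  expect_error(cumulative_percent(score_histogram(numeric(), "mqv")), "empty")
})

test_that("summarize_reads computes the dataset characteristics", {
  s <- summarize_reads(read_set("r1", "GC", "II"))
  expect_equal(s$pct_gc, 100)
  expect_equal(s$mean_quality, 40)
  expect_equal(s$pct_bases_ge_q30, 100)

  s2 <- summarize_reads(read_set("r1", "AT", "!!"))
  expect_equal(s2$pct_gc, 0)
  expect_equal(s2$pct_bases_ge_q30, 0)

  s3 <- summarize_reads(read_set(c("a", "b"),
                                 c(strrep("A", 100), strrep("G", 200)),
                                 c(strrep("I", 100), strrep("I", 200))))
  expect_equal(s3$mean_read_length, 150)
  expect_equal(s3$total_bases, 300)
  expect_equal(s3$mean_read_length * s3$n_reads, s3$total_bases)

  # Q30 convention: default >= 30, strict > 30
  exactly30 <- read_set("r", "ACGT", strrep(qchar(30), 4))
  expect_equal(summarize_reads(exactly30)$pct_bases_ge_q30, 100)
  expect_equal(summarize_reads(exactly30, q30_strict = TRUE)$pct_bases_ge_q30, 0)

  expect_error(summarize_reads(read_set(character(), character(), character())),
               "empty")
})

test_that("summarize_pairs pools both mates and counts pairs", {
  m1 <- read_set("p1/1", "GGGG", "IIII")
  m2 <- read_set("p1/2", "AATT", "####")
  s <- summarize_pairs(pair_set(m1, m2))
  expect_equal(s$n_pairs, 1)
  expect_equal(s$n_reads, 2)
  expect_equal(s$pct_gc, 50)
  expect_equal(s$mean_quality, (4 * 40 + 4 * 2) / 8)
})

test_that("chunked computation is bit-identical to the serial run", {
  reads <- generate_reads(100, L = 40, seed = 21)
  serial <- chunked_stats(reads, "mqv", chunk_size = nrow(reads))
  for (cs in c(1, 3, 7, 100, 1000)) {
    for (w in c(1, 4)) {
      got <- chunked_stats(reads, "mqv", chunk_size = cs, workers = w)
      expect_identical(got$histogram, serial$histogram)
      expect_identical(got$summary, serial$summary)
    }
  }
  # same for correctness products and base qualities
  for (kind in c("correctness_score", "base_quality")) {
    serial <- chunked_stats(reads, kind, chunk_size = 1000)
    got <- chunked_stats(reads, kind, chunk_size = 9, workers = 3)
    expect_identical(got, serial)
  }
  # and for pairs
  sim <- generate_from_genome(600, 6, L = 60, paired = TRUE,
                              insert_mean = 180, insert_sd = 12, seed = 9)
  serial <- chunked_stats(sim$pairs, "pe_mqv", chunk_size = 1e6)
  got <- chunked_stats(sim$pairs, "pe_mqv", chunk_size = 4, workers = 2)
  expect_identical(got, serial)
  expect_equal(serial$histogram$total, n_pairs(sim$pairs))
})

test_that("histogram totals conserve the number of scored items", {
  reads <- generate_reads(500, L = 30, seed = 2)
  h <- chunked_stats(reads, "mqv", chunk_size = 64)$histogram
  expect_equal(h$total, 500)
  expect_equal(sum(h$counts), 500)
  hb <- chunked_stats(reads, "base_quality", chunk_size = 64)$histogram
  expect_equal(hb$total, 500 * 30)
})

test_that("empirical MQV distribution follows the analytic i.i.d. law", {
  L <- 40
  model <- quality_model("iid_categorical",
                         scores = c(2L, 10L, 30L, 40L),
                         probs = c(0.03, 0.07, 0.4, 0.5))
  n <- 20000
  reads <- generate_reads(n, L = L, model = model, seed = 33)
  mq <- min_quality(reads)
  for (t in c(3, 10, 11, 30, 31, 40)) {
    theo <- base_tail <- switch(as.character(t),
      `3` = 0.97, `10` = 0.97, `11` = 0.9, `30` = 0.9, `31` = 0.5, `40` = 0.5)
    p <- base_tail^L
    emp <- mean(mq >= t)
    band <- stats::qnorm(0.995) * sqrt(p * (1 - p) / n)
    expect_lt(abs(emp - p), max(band, 3 / n))
  }
})

test_that("histogram report files are well-formed", {
  h <- score_histogram(rep(c(2, 10, 30), c(50, 30, 20)), "mqv")
  hp <- tempfile(fileext = ".tsv")
  cp <- tempfile(fileext = ".tsv")
  write_histogram(h, hp, cp)
  tab <- utils::read.delim(hp)
  expect_equal(tab$bin, c(2, 10, 30))
  expect_equal(tab$count, c(50, 30, 20))
  cum <- utils::read.delim(cp)
  expect_equal(cum$pct_at_least[cum$threshold == 3], 50)
})
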