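# Score distributions, cumulative views, dataset summaries, and the
# deterministic chunk-and-merge computation contract.

HIST_KINDS <- c("base_quality", "mqv", "pe_mqv", "correctness_score")

hist_domain_max <- function(kind) if (kind == "correctness_score") 100L else 93L

#' Integer-binned score histogram
#'
#' Bins per-base, per-read, or per-pair scores into an integer histogram.
#' Phred-scale kinds (`base_quality`, `mqv`, `pe_mqv`) take integer scores
#' in `[0, 93]` and bin identically; `correctness_score` takes raw ProductQ
#' values in `[0, 1]` and bins by `floor(product * 100)` (clipped to
#' `[0, 100]`), so bin b means "correctness score in `[b, b+1)`" --
#' matching the semantics of a filtering threshold `0.yy`.
#'
#' @param scores Numeric vector of scores (raw products for
#'   `correctness_score`).
#' @param kind One of `"base_quality"`, `"mqv"`, `"pe_mqv"`,
#'   `"correctness_score"`.
#' @return A `score_histogram`: list with `kind`, `counts` (named by bin),
#'   `total`.
#' @examples
#' score_histogram(c(2, 2, 9), "mqv")
#' @export
score_histogram <- function(scores, kind = HIST_KINDS) {
  kind <- match.arg(kind)
  if (kind == "correctness_score") {
    if (length(scores) && (min(scores) < 0 || max(scores) > 1))
      stop("correctness_score input must be raw products in [0, 1]",
           call. = FALSE)
    # +1e-9 guards against products like 0.29 whose *100 lands just below
    # the integer; ties at .5 still floor down.
    bins <- pmin(pmax(floor(scores * 100 + 1e-9), 0L), 100L)
  } else {
    if (length(scores) &&
        (any(scores != floor(scores)) || min(scores) < 0 || max(scores) > 93))
      stop(sprintf("%s scores must be integers in [0, 93]", kind),
           call. = FALSE)
    bins <- scores
  }
  counts <- table(bins)
  counts <- stats::setNames(as.integer(counts), names(counts))
  new_histogram(kind, counts)
}

new_histogram <- function(kind, counts) {
  if (length(counts)) {
    ord <- order(as.integer(names(counts)))
    counts <- counts[ord]
  }
  structure(list(kind = kind, counts = counts,
                 total = sum(as.numeric(counts))),
            class = "score_histogram")
}

#' @export
print.score_histogram <- function(x, ...) {
  cat(sprintf("<score_histogram> kind = %s, %d occupied bins, total = %g\n",
              x$kind, length(x$counts), x$total))
  if (length(x$counts))
    cat(sprintf("  bins %s..%s\n", names(x$counts)[1L],
                names(x$counts)[length(x$counts)]))
  invisible(x)
}

#' Merge score histograms
#'
#' Bin-wise sum of two histograms of the same kind -- the reducer of the
#' chunk-and-merge computation model. Merging is associative and
#' commutative with the empty histogram as identity, so any chunking of
#' the input yields the identical result.
#'
#' @param h1,h2 `score_histogram`s with equal `kind`.
#' @return The merged `score_histogram`.
#' @export
merge_histograms <- function(h1, h2) {
  stopifnot(inherits(h1, "score_histogram"), inherits(h2, "score_histogram"))
  if (h1$kind != h2$kind)
    stop(sprintf("cannot merge histograms of kind '%s' and '%s'",
                 h1$kind, h2$kind), call. = FALSE)
  keys <- union(names(h1$counts), names(h2$counts))
  a <- stats::setNames(integer(length(keys)), keys)
  a[names(h1$counts)] <- a[names(h1$counts)] + h1$counts
  a[names(h2$counts)] <- a[names(h2$counts)] + h2$counts
  new_histogram(h1$kind, a)
}

#' Cumulative percentage view of a histogram
#'
#' For each integer threshold t from the smallest occupied bin to one past
#' the largest, the percentage of items with score `>= t` (`at_least`, the
#' view the cumulative-percentage curves plot and threshold selection
#' reads) or `<= t` (`at_most`). `at_least` is non-increasing in t and
#' starts at 100 at the smallest occupied bin.
#'
#' @param h A non-empty `score_histogram`.
#' @param direction `"at_least"` or `"at_most"`.
#' @return Named numeric vector of percentages, names are thresholds.
#' @export
cumulative_percent <- function(h, direction = c("at_least", "at_most")) {
  stopifnot(inherits(h, "score_histogram"))
  direction <- match.arg(direction)
  if (h$total < 1) stop("cumulative view of an empty histogram", call. = FALSE)
  bins <- as.integer(names(h$counts))
  lo <- min(bins)
  hi <- max(bins)
  dense <- numeric(hi - lo + 1L)
  dense[bins - lo + 1L] <- h$counts
  t <- seq.int(lo, hi + 1L)
  cnt <- if (direction == "at_least") c(rev(cumsum(rev(dense))), 0)
         else c(cumsum(dense), h$total)
  stats::setNames(100 * cnt / h$total, t)
}

#' Summary statistics of a read set
#'
#' Dataset characteristics: number of reads (and pairs, for paired input),
#' total bases, mean read length, mean base quality, percentage of bases
#' at or above Q30, and GC content.
#'
#' @param reads A non-empty [read_set()].
#' @inheritParams decode_qualities
#' @param q30_strict If `TRUE`, the Q30 percentage counts bases with
#'   quality strictly greater than 30; the default follows the Illumina
#'   "Q30" convention of `>= 30`.
#' @return A `dataset_summary` list.
#' @export
summarize_reads <- function(reads, offset = 33L, q30_strict = FALSE) {
  stopifnot(is_read_set(reads))
  if (nrow(reads) == 0L) stop("cannot summarize an empty read set",
                              call. = FALSE)
  finish_acc(summary_acc(reads, offset), q30_strict = q30_strict)
}

#' @rdname summarize_reads
#' @param pairs A [pair_set()].
#' @export
summarize_pairs <- function(pairs, offset = 33L, q30_strict = FALSE) {
  stopifnot(inherits(pairs, "pair_set"))
  if (n_pairs(pairs) == 0L) stop("cannot summarize an empty pair set",
                                 call. = FALSE)
  acc <- combine_acc(summary_acc(pairs$mate1, offset),
                     summary_acc(pairs$mate2, offset))
  out <- finish_acc(acc, q30_strict = q30_strict)
  out$n_pairs <- n_pairs(pairs)
  out
}

# Exact integer accumulators: every derived statistic is a ratio of
# integer-valued sums, so chunked computation merges bit-identically.
summary_acc <- function(reads, offset = 33L) {
  lens <- nchar(reads$sequence)
  qv <- if (nrow(reads))
    utf8ToInt(paste(reads$quality, collapse = "")) - as.integer(offset)
  else integer()
  gc <- sum(lengths(regmatches(reads$sequence,
                               gregexpr("[GCgc]", reads$sequence))))
  list(n_reads = nrow(reads),
       total_bases = sum(as.numeric(lens)),
       q_sum = sum(as.numeric(qv)),
       n_q_ge30 = sum(qv >= 30L),
       n_q_gt30 = sum(qv > 30L),
       n_gc = gc)
}

combine_acc <- function(a, b) Map(`+`, a, b)

finish_acc <- function(acc, q30_strict = FALSE) {
  nq30 <- if (q30_strict) acc$n_q_gt30 else acc$n_q_ge30
  structure(list(n_reads = acc$n_reads,
                 n_pairs = NULL,
                 total_bases = acc$total_bases,
                 mean_read_length = acc$total_bases / acc$n_reads,
                 mean_quality = acc$q_sum / acc$total_bases,
                 pct_bases_ge_q30 = 100 * nq30 / acc$total_bases,
                 pct_gc = 100 * acc$n_gc / acc$total_bases),
            class = "dataset_summary")
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat("<dataset_summary>\n")
  cat(sprintf("  reads: %d%s  bases: %.0f  mean length: %.1f bp\n",
              x$n_reads,
              if (!is.null(x$n_pairs)) sprintf(" (%d pairs)", x$n_pairs) else "",
              x$total_bases, x$mean_read_length))
  cat(sprintf("  mean quality: %.2f  %% bases >= Q30: %.2f  %%GC: %.2f\n",
              x$mean_quality, x$pct_bases_ge_q30, x$pct_gc))
  invisible(x)
}

# Scores of one chunk of reads/pairs for a histogram kind.
chunk_scores <- function(x, kind, offset = 33L, k = NULL) {
  switch(kind,
    base_quality = unlist(qual_ints(x, offset), use.names = FALSE),
    mqv = min_quality(x, offset),
    correctness_score = if (is.null(k)) product_q(x, offset)
                        else kmer_min_product_q(x, k, offset),
    pe_mqv = pe_mqv(x, offset)$pe_mqv,
    stop(sprintf("unknown histogram kind '%s'", kind), call. = FALSE))
}

#' Chunked histogram and summary computation
#'
#' Splits the input into chunks, scores each chunk independently, assigns
#' chunks round-robin to `workers` logical workers, and merges the partial
#' histograms and summary accumulators. Because all accumulators are
#' integer-valued sums and histogram merging is a commutative monoid, the
#' result is bit-identical to the serial single-chunk computation for any
#' `chunk_size` and `workers` -- a deterministic stand-in for a map-reduce
#' aggregation.
#'
#' @param x A [read_set()], or a [pair_set()] for `kind = "pe_mqv"`.
#' @param kind Histogram kind, see [score_histogram()].
#' @param chunk_size Number of reads (or pairs) per chunk.
#' @param workers Number of logical workers the chunks are partitioned
#'   over (affects the merge tree only, never the result).
#' @inheritParams score_reads
#' @return List with elements `histogram` and `summary`.
#' @export
chunked_stats <- function(x, kind = HIST_KINDS, chunk_size = 10000L,
                          workers = 1L, offset = 33L, k = NULL) {
  kind <- match.arg(kind)
  stopifnot(chunk_size >= 1L, workers >= 1L)
  paired <- inherits(x, "pair_set")
  if (kind == "pe_mqv" && !paired)
    stop("pe_mqv statistics need a pair_set input", call. = FALSE)
  if (kind != "pe_mqv" && paired) {
    x <- interleave_pairs(x)
    paired <- FALSE
  }
  n <- if (paired) n_pairs(x) else nrow(x)
  if (n == 0L) stop("empty input", call. = FALSE)
  starts <- seq.int(1L, n, by = chunk_size)
  chunk_of <- function(i) {
    idx <- seq.int(starts[i], min(starts[i] + chunk_size - 1L, n))
    if (paired) x[idx] else x[idx, , drop = FALSE]
  }
  n_chunks <- length(starts)
  part <- lapply(seq_len(n_chunks), function(i) {
    ch <- chunk_of(i)
    acc <- if (paired) combine_acc(summary_acc(ch$mate1, offset),
                                   summary_acc(ch$mate2, offset))
           else summary_acc(ch, offset)
    list(hist = score_histogram(chunk_scores(ch, kind, offset, k), kind),
         acc = acc)
  })
  # round-robin assignment: worker w reduces its own chunks in order, then
  # workers merge in worker order
  by_worker <- split(part, (seq_len(n_chunks) - 1L) %% workers)
  reduced <- lapply(by_worker, function(ps) {
    list(hist = Reduce(merge_histograms, lapply(ps, `[[`, "hist")),
         acc = Reduce(combine_acc, lapply(ps, `[[`, "acc")))
  })
  hist <- Reduce(merge_histograms, lapply(reduced, `[[`, "hist"))
  acc <- Reduce(combine_acc, lapply(reduced, `[[`, "acc"))
  out <- finish_acc(acc)
  if (paired) out$n_pairs <- n
  list(histogram = hist, summary = out)
}

#' Write histogram reports
#'
#' Two-column tab-delimited reports: `(bin, count)` and `(threshold,
#' cumulative %at_least)` with percentages printed to 2 decimals.
#'
#' @param h A `score_histogram`.
#' @param hist_path,cum_path Output paths.
#' @export
write_histogram <- function(h, hist_path, cum_path = NULL) {
  stopifnot(inherits(h, "score_histogram"))
  writeLines(c("bin\tcount",
               sprintf("%s\t%d", names(h$counts), h$counts)), hist_path)
  if (!is.null(cum_path)) {
    cp <- cumulative_percent(h, "at_least")
    writeLines(c("threshold\tpct_at_least",
                 sprintf("%s\t%.2f", names(cp), cp)), cum_path)
  }
  invisible(h)
}
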