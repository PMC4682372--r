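# Threshold determination and subset filtering.
#
# The keep rule is inclusive (score >= threshold) for single-end and
# paired-end modes alike; `strict = TRUE` switches paired-end filtering to
# a strict > for users who read the PE definition that way.

#' Threshold for a target subset fraction
#'
#' Reads a threshold off the cumulative-percentage curve: the largest
#' integer threshold t such that the fraction of items with score `>= t`
#' is still at least `target_fraction`. When the target falls between two
#' occupied bins this over-keeps rather than under-keeps -- the safe
#' direction when the target encodes a required coverage depth.
#'
#' @param h A non-empty `score_histogram` (see [score_histogram()]).
#' @param target_fraction Desired kept fraction in `(0, 1]`.
#' @return List with `threshold` (integer), `kept_fraction` (the fraction
#'   actually kept at that threshold) and `keep_all` (`TRUE` when no
#'   threshold could keep at least the target and the smallest occupied
#'   bin was returned).
#' @examples
#' h <- score_histogram(rep(c(2, 10, 30), c(50, 30, 20)), "mqv")
#' threshold_for_fraction(h, 0.5)  # threshold 10, keeps exactly 50%
#' @export
threshold_for_fraction <- function(h, target_fraction) {
  stopifnot(inherits(h, "score_histogram"))
  if (!is.numeric(target_fraction) || length(target_fraction) != 1L ||
      target_fraction <= 0 || target_fraction > 1)
    stop("target_fraction must be in (0, 1]", call. = FALSE)
  cp <- cumulative_percent(h, "at_least")
  frac <- cp / 100
  ok <- which(frac >= target_fraction)
  if (length(ok) == 0L) {
    warning("no threshold keeps the target fraction; keeping everything",
            call. = FALSE)
    t <- as.integer(names(cp)[1L])
    return(list(threshold = t, kept_fraction = unname(frac[1L]),
                keep_all = TRUE))
  }
  i <- max(ok)
  list(threshold = as.integer(names(cp)[i]), kept_fraction = unname(frac[i]),
       keep_all = FALSE)
}

#' Subset fraction for a target coverage depth
#'
#' Converts a target coverage depth into the fraction of the dataset to
#' keep: `target_depth * genome_size / total_bases`, clamped to 1. Feed the
#' result to [threshold_for_fraction()] to pick a quality threshold; when
#' the genome size is unknown, [estimate_coverage()] supplies a k-mer-based
#' estimate.
#'
#' @param target_depth Desired coverage depth (x-fold), positive.
#' @param genome_size Genome size in bp, positive.
#' @param total_bases Total sequenced bases in the dataset, positive.
#' @return The fraction to keep, in `(0, 1]`.
#' @examples
#' fraction_for_depth(60, 1.1e9, 125e9)  # 0.528
#' @export
fraction_for_depth <- function(target_depth, genome_size, total_bases) {
  if (any(c(target_depth, genome_size, total_bases) <= 0))
    stop("target_depth, genome_size and total_bases must all be positive",
         call. = FALSE)
  min(1, target_depth * genome_size / total_bases)
}

selection_report <- function(mode, threshold, n_in, n_kept, k = NULL,
                             seed = NULL, estimated_depth_kept = NULL) {
  structure(list(mode = mode, threshold = threshold, k = k, seed = seed,
                 n_in = n_in, n_kept = n_kept,
                 kept_fraction = if (n_in > 0) n_kept / n_in else NA_real_,
                 estimated_depth_kept = estimated_depth_kept),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  thr <- if (is.null(x$threshold)) "" else sprintf(" threshold = %g", x$threshold)
  cat(sprintf("<selection_report> mode = %s%s: kept %d / %d (%.2f%%)\n",
              x$mode, thr, x$n_kept, x$n_in, 100 * x$kept_fraction))
  invisible(x)
}

check_int_threshold <- function(t) {
  if (!is.numeric(t) || length(t) != 1L || t != floor(t) || t < 0 || t > 93)
    stop("MQV threshold must be an integer in [0, 93]", call. = FALSE)
  as.integer(t)
}

#' Filter single-end reads by minimal quality (MinimalQ)
#'
#' Keeps exactly the reads whose MQV is at least `threshold`, preserving
#' input order.
#'
#' @param reads A [read_set()].
#' @param threshold Integer MQV threshold in `[0, 93]`.
#' @inheritParams decode_qualities
#' @return List with `reads` (the kept [read_set()]) and `report` (a
#'   `selection_report`).
#' @export
filter_minq <- function(reads, threshold, offset = 33L) {
  stopifnot(is_read_set(reads))
  threshold <- check_int_threshold(threshold)
  keep <- min_quality(reads, offset) >= threshold
  kept <- reads[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(reads = kept,
       report = selection_report("minq", threshold, nrow(reads), nrow(kept)))
}

#' Filter single-end reads by ProductQ
#'
#' Keeps the reads whose ProductQ score (whole-read product when `k` is
#' `NULL`, else the k-mer window minimum) is at least `threshold_product`,
#' preserving input order. The threshold acts on the raw product in
#' `[0, 1]`; a correctness-score threshold of `yy` corresponds to
#' `threshold_product = 0.yy`.
#'
#' @inheritParams filter_minq
#' @param threshold_product Real threshold in `[0, 1]` on the product.
#' @param k Optional k-mer window size.
#' @return List with `reads` and `report`.
#' @export
filter_productq <- function(reads, threshold_product, k = NULL,
                            offset = 33L) {
  stopifnot(is_read_set(reads))
  if (!is.numeric(threshold_product) || length(threshold_product) != 1L ||
      threshold_product < 0 || threshold_product > 1)
    stop("threshold_product must be in [0, 1]", call. = FALSE)
  score <- if (is.null(k)) product_q(reads, offset)
           else kmer_min_product_q(reads, k, offset)
  keep <- score >= threshold_product
  kept <- reads[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(reads = kept,
       report = selection_report("productq", threshold_product,
                                 nrow(reads), nrow(kept), k = k))
}

#' Filter read pairs by PE-MQV
#'
#' Keeps the pairs whose PE-MQV (the smaller of the two mates' MQVs) meets
#' the threshold; both mates are kept or dropped together and pair order
#' is preserved. The default rule is inclusive (`>=`), matching the
#' single-end definition; `strict = TRUE` uses `>`.
#'
#' @param pairs A [pair_set()].
#' @inheritParams filter_minq
#' @param strict Use a strict `>` comparison instead of `>=`.
#' @return List with `pairs` (kept [pair_set()]) and `report`.
#' @export
filter_pe <- function(pairs, threshold, offset = 33L, strict = FALSE) {
  stopifnot(inherits(pairs, "pair_set"))
  threshold <- check_int_threshold(threshold)
  pe <- pe_mqv(pairs, offset)$pe_mqv
  keep <- if (strict) pe > threshold else pe >= threshold
  kept <- pairs[keep]
  list(pairs = kept,
       report = selection_report(if (strict) "pe_minq_strict" else "pe_minq",
                                 threshold, n_pairs(pairs), n_pairs(kept)))
}

#' Random-selection baseline
#'
#' Keeps each read (or pair) independently with probability `fraction`,
#' using a seeded generator isolated from the caller's RNG state: the same
#' seed always yields the identical subset. This is the simple random
#' baseline that quality-based selection is compared against.
#'
#' @param x A [read_set()] or [pair_set()].
#' @param fraction Per-item keep probability in `(0, 1]`.
#' @param seed Integer seed recorded in the report.
#' @return List with `reads` or `pairs` plus `report`.
#' @export
filter_random <- function(x, fraction, seed = 1L) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  paired <- inherits(x, "pair_set")
  if (!paired) stopifnot(is_read_set(x))
  n <- if (paired) n_pairs(x) else nrow(x)
  keep <- with_seed(seed, stats::runif(n) <= fraction)
  rep <- selection_report("random", NULL, n, sum(keep), seed = seed)
  rep$threshold <- NULL
  rep$fraction <- fraction
  if (paired) {
    list(pairs = x[keep], report = rep)
  } else {
    kept <- x[keep, , drop = FALSE]
    rownames(kept) <- NULL
    list(reads = kept, report = rep)
  }
}
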