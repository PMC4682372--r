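# Read scores: MQV, ProductQ and the k-mer windowed minimum ProductQ, plus
# the paired-end PE-MQV.
#
# ProductQ works in log space: per-base terms log(1 - p) accumulate in a
# prefix sum, so a window product is exp of a difference of two prefix
# values. This is O(L) per read for all L-k+1 windows, underflow-safe for
# long reads, and order-independent. A base with Q = 0 has correctness
# probability 0; any window containing one scores exactly 0 (no -Inf
# arithmetic leaks out).

#' Decode an ASCII quality string to Phred scores
#'
#' @param quality A single quality string (characters `!`..`~`).
#' @param offset Encoding offset, 33 or 64.
#' @return Integer vector of Phred scores, one per character.
#' @examples
#' decode_qualities("II#II")  # 40 40 2 40 40
#' @export
decode_qualities <- function(quality, offset = 33L) {
  check_offset(offset)
  stopifnot(is.character(quality), length(quality) == 1L)
  v <- utf8ToInt(quality)
  q <- v - as.integer(offset)
  bad <- which(v < 33L | v > 126L | q < 0L | q > 93L)
  if (length(bad))
    stop(sprintf("invalid quality character '%s' at position %d for offset %d",
                 intToUtf8(v[bad[1L]]), bad[1L], offset), call. = FALSE)
  q
}

#' Phred score to base-calling error probability
#'
#' The defining identity of the Phred scale: `p = 10^(-Q/10)`, the
#' probability that the base call is wrong. Q30 corresponds to p = 0.001.
#'
#' @param Q Non-negative numeric vector of Phred scores.
#' @return Error probabilities in `(0, 1]`.
#' @examples
#' error_prob(c(0, 10, 30))
#' @export
error_prob <- function(Q) {
  if (any(Q < 0)) stop("Phred scores must be non-negative", call. = FALSE)
  10^(-Q / 10)
}

#' Minimal quality value (MQV) of each read
#'
#' The MinimalQ statistic: the smallest decoded base quality within a
#' read. The base with the lowest quality is the one most likely to break
#' read overlaps during assembly, so reads are ranked by their worst base.
#'
#' @param reads A [read_set()].
#' @inheritParams decode_qualities
#' @return Integer vector of MQVs, one per read.
#' @export
min_quality <- function(reads, offset = 33L) {
  stopifnot(is_read_set(reads))
  check_offset(offset)
  n <- nrow(reads)
  if (n == 0L) return(integer())
  lens <- nchar(reads$quality)
  L <- lens[1L]
  if (all(lens == L)) {
    # uniform read length: columns of the L x n score matrix are reads;
    # fold rows with pmin (exact integer min, ~30x faster than per-read)
    m <- matrix(utf8ToInt(paste(reads$quality, collapse = "")) -
                  as.integer(offset), nrow = L)
    out <- m[1L, ]
    for (i in seq_len(L)[-1L]) out <- pmin(out, m[i, ])
    return(as.integer(out))
  }
  vapply(qual_ints(reads, offset), min, integer(1L))
}

#' Whole-read ProductQ score
#'
#' The probability that a read contains no incorrect base call: the product
#' over all L bases of the per-base correctness probability `1 - 10^(-Q/10)`.
#' Computed as `exp(sum(log1p(-p)))`; a read containing a Q = 0 base scores
#' exactly 0.
#'
#' @inheritParams min_quality
#' @return Numeric vector of products in `[0, 1)`.
#' @export
product_q <- function(reads, offset = 33L) {
  stopifnot(is_read_set(reads))
  vapply(qual_ints(reads, offset),
         function(q) exp(sum(log1p(-10^(-q / 10)))), numeric(1L))
}

#' Minimum k-mer ProductQ score
#'
#' De Bruijn graph assemblers consume k-mers rather than whole reads, so a
#' read of length L is judged by its weakest length-k window: the score is
#' the minimum over the L-k+1 windows of the within-window product of
#' per-base correctness probabilities. With `k = L` this equals
#' [product_q()]. Reads shorter than k are scored as their whole-read
#' product (single short window), with a warning.
#'
#' @inheritParams min_quality
#' @param k Window (k-mer) size, a positive integer.
#' @return Numeric vector of window-minimum products in `[0, 1)`.
#' @export
kmer_min_product_q <- function(reads, k, offset = 33L) {
  stopifnot(is_read_set(reads))
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != floor(k))
    stop("k must be a positive integer", call. = FALSE)
  k <- as.integer(k)
  qs <- qual_ints(reads, offset)
  n_short <- sum(lengths(qs) < k)
  if (n_short > 0L)
    warning(sprintf("%d read(s) shorter than k = %d scored as whole-read ProductQ",
                    n_short, k), call. = FALSE)
  vapply(qs, function(q) {
    L <- length(q)
    if (any(q == 0L)) return(0)      # some window must contain the zero factor
    lp <- log1p(-10^(-q / 10))
    if (L <= k) return(exp(sum(lp)))
    S <- c(0, cumsum(lp))
    exp(min(S[(k + 1L):(L + 1L)] - S[1L:(L - k + 1L)]))
  }, numeric(1L))
}

#' Paired-end MQV
#'
#' PE-MQV treats a read pair as a unit: the score is the smaller of the two
#' mates' MQVs, so a pair is only as good as its worse mate.
#'
#' @param pairs A [pair_set()].
#' @inheritParams decode_qualities
#' @return A `data.frame` with columns `pair_id`, `mqv1`, `mqv2`, `pe_mqv`.
#' @export
pe_mqv <- function(pairs, offset = 33L) {
  stopifnot(inherits(pairs, "pair_set"))
  m1 <- min_quality(pairs$mate1, offset)
  m2 <- min_quality(pairs$mate2, offset)
  data.frame(pair_id = pairs$pair_id, mqv1 = m1, mqv2 = m2,
             pe_mqv = pmin(m1, m2), stringsAsFactors = FALSE)
}

#' Score a read set
#'
#' Convenience table of all per-read scores: read length, MQV, ProductQ
#' (whole-read, or the k-mer window minimum when `k` is given) and the
#' correctness score (ProductQ x 100, the reporting scale used by the
#' score distributions).
#'
#' @inheritParams min_quality
#' @param k Optional k-mer size; when supplied the ProductQ column is the
#'   windowed minimum of [kmer_min_product_q()].
#' @return A `data.frame` with columns `read_id`, `read_length`, `mqv`,
#'   `product_q`, `correctness_score`.
#' @export
score_reads <- function(reads, offset = 33L, k = NULL) {
  stopifnot(is_read_set(reads))
  pq <- if (is.null(k)) product_q(reads, offset)
        else kmer_min_product_q(reads, k, offset)
  data.frame(read_id = reads$read_id,
             read_length = nchar(reads$sequence),
             mqv = min_quality(reads, offset),
             product_q = pq,
             correctness_score = pq * 100,
             stringsAsFactors = FALSE)
}

#' @rdname score_reads
#' @param scores A score table from [score_reads()].
#' @param path Output path for the tab-delimited score file (columns
#'   `read_id`, `read_length`, `mqv`, `product_q` at 17 significant
#'   digits).
#' @export
write_scores <- function(scores, path) {
  lines <- sprintf("%s\t%d\t%d\t%.17g", scores$read_id, scores$read_length,
                   scores$mqv, scores$product_q)
  writeLines(c("read_id\tread_length\tmqv\tproduct_q", lines), path)
  invisible(length(lines))
}
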