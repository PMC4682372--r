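# Seeded synthetic FASTQ generation.
#
# The quality models emulate the empirical shape of modern Illumina data:
# the bulk of bases well above Q30 with a small per-base probability of a
# low-quality call. Even a 2% spike rate makes most 300 bp reads carry at
# least one low base, which is exactly the phenomenon that gives the MQV
# distribution its low peak while >80% of bases stay above Q30.

#' Quality model for synthetic reads
#'
#' Three per-base quality models, all i.i.d. across bases:
#' \describe{
#'   \item{`uniform`}{every base gets score `q`.}
#'   \item{`iid_categorical`}{scores drawn from `scores` with probabilities
#'     `probs`.}
#'   \item{`low_spike_mixture`}{with probability `q_low` a base draws
#'     uniformly from `low_scores`, otherwise uniformly from
#'     `high_scores`. Defaults (`q_low = 0.02`, low 2..9, high 30..40)
#'     emulate a MiSeq-like profile: ~98% of bases at Q30-Q40 yet most
#'     300 bp reads contain at least one base below Q10.}
#' }
#'
#' @param kind Model kind.
#' @param q Constant score for `uniform`.
#' @param scores,probs Score values and probabilities for
#'   `iid_categorical` (`probs` must sum to 1).
#' @param q_low Per-base spike probability for `low_spike_mixture`.
#' @param low_scores,high_scores Integer score ranges for the mixture.
#' @return A `quality_model`.
#' @export
quality_model <- function(kind = c("low_spike_mixture", "uniform",
                                   "iid_categorical"),
                          q = 40L, scores = NULL, probs = NULL,
                          q_low = 0.02, low_scores = 2:9,
                          high_scores = 30:40) {
  kind <- match.arg(kind)
  chk_scores <- function(s) {
    if (any(s < 0 | s > 93 | s != floor(s)))
      stop("quality scores must be integers in [0, 93]", call. = FALSE)
  }
  m <- switch(kind,
    uniform = {
      chk_scores(q)
      list(kind = kind, q = as.integer(q))
    },
    iid_categorical = {
      if (is.null(scores) || is.null(probs) || length(scores) != length(probs))
        stop("iid_categorical needs scores and probs of equal length",
             call. = FALSE)
      chk_scores(scores)
      if (abs(sum(probs) - 1) > 1e-9 || any(probs < 0))
        stop("probs must be non-negative and sum to 1", call. = FALSE)
      list(kind = kind, scores = as.integer(scores), probs = probs)
    },
    low_spike_mixture = {
      chk_scores(c(low_scores, high_scores))
      if (q_low < 0 || q_low > 1)
        stop("q_low must be in [0, 1]", call. = FALSE)
      list(kind = kind, q_low = q_low, low_scores = as.integer(low_scores),
           high_scores = as.integer(high_scores))
    })
  structure(m, class = "quality_model")
}

# Draw `total` i.i.d. base quality scores under `model` (uses the current
# RNG state; callers seed via with_seed).
sample_qualities <- function(model, total) {
  stopifnot(inherits(model, "quality_model"))
  if (total == 0L) return(integer())
  switch(model$kind,
    uniform = rep.int(model$q, total),
    iid_categorical = sample(model$scores, total, replace = TRUE,
                             prob = model$probs),
    low_spike_mixture = {
      q <- sample(model$high_scores, total, replace = TRUE)
      low <- stats::runif(total) < model$q_low
      nlow <- sum(low)
      if (nlow) q[low] <- sample(model$low_scores, nlow, replace = TRUE)
      q
    })
}

# Analytic P(base score >= t) under a quality model; the analytic MQV law
# P(MQV >= t) = P(base >= t)^L follows for i.i.d. bases.
base_score_tail <- function(model, t) {
  stopifnot(inherits(model, "quality_model"))
  switch(model$kind,
    uniform = as.numeric(model$q >= t),
    iid_categorical = sum(model$probs[model$scores >= t]),
    low_spike_mixture =
      model$q_low * mean(model$low_scores >= t) +
      (1 - model$q_low) * mean(model$high_scores >= t))
}

# Pack an integer score matrix layout (vector, read-major) into quality
# strings; bases analogous.
pack_strings <- function(chars, n, L) {
  if (n == 0L) return(character())
  m <- matrix(chars, nrow = n, byrow = TRUE)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Generate synthetic reads
#'
#' Seeded generator of uniform-random-base reads with qualities drawn from
#' a [quality_model()]. The seed fans out to independent sub-streams for
#' bases and qualities, so the base stream is unchanged when the quality
#' model changes. Deterministic: the same arguments always produce the
#' identical [read_set()].
#'
#' @param n Number of reads.
#' @param L Read length in bp (default 300, a MiSeq 2x300 configuration).
#' @param model A [quality_model()].
#' @param seed Integer seed.
#' @return A [read_set()] of `n` reads.
#' @examples
#' generate_reads(3, L = 10, quality_model("uniform", q = 30), seed = 1)
#' @export
generate_reads <- function(n, L = 300L, model = quality_model(), seed = 1L) {
  stopifnot(n >= 0, L >= 1)
  n <- as.integer(n); L <- as.integer(L)
  if (n == 0L)
    return(read_set(character(), character(), character(), validate = FALSE))
  sub <- with_seed(seed, sample.int(.Machine$integer.max, 2L))
  bases <- with_seed(sub[1L],
                     sample(c("A", "C", "G", "T"), n * L, replace = TRUE))
  qv <- with_seed(sub[2L], sample_qualities(model, n * L))
  qc <- strsplit(intToUtf8(qv + 33L), "")[[1L]]
  read_set(sprintf("read%06d", seq_len(n)),
           pack_strings(bases, n, L),
           pack_strings(qc, n, L),
           validate = FALSE)
}

#' Sample reads or read pairs from a random toy genome
#'
#' Generates a uniform-random circular toy genome and samples reads (or
#' proper mate pairs) from uniformly distributed start positions on either
#' strand convention folded into the forward sequence; reads that run past
#' the end wrap around, as on a circular bacterial chromosome, so every
#' position is covered at the same expected depth. Error-free by default:
#' each read is an exact substring of the circularised genome. Paired mode
#' emits forward/reverse-complement mates spanning a Gaussian fragment
#' length.
#'
#' @param genome_length Toy genome size in bp.
#' @param depth Target coverage depth (x-fold); the number of reads is
#'   `round(depth * genome_length / L)` (pairs: half that), so realized
#'   depth matches to rounding.
#' @param L Read length in bp.
#' @param paired Emit mate pairs instead of single-end reads.
#' @param insert_mean,insert_sd Fragment-length distribution for paired
#'   mode (mean must be at least `L`).
#' @param model A [quality_model()] for the qualities.
#' @param error_rate Per-base substitution probability (default 0,
#'   error-free).
#' @param seed Integer seed.
#' @return List with `genome` (character string), `reads` (or `pairs`),
#'   and `truth` (data.frame of 1-based start positions and, for pairs,
#'   fragment lengths).
#' @export
generate_from_genome <- function(genome_length, depth, L = 100L,
                                 paired = FALSE, insert_mean = 400L,
                                 insert_sd = 30L, model = quality_model("uniform"),
                                 error_rate = 0, seed = 1L) {
  stopifnot(genome_length >= L, depth > 0)
  if (paired && insert_mean < L)
    stop("insert_mean must be at least the read length", call. = FALSE)
  genome_length <- as.integer(genome_length); L <- as.integer(L)
  sub <- with_seed(seed, sample.int(.Machine$integer.max, 5L))
  g <- with_seed(sub[1L], paste(sample(c("A", "C", "G", "T"), genome_length,
                                       replace = TRUE), collapse = ""))
  g2 <- paste0(g, g)  # circular extension; substrings may wrap once
  take <- function(start, len) substring(g2, start, start + len - 1L)
  mutate <- function(seqs) {
    if (error_rate <= 0) return(seqs)
    vapply(seqs, function(s) {
      b <- strsplit(s, "")[[1L]]
      hit <- stats::runif(length(b)) < error_rate
      if (any(hit))
        b[hit] <- vapply(b[hit], function(x)
          sample(setdiff(c("A", "C", "G", "T"), x), 1L), character(1L))
      paste(b, collapse = "")
    }, character(1L), USE.NAMES = FALSE)
  }
  qual_for <- function(n_reads, sd_seed) {
    qv <- with_seed(sd_seed, sample_qualities(model, n_reads * L))
    pack_strings(strsplit(intToUtf8(qv + 33L), "")[[1L]], n_reads, L)
  }
  if (!paired) {
    n <- max(1L, as.integer(round(depth * genome_length / L)))
    s <- with_seed(sub[2L], sample.int(genome_length, n, replace = TRUE))
    seqs <- with_seed(sub[3L], mutate(take(s, L)))
    reads <- read_set(sprintf("read%06d", seq_len(n)), seqs,
                      qual_for(n, sub[4L]), validate = FALSE)
    list(genome = g, reads = reads, truth = data.frame(start = s))
  } else {
    n <- max(1L, as.integer(round(depth * genome_length / (2 * L))))
    st <- with_seed(sub[2L], {
      s <- sample.int(genome_length, n, replace = TRUE)
      f <- pmin(genome_length,
                pmax(L, as.integer(round(stats::rnorm(n, insert_mean,
                                                      insert_sd)))))
      list(s = s, f = f)
    })
    m1 <- with_seed(sub[3L], mutate(take(st$s, L)))
    m2seq <- revcomp(take(st$s + st$f - L, L))
    m2 <- with_seed(sub[5L], mutate(m2seq))
    pid <- sprintf("frag%06d", seq_len(n))
    q <- with_seed(sub[4L], {
      qv <- sample_qualities(model, 2L * n * L)
      qc <- strsplit(intToUtf8(qv + 33L), "")[[1L]]
      list(q1 = pack_strings(qc[seq_len(n * L)], n, L),
           q2 = pack_strings(qc[n * L + seq_len(n * L)], n, L))
    })
    pairs <- pair_set(read_set(paste0(pid, "/1"), m1, q$q1, validate = FALSE),
                      read_set(paste0(pid, "/2"), m2, q$q2, validate = FALSE))
    list(genome = g, pairs = pairs,
         truth = data.frame(start = st$s, fragment = st$f))
  }
}
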