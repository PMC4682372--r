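# Genome-size and coverage-depth estimation from the k-mer spectrum.
#
# With no reference genome, the genome size is estimated as the total
# number of k-mers in the reads divided by the k-mer coverage depth (the
# modal k-mer multiplicity), and the coverage depth as total bases divided
# by the estimated genome size. Desk-scale in-memory counting only.

#' k-mer multiplicity spectrum
#'
#' Counts every length-k window of every read (a read of length L >= k
#' contributes L-k+1 windows; windows containing a non-ACGT base are
#' skipped) and tabulates how many distinct k-mers were seen exactly m
#' times, for each multiplicity m. In canonical mode (the default, since
#' reads come from both strands) each k-mer is mapped to the
#' lexicographically smaller of itself and its reverse complement before
#' counting.
#'
#' @param reads A [read_set()].
#' @param k k-mer size, a positive integer.
#' @param canonical Canonicalize k-mers by strand (default `TRUE`).
#' @return A `kmer_spectrum`: list with `k`, `canonical`, and `counts`
#'   (named integer vector, multiplicity -> number of distinct k-mers).
#' @examples
#' kmer_multiplicity_histogram(read_set("r1", "ACGTA", "IIIII"), k = 4)
#' @export
kmer_multiplicity_histogram <- function(reads, k, canonical = TRUE) {
  stopifnot(is_read_set(reads))
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != floor(k))
    stop("k must be a positive integer", call. = FALSE)
  k <- as.integer(k)
  seqs <- toupper(reads$sequence)
  seqs <- seqs[nchar(seqs) >= k]
  km <- unlist(lapply(seqs, function(s) {
    n <- nchar(s) - k + 1L
    substring(s, 1L:n, k:(n + k - 1L))
  }), use.names = FALSE)
  if (length(km)) km <- km[!grepl("[^ACGT]", km)]
  if (canonical && length(km)) {
    rc <- revcomp(km)
    km <- ifelse(km <= rc, km, rc)
  }
  counts <- if (length(km)) {
    mult <- table(km)
    tab <- table(as.integer(mult))
    stats::setNames(as.integer(tab), names(tab))
  } else stats::setNames(integer(), character())
  structure(list(k = k, canonical = canonical, counts = counts),
            class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat(sprintf("<kmer_spectrum> k = %d (%s), %d occupied multiplicities, %d distinct k-mers\n",
              x$k, if (x$canonical) "canonical" else "literal",
              length(x$counts), sum(x$counts)))
  invisible(x)
}

#' Modal k-mer depth of a multiplicity spectrum
#'
#' Locates the k-mer coverage depth: the genomic peak of the multiplicity
#' spectrum at or after its first local minimum (the valley separating the
#' error-induced low-multiplicity tail from the genomic peak). The peak is
#' found on a 3-bin moving average of the counts, then refined to the
#' rounded count-weighted centroid within +-3*sqrt(peak) multiplicities
#' (about three Poisson standard deviations) -- a windowed Poisson mean
#' that is far more stable under the sampling noise of desk-scale spectra
#' than the raw argmax, while agreeing with it on clean unimodal spectra.
#' A spectrum that only decreases has no genomic peak; multiplicity 1 is
#' returned with a low-confidence warning.
#'
#' @param spectrum A non-empty `kmer_spectrum` (or a named count vector).
#' @return Integer modal depth, with attribute `low_confidence`.
#' @export
modal_kmer_depth <- function(spectrum) {
  counts <- if (inherits(spectrum, "kmer_spectrum")) spectrum$counts
            else spectrum
  if (length(counts) == 0L) stop("empty k-mer spectrum", call. = FALSE)
  m <- as.integer(names(counts))
  dense <- numeric(max(m))
  dense[m] <- counts
  hi <- length(dense)
  rising <- which(dense[-hi] < dense[-1L])   # i where count increases i -> i+1
  if (length(rising) == 0L) {
    warning("k-mer spectrum is monotonically decreasing; no genomic peak, returning depth 1 (low confidence)",
            call. = FALSE)
    return(structure(1L, low_confidence = TRUE))
  }
  valley <- rising[1L]
  sm <- as.numeric(stats::filter(c(0, dense, 0), rep(1 / 3, 3)))[2L:(hi + 1L)]
  cand <- which(seq_len(hi) >= valley & sm == max(sm[valley:hi]))
  peak <- cand[which.max(dense[cand])]      # ties: largest raw count
  w <- ceiling(3 * sqrt(peak))
  win <- max(valley, peak - w):min(hi, peak + w)
  mode <- round(sum(win * dense[win]) / sum(dense[win]))
  structure(as.integer(mode), low_confidence = FALSE)
}

#' Estimate genome size and coverage depth from reads
#'
#' Computes the k-mer spectrum, locates the modal k-mer depth, and derives
#' `genome_size_est = total_kmers / kmer_depth_mode` and
#' `coverage_depth_est = total_bases / genome_size_est`. The total k-mer
#' count sums all L-k+1 windows (including N-containing ones -- it
#' measures sequencing volume), while the spectrum peak is located on
#' clean k-mers only.
#'
#' @inheritParams kmer_multiplicity_histogram
#' @param k k-mer size (default 25, standard for depth spectra).
#' @return A `coverage_estimate`: list with `k`, `total_kmers`,
#'   `kmer_depth_mode`, `genome_size_est`, `coverage_depth_est`,
#'   `total_bases`, `low_confidence`.
#' @export
estimate_coverage <- function(reads, k = 25L, canonical = TRUE) {
  stopifnot(is_read_set(reads))
  L <- nchar(reads$sequence)
  total_kmers <- sum(pmax(0, L - k + 1))
  if (total_kmers == 0)
    stop(sprintf("no read is at least k = %d bases long", k), call. = FALSE)
  spec <- kmer_multiplicity_histogram(reads, k, canonical)
  mode <- modal_kmer_depth(spec)
  genome <- total_kmers / as.integer(mode)
  total_bases <- sum(as.numeric(L))
  structure(list(k = as.integer(k), total_kmers = total_kmers,
                 kmer_depth_mode = as.integer(mode),
                 genome_size_est = genome,
                 coverage_depth_est = total_bases / genome,
                 total_bases = total_bases,
                 low_confidence = isTRUE(attr(mode, "low_confidence")),
                 spectrum = spec),
            class = "coverage_estimate")
}

#' @export
print.coverage_estimate <- function(x, ...) {
  cat(sprintf("<coverage_estimate> k = %d: modal k-mer depth %d\n",
              x$k, x$kmer_depth_mode))
  cat(sprintf("  genome size ~ %.0f bp, coverage ~ %.1fx (%.0f total bases)%s\n",
              x$genome_size_est, x$coverage_depth_est, x$total_bases,
              if (x$low_confidence) "  [low confidence]" else ""))
  invisible(x)
}
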