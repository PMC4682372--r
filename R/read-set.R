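# Containers for reads and read pairs.
#
# A read_set is a data.frame with columns read_id, sequence, quality (one
# row per read); a pair_set is a list of two positionally synchronised
# read_sets plus the shared pair identifiers.

#' Construct a set of sequencing reads
#'
#' Builds the package's core container: a `data.frame` subclass
#' (`read_set`) with columns `read_id`, `sequence` and `quality`, one row
#' per read. Validation enforces the FASTQ record invariants: sequence and
#' quality strings of equal, positive length, sequence restricted to the
#' `A/C/G/T/N` alphabet, and every quality character decoding to a Phred
#' score in `[0, 93]` under `offset`.
#'
#' @param read_id Character vector of read identifiers (no leading `@`).
#' @param sequence Character vector of base strings.
#' @param quality Character vector of ASCII-encoded quality strings.
#' @param offset Quality encoding offset, 33 (Sanger) or 64.
#' @param validate Set `FALSE` to skip invariant checks (internal use when
#'   the inputs are known-valid by construction).
#' @return A `read_set`.
#' @examples
#' read_set("r1", "ACGT", "IIII")
#' @export
read_set <- function(read_id, sequence, quality, offset = 33L,
                     validate = TRUE) {
  rs <- data.frame(read_id = as.character(read_id),
                   sequence = as.character(sequence),
                   quality = as.character(quality),
                   stringsAsFactors = FALSE)
  class(rs) <- c("read_set", "data.frame")
  if (validate && nrow(rs) > 0L) validate_read_set(rs, offset)
  rs
}

#' @rdname read_set
#' @param x Object to test.
#' @export
is_read_set <- function(x) inherits(x, "read_set")

validate_read_set <- function(rs, offset = 33L) {
  check_offset(offset)
  ls <- nchar(rs$sequence)
  lq <- nchar(rs$quality)
  bad <- which(ls != lq)
  if (length(bad))
    stop(sprintf("record %d ('%s'): sequence length %d != quality length %d",
                 bad[1L], rs$read_id[bad[1L]], ls[bad[1L]], lq[bad[1L]]),
         call. = FALSE)
  bad <- which(ls < 1L)
  if (length(bad))
    stop(sprintf("record %d ('%s'): empty sequence", bad[1L],
                 rs$read_id[bad[1L]]), call. = FALSE)
  bad <- grep("[^ACGTNacgtn]", rs$sequence)
  if (length(bad))
    stop(sprintf("record %d ('%s'): sequence contains non-ACGTN characters",
                 bad[1L], rs$read_id[bad[1L]]), call. = FALSE)
  qv <- utf8ToInt(paste(rs$quality, collapse = ""))
  off <- which(qv < 33L | qv > 126L | qv - offset < 0L | qv - offset > 93L)
  if (length(off)) {
    rec <- rep.int(seq_len(nrow(rs)), lq)[off[1L]]
    stop(sprintf(
      "record %d ('%s'): quality character '%s' outside valid range for offset %d",
      rec, rs$read_id[rec], intToUtf8(qv[off[1L]]), offset), call. = FALSE)
  }
  invisible(rs)
}

check_offset <- function(offset) {
  if (!offset %in% c(33L, 64L))
    stop("quality offset must be 33 (Phred+33/Sanger) or 64 (Phred+64)",
         call. = FALSE)
  invisible(as.integer(offset))
}

# Decoded quality scores for every read, as a list of integer vectors in
# read order. Vectorised: one utf8ToInt call over the concatenation.
qual_ints <- function(reads, offset = 33L) {
  n <- nrow(reads)
  if (n == 0L) return(list())
  lens <- nchar(reads$quality)
  all <- utf8ToInt(paste(reads$quality, collapse = "")) - as.integer(offset)
  unname(split(all, factor(rep.int(seq_len(n), lens), levels = seq_len(n))))
}

#' Bind two mates into a set of read pairs
#'
#' A `pair_set` holds two positionally synchronised [read_set()]s plus the
#' shared pair identifier of each pair (the identifier stem after stripping
#' a trailing `/1` or `/2` mate tag, or the first whitespace-delimited
#' token for CASAVA 1.8-style headers). Construction fails with a
#' desynchronisation error if any two mates disagree on their stem.
#'
#' @param mate1,mate2 `read_set`s of equal length.
#' @return A `pair_set` (list with elements `pair_id`, `mate1`, `mate2`).
#' @examples
#' p <- pair_set(read_set("r1/1", "ACGT", "IIII"),
#'               read_set("r1/2", "TTTT", "IIII"))
#' n_pairs(p)
#' @export
pair_set <- function(mate1, mate2) {
  stopifnot(is_read_set(mate1), is_read_set(mate2))
  if (nrow(mate1) != nrow(mate2))
    stop(sprintf("mate files differ in record count (%d vs %d)",
                 nrow(mate1), nrow(mate2)), call. = FALSE)
  s1 <- pair_id_stem(mate1$read_id)
  s2 <- pair_id_stem(mate2$read_id)
  bad <- which(s1 != s2)
  if (length(bad))
    stop(sprintf("desynchronized pair at position %d: '%s' vs '%s'",
                 bad[1L], mate1$read_id[bad[1L]], mate2$read_id[bad[1L]]),
         call. = FALSE)
  rownames(mate1) <- NULL
  rownames(mate2) <- NULL
  structure(list(pair_id = s1, mate1 = mate1, mate2 = mate2),
            class = "pair_set")
}

#' @rdname pair_set
#' @param x A `pair_set`.
#' @export
n_pairs <- function(x) {
  stopifnot(inherits(x, "pair_set"))
  length(x$pair_id)
}

#' @export
`[.pair_set` <- function(x, i, ...) {
  m1 <- x$mate1[i, , drop = FALSE]
  m2 <- x$mate2[i, , drop = FALSE]
  rownames(m1) <- NULL
  rownames(m2) <- NULL
  structure(list(pair_id = x$pair_id[i], mate1 = m1, mate2 = m2),
            class = "pair_set")
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("<pair_set> %d read pairs\n", n_pairs(x)))
  if (n_pairs(x) > 0L)
    cat(sprintf("  first pair: %s (%d bp / %d bp)\n", x$pair_id[1L],
                nchar(x$mate1$sequence[1L]), nchar(x$mate2$sequence[1L])))
  invisible(x)
}

#' Shared identifier stem of paired-read headers
#'
#' Strips a trailing `/1` or `/2` mate tag; otherwise takes the first
#' whitespace-delimited token (Illumina CASAVA 1.8 headers carry the mate
#' number in the comment field).
#'
#' @param read_id Character vector of read identifiers.
#' @return Character vector of pair-identifier stems.
#' @export
pair_id_stem <- function(read_id) {
  tagged <- grepl("/[12]$", read_id)
  out <- read_id
  out[tagged] <- sub("/[12]$", "", read_id[tagged])
  out[!tagged] <- sub("[ \t].*$", "", read_id[!tagged])
  out
}

# Interleave a pair_set back into a single read_set (mate1, mate2, ...).
interleave_pairs <- function(pairs) {
  n <- n_pairs(pairs)
  idx <- rep(seq_len(n), each = 2L)
  m <- rep(c(TRUE, FALSE), n)
  out <- pairs$mate1[idx, , drop = FALSE]
  out[!m, ] <- pairs$mate2[idx[!m], , drop = FALSE]
  rownames(out) <- NULL
  out
}
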