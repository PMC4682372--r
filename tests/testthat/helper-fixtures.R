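# Shared test helpers: quality-string encoding and tiny FASTQ files built
# in code.

qchar <- function(q, offset = 33L) intToUtf8(q + offset)

# read_set with the given integer quality vectors; bases are all "A".
rs_from_quals <- function(..., offset = 33L) {
  quals <- list(...)
  read_set(sprintf("r%d", seq_along(quals)),
           vapply(quals, function(q) strrep("A", length(q)), character(1)),
           vapply(quals, qchar, character(1), offset = offset),
           offset = offset)
}

write_fastq_lines <- function(reads, path) {
  write_subset(reads, path, format = "fastq")
  path
}

tmp_fastq <- function(reads, ext = ".fastq") {
  f <- tempfile(fileext = ext)
  write_subset(reads, f, format = "fastq")
  f
}

# brute-force per-window ProductQ oracle, independent of the prefix-sum path
brute_kmer_min_pq <- function(q, k) {
  L <- length(q)
  if (L <= k) return(prod(1 - 10^(-q / 10)))
  min(vapply(1:(L - k + 1), function(i) prod(1 - 10^(-q[i:(i + k - 1)] / 10)),
             numeric(1)))
}
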