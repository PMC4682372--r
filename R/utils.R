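# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never perturb user
# randomness.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character strings in the
#' `A/C/G/T/N` alphabet (case preserved).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @examples
#' revcomp(c("ACGT", "AANG"))
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1L),
         USE.NAMES = FALSE)
}

# Wrap a string at `width` columns; returns a character vector of lines.
wrap_seq <- function(s, width = 80L) {
  n <- nchar(s)
  if (n <= width) return(s)
  starts <- seq.int(1L, n, by = width)
  substring(s, starts, pmin(starts + width - 1L, n))
}
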