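## Small shared helpers. Sequences are uppercase character strings over
## {A,C,G,T,N}; qualities travel as integer vectors or Phred+33 strings.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of nucleotide strings
#'
#' @param x character vector of sequences over {A,C,G,T,N}.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE), function(s) {
    paste(rev(s), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

complement_base <- function(b) {
  chartr("ACGTN", "TGCAN", b)
}

## Phred+33 encode/decode
qual_to_string <- function(q) {
  vapply(q, function(qq) rawToChar(as.raw(qq + 33L)), character(1))
}

string_to_qual <- function(s) {
  lapply(s, function(ss) as.integer(charToRaw(ss)) - 33L)
}

## constant quality character for an error rate (capped to [2, 60])
error_rate_to_q <- function(error_rate) {
  if (error_rate <= 0) return(60L)
  min(60L, max(2L, as.integer(round(-10 * log10(error_rate)))))
}

clamp01 <- function(x) pmin(1, pmax(0, x))

`%||%` <- function(a, b) if (is.null(a)) b else a

## split a string into single characters
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

## deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 1000L + as.integer(offset)) %% 2147483587L
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != round(x)) {
    stop(sprintf("`%s` must be a positive integer count", name), call. = FALSE)
  }
}

## evaluate code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% 2147483587L)
  code
}

## random DNA string(s)
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}
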