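## Read-level preprocessing: exact adapter trimming, then the length and
## per-position quality filters. Order is fixed: trim, length, quality;
## a read failing both filters is tallied once, under length.

#' Filter configuration for read preprocessing
#'
#' @param min_length,max_length retained read-length range (defaults 15-28).
#' @param min_quality minimum Phred score required at every position
#'   (default 30, i.e. an error rate of 0.1\%; 20 in relaxed mode).
#' @param adapter 3' adapter sequence, or "" for no trimming.
#' @return a \code{filter_config} list.
#' @export
filter_config <- function(min_length = 15L, max_length = 28L,
                          min_quality = 30L, adapter = "") {
  stopifnot(min_length > 0, min_length <= max_length,
            min_quality >= 0, min_quality <= 60)
  structure(list(min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 min_quality = as.integer(min_quality),
                 adapter = toupper(adapter)),
            class = "filter_config")
}

#' Trim a 3' adapter from reads
#'
#' The full adapter found anywhere in the read, or an adapter prefix of at
#' least \code{min_overlap} bases matching exactly at the read's 3' end, is
#' removed together with everything 3' of it. Qualities are trimmed in
#' lockstep. Reads without a match are returned unchanged.
#'
#' @param reads a small-read \code{data.frame}.
#' @param adapter non-empty adapter sequence.
#' @param min_overlap minimum exact suffix-anchored overlap (default 8).
#' @return the reads with trimmed \code{seq}/\code{qual}.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 8L) {
  adapter <- toupper(adapter)
  if (!nzchar(adapter)) stop("adapter must be non-empty", call. = FALSE)
  cut_at <- rep(NA_integer_, nrow(reads))
  ## full adapter anywhere
  hit <- regexpr(adapter, reads$seq, fixed = TRUE)
  cut_at[hit > 0] <- hit[hit > 0]
  ## suffix-anchored adapter prefix, longest first
  len <- nchar(reads$seq)
  max_pref <- min(nchar(adapter) - 1L, max(0L, max(len)))
  if (max_pref >= min_overlap) {
    for (k in seq(max_pref, min_overlap)) {
      pref <- substr(adapter, 1L, k)
      cand <- which(is.na(cut_at) & len >= k)
      if (!length(cand)) next
      ok <- substr(reads$seq[cand], len[cand] - k + 1L, len[cand]) == pref
      cut_at[cand[ok]] <- len[cand[ok]] - k + 1L
    }
  }
  w <- which(!is.na(cut_at))
  if (length(w)) {
    reads$seq[w] <- substr(reads$seq[w], 1L, cut_at[w] - 1L)
    reads$qual[w] <- substr(reads$qual[w], 1L, cut_at[w] - 1L)
    reads$has_n <- grepl("N", reads$seq, fixed = TRUE)
  }
  reads
}

#' Apply the length and quality read filters
#'
#' Keeps reads with \code{min_length <= length <= max_length} whose every
#' position has Phred quality \code{>= min_quality}. N bases count as
#' quality 0. Trims the adapter first when \code{config$adapter} is set.
#'
#' @param reads a small-read \code{data.frame}.
#' @param config a \code{\link{filter_config}}.
#' @return list with \code{kept} (filtered reads) and \code{tally}
#'   (named counts: input, kept, rejected_length, rejected_quality).
#' @export
filter_reads <- function(reads, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  n_in <- nrow(reads)
  if (is.null(reads$has_n)) {
    reads$has_n <- grepl("N", reads$seq, fixed = TRUE)
  }
  if (nzchar(config$adapter) && n_in) {
    reads <- trim_adapter(reads, config$adapter)
  }
  len <- nchar(reads$seq)
  ok_len <- len >= config$min_length & len <= config$max_length
  minq <- min_quality_per_read(reads)
  ok_q <- minq >= config$min_quality & !reads$has_n
  keep <- ok_len & ok_q
  tally <- c(input = n_in, kept = sum(keep),
             rejected_length = sum(!ok_len),
             rejected_quality = sum(ok_len & !ok_q))
  list(kept = reads[keep, , drop = FALSE], tally = tally)
}

## minimum Phred score per read (Inf for empty reads)
min_quality_per_read <- function(reads) {
  if (!nrow(reads)) return(numeric(0))
  vapply(reads$qual, function(q) {
    if (!nzchar(q)) return(Inf)
    min(as.integer(charToRaw(q))) - 33
  }, numeric(1), USE.NAMES = FALSE)
}
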