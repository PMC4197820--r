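## FASTQ IO. Reads are carried as a data.frame with columns
## read_id, seq, qual (Phred+33 string) and, when known, has_n.
## Parsing is strict: 4-line records, '@'/'+' markers, sequence and quality
## of equal length, qualities within [0, 60].

#' Construct a validated small-read table
#'
#' @param read_id character vector of read identifiers.
#' @param seq uppercase sequences over \{A,C,G,T,N\}.
#' @param qual either a list of integer Phred scores or a character vector of
#'   Phred+33 strings, one per read, same lengths as \code{seq}.
#' @return a \code{data.frame} with columns \code{read_id}, \code{seq},
#'   \code{qual} (Phred+33 string), \code{has_n} (logical flag for reads
#'   containing N bases).
#' @export
small_reads <- function(read_id, seq, qual) {
  seq <- toupper(seq)
  if (is.list(qual)) qual <- qual_to_string(qual)
  stopifnot(length(read_id) == length(seq), length(seq) == length(qual))
  bad_len <- which(nchar(seq) != nchar(qual))
  if (length(bad_len)) {
    stop(sprintf("sequence/quality length mismatch for record %d (%s)",
                 bad_len[1], read_id[bad_len[1]]), call. = FALSE)
  }
  if (length(seq) && any(grepl("[^ACGTN]", seq))) {
    stop("sequences must be over {A,C,G,T,N}", call. = FALSE)
  }
  qmax <- if (length(qual)) max(c(-1L, unlist(string_to_qual(qual)))) else 0L
  qmin <- if (length(qual)) min(c(61L, unlist(string_to_qual(qual)))) else 0L
  if (length(qual) && (qmax > 60L || qmin < 0L)) {
    stop("Phred qualities must lie in [0, 60]", call. = FALSE)
  }
  data.frame(read_id = as.character(read_id), seq = seq, qual = qual,
             has_n = grepl("N", seq, fixed = TRUE),
             stringsAsFactors = FALSE)
}

#' Read a FASTQ file (Phred+33)
#'
#' Validates 4-line record structure; N bases are permitted but flagged in
#' the \code{has_n} column. A trailing partial record is a format error
#' naming the first incomplete record.
#'
#' @param path path to an uncompressed or gzipped FASTQ file.
#' @return a small-read \code{data.frame}; see \code{\link{small_reads}}.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  n_complete <- length(lines) %/% 4L
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("truncated FASTQ record %d in %s", n_complete + 1L, path),
         call. = FALSE)
  }
  if (n_complete == 0L) {
    return(small_reads(character(0), character(0), character(0)))
  }
  idx <- seq_len(n_complete)
  hdr <- lines[4L * idx - 3L]
  seq <- lines[4L * idx - 2L]
  plus <- lines[4L * idx - 1L]
  qual <- lines[4L * idx]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad)) {
    stop(sprintf("malformed FASTQ record %d in %s", bad[1], path),
         call. = FALSE)
  }
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad)) {
    stop(sprintf("sequence/quality length mismatch in FASTQ record %d of %s",
                 bad[1], path), call. = FALSE)
  }
  small_reads(sub("^@", "", sub("\\s.*$", "", hdr)), seq, qual)
}

#' Write reads to a FASTQ file (Phred+33)
#'
#' @param reads a small-read \code{data.frame}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads)) {
    out <- rbind(paste0("@", reads$read_id), reads$seq, "+", reads$qual)
    writeLines(as.vector(out), path)
  } else {
    writeLines(character(0), path)
  }
  invisible(path)
}
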