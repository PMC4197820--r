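## Seed-and-extend short-read alignment with at most one mismatch (two in
## relaxed mode), best-stratum semantics and a 3' trim retry. The exact
## k-mer seed length defaults to 7: with m allowed mismatches a read is cut
## into at most m+1 exact stretches, so m+1 non-overlapping 7-mer seeds
## guarantee full sensitivity for any read of length >= 7*(m+1) -- which
## covers the 15-nt minimum read length at one mismatch. Reads too short
## for the seed scheme fall back to a full sliding-window scan.
##
## A brute-force aligner with the identical return contract serves as the
## independent oracle in the test suite.

#' Alignment policy
#'
#' @param max_mismatches maximum mismatches per alignment (0, 1 or 2;
#'   default 1).
#' @param multimap_limit maximum number of best-stratum hits tolerated
#'   before a read is suppressed (default 1; 5 in relaxed mode).
#' @param trim_retry retry unmapped reads with 1 then 2 bases removed from
#'   the 3' end (default TRUE).
#' @return an \code{align_policy} list.
#' @export
align_policy <- function(max_mismatches = 1L, multimap_limit = 1L,
                         trim_retry = TRUE) {
  stopifnot(max_mismatches %in% 0:2, multimap_limit >= 1)
  structure(list(max_mismatches = as.integer(max_mismatches),
                 multimap_limit = as.integer(multimap_limit),
                 trim_retry = isTRUE(trim_retry)),
            class = "align_policy")
}

#' Build an exact k-mer index over reference contigs
#'
#' @param contigs named list/vector of contig sequences.
#' @param k seed length (default 7; see the sensitivity note in the
#'   package sources).
#' @return an \code{align_index}.
#' @export
build_index <- function(contigs, k = 7L) {
  contigs <- as.list(contigs)
  stopifnot(length(contigs) >= 1L, !is.null(names(contigs)))
  sep <- strrep("N", 3L)
  genome <- paste(unlist(contigs), collapse = sep)
  lens <- unname(nchar(unlist(contigs)))
  starts <- cumsum(c(1L, head(lens + 3L, -1L)))  # global 1-based starts
  ends <- starts + lens - 1L
  gint <- as.integer(charToRaw(genome))
  n <- nchar(genome)
  kmap <- new.env(hash = TRUE, size = max(16L, n))
  if (n >= k) {
    pos <- seq_len(n - k + 1L)
    kmers <- substring(genome, pos, pos + k - 1L)
    valid <- !grepl("N", kmers, fixed = TRUE)
    spl <- split(pos[valid], kmers[valid])
    for (nm in names(spl)) assign(nm, spl[[nm]], envir = kmap)
  }
  structure(list(genome = genome, gint = gint, k = as.integer(k),
                 contig_names = names(contigs),
                 contig_starts = starts, contig_ends = ends,
                 kmap = kmap),
            class = "align_index")
}

## exact k-mer lookup (global 1-based positions on the forward genome)
kmer_lookup <- function(index, kmer) {
  get0(kmer, envir = index$kmap, ifnotfound = integer(0))
}

## enumerate all alignments of q (forward orientation) on the forward
## genome with <= max_mm mismatches; returns global starts + mismatch counts
enumerate_hits <- function(q, index, max_mm) {
  L <- nchar(q)
  k <- index$k
  n_seed <- max_mm + 1L
  qint <- as.integer(charToRaw(q))
  nG <- length(index$gint)
  if (L > nG) return(list(start = integer(0), mm = integer(0)))
  if (L >= n_seed * k) {
    offs <- (seq_len(n_seed) - 1L) * k
    cand <- unique(unlist(lapply(offs, function(o) {
      kmer_lookup(index, substr(q, o + 1L, o + k)) - o
    })))
    cand <- cand[cand >= 1L & cand <= nG - L + 1L]
  } else {
    ## sliding-window fallback for reads too short for the seed scheme
    cnt <- integer(nG - L + 1L)
    for (j in seq_len(L)) {
      cnt <- cnt + (index$gint[j:(nG - L + j)] != qint[j])
    }
    cand <- which(cnt <= max_mm)
  }
  if (!length(cand)) return(list(start = integer(0), mm = integer(0)))
  ## in-contig check
  ci <- findInterval(cand, index$contig_starts)
  ok <- ci >= 1L & cand + L - 1L <= index$contig_ends[ci]
  cand <- cand[ok]
  if (!length(cand)) return(list(start = integer(0), mm = integer(0)))
  mm <- vapply(cand, function(s) {
    sum(index$gint[s:(s + L - 1L)] != qint)
  }, integer(1))
  keep <- mm <= max_mm
  list(start = cand[keep], mm = mm[keep])
}

## single-sequence alignment against the index; no trim logic here
align_core <- function(seq, index, policy) {
  L <- nchar(seq)
  qf <- seq
  qr <- revcomp(seq)
  hf <- enumerate_hits(qf, index, policy$max_mismatches)
  hr <- enumerate_hits(qr, index, policy$max_mismatches)
  start <- c(hf$start, hr$start)
  if (!length(start)) return(list(state = "unmapped"))
  strand <- rep(c("+", "-"), c(length(hf$start), length(hr$start)))
  mm <- c(hf$mm, hr$mm)
  stratum <- min(mm)
  best <- which(mm == stratum)
  if (length(best) > policy$multimap_limit) {
    return(list(state = "suppressed", n_best = length(best),
                stratum = stratum))
  }
  ## deterministic order: global position, then + before -
  ord <- best[order(start[best], strand[best])]
  s <- start[ord[1]]
  str <- strand[ord[1]]
  q <- if (str == "+") qf else qr
  qint <- as.integer(charToRaw(q))
  mmj <- which(index$gint[s:(s + L - 1L)] != qint)   # positions in q
  ci <- findInterval(s, index$contig_starts)
  local0 <- s - index$contig_starts[ci]              # 0-based on contig
  if (length(mmj)) {
    refb <- substring(index$genome, s + mmj - 1L, s + mmj - 1L)
    if (str == "+") {
      off0 <- mmj - 1L
      readb <- substring(q, mmj, mmj)
    } else {
      off0 <- L - mmj
      refb <- complement_base(refb)
      readb <- complement_base(substring(q, mmj, mmj))
    }
    o <- order(off0)
    mismatches <- data.frame(offset = off0[o], ref = refb[o],
                             read = readb[o], stringsAsFactors = FALSE)
  } else {
    mismatches <- data.frame(offset = integer(0), ref = character(0),
                             read = character(0))
  }
  list(state = "mapped", contig = index$contig_names[ci], start = local0,
       strand = str, n_mismatch = stratum, mismatches = mismatches,
       n_best = length(best))
}

#' Align one read with best-stratum semantics and 3' trim retry
#'
#' Enumerates all alignments with at most \code{policy$max_mismatches}
#' mismatches on both strands. Perfect alignments (stratum 0) beat
#' one-mismatch alignments. If the best stratum holds more hits than
#' \code{policy$multimap_limit} the read is suppressed; if the read is
#' unmapped and trim retry is on, alignment is retried with 1 and then 2
#' bases removed from the 3' end, stopping at the first mappable state.
#'
#' @param seq read sequence (character scalar).
#' @param index an \code{\link{build_index}} result.
#' @param policy an \code{\link{align_policy}}.
#' @return list with \code{state} ("mapped", "unmapped" or "suppressed")
#'   and, when mapped: \code{contig}, \code{start} (0-based), \code{strand},
#'   \code{trim}, \code{aligned_length}, \code{n_mismatch},
#'   \code{mismatches} (offset/ref/read in read orientation, 0-based
#'   offsets from the read 5' end) and \code{n_best}.
#' @export
align_read <- function(seq, index, policy = align_policy()) {
  L <- nchar(seq)
  trims <- if (policy$trim_retry) 0:2 else 0L
  res <- list(state = "unmapped")
  for (tr in trims) {
    if (L - tr < 1L) break
    res <- align_core(substr(seq, 1L, L - tr), index, policy)
    if (res$state != "unmapped") {
      res$trim <- tr
      res$aligned_length <- L - tr
      return(res)
    }
  }
  res$trim <- NA_integer_
  res
}

#' Align a batch of reads
#'
#' Identical sequences are aligned once and the result reused.
#'
#' @param reads small-read \code{data.frame}.
#' @param index an alignment index.
#' @param policy an \code{\link{align_policy}}.
#' @return \code{data.frame}: read_id, state, contig, start, strand, trim,
#'   aligned_length, n_mismatch, n_best and \code{mismatches} (descriptor
#'   string \code{offset:ref>read}, ";"-joined, "" for perfect hits);
#'   extra read columns (e.g. sample_id) are carried through.
#' @export
align_reads <- function(reads, index, policy = align_policy()) {
  useq <- unique(reads$seq)
  res <- lapply(useq, align_read, index = index, policy = policy)
  fmt <- function(r) {
    if (r$state != "mapped") {
      return(data.frame(state = r$state, contig = NA_character_,
                        start = NA_integer_, strand = NA_character_,
                        trim = if (is.null(r$trim)) NA_integer_ else r$trim,
                        aligned_length = NA_integer_,
                        n_mismatch = NA_integer_,
                        n_best = if (is.null(r$n_best)) NA_integer_ else r$n_best,
                        mismatches = NA_character_,
                        stringsAsFactors = FALSE))
    }
    data.frame(state = "mapped", contig = r$contig, start = r$start,
               strand = r$strand, trim = r$trim,
               aligned_length = r$aligned_length,
               n_mismatch = r$n_mismatch, n_best = r$n_best,
               mismatches = mismatch_descriptor(r$mismatches),
               stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, lapply(res, fmt))
  idx <- match(reads$seq, useq)
  out <- cbind(reads[, setdiff(names(reads), "qual"), drop = FALSE],
               tab[idx, , drop = FALSE])
  rownames(out) <- NULL
  out
}

mismatch_descriptor <- function(mm) {
  if (is.null(mm) || nrow(mm) == 0L) return("")
  paste(sprintf("%d:%s>%s", mm$offset, mm$ref, mm$read), collapse = ";")
}

parse_mismatch_descriptor <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(data.frame(offset = integer(0), ref = character(0),
                      read = character(0)))
  }
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "[:>]")
  data.frame(offset = as.integer(vapply(parts, `[`, "", 1L)),
             ref = vapply(parts, `[`, "", 2L),
             read = vapply(parts, `[`, "", 3L), stringsAsFactors = FALSE)
}

#' Brute-force alignment oracle
#'
#' Sliding-window comparison at every position of every contig on both
#' strands, with the same return contract (including trim retry and
#' best-stratum/multimap semantics) as \code{\link{align_read}}.
#'
#' @param seq read sequence.
#' @param contigs named list of contig sequences.
#' @param policy an \code{\link{align_policy}}.
#' @return same shape as \code{\link{align_read}}.
#' @export
brute_force_align <- function(seq, contigs, policy = align_policy()) {
  contigs <- as.list(contigs)
  trims <- if (policy$trim_retry) 0:2 else 0L
  res <- list(state = "unmapped", trim = NA_integer_)
  for (tr in trims) {
    q0 <- substr(seq, 1L, nchar(seq) - tr)
    if (nchar(q0) < 1L) break
    res <- brute_force_core(q0, contigs, policy)
    if (res$state != "unmapped") {
      res$trim <- tr
      res$aligned_length <- nchar(q0)
      return(res)
    }
    res$trim <- NA_integer_
  }
  res
}

brute_force_core <- function(q0, contigs, policy) {
  L <- nchar(q0)
  hits <- list()
  for (ci in seq_along(contigs)) {
    cseq <- contigs[[ci]]
    nC <- nchar(cseq)
    if (nC < L) next
    cint <- as.integer(charToRaw(cseq))
    for (str in c("+", "-")) {
      q <- if (str == "+") q0 else revcomp(q0)
      qint <- as.integer(charToRaw(q))
      cnt <- integer(nC - L + 1L)
      for (j in seq_len(L)) cnt <- cnt + (cint[j:(nC - L + j)] != qint[j])
      for (s in which(cnt <= policy$max_mismatches)) {
        hits[[length(hits) + 1L]] <- list(ci = ci, s = s, strand = str,
                                          mm = cnt[s])
      }
    }
  }
  if (!length(hits)) return(list(state = "unmapped"))
  mm <- vapply(hits, `[[`, 0L, "mm")
  stratum <- min(mm)
  best <- which(mm == stratum)
  if (length(best) > policy$multimap_limit) {
    return(list(state = "suppressed", n_best = length(best),
                stratum = stratum))
  }
  ord <- order(vapply(hits[best], `[[`, 0L, "ci"),
               vapply(hits[best], `[[`, 0L, "s"),
               vapply(hits[best], `[[`, "", "strand"))
  h <- hits[[best[ord[1]]]]
  cseq <- contigs[[h$ci]]
  q <- if (h$strand == "+") q0 else revcomp(q0)
  win <- substr(cseq, h$s, h$s + L - 1L)
  wj <- which(chars(win) != chars(q))
  if (length(wj)) {
    refb <- substring(win, wj, wj)
    if (h$strand == "+") {
      off0 <- wj - 1L; readb <- substring(q, wj, wj)
    } else {
      off0 <- L - wj
      refb <- complement_base(refb)
      readb <- complement_base(substring(q, wj, wj))
    }
    o <- order(off0)
    mismatches <- data.frame(offset = off0[o], ref = refb[o],
                             read = readb[o], stringsAsFactors = FALSE)
  } else {
    mismatches <- data.frame(offset = integer(0), ref = character(0),
                             read = character(0))
  }
  list(state = "mapped", contig = names(contigs)[h$ci], start = h$s - 1L,
       strand = h$strand, n_mismatch = h$mm, mismatches = mismatches,
       n_best = length(best))
}
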