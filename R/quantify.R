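## Remapping-based editing-frequency estimation. For each conserved event
## the annotated sequence is extracted with 10 nt of genomic context on
## either side in three versions: unedited, edited (G at the site) and
## fake-edited (G at the nearest other A, an error-background control).
## Quality-filtered reads are counted for a version iff they match it
## exactly (no mismatches; a read may start and end anywhere inside the
## reference, so 3' non-templated tails must have been trimmed) and span
## that version's variant site. Reads consistent with more than one
## version, or spanning no site, are discarded.

#' Build edited / unedited / fake-edited variant references
#'
#' @param species,mirna_id,arm identify the annotation row.
#' @param position 1-based edited position within the annotated sequence;
#'   must be A in the unedited sequence.
#' @param bundle a \code{ref_bundle}.
#' @param flank genomic context on either side (default 10).
#' @return a \code{variant_refs} list: \code{refs} (named character:
#'   unedited, edited and usually fake), \code{site_offset} and
#'   \code{fake_offset} (1-based within the reference sequences),
#'   \code{mature_start0} (0-based offset of the annotated 5' end) and
#'   identity fields. The fake reference is omitted with a warning when no
#'   other A exists in the window.
#' @export
build_variant_refs <- function(species, mirna_id, position, bundle,
                               arm = "mature", flank = 10L) {
  ann <- bundle$annotations
  row <- ann[ann$species == species & ann$mirna_id == mirna_id &
               ann$arm == arm, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop(sprintf("no unique annotation for %s/%s/%s", species, mirna_id,
                 arm), call. = FALSE)
  }
  row <- row[1, ]
  ctg <- unlist(bundle$contigs)[[row$contig]]
  if (row$strand == "+") {
    s <- max(0L, row$start - flank)
    e <- min(nchar(ctg), row$end + flank)
    seq <- substr(ctg, s + 1L, e)
    up <- row$start - s
  } else {
    s <- max(0L, row$start - flank)
    e <- min(nchar(ctg), row$end + flank)
    seq <- revcomp(substr(ctg, s + 1L, e))
    up <- e - row$end
  }
  site <- up + position
  if (substr(seq, site, site) != "A") {
    stop(sprintf("event site is not A in the unedited sequence (%s/%s pos %d)",
                 species, mirna_id, position), call. = FALSE)
  }
  edited <- seq
  substr(edited, site, site) <- "G"
  refs <- c(unedited = seq, edited = edited)
  ## nearest other A; ties go to the 5' side
  a_pos <- setdiff(which(chars(seq) == "A"), site)
  fake_offset <- NA_integer_
  if (length(a_pos)) {
    d <- abs(a_pos - site)
    cand <- a_pos[d == min(d)]
    fake_offset <- min(cand)                        # 5' on a tie
    fake <- seq
    substr(fake, fake_offset, fake_offset) <- "G"
    refs["fake"] <- fake
  } else {
    warning(sprintf("no other A near site for %s/%s; fake reference omitted",
                    species, mirna_id), call. = FALSE)
  }
  structure(list(refs = refs, site_offset = site, fake_offset = fake_offset,
                 species = species, mirna_id = mirna_id, arm = arm,
                 position = position, mature_start0 = up,
                 mature_len = row$end - row$start),
            class = "variant_refs")
}

#' Count reads against the variant references
#'
#' @param reads small-read \code{data.frame} (quality-filtered, adapter
#'   trimmed).
#' @param vrefs a \code{\link{build_variant_refs}} result.
#' @param sample_id label attached to the output (default "all").
#' @return list with \code{quant} (one-row data.frame: sample_id, mirna_id,
#'   position, edited, unedited, fake, freq = edited/(edited+unedited),
#'   n_discarded) and \code{read_assign} (read_id, kind, offset5: the 5'
#'   start offset relative to the annotated start).
#' @export
remap_and_count <- function(reads, vrefs, sample_id = "all") {
  useq <- unique(reads$seq)
  kinds <- names(vrefs$refs)
  site_of <- c(unedited = vrefs$site_offset, edited = vrefs$site_offset,
               fake = vrefs$fake_offset)
  ## for each unique read sequence, the set of versions it supports
  assign_kind <- rep(NA_character_, length(useq))
  offset5 <- rep(NA_integer_, length(useq))
  for (i in seq_along(useq)) {
    q <- useq[i]
    L <- nchar(q)
    matched <- character(0)
    moff <- NA_integer_
    for (kd in kinds) {
      st <- site_of[[kd]]
      hit <- gregexpr(q, vrefs$refs[[kd]], fixed = TRUE)[[1]]
      if (hit[1] == -1L) next
      spanning <- hit[hit <= st & hit + L - 1L >= st]
      if (length(spanning)) {
        matched <- c(matched, kd)
        if (kd %in% c("edited", "unedited")) {
          moff <- spanning[1] - 1L - vrefs$mature_start0
        }
      }
    }
    if (length(matched) == 1L) {
      assign_kind[i] <- matched
      offset5[i] <- moff
    }
  }
  idx <- match(reads$seq, useq)
  kind <- assign_kind[idx]
  read_assign <- data.frame(read_id = reads$read_id, kind = kind,
                            offset5 = offset5[idx],
                            stringsAsFactors = FALSE)
  read_assign <- read_assign[!is.na(read_assign$kind), , drop = FALSE]
  counts <- c(edited = sum(kind == "edited", na.rm = TRUE),
              unedited = sum(kind == "unedited", na.rm = TRUE),
              fake = sum(kind == "fake", na.rm = TRUE))
  quant <- data.frame(sample_id = sample_id, mirna_id = vrefs$mirna_id,
                      position = vrefs$position,
                      edited = counts[["edited"]],
                      unedited = counts[["unedited"]],
                      fake = counts[["fake"]],
                      freq = editing_frequency(counts[["edited"]],
                                               counts[["unedited"]]),
                      n_discarded = sum(is.na(kind)),
                      stringsAsFactors = FALSE)
  list(quant = quant, read_assign = read_assign)
}

#' Editing frequency from variant counts
#'
#' @param edited,unedited read counts of the two variants.
#' @return edited / (edited + unedited); NA when no reads span the site.
#' @export
editing_frequency <- function(edited, unedited) {
  den <- edited + unedited
  ifelse(den > 0, edited / den, NA_real_)
}

#' Check counted reads for perfect matches elsewhere in the genome
#'
#' @param reads small-read \code{data.frame} of counted reads.
#' @param contigs named contig sequences (the relevant genome).
#' @param variant_loci data.frame of intervals belonging to the variant
#'   reference set (contig, start, end; 0-based half-open), typically the
#'   annotated intervals padded by the flank.
#' @return list: \code{n_reads}, \code{n_crossmap}, \code{fraction} and a
#'   per-read logical \code{flagged}.
#' @export
crossmap_check <- function(reads, contigs, variant_loci) {
  contigs <- as.list(contigs)
  useq <- unique(reads$seq)
  flagged_u <- vapply(useq, function(q) {
    L <- nchar(q)
    for (strand in c("+", "-")) {
      qq <- if (strand == "+") q else revcomp(q)
      for (cn in names(contigs)) {
        hit <- gregexpr(qq, contigs[[cn]], fixed = TRUE)[[1]]
        if (hit[1] == -1L) next
        for (s in hit) {
          s0 <- s - 1L
          inside <- any(variant_loci$contig == cn &
                          variant_loci$start <= s0 &
                          variant_loci$end >= s0 + L)
          if (!inside) return(TRUE)
        }
      }
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE)
  flagged <- flagged_u[match(reads$seq, useq)]
  list(n_reads = nrow(reads), n_crossmap = sum(flagged),
       fraction = if (nrow(reads)) sum(flagged) / nrow(reads) else 0,
       flagged = flagged)
}

#' 5' isomiR-by-editing breakdown
#'
#' Classifies counted reads by their 5' start offset relative to the
#' annotated miRNA start and by edited status, keeps the two offsets under
#' study (annotated start and -1 by default), and tests independence with
#' a chi-squared test on the 2x2 table (1 df, no continuity correction).
#'
#' @param read_assign \code{read_assign} table from
#'   \code{\link{remap_and_count}} (edited/unedited rows are used).
#' @param offsets the two 5' offsets to compare (default \code{c(0, -1)}).
#' @return list: \code{table} (offset x kind counts), \code{statistic},
#'   \code{p_value}, \code{low_expectation} (TRUE when any expected cell
#'   count is below 5, attached as a warning flag).
#' @export
isomir_editing_breakdown <- function(read_assign, offsets = c(0L, -1L)) {
  ra <- read_assign[read_assign$kind %in% c("edited", "unedited") &
                      read_assign$offset5 %in% offsets, , drop = FALSE]
  tab <- table(factor(ra$offset5, levels = offsets),
               factor(ra$kind, levels = c("edited", "unedited")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(table = tab, statistic = NA_real_, p_value = NA_real_,
                low_expectation = TRUE))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(table = tab, statistic = unname(ct$statistic),
       p_value = ct$p.value,
       low_expectation = any(ct$expected < 5))
}
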