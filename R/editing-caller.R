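## Per-site mismatch tallying inside annotated mature/star miRNAs, and the
## candidate-site filter battery: edge exclusion (first base / last two
## bases of the read or of the annotated sequence), perfect-read coverage,
## multiple-mismatch-type rejection, the 5%/five-read high tier, the 1%
## relaxed tier, trace classification and SNP overlap.

#' Caller thresholds
#'
#' @param high_min_reads minimum reads for each variant at the high tier
#'   (default 5).
#' @param high_min_frac minimum mismatch fraction of the miRNA's tissue
#'   read total at the high tier (default 0.05).
#' @param relaxed_min_freq minimum site-level mismatch frequency at the
#'   relaxed tier (default 0.01).
#' @param error_rate sequencing error rate used by the multiple-mismatch-
#'   type filter (default 0.001).
#' @return a \code{caller_config} list.
#' @export
caller_config <- function(high_min_reads = 5L, high_min_frac = 0.05,
                          relaxed_min_freq = 0.01, error_rate = 0.001) {
  structure(list(high_min_reads = as.integer(high_min_reads),
                 high_min_frac = high_min_frac,
                 relaxed_min_freq = relaxed_min_freq,
                 error_rate = error_rate),
            class = "caller_config")
}

#' Tally mismatches per site within annotated miRNAs
#'
#' Every mismatch of a mapped read lying inside an annotation on the same
#' strand increments the site/change-type counter in miRNA-sense
#' orientation (a genomic T>C under a minus-strand miRNA is recorded A>G).
#' Mismatches in the first or last two bases of the annotated sequence are
#' excluded outright; mismatches in the first base or last two bases of
#' the (post-trim) read are tallied separately as edge support and carry
#' no weight as evidence. Reads mapped to the opposite strand are ignored.
#'
#' @param hits alignment table from \code{\link{align_reads}}; a
#'   \code{sample_id} column is used to assign tissues via \code{samples}.
#' @param annotations miRNA annotation \code{data.frame} (with \code{seq}).
#' @param samples optional sample metadata mapping sample_id to tissue;
#'   without it all reads share the tissue "all".
#' @return \code{data.frame} with one row per (site, tissue, change type):
#'   species, mirna_id, arm, position (1-based in the annotation), contig,
#'   gpos (0-based genomic), strand, ref_base, tissue, change, mm_reads,
#'   edge_reads, perfect_reads (mismatch-free reads spanning the site),
#'   site_coverage (reads spanning the site), mirna_total (reads assigned
#'   to the miRNA in that tissue).
#' @export
collect_site_tallies <- function(hits, annotations, samples = NULL) {
  stopifnot(all(c("state", "contig", "start", "strand") %in% names(hits)))
  if (is.null(annotations$seq)) {
    stop("annotations must carry the annotated sequence (column 'seq')",
         call. = FALSE)
  }
  mapped <- hits[hits$state == "mapped", , drop = FALSE]
  tissue <- rep("all", nrow(mapped))
  if (!is.null(samples) && !is.null(mapped$sample_id)) {
    tissue <- samples$tissue[match(mapped$sample_id, samples$sample_id)]
    tissue[is.na(tissue)] <- "all"
  }
  mapped$.tissue <- tissue
  out <- list()
  for (ai in seq_len(nrow(annotations))) {
    a <- annotations[ai, ]
    alen_ann <- a$end - a$start
    rend <- mapped$start + mapped$aligned_length       # exclusive
    sel <- which(mapped$contig == a$contig & mapped$strand == a$strand &
                   mapped$start < a$end & rend > a$start)
    if (!length(sel)) next
    sub <- mapped[sel, , drop = FALSE]
    for (tis in unique(sub$.tissue)) {
      r <- sub[sub$.tissue == tis, , drop = FALSE]
      mirna_total <- nrow(r)
      mm_rows <- which(r$n_mismatch >= 1L & nzchar(r$mismatches) &
                         !is.na(r$mismatches))
      if (!length(mm_rows)) next
      ev <- do.call(rbind, lapply(mm_rows, function(i) {
        d <- parse_mismatch_descriptor(r$mismatches[i])
        d$alen <- r$aligned_length[i]
        d$rstart <- r$start[i]
        d
      }))
      ## genomic coordinate of each mismatch
      ev$gpos <- ifelse(rep(a$strand == "+", nrow(ev)),
                        ev$rstart + ev$offset,
                        ev$rstart + ev$alen - 1L - ev$offset)
      ev$pos <- if (a$strand == "+") ev$gpos - a$start + 1L else
        a$end - ev$gpos
      ev <- ev[ev$pos >= 1L & ev$pos <= alen_ann, , drop = FALSE]
      ## annotation-edge exclusion: first one / last two bases
      ev <- ev[ev$pos > 1L & ev$pos < alen_ann - 1L, , drop = FALSE]
      if (!nrow(ev)) next
      ## read-edge support: first base or last two bases of the read
      ev$edge <- ev$offset == 0L | ev$offset >= ev$alen - 2L
      ev$change <- paste0(ev$ref, ">", ev$read)
      ## per-site coverage and perfect support
      perf <- r$n_mismatch == 0L
      for (p in unique(ev$pos)) {
        g <- if (a$strand == "+") a$start + p - 1L else a$end - p
        span <- r$start <= g & (r$start + r$aligned_length) > g
        evp <- ev[ev$pos == p, , drop = FALSE]
        for (ch in unique(evp$change)) {
          e2 <- evp[evp$change == ch, , drop = FALSE]
          out[[length(out) + 1L]] <- data.frame(
            species = a$species, mirna_id = a$mirna_id, arm = a$arm,
            position = p, contig = a$contig, gpos = g, strand = a$strand,
            ref_base = substr(a$seq, p, p), tissue = tis, change = ch,
            mm_reads = sum(!e2$edge), edge_reads = sum(e2$edge),
            perfect_reads = sum(span & perf),
            site_coverage = sum(span), mirna_total = mirna_total,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(species = character(0), mirna_id = character(0),
                      arm = character(0), position = integer(0),
                      contig = character(0), gpos = integer(0),
                      strand = character(0), ref_base = character(0),
                      tissue = character(0), change = character(0),
                      mm_reads = integer(0), edge_reads = integer(0),
                      perfect_reads = integer(0),
                      site_coverage = integer(0),
                      mirna_total = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Apply the candidate-site filter battery and assign evidence tiers
#'
#' Per tissue, a site's dominant change reaches the high tier when the
#' mismatch variant and the perfectly matching variant each have at least
#' \code{high_min_reads} reads and the mismatch reads are at least
#' \code{high_min_frac} of the miRNA's read total in that tissue; the
#' relaxed tier when both variants have at least one read and the
#' site-level mismatch frequency is at least \code{relaxed_min_freq}; and
#' trace when mismatch reads exist below that frequency. Sites are
#' rejected when (a) their only mismatch support sits at read edges,
#' (b) no perfectly mapping read covers the site, (c) more than one
#' mismatch type exceeds the sequencing error rate, or (d) the position
#' coincides with a known SNP of the same species.
#'
#' @param tallies output of \code{\link{collect_site_tallies}}.
#' @param snps optional SNP table (species, contig, position).
#' @param config a \code{\link{caller_config}}.
#' @return \code{data.frame} of site calls, one row per site: identity
#'   columns, dominant \code{change}, \code{canonical} (dominant change is
#'   A>G), \code{tier} (high/relaxed/trace/rejected), per-tissue best
#'   evidence (best_tissue, best_freq, best_mm, best_perfect), rejection
#'   flags and \code{change_tie}.
#' @export
apply_site_filters <- function(tallies, snps = NULL,
                               config = caller_config()) {
  if (!nrow(tallies)) {
    return(cbind(tallies[, c("species", "mirna_id", "arm", "position",
                             "contig", "gpos", "strand", "ref_base")],
                 data.frame(change = character(0), canonical = logical(0),
                            tier = character(0), best_tissue = character(0),
                            best_freq = numeric(0), best_mm = integer(0),
                            best_perfect = integer(0),
                            edge_excluded = logical(0),
                            low_coverage = logical(0),
                            multi_type = logical(0),
                            below_threshold = logical(0),
                            snp_overlap = logical(0),
                            change_tie = logical(0))))
  }
  key <- paste(tallies$species, tallies$mirna_id, tallies$arm,
               tallies$position)
  out <- lapply(split(seq_len(nrow(tallies)), key), function(ix) {
    tt <- tallies[ix, , drop = FALSE]
    id <- tt[1, c("species", "mirna_id", "arm", "position", "contig",
                  "gpos", "strand", "ref_base")]
    ## dominant change type over all tissues (non-edge support)
    by_change <- tapply(tt$mm_reads, tt$change, sum)
    mx <- max(by_change)
    tie <- sum(by_change == mx) > 1L && mx > 0L
    dom <- sort(names(by_change)[by_change == mx])[1]
    ## multi-type: more than one change above the sequencing error rate,
    ## measured against the site's total coverage over all tissues
    total_cov <- sum(tapply(tt$site_coverage, tt$tissue, max))
    over <- (by_change / max(total_cov, 1L)) > config$error_rate &
      by_change > 0
    multi_type <- sum(over) > 1L
    edge_excluded <- sum(tt$mm_reads) == 0L && sum(tt$edge_reads) > 0L
    low_coverage <- sum(tt$perfect_reads) == 0L
    snp_overlap <- FALSE
    if (!is.null(snps) && nrow(snps)) {
      snp_overlap <- any(snps$species == id$species &
                           snps$contig == id$contig &
                           snps$position == id$gpos)
    }
    ## per-tissue tier for the dominant change
    td <- tt[tt$change == dom, , drop = FALSE]
    tier_of <- function(i) {
      mm <- td$mm_reads[i]; perf <- td$perfect_reads[i]
      cov <- td$site_coverage[i]; tot <- td$mirna_total[i]
      if (mm >= config$high_min_reads && perf >= config$high_min_reads &&
          mm / tot >= config$high_min_frac) return("high")
      if (mm >= 1L && perf >= 1L &&
          mm / cov >= config$relaxed_min_freq) return("relaxed")
      if (mm >= 1L) return("trace")
      "none"
    }
    tiers <- vapply(seq_len(nrow(td)), tier_of, character(1))
    rank <- c(high = 3L, relaxed = 2L, trace = 1L, none = 0L)
    best_i <- which.max(rank[tiers])
    tier <- tiers[best_i]
    below_threshold <- !tier %in% c("high", "relaxed")
    rejected <- edge_excluded || low_coverage || multi_type || snp_overlap
    freq <- td$mm_reads[best_i] / max(1L, td$site_coverage[best_i])
    cbind(id, data.frame(
      change = dom, canonical = !tie && dom == "A>G",
      tier = if (rejected) "rejected" else tier,
      best_tissue = td$tissue[best_i], best_freq = freq,
      best_mm = td$mm_reads[best_i], best_perfect = td$perfect_reads[best_i],
      edge_excluded = edge_excluded, low_coverage = low_coverage,
      multi_type = multi_type, below_threshold = below_threshold,
      snp_overlap = snp_overlap, change_tie = tie,
      stringsAsFactors = FALSE))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$species, res$mirna_id, res$position), , drop = FALSE]
}

#' Flag canonical A-to-I editing
#'
#' TRUE iff the site's dominant change type is A>G in miRNA sense; a tie
#' between change types yields FALSE with a warning.
#'
#' @param calls site-call \code{data.frame} from
#'   \code{\link{apply_site_filters}}.
#' @return logical vector, one element per call.
#' @export
classify_change <- function(calls) {
  if (any(calls$change_tie)) {
    warning(sprintf("%d site(s) with tied mismatch types classified as non-canonical",
                    sum(calls$change_tie)), call. = FALSE)
  }
  calls$change == "A>G" & !calls$change_tie
}
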