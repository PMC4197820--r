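## Cross-species conservation of editing sites: a unit-cost global pairwise
## aligner and a progressive star-topology multiple aligner for ~22-nt
## miRNA family sequences, ortholog selection by fewest mismatches,
## projection of site calls onto alignment columns, the conserved-site rule
## (non-gap A in every claiming species) and the >= 2-species requirement,
## plus the relaxed scan used for additional species.

## ---- pairwise global alignment, unit costs (match 0, mismatch 1, gap 1)

## returns list(a, b): gapped strings, and cost
nw_align <- function(a, b) {
  x <- chars(a); y <- chars(b)
  n <- length(x); m <- length(y)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1L] <- 0:n
  D[1L, ] <- 0:m
  for (i in seq_len(n)) {
    sub <- D[i, seq_len(m)] + (x[i] != y)          # diagonal moves
    del <- D[i, 2:(m + 1L)] + 1L                   # gap in b... row-wise
    row <- integer(m)
    prev <- D[i + 1L, 1L] <- i
    for (j in seq_len(m)) {
      v <- min(sub[j], del[j], prev + 1L)
      row[j] <- prev <- v
    }
    D[i + 1L, 2:(m + 1L)] <- row
  }
  ## traceback, preferring diagonal, then up (gap in b), then left
  i <- n; j <- m
  ga <- character(0); gb <- character(0)
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        D[i + 1L, j + 1L] == D[i, j] + (x[i] != y[j])) {
      ga <- c(x[i], ga); gb <- c(y[j], gb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && D[i + 1L, j + 1L] == D[i, j + 1L] + 1L) {
      ga <- c(x[i], ga); gb <- c("-", gb); i <- i - 1L
    } else {
      ga <- c("-", ga); gb <- c(y[j], gb); j <- j - 1L
    }
  }
  list(a = paste(ga, collapse = ""), b = paste(gb, collapse = ""),
       cost = D[n + 1L, m + 1L])
}

## unit-cost alignment cost only
nw_cost <- function(a, b) nw_align(a, b)$cost

#' Align the sequences of a miRNA family
#'
#' Progressive alignment over a star topology: the center sequence (the one
#' with the smallest summed distance to all others) is aligned pairwise to
#' every other member with unit costs and the pairs are merged under the
#' "once a gap, always a gap" rule. Deterministic; identical sequences
#' align gap-free.
#'
#' @param seqs named character vector of >= 2 member sequences (no empty
#'   sequences).
#' @return a \code{family_alignment}: \code{aligned} (named gapped strings
#'   of equal length) and \code{colmap} (per member, an integer vector
#'   mapping sequence position to alignment column).
#' @export
align_family <- function(seqs) {
  if (length(seqs) < 2L) stop("need at least 2 sequences", call. = FALSE)
  if (any(!nzchar(seqs))) stop("empty sequence in family", call. = FALSE)
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  dmat <- outer(seq_along(seqs), seq_along(seqs),
                Vectorize(function(i, j) {
                  if (i == j) 0L else nw_cost(seqs[[i]], seqs[[j]])
                }))
  center <- which.min(rowSums(dmat))
  aligned <- setNames(seqs[center], names(seqs)[center])
  for (i in setdiff(seq_along(seqs), center)) {
    pw <- nw_align(seqs[[center]], seqs[[i]])
    aligned <- merge_into_star(aligned, names(seqs)[center],
                               pw$a, pw$b, names(seqs)[i])
  }
  aligned <- aligned[names(seqs)]                    # input order
  colmap <- lapply(aligned, function(s) which(chars(s) != "-"))
  structure(list(aligned = aligned, colmap = colmap),
            class = "family_alignment")
}

## merge a pairwise (center', new') alignment into the growing MSA
merge_into_star <- function(msa, center_name, cp, np, new_name) {
  cm <- chars(msa[[center_name]])
  cpv <- chars(cp); npv <- chars(np)
  i <- 1L; j <- 1L
  out_cols_msa <- integer(0)   # 0 denotes an inserted all-gap column
  out_cols_new <- integer(0)
  while (i <= length(cm) || j <= length(cpv)) {
    if (i <= length(cm) && cm[i] == "-") {
      ## gap already in MSA center: keep MSA column, gap in new row
      out_cols_msa <- c(out_cols_msa, i)
      out_cols_new <- c(out_cols_new, 0L)
      i <- i + 1L
      next
    }
    if (j <= length(cpv) && cpv[j] == "-") {
      ## gap introduced by the new pair: all-gap column for existing rows
      out_cols_msa <- c(out_cols_msa, 0L)
      out_cols_new <- c(out_cols_new, j)
      j <- j + 1L
      next
    }
    ## both non-gap residues of the center: consume together
    out_cols_msa <- c(out_cols_msa, i)
    out_cols_new <- c(out_cols_new, j)
    i <- i + 1L; j <- j + 1L
  }
  pick <- function(s, cols) {
    v <- chars(s)
    paste(ifelse(cols == 0L, "-", v[pmax(cols, 1L)]), collapse = "")
  }
  merged <- vapply(msa, pick, character(1), cols = out_cols_msa)
  merged[new_name] <- pick(np, out_cols_new)
  merged
}

#' Select the most similar ortholog
#'
#' When a species contributes several candidate orthologs, the one with the
#' fewest mismatches (unit-cost alignment distance) to the reference mature
#' sequence is retained; ties are broken lexicographically by miRNA id,
#' with a warning.
#'
#' @param candidates data.frame with columns \code{mirna_id}, \code{seq}.
#' @param ref_seq reference mature sequence.
#' @return the selected \code{mirna_id}.
#' @export
select_ortholog <- function(candidates, ref_seq) {
  stopifnot(nrow(candidates) >= 1L)
  d <- vapply(candidates$seq, nw_cost, integer(1), a = ref_seq,
              USE.NAMES = FALSE)
  best <- which(d == min(d))
  ids <- sort(candidates$mirna_id[best])
  if (length(best) > 1L) {
    warning(sprintf("ortholog tie for reference sequence; keeping %s",
                    ids[1]), call. = FALSE)
  }
  ids[1]
}

#' Call conserved editing events across species
#'
#' Projects tiered site calls onto family-alignment columns. An event is
#' kept iff (a) the column carries a non-gap A in every claiming species
#' (conserved-site rule) and (b) at least \code{min_species} species reach
#' the relaxed tier or better, including at least \code{min_species}
#' species at the tier demanded by \code{mode} ("high" for the
#' high-confidence set, "relaxed" for the extended set). Per-species tiers
#' (high / relaxed / trace / none / no-data) are recorded for every
#' species present in \code{species_set}.
#'
#' @param calls site calls from \code{\link{apply_site_filters}}.
#' @param families family membership table (family_id, species, mirna_id).
#' @param annotations annotation table with \code{seq}.
#' @param min_species minimum number of species with tier >= relaxed
#'   (default 2).
#' @param mode "relaxed" (default) or "high".
#' @param species_set species to report tiers for (default: all in
#'   \code{families}).
#' @return \code{data.frame} of conserved events (family, arm, column,
#'   reference miRNA/position, per-species tier string, species counts);
#'   site calls on miRNAs absent from every family are returned in the
#'   \code{"orphans"} attribute.
#' @export
call_conserved_events <- function(calls, families, annotations,
                                  min_species = 2L,
                                  mode = c("relaxed", "high"),
                                  species_set = NULL) {
  mode <- match.arg(mode)
  species_set <- species_set %||% sort(unique(families$species))
  calls <- calls[calls$tier %in% c("high", "relaxed", "trace"), ,
                 drop = FALSE]
  fam_key <- paste(families$species, families$mirna_id)
  call_key <- paste(calls$species, calls$mirna_id)
  orphans <- calls[!call_key %in% fam_key, , drop = FALSE]
  calls <- calls[call_key %in% fam_key, , drop = FALSE]
  calls$family_id <- families$family_id[match(paste(calls$species,
                                                    calls$mirna_id),
                                              fam_key)]
  events <- list()
  rank <- c(high = 3L, relaxed = 2L, trace = 1L)
  for (fid in unique(calls$family_id)) {
    fam <- families[families$family_id == fid, , drop = FALSE]
    for (arm in unique(calls$arm[calls$family_id == fid])) {
      ann <- annotations[annotations$arm == arm &
                           paste(annotations$species,
                                 annotations$mirna_id) %in%
                           paste(fam$species, fam$mirna_id), ,
                         drop = FALSE]
      if (nrow(ann) < 1L) next
      ## one ortholog per species: fewest mismatches to the reference
      ref_seq <- ann$seq[1]
      keep <- unlist(lapply(split(seq_len(nrow(ann)), ann$species),
                            function(ix) {
        if (length(ix) == 1L) return(ix)
        sel <- select_ortholog(ann[ix, c("mirna_id", "seq")], ref_seq)
        ix[ann$mirna_id[ix] == sel]
      }))
      ann <- ann[sort(keep), , drop = FALSE]
      cc <- calls[calls$family_id == fid & calls$arm == arm &
                    paste(calls$species, calls$mirna_id) %in%
                    paste(ann$species, ann$mirna_id), , drop = FALSE]
      if (!nrow(cc)) next
      if (nrow(ann) >= 2L) {
        fa <- align_family(setNames(ann$seq, ann$species))
      } else {
        fa <- list(aligned = setNames(ann$seq, ann$species),
                   colmap = setNames(list(seq_len(nchar(ann$seq[1]))),
                                     ann$species))
      }
      cc$column <- vapply(seq_len(nrow(cc)), function(i) {
        fa$colmap[[cc$species[i]]][cc$position[i]]
      }, integer(1))
      for (col in unique(cc$column)) {
        ec <- cc[cc$column == col, , drop = FALSE]
        claiming <- unique(ec$species)
        base_at <- vapply(claiming, function(sp) {
          substr(fa$aligned[[sp]], col, col)
        }, character(1))
        if (any(base_at != "A")) next                 # conserved-site rule
        sp_tier <- setNames(rep("no-data", length(species_set)),
                            species_set)
        sp_tier[species_set %in% fam$species] <- "none"
        for (i in seq_len(nrow(ec))) {
          cur <- sp_tier[[ec$species[i]]]
          if (!cur %in% names(rank) ||
              rank[[ec$tier[i]]] > rank[[cur]]) {
            sp_tier[[ec$species[i]]] <- ec$tier[i]
          }
        }
        n_relaxed <- sum(sp_tier %in% c("high", "relaxed"))
        n_high <- sum(sp_tier == "high")
        need <- if (mode == "high") n_high else n_relaxed
        if (n_relaxed < min_species || need < min_species) next
        ref <- ec[which.max(rank[ec$tier]), ]
        events[[length(events) + 1L]] <- cbind(
          data.frame(family_id = fid, arm = arm, column = col,
                     mirna_id = ref$mirna_id, position = ref$position,
                     change = ref$change,
                     n_species = n_relaxed, n_high = n_high,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(sp_tier), stringsAsFactors = FALSE,
                        col.names = paste0("tier_", names(sp_tier))))
      }
    }
  }
  res <- if (length(events)) do.call(rbind, events) else
    data.frame(family_id = character(0), arm = character(0),
               column = integer(0), mirna_id = character(0),
               position = integer(0), change = character(0),
               n_species = integer(0), n_high = integer(0))
  rownames(res) <- NULL
  attr(res, "orphans") <- orphans
  res
}

#' Attach clade labels to conserved events from a species tree
#'
#' For each event, the species with evidence at the relaxed tier or
#' better define a clade: the smallest clade of the supplied tree
#' containing all of them. The label is the tree's node label when one
#' is present, otherwise the tip names joined with "+". Labels are
#' report metadata; divergence ages are never computed.
#'
#' @param events event table from \code{\link{call_conserved_events}}.
#' @param tree an \code{ape::phylo} tree or the path to a Newick file;
#'   tip labels must match the species identifiers.
#' @return \code{events} with a \code{clade} column.
#' @export
label_clades <- function(events, tree) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("clade labeling needs the 'ape' package", call. = FALSE)
  }
  if (is.character(tree)) tree <- ape::read.tree(tree)
  tier_cols <- grep("^tier_", names(events), value = TRUE)
  events$clade <- vapply(seq_len(nrow(events)), function(i) {
    sp <- sub("^tier_", "", tier_cols)[unlist(events[i, tier_cols]) %in%
                                         c("high", "relaxed")]
    sp <- intersect(sp, tree$tip.label)
    if (length(sp) == 0L) return(NA_character_)
    if (length(sp) == 1L) return(sp)
    node <- ape::getMRCA(tree, sp)
    lab <- NULL
    if (!is.null(tree$node.label)) {
      lab <- tree$node.label[node - length(tree$tip.label)]
    }
    if (!is.null(lab) && !is.na(lab) && nzchar(lab)) return(lab)
    clade_tips <- ape::extract.clade(tree, node)$tip.label
    paste(sort(clade_tips), collapse = "+")
  }, character(1))
  events
}

#' Relaxed editing scan for an additional species
#'
#' Establishes each event's locus in the target genome by mapping the
#' reference (e.g. human) mature/star sequence with at most two mismatches
#' (up to five locations, best stratum only), then classifies the site
#' from reads aligned with at most one mismatch: relaxed when matching and
#' mismatching variants have at least one read each and the A>G fraction
#' of reads covering the site is >= 1\%; trace below 1\%; none without
#' edited reads; no-data without spanning reads or a mappable locus. Only
#' reads whose base at the site has quality >= \code{min_site_q} count.
#'
#' @param reads small-read \code{data.frame} (already length/quality
#'   filtered at the relaxed threshold).
#' @param events_ref data.frame: mirna_id, seq (reference sense sequence),
#'   position (1-based edited position within it).
#' @param target_contigs named contig sequences of the additional species.
#' @param min_site_q site base quality threshold (default 30).
#' @return data.frame: mirna_id, position, tier, edited, unedited,
#'   coverage, freq.
#' @export
relaxed_species_scan <- function(reads, events_ref, target_contigs,
                                 min_site_q = 30L) {
  index <- build_index(target_contigs)
  loc_policy <- align_policy(max_mismatches = 2L, multimap_limit = 5L,
                             trim_retry = FALSE)
  read_policy <- align_policy(max_mismatches = 1L, multimap_limit = 5L,
                              trim_retry = TRUE)
  hits <- align_reads(reads, index, read_policy)
  hits$qual <- reads$qual[match(hits$read_id, reads$read_id)]
  out <- lapply(seq_len(nrow(events_ref)), function(i) {
    ev <- events_ref[i, ]
    base <- data.frame(mirna_id = ev$mirna_id, position = ev$position,
                       tier = "no-data", edited = 0L, unedited = 0L,
                       coverage = 0L, freq = NA_real_,
                       stringsAsFactors = FALSE)
    loc <- align_read(ev$seq, index, loc_policy)
    if (loc$state != "mapped") return(base)
    g <- if (loc$strand == "+") loc$start + ev$position - 1L else
      loc$start + loc$aligned_length - ev$position
    span <- which(hits$state == "mapped" & hits$contig == loc$contig &
                    hits$strand == loc$strand & hits$start <= g &
                    hits$start + hits$aligned_length > g)
    if (!length(span)) return(base)
    sub <- hits[span, , drop = FALSE]
    off <- if (loc$strand == "+") g - sub$start else
      sub$start + sub$aligned_length - 1L - g
    rb <- substr(sub$seq, off + 1L, off + 1L)
    if (loc$strand == "-") rb <- complement_base(rb)
    bq <- as.integer(charToRaw(paste(substr(sub$qual, off + 1L, off + 1L),
                                     collapse = ""))) - 33L
    ok <- bq >= min_site_q
    edited <- sum(rb[ok] == "G")
    unedited <- sum(rb[ok] == "A")
    cov <- sum(ok)
    if (cov == 0L) return(base)
    freq <- edited / cov
    tier <- if (edited >= 1L && unedited >= 1L && freq >= 0.01) "relaxed"
    else if (edited >= 1L) "trace" else "none"
    data.frame(mirna_id = ev$mirna_id, position = ev$position, tier = tier,
               edited = edited, unedited = unedited, coverage = cov,
               freq = freq, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
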