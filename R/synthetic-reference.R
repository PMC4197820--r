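## Synthetic reference bundles: per-species contigs carrying hairpin-style
## miRNA precursors (mature arm + loop + star arm), family membership across
## species, and a SNP table. Everything is deterministic for a fixed seed.

new_ref_bundle <- function(contigs, annotations, families, snps,
                           family_info = NULL) {
  structure(list(contigs = contigs, annotations = annotations,
                 families = families, snps = snps,
                 family_info = family_info),
            class = "ref_bundle")
}

#' @export
print.ref_bundle <- function(x, ...) {
  cat(sprintf("<ref_bundle> %d contig(s), %d annotation(s), %d famil%s, %d SNP(s)\n",
              length(x$contigs), nrow(x$annotations),
              length(unique(x$families$family_id)),
              if (length(unique(x$families$family_id)) == 1) "y" else "ies",
              nrow(x$snps)))
  invisible(x)
}

#' Contigs belonging to one species of a bundle
#'
#' @param bundle a \code{ref_bundle}.
#' @param species species identifier.
#' @return named list of contig sequences.
#' @export
species_contigs <- function(bundle, species) {
  cn <- unique(bundle$annotations$contig[bundle$annotations$species ==
                                           species])
  bundle$contigs[cn]
}

#' Generate a synthetic multi-species miRNA reference bundle
#'
#' Each family has a ~22-nt mature sequence; per-species orthologs differ by
#' at most \code{max_substitutions} substitutions within the mature
#' sequence. A configurable fraction of families carries a full ortholog
#' set across all species; the rest are restricted to a random subset of
#' species, so downstream stages can exercise the "no annotated ortholog"
#' path. Every mature arm is embedded in a hairpin-capable precursor
#' (mature + loop + reverse-complement star arm) with genomic flanks, on a
#' randomly chosen strand.
#'
#' @param n_species number of species (>= 1).
#' @param mirnas_per_species number of miRNA families (>= 1); full families
#'   contribute one miRNA per species.
#' @param seed integer seed; fixed seed gives a byte-identical bundle.
#' @param mature_len length of the mature arm (default 22).
#' @param full_family_frac fraction of families with a full ortholog set
#'   (default 0.6; at least one family is always full).
#' @param max_substitutions maximum substitutions between orthologous
#'   mature sequences (default 3).
#' @param n_snps_per_species SNPs placed per species (default 5); the first
#'   two fall inside mature intervals to exercise SNP exclusion.
#' @return a \code{ref_bundle}: list of \code{contigs} (named sequences),
#'   \code{annotations} (miRNA records incl. \code{seq}), \code{families},
#'   \code{snps} and \code{family_info} (which families are full).
#' @export
generate_reference <- function(n_species, mirnas_per_species, seed,
                               mature_len = 22L,
                               full_family_frac = 0.6,
                               max_substitutions = 3L,
                               n_snps_per_species = 5L) {
  stopifnot_scalar_count(n_species, "n_species")
  stopifnot_scalar_count(mirnas_per_species, "mirnas_per_species")
  with_seed(seed, {
    species <- sprintf("sp%02d", seq_len(n_species))
    fam_ids <- sprintf("fam%03d", seq_len(mirnas_per_species))
    n_full <- max(1L, round(full_family_frac * mirnas_per_species))
    full <- seq_len(mirnas_per_species) <= n_full

    ## base mature per family, with guaranteed internal adenosines
    base_mature <- random_dna(mirnas_per_species, mature_len)
    for (i in seq_along(base_mature)) {
      s <- chars(base_mature[i])
      pos <- sample(3:(mature_len - 2L), 3L)
      s[pos] <- "A"
      base_mature[i] <- paste(s, collapse = "")
    }

    fam_species <- lapply(seq_len(mirnas_per_species), function(i) {
      if (full[i] || n_species == 1L) return(species)
      k <- sample(seq_len(max(1L, n_species - 1L)), 1L)
      sort(sample(species, k))
    })

    ann <- list(); fam <- list(); contigs <- list(); snps <- list()
    loop_len <- 8L; flank <- 30L
    for (sp in species) {
      seqs <- character(0); rows <- list()
      offset <- 0L
      contig_name <- paste0(sp, "_chr1")
      for (i in seq_len(mirnas_per_species)) {
        if (!sp %in% fam_species[[i]]) next
        ## each ortholog deviates from the family consensus by at most
        ## half the bound, so pairwise divergence stays within it
        mat <- mutate_sequence(base_mature[i],
                               sample(0:(max_substitutions %/% 2), 1L))
        star <- revcomp(mutate_sequence(mat, 2L))
        precursor <- paste0(mat, random_dna(1, loop_len), star)
        strand <- sample(c("+", "-"), 1L)
        lp <- nchar(precursor)
        insert <- if (strand == "+") precursor else revcomp(precursor)
        left <- random_dna(1, flank)
        start0 <- offset + flank            # precursor start, 0-based
        seqs <- c(seqs, left, insert)
        offset <- offset + flank + lp
        mid <- sprintf("%s-mir%03d", sp, i)
        ## sense coordinates of the two arms within the precursor
        arm <- data.frame(
          arm = c("mature", "star"),
          p0 = c(0L, lp - mature_len),
          p1 = c(mature_len, lp),
          seq = c(mat, star),
          stringsAsFactors = FALSE)
        if (strand == "+") {
          gs <- start0 + arm$p0; ge <- start0 + arm$p1
        } else {
          gs <- start0 + lp - arm$p1; ge <- start0 + lp - arm$p0
        }
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp, mirna_id = mid, arm = arm$arm,
          family_id = fam_ids[i], contig = contig_name,
          start = gs, end = ge, strand = strand, seq = arm$seq,
          stringsAsFactors = FALSE)
        fam[[length(fam) + 1L]] <- data.frame(
          family_id = fam_ids[i], species = sp, mirna_id = mid,
          stringsAsFactors = FALSE)
      }
      seqs <- c(seqs, random_dna(1, flank))
      contigs[[contig_name]] <- paste(seqs, collapse = "")
      ann[[sp]] <- do.call(rbind, rows)

      ## SNPs: first two inside mature intervals, rest anywhere
      sp_ann <- ann[[sp]]
      mature_rows <- sp_ann[sp_ann$arm == "mature", , drop = FALSE]
      n_in <- min(2L, n_snps_per_species, nrow(mature_rows))
      pos_in <- integer(0)
      if (n_in > 0) {
        ri <- sample(seq_len(nrow(mature_rows)), n_in)
        pos_in <- mature_rows$start[ri] +
          sample(seq_len(mature_len), n_in, replace = TRUE) - 1L
      }
      n_out <- max(0L, n_snps_per_species - n_in)
      pos_out <- if (n_out > 0) {
        sample(seq_len(nchar(contigs[[contig_name]])), n_out) - 1L
      } else integer(0)
      pos <- unique(c(pos_in, pos_out))
      if (length(pos)) {
        ref <- substring(contigs[[contig_name]], pos + 1L, pos + 1L)
        alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L),
                      character(1))
        snps[[sp]] <- data.frame(
          species = sp, contig = contig_name, position = pos,
          ref = ref, alt = alt,
          af = round(runif(length(pos), 0.05, 0.5), 3),
          stringsAsFactors = FALSE, row.names = NULL)
      }
    }

    annotations <- do.call(rbind, ann)
    rownames(annotations) <- NULL
    families <- do.call(rbind, fam)
    rownames(families) <- NULL
    snp_tab <- if (length(snps)) do.call(rbind, snps) else
      data.frame(species = character(0), contig = character(0),
                 position = integer(0), ref = character(0),
                 alt = character(0), af = numeric(0))
    rownames(snp_tab) <- NULL
    new_ref_bundle(contigs, annotations, families, snp_tab,
                   family_info = data.frame(family_id = fam_ids,
                                            full = full,
                                            stringsAsFactors = FALSE))
  })
}

## apply exactly n substitutions at random positions
mutate_sequence <- function(seq, n) {
  if (n == 0L) return(seq)
  s <- chars(seq)
  pos <- sample(seq_along(s), min(n, length(s)))
  for (p in pos) s[p] <- sample(setdiff(DNA_BASES, s[p]), 1L)
  paste(s, collapse = "")
}
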