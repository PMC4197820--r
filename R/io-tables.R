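## Tab-delimited table IO: miRNA annotations (BED-like, 0-based half-open),
## SNP tables, family membership and generic result tables with commented
## headers. User-facing result tables report 1-based inclusive positions;
## all on-disk interval files are 0-based half-open.

ANNOT_COLS <- c("species", "mirna_id", "arm", "family_id",
                "contig", "start", "end", "strand")
SNP_COLS <- c("species", "contig", "position", "ref", "alt", "af")

#' Read a miRNA annotation table
#'
#' Columns: species, mirna_id, arm (\code{mature} or \code{star}),
#' family_id, contig, start, end (0-based half-open), strand (+/-).
#' When \code{contigs} is supplied, every interval is checked against its
#' contig and the annotated sequence (miRNA sense) is attached as
#' column \code{seq}.
#'
#' @param path tab-delimited file with a header row.
#' @param contigs optional named character vector/list of contig sequences.
#' @return \code{data.frame} of miRNA records.
#' @export
read_annotations <- function(path, contigs = NULL) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  missing_cols <- setdiff(ANNOT_COLS, names(ann))
  if (length(missing_cols)) {
    stop(sprintf("annotation table %s lacks column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  validate_annotations(ann, contigs)
  if (!is.null(contigs)) ann$seq <- annotation_sequences(ann, contigs)
  ann
}

validate_annotations <- function(ann, contigs = NULL) {
  bad <- which(!ann$strand %in% c("+", "-"))
  if (length(bad)) {
    stop(sprintf("invalid strand token '%s' in annotation row %d",
                 ann$strand[bad[1]], bad[1]), call. = FALSE)
  }
  if (any(ann$start < 0) || any(ann$end <= ann$start)) {
    stop("annotation intervals must satisfy 0 <= start < end", call. = FALSE)
  }
  if (!all(ann$arm %in% c("mature", "star"))) {
    stop("annotation arm must be 'mature' or 'star'", call. = FALSE)
  }
  if (!is.null(contigs)) {
    key <- paste(ann$species, ann$contig)
    ckey <- names(contigs)
    have <- ann$contig %in% ckey
    if (!all(have)) {
      stop(sprintf("annotation contig '%s' absent from reference",
                   ann$contig[which(!have)[1]]), call. = FALSE)
    }
    clen <- nchar(unlist(contigs))[ann$contig]
    over <- which(ann$end > clen)
    if (length(over)) {
      stop(sprintf("annotation interval outside contig in row %d", over[1]),
           call. = FALSE)
    }
  }
  invisible(ann)
}

## miRNA-sense sequence for each annotation row
annotation_sequences <- function(ann, contigs) {
  s <- substr(unlist(contigs)[ann$contig], ann$start + 1L, ann$end)
  neg <- ann$strand == "-"
  if (any(neg)) s[neg] <- revcomp(s[neg])
  s
}

#' Write a miRNA annotation table
#' @param ann annotation \code{data.frame} (see \code{\link{read_annotations}}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_annotations <- function(ann, path) {
  utils::write.table(ann[, ANNOT_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a SNP table
#'
#' Columns: species, contig, position (0-based), ref, alt and optionally
#' af (allele frequency). Ref and alt must be distinct bases in
#' \{A,C,G,T\}.
#'
#' @param path tab-delimited file with a header row.
#' @param contigs optional contig sequences; when given, the ref base is
#'   checked against the contig.
#' @return \code{data.frame} of SNP records.
#' @export
read_snp_table <- function(path, contigs = NULL) {
  snp <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- setdiff(SNP_COLS, c(names(snp), "af"))
  if (length(need)) {
    stop(sprintf("SNP table %s lacks column(s): %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (is.null(snp$af)) snp$af <- NA_real_
  if (any(!snp$ref %in% DNA_BASES) || any(!snp$alt %in% DNA_BASES) ||
      any(snp$ref == snp$alt)) {
    stop("SNP ref/alt must be distinct bases in {A,C,G,T}", call. = FALSE)
  }
  if (!is.null(contigs) && nrow(snp)) {
    obs <- substr(unlist(contigs)[snp$contig], snp$position + 1L,
                  snp$position + 1L)
    if (any(obs != snp$ref)) {
      stop("SNP ref base does not match the contig sequence", call. = FALSE)
    }
  }
  snp[, SNP_COLS]
}

#' Write a SNP table
#' @param snp SNP \code{data.frame}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_snp_table <- function(snp, path) {
  if (is.null(snp$af)) snp$af <- NA_real_
  utils::write.table(snp[, SNP_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a result table with a commented provenance header
#'
#' All positions in result tables are 1-based inclusive within the mature
#' or star miRNA, counted from the annotated 5' end; the header says so.
#'
#' @param records \code{data.frame} to write.
#' @param path output path.
#' @param header extra comment lines (without the leading \code{#}).
#' @return \code{path}, invisibly.
#' @export
write_results <- function(records, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# ", c(
    "positions are 1-based inclusive within the annotated miRNA",
    header))), con)
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a result table written by \code{\link{write_results}}
#' @param path path to the table.
#' @return \code{data.frame}.
#' @export
read_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Serialize a reference bundle to a directory
#'
#' Writes contigs as FASTA, annotations and SNPs as tab-delimited tables and
#' family membership as a three-column table (family_id, species, mirna_id).
#'
#' @param bundle a \code{ref_bundle} (see \code{\link{generate_reference}}).
#' @param dir output directory, created if needed.
#' @return \code{dir}, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dna <- Biostrings::DNAStringSet(unlist(bundle$contigs))
  Biostrings::writeXStringSet(dna, file.path(dir, "contigs.fa"))
  write_annotations(bundle$annotations, file.path(dir, "annotations.tsv"))
  utils::write.table(bundle$families, file.path(dir, "families.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_snp_table(bundle$snps, file.path(dir, "snps.tsv"))
  invisible(dir)
}

#' Load a reference bundle from a directory written by \code{\link{write_bundle}}
#' @param dir bundle directory.
#' @return a \code{ref_bundle} object.
#' @export
read_bundle <- function(dir) {
  dna <- Biostrings::readDNAStringSet(file.path(dir, "contigs.fa"))
  contigs <- as.list(setNames(as.character(dna), names(dna)))
  ann <- read_annotations(file.path(dir, "annotations.tsv"), contigs)
  fam <- utils::read.delim(file.path(dir, "families.tsv"),
                           stringsAsFactors = FALSE)
  snp <- read_snp_table(file.path(dir, "snps.tsv"), contigs)
  new_ref_bundle(contigs, ann, fam, snp)
}
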