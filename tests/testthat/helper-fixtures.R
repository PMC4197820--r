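## Shared fixture builders. Everything is generated in code; no files.

Q40 <- "I"   # Phred+33 for Q40

## reads with constant quality
mk_reads <- function(seqs, ids = NULL, qchar = Q40) {
  ids <- ids %||% sprintf("r%04d", seq_along(seqs))
  small_reads(ids, seqs, strrep(qchar, nchar(seqs)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

random_contig <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## a hand-built single-miRNA bundle: contig = left + mature + right, plus
## annotation; strand "+" unless stated
manual_bundle <- function(mature, left = strrep("C", 10),
                          right = strrep("C", 10), strand = "+",
                          species = "spX", mirna_id = "spX-mir1",
                          contig_name = "spX_chr1") {
  if (strand == "+") {
    contig <- paste0(left, mature, right)
  } else {
    contig <- paste0(left, revcomp(mature), right)
  }
  ann <- data.frame(species = species, mirna_id = mirna_id,
                    arm = "mature", family_id = "famX",
                    contig = contig_name, start = nchar(left),
                    end = nchar(left) + nchar(mature), strand = strand,
                    seq = mature, stringsAsFactors = FALSE)
  fam <- data.frame(family_id = "famX", species = species,
                    mirna_id = mirna_id, stringsAsFactors = FALSE)
  snp <- data.frame(species = character(0), contig = character(0),
                    position = integer(0), ref = character(0),
                    alt = character(0), af = numeric(0))
  mirededit:::new_ref_bundle(setNames(list(contig), contig_name), ann,
                             fam, snp)
}

## run the detection chain (filter, align, tally, call) for one bundle
detect_chain <- function(bundle, reads_df, samples = NULL,
                         caller = caller_config(), snps = NULL,
                         policy = align_policy()) {
  sp <- bundle$annotations$species[1]
  idx <- build_index(species_contigs(bundle, sp))
  fl <- filter_reads(reads_df, filter_config())
  hits <- align_reads(fl$kept, idx, policy)
  tal <- collect_site_tallies(hits, bundle$annotations, samples)
  list(hits = hits, tallies = tal,
       calls = apply_site_filters(tal, snps, caller))
}

## one-sample, one-species simulation shortcut
sim_one <- function(bundle, coverage, freq = 0, seed = 1,
                    error_rate = 0.001, tissue = "brain",
                    sites = NULL, tail_add_prob = 0.15,
                    five_prime_offsets = c("-1" = 0.1, "0" = 0.8,
                                           "1" = 0.1),
                    edit_cleavage_coupling = NULL, sample_id = "s1") {
  sp <- bundle$annotations$species[1]
  smp <- sample_meta(sample_id, sp, tissue = tissue)
  mat <- bundle$annotations[bundle$annotations$species == sp &
                              bundle$annotations$arm == "mature", ]
  expr <- data.frame(species = sp, mirna_id = mat$mirna_id,
                     mean_count = coverage, stringsAsFactors = FALSE)
  et <- NULL
  if (freq > 0) {
    sites <- sites %||% mirededit:::pick_edit_sites(mat)
    et <- data.frame(species = sp, mirna_id = sites$mirna_id,
                     position = sites$position, freq = freq,
                     stringsAsFactors = FALSE)
  }
  d <- sim_design(smp, expr, edit_truth = et, error_rate = error_rate,
                  tail_add_prob = tail_add_prob,
                  five_prime_offsets = five_prime_offsets,
                  edit_cleavage_coupling = edit_cleavage_coupling,
                  seed = seed)
  c(simulate_reads(bundle, d), list(samples = smp))
}
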