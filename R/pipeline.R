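## Pipeline orchestration: a validated run manifest plus one function per
## stage. Every stage is a pure function of its inputs and the recorded
## seed, writes tab-delimited outputs plus a JSON run report (per-filter
## in/out counts, seed), and names the stage to run first when an upstream
## artifact is missing.

#' Create and validate a run manifest
#'
#' @param output_dir directory all stages write to (created if needed).
#' @param seed integer seed recorded in every run report and used by every
#'   stochastic stage.
#' @param sim simulation parameters for \code{\link{run_simulate}}: a list
#'   with n_species, mirnas_per_species and optionally coverage, edit
#'   sites/frequencies (see Details of \code{\link{run_simulate}}).
#' @param filter a \code{\link{filter_config}}.
#' @param align a \code{\link{align_policy}}.
#' @param caller a \code{\link{caller_config}}.
#' @param min_species,conservation_mode conservation thresholds.
#' @param flank variant-reference flank (default 10).
#' @param min_reads_cancer per-sample coverage rule for the cancer stage
#'   (default 100).
#' @param min_edited_age minimum edited reads per miRNA for the age stage
#'   (default 10).
#' @return a \code{run_manifest} list.
#' @export
run_manifest <- function(output_dir, seed, sim = list(),
                         filter = filter_config(),
                         align = align_policy(),
                         caller = caller_config(),
                         min_species = 2L,
                         conservation_mode = "relaxed",
                         flank = 10L, min_reads_cancer = 100L,
                         min_edited_age = 10L) {
  stopifnot(is.character(output_dir), length(output_dir) == 1L)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 sim = sim, filter = filter, align = align,
                 caller = caller, min_species = as.integer(min_species),
                 conservation_mode = conservation_mode,
                 flank = as.integer(flank),
                 min_reads_cancer = as.integer(min_reads_cancer),
                 min_edited_age = as.integer(min_edited_age)),
            class = "run_manifest")
}

stage_path <- function(manifest, ...) file.path(manifest$output_dir, ...)

require_artifact <- function(manifest, rel, stage) {
  p <- stage_path(manifest, rel)
  if (!file.exists(p)) {
    stop(sprintf("missing artifact '%s'; run the `%s` stage first", rel,
                 stage), call. = FALSE)
  }
  p
}

write_report <- function(manifest, stage, counts) {
  rep <- c(list(stage = stage, seed = manifest$seed), counts)
  jsonlite::write_json(rep, stage_path(manifest,
                                       sprintf("report_%s.json", stage)),
                       auto_unbox = TRUE, digits = NA)
  invisible(rep)
}

#' Generate the synthetic dataset for a run
#'
#' Builds a reference bundle and simulates per-sample FASTQ files with a
#' truth table. \code{manifest$sim} understands: n_species,
#' mirnas_per_species, n_samples_per_species, coverage, edit_freq (editing
#' frequency planted at one internal A per mature miRNA; 0 = none),
#' error_rate, tissues.
#'
#' @param manifest a \code{\link{run_manifest}}.
#' @return the output directory, invisibly.
#' @export
run_simulate <- function(manifest) {
  p <- manifest$sim
  bundle <- generate_reference(p$n_species %||% 2L,
                               p$mirnas_per_species %||% 10L,
                               seed = derive_seed(manifest$seed, 11L))
  tissues <- p$tissues %||% "brain"
  species <- unique(bundle$annotations$species)
  samples <- do.call(rbind, lapply(species, function(sp) {
    sample_meta(sprintf("%s_%s", sp, tissues), sp, tissue = tissues)
  }))
  ## conserved sites (homologous alignment columns) in the first
  ## n_edited_families eligible families; optional species-private sites
  ## in families beyond those
  edit_truth <- NULL
  ef <- p$edit_freq %||% 0
  sites <- pick_conserved_edit_sites(bundle)
  if (ef > 0 && !is.null(sites)) {
    fams <- unique(sites$family_id)
    n_ed <- min(p$n_edited_families %||% length(fams), length(fams))
    planted <- sites[sites$family_id %in% fams[seq_len(n_ed)], ,
                     drop = FALSE]
    edit_truth <- data.frame(species = planted$species,
                             mirna_id = planted$mirna_id,
                             position = planted$position, freq = ef,
                             stringsAsFactors = FALSE)
    n_priv <- p$n_private_sites %||% 0L
    if (n_priv > 0L) {
      rest <- sites[!sites$family_id %in% fams[seq_len(n_ed)], ,
                    drop = FALSE]
      priv_fams <- unique(rest$family_id)
      priv <- do.call(rbind, lapply(head(priv_fams, n_priv),
                                    function(fid) {
        rest[rest$family_id == fid, ][1, ]
      }))
      if (!is.null(priv) && nrow(priv)) {
        edit_truth <- rbind(edit_truth, data.frame(
          species = priv$species, mirna_id = priv$mirna_id,
          position = priv$position, freq = ef,
          stringsAsFactors = FALSE))
      }
    }
  }
  mat <- bundle$annotations[bundle$annotations$arm == "mature", ]
  expr <- data.frame(species = mat$species, mirna_id = mat$mirna_id,
                     mean_count = p$coverage %||% 500,
                     stringsAsFactors = FALSE)
  design <- sim_design(samples, expr, edit_truth = edit_truth,
                       error_rate = p$error_rate %||% 0.001,
                       seed = derive_seed(manifest$seed, 12L))
  sim <- simulate_reads(bundle, design)
  write_bundle(bundle, stage_path(manifest, "bundle"))
  dir.create(stage_path(manifest, "reads"), showWarnings = FALSE)
  for (sid in samples$sample_id) {
    write_fastq(sim$reads[sim$reads$sample_id == sid, , drop = FALSE],
                stage_path(manifest, "reads", paste0(sid, ".fastq")))
  }
  utils::write.table(samples, stage_path(manifest, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, stage_path(manifest, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_report(manifest, "simulate",
               list(n_reads = nrow(sim$reads),
                    n_samples = nrow(samples),
                    n_mirnas = nrow(mat)))
  invisible(manifest$output_dir)
}

## shared by detect/quantify: load bundle + samples + filtered reads
load_run_inputs <- function(manifest) {
  bdir <- require_artifact(manifest, "bundle", "simulate")
  samples <- utils::read.delim(require_artifact(manifest, "samples.tsv",
                                                "simulate"),
                               stringsAsFactors = FALSE)
  bundle <- read_bundle(bdir)
  reads <- list(); tallies <- list()
  for (sid in samples$sample_id) {
    fq <- require_artifact(manifest, file.path("reads",
                                               paste0(sid, ".fastq")),
                           "simulate")
    r <- read_fastq(fq)
    fl <- filter_reads(r, manifest$filter)
    fl$kept$sample_id <- sid
    reads[[sid]] <- fl$kept
    tallies[[sid]] <- fl$tally
  }
  list(bundle = bundle, samples = samples, reads = reads,
       filter_tallies = tallies)
}

#' Detect conserved editing events
#'
#' Preprocess, align, tally, filter and conservation-call; writes
#' \code{calls.tsv} and \code{events.tsv}.
#'
#' @param manifest a \code{\link{run_manifest}}.
#' @return the conserved-event \code{data.frame}, invisibly.
#' @export
run_detect <- function(manifest) {
  inp <- load_run_inputs(manifest)
  bundle <- inp$bundle
  ## each sample's reads are mapped against its own species' genome
  hits <- list()
  for (sp in unique(inp$samples$species)) {
    index <- build_index(species_contigs(bundle, sp))
    for (sid in inp$samples$sample_id[inp$samples$species == sp]) {
      hits[[sid]] <- align_reads(inp$reads[[sid]], index,
                                 policy = manifest$align)
    }
  }
  hits <- do.call(rbind, hits)
  tallies <- collect_site_tallies(hits, bundle$annotations, inp$samples)
  calls <- apply_site_filters(tallies, bundle$snps, manifest$caller)
  events <- call_conserved_events(calls, bundle$families,
                                  bundle$annotations,
                                  min_species = manifest$min_species,
                                  mode = manifest$conservation_mode)
  write_results(calls, stage_path(manifest, "calls.tsv"))
  write_results(events, stage_path(manifest, "events.tsv"))
  kept <- sum(vapply(inp$filter_tallies, `[[`, 0, "kept"))
  input <- sum(vapply(inp$filter_tallies, `[[`, 0, "input"))
  write_report(manifest, "detect", list(
    reads_in = input, reads_kept = kept,
    reads_rejected = input - kept,
    reads_mapped = sum(hits$state == "mapped"),
    reads_suppressed = sum(hits$state == "suppressed"),
    reads_unmapped = sum(hits$state == "unmapped"),
    n_candidate_sites = nrow(calls),
    n_events = nrow(events)))
  invisible(events)
}

#' Quantify editing frequencies by remapping
#'
#' For every detected event and sample, counts quality-filtered reads
#' against edited/unedited/fake variant references and writes
#' \code{quant.tsv} with the cross-mapping fraction.
#'
#' @param manifest a \code{\link{run_manifest}}.
#' @return the quant \code{data.frame}, invisibly.
#' @export
run_quantify <- function(manifest) {
  evp <- require_artifact(manifest, "events.tsv", "detect")
  events <- read_results(evp)
  inp <- load_run_inputs(manifest)
  bundle <- inp$bundle
  if (!nrow(events)) {
    quant <- data.frame()
    write_results(quant, stage_path(manifest, "quant.tsv"))
    write_report(manifest, "quantify", list(n_quants = 0L))
    return(invisible(quant))
  }
  fam <- bundle$families
  rows <- list()
  crossmap_n <- 0L; counted_n <- 0L
  ann <- bundle$annotations
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    members <- fam[fam$family_id == ev$family_id, , drop = FALSE]
    ## project the event's alignment column onto every member
    mrows <- ann[ann$arm == ev$arm &
                   paste(ann$species, ann$mirna_id) %in%
                   paste(members$species, members$mirna_id), ,
                 drop = FALSE]
    fa <- if (nrow(mrows) >= 2L) {
      align_family(setNames(mrows$seq, mrows$mirna_id))
    } else {
      list(colmap = setNames(list(seq_len(nchar(mrows$seq[1]))),
                             mrows$mirna_id))
    }
    for (j in seq_len(nrow(mrows))) {
      sp <- mrows$species[j]; mid <- mrows$mirna_id[j]
      pos <- match(ev$column, fa$colmap[[mid]])
      if (is.na(pos)) next                      # gap in this member
      row <- mrows[j, , drop = FALSE]
      if (substr(row$seq[1], pos, pos) != "A") next
      vr <- build_variant_refs(sp, mid, pos, bundle, arm = ev$arm,
                               flank = manifest$flank)
      loci <- data.frame(contig = row$contig,
                         start = max(0L, row$start - manifest$flank),
                         end = row$end + manifest$flank)
      for (sid in inp$samples$sample_id[inp$samples$species == sp]) {
        rc <- remap_and_count(inp$reads[[sid]], vr, sample_id = sid)
        counted <- inp$reads[[sid]][inp$reads[[sid]]$read_id %in%
                                      rc$read_assign$read_id, ,
                                    drop = FALSE]
        cm <- crossmap_check(counted, bundle$contigs[row$contig], loci)
        rc$quant$crossmap_fraction <- cm$fraction
        rc$quant$species <- sp
        rows[[length(rows) + 1L]] <- rc$quant
        crossmap_n <- crossmap_n + cm$n_crossmap
        counted_n <- counted_n + cm$n_reads
      }
    }
  }
  quant <- do.call(rbind, rows)
  write_results(quant, stage_path(manifest, "quant.tsv"))
  write_report(manifest, "quantify",
               list(n_quants = nrow(quant), n_counted = counted_n,
                    n_crossmap = crossmap_n))
  invisible(quant)
}

#' Age-correlation stage
#'
#' @param manifest a \code{\link{run_manifest}}.
#' @return the correlation table, invisibly.
#' @export
run_timecourse <- function(manifest) {
  qp <- require_artifact(manifest, "quant.tsv", "quantify")
  quant <- read_results(qp)
  samples <- utils::read.delim(require_artifact(manifest, "samples.tsv",
                                                "simulate"),
                               stringsAsFactors = FALSE)
  if (all(is.na(samples$age))) {
    stop("samples carry no ages; the time-course stage needs an age column",
         call. = FALSE)
  }
  ages <- setNames(samples$age, samples$sample_id)
  res <- age_correlation(quant, ages,
                         min_edited = manifest$min_edited_age)
  write_results(res, stage_path(manifest, "age_correlation.tsv"))
  write_report(manifest, "timecourse",
               list(n_mirnas = if (is.null(res)) 0L else nrow(res)))
  invisible(res)
}

#' Matched tumor/normal stage
#'
#' @param manifest a \code{\link{run_manifest}}.
#' @return the \code{\link{cancer_pair_analysis}} result, invisibly.
#' @export
run_cancer <- function(manifest) {
  qp <- require_artifact(manifest, "quant.tsv", "quantify")
  quant <- read_results(qp)
  samples <- utils::read.delim(require_artifact(manifest, "samples.tsv",
                                                "simulate"),
                               stringsAsFactors = FALSE)
  res <- cancer_pair_analysis(quant, samples,
                              min_reads = manifest$min_reads_cancer)
  if (!is.null(res$pairs)) {
    write_results(res$pairs, stage_path(manifest, "cancer_pairs.tsv"))
  }
  write_report(manifest, "cancer", list(
    n_tested = res$n_tested, n_down = res$n_down,
    p_binomial = res$p_binomial, n_sig = res$n_sig,
    n_down_sig = res$n_down_sig, p_binomial_sig = res$p_binomial_sig,
    n_excluded = res$n_excluded))
  invisible(res)
}
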