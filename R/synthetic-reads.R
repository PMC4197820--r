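## Small-RNA read simulator. Reads are drawn from annotated mature arms
## with (a) site-specific A->G edits at programmed per-sample frequencies,
## (b) a 5' cleavage offset drawn from a (possibly editing-coupled)
## distribution, (c) optional 1-2 nt non-templated 3' additions and
## (d) per-base substitution errors with qualities consistent with the
## error rate (Q30 for the default 0.001). A per-read truth table records
## origin, edited status and offset for exact accounting in tests.

#' Construct sample metadata
#'
#' @param sample_id,species character vectors (recycled to common length).
#' @param tissue tissue label (brain, cerebellum, heart, kidney, testis or
#'   free text).
#' @param age numeric age (optional).
#' @param condition "normal" or "tumor" (optional).
#' @param patient_id links matched tumor/normal pairs (optional).
#' @param replicate_id optional replicate label.
#' @return \code{data.frame} of sample metadata.
#' @export
sample_meta <- function(sample_id, species, tissue = "brain", age = NA_real_,
                        condition = NA_character_, patient_id = NA_character_,
                        replicate_id = NA_character_) {
  data.frame(sample_id = sample_id, species = species, tissue = tissue,
             age = age, condition = condition, patient_id = patient_id,
             replicate_id = replicate_id, stringsAsFactors = FALSE)
}

#' Specify a read-simulation design
#'
#' @param samples sample metadata (\code{\link{sample_meta}}).
#' @param expression data.frame with columns species, mirna_id, mean_count
#'   and optionally sample_id (absent = same expectation in every sample);
#'   read counts are Poisson around mean_count.
#' @param edit_truth data.frame with columns species, mirna_id, position
#'   (1-based within the mature sequence), freq in [0,1] and optionally
#'   sample_id. NULL = no editing.
#' @param error_rate per-base substitution error probability (default 0.001,
#'   i.e. Q30).
#' @param tail_add_prob probability of a 1-2 nt non-templated 3' addition.
#' @param five_prime_offsets named probability vector over 5' start offsets
#'   relative to the annotated start (negative = upstream).
#' @param edit_cleavage_coupling optional offset distribution used for
#'   edited transcripts instead of \code{five_prime_offsets}, to couple 5'
#'   cleavage with editing.
#' @param seed integer seed.
#' @return a \code{sim_design} list.
#' @export
sim_design <- function(samples, expression, edit_truth = NULL,
                       error_rate = 0.001, tail_add_prob = 0.15,
                       five_prime_offsets = c("-1" = 0.1, "0" = 0.8, "1" = 0.1),
                       edit_cleavage_coupling = NULL, seed = 1L) {
  stopifnot(is.data.frame(samples), nrow(samples) >= 1L)
  if (is.null(expression$sample_id)) {
    expression <- merge(expression,
                        data.frame(sample_id = samples$sample_id), by = NULL)
  }
  if (any(expression$mean_count < 0)) {
    stop("per-sample expected counts must be >= 0", call. = FALSE)
  }
  if (!is.null(edit_truth)) {
    if (is.null(edit_truth$sample_id)) {
      edit_truth <- merge(edit_truth,
                          data.frame(sample_id = samples$sample_id), by = NULL)
    }
    if (any(edit_truth$freq < 0 | edit_truth$freq > 1)) {
      stop("editing frequencies must lie in [0,1]", call. = FALSE)
    }
  }
  check_offset_dist <- function(d) {
    if (abs(sum(d) - 1) > 1e-8 || any(d < 0)) {
      stop("offset distribution must be non-negative and sum to 1",
           call. = FALSE)
    }
    if (is.null(names(d))) stop("offset distribution must be named",
                                call. = FALSE)
  }
  check_offset_dist(five_prime_offsets)
  if (!is.null(edit_cleavage_coupling)) check_offset_dist(edit_cleavage_coupling)
  if (error_rate < 0 || error_rate >= 1) {
    stop("error_rate must lie in [0,1)", call. = FALSE)
  }
  structure(list(samples = samples, expression = expression,
                 edit_truth = edit_truth, error_rate = error_rate,
                 tail_add_prob = tail_add_prob,
                 five_prime_offsets = five_prime_offsets,
                 edit_cleavage_coupling = edit_cleavage_coupling,
                 seed = as.integer(seed)),
            class = "sim_design")
}

## sense-orientation context around an annotation: `up` extra 5' bases
annotation_context <- function(ann_row, contigs, up = 2L) {
  ctg <- unlist(contigs)[[ann_row$contig]]
  if (ann_row$strand == "+") {
    s <- max(0L, ann_row$start - up)
    up_eff <- ann_row$start - s
    list(seq = substr(ctg, s + 1L, ann_row$end), up = up_eff)
  } else {
    e <- min(nchar(ctg), ann_row$end + up)
    up_eff <- e - ann_row$end
    list(seq = revcomp(substr(ctg, ann_row$start + 1L, e)), up = up_eff)
  }
}

#' Simulate small-RNA reads with truth table
#'
#' @param bundle a \code{ref_bundle}.
#' @param design a \code{sim_design}. Editing positions must be A in the
#'   mature sense sequence, otherwise the design is rejected.
#' @return list with \code{reads} (small-read data.frame with a
#'   \code{sample_id} column) and \code{truth} (one row per read:
#'   sample_id, species, mirna_id, edited, offset, tail_len, n_errors).
#' @export
simulate_reads <- function(bundle, design) {
  stopifnot(inherits(bundle, "ref_bundle"), inherits(design, "sim_design"))
  ann <- bundle$annotations
  expr <- design$expression
  key <- paste(expr$species, expr$mirna_id)
  ann_key <- paste(ann$species, ann$mirna_id)[ann$arm == "mature"]
  if (!all(key %in% ann_key)) {
    stop(sprintf("design references miRNA absent from bundle: %s",
                 key[!key %in% ann_key][1]), call. = FALSE)
  }
  ## validate edit sites: must be A in mature sense
  et <- design$edit_truth
  if (!is.null(et) && nrow(et)) {
    mat <- ann[ann$arm == "mature", ]
    usites <- unique(et[, c("species", "mirna_id", "position")])
    for (i in seq_len(nrow(usites))) {
      u <- usites[i, ]
      row <- mat[mat$species == u$species & mat$mirna_id == u$mirna_id, ]
      if (nrow(row) == 0L) {
        stop(sprintf("edit site on unknown miRNA %s/%s", u$species,
                     u$mirna_id), call. = FALSE)
      }
      if (u$position < 1L || u$position > nchar(row$seq[1]) ||
          substr(row$seq[1], u$position, u$position) != "A") {
        stop(sprintf(
          "editing frequency specified at non-A reference position: %s/%s pos %d",
          u$species, u$mirna_id, u$position), call. = FALSE)
      }
    }
  }

  qchar <- rawToChar(as.raw(error_rate_to_q(design$error_rate) + 33L))
  with_seed(design$seed, {
    all_reads <- list(); all_truth <- list()
    for (si in seq_len(nrow(design$samples))) {
      smp <- design$samples[si, ]
      erows <- expr[expr$sample_id == smp$sample_id &
                      expr$species == smp$species, , drop = FALSE]
      for (ei in seq_len(nrow(erows))) {
        mid <- erows$mirna_id[ei]
        n <- rpois(1L, erows$mean_count[ei])
        if (n == 0L) next
        row <- ann[ann$species == smp$species & ann$mirna_id == mid &
                     ann$arm == "mature", ][1, ]
        ctx <- annotation_context(row, bundle$contigs, up = 2L)
        mlen <- nchar(row$seq)
        sites <- if (is.null(et)) NULL else
          et[et$sample_id == smp$sample_id & et$species == smp$species &
               et$mirna_id == mid, , drop = FALSE]
        gen <- simulate_mirna_reads(n, ctx, mlen, sites, design, qchar)
        ids <- sprintf("%s:%s:%05d:e%d:o%+d", smp$sample_id, mid,
                       seq_len(n), as.integer(gen$edited), gen$offset)
        all_reads[[length(all_reads) + 1L]] <- data.frame(
          read_id = ids, seq = gen$seq, qual = gen$qual,
          sample_id = smp$sample_id, stringsAsFactors = FALSE)
        all_truth[[length(all_truth) + 1L]] <- data.frame(
          read_id = ids, sample_id = smp$sample_id, species = smp$species,
          mirna_id = mid, edited = gen$edited, offset = gen$offset,
          tail_len = gen$tail_len, n_errors = gen$n_errors,
          stringsAsFactors = FALSE)
      }
    }
    reads <- if (length(all_reads)) do.call(rbind, all_reads) else
      data.frame(read_id = character(0), seq = character(0),
                 qual = character(0), sample_id = character(0))
    truth <- if (length(all_truth)) do.call(rbind, all_truth) else
      data.frame(read_id = character(0), sample_id = character(0),
                 species = character(0), mirna_id = character(0),
                 edited = logical(0), offset = integer(0),
                 tail_len = integer(0), n_errors = integer(0))
    rownames(reads) <- rownames(truth) <- NULL
    list(reads = reads, truth = truth)
  })
}

## generate n reads for one miRNA in one sample
simulate_mirna_reads <- function(n, ctx, mlen, sites, design, qchar) {
  k <- if (is.null(sites)) 0L else nrow(sites)
  edited_mat <- if (k > 0) {
    matrix(runif(n * k) < rep(sites$freq, each = n), nrow = n)
  } else {
    matrix(FALSE, nrow = n, ncol = 0)
  }
  edited <- if (k > 0) rowSums(edited_mat) > 0 else rep(FALSE, n)

  offs_dist <- design$five_prime_offsets
  offsets <- integer(n)
  n_ed <- sum(edited)
  if (!is.null(design$edit_cleavage_coupling) && n_ed > 0) {
    cp <- design$edit_cleavage_coupling
    offsets[edited] <- as.integer(sample(names(cp), n_ed, TRUE, prob = cp))
    if (n_ed < n) {
      offsets[!edited] <- as.integer(sample(names(offs_dist), n - n_ed, TRUE,
                                            prob = offs_dist))
    }
  } else {
    offsets <- as.integer(sample(names(offs_dist), n, TRUE,
                                 prob = offs_dist))
  }
  offsets <- pmax(offsets, -ctx$up)

  ## group reads by (edit pattern, offset) and build each variant once
  pat <- if (k > 0) {
    apply(edited_mat, 1L, function(z) paste(as.integer(z), collapse = ""))
  } else rep("", n)
  grp_key <- paste(pat, offsets)
  uk <- unique(grp_key)
  variant <- vapply(uk, function(kk) {
    parts <- strsplit(kk, " ", fixed = TRUE)[[1]]
    o <- as.integer(parts[length(parts)])
    bits <- if (k > 0) as.integer(chars(parts[1])) else integer(0)
    s <- ctx$seq
    if (k > 0) {
      for (j in which(bits == 1L)) {
        p <- ctx$up + sites$position[j]
        substr(s, p, p) <- "G"
      }
    }
    substr(s, ctx$up + 1L + o, nchar(s))
  }, character(1))
  seqs <- variant[grp_key]

  ## 3' non-templated additions
  tail_len <- ifelse(runif(n) < design$tail_add_prob,
                     sample(1:2, n, replace = TRUE), 0L)
  wt <- which(tail_len > 0)
  if (length(wt)) {
    tails <- vapply(tail_len[wt], function(tl) {
      paste(sample(DNA_BASES, tl, replace = TRUE), collapse = "")
    }, character(1))
    seqs[wt] <- paste0(seqs[wt], tails)
  }

  ## per-base substitution errors
  lens <- nchar(seqs)
  n_err <- if (design$error_rate > 0) rbinom(n, lens, design$error_rate)
  else integer(n)
  we <- which(n_err > 0)
  for (i in we) {
    s <- chars(seqs[i])
    pos <- sample(seq_along(s), n_err[i])
    for (p in pos) s[p] <- sample(setdiff(DNA_BASES, s[p]), 1L)
    seqs[i] <- paste(s, collapse = "")
  }
  list(seq = unname(seqs), qual = strrep(qchar, nchar(seqs)),
       edited = edited, offset = offsets, tail_len = as.integer(tail_len),
       n_errors = as.integer(n_err))
}

## pick a plantable edit site per mature miRNA: an internal A surviving the
## edge-exclusion rules (>= position 3, <= length - 2)
pick_edit_sites <- function(ann) {
  mat <- ann[ann$arm == "mature", , drop = FALSE]
  out <- lapply(seq_len(nrow(mat)), function(i) {
    s <- chars(mat$seq[i])
    cand <- which(s == "A")
    cand <- cand[cand >= 3L & cand <= length(s) - 2L]
    if (!length(cand)) return(NULL)
    data.frame(species = mat$species[i], mirna_id = mat$mirna_id[i],
               position = cand[ceiling(length(cand) / 2)],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## pick one edit site per family at a homologous position: an alignment
## column that is A in every member and internal (edge-safe) in every
## member; returns one row per member with the per-member 1-based position
pick_conserved_edit_sites <- function(bundle) {
  fam_ids <- unique(bundle$families$family_id)
  mat <- bundle$annotations[bundle$annotations$arm == "mature", ]
  out <- lapply(fam_ids, function(fid) {
    mem <- bundle$families[bundle$families$family_id == fid, ]
    rows <- mat[paste(mat$species, mat$mirna_id) %in%
                  paste(mem$species, mem$mirna_id), , drop = FALSE]
    if (nrow(rows) == 0L) return(NULL)
    if (nrow(rows) == 1L) {
      s <- chars(rows$seq[1])
      cand <- which(s == "A")
      cand <- cand[cand >= 3L & cand <= length(s) - 2L]
      if (!length(cand)) return(NULL)
      p <- cand[ceiling(length(cand) / 2)]
      return(data.frame(family_id = fid, species = rows$species,
                        mirna_id = rows$mirna_id, position = p,
                        stringsAsFactors = FALSE))
    }
    fa <- align_family(setNames(rows$seq, rows$mirna_id))
    ncol_aln <- nchar(fa$aligned[[1]])
    ok_cols <- Filter(function(col) {
      all(vapply(seq_len(nrow(rows)), function(j) {
        p <- match(col, fa$colmap[[rows$mirna_id[j]]])
        !is.na(p) &&
          substr(rows$seq[j], p, p) == "A" &&
          p >= 3L && p <= nchar(rows$seq[j]) - 2L
      }, logical(1)))
    }, seq_len(ncol_aln))
    if (!length(ok_cols)) return(NULL)
    col <- ok_cols[[ceiling(length(ok_cols) / 2)]]
    data.frame(family_id = fid, species = rows$species,
               mirna_id = rows$mirna_id,
               position = vapply(rows$mirna_id, function(mid) {
                 match(col, fa$colmap[[mid]])
               }, integer(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Simulate a developmental time course with editing and target expression
#'
#' Editing frequency changes linearly (in expectation) with normalized age;
#' expression of genes designated as targets of the edited miRNA form
#' decreases with age with the stated effect size plus Gaussian noise,
#' while targets of the unedited form are age-independent.
#'
#' @param bundle a \code{ref_bundle}.
#' @param ages numeric vector of >= 3 ages (one sample per age).
#' @param edit_slope editing-frequency change over the full age range;
#'   scalar or named per-miRNA vector.
#' @param target_coupling expression decrease of edited-form targets over
#'   the full age range (same units as the expression values).
#' @param seed integer seed.
#' @param species species to simulate (default: first in the bundle).
#' @param coverage expected reads per miRNA per sample.
#' @param base_freq editing frequency at the youngest age.
#' @param expr_noise_sd Gaussian noise on expression values.
#' @param n_targets genes per miRNA per form.
#' @param error_rate per-base sequencing error rate.
#' @return list: \code{reads}, \code{truth} (read truth), \code{samples},
#'   \code{sites}, \code{truth_freq} (per miRNA/sample expected frequency),
#'   \code{expression} (genes x samples matrix), \code{targets} (gene,
#'   mirna_id, form).
#' @export
simulate_timecourse <- function(bundle, ages, edit_slope, target_coupling = 1,
                                seed = 1L, species = NULL, coverage = 200,
                                base_freq = 0.05, expr_noise_sd = 0.5,
                                n_targets = 20L, error_rate = 0.001) {
  if (length(ages) < 3L) stop("at least 3 ages are required", call. = FALSE)
  species <- species %||% bundle$annotations$species[1]
  ann <- bundle$annotations[bundle$annotations$species == species, ]
  sites <- pick_edit_sites(ann)
  if (is.null(sites) || nrow(sites) == 0L) {
    stop("no editable A positions in this bundle", call. = FALSE)
  }
  slope <- if (length(edit_slope) == 1L && is.null(names(edit_slope))) {
    setNames(rep(edit_slope, nrow(sites)), sites$mirna_id)
  } else edit_slope
  z <- if (diff(range(ages)) > 0) (ages - min(ages)) / diff(range(ages))
  else rep(0, length(ages))
  samples <- sample_meta(sprintf("age%02d", seq_along(ages)), species,
                         tissue = "brain", age = ages)
  truth_freq <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
    data.frame(species = species, mirna_id = sites$mirna_id[i],
               position = sites$position[i], sample_id = samples$sample_id,
               age = ages,
               freq = clamp01(base_freq + slope[[sites$mirna_id[i]]] * z),
               stringsAsFactors = FALSE)
  }))
  expr_tab <- data.frame(species = species, mirna_id = sites$mirna_id,
                         mean_count = coverage, stringsAsFactors = FALSE)
  design <- sim_design(samples, expr_tab,
                       edit_truth = truth_freq[, c("species", "mirna_id",
                                                   "position", "sample_id",
                                                   "freq")],
                       error_rate = error_rate, seed = derive_seed(seed, 1L))
  sim <- simulate_reads(bundle, design)

  gene_expr <- with_seed(derive_seed(seed, 2L), {
    tg <- do.call(rbind, lapply(sites$mirna_id, function(mid) {
      data.frame(gene = c(sprintf("g_%s_ed%02d", mid, seq_len(n_targets)),
                          sprintf("g_%s_un%02d", mid, seq_len(n_targets))),
                 mirna_id = mid,
                 form = rep(c("edited", "unedited"), each = n_targets),
                 stringsAsFactors = FALSE)
    }))
    slopes <- ifelse(tg$form == "edited", -target_coupling, 0)
    m <- outer(slopes, z) + 8 +
      matrix(rnorm(nrow(tg) * length(z), sd = expr_noise_sd),
             nrow = nrow(tg))
    dimnames(m) <- list(tg$gene, samples$sample_id)
    list(expression = m, targets = tg)
  })
  list(reads = sim$reads, truth = sim$truth, samples = samples,
       sites = sites, truth_freq = truth_freq,
       expression = gene_expr$expression, targets = gene_expr$targets)
}

#' Simulate matched tumor/normal sample pairs
#'
#' Each patient contributes a control and a tumor sample; the tumor editing
#' frequency is the patient's control frequency shifted by
#' \code{down_effect} and clamped to [0,1].
#'
#' @param bundle a \code{ref_bundle}.
#' @param n_patients number of patients (>= 1).
#' @param down_effect frequency shift in the tumor sample, in [-1, 1].
#' @param seed integer seed.
#' @param species species to simulate (default: first in the bundle).
#' @param coverage expected reads per miRNA per sample.
#' @param base_freq_range range of control-sample frequencies.
#' @param tissue tissue label for all samples.
#' @param error_rate per-base sequencing error rate.
#' @return list: \code{reads}, \code{truth}, \code{samples}, \code{sites},
#'   \code{truth_freq} (patient, mirna_id, control/tumor frequency).
#' @export
simulate_matched_pairs <- function(bundle, n_patients, down_effect, seed = 1L,
                                   species = NULL, coverage = 1000,
                                   base_freq_range = c(0.3, 0.7),
                                   tissue = "kidney", error_rate = 0.001) {
  stopifnot_scalar_count(n_patients, "n_patients")
  if (abs(down_effect) > 1) {
    stop("down_effect must lie in [-1, 1]", call. = FALSE)
  }
  species <- species %||% bundle$annotations$species[1]
  ann <- bundle$annotations[bundle$annotations$species == species, ]
  sites <- pick_edit_sites(ann)
  if (is.null(sites) || nrow(sites) == 0L) {
    stop("no editable A positions in this bundle", call. = FALSE)
  }
  pts <- sprintf("p%02d", seq_len(n_patients))
  samples <- rbind(
    sample_meta(paste0(pts, "_n"), species, tissue = tissue,
                condition = "normal", patient_id = pts),
    sample_meta(paste0(pts, "_t"), species, tissue = tissue,
                condition = "tumor", patient_id = pts))
  truth_freq <- with_seed(derive_seed(seed, 3L), {
    ctrl <- matrix(runif(n_patients * nrow(sites), base_freq_range[1],
                         base_freq_range[2]),
                   nrow = n_patients)
    do.call(rbind, lapply(seq_len(n_patients), function(p) {
      data.frame(patient_id = pts[p], species = species,
                 mirna_id = sites$mirna_id, position = sites$position,
                 control_freq = ctrl[p, ],
                 tumor_freq = clamp01(ctrl[p, ] + down_effect),
                 stringsAsFactors = FALSE)
    }))
  })
  edit_truth <- rbind(
    data.frame(species = species, mirna_id = truth_freq$mirna_id,
               position = truth_freq$position,
               sample_id = paste0(truth_freq$patient_id, "_n"),
               freq = truth_freq$control_freq, stringsAsFactors = FALSE),
    data.frame(species = species, mirna_id = truth_freq$mirna_id,
               position = truth_freq$position,
               sample_id = paste0(truth_freq$patient_id, "_t"),
               freq = truth_freq$tumor_freq, stringsAsFactors = FALSE))
  expr_tab <- data.frame(species = species, mirna_id = sites$mirna_id,
                         mean_count = coverage, stringsAsFactors = FALSE)
  design <- sim_design(samples, expr_tab, edit_truth = edit_truth,
                       error_rate = error_rate,
                       seed = derive_seed(seed, 4L))
  sim <- simulate_reads(bundle, design)
  list(reads = sim$reads, truth = sim$truth, samples = samples,
       sites = sites, truth_freq = truth_freq)
}
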