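## Downstream statistics: seed-region classification, BH correction,
## exact two-sided binomial direction tests, per-pair chi-squared tests
## for matched tumor/normal samples, Spearman age correlations,
## target-expression comparison, tissue/species group tests and Ward
## hierarchical clustering of editing profiles.

#' Classify positions relative to the miRNA seed region
#'
#' The seed region is nucleotides 2-7/8 from the miRNA 5' end and is the
#' main determinant of target recognition; the default span is [2, 8]
#' inclusive, configurable to [2, 7].
#'
#' @param position 1-based position(s) within the mature miRNA.
#' @param seed_span inclusive span, default \code{c(2, 8)}.
#' @return logical vector: position falls inside the seed.
#' @export
seed_classify <- function(position, seed_span = c(2L, 8L)) {
  stopifnot(all(position >= 1L))
  position >= seed_span[1] & position <= seed_span[2]
}

#' Fraction of events inside the seed region
#'
#' @param positions 1-based event positions.
#' @param seed_span inclusive seed span.
#' @return fraction in [0, 1].
#' @export
seed_fraction <- function(positions, seed_span = c(2L, 8L)) {
  mean(seed_classify(positions, seed_span))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR control (monotone, order-preserving).
#'
#' @param p p-values in [0, 1].
#' @return q-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Exact two-sided binomial test of direction
#'
#' Two-sided exact p-value by minimum-likelihood summation; at the default
#' p0 = 0.5 this equals twice the one-sided tail, capped at 1.
#'
#' @param k observed successes (e.g. pairs where editing went down).
#' @param n trials.
#' @param p0 null success probability (default 0.5).
#' @return the two-sided p-value.
#' @export
binomial_direction_test <- function(k, n, p0 = 0.5) {
  if (n < 1L) stop("n must be at least 1", call. = FALSE)
  stopifnot(k >= 0, k <= n)
  stats::binom.test(k, n, p = p0)$p.value
}

#' Chi-squared comparison of a matched sample pair
#'
#' 1-df chi-squared on the 2x2 (edited, unedited) x (control, tumor)
#' table, without continuity correction; direction from the frequency
#' comparison.
#'
#' @param control,tumor one-row quant data.frames (or lists) with
#'   \code{edited} and \code{unedited} counts.
#' @param min_reads per-sample coverage requirement (default 100 reads).
#' @return one-row data.frame: control/tumor counts and frequencies,
#'   direction ("down", "up" or "tied"), statistic, p_value,
#'   low_expectation, passes_coverage.
#' @export
chisq_pair_test <- function(control, tumor, min_reads = 100L) {
  cc <- c(control$edited, control$unedited)
  tc <- c(tumor$edited, tumor$unedited)
  passes <- sum(cc) >= min_reads && sum(tc) >= min_reads
  f_c <- editing_frequency(cc[1], cc[2])
  f_t <- editing_frequency(tc[1], tc[2])
  direction <- if (is.na(f_c) || is.na(f_t) || f_t == f_c) "tied"
  else if (f_t < f_c) "down" else "up"
  tab <- rbind(control = cc, tumor = tc)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stat <- 0; p <- 1; lowexp <- TRUE
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    stat <- unname(ct$statistic); p <- ct$p.value
    lowexp <- any(ct$expected < 5)
  }
  data.frame(control_edited = cc[1], control_unedited = cc[2],
             tumor_edited = tc[1], tumor_unedited = tc[2],
             control_freq = f_c, tumor_freq = f_t, direction = direction,
             statistic = stat, p_value = p, low_expectation = lowexp,
             passes_coverage = passes, stringsAsFactors = FALSE)
}

#' Matched tumor/normal editing analysis
#'
#' Runs \code{\link{chisq_pair_test}} for every miRNA-patient combination
#' with sufficient coverage in both samples, applies BH correction across
#' all pairs, and summarizes the direction of change with exact binomial
#' tests over (a) all combinations and (b) the significant ones.
#'
#' @param quants quant \code{data.frame} (rows from
#'   \code{\link{remap_and_count}}) with columns sample_id, mirna_id,
#'   edited, unedited.
#' @param samples sample metadata with condition ("normal"/"tumor") and
#'   patient_id.
#' @param min_reads coverage requirement per sample (default 100).
#' @param alpha significance level on the BH-adjusted p (default 0.05).
#' @return list: \code{pairs} (per-combination table with q_value,
#'   significant, direction), \code{n_down}, \code{n_tested},
#'   \code{p_binomial} (all combinations), \code{n_down_sig},
#'   \code{n_sig}, \code{p_binomial_sig}, \code{n_excluded}.
#' @export
cancer_pair_analysis <- function(quants, samples, min_reads = 100L,
                                 alpha = 0.05) {
  meta <- samples[match(quants$sample_id, samples$sample_id), ]
  quants$patient_id <- meta$patient_id
  quants$condition <- meta$condition
  combos <- unique(quants[, c("patient_id", "mirna_id")])
  rows <- list(); n_excluded <- 0L
  for (i in seq_len(nrow(combos))) {
    pc <- combos[i, ]
    ctrl <- quants[quants$patient_id == pc$patient_id &
                     quants$mirna_id == pc$mirna_id &
                     quants$condition == "normal", , drop = FALSE]
    tum <- quants[quants$patient_id == pc$patient_id &
                    quants$mirna_id == pc$mirna_id &
                    quants$condition == "tumor", , drop = FALSE]
    if (nrow(ctrl) != 1L || nrow(tum) != 1L) next
    res <- chisq_pair_test(ctrl, tum, min_reads = min_reads)
    if (!res$passes_coverage) {
      n_excluded <- n_excluded + 1L
      next
    }
    rows[[length(rows) + 1L]] <- cbind(pc, res)
  }
  if (!length(rows)) {
    return(list(pairs = NULL, n_down = 0L, n_tested = 0L,
                p_binomial = NA_real_, n_down_sig = 0L, n_sig = 0L,
                p_binomial_sig = NA_real_, n_excluded = n_excluded))
  }
  pairs <- do.call(rbind, rows)
  pairs$q_value <- bh_adjust(pairs$p_value)
  pairs$significant <- pairs$q_value < alpha
  n_tested <- nrow(pairs)
  n_down <- sum(pairs$direction == "down")
  sig <- pairs[pairs$significant & pairs$direction != "tied", ,
               drop = FALSE]
  n_sig <- nrow(sig)
  n_down_sig <- sum(sig$direction == "down")
  list(pairs = pairs, n_down = n_down, n_tested = n_tested,
       p_binomial = binomial_direction_test(n_down, n_tested),
       n_down_sig = n_down_sig, n_sig = n_sig,
       p_binomial_sig = if (n_sig > 0)
         binomial_direction_test(n_down_sig, n_sig) else NA_real_,
       n_excluded = n_excluded)
}

#' Spearman correlation of editing frequency (or expression) with age
#'
#' Replicate samples of the same age are expected to have been merged
#' upstream. miRNAs are kept only when detected in all samples and backed
#' by at least \code{min_edited} edited reads in total; BH correction is
#' applied across the retained miRNAs.
#'
#' @param quants quant \code{data.frame} with columns sample_id, mirna_id,
#'   edited, unedited, freq.
#' @param ages named numeric vector: age per sample_id.
#' @param min_edited minimum total edited reads per miRNA (default 10).
#' @return \code{data.frame}: mirna_id, rho, p_value, q_value, n_samples,
#'   constant (TRUE when the frequency series is constant and rho is
#'   undefined).
#' @export
age_correlation <- function(quants, ages, min_edited = 10L) {
  if (length(unique(ages)) < 3L) {
    stop("at least 3 age points are required", call. = FALSE)
  }
  res <- lapply(split(quants, quants$mirna_id), function(q) {
    if (!all(names(ages) %in% q$sample_id)) return(NULL)   # not in all samples
    q <- q[match(names(ages), q$sample_id), ]
    if (any(is.na(q$freq))) return(NULL)
    if (sum(q$edited) < min_edited) return(NULL)
    constant <- length(unique(q$freq)) == 1L
    if (constant) {
      return(data.frame(mirna_id = q$mirna_id[1], rho = NA_real_,
                        p_value = NA_real_, n_samples = nrow(q),
                        constant = TRUE, stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(stats::cor.test(q$freq, ages,
                                           method = "spearman"))
    data.frame(mirna_id = q$mirna_id[1], rho = unname(ct$estimate),
               p_value = ct$p.value, n_samples = nrow(q),
               constant = FALSE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) return(NULL)
  rownames(res) <- NULL
  res$q_value <- NA_real_
  ok <- !res$constant
  if (any(ok)) res$q_value[ok] <- bh_adjust(res$p_value[ok])
  res[, c("mirna_id", "rho", "p_value", "q_value", "n_samples",
          "constant")]
}

#' Compare age trends of edited-form vs unedited-form target genes
#'
#' Genes predicted as targets of both forms are excluded; per remaining
#' gene the Spearman correlation of expression with age is computed, and
#' the two rho distributions are compared with a two-sided Mann-Whitney
#' test.
#'
#' @param targets data.frame: gene, form ("edited"/"unedited").
#' @param expression genes x samples matrix of normalized expression.
#' @param ages numeric vector of ages, one per expression column.
#' @return list: \code{rho_edited}, \code{rho_unedited}, \code{p_value},
#'   \code{n_excluded} (shared genes removed).
#' @export
target_expression_comparison <- function(targets, expression, ages) {
  shared <- intersect(targets$gene[targets$form == "edited"],
                      targets$gene[targets$form == "unedited"])
  tg <- targets[!targets$gene %in% shared, , drop = FALSE]
  rho_of <- function(genes) {
    genes <- intersect(genes, rownames(expression))
    vapply(genes, function(g) {
      suppressWarnings(stats::cor.test(expression[g, ], ages,
                                       method = "spearman"))$estimate
    }, numeric(1), USE.NAMES = FALSE)
  }
  rho_e <- rho_of(unique(tg$gene[tg$form == "edited"]))
  rho_u <- rho_of(unique(tg$gene[tg$form == "unedited"]))
  if (!length(rho_e)) stop("edited-target set empty after exclusion",
                           call. = FALSE)
  if (!length(rho_u)) stop("unedited-target set empty after exclusion",
                           call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(rho_e, rho_u))
  p <- if (is.nan(wt$p.value)) 1 else wt$p.value
  list(rho_edited = rho_e, rho_unedited = rho_u, p_value = p,
       n_excluded = length(shared))
}

#' Neural vs non-neural editing comparison
#'
#' Two-sided Mann-Whitney test of editing frequencies in neural tissues
#' (brain, cerebellum) versus non-neural tissues (heart, kidney, testis).
#'
#' @param quants quant \code{data.frame} with \code{freq}; tissue comes
#'   from \code{samples}.
#' @param samples sample metadata (sample_id, tissue).
#' @param neural,non_neural tissue groupings.
#' @return list: \code{p_value}, \code{median_neural},
#'   \code{median_non_neural}, group sizes.
#' @export
tissue_comparison <- function(quants, samples,
                              neural = c("brain", "cerebellum"),
                              non_neural = c("heart", "kidney", "testis")) {
  tis <- samples$tissue[match(quants$sample_id, samples$sample_id)]
  x <- quants$freq[tis %in% neural & !is.na(quants$freq)]
  y <- quants$freq[tis %in% non_neural & !is.na(quants$freq)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each tissue group needs at least 2 observations", call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  ## degenerate all-tied groups carry no evidence of a difference
  list(p_value = if (is.nan(wt$p.value)) 1 else wt$p.value,
       median_neural = stats::median(x),
       median_non_neural = stats::median(y),
       n_neural = length(x), n_non_neural = length(y))
}

#' Paired between-species editing comparison
#'
#' Two-sided Wilcoxon signed-rank test on per-miRNA editing frequencies
#' matched across two species.
#'
#' @param freq_a,freq_b paired frequency vectors (same miRNA order).
#' @return list with \code{p_value} and the medians.
#' @export
species_comparison <- function(freq_a, freq_b) {
  stopifnot(length(freq_a) == length(freq_b), length(freq_a) >= 2L)
  wt <- suppressWarnings(stats::wilcox.test(freq_a, freq_b,
                                            paired = TRUE))
  list(p_value = if (is.nan(wt$p.value)) 1 else wt$p.value,
       median_a = stats::median(freq_a),
       median_b = stats::median(freq_b))
}

#' Ward hierarchical clustering of editing profiles
#'
#' Classic Ward clustering (Ward's minimum-variance criterion on squared
#' Euclidean distances) of per-tissue editing-frequency vectors.
#'
#' @param freq_matrix rows = profiles (e.g. miRNA x species), columns =
#'   tissues; rows with missing values are dropped.
#' @return an \code{hclust} object.
#' @export
cluster_profiles <- function(freq_matrix) {
  m <- freq_matrix[stats::complete.cases(freq_matrix), , drop = FALSE]
  if (nrow(m) < 2L) stop("need at least 2 complete profiles", call. = FALSE)
  stats::hclust(stats::dist(m)^2, method = "ward.D")
}
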