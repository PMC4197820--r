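test_that("reference generation is deterministic and respects its invariants", {
  b1 <- generate_reference(2, 5, seed = 1)
  b2 <- generate_reference(2, 5, seed = 1)
  expect_identical(b1, b2)
  b3 <- generate_reference(2, 5, seed = 2)
  expect_false(identical(b1$contigs, b3$contigs))

  b <- generate_reference(1, 1, seed = 7)
  ann <- b$annotations
  clen <- nchar(unlist(b$contigs))[ann$contig]
  expect_true(all(ann$start >= 0 & ann$end <= clen))

  ## annotated sequence equals the (strand-aware) genomic slice
  b <- generate_reference(3, 6, seed = 42)
  ann <- b$annotations
  ctg <- unlist(b$contigs)
  ex <- substr(ctg[ann$contig], ann$start + 1, ann$end)
  neg <- ann$strand == "-"
  ex[neg] <- revcomp(ex[neg])
  expect_equal(unname(ex), ann$seq)

  ## SNP ref base matches the contig
  expect_equal(unname(substr(ctg[b$snps$contig], b$snps$position + 1,
                             b$snps$position + 1)),
               b$snps$ref)

  ## orthologous mature sequences stay within the substitution bound
  mat <- ann[ann$arm == "mature", ]
  for (fid in unique(mat$family_id)) {
    s <- mat$seq[mat$family_id == fid]
    if (length(s) < 2) next
    d <- utils::adist(s)
    expect_true(all(d[upper.tri(d)] <= 3))
  }

  expect_error(generate_reference(0, 5, seed = 1), "positive integer")
  expect_error(generate_reference(2, -1, seed = 1), "positive integer")
})

test_that("full families carry one ortholog per species", {
  b <- generate_reference(6, 20, seed = 3)
  full <- b$family_info$family_id[b$family_info$full]
  expect_gt(length(full), 0)
  counts <- table(b$families$family_id[b$families$family_id %in% full])
  expect_true(all(counts == 6))
  ## species-restricted families exist and have fewer members
  restr <- b$family_info$family_id[!b$family_info$full]
  expect_true(all(table(b$families$family_id[b$families$family_id %in%
                                               restr]) < 6))
})

test_that("read simulation hits its editing limits and conserves reads", {
  b <- generate_reference(1, 3, seed = 11)
  sites <- mirededit:::pick_edit_sites(b$annotations)

  ## no-edit, no-error limit: every site base is A
  s0 <- sim_one(b, coverage = 200, freq = 0, error_rate = 0,
                tail_add_prob = 0, seed = 4)
  expect_equal(nrow(s0$reads), nrow(s0$truth))
  expect_true(all(!s0$truth$edited))
  for (i in seq_len(nrow(sites))) {
    tr <- s0$truth[s0$truth$mirna_id == sites$mirna_id[i], ]
    rd <- s0$reads[match(tr$read_id, s0$reads$read_id), ]
    base <- substr(rd$seq, sites$position[i] - tr$offset,
                   sites$position[i] - tr$offset)
    expect_true(all(base == "A"))
  }

  ## saturation limit: frequency 1 puts G at every spanning site
  s1 <- sim_one(b, coverage = 300, freq = 1, error_rate = 0,
                tail_add_prob = 0, seed = 5, sites = sites)
  for (i in seq_len(nrow(sites))) {
    tr <- s1$truth[s1$truth$mirna_id == sites$mirna_id[i], ]
    rd <- s1$reads[match(tr$read_id, s1$reads$read_id), ]
    base <- substr(rd$seq, sites$position[i] - tr$offset,
                   sites$position[i] - tr$offset)
    expect_true(all(base == "G"))
  }

  ## intermediate frequency: edited fraction inside the exact binomial
  ## 99% interval around 0.30
  big <- manual_bundle(paste0("CGGT", "A", strrep("CGGT", 4), "AG"))
  s3 <- sim_one(big, coverage = 5000, freq = 0.30, error_rate = 0,
                seed = 6,
                sites = data.frame(species = "spX",
                                   mirna_id = "spX-mir1", position = 5))
  n <- nrow(s3$truth)
  k <- sum(s3$truth$edited)
  expect_gte(k, qbinom(0.005, n, 0.30))
  expect_lte(k, qbinom(0.995, n, 0.30))

  ## design errors
  expect_error(
    sim_one(b, coverage = 10, freq = 0.5, seed = 1,
            sites = data.frame(species = b$annotations$species[1],
                               mirna_id = sites$mirna_id[1],
                               position = which(chars(
                                 b$annotations$seq[match(
                                   sites$mirna_id[1],
                                   b$annotations$mirna_id)]) != "A")[1])),
    "non-A")
})

test_that("simulation is deterministic and errors match the error model", {
  b <- generate_reference(2, 4, seed = 9)
  s1 <- sim_one(b, coverage = 150, freq = 0.2, seed = 21)
  s2 <- sim_one(b, coverage = 150, freq = 0.2, seed = 21)
  expect_identical(s1, s2)
  ## FASTQ bytes identical too
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(s1$reads, f1); write_fastq(s2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))

  ## no-signal null: A>G fraction at an A site consistent with
  ## error_rate / 3 per substitution type
  mat <- paste0("CGGT", "A", strrep("CGGT", 4), "AG")
  nb <- manual_bundle(mat)
  s <- sim_one(nb, coverage = 120000, freq = 0, error_rate = 0.001,
               tail_add_prob = 0, seed = 31)
  site <- 5L
  span <- s$truth$offset < site
  rd <- s$reads[span, ]
  base <- substr(rd$seq, site - s$truth$offset[span],
                 site - s$truth$offset[span])
  n <- length(base)
  expect_gt(n, 1e5)
  k <- sum(base == "G")
  expect_gte(k, qbinom(0.005, n, 0.001 / 3))
  expect_lte(k, qbinom(0.995, n, 0.001 / 3))
})

test_that("time-course simulation produces the programmed age trends", {
  b <- generate_reference(1, 4, seed = 13)
  expect_error(simulate_timecourse(b, ages = c(1, 2), edit_slope = 0.1),
               "3 ages")

  tc0 <- simulate_timecourse(b, ages = c(1, 5, 10, 20), edit_slope = 0,
                             seed = 2, coverage = 30)
  f <- tc0$truth_freq
  for (mid in unique(f$mirna_id)) {
    expect_equal(length(unique(f$freq[f$mirna_id == mid])), 1L)
  }

  tc1 <- simulate_timecourse(b, ages = seq(1, 12), edit_slope = 0.5,
                             seed = 3, coverage = 30)
  f <- tc1$truth_freq
  for (mid in unique(f$mirna_id)) {
    ff <- f[f$mirna_id == mid, ]
    expect_equal(unname(cor(ff$freq, ff$age, method = "spearman")), 1)
  }

  ## edited-form targets decline with age; unedited-form targets do not
  tc2 <- simulate_timecourse(b, ages = seq(1, 12), edit_slope = 0.4,
                             target_coupling = 3, expr_noise_sd = 0,
                             seed = 4, coverage = 30)
  tg <- tc2$targets
  ed <- tc2$expression[tg$gene[tg$form == "edited"], , drop = FALSE]
  un <- tc2$expression[tg$gene[tg$form == "unedited"], , drop = FALSE]
  expect_true(all(apply(ed, 1, function(x) cor(x, tc2$samples$age)) < 0))
  expect_true(all(abs(apply(un, 1, function(x) diff(range(x)))) < 1e-9))
})

test_that("matched-pair simulation applies the tumor shift exactly", {
  b <- generate_reference(1, 3, seed = 17)
  expect_error(simulate_matched_pairs(b, 3, down_effect = -1.5),
               "down_effect")
  expect_error(simulate_matched_pairs(b, 0, down_effect = 0),
               "positive integer")

  mp0 <- simulate_matched_pairs(b, 4, down_effect = 0, seed = 5,
                                coverage = 20)
  expect_equal(mp0$truth_freq$control_freq, mp0$truth_freq$tumor_freq)

  mp <- simulate_matched_pairs(b, 4, down_effect = -0.2, seed = 5,
                               coverage = 20,
                               base_freq_range = c(0.5, 0.5))
  expect_equal(unique(mp$truth_freq$control_freq), 0.5)
  expect_equal(unique(mp$truth_freq$tumor_freq), 0.3)
  ## pairing recorded
  expect_setequal(unique(mp$samples$condition), c("normal", "tumor"))
  expect_equal(sum(table(mp$samples$patient_id) == 2), 4)
})
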