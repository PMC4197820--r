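test_that("pairwise alignment matches the unit-cost DP optimum", {
  fa <- align_family(c(a = "ACGTACGTACGTACGTACGTAC",
                       b = "ACGTACGTACGTACGTACGTAC"))
  expect_equal(nchar(fa$aligned[["a"]]), 22L)
  expect_false(any(grepl("-", fa$aligned, fixed = TRUE)))

  fa <- align_family(c(a = "ACGT", b = "AGT"))
  expect_equal(nchar(fa$aligned[["a"]]), 4L)
  expect_equal(sum(chars(fa$aligned[["b"]]) == "-"), 1L)

  ## cost oracle: unit-cost edit distance via adist on perturbed 22-mers
  set.seed(42)
  for (i in 1:20) {
    a <- random_contig(22, seed = 1000 + i)
    s <- chars(a)
    for (p in sample(22, sample(0:3, 1))) {
      s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
    }
    if (runif(1) < 0.5) s <- s[-sample(length(s), 1)]
    b <- paste(s, collapse = "")
    expect_equal(mirededit:::nw_cost(a, b),
                 as.integer(utils::adist(a, b)))
  }

  expect_error(align_family(c(a = "", b = "ACGT")), "empty")
  expect_error(align_family(c(a = "ACGT")), "at least 2")
})

test_that("column maps are consistent and rows have equal length", {
  seqs <- c(x = "ACGTACGTACGTACGTACGTAC",
            y = "ACGTACGTACGACGTACGTAC",    # one deletion
            z = "ACGTACTTACGTACGTACGTAC")   # one substitution
  fa <- align_family(seqs)
  expect_equal(length(unique(nchar(fa$aligned))), 1L)
  for (m in names(seqs)) {
    ## degapping reproduces the input
    expect_equal(gsub("-", "", fa$aligned[[m]], fixed = TRUE),
                 unname(seqs[[m]]))
    ## position -> column -> position round trip
    cm <- fa$colmap[[m]]
    for (pos in seq_len(nchar(seqs[[m]]))) {
      expect_equal(match(cm[pos], cm), pos)
    }
  }
})

test_that("ortholog selection keeps the fewest-mismatch candidate", {
  ref <- "ACGTACGTACGTACGTACGTAC"
  one <- ref; substr(one, 5, 5) <- "T"
  three <- ref
  substr(three, 2, 2) <- "T"; substr(three, 9, 9) <- "A"
  substr(three, 15, 15) <- "T"
  cand <- data.frame(mirna_id = c("m-far", "m-near"),
                     seq = c(three, one), stringsAsFactors = FALSE)
  expect_equal(select_ortholog(cand, ref), "m-near")
  expect_equal(select_ortholog(cand[1, ], ref), "m-far")
  tie <- data.frame(mirna_id = c("m-b", "m-a"), seq = c(one, one),
                    stringsAsFactors = FALSE)
  expect_warning(sel <- select_ortholog(tie, ref), "tie")
  expect_equal(sel, "m-a")
})

## minimal call/annotation scaffolding for conservation calls
cons_fixture <- function() {
  seqA <- "CGGTCAGGTCGGCTTGCCGGTC"              # A at position 6
  seqB <- seqA; substr(seqB, 15, 15) <- "C"     # same A at position 6
  seqG <- seqA; substr(seqG, 6, 6) <- "G"       # G instead of A
  ann <- data.frame(
    species = c("spA", "spB", "spC"),
    mirna_id = c("spA-m1", "spB-m1", "spC-m1"),
    arm = "mature", family_id = "fam1",
    contig = paste0(c("spA", "spB", "spC"), "_chr1"),
    start = 10L, end = 32L, strand = "+",
    seq = c(seqA, seqB, seqG), stringsAsFactors = FALSE)
  fam <- data.frame(family_id = "fam1",
                    species = c("spA", "spB", "spC"),
                    mirna_id = c("spA-m1", "spB-m1", "spC-m1"),
                    stringsAsFactors = FALSE)
  list(ann = ann, fam = fam)
}

mk_call <- function(species, mirna_id, position, tier,
                    change = "A>G") {
  data.frame(species = species, mirna_id = mirna_id, arm = "mature",
             position = position, contig = paste0(species, "_chr1"),
             gpos = 9L + position, strand = "+", ref_base = "A",
             change = change, tier = tier, stringsAsFactors = FALSE)
}

test_that("conserved events need >= 2 species and a conserved A", {
  fx <- cons_fixture()
  ## high tier in two species at the homologous column: one event
  calls <- rbind(mk_call("spA", "spA-m1", 6L, "high"),
                 mk_call("spB", "spB-m1", 6L, "high"))
  ev <- call_conserved_events(calls, fx$fam, fx$ann, mode = "high",
                              species_set = c("spA", "spB", "spC"))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$n_species, 2L)
  expect_equal(ev$tier_spA, "high")
  expect_equal(ev$tier_spB, "high")
  expect_equal(ev$tier_spC, "none")     # ortholog annotated, no call

  ## one species only: no event
  ev1 <- call_conserved_events(calls[1, ], fx$fam, fx$ann)
  expect_equal(nrow(ev1), 0L)

  ## claiming species with G at the column violates the conserved-site rule
  calls_g <- rbind(mk_call("spA", "spA-m1", 6L, "high"),
                   mk_call("spC", "spC-m1", 6L, "high", change = "G>A"))
  evg <- call_conserved_events(calls_g, fx$fam, fx$ann)
  expect_equal(nrow(evg), 0L)

  ## high mode requires two high-tier species; relaxed mode accepts 1%
  calls_hr <- rbind(mk_call("spA", "spA-m1", 6L, "high"),
                    mk_call("spB", "spB-m1", 6L, "relaxed"))
  expect_equal(nrow(call_conserved_events(calls_hr, fx$fam, fx$ann,
                                          mode = "high")), 0L)
  expect_equal(nrow(call_conserved_events(calls_hr, fx$fam, fx$ann,
                                          mode = "relaxed")), 1L)

  ## orphan calls (miRNA in no family) are reported, not dropped silently
  orphan <- mk_call("spA", "spA-notInFamily", 6L, "high")
  evo <- call_conserved_events(rbind(calls, orphan), fx$fam, fx$ann)
  expect_equal(nrow(attr(evo, "orphans")), 1L)
  expect_equal(attr(evo, "orphans")$mirna_id, "spA-notInFamily")
})

test_that("adding a species without data never changes existing events", {
  fx <- cons_fixture()
  calls <- rbind(mk_call("spA", "spA-m1", 6L, "high"),
                 mk_call("spB", "spB-m1", 6L, "high"))
  ev <- call_conserved_events(calls, fx$fam, fx$ann,
                              species_set = c("spA", "spB"))
  ev2 <- call_conserved_events(calls, fx$fam, fx$ann,
                               species_set = c("spA", "spB", "spZ"))
  expect_equal(ev2$n_species, ev$n_species)
  expect_equal(ev2$n_high, ev$n_high)
  expect_equal(ev2$tier_spZ, "no-data")
  shared <- intersect(names(ev), names(ev2))
  expect_equal(ev2[, shared], ev[, shared])
})

test_that("planted conserved events are recovered exactly", {
  b <- generate_reference(6, 10, seed = 33)
  sites <- mirededit:::pick_conserved_edit_sites(b)
  full <- b$family_info$family_id[b$family_info$full]
  cons_f <- intersect(unique(sites$family_id), full)[1:3]
  restr <- setdiff(unique(sites$family_id), cons_f)[1:5]
  calls <- list()
  for (fid in cons_f) {
    ss <- sites[sites$family_id == fid, ]
    for (j in seq_len(nrow(ss))) {
      calls[[length(calls) + 1L]] <-
        mk_call(ss$species[j], ss$mirna_id[j], ss$position[j], "high")
    }
  }
  for (fid in restr) {                       # single-species signals
    ss <- sites[sites$family_id == fid, ][1, ]
    calls[[length(calls) + 1L]] <-
      mk_call(ss$species, ss$mirna_id, ss$position, "high")
  }
  calls <- do.call(rbind, calls)
  ev <- call_conserved_events(calls, b$families, b$annotations,
                              min_species = 2)
  expect_equal(nrow(ev), 3L)
  expect_setequal(ev$family_id, cons_f)
})

test_that("clade labels come from the smallest containing clade", {
  skip_if_not_installed("ape")
  fx <- cons_fixture()
  calls <- rbind(mk_call("spA", "spA-m1", 6L, "high"),
                 mk_call("spB", "spB-m1", 6L, "high"))
  ev <- call_conserved_events(calls, fx$fam, fx$ann,
                              species_set = c("spA", "spB", "spC"))
  tree <- ape::read.tree(
    text = "((spA,spB)abclade,(spC,spD)cdclade)root;")
  lab <- label_clades(ev, tree)
  expect_equal(lab$clade, "abclade")
  ## unlabeled internal nodes fall back to the tip list
  tree2 <- ape::read.tree(text = "((spA,spB),(spC,spD));")
  expect_equal(label_clades(ev, tree2)$clade, "spA+spB")
  ## single claiming species labels as itself
  ev1 <- ev
  ev1$tier_spB <- "trace"
  expect_equal(label_clades(ev1, tree)$clade, "spA")
})

test_that("the relaxed species scan tiers sites from read evidence", {
  ref <- "CGGTCAGGTCGGCTTGCCGGTC"             # A at position 6
  ortho <- ref; substr(ortho, 12, 12) <- "A"  # 1 mismatch from reference
  genome <- list(tg_chr1 = paste0(random_contig(60, 61), ortho,
                                  random_contig(60, 62)))
  edited <- ortho; substr(edited, 6, 6) <- "G"
  ev <- data.frame(mirna_id = "mirX", seq = ref, position = 6L,
                   stringsAsFactors = FALSE)

  r <- relaxed_species_scan(mk_reads(c(rep(edited, 2), rep(ortho, 100))),
                            ev, genome)
  expect_equal(r$tier, "relaxed")
  expect_equal(r$edited, 2L)
  expect_equal(r$unedited, 100L)

  r <- relaxed_species_scan(mk_reads(c(edited, rep(ortho, 999))), ev,
                            genome)
  expect_equal(r$tier, "trace")

  r <- relaxed_species_scan(mk_reads(rep(ortho, 50)), ev, genome)
  expect_equal(r$tier, "none")

  ## no reads over the site
  r <- relaxed_species_scan(mk_reads(substr(genome[[1]], 5, 26)), ev,
                            genome)
  expect_equal(r$tier, "no-data")

  ## reference unmappable in the target genome
  r <- relaxed_species_scan(mk_reads(rep(ortho, 10)),
                            data.frame(mirna_id = "mirY",
                                       seq = random_contig(22, 63),
                                       position = 6L),
                            genome)
  expect_equal(r$tier, "no-data")

  ## low site quality does not count toward the tier
  lowq <- small_reads("lq", edited, strrep("5", 22))   # Q20 everywhere
  r <- relaxed_species_scan(rbind(mk_reads(rep(ortho, 50)), lowq), ev,
                            genome, min_site_q = 30)
  expect_equal(r$edited, 0L)
})
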