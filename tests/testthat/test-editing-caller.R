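## a mature sequence with a single internal A at position 6
MAT_A6 <- "CGGTCAGGTCGGCTTGCCGGTC"

tally_row <- function(position = 6L, change = "A>G", tissue = "brain",
                      mm = 0L, edge = 0L, perfect = 0L, cov = 0L,
                      total = 0L, species = "spX", gpos = 15L) {
  data.frame(species = species, mirna_id = "spX-mir1", arm = "mature",
             position = position, contig = "spX_chr1", gpos = gpos,
             strand = "+", ref_base = "A", tissue = tissue,
             change = change, mm_reads = mm, edge_reads = edge,
             perfect_reads = perfect, site_coverage = cov,
             mirna_total = total, stringsAsFactors = FALSE)
}

test_that("mismatches are tallied in miRNA-sense coordinates", {
  for (strand in c("+", "-")) {
    b <- manual_bundle(MAT_A6, strand = strand,
                       left = substr(random_contig(80, 1), 1, 30),
                       right = substr(random_contig(80, 2), 1, 30))
    edited <- MAT_A6
    substr(edited, 6, 6) <- "G"
    reads <- mk_reads(c(rep(MAT_A6, 10), rep(edited, 4)))
    ch <- detect_chain(b, reads)
    tal <- ch$tallies
    expect_equal(nrow(tal), 1L)
    expect_equal(tal$position, 6L)
    expect_equal(tal$change, "A>G")     # genomic T>C when strand is -
    expect_equal(tal$mm_reads, 4L)
    expect_equal(tal$perfect_reads, 10L)
    expect_equal(tal$site_coverage, 14L)
    expect_equal(tal$mirna_total, 14L)
    if (strand == "-") {
      ## the genomic change really is T>C on the contig
      g <- tal$gpos
      expect_equal(substr(b$contigs[[1]], g + 1, g + 1), "T")
    }
  }
})

test_that("edge positions are excluded from the tally entirely", {
  mat <- paste0("A", substr(MAT_A6, 2, 22))        # A at position 1
  b <- manual_bundle(mat)
  edited <- mat
  substr(edited, 1, 1) <- "G"
  ch <- detect_chain(b, mk_reads(c(rep(mat, 10), rep(edited, 5))))
  expect_equal(nrow(ch$tallies), 0L)

  ## last two annotation positions likewise
  mat2 <- paste0(substr(MAT_A6, 1, 20), "AG")
  b2 <- manual_bundle(mat2)
  ed2 <- mat2
  substr(ed2, 21, 21) <- "G"
  ch2 <- detect_chain(b2, mk_reads(c(rep(mat2, 10), rep(ed2, 5))))
  expect_equal(nrow(ch2$tallies), 0L)
})

test_that("the filter battery assigns tiers and rejection flags", {
  ## high tier: 6 mismatch reads, 100 perfect, 5.7% of the miRNA total
  calls <- apply_site_filters(tally_row(mm = 6L, perfect = 100L,
                                        cov = 106L, total = 106L))
  expect_equal(calls$tier, "high")
  expect_true(classify_change(calls))

  ## mismatch frequency below 5% of the total: not high, still relaxed
  calls <- apply_site_filters(tally_row(mm = 6L, perfect = 194L,
                                        cov = 200L, total = 400L))
  expect_equal(calls$tier, "relaxed")

  ## relaxed tier: 2%
  calls <- apply_site_filters(tally_row(mm = 2L, perfect = 98L,
                                        cov = 100L, total = 100L))
  expect_equal(calls$tier, "relaxed")

  ## trace: below 1%
  calls <- apply_site_filters(tally_row(mm = 1L, perfect = 500L,
                                        cov = 501L, total = 501L))
  expect_equal(calls$tier, "trace")
  expect_true(calls$below_threshold)

  ## edge-only support is rejected
  calls <- apply_site_filters(tally_row(mm = 0L, edge = 5L,
                                        perfect = 50L, cov = 55L,
                                        total = 55L))
  expect_equal(calls$tier, "rejected")
  expect_true(calls$edge_excluded)

  ## no perfectly mapping read over the site
  calls <- apply_site_filters(tally_row(mm = 6L, perfect = 0L,
                                        cov = 6L, total = 200L))
  expect_true(calls$low_coverage)
  expect_equal(calls$tier, "rejected")

  ## two mismatch types above the error rate
  two <- rbind(tally_row(mm = 40L, perfect = 900L, cov = 1000L,
                         total = 1000L),
               tally_row(change = "A>C", mm = 3L, perfect = 900L,
                         cov = 1000L, total = 1000L))
  calls <- apply_site_filters(two)
  expect_true(calls$multi_type)
  expect_equal(calls$tier, "rejected")
  ## a second type at the error rate or below does not trigger it
  two$mm_reads[2] <- 1L
  calls <- apply_site_filters(two)
  expect_false(calls$multi_type)
  expect_equal(calls$tier, "relaxed")   # 4% is below the 5% high bar

  ## SNP overlap rejects the site
  snp <- data.frame(species = "spX", contig = "spX_chr1", position = 15L,
                    ref = "A", alt = "G", af = 0.2)
  calls <- apply_site_filters(tally_row(mm = 50L, perfect = 500L,
                                        cov = 550L, total = 550L), snp)
  expect_true(calls$snp_overlap)
  expect_equal(calls$tier, "rejected")
})

test_that("canonical classification flags A>G and refuses ties", {
  cp <- apply_site_filters(tally_row(change = "C>T", mm = 9L,
                                     perfect = 90L, cov = 99L,
                                     total = 99L))
  expect_false(classify_change(cp))

  tie <- rbind(tally_row(mm = 5L, perfect = 90L, cov = 100L,
                         total = 100L),
               tally_row(change = "A>T", mm = 5L, perfect = 90L,
                         cov = 100L, total = 100L))
  calls <- apply_site_filters(tie)
  expect_true(calls$change_tie)
  expect_warning(flag <- classify_change(calls), "tie")
  expect_false(flag)
})

test_that("tally frequencies track the planted editing frequency", {
  b <- manual_bundle(MAT_A6, left = substr(random_contig(80, 5), 1, 30),
                     right = substr(random_contig(80, 6), 1, 30))
  s <- sim_one(b, coverage = 800, freq = 0.2, error_rate = 0, seed = 9,
               sites = data.frame(species = "spX",
                                  mirna_id = "spX-mir1", position = 6))
  ch <- detect_chain(b, s$reads, s$samples)
  tal <- ch$tallies[ch$tallies$change == "A>G", ]
  expect_equal(nrow(tal), 1L)
  k <- tal$mm_reads
  n <- tal$site_coverage
  expect_gte(k, qbinom(0.005, n, 0.2))
  expect_lte(k, qbinom(0.995, n, 0.2))
  expect_equal(ch$calls$tier[ch$calls$change == "A>G"], "high")
})
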