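test_that("seed classification follows the 2-7/8 convention", {
  expect_false(seed_classify(1))
  expect_true(seed_classify(2))
  expect_true(seed_classify(8))
  expect_false(seed_classify(8, seed_span = c(2, 7)))
  expect_false(seed_classify(9))
  expect_error(seed_classify(0))
  expect_equal(seed_fraction(c(2, 5, 9, 20)), 0.5)
})

test_that("BH adjustment is the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  ## monotone in rank, never below p
  set.seed(3)
  p <- runif(40)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
})

test_that("the exact binomial direction test is two-sided and symmetric", {
  expect_equal(binomial_direction_test(5, 10), 1)
  expect_error(binomial_direction_test(3, 0), "at least 1")
  for (n in c(7, 26, 213)) {
    for (k in c(0, 3, n %/% 2, n)) {
      expect_equal(binomial_direction_test(k, n),
                   binomial_direction_test(n - k, n))
    }
  }
  ## doubled-tail identity at p0 = 0.5
  expect_equal(binomial_direction_test(21, 26),
               min(1, 2 * sum(dbinom(21:26, 26, 0.5))))
})

test_that("the pair chi-squared matches closed form and sets direction", {
  same <- chisq_pair_test(list(edited = 200, unedited = 800),
                          list(edited = 100, unedited = 400))
  expect_equal(same$p_value, 1)
  expect_equal(same$direction, "tied")

  cmp <- chisq_pair_test(list(edited = 200, unedited = 800),
                         list(edited = 100, unedited = 900))
  expect_equal(cmp$direction, "down")
  tab <- rbind(c(200, 800), c(100, 900))
  n <- sum(tab)
  stat <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    prod(rowSums(tab)) / prod(colSums(tab))
  expect_equal(cmp$statistic, stat)
  expect_equal(cmp$p_value, pchisq(stat, 1, lower.tail = FALSE))

  ## 1-df identity: chi-squared equals the squared two-proportion z
  set.seed(9)
  for (i in 1:10) {
    a <- rbinom(1, 500, 0.3) + 1; b <- 501 - a
    c_ <- rbinom(1, 400, 0.4) + 1; d <- 401 - c_
    r <- chisq_pair_test(list(edited = a, unedited = b),
                         list(edited = c_, unedited = d))
    p1 <- a / (a + b); p2 <- c_ / (c_ + d); pp <- (a + c_) / (a + b + c_ + d)
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / (a + b) + 1 / (c_ + d)))
    expect_equal(r$statistic, z^2, tolerance = 1e-10)
  }

  under <- chisq_pair_test(list(edited = 10, unedited = 50),
                           list(edited = 5, unedited = 20),
                           min_reads = 100)
  expect_false(under$passes_coverage)
})

test_that("age correlations enforce the coverage rule and BH-correct", {
  ages <- setNames(c(1, 2, 5, 10, 20, 40), paste0("s", 1:6))
  mk <- function(mid, freqs, edited = 20) {
    data.frame(sample_id = names(ages), mirna_id = mid,
               edited = edited, unedited = 100 - edited, freq = freqs,
               stringsAsFactors = FALSE)
  }
  q <- rbind(mk("up", c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)),
             mk("low", c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), edited = 1),
             mk("const", rep(0.3, 6)))
  r <- age_correlation(q, ages)
  expect_false("low" %in% r$mirna_id)        # < 10 edited reads
  expect_equal(r$rho[r$mirna_id == "up"], 1)
  expect_true(r$constant[r$mirna_id == "const"])
  expect_true(all(r$q_value >= r$p_value, na.rm = TRUE))
  expect_error(age_correlation(q, ages[1:2]), "3 age")

  ## rho invariant under strictly monotone transforms of age
  r2 <- age_correlation(q, setNames(log(ages), names(ages)))
  expect_equal(r2$rho, r$rho)
})

test_that("target-expression comparison excludes shared genes", {
  ages <- c(1, 2, 4, 8, 16, 32)
  set.seed(11)
  genes <- c(sprintf("e%02d", 1:12), sprintf("u%02d", 1:12), "shared")
  expr <- matrix(rnorm(length(genes) * 6, 5), nrow = length(genes),
                 dimnames = list(genes, paste0("s", 1:6)))
  expr[1:12, ] <- expr[1:12, ] - outer(rep(2, 12), seq(0, 5))  # declining
  tg <- data.frame(
    gene = genes[c(1:12, 13:24, 25, 25)],
    form = c(rep("edited", 12), rep("unedited", 12), "edited",
             "unedited"),
    stringsAsFactors = FALSE)
  r <- target_expression_comparison(tg, expr, ages)
  expect_equal(r$n_excluded, 1L)
  expect_equal(length(r$rho_edited), 12L)
  expect_lt(r$p_value, 0.01)
  expect_true(all(r$rho_edited < 0))

  ## identical rho distributions: no signal
  expr[genes[19:24], ] <- expr[genes[13:18], ]
  tg0 <- data.frame(gene = genes[13:24],
                    form = rep(c("edited", "unedited"), each = 6),
                    stringsAsFactors = FALSE)
  r0 <- target_expression_comparison(tg0, expr, ages)
  expect_gt(r0$p_value, 0.5)

  expect_error(
    target_expression_comparison(
      data.frame(gene = c("g", "g"), form = c("edited", "unedited")),
      expr, ages),
    "edited-target")
})

test_that("tissue and species comparisons run two-sided group tests", {
  samples <- sample_meta(paste0("s", 1:5), "hsa",
                         tissue = c("brain", "cerebellum", "heart",
                                    "kidney", "testis"))
  q <- data.frame(sample_id = rep(paste0("s", 1:5), each = 3),
                  mirna_id = rep(c("m1", "m2", "m3"), 5),
                  freq = 0.3, stringsAsFactors = FALSE)
  r <- tissue_comparison(q, samples)
  expect_equal(r$p_value, 1)

  qq <- q
  qq$freq <- ifelse(samples$tissue[match(qq$sample_id,
                                         samples$sample_id)] %in%
                      c("brain", "cerebellum"), 0.6, 0.1)
  r2 <- tissue_comparison(qq, samples)
  expect_lt(r2$p_value, 0.01)
  expect_gt(r2$median_neural, r2$median_non_neural)

  expect_error(tissue_comparison(q[1, ], samples), "at least 2")

  sp <- species_comparison(c(0.5, 0.3, 0.2, 0.6), c(0.5, 0.3, 0.2, 0.6))
  expect_equal(sp$p_value, 1)
})

test_that("Ward clustering is deterministic and merges identical profiles first", {
  m <- rbind(a = c(0.1, 0.2, 0.3), b = c(0.1, 0.2, 0.3),
             c = c(0.8, 0.7, 0.9), d = c(0.82, 0.71, 0.88))
  hc <- cluster_profiles(m)
  expect_s3_class(hc, "hclust")
  ## identical rows merge first, at height 0
  expect_equal(sort(abs(hc$merge[1, ])), c(1, 2))
  expect_equal(hc$height[1], 0)
  expect_identical(cluster_profiles(m), cluster_profiles(m))
  expect_error(cluster_profiles(m[1, , drop = FALSE]), "at least 2")
  ## grouping recovers the two blocks
  expect_equal(unname(cutree(hc, 2)), c(1, 1, 2, 2))
})
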