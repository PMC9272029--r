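test_that("base frequencies normalize depths and flag zero-depth sites", {
  expect_equal(base_frequencies(c(20, 0, 0, 20)), c(0.5, 0, 0, 0.5))
  expect_equal(base_frequencies(c(3, 1, 0, 0)), c(0.75, 0.25, 0, 0))
  f <- base_frequencies(c(0, 0, 0, 0))
  expect_true(isTRUE(attr(f, "undefined")))
  expect_error(ed_site(f, c(1, 0, 0, 0)), "undefined")
})

test_that("ed_site matches hand values and is symmetric, bounded, zero iff equal", {
  expect_equal(ed_site(c(1, 0, 0, 0), c(0, 0, 0, 1)), sqrt(2))
  expect_equal(ed_site(c(0.5, 0.5, 0, 0), c(0.25, 0.25, 0.25, 0.25)), 0.5)
  set.seed(1)
  for (i in 1:50) {
    p <- rdirichlet_test(4); q <- rdirichlet_test(4)
    e <- ed_site(p, q)
    expect_equal(e, ed_site(q, p))
    expect_gte(e, 0); expect_lte(e, sqrt(2) + 1e-12)
    if (e == 0) expect_equal(p, q)
    expect_equal(ed_site(p, p), 0)
  }
})

test_that("power correction matches closed form", {
  expect_equal(ed_power(0), 0)
  expect_equal(ed_power(0.5, 5), 0.03125)
  expect_equal(ed_power(sqrt(2), 5), 2^2.5)
})

test_that("tricube fit preserves constants and matches hand-computed weights", {
  pos <- c(0, 1000, 2000)
  expect_equal(fit_ed_profile(rep("c", 3), pos, rep(0.7, 3), 1500), rep(0.7, 3))
  # centre site with window 1500: neighbours at d = 1000 get tricube weight
  w <- (1 - (1000 / 1500)^3)^3
  got <- fit_ed_profile(rep("c", 3), pos, c(0, 1, 0), 1500)
  expect_equal(got[2], 1 / (1 + 2 * w))
  # isolated spike: fitted peak strictly below raw spike, mass spreads
  expect_lt(got[2], 1)
  expect_gt(got[1], 0)
  # single site keeps its own value
  expect_equal(fit_ed_profile("c", 5L, 0.3, 1000), 0.3)
})

test_that("threshold is median plus three population SDs", {
  expect_equal(ed_threshold(rep(3, 10)), 3)
  expect_equal(ed_threshold(c(0, 0, 0, 0, 10)), 12)
  expect_equal(ed_threshold(c(1, 2, 3)), 2 + 3 * sqrt(2 / 3))
  expect_error(ed_threshold(numeric(0)), "at least 2")
  set.seed(2)
  x <- stats::runif(200)
  expect_equal(ed_threshold(x), ed_threshold(sample(x)))  # order-invariant
})

test_that("candidate intervals follow strict-threshold run logic", {
  chrom <- rep("c", 4); pos <- c(100, 200, 300, 10000)
  fitted <- c(5, 5, 5, 5)
  iv <- extract_candidate_intervals(chrom, pos, fitted, threshold = 1,
                                    merge_gap_bp = 1000)
  expect_equal(iv$start, c(100, 10000))
  expect_equal(iv$end, c(300, 10000))
  # nothing above threshold
  expect_equal(nrow(extract_candidate_intervals(chrom, pos, fitted, 10, 1000)), 0L)
  # ties at the threshold are not above it
  expect_equal(nrow(extract_candidate_intervals(chrom, pos, fitted, 5, 1000)), 0L)
  # all above: one interval spanning first to last site
  iv2 <- extract_candidate_intervals(chrom, pos, fitted, 1, 1e6)
  expect_equal(nrow(iv2), 1L)
  expect_equal(c(iv2$start, iv2$end), c(100, 10000))
})

test_that("interval intersection sweeps per chromosome", {
  a <- data.frame(chrom = "c", start = 1, end = 100)
  b <- data.frame(chrom = "c", start = 50, end = 200)
  expect_equal(intersect_intervals(a, b),
               data.frame(chrom = "c", start = 50, end = 100))
  expect_equal(nrow(intersect_intervals(a, data.frame(chrom = "c", start = 500,
                                                      end = 600))), 0L)
  a2 <- data.frame(chrom = "c", start = c(1, 20), end = c(10, 30))
  b2 <- data.frame(chrom = "c", start = 5, end = 25)
  expect_equal(intersect_intervals(a2, b2),
               data.frame(chrom = "c", start = c(5, 20), end = c(10, 25)))
  # different chromosomes never intersect
  expect_equal(nrow(intersect_intervals(a, data.frame(chrom = "d", start = 1,
                                                      end = 100))), 0L)
})

test_that("identical pools give zero ED and no intervals; 4 pools give 6 comparisons", {
  set.seed(3)
  n <- 40
  depths <- array(0, dim = c(n, 2, 4))
  depths[, 1, 1] <- 30; depths[, 1, 2] <- 10
  depths[, 2, ] <- depths[, 1, ]
  tab <- pool_site_table(data.frame(chrom = "c", pos = seq_len(n) * 1000,
                                    class = rep(c("SNP", "InDel"), n / 2)),
                         depths, c("P1", "P2"))
  sc <- ed_scan(tab, "P1", "P2", "SNP")
  expect_true(all(sc$profile$ed_raw == 0))
  expect_equal(nrow(sc$intervals), 0L)

  sim <- simulate_pool_seq(pool_sim_config(n_sites = 300,
                                           chrom_lengths = c(chr1 = 3e6),
                                           causal_regions = data.frame(
                                             chrom = "chr1", start = 1e6,
                                             end = 2e6, effect = 0.7),
                                           seed = 5))
  res <- run_pcamp(sim$table)
  expect_length(res$comparisons, choose(4, 2))
  expect_named(res$comparisons[1], "R01-R02")
})

test_that("pipeline matches the brute-force oracle on small site sets", {
  for (seed in c(101, 202)) {
    sim <- simulate_pool_seq(pool_sim_config(n_sites = 400,
                                             chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
                                             causal_regions = data.frame(
                                               chrom = "chr1", start = 5e5,
                                               end = 1e6, effect = 0.8),
                                             seed = seed))
    tab <- sim$table
    for (cls in c("SNP", "InDel")) {
      sc <- ed_scan(tab, "R01", "R04", cls, window_bp = 3e5, merge_gap_bp = 1e5)
      keep <- tab$sites$class == cls &
        rowSums(tab$depths[, 1, ]) > 0 & rowSums(tab$depths[, 4, ]) > 0
      fa <- tab$depths[keep, 1, ] / rowSums(tab$depths[keep, 1, ])
      fb <- tab$depths[keep, 4, ] / rowSums(tab$depths[keep, 4, ])
      ed5 <- sqrt(rowSums((fa - fb)^2))^5
      fit <- naive_tricube(tab$sites$chrom[keep], tab$sites$pos[keep], ed5, 3e5)
      expect_equal(sc$profile$ed_fitted, fit)
      n <- length(fit)
      thr <- stats::median(fit) + 3 * sqrt(sum((fit - mean(fit))^2) / n)
      expect_equal(sc$threshold, thr)
      oracle <- naive_intervals(tab$sites$chrom[keep], tab$sites$pos[keep],
                                fit, thr, 1e5)
      expect_equal(sc$intervals$start, oracle$start)
      expect_equal(sc$intervals$end, oracle$end)
      expect_equal(sc$intervals$peak_ed_fitted, oracle$peak_ed_fitted)
    }
  }
})

test_that("sites with zero depth in either pool are excluded, not scored zero", {
  depths <- array(10, dim = c(3, 2, 4))
  depths[2, 1, ] <- 0
  tab <- pool_site_table(data.frame(chrom = "c", pos = c(100, 200, 300),
                                    class = "SNP"),
                         depths, c("P1", "P2"))
  sc <- ed_scan(tab, "P1", "P2", "SNP")
  expect_equal(sc$profile$pos, c(100, 300))
})
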