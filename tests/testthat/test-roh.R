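test_that("window heterozygosity counts match a brute-force recount", {
  fx <- make_roh_genome(4e6, 7e-4, contig = "c1", seed = 31)
  tr <- window_heterozygosity(fx$het_pos, fx$contig_lengths,
                              callable_pos = fx$callable_pos)
  i <- sample(nrow(tr), 25)
  for (k in i) {
    in_win <- fx$het_pos$pos > tr$start[k] & fx$het_pos$pos <= tr$end[k]
    in_call <- fx$callable_pos$pos > tr$start[k] &
      fx$callable_pos$pos <= tr$end[k]
    expect_equal(tr$n_het[k], sum(in_win))
    expect_equal(tr$n_callable[k], sum(in_call))
  }
  expect_equal(tr$het_rate, tr$n_het / tr$n_callable)
})

test_that("short contigs are excluded entirely", {
  het <- data.frame(chrom = c("big", "small"), pos = c(100, 100))
  tr <- window_heterozygosity(het, c(big = 5e6, small = 2e6))
  expect_true(all(tr$contig == "big"))
  expect_error(window_heterozygosity(het, c(5e6, 2e6)), "named")
})

test_that("a 0.2% window rate sits exactly at the threshold boundary", {
  # 5,000 callable sites with 10 het -> rate 0.002, not strictly below
  tr <- data.frame(contig = "c", start = seq(0, 11e4, 1e4),
                   end = seq(1e4, 12e4, 1e4),
                   n_callable = 5000, n_het = 10,
                   het_rate = 10 / 5000, masked = FALSE)
  expect_equal(nrow(detect_roh(tr)), 0)
  tr$n_het <- 9
  tr$het_rate <- 9 / 5000
  expect_equal(nrow(detect_roh(tr)), 1)
})

test_that("runs shorter than min_windows or broken by masks do not call", {
  tr <- data.frame(contig = "c", start = seq(0, 19e4, 1e4),
                   end = seq(1e4, 20e4, 1e4),
                   n_callable = 2000, n_het = 20,
                   het_rate = 0.01, masked = FALSE)
  tr$n_het[5:13] <- 0; tr$het_rate[5:13] <- 0        # 9 windows only
  expect_equal(nrow(detect_roh(tr)), 0)
  tr$n_het[4] <- 0; tr$het_rate[4] <- 0              # now 10 windows
  expect_equal(detect_roh(tr)$n_windows, 10)
  tr$masked[8] <- TRUE                               # mask breaks the run
  expect_equal(nrow(detect_roh(tr)), 0)
})

test_that("implanted tracts are recovered at the standard parameters", {
  tracts <- data.frame(start = c(1e6, 4e6, 7.5e6),
                       end = c(1.3e6, 5.8e6, 8.1e6))
  fx <- make_roh_genome(1e7, 7e-4, tracts, seed = 32)
  tr <- window_heterozygosity(fx$het_pos, fx$contig_lengths,
                              callable_pos = fx$callable_pos)
  segs <- detect_roh(tr)
  sc <- roh_score(segs, tracts)
  expect_gte(sc$recall, 0.95)
  expect_gte(sc$precision, 0.95)
})

test_that("F_ROH profile arithmetic and brute-force agreement", {
  segs <- data.frame(contig = "c", start = c(0, 5e6),
                     end = c(1.2e6, 5.5e6),
                     length = c(1.2e6, 0.5e6), n_windows = c(120, 50))
  pr <- froh_profile(segs, 1e8, cutoffs = c(1e5, 1e6))
  expect_equal(pr$froh[pr$cutoff_bp == 1e6], 0.012)
  expect_equal(pr$froh[pr$cutoff_bp == 1e5], 0.017)
  none <- froh_profile(segs[0, ], 1e8)
  expect_true(all(none$froh == 0))
  set.seed(33)
  lens <- sample(5e4:3e6, 40)
  rsegs <- data.frame(contig = "c", start = 0, end = lens, length = lens,
                      n_windows = 1)
  pr2 <- froh_profile(rsegs, 5e8)
  for (k in seq_len(nrow(pr2)))
    expect_equal(pr2$froh[k], oracle_froh(lens, 5e8, pr2$cutoff_bp[k]))
  expect_true(all(diff(pr2$froh) <= 0))  # monotone nonincreasing
  expect_error(froh_profile(rsegs, 0), "positive")
})

test_that("cohort F_ROH table: identical cohorts give F ~ 0, p ~ 1", {
  p1 <- froh_profile(data.frame(contig = "c", start = 0, end = 5e5,
                                length = 5e5, n_windows = 50), 1e8)
  profs <- list(a = p1, b = p1, c = p1, d = p1)
  res <- cohort_froh_table(profs, c("x", "x", "y", "y"))
  expect_true(all(res$anova$degenerate))
  expect_true(all(res$anova$p == 1))
  expect_error(cohort_froh_table(profs, c("x", "x", "x", "y")), "two")
})

test_that("shifted cohorts are detected by the per-bin ANOVA", {
  set.seed(34)
  mk <- function(mu) froh_profile(
    data.frame(contig = "c", start = 0, end = mu, length = mu,
               n_windows = mu / 1e4), 1e8)
  profs <- c(lapply(rnorm(8, 2e6, 1e5), mk), lapply(rnorm(8, 4e5, 5e4), mk))
  res <- cohort_froh_table(profs, rep(c("hi", "lo"), each = 8))
  expect_lt(min(res$anova$p[res$anova$cutoff_bp <= 4e5]), 0.01)
})
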