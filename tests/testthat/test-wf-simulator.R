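scaled_cfg <- function(seed = 1L, ...) {
  args <- list(n_diploid_initial = 100L, genome_elements = 5e4,
               mu = 2e-6, rec = 0, burnin_generations = 1000L,
               sample_size = 10L, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

test_that("zero mutation rate gives a monomorphic sample", {
  gm <- wf_simulate(scaled_cfg(mu = 0), drop_monomorphic = FALSE)
  expect_equal(n_sites(gm), 0)
})

test_that("identical seed and config reproduce bit-identical output", {
  a <- wf_simulate(scaled_cfg(seed = 42))
  b <- wf_simulate(scaled_cfg(seed = 42))
  expect_identical(a$gt, b$gt)
  expect_identical(a$pos, b$pos)
  c <- wf_simulate(scaled_cfg(seed = 43))
  expect_false(identical(a$gt, c$gt))
})

test_that("drift is a martingale: mean final frequency equals the start", {
  # 300 independent sites starting at frequency 0.3 in a N=50 deme
  cnt <- wf_drift(50, rep(30L, 300), n_generations = 25, seed = 5)
  expect_equal(mean(cnt) / 100, 0.3, tolerance = 0.04)
})

test_that("heterozygosity decays at rate 1/(2N) under pure drift", {
  n <- 100; t <- 60
  h <- sapply(1:60, function(r) {
    cnt <- wf_drift(n, rep(n, 40L), t, seed = 100 + r)
    p <- cnt / (2 * n)
    mean(2 * p * (1 - p))
  })
  expect_equal(mean(h), 0.5 * (1 - 1 / (2 * n))^t, tolerance = 0.05)
})

test_that("scenario validation rejects malformed epoch tables", {
  expect_error(demographic_scenario("x",
    data.frame(start_gen = c(0, 0), deme0 = c(10, 10)), 5))
  expect_error(demographic_scenario("x",
    data.frame(start_gen = 0, deme0 = 1), 5))
  expect_error(demographic_scenario("x",
    data.frame(start_gen = 0, deme0 = 10), 5, migration = 0.7),
    "migration")
  expect_error(demographic_scenario("x",
    data.frame(start_gen = 5, deme0 = 10), 10))
})

test_that("sampling more individuals than the final deme size errors", {
  lib <- scenario_library(n_anc = 100, horizon_generations = 30)
  cfg <- scaled_cfg(sample_size = 50)
  expect_error(wf_simulate(cfg, lib$bottleneck_80), "sample_size")
})

test_that("scenario library scenarios are valid and convert to years", {
  lib <- scenario_library(n_anc = 1000)
  expect_true(all(vapply(lib, inherits, logical(1),
                         "demographic_scenario")))
  bn <- lib$bottleneck_80
  expect_equal(bn$epochs$deme0[2] / bn$epochs$deme0[1], 0.2,
               tolerance = 0.01)
  # the drop sits ~5 generations (~130 years) before sampling
  years_before <- generations_to_years(
    bn$n_generations - bn$epochs$start_gen[2],
    bn$generation_time_years)
  expect_gte(years_before, 100)
  expect_lte(years_before, 155)
  mig <- lib$bottleneck_80_migration
  expect_true(all(mig$epochs$deme1 > 0))
  expect_true(all(mig$migration > 0))
})

test_that("generations_to_years applies the generation time", {
  expect_equal(generations_to_years(4), 103.6)
  expect_equal(generations_to_years(0), 0)
  expect_equal(generations_to_years(30), 777)
  expect_equal(generations_to_years(10, 2), 20)
  expect_error(generations_to_years(-1))
})

test_that("sample_fsfs with one replicate equals simulate + fold", {
  cfg <- scaled_cfg(seed = 9)
  one <- sample_fsfs(cfg, n_replicates = 1, seed = 9)
  direct <- fsfs_from_genotypes(wf_simulate(cfg))
  expect_equal(one$counts, direct$counts)
})

test_that("neutral equilibrium folded SFS matches the 1/i + 1/(2n-i) shape", {
  cfg <- sim_config(n_diploid_initial = 100L, genome_elements = rep(1e4, 20),
                    mu = 5e-6, rec = 0, burnin_generations = 1000L,
                    sample_size = 8L, seed = 77L)
  sfs <- sample_fsfs(cfg, n_replicates = 25, seed = 77)
  n <- 8; nh <- 16
  expected <- sapply(1:n, function(i)
    if (i < n) 1 / i + 1 / (nh - i) else 1 / i)
  expected <- expected / sum(expected)
  observed <- sfs$counts / sum(sfs$counts)
  expect_lt(max(abs(observed - expected)), 0.035)
})

test_that("a recent severe bottleneck pushes Tajima's D upward", {
  cfg <- sim_config(n_diploid_initial = 100L, genome_elements = rep(1e4, 15),
                    mu = 5e-6, rec = 0, burnin_generations = 1000L,
                    sample_size = 15L, seed = 1L)
  lib <- scenario_library(n_anc = 100)
  d_con <- sapply(1:8, function(k) {
    cfg$seed <- 200L + k
    tajimas_d(wf_simulate(cfg, lib$constant))
  })
  d_bot <- sapply(1:8, function(k) {
    cfg$seed <- 300L + k
    tajimas_d(wf_simulate(cfg, lib$bottleneck_80))
  })
  expect_gt(mean(d_bot), mean(d_con))
  expect_gt(mean(d_bot), 0)
})
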