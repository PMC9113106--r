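test_that("individual heterozygosity is het calls over callable sites", {
  gt <- matrix(c(1L, rep(0L, 9)), 10, 1)
  gm <- genotype_matrix(rep("c1", 10), 1:10, rep("A", 10), rep("T", 10),
                        gt, "s1")
  expect_equal(unname(individual_heterozygosity(gm)), 0.1)
  gm$gt[, 1] <- 0L
  expect_equal(unname(individual_heterozygosity(gm)), 0)
  gm$gt[, 1] <- NA
  expect_error(individual_heterozygosity(gm), "callable")
})

test_that("nucleotide diversity matches the hand-evaluated estimator", {
  gm <- genotype_matrix("c1", 1L, "A", "T", matrix(c(1L, 1L), 1, 2),
                        c("a", "b"))
  expect_equal(nucleotide_diversity(gm, 1000),
               2 * 0.25 * (4 / 3) / 1000, tolerance = 1e-12)
  mono <- genotype_matrix("c1", 1L, "A", ".", matrix(0L, 1, 2),
                          c("a", "b"))
  expect_equal(nucleotide_diversity(mono, 1000), 0)
  expect_error(nucleotide_diversity(gm, 0), "positive")
})

test_that("nucleotide diversity equals brute-force pairwise differences", {
  gm <- random_gm(120, 7, seed = 22)
  expect_equal(nucleotide_diversity(gm, 5000) * 5000,
               oracle_pi_total(gm), tolerance = 1e-8)
})

test_that("Watterson's theta matches the harmonic-number formula", {
  expect_equal(watterson_theta(5, 4, 1000), 5 / ((11 / 6) * 1000),
               tolerance = 1e-12)
  expect_equal(watterson_theta(0, 10, 1000), 0)
})

test_that("Tajima's D: zero numerator, oracle agreement, error cases", {
  gm <- random_gm(150, 8, seed = 23)
  expect_equal(tajimas_d(gm), oracle_tajimas_d(gm), tolerance = 1e-8)
  gm_miss <- random_gm(150, 8, seed = 24, missing_frac = 0.05)
  expect_equal(tajimas_d(gm_miss), oracle_tajimas_d(gm_miss),
               tolerance = 1e-8)
  few <- genotype_matrix(c("c1", "c1"), 1:2, rep("A", 2), rep("T", 2),
                         matrix(1L, 2, 3), c("a", "b", "c"))
  expect_error(tajimas_d(few), "fewer than 3")
})

test_that("F_H is zero at HW proportions and one for full homozygotes", {
  # large sample at HW for p=0.5; focal individual het at every site ->
  # O_hom = 0 < E_hom; fully hom individual -> 1
  set.seed(25)
  n_sites <- 2000
  gt <- matrix(rbinom(n_sites * 40, 2, 0.5), n_sites, 40)
  hom <- ifelse(rowMeans(gt) > 1, 2L, 0L)  # all-homozygous individual
  gm <- genotype_matrix(rep("c1", n_sites), 1:n_sites, rep("A", n_sites),
                        rep("T", n_sites), cbind(gt, hom),
                        c(sprintf("s%d", 1:40), "homo"))
  fh <- f_h(gm)
  expect_equal(unname(fh["homo"]), 1, tolerance = 1e-6)
  expect_equal(mean(fh[1:40]), 0, tolerance = 0.02)
  mono <- genotype_matrix("c1", 1L, "A", ".", matrix(0L, 1, 2),
                          c("a", "b"))
  expect_error(f_h(mono), "monomorphic")
})

test_that("selfed offspring have F_H near one half", {
  rel <- data.frame(id = sprintf("self%d", 1:10),
                    parent1 = sprintf("F%d", 1:10),
                    parent2 = sprintf("F%d", 1:10))
  ped <- make_pedigree_genotypes(40, 6000, rel, seed = 26)
  fh <- f_h(ped$genotypes)
  expect_equal(mean(fh[sprintf("self%d", 1:10)]), 0.5, tolerance = 0.1)
  expect_equal(mean(fh[sprintf("F%d", 11:40)]), 0, tolerance = 0.05)
})

test_that("cohort summary returns one labeled row per cohort", {
  gm <- random_gm(300, 12, seed = 27)
  gm$cohorts <- rep(c("x", "y"), each = 6)
  tab <- cohort_diversity(gm, 1e5)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("mean_het", "pi_per_site", "pi_per_variant",
                    "theta_w_per_site", "tajimas_d", "mean_f_h")
                  %in% names(tab)))
  expect_true(all(is.finite(tab$tajimas_d)))
})
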