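test_that("site filters remove the documented cases and report counts", {
  # 20 individuals: one site with 10% missing exceeds the 5% ceiling
  gt <- matrix(1L, 3, 20)
  gt[3, 1:2] <- NA
  gm <- genotype_matrix(rep("c1", 3), 1:3, c("A", "AT", "C"),
                        c("T", "A", "G"), gt, sprintf("s%d", 1:20))
  cfg <- site_filter_config(het_excess_max = 1, min_minor_allele_count = 0)
  res <- apply_site_filters(gm, cfg)
  expect_equal(res$report$sites_removed[res$report$rule == "indel"], 1)
  expect_equal(res$report$sites_removed[res$report$rule == "missingness"], 1)
  expect_equal(n_sites(res$genotypes), 1)
  expect_equal(sum(res$report$sites_removed),
               n_sites(gm) - n_sites(res$genotypes))
})

test_that("all-pass input returns identity and an all-zero report", {
  gm <- random_gm(30, 10, seed = 5)
  cfg <- site_filter_config(max_missing_frac = 1, het_excess_max = 1,
                            min_minor_allele_count = 0)
  res <- apply_site_filters(gm, cfg)
  expect_equal(res$genotypes$gt, gm$gt)
  expect_true(all(res$report$sites_removed == 0))
})

test_that("depth filter requires depths", {
  gm <- random_gm(10, 4, seed = 6)
  expect_error(apply_site_filters(gm, site_filter_config(),
                                  expected_mean_depth = 20),
               "no depths")
})

test_that("random fixture survivors equal brute-force per-site re-check", {
  gm <- random_gm(1000, 12, seed = 7, missing_frac = 0.04)
  gm$dp <- matrix(rpois(1000 * 12, 20), 1000, 12)
  # implant some pathological sites
  gm$ref[5] <- "AT"
  gm$alt[9] <- "T,G"
  gm$dp[17, ] <- 200
  cfg <- site_filter_config()
  res <- apply_site_filters(gm, cfg, expected_mean_depth = 20)
  keep <- oracle_filter_keep(gm, cfg, expected_mean_depth = 20)
  expect_equal(n_sites(res$genotypes), sum(keep))
  expect_equal(res$genotypes$pos, gm$pos[keep])
  expect_equal(sum(res$report$sites_removed), 1000 - sum(keep))
})

test_that("duplicate columns within the window are pruned, distant ones kept", {
  gt <- matrix(sample(0:2, 40, replace = TRUE), 4, 10, byrow = TRUE)
  gt[2, ] <- gt[1, ]            # duplicate 1 kb away
  gt[4, ] <- gt[3, ]            # duplicate but far away
  gm <- genotype_matrix(rep("c1", 4), c(1000L, 2000L, 5000L, 2e6L),
                        rep("A", 4), rep("T", 4), gt,
                        sprintf("s%d", 1:10))
  out <- ld_prune(gm, window_kb = 1000, r2_max = 0.9)
  expect_true(all(c(1000L, 5000L, 2e6L) %in% out$pos))
  expect_false(2000L %in% out$pos)
  expect_error(ld_prune(gm, r2_max = 1.5), "r2_max")
})

test_that("pruned output satisfies the pairwise r2 constraint and is idempotent", {
  gm <- random_gm(200, 15, seed = 8)
  out <- ld_prune(gm, window_kb = 2, r2_max = 0.5)
  expect_equal(oracle_ld_violations(out, 2, 0.5), 0)
  again <- ld_prune(out, window_kb = 2, r2_max = 0.5)
  expect_equal(again$pos, out$pos)
})

test_that("pi-hat: duplicates ~1, pedigree expectations, ordering", {
  rel <- data.frame(id = c("kid1", "kid2"),
                    parent1 = c("F1", "F3"), parent2 = c("F2", "F4"))
  ped <- make_pedigree_genotypes(30, 8000, rel, seed = 9)
  gm <- ped$genotypes
  # duplicate F1 as an extra column
  dup <- genotype_matrix(gm$chrom, gm$pos, gm$ref, gm$alt,
                         cbind(gm$gt, gm$gt[, 1]),
                         c(gm$samples, "F1copy"))
  ph <- estimate_pihat(dup)
  expect_gt(ph["F1", "F1copy"], 0.95)
  expect_equal(ph["F1", "kid1"], 0.5, tolerance = 0.05)
  unrelated <- ph["F5", "F6"]
  expect_equal(unrelated, 0, tolerance = 0.05)
  expect_true(ph["F1", "F1copy"] >= ph["F1", "kid1"])
  expect_true(ph["F1", "kid1"] >= unrelated)
  expect_true(isSymmetric(ph))
  expect_error(estimate_pihat(
    genotype_matrix("c1", 1L, "A", "T", matrix(0L, 1, 3),
                    c("a", "b", "c"))), "polymorphic")
})

test_that("remove_related drops one of a duplicated pair, nothing else", {
  gm <- make_pedigree_genotypes(12, 4000, seed = 10)$genotypes
  untouched <- remove_related(gm, 0.2)
  expect_equal(n_ind(untouched), 12)
  dup <- genotype_matrix(gm$chrom, gm$pos, gm$ref, gm$alt,
                         cbind(gm$gt, gm$gt[, 1]),
                         c(gm$samples, "F1copy"))
  cleaned <- remove_related(dup, 0.2)
  expect_equal(n_ind(cleaned), 12)
  expect_equal(sum(c("F1", "F1copy") %in% cleaned$samples), 1)
  expect_error(remove_related(gm, 1.2), "cutoff")
})

test_that("removing a trio's links leaves all pairs below the cutoff", {
  rel <- data.frame(id = "kid", parent1 = "F1", parent2 = "F2")
  ped <- make_pedigree_genotypes(8, 6000, rel, seed = 11)
  cleaned <- remove_related(ped$genotypes, 0.2)
  ph <- estimate_pihat(cleaned)
  diag(ph) <- 0
  expect_lt(max(ph), 0.2)
})

test_that("thin_sites enforces spacing, keeps sparse data, is reproducible", {
  gm <- genotype_matrix(rep("c1", 3), c(100L, 110L, 5000L),
                        rep("A", 3), rep("T", 3),
                        matrix(1L, 3, 2), c("a", "b"))
  out <- thin_sites(gm, 1000, seed = 3)
  expect_equal(n_sites(out), 2)  # one of the close pair + the far site
  expect_true(5000L %in% out$pos)
  sparse <- genotype_matrix(rep("c1", 3), c(1L, 5000L, 10000L),
                            rep("A", 3), rep("T", 3),
                            matrix(1L, 3, 1), "a")
  expect_equal(thin_sites(sparse, 1000, seed = 1)$pos, sparse$pos)
  big <- random_gm(300, 4, seed = 12)
  expect_equal(thin_sites(big, 500, seed = 7)$pos,
               thin_sites(big, 500, seed = 7)$pos)
  d <- diff(thin_sites(big, 500, seed = 7)$pos)
  expect_true(all(d >= 500))
})
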