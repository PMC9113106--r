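# Synthetic-data validation experiments. These bundle the package's
# standard self-checks -- simulator calibration against coalescent
# expectations, demographic model recovery, ROH recovery on implanted
# tracts, pedigree-based relatedness/inbreeding recovery, and the
# qualitative diversity-inbreeding relationships -- so that tests and
# reproduction scripts run the exact same procedures.

#' Simulator calibration against neutral coalescent expectations
#'
#' Runs replicate neutral Wright-Fisher simulations at a scaled size that
#' preserves the population-scaled recombination rate and compares
#' Watterson's theta and nucleotide diversity with the coalescent
#' expectation 4 N mu, and Tajima's D with 0.
#'
#' @param n_replicates number of independent replicates.
#' @param n_diploid diploid population size.
#' @param l_genome genome length in bp (single element).
#' @param mu,rec per-site per-generation rates.
#' @param sample_size sampled diploids.
#' @param seed base seed; replicate k uses \code{seed + k - 1}.
#' @return list with means, the 4 N mu target, and the per-replicate
#'   table.
#' @export
calibration_experiment <- function(n_replicates = 20L, n_diploid = 500L,
                                   l_genome = 1e5, mu = 1e-6, rec = 1e-6,
                                   sample_size = 20L, seed = 1L) {
  per_rep <- t(vapply(seq_len(n_replicates), function(k) {
    cfg <- sim_config(n_diploid_initial = n_diploid,
                      genome_elements = l_genome, mu = mu, rec = rec,
                      burnin_generations = 10L * n_diploid,
                      sample_size = sample_size,
                      seed = as.integer(seed + k - 1L))
    gm <- wf_simulate(cfg)
    c(theta_w = watterson_theta(n_sites(gm), 2L * sample_size, l_genome),
      pi = nucleotide_diversity(gm, l_genome),
      tajimas_d = tajimas_d(gm))
  }, numeric(3)))
  list(theta_w = mean(per_rep[, "theta_w"]),
       pi = mean(per_rep[, "pi"]),
       tajimas_d = mean(per_rep[, "tajimas_d"]),
       target_4nmu = 4 * n_diploid * mu,
       per_replicate = as.data.frame(per_rep))
}

#' Demographic model recovery experiment
#'
#' Simulates data under a recent 80% bottleneck and ranks it against
#' candidate spectra (constant size, gradual decline, bottleneck) by the
#' multinomial log-likelihood; also measures how adding migration from an
#' unaffected deme to the true scenario's candidate changes its
#' log-likelihood when the observed data had none.
#'
#' @param n_observed number of observed data replicates to rank.
#' @param n_candidate_reps replicates averaged per candidate spectrum.
#' @param n_anc scaled ancestral deme size.
#' @param seed base seed.
#' @return list with \code{recovery_rate}, \code{migration_delta_loglik}
#'   (mean log-likelihood drop of the migration variant), and the ranking
#'   outcomes.
#' @export
recovery_experiment <- function(n_observed = 50L, n_candidate_reps = 25L,
                                n_anc = 100L, seed = 1L) {
  cfg <- sim_config(n_diploid_initial = n_anc,
                    genome_elements = rep(1e4, 45), mu = 5e-6, rec = 1e-6,
                    burnin_generations = 10L * n_anc, sample_size = 20L,
                    seed = as.integer(seed))
  lib <- scenario_library(n_anc = n_anc)
  cand <- list(
    constant = sample_fsfs(cfg, lib$constant, n_candidate_reps,
                           seed = seed + 1000L),
    decline = sample_fsfs(cfg, lib$decline, n_candidate_reps,
                          seed = seed + 2000L),
    bottleneck = sample_fsfs(cfg, lib$bottleneck_80, n_candidate_reps,
                             seed = seed + 3000L))
  cand_mig <- sample_fsfs(cfg, lib$bottleneck_80_migration,
                          n_candidate_reps, seed = seed + 4000L)
  winner <- character(n_observed)
  delta_mig <- numeric(n_observed)
  for (k in seq_len(n_observed)) {
    cfg_k <- cfg
    cfg_k$seed <- as.integer(seed + 5000L + k)
    obs <- fsfs_from_genotypes(wf_simulate(cfg_k, lib$bottleneck_80))
    winner[k] <- rank_scenarios(obs, cand)$name[1]
    delta_mig[k] <- multinomial_loglik(obs, cand$bottleneck) -
      multinomial_loglik(obs, cand_mig)
  }
  list(recovery_rate = mean(winner == "bottleneck"),
       migration_delta_loglik = mean(delta_mig),
       winners = winner)
}

#' ROH recovery on implanted autozygous tracts
#'
#' Generates genomes with known autozygous tracts, calls ROH at the
#' standard parameters (10 kbp tiling windows, 0.2% heterozygosity
#' ceiling, 10-window minimum, 3 Mbp contig floor) and scores base-pair
#' precision, recall, and the boundary error against the truth.
#'
#' @param n_fixtures number of independent fixture genomes.
#' @param seed base seed.
#' @param window_size,het_threshold,min_windows detection parameters.
#' @return list with \code{precision}, \code{recall},
#'   \code{mean_boundary_error_windows},
#'   \code{max_boundary_error_windows} and the per-fixture profile
#'   monotonicity flag \code{froh_monotone}.
#' @export
roh_recovery_experiment <- function(n_fixtures = 3L, seed = 1L,
                                    window_size = 10000L,
                                    het_threshold = 0.002,
                                    min_windows = 10L) {
  tracts <- data.frame(start = c(1.0e6, 3.5e6, 6.0e6, 8.4e6),
                       end = c(1.2e6, 4.9e6, 6.4e6, 9.2e6))
  tp <- fp <- fn <- 0
  berr <- c()
  monotone <- TRUE
  for (f in seq_len(n_fixtures)) {
    fx <- make_roh_genome(1e7, 7e-4, tracts, seed = seed + f - 1L)
    tr <- window_heterozygosity(fx$het_pos, fx$contig_lengths,
                                window_size = window_size,
                                callable_pos = fx$callable_pos)
    segs <- detect_roh(tr, het_threshold = het_threshold,
                       min_windows = min_windows)
    for (k in seq_len(nrow(tracts))) {
      ov <- sum(pmax(0, pmin(segs$end, tracts$end[k]) -
                       pmax(segs$start, tracts$start[k])))
      tp <- tp + ov
      fn <- fn + (tracts$end[k] - tracts$start[k]) - ov
      sub <- segs[segs$end > tracts$start[k] &
                    segs$start < tracts$end[k], ]
      if (nrow(sub) > 0)
        berr <- c(berr, abs(min(sub$start) - tracts$start[k]),
                  abs(max(sub$end) - tracts$end[k]))
    }
    fp <- fp + sum(segs$length) - sum(vapply(seq_len(nrow(segs)),
      function(s) sum(pmax(0, pmin(segs$end[s], tracts$end) -
                             pmax(segs$start[s], tracts$start))),
      numeric(1)))
    prof <- froh_profile(segs, 1e7)
    monotone <- monotone && all(diff(prof$froh) <= 1e-12)
  }
  list(precision = tp / (tp + fp), recall = tp / (tp + fn),
       mean_boundary_error_windows = mean(berr) / window_size,
       max_boundary_error_windows = max(berr) / window_size,
       froh_monotone = monotone)
}

#' Relatedness and inbreeding recovery from pedigree fixtures
#'
#' Builds a pedigree with parent-offspring pairs, unrelated founders and
#' selfed offspring, and measures pi-hat and F_H against their pedigree
#' expectations (0.5, 0, and 0.5 respectively); the random-mating founder
#' cohort's mean F_H is expected near 0.
#'
#' @param n_founders number of founders.
#' @param n_sites independent sites.
#' @param seed RNG seed.
#' @return list with \code{pihat_parent_offspring},
#'   \code{pihat_unrelated}, \code{fh_selfed}, \code{fh_random_mating}.
#' @export
pedigree_experiment <- function(n_founders = 40L, n_sites = 10000L,
                                seed = 1L) {
  rel <- rbind(
    data.frame(id = sprintf("po%d", 1:6),
               parent1 = sprintf("F%d", 1:6),
               parent2 = sprintf("F%d", 7:12)),
    data.frame(id = sprintf("self%d", 1:6),
               parent1 = sprintf("F%d", 13:18),
               parent2 = sprintf("F%d", 13:18)))
  ped <- make_pedigree_genotypes(n_founders, n_sites, rel, seed = seed)
  gm <- ped$genotypes
  ph <- estimate_pihat(gm)
  po <- mean(vapply(1:6, function(k)
    ph[sprintf("F%d", k), sprintf("po%d", k)], numeric(1)))
  founders <- sprintf("F%d", 19:n_founders)
  sub <- ph[founders, founders]
  unrel <- mean(sub[upper.tri(sub)])
  fh <- f_h(gm)
  list(pihat_parent_offspring = po,
       pihat_unrelated = unrel,
       fh_selfed = mean(fh[sprintf("self%d", 1:6)]),
       fh_random_mating = mean(fh[founders]))
}

#' Heterozygosity versus F_ROH across an inbreeding gradient
#'
#' Simulates individuals whose genomes carry increasing fractions of
#' autozygous tracts and correlates genome-wide heterozygosity with the
#' total F_ROH called from the same data; the association is expected to
#' be strongly negative.
#'
#' @param n_individuals gradient size.
#' @param max_fraction largest autozygous genome fraction.
#' @param seed base seed.
#' @return list with Pearson \code{r}, \code{p} and the per-individual
#'   table.
#' @export
inbreeding_gradient_experiment <- function(n_individuals = 10L,
                                           max_fraction = 0.5,
                                           seed = 1L) {
  l <- 1e7
  frac <- seq(0, max_fraction, length.out = n_individuals)
  tab <- do.call(rbind, lapply(seq_len(n_individuals), function(i) {
    n_tr <- 4L
    tlen <- frac[i] * l / n_tr
    starts <- seq(0.5e6, 8.5e6, length.out = n_tr)
    tracts <- if (tlen > 0)
      data.frame(start = starts, end = starts + tlen)
    else data.frame(start = numeric(0), end = numeric(0))
    fx <- make_roh_genome(l, 7e-4, tracts, seed = seed + i)
    he <- nrow(fx$het_pos) / nrow(fx$callable_pos)
    tr <- window_heterozygosity(fx$het_pos, fx$contig_lengths,
                                callable_pos = fx$callable_pos)
    segs <- detect_roh(tr)
    froh <- froh_profile(segs, l)$froh[1]
    data.frame(individual = i, autozygous_fraction = frac[i],
               het = he, froh = froh)
  }))
  ct <- pearson_correlation(tab$het, tab$froh)
  list(r = ct$r, p = ct$p, table = tab)
}

#' Cohort-separation null check on a panmictic sample
#'
#' Simulates one panmictic population, labels arbitrary cohorts, and runs
#' the PCoA label-permutation test; structure should not be detected.
#'
#' @param seed RNG seed.
#' @return list with the permutation \code{p_value} and the PCoA result.
#' @export
panmixia_experiment <- function(seed = 1L) {
  cfg <- sim_config(n_diploid_initial = 100L,
                    genome_elements = rep(1e4, 20), mu = 5e-6, rec = 1e-6,
                    burnin_generations = 1000L, sample_size = 24L,
                    seed = as.integer(seed))
  gm <- make_cohort_fixture(cfg, cohort_sizes = c(c1 = 8L, c2 = 8L,
                                                  c3 = 8L))
  pc <- pcoa_classic(allele_sharing_distance(gm), 2)
  sep <- pcoa_separation_test(pc, gm$cohorts, seed = seed)
  list(p_value = sep$p_value, pcoa = pc)
}
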