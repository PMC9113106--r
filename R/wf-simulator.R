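#' Wright-Fisher simulation configuration
#'
#' Parameters of the forward-in-time diploid simulator. The defaults are the
#' full-scale design used for whale-bottleneck scenario simulation: an
#' ancestral population of 50,000 diploids, three independently assorting
#' 10 Mbp genomic elements, a mutation rate of 1.54e-9 per site per
#' generation, a recombination rate of 1e-8 per site per generation, and a
#' 100,000-generation neutral burn-in. Tests and examples use scaled-down
#' configurations that preserve the population-scaled parameters.
#'
#' @param n_diploid_initial ancestral (burn-in) diploid population size.
#' @param genome_elements lengths in bp of the independently assorting
#'   genomic elements.
#' @param mu per-site per-generation mutation probability.
#' @param rec per-site per-generation recombination (crossover) probability.
#' @param burnin_generations neutral generations before demographic events.
#' @param sample_size number of diploids sampled at the final generation.
#' @param seed integer RNG seed.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_diploid_initial = 50000L,
                       genome_elements = c(1e7, 1e7, 1e7),
                       mu = 1.54e-9, rec = 1e-8,
                       burnin_generations = 100000L,
                       sample_size = 51L, seed = 1L) {
  stopifnot(mu >= 0, rec >= 0, all(genome_elements > 0),
            n_diploid_initial >= 2, burnin_generations >= 1,
            sample_size >= 1)
  structure(list(n_diploid_initial = as.integer(n_diploid_initial),
                 genome_elements = as.numeric(genome_elements),
                 mu = mu, rec = rec,
                 burnin_generations = as.integer(burnin_generations),
                 sample_size = as.integer(sample_size),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Demographic scenario
#'
#' A piecewise-constant deme-size history applied after burn-in, optionally
#' with a second deme and symmetric migration. Epoch rows give the
#' post-burn-in generation at which the sizes take effect; the focal
#' (sampled) deme is always deme 0. A second deme is founded from deme 0 at
#' the first generation it appears with a positive size.
#'
#' @param name scenario label.
#' @param epochs data.frame with columns \code{start_gen} (post-burn-in
#'   offsets, strictly increasing, first row 0), \code{deme0} and optionally
#'   \code{deme1} (diploid sizes; 0 means absent).
#' @param n_generations total post-burn-in generations; sampling happens at
#'   this generation.
#' @param migration per-epoch probability that a parent is drawn from the
#'   other deme (recycled if scalar); must lie in [0, 0.5].
#' @param generation_time_years years per generation, used only to report
#'   time scales in years (25.9 by default).
#' @return an object of class \code{demographic_scenario}.
#' @export
demographic_scenario <- function(name, epochs, n_generations,
                                 migration = 0,
                                 generation_time_years = 25.9) {
  epochs <- as.data.frame(epochs)
  if (is.null(epochs$deme1)) epochs$deme1 <- 0L
  stopifnot(nrow(epochs) >= 1,
            all(diff(epochs$start_gen) > 0),
            epochs$start_gen[1] == 0,
            all(epochs$deme0 >= 2),
            all(epochs$deme1 == 0 | epochs$deme1 >= 2),
            n_generations > max(epochs$start_gen))
  migration <- rep_len(migration, nrow(epochs))
  if (any(migration < 0 | migration > 0.5))
    stop("migration rates must lie in [0, 0.5]")
  structure(list(name = name,
                 epochs = data.frame(start_gen = as.integer(epochs$start_gen),
                                     deme0 = as.integer(epochs$deme0),
                                     deme1 = as.integer(epochs$deme1)),
                 n_generations = as.integer(n_generations),
                 migration = migration,
                 generation_time_years = generation_time_years),
            class = "demographic_scenario")
}

#' @export
print.demographic_scenario <- function(x, ...) {
  cat("demographic_scenario '", x$name, "': ", x$n_generations,
      " generations after burn-in (",
      round(generations_to_years(x$n_generations,
                                 x$generation_time_years)),
      " years)\n", sep = "")
  print(cbind(x$epochs, migration = x$migration), row.names = FALSE)
  invisible(x)
}

# Epoch schedule (n_gen, n0, n1, m) consumed by the C++ core.
scenario_schedule <- function(cfg, scenario) {
  sched <- data.frame(n_gen = cfg$burnin_generations,
                      n0 = cfg$n_diploid_initial, n1 = 0L, m = 0)
  if (!is.null(scenario)) {
    ep <- scenario$epochs
    dur <- diff(c(ep$start_gen, scenario$n_generations))
    sched <- rbind(sched,
                   data.frame(n_gen = dur, n0 = ep$deme0, n1 = ep$deme1,
                              m = scenario$migration))
  }
  sched
}

#' Run a forward Wright-Fisher simulation
#'
#' Simulates a diploid Wright-Fisher population under a finite-sites
#' mutation model (hits on an already-segregating position flip the allele,
#' so back mutation is possible) with Poisson crossovers within each genomic
#' element and free assortment between elements. After the burn-in at the
#' ancestral size the demographic scenario's epochs are applied, and
#' \code{sample_size} individuals are drawn without replacement from deme 0
#' at the final generation. Runs are bit-reproducible for a given seed.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param scenario a \code{\link{demographic_scenario}}, or NULL for a
#'   constant-size (burn-in only) run.
#' @param drop_monomorphic drop sites that are monomorphic within the
#'   sample (default TRUE).
#' @param sample_both_demes split the sample evenly between the two demes
#'   (requires a two-deme scenario); the returned matrix then carries
#'   cohort labels \code{deme0}/\code{deme1}. Default FALSE: all
#'   individuals come from the focal deme 0.
#' @return a \code{\link{genotype_matrix}} of the sampled individuals with
#'   contigs named \code{elem1}, \code{elem2}, ...
#' @export
wf_simulate <- function(cfg, scenario = NULL, drop_monomorphic = TRUE,
                        sample_both_demes = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  sched <- scenario_schedule(cfg, scenario)
  final_n0 <- sched$n0[nrow(sched)]
  final_n1 <- sched$n1[nrow(sched)]
  set.seed(cfg$seed)
  n_hap0 <- 2L * cfg$n_diploid_initial
  if (sample_both_demes) {
    n_a <- cfg$sample_size %/% 2L
    n_b <- cfg$sample_size - n_a
    if (n_a > final_n0 || n_b > final_n1)
      stop("sample_size exceeds the final deme sizes")
  } else if (cfg$sample_size > final_n0) {
    stop("sample_size exceeds the final size of the sampled deme")
  }
  st <- wf_run_cpp(matrix(0L, n_hap0, 0), matrix(0L, 0, 2),
                   cfg$n_diploid_initial, 0L,
                   as.matrix(sched[, c("n_gen", "n0", "n1")]),
                   sched$m, cfg$mu, cfg$rec, cfg$genome_elements,
                   TRUE)
  if (sample_both_demes) {
    pick <- c(sort(sample.int(final_n0, n_a)),
              final_n0 + sort(sample.int(final_n1, n_b)))
  } else {
    pick <- sort(sample.int(final_n0, cfg$sample_size))
  }
  hap_rows <- as.vector(rbind(2L * pick - 1L, 2L * pick))
  haps <- st$haps[hap_rows, , drop = FALSE]
  gt <- haps[seq(1, nrow(haps), 2), , drop = FALSE] +
    haps[seq(2, nrow(haps), 2), , drop = FALSE]
  gt <- t(gt)
  if (drop_monomorphic && ncol(gt) > 0) {
    ac <- rowSums(gt)
    seg <- ac > 0 & ac < 2 * cfg$sample_size
    gt <- gt[seg, , drop = FALSE]
    sites <- st$sites[seg, , drop = FALSE]
  } else sites <- st$sites
  chrom <- if (nrow(sites) > 0) paste0("elem", sites[, 1]) else character(0)
  genotype_matrix(chrom, sites[, 2],
                  rep("A", nrow(gt)), rep("T", nrow(gt)),
                  gt, sprintf("ind%02d", seq_len(cfg$sample_size)),
                  cohorts = if (sample_both_demes)
                    rep(c("deme0", "deme1"), c(n_a, n_b)) else NULL)
}

#' Pure-drift allele trajectories
#'
#' Low-level access to the simulator for drift experiments: starts a single
#' deme of \code{n_diploid} individuals with given derived-allele counts at
#' independent sites, runs \code{n_generations} of random mating without
#' pruning fixed or lost sites, and returns the final derived-allele counts.
#'
#' @param n_diploid diploid population size.
#' @param init_count integer vector of initial derived-allele counts (one
#'   site each), out of \code{2 * n_diploid} haplotypes.
#' @param n_generations generations to run.
#' @param mu,rec mutation and recombination rates (default 0: pure drift).
#' @param elem_length element length in bp.
#' @param seed RNG seed.
#' @return integer vector of final derived-allele counts.
#' @export
wf_drift <- function(n_diploid, init_count, n_generations,
                     mu = 0, rec = 0, elem_length = 1e6, seed = 1L) {
  n_hap <- 2L * n_diploid
  stopifnot(all(init_count >= 0), all(init_count <= n_hap))
  s <- length(init_count)
  set.seed(seed)
  haps <- matrix(0L, n_hap, s)
  for (k in seq_len(s))  # random carrier sets decorrelate linked sites
    if (init_count[k] > 0) haps[sample.int(n_hap, init_count[k]), k] <- 1L
  sites <- cbind(rep(1L, s), seq_len(s))
  set.seed(seed)
  st <- wf_run_cpp(haps, sites, n_diploid, 0L,
                   matrix(c(n_generations, n_diploid, 0L), 1, 3),
                   0, mu, rec, elem_length, FALSE)
  out <- integer(s)
  out[st$sites[, 2]] <- colSums(st$haps)
  out
}

#' Library of demographic scenarios
#'
#' Named scenario families expressed relative to an ancestral size
#' \code{n_anc} over a horizon of \code{horizon_generations} post-burn-in
#' generations (30 generations is about 800 years at 25.9 years per
#' generation): a constant-size control; a slow steady decline to
#' \code{decline_fraction} of the ancestral size (a minor gradual loss, as
#' opposed to a collapse); bottlenecks of 20/50/80% severity starting 5
#' generations (about 130 years) before sampling; an 80% bottleneck with
#' recovery; and an 80% bottleneck receiving migrants from an unaffected
#' sister deme.
#'
#' @param n_anc ancestral diploid size (defaults to the full-scale 50,000).
#' @param horizon_generations post-burn-in generations until sampling.
#' @param generation_time_years years per generation for reporting.
#' @param decline_fraction final size of the gradual-decline scenario as a
#'   fraction of \code{n_anc} (default 0.7).
#' @param migration_rate migration rate of the migration variant.
#' @return named list of \code{\link{demographic_scenario}} objects.
#' @export
scenario_library <- function(n_anc = 50000L, horizon_generations = 30L,
                             generation_time_years = 25.9,
                             decline_fraction = 0.7,
                             migration_rate = 0.1) {
  n_anc <- as.integer(n_anc)
  h <- as.integer(horizon_generations)
  stopifnot(n_anc >= 10, h >= 10)
  sz <- function(f) pmax(2L, as.integer(round(f * n_anc)))
  ds <- function(name, epochs, migration = 0)
    demographic_scenario(name, epochs, n_generations = h,
                         migration = migration,
                         generation_time_years = generation_time_years)
  decline_steps <- seq(0L, h - 5L, by = 5L)
  decline_sizes <- sz(seq(1, decline_fraction,
                          length.out = length(decline_steps)))
  list(
    constant = ds("constant",
                  data.frame(start_gen = 0L, deme0 = n_anc)),
    decline = ds("decline",
                 data.frame(start_gen = decline_steps,
                            deme0 = decline_sizes)),
    bottleneck_20 = ds("bottleneck_20",
                       data.frame(start_gen = c(0L, h - 5L),
                                  deme0 = c(n_anc, sz(0.8)))),
    bottleneck_50 = ds("bottleneck_50",
                       data.frame(start_gen = c(0L, h - 5L),
                                  deme0 = c(n_anc, sz(0.5)))),
    bottleneck_80 = ds("bottleneck_80",
                       data.frame(start_gen = c(0L, h - 5L),
                                  deme0 = c(n_anc, sz(0.2)))),
    bottleneck_80_recovery = ds("bottleneck_80_recovery",
                                data.frame(start_gen = c(0L, h - 6L, h - 3L),
                                           deme0 = c(n_anc, sz(0.2), n_anc))),
    bottleneck_80_migration = ds("bottleneck_80_migration",
                                 data.frame(start_gen = c(0L, h - 5L),
                                            deme0 = c(n_anc, sz(0.2)),
                                            deme1 = c(n_anc, n_anc)),
                                 migration = migration_rate)
  )
}

#' Replicate simulations and average the folded SFS
#'
#' Runs \code{\link{wf_simulate}} \code{n_replicates} times (replicate k
#' uses \code{seed + k - 1}), folds each sample's site frequency spectrum
#' and returns the mean spectrum. A replicate without segregating sites
#' contributes an all-zero spectrum.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param scenario a \code{\link{demographic_scenario}} or NULL.
#' @param n_replicates number of independent replicates.
#' @param seed base seed (defaults to \code{cfg$seed}).
#' @return a \code{\link{folded_sfs}} of mean per-bin counts, with the
#'   per-replicate spectra in attribute \code{"replicates"}.
#' @export
sample_fsfs <- function(cfg, scenario = NULL, n_replicates = 1L,
                        seed = cfg$seed) {
  stopifnot(n_replicates >= 1)
  n <- cfg$sample_size
  reps <- matrix(0, n_replicates, n)
  for (k in seq_len(n_replicates)) {
    cfg_k <- cfg
    cfg_k$seed <- as.integer(seed + k - 1L)
    gm <- wf_simulate(cfg_k, scenario)
    if (n_sites(gm) > 0) {
      sfs <- fsfs_from_genotypes(gm)
      reps[k, ] <- sfs$counts
    }
  }
  out <- folded_sfs(colMeans(reps), n_individuals = n)
  attr(out, "replicates") <- reps
  out
}
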