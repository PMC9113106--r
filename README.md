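# bottleneckR

Conservation-genomics toolkit for asking what a recent, short population
bottleneck — such as the collapse whaling inflicted on baleen whale
populations a century ago — did to a genome. Starting from diploid
genotype matrices (VCF), the package covers the full analysis chain:

- **Demography.** A forward-in-time diploid Wright–Fisher simulator
  (`wf_simulate`) with mutation, recombination, piecewise-constant deme
  sizes and two-deme migration; folded site-frequency spectra
  (`fsfs_from_genotypes`) and demographic scenario ranking by multinomial
  log-likelihood (`rank_scenarios`), with a library of bottleneck /
  decline / migration scenario families (`scenario_library`).
- **Diversity.** Genome-wide heterozygosity, nucleotide diversity π,
  Watterson's θ, Tajima's D, and the excess-homozygosity inbreeding
  coefficient F_H (`cohort_diversity` and friends).
- **Inbreeding from ROH.** Tiling-window detection of runs of
  homozygosity (`window_heterozygosity`, `detect_roh`; 10 kbp windows,
  0.2% heterozygosity ceiling, ≥10 windows by default) and length-binned
  F_ROH profiles with cohort ANOVA (`froh_profile`, `cohort_froh_table`).
- **Mutational load.** Codon-level SNV effect classification against a
  GFF3 + FASTA annotation — synonymous / missense / loss-of-function with
  splice, stop-gained and start-lost subtypes (`classify_effect`) — and
  per-individual load summaries split by zygosity (`load_summary`).
- **Structure.** Allele-sharing distances, classical PCoA and a
  label-permutation cohort-separation test (`pcoa_classic`,
  `pcoa_separation_test`); `run_pipeline` chains everything into a
  reproducible cohort report.
- **Filters.** The standard site/linkage/relatedness cleaning steps:
  indel/depth/missingness/het-excess/MAC filters (`apply_site_filters`),
  LD pruning (`ld_prune`), random thinning (`thin_sites`), and
  method-of-moments pi-hat relatedness with greedy removal
  (`estimate_pihat`, `remove_related`).
- **Synthetic truth.** Generators for implanted-ROH genomes, pedigrees
  with known kinship, and coding annotations with oracle-labelled
  variants (`make_roh_genome`, `make_pedigree_genotypes`,
  `make_cds_fixture`) used to validate every stage.

The scenario-comparison statistic is the log multinomial probability of
the observed folded spectrum under bin probabilities taken from a
candidate's simulated spectrum (Laplace-smoothed); diversity statistics
use the standard estimators (θ_W = S / (a₁L), unbiased π, Tajima's 1989
constants); F_ROH(c) is the fraction of the analyzed genome in ROH of
length ≥ c.

## Worked example: is there a bottleneck in this sample?

Simulate a 20-individual sample from a population that crashed by 80%
five generations (~130 years at 25.9 y/generation) before sampling, then
rank candidate demographies by the likelihood of its folded SFS:

```r
library(bottleneckR)

cfg <- sim_config(n_diploid_initial = 100, genome_elements = rep(1e4, 30),
                  mu = 5e-6, rec = 1e-6, burnin_generations = 1000,
                  sample_size = 20, seed = 7)
lib <- scenario_library(n_anc = 100)

obs_gm <- wf_simulate(cfg, lib$bottleneck_80)
obs <- fsfs_from_genotypes(obs_gm)
cand <- list(
  constant   = sample_fsfs(cfg, lib$constant,      10, seed = 100),
  decline    = sample_fsfs(cfg, lib$decline,       10, seed = 200),
  bottleneck = sample_fsfs(cfg, lib$bottleneck_80, 10, seed = 300))
rank_scenarios(obs, cand)
#>         name  loglik delta_loglik
#> 1 bottleneck -140.59        0.000
#> 2    decline -222.97      -82.376
#> 3   constant -279.91     -139.320
tajimas_d(obs_gm)
#> [1] 0.715
```

The bottleneck candidate wins by 82 log-likelihood units over the next
scenario: the observed spectrum's deficit of singletons and excess of
intermediate-frequency alleles (the same signal that makes Tajima's D
positive, here 0.72) matches the spectrum a recent crash produces. With
`seed = 7` these numbers reproduce exactly.

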