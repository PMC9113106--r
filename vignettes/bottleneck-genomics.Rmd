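---
title: "Assessing the genomic consequences of a recent bottleneck"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing the genomic consequences of a recent bottleneck}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bottleneckR)
```

## The problem

Industrial whaling reduced many baleen whale populations by an order of
magnitude within a few generations. Whether such a short, recent census
collapse leaves a detectable genomic footprint — and whether it has already
eroded diversity, raised inbreeding, or accumulated deleterious variation —
is a central question in conservation genomics. bottleneckR implements the
full analysis chain used to answer it from whole-genome diploid genotype
data: demographic inference by folded-site-frequency-spectrum (fSFS)
comparison against forward simulations, genome-wide diversity statistics,
runs of homozygosity (ROH) with length-binned inbreeding coefficients, and
codon-level mutational-load quantification. Because population-scale whale
data cannot ship with a package, every component is validated on synthetic
data whose ground truth is known by construction.

## The Wright–Fisher simulator

`wf_simulate()` is a forward-in-time diploid Wright–Fisher simulator:
discrete generations, random mating with selfing allowed, no selection.
Genomes are one or more genomic *elements* (independently assorting
chromosomes); within an element, meiosis places Poisson($rL$) crossovers
per gamete. Mutation is finite-sites: each gamete receives
Poisson($\mu L$) hits at uniform positions, and a hit on an
already-segregating position flips the allele, so back mutation is possible
(at the $\mu L$ values used here the difference from infinite-sites is
negligible). Demography is a piecewise-constant schedule of deme sizes; a
second deme can be founded from the focal deme and exchange migrants with
probability $m$ per parent draw. State is a dense 0/1 haplotype-by-site
matrix per element, with fixed and lost columns pruned every generation, so
memory tracks only segregating variation. All randomness flows through R's
RNG: a run is bit-reproducible from its seed, and replicate $k$ of any
experiment uses `seed + k - 1`.

The default `sim_config()` is the full-scale design: $N = 50{,}000$
diploids, three 10 Mbp elements, $\mu = 1.54\times10^{-9}$ and
$r = 10^{-8}$ per site per generation, a 100,000-generation burn-in, and a
generation time of 25.9 years for converting generations to calendar time.
That configuration is expressible but not meant to be run on a laptop; all
shipped experiments use scaled parameters that preserve the products
$N\mu$ and $Nr$ (e.g. $N = 500$ with $r = 10^{-6}$ keeps $Nr$ identical to
$N = 50{,}000$ with $r = 10^{-8}$). Calibration is checked against the
neutral coalescent: at equilibrium both Watterson's $\theta_W$ and $\pi$
estimate $4N\mu$, and Tajima's D is centred on zero. One point deserves
emphasis for anyone modifying the experiments: with little or no
recombination an entire element shares a single genealogy, so
per-replicate summary statistics (D especially) have enormous variance.
The calibration experiment therefore uses the scaled recombination rate,
and the model-recovery experiment uses many small independently assorting
elements (45 × 10 kb) rather than one long linked block.

## Demographic scenarios and fSFS ranking

`scenario_library()` parameterises the hypothesis families compared by the
demographic stage, expressed relative to an ancestral size over a 30
generation (~800 year) horizon: constant size; a *gradual decline*; sharp
bottlenecks of 20/50/80% severity starting 5 generations (~130 years)
before sampling; an 80% bottleneck with recovery; and an 80% bottleneck
receiving migrants ($m = 0.1$) from an unaffected sister deme. The decline
family declines to 70% of the ancestral size: it represents the
slow-steady-minor-decline hypothesis, deliberately distinct from a
collapse — a "gradual decline" all the way to 20% would simply be a slow
bottleneck and the fSFS cannot (and should not be expected to)
distinguish two parameterisations of the same event.

`fsfs_from_genotypes()` computes the folded SFS under a complete-case
rule: sites with any missing genotype are dropped. After the upstream ≤5%
missingness filter this discards little data; a hypergeometric projection
would be the natural extension if heavier missingness must be tolerated.
Scenario ranking uses the multinomial log-likelihood of the observed bin
counts under bin probabilities proportional to a candidate's simulated
counts plus a Laplace pseudocount of 1 (configurable). The pseudocount
keeps candidates with empty bins usable; the multinomial coefficient is
included so values are true log-probabilities; ties rank lexicographically.
Model recovery is quantified by `recovery_experiment()`: data simulated
under the 80% bottleneck is ranked against {constant, decline, bottleneck}
candidates, and the generating scenario should win in ≥90% of replicates
at desk scale. The same experiment verifies the migration effect: adding
migration from an unaffected deme to the true scenario's candidate lowers
that candidate's log-likelihood when the observed data had none, because
migration pulls the bottleneck deme's spectrum back toward the
constant-size spectrum.

## Diversity and inbreeding statistics

Per individual, `individual_heterozygosity()` is heterozygous calls over
non-missing genotyped sites — the input must include monomorphic sites so
the denominator is the callable genome. `nucleotide_diversity()` is the
unbiased per-site mean pairwise difference
$\sum_s 2\hat p_s(1-\hat p_s)\,\tfrac{2n_s}{2n_s-1} / L$; because the
callable length $L$ is a user-supplied denominator, the same function
yields the per-variant scale by passing the segregating-site count
instead, and `cohort_diversity()` reports both scales explicitly.
`watterson_theta()` and `tajimas_d()` use the standard constants; D uses
complete-case sites so all sites share one sample size. `f_h()` is the
excess-homozygosity inbreeding coefficient
$(O_{hom}-E_{hom})/(L-E_{hom})$ with $E_{hom}$ from full-sample allele
frequencies, clamped to $[-1,1]$; negative values flag heterozygote
excess.

Relatedness (`estimate_pihat()`) is the method-of-moments IBD estimator
from identity-by-state counts and sample allele frequencies —
$\hat\pi = P(\mathrm{IBD}{=}1)/2 + P(\mathrm{IBD}{=}2)$ — with each moment
clamped to $[0,1]$ before combination; no finite-sample allele-frequency
corrections are applied, which at the fixture scales biases pairs by well
under the 0.05 tolerance used in validation. `remove_related()` resolves
pairs above the cutoff (default 0.2) by dropping the higher-missingness
member, ties to the later sample, most related pair first — a
deterministic rule, since the choice is otherwise arbitrary.

## Runs of homozygosity

`window_heterozygosity()` tiles contigs with non-overlapping 10 kbp
windows (step = window size: the run-length × window-size bookkeeping of
the downstream length bins presumes tiling) and computes per-window
heterozygosity as heterozygous calls per *callable site*, not per bp.
This denominator matters: with a genome-wide background of ~0.07%
heterozygous sites per bp, a 0.2% per-bp ceiling would classify the whole
genome as ROH. Expressed per callable site at a realistic callable
density, background windows sit well above 0.2% and autozygous windows
well below it, which is the regime the window rule assumes. Contigs under
3 Mbp are excluded; windows with fewer callable sites than 10% of the
expected density are masked, and masked windows *break* runs (the
conservative choice — bridging across data gaps would inflate segment
lengths). `detect_roh()` emits maximal runs of ≥10 consecutive
below-threshold windows, snapped to window boundaries; `froh_profile()`
converts segments to $F_{ROH}$ — the fraction of the analyzed genome in
ROH at or above each length cutoff (100 kbp to 1 Mbp by default), monotone
nonincreasing by construction — and `cohort_froh_table()` adds the per-bin
one-way ANOVA across cohorts.

Validation uses `make_roh_genome()`: callable sites are a Poisson process
(0.2 per bp), heterozygous with probability 0.35% per callable site
outside implanted tracts and 10% of that inside them. The residual inside
rate deliberately emulates genotyping error; its side effect is that a
long tract occasionally contains a window above threshold, splitting the
called segment and truncating a short trailing fragment. For that reason
the recovery experiment scores the *mean* truth-boundary error (≤1 window
expected, observed ~0.2) alongside precision and recall (≥0.95), rather
than a worst-case bound that a single unlucky window would dominate.

## Mutational load

`classify_effect()` reclassifies SNVs the way a variant-effect annotator
would, restricted to single-nucleotide events: splice-site disruption
(first/last 2 bp of an intron), stop gained, and start lost are loss of
function; other amino-acid changes are missense; silent codon changes are
synonymous; everything else is noncoding. Stop-loss is counted as missense
by default (`stop_lost_is_lof` reclassifies it): it is the one high-impact
SNV class whose functional effect is routinely milder, and the default
keeps the LoF set conservative. One effect per variant with a most-severe
rule across transcripts; the standard genetic code is used. The
independent oracle in the fixture generator takes the *other* route —
rebuild the entire mutant CDS, translate both proteins, diff them — and
the two must agree exactly on 1,000 random variants spanning both strands.
`load_summary()` counts, per individual, carried variants (genotype 1 or
2) by category, splits LoF by zygosity, and defines load as LoF carried /
total carried, the proportion the study design uses; a cohort-wide
denominator is a one-line variant via `category_proportions()`.

## Structure and the report

`allele_sharing_distance()` ($\bar{|d_i - d_j|}/2$ over pairwise-complete
sites) feeds `pcoa_classic()`, classical metric scaling written from first
principles (double-centre $-D^2/2$, eigendecompose, scale by
$\sqrt\lambda$), with negative eigenvalues truncated and reported and a
deterministic sign convention; `ape::pcoa` is used in the test suite as
the independent reference. `pcoa_separation_test()` compares the observed
between-cohort centroid distance against label permutations — on a
panmictic simulation the p-value is null (the single-cluster case), on a
two-deme low-migration simulation it is significant (the positive
control). `run_pipeline()` chains filtering, diversity, F_H, ROH, load,
PCoA and the cross-statistic Pearson correlations into a `cohort_report`,
deterministic under its seed. No multiple-testing correction is applied
across the report's tests by default, matching common practice for such
descriptive cohort tables; `p_adjust = "BH"` enables Benjamini–Hochberg.

## What the synthetic data does and does not show

The generators reproduce the statistical structure the methods assume:
Wright–Fisher drift and mutation, Mendelian transmission in pedigrees,
Poisson-placed heterozygosity with implanted autozygous tracts, and CDS
models with known-effect variants. They do not model sequencing reads,
mapping artifacts, depth-dependent genotype error, allele-balance bias, or
reference bias — so passing tests demonstrate the correctness and power of
the estimators and callers under their model assumptions, not robustness
to upstream data-quality pathologies, which the site filters
(`apply_site_filters()`) only partially emulate via missingness and depth
fields.

## Problem sizes used by the shipped experiments

Calibration: 20 replicates at $N=500$, 100 kb, $\mu=10^{-6}$,
$r=10^{-6}$, burn-in $10N$, $n=20$ — both $\theta_W$ and $\pi$ within 15%
of $4N\mu = 0.002$ and mean D within ±0.3. Model recovery: $N=100$, 45
independent 10 kb elements, $\mu=5\times10^{-6}$, candidates averaged over
25 replicates, 50 observed replicates. ROH recovery: three 10 Mbp fixture
genomes with four tracts of 0.2–1.4 Mbp. Pedigrees: 40 founders, 10,000
sites, six parent-offspring and six selfed offspring. These sizes were
chosen as the smallest at which the expected effects dominate Monte-Carlo
noise by a comfortable margin.
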