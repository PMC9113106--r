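#' Site filter configuration
#'
#' Bundles the quality filters applied to a combined genotype data set before
#' population analyses: indel exclusion, divergent-coverage removal (>3x and
#' <0.3x of the expected mean coverage by default), per-site missingness,
#' biallelic restriction, heterozygote-excess removal (a paralog-collapse
#' heuristic) and a minor-allele-count floor (singletons dropped by default).
#'
#' @param max_missing_frac maximum fraction of missing calls per site.
#' @param depth_hi_ratio,depth_lo_ratio bounds on mean site depth as
#'   multiples of the expected mean coverage.
#' @param biallelic_only drop multiallelic records.
#' @param exclude_indels drop records whose REF or ALT allele is not a
#'   single base.
#' @param het_excess_max maximum observed heterozygote fraction per site.
#' @param min_minor_allele_count minimum minor allele count to keep a site;
#'   2 removes singletons, 0 disables the rule.
#' @return an object of class \code{site_filter_config}.
#' @export
site_filter_config <- function(max_missing_frac = 0.05,
                               depth_hi_ratio = 3,
                               depth_lo_ratio = 0.3,
                               biallelic_only = TRUE,
                               exclude_indels = TRUE,
                               het_excess_max = 0.6,
                               min_minor_allele_count = 2L) {
  stopifnot(max_missing_frac >= 0, max_missing_frac <= 1,
            het_excess_max >= 0, het_excess_max <= 1,
            min_minor_allele_count >= 0)
  if (depth_lo_ratio >= depth_hi_ratio)
    stop("depth_lo_ratio must be smaller than depth_hi_ratio")
  structure(list(max_missing_frac = max_missing_frac,
                 depth_hi_ratio = depth_hi_ratio,
                 depth_lo_ratio = depth_lo_ratio,
                 biallelic_only = biallelic_only,
                 exclude_indels = exclude_indels,
                 het_excess_max = het_excess_max,
                 min_minor_allele_count = as.integer(min_minor_allele_count)),
            class = "site_filter_config")
}

#' Apply site filters to a genotype matrix
#'
#' Rules are applied in a fixed order -- indels, depth, missingness,
#' biallelic, het-excess, minor allele count -- with each rule counted on
#' the survivors of the previous one, so the report's removals sum to the
#' difference in site numbers.
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param cfg a \code{\link{site_filter_config}}.
#' @param expected_mean_depth expected mean per-call coverage; the depth
#'   rule runs only when this is supplied and errors if the matrix carries
#'   no depths.
#' @return list with elements \code{genotypes} (filtered matrix) and
#'   \code{report} (data.frame of rule, sites_removed).
#' @export
apply_site_filters <- function(gm, cfg, expected_mean_depth = NULL) {
  stopifnot(inherits(cfg, "site_filter_config"))
  keep <- rep(TRUE, n_sites(gm))
  report <- data.frame(rule = character(0), sites_removed = integer(0))
  note <- function(rule, removed) {
    report <<- rbind(report,
                     data.frame(rule = rule, sites_removed = removed))
  }

  if (cfg$exclude_indels) {
    alt1 <- strsplit(gm$alt, ",", fixed = TRUE)
    is_indel <- nchar(gm$ref) != 1L |
      vapply(alt1, function(a) any(a != "." & nchar(a) != 1L), logical(1))
    note("indel", sum(keep & is_indel))
    keep <- keep & !is_indel
  } else note("indel", 0L)

  if (!is.null(expected_mean_depth)) {
    if (is.null(gm$dp))
      stop("depth filter requested but the matrix carries no depths")
    mean_dp <- rowMeans(gm$dp, na.rm = TRUE)
    bad_dp <- !is.na(mean_dp) &
      (mean_dp > cfg$depth_hi_ratio * expected_mean_depth |
         mean_dp < cfg$depth_lo_ratio * expected_mean_depth)
    note("depth", sum(keep & bad_dp))
    keep <- keep & !bad_dp
  } else note("depth", 0L)

  miss_frac <- rowMeans(is.na(gm$gt))
  bad_miss <- miss_frac > cfg$max_missing_frac
  note("missingness", sum(keep & bad_miss))
  keep <- keep & !bad_miss

  if (cfg$biallelic_only) {
    multi <- grepl(",", gm$alt, fixed = TRUE)
    note("biallelic", sum(keep & multi))
    keep <- keep & !multi
  } else note("biallelic", 0L)

  n_called <- site_n_called(gm)
  het_frac <- ifelse(n_called > 0,
                     rowSums(gm$gt == 1L, na.rm = TRUE) / n_called, 0)
  bad_het <- het_frac > cfg$het_excess_max
  note("het_excess", sum(keep & bad_het))
  keep <- keep & !bad_het

  if (cfg$min_minor_allele_count > 0) {
    ac <- site_alt_count(gm)
    an <- 2L * n_called
    mac <- pmin(ac, an - ac)
    bad_mac <- mac < cfg$min_minor_allele_count
    note("mac", sum(keep & bad_mac))
    keep <- keep & !bad_mac
  } else note("mac", 0L)

  list(genotypes = gm_subset(gm, sites = keep), report = report)
}

#' Prune sites in linkage disequilibrium
#'
#' Greedy LD pruning on genotype dosages: sites are visited left to right
#' within each contig and a site is dropped when its squared Pearson
#' correlation (pairwise-complete calls) with any retained site within the
#' window exceeds \code{r2_max}; the earlier site wins. Defaults mirror a
#' 1,000 kb / step 1 / r2 0.9 pruning pass.
#'
#' @param gm SNP-only \code{\link{genotype_matrix}}.
#' @param window_kb window size in kilobases.
#' @param step_sites window step in sites; only the exhaustive step of 1 is
#'   supported.
#' @param r2_max maximum allowed squared dosage correlation, in (0, 1].
#' @return pruned \code{genotype_matrix}.
#' @export
ld_prune <- function(gm, window_kb = 1000, step_sites = 1L, r2_max = 0.9) {
  if (r2_max <= 0 || r2_max > 1) stop("r2_max must be in (0, 1]")
  if (step_sites != 1L) stop("only a window step of 1 site is supported")
  win <- window_kb * 1000
  keep <- logical(n_sites(gm))
  for (ctg in unique(gm$chrom)) {
    idx <- which(gm$chrom == ctg)
    kept <- integer(0)
    for (i in idx) {
      near <- kept[gm$pos[i] - gm$pos[kept] <= win]
      drop <- FALSE
      for (j in rev(near)) {
        r <- suppressWarnings(
          stats::cor(gm$gt[i, ], gm$gt[j, ],
                     use = "pairwise.complete.obs"))
        if (!is.na(r) && r * r > r2_max) { drop <- TRUE; break }
      }
      if (!drop) kept <- c(kept, i)
    }
    keep[kept] <- TRUE
  }
  gm_subset(gm, sites = keep)
}

#' Pairwise relatedness (pi-hat) by method of moments
#'
#' Estimates the proportion of the genome shared identical by descent for
#' every pair of individuals from identity-by-state counts and sample allele
#' frequencies: P(IBD = 0, 1, 2) are solved by moments from the observed
#' IBS-class counts and pi-hat = P(IBD=1)/2 + P(IBD=2). Moment estimates are
#' clamped to [0, 1]. Only polymorphic sites inform the estimate.
#'
#' @param gm \code{\link{genotype_matrix}} with at least two individuals.
#' @return symmetric numeric matrix of pi-hat values with unit diagonal.
#' @export
estimate_pihat <- function(gm) {
  if (n_ind(gm) < 2) stop("pi-hat needs at least two individuals")
  poly <- site_is_polymorphic(gm)
  if (!any(poly)) stop("no polymorphic sites: allele frequencies undefined")
  g <- gm$gt[poly, , drop = FALSE]
  p <- site_alt_freq(gm)[poly]
  q <- 1 - p
  # Per-site IBS-class probabilities conditional on the IBD state.
  e_ibs0_z0 <- 2 * p^2 * q^2
  e_ibs1_z0 <- 4 * p^3 * q + 4 * p * q^3
  e_ibs2_z0 <- p^4 + q^4 + 4 * p^2 * q^2
  e_ibs1_z1 <- 2 * p * q
  e_ibs2_z1 <- p^2 + q^2
  n <- ncol(g)
  ph <- matrix(0, n, n, dimnames = list(gm$samples, gm$samples))
  diag(ph) <- 1
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(g[, i]) & !is.na(g[, j])
      if (!any(ok)) stop("individuals ", gm$samples[i], " and ",
                         gm$samples[j], " share no called sites")
      d <- abs(g[ok, i] - g[ok, j])
      ibs0 <- sum(d == 2)
      ibs1 <- sum(d == 1)
      ibs2 <- sum(d == 0)
      z0 <- ibs0 / sum(e_ibs0_z0[ok])
      z0 <- min(max(z0, 0), 1)
      z1 <- (ibs1 - z0 * sum(e_ibs1_z0[ok])) / sum(e_ibs1_z1[ok])
      z1 <- min(max(z1, 0), 1)
      z2 <- (ibs2 - z0 * sum(e_ibs2_z0[ok]) - z1 * sum(e_ibs2_z1[ok])) /
        sum(ok)
      z2 <- min(max(z2, 0), 1)
      pihat <- min(max(z1 / 2 + z2, 0), 1)
      ph[i, j] <- ph[j, i] <- pihat
    }
  }
  ph
}

#' Remove related individuals
#'
#' Greedily resolves every pair whose pi-hat exceeds the cutoff by dropping
#' the member with the higher missingness (ties: the later sample), starting
#' from the most related pair, until no pair exceeds the cutoff.
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param pihat_cutoff relatedness cutoff in (0, 1); 0.2 by default.
#' @return \code{genotype_matrix} restricted to the retained individuals.
#' @export
remove_related <- function(gm, pihat_cutoff = 0.2) {
  if (pihat_cutoff <= 0 || pihat_cutoff >= 1)
    stop("pihat_cutoff must be in (0, 1)")
  ph <- estimate_pihat(gm)
  diag(ph) <- 0
  miss <- colMeans(is.na(gm$gt))
  alive <- rep(TRUE, n_ind(gm))
  repeat {
    sub <- ph
    sub[!alive, ] <- 0
    sub[, !alive] <- 0
    if (max(sub) <= pihat_cutoff) break
    hit <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    drop <- if (miss[hit[1]] > miss[hit[2]]) hit[1]
            else if (miss[hit[2]] > miss[hit[1]]) hit[2]
            else max(hit)
    alive[drop] <- FALSE
  }
  gm_subset(gm, individuals = alive)
}

#' Randomly thin sites to a minimum spacing
#'
#' Keeps a random subset of sites such that no two retained sites on the
#' same contig lie within \code{min_spacing_bp} of each other: sites are
#' visited in a seeded random order and accepted when no previously accepted
#' site is closer than the spacing.
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param min_spacing_bp minimum distance between retained sites (1000 for
#'   one-SNP-per-kb thinning).
#' @param seed integer seed; identical seeds give identical output.
#' @return thinned \code{genotype_matrix}.
#' @export
thin_sites <- function(gm, min_spacing_bp = 1000L, seed = 1L) {
  set.seed(seed)
  keep <- logical(n_sites(gm))
  for (ctg in unique(gm$chrom)) {
    idx <- which(gm$chrom == ctg)
    ord <- idx[sample.int(length(idx))]
    acc <- numeric(0)
    for (i in ord) {
      if (!length(acc) || min(abs(acc - gm$pos[i])) >= min_spacing_bp) {
        acc <- c(acc, gm$pos[i])
        keep[i] <- TRUE
      }
    }
  }
  gm_subset(gm, sites = keep)
}
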