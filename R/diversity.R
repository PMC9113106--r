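#' Per-individual genome-wide heterozygosity
#'
#' Fraction of heterozygous calls among an individual's non-missing
#' genotyped sites. The matrix should include monomorphic sites so that the
#' denominator is the callable genome, making values comparable across
#' individuals (typically reported in percent).
#'
#' @param gm a \code{\link{genotype_matrix}} including monomorphic sites.
#' @return named numeric vector, one value per individual.
#' @export
individual_heterozygosity <- function(gm) {
  called <- colSums(!is.na(gm$gt))
  if (any(called == 0))
    stop("individual(s) without callable sites: ",
         paste(gm$samples[called == 0], collapse = ", "))
  stats::setNames(colSums(gm$gt == 1L, na.rm = TRUE) / called, gm$samples)
}

#' Nucleotide diversity per site
#'
#' Unbiased mean pairwise difference per callable site:
#' pi = sum over sites of 2*p*(1-p) * 2n/(2n-1), divided by the callable
#' length, with p the sample alternate-allele frequency and 2n the number
#' of called haplotypes at the site. To express diversity per variant
#' instead of per callable site, pass the number of segregating sites as
#' \code{l_callable}.
#'
#' @param gm a biallelic SNP \code{\link{genotype_matrix}}.
#' @param l_callable callable sequence length (including monomorphic
#'   sites) used as the denominator.
#' @return per-site nucleotide diversity.
#' @export
nucleotide_diversity <- function(gm, l_callable) {
  if (l_callable <= 0) stop("callable length must be positive")
  p <- site_alt_freq(gm)
  n2 <- 2 * site_n_called(gm)
  ok <- !is.na(p) & n2 >= 2
  terms <- 2 * p[ok] * (1 - p[ok]) * n2[ok] / (n2[ok] - 1)
  sum(terms) / l_callable
}

#' Watterson's theta per site
#'
#' theta_W = S / (a1 * L) with S the number of segregating sites, a1 the
#' harmonic number sum(1/i) for i = 1..n_hap-1, and L the callable length.
#'
#' @param s_segregating number of segregating sites.
#' @param n_hap number of sampled haplotypes (2 x diploids), at least 2.
#' @param l_callable callable sequence length.
#' @return per-site Watterson estimator.
#' @export
watterson_theta <- function(s_segregating, n_hap, l_callable) {
  stopifnot(n_hap >= 2, l_callable > 0)
  a1 <- sum(1 / seq_len(n_hap - 1))
  s_segregating / (a1 * l_callable)
}

#' Tajima's D
#'
#' Standardized difference between the pairwise-difference and
#' segregating-sites diversity estimators, using the standard constants
#' (a1, a2, b1, b2, c1, c2, e1, e2) for the haplotype sample size. Sites
#' with missing calls are excluded (complete-case), so all sites share the
#' same n. Positive values indicate an excess of intermediate-frequency
#' variants, as left by a recent contraction; negative values follow
#' expansions.
#'
#' @param gm a biallelic SNP \code{\link{genotype_matrix}}.
#' @return Tajima's D.
#' @export
tajimas_d <- function(gm) {
  n <- n_ind(gm)
  complete <- rowSums(is.na(gm$gt)) == 0
  ac <- rowSums(gm$gt[complete, , drop = FALSE])
  ac <- ac[ac > 0 & ac < 2 * n]
  s <- length(ac)
  if (s < 3) stop("Tajima's D undefined with fewer than 3 segregating sites")
  nh <- 2 * n
  p <- ac / nh
  pi_total <- sum(2 * p * (1 - p) * nh / (nh - 1))
  a1 <- sum(1 / seq_len(nh - 1))
  a2 <- sum(1 / seq_len(nh - 1)^2)
  b1 <- (nh + 1) / (3 * (nh - 1))
  b2 <- 2 * (nh^2 + nh + 3) / (9 * nh * (nh - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (nh + 2) / (a1 * nh) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_total - s / a1) / sqrt(e1 * s + e2 * s * (s - 1))
}

#' Excess-homozygosity inbreeding coefficient F_H
#'
#' Per individual, compares the observed number of homozygous genotypes at
#' its non-missing sites with the Hardy-Weinberg expectation from sample
#' allele frequencies: F_H = (O_hom - E_hom) / (L - E_hom). Negative values
#' indicate heterozygote excess. Values are clamped to [-1, 1].
#'
#' @param gm a \code{\link{genotype_matrix}}; allele frequencies are taken
#'   from the full sample.
#' @return named numeric vector of F_H values per individual.
#' @export
f_h <- function(gm) {
  p <- site_alt_freq(gm)
  exp_hom_site <- 1 - 2 * p * (1 - p)
  out <- numeric(n_ind(gm))
  for (i in seq_len(n_ind(gm))) {
    ok <- !is.na(gm$gt[, i]) & !is.na(p)
    l <- sum(ok)
    if (l == 0) stop("individual ", gm$samples[i], " has no callable sites")
    o_hom <- sum(gm$gt[ok, i] != 1L)
    e_hom <- sum(exp_hom_site[ok])
    if (e_hom >= l)
      stop("all sites monomorphic for individual ", gm$samples[i],
           ": F_H undefined")
    out[i] <- min(max((o_hom - e_hom) / (l - e_hom), -1), 1)
  }
  stats::setNames(out, gm$samples)
}

#' Per-cohort diversity summary
#'
#' Convenience wrapper computing, per cohort, mean heterozygosity, per-site
#' and per-variant nucleotide diversity, Watterson's theta and Tajima's D
#' from the cohort's columns of a genotype matrix.
#'
#' @param gm a \code{\link{genotype_matrix}} whose \code{cohorts} field is
#'   set (monomorphic sites included for the heterozygosity denominator).
#' @param l_callable callable genome length for the per-site scales.
#' @return data.frame with one row per cohort.
#' @export
cohort_diversity <- function(gm, l_callable) {
  if (is.null(gm$cohorts)) stop("genotype matrix has no cohort labels")
  het <- individual_heterozygosity(gm)
  fh <- f_h(gm)
  do.call(rbind, lapply(unique(gm$cohorts), function(ch) {
    sub <- gm_subset(gm, individuals = gm$cohorts == ch)
    seg <- site_is_polymorphic(sub) & rowSums(is.na(sub$gt)) == 0
    s <- sum(seg)
    data.frame(cohort = ch,
               n = n_ind(sub),
               mean_het = mean(het[gm$cohorts == ch]),
               pi_per_site = nucleotide_diversity(sub, l_callable),
               pi_per_variant = if (s > 0)
                 nucleotide_diversity(sub, s) else 0,
               theta_w_per_site = watterson_theta(s, 2 * n_ind(sub),
                                                  l_callable),
               tajimas_d = if (s >= 3) tajimas_d(sub) else NA_real_,
               mean_f_h = mean(fh[gm$cohorts == ch]))
  }))
}
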