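#' Folded site frequency spectrum
#'
#' Histogram of minor-allele counts over segregating sites for a sample of
#' \code{n_individuals} diploids. Bin i (i = 1..n) holds sites whose minor
#' allele appears i times among the 2n haplotypes; bin n holds
#' frequency-one-half alleles. Counts are integers for observed spectra and
#' may be fractional for replicate-averaged simulated spectra.
#'
#' @param counts nonnegative numeric vector of length \code{n_individuals}.
#' @param n_individuals diploid sample size.
#' @param n_sites_used number of segregating sites contributing (defaults
#'   to \code{sum(counts)}).
#' @return an object of class \code{folded_sfs}.
#' @export
folded_sfs <- function(counts, n_individuals,
                       n_sites_used = sum(counts)) {
  counts <- as.numeric(counts)
  if (length(counts) != n_individuals)
    stop("counts must have one bin per diploid individual")
  if (any(counts < 0)) stop("spectrum counts must be nonnegative")
  structure(list(counts = counts,
                 n_individuals = as.integer(n_individuals),
                 n_sites_used = n_sites_used),
            class = "folded_sfs")
}

#' @export
print.folded_sfs <- function(x, ...) {
  cat("folded_sfs: n =", x$n_individuals, "diploids,",
      format(x$n_sites_used), "segregating sites\n")
  print(stats::setNames(x$counts, seq_along(x$counts)))
  invisible(x)
}

#' Folded SFS from a genotype matrix
#'
#' Complete-case rule: sites with any missing genotype are excluded, as are
#' monomorphic sites. The minor-allele count of a site is
#' \code{min(c, 2n - c)} with c the alternate-allele count.
#'
#' @param gm a biallelic SNP \code{\link{genotype_matrix}}.
#' @return a \code{\link{folded_sfs}}.
#' @export
fsfs_from_genotypes <- function(gm) {
  n <- n_ind(gm)
  complete <- rowSums(is.na(gm$gt)) == 0
  ac <- rowSums(gm$gt[complete, , drop = FALSE])
  ac <- ac[ac > 0 & ac < 2 * n]
  if (!length(ac)) stop("no usable (complete, segregating) sites")
  minor <- pmin(ac, 2L * n - ac)
  folded_sfs(tabulate(minor, nbins = n), n_individuals = n)
}

#' Fold an unfolded site frequency spectrum
#'
#' @param unfolded_counts vector of length \code{n_haplotypes - 1}; element
#'   i is the number of sites with derived-allele count i.
#' @param n_haplotypes even haplotype sample size (2 x diploids).
#' @return a \code{\link{folded_sfs}} with bins
#'   \code{folded[i] = u[i] + u[2n - i]} for i < n and
#'   \code{folded[n] = u[n]}.
#' @export
fold_sfs <- function(unfolded_counts, n_haplotypes) {
  if (n_haplotypes %% 2 != 0)
    stop("n_haplotypes must be even (diploid samples)")
  if (length(unfolded_counts) != n_haplotypes - 1)
    stop("unfolded spectrum must have n_haplotypes - 1 bins")
  n <- n_haplotypes %/% 2
  f <- numeric(n)
  for (i in seq_len(n - 1))
    f[i] <- unfolded_counts[i] + unfolded_counts[n_haplotypes - i]
  f[n] <- unfolded_counts[n]
  folded_sfs(f, n_individuals = n)
}

#' Multinomial log-likelihood of an observed folded SFS
#'
#' Log probability of the observed bin counts under bin probabilities
#' proportional to the simulated counts plus a Laplace pseudocount
#' (multinomial coefficient included, so the value is an actual
#' log-probability). The pseudocount keeps simulated spectra with empty
#' bins usable.
#'
#' @param observed,simulated \code{\link{folded_sfs}} objects for the same
#'   diploid sample size; observed counts must be integers.
#' @param pseudocount added to every simulated bin (default 1).
#' @return the log-likelihood (finite scalar).
#' @export
multinomial_loglik <- function(observed, simulated, pseudocount = 1) {
  if (observed$n_individuals != simulated$n_individuals)
    stop("spectra have different sample sizes")
  if (length(observed$counts) != length(simulated$counts))
    stop("spectra have different numbers of bins")
  w <- simulated$counts + pseudocount
  if (any(w <= 0))
    stop("simulated counts plus pseudocount must be positive in every bin")
  stats::dmultinom(round(observed$counts), prob = w / sum(w), log = TRUE)
}

#' Rank demographic scenarios against an observed folded SFS
#'
#' Computes the multinomial log-likelihood of the observed spectrum under
#' each candidate's simulated spectrum and returns candidates sorted by
#' decreasing likelihood (ties broken by name) with the drop relative to
#' the best candidate.
#'
#' @param observed a \code{\link{folded_sfs}}.
#' @param candidates named list of \code{\link{folded_sfs}} objects (at
#'   least two).
#' @param pseudocount passed to \code{\link{multinomial_loglik}}.
#' @return data.frame with columns name, loglik, delta_loglik.
#' @export
rank_scenarios <- function(observed, candidates, pseudocount = 1) {
  if (length(candidates) < 2) stop("need at least two candidate scenarios")
  if (is.null(names(candidates)) || any(names(candidates) == ""))
    stop("candidates must be named")
  ll <- vapply(candidates, function(s)
    multinomial_loglik(observed, s, pseudocount), numeric(1))
  ord <- order(-ll, names(candidates))
  data.frame(name = names(candidates)[ord],
             loglik = ll[ord],
             delta_loglik = ll[ord] - max(ll),
             row.names = NULL)
}

#' Convert generations to years
#'
#' @param g number of generations (nonnegative).
#' @param generation_time_years years per generation; the default 25.9 is
#'   the fin whale generation time used throughout the package.
#' @return years.
#' @export
generations_to_years <- function(g, generation_time_years = 25.9) {
  stopifnot(all(g >= 0))
  g * generation_time_years
}
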