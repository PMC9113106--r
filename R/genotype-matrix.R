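#' Diploid genotype matrix
#'
#' The central data container: per-site, per-individual diploid genotype
#' codes together with site coordinates and alleles. Codes are
#' \code{0} (homozygous reference), \code{1} (heterozygous), \code{2}
#' (homozygous alternate) and \code{NA} (missing call). All population
#' statistics in the package consume this object.
#'
#' @param chrom character vector of contig names, one per site.
#' @param pos integer vector of 1-based site positions, strictly increasing
#'   within each contig.
#' @param ref,alt character vectors of reference and alternate alleles per
#'   site. Monomorphic sites carry \code{alt = "."}. Multiallelic sites join
#'   alternate alleles with commas.
#' @param gt integer matrix, sites x individuals, holding the genotype codes.
#' @param samples character vector of individual names (matrix columns).
#' @param dp optional numeric matrix of per-call read depths, same shape as
#'   \code{gt}.
#' @param cohorts optional character/factor grouping label per individual.
#'
#' @return An object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(chrom, pos, ref, alt, gt, samples,
                            dp = NULL, cohorts = NULL) {
  gt <- as.matrix(gt)
  storage.mode(gt) <- "integer"
  n_sites <- nrow(gt)
  stopifnot(length(chrom) == n_sites, length(pos) == n_sites,
            length(ref) == n_sites, length(alt) == n_sites)
  if (length(samples) != ncol(gt))
    stop("number of sample ids must equal the genotype matrix width")
  bad <- !(gt %in% c(0L, 1L, 2L) | is.na(gt))
  if (any(bad))
    stop("genotype codes must be 0, 1, 2 or NA")
  pos <- as.integer(pos)
  for (ctg in unique(chrom)) {
    p <- pos[chrom == ctg]
    if (length(p) > 1 && any(diff(p) <= 0))
      stop("positions must be strictly increasing within contig '", ctg, "'")
  }
  if (!is.null(dp)) {
    dp <- as.matrix(dp)
    stopifnot(all(dim(dp) == dim(gt)))
  }
  if (!is.null(cohorts)) {
    cohorts <- as.character(cohorts)
    stopifnot(length(cohorts) == length(samples))
  }
  structure(list(chrom = as.character(chrom), pos = pos,
                 ref = as.character(ref), alt = as.character(alt),
                 gt = gt, samples = as.character(samples),
                 dp = dp, cohorts = cohorts),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  n_poly <- sum(site_is_polymorphic(x))
  cat("genotype_matrix:", n_sites(x), "sites x", n_ind(x), "individuals\n")
  cat("  contigs:", length(unique(x$chrom)),
      " polymorphic sites:", n_poly, "\n")
  cat("  missing calls: ", sum(is.na(x$gt)),
      if (!is.null(x$dp)) " (depths present)" else "", "\n", sep = "")
  if (!is.null(x$cohorts))
    cat("  cohorts:", paste(names(table(x$cohorts)), table(x$cohorts),
                            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of sites / individuals in a genotype matrix
#' @param gm a \code{genotype_matrix}.
#' @return integer count.
#' @export
n_sites <- function(gm) nrow(gm$gt)

#' @rdname n_sites
#' @export
n_ind <- function(gm) ncol(gm$gt)

# Alternate-allele count and non-missing diploid count per site.
site_alt_count <- function(gm) rowSums(gm$gt, na.rm = TRUE)

site_n_called <- function(gm) rowSums(!is.na(gm$gt))

site_is_polymorphic <- function(gm) {
  ac <- site_alt_count(gm)
  an <- 2L * site_n_called(gm)
  ac > 0L & ac < an
}

# Sample alternate-allele frequency per site (non-missing calls only).
site_alt_freq <- function(gm) {
  an <- 2L * site_n_called(gm)
  ifelse(an > 0, site_alt_count(gm) / an, NA_real_)
}

#' Subset a genotype matrix
#'
#' @param gm a \code{genotype_matrix}.
#' @param sites logical or integer index of sites to keep.
#' @param individuals logical or integer index (or sample names) to keep.
#' @return a \code{genotype_matrix}.
#' @export
gm_subset <- function(gm, sites = NULL, individuals = NULL) {
  if (is.null(sites)) sites <- seq_len(n_sites(gm))
  if (is.null(individuals)) individuals <- seq_len(n_ind(gm))
  if (is.character(individuals)) individuals <- match(individuals, gm$samples)
  genotype_matrix(gm$chrom[sites], gm$pos[sites], gm$ref[sites],
                  gm$alt[sites],
                  gm$gt[sites, individuals, drop = FALSE],
                  gm$samples[individuals],
                  dp = if (is.null(gm$dp)) NULL else
                    gm$dp[sites, individuals, drop = FALSE],
                  cohorts = if (is.null(gm$cohorts)) NULL else
                    gm$cohorts[individuals])
}
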