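#' Allele-sharing distance matrix
#'
#' Pairwise genetic distance between individuals: the mean over
#' pairwise-complete sites of |dosage_i - dosage_j| / 2, so identical
#' genotypes give 0 and opposite homozygotes at every site give 1.
#'
#' @param gm a SNP \code{\link{genotype_matrix}}.
#' @return symmetric numeric matrix with zero diagonal and sample names as
#'   dimnames.
#' @export
allele_sharing_distance <- function(gm) {
  n <- n_ind(gm)
  d <- matrix(0, n, n, dimnames = list(gm$samples, gm$samples))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(gm$gt[, i]) & !is.na(gm$gt[, j])
      if (!any(ok))
        stop("individuals ", gm$samples[i], " and ", gm$samples[j],
             " share no called sites")
      d[i, j] <- d[j, i] <- mean(abs(gm$gt[ok, i] - gm$gt[ok, j])) / 2
    }
  }
  d
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centers -D^2/2, eigendecomposes, and scales eigenvectors by the
#' square roots of their (positive) eigenvalues. Axes are ordered by
#' decreasing eigenvalue; negative eigenvalues (non-Euclidean distances)
#' are truncated to zero for the variance decomposition and reported. Axis
#' signs follow the convention that the first nonzero loading of each axis
#' is positive.
#'
#' @param d symmetric distance matrix (e.g. from
#'   \code{\link{allele_sharing_distance}}).
#' @param n_axes number of axes to return (less than the number of
#'   samples).
#' @return list of class \code{pcoa_result} with \code{coordinates}
#'   (samples x axes), \code{eigenvalues}, \code{percent_variance} and
#'   \code{negative_eigenvalues}.
#' @export
pcoa_classic <- function(d, n_axes = 2L) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n_axes >= n) stop("n_axes must be smaller than the number of samples")
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% (d * d) %*% j
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  vals <- e$values
  pos <- pmax(vals, 0)
  coords <- matrix(0, n, n_axes,
                   dimnames = list(rownames(d),
                                   paste0("Axis", seq_len(n_axes))))
  for (k in seq_len(n_axes)) {
    if (pos[k] > 0) {
      v <- e$vectors[, k]
      nz <- which(abs(v) > 1e-12)
      if (length(nz) && v[nz[1]] < 0) v <- -v
      coords[, k] <- v * sqrt(pos[k])
    }
  }
  structure(list(coordinates = coords,
                 eigenvalues = vals[seq_len(n_axes)],
                 percent_variance = if (sum(pos) > 0)
                   100 * pos[seq_len(n_axes)] / sum(pos)
                 else rep(0, n_axes),
                 negative_eigenvalues = vals[vals < 0]),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("pcoa_result:", nrow(x$coordinates), "samples,",
      ncol(x$coordinates), "axes\n")
  cat("  percent variance:",
      paste(sprintf("%.1f%%", x$percent_variance), collapse = ", "), "\n")
  if (length(x$negative_eigenvalues))
    cat("  ", length(x$negative_eigenvalues),
        "negative eigenvalues truncated\n")
  invisible(x)
}

#' Permutation test for cohort separation in PCoA space
#'
#' Compares the observed between-cohort mean coordinate distance with its
#' distribution under random relabeling; a large p-value indicates no
#' detectable cohort structure (a single cluster).
#'
#' @param pcoa a \code{\link{pcoa_classic}} result.
#' @param cohorts cohort label per sample.
#' @param n_perm number of label permutations.
#' @param seed RNG seed.
#' @return list with \code{statistic} (observed mean between-cohort
#'   centroid distance) and \code{p_value}.
#' @export
pcoa_separation_test <- function(pcoa, cohorts, n_perm = 999L, seed = 1L) {
  co <- as.character(cohorts)
  xy <- pcoa$coordinates
  stat <- function(labels) {
    cent <- apply(xy, 2, function(col) tapply(col, labels, mean))
    mean(stats::dist(cent))
  }
  obs <- stat(co)
  set.seed(seed)
  perm <- replicate(n_perm, stat(sample(co)))
  list(statistic = obs,
       p_value = (1 + sum(perm >= obs)) / (n_perm + 1))
}
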