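#' Pearson correlation test
#'
#' Sample Pearson correlation with a two-sided p-value from the t
#' transform (delegated to \code{stats::cor.test}).
#'
#' @param x,y numeric vectors of equal length (at least 3), finite, with
#'   nonzero variance.
#' @return list with \code{r} and \code{p}.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("inputs must be finite")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' One-way fixed-effects ANOVA
#'
#' Classic one-way F test across groups (delegated to \code{stats::aov}).
#'
#' @param values numeric response.
#' @param groups group label per value; at least two groups with at least
#'   two members each.
#' @return list with \code{f}, \code{p}, \code{df_between},
#'   \code{df_within}.
#' @export
anova_oneway <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least two groups")
  if (any(tab < 2)) stop("every group needs at least two members")
  if (stats::var(values) == 0)
    stop("zero overall variance: ANOVA degenerate")
  s <- summary(stats::aov(values ~ groups))[[1]]
  list(f = s[["F value"]][1], p = s[["Pr(>F)"]][1],
       df_between = s[["Df"]][1], df_within = s[["Df"]][2])
}

#' Run the full cohort analysis pipeline
#'
#' Orchestrates the stages in a fixed order on a genotype matrix with
#' cohort labels: site filtering (optional), per-individual
#' heterozygosity and F_H, per-cohort diversity (pi, Watterson's theta,
#' Tajima's D), per-individual ROH calling and F_ROH profiles with a
#' per-bin cohort ANOVA, mutational-load summaries when a coding
#' annotation is supplied, PCoA on allele-sharing distances, and the
#' cross-statistic Pearson correlations (heterozygosity against total
#' F_ROH and F_H; load against heterozygosity and F_ROH). Deterministic
#' for a given seed. No multiple-testing correction is applied to the
#' report's tests by default; pass \code{p_adjust = "BH"} for
#' Benjamini-Hochberg adjusted ANOVA p-values.
#'
#' @param gm a \code{\link{genotype_matrix}} including monomorphic sites,
#'   with \code{cohorts} set.
#' @param contig_lengths named vector of contig lengths (for ROH and the
#'   callable length).
#' @param annotation optional \code{\link{coding_annotation}} enabling the
#'   load stage.
#' @param filter_cfg optional \code{\link{site_filter_config}} applied to
#'   the SNP subset before population analyses.
#' @param expected_mean_depth forwarded to
#'   \code{\link{apply_site_filters}}.
#' @param window_size,het_threshold,min_windows,min_contig_bp ROH stage
#'   parameters (defaults: 10 kbp windows, 0.2% heterozygosity, 10
#'   windows, 3 Mbp contig floor).
#' @param froh_cutoffs F_ROH length cutoffs in bp.
#' @param p_adjust "none" (default) or "BH".
#' @param seed integer seed controlling every stochastic step.
#' @return a \code{cohort_report}: list with \code{individual_table},
#'   \code{cohort_table}, \code{froh}, \code{load}, \code{pcoa},
#'   \code{correlations}, \code{anova}, and the logged \code{parameters}.
#' @export
run_pipeline <- function(gm, contig_lengths, annotation = NULL,
                         filter_cfg = NULL, expected_mean_depth = NULL,
                         window_size = 10000L, het_threshold = 0.002,
                         min_windows = 10L, min_contig_bp = 3e6,
                         froh_cutoffs = seq(1e5, 1e6, by = 1e5),
                         p_adjust = c("none", "BH"), seed = 1L) {
  p_adjust <- match.arg(p_adjust)
  if (is.null(gm$cohorts)) stop("stage cohorts: cohort labels are required")
  set.seed(seed)
  l_callable <- sum(contig_lengths)
  filter_report <- NULL
  snp <- gm_subset(gm, sites = site_is_polymorphic(gm))
  if (!is.null(filter_cfg)) {
    fr <- apply_site_filters(snp, filter_cfg, expected_mean_depth)
    snp <- fr$genotypes
    filter_report <- fr$report
  }

  het <- individual_heterozygosity(gm)
  fh <- f_h(gm)
  cohort_tab <- cohort_diversity(gm, l_callable)

  profiles <- lapply(seq_len(n_ind(gm)), function(i) {
    inp <- roh_inputs_from_gm(gm, i)
    tr <- window_heterozygosity(inp$het_pos, contig_lengths,
                                window_size = window_size,
                                callable_pos = inp$callable_pos,
                                min_contig_bp = min_contig_bp)
    segs <- detect_roh(tr, het_threshold = het_threshold,
                       min_windows = min_windows)
    analyzed <- sum(contig_lengths[contig_lengths >= min_contig_bp])
    froh_profile(segs, analyzed, cutoffs = froh_cutoffs)
  })
  names(profiles) <- gm$samples
  froh <- cohort_froh_table(profiles, gm$cohorts)
  froh_total <- vapply(profiles, function(p) p$froh[1], numeric(1))

  load_res <- NULL
  if (!is.null(annotation)) {
    eff <- classify_effect(snp, annotation)
    load_res <- list(summary = load_summary(eff, snp))
    load_res$proportions <- category_proportions(load_res$summary,
                                                 gm$cohorts)
  }

  d <- allele_sharing_distance(snp)
  pc <- pcoa_classic(d, n_axes = min(3L, n_ind(gm) - 1L))
  sep <- pcoa_separation_test(pc, gm$cohorts, seed = seed)

  safe_cor <- function(x, y) tryCatch(pearson_correlation(x, y),
                                      error = function(e) NULL)
  cors <- list(het_vs_froh = safe_cor(het, froh_total),
               het_vs_fh = safe_cor(het, fh))
  if (!is.null(load_res)) {
    ld <- load_res$summary$load
    cors$load_vs_het <- safe_cor(ld, het)
    cors$load_vs_froh <- safe_cor(ld, froh_total)
  }

  av <- list(het = anova_oneway(het, gm$cohorts))
  if (p_adjust == "BH") {
    pv <- stats::p.adjust(c(av$het$p, froh$anova$p), method = "BH")
    av$het$p_adjusted <- pv[1]
    froh$anova$p_adjusted <- pv[-1]
  }

  structure(list(
    individual_table = data.frame(individual = gm$samples,
                                  cohort = gm$cohorts,
                                  het = het, f_h = fh,
                                  froh_total = froh_total,
                                  row.names = NULL),
    cohort_table = cohort_tab,
    filter_report = filter_report,
    froh = froh,
    load = load_res,
    pcoa = pc,
    pcoa_separation = sep,
    correlations = cors,
    anova = av,
    parameters = list(window_size = window_size,
                      het_threshold = het_threshold,
                      min_windows = min_windows,
                      min_contig_bp = min_contig_bp,
                      l_callable = l_callable,
                      p_adjust = p_adjust, seed = seed)),
    class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("cohort_report (", nrow(x$individual_table), " individuals, ",
      length(unique(x$individual_table$cohort)), " cohorts)\n", sep = "")
  print(x$cohort_table, row.names = FALSE, digits = 4)
  cat("\nheterozygosity ANOVA: F =", signif(x$anova$het$f, 3),
      " p =", signif(x$anova$het$p, 3), "\n")
  for (nm in names(x$correlations)) {
    ct <- x$correlations[[nm]]
    if (!is.null(ct))
      cat(sprintf("  %-14s R = %.3f  P = %.3g\n", nm, ct$r, ct$p))
  }
  cat("PCoA axis variance:",
      paste(sprintf("%.1f%%", x$pcoa$percent_variance), collapse = ", "),
      "; cohort separation p =", signif(x$pcoa_separation$p_value, 3), "\n")
  invisible(x)
}
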