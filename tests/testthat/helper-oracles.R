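# Independent brute-force oracles, written against the definitions rather
# than the package's code paths.

# random small genotype matrix; missing_frac of calls set NA
random_gm <- function(n_sites, n_ind, seed, missing_frac = 0,
                      contig = "chr1") {
  set.seed(seed)
  gt <- matrix(sample(0:2, n_sites * n_ind, replace = TRUE,
                      prob = c(0.5, 0.3, 0.2)), n_sites, n_ind)
  if (missing_frac > 0)
    gt[runif(length(gt)) < missing_frac] <- NA
  genotype_matrix(rep(contig, n_sites),
                  sort(sample.int(n_sites * 50, n_sites)),
                  rep("A", n_sites), rep("T", n_sites), gt,
                  sprintf("s%02d", seq_len(n_ind)))
}

# folded SFS by explicit per-site recount
oracle_fsfs <- function(gm) {
  n <- length(gm$samples)
  counts <- numeric(n)
  for (s in seq_len(nrow(gm$gt))) {
    g <- gm$gt[s, ]
    if (any(is.na(g))) next
    c_alt <- sum(g)
    if (c_alt == 0 || c_alt == 2 * n) next
    minor <- min(c_alt, 2 * n - c_alt)
    counts[minor] <- counts[minor] + 1
  }
  counts
}

# multinomial log-pmf from first principles (lgamma form)
oracle_multinom_ll <- function(obs, prob) {
  lgamma(sum(obs) + 1) - sum(lgamma(obs + 1)) + sum(obs * log(prob))
}

# total pairwise difference over all haplotype pairs, enumerated from
# allele counts (alleles paired within genotypes per Hardy-Weinberg);
# partially missing sites contribute via their called genotypes only
oracle_pi_total <- function(gm) {
  n <- length(gm$samples)
  tot <- 0
  for (s in seq_len(nrow(gm$gt))) {
    g <- gm$gt[s, ]
    g <- g[!is.na(g)]
    if (length(g) < 2) next
    haps <- unlist(lapply(g, function(x)
      switch(x + 1, c(0, 0), c(0, 1), c(1, 1))))
    nh <- length(haps)
    diff <- 0
    for (i in seq_len(nh - 1))
      for (j in (i + 1):nh) diff <- diff + (haps[i] != haps[j])
    tot <- tot + diff / choose(nh, 2)
  }
  tot
}

# Tajima's D from first principles, using oracle_pi_total without the
# small-sample (2n/(2n-1)) factor folded differently: D uses the unbiased
# mean pairwise difference, which equals the average over all haplotype
# pairs computed above.
oracle_tajimas_d <- function(gm) {
  n <- length(gm$samples)
  nh <- 2 * n
  complete <- rowSums(is.na(gm$gt)) == 0
  ac <- rowSums(gm$gt[complete, , drop = FALSE])
  seg <- ac > 0 & ac < nh
  sub <- gm
  sub$gt <- gm$gt[complete, , drop = FALSE][seg, , drop = FALSE]
  s <- sum(seg)
  pi_t <- oracle_pi_total(sub)
  a1 <- sum(1 / 1:(nh - 1)); a2 <- sum(1 / (1:(nh - 1))^2)
  b1 <- (nh + 1) / (3 * (nh - 1)); b2 <- 2 * (nh^2 + nh + 3) / (9 * nh * (nh - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (nh + 2) / (a1 * nh) + a2 / a1^2
  (pi_t - s / a1) / sqrt(c1 / a1 * s + c2 / (a1^2 + a2) * s * (s - 1))
}

# all-pairs r^2 scan for LD pruning verification
oracle_ld_violations <- function(gm, window_kb, r2_max) {
  bad <- 0
  for (i in seq_len(nrow(gm$gt) - 1)) {
    for (j in (i + 1):nrow(gm$gt)) {
      if (gm$chrom[i] != gm$chrom[j]) next
      if (abs(gm$pos[j] - gm$pos[i]) > window_kb * 1000) next
      r <- suppressWarnings(cor(gm$gt[i, ], gm$gt[j, ],
                                use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 > r2_max) bad <- bad + 1
    }
  }
  bad
}

# site-filter survivors by independent per-site predicate evaluation
oracle_filter_keep <- function(gm, cfg, expected_mean_depth = NULL) {
  keep <- logical(nrow(gm$gt))
  for (s in seq_len(nrow(gm$gt))) {
    g <- gm$gt[s, ]
    alt <- strsplit(gm$alt[s], ",")[[1]]
    ok <- TRUE
    if (cfg$exclude_indels &&
        (nchar(gm$ref[s]) != 1 || any(alt != "." & nchar(alt) != 1)))
      ok <- FALSE
    if (ok && !is.null(expected_mean_depth)) {
      md <- mean(gm$dp[s, ], na.rm = TRUE)
      if (!is.na(md) && (md > cfg$depth_hi_ratio * expected_mean_depth ||
                         md < cfg$depth_lo_ratio * expected_mean_depth))
        ok <- FALSE
    }
    if (ok && mean(is.na(g)) > cfg$max_missing_frac) ok <- FALSE
    if (ok && cfg$biallelic_only && length(alt) > 1) ok <- FALSE
    if (ok) {
      nc <- sum(!is.na(g))
      if (nc > 0 && sum(g == 1, na.rm = TRUE) / nc > cfg$het_excess_max)
        ok <- FALSE
    }
    if (ok && cfg$min_minor_allele_count > 0) {
      ac <- sum(g, na.rm = TRUE); an <- 2 * sum(!is.na(g))
      if (min(ac, an - ac) < cfg$min_minor_allele_count) ok <- FALSE
    }
    keep[s] <- ok
  }
  keep
}

# F_ROH by explicit filter and sum
oracle_froh <- function(lengths, analyzed, cutoff)
  sum(lengths[lengths >= cutoff]) / analyzed

# tract/segment overlap bookkeeping for ROH scoring
overlap_bp <- function(a_start, a_end, b_start, b_end)
  sum(pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start)))

roh_score <- function(segments, tracts) {
  tp <- sum(vapply(seq_len(nrow(tracts)), function(k)
    overlap_bp(segments$start, segments$end,
               tracts$start[k], tracts$end[k]), numeric(1)))
  list(recall = tp / sum(tracts$end - tracts$start),
       precision = if (sum(segments$length) > 0)
         tp / sum(segments$length) else 1)
}

# per-truth-boundary error (bp) against nearest detected boundary of an
# overlapping segment
roh_boundary_errors <- function(segments, tracts) {
  errs <- c()
  for (k in seq_len(nrow(tracts))) {
    ov <- segments[segments$end > tracts$start[k] &
                     segments$start < tracts$end[k], ]
    if (nrow(ov) == 0) next
    errs <- c(errs, abs(min(ov$start) - tracts$start[k]),
              abs(max(ov$end) - tracts$end[k]))
  }
  errs
}
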