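#' Windowed heterozygosity track
#'
#' Tiles each retained contig with non-overlapping windows (step = window
#' size) and records per window the number of callable sites, the number of
#' heterozygous calls and their ratio. Contigs shorter than
#' \code{min_contig_bp} are excluded entirely (short scaffolds make ROH
#' length bookkeeping unreliable). Windows whose callable-site count falls
#' below \code{min_callable_frac} of the expected density are masked.
#'
#' @param het_pos data.frame with columns \code{chrom} and \code{pos}
#'   giving the individual's heterozygous positions (1-based).
#' @param contig_lengths named numeric vector of contig lengths in bp.
#' @param window_size window width in bp (default 10 kbp).
#' @param callable_pos optional data.frame(chrom, pos) of callable
#'   positions; when NULL every bp is treated as callable.
#' @param min_contig_bp minimum contig length analyzed (default 3 Mbp).
#' @param min_callable_frac masking floor: a window is masked when its
#'   callable sites are fewer than this fraction of the callable density
#'   expected from the window width (default 0.1).
#' @return data.frame of class \code{window_track} with columns contig,
#'   start, end (0-based half-open), n_callable, n_het, het_rate, masked.
#' @export
window_heterozygosity <- function(het_pos, contig_lengths,
                                  window_size = 10000L,
                                  callable_pos = NULL,
                                  min_contig_bp = 3e6,
                                  min_callable_frac = 0.1) {
  if (is.null(names(contig_lengths)) || any(names(contig_lengths) == ""))
    stop("contig_lengths must be a named vector")
  keep_ctg <- names(contig_lengths)[contig_lengths >= min_contig_bp]
  tracks <- lapply(keep_ctg, function(ctg) {
    len <- contig_lengths[[ctg]]
    n_win <- ceiling(len / window_size)
    starts <- (seq_len(n_win) - 1) * window_size
    ends <- pmin(starts + window_size, len)
    hp <- het_pos$pos[het_pos$chrom == ctg]
    n_het <- tabulate(pmin(floor((hp - 1) / window_size) + 1, n_win),
                      nbins = n_win)
    if (is.null(callable_pos)) {
      n_call <- ends - starts
      floor_call <- min_callable_frac * window_size
    } else {
      cp <- callable_pos$pos[callable_pos$chrom == ctg]
      n_call <- tabulate(pmin(floor((cp - 1) / window_size) + 1, n_win),
                         nbins = n_win)
      density <- length(cp) / len
      floor_call <- min_callable_frac * density * window_size
    }
    data.frame(contig = ctg, start = starts, end = ends,
               n_callable = n_call, n_het = n_het,
               het_rate = ifelse(n_call > 0, n_het / n_call, NA_real_),
               masked = n_call < floor_call | n_call == 0)
  })
  out <- do.call(rbind, tracks)
  if (is.null(out)) out <- data.frame(contig = character(0),
                                      start = numeric(0), end = numeric(0),
                                      n_callable = numeric(0),
                                      n_het = integer(0),
                                      het_rate = numeric(0),
                                      masked = logical(0))
  attr(out, "window_size") <- window_size
  class(out) <- c("window_track", "data.frame")
  out
}

# Build the per-individual inputs of window_heterozygosity from a genotype
# matrix: non-missing sites are callable, code-1 sites heterozygous.
roh_inputs_from_gm <- function(gm, individual) {
  if (is.character(individual)) individual <- match(individual, gm$samples)
  ok <- !is.na(gm$gt[, individual])
  list(het_pos = data.frame(chrom = gm$chrom[ok & gm$gt[, individual] == 1L],
                            pos = gm$pos[ok & gm$gt[, individual] == 1L]),
       callable_pos = data.frame(chrom = gm$chrom[ok], pos = gm$pos[ok]))
}

#' Detect runs of homozygosity from a window track
#'
#' A ROH is a maximal run of at least \code{min_windows} consecutive
#' unmasked windows with heterozygosity rate strictly below
#' \code{het_threshold}; masked and above-threshold windows break runs.
#' Segment coordinates snap to window boundaries (0-based half-open).
#'
#' @param track a \code{\link{window_heterozygosity}} track.
#' @param het_threshold per-window heterozygosity ceiling (default 0.002,
#'   i.e. 0.2%).
#' @param min_windows minimum run length in windows (default 10).
#' @return data.frame of class \code{roh_segments} with columns contig,
#'   start, end, length, n_windows.
#' @export
detect_roh <- function(track, het_threshold = 0.002, min_windows = 10L) {
  segs <- list()
  for (ctg in unique(track$contig)) {
    tr <- track[track$contig == ctg, ]
    low <- !tr$masked & !is.na(tr$het_rate) & tr$het_rate < het_threshold
    r <- rle(low)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1
    for (k in which(r$values & r$lengths >= min_windows)) {
      i1 <- starts_idx[k]; i2 <- ends_idx[k]
      segs[[length(segs) + 1]] <-
        data.frame(contig = ctg, start = tr$start[i1], end = tr$end[i2],
                   n_windows = i2 - i1 + 1)
    }
  }
  out <- if (length(segs)) do.call(rbind, segs) else
    data.frame(contig = character(0), start = numeric(0), end = numeric(0),
               n_windows = integer(0))
  out$length <- out$end - out$start
  out <- out[, c("contig", "start", "end", "length", "n_windows")]
  class(out) <- c("roh_segments", "data.frame")
  out
}

#' ROH-based inbreeding profile F_ROH by length cutoff
#'
#' F_ROH at cutoff c is the fraction of the analyzed genome covered by ROH
#' segments of length at least c. The default cutoffs run from 100 kbp to
#' 1 Mbp in 100 kbp steps (extend the vector for a finer long-ROH tail);
#' the profile is monotone nonincreasing in the cutoff by construction.
#'
#' @param segments a \code{\link{detect_roh}} result.
#' @param analyzed_length total length in bp of the analyzed (retained)
#'   contigs.
#' @param cutoffs length cutoffs in bp.
#' @return data.frame of class \code{froh_profile} with columns cutoff_bp
#'   and froh.
#' @export
froh_profile <- function(segments, analyzed_length,
                         cutoffs = seq(1e5, 1e6, by = 1e5)) {
  if (analyzed_length <= 0) stop("analyzed_length must be positive")
  froh <- vapply(cutoffs, function(c)
    sum(segments$length[segments$length >= c]) / analyzed_length,
    numeric(1))
  out <- data.frame(cutoff_bp = cutoffs, froh = froh)
  class(out) <- c("froh_profile", "data.frame")
  out
}

#' Compare F_ROH between cohorts
#'
#' Stacks per-individual F_ROH profiles into a long table and runs a
#' one-way ANOVA per length cutoff across cohorts.
#'
#' @param profiles named list of \code{\link{froh_profile}} objects, one
#'   per individual.
#' @param cohorts cohort label per individual (same order as
#'   \code{profiles}).
#' @return list with \code{table} (long-format data.frame) and
#'   \code{anova} (per-cutoff F statistic, p-value and a flag for
#'   degenerate zero-variance comparisons).
#' @export
cohort_froh_table <- function(profiles, cohorts) {
  cohorts <- as.character(cohorts)
  stopifnot(length(profiles) == length(cohorts))
  tab <- table(cohorts)
  if (length(tab) < 2) stop("need at least two cohorts")
  if (any(tab < 2)) stop("every cohort needs at least two members")
  ids <- names(profiles)
  if (is.null(ids)) ids <- sprintf("ind%02d", seq_along(profiles))
  long <- do.call(rbind, lapply(seq_along(profiles), function(i)
    data.frame(individual = ids[i], cohort = cohorts[i],
               profiles[[i]])))
  av <- do.call(rbind, lapply(unique(long$cutoff_bp), function(c) {
    sub <- long[long$cutoff_bp == c, ]
    degenerate <- stats::var(sub$froh) == 0
    if (degenerate) {
      data.frame(cutoff_bp = c,
                 group_means = I(list(tapply(sub$froh, sub$cohort, mean))),
                 f = 0, p = 1, degenerate = TRUE)
    } else {
      fit <- stats::aov(froh ~ cohort, data = sub)
      s <- summary(fit)[[1]]
      data.frame(cutoff_bp = c,
                 group_means = I(list(tapply(sub$froh, sub$cohort, mean))),
                 f = s[["F value"]][1], p = s[["Pr(>F)"]][1],
                 degenerate = FALSE)
    }
  }))
  list(table = long, anova = av)
}
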