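#' Coding annotation
#'
#' Holds, per transcript, the contig, strand, ordered CDS intervals
#' (1-based inclusive, GFF convention), the reading-frame phase of the
#' first coding segment, and accessors into the reference sequence.
#' Splice-site positions (the first and last 2 bp of every intron) are
#' derived from the interval structure.
#'
#' @param transcripts list of transcript descriptions, each a list with
#'   elements \code{id}, \code{contig}, \code{strand} ("+" or "-"),
#'   \code{intervals} (data.frame with \code{start}, \code{end}) and
#'   optional \code{phase} (default 0).
#' @param sequences named character vector (or
#'   \code{Biostrings::DNAStringSet}) of contig sequences.
#' @return an object of class \code{coding_annotation}.
#' @export
coding_annotation <- function(transcripts, sequences) {
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- as.character(sequences)
  sequences <- vapply(sequences, toupper, character(1))
  tx <- lapply(transcripts, function(t) {
    stopifnot(t$strand %in% c("+", "-"))
    iv <- t$intervals[order(t$intervals$start), , drop = FALSE]
    if (nrow(iv) > 1 && any(iv$start[-1] <= iv$end[-nrow(iv)]))
      stop("overlapping CDS intervals in transcript ", t$id)
    phase <- if (is.null(t$phase)) 0L else as.integer(t$phase)
    # genomic coding positions in transcription order
    if (t$strand == "+") {
      gpos <- unlist(lapply(seq_len(nrow(iv)),
                            function(i) iv$start[i]:iv$end[i]))
    } else {
      gpos <- unlist(lapply(rev(seq_len(nrow(iv))),
                            function(i) iv$end[i]:iv$start[i]))
    }
    if (phase > 0) gpos <- gpos[-seq_len(phase)]
    if (length(gpos) %% 3 != 0)
      stop("CDS length of transcript ", t$id,
           " is not divisible by 3 after phase adjustment")
    seq <- sequences[[t$contig]]
    bases <- substring(seq, gpos, gpos)
    if (t$strand == "-") bases <- chartr("ACGT", "TGCA", bases)
    splice <- integer(0)
    if (nrow(iv) > 1) {
      for (i in seq_len(nrow(iv) - 1))
        splice <- c(splice, iv$end[i] + 1:2, iv$start[i + 1] - 2:1)
    }
    list(id = t$id, contig = t$contig, strand = t$strand, intervals = iv,
         phase = phase, coding_pos = gpos,
         cds_seq = paste(bases, collapse = ""), splice_pos = splice)
  })
  names(tx) <- vapply(tx, `[[`, character(1), "id")
  structure(list(transcripts = tx, sequences = sequences),
            class = "coding_annotation")
}

#' Read a coding annotation from GFF3 + FASTA
#'
#' Collects CDS features from a GFF3 file (grouped by their Parent, or ID
#' when Parent is absent) together with the reference sequence.
#'
#' @param gff_path GFF3 file with CDS features carrying phase.
#' @param fasta_path FASTA reference for the same contigs.
#' @return a \code{\link{coding_annotation}}.
#' @export
read_coding_annotation <- function(gff_path, fasta_path) {
  gff <- ape::read.gff(gff_path)
  cds <- gff[gff$type == "CDS", ]
  if (nrow(cds) == 0) stop("no CDS features in ", gff_path)
  get_attr <- function(attr, key) {
    m <- regmatches(attr, regexpr(paste0(key, "=[^;]+"), attr))
    ifelse(lengths(regmatches(attr,
                              gregexpr(paste0(key, "=[^;]+"), attr))) > 0,
           sub(paste0(key, "="), "", m), NA_character_)
  }
  parent <- get_attr(cds$attributes, "Parent")
  id <- get_attr(cds$attributes, "ID")
  group <- ifelse(is.na(parent), id, parent)
  if (any(is.na(group))) stop("CDS features without Parent or ID attribute")
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  transcripts <- lapply(unique(group), function(g) {
    sub <- cds[group == g, ]
    # phase of the first CDS in transcription order
    first <- if (sub$strand[1] == "+") which.min(sub$start)
             else which.max(sub$end)
    ph <- suppressWarnings(as.integer(as.character(sub$phase[first])))
    list(id = g, contig = as.character(sub$seqid[1]),
         strand = as.character(sub$strand[1]),
         intervals = data.frame(start = sub$start, end = sub$end),
         phase = if (is.na(ph)) 0L else ph)
  })
  coding_annotation(transcripts, seqs)
}

severity_rank <- c(noncoding = 0, synonymous = 1, missense = 2, lof = 3)

#' Classify single-nucleotide variants by coding effect
#'
#' For every SNV, determines the most severe effect over all transcripts:
#' splice-site disruption (within the first or last 2 bp of an intron),
#' stop gained, start lost (all loss of function), amino-acid change
#' (missense), silent codon change (synonymous), or noncoding. The
#' affected codon is translated on the coding strand under the standard
#' genetic code.
#'
#' @param variants data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt} (single bases), or a
#'   \code{\link{genotype_matrix}} whose sites are used.
#' @param ann a \code{\link{coding_annotation}}; variant REF alleles must
#'   match the reference sequence.
#' @param stop_lost_is_lof classify the loss of a stop codon as LoF
#'   instead of missense (default FALSE).
#' @return data.frame of class \code{effect_calls} with columns chrom,
#'   pos, ref, alt, category, lof_subtype, codon_before, codon_after,
#'   aa_before, aa_after.
#' @export
classify_effect <- function(variants, ann, stop_lost_is_lof = FALSE) {
  if (inherits(variants, "genotype_matrix"))
    variants <- data.frame(chrom = variants$chrom, pos = variants$pos,
                           ref = variants$ref, alt = variants$alt)
  code <- Biostrings::GENETIC_CODE
  n <- nrow(variants)
  out <- data.frame(chrom = variants$chrom, pos = variants$pos,
                    ref = variants$ref, alt = variants$alt,
                    category = "noncoding", lof_subtype = "none",
                    codon_before = NA_character_,
                    codon_after = NA_character_,
                    aa_before = NA_character_, aa_after = NA_character_)
  for (v in seq_len(n)) {
    ref <- variants$ref[v]; alt <- variants$alt[v]
    if (!ref %in% c("A", "C", "G", "T") || !alt %in% c("A", "C", "G", "T"))
      stop("only single-base SNVs are supported (variant at ",
           variants$chrom[v], ":", variants$pos[v], ")")
    gbase <- substring(ann$sequences[[variants$chrom[v]]],
                       variants$pos[v], variants$pos[v])
    if (length(gbase) && nzchar(gbase) && gbase != ref)
      stop("REF allele mismatch at ", variants$chrom[v], ":",
           variants$pos[v], " (VCF ", ref, ", reference ", gbase, ")")
    best <- out[v, ]
    for (tx in ann$transcripts) {
      if (tx$contig != variants$chrom[v]) next
      call <- NULL
      if (variants$pos[v] %in% tx$splice_pos) {
        call <- list(category = "lof", lof_subtype = "splice_site",
                     codon_before = NA, codon_after = NA,
                     aa_before = NA, aa_after = NA)
      } else {
        k <- match(variants$pos[v], tx$coding_pos)
        if (!is.na(k)) {
          ci <- (k - 1) %/% 3
          codon_before <- substring(tx$cds_seq, 3 * ci + 1, 3 * ci + 3)
          alt_cs <- if (tx$strand == "-") chartr("ACGT", "TGCA", alt) else alt
          in_codon <- (k - 1) %% 3 + 1
          codon_after <- codon_before
          substring(codon_after, in_codon, in_codon) <- alt_cs
          aa_b <- unname(code[codon_before])
          aa_a <- unname(code[codon_after])
          cat <- if (ci == 0 && aa_b == "M" && aa_a != "M") "start_lost"
            else if (aa_a == "*" && aa_b != "*") "stop_gained"
            else if (aa_b == "*" && aa_a != "*")
              if (stop_lost_is_lof) "stop_lost" else "missense"
            else if (aa_a == aa_b) "synonymous" else "missense"
          call <- list(
            category = if (cat %in% c("start_lost", "stop_gained",
                                      "stop_lost")) "lof" else cat,
            lof_subtype = if (cat %in% c("start_lost", "stop_gained",
                                         "stop_lost", "splice_site"))
              cat else "none",
            codon_before = codon_before, codon_after = codon_after,
            aa_before = aa_b, aa_after = aa_a)
        }
      }
      if (!is.null(call) &&
          severity_rank[[call$category]] > severity_rank[[best$category]]) {
        best$category <- call$category
        best$lof_subtype <- call$lof_subtype
        best$codon_before <- call$codon_before
        best$codon_after <- call$codon_after
        best$aa_before <- call$aa_before
        best$aa_after <- call$aa_after
      }
    }
    out[v, ] <- best
  }
  class(out) <- c("effect_calls", "data.frame")
  out
}

#' Per-individual mutational load summary
#'
#' Counts, for every individual, the variants it carries (genotype code 1
#' or 2) in each effect category, splits the loss-of-function count by
#' zygosity, and reports the load statistic: the proportion of LoF variants
#' among the individual's total carried variants.
#'
#' @param effects an \code{\link{classify_effect}} result covering the
#'   matrix's sites.
#' @param gm \code{\link{genotype_matrix}} of the same variants.
#' @return data.frame of class \code{load_summary}: individual, n_total,
#'   n_syn, n_mis, n_lof, n_lof_het, n_lof_hom, load, p_syn, p_mis, p_lof.
#' @export
load_summary <- function(effects, gm) {
  key_e <- paste(effects$chrom, effects$pos)
  key_g <- paste(gm$chrom, gm$pos)
  idx <- match(key_g, key_e)
  if (any(is.na(idx)))
    stop("effect calls missing for ", sum(is.na(idx)), " matrix site(s)")
  cat <- effects$category[idx]
  out <- do.call(rbind, lapply(seq_len(n_ind(gm)), function(i) {
    g <- gm$gt[, i]
    carried <- !is.na(g) & g > 0L
    n_total <- sum(carried)
    n_lof_het <- sum(carried & cat == "lof" & g == 1L)
    n_lof_hom <- sum(carried & cat == "lof" & g == 2L)
    n_lof <- n_lof_het + n_lof_hom
    data.frame(individual = gm$samples[i],
               n_total = n_total,
               n_syn = sum(carried & cat == "synonymous"),
               n_mis = sum(carried & cat == "missense"),
               n_lof = n_lof,
               n_lof_het = n_lof_het, n_lof_hom = n_lof_hom,
               load = if (n_total > 0) n_lof / n_total else 0,
               no_variants = n_total == 0)
  }))
  out$p_syn <- ifelse(out$n_total > 0, out$n_syn / out$n_total, 0)
  out$p_mis <- ifelse(out$n_total > 0, out$n_mis / out$n_total, 0)
  out$p_lof <- ifelse(out$n_total > 0, out$n_lof / out$n_total, 0)
  class(out) <- c("load_summary", "data.frame")
  out
}

#' Compare effect-category proportions between cohorts
#'
#' Builds the long table of per-individual relative category abundances
#' and runs a one-way ANOVA per category across cohorts.
#'
#' @param summaries a \code{\link{load_summary}} data.frame.
#' @param cohorts cohort label per individual (same order).
#' @return list with \code{table} and per-category \code{anova}
#'   (F statistic and p-value).
#' @export
category_proportions <- function(summaries, cohorts) {
  cohorts <- as.character(cohorts)
  stopifnot(nrow(summaries) == length(cohorts))
  tab <- table(cohorts)
  if (length(tab) < 2) stop("need at least two cohorts")
  if (any(tab < 2)) stop("every cohort needs at least two members")
  long <- do.call(rbind, lapply(c("p_syn", "p_mis", "p_lof"), function(cl)
    data.frame(individual = summaries$individual, cohort = cohorts,
               category = sub("p_", "", cl), proportion = summaries[[cl]])))
  av <- do.call(rbind, lapply(unique(long$category), function(cl) {
    sub <- long[long$category == cl, ]
    if (stats::var(sub$proportion) == 0)
      return(data.frame(category = cl, f = 0, p = 1, degenerate = TRUE))
    s <- summary(stats::aov(proportion ~ cohort, data = sub))[[1]]
    data.frame(category = cl, f = s[["F value"]][1], p = s[["Pr(>F)"]][1],
               degenerate = FALSE)
  }))
  list(table = long, anova = av)
}
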