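#' Synthetic diploid genome with implanted autozygous tracts
#'
#' Emulates one individual's genotype track along a contig: callable
#' (genotyped) sites are placed by a Poisson process at
#' \code{callable_density} per bp, and each callable site is heterozygous
#' with probability \code{background_het_rate / callable_density} outside
#' the implanted tracts and \code{inside_factor} times that inside them (a
#' small residual het rate emulates genotyping error inside true
#' autozygous segments). The defaults give a genome-wide heterozygosity of
#' 7e-4 per bp -- a moderately diverse baleen-whale-scale genome -- at a
#' callable density where background windows (about 0.35% heterozygous
#' calls per callable site) sit clearly above a 0.2% window threshold and
#' autozygous windows (about 0.035%) clearly below it. Truth coordinates
#' are returned for scoring ROH callers.
#'
#' @param genome_length contig length in bp.
#' @param background_het_rate heterozygous sites per bp outside tracts.
#' @param tracts data.frame with columns \code{start}, \code{end}
#'   (0-based half-open, non-overlapping) of true autozygous tracts.
#' @param inside_factor multiplier of the background het probability
#'   inside tracts.
#' @param callable_density callable sites per bp.
#' @param contig contig name.
#' @param seed RNG seed.
#' @return list with \code{het_pos} and \code{callable_pos} (data.frames
#'   with chrom, pos; het positions are a subset of callable positions),
#'   \code{contig_lengths}, and \code{truth} (tracts, parameters, seed).
#' @export
make_roh_genome <- function(genome_length = 1e7,
                            background_het_rate = 7e-4,
                            tracts = data.frame(start = numeric(0),
                                                end = numeric(0)),
                            inside_factor = 0.1,
                            callable_density = 0.2,
                            contig = "chr1", seed = 1L) {
  tracts <- as.data.frame(tracts)
  if (nrow(tracts) > 0) {
    tracts <- tracts[order(tracts$start), , drop = FALSE]
    stopifnot(all(tracts$start >= 0), all(tracts$end <= genome_length),
              all(tracts$end > tracts$start))
    if (nrow(tracts) > 1 &&
        any(tracts$start[-1] < tracts$end[-nrow(tracts)]))
      stop("tracts must not overlap")
  }
  p_het <- background_het_rate / callable_density
  stopifnot(p_het <= 1)
  set.seed(seed)
  n <- min(stats::rpois(1, callable_density * genome_length), genome_length)
  pos <- sort(sample.int(genome_length, n))
  inside <- rep(FALSE, length(pos))
  for (k in seq_len(nrow(tracts)))
    inside <- inside | (pos > tracts$start[k] & pos <= tracts$end[k])
  het <- stats::runif(length(pos)) <
    ifelse(inside, inside_factor * p_het, p_het)
  list(het_pos = data.frame(chrom = contig, pos = pos[het]),
       callable_pos = data.frame(chrom = contig, pos = pos),
       contig_lengths = stats::setNames(genome_length, contig),
       truth = list(kind = "roh_genome", tracts = tracts,
                    background_het_rate = background_het_rate,
                    inside_factor = inside_factor,
                    callable_density = callable_density, seed = seed))
}

#' Pedigree genotypes with known kinship
#'
#' Founders are drawn from Hardy-Weinberg proportions at independent sites;
#' offspring receive one allele from each parent by Mendelian transmission
#' (selfing allowed by repeating a parent). Truth kinship coefficients are
#' computed from the pedigree by the standard recursion, so that the
#' expected pi-hat of a pair is twice its kinship (for outbred pairs) and
#' the expected inbreeding coefficient of an individual is the kinship of
#' its parents.
#'
#' @param n_founders number of unrelated founders (named F1, F2, ...).
#' @param n_sites number of independent biallelic sites.
#' @param relationships data.frame with columns \code{id},
#'   \code{parent1}, \code{parent2} defining non-founders; parents must be
#'   declared before their offspring.
#' @param allele_freqs optional vector of alternate-allele frequencies
#'   (recycled); drawn uniformly from [0.1, 0.5] when NULL.
#' @param seed RNG seed.
#' @return list with \code{genotypes} (a \code{\link{genotype_matrix}})
#'   and \code{truth} (kinship matrix, expected pi-hat matrix, inbreeding
#'   coefficients, seed).
#' @export
make_pedigree_genotypes <- function(n_founders, n_sites,
                                    relationships = NULL,
                                    allele_freqs = NULL, seed = 1L) {
  set.seed(seed)
  founders <- sprintf("F%d", seq_len(n_founders))
  if (is.null(relationships))
    relationships <- data.frame(id = character(0), parent1 = character(0),
                                parent2 = character(0))
  ids <- c(founders, relationships$id)
  if (anyDuplicated(ids)) stop("duplicated individual ids in pedigree")
  n <- length(ids)
  parent <- matrix(NA_integer_, n, 2)
  for (r in seq_len(nrow(relationships))) {
    i <- n_founders + r
    p <- match(c(relationships$parent1[r], relationships$parent2[r]), ids)
    if (any(is.na(p)) || any(p >= i))
      stop("parents of ", relationships$id[r],
           " must be declared earlier (cyclic or unknown pedigree)")
    parent[i, ] <- p
  }
  if (is.null(allele_freqs)) allele_freqs <- stats::runif(n_sites, 0.1, 0.5)
  p <- rep_len(allele_freqs, n_sites)
  hap <- array(NA_integer_, c(n_sites, n, 2))
  for (i in seq_len(n)) {
    if (is.na(parent[i, 1])) {
      hap[, i, 1] <- stats::rbinom(n_sites, 1, p)
      hap[, i, 2] <- stats::rbinom(n_sites, 1, p)
    } else {
      for (k in 1:2) {
        pick <- stats::rbinom(n_sites, 1, 0.5) + 1
        hap[, i, k] <- hap[cbind(seq_len(n_sites), parent[i, k], pick)]
      }
    }
  }
  gt <- hap[, , 1] + hap[, , 2]
  # pedigree kinship by the standard recursion
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  f <- numeric(n)
  for (i in seq_len(n)) {
    if (is.na(parent[i, 1])) {
      phi[i, i] <- 0.5
    } else {
      f[i] <- phi[parent[i, 1], parent[i, 2]]
      phi[i, i] <- 0.5 * (1 + f[i])
      for (j in seq_len(i - 1))
        phi[i, j] <- phi[j, i] <-
          0.5 * (phi[parent[i, 1], j] + phi[parent[i, 2], j])
    }
  }
  exp_pihat <- 2 * phi
  diag(exp_pihat) <- 1
  gm <- genotype_matrix(rep("chr1", n_sites), seq_len(n_sites),
                        rep("A", n_sites), rep("T", n_sites),
                        gt, ids)
  list(genotypes = gm,
       truth = list(kind = "pedigree", kinship = phi,
                    expected_pihat = exp_pihat, inbreeding = f,
                    seed = seed))
}

# ---- CDS fixture -----------------------------------------------------------

random_codons <- function(k) {
  bases <- c("A", "C", "G", "T")
  stops <- c("TAA", "TAG", "TGA")
  out <- character(k)
  for (i in seq_len(k)) {
    repeat {
      cd <- paste(sample(bases, 3, replace = TRUE), collapse = "")
      if (!cd %in% stops) break
    }
    out[i] <- cd
  }
  out
}

revcomp <- function(s)
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")

# Independent full-translation oracle: rebuilds the entire mutant CDS from
# the (possibly mutated) genome and compares whole translated proteins.
# Used to label fixture variants and, in tests, to cross-check the
# codon-level classifier.
oracle_effect <- function(chrom, pos, ref, alt, transcripts, sequences) {
  best <- "noncoding"
  rank <- c(noncoding = 0, synonymous = 1, missense = 2, lof = 3)
  for (t in transcripts) {
    if (t$contig != chrom) next
    iv <- t$intervals[order(t$intervals$start), , drop = FALSE]
    splice <- integer(0)
    if (nrow(iv) > 1)
      for (i in seq_len(nrow(iv) - 1))
        splice <- c(splice, iv$end[i] + 1:2, iv$start[i + 1] - 2:1)
    cat <- NULL
    if (pos %in% splice) {
      cat <- "lof"
    } else if (any(pos >= iv$start & pos <= iv$end)) {
      get_prot <- function(genome_seq) {
        pieces <- vapply(seq_len(nrow(iv)), function(i)
          substring(genome_seq, iv$start[i], iv$end[i]), character(1))
        cds <- paste(pieces, collapse = "")
        if (t$strand == "-") cds <- revcomp(cds)
        ph <- if (is.null(t$phase)) 0L else t$phase
        if (ph > 0) cds <- substring(cds, ph + 1)
        as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           no.init.codon = TRUE))
      }
      g <- sequences[[chrom]]
      stopifnot(substring(g, pos, pos) == ref)
      gm <- g
      substring(gm, pos, pos) <- alt
      p_ref <- get_prot(g)
      p_mut <- get_prot(gm)
      if (p_ref == p_mut) {
        cat <- "synonymous"
      } else {
        a_ref <- strsplit(p_ref, "")[[1]]
        a_mut <- strsplit(p_mut, "")[[1]]
        diff <- which(a_ref != a_mut)
        if (1 %in% diff && a_ref[1] == "M") cat <- "lof"          # start lost
        else if (any(a_mut[diff] == "*")) cat <- "lof"            # stop gained
        else cat <- "missense"                                    # incl. stop lost
      }
    }
    if (!is.null(cat) && rank[[cat]] > rank[[best]]) best <- cat
  }
  best
}

#' Synthetic coding annotation with known-effect variants
#'
#' Builds a toy contig carrying several genes (alternating strands, half of
#' them split by an intron so splice sites exist), a matching
#' \code{\link{coding_annotation}}, and a set of SNVs whose true effect
#' category is computed at generation time by an independent
#' full-translation oracle (whole mutant CDS rebuild and protein
#' comparison). The fixture guarantees at least one variant per category.
#'
#' @param n_genes number of genes.
#' @param gene_length coding length per gene in bp (divisible by 3).
#' @param n_variants number of random variants before the guaranteed
#'   per-category additions.
#' @param strand_mix alternate gene strands (default TRUE).
#' @param seed RNG seed.
#' @return list with \code{sequences} (named character), \code{annotation},
#'   \code{variants} (data.frame chrom, pos, ref, alt) and \code{truth}
#'   (data.frame with the oracle category per variant, plus parameters).
#' @export
make_cds_fixture <- function(n_genes = 6L, gene_length = 300L,
                             n_variants = 60L, strand_mix = TRUE,
                             seed = 1L) {
  stopifnot(gene_length %% 3 == 0, gene_length >= 9)
  set.seed(seed)
  intergenic <- 150L
  intron_len <- 100L
  bases <- c("A", "C", "G", "T")
  genome <- paste(sample(bases, intergenic, replace = TRUE), collapse = "")
  transcripts <- list()
  for (g in seq_len(n_genes)) {
    n_codon <- gene_length %/% 3
    cds <- paste(c("ATG", random_codons(n_codon - 2), "TAA"), collapse = "")
    strand <- if (strand_mix && g %% 2 == 0) "-" else "+"
    split_gene <- g %% 2 == 1  # half the genes get an intron
    if (split_gene) {
      cut <- 3 * (n_codon %/% 2) + 1  # split between codons
      intron <- paste0("GT",
                       paste(sample(bases, intron_len - 4, replace = TRUE),
                             collapse = ""), "AG")
      model <- paste0(substring(cds, 1, cut - 1), intron,
                      substring(cds, cut, gene_length))
      exon_model <- data.frame(start = c(1, cut + intron_len),
                               end = c(cut - 1, gene_length + intron_len))
    } else {
      model <- cds
      exon_model <- data.frame(start = 1, end = gene_length)
    }
    glen <- nchar(model)
    offset <- nchar(genome)
    if (strand == "+") {
      genome <- paste0(genome, model)
      iv <- data.frame(start = offset + exon_model$start,
                       end = offset + exon_model$end)
    } else {
      genome <- paste0(genome, revcomp(model))
      iv <- data.frame(start = offset + glen + 1 - exon_model$end,
                       end = offset + glen + 1 - exon_model$start)
    }
    transcripts[[g]] <- list(id = sprintf("gene%d", g), contig = "ctgA",
                             strand = strand, intervals = iv, phase = 0L)
    genome <- paste0(genome,
                     paste(sample(bases, intergenic, replace = TRUE),
                           collapse = ""))
  }
  sequences <- c(ctgA = genome)
  glen <- nchar(genome)
  draw_variant <- function(pos) {
    ref <- substring(genome, pos, pos)
    alt <- sample(setdiff(bases, ref), 1)
    data.frame(chrom = "ctgA", pos = pos, ref = ref, alt = alt)
  }
  pos <- sample.int(glen, n_variants)
  variants <- do.call(rbind, lapply(pos, draw_variant))
  truth_cat <- vapply(seq_len(nrow(variants)), function(v)
    oracle_effect("ctgA", variants$pos[v], variants$ref[v],
                  variants$alt[v], transcripts, sequences), character(1))
  # guarantee every category at least once
  for (want in c("noncoding", "synonymous", "missense", "lof")) {
    tries <- 0
    while (!want %in% truth_cat && tries < 5000) {
      tries <- tries + 1
      v <- draw_variant(sample.int(glen, 1))
      cat <- oracle_effect("ctgA", v$pos, v$ref, v$alt, transcripts,
                           sequences)
      if (cat == want) {
        variants <- rbind(variants, v)
        truth_cat <- c(truth_cat, cat)
      }
    }
    if (!want %in% truth_cat)
      stop("could not construct a ", want, " variant")
  }
  variants <- cbind(variants, truth_category = truth_cat)
  dup <- duplicated(variants$pos)
  variants <- variants[!dup, , drop = FALSE]
  variants <- variants[order(variants$pos), , drop = FALSE]
  rownames(variants) <- NULL
  list(sequences = sequences,
       annotation = coding_annotation(transcripts, sequences),
       transcripts = transcripts,
       variants = variants[, c("chrom", "pos", "ref", "alt")],
       truth = list(kind = "cds_fixture",
                    categories = variants$truth_category,
                    seed = seed))
}

#' Write a CDS fixture to FASTA + GFF3 + truth TSV
#'
#' @param fx a \code{\link{make_cds_fixture}} result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cds_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "fixture.fa")
  writeLines(c(paste0(">", names(fx$sequences)[1]), fx$sequences[[1]]),
             fasta)
  gff <- file.path(dir, "fixture.gff3")
  lines <- "##gff-version 3"
  for (t in fx$transcripts) {
    iv <- t$intervals
    for (i in seq_len(nrow(iv)))
      lines <- c(lines, paste(t$contig, "synthetic", "CDS", iv$start[i],
                              iv$end[i], ".", t$strand, t$phase,
                              paste0("Parent=", t$id), sep = "\t"))
  }
  writeLines(lines, gff)
  truth <- file.path(dir, "fixture_truth.tsv")
  utils::write.table(cbind(fx$variants, category = fx$truth$categories),
                     truth, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, gff = gff, truth = truth))
}

#' Panmictic cohort fixture from the Wright-Fisher simulator
#'
#' Simulates a single population and assigns consecutive individuals to
#' named cohorts, emulating temporally separated sampling of one panmictic
#' population (so no true genetic structure between cohorts exists).
#'
#' @param cfg a \code{\link{sim_config}} whose \code{sample_size} equals
#'   the sum of \code{cohort_sizes}.
#' @param scenario optional \code{\link{demographic_scenario}}.
#' @param cohort_sizes named integer vector of cohort sizes.
#' @return a \code{\link{genotype_matrix}} with cohort labels set.
#' @export
make_cohort_fixture <- function(cfg, scenario = NULL,
                                cohort_sizes = c(A = 10L, B = 10L)) {
  stopifnot(sum(cohort_sizes) == cfg$sample_size)
  gm <- wf_simulate(cfg, scenario)
  gm$cohorts <- rep(names(cohort_sizes), cohort_sizes)
  gm
}
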