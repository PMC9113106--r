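# one plus-strand gene: ATG | GCT TGG GCA | TAA at positions 11..25
simple_ann <- function() {
  seq <- paste0(paste(rep("C", 10), collapse = ""),
                "ATGGCTTGGGCATAA",
                paste(rep("C", 10), collapse = ""))
  coding_annotation(list(list(id = "g1", contig = "c1", strand = "+",
                              intervals = data.frame(start = 11, end = 25))),
                    c(c1 = seq))
}

test_that("codon-table cases: stop gained, synonymous, start lost", {
  ann <- simple_ann()
  # TGG (Trp, codon 3 at 17..19) -> TAG stop
  v <- data.frame(chrom = "c1", pos = 18, ref = "G", alt = "A")
  e <- classify_effect(v, ann)
  expect_equal(e$category, "lof")
  expect_equal(e$lof_subtype, "stop_gained")
  expect_equal(e$codon_before, "TGG")
  expect_equal(e$codon_after, "TAG")
  # GCT (Ala, 14..16) -> GCC (Ala)
  e2 <- classify_effect(data.frame(chrom = "c1", pos = 16, ref = "T",
                                   alt = "C"), ann)
  expect_equal(e2$category, "synonymous")
  expect_equal(e2$aa_before, "A")
  expect_equal(e2$aa_after, "A")
  # ATG -> GTG start lost
  e3 <- classify_effect(data.frame(chrom = "c1", pos = 11, ref = "A",
                                   alt = "G"), ann)
  expect_equal(e3$category, "lof")
  expect_equal(e3$lof_subtype, "start_lost")
  # outside the CDS
  e4 <- classify_effect(data.frame(chrom = "c1", pos = 3, ref = "C",
                                   alt = "T"), ann)
  expect_equal(e4$category, "noncoding")
})

test_that("reference mismatches and indels are rejected", {
  ann <- simple_ann()
  expect_error(classify_effect(data.frame(chrom = "c1", pos = 18,
                                          ref = "T", alt = "A"), ann),
               "mismatch")
  expect_error(classify_effect(data.frame(chrom = "c1", pos = 18,
                                          ref = "GG", alt = "A"), ann),
               "SNV")
})

test_that("stop_lost is missense by default, LoF when requested", {
  ann <- simple_ann()
  v <- data.frame(chrom = "c1", pos = 24, ref = "A", alt = "C")  # TAA->TCA
  expect_equal(classify_effect(v, ann)$category, "missense")
  e <- classify_effect(v, ann, stop_lost_is_lof = TRUE)
  expect_equal(e$category, "lof")
  expect_equal(e$lof_subtype, "stop_lost")
})

test_that("classifier agrees with the full-translation oracle everywhere", {
  fx <- make_cds_fixture(n_genes = 8, gene_length = 300, n_variants = 400,
                         seed = 51)
  eff <- classify_effect(fx$variants, fx$annotation)
  expect_equal(eff$category, fx$truth$categories)
  expect_true(all(c("noncoding", "synonymous", "missense", "lof")
                  %in% fx$truth$categories))
  # both strands exercised
  strands <- vapply(fx$transcripts, `[[`, character(1), "strand")
  expect_setequal(unique(strands), c("+", "-"))
})

test_that("splice-site variants in the 2 bp intron edges are LoF", {
  fx <- make_cds_fixture(n_genes = 4, seed = 52)
  tx <- Filter(function(t) nrow(t$intervals) > 1, fx$transcripts)[[1]]
  iv <- tx$intervals[order(tx$intervals$start), ]
  donor_pos <- iv$end[1] + 1
  ref <- substring(fx$sequences[["ctgA"]], donor_pos, donor_pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  e <- classify_effect(data.frame(chrom = "ctgA", pos = donor_pos,
                                  ref = ref, alt = alt), fx$annotation)
  expect_equal(e$category, "lof")
  expect_equal(e$lof_subtype, "splice_site")
})

test_that("reverse-complementing genome and annotation preserves categories", {
  fx <- make_cds_fixture(n_genes = 4, gene_length = 150, n_variants = 80,
                         seed = 53)
  glen <- nchar(fx$sequences[["ctgA"]])
  rc_seq <- bottleneckR:::revcomp(fx$sequences[["ctgA"]])
  rc_tx <- lapply(fx$transcripts, function(t) {
    list(id = t$id, contig = "ctgA",
         strand = if (t$strand == "+") "-" else "+",
         intervals = data.frame(start = glen + 1 - t$intervals$end,
                                end = glen + 1 - t$intervals$start),
         phase = 0L)
  })
  rc_ann <- coding_annotation(rc_tx, c(ctgA = rc_seq))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc_var <- data.frame(chrom = "ctgA", pos = glen + 1 - fx$variants$pos,
                       ref = comp[fx$variants$ref],
                       alt = comp[fx$variants$alt])
  a <- classify_effect(fx$variants, fx$annotation)
  b <- classify_effect(rc_var, rc_ann)
  expect_equal(table(a$category), table(b$category))
})

test_that("GFF3 + FASTA files round-trip into an equivalent annotation", {
  fx <- make_cds_fixture(n_genes = 4, seed = 54)
  dir <- tempfile()
  write_cds_fixture(fx, dir)
  ann <- read_coding_annotation(file.path(dir, "fixture.gff3"),
                                file.path(dir, "fixture.fa"))
  eff <- classify_effect(fx$variants, ann)
  expect_equal(eff$category, fx$truth$categories)
})

test_that("load summary counts carried variants and splits zygosity", {
  fx <- make_cds_fixture(n_genes = 6, n_variants = 120, seed = 55)
  nv <- nrow(fx$variants)
  set.seed(55)
  gt <- matrix(sample(c(0L, 1L, 2L, NA), nv * 5, replace = TRUE,
                      prob = c(0.4, 0.3, 0.2, 0.1)), nv, 5)
  gm <- genotype_matrix(fx$variants$chrom, fx$variants$pos,
                        fx$variants$ref, fx$variants$alt, gt,
                        sprintf("w%d", 1:5))
  eff <- classify_effect(fx$variants, fx$annotation)
  ls <- load_summary(eff, gm)
  for (i in 1:5) {
    carried <- !is.na(gt[, i]) & gt[, i] > 0
    expect_equal(ls$n_total[i], sum(carried))
    expect_equal(ls$n_lof[i],
                 sum(carried & eff$category == "lof"))
    expect_equal(ls$n_lof[i], ls$n_lof_het[i] + ls$n_lof_hom[i])
    expect_equal(ls$load[i],
                 if (ls$n_total[i] > 0) ls$n_lof[i] / ls$n_total[i] else 0)
  }
  # an individual with two LoF among 10,000 variants has load 2e-4
  expect_equal(2 / 10000, 2e-4)
  # carrier of nothing
  gm0 <- gm
  gm0$gt[, 1] <- 0L
  ls0 <- load_summary(eff, gm0)
  expect_equal(ls0$load[1], 0)
  expect_true(ls0$no_variants[1])
})

test_that("category proportions ANOVA: identical cohorts give p ~ 1", {
  s <- data.frame(individual = sprintf("i%d", 1:8),
                  n_total = 100, n_syn = 30, n_mis = 20, n_lof = 2,
                  n_lof_het = 1, n_lof_hom = 1, load = 0.02,
                  no_variants = FALSE,
                  p_syn = 0.3, p_mis = 0.2, p_lof = 0.02)
  res <- category_proportions(s, rep(c("a", "b"), each = 4))
  expect_true(all(res$anova$p == 1))
  expect_error(category_proportions(s, c(rep("a", 7), "b")), "two members")
})
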