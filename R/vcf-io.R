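#' Read a VCF file into a genotype matrix
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) and converts diploid GT fields to
#' genotype codes: hom-ref 0, het 1, hom-alt 2, "./." missing. Multiallelic
#' records are allowed; any heterozygous combination maps to 1 and any
#' homozygous non-reference genotype to 2.
#'
#' @param path VCF file (plain or gzipped).
#' @param keep_monomorphic keep records whose ALT is "." (needed for
#'   per-individual analyses such as heterozygosity and ROH). Default FALSE.
#' @return a \code{\link{genotype_matrix}} with per-call depths when the VCF
#'   carries DP.
#' @export
read_vcf <- function(path, keep_monomorphic = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (nrow(fix) == 0) stop("VCF contains no records: ", path)
  if (!"FORMAT" %in% colnames(v@gt))
    stop("VCF has no genotype (FORMAT/GT) columns: ", path)
  if (!any(grepl("(^|:)GT(:|$)", v@gt[, "FORMAT"])))
    stop("no GT field found in FORMAT: ", path)
  gt_chr <- vcfR::extract.gt(v, element = "GT")
  alt <- fix[, "ALT"]
  alt[is.na(alt)] <- "."
  keep <- rep(TRUE, nrow(fix))
  if (!keep_monomorphic) keep <- alt != "."
  code <- gt_to_code(gt_chr)
  dp <- NULL
  if (any(grepl("DP", v@gt[, "FORMAT"], fixed = TRUE))) {
    dp <- suppressWarnings(
      apply(vcfR::extract.gt(v, element = "DP"), 2, as.numeric))
    dp <- matrix(dp, nrow = nrow(gt_chr))
  }
  genotype_matrix(fix[keep, "CHROM"], as.integer(fix[keep, "POS"]),
                  fix[keep, "REF"], alt[keep],
                  code[keep, , drop = FALSE],
                  colnames(gt_chr),
                  dp = if (is.null(dp)) NULL else dp[keep, , drop = FALSE])
}

# "0/0"-style GT strings -> integer codes; errors on non-diploid calls.
gt_to_code <- function(gt_chr) {
  gt_chr <- as.matrix(gt_chr)
  u <- unique(as.vector(gt_chr))
  u <- u[!is.na(u)]
  map <- vapply(u, function(s) {
    al <- strsplit(s, "[/|]")[[1]]
    if (length(al) != 2)
      stop("non-diploid genotype '", s, "' (ploidy ", length(al), ")")
    if (any(al == ".")) return(NA_integer_)
    a <- suppressWarnings(as.integer(al))
    if (any(is.na(a))) stop("malformed GT field '", s, "'")
    if (a[1] != a[2]) 1L else if (a[1] == 0L) 0L else 2L
  }, integer(1))
  out <- matrix(map[match(as.vector(gt_chr), u)],
                nrow = nrow(gt_chr), ncol = ncol(gt_chr))
  out
}

#' Write a genotype matrix as a minimal VCF 4.2 file
#'
#' Emits CHROM/POS/REF/ALT plus GT (and DP when depths are present).
#' \code{read_vcf(write_vcf(gm), keep_monomorphic = TRUE)} round-trips the
#' data model exactly.
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               if (!is.null(gm$dp))
                 '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$samples), collapse = "\t")), con)
  if (n_sites(gm) == 0) return(invisible(path))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gm$gt + 1L],
                   nrow = n_sites(gm))
  gt_str[is.na(gm$gt)] <- "./."
  fmt <- "GT"
  if (!is.null(gm$dp)) {
    fmt <- "GT:DP"
    dp_str <- matrix(as.character(gm$dp), nrow = n_sites(gm))
    dp_str[is.na(gm$dp)] <- "."
    gt_str <- matrix(paste(gt_str, dp_str, sep = ":"), nrow = n_sites(gm))
  }
  body <- paste(gm$chrom, gm$pos, ".", gm$ref, gm$alt, ".", "PASS", ".",
                fmt, sep = "\t")
  body <- paste(body, apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}
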