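#' Write a genotype matrix as a minimal VCF 4.2
#'
#' Emits CHROM, POS, ID, REF, ALT and a GT-only FORMAT column per sample.
#' Dosage 0 becomes `0/0`, 1 becomes `0/1`, 2 becomes `1/1` and missing
#' becomes `./.`.
#'
#' @param G A `genotype_matrix`.
#' @param path Output path (plain text, uncompressed).
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  gt_code <- c("0/0", "0/1", "1/1")
  n <- nrow(G$dosages); m <- ncol(G$dosages)
  gt <- matrix("./.", m, n)
  d <- t(G$dosages)                      # m x n
  ok <- !is.na(d)
  gt[ok] <- gt_code[d[ok] + 1L]
  body <- cbind(G$map$chrom, G$map$pos, G$map$snp_id, G$map$ref, G$map$alt,
                ".", ".", ".", "GT", gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", G$sample_ids), collapse = "\t")), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a GT-only VCF into a genotype matrix
#'
#' Parses a biallelic-SNP VCF via \pkg{vcfR} and converts GT calls to dosages
#' (count of ALT alleles; `./.` becomes `NA`). Multiallelic records are
#' rejected.
#'
#' @param path Path to a VCF file.
#' @param pop_labels Optional integer population label per sample.
#' @return A `genotype_matrix`.
#' @export
read_vcf <- function(path, pop_labels = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE)))
    stop("only biallelic SNPs are supported")
  gt <- vcfR::extract.gt(v, element = "GT")
  ## dosage = number of ALT alleles; tolerate phased separators
  dos <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt))
  codes <- gsub("|", "/", gt, fixed = TRUE)
  lookup <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  dos[] <- lookup[t(codes)]
  genotype_matrix(dos,
                  chrom = as.integer(fix[, "CHROM"]),
                  pos = as.integer(fix[, "POS"]),
                  snp_ids = fix[, "ID"],
                  sample_ids = colnames(gt),
                  ref = fix[, "REF"], alt = fix[, "ALT"],
                  pop_labels = pop_labels)
}

#' Write / read a phenotype table TSV
#'
#' @param pheno A `phenotype_table` data frame.
#' @param path File path.
#' @return `write_phenotypes` invisibly returns `path`; `read_phenotypes`
#'   returns a `phenotype_table`.
#' @export
write_phenotypes <- function(pheno, path) {
  write_tsv(as.data.frame(pheno), path)
}

#' Write a per-image score table as TSV
#'
#' @param scores A `score_table` from [score_images()].
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_scores <- function(scores, path) {
  write_tsv(as.data.frame(scores), path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("phenotype_table", "data.frame")
  df
}
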