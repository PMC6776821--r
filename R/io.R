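# Readers/writers for the cohort file formats: pedigree/phenotype TSV,
# GWAS summary-statistics TSV, and VCF v4.2 genotypes (DS preferred, GT
# fallback).  TSV dialect: UTF-8, tab-separated, header row, "NA" missing.

#' Write / read a pedigree-phenotype table
#'
#' Tab-separated, header row, `NA` for missing; round-trips losslessly.
#'
#' @param ped a pedigree/phenotype `data.frame`.
#' @param path file path.
#' @return `read_pedigree` returns a `pedigree_table` data.frame.
#' @export
write_pedigree <- function(ped, path) {
  data.table::fwrite(as.data.frame(ped), path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  ped <- as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA",
                                         colClasses = NULL))
  class(ped) <- c("pedigree_table", "data.frame")
  ped
}

#' Write / read GWAS summary statistics
#'
#' Columns: `snp`, `chr`, `pos`, `a1` (effect allele), `a2`, `beta`, `se`,
#' `p`, `freq` (a1 frequency), `info`.
#'
#' @param ss summary-statistics `data.frame`.
#' @param path file path.
#' @export
write_sumstats <- function(ss, path) {
  data.table::fwrite(ss, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
}

#' Write genotype dosages as VCF v4.2
#'
#' Emits a minimal VCF with `GT` (hard calls from rounded dosage) and `DS`
#' fields; `a1` is written as the ALT allele so that ALT dosage equals the
#' stored a1 dosage.
#'
#' @param geno list with `geno` (n x m a1-dosage matrix) and `map`
#'   (data.frame `id`, `chr`, `pos`, `a1`, `a2`).
#' @param path output path.
#' @param sample_ids optional sample names (default `S1..Sn`).
#' @export
write_vcf <- function(geno, path, sample_ids = NULL) {
  D <- geno$geno; map <- geno$map
  n <- nrow(D); m <- ncol(D)
  if (m != nrow(map)) stopf("map/genotype dimension mismatch")
  if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_len(n))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of ALT allele\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sample_ids), collapse = "\t")), con)
  gt_of <- function(d) c("0/0", "0/1", "1/1")[pmin(pmax(round(d), 0), 2) + 1L]
  for (j in seq_len(m)) {
    d <- D[, j]
    fields <- ifelse(is.na(d), "./.:.",
                     paste0(gt_of(d), ":", formatC(d, format = "g")))
    writeLines(paste(c(map$chr[j], map$pos[j], map$id[j], map$a2[j],
                       map$a1[j], ".", "PASS", ".", "GT:DS", fields),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotype dosages from a VCF
#'
#' Uses the `DS` FORMAT field when present, otherwise counts ALT alleles
#' in `GT`.  Returns the same list structure [write_vcf()] consumes, with
#' the ALT allele stored as `a1` (the dosage-counted allele).
#'
#' @param path VCF path.
#' @return list with `geno` (n x m dosage matrix) and `map`.
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stopf("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  map <- data.frame(id = fix$ID, chr = fix$CHROM, pos = as.integer(fix$POS),
                    a1 = fix$ALT, a2 = fix$REF, stringsAsFactors = FALSE)
  fmt <- unique(v@gt[, "FORMAT"])
  if (any(grepl("DS", fmt))) {
    ds <- vcfR::extract.gt(v, element = "DS")
    D <- t(apply(ds, 1, as.numeric))
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    D <- t(apply(gt, 1, function(x) {
      vapply(strsplit(x, "[/|]"), function(a)
        sum(as.integer(a)), numeric(1))
    }))
  }
  D <- t(D)                               # samples x variants
  dimnames(D) <- NULL
  list(geno = D, map = map)
}
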