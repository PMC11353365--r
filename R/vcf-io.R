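# Plain-text VCF output for simulated cohorts. Only writing lives here;
# all VCF parsing goes through vcfR.

#' Contig lengths declared in a VCF header
#'
#' @param path Path to a plain or gzipped VCF.
#' @return Named numeric vector of `##contig` lengths; empty when the
#'   header declares none.
#' @export
vcf_contig_lengths <- function(path) {
  con <- gzfile(path, "r")
  on.exit(close(con))
  out <- numeric(0)
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || !startsWith(line, "##")) break
    m <- regmatches(line,
                    regexec("^##contig=<ID=([^,>]+),.*length=([0-9]+)", line))[[1]]
    if (length(m) == 3) out[m[2]] <- as.numeric(m[3])
  }
  out
}

vcf_header <- function(chrom, chrom_length, samples) {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chrom, as.integer(chrom_length)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

write_vcf_body <- function(path, chrom, pos, ref, alt, gt, samples,
                           chrom_length) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(vcf_header(chrom[1], chrom_length, samples), con)
  if (length(pos) > 0) {
    left <- paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT",
                  sep = "\t")
    writeLines(paste(left, apply(gt, 1, paste, collapse = "\t"),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Write a reference cohort as an unphased VCF
#'
#' @param cohort A [reference_cohort()].
#' @param path Output path.
#' @param chrom_length Chromosome length recorded in the contig header.
#' @return `path`, invisibly.
#' @export
write_reference_vcf <- function(cohort, path,
                                chrom_length = max(cohort$pos)) {
  stopifnot(inherits(cohort, "reference_cohort"))
  samples <- colnames(cohort$geno) %||%
    sprintf("REF%04d", seq_along(cohort$pop))
  gt <- matrix(c("0/0", "0/1", "1/1")[cohort$geno + 1L],
               nrow = nrow(cohort$geno))
  gt[is.na(cohort$geno)] <- "./."
  write_vcf_body(path, cohort$chrom, cohort$pos, cohort$ref, cohort$alt,
                 gt, samples, chrom_length)
}

#' Write admixed haplotypes as a phased VCF at panel sites
#'
#' Emits one record per panel SNP with `|`-separated genotypes assembled
#' from the two haplotype rows of each sample. For designed panels the
#' specific allele is the ALT allele over a fixed `A` REF.
#'
#' @param presence A [presence_matrix()].
#' @param path Output path.
#' @param chrom_length Chromosome length recorded in the contig header.
#' @return `path`, invisibly.
#' @export
write_admixed_vcf <- function(presence, path,
                              chrom_length = max(presence$panel$pos)) {
  stopifnot(inherits(presence, "presence_matrix"))
  panel <- presence$panel
  h1 <- which(presence$hap == 1L)
  h2 <- which(presence$hap == 2L)
  stopifnot(length(h1) == length(h2),
            all(presence$sample[h1] == presence$sample[h2]))
  alt <- panel$specific_allele
  ref <- ifelse(alt == "A", "C", "A")
  # X is haplotypes x SNPs; VCF rows are SNPs
  g1 <- t(presence$X[h1, , drop = FALSE])
  g2 <- t(presence$X[h2, , drop = FALSE])
  gt <- matrix(paste(g1, g2, sep = "|"), nrow = nrow(panel))
  write_vcf_body(path, panel$chrom, panel$pos, ref, alt, gt,
                 presence$sample[h1], chrom_length)
}
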