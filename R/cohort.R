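#' Reference cohort of genotyped individuals
#'
#' Bundles diallelic genotypes of the reference populations used to screen
#' population-specific SNPs. Genotypes are stored as minor-allele-agnostic
#' ALT-allele copy counts (0, 1, 2; `NA` for missing), one row per SNP and
#' one column per sample, and every sample is assigned to exactly one
#' reference population.
#'
#' @param chrom Character vector of chromosome ids, one per SNP.
#' @param pos Integer vector of 1-based positions (bp), one per SNP.
#' @param ref,alt Character vectors of reference and alternate alleles.
#' @param geno Numeric matrix of ALT-allele copy counts, SNPs x samples.
#' @param pop Factor (or character) of population labels, one per sample.
#'   At least two populations are required and every declared population
#'   must have at least one sample.
#'
#' @return An object of class `reference_cohort`: a list with elements
#'   `chrom`, `pos`, `ref`, `alt`, `geno` and `pop`, sorted by
#'   (chromosome, position).
#' @seealso [read_reference_vcf()], [screen_specific_snps()]
#' @export
reference_cohort <- function(chrom, pos, ref, alt, geno, pop) {
  geno <- as.matrix(geno)
  pop <- as.factor(pop)
  m <- length(pos)
  if (length(chrom) != m || length(ref) != m || length(alt) != m ||
      nrow(geno) != m) {
    stop("chrom, pos, ref, alt and geno rows must all have one entry per SNP")
  }
  if (ncol(geno) != length(pop)) {
    stop("geno must have one column per sample in `pop`")
  }
  if (nlevels(pop) < 2) {
    stop("at least two reference populations are required")
  }
  sizes <- tabulate(pop, nlevels(pop))
  if (any(sizes == 0)) {
    stop("reference population(s) with zero samples: ",
         paste(levels(pop)[sizes == 0], collapse = ", "))
  }
  bad <- !is.na(geno) & !(geno %in% 0:2)
  if (any(bad)) stop("genotype copy counts must be 0, 1, 2 or NA")
  ord <- order(chrom, pos)
  structure(
    list(chrom = as.character(chrom)[ord], pos = as.integer(pos)[ord],
         ref = as.character(ref)[ord], alt = as.character(alt)[ord],
         geno = geno[ord, , drop = FALSE], pop = pop),
    class = "reference_cohort"
  )
}

#' @export
print.reference_cohort <- function(x, ...) {
  cat("reference_cohort:", length(x$pos), "SNPs,", length(x$pop),
      "samples in", nlevels(x$pop), "populations\n")
  sizes <- table(x$pop)
  cat(paste0("  ", names(sizes), ": ", as.integer(sizes), collapse = "\n"),
      "\n")
  invisible(x)
}

#' Read a reference cohort from a VCF and a population map
#'
#' Phasing is irrelevant here: only ALT-allele copy counts are used. Samples
#' in the VCF without a population assignment are dropped.
#'
#' @param path Path to a (optionally gzipped) multi-sample VCF.
#' @param populations Either a named character vector mapping sample id to
#'   population label, or the path of a two-column tab-separated file
#'   (sample id, population label, no header).
#' @return A [reference_cohort()].
#' @export
read_reference_vcf <- function(path, populations) {
  if (is.character(populations) && length(populations) == 1 &&
      is.null(names(populations)) && file.exists(populations)) {
    map <- read.table(populations, header = FALSE, sep = "\t",
                      col.names = c("sample", "population"),
                      colClasses = "character")
    populations <- setNames(map$population, map$sample)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as_fix_matrix(vcfR::getFIX(v))
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- colnames(gt) %in% names(populations)
  if (!any(keep)) stop("no VCF sample has a population assignment")
  gt <- gt[, keep, drop = FALSE]
  geno <- alt_copy_counts(gt)
  reference_cohort(chrom = fix[, "CHROM"],
                   pos = as.integer(fix[, "POS"]),
                   ref = fix[, "REF"], alt = fix[, "ALT"],
                   geno = geno,
                   pop = populations[colnames(gt)])
}

# getFIX drops dimensions for single-record VCFs
as_fix_matrix <- function(fix) {
  if (is.null(dim(fix))) {
    matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  } else {
    fix
  }
}

# ALT copies per diploid genotype string ("0/1", "1|1", ...); NA when any
# allele is missing. Only 0/1 allele codes occur at diallelic records.
alt_copy_counts <- function(gt) {
  n1 <- nchar(gt) - nchar(gsub("1", "", gt, fixed = TRUE))
  n1[is.na(gt) | grepl(".", gt, fixed = TRUE)] <- NA
  matrix(as.integer(n1), nrow = nrow(gt), dimnames = dimnames(gt))
}
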