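#' Per-haplotype presence of population-specific alleles
#'
#' A presence matrix encodes, for each haploid genome and each panel SNP,
#' whether the SNP's population-specific allele is carried (1) or not (0).
#' Rows are haplotypes (two per diploid sample, interleaved), columns are
#' panel SNPs in panel order.
#'
#' @param X Binary integer matrix, haplotypes x panel SNPs.
#' @param sample Character vector of sample ids, one per row of `X`.
#' @param hap Integer vector of haplotype indices (1 or 2), one per row.
#' @param panel The [snp_panel()] the columns are aligned to.
#' @return An object of class `presence_matrix`.
#' @export
presence_matrix <- function(X, sample, hap, panel) {
  X <- as.matrix(X)
  stopifnot(inherits(panel, "snp_panel"))
  if (ncol(X) != nrow(panel)) {
    stop("presence matrix must have one column per panel SNP")
  }
  if (nrow(X) != length(sample) || nrow(X) != length(hap)) {
    stop("one sample id and haplotype index per presence-matrix row")
  }
  if (!all(X %in% 0:1)) stop("presence values must be 0 or 1")
  if (!all(hap %in% 1:2)) stop("haplotype indices must be 1 or 2")
  storage.mode(X) <- "integer"
  rownames(X) <- hap_key(sample, hap)
  structure(list(X = X, sample = as.character(sample),
                 hap = as.integer(hap), panel = panel),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("presence_matrix:", nrow(x$X), "haplotypes x", ncol(x$X),
      "panel SNPs;", length(unique(x$sample)), "samples\n")
  invisible(x)
}

#' Load phased haplotypes from a VCF against a SNP panel
#'
#' Reads a phased multi-sample VCF and encodes, per haplotype, the presence
#' of each panel SNP's population-specific allele. Panel SNPs are matched
#' by (chromosome, position); at matched sites the specific allele must be
#' the VCF REF or ALT allele. Panel SNPs absent from the VCF yield all-zero
#' columns with one summary warning, as do missing genotypes at matched
#' sites. Unphased genotypes at panel sites are an error: per-haplotype
#' windows require phase.
#'
#' @param path Path to a phased (optionally gzipped) VCF.
#' @param panel A [snp_panel()].
#' @return A [presence_matrix()] aligned to `panel`.
#' @export
load_phased_haplotypes <- function(path, panel) {
  stopifnot(inherits(panel, "snp_panel"))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as_fix_matrix(vcfR::getFIX(v))
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  n_s <- length(samples)
  H <- 2L * n_s
  M <- nrow(panel)
  X <- matrix(0L, H, M)

  vkey <- paste(fix[, "CHROM"], fix[, "POS"], sep = ":")
  pkey <- paste(panel$chrom, panel$pos, sep = ":")
  hit <- match(pkey, vkey)
  if (anyNA(hit)) {
    warning(sum(is.na(hit)),
            " panel SNP(s) absent from the VCF; treated as allele-absent")
  }
  miss_gt <- 0L
  for (j in which(!is.na(hit))) {
    r <- hit[j]
    ref <- fix[r, "REF"]; alt <- fix[r, "ALT"]
    a <- panel$specific_allele[j]
    if (grepl(",", alt, fixed = TRUE) || !(a %in% c(ref, alt))) {
      stop("allele mismatch between VCF and panel at ", pkey[j],
           " (panel allele ", a, ", VCF ", ref, "/", alt, ")")
    }
    g <- gt[r, ]
    has_na <- is.na(g) | grepl(".", g, fixed = TRUE)
    if (any(has_na)) {
      miss_gt <- miss_gt + sum(has_na)
      g[has_na] <- "0|0"  # absence, counted in the warning below
    }
    if (any(grepl("/", g, fixed = TRUE))) {
      bad <- samples[grepl("/", g, fixed = TRUE)][1]
      stop("unphased genotype at panel site ", pkey[j], " (sample ", bad,
           "); phased input is required")
    }
    code <- if (a == alt) "1" else "0"
    X[seq(1L, H, by = 2L), j] <- as.integer(substr(g, 1, 1) == code)
    X[seq(2L, H, by = 2L), j] <- as.integer(substr(g, 3, 3) == code)
  }
  if (miss_gt > 0) {
    warning(miss_gt,
            " missing genotype(s) at panel sites treated as allele-absent")
  }
  presence_matrix(X, sample = rep(samples, each = 2L),
                  hap = rep(1:2, times = n_s), panel = panel)
}

#' Re-align a presence matrix to another panel
#'
#' Used when inference runs on a screened panel while haplotypes were
#' encoded against the designed (or a larger) panel. Columns are matched by
#' (chromosome, position); panel SNPs without a counterpart become all-zero
#' columns with a warning.
#'
#' @param presence A [presence_matrix()].
#' @param panel Target [snp_panel()].
#' @return A [presence_matrix()] aligned to `panel`.
#' @export
align_presence <- function(presence, panel) {
  stopifnot(inherits(presence, "presence_matrix"),
            inherits(panel, "snp_panel"))
  src <- paste(presence$panel$chrom, presence$panel$pos, sep = ":")
  dst <- paste(panel$chrom, panel$pos, sep = ":")
  hit <- match(dst, src)
  if (anyNA(hit)) {
    warning(sum(is.na(hit)),
            " target panel SNP(s) missing from the presence matrix; ",
            "treated as allele-absent")
  }
  X <- matrix(0L, nrow(presence$X), length(dst))
  ok <- !is.na(hit)
  X[, ok] <- presence$X[, hit[ok], drop = FALSE]
  presence_matrix(X, presence$sample, presence$hap, panel)
}
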