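#' Construct a panel of population-specific SNPs
#'
#' A panel row records one SNP whose minor allele is confined to a single
#' reference population: its coordinates, the specific allele, the
#' population it is specific to, the allele's minor-allele frequency (MAF)
#' in that population and its observed copy count there. The panel carries
#' the complete list of reference population labels as an attribute, so
#' populations with an empty index set are still represented.
#'
#' @param chrom,pos SNP coordinates (1-based positions, sorted within the
#'   constructor).
#' @param specific_pop Population each SNP is specific to.
#' @param specific_allele The population-specific (minor) allele.
#' @param maf MAF of the specific allele in its population; in (0, 0.5].
#' @param count Copies of the specific allele observed in its population.
#' @param populations Character vector of all K reference population labels.
#' @return A `data.frame` of class `snp_panel`, sorted by (chrom, pos),
#'   with attribute `populations`.
#' @export
snp_panel <- function(chrom, pos, specific_pop, specific_allele, maf, count,
                      populations) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   specific_pop = as.character(specific_pop),
                   specific_allele = as.character(specific_allele),
                   maf = as.numeric(maf), count = as.integer(count),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  validate_panel(df, populations)
  structure(df, populations = as.character(populations),
            class = c("snp_panel", "data.frame"))
}

validate_panel <- function(df, populations) {
  if (length(populations) < 2) {
    stop("a panel needs at least two reference populations")
  }
  if (anyDuplicated(populations)) stop("duplicated population labels")
  if (nrow(df) == 0) return(invisible(df))
  if (!all(df$specific_pop %in% populations)) {
    stop("specific_pop outside the declared population labels")
  }
  if (anyDuplicated(df[c("chrom", "pos")])) {
    stop("duplicated (chrom, pos) in panel")
  }
  if (any(df$maf <= 0) || any(df$maf > 0.5)) {
    stop("panel MAFs must lie in (0, 0.5]")
  }
  if (any(df$count < 0)) stop("negative allele count in panel")
  invisible(df)
}

#' Reference population labels of a panel
#' @param panel A [snp_panel()].
#' @return Character vector of the K population labels.
#' @export
populations <- function(panel) attr(panel, "populations")

#' Per-population panel sizes M_k
#' @param panel A [snp_panel()].
#' @return Named integer vector over all K populations (zeros included).
#' @export
panel_sizes <- function(panel) {
  pops <- populations(panel)
  sizes <- table(factor(panel$specific_pop, levels = pops))
  setNames(as.integer(sizes), pops)
}

#' Screen a reference cohort for population-specific SNPs
#'
#' A SNP enters the panel when one of its two alleles (REF or ALT) has at
#' least `min_copies` copies in a single reference population, zero copies
#' in every other reference population, and is the minor allele within that
#' population (frequency at most 0.5; exactly 0.5 is allowed). SNPs with
#' any missing genotype are dropped first; non-diallelic records are
#' skipped with a warning. The MAF is the copy count divided by twice the
#' population's diploid sample size.
#'
#' @param cohort A [reference_cohort()].
#' @param min_copies Minimum copies of the specific allele in its
#'   population (default 5).
#' @return A [snp_panel()] over the cohort's population labels.
#' @export
screen_specific_snps <- function(cohort, min_copies = 5) {
  stopifnot(inherits(cohort, "reference_cohort"))
  if (min_copies < 1) stop("min_copies must be a positive integer")
  pop <- cohort$pop
  K <- nlevels(pop)
  n_k <- tabulate(pop, K)            # diploid sample sizes
  copies_k <- 2L * n_k

  keep <- rowSums(is.na(cohort$geno)) == 0
  dial <- !grepl(",", cohort$alt, fixed = TRUE) &
    nchar(cohort$ref) == 1 & nchar(cohort$alt) == 1
  if (any(!dial)) {
    warning(sum(!dial), " non-diallelic SNP record(s) skipped")
  }
  keep <- keep & dial
  idx <- which(keep)
  if (length(idx) == 0) {
    return(snp_panel(character(), integer(), character(), character(),
                     numeric(), integer(), populations = levels(pop)))
  }

  geno <- cohort$geno[idx, , drop = FALSE]
  ac <- t(rowsum(t(geno), pop))      # SNPs x K ALT copies
  rc <- matrix(copies_k, nrow(ac), K, byrow = TRUE) - ac

  pick <- function(cnt, allele) {
    nz <- cnt > 0
    sole <- rowSums(nz) == 1L
    k <- max.col(cnt, ties.method = "first")
    c_k <- cnt[cbind(seq_len(nrow(cnt)), k)]
    # minor within its population: frequency c_k / copies_k <= 0.5
    ok <- sole & c_k >= min_copies & c_k <= n_k[k]
    data.frame(i = which(ok), k = k[ok], count = c_k[ok],
               allele = allele[ok], stringsAsFactors = FALSE)
  }
  hits <- rbind(pick(ac, cohort$alt[idx]), pick(rc, cohort$ref[idx]))
  if (anyDuplicated(hits$i)) {
    # cannot happen under the minor-allele rule; guard against regressions
    stop("both alleles of one SNP qualified as population-specific")
  }
  snp_panel(chrom = cohort$chrom[idx][hits$i],
            pos = cohort$pos[idx][hits$i],
            specific_pop = levels(pop)[hits$k],
            specific_allele = hits$allele,
            maf = hits$count / copies_k[hits$k],
            count = hits$count,
            populations = levels(pop))
}

#' Write / read a panel of population-specific SNPs
#'
#' Tab-separated text with a single `#populations` meta line (all K
#' reference population labels, comma-separated) followed by a header and
#' one row per SNP: `chrom, pos, specific_pop, specific_allele, maf,
#' count`. Positions are 1-based to match VCF. MAFs are written at full
#' precision so the round trip is exact.
#'
#' @param panel A [snp_panel()].
#' @param path Output (input) file path.
#' @return `write_panel` returns `path` invisibly; `read_panel` returns a
#'   [snp_panel()].
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "snp_panel"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#populations\t",
                    paste(populations(panel), collapse = ",")), con)
  writeLines(paste(c("chrom", "pos", "specific_pop", "specific_allele",
                     "maf", "count"), collapse = "\t"), con)
  if (nrow(panel) > 0) {
    writeLines(paste(panel$chrom, panel$pos, panel$specific_pop,
                     panel$specific_allele, sprintf("%.17g", panel$maf),
                     panel$count, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2 || !startsWith(lines[1], "#populations\t")) {
    stop("panel file must start with a '#populations' meta line: ", path)
  }
  pops <- strsplit(sub("^#populations\t", "", lines[1]), ",", fixed = TRUE)[[1]]
  header <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  want <- c("chrom", "pos", "specific_pop", "specific_allele", "maf", "count")
  if (!identical(header, want)) stop("unexpected panel header: ", path)
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    return(snp_panel(character(), integer(), character(), character(),
                     numeric(), integer(), populations = pops))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6)) {
    stop("malformed panel line ", which(nf != 6)[1] + 2L, " in ", path)
  }
  m <- matrix(unlist(fields), ncol = 6, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  maf <- suppressWarnings(as.numeric(m[, 5]))
  count <- suppressWarnings(as.integer(m[, 6]))
  bad <- which(is.na(pos) | is.na(maf) | is.na(count))
  if (length(bad)) {
    stop("malformed panel line ", bad[1] + 2L, " in ", path)
  }
  o <- order(m[, 1], pos)
  if (is.unsorted(o, strictly = TRUE)) {
    stop("panel file not sorted by (chrom, pos): ", path)
  }
  if (anyDuplicated(data.frame(m[, 1], pos))) {
    dup <- which(duplicated(data.frame(m[, 1], pos)))[1]
    stop("duplicated (chrom, pos) at panel line ", dup + 2L, " in ", path)
  }
  snp_panel(chrom = m[, 1], pos = pos, specific_pop = m[, 3],
            specific_allele = m[, 4], maf = maf, count = count,
            populations = pops)
}
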