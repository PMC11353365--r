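#' Local ancestry information vector for one window
#'
#' The LAIV entry for population k is a moment estimator of the local
#' ancestral proportion: the number of population-k-specific alleles
#' observed in the window divided by the sum of their reference MAFs. When
#' the window holds no SNP specific to k the entry is 0 by convention
#' ("no evidence" must never win a call). Entries are nonnegative and may
#' exceed 1; the estimator uses only counts and MAF sums, so it does not
#' rest on linkage equilibrium between the panel SNPs.
#'
#' @param x Binary vector: presence of each window SNP's specific allele on
#'   one haplotype, aligned with `panel`.
#' @param panel A [snp_panel()] slice holding exactly the window's SNPs.
#' @return An object of class `laiv`: list with `phat`, `count` and
#'   `denom`, each a named length-K vector over the panel's populations.
#' @export
compute_laiv <- function(x, panel) {
  stopifnot(inherits(panel, "snp_panel"))
  if (length(x) != nrow(panel)) {
    stop("presence vector and panel slice are misaligned")
  }
  pops <- populations(panel)
  grp <- factor(panel$specific_pop, levels = pops)
  count <- vapply(split(as.numeric(x), grp), sum, 0)
  denom <- vapply(split(panel$maf, grp), sum, 0)
  phat <- ifelse(denom > 0, count / denom, 0)
  structure(list(phat = phat, count = count, denom = denom), class = "laiv")
}

#' Sliding-window LAIVs for every haplotype at every panel SNP
#'
#' For every panel SNP a window of `window_size` bp is centered at the
#' locus: positions within `floor(window_size/2)` bp on either side,
#' inclusive, truncated at chromosome ends. The LAIV of each haplotype is
#' computed in each window. Windows never cross chromosomes. The
#' implementation uses per-population cumulative sums, so total work is
#' linear in the number of panel SNPs; it is tied to the naive per-window
#' recomputation in the test suite.
#'
#' @param presence A [presence_matrix()].
#' @param window_size Window width in bp (default 2e6).
#' @return An object of class `laiv_track`: list with per-center `chrom`,
#'   `pos`, `lo`, `hi` (window bounds), per-population lists `phat` and
#'   `count` (each K matrices of haplotypes x centers), matrix `denom`
#'   (K x centers), plus `sample`, `hap` and `populations`.
#' @export
sliding_laivs <- function(presence, window_size = 2e6) {
  stopifnot(inherits(presence, "presence_matrix"), window_size >= 1)
  panel <- presence$panel
  pops <- populations(panel)
  K <- length(pops)
  H <- nrow(presence$X)
  half <- floor(window_size / 2)

  chroms <- unique(panel$chrom)
  phat <- rep(list(NULL), K); count <- rep(list(NULL), K)
  denom <- NULL; lo_all <- hi_all <- integer(0)
  for (cc in chroms) {
    cols <- which(panel$chrom == cc)
    p <- panel$pos[cols]
    lo <- findInterval(p - half - 1L, p) + 1L   # first index >= p - half
    hi <- findInterval(p + half, p)             # last  index <= p + half
    Xc <- presence$X[, cols, drop = FALSE]
    denom_block <- matrix(0, K, length(cols))
    for (k in seq_len(K)) {
      mask <- panel$specific_pop[cols] == pops[k]
      Xk <- Xc
      if (any(!mask)) Xk[, !mask] <- 0L
      S <- if (length(cols) == 1L) {
        matrix(as.numeric(Xk), nrow = H)
      } else {
        t(apply(Xk, 1, cumsum))
      }
      S0 <- cbind(0, S)
      cnt <- S0[, hi + 1L, drop = FALSE] - S0[, lo, drop = FALSE]
      d0 <- c(0, cumsum(panel$maf[cols] * mask))
      den <- d0[hi + 1L] - d0[lo]
      den[abs(den) < 1e-12] <- 0
      ph <- sweep(cnt, 2, den, "/")
      ph[, den == 0] <- 0
      dimnames(cnt) <- dimnames(ph) <- NULL
      phat[[k]] <- cbind(phat[[k]], ph)
      count[[k]] <- cbind(count[[k]], cnt)
      denom_block[k, ] <- den
    }
    denom <- cbind(denom, denom_block)
    lo_all <- c(lo_all, pmax(p - half, 1L))
    hi_all <- c(hi_all, p + half)
  }
  names(phat) <- names(count) <- pops
  rownames(denom) <- pops
  structure(list(chrom = panel$chrom, pos = panel$pos,
                 lo = lo_all, hi = hi_all,
                 phat = phat, count = count, denom = denom,
                 sample = presence$sample, hap = presence$hap,
                 populations = pops),
            class = "laiv_track")
}

#' @export
print.laiv_track <- function(x, ...) {
  cat("laiv_track:", length(x$pos), "window centers x",
      length(x$sample), "haplotypes;", length(x$populations),
      "populations\n")
  invisible(x)
}

#' Dump a LAIV track as a long-format data frame
#'
#' One row per (haplotype, window center), with `phat_<pop>` and
#' `count_<pop>` columns; useful for inspection and debugging.
#'
#' @param x A `laiv_track`.
#' @param ... Unused.
#' @return A `data.frame`.
#' @export
as.data.frame.laiv_track <- function(x, ...) {
  H <- length(x$sample); M <- length(x$pos)
  out <- data.frame(
    chrom = rep(x$chrom, each = H), pos = rep(x$pos, each = H),
    sample = rep(x$sample, times = M), hap = rep(x$hap, times = M),
    stringsAsFactors = FALSE)
  for (p in x$populations) out[[paste0("phat_", p)]] <- as.vector(x$phat[[p]])
  for (p in x$populations) out[[paste0("count_", p)]] <- as.vector(x$count[[p]])
  out
}
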