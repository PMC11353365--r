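# Independent brute-force oracles and tiny fixture builders. Everything
# here is deliberately written as plain per-element loops so it shares no
# code path with the package internals it checks.

# Build a reference cohort from designed per-population ALT copy counts:
# `alt_copies` is SNPs x K; copies are laid onto samples as homozygotes
# plus at most one heterozygote, which preserves the per-population totals.
cohort_from_alt_counts <- function(alt_copies, n_per_pop,
                                   pops = paste0("P", seq_len(ncol(alt_copies))),
                                   chrom = "1", pos = NULL,
                                   ref = "A", alt = "C") {
  M <- nrow(alt_copies)
  K <- ncol(alt_copies)
  n_per_pop <- rep_len(n_per_pop, K)
  pos <- pos %||% seq_len(M) * 1000L
  geno <- NULL
  for (k in seq_len(K)) {
    blk <- matrix(0L, M, n_per_pop[k])
    for (i in seq_len(M)) {
      cc <- alt_copies[i, k]
      stopifnot(cc <= 2 * n_per_pop[k])
      g <- c(rep(2L, cc %/% 2), rep(1L, cc %% 2))
      if (length(g)) blk[i, seq_along(g)] <- g
    }
    geno <- cbind(geno, blk)
  }
  reference_cohort(chrom = rep(chrom, M), pos = pos,
                   ref = rep_len(ref, M), alt = rep_len(alt, M),
                   geno = geno, pop = rep.int(pops, n_per_pop))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-SNP, per-population, per-allele loop applying the screening rule.
screen_oracle <- function(cohort, min_copies) {
  pops <- levels(cohort$pop)
  K <- length(pops)
  out <- list()
  for (i in seq_along(cohort$pos)) {
    g <- cohort$geno[i, ]
    if (any(is.na(g))) next
    if (grepl(",", cohort$alt[i], fixed = TRUE) ||
        nchar(cohort$ref[i]) != 1 || nchar(cohort$alt[i]) != 1) next
    for (side in c("alt", "ref")) {
      cnt <- numeric(K)
      for (k in seq_len(K)) {
        gk <- g[cohort$pop == pops[k]]
        cnt[k] <- if (side == "alt") sum(gk) else sum(2 - gk)
      }
      nz <- which(cnt > 0)
      if (length(nz) != 1) next
      k <- nz
      nk <- sum(cohort$pop == pops[k])
      if (cnt[k] >= min_copies && cnt[k] <= nk) {
        out[[length(out) + 1]] <- data.frame(
          chrom = cohort$chrom[i], pos = cohort$pos[i],
          specific_pop = pops[k],
          specific_allele = if (side == "alt") cohort$alt[i] else cohort$ref[i],
          maf = cnt[k] / (2 * nk), count = cnt[k],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), pos = integer(),
                      specific_pop = character(),
                      specific_allele = character(),
                      maf = numeric(), count = integer()))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Hand-loop evaluation of the moment estimator on one window.
laiv_oracle <- function(x, specific_pop, maf, pops) {
  phat <- count <- denom <- setNames(numeric(length(pops)), pops)
  for (k in pops) {
    for (m in seq_along(x)) {
      if (specific_pop[m] == k) {
        count[k] <- count[k] + x[m]
        denom[k] <- denom[k] + maf[m]
      }
    }
    phat[k] <- if (denom[k] > 0) count[k] / denom[k] else 0
  }
  list(phat = phat, count = count, denom = denom)
}

# Quick random panel + presence rows for the laiv/caller tests.
rand_panel <- function(M, K, L, pops = paste0("P", seq_len(K))) {
  pos <- sort(sample.int(L, M))
  snp_panel(chrom = "1", pos = pos,
            specific_pop = sample(pops, M, replace = TRUE),
            specific_allele = "C",
            maf = runif(M, 0.05, 0.5),
            count = 5L, populations = pops)
}

rand_presence <- function(panel, H = 4, p = 0.3) {
  X <- matrix(rbinom(H * nrow(panel), 1, p), H)
  presence_matrix(X, sample = paste0("S", rep(seq_len(ceiling(H / 2)),
                                              each = 2)[seq_len(H)]),
                  hap = rep(1:2, length.out = H), panel = panel)
}

# Per-bp brute force for the interval metrics (small extents only).
bp_labels <- function(seg, L) {
  lab <- rep(NA_character_, L)
  for (i in seq_len(nrow(seg))) {
    lab[(seg$start[i] + 1):seg$end[i]] <- seg$label[i]
  }
  lab
}

bp_consistency_oracle <- function(a, b, L, uncalled_as_disagreement = FALSE) {
  la <- bp_labels(a, L)
  lb <- bp_labels(b, L)
  both <- la != "UNCALLED" & lb != "UNCALLED"
  agree <- both & la == lb
  denom <- if (uncalled_as_disagreement) L else sum(both)
  if (denom == 0) NA_real_ else sum(agree) / denom
}

bp_uncalled_oracle <- function(seg, L) {
  sum(bp_labels(seg, L) == "UNCALLED") / L
}

# One-haplotype segment frame from explicit vectors.
seg_frame <- function(start, end, label, sample = "S1", hap = 1L,
                      chrom = "1") {
  n <- length(start)
  data.frame(chrom = rep_len(chrom, n), start = start, end = end,
             sample = rep_len(sample, n),
             haplotype = rep_len(as.integer(hap), n),
             label = label, stringsAsFactors = FALSE)
}
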