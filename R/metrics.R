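#' Pairwise consistency rate between two segment callsets
#'
#' By default the rate is the fraction of base pairs on which the two
#' callsets agree among the base pairs called by both -- uncalled regions
#' of either callset are excluded from numerator and denominator. With
#' `uncalled_as_disagreement = TRUE` the denominator is the full shared
#' extent, so base pairs uncalled by either side count against agreement.
#' Haplotypes are matched by (sample, haplotype index); both callsets must
#' cover the same haplotypes and the same chromosomal extents.
#'
#' @param a,b Segment `data.frame`s tiling the same extents.
#' @param uncalled_as_disagreement See above; default `FALSE`.
#' @return List with `per_haplotype` (data.frame: `agree_bp`,
#'   `both_called_bp`, `uncalled_either_bp`, `rate`) and `mean`, the
#'   haplotype-mean rate (haplotypes with an empty denominator are skipped
#'   from the mean).
#' @export
consistency_rate <- function(a, b, uncalled_as_disagreement = FALSE) {
  check_segment_frame(a)
  check_segment_frame(b)
  ka <- unique(hap_key(a$sample, a$haplotype))
  kb <- unique(hap_key(b$sample, b$haplotype))
  if (!setequal(ka, kb)) {
    stop("the two callsets cover different haplotype sets")
  }
  a_sp <- split(a, hap_key(a$sample, a$haplotype))
  b_sp <- split(b, hap_key(b$sample, b$haplotype))
  per <- vector("list", length(ka))
  for (i in seq_along(ka)) {
    p <- overlay_segments(a_sp[[ka[i]]], b_sp[[ka[i]]])
    len <- p$end - p$start
    both <- p$a != UNCALLED & p$b != UNCALLED
    agree <- both & p$a == p$b
    denom <- if (uncalled_as_disagreement) sum(len) else sum(len[both])
    g <- a_sp[[ka[i]]]
    per[[i]] <- data.frame(
      sample = g$sample[1], haplotype = g$haplotype[1],
      agree_bp = sum(len[agree]), both_called_bp = sum(len[both]),
      uncalled_either_bp = sum(len[!both]),
      rate = if (denom > 0) sum(len[agree]) / denom else NA_real_,
      stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, per)
  list(per_haplotype = per, mean = mean(per$rate, na.rm = TRUE))
}

#' Uncalled rate of a segment callset
#'
#' Fraction of base pairs labelled `"UNCALLED"`, per haplotype and as the
#' haplotype mean. Segments must tile each haplotype's extent without
#' gaps.
#'
#' @param segments A segment `data.frame`.
#' @return List with `per_haplotype` (data.frame with `rate`) and `mean`.
#' @export
uncalled_rate <- function(segments) {
  check_segment_frame(segments)
  sp <- split(segments, hap_key(segments$sample, segments$haplotype))
  per <- vector("list", length(sp))
  for (i in seq_along(sp)) {
    g <- sp[[i]][order(sp[[i]]$start), , drop = FALSE]
    check_tiling(g)
    len <- g$end - g$start
    per[[i]] <- data.frame(
      sample = g$sample[1], haplotype = g$haplotype[1],
      rate = sum(len[g$label == UNCALLED]) / sum(len),
      stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, per)
  list(per_haplotype = per, mean = mean(per$rate))
}
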