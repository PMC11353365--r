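#' Call the ancestry of one locus from its LAIV
#'
#' The winner is the population with the most ancestral information
#' (argmax of the LAIV). The locus stays uncalled when (a) the winning
#' value is below `laiv_min`, (b) the maximum is tied between populations
#' (a deterministic arbitrary winner would fabricate ancestry), or (c) the
#' window contains specific alleles of two or more populations and the
#' winner carries fewer than `allele_min` of them -- the guard against
#' panel misclassification errors. A window where only one population's
#' alleles occur is exempt from the allele-count gate.
#'
#' @param laiv A [compute_laiv()] result.
#' @param laiv_min Minimum winning information value (default 1e-6).
#' @param allele_min Minimum winning allele count when alleles of several
#'   populations share the window (default 2).
#' @return List with `call` (population label or `"UNCALLED"`), `value`
#'   (winning information) and `count` (winning allele count).
#' @export
call_locus <- function(laiv, laiv_min = 1e-6, allele_min = 2) {
  stopifnot(inherits(laiv, "laiv"), laiv_min >= 0, allele_min >= 0)
  mx <- max(laiv$phat)
  w <- which(laiv$phat == mx)
  call <- if (mx < laiv_min || length(w) > 1 ||
              (sum(laiv$count > 0) >= 2 && laiv$count[w] < allele_min)) {
    UNCALLED
  } else {
    names(laiv$phat)[w]
  }
  cnt <- if (length(w) == 1) unname(laiv$count[w]) else NA_integer_
  list(call = call, value = unname(mx), count = cnt)
}

#' Call ancestry at every window center of a LAIV track
#'
#' Vectorized [call_locus()] over all haplotypes and window centers.
#'
#' @param track A [sliding_laivs()] result.
#' @param laiv_min,allele_min See [call_locus()].
#' @return An object of class `locus_calls`: list with per-center `chrom`
#'   and `pos`, `sample`/`hap` per row, matrix `call` (haplotypes x
#'   centers; population label or `"UNCALLED"`), and matrices `value` and
#'   `count` of the winning information and allele count.
#' @export
call_loci <- function(track, laiv_min = 1e-6, allele_min = 2) {
  stopifnot(inherits(track, "laiv_track"), laiv_min >= 0, allele_min >= 0)
  pops <- track$populations
  K <- length(pops)
  mx <- track$phat[[1]]
  W <- matrix(1L, nrow(mx), ncol(mx))
  for (k in seq_len(K)[-1]) {
    upd <- track$phat[[k]] > mx
    W[upd] <- k
    mx[upd] <- track$phat[[k]][upd]
  }
  tie <- matrix(FALSE, nrow(mx), ncol(mx))
  npop <- matrix(0L, nrow(mx), ncol(mx))
  wcount <- matrix(0, nrow(mx), ncol(mx))
  for (k in seq_len(K)) {
    tie <- tie | (track$phat[[k]] == mx & W != k)
    npop <- npop + (track$count[[k]] > 0)
    sel <- W == k
    wcount[sel] <- track$count[[k]][sel]
  }
  call <- matrix(pops[W], nrow(mx), ncol(mx))
  call[mx < laiv_min | tie | (npop >= 2L & wcount < allele_min)] <- UNCALLED
  structure(list(chrom = track$chrom, pos = track$pos,
                 sample = track$sample, hap = track$hap,
                 call = call, value = mx, count = wcount,
                 populations = pops),
            class = "locus_calls")
}

#' @export
print.locus_calls <- function(x, ...) {
  cat("locus_calls:", length(x$sample), "haplotypes x", length(x$pos),
      "loci;", round(mean(x$call == UNCALLED), 4), "uncalled fraction\n")
  invisible(x)
}

#' @export
as.data.frame.locus_calls <- function(x, ...) {
  H <- length(x$sample); M <- length(x$pos)
  data.frame(chrom = rep(x$chrom, each = H), pos = rep(x$pos, each = H),
             sample = rep(x$sample, times = M),
             haplotype = rep(x$hap, times = M),
             call = as.vector(x$call), value = as.vector(x$value),
             count = as.vector(x$count), stringsAsFactors = FALSE)
}

#' Build ancestry segments from ordered per-locus calls of one haplotype
#'
#' Each called locus anchors its label on the 1 bp it occupies. The gap
#' strictly between two consecutive loci inherits their shared label when
#' the two calls coincide and is `"UNCALLED"` otherwise (including when
#' either side is uncalled). With `extend_ends = TRUE` (default) the
#' chromosome ends before the first and after the last locus take that
#' terminal locus's label; with `FALSE` they stay `"UNCALLED"`. Adjacent
#' same-label pieces are merged, so the result tiles
#' `[0, chromosome_length)` exactly with 0-based half-open intervals.
#'
#' @param pos Sorted 1-based positions of the called loci.
#' @param calls Character vector of per-locus calls (population label or
#'   `"UNCALLED"`), parallel to `pos`.
#' @param chromosome_length Chromosome length in bp.
#' @param chrom,sample,haplotype Metadata stamped on every segment.
#' @param extend_ends Extend terminal calls to the chromosome ends?
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `sample`,
#'   `haplotype`, `label`.
#' @export
segments_from_calls <- function(pos, calls, chromosome_length,
                                chrom = "1", sample = "S1", haplotype = 1L,
                                extend_ends = TRUE) {
  n <- length(pos)
  stopifnot(n == length(calls), n >= 1, chromosome_length >= max(pos))
  if (is.unsorted(pos, strictly = TRUE)) {
    stop("locus positions must be sorted and unique")
  }
  if (any(pos < 1)) stop("positions are 1-based and must be >= 1")
  end_lab <- function(lab) if (extend_ends) lab else UNCALLED
  s <- c(0, pos - 1)                       # head piece + anchors
  e <- c(pos[1] - 1, pos)
  l <- c(end_lab(calls[1]), calls)
  if (n > 1) {                             # inter-locus gaps
    gl <- ifelse(calls[-n] == calls[-1], calls[-1], UNCALLED)
    s <- c(s, pos[-n])
    e <- c(e, pos[-1] - 1)
    l <- c(l, gl)
  }
  s <- c(s, pos[n]); e <- c(e, chromosome_length)
  l <- c(l, end_lab(calls[n]))
  o <- order(s)
  s <- s[o]; e <- e[o]; l <- l[o]
  keep <- e > s
  s <- s[keep]; e <- e[keep]; l <- l[keep]
  r <- rle(l)
  last <- cumsum(r$lengths)
  first <- c(1L, head(last, -1L) + 1L)
  data.frame(chrom = chrom, start = s[first], end = e[last],
             sample = sample, haplotype = as.integer(haplotype),
             label = r$values, stringsAsFactors = FALSE)
}

#' Ancestry segments for all haplotypes of a callset
#'
#' Applies [segments_from_calls()] per haplotype and chromosome and
#' concatenates, sorted by (sample, haplotype, chrom, start).
#'
#' @param calls A [call_loci()] result.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param extend_ends See [segments_from_calls()].
#' @return A `data.frame` of segments.
#' @export
calls_to_segments <- function(calls, chrom_lengths, extend_ends = TRUE) {
  stopifnot(inherits(calls, "locus_calls"))
  chroms <- unique(calls$chrom)
  if (!all(chroms %in% names(chrom_lengths))) {
    stop("chrom_lengths must name every chromosome in the callset")
  }
  out <- vector("list", 0)
  for (cc in chroms) {
    j <- which(calls$chrom == cc)
    for (i in seq_along(calls$sample)) {
      out[[length(out) + 1L]] <- segments_from_calls(
        pos = calls$pos[j], calls = calls$call[i, j],
        chromosome_length = chrom_lengths[[cc]], chrom = cc,
        sample = calls$sample[i], haplotype = calls$hap[i],
        extend_ends = extend_ends)
    }
  }
  seg <- do.call(rbind, out)
  seg <- seg[order(seg$sample, seg$haplotype, seg$chrom, seg$start), ,
             drop = FALSE]
  rownames(seg) <- NULL
  seg
}

#' Full inference pipeline: presence matrix to calls and segments
#'
#' @param presence A [presence_matrix()].
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param window_size Window width in bp (default 2e6).
#' @param laiv_min,allele_min See [call_locus()].
#' @param extend_ends See [segments_from_calls()].
#' @return List with `calls` (a `locus_calls`) and `segments`
#'   (a `data.frame`).
#' @export
infer_ancestry <- function(presence, chrom_lengths, window_size = 2e6,
                           laiv_min = 1e-6, allele_min = 2,
                           extend_ends = TRUE) {
  track <- sliding_laivs(presence, window_size = window_size)
  calls <- call_loci(track, laiv_min = laiv_min, allele_min = allele_min)
  segments <- calls_to_segments(calls, chrom_lengths,
                                extend_ends = extend_ends)
  list(calls = calls, segments = segments)
}

check_segment_frame <- function(seg) {
  want <- c("chrom", "start", "end", "sample", "haplotype", "label")
  if (!all(want %in% names(seg))) {
    stop("segments need columns: ", paste(want, collapse = ", "))
  }
  if (any(seg$start >= seg$end)) stop("segment with start >= end")
  sp <- split(seg, list(seg$sample, seg$haplotype, seg$chrom), drop = TRUE)
  for (g in sp) {
    g <- g[order(g$start), , drop = FALSE]
    if (nrow(g) > 1 && any(g$start[-1] < g$end[-nrow(g)])) {
      stop("overlapping segments for sample ", g$sample[1], " haplotype ",
           g$haplotype[1], " on ", g$chrom[1])
    }
  }
  invisible(seg)
}

#' Write / read ancestry segments as BED-like text
#'
#' Tab-separated with header; columns `chrom`, `start`, `end`, `sample`,
#' `haplotype`, `label`; 0-based half-open coordinates; rows sorted by
#' (sample, haplotype, chrom, start). Overlapping segments within one
#' haplotype are refused.
#'
#' @param segments A segment `data.frame` (from [calls_to_segments()] or
#'   [simulate_admixed()] truth tracts).
#' @param path File path.
#' @return `write_segments` returns `path` invisibly; `read_segments`
#'   returns the segment `data.frame`.
#' @export
write_segments <- function(segments, path) {
  check_segment_frame(segments)
  seg <- segments[order(segments$sample, segments$haplotype, segments$chrom,
                        segments$start), , drop = FALSE]
  seg <- seg[c("chrom", "start", "end", "sample", "haplotype", "label")]
  write.table(format(seg, scientific = FALSE, trim = TRUE), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  seg <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = c(chrom = "character", start = "numeric",
                                   end = "numeric", sample = "character",
                                   haplotype = "integer",
                                   label = "character"))
  check_segment_frame(seg)
  seg
}
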