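pops5 <- c("AFR", "AMR", "EAS", "EUR", "SAS")

mk_laiv <- function(phat, count, pops = pops5) {
  structure(list(phat = setNames(phat, pops), count = setNames(count, pops),
                 denom = setNames(ifelse(phat > 0, count / phat, 0), pops)),
            class = "laiv")
}

test_that("per-locus calls follow argmax plus confidence gates", {
  # clear winner
  l <- mk_laiv(c(0.9, 0, 0, 0, 0), c(12, 0, 0, 0, 0))
  expect_equal(call_locus(l, laiv_min = 1e-6, allele_min = 2)$call, "AFR")

  # no information at all
  expect_equal(call_locus(mk_laiv(rep(0, 5), rep(0, 5)))$call, "UNCALLED")

  # two populations represented, winner below the allele-count gate
  l2 <- mk_laiv(c(2.0, 0.5, 0, 0, 0), c(1, 3, 0, 0, 0))
  expect_equal(call_locus(l2, allele_min = 2)$call, "UNCALLED")
  # the same window with the gate relaxed is called
  expect_equal(call_locus(l2, allele_min = 1)$call, "AFR")
  # a single-population window is exempt from the gate
  l3 <- mk_laiv(c(2.0, 0, 0, 0, 0), c(1, 0, 0, 0, 0))
  expect_equal(call_locus(l3, allele_min = 2)$call, "AFR")

  # exact tie for the maximum
  expect_equal(call_locus(mk_laiv(c(1, 1, 0, 0, 0),
                                  c(3, 3, 0, 0, 0)))$call, "UNCALLED")

  # laiv_min gate
  expect_equal(call_locus(mk_laiv(c(0.4, 0, 0, 0, 0), c(9, 0, 0, 0, 0)),
                          laiv_min = 0.5)$call, "UNCALLED")
})

test_that("vectorized calling agrees with call_locus window by window", {
  set.seed(10)
  panel <- rand_panel(M = 150, K = 3, L = 2e5)
  pm <- rand_presence(panel, H = 4)
  tr <- sliding_laivs(pm, window_size = 5e4)
  calls <- call_loci(tr, laiv_min = 0.2, allele_min = 2)
  half <- floor(5e4 / 2)
  for (j in sample(150, 20)) {
    win <- which(panel$pos >= panel$pos[j] - half &
                   panel$pos <= panel$pos[j] + half)
    slice <- snp_panel(panel$chrom[win], panel$pos[win],
                       panel$specific_pop[win], panel$specific_allele[win],
                       panel$maf[win], panel$count[win], populations(panel))
    for (h in 1:4) {
      one <- call_locus(compute_laiv(pm$X[h, win], slice),
                        laiv_min = 0.2, allele_min = 2)
      expect_equal(calls$call[h, j], one$call)
    }
  }
})

test_that("coinciding neighbours fill the gap and ends extend", {
  seg <- segments_from_calls(c(100L, 500L), c("AFR", "AFR"), 1000)
  expect_equal(seg$start, 0)
  expect_equal(seg$end, 1000)
  expect_equal(seg$label, "AFR")
})

test_that("differing neighbours leave the gap uncalled, anchors keep 1 bp", {
  seg <- segments_from_calls(c(100L, 500L), c("AFR", "EUR"), 1000)
  expect_equal(seg$label, c("AFR", "UNCALLED", "EUR"))
  expect_equal(seg$start, c(0, 100, 499))
  expect_equal(seg$end, c(100, 499, 1000))
})

test_that("alternating calls produce anchored points with uncalled gaps", {
  seg <- segments_from_calls(c(100L, 200L, 300L, 400L, 500L),
                             c("A", "B", "A", "B", "A"), 1000)
  expect_equal(nrow(seg), 9)
  expect_equal(seg$label, c("A", "UNCALLED", "B", "UNCALLED", "A",
                            "UNCALLED", "B", "UNCALLED", "A"))
  # brute-force interval construction: anchors are [pos-1, pos)
  expect_equal(seg$start, c(0, 100, 199, 200, 299, 300, 399, 400, 499))
  expect_equal(seg$end, c(100, 199, 200, 299, 300, 399, 400, 499, 1000))
})

test_that("end extension is optional and unsorted input errors", {
  seg <- segments_from_calls(c(100L, 500L), c("AFR", "AFR"), 1000,
                             extend_ends = FALSE)
  expect_equal(seg$label, c("UNCALLED", "AFR", "UNCALLED"))
  expect_equal(seg$start, c(0, 99, 500))
  expect_error(segments_from_calls(c(500L, 100L), c("A", "B"), 1000),
               "sorted")
})

test_that("segments always tile the chromosome exactly", {
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(1:30, 1)
    pos <- sort(sample.int(5000, n))
    calls <- sample(c("A", "B", "UNCALLED"), n, replace = TRUE)
    seg <- segments_from_calls(pos, calls, 5000)
    seg <- seg[order(seg$start), ]
    expect_equal(seg$start[1], 0)
    expect_equal(seg$end[nrow(seg)], 5000)
    expect_true(all(seg$start[-1] == seg$end[-nrow(seg)]))
    expect_equal(sum(seg$end - seg$start), 5000)
    # adjacent segments never share a label
    expect_true(all(seg$label[-1] != seg$label[-nrow(seg)]))
    # segment labels at locus positions match the calls
    at <- seg$label[findInterval(pos - 1, seg$start)]
    expect_equal(at, calls)
  }
})

test_that("stricter thresholds never convert uncalled loci into calls", {
  set.seed(13)
  panel <- rand_panel(M = 300, K = 3, L = 1e6)
  pm <- rand_presence(panel, H = 6, p = 0.2)
  tr <- sliding_laivs(pm, window_size = 1e5)
  base <- call_loci(tr, laiv_min = 0.1, allele_min = 1)
  for (lm in c(0.3, 0.8)) {
    for (am in c(2, 4)) {
      stricter <- call_loci(tr, laiv_min = lm, allele_min = am)
      flipped <- base$call == "UNCALLED" & stricter$call != "UNCALLED"
      expect_false(any(flipped))
    }
  }
})

test_that("a single represented population with laiv_min 0 calls everything", {
  cfg <- sim_config(K = 2, n_admixed = 5, chrom_length = 1e6,
                    snp_density = 1e-4, proportions = c(1, 0), seed = 3)
  ref <- simulate_reference(cfg)
  adm <- simulate_admixed(cfg, ref$panel)
  res <- infer_ancestry(adm$presence, c("1" = 1e6), window_size = 2e6,
                        laiv_min = 0, allele_min = 2)
  expect_true(all(res$segments$label == "POP1"))
  expect_equal(uncalled_rate(res$segments)$mean, 0)
})

test_that("segment files round-trip and refuse overlaps", {
  seg <- rbind(
    seg_frame(c(0, 100, 400), c(100, 400, 1000), c("A", "UNCALLED", "B")),
    seg_frame(c(0, 700), c(700, 1000), c("B", "A"), hap = 2L),
    seg_frame(0, 1000, "A", sample = "S0", hap = 1L))
  path <- withr::local_tempfile(fileext = ".bed")
  write_segments(seg, path)
  back <- read_segments(path)
  # output is sorted by (sample, haplotype, chrom, start)
  key <- order(seg$sample, seg$haplotype, seg$chrom, seg$start)
  expect_equal(back, structure(seg[key, ], row.names = seq_len(nrow(seg))))

  bad <- seg_frame(c(0, 50), c(100, 150), c("A", "B"))
  expect_error(write_segments(bad, path), "overlapping")

  empty <- seg_frame(numeric(), numeric(), character())
  write_segments(empty, path)
  expect_equal(nrow(read_segments(path)), 0)
})
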