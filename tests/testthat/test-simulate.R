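test_that("a fixed seed reproduces reference and admixed data bit for bit", {
  cfg <- sim_config(K = 3, chrom_length = 5e5, snp_density = 1e-4,
                    n_admixed = 4, seed = 21)
  r1 <- simulate_reference(cfg)
  r2 <- simulate_reference(cfg)
  expect_identical(r1$cohort$geno, r2$cohort$geno)
  expect_equal(r1$panel, r2$panel)
  a1 <- simulate_admixed(cfg, r1$panel)
  a2 <- simulate_admixed(cfg, r1$panel)
  expect_identical(a1$presence$X, a2$presence$X)
  expect_identical(a1$truth, a2$truth)
  # a different seed changes the draw
  r3 <- simulate_reference(sim_config(K = 3, chrom_length = 5e5,
                                      snp_density = 1e-4, n_admixed = 4,
                                      seed = 22))
  expect_false(identical(r1$cohort$geno, r3$cohort$geno))
})

test_that("designed SNP counts match the density within 4 SD", {
  cfg <- sim_config(K = 2, chrom_length = 1e6, snp_density = 1e-4, seed = 30)
  sizes <- panel_sizes(simulate_reference(cfg)$panel)
  # Poisson(100) per population: 4 sd = 40
  expect_true(all(abs(sizes - 100) <= 40))
})

test_that("a population left without SNPs is a hard error", {
  cfg <- sim_config(K = 2, chrom_length = 100, snp_density = 1e-4, seed = 1)
  expect_error(simulate_reference(cfg), "increase chrom_length")
})

test_that("with no misclassification the designed specific alleles stay exclusive", {
  cfg <- sim_config(K = 3, n_ref = 30, chrom_length = 1e6,
                    snp_density = 1e-4, mis_rate = 0, seed = 31)
  ref <- simulate_reference(cfg)
  screened <- screen_specific_snps(ref$cohort, min_copies = 1)
  # every screened SNP is a designed SNP of the same population
  key_d <- paste(ref$panel$pos, ref$panel$specific_pop)
  key_s <- paste(screened$pos, screened$specific_pop)
  expect_true(all(key_s %in% key_d))
  # and every designed SNP whose allele was sampled as a minor allele with
  # at least one copy is recovered
  realized <- ref$panel$count
  n_k <- setNames(rep(30, 3), populations(ref$panel))
  want <- realized >= 1 & realized <= n_k[ref$panel$specific_pop]
  expect_setequal(key_s, key_d[want])
})

test_that("misclassified SNPs hide a low-frequency allele in one other population", {
  cfg <- sim_config(K = 3, n_ref = 200, chrom_length = 1e6,
                    snp_density = 2e-4, mis_rate = 0.2, seed = 32)
  ref <- simulate_reference(cfg)
  hidden <- attr(ref$panel, "hidden_pop")
  expect_equal(length(hidden), nrow(ref$panel))
  frac <- mean(!is.na(hidden))
  expect_gt(frac, 0.1)
  expect_lt(frac, 0.3)
  expect_true(all(is.na(hidden) |
                    hidden != ref$panel$specific_pop))
  # hidden carriers show up in the hidden population's genotypes
  i <- which(!is.na(hidden))[1]
  carriers <- ref$cohort$geno[ref$cohort$pos == ref$panel$pos[i], ]
  by_pop <- tapply(carriers, ref$cohort$pop, sum)
  expect_true(all(by_pop[setdiff(names(by_pop),
                                 c(ref$panel$specific_pop[i],
                                   hidden[i]))] == 0))
})

test_that("breakpoint counts follow the Poisson admixture clock", {
  # g = 10, L = 2.5e8, r = 1e-8 -> expected 25 breakpoints per haplotype
  cfg <- sim_config(K = 2, n_admixed = 100, chrom_length = 2.5e8,
                    snp_density = 2e-6, generations = 10,
                    recomb_rate = 1e-8, seed = 33)
  ref <- simulate_reference(cfg)
  adm <- simulate_admixed(cfg, ref$panel)
  nb <- tapply(seq_len(nrow(adm$truth)),
               paste(adm$truth$sample, adm$truth$haplotype), length) - 1
  se <- sd(nb) / sqrt(length(nb))
  expect_lt(abs(mean(nb) - 25), 4 * se)
  # truth tracts tile the chromosome
  by_hap <- split(adm$truth, paste(adm$truth$sample, adm$truth$haplotype))
  for (g in by_hap[1:5]) {
    expect_equal(g$start[1], 0)
    expect_equal(g$end[nrow(g)], 2.5e8)
    if (nrow(g) > 1) expect_equal(g$start[-1], g$end[-nrow(g)])
  }
})

test_that("a degenerate mixture gives single-ancestry haplotypes", {
  cfg <- sim_config(K = 2, n_admixed = 10, chrom_length = 1e6,
                    snp_density = 1e-4, proportions = c(1, 0),
                    generations = 1, seed = 34)
  ref <- simulate_reference(cfg)
  adm <- simulate_admixed(cfg, ref$panel)
  expect_true(all(adm$truth$label == "POP1"))
  pop2 <- ref$panel$specific_pop == "POP2"
  expect_true(all(adm$presence$X[, pop2] == 0L))
})

test_that("recovery fractions are exact bp arithmetic and sum to one", {
  truth <- seg_frame(c(0, 400), c(400, 1000), c("AFR", "EUR"))
  # identical calls -> (1, 0, 0)
  ev <- evaluate_recovery(truth, truth)
  expect_equal(unname(ev$overall), c(1, 0, 0))
  # everything uncalled -> (0, 0, 1)
  ev2 <- evaluate_recovery(seg_frame(0, 1000, "UNCALLED"), truth)
  expect_equal(unname(ev2$overall), c(0, 0, 1))
  # half correct, half uncalled
  ev3 <- evaluate_recovery(
    seg_frame(c(0, 400, 500), c(400, 500, 1000),
              c("AFR", "EUR", "UNCALLED")), truth)
  expect_equal(unname(ev3$overall), c(0.5, 0, 0.5))
  # wrong ancestry on the EUR tract, per-ancestry breakdown
  ev4 <- evaluate_recovery(seg_frame(0, 1000, "AFR"), truth)
  expect_equal(unname(ev4$overall), c(0.4, 0.6, 0))
  afr <- ev4$by_ancestry[ev4$by_ancestry$ancestry == "AFR", ]
  eur <- ev4$by_ancestry[ev4$by_ancestry$ancestry == "EUR", ]
  expect_equal(afr$correct, 1)
  expect_equal(eur$wrong, 1)
  expect_equal(rowSums(ev4$by_ancestry[, c("correct", "wrong", "uncalled")]),
               c(1, 1), ignore_attr = TRUE)
})

test_that("recovery refuses mismatched haplotype sets", {
  a <- seg_frame(0, 100, "A")
  b <- seg_frame(0, 100, "A", sample = "S2")
  expect_error(evaluate_recovery(a, b), "different haplotype sets")
})

test_that("simulated VCF output reloads into the cohort that produced it", {
  cfg <- sim_config(K = 2, n_ref = 10, chrom_length = 2e5,
                    snp_density = 1e-4, seed = 35)
  ref <- simulate_reference(cfg)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_reference_vcf(ref$cohort, path, chrom_length = cfg$chrom_length)
  pops <- setNames(as.character(ref$cohort$pop), colnames(ref$cohort$geno))
  back <- read_reference_vcf(path, pops)
  expect_equal(unname(back$geno), unname(ref$cohort$geno))
  expect_equal(back$pos, ref$cohort$pos)
  expect_equal(screen_specific_snps(back, min_copies = 2),
               screen_specific_snps(ref$cohort, min_copies = 2))
})
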