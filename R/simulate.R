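#' Configuration for the synthetic admixture simulator
#'
#' Defines a single-chromosome study: K reference populations carrying
#' designed population-specific SNPs, plus admixed haplotypes built as
#' recombination mosaics of those populations with known truth tracts.
#'
#' @param K Number of reference populations (>= 2).
#' @param n_ref Diploid reference sample size per population (scalar or
#'   length K). Default 50.
#' @param n_admixed Number of admixed diploid samples. Default 50.
#' @param chrom Chromosome id. Default `"1"`.
#' @param chrom_length Chromosome length in bp. Default 1e8.
#' @param snp_density Designed population-specific SNPs per bp per
#'   population (scalar or length K). Default 1e-4.
#' @param maf_range Lower/upper bound of the uniform distribution the
#'   designed specific-allele frequencies are drawn from. Default
#'   c(0.05, 0.5).
#' @param proportions Admixture proportions over the K populations
#'   (sum to 1). Default uniform.
#' @param generations Generations since admixture g (>= 1); breakpoint
#'   density grows linearly in g. Default 10.
#' @param recomb_rate Recombination rate in Morgans per bp. Default 1e-8.
#' @param mis_rate Panel misclassification rate: probability that a
#'   designed "specific" SNP is secretly polymorphic at frequency
#'   `mis_freq` in one random other population. Default 0.
#' @param mis_freq Hidden allele frequency of misclassified SNPs.
#'   Default 0.005.
#' @param populations Population labels. Default `POP1..POPK`.
#' @param seed Integer seed; all simulator randomness flows from it
#'   (reference draws use `seed`, admixed draws `seed + 1`).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(K = 2, n_ref = 50, n_admixed = 50,
                       chrom = "1", chrom_length = 1e8,
                       snp_density = 1e-4, maf_range = c(0.05, 0.5),
                       proportions = rep(1 / K, K), generations = 10,
                       recomb_rate = 1e-8, mis_rate = 0, mis_freq = 0.005,
                       populations = sprintf("POP%d", seq_len(K)),
                       seed = 1) {
  K <- as.integer(K)
  n_ref <- rep_len(as.integer(n_ref), K)
  snp_density <- rep_len(as.numeric(snp_density), K)
  stopifnot(K >= 2, all(n_ref >= 1), n_admixed >= 1, chrom_length >= 1,
            length(populations) == K, length(proportions) == K,
            generations >= 1, recomb_rate > 0,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  if (any(snp_density <= 0)) stop("snp_density must be > 0")
  if (abs(sum(proportions) - 1) > 1e-8 || any(proportions < 0)) {
    stop("admixture proportions must be nonnegative and sum to 1")
  }
  if (mis_rate < 0 || mis_rate >= 1) stop("mis_rate must be in [0, 1)")
  structure(list(K = K, n_ref = n_ref, n_admixed = as.integer(n_admixed),
                 chrom = as.character(chrom),
                 chrom_length = as.numeric(chrom_length),
                 snp_density = snp_density, maf_range = as.numeric(maf_range),
                 proportions = as.numeric(proportions),
                 generations = as.numeric(generations),
                 recomb_rate = as.numeric(recomb_rate),
                 mis_rate = as.numeric(mis_rate),
                 mis_freq = as.numeric(mis_freq),
                 populations = as.character(populations),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a reference cohort carrying designed population-specific SNPs
#'
#' Per population k, `Poisson(density_k * chrom_length)` SNP positions are
#' drawn uniformly (without replacement) along the chromosome and each SNP
#' gets a designed specific-allele frequency from `Uniform(maf_range)`.
#' Reference haplotypes carry the specific allele with that frequency in
#' the specific population and never elsewhere -- except for a fraction
#' `mis_rate` of SNPs, which hide a low-frequency allele (`mis_freq`) in
#' one random other population, emulating panel misclassification caused by
#' finite reference samples. The REF allele of every designed SNP is `A`
#' and the specific allele is the ALT allele `C`.
#'
#' @param config A [sim_config()].
#' @return List with `cohort` (a [reference_cohort()]) and `panel` (the
#'   designed [snp_panel()], `maf` = designed frequency, `count` = copies
#'   realized in the simulated cohort; attributes `hidden_pop` and
#'   `hidden_freq` record the misclassification design, `NA` where none).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    K <- config$K
    m_k <- rpois(K, config$snp_density * config$chrom_length)
    if (any(m_k == 0)) {
      stop("population(s) received 0 designed SNPs (",
           paste(config$populations[m_k == 0], collapse = ", "),
           "); increase chrom_length or snp_density")
    }
    M <- sum(m_k)
    pos <- sort(sample.int(config$chrom_length, M))
    spop <- sample(rep.int(seq_len(K), m_k))     # random pop per position
    f <- runif(M, config$maf_range[1], config$maf_range[2])
    mis <- runif(M) < config$mis_rate
    hidden <- rep(NA_integer_, M)
    if (any(mis)) {
      hidden[mis] <- vapply(spop[mis], function(k) {
        sample(seq_len(K)[-k], 1)
      }, 1L)
    }

    # reference genotypes: ALT copy counts, SNPs x samples
    N <- sum(config$n_ref)
    geno <- matrix(0L, M, N)
    pop <- factor(rep.int(config$populations, config$n_ref),
                  levels = config$populations)
    col0 <- c(0L, cumsum(config$n_ref))
    for (j in seq_len(K)) {
      p_j <- ifelse(spop == j, f,
                    ifelse(mis & !is.na(hidden) & hidden == j,
                           config$mis_freq, 0))
      n_j <- config$n_ref[j]
      geno[, (col0[j] + 1L):col0[j + 1L]] <-
        matrix(rbinom(M * n_j, 2L, rep(p_j, n_j)), nrow = M)
    }
    samples <- sprintf("REF%04d", seq_len(N))
    colnames(geno) <- samples
    cohort <- reference_cohort(chrom = rep(config$chrom, M), pos = pos,
                               ref = rep("A", M), alt = rep("C", M),
                               geno = geno, pop = pop)

    realized <- t(rowsum(t(geno), pop))[cbind(seq_len(M), spop)]
    panel <- snp_panel(chrom = rep(config$chrom, M), pos = pos,
                       specific_pop = config$populations[spop],
                       specific_allele = rep("C", M),
                       maf = f, count = realized,
                       populations = config$populations)
    attr(panel, "hidden_pop") <-
      ifelse(is.na(hidden), NA_character_, config$populations[hidden])
    attr(panel, "hidden_freq") <- ifelse(is.na(hidden), NA_real_,
                                         config$mis_freq)
    list(cohort = cohort, panel = panel)
  })
}

#' Simulate admixed haplotypes as recombination mosaics
#'
#' Per haplotype, recombination breakpoints follow a Poisson process with
#' intensity `generations * recomb_rate` per bp; each tract's ancestry is
#' drawn independently from the admixture proportions (pool model). At a
#' panel SNP the specific allele is present with its panel frequency when
#' the covering tract has the SNP's specific ancestry, with the hidden
#' frequency when the tract has the SNP's hidden (misclassified) ancestry,
#' and never otherwise.
#'
#' @param config A [sim_config()].
#' @param panel A [snp_panel()], normally the designed panel from
#'   [simulate_reference()]. Its `maf` column drives the allele draws.
#' @return List with `presence` (a [presence_matrix()]) and `truth` (a
#'   segment `data.frame` of true ancestry tracts tiling
#'   `[0, chrom_length)`; adjacent tracts may share a label).
#' @export
simulate_admixed <- function(config, panel) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "snp_panel"))
  if (!all(panel$chrom == config$chrom)) {
    stop("panel chromosome does not match the configuration")
  }
  hidden_pop <- attr(panel, "hidden_pop") %||% rep(NA_character_, nrow(panel))
  hidden_freq <- attr(panel, "hidden_freq") %||% rep(NA_real_, nrow(panel))
  with_seed(config$seed + 1L, {
    H <- 2L * config$n_admixed
    M <- nrow(panel)
    L <- config$chrom_length
    lambda <- config$generations * config$recomb_rate * L
    samples <- sprintf("ADM%04d", seq_len(config$n_admixed))
    sample_row <- rep(samples, each = 2L)
    hap_row <- rep(1:2, times = config$n_admixed)

    X <- matrix(0L, H, M)
    truth <- vector("list", H)
    for (h in seq_len(H)) {
      nb <- rpois(1, lambda)
      bp <- sort(unique(floor(runif(nb, 1, L))))
      anc <- sample.int(config$K, length(bp) + 1L, replace = TRUE,
                        prob = config$proportions)
      truth[[h]] <- data.frame(
        chrom = config$chrom, start = c(0, bp), end = c(bp, L),
        sample = sample_row[h], haplotype = hap_row[h],
        label = config$populations[anc], stringsAsFactors = FALSE)
      # ancestry covering each panel SNP (1-based pos p occupies [p-1, p))
      a <- anc[findInterval(panel$pos - 1L, c(0, bp))]
      pr <- ifelse(config$populations[a] == panel$specific_pop, panel$maf,
                   ifelse(!is.na(hidden_pop) &
                            config$populations[a] == hidden_pop,
                          hidden_freq, 0))
      X[h, ] <- rbinom(M, 1L, pr)
    }
    list(presence = presence_matrix(X, sample_row, hap_row, panel),
         truth = do.call(rbind, truth))
  })
}

#' Compare called segments with simulator truth tracts
#'
#' Per haplotype, base pairs are partitioned into called-and-correct,
#' called-and-wrong and uncalled fractions (they sum to 1 exactly). The
#' cohort summary averages over haplotypes; a per-truth-ancestry breakdown
#' (fractions of the bp truly belonging to each ancestry) is also
#' returned, which is what the sparse-panel analyses use.
#'
#' @param segments Called segments (from [calls_to_segments()]).
#' @param truth Truth tracts (from [simulate_admixed()]).
#' @return List with `per_haplotype` (data.frame of fractions), `overall`
#'   (named numeric: `correct`, `wrong`, `uncalled`; haplotype means) and
#'   `by_ancestry` (data.frame of per-true-ancestry fractions).
#' @export
evaluate_recovery <- function(segments, truth) {
  check_segment_frame(segments)
  check_segment_frame(truth)
  ks <- unique(hap_key(segments$sample, segments$haplotype))
  kt <- unique(hap_key(truth$sample, truth$haplotype))
  if (!setequal(ks, kt)) {
    stop("segments and truth cover different haplotype sets")
  }
  seg_sp <- split(segments, hap_key(segments$sample, segments$haplotype))
  tru_sp <- split(truth, hap_key(truth$sample, truth$haplotype))
  per <- vector("list", length(ks))
  anc_bp <- NULL
  for (i in seq_along(ks)) {
    p <- overlay_segments(seg_sp[[ks[i]]], tru_sp[[ks[i]]])
    len <- p$end - p$start
    tot <- sum(len)
    unc <- p$a == UNCALLED
    corr <- !unc & p$a == p$b
    wrong <- !unc & p$a != p$b
    g <- seg_sp[[ks[i]]]
    per[[i]] <- data.frame(
      sample = g$sample[1], haplotype = g$haplotype[1],
      correct = sum(len[corr]) / tot, wrong = sum(len[wrong]) / tot,
      uncalled = sum(len[unc]) / tot, stringsAsFactors = FALSE)
    bp <- rowsum(cbind(correct = len * corr, wrong = len * wrong,
                       uncalled = len * unc, total = len), p$b)
    anc_bp <- if (is.null(anc_bp)) bp else {
      all_lab <- union(rownames(anc_bp), rownames(bp))
      m <- matrix(0, length(all_lab), 4,
                  dimnames = list(all_lab, colnames(bp)))
      m[rownames(anc_bp), ] <- m[rownames(anc_bp), ] + anc_bp
      m[rownames(bp), ] <- m[rownames(bp), ] + bp
      m
    }
  }
  per <- do.call(rbind, per)
  by_anc <- data.frame(ancestry = rownames(anc_bp),
                       correct = anc_bp[, "correct"] / anc_bp[, "total"],
                       wrong = anc_bp[, "wrong"] / anc_bp[, "total"],
                       uncalled = anc_bp[, "uncalled"] / anc_bp[, "total"],
                       row.names = NULL, stringsAsFactors = FALSE)
  list(per_haplotype = per,
       overall = c(correct = mean(per$correct), wrong = mean(per$wrong),
                   uncalled = mean(per$uncalled)),
       by_ancestry = by_anc)
}

# Overlay two tilings of the same extent for one haplotype: returns the
# refinement pieces with the label of each input ("a" and "b").
overlay_segments <- function(a, b) {
  a <- a[order(a$start), , drop = FALSE]
  b <- b[order(b$start), , drop = FALSE]
  check_tiling(a)
  check_tiling(b)
  if (a$start[1] != b$start[1] || a$end[nrow(a)] != b$end[nrow(b)]) {
    stop("the two segment sets cover different extents")
  }
  bounds <- sort(unique(c(a$start, a$end, b$start, b$end)))
  ps <- bounds[-length(bounds)]
  pe <- bounds[-1]
  data.frame(start = ps, end = pe,
             a = a$label[findInterval(ps, a$start)],
             b = b$label[findInterval(ps, b$start)],
             stringsAsFactors = FALSE)
}

# contiguity check for one haplotype's sorted segments
check_tiling <- function(g) {
  if (nrow(g) > 1 && any(g$start[-1] != g$end[-nrow(g)])) {
    stop("gaps in segment tiling for sample ", g$sample[1], " haplotype ",
         g$haplotype[1])
  }
  invisible(g)
}
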