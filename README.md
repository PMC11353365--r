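# laivr

Local ancestry inference from population-specific SNPs, in R.

Admixed genomes are mosaics of chromosomal segments inherited from
different ancestral populations. **laivr** assigns an ancestral origin to
each segment of a phased haplotype using only *population-specific SNPs* —
variants whose minor allele occurs in exactly one reference population —
and is aimed at population geneticists who want a fast, transparent,
counting-based alternative to HMM or machine-learning local ancestry
callers, plus a self-contained simulator to validate it.

## The method

Let θ<sub>k</sub> be the index set of panel SNPs specific to reference
population *k* (*k* = 1…K) and *f<sub>km</sub>* the minor-allele frequency
(MAF) of SNP *m* in population *k*. For a haplotype with allele-presence
indicators *X<sub>m</sub>* ∈ {0,1}, the **local ancestry information
vector** (LAIV) over a window has entries

&nbsp;&nbsp;&nbsp;&nbsp;p̂<sub>k</sub> = Σ<sub>m∈θk</sub> X<sub>m</sub> / Σ<sub>m∈θk</sub> f<sub>km</sub> ,

the method-of-moments estimator of the local ancestral proportion
p<sub>k</sub>: the observed count of population-*k*-specific alleles over
the count expected from a fully population-*k* haplotype. It depends only
on counts and MAF sums, so it needs no linkage-equilibrium assumption.
A window of fixed physical width (default 2 Mb) is centered at every panel
SNP; per window the population with the most ancestral information is
called, subject to a minimum information value (`laiv_min`, default 1e-6)
and — when alleles of several populations share the window — a minimum
winning allele count (`allele_min`, default 2) that guards against panel
misclassification errors. Loci between two coinciding calls inherit the
call; loci between differing calls stay uncalled. The panel itself is
screened from reference genotypes: a SNP qualifies when one population
carries at least `min_copies` (default 5) copies of an allele that is
absent from every other reference population and minor within its own.

## Worked example

Simulate a two-way admixed cohort (70% AFR / 30% EUR, 10 generations,
20 Mb), screen the panel, infer local ancestry and score it against the
simulator's truth tracts:

```r
library(laivr)
cfg <- sim_config(K = 2, n_ref = 50, n_admixed = 10, chrom_length = 2e7,
                  snp_density = 1e-4, proportions = c(0.7, 0.3),
                  generations = 10, populations = c("AFR", "EUR"), seed = 42)
ref   <- simulate_reference(cfg)
panel <- screen_specific_snps(ref$cohort, min_copies = 5)
panel_sizes(panel)
#>  AFR  EUR
#> 1925 1856
adm <- simulate_admixed(cfg, ref$panel)
pm  <- align_presence(adm$presence, panel)
res <- infer_ancestry(pm, chrom_lengths = c("1" = cfg$chrom_length),
                      window_size = 2e6, laiv_min = 1e-6, allele_min = 2)
head(res$segments, 4)
#>   chrom   start      end  sample haplotype    label
#> 1     1       0  1012808 ADM0001         1      EUR
#> 2     1 1012808  1030286 ADM0001         1 UNCALLED
#> 3     1 1030286 20000000 ADM0001         1      AFR
#> 4     1       0 20000000 ADM0001         2      EUR
round(evaluate_recovery(res$segments, adm$truth)$overall, 4)
#>  correct    wrong uncalled
#>   0.9966   0.0030   0.0004
```

Each screened population contributes ~1,900 specific SNPs (density 1e-4
per bp over 20 Mb, minus SNPs failing the 5-copy screen). The caller
recovers 99.7% of base pairs correctly; the 17 kb uncalled gap on
haplotype 1 of `ADM0001` sits at a recombination breakpoint, where windows
mix evidence from both flanking ancestries and neighbouring calls
disagree.

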