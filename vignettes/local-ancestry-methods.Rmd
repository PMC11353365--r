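---
title: "Local ancestry inference from population-specific SNPs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local ancestry inference from population-specific SNPs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laivr)
```

## The model

Consider a haplotype segment carrying $M$ diallelic SNPs, each specific to
one of $K$ reference populations: SNP $m \in \theta_k$ has minor-allele
frequency $f_{km} > 0$ in population $k$ and its minor allele is absent
from all other reference populations. If the segment descends from
population $k$ with probability $p_k$ (its local ancestral proportion),
the allele-presence indicator $X_m$ for $m \in \theta_k$ is Bernoulli with
success probability $p_k f_{km}$. Under independence of the SNPs the joint
likelihood factorises over populations and SNPs, and the method-of-moments
estimator of $p_k$ is

$$\hat p_k \;=\; \frac{\sum_{m \in \theta_k} X_m}
                     {\sum_{m \in \theta_k} f_{km}},$$

the observed count of population-$k$-specific alleles divided by the count
expected from a pure population-$k$ haplotype. The $K$-vector
$(\hat p_1, \dots, \hat p_K)$ is the *local ancestry information vector*
(LAIV). Two properties matter in practice:

* **Unbiasedness**: $E[\hat p_k] = p_k$, which holds with or without
  linkage disequilibrium among the SNPs, because the estimator uses only
  first moments. The test suite verifies this empirically for pure and
  segment-free mixed haplotypes (500 replicates, 4-standard-error bands).
* **No ceiling**: $\hat p_k$ is a ratio of a count to an expectation and
  can exceed 1 in finite windows; calling uses the argmax, so the scale
  overshoot is harmless.

When a window contains no SNP of $\theta_k$ the denominator is zero and we
define $\hat p_k = 0$. This convention is load-bearing: "no evidence" must
never win the argmax, and regions where a population's panel is sparse
should fall back to *uncalled* rather than being guessed.

## Windows and calling

A window of `window_size` bp (default 2,000,000) is centered at every
panel SNP: inclusive bounds at `floor(window_size/2)` bp on either side,
truncated at chromosome ends, never crossing a chromosome. The centre
SNP's own allele counts like any other. Per haplotype and window the
caller takes the argmax of the LAIV and leaves the locus uncalled when

1. the winning value is below `laiv_min` (default `1e-6`, i.e. any
   positive evidence suffices by default);
2. the maximum is exactly tied — a deterministic tie-break would fabricate
   ancestry;
3. alleles specific to two or more populations occur in the window and the
   winner carries fewer than `allele_min` (default 2) of them. This gate
   targets panel *misclassification errors*: a SNP that looks specific
   only because the other reference samples were too few to reveal its
   low-frequency allele elsewhere. Such stray alleles are sporadic, so
   demanding two concordant alleles in contested windows suppresses them.
   A window where only one population's alleles occur at all is exempt.

Both thresholds are monotone: raising either can only move loci from
called to uncalled (a property test asserts this).

The per-locus calls are then painted into segments. Each called locus
anchors its label on the single base pair it occupies; the open interval
between two consecutive loci inherits their shared label when the calls
coincide and is uncalled otherwise — between-locus ancestry is only ever
interpolated, never extrapolated across a disagreement. Regions without
any panel SNP (e.g. centromeres) follow the same rule, so they are
labelled only when both flanking calls agree. Chromosome ends outside the
outermost loci take the terminal call's label by default; this
extrapolation is the one place the rule is generous, and
`extend_ends = FALSE` turns it off. Segments per haplotype tile
$[0, L)$ exactly in 0-based half-open coordinates.

## Panel screening

A SNP enters the panel when one allele reaches `min_copies` (default 5)
copies in a single reference population, has zero copies in every other
reference population, and is the *minor* allele within its own population
(frequency $\le 0.5$; exactly 0.5 is allowed, since the rule bounds the
copy count, not the frequency). Both alleles of every SNP are screened —
the specification of "minor allele" leaves open whether REF or ALT carries
the population-specific signal, and an ALT-major population renders the
REF allele the interesting one. The two alleles of one SNP can never both
qualify: exclusivity plus the minor-allele bound are jointly
unsatisfiable for both alleles. SNPs with missing genotypes are dropped
before screening; non-diallelic records are skipped with a warning.
$f_{km}$ is estimated as copy count over $2n_k$. Contigs are screened
independently.

## The simulator

`simulate_reference()` and `simulate_admixed()` generate the study
conditions the package is validated under:

* Designed specific SNPs per population follow a Poisson count with mean
  `snp_density * chrom_length`, positions uniform, designed frequencies
  $f \sim U(0.05, 0.5)$ — the default density of $10^{-4}$/bp yields
  roughly one panel SNP per 10 kb per population, a deliberately
  information-rich regime comparable to a well-covered continental panel.
* Reference haplotypes draw the specific allele Bernoulli($f$) inside its
  population and never elsewhere, except for a fraction `mis_rate` of
  SNPs that hide a frequency-`mis_freq` (default 0.005) allele in one
  random other population — the misclassification error model.
* Admixed haplotypes are recombination mosaics: breakpoints follow a
  Poisson process of intensity $g \times r$ per bp (generations since
  admixture times the uniform recombination rate, default $10^{-8}$
  Morgans/bp ≈ 1 cM/Mb), and each tract's ancestry is drawn iid from the
  admixture proportions. This *pool* model was chosen over a Markov model
  with self-transitions: it has the right marginal proportions and the
  right $1/(g r)$ tract-length scaling, at the cost of allowing adjacent
  same-ancestry tracts (which merely merge). Defaults — $g = 10$,
  proportions (0.7, 0.3) in the two-way setting — mimic recent
  continental admixture such as African-American cohorts.
* All randomness flows from `seed` (reference draws) and `seed + 1`
  (admixed draws); runs are bit-reproducible.

What the simulator does **not** emulate: within-population linkage
disequilibrium, allele-frequency drift between the reference sample and
the true ancestral population, phasing errors, genotyping error, and
non-uniform recombination maps. Passing the validation suite therefore
demonstrates correctness of the estimator, caller and metrics under the
stated generative model — not performance on real cohorts, where
reference-panel adequacy dominates.

## Evaluation metrics

`evaluate_recovery()` overlays called segments on truth tracts and splits
every base pair into called-and-correct, called-and-wrong and uncalled;
the three fractions sum to 1 exactly (integer bp arithmetic), and a
per-true-ancestry breakdown exposes phenomena like the sparse-panel
effect, where thinning one population's panel tenfold measurably raises
that ancestry's uncalled fraction.

`consistency_rate()` compares two callsets. The field reports consistency
without fixing a denominator, so the package makes its choice explicit:
by default agreement is computed over base pairs *called by both*
callsets; `uncalled_as_disagreement = TRUE` switches to the full shared
extent. Haplotypes are matched by index — no phase-swap rematching, since
comparable callsets are expected to consume identical phased input.
Because of the denominator choice, consistency numbers are not claimed to
be numerically equivalent to any externally published ones.

## Numerical and implementation notes

* Sliding windows are contiguous index ranges over position-sorted
  panels, so per-population window counts come from cumulative sums:
  $O(M)$ per haplotype rather than $O(M \cdot w)$. Counts are integers
  stored in doubles (exact); MAF-sum denominators from cumulative-sum
  differences match naive summation to $\le 10^{-9}$ relative error, and
  magnitudes below $10^{-12}$ are snapped to the zero-denominator
  convention. A brute-force per-window oracle pins both down in the
  tests.
* Ties at the argmax compare doubles exactly; they arise in practice only
  from all-zero vectors or identical count/denominator ratios, both of
  which should stay uncalled.
* Panel SNPs absent from a sample's VCF contribute 0 to numerators while
  their $f$ stays in denominators, keeping the denominator a property of
  the panel alone; the loader warns so systematic site loss is visible.
  Unphased genotypes at panel sites are a hard error, not a warning —
  per-haplotype windows are meaningless without phase.
* Validation problem sizes: the end-to-end recovery runs use a 100 Mb
  chromosome, 100 haplotypes and ~20,000 panel SNPs (about 200 SNPs per
  2 Mb window), which gives the cohort-mean recovery fractions standard
  errors well below the margins being asserted; oracle-equivalence checks
  use 50 random instances of up to 1,000 SNPs.

## Known limitations

* Accuracy degrades at tract boundaries: within half a window of a
  breakpoint the LAIV mixes evidence from both ancestries, so calls near
  the flip point are noise-dominated, producing short uncalled (and
  occasionally wrong) stretches. Smaller windows sharpen boundaries but
  raise the uncalled rate; the 2 Mb default suits recent admixture with
  long tracts.
* A reference population with a sparse panel (the simulator's 10×-thinned
  regime) loses calls in its tracts rather than gaining wrong ones — the
  conservative failure mode, but a failure mode nonetheless.
* Diploid unphased calling, posterior probabilities, genetic-map (cM)
  windows and phase-error correction are out of scope.
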