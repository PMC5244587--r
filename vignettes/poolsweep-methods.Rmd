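---
title: "Methods: pool-seq sweep scanning, drift nulls, association and haplotype inference"
author: "poolsweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pool-seq sweep scanning, drift nulls, association and haplotype inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`poolsweep` analyses evolve-and-resequence experiments read out by pooled
whole-genome sequencing: two lines divergently selected from one base
population for many generations, sequenced as DNA pools, scanned for regions
of extreme allele-frequency differentiation, and interrogated downstream with
a drift null, a marker-trait association design, and haplotype-frequency
inference. The motivating system is a pair of White Leghorn chicken lines
selected bidirectionally for 39 generations on day-5 antibody titer against
sheep red blood cells, with relaxed (random-mated) sublines and an F2
intercross — but every component is parameterised and reusable.

This vignette records the models, conventions and numerical choices, and what
the synthetic-data tests do and do not establish.

## Pooled counts and site filters

The atomic unit is the per-site, per-pool vector of read counts of A, T, C,
G, N and deletions (the PoPoolation2 `sync` exchange format; positions are
1-based inclusive). Conventions:

* **Coverage bounds are exclusive on both sides.** A site is kept only when
  every pool's coverage is strictly above `min_cov` (default 10) and strictly
  below `max_cov` (default 100). The "minimum coverage 10 / maximum coverage
  100" phrasing used by windowed F_ST tools is read as the same rule; a single
  convention is applied everywhere.
* **N and deletion counts contribute to coverage but never to alleles.** This
  mirrors mpileup semantics: those reads occupy the site but carry no allele
  information.
* **Multi-allelic sites are reduced to the two highest-count alleles** summed
  across pools, ties broken by the fixed base order A < T < C < G. Downstream
  estimators are biallelic. A site is a SNP when both retained alleles reach
  `min_count` (default 3) summed across pools.

## Windowed F_ST

Per SNP, with counts $a_i, b_i$ of the two alleles and informative coverage
$n_i = a_i + b_i$ in pools $i = 1, 2$, the unbiased heterozygosity components
are

$$h_w = \frac{1}{2}\sum_{i=1,2} \frac{2 a_i b_i}{n_i (n_i - 1)}, \qquad
  h_b = \frac{a_1 b_2 + a_2 b_1}{n_1 n_2},$$

and windowed F_ST is the **ratio of sums** $\sum (h_b - h_w) / \sum h_b$ over
the SNPs of a window — not the mean of per-SNP ratios. Sites with $n_i < 2$
in a pool, or with $h_b = 0$ (both pools monomorphic for the same allele),
are undefined and skipped. Per-SNP numerators may be negative (the estimator
is unbiased around zero under no differentiation); raw window ratios are kept
in `fst_raw` and floored at zero in `fst`, which summaries use.

Windows are 1000 bp with 50% overlap by default, anchored at position 1 of
each chromosome; a final partial window is dropped so every window has the
stated width. The `covered_fraction` of a window counts positions present in
the input with coverage inside the filter bounds in both pools, divided by
the window length. The full-coverage default (`min_covered_fraction = 1`)
assumes an all-sites input; variant-only inputs (such as the synthetic sync
files, which contain no invariant positions) must set it to 0, as the
analysis scripts do.

Genome-wide heterozygosity summaries average $2p(1-p)$ over SNP sites only
(whether invariant sites should enter the average is a reporting choice; SNP
sites only is this package's convention, stated here because it changes the
absolute level but not the sweep/genome ratio).

## Sweep-region detection

Windows with F_ST strictly above the scan cutoff are clustered when the gap
between the end of one retained window and the start of the next is strictly
less than 0.5 Mb; clusters never span chromosomes. Clusters with a single
window or fewer than 2 SNPs (counted in retained windows only) are removed.
The cutoff is the 95th percentile of defined window F_ST values, computed by
linear interpolation of order statistics (quantile type 7) — percentile
method matters because data-derived cutoffs are reported to three decimals
and other interpolation rules move them.

**Tie rule at the maximum.** In strongly selected experiments a sizable
fraction of windows can sit exactly at F_ST = 1 (both pools fixed for
alternative alleles). If more than the top tail ties at the maximum, the
percentile equals the maximum and a strict comparison would retain nothing —
the opposite of the scan's purpose. The cutoff therefore steps down to the
largest distinct value below the maximum in that case; with all windows
equal there is nothing to step down to and the common value is returned.

## The drift null

`run_drift_null()` asks how much between-line differentiation *pure drift*
produces under the experimental breeding scheme, using a forward
Wright-Fisher simulation of a 5 Mb fragment:

1. **Standing variation.** The number of segregating sites is Poisson with
   mean $\theta L \sum_{i=1}^{2N-1} 1/i$ (the equilibrium expectation at
   per-site scaled diversity $\theta$, default $4 N_e \mu$ with $N_e = 500$
   and $\mu = 3.13 \times 10^{-7}$). Each site's derived-allele frequency is
   $i/2N$ with probability $\propto 1/i$ (the neutral spectrum), positions
   are uniform, haplotypes start at linkage equilibrium, and 50 generations
   of random mating with recombination induce LD at the ancestral scale.
   This replaces a full mutation-drift burn-in, which would cost thousands of
   generations for the same spectrum.
2. **Line drift.** Two lines of 25 diploids are founded from disjoint
   ancestral individuals. Each generation every offspring draws its mother
   uniformly (with replacement) from the line's 20 breeding females and its
   father from its 5 males, so the realized effective size follows
   $4 N_f N_m / (N_f + N_m) = 16$. Meioses recombine with a Poisson number
   of crossovers from the genetic map (2.8 cM/Mb for the macro-chromosome
   class, 6.4 for micro), and new mutations enter each gamete at
   $\theta / (4 N_e)$ per site.
3. **Differentiation readout.** A site is *differentiated* when the two
   lines are fixed for alternative alleles (an F_ST-threshold mode is also
   available). Differentiated sites closer than 50 kb are merged into
   regions spanning first to last site; regions need at least 2 sites, the
   same support rule the real-data sweep scan applies to its window
   clusters. The summary reports pooled region lengths (median/mean/max),
   the median windowed F_ST computed by the pool machinery from the
   exhaustive allele counts (coverage = 2N), the fraction of replicate
   fragments with at least one region, the mean percentage of fragment
   length covered by regions, and the **fixed percentage** — the mean
   percentage of segregating sites fixed for alternative alleles, which is
   the natural "how much of the variation did drift resolve oppositely"
   statistic for this null.

At these parameters the null is emphatically not negligible: across 200
replicates per class the package's own runs place the fixed percentage near
15-16% (macro) and 14-15% (micro), the median region length in the low
hundreds of kb, and the median window F_ST near 0.53-0.55. Two sensitivities
dominate, and both are worth knowing when comparing against any previously
published drift simulation of the same design: (i) the drift time scale
$\tau = t / 2N_e$ — fixation probabilities, and with them every region
statistic, fall steeply as the realized $N_e$ rises (balanced family
contributions, for instance, can nearly double it); and (ii) the
standing-variation density, which sets how many sites a resolved haplotype
block exhibits and therefore how long clustered regions are. A simulation
with the same nominal parameters but a different interpretation of either
knob produces region lengths differing by small integer factors while
leaving the qualitative conclusion (drift alone creates many long
fixed-difference regions at $N_e \approx 16{-}25$ over 39 generations)
unchanged.

The per-replicate cost is dominated by the ancestral population (1000
haplotypes × ~23,000 sites), so the generation loop is implemented in C++
(`src/gametes.cpp`) with the haplotype matrix stored as raw bytes; 200
replicates per class run in ~3 minutes on one CPU.

## The synthetic selection experiment

`simulate_experiment()` is the test harness for every empirical module and
emulates the experiment end to end:

* **Base population.** 90 candidates (30 male, 60 female) carrying 10,000
  segregating sites on a 50 Mb four-chromosome genome (two macro-like
  chromosomes at 2.8 cM/Mb, two micro-like at 6.4). Founder minor-allele
  frequencies follow a folded $1/p$ spectrum on [0.005, 0.5] — rare-skewed,
  as standing variation in a large randombred flock is; a uniform spectrum
  is available but overweights intermediate frequencies and inflates drift
  fixation.
* **Trait.** 50 additive QTL with exponentially distributed effect sizes,
  rescaled so the founder additive variance equals $h^2 V_P$ with
  $h^2 = 0.3$ and $V_P = 6.25$ on the log2-titer scale; a fixed sex effect
  (default 1 log2 unit for males) and Gaussian environment complete the
  phenotype, floored at 0 because titers cannot be negative (this floor is
  what lets the low line plateau while the high line keeps responding).
* **Selection.** Truncation within sex: the top (high line) or bottom (low
  line) 7 males / 28 females in generations 1-10, 8/32 thereafter, with at
  most 2 selected offspring per dam family within each sex — a quantitative
  stand-in for the experiment's restricted truncation selection. Matings
  balance both dam and sire contributions (round-robin), modelling the
  restriction's purpose of limiting family over-representation; this keeps
  the realized $N_e$ near the scheme's nominal 22.4-25.6 rather than below
  it.
* **Relaxed sublines** branch at generation 24 by random parent choice and
  random-mate for 16 generations.
* **Pool sequencing.** 30/30/20/16 individuals per population, per-site
  depth Poisson around 32.3/36.7/35.4/34.8×, allele reads binomial in the
  pool sample's frequency — no sequencing-error model beyond binomial
  sampling.
* **F2 design.** The generation-32 snapshots of the lines are crossed to 64
  F1s, intermated into a 256-bird F2 cohort, and the 64 highest plus 64
  lowest phenotypes are retained — a 50% two-tail selective-genotyping
  design (the cohort size is a package choice; only the 128 extremes are
  fixed by the emulated experiment). The marker panel is a random 1024-site
  subsample of sites polymorphic between the lines, coded 0/1/2 in copies of
  the high-line allele, carrying each line's allele frequency and their
  difference `delta_p`.

What passing tests on this generator show — and what they do not: the
generator reproduces the *structure* of the real data (sync pools with
realistic depth, trait trajectories with a low-line plateau, relaxed lines
with flat means and intermediate haplotype frequencies, sweep regions
containing the large planted QTL, a two-tier association table) but not its
genome scale, its alignment/genotyping artifacts, linked structural
variation, or any non-additive architecture. The sweep scan's false-negative
behaviour on fragmented real coverage (where `covered_fraction` bites) is
exercised only synthetically.

## Backward-elimination association

The association module regresses log2 day-5 titers on sex plus the additive
dosages of highly differentiated markers (`delta_p > 0.7`, strict), in two
stages: markers are clustered at < 5 Mb, each multi-marker cluster is
reduced to its most significant member by within-cluster backward
elimination, and the representatives enter a genome-wide backward
elimination reported at the 20% FDR tier with the subset surviving
continued elimination at 5% flagged.

The elimination step removes, at each iteration, the marker with the largest
p-value whose Benjamini-Hochberg-adjusted significance exceeds the working
threshold, refits, and stops when all remaining marker terms pass. **The BH
denominator stays anchored at the size of the full starting family**
($p_{(i)} \cdot m_0 / i$), not the current model size. With a shrinking
denominator the final survivor would be judged at its raw p-value despite
being effectively the minimum of $m_0$ null p-values, and ~64% of pure-noise
datasets (20 markers, n = 128) would retain a marker at the "5%" tier;
anchoring restores the nominal calibration (~5%, verified by simulation in
the test suite). Sex is never eliminated; effects are re-estimated in the
final joint model; perfectly collinear markers are dropped; markers with
more than 20% missing genotypes are excluded and remaining missing dosages
are mean-imputed; p-value ties remove the marker later in genome order, so
runs are deterministic.

**Known limitation — selective genotyping biases OLS effect sizes.** When
the analyzed individuals are the phenotypic extremes of a larger cohort,
ordinary least squares on the selected sample overestimates marker effects:
with 128 of 256 retained (both tails), the package's own simulations put the
estimate for a planted 2.0-unit QTL near 3.1 with a nominal s.e. of ~0.28.
Detection and ranking are unaffected — the bias is monotone — but reported
effect sizes from extreme-sampled designs should be read as inflated by
roughly the truncated-sample variance ratio, and are not corrected here
because the module deliberately implements the plain linear-model analysis.

## Haplotype inference from pooled frequencies

Within a candidate sweep region where one pool is (nearly) fixed:

1. `find_reference_pool()` picks the pool whose major-allele frequency is at
   least `fix_tol = 0.95` at the largest fraction of SNP sites (fixation
   cannot be required exactly at 30-35× read depth), failing explicitly when
   no pool reaches 90% of sites.
2. `polarize()` re-expresses every pool's frequency as that of the allele
   *not* on the reference haplotype and drops sites where the reference pool
   is not fixed within tolerance — the sequential position filter.
3. `infer_haplotypes()` clusters the site-by-pool polarized frequency matrix
   by k-means (k chosen from 3 downward, requiring at least 5 sites per band
   and band centers separated by more than `freq_tol = 0.15` in some pool;
   bands are matched across pools by shared site membership, never by
   frequency value, because haplotype frequencies differ between pools while
   site content does not). Each band is assigned a subset of at most two
   alternative haplotypes — a site carried by both shows a band at the sum
   of their frequencies — by enumerating the possible assignments and
   solving each pool's haplotype frequencies by weighted least squares,
   keeping the assignment with the smallest residual; a residual scale above
   `freq_tol` flags the model ambiguous. The reference haplotype's frequency
   is the complement.

With three haplotypes, 120 informative sites and 35× depth, recovery RMSE is
below 0.05 (verified over 100 simulated regions). The procedure formalises
an explicitly ad hoc published practice; its tolerances are declared
defaults, not derived quantities, and it does not attempt read-backed
phasing or likelihood-based pool deconvolution (which require founder
genomes this design lacks).

## Reproducibility and problem sizes

All stochastic components consume R's RNG, so `set.seed()` (or the `seed`
fields of the config objects) makes every pipeline stage reproducible,
including the C++ kernels. The test suite runs the drift null at 200
replicates per recombination class, the FDR calibration on 500 null
datasets, and the parameter-recovery and haplotype-recovery checks on 100
replicates each — sizes chosen so the full suite completes in minutes on a
single CPU while keeping Monte-Carlo error well inside the asserted
tolerances. `scripts/acceptance.R` re-runs the drift null from scratch at
200 replicates per class and writes the headline quantities as JSON.
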