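# poolsweep

Analysis of evolve-and-resequence experiments from pooled whole-genome
sequencing (pool-seq). The package was built around a classic design in
quantitative genetics: two lines of chickens selected divergently for 39
generations on day-5 antibody titer, sequenced as DNA pools together with
their relaxed (random-mated) sublines, scanned for selective sweeps, and
dissected with a drift null, an F2 marker-trait association analysis, and
haplotype-frequency inference inside candidate regions. Every step is
exposed as ordinary R functions, so the same machinery applies to any
two-line (or multi-pool) selection experiment.

## What it computes

* **Pool data model** — PoPoolation2 `sync` I/O (`read_sync`, `write_sync`),
  exclusive coverage filters (>10 and <100 reads in every pool), reduction of
  multi-allelic sites to the two top alleles (`biallelic_counts`).
* **Windowed F_ST** — the Karlsson ratio-of-sums estimator over 1000 bp
  windows with 50% overlap: per SNP
  `h_w = mean_i 2 a_i b_i / (n_i (n_i - 1))`,
  `h_b = (a1 b2 + a2 b1) / (n1 n2)`, window F_ST = `sum(h_b - h_w) / sum(h_b)`
  (`window_fst`, `pairwise_fst_matrix`), plus expected heterozygosity and the
  unequal-sex-ratio effective size `Ne = 4 Nf Nm / (Nf + Nm)`.
* **Sweep scan** — 95th-percentile cutoff on the window F_ST distribution,
  transitive clustering of extreme windows closer than 0.5 Mb, removal of
  single-window / <2-SNP clusters, region summaries and sweep/genome
  heterozygosity ratios (`fst_cutoff`, `cluster_windows`, `filter_regions`,
  `region_summary`, `sweep_het_ratio`).
* **Drift null** — a forward Wright-Fisher simulator (C++ core) of a 5 Mb
  fragment: equilibrium standing variation at ancestral Ne = 500
  (mu = 3.13e-7), two lines of 25 diploids with 80% breeding females
  drifting 39 generations, fixed-difference sites clustered at <50 kb
  (`drift_sim_config`, `run_drift_null`).
* **Synthetic experiment generator** — bidirectional restricted truncation
  selection on a 50-QTL additive trait (h2 = 0.3), relaxed sublines from
  generation 24, pool sequencing at 32-37x, and an F2 intercross with 128
  phenotypic extremes (`simulate_experiment`, `sample_pools`, `simulate_f2`).
* **Association** — two-stage multi-locus backward elimination of markers
  with pooled allele-frequency difference > 0.7, sex + additive dosage OLS on
  log2 titers, two-tier (5% / 20%) FDR reporting with the BH denominator
  anchored at the starting family size (`two_stage_scan`,
  `backward_eliminate`).
* **Haplotype inference** — reference-haplotype polarization of pooled
  frequencies inside a sweep region and band-clustering into per-pool
  haplotype frequencies (`find_reference_pool`, `polarize`,
  `infer_haplotypes`, `region_fst_table`).

See `vignettes/poolsweep-methods.Rmd` for the models, conventions and
numerical choices.

## Worked example

The `analysis/` directory is a numbered end-to-end workflow on synthetic
data. Running

```sh
Rscript analysis/01_simulate_experiment.R
Rscript analysis/02_sweep_scan.R
```

simulates the experiment and scans the pooled genomes, printing

```
Selected lines after 39 generations: high 16.1, low 0.3 (log2 titer)
Pooled 10000 sites x 4 populations -> results/synthetic/pools.sync
10000 of 10000 sites pass the coverage filters
95% F_ST cutoff: 0.981
20 sweep regions, total 32.37 Mb (64.7% of genome), mean/median 1618/1107 kb
top-10 planted QTL contained in a region: 10/10
sweep/genome heterozygosity ratios:
       pool sweep_het genome_het ratio
1   HighSel    0.1693      0.187 0.907
2    LowSel    0.0952      0.132 0.723
3 HighRelax    0.1798      0.192 0.936
4  LowRelax    0.1117      0.130 0.857
```

i.e. the two selected lines diverge by ~16 log2 units, the windowed-F_ST
scan recovers all ten largest planted QTL inside candidate sweep regions,
and heterozygosity inside sweeps is depressed relative to the genome in the
selected lines but not in the relaxed ones. `analysis/03_drift_null.R` runs
the neutral null per recombination class, `analysis/04_association.R`
produces the two-tier association table of the F2 extremes (retained markers
land 0-500 kb from planted QTL), and `analysis/05_haplotypes.R` polarizes a
sweep region against its fixed line and prints per-pool frequencies of the
segregating haplotypes, e.g.

```
          Haplo1 Haplo2 Haplo3
HighSel    0.151  0.446  0.403
LowSel     1.000  0.000  0.000
HighRelax  0.032  0.057  0.911
LowRelax   0.984  0.005  0.010
```

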