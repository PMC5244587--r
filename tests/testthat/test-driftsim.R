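# scaled-down configurations keep these tests fast; the full-scale run lives
# in the acceptance suite
small_cfg <- function(...) {
  drift_sim_config(locus_length = 2e5, ne_ancestral = 100,
                   burnin_generations = 10, n_replicates = 2, ...)
}

test_that("standing variation matches the neutral equilibrium expectations", {
  set.seed(21)
  cfg <- small_cfg()
  expect_equal(init_standing_variation(drift_sim_config(mu = 0))$n_sites, 0L)
  # Watterson: E[S] = theta * L * sum_{i<2N} 1/i
  twoN <- 2 * cfg$ne_ancestral
  expected_S <- cfg$theta_site * cfg$locus_length * sum(1 / seq_len(twoN - 1))
  S <- replicate(30, init_standing_variation(cfg)$n_sites)
  expect_lt(abs(mean(S) - expected_S) / expected_S, 0.1)
  # folded SFS shape: chi-square GOF against the analytic neutral spectrum
  cfg2 <- drift_sim_config(locus_length = 2e6, ne_ancestral = 50,
                           burnin_generations = 0)
  pop <- init_standing_variation(cfg2)
  cnt <- sim_allele_frequencies(pop)$count
  cnt <- cnt[cnt > 0 & cnt < 2 * cfg2$ne_ancestral]
  folded <- pmin(cnt, 2 * cfg2$ne_ancestral - cnt)
  n <- 2 * cfg2$ne_ancestral
  classes <- 1:(n / 2)
  p_exp <- (1 / classes + 1 / (n - classes)) / (1 + (classes < n / 2))
  p_exp <- p_exp / sum(p_exp)
  obs <- tabulate(folded, nbins = n / 2)
  bins <- c(1, 2, 3, 5, 10, 25, n / 2)          # pool sparse classes
  ob <- eb <- numeric(length(bins) - 0)
  lo <- 1
  for (k in seq_along(bins)) {
    ob[k] <- sum(obs[lo:bins[k]]); eb[k] <- sum(p_exp[lo:bins[k]]) * sum(obs)
    lo <- bins[k] + 1
  }
  chi <- sum((ob - eb)^2 / eb)
  expect_lt(chi, qchisq(0.999, df = length(bins) - 1))
})

test_that("zero generations of drift leaves line frequencies at the founder sample", {
  set.seed(22)
  cfg <- small_cfg(generations = 0)
  anc <- init_standing_variation(cfg)
  lines <- evolve_neutral(anc, cfg)
  f <- sim_allele_frequencies(lines$line1)
  expect_equal(lines$line1$generation, 0L)
  expect_equal(nrow(f), anc$n_sites)
  # founder columns are drawn from the ancestor, so frequencies must be
  # achievable subsamples (no drift applied)
  expect_true(all(f$count <= sim_allele_frequencies(anc)$count))
})

test_that("one generation of drift has variance p(1-p)/(2Ne) under the sex ratio", {
  set.seed(23)
  genome <- data.frame(chrom = "c", length_bp = 1e4, rec_cmmb = 0)
  n_line <- 25; n_f <- 20; n_m <- 5
  ne <- effective_population_size(n_f, n_m)   # 16
  p0 <- 0.5
  reps <- 600
  dp <- replicate(reps, {
    # exactly p0 at every site so the initial frequency is not itself random
    h <- t(replicate(10, sample(rep(c(1L, 0L), n_line))))
    pop <- sim_population(h, 1:10, rep("c", 10), genome)
    out <- poolsweep:::.evolve_random(pop, 1, n_f, n_m, 0)
    sim_allele_frequencies(out)$freq - p0
  })
  v <- var(as.numeric(dp))
  expect_lt(abs(v - p0 * (1 - p0) / (2 * ne)) / (p0 * (1 - p0) / (2 * ne)), 0.25)
})

test_that("between-line F_ST grows with drift time", {
  set.seed(24)
  fst_at <- function(gens) {
    cfg <- small_cfg(generations = gens)
    anc <- init_standing_variation(cfg)
    lines <- evolve_neutral(anc, cfg)
    mf <- poolsweep:::.merged_line_freqs(lines$line1, lines$line2)
    ps <- poolsweep:::.lines_as_pool_sites(mf, lines$line1$genome)
    wf <- window_fst(ps, min_count = 1, min_covered_fraction = 0,
                     chrom_lengths = c(sim = cfg$locus_length))
    mean(wf$fst, na.rm = TRUE)
  }
  short <- replicate(4, fst_at(3))
  long <- replicate(4, fst_at(39))
  expect_gt(mean(long), mean(short))
})

test_that("differentiated_regions clusters fixed-opposite sites like brute force", {
  expect_equal(nrow(differentiated_regions(c(1e4, 2e4), c(0.5, 1), c(0.5, 0))), 0L)
  r <- differentiated_regions(c(1e4, 2e4), c(1, 1), c(0, 0), cluster_gap = 5e4)
  expect_equal(r$length, 1e4)
  expect_equal(r$n_sites, 2L)
  # sites exactly cluster_gap apart split (strict rule)
  r2 <- differentiated_regions(c(1e4, 6e4), c(1, 1), c(0, 0), cluster_gap = 5e4)
  expect_equal(nrow(r2), 0L)     # two singleton clusters, both below min_sites
  set.seed(25)
  for (rep in 1:40) {
    n <- sample(5:40, 1)
    pos <- sort(sample.int(5e5, n))
    f1 <- sample(c(0, 0.5, 1), n, TRUE)
    f2 <- sample(c(0, 0.5, 1), n, TRUE)
    gap <- sample.int(1e5, 1)
    got <- differentiated_regions(pos, f1, f2, cluster_gap = gap, min_sites = 1)
    opp <- (f1 == 1 & f2 == 0) | (f1 == 0 & f2 == 1)
    cl <- bf_cluster(rep("x", sum(opp)), pos[opp], pos[opp], gap)
    expect_equal(nrow(got), length(unique(cl)))
    if (nrow(got) > 0) {
      expect_equal(got$start, as.numeric(tapply(pos[opp], cl, min)))
      expect_equal(got$end, as.numeric(tapply(pos[opp], cl, max)))
    }
  }
  # per-site F_ST threshold mode
  rt <- differentiated_regions(c(1e3, 2e3), c(0.95, 0.9), c(0.05, 0.1),
                               fst_threshold = 0.5, min_sites = 2)
  expect_equal(rt$n_sites, 2L)
})

test_that("run_drift_null is reproducible and reports the summary contract", {
  cfg <- small_cfg(seed = 99)
  s1 <- run_drift_null(cfg)
  s2 <- run_drift_null(cfg)
  expect_equal(s1$region_lengths, s2$region_lengths)
  expect_equal(s1$median_window_fst, s2$median_window_fst)
  expect_equal(s1$pct_sites_fixed_opposite, s2$pct_sites_fixed_opposite)
  expect_true(s1$frac_with_region >= 0 && s1$frac_with_region <= 1)
  expect_true(is.na(s1$max_length) || s1$max_length >= s1$mean_length)
  # a zero-generation null has no differentiated regions
  cfg0 <- small_cfg(generations = 0, seed = 1)
  s0 <- run_drift_null(cfg0)
  expect_equal(s0$frac_with_region, 0)
  expect_equal(s0$pct_covered, 0)
})

test_that("higher recombination gives stochastically shorter differentiated regions", {
  lens <- function(rec, seed) {
    cfg <- drift_sim_config(locus_length = 1e6, ne_ancestral = 150,
                            burnin_generations = 10, n_replicates = 6,
                            rec_rate = rec, seed = seed)
    unlist(run_drift_null(cfg)$region_lengths)
  }
  low <- lens(0.5, 31)
  high <- lens(12, 31)
  expect_gt(median(low), median(high))
})

test_that("window F_ST from simulator truth equals the pool-statistics route", {
  set.seed(26)
  cfg <- small_cfg()
  anc <- init_standing_variation(cfg)
  lines <- evolve_neutral(anc, cfg)
  mf <- poolsweep:::.merged_line_freqs(lines$line1, lines$line2)
  ps <- poolsweep:::.lines_as_pool_sites(mf, lines$line1$genome)
  wf <- window_fst(ps, min_count = 1, min_covered_fraction = 0,
                   chrom_lengths = c(sim = cfg$locus_length))
  # direct-formula oracle on ten random windows
  bc <- biallelic_counts(ps, min_count = 1)
  idx <- sample(which(!is.na(wf$fst)), 10)
  for (i in idx) {
    o <- oracle_window_fst(bc$a[, 1], bc$b[, 1], bc$a[, 2], bc$b[, 2],
                           ps$pos, wf$start[i])
    expect_equal(wf$fst_raw[i], o, tolerance = 1e-12)
  }
})
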