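# reduced experiment for speed: smaller genome/panel, fewer generations where
# the property under test allows it
fast_cfg <- function(...) {
  selection_sim_config(n_sites = 1500,
                       genome = data.frame(chrom = c("chr1", "chr2"),
                                           length_bp = c(1e7, 5e6),
                                           rec_cmmb = c(2.8, 6.4)),
                       f2_panel_size = 200, ...)
}

test_that("the experiment is reproducible under a fixed seed", {
  e1 <- simulate_experiment(fast_cfg(generations = 8, relax_at = 4,
                                     relax_generations = 2, f2_at = 6, seed = 5))
  e2 <- simulate_experiment(fast_cfg(generations = 8, relax_at = 4,
                                     relax_generations = 2, f2_at = 6, seed = 5))
  expect_identical(e1$trait_history, e2$trait_history)
  expect_identical(e1$populations$high_sel$geno, e2$populations$high_sel$geno)
  set.seed(5); p1 <- sample_pools(e1)
  set.seed(5); p2 <- sample_pools(e2)
  expect_identical(p1$counts, p2$counts)
})

test_that("selected lines diverge while relaxed lines stay flat", {
  set.seed(6)
  exp <- simulate_experiment(selection_sim_config(n_sites = 3000, seed = 61))
  th <- exp$trait_history
  m <- function(line, gen) mean(th$mean_phen[th$line == line & th$generation == gen])
  expect_gt(m("high_sel", 38) - m("low_sel", 38), 5)
  expect_lt(abs(m("high_sel", 0) - m("low_sel", 0)), 2)
  # relaxed lines: no systematic trend after branching (slope t-test, loose)
  for (ln in c("high_relax", "low_relax")) {
    sub <- th[th$line == ln, ]
    agg <- aggregate(mean_phen ~ generation, sub, mean)
    fit <- summary(lm(mean_phen ~ generation, agg))
    expect_gt(fit$coefficients["generation", "Pr(>|t|)"], 0.001)
  }
  # monotone divergence in expectation: late gap exceeds mid-experiment gap
  expect_gt(m("high_sel", 38) - m("low_sel", 38),
            m("high_sel", 10) - m("low_sel", 10) - 1)
})

test_that("a null architecture leaves only drift between the lines", {
  set.seed(7)
  cfg <- fast_cfg(n_qtl = 0, generations = 6, relax_at = 3,
                  relax_generations = 2, f2_at = 5)
  exp <- simulate_experiment(cfg)
  th <- exp$trait_history
  gap <- mean(th$mean_phen[th$line == "high_sel" & th$generation == 5]) -
         mean(th$mean_phen[th$line == "low_sel" & th$generation == 5])
  expect_lt(abs(gap), 2.5)    # no heritable trait, no sustained response
})

test_that("a single large-effect QTL fixes for alternative alleles in the lines", {
  hits <- 0
  for (seed in 1:5) {
    cfg <- fast_cfg(n_qtl = 1, h2 = 0.6, seed = seed)
    exp <- simulate_experiment(cfg)
    q <- exp$model$qtl_rows
    ph <- sim_allele_frequencies(exp$populations$high_sel)$freq[q]
    pl <- sim_allele_frequencies(exp$populations$low_sel)$freq[q]
    if (ph > 0.95 && pl < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("pool sampling follows the Poisson-depth binomial-read model", {
  set.seed(8)
  cfg <- fast_cfg(generations = 6, relax_at = 3, relax_generations = 2,
                  f2_at = 5, seed = 8)
  exp <- simulate_experiment(cfg)
  ps <- sample_pools(exp)
  cov <- pool_coverage(ps)
  expect_equal(unname(colMeans(cov)), cfg$mean_depth, tolerance = 0.05)
  # monomorphic sites yield single-allele counts
  f_high <- sim_allele_frequencies(exp$populations$high_sel)$freq
  mono <- which(f_high == 0)[1]
  expect_false(is.na(mono))
  nz <- sum(ps$counts[mono, 1:4, 1] > 0)
  expect_lte(nz, 1)
  # high-depth limit with pools = whole population: read frequencies converge
  # on the pool allele frequencies
  cfg2 <- fast_cfg(generations = 4, relax_at = 2, relax_generations = 1,
                   f2_at = 3, mean_depth = rep(5000, 4),
                   pool_sizes = rep(90, 4), seed = 9)
  exp2 <- simulate_experiment(cfg2)
  set.seed(10)
  ps2 <- sample_pools(exp2)
  af <- allele_frequencies(ps2, min_count = 1)
  truth <- sim_allele_frequencies(exp2$populations$high_sel)$freq
  seg <- which(truth > 0.1 & truth < 0.9)
  expect_gt(length(seg), 20)
  err <- abs(af$p_major[seg, 1] - pmax(truth[seg], 1 - truth[seg]))
  expect_lt(max(err, na.rm = TRUE), 0.05)
  # binomial sampling noise scale at finite depth: var ~ p(1-p)/depth
  p_target <- 0.5
  reads <- rbinom(4000, 36, p_target) / 36
  expect_lt(abs(var(reads) - p_target^2 / 36) / (p_target^2 / 36), 0.15)
})

test_that("the F2 extremes design is bimodal and null markers associate at chance", {
  set.seed(12)
  par <- make_f2_parent_lines()
  model <- toy_trait_model(qtl_rows = integer(0), effects = numeric(0))
  cfg <- selection_sim_config(f2_panel_size = 20, f2_cohort = 256,
                              f2_n_extremes = 128)
  panel <- simulate_f2(par$high, par$low, model, cfg)
  expect_s3_class(panel, "marker_panel")
  expect_equal(nrow(panel$individuals), 128)
  # null trait: single-marker association at ~chance level across markers
  pvals <- apply(panel$geno, 2, function(g) {
    if (sd(g) == 0) return(NA_real_)
    summary(lm(panel$individuals$phenotype ~ g))$coefficients[2, 4]
  })
  expect_lt(mean(pvals < 0.05, na.rm = TRUE), 0.25)
  # extremes selection leaves the centre of the distribution depleted:
  # almost nothing within a quarter-sd of the median (bimodal notch)
  model2 <- toy_trait_model(par$qtl_row, 2.0)
  panel2 <- simulate_f2(par$high, par$low, model2, cfg)
  ph <- panel2$individuals$phenotype
  centre <- mean(abs(ph - median(ph)) < 0.25 * sd(ph))
  expect_lt(centre, 0.1)   # a unimodal sample keeps ~20% in that band
  # planted QTL: homozygote class difference approximates 2a before selection bias
  qcol <- which(panel2$markers$effect != 0)
  if (length(qcol) == 1) {
    g <- panel2$geno[, qcol]
    diff_hom <- mean(ph[g == 2]) - mean(ph[g == 0])
    expect_gt(diff_hom, 2 * 2.0 * 0.8)
  }
})

test_that("pooled frequencies at large planted QTL separate the lines by > 0.7", {
  set.seed(13)
  ok <- 0
  for (seed in 1:4) {
    cfg <- fast_cfg(n_qtl = 3, h2 = 0.5, seed = 20 + seed)
    exp <- simulate_experiment(cfg)
    ps <- sample_pools(exp)
    af <- allele_frequencies(ps)
    q <- exp$model$qtl_rows[which.max(exp$model$effects)]
    dp <- abs(af$p1[q, 1] - af$p1[q, 2])
    if (!is.na(dp) && dp > 0.7) ok <- ok + 1
  }
  expect_gte(ok, 3)
})
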