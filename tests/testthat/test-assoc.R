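toy_panel <- function(geno, pheno, sex, chrom = NULL, pos = NULL, delta_p = NULL) {
  m <- ncol(geno)
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) pos <- seq(1e6, by = 1e6, length.out = m)
  if (is.null(delta_p)) delta_p <- rep(1, m)
  marker_panel(data.frame(id = sprintf("m%02d", seq_len(m)), chrom = chrom,
                          pos = pos, p_high = 1, p_low = 0, delta_p = delta_p,
                          effect = 0),
               geno,
               data.frame(id = seq_len(nrow(geno)), sex = ifelse(sex == 1, "M", "F"),
                          phenotype = pheno))
}

test_that("the delta_p screen uses a strict inequality", {
  set.seed(31)
  geno <- matrix(rbinom(40 * 3, 2, 0.5), 40, 3)
  panel <- toy_panel(geno, rnorm(40), rbinom(40, 1, 0.5),
                     delta_p = c(0.70, 0.71, 0.90))
  sub <- differentiated_marker_subset(panel, 0.7)
  expect_equal(sub$markers$id, c("m02", "m03"))
})

test_that("marker clustering matches the 5 Mb rule and brute force", {
  mk <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                   pos = c(1e6, 5.9e6, 11.1e6, 1e6))
  expect_equal(cluster_markers(mk, gap = 5e6), c(1L, 1L, 2L, 3L))
  mk2 <- data.frame(chrom = "chr1", pos = c(1e6, 6.2e6))
  expect_equal(cluster_markers(mk2, gap = 5e6), c(1L, 2L))
  set.seed(32)
  for (r in 1:40) {
    n <- sample(3:30, 1)
    chrom <- sort(sample(paste0("chr", 1:3), n, TRUE))
    pos <- sample.int(3e7, n)
    o <- order(chrom, pos); chrom <- chrom[o]; pos <- pos[o]
    gap <- sample.int(8e6, 1)
    got <- cluster_markers(data.frame(chrom = chrom, pos = pos), gap)
    expect_equal(got, bf_cluster(chrom, pos, pos, gap))
  }
})

test_that("backward elimination recovers a strong effect and drops pure noise", {
  set.seed(33)
  n <- 128
  sex <- rbinom(n, 1, 0.5)
  geno <- matrix(rbinom(n * 10, 2, 0.5), n, 10)
  y <- 1.5 * sex + 2.0 * geno[, 4] + rnorm(n)
  be <- backward_eliminate(geno, y, sex, fdr = 0.05)
  expect_true(4 %in% be$retained)
  row <- which(be$table$marker == 4)
  expect_lt(abs(be$table$estimate[row] - 2), 3 * be$table$se[row])
  # no markers at all: empty result, no error
  be0 <- backward_eliminate(geno[, 0, drop = FALSE], y, sex)
  expect_equal(length(be0$retained), 0L)
  # aliased duplicate marker columns are handled
  geno2 <- cbind(geno[, 4], geno[, 4], geno[, 1:3])
  be2 <- backward_eliminate(geno2, y, sex, fdr = 0.05)
  expect_true(length(be2$retained) >= 1)
})

test_that("null retention is controlled near the nominal FDR tier", {
  set.seed(34)
  hits <- 0
  reps <- 150
  for (r in seq_len(reps)) {
    geno <- matrix(rbinom(128 * 20, 2, 0.5), 128, 20)
    sex <- rbinom(128, 1, 0.5)
    y <- rnorm(128) + 0.5 * sex
    if (length(backward_eliminate(geno, y, sex, fdr = 0.05)$retained) > 0)
      hits <- hits + 1
  }
  expect_lt(hits / reps, 0.10)
})

test_that("two-stage scan keeps tier monotonicity and passes singletons through", {
  set.seed(35)
  n <- 128
  sex <- rbinom(n, 1, 0.5)
  # markers on 6 chromosomes -> all clusters are singletons
  geno <- matrix(rbinom(n * 6, 2, 0.5), n, 6)
  y <- 2.0 * geno[, 2] + sex + rnorm(n)
  panel <- toy_panel(geno, y, sex, chrom = paste0("chr", 1:6),
                     pos = rep(1e6, 6))
  res <- two_stage_scan(panel)
  expect_equal(attr(res, "n_representatives"), 6L)   # stage 1 is the identity
  expect_true("m02" %in% res$id)
  # monotonicity of tiers across random datasets: the 5% set within the 20% set
  for (r in 1:10) {
    geno <- matrix(rbinom(n * 12, 2, 0.5), n, 12)
    y <- rnorm(n) + sex + geno[, 1] * runif(1, 0, 2)
    panel <- toy_panel(geno, y, sex,
                       chrom = rep(paste0("chr", 1:4), each = 3),
                       pos = rep(c(1e6, 2e6, 20e6), 4))
    res <- two_stage_scan(panel)
    # every reported marker survived the loose tier; the strict tier flags a subset
    expect_true(all(res$fdr_tier %in% c("5%", "20%")))
    expect_lte(sum(res$fdr_tier == "5%"), nrow(res))
  }
})

test_that("permuting phenotypes destroys associations", {
  set.seed(36)
  n <- 128
  sex <- rbinom(n, 1, 0.5)
  geno <- matrix(rbinom(n * 15, 2, 0.5), n, 15)
  y <- 2 * geno[, 5] + sex + rnorm(n)
  hits <- 0
  for (r in 1:40) {
    yp <- sample(y)
    be <- backward_eliminate(geno, yp, sex, fdr = 0.05)
    if (length(be$retained) > 0) hits <- hits + 1
  }
  expect_lte(hits / 40, 0.125)
})

test_that("effect signs follow the high-line allele coding", {
  set.seed(37)
  par <- make_f2_parent_lines(n_sites = 300, qtl_row = 150L)
  model <- toy_trait_model(par$qtl_row, 2.0)
  cfg <- selection_sim_config(f2_panel_size = 300, f2_cohort = 256,
                              f2_n_extremes = 128)
  panel <- simulate_f2(par$high, par$low, model, cfg)
  qcol <- which(panel$markers$effect > 0)
  expect_equal(length(qcol), 1L)      # the planted QTL carries a positive effect
  res <- two_stage_scan(panel, delta = 0.7)
  expect_true(panel$markers$id[qcol] %in% res$id)
  expect_gt(res$estimate[res$id == panel$markers$id[qcol]], 0)
})

test_that("an empty screen yields an empty, flagged result", {
  set.seed(38)
  geno <- matrix(rbinom(50 * 4, 2, 0.5), 50, 4)
  panel <- toy_panel(geno, rnorm(50), rbinom(50, 1, 0.5),
                     delta_p = rep(0.2, 4))
  res <- two_stage_scan(panel)
  expect_equal(nrow(res), 0L)
  expect_match(attr(res, "status"), "screen")
})
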