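test_that("allele frequencies come from informative reads only", {
  cnt <- array(0L, dim = c(3, 6, 2))
  cnt[1, , 1] <- c(30L, 0L, 0L, 10L, 0L, 0L)   # A=30, G=10 -> p(A)=0.75
  cnt[1, , 2] <- c(20L, 0L, 0L, 20L, 0L, 0L)
  cnt[2, , 1] <- c(30L, 0L, 0L, 0L, 0L, 0L)    # fixed
  cnt[2, , 2] <- c(15L, 0L, 0L, 15L, 0L, 0L)
  cnt[3, , 1] <- c(0L, 0L, 0L, 0L, 25L, 0L)    # only N reads -> missing
  cnt[3, , 2] <- c(10L, 0L, 0L, 10L, 0L, 0L)
  s <- pool_sites(rep("chr1", 3), 1:3, rep("A", 3), cnt)
  af <- allele_frequencies(s, min_count = 3)
  expect_equal(af$p1[1, 1], 0.75)
  expect_equal(af$p1[2, 1], 1.0)
  expect_true(is.na(af$p1[3, 1]))
  expect_false(is.na(af$p1[3, 2]))
})

test_that("expected heterozygosity is 2p(1-p), maximal at 0.5, concave", {
  expect_equal(expected_heterozygosity(0.5), 0.5)
  expect_equal(expected_heterozygosity(1), 0)
  expect_equal(expected_heterozygosity(0.2), 0.32)
  p <- seq(0.01, 0.99, by = 0.01)
  h <- expected_heterozygosity(p)
  expect_equal(p[which.max(h)], 0.5)
  # concavity: midpoint value above the chord for random pairs
  set.seed(1)
  for (i in 1:20) {
    ab <- sort(runif(2))
    expect_gte(expected_heterozygosity(mean(ab)),
               mean(expected_heterozygosity(ab)))
  }
})

test_that("Karlsson per-SNP components match the closed formulas", {
  # maximal differentiation: fixed for opposite alleles
  k <- karlsson_snp_components(c(40, 0), c(0, 35))
  expect_equal(k$h_within, 0)
  expect_equal(k$h_between, 1)
  expect_true(k$defined)
  expect_equal(k$numerator / k$denominator, 1)
  # identical monomorphic pools: denominator 0, undefined
  k0 <- karlsson_snp_components(c(40, 0), c(35, 0))
  expect_false(k0$defined)
  # balanced polymorphism: frozen values from direct evaluation of
  # h_w = mean(2ab/(n(n-1))) and h_b = (a1 b2 + a2 b1)/(n1 n2)
  k2 <- karlsson_snp_components(c(25, 25), c(25, 25))
  expect_equal(k2$h_within, 1250 / 2450)
  expect_equal(k2$h_between, 0.5)
  expect_lt(k2$numerator, 0)     # unbiased estimator can go negative
  # n < 2 in a pool -> undefined
  expect_false(karlsson_snp_components(c(1, 0), c(20, 20))$defined)
})

test_that("window F_ST is the ratio of sums over window SNPs", {
  # one window of fixed-opposite SNPs -> fst 1; empty window -> NA
  cnt <- array(0L, dim = c(3, 6, 2))
  for (i in 1:3) { cnt[i, 1, 1] <- 30L; cnt[i, 2, 2] <- 30L }
  s <- pool_sites(rep("chr1", 3), c(100L, 400L, 900L), rep("A", 3), cnt)
  wf <- window_fst(s, min_covered_fraction = 0, chrom_lengths = c(chr1 = 2000))
  expect_equal(wf$fst[wf$start == 1], 1)
  w2 <- wf[wf$start == 1001, ]
  expect_true(is.na(w2$fst))
  expect_equal(w2$n_snps, 0L)
  # three hand-computed SNPs: ratio-of-sums equals summing components then dividing
  a1 <- c(20, 28, 5); b1 <- c(10, 2, 25)
  a2 <- c(5, 30, 18); b2 <- c(25, 0, 12)
  cnt <- array(0L, dim = c(3, 6, 2))
  cnt[, 1, 1] <- a1; cnt[, 2, 1] <- b1
  cnt[, 1, 2] <- a2; cnt[, 2, 2] <- b2
  s3 <- pool_sites(rep("chr1", 3), c(50L, 300L, 800L), rep("A", 3), cnt)
  wf3 <- window_fst(s3, min_count = 1, min_covered_fraction = 0,
                    chrom_lengths = c(chr1 = 1000))
  expect_equal(wf3$fst_raw[1],
               oracle_window_fst(a1, b1, a2, b2, c(50, 300, 800), 1),
               tolerance = 1e-12)
  # ratio-of-sums differs from mean-of-ratios here
  per_snp <- sapply(1:3, function(i)
    oracle_window_fst(a1[i], b1[i], a2[i], b2[i], 1, 1))
  expect_false(isTRUE(all.equal(wf3$fst_raw[1], mean(per_snp))))
  # unsorted input is rejected
  s_bad <- s3
  s_bad$pos <- rev(s_bad$pos)
  expect_error(window_fst(s_bad), "sorted")
})

test_that("window F_ST never exceeds 1 and is 1 only for all-fixed-opposite windows", {
  set.seed(42)
  for (r in 1:10) {
    s <- random_two_pool_sites(150, 20000)
    wf <- window_fst(s, min_count = 1, min_covered_fraction = 0,
                     chrom_lengths = c(chr1 = 20000))
    v <- wf$fst_raw[!is.na(wf$fst_raw)]
    expect_true(all(v <= 1 + 1e-12))
  }
})

test_that("covered fraction gates windows under the full-coverage convention", {
  cnt <- array(0L, dim = c(2, 6, 2))
  cnt[, 1, ] <- 20L; cnt[, 2, ] <- 20L
  s <- pool_sites(rep("chr1", 2), c(100L, 600L), rep("A", 2), cnt)
  wf <- window_fst(s, min_covered_fraction = 1, chrom_lengths = c(chr1 = 1000))
  expect_true(all(is.na(wf$fst)))      # SNP-only input can never reach fraction 1
  expect_equal(wf$covered_fraction[1], 2 / 1000)
})

test_that("pairwise F_ST matrix is symmetric, zero-diagonal, relabeling-equivariant", {
  set.seed(7)
  n <- 60
  pos <- sort(sample.int(30000, n))
  base <- rbinom(n, 30, 0.5)
  cnt <- array(0L, dim = c(n, 6, 3))
  cnt[, 1, 1] <- base; cnt[, 2, 1] <- 30L - base
  cnt[, 1, 2] <- base; cnt[, 2, 2] <- 30L - base      # pool 2 identical to pool 1
  cnt[, 2, 3] <- 30L                                  # pool 3 fixed for allele 2
  cnt[, 1, 3] <- 0L
  s <- pool_sites(rep("chr1", n), pos, rep("A", n), cnt,
                  pool_names = c("a", "b", "c"))
  m <- pairwise_fst_matrix(s, min_count = 1, chrom_lengths = c(chr1 = 30000))
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), c(0, 0, 0))
  expect_equal(m["a", "b"], 0)
  # permutation equivariance
  s2 <- s
  perm <- c(3, 1, 2)
  s2$counts <- s$counts[, , perm]
  s2$pool_names <- s$pool_names[perm]
  dimnames(s2$counts)[[3]] <- s2$pool_names
  m2 <- pairwise_fst_matrix(s2, min_count = 1, chrom_lengths = c(chr1 = 30000))
  expect_equal(m2[s2$pool_names, s2$pool_names][s$pool_names, s$pool_names],
               m[s$pool_names, s$pool_names])
})

test_that("effective population size follows the unequal-sex-ratio formula", {
  expect_equal(effective_population_size(28, 7), 22.4)
  expect_equal(effective_population_size(32, 8), 25.6)
  for (n in c(1, 5, 40)) expect_equal(effective_population_size(n, n), 2 * n)
})
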