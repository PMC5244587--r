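# Independent oracles and fixture builders shared across tests.
# Everything here is deliberately written as naive, direct code (quadratic
# loops, per-window recomputation) so it shares nothing with the package's
# vectorised implementations.

# brute-force transitive clustering of intervals by gap: O(n^2) closure
bf_cluster <- function(chrom, start, end, max_gap) {
  n <- length(start)
  if (n == 0) return(integer(0))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (chrom[i] != chrom[j]) { adj[i, j] <- FALSE; next }
    gap <- max(start[j] - end[i], start[i] - end[j], 0)
    adj[i, j] <- gap < max_gap
  }
  # transitive closure by repeated sweeps
  repeat {
    new_adj <- adj | (adj %*% adj > 0)
    if (identical(new_adj, adj)) break
    adj <- new_adj
  }
  comp <- integer(n); next_id <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      next_id <- next_id + 1L
      comp[adj[i, ]] <- next_id
    }
  }
  # canonicalise: relabel by first appearance
  as.integer(factor(comp, levels = unique(comp)))
}

# direct-formula Karlsson window F_ST, one window at a time
oracle_window_fst <- function(a1, b1, a2, b2, pos, win_start, window = 1000) {
  inw <- pos >= win_start & pos <= win_start + window - 1
  num <- den <- 0
  any_def <- FALSE
  for (i in which(inw)) {
    n1 <- a1[i] + b1[i]; n2 <- a2[i] + b2[i]
    if (n1 < 2 || n2 < 2) next
    hw <- (2 * a1[i] * b1[i] / (n1 * (n1 - 1)) +
           2 * a2[i] * b2[i] / (n2 * (n2 - 1))) / 2
    hb <- (a1[i] * b2[i] + a2[i] * b1[i]) / (n1 * n2)
    if (hb <= 0) next
    num <- num + (hb - hw); den <- den + hb
    any_def <- TRUE
  }
  if (!any_def) return(NA_real_)
  num / den
}

# random two-pool pool_sites on one chromosome with counts in the A/T slots
random_two_pool_sites <- function(n_sites, chrom_len, min_n = 12, max_n = 60) {
  pos <- sort(sample.int(chrom_len - 1, n_sites))
  cnt <- array(0L, dim = c(n_sites, 6, 2))
  for (p in 1:2) {
    n <- sample(min_n:max_n, n_sites, replace = TRUE)
    a <- rbinom(n_sites, n, runif(n_sites))
    cnt[, 1, p] <- a
    cnt[, 2, p] <- n - a
  }
  pool_sites(rep("chr1", n_sites), pos, rep("A", n_sites), cnt)
}

# 4-pool region synthesised from three known haplotypes with binomial reads;
# site classes: unique to Haplo2, unique to Haplo3, shared by both
make_hap_region <- function(n_per_class = 40, depth = 35,
                            hfreq = rbind(P1 = c(1, 0, 0),
                                          P2 = c(0.78, 0.22, 0),
                                          P3 = c(0, 0.2, 0.8),
                                          P4 = c(0.68, 0.32, 0)),
                            region_start = 1000L, region_len = 40000L) {
  n <- 3 * n_per_class
  cls <- rep(c("h2", "h3", "both"), each = n_per_class)
  pos <- sort(sample.int(region_len, n)) + region_start
  cnt <- array(0L, dim = c(n, 6, nrow(hfreq)))
  for (p in seq_len(nrow(hfreq))) {
    f <- hfreq[p, ]
    expct <- ifelse(cls == "h2", f[2], ifelse(cls == "h3", f[3], f[2] + f[3]))
    d <- rpois(n, depth)
    alt <- rbinom(n, d, expct)
    cnt[, 2, p] <- alt
    cnt[, 1, p] <- d - alt
  }
  pool_sites(rep("chrR", n), pos, rep("A", n), cnt, rownames(hfreq))
}

# toy single-chromosome genome for constructed populations
toy_genome <- function(len = 2e7, rec = 2.8, chrom = "chr1") {
  data.frame(chrom = chrom, length_bp = len, rec_cmmb = rec)
}

# two parental line populations fixed for alternative alleles at `qtl_row`,
# segregating at 0.5 elsewhere
make_f2_parent_lines <- function(n_sites = 400, n_ind = 30, qtl_row = 200L,
                                 genome = toy_genome()) {
  pos <- sort(sample.int(genome$length_bp - 1, n_sites))
  mk <- function(fixed_allele) {
    h <- matrix(as.integer(runif(n_sites * 2 * n_ind) < 0.5), n_sites, 2 * n_ind)
    h[qtl_row, ] <- fixed_allele
    sim_population(h, pos, rep(genome$chrom, n_sites), genome)
  }
  list(high = mk(1L), low = mk(0L), qtl_row = qtl_row, pos = pos)
}

# trait model list in the shape simulate_f2 expects
toy_trait_model <- function(qtl_rows, effects, ve = 4, intercept = 5,
                            sex_effect = 1, floor_zero = FALSE) {
  list(qtl_rows = qtl_rows, effects = effects, intercept = intercept,
       ve = ve, sex_effect = sex_effect, floor_zero = floor_zero)
}
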