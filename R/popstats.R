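#' Per-pool allele frequencies at the two dataset-level alleles
#'
#' Frequencies are computed from read counts of the two retained alleles only
#' (N and deletions never contribute). Pools with zero informative reads at a
#' site are flagged missing (`NA`).
#'
#' @param sites a [pool_sites] object (typically already coverage-filtered).
#' @param min_count passed to [biallelic_counts()].
#' @return list with `p1` (matrix sites x pools, frequency of the dataset
#'   major allele), `p_major` (per-pool major-allele frequency,
#'   `pmax(p1, 1 - p1)`), `n` (informative coverage) and the `biallelic_counts`
#'   fields `allele1`, `allele2`, `is_snp`.
#' @export
allele_frequencies <- function(sites, min_count = 3) {
  bc <- biallelic_counts(sites, min_count)
  p1 <- ifelse(bc$n > 0, bc$a / bc$n, NA_real_)
  if (!is.matrix(p1)) p1 <- matrix(p1, nrow = length(bc$allele1))
  list(p1 = p1, p_major = pmax(p1, 1 - p1), n = bc$n,
       allele1 = bc$allele1, allele2 = bc$allele2, is_snp = bc$is_snp)
}

#' Expected heterozygosity 2p(1-p)
#'
#' @param p allele frequency in `[0, 1]` (vectorised).
#' @return numeric in `[0, 0.5]`.
#' @export
expected_heterozygosity <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  2 * p * (1 - p)
}

#' Per-SNP components of the Karlsson ratio-of-sums F_ST estimator
#'
#' For two pools with counts `a_i`, `b_i` of the two alleles and informative
#' coverage `n_i = a_i + b_i`, the unbiased within-pool heterozygosity is
#' `2 a_i b_i / (n_i (n_i - 1))` (mean over the two pools) and the
#' between-pool heterozygosity is `(a1 b2 + a2 b1) / (n1 n2)`. The per-SNP
#' contribution to windowed F_ST is `numerator = h_between - h_within` over
#' `denominator = h_between`; windows are summed as ratio-of-sums. Components
#' are returned unclamped (the numerator may be negative). Sites with
#' `n_i < 2` in either pool, or with `denominator == 0` (both pools
#' monomorphic for the same allele), are undefined.
#'
#' @param counts1,counts2 length-2 numeric vectors `(a, b)`, or equal-length
#'   vectors `a1, b1, a2, b2` via the matrix interface below.
#' @return list with `h_within`, `h_between`, `numerator`, `denominator`,
#'   `defined` (logical).
#' @export
karlsson_snp_components <- function(counts1, counts2) {
  a1 <- counts1[[1]]; b1 <- counts1[[2]]
  a2 <- counts2[[1]]; b2 <- counts2[[2]]
  n1 <- a1 + b1; n2 <- a2 + b2
  ok <- n1 >= 2 & n2 >= 2
  h_w <- ifelse(ok, (2 * a1 * b1 / (n1 * (n1 - 1)) +
                     2 * a2 * b2 / (n2 * (n2 - 1))) / 2, NA_real_)
  h_b <- ifelse(ok, (a1 * b2 + a2 * b1) / (n1 * n2), NA_real_)
  defined <- ok & !is.na(h_b) & h_b > 0
  list(h_within = h_w, h_between = h_b,
       numerator = h_b - h_w, denominator = h_b, defined = defined)
}

# internal: window tiling anchored at position 1; final partial window dropped
.tile_windows <- function(chrom_len, window, step) {
  if (chrom_len < window) return(numeric(0))
  seq(1, chrom_len - window + 1, by = step)
}

#' Sliding-window F_ST between two pools
#'
#' Karlsson ratio-of-sums F_ST over fixed-width sliding windows (default
#' 1000 bp with 50% overlap). Per window, `fst = sum(num) / sum(den)` over the
#' SNPs with defined components; the raw ratio is kept in `fst_raw` and
#' `fst` is floored at 0. Windows failing the coverage fraction, or with no
#' defined SNPs, carry `fst = NA`. Windows tile each chromosome from position
#' 1 at the given step; a final partial window is dropped.
#'
#' @param sites a [pool_sites] object sorted by (chrom, pos).
#' @param pools length-2 integer or character vector selecting the pool pair.
#' @param window,step window width and step in bp.
#' @param min_count minimum summed allele count for SNP classification.
#' @param min_covered_fraction minimum fraction of window positions with
#'   coverage inside the filter bounds in both pools (1 per the full-coverage
#'   convention; set 0 for SNP-only input where invariant positions are not
#'   in the file).
#' @param params [site_filter_params()] supplying the coverage bounds used for
#'   the covered fraction.
#' @param chrom_lengths optional named vector of chromosome lengths; defaults
#'   to the last site position per chromosome.
#' @return data.frame with columns chrom, start, end, n_snps,
#'   covered_fraction, fst, fst_raw.
#' @export
window_fst <- function(sites, pools = c(1, 2), window = 1000, step = 500,
                       min_count = 3, min_covered_fraction = 1,
                       params = site_filter_params(),
                       chrom_lengths = NULL) {
  stopifnot(inherits(sites, "pool_sites"), length(pools) == 2)
  if (is.character(pools)) pools <- match(pools, sites$pool_names)
  n <- length(sites$pos)
  if (n > 1) {
    same <- sites$chrom[-1] == sites$chrom[-n]
    if (any(same & diff(sites$pos) < 0)) stop("sites must be sorted by (chrom, pos)")
    if (anyDuplicated(rle(sites$chrom)$values)) stop("sites must be grouped by chromosome")
  }
  bc <- biallelic_counts(sites, min_count)
  comp <- karlsson_snp_components(list(bc$a[, pools[1]], bc$b[, pools[1]]),
                                  list(bc$a[, pools[2]], bc$b[, pools[2]]))
  use <- bc$is_snp & comp$defined
  cov <- pool_coverage(sites)[, pools, drop = FALSE]
  covered <- rowSums(cov > params$min_cov & cov < params$max_cov) == 2L

  chroms <- unique(sites$chrom)
  out <- vector("list", length(chroms))
  for (k in seq_along(chroms)) {
    cc <- chroms[k]
    in_c <- sites$chrom == cc
    clen <- if (!is.null(chrom_lengths)) chrom_lengths[[cc]] else max(sites$pos[in_c])
    starts <- .tile_windows(clen, window, step)
    if (length(starts) == 0L) next
    nw <- length(starts)
    num <- den <- nsnp <- ncov <- numeric(nw)
    pos_c <- sites$pos[in_c]
    # map each site to the (at most ceiling(window/step)) windows containing it
    w_hi <- pmin(floor((pos_c - 1) / step), nw - 1)       # last window index (0-based)
    w_lo <- pmax(ceiling((pos_c - window) / step), 0)
    use_c <- use[in_c]; cov_c <- covered[in_c]
    num_c <- comp$numerator[in_c]; den_c <- comp$denominator[in_c]
    for (o in 0:(ceiling(window / step) - 1)) {
      w <- w_hi - o
      ok <- w >= w_lo & w >= 0
      if (!any(ok)) next
      wi <- w[ok] + 1L
      ncov <- ncov + tabulate(wi[cov_c[ok]], nbins = nw)
      sel <- ok & use_c
      if (any(sel)) {
        wj <- w[sel] + 1L
        nsnp <- nsnp + tabulate(wj, nbins = nw)
        agg <- rowsum(cbind(num_c[sel], den_c[sel]), group = wj)
        at <- as.integer(rownames(agg))
        num[at] <- num[at] + agg[, 1]
        den[at] <- den[at] + agg[, 2]
      }
    }
    frac <- ncov / window
    fst_raw <- ifelse(den > 0 & frac >= min_covered_fraction, num / den, NA_real_)
    out[[k]] <- data.frame(chrom = cc, start = starts, end = starts + window - 1,
                           n_snps = as.integer(nsnp), covered_fraction = frac,
                           fst = pmax(fst_raw, 0), fst_raw = fst_raw)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(chrom = character(0), start = numeric(0),
                                      end = numeric(0), n_snps = integer(0),
                                      covered_fraction = numeric(0),
                                      fst = numeric(0), fst_raw = numeric(0))
  rownames(res) <- NULL
  res
}

#' Pairwise mean window F_ST between all pools in a region
#'
#' Symmetric matrix of the mean (floored) window F_ST over all defined windows
#' for each pool pair, optionally restricted to a region.
#'
#' @param sites a [pool_sites] object.
#' @param pools pools to include (default all).
#' @param region optional list/vector `(chrom, start, end)` restricting sites.
#' @param ... passed to [window_fst()] (`min_covered_fraction` defaults to 0
#'   here: region slices are SNP-only in practice).
#' @return numeric matrix (pools x pools), diagonal 0; `NA` entries where no
#'   window is defined.
#' @export
pairwise_fst_matrix <- function(sites, pools = NULL, region = NULL, ...) {
  stopifnot(inherits(sites, "pool_sites"))
  if (is.null(pools)) pools <- seq_along(sites$pool_names)
  if (is.character(pools)) pools <- match(pools, sites$pool_names)
  if (length(pools) < 2) stop("need at least two pools")
  if (!is.null(region)) {
    keep <- sites$chrom == region[[1]] &
      sites$pos >= as.numeric(region[[2]]) & sites$pos <= as.numeric(region[[3]])
    sites <- sites[keep]
  }
  args <- list(...)
  if (is.null(args$min_covered_fraction)) args$min_covered_fraction <- 0
  k <- length(pools)
  m <- matrix(0, k, k, dimnames = list(sites$pool_names[pools],
                                       sites$pool_names[pools]))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    wf <- do.call(window_fst, c(list(sites = sites, pools = pools[c(i, j)]), args))
    v <- wf$fst[!is.na(wf$fst)]
    m[i, j] <- m[j, i] <- if (length(v)) mean(v) else NA_real_
  }
  m
}

#' Effective population size under unequal sex ratio
#'
#' `Ne = 4 Nf Nm / (Nf + Nm)` for `Nf` breeding females and `Nm` breeding
#' males per generation.
#'
#' @param n_females,n_males breeding parents per sex (>= 1).
#' @return numeric Ne.
#' @examples
#' effective_population_size(28, 7)  # 22.4
#' effective_population_size(32, 8)  # 25.6
#' @export
effective_population_size <- function(n_females, n_males) {
  stopifnot(n_females >= 1, n_males >= 1)
  4 * n_females * n_males / (n_females + n_males)
}
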