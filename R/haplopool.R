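#' Slice a pool_sites object to a genomic region
#'
#' @param sites a [pool_sites] object.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive bounds.
#' @return the [pool_sites] subset.
#' @export
region_sites <- function(sites, chrom, start, end) {
  sites[sites$chrom == chrom & sites$pos >= start & sites$pos <= end]
}

#' Find the pool fixed for one haplotype across a region
#'
#' Within a candidate sweep region, haplotype inference requires a reference
#' pool that is (nearly) fixed: the pool whose major-allele frequency is at
#' least `fix_tol` at the largest fraction of SNP sites. The search fails
#' when no pool is fixed at at least `min_frac` of the sites.
#'
#' @param sites [pool_sites] restricted to the region (see [region_sites()]).
#' @param fix_tol per-site fixation tolerance (default 0.95; pooled read
#'   counts at 30-35x carry sampling noise, so 1.0 is too strict).
#' @param min_frac minimum fraction of sites fixed (default 0.9).
#' @param min_sites minimum SNP sites required in the region (default 10).
#' @param min_count SNP classification threshold.
#' @return list: `status` ("ok" or "no reference haplotype"), `pool` (index
#'   or NA), `pool_name`, `frac_fixed` (per-pool fractions).
#' @export
find_reference_pool <- function(sites, fix_tol = 0.95, min_frac = 0.9,
                                min_sites = 10, min_count = 3) {
  af <- allele_frequencies(sites, min_count)
  snp <- af$is_snp
  if (sum(snp) < min_sites)
    stop(sprintf("region has %d SNP sites; need at least %d", sum(snp), min_sites))
  pm <- af$p_major[snp, , drop = FALSE]
  frac <- colMeans(pm >= fix_tol, na.rm = TRUE)
  names(frac) <- sites$pool_names
  best <- which.max(frac)
  if (frac[best] < min_frac) {
    return(list(status = "no reference haplotype", pool = NA_integer_,
                pool_name = NA_character_, frac_fixed = frac))
  }
  list(status = "ok", pool = unname(best), pool_name = sites$pool_names[best],
       frac_fixed = frac)
}

#' Polarize pooled frequencies against a reference haplotype
#'
#' Re-expresses every pool's allele frequency as the frequency of the allele
#' NOT carried by the reference pool's (fixed) haplotype, so the reference
#' pool sits near 0 everywhere and alternative haplotypes appear as bands of
#' elevated frequency. Sites where the reference pool is not fixed within
#' `fix_tol`, or has missing frequency, are dropped (the sequential ad hoc
#' position filter).
#'
#' @param sites [pool_sites] restricted to the region.
#' @param reference_pool pool index or name (e.g. from
#'   [find_reference_pool()]).
#' @param fix_tol reference fixation tolerance (default 0.95).
#' @param min_count SNP classification threshold.
#' @return a `polarized_region`: list with chrom, pos, `pfreq` (matrix sites x
#'   pools of polarized frequencies in `[0,1]`), `reference_pool`,
#'   `pool_names`.
#' @export
polarize <- function(sites, reference_pool, fix_tol = 0.95, min_count = 3) {
  if (is.character(reference_pool))
    reference_pool <- match(reference_pool, sites$pool_names)
  af <- allele_frequencies(sites, min_count)
  p_ref <- af$p1[, reference_pool]
  keep <- af$is_snp & !is.na(p_ref) & pmax(p_ref, 1 - p_ref) >= fix_tol
  p1 <- af$p1[keep, , drop = FALSE]
  ref_is_allele1 <- p_ref[keep] >= 0.5
  pf <- ifelse(matrix(ref_is_allele1, nrow(p1), ncol(p1)), 1 - p1, p1)
  structure(list(chrom = sites$chrom[keep], pos = sites$pos[keep],
                 pfreq = pf, reference_pool = reference_pool,
                 pool_names = sites$pool_names),
            class = "polarized_region")
}

#' @export
print.polarized_region <- function(x, ...) {
  cat(sprintf("<polarized_region> %d sites x %d pools (reference: %s)\n",
              nrow(x$pfreq), ncol(x$pfreq), x$pool_names[x$reference_pool]))
  invisible(x)
}

# candidate assignments of c site classes to subsets of k_alt = 2 alternative
# haplotypes; each subset is an indicator row of the class design matrix
.class_designs <- function(c_classes) {
  if (c_classes == 1) return(list(matrix(1, 1, 1)))   # one alternative haplotype
  if (c_classes == 2) {
    return(list(rbind(c(1, 0), c(0, 1)),      # two disjoint haplotypes
                rbind(c(1, 0), c(1, 1)),      # nested: class 2 shared
                rbind(c(1, 1), c(0, 1))))     # nested: class 1 shared
  }
  list(rbind(c(1, 0), c(0, 1), c(1, 1)),
       rbind(c(1, 0), c(1, 1), c(0, 1)),
       rbind(c(1, 1), c(1, 0), c(0, 1)))
}

#' Infer major haplotypes and their pool frequencies
#'
#' Groups the polarized site frequencies into at most `k_max - 1` + 1
#' frequency bands by k-means over the site-by-pool frequency matrix (so
#' bands are matched across pools by shared site membership, not by
#' frequency value), assigns each band a subset of the alternative
#' haplotypes (a site carried by two alternative haplotypes shows a band at
#' the sum of their frequencies), and solves the per-pool haplotype
#' frequencies by weighted least squares with the reference haplotype as the
#' complement.
#'
#' @param polarized a `polarized_region` from [polarize()].
#' @param k_max maximum number of haplotypes including the reference
#'   (default 3, i.e. up to two alternative haplotypes).
#' @param freq_tol band resolution tolerance: cluster centers closer than
#'   this in every pool are merged, and a model whose residual scale exceeds
#'   it is flagged ambiguous (default 0.15).
#' @param min_band_sites minimum informative sites per band (default 5);
#'   smaller bands are merged into their neighbour (by reducing k).
#' @return a `haplotype_model`: `freq` (pools x haplotypes matrix, Haplo1 =
#'   reference complement), `site_class` (band of each site),
#'   `class_subsets` (which alternative haplotypes each band tracks),
#'   `ambiguous` flag and `rss`.
#' @export
infer_haplotypes <- function(polarized, k_max = 3, freq_tol = 0.15,
                             min_band_sites = 5) {
  stopifnot(inherits(polarized, "polarized_region"), k_max >= 2)
  P <- polarized$pfreq
  n_pool <- ncol(P)
  if (nrow(P) < 2 * min_band_sites)
    stop("too few polarized sites to resolve haplotype bands")
  k_alt_max <- min(k_max - 1, 2)
  c_max <- if (k_alt_max == 1) 1L else 3L

  pick <- NULL
  for (k in rev(seq_len(c_max))) {
    km <- suppressWarnings(kmeans(P, centers = min(k, nrow(unique(P))),
                                  nstart = 10, iter.max = 50))
    if (length(km$size) < k) next
    if (min(km$size) < min_band_sites) next
    ok_sep <- TRUE
    if (k > 1) {
      d <- as.matrix(dist(km$centers, method = "maximum"))
      ok_sep <- min(d[upper.tri(d)]) > freq_tol
    }
    if (!ok_sep) next
    pick <- km
    break
  }
  if (is.null(pick)) {
    km <- kmeans(P, centers = 1)
    pick <- km
  }
  cc <- length(pick$size)
  centers <- matrix(pick$centers, nrow = cc)
  w <- pick$size

  designs <- if (k_alt_max == 1) list(matrix(1, 1, 1)) else .class_designs(cc)
  best <- NULL
  for (A in designs) {
    k_alt <- ncol(A)
    f <- matrix(0, n_pool, k_alt)
    rss <- 0
    AtWA <- t(A) %*% (w * A)
    for (j in seq_len(n_pool)) {
      sol <- tryCatch(solve(AtWA, t(A) %*% (w * centers[, j])),
                      error = function(e) NULL)
      if (is.null(sol)) { rss <- Inf; break }
      fj <- pmin(pmax(drop(sol), 0), 1)
      if (sum(fj) > 1) fj <- fj / sum(fj)
      f[j, ] <- fj
      rss <- rss + sum(w * (centers[, j] - drop(A %*% fj))^2)
    }
    if (is.null(best) || rss < best$rss)
      best <- list(rss = rss, f = f, A = A)
  }
  resid_scale <- sqrt(best$rss / (sum(w) * n_pool))
  freq <- cbind(pmax(1 - rowSums(best$f), 0), best$f)
  k_alt <- ncol(best$f)
  colnames(freq) <- paste0("Haplo", seq_len(1 + k_alt))
  rownames(freq) <- polarized$pool_names
  subsets <- lapply(seq_len(nrow(best$A)), function(i) which(best$A[i, ] == 1) + 1L)
  structure(list(freq = freq, site_class = pick$cluster,
                 class_subsets = subsets,
                 ambiguous = resid_scale > freq_tol, rss = best$rss,
                 reference_pool = polarized$reference_pool),
            class = "haplotype_model")
}

#' @export
print.haplotype_model <- function(x, ...) {
  cat(sprintf("<haplotype_model> %d haplotypes%s\n", ncol(x$freq),
              if (x$ambiguous) " (AMBIGUOUS fit)" else ""))
  print(round(x$freq, 3))
  invisible(x)
}

#' Pairwise mean F_ST between pools across a region
#'
#' Convenience wrapper around [pairwise_fst_matrix()] for a region slice.
#'
#' @param sites full [pool_sites] object.
#' @param chrom,start,end region coordinates (1-based inclusive).
#' @param ... passed to [pairwise_fst_matrix()].
#' @return symmetric matrix of mean window F_ST.
#' @export
region_fst_table <- function(sites, chrom, start, end, ...) {
  pairwise_fst_matrix(sites, region = list(chrom, start, end), ...)
}
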