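#' Percentile cutoff of the window F_ST distribution
#'
#' Linear interpolation between order statistics (quantile type 7), computed
#' over defined windows only. Window F_ST values above this cutoff (strictly)
#' are candidates for sweep regions.
#'
#' When more than the top percentile of windows ties at the distribution's
#' maximum (e.g. many windows fully fixed for alternative alleles in a
#' strongly selected experiment), the percentile equals the maximum and a
#' strict comparison would retain nothing; the cutoff then steps down to the
#' largest distinct value below the maximum so that the extreme class is
#' kept. If all windows are equal there is nothing to step down to and the
#' common value is returned.
#'
#' @param windows data.frame from [window_fst()].
#' @param percentile cutoff percentile (default 95).
#' @return the cutoff value.
#' @export
fst_cutoff <- function(windows, percentile = 95) {
  stopifnot(percentile > 0, percentile < 100)
  v <- windows$fst[!is.na(windows$fst)]
  if (length(v) == 0L) stop("no defined windows")
  ct <- unname(quantile(v, percentile / 100, type = 7))
  mx <- max(v)
  if (ct == mx && any(v < mx)) ct <- max(v[v < mx])
  ct
}

#' Cluster extreme-F_ST windows into candidate sweep regions
#'
#' Windows with `fst > cutoff` (strict) are grouped transitively when the gap
#' between the end of one retained window and the start of the next is
#' strictly less than `max_gap`; clusters never span chromosomes. Region SNP
#' counts sum the SNPs of the retained windows only. Overlapping windows are
#' merged naturally (negative gaps).
#'
#' @param windows data.frame from [window_fst()], sorted by (chrom, start).
#' @param cutoff F_ST cutoff, e.g. from [fst_cutoff()].
#' @param max_gap clustering distance in bp (default 5e5).
#' @return data.frame of regions: chrom, start, end, n_windows, n_snps,
#'   max_fst, mean_fst.
#' @export
cluster_windows <- function(windows, cutoff, max_gap = 5e5) {
  keep <- !is.na(windows$fst) & windows$fst > cutoff
  w <- windows[keep, , drop = FALSE]
  if (nrow(w) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      n_windows = integer(0), n_snps = integer(0),
                      max_fst = numeric(0), mean_fst = numeric(0)))
  }
  cl <- cluster_by_gap(w$chrom, w$start, w$end, max_gap)
  cl <- factor(cl, levels = unique(cl))   # keep genomic order, not lexicographic
  regions <- data.frame(
    chrom = tapply(w$chrom, cl, `[`, 1),
    start = tapply(w$start, cl, min),
    end = tapply(w$end, cl, max),
    n_windows = as.integer(tapply(w$start, cl, length)),
    n_snps = as.integer(tapply(w$n_snps, cl, sum)),
    max_fst = tapply(w$fst, cl, max),
    mean_fst = tapply(w$fst, cl, mean)
  )
  rownames(regions) <- NULL
  regions
}

#' Remove weakly supported sweep regions
#'
#' Drops clusters made of a single window or containing fewer than `min_snps`
#' SNPs.
#'
#' @param regions data.frame from [cluster_windows()].
#' @param min_windows,min_snps retention thresholds (defaults 2 and 2).
#' @return the filtered region data.frame.
#' @export
filter_regions <- function(regions, min_windows = 2, min_snps = 2) {
  regions[regions$n_windows >= min_windows & regions$n_snps >= min_snps, ,
          drop = FALSE]
}

#' Summary statistics of a sweep-region set
#'
#' @param regions region data.frame (disjoint).
#' @param genome_size total genome size in bp (> 0).
#' @return list: n_regions, total_span, pct_genome, mean_length,
#'   median_length, min_length, max_length. Lengths are `end - start`.
#' @export
region_summary <- function(regions, genome_size) {
  stopifnot(genome_size > 0)
  len <- regions$end - regions$start
  if (length(len) == 0L) {
    return(list(n_regions = 0L, total_span = 0, pct_genome = 0,
                mean_length = 0, median_length = 0,
                min_length = 0, max_length = 0))
  }
  list(n_regions = nrow(regions), total_span = sum(len),
       pct_genome = 100 * sum(len) / genome_size,
       mean_length = mean(len), median_length = median(len),
       min_length = min(len), max_length = max(len))
}

#' Heterozygosity inside sweep regions relative to genome-wide
#'
#' Per pool: the mean expected heterozygosity `2p(1-p)` over SNPs inside the
#' regions, the mean over all SNPs, and their ratio. `p` is the pool's
#' frequency of the dataset major allele.
#'
#' @param sites a [pool_sites] object (coverage-filtered).
#' @param regions region data.frame (chrom, start, end).
#' @param min_count SNP classification threshold.
#' @return data.frame with one row per pool: pool, sweep_het, genome_het,
#'   ratio. Ratio is `NA` when no SNP falls inside the regions.
#' @export
sweep_het_ratio <- function(sites, regions, min_count = 3) {
  af <- allele_frequencies(sites, min_count)
  snp <- af$is_snp & rowSums(is.na(af$p1)) == 0
  in_region <- rep(FALSE, length(sites$pos))
  for (r in seq_len(nrow(regions))) {
    in_region <- in_region | (sites$chrom == regions$chrom[r] &
                              sites$pos >= regions$start[r] &
                              sites$pos <= regions$end[r])
  }
  het <- expected_heterozygosity(af$p1)
  if (!is.matrix(het)) het <- matrix(het, ncol = length(sites$pool_names))
  genome_het <- colMeans(het[snp, , drop = FALSE])
  sweep_idx <- snp & in_region
  sweep_het <- if (any(sweep_idx)) colMeans(het[sweep_idx, , drop = FALSE])
               else rep(NA_real_, ncol(het))
  data.frame(pool = sites$pool_names, sweep_het = sweep_het,
             genome_het = genome_het, ratio = sweep_het / genome_het,
             row.names = NULL)
}

#' Export regions as BED
#'
#' BED uses 0-based half-open coordinates; internal regions are 1-based
#' inclusive, so `start - 1` is written.
#'
#' @param regions region data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
regions_to_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = as.integer(regions$start - 1),
                    end = as.integer(regions$end))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Intersect regions with an external interval set
#'
#' Generic overlap utility (e.g. against a catalogue of previously reported
#' trait-associated intervals read from BED).
#'
#' @param regions region data.frame (1-based inclusive).
#' @param other data.frame with chrom, start, end (1-based inclusive).
#' @return `regions` with an added `n_overlaps` column.
#' @export
intersect_regions <- function(regions, other) {
  n_overlaps <- vapply(seq_len(nrow(regions)), function(i) {
    sum(other$chrom == regions$chrom[i] &
        other$start <= regions$end[i] &
        other$end >= regions$start[i])
  }, integer(1))
  cbind(regions, n_overlaps = n_overlaps)
}

#' Read a BED file into 1-based inclusive intervals
#'
#' @param path BED file (0-based half-open).
#' @return data.frame chrom, start, end (1-based inclusive).
#' @export
read_bed <- function(path) {
  bed <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end"),
                    colClasses = c("character", "numeric", "numeric"))
  data.frame(chrom = bed$chrom, start = bed$start + 1, end = bed$end)
}
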