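#' Pooled allele-count container
#'
#' The atomic data structure of the package: per-site, per-pool read counts of
#' the four nucleotides plus N and deletion, as produced from an mpileup of
#' pooled libraries. Counts are stored as an integer array with dimensions
#' (sites, 6, pools); the 6 count slots are ordered A, T, C, G, N, del as in
#' the PoPoolation2 sync exchange format. Positions are 1-based inclusive.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions.
#' @param ref character vector of reference bases.
#' @param counts integer array, dim (n_sites, 6, n_pools), all entries >= 0.
#' @param pool_names optional character vector naming the pools.
#' @return an object of class `pool_sites`.
#' @export
pool_sites <- function(chrom, pos, ref, counts, pool_names = NULL) {
  n <- length(pos)
  stopifnot(length(chrom) == n, length(ref) == n,
            is.array(counts), length(dim(counts)) == 3L,
            dim(counts)[1] == n, dim(counts)[2] == 6L)
  if (any(counts < 0)) stop("negative read counts")
  storage.mode(counts) <- "integer"
  n_pools <- dim(counts)[3]
  if (is.null(pool_names)) pool_names <- paste0("pool", seq_len(n_pools))
  stopifnot(length(pool_names) == n_pools)
  dimnames(counts) <- list(NULL, c("A", "T", "C", "G", "N", "del"), pool_names)
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = as.character(ref), counts = counts,
                 pool_names = pool_names),
            class = "pool_sites")
}

#' @export
print.pool_sites <- function(x, ...) {
  cat(sprintf("<pool_sites> %d sites, %d pools (%s)\n",
              length(x$pos), length(x$pool_names),
              paste(x$pool_names, collapse = ", ")))
  invisible(x)
}

#' @export
length.pool_sites <- function(x) length(x$pos)

#' Subset sites of a pool_sites object
#'
#' @param x a `pool_sites` object.
#' @param i site index (logical or integer).
#' @param ... unused.
#' @return a `pool_sites` object with the selected sites.
#' @export
`[.pool_sites` <- function(x, i, ...) {
  pool_sites(x$chrom[i], x$pos[i], x$ref[i],
             x$counts[i, , , drop = FALSE], x$pool_names)
}

#' Per-pool site coverage
#'
#' Coverage is the sum of all six count slots (A, T, C, G, N, del) in a pool.
#'
#' @param sites a `pool_sites` object.
#' @return integer matrix (sites x pools).
#' @export
pool_coverage <- function(sites) {
  n <- length(sites$pos)
  n_pools <- dim(sites$counts)[3]
  out <- matrix(0L, n, n_pools, dimnames = list(NULL, sites$pool_names))
  for (p in seq_len(n_pools))
    out[, p] <- as.integer(rowSums(sites$counts[, , p, drop = FALSE]))
  out
}

#' Read a PoPoolation2 sync file
#'
#' One whitespace-separated row per site: chromosome, position, reference
#' base, then one `A:T:C:G:N:del` count string per pool.
#'
#' @param path file to read.
#' @param pool_names optional pool names (defaults to pool1, pool2, ...).
#' @return a [pool_sites] object, rows in file order.
#' @export
read_sync <- function(path, pool_names = NULL) {
  if (!file.exists(path)) stop("sync file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(pool_sites(character(0), integer(0), character(0),
                      array(integer(0), dim = c(0, 6, max(1, length(pool_names)))),
                      pool_names))
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != nf[1]) || nf[1] < 4L) {
    bad <- which(nf != nf[1] | nf < 4L)[1]
    stop(sprintf("sync parse error at line %d: expected %d fields, found %d",
                 bad, max(nf[1], 4L), nf[bad]))
  }
  n_pools <- nf[1] - 3L
  m <- matrix(unlist(fields), ncol = nf[1], byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos)) stop(sprintf("sync parse error at line %d: non-integer position",
                               which(is.na(pos))[1]))
  cnt <- array(NA_integer_, dim = c(nrow(m), 6, n_pools))
  for (p in seq_len(n_pools)) {
    parts <- strsplit(m[, 3L + p], ":", fixed = TRUE)
    if (any(lengths(parts) != 6L)) {
      bad <- which(lengths(parts) != 6L)[1]
      stop(sprintf("sync parse error at line %d: count field must have 6 entries", bad))
    }
    v <- suppressWarnings(as.integer(unlist(parts)))
    if (anyNA(v)) {
      bad <- ceiling(which(is.na(v))[1] / 6)
      stop(sprintf("sync parse error at line %d: non-integer count", bad))
    }
    cnt[, , p] <- matrix(v, ncol = 6, byrow = TRUE)
  }
  pool_sites(m[, 1], pos, m[, 3], cnt, pool_names)
}

#' Write a PoPoolation2 sync file
#'
#' Inverse of [read_sync()]: `read_sync(write_sync(x, f))` reproduces `x`.
#'
#' @param sites a [pool_sites] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sync <- function(sites, path) {
  stopifnot(inherits(sites, "pool_sites"))
  n <- length(sites$pos)
  n_pools <- dim(sites$counts)[3]
  cols <- vapply(seq_len(n_pools), function(p) {
    apply(sites$counts[, , p, drop = FALSE], 1,
          function(v) paste(v, collapse = ":"))
  }, character(n))
  if (n == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- do.call(paste, c(list(sites$chrom, sites$pos, sites$ref),
                            asplit(matrix(cols, nrow = n), 2),
                            sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Site filter parameters
#'
#' Coverage bounds are exclusive on both sides, reading ">10 and <100 reads"
#' and the window-F_ST tool's "minimum coverage 10 / maximum coverage 100" as
#' one rule. `min_count` is the minimum read count (summed across pools) for
#' an allele to be considered present when classifying a site as a SNP.
#'
#' @param min_cov exclusive lower coverage bound (default 10).
#' @param max_cov exclusive upper coverage bound (default 100).
#' @param min_count minimum allele count (default 3).
#' @return a `site_filter_params` list.
#' @export
site_filter_params <- function(min_cov = 10, max_cov = 100, min_count = 3) {
  stopifnot(min_cov < max_cov, min_count >= 1)
  structure(list(min_cov = min_cov, max_cov = max_cov, min_count = min_count),
            class = "site_filter_params")
}

#' Filter sites on per-pool coverage
#'
#' Retains sites whose coverage lies strictly between `min_cov` and `max_cov`
#' in every pool. Order-preserving and idempotent.
#'
#' @param sites a [pool_sites] object.
#' @param params a [site_filter_params] object.
#' @return the filtered [pool_sites] object.
#' @export
filter_sites <- function(sites, params = site_filter_params()) {
  stopifnot(inherits(sites, "pool_sites"), inherits(params, "site_filter_params"))
  cov <- pool_coverage(sites)
  keep <- rowSums(cov > params$min_cov & cov < params$max_cov) == ncol(cov)
  sites[keep]
}

#' Reduce sites to the two highest-count alleles
#'
#' Multi-allelic sites are reduced to the two alleles with the highest counts
#' summed across pools; ties are broken by the fixed base order A < T < C < G.
#' N and deletion counts contribute to coverage but never to alleles. A site
#' is classified as a SNP when both retained alleles reach `min_count` summed
#' across pools.
#'
#' @param sites a [pool_sites] object.
#' @param min_count minimum summed count for an allele to be present.
#' @return list with elements `allele1`, `allele2` (character, per site;
#'   `allele1` is the dataset-level major allele), `a`, `b` (integer matrices,
#'   sites x pools, counts of allele1 / allele2), `n` (informative coverage
#'   `a + b`) and `is_snp` (logical).
#' @export
biallelic_counts <- function(sites, min_count = 3) {
  stopifnot(inherits(sites, "pool_sites"))
  n <- length(sites$pos)
  n_pools <- dim(sites$counts)[3]
  base_counts <- sites$counts[, 1:4, , drop = FALSE]    # A,T,C,G only
  tot <- rowSums(base_counts, dims = 2)                 # sites x 4, summed over pools
  if (n == 0L) {
    em <- matrix(integer(0), 0, n_pools)
    return(list(allele1 = character(0), allele2 = character(0),
                a = em, b = em, n = em, is_snp = logical(0)))
  }
  if (!is.matrix(tot)) tot <- matrix(tot, n, 4)
  # top two alleles by summed count; ties broken by base order A<T<C<G
  i1 <- max.col(tot, ties.method = "first")
  tot2 <- tot
  tot2[cbind(seq_len(n), i1)] <- -1L
  i2 <- max.col(tot2, ties.method = "first")
  bases <- c("A", "T", "C", "G")
  idx <- function(k) cbind(seq_len(n), k)
  a <- b <- matrix(0L, n, n_pools)
  for (p in seq_len(n_pools)) {
    cp <- base_counts[, , p]
    if (n == 1L) cp <- matrix(cp, 1, 4)
    a[, p] <- cp[idx(i1)]
    b[, p] <- cp[idx(i2)]
  }
  present1 <- tot[idx(i1)] >= min_count
  present2 <- tot[idx(i2)] >= min_count
  list(allele1 = bases[i1], allele2 = bases[i2],
       a = a, b = b, n = a + b,
       is_snp = present1 & present2)
}
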