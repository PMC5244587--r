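#' Single-linkage clustering of genomic intervals by gap distance
#'
#' Groups sorted intervals (or points, where `start == end`) transitively:
#' two consecutive intervals on the same chromosome join one cluster when the
#' gap between the end of the first and the start of the next is strictly
#' less than `max_gap`. Clusters never span chromosomes.
#'
#' @param chrom character or factor vector of chromosome names.
#' @param start,end numeric interval bounds (points: pass the position twice).
#' @param max_gap numeric; strict upper bound on the joining gap (bp).
#' @return integer vector of cluster ids (1-based, in input order). Input must
#'   be sorted by (chrom, start); an error is raised otherwise.
#' @export
cluster_by_gap <- function(chrom, start, end, max_gap) {
  n <- length(start)
  stopifnot(length(chrom) == n, length(end) == n, max_gap > 0)
  if (n == 0L) return(integer(0))
  chrom <- as.character(chrom)
  same <- if (n > 1L) chrom[-1L] == chrom[-n] else logical(0)
  if (anyDuplicated(rle(chrom)$values))
    stop("intervals must be grouped by chromosome")
  if (any(same & start[-1L] < start[-n]))
    stop("intervals must be sorted by start within chromosome")
  new_cluster <- c(TRUE, !same | (start[-1L] - end[-n] >= max_gap))
  cumsum(new_cluster)
}

#' Distance from a point to a genomic interval
#'
#' Zero when the position lies inside `[start, end]`, otherwise the distance
#' to the nearest interval edge.
#'
#' @param pos numeric position(s), bp.
#' @param start,end interval bounds, bp.
#' @return numeric distance(s) in bp.
#' @export
distance_to_region <- function(pos, start, end) {
  stopifnot(all(end >= start))
  pmax(start - pos, pos - end, 0)
}

# internal: validate single positive scalar
.scalar <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower)
    stop(sprintf("'%s' must be a single number >= %s", name, lower))
  x
}
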