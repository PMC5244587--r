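#' Subset markers by pooled allele-frequency difference
#'
#' Retains markers whose between-line pooled allele-frequency difference
#' exceeds `delta` strictly (`delta_p > delta`), the rule used to focus the
#' association analysis on markers tagging divergent sweep regions.
#'
#' @param panel a [marker_panel].
#' @param delta strict lower bound on `delta_p` (default 0.7).
#' @return the filtered [marker_panel].
#' @export
differentiated_marker_subset <- function(panel, delta = 0.7) {
  stopifnot(inherits(panel, "marker_panel"))
  keep <- panel$markers$delta_p > delta
  marker_panel(panel$markers[keep, , drop = FALSE],
               panel$geno[, keep, drop = FALSE],
               panel$individuals)
}

#' Cluster markers into linked genomic groups
#'
#' Transitive single-linkage clustering of marker positions: markers on one
#' chromosome join a cluster when consecutive markers are less than `gap`
#' apart (strict); clusters never span chromosomes.
#'
#' @param markers data.frame with chrom and pos, sorted by (chrom, pos).
#' @param gap clustering distance in bp (default 5 Mb).
#' @return integer vector of cluster ids in marker order.
#' @export
cluster_markers <- function(markers, gap = 5e6) {
  cl <- cluster_by_gap(markers$chrom, markers$pos, markers$pos, gap)
  as.integer(factor(cl, levels = unique(cl)))
}

# ---- backward elimination under a stepwise FDR rule -------------------------

# OLS fit of phenotype ~ covariates + markers; returns per-marker estimate,
# s.e., p-value. Aliased markers are dropped with a warning.
.ols_marker_fit <- function(y, X_cov, X_mark) {
  X <- cbind(X_cov, X_mark)
  fit <- lm.fit(cbind(1, X), y)
  aliased <- is.na(fit$coefficients)   # perfectly collinear markers are dropped
  keep_mark <- !aliased[(2 + ncol(X_cov)):length(aliased)]
  X_mark <- X_mark[, keep_mark, drop = FALSE]
  X <- cbind(1, X_cov, X_mark)
  qrX <- qr(X)
  n <- length(y); pR <- qrX$rank
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  df <- n - pR
  if (df <= 0) stop("design has no residual degrees of freedom")
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX)[seq_len(pR), seq_len(pR), drop = FALSE])
  se_all <- sqrt(sigma2 * diag(XtXinv))
  idx_mark <- (2 + ncol(X_cov)):ncol(X)
  est <- beta[idx_mark]
  se <- se_all[idx_mark]
  tval <- est / se
  pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  list(estimate = est, se = se, p = pval, kept = which(keep_mark), df = df)
}

# BH-adjusted p-values anchored at the starting family size m0:
# adj_(i) = min_{j >= i} p_(j) * m0 / j  (monotone step-up)
.bh_anchor <- function(p, m0) {
  k <- length(p)
  o <- order(p)
  adj <- p[o] * m0 / seq_len(k)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(k)
  out[o] <- pmin(adj, 1)
  out
}

#' Backward elimination of marker terms under an FDR criterion
#'
#' Fits phenotype ~ covariates + additive marker dosages by ordinary least
#' squares and iteratively removes the marker with the largest p-value whose
#' Benjamini-Hochberg adjusted significance exceeds the working threshold,
#' refitting after each removal, until all remaining marker terms pass.
#' The BH denominator stays anchored at the number of marker terms in the
#' full starting model, which preserves the nominal false-retention rate
#' along the elimination path (with a shrinking denominator the final
#' survivor would be judged at its raw p-value despite being the minimum of
#' the starting family). Covariates (e.g. sex) are never eliminated; effects
#' are re-estimated in the final joint model.
#'
#' Markers with more than 20% missing genotypes are dropped; remaining
#' missing dosages are mean-imputed per marker. Ties on the maximal p-value
#' remove the marker later in genome order.
#'
#' @param geno integer matrix (individuals x markers), additive 0/1/2 coding.
#' @param phenotype numeric response (log2 titers).
#' @param covariates data.frame or matrix of covariates kept in every model
#'   (a factor-free numeric design; pass e.g. `sex == "M"`).
#' @param fdr working FDR threshold (default 0.05).
#' @param m_anchor BH denominator; defaults to `ncol(geno)` of this call.
#'   Pass the original family size when eliminating a pre-screened subset.
#' @return list: `retained` (marker column indices), `table` (data.frame
#'   marker, estimate, se, p, adj_p of the final model), `df` residual
#'   degrees of freedom.
#' @export
backward_eliminate <- function(geno, phenotype, covariates, fdr = 0.05,
                               m_anchor = ncol(geno)) {
  geno <- as.matrix(geno)
  X_cov <- as.matrix(covariates)
  storage.mode(X_cov) <- "double"
  n <- length(phenotype)
  stopifnot(nrow(geno) == n, nrow(X_cov) == n)
  miss <- colMeans(is.na(geno))
  active <- which(miss <= 0.2)
  G <- matrix(NA_real_, n, length(active))
  for (j in seq_along(active)) {
    v <- as.numeric(geno[, active[j]])
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    G[, j] <- v
  }
  if (length(active) == 0L) {
    return(list(retained = integer(0),
                table = data.frame(marker = integer(0), estimate = numeric(0),
                                   se = numeric(0), p = numeric(0),
                                   adj_p = numeric(0)),
                df = n - 1 - ncol(X_cov)))
  }
  cur <- seq_along(active)
  repeat {
    if (length(cur) == 0L) {
      fitted <- NULL
      break
    }
    fitted <- .ols_marker_fit(phenotype, X_cov, G[, cur, drop = FALSE])
    cur <- cur[fitted$kept]
    p <- fitted$p
    adj <- .bh_anchor(p, m_anchor)
    if (all(adj <= fdr)) break
    worst <- which(adj > fdr)
    # drop the largest p among failers; ties -> the marker later in genome order
    drop_local <- worst[p[worst] == max(p[worst])]
    cur <- cur[-drop_local[length(drop_local)]]
  }
  if (length(cur) == 0L) {
    return(list(retained = integer(0),
                table = data.frame(marker = integer(0), estimate = numeric(0),
                                   se = numeric(0), p = numeric(0),
                                   adj_p = numeric(0)),
                df = n - 1 - ncol(X_cov)))
  }
  adj <- .bh_anchor(fitted$p, m_anchor)
  list(retained = active[cur],
       table = data.frame(marker = active[cur], estimate = fitted$estimate,
                          se = fitted$se, p = fitted$p, adj_p = adj),
       df = fitted$df)
}

#' Two-stage marker association scan
#'
#' Stage 1 clusters the highly differentiated markers (`delta_p > delta`,
#' clusters separated by `gap`) and reduces every multi-marker cluster to one
#' representative by within-cluster backward elimination (the last survivor;
#' among several survivors, the one with the smallest marginal p in the joint
#' cluster model; if none survive, the marker with the smallest p in the full
#' cluster model). Stage 2 runs genome-wide backward elimination on the
#' representatives at the loose FDR tier and flags the subset that also
#' survives continued elimination at the strict tier.
#'
#' @param panel a [marker_panel].
#' @param delta allele-frequency-difference screen (default 0.7).
#' @param gap marker clustering distance (default 5 Mb).
#' @param fdr_tiers strict and loose FDR tiers (default `c(0.05, 0.20)`).
#' @return an `assoc_result`: data.frame with marker id, chrom, pos,
#'   estimate, se, p, fdr_tier ("5%" or "20%"), plus attributes recording the
#'   screened and representative marker counts. Empty with a `status`
#'   attribute when no marker passes the screen.
#' @export
two_stage_scan <- function(panel, delta = 0.7, gap = 5e6,
                           fdr_tiers = c(0.05, 0.20)) {
  stopifnot(inherits(panel, "marker_panel"))
  strict <- min(fdr_tiers); loose <- max(fdr_tiers)
  sub <- differentiated_marker_subset(panel, delta)
  sex <- as.numeric(sub$individuals$sex == "M")
  y <- sub$individuals$phenotype
  empty <- function(status) {
    structure(data.frame(id = character(0), chrom = character(0),
                         pos = numeric(0), estimate = numeric(0),
                         se = numeric(0), p = numeric(0),
                         fdr_tier = character(0)),
              status = status, n_screened = nrow(sub$markers),
              n_representatives = 0L, class = c("assoc_result", "data.frame"))
  }
  if (nrow(sub$markers) == 0L) return(empty("no marker passed the delta_p screen"))

  cl <- cluster_markers(sub$markers, gap)
  reps <- integer(0)
  for (k in unique(cl)) {
    idx <- which(cl == k)
    if (length(idx) == 1L) { reps <- c(reps, idx); next }
    be <- backward_eliminate(sub$geno[, idx, drop = FALSE], y, sex,
                             fdr = loose, m_anchor = length(idx))
    if (length(be$retained) == 1L) {
      reps <- c(reps, idx[be$retained])
    } else if (length(be$retained) > 1L) {
      best <- be$table$marker[which.min(be$table$p)]
      reps <- c(reps, idx[best])
    } else {
      full <- .ols_marker_fit(y, cbind(sex), sub$geno[, idx, drop = FALSE])
      reps <- c(reps, idx[full$kept[which.min(full$p)]])
    }
  }
  reps <- sort(reps)

  be20 <- backward_eliminate(sub$geno[, reps, drop = FALSE], y, sex,
                             fdr = loose, m_anchor = length(reps))
  if (length(be20$retained) == 0L) return(empty("no marker retained at the loose tier"))
  # continue eliminating from the loose-tier model at the strict tier
  be05 <- backward_eliminate(sub$geno[, reps[be20$retained], drop = FALSE], y,
                             sex, fdr = strict, m_anchor = length(reps))
  strict_set <- reps[be20$retained][be05$retained]
  out_idx <- reps[be20$retained]
  res <- data.frame(id = sub$markers$id[out_idx],
                    chrom = sub$markers$chrom[out_idx],
                    pos = sub$markers$pos[out_idx],
                    estimate = be20$table$estimate,
                    se = be20$table$se,
                    p = be20$table$p,
                    fdr_tier = ifelse(out_idx %in% strict_set,
                                      sprintf("%g%%", 100 * strict),
                                      sprintf("%g%%", 100 * loose)))
  structure(res, status = "ok", n_screened = nrow(sub$markers),
            n_representatives = length(reps),
            class = c("assoc_result", "data.frame"))
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("<assoc_result> %s: %d screened markers, %d cluster representatives, %d retained\n",
              attr(x, "status"), attr(x, "n_screened"),
              attr(x, "n_representatives"), nrow(x)))
  if (nrow(x)) print.data.frame(x, digits = 3)
  invisible(x)
}
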