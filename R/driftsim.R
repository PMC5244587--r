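#' Configuration for the neutral-drift null simulation
#'
#' Defines the two-epoch scheme used to quantify how much between-line
#' differentiation pure drift produces under the experiment's breeding
#' structure: an ancestral random-mating population of `ne_ancestral` diploids
#' carrying equilibrium standing variation on a single locus, from which two
#' lines of `n_line` diploids (a fraction `prop_female` of them breeding
#' females) drift independently for `generations` generations.
#'
#' Standing variation is parameterised by the per-site population-scaled
#' diversity `theta_site`; by default it equals `4 * ne_ancestral * mu`. The
#' per-site per-generation mutation rate used while the lines drift is
#' `theta_site / (4 * ne_ancestral)`, keeping the two epochs on one scale.
#'
#' @param locus_length locus size in bp (default 5 Mb).
#' @param mu per-site per-generation mutation rate (default 3.13e-7).
#' @param rec_rate recombination rate in cM/Mb (2.8 macro- or 6.4
#'   micro-chromosome scale).
#' @param ne_ancestral ancestral diploid population size (default 500).
#' @param n_line diploids per descendant line (default 25).
#' @param prop_female proportion of breeding females in each line (default 0.8).
#' @param generations generations of line drift (default 39).
#' @param n_replicates replicate fragments for [run_drift_null()] (default 200).
#' @param cluster_gap clustering distance for differentiated sites, bp
#'   (default 50 kb).
#' @param min_sites minimum differentiated sites per reported region
#'   (default 2, mirroring the sweep-region rule that discards clusters with
#'   fewer than 2 SNPs).
#' @param burnin_generations random-mating generations used to induce LD in
#'   the ancestral population after assembling haplotypes from the
#'   equilibrium site-frequency spectrum (default 50).
#' @param theta_site per-site scaled diversity of the standing variation;
#'   default `4 * ne_ancestral * mu`.
#' @param seed optional integer seed consumed by [run_drift_null()].
#' @return a `drift_sim_config` list.
#' @export
drift_sim_config <- function(locus_length = 5e6, mu = 3.13e-7, rec_rate = 2.8,
                             ne_ancestral = 500, n_line = 25, prop_female = 0.8,
                             generations = 39, n_replicates = 200,
                             cluster_gap = 5e4, min_sites = 2,
                             burnin_generations = 50,
                             theta_site = 4 * ne_ancestral * mu,
                             seed = NULL) {
  stopifnot(locus_length > 0, mu >= 0, rec_rate >= 0, ne_ancestral >= 2,
            n_line >= 2, prop_female > 0, prop_female < 1, generations >= 0,
            n_replicates >= 1, cluster_gap > 0, theta_site >= 0)
  structure(list(locus_length = locus_length, mu = mu, rec_rate = rec_rate,
                 ne_ancestral = ne_ancestral, n_line = n_line,
                 prop_female = prop_female, generations = generations,
                 n_replicates = n_replicates, cluster_gap = cluster_gap,
                 min_sites = min_sites,
                 burnin_generations = burnin_generations,
                 theta_site = theta_site, seed = seed),
            class = "drift_sim_config")
}

# ---- internal population representation ------------------------------------
# sim_population: geno = raw 0/1 matrix (site rows x haplotype columns, with
# spare row capacity), n_sites = active rows, pos = numeric bp (active, sorted
# within chromosome blocks), chrom_id = integer chromosome per site,
# genome = data.frame(chrom, length_bp, rec_cmmb), generation counter.

.new_sim_population <- function(geno, n_sites, pos, chrom_id, genome, generation = 0L) {
  structure(list(geno = geno, n_sites = n_sites, pos = pos,
                 chrom_id = chrom_id, genome = genome,
                 generation = generation),
            class = "sim_population")
}

#' Construct a diploid haplotype population
#'
#' Builds the population container used by the forward simulators from an
#' explicit 0/1 haplotype matrix — mainly useful for constructing small
#' populations with known haplotype content (e.g. parental lines fixed for
#' chosen alleles).
#'
#' @param haplotypes 0/1 matrix, sites in rows, haplotypes in columns (two
#'   consecutive columns per diploid individual).
#' @param pos site positions in bp, sorted within chromosomes.
#' @param chrom chromosome name per site (must match `genome$chrom`).
#' @param genome data.frame with columns chrom, length_bp, rec_cmmb.
#' @return a `sim_population`.
#' @export
sim_population <- function(haplotypes, pos, chrom, genome) {
  stopifnot(is.matrix(haplotypes), ncol(haplotypes) %% 2 == 0,
            nrow(haplotypes) == length(pos), length(chrom) == length(pos),
            all(haplotypes %in% c(0, 1)), all(chrom %in% genome$chrom))
  chrom_id <- match(chrom, genome$chrom)
  o <- order(chrom_id, pos)
  if (!identical(o, seq_along(pos))) stop("sites must be sorted by (chrom, pos)")
  geno <- matrix(as.raw(haplotypes), nrow(haplotypes), ncol(haplotypes))
  .new_sim_population(geno, nrow(geno), as.numeric(pos), chrom_id, genome)
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("<sim_population> %d haplotypes (%d diploids), %d segregating sites, generation %d\n",
              ncol(x$geno), ncol(x$geno) / 2, x$n_sites, x$generation))
  invisible(x)
}

# block offsets (0-based) of chromosome site ranges, for the C++ kernel
.block_starts <- function(chrom_id, n_sorted, n_chrom) {
  counts <- tabulate(chrom_id[seq_len(n_sorted)], nbins = n_chrom)
  as.integer(c(0, cumsum(counts)))
}

.map_morgans <- function(genome) genome$length_bp / 1e6 * genome$rec_cmmb / 100

# one generation of gamete formation; parents are 1-based individual indices
.make_offspring <- function(pop, mothers, fathers, mu_site, n_sorted, extra_chrom, extra_pos) {
  n_off <- length(mothers)
  par_ind <- integer(2 * n_off)
  par_ind[seq(1, 2 * n_off, 2)] <- mothers
  par_ind[seq(2, 2 * n_off, 2)] <- fathers
  res <- .gametes_cpp(pop$geno, n_sorted, pop$pos[seq_len(n_sorted)],
                      .block_starts(pop$chrom_id, n_sorted, nrow(pop$genome)),
                      pop$genome$length_bp, .map_morgans(pop$genome),
                      extra_chrom, extra_pos,
                      as.integer(2 * (par_ind - 1)),      # 0-based hap columns
                      as.integer(2 * (par_ind - 1) + 1),
                      mu_site)
  res
}

# evolve a population for n_gens generations; constant census, optional sexes
# (n_males = 0 -> monoecious random mating with selfing allowed)
.evolve_random <- function(pop, n_gens, n_females, n_males, mu_site) {
  n_ind <- ncol(pop$geno) / 2
  if (n_males > 0) stopifnot(n_females + n_males == n_ind)
  n_sorted <- pop$n_sites
  extra_chrom <- integer(0)
  extra_pos <- numeric(0)
  geno <- pop$geno
  if (mu_site == 0 && n_gens > 0) {
    # mutation-free phase: run all generations inside the C++ kernel
    pop$geno <- .wf_phase_cpp(geno, n_sorted, pop$pos[seq_len(n_sorted)],
                              .block_starts(pop$chrom_id, n_sorted, nrow(pop$genome)),
                              pop$genome$length_bp, .map_morgans(pop$genome),
                              n_gens, n_females, n_males)
    pop$generation <- pop$generation + n_gens
    return(pop)
  }
  for (g in seq_len(n_gens)) {
    if (n_males == 0) {
      mothers <- sample.int(n_ind, n_ind, replace = TRUE)
      fathers <- sample.int(n_ind, n_ind, replace = TRUE)
    } else {
      mothers <- sample.int(n_females, n_ind, replace = TRUE)
      fathers <- n_females + sample.int(n_males, n_ind, replace = TRUE)
    }
    tmp <- pop
    tmp$geno <- geno
    res <- .make_offspring(tmp, mothers, fathers, mu_site, n_sorted,
                           extra_chrom, extra_pos)
    geno <- res$geno
    extra_chrom <- res$extra_chrom
    extra_pos <- res$extra_pos
  }
  # consolidate mutation rows into sorted order
  n_extra <- length(extra_chrom)
  pop$geno <- geno
  if (n_extra > 0) {
    chrom_id <- c(pop$chrom_id[seq_len(n_sorted)], extra_chrom + 1L)
    pos <- c(pop$pos[seq_len(n_sorted)], extra_pos)
    n_act <- n_sorted + n_extra
    o <- order(chrom_id, pos)
    cap <- nrow(geno)
    new_geno <- geno
    new_geno[seq_len(n_act), ] <- geno[o, , drop = FALSE]
    pop$geno <- new_geno
    pop$pos <- pos[o]
    pop$chrom_id <- chrom_id[o]
    pop$n_sites <- n_act
  }
  pop$generation <- pop$generation + n_gens
  pop
}

#' Initialise ancestral standing variation
#'
#' Draws the number of segregating sites from the neutral equilibrium
#' expectation `theta_site * L * sum_{i=1}^{2N-1} 1/i`, gives each site a
#' derived-allele frequency `i / 2N` with probability proportional to `1/i`
#' (the neutral site-frequency spectrum), places sites uniformly on the
#' locus, assembles haplotypes at linkage equilibrium (each haplotype carries
#' the derived allele independently with the site's frequency), and then
#' burns the population in with `burnin_generations` of random mating with
#' recombination to induce realistic LD.
#'
#' @param config a [drift_sim_config()].
#' @return a `sim_population` of `2 * ne_ancestral` haplotypes.
#' @export
init_standing_variation <- function(config) {
  stopifnot(inherits(config, "drift_sim_config"))
  L <- config$locus_length
  twoN <- 2L * config$ne_ancestral
  genome <- data.frame(chrom = "sim", length_bp = L, rec_cmmb = config$rec_rate)
  harm <- sum(1 / seq_len(twoN - 1))
  S <- rpois(1, config$theta_site * L * harm)
  if (S == 0) {
    geno <- matrix(raw(0), 0, twoN)
    return(.new_sim_population(geno, 0L, numeric(0), integer(0), genome))
  }
  freq <- sample.int(twoN - 1, S, replace = TRUE,
                     prob = 1 / seq_len(twoN - 1)) / twoN
  pos <- sort(runif(S, 0, L))
  geno <- matrix(as.raw(0), S, twoN)
  chunk <- 2048L
  for (lo in seq(1, S, chunk)) {
    hi <- min(lo + chunk - 1L, S)
    nr <- hi - lo + 1L
    geno[lo:hi, ] <- as.raw(matrix(runif(nr * twoN), nr, twoN) < freq[lo:hi])
  }
  pop <- .new_sim_population(geno, S, pos, rep(1L, S), genome)
  if (config$burnin_generations > 0)
    pop <- .evolve_random(pop, config$burnin_generations,
                          n_females = 0, n_males = 0, mu_site = 0)
  pop$generation <- 0L   # burn-in is part of initialisation
  pop
}

#' Drift two descendant lines from an ancestral population
#'
#' Founds two lines by sampling `2 * n_line` distinct diploids from the
#' ancestral population and lets each drift for `generations` generations.
#' Each generation, every offspring draws its mother uniformly from the
#' line's breeding females and its father from its breeding males
#' (`round(prop_female * n_line)` females, the rest males), giving the
#' unequal-sex-ratio effective size `4 Nf Nm / (Nf + Nm)`. Gametes recombine
#' with a Poisson number of crossovers per meiosis set by the genetic map,
#' and new mutations arise at `theta_site / (4 ne_ancestral)` per site per
#' gamete.
#'
#' @param pop ancestral `sim_population` from [init_standing_variation()].
#' @param config the [drift_sim_config()].
#' @return list of two `sim_population` objects (`line1`, `line2`).
#' @export
evolve_neutral <- function(pop, config) {
  stopifnot(inherits(pop, "sim_population"), inherits(config, "drift_sim_config"))
  n_line <- config$n_line
  n_anc <- ncol(pop$geno) / 2
  stopifnot(2 * n_line <= n_anc)
  founders <- sample.int(n_anc, 2 * n_line)
  n_f <- round(config$prop_female * n_line)
  n_m <- n_line - n_f
  stopifnot(n_f >= 1, n_m >= 1)
  mu_line <- config$theta_site / (4 * config$ne_ancestral)
  lambda_mut <- mu_line * config$locus_length * 2 * n_line * config$generations
  margin <- ceiling(lambda_mut + 8 * sqrt(lambda_mut + 1) + 16)
  make_line <- function(ind) {
    cols <- as.vector(rbind(2 * ind - 1, 2 * ind))
    cap <- pop$n_sites + margin
    geno <- matrix(as.raw(0), cap, 2 * n_line)
    if (pop$n_sites > 0)
      geno[seq_len(pop$n_sites), ] <- pop$geno[seq_len(pop$n_sites), cols]
    line <- .new_sim_population(geno, pop$n_sites, pop$pos[seq_len(pop$n_sites)],
                                pop$chrom_id[seq_len(pop$n_sites)], pop$genome,
                                pop$generation)
    .evolve_random(line, config$generations, n_f, n_m, mu_line)
  }
  list(line1 = make_line(founders[seq_len(n_line)]),
       line2 = make_line(founders[n_line + seq_len(n_line)]))
}

#' Derived-allele frequencies of a simulated population
#'
#' @param pop a `sim_population`.
#' @return data.frame chrom_id, pos, count, freq.
#' @export
sim_allele_frequencies <- function(pop) {
  n <- pop$n_sites
  cnt <- .hap_counts_cpp(pop$geno, seq_len(ncol(pop$geno)) - 1L, n)
  data.frame(chrom_id = pop$chrom_id[seq_len(n)], pos = pop$pos[seq_len(n)],
             count = cnt, freq = cnt / ncol(pop$geno))
}

# merge the site registries of two lines descended from one ancestor:
# shared founder rows are identical; mutation rows are line-private (freq 0
# in the other line)
.merged_line_freqs <- function(line1, line2) {
  f1 <- sim_allele_frequencies(line1)
  f2 <- sim_allele_frequencies(line2)
  key1 <- paste(f1$chrom_id, f1$pos)
  key2 <- paste(f2$chrom_id, f2$pos)
  all_key <- union(key1, key2)
  i1 <- match(all_key, key1)
  i2 <- match(all_key, key2)
  chrom_id <- ifelse(is.na(i1), f2$chrom_id[i2], f1$chrom_id[i1])
  pos <- ifelse(is.na(i1), f2$pos[i2], f1$pos[i1])
  o <- order(chrom_id, pos)
  data.frame(chrom_id = chrom_id[o], pos = pos[o],
             count1 = ifelse(is.na(i1), 0L, f1$count[i1])[o],
             count2 = ifelse(is.na(i2), 0L, f2$count[i2])[o],
             n1 = ncol(line1$geno), n2 = ncol(line2$geno))
}

#' Cluster differentiated sites into regions
#'
#' A site is differentiated when the two lines are fixed for alternative
#' alleles (the default), or — when `fst_threshold` is given — when its
#' per-site fixation index `((f1-f2)/2)^2 / (p(1-p))` with `p = (f1+f2)/2`
#' exceeds the threshold. Differentiated sites closer than `cluster_gap` are
#' merged into regions spanning first to last site; regions with fewer than
#' `min_sites` sites are dropped.
#'
#' @param pos sorted site positions (bp).
#' @param freq1,freq2 derived-allele frequencies of the two lines at `pos`.
#' @param cluster_gap strict clustering distance in bp (default 50 kb).
#' @param min_sites minimum sites per region (default 2).
#' @param fst_threshold optional per-site F_ST threshold replacing the
#'   fixed-difference rule.
#' @return data.frame: start, end, n_sites, length (`end - start`).
#' @export
differentiated_regions <- function(pos, freq1, freq2, cluster_gap = 5e4,
                                   min_sites = 2, fst_threshold = NULL) {
  stopifnot(length(freq1) == length(pos), length(freq2) == length(pos))
  if (is.unsorted(pos)) stop("positions must be sorted")
  if (is.null(fst_threshold)) {
    diffd <- (freq1 >= 1 & freq2 <= 0) | (freq1 <= 0 & freq2 >= 1)
  } else {
    pbar <- (freq1 + freq2) / 2
    fst <- ifelse(pbar > 0 & pbar < 1,
                  ((freq1 - freq2) / 2)^2 / (pbar * (1 - pbar)), 0)
    diffd <- fst > fst_threshold
  }
  p <- pos[diffd]
  if (length(p) == 0L) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_sites = integer(0), length = numeric(0)))
  }
  cl <- cluster_by_gap(rep("x", length(p)), p, p, cluster_gap)
  cl <- factor(cl, levels = unique(cl))
  out <- data.frame(start = as.numeric(tapply(p, cl, min)),
                    end = as.numeric(tapply(p, cl, max)),
                    n_sites = as.integer(tapply(p, cl, length)))
  out$length <- out$end - out$start
  out <- out[out$n_sites >= min_sites, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export two drifted lines as exhaustive pooled counts
#'
#' Represents the lines' true allele counts as pooled "reads" (coverage =
#' haplotype count, counts = allele counts) so the terminal generations of a
#' drift run can be fed through the pool-statistics pipeline or written with
#' [write_sync()].
#'
#' @param line1,line2 `sim_population` lines from [evolve_neutral()].
#' @return a [pool_sites] object with two pools.
#' @export
lines_to_pool_sites <- function(line1, line2) {
  mf <- .merged_line_freqs(line1, line2)
  .lines_as_pool_sites(mf, line1$genome)
}

# represent the two lines' true allele counts as exhaustive pooled "reads"
# (coverage = 2N, counts = allele counts), for the windowed F_ST machinery
.lines_as_pool_sites <- function(mf, genome) {
  n <- nrow(mf)
  cnt <- array(0L, dim = c(n, 6, 2))
  cnt[, 1, 1] <- mf$n1 - mf$count1   # ancestral allele -> A
  cnt[, 2, 1] <- mf$count1           # derived allele  -> T
  cnt[, 1, 2] <- mf$n2 - mf$count2
  cnt[, 2, 2] <- mf$count2
  pool_sites(genome$chrom[mf$chrom_id], pmax(1L, as.integer(ceiling(mf$pos))),
             rep("A", n), cnt, c("line1", "line2"))
}

#' Run the neutral-drift null experiment
#'
#' Simulates `n_replicates` independent locus fragments: ancestral standing
#' variation, two lines drifting under the breeding scheme, then per
#' replicate (i) differentiated regions from fixed opposite alleles clustered
#' at `cluster_gap`, and (ii) windowed F_ST (1000 bp, 50% overlap) computed
#' by the pool statistics machinery from the exhaustive allele counts.
#' Reproducible given `config$seed`.
#'
#' @param config a [drift_sim_config()].
#' @param progress print a dot every 25 replicates.
#' @return a `drift_summary` list: per-replicate region tables, pooled region
#'   lengths with median/mean/max, median window F_ST over all defined
#'   windows, the fraction of replicates with at least one region, the mean
#'   percentage of the fragment covered by regions (`pct_covered`), the mean
#'   percentage of segregating sites fixed for alternative alleles
#'   (`pct_sites_fixed_opposite`, the "fixed percentage" of the null), and
#'   the configuration.
#' @export
run_drift_null <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "drift_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  L <- config$locus_length
  lengths_all <- vector("list", config$n_replicates)
  fst_all <- vector("list", config$n_replicates)
  regions_all <- vector("list", config$n_replicates)
  pct <- numeric(config$n_replicates)
  pct_sites <- numeric(config$n_replicates)
  has_region <- logical(config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    anc <- init_standing_variation(config)
    lines <- evolve_neutral(anc, config)
    mf <- .merged_line_freqs(lines$line1, lines$line2)
    f1 <- mf$count1 / mf$n1
    f2 <- mf$count2 / mf$n2
    seg <- !(f1 == f2 & (f1 == 0 | f1 == 1))
    opp <- (f1 >= 1 & f2 <= 0) | (f1 <= 0 & f2 >= 1)
    pct_sites[r] <- if (any(seg)) 100 * sum(opp) / sum(seg) else 0
    reg <- differentiated_regions(mf$pos, f1, f2,
                                  cluster_gap = config$cluster_gap,
                                  min_sites = config$min_sites)
    regions_all[[r]] <- reg
    lengths_all[[r]] <- reg$length
    has_region[r] <- nrow(reg) > 0
    pct[r] <- 100 * sum(reg$length) / L
    ps <- .lines_as_pool_sites(mf, lines$line1$genome)
    wf <- window_fst(ps, pools = c(1, 2), min_count = 1,
                     min_covered_fraction = 0,
                     chrom_lengths = setNames(L, "sim"))
    fst_all[[r]] <- wf$fst[!is.na(wf$fst)]
    if (progress && r %% 25 == 0) cat(".")
  }
  if (progress) cat("\n")
  lens <- unlist(lengths_all)
  structure(list(
    region_lengths = lengths_all,
    regions = regions_all,
    median_length = if (length(lens)) median(lens) else NA_real_,
    mean_length = if (length(lens)) mean(lens) else NA_real_,
    max_length = if (length(lens)) max(lens) else NA_real_,
    median_window_fst = median(unlist(fst_all)),
    frac_with_region = mean(has_region),
    pct_covered = mean(pct),
    pct_sites_fixed_opposite = mean(pct_sites),
    n_replicates = config$n_replicates,
    config = config), class = "drift_summary")
}

#' @export
print.drift_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<drift_summary> %d replicates (rec %.1f cM/Mb)\n",
           "  differentiated regions: median length %s bp, mean %s, max %s\n",
           "  median window F_ST %.3f\n",
           "  fragments with >=1 region: %.1f%%; mean %% of fragment covered: %.1f%%\n",
           "  mean %% of segregating sites fixed for alternative alleles: %.1f%%\n"),
    x$n_replicates, x$config$rec_rate,
    format(x$median_length), format(round(x$mean_length)), format(x$max_length),
    x$median_window_fst, 100 * x$frac_with_region, x$pct_covered,
    x$pct_sites_fixed_opposite))
  invisible(x)
}
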