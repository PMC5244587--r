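#' Configuration for the synthetic bidirectional selection experiment
#'
#' Emulates a 39-generation divergent truncation-selection experiment on a
#' polygenic trait measured on a log2 scale, with relaxed (random-mated)
#' sublines founded at generation 24, pooled sequencing of the four terminal
#' populations, and an F2 intercross of the selected lines genotyped at the
#' phenotypic extremes.
#'
#' Defaults follow the experiment being emulated: 30 male and 60 female
#' candidates per generation, 7/28 breeding males/females in generations
#' 1-10 and 8/32 thereafter, pools of 30/30/20/16 birds sequenced to mean
#' depths 32.3/36.7/35.4/34.8x, and 128 phenotypic extremes genotyped at
#' ~1024 markers. The trait architecture (50 additive QTL with exponential
#' effect sizes, h2 = 0.3, phenotype floored at 0) is the package's default
#' polygenic model; the genome is a desk-scale stand-in of two macro- and two
#' micro-chromosomes totalling 50 Mb.
#'
#' @param genome data.frame with columns chrom, length_bp, rec_cmmb.
#' @param n_sites segregating founder sites across the genome.
#' @param founder_spectrum "neutral" (folded 1/p site-frequency spectrum,
#'   rare-skewed like standing variation in a large randombred base flock) or
#'   "uniform" (flat on `founder_maf_range`).
#' @param founder_maf_range frequency bounds of founder variants.
#' @param n_qtl number of trait loci among the sites.
#' @param h2 narrow-sense heritability of the trait in the founders.
#' @param trait_mean founder trait mean (log2 titer scale).
#' @param var_p0 founder phenotypic variance.
#' @param sex_effect additive fixed effect of male sex on the trait.
#' @param floor_zero floor phenotypes at 0 (titers cannot be negative).
#' @param candidates_per_sex c(males, females) scored per generation.
#' @param parents_early,parents_late c(males, females) selected as parents in
#'   generations 1-10 and 11 onwards.
#' @param generations generations of selection.
#' @param relax_at generation at which relaxed sublines are founded.
#' @param relax_generations random-mating generations of the relaxed lines.
#' @param family_cap maximum selected offspring per dam family within a sex
#'   (restricted truncation selection).
#' @param pool_sizes,mean_depth per-population pool sizes and mean sequencing
#'   depths (HighSel, LowSel, HighRelax, LowRelax).
#' @param f2_at generation whose selected lines are intercrossed.
#' @param f2_n_f1 F1 individuals produced from reciprocal line crosses.
#' @param f2_cohort F2 cohort size from which extremes are drawn.
#' @param f2_n_extremes phenotypic extremes retained (half high, half low).
#' @param f2_panel_size marker panel size.
#' @param seed optional integer seed consumed by [simulate_experiment()].
#' @return a `selection_sim_config` list.
#' @export
selection_sim_config <- function(
    genome = data.frame(chrom = c("chr1", "chr2", "chr3", "chr4"),
                        length_bp = c(2e7, 1.5e7, 1e7, 5e6),
                        rec_cmmb = c(2.8, 2.8, 6.4, 6.4)),
    n_sites = 10000,
    founder_spectrum = c("neutral", "uniform"),
    founder_maf_range = c(0.005, 0.5),
    n_qtl = 50, h2 = 0.3, trait_mean = 9.5, var_p0 = 6.25,
    sex_effect = 1, floor_zero = TRUE,
    candidates_per_sex = c(males = 30, females = 60),
    parents_early = c(males = 7, females = 28),
    parents_late = c(males = 8, females = 32),
    generations = 39, relax_at = 24, relax_generations = 16, family_cap = 2,
    pool_sizes = c(high_sel = 30, low_sel = 30, high_relax = 20, low_relax = 16),
    mean_depth = c(32.3, 36.7, 35.4, 34.8),
    f2_at = 32, f2_n_f1 = 64, f2_cohort = 256, f2_n_extremes = 128,
    f2_panel_size = 1024, seed = NULL) {
  stopifnot(h2 > 0, h2 <= 1, n_qtl >= 0, n_qtl <= n_sites,
            relax_at < generations,
            parents_early[1] <= candidates_per_sex[1],
            parents_early[2] <= candidates_per_sex[2],
            parents_late[1] <= candidates_per_sex[1],
            parents_late[2] <= candidates_per_sex[2],
            f2_n_extremes <= f2_cohort,
            length(pool_sizes) == 4, length(mean_depth) == 4)
  founder_spectrum <- match.arg(founder_spectrum)
  structure(as.list(environment()), class = "selection_sim_config")
}

# --- internal helpers --------------------------------------------------------

# dosages (0/1/2) of the coded allele at given site rows; columns = individuals
.dosages <- function(pop, rows) {
  m <- matrix(as.integer(pop$geno[rows, , drop = FALSE]), nrow = length(rows))
  n_ind <- ncol(m) / 2
  m[, 2 * seq_len(n_ind) - 1, drop = FALSE] + m[, 2 * seq_len(n_ind), drop = FALSE]
}

.phenotypes <- function(pop, model, is_male) {
  n_ind <- ncol(pop$geno) / 2
  bv <- if (length(model$qtl_rows))
    drop(crossprod(.dosages(pop, model$qtl_rows), model$effects))
  else rep(0, n_ind)
  phen <- model$intercept + bv + model$sex_effect * is_male +
    rnorm(n_ind, 0, sqrt(model$ve))
  if (model$floor_zero) phen <- pmax(phen, 0)
  phen
}

# restricted truncation selection within one sex: rank candidates by
# direction * phenotype, take the best n subject to <= cap per dam family
.select_within_sex <- function(phen, dam_id, n, cap, direction) {
  ord <- order(direction * phen, decreasing = TRUE)
  taken <- integer(0)
  used <- table(factor(integer(0)))
  dam_count <- new.env()
  for (i in ord) {
    key <- as.character(dam_id[i])
    cnt <- if (is.null(dam_count[[key]])) 0L else dam_count[[key]]
    if (cnt >= cap) next
    dam_count[[key]] <- cnt + 1L
    taken <- c(taken, i)
    if (length(taken) == n) break
  }
  if (length(taken) < n) {
    # cap infeasible for this family structure: fill by rank, ignoring cap
    rest <- setdiff(ord, taken)
    taken <- c(taken, rest[seq_len(n - length(taken))])
  }
  taken
}

# one generation: select parents, mate, return offspring population + dam ids
.next_generation <- function(pop, model, config, generation, direction,
                             random_mating = FALSE, dam_id, is_male) {
  par <- if (generation <= 10) config$parents_early else config$parents_late
  n_m <- par[[1]]; n_f <- par[[2]]
  males <- which(is_male); females <- which(!is_male)
  if (random_mating) {
    sel_m <- sample(males, n_m)
    sel_f <- sample(females, n_f)
    phen <- NULL
  } else {
    phen <- .phenotypes(pop, model, is_male)
    sel_m <- males[.select_within_sex(phen[males], dam_id[males], n_m,
                                      config$family_cap, direction)]
    sel_f <- females[.select_within_sex(phen[females], dam_id[females], n_f,
                                        config$family_cap, direction)]
  }
  # balanced family contributions: the restricted breeding design equalizes
  # dam and sire use, which keeps Ne above the Poisson-family 4NfNm/(Nf+Nm)
  n_off <- sum(config$candidates_per_sex)
  mothers <- rep(sel_f, length.out = n_off)[sample.int(n_off)]
  fathers <- rep(sel_m, length.out = n_off)[sample.int(n_off)]
  res <- .make_offspring(pop, mothers, fathers, 0, pop$n_sites,
                         integer(0), numeric(0))
  new_pop <- pop
  new_pop$geno <- res$geno
  new_pop$generation <- pop$generation + 1L
  list(pop = new_pop, dam_id = mothers, phen = phen)
}

#' Simulate the bidirectional selection experiment
#'
#' Founds a base population with `n_sites` segregating sites (founder
#' frequencies uniform on 0.05-0.95, haplotypes at linkage equilibrium) and
#' an additive trait model with `n_qtl` loci whose exponential effect sizes
#' are scaled so the founder additive variance equals `h2 * var_p0`. Each
#' generation, all candidates are phenotyped and the top (high line) or
#' bottom (low line) candidates within each sex become parents under a per-dam
#' family cap; relaxed sublines branch at `relax_at` with random parent choice
#' thereafter. Per-generation trait means are recorded per line and sex.
#'
#' @param config a [selection_sim_config()].
#' @return a `selection_experiment` list: `populations` (high_sel, low_sel,
#'   high_relax, low_relax as `sim_population`s), `f2_parents` (line snapshots
#'   at `f2_at`), `trait_history` data.frame, `model` (QTL rows, effects,
#'   intercept, environmental variance), `sites` data.frame (chrom, pos,
#'   founder frequency, effect), and the config.
#' @export
simulate_experiment <- function(config = selection_sim_config()) {
  stopifnot(inherits(config, "selection_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  genome <- config$genome
  n_cand <- sum(config$candidates_per_sex)
  is_male <- c(rep(FALSE, config$candidates_per_sex[[2]]),
               rep(TRUE, config$candidates_per_sex[[1]]))

  # founder sites
  n_per_chrom <- pmax(1L, round(config$n_sites * genome$length_bp / sum(genome$length_bp)))
  pos <- unlist(lapply(seq_len(nrow(genome)),
                       function(c) sort(runif(n_per_chrom[c], 1, genome$length_bp[c]))))
  chrom_id <- rep(seq_len(nrow(genome)), n_per_chrom)
  S <- length(pos)
  lo <- config$founder_maf_range[1]; hi <- config$founder_maf_range[2]
  freq0 <- if (config$founder_spectrum == "neutral") {
    # folded neutral SFS: minor-allele frequency density ~ 1/p on [lo, hi],
    # drawn by inverse CDF, then randomly assigned to either allele
    maf <- lo * (hi / lo)^runif(S)
    ifelse(runif(S) < 0.5, maf, 1 - maf)
  } else {
    runif(S, lo, 1 - lo)
  }
  geno <- matrix(as.raw(0), S, 2 * n_cand)
  chunk <- 2048L
  for (lo in seq(1, S, chunk)) {
    hi <- min(lo + chunk - 1L, S)
    geno[lo:hi, ] <- as.raw(matrix(runif((hi - lo + 1) * 2 * n_cand),
                                   hi - lo + 1, 2 * n_cand) < freq0[lo:hi])
  }
  founders <- .new_sim_population(geno, S, pos, chrom_id, genome)

  # trait model
  qtl_rows <- sort(sample.int(S, config$n_qtl))
  raw_eff <- rexp(config$n_qtl)
  va_raw <- sum(2 * freq0[qtl_rows] * (1 - freq0[qtl_rows]) * raw_eff^2)
  effects <- raw_eff * sqrt(config$h2 * config$var_p0 / va_raw)
  ve <- (1 - config$h2) * config$var_p0
  mean_bv <- sum(2 * freq0[qtl_rows] * effects)
  intercept <- config$trait_mean - mean_bv -
    config$sex_effect * mean(is_male)
  model <- list(qtl_rows = qtl_rows, effects = effects, intercept = intercept,
                ve = ve, sex_effect = config$sex_effect,
                floor_zero = config$floor_zero)

  run_line <- function(direction) {
    pop <- founders
    dam_id <- seq_len(n_cand)
    hist <- list()
    snap_relax <- NULL; snap_f2 <- NULL
    for (g in seq_len(config$generations)) {
      step <- .next_generation(pop, model, config, g, direction,
                               random_mating = FALSE, dam_id, is_male)
      if (!is.null(step$phen)) {
        hist[[g]] <- data.frame(
          generation = g - 1L,
          sex = c("F", "M"),
          mean_phen = c(mean(step$phen[!is_male]), mean(step$phen[is_male])))
      }
      pop <- step$pop; dam_id <- step$dam_id
      if (g == config$relax_at) snap_relax <- list(pop = pop, dam_id = dam_id)
      if (g == config$f2_at) snap_f2 <- pop
    }
    list(pop = pop, relax = snap_relax, f2 = snap_f2, hist = do.call(rbind, hist))
  }
  high <- run_line(+1)
  low <- run_line(-1)

  run_relaxed <- function(snap) {
    pop <- snap$pop
    dam_id <- snap$dam_id
    hist <- list()
    for (g in seq_len(config$relax_generations)) {
      phen <- .phenotypes(pop, model, is_male)
      hist[[g]] <- data.frame(generation = config$relax_at + g - 1L,
                              sex = c("F", "M"),
                              mean_phen = c(mean(phen[!is_male]), mean(phen[is_male])))
      step <- .next_generation(pop, model, config, config$relax_at + g, 0,
                               random_mating = TRUE, dam_id, is_male)
      pop <- step$pop; dam_id <- step$dam_id
    }
    list(pop = pop, hist = do.call(rbind, hist))
  }
  high_relax <- run_relaxed(high$relax)
  low_relax <- run_relaxed(low$relax)

  th <- rbind(cbind(line = "high_sel", high$hist),
              cbind(line = "low_sel", low$hist),
              cbind(line = "high_relax", high_relax$hist),
              cbind(line = "low_relax", low_relax$hist))
  structure(list(
    populations = list(high_sel = high$pop, low_sel = low$pop,
                       high_relax = high_relax$pop, low_relax = low_relax$pop),
    f2_parents = list(high = high$f2, low = low$f2),
    trait_history = th,
    model = model,
    sites = data.frame(chrom = genome$chrom[chrom_id], pos = pos,
                       freq0 = freq0,
                       effect = {
                         e <- numeric(S); e[qtl_rows] <- effects; e
                       }),
    config = config), class = "selection_experiment")
}

#' @export
print.selection_experiment <- function(x, ...) {
  cat(sprintf("<selection_experiment> %d sites, %d QTL, %d generations (+%d relaxed)\n",
              nrow(x$sites), length(x$model$qtl_rows),
              x$config$generations, x$config$relax_generations))
  invisible(x)
}

#' Pooled sequencing of the terminal populations
#'
#' Samples `pool_sizes` individuals from each terminal population, draws a
#' Poisson read depth per site and pool around the pool's mean depth, and
#' draws allele reads binomially from the pool sample's allele frequency —
#' the standard pool-seq read-sampling model. Each site is assigned a
#' reference and an alternative nucleotide; the coded (founder-derived)
#' allele is the alternative base.
#'
#' @param experiment a `selection_experiment`.
#' @param config defaults to `experiment$config`.
#' @return a [pool_sites] object with pools HighSel, LowSel, HighRelax,
#'   LowRelax.
#' @export
sample_pools <- function(experiment, config = experiment$config) {
  pops <- experiment$populations
  stopifnot(length(pops) == 4)
  S <- pops[[1]]$n_sites
  bases <- c("A", "T", "C", "G")
  ref_base <- sample.int(4, S, replace = TRUE)
  alt_base <- ((ref_base - 1 + sample.int(3, S, replace = TRUE)) %% 4) + 1
  cnt <- array(0L, dim = c(S, 6, 4))
  for (p in seq_len(4)) {
    pop <- pops[[p]]
    n_ind <- ncol(pop$geno) / 2
    take <- sample.int(n_ind, config$pool_sizes[[p]])
    cols <- as.integer(c(rbind(2 * take - 1, 2 * take))) - 1L
    ac <- .hap_counts_cpp(pop$geno, cols, S)
    freq <- ac / (2 * config$pool_sizes[[p]])
    depth <- rpois(S, config$mean_depth[[p]])
    alt_reads <- rbinom(S, depth, freq)
    ref_reads <- depth - alt_reads
    cnt[cbind(seq_len(S), alt_base, p)] <- as.integer(alt_reads)
    cnt[cbind(seq_len(S), ref_base, p)] <-
      cnt[cbind(seq_len(S), ref_base, p)] + as.integer(ref_reads)
  }
  pool_sites(experiment$sites$chrom, as.integer(ceiling(experiment$sites$pos)),
             bases[ref_base], cnt,
             c("HighSel", "LowSel", "HighRelax", "LowRelax"))
}

#' Marker panel container for the F2 association design
#'
#' @param markers data.frame: id, chrom, pos, p_high, p_low, delta_p, effect.
#' @param geno integer matrix (individuals x markers), additive coding 0/1/2
#'   counting copies of the high-line allele.
#' @param individuals data.frame: id, sex ("F"/"M"), phenotype (log2 scale).
#' @return a `marker_panel` object.
#' @export
marker_panel <- function(markers, geno, individuals) {
  stopifnot(nrow(markers) == ncol(geno), nrow(individuals) == nrow(geno),
            all(geno %in% c(0L, 1L, 2L, NA_integer_)))
  structure(list(markers = markers, geno = geno, individuals = individuals),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("<marker_panel> %d markers x %d individuals\n",
              nrow(x$markers), nrow(x$individuals)))
  invisible(x)
}

#' Simulate the F2 intercross and its phenotypic extremes
#'
#' Crosses two line populations reciprocally to produce F1s, intermates the
#' F1s into an F2 cohort, phenotypes the cohort under the experiment's trait
#' model, and retains the highest and lowest `f2_n_extremes / 2` phenotypes.
#' The marker panel is a random down-sample of sites polymorphic between the
#' two lines; genotypes are coded as copies of the high-line allele, and each
#' marker carries the two lines' pool-sample allele frequencies (`p_high`,
#' `p_low`) and their absolute difference `delta_p`.
#'
#' @param high,low `sim_population` line snapshots (e.g.
#'   `experiment$f2_parents`).
#' @param model trait model (`experiment$model`).
#' @param config a [selection_sim_config()].
#' @param pool_freq optional 2-column matrix of externally measured pooled
#'   frequencies (coded allele) to use instead of the line sample frequencies.
#' @return a [marker_panel]. Marker column `effect` carries the true QTL
#'   effect of the underlying site (0 for neutral markers).
#' @export
simulate_f2 <- function(high, low, model, config, pool_freq = NULL) {
  stopifnot(inherits(high, "sim_population"), inherits(low, "sim_population"),
            high$n_sites == low$n_sites)
  S <- high$n_sites
  n_high <- ncol(high$geno) / 2
  n_low <- ncol(low$geno) / 2

  # F1: each gets one gamete from a high parent, one from a low parent
  combined <- high
  combined$geno <- cbind(high$geno[seq_len(nrow(high$geno)), , drop = FALSE],
                         low$geno[seq_len(nrow(high$geno)), , drop = FALSE])
  n_f1 <- config$f2_n_f1
  res_f1 <- .make_offspring(combined,
                            mothers = sample.int(n_high, n_f1, replace = TRUE),
                            fathers = n_high + sample.int(n_low, n_f1, replace = TRUE),
                            0, S, integer(0), numeric(0))
  f1 <- combined; f1$geno <- res_f1$geno

  # F2: intermate F1s (distinct parents per offspring)
  n_f2 <- config$f2_cohort
  mothers <- sample.int(n_f1, n_f2, replace = TRUE)
  shift <- sample.int(n_f1 - 1, n_f2, replace = TRUE)
  fathers <- ((mothers - 1 + shift) %% n_f1) + 1
  res_f2 <- .make_offspring(f1, mothers, fathers, 0, S, integer(0), numeric(0))
  f2 <- f1; f2$geno <- res_f2$geno

  is_male <- sample(rep(c(FALSE, TRUE), length.out = n_f2))
  phen <- .phenotypes(f2, model, is_male)

  k <- config$f2_n_extremes / 2
  ord <- order(phen)
  keep <- c(ord[seq_len(k)], ord[(n_f2 - k + 1):n_f2])

  # line frequencies of the coded allele
  p_high <- .hap_counts_cpp(high$geno, seq_len(2 * n_high) - 1L, S) / (2 * n_high)
  p_low <- .hap_counts_cpp(low$geno, seq_len(2 * n_low) - 1L, S) / (2 * n_low)
  if (!is.null(pool_freq)) { p_high <- pool_freq[, 1]; p_low <- pool_freq[, 2] }
  polym <- !(p_high == p_low & (p_high == 0 | p_high == 1))
  cand <- which(polym)
  if (length(cand) < 2) stop("insufficient markers polymorphic between lines")
  panel <- sort(sample(cand, min(config$f2_panel_size, length(cand))))

  dos <- t(.dosages(f2, panel))[keep, , drop = FALSE]   # individuals x markers
  flip <- p_high[panel] < p_low[panel]                  # high-line allele coding
  dos[, flip] <- 2L - dos[, flip]
  ph <- ifelse(flip, 1 - p_high[panel], p_high[panel])
  pl <- ifelse(flip, 1 - p_low[panel], p_low[panel])

  eff <- numeric(S); eff[model$qtl_rows] <- model$effects
  markers <- data.frame(
    id = sprintf("snp%05d", panel),
    chrom = high$genome$chrom[high$chrom_id[panel]],
    pos = high$pos[panel],
    p_high = ph, p_low = pl, delta_p = ph - pl,
    effect = ifelse(flip, -eff[panel], eff[panel]))
  individuals <- data.frame(id = sprintf("f2_%03d", keep),
                            sex = ifelse(is_male[keep], "M", "F"),
                            phenotype = phen[keep])
  marker_panel(markers, dos, individuals)
}
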