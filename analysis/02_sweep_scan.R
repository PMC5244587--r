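#!/usr/bin/env Rscript
# Step 2 — scan the pooled genomes for candidate selective-sweep regions.
#
# Reads the sync file from step 1, applies the coverage filters (>10 and
# <100 reads in every pool), computes Karlsson F_ST between the two selected
# lines over 1000 bp windows with 50% overlap, clusters windows above the
# 95th-percentile cutoff (<0.5 Mb apart), removes single-window / <2-SNP
# clusters, and summarises the region set and the sweep/genome
# heterozygosity ratios of all four pools.

library(poolsweep)

in_dir <- "results/synthetic"
out_dir <- "results/scan"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

exp <- readRDS(file.path(in_dir, "experiment.rds"))
chrom_lengths <- setNames(exp$config$genome$length_bp, exp$config$genome$chrom)

pools <- read_sync(file.path(in_dir, "pools.sync"),
                   pool_names = c("HighSel", "LowSel", "HighRelax", "LowRelax"))
sites <- filter_sites(pools, site_filter_params(10, 100, 3))
cat(sprintf("%d of %d sites pass the coverage filters\n",
            length(sites), length(pools)))

# SNP-only input: the sync holds variant sites only, so the full-coverage
# window fraction is not evaluable and is disabled here
wf <- window_fst(sites, pools = c("HighSel", "LowSel"),
                 min_covered_fraction = 0, chrom_lengths = chrom_lengths)
write.table(wf, file.path(out_dir, "windows_highsel_lowsel.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cutoff <- fst_cutoff(wf, 95)
regions <- filter_regions(cluster_windows(wf, cutoff, max_gap = 5e5))
write.table(regions, file.path(out_dir, "sweep_regions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
regions_to_bed(regions, file.path(out_dir, "sweep_regions.bed"))

summ <- region_summary(regions, sum(exp$config$genome$length_bp))
het <- sweep_het_ratio(sites, regions)
write.table(het, file.path(out_dir, "het_ratios.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# how many planted QTL of large effect fall inside detected regions
qtl <- exp$sites[exp$sites$effect != 0, ]
big <- qtl[abs(qtl$effect) >= sort(abs(qtl$effect), decreasing = TRUE)[10], ]
hit <- vapply(seq_len(nrow(big)), function(i) {
  any(regions$chrom == big$chrom[i] & regions$start <= big$pos[i] &
        regions$end >= big$pos[i])
}, logical(1))

cat(sprintf("95%% F_ST cutoff: %.3f\n", cutoff))
cat(sprintf("%d sweep regions, total %.2f Mb (%.1f%% of genome), mean/median %.0f/%.0f kb\n",
            summ$n_regions, summ$total_span / 1e6, summ$pct_genome,
            summ$mean_length / 1e3, summ$median_length / 1e3))
cat(sprintf("top-10 planted QTL contained in a region: %d/10\n", sum(hit)))
cat("sweep/genome heterozygosity ratios:\n")
print(het, digits = 3)
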