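#!/usr/bin/env Rscript
# Step 5 — infer haplotype frequencies inside a candidate sweep region.
#
# Takes the sweep regions from step 2, looks for one where one selected line
# is fixed (the reference haplotype) while other pools still segregate,
# polarizes all pooled frequencies against the reference, groups the
# polarized sites into frequency bands, and reports per-pool haplotype
# frequencies plus the pairwise mean-F_ST matrix across the region.

library(poolsweep)

in_dir <- "results"
out_dir <- "results/haplotypes"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

pools <- read_sync(file.path(in_dir, "synthetic", "pools.sync"),
                   pool_names = c("HighSel", "LowSel", "HighRelax", "LowRelax"))
sites <- filter_sites(pools)
regions <- read.table(file.path(in_dir, "scan", "sweep_regions.tsv"),
                      header = TRUE, sep = "\t")
regions <- regions[order(-regions$n_snps), ]

chosen <- NULL
for (i in seq_len(nrow(regions))) {
  reg <- region_sites(sites, regions$chrom[i], regions$start[i], regions$end[i])
  af <- allele_frequencies(reg)
  if (sum(af$is_snp) < 20) next
  rp <- tryCatch(find_reference_pool(reg), error = function(e) NULL)
  if (is.null(rp) || rp$status != "ok") next
  # want a region still segregating in at least one non-reference pool
  seg_frac <- 1 - rp$frac_fixed[-rp$pool]
  if (max(seg_frac) < 0.2) next
  chosen <- list(region = regions[i, ], sites = reg, rp = rp)
  break
}
if (is.null(chosen)) stop("no sweep region with a fixed reference pool and residual segregation")

r <- chosen$region
cat(sprintf("region %s:%d-%d (%d SNPs), reference pool %s\n",
            r$chrom, r$start, r$end, r$n_snps, chosen$rp$pool_name))

pol <- polarize(chosen$sites, chosen$rp$pool)
pf <- data.frame(chrom = pol$chrom, pos = pol$pos, round(pol$pfreq, 4))
names(pf)[-(1:2)] <- pol$pool_names
write.table(pf, file.path(out_dir, "polarized_frequencies.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

hm <- infer_haplotypes(pol)
print(hm)
write.table(data.frame(pool = rownames(hm$freq), round(hm$freq, 3)),
            file.path(out_dir, "haplotype_frequencies.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

m <- region_fst_table(sites, r$chrom, r$start, r$end)
print(round(m, 3))
write.table(round(m, 4), file.path(out_dir, "region_fst_matrix.tsv"),
            sep = "\t", quote = FALSE)
cat(sprintf("most differentiated pool across the region: %s\n",
            rownames(m)[which.max(rowMeans(m, na.rm = TRUE))]))
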