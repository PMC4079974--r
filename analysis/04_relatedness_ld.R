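#!/usr/bin/env Rscript
# Relatedness and linkage disequilibrium: VanRaden GRM and pair
# bookkeeping, LD pruning, principal components with and without the
# inversion regions, Tracy-Widom eigenvalue tests, LD decay by arm, a
# sliding-window LD track, and long-range high-LD counts stratified by
# inversion membership.

source("analysis/config.R")
cfg <- study_config()
pan <- study_panel(cfg)
out <- results_dir()
gm <- pan$gm
clen <- contig_lengths(cfg)
ir <- inversion_regions(cfg)

G <- compute_grm(gm)
write_tsv(as.data.frame(G$values), file.path(out, "grm.tsv"))
rs <- relatedness_summary(G)
write_tsv(rs$histogram, file.path(out, "relatedness_histogram.tsv"))
cat(sprintf("GRM over %d variants; %d pairs; %.1f%% above 0.05, %.2f%% above 0.5\n",
            G$n_variants, rs$n_pairs, rs$percents[1], rs$percents[2]))

kept <- ld_prune(gm, window = 500, r2_max = 0.2)
cat(sprintf("LD pruning: %d -> %d variants\n", ncol(gm$geno), length(kept)))
write_tsv(data.frame(variant = gm$variants$id[kept]),
          file.path(out, "ld_pruned_variants.tsv"))

# PCA on the MAF-filtered set: at this panel scale aggressive pruning
# leaves too few inversion-linked markers to display the karyotype
# clustering, so the pruned list is reported separately above
excl <- data.frame(contig = ir$contig, start = ir$start - 2e4,
                   end = ir$end + 2e4)
pc_all <- grm_pca(gm, n_pc = 8)
pc_ex <- grm_pca(gm, exclude_regions = excl, n_pc = 8)
sc <- as.data.frame(pc_all$scores)
sc$line_id <- rownames(pc_all$scores)
sc$inv1 <- pan$panel$inv1_dosage
sc$inv2 <- pan$panel$inv2_dosage
write_tsv(sc, file.path(out, "pca_scores.tsv"))
write_tsv(data.frame(component = seq_along(pc_all$tw_p),
                     eigenvalue = pc_all$eigenvalues[seq_along(pc_all$tw_p)],
                     tw_stat = pc_all$tw_stat, tw_p = pc_all$tw_p),
          file.path(out, "tracy_widom.tsv"))
n_sig <- sum(pc_all$tw_p < 0.01, na.rm = TRUE)
cat(sprintf("PCA: %d leading eigenvalues significant at TW P < 0.01 (with inversions)\n",
            n_sig))
lab <- pan$panel$inv1_dosage
kl <- lab %in% c(0L, 2L)
sep <- function(s) {
  s <- s[kl, 1:2]; l <- lab[kl]
  sqrt(sum((colMeans(s[l == 0, ]) - colMeans(s[l == 2, ]))^2)) /
    mean(apply(s, 2, sd))
}
cat(sprintf("karyotype separation on PC1/2: %.2f with inversions, %.2f after excluding them\n",
            sep(pc_all$scores), sep(pc_ex$scores)))

dec <- ld_decay(gm, max_distance = 5e4,
                breaks = c(0, 100, 500, 1000, 5000, 2e4, 5e4),
                max_pairs = 2e5, seed = cfg$seed + 30L)
write_tsv(dec, file.path(out, "ld_decay.tsv"))
xr <- tapply(dec$mean_r2[dec$bin_end <= 1000], dec$contig[dec$bin_end <= 1000], mean)
cat("short-range mean r2 by arm:\n"); print(round(xr, 3))

tr <- ld_windows(gm, pair_dist = c(50, 150), window = 1e5, step = 5e4,
                 contig_lengths = clen)
write_tsv(tr, file.path(out, "ld_windows.tsv"))

d <- haploid_dosage(gm)
mac <- round(pmin(colMeans(d, na.rm = TRUE), 1 - colMeans(d, na.rm = TRUE)) *
               colSums(!is.na(d)))
macs <- sort(intersect(unique(mac[gm$variants$inv_fixed > 0]),
                       unique(mac[gm$variants$inv_fixed == 0])))
macs <- head(macs[macs >= 1], 8)
hc <- high_ld_counts(gm, mac_values = macs, r2_min = 0.95,
                     n_focal = 100, inversion_regions = ir,
                     seed = cfg$seed + 31L)
write_tsv(hc, file.path(out, "high_ld_counts.tsv"))
agg <- tapply(hc$mean_genomewide, hc$stratum, mean)
cat(sprintf("mean genome-wide strong-LD partners: inside inversions %.1f, outside %.1f\n",
            agg[["inside"]], agg[["outside"]]))
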