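#!/usr/bin/env Rscript
# Association mapping: two-stage adjustment for Wolbachia and inversion
# karyotypes, single-variant mixed-model scan against the GRM with
# inflation diagnostics, gene-based burden and SKAT tests with principal
# component covariates, and the genome-size-on-inversion-count model.

source("analysis/config.R")
cfg <- study_config()
pan <- study_panel(cfg)
out <- results_dir()
gm <- pan$gm

G <- compute_grm(gm)
y <- pan$phenotypes$trait
adj <- adjust_phenotype(y, pan$panel)
sub <- subset_gm(gm, variants = which(minor_freq(gm) >= 0.05))

scan_raw <- mixed_model_scan(y, sub, diag(nrow(pan$panel)))
scan_adj <- mixed_model_scan(adj, sub, G)
write_tsv(scan_adj, file.path(out, "mixed_model_scan.tsv"))
lam_raw <- qq_inflation(scan_raw$p)$lambda
lam_adj <- qq_inflation(scan_adj$p)$lambda
cat(sprintf("scan of %d common variants: lambda %.2f unadjusted -> %.2f adjusted (h2 = %.2f)\n",
            nrow(scan_adj), lam_raw, lam_adj, attr(scan_adj, "h2")))
bonf <- 0.05 / nrow(scan_adj)
cat(sprintf("Bonferroni threshold %.2e: %d significant variants\n",
            bonf, sum(scan_adj$p < bonf, na.rm = TRUE)))

## gene-based tests with Wolbachia + inversions + top PCs as covariates
kept <- ld_prune(gm, window = 500, r2_max = 0.2)
pc <- grm_pca(subset_gm(gm, variants = kept), n_pc = 12)
n_pc_used <- max(1, sum(pc$tw_p < 0.01, na.rm = TRUE))
cat(sprintf("using %d principal components (Tracy-Widom P < 0.01) as covariates\n",
            n_pc_used))
kcols <- grep("^inv[0-9]+_dosage$", names(pan$panel), value = TRUE)
covar <- cbind(wolbachia = pan$panel$wolbachia,
               as.matrix(pan$panel[, kcols]),
               pc$scores[, seq_len(n_pc_used), drop = FALSE])
genes <- unlist(pan$founders$gene_models, recursive = FALSE)
rows <- list()
for (g in genes) {
  idx <- gene_window_variants(gm, g, flank = 1000)
  if (length(idx) == 0) next
  bt <- burden_test(gm, idx, y, covariates = covar)
  st <- skat_test(gm, idx, y, covariates = covar)
  if (is.null(bt) || is.null(st)) next
  rows[[length(rows) + 1L]] <- data.frame(
    gene_id = g$gene_id, n_variants = bt$n_variants,
    burden_p = bt$p, skat_p = st$p)
}
gene_tab <- do.call(rbind, rows)
write_tsv(gene_tab, file.path(out, "gene_tests.tsv"))
cat(sprintf("gene-based tests on %d genes: burden lambda %.2f, SKAT lambda %.2f\n",
            nrow(gene_tab), qq_inflation(gene_tab$burden_p)$lambda,
            qq_inflation(gene_tab$skat_p)$lambda))
cat(sprintf("gene-level Bonferroni 0.05: %d burden, %d SKAT hits\n",
            sum(gene_tab$burden_p < 0.05 / nrow(gene_tab)),
            sum(gene_tab$skat_p < 0.05 / nrow(gene_tab))))

## Wolbachia status as a binary trait (logit link, no Wolbachia covariate)
covar_w <- covar[, colnames(covar) != "wolbachia", drop = FALSE]
rows_w <- list()
for (g in genes[seq_len(min(30, length(genes)))]) {
  idx <- gene_window_variants(gm, g, flank = 1000)
  if (length(idx) == 0) next
  bt <- burden_test(gm, idx, pan$panel$wolbachia, covariates = covar_w,
                    family = "binomial")
  if (!is.null(bt))
    rows_w[[length(rows_w) + 1L]] <- data.frame(gene_id = g$gene_id,
                                                burden_p = bt$p)
}
wol_tab <- do.call(rbind, rows_w)
write_tsv(wol_tab, file.path(out, "wolbachia_gene_tests.tsv"))

## genome size vs inversion count
fit <- genome_size_model(pan$phenotypes$genome_size_mb,
                         pan$phenotypes$n_inversions,
                         replicates = pan$genome_size_replicates)
cat(sprintf("genome size on inversion count: b = %.2f Mb (F = %.2f, P = %.3g); among-line ANOVA F = %.2f\n",
            fit$b, fit$F, fit$p, fit$anova_F))
write_tsv(data.frame(b = fit$b, F = fit$F, p = fit$p,
                     anova_F = fit$anova_F, anova_p = fit$anova_p),
          file.path(out, "genome_size_model.tsv"))
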