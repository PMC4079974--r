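#!/usr/bin/env Rscript
# Functional annotation: consequence classes for every variant against
# the toy gene models, line-specific protein-damage calls (variant
# application, translation, global-alignment identity < 90% or start/
# stop loss, all splice variants affected), damage histograms, and a
# panel-wide compensatory-pair scan.

source("analysis/config.R")
cfg <- study_config()
pan <- study_panel(cfg)
out <- results_dir()
gm <- pan$gm

## consequence classification (restricted to variants near genes)
calls <- list()
for (cn in names(pan$founders$gene_models)) {
  seq <- pan$founders$ref[[cn]]
  for (g in pan$founders$gene_models[[cn]]) {
    sp <- genarch:::gene_span(g)
    idx <- which(gm$variants$contig == cn &
                   gm$variants$pos >= sp[1] - 200 &
                   gm$variants$pos < sp[2] + 200)
    for (j in idx) {
      cc <- classify_consequence(gm$variants[j, ], g, seq)
      cc$gene_id <- g$gene_id
      calls[[length(calls) + 1L]] <- cc
    }
  }
}
calls <- do.call(rbind, calls)
write_tsv(calls, file.path(out, "consequence_calls.tsv"))
tab <- sort(table(calls$class), decreasing = TRUE)
cat("consequence classes:\n"); print(tab)
cat(sprintf("potentially damaging calls: %d (%.1f%%)\n",
            sum(calls$damaging), 100 * mean(calls$damaging)))

## damaging variants sit at lower frequencies
maf <- minor_freq(gm)
dmg_var <- unique(calls$variant[calls$damaging])
cls_var <- unique(calls$variant[!calls$damaging &
                                  calls$class %in% c("SYNONYMOUS",
                                                     "INTRON")])
cat(sprintf("median MAF: damaging %.3f vs synonymous/intronic %.3f\n",
            median(maf[dmg_var], na.rm = TRUE),
            median(maf[cls_var], na.rm = TRUE)))

## line-specific gene damage over genes carrying damaging calls
cand_genes <- unique(calls$gene_id[calls$damaging])
reports <- list()
for (cn in names(pan$founders$gene_models)) {
  seq <- pan$founders$ref[[cn]]
  for (g in pan$founders$gene_models[[cn]]) {
    if (!(g$gene_id %in% cand_genes)) next
    for (li in gm$line_ids)
      reports[[length(reports) + 1L]] <- gene_damage(gm, g, seq, li)
  }
}
reports <- do.call(rbind, reports)
write_tsv(reports, file.path(out, "gene_damage.tsv"))
ds <- damage_summary(reports)
write_tsv(ds$genes_per_line, file.path(out, "damaged_genes_per_line.tsv"))
write_tsv(ds$lines_per_gene, file.path(out, "lines_per_damaged_gene.tsv"))
cat(sprintf("%d genes damaged in at least one line; mean %.1f damaged genes per line (of %d genes screened)\n",
            ds$n_damaged_genes, ds$mean_genes_per_line,
            length(cand_genes)))

## compensatory pairs
pairs <- list()
for (cn in names(pan$founders$gene_models)) {
  seq <- pan$founders$ref[[cn]]
  for (g in pan$founders$gene_models[[cn]]) {
    pp <- find_compensatory_pairs(gm, g, seq)
    if (nrow(pp)) pairs[[length(pairs) + 1L]] <- pp
  }
}
if (length(pairs)) {
  pairs <- do.call(rbind, pairs)
  write_tsv(pairs, file.path(out, "compensatory_pairs.tsv"))
  cat(sprintf("compensatory pairs: %d (%s); median distance %.0f bp, median D' = %.2f\n",
              nrow(pairs), paste(names(table(pairs$mechanism)),
                                 collapse = "/"),
              median(pairs$distance), median(pairs$D_prime)))
} else {
  cat("no compensatory pairs segregate in this panel draw\n")
  write_tsv(data.frame(), file.path(out, "compensatory_pairs.tsv"))
}
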