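# Plain-text interchange: VCF (one sample per line, GT:DP:GQ), FASTA,
# BED/GFF tracks and TSV metadata. Internal coordinates are 0-based
# half-open and are converted to 1-based on VCF/GFF output.

#' Write a genotype matrix as VCF
#'
#' One sample per line; genotypes are emitted as `0/0`, `1/1`, `0/1`
#' (residual segregating) or `./.`, with per-call DP and GQ when
#' available.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @param contig_lengths Optional named vector for `##contig` headers.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(gm, path, contig_lengths = NULL) {
  v <- gm$variants
  n <- nrow(gm$geno)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  if (!is.null(contig_lengths))
    for (cn in names(contig_lengths))
      writeLines(sprintf("##contig=<ID=%s,length=%d>", cn,
                         as.integer(contig_lengths[[cn]])), con)
  writeLines(paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                    "Description=\"Genotype\">"), con)
  writeLines(paste0("##FORMAT=<ID=DP,Number=1,Type=Integer,",
                    "Description=\"Depth\">"), con)
  writeLines(paste0("##FORMAT=<ID=GQ,Number=1,Type=Integer,",
                    "Description=\"Genotype quality\">"), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", gm$line_ids),
                   collapse = "\t"), con)
  gt_map <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(v))) {
    g <- gm$geno[, j]
    gt <- ifelse(is.na(g), "./.", gt_map[g + 1L])
    if (!is.null(gm$depth))
      gt <- paste0(gt, ":", gm$depth[, j],
                   ":", round(pmin(gm$gq[, j], 99)))
    fmt <- if (!is.null(gm$depth)) "GT:DP:GQ" else "GT"
    qual <- if (!is.null(v$site_qual) && !is.na(v$site_qual[j]))
      sprintf("%.0f", v$site_qual[j]) else "."
    writeLines(paste(c(v$contig[j], v$pos[j] + 1L,
                       v$id[j] %||% ".", v$ref[j], v$alt[j], qual,
                       "PASS", ".", fmt, gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF written by [write_panel_vcf()] into a genotype matrix
#'
#' @param path VCF path (uncompressed; GT or GT:DP:GQ format).
#' @return A [genotype_matrix()].
#' @export
read_panel_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  hdr <- strsplit(body[1], "\t")[[1]]
  line_ids <- hdr[-(1:9)]
  rows <- strsplit(body[-1], "\t")
  m <- length(rows); n <- length(line_ids)
  v <- data.frame(contig = vapply(rows, `[`, "", 1),
                  pos = as.numeric(vapply(rows, `[`, "", 2)) - 1,
                  id = suppressWarnings(as.integer(vapply(rows, `[`, "", 3))),
                  ref = vapply(rows, `[`, "", 4),
                  alt = vapply(rows, `[`, "", 5),
                  site_qual = suppressWarnings(
                    as.numeric(vapply(rows, `[`, "", 6))),
                  stringsAsFactors = FALSE)
  v$type <- ifelse(nchar(v$ref) == nchar(v$alt) & nchar(v$ref) == 1, "snp",
                   ifelse(nchar(v$alt) < nchar(v$ref), "del", "ins"))
  v$size <- nchar(v$alt) - nchar(v$ref)
  geno <- matrix(NA_integer_, n, m)
  depth <- gq <- NULL
  has_dp <- grepl("DP", vapply(rows, `[`, "", 9))[1]
  if (has_dp) { depth <- matrix(NA_integer_, n, m); gq <- depth }
  code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  for (j in seq_len(m)) {
    cells <- rows[[j]][-(1:9)]
    parts <- strsplit(cells, ":")
    gt <- vapply(parts, `[`, "", 1)
    geno[, j] <- unname(code[gt])
    if (has_dp) {
      depth[, j] <- as.integer(vapply(parts, `[`, "", 2))
      gq[, j] <- as.integer(vapply(parts, `[`, "", 3))
    }
  }
  genotype_matrix(geno, v, line_ids = line_ids, depth = depth, gq = gq)
}

#' Write named sequences as FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write intervals as BED (0-based half-open)
#' @param df Data frame `contig`, `start`, `end` and optional further
#'   columns (written as BED name/score fields).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write toy gene models as GFF3
#' @param models List of [gene_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in models) {
    sp <- gene_span(g)
    writeLines(sprintf("%s\tgenarch\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$contig, sp[1] + 1, sp[2], g$strand, g$gene_id), con)
    for (tx in g$transcripts) {
      writeLines(sprintf("%s\tgenarch\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                         g$contig, min(tx$exons) + 1, max(tx$exons),
                         g$strand, tx$tx_id, g$gene_id), con)
      for (i in seq_len(nrow(tx$exons)))
        writeLines(sprintf("%s\tgenarch\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                           g$contig, tx$exons[i, 1] + 1, tx$exons[i, 2],
                           g$strand, tx$tx_id), con)
      cb <- cds_blocks(tx)
      for (i in seq_len(nrow(cb)))
        writeLines(sprintf("%s\tgenarch\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                           g$contig, cb[i, 1] + 1, cb[i, 2],
                           g$strand, tx$tx_id), con)
    }
  }
  invisible(path)
}

#' Write a data frame as TSV
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
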