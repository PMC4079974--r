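#' Construct a toy gene model
#'
#' Minimal transcript-bearing gene model used as the substrate for
#' consequence and damage annotation. All coordinates are 0-based
#' half-open genomic intervals on the gene's contig.
#'
#' @param gene_id Gene identifier.
#' @param contig Contig name.
#' @param strand `"+"` or `"-"`.
#' @param transcripts List of transcripts; each a list with `tx_id`,
#'   `exons` (two-column matrix of `start`, `end`, ordered by start,
#'   non-overlapping) and `cds` (length-2 genomic interval covered by
#'   coding sequence, intersected with exons to give coding blocks).
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(gene_id, contig, strand, transcripts) {
  stopifnot(strand %in% c("+", "-"), length(transcripts) >= 1)
  for (tx in transcripts) {
    ex <- tx$exons
    stopifnot(is.matrix(ex), ncol(ex) == 2, all(ex[, 2] > ex[, 1]))
    if (nrow(ex) > 1)
      stopifnot(all(ex[-1, 1] >= ex[-nrow(ex), 2]))  # ordered, disjoint
    stopifnot(length(tx$cds) == 2, tx$cds[2] > tx$cds[1])
  }
  structure(list(gene_id = gene_id, contig = contig, strand = strand,
                 transcripts = transcripts),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s%s) %d transcript(s)\n",
              x$gene_id, x$contig, x$strand, length(x$transcripts)))
  invisible(x)
}

# Coding blocks of a transcript: exon pieces inside the CDS interval,
# as a matrix of 0-based half-open intervals in genomic order.
cds_blocks <- function(tx) {
  ex <- tx$exons
  s <- pmax(ex[, 1], tx$cds[1])
  e <- pmin(ex[, 2], tx$cds[2])
  keep <- e > s
  cbind(s[keep], e[keep])
}

# Total gene span (min exon start, max exon end over transcripts).
gene_span <- function(gm) {
  r <- range(unlist(lapply(gm$transcripts, function(tx) tx$exons)))
  c(r[1], r[2])
}

#' Generate toy gene models tiling a contig
#'
#' Places regularly spaced two-exon genes (5' UTR, two coding exons
#' separated by one intron, 3' UTR) on alternating strands. Each CDS is
#' 600 bp (200 codons). Used both by the panel simulator (to define
#' coding sequence for frame-shift depletion) and as annotation
#' substrates.
#'
#' @param contig Contig name.
#' @param contig_length Length in bp.
#' @param spacing Distance between gene starts (bp).
#' @param offset Start of the first gene (bp).
#' @return List of [gene_model()] objects.
#' @export
toy_gene_models <- function(contig, contig_length, spacing = 10000L,
                            offset = 1000L) {
  starts <- seq(offset, contig_length - 800L, by = spacing)
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    exons <- rbind(c(s, s + 350L), c(s + 430L, s + 780L))
    cds <- c(s + 50L, s + 730L)
    strand <- if (i %% 2L == 1L) "+" else "-"
    out[[i]] <- gene_model(sprintf("%s_g%03d", contig, i), contig, strand,
                           list(list(tx_id = sprintf("%s_g%03d_t1", contig, i),
                                     exons = exons, cds = cds)))
  }
  out
}

# Union of CDS intervals of a list of gene models on one contig
# (two-column matrix, possibly empty).
cds_intervals <- function(models) {
  if (length(models) == 0) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, lapply(models, function(g)
    do.call(rbind, lapply(g$transcripts, cds_blocks))))
}

# Is each position (0-based) inside any interval of a two-column matrix?
in_intervals <- function(pos, iv) {
  if (nrow(iv) == 0) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(iv)))
    out <- out | (pos >= iv[i, 1] & pos < iv[i, 2])
  out
}
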