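# Functional consequence classification against toy gene models,
# line-specific protein damage by variant application + translation +
# global-alignment identity, and compensatory-pair detection.

DAMAGING_CLASSES <- c("SPLICE_SITE_ACCEPTOR", "SPLICE_SITE_DONOR",
                      "START_LOST", "FRAME_SHIFT", "STOP_GAINED",
                      "STOP_LOST")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# Spliced plus-strand CDS of a transcript plus a genomic-position ->
# 0-based spliced-index map.
splice_cds <- function(contig_seq, tx) {
  blocks <- cds_blocks(tx)
  lens <- blocks[, 2] - blocks[, 1]
  offs <- cumsum(c(0, lens[-length(lens)]))
  seqs <- vapply(seq_len(nrow(blocks)), function(i)
    subseq0(contig_seq, blocks[i, 1], blocks[i, 2]), character(1))
  index0 <- function(pos) {
    for (i in seq_len(nrow(blocks)))
      if (pos >= blocks[i, 1] && pos < blocks[i, 2])
        return(offs[i] + pos - blocks[i, 1])
    NA_integer_
  }
  list(blocks = blocks, seq = paste(seqs, collapse = ""),
       index0 = index0, n = sum(lens))
}

comp_base <- function(b) chartr("ACGT", "TGCA", b)

#' Classify the functional consequence of a variant on a gene model
#'
#' One call per transcript. Splice sites are the 2 bp at each intron
#' end; an indel in coding sequence whose length change is not a
#' multiple of 3 is a FRAME_SHIFT; substitutions creating or removing a
#' stop codon, or disrupting the start ATG, yield STOP_GAINED /
#' STOP_LOST / START_LOST. The six classes splice acceptor/donor, start
#' lost, frame shift, stop gained and stop lost are flagged potentially
#' damaging.
#'
#' @param variant One-row data frame (or list) with `contig`, `pos`,
#'   `ref`, `alt`.
#' @param gene A [gene_model()].
#' @param contig_seq Reference sequence of the gene's contig.
#' @return Data frame with `variant`, `transcript`, `class`, `damaging`.
#' @export
classify_consequence <- function(variant, gene, contig_seq) {
  if (variant$contig != gene$contig)
    stop("variant lies outside the gene's contig")
  if (variant$pos < 0 || variant$pos >= nchar(contig_seq))
    stop("variant position outside the contig")
  pos <- variant$pos; ref <- variant$ref; alt <- variant$alt
  is_indel <- nchar(ref) != nchar(alt)
  eff <- if (is_indel) pos + 1 else pos   # first changed base
  span <- gene_span(gene)
  out <- list()
  for (tx in gene$transcripts) {
    cls <- NULL
    ex <- tx$exons
    # splice sites: 2 bp at each intron end
    if (nrow(ex) > 1) {
      for (i in seq_len(nrow(ex) - 1)) {
        i_start <- ex[i, 2]; i_end <- ex[i + 1, 1]
        left <- eff >= i_start & eff < i_start + 2
        right <- eff >= i_end - 2 & eff < i_end
        if (left) cls <- if (gene$strand == "+") "SPLICE_SITE_DONOR" else
          "SPLICE_SITE_ACCEPTOR"
        if (right) cls <- if (gene$strand == "+") "SPLICE_SITE_ACCEPTOR" else
          "SPLICE_SITE_DONOR"
      }
    }
    sc <- splice_cds(contig_seq, tx)
    in_cds <- !is.na(sc$index0(eff))
    if (is.null(cls) && in_cds) {
      n <- sc$n
      # reading-orientation CDS and codon housekeeping
      if (is_indel) {
        size <- nchar(alt) - nchar(ref)
        affected <- if (nchar(ref) > 1) seq(pos + 1, pos + nchar(ref) - 1)
        else eff
        ridx <- vapply(affected, function(p) {
          i0 <- sc$index0(p)
          if (is.na(i0)) NA_real_ else
            as.numeric(if (gene$strand == "+") i0 else n - 1L - i0)
        }, numeric(1))
        ridx <- ridx[!is.na(ridx)]
        if (length(ridx) && any(ridx < 3)) cls <- "START_LOST"
        else if (length(ridx) && any(ridx >= n - 3)) cls <- "STOP_LOST"
        else if (size %% 3 != 0) cls <- "FRAME_SHIFT"
        else cls <- if (size < 0) "CODON_DELETION" else "CODON_INSERTION"
      } else {
        i0 <- sc$index0(pos)
        r0 <- if (gene$strand == "+") i0 else n - 1L - i0
        cod_i <- r0 %/% 3
        R <- if (gene$strand == "+") sc$seq else revcomp(sc$seq)
        ref_cod <- substr(R, 3 * cod_i + 1, 3 * cod_i + 3)
        alt_r <- if (gene$strand == "+") alt else comp_base(alt)
        new_cod <- ref_cod
        substr(new_cod, r0 %% 3 + 1, r0 %% 3 + 1) <- alt_r
        last_i <- n %/% 3 - 1
        if (cod_i == 0 && new_cod != "ATG") cls <- "START_LOST"
        else if (cod_i == last_i && ref_cod %in% STOP_CODONS &&
                 !(new_cod %in% STOP_CODONS)) cls <- "STOP_LOST"
        else if (!(ref_cod %in% STOP_CODONS) && new_cod %in% STOP_CODONS)
          cls <- "STOP_GAINED"
        else {
          aa_ref <- translate_cds(ref_cod, stop_at_stop = FALSE)
          aa_new <- translate_cds(new_cod, stop_at_stop = FALSE)
          cls <- if (aa_ref == aa_new) "SYNONYMOUS" else "MISSENSE"
        }
      }
    }
    if (is.null(cls)) {
      in_exon <- any(eff >= ex[, 1] & eff < ex[, 2])
      if (in_exon) {
        # upstream of the CDS in transcription order is the 5' UTR
        cls <- if (gene$strand == "+") {
          if (eff < tx$cds[1]) "UTR_5" else "UTR_3"
        } else {
          if (eff >= tx$cds[2]) "UTR_5" else "UTR_3"
        }
      } else if (eff >= span[1] && eff < span[2]) {
        cls <- "INTRON"
      } else cls <- "INTERGENIC"
    }
    out[[length(out) + 1L]] <- data.frame(
      variant = variant$id %||% NA_integer_, transcript = tx$tx_id,
      class = cls, damaging = cls %in% DAMAGING_CLASSES,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Apply one line's homozygous variants to a transcript's CDS
#'
#' Variants whose reference span falls inside a coding block are applied
#' right-to-left in genomic coordinates on the spliced plus-strand CDS;
#' the result is reverse-complemented for minus-strand transcripts so it
#' reads in translation orientation. Variants with overlapping reference
#' spans are an error.
#'
#' @param tx A transcript (element of `gene_model$transcripts`).
#' @param strand Gene strand.
#' @param contig_seq Reference contig sequence.
#' @param variants Data frame (`pos`, `ref`, `alt`) of homozygous
#'   variants carried by the line; variants not overlapping the CDS are
#'   ignored.
#' @return The line's CDS sequence (reading orientation).
#' @export
apply_variants_to_transcript <- function(tx, strand, contig_seq,
                                         variants) {
  sc <- splice_cds(contig_seq, tx)
  cds <- sc$seq
  if (nrow(variants) == 0)
    return(if (strand == "-") revcomp(cds) else cds)
  v <- variants[order(variants$pos), , drop = FALSE]
  ends <- v$pos + nchar(v$ref)
  if (nrow(v) > 1 && any(v$pos[-1] < ends[-length(ends)])) {
    i <- which(v$pos[-1] < ends[-length(ends)])[1]
    stop(sprintf("overlapping variants at %d and %d", v$pos[i], v$pos[i + 1]))
  }
  v <- v[order(-v$pos), , drop = FALSE]  # right-to-left
  for (i in seq_len(nrow(v))) {
    i0 <- sc$index0(v$pos[i])
    if (is.na(i0)) next
    if (is.na(sc$index0(v$pos[i] + nchar(v$ref[i]) - 1))) next  # crosses block edge
    cds <- paste0(substr(cds, 1, i0),
                  v$alt[i],
                  substr(cds, i0 + nchar(v$ref[i]) + 1, nchar(cds)))
  }
  if (strand == "-") revcomp(cds) else cds
}

#' Translate a CDS with the standard genetic code
#'
#' Translation stops at the first stop codon; a trailing partial codon
#' is dropped.
#'
#' @param cds DNA string (length >= 1; empty input is an error).
#' @param stop_at_stop Stop at the first stop codon (default) or
#'   translate through (stops become `*`).
#' @return Protein string; attribute `"has_stop"` records whether a stop
#'   codon was reached.
#' @export
translate_cds <- function(cds, stop_at_stop = TRUE) {
  if (length(cds) != 1 || is.na(cds) || nchar(cds) == 0)
    stop("empty coding sequence")
  n3 <- nchar(cds) %/% 3
  if (n3 == 0) return(structure("", has_stop = FALSE))
  codons <- substring(cds, 3 * seq_len(n3) - 2, 3 * seq_len(n3))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  if (stop_at_stop) {
    stop_i <- which(aa == "*")
    if (length(stop_i)) {
      return(structure(paste(aa[seq_len(stop_i[1] - 1)], collapse = ""),
                       has_stop = TRUE))
    }
    structure(paste(aa, collapse = ""), has_stop = FALSE)
  } else structure(paste(aa, collapse = ""),
                   has_stop = any(aa == "*"))
}

#' Global alignment percent identity between two proteins
#'
#' End-to-end global alignment with BLOSUM62 scores, gap open 12 and gap
#' extend 2; identity is 100 x matches over the alignment length
#' including gap columns.
#'
#' @param protein_a,protein_b Protein strings.
#' @return Percent identity (0 for an empty protein, with a note
#'   attribute).
#' @export
global_identity <- function(protein_a, protein_b) {
  if (nchar(protein_a) == 0 || nchar(protein_b) == 0)
    return(structure(0, note = "empty protein"))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(protein_a), Biostrings::AAString(protein_b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 12, gapExtension = 2)
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  100 * sum(a == b & a != "-") / length(a)
}

#' Line-specific gene damage report
#'
#' Applies all of a line's homozygous variants to each transcript,
#' translates, and calls the transcript damaged when the start or stop
#' codon is lost or the global identity to the reference protein falls
#' below `identity_min`. The gene is damaged only if every splice
#' variant is damaged.
#'
#' @param gm A [genotype_matrix()].
#' @param gene A [gene_model()].
#' @param contig_seq Reference contig sequence.
#' @param line Line id or index.
#' @param identity_min Identity threshold (percent, default 90).
#' @return One-row data frame: `line_id`, `gene_id`, `start_lost`,
#'   `stop_lost`, `identity` (minimum over transcripts), `damaged`.
#' @export
gene_damage <- function(gm, gene, contig_seq, line, identity_min = 90) {
  li <- if (is.character(line)) match(line, gm$line_ids) else line
  hom <- which(gm$geno[li, ] == 2L & gm$variants$contig == gene$contig)
  v <- gm$variants[hom, , drop = FALSE]
  any_start <- FALSE; any_stop <- FALSE
  min_ident <- 100
  all_damaged <- TRUE
  for (tx in gene$transcripts) {
    ref_cds <- apply_variants_to_transcript(tx, gene$strand, contig_seq,
                                            v[0, , drop = FALSE])
    var_cds <- apply_variants_to_transcript(tx, gene$strand, contig_seq, v)
    start_lost <- substr(var_cds, 1, 3) != "ATG"
    p_ref <- translate_cds(ref_cds)
    p_var <- translate_cds(var_cds)
    stop_lost <- !attr(p_var, "has_stop")
    ident <- if (identical(as.character(p_ref), as.character(p_var))) 100
    else as.numeric(global_identity(p_ref, p_var))
    damaged <- start_lost || stop_lost || ident < identity_min
    any_start <- any_start || start_lost
    any_stop <- any_stop || stop_lost
    min_ident <- min(min_ident, ident)
    all_damaged <- all_damaged && damaged
  }
  data.frame(line_id = gm$line_ids[li], gene_id = gene$gene_id,
             start_lost = any_start, stop_lost = any_stop,
             identity = min_ident, damaged = all_damaged,
             stringsAsFactors = FALSE)
}

#' Panel-wide damage histograms
#'
#' @param reports Data frame of [gene_damage()] rows over lines x genes.
#' @return List: `genes_per_line` and `lines_per_gene` histograms (data
#'   frames `value`, `count`), `n_damaged_genes` (distinct genes damaged
#'   in at least one line), `mean_genes_per_line`.
#' @export
damage_summary <- function(reports) {
  dmg <- reports[reports$damaged, , drop = FALSE]
  per_line <- table(factor(dmg$line_id, levels = unique(reports$line_id)))
  per_gene <- table(dmg$gene_id)
  tab_df <- function(t) {
    if (length(t) == 0)
      return(data.frame(value = integer(), count = integer()))
    tt <- table(as.integer(t))
    data.frame(value = as.integer(names(tt)), count = as.integer(tt))
  }
  list(genes_per_line = tab_df(per_line),
       lines_per_gene = tab_df(per_gene),
       n_damaged_genes = length(per_gene),
       mean_genes_per_line = mean(as.integer(per_line)))
}

#' Find compensatory variant pairs in a gene
#'
#' Frame-restoring pairs: two indels in the same transcript, each
#' frame-shifting alone, whose summed length change is a multiple of 3
#' and whose homozygous carrier sets coincide. Stop-rescuing pairs: a
#' SNP that creates a premature stop alone, paired with a SNP in the
#' same codon whose joint application avoids the stop, where the
#' stop-creating allele occurs only in lines carrying the rescuer. D'
#' is reported for every pair.
#'
#' @param gm A [genotype_matrix()].
#' @param gene A [gene_model()].
#' @param contig_seq Reference contig sequence.
#' @return Data frame `gene_id`, `var_a`, `var_b`, `mechanism`,
#'   `distance`, `D_prime` (zero rows when no pair qualifies).
#' @export
find_compensatory_pairs <- function(gm, gene, contig_seq) {
  span <- gene_span(gene)
  cand <- which(gm$variants$contig == gene$contig &
                  gm$variants$pos >= span[1] & gm$variants$pos < span[2])
  D <- haploid_dosage(gm)
  out <- list()
  carriers <- function(j) which(gm$geno[, j] == 2L)
  for (tx in gene$transcripts) {
    cls <- vapply(cand, function(j) {
      classify_consequence(gm$variants[j, ], gene, contig_seq)$class[
        match(tx$tx_id, vapply(gene$transcripts, `[[`, character(1), "tx_id"))]
    }, character(1))
    # frame-restoring indel pairs
    fs <- cand[cls == "FRAME_SHIFT"]
    if (length(fs) >= 2) {
      cmb <- utils::combn(fs, 2)
      for (q in seq_len(ncol(cmb))) {
        i <- cmb[1, q]; j <- cmb[2, q]
        if ((gm$variants$size[i] + gm$variants$size[j]) %% 3 != 0) next
        ci <- carriers(i); cj <- carriers(j)
        if (length(ci) == 0 || !setequal(ci, cj)) next
        lp <- ld_pair(D[, i], D[, j])
        out[[length(out) + 1L]] <- data.frame(
          gene_id = gene$gene_id, var_a = gm$variants$id[i],
          var_b = gm$variants$id[j], mechanism = "frame_restoring_indels",
          distance = abs(gm$variants$pos[j] - gm$variants$pos[i]),
          D_prime = lp$D_prime, stringsAsFactors = FALSE)
      }
    }
    # stop-rescuing SNP pairs (same codon)
    sg <- cand[cls == "STOP_GAINED"]
    snps <- cand[nchar(gm$variants$ref[cand]) == 1 &
                   nchar(gm$variants$alt[cand]) == 1]
    sc <- splice_cds(contig_seq, tx)
    n <- sc$n
    codon_of <- function(j) {
      i0 <- sc$index0(gm$variants$pos[j])
      if (is.na(i0)) return(NA_integer_)
      r0 <- if (gene$strand == "+") i0 else n - 1L - i0
      r0 %/% 3
    }
    for (i in sg) {
      cod_i <- codon_of(i)
      if (is.na(cod_i)) next
      for (j in setdiff(snps, i)) {
        if (is.na(codon_of(j)) || codon_of(j) != cod_i) next
        # joint codon must not be a stop
        vv <- gm$variants[c(i, j), , drop = FALSE]
        joint <- apply_variants_to_transcript(tx, gene$strand, contig_seq, vv)
        cod <- substr(joint, 3 * cod_i + 1, 3 * cod_i + 3)
        if (cod %in% STOP_CODONS) next
        ci <- carriers(i); cj <- carriers(j)
        if (length(ci) == 0 || !all(ci %in% cj)) next
        lp <- ld_pair(D[, i], D[, j])
        out[[length(out) + 1L]] <- data.frame(
          gene_id = gene$gene_id, var_a = gm$variants$id[i],
          var_b = gm$variants$id[j], mechanism = "stop_rescuing_snp",
          distance = abs(gm$variants$pos[j] - gm$variants$pos[i]),
          D_prime = lp$D_prime, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(gene_id = character(), var_a = integer(),
                      var_b = integer(), mechanism = character(),
                      distance = numeric(), D_prime = numeric()))
  unique(do.call(rbind, out))
}
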