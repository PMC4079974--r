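# Independent consequence oracle: rebuilds the CDS from the mutated
# genomic sequence and compares translations codon by codon.
oracle_snp_class <- function(seq, gene, pos, alt) {
  tx <- gene$transcripts[[1]]
  extract <- function(s) {
    blocks <- cds_blocks(tx)
    out <- paste(vapply(seq_len(nrow(blocks)), function(i)
      substr(s, blocks[i, 1] + 1, blocks[i, 2]), character(1)),
      collapse = "")
    if (gene$strand == "-") revcomp(out) else out
  }
  mut <- replace_bases(seq, pos, alt)
  r <- extract(seq); m <- extract(mut)
  if (r == m) return(NA_character_)
  n3 <- nchar(r) / 3
  rc <- substring(r, 3 * seq_len(n3) - 2, 3 * seq_len(n3))
  mc <- substring(m, 3 * seq_len(n3) - 2, 3 * seq_len(n3))
  i <- which(rc != mc)
  stops <- c("TAA", "TAG", "TGA")
  if (i == 1 && mc[i] != "ATG") return("START_LOST")
  if (i == n3 && rc[i] %in% stops && !(mc[i] %in% stops))
    return("STOP_LOST")
  if (!(rc[i] %in% stops) && mc[i] %in% stops) return("STOP_GAINED")
  aa <- function(cod) unname(Biostrings::GENETIC_CODE[cod])
  if (identical(aa(rc[i]), aa(mc[i]))) "SYNONYMOUS" else "MISSENSE"
}

test_that("SNP consequences agree with exhaustive per-codon enumeration", {
  for (strand in c("+", "-")) {
    fx <- tiny_gene_fixture(cds_len = 60, strand = strand,
                            seed = if (strand == "+") 7 else 8)
    cb <- cds_blocks(fx$gene$transcripts[[1]])
    positions <- seq(cb[1, 1], cb[1, 2] - 1)
    for (pos in positions) {
      refb <- substr(fx$seq, pos + 1, pos + 1)
      for (alt in setdiff(c("A", "C", "G", "T"), refb)) {
        got <- classify_consequence(
          data.frame(contig = "c1", pos = pos, ref = refb, alt = alt,
                     id = 1), fx$gene, fx$seq)$class
        want <- oracle_snp_class(fx$seq, fx$gene, pos, alt)
        expect_equal(got, want,
                     label = sprintf("pos %d alt %s strand %s: %s",
                                     pos, alt, strand, got),
                     expected.label = want)
      }
    }
  }
})

test_that("indel consequences follow the length-mod-3 rule", {
  fx <- tiny_gene_fixture(cds_len = 60, strand = "+", seed = 9)
  mid <- cds_blocks(fx$gene$transcripts[[1]])[1, 1] + 30
  refb <- substr(fx$seq, mid + 1, mid + 2)
  del1 <- data.frame(contig = "c1", pos = mid, ref = refb,
                     alt = substr(refb, 1, 1), id = 1)
  cc <- classify_consequence(del1, fx$gene, fx$seq)
  expect_equal(cc$class, "FRAME_SHIFT")
  expect_true(cc$damaging)
  ref4 <- substr(fx$seq, mid + 1, mid + 4)
  del3 <- data.frame(contig = "c1", pos = mid, ref = ref4,
                     alt = substr(ref4, 1, 1), id = 2)
  expect_equal(classify_consequence(del3, fx$gene, fx$seq)$class,
               "CODON_DELETION")
  expect_error(classify_consequence(
    data.frame(contig = "c2", pos = 1, ref = "A", alt = "T", id = 3),
    fx$gene, fx$seq), "contig")
})

test_that("variant application and translation follow the standard rules", {
  expect_equal(as.character(translate_cds("ATGAAATAA")), "MK")
  expect_equal(as.character(translate_cds("ATGTAA")), "M")
  expect_equal(as.character(translate_cds("ATGAA")), "M")
  expect_true(attr(translate_cds("ATGTAA"), "has_stop"))
  expect_false(attr(translate_cds("ATGAAA"), "has_stop"))
  expect_error(translate_cds(""))

  fx <- tiny_gene_fixture(cds_len = 60, seed = 10)
  tx <- fx$gene$transcripts[[1]]
  cds0 <- apply_variants_to_transcript(tx, "+", fx$seq,
                                       data.frame(pos = numeric(0),
                                                  ref = character(0),
                                                  alt = character(0)))
  expect_equal(nchar(cds0), 60)
  # two SNPs change exactly two positions
  cb <- cds_blocks(tx)
  p1 <- cb[1, 1] + 10; p2 <- cb[1, 1] + 40
  v2 <- data.frame(pos = c(p1, p2),
                   ref = substring(fx$seq, c(p1, p2) + 1, c(p1, p2) + 1),
                   alt = c("A", "C"))
  v2$alt <- ifelse(v2$alt == v2$ref, c("G", "T"), v2$alt)
  cds2 <- apply_variants_to_transcript(tx, "+", fx$seq, v2)
  expect_equal(sum(strsplit(cds0, "")[[1]] != strsplit(cds2, "")[[1]]), 2)
  # +1 then -1 bp leaves the length unchanged
  q1 <- cb[1, 1] + 12; q2 <- cb[1, 1] + 20
  vv <- data.frame(pos = c(q1, q2),
                   ref = c(substr(fx$seq, q1 + 1, q1 + 1),
                           substr(fx$seq, q2 + 1, q2 + 2)),
                   alt = c(paste0(substr(fx$seq, q1 + 1, q1 + 1), "G"),
                           substr(fx$seq, q2 + 1, q2 + 1)))
  expect_equal(nchar(apply_variants_to_transcript(tx, "+", fx$seq, vv)),
               60)
  # overlapping variants are an error
  ov <- data.frame(pos = c(q1, q1 + 1),
                   ref = c(substr(fx$seq, q1 + 1, q1 + 3), "A"),
                   alt = c(substr(fx$seq, q1 + 1, q1 + 1), "T"))
  expect_error(apply_variants_to_transcript(tx, "+", fx$seq, ov),
               "overlapping")
})

test_that("global identity is symmetric, complete, and falls under truncation", {
  p <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  expect_equal(global_identity(p, p), 100)
  q <- "MKTAYIAKQRQISFVK"
  expect_equal(global_identity(p, q), global_identity(q, p))
  expect_lt(global_identity(p, q), 90)
  expect_equal(as.numeric(global_identity("", p)), 0)
  # a frameshift-truncated product of a 200-codon gene scores far below
  # the damage threshold
  fx <- tiny_gene_fixture(cds_len = 300, seed = 11)
  tx <- fx$gene$transcripts[[1]]
  cds_ref <- apply_variants_to_transcript(tx, "+", fx$seq,
                                          data.frame(pos = numeric(0),
                                                     ref = character(0),
                                                     alt = character(0)))
  mid <- cds_blocks(tx)[1, 1] + 40
  fs <- data.frame(pos = mid, ref = substr(fx$seq, mid + 1, mid + 2),
                   alt = substr(fx$seq, mid + 1, mid + 1))
  cds_fs <- apply_variants_to_transcript(tx, "+", fx$seq, fs)
  ident <- global_identity(translate_cds(cds_ref), translate_cds(cds_fs))
  expect_lt(ident, 90)
})

test_that("gene damage requires every splice variant to be affected", {
  fx <- tiny_gene_fixture(cds_len = 120, seed = 12)
  tx1 <- fx$gene$transcripts[[1]]
  # second transcript with a different CDS (shifted window), unaffected
  # by a variant in tx1's first half
  tx2 <- list(tx_id = "tg1_t2", exons = tx1$exons,
              cds = c(tx1$cds[1] + 60, tx1$cds[2]))
  gene2 <- gene_model("tg2", "c1", "+", list(tx1, tx2))
  seq2 <- patch_gene_sequences(fx$seq, list(gene2))
  mid <- tx1$cds[1] + 10
  geno <- matrix(c(2L), 1, 1)
  v <- data.frame(contig = "c1", pos = mid,
                  ref = substr(seq2, mid + 1, mid + 2),
                  alt = substr(seq2, mid + 1, mid + 1),
                  type = "del", size = -1L, id = 1L)
  gm <- genotype_matrix(geno, v, line_ids = "l1")
  rep2 <- gene_damage(gm, gene2, seq2, "l1")
  expect_false(rep2$damaged)          # tx2 untouched
  gene1 <- gene_model("tg1", "c1", "+", list(tx1))
  rep1 <- gene_damage(gm, gene1, seq2, "l1")
  expect_true(rep1$damaged)           # early frameshift, single transcript
  expect_lt(rep1$identity, 90)
  # synonymous-only line: identity 100, not damaged
  syn <- NULL
  cb <- cds_blocks(tx1)
  for (pos in seq(cb[1, 1], cb[1, 2] - 1)) {
    refb <- substr(seq2, pos + 1, pos + 1)
    for (alt in setdiff(c("A", "C", "G", "T"), refb)) {
      if (identical(oracle_snp_class(seq2, gene1, pos, alt),
                    "SYNONYMOUS")) {
        syn <- list(pos = pos, ref = refb, alt = alt); break
      }
    }
    if (!is.null(syn)) break
  }
  vs <- data.frame(contig = "c1", pos = syn$pos, ref = syn$ref,
                   alt = syn$alt, type = "snp", size = 0L, id = 1L)
  gms <- genotype_matrix(matrix(2L, 1, 1), vs, line_ids = "l1")
  reps <- gene_damage(gms, gene1, seq2, "l1")
  expect_false(reps$damaged)
  expect_equal(reps$identity, 100)
})

test_that("damage histograms aggregate lines and genes", {
  expect_equal(damage_summary(data.frame(line_id = "l1", gene_id = "g1",
                                         damaged = FALSE))$n_damaged_genes, 0)
  reports <- expand.grid(line_id = paste0("l", 1:10),
                         gene_id = "g1", stringsAsFactors = FALSE)
  reports$damaged <- c(rep(TRUE, 3), rep(FALSE, 7))
  ds <- damage_summary(reports)
  expect_equal(ds$lines_per_gene$value, 3)
  expect_equal(ds$mean_genes_per_line, 0.3)
  expect_equal(ds$n_damaged_genes, 1)
})

test_that("compensatory pair finder recovers planted pairs and rejects nulls", {
  fx <- tiny_gene_fixture(cds_len = 120, seed = 13)
  tx <- fx$gene$transcripts[[1]]
  cb <- cds_blocks(tx)
  n <- 12
  carriers <- 1:5
  p1 <- cb[1, 1] + 30; p2 <- p1 + 3
  # +1 bp and -1 bp indels 3 bp apart, identical carrier sets
  v <- data.frame(contig = "c1",
                  pos = c(p1, p2),
                  ref = c(substr(fx$seq, p1 + 1, p1 + 1),
                          substr(fx$seq, p2 + 1, p2 + 2)),
                  alt = c(paste0(substr(fx$seq, p1 + 1, p1 + 1), "T"),
                          substr(fx$seq, p2 + 1, p2 + 1)),
                  type = c("ins", "del"), size = c(1L, -1L), id = 1:2)
  g <- matrix(0L, n, 2)
  g[carriers, ] <- 2L
  gm <- genotype_matrix(g, v)
  pairs <- find_compensatory_pairs(gm, fx$gene, fx$seq)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$mechanism, "frame_restoring_indels")
  expect_equal(pairs$D_prime, 1)
  expect_equal(pairs$distance, 3)
  # applying the pair restores identity relative to either alone
  cds_pair <- apply_variants_to_transcript(tx, "+", fx$seq, v)
  cds_one <- apply_variants_to_transcript(tx, "+", fx$seq, v[1, ])
  ref_cds <- apply_variants_to_transcript(tx, "+", fx$seq, v[0, ])
  id_pair <- global_identity(translate_cds(ref_cds),
                             translate_cds(cds_pair))
  id_one <- global_identity(translate_cds(ref_cds),
                            translate_cds(cds_one))
  expect_gte(id_pair, id_one)
  # a lone frameshift yields no pair
  gm1 <- genotype_matrix(g[, 1, drop = FALSE], v[1, , drop = FALSE])
  expect_equal(nrow(find_compensatory_pairs(gm1, fx$gene, fx$seq)), 0)
  # carrier sets that differ disqualify the pair
  g2 <- g; g2[6, 2] <- 2L
  expect_equal(nrow(find_compensatory_pairs(genotype_matrix(g2, v),
                                            fx$gene, fx$seq)), 0)
})

test_that("stop-rescue SNP pairs are detected with carrier containment", {
  fx <- tiny_gene_fixture(cds_len = 120, seed = 14)
  tx <- fx$gene$transcripts[[1]]
  cb <- cds_blocks(tx)
  # find a codon where one SNP creates a stop and a second same-codon
  # SNP rescues it
  found <- NULL
  for (cod in 2:30) {
    base0 <- cb[1, 1] + 3 * (cod - 1)
    for (off1 in 0:2) for (a1 in c("A", "C", "G", "T")) {
      pos1 <- base0 + off1
      r1 <- substr(fx$seq, pos1 + 1, pos1 + 1)
      if (a1 == r1) next
      if (!identical(oracle_snp_class(fx$seq, fx$gene, pos1, a1),
                     "STOP_GAINED")) next
      for (off2 in setdiff(0:2, off1)) for (a2 in c("A", "C", "G", "T")) {
        pos2 <- base0 + off2
        r2 <- substr(fx$seq, pos2 + 1, pos2 + 1)
        if (a2 == r2) next
        joint <- replace_bases(fx$seq, c(pos1, pos2), c(a1, a2))
        codon <- substr(joint, base0 + 1, base0 + 3)
        if (!(codon %in% c("TAA", "TAG", "TGA"))) {
          found <- data.frame(contig = "c1", pos = c(pos1, pos2),
                              ref = c(r1, r2), alt = c(a1, a2),
                              type = "snp", size = 0L, id = 1:2)
          break
        }
      }
      if (!is.null(found)) break
    }
    if (!is.null(found)) break
  }
  expect_false(is.null(found))
  n <- 10
  g <- matrix(0L, n, 2)
  g[1:3, 1] <- 2L          # stop allele only in rescuer carriers
  g[1:5, 2] <- 2L
  gm <- genotype_matrix(g, found)
  pairs <- find_compensatory_pairs(gm, fx$gene, fx$seq)
  expect_true("stop_rescuing_snp" %in% pairs$mechanism)
  # violating containment removes the pair
  g2 <- g; g2[7, 1] <- 2L
  p2 <- find_compensatory_pairs(genotype_matrix(g2, found), fx$gene,
                                fx$seq)
  expect_false("stop_rescuing_snp" %in% p2$mechanism)
})
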