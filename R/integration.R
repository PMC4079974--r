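# Multi-caller variant integration: haplotype bins, indel normalization
# and cross-caller consensus, a binomial-posterior genotype model on
# supporting/opposing read counts, freeze-quality filtering, and the
# Fisher concordance machinery used for cross-platform validation.

#' Group non-SNP variants into haplotype bins
#'
#' Consecutive non-SNP variants on a contig fall in the same bin unless
#' they are separated by a run of at least `flank` bp containing no
#' non-SNP variant; each bin's interval is the span of its members
#' extended by `flank` bp on both sides, clipped to the contig bounds.
#' SNP-only regions form no bins.
#'
#' @param variants Data frame with `contig`, `pos`, `ref`, `type`
#'   columns, sorted by contig then position.
#' @param flank Flank / separation length in bp (default 110).
#' @param contig_lengths Optional named vector for clipping bin ends.
#' @return Data frame: `contig`, `start`, `end` (0-based half-open),
#'   `n_members`, `members` (list column of variant row indices).
#' @export
build_haplotype_bins <- function(variants, flank = 110L,
                                 contig_lengths = NULL) {
  v <- variants
  o <- order(match(v$contig, unique(v$contig)), v$pos)
  if (any(o != seq_len(nrow(v))))
    stop("contract error: variants must be sorted by contig and position")
  idx <- which(v$type != "snp")
  if (length(idx) == 0)
    return(data.frame(contig = character(), start = numeric(),
                      end = numeric(), n_members = integer()))
  out <- list()
  for (cn in unique(v$contig[idx])) {
    ci <- idx[v$contig[idx] == cn]
    pos <- v$pos[ci]
    end <- pos + nchar(v$ref[ci])     # span of the reference allele
    gap_new <- c(TRUE, pos[-1] - end[-length(end)] >= flank)
    bin_id <- cumsum(gap_new)
    for (b in unique(bin_id)) {
      mem <- ci[bin_id == b]
      s <- max(0, min(v$pos[mem]) - flank)
      e <- max(v$pos[mem] + nchar(v$ref[mem])) + flank
      if (!is.null(contig_lengths) && cn %in% names(contig_lengths))
        e <- min(e, contig_lengths[[cn]])
      out[[length(out) + 1L]] <- data.frame(
        contig = cn, start = s, end = e, n_members = length(mem),
        stringsAsFactors = FALSE)
      out[[length(out)]]$members <- I(list(mem))
    }
  }
  do.call(rbind, out)
}

#' Left-align and trim a variant against the reference
#'
#' Canonical representation for indels: trims shared trailing and leading
#' bases and shifts the event as far left as the reference allows, so
#' that alternative alignments of one indel collapse to a single record.
#'
#' @param contig_seq Reference sequence of the variant's contig (string).
#' @param pos 0-based position.
#' @param ref,alt Allele strings.
#' @return List `pos`, `ref`, `alt` in normalized form.
#' @export
left_align_variant <- function(contig_seq, pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  repeat {
    if (length(r) > 0 && length(a) > 0 && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]; a <- a[-length(a)]
    } else if (length(r) == 0 || length(a) == 0) {
      if (pos == 0) break
      b <- substr(contig_seq, pos, pos)   # base at pos-1 (0-based)
      r <- c(b, r); a <- c(b, a); pos <- pos - 1L
    } else break
  }
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1L
  }
  list(pos = pos, ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

#' Cross-caller consensus variant list
#'
#' Takes per-caller variant lists, normalizes non-SNP representations by
#' left alignment when the reference is available, and returns the union
#' keyed by (contig, pos, ref, alt) with the number of callers supporting
#' each record. Records sharing a position but disagreeing on the
#' reference allele are retained and flagged, not merged.
#'
#' @param caller_lists List of data frames (or of
#'   [emit_caller_outputs()]-style lists carrying `$variants`).
#' @param reference Optional named character vector of contig sequences,
#'   enabling indel left-alignment.
#' @return Data frame of unique variants with `support` (caller count)
#'   and `ref_conflict` columns, sorted by contig and position.
#' @export
consensus_variants <- function(caller_lists, reference = NULL) {
  lists <- lapply(caller_lists, function(x)
    if (is.data.frame(x)) x else x$variants)
  lists <- lapply(lists, normalize_variants, reference = reference)
  all <- do.call(rbind, lapply(lists, function(df)
    df[, c("contig", "pos", "ref", "alt"), drop = FALSE]))
  key <- paste(all$contig, all$pos, all$ref, all$alt, sep = ":")
  tab <- table(key)
  uniq <- all[!duplicated(key), , drop = FALSE]
  uniq$support <- as.integer(tab[paste(uniq$contig, uniq$pos, uniq$ref,
                                       uniq$alt, sep = ":")])
  site <- paste(uniq$contig, uniq$pos, sep = ":")
  nref <- tapply(uniq$ref, site, function(r) length(unique(r)))
  uniq$ref_conflict <- as.integer(nref[site]) > 1L
  uniq <- uniq[order(match(uniq$contig, unique(uniq$contig)), uniq$pos,
                     uniq$ref, uniq$alt), , drop = FALSE]
  rownames(uniq) <- NULL
  uniq
}

# Left-align non-SNP records against the reference (shared by consensus
# construction and count pooling).
normalize_variants <- function(df, reference = NULL) {
  if (!is.null(reference)) {
    nonsnp <- which(nchar(df$ref) != nchar(df$alt))
    for (i in nonsnp) {
      la <- left_align_variant(reference[[df$contig[i]]],
                               df$pos[i], df$ref[i], df$alt[i])
      df$pos[i] <- la$pos; df$ref[i] <- la$ref; df$alt[i] <- la$alt
    }
  }
  df
}

#' Genotype call from supporting/opposing read counts
#'
#' Posterior over {homozygous reference, homozygous alternate,
#' segregating} with binomial read likelihoods: the probability that a
#' read supports the alternate allele is `error`, `1 - error`, and `0.5`
#' under the three genotypes respectively, combined with a uniform prior.
#' The call is the posterior mode; genotype quality is the phred score of
#' one minus the maximum posterior; zero depth yields a missing call.
#'
#' @param support,oppose Non-negative integer vectors (or matrices) of
#'   reads supporting/opposing the alternate allele.
#' @param error Per-read sequencing error probability, in (0, 0.5).
#' @return Data frame with `call` (`hom_ref`, `hom_alt`, `segregating`,
#'   `missing`), `code` (0/2/1/NA), `gq`, `depth`, and posterior columns
#'   `p_hom_ref`, `p_hom_alt`, `p_seg`.
#' @export
genotype_from_counts <- function(support, oppose, error = 0.01) {
  if (length(error) != 1 || is.na(error) || error <= 0 || error >= 0.5)
    stop("`error` must lie strictly between 0 and 0.5")
  s <- as.vector(support); o <- as.vector(oppose)
  if (any(s < 0) || any(o < 0)) stop("counts must be non-negative")
  d <- s + o
  ll <- cbind(hom_ref = dbinom(s, d, error, log = TRUE),
              seg = dbinom(s, d, 0.5, log = TRUE),
              hom_alt = dbinom(s, d, 1 - error, log = TRUE))
  lse <- apply(ll, 1, logsumexp)
  post <- exp(ll - lse)
  which_max <- max.col(ll, ties.method = "first")
  call <- c("hom_ref", "segregating", "hom_alt")[which_max]
  code <- c(0L, 1L, 2L)[which_max]
  pmax_ <- post[cbind(seq_along(s), which_max)]
  gq <- -10 * log10(pmax(1 - pmax_, 1e-300))
  miss <- d == 0
  call[miss] <- "missing"; code[miss] <- NA_integer_; gq[miss] <- 0
  data.frame(call = call, code = code, gq = gq, depth = d,
             p_hom_ref = post[, "hom_ref"], p_seg = post[, "seg"],
             p_hom_alt = post[, "hom_alt"], stringsAsFactors = FALSE)
}

#' Integrate pooled caller read counts into a genotype matrix
#'
#' Builds the consensus variant list over callers, pools supporting and
#' opposing read counts across callers per (line, variant), genotypes
#' every call with [genotype_from_counts()], and assigns each site a
#' phred-scaled variant quality score equal to the summed evidence
#' against all-homozygous-reference (`sum over lines of -10 log10
#' P(hom_ref)`), so that sites never supported by any line score near
#' zero.
#'
#' @param caller_outputs List from [emit_caller_outputs()].
#' @param reference Optional contig sequences for left alignment.
#' @param error Sequencing error rate for the genotype model.
#' @param line_ids Line identifiers.
#' @return A [genotype_matrix()] with `depth`, `gq` and per-site
#'   `site_qual`.
#' @export
integrate_panel <- function(caller_outputs, reference = NULL, error = 0.01,
                            line_ids = NULL) {
  cons <- consensus_variants(caller_outputs, reference = reference)
  keyc <- paste(cons$contig, cons$pos, cons$ref, cons$alt, sep = ":")
  n <- nrow(caller_outputs[[1]]$support)
  m <- nrow(cons)
  support <- matrix(0L, n, m)
  oppose <- matrix(0L, n, m)
  for (co in caller_outputs) {
    cv <- normalize_variants(co$variants, reference = reference)
    k <- paste(cv$contig, cv$pos, cv$ref, cv$alt, sep = ":")
    j <- match(k, keyc)
    support[, j] <- support[, j] + co$support
    oppose[, j] <- oppose[, j] + co$oppose
  }
  gc_ <- genotype_from_counts(support, oppose, error = error)
  geno <- matrix(gc_$code, n, m)
  gq <- matrix(gc_$gq, n, m)
  depth <- matrix(gc_$depth, n, m)
  p_hr <- matrix(gc_$p_hom_ref, n, m)
  cons$site_qual <- pmin(colSums(-10 * log10(pmax(p_hr, 1e-300))), 1e6)
  cons$type <- ifelse(nchar(cons$ref) == nchar(cons$alt) &
                        nchar(cons$ref) == 1L, "snp",
                      ifelse(nchar(cons$alt) < nchar(cons$ref), "del", "ins"))
  genotype_matrix(geno, cons, line_ids = line_ids %||% paste0("line_", seq_len(n)),
                  depth = depth, gq = gq)
}

#' Freeze-quality filter policy
#'
#' @param min_site_qual Minimum phred site quality (default 500).
#' @param min_depth Minimum per-call depth (default 1).
#' @param min_gq Minimum per-call phred genotype quality (default 20).
#' @param biallelic_only Drop sites with more than one alternate allele.
#' @param nonoverlapping_only Drop variants whose reference spans overlap
#'   another variant on the same contig.
#' @return Object of class `filter_policy`.
#' @export
filter_policy <- function(min_site_qual = 500, min_depth = 1, min_gq = 20,
                          biallelic_only = TRUE, nonoverlapping_only = TRUE) {
  stopifnot(min_site_qual >= 0, min_depth >= 0, min_gq >= 0)
  structure(list(min_site_qual = min_site_qual, min_depth = min_depth,
                 min_gq = min_gq, biallelic_only = biallelic_only,
                 nonoverlapping_only = nonoverlapping_only),
            class = "filter_policy")
}

#' Apply freeze-quality filters to a genotype matrix
#'
#' Site-level criteria (site quality, biallelism, non-overlap) drop
#' variants; genotype-level criteria (depth, genotype quality) set
#' individual calls missing. Filtering is idempotent.
#'
#' @param gm A [genotype_matrix()] carrying `site_qual` and (optionally)
#'   `depth` and `gq` matrices.
#' @param policy A [filter_policy()].
#' @return Filtered `genotype_matrix`; counts removed per criterion are
#'   attached as attribute `"filter_report"`.
#' @export
apply_freeze_filters <- function(gm, policy = filter_policy()) {
  v <- gm$variants
  m <- nrow(v)
  drop_qual <- if (!is.null(v$site_qual))
    !is.na(v$site_qual) & v$site_qual < policy$min_site_qual else
      rep(FALSE, m)
  site <- paste(v$contig, v$pos, sep = ":")
  drop_multi <- if (policy$biallelic_only)
    site %in% site[duplicated(site)] else rep(FALSE, m)
  drop_overlap <- rep(FALSE, m)
  if (policy$nonoverlapping_only) {
    for (cn in unique(v$contig)) {
      i <- which(v$contig == cn)
      o <- i[order(v$pos[i])]
      s <- v$pos[o]; e <- v$pos[o] + nchar(v$ref[o])
      if (length(o) > 1) {
        ov <- c(FALSE, s[-1] < cummax(e[-length(e)]))
        # mark both partners of an overlap
        hit <- which(ov)
        drop_overlap[o[hit]] <- TRUE
        drop_overlap[o[pmax(hit - 1, 1)]] <- drop_overlap[o[pmax(hit - 1, 1)]] | ov[hit]
      }
    }
  }
  keep <- !(drop_qual | drop_multi | drop_overlap)
  out <- subset_gm(gm, variants = which(keep))
  n_low_depth <- 0L; n_low_gq <- 0L
  if (!is.null(out$depth)) {
    bad <- out$depth < policy$min_depth & !is.na(out$geno)
    n_low_depth <- sum(bad)
    out$geno[bad] <- NA_integer_
  }
  if (!is.null(out$gq)) {
    bad <- out$gq < policy$min_gq & !is.na(out$geno)
    n_low_gq <- sum(bad)
    out$geno[bad] <- NA_integer_
  }
  attr(out, "filter_report") <- data.frame(
    criterion = c("site_quality", "multiallelic", "overlapping",
                  "call_depth", "call_gq"),
    removed = c(sum(drop_qual), sum(drop_multi), sum(drop_overlap),
                n_low_depth, n_low_gq))
  out
}

#' Concordance test between two platforms' read counts
#'
#' Two-sided Fisher's exact test on the 2x2 table of supporting/opposing
#' read counts from two genotyping platforms for the same variant and
#' line; discordance is declared when p falls below `alpha`.
#'
#' @param counts_a,counts_b Length-2 vectors `(supporting, opposing)`.
#' @param alpha Significance level for declaring discordance.
#' @return List `p_value`, `concordant`.
#' @export
concordance_test <- function(counts_a, counts_b, alpha = 0.05) {
  stopifnot(length(counts_a) == 2, length(counts_b) == 2,
            all(c(counts_a, counts_b) >= 0))
  if (sum(counts_a) + sum(counts_b) == 0)
    return(list(p_value = 1, concordant = TRUE))
  p <- fisher_exact(rbind(counts_a, counts_b))
  list(p_value = p, concordant = p >= alpha)
}

#' Percent concordance of validated calls
#'
#' @param concordant Number of concordant comparisons.
#' @param total Total comparisons (> 0).
#' @return Percent concordance, rounded to 2 decimal places.
#' @examples
#' validation_summary(1458, 1463)  # 99.66
#' @export
validation_summary <- function(concordant, total) {
  if (length(total) != 1 || total <= 0) stop("`total` must be positive")
  if (concordant < 0 || concordant > total)
    stop("`concordant` must lie in [0, total]")
  round(100 * concordant / total, 2)
}
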