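# Population-genomic statistics over the inbred panel. Lines are treated
# as single haplotypes throughout: a residual segregating call is missing
# data at that site for that line (inbreeding coefficient ~0.99 makes the
# haploid reading the natural convention for an inbred panel).

#' Per-line segregating-site profiles
#'
#' Percent of variant sites called segregating in each line, optionally
#' per contig. Lines with zero non-missing calls on a contig are flagged
#' with `NA`.
#'
#' @param gm A [genotype_matrix()].
#' @param by_contig Split by contig (default) or genome-wide.
#' @return Data frame `line_id`, `contig`, `n_called`, `n_segregating`,
#'   `percent_segregating`.
#' @export
segregating_fraction <- function(gm, by_contig = TRUE) {
  contigs <- if (by_contig) unique(gm$variants$contig) else "genome"
  out <- list()
  for (cn in contigs) {
    sel <- if (by_contig) gm$variants$contig == cn else
      rep(TRUE, ncol(gm$geno))
    g <- gm$geno[, sel, drop = FALSE]
    called <- rowSums(!is.na(g))
    seg <- rowSums(g == 1L, na.rm = TRUE)
    out[[length(out) + 1L]] <- data.frame(
      line_id = gm$line_ids, contig = cn, n_called = called,
      n_segregating = seg,
      percent_segregating = ifelse(called > 0, 100 * seg / called, NA_real_),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Association between high segregating fractions and heterokaryotypy
#'
#' Cross-tabulates line x arm combinations by whether the percent of
#' segregating sites reaches `threshold` and whether the line is
#' heterokaryotypic for an inversion on that arm, then tests the 2x2
#' table with [fisher_exact()].
#'
#' @param profiles Output of [segregating_fraction()].
#' @param karyotypes Data frame `line_id`, `contig`, `het` (logical:
#'   heterokaryotypic for any inversion on that arm). Combinations
#'   absent from this table are excluded with a warning.
#' @param threshold Percent segregating threshold (default 9, the
#'   empirical break between homokaryotypic and heterokaryotypic
#'   distributions).
#' @return List with `table` (2x2: rows >= / < threshold, columns het /
#'   hom) and `p_value`.
#' @export
inversion_association <- function(profiles, karyotypes, threshold = 9) {
  key_p <- paste(profiles$line_id, profiles$contig)
  key_k <- paste(karyotypes$line_id, karyotypes$contig)
  j <- match(key_p, key_k)
  if (anyNA(j)) {
    warning(sum(is.na(j)), " line/arm combination(s) without karyotype excluded")
  }
  ok <- !is.na(j) & !is.na(profiles$percent_segregating)
  hi <- profiles$percent_segregating[ok] >= threshold
  het <- karyotypes$het[j[ok]]
  tab <- matrix(c(sum(hi & het), sum(!hi & het),
                  sum(hi & !het), sum(!hi & !het)), 2, 2,
                dimnames = list(c(">=thr", "<thr"), c("het", "hom")))
  list(table = tab, p_value = fisher_exact(tab))
}

#' Heterokaryotype table from panel metadata
#'
#' @param panel Panel metadata from [simulate_inbreeding()].
#' @param config The matching [sim_config()] (maps inversions to arms).
#' @param contigs Contig names to report (default: all in the config).
#' @return Data frame `line_id`, `contig`, `het` suitable for
#'   [inversion_association()].
#' @export
karyotype_het_table <- function(panel, config,
                                contigs = config$contigs$name) {
  arms <- vapply(config$inversions, `[[`, character(1), "arm")
  out <- list()
  for (cn in contigs) {
    ks <- which(arms == cn)
    het <- rep(FALSE, nrow(panel))
    for (k in ks) het <- het | panel[[paste0("inv", k, "_dosage")]] == 1L
    out[[length(out) + 1L]] <- data.frame(line_id = panel$line_id,
                                          contig = cn, het = het,
                                          stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Per-site heterozygosity terms 2 p (1-p) n/(n-1) over non-missing
# haploid calls; sites with < 2 callable lines contribute NA.
site_pi_terms <- function(gm, sel = rep(TRUE, ncol(gm$geno)),
                          lines = seq_len(nrow(gm$geno))) {
  d <- haploid_dosage(gm)[lines, sel, drop = FALSE]
  n <- colSums(!is.na(d))
  p <- colMeans(d, na.rm = TRUE)
  ifelse(n >= 2, 2 * p * (1 - p) * n / (n - 1), NA_real_)
}

#' Nucleotide (and indel) diversity in non-overlapping windows
#'
#' Per window, \eqn{\pi = \sum_{sites} \frac{n}{n-1} 2 p (1-p) / w} with
#' `n` the number of lines with a usable haploid call at the site and `w`
#' the window length. Indels and multi-nucleotide variants receive the
#' same weight as SNPs regardless of length.
#'
#' @param gm A [genotype_matrix()].
#' @param window_size Window length in bp (default 1e5, non-overlapping).
#' @param variant_class `"snp"`, `"indel"` or `"all"`.
#' @param contig_lengths Named vector of contig lengths; defaults to the
#'   last variant position per contig rounded up to a full window.
#' @return Data frame `contig`, `start`, `end`, `pi`, `n_sites`
#'   (`pi = NA` flags windows whose variant sites are all uncallable).
#' @export
nucleotide_diversity <- function(gm, window_size = 1e5,
                                 variant_class = c("all", "snp", "indel"),
                                 contig_lengths = NULL) {
  variant_class <- match.arg(variant_class)
  keep <- switch(variant_class,
                 all = rep(TRUE, nrow(gm$variants)),
                 snp = gm$variants$type == "snp",
                 indel = gm$variants$type %in% c("del", "ins"))
  terms <- rep(NA_real_, nrow(gm$variants))
  terms[keep] <- site_pi_terms(gm, keep)
  out <- list()
  for (cn in unique(gm$variants$contig)) {
    L <- if (!is.null(contig_lengths) && cn %in% names(contig_lengths))
      contig_lengths[[cn]] else
        (floor(max(gm$variants$pos[gm$variants$contig == cn]) / window_size) + 1) *
        window_size
    starts <- seq(0, L - 1, by = window_size)
    for (s in starts) {
      i <- which(gm$variants$contig == cn & gm$variants$pos >= s &
                   gm$variants$pos < s + window_size & keep)
      tt <- terms[i]
      pi <- if (length(i) == 0) 0 else if (all(is.na(tt))) NA_real_ else
        sum(tt, na.rm = TRUE) / min(window_size, L - s)
      out[[length(out) + 1L]] <- data.frame(
        contig = cn, start = s, end = min(s + window_size, L), pi = pi,
        n_sites = sum(!is.na(tt)), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Per-window divergence to the outgroup
#'
#' `k` = number of fixed differences (sites where every callable line
#' shares one allele and that allele differs from the outgroup allele)
#' divided by window length. Sites with unknown outgroup state are
#' skipped.
#'
#' @param gm A [genotype_matrix()].
#' @param outgroup Character vector of outgroup alleles aligned to
#'   `gm$variants` rows (`NA` = unknown).
#' @param window_size Window length in bp.
#' @param contig_lengths Optional named contig lengths.
#' @return Data frame `contig`, `start`, `end`, `k`, `n_fixed`.
#' @export
divergence_windows <- function(gm, outgroup, window_size = 1e5,
                               contig_lengths = NULL) {
  stopifnot(length(outgroup) == nrow(gm$variants))
  d <- haploid_dosage(gm)
  n <- colSums(!is.na(d))
  p <- colMeans(d, na.rm = TRUE)
  panel_allele <- ifelse(p == 1, gm$variants$alt,
                         ifelse(p == 0, gm$variants$ref, NA))
  fixed_diff <- !is.na(panel_allele) & !is.na(outgroup) & n >= 1 &
    panel_allele != outgroup
  out <- list()
  for (cn in unique(gm$variants$contig)) {
    L <- if (!is.null(contig_lengths) && cn %in% names(contig_lengths))
      contig_lengths[[cn]] else
        (floor(max(gm$variants$pos[gm$variants$contig == cn]) / window_size) + 1) *
        window_size
    starts <- seq(0, L - 1, by = window_size)
    for (s in starts) {
      i <- gm$variants$contig == cn & gm$variants$pos >= s &
        gm$variants$pos < s + window_size
      nf <- sum(fixed_diff[i])
      out[[length(out) + 1L]] <- data.frame(
        contig = cn, start = s, end = min(s + window_size, L),
        k = nf / min(window_size, L - s), n_fixed = nf,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Polarize indels against outgroup alleles
#'
#' The ancestral allele is the panel allele exactly matching the
#' outgroup; the other allele is derived. Sites where the outgroup
#' matches neither allele are unpolarized and excluded from derived
#' classifications. The derived type compares allele lengths: shorter
#' derived allele = deletion, longer = insertion.
#'
#' @param gm A [genotype_matrix()] (only non-SNP rows are polarized
#'   unless `include_snps`).
#' @param outgroup Character vector of outgroup alleles aligned to
#'   `gm$variants`.
#' @param include_snps Also polarize SNPs (derived type
#'   "substitution").
#' @return Data frame with `id`, `contig`, `pos`, `status`
#'   (`polarized`/`unpolarized`), `ancestral` (`ref`/`alt`),
#'   `derived_type`, `derived_count`, `n_called`, `derived_freq`.
#' @export
polarize_indels <- function(gm, outgroup, include_snps = FALSE) {
  stopifnot(length(outgroup) == nrow(gm$variants))
  sel <- if (include_snps) rep(TRUE, nrow(gm$variants)) else
    gm$variants$type %in% c("del", "ins")
  v <- gm$variants[sel, , drop = FALSE]
  og <- outgroup[sel]
  d <- haploid_dosage(gm)[, sel, drop = FALSE]
  match_ref <- !is.na(og) & og == v$ref
  match_alt <- !is.na(og) & og == v$alt
  status <- ifelse(xor(match_ref, match_alt), "polarized", "unpolarized")
  ancestral <- ifelse(match_ref, "ref", ifelse(match_alt, "alt", NA))
  derived <- ifelse(ancestral == "ref", "alt", "ref")
  dlen <- ifelse(derived == "alt", nchar(v$alt), nchar(v$ref))
  alen <- ifelse(ancestral == "alt", nchar(v$alt), nchar(v$ref))
  derived_type <- ifelse(dlen < alen, "deletion",
                         ifelse(dlen > alen, "insertion", "substitution"))
  derived_type[status != "polarized"] <- NA
  n_called <- colSums(!is.na(d))
  alt_count <- colSums(d, na.rm = TRUE)
  derived_count <- ifelse(derived == "alt", alt_count, n_called - alt_count)
  derived_count[status != "polarized"] <- NA
  data.frame(id = v$id %||% seq_len(nrow(v)), contig = v$contig,
             pos = v$pos, status = status, ancestral = ancestral,
             derived_type = derived_type, derived_count = derived_count,
             n_called = n_called,
             derived_freq = derived_count / pmax(n_called, 1),
             stringsAsFactors = FALSE)
}

#' Allele-frequency spectrum by functional class
#'
#' Histogram of minor or derived allele frequencies per class of
#' variants; counts per class sum to the number of classified variants.
#'
#' @param freq Numeric vector of allele frequencies (minor: in `[0, .5]`;
#'   derived: in `[0, 1]`). `NA` entries are dropped.
#' @param class Character vector of per-variant classes (same length).
#' @param breaks Bin boundaries (default deciles of `[0, 1]`).
#' @return Data frame `class`, `bin`, `count`.
#' @export
frequency_spectrum <- function(freq, class = rep("all", length(freq)),
                               breaks = seq(0, 1, by = 0.1)) {
  ok <- !is.na(freq)
  freq <- freq[ok]; class <- class[ok]
  bin <- cut(freq, breaks = breaks, include.lowest = TRUE, right = FALSE)
  # place values equal to the top break in the last bin
  bin[freq >= breaks[length(breaks)]] <- levels(bin)[nlevels(bin)]
  out <- as.data.frame(table(class = class, bin = bin),
                       stringsAsFactors = FALSE)
  names(out)[3] <- "count"
  out
}

#' Diversity within and between inversion karyotypes
#'
#' Nucleotide diversity inside an inversion region computed within
#' standard-homokaryotypic lines, within inverted-homokaryotypic lines,
#' and between the two groups (mean per-site pairwise difference across
#' group pairs divided by region length).
#'
#' @param gm A [genotype_matrix()].
#' @param karyotype Per-line labels: `"standard"`, `"inverted"`, or `NA`
#'   (heterokaryotypic / unknown lines are excluded).
#' @param region List or vector `(contig, start, end)`.
#' @return List `pi_standard`, `pi_inverted`, `pi_between`, `n_standard`,
#'   `n_inverted` (within-group values `NA` when a group has < 2 lines).
#' @export
karyotype_diversity <- function(gm, karyotype, region) {
  contig <- region[[1]]; start <- as.numeric(region[[2]])
  end <- as.numeric(region[[3]])
  len <- end - start
  sel <- gm$variants$contig == contig & gm$variants$pos >= start &
    gm$variants$pos < end
  std <- which(karyotype == "standard")
  inv <- which(karyotype == "inverted")
  within_pi <- function(lines) {
    if (length(lines) < 2) return(NA_real_)
    sum(site_pi_terms(gm, sel, lines), na.rm = TRUE) / len
  }
  d <- haploid_dosage(gm)[, sel, drop = FALSE]
  between <- if (length(std) == 0 || length(inv) == 0) NA_real_ else {
    p_s <- colMeans(d[std, , drop = FALSE], na.rm = TRUE)
    p_i <- colMeans(d[inv, , drop = FALSE], na.rm = TRUE)
    sum(p_s * (1 - p_i) + p_i * (1 - p_s), na.rm = TRUE) / len
  }
  list(pi_standard = within_pi(std), pi_inverted = within_pi(inv),
       pi_between = between,
       n_standard = length(std), n_inverted = length(inv))
}

#' SNP density around intermediate-frequency focal variants
#'
#' For each focal variant (minor allele frequency inside `maf_band`),
#' counts SNPs at each distance up to `window` bp on either side,
#' stratified by the SNP's minor-allele-count class and by whether the
#' SNP's minor allele is present among lines carrying versus not
#' carrying the focal minor allele. Reported as the mean count per focal
#' variant at each distance.
#'
#' @param gm A [genotype_matrix()].
#' @param focal_types Variant types eligible as focal variants.
#' @param maf_band Closed MAF interval for focal variants.
#' @param window Maximum distance (bp).
#' @param mac_breaks Minor-allele-count class boundaries (left-closed).
#' @return Data frame `distance`, `mac_class`, `stratum`
#'   (`carrier`/`non_carrier`), `mean_count`, plus attribute `n_focal`.
#' @export
variant_clustering <- function(gm, focal_types = c("del", "ins"),
                               maf_band = c(0.40, 0.50), window = 100L,
                               mac_breaks = c(1, 2, 6, Inf)) {
  d <- haploid_dosage(gm)
  p <- colMeans(d, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  mac <- round(maf * colSums(!is.na(d)))
  is_snp <- gm$variants$type == "snp"
  focal <- which(gm$variants$type %in% focal_types &
                   maf >= maf_band[1] & maf <= maf_band[2])
  classes <- paste0("mac[", mac_breaks[-length(mac_breaks)], ",",
                    mac_breaks[-1], ")")
  snp_class <- cut(mac, mac_breaks, right = FALSE, labels = classes)
  minor_is_alt <- p <= 0.5
  acc <- array(0, dim = c(window, length(classes), 2),
               dimnames = list(NULL, classes, c("carrier", "non_carrier")))
  if (length(focal) == 0) stop("no focal variants in the MAF band")
  for (f in focal) {
    carriers <- which(d[, f] == (if (minor_is_alt[f]) 1 else 0))
    non_carriers <- setdiff(which(!is.na(d[, f])), carriers)
    near <- which(is_snp & gm$variants$contig == gm$variants$contig[f] &
                    abs(gm$variants$pos - gm$variants$pos[f]) >= 1 &
                    abs(gm$variants$pos - gm$variants$pos[f]) <= window)
    for (s in near) {
      dist <- abs(gm$variants$pos[s] - gm$variants$pos[f])
      cl <- as.character(snp_class[s])
      if (is.na(cl)) next
      minor_val <- if (minor_is_alt[s]) 1 else 0
      if (length(carriers) &&
          any(d[carriers, s] == minor_val, na.rm = TRUE))
        acc[dist, cl, "carrier"] <- acc[dist, cl, "carrier"] + 1
      if (length(non_carriers) &&
          any(d[non_carriers, s] == minor_val, na.rm = TRUE))
        acc[dist, cl, "non_carrier"] <- acc[dist, cl, "non_carrier"] + 1
    }
  }
  out <- expand.grid(distance = seq_len(window), mac_class = classes,
                     stratum = c("carrier", "non_carrier"),
                     stringsAsFactors = FALSE)
  out$mean_count <- as.vector(acc) / length(focal)
  attr(out, "n_focal") <- length(focal)
  out
}

#' Rank correlation between diversity and recombination rate
#'
#' Spearman correlation across windows matched between a diversity track
#' and a recombination-rate track (ties mid-ranked).
#'
#' @param diversity Output of [nucleotide_diversity()].
#' @param recmap Data frame `contig`, `start`, `rate` (cM/Mb per window).
#' @return List `rho`, `p_value`, `n_windows`; `rho = NA` with a flag
#'   when fewer than 3 matched windows or a degenerate (constant) track.
#' @export
recombination_correlation <- function(diversity, recmap) {
  key_d <- paste(diversity$contig, diversity$start)
  key_r <- paste(recmap$contig, recmap$start)
  j <- match(key_d, key_r)
  ok <- !is.na(j) & !is.na(diversity$pi)
  x <- diversity$pi[ok]; y <- recmap$rate[j[ok]]
  if (sum(ok) < 3 || length(unique(x)) < 2 || length(unique(y)) < 2)
    return(list(rho = NA_real_, p_value = NA_real_, n_windows = sum(ok),
                degenerate = TRUE))
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_windows = sum(ok), degenerate = FALSE)
}

#' Variant enrichment or depletion across chromatin domains
#'
#' Fold enrichment = (variants in domain / domain bp) over (variants
#' genome-wide / total bp), with a two-sided binomial test of the
#' domain's count against expectation proportional to its length.
#' Positions not covered by any domain form an `"other"` class.
#'
#' @param variants Variant data frame (`contig`, `pos`, `type`).
#' @param domains Data frame `contig`, `start`, `end`, `class` (0-based
#'   half-open intervals; zero-length intervals are excluded).
#' @param contig_lengths Named vector of contig lengths (for the
#'   uncovered "other" class).
#' @param by_type Split by variant type.
#' @return Data frame `domain_class`, `variant_class`, `n_variants`,
#'   `domain_bp`, `fold`, `p_value`.
#' @export
chromatin_enrichment <- function(variants, domains, contig_lengths,
                                 by_type = TRUE) {
  domains <- domains[domains$end > domains$start, , drop = FALSE]
  assign_class <- rep("other", nrow(variants))
  for (i in seq_len(nrow(domains))) {
    hit <- variants$contig == domains$contig[i] &
      variants$pos >= domains$start[i] & variants$pos < domains$end[i]
    assign_class[hit] <- domains$class[i]
  }
  total_bp <- sum(contig_lengths)
  bp <- tapply(domains$end - domains$start, domains$class, sum)
  bp <- c(bp, other = total_bp - sum(bp))
  vclass <- if (by_type) variants$type else rep("all", nrow(variants))
  out <- list()
  for (vc in unique(vclass)) {
    tot <- sum(vclass == vc)
    for (dc in names(bp)) {
      cnt <- sum(vclass == vc & assign_class == dc)
      expd <- bp[[dc]] / total_bp
      fold <- (cnt / bp[[dc]]) / (tot / total_bp)
      p <- if (tot > 0) binom.test(cnt, tot, expd)$p.value else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        domain_class = dc, variant_class = vc, n_variants = cnt,
        domain_bp = bp[[dc]], fold = fold, p_value = p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
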