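# Pairwise linkage disequilibrium on the inbred panel. Lines are haploid
# gametes: residual segregating calls become missing and pairs of sites
# use pairwise-complete lines. Distances are measured between variant
# start coordinates.

#' LD coefficients for one pair of sites
#'
#' From per-line haploid alleles: \eqn{D = p_{AB} - p_A p_B},
#' \eqn{r^2 = D^2 / (p_A(1-p_A) p_B(1-p_B))}, and \eqn{D' = |D|/D_{max}}
#' with \eqn{D_{max} = \min(p_A(1-p_B), (1-p_A)p_B)} for positive `D`
#' and \eqn{\min(p_A p_B, (1-p_A)(1-p_B))} for negative `D`.
#'
#' @param a,b Numeric vectors of 0/1 alleles per line (`NA` allowed);
#'   pairwise-complete lines are used.
#' @return List `D`, `D_prime`, `r2`, `n` — or `NULL` (with attribute) if
#'   fewer than 2 complete lines or either site is monomorphic among
#'   them.
#' @export
ld_pair <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 2 || length(unique(a)) < 2 || length(unique(b)) < 2)
    return(structure(list(D = NA_real_, D_prime = NA_real_,
                          r2 = NA_real_, n = n), undefined = TRUE))
  pA <- mean(a); pB <- mean(b); pAB <- mean(a * b)
  D <- pAB - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  Dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  Dp <- if (D == 0) 0 else abs(D) / Dmax
  list(D = D, D_prime = Dp, r2 = r2, n = n)
}

#' LD decay with physical distance, per chromosome arm
#'
#' Mean \eqn{r^2} over intra-arm variant pairs binned by distance
#' between start coordinates. Pairs are subsampled (with the given seed)
#' when an arm exceeds `max_pairs`.
#'
#' @param gm A [genotype_matrix()].
#' @param max_distance Maximum pair distance (bp).
#' @param breaks Distance-bin boundaries (bp).
#' @param maf_min Minor-allele-frequency floor.
#' @param max_pairs Pair subsampling cap per arm.
#' @param seed Seed for pair subsampling.
#' @return Data frame `contig`, `bin_start`, `bin_end`, `mean_r2`,
#'   `n_pairs` (empty bins omitted).
#' @export
ld_decay <- function(gm, max_distance = 1e4,
                     breaks = c(0, 10, 50, 100, 500, 1000, 5000, 1e4),
                     maf_min = 0.05, max_pairs = 2e6, seed = 1L) {
  D <- haploid_dosage(gm)
  keep <- minor_freq(gm) >= maf_min
  keep[is.na(keep)] <- FALSE
  out <- list()
  set.seed(seed)
  for (cn in unique(gm$variants$contig)) {
    idx <- which(keep & gm$variants$contig == cn)
    if (length(idx) < 2) next
    pos <- gm$variants$pos[idx]
    pr <- utils::combn(length(idx), 2)
    dist <- pos[pr[2, ]] - pos[pr[1, ]]
    sel <- which(abs(dist) <= max_distance)
    if (length(sel) > max_pairs) sel <- sample(sel, max_pairs)
    if (length(sel) == 0) next
    r2 <- vapply(sel, function(j)
      ld_pair(D[, idx[pr[1, j]]], D[, idx[pr[2, j]]])$r2, numeric(1))
    bin <- cut(abs(dist[sel]), breaks, include.lowest = TRUE)
    for (b in levels(bin)) {
      v <- r2[bin == b & !is.na(r2)]
      if (length(v) == 0) next
      lims <- as.numeric(strsplit(gsub("[][()]", "", b), ",")[[1]])
      out[[length(out) + 1L]] <- data.frame(
        contig = cn, bin_start = lims[1], bin_end = lims[2],
        mean_r2 = mean(v), n_pairs = length(v), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(data.frame(contig = character(),
                                          bin_start = numeric(),
                                          bin_end = numeric(),
                                          mean_r2 = numeric(),
                                          n_pairs = integer()))
  do.call(rbind, out)
}

#' Sliding-window track of short-range LD
#'
#' Mean \eqn{r^2} between variant pairs `pair_dist[1]`-`pair_dist[2]` bp
#' apart, in sliding windows (pair midpoint in window).
#'
#' @param gm A [genotype_matrix()].
#' @param pair_dist Length-2 pair-distance band (bp; default 50-150).
#' @param window Window size (bp, default 1 Mb).
#' @param step Step (bp, default 100 kb).
#' @param maf_min MAF floor.
#' @param contig_lengths Optional named contig lengths.
#' @return Data frame `contig`, `start`, `end`, `mean_r2`, `n_pairs`
#'   (windows with no pairs report `NA`).
#' @export
ld_windows <- function(gm, pair_dist = c(50, 150), window = 1e6,
                       step = 1e5, maf_min = 0.05, contig_lengths = NULL) {
  D <- haploid_dosage(gm)
  keep <- minor_freq(gm) >= maf_min
  keep[is.na(keep)] <- FALSE
  out <- list()
  for (cn in unique(gm$variants$contig)) {
    idx <- which(keep & gm$variants$contig == cn)
    pos <- gm$variants$pos[idx]
    L <- if (!is.null(contig_lengths) && cn %in% names(contig_lengths))
      contig_lengths[[cn]] else max(pos, 0) + 1
    # qualifying pairs once per contig
    mids <- numeric(0); r2s <- numeric(0)
    if (length(idx) >= 2) {
      o <- order(pos); idx <- idx[o]; pos <- pos[o]
      for (i in seq_along(idx)) {
        j <- which(pos > pos[i] + pair_dist[1] - 1 &
                     pos <= pos[i] + pair_dist[2])
        for (jj in j) {
          r2 <- ld_pair(D[, idx[i]], D[, idx[jj]])$r2
          if (!is.na(r2)) {
            mids <- c(mids, (pos[i] + pos[jj]) / 2)
            r2s <- c(r2s, r2)
          }
        }
      }
    }
    starts <- seq(0, max(L - window, 0), by = step)
    if (length(starts) == 0) starts <- 0
    for (s in starts) {
      inw <- mids >= s & mids < s + window
      out[[length(out) + 1L]] <- data.frame(
        contig = cn, start = s, end = s + window,
        mean_r2 = if (any(inw)) mean(r2s[inw]) else NA_real_,
        n_pairs = sum(inw), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Long-range high-LD counts by minor allele count
#'
#' For each requested minor-allele-count value, samples focal variants
#' and counts, per focal variant, how many other variants are in strong
#' LD (\eqn{r^2 >} `r2_min`) with it locally (within `local_radius` bp
#' on the same contig) and genome-wide (everywhere else), excluding the
#' focal variant itself. Optionally stratifies focal variants by
#' inversion-interval membership.
#'
#' @param gm A [genotype_matrix()].
#' @param mac_values Integer minor-allele-count values for focal
#'   variants.
#' @param r2_min Strong-LD threshold (default 0.95).
#' @param local_radius Local window (bp, default 1 kb).
#' @param n_focal Focal variants sampled per count value (all candidates
#'   when fewer are available).
#' @param inversion_regions Optional data frame `contig`, `start`, `end`
#'   defining inversion intervals for stratification.
#' @param seed Sampling seed.
#' @return Data frame `mac`, `stratum`, `n_focal`, `mean_local`,
#'   `mean_genomewide`.
#' @export
high_ld_counts <- function(gm, mac_values, r2_min = 0.95,
                           local_radius = 1000, n_focal = 1000L,
                           inversion_regions = NULL, seed = 1L) {
  set.seed(seed)
  D <- haploid_dosage(gm)
  p <- colMeans(D, na.rm = TRUE)
  nc <- colSums(!is.na(D))
  mac <- round(pmin(p, 1 - p) * nc)
  poly <- mac >= 1
  in_inv <- rep(FALSE, ncol(D))
  if (!is.null(inversion_regions)) {
    for (i in seq_len(nrow(inversion_regions)))
      in_inv <- in_inv | (gm$variants$contig == inversion_regions$contig[i] &
                            gm$variants$pos >= inversion_regions$start[i] &
                            gm$variants$pos < inversion_regions$end[i])
  }
  strata <- if (is.null(inversion_regions)) list(all = rep(TRUE, ncol(D)))
  else list(inside = in_inv, outside = !in_inv)
  out <- list()
  for (mv in mac_values) {
    for (sn in names(strata)) {
      cand <- which(mac == mv & poly & strata[[sn]])
      if (length(cand) == 0) next
      focal <- if (length(cand) > n_focal) sample(cand, n_focal) else cand
      loc <- gw <- numeric(length(focal))
      for (fi in seq_along(focal)) {
        f <- focal[fi]
        r2 <- suppressWarnings(
          as.vector(stats::cor(D[, f], D, use = "pairwise.complete.obs"))^2)
        hit <- which(!is.na(r2) & r2 > r2_min)
        hit <- setdiff(hit, f)
        is_local <- gm$variants$contig[hit] == gm$variants$contig[f] &
          abs(gm$variants$pos[hit] - gm$variants$pos[f]) <= local_radius
        loc[fi] <- sum(is_local)
        gw[fi] <- sum(!is_local)
      }
      out[[length(out) + 1L]] <- data.frame(
        mac = mv, stratum = sn, n_focal = length(focal),
        mean_local = mean(loc), mean_genomewide = mean(gw),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
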