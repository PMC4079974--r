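# Brute-force oracles used below: direct pairwise-difference counting
# for pi, and full margin-fixed table enumeration for Fisher's test.

pi_bruteforce <- function(d, len) {
  # d: lines x sites 0/1/NA; mean pairwise difference per site / length
  tot <- 0
  for (s in seq_len(ncol(d))) {
    x <- d[, s]; x <- x[!is.na(x)]
    if (length(x) < 2) next
    pr <- utils::combn(length(x), 2)
    tot <- tot + mean(x[pr[1, ]] != x[pr[2, ]])
  }
  tot / len
}

fisher_enum <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c_ + d; k <- a + c_
  aa <- max(0, k - n):min(k, m)
  pr <- dhyper(aa, m, n, k)
  sum(pr[pr <= dhyper(a, m, n, k) * (1 + 1e-7)])
}

test_that("log-space Fisher matches enumeration and the printed table", {
  expect_equal(fisher_exact(matrix(c(1, 1, 1, 1), 2)), 1)
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-12)
  p <- fisher_exact(matrix(c(60, 6, 2, 752), 2))
  expect_equal(signif(p, 3), 1.91e-81)
  set.seed(31)
  for (rep in 1:60) {
    tab <- matrix(rpois(4, sample(1:12, 1)), 2)
    if (sum(tab) > 60 || sum(tab) == 0) next
    expect_equal(fisher_exact(tab), fisher_enum(tab), tolerance = 1e-10)
    expect_equal(fisher_exact(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-8)
  }
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)))
})

test_that("segregating-site profiles count per line and contig", {
  geno <- rbind(c(1L, 0L, 0L, 2L), c(0L, 0L, 0L, 0L), c(NA, NA, 1L, 1L))
  v <- data.frame(contig = c("a", "a", "b", "b"), pos = c(1, 2, 1, 2),
                  ref = "A", alt = "T", type = "snp")
  gm <- genotype_matrix(geno, v, line_ids = c("l1", "l2", "l3"))
  sf <- segregating_fraction(gm)
  expect_equal(sf$percent_segregating[sf$line_id == "l1" & sf$contig == "a"], 50)
  expect_equal(sf$percent_segregating[sf$line_id == "l2" & sf$contig == "a"], 0)
  expect_true(is.na(sf$percent_segregating[sf$line_id == "l3" & sf$contig == "a"]))
  expect_equal(sf$percent_segregating[sf$line_id == "l3" & sf$contig == "b"], 100)
})

test_that("heterokaryotypy and high segregating fractions associate strongly", {
  pan <- cached_panel("default")
  cfg <- cached_config("default")
  sf <- segregating_fraction(pan$gm)
  sf <- sf[sf$contig %in% c("2L", "2R"), ]
  kt <- karyotype_het_table(pan$panel, cfg, contigs = c("2L", "2R"))
  ia <- inversion_association(sf, kt, threshold = 9)
  expect_lt(ia$p_value, 1e-6)
  expect_gt(ia$table[">=thr", "het"], 0)
  expect_equal(ia$table[">=thr", "hom"], 0)
  # degenerate: all-homokaryotypic labels give p = 1
  kt0 <- kt; kt0$het <- FALSE
  expect_equal(inversion_association(sf, kt0)$p_value, 1)
})

test_that("windowed pi matches hand computation and brute force", {
  # one SNP at p = 0.5 among 4 lines in a 100-bp window
  geno <- matrix(c(0L, 0L, 2L, 2L), 4, 1)
  v <- data.frame(contig = "w", pos = 10, ref = "A", alt = "T",
                  type = "snp")
  gm <- genotype_matrix(geno, v)
  nd <- nucleotide_diversity(gm, window_size = 100,
                             contig_lengths = c(w = 100))
  expect_equal(nd$pi, (4 / 3) * 0.5 / 100, tolerance = 1e-12)
  # monomorphic window
  gm0 <- genotype_matrix(matrix(0L, 4, 1), v)
  expect_equal(nucleotide_diversity(gm0, 100,
                                    contig_lengths = c(w = 100))$pi, 0)
  # a long deletion at p = 0.5 contributes exactly like a SNP
  v2 <- data.frame(contig = "w", pos = 10, ref = "ACGTACGTACG",
                   alt = "A", type = "del")
  nd2 <- nucleotide_diversity(genotype_matrix(geno, v2), 100,
                              variant_class = "indel",
                              contig_lengths = c(w = 100))
  expect_equal(nd2$pi, nd$pi)
  # brute-force pairwise oracle on random instances with <= 8 lines
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(3:8, 1); m <- sample(2:12, 1)
    g <- matrix(sample(c(0L, 1L, 2L, NA), n * m, replace = TRUE,
                       prob = c(.4, .1, .4, .1)), n, m)
    vv <- data.frame(contig = "w", pos = sort(sample(0:999, m)),
                     ref = "A", alt = "T", type = "snp")
    gmr <- genotype_matrix(g, vv)
    got <- nucleotide_diversity(gmr, 1000, contig_lengths = c(w = 1000))
    want <- pi_bruteforce(haploid_dosage(gmr), 1000)
    if (is.na(got$pi)) expect_equal(want, 0) else
      expect_equal(got$pi, want, tolerance = 1e-12)
  }
})

test_that("divergence counts fixed differences against the outgroup", {
  geno <- matrix(c(2L, 2L, 0L, 0L, 2L, 0L, 0L, 0L), 2, 4)
  v <- data.frame(contig = "w", pos = c(5, 15, 25, 35), ref = "A",
                  alt = "T", type = "snp")
  gm <- genotype_matrix(geno, v)
  # site1 fixed alt, site2 fixed ref, site3 polymorphic, site4 fixed ref
  og <- c("A", "T", "A", "A")   # site1 differs, site2 differs, site4 same
  dv <- divergence_windows(gm, og, window_size = 1000,
                           contig_lengths = c(w = 1000))
  expect_equal(dv$n_fixed, 2)
  expect_equal(dv$k, 2 / 1000)
  # outgroup identical to the fixed panel allele everywhere -> k = 0
  og2 <- c("T", "A", "A", "A")
  expect_equal(divergence_windows(gm, og2, 1000,
                                  contig_lengths = c(w = 1000))$k, 0)
  # parameter recovery on the simulated panel
  pan <- cached_panel("nolinv")
  cfg <- cached_config("nolinv")
  # panel-fixed derived sites differ from the (ancestral) outgroup
  dvp <- divergence_windows(pan$gm, pan$founders$outgroup, 2e5,
                            contig_lengths = c("2L" = 2e5, X = 2e5))
  expect_gt(sum(dvp$n_fixed), 0)
})

test_that("indel polarization recovers the generative deletion share", {
  pan <- cached_panel("default")
  gm <- pan$gm; f <- pan$founders
  pol <- polarize_indels(gm, f$outgroup)
  v <- gm$variants[gm$variants$type %in% c("del", "ins"), ]
  expect_equal(nrow(pol), nrow(v))
  expect_equal(sum(pol$status == "polarized") +
                 sum(pol$status == "unpolarized"), nrow(v))
  # polarized calls agree with the generative truth
  ok <- pol$status == "polarized"
  truth <- v$derived_type[ok]
  expect_true(all(pol$derived_type[ok] == truth))
  # reference-based labels mislabel a minority; polarized labels do not
  ref_label <- ifelse(v$type == "del", "deletion", "insertion")
  expect_gt(mean(ref_label != v$derived_type), 0.02)
  # swapping ref/alt labels leaves derived_type invariant
  gm2 <- gm
  gm2$variants <- transform(gm$variants, ref = alt, alt = ref,
                            derived_allele = ifelse(derived_allele == "ref",
                                                    "alt", "ref"))
  gm2$geno <- 2L - gm$geno
  pol2 <- polarize_indels(gm2, f$outgroup)
  expect_identical(pol$derived_type, pol2$derived_type)
  expect_identical(pol$derived_count, pol2$derived_count)
})

test_that("frequency spectra conserve counts and detect planted rare excess", {
  set.seed(51)
  fr <- c(runif(300), rep(NA, 10))
  cl <- sample(c("cds", "intron"), 310, replace = TRUE)
  fs <- frequency_spectrum(fr, cl)
  expect_equal(sum(fs$count), 300)
  # derived count 1 of 10 lines falls in the [0, 0.1) bin
  fs1 <- frequency_spectrum(0.1 * 0.999, "x")
  expect_equal(fs1$count[fs1$bin == "[0,0.1)"], 1)
  # class sampled with frequency-downweighting shows low-frequency excess
  neutral <- runif(4000)
  weighted <- neutral[runif(4000) < (1 - neutral)^2][1:1500]
  f_n <- ecdf(neutral); f_w <- ecdf(weighted)
  grid <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(f_w(grid) >= f_n(grid) - 0.02))
  expect_gt(max(f_w(grid) - f_n(grid)), 0.15)
})

test_that("karyotype diversity is elevated between diverged karyotypes", {
  pan <- cached_panel("default")
  cfg <- cached_config("default")
  iv <- cfg$inversions[[1]]
  kary <- ifelse(pan$panel$inv1_dosage == 2L, "inverted",
                 ifelse(pan$panel$inv1_dosage == 0L, "standard", NA))
  kd <- karyotype_diversity(pan$gm, kary,
                            region = list(iv$arm, iv$start, iv$end))
  expect_gte(kd$n_standard, 2)
  expect_gt(kd$pi_between, max(kd$pi_standard, kd$pi_inverted,
                               na.rm = TRUE))
  # undiverged panel: between ~ mean(within) (exchangeability)
  pan0 <- cached_panel("nolinv")
  g0 <- pan0$gm
  half <- rep(c("standard", "inverted"), length.out = nrow(g0$geno))
  kd0 <- karyotype_diversity(g0, half, region = list("2L", 0, 2e5))
  expect_lt(abs(kd0$pi_between - mean(c(kd0$pi_standard,
                                        kd0$pi_inverted))),
            0.25 * kd0$pi_between)
  # two identical lines per class give all-zero diversity
  gid <- genotype_matrix(matrix(c(0L, 0L, 2L, 2L), 4, 1),
                         data.frame(contig = "w", pos = 5, ref = "A",
                                    alt = "T", type = "snp"))
  kdi <- karyotype_diversity(gid, c("standard", "standard", "inverted",
                                    "inverted"), list("w", 0, 100))
  expect_equal(kdi$pi_standard, 0)
  expect_equal(kdi$pi_inverted, 0)
  expect_gt(kdi$pi_between, 0)  # classes fixed for different alleles
})

test_that("variant clustering separates carrier and non-carrier strata", {
  # constructed fixture: SNPs planted within 20 bp of focal indels only
  # on carrier haplotypes; far SNPs on all haplotypes
  set.seed(61)
  n <- 20
  carriers <- 1:10
  focal_pos <- c(1000, 3000, 5000)
  rows <- list(); genos <- list()
  for (fp in focal_pos) {
    g <- integer(n); g[carriers] <- 2L
    rows[[length(rows) + 1]] <- data.frame(contig = "c", pos = fp,
                                           ref = "AT", alt = "A",
                                           type = "del")
    genos[[length(genos) + 1]] <- g
    for (dd in c(5, 12, 18)) {
      gs <- integer(n); gs[sample(carriers, 5)] <- 2L
      rows[[length(rows) + 1]] <- data.frame(contig = "c", pos = fp + dd,
                                             ref = "A", alt = "G",
                                             type = "snp")
      genos[[length(genos) + 1]] <- gs
    }
  }
  v <- do.call(rbind, rows)
  g <- do.call(cbind, genos)
  o <- order(v$pos); v <- v[o, ]; g <- g[, o]
  gm <- genotype_matrix(g, v)
  prof <- variant_clustering(gm, focal_types = "del",
                             maf_band = c(0.3, 0.5), window = 100,
                             mac_breaks = c(1, Inf))
  near_car <- prof$mean_count[prof$stratum == "carrier" &
                                prof$distance <= 20]
  far_car <- prof$mean_count[prof$stratum == "carrier" &
                               prof$distance > 20]
  noncar <- prof$mean_count[prof$stratum == "non_carrier"]
  expect_gt(sum(near_car), 0)
  expect_equal(sum(far_car), 0)
  expect_equal(sum(noncar), 0)
  expect_equal(sum(prof$mean_count[prof$stratum == "carrier"]) *
                 attr(prof, "n_focal"), 9)
})

test_that("diversity-recombination correlation behaves at the extremes", {
  div <- data.frame(contig = "c", start = seq(0, 9e5, 1e5),
                    pi = seq(0.001, 0.01, length.out = 10))
  rec <- data.frame(contig = "c", start = seq(0, 9e5, 1e5),
                    rate = exp(seq(0.1, 1, length.out = 10)))
  rc <- recombination_correlation(div, rec)
  expect_equal(rc$rho, 1)
  div2 <- div; div2$pi <- 0.005
  expect_true(recombination_correlation(div2, rec)$degenerate)
  expect_true(recombination_correlation(div[1:2, ], rec)$degenerate)
  # permuted tracks: null rho near zero across replicates
  set.seed(71)
  rhos <- replicate(50, {
    rec2 <- rec; rec2$rate <- sample(rec$rate)
    recombination_correlation(div, rec2)$rho
  })
  expect_lt(abs(mean(rhos)), 0.15)
})

test_that("chromatin enrichment recovers planted density differences", {
  set.seed(81)
  L <- 1e5
  domains <- data.frame(contig = "c", start = c(0, 5e4),
                        end = c(5e4, 8e4),
                        class = c("active", "repressed"))
  # uniform variants -> folds near 1
  v_u <- data.frame(contig = "c", pos = sample.int(L, 3000) - 1,
                    type = "snp")
  en_u <- chromatin_enrichment(v_u, domains, c(c = L), by_type = FALSE)
  expect_true(all(abs(en_u$fold - 1) < 0.25))
  # doubled density in "repressed"
  v_d <- rbind(v_u, data.frame(contig = "c",
                               pos = sample(5e4:(8e4 - 1), 900),
                               type = "snp"))
  en_d <- chromatin_enrichment(v_d, domains, c(c = L), by_type = FALSE)
  row <- en_d[en_d$domain_class == "repressed", ]
  expect_gt(row$fold, 1.5)
  expect_lt(row$p_value, 1e-6)
  # empty domain class reports fold 0
  dom2 <- rbind(domains, data.frame(contig = "c", start = 9e4, end = 95e3,
                                    class = "empty"))
  v_e <- v_u[v_u$pos < 8e4, ]
  en_e <- chromatin_enrichment(v_e, dom2, c(c = L), by_type = FALSE)
  expect_equal(en_e$fold[en_e$domain_class == "empty"], 0)
})

test_that("X-linked diversity is below autosomal diversity on the panel", {
  pan <- cached_panel("nolinv")
  nd <- nucleotide_diversity(pan$gm, 5e4, "snp",
                             contig_lengths = c("2L" = 2e5, X = 2e5))
  expect_lt(mean(nd$pi[nd$contig == "X"], na.rm = TRUE),
            mean(nd$pi[nd$contig == "2L"], na.rm = TRUE))
})
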