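test_that("identical seeds give identical panels", {
  cfg <- sim_config(n_lines = 8, seed = 33,
                    contigs = data.frame(name = "2L", length = 1e5,
                                         is_X = FALSE),
                    inversions = list(inversion_spec("2L", 2e4, 8e4, 0.2,
                                                     divergence = 0.001)))
  a <- simulate_panel(cfg, phenotypes = TRUE)
  b <- simulate_panel(cfg, phenotypes = TRUE)
  expect_identical(a$gm$geno, b$gm$geno)
  expect_identical(a$founders$variants, b$founders$variants)
  expect_identical(a$panel, b$panel)
  expect_identical(a$phenotypes, b$phenotypes)
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(deletion_fraction = 1.3), "probabilities")
  expect_error(sim_config(contigs = data.frame(name = "c", length = 0,
                                               is_X = FALSE)), "config error")
  expect_error(sim_config(inversions = list(
    inversion_spec("2L", 1e5, 9e5, 0.1))), "inside its contig")
  expect_error(inversion_spec("2L", 100, 50, 0.1))
})

test_that("realized derived deletion share tracks the configured fraction", {
  cfg <- sim_config(n_lines = 4, seed = 55, snp_rate = 0.001,
                    indel_rate = 0.02, inversions = list(),
                    contigs = data.frame(name = "2L", length = 5e5,
                                         is_X = FALSE))
  f <- simulate_founders(cfg)
  ind <- f$variants$derived_type %in% c("deletion", "insertion")
  n <- sum(ind)
  expect_gt(n, 8000)
  share <- mean(f$variants$derived_type[ind] == "deletion")
  half99 <- qnorm(0.995) * sqrt(0.69 * 0.31 / n)
  expect_lt(abs(share - 0.69), half99)
})

test_that("degenerate rates produce degenerate founder sets", {
  cfg <- sim_config(n_lines = 4, seed = 5, snp_rate = 0,
                    indel_rate = 0.001, inversions = list(),
                    contigs = data.frame(name = "2L", length = 5e4,
                                         is_X = FALSE))
  f <- simulate_founders(cfg)
  expect_equal(sum(f$variants$type == "snp"), 0)
  # zero divergence: inverted and standard founders show no excess
  # fixed differences inside the inversion
  cfg2 <- sim_config(n_lines = 4, seed = 5,
                     inversions = list(inversion_spec("2L", 6e4, 2.4e5, 0.3,
                                                      divergence = 0)))
  f2 <- simulate_founders(cfg2)
  expect_equal(sum(f2$variants$inv_fixed > 0), 0)
})

test_that("non-3n indels in coding sequence are depleted at the configured rate", {
  cfg <- sim_config(n_lines = 4, seed = 56, snp_rate = 0.001,
                    indel_rate = 0.02, inversions = list(),
                    cds_frameshift_depletion = 0.2,
                    contigs = data.frame(name = "2L", length = 5e5,
                                         is_X = FALSE))
  f <- simulate_founders(cfg)
  v <- f$variants[f$variants$type %in% c("del", "ins"), ]
  non3 <- abs(v$size) %% 3 != 0
  r_cds <- sum(non3 & v$in_cds) / sum(!non3 & v$in_cds)
  r_out <- sum(non3 & !v$in_cds) / sum(!non3 & !v$in_cds)
  expect_gt(sum(v$in_cds), 150)
  expect_gt(r_cds / r_out, 0.10)
  expect_lt(r_cds / r_out, 0.35)
})

test_that("zero generations of inbreeding leave founder-level heterozygosity", {
  cfg <- sim_config(n_lines = 40, seed = 77, generations_inbreeding = 0,
                    inversions = list(),
                    contigs = data.frame(name = "2L", length = 1e5,
                                         is_X = FALSE))
  pan <- simulate_panel(cfg)
  hap <- pan$founders$hap
  obs <- exp_het <- numeric(40)
  for (i in seq_len(40)) {
    q <- as.integer(pan$panel[i, c("founder_a", "founder_b",
                                   "founder_c", "founder_d")])
    p1 <- (hap[q[1], ] + hap[q[2], ]) / 2
    p2 <- (hap[q[3], ] + hap[q[4], ]) / 2
    exp_het[i] <- mean(p1 * (1 - p2) + p2 * (1 - p1))
    obs[i] <- mean(pan$gm$geno[i, ] == 1L)
  }
  # first-generation offspring of the founder couple: heterozygosity
  # equals the expected founder heterozygosity
  expect_lt(abs(mean(obs) - mean(exp_het)), 0.01)
  expect_gt(mean(obs), 0.2)
})

test_that("residual heterozygosity matches a pattern-aware pedigree oracle", {
  pan <- cached_panel("nolinv")
  cfg <- cached_config("nolinv")
  gm <- pan$gm; f <- pan$founders; p <- pan$panel
  H <- nrow(f$hap)
  # observed: per-line segregating fraction among autosomal sites where
  # the line's four founder haplotypes segregate
  aut <- which(gm$variants$contig == "2L")
  per_line <- vapply(seq_len(nrow(p)), function(i) {
    q <- as.integer(p[i, c("founder_a", "founder_b", "founder_c",
                           "founder_d")])
    cs <- colSums(f$hap[q, aut, drop = FALSE])
    sel <- cs > 0 & cs < 4
    mean(gm$geno[i, aut][sel] == 1L)
  }, numeric(1))
  obs <- mean(per_line)
  se_obs <- sd(per_line) / sqrt(length(per_line))
  # oracle: Monte-Carlo over founder allele patterns x label pedigrees;
  # independent of the breeding code (no recombination machinery)
  set.seed(404)
  R <- 40000L
  i_der <- sample(seq_len(H - 1), R, replace = TRUE,
                  prob = 1 / seq_len(H - 1))
  alle <- vapply(i_der, function(i) {
    a <- integer(4)
    a[sample.int(4, min(4, rhyper(1, i, H - i, 4)))] <- 1L
    a
  }, integer(4))
  seg <- colSums(alle) %in% 1:3
  alle <- alle[, seg, drop = FALSE]
  Rk <- ncol(alle)
  mom <- cbind(rep(1L, Rk), rep(2L, Rk))
  dad <- cbind(rep(3L, Rk), rep(4L, Rk))
  pick <- function(par) par[cbind(seq_len(Rk),
                                  sample.int(2L, Rk, replace = TRUE))]
  for (t in 1:21) {  # founding sib pair + 20 generations of sib mating
    c1 <- cbind(pick(mom), pick(dad)); c2 <- cbind(pick(mom), pick(dad))
    mom <- c1; dad <- c2
  }
  a1 <- alle[cbind(mom[, 1], seq_len(Rk))]
  a2 <- alle[cbind(mom[, 2], seq_len(Rk))]
  oracle <- mean(a1 != a2)
  se_or <- sqrt(oracle * (1 - oracle) / Rk)
  expect_lt(abs(obs - oracle), 3 * (se_obs + se_or))
})

test_that("forced heterokaryotypes stay heterozygous across the inversion", {
  pan <- cached_panel("default")
  cfg <- cached_config("default")
  gm <- pan$gm; p <- pan$panel
  het1 <- which(p$inv1_dosage == 1L)
  hom1 <- which(p$inv1_dosage != 1L)
  expect_gt(length(het1), 0)
  iv <- cfg$inversions[[1]]
  inside <- gm$variants$contig == iv$arm & gm$variants$pos >= iv$start &
    gm$variants$pos < iv$end
  outside <- gm$variants$contig == iv$arm & !inside
  pct <- function(lines, sel)
    100 * mean(gm$geno[lines, sel] == 1L, na.rm = TRUE)
  expect_gt(pct(het1, inside), 9)
  expect_gt(pct(het1, inside), 3 * max(pct(het1, outside), 0.1))
  expect_lt(pct(hom1, inside), 2)
})

test_that("Wolbachia prevalence and karyotype frequencies match configuration", {
  pan <- cached_panel("default")
  cfg <- cached_config("default")
  n <- nrow(pan$panel)
  prev <- mean(pan$panel$wolbachia)
  expect_lt(abs(prev - cfg$wolbachia_prevalence),
            qnorm(0.995) * sqrt(0.53 * 0.47 / n))
  kf <- mean(pan$founders$inv_status[, 1])
  H <- nrow(pan$founders$hap)
  expect_lt(abs(kf - cfg$inversions[[1]]$karyotype_frequency),
            qnorm(0.995) * sqrt(0.15 * 0.85 / H) + 1e-9)
})

test_that("phenotype generator respects configured effects", {
  # all effects zero, no polygenic term: variance equals residual
  cfg0 <- sim_config(n_lines = 400, seed = 61, snp_rate = 5e-4,
                     indel_rate = 0, inversions = list(),
                     contigs = data.frame(name = "2L", length = 5e4,
                                          is_X = FALSE),
                     phenotype_effects = list(
                       intercept = 0, wolbachia = 0, inversion = 0,
                       polygenic_var = 0, residual_var = 1,
                       genome_size_base_mb = 175.6,
                       genome_size_per_indel_bp = 0,
                       genome_size_per_inversion_mb = 0,
                       genome_size_sd_mb = 1, genome_size_meas_sd_mb = 0.5,
                       n_size_reps = 3L))
  pan0 <- simulate_panel(cfg0, phenotypes = TRUE)
  expect_lt(abs(var(pan0$phenotypes$trait) - 1), 0.3)
  expect_lt(abs(mean(pan0$phenotypes$trait)), 0.2)
  # a Wolbachia effect of 1 with small residual: two-group difference ~1
  cfg1 <- sim_config(n_lines = 200, seed = 62, snp_rate = 5e-4,
                     indel_rate = 0, inversions = list(),
                     contigs = data.frame(name = "2L", length = 5e4,
                                          is_X = FALSE),
                     phenotype_effects = list(
                       intercept = 0, wolbachia = 1, inversion = 0,
                       polygenic_var = 0, residual_var = 0.01,
                       genome_size_base_mb = 175.6,
                       genome_size_per_indel_bp = 0,
                       genome_size_per_inversion_mb = 0,
                       genome_size_sd_mb = 1, genome_size_meas_sd_mb = 0.5,
                       n_size_reps = 3L))
  pan1 <- simulate_panel(cfg1, phenotypes = TRUE)
  tt <- t.test(pan1$phenotypes$trait ~ pan1$panel$wolbachia)
  expect_lt(abs(diff(tt$estimate) - 1), 0.1)
})

test_that("caller emission with zero error reproduces the truth", {
  pan <- cached_panel("nolinv")
  gm <- pan$gm
  out <- emit_caller_outputs(gm, n_callers = 3,
                             profile = list(fn_rate = 0, fp_rate = 0,
                                            mean_depth = 30,
                                            seq_error = 0.01),
                             seed = 9)
  for (co in out) {
    expect_equal(nrow(co$variants), ncol(gm$geno))
    expect_false(any(co$variants$is_fp))
    expect_identical(co$variants$pos, gm$variants$pos)
  }
})

test_that("multi-caller union misses variants at about the joint FN rate", {
  pan <- cached_panel("default")
  gm <- pan$gm
  out <- emit_caller_outputs(gm, n_callers = 5,
                             profile = list(fn_rate = 0.2, fp_rate = 0,
                                            mean_depth = 12,
                                            seq_error = 0.01),
                             seed = 10)
  V <- ncol(gm$geno)
  seen <- unique(unlist(lapply(out, function(co) co$variants$truth_idx)))
  n_missed <- V - length(seen)
  expect_lte(n_missed, qbinom(0.9999, V, 0.2^5))
})

test_that("zero read depth yields missing calls everywhere", {
  gc0 <- genotype_from_counts(rep(0, 5), rep(0, 5))
  expect_true(all(gc0$call == "missing"))
  expect_true(all(is.na(gc0$code)))
})
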