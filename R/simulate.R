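# Synthetic inbred-line panel generator. All stochastic draws flow from
# the single integer seed in the configuration: simulate_founders() seeds
# the generator at `seed`, simulate_inbreeding() at `seed + 1` and
# simulate_phenotypes() at `seed + 2`, so each stage is reproducible in
# isolation and the full pipeline is byte-identical across runs.

# Draw n derived-allele counts in 1..(H-1).
draw_derived_count <- function(sfs, H, n) {
  if (n == 0) return(integer(0))
  if (is.function(sfs)) return(vapply(seq_len(n), function(i) sfs(H), numeric(1)))
  i <- seq_len(H - 1)
  sample(i, n, replace = TRUE, prob = 1 / i)
}

# Founder haplotype columns for a block of variants: haplotypes in S_j
# carry the derived allele; the column is alt-allele (0/1) coded given
# which allele is derived.
hap_block <- function(H, S_list, der_is_ref) {
  n <- length(S_list)
  m <- matrix(rep(as.integer(der_is_ref), each = H), H, n)
  if (n == 0) return(m)
  lens <- lengths(S_list)
  idx <- cbind(unlist(S_list), rep.int(seq_len(n), lens))
  m[idx] <- rep.int(1L - as.integer(der_is_ref), lens)
  m
}

# Write start/stop codons into the reference and remove internal in-frame
# stops so that every toy gene encodes a clean reference protein.
patch_gene_sequences <- function(seq, models) {
  stops <- c("TAA", "TAG", "TGA")
  v <- strsplit(seq, "")[[1]]
  for (g in models) {
    for (tx in g$transcripts) {
      blocks <- cds_blocks(tx)
      pos <- unlist(apply(blocks, 1, function(b) seq(b[1], b[2] - 1),
                          simplify = FALSE))
      if (g$strand == "-") pos <- rev(pos)
      cds <- v[pos + 1L]
      if (g$strand == "-") cds <- chartr("ACGT", "TGCA", cds)
      n <- length(cds)
      cds[1:3] <- c("A", "T", "G")
      cds[(n - 2):n] <- c("T", "A", "A")
      for (j in seq_len(n %/% 3 - 1)) {
        cod <- paste(cds[(3 * j - 2):(3 * j)], collapse = "")
        if (cod %in% stops) cds[3 * j - 2] <- "C"
      }
      if (g$strand == "-") cds <- chartr("ACGT", "TGCA", cds)
      v[pos + 1L] <- cds
    }
  }
  paste(v, collapse = "")
}

#' Simulate founder haplotypes, variants and outgroup alleles
#'
#' Generates per-contig reference sequences carrying toy gene models,
#' then seeds segregating SNPs and indels among `n_founder_haplotypes`
#' founder haplotypes. Indel derived alleles are deletions with
#' probability `deletion_fraction`; non-3n indels inside coding sequence
#' are retained at the configured depletion rate. The reference sequence
#' is itself a population sample, so it carries the derived allele with
#' probability equal to the derived-allele frequency (which is what makes
#' reference-based insertion/deletion labels disagree with the polarized
#' labels for a minority of sites). Inverted founder haplotypes carry
#' excess fixed differences inside each inversion interval. The outgroup
#' allele equals the ancestral allele at every site except a configured
#' fraction where the outgroup lineage has itself diverged.
#'
#' @param config A [sim_config()].
#' @return Object of class `founder_set`: reference sequences, variant
#'   table (with truth columns `derived_allele`, `derived_type`,
#'   `in_cds`, `inv_fixed`), founder haplotype matrix (haplotypes x
#'   variants, 0 = ref allele, 1 = alt allele), per-haplotype inversion
#'   orientations, outgroup alleles, and gene models.
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  H <- config$n_founder_haplotypes
  K <- length(config$inversions)

  models <- list()
  ref <- character(nrow(config$contigs))
  names(ref) <- config$contigs$name
  for (ci in seq_len(nrow(config$contigs))) {
    cn <- config$contigs$name[ci]
    L <- config$contigs$length[ci]
    models[[cn]] <- toy_gene_models(cn, L, spacing = config$gene_spacing)
    ref[cn] <- patch_gene_sequences(rand_dna(L), models[[cn]])
  }

  inv_status <- matrix(0L, H, K)
  for (k in seq_len(K)) {
    f_k <- config$inversions[[k]]$karyotype_frequency
    draw <- rbinom(H, 1L, f_k)
    # a polymorphic inversion spec must actually segregate among the
    # founders; redraw degenerate samples
    if (f_k > 0 && f_k < 1) {
      tries <- 0L
      while ((sum(draw) == 0L || sum(draw) == H) && tries < 100L) {
        draw <- rbinom(H, 1L, f_k)
        tries <- tries + 1L
      }
    }
    inv_status[, k] <- draw
  }

  blocks <- list()      # variant data frames
  hap_blocks <- list()  # matching founder haplotype column blocks

  for (ci in seq_len(nrow(config$contigs))) {
    cn <- config$contigs$name[ci]
    L <- config$contigs$length[ci]
    fac <- if (config$contigs$is_X[ci]) config$x_rate_factor else 1
    cds_iv <- cds_intervals(models[[cn]])

    # --- SNPs ---
    n_snp <- rbinom(1L, L, config$snp_rate * fac)
    if (n_snp > 0) {
      pos <- sort(sample.int(L, n_snp) - 1L)
      refa <- substring(ref[cn], pos + 1L, pos + 1L)
      alta <- other_base(refa)
      cnt <- draw_derived_count(config$founder_sfs, H, n_snp)
      S <- lapply(cnt, function(k) sample.int(H, k))
      dref <- runif(n_snp) < cnt / H
      blocks[[length(blocks) + 1L]] <- data.frame(
        contig = cn, pos = pos, ref = refa, alt = alta, type = "snp",
        size = 0L, derived_allele = ifelse(dref, "ref", "alt"),
        derived_type = "substitution", in_cds = in_intervals(pos, cds_iv),
        inv_fixed = 0L, stringsAsFactors = FALSE)
      hap_blocks[[length(hap_blocks) + 1L]] <- hap_block(H, S, dref)
    }

    # --- indels ---
    n_ind <- rbinom(1L, L, config$indel_rate * fac)
    if (n_ind > 0) {
      pos <- sort(sample.int(max(L - 200L, 1L), n_ind) - 1L)
      sizes <- sample(config$indel_sizes$size, n_ind, replace = TRUE,
                      prob = config$indel_sizes$prob)
      is_del <- runif(n_ind) < config$deletion_fraction
      in_cds <- in_intervals(pos, cds_iv)
      keep <- !(in_cds & sizes %% 3 != 0) |
        runif(n_ind) < config$cds_frameshift_depletion
      # drop overlapping events (ref-allele spans must not intersect)
      prev_end <- -1
      for (j in seq_len(n_ind)) {
        if (!keep[j]) next
        if (pos[j] <= prev_end) { keep[j] <- FALSE; next }
        prev_end <- pos[j] + sizes[j]
      }
      pos <- pos[keep]; sizes <- sizes[keep]; is_del <- is_del[keep]
      in_cds <- in_cds[keep]
      n_k <- length(pos)
      if (n_k > 0) {
        cnt <- draw_derived_count(config$founder_sfs, H, n_k)
        S <- lapply(cnt, function(k) sample.int(H, k))
        dref <- runif(n_k) < cnt / H
        # ancestral is the long allele for a derived deletion, short for
        # a derived insertion
        ref_is_long <- (is_del & !dref) | (!is_del & dref)
        anchor <- substring(ref[cn], pos + 1L, pos + 1L)
        long_from_ref <- substring(ref[cn], pos + 1L, pos + sizes + 1L)
        long_rand <- paste0(anchor, vapply(sizes, rand_dna, character(1)))
        refa <- ifelse(ref_is_long, long_from_ref, anchor)
        alta <- ifelse(ref_is_long, anchor, long_rand)
        blocks[[length(blocks) + 1L]] <- data.frame(
          contig = cn, pos = pos, ref = refa, alt = alta,
          type = ifelse(nchar(alta) < nchar(refa), "del", "ins"),
          size = nchar(alta) - nchar(refa),
          derived_allele = ifelse(dref, "ref", "alt"),
          derived_type = ifelse(is_del, "deletion", "insertion"),
          in_cds = in_cds, inv_fixed = 0L, stringsAsFactors = FALSE)
        hap_blocks[[length(hap_blocks) + 1L]] <- hap_block(H, S, dref)
      }
    }

    # --- inversion fixed differences ---
    for (k in seq_len(K)) {
      iv <- config$inversions[[k]]
      if (iv$arm != cn || iv$divergence <= 0) next
      n_inv_hap <- sum(inv_status[, k])
      if (n_inv_hap == 0 || n_inv_hap == H) next
      span <- iv$end - iv$start
      n_d <- rbinom(1L, span, iv$divergence)
      if (n_d == 0) next
      pos <- sort(sample.int(span, n_d) - 1L + iv$start)
      refa <- substring(ref[cn], pos + 1L, pos + 1L)
      blocks[[length(blocks) + 1L]] <- data.frame(
        contig = cn, pos = pos, ref = refa, alt = other_base(refa),
        type = "snp", size = 0L, derived_allele = "alt",
        derived_type = "substitution", in_cds = in_intervals(pos, cds_iv),
        inv_fixed = k, stringsAsFactors = FALSE)
      hap_blocks[[length(hap_blocks) + 1L]] <-
        matrix(rep(inv_status[, k], n_d), H, n_d)
    }
  }

  variants <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(contig = character(), pos = numeric(), ref = character(),
               alt = character(), type = character(), size = integer(),
               derived_allele = character(), derived_type = character(),
               in_cds = logical(), inv_fixed = integer())
  hap <- if (length(hap_blocks)) do.call(cbind, hap_blocks) else
    matrix(0L, H, 0)

  # one variant per (contig, pos), ordered, with non-overlapping
  # reference spans (a deletion must not swallow a SNP)
  key <- paste(variants$contig, variants$pos)
  keep <- !duplicated(key)
  variants <- variants[keep, , drop = FALSE]
  hap <- hap[, keep, drop = FALSE]
  o <- order(match(variants$contig, config$contigs$name), variants$pos)
  variants <- variants[o, , drop = FALSE]
  hap <- hap[, o, drop = FALSE]
  keep2 <- rep(TRUE, nrow(variants))
  prev_contig <- ""; prev_end <- -1
  for (j in seq_len(nrow(variants))) {
    if (variants$contig[j] != prev_contig) { prev_contig <- variants$contig[j]; prev_end <- -1 }
    if (variants$pos[j] < prev_end) { keep2[j] <- FALSE; next }
    prev_end <- variants$pos[j] + nchar(variants$ref[j])
  }
  variants <- variants[keep2, , drop = FALSE]
  hap <- hap[, keep2, drop = FALSE]
  rownames(variants) <- NULL
  variants$id <- seq_len(nrow(variants))

  anc <- ifelse(variants$derived_allele == "ref", variants$alt, variants$ref)
  og <- anc
  mm <- runif(length(og)) < config$outgroup_mismatch
  if (any(mm)) {
    og[mm] <- vapply(og[mm], function(a) {
      if (nchar(a) == 1L) other_base(a) else {
        mid <- 1L + sample.int(nchar(a) - 1L, 1L)
        replace_bases(a, mid - 1L, other_base(substr(a, mid, mid)))
      }
    }, character(1), USE.NAMES = FALSE)
  }

  structure(list(config = config, ref = ref, variants = variants,
                 hap = hap, inv_status = inv_status,
                 outgroup = og, gene_models = models),
            class = "founder_set")
}

#' @export
print.founder_set <- function(x, ...) {
  cat(sprintf("founder_set: %d haplotypes, %d variants on %d contig(s)\n",
              nrow(x$hap), nrow(x$variants), length(x$ref)))
  invisible(x)
}

# One gamete from a diploid parent. `h` is a V x 2 allele matrix, `orient`
# a K x 2 inversion-orientation matrix. Crossovers are Poisson per contig,
# uniformly placed, and fully suppressed inside the intervals of
# inversions for which the parent is heterokaryotypic.
make_gamete <- function(h, orient, ped) {
  V <- nrow(h)
  gh <- integer(V)
  gor <- integer(nrow(orient))
  for (ci in seq_along(ped$contig_names)) {
    cx <- runif(rpois(1L, ped$cx_mean), 0, ped$contig_len[ci])
    invs <- ped$inv_by_contig[[ci]]
    for (k in invs) {
      if (ped$inv_suppressed[k] && orient[k, 1L] != orient[k, 2L])
        cx <- cx[cx < ped$inv_start[k] | cx >= ped$inv_end[k]]
    }
    cx <- sort(cx)
    start <- sample.int(2L, 1L)
    idx <- ped$var_idx[[ci]]
    if (length(idx)) {
      phase <- (start + findInterval(ped$var_pos[[ci]], cx)) %% 2L + 1L
      gh[idx] <- h[cbind(idx, phase)]
    }
    for (k in invs)
      gor[k] <- orient[k, (start + findInterval(ped$inv_start[k], cx)) %% 2L + 1L]
  }
  list(h = gh, orient = gor)
}

#' Breed inbred lines from founder haplotypes
#'
#' Each line descends from two founder haplotypes through
#' `generations_inbreeding` generations of full-sib mating with
#' recombination (one crossover per arm per meiosis on average, uniform
#' position, fully suppressed within heterokaryotypic inversion
#' intervals). A line founded by discordant karyotypes is, with
#' probability `het_retention`, maintained heterokaryotypic throughout
#' (offspring are resampled until heterokaryotypic), so it retains
#' heterozygosity across the inverted interval. Residual heterozygosity
#' is recorded as a segregating call (code 1).
#'
#' @param founders A [simulate_founders()] result.
#' @param config The same [sim_config()] used for the founders.
#' @return List with `gm` (a [genotype_matrix()] of true genotypes) and
#'   `panel` (per-line metadata: founder pair, Wolbachia status,
#'   per-inversion karyotype dosage 0/1/2, forced-heterokaryotype flag).
#' @export
simulate_inbreeding <- function(founders, config = founders$config) {
  stopifnot(inherits(founders, "founder_set"))
  set.seed(config$seed + 1L)
  H <- nrow(founders$hap)
  V <- nrow(founders$variants)
  K <- ncol(founders$inv_status)
  n <- config$n_lines

  ped <- list(
    contig_names = config$contigs$name,
    contig_len = config$contigs$length,
    cx_mean = config$crossovers_per_meiosis,
    var_idx = lapply(config$contigs$name,
                     function(cn) which(founders$variants$contig == cn)),
    var_pos = lapply(config$contigs$name, function(cn)
      founders$variants$pos[founders$variants$contig == cn]),
    inv_start = vapply(config$inversions, `[[`, numeric(1), "start"),
    inv_end = vapply(config$inversions, `[[`, numeric(1), "end"),
    inv_suppressed = vapply(config$inversions, `[[`, logical(1),
                            "recombination_suppressed"),
    inv_by_contig = lapply(config$contigs$name, function(cn)
      which(vapply(config$inversions, `[[`, character(1), "arm") == cn)))

  geno <- matrix(NA_integer_, n, V)
  kary <- matrix(0L, n, K)
  fnd <- matrix(0L, n, 4)
  forced <- logical(n)

  for (i in seq_len(n)) {
    # a wild-caught mated pair: four founder haplotypes per line
    quad <- sample.int(H, 4L)
    fnd[i, ] <- quad
    or4 <- founders$inv_status[quad, , drop = FALSE]
    # inversions whose orientations still segregate among the founders
    # of this line (a heterokaryotypic child is constructible)
    disc <- if (K > 0) which(colSums(or4) %% 4 != 0) else integer(0)
    forced[i] <- length(disc) > 0 && runif(1) < config$het_retention
    p1 <- list(h = cbind(founders$hap[quad[1], ], founders$hap[quad[2], ]),
               orient = cbind(or4[1, ], or4[2, ]))
    p2 <- list(h = cbind(founders$hap[quad[3], ], founders$hap[quad[4], ]),
               orient = cbind(or4[3, ], or4[4, ]))
    if (K == 0) { p1$orient <- matrix(0L, 0, 2); p2$orient <- p1$orient }
    # one child; for maintained-heterokaryotypic lines, resample until
    # the child is heterokaryotypic at every discordant inversion
    make_child <- function(pa, pb, force) {
      for (try in seq_len(1000L)) {
        ga <- make_gamete(pa$h, pa$orient, ped)
        gb <- make_gamete(pb$h, pb$orient, ped)
        ch <- list(h = cbind(ga$h, gb$h),
                   orient = cbind(ga$orient, gb$orient))
        if (!force || all(ch$orient[disc, 1] != ch$orient[disc, 2]))
          return(ch)
      }
      ch
    }
    # the founder couple's offspring are the founding sib pair; then
    # `generations_inbreeding` rounds of brother-sister mating
    for (t in seq_len(config$generations_inbreeding + 1L)) {
      c1 <- make_child(p1, p2, forced[i])
      c2 <- make_child(p1, p2, forced[i])
      p1 <- c1; p2 <- c2
    }
    geno[i, ] <- p1$h[, 1] + p1$h[, 2]
    if (K > 0) kary[i, ] <- p1$orient[, 1] + p1$orient[, 2]
  }

  line_ids <- sprintf("line_%03d", seq_len(n))
  panel <- data.frame(line_id = line_ids,
                      founder_a = fnd[, 1], founder_b = fnd[, 2],
                      founder_c = fnd[, 3], founder_d = fnd[, 4],
                      wolbachia = rbinom(n, 1L, config$wolbachia_prevalence),
                      forced_het = forced, stringsAsFactors = FALSE)
  for (k in seq_len(K))
    panel[[paste0("inv", k, "_dosage")]] <- kary[, k]
  attr(panel, "inversion_names") <-
    vapply(config$inversions, `[[`, character(1), "name")

  vars <- founders$variants
  vars$site_qual <- NA_real_
  list(gm = genotype_matrix(geno, vars, line_ids = line_ids), panel = panel)
}

#' Simulate line-mean phenotypes and genome sizes
#'
#' Line mean = intercept + Wolbachia effect + per-inversion karyotype
#' effects + a polygenic deviate with covariance proportional to the
#' relationship matrix + residual noise. Genome size (Mb) = base + signed
#' indel content + per-inverted-region offset + noise, with replicate
#' measurements (measurement error) for the among-line ANOVA.
#'
#' @param panel Line metadata from [simulate_inbreeding()].
#' @param relationship Optional [compute_grm()]-style relationship matrix
#'   (positive semi-definite) for the polygenic component; `NULL` drops
#'   the component.
#' @param config A [sim_config()]; effect sizes come from
#'   `config$phenotype_effects`.
#' @param gm Optional [genotype_matrix()]; supplies per-line signed indel
#'   content for genome size.
#' @return List with `phenotypes` (line_id, trait, genome_size_mb,
#'   n_inversions) and `genome_size_replicates` (long data frame of
#'   replicate measurements).
#' @export
simulate_phenotypes <- function(panel, relationship = NULL, config, gm = NULL) {
  set.seed(config$seed + 2L)
  ef <- config$phenotype_effects
  n <- nrow(panel)
  kcols <- grep("^inv[0-9]+_dosage$", names(panel), value = TRUE)
  inv_dos <- as.matrix(panel[, kcols, drop = FALSE])
  inv_eff <- rep_len(ef$inversion, length(kcols))

  y <- ef$intercept + ef$wolbachia * panel$wolbachia +
    as.numeric(inv_dos %*% inv_eff)
  if (!is.null(relationship) && ef$polygenic_var > 0) {
    Gm <- if (inherits(relationship, "relationship_matrix"))
      relationship$values else as.matrix(relationship)
    if (nrow(Gm) != n) stop("key error: relationship and panel line sets differ")
    ch <- chol(Gm + diag(1e-6, n))
    y <- y + sqrt(ef$polygenic_var) * as.numeric(t(ch) %*% rnorm(n))
  }
  y <- y + rnorm(n, 0, sqrt(ef$residual_var))

  indel_bp <- if (!is.null(gm)) {
    d <- haploid_dosage(gm); d[is.na(d)] <- 0
    as.numeric(d %*% ifelse(is.na(gm$variants$size), 0, gm$variants$size))
  } else rep(0, n)
  n_inv <- rowSums(inv_dos > 0)
  gs <- ef$genome_size_base_mb + ef$genome_size_per_indel_bp * indel_bp +
    ef$genome_size_per_inversion_mb * n_inv +
    rnorm(n, 0, ef$genome_size_sd_mb)

  reps <- data.frame(
    line_id = rep(panel$line_id, each = ef$n_size_reps),
    replicate = rep(seq_len(ef$n_size_reps), n),
    genome_size_mb = rep(gs, each = ef$n_size_reps) +
      rnorm(n * ef$n_size_reps, 0, ef$genome_size_meas_sd_mb),
    stringsAsFactors = FALSE)

  list(phenotypes = data.frame(line_id = panel$line_id, trait = y,
                               genome_size_mb = gs, n_inversions = n_inv,
                               stringsAsFactors = FALSE),
       genome_size_replicates = reps)
}

#' Emit corrupted per-caller variant lists with read support
#'
#' Stand-in for a battery of independent variant callers: each caller
#' sees the true variant list through a false-negative filter, gains
#' false-positive calls at random positions, and reports per-line
#' supporting/opposing read counts drawn from a Poisson read-depth model
#' with binomial allele sampling at the given sequencing error rate.
#'
#' @param truth A [genotype_matrix()] of true genotypes.
#' @param n_callers Number of callers.
#' @param profile List with `fn_rate`, `fp_rate` (per true variant),
#'   `mean_depth`, `seq_error`.
#' @param seed Integer seed.
#' @return List of per-caller lists, each with `variants` (data frame;
#'   false positives flagged by `is_fp`, true calls keep their index in
#'   the truth table as `truth_idx`), and `support` / `oppose` read-count
#'   matrices (lines x variants).
#' @export
emit_caller_outputs <- function(truth, n_callers = 7L,
                                profile = list(fn_rate = 0, fp_rate = 0,
                                               mean_depth = 12,
                                               seq_error = 0.01),
                                seed = 1L) {
  stopifnot(profile$fn_rate >= 0, profile$fn_rate <= 1,
            profile$fp_rate >= 0, profile$mean_depth >= 0)
  set.seed(seed)
  n <- nrow(truth$geno); V <- ncol(truth$geno)
  contig_len <- tapply(truth$variants$pos, truth$variants$contig, max)
  out <- vector("list", n_callers)
  for (cc in seq_len(n_callers)) {
    keep <- runif(V) >= profile$fn_rate
    vars <- truth$variants[keep, , drop = FALSE]
    vars$is_fp <- FALSE
    vars$truth_idx <- which(keep)
    g <- truth$geno[, keep, drop = FALSE]
    n_fp <- rbinom(1L, V, profile$fp_rate)
    if (n_fp > 0) {
      fp_contig <- sample(names(contig_len), n_fp, replace = TRUE)
      fp_pos <- floor(runif(n_fp) * contig_len[fp_contig])
      fp_ref <- sample(BASES, n_fp, replace = TRUE)
      fp <- vars[rep(NA_integer_, n_fp), , drop = FALSE]
      fp$contig <- fp_contig; fp$pos <- fp_pos
      fp$ref <- fp_ref; fp$alt <- other_base(fp_ref)
      fp$type <- "snp"; fp$size <- 0L; fp$inv_fixed <- 0L
      fp$is_fp <- TRUE; fp$truth_idx <- NA_integer_
      vars <- rbind(vars, fp)
      g <- cbind(g, matrix(0L, n, n_fp))
    }
    o <- order(match(vars$contig, names(contig_len)), vars$pos)
    vars <- vars[o, , drop = FALSE]; rownames(vars) <- NULL
    g <- g[, o, drop = FALSE]
    m <- ncol(g)
    depth <- matrix(rpois(n * m, profile$mean_depth), n, m)
    p_alt <- matrix(profile$seq_error, n, m)
    p_alt[g == 1L] <- 0.5
    p_alt[g == 2L] <- 1 - profile$seq_error
    support <- matrix(rbinom(n * m, as.vector(depth), as.vector(p_alt)), n, m)
    out[[cc]] <- list(variants = vars, support = support,
                      oppose = depth - support)
  }
  out
}

#' Simulate a complete panel (founders, inbreeding, phenotypes)
#'
#' Convenience wrapper chaining [simulate_founders()],
#' [simulate_inbreeding()] and (optionally) [simulate_phenotypes()].
#'
#' @param config A [sim_config()].
#' @param phenotypes Also simulate phenotypes (without a polygenic
#'   component unless `relationship` is given).
#' @param relationship Optional relationship matrix for the polygenic
#'   component.
#' @return List with `founders`, `gm`, `panel`, and (if requested)
#'   `phenotypes` and `genome_size_replicates`.
#' @export
simulate_panel <- function(config = sim_config(), phenotypes = FALSE,
                           relationship = NULL) {
  founders <- simulate_founders(config)
  br <- simulate_inbreeding(founders, config)
  out <- list(founders = founders, gm = br$gm, panel = br$panel)
  if (phenotypes) {
    ph <- simulate_phenotypes(br$panel, relationship, config, gm = br$gm)
    out$phenotypes <- ph$phenotypes
    out$genome_size_replicates <- ph$genome_size_replicates
  }
  out
}
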