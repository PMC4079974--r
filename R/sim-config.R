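#' Specify a polymorphic inversion for the panel simulator
#'
#' An inversion is an interval on one chromosome arm that segregates in
#' the founder population at a given karyotype frequency. Inverted and
#' standard founder haplotypes carry excess fixed differences inside the
#' interval (`divergence` per bp), and recombination in inversion
#' heterokaryotypes is fully suppressed inside the interval when
#' `recombination_suppressed` is set, emulating the loss of single
#' crossover products in paracentric inversion heterozygotes.
#'
#' @param arm Contig (chromosome arm) name.
#' @param start,end 0-based half-open interval on the arm (bp).
#' @param karyotype_frequency Frequency of the inverted orientation among
#'   founder haplotypes.
#' @param divergence Per-bp rate of fixed differences between inverted
#'   and standard founder haplotypes inside the interval.
#' @param recombination_suppressed Suppress crossovers inside the
#'   interval in heterokaryotypes (default `TRUE`).
#' @param name Inversion label.
#' @return Object of class `inversion_spec`.
#' @export
inversion_spec <- function(arm, start, end, karyotype_frequency,
                           divergence = 0, recombination_suppressed = TRUE,
                           name = sprintf("In(%s)", arm)) {
  stopifnot(start < end, divergence >= 0,
            karyotype_frequency >= 0, karyotype_frequency <= 1)
  structure(list(arm = arm, start = as.numeric(start), end = as.numeric(end),
                 karyotype_frequency = karyotype_frequency,
                 divergence = divergence,
                 recombination_suppressed = isTRUE(recombination_suppressed),
                 name = name),
            class = "inversion_spec")
}

#' Configuration for the synthetic inbred-line panel
#'
#' Defines the study conditions the generator emulates: a panel of lines
#' derived from a natural population by `generations_inbreeding`
#' generations of full-sib mating (default 20, expected F = 0.986),
#' segregating SNPs and deletion-biased indels (derived deletions make up
#' `deletion_fraction` of indel events, default 0.69 so deletions
#' outnumber insertions about 2.2:1), frame-shift depletion in coding
#' sequence, polymorphic inversions genetically diverged from the
#' standard karyotype, an outgroup carrying the ancestral allele for
#' polarization, binary endosymbiont (Wolbachia) infection status
#' (default prevalence 0.53), and line-mean phenotypes with inversion,
#' infection and polygenic components.
#'
#' @param n_lines Number of inbred lines.
#' @param n_founder_haplotypes Number of founder haplotypes sampled from
#'   the natural population.
#' @param contigs Data frame with columns `name`, `length` (bp), `is_X`.
#' @param snp_rate,indel_rate Per-bp probability that a site segregates
#'   as a SNP / hosts an indel among the founders.
#' @param deletion_fraction Probability that an indel's derived allele is
#'   a deletion.
#' @param indel_sizes Data frame `size`, `prob`: discrete indel size
#'   distribution (bp), with a 1-2 bp mode and rare large events.
#' @param cds_frameshift_depletion Multiplicative retention probability
#'   for non-3n indels inside coding sequence (purifying-selection
#'   stand-in).
#' @param inversions List of [inversion_spec()] objects.
#' @param generations_inbreeding Full-sib generations per line.
#' @param wolbachia_prevalence Probability a line is infected.
#' @param het_retention Probability that a line founded by discordant
#'   karyotypes is maintained heterokaryotypic through inbreeding
#'   (balancing-selection stand-in; gives the panel its heterokaryotypic
#'   lines).
#' @param x_rate_factor Multiplier on variant rates for X-linked contigs
#'   (3/4 autosomal effective size).
#' @param outgroup_mismatch Probability that the outgroup allele at a
#'   site has itself diverged, making the site unpolarizable by exact
#'   matching.
#' @param crossovers_per_meiosis Mean number of crossovers per arm per
#'   meiosis (Poisson).
#' @param founder_sfs Either `"neutral"` (derived-allele count `i` drawn
#'   with probability proportional to `1/i`) or a function
#'   `f(n_haplotypes)` returning one derived count in
#'   `1..(n_haplotypes-1)`.
#' @param phenotype_effects Named list of generative effect sizes; see
#'   [simulate_phenotypes()].
#' @param gene_spacing Spacing of toy gene models along each contig (bp).
#' @param seed Integer seed; fully determines all generator output.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_lines = 40L,
                       n_founder_haplotypes = 30L,
                       contigs = data.frame(
                         name = c("2L", "2R", "X"),
                         length = c(3e5, 3e5, 3e5),
                         is_X = c(FALSE, FALSE, TRUE)),
                       snp_rate = 0.004,
                       indel_rate = 0.0008,
                       deletion_fraction = 0.69,
                       indel_sizes = data.frame(
                         size = c(1, 2, 3, 4, 5, 6, 8, 10, 50, 150),
                         prob = c(0.38, 0.25, 0.10, 0.07, 0.05, 0.04,
                                  0.04, 0.03, 0.02, 0.02)),
                       cds_frameshift_depletion = 0.2,
                       inversions = list(
                         inversion_spec("2L", 6e4, 2.4e5, 0.15,
                                        divergence = 0.002, name = "In(2L)A"),
                         inversion_spec("2R", 1e5, 2.6e5, 0.10,
                                        divergence = 0.0015, name = "In(2R)B")),
                       generations_inbreeding = 20L,
                       wolbachia_prevalence = 0.53,
                       het_retention = 0.3,
                       x_rate_factor = 0.75,
                       outgroup_mismatch = 0.1,
                       crossovers_per_meiosis = 1,
                       founder_sfs = "neutral",
                       phenotype_effects = list(
                         intercept = 10,
                         wolbachia = 0.5,
                         inversion = 0.8,
                         polygenic_var = 0.3,
                         residual_var = 0.5,
                         genome_size_base_mb = 175.6,
                         genome_size_per_indel_bp = 2e-4,
                         genome_size_per_inversion_mb = -0.5,
                         genome_size_sd_mb = 1.1,
                         genome_size_meas_sd_mb = 1.95,
                         n_size_reps = 5L),
                       gene_spacing = 10000L,
                       seed = 1L) {
  probs <- c(snp_rate, indel_rate, deletion_fraction, wolbachia_prevalence,
             het_retention, outgroup_mismatch, cds_frameshift_depletion)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (any(contigs$length <= 0)) stop("config error: contig lengths must be > 0")
  if (abs(sum(indel_sizes$prob) - 1) > 1e-8)
    stop("indel size distribution must sum to 1")
  for (iv in inversions) {
    stopifnot(inherits(iv, "inversion_spec"))
    len <- contigs$length[match(iv$arm, contigs$name)]
    if (is.na(len) || iv$start < 0 || iv$end > len)
      stop("inversion interval must lie inside its contig")
  }
  if (n_lines < 1 || n_founder_haplotypes < 4)
    stop("need at least 1 line and 4 founder haplotypes")
  structure(list(n_lines = as.integer(n_lines),
                 n_founder_haplotypes = as.integer(n_founder_haplotypes),
                 contigs = contigs, snp_rate = snp_rate,
                 indel_rate = indel_rate,
                 deletion_fraction = deletion_fraction,
                 indel_sizes = indel_sizes,
                 cds_frameshift_depletion = cds_frameshift_depletion,
                 inversions = inversions,
                 generations_inbreeding = as.integer(generations_inbreeding),
                 wolbachia_prevalence = wolbachia_prevalence,
                 het_retention = het_retention,
                 x_rate_factor = x_rate_factor,
                 outgroup_mismatch = outgroup_mismatch,
                 crossovers_per_meiosis = crossovers_per_meiosis,
                 founder_sfs = founder_sfs,
                 phenotype_effects = phenotype_effects,
                 gene_spacing = as.integer(gene_spacing),
                 seed = as.integer(seed)),
            class = "sim_config")
}
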