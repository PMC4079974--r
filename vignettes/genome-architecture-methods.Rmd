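---
title: "Models and methods: genome architecture of an inbred line panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: genome architecture of an inbred line panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genarch)
```

`genarch` implements an end-to-end analysis of natural variation in
genome architecture for a panel of inbred lines derived from a wild
population by repeated full-sib mating: variant integration across
multiple callers, freeze-quality filtering, population genomics of SNPs
and indels, chromosomal-inversion structure, genomic relatedness and
principal components, linkage disequilibrium, functional and
protein-damage annotation, and mixed-model / gene-based association
mapping. Every analysis is exercised on a bundled synthetic panel
generator, so the whole pipeline is testable without any external data.
This vignette records the models, the assumptions behind them, and the
design decisions that were genuinely open.

## The inbreeding model

Each line descends from a single wild-caught mated pair — four founder
haplotypes — through `generations_inbreeding` rounds of brother–sister
mating (default 20). The expected inbreeding coefficient follows the
classical full-sib recurrence

$$F_t = \tfrac{1}{4}\left(1 + 2F_{t-1} + F_{t-2}\right), \qquad
F_0 = F_{-1} = 0,$$

implemented in `expected_inbreeding()`. Twenty generations give
$F_{20} = 0.9863$, i.e. about 1.4% of initially heterozygous loci are
expected to remain segregating. Two conventions matter here and are easy
to get wrong:

* **Generation counting.** $F_1 = 1/4$ is the inbreeding of the
  *offspring of the first sib pair*. The forward simulators therefore
  perform one initial transmission (founder couple → founding sibs)
  followed by `generations` rounds of sib mating. `simulate_ibd_fullsib()`
  is a direct Monte-Carlo transmission of four distinct allele labels
  through this pedigree and reproduces the recurrence to Monte-Carlo
  error; it is the oracle used by the tests.
* **Identity by descent vs identity in state.** $1 - F_t$ is an IBD
  quantity. At a biallelic site two non-IBD lineages can still carry the
  same allele, so the *observable* residual heterozygosity of a
  simulated line, conditioned on the site segregating among its four
  founders, is somewhat below $1 - F_t$. The test suite checks the
  genotype-level quantity against a pattern-aware oracle that combines
  the label pedigree with founder allele configurations drawn from the
  configured frequency spectrum.

## The synthetic panel generator

`sim_config()` fixes the study conditions; `simulate_panel()` executes
them. The defaults are chosen once to mirror the population the
analyses assume:

* **Founders.** 30 founder haplotypes on three chromosome arms (two
  autosomal, one X). SNPs arise at `snp_rate` = 0.004/bp and indels at
  `indel_rate` = 0.0008/bp; derived-allele counts follow a neutral
  $1/i$ frequency spectrum (the natural population's true spectrum is
  unknown, so it is exposed as configuration rather than fixed).
* **Deletion bias.** An indel's derived allele is a deletion with
  probability `deletion_fraction` = 0.69, matching a derived
  deletion:insertion ratio of about 2.2:1. Indel sizes have a 1–2 bp
  mode with rare large events. Non-3n indels inside coding sequence are
  retained at `cds_frameshift_depletion` = 0.2, a multiplicative
  purifying-selection stand-in.
* **The reference is a population sample.** At every site the reference
  sequence carries the derived allele with probability equal to the
  derived-allele frequency. Reference-based "deletion"/"insertion"
  labels therefore disagree with the evolutionary polarization for a
  predictable minority of sites, which is exactly the distinction the
  polarization analysis is meant to expose.
* **Outgroup.** The outgroup allele equals the ancestral allele except
  at an `outgroup_mismatch` = 0.1 fraction of sites where the outgroup
  lineage has itself diverged; those sites become unpolarizable under
  the exact-match rule.
* **Inversions.** Each `inversion_spec()` is an interval segregating at
  a karyotype frequency (defaults 0.15 and 0.10 on the two autosomal
  arms), carrying excess fixed differences between inverted and
  standard founder haplotypes (`divergence` per bp). A polymorphic
  inversion is guaranteed to segregate among the founders (degenerate
  draws are resampled). Recombination is one crossover per arm per
  meiosis on average, uniformly placed, and fully suppressed inside the
  interval in heterokaryotypes. Lines founded by discordant karyotypes
  are maintained heterokaryotypic with probability `het_retention` =
  0.3 — a balancing-selection stand-in that gives the panel its
  heterokaryotypic lines, which would otherwise be lost at the
  $1 - F$ rate.
* **X chromosome.** Variant rates on X-flagged contigs are multiplied
  by 0.75 (three-quarters autosomal effective size), which suffices for
  the X-versus-autosome diversity contrasts; male/female transmission
  asymmetry is not modelled.
* **Phenotypes.** Line means are intercept + Wolbachia effect +
  per-inversion karyotype effects + a polygenic deviate with covariance
  proportional to a supplied relationship matrix + residual noise.
  Genome size (Mb) is a base value (175.6) plus signed indel content,
  a per-inverted-region offset (−0.5 Mb), and line-level noise, with
  replicate measurements at measurement sd 1.95 Mb and 5 replicates per
  line — numbers back-derived from the stated measurement-precision
  criterion (0.5% standard error at ~175 Mb) and the printed among-line
  ANOVA range.
* **Determinism.** A single integer seed fixes everything; stages seed
  at `seed`, `seed + 1`, `seed + 2` so they are reproducible in
  isolation.

What the generator deliberately does *not* emulate: read-level
sequencing (callers are emulated at the call level), transposable
elements, demographic history, crossover interference, and sex
chromosomes' transmission genetics. Passing tests therefore demonstrate
the correctness of the statistical machinery under the stated
generative model, not robustness to every artefact of real short-read
data.

## Variant integration

`emit_caller_outputs()` corrupts the truth into per-caller variant
lists with false negatives, false positives and Poisson read depth;
`consensus_variants()` unions them after left-aligning indels (so
alternative alignments of one event collapse to one record), keeping
records that disagree on the reference allele flagged rather than
merged. `build_haplotype_bins()` groups non-SNP variants separated by
less than a 110 bp clean flank into bins — the garbled published
wording of the bin rule is resolved as: a single non-SNP-free run of at
least 110 bp on each side separates bins.

`genotype_from_counts()` is a deliberately simple, fully documented
genotype model standing in for the original design-aware caller: a
uniform prior over {hom ref, segregating, hom alt} with binomial read
likelihoods at alternate-read probabilities $\epsilon$, $1/2$ and
$1-\epsilon$. Genotype quality is the phred score of one minus the
maximum posterior; zero depth is missing. Site quality is the pooled
evidence against all-homozygous-reference,
$\sum_i -10\log_{10} P(\text{hom ref}_i)$, which cleanly separates
supported sites from false positives at the freeze threshold of 500.
`apply_freeze_filters()` drops sites below that quality, multiallelic
records and overlapping records, and blanks calls below depth 1 or
genotype quality 20; filtering is idempotent.

Cross-platform validation uses a two-sided Fisher's exact test on the
2×2 supporting/opposing read-count table (`concordance_test()`),
declaring discordance at a nominal 5% level. The Fisher p-value itself
(`fisher_exact()`) sums hypergeometric probabilities no larger than the
observed table's, accumulated in log space so that extreme tables (the
inversion association table reaches $10^{-81}$) do not underflow.

## Population genomics

Inbred lines are read as single haplotypes everywhere: a residual
segregating call is treated as missing for that line at that site. Per
window of 100 kb, diversity is
$\pi = \sum_{\text{sites}} \frac{n}{n-1}\, 2p(1-p) / w$ with $n$ the
callable lines at the site — algebraically identical to the mean
pairwise difference, which is how the brute-force test oracle computes
it. Whether the published windowed diversity used the $n/(n-1)$
correction is unstated; it is used here and documented. $\pi_{indel}$
is the same statistic over indel sites, each indel counting once
regardless of length; divergence $k$ counts panel-fixed differences
from the outgroup per bp.

Polarization assigns ancestral state by exact match of the outgroup
allele; sites matching neither allele are excluded (the exact-match
rule is a declared stand-in for the published supplementary protocol,
consistent with its excluded fraction). Derived type compares allele
lengths. Spectra, within/between-karyotype diversity, SNP clustering
around intermediate-frequency focal variants (±100 bp, MAF 0.40–0.50,
carrier-stratified), recombination-rank correlations, and
chromatin-domain binomial enrichment follow directly; the 9%/2%
segregating thresholds and the clustering windows are configuration
defaults, not constants.

## Relatedness and principal components

`compute_grm()` uses the VanRaden estimator
$G = ZZ^\top / (2\sum_k p_k(1-p_k))$ on 0/2 dosages (MAF ≥ 0.05, call
rate ≥ 0.8, segregating calls missing, missing mean-imputed per variant
— imputation preserves the centering), normalized by the mean diagonal.
Per-chromosome GRMs combine to the genome-wide GRM when weighted by
their heterozygosity denominators, which the tests assert.

`grm_pca()` standardizes each variant and eigen-decomposes the line ×
line covariance. Two numerical choices depart from the diploid
textbook convention and are worth recording. First, inbred 0/2 dosages
have variance $4p(1-p)$, so the scale is $2\sqrt{p(1-p)}$ (scores are
identical up to a global constant; calibration is not). Second,
standardizing by allele frequencies estimated from the same column
inflates every column's sample variance by $n/(n-1)$; the matrix is
shrunk by $\sqrt{(n-1)/n}$ to remove this. With both corrections the
leading eigenvalue of a pure-noise panel follows the Tracy–Widom law
closely (the test suite checks the null rejection rate; the
implementation is mildly conservative). Tracy–Widom probabilities use
the shifted-gamma approximation of the TW1 distribution (accurate to
about $10^{-3}$), and the $i$-th eigenvalue is tested with the sample
size notionally reduced by the $i-1$ leading directions. A
moment-based "effective marker count" normalization was evaluated and
was less well calibrated on haploid dosages, so it is not used.

LD pruning is greedy and deterministic: left-to-right windows of 500
variants (half-window step), repeatedly dropping the later member of
the worst pair until no retained pair reaches $r^2 = 0.2$.

## Linkage disequilibrium

`ld_pair()` computes $D$, $D'$ and $r^2$ from haploid allele vectors
with pairwise-complete lines; $r^2$ equals the squared Pearson
correlation, which the tests verify on random instances, and $D' = 1$
whenever a gamete class is absent (brute-forced over all small tables).
Decay curves, 1 Mb / 100 kb sliding-window tracks of 50–150 bp pair
LD, and long-range strong-LD counts ($r^2 > 0.95$, local radius 1 kb,
sampled focal variants stratified by minor-allele count and inversion
membership) follow the corresponding genome-scale analyses at desk
scale; pair subsampling (default cap 2×10⁶ pairs per arm, seeded) is a
documented deviation knob. Distances are measured between variant
start coordinates.

## Annotation and protein damage

Consequences are classified against toy gene models (two coding exons,
600 bp CDS, alternating strands): splice sites are the 2 bp at each
intron end; CDS indels are frame-shifts unless their length change is a
multiple of 3; substitutions creating or removing stops, or disrupting
the start ATG, are classified accordingly; the six classes splice
acceptor/donor, start lost, frame shift, stop gained and stop lost are
"potentially damaging". The classifier agrees with an exhaustive
per-codon enumeration oracle on both strands.

Line-specific damage applies all homozygous variants of a line to each
transcript right-to-left in genomic coordinates, reverse-complements
minus-strand products, translates with the standard code (stop at first
stop, trailing partial codon dropped), and compares to the reference
protein by global alignment with BLOSUM62 scores, gap open 12 / gap
extend 2 — stretcher-like defaults; the published parameters are not
stated, so these are declared and configurable. Identity uses the
alignment length including gaps as denominator (also a documented
choice; gapped vs ungapped is unstated in the source methods). A
transcript is damaged if the start or stop is lost or identity falls
below 90%; a gene is damaged only if *every* splice variant is damaged.
Compensatory pairs are frame-restoring indel pairs (each frame-shifting
alone, jointly in-frame, identical homozygous carrier sets) and
stop-rescuing same-codon SNP pairs (stop allele present only in rescuer
carriers), each reported with $D'$.

## Association mapping

Mapping is two-stage. `adjust_phenotype()` regresses line means on
Wolbachia status and inversion karyotype dosages and keeps residuals
plus the grand mean. `mixed_model_scan()` fits
$y = Xb + Zu + e$ with $\mathrm{var}(u) = \sigma_g^2 G$: variance
components are estimated once on the null model by maximum likelihood
after eigen-rotation by $G$ (ML chosen for determinism; the original
analysis names a program, not an estimator), then each variant is
tested by weighted least squares in the rotated basis with a t
reference on $n-2$ degrees of freedom. With $G = I$ this reproduces
ordinary least-squares p-values exactly, which is a test invariant.
Restriction to MAF ≥ 0.05 is the contract for single-variant scans.

Gene-based tests aggregate variants within the gene span ± 1 kb (gene
span rather than transcript span; configurable). The burden score per
line is $\sum_j w_j g_{ij}$ with $w_j = 1/\sqrt{p_j(1-p_j)/n}$ —
the reciprocal standard deviation of the estimated minor allele
frequency with haploid $n$, the ploidy convention the source leaves
unstated — tested by a covariate-adjusted score test against an
$F(1, n-q)$ reference (the chi-square reference is anti-conservative
in small panels; the F reference matches the t-test the statistic
reduces to). SKAT uses the unweighted linear kernel
$K = GG^\top$, $Q = r^\top K r$, with the null mixture-of-chi-squares
evaluated by moment matching (Liu-type); accuracy is validated against
the calibration suite rather than exact mixture inversion. Binary
traits (Wolbachia status) use a logistic null model. PC covariates
default to those with Tracy–Widom p < 0.01. Genomic inflation is
$\lambda$ = median observed $\chi^2_1$ quantile / 0.4549.

The genome-size model regresses line-mean size on the number of
polymorphic inverted regions carried, alongside a one-way among-line
ANOVA on replicate measurements. The source describes the ANOVA
response once as the within-line standard deviation and elsewhere
analyses mean size; both readings are implemented
(`genome_size_model(..., response = "sd")`), and the discrepancy is
flagged rather than resolved.

## Problem sizes and calibration conditions

The bundled analyses and tests run at desk scale: panels of 40–205
lines on 2–3 contigs of 0.1–1 Mb, a few thousand variants. Type-I
calibration of the scan and the gene-based tests uses 5,000 null
replicates at the study's panel size of 205 lines, where the
asymptotic references hold well; the deletion-share recovery runs at
roughly 22,000 simulated indels; the forward IBD check uses 2×10⁶
transmissions. The acceptance script (`scripts/acceptance.R`)
recomputes all headline quantities from scratch at these sizes in
about 15 seconds.

## Known limitations

* The genotype model is a stand-in with a uniform prior; the original
  design-aware likelihood is not reproduced, and its prior is unknown.
* Breakpoint-proximity diversity profiles are computed as plain
  sub-window statistics without smoothing, since local variation is
  expected to swamp the breakpoint signal at this scale.
* The Tracy–Widom test is approximate (shifted-gamma TW1, step-down
  sample-size heuristic) and errs on the conservative side.
* SKAT p-values from moment matching lose accuracy in the extreme tail
  (roughly below $10^{-4}$); Bonferroni decisions at desk scale are
  unaffected.
* Heterokaryotype maintenance, the neutral $1/i$ founder spectrum, and
  call-level caller emulation are modelling conveniences; none is a
  claim about mechanism in real panels.
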