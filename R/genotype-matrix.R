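#' Construct a genotype matrix
#'
#' Central exchange object for the pipeline: a lines x variants matrix of
#' per-line calls. Calls are coded as the number of alternate-allele
#' copies in the (nominally inbred) line: `0` homozygous reference, `2`
#' homozygous alternate, `1` residually segregating (the line's two
#' descendant haplotypes disagree), `NA` missing.
#'
#' @param geno Integer matrix, lines x variants, values in `{0, 1, 2, NA}`.
#' @param variants Data frame with one row per variant; must contain at
#'   least `contig`, `pos` (0-based), `ref`, `alt`, `type`. A `site_qual`
#'   column (phred) and other annotation columns are carried along.
#' @param line_ids Character vector of line identifiers (rownames).
#' @param depth,gq Optional matrices of per-call sequencing depth and
#'   phred-scaled genotype quality, same shape as `geno`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, variants, line_ids = rownames(geno),
                            depth = NULL, gq = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(variants) != ncol(geno))
    stop("`variants` must have one row per genotype column")
  if (is.null(line_ids)) line_ids <- paste0("line_", seq_len(nrow(geno)))
  stopifnot(length(line_ids) == nrow(geno))
  if (!is.null(depth)) stopifnot(all(dim(depth) == dim(geno)))
  if (!is.null(gq)) stopifnot(all(dim(gq) == dim(geno)))
  rownames(geno) <- line_ids
  structure(list(geno = geno, variants = as.data.frame(variants),
                 line_ids = as.character(line_ids),
                 depth = depth, gq = gq),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d lines x %d variants\n",
              nrow(x$geno), ncol(x$geno)))
  tab <- table(x$variants$type)
  cat("  variant types:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by variant and/or line index
#' @param gm A [genotype_matrix()].
#' @param variants Integer/logical index over variant columns.
#' @param lines Integer/logical/character index over lines.
#' @return A `genotype_matrix` restricted to the selection.
#' @export
subset_gm <- function(gm, variants = NULL, lines = NULL) {
  if (is.null(variants)) variants <- seq_len(ncol(gm$geno))
  if (is.null(lines)) lines <- seq_len(nrow(gm$geno))
  genotype_matrix(gm$geno[lines, variants, drop = FALSE],
                  gm$variants[variants, , drop = FALSE],
                  line_ids = gm$line_ids[if (is.character(lines))
                    match(lines, gm$line_ids) else lines],
                  depth = if (!is.null(gm$depth)) gm$depth[lines, variants, drop = FALSE],
                  gq = if (!is.null(gm$gq)) gm$gq[lines, variants, drop = FALSE])
}

#' Haploid allele dosages from an inbred-line genotype matrix
#'
#' Inbred lines are read as single haplotypes: homozygous calls map to
#' allele dosage 0 or 1 and residual segregating calls are treated as
#' missing at that site for that line.
#'
#' @param gm A [genotype_matrix()].
#' @return Numeric matrix (lines x variants) with values 0, 1 or `NA`.
#' @export
haploid_dosage <- function(gm) {
  d <- gm$geno
  d[d == 1L] <- NA_integer_
  d / 2
}

#' Alternate-allele frequencies over non-missing haploid calls
#' @param gm A [genotype_matrix()].
#' @return Numeric vector of per-variant alternate-allele frequencies
#'   (NaN where no line is callable).
#' @export
alt_freq <- function(gm) {
  colMeans(haploid_dosage(gm), na.rm = TRUE)
}

#' Minor-allele frequencies over non-missing haploid calls
#' @param gm A [genotype_matrix()].
#' @return Numeric vector, `pmin(p, 1 - p)` of [alt_freq()].
#' @export
minor_freq <- function(gm) {
  p <- alt_freq(gm)
  pmin(p, 1 - p)
}

#' Per-variant call rate (fraction of lines with a usable haploid call)
#' @param gm A [genotype_matrix()].
#' @return Numeric vector in `[0, 1]`.
#' @export
call_rate <- function(gm) {
  colMeans(!is.na(haploid_dosage(gm)))
}
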