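# Two-stage association mapping: covariate adjustment, single-variant
# mixed-model scans against the genomic relationship matrix, gene-based
# weighted burden and linear-kernel SKAT tests, inflation diagnostics,
# and the genome-size-on-inversion-count model.

#' Adjust line means for Wolbachia and inversion karyotypes
#'
#' Least-squares fit of line means on infection status (0/1) and
#' per-inversion karyotype dosage (0/1/2); adjusted values are the
#' residuals plus the grand mean. Aliased covariate columns are dropped
#' with a warning.
#'
#' @param y Numeric vector of line means (order matching `panel`).
#' @param panel Panel metadata with `wolbachia` and `inv*_dosage`
#'   columns.
#' @param use_wolbachia,use_inversions Include the respective covariate
#'   blocks.
#' @return Object of class `adjusted_phenotype`: `line_ids`, `raw`,
#'   `adjusted`, `design` (the covariate matrix actually fitted).
#' @export
adjust_phenotype <- function(y, panel, use_wolbachia = TRUE,
                             use_inversions = TRUE) {
  stopifnot(length(y) == nrow(panel))
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "intercept"))
  if (use_wolbachia) X <- cbind(X, wolbachia = panel$wolbachia)
  if (use_inversions) {
    kcols <- grep("^inv[0-9]+_dosage$", names(panel), value = TRUE)
    for (kc in kcols) X <- cbind(X, panel[[kc]])
    colnames(X)[(ncol(X) - length(kcols) + 1):ncol(X)] <- kcols
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    warning("dropping aliased covariate(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  fit <- lm.fit(X, y)
  adj <- fit$residuals + mean(y)
  structure(list(line_ids = panel$line_id, raw = y, adjusted = adj,
                 design = X),
            class = "adjusted_phenotype")
}

# Profile ML of the heritability ratio on the eigen-rotated null model.
fit_null_mm <- function(ystar, ones_star, d) {
  n <- length(ystar)
  negll <- function(h2) {
    v <- h2 * d + (1 - h2)
    w <- 1 / v
    mu <- sum(w * ones_star * ystar) / sum(w * ones_star^2)
    r <- ystar - mu * ones_star
    s2 <- sum(r^2 * w) / n
    0.5 * (n * log(s2) + sum(log(v)))
  }
  opt <- optimize(negll, c(0, 0.999))
  h2 <- opt$minimum
  v <- h2 * d + (1 - h2)
  w <- 1 / v
  mu <- sum(w * ones_star * ystar) / sum(w * ones_star^2)
  s2 <- sum((ystar - mu * ones_star)^2 * w) / n
  list(h2 = h2, sigma2_g = h2 * s2, sigma2_e = (1 - h2) * s2, v = v)
}

#' Single-variant mixed-model association scan
#'
#' Fits \eqn{y = X b + Z u + e} with polygenic covariance
#' \eqn{G \sigma^2_g}: variance components are estimated once by maximum
#' likelihood on the null model after eigen-rotation by `G`'s
#' eigenvectors, then each variant is tested by generalized least
#' squares (weighted regression in the rotated basis) with a Wald t
#' test. Variants below the minor-allele-frequency floor are skipped,
#' as are variants whose rotated design is singular.
#'
#' @param y Adjusted phenotype values (or an [adjust_phenotype()]
#'   result).
#' @param gm A [genotype_matrix()].
#' @param G A [compute_grm()] result (normalized).
#' @param maf_min MAF floor (default 0.05).
#' @return Data frame `variant`, `maf`, `b`, `se`, `p`, with variance
#'   components in attributes `sigma2_g`, `sigma2_e`, `h2`.
#' @export
mixed_model_scan <- function(y, gm, G, maf_min = 0.05) {
  if (inherits(y, "adjusted_phenotype")) y <- y$adjusted
  Gm <- if (inherits(G, "relationship_matrix")) G$values else as.matrix(G)
  n <- length(y)
  stopifnot(nrow(Gm) == n, nrow(gm$geno) == n)
  ee <- eigen(Gm, symmetric = TRUE)
  U <- ee$vectors; d <- pmax(ee$values, 0)
  ystar <- drop(crossprod(U, y))
  ones_star <- drop(crossprod(U, rep(1, n)))
  null <- fit_null_mm(ystar, ones_star, d)
  w <- 1 / null$v
  maf <- minor_freq(gm)
  test_idx <- which(!is.na(maf) & maf >= maf_min)
  D <- haploid_dosage(gm)
  out <- data.frame(variant = gm$variants$id[test_idx],
                    maf = maf[test_idx], b = NA_real_, se = NA_real_,
                    p = NA_real_)
  for (k in seq_along(test_idx)) {
    x <- D[, test_idx[k]]
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    X <- cbind(1, x)
    Xs <- crossprod(U, X)
    XtWX <- crossprod(Xs, Xs * w)
    if (abs(det(XtWX)) < 1e-12) next
    XtWy <- crossprod(Xs, ystar * w)
    beta <- solve(XtWX, XtWy)
    r <- ystar - Xs %*% beta
    s2 <- sum(r^2 * w) / (n - 2)
    seb <- sqrt(diag(solve(XtWX)) * s2)
    tt <- beta[2] / seb[2]
    out$b[k] <- beta[2]; out$se[k] <- seb[2]
    out$p[k] <- 2 * pt(-abs(tt), df = n - 2)
  }
  attr(out, "sigma2_g") <- null$sigma2_g
  attr(out, "sigma2_e") <- null$sigma2_e
  attr(out, "h2") <- null$h2
  out
}

# Liu et al. moment-matching p-value for Q ~ sum lambda_i chi2_1.
liu_pvalue <- function(q, lambda) {
  lambda <- lambda[lambda > 1e-10 * max(lambda, 1e-300)]
  if (length(lambda) == 0) return(1)
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    a <- 1 / s1; delta <- 0; l <- c2^3 / c3^2
  }
  muQ <- c1; sigmaQ <- sqrt(2 * c2)
  tstar <- (q - muQ) / sigmaQ
  muX <- l + delta; sigmaX <- sqrt(2) * a
  pchisq(tstar * sigmaX + muX, df = l, ncp = delta, lower.tail = FALSE)
}

# Null-model pieces shared by the gene-based tests.
gene_test_null <- function(y, X, family) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  if (family == "gaussian") {
    fit <- lm.fit(X, y)
    r <- fit$residuals
    s2 <- sum(r^2) / (length(y) - ncol(X))
    H <- X %*% solve(crossprod(X)) %*% t(X)
    list(resid = r, P = s2 * (diag(length(y)) - H), W = NULL)
  } else {
    fit <- glm.fit(X, y, family = binomial())
    mu <- fit$fitted.values
    W <- mu * (1 - mu)
    WX <- X * W
    P <- diag(W) - WX %*% solve(crossprod(X, WX)) %*% t(WX)
    list(resid = y - mu, P = P, W = W)
  }
}

#' Weighted burden test for a set of variants
#'
#' Per-line burden score \eqn{\sum_j w_j g_{ij}} with
#' \eqn{w_j = 1/\sqrt{p_j (1-p_j)/n}} (the reciprocal of the standard
#' deviation of the estimated minor allele frequency, haploid `n`),
#' tested against the phenotype by a covariate-adjusted score test.
#' Binary traits use a logistic null model.
#'
#' @param gm A [genotype_matrix()].
#' @param variant_idx Column indices of the gene's variants.
#' @param y Phenotype vector (0/1 for `family = "binomial"`).
#' @param covariates Optional covariate matrix (intercept added).
#' @param family `"gaussian"` or `"binomial"`.
#' @return One-row data frame `test`, `statistic`, `p`, `n_variants`
#'   (`NULL` if no variant is polymorphic).
#' @export
burden_test <- function(gm, variant_idx, y, covariates = NULL,
                        family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  Dm <- haploid_dosage(gm)[, variant_idx, drop = FALSE]
  p <- colMeans(Dm, na.rm = TRUE)
  nn <- colSums(!is.na(Dm))
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) return(NULL)
  Dm <- Dm[, poly, drop = FALSE]; p <- p[poly]; nn <- nn[poly]
  for (j in seq_len(ncol(Dm))) Dm[is.na(Dm[, j]), j] <- p[j]
  w <- 1 / sqrt(p * (1 - p) / nn)
  burden <- drop(Dm %*% w)
  X <- cbind(intercept = rep(1, length(y)), covariates)
  nul <- gene_test_null(y, X, family)
  U <- sum(burden * nul$resid)
  V <- drop(t(burden) %*% nul$P %*% burden)
  if (V <= 0) return(NULL)
  stat <- U^2 / V
  # F(1, n - q) reference: matches the t-test this reduces to and keeps
  # the size correct in small panels (chi-square is anti-conservative)
  df2 <- length(y) - ncol(X)
  p <- if (family == "gaussian") pf(stat, 1, df2, lower.tail = FALSE)
  else pchisq(stat, 1, lower.tail = FALSE)
  data.frame(test = "burden", statistic = stat, p = p,
             n_variants = ncol(Dm), stringsAsFactors = FALSE)
}

#' Linear-kernel SKAT test for a set of variants
#'
#' Variance-component score test with the unweighted linear kernel
#' \eqn{K = G G^T} built from the gene's genotype matrix:
#' \eqn{Q = r^T K r} for null-model residuals `r`, with the null
#' distribution (a mixture of chi-squares) evaluated by moment matching.
#'
#' @inheritParams burden_test
#' @return One-row data frame `test`, `statistic` (Q), `p`,
#'   `n_variants`.
#' @export
skat_test <- function(gm, variant_idx, y, covariates = NULL,
                      family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  Dm <- haploid_dosage(gm)[, variant_idx, drop = FALSE]
  p <- colMeans(Dm, na.rm = TRUE)
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) return(NULL)
  Dm <- Dm[, poly, drop = FALSE]; p <- p[poly]
  for (j in seq_len(ncol(Dm))) Dm[is.na(Dm[, j]), j] <- p[j]
  X <- cbind(intercept = rep(1, length(y)), covariates)
  nul <- gene_test_null(y, X, family)
  Q <- sum(drop(crossprod(Dm, nul$resid))^2)
  PK <- nul$P %*% tcrossprod(Dm)
  lambda <- Re(eigen(PK, only.values = TRUE)$values)
  data.frame(test = "skat", statistic = Q, p = liu_pvalue(Q, lambda),
             n_variants = ncol(Dm), stringsAsFactors = FALSE)
}

#' Variants within a gene window
#'
#' @param gm A [genotype_matrix()].
#' @param gene A [gene_model()] (or list with `contig` and a span).
#' @param flank Window extension beyond the gene span (bp, default
#'   1 kb).
#' @param maf_range Closed MAF interval (`c(0, 1)` keeps all).
#' @return Integer vector of variant column indices.
#' @export
gene_window_variants <- function(gm, gene, flank = 1000,
                                 maf_range = c(0, 1)) {
  span <- gene_span(gene)
  maf <- minor_freq(gm)
  which(gm$variants$contig == gene$contig &
          gm$variants$pos >= span[1] - flank &
          gm$variants$pos < span[2] + flank &
          !is.na(maf) & maf >= maf_range[1] & maf <= maf_range[2])
}

#' Genomic inflation factor and QQ table
#'
#' \eqn{\lambda} = median observed 1-df chi-square quantile divided by
#' 0.4549 (the null median).
#'
#' @param p Vector of p-values.
#' @return List `lambda`, `qq` (data frame `expected`, `observed`, on
#'   the -log10 scale).
#' @export
qq_inflation <- function(p) {
  p <- p[!is.na(p)]
  chi <- qchisq(p, df = 1, lower.tail = FALSE)
  lambda <- median(chi) / qchisq(0.5, df = 1, lower.tail = FALSE)
  o <- sort(p)
  e <- (seq_along(o) - 0.5) / length(o)
  list(lambda = lambda,
       qq = data.frame(expected = -log10(e), observed = -log10(o)))
}

#' Genome size versus inversion count
#'
#' Least-squares regression of line-mean genome size on the number of
#' segregating/polymorphic inversions carried (0-4), plus a one-way
#' among-line ANOVA on replicate size measurements. The within-line
#' standard deviation can be regressed on the count instead via
#' `response = "sd"` (both readings of the model are provided).
#'
#' @param sizes Line-mean genome sizes (Mb).
#' @param inversion_counts Integer inversion counts per line.
#' @param replicates Optional data frame `line_id`, `genome_size_mb` of
#'   replicate measurements for the ANOVA.
#' @param response For the regression: line `"mean"` sizes (default) or
#'   within-line `"sd"` from `replicates`.
#' @return List `b` (slope), `F`, `df`, `p`, and (given replicates)
#'   `anova_F`, `anova_p`.
#' @export
genome_size_model <- function(sizes, inversion_counts, replicates = NULL,
                              response = c("mean", "sd")) {
  response <- match.arg(response)
  if (length(unique(inversion_counts)) < 2)
    stop("inversion counts are constant; slope undefined")
  yv <- sizes
  if (response == "sd") {
    if (is.null(replicates)) stop("`replicates` required for response = 'sd'")
    yv <- tapply(replicates$genome_size_mb, replicates$line_id, sd)
    yv <- as.numeric(yv[match(names(yv), names(yv))])
    inversion_counts <- inversion_counts[seq_along(yv)]
  }
  fit <- lm(yv ~ inversion_counts)
  an <- anova(fit)
  out <- list(b = unname(coef(fit)[2]), F = an$`F value`[1],
              df = unname(an$Df), p = an$`Pr(>F)`[1])
  if (!is.null(replicates)) {
    av <- anova(lm(genome_size_mb ~ factor(line_id), data = replicates))
    out$anova_F <- av$`F value`[1]
    out$anova_p <- av$`Pr(>F)`[1]
  }
  out
}
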