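#' Pairwise IBS kinship statistics
#'
#' Joint-genotype category counts and the allele-frequency-free KING-robust
#' kinship estimator for a pair of individuals, with the R0/R1 identity-by-
#' state ratios used to separate relationship classes.
#'
#' `kinship = (N11 - 2 (N02 + N20)) / (Nhet_i + Nhet_j)`, where `N(a,b)`
#' counts sites with genotype `a` in the first and `b` in the second
#' individual and `Nhet` counts heterozygous sites per individual;
#' `R0 = (N02 + N20) / N11`; `R1 = N11 / (sum of discordant and double-het
#' categories)`.  Pairs compared at fewer than `min_sites` sites are flagged
#' and excluded from population summaries.
#'
#' @param g1,g2 genotype vectors (0/1/2, `NA` missing) on the same sites.
#' @param min_sites overlap threshold below which the pair is flagged
#'   (default 100,000, the pair filter used with sparse low-coverage data).
#' @return a one-row data.frame with counts, `R0`, `R1`, `king`, `degree`
#'   and the `filtered` flag.
#' @export
pair_ibs_stats <- function(g1, g2, min_sites = 1e5) {
  stopifnot(length(g1) == length(g2))
  ok <- !is.na(g1) & !is.na(g2)
  n <- sum(ok)
  if (n == 0) stop("no overlapping genotyped sites")
  a <- g1[ok]; b <- g2[ok]
  counts <- table(factor(a, 0:2), factor(b, 0:2))
  N11 <- counts["1", "1"]
  Nopp <- counts["0", "2"] + counts["2", "0"]
  het_i <- sum(counts["1", ])
  het_j <- sum(counts[, "1"])
  king <- if (het_i + het_j > 0) (N11 - 2 * Nopp) / (het_i + het_j) else NA_real_
  disc <- counts["0", "1"] + counts["1", "0"] + counts["1", "2"] +
    counts["2", "1"] + Nopp
  R0 <- if (N11 > 0) Nopp / N11 else NA_real_
  R1 <- if (disc + N11 > 0) N11 / (disc + N11) else NA_real_
  data.frame(n_sites = n,
             n11 = as.integer(N11), n_opp = as.integer(Nopp),
             R0 = R0, R1 = R1, king = king,
             degree = classify_degree(king),
             filtered = n < min_sites,
             stringsAsFactors = FALSE)
}

#' Kinship degree from the KING-robust estimate
#'
#' Standard powers-of-two kinship bins: identical/self above `2^-1.5`,
#' then 1st, 2nd, 3rd degree down to unrelated below `2^-4.5`.
#'
#' @param kinship numeric kinship estimate(s).
#' @return character vector of degree labels.
#' @export
#' @examples
#' classify_degree(c(0.5, 0.25, 0.01))
classify_degree <- function(kinship) {
  cuts <- 2^-c(1.5, 2.5, 3.5, 4.5)
  labels <- c("identical/self", "1st", "2nd", "3rd", "unrelated")
  out <- rep(NA_character_, length(kinship))
  fin <- is.finite(kinship)
  out[fin] <- labels[findInterval(-kinship[fin], -c(Inf, cuts)) ]
  out
}

#' All-pairs kinship table
#'
#' @param geno genotype matrix (sites x individuals).
#' @param min_sites pair filter threshold, see [pair_ibs_stats()].
#' @return data.frame with one row per unordered pair.
#' @export
kinship_all_pairs <- function(geno, min_sites = 1e5) {
  ids <- colnames(geno)
  if (is.null(ids)) ids <- sprintf("ind%02d", seq_len(ncol(geno)))
  pairs <- utils::combn(ncol(geno), 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    cbind(data.frame(id1 = ids[i], id2 = ids[j], stringsAsFactors = FALSE),
          pair_ibs_stats(geno[, i], geno[, j], min_sites = min_sites))
  }))
  rownames(out) <- NULL
  out
}

#' Individual inbreeding coefficient from genotype likelihoods
#'
#' Maximum-likelihood estimate of the per-individual inbreeding coefficient
#' `F` in `[-1, 1]` against population allele frequencies, using the
#' inbreeding-parameterised genotype prior `P(0) = (1-f)^2 + f(1-f)F`,
#' `P(1) = 2f(1-f)(1-F)`, `P(2) = f^2 + f(1-f)F` (clipped at zero and
#' renormalised where `F < 0` makes a prior negative).  Negative `F`
#' indicates heterozygote excess, positive `F` homozygote excess.
#'
#' @param gl a [gl_matrix()].
#' @param variants a `variant_table` with `af_alt` (the population allele
#'   frequencies); its sites are looked up in `gl`.
#' @param min_sites minimum polymorphic sites with data per individual
#'   (default 100).
#' @param tol optimisation tolerance (default 1e-9).
#' @return data.frame with `individual`, `F`, `n_sites`, `converged`.
#' @export
individual_F <- function(gl, variants, min_sites = 100, tol = 1e-9) {
  stopifnot(inherits(gl, "gl_matrix"))
  m <- match(variants$pos, gl$pos)
  if (anyNA(m)) stop("variants not present in the GL matrix")
  f <- variants$af_alt
  N <- ncol(gl$depth)
  out <- data.frame(individual = gl$individual %||% sprintf("ind%02d", 1:N),
                    F = NA_real_, n_sites = 0L, converged = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(N)) {
    dep <- gl$depth[m, j]
    has <- dep > 0
    ns <- sum(has)
    out$n_sites[j] <- ns
    if (ns < min_sites) next
    l0 <- gl$hom_ref[m, j][has]; l1 <- gl$het[m, j][has]
    l2 <- gl$hom_alt[m, j][has]
    M <- pmax(l0, l1, l2)
    w0 <- exp(l0 - M); w1 <- exp(l1 - M); w2 <- exp(l2 - M)
    fs <- f[has]
    ll <- function(F) {
      p0 <- pmax((1 - fs)^2 + fs * (1 - fs) * F, 0)
      p1 <- pmax(2 * fs * (1 - fs) * (1 - F), 0)
      p2 <- pmax(fs^2 + fs * (1 - fs) * F, 0)
      s <- p0 + p1 + p2
      sum(log(pmax((w0 * p0 + w1 * p1 + w2 * p2) / s, 1e-300)))
    }
    opt <- optimize(ll, c(-1, 1), maximum = TRUE, tol = tol)
    Fhat <- opt$maximum
    # optimize never evaluates the exact interval ends; snap when boundary
    # values dominate
    if (ll(-1) > opt$objective) Fhat <- -1
    if (ll(1) > max(opt$objective, ll(-1))) Fhat <- 1
    out$F[j] <- max(-1, min(1, Fhat))
    out$converged[j] <- TRUE
  }
  out
}

#' Genotype covariance PCA
#'
#' Standardises genotypes by allele frequency, `(g - 2f) / sqrt(2f(1-f))`,
#' forms the individual-by-individual covariance matrix averaged over sites,
#' and eigendecomposes it.
#'
#' @param geno genotype matrix (sites x individuals), `NA` allowed
#'   (mean-imputed after standardisation).
#' @param f alternate-allele frequencies per site; defaults to sample
#'   frequencies from `geno`.
#' @return list with `scores` (individuals x PCs), `values` (eigenvalues),
#'   `cov` (covariance matrix).
#' @export
covariance_pca <- function(geno, f = NULL) {
  if (ncol(geno) < 2 || nrow(geno) < 2)
    stop("need at least 2 individuals and 2 sites")
  if (is.null(f)) f <- rowMeans(geno, na.rm = TRUE) / 2
  m <- rowMeans(geno, na.rm = TRUE)
  v <- rowMeans(geno^2, na.rm = TRUE) - m^2
  poly <- f > 0 & f < 1 & !is.na(f) & v > 1e-12
  if (!any(poly)) stop("no polymorphic sites")
  g <- geno[poly, , drop = FALSE]
  fp <- f[poly]
  X <- (g - 2 * fp) / sqrt(2 * fp * (1 - fp))
  X[is.na(X)] <- 0
  C <- crossprod(X) / nrow(X)
  eig <- eigen(C, symmetric = TRUE)
  scores <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)))
  rownames(scores) <- colnames(geno)
  rownames(C) <- colnames(C) <- colnames(geno)
  list(scores = scores, values = eig$values, cov = C)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
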