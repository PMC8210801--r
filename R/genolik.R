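#' Genotype log-likelihoods from read counts
#'
#' Computes the three diploid genotype log-likelihoods from counts of reads
#' supporting the reference and alternate allele, under the SAMtools-style
#' error model: a read matches its template allele with probability `1 - e`
#' and reports any given other base with probability `e/3`; the likelihood of
#' a genotype is the product over reads of the mean over the genotype's two
#' alleles.
#'
#' @param ref_count,alt_count non-negative counts (scalars, vectors or
#'   matrices of matching shape).
#' @param e per-base sequencing error rate, in (0, 0.75).
#' @return a list with components `hom_ref`, `het`, `hom_alt` of the same
#'   shape as the inputs, in natural log.  With zero reads all three are 0
#'   (flat likelihood).
#' @export
#' @examples
#' gl_from_pileup(4, 0, e = 0.01)
gl_from_pileup <- function(ref_count, alt_count, e) {
  stopifnot(e > 0, e < 0.75, all(ref_count >= 0), all(alt_count >= 0))
  match_l <- log(1 - e)
  mism_l <- log(e / 3)
  het_l <- log(((1 - e) + e / 3) / 2)
  list(hom_ref = ref_count * match_l + alt_count * mism_l,
       het     = (ref_count + alt_count) * het_l,
       hom_alt = ref_count * mism_l + alt_count * match_l)
}

#' Genotype-likelihood matrix from a pileup
#'
#' @param pileup a [as_pileup()] / [simulate_pileups()] object.
#' @param e per-base error rate used in the likelihood model.
#' @return object of class `gl_matrix`: log-likelihood matrices `hom_ref`,
#'   `het`, `hom_alt` (sites x individuals), a `depth` matrix, and site
#'   metadata.
#' @export
gl_matrix <- function(pileup, e = 0.01) {
  stopifnot(inherits(pileup, "pileup"))
  gl <- gl_from_pileup(pileup$ref, pileup$alt, e)
  structure(list(chrom = pileup$chrom, pos = pileup$pos,
                 hom_ref = gl$hom_ref, het = gl$het, hom_alt = gl$hom_alt,
                 depth = pileup$ref + pileup$alt,
                 ref_reads = pileup$ref, alt_reads = pileup$alt,
                 ref_allele = pileup$ref_allele,
                 alt_allele = pileup$alt_allele,
                 individual = pileup$individual, pop = pileup$pop,
                 error_rate = e),
            class = "gl_matrix")
}

#' @export
print.gl_matrix <- function(x, ...) {
  cat(sprintf("gl_matrix: %d sites x %d individuals (e = %g)\n",
              nrow(x$depth), ncol(x$depth), x$error_rate))
  invisible(x)
}

# Vectorised EM for the alternate-allele frequency at every site.
# L* are log-likelihood matrices (sites x individuals); rows with no data
# return NA.  Returns list(f, n_ind, loglik, loglik0).
af_em_matrix <- function(hom_ref, het, hom_alt, depth,
                         tol = 1e-8, max_iter = 200, f_init = 0.25) {
  S <- nrow(depth); N <- ncol(depth)
  has <- depth > 0
  n_ind <- rowSums(has)
  # normalise triplets so exp() is stable; constant shifts cancel throughout
  M <- pmax(hom_ref, het, hom_alt)
  w0 <- exp(hom_ref - M); w1 <- exp(het - M); w2 <- exp(hom_alt - M)
  w0[!has] <- 0; w1[!has] <- 0; w2[!has] <- 0
  f <- rep(f_init, S)
  active <- which(n_ind > 0)
  f[n_ind == 0] <- NA_real_
  iter <- 0
  while (length(active) && iter < max_iter) {
    iter <- iter + 1
    fa <- f[active]
    p0 <- (1 - fa)^2; p1 <- 2 * fa * (1 - fa); p2 <- fa^2
    a0 <- w0[active, , drop = FALSE] * p0
    a1 <- w1[active, , drop = FALSE] * p1
    a2 <- w2[active, , drop = FALSE] * p2
    tot <- a0 + a1 + a2
    eg <- (a1 + 2 * a2) / tot
    eg[!has[active, , drop = FALSE]] <- 0
    fnew <- rowSums(eg) / (2 * n_ind[active])
    conv <- abs(fnew - fa) < tol
    f[active] <- fnew
    active <- active[!conv]
  }
  # log-likelihood at the MLE and at f = 0 (for the polymorphism LRT)
  p0 <- (1 - f)^2; p1 <- 2 * f * (1 - f); p2 <- f^2
  lik <- w0 * p0 + w1 * p1 + w2 * p2
  lik[!has] <- 1
  lik0 <- w0
  lik0[!has] <- 1
  list(f = f, n_ind = n_ind,
       loglik = rowSums(log(pmax(lik, 1e-300))),
       loglik0 = rowSums(log(pmax(lik0, 1e-300))))
}

#' Maximum-likelihood allele frequency for one site
#'
#' EM estimate of the alternate-allele frequency from the genotype
#' log-likelihoods of all individuals at a site, assuming Hardy-Weinberg
#' genotype proportions.  Individuals without data (zero depth) are ignored;
#' an all-missing site returns `NA`.
#'
#' @param hom_ref,het,hom_alt numeric vectors of log-likelihoods across
#'   individuals.
#' @param depth optional read depths (defaults treat a flat triplet as
#'   missing).
#' @param tol,max_iter,f_init EM convergence tolerance, iteration cap and
#'   starting frequency.
#' @return the ML alternate-allele frequency in `[0, 1]`.
#' @export
estimate_af_em <- function(hom_ref, het, hom_alt, depth = NULL,
                           tol = 1e-8, max_iter = 200, f_init = 0.25) {
  if (is.null(depth))
    depth <- as.integer(!(hom_ref == 0 & het == 0 & hom_alt == 0))
  res <- af_em_matrix(matrix(hom_ref, 1), matrix(het, 1),
                      matrix(hom_alt, 1), matrix(depth, 1),
                      tol = tol, max_iter = max_iter, f_init = f_init)
  unname(res$f)
}

# One-sided likelihood-ratio test for heterozygote excess at a site, using an
# inbreeding-parameterised genotype prior P(0) = (1-f)^2 + f(1-f)F,
# P(1) = 2f(1-f)(1-F), P(2) = f^2 + f(1-f)F with F in [-1, 1] (priors clipped
# at zero and renormalised).  Returns p = 1 unless the ML F is negative.
hwe_site <- function(w0, w1, w2, f) {
  if (is.na(f) || f <= 0 || f >= 1) return(1)
  ll <- function(F) {
    p0 <- pmax((1 - f)^2 + f * (1 - f) * F, 0)
    p1 <- pmax(2 * f * (1 - f) * (1 - F), 0)
    p2 <- pmax(f^2 + f * (1 - f) * F, 0)
    s <- p0 + p1 + p2
    sum(log(pmax(w0 * p0 / s + w1 * p1 / s + w2 * p2 / s, 1e-300)))
  }
  opt <- optimize(ll, c(-1, 1), maximum = TRUE, tol = 1e-7)
  if (opt$maximum >= 0) return(1)
  lambda <- 2 * (opt$objective - ll(0))
  if (lambda <= 0) return(1)
  pchisq(lambda, df = 1, lower.tail = FALSE)
}

#' Hardy-Weinberg (heterozygote-excess) test for one site
#'
#' @param hom_ref,het,hom_alt genotype log-likelihood vectors across
#'   individuals.
#' @param f the site's ML alternate-allele frequency.
#' @param depth optional depths; zero-depth individuals are dropped.
#' @return one-sided p-value; small values indicate heterozygote excess
#'   (paralog-collapse signature).  Monomorphic input gives 1.
#' @export
hwe_test <- function(hom_ref, het, hom_alt, f, depth = NULL) {
  if (is.null(depth))
    depth <- as.integer(!(hom_ref == 0 & het == 0 & hom_alt == 0))
  has <- depth > 0
  if (!any(has)) return(1)
  M <- pmax(hom_ref, het, hom_alt)
  hwe_site(exp(hom_ref - M)[has], exp(het - M)[has], exp(hom_alt - M)[has], f)
}

#' Site filter profiles
#'
#' The two filter profiles used throughout the analyses: `"population"`
#' retains maximum per-individual information (minimum 60 individuals with
#' data, total depth at most 500); `"genomic"` retains maximum genomic
#' information from a small balanced subset (minimum 15 individuals, total
#' depth at most 100).
#'
#' @param profile `"population"` or `"genomic"`.
#' @return list with `min_ind` and `max_depth`.
#' @export
filter_profile <- function(profile = c("population", "genomic")) {
  profile <- match.arg(profile)
  switch(profile,
         population = list(min_ind = 60L, max_depth = 500L),
         genomic = list(min_ind = 15L, max_depth = 100L))
}

#' Call polymorphic sites from genotype likelihoods
#'
#' Estimates per-site allele frequencies by EM, tests polymorphism with a
#' likelihood-ratio test of the ML frequency against `f = 0` (chi-square with
#' 1 df), and applies the minor-allele-frequency, individuals-with-data,
#' total-depth, and Hardy-Weinberg heterozygote-excess filters.
#'
#' @param gl a [gl_matrix()].
#' @param p_cut polymorphism p-value cutoff (default `1e-6`).
#' @param maf_min minimum minor-allele frequency (default 0.05).
#' @param min_ind minimum number of individuals with data.
#' @param max_depth maximum summed depth across individuals (repeat-region
#'   guard).
#' @param hwe_cut sites with heterozygote-excess p below this are removed
#'   (default 0.01).
#' @return a `variant_table` data.frame of retained sites with columns
#'   `chrom`, `pos` (0-based), `major`, `minor`, `ref`, `alt`, `af_alt`,
#'   `maf`, `n_ind`, `lrt_p`, `hwe_p`, and placeholder annotation columns
#'   `context`/`impact_class` (filled by [annotate_variants()] or
#'   [classify_variants()]).
#' @export
call_snps <- function(gl, p_cut = 1e-6, maf_min = 0.05,
                      min_ind = 1L, max_depth = Inf, hwe_cut = 0.01) {
  stopifnot(inherits(gl, "gl_matrix"), p_cut > 0, maf_min >= 0)
  N <- ncol(gl$depth)
  if (min_ind > N) stop("min_ind exceeds the number of individuals")
  em <- af_em_matrix(gl$hom_ref, gl$het, gl$hom_alt, gl$depth)
  lambda <- pmax(2 * (em$loglik - em$loglik0), 0)
  lrt_p <- pchisq(lambda, df = 1, lower.tail = FALSE)
  maf <- pmin(em$f, 1 - em$f)
  tot_depth <- rowSums(gl$depth)

  pass <- !is.na(em$f) & lrt_p < p_cut & maf >= maf_min &
    em$n_ind >= min_ind & tot_depth <= max_depth
  idx <- which(pass)
  hwe_p <- vapply(idx, function(s) {
    hwe_test(gl$hom_ref[s, ], gl$het[s, ], gl$hom_alt[s, ],
             em$f[s], gl$depth[s, ])
  }, numeric(1))
  keep <- hwe_p >= hwe_cut
  idx <- idx[keep]

  ref_al <- if (is.null(gl$ref_allele)) rep("R", length(gl$pos)) else gl$ref_allele
  alt_al <- if (is.null(gl$alt_allele)) rep("A", length(gl$pos)) else gl$alt_allele
  # major/minor by read-count plurality, lexicographic tie-break
  ref_tot <- rowSums(gl$ref_reads)[idx]
  alt_tot <- rowSums(gl$alt_reads)[idx]
  ref_major <- ref_tot > alt_tot |
    (ref_tot == alt_tot & ref_al[idx] <= alt_al[idx])
  out <- data.frame(
    chrom = rep(gl$chrom[1], length(idx)),
    pos = gl$pos[idx],
    ref = ref_al[idx],
    alt = alt_al[idx],
    major = ifelse(ref_major, ref_al[idx], alt_al[idx]),
    minor = ifelse(ref_major, alt_al[idx], ref_al[idx]),
    af_alt = em$f[idx],
    maf = maf[idx],
    n_ind = em$n_ind[idx],
    lrt_p = lrt_p[idx],
    hwe_p = hwe_p[keep],
    context = rep(NA_character_, length(idx)),
    impact_class = rep(NA_character_, length(idx)),
    stringsAsFactors = FALSE)
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Posterior genotype calls
#'
#' Calls each individual's genotype at each retained variant as the maximum
#' a-posteriori genotype under a Hardy-Weinberg prior built from the site's
#' ML alternate-allele frequency.  Individuals below `min_depth` at a site
#' (and flat likelihoods) are set missing.
#'
#' @param gl a [gl_matrix()].
#' @param variants a `variant_table` from [call_snps()].
#' @param min_depth minimum individual depth (default 5).
#' @return integer matrix (variants x individuals) of alternate-allele counts
#'   0/1/2 with `NA` for missing, with the variant positions as an attribute.
#' @export
call_genotypes <- function(gl, variants, min_depth = 5L) {
  stopifnot(inherits(gl, "gl_matrix"))
  m <- match(variants$pos, gl$pos)
  if (anyNA(m)) stop("variants not present in the GL matrix")
  f <- variants$af_alt
  l0 <- gl$hom_ref[m, , drop = FALSE]
  l1 <- gl$het[m, , drop = FALSE]
  l2 <- gl$hom_alt[m, , drop = FALSE]
  post0 <- l0 + log((1 - f)^2)
  post1 <- l1 + log(2 * f * (1 - f))
  post2 <- l2 + log(f^2)
  geno <- max.col(cbind(as.vector(post0), as.vector(post1),
                        as.vector(post2)), ties.method = "first") - 1L
  geno <- matrix(geno, nrow(post0), ncol(post0))
  dep <- gl$depth[m, , drop = FALSE]
  geno[dep < min_depth | dep == 0L] <- NA_integer_   # flat GL is never called
  colnames(geno) <- gl$individual
  attr(geno, "pos") <- variants$pos
  attr(geno, "chrom") <- variants$chrom
  geno
}
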