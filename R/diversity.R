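#' Folded site frequency spectrum with bootstraps
#'
#' Tabulates the minor-allele-count spectrum from called genotypes (or a
#' haplotype matrix) and attaches 100 site-resampling bootstrap replicates;
#' the bootstrap mean spectrum is the point estimate used downstream.
#'
#' @param geno integer matrix (sites x individuals) of alternate-allele
#'   counts 0/1/2 (`NA` allowed), or a binary haplotype matrix
#'   (sites x chromosomes) when `haplotypes = TRUE`.
#' @param n_boot number of site bootstraps (default 100).
#' @param haplotypes interpret `geno` as a haplotype matrix.
#' @param mask optional logical vector of sites to keep (e.g. a genic mask)
#'   applied before the spectrum is formed.
#' @return object of class `sfs`: `spectrum` (counts indexed 0..n/2),
#'   `boot` matrix of replicates, `boot_mean`, `n_chrom`, `L`.
#' @export
folded_sfs <- function(geno, n_boot = 100, haplotypes = FALSE, mask = NULL) {
  if (!is.null(mask)) geno <- geno[mask, , drop = FALSE]
  n_chrom <- if (haplotypes) ncol(geno) else 2L * ncol(geno)
  if (n_chrom < 4 && !haplotypes)
    stop("folded_sfs needs at least two individuals")
  alt <- rowSums(geno, na.rm = TRUE)
  n_called <- if (haplotypes) rowSums(!is.na(geno))
              else 2L * rowSums(!is.na(geno))
  # fold against the called chromosome count at each site
  minor <- pmin(alt, n_called - alt)
  # project onto the full spectrum length for indexing
  kmax <- n_chrom %/% 2L
  spectrum <- tabulate(minor + 1L, nbins = kmax + 1L)
  names(spectrum) <- 0:kmax
  S <- nrow(geno)
  boot <- matrix(0, n_boot, kmax + 1L)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(S, S, replace = TRUE)
    boot[b, ] <- tabulate(minor[idx] + 1L, nbins = kmax + 1L)
  }
  structure(list(spectrum = spectrum,
                 boot = boot,
                 boot_mean = colMeans(boot),
                 n_chrom = n_chrom,
                 L = S), class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat(sprintf("folded SFS: n_chrom = %d, %d sites\n", x$n_chrom, x$L))
  print(x$spectrum)
  invisible(x)
}

#' Watterson's theta per site
#'
#' `theta_W = S / (a_n * L)` with `a_n = sum_{i=1}^{n-1} 1/i`.
#'
#' @param S number of segregating sites.
#' @param n_chrom number of chromosomes sampled (2 x individuals).
#' @param L number of sites surveyed.
#' @return per-site Watterson's theta.
#' @export
#' @examples
#' watterson_theta(11, 10, 1000)
watterson_theta <- function(S, n_chrom, L) {
  stopifnot(n_chrom >= 2, L > 0, S >= 0)
  S / (harmonic(n_chrom - 1L) * L)
}

#' @rdname watterson_theta
#' @param n upper limit of the harmonic sum.
#' @export
harmonic <- function(n) sum(1 / seq_len(n))

#' Per-individual heterozygosity
#'
#' Proportion of an individual's genotyped sites that are heterozygous.
#'
#' @param geno genotype matrix (sites x individuals), 0/1/2 with `NA`.
#' @param L optional total sites surveyed per individual (defaults to the
#'   number of genotyped sites, i.e. heterozygous fraction of variable
#'   genotyped sites; pass the monomorphic-inclusive total to get a per-bp
#'   rate).
#' @return named numeric vector of heterozygosities, `NA` where an individual
#'   has no genotyped site.
#' @export
heterozygosity_per_individual <- function(geno, L = NULL) {
  het <- colSums(geno == 1L, na.rm = TRUE)
  n <- if (is.null(L)) colSums(!is.na(geno)) else rep(L, ncol(geno))
  out <- ifelse(n > 0, het / n, NA_real_)
  names(out) <- colnames(geno)
  out
}

#' Mutation rate from interspecific divergence
#'
#' `mu = (mismatches / valid length) / (2 * t)`: alignment columns where
#' either sequence has an N/n or a gap are excluded from both numerator and
#' denominator.
#'
#' @param seq_a,seq_b aligned sequences (character scalars or vectors of
#'   single characters, same length).
#' @param t_div divergence time in years.
#' @return per-site per-year mutation rate.
#' @export
#' @examples
#' mutation_rate_from_divergence(strrep("A", 100), strrep("A", 100), 3.5e7)
mutation_rate_from_divergence <- function(seq_a, seq_b, t_div) {
  stopifnot(t_div > 0)
  a <- toupper(split_chars(seq_a))
  b <- toupper(split_chars(seq_b))
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
  valid <- !(a %in% c("N", "-")) & !(b %in% c("N", "-"))
  n_valid <- sum(valid)
  if (n_valid == 0) stop("no valid aligned sites")
  mism <- sum(a[valid] != b[valid])
  (mism / n_valid) / (2 * t_div)
}

#' Effective population size from Watterson's theta
#'
#' `Ne = theta_W / (4 * mu * gen_per_year)`; with the default
#' `gen_per_year = 1` this reproduces the literal `theta = 4 Ne mu`
#' arithmetic with a per-year mutation rate.  A standard error on `theta_W`
#' propagates to a 95% CI.
#'
#' @param theta_w per-site Watterson's theta.
#' @param mu per-site per-year mutation rate (> 0).
#' @param theta_se optional standard error of `theta_w`.
#' @param gen_per_year generations per year (default 1).
#' @return list with `Ne` and (when `theta_se` is given) `ci` (95%).
#' @export
#' @examples
#' ne_from_theta(5.37e-4, 3.14e-9)$Ne
ne_from_theta <- function(theta_w, mu, theta_se = NULL, gen_per_year = 1) {
  stopifnot(mu > 0, theta_w >= 0, gen_per_year > 0)
  denom <- 4 * mu * gen_per_year
  out <- list(Ne = theta_w / denom)
  if (!is.null(theta_se))
    out$ci <- c(theta_w - 1.96 * theta_se, theta_w + 1.96 * theta_se) / denom
  out
}

# split a character scalar into single characters; pass vectors through
split_chars <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) strsplit(x, "")[[1]] else as.character(x)
}
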