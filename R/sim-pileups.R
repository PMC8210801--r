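#' Simulate low-coverage read pileups
#'
#' Generates per-site, per-individual counts of reads supporting the ancestral
#' (reference) and derived (alternate) allele.  Depth is Poisson with mean
#' `config$mean_depth`; each read is drawn from one of the individual's two
#' true alleles at random and reports the site's other allele with probability
#' `config$error_rate` (the biallelic collapse of the per-base `e/3` model).
#'
#' @param truth a [simulate_populations()] result.
#' @param config the [sim_config()] used to generate `truth` (supplies
#'   `mean_depth` and `error_rate`).
#' @return an object of class `pileup`: list with integer matrices `ref` and
#'   `alt` (sites x individuals), plus site metadata carried over from
#'   `truth`.
#' @export
simulate_pileups <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  if (config$mean_depth < 0) stop("mean_depth must be >= 0")
  g <- truth$true_genotypes
  S <- nrow(g); N <- ncol(g)
  depth <- matrix(rpois(S * N, config$mean_depth), S, N)
  e <- config$error_rate
  # P(read reports alt | genotype g) = (g/2)(1-e) + (1-g/2) e
  p_alt <- (g / 2) * (1 - e) + (1 - g / 2) * e
  alt <- matrix(rbinom(S * N, depth, p_alt), S, N)
  structure(list(chrom = truth$chrom,
                 pos = truth$pos,
                 ref = depth - alt,
                 alt = alt,
                 ref_allele = truth$ancestral_allele,
                 alt_allele = truth$alt_allele,
                 individual = truth$individual,
                 pop = truth$pop),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("pileup: %d sites x %d individuals, mean depth %.2f\n",
              nrow(x$ref), ncol(x$ref), mean(x$ref + x$alt)))
  invisible(x)
}

#' Construct a pileup object from count matrices
#'
#' Low-level constructor used by the file readers and tests.
#'
#' @param ref,alt integer matrices (sites x individuals) of reads supporting
#'   the reference and alternate allele.
#' @param pos 0-based positions; defaults to `0:(nrow(ref)-1)`.
#' @param chrom chromosome name.
#' @param individual individual ids.
#' @param pop optional population labels.
#' @return a `pileup` object.
#' @export
as_pileup <- function(ref, alt, pos = seq_len(nrow(ref)) - 1L,
                      chrom = "chr1",
                      individual = sprintf("ind%02d", seq_len(ncol(ref))),
                      pop = NULL) {
  stopifnot(all(dim(ref) == dim(alt)), all(ref >= 0), all(alt >= 0))
  structure(list(chrom = chrom, pos = as.integer(pos),
                 ref = ref, alt = alt,
                 ref_allele = NULL, alt_allele = NULL,
                 individual = individual, pop = pop),
            class = "pileup")
}
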