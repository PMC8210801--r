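#' Simulation configuration
#'
#' Builds and validates the configuration for the forward Wright-Fisher
#' simulator.  Defaults describe the demographic contrast the package's
#' analyses are calibrated on: a large outbred population and a much smaller
#' partially selfing population that split from a common ancestor, with genes
#' carrying deleterious mutations in three coding impact classes (HIGH,
#' MODERATE, LOW) plus neutral MODIFIER mutations elsewhere.
#'
#' @param n_pops number of extant populations (1--3).
#' @param pop_sizes integer vector of diploid census sizes, one per population.
#'   The first entry is also the ancestral size during burn-in.
#' @param split_gens generations elapsed since the populations split from the
#'   ancestral population (ignored when `n_pops == 1`).
#' @param selfing_rates per-population probability in `[0, 1]` that an
#'   offspring is produced by self-fertilisation.
#' @param seq_length total simulated sequence length in bp.
#' @param n_genes number of non-overlapping genes placed on the sequence.
#' @param gene_length coding length (CDS, bp) of each gene; must be a multiple
#'   of 3.
#' @param mu_sim per-site per-generation mutation rate.
#' @param class_probs named numeric, probability that a new coding mutation is
#'   `high`, `moderate` or `low` impact; must sum to 1.
#' @param sel_coeffs named numeric, selection coefficient `s` per impact class
#'   (`modifier` is forced to 0); all in `[0, 1]`.
#' @param dominance_h named numeric, dominance coefficient `h` per class, in
#'   `[0, 1]`.
#' @param mean_depth expected per-individual sequencing depth for simulated
#'   read pileups.
#' @param error_rate per-base sequencing error rate `e`.
#' @param n_sample individuals sampled per population at the end of the
#'   simulation.
#' @param init `"coalescent"` seeds the ancestral population from a neutral
#'   coalescent draw followed by a selection-equilibration burn-in;
#'   `"monomorphic"` starts from an invariant sequence and burns in for
#'   `10 * N` generations.
#' @param burnin_gens forward burn-in generations before the split; `NULL`
#'   picks the default for `init` (`0.5 * N` for coalescent initialisation,
#'   `10 * N` for monomorphic).
#' @param seed integer RNG seed; identical seeds give identical simulations.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_pops = 2,
                       pop_sizes = c(1000, 50),
                       split_gens = 200,
                       selfing_rates = c(0, 0.3),
                       seq_length = 850000,
                       n_genes = 90,
                       gene_length = 3000,
                       mu_sim = 1.5e-7,
                       class_probs = c(high = 0.05, moderate = 0.70, low = 0.25),
                       sel_coeffs = c(high = 0.3, moderate = 0.02, low = 0.002,
                                      modifier = 0),
                       dominance_h = c(high = 0, moderate = 0.25, low = 0.5,
                                       modifier = 0.5),
                       mean_depth = 20,
                       error_rate = 0.01,
                       n_sample = 7,
                       init = c("coalescent", "monomorphic"),
                       burnin_gens = NULL,
                       seed = 1L) {
  init <- match.arg(init)
  if (missing(pop_sizes)) pop_sizes <- rep_len(pop_sizes, n_pops)
  if (missing(selfing_rates)) selfing_rates <- rep_len(selfing_rates, n_pops)
  stopifnot(n_pops >= 1, n_pops <= 3,
            length(pop_sizes) == n_pops,
            all(pop_sizes >= 2),
            length(selfing_rates) == n_pops,
            all(selfing_rates >= 0 & selfing_rates <= 1),
            seq_length > 0, n_genes >= 0, gene_length > 0,
            mu_sim >= 0, mean_depth >= 0,
            error_rate >= 0, error_rate < 0.75,
            n_sample >= 1, all(n_sample <= pop_sizes))
  if (n_pops > 1) stopifnot(length(split_gens) == 1, split_gens >= 1)
  if (gene_length %% 3 != 0)
    stop("gene_length must be a multiple of 3")
  cls <- c("high", "moderate", "low")
  class_probs <- class_probs[cls]
  if (anyNA(class_probs) || abs(sum(class_probs) - 1) > 1e-8)
    stop("class_probs must be named {high, moderate, low} and sum to 1")
  full <- c(cls, "modifier")
  sel_coeffs <- sel_coeffs[full]
  dominance_h <- dominance_h[full]
  if (anyNA(sel_coeffs) || anyNA(dominance_h))
    stop("sel_coeffs and dominance_h must name all of high/moderate/low/modifier")
  if (any(sel_coeffs < 0) || any(sel_coeffs > 1))
    stop("selection coefficients must be in [0, 1]")
  if (any(dominance_h < 0) || any(dominance_h > 1))
    stop("dominance coefficients must be in [0, 1]")
  sel_coeffs["modifier"] <- 0
  if (is.null(burnin_gens))
    burnin_gens <- if (init == "coalescent") ceiling(0.5 * pop_sizes[1])
                   else 10L * pop_sizes[1]
  structure(list(n_pops = as.integer(n_pops),
                 pop_sizes = as.integer(pop_sizes),
                 split_gens = as.integer(split_gens),
                 selfing_rates = as.numeric(selfing_rates),
                 seq_length = as.integer(seq_length),
                 n_genes = as.integer(n_genes),
                 gene_length = as.integer(gene_length),
                 mu_sim = mu_sim,
                 class_probs = class_probs,
                 sel_coeffs = sel_coeffs,
                 dominance_h = dominance_h,
                 mean_depth = mean_depth,
                 error_rate = error_rate,
                 n_sample = as.integer(n_sample),
                 init = init,
                 burnin_gens = as.integer(burnin_gens),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Wright-Fisher simulation config\n")
  cat(sprintf("  populations : %d (2N = %s; selfing = %s)\n", x$n_pops,
              paste(2L * x$pop_sizes, collapse = ", "),
              paste(x$selfing_rates, collapse = ", ")))
  if (x$n_pops > 1) cat(sprintf("  split       : %d generations ago\n", x$split_gens))
  cat(sprintf("  sequence    : %d bp, %d genes x %d bp CDS\n",
              x$seq_length, x$n_genes, x$gene_length))
  cat(sprintf("  mutation    : mu = %g /site/gen; coding DFE P(H,M,L) = %s\n",
              x$mu_sim, paste(x$class_probs, collapse = "/")))
  cat(sprintf("  reads       : %gx mean depth, error %g\n", x$mean_depth, x$error_rate))
  cat(sprintf("  init        : %s, burn-in %d generations, seed %d\n",
              x$init, x$burnin_gens, x$seed))
  invisible(x)
}
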