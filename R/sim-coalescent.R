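#' Neutral coalescent haplotypes
#'
#' Samples `n` haplotypes at an unlinked locus under the standard neutral
#' coalescent, optionally with a piecewise-constant population-size history.
#' Used to seed the forward simulator at equilibrium and as an independent
#' generator for estimator calibration.
#'
#' @param n number of haplotypes (chromosomes).
#' @param theta locus-wide scaled mutation rate `4*N*mu*L`.
#' @param epochs optional `data.frame(time, size)` of epoch boundaries: from
#'   scaled time `time[i]` (units of `2N0` generations, looking backwards)
#'   the relative population size is `size[i]`.  The first row must have
#'   `time = 0`; default is a single epoch of size 1.
#' @return integer matrix (segregating sites x `n`) of derived-allele
#'   indicators.  May have zero rows.
#' @export
#' @examples
#' set.seed(1)
#' h <- coalescent_haplotypes(10, theta = 5)
#' dim(h)
coalescent_haplotypes <- function(n, theta, epochs = NULL) {
  stopifnot(n >= 2, theta >= 0)
  if (is.null(epochs)) epochs <- data.frame(time = 0, size = 1)
  stopifnot(epochs$time[1] == 0, all(diff(epochs$time) > 0),
            all(epochs$size > 0))

  n_nodes <- 2L * n - 1L
  time <- numeric(n_nodes)
  child1 <- integer(n_nodes); child2 <- integer(n_nodes)
  active <- seq_len(n)
  nxt <- n + 1L
  t <- 0
  ep <- 1L
  k <- n
  while (k > 1L) {
    rate <- k * (k - 1) / 2 / epochs$size[ep]
    dt <- stats::rexp(1, rate)
    boundary <- if (ep < nrow(epochs)) epochs$time[ep + 1L] else Inf
    if (t + dt > boundary) { t <- boundary; ep <- ep + 1L; next }
    t <- t + dt
    pick <- sample.int(k, 2L)
    a <- active[pick[1L]]; b <- active[pick[2L]]
    time[nxt] <- t; child1[nxt] <- a; child2[nxt] <- b
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
    k <- k - 1L
  }

  parent_time <- numeric(n_nodes)
  for (v in seq.int(n + 1L, n_nodes)) {
    parent_time[child1[v]] <- time[v]
    parent_time[child2[v]] <- time[v]
  }
  blen <- parent_time - time
  blen[n_nodes] <- 0   # root
  total <- sum(blen)
  S <- rpois(1, theta / 2 * total)
  if (S == 0) return(matrix(0L, 0, n))

  # leaf sets, built in creation order (children always precede parents)
  leaves <- vector("list", n_nodes)
  for (v in seq_len(n)) leaves[[v]] <- v
  for (v in seq.int(n + 1L, n_nodes))
    leaves[[v]] <- c(leaves[[child1[v]]], leaves[[child2[v]]])

  branch <- sample.int(n_nodes, S, replace = TRUE, prob = blen)
  mat <- matrix(0L, S, n)
  for (i in seq_len(S)) mat[i, leaves[[branch[i]]]] <- 1L
  mat
}

#' Pedigree genotype pairs for kinship calibration
#'
#' Gene-drops a two-individual pedigree relationship through unlinked sites
#' with known allele frequencies, producing called-genotype vectors (0/1/2
#' alternate-allele counts) for the pair.  Founders are drawn from
#' Hardy-Weinberg proportions.
#'
#' @param relationship one of `"self"`, `"parent-offspring"`, `"full-sib"`,
#'   `"half-sib"`, `"first-cousin"`, `"unrelated"`.
#' @param n_sites number of unlinked sites.
#' @param maf_range range from which each site's allele frequency is drawn
#'   uniformly.
#' @return list with genotype vectors `g1`, `g2` and the frequencies `f`.
#' @export
sim_pedigree_pair <- function(relationship = c("unrelated", "parent-offspring",
                                               "full-sib", "half-sib",
                                               "first-cousin", "self"),
                              n_sites = 50000,
                              maf_range = c(0.05, 0.5)) {
  relationship <- match.arg(relationship)
  f <- runif(n_sites, maf_range[1], maf_range[2])
  hap <- function() rbinom(n_sites, 1L, f)
  founder <- function() hap() + hap()
  gamete <- function(g) {               # transmitted allele from genotype
    ifelse(g == 1L, rbinom(n_sites, 1L, 0.5), g / 2L)
  }
  child <- function(gm, gf) gamete(gm) + gamete(gf)
  switch(relationship,
    "self" = { g <- founder(); list(g1 = g, g2 = g, f = f) },
    "unrelated" = list(g1 = founder(), g2 = founder(), f = f),
    "parent-offspring" = {
      p <- founder()
      list(g1 = p, g2 = child(p, founder()), f = f)
    },
    "full-sib" = {
      m <- founder(); fa <- founder()
      list(g1 = child(m, fa), g2 = child(m, fa), f = f)
    },
    "half-sib" = {
      m <- founder()
      list(g1 = child(m, founder()), g2 = child(m, founder()), f = f)
    },
    "first-cousin" = {
      gm <- founder(); gf <- founder()
      s1 <- child(gm, gf); s2 <- child(gm, gf)   # sibling parents
      list(g1 = child(s1, founder()), g2 = child(s2, founder()), f = f)
    })
}
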