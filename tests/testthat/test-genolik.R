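test_that("genotype likelihoods follow the read-error model", {
  # no reads: flat triplet
  fl <- gl_from_pileup(0, 0, 0.01)
  expect_equal(unlist(fl), c(hom_ref = 0, het = 0, hom_alt = 0))
  # 4 reference reads at e = 0.01
  gl <- gl_from_pileup(4, 0, 0.01)
  expect_equal(gl$hom_ref, 4 * log(0.99))
  expect_equal(gl$het, 4 * log((0.99 + 0.01 / 3) / 2))
  expect_equal(gl$hom_alt, 4 * log(0.01 / 3))
  expect_equal(round(c(gl$hom_ref, gl$het, gl$hom_alt), 4),
               c(-0.0402, -2.7993, -22.8151))
  # balanced reads: het strictly most likely
  gb <- gl_from_pileup(3, 3, 0.01)
  expect_gt(gb$het, gb$hom_ref)
  expect_gt(gb$het, gb$hom_alt)
})

test_that("the EM allele frequency matches trivial cases and a grid-search oracle", {
  e <- 0.01
  # all individuals certainly hom-ref
  g0 <- gl_from_pileup(rep(30, 8), rep(0, 8), e)
  expect_equal(estimate_af_em(g0$hom_ref, g0$het, g0$hom_alt), 0,
               tolerance = 1e-6)
  # all individuals certainly het
  gh <- gl_from_pileup(rep(15, 8), rep(15, 8), e)
  expect_equal(estimate_af_em(gh$hom_ref, gh$het, gh$hom_alt), 0.5,
               tolerance = 1e-4)
  # random 6-individual columns vs brute-force grid maximisation
  set.seed(42)
  grid <- seq(0, 1, by = 1e-4)
  for (rep in 1:20) {
    ref <- rpois(6, 4); alt <- rpois(6, 2)
    gl <- gl_from_pileup(ref, alt, e)
    fhat <- estimate_af_em(gl$hom_ref, gl$het, gl$hom_alt,
                           depth = ref + alt)
    ll <- vapply(grid, function(f) {
      sum(log((1 - f)^2 * exp(gl$hom_ref) + 2 * f * (1 - f) * exp(gl$het) +
                f^2 * exp(gl$hom_alt))[ref + alt > 0])
    }, numeric(1))
    expect_lt(abs(fhat - grid[which.max(ll)]), 1e-3)
  }
})

test_that("the EM is invariant to shifting a log-likelihood triplet", {
  set.seed(1)
  ref <- rpois(10, 5); alt <- rpois(10, 3)
  gl <- gl_from_pileup(ref, alt, 0.01)
  f1 <- estimate_af_em(gl$hom_ref, gl$het, gl$hom_alt, depth = ref + alt)
  shift <- c(5, rep(0, 9))
  f2 <- estimate_af_em(gl$hom_ref + shift, gl$het + shift,
                       gl$hom_alt + shift, depth = ref + alt)
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("SNP calling applies the polymorphism, MAF, coverage and HWE filters", {
  set.seed(9)
  N <- 30
  # truth: 60 sites at f = 0.3, 60 monomorphic
  f <- c(rep(0.3, 60), rep(0, 60))
  geno <- t(sapply(f, function(p) rbinom(N, 2, p)))
  gl <- gl_from_genotypes(geno, depth = 20)
  v <- call_snps(gl, min_ind = 25)
  expect_true(all(v$pos %in% (0:59)))          # no monomorphic site called
  expect_gt(nrow(v), 40)                       # most true SNPs recovered
  expect_lt(abs(mean(v$maf) - 0.3), 0.03)
  expect_lt(max(abs(v$maf - 0.3)), 0.25)
  expect_true(all(v$n_ind >= 25 & v$hwe_p >= 0.01 & v$lrt_p < 1e-6))

  # a clear SNP with data in min_ind - 1 individuals is dropped
  geno2 <- matrix(1L, 5, N)
  pile <- simulate_pileups(fake_truth(geno2), list(mean_depth = 20,
                                                   error_rate = 0.01))
  pile$ref[, 1:6] <- 0L; pile$alt[, 1:6] <- 0L    # 24 individuals with data
  gl2 <- gl_matrix(pile, e = 0.01)
  expect_equal(nrow(call_snps(gl2, min_ind = 25)), 0)
  expect_gt(nrow(call_snps(gl2, min_ind = 24, hwe_cut = 0)), 0)

  # summed-depth ceiling drops repeat-like sites
  expect_equal(nrow(call_snps(gl2, min_ind = 10, max_depth = 100,
                              hwe_cut = 0)), 0)
  expect_error(call_snps(gl, min_ind = N + 1), "min_ind")
})

test_that("the heterozygote-excess test removes collapsed paralogs", {
  e <- 0.01
  # genotype counts at exact HWE proportions: p ~ 1
  n_g <- c(25, 50, 25)
  geno <- rep(0:2, n_g)
  gl <- gl_from_pileup(ifelse(geno == 2, 0, 20) - ifelse(geno == 1, 10, 0),
                       ifelse(geno == 0, 0, 20) - ifelse(geno == 1, 10, 0), e)
  p_hwe <- hwe_test(gl$hom_ref, gl$het, gl$hom_alt, f = 0.5)
  expect_gt(p_hwe, 0.5)
  # every individual het at f = 0.5, N = 50: strong excess
  gh <- gl_from_pileup(rep(10, 50), rep(10, 50), e)
  expect_lt(hwe_test(gh$hom_ref, gh$het, gh$hom_alt, f = 0.5), 0.01)
  # monomorphic input
  expect_equal(hwe_test(rep(0, 5), rep(0, 5), rep(0, 5), f = 0), 1)

  # simulated paralog collapse: every individual looks het at 2x20x
  set.seed(12)
  removed <- 0
  for (s in 1:100) {
    ref <- rbinom(50, 40, 0.5); alt <- 40 - ref
    gl <- gl_from_pileup(ref, alt, e)
    f <- estimate_af_em(gl$hom_ref, gl$het, gl$hom_alt, depth = ref + alt)
    p <- hwe_test(gl$hom_ref, gl$het, gl$hom_alt, f, depth = ref + alt)
    if (p < 0.01) removed <- removed + 1
  }
  expect_gte(removed, 90)
})

test_that("posterior genotype calls respect the depth threshold and recover truth", {
  set.seed(31)
  N <- 25
  geno <- t(sapply(runif(300, 0.1, 0.5), function(p) rbinom(N, 2, p)))
  gl <- gl_from_genotypes(geno, depth = 20)
  v <- call_snps(gl, min_ind = 20)
  called <- call_genotypes(gl, v, min_depth = 5)
  m <- match(v$pos, 0:(nrow(geno) - 1))
  truth_called <- geno[m, ]
  ok <- !is.na(called)
  expect_gt(mean(called[ok] == truth_called[ok]), 0.99)
  # depth below threshold is missing regardless of signal
  gl$depth[1, 1] <- 4L
  called2 <- call_genotypes(gl, v, min_depth = 5)
  if (v$pos[1] == 0) expect_true(is.na(called2[1, 1]))
  # flat likelihoods (no reads) are missing
  pile0 <- as_pileup(matrix(0L, 1, N), matrix(0L, 1, N))
  gl0 <- gl_matrix(pile0)
  v0 <- v[1, ]; v0$pos <- 0L
  expect_true(all(is.na(call_genotypes(gl0, v0, min_depth = 0))))
})

test_that("mean called MAF is unbiased across true frequencies", {
  set.seed(55)
  N <- 30
  for (f in c(0.1, 0.25, 0.4)) {
    geno <- t(sapply(rep(f, 400), function(p) rbinom(N, 2, p)))
    gl <- gl_from_genotypes(geno, depth = 10)
    v <- call_snps(gl, min_ind = 25)
    se <- sd(v$maf) / sqrt(nrow(v))
    expect_lt(abs(mean(v$maf) - f), 2 * se + 0.01)
  }
})

test_that("the polymorphism LRT has the stated type-I error control", {
  # 1e6 monomorphic sites at ~2x in 6 individuals: <= 5 false calls at 1e-6
  set.seed(314)
  S <- 1e6; N <- 6
  depth <- matrix(rpois(S * N, 20), S, N)
  alt <- matrix(rbinom(S * N, depth, 0.01), S, N)   # sequencing errors only
  gl <- gl_matrix(as_pileup(depth - alt, alt), e = 0.01)
  em <- genload:::af_em_matrix(gl$hom_ref, gl$het, gl$hom_alt, gl$depth)
  lambda <- pmax(2 * (em$loglik - em$loglik0), 0)
  p <- pchisq(lambda, 1, lower.tail = FALSE)
  expect_lte(sum(p < 1e-6, na.rm = TRUE), 5)
})
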