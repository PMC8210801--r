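test_that("self-comparison gives kinship one half", {
  set.seed(1)
  g <- rbinom(500, 2, 0.3)
  r <- pair_ibs_stats(g, g, min_sites = 100)
  expect_equal(r$king, 0.5)
  expect_equal(r$R0, 0)
  expect_equal(r$degree, "identical/self")
  expect_false(r$filtered)                      # 500 >= the 100-site floor
  expect_true(pair_ibs_stats(g, g)$filtered)    # default floor is 100,000
})

test_that("kinship degree bins follow the powers-of-two thresholds", {
  expect_equal(classify_degree(c(0.5, 0.25, 0.13, 0.06, 0.01)),
               c("identical/self", "1st", "2nd", "3rd", "unrelated"))
  expect_true(is.na(classify_degree(NA_real_)))
})

test_that("pedigree pairs produce the expected kinship and R0", {
  set.seed(21)
  po <- replicate(8, {
    p <- sim_pedigree_pair("parent-offspring", n_sites = 20000)
    unlist(pair_ibs_stats(p$g1, p$g2, min_sites = 1)[c("king", "R0")])
  })
  expect_gt(mean(po["king", ]), 0.20)
  expect_lt(mean(po["king", ]), 0.30)
  expect_lt(mean(po["R0", ]), 0.005)
  un <- replicate(8, {
    p <- sim_pedigree_pair("unrelated", n_sites = 20000)
    pair_ibs_stats(p$g1, p$g2, min_sites = 1)$king
  })
  expect_lt(abs(mean(un)), 0.02)
})

test_that("kinship ranks relationships in the expected order", {
  set.seed(33)
  rels <- c("self", "full-sib", "parent-offspring", "half-sib",
            "first-cousin", "unrelated")
  means <- sapply(rels, function(r) {
    mean(replicate(25, {
      p <- sim_pedigree_pair(r, n_sites = 3000)
      pair_ibs_stats(p$g1, p$g2, min_sites = 1)$king
    }))
  })
  expect_gt(means["self"], means["full-sib"])
  expect_lt(abs(means["full-sib"] - means["parent-offspring"]), 0.05)
  expect_gt(means["parent-offspring"], means["half-sib"])
  expect_gt(means["half-sib"], means["first-cousin"])
  expect_gt(means["first-cousin"], means["unrelated"])
})

test_that("kinship is invariant to relabeling alleles at any subset of sites", {
  set.seed(44)
  p <- sim_pedigree_pair("full-sib", n_sites = 5000)
  k1 <- pair_ibs_stats(p$g1, p$g2, min_sites = 1)$king
  flip <- sample(c(TRUE, FALSE), 5000, replace = TRUE)
  g1 <- ifelse(flip, 2L - p$g1, p$g1)
  g2 <- ifelse(flip, 2L - p$g2, p$g2)
  expect_equal(pair_ibs_stats(g1, g2, min_sites = 1)$king, k1)
})

test_that("inbreeding ML hits the boundaries and the HWE null", {
  # certain heterozygote at every f = 0.5 site: maximal het excess, F = -1
  ref <- matrix(15L, 300, 1); alt <- matrix(15L, 300, 1)
  gl <- gl_matrix(as_pileup(ref, alt), e = 0.01)
  v <- data.frame(pos = 0:299, af_alt = 0.5)
  fi <- individual_F(gl, v, min_sites = 100)
  expect_equal(fi$F, -1)
  expect_true(fi$converged)

  # genotypes drawn at HWE: |F| small
  set.seed(10)
  f <- runif(20000, 0.1, 0.5)
  geno <- matrix(rbinom(20000, 2, f), ncol = 1)
  glh <- gl_from_genotypes(geno, depth = 20)
  vh <- data.frame(pos = 0:19999, af_alt = f)
  fih <- individual_F(glh, vh)
  expect_lt(abs(fih$F), 0.02)

  # one selfing generation from outbred parents: F near 0.5
  set.seed(11)
  fs <- runif(30000, 0.1, 0.5)
  parent <- rbinom(30000, 2, fs)
  gam <- function(g) ifelse(g == 1L, rbinom(length(g), 1, 0.5), g / 2L)
  child <- matrix(as.integer(gam(parent) + gam(parent)), ncol = 1)
  glc <- gl_from_genotypes(child, depth = 20)
  fic <- individual_F(glc, data.frame(pos = 0:29999, af_alt = fs))
  expect_lt(abs(fic$F - 0.5), 0.1)

  # too few sites: flagged, not estimated
  few <- individual_F(gl_matrix(as_pileup(ref[1:10, , drop = FALSE],
                                          alt[1:10, , drop = FALSE])),
                      data.frame(pos = 0:9, af_alt = 0.5), min_sites = 100)
  expect_true(is.na(few$F))
})

test_that("F estimates track the pedigree truth and rise with the selfing rate", {
  set.seed(66)
  alphas <- c(0, 0.2, 0.5, 0.8, 1.0)
  res <- lapply(alphas, function(alpha) {
    cfg <- sim_config(n_pops = 1, pop_sizes = 150, selfing_rates = alpha,
                      seq_length = 250000, n_genes = 0, mu_sim = 5e-7,
                      n_sample = 40, seed = round(alpha * 100) + 7,
                      burnin_gens = 75)
    truth <- simulate_populations(cfg)
    pile <- simulate_pileups(truth, cfg)
    gl <- gl_matrix(pile, e = cfg$error_rate)
    v <- call_snps(gl, min_ind = 30, maf_min = 0.01)
    fi <- individual_F(gl, v, min_sites = 50)
    list(alpha = alpha, fhat = fi$F, truef = truth$true_F)
  })
  # calibration: mean estimate close to the sample's realized pedigree F
  for (r in res)
    expect_lt(abs(mean(r$fhat, na.rm = TRUE) - mean(r$truef)), 0.1)
  # monotone trend over individuals
  a <- unlist(lapply(res, function(r) rep(r$alpha, length(r$fhat))))
  fh <- unlist(lapply(res, `[[`, "fhat"))
  ct <- cor.test(a, fh, method = "spearman", exact = FALSE)
  expect_gt(ct$estimate, 0.5)
  expect_lt(ct$p.value, 1e-6)
})

test_that("covariance PCA separates diverged populations and is well formed", {
  set.seed(77)
  # Balding-Nichols draw at Fst ~ 0.13
  Fst <- 0.13
  p0 <- runif(800, 0.2, 0.8)
  shape <- (1 - Fst) / Fst
  pA <- rbeta(800, p0 * shape, (1 - p0) * shape)
  pB <- rbeta(800, p0 * shape, (1 - p0) * shape)
  gA <- sapply(1:12, function(i) rbinom(800, 2, pA))
  gB <- sapply(1:12, function(i) rbinom(800, 2, pB))
  geno <- cbind(gA, gB)
  pca <- covariance_pca(geno)
  pc1 <- pca$scores[, 1]
  expect_true(max(pc1[1:12]) < min(pc1[13:24]) ||
                min(pc1[1:12]) > max(pc1[13:24]))
  expect_equal(pca$cov, t(pca$cov))
  expect_true(all(abs(Im(pca$values)) == 0))
  # duplicated individuals get identical scores
  dup <- cbind(geno, geno[, 1])
  pd <- covariance_pca(dup)
  expect_equal(pd$scores[1, ], pd$scores[25, ], tolerance = 1e-8)
  expect_error(covariance_pca(matrix(1L, 5, 3)))
})
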