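test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(sel_coeffs = c(high = 1.5, moderate = 0.02,
                                         low = 0.002, modifier = 0)),
               "selection")
  expect_error(sim_config(dominance_h = c(high = -0.1, moderate = 0.25,
                                          low = 0.5, modifier = 0.5)),
               "dominance")
  expect_error(sim_config(class_probs = c(high = 0.5, moderate = 0.5,
                                          low = 0.5)), "sum to 1")
  expect_error(sim_config(selfing_rates = c(0, 1.2)), "selfing")
  expect_error(sim_config(gene_length = 100), "multiple of 3")
})

test_that("no mutation means no variation", {
  cfg <- sim_config(n_pops = 1, pop_sizes = 20, seq_length = 10000,
                    n_genes = 1, gene_length = 300, mu_sim = 0,
                    n_sample = 5, seed = 1, burnin_gens = 30)
  truth <- simulate_populations(cfg)
  expect_equal(length(truth$pos), 0)
  expect_equal(nrow(truth$true_genotypes), 0)
})

test_that("identical seeds reproduce identical simulations", {
  cfg <- small_sim_config(seed = 99)
  t1 <- simulate_populations(cfg)
  t2 <- simulate_populations(cfg)
  expect_identical(t1, t2)
  set.seed(7); p1 <- simulate_pileups(t1, cfg)
  set.seed(7); p2 <- simulate_pileups(t1, cfg)
  expect_identical(p1, p2)
})

test_that("neutral segregating-site counts match the coalescent expectation", {
  # E[S] = theta * a_n for n chromosomes; theta = 10, n = 20 -> 35.48
  set.seed(101)
  n <- 20; theta <- 10
  S <- replicate(1000, nrow(coalescent_haplotypes(n, theta)))
  expected <- theta * sum(1 / seq_len(n - 1))
  expect_equal(expected, 35.477, tolerance = 1e-4)
  # Var(S) = theta a_n + theta^2 b_n; allow 4 SE
  se <- sqrt((theta * sum(1 / 1:19) + theta^2 * sum(1 / (1:19)^2)) / 1000)
  expect_lt(abs(mean(S) - expected), 4 * se)
})

test_that("neutral folded SFS matches the 1/i + 1/(n-i) expectation", {
  set.seed(202)
  n <- 20
  counts <- numeric(n %/% 2)
  for (r in 1:600) {
    h <- coalescent_haplotypes(n, 5)
    if (nrow(h) == 0) next
    d <- rowSums(h)
    minor <- pmin(d, n - d)
    counts <- counts + tabulate(minor, nbins = n %/% 2)
  }
  i <- seq_len(n %/% 2)
  expected <- (1 / i + 1 / (n - i)) / (1 + (i == n - i))
  expected <- expected / sum(expected)
  obs <- counts / sum(counts)
  expect_gt(cor(obs, expected), 0.99)
  expect_lt(max(abs(obs - expected)), 0.03)
})

test_that("obligate selfing drives inbreeding towards 1", {
  # F_t = 1 - 2^-t from the F' = (1 + F)/2 recursion; at t = 20, F > 0.999
  cfg <- sim_config(n_pops = 1, pop_sizes = 40, selfing_rates = 1,
                    seq_length = 10000, n_genes = 1, gene_length = 300,
                    mu_sim = 1e-6, n_sample = 20, seed = 5,
                    init = "monomorphic", burnin_gens = 20)
  truth <- simulate_populations(cfg)
  expect_gt(mean(truth$true_F), 0.9)
})

test_that("genotypes equal the sum of the two haplotypes and classes respect context", {
  truth <- simulate_populations(small_sim_config(seed = 3))
  h <- truth$haplotypes
  expect_identical(truth$true_genotypes,
                   h[, seq(1, ncol(h), 2)] + h[, seq(2, ncol(h), 2)],
                   ignore_attr = TRUE)
  expect_true(all(truth$site_class[truth$site_context != "CDS"] == "MODIFIER"))
  expect_true(all(truth$site_class %in%
                    c("MODIFIER", "HIGH", "MODERATE", "LOW")))
})

test_that("selection keeps deleterious alleles rarer than neutral ones", {
  set.seed(77)
  high_f <- c(); mod_f <- c()
  for (r in 1:12) {
    cfg <- sim_config(n_pops = 1, pop_sizes = 150, seq_length = 120000,
                      n_genes = 12, gene_length = 1200, mu_sim = 8e-7,
                      sel_coeffs = c(high = 0.3, moderate = 0.05, low = 0.002,
                                     modifier = 0),
                      dominance_h = c(high = 0.3, moderate = 0.3, low = 0.5,
                                      modifier = 0.5),
                      n_sample = 30, seed = 1000 + r, burnin_gens = 150)
    truth <- simulate_populations(cfg)
    f <- rowSums(truth$haplotypes) / ncol(truth$haplotypes)
    high_f <- c(high_f, f[truth$site_class %in% c("HIGH", "MODERATE")])
    mod_f <- c(mod_f, f[truth$site_class == "MODIFIER"])
  }
  wt <- wilcox.test(high_f, mod_f, alternative = "less")
  expect_lt(wt$p.value, 0.05)
})

test_that("pileup depths and read identities follow the error model", {
  geno <- matrix(rep(c(0L, 1L, 2L), each = 40), nrow = 3, ncol = 40,
                 byrow = TRUE)
  # zero depth
  cfg0 <- list(mean_depth = 0, error_rate = 0.01)
  p0 <- simulate_pileups(fake_truth(geno), cfg0)
  expect_true(all(p0$ref == 0) && all(p0$alt == 0))
  # hom-ref with e = 0: no alt reads ever
  set.seed(1)
  pe <- simulate_pileups(fake_truth(matrix(0L, 5, 30)),
                         list(mean_depth = 10, error_rate = 0))
  expect_true(all(pe$alt == 0))
  # heterozygote at high depth: alt fraction ~ 0.5 within 3 binomial SE
  set.seed(2)
  ph <- simulate_pileups(fake_truth(matrix(1L, 1, 1)),
                         list(mean_depth = 1e5, error_rate = 0.01))
  d <- ph$ref[1, 1] + ph$alt[1, 1]
  expect_lt(abs(ph$alt[1, 1] / d - 0.5), 3 * sqrt(0.25 / d))
})

test_that("the engineered reference reproduces the simulated impact classes", {
  truth <- simulate_populations(small_sim_config(seed = 11))
  models <- gene_models_from_layout(truth$layout)
  vt <- classify_variants(variant_table_from_truth(truth), models,
                          truth$reference, flank = truth$layout$flank)
  expect_identical(vt$impact_class, truth$site_class)
  expect_identical(vt$context, truth$site_context)
})
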