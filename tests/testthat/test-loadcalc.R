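test_that("the effect classifier handles the canonical toy-codon cases", {
  mod <- toy_gene(); ref <- toy_ref
  # CDS position 4 (1-based), A->T: AAA -> TAA, premature stop
  r <- classify_variant(3, "T", mod, ref)
  expect_equal(r$effect, "stop_gained"); expect_equal(r$impact_class, "HIGH")
  # CDS position 6, A->G: AAA -> AAG, synonymous
  r <- classify_variant(5, "G", mod, ref)
  expect_equal(r$effect, "synonymous"); expect_equal(r$impact_class, "LOW")
  # CDS position 7, T->A: TGC -> AGC, missense
  r <- classify_variant(6, "A", mod, ref)
  expect_equal(r$effect, "missense"); expect_equal(r$impact_class, "MODERATE")
  # start and stop codon disruptions
  expect_equal(classify_variant(0, "C", mod, ref)$effect, "start_lost")
  expect_equal(classify_variant(9, "G", mod, ref)$effect, "stop_lost")
  expect_equal(classify_variant(10, "G", mod, ref)$effect, "stop_retained")
  # outside every feature and beyond the flank
  far <- classify_variant(9000, "G", mod, paste0(ref, strrep("A", 9500)))
  expect_equal(far$impact_class, "MODIFIER")
  expect_equal(far$context, "intergenic")
})

test_that("classification agrees with a re-translate-and-diff oracle at every SNP", {
  tg <- toy_gene_set()
  refv <- strsplit(tg$ref, "")[[1]]
  for (pos0 in 0:(nchar(tg$ref) - 1)) {
    for (alt in setdiff(c("A", "C", "G", "T"), refv[pos0 + 1])) {
      got <- classify_variant(pos0, alt, tg$models, tg$ref)$impact_class
      want <- brute_force_effect(pos0, alt, tg$models, tg$ref)
      expect_equal(got, want,
                   label = sprintf("pos %d %s>%s: %s", pos0,
                                   refv[pos0 + 1], alt, got),
                   expected.label = want)
    }
  }
})

test_that("a CDS whose length is not a multiple of 3 is skipped with a warning", {
  bad <- list(list(gene_id = "oops", strand = "+", cds = rbind(c(1, 10)),
                   introns = NULL, utrs = NULL, body = c(1, 10)))
  expect_warning(r <- classify_variant(4, "T", bad, strrep("A", 20)),
                 "multiple of 3")
  expect_equal(r$impact_class, "MODIFIER")   # falls through to flank/intergenic
})

test_that("potential load counts carried deleterious sites over the genic total", {
  set.seed(2)
  n_sites <- 200
  impact <- rep("MODIFIER", n_sites)
  impact[1:4] <- "HIGH"
  geno <- matrix(0L, n_sites, 3)
  geno[1:4, 1] <- c(1L, 2L, 1L, 1L)       # individual 1 carries 4 HIGH sites
  geno[5:60, ] <- 1L                      # shared modifier variation
  lp <- load_potential(geno, impact)
  expect_equal(unname(lp$per_individual[1, "HIGH"]), 4 / 200)
  expect_equal(unname(lp$per_individual[2, "HIGH"]), 0)
  expect_equal(sum(lp$population), 1)
  expect_equal(unname(lp$population["HIGH"]), 4 / 200)
  expect_error(load_potential(geno[0, , drop = FALSE], character(0)))
})

test_that("realized load matches the worked zygosity example in both modes", {
  impact <- rep("HIGH", 4)
  geno <- matrix(c(2L, 1L, 1L, 0L), 4, 1)
  expect_equal(unname(load_realized(geno, impact,
                                    mode = "hom")$per_individual[1, "HIGH"]), 0.25)
  expect_equal(unname(load_realized(geno, impact,
                                    mode = "alleles")$per_individual[1, "HIGH"]), 0.5)
  expect_equal(unname(load_realized(matrix(0L, 4, 1),
                                    impact)$per_individual[1, "HIGH"]), 0)
  expect_equal(unname(load_realized(matrix(2L, 4, 1),
                                    impact)$per_individual[1, "HIGH"]), 1)
  expect_equal(unname(load_realized(matrix(2L, 4, 1), impact,
                             mode = "alleles")$per_individual[1, "HIGH"]), 1)
  # no genotyped class-i site: missing
  expect_true(is.na(load_realized(matrix(NA_integer_, 4, 1),
                                  impact)$per_individual[1, "HIGH"]))
})

test_that("realized load is bounded and capped by the non-heterozygous fraction", {
  set.seed(7)
  for (rep in 1:20) {
    impact <- sample(c("HIGH", "MODERATE", "LOW", "MODIFIER"), 50,
                     replace = TRUE)
    geno <- matrix(sample(c(0:2, NA), 200, replace = TRUE), 50, 4)
    lr <- load_realized(geno, impact, mode = "hom")$per_individual
    la <- load_realized(geno, impact, mode = "alleles")$per_individual
    expect_true(all(lr >= 0 & lr <= 1, na.rm = TRUE))
    expect_true(all(la >= 0 & la <= 1, na.rm = TRUE))
    for (cl in colnames(lr)) for (j in 1:4) {
      gc <- geno[impact == cl, j]
      if (sum(!is.na(gc)) == 0) next
      het_frac <- mean(gc == 1L, na.rm = TRUE)
      expect_lte(lr[j, cl], 1 - het_frac + 1e-12)
    }
  }
})

test_that("Welch's t matches the closed form", {
  w0 <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$t, 0); expect_equal(w0$p, 1)
  w <- welch_t(c(1, 2, 3), c(2, 4, 6))
  expect_equal(w$t, -1.549, tolerance = 1e-3)
  expect_equal(w$df, 2.941, tolerance = 1e-3)
  # reference arithmetic on random group pairs
  set.seed(8)
  for (rep in 1:100) {
    a <- rnorm(sample(3:10, 1)); b <- rnorm(sample(3:10, 1), 0.5)
    w <- welch_t(a, b)
    se2 <- var(a) / length(a) + var(b) / length(b)
    t_ref <- (mean(a) - mean(b)) / sqrt(se2)
    df_ref <- se2^2 / ((var(a) / length(a))^2 / (length(a) - 1) +
                         (var(b) / length(b))^2 / (length(b) - 1))
    p_ref <- 2 * pt(-abs(t_ref), df_ref)
    expect_equal(w$t, t_ref, tolerance = 1e-10)
    expect_equal(w$df, df_ref, tolerance = 1e-10)
    expect_equal(w$p, p_ref, tolerance = 1e-10)
  }
})

test_that("population-mean realized load rises with the selfing rate", {
  set.seed(90)
  alphas <- c(0, 0.4, 0.8)
  reps <- 30
  vals <- expand.grid(alpha = alphas, rep = seq_len(reps))
  vals$load <- NA_real_
  for (i in seq_len(nrow(vals))) {
    cfg <- sim_config(n_pops = 1, pop_sizes = 60,
                      selfing_rates = vals$alpha[i],
                      seq_length = 200000, n_genes = 20, gene_length = 900,
                      mu_sim = 1.2e-6, n_sample = 10,
                      seed = sample.int(1e6, 1), burnin_gens = 60)
    truth <- simulate_populations(cfg)
    if (length(truth$pos) == 0) next
    genic <- truth$site_context != "intergenic"
    lr <- load_realized(truth$true_genotypes, truth$site_class,
                        genic)$per_individual
    vals$load[i] <- mean(lr[, c("MODERATE", "LOW")], na.rm = TRUE)
  }
  ct <- cor.test(vals$alpha, vals$load, method = "spearman", exact = FALSE)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.05)
})
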