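#' Number of unordered individual pairs
#'
#' @param N number of individuals (>= 2).
#' @return `N * (N - 1) / 2`.
#' @export
#' @examples
#' n_pairs(74)
n_pairs <- function(N) {
  stopifnot(N >= 2)
  N * (N - 1) / 2
}

# subset a gl_matrix to a set of individuals (columns)
gl_subset <- function(gl, cols) {
  out <- gl
  for (f in c("hom_ref", "het", "hom_alt", "depth", "ref_reads", "alt_reads"))
    out[[f]] <- gl[[f]][, cols, drop = FALSE]
  out$individual <- gl$individual[cols]
  out$pop <- gl$pop[cols]
  out
}

# per-population alternate-allele frequencies and chromosomes-with-data at
# the pooled variant sites
pop_af <- function(gl, variants, cols) {
  sub <- gl_subset(gl, cols)
  m <- match(variants$pos, sub$pos)
  em <- af_em_matrix(sub$hom_ref[m, , drop = FALSE],
                     sub$het[m, , drop = FALSE],
                     sub$hom_alt[m, , drop = FALSE],
                     sub$depth[m, , drop = FALSE])
  list(f = em$f, n_chrom = 2L * em$n_ind)
}

#' Mito-like alignment from simulation truth
#'
#' Substitutes each individual's first haplotype into the reference
#' sequence, yielding one haploid sequence per individual (a stand-in for a
#' consensus mitogenome alignment).
#'
#' @param truth a [simulate_populations()] result.
#' @return an [alignment_set()] with population labels.
#' @export
alignment_from_truth <- function(truth) {
  refv <- split_chars(truth$reference)
  hap1 <- truth$haplotypes[, seq(1, ncol(truth$haplotypes), by = 2),
                           drop = FALSE]
  seqs <- vapply(seq_len(ncol(hap1)), function(j) {
    s <- refv
    carr <- hap1[, j] == 1L
    s[truth$pos[carr] + 1L] <- truth$alt_allele[carr]
    paste(s, collapse = "")
  }, character(1))
  alignment_set(seqs, pops = truth$pop, ids = truth$individual)
}

#' Pipeline configuration
#'
#' Bundles the knobs of [run_all()].  Filter thresholds default to values
#' scaled to the simulated data (the study-scale profiles for real
#' low-coverage cohorts are available via [filter_profile()]).
#'
#' @param sim a [sim_config()].
#' @param min_ind minimum individuals with data per site (default 80% of the
#'   pooled sample, mirroring the population-profile rationale).
#' @param max_depth maximum summed depth per site (default `Inf`; set from
#'   [filter_profile()] for study-scale data).
#' @param min_pair_sites kinship pair filter (default 500 at simulation
#'   scale; 100,000 for genome-scale data).
#' @param window,step window size and step in bp for the scans.
#' @param z_cut Z(Fst) outlier threshold in SD units.
#' @param min_window_sites per-window site floor for the outlier scan.
#' @param load_mode Load_R numerator mode, `"hom"` or `"alleles"`.
#' @param n_sub,n_perm subsample size and permutations for the
#'   alignment-based comparison.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            min_ind = NULL,
                            max_depth = Inf,
                            min_pair_sites = 500,
                            window = 100000, step = 50000,
                            z_cut = 5, min_window_sites = 10,
                            load_mode = c("hom", "alleles"),
                            n_sub = 7, n_perm = 100) {
  load_mode <- match.arg(load_mode)
  n_tot <- sim$n_pops * sim$n_sample
  if (is.null(min_ind)) min_ind <- max(2L, ceiling(0.8 * n_tot))
  structure(list(sim = sim, min_ind = as.integer(min_ind),
                 max_depth = max_depth, min_pair_sites = min_pair_sites,
                 window = window, step = step, z_cut = z_cut,
                 min_window_sites = min_window_sites,
                 load_mode = load_mode, n_sub = n_sub, n_perm = n_perm),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a simulated dataset
#'
#' simulate -> pileups -> genotype likelihoods -> SNP calling -> genotype
#' calling -> diversity -> kinship / inbreeding / PCA -> differentiation and
#' neutrality scans -> impact classification and load -> alignment
#' statistics.  Fully deterministic under the simulation seed.
#'
#' @param config a [pipeline_config()].
#' @return a structured report list; each section is the output of the
#'   corresponding module function.
#' @export
run_all <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config$sim
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  truth <- stage("simulate", simulate_populations(cfg))
  pile <- stage("simulate", simulate_pileups(truth, cfg))
  gl <- stage("call", gl_matrix(pile, e = cfg$error_rate))
  variants <- stage("call",
                    call_snps(gl, min_ind = config$min_ind,
                              max_depth = config$max_depth))
  if (nrow(variants) == 0)
    stage("call", stop("no variants passed the calling filters"))
  geno <- stage("call", call_genotypes(gl, variants))
  models <- gene_models_from_layout(truth$layout)
  variants <- stage("load",
                    classify_variants(variants, models, truth$reference,
                                      flank = truth$layout$flank))

  pops <- unique(truth$pop)
  cols_of <- lapply(pops, function(p) which(truth$pop == p))
  names(cols_of) <- pops

  # --- diversity per population -----------------------------------------
  diversity <- stage("diversity", lapply(pops, function(p) {
    cols <- cols_of[[p]]
    sub <- geno[, cols, drop = FALSE]
    seg <- which(rowSums(sub, na.rm = TRUE) > 0 &
                   rowSums(sub, na.rm = TRUE) < 2 * rowSums(!is.na(sub)))
    sfs <- folded_sfs(sub[seg, , drop = FALSE])
    S <- length(seg)
    th <- watterson_theta(S, 2 * length(cols), cfg$seq_length)
    list(S = S, theta_w = th,
         het = heterozygosity_per_individual(sub, L = cfg$seq_length),
         sfs = sfs,
         Ne = ne_from_theta(th, cfg$mu_sim)$Ne)
  }))
  names(diversity) <- pops

  # --- relatedness -------------------------------------------------------
  kin <- stage("kinship",
               kinship_all_pairs(geno, min_sites = config$min_pair_sites))
  inbreeding <- stage("inbreeding", do.call(rbind, lapply(pops, function(p) {
    cols <- cols_of[[p]]
    paf <- pop_af(gl, variants, cols)
    ok <- !is.na(paf$f) & paf$f > 0 & paf$f < 1
    vsub <- variants[ok, , drop = FALSE]
    vsub$af_alt <- paf$f[ok]
    fi <- individual_F(gl_subset(gl, cols), vsub,
                       min_sites = min(100, max(10, sum(ok) %/% 2)))
    fi$pop <- p
    fi
  })))
  pca <- stage("pca", covariance_pca(geno))

  # --- differentiation scans --------------------------------------------
  windows <- make_windows(cfg$seq_length, config$window, config$step)
  scans <- NULL
  if (length(pops) > 1) {
    prs <- utils::combn(pops, 2)
    scans <- lapply(seq_len(ncol(prs)), function(k) {
      pa <- prs[1, k]; pb <- prs[2, k]
      fa <- pop_af(gl, variants, cols_of[[pa]])
      fb <- pop_af(gl, variants, cols_of[[pb]])
      ok <- !is.na(fa$f) & !is.na(fb$f) & fa$n_chrom >= 2 & fb$n_chrom >= 2
      fst <- fst_window(variants$pos[ok], fa$f[ok], fb$f[ok],
                        fa$n_chrom[ok], fb$n_chrom[ok], windows = windows)
      zf <- z_fst_outliers(fst$windows, z_cut = config$z_cut,
                           min_sites = config$min_window_sites)
      dxy <- dxy_window(variants$pos[ok], fa$f[ok], fb$f[ok], windows)
      list(pair = c(pa, pb), global_fst = fst$global,
           global_ci = fst$global_ci, windows = zf, dxy = dxy)
    })
  }
  fu_li <- lapply(pops, function(p) {
    cols <- cols_of[[p]]
    sub <- geno[, cols, drop = FALSE]
    complete <- rowSums(is.na(sub)) == 0
    dc <- rowSums(sub[complete, , drop = FALSE])
    segc <- dc > 0 & dc < 2 * length(cols)
    fu_li_window(variants$pos[complete][segc], dc[segc],
                 2L * length(cols), windows)
  })
  names(fu_li) <- pops

  # --- load --------------------------------------------------------------
  genic <- variants$context != "intergenic"
  load <- stage("load", load_table(geno, variants$impact_class, truth$pop,
                                   genic = genic, mode = config$load_mode))

  # --- alignment statistics ---------------------------------------------
  aln <- alignment_from_truth(truth)
  seqdiv <- list(per_pop = lapply(pops, function(p) {
    idx <- which(truth$pop == p)
    sub <- alignment_set(apply(aln$mat[idx, , drop = FALSE], 1, paste,
                               collapse = ""),
                         pops = aln$pops[idx], ids = aln$ids[idx])
    hs <- haplotype_stats(sub)
    list(n_haplotypes = hs$n_haplotypes, hd = hs$hd,
         n_parsimony_informative = hs$n_parsimony_informative,
         pi = nucleotide_diversity(sub))
  }))
  names(seqdiv$per_pop) <- pops
  if (length(pops) > 1 && all(table(truth$pop) >= config$n_sub)) {
    seqdiv$subsample <- subsample_compare(aln, pops[1], pops[2],
                                          n_sub = config$n_sub,
                                          n_perm = config$n_perm)
  }

  list(config = config, truth = truth, variants = variants,
       genotypes = geno, diversity = diversity,
       kinship = kin, inbreeding = inbreeding, pca = pca,
       scans = scans, fu_li = fu_li, load = load, seqdiv = seqdiv,
       n_pairs = n_pairs(ncol(geno)))
}

#' Write a pipeline report to JSON
#'
#' Serialises the numeric summaries of a [run_all()] report (omitting the
#' large matrices) to JSON.
#'
#' @param report a [run_all()] result.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_report <- function(report, path) {
  slim <- list(
    n_pairs = report$n_pairs,
    n_variants = nrow(report$variants),
    diversity = lapply(report$diversity, function(d)
      list(S = d$S, theta_w = d$theta_w, Ne = d$Ne,
           mean_het = mean(d$het, na.rm = TRUE))),
    kinship_degrees = as.list(table(report$kinship$degree[!report$kinship$filtered])),
    mean_F = lapply(split(report$inbreeding$F, report$inbreeding$pop),
                    mean, na.rm = TRUE),
    global_fst = if (!is.null(report$scans))
      lapply(report$scans, function(s)
        list(pair = paste(s$pair, collapse = "-"), fst = s$global_fst,
             ci = s$global_ci)),
    load_population = report$load$population,
    load_tests = report$load$tests,
    seqdiv = report$seqdiv$per_pop)
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}
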