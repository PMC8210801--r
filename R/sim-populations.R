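#' Simulate populations under selection, selfing and splits
#'
#' Runs a forward Wright-Fisher simulation of the configured demography:
#' an ancestral population is equilibrated (coalescent-seeded by default,
#' or a `10 * N`-generation forward burn-in), split into daughter populations,
#' and evolved with per-population selfing.  Coding mutations carry
#' class-specific selection (fitness 1, `1 - hs`, `1 - s` for genotypes
#' 0/1/2); non-coding mutations are neutral MODIFIER sites.  At the end,
#' `n_sample` individuals per population are drawn and returned with the full
#' ground truth used by the estimator calibration tests.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `sim_truth`: a list with
#'   \describe{
#'   \item{pos}{0-based site positions (sorted) of segregating sites in the
#'     pooled sample, plus cross-population fixed differences.}
#'   \item{haplotypes}{binary derived-allele matrix, sites x chromosomes.}
#'   \item{true_genotypes}{integer matrix sites x individuals, in 0/1/2.}
#'   \item{site_class}{impact class per site (MODIFIER/HIGH/MODERATE/LOW).}
#'   \item{site_context}{CDS/intron/UTR/upstream/downstream/intergenic.}
#'   \item{ancestral_allele, alt_allele}{bases; the reference equals the
#'     ancestral state and the alternate allele is the derived (putatively
#'     deleterious) allele.}
#'   \item{reference}{reference chromosome sequence (character scalar).}
#'   \item{pop}{population label per sampled individual.}
#'   \item{true_F}{expected (pedigree selfing-recursion) inbreeding
#'     coefficient per sampled individual, relative to its contemporary
#'     population.}
#'   \item{pedigree}{parent indices (within the final generation of the
#'     individual's population) per sampled individual.}
#'   \item{layout}{gene architecture, see [genome_layout()].}
#'   }
#' @export
#' @examples
#' cfg <- sim_config(n_pops = 1, pop_sizes = 30, seq_length = 20000,
#'                   n_genes = 2, gene_length = 300, mu_sim = 1e-6,
#'                   n_sample = 10, seed = 42)
#' truth <- simulate_populations(cfg)
#' table(truth$site_class)
simulate_populations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  layout <- genome_layout(config)
  mut <- mutable_positions(layout, config$seq_length)
  N1 <- config$pop_sizes[1]
  # selection/dominance vectors indexed by the engine's class codes
  # (0 MODIFIER, 1 HIGH, 2 MODERATE, 3 LOW)
  s_code <- as.numeric(config$sel_coeffs[c("modifier", "high", "moderate", "low")])
  h_code <- as.numeric(config$dominance_h[c("modifier", "high", "moderate", "low")])

  # --- ancestral population ---------------------------------------------
  if (config$init == "coalescent" && config$mu_sim > 0) {
    # the forward engine transmits sites independently (free recombination),
    # so its stationary state has independent genealogies across loci; the
    # init therefore draws one coalescent per 5-kb block rather than a single
    # fully linked genealogy for the whole sequence
    n_blocks <- max(1L, ceiling(length(mut$pos) / 5000))
    theta_block <- 4 * N1 * config$mu_sim * length(mut$pos) / n_blocks
    hap0 <- do.call(rbind, lapply(seq_len(n_blocks), function(b)
      coalescent_haplotypes(2L * N1, theta_block)))
    take <- sample.int(length(mut$pos), nrow(hap0))
    pos0 <- mut$pos[take]
    cls0 <- draw_classes(mut$codon[take], config$class_probs)
  } else {
    hap0 <- matrix(0L, 0, 2L * N1)
    pos0 <- integer(0)
    cls0 <- integer(0)
  }
  anc <- .wf_evolve_cpp(hap0, pos0, cls0, rep(0, N1), N1,
                        config$selfing_rates[1], config$burnin_gens,
                        config$mu_sim, mut$pos, mut$codon,
                        as.numeric(config$class_probs),
                        s_code, h_code)

  # --- split and daughter populations -----------------------------------
  pops <- vector("list", config$n_pops)
  if (config$n_pops == 1L) {
    pops[[1]] <- anc
  } else {
    for (i in seq_len(config$n_pops)) {
      Ni <- config$pop_sizes[i]
      founders <- sample.int(N1, Ni, replace = TRUE)
      cols <- as.vector(rbind(2L * founders - 1L, 2L * founders))
      fhap <- anc$hap[, cols, drop = FALSE]
      pops[[i]] <- .wf_evolve_cpp(fhap, anc$pos, anc$class,
                                  anc$F[founders], Ni,
                                  config$selfing_rates[i], config$split_gens,
                                  config$mu_sim, mut$pos, mut$codon,
                                  as.numeric(config$class_probs),
                                  s_code, h_code)
    }
  }

  # --- merge sites across populations ------------------------------------
  # keep sites segregating in >= 1 population, plus sites fixed in some but
  # not all populations (fixed differences); drop global substitutions
  seg_pos <- sort(unique(unlist(lapply(pops, `[[`, "pos"))))
  fix_tab <- unique(do.call(rbind, lapply(pops, function(p)
    data.frame(pos = p$fixed_pos, class = p$fixed_class))))
  fixed_everywhere <- if (nrow(fix_tab)) {
    vapply(fix_tab$pos, function(p) all(vapply(pops, function(pp)
      p %in% pp$fixed_pos, logical(1))), logical(1))
  } else logical(0)
  keep_fixed <- setdiff(fix_tab$pos[!fixed_everywhere], seg_pos)
  pos_all <- sort(unique(c(seg_pos, keep_fixed)))
  S <- length(pos_all)

  # impact class per site: pre-split sites agree across pops; for the rare
  # independent post-split hits at one position, the first population's draw
  # wins (its fitness effect was simulated per-population anyway)
  cls_all <- rep(NA_integer_, S)
  for (p in pops) {
    m <- match(p$pos, pos_all)
    fill <- is.na(cls_all[m])
    cls_all[m[fill]] <- p$class[fill]
    if (length(p$fixed_pos)) {
      mf <- match(p$fixed_pos, pos_all)
      ok <- !is.na(mf) & is.na(cls_all[mf])
      cls_all[mf[ok]] <- p$fixed_class[ok]
    }
  }

  # --- sample individuals -------------------------------------------------
  n_tot <- config$n_pops * config$n_sample
  hap_out <- matrix(0L, S, 2L * n_tot)
  true_F <- numeric(n_tot)
  ped <- matrix(NA_integer_, n_tot, 2,
                dimnames = list(NULL, c("mother", "father")))
  pop_lab <- character(n_tot)
  ind_id <- character(n_tot)
  k <- 0L
  for (i in seq_len(config$n_pops)) {
    p <- pops[[i]]
    picks <- sample.int(config$pop_sizes[i], config$n_sample)
    m <- match(p$pos, pos_all)
    fixed_rows <- match(intersect(p$fixed_pos, pos_all), pos_all)
    for (j in seq_len(config$n_sample)) {
      k <- k + 1L
      cols <- c(2L * picks[j] - 1L, 2L * picks[j])
      block <- matrix(0L, S, 2)
      block[m, ] <- p$hap[, cols, drop = FALSE]
      if (length(fixed_rows)) block[fixed_rows, ] <- 1L
      hap_out[, c(2L * k - 1L, 2L * k)] <- block
      true_F[k] <- p$F[picks[j]]
      ped[k, ] <- p$pedigree[picks[j], ] + 1L
      pop_lab[k] <- paste0("pop", i)
      ind_id[k] <- sprintf("pop%d_ind%02d", i, j)
    }
  }
  geno <- hap_out[, seq(1, 2 * n_tot, by = 2), drop = FALSE] +
          hap_out[, seq(2, 2 * n_tot, by = 2), drop = FALSE]
  colnames(geno) <- ind_id

  # --- drop sites invariant in the pooled sample --------------------------
  tot <- rowSums(hap_out)
  keep <- tot > 0L & tot < 2L * n_tot
  pos_all <- pos_all[keep]; cls_all <- cls_all[keep]
  hap_out <- hap_out[keep, , drop = FALSE]
  geno <- geno[keep, , drop = FALSE]

  # --- engineer the reference so sequence-based classification matches ----
  refbuild <- build_reference(layout, pos_all, cls_all, config)

  structure(list(
    chrom = "chr1",
    pos = pos_all,
    haplotypes = hap_out,
    true_genotypes = geno,
    site_class = class_label(refbuild$class),
    site_context = layout$context[pos_all + 1L],
    ancestral_allele = refbuild$ref[pos_all + 1L],
    alt_allele = refbuild$alt,
    reference = paste(refbuild$ref, collapse = ""),
    pop = pop_lab,
    individual = ind_id,
    true_F = true_F,
    pedigree = ped,
    layout = layout,
    config = config), class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d segregating sites x %d individuals (%d pops)\n",
              length(x$pos), ncol(x$true_genotypes), x$config$n_pops))
  print(table(class = x$site_class))
  invisible(x)
}

# Codon/alt templates realising each impact class at each codon offset.
# Used to back-fill the reference sequence after the forward simulation so
# that re-translating the engineered codon reproduces the simulated class.
.codon_templates <- list(
  HIGH     = list(`0` = c("CAA", "T"),  # CAA -> TAA, stop_gained
                  `1` = c("TCA", "A"),  # TCA -> TAA
                  `2` = c("TGC", "A")), # TGC -> TGA
  MODERATE = list(`0` = c("AAA", "G"),  # Lys -> Glu
                  `1` = c("AAA", "G"),  # Lys -> Arg
                  `2` = c("ATC", "G")), # Ile -> Met
  LOW      = list(`0` = c("TTA", "C"),  # Leu -> Leu
                  `1` = NULL,           # impossible mid-codon
                  `2` = c("AAA", "G"))) # Lys -> Lys

.non_stop_codons <- local({
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
})

# Builds the reference chromosome (ancestral sequence) and per-site alternate
# alleles.  CDS codons hosting a variant get an engineered codon from
# .codon_templates; when two variants share a codon the later one takes
# whatever alternate base realises its class given the already-fixed codon,
# or is relabelled to the effect it actually has (rare).
build_reference <- function(layout, pos_all, cls_all, config) {
  L <- config$seq_length
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)
  g <- layout$genes
  cds_positions_of <- function(i) {
    c(seq.int(g$cds1_start[i] + 1L, g$cds1_end[i]),
      seq.int(g$cds2_start[i] + 1L, g$cds2_end[i]))  # 1-based genome index
  }
  for (i in seq_len(nrow(g))) {
    cpos <- cds_positions_of(i)
    ncod <- length(cpos) %/% 3L
    codons <- sample(.non_stop_codons, ncod, replace = TRUE)
    codons[1] <- "ATG"
    codons[ncod] <- "TAA"
    ref[cpos] <- unlist(strsplit(codons, ""), use.names = FALSE)
    ref[g$intron_start[i] + 1:2] <- c("G", "T")      # splice donor
    ref[g$cds2_start[i] - 1:0] <- c("A", "G")        # splice acceptor
  }

  alt <- rep(NA_character_, length(pos_all))
  cls_out <- cls_all
  engineered <- new.env(hash = TRUE)
  in_cds <- layout$context[pos_all + 1L] == "CDS"
  for (k in which(in_cds)) {
    p1 <- pos_all[k] + 1L
    gi <- layout$cds_gene[p1]
    cp <- layout$cds_pos[p1]
    off <- cp %% 3L
    codon_idx <- cp %/% 3L
    cpos <- cds_positions_of(gi)
    codon_genome <- cpos[codon_idx * 3L + 1:3]
    key <- sprintf("%d_%d", gi, codon_idx)
    want <- class_label(cls_all[k])
    if (is.null(engineered[[key]])) {
      tpl <- .codon_templates[[want]][[as.character(off)]]
      ref[codon_genome] <- strsplit(tpl[1], "")[[1]]
      alt[k] <- tpl[2]
      engineered[[key]] <- TRUE
    } else {
      codon <- paste(ref[codon_genome], collapse = "")
      cands <- setdiff(bases, ref[p1])
      effs <- vapply(cands, function(b) snv_effect_codon(codon, off, b),
                     character(1))
      hit <- which(effect_to_class(effs) == want)
      if (length(hit)) {
        alt[k] <- cands[hit[1]]
      } else {
        alt[k] <- cands[1]
        cls_out[k] <- match(effect_to_class(effs[1]), CLASS_LEVELS) - 1L
      }
    }
  }
  noncds <- which(!in_cds)
  if (length(noncds)) {
    cur <- ref[pos_all[noncds] + 1L]
    alt[noncds] <- vapply(cur, function(b) sample(setdiff(bases, b), 1),
                          character(1))
  }
  list(ref = ref, alt = alt, class = cls_out)
}
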