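#' Gene models for variant-effect classification
#'
#' Builds the minimal transcript models (ordered CDS intervals, introns,
#' UTRs, strand) used by [classify_variants()], either from a simulator
#' layout or from a GFF3 file.
#'
#' @param layout a [genome_layout()] result.
#' @return a list of gene models; each has `gene_id`, `strand`, `cds` (matrix
#'   of 1-based inclusive start/end rows in transcription order), `introns`,
#'   `utrs`, and `body` (1-based inclusive gene span).
#' @export
gene_models_from_layout <- function(layout) {
  g <- layout$genes
  lapply(seq_len(nrow(g)), function(i) {
    list(gene_id = g$gene_id[i],
         strand = g$strand[i],
         cds = rbind(c(g$cds1_start[i] + 1L, g$cds1_end[i]),
                     c(g$cds2_start[i] + 1L, g$cds2_end[i])),
         introns = rbind(c(g$intron_start[i] + 1L, g$cds2_start[i])),
         utrs = rbind(c(g$utr5_start[i] + 1L, g$cds1_start[i]),
                      c(g$utr3_start[i] + 1L, g$body_end[i])),
         body = c(g$body_start[i] + 1L, g$body_end[i]))
  })
}

#' @rdname gene_models_from_layout
#' @param gff_path path to a GFF3 file with gene/mRNA/CDS/UTR features.
#' @export
gene_models_from_gff <- function(gff_path) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  lapply(seq_along(genes), function(i) {
    gid <- genes$ID[i]
    par <- vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                  character(1))
    mrna <- gr[gr$type == "mRNA" & par == gid]
    mid <- if (length(mrna)) mrna$ID[1] else gid
    feat <- gr[par %in% c(gid, mid)]
    cds <- feat[feat$type == "CDS"]
    utr <- feat[feat$type %in% c("five_prime_UTR", "three_prime_UTR")]
    strand <- as.character(GenomicRanges::strand(genes))[i]
    cds <- cds[order(GenomicRanges::start(cds))]
    cdsm <- cbind(GenomicRanges::start(cds), GenomicRanges::end(cds))
    if (strand == "-") cdsm <- cdsm[rev(seq_len(nrow(cdsm))), , drop = FALSE]
    introns <- NULL
    if (nrow(cdsm) > 1) {
      o <- cdsm[order(cdsm[, 1]), , drop = FALSE]
      introns <- cbind(o[-nrow(o), 2] + 1L, o[-1, 1] - 1L)
    }
    list(gene_id = gid, strand = strand, cds = cdsm,
         introns = introns,
         utrs = cbind(GenomicRanges::start(utr), GenomicRanges::end(utr)),
         body = c(GenomicRanges::start(genes)[i], GenomicRanges::end(genes)[i]))
  })
}

.complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

# Effect of substituting `alt` at 0-based offset `off` of `codon`.
# `first`/`last` mark the start and stop codon of the transcript.
snv_effect_codon <- function(codon, off, alt, first = FALSE, last = FALSE) {
  alt_codon <- codon
  substr(alt_codon, off + 1, off + 1) <- alt
  ref_aa <- translate_codon(codon)
  alt_aa <- translate_codon(alt_codon)
  if (first && codon == "ATG" && alt_codon != "ATG") return("start_lost")
  if (ref_aa == "*" && alt_aa == "*") return("stop_retained")
  if (ref_aa == "*" && alt_aa != "*") return("stop_lost")
  if (ref_aa != "*" && alt_aa == "*") return("stop_gained")
  if (ref_aa == alt_aa) return("synonymous")
  "missense"
}

effect_to_class <- function(effect) {
  unname(c(stop_gained = "HIGH", stop_lost = "HIGH", start_lost = "HIGH",
           splice_donor = "HIGH", splice_acceptor = "HIGH",
           missense = "MODERATE",
           synonymous = "LOW", stop_retained = "LOW")[effect])
}

#' Classify the impact of a single-nucleotide variant
#'
#' Translates CDS variants in frame and strand, and maps the predicted
#' effect on the protein to an impact class: premature stop, lost stop or
#' start, and splice-site (first/last two intronic bases) changes are HIGH;
#' missense is MODERATE; synonymous and stop-retained are LOW; intron, UTR,
#' flank (within `flank` bp of the gene body) and intergenic variants are
#' MODIFIER.  The alternate allele is assumed deleterious relative to the
#' reference.
#'
#' @param pos 0-based variant position.
#' @param alt alternate base.
#' @param models gene-model list ([gene_models_from_layout()] /
#'   [gene_models_from_gff()]).
#' @param reference reference chromosome sequence (character scalar).
#' @param flank flank size in bp for upstream/downstream annotation
#'   (default 5000).
#' @return list with `impact_class`, `effect` and `context`.
#' @export
#' @examples
#' ref <- "ATGAAATGCTAA"
#' mod <- list(list(gene_id = "g1", strand = "+",
#'                  cds = rbind(c(1, 12)), introns = NULL,
#'                  utrs = NULL, body = c(1, 12)))
#' classify_variant(3, "T", mod, ref)$effect  # Lys -> stop
classify_variant <- function(pos, alt, models, reference, flank = 5000) {
  refv <- split_chars(reference)
  p1 <- pos + 1L
  for (mod in models) {
    ncds <- nrow(mod$cds)
    # CDS?
    hit <- which(p1 >= mod$cds[, 1] & p1 <= mod$cds[, 2])
    if (length(hit)) {
      if (sum(mod$cds[, 2] - mod$cds[, 1] + 1L) %% 3L != 0L) {
        warning(sprintf("gene %s: CDS length not a multiple of 3; skipped",
                        mod$gene_id))
        next
      }
      cds_pos_list <- lapply(seq_len(ncds), function(k)
        seq.int(mod$cds[k, 1], mod$cds[k, 2]))
      if (mod$strand == "-")
        cds_pos_list <- lapply(cds_pos_list, rev)
      cds_positions <- unlist(cds_pos_list, use.names = FALSE)
      idx <- match(p1, cds_positions) - 1L        # 0-based CDS coordinate
      n_codons <- length(cds_positions) %/% 3L
      codon_idx <- idx %/% 3L
      off <- idx %% 3L
      codon_genome <- cds_positions[codon_idx * 3L + 1:3]
      codon_bases <- refv[codon_genome]
      alt_b <- alt
      if (mod$strand == "-") {
        codon_bases <- .complement[codon_bases]
        alt_b <- .complement[[alt]]
      }
      eff <- snv_effect_codon(paste(codon_bases, collapse = ""), off, alt_b,
                              first = codon_idx == 0L,
                              last = codon_idx == n_codons - 1L)
      return(list(impact_class = effect_to_class(eff), effect = eff,
                  context = "CDS", gene = mod$gene_id))
    }
    # splice site / intron?
    if (!is.null(mod$introns)) {
      for (k in seq_len(nrow(mod$introns))) {
        a <- mod$introns[k, 1]; b <- mod$introns[k, 2]
        if (p1 >= a && p1 <= b) {
          donor <- if (mod$strand == "+") p1 <= a + 1L else p1 >= b - 1L
          accept <- if (mod$strand == "+") p1 >= b - 1L else p1 <= a + 1L
          if (donor)
            return(list(impact_class = "HIGH", effect = "splice_donor",
                        context = "intron", gene = mod$gene_id))
          if (accept)
            return(list(impact_class = "HIGH", effect = "splice_acceptor",
                        context = "intron", gene = mod$gene_id))
          return(list(impact_class = "MODIFIER", effect = "intron_variant",
                      context = "intron", gene = mod$gene_id))
        }
      }
    }
    if (!is.null(mod$utrs) && nrow(mod$utrs) > 0) {
      for (k in seq_len(nrow(mod$utrs))) {
        if (p1 >= mod$utrs[k, 1] && p1 <= mod$utrs[k, 2])
          return(list(impact_class = "MODIFIER", effect = "UTR_variant",
                      context = "UTR", gene = mod$gene_id))
      }
    }
  }
  # flanks (nearest gene wins)
  best <- NULL; bestd <- Inf
  for (mod in models) {
    if (p1 < mod$body[1] && mod$body[1] - p1 <= flank) {
      d <- mod$body[1] - p1
      lab <- if (mod$strand == "+") "upstream" else "downstream"
    } else if (p1 > mod$body[2] && p1 - mod$body[2] <= flank) {
      d <- p1 - mod$body[2]
      lab <- if (mod$strand == "+") "downstream" else "upstream"
    } else next
    if (d < bestd) { bestd <- d; best <- list(lab = lab, gene = mod$gene_id) }
  }
  if (!is.null(best))
    return(list(impact_class = "MODIFIER",
                effect = paste0(best$lab, "_gene_variant"),
                context = best$lab, gene = best$gene))
  list(impact_class = "MODIFIER", effect = "intergenic_variant",
       context = "intergenic", gene = NA_character_)
}

#' Classify all variants in a table
#'
#' @param variants a `variant_table` (needs `pos` and `alt`).
#' @param models,reference,flank see [classify_variant()].
#' @return the table with `context`, `impact_class` and `effect` filled in.
#' @export
classify_variants <- function(variants, models, reference, flank = 5000) {
  refv <- split_chars(reference)
  res <- lapply(seq_len(nrow(variants)), function(i)
    classify_variant(variants$pos[i], variants$alt[i], models, refv,
                     flank = flank))
  variants$context <- vapply(res, `[[`, character(1), "context")
  variants$impact_class <- vapply(res, `[[`, character(1), "impact_class")
  variants$effect <- vapply(res, `[[`, character(1), "effect")
  variants
}

#' Potential load (Load_P)
#'
#' The proportion of a population's genic variants that falls in each impact
#' class.  The per-individual form counts the class-i genic sites at which
#' the individual carries at least one alternate allele, divided by the
#' total number of genic segregating sites in the population; the
#' population-level form uses the class-i segregating count as numerator
#' (so the four classes sum to 1).
#'
#' @param geno genotype matrix (sites x individuals) for the population's
#'   individuals, alternate-allele counts with `NA` missing.
#' @param impact impact class per site (`HIGH`/`MODERATE`/`LOW`/`MODIFIER`).
#' @param genic logical per site: inside the genic annotation (gene body
#'   plus flanks).  Non-genic sites are excluded from numerator and
#'   denominator.
#' @return list with `per_individual` (individuals x classes matrix),
#'   `population` (named class proportions) and `n_genic` (the denominator).
#' @export
load_potential <- function(geno, impact, genic = rep(TRUE, length(impact))) {
  stopifnot(nrow(geno) == length(impact), length(genic) == length(impact))
  g <- geno[genic, , drop = FALSE]
  imp <- factor(impact[genic], levels = CLASS_LEVELS)
  n_genic <- sum(genic)
  if (n_genic == 0) stop("no genic variants in this population")
  carries <- (!is.na(g)) & g >= 1L
  per_ind <- vapply(CLASS_LEVELS, function(cl)
    colSums(carries[imp == cl, , drop = FALSE]), numeric(ncol(g))) / n_genic
  if (is.null(dim(per_ind)))
    per_ind <- matrix(per_ind, nrow = 1, dimnames = list(NULL, CLASS_LEVELS))
  rownames(per_ind) <- colnames(g)
  pop <- table(imp) / n_genic
  list(per_individual = per_ind,
       population = c(pop),
       n_genic = n_genic)
}

#' Realized load (Load_R)
#'
#' The per-individual proportion of class-i deleterious variants manifested
#' in the genome.  In mode `"hom"` (the default) the numerator counts two
#' alleles for every homozygous-alternate class-i site; in mode `"alleles"`
#' it counts all alternate alleles (heterozygotes included).  The
#' denominator is twice the number of class-i genic sites genotyped in that
#' individual.
#'
#' @inheritParams load_potential
#' @param mode `"hom"` or `"alleles"`.
#' @return list with `per_individual` (individuals x classes matrix, `NA`
#'   where an individual has no genotyped class-i site) and the `mode`.
#' @export
load_realized <- function(geno, impact, genic = rep(TRUE, length(impact)),
                          mode = c("hom", "alleles")) {
  mode <- match.arg(mode)
  stopifnot(nrow(geno) == length(impact))
  g <- geno[genic, , drop = FALSE]
  imp <- factor(impact[genic], levels = CLASS_LEVELS)
  out <- matrix(NA_real_, ncol(g), length(CLASS_LEVELS),
                dimnames = list(colnames(g), CLASS_LEVELS))
  for (cl in CLASS_LEVELS) {
    gc <- g[imp == cl, , drop = FALSE]
    n_typed <- colSums(!is.na(gc))
    num <- if (mode == "hom") 2 * colSums(gc == 2L, na.rm = TRUE)
           else colSums(gc, na.rm = TRUE)
    out[, cl] <- ifelse(n_typed > 0, num / (2 * n_typed), NA_real_)
  }
  list(per_individual = out, mode = mode)
}

#' Welch's two-sample t-test
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @return list with `t`, `df`, `p`.
#' @export
#' @examples
#' welch_t(c(1, 2, 3), c(2, 4, 6))
welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = length(a) + length(b) - 2,
                                        p = 1))
  }
  tt <- t.test(a, b)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Per-individual load table with between-population tests
#'
#' Computes Load_P and Load_R for every individual, grouped by population,
#' and Welch's t-tests between every population pair for each impact class
#' and statistic.
#'
#' @param geno genotype matrix across all individuals.
#' @param impact impact class per site.
#' @param pop population label per individual (column).
#' @param genic logical genic mask per site.
#' @param mode Load_R mode, see [load_realized()].
#' @param p_adjust optional p-value adjustment method for the Welch tests
#'   (e.g. `"BH"`); default `"none"` mirrors per-test reporting.
#' @return list with `individual` (long data.frame: individual, pop, class,
#'   load_p, load_r), `population` (population-level Load_P proportions),
#'   and `tests` (Welch results per pair, class, statistic).
#' @export
load_table <- function(geno, impact, pop, genic = rep(TRUE, length(impact)),
                       mode = c("hom", "alleles"), p_adjust = "none") {
  mode <- match.arg(mode)
  stopifnot(ncol(geno) == length(pop))
  pops <- unique(pop)
  ind_rows <- list(); pop_rows <- list()
  per_pop <- list()
  for (pk in pops) {
    cols <- which(pop == pk)
    sub <- geno[, cols, drop = FALSE]
    # the population's gene pool: sites where it carries >= 1 alternate
    # allele, including sites fixed for the alternate within the population
    # (drift fixations of deleterious alleles are realized load)
    seg <- rowSums(sub, na.rm = TRUE) > 0
    segsub <- sub[seg, , drop = FALSE]
    lp <- load_potential(segsub, impact[seg], genic[seg])
    lr <- load_realized(segsub, impact[seg], genic[seg], mode = mode)
    per_pop[[pk]] <- list(lp = lp, lr = lr)
    for (cl in CLASS_LEVELS) {
      ind_rows[[length(ind_rows) + 1L]] <- data.frame(
        individual = colnames(sub) %||% paste0(pk, "_", seq_along(cols)),
        pop = pk, class = cl,
        load_p = lp$per_individual[, cl],
        load_r = lr$per_individual[, cl],
        stringsAsFactors = FALSE)
    }
    pop_rows[[pk]] <- data.frame(pop = pk, class = CLASS_LEVELS,
                                 load_p_pop = as.numeric(lp$population),
                                 n_genic = lp$n_genic,
                                 stringsAsFactors = FALSE)
  }
  tests <- list()
  if (length(pops) > 1) {
    prs <- utils::combn(pops, 2)
    for (k in seq_len(ncol(prs))) {
      pa <- prs[1, k]; pb <- prs[2, k]
      for (cl in CLASS_LEVELS) for (stat in c("load_p", "load_r")) {
        va <- per_pop[[pa]][[if (stat == "load_p") "lp" else "lr"]]$per_individual[, cl]
        vb <- per_pop[[pb]][[if (stat == "load_p") "lp" else "lr"]]$per_individual[, cl]
        va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
        if (length(va) >= 2 && length(vb) >= 2 &&
            (var(va) > 0 || var(vb) > 0)) {
          wt <- welch_t(va, vb)
          tests[[length(tests) + 1L]] <- data.frame(
            pop_a = pa, pop_b = pb, class = cl, statistic = stat,
            mean_a = mean(va), mean_b = mean(vb),
            t = wt$t, df = wt$df, p = wt$p, stringsAsFactors = FALSE)
        }
      }
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else NULL
  if (!is.null(tests) && p_adjust != "none")
    tests$p_adj <- stats::p.adjust(tests$p, method = p_adjust)
  list(individual = do.call(rbind, ind_rows),
       population = do.call(rbind, pop_rows),
       tests = tests,
       mode = mode)
}
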