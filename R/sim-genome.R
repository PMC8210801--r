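#' Genome architecture for the simulator
#'
#' Places `n_genes` non-overlapping genes on a single chromosome, each with a
#' 5' UTR, two CDS exons separated by one intron, and a 3' UTR, all on the
#' plus strand.  Flank windows of `flank` bp on either side of the gene body
#' are labelled upstream/downstream; everything else is intergenic.
#'
#' @param config a [sim_config()] object.
#' @param flank flank window size in bp (upstream/downstream annotation).
#' @param utr_len UTR length in bp.
#' @param intron_len intron length in bp.
#' @return a list with `genes` (one row per gene, 0-based half-open
#'   coordinates), `context` (character vector, one label per bp) and
#'   `cds_map` (per CDS bp: gene index and 0-based position within the CDS).
#' @keywords internal
genome_layout <- function(config, flank = 5000L, utr_len = 200L,
                          intron_len = 500L) {
  L <- config$seq_length
  ng <- config$n_genes
  context <- rep("intergenic", L)
  if (ng == 0) {
    return(list(genes = data.frame(), context = context,
                cds_gene = integer(0), cds_pos = integer(0),
                flank = flank))
  }
  cds_len <- config$gene_length
  cds1 <- (cds_len %/% 6L) * 3L          # exon 1 coding length (multiple of 3)
  cds2 <- cds_len - cds1
  body <- 2L * utr_len + cds1 + intron_len + cds2
  gap <- (L - ng * body) %/% (ng + 1L)
  if (gap < 1) stop("seq_length too small for the requested gene architecture")
  starts <- gap + (seq_len(ng) - 1L) * (body + gap)   # 0-based body starts

  genes <- data.frame(
    gene_id = sprintf("gene%03d", seq_len(ng)),
    strand = "+",
    body_start = starts,
    utr5_start = starts,
    cds1_start = starts + utr_len,
    intron_start = starts + utr_len + cds1,
    cds2_start = starts + utr_len + cds1 + intron_len,
    utr3_start = starts + utr_len + cds1 + intron_len + cds2,
    body_end = starts + body)
  genes$cds1_end <- genes$intron_start
  genes$cds2_end <- genes$utr3_start

  idx <- function(a, b) if (b > a) seq.int(a + 1L, b) else integer(0)  # 1-based
  # flanks first so gene features override them; where two genes' flanks
  # overlap the nearer gene wins (matching the classifier's rule)
  bestd <- rep(Inf, L)
  for (i in seq_len(ng)) {
    up <- idx(max(0L, genes$body_start[i] - flank), genes$body_start[i])
    d_up <- genes$body_start[i] + 1L - up
    dn <- idx(genes$body_end[i], min(L, genes$body_end[i] + flank))
    d_dn <- dn - genes$body_end[i]
    w <- d_dn < bestd[dn]
    context[dn[w]] <- "downstream"; bestd[dn[w]] <- d_dn[w]
    w <- d_up < bestd[up]
    context[up[w]] <- "upstream"; bestd[up[w]] <- d_up[w]
  }
  cds_gene <- integer(L); cds_pos <- integer(L)  # 1-indexed by genome pos + 1
  for (i in seq_len(ng)) {
    context[idx(genes$utr5_start[i], genes$cds1_start[i])] <- "UTR"
    context[idx(genes$utr3_start[i], genes$body_end[i])] <- "UTR"
    context[idx(genes$intron_start[i], genes$cds2_start[i])] <- "intron"
    c1 <- idx(genes$cds1_start[i], genes$cds1_end[i])
    c2 <- idx(genes$cds2_start[i], genes$cds2_end[i])
    context[c(c1, c2)] <- "CDS"
    cds_gene[c(c1, c2)] <- i
    cds_pos[c(c1, c2)] <- seq_along(c(c1, c2)) - 1L
  }
  list(genes = genes, context = context, cds_gene = cds_gene,
       cds_pos = cds_pos, flank = flank,
       utr_len = utr_len, intron_len = intron_len)
}

# Mutable positions (0-based) and their codon codes for the mutation model.
# Splice dinucleotides, the start codon and the stop codon are held invariant
# so that every non-CDS variant is MODIFIER and every CDS variant has an
# engineerable coding effect.
mutable_positions <- function(layout, seq_length) {
  blocked <- logical(seq_length)
  g <- layout$genes
  for (i in seq_len(nrow(g))) {
    # splice donor (first 2 intron bases) and acceptor (last 2)
    blocked[g$intron_start[i] + 1:2] <- TRUE
    blocked[g$cds2_start[i] - 1:0] <- TRUE
    blocked[g$cds1_start[i] + 1:3] <- TRUE        # start codon ATG
    blocked[g$cds2_end[i] - 2:0] <- TRUE          # stop codon
  }
  pos0 <- which(!blocked) - 1L
  codon <- ifelse(layout$context[pos0 + 1L] == "CDS",
                  (layout$cds_pos[pos0 + 1L] %% 3L) + 1L, 0L)
  list(pos = pos0, codon = as.integer(codon))
}

# draw impact-class codes (0 MOD, 1 HIGH, 2 MODERATE, 3 LOW) for mutations at
# given positions, matching the C++ engine's renormalisation rule (mid-codon
# changes cannot be synonymous under the standard genetic code)
draw_classes <- function(codon_code, class_probs) {
  n <- length(codon_code)
  out <- integer(n)
  coding <- codon_code > 0
  if (any(coding)) {
    ph <- class_probs[["high"]]; pm <- class_probs[["moderate"]]
    u <- runif(sum(coding))
    cc <- codon_code[coding]
    cl <- integer(sum(coding))
    mid <- cc == 2L
    cl[mid] <- ifelse(u[mid] < ph / (ph + pm), 1L, 2L)
    cl[!mid] <- ifelse(u[!mid] < ph, 1L,
                       ifelse(u[!mid] < ph + class_probs[["moderate"]], 2L, 3L))
    out[coding] <- cl
  }
  out
}

CLASS_LEVELS <- c("MODIFIER", "HIGH", "MODERATE", "LOW")

class_label <- function(code) CLASS_LEVELS[code + 1L]
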