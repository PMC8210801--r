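# shared fixtures and small oracles used across test files

# single-exon toy gene: ATG AAA TGC TAA on the plus strand, CDS at genome
# positions 1..12 (1-based)
toy_gene <- function() {
  list(list(gene_id = "toy1", strand = "+",
            cds = rbind(c(1, 12)), introns = NULL,
            utrs = NULL, body = c(1, 12)))
}
toy_ref <- "ATGAAATGCTAA"

# two-gene toy set exercising strand, introns and UTRs; returns models and a
# reference sequence.  Gene A: + strand with one intron; gene B: - strand.
toy_gene_set <- function() {
  # layout (1-based):
  #  1-10   intergenic
  # 11-16   gene A 5'UTR
  # 17-25   gene A CDS exon 1 (ATG AAA TGC)
  # 26-45   gene A intron (GT...AG)
  # 46-54   gene A CDS exon 2 (GGG TCA TAA)
  # 55-60   gene A 3'UTR
  # 61-70   intergenic
  # 71-82   gene B CDS on - strand: transcript ATG CCC TAA
  ref <- paste0(
    "CCCCCCCCCC",
    "TTTTTT",
    "ATGAAATGC",
    "GT", strrep("C", 16), "AG",
    "GGGTCATAA",
    "TTTTTT",
    "AAAAAAAAAA",
    "TTAGGGCATCCC"  # revcomp(GGGATGCCCTAA)... see below
  )
  # gene B transcript ATG CCC TAA on minus strand occupying 71..79:
  # genome 71..79 = revcomp("ATGCCCTAA") = "TTAGGGCAT"
  models <- list(
    list(gene_id = "gA", strand = "+",
         cds = rbind(c(17, 25), c(46, 54)),
         introns = rbind(c(26, 45)),
         utrs = rbind(c(11, 16), c(55, 60)),
         body = c(11, 60)),
    list(gene_id = "gB", strand = "-",
         cds = rbind(c(71, 79)),
         introns = NULL, utrs = NULL,
         body = c(71, 79)))
  list(models = models, ref = substr(ref, 1, 82))
}

# brute-force effect oracle: mutate the genome, re-extract and translate the
# CDS with Biostrings, and diff the proteins; splice sites handled by rule
brute_force_effect <- function(pos0, alt, models, ref) {
  refv <- strsplit(ref, "")[[1]]
  p1 <- pos0 + 1L
  for (mod in models) {
    cds_idx <- unlist(lapply(seq_len(nrow(mod$cds)), function(k)
      seq.int(mod$cds[k, 1], mod$cds[k, 2])))
    if (p1 %in% cds_idx) {
      mutv <- refv
      mutv[p1] <- alt
      get_prot <- function(v) {
        cds <- paste(v[cds_idx], collapse = "")
        d <- Biostrings::DNAString(cds)
        if (mod$strand == "-") d <- Biostrings::reverseComplement(d)
        # literal codon translation: initiator-codon special-casing would
        # silently turn start-lost changes into synonymous ones
        as.character(Biostrings::translate(d, no.init.codon = TRUE,
                                           if.fuzzy.codon = "X"))
      }
      ref_p <- get_prot(refv)
      alt_p <- get_prot(mutv)
      if (identical(ref_p, alt_p)) {
        # same protein: synonymous or stop_retained -> LOW
        return("LOW")
      }
      ref_a <- strsplit(ref_p, "")[[1]]
      alt_a <- strsplit(alt_p, "")[[1]]
      diff <- which(ref_a != alt_a)
      if (length(diff) == 0) return("LOW")
      i <- diff[1]
      if (i == 1 && ref_a[1] == "M") return("HIGH")          # start lost
      if (alt_a[i] == "*") return("HIGH")                    # stop gained
      if (ref_a[i] == "*") return("HIGH")                    # stop lost
      return("MODERATE")                                     # missense
    }
    if (!is.null(mod$introns)) {
      for (k in seq_len(nrow(mod$introns))) {
        a <- mod$introns[k, 1]; b <- mod$introns[k, 2]
        if (p1 >= a && p1 <= b) {
          if (p1 <= a + 1L || p1 >= b - 1L) return("HIGH")   # splice
          return("MODIFIER")
        }
      }
    }
  }
  "MODIFIER"
}

# tiny sim_truth stand-in for pileup unit tests
fake_truth <- function(geno, pos = seq_len(nrow(geno)) - 1L) {
  structure(list(chrom = "chr1", pos = pos,
                 true_genotypes = geno,
                 ancestral_allele = rep("A", nrow(geno)),
                 alt_allele = rep("T", nrow(geno)),
                 individual = sprintf("i%02d", seq_len(ncol(geno))),
                 pop = rep("pop1", ncol(geno))),
            class = "sim_truth")
}

# genotypes -> pileup -> gl_matrix at a given depth/error
gl_from_genotypes <- function(geno, depth = 20, e = 0.01) {
  cfg <- list(mean_depth = depth, error_rate = e)
  pile <- simulate_pileups(fake_truth(geno), config = cfg)
  gl_matrix(pile, e = e)
}

# small default-style config scaled for fast tests
small_sim_config <- function(...) {
  sim_config(n_pops = 1, pop_sizes = 60, seq_length = 60000, n_genes = 6,
             gene_length = 300, mu_sim = 5e-7, n_sample = 15, ...)
}
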