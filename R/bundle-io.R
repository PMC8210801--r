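#' Variant table from simulation truth
#'
#' Builds the called-variant-style table (positions, alleles, sample allele
#' frequency, context, impact class) directly from ground truth, bypassing
#' the read-evidence pipeline.  Used for writer round-trips and for oracle
#' cross-checks of the calling pipeline.
#'
#' @param truth a [simulate_populations()] result.
#' @return a `variant_table` data.frame.
#' @export
variant_table_from_truth <- function(truth) {
  n_chrom <- ncol(truth$haplotypes)
  af <- rowSums(truth$haplotypes) / n_chrom
  out <- data.frame(
    chrom = truth$chrom,
    pos = truth$pos,
    ref = truth$ancestral_allele,
    alt = truth$alt_allele,
    major = ifelse(af <= 0.5, truth$ancestral_allele, truth$alt_allele),
    minor = ifelse(af <= 0.5, truth$alt_allele, truth$ancestral_allele),
    af_alt = af,
    maf = pmin(af, 1 - af),
    n_ind = ncol(truth$true_genotypes),
    lrt_p = 0,
    hwe_p = 1,
    context = truth$site_context,
    impact_class = truth$site_class,
    stringsAsFactors = FALSE)
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Write a truth bundle to disk
#'
#' Emits the simulated dataset in standard interchange formats: a VCF v4.2
#' with true genotypes (and DP/AD/PL when a pileup is supplied), a GFF3 of
#' the gene models, a FASTA with the reference and ancestral sequences, a
#' long-format pileup TSV, and a truth JSON (classes, contexts, inbreeding,
#' pedigree, config).  Coordinates are 1-based in VCF/GFF3 and 0-based in
#' the pileup TSV.
#'
#' @param truth a [simulate_populations()] result.
#' @param config its [sim_config()].
#' @param outdir output directory (created if needed).
#' @param pileup optional [simulate_pileups()] result.
#' @return invisibly, the named vector of file paths written.
#' @export
write_truth_bundle <- function(truth, config = truth$config, outdir,
                               pileup = NULL) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  paths <- c(vcf = file.path(outdir, "variants.vcf"),
             gff = file.path(outdir, "genes.gff3"),
             fasta = file.path(outdir, "reference.fa"),
             pileup = file.path(outdir, "pileup.tsv"),
             truth = file.path(outdir, "truth.json"))

  # FASTA ------------------------------------------------------------------
  seqs <- Biostrings::DNAStringSet(c(chr1 = truth$reference,
                                     chr1_ancestral = truth$reference))
  Biostrings::writeXStringSet(seqs, paths["fasta"])

  # GFF3 -------------------------------------------------------------------
  g <- truth$layout$genes
  lines <- "##gff-version 3"
  row9 <- function(start0, end0, type, id, parent = NULL, phase = ".") {
    attrs <- paste0("ID=", id, if (!is.null(parent)) paste0(";Parent=", parent))
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t+\t%s\t%s",
            truth$chrom, "genload", type, start0 + 1L, end0, phase, attrs)
  }
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]; mid <- paste0(gid, ".t1")
    cds1_len <- g$cds1_end[i] - g$cds1_start[i]
    phase2 <- (3L - cds1_len %% 3L) %% 3L
    lines <- c(lines,
      row9(g$body_start[i], g$body_end[i], "gene", gid),
      row9(g$body_start[i], g$body_end[i], "mRNA", mid, gid),
      row9(g$utr5_start[i], g$cds1_start[i], "five_prime_UTR",
           paste0(mid, ".utr5"), mid),
      row9(g$cds1_start[i], g$cds1_end[i], "CDS", paste0(mid, ".cds"), mid,
           phase = "0"),
      row9(g$cds2_start[i], g$cds2_end[i], "CDS", paste0(mid, ".cds"), mid,
           phase = as.character(phase2)),
      row9(g$utr3_start[i], g$body_end[i], "three_prime_UTR",
           paste0(mid, ".utr3"), mid))
  }
  writeLines(lines, paths["gff"])

  # VCF --------------------------------------------------------------------
  ids <- truth$individual
  geno <- truth$true_genotypes
  gt <- matrix(c("0/0", "0/1", "1/1")[geno + 1L], nrow(geno), ncol(geno))
  fmt <- "GT"
  if (!is.null(pileup)) {
    stopifnot(identical(pileup$pos, truth$pos))
    gl <- gl_from_pileup(pileup$ref, pileup$alt, config$error_rate)
    pl <- function(x, m) pmax(0L, as.integer(round(-10 * (x - m) / log(10))))
    m3 <- pmax(gl$hom_ref, gl$het, gl$hom_alt)
    gt <- matrix(sprintf("%s:%d:%d,%d:%d,%d,%d", gt,
                         pileup$ref + pileup$alt, pileup$ref, pileup$alt,
                         pl(gl$hom_ref, m3), pl(gl$het, m3), pl(gl$hom_alt, m3)),
                 nrow(geno), ncol(geno))
    fmt <- "GT:DP:AD:PL"
  }
  vcf <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", truth$chrom, config$seq_length),
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
           "##INFO=<ID=IMPACT,Number=1,Type=String,Description=\"Impact class\">",
           "##INFO=<ID=CONTEXT,Number=1,Type=String,Description=\"Genomic context\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled GL\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  info <- sprintf("AA=%s;IMPACT=%s;CONTEXT=%s", truth$ancestral_allele,
                  truth$site_class, truth$site_context)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\t%s\t%s",
                  truth$chrom, truth$pos + 1L, truth$ancestral_allele,
                  truth$alt_allele, info, fmt,
                  apply(gt, 1, paste, collapse = "\t"))
  writeLines(c(vcf, body), paths["vcf"])

  # pileup TSV -------------------------------------------------------------
  if (!is.null(pileup)) {
    S <- length(pileup$pos); N <- ncol(pileup$ref)
    tab <- data.frame(chrom = truth$chrom,
                      pos0 = rep(pileup$pos, N),
                      individual = rep(ids, each = S),
                      ref_count = as.vector(pileup$ref),
                      alt_count = as.vector(pileup$alt))
    write.table(tab, paths["pileup"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else paths <- paths[names(paths) != "pileup"]

  # truth JSON --------------------------------------------------------------
  jsonlite::write_json(
    list(config = unclass(config),
         individuals = ids, pop = truth$pop,
         true_F = truth$true_F,
         pedigree = truth$pedigree,
         pos = truth$pos,
         site_class = truth$site_class,
         site_context = truth$site_context),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a truth bundle
#'
#' Re-reads the files written by [write_truth_bundle()] through standard
#' parsers (vcfR, rtracklayer, Biostrings) and reconstructs the variant
#' table, genotype matrix, gene models and pileup.
#'
#' @param dir bundle directory.
#' @return list with `variants` (a `variant_table`), `genotypes`, `models`,
#'   `reference`, `pileup` (or `NULL`), `truth_meta`.
#' @export
read_truth_bundle <- function(dir) {
  vcf <- vcfR::read.vcfR(file.path(dir, "variants.vcf"), verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  info <- fix[, "INFO"]
  grab <- function(key) sub(sprintf(".*%s=([^;]+).*", key), "\\1", info)
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  geno <- matrix(match(gt_raw, c("0/0", "0/1", "1/1")) - 1L,
                 nrow(gt_raw), ncol(gt_raw))
  colnames(geno) <- colnames(gt_raw)
  af <- rowMeans(geno, na.rm = TRUE) / 2
  variants <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]) - 1L,
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    major = ifelse(af <= 0.5, fix[, "REF"], fix[, "ALT"]),
    minor = ifelse(af <= 0.5, fix[, "ALT"], fix[, "REF"]),
    af_alt = af,
    maf = pmin(af, 1 - af),
    n_ind = ncol(geno),
    lrt_p = 0, hwe_p = 1,
    context = grab("CONTEXT"),
    impact_class = grab("IMPACT"),
    stringsAsFactors = FALSE)
  class(variants) <- c("variant_table", "data.frame")

  fa <- Biostrings::readDNAStringSet(file.path(dir, "reference.fa"))
  models <- gene_models_from_gff(file.path(dir, "genes.gff3"))

  pfile <- file.path(dir, "pileup.tsv")
  pileup <- NULL
  if (file.exists(pfile)) {
    tab <- read.table(pfile, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    ids <- unique(tab$individual)
    pos <- unique(tab$pos0)
    ref <- matrix(tab$ref_count, length(pos), length(ids))
    alt <- matrix(tab$alt_count, length(pos), length(ids))
    pileup <- as_pileup(ref, alt, pos = pos, chrom = tab$chrom[1],
                        individual = ids)
    pileup$ref_allele <- variants$ref
    pileup$alt_allele <- variants$alt
  }
  meta <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
  list(variants = variants, genotypes = geno, models = models,
       reference = as.character(fa[["chr1"]]), pileup = pileup,
       truth_meta = meta)
}
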