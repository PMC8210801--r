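#' Alignment set for sequence diversity statistics
#'
#' Wraps an aligned set of equal-length sequences with population labels and
#' a valid-site mask.  By default columns containing a gap or N in any
#' sequence are masked out of every statistic (complete deletion); pairwise
#' statistics can opt into pairwise deletion.
#'
#' @param seqs character vector of aligned sequences (equal length), or a
#'   list of per-sequence character vectors, or a `Biostrings::DNAStringSet`.
#' @param pops optional population label per sequence.
#' @param ids sequence ids.
#' @param trim_ends bases to trim from either end before analysis (circular
#'   alignment artifact control; default 0).
#' @return object of class `alignment_set`: `mat` (character matrix,
#'   sequences x columns), `mask` (logical, valid columns), `pops`, `ids`.
#' @export
alignment_set <- function(seqs, pops = NULL, ids = NULL, trim_ends = 0) {
  if (inherits(seqs, "DNAStringSet")) {
    if (is.null(ids)) ids <- names(seqs)
    seqs <- as.character(seqs)
  }
  if (is.list(seqs)) seqs <- vapply(seqs, paste, character(1), collapse = "")
  if (length(unique(nchar(seqs))) != 1)
    stop("sequences must be aligned to equal length")
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  if (trim_ends > 0) {
    keep <- seq.int(trim_ends + 1L, ncol(mat) - trim_ends)
    mat <- mat[, keep, drop = FALSE]
  }
  mask <- colSums(mat == "N" | mat == "-") == 0
  if (is.null(ids)) ids <- sprintf("seq%02d", seq_len(nrow(mat)))
  structure(list(mat = mat, mask = mask,
                 pops = pops, ids = ids), class = "alignment_set")
}

#' Haplotype statistics of an alignment
#'
#' Unique sequences over the valid (ungapped, N-free) columns define the
#' haplotypes; haplotype diversity is `Hd = n (1 - sum p_h^2) / (n - 1)`;
#' parsimony-informative columns have at least two alleles each present in
#' at least two sequences.
#'
#' @param aln an [alignment_set()] (optionally pre-subset).
#' @return list with `n_haplotypes`, `hd`, `n_parsimony_informative`,
#'   `haplotype` (index per sequence).
#' @export
haplotype_stats <- function(aln) {
  stopifnot(inherits(aln, "alignment_set"))
  m <- aln$mat[, aln$mask, drop = FALSE]
  n <- nrow(m)
  if (n < 2) stop("need at least 2 sequences")
  key <- apply(m, 1, paste, collapse = "")
  hap <- as.integer(factor(key, levels = unique(key)))
  ph <- as.numeric(table(hap)) / n
  hd <- n * (1 - sum(ph^2)) / (n - 1)
  pi_inf <- sum(apply(m, 2, function(col) {
    tb <- table(col)
    sum(tb >= 2) >= 2
  }))
  list(n_haplotypes = length(unique(hap)), hd = hd,
       n_parsimony_informative = pi_inf, haplotype = hap)
}

#' Per-site nucleotide diversity of an alignment
#'
#' Mean pairwise difference per valid site over all sequence pairs.
#'
#' @param aln an [alignment_set()].
#' @return per-site pi.
#' @export
nucleotide_diversity <- function(aln) {
  stopifnot(inherits(aln, "alignment_set"))
  m <- aln$mat[, aln$mask, drop = FALSE]
  n <- nrow(m)
  if (n < 2) stop("need at least 2 sequences")
  L <- ncol(m)
  if (L == 0) return(0)
  total <- 0
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n))
    total <- total + sum(m[i, ] != m[j, ])
  total / (n * (n - 1) / 2) / L
}

.purines <- c("A", "G")
.pyrimidines <- c("C", "T")

#' Kimura two-parameter distance
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` with `P` and `Q` the
#' transition and transversion proportions over jointly valid sites.
#' Saturated pairs (non-positive log arguments) return `NA` with a warning.
#'
#' @param seq_a,seq_b aligned sequences (character scalars or vectors).
#' @return the K2P distance.
#' @export
#' @examples
#' k2p_distance("ACGT", "ACGA")
k2p_distance <- function(seq_a, seq_b) {
  a <- toupper(split_chars(seq_a)); b <- toupper(split_chars(seq_b))
  stopifnot(length(a) == length(b))
  valid <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(valid)) stop("no valid sites")
  a <- a[valid]; b <- b[valid]
  diff <- a != b
  ts <- diff & ((a %in% .purines & b %in% .purines) |
                  (a %in% .pyrimidines & b %in% .pyrimidines))
  P <- mean(ts); Q <- mean(diff & !ts)
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) {
    warning("K2P distance saturated; returning NA")
    return(NA_real_)
  }
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

#' K2P distance matrix of an alignment
#'
#' @param aln an [alignment_set()].
#' @return symmetric matrix of pairwise K2P distances (zero diagonal).
#' @export
k2p_matrix <- function(aln) {
  m <- aln$mat[, aln$mask, drop = FALSE]
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n))
    D[i, j] <- D[j, i] <- k2p_distance(m[i, ], m[j, ])
  D
}

#' Subsampled between-population comparison of a diversity statistic
#'
#' Draws `n_sub` sequences per population without replacement, `n_perm`
#' times, recomputing `statistic` for each population each time; the
#' empirical two-sided p-value is twice the proportion of permutations in
#' which the between-population difference has the opposite sign to (or
#' reverses) the mean difference, capped at 1.  A Welch t-test on the
#' permutation values is reported as a labelled secondary output.
#'
#' @param aln an [alignment_set()] with population labels.
#' @param pop_a,pop_b the two population labels to compare.
#' @param n_sub sequences per population per draw (default 7).
#' @param n_perm permutations (default 100).
#' @param statistic function of an `alignment_set` returning a scalar
#'   (default [nucleotide_diversity()]).
#' @return list with per-permutation `stat_a`, `stat_b`, the observed means,
#'   `p_empirical` and `welch` (secondary).
#' @export
subsample_compare <- function(aln, pop_a, pop_b, n_sub = 7, n_perm = 100,
                              statistic = nucleotide_diversity) {
  stopifnot(inherits(aln, "alignment_set"), !is.null(aln$pops))
  ia <- which(aln$pops == pop_a); ib <- which(aln$pops == pop_b)
  if (length(ia) < n_sub || length(ib) < n_sub)
    stop("population smaller than the subsample size")
  sub_aln <- function(idx) {
    structure(list(mat = aln$mat[idx, , drop = FALSE], mask = aln$mask,
                   pops = aln$pops[idx], ids = aln$ids[idx]),
              class = "alignment_set")
  }
  stat_a <- numeric(n_perm); stat_b <- numeric(n_perm)
  for (k in seq_len(n_perm)) {
    stat_a[k] <- statistic(sub_aln(sample(ia, n_sub)))
    stat_b[k] <- statistic(sub_aln(sample(ib, n_sub)))
  }
  d <- stat_a - stat_b
  md <- mean(d)
  p_emp <- if (md == 0) 1 else min(1, 2 * mean(sign(d) != sign(md)))
  welch <- if (n_perm >= 2 && (var(stat_a) > 0 || var(stat_b) > 0))
    welch_t(stat_a, stat_b) else list(t = NA_real_, df = NA_real_, p = NA_real_)
  list(stat_a = stat_a, stat_b = stat_b,
       mean_a = mean(stat_a), mean_b = mean(stat_b),
       p_empirical = p_emp, welch = welch)
}
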