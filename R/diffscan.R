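#' Sliding windows over a chromosome
#'
#' @param chrom_length chromosome length in bp.
#' @param win window width (default 100,000).
#' @param step step between window starts (default 50,000).
#' @return data.frame with 0-based half-open `start`/`end`.
#' @export
make_windows <- function(chrom_length, win = 100000, step = 50000) {
  starts <- seq(0, max(0, chrom_length - 1), by = step)
  out <- data.frame(start = starts, end = pmin(starts + win, chrom_length))
  out[out$end > out$start, , drop = FALSE]
}

# Hudson/Bhatia per-site Fst components with sample-size correction.
# p1, p2: allele frequencies; n1, n2: chromosomes with data.
hudson_components <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(num = num, den = den)
}

#' Windowed and global Hudson Fst
#'
#' Hudson's estimator with sample-size correction, combined as a ratio of
#' sums within each window: `N = (p1-p2)^2 - p1(1-p1)/(n1-1) -
#' p2(1-p2)/(n2-1)`, `D = p1(1-p2) + p2(1-p1)`, `Fst = sum(N)/sum(D)`.
#' The global estimate is the ratio of sums over all sites, with a 95% CI
#' from site bootstraps.  Negative window values are retained (clipping
#' would distort the null standard deviation used by the outlier scan).
#'
#' @param pos 0-based site positions.
#' @param p1,p2 per-site allele frequencies in the two populations.
#' @param n1,n2 chromosomes with data per site in each population (scalars
#'   or vectors); both must be >= 2 for a site to be used.
#' @param windows data.frame from [make_windows()]; `NULL` gives only the
#'   global estimate.
#' @param n_boot site bootstraps for the global CI (default 100).
#' @return list with `windows` (per-window `fst`, `n_sites`; `NA` for empty
#'   windows), `global`, `global_ci`.
#' @export
fst_window <- function(pos, p1, p2, n1, n2, windows = NULL, n_boot = 100) {
  n1 <- rep_len(n1, length(pos)); n2 <- rep_len(n2, length(pos))
  use <- n1 >= 2 & n2 >= 2 & !is.na(p1) & !is.na(p2)
  pos <- pos[use]
  hc <- hudson_components(p1[use], p2[use], n1[use], n2[use])
  global <- sum(hc$num) / sum(hc$den)
  boot <- replicate(n_boot, {
    i <- sample.int(length(pos), length(pos), replace = TRUE)
    sum(hc$num[i]) / sum(hc$den[i])
  })
  out <- list(global = global,
              global_ci = unname(quantile(boot, c(0.025, 0.975))))
  if (!is.null(windows)) {
    wfst <- numeric(nrow(windows)); wn <- integer(nrow(windows))
    for (w in seq_len(nrow(windows))) {
      inw <- pos >= windows$start[w] & pos < windows$end[w]
      wn[w] <- sum(inw)
      wfst[w] <- if (wn[w] > 0) sum(hc$num[inw]) / sum(hc$den[inw]) else NA_real_
    }
    out$windows <- cbind(windows, data.frame(n_sites = wn, fst = wfst))
  }
  out
}

#' Z-transformed Fst outlier scan
#'
#' Standardises window Fst values around their mean and flags windows more
#' than `z_cut` standard deviations away.  Windows with fewer than
#' `min_sites` usable sites are excluded first (low-data windows produce
#' spuriously extreme values).
#'
#' @param window_fst data.frame with `fst` and `n_sites` columns (from
#'   [fst_window()]).
#' @param z_cut outlier threshold in SD units (default 5).
#' @param min_sites per-window site floor (default 10).
#' @return the input with `z_fst` and logical `outlier` columns (`NA` for
#'   excluded windows).
#' @export
z_fst_outliers <- function(window_fst, z_cut = 5, min_sites = 10) {
  ok <- !is.na(window_fst$fst) & window_fst$n_sites >= min_sites
  if (sum(ok) < 2) stop("need at least 2 usable windows")
  v <- window_fst$fst[ok]
  s <- sd(v)
  z <- if (s > 0) (v - mean(v)) / s else rep(0, length(v))
  window_fst$z_fst <- NA_real_
  window_fst$z_fst[ok] <- z
  window_fst$outlier <- !is.na(window_fst$z_fst) &
    abs(window_fst$z_fst) > z_cut
  window_fst
}

#' Windowed absolute divergence (Dxy)
#'
#' Per-site `dxy = p1 (1 - p2) + p2 (1 - p1)`, summed over variant sites in
#' each window and divided by the window length in bp (sites fixed in one
#' population still contribute, monomorphic-in-both sites contribute zero).
#'
#' @inheritParams fst_window
#' @param windows data.frame from [make_windows()].
#' @return the `windows` frame with `n_sites` and `dxy` columns.
#' @export
dxy_window <- function(pos, p1, p2, windows) {
  d <- p1 * (1 - p2) + p2 * (1 - p1)
  out <- windows
  out$n_sites <- 0L; out$dxy <- 0
  for (w in seq_len(nrow(windows))) {
    inw <- pos >= windows$start[w] & pos < windows$end[w]
    out$n_sites[w] <- sum(inw)
    out$dxy[w] <- sum(d[inw]) / (windows$end[w] - windows$start[w])
  }
  out
}

# Fu & Li (1993) variance coefficients (with the corrected u_F/v_F), for a
# sample of n chromosomes with an outgroup (polarised mutations).
fu_li_coeffs <- function(n) {
  stopifnot(n >= 3)
  a_n <- harmonic(n - 1)
  b_n <- sum(1 / seq_len(n - 1)^2)
  c_n <- if (n == 2) 1 else 2 * (n * a_n - 2 * (n - 1)) / ((n - 1) * (n - 2))
  v_D <- 1 + a_n^2 / (b_n + a_n^2) * (c_n - (n + 1) / (n - 1))
  u_D <- a_n - 1 - v_D
  v_F <- (c_n + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) - 2 / (n - 1)) /
    (a_n^2 + b_n)
  u_F <- (1 + (n + 1) / (3 * (n - 1)) -
            4 * (n + 1) / (n - 1)^2 * (harmonic(n) - 2 * n / (n + 1))) /
    a_n - v_F
  list(a_n = a_n, u_D = u_D, v_D = v_D, u_F = u_F, v_F = v_F)
}

#' Fu & Li's D and F neutrality statistics
#'
#' Computed from ancestrally polarised derived-allele counts:
#' `D = (eta - a_n eta_s) / sqrt(u_D eta + v_D eta^2)` contrasts total
#' mutations `eta` against singletons `eta_s`;
#' `F = (pi - eta_s) / sqrt(u_F eta + v_F eta^2)` uses mean pairwise
#' differences `pi` instead.  Undefined (returns `NA`) when `eta = 0`.
#' An excess of rare (singleton) variants — as after an expansion — drives
#' both statistics negative; a deficit after a bottleneck drives them
#' positive.
#'
#' @param derived_counts integer vector of derived-allele counts, one per
#'   segregating site, each in `1..(n_chrom-1)`.
#' @param n_chrom number of sampled chromosomes.
#' @return list with `eta`, `eta_s`, `pi`, `fu_li_d`, `fu_li_f`.
#' @export
fu_li_stats <- function(derived_counts, n_chrom) {
  stopifnot(n_chrom >= 3)
  dc <- derived_counts[!is.na(derived_counts)]
  if (any(dc < 1 | dc > n_chrom - 1))
    stop("derived counts must be in 1..(n_chrom - 1) for segregating sites")
  eta <- length(dc)
  if (eta == 0)
    return(list(eta = 0L, eta_s = 0L, pi = 0,
                fu_li_d = NA_real_, fu_li_f = NA_real_))
  eta_s <- sum(dc == 1L)
  pi <- sum(2 * dc * (n_chrom - dc)) / (n_chrom * (n_chrom - 1))
  co <- fu_li_coeffs(n_chrom)
  D <- (eta - co$a_n * eta_s) / sqrt(co$u_D * eta + co$v_D * eta^2)
  F <- (pi - eta_s) / sqrt(co$u_F * eta + co$v_F * eta^2)
  list(eta = eta, eta_s = eta_s, pi = pi, fu_li_d = D, fu_li_f = F)
}

#' Windowed Fu & Li statistics
#'
#' @param pos 0-based positions of polarised segregating sites.
#' @param derived_counts derived-allele counts per site.
#' @param n_chrom sampled chromosomes.
#' @param windows data.frame from [make_windows()].
#' @return `windows` with `eta`, `eta_s`, `fu_li_d`, `fu_li_f` per window.
#' @export
fu_li_window <- function(pos, derived_counts, n_chrom, windows) {
  out <- windows
  out$eta <- 0L; out$eta_s <- 0L
  out$fu_li_d <- NA_real_; out$fu_li_f <- NA_real_
  for (w in seq_len(nrow(windows))) {
    inw <- pos >= windows$start[w] & pos < windows$end[w]
    st <- fu_li_stats(derived_counts[inw], n_chrom)
    out$eta[w] <- st$eta; out$eta_s[w] <- st$eta_s
    out$fu_li_d[w] <- st$fu_li_d; out$fu_li_f[w] <- st$fu_li_f
  }
  out
}
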