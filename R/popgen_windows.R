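#' Tile chromosomes into non-overlapping windows
#'
#' Windows are 0-based half-open and anchored at coordinate 0; the terminal
#' window of each chromosome is kept (and flagged) even when shorter than
#' `window_size`.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param window_size window size in bp.
#' @return data.frame(chrom, start, end, partial).
#' @export
make_windows <- function(chrom_lengths, window_size) {
  abort_if(window_size <= 0, "window_size must be > 0")
  abort_if(is.null(names(chrom_lengths)), "chrom_lengths must be named")
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, max(0, len - 1), by = window_size)
    ends <- pmin(starts + window_size, len)
    data.frame(chrom = ch, start = starts, end = ends,
               partial = (ends - starts) < window_size,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## per-site pi ingredients: n = non-missing allele count, p = alt frequency
site_freq <- function(geno) {
  nonmiss <- !is.na(geno)
  n <- 2L * rowSums(nonmiss)
  ac <- rowSums(geno, na.rm = TRUE)
  list(n = n, p = ifelse(n > 0, ac / n, NA_real_))
}

#' Windowed nucleotide diversity (pi)
#'
#' Per window, pi = (1/L) * sum over sites of n/(n-1) * 2 p (1-p), where n is
#' the non-missing allele count at the site, p the alt-allele frequency and L
#' the full window length (monomorphic positions count in the denominator,
#' the windowed-pi convention of vcftools). Windows without usable variant
#' sites get 0.
#'
#' @param geno variant_set (biallelic SNPs).
#' @param samples sample ids to use.
#' @param windows data.frame from [make_windows()].
#' @return windows with columns statistic_name, value, n_sites appended.
#' @export
window_pi <- function(geno, samples, windows) {
  g <- geno$geno[, samples, drop = FALSE]
  sf <- site_freq(g)
  use <- sf$n >= 2 & !is.na(sf$p) & sf$p > 0 & sf$p < 1
  contrib <- ifelse(use, sf$n / (sf$n - 1) * 2 * sf$p * (1 - sf$p), 0)
  wsize <- max(windows$end - windows$start)
  key_w <- paste(windows$chrom, window_index(windows$start + 1L, wsize))
  key_s <- paste(geno$info$chrom, window_index(geno$info$pos, wsize))
  idx <- match(key_s, key_w)
  sums <- rep(0, nrow(windows)); nsites <- rep(0L, nrow(windows))
  ok <- !is.na(idx)
  if (any(ok)) {
    sums[sort(unique(idx[ok]))] <-
      rowsum(contrib[ok], idx[ok], reorder = TRUE)[, 1]
    nsites[sort(unique(idx[ok]))] <-
      rowsum(as.integer(use[ok]), idx[ok], reorder = TRUE)[, 1]
  }
  windows$statistic_name <- "pi"
  windows$value <- sums / (windows$end - windows$start)
  windows$n_sites <- nsites
  windows
}

## Weir & Cockerham (1984) per-site variance components for two populations.
## Returns a, b, c vectors; sites unusable in either group get NA.
wc_components <- function(geno, groupA, groupB) {
  gA <- geno[, groupA, drop = FALSE]; gB <- geno[, groupB, drop = FALSE]
  nA <- rowSums(!is.na(gA)); nB <- rowSums(!is.na(gB))   # diploid counts
  pA <- ifelse(nA > 0, rowSums(gA, na.rm = TRUE) / (2 * nA), NA_real_)
  pB <- ifelse(nB > 0, rowSums(gB, na.rm = TRUE) / (2 * nB), NA_real_)
  hA <- ifelse(nA > 0, rowSums(gA == 1L, na.rm = TRUE) / nA, NA_real_)
  hB <- ifelse(nB > 0, rowSums(gB == 1L, na.rm = TRUE) / nB, NA_real_)
  r <- 2
  nbar <- (nA + nB) / r
  usable <- nA >= 1 & nB >= 1 & nbar > 1
  nc <- (r * nbar - (nA^2 + nB^2) / (r * nbar)) / (r - 1)
  pbar <- (nA * pA + nB * pB) / (r * nbar)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nA * hA + nB * hB) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  poly <- !is.na(pbar) & pbar > 0 & pbar < 1
  usable <- usable & poly
  a[!usable] <- NA_real_; b[!usable] <- NA_real_; cc[!usable] <- NA_real_
  list(a = a, b = b, c = cc, usable = usable)
}

#' Windowed Weir-Cockerham FST
#'
#' Two-population Weir & Cockerham (1984) estimator in the weighted windowed
#' form: theta-hat = sum(a) / sum(a + b + c) over contributing sites. Sites
#' monomorphic over both groups or with a fully missing group are skipped;
#' windows with no contributing site are NA (undefined).
#'
#' @inheritParams window_pi
#' @param groupA,groupB disjoint sample id vectors (>= 2 samples each for a
#'   meaningful estimate; >= 1 accepted).
#' @return windows with statistic_name, value, n_sites appended.
#' @export
window_fst <- function(geno, groupA, groupB, windows) {
  comp <- wc_components(geno$geno, groupA, groupB)
  wsize <- max(windows$end - windows$start)
  key_w <- paste(windows$chrom, window_index(windows$start + 1L, wsize))
  key_s <- paste(geno$info$chrom, window_index(geno$info$pos, wsize))
  idx <- match(key_s, key_w)
  ok <- comp$usable & !is.na(idx)
  num <- rep(0, nrow(windows)); den <- rep(0, nrow(windows))
  nsites <- rep(0L, nrow(windows))
  if (any(ok)) {
    u <- sort(unique(idx[ok]))
    num[u] <- rowsum(comp$a[ok], idx[ok], reorder = TRUE)[, 1]
    den[u] <- rowsum((comp$a + comp$b + comp$c)[ok], idx[ok], reorder = TRUE)[, 1]
    nsites[u] <- rowsum(rep(1L, sum(ok)), idx[ok], reorder = TRUE)[, 1]
  }
  windows$statistic_name <- "fst"
  windows$value <- ifelse(nsites > 0 & den != 0, num / den, NA_real_)
  windows$n_sites <- nsites
  windows
}

#' Select low-diversity (LDGR) and high-divergence (HDGR) windows
#'
#' LDGRs are the windows in the lowest `low_q` tail of pi; HDGRs the highest
#' `high_q` tail of FST. Tails use a closed threshold, so tied windows are
#' all included and the selected count can exceed the nominal fraction.
#'
#' @param pi_stats,fst_stats window stats from [window_pi()] / [window_fst()]
#'   over the same window grid (either may be NULL).
#' @param low_q,high_q tail fractions (default 0.05 each).
#' @return list(ldgr, hdgr, overlap): selected window data.frames and their
#'   intersection (by chrom/start/end).
#' @export
select_ldgr_hdgr <- function(pi_stats, fst_stats, low_q = 0.05, high_q = 0.05) {
  ldgr <- hdgr <- NULL
  if (!is.null(pi_stats)) {
    if (sum(!is.na(pi_stats$value)) < 1 / low_q)
      warning("fewer than 1/low_q windows; quantile still applied")
    ldgr <- pi_stats[tail_select(pi_stats$value, low_q, lower = TRUE), , drop = FALSE]
  }
  if (!is.null(fst_stats))
    hdgr <- fst_stats[tail_select(fst_stats$value, high_q, lower = FALSE), , drop = FALSE]
  overlap <- NULL
  if (!is.null(ldgr) && !is.null(hdgr)) {
    key <- function(d) paste(d$chrom, d$start, d$end)
    overlap <- ldgr[key(ldgr) %in% key(hdgr), c("chrom", "start", "end"), drop = FALSE]
  }
  list(ldgr = ldgr, hdgr = hdgr, overlap = overlap)
}

#' Greedy LD pruning of a SNP panel
#'
#' Sliding windows of `window_n_snps` SNPs advanced by `step`; within each
#' window, for every ordered pair of still-kept SNPs with squared dosage
#' correlation above `r2_max` (missing values pairwise-deleted), the
#' right-hand SNP is dropped. Deterministic left-to-right order per
#' chromosome.
#'
#' @param geno variant_set (dosage matrix used).
#' @param window_n_snps,step,r2_max pruning parameters (defaults 50/5/0.2).
#' @return pruned variant_set.
#' @export
ld_prune <- function(geno, window_n_snps = 50L, step = 5L, r2_max = 0.2) {
  keep <- rep(TRUE, nrow(geno$info))
  for (ch in unique(geno$info$chrom)) {
    idx <- which(geno$info$chrom == ch)
    m <- length(idx)
    if (m < 2) next
    starts <- seq(1L, m, by = step)
    for (s in starts) {
      w <- idx[s:min(s + window_n_snps - 1L, m)]
      w <- w[keep[w]]
      if (length(w) < 2) next
      cm <- suppressWarnings(
        cor(geno$geno[w, , drop = FALSE] |> t(),
            use = "pairwise.complete.obs"))
      r2 <- cm^2
      for (i in seq_len(length(w) - 1L)) {
        if (!keep[w[i]]) next
        for (j in seq(i + 1L, length(w))) {
          if (keep[w[j]] && isTRUE(r2[i, j] > r2_max)) keep[w[j]] <- FALSE
        }
      }
    }
  }
  subset_variants(geno, sites = keep)
}

#' Principal component analysis of a feature-by-sample matrix
#'
#' Features (rows) are mean-imputed at missing entries, centered, and for
#' genotype dosages variance-standardized; zero-variance features are
#' dropped. Sample coordinates come from the singular value decomposition of
#' the resulting matrix.
#'
#' @param mat numeric matrix, features x samples (dosages or beta values).
#' @param n_components number of components to return.
#' @param standardize divide each centered feature by its standard deviation
#'   (default TRUE, the genotype convention; use FALSE for beta values).
#' @return list(coordinates: samples x PCs, explained: variance fractions,
#'   n_features).
#' @export
genotype_pca <- function(mat, n_components = 10L, standardize = TRUE) {
  m <- as.matrix(mat)
  rm_ <- rowMeans(m, na.rm = TRUE)
  miss <- is.na(m)
  if (any(miss)) m[miss] <- rm_[row(m)[miss]]
  m <- m - rowMeans(m)
  v <- apply(m, 1, stats::var)
  keep <- v > 0 & !is.na(v)
  if (!all(keep)) {
    message(sum(!keep), " zero-variance features dropped")
    m <- m[keep, , drop = FALSE]; v <- v[keep]
  }
  abort_if(nrow(m) == 0L, "no features with nonzero variance")
  if (standardize) m <- m / sqrt(v)
  p <- stats::prcomp(t(m), center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(p$x))
  expl <- p$sdev^2 / sum(p$sdev^2)
  list(coordinates = p$x[, seq_len(k), drop = FALSE],
       explained = expl[seq_len(k)], n_features = nrow(m))
}
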