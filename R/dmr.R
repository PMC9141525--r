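#' Cochran-Mantel-Haenszel test over 2x2 strata
#'
#' Chi-square form without continuity correction:
#' chi2 = (sum_k (a_k - E_k))^2 / sum_k V_k, where a_k is the group-A
#' methylated count of stratum k and E_k, V_k are the hypergeometric mean
#' and variance of a_k given the stratum margins. Strata with any zero
#' margin are uninformative and skipped.
#'
#' @param strata list of 2x2 matrices (rows = groups, cols = outcome), or a
#'   2 x 2 x K array.
#' @return list(statistic, p_value, n_strata). When no stratum is
#'   informative the test is undefined (all NA, n_strata = 0).
#' @export
cmh_test <- function(strata) {
  if (is.array(strata) && length(dim(strata)) == 3L)
    strata <- lapply(seq_len(dim(strata)[3]), function(k) strata[, , k])
  a <- e <- v <- numeric(0)
  for (tb in strata) {
    r1 <- sum(tb[1, ]); r2 <- sum(tb[2, ])
    c1 <- sum(tb[, 1]); c2 <- sum(tb[, 2])
    n <- r1 + r2
    if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) next
    a <- c(a, tb[1, 1])
    e <- c(e, r1 * c1 / n)
    v <- c(v, r1 * r2 * c1 * c2 / (n^2 * (n - 1)))
  }
  if (!length(a) || sum(v) == 0)
    return(list(statistic = NA_real_, p_value = NA_real_, n_strata = length(a)))
  stat <- (sum(a) - sum(e))^2 / sum(v)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       n_strata = length(a))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement, order-preserving with the
#' input vector.
#'
#' @param p numeric p values in [0, 1]; NA entries are an error.
#' @return adjusted p values.
#' @export
bh_adjust <- function(p) {
  abort_if(anyNA(p), "NA p values are not allowed")
  abort_if(any(p < 0 | p > 1), "p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Windowed CMH scan for differentially methylated regions
#'
#' The genome is tiled into non-overlapping `window`-bp windows (anchored at
#' coordinate 0 per chromosome). Within a window each CG site is one CMH
#' stratum, with read counts pooled over the covered samples of each group
#' at that site. Windows with fewer than `min_sites` informative strata are
#' left untested and excluded from the BH family; BH runs over all tested
#' windows genome-wide. A window is a DMR when adjusted p < `alpha` and the
#' pooled methylation divergence |beta_A - beta_B| exceeds `min_div`.
#'
#' @param mm methylation_matrix (depth-filtered, see
#'   [build_methylation_matrix()]).
#' @param groupA,groupB disjoint sample id vectors (>= 2 samples each).
#' @param window window size in bp (default 100).
#' @param min_sites minimum informative strata per tested window (default 3).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param min_div minimum pooled-beta divergence (default 0.25).
#' @return data.frame of DMR records: chrom, start, end (0-based half-open),
#'   comparison, cmh_statistic, p_value, p_adjusted, divergence, n_strata,
#'   tested, is_dmr.
#' @export
scan_dmrs <- function(mm, groupA, groupB, window = 100L, min_sites = 3L,
                      alpha = 0.05, min_div = 0.25) {
  abort_if(!length(groupA) || !length(groupB), "empty group")
  abort_if(length(intersect(groupA, groupB)) > 0, "groups must be disjoint")
  methA <- rowSums(mm$meth[, groupA, drop = FALSE], na.rm = TRUE)
  totA  <- rowSums(mm$total[, groupA, drop = FALSE], na.rm = TRUE)
  methB <- rowSums(mm$meth[, groupB, drop = FALSE], na.rm = TRUE)
  totB  <- rowSums(mm$total[, groupB, drop = FALSE], na.rm = TRUE)
  unmA <- totA - methA; unmB <- totB - methB
  n <- totA + totB
  cM <- methA + methB; cU <- unmA + unmB
  informative <- totA > 0 & totB > 0 & cM > 0 & cU > 0
  e <- ifelse(informative, totA * cM / n, 0)
  v <- ifelse(informative, totA * totB * cM * cU / (n^2 * (n - 1)), 0)
  a <- ifelse(informative, methA, 0)

  widx <- window_index(mm$pos, window)
  key <- paste0(mm$chrom, ":", widx)
  grp <- factor(key, levels = unique(key))
  sum_by <- function(x) rowsum(x, grp, reorder = FALSE)[, 1]
  S_a <- sum_by(a); S_e <- sum_by(e); S_v <- sum_by(v)
  K <- sum_by(as.numeric(informative))
  W_methA <- sum_by(methA); W_totA <- sum_by(totA)
  W_methB <- sum_by(methB); W_totB <- sum_by(totB)

  first <- !duplicated(key)
  chrom <- mm$chrom[first]; wi <- widx[first]
  stat <- ifelse(S_v > 0, (S_a - S_e)^2 / S_v, NA_real_)
  tested <- K >= min_sites & S_v > 0
  pval <- rep(NA_real_, length(stat))
  pval[tested] <- stats::pchisq(stat[tested], df = 1, lower.tail = FALSE)
  padj <- rep(NA_real_, length(stat))
  if (any(tested)) padj[tested] <- bh_adjust(pval[tested])
  div <- abs(ifelse(W_totA > 0, W_methA / W_totA, NA_real_) -
             ifelse(W_totB > 0, W_methB / W_totB, NA_real_))
  out <- data.frame(
    chrom = chrom,
    start = wi * as.integer(window),
    end = (wi + 1L) * as.integer(window),
    comparison = paste0(paste(groupA, collapse = ","), " vs ",
                        paste(groupB, collapse = ",")),
    cmh_statistic = stat, p_value = pval, p_adjusted = padj,
    divergence = div, n_strata = as.integer(K), tested = tested,
    stringsAsFactors = FALSE)
  out$is_dmr <- !is.na(out$p_adjusted) & out$p_adjusted < alpha &
    !is.na(out$divergence) & out$divergence > min_div
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Call differentially methylated genes from DMR windows
#'
#' Per gene, the union of overlapping DMR windows is intersected with the
#' genic interval; genes whose covered fraction strictly exceeds
#' `threshold` are DMGs.
#'
#' @param dmrs data.frame from [scan_dmrs()] (only rows with is_dmr used).
#' @param genes gene model table (gene_id, chrom, start, end; 1-based
#'   inclusive).
#' @param threshold genic fraction cutoff (default 0.20, strict >).
#' @return data.frame(gene_id, dmr_bases, gene_length, fraction, is_dmg).
#' @export
call_dmgs <- function(dmrs, genes, threshold = 0.20) {
  d <- dmrs[dmrs$is_dmr, , drop = FALSE]
  dmr_bases <- integer(nrow(genes))
  if (nrow(d)) {
    gr_d <- GenomicRanges::reduce(GenomicRanges::GRanges(
      d$chrom, IRanges::IRanges(d$start + 1L, d$end)))
    gr_g <- GenomicRanges::GRanges(genes$chrom,
                                   IRanges::IRanges(genes$start, genes$end))
    hits <- GenomicRanges::findOverlaps(gr_g, gr_d)
    if (length(hits)) {
      inter <- IRanges::pintersect(gr_g[S4Vectors::queryHits(hits)],
                                   gr_d[S4Vectors::subjectHits(hits)])
      w <- rowsum(GenomicRanges::width(inter), S4Vectors::queryHits(hits))
      dmr_bases[as.integer(rownames(w))] <- w[, 1]
    }
  }
  gene_length <- genes$end - genes$start + 1L
  fraction <- dmr_bases / gene_length
  data.frame(gene_id = genes$gene_id, dmr_bases = dmr_bases,
             gene_length = gene_length, fraction = fraction,
             is_dmg = fraction > threshold, stringsAsFactors = FALSE)
}
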