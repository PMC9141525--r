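#' Apply the depth filter and QC mask to cytosine counts
#'
#' Entries with total read count below `min_depth` are set to missing (not
#' zero). The PCA QC mask marks sites covered in at least 80 percent of
#' samples.
#'
#' @param mm methylation_matrix of raw counts.
#' @param sheet sample sheet (order of samples enforced when given).
#' @param min_depth minimum reads per site per sample (default 3, kept when
#'   total >= min_depth).
#' @param qc_coverage fraction of samples that must cover a site for it to
#'   enter the PCA mask (default 0.8).
#' @return methylation_matrix with `qc_mask` attribute.
#' @export
build_methylation_matrix <- function(mm, sheet = NULL, min_depth = 3L,
                                     qc_coverage = 0.8) {
  samples <- if (is.null(sheet)) mm$samples else
    intersect(sheet$sample_id, mm$samples)
  meth <- mm$meth[, samples, drop = FALSE]
  total <- mm$total[, samples, drop = FALSE]
  low <- is.na(total) | total < min_depth
  meth[low] <- NA_integer_; total[low] <- NA_integer_
  abort_if(!any(!is.na(total)), "no site passes the depth filter")
  out <- methylation_matrix(mm$chrom, mm$pos, meth, total, samples)
  attr(out, "qc_mask") <- rowMeans(!is.na(out$total)) >= qc_coverage
  out
}

#' Genome-wide CG methylation level of one sample
#'
#' Weighted (read-pooled) mean: 100 * sum(meth) / sum(total) over the
#' sample's covered sites.
#'
#' @param mm methylation_matrix.
#' @param sample sample id.
#' @return percentage in [0, 100].
#' @export
global_methylation_level <- function(mm, sample) {
  100 * sum(mm$meth[, sample], na.rm = TRUE) /
    sum(mm$total[, sample], na.rm = TRUE)
}

#' PCA of the methylome
#'
#' Applies the QC mask (site covered in >= 80 percent of samples), mean
#' imputes remaining missing beta values per site, and delegates to
#' [genotype_pca()] with centering but no variance standardization.
#'
#' @param mm methylation_matrix from [build_methylation_matrix()].
#' @param n_components number of components.
#' @return list(coordinates, explained, n_features).
#' @export
methylome_pca <- function(mm, n_components = 10L) {
  mask <- attr(mm, "qc_mask")
  if (is.null(mask)) mask <- rowMeans(!is.na(mm$total)) >= 0.8
  b <- beta_values(mm)[mask, , drop = FALSE]
  genotype_pca(b, n_components, standardize = FALSE)
}

#' Chromosomal methylation discrepancy index (MDI)
#'
#' MDI = (100 / |W|) * sum over windows w of |mean beta(sample, w) -
#' mean beta(reference, w)|, where the within-window means are read-pooled
#' and W is the set of windows on the chromosome in which both samples have
#' at least one covered site.
#'
#' @param mm methylation_matrix.
#' @param sample,reference_sample sample ids.
#' @param chromosome chromosome id.
#' @param window window size in bp (default 100 kb).
#' @return MDI value (percentage points), or NA when no shared window.
#' @export
compute_mdi <- function(mm, sample, reference_sample, chromosome,
                        window = 100000L) {
  on_chr <- mm$chrom == chromosome
  abort_if(!any(on_chr), "chromosome not present")
  wi <- window_index(mm$pos[on_chr], window)
  pool <- function(s) {
    me <- rowsum(ifelse(is.na(mm$meth[on_chr, s]), 0, mm$meth[on_chr, s]), wi)
    to <- rowsum(ifelse(is.na(mm$total[on_chr, s]), 0, mm$total[on_chr, s]), wi)
    ifelse(to[, 1] > 0, me[, 1] / to[, 1], NA_real_)
  }
  b1 <- pool(sample); b2 <- pool(reference_sample)
  ok <- !is.na(b1) & !is.na(b2)
  if (!any(ok)) return(NA_real_)
  100 * mean(abs(b1[ok] - b2[ok]))
}

#' Detect CpG islands (Gardiner-Garden and Frommer criteria)
#'
#' 100-bp windows slid by 1 bp are flagged when GC fraction > `min_gc` and
#' observed/expected CpG > `min_oe` (Exp = C * G / window length). N bases
#' are excluded from composition and windows with more than 50 percent N
#' are skipped. Overlapping flagged windows are merged; merged runs longer
#' than `min_len` bp are reported as islands with composition recomputed
#' over the merged interval.
#'
#' @param sequence DNA sequence (character or DNAString).
#' @param min_gc GC fraction threshold (default 0.5, strict >).
#' @param min_oe observed/expected CpG threshold (default 0.6, strict >).
#' @param win scan window (default 100 bp).
#' @param min_len minimum island length (default 200 bp, strict >).
#' @return data.frame(start, end, length, gc_fraction, obs_exp_cpg) with
#'   0-based half-open coordinates.
#' @export
detect_cg_islands <- function(sequence, min_gc = 0.5, min_oe = 0.6,
                              win = 100L, min_len = 200L) {
  s <- toupper(as.character(sequence))
  L <- nchar(s)
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), gc_fraction = numeric(0),
                      obs_exp_cpg = numeric(0))
  if (L < win) return(empty)
  ch <- strsplit(s, "")[[1]]
  isC <- ch == "C"; isG <- ch == "G"; isN <- !(ch %in% c("A", "C", "G", "T"))
  isCpG <- c(isC[-L] & isG[-1], FALSE)
  cum <- function(x) c(0, cumsum(x))
  cC <- cum(isC); cG <- cum(isG); cN <- cum(isN); cCpG <- cum(isCpG)
  i <- seq_len(L - win + 1L)
  nC <- cC[i + win] - cC[i]; nG <- cG[i + win] - cG[i]
  nN <- cN[i + win] - cN[i]
  ## CpG pairs fully inside the window: pair positions i .. i+win-2
  nCpG <- cCpG[i + win - 1L] - cCpG[i]
  eff <- win - nN
  gc <- ifelse(eff > 0, (nC + nG) / eff, 0)
  expCpG <- ifelse(eff > 0, nC * nG / eff, 0)
  oe <- ifelse(expCpG > 0, nCpG / expCpG, 0)
  flag <- gc > min_gc & oe > min_oe & nN <= win / 2
  if (!any(flag)) return(empty)
  ## merge overlapping flagged windows [i-1, i-1+win) (0-based)
  fi <- which(flag)
  brk <- c(TRUE, diff(fi) > win)
  run <- cumsum(brk)
  starts <- tapply(fi, run, min) - 1L
  ends <- tapply(fi, run, max) - 1L + win
  len <- ends - starts
  keep <- len > min_len
  if (!any(keep)) return(empty)
  starts <- starts[keep]; ends <- ends[keep]
  gc_f <- oe_f <- numeric(length(starts))
  for (k in seq_along(starts)) {
    a <- starts[k] + 1L; b <- ends[k]
    nc <- cC[b + 1L] - cC[a]; ng <- cG[b + 1L] - cG[a]
    nn <- cN[b + 1L] - cN[a]; np <- cCpG[b] - cCpG[a]
    el <- (b - a + 1L) - nn
    gc_f[k] <- if (el > 0) (nc + ng) / el else 0
    oe_f[k] <- if (nc * ng > 0) np / (nc * ng / el) else 0
  }
  data.frame(start = as.integer(starts), end = as.integer(ends),
             length = as.integer(ends - starts), gc_fraction = gc_f,
             obs_exp_cpg = oe_f)
}

## pooled-count metaprofile accumulator: bins sites of many regions into a
## fixed flank/body/flank scheme, pooling read counts per group.
metaprofile_accumulate <- function(mm, regions, groups, flank, flank_bin,
                                   body_bins) {
  n_flank_bins <- as.integer(flank / flank_bin)
  n_bins <- 2L * n_flank_bins + body_bins
  res <- lapply(groups, function(s)
    list(meth = numeric(n_bins), total = numeric(n_bins)))
  ord <- order(mm$chrom, mm$pos)
  for (r in seq_len(nrow(regions))) {
    chrom <- regions$chrom[r]
    rs <- regions$start[r]; re <- regions$end[r]   # 1-based inclusive body
    minus <- !is.null(regions$strand) && regions$strand[r] == "-"
    on <- which(mm$chrom == chrom & mm$pos >= rs - flank & mm$pos <= re + flank)
    if (!length(on)) next
    pos <- mm$pos[on]
    bin <- integer(length(pos))
    up <- pos < rs; down <- pos > re; body <- !up & !down
    bin[up] <- n_flank_bins - 1L - pmin((rs - 1L - pos[up]) %/% flank_bin,
                                        n_flank_bins - 1L)
    bin[down] <- 2L * n_flank_bins + body_bins - n_flank_bins +
      pmin((pos[down] - re - 1L) %/% flank_bin, n_flank_bins - 1L)
    blen <- re - rs + 1L
    rel <- (pos[body] - rs) / blen
    bin[body] <- n_flank_bins + pmin(floor(rel * body_bins), body_bins - 1L)
    if (minus) bin <- n_bins - 1L - bin
    for (g in names(groups)) {
      me <- mm$meth[on, groups[[g]], drop = FALSE]
      to <- mm$total[on, groups[[g]], drop = FALSE]
      res[[g]]$meth <- res[[g]]$meth +
        rowsum_padded(rowSums(me, na.rm = TRUE), bin, n_bins)
      res[[g]]$total <- res[[g]]$total +
        rowsum_padded(rowSums(to, na.rm = TRUE), bin, n_bins)
    }
  }
  out <- lapply(names(res), function(g) {
    data.frame(group = g, bin = seq_len(n_bins) - 1L,
               beta = ifelse(res[[g]]$total > 0,
                             res[[g]]$meth / res[[g]]$total, NA_real_),
               total = res[[g]]$total, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

rowsum_padded <- function(x, bin, n_bins) {
  out <- numeric(n_bins)
  s <- rowsum(x, bin)
  out[as.integer(rownames(s)) + 1L] <- s[, 1]
  out
}

#' Genic methylation metaprofile
#'
#' Mean pooled CG methylation across genes, from `flank` bp upstream of the
#' TSS to `flank` bp downstream of the TES, strand-aware (TSS on the left).
#' Flanks are binned at 100 bp; gene bodies are linearly rescaled to
#' `body_bins` bins. Beta values are read-count pooled over genes and group
#' samples per bin.
#'
#' @param mm methylation_matrix.
#' @param genes gene table (chrom, start, end, strand).
#' @param groups named list of sample id vectors.
#' @param flank flank width in bp (default 5000).
#' @param body_bins bins across the gene body (default 100).
#' @return long data.frame(group, bin, beta, total).
#' @export
gene_metaprofile <- function(mm, genes, groups, flank = 5000L,
                             body_bins = 100L) {
  metaprofile_accumulate(mm, genes, groups, flank, 100L, body_bins)
}

#' CpG-island methylation metaprofile
#'
#' Island bodies rescaled to `body_bins` bins with `shore`-bp shores binned
#' at 100 bp on either side; beta pooled per bin per group.
#'
#' @param mm methylation_matrix.
#' @param islands island table from [detect_cg_islands()] with a chrom
#'   column (0-based half-open start/end).
#' @param groups named list of sample id vectors.
#' @param shore shore width in bp (default 2000).
#' @param body_bins bins across the island (default 40).
#' @return long data.frame(group, bin, beta, total).
#' @export
cgi_metaprofile <- function(mm, islands, groups, shore = 2000L,
                            body_bins = 40L) {
  if (!nrow(islands)) {
    warning("no islands to profile")
    return(data.frame(group = character(0), bin = integer(0),
                      beta = numeric(0), total = numeric(0)))
  }
  regions <- data.frame(chrom = islands$chrom, start = islands$start + 1L,
                        end = islands$end, strand = "+",
                        stringsAsFactors = FALSE)
  metaprofile_accumulate(mm, regions, groups, shore, 100L, body_bins)
}
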