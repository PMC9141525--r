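#' Classify CG loci by CG-loss variation
#'
#' A CG locus (C at `pos`, G at `pos + 1` on the plus strand) carries a
#' CG-loss variation when a SNP sits on either base, or an INDEL's
#' reference span overlaps either base. When several variants hit a locus
#' the leftmost is taken as the causal key; its alt-allele dosage per
#' sample is attached.
#'
#' @param mm methylation_matrix (CG site grid).
#' @param variants variant_set.
#' @param reference DNAStringSet (used to check the locus is a reference
#'   CpG; mismatches are an error).
#' @return data.frame(chrom, pos, carrying, variant_idx) plus a `dosage`
#'   matrix attribute (loci x samples, NA rows for non-carrying loci).
#' @export
classify_cg_loss_loci <- function(mm, variants, reference = NULL) {
  info <- variants$info
  if (!is.null(reference)) {
    for (ch in unique(mm$chrom)) {
      p <- mm$pos[mm$chrom == ch]
      dinuc <- as.character(Biostrings::extractAt(
        reference[[ch]], IRanges::IRanges(p, p + 1L)))
      abort_if(any(dinuc != "CG"),
               sprintf("non-CpG reference dinucleotide on %s", ch))
    }
  }
  n_loci <- length(mm$pos)
  variant_idx <- rep(NA_integer_, n_loci)
  span_end <- info$pos + nchar(info$ref) - 1L
  gr_v <- GenomicRanges::GRanges(info$chrom,
                                 IRanges::IRanges(info$pos, span_end))
  gr_l <- GenomicRanges::GRanges(mm$chrom, IRanges::IRanges(mm$pos, mm$pos + 1L))
  hits <- GenomicRanges::findOverlaps(gr_l, gr_v)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ## SNPs only qualify when sitting exactly on the C or the G
  snp_ok <- info$is_snp[sh] &
    (info$pos[sh] == mm$pos[qh] | info$pos[sh] == mm$pos[qh] + 1L)
  keep <- snp_ok | !info$is_snp[sh]
  qh <- qh[keep]; sh <- sh[keep]
  if (length(qh)) {
    o <- order(qh, info$pos[sh])
    first <- !duplicated(qh[o])
    variant_idx[qh[o][first]] <- sh[o][first]
  }
  carrying <- !is.na(variant_idx)
  dosage <- matrix(NA_integer_, n_loci, length(variants$samples),
                   dimnames = list(NULL, variants$samples))
  if (any(carrying))
    dosage[carrying, ] <- variants$geno[variant_idx[carrying], , drop = FALSE]
  out <- data.frame(chrom = mm$chrom, pos = mm$pos, carrying = carrying,
                    variant_idx = variant_idx, stringsAsFactors = FALSE)
  attr(out, "dosage") <- dosage
  out
}

#' Linear regression of methylation on CG-loss dosage
#'
#' Ordinary least squares of per-sample beta on alt-allele dosage.
#'
#' @param dosage numeric vector in \{0, 1, 2\} (NA allowed).
#' @param beta numeric beta values per sample.
#' @return list(slope, r_squared, n); NA slope when dosage has no variance
#'   or fewer than 3 complete pairs.
#' @export
cg_loss_regression <- function(dosage, beta) {
  ok <- !is.na(dosage) & !is.na(beta)
  n <- sum(ok)
  if (n < 3L || stats::var(dosage[ok]) == 0)
    return(list(slope = NA_real_, r_squared = NA_real_, n = n))
  fit <- stats::lm.fit(cbind(1, dosage[ok]), beta[ok])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((beta[ok] - mean(beta[ok]))^2)
  list(slope = unname(fit$coefficients[2]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       n = n)
}

#' Rank CG loci into methylation-variability categories
#'
#' Loci are ranked by the standard deviation of beta across samples
#' (missing skipped); ranks 1..cut1 are "very_high", cut1+1..cut2 "high",
#' cut2+1..cut3 "moderate" and the rest "low". With fewer loci than cut3
#' the cutoffs are scaled proportionally (ratios preserved).
#'
#' @param mm methylation_matrix (or a beta matrix).
#' @param cutoffs rank cutoffs, default c(10000, 50000, 150000).
#' @return data.frame(sd, rank, category).
#' @export
variability_categories <- function(mm, cutoffs = c(10000L, 50000L, 150000L)) {
  b <- if (inherits(mm, "methylation_matrix")) beta_values(mm) else as.matrix(mm)
  sds <- apply(b, 1, stats::sd, na.rm = TRUE)
  sds[is.na(sds)] <- 0
  n <- length(sds)
  if (n < max(cutoffs)) {
    f <- n / max(cutoffs)
    cutoffs <- pmax(1L, as.integer(round(cutoffs * f)))
    message("fewer loci than top cutoff; cutoffs scaled to ",
            paste(cutoffs, collapse = "/"))
  }
  rk <- rank(-sds, ties.method = "first")
  category <- cut(rk, breaks = c(0, cutoffs, Inf),
                  labels = c("very_high", "high", "moderate", "low"))
  data.frame(sd = sds, rank = rk, category = as.character(category),
             stringsAsFactors = FALSE)
}

## residualize columns of x on covariates (with intercept)
residualize <- function(x, covars) {
  q <- qr(cbind(1, covars))
  qr.resid(q, x)
}

#' Eigenstrat-corrected cis-driver scan for DMRs
#'
#' Per DMR the phenotype is the read-pooled beta per sample over the DMR
#' window; candidate variants lie within `flank` bp of the window. Both
#' phenotype and candidate dosages are residualized on the top `n_pcs`
#' principal components of the genome-wide standardized dosage matrix, and
#' association is tested by chi2 = (n - n_pcs - 1) r^2 on 1 df, r being
#' the residual correlation. A DMR is associated at threshold theta when
#' its best p value is below theta.
#'
#' @param dmrs data.frame with chrom, start, end (0-based half-open
#'   windows).
#' @param geno variant_set.
#' @param mm methylation_matrix.
#' @param samples samples to scan (default all of `mm$samples`).
#' @param flank window extension in bp (default 500).
#' @param n_pcs number of axes removed (default 10, the Eigenstrat
#'   convention; must leave n - n_pcs - 1 > 0).
#' @param thresholds significance grid (default 5e-5 down to 5e-8).
#' @param min_samples minimum phenotyped samples per DMR (default 5).
#' @param return_all also return every candidate chi-square statistic (attr
#'   `all_chisq`), e.g. for genomic-control diagnostics.
#' @return data.frame(chrom, start, end, n_candidates, best_variant,
#'   best_p, n_used, skipped) with one `assoc_<theta>` column per
#'   threshold; attr `summary` holds the associated fraction per threshold.
#' @export
cis_driver_scan <- function(dmrs, geno, mm, samples = mm$samples,
                            flank = 500L, n_pcs = 10L,
                            thresholds = c(5e-5, 5e-6, 5e-7, 5e-8),
                            min_samples = 5L, return_all = FALSE) {
  samples <- intersect(samples, geno$samples)
  g <- geno$geno[, samples, drop = FALSE]
  gm <- rowMeans(g, na.rm = TRUE)
  gi <- g; miss <- is.na(gi); gi[miss] <- gm[row(gi)[miss]]
  gv <- apply(gi, 1, stats::var)
  std <- (gi[gv > 0, , drop = FALSE] - gm[gv > 0]) / sqrt(gv[gv > 0])
  pcs <- stats::prcomp(t(std), center = FALSE)$x[, seq_len(n_pcs), drop = FALSE]
  all_chisq <- list()
  thr_names <- paste0("assoc_", formatC(thresholds, format = "g"))
  out <- dmrs[, c("chrom", "start", "end"), drop = FALSE]
  out$n_candidates <- 0L; out$best_variant <- NA_character_
  out$best_p <- NA_real_; out$n_used <- NA_integer_; out$skipped <- FALSE
  for (tn in thr_names) out[[tn]] <- NA
  info <- geno$info
  for (i in seq_len(nrow(dmrs))) {
    w_lo <- dmrs$start[i] + 1L - flank; w_hi <- dmrs$end[i] + flank
    cand <- which(info$chrom == dmrs$chrom[i] &
                  info$pos >= w_lo & info$pos <= w_hi)
    out$n_candidates[i] <- length(cand)
    sites <- which(mm$chrom == dmrs$chrom[i] &
                   mm$pos > dmrs$start[i] & mm$pos <= dmrs$end[i])
    if (!length(sites) || !length(cand)) { out$skipped[i] <- TRUE; next }
    me <- colSums(mm$meth[sites, samples, drop = FALSE], na.rm = TRUE)
    to <- colSums(mm$total[sites, samples, drop = FALSE], na.rm = TRUE)
    phen_ok <- to > 0
    n <- sum(phen_ok)
    if (n < max(min_samples, n_pcs + 3L)) { out$skipped[i] <- TRUE; next }
    y <- (me / to)[phen_ok]
    x <- t(gi[cand, phen_ok, drop = FALSE])
    covs <- pcs[phen_ok, , drop = FALSE]
    ry <- residualize(y, covs)
    rx <- residualize(x, covs)
    sdy <- stats::sd(ry); sdx <- apply(rx, 2, stats::sd)
    usable <- sdx > 0 & sdy > 0
    if (!any(usable)) { out$skipped[i] <- TRUE; next }
    r <- suppressWarnings(as.vector(cor(ry, rx[, usable, drop = FALSE])))
    chi2 <- (n - n_pcs - 1) * r^2
    if (return_all) all_chisq[[length(all_chisq) + 1L]] <- chi2
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
    best <- which.min(p)
    ci <- cand[usable][best]
    out$best_variant[i] <- paste0(info$chrom[ci], ":", info$pos[ci])
    out$best_p[i] <- p[best]
    out$n_used[i] <- n
    for (k in seq_along(thresholds))
      out[[thr_names[k]]][i] <- p[best] < thresholds[k]
  }
  summ <- vapply(thr_names, function(tn) mean(out[[tn]], na.rm = TRUE),
                 numeric(1))
  attr(out, "summary") <- data.frame(threshold = thresholds,
                                     associated_fraction = unname(summ))
  if (return_all) attr(out, "all_chisq") <- unlist(all_chisq)
  out
}

#' Association between DMGs and selection classes (chi-square)
#'
#' Builds the 2x2 table DMG vs non-DMG by under-selection vs not, for the
#' positive and the purifying class in turn, and applies a Pearson
#' chi-square test without continuity correction. Output rows mirror a
#' per-comparison association table: percent of DMGs and of non-DMGs in
#' the selection class plus the unadjusted p value.
#'
#' @param dmgs data.frame from [call_dmgs()].
#' @param selection data.frame from [classify_selection()].
#' @param comparison label recorded in the output.
#' @return data.frame(comparison, selection_type, pct_dmg, pct_non_dmg,
#'   n_dmg, n_non_dmg, chisq, p_value).
#' @export
dmg_selection_chisq <- function(dmgs, selection, comparison = "") {
  abort_if(!any(dmgs$is_dmg), "empty DMG set")
  merged <- merge(dmgs[, c("gene_id", "is_dmg")],
                  selection[selection$class != "undefined",
                            c("gene_id", "class")],
                  by = "gene_id")
  out <- lapply(c("positive", "purifying"), function(sel) {
    tab <- table(factor(merged$is_dmg, levels = c(TRUE, FALSE)),
                 factor(merged$class == sel, levels = c(TRUE, FALSE)))
    test <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(comparison = comparison, selection_type = sel,
               pct_dmg = 100 * tab[1, 1] / sum(tab[1, ]),
               pct_non_dmg = 100 * tab[2, 1] / sum(tab[2, ]),
               n_dmg = sum(tab[1, ]), n_non_dmg = sum(tab[2, ]),
               chisq = unname(test$statistic), p_value = test$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
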