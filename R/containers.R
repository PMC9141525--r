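#' Construct a variant set
#'
#' Container binding per-site metadata to an alt-allele dosage matrix. All
#' records are biallelic (multiallelic VCF records are split upstream);
#' dosages are 0/1/2 alt-allele counts with NA for missing calls.
#'
#' @param info data.frame with columns chrom, pos (1-based), ref, alt,
#'   consequence, impact, gene_id, mq, is_snp.
#' @param geno integer matrix, sites x samples, entries in \{0,1,2,NA\}.
#' @param samples character vector of sample ids (column order of `geno`).
#' @return object of class `variant_set`.
#' @export
variant_set <- function(info, geno, samples) {
  abort_if(nrow(info) != nrow(geno), "info/geno row mismatch")
  abort_if(length(samples) != ncol(geno), "samples/geno column mismatch")
  abort_if(any(info$pos < 1L), "positions must be 1-based (>= 1)")
  abort_if(any(info$ref == info$alt), "ref and alt alleles must differ")
  colnames(geno) <- samples
  if (!"is_snp" %in% names(info))
    info$is_snp <- nchar(info$ref) == 1L & nchar(info$alt) == 1L
  structure(list(info = info, geno = geno, samples = samples),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d sites x %d samples (%d SNPs, %d INDELs)\n",
              nrow(x$info), length(x$samples), sum(x$info$is_snp),
              sum(!x$info$is_snp)))
  invisible(x)
}

#' Subset a variant set by site and/or sample
#' @param x variant_set
#' @param sites logical/integer site index
#' @param samples character/integer sample index
#' @return variant_set
#' @export
subset_variants <- function(x, sites = NULL, samples = NULL) {
  info <- x$info; geno <- x$geno
  if (!is.null(sites)) { info <- info[sites, , drop = FALSE]; geno <- geno[sites, , drop = FALSE] }
  if (!is.null(samples)) geno <- geno[, samples, drop = FALSE]
  variant_set(info, geno, colnames(geno))
}

#' Construct a methylation matrix
#'
#' Per-CG-site methylated / total read counts per sample. Positions are the
#' 1-based coordinate of the C on the plus strand; counts from the two
#' strands of a symmetric CpG are merged upstream when strand merging is on.
#'
#' @param chrom,pos site coordinates (pos 1-based).
#' @param meth,total integer matrices (sites x samples); NA marks missing.
#' @param samples character sample ids.
#' @return object of class `methylation_matrix`.
#' @export
methylation_matrix <- function(chrom, pos, meth, total, samples) {
  abort_if(length(chrom) != nrow(meth) || length(pos) != nrow(meth),
           "site metadata length must equal matrix rows")
  abort_if(any(meth > total, na.rm = TRUE), "meth count exceeds total")
  abort_if(any(total < 0, na.rm = TRUE) || any(meth < 0, na.rm = TRUE),
           "negative counts")
  o <- order(chrom, pos)
  colnames(meth) <- samples; colnames(total) <- samples
  structure(list(chrom = chrom[o], pos = pos[o],
                 meth = meth[o, , drop = FALSE], total = total[o, , drop = FALSE],
                 samples = samples),
            class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf("methylation_matrix: %d CG sites x %d samples\n",
              length(x$pos), length(x$samples)))
  invisible(x)
}

#' Per-site methylation level (beta value) matrix
#' @param mm methylation_matrix
#' @return numeric matrix of meth/total in [0,1], NA where uncovered.
#' @export
beta_values <- function(mm) mm$meth / mm$total
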