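#' Read and validate a sample sheet
#'
#' TSV with header columns sample_id, species, lineage, is_hybrid.
#'
#' @param path file path.
#' @param lineages allowed lineage labels (default: any nonempty label).
#' @return data.frame of class `sample_sheet`.
#' @export
read_sample_sheet <- function(path, lineages = NULL) {
  sheet <- data.table::setDF(data.table::fread(path, sep = "\t",
                                               colClasses = "character"))
  need <- c("sample_id", "species", "lineage", "is_hybrid")
  abort_if(!all(need %in% names(sheet)),
           "sample sheet must have columns ", paste(need, collapse = ", "))
  sheet$is_hybrid <- as.logical(sheet$is_hybrid)
  dup <- sheet$sample_id[duplicated(sheet$sample_id)]
  abort_if(length(dup) > 0, "duplicated sample_id: ", paste(dup, collapse = ", "))
  bad <- which(!nzchar(sheet$species) | !nzchar(sheet$lineage) |
               is.na(sheet$is_hybrid))
  abort_if(length(bad) > 0, "invalid sample sheet row(s): ",
           paste(bad, collapse = ", "))
  if (!is.null(lineages)) {
    bad <- which(!sheet$lineage %in% lineages)
    abort_if(length(bad) > 0,
             "unknown lineage label in row(s): ", paste(bad, collapse = ", "))
  }
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}

## parse the first ANN entry matching the alt allele
parse_ann <- function(ann, alt) {
  if (is.na(ann) || !nzchar(ann))
    return(c(consequence = "unknown", impact = "MODIFIER", gene_id = NA))
  entries <- strsplit(ann, ",", fixed = TRUE)[[1]]
  fields <- strsplit(entries, "|", fixed = TRUE)
  hit <- which(vapply(fields, function(f) f[1] == alt, logical(1)))
  f <- if (length(hit)) fields[[hit[1]]] else fields[[1]]
  c(consequence = f[2] %||% "unknown",
    impact = if (length(f) >= 3) f[3] else "MODIFIER",
    gene_id = if (length(f) >= 4 && nzchar(f[4])) f[4] else NA)
}

#' Read, filter and split variants from a VCF
#'
#' Applies the high-quality variant filter: per-sample genotypes with
#' DP <= `min_depth` are set missing, records with INFO MQ <= `min_mq` are
#' dropped, and records whose missing-genotype fraction is >= `max_missing`
#' are dropped. Multiallelic records are split into biallelic records
#' (genotypes carrying a different alt allele become missing in the split
#' record). Consequence/impact/gene are parsed from the first SnpEff-style
#' ANN entry matching the alt allele; records without ANN get consequence
#' "unknown" (with a warning) and are retained.
#'
#' @param path VCF 4.x file.
#' @param sheet sample sheet; sample columns are reordered to match.
#' @param min_depth genotype depth cutoff (default 3; kept when DP >
#'   min_depth).
#' @param min_mq mapping-quality cutoff (default 20, strict >; records
#'   without MQ are retained).
#' @param max_missing maximum missing fraction (default 0.01, strict <).
#' @return variant_set.
#' @export
read_vcf_variants <- function(path, sheet, min_depth = 3L, min_mq = 20,
                              max_missing = 0.01) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  abort_if(!all(sheet$sample_id %in% colnames(gt)),
           "VCF is missing sheet samples")
  gt <- gt[, sheet$sample_id, drop = FALSE]
  if (!is.null(dp)) dp <- dp[, sheet$sample_id, drop = FALSE]
  info <- fix[, "INFO"]
  mq <- suppressWarnings(as.numeric(sub(".*MQ=([0-9.]+).*", "\\1",
                                        ifelse(grepl("(^|;)MQ=", info),
                                               info, NA))))
  ann <- ifelse(grepl("(^|;)ANN=", info),
                sub(".*(?:^|;)ANN=([^;]*).*", "\\1", info), NA)
  n_samp <- nrow(sheet)
  keep_mq <- is.na(mq) | mq > min_mq
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)

  ## fast path: biallelic records, vectorized genotype decoding
  dose_lookup <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L,
                   "0|1" = 1L, "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  bi <- which(!multi & keep_mq)
  info_list <- list(); geno_list <- list()
  n_malformed <- 0L
  if (length(bi)) {
    gtb <- gt[bi, , drop = FALSE]
    dose <- matrix(dose_lookup[gtb], nrow = length(bi),
                   dimnames = dimnames(gtb))
    missing_token <- is.na(gtb) | gtb %in% c("./.", ".|.", ".")
    malformed <- is.na(dose) & !missing_token
    bad_rec <- rowSums(malformed) > 0L
    n_malformed <- n_malformed + sum(bad_rec)
    if (!is.null(dp))
      dose[is.na(dp[bi, , drop = FALSE]) | dp[bi, , drop = FALSE] <= min_depth] <-
        NA_integer_
    keep <- !bad_rec & rowMeans(is.na(dose)) < max_missing
    if (any(keep)) {
      sel <- bi[keep]
      info_list[[1]] <- data.frame(
        chrom = fix[sel, "CHROM"], pos = as.integer(fix[sel, "POS"]),
        ref = fix[sel, "REF"], alt = fix[sel, "ALT"], mq = mq[sel],
        ann = ann[sel], stringsAsFactors = FALSE)
      geno_list[[1]] <- dose[keep, , drop = FALSE]
    }
  }

  ## slow path: multiallelic records split into biallelic records
  for (r in which(multi & keep_mq)) {
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    alleles <- strsplit(gsub("|", "/", gt[r, ], fixed = TRUE), "/", fixed = TRUE)
    bad_fmt <- vapply(alleles, function(a)
      length(a) != 2L || !all(a %in% c(".", as.character(0:length(alts)))),
      logical(1))
    if (any(bad_fmt & !is.na(gt[r, ]))) { n_malformed <- n_malformed + 1L; next }
    dpr <- if (is.null(dp)) rep(Inf, n_samp) else dp[r, ]
    for (ai in seq_along(alts)) {
      if (alts[ai] == fix[r, "REF"]) next
      dose <- vapply(alleles, function(a) {
        if (any(a == ".")) return(NA_integer_)
        ia <- as.integer(a)
        if (any(!ia %in% c(0L, ai))) return(NA_integer_)  # other alt allele
        sum(ia == ai)
      }, integer(1))
      dose[is.na(dpr) | dpr <= min_depth] <- NA_integer_
      if (mean(is.na(dose)) >= max_missing) next
      info_list[[length(info_list) + 1L]] <- data.frame(
        chrom = fix[r, "CHROM"], pos = as.integer(fix[r, "POS"]),
        ref = fix[r, "REF"], alt = alts[ai], mq = mq[r], ann = ann[r],
        stringsAsFactors = FALSE)
      geno_list[[length(geno_list) + 1L]] <- matrix(dose, nrow = 1)
    }
  }
  if (n_malformed > 0)
    message(n_malformed, " record(s) with malformed genotypes dropped")
  abort_if(!length(info_list), "no variant passed the filters")
  info_df <- do.call(rbind, info_list)
  geno <- do.call(rbind, geno_list)
  annp <- t(mapply(parse_ann, info_df$ann, info_df$alt, USE.NAMES = FALSE))
  n_no_ann <- sum(is.na(info_df$ann))
  if (n_no_ann > 0)
    warning(n_no_ann, " record(s) without ANN annotation; consequence set ",
            "to 'unknown'")
  info_df$consequence <- annp[, "consequence"]
  info_df$impact <- annp[, "impact"]
  info_df$gene_id <- annp[, "gene_id"]
  info_df$ann <- NULL
  rownames(info_df) <- NULL
  rownames(geno) <- NULL
  o <- order(info_df$chrom, info_df$pos, info_df$alt)
  variant_set(info_df[o, , drop = FALSE], geno[o, , drop = FALSE],
              sheet$sample_id)
}

#' Read per-sample cytosine reports into a methylation matrix
#'
#' Bismark-style tab-separated reports (chrom, pos, strand, count_meth,
#' count_unmeth, context), one file per sample. Only CG-context rows are
#' used. With `merge_strands` (default) the minus-strand C of a symmetric
#' CpG (position p+1) is merged onto the plus-strand C at p by summing
#' counts. Sites with total < `min_depth` for a sample are missing for
#' that sample.
#'
#' @param paths named character vector (sample id -> file path).
#' @param min_depth per-sample depth cutoff (default 1: any covered row
#'   kept; apply the analysis filter with
#'   [build_methylation_matrix()]).
#' @param merge_strands merge symmetric CpG strands (default TRUE).
#' @return methylation_matrix.
#' @export
read_cytosine_report <- function(paths, min_depth = 1L, merge_strands = TRUE) {
  abort_if(is.null(names(paths)), "paths must be named by sample id")
  per_sample <- lapply(paths, function(p) {
    d <- data.table::fread(p, sep = "\t", header = FALSE,
      col.names = c("chrom", "pos", "strand", "meth", "unmeth", "context"))
    d <- d[d$context == "CG", ]
    abort_if(any(d$meth < 0) || any(d$unmeth < 0), "negative counts in ", p)
    if (merge_strands) d$pos <- ifelse(d$strand == "-", d$pos - 1L, d$pos)
    d <- d[, list(meth = sum(meth), unmeth = sum(unmeth)),
           by = c("chrom", "pos")]
    d
  })
  keys <- unique(data.table::rbindlist(
    lapply(per_sample, function(d) d[, c("chrom", "pos")])))
  data.table::setorder(keys, chrom, pos)
  n <- nrow(keys)
  samples <- names(paths)
  meth <- total <- matrix(NA_integer_, n, length(samples),
                          dimnames = list(NULL, samples))
  kk <- paste0(keys$chrom, ":", keys$pos)
  for (s in samples) {
    d <- per_sample[[s]]
    idx <- match(paste0(d$chrom, ":", d$pos), kk)
    tot <- d$meth + d$unmeth
    ok <- tot >= min_depth
    meth[idx[ok], s] <- d$meth[ok]
    total[idx[ok], s] <- tot[ok]
  }
  methylation_matrix(keys$chrom, keys$pos, meth, total, samples)
}

#' Read gene models from a GFF3 file
#'
#' One gene model per gene feature; the first mRNA's CDS segments are used
#' (a message notes multi-mRNA genes). Genes whose total CDS length is not
#' divisible by 3 are flagged ineligible for dN/dS but retained.
#'
#' @param path GFF3 file with gene/mRNA/CDS features.
#' @return data.frame(gene_id, chrom, start, end, strand, tss, tes,
#'   dnds_eligible) with a `cds` list-column of (start, end) matrices.
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  is_gene <- md$type == "gene"
  is_mrna <- md$type == "mRNA"
  is_cds <- md$type == "CDS"
  gene_ids <- as.character(md$ID[is_gene])
  gdf <- data.frame(
    gene_id = gene_ids,
    chrom = as.character(GenomicRanges::seqnames(gr)[is_gene]),
    start = GenomicRanges::start(gr)[is_gene],
    end = GenomicRanges::end(gr)[is_gene],
    strand = as.character(GenomicRanges::strand(gr)[is_gene]),
    stringsAsFactors = FALSE)
  mrna_id <- as.character(md$ID[is_mrna])
  mrna_parent <- as.character(md$Parent)[is_mrna]
  cds_parent <- as.character(md$Parent)[is_cds]
  cds_start <- GenomicRanges::start(gr)[is_cds]
  cds_end <- GenomicRanges::end(gr)[is_cds]
  n_multi <- 0L
  cds_list <- vector("list", nrow(gdf))
  for (i in seq_len(nrow(gdf))) {
    mr <- mrna_id[mrna_parent == gdf$gene_id[i]]
    if (length(mr) > 1L) n_multi <- n_multi + 1L
    if (!length(mr)) { cds_list[[i]] <- matrix(numeric(0), 0, 2); next }
    sel <- cds_parent == mr[1]
    o <- order(cds_start[sel])
    cds_list[[i]] <- cbind(start = cds_start[sel][o], end = cds_end[sel][o])
  }
  if (n_multi > 0)
    message(n_multi, " gene(s) with multiple mRNAs; first mRNA CDS used")
  gdf$tss <- ifelse(gdf$strand == "-", gdf$end, gdf$start)
  gdf$tes <- ifelse(gdf$strand == "-", gdf$start, gdf$end)
  gdf$cds <- cds_list
  cds_len <- vapply(cds_list, function(m)
    if (nrow(m)) sum(m[, 2] - m[, 1] + 1) else 0, numeric(1))
  gdf$dnds_eligible <- cds_len > 0 & cds_len %% 3 == 0
  gdf
}
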