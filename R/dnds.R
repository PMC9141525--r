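## Nei-Gojobori (1986) machinery. Per-codon synonymous site fractions and
## pathway-averaged difference counts are precomputed once into lookup
## tables; mutations creating a stop codon count as nonsynonymous sites, and
## substitution pathways passing through a stop codon are excluded from the
## pathway average (all-blocked codon pairs fall back to the unrestricted
## average).

.ng86 <- new.env(parent = emptyenv())

ng86_tables <- function() {
  if (!is.null(.ng86$S)) return(as.list(.ng86))
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases,
                            function(ab, c) paste0(ab, c)))
  codons <- sort(codons)
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[codons]
  syn_sites <- setNames(numeric(64), codons)
  for (cd in codons) {
    if (aa[cd] == "*") next
    s <- 0
    for (p in 1:3) for (b in setdiff(bases, substr(cd, p, p))) {
      alt <- cd; substr(alt, p, p) <- b
      if (gc[alt] != "*" && gc[alt] == aa[cd]) s <- s + 1 / 3
    }
    syn_sites[cd] <- s
  }
  ## pathway-averaged (nd, sd) for every codon pair
  ND <- SD <- matrix(0, 64, 64, dimnames = list(codons, codons))
  for (i in 1:64) for (j in 1:64) {
    c1 <- codons[i]; c2 <- codons[j]
    if (aa[c1] == "*" || aa[c2] == "*") next
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    k <- length(pos)
    if (k == 0) next
    perms <- if (k == 1) list(pos) else
      if (k == 2) list(pos, rev(pos)) else
      lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
             function(o) pos[o])
    eval_path <- function(order, allow_stop) {
      cur <- c1; nd <- 0; sd <- 0
      for (p in order) {
        nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
        if (!allow_stop && gc[nxt] == "*") return(NULL)
        if (gc[cur] == gc[nxt]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(nd, sd)
    }
    res <- Filter(Negate(is.null), lapply(perms, eval_path, allow_stop = FALSE))
    if (!length(res))
      res <- Filter(Negate(is.null), lapply(perms, eval_path, allow_stop = TRUE))
    m <- do.call(rbind, res)
    ND[i, j] <- mean(m[, 1]); SD[i, j] <- mean(m[, 2])
  }
  .ng86$codons <- codons; .ng86$aa <- aa
  .ng86$S <- syn_sites; .ng86$ND <- ND; .ng86$SD <- SD
  as.list(.ng86)
}

split_codons <- function(x) {
  abort_if(nchar(x) %% 3 != 0, "sequence length not a multiple of 3")
  substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
}

#' Pairwise dN/dS by the Nei-Gojobori (1986) method
#'
#' Synonymous/nonsynonymous site counts are averaged over both sequences,
#' difference counts are pathway-averaged over substitution orders at
#' multi-hit codons, proportions pN = Nd/N and pS = Sd/S are Jukes-Cantor
#' corrected (d = -3/4 log(1 - 4/3 p)). The ratio is NA (undefined) when
#' dS = 0; when a proportion reaches the correction bound (p >= 3/4) the
#' corresponding distance saturates to Inf.
#'
#' @param cds_a,cds_b equal-length in-frame coding sequences (character).
#' @return list(dN, dS, ratio, pN, pS).
#' @export
ng86_dnds <- function(cds_a, cds_b) {
  abort_if(nchar(cds_a) != nchar(cds_b), "sequence length mismatch")
  tb <- ng86_tables()
  ca <- split_codons(toupper(cds_a)); cb <- split_codons(toupper(cds_b))
  ia <- match(ca, tb$codons); ib <- match(cb, tb$codons)
  abort_if(anyNA(ia) || anyNA(ib), "non-ACGT codon in input")
  abort_if(any(tb$aa[ia] == "*") || any(tb$aa[ib] == "*"),
           "internal stop codon in input")
  Sa <- sum(tb$S[ia]); Sb <- sum(tb$S[ib])
  S <- (Sa + Sb) / 2
  N <- 3 * length(ia) - S
  idx <- cbind(ia, ib)
  Nd <- sum(tb$ND[idx]); Sd <- sum(tb$SD[idx])
  pN <- if (N > 0) Nd / N else 0
  pS <- if (S > 0) Sd / S else 0
  jc <- function(p) if (p >= 3 / 4) Inf else -3 / 4 * log(1 - 4 / 3 * p)
  dN <- jc(pN); dS <- jc(pS)
  ratio <- if (dS == 0 || (is.infinite(dN) && is.infinite(dS))) NA_real_
           else dN / dS
  list(dN = dN, dS = dS, ratio = ratio, pN = pN, pS = pS)
}

#' Sample-level consensus coding sequence
#'
#' Reference CDS with the sample's homozygous-alternate SNPs substituted;
#' heterozygous calls and INDELs are ignored (the biological consequence of
#' a heterozygous variant in a selfing-capable perennial is ambiguous, so
#' only fixed homozygous states enter the dN/dS comparison). Minus-strand
#' genes are reverse-complemented to coding orientation.
#'
#' @param gene one row of a gene model table (needs chrom, strand and a
#'   `cds` list-column of (start, end) matrices, 1-based inclusive).
#' @param reference DNAStringSet keyed by chromosome.
#' @param geno variant_set.
#' @param sample sample id.
#' @return character coding sequence.
#' @export
consensus_cds <- function(gene, reference, geno, sample) {
  segs <- gene$cds[[1]]
  chrom_seq <- reference[[gene$chrom]]
  pieces <- character(nrow(segs))
  info <- geno$info
  gvec <- geno$geno[, sample]
  cand <- which(info$chrom == gene$chrom & info$is_snp &
                !is.na(gvec) & gvec == 2L)
  for (k in seq_len(nrow(segs))) {
    s <- segs[k, 1]; e <- segs[k, 2]
    seq_k <- strsplit(as.character(Biostrings::subseq(chrom_seq, s, e)), "")[[1]]
    hit <- cand[info$pos[cand] >= s & info$pos[cand] <= e]
    for (h in hit) {
      off <- info$pos[h] - s + 1L
      abort_if(seq_k[off] != info$ref[h],
               sprintf("reference mismatch at %s:%d (have %s, variant ref %s)",
                       gene$chrom, info$pos[h], seq_k[off], info$ref[h]))
      seq_k[off] <- info$alt[h]
    }
    pieces[k] <- paste(seq_k, collapse = "")
  }
  cds <- paste(pieces, collapse = "")
  if (gene$strand == "-")
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  cds
}

#' Mean cross-clade pairwise dN/dS for one gene
#'
#' dN/dS is computed for every cross-clade sample pair from consensus coding
#' sequences and the defined (non-NA) ratios are averaged. Identical
#' sequence pairs are collapsed and weighted by multiplicity.
#'
#' @param gene gene model row (dnds-eligible).
#' @param reference DNAStringSet.
#' @param geno variant_set.
#' @param samplesA,samplesB samples of the two clades.
#' @return mean ratio (NA when no pair has a defined ratio).
#' @export
gene_pairwise_dnds <- function(gene, reference, geno, samplesA, samplesB) {
  seqA <- vapply(samplesA, function(s) consensus_cds(gene, reference, geno, s), "")
  seqB <- vapply(samplesB, function(s) consensus_cds(gene, reference, geno, s), "")
  ua <- table(seqA); ub <- table(seqB)
  tot_w <- 0; tot <- 0
  for (i in seq_along(ua)) for (j in seq_along(ub)) {
    r <- ng86_dnds(names(ua)[i], names(ub)[j])$ratio
    if (!is.na(r) && is.finite(r)) {
      w <- ua[[i]] * ub[[j]]
      tot <- tot + w * r; tot_w <- tot_w + w
    }
  }
  if (tot_w == 0) NA_real_ else tot / tot_w
}

#' Classify genes into selection classes from mean dN/dS
#'
#' The 5 percent highest defined means are labelled `positive`, the 5
#' percent lowest `purifying` (closed thresholds, ties included); genes with
#' undefined means are labelled `undefined` and excluded from the quantiles.
#'
#' @param mean_dnds named numeric vector (gene_id -> mean ratio, NA allowed).
#' @param quantile tail fraction (default 0.05).
#' @return data.frame(gene_id, mean_dnds, class).
#' @export
classify_selection <- function(mean_dnds, quantile = 0.05) {
  cls <- rep("neutral", length(mean_dnds))
  cls[is.na(mean_dnds)] <- "undefined"
  cls[tail_select(mean_dnds, quantile, lower = FALSE)] <- "positive"
  cls[tail_select(mean_dnds, quantile, lower = TRUE)] <- "purifying"
  data.frame(gene_id = names(mean_dnds), mean_dnds = unname(mean_dnds),
             class = cls, stringsAsFactors = FALSE)
}
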