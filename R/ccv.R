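## consequence vocabulary -> CCV impact class
.impact_map <- c(
  frameshift_variant = "frameshift",
  stop_gained = "stop_gain",
  stop_lost = "stop_loss",
  start_lost = "start_loss",
  splice_acceptor_variant = "splicing",
  splice_donor_variant = "splicing")

#' Map a consequence annotation to a CCV impact class
#'
#' Only the five high-impact classes enter CCV calling: frameshift,
#' stop_gain, stop_loss, start_loss and splicing. Composite annotations
#' ("&"-joined) match on any component; everything else returns NA.
#'
#' @param consequence character vector of consequence strings.
#' @return character vector of impact classes or NA.
#' @export
classify_impact <- function(consequence) {
  vapply(strsplit(as.character(consequence), "&", fixed = TRUE), function(cs) {
    hit <- .impact_map[cs]
    hit <- hit[!is.na(hit)]
    if (length(hit)) hit[[1]] else NA_character_
  }, character(1))
}

#' Resolve a clade label to its sample ids
#'
#' A clade label is matched against the species column first, then the
#' lineage column; hybrid samples never enter a clade.
#'
#' @param sheet sample sheet.
#' @param clade species or lineage label.
#' @return character vector of sample ids (error if empty).
#' @export
clade_samples <- function(sheet, clade) {
  s <- sheet[!sheet$is_hybrid, , drop = FALSE]
  hit <- s$sample_id[s$species == clade]
  if (!length(hit)) hit <- s$sample_id[s$lineage == clade]
  abort_if(!length(hit), sprintf("no non-hybrid samples in clade '%s'", clade))
  hit
}

#' Call conservative clade-specific variants (CCVs)
#'
#' A variant is a CCV for (carrier, reference) when its consequence maps to
#' one of the five high-impact classes, every carrier-clade sample is
#' homozygous-alternate, and every reference-clade sample is
#' homozygous-reference. A heterozygous or missing genotype anywhere in
#' either clade disqualifies the variant (conservative reading of
#' "conserved across all samples ... not present in any sample").
#'
#' @param variants variant_set.
#' @param sheet sample sheet.
#' @param carrier,reference clade labels (species or lineage); hybrids are
#'   excluded.
#' @return data.frame of CCV records (Table-1 shaped plus gene_id and
#'   impact_class).
#' @export
call_ccvs <- function(variants, sheet, carrier, reference) {
  abort_if(carrier == reference, "carrier and reference clade must differ")
  car <- clade_samples(sheet, carrier)
  ref <- clade_samples(sheet, reference)
  cls <- classify_impact(variants$info$consequence)
  gcar <- variants$geno[, car, drop = FALSE]
  gref <- variants$geno[, ref, drop = FALSE]
  ok <- !is.na(cls) &
    rowSums(is.na(gcar)) == 0L & rowSums(gcar == 2L) == length(car) &
    rowSums(is.na(gref)) == 0L & rowSums(gref == 0L) == length(ref)
  info <- variants$info[ok, , drop = FALSE]
  data.frame(gene_id = info$gene_id,
             carrier_clade = rep_len(carrier, nrow(info)),
             reference_clade = rep_len(reference, nrow(info)),
             chromosome = info$chrom, position = info$pos,
             ref_allele = info$ref, alt_allele = info$alt,
             impact_class = cls[ok], stringsAsFactors = FALSE)
}

#' Annotate CCVs with genomic context
#'
#' A CCV is `genic` when its position falls inside any gene's [start, end]
#' interval, else `intergenic`; the genic fraction is attached as an
#' attribute.
#'
#' @param ccvs data.frame from [call_ccvs()].
#' @param genes gene table (chrom, start, end).
#' @return ccvs with a `context` column and attr `genic_fraction`.
#' @export
annotate_ccv_context <- function(ccvs, genes) {
  if (!nrow(ccvs)) {
    ccvs$context <- character(0)
    attr(ccvs, "genic_fraction") <- NA_real_
    return(ccvs)
  }
  genic <- vapply(seq_len(nrow(ccvs)), function(i) {
    any(genes$chrom == ccvs$chromosome[i] &
        genes$start <= ccvs$position[i] & genes$end >= ccvs$position[i])
  }, logical(1))
  ccvs$context <- ifelse(genic, "genic", "intergenic")
  attr(ccvs, "genic_fraction") <- mean(genic)
  ccvs
}
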