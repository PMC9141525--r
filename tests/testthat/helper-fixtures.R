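# Shared fixtures. Heavy simulations are memoised so several test files can
# reuse the same default dataset within one session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

default_sim <- function(seed = 1) {
  cached(paste0("default_sim_", seed), simulate_dataset(sim_config(seed = seed)))
}

## small variant_set straight from matrices
make_vs <- function(geno, pos = NULL, chrom = "chr1", ref = "A", alt = "T",
                    consequence = "intergenic_region", impact = "MODIFIER",
                    gene_id = NA_character_) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  if (is.null(pos)) pos <- seq_len(n) * 10L
  if (is.null(colnames(geno))) colnames(geno) <- paste0("s", seq_len(ncol(geno)))
  info <- data.frame(chrom = rep_len(chrom, n), pos = pos,
                     ref = rep_len(ref, n), alt = rep_len(alt, n),
                     consequence = rep_len(consequence, n),
                     impact = rep_len(impact, n),
                     gene_id = rep_len(gene_id, n), mq = 50,
                     stringsAsFactors = FALSE)
  variant_set(info, geno, colnames(geno))
}

make_mm <- function(meth, total, pos = NULL, chrom = "chr1") {
  meth <- as.matrix(meth); total <- as.matrix(total)
  if (is.null(colnames(meth))) colnames(meth) <- paste0("s", seq_len(ncol(meth)))
  colnames(total) <- colnames(meth)
  if (is.null(pos)) pos <- seq_len(nrow(meth)) * 10L
  methylation_matrix(rep_len(chrom, nrow(meth)), pos, meth, total,
                     colnames(meth))
}

## minimal sample sheet
make_sheet <- function(species, lineage = species, n_each = 2,
                       hybrids = 0) {
  rows <- do.call(rbind, lapply(seq_along(species), function(i)
    data.frame(sample_id = paste0(species[i], "_", seq_len(n_each)),
               species = species[i], lineage = lineage[i], is_hybrid = FALSE,
               stringsAsFactors = FALSE)))
  if (hybrids > 0)
    rows <- rbind(rows, data.frame(
      sample_id = paste0("hyb_", seq_len(hybrids)),
      species = "hybrid", lineage = lineage[1], is_hybrid = TRUE,
      stringsAsFactors = FALSE))
  class(rows) <- c("sample_sheet", "data.frame")
  rows
}

## write a small VCF from a spec table; gts is a sites x samples matrix of
## strings like "0/0"; dp defaults to 10 everywhere
write_toy_vcf <- function(path, chrom, pos, ref, alt, ann, gts, dp = NULL,
                          mq = 60) {
  samples <- colnames(gts)
  if (is.null(dp)) dp <- matrix(10L, nrow(gts), ncol(gts))
  mq <- rep_len(mq, length(pos))
  header <- c("##fileformat=VCFv4.2",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"MQ\">",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"ANN\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_along(pos), function(i)
    paste(c(chrom[i], pos[i], ".", ref[i], alt[i], "99", "PASS",
            paste0("MQ=", mq[i], ";ANN=", ann[i]), "GT:DP",
            paste0(gts[i, ], ":", dp[i, ])), collapse = "\t"), "")
  writeLines(c(header, body), path)
  path
}

## the published high-impact clade-specific variant table, one row per
## (variant, carrier, reference) entry as printed; used as a toy input and
## as the expected output of the CCV caller
table1_ccv_rows <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = '
gene carrier reference chrom pos ref alt impact_class consequence
Aqcoe1G273400 Asian American Chr1 18994915 GAA GAAA frameshift frameshift_variant
Aqcoe2G151500 European American Chr2 15305837 A G splicing splice_donor_variant
Aqcoe2G151500 European American Chr2 15307442 A C stop_gain stop_gained
Aqcoe2G151500 European American Chr2 15309865 AATATATAT AATATATATAT frameshift frameshift_variant
Aqcoe2G151500 European Asian Chr2 15307442 A C stop_gain stop_gained
Aqcoe2G151500 European Asian Chr2 15309865 AATATATAT AATATATATAT frameshift frameshift_variant
Aqcoe2G151500 oxysepala japonica Chr2 15305837 A G splicing splice_donor_variant
Aqcoe2G151500 oxysepala japonica Chr2 15309267 AT A frameshift frameshift_variant
Aqcoe2G177700 European American Chr2 21794397 TATGCACCAAAGGTATCACGATGC TATGC frameshift frameshift_variant
Aqcoe2G177700 European American Chr2 21794979 TT TTGT frameshift frameshift_variant
Aqcoe2G177700 European Asian Chr2 21794397 TATGCACCAAAGGTATCACGATGC TATGC frameshift frameshift_variant
Aqcoe2G177700 oxysepala japonica Chr2 21795089 CA C frameshift frameshift_variant
Aqcoe6G208600 European American Chr6 15364081 A ATCTCTTCG frameshift frameshift_variant
Aqcoe6G208600 European Asian Chr6 15364081 A ATCTCTTCG frameshift frameshift_variant
Aqcoe6G208600 japonica oxysepala Chr6 15364330 TAA TA frameshift frameshift_variant
Aqcoe6G253800 European American Chr6 22789898 C T stop_gain stop_gained
Aqcoe6G253800 European American Chr6 22790012 G A splicing splice_donor_variant
Aqcoe6G253800 European Asian Chr6 22789898 C T stop_gain stop_gained
Aqcoe6G253800 japonica oxysepala Chr6 22790012 G A splicing splice_donor_variant
Aqcoe2G276600 Asian American Chr2 33314422 AGGGGG AGGGGGG frameshift frameshift_variant
Aqcoe6G160300 japonica oxysepala Chr6 9414625 G A stop_gain stop_gained
Aqcoe7G062500 oxysepala japonica Chr7 3789055 G A stop_gain stop_gained
')
}

## encode the published table as a toy VCF: carrier-clade samples are 1/1,
## everyone else 0/0 -- except that a variant printed against one reference
## clade but NOT against another (whose samples would otherwise all be
## homozygous reference) gets one heterozygous sample in the unprinted
## reference clade, since the published absence implies the variant was not
## uniformly absent there
table1_toy_vcf <- function(path, sheet) {
  rows <- table1_ccv_rows()
  key <- paste(rows$chrom, rows$pos, rows$ref, rows$alt)
  uniq <- !duplicated(key)
  u <- rows[uniq, ]
  ukey <- key[uniq]
  carriers <- lapply(ukey, function(k)
    unique(unlist(lapply(rows$carrier[key == k], clade_samples,
                         sheet = sheet))))
  gts <- t(vapply(seq_len(nrow(u)), function(i)
    ifelse(sheet$sample_id %in% carriers[[i]], "1/1", "0/0"),
    character(nrow(sheet))))
  colnames(gts) <- sheet$sample_id
  pairs <- unique(rows[, c("carrier", "reference")])
  printed <- paste(key, rows$carrier, rows$reference)
  for (i in seq_len(nrow(u))) for (j in seq_len(nrow(pairs))) {
    car <- clade_samples(sheet, pairs$carrier[j])
    ref <- clade_samples(sheet, pairs$reference[j])
    would_call <- all(car %in% carriers[[i]]) &&
      !any(ref %in% carriers[[i]])
    k <- paste(ukey[i], pairs$carrier[j], pairs$reference[j])
    if (would_call && !(k %in% printed)) gts[i, ref[1]] <- "0/1"
  }
  write_toy_vcf(path, u$chrom, u$pos, u$ref, u$alt,
                paste0(u$alt, "|", u$consequence, "|HIGH|", u$gene, "|||||"),
                gts)
  list(rows = rows, pairs = pairs)
}
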