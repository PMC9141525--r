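#' Write window statistics as BED and TSV
#'
#' BED is 0-based half-open with the statistic value in column 5; the TSV
#' carries all columns.
#'
#' @param windows window stats data.frame.
#' @param bed_path,tsv_path output paths (either may be NULL).
#' @export
write_windows <- function(windows, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = windows$chrom, start = windows$start,
                      end = windows$end,
                      name = paste0(windows$statistic_name %||% "window",
                                    "_", seq_len(nrow(windows))),
                      score = windows$value %||% 0)
    data.table::fwrite(bed, bed_path, sep = "\t", col.names = FALSE)
  }
  if (!is.null(tsv_path))
    data.table::fwrite(windows, tsv_path, sep = "\t")
  invisible(NULL)
}

#' Read a windows BED file back into a data.frame
#' @param path BED path written by [write_windows()].
#' @return data.frame(chrom, start, end, name, value).
#' @export
read_windows_bed <- function(path) {
  d <- data.table::setDF(data.table::fread(path, sep = "\t", header = FALSE))
  names(d) <- c("chrom", "start", "end", "name", "value")[seq_len(ncol(d))]
  d
}

#' Write a CCV table in the published column layout
#'
#' Columns: Gene, Variant-Carrying, Reference, Chromosome, Position,
#' Reference Allele, Variant, Annotation (plus Context when present).
#'
#' @param ccvs data.frame from [call_ccvs()].
#' @param path output TSV.
#' @export
write_ccv_table <- function(ccvs, path) {
  out <- data.frame(
    Gene = ccvs$gene_id, `Variant-Carrying` = ccvs$carrier_clade,
    Reference = ccvs$reference_clade, Chromosome = ccvs$chromosome,
    Position = ccvs$position, `Reference Allele` = ccvs$ref_allele,
    Variant = ccvs$alt_allele,
    Annotation = gsub("_", " ", ccvs$impact_class),
    check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(ccvs$context)) out$Context <- ccvs$context
  data.table::fwrite(out, path, sep = "\t")
  invisible(NULL)
}

#' Write a phylogeny as newick
#' @param tree phylo object.
#' @param path output path.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(NULL)
}

#' Write a generic result table as TSV
#' @param x data.frame.
#' @param path output path.
#' @export
write_result_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", na = "NA")
  invisible(NULL)
}

#' Write a bundle of result tables to a directory
#'
#' Dispatches on element names: window stats (windows_*), trees (tree_*),
#' CCV tables (ccvs*), everything else as plain TSV. Fails before writing
#' anything if the directory cannot be created.
#'
#' @param results named list of result objects.
#' @param out_dir output directory.
#' @return invisible vector of written paths.
#' @export
write_outputs <- function(results, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  abort_if(!ok, "cannot create output directory ", out_dir)
  abort_if(file.access(out_dir, 2) != 0, "output directory not writable")
  paths <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (inherits(x, "phylo")) {
      p <- file.path(out_dir, paste0(nm, ".nwk")); write_tree_newick(x, p)
    } else if (startsWith(nm, "windows_")) {
      p <- file.path(out_dir, paste0(nm, ".tsv"))
      write_windows(x, bed_path = file.path(out_dir, paste0(nm, ".bed")),
                    tsv_path = p)
    } else if (startsWith(nm, "ccv")) {
      p <- file.path(out_dir, paste0(nm, ".tsv")); write_ccv_table(x, p)
    } else {
      p <- file.path(out_dir, paste0(nm, ".tsv")); write_result_tsv(x, p)
    }
    paths <- c(paths, p)
  }
  invisible(paths)
}
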