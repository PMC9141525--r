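#' Pipeline run configuration
#'
#' Bundles every analysis threshold in one place (no stage hard-codes
#' them): 100 kb windows for the diversity/divergence scans, 100 bp DMR
#' windows, depth filters of >3 (variants) and >=3 reads (cytosines),
#' MQ > 20, missing fraction < 1 percent, BH alpha 0.05, 25 percent
#' divergence, 20 percent DMG genic fraction, 5 percent dN/dS tails,
#' 500 bp cis-driver flank and the Eigenstrat axis count.
#'
#' @param sim sim_config for the `simulate` stage.
#' @param out_dir output directory.
#' @param ... threshold overrides (see defaults in the function body).
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), out_dir = tempfile("radiadiv_"),
                       ...) {
  rc <- list(
    sim = sim, out_dir = out_dir,
    seed = sim$seed,
    scan_window_bp = 100000L,
    dmr_window_bp = 100L,
    vcf_min_depth = 3L, vcf_min_mq = 20, vcf_max_missing = 0.01,
    meth_min_depth = 3L,
    bh_alpha = 0.05, min_divergence = 0.25, dmg_threshold = 0.20,
    dnds_quantile = 0.05, ldgr_quantile = 0.05, hdgr_quantile = 0.05,
    driver_flank = 500L, n_pcs = 10L,
    driver_thresholds = c(5e-5, 5e-6, 5e-7, 5e-8),
    dmr_min_sites = 3L,
    ld_window_snps = 50L, ld_step = 5L, ld_r2_max = 0.2,
    mdi_reference = NULL, mdi_window_bp = 100000L)
  over <- list(...)
  bad <- setdiff(names(over), names(rc))
  abort_if(length(bad) > 0, "unknown run_config field(s): ",
           paste(bad, collapse = ", "))
  rc[names(over)] <- over
  structure(rc, class = "run_config")
}

stage_order <- c("simulate", "io", "popgen", "ccv", "methylome", "dmr",
                 "integrate")

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order
#' (simulate -> io -> popgen/methylome -> ccv/dmr -> integrate) over a
#' synthetic bundle, writing result tables under `out_dir/results` and a
#' resolved-config snapshot. Re-running with the same configuration
#' produces identical outputs.
#'
#' @param rc run_config.
#' @param stages subset of stages (default all); requesting a stage whose
#'   dependency is absent is an error naming the missing stage.
#' @param state optionally, the state list of a previous partial run.
#' @return invisible state list with all stage results.
#' @export
run_pipeline <- function(rc, stages = stage_order, state = list()) {
  abort_if(!all(stages %in% stage_order), "unknown stage name")
  stages <- stage_order[stage_order %in% stages]
  res_dir <- file.path(rc$out_dir, "results")
  dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)
  need <- function(dep, for_stage)
    abort_if(is.null(state[[dep]]),
             sprintf("stage '%s' requires missing stage '%s'", for_stage, dep))
  log <- function(...) message(sprintf(...))

  if ("simulate" %in% stages) {
    state$simulate <- generate_dataset(rc$sim, file.path(rc$out_dir, "data"))
    log("simulate: %d variants, %d CG sites, %d samples",
        nrow(state$simulate$vars$variants$info),
        length(state$simulate$meth$mm$pos), nrow(state$simulate$sheet))
  }
  if ("io" %in% stages) {
    if (is.null(state$simulate)) {
      ## resume from a previously generated bundle on disk
      data_dir <- file.path(rc$out_dir, "data")
      need_files <- c("sample_sheet.tsv", "variants.vcf", "genes.gff3",
                      "reference.fa")
      if (dir.exists(data_dir) &&
          all(file.exists(file.path(data_dir, need_files)))) {
        rp <- list.files(file.path(data_dir, "reports"), full.names = TRUE)
        names(rp) <- sub("\\.CpG_report\\.txt$", "", basename(rp))
        state$simulate <- list(
          paths = list(sheet = file.path(data_dir, "sample_sheet.tsv"),
                       vcf = file.path(data_dir, "variants.vcf"),
                       gff = file.path(data_dir, "genes.gff3"),
                       fasta = file.path(data_dir, "reference.fa")),
          report_paths = rp)
      }
    }
    need("simulate", "io")
    p <- state$simulate$paths
    sheet <- read_sample_sheet(p$sheet)
    variants <- read_vcf_variants(p$vcf, sheet, min_depth = rc$vcf_min_depth,
                                  min_mq = rc$vcf_min_mq,
                                  max_missing = rc$vcf_max_missing)
    mm_raw <- read_cytosine_report(state$simulate$report_paths)
    mm <- build_methylation_matrix(mm_raw, sheet,
                                   min_depth = rc$meth_min_depth)
    genes <- read_gff3_genes(p$gff)
    reference <- Biostrings::readDNAStringSet(p$fasta)
    names(reference) <- sub(" .*", "", names(reference))
    state$io <- list(sheet = sheet, variants = variants, mm = mm,
                     genes = genes, reference = reference)
    log("io: %d QC-pass variants, %d CG sites after depth filter",
        nrow(variants$info), sum(attr(mm, "qc_mask")))
  }
  sheet <- state$io$sheet; io <- state$io
  simcfg <- rc$sim

  if ("popgen" %in% stages) {
    need("io", "popgen")
    snps <- subset_variants(io$variants, sites = io$variants$info$is_snp)
    chrom_lengths <- setNames(Biostrings::width(io$reference),
                              names(io$reference))
    windows <- make_windows(chrom_lengths, rc$scan_window_bp)
    gA <- clade_samples(sheet, simcfg$dmr_comparison[1])
    gB <- clade_samples(sheet, simcfg$dmr_comparison[2])
    pi_by_clade <- lapply(
      setNames(nm = c(names(simcfg$lineages), simcfg$dmr_comparison)),
      function(cl) window_pi(snps, clade_samples(sheet, cl), windows))
    fst <- window_fst(snps, gA, gB, windows)
    regions <- select_ldgr_hdgr(pi_by_clade[[simcfg$dmr_comparison[1]]],
                                fst, rc$ldgr_quantile, rc$hdgr_quantile)
    pruned <- ld_prune(snps, rc$ld_window_snps, rc$ld_step, rc$ld_r2_max)
    pca <- genotype_pca(pruned$geno, n_components = 10L)
    dst <- allele_sharing_dist(snps)
    tree <- nj_tree(dst)
    dnds <- compute_selection_classes(io$genes, io$reference, io$variants,
                                      sheet, simcfg$selection_comparison,
                                      rc$dnds_quantile)
    dnds_cmp <- compute_selection_classes(io$genes, io$reference, io$variants,
                                          sheet, simcfg$dmr_comparison,
                                          rc$dnds_quantile)
    state$popgen <- list(windows = windows, pi = pi_by_clade, fst = fst,
                         regions = regions, pca = pca, tree = tree,
                         n_pruned = nrow(pruned$info),
                         selection = dnds, selection_cmp = dnds_cmp)
    write_outputs(c(
      list(windows_fst = fst, tree_genome = tree,
           pca_coordinates = as.data.frame(pca$coordinates),
           selection_classes = dnds, selection_classes_cmp = dnds_cmp),
      setNames(pi_by_clade, paste0("windows_pi_", names(pi_by_clade)))),
      res_dir)
    log("popgen: %d SNPs (%d LD-pruned), FST windows=%d, %d positive / %d purifying genes",
        nrow(snps$info), nrow(pruned$info), nrow(fst),
        sum(dnds$class == "positive"), sum(dnds$class == "purifying"))
  }
  if ("ccv" %in% stages) {
    need("io", "ccv")
    tabs <- lapply(simcfg$ccv_pairs, function(pr)
      annotate_ccv_context(call_ccvs(io$variants, sheet, pr[1], pr[2]),
                           io$genes))
    ccvs <- do.call(rbind, tabs)
    state$ccv <- ccvs
    write_outputs(list(ccvs = ccvs), res_dir)
    log("ccv: %d conservative clade-specific variants", nrow(ccvs))
  }
  if ("methylome" %in% stages) {
    need("io", "methylome")
    glob <- data.frame(
      sample_id = sheet$sample_id,
      pct_methylated = vapply(sheet$sample_id, function(s)
        global_methylation_level(io$mm, s), numeric(1)))
    mpca <- methylome_pca(io$mm)
    ## MDI reference defaults to the first A. viridiflora accession (the
    ## published choice) when the panel has one, else the first sample
    viri <- sheet$sample_id[!sheet$is_hybrid & sheet$species == "viridiflora"]
    ref_sample <- rc$mdi_reference %||%
      (if (length(viri)) viri[1] else sheet$sample_id[1])
    mdi <- do.call(rbind, lapply(names(io$reference), function(ch)
      data.frame(chrom = ch, sample_id = sheet$sample_id,
                 mdi = vapply(sheet$sample_id, function(s)
                   compute_mdi(io$mm, s, ref_sample, ch, rc$mdi_window_bp),
                   numeric(1)))))
    islands <- do.call(rbind, lapply(names(io$reference), function(ch) {
      d <- detect_cg_islands(io$reference[[ch]])
      if (nrow(d)) cbind(chrom = ch, d) else NULL
    }))
    groups <- lapply(setNames(nm = names(simcfg$lineages)),
                     function(l) clade_samples(sheet, l))
    prof_gene <- gene_metaprofile(io$mm, io$genes, groups)
    prof_cgi <- if (!is.null(islands) && nrow(islands))
      cgi_metaprofile(io$mm, islands, groups) else NULL
    state$methylome <- list(global = glob, pca = mpca, mdi = mdi,
                            islands = islands, prof_gene = prof_gene,
                            prof_cgi = prof_cgi)
    write_outputs(Filter(Negate(is.null),
      list(global_methylation = glob, mdi = mdi, cg_islands = islands,
           profile_genic = prof_gene, profile_cgi = prof_cgi)), res_dir)
    log("methylome: mean global level %.1f%%, %d CG islands",
        mean(glob$pct_methylated), if (is.null(islands)) 0L else nrow(islands))
  }
  if ("dmr" %in% stages) {
    need("io", "dmr")
    gA <- clade_samples(sheet, simcfg$dmr_comparison[1])
    gB <- clade_samples(sheet, simcfg$dmr_comparison[2])
    dmrs <- scan_dmrs(io$mm, gA, gB, window = rc$dmr_window_bp,
                      min_sites = rc$dmr_min_sites, alpha = rc$bh_alpha,
                      min_div = rc$min_divergence)
    dmgs <- call_dmgs(dmrs, io$genes, rc$dmg_threshold)
    state$dmr <- list(dmrs = dmrs, dmgs = dmgs)
    write_outputs(list(dmrs = dmrs[dmrs$is_dmr, ], dmgs = dmgs), res_dir)
    log("dmr: %d/%d tested windows are DMRs; %d DMGs",
        sum(dmrs$is_dmr), sum(dmrs$tested), sum(dmgs$is_dmg))
  }
  if ("integrate" %in% stages) {
    need("dmr", "integrate"); need("popgen", "integrate")
    cgl <- classify_cg_loss_loci(io$mm, io$variants, io$reference)
    varcat <- variability_categories(io$mm)
    called <- state$dmr$dmrs[state$dmr$dmrs$is_dmr, , drop = FALSE]
    drivers <- cis_driver_scan(called, io$variants, io$mm,
                               flank = rc$driver_flank, n_pcs = rc$n_pcs,
                               thresholds = rc$driver_thresholds)
    assoc <- if (any(state$dmr$dmgs$is_dmg))
      dmg_selection_chisq(state$dmr$dmgs, state$popgen$selection_cmp,
                          paste(simcfg$dmr_comparison, collapse = "-"))
    else {
      message("no DMG called; association table left empty")
      data.frame(comparison = character(0), selection_type = character(0),
                 pct_dmg = numeric(0), pct_non_dmg = numeric(0),
                 n_dmg = integer(0), n_non_dmg = integer(0),
                 chisq = numeric(0), p_value = numeric(0))
    }
    state$integrate <- list(cg_loss = cgl, variability = varcat,
                            drivers = drivers,
                            driver_summary = attr(drivers, "summary"),
                            association = assoc)
    write_outputs(list(cg_loss = cgl, variability = varcat,
                       driver_scan = drivers,
                       driver_summary = attr(drivers, "summary"),
                       dmg_selection = assoc), res_dir)
    log("integrate: %.1f%% CG loci carry CG-loss; %.1f%% DMRs cis-associated at 5e-5",
        100 * mean(cgl$carrying),
        100 * attr(drivers, "summary")$associated_fraction[1])
  }
  cfg <- unclass(rc); cfg$sim <- NULL
  yaml::write_yaml(cfg, file.path(rc$out_dir, "resolved_config.yaml"))
  invisible(state)
}

#' Per-gene mean cross-clade dN/dS and selection classes
#'
#' Convenience wrapper chaining [gene_pairwise_dnds()] over all
#' dnds-eligible genes and [classify_selection()]. Genes whose consensus
#' sequences contain premature stops (e.g. carriers of a planted stop-gain
#' variant) get an undefined mean.
#'
#' @param genes gene table.
#' @param reference DNAStringSet.
#' @param geno variant_set.
#' @param sheet sample sheet.
#' @param comparison length-2 clade labels.
#' @param quantile tail fraction.
#' @return data.frame from [classify_selection()].
#' @export
compute_selection_classes <- function(genes, reference, geno, sheet,
                                      comparison, quantile = 0.05) {
  sA <- clade_samples(sheet, comparison[1])
  sB <- clade_samples(sheet, comparison[2])
  means <- vapply(seq_len(nrow(genes)), function(i) {
    if (!genes$dnds_eligible[i]) return(NA_real_)
    tryCatch(gene_pairwise_dnds(genes[i, , drop = FALSE], reference, geno,
                                sA, sB),
             error = function(e) NA_real_)
  }, numeric(1))
  names(means) <- genes$gene_id
  classify_selection(means, quantile)
}
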