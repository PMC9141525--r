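#' Simulation configuration
#'
#' Defaults emulate the study design the package targets: 3 continental
#' lineages, 10 species, 36 accessions (including 4 putative hybrids of the
#' two focal Asian sister species), 2 chromosomes of 1 Mb. Variants are
#' dropped on the lineage/species tree (clade-fixed, species-fixed and
#' within-species segregating classes), CG methylation follows a bimodal
#' beta mixture with species- and lineage-structured sites, and the planted
#' truth (CCVs, DMRs, cis drivers, CG-loss loci, selection classes) is
#' recorded in a manifest.
#'
#' @param seed integer RNG seed.
#' @param ... overrides for any default listed below.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = 2L,
    chrom_length = 1e6,
    lineages = list(
      Asian = c(japonica = 7L, oxysepala = 7L, yabeana = 2L, viridiflora = 2L),
      European = c(fragrans = 3L, alpina = 3L),
      American = c(coerulea = 2L, formosa = 2L, chrysantha = 2L,
                   canadensis = 2L)),
    n_hybrids = 4L,
    hybrid_parents = c("japonica", "oxysepala"),
    n_genes_per_chrom = 150L,
    gene_codons = c(120L, 350L),
    n_islands_per_chrom = 15L,
    island_length = c(250L, 1500L),
    background_gc = 0.36,
    lineage_snp_rate = 1e-4,
    species_snp_rate = 1e-4,
    poly_snp_rate = 2e-4,
    indel_fraction = 0.1,
    qc_fail_fraction = 0.02,
    ccv_per_pair = 3L,
    ccv_pairs = list(c("japonica", "oxysepala"), c("oxysepala", "japonica"),
                     c("European", "American"), c("European", "Asian"),
                     c("Asian", "American")),
    ccv_genic_fraction = 0.6,
    selection_comparison = c("Asian", "European"),
    n_positive_genes = 15L,
    n_purifying_genes = 15L,
    species_syn_per_gene = 0.15,
    species_nonsyn_per_gene = 0.15,
    cg_loss_fraction = 0.2,
    dmr_comparison = c("japonica", "oxysepala"),
    n_planted_dmrs = 200L,
    dmr_delta_beta = 0.4,
    cis_driver_fraction = 0.5,
    window_bp = 100L,
    meth_weight_high = 0.6,
    beta_high = c(8, 2),
    beta_low = c(2, 8),
    beta_island = c(2, 8),
    lineage_meth_frac = 0.05,
    species_meth_frac = 0.10,
    epimutation_rate = 0.015,
    sample_noise_sd = 0.03,
    depth_mean = 12,
    depth_dispersion = 5,
    vcf_depth_min = 4L,
    vcf_depth_mean = 12,
    vcf_depth_size = 8)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  abort_if(length(bad) > 0, "unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  abort_if(cfg$dmr_delta_beta <= 0 || cfg$dmr_delta_beta > 1,
           "dmr_delta_beta must lie in (0, 1]")
  abort_if(any(unlist(cfg$lineages) < 2L), "need >= 2 samples per species")
  structure(cfg, class = "sim_config")
}

#' Two-group benchmark configuration for DMR calling
#'
#' Two species of 6 samples each on separate lineages, 2 x 1 Mb genome,
#' 200 planted DMRs with a 0.4 beta shift, no other structured effects
#' (no CG-loss, no species- or lineage-level methylation divergence), so
#' every real group difference is a planted one.
#'
#' @param seed RNG seed.
#' @param ... further overrides.
#' @return sim_config.
#' @export
dmr_benchmark_config <- function(seed = 1L, ...) {
  sim_config(seed = seed,
             lineages = list(L1 = c(spA = 6L), L2 = c(spB = 6L)),
             n_hybrids = 0L, hybrid_parents = NULL,
             n_genes_per_chrom = 20L, n_islands_per_chrom = 0L,
             ccv_per_pair = 0L, ccv_pairs = list(),
             selection_comparison = c("L1", "L2"),
             n_positive_genes = 0L, n_purifying_genes = 0L,
             cg_loss_fraction = 0, cis_driver_fraction = 0,
             dmr_comparison = c("spA", "spB"),
             lineage_meth_frac = 0, species_meth_frac = 0,
             epimutation_rate = 0, ...)
}

#' Null configuration (no group effects at all)
#'
#' Like [dmr_benchmark_config()] but with zero planted DMRs and zero
#' per-sample noise: counts are exactly binomial around one shared beta per
#' site, the regime in which the CMH scan's raw p values should be uniform.
#'
#' @param seed RNG seed.
#' @param ... further overrides.
#' @return sim_config.
#' @export
null_methylome_config <- function(seed = 1L, ...) {
  dmr_benchmark_config(seed = seed, n_planted_dmrs = 0L,
                       sample_noise_sd = 0, chrom_length = 1.75e6, ...)
}

#' Sample sheet implied by a simulation configuration
#' @param config sim_config.
#' @return sample_sheet data.frame.
#' @export
sim_sample_sheet <- function(config) {
  rows <- list()
  for (lin in names(config$lineages)) {
    sp <- config$lineages[[lin]]
    for (s in names(sp)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = paste0(s, "_", seq_len(sp[[s]])),
        species = s, lineage = lin, is_hybrid = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  if (config$n_hybrids > 0L) {
    par_lin <- names(Filter(function(x)
      config$hybrid_parents[1] %in% names(x), config$lineages))[1]
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = paste0("hybrid_", seq_len(config$n_hybrids)),
      species = paste(config$hybrid_parents, collapse = "_x_"),
      lineage = par_lin, is_hybrid = TRUE, stringsAsFactors = FALSE)
  }
  sheet <- do.call(rbind, rows)
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}

## iid DNA with given GC content
random_dna <- function(n, gc) {
  sample(c("A", "T", "C", "G"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

.sense_codons <- function() {
  tb <- ng86_tables()
  tb$codons[tb$aa != "*"]
}

## codons whose third position is 4-fold degenerate
.fourfold_codons <- function() {
  pre <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")
  as.vector(outer(pre, c("T", "C", "A", "G"), paste0))
}

#' Simulate a reference genome with genes and CpG islands
#'
#' Background sequence is iid with about 36 percent GC (so spurious
#' CpG-island calls are essentially impossible: random windows fail the
#' GC > 50 percent gate). CpG-rich islands (GC >= 0.6, observed/expected
#' CpG >= 0.8, length 250-1500 bp) and non-overlapping protein-coding
#' genes (CDS from sense codons, length divisible by 3, optional single
#' intron, random strand) are planted at recorded positions.
#'
#' @param config sim_config (caller seeds the RNG; see
#'   [simulate_dataset()]).
#' @return list(seqs: DNAStringSet, genes, islands, cpg: data.frame of all
#'   CpG C positions, cds_mask/cg_mask: per-chromosome logical vectors).
#' @export
simulate_reference <- function(config) {
  L <- config$chrom_length
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  sense <- .sense_codons()
  ## codon usage weighted to the background GC so coding sequence cannot
  ## trip the CpG-island GC gate (uniform codon usage would sit near 50%,
  ## and the scan's run-merging chains sporadic windows into islands)
  cod_gc <- config$background_gc
  base_p <- c(A = (1 - cod_gc) / 2, T = (1 - cod_gc) / 2,
              C = cod_gc / 2, G = cod_gc / 2)
  sense_w <- vapply(strsplit(sense, ""), function(b) prod(base_p[b]), 1)
  fourfold <- .fourfold_codons()
  need <- config$n_genes_per_chrom * (max(config$gene_codons) * 3 + 400) +
    config$n_islands_per_chrom * max(config$island_length)
  abort_if(need > 0.9 * L,
           sprintf("genome too small: need >= %d bp per chromosome", ceiling(need / 0.9)))
  seqs <- list(); genes <- list(); islands <- list()
  gid <- 0L
  for (ch in chroms) {
    base <- random_dna(L, config$background_gc)
    ## feature lengths: genes then islands, shuffled for placement order
    g_spec <- lapply(seq_len(config$n_genes_per_chrom), function(i) {
      n_cod <- sample(config$gene_codons[1]:config$gene_codons[2], 1L)
      two_exon <- runif(1) < 0.4
      intron <- if (two_exon) sample(100:300, 1L) else 0L
      list(kind = "gene", n_cod = n_cod, intron = intron,
           len = n_cod * 3L + intron)
    })
    i_spec <- lapply(seq_len(config$n_islands_per_chrom), function(i)
      list(kind = "island",
           len = sample(config$island_length[1]:config$island_length[2], 1L)))
    feats <- c(g_spec, i_spec)
    if (length(feats)) feats <- feats[sample(length(feats))]
    lens <- vapply(feats, `[[`, numeric(1), "len")
    gap_total <- L - sum(lens) - 200L * (length(feats) + 1L)
    abort_if(gap_total < 0, "genome too small for requested features")
    gw <- runif(length(feats) + 1L)
    gaps <- floor(gw / sum(gw) * gap_total) + 200L
    pos <- 1L
    for (k in seq_along(feats)) {
      pos <- pos + gaps[k]
      f <- feats[[k]]
      s <- pos; e <- pos + f$len - 1L
      if (f$kind == "island") {
        for (try in 1:25) {
          isl <- sample(c("A", "T", "C", "G"), f$len, replace = TRUE,
                        prob = c(0.17, 0.17, 0.33, 0.33))
          nC <- sum(isl == "C"); nG <- sum(isl == "G")
          nCpG <- sum(isl[-f$len] == "C" & isl[-1] == "G")
          gc <- (nC + nG) / f$len
          oe <- if (nC * nG > 0) nCpG / (nC * nG / f$len) else 0
          if (gc >= 0.6 && oe >= 0.8) break
        }
        base[s:e] <- isl
        islands[[length(islands) + 1L]] <-
          data.frame(chrom = ch, start = s - 1L, end = e,
                     stringsAsFactors = FALSE)
      } else {
        gid <- gid + 1L
        cod <- c("ATG", sample(sense, f$n_cod - 1L, replace = TRUE,
                               prob = sense_w))
        cds <- strsplit(paste(cod, collapse = ""), "")[[1]]
        strand <- sample(c("+", "-"), 1L)
        if (f$intron > 0L) {
          cut <- 3L * sample(10:(f$n_cod - 10L), 1L)  # codon boundary
          seg1 <- c(s, s + cut - 1L)
          seg2 <- c(s + cut + f$intron, e)
          segs <- rbind(seg1, seg2)
        } else segs <- matrix(c(s, e), 1L, 2L)
        genic <- if (strand == "+") cds else
          rev(chartr("ACGT", "TGCA", cds))
        off <- 0L
        for (r in seq_len(nrow(segs))) {
          w <- segs[r, 2] - segs[r, 1] + 1L
          base[segs[r, 1]:segs[r, 2]] <- genic[(off + 1L):(off + w)]
          off <- off + w
        }
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = sprintf("gene%04d", gid), chrom = ch, start = s, end = e,
          strand = strand, stringsAsFactors = FALSE)
        genes[[length(genes)]]$cds <- list(unname(segs))
      }
      pos <- e + 1L
    }
    seqs[[ch]] <- paste(base, collapse = "")
  }
  genes <- do.call(rbind, genes)
  genes$start <- as.integer(genes$start); genes$end <- as.integer(genes$end)
  genes$cds <- lapply(genes$cds, function(m)
    matrix(as.integer(m), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  genes$tss <- ifelse(genes$strand == "-", genes$end, genes$start)
  genes$tes <- ifelse(genes$strand == "-", genes$start, genes$end)
  genes$dnds_eligible <- TRUE
  islands <- if (length(islands)) do.call(rbind, islands) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  dss <- Biostrings::DNAStringSet(unlist(seqs))
  names(dss) <- chroms
  ## CpG grid and masks
  cpg <- list(); cds_mask <- list(); cg_mask <- list()
  for (ch in chroms) {
    v <- strsplit(seqs[[ch]], "")[[1]]
    p <- which(v[-length(v)] == "C" & v[-1] == "G")
    cpg[[ch]] <- data.frame(chrom = ch, pos = p, stringsAsFactors = FALSE)
    cm <- logical(L)
    gch <- genes[genes$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(gch)))
      for (r in seq_len(nrow(gch$cds[[i]])))
        cm[gch$cds[[i]][r, 1]:gch$cds[[i]][r, 2]] <- TRUE
    cds_mask[[ch]] <- cm
    km <- logical(L); km[p] <- TRUE; km[p + 1L] <- TRUE
    cg_mask[[ch]] <- km
  }
  list(seqs = dss, genes = genes, islands = islands,
       cpg = do.call(rbind, cpg), cds_mask = cds_mask, cg_mask = cg_mask)
}

## ---- variant simulation ----------------------------------------------------

## genomic coordinates of each coding position of a gene (coding order)
coding_map <- function(gene) {
  segs <- gene$cds[[1]]
  g <- unlist(lapply(seq_len(nrow(segs)), function(r) segs[r, 1]:segs[r, 2]))
  if (gene$strand == "-") rev(g) else g
}

comp_base <- function(b) chartr("ACGT", "TGCA", b)

#' Simulate clade-structured variants with planted truth
#'
#' Variants are dropped on the lineage/species tree: lineage-fixed,
#' species-fixed and within-species segregating classes (a configured
#' fraction as 1-3 bp INDELs), placed outside coding sequence and outside
#' CpG dinucleotides. On top of the background: per-gene synonymous /
#' nonsynonymous coding substitutions realizing the planted selection
#' classes, conservative clade-specific high-impact variants (CCVs,
#' homozygous-alternate in every carrier-clade sample, homozygous-reference
#' everywhere else), CG-loss SNPs ablating CpG dinucleotides, cis-driver
#' variants for a fraction of planted DMR windows, and a small set of
#' QC-fail chaff records (low MQ or low DP) that the VCF reader must drop.
#' Hybrid genotypes are drawn allele-wise from the two parent species'
#' realized allele frequencies.
#'
#' @param config sim_config.
#' @param ref output of [simulate_reference()].
#' @return list(variants: variant_set (QC-pass truth), emit: emission table
#'   for [generate_dataset()], manifest: planted-truth list).
#' @export
simulate_variants <- function(config, ref) {
  sheet <- sim_sample_sheet(config)
  samples <- sheet$sample_id
  ns <- length(samples)
  chroms <- names(ref$seqs)
  L <- config$chrom_length
  species <- unique(sheet$species[!sheet$is_hybrid])
  sp_samples <- lapply(setNames(species, species),
                       function(s) sheet$sample_id[sheet$species == s])
  lin_samples <- lapply(setNames(names(config$lineages), names(config$lineages)),
                        function(l) sheet$sample_id[sheet$lineage == l &
                                                    !sheet$is_hybrid])
  hybrids <- sheet$sample_id[sheet$is_hybrid]

  occupied <- lapply(setNames(chroms, chroms), function(ch) logical(L))
  seq_chars <- lapply(setNames(chroms, chroms), function(ch)
    strsplit(as.character(ref$seqs[[ch]]), "")[[1]])

  rows <- list()   # each: list(chrom,pos,ref,alt,consequence,impact,gene_id,dosage,tag)
  add_row <- function(chrom, pos, refa, alta, consequence, impact, gene_id,
                      dosage, tag) {
    rows[[length(rows) + 1L]] <<- list(
      chrom = chrom, pos = pos, ref = refa, alt = alta,
      consequence = consequence, impact = impact, gene_id = gene_id,
      dosage = dosage, tag = tag)
    span <- pos:(pos + nchar(refa) - 1L)
    occupied[[chrom]][span] <<- TRUE
  }
  genic_annot <- function(chrom, pos) {
    g <- ref$genes
    hit <- which(g$chrom == chrom & g$start <= pos & g$end >= pos)
    if (length(hit)) list(consequence = "intron_variant", impact = "MODIFIER",
                          gene_id = g$gene_id[hit[1]])
    else list(consequence = "intergenic_region", impact = "MODIFIER",
              gene_id = NA_character_)
  }
  free_pool <- function(ch, span = 1L) {
    ok <- !occupied[[ch]] & !ref$cds_mask[[ch]] & !ref$cg_mask[[ch]]
    ok[(L - 4L):L] <- FALSE
    if (span > 1L)
      for (k in 1L:(span - 1L)) ok <- ok & c(ok[-seq_len(k)], rep(FALSE, k))
    which(ok)
  }
  dosage_for <- function(carrier_samples, value = 2L) {
    d <- integer(ns); names(d) <- samples
    d[carrier_samples] <- value
    d
  }

  ## -- background tree-drop variants (non-coding, non-CpG) --
  for (ch in chroms) {
    n_lin <- rpois(length(lin_samples), config$lineage_snp_rate * L)
    n_sp <- rpois(length(sp_samples), config$species_snp_rate * L)
    n_poly <- rpois(length(sp_samples), config$poly_snp_rate * L)
    total <- sum(n_lin) + sum(n_sp) + sum(n_poly)
    if (total == 0L) next
    pool <- free_pool(ch, span = 4L)
    pos_all <- sort(sample(pool, total))
    ## enforce pairwise distance >= 4 so indel spans cannot collide
    keep <- c(TRUE, diff(pos_all) >= 4L)
    pos_all <- pos_all[keep]
    total <- length(pos_all)
    owner <- sample(rep(c(paste0("lin:", names(lin_samples)),
                          paste0("sp:", names(sp_samples)),
                          paste0("poly:", names(sp_samples))),
                        times = c(n_lin, n_sp, n_poly))[seq_len(total)])
    is_indel <- runif(total) < config$indel_fraction
    for (k in seq_len(total)) {
      p <- pos_all[k]
      refb <- seq_chars[[ch]][p]
      if (is_indel[k]) {
        if (runif(1) < 0.5) {          # insertion
          refa <- refb
          alta <- paste0(refb, paste(random_dna(sample(1:3, 1L), 0.4),
                                     collapse = ""))
        } else {                        # deletion
          dl <- sample(1:3, 1L)
          refa <- paste(seq_chars[[ch]][p:(p + dl)], collapse = "")
          alta <- refb
        }
      } else {
        refa <- refb
        alta <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
      }
      ow <- strsplit(owner[k], ":", fixed = TRUE)[[1]]
      if (ow[1] == "lin") d <- dosage_for(lin_samples[[ow[2]]])
      else if (ow[1] == "sp") d <- dosage_for(sp_samples[[ow[2]]])
      else {
        f <- runif(1, 0.1, 0.9)
        d <- integer(ns); names(d) <- samples
        d[sp_samples[[ow[2]]]] <- rbinom(length(sp_samples[[ow[2]]]), 2L, f)
      }
      an <- genic_annot(ch, p)
      add_row(ch, p, refa, alta, an$consequence, an$impact, an$gene_id, d,
              "background")
    }
  }

  ## -- per-gene coding substitutions realizing selection classes --
  tbng <- ng86_tables()
  fourfold <- .fourfold_codons()
  genes <- ref$genes
  sel_cfg <- config$selection_comparison
  clade_of <- function(lab) {
    if (lab %in% names(lin_samples)) lin_samples[[lab]] else sp_samples[[lab]]
  }
  sel_class <- rep("background", nrow(genes))
  if (config$n_positive_genes + config$n_purifying_genes > 0L) {
    idx <- sample(nrow(genes), config$n_positive_genes + config$n_purifying_genes)
    sel_class[idx[seq_len(config$n_positive_genes)]] <- "positive"
    if (config$n_purifying_genes > 0L)
      sel_class[idx[config$n_positive_genes + seq_len(config$n_purifying_genes)]] <-
        "purifying"
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, , drop = FALSE]
    cmap <- coding_map(g)
    n_cod <- length(cmap) %/% 3L
    cds <- vapply(seq_len(n_cod), function(k) {
      b <- seq_chars[[g$chrom]][cmap[(3 * k - 2):(3 * k)]]
      if (g$strand == "-") b <- comp_base(b)
      paste(b, collapse = "")
    }, "")
    counts <- switch(sel_class[i],
      positive = c(nonsyn = 14L + rpois(1, 2), syn = 1L),
      purifying = c(nonsyn = 1L, syn = 14L + rpois(1, 2)),
      background = c(nonsyn = 1L + rpois(1, 1), syn = 1L + rpois(1, 1)))
    cand_syn <- which(cds %in% fourfold)
    n_syn <- min(counts[["syn"]], length(cand_syn))
    syn_idx <- if (n_syn > 0) sample(cand_syn, n_syn) else integer(0)
    cand_non <- setdiff(2:n_cod, syn_idx)
    n_non <- min(counts[["nonsyn"]], length(cand_non))
    non_idx <- if (n_non > 0) sample(cand_non, n_non) else integer(0)
    plant_sub <- function(cod_idx, kind, carrier) {
      cod <- cds[cod_idx]
      if (kind == "syn") {
        cp <- 3L
        newb <- sample(setdiff(c("A", "C", "G", "T"), substr(cod, 3, 3)), 1L)
      } else {
        cp <- 2L
        opts <- setdiff(c("A", "C", "G", "T"), substr(cod, 2, 2))
        ok <- vapply(opts, function(b) {
          alt <- cod; substr(alt, 2, 2) <- b
          tbng$aa[alt] != "*" && tbng$aa[alt] != tbng$aa[cod]
        }, logical(1))
        if (!any(ok)) return(invisible(NULL))
        newb <- sample(rep(opts[ok], 2L), 1L)
      }
      coding_pos <- 3L * (cod_idx - 1L) + cp
      gpos <- cmap[coding_pos]
      refb <- seq_chars[[g$chrom]][gpos]
      altb <- if (g$strand == "-") comp_base(newb) else newb
      if (occupied[[g$chrom]][gpos] || altb == refb) return(invisible(NULL))
      add_row(g$chrom, gpos, refb, altb,
              if (kind == "syn") "synonymous_variant" else "missense_variant",
              if (kind == "syn") "LOW" else "MODERATE",
              g$gene_id, dosage_for(carrier), paste0("selection_", kind))
    }
    for (k in syn_idx) plant_sub(k, "syn", clade_of(sample(sel_cfg, 1L)))
    for (k in non_idx) plant_sub(k, "nonsyn", clade_of(sample(sel_cfg, 1L)))
    ## species-private coding substitutions: every species pair then has
    ## defined dN/dS, independent of the clade-level planted classes
    used <- c(syn_idx, non_idx)
    for (sp in names(sp_samples)) {
      ks <- rpois(1, config$species_syn_per_gene)
      kn <- rpois(1, config$species_nonsyn_per_gene)
      if (ks > 0L) {
        cand <- setdiff(cand_syn, used)
        take <- head(sample(cand), ks); used <- c(used, take)
        for (k in take) plant_sub(k, "syn", sp_samples[[sp]])
      }
      if (kn > 0L) {
        cand <- setdiff(2:n_cod, used)
        take <- head(sample(cand), kn); used <- c(used, take)
        for (k in take) plant_sub(k, "nonsyn", sp_samples[[sp]])
      }
    }
  }
  manifest_selection <- data.frame(gene_id = genes$gene_id, class = sel_class,
                                   stringsAsFactors = FALSE)

  ## -- planted CCVs --
  ccv_classes <- c(frameshift = "frameshift_variant",
                   stop_gain = "stop_gained", stop_loss = "stop_lost",
                   start_loss = "start_lost", splicing = "splice_donor_variant")
  manifest_ccv <- list()
  if (config$ccv_per_pair > 0L) for (pair in config$ccv_pairs) {
    for (k in seq_len(config$ccv_per_pair)) {
      cls <- sample(names(ccv_classes), 1L)
      genic <- runif(1) < config$ccv_genic_fraction
      for (try in 1:50) {
        if (genic) {
          gi <- sample(nrow(genes), 1L)
          cmap <- coding_map(genes[gi, , drop = FALSE])
          p <- sample(cmap, 1L)
          ch <- genes$chrom[gi]; gene_id <- genes$gene_id[gi]
        } else {
          ch <- sample(chroms, 1L)
          p <- free_pool(ch, span = 4L)
          p <- sample(p, 1L)
          gene_id <- NA_character_
          cls <- sample(c("splicing"), 1L)
        }
        if (!occupied[[ch]][p]) break
      }
      if (occupied[[ch]][p]) next   # placement failed after retries; logged
      refb <- seq_chars[[ch]][p]
      if (cls == "frameshift") {
        refa <- refb; alta <- paste0(refb, paste(random_dna(2, 0.4), collapse = ""))
      } else {
        refa <- refb; alta <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
      }
      carrier_s <- clade_of(pair[1])
      d <- dosage_for(carrier_s)
      add_row(ch, p, refa, alta, ccv_classes[[cls]], "HIGH", gene_id, d, "ccv")
      manifest_ccv[[length(manifest_ccv) + 1L]] <- data.frame(
        chrom = ch, pos = p, ref = refa, alt = alta,
        carrier = pair[1], reference = pair[2], impact_class = cls,
        gene_id = gene_id, stringsAsFactors = FALSE)
    }
  }
  manifest_ccv <- if (length(manifest_ccv)) do.call(rbind, manifest_ccv) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), carrier = character(0),
               reference = character(0), impact_class = character(0),
               gene_id = character(0))

  ## -- planted DMR windows (selected here so CG-loss avoids them; the
  ##    methylation effects themselves are realized in simulate_methylomes) --
  wbp <- config$window_bp
  manifest_dmr <- NULL
  if (config$n_planted_dmrs > 0L) {
    cand <- list()
    for (ch in chroms) {
      p <- ref$cpg[ref$cpg$chrom == ch, "pos"]
      wi <- window_index(p, wbp)
      cnt <- table(wi)
      ## planted DMRs sit in CpG-dense windows (>= 6 CpGs): a differentially
      ## methylated region is only meaningful where there is CpG signal to
      ## carry it, and the pooled-beta phenotype is then well measured
      good <- as.integer(names(cnt))[cnt >= 6L]
      ## windows free of coding sequence
      cdsm <- ref$cds_mask[[ch]]
      ok <- vapply(good, function(w)
        !any(cdsm[(w * wbp + 1L):min(L, (w + 1L) * wbp)]), logical(1))
      cand[[ch]] <- data.frame(chrom = ch, win = good[ok],
                               stringsAsFactors = FALSE)
    }
    cand <- do.call(rbind, cand)
    abort_if(nrow(cand) < config$n_planted_dmrs,
             "not enough eligible windows for planted DMRs")
    sel <- cand[sample(nrow(cand), config$n_planted_dmrs), , drop = FALSE]
    manifest_dmr <- data.frame(
      chrom = sel$chrom, start = sel$win * wbp, end = (sel$win + 1L) * wbp,
      comparison = paste(config$dmr_comparison, collapse = "_vs_"),
      base_beta = runif(nrow(sel), 0.1, 0.5),
      delta_beta = config$dmr_delta_beta,
      driver = runif(nrow(sel)) < config$cis_driver_fraction,
      driver_pos = NA_integer_, stringsAsFactors = FALSE)
  }

  ## -- cis-driver variants for driver-paired DMR windows --
  if (!is.null(manifest_dmr) && any(manifest_dmr$driver)) {
    gA <- sp_samples[[config$dmr_comparison[1]]]
    gB <- sp_samples[[config$dmr_comparison[2]]]
    others <- setdiff(samples, c(gA, gB, hybrids))
    for (i in which(manifest_dmr$driver)) {
      ch <- manifest_dmr$chrom[i]
      cand <- (manifest_dmr$start[i] + 1L):manifest_dmr$end[i]
      cand <- cand[!occupied[[ch]][cand] & !ref$cg_mask[[ch]][cand]]
      if (!length(cand)) { manifest_dmr$driver[i] <- FALSE; next }
      p <- sample(cand, 1L)
      refb <- seq_chars[[ch]][p]
      alta <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
      d <- integer(ns); names(d) <- samples
      d[gA] <- rbinom(length(gA), 2L, 0.85)
      d[gB] <- rbinom(length(gB), 2L, 0.15)
      d[others] <- rbinom(length(others), 2L, 0.5)
      an <- genic_annot(ch, p)
      add_row(ch, p, refb, alta, an$consequence, an$impact, an$gene_id, d,
              "driver")
      manifest_dmr$driver_pos[i] <- p
    }
  }

  ## -- CG-loss SNPs on CpG dinucleotides (outside CDS and planted DMRs) --
  manifest_cgl <- NULL
  if (config$cg_loss_fraction > 0) {
    cpg <- ref$cpg
    elig <- rep(TRUE, nrow(cpg))
    for (ch in chroms) {
      on <- cpg$chrom == ch
      p <- cpg$pos[on]
      bad <- ref$cds_mask[[ch]][p] | ref$cds_mask[[ch]][p + 1L] |
        occupied[[ch]][p] | occupied[[ch]][p + 1L]
      if (!is.null(manifest_dmr)) {
        md <- manifest_dmr[manifest_dmr$chrom == ch, , drop = FALSE]
        if (nrow(md)) {
          wi <- window_index(p, wbp)
          bad <- bad | wi %in% (md$start %/% wbp)
        }
      }
      elig[on] <- !bad
    }
    n_cgl <- floor(config$cg_loss_fraction * nrow(cpg))
    pick <- sample(which(elig), min(n_cgl, sum(elig)))
    kind_w <- c(lin = 0.2, sp = 0.4, poly = 0.4)
    cgl_rows <- vector("list", length(pick))
    for (j in seq_along(pick)) {
      i <- pick[j]
      ch <- cpg$chrom[i]; cpos <- cpg$pos[i]
      on_c <- runif(1) < 0.5
      p <- if (on_c) cpos else cpos + 1L
      refb <- if (on_c) "C" else "G"
      alta <- if (on_c) sample(c("T", "A"), 1L) else sample(c("A", "T"), 1L)
      kind <- sample(names(kind_w), 1L, prob = kind_w)
      if (kind == "lin") d <- dosage_for(lin_samples[[sample(names(lin_samples), 1L)]])
      else if (kind == "sp") d <- dosage_for(sp_samples[[sample(names(sp_samples), 1L)]])
      else {
        spn <- sample(names(sp_samples), 1L)
        f <- runif(1, 0.2, 0.8)
        d <- integer(ns); names(d) <- samples
        d[sp_samples[[spn]]] <- rbinom(length(sp_samples[[spn]]), 2L, f)
      }
      an <- genic_annot(ch, p)
      add_row(ch, p, refb, alta, an$consequence, an$impact, an$gene_id, d,
              "cg_loss")
      cgl_rows[[j]] <- data.frame(chrom = ch, c_pos = cpos, var_pos = p,
                                  ref = refb, alt = alta,
                                  stringsAsFactors = FALSE)
    }
    manifest_cgl <- do.call(rbind, cgl_rows)
  }

  ## -- QC-fail chaff (low MQ or low DP; must be dropped by the reader) --
  n_chaff <- floor(config$qc_fail_fraction * length(rows))
  chaff_idx <- integer(0)
  if (n_chaff > 0L) for (k in seq_len(n_chaff)) {
    ch <- sample(chroms, 1L)
    pool <- free_pool(ch)
    p <- sample(pool, 1L)
    refb <- seq_chars[[ch]][p]
    alta <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
    an <- genic_annot(ch, p)
    d <- dosage_for(sample(samples, sample(3:10, 1L)), value = 1L)
    add_row(ch, p, refb, alta, an$consequence, an$impact, an$gene_id, d,
            if (runif(1) < 0.5) "chaff_mq" else "chaff_dp")
    chaff_idx <- c(chaff_idx, length(rows))
  }

  ## -- assemble; draw hybrid genotypes from parent allele frequencies --
  info <- data.frame(
    chrom = vapply(rows, `[[`, "", "chrom"),
    pos = vapply(rows, function(r) as.integer(r$pos), 1L),
    ref = vapply(rows, `[[`, "", "ref"),
    alt = vapply(rows, `[[`, "", "alt"),
    consequence = vapply(rows, `[[`, "", "consequence"),
    impact = vapply(rows, `[[`, "", "impact"),
    gene_id = vapply(rows, function(r) as.character(r$gene_id), ""),
    tag = vapply(rows, `[[`, "", "tag"),
    stringsAsFactors = FALSE)
  geno <- do.call(rbind, lapply(rows, `[[`, "dosage"))
  colnames(geno) <- samples
  if (length(hybrids) > 0L) {
    p1 <- sp_samples[[config$hybrid_parents[1]]]
    p2 <- sp_samples[[config$hybrid_parents[2]]]
    f1 <- rowMeans(geno[, p1, drop = FALSE]) / 2
    f2 <- rowMeans(geno[, p2, drop = FALSE]) / 2
    for (h in hybrids)
      geno[, h] <- rbinom(nrow(geno), 1L, f1) + rbinom(nrow(geno), 1L, f2)
  }
  o <- order(info$chrom, info$pos)
  info <- info[o, , drop = FALSE]; geno <- geno[o, , drop = FALSE]
  rownames(info) <- NULL
  is_chaff <- info$tag %in% c("chaff_mq", "chaff_dp")
  mq <- round(pmax(30, rnorm(nrow(info), 50, 5)), 1)
  mq[info$tag == "chaff_mq"] <- 15
  info$mq <- mq
  clean <- variant_set(
    info[!is_chaff, setdiff(names(info), "tag"), drop = FALSE],
    geno[!is_chaff, , drop = FALSE], samples)
  list(variants = clean,
       emit = list(info = info, geno = geno),
       manifest = list(selection = manifest_selection, ccvs = manifest_ccv,
                       dmrs = manifest_dmr, cg_loss = manifest_cgl))
}

## ---- methylome simulation --------------------------------------------------

rbeta2 <- function(n, ab) rbeta(n, ab[1], ab[2])

#' Simulate per-sample cytosine methylation counts
#'
#' Latent per-site beta values follow a bimodal beta mixture (plant
#' gene-body-like), with island sites drawn from a low-methylation
#' distribution. A configured fraction of sites is redrawn per lineage and
#' per species (creating the clade structure the methylome PCA and MDI see).
#' Planted DMR windows shift the compared groups by delta-beta (driver
#' windows key the shift to the driver genotype dosage instead of the
#' species label); any variant ablating a CpG (CG-loss) multiplies the
#' carrier's beta by 1 - dosage/2. Per-sample noise is Gaussian on beta;
#' read depths are negative-binomial per strand and methylated counts
#' binomial given depth and beta.
#'
#' @param config sim_config.
#' @param ref output of [simulate_reference()].
#' @param vars output of [simulate_variants()].
#' @return list(mm: methylation_matrix of merged counts, strands: per-strand
#'   count matrices for report emission, manifest: list(dmrs, cg_loss)).
#' @export
simulate_methylomes <- function(config, ref, vars) {
  sheet <- sim_sample_sheet(config)
  samples <- sheet$sample_id
  ns <- length(samples)
  cpg <- ref$cpg
  n <- nrow(cpg)
  species <- unique(sheet$species[!sheet$is_hybrid])
  wbp <- config$window_bp

  mix_draw <- function(k) {
    hi <- runif(k) < config$meth_weight_high
    ifelse(hi, rbeta2(k, config$beta_high), rbeta2(k, config$beta_low))
  }
  beta0 <- mix_draw(n)
  if (nrow(ref$islands)) {
    isl <- rep(FALSE, n)
    for (r in seq_len(nrow(ref$islands))) {
      on <- cpg$chrom == ref$islands$chrom[r] &
        cpg$pos > ref$islands$start[r] & cpg$pos <= ref$islands$end[r]
      isl[on] <- TRUE
    }
    beta0[isl] <- rbeta2(sum(isl), config$beta_island)
  }
  bsp <- matrix(beta0, n, length(species),
                dimnames = list(NULL, species))

  ## site keys of planted DMR windows (excluded from clade redraws)
  dmr_manifest <- vars$manifest$dmrs
  in_dmr <- rep(FALSE, n)
  if (!is.null(dmr_manifest) && nrow(dmr_manifest)) {
    key_d <- paste0(dmr_manifest$chrom, ":", dmr_manifest$start %/% wbp)
    in_dmr <- paste0(cpg$chrom, ":", window_index(cpg$pos, wbp)) %in% key_d
  }
  free <- which(!in_dmr)
  ## clade-structured methylation comes in regional blocks (~300 bp), the
  ## way heritable epimutations spread over neighbouring CpGs; block count
  ## is set so the expected redrawn-site fraction matches the configured one
  chrom_rle <- rle(cpg$chrom)
  chrom_off <- c(0L, cumsum(chrom_rle$lengths))
  redraw_blocks <- function(frac, half = 150L) {
    m <- max(1L, floor(frac * n / 8))
    anchors <- sample(free, m)
    hit <- unlist(lapply(anchors, function(a) {
      ci <- findInterval(a, chrom_off + 1L)   # chromosome block of index a
      lo <- chrom_off[ci] + 1L; hi <- chrom_off[ci + 1L]
      p <- cpg$pos[lo:hi]
      i1 <- findInterval(cpg$pos[a] - half - 1L, p) + 1L
      i2 <- findInterval(cpg$pos[a] + half, p)
      if (i2 < i1) integer(0) else (lo:hi)[i1:i2]
    }))
    hit <- unique(hit)
    hit[!in_dmr[hit]]
  }
  if (config$lineage_meth_frac > 0) for (lin in names(config$lineages)) {
    pickl <- redraw_blocks(config$lineage_meth_frac)
    bsp[pickl, names(config$lineages[[lin]])] <- mix_draw(length(pickl))
  }
  if (config$species_meth_frac > 0) for (s in species) {
    picks <- redraw_blocks(config$species_meth_frac)
    bsp[picks, s] <- mix_draw(length(picks))
  }

  ## planted DMR effects at the species level (driver windows stay at base)
  site_window <- paste0(cpg$chrom, ":", window_index(cpg$pos, wbp))
  if (!is.null(dmr_manifest) && nrow(dmr_manifest)) {
    spA <- config$dmr_comparison[1]; spB <- config$dmr_comparison[2]
    for (i in seq_len(nrow(dmr_manifest))) {
      on <- site_window == paste0(dmr_manifest$chrom[i], ":",
                                  dmr_manifest$start[i] %/% wbp)
      b <- dmr_manifest$base_beta[i]; dlt <- dmr_manifest$delta_beta[i]
      if (dmr_manifest$driver[i]) {
        bsp[on, ] <- b
      } else {
        bsp[on, ] <- b + dlt / 2
        bsp[on, spA] <- clamp(b + dlt, 0.001, 0.999)
        bsp[on, spB] <- b
      }
    }
  }

  ## expand to samples (+ hybrid mid-parent, + noise)
  sp_of <- sheet$species; names(sp_of) <- sheet$sample_id
  B <- matrix(0, n, ns, dimnames = list(NULL, samples))
  for (s in samples) {
    if (sheet$is_hybrid[match(s, sheet$sample_id)]) {
      B[, s] <- (bsp[, config$hybrid_parents[1]] +
                 bsp[, config$hybrid_parents[2]]) / 2
    } else B[, s] <- bsp[, sp_of[[s]]]
  }
  if (config$sample_noise_sd > 0)
    B <- clamp(B + matrix(rnorm(n * ns, 0, config$sample_noise_sd), n, ns),
               0.001, 0.999)

  ## sporadic epimutations: individual site-x-sample cells redrawn from the
  ## baseline mixture, the stochastic epiallele component that gives
  ## non-variant loci their intra-species variability; planted DMR windows
  ## are spared so their calibrated effects stay intact
  if (config$epimutation_rate > 0) {
    cells <- which(matrix(runif(n * ns) < config$epimutation_rate, n, ns) &
                   !in_dmr)
    if (length(cells)) B[cells] <- mix_draw(length(cells))
  }

  ## driver windows: beta keyed to driver genotype dosage
  if (!is.null(dmr_manifest) && any(dmr_manifest$driver)) {
    vinfo <- vars$variants$info
    for (i in which(dmr_manifest$driver)) {
      vp <- dmr_manifest$driver_pos[i]
      vi <- which(vinfo$chrom == dmr_manifest$chrom[i] & vinfo$pos == vp)
      if (!length(vi)) next
      dos <- vars$variants$geno[vi[1], ]
      on <- site_window == paste0(dmr_manifest$chrom[i], ":",
                                  dmr_manifest$start[i] %/% wbp)
      b <- dmr_manifest$base_beta[i]; dlt <- dmr_manifest$delta_beta[i]
      shift <- b + dlt * ifelse(is.na(dos), 1, dos) / 2
      eps <- if (config$sample_noise_sd > 0)
        matrix(rnorm(sum(on) * ns, 0, config$sample_noise_sd), sum(on), ns)
        else 0
      B[on, ] <- clamp(matrix(shift, sum(on), ns, byrow = TRUE) + eps,
                       0.001, 0.999)
    }
  }

  ## CG-loss ablation: any variant hitting a CpG dinucleotide
  mm_grid <- methylation_matrix(cpg$chrom, cpg$pos,
                                matrix(0L, n, 1, dimnames = list(NULL, "g")),
                                matrix(0L, n, 1, dimnames = list(NULL, "g")),
                                "g")
  cgl <- classify_cg_loss_loci(mm_grid, vars$variants)
  dos_cg <- attr(cgl, "dosage")
  carrying <- which(cgl$carrying)
  if (length(carrying)) {
    d <- dos_cg[carrying, samples, drop = FALSE]
    d[is.na(d)] <- 0L
    B[carrying, ] <- B[carrying, , drop = FALSE] * (1 - d / 2)
  }

  ## read depths per strand, methylated counts binomial given beta
  mu <- config$depth_mean / 2; sz <- config$depth_dispersion
  dp_p <- matrix(rnbinom(n * ns, mu = mu, size = sz), n, ns,
                 dimnames = list(NULL, samples))
  dp_m <- matrix(rnbinom(n * ns, mu = mu, size = sz), n, ns,
                 dimnames = list(NULL, samples))
  me_p <- matrix(rbinom(n * ns, dp_p, B), n, ns, dimnames = list(NULL, samples))
  me_m <- matrix(rbinom(n * ns, dp_m, B), n, ns, dimnames = list(NULL, samples))
  mm <- methylation_matrix(cpg$chrom, cpg$pos, me_p + me_m, dp_p + dp_m,
                           samples)
  list(mm = mm,
       strands = list(chrom = cpg$chrom, pos = cpg$pos,
                      dp_plus = dp_p, me_plus = me_p,
                      dp_minus = dp_m, me_minus = me_m),
       manifest = list(dmrs = dmr_manifest, cg_loss = cgl))
}

#' Simulate a complete in-memory dataset
#'
#' Seeds the RNG from `config$seed` and chains
#' [simulate_reference()], [simulate_variants()] and
#' [simulate_methylomes()]. Deterministic given the seed.
#'
#' @param config sim_config.
#' @return list(config, sheet, ref, vars, meth, manifest).
#' @export
simulate_dataset <- function(config) {
  set.seed(config$seed)
  ref <- simulate_reference(config)
  vars <- simulate_variants(config, ref)
  meth <- simulate_methylomes(config, ref, vars)
  manifest <- c(vars$manifest["selection"], vars$manifest["ccvs"],
                meth$manifest)
  list(config = config, sheet = sim_sample_sheet(config), ref = ref,
       vars = vars, meth = meth, manifest = manifest)
}

## ---- file emission ---------------------------------------------------------

write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, , drop = FALSE]
    lines <- c(lines,
      paste(g$chrom, "radiadiv", "gene", g$start, g$end, ".", g$strand, ".",
            paste0("ID=", g$gene_id), sep = "\t"),
      paste(g$chrom, "radiadiv", "mRNA", g$start, g$end, ".", g$strand, ".",
            paste0("ID=", g$gene_id, ".1;Parent=", g$gene_id), sep = "\t"))
    segs <- g$cds[[1]]
    phase <- 0L
    ord <- if (g$strand == "-") rev(seq_len(nrow(segs))) else seq_len(nrow(segs))
    ph <- integer(nrow(segs))
    for (k in seq_along(ord)) {
      ph[ord[k]] <- phase
      phase <- (3L - ((segs[ord[k], 2] - segs[ord[k], 1] + 1L - phase) %% 3L)) %% 3L
    }
    for (r in seq_len(nrow(segs)))
      lines <- c(lines,
        paste(g$chrom, "radiadiv", "CDS", segs[r, 1], segs[r, 2], ".",
              g$strand, ph[r],
              paste0("ID=", g$gene_id, ".1.cds;Parent=", g$gene_id, ".1"),
              sep = "\t"))
  }
  writeLines(lines, path)
}

write_sim_vcf <- function(emit, samples, config, path) {
  info <- emit$info; geno <- emit$geno
  dp <- matrix(config$vcf_depth_min +
                 rnbinom(nrow(info) * length(samples),
                         mu = config$vcf_depth_mean, size = config$vcf_depth_size),
               nrow(info), length(samples))
  dp[info$tag == "chaff_dp", ] <- 2L
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c("##fileformat=VCFv4.2",
    "##source=radiadiv-simulator",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    paste0("##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional ",
           "annotations: 'Allele|Annotation|Impact|Gene'\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  ann <- paste0(info$alt, "|", info$consequence, "|", info$impact, "|",
                ifelse(is.na(info$gene_id), "", info$gene_id), "|||||")
  body <- vapply(seq_len(nrow(info)), function(i) {
    gts <- gt_code[as.character(geno[i, ])]
    gts[is.na(gts)] <- "./."
    paste(c(info$chrom[i], info$pos[i], ".", info$ref[i], info$alt[i],
            "100", "PASS",
            paste0("MQ=", info$mq[i], ";ANN=", ann[i]), "GT:DP",
            paste0(gts, ":", dp[i, ])), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
}

write_cytosine_reports <- function(strands, samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (s in samples) {
    plus <- data.table::data.table(
      chrom = strands$chrom, pos = strands$pos, strand = "+",
      meth = strands$me_plus[, s],
      unmeth = strands$dp_plus[, s] - strands$me_plus[, s], context = "CG")
    minus <- data.table::data.table(
      chrom = strands$chrom, pos = strands$pos + 1L, strand = "-",
      meth = strands$me_minus[, s],
      unmeth = strands$dp_minus[, s] - strands$me_minus[, s], context = "CG")
    d <- rbind(plus, minus)
    data.table::setorder(d, chrom, pos)
    p <- file.path(dir, paste0(s, ".CpG_report.txt"))
    data.table::fwrite(d, p, sep = "\t", col.names = FALSE)
    paths <- c(paths, p)
  }
  names(paths) <- samples
  paths
}

#' Generate and write a complete synthetic dataset bundle
#'
#' Writes reference FASTA, GFF3 gene models, an annotated VCF, per-sample
#' Bismark-style CpG reports, the sample sheet, a JSON truth manifest and a
#' YAML snapshot of the configuration. Byte-identical across runs with the
#' same config (all randomness is seeded from `config$seed`).
#'
#' @param config sim_config.
#' @param out_dir output directory.
#' @return invisible list as [simulate_dataset()] plus `paths`.
#' @export
generate_dataset <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_dataset(config)
  paths <- list(
    fasta = file.path(out_dir, "reference.fa"),
    gff = file.path(out_dir, "genes.gff3"),
    vcf = file.path(out_dir, "variants.vcf"),
    sheet = file.path(out_dir, "sample_sheet.tsv"),
    reports = file.path(out_dir, "reports"),
    manifest = file.path(out_dir, "manifest.json"),
    config = file.path(out_dir, "config.yaml"))
  Biostrings::writeXStringSet(sim$ref$seqs, paths$fasta, width = 80L)
  write_gff3(sim$ref$genes, paths$gff)
  write_sim_vcf(sim$vars$emit, sim$sheet$sample_id, config, paths$vcf)
  data.table::fwrite(sim$sheet, paths$sheet, sep = "\t")
  report_paths <- write_cytosine_reports(sim$meth$strands,
                                         sim$sheet$sample_id, paths$reports)
  manifest_json <- list(
    selection = sim$manifest$selection,
    ccvs = sim$manifest$ccvs,
    dmrs = sim$manifest$dmrs,
    cg_loss_carrying = sum(sim$manifest$cg_loss$carrying),
    islands = sim$ref$islands)
  jsonlite::write_json(manifest_json, paths$manifest, digits = NA,
                       na = "null")
  cfg <- unclass(config)
  cfg$lineages <- lapply(cfg$lineages, as.list)
  cfg$ccv_pairs <- lapply(cfg$ccv_pairs, as.list)
  yaml::write_yaml(cfg, paths$config)
  sim$paths <- paths
  sim$report_paths <- report_paths
  invisible(sim)
}
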