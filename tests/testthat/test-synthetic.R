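small_cfg <- function(seed = 41, ...) {
  sim_config(seed = seed, chrom_length = 1.5e5, n_genes_per_chrom = 10,
             n_islands_per_chrom = 3, n_planted_dmrs = 10,
             n_positive_genes = 2L, n_purifying_genes = 2L,
             cg_loss_fraction = 0.05, ...)
}

test_that("generation is byte-identical under a fixed seed and differs across seeds", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- generate_dataset(small_cfg(41), d1)
  s2 <- generate_dataset(small_cfg(41), d2)
  files <- c("reference.fa", "genes.gff3", "variants.vcf", "sample_sheet.tsv",
             "manifest.json", "config.yaml")
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  r1 <- list.files(file.path(d1, "reports"), full.names = TRUE)
  r2 <- list.files(file.path(d2, "reports"), full.names = TRUE)
  expect_identical(unname(tools::md5sum(r1)), unname(tools::md5sum(r2)))

  s3 <- simulate_dataset(small_cfg(42))
  expect_false(identical(s3$manifest$dmrs, s1$manifest$dmrs))
})

test_that("planted islands satisfy the detection criteria; none arise by chance", {
  sim <- simulate_dataset(small_cfg(43))
  isl <- sim$ref$islands
  expect_equal(nrow(isl), 6L)
  for (r in seq_len(nrow(isl))) {
    s <- as.character(Biostrings::subseq(sim$ref$seqs[[isl$chrom[r]]],
                                         isl$start[r] + 1L, isl$end[r]))
    ch <- strsplit(s, "")[[1]]
    gc <- mean(ch %in% c("C", "G"))
    ncpg <- sum(ch[-length(ch)] == "C" & ch[-1] == "G")
    oe <- ncpg / (sum(ch == "C") * sum(ch == "G") / length(ch))
    expect_gte(gc, 0.6)
    expect_gte(oe, 0.8)
    expect_gte(isl$end[r] - isl$start[r], 250L)
  }

  ## background at 36 percent GC is essentially island-free: across seeds,
  ## at most the odd marginal call barely clearing the 200-bp floor, and
  ## never anything in the planted size range (>= 250 bp)
  total_hits <- 0L
  for (seed in 44:48) {
    ref0 <- simulate_dataset(small_cfg(seed, n_islands_per_chrom = 0L,
                                       n_planted_dmrs = 0L))$ref
    for (ch in names(ref0$seqs)) {
      isl0 <- detect_cg_islands(ref0$seqs[[ch]])
      total_hits <- total_hits + nrow(isl0)
      if (nrow(isl0)) expect_true(all(isl0$length < 250))
    }
  }
  expect_lte(total_hits, 3L)
})

test_that("requested gene count is honored with non-overlapping models", {
  sim <- simulate_dataset(small_cfg(49))
  g <- sim$ref$genes
  expect_equal(nrow(g), 20L)
  for (ch in unique(g$chrom)) {
    gc <- g[g$chrom == ch, ]
    o <- order(gc$start)
    expect_true(all(gc$start[o][-1] > gc$end[o][-nrow(gc)]))
  }
  cds_len <- vapply(g$cds, function(m) sum(m[, 2] - m[, 1] + 1), 1)
  expect_true(all(cds_len %% 3 == 0))
})

test_that("planted CCVs are homozygous-fixed in carriers and absent elsewhere", {
  sim <- cached("synth_small_50", simulate_dataset(small_cfg(50)))
  man <- sim$manifest$ccvs
  expect_equal(nrow(man), 15L)
  vs <- sim$vars$variants
  sheet <- sim$sheet
  for (i in seq_len(nrow(man))) {
    vi <- which(vs$info$chrom == man$chrom[i] & vs$info$pos == man$pos[i] &
                vs$info$alt == man$alt[i])
    expect_length(vi, 1L)
    car <- clade_samples(sheet, man$carrier[i])
    others <- setdiff(sheet$sample_id[!sheet$is_hybrid], car)
    expect_true(all(vs$geno[vi, car] == 2L))
    expect_true(all(vs$geno[vi, others] == 0L))
    expect_equal(vs$info$impact[vi], "HIGH")
  }
})

test_that("zero CG-loss fraction yields an empty CG-loss manifest", {
  sim <- simulate_dataset(small_cfg(51, cg_loss_fraction = 0,
                                    n_planted_dmrs = 0L))
  expect_true(is.null(sim$vars$manifest$cg_loss))
})

test_that("hybrids carry mosaic genotypes of the two parent species", {
  sim <- cached("synth_small_50", simulate_dataset(small_cfg(50)))
  vs <- sim$vars$variants; sheet <- sim$sheet
  hyb <- sheet$sample_id[sheet$is_hybrid]
  expect_length(hyb, 4L)
  jap <- clade_samples(sheet, "japonica")
  oxy <- clade_samples(sheet, "oxysepala")
  f_jap <- rowMeans(vs$geno[, jap]) / 2
  f_oxy <- rowMeans(vs$geno[, oxy]) / 2
  ## where one parent species is fixed alt and the other fixed ref, every
  ## hybrid must be heterozygous
  fixed_diff <- which(f_jap == 1 & f_oxy == 0 | f_jap == 0 & f_oxy == 1)
  expect_gt(length(fixed_diff), 10L)
  expect_true(all(vs$geno[fixed_diff, hyb] == 1L))
  ## where both parents are fixed ref, hybrids are ref
  both_ref <- which(f_jap == 0 & f_oxy == 0)
  expect_true(all(vs$geno[both_ref, hyb] == 0L))
})

test_that("CG-loss carriers lose methylation in proportion to dosage", {
  sim <- cached("synth_small_50", simulate_dataset(small_cfg(50)))
  cgl <- sim$manifest$cg_loss
  dos <- attr(cgl, "dosage")
  b <- beta_values(sim$meth$mm)
  hom_rows <- which(cgl$carrying & apply(dos == 2L, 1, any, na.rm = TRUE))
  hom_beta <- unlist(lapply(hom_rows, function(r)
    b[r, which(dos[r, ] == 2L)]))
  expect_lt(mean(hom_beta, na.rm = TRUE), 0.05)
})

test_that("planted DMR windows show the configured group difference", {
  sims <- lapply(52:54, function(s)
    simulate_dataset(dmr_benchmark_config(s, chrom_length = 2e5,
                                          n_planted_dmrs = 30L)))
  for (sim in sims) {
    mm <- sim$meth$mm
    man <- sim$manifest$dmrs
    gA <- clade_samples(sim$sheet, "spA"); gB <- clade_samples(sim$sheet, "spB")
    dd <- vapply(seq_len(nrow(man)), function(i) {
      on <- mm$chrom == man$chrom[i] & mm$pos > man$start[i] &
        mm$pos <= man$end[i]
      bA <- sum(mm$meth[on, gA], na.rm = TRUE) / sum(mm$total[on, gA], na.rm = TRUE)
      bB <- sum(mm$meth[on, gB], na.rm = TRUE) / sum(mm$total[on, gB], na.rm = TRUE)
      abs(bA - bB)
    }, 1)
    expect_true(all(abs(dd - 0.4) < 0.1))
  }
})

test_that("the emitted bundle parses through every reader", {
  d <- withr::local_tempdir()
  sim <- generate_dataset(small_cfg(55), d)
  sheet <- read_sample_sheet(file.path(d, "sample_sheet.tsv"))
  expect_equal(nrow(sheet), 36L)
  expect_equal(length(unique(sheet$species[!sheet$is_hybrid])), 10L)
  expect_equal(length(unique(sheet$lineage)), 3L)
  vs <- read_vcf_variants(file.path(d, "variants.vcf"), sheet)
  expect_identical(vs$geno, sim$vars$variants$geno)
  expect_identical(vs$info$consequence, sim$vars$variants$info$consequence)
  mm <- read_cytosine_report(sim$report_paths)
  expect_identical(mm$pos, sim$meth$mm$pos)
  covered <- !is.na(mm$meth)
  expect_identical(mm$meth[covered], sim$meth$mm$meth[covered])
  genes <- read_gff3_genes(file.path(d, "genes.gff3"))
  expect_identical(genes$gene_id, sim$ref$genes$gene_id)
  expect_identical(genes$cds, sim$ref$genes$cds)
  expect_true(all(genes$dnds_eligible))
  fa <- Biostrings::readDNAStringSet(file.path(d, "reference.fa"))
  expect_identical(as.character(fa[[1]]), as.character(sim$ref$seqs[[1]]))
})
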