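## CG grid at positions 100/101 and 300/301 with a matching reference
cg_loss_fixture <- function(info_rows, geno) {
  seqs <- rep("A", 400)
  seqs[c(100, 300)] <- "C"; seqs[c(101, 301)] <- "G"
  ref <- Biostrings::DNAStringSet(c(chr1 = paste(seqs, collapse = "")))
  mm <- make_mm(matrix(5L, 2, ncol(geno)), matrix(10L, 2, ncol(geno)),
                pos = c(100L, 300L))
  vs <- variant_set(info_rows, geno, colnames(geno))
  list(mm = mm, vs = vs, ref = ref)
}

test_that("CG-loss classification follows the SNP/INDEL overlap rules", {
  info <- data.frame(
    chrom = "chr1",
    pos = c(100L, 110L, 298L),
    ref = c("C", "A", "AACG"),     # SNP on the C; SNP 10 bp away; deletion
    alt = c("T", "T", "A"),        # spanning the G at 301
    consequence = "intergenic_region", impact = "MODIFIER",
    gene_id = NA, mq = 50, stringsAsFactors = FALSE)
  geno <- matrix(c(2L, 1L, 0L,
                   0L, 0L, 2L), 3, 2,
                 dimnames = list(NULL, c("s1", "s2")))
  fx <- cg_loss_fixture(info, geno)
  out <- classify_cg_loss_loci(fx$mm, fx$vs, fx$ref)
  expect_equal(out$carrying, c(TRUE, TRUE))
  expect_equal(out$variant_idx, c(1L, 3L))
  dos <- attr(out, "dosage")
  expect_equal(unname(dos[1, ]), c(2L, 0L))
  expect_equal(unname(dos[2, ]), c(0L, 2L))

  ## a SNP 10 bp away alone does not flag the locus
  out2 <- classify_cg_loss_loci(fx$mm, subset_variants(fx$vs, sites = 2),
                                fx$ref)
  expect_false(any(out2$carrying))

  ## a non-CpG reference dinucleotide is an error
  bad_ref <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 400)))
  expect_error(classify_cg_loss_loci(fx$mm, fx$vs, bad_ref), "non-CpG")
})

test_that("CG-loss regression recovers exact and planted effects", {
  ## noiseless two-point fit: non-carriers 0.9, hom carriers 0.0
  dosage <- c(0, 0, 0, 2, 2, 2)
  beta <- c(0.9, 0.9, 0.9, 0, 0, 0)
  r <- cg_loss_regression(dosage, beta)
  expect_equal(r$slope, -0.45)
  expect_equal(r$r_squared, 1)

  ## degenerate dosage is undefined
  expect_true(is.na(cg_loss_regression(rep(2, 6), beta)$slope))
  expect_true(is.na(cg_loss_regression(c(0, 1), c(0.1, 0.2))$slope))

  ## planted per-allele effect of -beta0/2, n = 36, noise sd 0.05:
  ## slope within 10 percent relative error
  set.seed(131)
  dose <- rbinom(36, 2, 0.5)
  bb <- clamp(0.9 * (1 - dose / 2) + rnorm(36, 0, 0.05), 0, 1)
  fit <- cg_loss_regression(dose, bb)
  expect_lt(abs(fit$slope - (-0.45)) / 0.45, 0.10)

  ## under the null, R^2 has expectation ~ 1/(n-1)
  set.seed(132)
  r2 <- replicate(400, {
    d <- rbinom(24, 2, 0.5)
    cg_loss_regression(d, runif(24))$r_squared
  })
  expect_lt(abs(mean(r2, na.rm = TRUE) - 1 / 23), 0.015)
})

test_that("variability categories follow the rank cutoffs", {
  set.seed(133)
  b <- matrix(runif(200 * 6), 200, 6)
  vc <- variability_categories(b, cutoffs = c(10L, 50L, 150L))
  expect_equal(sum(vc$category == "very_high"), 10L)
  expect_equal(sum(vc$category == "high"), 40L)
  expect_equal(sum(vc$category == "moderate"), 100L)
  expect_equal(sum(vc$category == "low"), 50L)
  expect_equal(vc$category[vc$rank == 5], "very_high")
  expect_equal(vc$category[vc$rank == 100], "moderate")
  ## ranking is by decreasing SD
  expect_true(all(vc$sd[vc$category == "very_high"] >=
                  max(vc$sd[vc$category == "low"])))

  ## proportional scaling preserves the 10/50/150 ratios
  expect_message(vc2 <- variability_categories(b), "scaled")
  expect_equal(sum(vc2$category == "very_high"), round(200 * 10000 / 150000))

  ## constant loci all become low under explicit cutoffs
  const <- matrix(0.5, 30, 4)
  vc3 <- variability_categories(const, cutoffs = c(1L, 2L, 3L))
  expect_equal(sum(vc3$category == "low"), 27L)
})

test_that("a phenotype equal to a candidate dosage is always associated", {
  set.seed(134)
  n <- 40; samples <- paste0("s", 1:n)
  geno <- matrix(rbinom(40 * n, 2, 0.5), 40,
                 dimnames = list(NULL, samples))
  vs <- make_vs(geno, pos = seq(100L, by = 200L, length.out = 40))
  target <- 20L
  beta <- clamp(geno[target, ] / 2, 0.02, 0.98)
  to <- matrix(1000L, 1, n, dimnames = list(NULL, samples))
  me <- matrix(as.integer(round(1000 * beta)), 1, n,
               dimnames = list(NULL, samples))
  mm <- methylation_matrix("chr1", vs$info$pos[target] + 1L, me, to, samples)
  dmrs <- data.frame(chrom = "chr1", start = vs$info$pos[target] - 50L,
                     end = vs$info$pos[target] + 50L)
  sc <- cis_driver_scan(dmrs, vs, mm, n_pcs = 2)
  expect_lt(sc$best_p, 1e-8)
  expect_true(all(unlist(sc[, grep("assoc_", names(sc))])))
  ## associated flags are monotone along the threshold grid
  s <- attr(sc, "summary")
  expect_true(all(diff(s$associated_fraction) <= 0))
})

test_that("permuted phenotypes associate at the null rate", {
  set.seed(135)
  n <- 30; samples <- paste0("s", 1:n)
  n_dmr <- 400
  geno <- matrix(rbinom(n_dmr * n, 2, 0.5), n_dmr,
                 dimnames = list(NULL, samples))
  pos <- seq(500L, by = 1000L, length.out = n_dmr)
  vs <- make_vs(geno, pos = pos)
  to <- matrix(200L, n_dmr, n, dimnames = list(NULL, samples))
  me <- matrix(rbinom(n_dmr * n, 200, 0.5), n_dmr,
               dimnames = list(NULL, samples))
  mm <- methylation_matrix(rep("chr1", n_dmr), pos + 1L, me, to, samples)
  dmrs <- data.frame(chrom = "chr1", start = pos - 50L, end = pos + 50L)
  sc <- cis_driver_scan(dmrs, vs, mm, n_pcs = 2)
  hits <- sum(sc[["assoc_5e-05"]], na.rm = TRUE)
  ## each DMR tests one candidate; binomial null at 5e-5
  expect_gt(binom.test(hits, n_dmr, 5e-5)$p.value, 0.01)
})

test_that("DMG x selection chi-square matches a contingency oracle", {
  dmgs <- data.frame(gene_id = paste0("g", 1:600),
                     is_dmg = rep(c(TRUE, FALSE), c(200, 400)))
  sel <- data.frame(gene_id = paste0("g", 1:600),
                    class = c(rep("positive", 20), rep("neutral", 180),
                              rep("positive", 10), rep("neutral", 390)))
  out <- dmg_selection_chisq(dmgs, sel, "toy")
  pos <- out[out$selection_type == "positive", ]
  expect_equal(pos$pct_dmg, 10)
  expect_equal(pos$pct_non_dmg, 2.5)
  ## independent Pearson formula
  tab <- matrix(c(20, 180, 10, 390), 2, 2, byrow = TRUE)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi <- sum((tab - e)^2 / e)
  expect_equal(pos$chisq, chi, tolerance = 1e-9)
  expect_equal(pos$p_value, pchisq(chi, 1, lower.tail = FALSE),
               tolerance = 1e-12)

  ## equal margins give statistic 0 and p 1
  sel2 <- data.frame(gene_id = paste0("g", 1:600),
                     class = rep(c("positive", "neutral"), 300))
  out2 <- dmg_selection_chisq(dmgs, sel2, "toy")
  expect_equal(out2$chisq[1], 0, tolerance = 1e-12)
  expect_equal(out2$p_value[1], 1, tolerance = 1e-9)

  expect_error(dmg_selection_chisq(
    data.frame(gene_id = "g", is_dmg = FALSE), sel, "x"), "empty")
})
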