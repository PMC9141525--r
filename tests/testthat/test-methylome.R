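test_that("depth filter marks shallow sites missing and builds the QC mask", {
  meth <- matrix(c(2L, 1L, 5L,
                   2L, 9L, 0L), 3, 2)
  total <- matrix(c(3L, 2L, 10L,
                    4L, 10L, 2L), 3, 2)
  mm <- build_methylation_matrix(make_mm(meth, total), min_depth = 3L)
  b <- beta_values(mm)
  expect_equal(b[1, 1][[1]], 2 / 3)
  expect_true(is.na(b[2, 1]))       # depth 2 -> missing, not zero
  expect_equal(b[2, 2][[1]], 0.9)
  expect_true(is.na(b[3, 2]))
  mask <- attr(mm, "qc_mask")
  expect_equal(mask, c(TRUE, FALSE, FALSE))  # rows 2,3 covered in 50% < 80%
})

test_that("sites missing in more than 20 percent of samples leave the mask", {
  set.seed(111)
  n_s <- 36
  total <- matrix(10L, 2, n_s); meth <- matrix(5L, 2, n_s)
  total[2, 1:8] <- 1L; meth[2, 1:8] <- 0L  # covered in 28/36 = 77.8% < 80%
  mm <- build_methylation_matrix(make_mm(meth, total), min_depth = 3L)
  expect_equal(attr(mm, "qc_mask"), c(TRUE, FALSE))
})

test_that("global methylation level is the read-weighted mean", {
  mm <- make_mm(matrix(c(10L, 0L), 2, 1), matrix(c(10L, 10L), 2, 1))
  expect_equal(global_methylation_level(mm, "s1"), 50)
  mm1 <- make_mm(matrix(c(3L, 7L), 2, 1), matrix(c(10L, 10L), 2, 1))
  expect_equal(global_methylation_level(mm1, "s1"), 50)
  mm2 <- make_mm(matrix(10L, 2, 1), matrix(10L, 2, 1))
  expect_equal(global_methylation_level(mm2, "s1"), 100)
  mm3 <- make_mm(matrix(0L, 2, 1), matrix(10L, 2, 1))
  expect_equal(global_methylation_level(mm3, "s1"), 0)
})

test_that("methylome PCA separates species groups on synthetic data", {
  sim <- default_sim(1)
  mm <- build_methylation_matrix(sim$meth$mm, sim$sheet, min_depth = 3L)
  p <- methylome_pca(mm, 4)
  ## duplicate-sample check on a copy
  b <- beta_values(mm)[attr(mm, "qc_mask"), ]
  pd <- genotype_pca(cbind(b, b[, 1]), 2, standardize = FALSE)
  expect_equal(pd$coordinates[1, ], pd$coordinates[ncol(b) + 1, ],
               ignore_attr = TRUE, tolerance = 1e-8)
  ## silhouette of lineage labels on the first two axes is positive
  xy <- p$coordinates[, 1:2]
  lab <- sim$sheet$lineage[match(rownames(xy), sim$sheet$sample_id)]
  centroid <- apply(xy, 2, function(v) tapply(v, lab, mean))
  sil <- vapply(seq_len(nrow(xy)), function(i) {
    d <- sqrt(rowSums((centroid - matrix(xy[i, ], nrow(centroid), 2,
                                         byrow = TRUE))^2))
    own <- d[lab[i]]; other <- min(d[setdiff(names(d), lab[i])])
    (other - own) / max(own, other)
  }, numeric(1))
  expect_gt(mean(sil), 0)
})

test_that("MDI satisfies identity, symmetry and the window arithmetic", {
  pos <- as.integer(seq(50000, 950000, by = 100000))
  me <- cbind(a = rep(5L, 10), b = rep(5L, 10))
  to <- cbind(a = rep(10L, 10), b = rep(10L, 10))
  me[3, "b"] <- 10L   # one window of ten differs by 0.5
  mm <- methylation_matrix(rep("chr1", 10), pos, me, to, c("a", "b"))
  expect_equal(compute_mdi(mm, "a", "b", "chr1"), 5.0)
  expect_equal(compute_mdi(mm, "a", "a", "chr1"), 0)
  expect_equal(compute_mdi(mm, "b", "a", "chr1"), compute_mdi(mm, "a", "b", "chr1"))
  expect_error(compute_mdi(mm, "a", "b", "chrX"), "not present")
})

test_that("island detector criteria behave on forced sequences", {
  rep_cg <- strrep("CG", 300)
  isl <- detect_cg_islands(rep_cg)
  expect_equal(nrow(isl), 1L)
  expect_gt(isl$length[1], 200)
  expect_equal(isl$gc_fraction[1], 1)
  expect_equal(isl$obs_exp_cpg[1], 2)
  expect_equal(nrow(detect_cg_islands(strrep("A", 2000))), 0L)
  ## N-heavy windows are skipped without error
  expect_equal(nrow(detect_cg_islands(paste0(strrep("N", 300),
                                             strrep("A", 300)))), 0L)
})

test_that("island detector equals the brute-force criterion oracle", {
  set.seed(112)
  for (i in 1:40) {
    L <- sample(150:900, 1)
    gc <- runif(1, 0.35, 0.75)
    s <- paste(sample(c("A", "T", "C", "G"), L, TRUE,
                      c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
               collapse = "")
    a <- detect_cg_islands(s); b <- islands_bruteforce(s)
    expect_identical(a$start, b$start)
    expect_identical(a$end, b$end)
  }
})

make_uniform_mm <- function(beta = 0.5, n = 600, span = 60000, seed = 1) {
  set.seed(seed)
  pos <- sort(sample(seq_len(span), n))
  to <- matrix(20L, n, 2, dimnames = list(NULL, c("x", "y")))
  me <- matrix(as.integer(round(20 * beta)), n, 2,
               dimnames = list(NULL, c("x", "y")))
  methylation_matrix(rep("g", n), pos, me, to, c("x", "y"))
}

test_that("metaprofiles are flat for uniform methylation and strand-aware", {
  mm <- make_uniform_mm(0.5)
  genes <- data.frame(gene_id = "g1", chrom = "g", start = 20000L,
                      end = 30000L, strand = "+")
  pr <- gene_metaprofile(mm, genes, list(all = c("x", "y")), flank = 5000)
  expect_equal(nrow(pr), 200L)  # 50 + 100 + 50 bins
  expect_true(all(abs(pr$beta[!is.na(pr$beta)] - 0.5) < 1e-12))

  ## minus-strand gene gives the reversed bin series
  genes$strand <- "-"
  pr2 <- gene_metaprofile(mm, genes, list(all = c("x", "y")), flank = 5000)
  expect_equal(pr2$beta, rev(pr$beta))
  expect_equal(pr2$total, rev(pr$total))

  ## conservation: weighted bin mean equals the pooled regional mean
  expect_equal(weighted.mean(pr$beta, pr$total, na.rm = TRUE), 0.5)
})

test_that("planted TSS dip is recovered in the genic profile", {
  mm <- make_uniform_mm(0.8, n = 2000, span = 60000, seed = 3)
  ## depress methylation within 500 bp of the TSS
  dip <- mm$pos >= 19500 & mm$pos <= 20500
  mm$meth[dip, ] <- 2L
  genes <- data.frame(gene_id = "g1", chrom = "g", start = 20000L,
                      end = 30000L, strand = "+")
  pr <- gene_metaprofile(mm, genes, list(all = c("x", "y")), flank = 5000)
  tss_bins <- pr$bin >= 45 & pr$bin <= 54
  expect_lt(mean(pr$beta[tss_bins], na.rm = TRUE), 0.4)
  expect_gt(mean(pr$beta[pr$bin > 100 & pr$bin < 140], na.rm = TRUE), 0.7)
})

test_that("island profile shifts with a group-wide offset and recovers a planted center", {
  set.seed(113)
  n <- 1500; span <- 30000
  pos <- sort(sample(seq_len(span), n))
  to <- matrix(50L, n, 4, dimnames = list(NULL, paste0("s", 1:4)))
  b <- matrix(0.4, n, 4)
  b[, 3:4] <- 0.5                      # group B shifted +0.1 everywhere
  me <- matrix(as.integer(round(50 * b)), n, 4,
               dimnames = list(NULL, paste0("s", 1:4)))
  mm <- methylation_matrix(rep("g", n), pos, me, to, paste0("s", 1:4))
  islands <- data.frame(chrom = "g", start = 12000L, end = 14000L)
  pr <- cgi_metaprofile(mm, islands, list(A = c("s1", "s2"),
                                          B = c("s3", "s4")))
  bA <- pr$beta[pr$group == "A"]; bB <- pr$beta[pr$group == "B"]
  ok <- !is.na(bA) & !is.na(bB)
  expect_true(all(abs((bB - bA)[ok] - 0.1) < 1e-9))

  ## no islands -> empty profile with a warning
  expect_warning(empty <- cgi_metaprofile(mm, islands[0, ], list(A = "s1")),
                 "no islands")
  expect_equal(nrow(empty), 0L)
})
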