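test_that("window tiling anchors at zero and keeps the partial tail", {
  w <- make_windows(c(chr1 = 250000), 100000)
  expect_equal(w$start, c(0, 100000, 200000))
  expect_equal(w$end, c(100000, 200000, 250000))
  expect_equal(w$partial, c(FALSE, FALSE, TRUE))
  expect_equal(nrow(make_windows(c(c = 50), 100)), 1L)
  expect_equal(nrow(make_windows(c(a = 1e6), 100)), 10000L)
})

test_that("windowed pi matches the hand formula and the pairwise oracle", {
  ## one SNP, 4 diploids, alt dosage sum 4 (p = 0.5), L = 1000
  vs <- make_vs(matrix(c(2, 2, 0, 0), 1, 4), pos = 5L)
  w <- make_windows(c(chr1 = 1000), 1000)
  expect_equal(window_pi(vs, vs$samples, w)$value, (8 / 7) * 0.5 / 1000)

  ## monomorphic window
  vs0 <- make_vs(matrix(2, 1, 4), pos = 5L)
  expect_equal(window_pi(vs0, vs0$samples, w)$value, 0)

  ## random windows against the brute-force pairwise-difference oracle
  set.seed(71)
  for (rep in 1:15) {
    g <- matrix(sample(c(0L, 1L, 2L, NA), 50 * 8, TRUE, c(.4, .3, .25, .05)),
                50, 8)
    vs <- make_vs(g, pos = sort(sample(1:999, 50)))
    got <- window_pi(vs, vs$samples, w)$value
    expect_equal(got, pi_bruteforce(g, 1000), tolerance = 1e-12)
  }
})

test_that("windowed FST matches Weir-Cockerham oracle; fixed difference is 1", {
  w <- make_windows(c(chr1 = 1000), 1000)
  gA <- paste0("s", 1:5); gB <- paste0("s", 6:10)

  vf <- make_vs(matrix(c(rep(2L, 5), rep(0L, 5)), 1, 10), pos = 5L)
  expect_identical(window_fst(vf, gA, gB, w)$value, 1)

  ## identical monomorphic groups -> undefined
  vm <- make_vs(matrix(2L, 3, 10))
  expect_true(is.na(window_fst(vm, gA, gB, w)$value))

  set.seed(72)
  for (rep in 1:15) {
    g <- matrix(sample(c(0L, 1L, 2L, NA), 50 * 10, TRUE, c(.4, .3, .25, .05)),
                50, 10)
    vs <- make_vs(g, pos = sort(sample(1:999, 50)))
    got <- window_fst(vs, gA, gB, w)$value
    want <- fst_bruteforce(g, 1:5, 6:10)
    if (is.na(want)) expect_true(is.na(got))
    else expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("pi and FST are invariant under sample and site reordering", {
  set.seed(73)
  g <- matrix(sample(c(0L, 1L, 2L), 40 * 10, TRUE), 40, 10)
  vs <- make_vs(g, pos = sort(sample(1:999, 40)))
  w <- make_windows(c(chr1 = 1000), 1000)
  base_pi <- window_pi(vs, vs$samples, w)$value
  base_fst <- window_fst(vs, paste0("s", 1:5), paste0("s", 6:10), w)$value
  site_perm <- sample(40); samp_perm <- sample(10)
  geno_perm <- vs$geno[site_perm, samp_perm]
  vs2 <- variant_set(vs$info[site_perm, ], geno_perm, colnames(geno_perm))
  expect_equal(window_pi(vs2, vs$samples, w)$value, base_pi)
  expect_equal(window_fst(vs2, paste0("s", 1:5), paste0("s", 6:10), w)$value,
               base_fst)
})

test_that("pooling two identical populations never gives positive FST", {
  set.seed(74)
  g <- matrix(sample(c(0L, 1L, 2L), 200 * 12, TRUE, c(.5, .3, .2)), 200, 12)
  vs <- make_vs(g, pos = sort(sample(1:19999, 200)))
  w <- make_windows(c(chr1 = 20000), 2000)
  same <- window_fst(vs, vs$samples, vs$samples, w)$value
  expect_true(all(same[!is.na(same)] <= 1e-12))
})

test_that("LDGR/HDGR tails use closed thresholds", {
  w <- make_windows(c(chr1 = 40000), 1000)
  w$statistic_name <- "pi"; w$value <- seq_len(40); w$n_sites <- 1L
  f <- w; f$statistic_name <- "fst"
  sel <- select_ldgr_hdgr(w, f, 0.05, 0.05)
  expect_equal(nrow(sel$ldgr), 2L)   # ceiling(0.05 * 40)
  expect_equal(nrow(sel$hdgr), 2L)
  expect_equal(nrow(sel$overlap), 0L)

  ## all tied -> every window included
  w$value <- rep(1, 40)
  expect_equal(nrow(select_ldgr_hdgr(w, NULL)$ldgr), 40L)

  ## overlapping tails intersect on window identity
  f$value <- -seq_len(40)   # highest fst = lowest pi windows
  sel2 <- select_ldgr_hdgr(w[1:40, ], f, 0.5, 0.5)
  expect_gt(nrow(sel2$overlap), 0L)
})

test_that("LD pruning drops duplicated SNPs and follows the greedy trace", {
  set.seed(75)
  base <- sample(c(0L, 1L, 2L), 30, TRUE)
  g <- rbind(base, base, sample(c(0L, 1L, 2L), 30, TRUE))
  vs <- make_vs(g)
  pruned <- ld_prune(vs, window_n_snps = 10, step = 5, r2_max = 0.2)
  expect_equal(nrow(pruned$info), 2L)
  expect_equal(pruned$info$pos, vs$info$pos[c(1, 3)])

  ## independent SNPs survive
  set.seed(76)
  gi <- matrix(sample(c(0L, 1L, 2L), 20 * 200, TRUE), 20, 200)
  vsi <- make_vs(gi)
  expect_equal(nrow(ld_prune(vsi)$info), 20L)

  ## 3-SNP chain: r2(1,2) > max and r2(2,3) > max but r2(1,3) small;
  ## greedy drops SNP 2 from the pair (1,2) and then keeps 3
  x <- c(rep(0L, 10), rep(2L, 10))
  y <- x; y[1] <- 2L; y[20] <- 0L
  z <- y; z[2] <- 2L; z[19] <- 0L; z[3] <- 2L; z[18] <- 0L
  ## r2 roughly decreasing with index distance
  ch <- rbind(x, y, z)
  vc <- make_vs(ch)
  pr <- ld_prune(vc, window_n_snps = 3, step = 1, r2_max = 0.2)
  r13 <- cor(x, z)^2
  expected <- if (r13 > 0.2) 1L else 2L
  expect_equal(nrow(pr$info), expected)
  expect_equal(pr$info$pos[1], vc$info$pos[1])
})

test_that("PCA matches an eigendecomposition oracle and handles edge cases", {
  set.seed(77)
  m <- matrix(rnorm(50 * 8), 50, 8)
  p <- genotype_pca(m, 3, standardize = FALSE)
  ## oracle: eigenvectors of the sample covariance of centered features
  mc <- m - rowMeans(m)
  ev <- eigen(crossprod(mc))$vectors[, 1:3]
  for (k in 1:3) {
    cc <- abs(cor(p$coordinates[, k], ev[, k]))
    expect_gt(cc, 1 - 1e-8)
  }
  expect_true(all(diff(p$explained) <= 1e-12))

  ## duplicated samples project identically
  m2 <- cbind(m, m[, 1])
  p2 <- genotype_pca(m2, 2, standardize = FALSE)
  expect_equal(p2$coordinates[1, ], p2$coordinates[9, ],
               ignore_attr = TRUE)

  ## rank-1 matrix -> PC1 explains everything
  r1 <- outer(rnorm(30), rnorm(6))
  pr <- genotype_pca(r1, 2, standardize = FALSE)
  expect_gt(pr$explained[1], 1 - 1e-10)

  expect_error(genotype_pca(matrix(1, 5, 4)), "variance")
})

test_that("neighbor joining recovers additive trees exactly", {
  expect_error(nj_tree(matrix(0, 2, 2, dimnames = list(c("a", "b"),
                                                       c("a", "b")))),
               "at least 3")
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(d3)
  expect_setequal(t3$edge.length, c(1, 2, 3))

  set.seed(78)
  for (rep in 1:25) {
    tr <- ape::rtree(sample(6:10, 1))
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
    d <- ape::cophenetic.phylo(tr)
    mine <- nj_tree(d)
    expect_equal(ape::dist.topo(ape::unroot(tr), mine), 0,
                 ignore_attr = TRUE)
    back <- ape::cophenetic.phylo(mine)[rownames(d), colnames(d)]
    expect_lt(max(abs(back - d)), 1e-8)
  }
})

test_that("every NJ join agrees with the exhaustive minimum-Q oracle", {
  set.seed(79)
  for (rep in 1:10) {
    n <- 8
    pts <- matrix(rnorm(n * 4), n)
    d <- as.matrix(dist(pts))
    dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
    expect_equal(ape::dist.topo(nj_tree(d), nj_oracle_tree(d)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("allele-sharing distance is zero for identical samples", {
  set.seed(80)
  g <- matrix(sample(c(0L, 2L), 100 * 3, TRUE), 100, 3)
  g <- cbind(g, g[, 1])
  vs <- make_vs(g)
  d <- allele_sharing_dist(vs)
  expect_equal(d["s1", "s4"][[1]], 0)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
})
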