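#' Allele-sharing distance matrix
#'
#' d(a,b) = 1 - shared alleles / (2 * compared loci), where per comparable
#' locus the number of shared alleles between two diploid genotypes with alt
#' dosages (da, db) is 2 - |da - db|. By default only loci at which both
#' samples are homozygous contribute (heterozygous calls excluded).
#'
#' @param geno variant_set.
#' @param samples sample ids (default all).
#' @param hom_only restrict to loci homozygous in both samples (default TRUE).
#' @return symmetric matrix with zero diagonal.
#' @export
allele_sharing_dist <- function(geno, samples = geno$samples, hom_only = TRUE) {
  g <- geno$geno[, samples, drop = FALSE]
  n <- length(samples)
  d <- matrix(0, n, n, dimnames = list(samples, samples))
  for (i in seq_len(n - 1L)) {
    gi <- g[, i]
    for (j in seq(i + 1L, n)) {
      gj <- g[, j]
      ok <- !is.na(gi) & !is.na(gj)
      if (hom_only) ok <- ok & gi != 1L & gj != 1L
      L <- sum(ok)
      d[i, j] <- d[j, i] <-
        if (L == 0L) NA_real_ else sum(abs(gi[ok] - gj[ok])) / (2 * L)
    }
  }
  d
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Classic agglomerative neighbor joining on a symmetric distance matrix.
#' At each step the pair minimizing Q(i,j) = (m-2) d(i,j) - r_i - r_j is
#' joined; ties are broken by the smallest (i,j) index pair in the current
#' node ordering. Negative branch lengths are clamped to 0.
#'
#' @param d symmetric numeric matrix with zero diagonal and row/col names.
#' @return unrooted `phylo` object (ape) with tip labels from `d`.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  abort_if(n < 3L, "need at least 3 samples for neighbor joining")
  abort_if(is.null(rownames(d)), "distance matrix must have row names")
  abort_if(any(abs(d - t(d)) > 1e-12), "distance matrix must be symmetric")
  labels <- rownames(d)
  ## phylo node ids: tips 1..n, internals n+1 .. 2n-2 (root-ish last)
  node_id <- seq_len(n)
  next_internal <- 2L * n - 2L   # allocate downward so root gets n+1
  edges <- matrix(0L, 0L, 2L); lens <- numeric(0)
  active <- d
  while (nrow(active) > 3L) {
    m <- nrow(active)
    r <- rowSums(active)
    q <- (m - 2) * active - outer(r, r, `+`)
    diag(q) <- Inf
    ij <- which(q == min(q), arr.ind = TRUE)
    ij <- ij[ij[, 1] < ij[, 2], , drop = FALSE]
    ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE][1, ]
    i <- ij[1]; j <- ij[2]
    vi <- active[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- active[i, j] - vi
    new <- next_internal; next_internal <- next_internal - 1L
    edges <- rbind(edges, c(new, node_id[i]), c(new, node_id[j]))
    lens <- c(lens, max(0, vi), max(0, vj))
    dnew <- (active[i, ] + active[j, ] - active[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    active <- rbind(cbind(active[keep, keep, drop = FALSE], dnew[keep]),
                    c(dnew[keep], 0))
    node_id <- c(node_id[keep], new)
  }
  ## resolve the final three nodes around one internal vertex
  da <- active[1, 2]; db <- active[1, 3]; dc <- active[2, 3]
  v1 <- (da + db - dc) / 2; v2 <- (da + dc - db) / 2; v3 <- (db + dc - da) / 2
  centre <- next_internal
  edges <- rbind(edges, c(centre, node_id[1]), c(centre, node_id[2]),
                 c(centre, node_id[3]))
  lens <- c(lens, max(0, v1), max(0, v2), max(0, v3))
  tr <- structure(list(edge = edges, edge.length = lens,
                       tip.label = labels, Nnode = n - 2L),
                  class = "phylo", order = NULL)
  ape::reorder.phylo(tr, "cladewise")
}
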