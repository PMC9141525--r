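# Independent oracles used to cross-check the package implementations.
# These are deliberately written in the most direct (slow) way possible and
# share no code with the functions they check.

## nucleotide diversity: brute-force pairwise allele mismatches per site
pi_bruteforce <- function(geno, L) {
  tot <- 0
  for (s in seq_len(nrow(geno))) {
    al <- unlist(lapply(geno[s, ], function(d)
      if (is.na(d)) NULL else c(rep(1, d), rep(0, 2 - d))))
    n <- length(al)
    if (n < 2) next
    mism <- 0; cnt <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      mism <- mism + (al[i] != al[j]); cnt <- cnt + 1
    }
    tot <- tot + mism / cnt
  }
  tot / L
}

## Weir & Cockerham (1984) two-population theta, scalar per-site sums
fst_bruteforce <- function(geno, ia, ib) {
  A <- 0; D <- 0
  for (s in seq_len(nrow(geno))) {
    ga <- geno[s, ia]; gb <- geno[s, ib]
    ga <- ga[!is.na(ga)]; gb <- gb[!is.na(gb)]
    if (!length(ga) || !length(gb)) next
    n1 <- length(ga); n2 <- length(gb); r <- 2
    nbar <- (n1 + n2) / r
    if (nbar <= 1) next
    p1 <- sum(ga) / (2 * n1); p2 <- sum(gb) / (2 * n2)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    if (pbar <= 0 || pbar >= 1) next
    h1 <- mean(ga == 1); h2 <- mean(gb == 1)
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- nbar / nc *
      (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    A <- A + a; D <- D + a + b + cc
  }
  if (D == 0) NA_real_ else A / D
}

## CMH chi-square via the textbook per-stratum sums, written independently
cmh_bruteforce <- function(strata) {
  num <- 0; den <- 0; used <- 0
  for (tb in strata) {
    a <- tb[1, 1]; b <- tb[1, 2]; c0 <- tb[2, 1]; d <- tb[2, 2]
    n <- a + b + c0 + d
    if ((a + b) == 0 || (c0 + d) == 0 || (a + c0) == 0 || (b + d) == 0) next
    num <- num + a - (a + b) * (a + c0) / n
    den <- den + (a + b) * (c0 + d) * (a + c0) * (b + d) / (n^2 * (n - 1))
    used <- used + 1
  }
  if (used == 0 || den == 0) return(list(statistic = NA_real_, p = NA_real_))
  stat <- num^2 / den
  list(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE))
}

## GGF CpG-island scan evaluated window by window with plain loops
islands_bruteforce <- function(s, win = 100, min_len = 200) {
  ch <- strsplit(toupper(s), "")[[1]]; L <- length(ch)
  none <- data.frame(start = integer(0), end = integer(0))
  if (L < win) return(none)
  flags <- logical(L - win + 1)
  for (i in seq_along(flags)) {
    w <- ch[i:(i + win - 1)]
    nN <- sum(!w %in% c("A", "C", "G", "T"))
    if (nN > win / 2) next
    nC <- sum(w == "C"); nG <- sum(w == "G"); eff <- win - nN
    gc <- (nC + nG) / eff
    ncpg <- sum(w[-win] == "C" & w[-1] == "G")
    e <- nC * nG / eff
    oe <- if (e > 0) ncpg / e else 0
    flags[i] <- gc > 0.5 && oe > 0.6
  }
  fi <- which(flags)
  if (!length(fi)) return(none)
  brk <- c(TRUE, diff(fi) > win); run <- cumsum(brk)
  st <- tapply(fi, run, min) - 1L; en <- tapply(fi, run, max) - 1L + win
  keep <- (en - st) > min_len
  data.frame(start = as.integer(st[keep]), end = as.integer(en[keep]))
}

## NG86 per-codon quantities by explicit enumeration (site counts over the
## three positions; difference counts averaged over substitution orders,
## skipping orders that pass through stop codons, falling back to all)
ng86_bruteforce <- function(a, b) {
  gc <- Biostrings::GENETIC_CODE
  bases <- c("T", "C", "A", "G")
  codons_a <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  codons_b <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  syn_sites <- function(cod) {
    s <- 0
    for (p in 1:3) for (bb in setdiff(bases, substr(cod, p, p))) {
      alt <- cod; substr(alt, p, p) <- bb
      if (gc[alt] != "*" && gc[alt] == gc[cod]) s <- s + 1 / 3
    }
    s
  }
  path_counts <- function(c1, c2) {
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(pos)) return(c(0, 0))
    perms <- if (length(pos) == 1) list(pos) else {
      pm <- list()
      rec <- function(prefix, rest) {
        if (!length(rest)) pm[[length(pm) + 1]] <<- prefix
        else for (k in seq_along(rest)) rec(c(prefix, rest[k]), rest[-k])
      }
      rec(integer(0), pos); pm
    }
    walk <- function(ord, allow) {
      cur <- c1; nd <- 0; sd <- 0
      for (p in ord) {
        nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
        if (!allow && gc[nxt] == "*") return(NULL)
        if (gc[cur] == gc[nxt]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(nd, sd)
    }
    res <- Filter(Negate(is.null), lapply(perms, walk, allow = FALSE))
    if (!length(res)) res <- lapply(perms, walk, allow = TRUE)
    colMeans(do.call(rbind, res))
  }
  S <- (sum(vapply(codons_a, syn_sites, 0)) +
        sum(vapply(codons_b, syn_sites, 0))) / 2
  N <- 3 * length(codons_a) - S
  nd <- 0; sd <- 0
  for (k in seq_along(codons_a)) {
    pc <- path_counts(codons_a[k], codons_b[k])
    nd <- nd + pc[1]; sd <- sd + pc[2]
  }
  pN <- if (N > 0) nd / N else 0
  pS <- if (S > 0) sd / S else 0
  jc <- function(p) if (p >= 3 / 4) Inf else -3 / 4 * log(1 - 4 / 3 * p)
  list(dN = jc(pN), dS = jc(pS), pN = pN, pS = pS)
}

## one neighbor-joining step by exhaustive Q search (smallest-(i,j) ties)
nj_min_q <- function(d) {
  m <- nrow(d); r <- rowSums(d)
  best <- NULL; bestq <- Inf
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    q <- (m - 2) * d[i, j] - r[i] - r[j]
    if (q < bestq - 1e-12) { bestq <- q; best <- c(i, j) }
  }
  best
}

## random in-frame coding sequence without stop codons, starting with ATG
random_cds <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste(c("ATG", sample(sense, n_codons - 1, replace = TRUE)), collapse = "")
}

## full NJ replay driven by the exhaustive minimum-Q search; returns the
## unrooted topology as a phylo object (branch lengths ignored)
nj_oracle_tree <- function(d) {
  act <- d; labels <- rownames(d)
  while (nrow(act) > 3) {
    pick <- nj_min_q(act)
    m <- nrow(act); i <- pick[1]; j <- pick[2]
    dnew <- (act[i, ] + act[j, ] - act[i, j]) / 2
    keep <- setdiff(seq_len(m), pick)
    nm <- paste0("(", labels[i], ",", labels[j], ")")
    act <- rbind(cbind(act[keep, keep, drop = FALSE], dnew[keep]),
                 c(dnew[keep], 0))
    labels <- c(labels[keep], nm)
    rownames(act) <- colnames(act) <- labels
  }
  ape::read.tree(text = paste0("(", labels[1], ",", labels[2], ",",
                               labels[3], ");"))
}
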