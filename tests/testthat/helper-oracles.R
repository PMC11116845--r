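# Independent brute-force oracles and small fixture builders.  These are
# deliberately written as direct transcriptions of the definitions (explicit
# loops, no shared code with the package internals) so they can vouch for the
# implementation.

# classical scaling by explicit double-centering and eigendecomposition
brute_pcoa <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  d2 <- d^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% d2 %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-8
  vals <- e$values[keep]
  coords <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(vals), sum(keep))
  rownames(coords) <- rownames(d)
  list(eigenvalues = vals, coordinates = coords)
}

# sign convention used by the package: largest-magnitude entry positive
flip_signs <- function(m) {
  for (k in seq_len(ncol(m))) {
    i <- which.max(abs(m[, k]))
    if (m[i, k] < 0) m[, k] <- -m[, k]
  }
  m
}

# direct-loop fixed-difference count over a frequency table
oracle_fixed_diff <- function(tbl, a, b, tau, mode = "max") {
  total <- 0L
  for (l in tbl$loci) {
    xa <- tbl$freq[[a]][[l]]
    xb <- tbl$freq[[b]][[l]]
    if (!length(xa) || !length(xb)) next
    s_a <- 0
    s_b <- 0
    for (al in names(xa)) {
      if (xa[[al]] > 0 && al %in% names(xb) && xb[[al]] > 0) {
        s_a <- s_a + xa[[al]]
        s_b <- s_b + xb[[al]]
      }
    }
    ok <- if (mode == "max") max(s_a, s_b) <= tau else s_a + s_b <= tau
    if (ok) total <- total + 1L
  }
  total
}

# direct-loop Nei's distance (unbiased correction, clamped exactly as stated)
oracle_nei_d <- function(tbl, a, b) {
  jx <- jy <- jxy <- numeric(0)
  for (l in tbl$loci) {
    xa <- tbl$freq[[a]][[l]]
    xb <- tbl$freq[[b]][[l]]
    na2 <- tbl$copies[a, l]
    nb2 <- tbl$copies[b, l]
    if (na2 < 2 || nb2 < 2) next
    hx <- (na2 * sum(xa^2) - 1) / (na2 - 1)
    hy <- (nb2 * sum(xb^2) - 1) / (nb2 - 1)
    hx <- min(max(hx, 0), 1)
    hy <- min(max(hy, 0), 1)
    s <- 0
    for (al in union(names(xa), names(xb))) {
      fa <- if (al %in% names(xa)) xa[[al]] else 0
      fb <- if (al %in% names(xb)) xb[[al]] else 0
      s <- s + fa * fb
    }
    jx <- c(jx, hx); jy <- c(jy, hy); jxy <- c(jxy, s)
  }
  i <- mean(jxy) / sqrt(mean(jx) * mean(jy))
  if (is.na(i) || i <= 0) return(Inf)
  if (i > 1) return(0)
  -log(i)
}

# double-loop p-distance matrix with pairwise deletion
oracle_p_matrix <- function(aln) {
  m <- unclass(aln)
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      comp <- 0L
      diff <- 0L
      for (s in seq_len(ncol(m))) {
        b1 <- m[i, s]
        b2 <- m[j, s]
        if (b1 %in% c("A", "C", "G", "T") && b2 %in% c("A", "C", "G", "T")) {
          comp <- comp + 1L
          if (b1 != b2) diff <- diff + 1L
        }
      }
      out[i, j] <- if (comp) diff / comp else NA_real_
    }
  }
  out
}

# hand-built allele-frequency table (bypasses genotype data) for statistics
# with exactly specified frequencies
make_freq_table <- function(freq, copies) {
  groups <- names(freq)
  loci <- names(freq[[1]])
  cp <- matrix(copies, length(groups), length(loci),
               dimnames = list(groups, loci))
  structure(list(groups = groups, loci = loci,
                 sizes = stats::setNames(rep(copies / 2, length(groups)), groups),
                 freq = freq, copies = cp),
            class = "allele_freq_table")
}

# random small frequency table: 2 groups, random loci/alleles, frequencies
# from genotype counts so copies are consistent
random_freq_table <- function(n_loci = 8, n_per_group = 12) {
  labels <- c("A", "B")
  freq <- list()
  for (g in labels) {
    freq[[g]] <- list()
    for (l in seq_len(n_loci)) {
      alleles <- sample(letters[1:5], sample(1:4, 1))
      counts <- stats::rmultinom(1, 2 * n_per_group, rep(1, length(alleles)))[, 1]
      keep <- counts > 0
      freq[[g]][[paste0("loc", l)]] <-
        stats::setNames(counts[keep] / sum(counts), alleles[keep])
    }
  }
  make_freq_table(freq, copies = 2 * n_per_group)
}

# random genotype dataset built in code (no files)
random_dataset <- function(n = 6, loci = c("Aat", "Idh"), missing = 0) {
  a1 <- matrix(sample(c("a", "b", "c"), n * length(loci), TRUE), n,
               dimnames = list(NULL, loci))
  a2 <- matrix(sample(c("a", "b", "c"), n * length(loci), TRUE), n,
               dimnames = list(NULL, loci))
  swap <- a1 > a2
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  if (missing > 0) {
    mask <- matrix(stats::runif(n * length(loci)) < missing, n)
    a1[mask] <- NA; a2[mask] <- NA
  }
  allozyme_dataset(
    data.frame(id = sprintf("i%02d", seq_len(n)),
               site = rep(c("s1", "s2"), length.out = n)),
    a1, a2)
}

# random additive tree with strictly positive branch lengths and its exact
# leaf-to-leaf path-length matrix (the oracle for NJ recovery)
random_additive_case <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, rooted = FALSE,
                   br = function(k) stats::runif(k, 0.2, 1.5))
  dm <- ape::cophenetic.phylo(tr)
  dm <- dm[order(rownames(dm)), order(colnames(dm))]
  list(tree = tr, dm = dm)
}

# topology + branch-length equality for unrooted trees, via the additive
# path-length matrix (invariant to representation)
same_tree <- function(t1, t2, tol = 1e-8) {
  d1 <- ape::cophenetic.phylo(t1)
  d2 <- ape::cophenetic.phylo(t2)
  if (!setequal(rownames(d1), rownames(d2))) return(FALSE)
  d2 <- d2[rownames(d1), colnames(d1)]
  topo <- ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
  topo && max(abs(d1 - d2)) < tol
}
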