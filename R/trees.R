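validate_dist_matrix <- function(dm) {
  if (!is.matrix(dm) || !is.numeric(dm)) stop("distance matrix must be numeric")
  labs <- rownames(dm)
  if (is.null(labs) || !identical(labs, colnames(dm)) || anyDuplicated(labs))
    stop("distance matrix needs matching unique row/column labels")
  bad <- which(!is.finite(dm), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-finite distance between '%s' and '%s'",
                 labs[bad[1, 1]], labs[bad[1, 2]]))
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix not symmetric")
  if (any(diag(dm) != 0)) stop("distance matrix diagonal must be 0")
  if (any(dm < 0)) stop("distance matrix has negative entries")
  invisible(labs)
}

quote_label <- function(lab) {
  needs <- grepl("[^A-Za-z0-9_.+|-]", lab)
  ifelse(needs, paste0("'", gsub("'", "''", lab), "'"), lab)
}

unquote_label <- function(lab) {
  q <- grepl("^'.*'$", lab)
  lab[q] <- gsub("''", "'", sub("^'(.*)'$", "\\1", lab[q]))
  lab
}

fmt_len <- function(x, precision) sprintf("%.*g", precision, x)

#' Neighbour-joining tree from a distance matrix
#'
#' Standard agglomeration under the Q-criterion.  Two conventions make the
#' result fully deterministic and well-formed: ties in Q are broken by the
#' lexicographically smallest pair of labels (each internal node is
#' represented by the smallest leaf label beneath it), and a negative
#' branch length arising at a join is clamped to zero with the deficit
#' moved to its sibling branch, preserving the path length between the
#' joined nodes.  On an exactly additive matrix neither convention fires
#' and the generating tree is recovered exactly.
#'
#' @param dm symmetric numeric matrix with zero diagonal, finite entries
#'   and matching row/column labels; at least 3 labels.
#' @return an unrooted `phylo` tree (see \pkg{ape}) with attributes
#'   `n_clamped` (number of clamped branches) and `raw_joins` (per-join raw
#'   branch lengths before clamping).
#' @export
neighbor_joining <- function(dm) {
  labs <- validate_dist_matrix(dm)
  n0 <- length(labs)
  if (n0 < 3L) stop("need at least 3 labels")
  D <- dm
  frag <- quote_label(labs)       # newick fragment per active node
  minleaf <- labs                 # tie-break key: smallest leaf label below node
  n_clamped <- 0L
  raw_joins <- list()

  clamp_pair <- function(li, lj) {
    # clamp a negative length to 0, moving the deficit to the sibling so the
    # path length li + lj is preserved
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(li, lj)
  }

  while (nrow(D) > 3L) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    tol <- max(1e-12, abs(qmin) * 1e-12)
    cand <- which(Q <= qmin + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij) {
      p <- sort(c(minleaf[ij[1]], minleaf[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    # canonical child order: smaller minleaf label first (permutation invariance)
    if (minleaf[j] < minleaf[i]) { tmp <- i; i <- j; j <- tmp }
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    raw_joins[[length(raw_joins) + 1L]] <-
      list(a = minleaf[i], b = minleaf[j], raw = c(li, lj))
    if (li < 0 || lj < 0) n_clamped <- n_clamped + sum(c(li, lj) < 0)
    l <- clamp_pair(li, lj)
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt_len(l[1], 12),
                        frag[j], fmt_len(l[2], 12))
    new_minleaf <- min(minleaf[i], minleaf[j])
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    frag <- c(frag[keep], new_frag)
    minleaf <- c(minleaf[keep], new_minleaf)
    dimnames(D) <- list(minleaf, minleaf)
  }

  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  raw_joins[[length(raw_joins) + 1L]] <-
    list(a = minleaf[1], b = minleaf[2], c = minleaf[3], raw = c(l1, l2, l3))
  if (any(c(l1, l2, l3) < 0)) {
    n_clamped <- n_clamped + sum(c(l1, l2, l3) < 0)
    l1 <- max(l1, 0); l2 <- max(l2, 0); l3 <- max(l3, 0)
  }
  ord <- order(minleaf)  # canonical child order at the root join
  lens <- c(l1, l2, l3)[ord]
  frs <- frag[ord]
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frs[1], fmt_len(lens[1], 12), frs[2], fmt_len(lens[2], 12),
                 frs[3], fmt_len(lens[3], 12))
  phy <- ape::read.tree(text = nwk)
  phy$tip.label <- unquote_label(phy$tip.label)
  attr(phy, "n_clamped") <- n_clamped
  attr(phy, "raw_joins") <- raw_joins
  phy
}

#' Serialise a tree to newick text
#'
#' Writes branch lengths at the given significant-digit precision and
#' single-quotes any label containing newick metacharacters or whitespace
#' (internal quotes doubled), so trees with labels such as site names
#' round-trip through [ape::read.tree()].
#'
#' @param tree a `phylo` object.
#' @param precision significant digits for branch lengths (default 10).
#' @param path optional file to write to.
#' @return the newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, precision = 10, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  render <- function(node) {
    idx <- children[[as.character(node)]]
    if (is.null(idx)) return(quote_label(tree$tip.label[node]))
    parts <- vapply(idx, function(e) {
      child <- tree$edge[e, 2]
      len <- if (is.null(tree$edge.length)) NULL else tree$edge.length[e]
      sub <- render(child)
      if (is.null(len)) sub else paste0(sub, ":", fmt_len(len, precision))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  out <- paste0(render(root), ";")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Read a newick tree, unquoting labels
#'
#' Thin wrapper over [ape::read.tree()] that strips the single-quote
#' escaping produced by [write_newick()].
#'
#' @param text newick string (or use `path`).
#' @param path file to read from.
#' @return a `phylo` object.
#' @export
read_newick <- function(text = NULL, path = NULL) {
  phy <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  phy$tip.label <- unquote_label(phy$tip.label)
  phy
}

#' Write / read a PHYLIP square distance matrix
#'
#' Relaxed PHYLIP: first line the number of taxa, then one row per taxon
#' with the label (whitespace-free) followed by the full row of distances.
#'
#' @param dm labelled symmetric matrix.
#' @param path file path.
#' @export
write_phylip_dist <- function(dm, path) {
  validate_dist_matrix(dm)
  labs <- gsub("[[:space:]]+", "_", rownames(dm))
  lines <- c(sprintf("%5d", nrow(dm)),
             vapply(seq_len(nrow(dm)), function(i) {
               paste(c(labs[i], sprintf("%.10f", dm[i, ])), collapse = "  ")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_phylip_dist
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  rows <- strsplit(trimws(lines[1 + seq_len(n)]), "[[:space:]]+")
  labs <- vapply(rows, `[[`, character(1), 1)
  dm <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(n)))
  dimnames(dm) <- list(labs, labs)
  dm
}

#' Write / read a labelled TSV distance matrix
#' @param dm labelled symmetric matrix.
#' @param path file path.
#' @export
write_dist_tsv <- function(dm, path) {
  utils::write.table(dm, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_dist_tsv
#' @export
read_dist_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                              check.names = FALSE))
}
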