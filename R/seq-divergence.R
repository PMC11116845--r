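#' Aligned DNA sequences
#'
#' A `dna_alignment` is a character matrix (sequences x columns) over the
#' residue alphabet `A C G T N -`, upper case, with unique sequence ids as
#' row names.  `N` marks missing data; gaps are treated like missing data
#' by the distance functions (protein-coding mitochondrial alignments use
#' them for absent flanks, not indel history).
#'
#' @param seqs character matrix, or a named list/vector of equal-length
#'   sequence strings.
#' @return object of class `dna_alignment`.
#' @export
dna_alignment <- function(seqs) {
  if (!is.matrix(seqs)) {
    ids <- names(seqs)
    if (is.null(ids)) stop("sequences must be named")
    chars <- strsplit(toupper(unlist(seqs)), "")
    lens <- lengths(chars)
    if (length(unique(lens)) > 1L) {
      bad <- ids[which(lens != lens[1])[1]]
      stop("ragged alignment: record '", bad, "' has length ",
           lens[ids == bad][1], ", expected ", lens[1])
    }
    seqs <- do.call(rbind, chars)
    rownames(seqs) <- ids
  } else {
    seqs[] <- toupper(seqs)
  }
  if (is.null(rownames(seqs)) || anyDuplicated(rownames(seqs)))
    stop("alignment needs unique sequence ids")
  unknown <- !(seqs %in% c("A", "C", "G", "T", "N", "-"))
  if (any(unknown)) {
    warning(sum(unknown), " residue(s) outside {A,C,G,T,N,-} recoded to N")
    seqs[unknown] <- "N"
  }
  structure(seqs, class = c("dna_alignment", class(seqs)))
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("dna_alignment: %d sequences x %d columns\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Records must all have the same length (ragged input is an error naming
#' the offending record).  Residues outside `A C G T N -` (e.g. IUPAC
#' ambiguity codes) are recoded to `N` with a warning giving the count.
#'
#' @param path FASTA file.
#' @return a [dna_alignment()].
#' @export
read_alignment <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "DNA", forceDNAtolower = FALSE,
                             set.attributes = FALSE)
  dna_alignment(stats::setNames(vapply(recs, paste, character(1), collapse = ""),
                                names(recs)))
}

#' Write an alignment as FASTA
#' @param aln a [dna_alignment()].
#' @param path output file.
#' @export
write_alignment <- function(aln, path) {
  seqinr::write.fasta(lapply(seq_len(nrow(aln)), function(i) aln[i, ]),
                      names = rownames(aln), file.out = path, nbchar = 70)
  invisible(path)
}

#' p-distance between two aligned sequences
#'
#' Proportion of differing sites among the sites where both sequences carry
#' an unambiguous base (pairwise deletion: any site with `N` or `-` in
#' either sequence is excluded).  Comparison is case-insensitive.
#'
#' @param s1,s2 equal-length character vectors of residues, or single
#'   sequence strings.
#' @return proportion in `[0, 1]`; an error if no site is comparable.
#' @export
p_distance <- function(s1, s2) {
  if (length(s1) == 1L && nchar(s1) > 1L) s1 <- strsplit(s1, "")[[1]]
  if (length(s2) == 1L && nchar(s2) > 1L) s2 <- strsplit(s2, "")[[1]]
  if (length(s1) != length(s2)) stop("sequences must have equal length")
  s1 <- toupper(s1); s2 <- toupper(s2)
  ok <- s1 %in% c("A", "C", "G", "T") & s2 %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("no comparable site between the two sequences")
  sum(s1[ok] != s2[ok]) / sum(ok)
}

#' Pairwise p-distance matrix
#'
#' All pairwise p-distances of an alignment under pairwise deletion,
#' delegated to [ape::dist.dna()] (`model = "raw"`).  Pairs with no
#' comparable site are flagged as `NA` (attribute `undefined_pairs`) rather
#' than raising an error.
#'
#' @param aln a [dna_alignment()].
#' @return symmetric labelled matrix with zero diagonal; attribute
#'   `undefined_pairs` lists id pairs with no overlap.
#' @export
pairwise_p_matrix <- function(aln) {
  if (nrow(aln) < 2L) stop("need at least two sequences")
  db <- ape::as.DNAbin(apply(unclass(aln), c(1, 2), tolower))
  dm <- suppressWarnings(
    as.matrix(ape::dist.dna(db, model = "raw", pairwise.deletion = TRUE)))
  undef <- which(!is.finite(dm) & upper.tri(dm), arr.ind = TRUE)
  pairs <- if (nrow(undef))
    data.frame(id1 = rownames(dm)[undef[, 1]], id2 = colnames(dm)[undef[, 2]],
               stringsAsFactors = FALSE)
  else data.frame(id1 = character(0), id2 = character(0))
  dm[!is.finite(dm)] <- NA_real_
  diag(dm) <- 0
  attr(dm, "undefined_pairs") <- pairs
  dm
}

#' Prune an alignment to a column window
#'
#' @param aln a [dna_alignment()].
#' @param start,end 1-based inclusive column bounds.
#' @return the sliced [dna_alignment()].
#' @export
prune_alignment <- function(aln, start, end) {
  if (start < 1L || end > ncol(aln) || start > end)
    stop("window [", start, ", ", end, "] out of bounds for ", ncol(aln),
         " columns")
  dna_alignment(unclass(aln)[, start:end, drop = FALSE])
}

#' Divergence ranges among and within clades
#'
#' Min/max pairwise distance for every clade pair (among) and for each
#' clade with at least two members (within).  Ids listed in `excluded` are
#' dropped before summarising; `NA` (undefined) pairs are ignored.
#'
#' @param dm a pairwise distance matrix (e.g. [pairwise_p_matrix()]).
#' @param clades named character vector id -> clade, or a data frame with
#'   columns `id` and `clade`.
#' @param excluded ids to drop (default none).
#' @return object of class `divergence_summary` with matrices `min`, `max`
#'   and `n_pairs` (clade x clade; diagonal = within-clade, `NA` when a
#'   clade has fewer than two members).
#' @export
clade_divergence_summary <- function(dm, clades, excluded = character(0)) {
  if (is.data.frame(clades))
    clades <- stats::setNames(as.character(clades$clade), as.character(clades$id))
  clades <- clades[!names(clades) %in% excluded]
  missing_ids <- setdiff(names(clades), rownames(dm))
  if (length(missing_ids))
    stop("clade member absent from distance matrix: ",
         paste(missing_ids, collapse = ", "))
  labs <- unique(unname(clades))
  k <- length(labs)
  mn <- mx <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  np <- matrix(0L, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k)) {
    for (j in seq_len(i)) {
      ids_i <- names(clades)[clades == labs[i]]
      ids_j <- names(clades)[clades == labs[j]]
      vals <- dm[ids_i, ids_j, drop = FALSE]
      if (i == j) vals <- vals[upper.tri(vals)]
      vals <- vals[!is.na(vals)]
      if (length(vals)) {
        mn[i, j] <- mn[j, i] <- min(vals)
        mx[i, j] <- mx[j, i] <- max(vals)
      }
      np[i, j] <- np[j, i] <- length(vals)
    }
  }
  structure(list(min = mn, max = mx, n_pairs = np, clades = labs),
            class = "divergence_summary")
}

#' Format a divergence summary as a range table
#'
#' Lower triangle plus diagonal, each cell `min-max`, proportions to 3
#' decimals or percentages to 2 decimals.
#'
#' @param x a [clade_divergence_summary()] result.
#' @param percent render as percentages.
#' @return character matrix.
#' @export
format_divergence_summary <- function(x, percent = FALSE) {
  f <- function(v) {
    if (is.na(v)) return(NA_character_)
    if (percent) sprintf("%.2f", 100 * v) else sprintf("%.3f", v)
  }
  k <- length(x$clades)
  out <- matrix("", k, k, dimnames = dimnames(x$min))
  for (i in seq_len(k)) {
    for (j in seq_len(i)) {
      if (is.na(x$min[i, j])) {
        out[i, j] <- "-"
      } else {
        out[i, j] <- paste0(f(x$min[i, j]),
                            if (x$min[i, j] != x$max[i, j])
                              paste0("-", f(x$max[i, j])))
      }
    }
  }
  out
}

#' @export
print.divergence_summary <- function(x, ...) {
  cat("p-distance ranges among (lower triangle) and within (diagonal) clades\n")
  print(format_divergence_summary(x), quote = FALSE, na.print = "")
  invisible(x)
}
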