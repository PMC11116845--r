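#' Allele frequencies per group and locus
#'
#' Counts gene copies per (group, locus) with missing genotypes excluded
#' from the denominator.  A (group, locus) cell with no scored individuals
#' is recorded as undefined (empty frequency vector, zero copies) rather
#' than dropped, so downstream statistics can apply their own rule.
#'
#' @param x an [allozyme_dataset()].
#' @param grouping either a named character vector mapping individual id to
#'   group label, the string `"site"` (group by the dataset's site column),
#'   or a [stepwise_delineate()] result (group by inferred lineage, admixed
#'   individuals excluded).
#' @return object of class `allele_freq_table`: `groups`, `loci`, `sizes`
#'   (individuals per group), `freq` (list: group -> locus -> named numeric
#'   frequency vector) and `copies` (groups x loci matrix of gene-copy
#'   counts, `2n`).
#' @export
allele_frequencies <- function(x, grouping = "site") {
  if (inherits(grouping, "lineage_assignment")) grouping <- lineage_labels(grouping)
  if (identical(grouping, "site"))
    grouping <- stats::setNames(x$individuals$site, x$individuals$id)
  if (is.null(names(grouping)))
    stop("`grouping` must be a named vector (id -> group)")
  unknown <- setdiff(names(grouping), x$individuals$id)
  if (length(unknown))
    stop("grouping refers to unknown individual: ", paste(unknown, collapse = ", "))
  groups <- sort(unique(unname(grouping)))
  if (!length(groups)) stop("no groups supplied")
  sizes <- stats::setNames(integer(length(groups)), groups)
  copies <- matrix(0L, length(groups), length(x$loci),
                   dimnames = list(groups, x$loci))
  freq <- stats::setNames(vector("list", length(groups)), groups)
  for (g in groups) {
    ids <- names(grouping)[grouping == g]
    if (!length(ids)) stop("group with zero individuals: ", g)
    sizes[g] <- length(ids)
    rows <- match(ids, x$individuals$id)
    freq[[g]] <- stats::setNames(vector("list", length(x$loci)), x$loci)
    for (j in seq_along(x$loci)) {
      al <- c(x$a1[rows, j], x$a2[rows, j])
      al <- al[!is.na(al)]
      copies[g, j] <- length(al)
      if (length(al)) {
        tb <- table(al)
        freq[[g]][[j]] <- stats::setNames(as.numeric(tb) / length(al), names(tb))
      } else {
        freq[[g]][[j]] <- numeric(0)
      }
    }
  }
  structure(list(groups = groups, loci = x$loci, sizes = sizes,
                 freq = freq, copies = copies),
            class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat(sprintf("allele_freq_table: %d groups (%s), %d loci\n",
              length(x$groups), paste(x$groups, collapse = ", "),
              length(x$loci)))
  invisible(x)
}

check_groups <- function(tbl, ...) {
  unknown <- setdiff(c(...), tbl$groups)
  if (length(unknown))
    stop("unknown group label: ", paste(unknown, collapse = ", "))
}

#' Fixed allelic differences with a shared-allele tolerance
#'
#' A locus is diagnostic between two groups when the alleles they share
#' account for at most `tau` of the allele frequencies in each group
#' (`mode = "max"`: `max(S_A, S_B) <= tau` where `S_A` is the summed
#' frequency, within group A, of alleles also present in B).  With `tau = 0`
#' this reduces to a strict fixed difference (disjoint allele sets).  The
#' alternative reading of a pooled budget across both groups
#' (`S_A + S_B <= tau`) is available as `mode = "sum"`.  A locus undefined
#' (unscored) in either group is never diagnostic.
#'
#' @param tbl an [allele_frequencies()] table.
#' @param a,b group labels.
#' @param tau shared-allele tolerance in `[0, 1)`; default 0.10.
#' @param mode `"max"` (default) or `"sum"`; see above.
#' @return object of class `fixed_diff`: `groups`, `tau`, `mode`,
#'   `per_locus` data frame (`locus`, `n_shared`, `S_A`, `S_B`,
#'   `diagnostic`; `diagnostic` is `NA` for undefined loci) and `total`.
#' @export
count_fixed_differences <- function(tbl, a, b, tau = 0.10,
                                    mode = c("max", "sum")) {
  mode <- match.arg(mode)
  stopifnot(tau >= 0, tau < 1)
  check_groups(tbl, a, b)
  per <- lapply(tbl$loci, function(l) {
    xa <- tbl$freq[[a]][[l]]
    xb <- tbl$freq[[b]][[l]]
    if (!length(xa) || !length(xb))
      return(data.frame(locus = l, n_shared = NA_integer_, S_A = NA_real_,
                        S_B = NA_real_, diagnostic = NA, stringsAsFactors = FALSE))
    shared <- intersect(names(xa)[xa > 0], names(xb)[xb > 0])
    s_a <- sum(xa[shared])
    s_b <- sum(xb[shared])
    diag <- switch(mode, max = max(s_a, s_b) <= tau, sum = s_a + s_b <= tau)
    data.frame(locus = l, n_shared = length(shared), S_A = s_a, S_B = s_b,
               diagnostic = diag, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  structure(list(groups = c(a, b), tau = tau, mode = mode, per_locus = per,
                 total = sum(per$diagnostic, na.rm = TRUE)),
            class = "fixed_diff")
}

#' @export
print.fixed_diff <- function(x, ...) {
  cat(sprintf("fixed differences %s vs %s: %d loci diagnostic (tau = %.2f, mode = %s)\n",
              x$groups[1], x$groups[2], x$total, x$tau, x$mode))
  invisible(x)
}

#' Per-locus allele-frequency differential
#'
#' For each locus, the largest absolute difference in allele frequency
#' between two groups (an allele absent from a group has frequency 0).
#' Loci undefined in either group are skipped with a warning.
#'
#' @param tbl an [allele_frequencies()] table.
#' @param a,b group labels.
#' @param threshold flag loci whose differential exceeds this (default 0.40).
#' @return data frame (`locus`, `delta_p`, `exceeds`) with the threshold as
#'   an attribute.
#' @export
delta_p <- function(tbl, a, b, threshold = 0.40) {
  check_groups(tbl, a, b)
  skipped <- character(0)
  rows <- lapply(tbl$loci, function(l) {
    xa <- tbl$freq[[a]][[l]]
    xb <- tbl$freq[[b]][[l]]
    if (!length(xa) || !length(xb)) {
      skipped <<- c(skipped, l)
      return(NULL)
    }
    alleles <- union(names(xa), names(xb))
    fa <- ifelse(alleles %in% names(xa), xa[alleles], 0)
    fb <- ifelse(alleles %in% names(xb), xb[alleles], 0)
    dp <- max(abs(fa - fb))
    data.frame(locus = l, delta_p = dp, exceeds = dp > threshold,
               stringsAsFactors = FALSE)
  })
  if (length(skipped))
    warning("locus undefined in one group, skipped: ",
            paste(skipped, collapse = ", "))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(locus = character(0), delta_p = numeric(0),
                      exceeds = logical(0))
  attr(out, "threshold") <- threshold
  out
}

#' Nei's genetic distance between two groups
#'
#' Nei's standard genetic distance `D = -ln(I)` with, by default, the
#' small-sample unbiased correction of the within-group gene identities:
#' per locus `Jx = (2n_A * sum(x_i^2) - 1) / (2n_A - 1)` (analogously `Jy`),
#' `Jxy = sum(x_i * y_i)`, and `I = mean(Jxy) / sqrt(mean(Jx) * mean(Jy))`
#' with arithmetic means over the loci scoreable (`2n >= 2`) in both groups.
#' Per-locus `Jx`/`Jy` are clamped to `[0, 1]` before averaging.  At small
#' sample sizes the unbiased correction can push `I` above 1; the identity
#' is then clamped to 1 (so `D = 0`) and a note is recorded.  `I = 0` gives
#' `D = +Inf`.  With `unbiased = FALSE` the raw identities `Jx = sum(x^2)`
#' are used, under which `D` of a group with itself is exactly 0.
#'
#' @param tbl an [allele_frequencies()] table.
#' @param a,b group labels.
#' @param unbiased apply the small-sample correction (default `TRUE`).
#' @return object of class `nei_d`: `groups`, `per_locus` data frame
#'   (`locus`, `jx`, `jy`, `jxy`), `I_raw`, `I`, `D`, `n_loci`,
#'   `dropped_loci`, `note`.
#' @export
nei_D <- function(tbl, a, b, unbiased = TRUE) {
  check_groups(tbl, a, b)
  min_copies <- if (unbiased) 2L else 1L
  scoreable_a <- tbl$copies[a, ] >= min_copies
  scoreable_b <- tbl$copies[b, ] >= min_copies
  if (!any(scoreable_a)) stop("group '", a, "' has no scoreable locus")
  if (!any(scoreable_b)) stop("group '", b, "' has no scoreable locus")
  use <- scoreable_a & scoreable_b
  if (!any(use)) stop("no locus scoreable in both groups")
  dropped <- tbl$loci[!use]
  rows <- lapply(tbl$loci[use], function(l) {
    xa <- tbl$freq[[a]][[l]]
    xb <- tbl$freq[[b]][[l]]
    jx <- sum(xa^2)
    jy <- sum(xb^2)
    if (unbiased) {
      na2 <- tbl$copies[a, l]
      nb2 <- tbl$copies[b, l]
      jx <- (na2 * jx - 1) / (na2 - 1)
      jy <- (nb2 * jy - 1) / (nb2 - 1)
    }
    jx <- min(max(jx, 0), 1)
    jy <- min(max(jy, 0), 1)
    alleles <- union(names(xa), names(xb))
    fa <- ifelse(alleles %in% names(xa), xa[alleles], 0)
    fb <- ifelse(alleles %in% names(xb), xb[alleles], 0)
    data.frame(locus = l, jx = jx, jy = jy, jxy = sum(fa * fb),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  note <- character(0)
  denom <- sqrt(mean(per$jx) * mean(per$jy))
  i_raw <- if (denom > 0) mean(per$jxy) / denom else NA_real_
  if (is.na(i_raw) || i_raw <= 0) {
    i <- 0
    d <- Inf
    note <- c(note, "identity non-positive; D set to +Inf")
  } else if (i_raw > 1) {
    i <- 1
    d <- 0
    note <- c(note, sprintf("identity %.6f exceeded 1 (unbiased correction at small n); clamped", i_raw))
  } else {
    i <- i_raw
    d <- -log(i)
  }
  structure(list(groups = c(a, b), per_locus = per, I_raw = i_raw, I = i, D = d,
                 n_loci = sum(use), dropped_loci = dropped, note = note),
            class = "nei_d")
}

#' @export
print.nei_d <- function(x, ...) {
  cat(sprintf("Nei's D %s vs %s: D = %.4f (I = %.4f over %d loci)\n",
              x$groups[1], x$groups[2], x$D, x$I, x$n_loci))
  if (length(x$note)) cat("  note:", paste(x$note, collapse = "; "), "\n")
  invisible(x)
}

#' Pairwise diagnosability and divergence matrices
#'
#' Fixed-difference counts and Nei's distances for every pair of groups,
#' as two symmetric labelled matrices.  The print method renders them as a
#' single combined table with fixed differences in the lower-left triangle
#' and Nei's D (2 decimals) in the upper-right, the conventional layout for
#' candidate-taxon comparisons.
#'
#' @param tbl an [allele_frequencies()] table.
#' @param groups group labels to include (default: all, in table order).
#' @param tau,mode passed to [count_fixed_differences()].
#' @param unbiased passed to [nei_D()].
#' @return object of class `diag_matrices`: `fixed` (integer matrix),
#'   `nei_d` (numeric matrix), `sizes`, plus the parameters used.
#' @export
pairwise_matrices <- function(tbl, groups = NULL, tau = 0.10,
                              mode = c("max", "sum"), unbiased = TRUE) {
  mode <- match.arg(mode)
  if (is.null(groups)) groups <- tbl$groups
  check_groups(tbl, groups)
  if (length(groups) < 2L) stop("need at least two groups")
  k <- length(groups)
  fixed <- matrix(0L, k, k, dimnames = list(groups, groups))
  nd <- matrix(0, k, k, dimnames = list(groups, groups))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      fd <- count_fixed_differences(tbl, groups[i], groups[j], tau = tau, mode = mode)
      d <- nei_D(tbl, groups[i], groups[j], unbiased = unbiased)
      fixed[i, j] <- fixed[j, i] <- fd$total
      nd[i, j] <- nd[j, i] <- d$D
    }
  }
  structure(list(fixed = fixed, nei_d = nd,
                 sizes = tbl$sizes[groups],
                 tau = tau, mode = mode, unbiased = unbiased),
            class = "diag_matrices")
}

#' Render the combined lower/upper-triangle table
#'
#' @param x a [pairwise_matrices()] result.
#' @param digits decimals for Nei's D (default 2).
#' @return character matrix (lower = fixed differences, upper = Nei's D).
#' @export
format_combined_table <- function(x, digits = 2) {
  groups <- rownames(x$fixed)
  k <- length(groups)
  out <- matrix("-", k, k,
                dimnames = list(sprintf("%s (%d)", groups, x$sizes),
                                groups))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i > j) out[i, j] <- as.character(x$fixed[i, j])
      if (i < j) out[i, j] <- formatC(x$nei_d[i, j], digits = digits, format = "f")
    }
  }
  out
}

#' @export
print.diag_matrices <- function(x, ...) {
  cat(sprintf("Pairwise diagnosability (lower: fixed differences, tau = %.2f, mode = %s)\n",
              x$tau, x$mode))
  cat(sprintf("and Nei's %sD (upper)\n", if (x$unbiased) "unbiased " else ""))
  print(format_combined_table(x), quote = FALSE)
  invisible(x)
}
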