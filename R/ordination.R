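#' Allele-dosage encoding of genotypes
#'
#' Expands a genotype dataset into a numeric matrix with one column per
#' (locus, allele) pair observed in the dataset.  A homozygote contributes
#' dosage 1 to its allele's column, a heterozygote 0.5 to each of its two
#' alleles, so non-missing dosages sum to 1 across each locus's columns.
#' Missing genotypes are mean-imputed per column from the individuals
#' scored at that locus; because the encoding is recomputed for every
#' analysis subset, imputation never imports information from outside the
#' subset being ordinated.
#'
#' @param x an [allozyme_dataset()].
#' @return numeric matrix (individuals x allele columns) with attributes
#'   `locus`, `allele` (column annotations) and `imputed` (logical matrix
#'   marking mean-imputed cells).
#' @export
encode_genotypes <- function(x) {
  if (n_individuals(x) < 1L) stop("empty dataset")
  all_missing <- rowSums(!is.na(x$a1)) == 0L
  if (any(all_missing))
    stop("individual scored at no locus: ",
         paste(x$individuals$id[all_missing], collapse = ", "))
  universe <- allele_universe(x)
  cols <- list()
  col_locus <- character(0)
  col_allele <- character(0)
  for (j in seq_along(x$loci)) {
    alleles <- universe[[j]]
    if (!length(alleles)) next  # locus unscored in this subset
    g1 <- x$a1[, j]
    g2 <- x$a2[, j]
    for (al in alleles) {
      dose <- ((g1 == al) + (g2 == al)) / 2
      cols[[length(cols) + 1L]] <- dose
      col_locus <- c(col_locus, x$loci[j])
      col_allele <- c(col_allele, al)
    }
  }
  m <- do.call(cbind, cols)
  dimnames(m) <- list(x$individuals$id, paste(col_locus, col_allele, sep = "."))
  imputed <- is.na(m)
  for (k in seq_len(ncol(m))) {
    if (any(imputed[, k])) m[imputed[, k], k] <- mean(m[, k], na.rm = TRUE)
  }
  attr(m, "locus") <- col_locus
  attr(m, "allele") <- col_allele
  attr(m, "imputed") <- imputed
  m
}

canonicalise_signs <- function(m) {
  if (!ncol(m)) return(m)
  for (k in seq_len(ncol(m))) {
    i <- which.max(abs(m[, k]))
    if (m[i, k] < 0) m[, k] <- -m[, k]
  }
  m
}

#' Principal coordinates analysis of individuals
#'
#' Classical metric scaling of the Euclidean distances between the rows of a
#' dosage matrix (or any numeric matrix).  Only axes with positive
#' eigenvalues are retained; percent contributions are relative to the sum
#' of positive eigenvalues, matching the axis labels conventionally shown on
#' ordination scatterplots.  Axis signs are canonicalised so the
#' largest-magnitude coordinate on each axis is positive, making results
#' reproducible bit-for-bit.
#'
#' @param x numeric matrix with row names (e.g. from [encode_genotypes()]),
#'   or a `dist` object.
#' @return object of class `pcoa_result`: list with `coordinates`
#'   (individuals x axes), `eigenvalues` (positive, descending) and
#'   `percent_contribution` (sums to 100).  A fully degenerate input (all
#'   points identical) yields zero axes rather than an error.
#' @export
pcoa_coords <- function(x) {
  d <- if (inherits(x, "dist")) x else stats::dist(x)
  labs <- attr(d, "Labels")
  n <- attr(d, "Size")
  if (n < 2L) stop("need at least two individuals")
  if (max(d) <= 0) {
    return(structure(list(
      coordinates = matrix(0, n, 0, dimnames = list(labs, NULL)),
      eigenvalues = numeric(0),
      percent_contribution = numeric(0)), class = "pcoa_result"))
  }
  res <- ape::pcoa(d)
  eig <- res$values$Eigenvalues
  keep <- eig > max(eig) * 1e-8
  eig <- eig[keep]
  coords <- res$vectors[, seq_along(eig), drop = FALSE]
  coords <- canonicalise_signs(coords)
  dimnames(coords) <- list(labs, paste0("Axis", seq_along(eig)))
  structure(list(
    coordinates = coords,
    eigenvalues = eig,
    percent_contribution = 100 * eig / sum(eig)), class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("pcoa_result: %d individuals, %d positive axes\n",
              nrow(x$coordinates), length(x$eigenvalues)))
  if (length(x$eigenvalues)) {
    k <- min(4L, length(x$eigenvalues))
    cat("  leading axes (% contribution):",
        paste(sprintf("%.1f", x$percent_contribution[seq_len(k)]), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Detect a cluster split in an ordination
#'
#' Automates the by-eye reading of an ordination scatter: single-linkage
#' clustering on the first one or two axes, accepted as a genuine split when
#' (i) the smallest between-cluster gap (the next single-linkage merge
#' height) exceeds `gap_factor` times the median within-cluster
#' nearest-neighbour distance, (ii) that gap also exceeds `spread_factor`
#' times the pooled within-cluster RMS deviation -- clusters separated by a
#' corridor comparable to their own scatter do not read as discrete on a
#' scatterplot, and small samples routinely produce local density gaps that
#' satisfy (i) alone -- and (iii) every child cluster has at least
#' `min_cluster` members.  The
#' smallest number of clusters satisfying both criteria is returned, so a
#' three-way structure may be found as one 3-way split or as two nested
#' 2-way splits depending on relative gap sizes; the final leaf partition is
#' the same either way.  Rows are processed in lexicographic id order so
#' clustering ties are deterministic.
#'
#' @param pc a [pcoa_coords()] result.
#' @param gap_factor gap acceptance multiplier (default 3).
#' @param min_cluster minimum child cluster size (default 4).
#' @param spread_factor multiplier on the pooled within-cluster RMS
#'   deviation that the gap must also exceed (default 1.5, roughly two
#'   within-cluster standard deviations for a 2-D Gaussian cluster).
#' @return object of class `split_decision`: `accepted`, `children` (list of
#'   id vectors, largest first; empty when not accepted), `k`, `gap`,
#'   `within_nn` (median nearest-neighbour distance), `gap_ratio`,
#'   `spread_ratio` (gap / pooled within-cluster RMS deviation).
#' @export
detect_split <- function(pc, gap_factor = 3, min_cluster = 4,
                         spread_factor = 1.5) {
  stopifnot(inherits(pc, "pcoa_result"))
  reject <- function() structure(list(accepted = FALSE, children = list(),
                                      k = 1L, gap = NA_real_, within_nn = NA_real_,
                                      gap_ratio = NA_real_, spread_ratio = NA_real_),
                                 class = "split_decision")
  if (!length(pc$eigenvalues)) return(reject())
  coords <- pc$coordinates[, seq_len(min(2L, ncol(pc$coordinates))), drop = FALSE]
  coords <- coords[order(rownames(coords)), , drop = FALSE]
  n <- nrow(coords)
  if (n < 2L * min_cluster) return(reject())
  d <- stats::dist(coords)
  dm <- as.matrix(d)
  diag(dm) <- Inf
  hc <- stats::hclust(d, method = "single")
  heights <- hc$height
  best <- reject()
  for (k in 2:min(floor(n / min_cluster), n - 1L)) {
    part <- stats::cutree(hc, k = k)
    sizes <- tabulate(part, k)
    if (any(sizes < min_cluster)) next
    gap <- heights[n - k + 1L]
    nn <- vapply(seq_len(n), function(i) {
      same <- part == part[i]
      same[i] <- FALSE
      min(dm[i, same])
    }, numeric(1))
    within_nn <- stats::median(nn)
    if (within_nn <= 0 || gap <= gap_factor * within_nn) next
    wss <- 0
    for (ki in seq_len(k)) {
      cc <- coords[part == ki, , drop = FALSE]
      wss <- wss + sum(rowSums(scale(cc, scale = FALSE)^2))
    }
    rms <- sqrt(wss / n)
    if (rms <= 0 || gap <= spread_factor * rms) next
    members <- split(rownames(coords), part)
    ord <- order(-lengths(members), vapply(members, min, character(1)))
    best <- structure(list(accepted = TRUE,
                           children = unname(members[ord]),
                           k = as.integer(k), gap = gap, within_nn = within_nn,
                           gap_ratio = gap / within_nn,
                           spread_ratio = gap / rms),
                      class = "split_decision")
    break
  }
  best
}

#' @export
print.split_decision <- function(x, ...) {
  if (x$accepted) {
    cat(sprintf("split accepted: %d children (sizes %s), gap ratio %.1f\n",
                x$k, paste(lengths(x$children), collapse = "/"), x$gap_ratio))
  } else {
    cat("no split accepted\n")
  }
  invisible(x)
}

#' Flag putatively admixed individuals at a split
#'
#' An individual is flagged as admixed (F1-like) between the two largest
#' child clusters of an accepted split when (a) its projection onto the line
#' joining the two cluster centroids (in the plane of the first two axes)
#' lies strictly between the clusters' convex ranges -- computed over each
#' cluster's core members, i.e. after trimming small satellite components
#' (single linkage cut at 3x the cluster's median nearest-neighbour
#' distance), so that hybrids attached to a cluster cannot stretch its
#' range or pollute its allele frequencies -- and (b) it carries
#' alleles from both clusters at at least `mixed_threshold` of its scoreable
#' diagnostic loci.  Diagnostic loci are computed between the two clusters
#' with [count_fixed_differences()] at tolerance `tau`.
#'
#' @param x the [allozyme_dataset()] the split was computed on.
#' @param pc the [pcoa_coords()] result for `x`.
#' @param split an accepted [detect_split()] decision.
#' @param tau shared-allele tolerance for diagnostic loci (default 0.10).
#' @param mixed_threshold minimum fraction of scoreable diagnostic loci with
#'   mixed allele carriage (default 0.5).
#' @param min_cluster minimum size of a retained core component (default 4,
#'   matching [detect_split()]).
#' @return list with `ids` (flagged individuals), `diagnostic_loci`, and a
#'   per-individual `detail` data frame.
#' @export
flag_admixture <- function(x, pc, split, tau = 0.10, mixed_threshold = 0.5,
                           min_cluster = 4) {
  stopifnot(inherits(split, "split_decision"))
  empty <- list(ids = character(0), diagnostic_loci = character(0),
                detail = data.frame())
  if (!split$accepted) return(empty)
  big <- split$children[1:2]

  coords <- pc$coordinates[, seq_len(min(2L, ncol(pc$coordinates))), drop = FALSE]

  # core of a child: its members minus small satellite components (single
  # linkage in the axis plane, cut at 3x the child's median nearest-neighbour
  # distance).  Hybrids attached to a cluster sit far from its bulk, so they
  # fall into satellites and cannot stretch the cluster's convex range (or
  # pollute its allele frequencies) over themselves.
  core_of <- function(members) {
    if (length(members) < 2L) return(members)
    xy <- coords[members, , drop = FALSE]
    d <- stats::dist(xy)
    dm2 <- as.matrix(d)
    diag(dm2) <- Inf
    med_nn <- stats::median(apply(dm2, 1, min))
    if (!is.finite(med_nn) || med_nn <= 0) return(members)
    comp <- stats::cutree(stats::hclust(d, method = "single"), h = 3 * med_nn)
    sizes <- table(comp)
    keep <- names(sizes)[sizes >= min(min_cluster, max(sizes))]
    members[comp %in% as.integer(keep)]
  }
  core_a <- core_of(big[[1]])
  core_b <- core_of(big[[2]])

  # project everyone onto the axis joining the two core centroids
  cen_a <- colMeans(coords[core_a, , drop = FALSE])
  cen_b <- colMeans(coords[core_b, , drop = FALSE])
  dir <- cen_b - cen_a
  nd <- sqrt(sum(dir^2))
  if (nd <= 0) return(empty)
  proj <- as.vector(coords %*% (dir / nd))
  names(proj) <- rownames(coords)

  # criterion (a): strictly between the cores' convex ranges
  ra <- range(proj[core_a])
  rb <- range(proj[core_b])
  if (max(ra) < min(rb)) {
    between <- proj > max(ra) & proj < min(rb)
  } else if (max(rb) < min(ra)) {
    between <- proj > max(rb) & proj < min(ra)
  } else {
    between <- rep(FALSE, length(proj))  # convex ranges overlap: nobody between
  }
  between <- between & !names(proj) %in% c(core_a, core_b)

  # diagnostic loci between the cluster cores
  grp <- stats::setNames(rep(c("A", "B"), c(length(core_a), length(core_b))),
                         c(core_a, core_b))
  sub <- subset_genotypes(x, individuals = names(grp))
  ft <- allele_frequencies(sub, grp[sub$individuals$id])
  fd <- count_fixed_differences(ft, "A", "B", tau = tau)
  diag_loci <- fd$per_locus$locus[which(fd$per_locus$diagnostic)]
  if (!length(diag_loci)) return(empty)
  set_a <- set_b <- list()
  for (l in diag_loci) {
    xa <- ft$freq[["A"]][[l]]
    xb <- ft$freq[["B"]][[l]]
    set_a[[l]] <- names(xa)[xa > 0]
    set_b[[l]] <- names(xb)[xb > 0]
  }

  # criterion (b): mixed allele carriage at >= mixed_threshold of the
  # scoreable diagnostic loci
  detail <- do.call(rbind, lapply(names(proj), function(id) {
    i <- match(id, x$individuals$id)
    scoreable <- 0L
    mixed <- 0L
    for (l in diag_loci) {
      al1 <- x$a1[i, l]
      al2 <- x$a2[i, l]
      if (is.na(al1)) next
      scoreable <- scoreable + 1L
      in_a <- c(al1 %in% set_a[[l]], al2 %in% set_a[[l]])
      in_b <- c(al1 %in% set_b[[l]], al2 %in% set_b[[l]])
      # mixed carriage: one allele traceable to each cluster, and the pair is
      # not wholly composed of alleles shared by both clusters
      if (any(in_a) && any(in_b) && !all(in_a & in_b)) mixed <- mixed + 1L
    }
    data.frame(id = id, scoreable = scoreable, mixed = mixed,
               between = unname(between[id]), stringsAsFactors = FALSE)
  }))
  unscoreable <- detail$id[detail$between & detail$scoreable == 0L]
  if (length(unscoreable))
    warning("intermediate individual(s) with no scoreable diagnostic locus, not flagged: ",
            paste(unscoreable, collapse = ", "))
  flagged <- detail$id[detail$between & detail$scoreable > 0L &
                         detail$mixed / pmax(detail$scoreable, 1L) >= mixed_threshold]
  list(ids = flagged, diagnostic_loci = diag_loci, detail = detail)
}

#' Stepwise lineage delineation
#'
#' Recursive, individual-based delineation of genetic lineages: encode the
#' current group of individuals ([encode_genotypes()], so imputation is
#' local to the group), ordinate ([pcoa_coords()]), test for a cluster split
#' ([detect_split()]), flag admixed individuals between the two largest
#' children ([flag_admixture()]), and recurse into each child until no split
#' is accepted.  No locality or other prior grouping enters the procedure.
#'
#' @param x an [allozyme_dataset()].
#' @param gap_factor,min_cluster,spread_factor passed to [detect_split()].
#' @param tau shared-allele tolerance used when deriving diagnostic loci for
#'   admixture flagging.
#' @param pin optional manual override: data frame with columns `id` and
#'   `lineage` (or a named character vector).  Pinned individuals keep the
#'   given label and are excluded from the clustering recursion.
#' @param keep_coords if `TRUE`, each step's ordination coordinates are kept
#'   in the provenance log (for plotting/export).
#' @return object of class `lineage_assignment`: a data frame-like
#'   `assignment` (`id`, `lineage`, `admixed`, `pinned`) plus a `provenance`
#'   list recording every ordination and split decision, and the parameters
#'   used.  Admixed individuals carry `lineage = NA` and `admixed = TRUE`.
#' @export
stepwise_delineate <- function(x, gap_factor = 3, min_cluster = 4,
                               spread_factor = 1.5, tau = 0.10,
                               pin = NULL, keep_coords = FALSE) {
  if (n_individuals(x) < 1L) stop("empty dataset")
  pins <- character(0)
  if (!is.null(pin)) {
    if (is.data.frame(pin)) pins <- stats::setNames(as.character(pin$lineage),
                                                    as.character(pin$id))
    else pins <- pin
    unknown <- setdiff(names(pins), x$individuals$id)
    if (length(unknown))
      stop("pinned id not in dataset: ", paste(unknown, collapse = ", "))
  }
  free_ids <- setdiff(x$individuals$id, names(pins))

  provenance <- list()
  leaves <- list()
  admixed_ids <- character(0)

  recurse <- function(ids, path) {
    sub <- subset_genotypes(x, individuals = ids)
    step <- list(group = path, n = length(ids))
    if (length(ids) >= 2L) {
      pc <- pcoa_coords(encode_genotypes(sub))
      dec <- detect_split(pc, gap_factor = gap_factor, min_cluster = min_cluster,
                          spread_factor = spread_factor)
      step$axes_percent <- pc$percent_contribution[seq_len(min(2L, length(pc$eigenvalues)))]
      step$accepted <- dec$accepted
      step$k <- dec$k
      step$gap_ratio <- dec$gap_ratio
      if (keep_coords) step$coordinates <- pc$coordinates
    } else {
      dec <- structure(list(accepted = FALSE, children = list()),
                       class = "split_decision")
      step$accepted <- FALSE
    }
    if (dec$accepted) {
      adm <- flag_admixture(sub, pc, dec, tau = tau, min_cluster = min_cluster)
      step$admixed <- adm$ids
      admixed_ids <<- c(admixed_ids, adm$ids)
      step$children_sizes <- lengths(dec$children)
      provenance[[length(provenance) + 1L]] <<- step
      for (ci in seq_along(dec$children)) {
        child <- setdiff(dec$children[[ci]], adm$ids)
        if (length(child))
          recurse(child, paste0(path, ".", ci))
      }
    } else {
      provenance[[length(provenance) + 1L]] <<- step
      leaves[[length(leaves) + 1L]] <<- list(path = path, ids = ids)
    }
  }
  if (length(free_ids)) recurse(free_ids, "root")

  assignment <- data.frame(id = x$individuals$id,
                           lineage = NA_character_,
                           admixed = FALSE, pinned = FALSE,
                           stringsAsFactors = FALSE)
  for (li in seq_along(leaves)) {
    assignment$lineage[assignment$id %in% leaves[[li]]$ids] <- paste0("L", li)
  }
  assignment$admixed[assignment$id %in% admixed_ids] <- TRUE
  assignment$lineage[assignment$admixed] <- NA_character_
  if (length(pins)) {
    idx <- match(names(pins), assignment$id)
    assignment$lineage[idx] <- unname(pins)
    assignment$pinned[idx] <- TRUE
    assignment$admixed[idx] <- FALSE
  }
  structure(list(assignment = assignment,
                 provenance = provenance,
                 leaves = lapply(leaves, `[[`, "path"),
                 params = list(gap_factor = gap_factor, min_cluster = min_cluster,
                               spread_factor = spread_factor, tau = tau)),
            class = "lineage_assignment")
}

#' @export
print.lineage_assignment <- function(x, ...) {
  tab <- table(x$assignment$lineage, useNA = "no")
  cat(sprintf("lineage_assignment: %d lineages over %d individuals (%d admixed)\n",
              length(tab), nrow(x$assignment), sum(x$assignment$admixed)))
  for (l in names(tab)) cat(sprintf("  %s: %d\n", l, tab[[l]]))
  invisible(x)
}

#' Extract the lineage labels as a named vector
#' @param x a `lineage_assignment`
#' @param drop_admixed drop admixed (unassigned) individuals (default TRUE)
#' @export
lineage_labels <- function(x, drop_admixed = TRUE) {
  a <- x$assignment
  if (drop_admixed) a <- a[!is.na(a$lineage), , drop = FALSE]
  stats::setNames(a$lineage, a$id)
}
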