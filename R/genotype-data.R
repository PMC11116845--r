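#' Codominant multi-locus genotype datasets
#'
#' An `allozyme_dataset` holds diploid codominant genotypes for a set of
#' individuals scored at a common panel of loci, together with site (and
#' optionally region) metadata.  Genotypes are unordered allele pairs;
#' `"a/b"` and `"b/a"` are the same observation.  Missing genotypes are
#' allowed and are represented by `NA` in both allele slots.
#'
#' Internally the two alleles of each genotype are stored in two character
#' matrices (`a1`, `a2`, individuals x loci) with `a1 <= a2` elementwise,
#' which makes the unordered-pair identity structural rather than something
#' every consumer has to re-normalise.
#'
#' @param individuals data frame with columns `id`, `site` and optionally
#'   `region`; one row per individual, `id` unique.
#' @param a1,a2 character matrices (individuals x loci) of allele labels,
#'   `NA` for missing genotypes.  Column names are the locus names.
#' @return An object of class `allozyme_dataset`.
#' @export
allozyme_dataset <- function(individuals, a1, a2) {
  stopifnot(is.data.frame(individuals), is.matrix(a1), is.matrix(a2))
  if (!all(c("id", "site") %in% names(individuals)))
    stop("`individuals` must have columns 'id' and 'site'")
  individuals$id <- as.character(individuals$id)
  individuals$site <- as.character(individuals$site)
  if (anyDuplicated(individuals$id))
    stop("duplicate individual id: ",
         paste(unique(individuals$id[duplicated(individuals$id)]), collapse = ", "))
  if (!identical(dim(a1), dim(a2)))
    stop("allele matrices must have identical dimensions")
  if (nrow(a1) != nrow(individuals))
    stop("allele matrices must have one row per individual")
  if (is.null(colnames(a1)) || anyDuplicated(colnames(a1)))
    stop("allele matrices must have unique locus column names")
  # missingness must agree between the two slots
  if (!identical(is.na(a1), is.na(a2)))
    stop("a genotype must be missing in both allele slots or neither")
  # enforce unordered-pair canonical form a1 <= a2
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]
    a1[swap] <- a2[swap]
    a2[swap] <- tmp
  }
  rownames(a1) <- rownames(a2) <- individuals$id
  structure(
    list(individuals = individuals, loci = colnames(a1), a1 = a1, a2 = a2),
    class = "allozyme_dataset"
  )
}

#' @export
print.allozyme_dataset <- function(x, ...) {
  n_missing <- sum(is.na(x$a1))
  cat(sprintf(
    "allozyme_dataset: %d individuals, %d sites, %d loci (%.1f%% missing genotypes)\n",
    nrow(x$individuals), length(unique(x$individuals$site)), length(x$loci),
    100 * n_missing / max(1L, length(x$a1))))
  invisible(x)
}

#' Number of individuals in a dataset
#' @param x an `allozyme_dataset`
#' @export
n_individuals <- function(x) nrow(x$individuals)

#' Observed allele universe per locus
#'
#' The sorted set of distinct allele labels observed at each locus, computed
#' from the genotypes actually present in `x` (so it shrinks automatically
#' when a dataset is subset).
#'
#' @param x an `allozyme_dataset`
#' @return named list of character vectors, one per locus.
#' @export
allele_universe <- function(x) {
  out <- lapply(seq_along(x$loci), function(j) {
    sort(unique(stats::na.omit(c(x$a1[, j], x$a2[, j]))))
  })
  names(out) <- x$loci
  out
}

parse_genotype_token <- function(token, row_label, locus) {
  token <- trimws(token)
  if (token == "" || is.na(token)) return(c(NA_character_, NA_character_))
  if (grepl("/", token, fixed = TRUE)) {
    parts <- strsplit(token, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2L || any(parts == ""))
      stop(sprintf("malformed genotype token '%s' at individual '%s', locus '%s'",
                   token, row_label, locus), call. = FALSE)
  } else if (nchar(token) == 2L) {
    parts <- c(substr(token, 1, 1), substr(token, 2, 2))
  } else {
    stop(sprintf("malformed genotype token '%s' at individual '%s', locus '%s'",
                 token, row_label, locus), call. = FALSE)
  }
  parts <- tolower(parts)
  if (any(!grepl("^[a-z0-9]+$", parts)))
    stop(sprintf("invalid allele label in token '%s' at individual '%s', locus '%s'",
                 token, row_label, locus), call. = FALSE)
  sort(parts)
}

#' Read a genotype table
#'
#' Reads a delimited text file with header
#' `individual,site[,region],locus1,...,locusL` and one row per individual.
#' Genotype tokens may be two single-character alleles run together
#' (`"ab"`, `"aa"`) or slash-separated (`"a/b"`, allowing multi-character
#' allele labels); an empty field is a missing genotype.  Allele labels are
#' case-normalised to lower case.  Anything else is rejected with an error
#' naming the individual and locus.
#'
#' @param path file path.
#' @param sep field separator; by default inferred from the extension
#'   (`.csv` comma, otherwise tab).
#' @return an [allozyme_dataset()].
#' @seealso [write_genotypes()] for the inverse; the written form uses the
#'   slash dialect and round-trips exactly.
#' @export
read_genotypes <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, colClasses = "character",
                           check.names = FALSE, na.strings = NULL,
                           stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  if (ncol(tab) < 3L) stop("genotype table needs id, site and at least one locus column")
  if (names(tab)[1] != "individual" || names(tab)[2] != "site")
    stop("genotype table header must start with 'individual,site'")
  has_region <- ncol(tab) >= 3L && names(tab)[3] == "region"
  meta_cols <- if (has_region) 3L else 2L
  loci <- names(tab)[(meta_cols + 1L):ncol(tab)]
  individuals <- data.frame(id = tab[[1]], site = tab[[2]],
                            stringsAsFactors = FALSE)
  if (has_region) individuals$region <- tab[[3]]
  n <- nrow(tab)
  a1 <- a2 <- matrix(NA_character_, n, length(loci), dimnames = list(NULL, loci))
  for (j in seq_along(loci)) {
    col <- tab[[meta_cols + j]]
    for (i in seq_len(n)) {
      al <- parse_genotype_token(col[i], individuals$id[i], loci[j])
      a1[i, j] <- al[1]
      a2[i, j] <- al[2]
    }
  }
  allozyme_dataset(individuals, a1, a2)
}

format_genotype_token <- function(x, y) {
  ifelse(is.na(x), "", paste0(x, "/", y))
}

#' Write a genotype table
#'
#' Writes the canonical dialect read by [read_genotypes()]: comma-separated,
#' slash-form genotypes with homozygotes written explicitly (`"a/a"`) and
#' missing genotypes as empty fields.  `write_genotypes(read_genotypes(f))`
#' is byte-identical for files already in this dialect.
#'
#' @param x an `allozyme_dataset`.
#' @param path output file path.
#' @export
write_genotypes <- function(x, path) {
  has_region <- "region" %in% names(x$individuals)
  header <- paste(c("individual", "site", if (has_region) "region", x$loci),
                  collapse = ",")
  body <- vapply(seq_len(n_individuals(x)), function(i) {
    toks <- format_genotype_token(x$a1[i, ], x$a2[i, ])
    paste(c(x$individuals$id[i], x$individuals$site[i],
            if (has_region) x$individuals$region[i], toks), collapse = ",")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Subset a genotype dataset
#'
#' Select individuals directly, by site, and/or a subset of loci.  Row
#' selectors are combined by intersection.  The allele universe of the
#' result reflects only the genotypes retained (see [allele_universe()]).
#'
#' @param x an `allozyme_dataset`.
#' @param individuals character vector of individual ids, or `NULL`.
#' @param sites character vector of site labels, or `NULL`.
#' @param loci character vector of locus names, or `NULL`.
#' @export
subset_genotypes <- function(x, individuals = NULL, sites = NULL, loci = NULL) {
  keep <- rep(TRUE, n_individuals(x))
  if (!is.null(individuals)) {
    unknown <- setdiff(individuals, x$individuals$id)
    if (length(unknown))
      stop("unknown individual id: ", paste(unknown, collapse = ", "))
    keep <- keep & x$individuals$id %in% individuals
  }
  if (!is.null(sites)) {
    unknown <- setdiff(sites, x$individuals$site)
    if (length(unknown))
      stop("unknown site: ", paste(unknown, collapse = ", "))
    keep <- keep & x$individuals$site %in% sites
  }
  cols <- x$loci
  if (!is.null(loci)) {
    unknown <- setdiff(loci, x$loci)
    if (length(unknown))
      stop("unknown locus: ", paste(unknown, collapse = ", "))
    cols <- x$loci[x$loci %in% loci]
  }
  if (!any(keep)) stop("empty individual selection")
  if (!length(cols)) stop("empty locus selection")
  allozyme_dataset(x$individuals[keep, , drop = FALSE],
                   x$a1[keep, cols, drop = FALSE],
                   x$a2[keep, cols, drop = FALSE])
}

#' Export to Genepop format
#'
#' Two-digit allele codes are assigned per locus in sorted label order
#' (`01`, `02`, ...); missing genotypes become `0000`.  Sites map to Genepop
#' `Pop` blocks, in order of first appearance.
#'
#' @param x an `allozyme_dataset`.
#' @param path output file path.
#' @param title first (comment) line of the file.
#' @export
write_genepop <- function(x, path, title = "cladelim genotype export") {
  universe <- allele_universe(x)
  codes <- lapply(universe, function(al) {
    stats::setNames(sprintf("%02d", seq_along(al)), al)
  })
  lines <- c(title, x$loci)
  for (s in unique(x$individuals$site)) {
    lines <- c(lines, "Pop")
    for (i in which(x$individuals$site == s)) {
      toks <- vapply(seq_along(x$loci), function(j) {
        if (is.na(x$a1[i, j])) return("0000")
        cd <- codes[[j]]
        paste0(cd[[x$a1[i, j]]], cd[[x$a2[i, j]]])
      }, character(1))
      lines <- c(lines, paste0(x$individuals$id[i], " ,  ",
                               paste(toks, collapse = " ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
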