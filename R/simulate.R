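#' Specify a synthetic lineage
#'
#' @param label lineage label.
#' @param n number of individuals to simulate.
#' @param freqs named list locus -> named numeric allele-frequency vector
#'   (each summing to 1).
#' @param missing_rate per-genotype missing probability in `[0, 1)`.
#' @param sites number of sites to spread individuals over (round-robin).
#' @return object of class `lineage_spec`.
#' @export
lineage_spec <- function(label, n, freqs, missing_rate = 0, sites = 1L) {
  stopifnot(n >= 1, missing_rate >= 0, missing_rate < 1, sites >= 1)
  for (l in names(freqs)) {
    if (abs(sum(freqs[[l]]) - 1) > 1e-9)
      stop("frequencies at locus '", l, "' of lineage '", label,
           "' do not sum to 1")
    if (is.null(names(freqs[[l]])))
      stop("frequencies at locus '", l, "' must be a named vector")
  }
  structure(list(label = label, n = as.integer(n), freqs = freqs,
                 missing_rate = missing_rate, sites = as.integer(sites)),
            class = "lineage_spec")
}

#' Assemble a simulation scenario
#'
#' Builds the per-locus allele-frequency vectors for `K` lineages with a
#' planted, checkable amount of differentiation:
#'
#' * For each lineage pair named in `diag_counts`, that many diagnostic
#'   loci are planted: one lineage fixed for allele `a`, the other fixed
#'   for `b`, and every other lineage polymorphic for both
#'   (`a` at `off_pair_freq`), so the locus is diagnostic for the named
#'   pair only.
#' * `shared_loci` further loci are polymorphic with identical frequencies
#'   (`a` at `shared_major_freq`) in every lineage, emulating the
#'   low-level shared polymorphism typical of conspecific allozyme data.
#'
#' @param labels lineage labels (length K).
#' @param n_per individuals per lineage (recycled).
#' @param diag_counts named integer vector of planted diagnostic-locus
#'   counts; names are `"A|B"` pairs of lineage labels.
#' @param shared_loci number of shared polymorphic loci.
#' @param missing_rate per-genotype missing probability.
#' @param sites_per_lineage sites per lineage.
#' @param admixed named integer vector of F1 counts per pair (`"A|B"`), or
#'   `NULL`.
#' @param off_pair_freq frequency of allele `a` in lineages outside a
#'   diagnostic pair (default 0.7, keeping both alleles common enough that
#'   a planted locus is essentially never mistaken as diagnostic for an
#'   unnamed pair in a finite sample).
#' @param shared_major_freq major-allele frequency at shared loci
#'   (default 0.9).
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(labels, n_per = 25, diag_counts = integer(0),
                            shared_loci = 20, missing_rate = 0,
                            sites_per_lineage = 1L, admixed = NULL,
                            off_pair_freq = 0.7, shared_major_freq = 0.9) {
  K <- length(labels)
  stopifnot(K >= 1, !anyDuplicated(labels))
  n_per <- rep_len(n_per, K)
  parse_pair <- function(nm) {
    p <- strsplit(nm, "|", fixed = TRUE)[[1]]
    if (length(p) != 2L || !all(p %in% labels) || p[1] == p[2])
      stop("bad lineage pair name: '", nm, "'")
    p
  }
  freqs <- lapply(labels, function(...) list())
  names(freqs) <- labels
  locus_truth <- list()
  idx <- 0L
  for (nm in names(diag_counts)) {
    pair <- parse_pair(nm)
    for (r in seq_len(diag_counts[[nm]])) {
      idx <- idx + 1L
      locus <- sprintf("D%02d_%s", idx, gsub("|", "x", nm, fixed = TRUE))
      for (lab in labels) {
        freqs[[lab]][[locus]] <-
          if (lab == pair[1]) c(a = 1)
          else if (lab == pair[2]) c(b = 1)
          else c(a = off_pair_freq, b = 1 - off_pair_freq)
      }
      locus_truth[[locus]] <- pair
    }
  }
  for (r in seq_len(shared_loci)) {
    locus <- sprintf("S%02d", r)
    for (lab in labels)
      freqs[[lab]][[locus]] <- c(a = shared_major_freq, b = 1 - shared_major_freq)
  }
  # config validation: a planted diagnostic locus must have disjoint allele
  # sets between its named pair
  for (locus in names(locus_truth)) {
    pair <- locus_truth[[locus]]
    sa <- names(freqs[[pair[1]]][[locus]])
    sb <- names(freqs[[pair[2]]][[locus]])
    if (length(intersect(sa, sb)))
      stop("planted diagnostic locus '", locus, "' shares alleles between ",
           pair[1], " and ", pair[2])
  }
  lineages <- lapply(seq_len(K), function(k) {
    lineage_spec(labels[k], n_per[k], freqs[[labels[k]]],
                 missing_rate = missing_rate, sites = sites_per_lineage)
  })
  if (!is.null(admixed)) for (nm in names(admixed)) parse_pair(nm)
  structure(list(lineages = lineages, labels = labels,
                 diag_counts = diag_counts, diagnostic_loci = locus_truth,
                 admixed = admixed),
            class = "scenario_config")
}

#' The default three-lineage study scenario
#'
#' Three lineages of 25 individuals (two sites each), 40 loci: 4, 6 and 8
#' planted diagnostic loci for the pairs L1|L2, L1|L3 and L2|L3, plus 22
#' shared polymorphic loci, with 5\% missing genotypes.
#'
#' @param ... overrides passed to [scenario_config()].
#' @export
default_scenario <- function(...) {
  args <- utils::modifyList(
    list(labels = c("L1", "L2", "L3"), n_per = 25,
         diag_counts = c("L1|L2" = 4L, "L1|L3" = 6L, "L2|L3" = 8L),
         shared_loci = 22, missing_rate = 0.05, sites_per_lineage = 2L),
    list(...))
  do.call(scenario_config, args)
}

draw_genotype <- function(freq) {
  sort(sample(names(freq), 2L, replace = TRUE, prob = freq))
}

#' Simulate a genotype dataset with known lineage structure
#'
#' Each individual's genotype at each locus is two independent allele draws
#' from its lineage's frequency vector (Hardy-Weinberg proportions), then
#' masked to missing with the lineage's missing rate.  Requested F1
#' admixed individuals draw one allele from each parental lineage at every
#' locus.  Fully deterministic given `seed`.
#'
#' @param config a [scenario_config()].
#' @param seed integer RNG seed (required, for reproducibility).
#' @return list with `dataset` (an [allozyme_dataset()]) and `truth`
#'   (data frame `id`, `lineage`, `admixed`).
#' @export
simulate_genotypes <- function(config, seed) {
  stopifnot(inherits(config, "scenario_config"))
  if (missing(seed)) stop("`seed` is required")
  set.seed(seed)
  loci <- names(config$lineages[[1]]$freqs)
  rows_meta <- list()
  g1 <- g2 <- list()
  truth <- list()
  for (spec in config$lineages) {
    for (i in seq_len(spec$n)) {
      id <- sprintf("%s_%03d", spec$label, i)
      site <- sprintf("%s_s%d", spec$label, ((i - 1L) %% spec$sites) + 1L)
      a1 <- a2 <- character(length(loci))
      for (j in seq_along(loci)) {
        al <- draw_genotype(spec$freqs[[loci[j]]])
        a1[j] <- al[1]; a2[j] <- al[2]
      }
      if (spec$missing_rate > 0) {
        mask <- stats::runif(length(loci)) < spec$missing_rate
        a1[mask] <- NA_character_; a2[mask] <- NA_character_
      }
      rows_meta[[id]] <- data.frame(id = id, site = site, stringsAsFactors = FALSE)
      g1[[id]] <- a1; g2[[id]] <- a2
      truth[[id]] <- data.frame(id = id, lineage = spec$label, admixed = FALSE,
                                stringsAsFactors = FALSE)
    }
  }
  if (!is.null(config$admixed)) {
    specs <- stats::setNames(config$lineages,
                             vapply(config$lineages, `[[`, character(1), "label"))
    for (nm in names(config$admixed)) {
      pair <- strsplit(nm, "|", fixed = TRUE)[[1]]
      for (i in seq_len(config$admixed[[nm]])) {
        id <- sprintf("F1_%sx%s_%02d", pair[1], pair[2], i)
        a1 <- a2 <- character(length(loci))
        for (j in seq_along(loci)) {
          fa <- specs[[pair[1]]]$freqs[[loci[j]]]
          fb <- specs[[pair[2]]]$freqs[[loci[j]]]
          al <- sort(c(sample(names(fa), 1L, prob = fa),
                       sample(names(fb), 1L, prob = fb)))
          a1[j] <- al[1]; a2[j] <- al[2]
        }
        rows_meta[[id]] <- data.frame(id = id, site = "admixed_zone",
                                      stringsAsFactors = FALSE)
        g1[[id]] <- a1; g2[[id]] <- a2
        truth[[id]] <- data.frame(id = id, lineage = NA_character_,
                                  admixed = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  meta <- do.call(rbind, rows_meta)
  rownames(meta) <- NULL
  m1 <- do.call(rbind, g1)
  m2 <- do.call(rbind, g2)
  colnames(m1) <- colnames(m2) <- loci
  list(dataset = allozyme_dataset(meta, m1, m2),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Simulate aligned sequences along a tree
#'
#' Jukes-Cantor evolution along a (newick or `phylo`) tree with branch
#' lengths in expected substitutions per site, starting from a root
#' sequence uniform over `{A, C, G, T}` (delegated to
#' [phangorn::simSeq()]).  Optionally, terminal runs of each sequence are
#' masked to `N` to emulate partial amplicons of varying length.
#'
#' @param tree a `phylo` object or newick string.
#' @param length number of sites.
#' @param seed integer RNG seed (required).
#' @param clades optional named vector leaf id -> clade label, returned
#'   alongside the alignment as ground truth.
#' @param seq_lengths optional integer vector (recycled over leaves): the
#'   retained contiguous length per sequence; the remainder, split between
#'   the two ends at random, is masked to `N`.
#' @return list with `alignment` (a [dna_alignment()]) and `clades`.
#' @export
simulate_sequences <- function(tree, length, seed, clades = NULL,
                               seq_lengths = NULL) {
  if (missing(seed)) stop("`seed` is required")
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"), length >= 1)
  set.seed(seed)
  sim <- phangorn::simSeq(tree, l = length, type = "DNA")
  m <- toupper(as.character(sim))
  aln <- unclass(dna_alignment(m))
  if (!is.null(seq_lengths)) {
    keep <- rep_len(as.integer(seq_lengths), nrow(aln))
    for (i in seq_len(nrow(aln))) {
      if (keep[i] >= ncol(aln)) next
      start <- sample.int(ncol(aln) - keep[i] + 1L, 1L)
      mask <- setdiff(seq_len(ncol(aln)), start:(start + keep[i] - 1L))
      aln[i, mask] <- "N"
    }
  }
  if (!is.null(clades)) {
    unknown <- setdiff(names(clades), rownames(aln))
    if (length(unknown))
      stop("clade label for unknown leaf: ", paste(unknown, collapse = ", "))
  }
  list(alignment = dna_alignment(aln), clades = clades)
}
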