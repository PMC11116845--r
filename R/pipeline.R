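#' Run the full delineation and divergence analysis
#'
#' Orchestrates the whole workflow over a genotype table and (optionally)
#' an aligned sequence set: stepwise lineage delineation, allele-frequency
#' tables, fixed-difference and Nei's D matrices over lineages, Nei's D
#' between sites with a neighbour-joining tree, and p-distance matrices
#' with among/within-clade range summaries.  Every artefact is written to
#' `out_dir` alongside the verbatim configuration and its hash, so two runs
#' with identical config and inputs produce byte-identical machine outputs.
#'
#' @param config a list (or path to a JSON file) with entries:
#'   `genotypes` (path to a genotype table, or an [allozyme_dataset()]);
#'   optional `alignment` (FASTA path or [dna_alignment()]); optional
#'   `clades` (CSV path with columns `id,clade`, or a named vector) and
#'   `excluded` (ids to drop from clade summaries); optional `pin`
#'   (assignment CSV path or data frame passed to [stepwise_delineate()]);
#'   parameters `gap_factor` (3), `min_cluster` (4), `tau` (0.10),
#'   `tolerance_mode` (`"max"`), `window` (`NULL` or `c(start, end)` for a
#'   pruned-alignment summary).
#' @param out_dir output directory (created if absent).
#' @return (invisibly) a list with the main in-memory results:
#'   `assignment`, `freq`, `matrices`, `site_nei_d`, `tree`, `p_matrix`,
#'   `summary`.
#' @export
run_full <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  defaults <- list(gap_factor = 3, min_cluster = 4, tau = 0.10,
                   tolerance_mode = "max", window = NULL)
  config <- utils::modifyList(defaults, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }

  # record the configuration verbatim, with a content hash for provenance
  cfg_json <- file.path(out_dir, "config.json")
  serialisable <- config[vapply(config, function(v)
    is.atomic(v) || is.null(v), logical(1))]
  jsonlite::write_json(serialisable, cfg_json, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  cfg_hash <- unname(tools::md5sum(cfg_json))

  ds <- stage("read_genotypes", {
    if (inherits(config$genotypes, "allozyme_dataset")) config$genotypes
    else read_genotypes(config$genotypes)
  })

  pin <- NULL
  if (!is.null(config$pin)) {
    pin <- if (is.character(config$pin))
      utils::read.csv(config$pin, stringsAsFactors = FALSE)
    else config$pin
  }

  assignment <- stage("delineate", stepwise_delineate(
    ds, gap_factor = config$gap_factor, min_cluster = config$min_cluster,
    tau = config$tau, pin = pin, keep_coords = TRUE))
  utils::write.csv(assignment$assignment,
                   file.path(out_dir, "assignment.csv"), row.names = FALSE)
  prov <- lapply(assignment$provenance, function(s) {
    if (!is.null(s$coordinates)) {
      utils::write.csv(
        data.frame(id = rownames(s$coordinates), s$coordinates,
                   check.names = FALSE),
        file.path(out_dir, sprintf("coords_%s.csv", s$group)),
        row.names = FALSE)
      s$coordinates <- NULL
    }
    s
  })
  jsonlite::write_json(list(config_hash = cfg_hash, steps = prov),
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  labels <- lineage_labels(assignment)
  n_lineages <- length(unique(labels))
  freq <- matrices <- NULL
  if (n_lineages >= 1L) {
    freq <- stage("allele_frequencies", allele_frequencies(ds, labels))
    freq_long <- do.call(rbind, lapply(freq$groups, function(g) {
      do.call(rbind, lapply(freq$loci, function(l) {
        x <- freq$freq[[g]][[l]]
        if (!length(x)) return(NULL)
        data.frame(group = g, locus = l, allele = names(x), freq = unname(x),
                   copies = freq$copies[g, l], stringsAsFactors = FALSE)
      }))
    }))
    utils::write.table(freq_long, file.path(out_dir, "allele_frequencies.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (n_lineages >= 2L) {
    matrices <- stage("pairwise_matrices", pairwise_matrices(
      freq, tau = config$tau, mode = config$tolerance_mode))
    write_dist_tsv(matrices$nei_d, file.path(out_dir, "nei_d_lineages.tsv"))
    utils::write.table(matrices$fixed,
                       file.path(out_dir, "fixed_differences.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    writeLines(c("Lower left triangle: fixed differences; upper right: Nei's unbiased D",
                 utils::capture.output(print(format_combined_table(matrices),
                                             quote = FALSE))),
               file.path(out_dir, "divergence_table.txt"))
  }

  site_nei_d <- tree <- NULL
  sites_of_assigned <- ds$individuals$site[ds$individuals$id %in% names(labels)]
  if (length(unique(sites_of_assigned)) >= 3L) {
    site_freq <- stage("site_frequencies", allele_frequencies(
      subset_genotypes(ds, individuals = names(labels)), "site"))
    site_nei_d <- stage("site_nei_d",
                        pairwise_matrices(site_freq, tau = config$tau)$nei_d)
    write_dist_tsv(site_nei_d, file.path(out_dir, "nei_d_sites.tsv"))
    if (all(is.finite(site_nei_d))) {
      tree <- stage("neighbor_joining", neighbor_joining(site_nei_d))
      write_newick(tree, path = file.path(out_dir, "nj_sites.nwk"))
      raw <- attr(tree, "raw_joins")
      jsonlite::write_json(raw, file.path(out_dir, "nj_raw_joins.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    }
  }

  p_matrix <- summary <- NULL
  if (!is.null(config$alignment)) {
    aln <- stage("read_alignment", {
      if (inherits(config$alignment, "dna_alignment")) config$alignment
      else read_alignment(config$alignment)
    })
    p_matrix <- stage("pairwise_p_matrix", pairwise_p_matrix(aln))
    write_dist_tsv(p_matrix, file.path(out_dir, "p_distance.tsv"))
    if (!is.null(config$clades)) {
      clades <- if (is.character(config$clades) && length(config$clades) == 1L &&
                    file.exists(config$clades))
        utils::read.csv(config$clades, stringsAsFactors = FALSE)
      else config$clades
      excluded <- if (is.null(config$excluded)) character(0) else config$excluded
      summary <- stage("clade_divergence_summary",
                       clade_divergence_summary(p_matrix, clades, excluded))
      utils::write.table(format_divergence_summary(summary),
                         file.path(out_dir, "pdist_summary.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA, na = "")
      if (!is.null(config$window)) {
        pruned <- stage("prune_alignment", prune_alignment(
          aln, config$window[1], config$window[2]))
        psum <- stage("pruned_summary", clade_divergence_summary(
          pairwise_p_matrix(pruned), clades, excluded))
        utils::write.table(format_divergence_summary(psum),
                           file.path(out_dir, "pdist_summary_pruned.tsv"),
                           sep = "\t", quote = FALSE, col.names = NA, na = "")
      }
    }
  }

  report <- c(
    "# Cryptic-lineage analysis report", "",
    sprintf("Config hash: %s", cfg_hash),
    sprintf("Individuals: %d; loci: %d", n_individuals(ds), length(ds$loci)),
    sprintf("Lineages delineated: %d (%d admixed individuals)",
            n_lineages, sum(assignment$assignment$admixed)), "")
  if (!is.null(matrices))
    report <- c(report, "## Diagnosability and Nei's D",
                utils::capture.output(print(matrices)), "")
  if (!is.null(tree))
    report <- c(report, "## NJ tree over sites (newick)",
                write_newick(tree), "")
  if (!is.null(summary))
    report <- c(report, "## p-distance clade summary",
                utils::capture.output(print(summary)), "")
  if (is.null(p_matrix))
    report <- c(report, "Sequence sections absent (no alignment supplied).")
  writeLines(report, file.path(out_dir, "report.md"))

  invisible(list(assignment = assignment, freq = freq, matrices = matrices,
                 site_nei_d = site_nei_d, tree = tree, p_matrix = p_matrix,
                 summary = summary, config_hash = cfg_hash))
}
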