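toy_fasta <- function(seqs) {
  f <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  writeLines(unlist(lapply(names(seqs), function(id) c(paste0(">", id), seqs[[id]]))), f)
  f
}

test_that("FASTA alignments are read, validated and sanitised", {
  f <- toy_fasta(c(s1 = "ACGTACGTAA", s2 = "ACGTNCGT-A"))
  aln <- read_alignment(f)
  expect_equal(dim(aln), c(2L, 10L))
  expect_equal(rownames(aln), c("s1", "s2"))

  # IUPAC ambiguity codes are recoded to N with a warning
  f2 <- toy_fasta(c(s1 = "ACGR", s2 = "ACGT"))
  expect_warning(aln2 <- read_alignment(f2), "recoded to N")
  expect_equal(unname(aln2["s1", 4]), "N")

  # ragged input names the offending record
  f3 <- toy_fasta(c(ok = "ACGT", short = "ACG"))
  expect_error(read_alignment(f3), "ragged alignment: record 'short'")
})

test_that("p-distance implements pairwise deletion, case-insensitively", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("ACGT", "AGGT"), 0.25)
  # N excluded pairwise: 3 compared sites, 1 different
  expect_equal(p_distance("ACNT", "ACGA"), 1 / 3)
  expect_equal(p_distance("acgt", "AGGT"), 0.25)
  expect_equal(p_distance("AC-T", "ACGT"), 0)
  expect_equal(p_distance("ACGT", "ACNT"), p_distance("ACNT", "ACGT"))
  expect_error(p_distance("NNNN", "ACGT"), "no comparable site")
  expect_error(p_distance("ACG", "ACGT"), "equal length")
})

test_that("an all-missing column changes no pairwise distance", {
  set.seed(47)
  m <- matrix(sample(c("A", "C", "G", "T"), 5 * 30, TRUE), 5,
              dimnames = list(paste0("s", 1:5), NULL))
  aln1 <- dna_alignment(m)
  aln2 <- dna_alignment(cbind(m, matrix("N", 5, 1)))
  expect_equal(unclass(pairwise_p_matrix(aln1)),
               unclass(pairwise_p_matrix(aln2))[, ],
               ignore_attr = TRUE)
})

test_that("the pairwise matrix equals a brute-force double loop", {
  set.seed(53)
  m <- matrix(sample(c("A", "C", "G", "T", "N", "-"), 20 * 60, TRUE,
                     prob = c(0.22, 0.22, 0.22, 0.22, 0.08, 0.04)), 20,
              dimnames = list(sprintf("q%02d", 1:20), NULL))
  aln <- dna_alignment(m)
  got <- pairwise_p_matrix(aln)
  expect_equal(got[, ], oracle_p_matrix(aln), tolerance = 1e-12,
               ignore_attr = TRUE)
  # three identical records give a zero matrix
  z <- dna_alignment(matrix("A", 3, 8, dimnames = list(letters[1:3], NULL)))
  expect_true(all(pairwise_p_matrix(z) == 0))
})

test_that("non-overlapping pairs are flagged as undefined, not errors", {
  aln <- dna_alignment(c(a = "AANNNN", b = "NNNNAA", c = "AAAAAA"))
  dm <- pairwise_p_matrix(aln)
  expect_true(is.na(dm["a", "b"]))
  expect_equal(dm["a", "c"], 0)
  expect_equal(attr(dm, "undefined_pairs")$id1, "a")
  expect_equal(attr(dm, "undefined_pairs")$id2, "b")
})

test_that("clade summaries report among/within ranges with exclusions", {
  # two clades of internally identical sequences differing at 5 of 100 sites
  base <- paste(rep("ACGT", 25), collapse = "")
  alt <- base
  substr(alt, 1, 5) <- "CGTAC"  # shifts each of the first five bases
  aln <- dna_alignment(c(a1 = base, a2 = base, b1 = alt, b2 = alt, solo = base))
  dm <- pairwise_p_matrix(aln)
  cl <- c(a1 = "north", a2 = "north", b1 = "south", b2 = "south",
          solo = "lonely")
  s <- clade_divergence_summary(dm, cl)
  expect_equal(s$min["north", "south"], 0.05)
  expect_equal(s$max["north", "south"], 0.05)
  expect_equal(s$min["north", "north"], 0)
  expect_equal(s$max["north", "north"], 0)
  # single-member clade: within range undefined
  expect_true(is.na(s$min["lonely", "lonely"]))
  fmt <- format_divergence_summary(s)
  expect_equal(fmt["south", "north"], "0.050")
  expect_equal(fmt["north", "north"], "0.000")
  pct <- format_divergence_summary(s, percent = TRUE)
  expect_equal(pct["south", "north"], "5.00")
  # exclusions drop individuals before summarising
  s2 <- clade_divergence_summary(dm, cl, excluded = c("b2", "solo"))
  expect_equal(unname(s2$n_pairs["north", "south"]), 2L)
  expect_false("lonely" %in% s2$clades)
  expect_error(clade_divergence_summary(dm, c(ghost = "north")),
               "absent from distance matrix")
})

test_that("pruning slices columns and commutes with the p-distance", {
  set.seed(59)
  m <- matrix(sample(c("A", "C", "G", "T", "N"), 4 * 50, TRUE), 4,
              dimnames = list(paste0("s", 1:4), NULL))
  aln <- dna_alignment(m)
  pr <- prune_alignment(aln, 11, 30)
  expect_equal(ncol(pr), 20)
  expect_equal(unclass(pr), unclass(aln)[, 11:30])
  expect_equal(unclass(prune_alignment(aln, 1, 50)), unclass(aln))
  # slice-then-distance equals distance restricted to the window
  expect_equal(pairwise_p_matrix(pr)[, ],
               oracle_p_matrix(dna_alignment(unclass(aln)[, 11:30])),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(prune_alignment(aln, 0, 10), "out of bounds")
  expect_error(prune_alignment(aln, 40, 60), "out of bounds")
})

test_that("star-tree simulations match the Jukes-Cantor expectation", {
  # 8 leaves at branch length d from a star: every pair is 2d apart, so the
  # expected p-distance is 0.75 * (1 - exp(-8d/3))
  d <- 0.05
  star <- ape::read.tree(text = paste0("(", paste0("t", 1:8, ":", d, collapse = ","), ");"))
  expected <- 0.75 * (1 - exp(-8 * d / 3))
  set.seed(61)
  means <- replicate(30, {
    sim <- simulate_sequences(star, length = 1000, seed = sample.int(1e6, 1))
    dm <- pairwise_p_matrix(sim$alignment)
    mean(dm[upper.tri(dm)])
  })
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - expected), 3 * se + 1e-4)
})
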