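test_that("allele frequencies count gene copies with missing genotypes excluded", {
  a1 <- cbind(L1 = c("a", "a"), L2 = c("a", NA))
  a2 <- cbind(L1 = c("a", "b"), L2 = c("b", NA))
  ds <- allozyme_dataset(data.frame(id = c("i1", "i2"), site = "s"), a1, a2)
  ft <- allele_frequencies(ds, c(i1 = "G", i2 = "G"))
  # a/a plus a/b: x_a = 0.75, x_b = 0.25, 2n = 4
  expect_equal(ft$freq$G$L1, c(a = 0.75, b = 0.25))
  expect_equal(unname(ft$copies["G", "L1"]), 4)
  # one individual missing at L2: 2 gene copies remain
  expect_equal(ft$freq$G$L2, c(a = 0.5, b = 0.5))
  expect_equal(unname(ft$copies["G", "L2"]), 2)
  expect_error(allele_frequencies(ds, c(i1 = "G", ghost = "H")),
               "unknown individual")
})

test_that("frequency estimates concentrate at large n", {
  cfg <- scenario_config("A", n_per = 500, shared_loci = 1,
                         shared_major_freq = 0.7)
  sim <- simulate_genotypes(cfg, seed = 13)
  ft <- allele_frequencies(sim$dataset,
                           setNames(rep("A", 500), sim$truth$id))
  expect_lt(abs(ft$freq$A$S01[["a"]] - 0.7), 0.05)
})

test_that("the tolerance rule classifies the documented cases", {
  tb <- make_freq_table(list(
    A = list(l1 = c(a = 1), l2 = c(a = 0.95, b = 0.05),
             l3 = c(a = 0.92, b = 0.08), l4 = c(a = 0.5, b = 0.5)),
    B = list(l1 = c(b = 1), l2 = c(b = 1),
             l3 = c(b = 0.06, c = 0.94), l4 = c(a = 0.5, b = 0.5))),
    copies = 40)
  fd0 <- count_fixed_differences(tb, "A", "B", tau = 0)
  # disjoint fixation is diagnostic at any tolerance
  expect_true(fd0$per_locus$diagnostic[fd0$per_locus$locus == "l1"])
  fd10 <- count_fixed_differences(tb, "A", "B", tau = 0.10)
  per <- fd10$per_locus
  expect_true(per$diagnostic[per$locus == "l1"])
  # shared allele b: S_A = 0.05 but S_B = 1.0 -> not diagnostic under max
  expect_false(per$diagnostic[per$locus == "l2"])
  expect_equal(per$S_A[per$locus == "l2"], 0.05)
  expect_equal(per$S_B[per$locus == "l2"], 1.0)
  # S_A = 0.08, S_B = 0.06, max <= 0.10 -> diagnostic
  expect_true(per$diagnostic[per$locus == "l3"])
  expect_equal(fd10$total, 2)
  # the pooled-budget mode rejects l3 (0.08 + 0.06 > 0.10)
  fds <- count_fixed_differences(tb, "A", "B", tau = 0.10, mode = "sum")
  expect_false(fds$per_locus$diagnostic[fds$per_locus$locus == "l3"])
  expect_error(count_fixed_differences(tb, "A", "Z"), "unknown group")
})

test_that("a locus undefined in either group is never diagnostic", {
  tb <- make_freq_table(list(A = list(l1 = c(a = 1)), B = list(l1 = c(b = 1))),
                        copies = 10)
  tb$freq$B$l1 <- numeric(0)
  tb$copies["B", "l1"] <- 0
  fd <- count_fixed_differences(tb, "A", "B", tau = 0)
  expect_true(is.na(fd$per_locus$diagnostic))
  expect_equal(fd$total, 0)
})

test_that("fixed-difference counts are monotone non-decreasing in tolerance", {
  set.seed(31)
  for (rep in 1:25) {
    tb <- random_freq_table()
    counts <- vapply(c(0, 0.05, 0.10, 0.20), function(tau)
      count_fixed_differences(tb, "A", "B", tau = tau)$total, numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("rare-allele pooling never lowers the diagnostic count", {
  # reassigning each group's rare alleles to its own majority allele can only
  # remove low-frequency sharing, so the diagnostic count may only grow
  merge_rare <- function(tb, cut = 0.05) {
    for (g in tb$groups) for (l in tb$loci) {
      x <- tb$freq[[g]][[l]]
      if (length(x) < 2) next
      major <- names(x)[which.max(x)]
      rare <- names(x)[x < cut & names(x) != major]
      if (length(rare)) {
        x[major] <- x[major] + sum(x[rare])
        x <- x[!names(x) %in% rare]
        tb$freq[[g]][[l]] <- x
      }
    }
    tb
  }
  set.seed(43)
  for (rep in 1:25) {
    tb <- random_freq_table(n_loci = 10, n_per_group = 20)
    n0 <- count_fixed_differences(tb, "A", "B", tau = 0.10)$total
    n1 <- count_fixed_differences(merge_rare(tb), "A", "B", tau = 0.10)$total
    expect_gte(n1, n0)
  }
})

test_that("delta_p reports the maximal per-locus frequency differential", {
  tb <- make_freq_table(list(
    A = list(l1 = c(a = 0.5, b = 0.5), l2 = c(a = 1)),
    B = list(l1 = c(a = 0.5, b = 0.5), l2 = c(a = 0.55, b = 0.45))),
    copies = 30)
  dp <- delta_p(tb, "A", "B")
  expect_equal(dp$delta_p[dp$locus == "l1"], 0)
  expect_equal(dp$delta_p[dp$locus == "l2"], 0.45)
  expect_true(dp$exceeds[dp$locus == "l2"])
  tb$freq$B$l1 <- numeric(0)
  tb$copies["B", "l1"] <- 0
  expect_warning(dp2 <- delta_p(tb, "A", "B"), "skipped: l1")
  expect_equal(dp2$locus, "l2")
})

test_that("Nei's D handles the identity, disjoint-fixation and clamp cases", {
  # identical monomorphic groups: I = 1, D = 0
  tb <- make_freq_table(list(A = list(l1 = c(a = 1)), B = list(l1 = c(a = 1))),
                        copies = 20)
  d <- nei_D(tb, "A", "B")
  expect_equal(d$I, 1)
  expect_equal(d$D, 0)

  # fixation for different alleles: Jxy = 0, D = +Inf
  tb2 <- make_freq_table(list(A = list(l1 = c(a = 1)), B = list(l1 = c(b = 1))),
                         copies = 20)
  expect_equal(nei_D(tb2, "A", "B")$D, Inf)

  # the unbiased-estimator overshoot: x = y = (.5, .5) at 2n = 20 gives
  # J_hat = 9/19, I = (1/2)/(9/19) = 19/18 > 1 -> clamped to D = 0 with a note
  tb3 <- make_freq_table(list(A = list(l1 = c(a = 0.5, b = 0.5)),
                              B = list(l1 = c(a = 0.5, b = 0.5))),
                         copies = 20)
  d3 <- nei_D(tb3, "A", "B")
  expect_equal(d3$per_locus$jx, 9 / 19)
  expect_equal(d3$I_raw, 19 / 18)
  expect_equal(d3$D, 0)
  expect_match(d3$note, "clamped")

  # without the correction, D of a group against itself is exactly 0
  expect_identical(nei_D(tb3, "A", "A", unbiased = FALSE)$D, 0)
  expect_error(nei_D(make_freq_table(
    list(A = list(l1 = c(a = 1)), B = list(l1 = c(a = 1))), copies = 1),
    "A", "B"), "no scoreable locus")
})

test_that("both statistics agree exactly with direct-loop oracles on random tables", {
  set.seed(57)
  for (rep in 1:100) {
    tb <- random_freq_table()
    tau <- sample(c(0, 0.05, 0.10, 0.20), 1)
    expect_identical(count_fixed_differences(tb, "A", "B", tau = tau)$total,
                     oracle_fixed_diff(tb, "A", "B", tau))
    d <- nei_D(tb, "A", "B")
    expect_equal(d$D, oracle_nei_d(tb, "A", "B"), tolerance = 1e-12)
    # symmetry
    expect_equal(d$D, nei_D(tb, "B", "A")$D, tolerance = 1e-12)
  }
})

test_that("pairwise matrices mirror planted structure and render as one table", {
  cfg <- scenario_config(c("A", "B", "C"), n_per = 20,
                         diag_counts = c("A|B" = 2L, "A|C" = 5L, "B|C" = 7L),
                         shared_loci = 10)
  sim <- simulate_genotypes(cfg, seed = 71)
  ft <- allele_frequencies(sim$dataset,
                           setNames(sim$truth$lineage, sim$truth$id))
  m <- pairwise_matrices(ft, tau = 0)
  expect_equal(m$fixed["A", "B"], 2L)
  expect_equal(m$fixed["A", "C"], 5L)
  expect_equal(m$fixed["B", "C"], 7L)
  expect_equal(m$fixed, t(m$fixed))
  expect_equal(m$nei_d, t(m$nei_d))
  tab <- format_combined_table(m)
  expect_equal(tab["B (20)", "A"], "2")                # lower: counts
  expect_match(tab["A (20)", "B"], "^[0-9]+\\.[0-9]{2}$")  # upper: D, 2 dp
  # two identical groups: no fixed differences, D ~ 0
  ids <- sim$truth$id[sim$truth$lineage == "A"]
  half <- setNames(rep(c("A1", "A2"), length.out = length(ids)), ids)
  m0 <- pairwise_matrices(allele_frequencies(sim$dataset, half), tau = 0.10)
  expect_equal(m0$fixed["A1", "A2"], 0L)
  expect_lt(m0$nei_d["A1", "A2"], 0.02)
})
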