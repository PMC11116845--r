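test_that("dosage encoding follows the codominant definition and imputes subset means", {
  a1 <- rbind(c("a"), c("a"), c("a"), c(NA))
  a2 <- rbind(c("a"), c("b"), c("b"), c(NA))
  colnames(a1) <- colnames(a2) <- "L1"
  extra1 <- matrix("a", 4, 1, dimnames = list(NULL, "L2"))  # keeps row 4 scoreable
  ds <- allozyme_dataset(
    data.frame(id = paste0("i", 1:4), site = "s1"),
    cbind(a1, extra1), cbind(a2, extra1))
  m <- encode_genotypes(ds)
  # homozygote a/a -> (a:1, b:0); heterozygote a/b -> (0.5, 0.5)
  expect_equal(unname(m[1, c("L1.a", "L1.b")]), c(1, 0))
  expect_equal(unname(m[2, c("L1.a", "L1.b")]), c(0.5, 0.5))
  # non-missing dosages sum to 1 across the locus
  expect_equal(unname(rowSums(m[1:3, c("L1.a", "L1.b")])), rep(1, 3))
  # missing cell imputed with the observed column mean: mean(0, .5, .5) = 1/3
  expect_equal(unname(m[4, "L1.b"]), mean(c(0, 0.5, 0.5)))
  expect_true(attr(m, "imputed")[4, "L1.b"])
  # a fully monomorphic column is retained
  expect_true("L2.a" %in% colnames(m))
})

test_that("an imputed dosage equals the stated observed mean", {
  # column where allele a has observed mean dosage mean(.5, .5, 0, 0) = 0.25
  a1 <- cbind(L1 = c("a", "a", "b", "b", NA), L2 = rep("a", 5))
  a2 <- cbind(L1 = c("b", "b", "b", "b", NA), L2 = rep("a", 5))
  ds <- allozyme_dataset(data.frame(id = paste0("i", 1:5), site = "s"), a1, a2)
  m <- encode_genotypes(ds)
  expect_equal(unname(m[5, "L1.a"]), 0.25)
})

test_that("encoding rejects an individual scored at no locus", {
  a1 <- cbind(L1 = c("a", NA))
  ds <- allozyme_dataset(data.frame(id = c("ok", "ghost"), site = "s"), a1, a1)
  expect_error(encode_genotypes(ds), "ghost")
})

test_that("three equidistant points yield two equal axes at 50% each", {
  d <- matrix(1, 3, 3) - diag(3)
  dimnames(d) <- list(letters[1:3], letters[1:3])
  pc <- pcoa_coords(stats::as.dist(d))
  expect_length(pc$eigenvalues, 2)
  expect_equal(pc$eigenvalues[1], pc$eigenvalues[2], tolerance = 1e-9)
  expect_equal(pc$percent_contribution, c(50, 50), tolerance = 1e-9)
})

test_that("pcoa reproduces distances, matches the brute-force oracle, and conserves variance", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    x <- matrix(rnorm(n * sample(2:5, 1)), n)
    rownames(x) <- paste0("p", seq_len(n))
    pc <- pcoa_coords(x)
    # recovered pairwise distances match the input exactly (Euclidean input)
    expect_lt(max(abs(dist(pc$coordinates) - dist(x))), 1e-9)
    # coordinates equal the independent double-centering oracle up to sign
    o <- brute_pcoa(as.matrix(dist(x)))
    expect_equal(pc$eigenvalues, o$eigenvalues, tolerance = 1e-9)
    expect_lt(max(abs(pc$coordinates - flip_signs(o$coordinates))), 1e-7)
    # conservation of variance: positive eigenvalues sum to total centred SS
    xc <- scale(x, scale = FALSE)
    expect_equal(sum(pc$eigenvalues), sum(xc^2), tolerance = 1e-9)
  }
})

test_that("pcoa is deterministic and degenerate input yields zero axes", {
  set.seed(3)
  x <- matrix(rnorm(30), 10)
  rownames(x) <- paste0("p", 1:10)
  expect_identical(pcoa_coords(x), pcoa_coords(x))
  xx <- matrix(1, 5, 3, dimnames = list(paste0("p", 1:5), NULL))
  pc <- pcoa_coords(xx)
  expect_length(pc$eigenvalues, 0)
  expect_equal(ncol(pc$coordinates), 0)
})

test_that("detect_split separates well-spaced clusters and rejects panmixia", {
  set.seed(21)
  # two clusters separated by 10x the within-cluster spread
  x <- rbind(matrix(rnorm(40, 0, 0.5), 20),
             matrix(rnorm(40, 10, 0.5), 20))
  rownames(x) <- sprintf("i%02d", 1:40)
  dec <- detect_split(pcoa_coords(x))
  expect_true(dec$accepted)
  expect_length(dec$children, 2)
  truth <- rep(1:2, each = 20)
  got <- rep(NA_integer_, 40)
  for (k in 1:2) got[match(dec$children[[k]], rownames(x))] <- k
  expect_equal(mclust::adjustedRandIndex(truth, got), 1)

  # one panmictic cloud: no split
  y <- matrix(rnorm(80), 40)
  rownames(y) <- sprintf("i%02d", 1:40)
  expect_false(detect_split(pcoa_coords(y))$accepted)

  # children below the minimum size block acceptance
  z <- rbind(matrix(rnorm(6, 0, 0.3), 3), matrix(rnorm(74, 10, 0.3), 37))
  rownames(z) <- sprintf("i%02d", 1:40)
  expect_false(detect_split(pcoa_coords(z), min_cluster = 4)$accepted)
})

test_that("stepwise delineation recovers planted lineages and nested structure", {
  # two lineages, five fully diagnostic loci
  cfg2 <- scenario_config(c("A", "B"), n_per = 20,
                          diag_counts = c("A|B" = 5L), shared_loci = 10)
  sim <- simulate_genotypes(cfg2, seed = 101)
  asg <- stepwise_delineate(sim$dataset)
  labs <- lineage_labels(asg)
  expect_equal(length(unique(labs)), 2)
  truth <- setNames(sim$truth$lineage, sim$truth$id)
  expect_equal(mclust::adjustedRandIndex(labs, truth[names(labs)]), 1)

  # a single panmictic lineage stays one cluster
  cfg1 <- scenario_config("A", n_per = 20, shared_loci = 15)
  sim1 <- simulate_genotypes(cfg1, seed = 5)
  expect_equal(length(unique(lineage_labels(stepwise_delineate(sim1$dataset)))), 1)

  # nested structure: deep split, then a shallower split on one side
  cfg3 <- scenario_config(c("A", "B", "C"), n_per = 20,
                          diag_counts = c("A|B" = 12L, "A|C" = 12L, "B|C" = 4L),
                          shared_loci = 12)
  sim3 <- simulate_genotypes(cfg3, seed = 77)
  asg3 <- stepwise_delineate(sim3$dataset)
  labs3 <- lineage_labels(asg3)
  expect_equal(length(unique(labs3)), 3)
  truth3 <- setNames(sim3$truth$lineage, sim3$truth$id)
  expect_equal(mclust::adjustedRandIndex(labs3, truth3[names(labs3)]), 1)
  # provenance logs every ordination step
  expect_gte(length(asg3$provenance), 3)
  expect_true(all(vapply(asg3$provenance, function(s) is.character(s$group),
                         logical(1))))
})

test_that("same input and seed reproduce the assignment bit-identically", {
  cfg <- default_scenario()
  s1 <- simulate_genotypes(cfg, seed = 9)
  s2 <- simulate_genotypes(cfg, seed = 9)
  expect_identical(s1, s2)
  expect_identical(stepwise_delineate(s1$dataset), stepwise_delineate(s2$dataset))
})

test_that("planted F1 individuals are flagged as admixed, pure ones are not", {
  cfg <- scenario_config(c("A", "B"), n_per = 20,
                         diag_counts = c("A|B" = 6L), shared_loci = 12,
                         admixed = c("A|B" = 2L))
  sim <- simulate_genotypes(cfg, seed = 303)
  asg <- stepwise_delineate(sim$dataset)
  f1 <- sim$truth$id[sim$truth$admixed]
  expect_setequal(asg$assignment$id[asg$assignment$admixed], f1)
  # pure individuals keep their lineages, perfectly
  labs <- lineage_labels(asg)
  truth <- setNames(sim$truth$lineage, sim$truth$id)
  pure <- names(labs)[!names(labs) %in% f1]
  expect_equal(mclust::adjustedRandIndex(labs[pure], truth[pure]), 1)
})

test_that("an F1 with every diagnostic locus missing is warned about, not flagged", {
  cfg <- scenario_config(c("A", "B"), n_per = 20,
                         diag_counts = c("A|B" = 6L), shared_loci = 12,
                         admixed = c("A|B" = 1L))
  sim <- simulate_genotypes(cfg, seed = 404)
  ds <- sim$dataset
  f1 <- sim$truth$id[sim$truth$admixed]
  diag_loci <- names(cfg$diagnostic_loci)
  i <- match(f1, ds$individuals$id)
  ds$a1[i, diag_loci] <- NA
  ds$a2[i, diag_loci] <- NA
  expect_warning(asg <- stepwise_delineate(ds), "no scoreable diagnostic locus")
  expect_false(asg$assignment$admixed[asg$assignment$id == f1])
})

test_that("pinned assignments override clustering and are excluded from it", {
  cfg <- scenario_config(c("A", "B"), n_per = 15,
                         diag_counts = c("A|B" = 5L), shared_loci = 10)
  sim <- simulate_genotypes(cfg, seed = 55)
  pin <- data.frame(id = sim$truth$id[1:3], lineage = "pinned_here")
  asg <- stepwise_delineate(sim$dataset, pin = pin)
  a <- asg$assignment
  expect_equal(a$lineage[match(pin$id, a$id)], rep("pinned_here", 3))
  expect_true(all(a$pinned[match(pin$id, a$id)]))
  # the rest are still delineated into the two lineages
  expect_equal(length(unique(a$lineage[!a$pinned])), 2)
})
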