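test_that("Haldane's mapping function and its inverse are consistent", {
  r <- c(0, 0.05, 0.25, 0.49)
  expect_equal(haldane_inv(haldane(r)), r, tolerance = 1e-12)
  expect_equal(haldane(0.25), -50 * log(0.5))   # 34.657 cM
  expect_equal(haldane(0), 0)
  expect_error(haldane(0.5), "0.5")
  expect_error(haldane_inv(-1), "nonnegative")
  # distances are superadditive under independence: d(r12) of the composite
  # fraction r12 = r1(1-r2) + r2(1-r1) equals d(r1) + d(r2)
  r1 <- 0.1; r2 <- 0.2
  r12 <- r1 * (1 - r2) + r2 * (1 - r1)
  expect_equal(haldane(r12), haldane(r1) + haldane(r2), tolerance = 1e-12)
})

test_that("the linkage LOD is maximal at zero recombinants and falls to 0 at r = 1/2", {
  expect_equal(lod_score(0, 200), 200 * log10(2))   # ~60.2
  expect_equal(lod_score(100, 200), 0)
  lods <- lod_score(0:99, 200)
  expect_true(all(diff(lods) < 0))
})

test_that("doubled-haploid gametes recombine at Haldane's rate", {
  genome <- sim_genome(11, 100)
  pop <- simulate_dh(genome, seq_len(11), pop_size = 4000, seed = 99)
  g <- pop$genotypes
  expect_equal(dim(g), c(4000L, 11L))
  expect_true(all(g %in% c(0L, 1L)))
  # terminal pair: 100 cM apart -> r = (1 - e^-2)/2 = 0.432
  r_far <- mean(g[, 1] != g[, 11])
  expect_lt(abs(r_far - haldane_inv(100)), 3 * sqrt(0.25 / 4000) + 0.005)
  # adjacent pair: 10 cM -> r = 0.0906
  r_near <- mean(g[, 1] != g[, 2])
  se <- sqrt(haldane_inv(10) * (1 - haldane_inv(10)) / 4000)
  expect_lt(abs(r_near - haldane_inv(10)), 4 * se)
  # phase is random, so allele frequencies are near 1/2
  expect_lt(abs(mean(g) - 0.5), 0.05)
})

test_that("weighted least squares recovers positions from exact distances", {
  pos <- c(0, 2, 5, 5.5, 11)
  pairs <- t(combn(5, 2))
  d <- pos[pairs[, 2]] - pos[pairs[, 1]]
  x <- dagmap:::.wls_positions(pairs[, 1], pairs[, 2], d,
                               w = rep(1, nrow(pairs)), m = 5)
  expect_equal(x, pos, tolerance = 1e-10)
  # disconnected loci are reported, not silently misplaced
  expect_error(dagmap:::.wls_positions(1L, 2L, 1, w = 1, m = 3),
               "do not connect")
})

test_that("estimate_map bins co-segregating markers and recovers pair distances", {
  genome <- sim_genome(2, 20)
  pop <- simulate_dh(genome, 1:2, pop_size = 500, seed = 123)
  M <- estimate_map(pop, genome)
  k <- sum(pop$genotypes[, 1] != pop$genotypes[, 2])
  # positions are stored at 1e-6 cM precision, so compare at that scale
  expect_equal(map_length(M), haldane(k / 500), tolerance = 1e-6)

  # markers at identical true positions have zero recombinants only in
  # expectation; but identical genotype columns must land in one bin
  pop2 <- pop
  pop2$genotypes <- cbind(pop$genotypes[, 1], pop$genotypes[, 1],
                          pop$genotypes[, 2])
  pop2$polymorphic <- 1:3
  genome3 <- sim_genome(3, 20)
  M2 <- estimate_map(pop2, genome3)
  pos <- marker_positions(M2)
  expect_equal(pos[[1]], pos[[2]])
  expect_length(M2$bins, 2L)
})

test_that("estimated maps are deterministic, anchored, and ordered", {
  genome <- sim_genome(200, 100)
  design <- cross_design(n_crosses = 2)
  s1 <- simulate_linkage_maps(genome, design, seed = 5)
  s2 <- simulate_linkage_maps(genome, design, seed = 5)
  expect_identical(s1$maps, s2$maps)
  for (M in s1$maps) {
    expect_equal(M$positions[1], 0)
    expect_true(all(diff(M$positions) > 0))
    # estimated marker order equals the true order (positions were fit
    # with the physical order fixed)
    idx <- match(map_markers(M), genome$markers)
    expect_true(all(diff(idx) > 0))
  }
  # about 30% of markers segregate per cross
  frac <- length(map_markers(s1$maps[[1]])) / 200
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 200))
})

test_that("map accuracy is translation-invariant and zero for the truth", {
  genome <- sim_genome(50, 100)
  idx <- seq(2, 50, by = 3)
  truth <- consensus_map(as.list(genome$markers[idx]),
                         genome$positions[idx] - genome$positions[idx][1])
  expect_equal(map_accuracy(truth, genome), 0, tolerance = 1e-10)
  # a uniform shift is removed by the best-fit translation
  sh <- truth; sh$positions <- sh$positions + 7
  expect_equal(map_accuracy(sh, genome), 0, tolerance = 1e-10)
  expect_error(map_accuracy(consensus_map(list("zz"), 0), genome),
               "absent from the genome")
  # L2 dominates L1 for any error pattern
  noisy <- truth
  set.seed(1); noisy$positions <- sort(noisy$positions + rnorm(length(idx)))
  noisy$positions <- noisy$positions - noisy$positions[1]
  expect_gte(map_accuracy(noisy, genome, "L2"),
             map_accuracy(noisy, genome, "L1"))
})

test_that("study replicates are reproducible and correctly summarized", {
  st1 <- run_consensus_study(g_values = 2, reps = 2, seed = 77,
                             n_markers = 60, genome_length = 30)
  st2 <- run_consensus_study(g_values = 2, reps = 2, seed = 77,
                             n_markers = 60, genome_length = 30)
  num <- setdiff(names(st1$replicates), "seconds")  # wall time jitters
  expect_identical(st1$replicates[num], st2$replicates[num])
  expect_s3_class(st1, "sim_study")
  # summary means equal the replicate means
  cell <- study_cell(st1, 2, "QP", "rmse")
  rows <- st1$replicates
  v <- rows$rmse[rows$method == "QP"]
  expect_equal(cell$mean, mean(v))
  expect_equal(cell$se, sd(v) / sqrt(2))
  expect_equal(cell$n, 2L)
  # LP and QP are computed on the same replicate's maps: same marker count
  expect_equal(rows$n_markers[rows$method == "LP"],
               rows$n_markers[rows$method == "QP"])
})
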