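test_that("build_system reindexes vertices topologically with one row per edge", {
  maps <- random_map_set(n_markers = 15, n_maps = 3, seed = 1)
  G <- merge_linkage_maps(maps)
  S <- build_system(G)
  expect_equal(S$n, n_vertices(G))
  expect_equal(S$p, nrow(G$edges))
  expect_equal(S$r, nrow(zero_edges(G)))
  expect_equal(nrow(S$C), S$p + S$r)
  # every directed row points forward in the column (topological) order
  At <- as(S$A, "TsparseMatrix")
  for (row in unique(At@i)) {
    cols <- At@j[At@i == row] + 1L
    sgn <- At@x[At@i == row]
    expect_true(cols[sgn > 0] > cols[sgn < 0])
  }
  # the columns' marker sets partition the graph's markers
  expect_setequal(unlist(S$markers, use.names = FALSE), G$markers)
  expect_equal(sum(lengths(S$markers)), length(G$markers))
})

test_that("least-squares linearization averages parallel interval estimates", {
  # two maps disagree on one interval: 2 cM vs 4 cM, equal weight -> 3 cM
  m1 <- linkage_map(c("a", "b"), c(0, 2), map_id = "m1")
  m2 <- linkage_map(c("a", "b"), c(0, 4), map_id = "m2")
  S <- build_system(merge_linkage_maps(list(m1, m2)))
  sol <- solve_qp(S)
  expect_equal(sol$x, c(0, 3), tolerance = 1e-8)
  expect_equal(sol$objective, 2, tolerance = 1e-8)

  # weighted: weights 3 and 1 -> weighted mean 2.5
  Sw <- toy_system(2, c(1, 1), c(2, 2), d = c(2, 4), q = c(3, 1))
  solw <- solve_qp(Sw)
  expect_equal(solw$x, c(0, 2.5), tolerance = 1e-8)
  expect_equal(solw$objective, 3 * 0.25 + 1 * 2.25, tolerance = 1e-8)
})

test_that("least-absolute-deviation linearization finds the weighted median", {
  # unweighted: median of {2, 4, 9} is 4, objective |2-4| + |9-4| = 7
  S <- toy_system(2, c(1, 1, 1), c(2, 2, 2), d = c(2, 4, 9), q = c(1, 1, 1))
  sol <- solve_lp(S)
  expect_equal(sol$x[2], 4, tolerance = 1e-6)
  expect_equal(sol$objective, 7, tolerance = 1e-6)
  # weight 3 on the 9 cM estimate moves the weighted median to 9
  Sw <- toy_system(2, c(1, 1, 1), c(2, 2, 2), d = c(2, 4, 9), q = c(1, 1, 3))
  solw <- solve_lp(Sw)
  expect_equal(solw$x[2], 9, tolerance = 1e-6)
  expect_equal(solw$objective, 12, tolerance = 1e-6)
})

test_that("LP objective matches exhaustive breakpoint search on chain systems", {
  for (seed in 1:12) {
    chain <- random_chain_maps(n_vertices = sample(3:7, 1L), seed = 500 + seed)
    S <- build_system(merge_linkage_maps(chain$maps))
    sol <- solve_lp(S)
    want <- sum(vapply(chain$gap_lengths, function(d)
      l1_gap_optimum(d, rep(1, length(d))), numeric(1)))
    expect_equal(sol$objective, want, tolerance = 1e-6)
  }
})

test_that("quadratic-program solutions satisfy the KKT conditions", {
  for (seed in 1:8) {
    maps <- random_map_set(n_markers = 20, n_maps = 4, seed = 600 + seed)
    S <- build_system(merge_linkage_maps(maps))
    sol <- solve_qp(S)
    kkt <- kkt_residuals(sol)
    expect_lt(kkt$stationarity, 1e-6)
    expect_gt(kkt$feasibility, -1e-8)
    expect_gt(kkt$min_multiplier, -1e-8)
    expect_lt(kkt$comp_slack, 1e-6)
  }
})

test_that("both linearizations honor every order constraint exactly", {
  for (seed in 1:8) {
    maps <- random_map_set(n_markers = 15, n_maps = 3, seed = 700 + seed)
    S <- build_system(merge_linkage_maps(maps))
    for (sol in list(solve_qp(S), solve_lp(S))) {
      expect_gte(min(as.numeric(S$A %*% sol$x)), -1e-8)
      expect_equal(min(sol$x), 0)
    }
  }
})

test_that("a single map is reproduced with zero objective by both methods", {
  M <- linkage_map(sprintf("m%d", 1:8), c(0, 0, 1.5, 4, 4, 4, 9, 12.5))
  S <- build_system(merge_linkage_maps(list(M)))
  for (sol in list(solve_qp(S), solve_lp(S))) {
    expect_equal(sol$objective, 0, tolerance = 1e-8)
    cm <- rescale(sol, list(M))
    expect_equal(marker_positions(cm)[map_markers(M)],
                 marker_positions(M)[map_markers(M)], tolerance = 1e-6)
    expect_equal(map_error(cm, list(M)), 0, tolerance = 1e-6)
  }
})

test_that("rescaling restores the mean linkage-map length", {
  maps <- random_map_set(n_markers = 15, n_maps = 3, seed = 900)
  sol <- solve_qp(build_system(merge_linkage_maps(maps)))
  cm <- rescale(sol, maps)
  expect_equal(map_length(cm),
               mean(vapply(maps, map_length, numeric(1))), tolerance = 1e-8)
  cm_raw <- rescale(sol, maps, enabled = FALSE)
  expect_equal(cm_raw$scale_factor, 1)
  expect_equal(map_length(cm_raw), max(sol$x), tolerance = 1e-10)
})

test_that("map_error measures same-bin and adjacent-bin deviations", {
  M <- linkage_map(c("a", "b", "c"), c(0, 0, 4), map_id = "m")
  # consensus separates a and b by 1 cM and compresses the interval to 3 cM
  cm <- consensus_map(list("a", "b", "c"), c(0, 1, 3))
  # pairs: (a,b) same-bin |1-0|; adjacent (a,c) |3-4|, (b,c) |2-4|
  expect_equal(map_error(cm, list(M), norm = "L1"), (1 + 1 + 2) / 3)
  expect_equal(map_error(cm, list(M), norm = "L2"), sqrt((1 + 1 + 4) / 3))
  expect_equal(map_error(cm, list(M), norm = "L1", denominator = "intervals"),
               (1 + 3) / 2)
  expect_error(map_error(consensus_map(list("a"), 0), list(M)),
               "absent from the consensus")
})

test_that("linearize_maps runs the full pipeline and attaches the solution", {
  maps <- random_map_set(n_markers = 12, n_maps = 3, seed = 901)
  cm <- linearize_maps(maps, method = "QP")
  expect_s3_class(cm, "consensus_map")
  expect_setequal(map_markers(cm), unique(unlist(lapply(maps, map_markers))))
  sol <- attr(cm, "solution")
  expect_s3_class(sol, "map_solution")
  expect_equal(sol$method, "QP")
  # the consensus respects every map's bin order
  pos <- marker_positions(cm)
  for (M in maps) {
    mp <- marker_positions(M)
    for (i in seq_along(mp)) for (j in seq_along(mp))
      if (mp[i] < mp[j])
        expect_lte(pos[names(mp)[i]], pos[names(mp)[j]] + 1e-8)
  }
})
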