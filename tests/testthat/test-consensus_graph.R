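test_that("a single map becomes an unbranched chain with product weights", {
  M <- linkage_map(c("a", "b", "c", "d"), c(0, 0, 2, 5), map_id = "m1")
  G <- graph_from_map(M)
  expect_equal(n_vertices(G), 3L)
  expect_equal(unname(vertex_markers(G)),
               list(c("a", "b"), "c", "d"))
  e <- G$edges[order(G$edges$length), ]
  expect_equal(e$length, c(2, 3))
  # first interval: bin sizes 2 x 1, second: 1 x 1
  expect_equal(e$weight, c(2, 1))
  # one zero-length pair inside the co-located bin
  ze <- zero_edges(G)
  expect_equal(nrow(G$zero), 1L)
  expect_equal(nrow(ze), 0L)   # co-resident pairs carry no information
})

test_that("merging a map into itself changes neither bins nor order", {
  M <- linkage_map(sprintf("m%d", 1:6), c(0, 0, 1, 3, 3, 7))
  G1 <- graph_from_map(M)
  G2 <- merge(G1, M)
  expect_equal(vertex_markers(G2), vertex_markers(G1))
  expect_equal(pair_keys(marker_order_pairs(G2)),
               pair_keys(marker_order_pairs(G1)))
})

test_that("after merging a map, every vertex is inside one of its bins or disjoint from it", {
  for (seed in 1:25) {
    maps <- random_map_set(n_markers = 20, n_maps = 3, seed = seed)
    G <- merge_linkage_maps(maps)
    last <- maps[[length(maps)]]
    for (vm in vertex_markers(G)) {
      inside <- vapply(last$bins, function(b) all(vm %in% b), logical(1))
      disjoint <- !any(vm %in% map_markers(last))
      expect_true(any(inside) || disjoint)
    }
  }
})

test_that("per-map edge weight totals equal the product of bin sizes per interval", {
  for (seed in 1:15) {
    maps <- random_map_set(n_markers = 15, n_maps = 3, seed = 100 + seed)
    G <- merge_linkage_maps(maps)
    for (M in maps) {
      em <- G$edges[G$edges$map == M$map_id, ]
      got <- as.numeric(tapply(em$weight, signif(em$length, 10), sum))
      sizes <- lengths(M$bins)
      want <- sizes[-length(sizes)] * sizes[-1L]
      lens <- diff(M$positions)
      want <- as.numeric(tapply(want, signif(lens, 10), sum))
      expect_equal(got, want)
    }
  }
})

test_that("strongly connected components agree with an independent graph library", {
  set.seed(42)
  for (case in 1:30) {
    n <- sample(4:15, 1L)
    m <- sample(3:(3 * n), 1L)
    tl <- sample.int(n, m, replace = TRUE)
    hd <- sample.int(n, m, replace = TRUE)
    keep <- tl != hd
    tl <- tl[keep]; hd <- hd[keep]
    if (!length(tl)) next
    G <- toy_digraph(n, tl, hd)
    got <- strongly_connected_components(G)
    ig <- igraph::graph_from_edgelist(cbind(tl, hd), directed = TRUE)
    ig <- igraph::add_vertices(ig, max(0L, n - igraph::vcount(ig)))
    want <- igraph::components(ig, mode = "strong")$membership
    # same partition: two vertices share a component iff the oracle says so
    got_id <- integer(n)
    for (k in seq_along(got)) got_id[got[[k]]] <- k
    expect_equal(outer(got_id, got_id, "=="), outer(want, want, "=="))
  }
})

test_that("assert_acyclic returns a topological order and flags cycles", {
  set.seed(7)
  for (case in 1:20) {
    n <- sample(5:20, 1L)
    # random DAG: edges only forward in a hidden permutation
    perm <- sample.int(n)
    m <- sample(n:(3 * n), 1L)
    a <- sample.int(n, m, replace = TRUE)
    b <- sample.int(n, m, replace = TRUE)
    keep <- perm[a] < perm[b]
    if (!any(keep)) next
    G <- toy_digraph(n, a[keep], b[keep])
    topo <- assert_acyclic(G)
    expect_setequal(topo, seq_len(n))
    rank <- match(seq_len(n), topo)
    expect_true(all(rank[a[keep]] < rank[b[keep]]))
  }
  # a two-vertex cycle raises the structured conflict condition
  Gc <- toy_digraph(3, c(1, 2, 2), c(2, 1, 3))
  err <- tryCatch(assert_acyclic(Gc), dagmap_conflict = function(c) c)
  expect_s3_class(err, "dagmap_conflict")
  expect_length(err$components, 1L)
  expect_setequal(err$components[[1L]], c(1L, 2L))
})

test_that("two maps with opposite marker order produce an ordering conflict", {
  m1 <- linkage_map(c("a", "b"), c(0, 2), map_id = "m1")
  m2 <- linkage_map(c("b", "a"), c(0, 2), map_id = "m2")
  G <- merge_linkage_maps(list(m1, m2))
  expect_error(assert_acyclic(G), class = "dagmap_conflict")
  expect_error(merge_linkage_maps(list(
    m1, linkage_map("z", 0, map_id = "m3", group_id = "2"))),
    "different linkage groups")
})

test_that("conflict DOT export marks the offending component", {
  m1 <- linkage_map(c("a", "b", "c"), c(0, 2, 4), map_id = "m1")
  m2 <- linkage_map(c("c", "b", "d"), c(0, 2, 4), map_id = "m2")
  G <- merge_linkage_maps(list(m1, m2))
  comps <- strongly_connected_components(G)
  expect_true(any(lengths(comps) > 1L))
  dot <- export_dot(G, mode = "conflicts")
  expect_match(paste(dot, collapse = "\n"), "digraph")
  expect_match(paste(dot, collapse = "\n"), "\\bb\\b")
})
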