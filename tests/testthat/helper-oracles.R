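# Independent oracles and generators shared across the test files.  All of
# these deliberately avoid the package's graph machinery: precedence closures
# are computed by dense boolean matrix squaring, linear-program optima by
# exhaustive breakpoint search, so they can certify the production code.

# A random conflict-free set of linkage maps: markers are drawn from one
# fixed true order and each map's positions are nondecreasing in that order,
# so no two maps can ever disagree on direction.  Zero gaps create
# multi-marker bins.
random_map_set <- function(n_markers, n_maps, seed) {
  set.seed(seed)
  markers <- sprintf("mk%03d", seq_len(n_markers))
  lapply(seq_len(n_maps), function(k) {
    sz <- sample(2:n_markers, 1L)
    idx <- sort(sample.int(n_markers, sz))
    gaps <- ifelse(stats::runif(sz - 1L) < 0.35, 0,
                   round(stats::runif(sz - 1L, 0.5, 10), 2))
    linkage_map(markers[idx], cumsum(c(0, gaps)), map_id = paste0("m", k))
  })
}

# Marker-level precedence closure of a set of maps: the union of "a is in an
# earlier bin than b" over all maps, transitively closed by repeated boolean
# matrix squaring.  Returned as sorted "from\rto" keys.
closure_pairs <- function(maps) {
  markers <- sort(unique(unlist(lapply(maps, map_markers))))
  n <- length(markers)
  R <- matrix(FALSE, n, n, dimnames = list(markers, markers))
  for (M in maps) {
    nb <- length(M$bins)
    if (nb < 2L) next
    for (i in seq_len(nb - 1L))
      for (j in (i + 1L):nb)
        R[M$bins[[i]], M$bins[[j]]] <- TRUE
  }
  repeat {
    R2 <- R | ((R %*% R) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  idx <- which(R, arr.ind = TRUE)
  sort(paste(markers[idx[, 1L]], markers[idx[, 2L]], sep = "\r"))
}

pair_keys <- function(df) sort(paste(df$from, df$to, sep = "\r"))

# A consensus graph with prescribed vertices and directed edges (one marker
# per vertex), for exercising the graph algorithms on arbitrary digraphs,
# including cyclic ones the merge could never produce on valid input.
toy_digraph <- function(n, tail, head) {
  structure(list(
    markers = sprintf("v%d", seq_len(n)),
    vertex  = seq_len(n),
    next_id = n + 1L,
    edges = data.frame(tail = as.integer(tail), head = as.integer(head),
                       length = rep(1, length(tail)),
                       weight = rep(1, length(tail)),
                       map = rep("toy", length(tail)),
                       stringsAsFactors = FALSE),
    zero = data.frame(a = character(0), b = character(0),
                      weight = numeric(0), map = character(0),
                      stringsAsFactors = FALSE),
    maps = "toy", group_id = "1"), class = "consensus_graph")
}

# A linear system built directly from incidence rows: directed rows
# (tail -> head, target length d, weight q) and zero-length rows.
toy_system <- function(n, tail, head, d, q,
                       ztail = integer(0), zhead = integer(0),
                       zq = numeric(0)) {
  inc <- function(ti, hi) {
    m <- length(ti)
    Matrix::sparseMatrix(i = rep(seq_len(m), 2L), j = c(ti, hi),
                         x = c(rep(-1, m), rep(1, m)), dims = c(m, n))
  }
  A <- inc(tail, head)
  B <- inc(ztail, zhead)
  structure(list(A = A, B = B, C = rbind(A, B),
                 d = c(d, rep(0, length(ztail))),
                 q = c(q, zq),
                 n = n, p = length(tail), r = length(ztail),
                 vertex_ids = seq_len(n),
                 markers = as.list(sprintf("v%d", seq_len(n))),
                 group_id = "1"),
            class = "linear_system")
}

# Exhaustive-breakpoint optimum of min_t sum_k w_k |t - d_k| over t >= 0:
# some breakpoint (or 0) is always optimal for a piecewise-linear convex
# objective.
l1_gap_optimum <- function(d, w) {
  cand <- unique(c(0, d[d >= 0]))
  min(vapply(cand, function(t) sum(w * abs(t - d)), numeric(1)))
}

# Maps describing a path a1 -> a2 -> ... with several independent two-marker
# maps per gap, so the weighted-L1 linearization decomposes exactly into one
# scalar problem per gap (the oracle above).
random_chain_maps <- function(n_vertices, seed) {
  set.seed(seed)
  markers <- sprintf("c%02d", seq_len(n_vertices))
  maps <- list()
  d <- list()
  for (i in seq_len(n_vertices - 1L)) {
    k <- sample(1:3, 1L)
    d[[i]] <- round(stats::runif(k, 0, 8), 2)
    for (e in seq_len(k))
      maps[[length(maps) + 1L]] <- linkage_map(
        markers[c(i, i + 1L)], c(0, d[[i]][e]),
        map_id = sprintf("gap%d_%d", i, e))
  }
  list(maps = maps, gap_lengths = d)
}
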