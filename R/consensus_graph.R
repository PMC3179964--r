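# Building the consensus graph: sequential merge of linkage maps, zero-length
# (co-bin) edge bookkeeping, cycle detection via two depth-first searches.
#
# Representation: markers live in a flat character vector with a parallel
# integer vector giving each marker's vertex id.  Vertex ids are allocated
# from a counter and never reused, so a "vertex" is simply the set of markers
# currently carrying its id.  Directed edges reference vertex ids; zero-length
# edges reference marker names and are resolved to vertices lazily (a vertex
# split can therefore never strand a zero-length edge on a stale id).

new_consensus_graph <- function(group_id = NA_character_) {
  structure(list(
    markers = character(0),
    vertex  = integer(0),
    next_id = 1L,
    edges = data.frame(tail = integer(0), head = integer(0),
                       length = numeric(0), weight = numeric(0),
                       map = character(0), stringsAsFactors = FALSE),
    zero = data.frame(a = character(0), b = character(0),
                      weight = numeric(0), map = character(0),
                      stringsAsFactors = FALSE),
    maps = character(0),
    group_id = group_id),
    class = "consensus_graph")
}

#' Vertex ids of a consensus graph
#' @param G a `consensus_graph`.
#' @return sorted integer vector of vertex ids.
#' @export
vertex_ids <- function(G) sort(unique(G$vertex))

#' Marker sets per vertex
#' @param G a `consensus_graph`.
#' @return named list: vertex id (as character) -> character vector of markers.
#' @export
vertex_markers <- function(G) {
  sp <- split(G$markers, G$vertex)
  sp[order(as.integer(names(sp)))]
}

#' Number of vertices
#' @param G a `consensus_graph`.
#' @export
n_vertices <- function(G) length(unique(G$vertex))

#' Zero-length edges resolved to vertices
#'
#' Co-binned marker pairs are stored by marker name; this accessor resolves
#' them to the current vertices and drops pairs whose two markers reside in
#' the same vertex (such pairs contribute exactly zero error to the
#' linearization and carry no information).
#'
#' @param G a `consensus_graph`.
#' @return data.frame with columns `u`, `v` (vertex ids, u < v), `weight`,
#'   `map`.
#' @export
zero_edges <- function(G) {
  if (nrow(G$zero) == 0L)
    return(data.frame(u = integer(0), v = integer(0), weight = numeric(0),
                      map = character(0), stringsAsFactors = FALSE))
  va <- G$vertex[match(G$zero$a, G$markers)]
  vb <- G$vertex[match(G$zero$b, G$markers)]
  keep <- va != vb
  data.frame(u = pmin(va, vb)[keep], v = pmax(va, vb)[keep],
             weight = G$zero$weight[keep], map = G$zero$map[keep],
             stringsAsFactors = FALSE)
}

#' @export
print.consensus_graph <- function(x, ...) {
  cat(sprintf(
    "Consensus graph (group %s): %d markers, %d vertices, %d directed edges, %d zero-length pairs; maps: %s\n",
    x$group_id, length(x$markers), n_vertices(x), nrow(x$edges),
    nrow(x$zero), paste(x$maps, collapse = ", ")))
  invisible(x)
}

#' Convert a single linkage map into an unbranched consensus graph
#'
#' Each bin becomes one vertex; each interval between adjacent bins becomes a
#' directed edge whose length is the interval distance and whose weight is
#' the product of the two bin sizes; every unordered pair of co-binned
#' markers is recorded as a zero-length edge of weight 1.
#'
#' @param M a [linkage_map()].
#' @return a `consensus_graph`.
#' @export
graph_from_map <- function(M) {
  stopifnot(inherits(M, "linkage_map"))
  merge(new_consensus_graph(M$group_id), M)
}

#' Merge a linkage map into a consensus graph
#'
#' Implements the sequential merge: for each bin `v` of the map in order,
#' every graph vertex `w` sharing markers with `v` is kept intact when all
#' its markers lie in `v`, and otherwise split into the shared part and the
#' remainder, with every directed edge in or out of `w` replicated for both
#' parts.  Markers of `v` new to the graph form one new vertex.  After all
#' bins are placed, a directed edge is added for every map interval, from
#' each vertex holding markers of the proximal bin to each vertex holding
#' markers of the distal bin.  Each edge stands for all marker pairs of its
#' map interval that its endpoints hold, so its weight is the product of the
#' two endpoint vertex sizes; weights are recomputed after every merge
#' because later splits refine the endpoints (the per-interval weight total
#' is always the product of the interval's bin sizes).  Co-binned marker
#' pairs are recorded as zero-length edges (which carry no ordinal meaning).
#'
#' Cycles are *not* detected here; use [assert_acyclic()].
#'
#' @param x a `consensus_graph` (possibly empty).
#' @param y a [linkage_map()] from the same linkage group.
#' @param ... unused.
#' @return the merged `consensus_graph`.
#' @export
merge.consensus_graph <- function(x, y, ...) {
  G <- x; M <- y
  stopifnot(inherits(M, "linkage_map"))
  if (is.na(G$group_id)) G$group_id <- M$group_id
  if (!identical(G$group_id, M$group_id))
    stop("cannot merge map of group '", M$group_id,
         "' into a graph for group '", G$group_id, "'")

  nb <- length(M$bins)
  # -- phase 1: place every bin's markers, splitting vertices as needed
  for (b in seq_len(nb)) {
    bm <- M$bins[[b]]
    idx <- match(bm, G$markers)
    present <- !is.na(idx)
    if (any(present)) {
      for (w in unique(G$vertex[idx[present]])) {
        members <- which(G$vertex == w)
        inbin <- G$markers[members] %in% bm
        if (!all(inbin)) {
          w1 <- G$next_id; G$next_id <- G$next_id + 1L
          G$vertex[members[inbin]] <- w1
          # replicate all directed edges of w for the split-off part w1
          et <- G$edges$tail == w
          eh <- G$edges$head == w
          if (any(et | eh)) {
            rep1 <- G$edges[et | eh, , drop = FALSE]
            rep1$tail[rep1$tail == w] <- w1
            rep1$head[rep1$head == w] <- w1
            G$edges <- rbind(G$edges, rep1)
          }
        }
      }
    }
    newm <- bm[!present]
    if (length(newm)) {
      id <- G$next_id; G$next_id <- G$next_id + 1L
      G$markers <- c(G$markers, newm)
      G$vertex <- c(G$vertex, rep(id, length(newm)))
    }
  }

  # -- phase 2: interval edges between consecutive bins (post-split vertices)
  if (nb >= 2L) {
    vert_of <- function(mk) G$vertex[match(mk, G$markers)]
    cnt_head <- table(vert_of(M$bins[[1L]]))
    add <- vector("list", nb - 1L)
    for (b in seq_len(nb - 1L)) {
      cnt_tail <- cnt_head
      cnt_head <- table(vert_of(M$bins[[b + 1L]]))
      len <- M$positions[b + 1L] - M$positions[b]
      tl <- as.integer(names(cnt_tail)); hd <- as.integer(names(cnt_head))
      add[[b]] <- data.frame(
        tail = rep(tl, times = length(hd)),
        head = rep(hd, each = length(tl)),
        length = len,
        weight = as.numeric(outer(as.vector(cnt_tail), as.vector(cnt_head))),
        map = M$map_id, stringsAsFactors = FALSE)
    }
    G$edges <- rbind(G$edges, do.call(rbind, add))
  }

  # -- zero-length edges: one per unordered co-binned marker pair
  zi <- Filter(function(b) length(b) >= 2L, M$bins)
  if (length(zi)) {
    zp <- do.call(rbind, lapply(zi, function(bm) {
      cb <- utils::combn(sort(bm), 2L)
      data.frame(a = cb[1L, ], b = cb[2L, ], weight = 1,
                 map = M$map_id, stringsAsFactors = FALSE)
    }))
    G$zero <- rbind(G$zero, zp)
  }

  G$maps <- c(G$maps, M$map_id)
  rownames(G$edges) <- NULL
  # every edge endpoint stays contained in the map bin it came from (vertices
  # only ever refine), so the number of marker pairs an edge stands for is
  # always the product of its endpoints' current sizes; recompute after the
  # splits above so the objective weights stay exact
  if (nrow(G$edges)) {
    sz <- table(G$vertex)
    G$edges$weight <- as.numeric(sz[as.character(G$edges$tail)]) *
      as.numeric(sz[as.character(G$edges$head)])
  }
  G
}

#' Merge a sequence of linkage maps into one consensus graph
#'
#' Sequential left fold: the first two maps are merged, the result is merged
#' with the third, and so on.  Any merge order yields a graph with the same
#' marker-level transitive closure.
#'
#' @param maps list of [linkage_map()] objects sharing one `group_id`.
#' @param verbose log vertex/edge counts after each merge (default FALSE).
#' @return a `consensus_graph`.
#' @export
merge_linkage_maps <- function(maps, verbose = FALSE) {
  stopifnot(length(maps) >= 1L)
  grp <- unique(vapply(maps, function(m) m$group_id, character(1)))
  if (length(grp) > 1L)
    stop("maps belong to different linkage groups: ",
         paste(grp, collapse = ", "))
  G <- new_consensus_graph(grp)
  for (M in maps) {
    G <- merge(G, M)
    if (verbose)
      message(sprintf("merged %-8s -> %d vertices, %d directed edges, %d zero pairs",
                      M$map_id, n_vertices(G), nrow(G$edges), nrow(G$zero)))
  }
  G
}

# adjacency lists over unique directed vertex pairs; neighbours sorted
# ascending for reproducible traversal order
.adjacency <- function(ids, tail, head, reverse = FALSE) {
  if (reverse) { tmp <- tail; tail <- head; head <- tmp }
  key <- !duplicated(paste(tail, head))
  tail <- tail[key]; head <- head[key]
  adj <- rep(list(integer(0)), length(ids))
  names(adj) <- as.character(ids)
  if (length(tail)) {
    sp <- split(head, tail)
    sp <- lapply(sp, sort)
    adj[names(sp)] <- sp
  }
  adj
}

# iterative DFS over all vertices (ascending id order), returning the
# vertices in increasing finish time
.dfs_finish <- function(ids, adj) {
  n <- length(ids)
  index <- stats::setNames(seq_len(n), as.character(ids))
  visited <- logical(n)
  finish <- integer(0)
  for (s in seq_len(n)) {
    if (visited[s]) next
    stack_v <- s; stack_i <- 0L; top <- 1L
    visited[s] <- TRUE
    while (top > 0L) {
      v <- stack_v[top]
      nb <- index[as.character(adj[[v]])]
      i <- stack_i[top] + 1L
      advanced <- FALSE
      while (i <= length(nb)) {
        w <- nb[[i]]
        if (!visited[w]) {
          stack_i[top] <- i
          top <- top + 1L
          stack_v[top] <- w; stack_i[top] <- 0L
          visited[w] <- TRUE
          advanced <- TRUE
          break
        }
        i <- i + 1L
      }
      if (!advanced) {
        if (i > length(nb)) {
          finish <- c(finish, v)
          top <- top - 1L
        }
      }
    }
  }
  ids[finish]
}

# DFS collecting one tree per start, starts taken in the given order
.dfs_components <- function(ids, adj, order_ids) {
  index <- stats::setNames(seq_along(ids), as.character(ids))
  visited <- logical(length(ids))
  comps <- list()
  for (s in order_ids) {
    si <- index[[as.character(s)]]
    if (visited[si]) next
    comp <- integer(0)
    stack <- si; visited[si] <- TRUE
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      comp <- c(comp, v)
      nb <- index[as.character(adj[[v]])]
      nb <- nb[!visited[nb]]
      if (length(nb)) { visited[nb] <- TRUE; stack <- c(stack, nb) }
    }
    comps[[length(comps) + 1L]] <- sort(ids[comp])
  }
  comps
}

#' Strongly connected components of the consensus graph
#'
#' Two-pass depth-first search: a DFS of the reverse graph produces the
#' vertices in increasing finish time; a DFS of the forward graph, seeded in
#' decreasing finish time, then yields one tree per strongly connected
#' component.  Zero-length edges are ignored (they are not part of the
#' topology).  A non-singleton component is an ordering conflict between the
#' merged linkage maps.
#'
#' @param G a `consensus_graph`.
#' @return list of integer vectors (vertex ids), one per component.
#' @export
strongly_connected_components <- function(G) {
  ids <- vertex_ids(G)
  if (!length(ids)) return(list())
  adjR <- .adjacency(ids, G$edges$tail, G$edges$head, reverse = TRUE)
  adjF <- .adjacency(ids, G$edges$tail, G$edges$head, reverse = FALSE)
  fin <- .dfs_finish(ids, adjR)            # increasing finish time on G^R
  .dfs_components(ids, adjF, rev(fin))     # forward DFS in decreasing finish
}

#' Assert that a consensus graph is acyclic and return a topological order
#'
#' If every strongly connected component is a singleton the graph is a DAG
#' and the increasing finish-time order of the reverse-graph depth-first
#' search is returned (a valid topological order of the forward graph).
#' Otherwise an error of class `dagmap_conflict` is raised whose condition
#' carries the offending components (field `components`), ready for
#' [export_dot()] with `mode = "conflicts"`.
#'
#' @param G a `consensus_graph`.
#' @return integer vector of vertex ids in topological order.
#' @export
assert_acyclic <- function(G) {
  ids <- vertex_ids(G)
  if (!length(ids)) return(integer(0))
  adjR <- .adjacency(ids, G$edges$tail, G$edges$head, reverse = TRUE)
  fin <- .dfs_finish(ids, adjR)
  adjF <- .adjacency(ids, G$edges$tail, G$edges$head, reverse = FALSE)
  comps <- .dfs_components(ids, adjF, rev(fin))
  bad <- comps[lengths(comps) > 1L]
  if (length(bad)) {
    vm <- vertex_markers(G)
    msg <- sprintf(
      "ordering conflict: %d strongly connected component(s) with >1 vertex (e.g. markers %s)",
      length(bad), paste(utils::head(unlist(vm[as.character(bad[[1L]])]), 6L),
                         collapse = ", "))
    cond <- structure(class = c("dagmap_conflict", "error", "condition"),
                      list(message = msg, call = sys.call(-1),
                           components = bad))
    stop(cond)
  }
  fin
}

#' Marker-level reachability of a consensus graph
#'
#' For tests and reporting: the set of ordered marker pairs (a, b) such that
#' there is a directed path from a's vertex to b's vertex.
#'
#' @param G a `consensus_graph` (need not be acyclic; pairs inside a cycle
#'   appear in both directions).
#' @return data.frame with character columns `from`, `to`.
#' @export
marker_order_pairs <- function(G) {
  ids <- vertex_ids(G)
  n <- length(ids)
  if (n == 0L) return(data.frame(from = character(0), to = character(0)))
  reach <- .reach_matrix(ids, G$edges$tail, G$edges$head)
  vm <- vertex_markers(G)
  out <- list()
  for (i in seq_len(n)) {
    js <- which(reach[i, ])
    if (!length(js)) next
    fr <- vm[[as.character(ids[i])]]
    to <- unlist(vm[as.character(ids[js])], use.names = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      from = rep(fr, times = length(to)), to = rep(to, each = length(fr)),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(from = character(0), to = character(0)))
  do.call(rbind, out)
}

# boolean reachability matrix (strict: diagonal FALSE unless on a cycle),
# computed by breadth-first expansion of the adjacency matrix
.reach_matrix <- function(ids, tail, head) {
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  if (length(tail)) {
    ti <- match(tail, ids); hi <- match(head, ids)
    A[cbind(ti, hi)] <- TRUE
  }
  R <- A
  repeat {                       # closure by repeated squaring
    R2 <- R | (R %*% R > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R
}

#' Export a consensus graph as Graphviz DOT text
#'
#' `mode = "full"` renders every vertex (labelled with its markers) and every
#' directed edge labelled with its length in cM; zero-length edges are drawn
#' dashed and undirected.  `mode = "conflicts"` renders only the non-singleton
#' strongly connected components, one cluster each, for manual curation of
#' ordering conflicts.
#'
#' @param G a `consensus_graph` (or, via its method, an `ordinal_graph`).
#' @param mode `"full"` or `"conflicts"`.
#' @param file optional path; when given the DOT text is also written there.
#' @param ... unused.
#' @return DOT text as a single character string (invisibly when `file` is
#'   given).
#' @export
export_dot <- function(G, mode = c("full", "conflicts"), file = NULL, ...) {
  UseMethod("export_dot")
}

.dot_label <- function(markers) paste(markers, collapse = "\\n")

.dot_write <- function(lines, file) {
  txt <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' @export
export_dot.consensus_graph <- function(G, mode = c("full", "conflicts"),
                                       file = NULL, ...) {
  mode <- match.arg(mode)
  vm <- vertex_markers(G)
  node_line <- function(id)
    sprintf("  v%s [label=\"%s\"];", id, .dot_label(vm[[as.character(id)]]))
  lines <- c(sprintf("digraph consensus {"),
             "  node [shape=box];")
  if (mode == "full") {
    lines <- c(lines, vapply(vertex_ids(G), node_line, character(1)))
    if (nrow(G$edges))
      lines <- c(lines, sprintf("  v%d -> v%d [label=\"%.4g\"];",
                                G$edges$tail, G$edges$head, G$edges$length))
    ze <- zero_edges(G)
    if (nrow(ze))
      lines <- c(lines, sprintf(
        "  v%d -> v%d [style=dashed, dir=none, constraint=false];",
        ze$u, ze$v))
  } else {
    comps <- strongly_connected_components(G)
    comps <- comps[lengths(comps) > 1L]
    for (k in seq_along(comps)) {
      cc <- comps[[k]]
      lines <- c(lines, sprintf("  subgraph cluster_%d {", k),
                 paste0("  ", vapply(cc, node_line, character(1))))
      keep <- G$edges$tail %in% cc & G$edges$head %in% cc
      if (any(keep)) {
        e <- unique(G$edges[keep, c("tail", "head")])
        lines <- c(lines, sprintf("    v%d -> v%d;", e$tail, e$head))
      }
      lines <- c(lines, "  }")
    }
  }
  .dot_write(c(lines, "}"), file)
}
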