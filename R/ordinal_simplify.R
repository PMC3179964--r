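# Simplification of an acyclic consensus graph to the minimal ordinally
# equivalent DAG: transitive edge reduction followed by coalescing of
# vertices with identical neighbourhoods.

new_ordinal_graph <- function(vertices, edges, group_id = NA_character_) {
  structure(list(vertices = vertices,   # named list: id -> markers
                 edges = edges,         # data.frame(tail, head), unweighted
                 group_id = group_id),
            class = "ordinal_graph")
}

#' @export
print.ordinal_graph <- function(x, ...) {
  cat(sprintf("Ordinal consensus graph: %d vertices, %d edges\n",
              length(x$vertices), nrow(x$edges)))
  invisible(x)
}

#' Reachable vertex sets of an acyclic consensus graph
#'
#' Processes the vertices in reverse topological order, so each vertex's
#' reachable set is its direct successors united with their (already
#' computed) reachable sets.  The set for a vertex excludes the vertex
#' itself.
#'
#' @param G an acyclic `consensus_graph`.
#' @param topo optional topological order (from [assert_acyclic()]); computed
#'   when missing.  A cyclic graph raises the conflict error.
#' @return named list: vertex id (character) -> integer vector of reachable
#'   vertex ids.
#' @export
descendant_sets <- function(G, topo = NULL) {
  if (is.null(topo)) topo <- assert_acyclic(G)
  ids <- vertex_ids(G)
  R <- .descendants_matrix(ids, topo, G$edges$tail, G$edges$head)
  out <- lapply(seq_along(ids), function(i) ids[R[i, ]])
  names(out) <- as.character(ids)
  out
}

# logical reach matrix (rows/cols in `ids` order) for an acyclic edge list
.descendants_matrix <- function(ids, topo, tail, head) {
  n <- length(ids)
  R <- matrix(FALSE, n, n)
  if (length(tail)) {
    key <- !duplicated(paste(tail, head))
    ti <- match(tail[key], ids); hi <- match(head[key], ids)
    succ <- split(hi, ti)
    for (v in match(rev(topo), ids)) {
      s <- succ[[as.character(v)]]
      if (is.null(s)) next
      row <- R[v, ]
      row[s] <- TRUE
      for (w in s) row <- row | R[w, ]
      R[v, ] <- row
    }
  }
  R
}

#' Transitive edge reduction of an acyclic consensus graph
#'
#' Parallel edges are first collapsed (the ordinal graph is unweighted).
#' Then, for each vertex, its out-neighbours are sorted in topological order
#' and the edge to neighbour `Q[k]` is removed whenever `Q[k]` is reachable
#' from an earlier neighbour `Q[j]`, `j < k`.  For a DAG this yields the
#' unique transitive reduction, so the marker-level ordering implied by the
#' graph is unchanged.
#'
#' @param G an acyclic `consensus_graph`.
#' @return an `ordinal_graph`.
#' @export
reduce_edges <- function(G) {
  topo <- assert_acyclic(G)
  ids <- vertex_ids(G)
  R <- .descendants_matrix(ids, topo, G$edges$tail, G$edges$head)
  rank_of <- stats::setNames(seq_along(topo), as.character(topo))
  key <- !duplicated(paste(G$edges$tail, G$edges$head))
  tl <- match(G$edges$tail[key], ids); hd <- match(G$edges$head[key], ids)
  keep <- logical(length(tl))
  for (v in unique(tl)) {
    sel <- which(tl == v)
    Q <- hd[sel][order(rank_of[as.character(ids[hd[sel]])])]
    kq <- rep(TRUE, length(Q))
    for (k in seq_along(Q)) {
      if (k == 1L) next
      if (any(R[Q[seq_len(k - 1L)], Q[k]])) kq[k] <- FALSE
    }
    keep[sel[order(rank_of[as.character(ids[hd[sel]])])]] <- kq
  }
  vm <- vertex_markers(G)
  new_ordinal_graph(
    vertices = vm,
    edges = data.frame(tail = ids[tl[keep]], head = ids[hd[keep]],
                       stringsAsFactors = FALSE),
    group_id = G$group_id)
}

#' Coalesce ordinally redundant vertices
#'
#' Vertices with identical in-neighbour sets *and* identical out-neighbour
#' sets cannot be path-connected, so merging them (their marker sets are
#' unioned) leaves the marker-level ordering unchanged.  This typically
#' recombines bins that were split during graph construction only because
#' two maps disagreed on distances.  Iterated to a fixpoint.
#'
#' @param G an `ordinal_graph` produced by [reduce_edges()].
#' @return an `ordinal_graph`.
#' @export
coalesce_vertices <- function(G) {
  stopifnot(inherits(G, "ordinal_graph"))
  repeat {
    ids <- as.integer(names(G$vertices))
    e <- G$edges
    ins <- lapply(stats::setNames(nm = ids), function(v)
      sort(unique(e$tail[e$head == v])))
    outs <- lapply(stats::setNames(nm = ids), function(v)
      sort(unique(e$head[e$tail == v])))
    sig <- vapply(as.character(ids), function(k)
      paste(paste(ins[[k]], collapse = ","), "|",
            paste(outs[[k]], collapse = ",")), character(1))
    groups <- split(ids, sig)
    groups <- groups[lengths(groups) > 1L]
    if (!length(groups)) break
    remap <- stats::setNames(ids, as.character(ids))
    for (g in groups) {
      tgt <- min(g)
      remap[as.character(g)] <- tgt
      G$vertices[[as.character(tgt)]] <-
        sort(unlist(G$vertices[as.character(g)], use.names = FALSE))
      drop <- setdiff(g, tgt)
      G$vertices[as.character(drop)] <- NULL
    }
    e$tail <- unname(remap[as.character(e$tail)])
    e$head <- unname(remap[as.character(e$head)])
    e <- unique(e[e$tail != e$head, , drop = FALSE])
    rownames(e) <- NULL
    G$edges <- e
  }
  G
}

#' Simplify an acyclic consensus graph to its minimal ordinal form
#'
#' Convenience wrapper: [reduce_edges()] then [coalesce_vertices()].
#'
#' @param G an acyclic `consensus_graph`.
#' @return an `ordinal_graph` that is ordinally equivalent to `G`.
#' @export
ordinal_graph <- function(G) coalesce_vertices(reduce_edges(G))

#' Marker-level order pairs of an ordinal graph
#' @param G an `ordinal_graph`.
#' @return data.frame with columns `from`, `to` (see [marker_order_pairs()]).
#' @export
ordinal_order_pairs <- function(G) {
  ids <- as.integer(names(G$vertices))
  n <- length(ids)
  if (n == 0L) return(data.frame(from = character(0), to = character(0)))
  reach <- .reach_matrix(ids, G$edges$tail, G$edges$head)
  out <- list()
  for (i in seq_len(n)) {
    js <- which(reach[i, ])
    if (!length(js)) next
    fr <- G$vertices[[i]]
    to <- unlist(G$vertices[js], use.names = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      from = rep(fr, times = length(to)), to = rep(to, each = length(fr)),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(from = character(0), to = character(0)))
  do.call(rbind, out)
}

#' @export
export_dot.ordinal_graph <- function(G, mode = "full", file = NULL, ...) {
  lines <- c("digraph ordinal {", "  node [shape=box];",
             vapply(names(G$vertices), function(id)
               sprintf("  v%s [label=\"%s\"];", id,
                       .dot_label(G$vertices[[id]])), character(1)))
  if (nrow(G$edges))
    lines <- c(lines, sprintf("  v%d -> v%d;", G$edges$tail, G$edges$head))
  .dot_write(c(lines, "}"), file)
}
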