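# Linearizing the consensus graph into a consensus map.
#
# The graph defines a weighted least-deviation problem over bin positions x:
#   minimize  sum_k q_k | c_k' x - d_k |^alpha   subject to  A x >= 0,
# where each row c_k' of the stacked incidence matrix C = [A; B] has -1 at
# the tail and +1 at the head of an edge, d_k is the edge length (0 for
# zero-length edges) and q_k the edge weight.  alpha = 2 gives a strictly
# convex quadratic program once an anchor row pins the origin; alpha = 1
# gives the weighted-L1 linear program.

#' Build the incidence system of an acyclic consensus graph
#'
#' Vertices are reindexed 1..n in topological order (the first vertex in
#' topological order is the anchor used to fix the map origin).  Each
#' directed edge contributes one row of `A` (parallel edges stay separate
#' rows), each zero-length edge resolved to a distinct vertex pair
#' contributes one row of `B`; `C` stacks `A` over `B`; `d` holds edge
#' lengths and `q` the positive weights.
#'
#' @param G an acyclic `consensus_graph`.
#' @return object of class `linear_system`: sparse matrices `A`, `B`, `C`
#'   (\pkg{Matrix}), numeric `d`, `q`, counts `n`, `p`, `r`, `vertex_ids`
#'   (original id per column) and `markers` (list of marker sets per column).
#' @export
build_system <- function(G) {
  topo <- assert_acyclic(G)
  n <- length(topo)
  col_of <- stats::setNames(seq_len(n), as.character(topo))
  p <- nrow(G$edges)
  ze <- zero_edges(G)
  r <- nrow(ze)
  inc <- function(tail, head, m) {
    if (m == 0L)
      return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                  dims = c(0L, n)))
    Matrix::sparseMatrix(
      i = rep(seq_len(m), 2L),
      j = c(col_of[as.character(tail)], col_of[as.character(head)]),
      x = c(rep(-1, m), rep(1, m)), dims = c(m, n))
  }
  A <- inc(G$edges$tail, G$edges$head, p)
  B <- inc(ze$u, ze$v, r)
  vm <- vertex_markers(G)
  structure(list(A = A, B = B, C = rbind(A, B),
                 d = c(G$edges$length, rep(0, r)),
                 q = c(G$edges$weight, ze$weight),
                 n = n, p = p, r = r,
                 vertex_ids = topo,
                 markers = vm[as.character(topo)],
                 group_id = G$group_id),
            class = "linear_system")
}

#' @export
print.linear_system <- function(x, ...) {
  cat(sprintf("Linear system: n = %d vertices, p = %d directed rows, r = %d zero rows\n",
              x$n, x$p, x$r))
  invisible(x)
}

# Aggregate rows identical in (i, j, d): summing their weights changes
# neither optimum nor objective, and shrinks the problem handed to the
# numerical backend.  Returns list(i, j, d, w) with i/j column indices.
.aggregate_rows <- function(S) {
  Ct <- as(S$C, "TsparseMatrix")
  m <- nrow(S$C)
  i <- integer(m); j <- integer(m)
  neg <- Ct@x < 0
  i[Ct@i[neg] + 1L] <- Ct@j[neg] + 1L
  j[Ct@i[!neg] + 1L] <- Ct@j[!neg] + 1L
  key <- paste(i, j, signif(S$d, 12))
  grp <- match(key, unique(key))
  list(i = i[!duplicated(grp)], j = j[!duplicated(grp)],
       d = S$d[!duplicated(grp)],
       w = as.numeric(tapply(S$q, grp, sum))[order(unique(grp))])
}

# anchor rows: one per weakly connected component of the union of objective
# rows (directed + zero-length); the anchored vertex of each component is
# the component member that comes first in topological (column) order
.anchor_columns <- function(S) {
  parent <- seq_len(S$n)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  unite <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <<- ra; invisible(NULL) }
  Ct <- as(S$C, "TsparseMatrix")
  if (nrow(S$C)) {
    rows <- split(Ct@j + 1L, Ct@i)
    for (cols in rows) if (length(cols) == 2L) unite(cols[1L], cols[2L])
  }
  roots <- vapply(seq_len(S$n), find, integer(1))
  vapply(split(seq_len(S$n), roots), min, integer(1))
}

# incidence rows (i -> j, meaning x_j - x_i) plus anchor rows for each
# component, as one sparse matrix; anchors have a single +1
.stack_with_anchors <- function(agg, anchors, n) {
  m <- length(agg$d)
  Matrix::sparseMatrix(
    i = c(rep(seq_len(m), 2L), m + seq_along(anchors)),
    j = c(agg$i, agg$j, anchors),
    x = c(rep(-1, m), rep(1, m), rep(1, length(anchors))),
    dims = c(m + length(anchors), n))
}

.objective_value <- function(S, x, alpha) {
  res <- as.numeric(S$C %*% x) - S$d
  if (alpha == 2) sum(S$q * res^2) else sum(S$q * abs(res))
}

# enforce A x >= 0 exactly: sweep vertices in column (topological) order and
# lift each head to at least the largest of its tails
.clamp_monotone <- function(S, x) {
  agg <- .aggregate_order_pairs(S)
  if (!length(agg$i)) return(x - min(x))
  heads <- split(agg$i, agg$j)   # tails per head, keyed by head column
  for (j in sort(unique(agg$j))) {
    t <- heads[[as.character(j)]]
    x[j] <- max(x[j], x[t])
  }
  x - min(x)
}

# unique order constraints (tail column i, head column j) from A rows
.aggregate_order_pairs <- function(S) {
  if (S$p == 0L) return(list(i = integer(0), j = integer(0)))
  At <- as(S$A, "TsparseMatrix")
  m <- S$p
  i <- integer(m); j <- integer(m)
  neg <- At@x < 0
  i[At@i[neg] + 1L] <- At@j[neg] + 1L
  j[At@i[!neg] + 1L] <- At@j[!neg] + 1L
  key <- !duplicated(paste(i, j))
  list(i = i[key], j = j[key])
}

.new_solution <- function(x, S, method, objective, extra = list()) {
  structure(c(list(x = as.numeric(x), objective = objective, method = method,
                   system = S), extra),
            class = "map_solution")
}

#' @export
print.map_solution <- function(x, ...) {
  cat(sprintf("%s solution: %d bins, length %.4g cM, objective %.6g\n",
              x$method, length(x$x), max(x$x), x$objective))
  invisible(x)
}

#' Solve the weighted least-squares linearization (quadratic program)
#'
#' Minimizes `(Cx - d)' diag(q) (Cx - d)` subject to `Ax >= 0`.  An anchor
#' row (a single 1 in the column of the first vertex in topological order,
#' target 0) is appended per connected component of the objective system,
#' which makes the quadratic form positive definite; the dual active-set
#' method of \pkg{quadprog} then returns the exact KKT point.  The solution
#' is shifted so that `min(x) = 0`.
#'
#' @param S a `linear_system` from [build_system()].
#' @return a `map_solution` with fields `x` (positions per column of `S`),
#'   `objective` (weighted squared error, anchors excluded), `method`
#'   (`"QP"`), `lagrangian` (multipliers for the unique order constraints
#'   `ord_i`, `ord_j`).
#' @export
solve_qp <- function(S) {
  stopifnot(inherits(S, "linear_system"))
  n <- S$n
  if (n == 1L)
    return(.new_solution(0, S, "QP", 0))
  agg <- .aggregate_rows(S)
  anchors <- .anchor_columns(S)
  Caug <- .stack_with_anchors(agg, anchors, n)
  daug <- c(agg$d, rep(0, length(anchors)))
  waug <- c(agg$w, rep(1, length(anchors)))
  Dmat <- as.matrix(2 * Matrix::crossprod(Caug * sqrt(waug)))
  dvec <- as.numeric(2 * Matrix::crossprod(Caug, waug * daug))
  ord <- .aggregate_order_pairs(S)
  m <- length(ord$i)
  sol <- NULL
  ridge <- 0
  for (attempt in 1:3) {
    sol <- tryCatch({
      if (m > 0L) {
        Amat <- matrix(c(rep(-1, m), rep(1, m)), nrow = 2, byrow = TRUE)
        Aind <- rbind(rep(2L, m), ord$i, ord$j)
        quadprog::solve.QP.compact(Dmat + diag(ridge, n), dvec, Amat, Aind,
                                   bvec = rep(0, m))
      } else {
        list(solution = solve(Dmat + diag(ridge, n), dvec),
             Lagrangian = numeric(0))
      }
    }, error = function(e) e)
    if (!inherits(sol, "error")) break
    ridge <- max(ridge * 100, 1e-8 * max(diag(Dmat)))
  }
  if (inherits(sol, "error"))
    stop("quadratic program failed: ", conditionMessage(sol))
  x <- sol$solution
  x <- x - min(x)
  .new_solution(x, S, "QP", .objective_value(S, x, 2),
                list(lagrangian = sol$Lagrangian, ord_i = ord$i, ord_j = ord$j))
}

#' KKT residuals of a quadratic-program solution
#'
#' Diagnostics for the stationarity, feasibility and complementary-slackness
#' conditions of the order-constrained weighted least-squares problem.
#'
#' @param sol a `map_solution` from [solve_qp()].
#' @return list with `stationarity` (max-norm of the Lagrangian gradient),
#'   `feasibility` (most negative constraint value, 0 when none), `min_multiplier`
#'   (most negative multiplier) and `comp_slack` (max |lambda * slack|).
#' @export
kkt_residuals <- function(sol) {
  stopifnot(identical(sol$method, "QP"))
  S <- sol$system
  agg <- .aggregate_rows(S)
  anchors <- .anchor_columns(S)
  Caug <- .stack_with_anchors(agg, anchors, S$n)
  daug <- c(agg$d, rep(0, length(anchors)))
  waug <- c(agg$w, rep(1, length(anchors)))
  # translate to the solver's origin: anchor columns at 0, not min(x) = 0
  x <- sol$x
  if (length(anchors)) x <- x - (Caug[length(agg$d) + 1L, , drop = FALSE] %*% x)[1L]
  grad <- as.numeric(2 * Matrix::crossprod(Caug, waug * (as.numeric(Caug %*% x) - daug)))
  lam <- sol$lagrangian
  slack <- sol$x[sol$ord_j] - sol$x[sol$ord_i]
  if (length(lam)) {
    Gt <- Matrix::sparseMatrix(i = c(sol$ord_i, sol$ord_j),
                               j = rep(seq_along(lam), 2L),
                               x = c(rep(-1, length(lam)), rep(1, length(lam))),
                               dims = c(S$n, length(lam)))
    grad <- grad - as.numeric(Gt %*% lam)
  }
  list(stationarity = if (length(grad)) max(abs(grad)) else 0,
       feasibility = if (length(slack)) min(slack, 0) else 0,
       min_multiplier = if (length(lam)) min(lam, 0) else 0,
       comp_slack = if (length(lam)) max(abs(lam * slack)) else 0)
}

#' Solve the weighted least-absolute-deviation linearization (linear program)
#'
#' Minimizes `sum_k q_k |c_k' x - d_k|` subject to `Ax >= 0` (the linear
#' program obtained by introducing one auxiliary error variable per row).
#' The solver is a sparse ADMM iteration on the equivalent splitting
#' `min g(y) s.t. y = Mx` -- where `g` is the weighted L1 distance to `d` on
#' objective rows and the indicator of nonnegativity on constraint rows --
#' followed by an active-set polishing step that solves the equality system
#' of the identified optimal face.  The returned positions satisfy the order
#' constraints exactly (a final monotone sweep in topological order) and are
#' shifted so `min(x) = 0`.
#'
#' @param S a `linear_system` from [build_system()].
#' @param control list of solver settings: `max_iter` (default 6000; at study
#'   scale the objective is converged to a few parts in 1e5 well before this),
#'   `eps` (residual tolerance, default 1e-8), `rho` (initial penalty, default
#'   1), `check_every` (default 25), `polish_every` (default 500),
#'   `stall_polishes` (default 2; the iteration stops early once this many
#'   consecutive polishes leave the best objective unchanged to 1e-6 relative).
#' @return a `map_solution` with `method = "LP"`, `objective` the weighted L1
#'   error, and `z` the absolute residuals per row of `C`.
#' @export
solve_lp <- function(S, control = list()) {
  stopifnot(inherits(S, "linear_system"))
  ctl <- utils::modifyList(list(max_iter = 6000L, eps = 1e-8, rho = 1,
                                check_every = 25L, polish_every = 500L,
                                stall_polishes = 2L), control)
  n <- S$n
  if (n == 1L)
    return(.new_solution(0, S, "LP", 0, list(z = abs(S$d))))
  agg <- .aggregate_rows(S)
  anchors <- .anchor_columns(S)
  Cagg <- .stack_with_anchors(agg, anchors, n)     # objective rows
  dagg <- c(agg$d, rep(0, length(anchors)))
  wagg <- c(agg$w, rep(1, length(anchors)))
  ord <- .aggregate_order_pairs(S)
  mA <- length(ord$i)
  Aagg <- Matrix::sparseMatrix(i = rep(seq_len(mA), 2L), j = c(ord$i, ord$j),
                               x = c(rep(-1, mA), rep(1, mA)), dims = c(mA, n))
  M <- rbind(Cagg, Aagg)
  mC <- nrow(Cagg)
  MtM <- Matrix::crossprod(M)
  Ch <- Matrix::Cholesky(MtM, LDL = FALSE, perm = TRUE)
  rho <- ctl$rho
  y <- c(dagg, rep(0, mA)); u <- numeric(mC + mA)
  best_x <- NULL; best_obj <- Inf
  soft <- function(v, k) sign(v) * pmax(abs(v) - k, 0)
  evaluate <- function(x) {
    x <- .clamp_monotone(S, x)
    obj <- .objective_value(S, x, 1)
    if (obj < best_obj - 1e-12) { best_obj <<- obj; best_x <<- x }
    obj
  }
  polish <- function(x, u) {
    actC <- abs(rho * u[seq_len(mC)]) < wagg * (1 - 1e-7)
    sA <- as.numeric(Aagg %*% x)
    actA <- if (mA) (u[mC + seq_len(mA)] < -1e-12 | sA < 1e-9) else logical(0)
    E <- rbind(Cagg[actC, , drop = FALSE], Aagg[actA, , drop = FALSE])
    if (nrow(E) == 0L) return(invisible(NULL))
    rhs <- c(dagg[actC], rep(0, sum(actA)))
    xs <- tryCatch(as.numeric(Matrix::solve(
      Matrix::crossprod(E) + Matrix::Diagonal(n, 1e-10),
      Matrix::crossprod(E, rhs))), error = function(e) NULL)
    if (!is.null(xs)) evaluate(xs)
    invisible(NULL)
  }
  x <- numeric(n)
  y_old <- y
  stall <- 0L; last_polish_obj <- Inf
  for (it in seq_len(ctl$max_iter)) {
    x <- as.numeric(Matrix::solve(Ch, Matrix::crossprod(M, y - u)))
    Mx <- as.numeric(M %*% x)
    t <- Mx + u
    y <- c(dagg + soft(t[seq_len(mC)] - dagg, wagg / rho),
           if (mA) pmax(t[mC + seq_len(mA)], 0) else numeric(0))
    u <- t - y
    if (it %% ctl$check_every == 0L || it == ctl$max_iter) {
      rp <- max(abs(Mx - y))
      rd <- rho * max(abs(as.numeric(Matrix::crossprod(M, y - y_old))))
      scale <- max(1, max(abs(Mx)))
      if (rp < ctl$eps * scale && rd < ctl$eps * scale) {
        evaluate(x); polish(x, u)
        break
      }
      if (it %% ctl$polish_every == 0L) {
        evaluate(x); polish(x, u)
        # the active set has stabilized when repeated polishes agree
        if (is.finite(best_obj) &&
            abs(best_obj - last_polish_obj) <= 1e-6 * max(1, best_obj)) {
          stall <- stall + 1L
          if (stall >= ctl$stall_polishes) break
        } else stall <- 0L
        last_polish_obj <- best_obj
      }
      if (rp > 10 * rd) { rho <- rho * 2; u <- u / 2 }
      else if (rd > 10 * rp) { rho <- rho / 2; u <- u * 2 }
    }
    y_old <- y
  }
  evaluate(x); polish(x, u)
  if (is.null(best_x)) stop("linear program failed to produce a feasible point")
  x <- best_x
  .new_solution(x, S, "LP", best_obj,
                list(z = abs(as.numeric(S$C %*% x) - S$d)))
}

#' Turn a solver result into a consensus map, optionally rescaling
#'
#' Both linearizations compress the consensus relative to the component
#' linkage maps; by default the map is stretched so its total length equals
#' the mean length of the input maps.
#'
#' @param result a `map_solution` from [solve_qp()] or [solve_lp()].
#' @param maps the linkage maps the consensus graph was built from.
#' @param enabled rescale (default TRUE)?  When FALSE, `scale_factor` is 1.
#' @return a [consensus_map()].
#' @export
rescale <- function(result, maps, enabled = TRUE) {
  stopifnot(inherits(result, "map_solution"))
  x <- result$x
  len <- max(x) - min(x)
  factor <- 1
  if (enabled) {
    target <- mean(vapply(maps, map_length, numeric(1)))
    if (len > 0) {
      factor <- target / len
    } else if (target > 0) {
      warning("consensus has zero length; rescaling skipped")
    }
  }
  consensus_map(result$system$markers, (x - min(x)) * factor,
                scale_factor = factor, method = result$method,
                group_id = result$system$group_id)
}

#' Error between a consensus map and its component linkage maps
#'
#' Evaluates, over every marker pair in the same or adjacent bins of each
#' linkage map, the deviation between the consensus-map distance and the
#' linkage-map distance; normalizes by the number of pairs (or by the number
#' of distinct map intervals) and, for the L2 norm, takes the square root
#' (an RMS error in cM).
#'
#' @param consensus a `consensus_map` containing every map marker.
#' @param maps list of [linkage_map()] objects.
#' @param norm `"L1"` (mean absolute) or `"L2"` (RMS).
#' @param denominator `"pairs"` (default: every marker pair counts once) or
#'   `"intervals"` (normalize by the number of distinct same/adjacent bin
#'   pairs).
#' @return single numeric value in cM.
#' @export
map_error <- function(consensus, maps, norm = c("L1", "L2"),
                      denominator = c("pairs", "intervals")) {
  norm <- match.arg(norm); denominator <- match.arg(denominator)
  pos <- marker_positions(consensus)
  total <- 0; count <- 0
  for (M in maps) {
    missing <- setdiff(map_markers(M), names(pos))
    if (length(missing))
      stop("marker(s) absent from the consensus map: ",
           paste(missing, collapse = ", "))
    nb <- length(M$bins)
    for (b in seq_len(nb)) {
      bm <- M$bins[[b]]
      if (length(bm) >= 2L) {           # same-bin pairs, d = 0
        xp <- pos[bm]
        dif <- abs(outer(xp, xp, `-`))[upper.tri(diag(length(bm)))]
        npair <- length(dif)
        total <- total + if (norm == "L2") sum(dif^2) else sum(dif)
        count <- count + if (denominator == "pairs") npair else 1
      }
      if (b < nb) {                     # adjacent-bin pairs
        cm <- M$bins[[b + 1L]]
        d <- M$positions[b + 1L] - M$positions[b]
        dif <- abs(outer(pos[cm], pos[bm], `-`) - d)
        npair <- length(dif)
        total <- total + if (norm == "L2") sum(dif^2) else sum(dif)
        count <- count + if (denominator == "pairs") npair else 1
      }
    }
  }
  if (count == 0) return(0)
  if (norm == "L2") sqrt(total / count) else total / count
}

#' Build a consensus map from linkage maps in one call
#'
#' Merges the maps, checks for ordering conflicts, builds the incidence
#' system, solves the requested program and (by default) rescales the result
#' to the mean linkage-map length.
#'
#' @param maps list of [linkage_map()] objects (same linkage group).
#' @param method `"QP"` (default) or `"LP"`.
#' @param rescale rescale to the mean map length (default TRUE)?
#' @param verbose log merge progress.
#' @return a [consensus_map()]; the solver result is attached as attribute
#'   `"solution"`.
#' @export
linearize_maps <- function(maps, method = c("QP", "LP"), rescale = TRUE,
                           verbose = FALSE) {
  method <- match.arg(method)
  G <- merge_linkage_maps(maps, verbose = verbose)
  S <- build_system(G)
  sol <- if (method == "QP") solve_qp(S) else solve_lp(S)
  rescale_solution <- get("rescale", envir = environment(solve_qp))
  cm <- rescale_solution(sol, maps, enabled = rescale)
  attr(cm, "solution") <- sol
  cm
}
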