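# Doubled-haploid simulation framework: true genome, segregating marker
# sets, gamete formation without crossover interference, and linkage-map
# estimation by LOD-weighted least squares under Haldane's mapping function.

#' True genome for simulation
#'
#' Evenly spaced markers on a single chromosome of the given genetic length.
#'
#' @param n_markers number of markers (default 1000).
#' @param length total map length in cM (default 100).
#' @return object of class `sim_genome` with fields `positions` (cM, strictly
#'   increasing, spanning `[0, length]`) and `markers` (names `M0001`, ...).
#' @export
sim_genome <- function(n_markers = 1000, length = 100) {
  stopifnot(n_markers >= 2, length > 0)
  structure(list(
    positions = seq(0, length, length.out = n_markers),
    markers = sprintf("M%0*d", nchar(as.character(n_markers)),
                      seq_len(n_markers)),
    length = length),
    class = "sim_genome")
}

#' Cross design for the simulation study
#'
#' @param n_crosses number of doubled-haploid populations `g`.
#' @param identity expected parental sequence identity in (0, 1); each marker
#'   segregates in a cross independently with probability `1 - identity`
#'   (default 0.70, i.e. 30\% of markers polymorphic).
#' @param pop_size doubled-haploid individuals per cross (default 200).
#' @param window number of adjacent polymorphic loci whose pairwise
#'   recombination estimates enter the weighted least-squares map fit
#'   (default 4).
#' @return object of class `cross_design`.
#' @export
cross_design <- function(n_crosses = 2, identity = 0.70, pop_size = 200,
                         window = 4) {
  stopifnot(n_crosses >= 1, identity > 0, identity < 1, pop_size >= 2,
            window >= 2)
  structure(list(n_crosses = n_crosses, identity = identity,
                 pop_size = pop_size, window = window),
            class = "cross_design")
}

#' Draw the polymorphic marker set of each cross
#'
#' Each marker is polymorphic in each cross independently with probability
#' `1 - identity`; this is how an average parental sequence identity enters
#' the study (parent haplotypes need not be materialized).
#'
#' @param genome a [sim_genome()].
#' @param design a [cross_design()].
#' @param seed optional integer; when given, `set.seed(seed)` is called.
#' @return list of integer vectors (marker indices), one per cross.
#' @export
simulate_polymorphisms <- function(genome, design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(genome$positions)
  lapply(seq_len(design$n_crosses), function(i)
    which(stats::runif(n) < 1 - design$identity))
}

#' Simulate a doubled-haploid population
#'
#' One meiosis per individual: the crossover count on the chromosome is
#' Poisson with mean `length/100` (one expected crossover per Morgan, no
#' interference), crossover positions are uniform, and the parental phase
#' alternates at each crossover from a random starting phase.  Doubling the
#' gamete makes the individual fully homozygous, so the genotype *is* the
#' gamete restricted to the polymorphic markers.
#'
#' @param genome a [sim_genome()].
#' @param polymorphic integer vector of segregating marker indices.
#' @param pop_size number of individuals.
#' @param seed optional integer seed.
#' @return object of class `dh_population`: `polymorphic` (indices) and
#'   `genotypes` (`pop_size` x `length(polymorphic)` 0/1 matrix of parental
#'   origin).
#' @export
simulate_dh <- function(genome, polymorphic, pop_size = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- genome$positions[polymorphic]
  L <- genome$length
  geno <- matrix(0L, nrow = pop_size, ncol = length(pos))
  for (i in seq_len(pop_size)) {
    nco <- stats::rpois(1L, L / 100)
    start <- stats::rbinom(1L, 1L, 0.5)
    if (nco == 0L) {
      geno[i, ] <- start
    } else {
      xo <- sort(stats::runif(nco, 0, L))
      geno[i, ] <- (start + findInterval(pos, xo)) %% 2L
    }
  }
  structure(list(polymorphic = polymorphic, genotypes = geno),
            class = "dh_population")
}

#' Haldane's mapping function and its inverse
#'
#' `haldane(r)` converts a recombination fraction to a map distance,
#' `d = -50 ln(1 - 2r)` cM, assuming no crossover interference;
#' `haldane_inv(d)` converts back, `r = (1 - exp(-2d/100)) / 2`.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @param d map distance(s) in cM, nonnegative.
#' @return numeric vector of distances (cM) or fractions.
#' @export
haldane <- function(r) {
  if (any(r < 0 | r >= 0.5))
    stop("recombination fraction must lie in [0, 0.5); r >= 0.5 maps to an infinite distance")
  -50 * log(1 - 2 * r)
}

#' @rdname haldane
#' @export
haldane_inv <- function(d) {
  if (any(d < 0)) stop("map distance must be nonnegative")
  (1 - exp(-2 * d / 100)) / 2
}

#' LOD score of linkage for a doubled-haploid (backcross-type) marker pair
#'
#' Log10 likelihood ratio of the estimated recombination fraction against
#' the null of free recombination (r = 1/2):
#' `LOD = k log10(2 r) + (n - k) log10(2 (1 - r))` with `r = k/n`; the
#' boundary `k = 0` is the limit `n log10 2`.
#'
#' @param n_recomb number of recombinant individuals `k`.
#' @param n number of scored individuals.
#' @return LOD score(s).
#' @export
lod_score <- function(n_recomb, n) {
  stopifnot(all(n_recomb >= 0), all(n_recomb <= n))
  r <- n_recomb / n
  t1 <- ifelse(n_recomb == 0, 0, n_recomb * log10(2 * r))
  t2 <- ifelse(n_recomb == n, 0, (n - n_recomb) * log10(2 * (1 - r)))
  t1 + t2
}

# weighted least squares for positions given pairwise distances d between
# loci i < j (indices into 1..m), with x_1 = 0; returns x of length m.
# The normal equations are a weighted graph Laplacian; dropping the first
# row/column anchors the origin.
.wls_positions <- function(i, j, d, w, m) {
  stopifnot(length(i) == length(j), length(d) == length(i))
  keep <- w > 0
  i <- i[keep]; j <- j[keep]; d <- d[keep]; w <- w[keep]
  if (m == 1L) return(0)
  L <- Matrix::sparseMatrix(
    i = c(i, j, i, j), j = c(i, j, j, i),
    x = c(w, w, -w, -w), dims = c(m, m), symmetric = FALSE)
  b <- numeric(m)
  bi <- tapply(w * d, i, sum); b[as.integer(names(bi))] <- -bi
  bj <- tapply(w * d, j, sum)
  b[as.integer(names(bj))] <- b[as.integer(names(bj))] + bj
  x <- numeric(m)
  sub <- tryCatch(
    as.numeric(Matrix::solve(L[-1L, -1L, drop = FALSE], b[-1L])),
    error = function(e)
      stop("weighted least-squares system is singular; the retained marker ",
           "pairs do not connect all loci"))
  x[-1L] <- sub
  x
}

#' Estimate a linkage map from a doubled-haploid population
#'
#' Adjacent markers with zero observed recombinants have identical genotype
#' columns in a doubled-haploid population and are first collapsed into one
#' marker bin (the map distance between co-segregating markers is zero by
#' definition).  For every bin pair within a sliding window of `window`
#' adjacent bins, the recombination fraction is estimated as the recombinant
#' count over the population size, converted to cM with Haldane's mapping
#' function, and weighted by the pair's LOD score.  Bin positions are then
#' fit by weighted least squares on `d_ij = x_j - x_i` (order fixed to the
#' true physical order, `x_1 = 0`).  Pairs with an estimated fraction
#' >= 0.5 are dropped from the fit.  Negative fitted intervals are clamped
#' to 0 and the flanking bins merged.
#'
#' @param pop a [simulate_dh()] population.
#' @param genome the [sim_genome()] the population derives from.
#' @param window adjacent-bin window for pairwise estimates (default 4).
#' @param map_id identifier for the resulting map.
#' @return a [linkage_map()] whose marker names are the genome's.
#' @export
estimate_map <- function(pop, genome, window = 4, map_id = "sim") {
  g <- pop$genotypes
  m <- ncol(g)
  if (m < 2L) stop("need at least 2 polymorphic markers to estimate a map")
  nind <- nrow(g)
  # collapse runs of identical adjacent genotype columns into bins
  adj_rec <- colSums(g[, -m, drop = FALSE] != g[, -1L, drop = FALSE])
  bin_of <- cumsum(c(1L, as.integer(adj_rec > 0)))
  nb <- bin_of[m]
  gb <- g[, !duplicated(bin_of), drop = FALSE]    # one genotype per bin
  if (nb < 2L) {
    return(linkage_map(genome$markers[pop$polymorphic], rep(0, m),
                       map_id = map_id, group_id = "sim"))
  }
  pairs_i <- integer(0); pairs_j <- integer(0); nrec <- integer(0)
  for (k in seq_len(min(window - 1L, nb - 1L))) {
    ii <- seq_len(nb - k)
    pairs_i <- c(pairs_i, ii)
    pairs_j <- c(pairs_j, ii + k)
    nrec <- c(nrec, colSums(gb[, ii, drop = FALSE] != gb[, ii + k, drop = FALSE]))
  }
  r_hat <- nrec / nind
  usable <- r_hat < 0.5
  w <- numeric(length(r_hat))
  w[usable] <- lod_score(nrec[usable], nind)
  d_hat <- numeric(length(r_hat))
  d_hat[usable] <- haldane(r_hat[usable])
  x <- .wls_positions(pairs_i, pairs_j, d_hat, w, nb)
  gaps <- pmax(diff(x), 0)              # fixed order forbids sign flips
  x <- cumsum(c(0, gaps))
  linkage_map(genome$markers[pop$polymorphic], x[bin_of], map_id = map_id,
              group_id = "sim")
}

#' Simulate a set of linkage maps under one cross design
#'
#' Draws polymorphic sets, simulates the doubled-haploid populations and
#' estimates one linkage map per cross.
#'
#' @param genome a [sim_genome()].
#' @param design a [cross_design()].
#' @param seed optional integer seed.
#' @return list with `maps` (list of [linkage_map()]) and `populations`.
#' @export
simulate_linkage_maps <- function(genome, design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  poly <- simulate_polymorphisms(genome, design)
  pops <- lapply(poly, function(p)
    simulate_dh(genome, p, pop_size = design$pop_size))
  maps <- lapply(seq_along(pops), function(k)
    estimate_map(pops[[k]], genome, window = design$window,
                 map_id = paste0("sim", k)))
  list(maps = maps, populations = pops)
}

#' Accuracy of a consensus map against the true simulated genome
#'
#' The consensus map is compared with the true positions of its markers
#' after removing the best-fit translation (the maps share an origin
#' convention only up to an offset).  The consensus map should already be on
#' the linkage-map scale (see [rescale()]).
#'
#' @param consensus a `consensus_map` (or `linkage_map`) whose markers are a
#'   subset of the genome's.
#' @param genome the [sim_genome()].
#' @param norm `"L2"` (RMS, default) or `"L1"` (mean absolute).
#' @return error in cM.
#' @export
map_accuracy <- function(consensus, genome, norm = c("L2", "L1")) {
  norm <- match.arg(norm)
  est <- marker_positions(consensus)
  idx <- match(names(est), genome$markers)
  if (anyNA(idx))
    stop("consensus contains markers absent from the genome: ",
         paste(names(est)[is.na(idx)], collapse = ", "))
  truth <- genome$positions[idx]
  delta <- est - truth
  delta <- delta - mean(delta)          # best-fit translation
  if (norm == "L2") sqrt(mean(delta^2)) else mean(abs(delta))
}
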