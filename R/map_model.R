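# Domain types for linkage maps and consensus maps, plus delimited-file I/O.
# Positions are in centiMorgans (cM) throughout.

#' Construct a linkage map from marker names and positions
#'
#' A linkage map is an ordered sequence of marker *bins* for one mapping
#' population and one linkage group.  Markers whose positions coincide
#' (exact equality after rounding to `precision` decimals) are placed in the
#' same bin, because zero observed recombination carries no ordinal
#' information.  Positions are shifted so the first bin sits at 0 cM.
#'
#' @param marker character vector of marker names (unique, nonempty).
#' @param position numeric vector of map positions in cM, same length as
#'   `marker`.
#' @param map_id population identifier (e.g. `"OWB"`).
#' @param group_id linkage group / chromosome identifier.
#' @param precision number of decimals used when deciding that two markers
#'   share a bin (default 6).
#' @return An object of class `linkage_map` with fields `bins` (list of
#'   character vectors), `positions` (numeric, strictly increasing, first
#'   element 0), `map_id`, `group_id`.
#' @examples
#' m <- linkage_map(c("A", "B", "C"), c(0, 0, 1.5), map_id = "pop1")
#' length(m$bins)  # 2 bins: {A,B}@0 and {C}@1.5
#' @export
linkage_map <- function(marker, position, map_id = "map", group_id = "1",
                        precision = 6) {
  marker <- as.character(marker)
  if (length(marker) == 0L) stop("a linkage map needs at least one marker")
  if (any(is.na(marker)) || any(!nzchar(marker)))
    stop("marker names must be nonempty")
  if (length(position) != length(marker))
    stop("'marker' and 'position' must have the same length")
  position <- as.numeric(position)
  if (any(is.na(position)))
    stop("non-numeric or missing position for marker(s): ",
         paste(marker[is.na(position)], collapse = ", "))
  dup <- unique(marker[duplicated(marker)])
  if (length(dup))
    stop("duplicate marker(s) within linkage group: ",
         paste(dup, collapse = ", "))
  pos <- round(position, precision)
  ord <- order(pos, marker)
  pos <- pos[ord]; marker <- marker[ord]
  pos <- round(pos - pos[1L], precision)
  grp <- cumsum(c(TRUE, diff(pos) != 0))
  bins <- split(marker, grp)
  names(bins) <- NULL
  structure(list(bins = bins,
                 positions = pos[!duplicated(grp)],
                 map_id = as.character(map_id),
                 group_id = as.character(group_id)),
            class = "linkage_map")
}

#' @export
print.linkage_map <- function(x, ...) {
  cat(sprintf("Linkage map '%s' (group %s): %d markers in %d bins, %.4g cM\n",
              x$map_id, x$group_id, sum(lengths(x$bins)), length(x$bins),
              map_length(x)))
  invisible(x)
}

#' Total length of a map in cM
#'
#' @param x a `linkage_map` or `consensus_map`.
#' @return Position of the last bin minus the first (maps start at 0).
#' @export
map_length <- function(x) {
  if (length(x$positions) == 0L) return(0)
  max(x$positions) - min(x$positions)
}

#' All marker names of a map
#' @param x a `linkage_map` or `consensus_map`.
#' @return character vector.
#' @export
map_markers <- function(x) unlist(x$bins, use.names = FALSE)

# sniff "," vs tab from the header line
.sniff_sep <- function(path) {
  l1 <- readLines(path, n = 1L)
  if (length(l1) == 0L) stop("empty file: ", path)
  if (lengths(regmatches(l1, gregexpr("\t", l1))) > 0) "\t" else ","
}

#' Read a linkage map from a delimited table
#'
#' The file must be a headered CSV or TSV (delimiter sniffed) with columns
#' `marker`, `group` and `position_cM`, in any order.  Markers at identical
#' positions (after rounding to `precision` decimals) are grouped into one
#' bin and the map is shifted so its first bin is at 0 cM.
#'
#' @param path file path.
#' @param map_id population identifier recorded on the map; defaults to the
#'   file name without extension.
#' @param group which linkage group to read when the file contains several;
#'   by default the file must contain exactly one.
#' @param precision decimals used for position equality (default 6).
#' @return A [linkage_map()] object.
#' @export
read_linkage_map <- function(path, map_id = NULL, group = NULL,
                             precision = 6) {
  if (is.null(map_id))
    map_id <- sub("\\.[^.]*$", "", basename(path))
  sep <- .sniff_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", strip.white = TRUE,
                           comment.char = "", quote = "\"")
  need <- c("marker", "group", "position_cM")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  if (!is.null(group)) tab <- tab[tab$group == as.character(group), , drop = FALSE]
  if (nrow(tab) == 0L) stop("no rows for the requested group in ", path)
  grps <- unique(tab$group)
  if (length(grps) > 1L)
    stop("file ", path, " contains several linkage groups (",
         paste(grps, collapse = ", "), "); use the 'group' argument")
  pos <- suppressWarnings(as.numeric(tab$position_cM))
  if (any(is.na(pos))) {
    bad <- which(is.na(pos))[1L]
    stop("non-numeric position '", tab$position_cM[bad], "' at line ",
         bad + 1L, " of ", path)
  }
  linkage_map(tab$marker, pos, map_id = map_id, group_id = grps,
              precision = precision)
}

#' Construct a consensus map object
#'
#' @param bins list of character vectors (disjoint marker sets).
#' @param positions numeric vector of bin positions (cM), nondecreasing,
#'   minimum 0.
#' @param scale_factor positive rescaling factor that was applied (1 if none).
#' @param method `"LP"`, `"QP"`, or `NA` when not produced by a solver.
#' @param group_id linkage group identifier.
#' @return object of class `consensus_map`.
#' @export
consensus_map <- function(bins, positions, scale_factor = 1, method = NA_character_,
                          group_id = "1") {
  stopifnot(length(bins) == length(positions))
  if (length(positions)) {
    ord <- order(positions)
    bins <- bins[ord]; positions <- positions[ord]
    positions <- positions - positions[1L]
    mk <- unlist(bins, use.names = FALSE)
    if (anyDuplicated(mk))
      stop("markers assigned to more than one consensus bin: ",
           paste(unique(mk[duplicated(mk)]), collapse = ", "))
  }
  structure(list(bins = bins, positions = as.numeric(positions),
                 scale_factor = scale_factor, method = method,
                 group_id = as.character(group_id)),
            class = "consensus_map")
}

#' @export
print.consensus_map <- function(x, ...) {
  cat(sprintf(
    "Consensus map (%s): %d markers in %d bins, %.4g cM (scale factor %.4g)\n",
    ifelse(is.na(x$method), "unsolved", x$method),
    sum(lengths(x$bins)), length(x$bins), map_length(x), x$scale_factor))
  invisible(x)
}

#' Positions of individual markers on a consensus map
#' @param x a `consensus_map` (or `linkage_map`).
#' @return named numeric vector, one entry per marker.
#' @export
marker_positions <- function(x) {
  n <- lengths(x$bins)
  stats::setNames(rep(x$positions, n), unlist(x$bins, use.names = FALSE))
}

#' Write a consensus map to a CSV file
#'
#' Columns `marker`, `bin_index`, `position_cM`, sorted by position then bin.
#' An empty map produces a header-only file.  The output round-trips through
#' [read_consensus_map()].
#'
#' @param map a `consensus_map`.
#' @param path output file path.
#' @export
write_consensus_map <- function(map, path) {
  stopifnot(inherits(map, "consensus_map"))
  n <- lengths(map$bins)
  df <- data.frame(marker = as.character(unlist(map$bins, use.names = FALSE)),
                   bin_index = rep(seq_along(map$bins), n),
                   position_cM = rep(round(map$positions, 6), n),
                   stringsAsFactors = FALSE)
  if (nrow(df))
    df <- df[order(df$position_cM, df$bin_index, df$marker), , drop = FALSE]
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write consensus map to ", path, ": ",
                        conditionMessage(ok))
  invisible(NULL)
}

#' Read a consensus map written by [write_consensus_map()]
#' @param path file path.
#' @return a `consensus_map` (method/scale factor are not stored in the file).
#' @export
read_consensus_map <- function(path) {
  tab <- utils::read.csv(path, colClasses = c("character", "integer", "numeric"))
  if (nrow(tab) == 0L)
    return(consensus_map(list(), numeric(0)))
  bins <- split(tab$marker, tab$bin_index)
  pos <- vapply(split(tab$position_cM, tab$bin_index), `[`, numeric(1), 1L)
  ord <- order(pos, as.integer(names(bins)))
  consensus_map(unname(bins[ord]), unname(pos[ord]))
}

#' The four barley 5HS-telomere linkage maps bundled with the package
#'
#' Returns the published short-arm telomere region of barley chromosome 5H
#' for the Steptoe x Morex (SM), Oregon Wolfe Barley (OWB), Morex x Barke
#' (MB) and Haruna Nijo x OUH602 (HO) mapping populations.  Nine of the
#' markers tag genes at the barley grain hardness locus
#' (*hinb*/*hina*/*gsp*).  Useful as a small real-data worked example.
#'
#' @return named list of four [linkage_map()] objects.
#' @export
barley_5HS_maps <- function() {
  files <- c(SM = "barley_5HS_SM.csv", OWB = "barley_5HS_OWB.csv",
             MB = "barley_5HS_MB.csv", HO = "barley_5HS_HO.csv")
  lapply(stats::setNames(nm = names(files)), function(id)
    read_linkage_map(system.file("extdata", files[[id]], package = "dagmap",
                                 mustWork = TRUE), map_id = id))
}

#' Markers of the barley grain hardness locus
#'
#' The nine SNP markers at the 5HS hardness locus, named by gene.
#' @return named character vector (names are the genes).
#' @export
hardness_markers <- function() {
  c(hinb = "3_0983", hinb = "3_0984",
    hina = "2_0226", hina = "3_0978", hina = "3_0979", hina = "3_0980",
    gsp = "3_0975", gsp = "3_0976", gsp = "3_0977")
}
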