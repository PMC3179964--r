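# The simulation study: per-replicate consensus construction and accuracy
# scoring over a grid of cross counts, with mean (SE) summaries.

# deterministic 31-bit child seed per (master seed, g, replicate)
.child_seed <- function(seed, g, rep) {
  as.integer((as.numeric(seed) * 7919 + g * 104729 + rep * 1299709) %%
               2147483647)
}

#' Run the doubled-haploid consensus-map study
#'
#' For each number of crosses `g` and each replicate: simulate `g`
#' doubled-haploid populations from one true genome, estimate their linkage
#' maps, merge them into a consensus graph and linearize with each requested
#' method; record the consensus marker count, the unrescaled consensus
#' length, and the mean-absolute and RMS error of the rescaled consensus
#' against the true marker positions (translation-aligned).  With `g = 1`
#' the consensus is the single estimated map itself and both methods
#' coincide with it.
#'
#' All randomness derives from `seed` through fixed per-replicate child
#' seeds, so any subset of the grid reproduces the same replicates.
#'
#' @param g_values numbers of linkage maps to integrate (default
#'   `c(1, 2, 4, 6, 8)`).
#' @param reps replicates per grid cell (>= 2).
#' @param seed master integer seed.
#' @param n_markers,genome_length true genome (defaults 1000 markers,
#'   100 cM).
#' @param identity,pop_size,window cross design (defaults 0.70, 200, 4).
#' @param methods linearization methods (default `c("LP", "QP")`).
#' @param verbose print a line per replicate.
#' @return object of class `sim_study`: `replicates` (long data.frame with
#'   one row per g/replicate/method) and `summary` (mean and SE per cell,
#'   `SE = sd/sqrt(reps)`).
#' @export
run_consensus_study <- function(g_values = c(1, 2, 4, 6, 8), reps = 20,
                                seed = 1, n_markers = 1000,
                                genome_length = 100, identity = 0.70,
                                pop_size = 200, window = 4,
                                methods = c("LP", "QP"), verbose = FALSE) {
  stopifnot(reps >= 2)
  methods <- match.arg(methods, c("LP", "QP"), several.ok = TRUE)
  genome <- sim_genome(n_markers, genome_length)
  rows <- list()
  for (g in g_values) {
    design <- cross_design(n_crosses = g, identity = identity,
                           pop_size = pop_size, window = window)
    for (rp in seq_len(reps)) {
      sim <- simulate_linkage_maps(genome, design,
                                   seed = .child_seed(seed, g, rp))
      maps <- sim$maps
      mean_len <- mean(vapply(maps, map_length, numeric(1)))
      if (g == 1L) {
        M <- maps[[1L]]
        cm <- consensus_map(M$bins, M$positions, method = NA_character_,
                            group_id = M$group_id)
        for (method in methods)
          rows[[length(rows) + 1L]] <- data.frame(
            g = g, rep = rp, method = method,
            n_markers = length(map_markers(M)),
            length_unrescaled = map_length(M),
            mean_map_length = mean_len,
            mae = map_accuracy(cm, genome, "L1"),
            rmse = map_accuracy(cm, genome, "L2"),
            seconds = 0, stringsAsFactors = FALSE)
        next
      }
      G <- merge_linkage_maps(maps)
      S <- build_system(G)
      for (method in methods) {
        t0 <- proc.time()[["elapsed"]]
        sol <- if (method == "QP") solve_qp(S) else solve_lp(S)
        dt <- proc.time()[["elapsed"]] - t0
        cm <- rescale(sol, maps, enabled = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          g = g, rep = rp, method = method,
          n_markers = sum(lengths(cm$bins)),
          length_unrescaled = max(sol$x),
          mean_map_length = mean_len,
          mae = map_accuracy(cm, genome, "L1"),
          rmse = map_accuracy(cm, genome, "L2"),
          seconds = dt, stringsAsFactors = FALSE)
      }
      if (verbose)
        message(sprintf("g=%d rep %d/%d done (%d vertices)", g, rp, reps,
                        S$n))
    }
  }
  replicates <- do.call(rbind, rows)
  structure(list(replicates = replicates,
                 summary = summarize_study(replicates)),
            class = "sim_study")
}

#' Mean (SE) summary of study replicates
#'
#' @param replicates the long data.frame from [run_consensus_study()].
#' @return data.frame with one row per (g, method, metric): `mean` and `se`
#'   (`sd/sqrt(n)`).
#' @export
summarize_study <- function(replicates) {
  metrics <- c("n_markers", "length_unrescaled", "mean_map_length",
               "mae", "rmse", "seconds")
  out <- list()
  for (g in sort(unique(replicates$g)))
    for (method in sort(unique(replicates$method))) {
      sub <- replicates[replicates$g == g & replicates$method == method, ]
      if (!nrow(sub)) next
      for (metric in metrics) {
        v <- sub[[metric]]
        out[[length(out) + 1L]] <- data.frame(
          g = g, method = method, metric = metric, n = length(v),
          mean = mean(v), se = stats::sd(v) / sqrt(length(v)),
          stringsAsFactors = FALSE)
      }
    }
  do.call(rbind, out)
}

#' @export
print.sim_study <- function(x, ...) {
  cat("Doubled-haploid consensus-map study\n")
  s <- x$summary
  for (metric in unique(s$metric)) {
    cat("\n", metric, ":\n", sep = "")
    sub <- s[s$metric == metric, ]
    tab <- stats::reshape(sub[, c("g", "method", "mean")],
                          direction = "wide", idvar = "method",
                          timevar = "g")
    print(tab, row.names = FALSE)
  }
  invisible(x)
}

#' Extract one summary cell from a study
#' @param study a `sim_study`.
#' @param g,method,metric cell coordinates (method ignored with a warning if
#'   absent).
#' @return list with `mean`, `se`, `n`.
#' @export
study_cell <- function(study, g, method, metric) {
  s <- study$summary
  row <- s[s$g == g & s$method == method & s$metric == metric, ]
  if (nrow(row) != 1L) stop("no unique summary cell for g=", g, " method=",
                            method, " metric=", metric)
  list(mean = row$mean, se = row$se, n = row$n)
}
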