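# Free-energy surfaces over 2-D projections and barrier estimation between
# basins via a minimax (watershed-saddle) path search on the binned grid.

#' Free-energy surface over a 2-D projection
#'
#' Histograms the samples on an `n_bins x n_bins` grid and converts counts
#' to free energies in kT units, `F = -ln(p / p_max)`, so the most populated
#' bin sits at 0 and empty bins are +Inf.  The surface is invariant to
#' rescaling the sample count.
#'
#' @param projections two-column matrix (e.g. IC1, IC2 from
#'   [tica_transform()]).
#' @param n_bins bins per axis (default 50).
#' @param limits optional list with `x` and `y` range c(lo, hi); default the
#'   data range.
#' @return object of class `fes_grid`: `free_energy` (matrix, kT), `counts`,
#'   `x_edges`, `y_edges`, `x_mid`, `y_mid`.
#' @export
free_energy_surface <- function(projections, n_bins = 50L, limits = NULL) {
  p <- as.matrix(projections)
  stopifnot(ncol(p) == 2L, nrow(p) >= 1L)
  rng <- limits %||% list(x = range(p[, 1L]), y = range(p[, 2L]))
  eps <- function(r) if (diff(r) == 0) r + c(-0.5, 0.5) else r
  rx <- eps(rng$x); ry <- eps(rng$y)
  xe <- seq(rx[1L], rx[2L], length.out = n_bins + 1L)
  ye <- seq(ry[1L], ry[2L], length.out = n_bins + 1L)
  xi <- pmin(pmax(findInterval(p[, 1L], xe, rightmost.closed = TRUE), 1L), n_bins)
  yi <- pmin(pmax(findInterval(p[, 2L], ye, rightmost.closed = TRUE), 1L), n_bins)
  counts <- matrix(0L, n_bins, n_bins)
  for (k in seq_len(nrow(p))) counts[xi[k], yi[k]] <- counts[xi[k], yi[k]] + 1L
  fe <- -log(counts / max(counts))
  structure(list(free_energy = fe, counts = counts, x_edges = xe, y_edges = ye,
                 x_mid = (xe[-1L] + xe[-length(xe)]) / 2,
                 y_mid = (ye[-1L] + ye[-length(ye)]) / 2),
            class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  cat(sprintf("fes_grid: %d x %d bins, %d occupied, F range [0, %.2f] kT\n",
              nrow(x$free_energy), ncol(x$free_energy), sum(x$counts > 0L),
              max(x$free_energy[is.finite(x$free_energy)])))
  invisible(x)
}

# Locate the occupied bin nearest a coordinate pair (or accept bin indices).
locate_basin <- function(fes, basin) {
  if (length(basin) != 2L) stop("basin must be (x, y) or (i, j) of length 2")
  if (all(basin == round(basin)) && all(basin >= 1) &&
      basin[1L] <= nrow(fes$free_energy) && basin[2L] <= ncol(fes$free_energy) &&
      is.finite(fes$free_energy[basin[1L], basin[2L]])) {
    return(as.integer(basin))
  }
  occ <- which(fes$counts > 0L, arr.ind = TRUE)
  d2 <- (fes$x_mid[occ[, 1L]] - basin[1L])^2 + (fes$y_mid[occ[, 2L]] - basin[2L])^2
  as.integer(occ[which.min(d2), ])
}

#' Barrier between two basins on a free-energy surface
#'
#' Finds the minimax path (the path whose highest free energy is lowest —
#' the watershed saddle) between two basins over 8-connected occupied bins,
#' by a Dijkstra-type search under the max-cost metric.  The barrier is the
#' saddle value minus the higher of the two basin minima.
#'
#' @param fes a `fes_grid`.
#' @param basin_a,basin_b basin positions: bin indices c(i, j) or projection
#'   coordinates (mapped to the nearest occupied bin).
#' @return list `barrier` (kT), `saddle`, `connected` (FALSE when no finite
#'   path exists, in which case barrier is NA).
#' @export
estimate_barrier <- function(fes, basin_a, basin_b) {
  fe <- fes$free_energy
  a <- locate_basin(fes, basin_a)
  b <- locate_basin(fes, basin_b)
  n1 <- nrow(fe); n2 <- ncol(fe)
  cost <- matrix(Inf, n1, n2)     # minimax value of best path found so far
  cost[a[1L], a[2L]] <- fe[a[1L], a[2L]]
  visited <- matrix(FALSE, n1, n2)
  steps <- expand.grid(di = -1:1, dj = -1:1)
  steps <- steps[!(steps$di == 0 & steps$dj == 0), ]
  repeat {
    u <- which(!visited & is.finite(cost))
    if (!length(u)) break
    u <- u[which.min(cost[u])]
    ui <- (u - 1L) %% n1 + 1L; uj <- (u - 1L) %/% n1 + 1L
    visited[ui, uj] <- TRUE
    if (ui == b[1L] && uj == b[2L]) break
    for (s in seq_len(nrow(steps))) {
      vi <- ui + steps$di[s]; vj <- uj + steps$dj[s]
      if (vi < 1L || vi > n1 || vj < 1L || vj > n2) next
      if (visited[vi, vj] || !is.finite(fe[vi, vj])) next
      cand <- max(cost[ui, uj], fe[vi, vj])
      if (cand < cost[vi, vj]) cost[vi, vj] <- cand
    }
  }
  saddle <- cost[b[1L], b[2L]]
  if (!is.finite(saddle))
    return(list(barrier = NA_real_, saddle = NA_real_, connected = FALSE))
  base <- max(fe[a[1L], a[2L]], fe[b[1L], b[2L]])
  list(barrier = saddle - base, saddle = saddle, connected = TRUE)
}
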