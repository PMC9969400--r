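#' Stationary points of a free-energy grid
#'
#' Minima are unmasked bins strictly below all their unmasked neighbours
#' (4/8-neighbourhood in 2D, 2-neighbourhood in 1D). Exact energy ties on a
#' plateau are resolved by lexicographic node order (first coordinate index,
#' then second): the lexicographically first plateau node can qualify, later
#' ones cannot. Saddles are the peak nodes of the bottleneck-optimal paths
#' ([trace_mep()]) between pairs of basins, de-duplicated by node; each
#' saddle records the basin pair whose path first produced it (pairs are
#' visited in order of increasing basin separation).
#'
#' @param grid an `fe_grid` from [solve_wham()].
#' @param connectivity 8 (default, diagonal moves allowed) or 4; ignored
#'   in 1D.
#' @param min_prominence kcal/mol; a minimum whose lowest pass to any
#'   deeper basin rises less than this above it is treated as statistical
#'   ripple and merged away (0, the default, keeps every strict local
#'   minimum — use it on noise-free grids; sampled PMFs warrant a floor of
#'   order the bootstrap error times a few).
#' @return a `stationary_points` list: `minima` (data frame: node index per
#'   coordinate, coordinate values, `energy`, `basin` label) and `saddles`
#'   (the same columns plus `basin_from`, `basin_to`).
#' @export
find_stationary_points <- function(grid, connectivity = 8, min_prominence = 0) {
  stopifnot(inherits(grid, "fe_grid"))
  if (all(grid$mask)) stop("fully masked grid: no unmasked bin to analyse")
  fe <- grid$free_energy
  nbin <- grid$nbin
  nb <- length(fe)
  is_min <- logical(nb)
  for (v in which(!grid$mask)) {
    nbs <- .grid_neighbours(v, nbin, connectivity)
    nbs <- nbs[!grid$mask[nbs]]
    ev <- fe[v]
    lower <- fe[nbs] < ev
    tie <- fe[nbs] == ev
    # plateau tie-break: node must precede every equal-energy neighbour
    is_min[v] <- !any(lower) && all(nbs[tie] > v)
  }
  mins <- which(is_min)
  mins <- mins[order(fe[mins], mins)]
  if (min_prominence > 0 && length(mins) > 1) {
    keep <- rep(TRUE, length(mins))
    for (k in seq_along(mins)[-1]) {        # mins sorted by energy: [1] is global
      deeper <- mins[seq_len(k - 1L)][keep[seq_len(k - 1L)]]
      bn <- .bottleneck_values(grid, mins[k], deeper, connectivity)
      if (min(bn) - fe[mins[k]] < min_prominence) keep[k] <- FALSE
    }
    mins <- mins[keep]
  }
  minima <- cbind(.node_frame(mins, grid), basin = seq_along(mins))
  minima <- minima[order(minima$node), , drop = FALSE]
  minima$basin <- seq_len(nrow(minima))  # label basins in lexicographic node order
  rownames(minima) <- NULL

  saddles <- minima[0, c(names(.node_frame(integer(0), grid)))]
  saddles$basin_from <- integer(0); saddles$basin_to <- integer(0)
  if (nrow(minima) > 1) {
    pairs <- utils::combn(nrow(minima), 2)
    sep <- abs(minima$node[pairs[2, ]] - minima$node[pairs[1, ]])
    pairs <- pairs[, order(sep), drop = FALSE]
    seen <- integer(0)
    for (pc in seq_len(ncol(pairs))) {
      i <- pairs[1, pc]; j <- pairs[2, pc]
      path <- tryCatch(
        trace_mep(grid, minima$node[i], minima$node[j], connectivity = connectivity),
        fel_no_path = function(e) NULL)
      if (is.null(path)) next
      pk <- path$nodes[path$peak_index]
      if (pk %in% seen || pk %in% minima$node) next
      seen <- c(seen, pk)
      row <- .node_frame(pk, grid)
      row$basin_from <- minima$basin[i]; row$basin_to <- minima$basin[j]
      saddles <- rbind(saddles, row)
    }
  }
  rownames(saddles) <- NULL
  structure(list(minima = minima, saddles = saddles,
                 connectivity = if (grid$dim == 2L) connectivity else 2L),
            class = "stationary_points")
}

#' @export
print.stationary_points <- function(x, ...) {
  cat(sprintf("stationary_points: %d minima, %d saddles (%d-connectivity)\n",
              nrow(x$minima), nrow(x$saddles), x$connectivity))
  cat("minima:\n"); print(x$minima, row.names = FALSE)
  if (nrow(x$saddles)) { cat("saddles:\n"); print(x$saddles, row.names = FALSE) }
  invisible(x)
}

# flat-index neighbours on a 1D/2D grid
.grid_neighbours <- function(v, nbin, connectivity = 8) {
  if (length(nbin) == 1L) {
    nbs <- c(v - 1L, v + 1L)
    return(nbs[nbs >= 1L & nbs <= nbin[1]])
  }
  i <- ((v - 1L) %% nbin[1]) + 1L
  j <- ((v - 1L) %/% nbin[1]) + 1L
  if (connectivity == 8) {
    di <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
    dj <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  } else {
    di <- c(-1L, 1L, 0L, 0L); dj <- c(0L, 0L, -1L, 1L)
  }
  ii <- i + di; jj <- j + dj
  ok <- ii >= 1L & ii <= nbin[1] & jj >= 1L & jj <= nbin[2]
  ii[ok] + (jj[ok] - 1L) * nbin[1]
}

# data frame describing grid nodes: flat index, per-coordinate bin index,
# coordinate centres, energy
.node_frame <- function(nodes, grid) {
  nbin <- grid$nbin
  if (grid$dim == 1L) {
    df <- data.frame(node = nodes, i1 = nodes,
                     x1 = grid$centres[[1]][nodes])
  } else {
    i <- ((nodes - 1L) %% nbin[1]) + 1L
    j <- ((nodes - 1L) %/% nbin[1]) + 1L
    df <- data.frame(node = nodes, i1 = i, i2 = j,
                     x1 = grid$centres[[1]][i], x2 = grid$centres[[2]][j])
  }
  df$energy <- grid$free_energy[nodes]
  df
}

# resolve a basin argument to a flat node index: a length-1 whole number in
# [1, n_bins] is a node index; anything else is a coordinate vector snapped
# to the nearest unmasked bin
.resolve_node <- function(grid, node) {
  node <- as.numeric(node)
  if (length(node) == 1L && node %% 1 == 0 &&
      node >= 1 && node <= length(grid$free_energy)) {
    v <- as.integer(node)
    if (grid$mask[v]) stop("node ", v, " is masked")
    return(v)
  }
  if (length(node) != grid$dim)
    stop("basin must be a node index or a ", grid$dim, "-coordinate point")
  cen <- as.matrix(do.call(expand.grid, grid$centres))
  d2 <- rowSums(sweep(cen, 2, node)^2)
  d2[grid$mask] <- Inf
  which.min(d2)
}

#' Trace the minimum-energy path between two basins
#'
#' Among all neighbour-connected grid paths between the two basins, returns
#' one minimising the maximum node energy (the bottleneck / minimax
#' criterion, i.e. the lowest pass over the landscape); ties are broken by
#' minimising total path energy, then by lexicographic node order.
#' Implemented as bottleneck Dijkstra followed by a shortest-path pass
#' restricted to the sub-level set at the bottleneck energy, so the descent
#' segments from the pass down to each basin follow low-energy (steepest
#' available) routes. Masked bins are impassable.
#'
#' @param grid an `fe_grid`.
#' @param from,to basin specifications: a flat node index (e.g. from
#'   [find_stationary_points()]'s `minima$node`) or a coordinate vector
#'   snapped to the nearest unmasked bin.
#' @param connectivity 8 (default) or 4; ignored in 1D.
#' @return a `reaction_path`: list with `nodes` (ordered flat indices),
#'   `coords` (matrix of bin-centre coordinates along the path), `energy`
#'   (kcal/mol along the path), `peak_index`, `peak_energy`.
#' @export
trace_mep <- function(grid, from, to, connectivity = 8) {
  stopifnot(inherits(grid, "fe_grid"))
  s <- .resolve_node(grid, from)
  t <- .resolve_node(grid, to)
  fe <- grid$free_energy
  nb <- length(fe)
  if (s == t) {
    return(.make_path(grid, s))
  }
  # pass 1: bottleneck Dijkstra (cost of a path = max node energy on it)
  dist <- rep(Inf, nb)
  dist[s] <- fe[s]
  done <- grid$mask  # masked nodes never enter
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    v <- cand[which.min(dist[cand])]
    if (v == t) break
    done[v] <- TRUE
    for (w in .grid_neighbours(v, grid$nbin, connectivity)) {
      if (done[w]) next
      alt <- max(dist[v], fe[w])
      if (alt < dist[w]) dist[w] <- alt
    }
  }
  if (!is.finite(dist[t])) {
    comp_s <- .component_of(grid, s, connectivity)
    stop(structure(class = c("fel_no_path", "error", "condition"), list(
      message = paste0("no path: basins at nodes ", s, " and ", t,
                       " lie in disconnected unmasked components (",
                       sum(comp_s), " nodes reachable from the start basin)"),
      call = sys.call(-1))))
  }
  bottleneck <- dist[t]
  # pass 2: min-total-energy path within the sub-level set {E <= bottleneck}
  allow <- !grid$mask & fe <= bottleneck + 1e-12
  dist2 <- rep(Inf, nb); prev <- rep(NA_integer_, nb)
  dist2[s] <- fe[s]
  done2 <- !allow
  repeat {
    cand <- which(!done2 & is.finite(dist2))
    if (!length(cand)) break
    v <- cand[which.min(dist2[cand])]  # which.min: lexicographic tie-break
    if (v == t) break
    done2[v] <- TRUE
    for (w in .grid_neighbours(v, grid$nbin, connectivity)) {
      if (done2[w]) next
      alt <- dist2[v] + fe[w]
      if (alt < dist2[w] - 1e-15) { dist2[w] <- alt; prev[w] <- v }
    }
  }
  nodes <- t
  while (nodes[1] != s) nodes <- c(prev[nodes[1]], nodes)
  .make_path(grid, nodes)
}

# single-source bottleneck Dijkstra: lowest max-energy pass from s to each
# of the target nodes (Inf where disconnected)
.bottleneck_values <- function(grid, s, targets, connectivity) {
  fe <- grid$free_energy
  dist <- rep(Inf, length(fe))
  dist[s] <- fe[s]
  done <- grid$mask
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    v <- cand[which.min(dist[cand])]
    done[v] <- TRUE
    for (w in .grid_neighbours(v, grid$nbin, connectivity)) {
      if (done[w]) next
      alt <- max(dist[v], fe[w])
      if (alt < dist[w]) dist[w] <- alt
    }
    if (all(done[targets])) break
  }
  dist[targets]
}

.component_of <- function(grid, s, connectivity) {
  seen <- logical(length(grid$free_energy))
  seen[s] <- TRUE
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      ws <- .grid_neighbours(v, grid$nbin, connectivity)
      ws <- ws[!seen[ws] & !grid$mask[ws]]
      seen[ws] <- TRUE
      nxt <- c(nxt, ws)
    }
    frontier <- nxt
  }
  seen
}

.make_path <- function(grid, nodes) {
  df <- .node_frame(nodes, grid)
  en <- df$energy
  pk <- which.max(en)
  structure(list(
    nodes = nodes,
    coords = as.matrix(df[, grep("^x", names(df)), drop = FALSE]),
    energy = en,
    peak_index = pk,
    peak_energy = en[pk]
  ), class = "reaction_path")
}

#' @export
print.reaction_path <- function(x, ...) {
  cat(sprintf("reaction_path: %d nodes, peak %.3f kcal/mol at node %d of %d\n",
              length(x$nodes), x$peak_energy, x$peak_index, length(x$nodes)))
  invisible(x)
}

#' Barrier height along a reaction path
#'
#' The free-energy barrier is the path's peak energy minus a reference
#' energy: by default the energy of the path's start node (the reactant
#' basin), or any explicit state energy.
#'
#' @param path a [trace_mep()] `reaction_path`.
#' @param reference reference energy in kcal/mol; default the start node's
#'   energy.
#' @return barrier in kcal/mol (non-negative when the reference is the path
#'   minimum).
#' @examples
#' # peak 5 over a start at 0 -> barrier 5
#' @export
extract_barrier <- function(path, reference = NULL) {
  stopifnot(inherits(path, "reaction_path"))
  if (!length(path$energy)) stop("empty path")
  if (is.null(reference)) reference <- path$energy[1]
  path$peak_energy - reference
}
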