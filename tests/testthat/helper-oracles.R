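# Independent oracles used across the suite. Everything here is written
# from first principles (enumeration, closed forms, textbook algorithms)
# and never calls the code paths it checks.

# fe_grid built directly from an energy matrix (1D vector or 2D matrix,
# column = second coordinate); for path/stationary-point tests
grid_from_matrix <- function(m, mask = NULL, bin_width = 0.1) {
  if (is.null(dim(m))) m <- matrix(m, ncol = 1)
  nbin <- dim(m)
  dim1 <- ncol(m) == 1L
  edges <- lapply(if (dim1) nbin[1] else nbin, function(n) bin_width * (0:n))
  if (dim1) nbin <- nbin[1]
  fe <- as.vector(m)
  msk <- if (is.null(mask)) rep(FALSE, length(fe)) else as.vector(mask)
  fe[msk] <- NA_real_
  structure(list(
    centres = lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2),
    edges = edges, free_energy = fe, error = rep(NA_real_, length(fe)),
    mask = msk, prob = NULL, shifts = NULL, iterations = 0L, residual = 0,
    temperature = 310.15, dim = if (dim1) 1L else 2L,
    nbin = as.integer(nbin)
  ), class = "fe_grid")
}

# 8-connected neighbours of flat index v on an nr x nc grid (oracle copy)
.or_neigh <- function(v, nr, nc, connectivity = 8) {
  i <- ((v - 1L) %% nr) + 1L
  j <- ((v - 1L) %/% nr) + 1L
  if (nc == 1L) {
    nbs <- c(v - 1L, v + 1L)
    return(nbs[nbs >= 1L & nbs <= nr])
  }
  if (connectivity == 8) {
    d <- expand.grid(di = -1:1, dj = -1:1)
    d <- d[!(d$di == 0 & d$dj == 0), ]
  } else d <- data.frame(di = c(-1, 1, 0, 0), dj = c(0, 0, -1, 1))
  ii <- i + d$di; jj <- j + d$dj
  ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
  as.integer(ii[ok] + (jj[ok] - 1) * nr)
}

# bottleneck (minimax) oracle: smallest energy level at which start and end
# are connected in the sub-level-set graph; exact, independent of Dijkstra
minimax_oracle_sweep <- function(m, s, t, mask = NULL, connectivity = 8) {
  fe <- as.vector(m)
  nr <- nrow(m); nc <- ncol(m)
  msk <- if (is.null(mask)) rep(FALSE, length(fe)) else as.vector(mask)
  for (lev in sort(unique(fe[!msk & fe >= max(fe[s], fe[t])]))) {
    ok <- !msk & fe <= lev
    if (!ok[s] || !ok[t]) next
    seen <- logical(length(fe)); seen[s] <- TRUE; frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        ws <- .or_neigh(v, nr, nc, connectivity)
        ws <- ws[ok[ws] & !seen[ws]]
        seen[ws] <- TRUE; nxt <- c(nxt, ws)
      }
      frontier <- nxt
    }
    if (seen[t]) return(lev)
  }
  Inf
}

# genuine all-simple-paths enumeration (tiny grids only): minimum over all
# simple paths of the maximum node energy
minimax_oracle_dfs <- function(m, s, t, connectivity = 8) {
  fe <- as.vector(m)
  nr <- nrow(m); nc <- ncol(m)
  best <- Inf
  visit <- function(v, peak) {
    peak <- max(peak, fe[v])
    if (peak >= best) return()
    if (v == t) { best <<- peak; return() }
    on_path[v] <<- TRUE
    for (w in .or_neigh(v, nr, nc, connectivity))
      if (!on_path[w]) visit(w, peak)
    on_path[v] <<- FALSE
  }
  on_path <- logical(length(fe))
  visit(s, -Inf)
  best
}

# textbook natural cubic spline (tridiagonal second-derivative solve),
# independent of stats::splinefun
natural_spline_oracle <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  if (n == 2) return(y[1] + (y[2] - y[1]) / h * (xout - x[1]))
  a <- numeric(n); b <- numeric(n); c <- numeric(n); d <- numeric(n)
  # solve for second derivatives M with M[1] = M[n] = 0
  A <- matrix(0, n - 2, n - 2)
  rhs <- numeric(n - 2)
  for (i in 2:(n - 1)) {
    r <- i - 1
    if (r > 1) A[r, r - 1] <- h[i - 1]
    A[r, r] <- 2 * (h[i - 1] + h[i])
    if (r < n - 2) A[r, r + 1] <- h[i]
    rhs[r] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  M <- c(0, solve(A, rhs), 0)
  vapply(xout, function(q) {
    i <- findInterval(q, x, rightmost.closed = TRUE)
    i <- min(max(i, 1L), n - 1L)
    t1 <- x[i + 1] - q; t2 <- q - x[i]
    (M[i] * t1^3 + M[i + 1] * t2^3) / (6 * h[i]) +
      (y[i] / h[i] - M[i] * h[i] / 6) * t1 +
      (y[i + 1] / h[i] - M[i + 1] * h[i] / 6) * t2
  }, numeric(1))
}

# exact rational window-centre enumeration with integer arithmetic: centres
# as integer multiples of 1/denom Angstrom
enumerate_centres_exact <- function(range, coarse_step, fine_step = NULL,
                                    fine_regions = NULL, denom = 10000L) {
  to_int <- function(v) as.integer(round(v * denom))
  cs <- to_int(coarse_step)
  lo <- to_int(range[1]); hi <- to_int(range[2])
  cen <- seq(lo, hi, by = cs)
  for (reg in fine_regions) {
    fs <- to_int(fine_step)
    f <- seq(to_int(reg[1]), to_int(reg[2]), by = fs)
    cen <- union(cen, f)
  }
  sort(cen) / denom
}

# direct (non-log-domain) WHAM fixed-point iteration for small instances
wham_oracle <- function(counts, bias, n_i, kt, tol = 1e-12, maxit = 200000) {
  W <- nrow(counts); B <- ncol(counts)
  f <- rep(0, W)
  nb <- colSums(counts)
  for (it in seq_len(maxit)) {
    den <- numeric(B)
    for (b in seq_len(B)) den[b] <- sum(n_i * exp((f - bias[, b]) / kt))
    p <- nb / den
    p <- p / sum(p)
    fnew <- vapply(seq_len(W), function(w)
      -kt * log(sum(p * exp(-bias[w, ] / kt))), numeric(1))
    fnew <- fnew - fnew[1]
    if (max(abs(fnew - f)) < tol) { f <- fnew; break }
    f <- fnew
  }
  pmf <- -kt * log(p)
  list(f = f, pmf = pmf - min(pmf[is.finite(pmf)]), p = p)
}
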