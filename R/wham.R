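#' Bin biased window samples onto a histogram grid
#'
#' Tallies every window's retained samples into per-coordinate bins.
#' Bins are half-open \[lo, hi) with the last bin closed; a sample landing
#' exactly on an interior edge is counted in the higher bin.
#'
#' @param windows a `bias_windows` table.
#' @param series list of `window_timeseries`, one per window row (matched
#'   by `window_id`).
#' @param bin_width bin width in Angstrom (default 0.02, the finest window
#'   spacing); used for every coordinate. Ignored when `edges` is given.
#' @param edges optional list of per-coordinate bin-edge vectors (strictly
#'   increasing); overrides `bin_width`.
#' @param clip if `TRUE`, samples outside the edges are silently dropped;
#'   if `FALSE` (default) they are an error.
#' @return a `histogram_grid`: list with `edges`, `centres`, `counts`
#'   (windows x bins matrix, bins flattened first-coordinate-fastest),
#'   `n_samples` per window, `dim`, `nbin` per coordinate.
#' @export
histogram_windows <- function(windows, series, bin_width = 0.02, edges = NULL,
                              clip = FALSE) {
  d <- .window_dim(windows)
  if (length(series) != nrow(windows))
    stop("need one time series per window (", nrow(windows), " windows, ",
         length(series), " series)")
  ids <- vapply(series, `[[`, integer(1), "window_id")
  ord <- match(windows$id, ids)
  if (anyNA(ord)) stop("series/window mismatch: missing window id(s) ",
                       paste(windows$id[is.na(ord)], collapse = ", "))
  series <- series[ord]
  for (s in series) if (nrow(s$samples) == 0) stop("empty series for window ", s$window_id)

  if (is.null(edges)) {
    if (bin_width <= 0) stop("bin_width must be positive")
    all_s <- do.call(rbind, lapply(series, `[[`, "samples"))
    edges <- lapply(seq_len(d), function(j) {
      rg <- range(all_s[, j])
      lo <- floor(rg[1] / bin_width) * bin_width
      n <- ceiling((rg[2] - lo) / bin_width - 1e-12)
      lo + bin_width * (0:max(n, 1L))
    })
  }
  if (!is.list(edges)) edges <- list(edges)
  stopifnot(length(edges) == d)
  for (e in edges) if (is.unsorted(e, strictly = TRUE)) stop("bin edges must be strictly increasing")

  nbin <- vapply(edges, function(e) length(e) - 1L, integer(1))
  nb_tot <- prod(nbin)
  counts <- matrix(0, nrow(windows), nb_tot)
  for (i in seq_along(series)) {
    x <- series[[i]]$samples
    idx <- matrix(0L, nrow(x), d)
    ok <- rep(TRUE, nrow(x))
    for (j in seq_len(d)) {
      b <- findInterval(x[, j], edges[[j]], rightmost.closed = TRUE)
      out <- b < 1L | b > nbin[j]
      if (any(out)) {
        if (!clip) stop("window ", windows$id[i], " has samples outside the bin edges",
                        " (enable clip to drop them)")
        ok <- ok & !out
      }
      idx[, j] <- b
    }
    idx <- idx[ok, , drop = FALSE]
    flat <- idx[, 1]
    if (d == 2L) flat <- flat + (idx[, 2] - 1L) * nbin[1]
    tab <- tabulate(flat, nbins = nb_tot)
    counts[i, ] <- tab
  }
  structure(list(
    edges = edges,
    centres = lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2),
    counts = counts,
    n_samples = rowSums(counts),
    dim = d, nbin = nbin
  ), class = "histogram_grid")
}

# log(sum(exp(v))) with -Inf safety
.lse <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

# bias energy of every window at every bin centre, kcal/mol (W x B matrix)
.bias_matrix <- function(windows, hist, bias_offsets = NULL) {
  d <- hist$dim
  cen_grid <- as.matrix(do.call(expand.grid, hist$centres))
  W <- nrow(windows)
  B <- nrow(cen_grid)
  Bm <- matrix(0, W, B)
  for (i in seq_len(W)) Bm[i, ] <- bias_energy(windows, i, cen_grid)
  if (!is.null(bias_offsets)) Bm <- Bm + rep(bias_offsets, length.out = W)
  Bm
}

#' Solve the WHAM equations for a free-energy grid
#'
#' Self-consistent weighted-histogram iteration combining all biased window
#' histograms into one unbiased probability per bin:
#' P(b) = sum_i n_i(b) / sum_i N_i exp\{\[F_i - U_i(b)\]/kB T\}, with window
#' free energies F_i = -kB T log sum_b P(b) exp\{-U_i(b)/kB T\}. All
#' accumulation is in the log domain; the shifts are gauged by F_1 = 0 and
#' iterated until max_i |dF_i| falls below `tolerance`. The returned PMF is
#' -kB T log P(b), offset so the minimum over sampled (unmasked) bins is 0;
#' bins with zero total count are masked, never imputed.
#'
#' @param hist a [histogram_windows()] grid.
#' @param windows the matching `bias_windows` table.
#' @param temperature K; defaults to the windows' declared temperature.
#' @param tolerance convergence threshold on the window shifts, kcal/mol
#'   (default 1e-6).
#' @param max_iterations iteration cap (default 1e5).
#' @param bias_offsets optional per-window constant added to the bias energy
#'   (gauge term; the PMF is invariant to it).
#' @param f_init optional warm-start vector of window shifts.
#' @return a `fe_grid`: list with `centres`, `edges`, `free_energy` (vector
#'   over flattened bins, NA where masked), `error` (NA until
#'   [bootstrap_errors()] fills it), `mask` (TRUE = unsampled), `prob`,
#'   `shifts`, `iterations`, `residual`, `temperature`, `dim`, `nbin`.
#' @seealso [compute_pmf()] for the one-call sampling + WHAM wrapper.
#' @export
solve_wham <- function(hist, windows, temperature = NULL, tolerance = 1e-6,
                       max_iterations = 1e5, bias_offsets = NULL, f_init = NULL) {
  stopifnot(inherits(hist, "histogram_grid"))
  if (nrow(windows) < 1) stop("need at least one window")
  if (is.null(temperature)) temperature <- windows$temperature[1]
  if (temperature <= 0) stop("temperature must be positive")
  kt <- kT(temperature)
  W <- nrow(hist$counts)
  Bm <- .bias_matrix(windows, hist, bias_offsets)
  tot <- colSums(hist$counts)
  mask <- tot == 0
  if (all(mask)) stop("all bins are empty")
  if (W > 1) .warn_on_disconnected_support(hist)
  log_nb <- ifelse(mask, -Inf, log(tot))
  log_Ni <- log(hist$n_samples)
  unm <- which(!mask)

  f <- if (is.null(f_init)) numeric(W) else f_init - f_init[1]
  negBu <- -Bm[, unm, drop = FALSE] / kt   # W x B', fixed
  it <- 0L; resid <- Inf
  logP_un <- NULL
  repeat {
    it <- it + 1L
    A <- negBu + (f / kt + log_Ni)         # column-recycled over rows
    m <- A[1, ]
    if (W > 1) for (w in 2:W) m <- pmax(m, A[w, ])
    logden <- m + log(colSums(exp(A - rep(m, each = W))))
    logP_un <- log_nb[unm] - logden
    logP_un <- logP_un - .lse(logP_un)     # normalise: sum_b P(b) = 1
    Cm <- negBu + rep(logP_un, each = W)
    fnew <- -kt * apply(Cm, 1, .lse)
    fnew <- fnew - fnew[1]
    resid <- max(abs(fnew - f))
    f <- fnew
    if (resid < tolerance || it >= max_iterations) break
  }
  if (resid >= tolerance)
    warning("WHAM did not converge in ", max_iterations,
            " iterations (residual ", signif(resid, 3), " kcal/mol)")

  fe <- rep(NA_real_, length(tot))
  fe[unm] <- -kt * logP_un
  fe[unm] <- fe[unm] - min(fe[unm])
  prob <- rep(0, length(tot))
  prob[unm] <- exp(logP_un)
  structure(list(
    centres = hist$centres, edges = hist$edges,
    free_energy = fe, error = rep(NA_real_, length(tot)),
    mask = mask, prob = prob, shifts = f,
    iterations = it, residual = resid,
    temperature = temperature, dim = hist$dim, nbin = hist$nbin
  ), class = "fe_grid")
}

# window-overlap check; disconnected support only warns: WHAM still solves,
# but relative PMF offsets across the gap are arbitrary and path tracing
# across it will fail downstream
.warn_on_disconnected_support <- function(hist) {
  occ <- hist$counts > 0
  visited <- c(TRUE, rep(FALSE, nrow(occ) - 1L))
  repeat {
    covered <- colSums(occ[visited, , drop = FALSE]) > 0
    reach <- as.vector(occ %*% covered) > 0 & !visited
    if (!any(reach)) break
    visited <- visited | reach
  }
  if (!all(visited))
    warning("histogram support is disconnected: window(s) ",
            paste(which(!visited), collapse = ", "),
            " share no occupied bin with the rest")
  invisible(NULL)
}

#' @export
print.fe_grid <- function(x, ...) {
  cat(sprintf("fe_grid: %s bins (%dD), %d masked; T = %.2f K\n",
              paste(x$nbin, collapse = " x "), x$dim, sum(x$mask), x$temperature))
  cat(sprintf("  WHAM converged in %d iterations (residual %.3g kcal/mol)\n",
              x$iterations, x$residual))
  rng <- range(x$free_energy, na.rm = TRUE)
  cat(sprintf("  free energy range [%.3f, %.3f] kcal/mol", rng[1], rng[2]))
  if (any(is.finite(x$error))) cat(sprintf("; median bootstrap error %.3f",
                                           stats::median(x$error, na.rm = TRUE)))
  cat("\n")
  invisible(x)
}

#' Monte Carlo bootstrap errors for a WHAM free-energy grid
#'
#' For each replicate the retained samples of every window are resampled
#' with replacement (replicate size = original size; realised as a
#' multinomial redraw of that window's histogram counts, which is the same
#' distribution), WHAM is re-solved warm-started from the base solution,
#' and every replicate PMF is offset-aligned at the base solution's
#' global-minimum bin. The reported error is the per-bin standard deviation
#' across replicates.
#'
#' @param hist a [histogram_windows()] grid.
#' @param windows the matching `bias_windows` table.
#' @param n_boot number of replicates (>= 2).
#' @param seed integer RNG seed.
#' @param temperature,tolerance,max_iterations as in [solve_wham()].
#' @param base optional precomputed [solve_wham()] solution to align against
#'   (recomputed if missing).
#' @param series optional list of `window_timeseries`; when given together
#'   with `block_length`, contiguous blocks of the raw series are resampled
#'   instead of individual samples (for serially correlated input).
#' @param block_length block size in samples for the block bootstrap.
#' @param resample set `FALSE` to disable resampling (degenerate mode: all
#'   errors are exactly 0; used to validate the machinery).
#' @return an `fe_grid` equal to `base` with the `error` field filled
#'   (NA on masked bins).
#' @export
bootstrap_errors <- function(hist, windows, n_boot = 50, seed = 1,
                             temperature = NULL, tolerance = 1e-6,
                             max_iterations = 1e5, base = NULL,
                             series = NULL, block_length = NULL,
                             resample = TRUE) {
  if (n_boot < 2) stop("n_boot must be >= 2")
  if (is.null(base))
    base <- solve_wham(hist, windows, temperature, tolerance, max_iterations)
  ref_bin <- which.min(ifelse(base$mask, Inf, base$free_energy))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  nb <- length(base$free_energy)
  reps <- matrix(NA_real_, n_boot, nb)
  for (r in seq_len(n_boot)) {
    h <- hist
    if (resample) {
      if (!is.null(series) && !is.null(block_length)) {
        h <- .block_resample_hist(hist, windows, series, block_length)
      } else {
        for (i in seq_len(nrow(hist$counts))) {
          n <- hist$n_samples[i]
          h$counts[i, ] <- as.numeric(stats::rmultinom(1, n, hist$counts[i, ] / n))
        }
        h$n_samples <- rowSums(h$counts)
      }
    }
    sol <- suppressWarnings(solve_wham(h, windows, temperature, tolerance,
                                       max_iterations, f_init = base$shifts))
    fe <- sol$free_energy
    anchor <- fe[ref_bin]
    if (!is.finite(anchor)) anchor <- min(fe, na.rm = TRUE)
    reps[r, ] <- fe - anchor
  }
  err <- apply(reps, 2, function(v) {
    v <- v[is.finite(v)]
    if (length(v) >= 2) stats::sd(v) else NA_real_
  })
  err[base$mask] <- NA_real_
  base$error <- err
  base
}

# block bootstrap: resample contiguous blocks of each raw series, re-bin
.block_resample_hist <- function(hist, windows, series, block_length) {
  ids <- vapply(series, `[[`, integer(1), "window_id")
  series <- series[match(windows$id, ids)]
  new_series <- lapply(series, function(s) {
    n <- nrow(s$samples)
    bl <- min(max(1L, as.integer(block_length)), n)
    nblk <- ceiling(n / bl)
    starts <- sample.int(n - bl + 1L, nblk, replace = TRUE)
    idx <- as.vector(vapply(starts, function(st) st + 0:(bl - 1L), integer(bl)))[seq_len(n)]
    s$samples <- s$samples[idx, , drop = FALSE]
    s
  })
  histogram_windows(windows, new_series, edges = hist$edges, clip = TRUE)
}

#' Sample, histogram and solve in one call
#'
#' Convenience wrapper running [sample_windows()], [histogram_windows()],
#' [solve_wham()] and optionally [bootstrap_errors()].
#'
#' @param landscape a [make_surface()] landscape.
#' @param windows a `bias_windows` table.
#' @param seed base seed for sampling (bootstrap uses `seed + 1`).
#' @param bin_width histogram bin width, Angstrom.
#' @param n_boot bootstrap replicates (0 disables error bars).
#' @param tolerance,max_iterations passed to [solve_wham()].
#' @param ... passed to [sample_window()].
#' @return an `fe_grid`.
#' @export
compute_pmf <- function(landscape, windows, seed, bin_width = 0.02,
                        n_boot = 0, tolerance = 1e-6, max_iterations = 1e5, ...) {
  series <- sample_windows(landscape, windows, seed, ...)
  hist <- histogram_windows(windows, series, bin_width = bin_width)
  grid <- solve_wham(hist, windows, tolerance = tolerance,
                     max_iterations = max_iterations)
  if (n_boot >= 2)
    grid <- bootstrap_errors(hist, windows, n_boot = n_boot, seed = seed + 1,
                             tolerance = tolerance,
                             max_iterations = max_iterations, base = grid)
  grid
}
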