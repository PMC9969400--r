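#' Build an umbrella-sampling window grid
#'
#' Lays out harmonic-restraint window centres over the reaction-coordinate
#' ranges: a coarse grid (default 0.1 A, the usual scan step) everywhere,
#' optionally refined to a fine step (default 0.02 A, used near transition
#' states) inside explicit sub-regions. Centres are generated by integer
#' index from the range lower bound — never by floating-point accumulation —
#' with both endpoints included; fine-region centres are de-duplicated
#' against coarse centres within 1e-9 A. For two coordinates the window set
#' is the Cartesian product of the per-coordinate centre lists, e.g. the
#' standard 2D landscape scheme over \[1.4, 2.5\] x \[1.0, 2.0\] A at 0.1 A
#' yields 12 x 11 = 132 windows.
#'
#' @param ranges a closed interval `c(lo, hi)` or a list of one such
#'   interval per coordinate.
#' @param coarse_step grid spacing in Angstrom (default 0.1).
#' @param fine_step spacing inside `fine_regions` (default 0.02); must be
#'   smaller than `coarse_step` when fine regions are given.
#' @param fine_regions `NULL`, or a list (per coordinate) of lists of
#'   sub-intervals of that coordinate's range to tile at `fine_step`. For a
#'   1D scheme a plain list of intervals is accepted.
#' @param force_constant harmonic restraint force constant, kcal/mol/A^2.
#'   The default is the declared 200 kJ/mol/A^2 converted with
#'   [kj_to_kcal()].
#' @param n_samples samples to retain per window (default 5000).
#' @param temperature K (default 310.15).
#' @return a `bias_windows` data frame: `id`, `centre_1` (and `centre_2`),
#'   `force_constant`, `n_samples`, `temperature`.
#' @examples
#' w <- generate_window_grid(list(c(1.4, 2.5), c(1.0, 2.0)), coarse_step = 0.1)
#' nrow(w)  # 132
#' @export
generate_window_grid <- function(ranges, coarse_step = 0.1, fine_step = 0.02,
                                 fine_regions = NULL,
                                 force_constant = kj_to_kcal(200),
                                 n_samples = 5000,
                                 temperature = fel_constants$T_default) {
  if (is.numeric(ranges)) ranges <- list(ranges)
  stopifnot(is.list(ranges), length(ranges) %in% c(1L, 2L))
  if (coarse_step <= 0) stop("coarse_step must be positive")
  if (!is.null(fine_regions)) {
    if (!(fine_step > 0 && fine_step < coarse_step))
      stop("need coarse_step > fine_step > 0 when fine regions are given")
    if (length(ranges) == 1L && !is.list(fine_regions[[1]]))
      fine_regions <- list(fine_regions)
    stopifnot(length(fine_regions) <= length(ranges))
  }
  if (force_constant <= 0) stop("force_constant must be positive")
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (temperature <= 0) stop("temperature must be positive")

  centres <- vector("list", length(ranges))
  for (d in seq_along(ranges)) {
    rg <- ranges[[d]]
    if (!(length(rg) == 2 && rg[1] <= rg[2])) stop("range ", d, " is empty or malformed")
    cs <- .tile(rg, coarse_step)
    fr <- if (!is.null(fine_regions) && length(fine_regions) >= d) fine_regions[[d]] else NULL
    for (reg in fr) {
      if (!(reg[1] >= rg[1] - 1e-9 && reg[2] <= rg[2] + 1e-9 && reg[1] <= reg[2]))
        stop("fine region [", reg[1], ", ", reg[2], "] outside range ", d)
      fs <- .tile(reg, fine_step)
      keep <- vapply(fs, function(v) all(abs(v - cs) > 1e-9), logical(1))
      cs <- c(cs, fs[keep])
    }
    cs <- sort(cs)
    centres[[d]] <- cs[c(TRUE, diff(cs) > 1e-9)]  # de-duplicate overlapping fine regions
  }

  grid <- do.call(expand.grid, c(centres, KEEP.OUT.ATTRS = FALSE))
  names(grid) <- paste0("centre_", seq_along(centres))
  w <- data.frame(id = seq_len(nrow(grid)), grid,
                  force_constant = force_constant,
                  n_samples = as.integer(n_samples),
                  temperature = temperature)
  class(w) <- c("bias_windows", "data.frame")
  w
}

# inclusive tiling of [lo, hi] by integer index; endpoint kept if it lands
# within 1e-9 of an index point or the interval is degenerate
.tile <- function(rg, step) {
  n <- floor((rg[2] - rg[1]) / step + 1e-9)
  rg[1] + step * (0:n)
}

#' @export
print.bias_windows <- function(x, ...) {
  ncoord <- sum(grepl("^centre_", names(x)))
  cat(sprintf("bias_windows: %d umbrella windows over %d coordinate(s)\n",
              nrow(x), ncoord))
  cat(sprintf("  force constant %.4f kcal/mol/A^2, %d samples/window, %.2f K\n",
              x$force_constant[1], x$n_samples[1], x$temperature[1]))
  NextMethod()
}

# number of coordinates of a window table
.window_dim <- function(windows) sum(grepl("^centre_", names(windows)))

# centre of one window as a numeric vector
.window_centre <- function(windows, i) {
  as.numeric(windows[i, paste0("centre_", seq_len(.window_dim(windows)))])
}

# harmonic bias energy of points x (matrix) under window i, kcal/mol
bias_energy <- function(windows, i, x) {
  cen <- .window_centre(windows, i)
  k <- windows$force_constant[i]
  0.5 * k * rowSums(sweep(.as_points(x, length(cen)), 2, cen)^2)
}
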