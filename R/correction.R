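#' Anchor set for a dual-level energy correction
#'
#' Holds matched low-level (semiempirical) and high-level (DFT) energies at
#' anchor structures along a reaction path, parameterised by a strictly
#' increasing progress coordinate (the reaction-coordinate value for 1D
#' profiles; cumulative arc length for 2D paths). The per-anchor difference
#' dE = high - low is always recomputed from the two energy lists.
#'
#' @param positions strictly increasing numeric progress values (>= 2).
#' @param low,high energies at the anchors, kcal/mol.
#' @return a `correction_anchors` data frame with columns `position`,
#'   `low`, `high`, `delta`.
#' @export
correction_anchors <- function(positions, low, high) {
  stopifnot(is.numeric(positions), is.numeric(low), is.numeric(high))
  if (length(positions) < 2) stop("need at least 2 anchors")
  if (length(low) != length(positions) || length(high) != length(positions))
    stop("positions, low and high must have equal length")
  if (any(diff(positions) <= 0))
    stop("anchor positions must be strictly increasing (duplicates are not allowed)")
  structure(data.frame(position = positions, low = low, high = high,
                       delta = high - low),
            class = c("correction_anchors", "data.frame"))
}

#' Build the dual-level correction spline
#'
#' Fits a natural cubic spline S through the anchor differences
#' (position_j, dE_j), dE = E_high - E_low, reproducing every dE_j exactly.
#' The corrected profile E_corr = E_low + S(position) is produced by
#' [apply_correction()]. With exactly two anchors the natural spline is the
#' straight line through them. S is defined only on
#' \[first anchor, last anchor\]; evaluation outside that span is an error,
#' never an extrapolation.
#'
#' @param anchors a [correction_anchors()] object (or a data frame with
#'   `position`, `low`, `high`).
#' @return a `correction_spline`: list with `position`, `delta`, `boundary`
#'   (`"natural"`), and `span`.
#' @export
build_correction <- function(anchors) {
  if (!inherits(anchors, "correction_anchors"))
    anchors <- correction_anchors(anchors$position, anchors$low, anchors$high)
  structure(list(position = anchors$position, delta = anchors$delta,
                 boundary = "natural",
                 span = range(anchors$position)),
            class = "correction_spline")
}

#' Evaluate a correction spline
#'
#' @param spline a [build_correction()] object.
#' @param position numeric query positions, all within the anchor span.
#' @return S(position), kcal/mol.
#' @export
eval_correction <- function(spline, position) {
  stopifnot(inherits(spline, "correction_spline"))
  tol <- 1e-9
  if (any(position < spline$span[1] - tol | position > spline$span[2] + tol))
    stop("query position outside the anchor span [",
         spline$span[1], ", ", spline$span[2], "]; extrapolation is not allowed")
  f <- stats::splinefun(spline$position, spline$delta, method = "natural")
  f(pmin(pmax(position, spline$span[1]), spline$span[2]))
}

#' @export
print.correction_spline <- function(x, ...) {
  cat(sprintf("correction_spline: %d anchors on [%g, %g], %s boundary\n",
              length(x$position), x$span[1], x$span[2], x$boundary))
  cat(sprintf("  dE range [%.4f, %.4f] kcal/mol\n", min(x$delta), max(x$delta)))
  invisible(x)
}

#' Apply a dual-level correction to a low-level profile
#'
#' Element-wise E_corr = E_low + S(position); by default the corrected
#' energies are re-offset so their minimum is 0 (relative barriers are
#' invariant to any constant part of S). The input vector is not modified.
#'
#' @param profile_energies low-level energies along the path, kcal/mol.
#' @param positions matching progress values (within the spline's span).
#' @param spline a [build_correction()] object.
#' @param offset re-offset so min = 0 (default TRUE).
#' @return corrected energies, kcal/mol.
#' @export
apply_correction <- function(profile_energies, positions, spline, offset = TRUE) {
  stopifnot(length(profile_energies) == length(positions))
  out <- profile_energies + eval_correction(spline, positions)
  if (offset) out <- out - min(out)
  out
}

#' Progress coordinate of a reaction path
#'
#' For a 1D path, the reaction-coordinate value at each node; for a 2D
#' path, the cumulative Euclidean arc length along the traced path
#' (starting at 0).
#'
#' @param path a [trace_mep()] `reaction_path`.
#' @return numeric progress values, one per path node.
#' @export
path_progress <- function(path) {
  stopifnot(inherits(path, "reaction_path"))
  if (ncol(path$coords) == 1L) return(path$coords[, 1])
  steps <- sqrt(rowSums(diff(path$coords)^2))
  c(0, cumsum(steps))
}
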