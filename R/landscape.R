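#' Analytic surrogate energy landscapes
#'
#' A `surrogate_landscape` is a closed-form potential energy surface over one
#' or two reaction coordinates (Angstrom), standing in for the semiempirical
#' QM/MM surface an MD engine would provide. Every preset carries its exact
#' stationary points (minima and saddles, with energies) so that downstream
#' estimates — sampled histograms, WHAM profiles, traced paths, extracted
#' barriers — can be checked against closed-form values.
#'
#' Available presets:
#' \describe{
#'   \item{`harmonic`}{U = sum_d kappa/2 (x_d - centre_d)^2. Parameters:
#'     `kappa` (kcal/mol/A^2, default 2), `centre` (default 0), `dim`
#'     (1 or 2, default 1), `domain` (default \[-1, 1\] per coordinate).}
#'   \item{`double_well_1d`}{U = h * 16 u^2 (1-u)^2 with u = (x - a)/(b - a):
#'     two equal minima at `wells` a, b (default 1.2 and 2.2 A, energy 0) and
#'     one saddle at the midpoint with energy `barrier` (default 5 kcal/mol).}
#'   \item{`double_well_2d`}{the 1D double well along the first (heavy-atom)
#'     coordinate plus a harmonic term kappa_y/2 (y - centre_y)^2 in the
#'     second (proton) coordinate; two minima and one saddle, all at
#'     y = `centre_y`.}
#'   \item{`four_state_2d`}{a sextic triple well along the first coordinate
#'     (derivative constructed as a quintic with prescribed roots, so minima
#'     and saddles sit exactly at `minima_x` and `saddles_x`) plus the same
#'     harmonic transverse term; three minima and two saddles, mimicking a
#'     reactant / tetrahedral-intermediate / acyl-enzyme profile
#'     (RC -> TS1 -> TI1 -> TS2 -> EAM). The amplitude is scaled so the
#'     highest saddle sits `barrier` kcal/mol above the global minimum.}
#' }
#'
#' @param preset_name one of `"harmonic"`, `"double_well_1d"`,
#'   `"double_well_2d"`, `"four_state_2d"`.
#' @param parameters named list overriding preset defaults (see Details).
#' @return An object of class `surrogate_landscape`: a list with `name`,
#'   `dim`, `domain` (list of per-coordinate closed intervals), `params`,
#'   `stationary` (list with data frames `minima` and `saddles`, coordinates
#'   plus `energy`), and internal energy/gradient closures.
#' @examples
#' l <- make_surface("double_well_1d")
#' landscape_energy(l, 1.7)          # the barrier top, 5 kcal/mol
#' l$stationary$saddles
#' @export
make_surface <- function(preset_name, parameters = list()) {
  stopifnot(is.character(preset_name), length(preset_name) == 1)
  if (!is.list(parameters)) stop("`parameters` must be a named list")
  builder <- switch(preset_name,
    harmonic       = .surface_harmonic,
    double_well_1d = .surface_double_well_1d,
    double_well_2d = .surface_double_well_2d,
    four_state_2d  = .surface_four_state_2d,
    stop("unknown preset: '", preset_name, "'")
  )
  l <- builder(parameters)
  l$preset <- preset_name
  class(l) <- "surrogate_landscape"
  .validate_landscape(l)
  l
}

.validate_landscape <- function(l) {
  stopifnot(l$dim %in% c(1L, 2L), length(l$domain) == l$dim)
  for (iv in l$domain) {
    if (!(length(iv) == 2 && is.finite(iv[1]) && is.finite(iv[2]) && iv[1] <= iv[2]))
      stop("domain must be a finite closed interval per coordinate")
  }
  # energy must be finite everywhere on the domain: probe a coarse grid
  probe <- lapply(l$domain, function(iv) seq(iv[1], iv[2], length.out = 25))
  pts <- as.matrix(do.call(expand.grid, probe))
  if (!all(is.finite(landscape_energy(l, pts))))
    stop("landscape energy is not finite on its domain")
  invisible(l)
}

.as_points <- function(x, dim) {
  if (is.null(dim(x))) {
    if (length(x) == dim) x <- matrix(x, nrow = 1)
    else if (dim == 1L) x <- matrix(x, ncol = 1)
    else stop("points must have ", dim, " coordinates")
  }
  x <- as.matrix(x)
  if (ncol(x) != dim) stop("points must have ", dim, " coordinates")
  storage.mode(x) <- "double"
  x
}

#' Evaluate a surrogate landscape
#'
#' @param landscape a `surrogate_landscape`.
#' @param x a numeric vector (one point, or many points for a 1D landscape)
#'   or a matrix with one point per row.
#' @return `landscape_energy`: numeric vector of energies (kcal/mol).
#'   `landscape_gradient`: matrix of analytic gradients (kcal/mol/A), one row
#'   per point.
#' @export
landscape_energy <- function(landscape, x) {
  stopifnot(inherits(landscape, "surrogate_landscape"))
  landscape$energy_fn(.as_points(x, landscape$dim))
}

#' @rdname landscape_energy
#' @export
landscape_gradient <- function(landscape, x) {
  stopifnot(inherits(landscape, "surrogate_landscape"))
  landscape$grad_fn(.as_points(x, landscape$dim))
}

#' Evaluate a landscape on a regular bin grid
#'
#' Builds an `fe_grid` (the container produced by [solve_wham()]) directly
#' from the analytic surface, with no sampling and no masked bins: the
#' noise-free reference for the path and stationary-point machinery.
#'
#' @param landscape a [make_surface()] landscape.
#' @param bin_width bin width in Angstrom (default 0.02).
#' @return an `fe_grid` with `free_energy` = U at the bin centres, offset
#'   so the minimum is 0.
#' @export
landscape_to_grid <- function(landscape, bin_width = 0.02) {
  stopifnot(inherits(landscape, "surrogate_landscape"))
  edges <- lapply(landscape$domain, function(iv) {
    n <- ceiling((iv[2] - iv[1]) / bin_width - 1e-9)
    iv[1] + bin_width * (0:max(n, 1L))
  })
  centres <- lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2)
  nbin <- vapply(edges, function(e) length(e) - 1L, integer(1))
  cen <- as.matrix(do.call(expand.grid, centres))
  fe <- landscape_energy(landscape, cen)
  fe <- fe - min(fe)
  structure(list(
    centres = centres, edges = edges, free_energy = fe,
    error = rep(NA_real_, length(fe)), mask = rep(FALSE, length(fe)),
    prob = NULL, shifts = NULL, iterations = 0L, residual = 0,
    temperature = fel_constants$T_default, dim = landscape$dim, nbin = nbin
  ), class = "fe_grid")
}

#' @export
print.surrogate_landscape <- function(x, ...) {
  cat("surrogate landscape '", x$preset, "' (", x$dim, "D)\n", sep = "")
  for (d in seq_len(x$dim))
    cat(sprintf("  coord %d domain: [%g, %g] A\n", d, x$domain[[d]][1], x$domain[[d]][2]))
  cat("  minima:\n")
  print(x$stationary$minima, row.names = FALSE)
  if (nrow(x$stationary$saddles)) {
    cat("  saddles:\n")
    print(x$stationary$saddles, row.names = FALSE)
  } else cat("  saddles: none\n")
  invisible(x)
}

.merge_params <- function(defaults, parameters) {
  unknown <- setdiff(names(parameters), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s) for this preset: ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, parameters)
}

.surface_harmonic <- function(parameters) {
  p <- .merge_params(list(kappa = 2, centre = 0, dim = 1L, domain = NULL), parameters)
  if (any(p$kappa <= 0)) stop("kappa must be positive (energy unbounded below otherwise)")
  d <- as.integer(p$dim)
  kappa <- rep_len(p$kappa, d)
  centre <- rep_len(p$centre, d)
  domain <- p$domain
  if (is.null(domain)) domain <- lapply(centre, function(c0) c(c0 - 1, c0 + 1))
  if (is.numeric(domain)) domain <- list(domain)
  minima <- as.data.frame(c(as.list(centre), list(energy = 0)))
  names(minima) <- c(paste0("x", seq_len(d)), "energy")
  list(
    dim = d, domain = domain,
    params = list(kappa = kappa, centre = centre),
    energy_fn = function(x) {
      as.numeric(sweep(x, 2, centre)^2 %*% (kappa / 2))
    },
    grad_fn = function(x) sweep(sweep(x, 2, centre), 2, kappa, `*`),
    stationary = list(minima = minima,
                      saddles = minima[0, , drop = FALSE])
  )
}

# quartic double well along one axis: h * 16 u^2 (1-u)^2, u = (x-a)/(b-a)
.dw_energy <- function(x, a, b, h) {
  u <- (x - a) / (b - a)
  16 * h * u^2 * (1 - u)^2
}
.dw_grad <- function(x, a, b, h) {
  u <- (x - a) / (b - a)
  32 * h * u * (1 - u) * (1 - 2 * u) / (b - a)
}

.surface_double_well_1d <- function(parameters) {
  p <- .merge_params(list(wells = c(1.2, 2.2), barrier = 5, domain = NULL), parameters)
  a <- p$wells[1]; b <- p$wells[2]
  if (!(a < b)) stop("wells must be ordered a < b")
  if (p$barrier <= 0) stop("barrier must be positive")
  domain <- if (is.null(p$domain)) c(a - 0.4, b + 0.4) else p$domain
  s <- (a + b) / 2
  list(
    dim = 1L, domain = list(domain),
    params = p[c("wells", "barrier")],
    energy_fn = function(x) .dw_energy(x[, 1], a, b, p$barrier),
    grad_fn = function(x) matrix(.dw_grad(x[, 1], a, b, p$barrier), ncol = 1),
    stationary = list(
      minima  = data.frame(x1 = c(a, b), energy = c(0, 0)),
      saddles = data.frame(x1 = s, energy = p$barrier)
    )
  )
}

.surface_double_well_2d <- function(parameters) {
  p <- .merge_params(list(wells = c(1.2, 2.2), barrier = 5, kappa_y = 4,
                          centre_y = 1.5, domain = NULL), parameters)
  a <- p$wells[1]; b <- p$wells[2]
  if (!(a < b)) stop("wells must be ordered a < b")
  if (p$barrier <= 0 || p$kappa_y <= 0) stop("barrier and kappa_y must be positive")
  domain <- p$domain
  if (is.null(domain)) domain <- list(c(a - 0.4, b + 0.4), c(p$centre_y - 0.5, p$centre_y + 0.5))
  s <- (a + b) / 2
  list(
    dim = 2L, domain = domain,
    params = p[c("wells", "barrier", "kappa_y", "centre_y")],
    energy_fn = function(x)
      .dw_energy(x[, 1], a, b, p$barrier) + p$kappa_y / 2 * (x[, 2] - p$centre_y)^2,
    grad_fn = function(x)
      cbind(.dw_grad(x[, 1], a, b, p$barrier), p$kappa_y * (x[, 2] - p$centre_y)),
    stationary = list(
      minima  = data.frame(x1 = c(a, b), x2 = p$centre_y, energy = c(0, 0)),
      saddles = data.frame(x1 = s, x2 = p$centre_y, energy = p$barrier)
    )
  )
}

# Triple well whose derivative is A * (x-m1)(x-s1)(x-m2)(x-s2)(x-m3): the
# stationary points are exactly the prescribed roots; energies follow by
# integrating the quintic analytically (polynomial coefficients below).
.surface_four_state_2d <- function(parameters) {
  p <- .merge_params(list(minima_x = c(1.2, 1.7, 2.2), saddles_x = c(1.43, 1.95),
                          barrier = 6, kappa_y = 4, centre_y = 1.5,
                          domain = NULL), parameters)
  r <- sort(c(p$minima_x, p$saddles_x))
  if (length(p$minima_x) != 3 || length(p$saddles_x) != 2)
    stop("four_state_2d needs 3 minima_x and 2 saddles_x")
  if (!all(r == c(p$minima_x[1], p$saddles_x[1], p$minima_x[2],
                  p$saddles_x[2], p$minima_x[3])))
    stop("minima_x and saddles_x must interleave: m1 < s1 < m2 < s2 < m3")
  if (p$barrier <= 0 || p$kappa_y <= 0) stop("barrier and kappa_y must be positive")
  # expand prod(x - r_i) into ascending coefficients, then integrate termwise
  cf <- 1
  for (ri in r) cf <- c(0, cf) - c(ri * cf, 0)  # multiply by (x - ri)
  icf <- cf / seq_along(cf)                     # coeffs of x^1 .. x^6
  poly_u <- function(x) {
    acc <- 0
    for (k in rev(seq_along(icf))) acc <- acc * x + icf[k]
    acc * x
  }
  u_min <- poly_u(p$minima_x); u_sad <- poly_u(p$saddles_x)
  amp <- p$barrier / (max(u_sad) - min(u_min))  # positive leading coeff: outer roots are minima
  e0 <- amp * min(u_min)
  poly_g <- function(x) {
    acc <- 0
    for (k in rev(seq_along(cf))) acc <- acc * x + cf[k]
    acc
  }
  domain <- p$domain
  if (is.null(domain)) domain <- list(c(r[1] - 0.2, r[5] + 0.2),
                                      c(p$centre_y - 0.5, p$centre_y + 0.5))
  list(
    dim = 2L, domain = domain,
    params = p[c("minima_x", "saddles_x", "barrier", "kappa_y", "centre_y")],
    energy_fn = function(x)
      amp * poly_u(x[, 1]) - e0 + p$kappa_y / 2 * (x[, 2] - p$centre_y)^2,
    grad_fn = function(x)
      cbind(amp * poly_g(x[, 1]), p$kappa_y * (x[, 2] - p$centre_y)),
    stationary = list(
      minima  = data.frame(x1 = p$minima_x, x2 = p$centre_y,
                           energy = amp * u_min - e0),
      saddles = data.frame(x1 = p$saddles_x, x2 = p$centre_y,
                           energy = amp * u_sad - e0)
    )
  )
}
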