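#' Sample one umbrella window by Metropolis Monte Carlo
#'
#' Draws coordinate samples from the biased Boltzmann density
#' p(x) ~ exp\{-\[U(x) + sum_d k/2 (x_d - c_d)^2\] / kB T\} on the landscape
#' domain (proposals outside the domain are rejected, i.e. the density is
#' truncated to the domain). A stand-in for the restrained MD engine: only
#' the stationary distribution matters to the downstream WHAM stage, so a
#' Metropolis chain with Gaussian proposals is sufficient. The proposal
#' scale is auto-tuned during burn-in towards 30-50% acceptance and then
#' frozen; the burn-in (first 20% of the chain by default) is discarded and
#' its length recorded. Identical `(landscape, window, seed)` inputs
#' reproduce the output bit-for-bit.
#'
#' @param landscape a [make_surface()] landscape.
#' @param window one row of a `bias_windows` table (or a list with `id`,
#'   `centre_1` (`centre_2`), `force_constant`, `n_samples`, `temperature`).
#' @param seed integer RNG seed (required; the global RNG state is restored
#'   on exit).
#' @param proposal_scale initial Gaussian proposal standard deviation in
#'   Angstrom; defaults to the restrained harmonic width
#'   sqrt(kB T / force_constant) scaled by 2.4/sqrt(d).
#' @param burn_in_fraction fraction of the total chain discarded as burn-in
#'   (default 0.2).
#' @param thin keep every `thin`-th post-burn-in state (default 1).
#' @return a `window_timeseries`: list with `window_id`, `samples` (matrix,
#'   `n_samples` rows), `seed`, `burn_in_discarded`, `acceptance_rate`,
#'   `proposal_scale`.
#' @examples
#' l <- make_surface("harmonic", list(kappa = 1, domain = c(-5, 5)))
#' w <- generate_window_grid(c(0, 0), force_constant = 1e-12, n_samples = 2000)
#' ts <- sample_window(l, w[1, ], seed = 7)
#' var(ts$samples[, 1])  # ~ kB*T/kappa
#' @export
sample_window <- function(landscape, window, seed, proposal_scale = NULL,
                          burn_in_fraction = 0.2, thin = 1L) {
  stopifnot(inherits(landscape, "surrogate_landscape"))
  if (missing(seed)) stop("an explicit seed is required")
  d <- landscape$dim
  cen <- as.numeric(window[paste0("centre_", seq_len(d))])
  k <- as.numeric(window[["force_constant"]])
  n_keep <- as.integer(window[["n_samples"]])
  temperature <- as.numeric(window[["temperature"]])
  if (temperature <= 0) stop("temperature must be positive")
  if (anyNA(cen) || length(cen) != d) stop("window centre does not match landscape dimensionality")
  lo <- vapply(landscape$domain, `[`, numeric(1), 1)
  hi <- vapply(landscape$domain, `[`, numeric(1), 2)
  if (any(cen < lo) || any(cen > hi)) stop("window centre outside landscape domain")
  beta <- 1 / kT(temperature)
  if (is.null(proposal_scale))
    proposal_scale <- 2.4 / sqrt(d) * sqrt(1 / (beta * max(k, 1e-6)))
  if (proposal_scale <= 0) stop("proposal scale must be positive")
  thin <- max(1L, as.integer(thin))

  n_prod <- n_keep * thin
  total <- ceiling(n_prod / (1 - burn_in_fraction))
  burn <- total - n_prod

  u_total <- function(x) {
    landscape$energy_fn(matrix(x, nrow = 1)) + 0.5 * k * sum((x - cen)^2)
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  zs <- matrix(stats::rnorm(total * d), total, d)
  logu <- log(stats::runif(total))

  x <- pmin(pmax(cen, lo), hi)
  e <- u_total(x)
  scale <- proposal_scale
  acc_window <- 0L; acc_total <- 0L
  keep <- matrix(NA_real_, n_keep, d)
  ik <- 0L
  for (t in seq_len(total)) {
    prop <- x + scale * zs[t, ]
    if (all(prop >= lo) && all(prop <= hi)) {
      ep <- u_total(prop)
      if (logu[t] < beta * (e - ep)) {
        x <- prop; e <- ep
        acc_window <- acc_window + 1L
        if (t > burn) acc_total <- acc_total + 1L
      }
    }
    if (t <= burn) {
      if (t %% 50L == 0L) {  # adapt only during burn-in
        rate <- acc_window / 50
        if (rate < 0.3) scale <- scale * 0.8
        else if (rate > 0.5) scale <- scale * 1.25
        acc_window <- 0L
      }
    } else if ((t - burn) %% thin == 0L) {
      ik <- ik + 1L
      keep[ik, ] <- x
    }
  }

  structure(list(
    window_id = as.integer(window[["id"]]),
    samples = keep,
    seed = as.integer(seed),
    burn_in_discarded = as.integer(burn),
    acceptance_rate = acc_total / n_prod,
    proposal_scale = scale
  ), class = "window_timeseries")
}

#' @export
print.window_timeseries <- function(x, ...) {
  cat(sprintf("window_timeseries: window %d, %d samples (%dD), seed %d\n",
              x$window_id, nrow(x$samples), ncol(x$samples), x$seed))
  cat(sprintf("  burn-in discarded %d, acceptance %.2f, proposal scale %.4g A\n",
              x$burn_in_discarded, x$acceptance_rate, x$proposal_scale))
  invisible(x)
}

#' Sample every window of a grid
#'
#' Runs [sample_window()] over all rows of a window table with per-window
#' seeds derived deterministically from one base seed.
#'
#' @param landscape a [make_surface()] landscape.
#' @param windows a `bias_windows` table.
#' @param seed base integer seed; window i uses an independent substream
#'   seed drawn from it.
#' @param ... passed to [sample_window()].
#' @return list of `window_timeseries`, one per window row.
#' @export
sample_windows <- function(landscape, windows, seed, ...) {
  seeds <- derive_seeds(seed, nrow(windows))
  lapply(seq_len(nrow(windows)), function(i)
    sample_window(landscape, windows[i, ], seed = seeds[i], ...))
}

#' Derive reproducible substream seeds from a base seed
#'
#' @param seed base integer seed.
#' @param n number of substream seeds.
#' @return integer vector of `n` distinct seeds in `[1, 2^31 - 1]`.
#' @export
derive_seeds <- function(seed, n) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}
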