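kB <- 0.0019872041

# a window table row built by hand (bypassing generate_window_grid)
manual_window <- function(centre, k, n, temperature = 310.15) {
  w <- data.frame(id = 1L, centre_1 = centre, force_constant = k,
                  n_samples = as.integer(n), temperature = temperature)
  class(w) <- c("bias_windows", "data.frame")
  w
}

manual_series <- function(samples, id = 1L) {
  structure(list(window_id = as.integer(id),
                 samples = matrix(samples, ncol = 1),
                 seed = 0L, burn_in_discarded = 0L,
                 acceptance_rate = NA_real_, proposal_scale = NA_real_),
            class = "window_timeseries")
}

test_that("histogramming follows the half-open bin convention", {
  w <- manual_window(1.1, 1, 3)
  h <- histogram_windows(w, list(manual_series(c(1.05, 1.15, 1.15))),
                         edges = list(c(1.0, 1.1, 1.2)))
  expect_equal(as.vector(h$counts), c(1, 2))
  # a sample exactly on an interior edge goes to the higher bin
  h2 <- histogram_windows(manual_window(1.1, 1, 1), list(manual_series(1.1)),
                          edges = list(c(1.0, 1.1, 1.2)))
  expect_equal(as.vector(h2$counts), c(0, 1))
  # ... and the last bin is closed
  h3 <- histogram_windows(manual_window(1.1, 1, 1), list(manual_series(1.2)),
                          edges = list(c(1.0, 1.1, 1.2)))
  expect_equal(as.vector(h3$counts), c(0, 1))
})

test_that("histogram counts are conserved and validated", {
  set.seed(42)
  x <- stats::runif(10000, 1, 2)
  h <- histogram_windows(manual_window(1.5, 1, 10000), list(manual_series(x)),
                         bin_width = 0.02)
  expect_equal(sum(h$counts), 10000)
  expect_equal(h$n_samples, 10000)
  expect_error(histogram_windows(manual_window(1.5, 1, 2),
                                 list(manual_series(c(1.5, 9)),
                                      manual_series(1.5, id = 2L))),
               "one time series per window")
  expect_error(histogram_windows(manual_window(1.5, 1, 1),
                                 list(manual_series(numeric(0)))),
               "empty series")
  expect_error(histogram_windows(manual_window(1.5, 1, 2),
                                 list(manual_series(c(1.5, 9))),
                                 edges = list(c(1, 1.5, 2))),
               "outside the bin edges")
})

test_that("an unbiased window over a flat landscape gives a flat PMF", {
  l <- make_surface("harmonic", list(kappa = 1e-9, domain = c(0, 1)))
  w <- manual_window(0.5, 1e-12, 20000)
  # thin so the retained samples are near-independent and the resampling
  # bootstrap error is an honest error for them
  ts <- sample_window(l, w[1, ], seed = 31, proposal_scale = 0.5, thin = 5L)
  h <- histogram_windows(w, list(ts), bin_width = 0.05)
  g <- solve_wham(h, w)
  g <- bootstrap_errors(h, w, n_boot = 30, seed = 1, base = g)
  # every bin within 3 bootstrap standard errors of flatness: the PMF is
  # anchored at its minimum bin, so the relevant error on fe[b] - 0 is the
  # combined error of the bin and the anchor
  err_anchor <- g$error[which.min(g$free_energy)]
  expect_true(all(g$free_energy <= 3 * (g$error + err_anchor)))
})

test_that("WHAM recovers the harmonic PMF from overlapping windows", {
  l <- make_surface("harmonic")  # kappa = 2, domain [-1, 1]
  w <- generate_window_grid(c(-1, 1), coarse_step = 0.5, n_samples = 20000)
  g <- compute_pmf(l, w, seed = 11)
  cen <- g$centres[[1]]
  sel <- cen >= -0.8 & cen <= 0.8 & !g$mask  # central 80% of the domain
  ref <- cen[sel]^2  # 1/2 * kappa * x^2, kappa = 2
  # the PMF is defined up to an additive constant: align it by least squares
  dev <- g$free_energy[sel] - ref
  expect_lt(sqrt(mean((dev - mean(dev))^2)), 0.15)
})

test_that("WHAM recovers the double-well construction barrier", {
  l <- make_surface("double_well_1d")
  w <- generate_window_grid(c(0.9, 2.5), coarse_step = 0.1, n_samples = 8000)
  g <- compute_pmf(l, w, seed = 21)
  cen <- g$centres[[1]]
  well1 <- min(g$free_energy[!g$mask & abs(cen - 1.2) < 0.1])
  top <- max(g$free_energy[!g$mask & abs(cen - 1.7) < 0.1])
  expect_lt(abs((top - well1) - 5), 0.3)
})

test_that("small instances agree with an independent fixed-point oracle", {
  kt <- kB * 310.15
  set.seed(7)
  for (case in 1:3) {
    W <- sample(1:3, 1); B <- sample(5:20, 1)
    counts <- matrix(rpois(W * B, 30) + 1, W, B)
    w <- data.frame(id = seq_len(W), centre_1 = seq_len(W) * 0.1,
                    force_constant = 1, n_samples = rowSums(counts),
                    temperature = 310.15)
    class(w) <- c("bias_windows", "data.frame")
    h <- structure(list(edges = list(0.1 * (0:B)),
                        centres = list(0.1 * (1:B) - 0.05),
                        counts = counts, n_samples = rowSums(counts),
                        dim = 1L, nbin = as.integer(B)), class = "histogram_grid")
    # the oracle recomputes the harmonic bias matrix from the window table
    bias_real <- t(vapply(seq_len(W), function(i)
      0.5 * 1 * (h$centres[[1]] - w$centre_1[i])^2, numeric(B)))
    sol <- suppressWarnings(solve_wham(h, w, tolerance = 1e-10))
    or <- wham_oracle(counts, bias_real, rowSums(counts), kt)
    expect_equal(sol$shifts, or$f, tolerance = 1e-6)
    expect_equal(sol$free_energy, or$pmf, tolerance = 1e-6)
  }
})

test_that("bin probabilities are conserved and the PMF offset is zero", {
  l <- make_surface("double_well_1d")
  w <- generate_window_grid(c(1.0, 2.4), coarse_step = 0.2, n_samples = 2000)
  series <- sample_windows(l, w, seed = 3)
  h <- histogram_windows(w, series, bin_width = 0.05)
  g <- solve_wham(h, w)
  expect_lt(abs(sum(g$prob) - 1), 1e-10)
  expect_equal(min(g$free_energy[!g$mask]), 0)
  expect_true(all(is.na(g$free_energy[g$mask])))
  expect_equal(g$shifts[1], 0)
})

test_that("the PMF is gauge-invariant under constant bias offsets", {
  l <- make_surface("double_well_1d")
  w <- generate_window_grid(c(1.0, 2.4), coarse_step = 0.2, n_samples = 2000)
  series <- sample_windows(l, w, seed = 13)
  h <- histogram_windows(w, series, bin_width = 0.05)
  a <- solve_wham(h, w, tolerance = 1e-9)
  b <- solve_wham(h, w, tolerance = 1e-9,
                  bias_offsets = rep(7.5, nrow(w)))
  expect_equal(a$free_energy, b$free_energy, tolerance = 1e-6)
})

test_that("bootstrap errors behave like errors", {
  l <- make_surface("harmonic")
  w <- generate_window_grid(c(-1, 1), coarse_step = 0.5, n_samples = 5000)
  series <- sample_windows(l, w, seed = 17)
  h <- histogram_windows(w, series, bin_width = 0.04)
  base <- solve_wham(h, w)
  # degenerate mode: no resampling, zero variance
  g0 <- bootstrap_errors(h, w, n_boot = 5, seed = 1, base = base, resample = FALSE)
  expect_true(all(g0$error[!g0$mask] == 0))
  # determinism
  g1 <- bootstrap_errors(h, w, n_boot = 15, seed = 8, base = base)
  g2 <- bootstrap_errors(h, w, n_boot = 15, seed = 8, base = base)
  expect_identical(g1$error, g2$error)
  expect_error(bootstrap_errors(h, w, n_boot = 1, seed = 1), "n_boot")
  # errors shrink with sample size
  w4 <- generate_window_grid(c(-1, 1), coarse_step = 0.5, n_samples = 20000)
  s4 <- sample_windows(l, w4, seed = 17)
  h4 <- histogram_windows(w4, s4, bin_width = 0.04)
  g4 <- bootstrap_errors(h4, w4, n_boot = 15, seed = 8)
  expect_lt(stats::median(g4$error, na.rm = TRUE),
            stats::median(g1$error, na.rm = TRUE))
  # block bootstrap path runs and gives nonzero errors
  gb <- bootstrap_errors(h, w, n_boot = 5, seed = 2, base = base,
                         series = series, block_length = 100)
  expect_true(any(gb$error[!gb$mask] > 0))
})

test_that("disconnected window support triggers a warning, not a failure", {
  w <- rbind(manual_window(1.05, 1, 3), manual_window(1.05, 1, 3))
  w$id <- 1:2
  s1 <- manual_series(c(1.02, 1.04, 1.06), id = 1L)
  s2 <- manual_series(c(1.52, 1.54, 1.56), id = 2L)
  h <- histogram_windows(w, list(s1, s2), edges = list(seq(1.0, 1.6, 0.1)))
  expect_warning(solve_wham(h, w), "disconnected")
})
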