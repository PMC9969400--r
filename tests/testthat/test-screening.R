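test_that("profiles validate ids, phases, barriers and state labels", {
  p <- assemble_profile("2a", "acylation", c(TS1 = 22.0, TS2 = 22.2), "FEL")
  expect_s3_class(p, "reaction_profile")
  expect_equal(unname(p$barriers), c(22.0, 22.2))
  p2 <- assemble_profile("11b", "deacylation", c(TS3 = 18.2, TS4 = 19.8), "PES")
  expect_equal(names(p2$barriers), c("TS3", "TS4"))
  expect_error(assemble_profile("2a", "acylation", c(TS1 = -1.0, TS2 = 1), "FEL"),
               "non-negative")
  expect_error(assemble_profile("2a", "acylation", c(TS1 = 20), "FEL"),
               "missing transition state")
  expect_error(assemble_profile("2a", "acylation", c(TS3 = 20, TS4 = 21), "FEL"),
               "transition states")
  expect_error(assemble_profile("conj-2a", "acylation",
                                c(TS1 = 20, TS2 = 21), "FEL"), "grammar")
  expect_error(assemble_profile("2a", "hydration", c(TS1 = 20, TS2 = 21), "FEL"))
  # partial profiles are allowed when requested (single-step scans)
  p3 <- assemble_profile("3a", "acylation", c(TS1 = 28.5), "PES", partial = TRUE)
  expect_equal(unname(p3$barriers), 28.5)
})

test_that("the rate-limiting step is the largest barrier, later on ties", {
  expect_equal(rate_limiting(assemble_profile("11a", "deacylation",
                                              c(TS3 = 16.4, TS4 = 20.1), "FEL")),
               c(TS4 = 20.1))
  expect_equal(rate_limiting(assemble_profile("4b", "acylation",
                                              c(TS1 = 20.2, TS2 = 19.1), "FEL")),
               c(TS1 = 20.2))
  expect_equal(rate_limiting(assemble_profile("1a", "acylation",
                                              c(TS1 = 5.0, TS2 = 5.0), "FEL")),
               c(TS2 = 5.0))
})

test_that("screening ranks the published acylation set with 4b first", {
  profs <- profiles_from_table(pdc_reference_barriers("acylation"))
  res <- screen(profs, threshold = 25.0)
  expect_true(all(res$viable))
  expect_equal(res$id[res$rank == 1], "4b")
  expect_equal(res$rate_limiting_dg[res$rank == 1], 20.2)
  expect_identical(sort(res$rank), 1:6)
  # ranking ascending in barrier
  expect_true(all(diff(res$rate_limiting_dg[order(res$rank)]) >= 0))
})

test_that("barriers above threshold are screened out", {
  over <- assemble_profile("3a", "acylation", c(TS1 = 28.5), "PES", partial = TRUE)
  under <- assemble_profile("3c", "acylation", c(TS1 = 16.7), "PES", partial = TRUE)
  res <- screen(list(over, under), threshold = 25.0)
  expect_equal(res$viable, c(FALSE, TRUE))
  expect_true(is.na(res$rank[1]))
  # boundary equality is not viable (strictly below the threshold)
  at <- assemble_profile("9a", "acylation", c(TS1 = 25.0, TS2 = 10), "FEL")
  expect_false(screen(list(at), threshold = 25.0)$viable)
  expect_identical(nrow(screen(list())), 0L)
  expect_error(screen(list(over, over)), "duplicate")
})

test_that("screening is monotone and permutation-invariant", {
  set.seed(91)
  profs <- lapply(1:6, function(i)
    assemble_profile(paste0(i, "a"), "acylation",
                     c(TS1 = stats::runif(1, 15, 35),
                       TS2 = stats::runif(1, 15, 35)), "FEL"))
  res <- screen(profs)
  # raising a barrier never turns non-viable into viable
  for (i in seq_along(profs)) {
    bump <- profs
    bump[[i]]$barriers["TS1"] <- bump[[i]]$barriers["TS1"] + 5
    res2 <- screen(bump)
    expect_true(all(res2$viable <= res$viable))
  }
  # permutation invariance of the per-id verdict and rank
  perm <- sample(seq_along(profs))
  resp <- screen(profs[perm])
  m <- match(res$id, resp$id)
  expect_equal(res$viable, resp$viable[m])
  expect_equal(res$rank, resp$rank[m])
})

test_that("Eyring conversion is exact and self-inverse", {
  # prefactor from the SI constants directly
  pre <- 1.380649e-23 * 310.15 / 6.62607015e-34
  expect_equal(dg_to_rate(0), pre)
  expect_equal(pre, 6.46e12, tolerance = 0.001)
  dg <- seq(0, 40, by = 0.25)
  expect_lt(max(abs(rate_to_dg(dg_to_rate(dg)) - dg)), 1e-10)
  # a 1 kcal/mol difference changes the rate by exp(1/kB T)
  ratio <- dg_to_rate(19.7) / dg_to_rate(20.7)
  expect_equal(ratio, exp(1 / (0.0019872041 * 310.15)), tolerance = 1e-10)
  expect_equal(ratio, 5.07, tolerance = 0.002)
  expect_error(dg_to_rate(1, temperature = 0), "temperature")
  expect_error(rate_to_dg(-1), "rate")
})

test_that("the deacylation reference set ranks its carriers coherently", {
  profs <- profiles_from_table(pdc_reference_barriers("deacylation"))
  res <- screen(profs, threshold = 25.0)
  expect_true(all(res$viable))
  rl <- stats::setNames(res$rate_limiting_dg, res$id)
  expect_equal(rl[["11a"]], 20.1)
  expect_equal(rl[["11b"]], 19.8)
  expect_equal(rl[["11c"]], 21.8)
  expect_equal(res$rate_limiting_step[res$id == "11b"], "TS4")
  expect_equal(max(res$rate_limiting_dg), 21.8)
})
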