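test_that("critical points of the default profile sit at the landmark positions", {
  fes <- fx_analytic_fes(fx_default_landscape())
  cp <- find_critical_points(fes)
  mins <- cp[cp$type == "min", ]
  sad <- cp[cp$type == "saddle", ]
  expect_equal(nrow(mins), 3)
  # main saddle at s = 12 +/- 0.5; metastable external minimum in [15, 16]
  expect_lt(abs(sad$s[which.max(sad$F)] - 12), 0.5)
  expect_true(any(mins$s > 15 & mins$s < 16))
})

test_that("degenerate profiles are handled: parabola, flat, equal wells", {
  s <- seq(-2, 2, 0.01)
  para <- fes_profile(s, 2 * s^2)
  cp <- find_critical_points(para)
  expect_equal(sum(cp$type == "min"), 1)
  expect_equal(sum(cp$type == "saddle"), 0)
  flat <- fes_profile(s, rep(0, length(s)))
  expect_warning(cp2 <- find_critical_points(flat), "flat")
  expect_equal(nrow(cp2), 0)
  # symmetric polynomial double well: minima at +/-1, saddle at 0
  dwF <- (s^2 - 1)^2
  cp3 <- find_critical_points(fes_profile(s, dwF))
  expect_equal(sort(cp3$s[cp3$type == "min"]), c(-1, 1), tolerance = 0.011)
  expect_equal(cp3$s[cp3$type == "saddle"], 0, tolerance = 0.011)
})

test_that("basin free energies: identity, harmonic offset, antisymmetry", {
  s <- seq(-4, 4, 0.005)
  offs <- 2.5
  Fv <- ifelse(s < 0, 2 * (s + 2)^2, offs + 2 * (s - 2)^2)
  fes <- fes_profile(s, Fv)
  same <- basin_free_energy(fes, c(-4, 0), c(-4, 0), 300)
  expect_equal(same$dG, 0, tolerance = 1e-12)
  d <- basin_free_energy(fes, c(0, 4), c(-4, 0), 300)
  expect_equal(d$dG, offs, tolerance = 1e-3)
  # exact antisymmetry
  rev <- basin_free_energy(fes, c(-4, 0), c(0, 4), 300)
  expect_equal(d$dG, -rev$dG, tolerance = 1e-12)
})

test_that("the external pose sits 4 kcal/mol above the main minimum", {
  fes <- fx_analytic_fes(fx_default_landscape())
  d <- basin_free_energy(fes, c(14, 17), c(1.5, 4.5), 300)
  expect_equal(d$dG, 4.0, tolerance = 0.15)
})

test_that("standard-state correction follows kT log(V/V0)", {
  expect_equal(standard_state_correction(1660, 300), 0, tolerance = 1e-12)
  expect_equal(standard_state_correction(16600, 300), 1.3726,
    tolerance = 1e-3
  )
  expect_equal(
    standard_state_correction(166, 300),
    -standard_state_correction(16600, 300),
    tolerance = 1e-12
  )
  expect_error(standard_state_correction(-1), "V_unbound")
  bdg <- binding_free_energy(-9.4, 16600, 300)
  expect_equal(bdg$dG_std, bdg$dG_raw + bdg$correction, tolerance = 1e-15)
})

test_that("the two binding routes combine and close", {
  fb <- combine_cycle(-14, 6.0, "flip-bind")
  expect_equal(fb$total, -8, tolerance = 1e-15)
  bf <- combine_cycle(-8, 0, "bind-flip")
  expect_equal(bf$total, -8, tolerance = 1e-15)
  cc <- cycle_closure(fb, bf, err_a = 1, err_b = 1)
  expect_true(cc$closed)
  expect_equal(combine_cycle(0, 0)$total, 0)
  expect_error(combine_cycle(-14, 6, "fold-bind"))
  expect_error(combine_cycle(Inf, 0, "flip-bind"))
})

test_that("Boltzmann populations: equal split, 4 kcal/mol minor state, normalization", {
  expect_equal(boltzmann_population(c(0, 0), 300), c(0.5, 0.5))
  p <- boltzmann_population(c(0, 4), 300)
  expect_equal(p[2], 1.217e-3, tolerance = 1e-2)
  set.seed(1)
  for (i in 1:20) {
    p <- boltzmann_population(rnorm(5, 0, 3), 300)
    expect_equal(sum(p), 1, tolerance = 1e-15)
  }
  expect_error(boltzmann_population(0), "2 states")
})

test_that("basin-integrated minor population exceeds the point estimate", {
  # the metastable pose occupies a finite basin; integrating it against the
  # bound basin gives a larger population than the point-state value
  fes <- fx_analytic_fes(fx_default_landscape())
  kT <- kT_kcal(300)
  zA <- sum(exp(-fes$F[fes$s >= 1.5 & fes$s <= 7.5] / kT))
  zC <- sum(exp(-fes$F[fes$s >= 14 & fes$s <= 17] / kT))
  p_int <- zC / (zA + zC)
  p_point <- boltzmann_population(c(0, 4), 300)[2]
  expect_gt(p_int, p_point)
  expect_lt(p_int, 0.05)
})

test_that("barrier heights from analytic profiles are exact", {
  fes_p <- fx_analytic_fes(fx_full_scale())
  f <- fx_full_scale()$features
  b <- barrier_height(fes_p, c(1.5, 4.5), f$s[f$label == "TS"])
  expect_equal(b$dG_barrier, 16.5, tolerance = 1e-4)
  s <- seq(0, 1, 0.01)
  flat <- fes_profile(s, rep(0, 101))
  expect_equal(barrier_height(flat, c(0, 0.5), 0.8)$dG_barrier, 0)
  well <- fes_profile(s, (s - 0.5)^2)
  expect_error(barrier_height(well, c(0.7, 0.9), 0.5), "below")
})

test_that("all thermodynamic outputs are gauge invariant under F + const", {
  fes <- fx_analytic_fes(fx_default_landscape())
  raw <- list(s = fes$s, F = fes$F + 7.3, err = fes$err)
  shifted <- fes_profile(raw$s, raw$F, raw$err)
  d1 <- basin_free_energy(fes, c(14, 17), c(1.5, 4.5), 300)$dG
  d2 <- basin_free_energy(shifted, c(14, 17), c(1.5, 4.5), 300)$dG
  expect_lt(abs(d1 - d2), 1e-10)
  b1 <- barrier_height(fes, c(1.5, 4.5), 12)$dG_barrier
  b2 <- barrier_height(shifted, c(1.5, 4.5), 12)$dG_barrier
  expect_lt(abs(b1 - b2), 1e-10)
  p1 <- boltzmann_population(c(1, 3), 300)
  p2 <- boltzmann_population(c(1, 3) + 11.1, 300)
  expect_lt(max(abs(p1 - p2)), 1e-10)
})

test_that("watershed assignment drains every bin to the right minimum", {
  fes <- fx_analytic_fes(fx_default_landscape())
  basins <- watershed_basins(fes)
  mins <- attr(basins, "minima")
  # bins at the declared minima map to themselves
  f <- fx_default_landscape()$features
  for (lab in c("A", "B", "C")) {
    i <- which.min(abs(fes$s - f$s[f$label == lab]))
    expect_equal(mins$s[basins[i]], f$s[f$label == lab], tolerance = 0.05)
  }
  # the assignment changes exactly at saddles: count distinct runs
  expect_lte(length(rle(as.integer(basins))$lengths), nrow(mins) + 2)
})

test_that("FES TSV round trip preserves the profile", {
  fes <- fx_analytic_fes(fx_asym_dw(), dx = 0.05)
  f <- tempfile(fileext = ".tsv")
  write_fes(fes, f)
  back <- read_fes(f)
  expect_equal(back$F, fes$F, tolerance = 1e-8)
  unlink(f)
})

test_that("resampled uncertainty propagates per-bin errors", {
  s <- seq(-2, 2, 0.01)
  fes <- fes_profile(s, (s^2 - 1)^2, err = rep(0.1, length(s)))
  d <- basin_free_energy(fes, c(0, 2), c(-2, 0), 300, seed = 3)
  expect_gt(d$err, 0)
  expect_lt(d$err, 0.1) # independent bin errors largely cancel
})
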