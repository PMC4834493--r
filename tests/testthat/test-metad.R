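test_that("invalid metadynamics parameters are rejected", {
  dw <- landscape_preset("double_well")
  expect_error(
    run_metad(dw, 1000, params = list(gamma = 0.5)),
    "gamma"
  )
  expect_error(run_metad(dw, 1000, params = list(pace = 5)), "pace")
})

test_that("infinite bias factor gives constant hill heights", {
  dw <- landscape_preset("double_well")
  md <- run_metad(dw, 5e4, params = list(gamma = Inf, sigma = 0.2), seed = 1)
  expect_true(all(md$hills$height == md$hills$height[1]))
})

test_that("well-tempered heights follow the tempering rule and decay", {
  dw <- landscape_preset("double_well")
  md <- run_metad(dw, 4e5,
    params = list(gamma = 8, sigma = 0.2),
    seed = 2
  )
  h <- md$hills
  # the deposited height must equal w0 exp(-V_bias(center)/(kB dT)) with
  # V_bias the sum of all earlier hills (grid interpolation tolerance)
  kBdT <- kT_kcal(300) / 300 * (8 - 1) * 300
  idx <- c(50, 200, 400, 790)
  for (i in idx) {
    prev <- h[seq_len(i - 1), ]
    V <- sum(prev$height * exp(-0.5 * ((prev$s - h$s[i]) / prev$sigma_s)^2))
    expect_equal(h$height[i], 0.1 * exp(-V / kBdT), tolerance = 0.02)
  }
  # heights are non-increasing within any fixed bin as deposition proceeds
  bins <- cut(h$s, seq(-4, 4, 0.05))
  worst <- max(unlist(tapply(h$height, bins, function(x) {
    if (length(x) < 2) 0 else max(diff(x))
  })), na.rm = TRUE)
  expect_lt(worst, 0.05 * 0.1)
})

test_that("empty and single-hill reconstructions behave analytically", {
  empty <- hills_log(data.frame(
    time = numeric(), s = numeric(),
    sigma_s = numeric(), height = numeric(), biasf = numeric()
  ))
  expect_warning(f0 <- reconstruct_fes(empty, grid = seq(0, 1, 0.1)), "flat")
  expect_true(all(f0$F == 0))
  one <- hills_log(data.frame(
    time = 1, s = 0, sigma_s = 0.2, height = 1,
    biasf = Inf
  ))
  f1 <- reconstruct_fes(one, grid = seq(-3, 3, 0.01))
  expect_equal(f1$s[which.min(f1$F)], 0, tolerance = 0.011)
  far <- abs(f1$s) > 2
  expect_equal(mean(f1$F[far]) - min(f1$F), 1, tolerance = 1e-3)
})

test_that("reconstruction is invariant to hill deposition order", {
  dw <- landscape_preset("double_well")
  md <- run_metad(dw, 1e5, params = list(sigma = 0.2), seed = 3)
  grid <- seq(-5, 5, 0.05)
  f1 <- reconstruct_fes(md$hills, grid)
  # same Gaussian set deposited in a different order: permute the
  # centers/heights while keeping the time column valid
  perm <- order(md$hills$s)
  shuffled <- md$hills
  shuffled[, c("s", "height", "sigma_s")] <-
    md$hills[perm, c("s", "height", "sigma_s")]
  f2 <- reconstruct_fes(hills_log(shuffled), grid)
  expect_lt(max(abs(f1$F - f2$F)), 1e-10)
})

test_that("metadynamics recovers the quadrature free-energy difference", {
  lsa <- fx_asym_dw()
  md <- run_metad(lsa, 2e6, params = list(sigma = 0.2), seed = 4)
  est <- metad_dG(md$hills, c(0, 4), c(-4, 0), 300)
  expect_equal(est$dG, 1.0, tolerance = 0.3)
})

test_that("multiple walkers agree with a single walker within error bars", {
  lsa <- fx_asym_dw()
  md1 <- run_metad(lsa, 2e6, params = list(sigma = 0.2), seed = 5)
  md4 <- run_metad(lsa, 5e5,
    params = list(sigma = 0.2), nwalkers = 4,
    seed = 6
  )
  e1 <- metad_dG(md1$hills, c(0, 4), c(-4, 0), 300)
  e4 <- metad_dG(md4$hills, c(0, 4), c(-4, 0), 300)
  expect_lt(
    abs(e1$dG - e4$dG),
    sqrt(e1$err^2 + e4$err^2) + 0.15
  )
})

test_that("reported error bar covers the quadrature value across seeds", {
  lsa <- fx_asym_dw()
  hits <- 0
  nrep <- 20
  for (sd in seq_len(nrep)) {
    md <- run_metad(lsa, 6e5, params = list(sigma = 0.2), seed = 100 + sd)
    est <- metad_dG(md$hills, c(0, 4), c(-4, 0), 300)
    if (abs(est$dG - 1.0) <= est$err + 0.1) hits <- hits + 1
  }
  expect_gte(hits, 0.9 * nrep)
})

test_that("HILLS text round trip preserves the log; malformed logs rejected", {
  dw <- landscape_preset("double_well")
  md <- run_metad(dw, 5e4, params = list(sigma = 0.2), seed = 7)
  f <- tempfile(fileext = ".hills")
  write_hills(md$hills, f)
  lines <- readLines(f)
  expect_match(lines[1], "^#! FIELDS time s sigma_s height biasf")
  back <- read_hills(f)
  expect_equal(back$s, md$hills$s, tolerance = 1e-8)
  expect_equal(back$height, md$hills$height, tolerance = 1e-6)
  expect_true(all(is.infinite(back$biasf) == is.infinite(md$hills$biasf)))
  unlink(f)
  expect_error(
    hills_log(data.frame(
      time = 1, s = 0, sigma_s = -0.1, height = 1,
      biasf = 8
    )),
    "widths"
  )
  expect_error(
    hills_log(data.frame(
      time = 1, s = 0, sigma_s = 0.1, height = 0,
      biasf = 8
    )),
    "heights"
  )
})

test_that("snapshot uncertainty vanishes when the window only adds a constant", {
  # the late hill is so wide it shifts the profile by (almost) a constant;
  # mean alignment must absorb it
  h <- hills_log(data.frame(
    time = c(1, 1.2, 3), s = c(0, 0.5, 0.2), sigma_s = c(0.2, 0.2, 500),
    height = 1, biasf = Inf
  ))
  grid <- seq(-2, 3, 0.05)
  u <- fes_uncertainty(h, grid, window = 0.5, nsnap = 5)
  expect_lt(max(u), 1e-4)
  expect_error(fes_uncertainty(h, grid, window = 1.5), "window")
  expect_error(fes_uncertainty(h, grid, nsnap = 3), "5")
})

test_that("replica exchange follows the Metropolis rule", {
  dw <- landscape_preset("double_well")
  mk <- function(x, T) list(x = x, temperature = T, landscape = dw)
  # equal temperatures: always accepted
  r <- replica_exchange_step(list(mk(-1.5, 300), mk(1.2, 300)), seed = 1)
  expect_equal(r$exchanges$prob, 1)
  # equal energies: always accepted
  r2 <- replica_exchange_step(list(mk(-1.5, 300), mk(-1.5, 450)), seed = 1)
  expect_equal(r2$exchanges$prob, 1)
  # mismatched landscapes rejected
  other <- landscape_preset("harmonic")
  expect_error(
    replica_exchange_step(list(mk(-1.5, 300), list(
      x = 0,
      temperature = 400, landscape = other
    ))),
    "mismatched landscape"
  )
})

test_that("mean swap acceptance matches a brute-force Monte-Carlo estimate", {
  # two harmonic replicas at different temperatures
  hw <- landscape_preset("harmonic", k = 2)
  T1 <- 300
  T2 <- 500
  set.seed(8)
  n <- 4000
  x1 <- rnorm(n, 0, sqrt(kT_kcal(T1) / 2))
  x2 <- rnorm(n, 0, sqrt(kT_kcal(T2) / 2))
  acc <- vapply(seq_len(n), function(i) {
    st <- list(
      list(x = x1[i], temperature = T1, landscape = hw),
      list(x = x2[i], temperature = T2, landscape = hw)
    )
    replica_exchange_step(st, seed = i)$exchanges$accepted
  }, TRUE)
  # independent estimate: direct average of the analytic acceptance law
  # over fresh equilibrium samples
  set.seed(9)
  y1 <- rnorm(n, 0, sqrt(kT_kcal(T1) / 2))
  y2 <- rnorm(n, 0, sqrt(kT_kcal(T2) / 2))
  b1 <- 1 / kT_kcal(T1)
  b2 <- 1 / kT_kcal(T2)
  ref <- mean(pmin(1, exp((b1 - b2) * (y1^2 - y2^2))))
  expect_equal(mean(acc), ref, tolerance = 0.02 + 3 * sqrt(0.25 / n))
})

test_that("bias flattens a symmetric double well to even occupancy", {
  dw <- landscape_preset("double_well")
  md <- run_metad(dw, 1e6, params = list(sigma = 0.2), seed = 10)
  # final third of the trajectory, after the bias has filled the wells
  x <- md$traj[, 1]
  x <- x[seq(floor(2 * length(x) / 3), length(x))]
  expect_lt(abs(mean(x > 0) - 0.5), 0.2)
})
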