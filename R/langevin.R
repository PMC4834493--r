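#' Langevin dynamics on a toy landscape
#'
#' BAOAB-splitting Langevin integrator (compiled core).  Samples the
#' Boltzmann distribution of the landscape (plus any external bias) in the
#' long-time limit; identical inputs and seed give bit-identical
#' trajectories.
#'
#' @param landscape a `toy_landscape` (1D dynamics; the flip axis, if any,
#'   is analytic only)
#' @param nsteps number of integration steps
#' @param dt time step in ps; rejected if too large for the stiffest part
#'   of the potential (energy drift per step must stay well below 1e-3 kT)
#' @param friction friction coefficient in 1/ps
#' @param seed integer RNG seed
#' @param temperature thermostat target in K (defaults to the landscape's)
#' @param x0 starting position (default: deepest declared minimum, else
#'   domain centre)
#' @param v0 starting velocity in u/ps; `NULL` draws Maxwell-Boltzmann
#' @param stride record every `stride`-th step
#' @param mass particle mass (kcal/mol ps^2 / u^2)
#' @param bias optional `fes_profile`-like external bias: a list/data.frame
#'   with `s` (uniform grid) and `bias` (kcal/mol) to be added to the
#'   potential
#' @return a `fb_trajectory`: data.frame with `time_ps`, `s`, `v` plus
#'   metadata attributes
#' @examples
#' tr <- langevin_run(landscape_preset("harmonic"),
#'   nsteps = 2000, dt = 0.02,
#'   seed = 1
#' )
#' var(tr$s)
#' @export
langevin_run <- function(landscape, nsteps, dt = 0.02, friction = 1,
                         seed = 1, temperature = landscape$temperature,
                         x0 = NULL, v0 = NULL, stride = 10, mass = 1,
                         bias = NULL) {
  stopifnot(inherits(landscape, "toy_landscape"))
  .check_dt(landscape, dt, mass, temperature)
  if (is.null(x0)) {
    mins <- landscape$features[landscape$features$role == "min", , drop = FALSE]
    x0 <- if (nrow(mins) > 0) {
      mins$s[which.min(mins$F)]
    } else if (!is.null(landscape$harmonic)) {
      landscape$harmonic$center
    } else {
      mean(landscape$domain)
    }
  }
  h <- landscape$harmonic
  bg <- NULL
  glo <- 0
  gdx <- 1
  if (!is.null(bias)) {
    bs <- bias$s
    gdx <- bs[2] - bs[1]
    glo <- bs[1]
    bg <- as.numeric(bias$bias)
  }
  set.seed(seed)
  res <- cpp_langevin(
    landscape$terms$center, landscape$terms$height,
    landscape$terms$width, landscape$domain[1], landscape$domain[2],
    landscape$kwall, if (is.null(h)) -1 else h$k,
    if (is.null(h)) 0 else h$center,
    x0, if (is.null(v0)) 0 else v0, is.null(v0),
    as.integer(nsteps), dt, as.integer(stride), friction, temperature,
    mass, bg, glo, gdx
  )
  if (isTRUE(res$diverged)) {
    stop(sprintf(
      "trajectory diverged at t = %.3g ps (coordinate left the domain by more than 10x its span); reduce dt or check the landscape",
      res$t_diverged
    ))
  }
  out <- data.frame(time_ps = res$time_ps, s = res$s, v = res$v)
  structure(out,
    class = c("fb_trajectory", "data.frame"),
    dt = dt, stride = as.integer(stride), seed = seed,
    temperature = temperature, friction = friction, mass = mass,
    final_x = res$final_x, final_v = res$final_v
  )
}

# dt admissibility: on the stiffest harmonic component of the potential
# (max curvature K over the domain) the BAOAB/Verlet energy error per step
# scales as (omega dt)^2; omega*dt < 0.1 keeps the drift per step below
# 1e-3 kT for the energies involved here.
.check_dt <- function(landscape, dt, mass, temperature) {
  s <- seq(landscape$domain[1], landscape$domain[2], length.out = 801)
  eps <- diff(landscape$domain) / 4000
  u <- ls_potential(landscape, s)
  up <- ls_potential(landscape, s + eps)
  um <- ls_potential(landscape, s - eps)
  K <- max(abs((up - 2 * u + um) / eps^2))
  if (!is.null(landscape$harmonic)) K <- max(K, landscape$harmonic$k)
  omega <- sqrt(K / mass)
  if (omega * dt >= 0.25) {
    stop(sprintf(
      "dt = %g ps too large for this landscape (omega*dt = %.3g >= 0.25): energy drift per step would exceed 1e-3 kT",
      dt, omega * dt
    ))
  }
  invisible(TRUE)
}

#' @export
print.fb_trajectory <- function(x, ...) {
  cat(sprintf(
    "Langevin trajectory: %d frames, dt = %g ps (stride %d), T = %g K, seed %s\n",
    nrow(x), attr(x, "dt"), attr(x, "stride"), attr(x, "temperature"),
    format(attr(x, "seed"))
  ))
  invisible(x)
}

#' @export
plot.fb_trajectory <- function(x, ...) {
  graphics::plot(x$time_ps, x$s,
    type = "l", xlab = "time [ps]",
    ylab = "s", ...
  )
  invisible(x)
}

#' Write / read a trajectory as TSV (`time_ps`, `s` columns)
#' @param traj a `fb_trajectory`
#' @param path file path
#' @export
write_trajectory <- function(traj, path) {
  write.table(traj[, c("time_ps", "s")],
    path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("time_ps", "s") %in% names(d)))
  d
}
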