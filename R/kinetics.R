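#' Interface set for shooting across a barrier
#' @param s strictly monotone s values spanning the barrier region
#' @param saddle_s saddle position (must lie within the span)
#' @return an `interface_set`
#' @export
interface_set <- function(s, saddle_s) {
  if (any(diff(s) <= 0)) stop("interfaces must be strictly monotone in s")
  if (saddle_s < min(s) || saddle_s > max(s)) {
    stop("the saddle must lie within the interface span")
  }
  structure(list(s = s, saddle_s = saddle_s), class = "interface_set")
}

#' Default interfaces: n evenly spaced across saddle +/- half-width
#' @param saddle_s saddle position on s
#' @param n number of interfaces
#' @param halfwidth half-span in s units
#' @export
default_interfaces <- function(saddle_s, n = 5, halfwidth = 1) {
  interface_set(seq(saddle_s - halfwidth, saddle_s + halfwidth,
    length.out = n
  ), saddle_s)
}

#' Unbiased shooting from barrier interfaces
#'
#' Launches `n_traj` unbiased trajectories per interface with
#' Maxwell-Boltzmann velocities and integrates each until it commits to
#' the bound side (`s <= bound_s`), the unbound side (`s >= unbound_s`) or
#' times out.  Forward means toward the unbound side.
#'
#' @param landscape a `toy_landscape`
#' @param interfaces an `interface_set`
#' @param n_traj trajectories per interface (>= 100)
#' @param bound_s,unbound_s commitment boundaries (defaults: one hill
#'   width inside the flanking minima of the declared saddle)
#' @param max_steps per-trajectory step cap
#' @param seed RNG seed
#' @param dt,friction,mass,temperature integrator settings
#' @return a `shooting_ensemble`: per-trajectory records (`interface`,
#'   `s0`, `v0`, `outcome` in bound/unbound/timeout, `fpt_ps`) plus
#'   metadata
#' @export
run_shooting <- function(landscape, interfaces, n_traj = 200,
                         bound_s = NULL, unbound_s = NULL,
                         max_steps = 2e6, seed = 1, dt = 0.02,
                         friction = 1, mass = 1,
                         temperature = landscape$temperature) {
  stopifnot(inherits(interfaces, "interface_set"))
  if (n_traj < 100) stop("need at least 100 trajectories per interface")
  feats <- landscape$features
  if (is.null(bound_s) || is.null(unbound_s)) {
    mins <- feats[feats$role == "min", , drop = FALSE]
    left <- mins$s[mins$s < interfaces$saddle_s]
    right <- mins$s[mins$s > interfaces$saddle_s]
    if (is.null(bound_s)) {
      if (length(left) == 0) stop("no bound-side minimum below the saddle")
      bound_s <- max(left)
    }
    if (is.null(unbound_s)) {
      unbound_s <- if (length(right) > 0) min(right) else landscape$domain[2] - 1
    }
  }
  .check_dt(landscape, dt, mass, temperature)
  h <- landscape$harmonic
  kT <- .kB * temperature
  set.seed(seed)
  x0 <- rep(interfaces$s, each = n_traj)
  v0 <- rnorm(length(x0), 0, sqrt(kT / mass))
  res <- cpp_shoot(
    landscape$terms$center, landscape$terms$height,
    landscape$terms$width, landscape$domain[1], landscape$domain[2],
    landscape$kwall, if (is.null(h)) -1 else h$k,
    if (is.null(h)) 0 else h$center,
    x0, v0, bound_s, unbound_s, dt, friction, temperature, mass,
    max_steps
  )
  out <- data.frame(
    interface = rep(seq_along(interfaces$s), each = n_traj),
    s0 = x0, v0 = v0,
    outcome = c("bound", "unbound", "timeout")[res$outcome + 1],
    fpt_ps = res$fpt_ps
  )
  fto <- mean(out$outcome == "timeout")
  if (fto > 0.10) {
    warning(sprintf(
      "%.0f%% of trajectories timed out; consider raising max_steps",
      100 * fto
    ))
  }
  structure(
    list(
      trajectories = out, interfaces = interfaces,
      n_traj = n_traj, bound_s = bound_s, unbound_s = unbound_s,
      temperature = temperature, friction = friction, mass = mass
    ),
    class = "shooting_ensemble"
  )
}

#' @export
print.shooting_ensemble <- function(x, ...) {
  tab <- table(x$trajectories$interface, x$trajectories$outcome)
  cat(sprintf(
    "Shooting ensemble: %d interfaces x %d trajectories (bound side s <= %.3g, unbound s >= %.3g)\n",
    length(x$interfaces$s), x$n_traj, x$bound_s, x$unbound_s
  ))
  print(tab)
  invisible(x)
}

#' Transmission (recrossing) coefficient from a shooting ensemble
#'
#' Positive-flux estimator at the saddle interface: with
#' `p+ = P(commit unbound | forward initial velocity)` and
#' `p- = P(commit unbound | backward initial velocity)`, the recrossing
#' factor is `kappa = p+ - p-`, the fraction of the ballistic (TST) flux
#' that survives recrossing.  The confidence interval combines the two
#' binomial errors.
#'
#' @param ensemble a `shooting_ensemble`
#' @param level confidence level
#' @return list with `kappa`, `ci` (length 2), per-interface conditional
#'   crossing table and `converged` flag (FALSE when no forward start
#'   committed unbound, in which case `kappa` is the binomial lower bound)
#' @export
transmission_coefficient <- function(ensemble, level = 0.95) {
  tr <- ensemble$trajectories
  sI <- which.min(abs(ensemble$interfaces$s - ensemble$interfaces$saddle_s))
  if (!any(tr$interface == sI)) stop("saddle interface not populated")
  per <- do.call(rbind, lapply(split(tr, tr$interface), function(d) {
    data.frame(
      interface = d$interface[1], s = d$s0[1],
      p_fwd = mean(d$outcome[d$v0 > 0] == "unbound"),
      p_bwd = mean(d$outcome[d$v0 < 0] == "unbound"),
      n = nrow(d)
    )
  }))
  d <- tr[tr$interface == sI, ]
  fwd <- d$v0 > 0
  n1 <- sum(fwd)
  n2 <- sum(!fwd)
  k1 <- sum(d$outcome[fwd] == "unbound")
  k2 <- sum(d$outcome[!fwd] == "unbound")
  p1 <- k1 / n1
  p2 <- k2 / n2
  kappa <- p1 - p2
  se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  zq <- qnorm(1 - (1 - level) / 2)
  converged <- k1 > 0 && kappa > 0
  if (!converged) {
    # no net forward flux resolved: report the binomial lower bound
    kappa <- max(kappa, 1 / (n1 + 1))
    warning("transmission coefficient unconverged: no net forward crossings; reporting a lower bound")
  }
  list(
    kappa = min(kappa, 1),
    ci = c(max(kappa - zq * se, 0), min(kappa + zq * se, 1)),
    per_interface = per, converged = converged
  )
}

#' Classical positive-flux TST rate from a 1D profile
#'
#' \eqn{k_{TST} = \frac{1}{2}\langle|v|\rangle e^{-\beta F(s^*)} /
#' \int_{bound} e^{-\beta F} ds} with
#' \eqn{\langle|v|\rangle/2 = \sqrt{k_B T / (2 \pi m)}}; returned in 1/s.
#'
#' @param landscape a `toy_landscape` (evaluated on a fine grid)
#' @param saddle_s saddle position
#' @param bound length-2 s interval of the reactant basin
#' @param temperature temperature in K
#' @param mass particle mass
#' @return TST rate in 1/s
#' @export
tst_rate_flux <- function(landscape, saddle_s, bound,
                          temperature = landscape$temperature, mass = 1) {
  kT <- .kB * temperature
  f <- function(x) exp(-ls_potential(landscape, x) / kT)
  Zb <- integrate(f, bound[1], bound[2], rel.tol = 1e-10)$value
  vbar2 <- sqrt(kT / (2 * pi * mass)) # u/ps
  (vbar2 * f(saddle_s) / Zb) * 1e12
}

#' Unbinding rate estimate (TS-PPTIS style)
#'
#' Combines the free-energy barrier with a shooting-derived recrossing
#' factor: `k = kappa_recross * k_TST_flux`.  Reported in the Eyring
#' convention: `k = (kB T / h) * kappa * exp(-dG / RT)` where `kappa` is
#' the effective transmission coefficient implied by the computed rate
#' (it absorbs recrossing and the diffusive prefactor), so the identity
#' holds exactly.
#'
#' @param landscape a `toy_landscape` with a declared saddle
#' @param ensemble optional precomputed `shooting_ensemble`
#' @param bound length-2 reactant basin interval (default: watershed
#'   around the deepest minimum, shrunk by one grid bin)
#' @param saddle_s saddle position (default: highest declared saddle)
#' @param temperature,mass as elsewhere
#' @param ... passed to [run_shooting()] when `ensemble` is NULL
#' @return a `rate_estimate`
#' @export
pptis_rate <- function(landscape, ensemble = NULL, bound = NULL,
                       saddle_s = NULL,
                       temperature = landscape$temperature, mass = 1, ...) {
  feats <- landscape$features
  if (is.null(saddle_s)) {
    ts <- feats[feats$role == "ts", , drop = FALSE]
    if (nrow(ts) == 0) stop("landscape has no declared saddle")
    saddle_s <- ts$s[which.max(ts$F)]
  }
  mins <- feats[feats$role == "min", , drop = FALSE]
  a <- mins$s[which.min(mins$F)]
  if (is.null(bound)) {
    # reactant basin: from the domain edge (or previous saddle) up to the
    # main saddle
    lower <- max(c(landscape$domain[1], feats$s[feats$role == "ts" &
      feats$s < a]))
    bound <- c(lower, saddle_s)
  }
  if (is.null(ensemble)) {
    ensemble <- run_shooting(landscape, default_interfaces(saddle_s),
      temperature = temperature, mass = mass, ...
    )
  }
  tc <- transmission_coefficient(ensemble)
  kT <- .kB * temperature
  dG <- ls_potential(landscape, saddle_s) -
    ls_potential(landscape, mins$s[which.min(mins$F)])
  ktst <- tst_rate_flux(landscape, saddle_s, bound, temperature, mass)
  k <- tc$kappa * ktst
  krange <- tc$ci * ktst
  rate_estimate(
    dG_barrier = dG, k = k, temperature = temperature,
    range = krange, kappa_recross = tc$kappa,
    kappa_recross_ci = tc$ci
  )
}

#' Rate estimate container (Eyring convention)
#'
#' Holds the (barrier, transmission coefficient, prefactor, rate) tuple
#' with the exact identity `k = prefactor * kappa * exp(-dG / kB T)`,
#' `prefactor = kB T / h`.
#'
#' @param dG_barrier barrier in kcal/mol
#' @param k rate in 1/s (if missing, computed from `kappa`)
#' @param kappa Eyring transmission coefficient in (0, 1] (if missing,
#'   derived from `k`)
#' @param temperature temperature in K
#' @param range optional sampling range (min, max) in 1/s
#' @param kappa_recross,kappa_recross_ci optional shooting recrossing
#'   factor and its confidence interval
#' @return a `rate_estimate`
#' @export
rate_estimate <- function(dG_barrier, k = NULL, kappa = NULL,
                          temperature = 300, range = NULL,
                          kappa_recross = NULL, kappa_recross_ci = NULL) {
  stopifnot(dG_barrier >= 0)
  pref <- .kB_SI * temperature / .h_SI
  boltz <- exp(-dG_barrier / (.kB * temperature))
  if (is.null(k) && is.null(kappa)) stop("supply k or kappa")
  if (is.null(k)) {
    stopifnot(kappa > 0, kappa <= 1)
    k <- pref * kappa * boltz
  } else {
    kappa <- k / (pref * boltz)
  }
  if (is.null(range)) range <- c(k, k)
  structure(
    list(
      dG_barrier = dG_barrier, kappa = kappa, prefactor = pref,
      k = k, range = range, temperature = temperature,
      kappa_recross = kappa_recross,
      kappa_recross_ci = kappa_recross_ci
    ),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "Rate estimate: dG = %.2f kcal/mol, kappa(Eyring) = %.3g, k = %.4g 1/s (range %.3g to %.3g)\n",
    x$dG_barrier, x$kappa, x$k, x$range[1], x$range[2]
  ))
  if (!is.null(x$kappa_recross)) {
    cat(sprintf("  shooting recrossing factor: %.3g\n", x$kappa_recross))
  }
  invisible(x)
}

#' Eyring rate from a barrier and transmission coefficient
#'
#' `k = (kB T / h) * kappa * exp(-dG / kB T)`; with `kappa = 1` this is
#' the ballistic transition-state upper bound on the rate.
#'
#' @param dG_barrier barrier in kcal/mol (>= 0)
#' @param kappa transmission coefficient in (0, 1]
#' @param temperature temperature in K
#' @return a `rate_estimate`
#' @examples
#' rate_from_barrier(16.5, kappa = 1, temperature = 300)$k # ~6 1/s
#' @export
rate_from_barrier <- function(dG_barrier, kappa = 1, temperature = 300) {
  stopifnot(kappa > 0, kappa <= 1, dG_barrier >= 0)
  rate_estimate(dG_barrier,
    kappa = kappa, temperature = temperature
  )
}

#' Brute-force mean-first-passage rate (oracle)
#'
#' Long unbiased Langevin runs from the deepest minimum until first
#' passage to `target_s`; the rate is `1 / mean(fpt)` with the standard
#' error of an exponential first-passage-time sample.
#'
#' @param landscape a `toy_landscape`
#' @param target_s absorbing boundary on s
#' @param nruns number of independent first-passage runs
#' @param max_steps per-run step cap
#' @param seed RNG seed
#' @param dt,friction,mass,temperature integrator settings
#' @param x0 start position (default: deepest declared minimum)
#' @return list with `k` (1/s), `ci`, `mfpt_ps`, `n_escaped`
#' @export
brute_force_mfpt <- function(landscape, target_s, nruns = 60,
                             max_steps = 2e8, seed = 1, dt = 0.02,
                             friction = 1, mass = 1,
                             temperature = landscape$temperature,
                             x0 = NULL) {
  mins <- landscape$features[landscape$features$role == "min", , drop = FALSE]
  if (is.null(x0)) x0 <- mins$s[which.min(mins$F)]
  h <- landscape$harmonic
  kT <- .kB * temperature
  set.seed(seed)
  v0 <- rnorm(nruns, 0, sqrt(kT / mass))
  res <- cpp_shoot(
    landscape$terms$center, landscape$terms$height,
    landscape$terms$width, landscape$domain[1], landscape$domain[2],
    landscape$kwall, if (is.null(h)) -1 else h$k,
    if (is.null(h)) 0 else h$center,
    rep(x0, nruns), v0, -Inf, target_s, dt, friction, temperature,
    mass, max_steps
  )
  esc <- res$outcome == 1
  if (sum(esc) < 5) stop("fewer than 5 escapes; raise max_steps or nruns")
  fpt <- res$fpt_ps[esc]
  mfpt <- mean(fpt)
  k <- 1e12 / mfpt
  relse <- 1 / sqrt(length(fpt)) # exponential fpt: sd ~ mean
  list(
    k = k, ci = k * c(1 / (1 + 2 * relse), 1 / max(1 - 2 * relse, 0.05)),
    mfpt_ps = mfpt, n_escaped = sum(esc)
  )
}

#' Fit the dissociation phase of an SPR sensorgram
#'
#' Least-squares fit of `R(t) = R0 * exp(-kd * t) + c` with asymptotic
#' confidence intervals.  Invariant to rescaling of the response.
#'
#' @param sensorgram data.frame with columns `time_s` and `response_RU`
#' @param level confidence level
#' @return a `dissociation_fit` with `kd`, `R0`, `c`, standard errors and
#'   `ci` for `kd`
#' @export
fit_dissociation <- function(sensorgram, level = 0.95) {
  d <- as.data.frame(sensorgram)
  stopifnot(all(c("time_s", "response_RU") %in% names(d)))
  if (nrow(d) < 10) stop("need at least 10 points")
  r <- d$response_RU
  t <- d$time_s
  c0 <- min(r)
  amp <- max(r) - c0
  rng <- sd(r)
  slope <- coef(lm(r ~ t))[2]
  if (amp <= 1e-12 * max(abs(r), 1) || slope >= 0) {
    stop("no dissociation detected: signal does not decay")
  }
  # log-linear start for kd on the upper part of the decay
  top <- r - c0 > 0.2 * amp
  k0 <- -coef(lm(log(r[top] - c0 + 0.05 * amp) ~ t[top]))[2]
  k0 <- max(k0, 1e-6)
  fit <- minpack.lm::nlsLM(
    response_RU ~ R0 * exp(-kd * time_s) + c0f,
    data = d, start = list(R0 = amp, kd = k0, c0f = c0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  if (!is.finite(se[["kd"]]) || est[["R0"]] <= 0 ||
    se[["kd"]] > 10 * abs(est[["kd"]])) {
    stop("dissociation rate unidentifiable from this sensorgram")
  }
  zq <- qnorm(1 - (1 - level) / 2)
  structure(
    list(
      kd = est[["kd"]], R0 = est[["R0"]], c = est[["c0f"]],
      se = se, ci = est[["kd"]] + c(-1, 1) * zq * se[["kd"]],
      level = level, fit = fit, data = d
    ),
    class = "dissociation_fit"
  )
}

#' @export
print.dissociation_fit <- function(x, ...) {
  cat(sprintf(
    "Dissociation fit: kd = %.4g 1/s (%g%% CI %.4g to %.4g), R0 = %.3g RU, baseline %.3g RU\n",
    x$kd, 100 * x$level, x$ci[1], x$ci[2], x$R0, x$c
  ))
  invisible(x)
}

#' @export
coef.dissociation_fit <- function(object, ...) {
  c(kd = object$kd, R0 = object$R0, c = object$c)
}

#' @export
plot.dissociation_fit <- function(x, ...) {
  graphics::plot(x$data$time_s, x$data$response_RU,
    pch = 16, cex = 0.4,
    xlab = "time [s]", ylab = "response [RU]", ...
  )
  lines(x$data$time_s, predict(x$fit), col = 2, lwd = 2)
  invisible(x)
}
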