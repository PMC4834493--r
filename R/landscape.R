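#' Analytic toy free-energy landscapes
#'
#' A `toy_landscape` is a sum of Gaussian wells and barriers (plus optional
#' harmonic term and soft quadratic walls at the domain edges) standing in
#' for the free-energy surface of ligand (un)binding along a path
#' coordinate `s`.  Declared minima and transition states are refined to
#' the true critical points of the analytic form, and the Gaussian
#' amplitudes are calibrated so the potential at each refined critical
#' point equals its requested free energy exactly.
#'
#' @param features data.frame with columns `label`, `role` (`"min"` or
#'   `"ts"`), `center` (position on the s axis), `F` (target free energy,
#'   kcal/mol, on an absolute scale where the flat far field sits at 0) and
#'   `width` (Gaussian width, s units).
#' @param temperature temperature in K recorded with the landscape.
#' @param domain length-2 numeric; soft walls rise outside this interval.
#' @param kwall wall stiffness, kcal/mol per squared s unit.
#' @param harmonic optional `list(k =, center =)` harmonic term.
#' @param q optional second (flip) axis: `list(centers =, depths =,
#'   widths =, coupling =)` giving Gaussian double-well terms in `q` and a
#'   bilinear `coupling * s * q` term (analytic only; dynamics run in 1D).
#' @return an object of class `toy_landscape`.
#' @examples
#' ls <- landscape_preset("double_well")
#' ls_potential(ls, c(-1.5, 0, 1.5))
#' @export
make_landscape <- function(features, temperature = 300, domain = NULL,
                           kwall = 10, harmonic = NULL, q = NULL) {
  if (!is.null(features)) {
    features <- as.data.frame(features)
    stopifnot(all(c("label", "role", "center", "F", "width") %in%
      names(features)))
    if (any(features$width <= 0)) {
      stop("negative or zero Gaussian widths are not allowed")
    }
    mins <- features[features$role == "min", , drop = FALSE]
    tss <- features[features$role == "ts", , drop = FALSE]
    if (nrow(tss) > 0 && nrow(mins) < 2) {
      stop("no saddle: a transition state needs at least two minima")
    }
    if (nrow(mins) > 1) {
      for (i in seq_len(nrow(mins) - 1)) {
        for (j in (i + 1):nrow(mins)) {
          d <- abs(mins$center[i] - mins$center[j])
          if (d < (mins$width[i] + mins$width[j]) / 2) {
            stop(sprintf(
              "overlapping minima '%s' and '%s' (separation %.3g < %.3g)",
              mins$label[i], mins$label[j], d,
              (mins$width[i] + mins$width[j]) / 2
            ))
          }
        }
      }
    }
    # a TS may sit between two minima or between the last minimum and the
    # flat far field; it may not coincide with a minimum
    if (nrow(tss) > 0 && nrow(mins) > 0) {
      for (i in seq_len(nrow(tss))) {
        if (any(abs(tss$center[i] - mins$center) <
          pmax(tss$width[i], mins$width) / 2)) {
          stop("no saddle: transition state coincides with a minimum")
        }
      }
    }
  } else {
    features <- data.frame(
      label = character(), role = character(),
      center = numeric(), F = numeric(), width = numeric()
    )
  }
  if (is.null(domain)) {
    domain <- if (nrow(features) > 0) {
      range(features$center) + c(-4, 4) * max(features$width, 1)
    } else if (!is.null(harmonic)) {
      harmonic$center + c(-6, 6)
    } else {
      c(0, 1)
    }
  }
  obj <- structure(
    list(
      terms = data.frame(
        center = features$center,
        height = features$F, # initial guess, calibrated below
        width = features$width
      ),
      features = features,
      temperature = temperature, domain = domain, kwall = kwall,
      harmonic = harmonic, q = q, dim = if (is.null(q)) 1L else 2L,
      cv_labels = if (is.null(q)) "s" else c("s", "q_flip")
    ),
    class = "toy_landscape"
  )
  if (nrow(features) > 0) obj <- .calibrate_landscape(obj)
  obj
}

# Fixed-point calibration of Gaussian amplitudes so that the potential at
# each refined critical point equals the requested free energy; critical
# points re-located after each pass.
.calibrate_landscape <- function(ls) {
  feats <- ls$features
  for (outer in 1:6) {
    # amplitude adjustment at current critical-point positions
    for (it in 1:80) {
      u <- ls_potential(ls, feats$center)
      err <- feats$F - u
      ls$terms$height <- ls$terms$height + err
      if (max(abs(err)) < 1e-12) break
    }
    # refine positions to the true critical points
    newc <- feats$center
    for (i in seq_len(nrow(feats))) {
      w <- feats$width[i]
      intv <- c(feats$center[i] - 0.9 * w, feats$center[i] + 0.9 * w)
      op <- optimize(function(x) ls_potential(ls, x),
        interval = intv,
        maximum = (feats$role[i] == "ts"), tol = 1e-12
      )
      newc[i] <- if (feats$role[i] == "ts") op$maximum else op$minimum
    }
    shift <- max(abs(newc - feats$center))
    feats$center <- newc
    if (shift < 1e-10) break
  }
  # final amplitude pass at the refined positions
  for (it in 1:80) {
    u <- ls_potential(ls, feats$center)
    err <- feats$F - u
    ls$terms$height <- ls$terms$height + err
    if (max(abs(err)) < 1e-12) break
  }
  grad <- ls_grad(ls, feats$center)
  if (any(abs(grad) > 1e-6)) {
    stop("landscape calibration failed: non-zero gradient at a declared ",
      "critical point (max |grad| = ", format(max(abs(grad)))
    )
  }
  feats$s <- feats$center
  ls$features <- feats
  ls
}

#' Evaluate the landscape potential
#' @param landscape a `toy_landscape`
#' @param s positions on the s axis
#' @param q optional positions on the flip axis (2D landscapes)
#' @return potential energy in kcal/mol
#' @export
ls_potential <- function(landscape, s, q = NULL) {
  h <- landscape$harmonic
  u <- cpp_potential(
    as.numeric(s), landscape$terms$center, landscape$terms$height,
    landscape$terms$width, landscape$domain[1], landscape$domain[2],
    landscape$kwall, if (is.null(h)) -1 else h$k,
    if (is.null(h)) 0 else h$center
  )
  if (!is.null(q)) {
    if (is.null(landscape$q)) stop("landscape has no flip axis")
    qq <- landscape$q
    uq <- rep(0, length(q))
    for (j in seq_along(qq$centers)) {
      uq <- uq + qq$depths[j] * exp(-0.5 * ((q - qq$centers[j]) / qq$widths[j])^2)
    }
    u <- u + uq + qq$coupling * s * q
  }
  u
}

#' Numerical gradient of the landscape potential along s
#' @inheritParams ls_potential
#' @param eps finite-difference step
#' @return dU/ds in kcal/mol per s unit
#' @export
ls_grad <- function(landscape, s, eps = 1e-6) {
  (ls_potential(landscape, s + eps) - ls_potential(landscape, s - eps)) /
    (2 * eps)
}

#' Built-in landscape presets
#'
#' `"default"`: the binding landscape used throughout — deep bound basin
#' with two near-degenerate minima A (s ~ 3, F = 0 relative to A) and
#' B (s ~ 6, +0.3 kcal/mol), the main transition state at s ~ 12, a
#' metastable external pose C at s ~ 15.5 (+4.0 kcal/mol), a smaller exit
#' barrier and a flat unbound plateau for s > 22.  The main barrier
#' defaults to 7 kcal/mol so that brute-force rate oracles are feasible;
#' `barrier = 16.5` gives the full-scale variant used by analytic
#' calculations.  `"double_well"` / `"asym_double_well"`: symmetric and
#' asymmetric two-state systems (the asymmetric well separation free
#' energy is calibrated by quadrature to exactly 1.0 kcal/mol).
#' `"harmonic"`: a single harmonic well.
#'
#' @param name preset name
#' @param barrier main barrier height in kcal/mol (default preset)
#' @param temperature temperature in K
#' @param k spring constant for the harmonic preset (kcal/mol/u^2)
#' @param with_flip attach the 2D flip axis (default preset only)
#' @return a `toy_landscape`
#' @export
landscape_preset <- function(name = c(
                               "default", "double_well",
                               "asym_double_well", "harmonic"
                             ),
                             barrier = 7, temperature = 300, k = 2,
                             with_flip = FALSE) {
  name <- match.arg(name)
  if (name == "harmonic") {
    return(make_landscape(NULL,
      temperature = temperature,
      domain = c(-6, 6), harmonic = list(k = k, center = 0)
    ))
  }
  if (name == "double_well") {
    feats <- data.frame(
      label = c("L", "ts", "R"), role = c("min", "ts", "min"),
      center = c(-1.5, 0, 1.5), F = c(-3, 0, -3), width = c(0.5, 0.4, 0.5)
    )
    return(make_landscape(feats,
      temperature = temperature,
      domain = c(-4, 4)
    ))
  }
  if (name == "asym_double_well") {
    build <- function(f2) {
      feats <- data.frame(
        label = c("L", "ts", "R"), role = c("min", "ts", "min"),
        center = c(-1.5, 0, 1.5), F = c(-3, 0, f2), width = c(0.5, 0.4, 0.5)
      )
      make_landscape(feats, temperature = temperature, domain = c(-4, 4))
    }
    # calibrate the shallow-well depth so the basin free-energy difference
    # (quadrature oracle) is exactly 1.0 kcal/mol
    target <- 1.0
    g <- function(f2) {
      lsq <- build(f2)
      free_energy_quadrature(lsq, c(0, 4), temperature) -
        free_energy_quadrature(lsq, c(-4, 0), temperature) - target
    }
    f2 <- uniroot(g, c(-2.6, -1.4), tol = 1e-10)$root
    lsq <- build(f2)
    attr(lsq, "dG_quadrature") <- target
    return(lsq)
  }
  # default binding landscape; absolute scale: unbound plateau at 0,
  # main minimum A at -4.5
  base <- -4.5
  feats <- data.frame(
    label = c("A", "tsAB", "B", "TS", "C", "ts2"),
    role = c("min", "ts", "min", "ts", "min", "ts"),
    center = c(3, 4.5, 6, 12, 15.5, 19),
    F = c(base, base + 1.5, base + 0.3, base + barrier, base + 4.0, 0.5),
    width = c(0.8, 0.5, 0.8, 1.2, 0.8, 0.9)
  )
  # flip axis: DFG-in well (q = -1) deeper than DFG-out (q = +1); the
  # shallow-well depth is calibrated so the quadrature flip penalty is
  # exactly 6 kcal/mol (the apo value), not just the point-energy gap
  q <- NULL
  if (with_flip) {
    kT <- .kB * temperature
    uq <- function(x, depth) {
      -9 * exp(-0.5 * ((x + 1) / 0.45)^2) +
        depth * exp(-0.5 * ((x - 1) / 0.45)^2)
    }
    zq <- function(depth, lim) {
      integrate(function(x) exp(-uq(x, depth) / kT), lim[1], lim[2],
        rel.tol = 1e-10
      )$value
    }
    g <- function(depth) {
      -kT * log(zq(depth, c(0, 4)) / zq(depth, c(-4, 0))) - 6.0
    }
    d2 <- uniroot(g, c(-5, -1.5), tol = 1e-10)$root
    q <- list(
      centers = c(-1, 1), depths = c(-9, d2),
      widths = c(0.45, 0.45), coupling = 0
    )
  }
  make_landscape(feats,
    temperature = temperature, domain = c(0, 30),
    kwall = 10, q = q
  )
}

#' Basin free energy by direct quadrature (oracle)
#'
#' Computes `-kT log integral(exp(-U/kT))` over an interval of the analytic
#' potential.  This is the independent reference for all sampled estimates.
#'
#' @param landscape a `toy_landscape`
#' @param interval length-2 numeric interval on s
#' @param temperature temperature in K
#' @return free energy in kcal/mol
#' @export
free_energy_quadrature <- function(landscape, interval,
                                   temperature = landscape$temperature) {
  kT <- .kB * temperature
  f <- function(x) exp(-ls_potential(landscape, x) / kT)
  z <- integrate(f, interval[1], interval[2],
    rel.tol = 1e-10,
    subdivisions = 2000L
  )$value
  -kT * log(z)
}

#' Flip penalty from the 2D landscape by quadrature over the flip axis
#'
#' Free-energy cost of the conformational flip at a fixed path position:
#' \eqn{-k_B T \log[\int_{q>0} e^{-\beta U(s,q)} dq / \int_{q<0}
#' e^{-\beta U(s,q)} dq]} (out-state relative to in-state).
#'
#' @param landscape a 2D `toy_landscape` (built with a flip axis)
#' @param s path position at which the penalty is evaluated
#' @param temperature temperature in K
#' @param qlim integration half-range on q
#' @return flip free-energy penalty in kcal/mol
#' @export
flip_penalty <- function(landscape, s,
                         temperature = landscape$temperature, qlim = 4) {
  if (is.null(landscape$q)) stop("landscape has no flip axis")
  kT <- .kB * temperature
  f <- function(q) exp(-ls_potential(landscape, rep(s, length(q)), q) / kT)
  zout <- integrate(f, 0, qlim, rel.tol = 1e-10)$value
  zin <- integrate(f, -qlim, 0, rel.tol = 1e-10)$value
  -kT * log(zout / zin)
}

#' @export
print.toy_landscape <- function(x, ...) {
  cat(sprintf(
    "Toy landscape (%dD), T = %g K, domain [%g, %g]\n", x$dim,
    x$temperature, x$domain[1], x$domain[2]
  ))
  if (nrow(x$features) > 0) {
    cat("Critical points (calibrated):\n")
    print(x$features[, c("label", "role", "s", "F")], row.names = FALSE)
  }
  if (!is.null(x$harmonic)) {
    cat(sprintf(
      "Harmonic term: k = %g kcal/mol/u^2 at s = %g\n",
      x$harmonic$k, x$harmonic$center
    ))
  }
  invisible(x)
}

#' @export
plot.toy_landscape <- function(x, n = 400, ...) {
  s <- seq(x$domain[1], x$domain[2], length.out = n)
  graphics::plot(s, ls_potential(x, s),
    type = "l", xlab = "s",
    ylab = "U(s) [kcal/mol]", ...
  )
  if (nrow(x$features) > 0) {
    points(x$features$s, x$features$F,
      pch = ifelse(x$features$role == "min", 19, 4)
    )
  }
  invisible(x)
}
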