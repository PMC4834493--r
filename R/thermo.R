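#' Critical points of a 1D free-energy profile
#'
#' Local minima (filtered by a prominence threshold: the profile must rise
#' at least `min_depth` above the minimum on both sides before the next
#' retained minimum or the grid edge) and the saddle between each pair of
#' adjacent minima (the profile maximum on the connecting segment).
#' Labelling is deterministic by increasing s.
#'
#' @param fes a `fes_profile`
#' @param min_depth prominence threshold in kcal/mol
#' @return data.frame with `label`, `type` (`min`/`saddle`), `s`, `F`
#' @export
find_critical_points <- function(fes, min_depth = 0.2) {
  Fv <- fes$F
  s <- fes$s
  n <- length(Fv)
  if (diff(range(Fv)) < min_depth) {
    warning("essentially flat profile: no critical points found")
    return(data.frame(
      label = character(), type = character(),
      s = numeric(), F = numeric()
    ))
  }
  imin <- which(diff(sign(diff(Fv))) > 0) + 1L
  if (Fv[1] < Fv[2]) imin <- c(1L, imin)
  if (Fv[n] < Fv[n - 1]) imin <- c(imin, n)
  # prominence filter: lowest separating barrier to a deeper (or equal)
  # minimum, or to the grid edge, must exceed min_depth
  keep <- logical(length(imin))
  for (k in seq_along(imin)) {
    i <- imin[k]
    rise_left <- if (i == 1) Inf else max(Fv[1:i]) - Fv[i]
    rise_right <- if (i == n) Inf else max(Fv[i:n]) - Fv[i]
    # barrier to the nearest retained neighbour candidates
    lb <- if (k > 1) max(Fv[imin[k - 1]:i]) - Fv[i] else rise_left
    rb <- if (k < length(imin)) max(Fv[i:imin[k + 1]]) - Fv[i] else rise_right
    keep[k] <- min(lb, rb) >= min_depth
  }
  imin <- imin[keep]
  if (length(imin) == 0) {
    warning("no minima exceed the prominence threshold")
    return(data.frame(
      label = character(), type = character(),
      s = numeric(), F = numeric()
    ))
  }
  out <- data.frame(
    label = LETTERS[seq_along(imin)], type = "min",
    s = s[imin], F = Fv[imin]
  )
  if (length(imin) > 1) {
    for (k in seq_len(length(imin) - 1)) {
      seg <- imin[k]:imin[k + 1]
      im <- seg[which.max(Fv[seg])]
      out <- rbind(out, data.frame(
        label = paste0("ts", k), type = "saddle", s = s[im], F = Fv[im]
      ))
    }
  }
  out <- out[order(out$s), ]
  rownames(out) <- NULL
  out
}

#' Watershed basin assignment on a 1D grid
#'
#' Assigns each grid bin to the minimum it drains to by steepest descent.
#'
#' @param fes a `fes_profile`
#' @param minima optional critical-point table from
#'   [find_critical_points()]
#' @return integer vector of basin ids (index into the minima, by
#'   increasing s), with the minima table as attribute `minima`
#' @export
watershed_basins <- function(fes, minima = NULL) {
  if (is.null(minima)) minima <- find_critical_points(fes)
  mins <- minima[minima$type == "min", , drop = FALSE]
  n <- length(fes$F)
  assign <- integer(n)
  sink_of <- integer(n)
  for (i in seq_len(n)) {
    j <- i
    repeat {
      left <- if (j > 1) fes$F[j - 1] else Inf
      right <- if (j < n) fes$F[j + 1] else Inf
      if (left >= fes$F[j] && right >= fes$F[j]) break
      j <- if (left < right) j - 1 else j + 1
    }
    sink_of[i] <- j
  }
  for (i in seq_len(n)) {
    assign[i] <- which.min(abs(fes$s[sink_of[i]] - mins$s))
  }
  structure(assign, minima = mins)
}

#' Free-energy difference between two basins of a profile
#'
#' \eqn{\Delta G = -k_B T \log[\int_X e^{-\beta F} ds / \int_Y e^{-\beta F} ds]}
#' by trapezoidal quadrature on the profile grid; the uncertainty is
#' propagated from the per-bin errors by seeded Gaussian resampling.
#'
#' @param fes a `fes_profile`
#' @param basin_x,basin_y length-2 s intervals (X relative to Y)
#' @param temperature temperature in K
#' @param nresample resamples for the uncertainty propagation
#' @param seed RNG seed for the resampling
#' @return list with `dG` and `err` (kcal/mol)
#' @export
basin_free_energy <- function(fes, basin_x, basin_y, temperature = 300,
                              nresample = 200, seed = 1) {
  stopifnot(temperature > 0)
  kT <- .kB * temperature
  zone <- function(Fv, intv) {
    keep <- fes$s >= intv[1] & fes$s <= intv[2]
    if (sum(keep) < 2) stop("basin interval must contain at least 2 grid bins")
    if (min(Fv[keep]) >= max(fes$F) - 1e-9 && diff(range(fes$F)) > 0) {
      stop("unsampled basin: all free energies at the grid maximum")
    }
    .trapz(fes$s[keep], exp(-Fv[keep] / kT))
  }
  dG <- -kT * log(zone(fes$F, basin_x) / zone(fes$F, basin_y))
  err <- 0
  if (any(fes$err > 0)) {
    set.seed(seed)
    reps <- replicate(nresample, {
      Fr <- fes$F + rnorm(length(fes$F), 0, fes$err)
      -kT * log(zone(Fr, basin_x) / zone(Fr, basin_y))
    })
    err <- sd(reps)
  }
  list(dG = dG, err = err)
}

.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Standard-state (1 M) volume correction
#'
#' \eqn{k_B T \log(V_{unbound} / V_0)} with \eqn{V_0 = 1660} cubic Angstrom,
#' the volume per molecule at 1 M.  Added to the raw basin-integrated
#' binding free energy to refer it to the standard state.
#'
#' @param V_unbound sampled unbound volume in cubic Angstrom
#' @param temperature temperature in K
#' @return correction in kcal/mol
#' @export
standard_state_correction <- function(V_unbound, temperature = 300) {
  stopifnot(V_unbound > 0)
  .kB * temperature * log(V_unbound / .V0_A3)
}

#' Standard-state corrected binding free energy
#' @param dG_raw raw basin-integrated binding free energy (kcal/mol)
#' @param V_unbound sampled unbound volume in cubic Angstrom
#' @param temperature temperature in K
#' @param err uncertainty on `dG_raw`
#' @return a `binding_dG` list: `dG_raw`, `correction`, `dG_std`
#'   (= dG_raw + correction, exact), `err`
#' @export
binding_free_energy <- function(dG_raw, V_unbound, temperature = 300,
                                err = 0) {
  corr <- standard_state_correction(V_unbound, temperature)
  structure(
    list(
      dG_raw = dG_raw, correction = corr,
      dG_std = dG_raw + corr, err = err
    ),
    class = "binding_dG"
  )
}

#' @export
print.binding_dG <- function(x, ...) {
  cat(sprintf(
    "Binding dG: raw %.2f + std-state correction %.2f = %.2f +/- %.2f kcal/mol\n",
    x$dG_raw, x$correction, x$dG_std, x$err
  ))
  invisible(x)
}

#' Thermodynamic cycle for the two binding routes
#'
#' The conformational-selection route ("flip-bind": the kinase flips to
#' DFG-out first, paying the flip penalty, then binds along the path) and
#' the induced-fit route ("bind-flip": binding drives the flip, all in the
#' path term) must close to the same total.
#'
#' @param path_dG free energy of the association path component (kcal/mol)
#' @param flip_dG DFG-flip penalty component (kcal/mol; 0 for bind-flip)
#' @param route `"flip-bind"` or `"bind-flip"`
#' @return a `thermo_cycle`: components and their `total` (exact sum)
#' @examples
#' combine_cycle(-14, 6, "flip-bind")$total # -8
#' @export
combine_cycle <- function(path_dG, flip_dG = 0, route = c(
                            "flip-bind",
                            "bind-flip"
                          )) {
  route <- match.arg(route)
  stopifnot(is.finite(path_dG), is.finite(flip_dG))
  structure(
    list(
      route = route,
      components = c(
        `path association` = path_dG,
        `DFG-flip penalty` = flip_dG
      ),
      total = path_dG + flip_dG
    ),
    class = "thermo_cycle"
  )
}

#' @export
print.thermo_cycle <- function(x, ...) {
  cat(sprintf("Thermodynamic cycle (%s):\n", x$route))
  for (nm in names(x$components)) {
    cat(sprintf("  %-18s %+7.2f kcal/mol\n", nm, x$components[[nm]]))
  }
  cat(sprintf("  %-18s %+7.2f kcal/mol\n", "total", x$total))
  invisible(x)
}

#' Cycle-closure check between two routes
#' @param cycle_a,cycle_b `thermo_cycle` objects
#' @param err_a,err_b route uncertainties (kcal/mol)
#' @return list with the absolute `gap`, the combined uncertainty and
#'   logical `closed`
#' @export
cycle_closure <- function(cycle_a, cycle_b, err_a = 0, err_b = 0) {
  gap <- abs(cycle_a$total - cycle_b$total)
  tol <- sqrt(err_a^2 + err_b^2)
  list(gap = gap, tol = tol, closed = gap <= max(tol, 1e-10))
}

#' Boltzmann populations of discrete states
#' @param dG state free energies (kcal/mol; any common offset cancels)
#' @param temperature temperature in K
#' @return normalized populations (sum exactly 1)
#' @export
boltzmann_population <- function(dG, temperature = 300) {
  if (length(dG) < 2) stop("need at least 2 states")
  w <- exp(-(dG - min(dG)) / (.kB * temperature))
  w / sum(w)
}

#' Barrier height from a profile
#' @param fes a `fes_profile`
#' @param basin length-2 s interval of the starting basin
#' @param saddle_s s position of the saddle
#' @return list with `dG_barrier` (F(saddle) - min F in basin) and `err`
#'   (basin-minimum and saddle bin errors combined in quadrature)
#' @export
barrier_height <- function(fes, basin, saddle_s) {
  keep <- fes$s >= basin[1] & fes$s <= basin[2]
  i0 <- which(keep)[which.min(fes$F[keep])]
  is <- which.min(abs(fes$s - saddle_s))
  if (fes$F[is] < fes$F[i0] - 1e-12) {
    stop("saddle lies below the basin minimum")
  }
  list(
    dG_barrier = fes$F[is] - fes$F[i0],
    err = sqrt(fes$err[is]^2 + fes$err[i0]^2)
  )
}
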