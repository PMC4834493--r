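#' Well-tempered metadynamics on a toy landscape
#'
#' Runs `nwalkers` Langevin walkers that share a single history-dependent
#' bias.  Every `pace` steps each walker deposits a Gaussian hill of width
#' `sigma` at its current position; in the well-tempered variant the hill
#' height is scaled as \eqn{w_k = w_0 \exp(-V_b(s_k)/(k_B \Delta T))} with
#' \eqn{\Delta T = (\gamma - 1) T}.  `gamma = Inf` gives standard
#' (constant-height) metadynamics.
#'
#' @param landscape a `toy_landscape`
#' @param nsteps integration steps per walker
#' @param params list of metadynamics parameters: `w0` initial hill height
#'   (kcal/mol), `sigma` hill width (s units), `gamma` bias factor (> 1, or
#'   `Inf`), `pace` deposition stride in steps (>= 10)
#' @param nwalkers number of walkers sharing the bias
#' @param seed integer RNG seed
#' @param dt,friction,mass,stride,temperature integrator settings as in
#'   [langevin_run()]
#' @param x0 starting positions (recycled over walkers; default: declared
#'   minima, recycled)
#' @param grid_dx bias grid spacing (s units)
#' @return list with `hills` (a `hills_log`), `traj` (matrix of strided
#'   walker positions with attribute `time_ps`) and `bias` (final bias grid)
#' @examples
#' ls <- landscape_preset("double_well")
#' md <- run_metad(ls, nsteps = 5e4, seed = 1)
#' fes <- reconstruct_fes(md$hills, grid = seq(-4, 4, 0.05))
#' @export
run_metad <- function(landscape, nsteps,
                      params = list(w0 = 0.1, sigma = 0.3, gamma = 8, pace = 500),
                      nwalkers = 1, seed = 1, dt = 0.02, friction = 1,
                      mass = 1, stride = 100,
                      temperature = landscape$temperature, x0 = NULL,
                      grid_dx = 0.05) {
  stopifnot(inherits(landscape, "toy_landscape"))
  defaults <- list(w0 = 0.1, sigma = 0.3, gamma = 8, pace = 500)
  params <- utils::modifyList(defaults, params)
  if (params$pace < 10) stop("pace must be at least 10 integrator steps")
  if (!is.infinite(params$gamma) && params$gamma <= 1) {
    stop("bias factor gamma must exceed 1 in well-tempered mode (use gamma = Inf for standard metadynamics)")
  }
  .check_dt(landscape, dt, mass, temperature)
  if (is.null(x0)) {
    mins <- landscape$features[landscape$features$role == "min", , drop = FALSE]
    x0 <- if (nrow(mins) > 0) mins$s else mean(landscape$domain)
  }
  x0 <- rep_len(x0, nwalkers)
  h <- landscape$harmonic
  pad <- 6 * params$sigma
  glo <- landscape$domain[1] - pad
  ghi <- landscape$domain[2] + pad
  set.seed(seed)
  res <- cpp_metad(
    landscape$terms$center, landscape$terms$height,
    landscape$terms$width, landscape$domain[1], landscape$domain[2],
    landscape$kwall, if (is.null(h)) -1 else h$k,
    if (is.null(h)) 0 else h$center,
    x0, as.integer(nsteps), dt, as.integer(stride), friction,
    temperature, mass, params$w0, params$sigma,
    if (is.infinite(params$gamma)) -1 else params$gamma,
    as.integer(params$pace), glo, ghi, grid_dx
  )
  if (isTRUE(res$diverged)) {
    stop("walker divergence: a walker left the domain by more than 10x its span; see the deposition log up to the abort")
  }
  hills <- hills_log(data.frame(
    time = res$hill_time, s = res$hill_center, sigma_s = params$sigma,
    height = res$hill_height, biasf = params$gamma,
    walker = res$hill_walker
  ))
  traj <- res$traj
  attr(traj, "time_ps") <- res$rec_time
  list(
    hills = hills, traj = traj,
    bias = list(
      s = seq(glo, by = grid_dx, length.out = length(res$bias_grid)),
      bias = res$bias_grid
    )
  )
}

#' HILLS logs (PLUMED text dialect)
#'
#' A `hills_log` is a data.frame of deposited bias Gaussians with columns
#' `time` (ps), `s` (center), `sigma_s` (width), `height` (kcal/mol),
#' `biasf` (bias factor, `Inf` for standard metadynamics) and `walker`.
#'
#' @param df data.frame with the columns above (`walker` optional)
#' @return a `hills_log`
#' @export
hills_log <- function(df) {
  df <- as.data.frame(df)
  need <- c("time", "s", "sigma_s", "height", "biasf")
  if (!all(need %in% names(df))) {
    stop(
      "hills log must have columns ",
      paste(need, collapse = ", ")
    )
  }
  if (is.null(df$walker)) df$walker <- rep(1L, nrow(df))
  if (nrow(df) > 0) {
    if (any(!is.finite(df$height)) || any(df$height <= 0)) {
      stop("malformed hills: heights must be positive and finite")
    }
    if (any(!is.finite(df$sigma_s)) || any(df$sigma_s <= 0)) {
      stop("malformed hills: widths must be positive and finite")
    }
    if (any(unlist(tapply(df$time, df$walker, function(t) diff(t) < 0)))) {
      stop("malformed hills: times must be non-decreasing per walker")
    }
  }
  structure(df, class = c("hills_log", "data.frame"))
}

#' Write / read a HILLS log in the PLUMED text dialect
#'
#' Format: `#! FIELDS time s sigma_s height biasf` header then one Gaussian
#' per line.  The reader is strict: malformed widths or heights are
#' rejected.
#'
#' @param hills a `hills_log`
#' @param path file path
#' @export
write_hills <- function(hills, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#! FIELDS time s sigma_s height biasf walker", con)
  bf <- ifelse(is.infinite(hills$biasf), -1, hills$biasf)
  writeLines(sprintf(
    "%.6f %.9f %.6f %.9g %.4f %d", hills$time, hills$s,
    hills$sigma_s, hills$height, bf, hills$walker
  ), con)
  invisible(path)
}

#' @rdname write_hills
#' @export
read_hills <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#!\\s*FIELDS", lines, value = TRUE)
  if (length(hdr) == 0) stop("not a HILLS file: missing '#! FIELDS' header")
  fields <- strsplit(sub("^#!\\s*FIELDS\\s+", "", hdr[1]), "\\s+")[[1]]
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  d <- read.table(text = body, col.names = fields)
  if (!is.null(d$biasf)) d$biasf[d$biasf <= 0] <- Inf
  hills_log(d)
}

#' Reconstruct the free-energy profile from a hills log
#'
#' For well-tempered deposition the free energy is
#' \eqn{F(s) = -\gamma/(\gamma - 1) V_b(s)} (just \eqn{-V_b} for standard
#' metadynamics), with \eqn{V_b} the deposited Gaussian sum; the profile is
#' shifted so its minimum is 0.
#'
#' @param hills a `hills_log`
#' @param grid strictly increasing numeric grid over s, covering all hill
#'   centers +/- 3 sigma (default: that span at `dx` spacing)
#' @param dx spacing of the default grid
#' @param uncertainty logical; also estimate per-bin uncertainty via
#'   [fes_uncertainty()]
#' @param window final deposition fraction used for the uncertainty
#' @param nsnap profile snapshots used for the uncertainty
#' @return a `fes_profile`: list with `s`, `F` (min 0), `err`
#' @export
reconstruct_fes <- function(hills, grid = NULL, uncertainty = FALSE,
                            window = 0.2, nsnap = 10, dx = 0.05) {
  stopifnot(inherits(hills, "hills_log"))
  if (is.null(grid)) {
    grid <- seq(min(hills$s - 3 * hills$sigma_s),
      max(hills$s + 3 * hills$sigma_s) + dx,
      by = dx
    )
  }
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (nrow(hills) == 0) {
    warning("empty hills log: returning a flat profile")
    return(fes_profile(grid, rep(0, length(grid)), rep(0, length(grid))))
  }
  if (min(hills$s - 3 * hills$sigma_s) < min(grid) ||
    max(hills$s + 3 * hills$sigma_s) > max(grid)) {
    stop("grid must cover all hill centers +/- 3 sigma")
  }
  Fv <- .fes_from_hills(hills, grid)
  err <- rep(0, length(grid))
  if (uncertainty) err <- fes_uncertainty(hills, grid, window, nsnap)
  fes_profile(grid, Fv, err)
}

.fes_from_hills <- function(hills, grid) {
  V <- rep(0, length(grid))
  if (nrow(hills) == 0) {
    return(V)
  }
  # vectorized over hills in blocks to bound memory
  idx <- seq_len(nrow(hills))
  for (block in split(idx, ceiling(idx / 2000))) {
    V <- V + colSums(hills$height[block] *
      exp(-0.5 * ((outer(hills$s[block], grid, "-")) /
        hills$sigma_s[block])^2))
  }
  g <- hills$biasf[1]
  fac <- if (is.infinite(g)) 1 else g / (g - 1)
  Fv <- -fac * V
  Fv - min(Fv)
}

#' Per-bin uncertainty of a reconstructed profile
#'
#' Standard deviation over mean-aligned profiles reconstructed at `nsnap`
#' evenly spaced deposition times inside the final `window` fraction of the
#' run (metadynamics profiles are defined up to a constant, so each
#' snapshot has its mean over the alignment region subtracted first).
#'
#' @inheritParams reconstruct_fes
#' @param align_region optional length-2 interval on s over which snapshot
#'   means are aligned (default: the whole grid)
#' @return per-bin standard deviation, kcal/mol
#' @export
fes_uncertainty <- function(hills, grid, window = 0.2, nsnap = 10,
                            align_region = NULL) {
  stopifnot(inherits(hills, "hills_log"))
  if (window <= 0 || window > 1) {
    stop("window must be a fraction of the run in (0, 1]")
  }
  if (nsnap < 5) stop("need at least 5 reconstruction snapshots")
  tmax <- max(hills$time)
  t0 <- tmax * (1 - window)
  times <- seq(t0, tmax, length.out = nsnap)
  keep <- if (is.null(align_region)) {
    rep(TRUE, length(grid))
  } else {
    grid >= align_region[1] & grid <= align_region[2]
  }
  profs <- sapply(times, function(tt) {
    f <- .fes_from_hills(hills[hills$time <= tt, , drop = FALSE], grid)
    f - mean(f[keep])
  })
  apply(profs, 1, sd)
}

#' Basin free-energy difference from a hills log, with sampling uncertainty
#'
#' Reconstructs the profile at `nsnap` deposition times inside the final
#' `window` fraction, computes the basin free-energy difference at each
#' snapshot and reports the final-profile estimate together with a
#' `level` confidence half-width from the snapshot spread (which captures
#' the correlated drift of the whole profile that per-bin errors miss).
#'
#' @inheritParams fes_uncertainty
#' @param basin_x,basin_y length-2 s intervals
#' @param temperature temperature in K
#' @param level confidence level for the half-width
#' @return list with `dG`, `err` (half-width, kcal/mol) and the snapshot
#'   values
#' @export
metad_dG <- function(hills, basin_x, basin_y, temperature = 300,
                     window = 0.2, nsnap = 10, level = 0.95) {
  stopifnot(inherits(hills, "hills_log"))
  if (window <= 0 || window > 1) stop("window must be in (0, 1]")
  if (nsnap < 5) stop("need at least 5 snapshots")
  tmax <- max(hills$time)
  times <- seq(tmax * (1 - window), tmax, length.out = nsnap)
  grid <- seq(min(hills$s - 3 * hills$sigma_s),
    max(hills$s + 3 * hills$sigma_s) + 0.05,
    by = 0.05
  )
  vals <- vapply(times, function(tt) {
    f <- fes_profile(grid, .fes_from_hills(
      hills[hills$time <= tt, , drop = FALSE], grid
    ))
    basin_free_energy(f, basin_x, basin_y, temperature)$dG
  }, 0)
  zq <- qnorm(1 - (1 - level) / 2)
  list(dG = vals[nsnap], err = zq * sd(vals), snapshots = vals)
}

#' Free-energy profile container
#' @param s strictly increasing grid
#' @param F free energies, kcal/mol (shifted so min(F) = 0)
#' @param err per-bin uncertainty, kcal/mol (>= 0)
#' @return a `fes_profile`
#' @export
fes_profile <- function(s, F, err = rep(0, length(s))) {
  if (any(diff(s) <= 0)) stop("grid must be strictly increasing")
  if (any(err < 0)) stop("uncertainty must be non-negative")
  F <- F - min(F)
  structure(list(s = s, F = F, err = err), class = "fes_profile")
}

#' @export
print.fes_profile <- function(x, ...) {
  cat(sprintf(
    "Free-energy profile: %d bins on [%g, %g], range %.3g kcal/mol, median err %.3g\n",
    length(x$s), min(x$s), max(x$s), max(x$F), median(x$err)
  ))
  invisible(x)
}

#' @export
plot.fes_profile <- function(x, ...) {
  graphics::plot(x$s, x$F,
    type = "l", xlab = "s", ylab = "F(s) [kcal/mol]",
    ...
  )
  if (any(x$err > 0)) {
    lines(x$s, x$F + x$err, lty = 3)
    lines(x$s, pmax(x$F - x$err, 0), lty = 3)
  }
  invisible(x)
}

#' Write / read a free-energy profile as TSV (s, F, err)
#' @param fes a `fes_profile`
#' @param path file path
#' @export
write_fes <- function(fes, path) {
  write.table(data.frame(s = fes$s, F = fes$F, err = fes$err), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_fes
#' @export
read_fes <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t")
  fes_profile(d$s, d$F, d$err)
}

#' One parallel-tempering exchange sweep
#'
#' Attempts Metropolis swaps between neighbouring replicas: a swap of
#' replicas i and j is accepted with probability
#' \eqn{\min(1, \exp[(\beta_i - \beta_j)(U_i - U_j)])}, where U includes
#' any bias attached to a replica.
#'
#' @param states list of replica states, each a list with `x` (position),
#'   `temperature` (K), `landscape` (shared `toy_landscape`) and optional
#'   `bias` (grid list as in [langevin_run()])
#' @param seed integer RNG seed
#' @return list with the (possibly swapped) `states` and an `exchanges`
#'   data.frame of attempts (`i`, `j`, `prob`, `accepted`)
#' @export
replica_exchange_step <- function(states, seed = 1) {
  if (length(states) < 2) stop("need at least 2 replicas")
  ref <- states[[1]]$landscape
  for (st in states) {
    if (!identical(st$landscape$terms, ref$terms)) {
      stop("mismatched landscape between replicas")
    }
  }
  energy_of <- function(st) {
    u <- ls_potential(st$landscape, st$x)
    if (!is.null(st$bias)) {
      u <- u + approx(st$bias$s, st$bias$bias, xout = st$x, rule = 2)$y
    }
    u
  }
  set.seed(seed)
  rec <- NULL
  for (i in seq_len(length(states) - 1)) {
    j <- i + 1
    bi <- 1 / (.kB * states[[i]]$temperature)
    bj <- 1 / (.kB * states[[j]]$temperature)
    ui <- energy_of(states[[i]])
    uj <- energy_of(states[[j]])
    prob <- min(1, exp((bi - bj) * (ui - uj)))
    acc <- runif(1) < prob
    if (acc) {
      xi <- states[[i]]$x
      states[[i]]$x <- states[[j]]$x
      states[[j]]$x <- xi
    }
    rec <- rbind(rec, data.frame(i = i, j = j, prob = prob, accepted = acc))
  }
  list(states = states, exchanges = rec)
}
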