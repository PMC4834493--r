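#' 15N relaxation from the Lipari-Szabo spectral density
#'
#' Model-free spectral density
#' \deqn{J(\omega) = \frac{2}{5}\left[\frac{S^2 \tau_c}{1 + (\omega\tau_c)^2}
#'   + \frac{(1 - S^2)\tau'}{1 + (\omega\tau')^2}\right],\quad
#'   1/\tau' = 1/\tau_c + 1/\tau_e,}
#' with the standard 15N dipolar/CSA expressions for R1, R2 and the
#' heteronuclear NOE.  Interaction constants: N-H bond length 1.02 A,
#' 15N CSA -160 ppm, standard gyromagnetic ratios.
#'
#' @param S2 order parameters in (0, 1]
#' @param tauc_ns global tumbling time (ns)
#' @param te_ps internal correlation time (ps); 0 collapses tau' to 0
#' @param rex exchange contribution added to R2 (1/s)
#' @param field_MHz spectrometer 1H frequency
#' @return list with vectors `R1`, `R2` (1/s) and `NOE`
#' @export
relaxation_rates <- function(S2, tauc_ns, te_ps = 0, rex = 0,
                             field_MHz = 700) {
  gH <- 2.6752218744e8 # rad/s/T
  gN <- -2.7126e7
  hbar <- 1.054571817e-34
  rNH <- 1.02e-10
  csa <- -160e-6
  B0 <- 2 * pi * field_MHz * 1e6 / gH
  wH <- gH * B0
  wN <- gN * B0 # negative
  d <- 1e-7 * gH * gN * hbar / rNH^3 # rad/s
  d2 <- d^2
  c2 <- (wN * csa)^2 / 3
  tauc <- tauc_ns * 1e-9
  te <- te_ps * 1e-12
  tp <- ifelse(te > 0, 1 / (1 / tauc + 1 / te), 0)
  Jw <- function(w) {
    (2 / 5) * (S2 * tauc / (1 + (w * tauc)^2) +
      (1 - S2) * tp / (1 + (w * tp)^2))
  }
  J0 <- Jw(0)
  JN <- Jw(abs(wN))
  JH <- Jw(abs(wH))
  JmN <- Jw(abs(wH - wN))
  JpN <- Jw(abs(wH + wN))
  R1 <- (d2 / 4) * (JmN + 3 * JN + 6 * JpN) + c2 * JN
  R2 <- (d2 / 8) * (4 * J0 + JmN + 3 * JN + 6 * JH + 6 * JpN) +
    (c2 / 6) * (4 * J0 + 3 * JN) + rex
  NOE <- 1 + (d2 / 4) * (gH / gN) * (6 * JpN - JmN) / R1
  list(R1 = R1, R2 = R2, NOE = NOE)
}

#' Lipari-Szabo model-free fit of a relaxation table
#'
#' Two-stage fit: (1) the global isotropic tumbling time from the trimmed
#' R2/R1 ratio (the ratio is independent of S2 in the single-Lorentzian
#' limit), optionally refined by minimizing the pooled misfit of the
#' trimmed subset; (2) per-residue model selection among (S2), (S2, te)
#' and (S2, Rex) by an information criterion on the error-weighted misfit
#' (chi^2 + 2 k), tie-breaking toward the simpler model.
#'
#' @param data relaxation table from [gen_relaxation()] or
#'   [read_relaxation()]: columns `residue`, `R1`, `R2`, `NOE` (+ optional
#'   `*_err`), attribute or argument `field_MHz`
#' @param field_MHz spectrometer 1H frequency (default from the table)
#' @param tauc_ns optional fixed tumbling time (skips stage 1)
#' @param refine logical; refine the ratio-derived tauc against the pooled
#'   per-residue misfit
#' @param noe_min,trim trimming controls for the rigid subset
#' @return a `modelfree_fit`: global `tauc_ns` plus a per-residue table
#'   with `S2`, `te_ps`, `Rex`, `model`, `chisq`
#' @export
fit_modelfree <- function(data, field_MHz = attr(data, "field_MHz"),
                          tauc_ns = NULL, refine = TRUE, noe_min = 0.65,
                          trim = 0.1) {
  d <- as.data.frame(data)
  stopifnot(all(c("residue", "R1", "R2", "NOE") %in% names(d)))
  if (is.null(field_MHz)) stop("field_MHz must be supplied")
  n <- nrow(d)
  if (n < 10) stop("need at least 10 residues for the global tauc stage")
  err <- function(col, vals) {
    e <- d[[paste0(col, "_err")]]
    if (is.null(e)) e <- rep(0, n)
    pmax(e, 1e-3 * abs(vals)) # relative floor keeps chi^2 well defined
  }
  eR1 <- err("R1", d$R1)
  eR2 <- err("R2", d$R2)
  eNOE <- err("NOE", d$NOE)
  if (any(d$R2 < d$R1)) {
    warning("R2 < R1 for some residues (unexpected for ns tumbling); flagged, not rejected")
  }
  # rigid subset: NOE high enough, R1R2 inside the trimmed band
  r1r2 <- d$R1 * d$R2
  qs <- quantile(r1r2, c(trim, 1 - trim))
  rigid <- which(d$NOE > noe_min & r1r2 >= qs[1] & r1r2 <= qs[2])
  if (length(rigid) < 3) stop("tauc unidentifiable: no residue passes the rigid-subset trim")
  if (is.null(tauc_ns)) {
    ratio <- median(d$R2[rigid] / d$R1[rigid])
    ratio_of <- function(tc) {
      rr <- relaxation_rates(0.9, tc, 0, 0, field_MHz)
      rr$R2 / rr$R1
    }
    tauc_ns <- uniroot(function(tc) ratio_of(tc) - ratio, c(0.5, 100),
      tol = 1e-8
    )$root
    if (refine) {
      sub <- rigid[seq(1, length(rigid), length.out = min(15, length(rigid)))]
      pooled <- function(tc) {
        sum(vapply(sub, function(i) {
          .mf_fit_residue(
            d$R1[i], d$R2[i], d$NOE[i], eR1[i], eR2[i],
            eNOE[i], tc, field_MHz
          )$chisq
        }, 0))
      }
      tauc_ns <- optimize(pooled, tauc_ns * c(0.9, 1.1), tol = 1e-4)$minimum
    }
  }
  fits <- lapply(seq_len(n), function(i) {
    .mf_fit_residue(
      d$R1[i], d$R2[i], d$NOE[i], eR1[i], eR2[i], eNOE[i],
      tauc_ns, field_MHz
    )
  })
  tab <- data.frame(
    residue = d$residue,
    S2 = vapply(fits, `[[`, 0, "S2"),
    te_ps = vapply(fits, `[[`, 0, "te_ps"),
    Rex = vapply(fits, `[[`, 0, "Rex"),
    model = vapply(fits, `[[`, 0L, "model"),
    chisq = vapply(fits, `[[`, 0, "chisq")
  )
  structure(
    list(
      tauc_ns = tauc_ns, table = tab, field_MHz = field_MHz,
      rigid_subset = d$residue[rigid]
    ),
    class = "modelfree_fit"
  )
}

# per-residue model selection: model 1 (S2), 2 (S2, te), 3 (S2, Rex)
.mf_fit_residue <- function(R1, R2, NOE, e1, e2, e3, tauc_ns, field) {
  obs <- c(R1, R2, NOE)
  errs <- c(e1, e2, e3)
  chi <- function(S2, te, rex) {
    rr <- relaxation_rates(S2, tauc_ns, te, rex, field)
    sum(((c(rr$R1, rr$R2, rr$NOE) - obs) / errs)^2)
  }
  # model 1
  f1 <- optimize(function(p) chi(p, 0, 0), c(1e-3, 1), tol = 1e-9)
  best <- list(
    S2 = f1$minimum, te_ps = NA_real_, Rex = NA_real_,
    model = 1L, chisq = f1$objective, crit = f1$objective + 2
  )
  # model 2
  f2 <- optim(c(max(min(f1$minimum, 0.99), 0.05), 30),
    function(p) chi(p[1], p[2], 0),
    method = "L-BFGS-B",
    lower = c(1e-3, 1e-3), upper = c(1, 0.5 * tauc_ns * 1e3)
  )
  if (f2$value + 4 < best$crit - 1e-9) {
    best <- list(
      S2 = f2$par[1], te_ps = f2$par[2], Rex = NA_real_,
      model = 2L, chisq = f2$value, crit = f2$value + 4
    )
  }
  # model 3
  f3 <- optim(c(max(min(f1$minimum, 0.99), 0.05), 1),
    function(p) chi(p[1], 0, p[2]),
    method = "L-BFGS-B",
    lower = c(1e-3, 0), upper = c(1, 100)
  )
  if (f3$value + 4 < best$crit - 1e-9) {
    best <- list(
      S2 = f3$par[1], te_ps = NA_real_, Rex = f3$par[2],
      model = 3L, chisq = f3$value, crit = f3$value + 4
    )
  }
  best
}

#' @export
print.modelfree_fit <- function(x, ...) {
  cat(sprintf(
    "Model-free fit: tauc = %.2f ns, %d residues, mean S2 = %.3f (models: %s)\n",
    x$tauc_ns, nrow(x$table), mean(x$table$S2),
    paste(names(table(x$table$model)), table(x$table$model),
      sep = ":",
      collapse = " "
    )
  ))
  invisible(x)
}

#' @export
coef.modelfree_fit <- function(object, ...) {
  setNames(object$table$S2, object$table$residue)
}

#' @export
summary.modelfree_fit <- function(object, ...) {
  cat(sprintf(
    "tauc = %.3f ns; S2: mean %.3f, median %.3f, range [%.3f, %.3f]\n",
    object$tauc_ns, mean(object$table$S2), median(object$table$S2),
    min(object$table$S2), max(object$table$S2)
  ))
  invisible(object$table)
}

#' Flag exchange-broadened residues from the R1R2 product
#'
#' Residues whose `R1 * R2` exceeds the 10 percent trimmed mean by more
#' than `nsd` trimmed standard deviations are flagged as carrying mu-s to
#' ms exchange (Rex) contributions.
#'
#' @param data relaxation table (columns `R1`, `R2`, `residue`)
#' @param nsd threshold in trimmed standard deviations
#' @return integer vector of flagged residue numbers
#' @export
r1r2_exchange_flag <- function(data, nsd = 1.5) {
  d <- as.data.frame(data)
  if (nrow(d) < 5) stop("need at least 5 residues to estimate the R1R2 baseline")
  p <- d$R1 * d$R2
  qs <- quantile(p, c(0.1, 0.9))
  core <- p[p >= qs[1] & p <= qs[2]]
  thr <- mean(core) + nsd * sd(core)
  if (!is.finite(thr)) {
    return(integer(0))
  }
  d$residue[p > thr]
}

#' Chemical-shift table constructor
#' @param df data.frame with columns `residue`, `aa`, `dH_ppm`, `dN_ppm`,
#'   `visible`, `assigned`
#' @param state `"apo"` or `"bound"`
#' @return a `shift_table`
#' @export
shift_table <- function(df, state = "apo") {
  df <- as.data.frame(df)
  need <- c("residue", "aa", "dH_ppm", "dN_ppm", "visible", "assigned")
  stopifnot(all(need %in% names(df)))
  if (any(df$assigned & !df$visible)) {
    stop("assigned residues must be visible")
  }
  if (any(df$visible & (!is.finite(df$dH_ppm) | !is.finite(df$dN_ppm)))) {
    stop("visible residues must have finite shifts")
  }
  structure(df, class = c("shift_table", "data.frame"), state = state)
}

#' Combined chemical-shift perturbation and signal bookkeeping
#'
#' For residues visible in both states,
#' \eqn{\Delta\delta = \sqrt{\Delta\delta_H^2 + (\alpha \Delta\delta_N)^2}}
#' with nitrogen weight `alpha` (default 0.15).  Residues are classed as
#' `appearing` (invisible in the first state, visible in the second),
#' `disappearing`, `unchanged` (visible in both) or `absent`.  The
#' bookkeeping block reports total/visible/assigned counts for the first
#' state and the percentage of visible signals that are assigned.
#'
#' @param apo,bound `shift_table`s with matching residue numbering
#' @param alpha nitrogen weight
#' @return a `csp_result`: per-residue `table` (with `dd_ppm`, `class`)
#'   and `bookkeeping`
#' @export
csp <- function(apo, bound, alpha = 0.15) {
  stopifnot(inherits(apo, "shift_table"), inherits(bound, "shift_table"))
  if (nrow(apo) != nrow(bound) || any(apo$residue != bound$residue)) {
    bad <- if (nrow(apo) == nrow(bound)) {
      i <- which(apo$residue != bound$residue)[1]
      sprintf("%s vs residue %s", apo$residue[i], bound$residue[i])
    } else {
      "(tables differ in length)"
    }
    stop("residue numbering mismatch, first conflict at residue ", bad)
  }
  both <- apo$visible & bound$visible
  ddH <- bound$dH_ppm - apo$dH_ppm
  ddN <- bound$dN_ppm - apo$dN_ppm
  dd <- ifelse(both, sqrt(ddH^2 + (alpha * ddN)^2), NA_real_)
  cls <- ifelse(both, "unchanged",
    ifelse(!apo$visible & bound$visible, "appearing",
      ifelse(apo$visible & !bound$visible, "disappearing", "absent")
    )
  )
  book <- list(
    total = nrow(apo), visible = sum(apo$visible),
    assigned = sum(apo$assigned),
    pct_assigned_of_visible = round(100 * sum(apo$assigned) /
      sum(apo$visible)),
    appearing = sum(cls == "appearing"),
    disappearing = sum(cls == "disappearing")
  )
  structure(
    list(
      table = data.frame(
        residue = apo$residue, ddH_ppm = ddH,
        ddN_ppm = ddN, dd_ppm = dd, class = cls
      ),
      bookkeeping = book, alpha = alpha
    ),
    class = "csp_result"
  )
}

#' @export
print.csp_result <- function(x, ...) {
  b <- x$bookkeeping
  cat(sprintf(
    "CSP: %d residues; %d visible, %d assigned (%d%%) in the reference state\n",
    b$total, b$visible, b$assigned, b$pct_assigned_of_visible
  ))
  cat(sprintf(
    "  appearing %d, disappearing %d; median |dd| = %.3g ppm\n",
    b$appearing, b$disappearing, median(x$table$dd_ppm, na.rm = TRUE)
  ))
  invisible(x)
}

# Random-coil 1H(N)/15N reference shifts (ppm); simplified consensus
# values used by the chemical-shift index.
.random_coil <- data.frame(
  aa = c(
    "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
    "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
    "TYR", "VAL"
  ),
  dH_ppm = c(
    8.24, 8.23, 8.40, 8.34, 8.32, 8.32, 8.42, 8.33, 8.42, 8.00,
    8.16, 8.29, 8.28, 8.30, NA, 8.31, 8.15, 8.25, 8.12, 8.03
  ),
  dN_ppm = c(
    123.8, 120.5, 118.7, 120.4, 118.8, 119.8, 120.2, 108.8,
    118.2, 119.9, 121.8, 120.4, 119.6, 120.3, NA, 115.7, 113.6,
    121.3, 120.3, 119.2
  )
)

#' Chemical-shift index against random-coil reference values
#'
#' Per-residue secondary shift (observed minus random coil) and a
#' three-level index: +1 above `threshold`, -1 below `-threshold`,
#' else 0.  Residues whose amino-acid type is missing from the reference
#' are skipped with a warning.
#'
#' @param shifts a `shift_table`
#' @param reference reference table with `aa` and the chosen column
#'   (default: built-in simplified random-coil HN/N values)
#' @param column `"dH_ppm"` or `"dN_ppm"`
#' @param threshold index threshold in ppm
#' @return data.frame `residue`, `secondary_shift`, `index`
#' @export
csi <- function(shifts, reference = NULL, column = "dH_ppm",
                threshold = 0.7) {
  stopifnot(inherits(shifts, "shift_table"))
  if (is.null(reference)) reference <- .random_coil
  ref <- setNames(reference[[column]], reference$aa)
  have <- shifts$aa %in% names(ref)[!is.na(ref)]
  if (any(!have & shifts$visible)) {
    warning(
      "skipping residues with no random-coil reference: ",
      paste(unique(shifts$aa[!have & shifts$visible]), collapse = ", ")
    )
  }
  keep <- have & shifts$visible
  sec <- shifts[[column]][keep] - ref[shifts$aa[keep]]
  data.frame(
    residue = shifts$residue[keep],
    secondary_shift = as.numeric(sec),
    index = ifelse(sec > threshold, 1L, ifelse(sec < -threshold, -1L, 0L))
  )
}

#' Trajectory-derived order parameter and fluctuation amplitude
#'
#' `traj_order_parameter` estimates S2 as the plateau of the internal
#' rank-2 (P2) orientational autocorrelation of a unit-vector time series:
#' the mean of C(t) over the final plateau window.
#' `traj_rmsf` is the root-mean-square fluctuation of a coordinate series.
#'
#' @param vectors n x 3 matrix of unit vectors (tolerance 1e-6 on the
#'   norm; non-unit input is rejected)
#' @param max_lag_frac largest lag as a fraction of the series length
#' @param plateau_frac final fraction of the lag range averaged as the
#'   plateau
#' @return estimated S2 in [0, 1]
#' @export
traj_order_parameter <- function(vectors, max_lag_frac = 0.2,
                                 plateau_frac = 0.5) {
  v <- as.matrix(vectors)
  stopifnot(ncol(v) == 3)
  nrm <- sqrt(rowSums(v^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    stop("order parameter needs unit vectors (normalize first)")
  }
  n <- nrow(v)
  if (n < 50) stop("series too short for a plateau estimate")
  lags <- seq_len(max(2, floor(n * max_lag_frac)))
  Ct <- vapply(lags, function(l) {
    dots <- rowSums(v[1:(n - l), , drop = FALSE] *
      v[(1 + l):n, , drop = FALSE])
    mean(1.5 * dots^2 - 0.5)
  }, 0)
  win <- lags > max(lags) * (1 - plateau_frac)
  max(0, min(1, mean(Ct[win])))
}

#' @rdname traj_order_parameter
#' @param coords n x k coordinate matrix (or vector)
#' @export
traj_rmsf <- function(coords) {
  x <- as.matrix(coords)
  sqrt(mean(rowSums((x - matrix(colMeans(x), nrow(x), ncol(x),
    byrow = TRUE
  ))^2)))
}

#' Per-residue trajectory dynamics table
#' @param vector_list named list of n x 3 unit-vector series (names =
#'   residue numbers)
#' @param ... passed to [traj_order_parameter()]
#' @return data.frame `residue`, `S2`
#' @export
traj_dynamics <- function(vector_list, ...) {
  data.frame(
    residue = as.integer(names(vector_list)),
    S2 = vapply(vector_list, traj_order_parameter, 0, ...)
  )
}

#' Mean percentage deviation between simulated and NMR order parameters
#' @param md data.frame `residue`, `S2` (trajectory estimates)
#' @param nmr a `modelfree_fit` or data.frame `residue`, `S2`
#' @return list with `mean_pct_deviation` and the per-residue `table`
#' @export
compare_s2 <- function(md, nmr) {
  nm <- if (inherits(nmr, "modelfree_fit")) nmr$table else as.data.frame(nmr)
  m <- merge(as.data.frame(md), nm[, c("residue", "S2")],
    by = "residue",
    suffixes = c("_md", "_nmr")
  )
  if (nrow(m) == 0) stop("no overlapping residues")
  m$pct_dev <- 100 * abs(m$S2_md - m$S2_nmr) / m$S2_nmr
  list(mean_pct_deviation = mean(m$pct_dev), table = m)
}

#' H/D-exchange fit: protection factors and local-unfolding free energies
#'
#' Per-residue single-exponential least-squares fit of the intensity decay
#' gives `k_exch`; the protection factor is `P = k_intr / k_exch` and the
#' local-unfolding free energy `dG = RT log(P)` (an exact identity).
#' Residues already exchanged out before the first timepoint are reported
#' as upper bounds on P; non-decaying curves as lower bounds.
#'
#' @param curves long-format data.frame `residue`, `time_min`, `intensity`
#' @param k_intr data.frame `residue`, `k_intr` (1/min, > 0)
#' @param temperature temperature in K (default 298, typical exchange
#'   conditions)
#' @return an `exchange_fit` data.frame: `residue`, `k_exch`, `k_intr`,
#'   `P`, `dG_unfold`, `bound` (`"none"`, `"lower"`, `"upper"`)
#' @export
hdx_fit <- function(curves, k_intr, temperature = 298) {
  d <- as.data.frame(curves)
  stopifnot(all(c("residue", "time_min", "intensity") %in% names(d)))
  ki <- setNames(k_intr$k_intr, k_intr$residue)
  if (any(ki <= 0)) stop("intrinsic rates must be positive")
  RT <- .kB * temperature
  out <- do.call(rbind, lapply(split(d, d$residue), function(dd) {
    res <- dd$residue[1]
    if (nrow(dd) < 4) stop("need at least 4 timepoints per residue")
    tt <- dd$time_min
    ii <- dd$intensity
    bound <- "none"
    k1 <- ki[[as.character(res)]]
    if (all(ii < 0.1)) {
      # fully exchanged before the first timepoint: k_exch lower bound,
      # hence an upper bound on P
      ke <- log(10) / tt[1]
      bound <- "upper"
    } else if (ii[length(ii)] > 0.8 * ii[1]) {
      # effectively no decay: k_exch upper bound, lower bound on P
      ke <- 0.05 / tt[length(tt)]
      bound <- "lower"
    } else {
      k0 <- max(-coef(lm(log(pmax(ii, 1e-3)) ~ tt))[2], 1e-8)
      fit <- try(
        minpack.lm::nlsLM(ii ~ A * exp(-k * tt),
          start = list(A = max(ii[1], 0.5), k = k0),
          lower = c(0, 0),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        ),
        silent = TRUE
      )
      ke <- if (inherits(fit, "try-error")) k0 else coef(fit)[["k"]]
    }
    P <- k1 / ke
    data.frame(
      residue = res, k_exch = ke, k_intr = k1, P = P,
      dG_unfold = RT * log(P), bound = bound
    )
  }))
  rownames(out) <- NULL
  structure(out, class = c("exchange_fit", "data.frame"), RT = RT)
}

#' @export
print.exchange_fit <- function(x, ...) {
  cat(sprintf(
    "H/D-exchange fit: %d residues, protection factors %.3g to %.3g, dG_unfold %.2f to %.2f kcal/mol (%d bounded)\n",
    nrow(x), min(x$P), max(x$P), min(x$dG_unfold), max(x$dG_unfold),
    sum(x$bound != "none")
  ))
  invisible(x)
}

#' Local-unfolding free energy from a protection factor
#' @param P protection factor (> 0)
#' @param temperature temperature in K
#' @return `RT * log(P)` in kcal/mol
#' @export
dG_from_protection <- function(P, temperature = 298) {
  stopifnot(all(P > 0))
  .kB * temperature * log(P)
}

# Simplified intrinsic-exchange coefficient table (versioned
# "BE93-simplified-1"): per-residue-type log10 factors for the acid- and
# base-catalysed pathways contributed by the residue's own side chain (L,
# applied to its amide) and by its predecessor (R).  A reduced, smoothed
# variant of the classic poly-DL-alanine referencing scheme -- adequate
# for synthetic work, not a replacement for the full published tables.
.be_coeff <- data.frame(
  aa = c(
    "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
    "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
    "TYR", "VAL"
  ),
  acid_L = c(
    0.00, -0.59, -0.58, 0.90, -0.54, -0.47, -0.90, -0.22, -0.80,
    -0.91, -0.57, -0.56, -0.64, -0.52, 0.00, -0.44, -0.79, -0.40,
    -0.41, -0.74
  ),
  acid_R = c(
    0.00, -0.32, -0.13, 0.58, -0.46, -0.27, -0.31, 0.22, -0.51,
    -0.59, -0.13, -0.29, -0.28, -0.43, -0.19, -0.39, -0.47, -0.44,
    -0.37, -0.30
  ),
  base_L = c(
    0.00, 0.08, 0.49, 0.10, 0.62, 0.06, -0.11, 0.27, 0.80,
    -0.73, -0.58, -0.04, -0.01, -0.24, 0.00, 0.37, -0.07, -0.41,
    -0.27, -0.70
  ),
  base_R = c(
    0.00, 0.22, 0.32, -0.18, 0.55, 0.20, -0.15, 0.17, 0.83,
    -0.23, -0.21, 0.12, 0.11, 0.06, -0.24, 0.30, 0.20, -0.11,
    0.05, -0.14
  )
)

#' Simplified sequence-based intrinsic exchange rates
#'
#' Reference implementation (version `BE93-simplified-1`) of the
#' sequence-dependent intrinsic amide exchange rate:
#' `k_intr = k_A 10^(AL + AR) [H+] + k_B 10^(BL + BR) [OH-]`, with
#' per-residue-type left/right log-factors from a reduced coefficient
#' table and Arrhenius temperature scaling.  Intended as a convenient
#' stand-in when no measured intrinsic-rate table is available; for real
#' analyses supply `k_intr` directly.
#'
#' @param sequence character vector of 3-letter residue codes
#' @param pH solution pH
#' @param temperature temperature in K
#' @return data.frame `residue`, `aa`, `k_intr` (1/min); prolines and the
#'   N-terminal residue get `NA` (no exchangeable backbone amide proton in
#'   the measured sense)
#' @export
intrinsic_rates <- function(sequence, pH = 7.0, temperature = 298) {
  aa <- toupper(sequence)
  bad <- setdiff(unique(aa), .be_coeff$aa)
  if (length(bad) > 0) stop("unknown residue codes: ", paste(bad, collapse = ", "))
  kA_ref <- 10^1.62 # 1/(M min) at 293 K, poly-alanine reference
  kB_ref <- 10^10.05
  Ea_A <- 14
  Ea_B <- 17 # kcal/mol activation energies
  arr <- function(Ea) exp(-Ea / .kB * (1 / temperature - 1 / 293))
  Hp <- 10^(-pH)
  OH <- 10^(-(15.7 - pH))
  co <- .be_coeff[match(aa, .be_coeff$aa), ]
  n <- length(aa)
  AL <- co$acid_L
  BL <- co$base_L
  AR <- c(NA, co$acid_R[-n])
  BR <- c(NA, co$base_R[-n])
  k <- kA_ref * arr(Ea_A) * 10^(AL + AR) * Hp +
    kB_ref * arr(Ea_B) * 10^(BL + BR) * OH
  k[aa == "PRO"] <- NA
  k[1] <- NA
  data.frame(residue = seq_len(n), aa = aa, k_intr = k)
}

#' Minimal NMR-STAR chemical-shift reader
#'
#' Extracts backbone H/N chemical shifts from the `Atom_chem_shift` loop
#' of an NMR-STAR 3 file (read-only, minimal: whitespace-separated loop
#' rows only).  Useful for importing deposited assignments.
#'
#' @param path NMR-STAR file path
#' @return a `shift_table` (all parsed residues visible and assigned)
#' @export
read_nmrstar_shifts <- function(path) {
  lines <- readLines(path)
  starts <- grep("^\\s*loop_\\s*$", lines)
  for (st in starts) {
    j <- st + 1
    tags <- character()
    while (j <= length(lines) && grepl("^\\s*_", lines[j])) {
      tags <- c(tags, sub("^\\s*", "", sub("\\s*$", "", lines[j])))
      j <- j + 1
    }
    if (!any(grepl("Atom_chem_shift", tags))) next
    tagnames <- sub("^_[A-Za-z_0-9]+\\.", "", tags)
    rows <- list()
    while (j <= length(lines) && !grepl("^\\s*(stop_|loop_)", lines[j])) {
      ln <- trimws(lines[j])
      if (nzchar(ln) && !startsWith(ln, "#")) rows[[length(rows) + 1]] <- ln
      j <- j + 1
    }
    d <- read.table(text = paste(rows, collapse = "\n"), col.names = tagnames)
    need <- c("Comp_index_ID", "Comp_ID", "Atom_ID", "Val")
    if (!all(need %in% names(d))) stop("chemical-shift loop lacks ", paste(setdiff(need, names(d)), collapse = ", "))
    d <- d[d$Atom_ID %in% c("H", "N"), need]
    wide <- merge(
      d[d$Atom_ID == "H", c("Comp_index_ID", "Comp_ID", "Val")],
      d[d$Atom_ID == "N", c("Comp_index_ID", "Val")],
      by = "Comp_index_ID", all = TRUE
    )
    names(wide) <- c("residue", "aa", "dH_ppm", "dN_ppm")
    wide$visible <- is.finite(wide$dH_ppm) & is.finite(wide$dN_ppm)
    wide$assigned <- wide$visible
    wide$aa <- toupper(wide$aa)
    return(shift_table(wide[order(wide$residue), ], state = "apo"))
  }
  stop("no Atom_chem_shift loop found")
}

#' Write / read per-residue TSV tables
#' @param x data.frame
#' @param path file path
#' @export
write_residue_table <- function(x, path) {
  write.table(as.data.frame(x), path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_residue_table
#' @export
read_residue_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t")
}

#' @rdname write_residue_table
#' @param field_MHz field attached to a re-read relaxation table
#' @export
read_relaxation <- function(path, field_MHz = 700) {
  d <- read_residue_table(path)
  attr(d, "field_MHz") <- field_MHz
  d
}
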