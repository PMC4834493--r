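#' Ground truth for the synthetic spectroscopic generators
#'
#' Deterministic per-residue ground-truth parameters feeding the NMR/SPR
#' generators, so every downstream fitter can be tested by parameter
#' recovery.  The apo and bound presets differ only in the mean order
#' parameter (0.85 vs 0.87): most of the chain is rigid, the termini and
#' two loop segments are mobile, and the vector is affinely adjusted so
#' its mean hits the target exactly.  The default tumbling time is 18 ns
#' (plausible for a ~32 kDa kinase domain); protection factors span
#' 10 to 1e6 log-uniformly and the dissociation rate is drawn uniformly in
#' [0.024, 0.19] 1/s.
#'
#' @param n_res number of residues
#' @param state `"apo"` or `"bound"`
#' @param tauc_ns global tumbling time (ns)
#' @param te_ps internal correlation time (ps)
#' @param rex per-residue exchange contributions (1/s; recycled)
#' @param pocket residue indices carrying binding shift perturbations
#' @param kd_seed seed for the dissociation-rate draw (NULL: midpoint)
#' @return a `ground_truth` list
#' @export
ground_truth <- function(n_res = 250, state = c("apo", "bound"),
                         tauc_ns = 18, te_ps = 30, rex = 0,
                         pocket = 101:125, kd_seed = NULL) {
  state <- match.arg(state)
  target <- if (state == "apo") 0.85 else 0.87
  i <- seq_len(n_res)
  s2 <- rep(0.89, n_res)
  # flexible N-terminus, two mobile loops (the second stands in for the
  # helix-flanking loops that stay mobile in both forms)
  nterm <- min(8, max(2, round(n_res / 6)))
  s2[seq_len(nterm)] <- seq(0.45, 0.85, length.out = nterm)
  loop1 <- intersect(round(n_res * 0.35) + 0:5, i)
  loop2 <- intersect(round(n_res * 0.78) + 0:7, i)
  s2[loop1] <- 0.74
  s2[loop2] <- 0.70
  s2 <- s2 + 0.015 * sin(i / 7) # mild smooth variation
  # affine adjustment to hit the target mean exactly while staying in (0,1];
  # the spread is compressed if the shift would push any residue past 1
  s2 <- s2 + (target - mean(s2))
  while (any(s2 > 1 | s2 <= 0)) {
    s2 <- target + (s2 - target) * 0.9
  }
  stopifnot(all(s2 > 0 & s2 <= 1))
  if (!isTRUE(all.equal(mean(s2), target))) stop("mean adjustment failed")
  P <- 10^seq(1, 6, length.out = n_res)[order(order(sin(i * 1.7)))]
  k_intr <- rep(10, n_res) * (1 + 0.5 * cos(i / 5)) # 1/min
  kd <- if (is.null(kd_seed)) {
    mean(c(0.024, 0.19))
  } else {
    set.seed(kd_seed)
    runif(1, 0.024, 0.19)
  }
  shift <- numeric(n_res)
  shift[pocket] <- 0.12 + 0.1 * abs(sin(pocket)) # ppm, 1H-equivalent scale
  structure(
    list(
      n_res = n_res, state = state,
      S2_true = s2, tauc_true_ns = tauc_ns,
      te_true_ps = rep_len(te_ps, n_res),
      Rex_true = rep_len(rex, n_res),
      P_true = P, k_intr = k_intr, k_exch_true = k_intr / P,
      shift_map_ppm = shift, pocket = pocket, kd_true = kd
    ),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "Ground truth (%s): %d residues, mean S2 = %.3f, tauc = %g ns, kd = %.3g 1/s\n",
    x$state, x$n_res, mean(x$S2_true), x$tauc_true_ns, x$kd_true
  ))
  invisible(x)
}

#' Generate a synthetic 15N relaxation table
#'
#' R1, R2 and heteronuclear NOE computed from the model-free spectral
#' density at the stated field, plus fractional Gaussian noise.
#'
#' @param truth a `ground_truth`
#' @param field spectrometer 1H frequency in MHz (500, 600, 700 or 1000)
#' @param noise fractional standard deviation (>= 0)
#' @param seed RNG seed
#' @return a relaxation table: data.frame with `residue`, `R1`, `R2`,
#'   `NOE` and their errors, with the field in attribute `field_MHz`
#' @export
gen_relaxation <- function(truth, field = 700, noise = 0.02, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!field %in% c(500, 600, 700, 1000)) {
    stop("field must be one of 500, 600, 700, 1000 MHz")
  }
  if (noise < 0) stop("noise must be non-negative")
  stopifnot(all(truth$S2_true > 0 & truth$S2_true <= 1))
  rr <- relaxation_rates(
    truth$S2_true, truth$tauc_true_ns,
    truth$te_true_ps, truth$Rex_true, field
  )
  set.seed(seed)
  n <- truth$n_res
  noisy <- function(x) x * (1 + noise * rnorm(n))
  d <- data.frame(
    residue = seq_len(n),
    R1 = noisy(rr$R1), R2 = noisy(rr$R2), NOE = noisy(rr$NOE),
    R1_err = noise * rr$R1, R2_err = noise * rr$R2,
    NOE_err = noise * abs(rr$NOE)
  )
  attr(d, "field_MHz") <- field
  attr(d, "truth") <- truth
  d
}

#' Generate synthetic H/D-exchange decay curves
#'
#' Per-residue normalized peak intensity `exp(-k_exch * t)` plus Gaussian
#' noise, with the intrinsic rates attached.
#'
#' @param truth a `ground_truth`
#' @param timepoints strictly increasing exchange times in minutes (>= 4)
#' @param noise absolute Gaussian noise sd on the normalized intensity
#' @param seed RNG seed
#' @return long-format data.frame `residue`, `time_min`, `intensity`, with
#'   a `k_intr` table in attribute `k_intr`
#' @export
gen_hdx <- function(truth, timepoints = c(5, 15, 30, 60, 120, 240, 480, 1440),
                    noise = 0.03, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  if (length(timepoints) < 4 || any(diff(timepoints) <= 0)) {
    stop("timepoints must be strictly increasing with at least 4 points")
  }
  set.seed(seed)
  n <- truth$n_res
  d <- expand.grid(residue = seq_len(n), time_min = timepoints)
  d <- d[order(d$residue, d$time_min), ]
  d$intensity <- exp(-truth$k_exch_true[d$residue] * d$time_min) +
    noise * rnorm(nrow(d))
  rownames(d) <- NULL
  attr(d, "k_intr") <- data.frame(
    residue = seq_len(n),
    k_intr = truth$k_intr
  )
  attr(d, "truth") <- truth
  d
}

#' Generate a synthetic SPR dissociation-phase sensorgram
#'
#' `R(t) = R0 * exp(-kd * t) + baseline + noise`.
#'
#' @param kd_true dissociation rate in 1/s (> 0)
#' @param R0 initial response amplitude (RU)
#' @param baseline baseline response (RU)
#' @param noise Gaussian noise sd (RU)
#' @param duration duration in s (default 5 half-lives; a duration shorter
#'   than `1/kd_true` triggers a poorly-constrained-fit warning)
#' @param dt_s sampling interval (s)
#' @param seed RNG seed
#' @return data.frame with `time_s`, `response_RU`
#' @export
gen_sensorgram <- function(kd_true, R0 = 100, baseline = 10, noise = 1,
                           duration = NULL, dt_s = 0.1, seed = 1) {
  stopifnot(kd_true > 0)
  if (is.null(duration)) duration <- 5 * log(2) / kd_true
  if (duration < 1 / kd_true) {
    warning("duration shorter than 1/kd_true: expect a poorly constrained fit")
  }
  set.seed(seed)
  t <- seq(0, duration, by = dt_s)
  data.frame(
    time_s = t,
    response_RU = R0 * exp(-kd_true * t) + baseline +
      noise * rnorm(length(t))
  )
}

#' Generate apo/bound chemical-shift tables with visibility flags
#'
#' Binding-induced perturbations are non-zero only inside the declared
#' pocket; a configurable number of residues is invisible in the apo state
#' and becomes visible on binding (signals broadened beyond detection by
#' slow conformational exchange in the free form reappear when the ligand
#' quenches that exchange).
#'
#' @param truth a `ground_truth`
#' @param pocket pocket residue set (default: from `truth`)
#' @param n_total total backbone amides
#' @param n_visible_apo visible signals in the apo spectrum
#' @param n_assigned_apo assigned signals among the visible apo ones
#' @param seed RNG seed
#' @return list with `apo` and `bound` shift tables (columns `residue`,
#'   `aa`, `dH_ppm`, `dN_ppm`, `visible`, `assigned`)
#' @export
gen_shift_tables <- function(truth, pocket = truth$pocket, n_total = 268,
                             n_visible_apo = 196, n_assigned_apo = 179,
                             seed = 1) {
  if (n_total < 1) stop("empty residue range")
  if (!all(pocket %in% seq_len(n_total))) {
    stop("pocket must be a subset of the residue range")
  }
  set.seed(seed)
  aa3 <- c(
    "ALA", "ARG", "ASN", "ASP", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "SER", "THR", "TRP", "TYR", "VAL"
  )
  res <- seq_len(n_total)
  aa <- sample(aa3, n_total, replace = TRUE)
  dH <- 8.3 + 0.45 * rnorm(n_total)
  dN <- 119 + 4.0 * rnorm(n_total)
  # the pocket stays visible in both states so the perturbation map support
  # is exactly the pocket set
  invisible_apo <- sample(setdiff(res, pocket), n_total - n_visible_apo)
  visible_apo <- setdiff(res, invisible_apo)
  assigned_apo <- sort(sample(visible_apo, n_assigned_apo))
  apo <- data.frame(
    residue = res, aa = aa, dH_ppm = dH, dN_ppm = dN,
    visible = res %in% visible_apo, assigned = res %in% assigned_apo
  )
  apo$dH_ppm[!apo$visible] <- NA
  apo$dN_ppm[!apo$visible] <- NA
  # bound state: pocket perturbations, most missing signals reappear
  pert <- numeric(n_total)
  pert[pocket] <- truth$shift_map_ppm[pocket]
  reappear <- sample(invisible_apo, round(0.75 * length(invisible_apo)))
  visible_bound <- sort(union(visible_apo, reappear))
  bound <- data.frame(
    residue = res, aa = aa,
    dH_ppm = dH + pert * sign(sin(res * 3)),
    dN_ppm = dN + pert / 0.15 * 0.6 * sign(cos(res * 5)),
    visible = res %in% visible_bound,
    assigned = res %in% sort(union(assigned_apo, reappear))
  )
  bound$dH_ppm[!bound$visible] <- NA
  bound$dN_ppm[!bound$visible] <- NA
  bound$dH_ppm[bound$visible & !apo$visible] <- dH[bound$visible & !apo$visible]
  bound$dN_ppm[bound$visible & !apo$visible] <- dN[bound$visible & !apo$visible]
  list(apo = shift_table(apo, "apo"), bound = shift_table(bound, "bound"))
}

#' Unit vectors diffusing uniformly in a cone (for order-parameter tests)
#'
#' Draws orientations uniformly within a cone of semi-angle `theta_deg`
#' about the z axis; the equilibrium order parameter of this motion is the
#' cone-model closed form `[cos(theta) (1 + cos(theta)) / 2]^2`.
#'
#' @param theta_deg cone semi-angle in degrees
#' @param n number of frames
#' @param seed RNG seed
#' @return n x 3 matrix of unit vectors
#' @export
gen_cone_vectors <- function(theta_deg, n = 3000, seed = 1) {
  set.seed(seed)
  ct <- cos(theta_deg * pi / 180)
  cz <- runif(n, ct, 1)
  sz <- sqrt(1 - cz^2)
  phi <- runif(n, 0, 2 * pi)
  cbind(sz * cos(phi), sz * sin(phi), cz)
}
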