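# Shared fixtures, built once per test run.

fx <- new.env()

fx_default_landscape <- function() {
  if (is.null(fx$default)) fx$default <- landscape_preset("default")
  fx$default
}

fx_full_scale <- function() {
  if (is.null(fx$full)) fx$full <- landscape_preset("default", barrier = 16.5)
  fx$full
}

fx_asym_dw <- function() {
  if (is.null(fx$asym)) fx$asym <- landscape_preset("asym_double_well")
  fx$asym
}

# analytic profile of a landscape sampled on a grid, as a fes_profile
fx_analytic_fes <- function(landscape, dx = 0.02) {
  s <- seq(landscape$domain[1], landscape$domain[2], by = dx)
  fes_profile(s, ls_potential(landscape, s))
}

# hand-built shooting ensemble with prescribed commitment outcomes
fx_make_ensemble <- function(outcome_fwd, outcome_bwd, s0 = 0, saddle_s = 0) {
  n1 <- length(outcome_fwd)
  n2 <- length(outcome_bwd)
  tr <- data.frame(
    interface = 1L, s0 = s0,
    v0 = c(rep(1, n1), rep(-1, n2)),
    outcome = c(outcome_fwd, outcome_bwd),
    fpt_ps = 1
  )
  structure(
    list(
      trajectories = tr,
      interfaces = interface_set(s0, saddle_s),
      n_traj = n1 + n2, bound_s = s0 - 1, unbound_s = s0 + 1,
      temperature = 300, friction = 1, mass = 1
    ),
    class = "shooting_ensemble"
  )
}
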