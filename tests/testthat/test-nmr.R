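test_that("model-free fit recovers noiseless synthetic parameters exactly", {
  gt <- ground_truth(60, "bound", tauc_ns = 18)
  d <- gen_relaxation(gt, 700, noise = 0, seed = 1)
  mf <- fit_modelfree(d)
  expect_equal(mf$tauc_ns, 18, tolerance = 0.05 / 18)
  expect_lt(max(abs(mf$table$S2 - gt$S2_true)), 1e-3)
  expect_equal(mean(mf$table$S2), 0.87, tolerance = 1e-3)
})

test_that("apo preset mean order parameter is recovered to 3 decimals", {
  gt <- ground_truth(60, "apo")
  mf <- fit_modelfree(gen_relaxation(gt, 700, noise = 0, seed = 2))
  expect_equal(round(mean(mf$table$S2), 3), 0.85)
})

test_that("rigid-limit data select the simplest model without te", {
  gt <- ground_truth(40)
  gt$S2_true[] <- 1
  gt$te_true_ps[] <- 0
  d <- gen_relaxation(gt, 700, noise = 0, seed = 3)
  mf <- fit_modelfree(d, refine = FALSE)
  expect_true(all(mf$table$model == 1L))
  expect_true(all(is.na(mf$table$te_ps)))
  expect_equal(mf$table$S2, rep(1, 40), tolerance = 1e-3)
})

test_that("noisy round trip keeps the mean order-parameter error small", {
  gt <- ground_truth(80, "apo")
  d <- gen_relaxation(gt, 700, noise = 0.02, seed = 4)
  mf <- fit_modelfree(d)
  expect_lt(mean(abs(mf$table$S2 - gt$S2_true)), 0.02)
})

test_that("model-free fitter demands enough residues", {
  gt <- ground_truth(8)
  d <- gen_relaxation(gt, 700, noise = 0, seed = 1)
  expect_error(fit_modelfree(d), "10 residues")
})

test_that("R1R2 exchange flag isolates the injected exchange residue", {
  gt <- ground_truth(60)
  gt$S2_true[] <- 0.85 # dynamically uniform chain
  base <- gen_relaxation(gt, 700, noise = 0, seed = 5)
  expect_length(r1r2_exchange_flag(base), 0)
  gt2 <- gt
  gt2$Rex_true <- c(rep(0, 29), 5, rep(0, 30))
  d2 <- gen_relaxation(gt2, 700, noise = 0, seed = 5)
  expect_equal(r1r2_exchange_flag(d2), 30)
  expect_length(r1r2_exchange_flag(d2, nsd = Inf), 0)
  expect_error(r1r2_exchange_flag(base[1:3, ]), "5 residues")
})

test_that("combined shift perturbation follows the weighted formula", {
  mk <- function(dH, dN) {
    shift_table(data.frame(
      residue = 1:2, aa = "ALA", dH_ppm = c(8, 8 + dH),
      dN_ppm = c(119, 119 + dN), visible = TRUE, assigned = TRUE
    ))
  }
  cs <- csp(mk(0, 0), mk(0.1, 1.0), alpha = 0.15)
  expect_equal(cs$table$dd_ppm[2], sqrt(0.1^2 + 0.15^2), tolerance = 1e-12)
  expect_equal(cs$table$dd_ppm[2], 0.180, tolerance = 1e-2)
  expect_equal(cs$table$dd_ppm[1], 0)
  # identical tables: all zero, nothing appears or disappears
  same <- csp(mk(0, 0), mk(0, 0))
  expect_true(all(same$table$dd_ppm == 0))
  expect_equal(same$bookkeeping$appearing, 0)
  expect_equal(same$bookkeeping$disappearing, 0)
})

test_that("signal bookkeeping reports the assigned fraction of visible peaks", {
  gt <- ground_truth(250)
  st <- gen_shift_tables(gt,
    n_total = 268, n_visible_apo = 196,
    n_assigned_apo = 179, seed = 1
  )
  b <- csp(st$apo, st$bound)$bookkeeping
  expect_equal(b$total, 268)
  expect_equal(b$visible, 196)
  expect_equal(b$assigned, 179)
  expect_equal(b$pct_assigned_of_visible, 91)
})

test_that("state exchange swaps appearing and disappearing but keeps dd", {
  gt <- ground_truth(250)
  st <- gen_shift_tables(gt, seed = 6)
  ab <- csp(st$apo, st$bound)
  ba <- csp(st$bound, st$apo)
  expect_equal(ab$table$dd_ppm, ba$table$dd_ppm, tolerance = 1e-12)
  expect_equal(ab$bookkeeping$appearing, ba$bookkeeping$disappearing)
  expect_equal(ab$bookkeeping$disappearing, ba$bookkeeping$appearing)
})

test_that("mismatched residue numbering is reported with the first conflict", {
  a <- shift_table(data.frame(
    residue = 1:3, aa = "ALA", dH_ppm = 8,
    dN_ppm = 119, visible = TRUE, assigned = TRUE
  ))
  b <- shift_table(data.frame(
    residue = c(1, 5, 3), aa = "ALA", dH_ppm = 8,
    dN_ppm = 119, visible = TRUE, assigned = TRUE
  ))
  expect_error(csp(a, b), "residue 5")
})

test_that("chemical-shift index thresholds and reference handling", {
  st <- shift_table(data.frame(
    residue = 1:4, aa = c("ALA", "GLY", "ALA", "ALA"),
    dH_ppm = c(8.24, 8.33, 8.24 + 1, 8.24 - 1),
    dN_ppm = 119, visible = TRUE, assigned = TRUE
  ))
  idx <- csi(st, column = "dH_ppm", threshold = 0.7)
  expect_equal(idx$index, c(0L, 0L, 1L, -1L))
  expect_equal(idx$secondary_shift[1], 0, tolerance = 1e-12)
  # helix-like contiguous downfield segment is recovered as constructed
  n <- 20
  seg <- 8:13
  dh <- rep(8.24, n)
  dh[seg] <- 8.24 - 1.0
  st2 <- shift_table(data.frame(
    residue = 1:n, aa = "ALA", dH_ppm = dh,
    dN_ppm = 119, visible = TRUE, assigned = TRUE
  ))
  idx2 <- csi(st2, threshold = 0.7)
  expect_equal(idx2$residue[idx2$index == -1L], seg)
  # unknown residue type skipped with a warning
  st3 <- shift_table(data.frame(
    residue = 1:2, aa = c("ALA", "XXX"),
    dH_ppm = 8.2, dN_ppm = 119, visible = TRUE, assigned = TRUE
  ))
  expect_warning(idx3 <- csi(st3), "no random-coil reference")
  expect_equal(nrow(idx3), 1)
})

test_that("trajectory order parameter: static, cone and isotropic limits", {
  v_static <- matrix(rep(c(0, 0, 1), each = 200), ncol = 3)
  expect_equal(traj_order_parameter(v_static), 1, tolerance = 1e-12)
  expect_equal(traj_rmsf(v_static), 0, tolerance = 1e-12)
  for (th in c(10, 20, 30, 45, 60, 70, 80)) {
    v <- gen_cone_vectors(th, 3000, seed = th)
    ct <- cos(th * pi / 180)
    expect_lt(
      abs(traj_order_parameter(v) - (ct * (1 + ct) / 2)^2),
      0.02
    )
  }
  v_iso <- gen_cone_vectors(180, 4000, seed = 99)
  expect_lt(traj_order_parameter(v_iso), 0.02)
  expect_error(traj_order_parameter(2 * v_iso), "unit vectors")
})

test_that("simulation-vs-NMR order parameter deviation is computed as stated", {
  md <- data.frame(residue = 1:50, S2 = rep(0.8, 50))
  self <- compare_s2(md, data.frame(residue = 1:50, S2 = rep(0.8, 50)))
  expect_equal(self$mean_pct_deviation, 0)
  five <- compare_s2(
    data.frame(residue = 1:50, S2 = 0.8 * 1.05),
    data.frame(residue = 1:50, S2 = rep(0.8, 50))
  )
  expect_equal(five$mean_pct_deviation, 5.0, tolerance = 1e-9)
  expect_error(
    compare_s2(md, data.frame(residue = 60:70, S2 = 0.8)),
    "overlap"
  )
})

test_that("matched-dynamics preset keeps simulated and fitted S2 within 9%", {
  gt <- ground_truth(80, "apo")
  d <- gen_relaxation(gt, 700, noise = 0.02, seed = 7)
  mf <- fit_modelfree(d)
  # trajectory-side estimates: cone widths chosen to reproduce the truth
  theta <- acos((-1 + sqrt(1 + 8 * sqrt(gt$S2_true))) / 2)
  md <- data.frame(residue = 1:80, S2 = vapply(seq_len(80), function(i) {
    traj_order_parameter(gen_cone_vectors(theta[i] * 180 / pi, 1500,
      seed = 700 + i
    ))
  }, 0))
  cmp <- compare_s2(md, mf)
  expect_lt(cmp$mean_pct_deviation, 9)
})

test_that("exchange fits recover protection factors and free energies", {
  expect_equal(dG_from_protection(1000, 298), 4.09, tolerance = 1e-2)
  expect_equal(dG_from_protection(1, 298), 0, tolerance = 1e-15)
  # monotone in P
  P <- 10^seq(0, 6, length.out = 13)
  expect_true(all(diff(dG_from_protection(P)) > 0))
  # unprotected residue: P = 1, dG = 0
  ki <- data.frame(residue = 1, k_intr = 0.01)
  curves <- data.frame(
    residue = 1, time_min = c(10, 50, 100, 300, 600),
    intensity = exp(-0.01 * c(10, 50, 100, 300, 600))
  )
  ef <- hdx_fit(curves, ki)
  expect_equal(ef$P, 1, tolerance = 1e-6)
  expect_equal(ef$dG_unfold, 0, tolerance = 1e-6)
})

test_that("protected preset round trip stays within 0.2 kcal/mol", {
  gt <- ground_truth(40)
  d <- gen_hdx(gt, noise = 0.01, seed = 8)
  ef <- hdx_fit(d, attr(d, "k_intr"))
  # residues whose decay is observed: at least two half-lives inside the
  # window and no more than two elapsed before the first timepoint
  tmax <- max(d$time_min)
  ok <- ef$bound == "none" & gt$k_exch_true >= 2 * log(2) / tmax &
    gt$k_exch_true <= log(4) / min(d$time_min)
  expect_gt(sum(ok), 5)
  dg_true <- dG_from_protection(gt$P_true[ef$residue[ok]])
  expect_lt(max(abs(ef$dG_unfold[ok] - dg_true)), 0.2)
  # fitted dG spans the 4-8 kcal/mol window for P in 1e3..1e6
  span <- range(dG_from_protection(c(1e3, 1e6)))
  expect_equal(span, c(4.09, 8.18), tolerance = 1e-2)
})

test_that("non-decaying and fully exchanged curves are flagged as bounds", {
  ki <- data.frame(residue = 1:2, k_intr = c(10, 10))
  tp <- c(5, 30, 120, 600)
  curves <- rbind(
    data.frame(residue = 1, time_min = tp, intensity = c(1, 0.99, 1.01, 0.98)),
    data.frame(residue = 2, time_min = tp, intensity = rep(0.01, 4))
  )
  ef <- hdx_fit(curves, ki)
  expect_equal(ef$bound, c("lower", "upper"))
  expect_gt(ef$P[1], 1e4)
})

test_that("simplified intrinsic rates behave physically", {
  seqs <- c("MET", "ALA", "GLY", "PRO", "LEU", "ASP", "HIS")
  k7 <- intrinsic_rates(seqs, pH = 7)
  expect_true(is.na(k7$k_intr[1])) # N-terminus
  expect_true(is.na(k7$k_intr[4])) # proline
  expect_true(all(k7$k_intr[-c(1, 4)] > 0))
  # base catalysis dominates near neutral pH: rates rise with pH
  k8 <- intrinsic_rates(seqs, pH = 8)
  expect_true(all(k8$k_intr[-c(1, 4)] > k7$k_intr[-c(1, 4)]))
  expect_error(intrinsic_rates(c("ALA", "ZZZ")), "unknown residue")
})

test_that("minimal NMR-STAR reader extracts H/N shift pairs", {
  star <- c(
    "data_synthetic", "save_assigned_chemical_shifts", "loop_",
    "_Atom_chem_shift.ID", "_Atom_chem_shift.Comp_index_ID",
    "_Atom_chem_shift.Comp_ID", "_Atom_chem_shift.Atom_ID",
    "_Atom_chem_shift.Val",
    "1 2 ALA H 8.21", "2 2 ALA N 123.5",
    "3 3 GLY H 8.40", "4 3 GLY N 109.1",
    "5 3 GLY CA 45.2",
    "stop_", "save_"
  )
  f <- tempfile(fileext = ".str")
  writeLines(star, f)
  st <- read_nmrstar_shifts(f)
  expect_equal(st$residue, c(2, 3))
  expect_equal(st$dH_ppm, c(8.21, 8.40))
  expect_equal(st$dN_ppm, c(123.5, 109.1))
  expect_true(all(st$visible))
  unlink(f)
})

test_that("residue tables survive a TSV round trip", {
  gt <- ground_truth(20)
  d <- gen_relaxation(gt, 700, noise = 0.02, seed = 9)
  f <- tempfile(fileext = ".tsv")
  write_residue_table(d, f)
  back <- read_relaxation(f, field_MHz = 700)
  expect_equal(back$R1, d$R1, tolerance = 1e-10)
  expect_equal(attr(back, "field_MHz"), 700)
  unlink(f)
})
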