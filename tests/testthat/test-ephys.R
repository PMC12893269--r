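test_that("Henderson-Hasselbalch bicarbonate follows its closed form", {
  expect_equal(hh_bicarbonate(7.4, 7.4, 26), 26)
  expect_equal(hh_bicarbonate(6.4, 7.4, 26), 2.6)
  expect_equal(hh_bicarbonate(7.2, 7.4, 26), 26 * 10^(-0.2))
  # multiplicative in the extracellular concentration
  expect_equal(hh_bicarbonate(7.2, 7.4, 52), 2 * hh_bicarbonate(7.2, 7.4, 26))
  expect_error(hh_bicarbonate(0, 7.4, 26), "pH")
  expect_error(hh_bicarbonate(7.2, 7.4, -1), "positive")
})

test_that("GHK reversal matches Nernst, brute-force formula and monotonicity", {
  sym <- ion_conditions(cl_i_mM = 130, cl_o_mM = 130, hco3_i_mM = 26,
                        hco3_o_mM = 26, perm_ratio = 0.3)
  expect_equal(ghk_reversal(sym), 0)
  nernst <- ion_conditions(cl_i_mM = 13, cl_o_mM = 130, perm_ratio = 0)
  expect_equal(ghk_reversal(nernst), -60.5, tolerance = 1e-3)
  # independent brute-force evaluation of the same formula
  cc <- ion_conditions(cl_i_mM = 19, cl_o_mM = 133.5)
  rtf <- 1000 * 8.31446261815324 * 305.15 / 96485.33212331
  brute <- rtf * log((19 + 0.3 * cc$hco3_i_mM) / (133.5 + 0.3 * 26))
  expect_equal(ghk_reversal(cc), brute, tolerance = 1e-9)
  # strictly increasing in intracellular chloride
  es <- vapply(c(5, 10, 20, 40, 80), function(cl)
    ghk_reversal(ion_conditions(cl_i_mM = cl, cl_o_mM = 133.5)), numeric(1))
  expect_true(all(diff(es) > 0))
})

test_that("GHK inversion is exact and errors outside its domain", {
  for (cl in c(6, 19, 41)) {
    cc <- ion_conditions(cl_i_mM = cl, cl_o_mM = 133.5)
    expect_equal(invert_ghk_cl(ghk_reversal(cc), cc), cl, tolerance = 1e-9)
  }
  r0 <- ion_conditions(cl_i_mM = 10, cl_o_mM = 130, perm_ratio = 0)
  rtf <- 1000 * 8.31446261815324 * 305.15 / 96485.33212331
  expect_equal(invert_ghk_cl(-40, r0), 130 * exp(-40 / rtf))
  cc <- ion_conditions(cl_i_mM = 19, cl_o_mM = 133.5)
  expect_error(invert_ghk_cl(-150, cc), "admissible")
})

test_that("I-V reversal estimation is exact on lines and unbiased in noise", {
  est <- estimate_reversal_from_iv(c(-70, -50), c(-10, 10), v_rest_mV = -70)
  expect_equal(est$e_gaba_mV, -60)
  expect_equal(est$conductance_nS, 1)
  expect_equal(est$df_mV, 10)
  v5 <- seq(-78.4, -38.4, by = 10)
  est2 <- estimate_reversal_from_iv(v5, 2.5 * (v5 + 48.4))
  expect_equal(est2$e_gaba_mV, -48.4)
  # simulation: sigma = 2 pA, 5 voltages, bias < 1 mV over 1000 replicates
  set.seed(99)
  errs <- vapply(1:1000, function(r) {
    iv <- generate_iv_curve(-55, 1, v_steps_mV = v5, noise_sd_pA = 2)
    estimate_reversal_from_iv(iv$v_mV, iv$i_pA)$e_gaba_mV + 55
  }, numeric(1))
  expect_lt(abs(mean(errs)), 1)
  expect_error(estimate_reversal_from_iv(c(-70, -50), c(5, 5)), "slope")
  neg <- estimate_reversal_from_iv(c(-70, -50), c(10, -10))
  expect_equal(neg$flag, "negative_slope")
})

test_that("Henderson junction potentials match closed forms and symmetry", {
  a <- solution_composition(c("K", "Cl"), c(150, 150))
  expect_equal(ljp_henderson(a, a), 0)
  b <- solution_composition(c("K", "Cl"), c(15, 15))
  # two-ion dilution junction closed form
  uK <- 1; uCl <- 76.31 / 73.48
  rtf <- 1000 * 8.31446261815324 * 298.15 / 96485.33212331
  closed <- rtf * (uK - uCl) / (uK + uCl) * log(150 / 15)
  expect_equal(ljp_henderson(a, b, temperature_K = 298.15), closed,
               tolerance = 0.01 / abs(closed))
  expect_equal(ljp_henderson(b, a), -ljp_henderson(a, b), tolerance = 1e-12)
  # low-mobility anion pipette vs saline bath: positive LJP, ~10-20 mV scale
  pip <- solution_composition(c("K", "gluconate"), c(150, 150))
  bath <- solution_composition(c("Na", "Cl"), c(150, 150))
  v <- ljp_henderson(pip, bath)
  expect_gt(v, 5); expect_lt(v, 25)
  expect_error(ljp_henderson(
    solution_composition("unobtainium", 10, charge = 1, mobility = NULL),
    bath), "mobility table")
})

test_that("passive properties recover from the capacitive transient", {
  tr <- generate_rc_transient(10, 150, -10, fs_hz = 10000)
  est <- rc_from_transient(tr, 10000, -10)
  expect_equal(est$rs_MOhm, 10, tolerance = 0.01)
  expect_equal(est$capacity_pF, 150, tolerance = 0.01)
  # doubling C doubles the estimate and leaves Rs unchanged
  est2 <- rc_from_transient(generate_rc_transient(10, 300, -10, 10000, 0.1),
                            10000, -10)
  expect_equal(est2$capacity_pF / est$capacity_pF, 2, tolerance = 0.02)
  expect_equal(est2$rs_MOhm, est$rs_MOhm, tolerance = 1e-6)
  expect_error(rc_from_transient(rep(0, 100), 10000, -10), "all-zero")
  expect_error(rc_from_transient(tr, 10000, 0), "nonzero")
})

test_that("series-resistance QC uses a strict 20% bound", {
  expect_true(qc_series_resistance(c(10, 11)))
  expect_false(qc_series_resistance(c(10, 12.5)))
  expect_true(qc_series_resistance(c(10, 8)))    # exactly 20% still passes
  expect_error(qc_series_resistance(10), "2")
  expect_error(qc_series_resistance(c(0, 5)), "positive")
})

test_that("tonic currents from all-point histograms are mode differences", {
  set.seed(55)
  n <- 10 * 2000
  a <- rnorm(n, -200, 5)
  t0 <- tonic_from_histogram(a, a, 2000)
  expect_equal(t0$tonic_pA, 0)
  b <- rnorm(n, -170, 5)
  t1 <- tonic_from_histogram(a, b, 2000, capacity_pF = 150,
                             rs_before_MOhm = 8.1, rs_during_MOhm = 8.4)
  expect_lt(abs(t1$tonic_pA - 30), 1)
  expect_equal(t1$density_pA_per_pF, t1$tonic_pA / 150)
  expect_true(t1$qc_pass)
  # equivariance: adding a constant to the during-trace shifts the result
  t2 <- tonic_from_histogram(a, b + 12.34, 2000)
  expect_equal(t2$tonic_pA - t1$tonic_pA, 12.34, tolerance = 1e-9)
  expect_error(tonic_from_histogram(a[1:100], b, 2000), "10 s")
  # two comparable histogram peaks trigger the ambiguity warning
  bim <- c(rnorm(n / 2, -200, 2), rnorm(n / 2, -150, 2))
  expect_warning(tonic_from_histogram(bim, bim, 2000), "ambiguous")
})
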