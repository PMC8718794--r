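test_that("troponin flux follows its mass-action form", {
  p <- list(k_on = 0.0327, k_off = 0.5, b_total = 70)
  # equilibrium occupancy gives zero net flux
  kd <- p$k_off / p$k_on
  for (ca in c(0.1, 1, 10)) {
    b_eq <- p$b_total * ca / (ca + kd)
    expect_equal(troponin_flux(ca, b_eq, p), 0, tolerance = 1e-12)
  }
  # pure unbinding at zero Ca
  expect_equal(troponin_flux(0, 7, p), -3.5)
  # derived equilibrium point: kd = 0.5/0.0327 = 15.29 uM, so at 1 uM
  # the bound fraction is 70/(1 + 15.29)
  expect_equal(kd, 15.29, tolerance = 1e-3)
  expect_equal(70 * 1 / (1 + kd), 4.297, tolerance = 1e-3)

  expect_error(troponin_flux(1, 71, p), class = "alternans_invariant_violation")
  expect_error(troponin_flux(-1, 5, p), class = "alternans_invalid_parameter")
})

test_that("default parameter sets differ only in the troponin off-rate", {
  ctl <- make_default_params("control")
  red <- make_default_params("reduced_koff")
  expect_equal(ctl$troponin$k_off, 0.5)
  expect_equal(red$troponin$k_off, 0.1)
  expect_equal(ctl$troponin$k_on, 0.0327)
  expect_equal(ctl$serca$kd, 0.25)
  ctl$troponin$k_off <- red$troponin$k_off
  ctl$variant <- red$variant
  expect_identical(ctl, red)

  full <- make_default_params("control", scale = "full")
  expect_equal(full$lattice$nx * full$lattice$ny * full$lattice$nz, 20000)
})

test_that("a quiescent equilibrated closed cell is a fixed point", {
  p <- tiny_params()
  st <- new_cell_state(p)
  # relax deterministically to the closed-cell equilibrium first
  st <- step_cell(st, p, t_ms = 3000, stochastic = FALSE)
  before <- state_concentrations(st, p)
  st2 <- step_cell(st, p, t_ms = 50, stochastic = FALSE)
  after <- state_concentrations(st2, p)
  expect_equal(after$ca_cyto, before$ca_cyto, tolerance = 1e-6)
  expect_equal(after$ca_trpn, before$ca_trpn, tolerance = 1e-6)
  expect_equal(after$ca_nsr, before$ca_nsr, tolerance = 1e-4)
})

test_that("troponin occupancy relaxes to its closed-form equilibrium", {
  p <- tiny_params()
  st <- new_cell_state(p)
  st <- step_cell(st, p, t_ms = 2000, stochastic = FALSE)
  cc <- state_concentrations(st, p)
  kd <- p$troponin$k_off / p$troponin$k_on
  b_pred <- p$troponin$b_total * cc$ca_cyto / (cc$ca_cyto + kd)
  expect_equal(cc$ca_trpn, b_pred, tolerance = 1e-6)
  expect_true(all(cc$ca_trpn >= 0 & cc$ca_trpn <= p$troponin$b_total))
})

test_that("closed-cell stochastic runs conserve total calcium", {
  p <- tiny_params()
  tr <- run_closed(p, 2000, seed = 1)
  expect_lt(check_conservation(tr), 1e-10)

  # opening a constant efflux makes total Ca fall monotonically
  p2 <- p
  p2$other_fluxes$background_influx <- 0
  p2$other_fluxes$trigger_flux <- 0
  st <- new_cell_state(p2)
  out <- alternans:::cru_run_cpp(alternans:::par_flat(p2), numeric(0), 500,
                                 1L, FALSE, 10, unclass(st), FALSE)
  expect_true(all(diff(out$total_ca) < 0))
})

test_that("identical seeds reproduce identical trajectories", {
  p <- tiny_params()
  a <- quiet_paced(p, pacing_protocol(300, 4, 2), seed = 11)
  b <- quiet_paced(p, pacing_protocol(300, 4, 2), seed = 11)
  expect_identical(a$ca, b$ca)
  expect_identical(a$peaks, b$peaks)
  c <- quiet_paced(p, pacing_protocol(300, 4, 2), seed = 12)
  expect_false(identical(a$ca, c$ca))
})

test_that("halving the time step changes per-beat peaks by less than 1 percent", {
  p <- make_default_params("control")
  a <- quiet_paced(p, pacing_protocol(400, 8, 6), seed = 3)
  p2 <- p; p2$dt <- p$dt / 2
  b <- quiet_paced(p2, pacing_protocol(400, 8, 6), seed = 3)
  expect_lt(abs(mean(b$peaks) / mean(a$peaks) - 1), 0.01)
})

test_that("pacing protocol and scan inputs are validated", {
  expect_error(pacing_protocol(-100), class = "alternans_invalid_parameter")
  expect_error(pacing_protocol(400, 5, 5), class = "alternans_invalid_parameter")
  p <- tiny_params()
  expect_error(scan_pcl(p, numeric(0)), class = "alternans_invalid_parameter")
})

test_that("a single-PCL scan reduces to one paced run plus a flag", {
  p <- make_default_params("control")
  bif <- scan_pcl(p, 500, protocol = pacing_protocol(500, 8, 6), seeds = 5L)
  expect_equal(nrow(bif$table), 1)
  tr <- quiet_paced(p, pacing_protocol(500, 8, 6), seed = 5L)
  last2 <- tail(tr$peaks, 2)
  expect_equal(c(bif$table$peak1, bif$table$peak2), last2)
  expect_identical(bif$table$flag,
                   abs(diff(last2)) / mean(last2) > bif$threshold)
})
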