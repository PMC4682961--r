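test_that("parameter constructors validate and apply multipliers", {
  p <- myocyte_params(c(I_CaL = 4, I_Kr = 0.21))
  expect_equal(unname(p$multipliers["I_CaL"]), 4)
  expect_equal(unname(p$multipliers["I_Kr"]), 0.21)
  expect_true(all(p$multipliers[setdiff(names(p$multipliers),
                                        c("I_CaL", "I_Kr"))] == 1))
  expect_error(myocyte_params(c(I_CaL = -1)), "> 0")
  expect_error(myocyte_params(c(bogus = 2)), "subset")
  expect_error(myocyte_params(membrane_capacitance = 0), "> 0")
  expect_error(make_ead_parameters("type-I", g_cal_mult = 0), "> 0")

  # type-I defaults are the study's stated multipliers
  p1 <- make_ead_parameters("type-I")
  expect_equal(unname(p1$multipliers[c("I_CaL", "I_Kr")]), c(4, 0.21))
  # identity multipliers give control parameters
  pid <- make_ead_parameters("type-I", 1, 1)
  expect_equal(pid$multipliers, myocyte_params()$multipliers)
  # type-II has a lower G_Kr than type-I
  p2 <- make_ead_parameters("type-II")
  expect_lt(p2$multipliers["I_Kr"], 0.21)
})

test_that("gap and fibroblast currents follow their closed forms", {
  expect_equal(gap_current(-80, -80, 8), 0)
  expect_equal(gap_current(0, -30, 8), 240)   # 8 nS x 30 mV = 240 pA
  expect_equal(gap_current(37, -12, 0), 0)
  expect_error(gap_current(0, 0, -1), ">= 0")

  fp <- fibroblast_params(-30, g_f = 4)
  expect_equal(fibroblast_current(-30, fp), 0)     # Vf = Ef
  expect_equal(fibroblast_current(0, fp), 120)     # 4 nS x 30 mV
  pw <- fibroblast_params(-35, model = "piecewise")
  expect_equal(fibroblast_current(-25, pw), 2 * 10)  # low branch
  expect_equal(fibroblast_current(-10, pw), 4 * 25)  # high branch
  expect_error(fibroblast_params(-30, g_f = 0), "> 0")
})

test_that("ionic_rhs sums exactly the 14 roster currents and scales linearly", {
  s <- initial_state()
  r <- ionic_rhs(s)
  expect_named(r$currents, eadclump:::CURRENT_NAMES)
  expect_equal(r$i_ion, sum(r$currents))
  expect_true(all(is.finite(r$currents)))

  # doubling one multiplier doubles exactly that component at fixed state
  r2 <- ionic_rhs(s, myocyte_params(c(I_Kr = 2)))
  expect_equal(r2$currents["I_Kr"], 2 * r$currents["I_Kr"])
  others <- setdiff(names(r$currents), "I_Kr")
  expect_equal(r2$currents[others], r$currents[others])

  expect_error(ionic_rhs(rep(NA_real_, 35)), "finite")
})

test_that("control myocyte has a quiescent steady state", {
  srest <- cached("rested_control", resting_state())
  r <- ionic_rhs(srest)
  expect_lt(abs(r$i_ion), 0.05)
  # rest stability: < 1 mV drift over a further 1000 ms
  u <- composite_unit(state = srest)
  tr <- simulate_cell(u, stimulus_protocol(NULL, 0, 1, Inf, 1e9),
                      duration_ms = 1000)
  expect_lt(max(abs(tr$vm_mV - tr$vm_mV[1])), 1)
})

test_that("composite stepping respects the coupling bookkeeping", {
  srest <- cached("rested_control", resting_state())
  fp <- fibroblast_params(-20)
  u <- composite_unit(myocyte_params(), fp, g_gap = 8, state = srest,
                      vf = -60)
  dt <- 0.02
  igap <- gap_current(u$state[["v"]], u$vf, u$g_gap)
  If <- fibroblast_current(u$vf, fp)
  u1 <- step_composite(u, dt = dt)
  # fibroblast update is exactly (Igap - If)/Cf forward Euler
  expect_equal(u1$vf, u$vf + dt * (igap - If) / fp$c_f, tolerance = 1e-12)
  # myocyte's gap contribution is -Igap/Cm: compare against g_gap = 0 step
  u0 <- u; u0$g_gap <- 0; u0$fibroblast <- NULL; u0$vf <- NA_real_
  u0 <- step_composite(u0, dt = dt)
  dv_gap <- u1$state[["v"]] - u0$state[["v"]]
  expect_equal(dv_gap, -dt * igap / 185, tolerance = 1e-12)
  # charge antisymmetry: Cm dVm(gap) = -Cf dVf(gap)
  dvf_gap <- u1$vf - (u$vf + dt * (-If) / fp$c_f)
  expect_equal(185 * dv_gap, -fp$c_f * dvf_gap, tolerance = 1e-10)
})

test_that("uncoupled fibroblast relaxes to E_f with time constant C_f/G_f", {
  fp <- fibroblast_params(-35, g_f = 4, c_f = 6.3)
  u <- composite_unit(myocyte_params(), fp, g_gap = 0, vf = -80)
  tau <- fp$c_f / fp$g_f # 1.575 ms
  tr <- simulate_cell(u, stimulus_protocol(NULL, 0, 1, Inf, 1e9),
                      duration_ms = 10, dt = 0.005, sample_ms = 0.005)
  vf <- tr$vf_mV
  expect_true(all(diff(vf) >= 0))                 # monotone toward E_f
  k <- which.min(abs(tr$time_ms - tau))
  frac <- (vf[k] - fp$e_f) / (vf[1] - fp$e_f)
  expect_equal(frac, exp(-1), tolerance = 0.02)
})

test_that("g_gap = 0 composite is bitwise identical to the isolated myocyte", {
  p1 <- make_ead_parameters("type-I")
  iso <- simulate_cell(composite_unit(p1), cell_pacing(),
                       duration_ms = 3000)
  cmp <- simulate_cell(composite_unit(p1, fibroblast_params(-35), g_gap = 0),
                       cell_pacing(), duration_ms = 3000)
  expect_identical(iso$vm_mV, cmp$vm_mV)
})

test_that("control pacing yields normal APs and halving dt moves APD < 1%", {
  tr <- control_trace()
  aps <- detect_aps(tr)
  expect_equal(nrow(aps), 5)
  expect_true(all(aps$repolarized))
  expect_true(all(classify_ap(aps) == "normal"))
  expect_equal(sum(aps$n_eads), 0)

  apd_at <- function(dt) {
    t2 <- simulate_cell(composite_unit(), cell_pacing(pcl = Inf),
                        duration_ms = 600, dt = dt, sample_ms = 0.5)
    detect_aps(t2)$apd_ms[1]
  }
  expect_lt(abs(apd_at(0.01) - apd_at(0.02)) / apd_at(0.02), 0.01)
})

test_that("state invariants hold over 15 s of paced type-I simulation", {
  tr <- cached("comp_iso_0",
               simulate_cell(composite_unit(make_ead_parameters("type-I")),
                             cell_pacing(), duration_ms = 15000))
  s <- attr(tr, "unit")$state
  gates <- s[c("m", "h", "j", "a", "iF", "iS", "ap", "iFp", "iSp", "d",
               "ff", "fs", "fcaf", "fcas", "jca", "nca", "ffp", "fcafp",
               "xrf", "xrs", "xs1", "xs2", "xk1")]
  expect_true(all(gates >= 0 & gates <= 1))
  concs <- s[c("nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr")]
  expect_true(all(concs > 0))
  expect_true(all(is.finite(s)))
  expect_true(s[["v"]] > -150 && s[["v"]] < 100)
})

test_that("single-cell phenotypes match the stated EAD classes", {
  cls1 <- classify_ap(detect_aps(typeI_trace()))
  expect_true("type-I" %in% cls1)
  expect_false("type-II" %in% cls1)
  cls2 <- classify_ap(detect_aps(typeII_trace()))
  expect_true("type-II" %in% cls2)
  # type-II: decaying oscillations, elevated final potential
  aps2 <- detect_aps(typeII_trace())
  e <- attr(aps2, "eads")[[which(cls2 == "type-II")[1]]]
  expect_gte(nrow(e), 2)
  expect_lt(tail(e$amplitude_mV, 1), e$amplitude_mV[1])
})
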