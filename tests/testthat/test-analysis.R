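# synthetic AP: resting -85, square-ish depolarization with optional
# EAD bumps during repolarization
synth_ap <- function(dt = 1, bumps = numeric(0), bump_w = 12,
                     apd = 300, t_up = 100, total = 1000, rest = -85) {
  t <- seq(0, total, by = dt)
  v <- rep(rest, length(t))
  plateau <- t >= t_up & t < t_up + apd
  v[plateau] <- 20 - 80 * (t[plateau] - t_up) / apd
  for (k in seq_along(bumps)) {
    tc <- t_up + apd * (0.3 + 0.15 * k)
    v <- v + bumps[k] * exp(-((t - tc) / bump_w)^2)
  }
  data.frame(time_ms = t, vm_mV = v)
}

test_that("detect_aps: empty, counting and features", {
  flat <- data.frame(time_ms = 0:500, vm_mV = rep(-85, 501))
  expect_equal(nrow(detect_aps(flat)), 0)

  one <- synth_ap()
  aps <- detect_aps(one)
  expect_equal(nrow(aps), 1)
  expect_true(aps$repolarized)
  expect_equal(aps$rest_mV, -85, tolerance = 0.5)
  expect_equal(aps$n_eads, 0)

  expect_error(detect_aps(data.frame(time_ms = 1:3, vm_mV = c(1, NA, 2))),
               "finite")
})

test_that("detect_eads: monotone segments, planted and decaying bumps", {
  # monotonic repolarization -> no EADs
  t <- 0:300
  expect_equal(nrow(detect_eads(t, 30 - 0.3 * t)), 0)

  # damped oscillation riding a plateau -> strictly decreasing amplitudes
  v <- -20 + 12 * exp(-t / 150) * cos(2 * pi * t / 60)
  e <- detect_eads(t, v)
  expect_gte(nrow(e), 3)
  expect_true(all(diff(e$amplitude_mV) < 0))

  # prominence threshold filters small ripples
  v2 <- 30 - 0.3 * t + 0.3 * sin(2 * pi * t / 40)
  expect_equal(nrow(detect_eads(t, v2, prominence = 1)), 0)
})

test_that("classify_ap on constructed phenotypes", {
  expect_equal(classify_ap(detect_aps(synth_ap())), "normal")
  # growing bumps, full repolarization -> type-I
  grow <- synth_ap(bumps = c(8, 14, 22))
  expect_equal(classify_ap(detect_aps(grow)), "type-I")
  # decaying bumps with elevated final potential -> type-II
  tt <- seq(0, 1000, by = 1)
  v <- ifelse(tt < 100, -85, -20 + 14 * exp(-(tt - 100) / 250) *
                               cos(2 * pi * (tt - 100) / 120))
  decay <- data.frame(time_ms = tt, vm_mV = v)
  expect_equal(classify_ap(detect_aps(decay)), "type-II")
})

test_that("classification is invariant to time shifts and 2x resampling", {
  tr <- typeI_trace()
  base <- classify_ap(detect_aps(tr))
  shifted <- data.frame(time_ms = tr$time_ms + 137.5, vm_mV = tr$vm_mV)
  expect_equal(classify_ap(detect_aps(shifted)), base)
  up <- approx(tr$time_ms, tr$vm_mV, xout = seq(0, max(tr$time_ms), by = 0.5))
  up2 <- data.frame(time_ms = up$x, vm_mV = up$y)
  expect_equal(classify_ap(detect_aps(up2)), base)
})

test_that("conduction_velocity validates its inputs", {
  expect_equal(conduction_velocity(c(10, 20), 0.65), 65)
  expect_error(conduction_velocity(c(10, NA), 1), "finite")
  expect_error(conduction_velocity(c(10, 20), 0), "distinct")
  expect_error(conduction_velocity(c(10, 10), 1), "equal")
})

test_that("CV scales as sqrt(D) on control cables", {
  # dx = 0.01 cm: at quarter coupling the upstroke spans so few 0.02 cm
  # cells that lattice discreteness depresses CV beyond the continuum
  # sqrt(D) law; the refined grid restores the physical scaling
  cv1 <- cable_cv(control_cable_run(dx = 0.01))
  for (alpha in c(0.25, 0.49)) {
    cva <- cable_cv(control_cable_run(dscale = alpha, dx = 0.01))
    expect_equal(cva / cv1, sqrt(alpha), tolerance = 0.1)
  }
})

test_that("count_pvcs attribution on constructed traces", {
  # 3 sensors, paced upstrokes at 100/1100/2100 (+delay), one ectopic
  # wavefront at ~1600 seen by all sensors within 40 ms
  t <- seq(0, 3000, by = 1)
  mk <- function(times) {
    v <- rep(-85, length(t))
    for (tt in times) v[t >= tt & t <= tt + 120] <- 10
    v
  }
  tr <- cbind(mk(c(110, 1110, 2110, 1600)),
              mk(c(140, 1140, 2140, 1620)),
              mk(c(170, 1170, 2170, 1640)))
  rep <- count_pvcs(tr, time = t, pacing_times = c(100, 1100, 2100),
                    delay_ms = 300)
  expect_equal(rep$n, 1)
  expect_equal(rep$events$time_ms, 1600, tolerance = 2)

  # additivity over disjoint windows
  n1 <- count_pvcs(tr, time = t, pacing_times = c(100, 1100, 2100),
                   delay_ms = 300, window = c(0, 1500))$n
  n2 <- count_pvcs(tr, time = t, pacing_times = c(100, 1100, 2100),
                   delay_ms = 300, window = c(1500.5, 3000))$n
  expect_equal(n1 + n2, rep$n)

  # all-attributed -> zero
  tr0 <- tr[, 1:2]
  rep0 <- count_pvcs(mk(c(110, 1110, 2110)), time = t,
                     pacing_times = c(100, 1100, 2100), delay_ms = 300)
  expect_equal(rep0$n, 0)
})

test_that("averaged spectrum: pure tone, Parseval, pacing fundamental", {
  dt <- 0.002  # s
  t <- seq(0, 10 - dt, by = dt)
  x <- sin(2 * pi * 5 * t)
  tr <- cbind(x, x, x, x)
  sp <- averaged_power_spectrum(tr, time = t * 1000, window = c(0, 1e4))
  expect_equal(sp$peaks$freq_hz[1], 5, tolerance = 0.01)
  expect_equal(nrow(sp$peaks[sp$peaks$power > 0.01 * max(sp$peaks$power), ]),
               1)

  # Parseval within 1% on random signals
  set.seed(42)
  y <- rnorm(2048)
  spy <- averaged_power_spectrum(cbind(y), time = seq_along(y),
                                 window = range(seq_along(y)))
  expect_equal(sum(spy$power), mean((y - mean(y))^2), tolerance = 0.01)

  # paced cable at PCL 1000 -> 1 Hz fundamental with harmonics
  run <- pattern_run("A")
  sp2 <- averaged_power_spectrum(run$traces, time = run$time,
                                 window = c(0, 10000))
  f0 <- sp2$peaks$freq_hz[which.max(sp2$peaks$power)]
  expect_lt(abs(f0 - round(f0)), 0.05)  # 1 Hz or a harmonic
  expect_true(any(abs(sp2$peaks$freq_hz - 1) < 0.05))

  expect_warning(averaged_power_spectrum(cbind(y[1:100]),
                                         time = seq_len(100) * 10,
                                         window = c(0, 1000)), "short")
})

test_that("index_peaks: worked examples", {
  r <- index_peaks(c(2, 4, 6))
  expect_equal(r$classification, "periodic")
  expect_equal(r$omega1, 2, tolerance = 1e-9)

  expect_equal(index_peaks(4.38)$classification, "periodic")

  # the quasiperiodic peak set {w2-w1, w1, w2, w1+w2}
  w1 <- 2.73; w2 <- 3.64
  r2 <- index_peaks(c(w2 - w1, w1, w2, w1 + w2))
  expect_equal(r2$classification, "quasiperiodic")
  expect_equal(r2$omega1, w1, tolerance = 0.02 * w1)
  expect_equal(r2$omega2, w2, tolerance = 0.02 * w2)
  expect_true(all(abs(r2$table$residual) <= 0.02 * w1))

  expect_equal(index_peaks(numeric(0))$classification, "other")
})

test_that("index_peaks recovers planted two-tone bases over 100 draws", {
  w1 <- 2.73; w2 <- 3.64
  ok <- 0
  for (s in 1:100) {
    set.seed(s)
    # peak frequencies with up to 0.5% measurement jitter
    f <- c(w2 - w1, w1, w2, w1 + w2, 2 * w1, 2 * w2)
    f <- f * (1 + rnorm(length(f), 0, 0.002))
    r <- index_peaks(f)
    if (r$classification == "quasiperiodic" &&
        abs(r$omega1 - w1) < 0.02 * w1 &&
        abs(r$omega2 - w2) < 0.02 * w2) ok <- ok + 1
  }
  expect_gte(ok, 95)
})
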